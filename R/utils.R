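# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without clobbering the caller's
# random stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv(), inherits = FALSE)
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Fan a global seed out to a per-stage seed, kept inside 32-bit range.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483587 + 1)
}

nd_log <- function(...) {
  message(sprintf(...))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
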