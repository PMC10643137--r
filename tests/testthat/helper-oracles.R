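# Independent brute-force oracles used to validate the implementation.
# These deliberately use naive algorithms (enumeration, per-base masks)
# so they share no code path with the package.

# quick trajectory builder
mk_traj <- function(pos, dt = 0.02, id = "t", frames = NULL) {
  pos <- as.matrix(pos)
  trajectory(id, dt, frames %||% (seq_len(nrow(pos)) - 1L), pos)
}
if (!exists("%||%")) `%||%` <- function(a, b) if (is.null(a)) b else a

.permutations <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) for (p in .permutations(v[-i]))
    out[[length(out) + 1]] <- c(v[i], p)
  out
}

# Exhaustive minimal-distance matching between two point sets under a
# distance cap. Returns a 2-column matrix of (i, j) pairs that maximizes
# the number of links and, among those, minimizes total distance.
oracle_match <- function(A, B, max_jump) {
  nA <- nrow(A); nB <- nrow(B)
  D <- as.matrix(dist(rbind(A, B)))[seq_len(nA), nA + seq_len(nB), drop = FALSE]
  best <- matrix(integer(0), 0, 2, dimnames = list(NULL, c("i", "j")))
  best_key <- c(0, 0)
  for (k in seq_len(min(nA, nB))) {
    for (sa in combn(seq_len(nA), k, simplify = FALSE)) {
      for (sb in combn(seq_len(nB), k, simplify = FALSE)) {
        for (pb in .permutations(sb)) {
          d <- D[cbind(sa, pb)]
          if (any(d > max_jump)) next
          key <- c(k, sum(d))
          if (key[1] > best_key[1] ||
              (key[1] == best_key[1] && key[2] < best_key[2])) {
            best_key <- key
            best <- cbind(i = sa, j = pb)
          }
        }
      }
    }
  }
  best
}

# Chain per-frame-pair oracle matchings into full track index paths.
oracle_link <- function(locs, max_jump) {
  frames <- sort(unique(locs$frame))
  rows_by_frame <- split(seq_len(nrow(locs)), locs$frame)
  axes <- intersect(c("x", "y", "z"), names(locs))
  tracks <- lapply(rows_by_frame[[as.character(frames[1])]], function(r) r)
  for (fi in seq_along(frames)[-1]) {
    prev_rows <- vapply(tracks, function(tr) tr[length(tr)], 0L)
    alive <- locs$frame[prev_rows] == frames[fi] - 1L
    cur <- rows_by_frame[[as.character(frames[fi])]]
    A <- as.matrix(locs[prev_rows[alive], axes, drop = FALSE])
    B <- as.matrix(locs[cur, axes, drop = FALSE])
    m <- if (nrow(A) && nrow(B)) oracle_match(A, B, max_jump) else
      matrix(integer(0), 0, 2)
    used_b <- logical(length(cur))
    alive_idx <- which(alive)
    if (nrow(m)) for (r in seq_len(nrow(m))) {
      ti <- alive_idx[m[r, 1]]
      tracks[[ti]] <- c(tracks[[ti]], cur[m[r, 2]])
      used_b[m[r, 2]] <- TRUE
    }
    for (b in cur[!used_b]) tracks[[length(tracks) + 1]] <- b
  }
  Filter(function(tr) length(tr) >= 2, tracks)
}

# Per-base oracle for the RE pipeline: merge peaks with gap < merge_gap,
# drop merged peaks shorter than min_len, drop peaks overlapping promoters.
oracle_re_pipeline <- function(peaks, promoters, size, merge_gap = 500L,
                               min_len = 500L) {
  peaks <- peaks[order(peaks$start), , drop = FALSE]
  merged <- list()
  cur <- c(peaks$start[1], peaks$end[1])
  if (nrow(peaks) > 1) for (i in 2:nrow(peaks)) {
    if (peaks$start[i] - cur[2] < merge_gap) {
      cur[2] <- max(cur[2], peaks$end[i])
    } else {
      merged[[length(merged) + 1]] <- cur
      cur <- c(peaks$start[i], peaks$end[i])
    }
  }
  merged[[length(merged) + 1]] <- cur
  merged <- Filter(function(iv) iv[2] - iv[1] >= min_len, merged)
  if (nrow(promoters)) {
    pmask <- logical(size)
    for (r in seq_len(nrow(promoters)))
      pmask[(promoters$start[r] + 1):min(promoters$end[r], size)] <- TRUE
    merged <- Filter(function(iv) !any(pmask[(iv[1] + 1):min(iv[2], size)]), merged)
  }
  if (!length(merged)) return(data.frame(start = integer(0), end = integer(0)))
  do.call(rbind, lapply(merged, function(iv)
    data.frame(start = iv[1], end = iv[2])))
}

# Per-base mean-signal oracle
oracle_activity <- function(re, signal, size) {
  base <- numeric(size)
  for (r in seq_len(nrow(signal)))
    base[(signal$start[r] + 1):min(signal$end[r], size)] <- signal$score[r]
  vapply(seq_len(nrow(re)), function(r)
    mean(base[(re$start[r] + 1):min(re$end[r], size)]), numeric(1))
}
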