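#' Binned Hi-C contact matrix in sparse triplet form
#'
#' Stores per-chromosome `(bin_i, bin_j, value)` triplets at a fixed bin
#' size (default 5 kb, the resolution the activity-by-contact model uses).
#' Bins are 0-based; the matrix is symmetric on access (triplets are
#' canonicalized to `bin_i <= bin_j`).
#'
#' @param triplets data frame with columns `chrom`, `bin_i`, `bin_j`,
#'   `value` (values >= 0).
#' @param bin_size bin size in bp.
#' @param chrom_sizes named numeric vector of chromosome lengths in bp.
#' @param normalization free-text tag recording how values were normalized.
#' @return Object of class `nd_contact_matrix`.
#' @export
contact_matrix <- function(triplets, bin_size = 5000L, chrom_sizes,
                           normalization = "raw") {
  stopifnot(all(c("chrom", "bin_i", "bin_j", "value") %in% names(triplets)))
  if (any(triplets$value < 0)) stop("contact values must be >= 0")
  if (is.null(names(chrom_sizes))) stop("chrom_sizes must be named")
  i <- pmin(triplets$bin_i, triplets$bin_j)
  j <- pmax(triplets$bin_i, triplets$bin_j)
  tri <- data.frame(chrom = as.character(triplets$chrom),
                    bin_i = as.integer(i), bin_j = as.integer(j),
                    value = as.numeric(triplets$value),
                    stringsAsFactors = FALSE)
  nbins <- ceiling(chrom_sizes / bin_size)
  bad <- tri$bin_i < 0 | tri$bin_j >= nbins[tri$chrom] | is.na(nbins[tri$chrom])
  if (any(bad)) stop("bin indices outside chromosome length for ",
                     sum(bad), " triplet(s)")
  # collapse duplicates arising from symmetrization
  key <- paste(tri$chrom, tri$bin_i, tri$bin_j)
  if (anyDuplicated(key)) {
    tri <- aggregate(value ~ chrom + bin_i + bin_j, tri, sum)
  }
  structure(list(triplets = tri, bin_size = as.integer(bin_size),
                 chrom_sizes = chrom_sizes, normalization = normalization),
            class = "nd_contact_matrix")
}

#' @export
print.nd_contact_matrix <- function(x, ...) {
  cat(sprintf("<nd_contact_matrix> %d kb bins, %d triplets, %d chromosome(s), normalization '%s'\n",
              x$bin_size %/% 1000L, nrow(x$triplets), length(x$chrom_sizes),
              x$normalization))
  invisible(x)
}

#' Read/write a contact matrix as TSV triplets with a JSON header sidecar
#'
#' The triplet file has columns `chrom, bin_i, bin_j, value`; the sidecar
#' (`<path>.json`) records the bin size, chromosome sizes and the
#' normalization tag.
#'
#' @param cm an [contact_matrix()].
#' @param path triplet TSV path.
#' @return `write_contact_matrix` returns `path` invisibly;
#'   `read_contact_matrix` returns the reconstructed matrix.
#' @export
write_contact_matrix <- function(cm, path) {
  df <- cm$triplets
  df$value <- sprintf("%.17g", df$value)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(bin_size = cm$bin_size,
         chrom_sizes = as.list(cm$chrom_sizes),
         normalization = cm$normalization),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_contact_matrix
#' @export
read_contact_matrix <- function(path) {
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- read.delim(path, sep = "\t", header = TRUE,
                   colClasses = c("character", "integer", "integer", "numeric"))
  contact_matrix(df, bin_size = hdr$bin_size,
                 chrom_sizes = unlist(hdr$chrom_sizes),
                 normalization = hdr$normalization)
}

# mean contact per genomic distance over all possible intra-chromosomal
# bin pairs (absent triplets count as 0)
.decay_curve <- function(cm, max_dist = 5e6) {
  tri <- cm$triplets
  tri <- tri[tri$bin_i != tri$bin_j, , drop = FALSE]
  sep <- tri$bin_j - tri$bin_i
  max_sep <- floor(max_dist / cm$bin_size)
  sep_sum <- tapply(tri$value[sep <= max_sep], sep[sep <= max_sep], sum)
  nbins <- ceiling(cm$chrom_sizes / cm$bin_size)
  out <- data.frame(sep = seq_len(max_sep))
  out$n_pairs <- vapply(out$sep, function(s) sum(pmax(nbins - s, 0)), numeric(1))
  out$total <- 0
  got <- as.integer(names(sep_sum))
  out$total[match(got, out$sep)] <- as.numeric(sep_sum)
  out <- out[out$n_pairs > 0, , drop = FALSE]
  out$distance <- out$sep * cm$bin_size
  out$mean_contact <- out$total / out$n_pairs
  out
}

#' Fit the contact distance-decay exponent
#'
#' Contact frequency decays as a power law of genomic distance,
#' `C ~ d^-gamma`; `gamma` is the negative slope of the least-squares line
#' through `log(mean contact)` vs `log(distance)` over the configured
#' distance range.
#'
#' @param cm an [contact_matrix()].
#' @param range distance range in bp (default 10 kb to 5 Mb).
#' @return Object of class `nd_gamma_fit`: `gamma`, `intercept` (natural
#'   log scale), `n_bins` used, and the decay curve table.
#' @export
fit_gamma <- function(cm, range = c(1e4, 5e6)) {
  if (range[1] >= range[2]) stop("empty distance range")
  curve <- .decay_curve(cm, max_dist = range[2])
  use <- curve$distance >= range[1] & curve$distance <= range[2] &
    curve$mean_contact > 0
  if (sum(use) < 10L)
    stop("need >= 10 distance bins with positive mean contact, got ", sum(use))
  fit <- lm(log(mean_contact) ~ log(distance), data = curve[use, ])
  structure(list(gamma = -unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 n_bins = sum(use), range = range, curve = curve),
            class = "nd_gamma_fit")
}

#' @export
print.nd_gamma_fit <- function(x, ...) {
  cat(sprintf("<nd_gamma_fit> gamma = %.4f over %g-%g bp (%d distance bins)\n",
              x$gamma, x$range[1], x$range[2], x$n_bins))
  invisible(x)
}

# expected contact at distance d under the fitted decay curve
.decay_expectation <- function(gamma_fit, d) {
  d <- pmax(d, 1)
  exp(gamma_fit$intercept - gamma_fit$gamma * log(d))
}

# marginal coverage per bin (sum of all triplet values touching the bin;
# diagonal entries counted once)
.bin_coverage <- function(cm) {
  tri <- cm$triplets
  off <- tri$bin_i != tri$bin_j
  ids <- c(paste(tri$chrom, tri$bin_i), paste(tri$chrom[off], tri$bin_j[off]))
  vals <- c(tri$value, tri$value[off])
  tapply(vals, ids, sum)
}

#' Contact frequency between two bins, with power-law imputation
#'
#' Returns the observed (normalized) matrix value for a well-covered bin
#' pair. A pair is poorly covered when either anchoring bin's marginal
#' coverage falls below the `coverage_quantile` of all bin marginals; for
#' such pairs (and pairs with no recorded contact in a poorly covered
#' region) the value is imputed from the fitted power-law decay curve at
#' the pair's genomic distance, so imputation is continuous in distance.
#' Trans (inter-chromosomal) pairs are excluded from the candidate set
#' and return `NA`.
#'
#' @param cm an [contact_matrix()].
#' @param chrom chromosome of both bins.
#' @param bin_p,bin_r 0-based bin indices.
#' @param gamma_fit an [fit_gamma()] result for this matrix.
#' @param coverage_quantile marginal-coverage quantile below which a bin is
#'   poorly covered (default 0.05).
#' @return A list: `value`, `imputed` flag, `distance` (bp). `value` is
#'   `NA` for a trans pair.
#' @export
get_contact <- function(cm, chrom, bin_p, bin_r, gamma_fit,
                        coverage_quantile = 0.05) {
  if (length(chrom) != 1L) stop("one pair at a time; chrom must be scalar")
  d <- abs(bin_r - bin_p) * cm$bin_size
  cov <- .bin_coverage(cm)
  thr <- quantile(cov, coverage_quantile, names = FALSE)
  kp <- paste(chrom, bin_p); kr <- paste(chrom, bin_r)
  poor <- is.na(cov[kp]) || is.na(cov[kr]) || cov[kp] < thr || cov[kr] < thr
  if (poor) {
    return(list(value = .decay_expectation(gamma_fit, d), imputed = TRUE,
                distance = d))
  }
  i <- min(bin_p, bin_r); j <- max(bin_p, bin_r)
  tri <- cm$triplets
  hit <- which(tri$chrom == chrom & tri$bin_i == i & tri$bin_j == j)
  val <- if (length(hit)) sum(tri$value[hit]) else 0
  list(value = val, imputed = FALSE, distance = d)
}
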