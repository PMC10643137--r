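#' Simulate a toy genome for activity-by-contact analysis
#'
#' Builds a small synthetic genome with everything the ABC module
#' consumes: a TSS table, H3K4me3 peaks over (most) promoters, per-
#' condition H3K27ac peak sets and per-base signal, and per-condition
#' 5 kb contact matrices whose mean contact decays as a power law of
#' distance (`C ~ d^-gamma`) with optional Poisson sampling noise.
#' Optionally, specific promoter-element pairs can be "planted" with
#' boosted activity and contact so that end-to-end link calling has known
#' positives. RE coordinates are shared between conditions so link IDs
#' are comparable.
#'
#' @param seed integer seed.
#' @param chrom_size chromosome length in bp (single chromosome `"chrT"`).
#' @param bin_size contact bin size in bp.
#' @param n_genes number of genes (one TSS each).
#' @param n_enhancers number of intergenic H3K27ac peaks per condition.
#' @param gamma decay exponent of the contact power law.
#' @param contact_scale contact at 1 bin distance.
#' @param noise `"poisson"` to draw Poisson counts around the power-law
#'   expectation, `"none"` for the exact expectation.
#' @param planted optional data frame with columns `gene` (gene index),
#'   `enhancer` (enhancer index), `boost` (multiplier applied to the
#'   planted pair's contact) — applied to the WT condition.
#' @return List with `tss`, `h3k4me3`, and per-condition (`WT`, `KO`)
#'   lists holding `h3k27ac`, `signal`, `contacts`
#'   (an [contact_matrix()]); plus `meta`.
#' @export
simulate_toy_genome <- function(seed = 1L, chrom_size = 2e6, bin_size = 5000L,
                                n_genes = 12L, n_enhancers = 30L,
                                gamma = 1.0, contact_scale = 100,
                                noise = c("poisson", "none"),
                                planted = NULL) {
  noise <- match.arg(noise)
  with_seed(derive_seed(seed, "toygenome"), {
    chrom <- "chrT"
    n_bins <- as.integer(ceiling(chrom_size / bin_size))
    # gene TSS spread over the chromosome, away from the edges
    tss_pos <- sort(as.integer(round(seq(0.05, 0.95, length.out = n_genes) *
                                       chrom_size))) +
      sample(-2000:2000, n_genes, replace = TRUE)
    tss <- data.frame(chrom = chrom, pos = tss_pos,
                      gene_id = sprintf("gene%02d", seq_len(n_genes)),
                      tss_id = sprintf("gene%02d_t1", seq_len(n_genes)),
                      stringsAsFactors = FALSE)
    # H3K4me3 peaks over most promoters (one TSS left unsupported; a
    # planted pair is functional by construction, so its gene stays
    # supported)
    droppable <- setdiff(seq_len(n_genes), planted$gene)
    supported <- setdiff(seq_len(n_genes), sample(droppable, 1L))
    h3k4me3 <- data.frame(chrom = chrom,
                          start = pmax(tss_pos[supported] - 300L, 0L),
                          end = tss_pos[supported] + 300L)
    # enhancer coordinates shared between conditions (so link IDs are
    # comparable); activity is condition-specific
    enh_centers <- sort(sample.int(chrom_size - 20000L, n_enhancers) + 10000L)
    widths <- sample(600:2000, n_enhancers, replace = TRUE)
    base_amp <- runif(n_enhancers, 1, 8)
    prom_amp <- runif(n_genes, 1, 6)
    make_condition <- function(cond) {
      # most peaks detected in both conditions, a few condition-specific;
      # planted enhancers are always detected in WT
      detected <- runif(n_enhancers) < 0.85
      if (cond == "WT" && !is.null(planted)) detected[planted$enhancer] <- TRUE
      h3k27ac <- data.frame(chrom = chrom,
                            start = pmax(enh_centers - widths %/% 2L, 0L),
                            end = enh_centers + widths %/% 2L)[detected, ]
      # per-base signal: steps over enhancer peaks (condition-perturbed
      # amplitudes) and over promoters, so promoter-class elements carry
      # activity as in real H3K27ac profiles
      amp <- base_amp[detected] * exp(rnorm(sum(detected), 0, 0.3))
      signal <- rbind(
        data.frame(chrom = chrom, start = h3k27ac$start,
                   end = h3k27ac$end, score = amp),
        data.frame(chrom = chrom, start = pmax(tss_pos - 800L, 0L),
                   end = tss_pos + 800L,
                   score = prom_amp * exp(rnorm(n_genes, 0, 0.3))))
      signal <- signal[order(signal$start), ]
      # contacts: expectation contact_scale * sep^-gamma on every pair
      # within 5 Mb (here the whole chromosome)
      ij <- which(upper.tri(matrix(0, n_bins, n_bins), diag = FALSE),
                  arr.ind = TRUE)
      sep <- ij[, 2] - ij[, 1]
      keep <- sep <= floor(5e6 / bin_size)
      ij <- ij[keep, , drop = FALSE]; sep <- sep[keep]
      mu <- contact_scale * sep^(-gamma)
      val <- if (noise == "poisson") stats::rpois(length(mu), mu) else mu
      tri <- data.frame(chrom = chrom, bin_i = ij[, 1] - 1L,
                        bin_j = ij[, 2] - 1L, value = val)
      tri <- tri[tri$value > 0, , drop = FALSE]
      list(h3k27ac = h3k27ac, signal = signal,
           contacts = contact_matrix(tri, bin_size = bin_size,
                                     chrom_sizes = c(chrT = chrom_size),
                                     normalization = "synthetic"),
           enh_centers = enh_centers, detected = detected)
    }
    wt <- make_condition("WT")
    ko <- make_condition("KO")
    wt$detected <- NULL; ko$detected <- NULL
    if (!is.null(planted)) {
      for (r in seq_len(nrow(planted))) {
        g <- planted$gene[r]; e <- planted$enhancer[r]
        pb <- tss_pos[g] %/% bin_size
        eb <- wt$enh_centers[e] %/% bin_size
        i <- min(pb, eb); j <- max(pb, eb)
        tri <- wt$contacts$triplets
        hit <- which(tri$bin_i == i & tri$bin_j == j)
        if (length(hit)) tri$value[hit] <- tri$value[hit] * planted$boost[r]
        else tri <- rbind(tri, data.frame(chrom = "chrT", bin_i = i, bin_j = j,
                                          value = planted$boost[r]))
        wt$contacts <- contact_matrix(tri, bin_size = bin_size,
                                      chrom_sizes = c(chrT = chrom_size),
                                      normalization = "synthetic")
        # boost the planted enhancer's activity too (signal rows hold the
        # detected enhancers first, then the promoters)
        wt$signal$score[wt$signal$start == pmax(enh_centers[e] - widths[e] %/% 2L, 0L)] <-
          max(wt$signal$score) * 2
      }
    }
    list(tss = tss, h3k4me3 = h3k4me3, WT = wt, KO = ko,
         meta = list(chrom_size = chrom_size, bin_size = bin_size,
                     gamma = gamma, contact_scale = contact_scale,
                     noise = noise, seed = seed))
  })
}

#' Random peak set on a tiny genome (oracle-testing helper)
#'
#' Draws `n` random intervals on a genome of `size` bp; used to compare
#' the interval pipeline against brute-force per-base oracles.
#'
#' @param n number of peaks.
#' @param size genome size in bp.
#' @param max_width maximal peak width.
#' @param seed integer seed.
#' @return Peak data frame (`chrom`, `start`, `end`), sorted.
#' @export
random_toy_peaks <- function(n = 20L, size = 1e5, max_width = 2000L, seed = 1L) {
  with_seed(seed, {
    start <- sample.int(size - max_width, n)
    w <- sample.int(max_width, n)
    out <- data.frame(chrom = "chrT", start = start, end = start + w)
    out[order(out$start), ]
  })
}
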