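# Activity-by-contact enhancer-promoter link calling. Genomic intervals
# are BED-convention (0-based half-open) in user-facing data frames and
# converted to 1-based GRanges internally for overlap machinery.

.df_to_gr <- function(df) {
  GRanges(df$chrom, IRanges(df$start + 1L, df$end))
}

.gr_to_df <- function(gr, extra = NULL) {
  out <- data.frame(chrom = as.character(seqnames(gr)),
                    start = start(gr) - 1L, end = end(gr),
                    stringsAsFactors = FALSE)
  if (!is.null(extra)) out <- cbind(out, extra)
  out
}

.check_chroms <- function(a, b, what) {
  extra <- setdiff(unique(a), unique(b))
  if (length(extra) && length(intersect(unique(a), unique(b))) == 0L)
    stop("chromosome naming mismatch in ", what, ": ",
         paste(utils::head(extra, 5), collapse = ", "))
}

#' Define promoter intervals from TSS positions and H3K4me3 peaks
#'
#' A promoter is the interval 1 kb either side of a transcription start
#' site that overlaps (by at least 1 bp) an H3K4me3 peak; TSS without peak
#' support are dropped. A gene with several TSS yields several promoter
#' records.
#'
#' @param tss data frame with columns `chrom`, `pos` (0-based TSS
#'   coordinate; for stranded transcript records, the 5' end), `gene_id`,
#'   and optionally `tss_id` and `strand`.
#' @param h3k4me3_peaks peak data frame (`chrom`, `start`, `end`).
#' @param flank promoter half-width in bp (default 1000).
#' @return Data frame of promoter intervals with columns `chrom`, `start`,
#'   `end`, `id`, `gene_id`, `tss_pos`, `class = "promoter"`; attribute
#'   `n_dropped` counts TSS without peak overlap.
#' @export
define_promoters <- function(tss, h3k4me3_peaks, flank = 1000L) {
  stopifnot(all(c("chrom", "pos", "gene_id") %in% names(tss)),
            all(c("chrom", "start", "end") %in% names(h3k4me3_peaks)))
  .check_chroms(tss$chrom, h3k4me3_peaks$chrom, "define_promoters")
  prom <- data.frame(chrom = tss$chrom,
                     start = pmax(tss$pos - flank, 0L),
                     end = tss$pos + flank,
                     gene_id = tss$gene_id,
                     tss_pos = tss$pos,
                     stringsAsFactors = FALSE)
  prom$id <- if ("tss_id" %in% names(tss)) tss$tss_id else
    sprintf("%s_p%d", tss$gene_id, tss$pos)
  hit <- overlapsAny(.df_to_gr(prom), .df_to_gr(h3k4me3_peaks))
  out <- prom[hit, c("chrom", "start", "end", "id", "gene_id", "tss_pos")]
  out$class <- "promoter"
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!hit)
  out
}

#' Build the regulatory-element master list from H3K27ac peaks
#'
#' Applies the published pipeline in order: (1) merge H3K27ac peaks closer
#' than 500 bp (gap < `merge_gap`; bookended peaks always merge);
#' (2) discard merged peaks shorter than `min_length` bp; (3) discard
#' peaks overlapping any promoter; (4) the master list is the union of the
#' surviving intergenic elements and the promoter intervals.
#'
#' @param h3k27ac_peaks peak data frame (`chrom`, `start`, `end`).
#' @param promoters promoter data frame from [define_promoters()].
#' @param merge_gap merge peaks with gap strictly below this (bp).
#' @param min_length discard merged peaks with length below this (bp).
#' @return Data frame of regulatory elements: `chrom`, `start`, `end`,
#'   `id`, `class` (`"intergenic_re"` or `"promoter"`).
#' @export
define_res <- function(h3k27ac_peaks, promoters, merge_gap = 500L,
                       min_length = 500L) {
  gr <- .df_to_gr(h3k27ac_peaks)
  merged <- reduce(gr, min.gapwidth = merge_gap)
  merged <- merged[width(merged) >= min_length]
  if (nrow(promoters))
    merged <- merged[!overlapsAny(merged, .df_to_gr(promoters))]
  inter <- .gr_to_df(merged)
  inter$id <- sprintf("re_%s_%d_%d", inter$chrom, inter$start, inter$end)
  inter$class <- rep("intergenic_re", nrow(inter))
  prom <- promoters[c("chrom", "start", "end", "id", "class")]
  out <- rbind(inter[c("chrom", "start", "end", "id", "class")], prom)
  out <- out[order(out$chrom, out$start), ]
  rownames(out) <- NULL
  out
}

#' Mean per-base H3K27ac signal over a regulatory element
#'
#' The activity `A_r` of an element is the mean per-base signal across its
#' interval; bases not covered by any signal segment count as 0.
#'
#' @param re data frame of one or more element intervals (`chrom`,
#'   `start`, `end`).
#' @param signal bedGraph-style data frame (`chrom`, `start`, `end`,
#'   `score`) of per-base signal.
#' @return Numeric vector of activities, one per element row (0 with a
#'   warning for zero-coverage elements).
#' @export
score_activity <- function(re, signal) {
  stopifnot(all(c("chrom", "start", "end", "score") %in% names(signal)))
  re_gr <- .df_to_gr(re)
  sig_gr <- .df_to_gr(signal)
  hits <- findOverlaps(re_gr, sig_gr)
  acts <- numeric(length(re_gr))
  if (length(hits)) {
    ov <- pintersect(re_gr[queryHits(hits)], sig_gr[subjectHits(hits)])
    contrib <- width(ov) * signal$score[subjectHits(hits)]
    sums <- tapply(contrib, queryHits(hits), sum)
    acts[as.integer(names(sums))] <- as.numeric(sums)
  }
  acts <- acts / (re$end - re$start)
  uncovered <- !(seq_along(acts) %in% queryHits(hits))
  if (any(uncovered))
    warning(sprintf("%d element(s) with zero signal coverage scored 0", sum(uncovered)))
  acts
}

#' Score all candidate enhancer-promoter pairs for a set of promoters
#'
#' For each promoter `p`, the candidate set `N(p)` holds every regulatory
#' element within `max_dist` (5 Mb) on the same chromosome. The score of
#' element `r` is `ABC = A_r C_pr / sum_{s in N(p)} A_s C_ps`, with
#' activity `A` the mean H3K27ac signal and contact `C` the (possibly
#' power-law-imputed) 5 kb bin contact between the promoter and element
#' midpoints. Scores over one promoter's candidates sum to 1; promoters
#' whose denominator is 0 are skipped with a warning.
#'
#' @param promoters promoter data frame ([define_promoters()]).
#' @param res master RE list ([define_res()]).
#' @param activities numeric vector of activities aligned with `res` rows
#'   ([score_activity()]).
#' @param cm contact matrix ([contact_matrix()]).
#' @param gamma_fit decay fit for imputation ([fit_gamma()]).
#' @param max_dist candidate radius in bp (default 5 Mb).
#' @param coverage_quantile see [get_contact()].
#' @param condition condition tag stored on each link (e.g. `"WT"`).
#' @return Data frame of links: `link_id`, `condition`, `promoter_id`,
#'   `promoter_pos`, `re_id`, `re_class`, `activity`, `contact`,
#'   `imputed`, `distance`, `abc_score`.
#' @export
abc_scores <- function(promoters, res, activities, cm, gamma_fit,
                       max_dist = 5e6, coverage_quantile = 0.05,
                       condition = "WT") {
  stopifnot(nrow(res) == length(activities))
  cov <- .bin_coverage(cm)
  thr <- quantile(cov, coverage_quantile, names = FALSE)
  tri <- cm$triplets
  tri_key <- paste(tri$chrom, tri$bin_i, tri$bin_j)
  p_mid <- (promoters$start + promoters$end) %/% 2L
  r_mid <- (res$start + res$end) %/% 2L
  p_bin <- p_mid %/% cm$bin_size
  r_bin <- r_mid %/% cm$bin_size
  out <- vector("list", nrow(promoters))
  for (k in seq_len(nrow(promoters))) {
    cand <- which(res$chrom == promoters$chrom[k] &
                    abs(r_mid - p_mid[k]) <= max_dist)
    if (!length(cand)) next
    d <- abs(r_bin[cand] - p_bin[k]) * cm$bin_size
    kp <- paste(promoters$chrom[k], p_bin[k])
    kr <- paste(res$chrom[cand], r_bin[cand])
    poor <- is.na(cov[kp]) || cov[kp] < thr
    poor_r <- is.na(cov[kr]) | cov[kr] < thr | poor
    i <- pmin(p_bin[k], r_bin[cand]); j <- pmax(p_bin[k], r_bin[cand])
    obs <- tri$value[match(paste(promoters$chrom[k], i, j), tri_key)]
    obs[is.na(obs)] <- 0
    contact <- ifelse(poor_r, .decay_expectation(gamma_fit, d), obs)
    num <- activities[cand] * contact
    denom <- sum(num)
    if (denom <= 0) {
      warning("promoter ", promoters$id[k], " skipped: zero ABC denominator")
      next
    }
    out[[k]] <- data.frame(
      link_id = sprintf("%s:%d:%s", promoters$id[k], promoters$start[k],
                        res$id[cand]),
      condition = condition,
      promoter_id = promoters$id[k], promoter_pos = promoters$start[k],
      re_id = res$id[cand], re_class = res$class[cand],
      activity = activities[cand], contact = contact,
      imputed = as.logical(poor_r), distance = d,
      abc_score = num / denom,
      stringsAsFactors = FALSE)
  }
  res_df <- do.call(rbind, out)
  if (is.null(res_df))
    stop("no promoter had a non-empty candidate set")
  rownames(res_df) <- NULL
  res_df
}

#' Call strong links across two conditions
#'
#' Pools the link scores of both conditions, takes the pooled
#' `quantile` (default 90th percentile) of ABC scores as the strong-link
#' threshold, keeps every link with score >= threshold (ties at the
#' threshold are kept, so the strong set can slightly exceed 10%), and
#' categorizes each strong link ID as present in one condition only or in
#' both.
#'
#' @param links_a,links_b link tables from [abc_scores()] for the two
#'   conditions (e.g. wild-type and knockout).
#' @param quantile pooled score quantile defining "strong" (default 0.90).
#' @return List with `threshold` (realized score cutoff), `strong`
#'   (row-bound strong links with a `category` column:
#'   `"<condA>-unique"`, `"<condB>-unique"`, `"common"`), and per-category
#'   counts.
#' @export
call_links <- function(links_a, links_b, quantile = 0.90) {
  pooled <- rbind(links_a, links_b)
  if (!nrow(pooled)) stop("insufficient data: no links to pool")
  thr <- stats::quantile(pooled$abc_score, quantile, names = FALSE)
  strong <- pooled[pooled$abc_score >= thr, , drop = FALSE]
  conds <- unique(pooled$condition)
  if (length(conds) != 2L) stop("expected exactly two conditions, got ",
                                paste(conds, collapse = ", "))
  ids_a <- strong$link_id[strong$condition == conds[1]]
  ids_b <- strong$link_id[strong$condition == conds[2]]
  strong$category <- ifelse(strong$link_id %in% intersect(ids_a, ids_b), "common",
                            paste0(strong$condition, "-unique"))
  rownames(strong) <- NULL
  list(threshold = thr, strong = strong,
       counts = table(strong$category))
}

#' Link-length distributions by category, with a location-shift test
#'
#' Summarizes intrachromosomal link lengths (promoter-element genomic
#' distance) per category and compares categories pairwise with a
#' two-sample rank test (Wilcoxon/Mann-Whitney).
#'
#' @param strong strong-link table with `category` and `distance` columns
#'   (from [call_links()]).
#' @return List with `lengths` (split by category), `medians`, and
#'   `tests` (data frame of pairwise comparisons: categories, n, W
#'   statistic, p value). Categories with fewer than 2 links are skipped
#'   with a warning.
#' @export
link_lengths <- function(strong) {
  sp <- split(strong$distance, strong$category)
  small <- names(sp)[vapply(sp, length, 0L) < 2L]
  if (length(small)) {
    warning("skipping category(ies) with < 2 links: ",
            paste(small, collapse = ", "))
    sp <- sp[!(names(sp) %in% small)]
  }
  tests <- NULL
  if (length(sp) >= 2L) {
    prs <- utils::combn(names(sp), 2L)
    tests <- do.call(rbind, lapply(seq_len(ncol(prs)), function(c_) {
      a <- prs[1, c_]; b <- prs[2, c_]
      wt <- suppressWarnings(wilcox.test(sp[[a]], sp[[b]]))
      data.frame(category_a = a, category_b = b,
                 n_a = length(sp[[a]]), n_b = length(sp[[b]]),
                 W = unname(wt$statistic), p = wt$p.value,
                 stringsAsFactors = FALSE)
    }))
  }
  list(lengths = sp, medians = vapply(sp, median, numeric(1)), tests = tests)
}

#' Chi-squared enrichment of link categories against gene regulation
#'
#' Associates each strong link with its promoter's gene, builds the
#' contingency table of link category x regulation label (up/down/
#' unchanged), computes the chi-squared statistic with `(R-1)(C-1)`
#' degrees of freedom (no continuity correction) and per-cell fold
#' enrichment (observed / expected under independent margins).
#'
#' @param strong strong-link table with `category` and `promoter_id`.
#' @param promoters promoter table mapping `id` to `gene_id`.
#' @param regulation data frame with `gene_id` and `label` columns; every
#'   linked gene must appear.
#' @return List with `table` (observed counts), `expected`, `chisq`, `df`,
#'   `p`, `fold_enrichment`. Warns when any expected cell is below 1.
#' @export
enrichment_chi2 <- function(strong, promoters, regulation) {
  gene <- promoters$gene_id[match(strong$promoter_id, promoters$id)]
  lab <- regulation$label[match(gene, regulation$gene_id)]
  if (any(is.na(lab)))
    stop("regulation label missing for gene(s): ",
         paste(utils::head(unique(gene[is.na(lab)]), 5), collapse = ", "))
  tab <- table(category = strong$category, regulation = lab)
  res <- suppressWarnings(chisq.test(tab, correct = FALSE))
  if (any(res$expected < 1))
    warning("expected cell count < 1; consider an exact test")
  list(table = tab, expected = res$expected,
       chisq = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value,
       fold_enrichment = tab / res$expected)
}

#' Read/write BED-like interval tables
#'
#' `read_peaks` reads BED3+ into the package's 0-based data frame;
#' `write_links_bed` writes strong links as BED with the ABC score scaled
#' by 1000 in column 5 plus a full-precision TSV sidecar
#' (`<path>.tsv`).
#'
#' @param path file path.
#' @return `read_peaks`: data frame `chrom`, `start`, `end` (plus `name`,
#'   `score` when present).
#' @export
read_peaks <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  df <- .gr_to_df(gr)
  md <- mcols(gr)
  if ("name" %in% names(md)) df$name <- md$name
  if ("score" %in% names(md)) df$score <- md$score
  df
}

#' @rdname read_peaks
#' @param peaks interval data frame (`chrom`, `start`, `end`, optional
#'   `name`, `score`).
#' @export
write_peaks <- function(peaks, path) {
  gr <- .df_to_gr(peaks)
  if ("name" %in% names(peaks)) names(gr) <- peaks$name
  if ("score" %in% names(peaks)) mcols(gr)$score <- peaks$score
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @rdname read_peaks
#' @export
read_signal <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  df <- .gr_to_df(gr)
  df$score <- mcols(gr)$score
  df
}

#' @rdname read_peaks
#' @param signal bedGraph data frame (`chrom`, `start`, `end`, `score`).
#' @export
write_signal <- function(signal, path) {
  gr <- .df_to_gr(signal)
  mcols(gr)$score <- signal$score
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' @rdname read_peaks
#' @param strong strong-link table (from [call_links()]).
#' @export
write_links_bed <- function(strong, path) {
  re_start <- as.integer(sub(".*_(\\d+)_\\d+$", "\\1", strong$re_id))
  df <- data.frame(chrom = sub("^re_(.+)_\\d+_\\d+$", "\\1", strong$re_id),
                   start = ifelse(is.na(re_start), strong$promoter_pos, re_start),
                   end = ifelse(is.na(re_start), strong$promoter_pos + 1L,
                                re_start + 1L),
                   name = strong$link_id,
                   score = pmin(round(strong$abc_score * 1000), 1000L))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  side <- strong
  side$abc_score <- sprintf("%.17g", side$abc_score)
  write.table(side, paste0(path, ".tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a TSS table
#'
#' Accepts a BED-like TSV with columns `chrom`, `pos`, `gene_id` (plus
#' optional `tss_id`, `strand`), or a minimal GTF subset (transcript rows;
#' the strand-aware 5' end becomes the TSS, converted to 0-based).
#'
#' @param path file path.
#' @param format `"tsv"` or `"gtf"`.
#' @return TSS data frame for [define_promoters()].
#' @export
read_tss <- function(path, format = c("tsv", "gtf")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- read.delim(path, sep = "\t", header = TRUE)
    miss <- setdiff(c("chrom", "pos", "gene_id"), names(df))
    if (length(miss)) stop("TSS table missing column(s): ",
                           paste(miss, collapse = ", "))
    return(df)
  }
  gr <- rtracklayer::import(path, format = "GFF")
  gr <- gr[gr$type == "transcript"]
  str <- as.character(GenomicRanges::strand(gr))
  pos <- ifelse(str == "-", end(gr) - 1L, start(gr) - 1L)
  data.frame(chrom = as.character(seqnames(gr)), pos = pos,
             gene_id = gr$gene_id,
             tss_id = if (!is.null(gr$transcript_id)) gr$transcript_id else
               sprintf("%s_p%d", gr$gene_id, pos),
             strand = str,
             stringsAsFactors = FALSE)
}
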