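test_that("promoters require an H3K4me3-supported TSS", {
  tss <- data.frame(chrom = "chrT", pos = c(10000L, 50000L, 90000L),
                    gene_id = c("g1", "g2", "g3"))
  peaks <- data.frame(chrom = "chrT", start = c(9500L, 89000L),
                      end = c(9600L, 89500L))
  prom <- define_promoters(tss, peaks)
  expect_equal(nrow(prom), 2)
  expect_equal(prom$start[1], 9000L)
  expect_equal(prom$end[1], 11000L)
  expect_equal(attr(prom, "n_dropped"), 1)

  # brute-force all-pairs overlap oracle on random inputs
  set.seed(50)
  for (i in 1:5) {
    tss_r <- data.frame(chrom = "chrT",
                        pos = sample.int(90000L, 8) + 2000L,
                        gene_id = sprintf("g%d", 1:8))
    pk <- random_toy_peaks(n = 6, size = 1e5, seed = 100 + i)
    prom_r <- define_promoters(tss_r, pk)
    want <- vapply(seq_len(8), function(j) {
      s <- tss_r$pos[j] - 1000L; e <- tss_r$pos[j] + 1000L
      any(pmax(s, pk$start) < pmin(e, pk$end))
    }, TRUE)
    expect_equal(nrow(prom_r), sum(want))
  }

  expect_error(define_promoters(transform(tss, chrom = "1"), peaks),
               "mismatch")
})

test_that("RE pipeline applies merge, length and promoter rules in order", {
  prom0 <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), id = character(0),
                      class = character(0))
  # gap 400 < 500 merges; total length 1300 >= 500 kept
  pk <- data.frame(chrom = "chrT", start = c(0L, 800L), end = c(400L, 1300L))
  re <- define_res(pk, prom0)
  expect_equal(re[re$class == "intergenic_re", c("start", "end")],
               data.frame(start = 0L, end = 1300L))

  # lone short peak discarded
  expect_equal(nrow(define_res(data.frame(chrom = "chrT", start = 0L,
                                          end = 450L), prom0)), 0)

  # bookended peaks (gap 0) always merge
  pk2 <- data.frame(chrom = "chrT", start = c(0L, 300L), end = c(300L, 700L))
  expect_equal(define_res(pk2, prom0)$end, 700L)

  # random peak sets against the per-base brute-force oracle
  for (i in 1:6) {
    pk_r <- random_toy_peaks(n = 20, size = 1e5, seed = 200 + i)
    prom_r <- data.frame(chrom = "chrT",
                         start = c(20000L, 60000L, 81000L),
                         end = c(22000L, 62000L, 83000L),
                         id = c("p1", "p2", "p3"), class = "promoter")
    got <- define_res(pk_r, prom_r)
    got_int <- got[got$class == "intergenic_re", c("start", "end")]
    want <- oracle_re_pipeline(pk_r, prom_r, size = 1e5)
    expect_equal(unname(as.matrix(got_int)), unname(as.matrix(want)))
  }
})

test_that("activity is the per-base mean signal over the element", {
  re <- data.frame(chrom = "chrT", start = 1000L, end = 2000L)
  sig_u <- data.frame(chrom = "chrT", start = 0L, end = 5000L, score = 2)
  expect_equal(score_activity(re, sig_u), 2)

  # signal 4.0 over exactly half the element
  sig_h <- data.frame(chrom = "chrT", start = 1000L, end = 1500L, score = 4)
  expect_equal(score_activity(re, sig_h), 2)

  # random step signal equals the per-base oracle
  set.seed(51)
  for (i in 1:5) {
    re_r <- random_toy_peaks(n = 4, size = 5e4, seed = 300 + i)
    edges <- sort(sample.int(5e4, 9))
    sig_r <- data.frame(chrom = "chrT", start = c(0L, edges),
                        end = c(edges, 50000L),
                        score = round(runif(10, 0, 5), 3))
    expect_equal(score_activity(re_r, sig_r),
                 oracle_activity(re_r, sig_r, 5e4), tolerance = 1e-12)
  }

  expect_warning(score_activity(data.frame(chrom = "chrT", start = 0L,
                                           end = 100L), sig_h),
                 "zero signal")
})

test_that("gamma is recovered from constructed decay matrices", {
  mk_cm <- function(f, n_bins = 300, bin = 5000L) {
    ij <- which(upper.tri(matrix(0, n_bins, n_bins)), arr.ind = TRUE)
    sep <- ij[, 2] - ij[, 1]
    contact_matrix(data.frame(chrom = "chrT", bin_i = ij[, 1] - 1L,
                              bin_j = ij[, 2] - 1L, value = f(sep * bin)),
                   bin_size = bin, chrom_sizes = c(chrT = n_bins * bin))
  }
  # exact power law: gamma to 1e-6
  cm1 <- mk_cm(function(d) 100 * (d / 5000)^(-1))
  expect_equal(fit_gamma(cm1)$gamma, 1, tolerance = 1e-6)
  # constant contact: gamma 0
  cm0 <- mk_cm(function(d) 3 + 0 * d)
  expect_equal(fit_gamma(cm0)$gamma, 0, tolerance = 1e-10)
  # Poisson noise at high counts: within 0.05
  set.seed(52)
  cmp <- mk_cm(function(d) rpois(length(d), 5000 * (d / 5000)^(-1.2)))
  expect_lt(abs(fit_gamma(cmp)$gamma - 1.2), 0.05)
  expect_error(fit_gamma(cm1, range = c(5e6, 1e4)), "empty")
})

test_that("contacts are observed when covered and imputed continuously", {
  set.seed(53)
  n_bins <- 200; bin <- 5000L
  ij <- which(upper.tri(matrix(0, n_bins, n_bins)), arr.ind = TRUE)
  sep <- ij[, 2] - ij[, 1]
  val <- 200 * sep^(-1)
  # bins 40-44 get no reads at all: poorly covered
  dead <- (ij[, 1] - 1L) %in% 40:44 | (ij[, 2] - 1L) %in% 40:44
  tri <- data.frame(chrom = "chrT", bin_i = ij[, 1] - 1L,
                    bin_j = ij[, 2] - 1L, value = ifelse(dead, 0, val))
  tri <- tri[tri$value > 0, ]
  cm <- contact_matrix(tri, bin, c(chrT = n_bins * bin))
  gf <- fit_gamma(cm, range = c(1e4, 9e5))

  # well-covered pair: value verbatim
  got <- get_contact(cm, "chrT", 10L, 20L, gf)
  expect_false(got$imputed)
  expect_equal(got$value, 200 / 10)

  # dead-bin pair: the fitted power-law expectation at that distance
  imp <- get_contact(cm, "chrT", 42L, 60L, gf)
  expect_true(imp$imputed)
  expect_equal(imp$value, exp(gf$intercept - gf$gamma * log(18 * bin)),
               tolerance = 1e-12)

  # continuity scan: imputed values change smoothly with distance
  vals <- vapply(50:80, function(b)
    get_contact(cm, "chrT", 42L, b, gf)$value, numeric(1))
  rel_step <- abs(diff(log(vals)))
  expect_true(all(rel_step < 0.2))
})

test_that("ABC scores follow the normalized activity-by-contact equation", {
  # two elements, A = (3, 1), C = (2, 2) -> scores (0.75, 0.25)
  bin <- 5000L
  prom <- data.frame(chrom = "chrT", start = 9000L, end = 11000L,
                     id = "p1", gene_id = "g1", tss_pos = 10000L,
                     class = "promoter")
  res <- data.frame(chrom = "chrT", start = c(30000L, 50000L),
                    end = c(31000L, 51000L), id = c("e1", "e2"),
                    class = "intergenic_re")
  tri <- data.frame(chrom = "chrT",
                    bin_i = c(2L, 2L), bin_j = c(6L, 10L), value = c(2, 2))
  # pad coverage so no bin is "poor": add self-contacts everywhere
  pad <- data.frame(chrom = "chrT", bin_i = 0:39, bin_j = 0:39, value = 5)
  cm <- contact_matrix(rbind(tri, pad), bin, c(chrT = 200000))
  gf <- list(gamma = 1, intercept = log(100))
  links <- abc_scores(prom, res, activities = c(3, 1), cm, gf,
                      coverage_quantile = 0)
  expect_equal(links$abc_score, c(0.75, 0.25))

  # single candidate: score 1
  links1 <- abc_scores(prom, res[1, ], activities = 3, cm, gf,
                       coverage_quantile = 0)
  expect_equal(links1$abc_score, 1)

  # joint rescaling of activities leaves scores unchanged
  links2 <- abc_scores(prom, res, activities = 7 * c(3, 1), cm, gf,
                       coverage_quantile = 0)
  expect_equal(links2$abc_score, links$abc_score)
})

test_that("strong links are the pooled top decile with ID set algebra", {
  mk_links <- function(scores, cond, ids = seq_along(scores))
    data.frame(link_id = sprintf("L%03d", ids), condition = cond,
               promoter_id = "p", promoter_pos = 0L,
               re_id = sprintf("e%03d", ids), re_class = "intergenic_re",
               activity = 1, contact = 1, imputed = FALSE,
               distance = 1e5 * ids, abc_score = scores)
  # 10 links 0.01..0.10 -> exactly one strong link
  la <- mk_links(seq(0.01, 0.05, by = 0.01), "WT")
  lb <- mk_links(seq(0.06, 0.10, by = 0.01), "KO", ids = 6:10)
  called <- call_links(la, lb)
  expect_equal(nrow(called$strong), 1)
  expect_equal(called$strong$abc_score, 0.10)

  # a link above threshold in both conditions is common
  la2 <- mk_links(c(0.9, seq(0.01, 0.09, by = 0.01)), "WT", ids = 1:10)
  lb2 <- mk_links(c(0.85, seq(0.011, 0.091, by = 0.01)), "KO",
                  ids = c(1, 11:19))
  called2 <- call_links(la2, lb2)
  expect_setequal(called2$strong$category, "common")
  expect_equal(nrow(called2$strong), 2)

  # random two-condition synthesis equals brute-force set operations
  set.seed(54)
  for (i in 1:5) {
    sa <- round(runif(40), 3); sb <- round(runif(40), 3)
    ia <- sample.int(60, 40); ib <- sample.int(60, 40)
    ca <- call_links(mk_links(sa, "WT", ia), mk_links(sb, "KO", ib))
    pooled <- c(sa, sb)
    thr <- quantile(pooled, 0.9, names = FALSE)
    id_a <- sprintf("L%03d", ia)[sa >= thr]
    id_b <- sprintf("L%03d", ib)[sb >= thr]
    want <- c(rep("common", 2 * length(intersect(id_a, id_b))),
              rep("WT-unique", length(setdiff(id_a, id_b))),
              rep("KO-unique", length(setdiff(id_b, id_a))))
    expect_equal(sort(ca$strong$category), sort(want))
  }
})

test_that("link-length distributions separate and the null stays flat", {
  mk <- function(d, cat) data.frame(category = cat, distance = d)
  # constructed separation: WT-unique 2 Mb vs KO-unique 1 Mb
  set.seed(55)
  strong <- rbind(mk(rnorm(100, 2e6, 1e5), "WT-unique"),
                  mk(rnorm(100, 1e6, 1e5), "KO-unique"))
  ll <- link_lengths(strong)
  expect_gt(ll$medians["WT-unique"], ll$medians["KO-unique"])
  expect_lt(ll$tests$p, 0.001)
  expect_equal(unname(ll$medians["WT-unique"]), median(strong$distance[1:100]))

  # identical distributions: non-significant in >= 90% of replicates
  set.seed(56)
  ps <- replicate(30, {
    s <- rbind(mk(rexp(60, 1e-6), "a"), mk(rexp(60, 1e-6), "b"))
    link_lengths(s)$tests$p
  })
  expect_gte(mean(ps > 0.05), 0.9)

  expect_warning(link_lengths(rbind(mk(1:10 * 1e5, "a"), mk(2e6, "b"))),
                 "skipping")
})

test_that("chi-squared enrichment matches the closed 2x2 form", {
  prom <- data.frame(id = c("p1", "p2"), gene_id = c("g1", "g2"))
  strong <- data.frame(
    category = rep(c("WT-unique", "KO-unique"), c(40, 40)),
    promoter_id = c(rep("p1", 30), rep("p2", 10), rep("p1", 10), rep("p2", 30)))
  reg <- data.frame(gene_id = c("g1", "g2"), label = c("up", "down"))
  enr <- enrichment_chi2(strong, prom, reg)
  # [[30,10],[10,30]]: chi2 = n(ad-bc)^2 / ((a+b)(c+d)(a+c)(b+d)) = 20
  expect_equal(enr$chisq, 80 * (900 - 100)^2 / (40 * 40 * 40 * 40))
  expect_equal(enr$chisq, 20)
  expect_equal(enr$df, 1)

  # independent margins: fold enrichment 1 everywhere
  strong2 <- data.frame(
    category = rep(c("a", "b"), c(40, 20)),
    promoter_id = rep(c("p1", "p2", "p1", "p2"), c(20, 20, 10, 10)))
  enr2 <- enrichment_chi2(strong2, prom, reg)
  expect_true(all(abs(enr2$fold_enrichment - 1) < 1e-12))

  # chi-squared is invariant under row swaps
  strong3 <- strong
  strong3$category <- ifelse(strong$category == "WT-unique",
                             "KO-unique", "WT-unique")
  expect_equal(enrichment_chi2(strong3, prom, reg)$chisq, enr$chisq)

  expect_error(enrichment_chi2(strong, prom,
                               data.frame(gene_id = "g1", label = "up")),
               "missing")
})

test_that("interval and matrix files round-trip through standard formats", {
  pk <- data.frame(chrom = "chrT", start = c(100L, 900L), end = c(400L, 1500L),
                   name = c("a", "b"), score = c(5, 7))
  f <- withr::local_tempfile(fileext = ".bed")
  write_peaks(pk, f)
  back <- read_peaks(f)
  expect_equal(back[c("chrom", "start", "end")], pk[c("chrom", "start", "end")])

  sig <- data.frame(chrom = "chrT", start = c(0L, 500L), end = c(500L, 800L),
                    score = c(1.5, 3))
  fs <- withr::local_tempfile(fileext = ".bedGraph")
  write_signal(sig, fs)
  expect_equal(read_signal(fs), sig)

  cm <- contact_matrix(data.frame(chrom = "chrT", bin_i = c(0L, 1L),
                                  bin_j = c(1L, 3L), value = c(2.5, 1.25)),
                       5000L, c(chrT = 50000))
  fc <- withr::local_tempfile(fileext = ".tsv")
  write_contact_matrix(cm, fc)
  cm2 <- read_contact_matrix(fc)
  expect_equal(cm2$triplets, cm$triplets)
  expect_equal(cm2$bin_size, cm$bin_size)
  expect_equal(cm2$chrom_sizes, cm$chrom_sizes)
})

test_that("planted high activity x contact pairs become the top links", {
  g <- simulate_toy_genome(seed = 60, noise = "none",
                           planted = data.frame(gene = 3, enhancer = 5,
                                                boost = 50))
  prom <- define_promoters(g$tss, g$h3k4me3)
  res <- define_res(g$WT$h3k27ac, prom)
  act <- suppressWarnings(score_activity(res, g$WT$signal))
  gf <- fit_gamma(g$WT$contacts)
  links <- abc_scores(prom, res, act, g$WT$contacts, gf)
  top <- links[which.max(links$abc_score), ]
  expect_equal(top$promoter_id, prom$id[prom$gene_id == "gene03"])
})
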