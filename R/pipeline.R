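#' Pipeline run configuration
#'
#' Bundles every tunable of the analysis with defaults equal to the
#' published constants: 11-frame window, MSD lags 1..5, 2-component
#' Stage-1 mixture with 10 EM restarts and 1e-6 covariance regularization,
#' 20-dwell minimum for exponential fits, 5 kb contact bins, 5 Mb
#' candidate radius, 0.90 strong-link quantile, 500 bp merge gap and
#' minimum RE length, 1 kb promoter flank. Serializes losslessly to flat
#' JSON.
#'
#' @param seed global seed; per-stage seeds are derived from it by a
#'   documented hash ([run_pipeline()] manifest records both).
#' @param ... overrides of any default field.
#' @return Named list of class `nd_run_config`.
#' @export
run_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    window_len = 11L, msd_max_lag = 5L, min_traj_len = 11L,
    n_components = 2L, n_init = 10L, cov_reg = 1e-6,
    min_dwells = 20L, min_duration_s = 5,
    bin_size = 5000L, search_radius = 5e6, strong_quantile = 0.90,
    merge_gap = 500L, min_re_length = 500L, promoter_flank = 1000L,
    coverage_quantile = 0.05,
    scenario = "stage1_20ms", n_tracks = NA_integer_,
    max_jump = 0.8, dt = 0.02)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  class(cfg) <- "nd_run_config"
  cfg
}

#' @rdname run_config
#' @param cfg an `nd_run_config`.
#' @param path JSON file path.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname run_config
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- Filter(Negate(is.null), cfg)
  out <- do.call(run_config, cfg)
  int_fields <- c("window_len", "msd_max_lag", "min_traj_len", "n_components",
                  "n_init", "min_dwells", "bin_size", "merge_gap",
                  "min_re_length", "promoter_flank", "n_tracks")
  for (f in int_fields) out[[f]] <- as.integer(out[[f]])
  out
}

.manifest <- function(cfg, inputs, outputs, outdir) {
  cfg_file <- tempfile(fileext = ".json")
  write_config(cfg, cfg_file)
  man <- list(
    package = "nucdyn",
    version = as.character(utils::packageVersion("nucdyn")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = cfg$seed,
    config = unclass(cfg),
    config_md5 = unname(tools::md5sum(cfg_file)),
    inputs = lapply(inputs, function(p) list(path = p,
                                             md5 = unname(tools::md5sum(p)))),
    outputs = outputs)
  unlink(cfg_file)
  jsonlite::write_json(man, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(man)
}

.need_input <- function(inputs, key) {
  p <- inputs[[key]]
  if (is.null(p)) stop("missing required input '", key, "'")
  if (!file.exists(p)) stop("input file not found: ", p)
  p
}

#' Run a pipeline subcommand
#'
#' Single entry point behind the command-line wrapper. Every subcommand
#' writes its outputs plus a `manifest.json` recording the package
#' version, seed, full configuration with its MD5, and input checksums,
#' so identical config + inputs reproduce identical outputs.
#'
#' Subcommands: `simulate` (benchmark scenario to trajectory/label
#' files), `link` (localizations to trajectories), `features`
#' (trajectories to window features), `segment` (trajectories to
#' Stage-1 model + labels + fractions; with simulated labels, an accuracy
#' report), `substates` (500 ms trajectories to S/F1/F2 fit),
#' `kinetics` (label series to dwell fits), `abc-call` (toy/real
#' genomics inputs to scored links), `abc-compare` (two link tables to
#' strong links, categories, length test).
#'
#' @param command subcommand name.
#' @param config an [run_config()].
#' @param inputs named list of input file paths (see details per
#'   subcommand in the vignette).
#' @param outdir output directory (created if needed).
#' @return Named list of output file paths, invisibly.
#' @export
run_pipeline <- function(command, config = run_config(), inputs = list(),
                         outdir = ".") {
  commands <- c("simulate", "link", "features", "segment", "substates",
                "kinetics", "abc-call", "abc-compare")
  if (!command %in% commands)
    stop("unknown subcommand '", command, "'; options: ",
         paste(commands, collapse = ", "))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wcfg <- window_config(config$window_len, config$msd_max_lag,
                        config$min_traj_len)
  out <- switch(command,
    simulate = {
      bench <- make_benchmark_suite(config$scenario, seed = config$seed,
                                    n_tracks = if (is.na(config$n_tracks)) NULL
                                               else config$n_tracks)
      paths <- character(0)
      if (config$scenario == "timelapse") {
        p <- file.path(outdir, "timelapse_series.tsv")
        write.table(bench$series, p, sep = "\t", quote = FALSE, row.names = FALSE)
        paths <- c(series = p)
      } else {
        p1 <- file.path(outdir, "trajectories.tsv")
        write_trajectories(bench$trajectories, p1)
        lab <- do.call(rbind, lapply(seq_along(bench$trajectories), function(i) {
          tr <- bench$trajectories[[i]]
          data.frame(traj_id = tr$id, frame = tr$frames,
                     true_state = bench$states[[i]])
        }))
        p2 <- file.path(outdir, "true_states.tsv")
        write.table(lab, p2, sep = "\t", quote = FALSE, row.names = FALSE)
        paths <- c(trajectories = p1, states = p2)
      }
      paths
    },
    link = {
      locs <- read_localizations(.need_input(inputs, "localizations"))
      trajs <- link_localizations(locs, max_jump = config$max_jump,
                                  dt = config$dt)
      if (!length(trajs)) stop("no trajectories of length >= 2 were linked")
      p <- file.path(outdir, "trajectories.tsv")
      write_trajectories(trajs, p)
      c(trajectories = p)
    },
    features = {
      trajs <- read_trajectories(.need_input(inputs, "trajectories"))
      feats <- pooled_features(trajs, wcfg)
      p <- file.path(outdir, "window_features.tsv")
      write.table(feats, p, sep = "\t", quote = FALSE, row.names = FALSE)
      c(features = p)
    },
    segment = {
      trajs <- read_trajectories(.need_input(inputs, "trajectories"))
      seg <- segment_trajectories(trajs, wcfg,
                                  seed = derive_seed(config$seed, "segment"),
                                  n_components = config$n_components)
      p1 <- file.path(outdir, "frame_labels.tsv")
      write.table(seg$frames, p1, sep = "\t", quote = FALSE, row.names = FALSE)
      fr_w <- state_fractions(seg$frames, by = "windows")
      fr_t <- state_fractions(seg$frames, by = "trajectories")
      rep_ <- list(model_means = as.data.frame(seg$model$means_original),
                   confined_component = seg$model$confined_component,
                   separation_sd = seg$model$separation,
                   fractions_windows = as.list(fr_w),
                   fractions_trajectories = as.list(fr_t))
      if (!is.null(inputs$states)) {
        truth <- read.delim(inputs$states)
        key <- paste(seg$frames$traj_id, seg$frames$frame)
        tkey <- paste(truth$traj_id, truth$frame)
        m <- match(key, tkey)
        cmpb <- seg$frames$label != "unassigned" & !is.na(m)
        pred_bound <- seg$frames$label[cmpb] == "confined"
        true_bound <- truth$true_state[m][cmpb] %in%
          c("bound", "S", "confined_ou", "confined")
        rep_$accuracy <- mean(pred_bound == true_bound)
      }
      p2 <- file.path(outdir, "segmentation_report.json")
      jsonlite::write_json(rep_, p2, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
      c(frame_labels = p1, report = p2)
    },
    substates = {
      trajs <- read_trajectories(.need_input(inputs, "trajectories"))
      # low-mobility 500 ms data: fit the slow/fast mixture in log space
      seg <- segment_trajectories(trajs, wcfg,
                                  seed = derive_seed(config$seed, "segment"),
                                  transform = "log")
      dur <- setNames(vapply(trajs, traj_duration, 0),
                      vapply(trajs, function(t) t$id, ""))
      sf <- split_slow_fast(seg$windows, dur,
                            min_duration = config$min_duration_s,
                            model = seg$model)
      fit <- fit_alpha_mixture(sf$fast$alpha, n_slow = nrow(sf$slow),
                               seed = derive_seed(config$seed, "substates"))
      frames <- assign_substates(seg$frames, fit)
      p1 <- file.path(outdir, "substate_labels.tsv")
      write.table(frames, p1, sep = "\t", quote = FALSE, row.names = FALSE)
      p2 <- file.path(outdir, "substate_fit.json")
      jsonlite::write_json(
        list(alpha_means = fit$means, alpha_sds = fit$sds,
             weights = fit$weights, proportions = as.list(fit$proportions),
             ci = as.data.frame(fit$ci)),
        p2, auto_unbox = TRUE, digits = NA, pretty = TRUE)
      c(labels = p1, fit = p2)
    },
    kinetics = {
      frames <- read.delim(.need_input(inputs, "frame_labels"))
      dt <- config$dt
      dw <- extract_dwells(frames, dt = dt, kind = "association")
      fit <- fit_exponential(dw, min_n = config$min_dwells)
      p <- file.path(outdir, "kinetics.json")
      jsonlite::write_json(
        list(kind = "association", rate = fit$rate, mean_time = fit$mean_time,
             ci = as.list(fit$ci), n = fit$n, n_censored = fit$n_censored,
             gof_p = fit$gof_p),
        p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
      c(kinetics = p)
    },
    `abc-call` = {
      tss <- read_tss(.need_input(inputs, "tss"))
      k4 <- read_peaks(.need_input(inputs, "h3k4me3"))
      k27 <- read_peaks(.need_input(inputs, "h3k27ac"))
      sig <- read_signal(.need_input(inputs, "signal"))
      cm <- read_contact_matrix(.need_input(inputs, "contacts"))
      prom <- define_promoters(tss, k4, flank = config$promoter_flank)
      res <- define_res(k27, prom, merge_gap = config$merge_gap,
                        min_length = config$min_re_length)
      act <- suppressWarnings(score_activity(res, sig))
      gf <- fit_gamma(cm)
      links <- abc_scores(prom, res, act, cm, gf,
                          max_dist = config$search_radius,
                          coverage_quantile = config$coverage_quantile,
                          condition = inputs$condition %||% "WT")
      p <- file.path(outdir, sprintf("links_%s.tsv",
                                     inputs$condition %||% "WT"))
      write.table(links, p, sep = "\t", quote = FALSE, row.names = FALSE)
      c(links = p)
    },
    `abc-compare` = {
      la <- read.delim(.need_input(inputs, "links_a"))
      lb <- read.delim(.need_input(inputs, "links_b"))
      called <- call_links(la, lb, quantile = config$strong_quantile)
      p1 <- file.path(outdir, "strong_links.tsv")
      write.table(called$strong, p1, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      ll <- suppressWarnings(link_lengths(called$strong))
      p2 <- file.path(outdir, "link_compare.json")
      jsonlite::write_json(
        list(threshold = called$threshold,
             counts = as.list(called$counts),
             medians = as.list(ll$medians),
             tests = ll$tests),
        p2, auto_unbox = TRUE, digits = NA, pretty = TRUE)
      c(strong_links = p1, report = p2)
    })
  file_inputs <- Filter(function(p) is.character(p) && file.exists(p), inputs)
  .manifest(config, file_inputs, as.list(out), outdir)
  invisible(c(out, manifest = file.path(outdir, "manifest.json")))
}
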