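.config_spec <- list(
  seed = NULL, out_dir = NULL,
  simulate = c("n_parcels", "n_markers", "n_active", "target_r2",
               "delta_mean", "delta_sd", "sa_range", "noise_sd",
               "n_subjects", "sessions", "subject_noise_sd",
               "n_signal_genes", "n_null_genes"),
  surrogates = c("n", "resample"),
  reduce = c("enabled", "threshold", "kappa", "n_null"),
  windows = c("start", "stop", "step", "length", "extra"),
  scan = c("mode", "n_null", "baseline_correct", "percentile", "sex"),
  dominance = c("n_null", "windows_extra"),
  influence = c("window"),
  genes = c("enabled", "n_null", "period"),
  subjects = c("enabled", "n_null", "pairs", "include_markers"))

.validate_config <- function(config) {
  unknown <- setdiff(names(config), names(.config_spec))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (sec in names(config)) {
    allowed <- .config_spec[[sec]]
    if (is.null(allowed)) next
    bad <- setdiff(names(config[[sec]]), allowed)
    if (length(bad))
      stop("unknown key(s) in config section '", sec, "': ",
           paste(bad, collapse = ", "))
  }
  invisible(config)
}

.cfg <- function(config, section, key, default) {
  v <- config[[section]][[key]]
  v %||% default
}

.write_df <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE)
  for (j in which(num)) df[[j]] <- sprintf("%.12g", df[[j]])
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  path
}

#' Run the end-to-end synthetic colocalization pipeline
#'
#' Sequences the stages - synthetic input generation, factor reduction,
#' change-map extraction, constant surrogate-ensemble generation, window
#' scan, dominance scan, regional influence, developmental gene-expression
#' period tests, and the subject-level group test - in dependency order,
#' writing every result table plus a JSON manifest (settings, seed, file
#' checksums) into the run directory. One seed in the config determines all
#' stochastic behavior; reruns with the same config are byte-identical.
#'
#' @param config nested named list (or path to a YAML file) with sections
#'   `simulate`, `surrogates`, `reduce`, `windows`, `scan`, `dominance`,
#'   `influence`, `genes`, `subjects`; unknown keys are rejected before any
#'   computation.
#' @param out_dir run directory (created if needed); defaults to
#'   `config$out_dir`.
#' @return the run directory path, invisibly.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  .validate_config(config)
  out_dir <- out_dir %||% config$out_dir
  if (is.null(out_dir)) stop("an output directory is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)

  message("[simulate] generating synthetic inputs")
  np <- .cfg(config, "simulate", "n_parcels", 60L)
  nm <- .cfg(config, "simulate", "n_markers", 6L)
  na <- .cfg(config, "simulate", "n_active", 3L)
  geom <- make_geometry(np, seed = seed)
  sim_m <- simulate_markers(geom, k_latent = nm, loadings = diag(nm),
                            sa_range = .cfg(config, "simulate", "sa_range", 0.3),
                            noise_sd = .cfg(config, "simulate", "noise_sd", 0.1),
                            seed = seed + 1L)
  markers <- sim_m$markers
  w_active <- setNames(seq(1, 0.4, length.out = na),
                       markers$marker_names[seq_len(na)])
  schedule <- list(
    list(window = c(5, 30), weights = w_active),
    list(window = c(30, 60), weights = w_active / 2),
    list(window = c(60, 90), weights = -w_active))
  sim_t <- simulate_ct_trajectories(
    geom, markers, schedule,
    target_r2 = .cfg(config, "simulate", "target_r2", 0.5),
    delta_mean = .cfg(config, "simulate", "delta_mean", -0.01),
    delta_sd = .cfg(config, "simulate", "delta_sd", 0.02),
    seed = seed + 2L)
  grid <- sim_t$grid
  write_parcel_table(markers, file.path(out_dir, "markers.csv"))
  jsonlite::write_json(
    list(seed = seed,
         windows = lapply(sim_t$truth$windows, function(w)
           list(window = w$window, weights = as.list(w$weights),
                target_r2 = w$target_r2, realized_r2 = w$realized_r2))),
    file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)

  message("[surrogates] constant null ensembles")
  n_sur <- .cfg(config, "surrogates", "n", 200L)
  ens <- marker_surrogates(markers, geom, n = n_sur, seed = seed + 10L,
                           resample = .cfg(config, "surrogates", "resample",
                                           TRUE))
  fit_df <- data.frame(marker = names(ens),
                       median_fit_score = vapply(ens, function(e)
                         stats::median(e$fit_scores, na.rm = TRUE), 0))
  .write_df(fit_df, file.path(out_dir, "surrogate_fit.csv"))

  if (isTRUE(.cfg(config, "reduce", "enabled", TRUE))) {
    message("[reduce] factor analysis")
    sol <- fit_factors(markers,
                       threshold = .cfg(config, "reduce", "threshold", 0.01),
                       kappa = .cfg(config, "reduce", "kappa", 4))
    .write_df(data.frame(marker = sol$marker_names, sol$loadings,
                         check.names = FALSE),
              file.path(out_dir, "factor_loadings.csv"))
    .write_df(data.frame(parcel = rownames(sol$factor_scores),
                         sol$factor_scores, check.names = FALSE),
              file.path(out_dir, "factor_scores.csv"))
  }

  message("[trajectories] change maps")
  wins <- sliding_windows(
    start = .cfg(config, "windows", "start", 5),
    stop = .cfg(config, "windows", "stop", 90),
    step = .cfg(config, "windows", "step", 1),
    length = .cfg(config, "windows", "length", 5),
    extra = .cfg(config, "windows", "extra", list(c(5, 30))))
  cm_rows <- lapply(wins, function(w) {
    cm <- ct_change(grid, w[1], w[2])
    data.frame(window_start = w[1], window_end = w[2],
               parcel = cm$labels, delta = cm$values,
               stringsAsFactors = FALSE)
  })
  .write_df(do.call(rbind, cm_rows), file.path(out_dir, "change_maps.csv"))

  message("[scan] window regression scan")
  scan_tab <- scan_windows(
    grid, markers, wins, ens,
    mode = .cfg(config, "scan", "mode", "univariate"),
    baseline_correct = .cfg(config, "scan", "baseline_correct", FALSE),
    n_null = .cfg(config, "scan", "n_null", n_sur),
    percentile = .cfg(config, "scan", "percentile", 50),
    sex = .cfg(config, "scan", "sex", "average"))
  .write_df(scan_tab, file.path(out_dir, "scan.csv"))

  message("[dominance] window dominance scan")
  dom_tab <- dominance_scan(grid, markers, wins, ens,
                            n_null = .cfg(config, "dominance", "n_null",
                                          n_sur))
  .write_df(dom_tab, file.path(out_dir, "dominance.csv"))

  message("[influence] regional influence for the main period")
  inf_w <- .cfg(config, "influence", "window", c(5, 30))
  infl <- region_influence(ct_change(grid, inf_w[1], inf_w[2]), markers)
  .write_df(data.frame(parcel = infl$labels, infl$delta_pe,
                       check.names = FALSE),
            file.path(out_dir, "influence.csv"))

  if (isTRUE(.cfg(config, "genes", "enabled", TRUE))) {
    message("[genes] developmental expression period tests")
    nsig <- .cfg(config, "simulate", "n_signal_genes", 3L)
    signal <- setNames(lapply(seq_len(nsig), function(i)
      c(10 + 5 * (i - 1), 8, 1.5)), sprintf("SIG%02d", seq_len(nsig)))
    expr <- simulate_expression(
      signal_genes = signal,
      n_null_genes = .cfg(config, "simulate", "n_null_genes", 500L),
      seed = seed + 20L)
    gtab <- period_scan(expr,
                        gene_sets = lapply(names(signal), function(g) g) |>
                          setNames(names(signal)),
                        periods = .cfg(config, "genes", "period", c(5, 30)),
                        n_null = .cfg(config, "genes", "n_null", 500L),
                        seed = seed + 21L)
    .write_df(gtab, file.path(out_dir, "gene_periods.csv"))
  }

  if (isTRUE(.cfg(config, "subjects", "enabled", TRUE))) {
    message("[subjects] longitudinal subject-level validation")
    subs <- simulate_subjects(
      grid, geom, n_subjects = .cfg(config, "simulate", "n_subjects", 40L),
      subject_noise_sd = .cfg(config, "simulate", "subject_noise_sd", 0.05),
      seed = seed + 30L)
    qc <- qc_filter(subs)
    ch <- subject_changes(subs[qc$keep_rows, ],
                          session_pairs = .cfg(config, "subjects", "pairs",
                                               list(c("T0", "T2"))))
    gt <- group_null_test(
      ch, markers, ens,
      n_null = .cfg(config, "subjects", "n_null", min(n_sur, 200L)),
      include_markers = .cfg(config, "subjects", "include_markers", TRUE))
    cohort <- subject_dominance_scan(ch, markers, cohort_average = TRUE)
    per_sub <- subject_dominance_scan(ch, markers)
    .write_df(per_sub, file.path(out_dir, "subject_dominance.csv"))
    jsonlite::write_json(
      list(n_subjects = length(unique(ch$subject)),
           n_excluded_qc = qc$n_excluded,
           p_full = gt$p_full,
           observed_mean_full_r2 = gt$observed_mean_full_r2,
           p_markers = as.list(gt$p_markers %||% list()),
           cohort_average_full_r2 = cohort$full_r2),
      file.path(out_dir, "subjects_group_test.json"), auto_unbox = TRUE,
      digits = NA)
  }

  settings <- config
  settings$seed <- seed
  files <- sort(setdiff(list.files(out_dir), "manifest.json"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("ctcoloc")),
    seed = seed, settings = settings,
    files = lapply(setNames(files, files), function(f)
      unname(tools::md5sum(file.path(out_dir, f)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Write a human-readable summary report of a pipeline run
#'
#' Summarizes peak dominance windows per marker, FDR-significant windows,
#' gene period tests and the subject-level R-squared distribution from a
#' completed [run_pipeline()] directory. Regeneration is idempotent.
#'
#' @param run_dir a completed run directory.
#' @return the report file path, invisibly.
#' @export
write_report <- function(run_dir) {
  need <- c("manifest.json", "scan.csv", "dominance.csv")
  missing <- need[!file.exists(file.path(run_dir, need))]
  if (length(missing))
    stop("incomplete run; missing stage output(s): ",
         paste(missing, collapse = ", "))
  dom <- read.csv(file.path(run_dir, "dominance.csv"))
  scan <- read.csv(file.path(run_dir, "scan.csv"))
  lines <- c("ctcoloc run report", strrep("=", 60))
  mk <- setdiff(unique(dom$marker), "full_model")
  lines <- c(lines, "", "Peak dominance window per marker:")
  for (m in mk) {
    dm <- dom[dom$marker == m, ]
    i <- which.max(dm$r2)
    lines <- c(lines, sprintf(
      "  %-12s peak share %.3f in window (%g, %g), p = %.4g, q = %.4g",
      m, dm$r2[i], dm$window_start[i], dm$window_end[i], dm$p[i], dm$q[i]))
  }
  sig <- scan[scan$q < 0.05, ]
  lines <- c(lines, "",
             sprintf("FDR-significant scan models (q < 0.05): %d of %d",
                     nrow(sig), nrow(scan)))
  gp <- file.path(run_dir, "gene_periods.csv")
  if (file.exists(gp)) {
    g <- read.csv(gp)
    lines <- c(lines, "", "Gene period tests:",
               sprintf("  %-10s %-6s value %.3f  p = %.4g  q = %.4g",
                       g$gene_set, g$statistic, g$value, g$p, g$q))
  }
  sj <- file.path(run_dir, "subject_dominance.csv")
  if (file.exists(sj)) {
    s <- read.csv(sj)
    r2 <- s$r2[s$marker == "full_model"]
    qs <- quantile(r2, c(0.25, 0.5, 0.75), names = FALSE)
    lines <- c(lines, "", sprintf(
      "Subject-level full-model R2 quartiles: %.3f / %.3f / %.3f (n = %d)",
      qs[1], qs[2], qs[3], length(r2)))
  }
  path <- file.path(run_dir, "report.txt")
  writeLines(lines, path)
  invisible(path)
}
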