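#' Simulate spatially autocorrelated marker maps with latent-factor structure
#'
#' Latent factors are Gaussian random fields with covariance `exp(-d/rho)` on
#' the parcel distance matrix; marker m is the loading-weighted sum of
#' factors plus iid noise, Z-standardized column-wise.
#'
#' @param geom a [parcel_geometry()].
#' @param k_latent number of latent factors (>= 1).
#' @param loadings markers x k loading matrix; default identity (one
#'   independent field per marker).
#' @param sa_range spatial autocorrelation range `rho` (> 0), in the units of
#'   the distance matrix.
#' @param noise_sd iid noise SD added to each marker before standardization.
#' @param modality modality tag(s) for the markers.
#' @param seed RNG seed.
#' @return list with `markers` (a [marker_set()]) and `truth` (latent fields,
#'   loadings, noise SD, seed).
#' @export
simulate_markers <- function(geom, k_latent, loadings = diag(k_latent),
                             sa_range = 0.3, noise_sd = 0.1,
                             modality = "nuclear_imaging", seed = 1L) {
  stopifnot(inherits(geom, "parcel_geometry"), k_latent >= 1)
  loadings <- as.matrix(loadings)
  if (ncol(loadings) != k_latent)
    stop("loadings must have k_latent columns")
  n_markers <- nrow(loadings)
  ch <- .grf_chol(geom, sa_range)
  local_seed(seed, {
    p <- length(geom$labels)
    fac <- .grf_draw(ch, k_latent)
    raw <- fac %*% t(loadings) +
      matrix(rnorm(p * n_markers, sd = noise_sd), p, n_markers)
    colnames(raw) <- rownames(loadings) %||%
      sprintf("m%02d", seq_len(n_markers))
    rownames(raw) <- geom$labels
    ms <- zscore_parcels(marker_set(raw, modality = modality))
    truth <- list(latent_factors = fac, loading_matrix = loadings,
                  noise_sd = noise_sd, sa_range = sa_range, rng_seed = seed)
    list(markers = ms, truth = truth)
  })
}

.resolve_schedule <- function(schedule, marker_names) {
  lapply(schedule, function(e) {
    stopifnot(is.list(e), length(e$window) == 2L)
    w <- setNames(numeric(length(marker_names)), marker_names)
    if (!is.null(e$weights) && length(e$weights)) {
      if (is.null(names(e$weights)))
        stop("schedule weights must be named by marker")
      unknown <- setdiff(names(e$weights), marker_names)
      if (length(unknown)) stop("unknown marker in weights: ",
                                paste(unknown, collapse = ", "))
      w[names(e$weights)] <- e$weights
    }
    list(window = as.numeric(e$window), weights = w,
         target_r2 = e$target_r2, delta_mean = e$delta_mean,
         delta_sd = e$delta_sd)
  })
}

#' Simulate a CT trajectory grid with planted colocalization
#'
#' For each schedule window `(i, j)` a target relative-change map is planted
#' as `delta = s + noise`, where `s` is the weighted marker combination
#' `M w`, and the spatially autocorrelated noise field is residualized on `s`
#' and scaled so that `cor(M w, delta)^2` equals `target_r2` exactly. CT is
#' integrated multiplicatively across the window knots,
#' `CT(j) = CT(i) * (1 + delta)`, and emitted on the default 0.5-year grid by
#' monotone (Fritsch-Carlson) interpolation, so the planted change maps are
#' recovered exactly at window endpoints. Percentile curves are fixed
#' multiplicative offsets of the median and the two sex curves are symmetric
#' around it, so the sex-averaged median reproduces the planted changes.
#'
#' @param geom a [parcel_geometry()].
#' @param markers a [marker_set()] (standardized columns).
#' @param weight_schedule list of entries `list(window = c(i, j), weights =
#'   named numeric, target_r2 =, delta_mean =, delta_sd =)`; the windows must
#'   tile `[min age, max age]` contiguously. Per-entry values default to the
#'   function-level arguments.
#' @param target_r2 planted squared correlation between `M w` and the change
#'   map, in (0, 1]; ignored for all-zero weights.
#' @param delta_mean,delta_sd mean and SD (across parcels) of each window's
#'   relative change map; defaults emulate mild cortical thinning.
#' @param baseline_ct mean CT (mm) at the youngest age.
#' @param sa_range spatial range of the noise fields.
#' @param percentile_spread,sex_gap multiplicative offsets generating the
#'   percentile and sex curves.
#' @param ages output age grid; default [default_age_grid()].
#' @param seed RNG seed.
#' @return list with `grid` (a [trajectory_grid()]) and `truth` (per-window
#'   weights, planted maps, target and realized R-squared, seed).
#' @export
simulate_ct_trajectories <- function(geom, markers, weight_schedule,
                                     target_r2 = 0.5, delta_mean = -0.01,
                                     delta_sd = 0.02, baseline_ct = 2.5,
                                     sa_range = 0.3, percentile_spread = 0.04,
                                     sex_gap = 0.02,
                                     ages = default_age_grid(), seed = 1L) {
  stopifnot(inherits(geom, "parcel_geometry"), inherits(markers, "marker_set"))
  sched <- .resolve_schedule(weight_schedule, markers$marker_names)
  starts <- vapply(sched, function(e) e$window[1], 0)
  sched <- sched[order(starts)]
  knots <- c(vapply(sched, function(e) e$window[1], 0),
             sched[[length(sched)]]$window[2])
  if (abs(knots[1] - min(ages)) > 1e-8 ||
      abs(knots[length(knots)] - max(ages)) > 1e-8 ||
      any(abs(vapply(sched, function(e) e$window[2], 0) -
              knots[-1]) > 1e-8))
    stop("schedule windows must tile the age grid contiguously")
  ch <- .grf_chol(geom, sa_range)
  p <- length(geom$labels)
  M <- markers$x[geom$labels, , drop = FALSE]
  local_seed(seed, {
    base <- baseline_ct * (1 + 0.05 * as.vector(.grf_draw(ch, 1)))
    base <- pmax(base, 0.2 * baseline_ct)
    ct_knots <- matrix(NA_real_, p, length(knots))
    ct_knots[, 1] <- base
    truth_windows <- vector("list", length(sched))
    for (k in seq_along(sched)) {
      e <- sched[[k]]
      r2 <- e$target_r2 %||% target_r2
      dm <- e$delta_mean %||% delta_mean
      ds <- e$delta_sd %||% delta_sd
      s0 <- as.vector(M %*% e$weights)
      noise <- as.vector(.grf_draw(ch, 1))
      if (all(e$weights == 0)) {
        v <- noise - mean(noise)
        delta <- dm + if (ds > 0) ds * v / sd(v) else 0
        realized <- 0
      } else {
        if (!is.finite(r2) || r2 <= 0 || r2 > 1)
          stop("target_r2 must be in (0, 1] when weights are nonzero")
        u <- (s0 - mean(s0)) / sd(s0)
        res <- noise - mean(noise) - sum((noise - mean(noise)) * u) / sum(u^2) * u
        v <- if (sd(res) > 0) res / sd(res) else res
        delta <- dm + ds * (sqrt(r2) * u + sqrt(1 - r2) * v)
        realized <- cor(s0, delta)^2
      }
      ct_knots[, k + 1] <- ct_knots[, k] * (1 + delta)
      if (any(ct_knots[, k + 1] <= 0))
        stop("CT became non-positive during integration; ",
             "reduce the change-map amplitude (delta_mean/delta_sd)")
      truth_windows[[k]] <- list(window = e$window, weights = e$weights,
                                 target_r2 = if (all(e$weights == 0)) 0 else r2,
                                 realized_r2 = realized, delta = delta,
                                 delta_mean = dm, delta_sd = ds)
    }
    med <- matrix(NA_real_, p, length(ages))
    for (r in seq_len(p)) {
      f <- splinefun(knots, ct_knots[r, ], method = "monoH.FC")
      med[r, ] <- f(ages)
    }
    pct <- default_percentiles()
    zoff <- qnorm(pct / 100)
    arr <- array(NA_real_, dim = c(p, length(ages), length(pct), 2L))
    for (q in seq_along(pct)) {
      curve <- med * (1 + percentile_spread * zoff[q])
      arr[, , q, 1] <- curve * (1 + sex_gap / 2)  # female
      arr[, , q, 2] <- curve * (1 - sex_gap / 2)  # male
    }
    if (any(arr <= 0))
      stop("CT grid contains non-positive values; reduce amplitudes")
    grid <- trajectory_grid(arr, labels = geom$labels, ages = ages,
                            percentiles = pct, sexes = c("female", "male"))
    list(grid = grid,
         truth = list(windows = truth_windows, rng_seed = seed,
                      baseline_ct = baseline_ct))
  })
}

#' Simulate longitudinal subjects around a population trajectory grid
#'
#' Each subject's CT is the population sex-average median curve evaluated at
#' jittered session ages, scaled by a subject-level spatially correlated
#' multiplicative offset (constant across sessions), a small multiplicative
#' site effect, plus iid session noise. A skewed surface-defect count is
#' drawn per session for QC testing.
#'
#' @param grid a [trajectory_grid()].
#' @param geom the [parcel_geometry()] the grid lives on.
#' @param n_subjects number of subjects.
#' @param sessions named numeric vector of nominal session ages, e.g.
#'   `c(T0 = 10, T2 = 12)`; at least 2 for longitudinal output.
#' @param age_jitter SD (years) of per-subject age jitter, shared across a
#'   subject's sessions.
#' @param subject_noise_sd SD of the subject-level multiplicative offset field.
#' @param session_noise_sd SD (mm) of iid per-session measurement noise.
#' @param n_sites,site_sd number of sites and SD of multiplicative site
#'   effects (0 disables site effects).
#' @param sa_range spatial range of the subject offset fields.
#' @param seed RNG seed.
#' @return a `data.frame` of class `subject_table` with columns `subject,
#'   session, age, sex, site, defect_count` followed by one CT column per
#'   parcel; parcel labels stored in `attr(, "parcel_labels")`.
#' @export
simulate_subjects <- function(grid, geom, n_subjects,
                              sessions = c(T0 = 10, T2 = 12),
                              age_jitter = 0.25, subject_noise_sd = 0.05,
                              session_noise_sd = 0.01, n_sites = 4,
                              site_sd = 0.01, sa_range = 0.3, seed = 1L) {
  stopifnot(inherits(grid, "trajectory_grid"))
  if (length(sessions) < 2L)
    stop("need >=2 sessions per subject for longitudinal output")
  if (is.null(names(sessions)))
    names(sessions) <- paste0("T", seq_along(sessions) - 1)
  if (any(sessions < min(grid$ages) | sessions > max(grid$ages)))
    stop("session ages outside the trajectory grid range")
  ch <- if (subject_noise_sd > 0) .grf_chol(geom, sa_range) else NULL
  p <- length(grid$labels)
  med <- (grid$ct[, , which(grid$percentiles == 50), "female"] +
          grid$ct[, , which(grid$percentiles == 50), "male"]) / 2
  pop_at <- function(a) {
    a <- min(max(a, min(grid$ages)), max(grid$ages))
    i <- findInterval(a, grid$ages, all.inside = TRUE)
    w <- (a - grid$ages[i]) / (grid$ages[i + 1] - grid$ages[i])
    med[, i] * (1 - w) + med[, i + 1] * w
  }
  local_seed(seed, {
    sites <- paste0("site", seq_len(max(1, n_sites)))
    site_fx <- setNames(if (site_sd > 0) rnorm(length(sites), sd = site_sd)
                        else numeric(length(sites)), sites)
    ns <- length(sessions)
    offs <- if (subject_noise_sd > 0)
      subject_noise_sd * .grf_draw(ch, n_subjects)
    else matrix(0, p, n_subjects)
    jit <- if (age_jitter > 0) rnorm(n_subjects, sd = age_jitter)
           else numeric(n_subjects)
    sex <- sample(c("female", "male"), n_subjects, replace = TRUE)
    site <- sample(sites, n_subjects, replace = TRUE)
    nrows <- n_subjects * ns
    ct_mat <- matrix(NA_real_, nrows, p)
    age_vec <- numeric(nrows)
    r <- 0L
    for (s in seq_len(n_subjects)) {
      for (k in seq_len(ns)) {
        r <- r + 1L
        age <- min(max(sessions[k] + jit[s], min(grid$ages)),
                   max(grid$ages))
        age_vec[r] <- age
        ct_mat[r, ] <- pop_at(age) * (1 + offs[, s]) *
          (1 + site_fx[site[s]])
      }
    }
    if (session_noise_sd > 0)
      ct_mat <- ct_mat + matrix(rnorm(nrows * p, sd = session_noise_sd),
                                nrows, p)
    out <- data.frame(
      subject = rep(sprintf("sub%04d", seq_len(n_subjects)), each = ns),
      session = rep(names(sessions), n_subjects),
      age = age_vec,
      sex = rep(sex, each = ns),
      site = rep(site, each = ns),
      defect_count = round(rlnorm(nrows, meanlog = log(30), sdlog = 0.5)),
      ct_mat, check.names = FALSE, stringsAsFactors = FALSE)
    names(out)[-(1:6)] <- grid$labels
    attr(out, "parcel_labels") <- grid$labels
    class(out) <- c("subject_table", class(out))
    out
  })
}

#' Simulate developmental gene-expression trajectories
#'
#' Subject ages are log-uniform over the age range (defaults mirror a
#' postnatal donor cohort: n = 33, 0.33-82.05 years). Signal genes follow
#' `baseline + amplitude * exp(-(age - peak)^2 / (2 width^2)) + noise`; null
#' genes are flat plus noise and flagged `non_brain`.
#'
#' @param n_subjects number of donors (>= 5).
#' @param age_range length-2 range in years.
#' @param signal_genes named list, gene -> `c(peak_age, width, amplitude)`.
#' @param n_null_genes number of flat non-brain genes.
#' @param baseline baseline log2 expression level.
#' @param noise_sd iid noise SD on every gene x subject value.
#' @param seed RNG seed.
#' @return an object of class `dev_expression_table` with fields `genes`,
#'   `ages`, `x` (genes x subjects), `non_brain` (logical per gene).
#' @export
simulate_expression <- function(n_subjects = 33, age_range = c(0.33, 82.05),
                                signal_genes = list(), n_null_genes = 2154,
                                baseline = 5, noise_sd = 0.5, seed = 1L) {
  if (n_subjects < 5L) stop("need >= 5 subjects")
  for (g in signal_genes)
    if (g[2] <= 0) stop("signal gene width must be > 0")
  local_seed(seed, {
    ages <- sort(exp(runif(n_subjects, log(age_range[1]), log(age_range[2]))))
    ngenes <- length(signal_genes) + n_null_genes
    gnames <- c(names(signal_genes),
                sprintf("NULLG%04d", seq_len(n_null_genes)))
    x <- matrix(baseline + rnorm(ngenes * n_subjects, sd = noise_sd),
                ngenes, n_subjects, dimnames = list(gnames, NULL))
    for (i in seq_along(signal_genes)) {
      g <- signal_genes[[i]]
      x[i, ] <- x[i, ] + g[3] * exp(-(ages - g[1])^2 / (2 * g[2]^2))
    }
    structure(list(genes = gnames, ages = ages, x = x,
                   non_brain = c(rep(FALSE, length(signal_genes)),
                                 rep(TRUE, n_null_genes))),
              class = "dev_expression_table")
  })
}

#' @export
print.dev_expression_table <- function(x, ...) {
  cat(sprintf(
    "dev_expression_table: %d genes (%d non-brain) x %d subjects, ages %.2f-%.2f\n",
    length(x$genes), sum(x$non_brain), length(x$ages), min(x$ages),
    max(x$ages)))
  invisible(x)
}
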