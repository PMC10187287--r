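# Centered-cross-product R^2 of each target column on a fixed predictor
# matrix (intercept implicit through centering).
.r2_quad <- function(X, Y) {
  Xc <- sweep(X, 2L, colMeans(X))
  Yc <- sweep(Y, 2L, colMeans(Y))
  as.vector(cpp_block_r2(Xc, Yc, ncol(Xc)))
}

.adjust_r2 <- function(r2, n, p) 1 - (1 - r2) * (n - 1) / (n - p - 1)

# Residualize y on covariate columns Z (with intercept).
.residualize <- function(y, Z) {
  fit <- lm.fit(cbind(1, Z), y)
  fit$residuals
}

#' Ordinary least-squares spatial R-squared
#'
#' Regresses a change map (or any parcel map) on a set of marker maps across
#' parcels (listwise-complete, intercept included) and returns raw and
#' adjusted R-squared with coefficients.
#'
#' @param target a [change_map()] / [parcel_map()] or numeric vector.
#' @param predictors a [marker_set()].
#' @return an object of class `regression_result` with `r2`, `adjusted_r2`,
#'   `coefficients`, `n_parcels`, `predictor_names`.
#' @export
spatial_r2 <- function(target, predictors) {
  stopifnot(inherits(predictors, "marker_set"))
  if (is.numeric(target))
    target <- parcel_map(target, labels = predictors$labels, name = "target")
  al <- align_and_mask(target, predictors, policy = "listwise")
  y <- al$sets[[1]]$values
  X <- al$sets[[2]]$x
  n <- length(y); p <- ncol(X)
  if (n <= p + 1L) stop("need more parcels than predictors + 1")
  qrX <- qr(cbind(`(Intercept)` = 1, X))
  if (qrX$rank < p + 1L) {
    aliased <- colnames(qrX$qr)[qrX$pivot[-seq_len(qrX$rank)]]
    stop("rank-deficient design; collinear columns: ",
         paste(aliased, collapse = ", "))
  }
  fit <- lm.fit(cbind(`(Intercept)` = 1, X), y)
  r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  structure(list(r2 = r2, adjusted_r2 = .adjust_r2(r2, n, p),
                 coefficients = fit$coefficients[-1],
                 intercept = fit$coefficients[1],
                 n_parcels = n, predictor_names = colnames(X)),
            class = "regression_result")
}

#' Empirical one-sided p-value against a null distribution
#'
#' `p = (1 + #\{null >= observed\}) / (1 + N)` for the positive side (ties
#' count against the observation); `>=` becomes `<=` for `side =
#' "negative"`. Guaranteed > 0.
#'
#' @param observed observed statistic (scalar).
#' @param nulls numeric vector of null statistics (non-empty).
#' @param side `"positive"` or `"negative"`.
#' @return empirical p-value in (0, 1].
#' @export
empirical_p <- function(observed, nulls, side = c("positive", "negative")) {
  side <- match.arg(side)
  nulls <- nulls[is.finite(nulls)]
  if (!length(nulls)) stop("empty null distribution")
  k <- if (side == "positive") sum(nulls >= observed) else sum(nulls <= observed)
  (1 + k) / (1 + length(nulls))
}

#' Benjamini-Hochberg FDR correction within families
#'
#' Step-up BH applied independently within each family of p-values.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @param family family labels (same length as `p`); `NULL` = one family.
#' @return vector of q-values, same order as `p`.
#' @export
fdr_bh <- function(p, family = NULL) {
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p-values must lie in [0, 1]")
  if (is.null(family)) family <- rep("all", length(p))
  q <- rep(NA_real_, length(p))
  for (f in unique(family)) {
    i <- which(family == f)
    q[i] <- p.adjust(p[i], method = "BH")
  }
  q
}

# Assemble the k-th joint null predictor matrix from per-marker ensembles.
.null_predictors <- function(ensembles, k, labels) {
  X <- vapply(ensembles, function(e) e$maps[labels, k], numeric(length(labels)))
  colnames(X) <- names(ensembles)
  X
}

#' Scan precomputed change maps against markers with surrogate nulls
#'
#' The inference core behind [scan_windows()]. For each target map and each
#' model (one per marker in `univariate` mode; one per modality or one
#' overall in the multivariate modes), the observed R-squared is compared to
#' null R-squared values in which iteration k uses the k-th surrogate of
#' every predictor simultaneously, giving positive-sided empirical p-values.
#' FDR families: univariate within each modality across all targets;
#' multivariate across all models and modalities.
#'
#' @param targets list of [change_map()] objects (or a single one).
#' @param markers a [marker_set()].
#' @param ensembles named list of surrogate ensembles, one per marker (see
#'   [marker_surrogates()]).
#' @param mode `"univariate"`, `"multivariate_by_modality"` or
#'   `"multivariate_all"`.
#' @param covariates optional [marker_set()] of nuisance maps residualized
#'   from each target before regression.
#' @param n_null number of null iterations (default: ensemble size).
#' @return data.frame of class `inference_table` with columns `window_start`,
#'   `window_end`, `marker`, `modality`, `r2`, `r2_adj`, `p`, `family`, `q`,
#'   `n_parcels`.
#' @export
scan_change_maps <- function(targets, markers, ensembles,
                             mode = c("univariate", "multivariate_by_modality",
                                      "multivariate_all"),
                             covariates = NULL, n_null = NULL) {
  mode <- match.arg(mode)
  if (inherits(targets, "change_map")) targets <- list(targets)
  stopifnot(inherits(markers, "marker_set"))
  miss <- setdiff(markers$marker_names, names(ensembles))
  if (length(miss))
    stop("missing surrogate ensemble for marker(s): ",
         paste(miss, collapse = ", "))
  n_null <- n_null %||% min(vapply(ensembles, function(e) ncol(e$maps), 0L))
  short <- names(ensembles)[vapply(ensembles, function(e) ncol(e$maps), 0L) <
                              n_null]
  if (length(short))
    stop("ensemble smaller than n_null for: ", paste(short, collapse = ", "))

  al <- align_and_mask(c(targets, list(markers)), policy = "listwise")
  labels <- al$labels
  X <- al$sets[[length(al$sets)]]$x
  Y <- vapply(al$sets[seq_along(targets)], function(m) m$values,
              numeric(length(labels)))
  Y <- matrix(Y, ncol = length(targets))
  if (!is.null(covariates)) {
    Zc <- covariates$x[match(labels, covariates$labels), , drop = FALSE]
    Y <- apply(Y, 2L, .residualize, Z = Zc)
  }
  groups <- switch(mode,
    univariate = lapply(markers$marker_names, function(m) m),
    multivariate_by_modality = split(markers$marker_names,
                                     markers$modality[markers$marker_names]),
    multivariate_all = list(all = markers$marker_names))
  if (mode == "univariate") names(groups) <- markers$marker_names

  n <- length(labels)
  Xnull <- lapply(seq_len(n_null), function(k)
    .null_predictors(ensembles, k, labels))

  rows <- list()
  for (gi in seq_along(groups)) {
    g <- groups[[gi]]
    mod <- paste(unique(markers$modality[g]), collapse = "+")
    label <- if (mode == "univariate") g else
      paste0("combined_", if (mode == "multivariate_all") "all" else mod)
    obs <- .r2_quad(X[, g, drop = FALSE], Y)
    nullmat <- vapply(Xnull, function(Xk)
      .r2_quad(Xk[, g, drop = FALSE], Y), numeric(ncol(Y)))
    nullmat <- matrix(nullmat, nrow = ncol(Y))
    for (t in seq_along(targets)) {
      p <- empirical_p(obs[t], nullmat[t, ])
      rows[[length(rows) + 1L]] <- data.frame(
        window_start = targets[[t]]$window[1],
        window_end = targets[[t]]$window[2],
        marker = label, modality = mod, r2 = obs[t],
        r2_adj = .adjust_r2(obs[t], n, length(g)), p = p,
        family = if (mode == "univariate") paste0("univariate_", mod)
                 else "multivariate",
        n_parcels = n, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$q <- fdr_bh(out$p, out$family)
  class(out) <- c("inference_table", class(out))
  out
}

#' Sliding-window regression scan of CT change on markers
#'
#' Extracts the relative CT change map for every window from the trajectory
#' grid and delegates to [scan_change_maps()]. With `baseline_correct` the
#' change map is first residualized on the cross-sectional CT map at the
#' window start, so the predictor count (and hence null comparability) is
#' preserved.
#'
#' @param grid a [trajectory_grid()].
#' @param markers a [marker_set()].
#' @param windows list of windows from [sliding_windows()].
#' @param ensembles constant per-marker surrogate ensembles.
#' @param mode,covariates,n_null see [scan_change_maps()].
#' @param baseline_correct residualize each change map on baseline CT.
#' @param percentile,sex CT curve selection (see [ct_change()]).
#' @return an `inference_table` data.frame.
#' @export
scan_windows <- function(grid, markers, windows, ensembles,
                         mode = c("univariate", "multivariate_by_modality",
                                  "multivariate_all"),
                         baseline_correct = FALSE, covariates = NULL,
                         n_null = NULL, percentile = 50, sex = "average") {
  mode <- match.arg(mode)
  targets <- lapply(windows, function(w) {
    cm <- ct_change(grid, w[1], w[2], percentile = percentile, sex = sex)
    if (baseline_correct) {
      base <- .ct_slice(grid, w[1], percentile, sex)
      cm$values <- .residualize(cm$values, base)
    }
    cm
  })
  scan_change_maps(targets, markers, ensembles, mode = mode,
                   covariates = covariates, n_null = n_null)
}

#' Spearman correlation between a window-wise statistic and a confound
#'
#' E.g. correlating the per-window R-squared series with the number of
#' subjects behind each window, or with the distance in years between the
#' window midpoint and the marker source age.
#'
#' @param window_statistics numeric per-window values (>= 4).
#' @param covariate numeric per-window covariate, same length.
#' @return list with `rho` and asymptotic `p`.
#' @export
confound_correlation <- function(window_statistics, covariate) {
  stopifnot(length(window_statistics) == length(covariate))
  if (length(covariate) < 4L) stop("need >= 4 windows")
  if (sd(covariate, na.rm = TRUE) == 0) stop("constant covariate")
  ct <- suppressWarnings(cor.test(window_statistics, covariate,
                                  method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value)
}
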