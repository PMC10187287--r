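# Centered cross-moment pieces for the dominance kernel.
.dom_moments <- function(X, Y) {
  Xc <- sweep(X, 2L, colMeans(X))
  Yc <- sweep(Y, 2L, colMeans(Y))
  list(Cxx = crossprod(Xc), Cxy = crossprod(Xc, Yc), vy = colSums(Yc^2))
}

.check_dom_design <- function(X) {
  p <- ncol(X)
  if (p > 15L)
    stop("dominance analysis supports at most 15 predictors (2^p subset ",
         "enumeration); reduce the predictor set first")
  qrX <- qr(cbind(1, X))
  if (qrX$rank < p + 1L) stop("rank-deficient predictor matrix")
}

#' Dominance-analysis decomposition of explained variance
#'
#' Total (general) dominance: for each predictor x, the average over subset
#' sizes s of the mean incremental R-squared gained by adding x to each
#' size-s subset of the remaining predictors. The per-predictor shares sum
#' exactly to the full-model R-squared (raw R-squared; the adjusted value is
#' reported for the full model only, since the sum identity does not hold for
#' adjusted components). Spearman correlations between target and each
#' marker are emitted alongside to sign the associations.
#'
#' @param target a [change_map()] / [parcel_map()] or numeric vector.
#' @param predictors a [marker_set()] with at most 15 markers.
#' @return an object of class `dominance_result` with `full_r2`,
#'   `adjusted_r2`, `total_dominance` (named), `spearman_rho` (named),
#'   `n_parcels`, `window`.
#' @export
dominance_decompose <- function(target, predictors) {
  stopifnot(inherits(predictors, "marker_set"))
  if (is.numeric(target))
    target <- parcel_map(target, labels = predictors$labels, name = "target")
  al <- align_and_mask(target, predictors, policy = "listwise")
  y <- al$sets[[1]]$values
  X <- al$sets[[2]]$x
  .check_dom_design(X)
  mo <- .dom_moments(X, matrix(y, ncol = 1))
  res <- cpp_dominance(mo$Cxx, mo$Cxy, mo$vy)
  dom <- setNames(as.vector(res$dominance), colnames(X))
  rho <- apply(X, 2L, function(col)
    suppressWarnings(cor(col, y, method = "spearman")))
  structure(list(full_r2 = as.vector(res$full_r2),
                 adjusted_r2 = .adjust_r2(as.vector(res$full_r2),
                                          length(y), ncol(X)),
                 total_dominance = dom, spearman_rho = rho,
                 n_parcels = length(y),
                 window = target$window %||% c(NA, NA)),
            class = "dominance_result")
}

#' @export
print.dominance_result <- function(x, ...) {
  cat(sprintf("dominance_result: full R2 = %.4f over %d parcels\n",
              x$full_r2, x$n_parcels))
  print(round(sort(x$total_dominance, decreasing = TRUE), 4))
  invisible(x)
}

# Dominance of many targets at once against one predictor matrix; returns
# list(full_r2 = n-vector, dominance = p x n).
.dominance_multi <- function(X, Y) {
  mo <- .dom_moments(X, Y)
  cpp_dominance(mo$Cxx, mo$Cxy, mo$vy)
}

#' Window-wise dominance scan with surrogate-null significance
#'
#' Runs [dominance_decompose()] for the change map of every window, then
#' recomputes the whole set of statistics for each null iteration with all
#' predictors jointly replaced by their k-th surrogates, yielding positive-
#' sided empirical p-values for the full-model R-squared and every
#' predictor-wise total dominance. All p-values (windows x (1 + p)) form a
#' single FDR family.
#'
#' @param grid a [trajectory_grid()].
#' @param markers a [marker_set()] (<= 15 markers).
#' @param windows list of windows; the default adds the (5, 30) main
#'   developmental period to the 81 sliding windows.
#' @param ensembles constant per-marker surrogate ensembles.
#' @param n_null number of null iterations (default: ensemble size).
#' @param percentile,sex CT curve selection.
#' @return data.frame of class `dominance_table`: one row per window x
#'   (full model + marker) with `r2` (dominance share or full R2), `p`, `q`,
#'   `spearman_rho`.
#' @export
dominance_scan <- function(grid, markers, windows = sliding_windows(),
                           ensembles, n_null = NULL, percentile = 50,
                           sex = "average") {
  stopifnot(inherits(markers, "marker_set"))
  n_null <- n_null %||% min(vapply(ensembles, function(e) ncol(e$maps), 0L))
  targets <- lapply(windows, function(w)
    ct_change(grid, w[1], w[2], percentile = percentile, sex = sex))
  al <- align_and_mask(c(targets, list(markers)), policy = "listwise")
  labels <- al$labels
  X <- al$sets[[length(al$sets)]]$x
  .check_dom_design(X)
  Y <- vapply(al$sets[seq_along(targets)], function(m) m$values,
              numeric(length(labels)))
  Y <- matrix(Y, ncol = length(targets))
  p <- ncol(X)

  obs <- .dominance_multi(X, Y)
  null_full <- matrix(NA_real_, length(targets), n_null)
  null_dom <- array(NA_real_, c(p, length(targets), n_null))
  for (k in seq_len(n_null)) {
    Xk <- .null_predictors(ensembles, k, labels)[, colnames(X), drop = FALSE]
    nk <- .dominance_multi(Xk, Y)
    null_full[, k] <- nk$full_r2
    null_dom[, , k] <- nk$dominance
  }

  rows <- list()
  for (t in seq_along(targets)) {
    w <- windows[[t]]
    rows[[length(rows) + 1L]] <- data.frame(
      window_start = w[1], window_end = w[2], marker = "full_model",
      r2 = obs$full_r2[t],
      r2_adj = .adjust_r2(obs$full_r2[t], length(labels), p),
      p = empirical_p(obs$full_r2[t], null_full[t, ]),
      spearman_rho = NA_real_, stringsAsFactors = FALSE)
    for (x in seq_len(p)) {
      rows[[length(rows) + 1L]] <- data.frame(
        window_start = w[1], window_end = w[2], marker = colnames(X)[x],
        r2 = obs$dominance[x, t], r2_adj = NA_real_,
        p = empirical_p(obs$dominance[x, t], null_dom[x, t, ]),
        spearman_rho = suppressWarnings(
          cor(X[, x], Y[, t], method = "spearman")),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$family <- "dominance"
  out$q <- fdr_bh(out$p, out$family)
  class(out) <- c("dominance_table", class(out))
  out
}

#' Regional influence (prediction-error difference) maps
#'
#' For each predictor x, refits the model without x and maps, per parcel,
#' `dPE = |residual of reduced model| - |residual of full model|`. Positive
#' values mark parcels whose fit depends on x; a predictor whose removal
#' leaves fitted values unchanged has an identically zero column.
#'
#' @param target a [change_map()] / [parcel_map()] or numeric vector.
#' @param predictors a [marker_set()].
#' @param signed return signed residual differences instead of the absolute
#'   form (diagnostic).
#' @return an object of class `influence_map`: list with `labels`,
#'   `delta_pe` (parcel x marker matrix), `window`.
#' @export
region_influence <- function(target, predictors, signed = FALSE) {
  stopifnot(inherits(predictors, "marker_set"))
  if (is.numeric(target))
    target <- parcel_map(target, labels = predictors$labels, name = "target")
  al <- align_and_mask(target, predictors, policy = "listwise")
  y <- al$sets[[1]]$values
  X <- al$sets[[2]]$x
  p <- ncol(X)
  qr_full <- qr(cbind(1, X))
  if (qr_full$rank < p + 1L) stop("rank-deficient full model")
  res_full <- lm.fit(cbind(1, X), y)$residuals
  dpe <- matrix(NA_real_, length(y), p,
                dimnames = list(al$labels, colnames(X)))
  for (x in seq_len(p)) {
    Xr <- X[, -x, drop = FALSE]
    if (ncol(Xr) > 0 && qr(cbind(1, Xr))$rank < ncol(Xr) + 1L)
      stop("rank-deficient reduced model without '", colnames(X)[x], "'")
    res_red <- lm.fit(cbind(1, Xr), y)$residuals
    dpe[, x] <- if (signed) res_red - res_full
                else abs(res_red) - abs(res_full)
  }
  structure(list(labels = al$labels, delta_pe = dpe,
                 window = target$window %||% c(NA, NA)),
            class = "influence_map")
}
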