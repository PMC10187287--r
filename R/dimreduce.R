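# Minimum-residual (ULS) factor extraction: given uniquenesses psi, the best
# rank-nf approximation of R - diag(psi) is its eigen truncation; optimize
# psi to minimize the off-diagonal squared residuals of R - LL'.
.minres_loadings <- function(R, nf) {
  p <- ncol(R)
  eig_load <- function(psi) {
    e <- eigen(R - diag(psi, p), symmetric = TRUE)
    k <- seq_len(nf)
    L <- e$vectors[, k, drop = FALSE] %*%
      diag(sqrt(pmax(e$values[k], 0)), nf)
    L
  }
  objective <- function(psi) {
    L <- eig_load(psi)
    res <- R - tcrossprod(L)
    diag(res) <- 0
    sum(res^2)
  }
  smc <- tryCatch(1 - 1 / diag(solve(R)), error = function(e)
    rep(0.5, p))
  start <- pmin(pmax(1 - smc, 0.05), 0.95)
  opt <- optim(start, objective, method = "L-BFGS-B",
               lower = rep(0.001, p), upper = rep(1, p),
               control = list(maxit = 500))
  L <- eig_load(opt$par)
  rownames(L) <- rownames(R)
  list(loadings = L, uniquenesses = opt$par, criterion = opt$value)
}

# Flip each loading column so its largest-|loading| entry is positive.
.fix_signs <- function(L) {
  for (j in seq_len(ncol(L))) {
    i <- which.max(abs(L[, j]))
    if (L[i, j] < 0) L[, j] <- -L[, j]
  }
  L
}

.max_extractable <- function(p) {
  # largest nf with non-negative degrees of freedom of the factor model
  nf <- 1L
  while (nf < p) {
    df <- p * (p - 1) / 2 - p * (nf + 1L) + (nf + 1L) * nf / 2
    if (df < 0) break
    nf <- nf + 1L
  }
  max(1L, nf)
}

#' Factor-analytic reduction of a marker set
#'
#' Minimum-residual (minres) extraction on the marker correlation matrix.
#' Factor retention is decided on the UNROTATED variance fractions
#' (sum of squared loadings / number of markers): every factor explaining at
#' least `threshold` of the set's variance is kept. Retained factors are
#' promax-rotated (oblique; correlated factors allowed), per-parcel factor
#' scores are computed by the regression (Thurstone) method, and factors are
#' named by assigning each marker to the factor it loads on most (see
#' [name_factors()]).
#'
#' @param markers a [marker_set()] with >= 2 markers (columns are
#'   standardized internally).
#' @param threshold unrotated variance fraction for retention, in (0, 1);
#'   default 0.01.
#' @param rotation `"promax"` or `"none"`.
#' @param kappa promax power (conventional default 4).
#' @return an object of class `factor_solution`: `loadings` (markers x
#'   factors, rotated pattern), `unrotated_variance_fractions` (all
#'   extractable factors), `factor_scores` (parcels x factors),
#'   `factor_names`, `assignments` (marker -> factor),
#'   `total_variance_explained` (fraction, from communalities),
#'   `rotated_variance_fractions`, `phi` (factor correlations),
#'   `communalities`, `retention_threshold`.
#' @export
fit_factors <- function(markers, threshold = 0.01,
                        rotation = c("promax", "none"), kappa = 4) {
  rotation <- match.arg(rotation)
  stopifnot(inherits(markers, "marker_set"))
  if (threshold <= 0 || threshold >= 1)
    stop("retention threshold must lie in (0, 1)")
  X <- markers$x[complete.cases(markers$x), , drop = FALSE]
  p <- ncol(X)
  if (p < 2L) stop("need >= 2 markers")
  if (nrow(X) <= p)
    warning("fewer parcels than markers + 1; solution may be unstable")
  Z <- scale(X)
  R <- cor(X)
  if (!all(is.finite(R))) stop("constant marker column")
  if (rcond(R) < 1e-12)
    stop("singular marker correlation matrix; consider ridge jitter or ",
         "dropping collinear markers")
  nf_max <- .max_extractable(p)
  full <- .minres_loadings(R, nf_max)
  fractions <- colSums(full$loadings^2) / p
  ord <- order(fractions, decreasing = TRUE)
  fractions <- fractions[ord]
  k <- sum(fractions >= threshold)
  if (k == 0L) stop("no factors retained at threshold ", threshold)
  fit <- if (k == nf_max) list(loadings = full$loadings[, ord, drop = FALSE])
         else .minres_loadings(R, k)
  L <- .fix_signs(fit$loadings[, seq_len(k), drop = FALSE])
  if (rotation == "promax" && k > 1L) {
    pm <- promax(L, m = kappa)
    Lr <- unclass(pm$loadings)
    phi <- tcrossprod(solve(pm$rotmat))
    # sign convention: flip columns so the largest-|loading| entry is
    # positive, and flip phi consistently so the factor model is unchanged
    s <- vapply(seq_len(k), function(j) {
      sign(Lr[which.max(abs(Lr[, j])), j])
    }, 0)
    Lr <- sweep(Lr, 2L, s, `*`)
    phi <- phi * tcrossprod(s)
  } else {
    Lr <- L
    phi <- diag(k)
  }
  dimnames(phi) <- NULL
  structure_mat <- Lr %*% phi
  W <- solve(R, structure_mat)
  scores <- Z %*% W
  # communality is rotation-invariant; computing it from the unrotated
  # loadings keeps it stable when a degenerate (e.g. null-map) solution
  # makes the oblique rotation matrix near-singular
  communal <- rowSums(L^2)
  rot_var <- colSums(structure_mat * Lr) / p
  sol <- structure(list(
    loadings = Lr,
    unrotated_variance_fractions = fractions,
    factor_scores = scores,
    phi = phi,
    communalities = setNames(communal, colnames(X)),
    rotated_variance_fractions = rot_var,
    total_variance_explained = sum(communal) / p,
    retention_threshold = threshold,
    marker_names = colnames(X),
    modality = markers$modality,
    kappa = kappa, rotation = rotation),
    class = "factor_solution")
  nm <- name_factors(sol)
  sol$factor_names <- nm$labels
  sol$assignments <- nm$assignments
  colnames(sol$loadings) <- nm$labels
  colnames(sol$factor_scores) <- nm$labels
  rownames(sol$factor_scores) <- rownames(X)
  sol
}

#' @export
print.factor_solution <- function(x, ...) {
  cat(sprintf(
    "factor_solution: %d factor(s) retained (threshold %.2g), total variance %.1f%%\n",
    ncol(x$loadings), x$retention_threshold,
    100 * x$total_variance_explained))
  cat("factors:", paste(x$factor_names, collapse = ", "), "\n")
  invisible(x)
}

.modality_prefix <- function(m) {
  switch(m, nuclear_imaging = "ni", mrna_expression = "ce",
         mri_microstructure = "mr", "fx")
}

#' Name factors by their most-loading markers
#'
#' Each marker is assigned to the factor it loads on the most (maximum
#' absolute loading; exact ties break to the lower factor index). A factor's
#' label concatenates its assigned markers' names under a modality prefix
#' (`ni`/`ce`/`mr`); factors with no assigned marker are labeled
#' `unassigned_k`.
#'
#' @param solution a `factor_solution`.
#' @param marker_names optional marker subset/order.
#' @return list with `labels` (per factor) and `assignments` (marker ->
#'   factor index).
#' @export
name_factors <- function(solution, marker_names = solution$marker_names) {
  L <- solution$loadings[marker_names, , drop = FALSE]
  k <- ncol(L)
  assign_to <- apply(abs(L), 1L, which.max)  # ties -> first (lower index)
  labels <- character(k)
  for (j in seq_len(k)) {
    members <- marker_names[assign_to == j]
    if (!length(members)) {
      labels[j] <- paste0("unassigned_", j)
    } else {
      pref <- .modality_prefix(names(sort(table(
        solution$modality[members]), decreasing = TRUE))[1])
      labels[j] <- paste0(pref, j, ":", paste(members, collapse = "+"))
    }
  }
  list(labels = labels, assignments = setNames(assign_to, marker_names))
}

#' Validate a factor solution against surrogate-map null solutions
#'
#' Refits the factor analysis, with identical settings, on marker sets
#' assembled from the k-th surrogate of every marker (all markers replaced
#' jointly per iteration) and compares the observed total variance explained
#' to the null distribution: `p = (1 + #\{null >= observed\}) / (1 + n_null)`.
#'
#' @param markers a [marker_set()].
#' @param surrogate_sets named list of surrogate ensembles, one per marker.
#' @param n_null number of null iterations (> 0); every ensemble must hold
#'   at least this many maps.
#' @param threshold,rotation,kappa settings forwarded to [fit_factors()].
#' @return list with `p`, `observed`, `nulls`.
#' @export
validate_factors_null <- function(markers, surrogate_sets, n_null,
                                  threshold = 0.01, rotation = "promax",
                                  kappa = 4) {
  stopifnot(inherits(markers, "marker_set"))
  if (n_null <= 0) stop("n_null must be > 0")
  sizes <- vapply(surrogate_sets[markers$marker_names],
                  function(e) ncol(e$maps), 0L)
  if (any(is.na(sizes)) || any(sizes < n_null))
    stop("every marker needs a surrogate ensemble of size >= n_null")
  fit_tve <- function(ms) {
    sol <- tryCatch(fit_factors(ms, threshold = threshold,
                                rotation = rotation, kappa = kappa),
                    error = function(e) NULL)
    if (is.null(sol)) 0 else sol$total_variance_explained
  }
  observed <- fit_tve(markers)
  nulls <- vapply(seq_len(n_null), function(k) {
    Xk <- .null_predictors(surrogate_sets[markers$marker_names], k,
                           markers$labels)
    fit_tve(marker_set(Xk, labels = markers$labels,
                       modality = markers$modality))
  }, 0)
  list(p = empirical_p(observed, nulls), observed = observed, nulls = nulls)
}

#' Top-loading original atlases of a factor
#'
#' Markers sorted by absolute loading on the factor (descending), truncated
#' to at most `max_n` and filtered at `|loading| >= min_abs_loading`.
#'
#' @param solution a `factor_solution`.
#' @param factor factor index or name.
#' @param max_n maximum number of markers returned (default 5).
#' @param min_abs_loading absolute loading cutoff (default 0.3).
#' @return character vector of marker names (possibly empty).
#' @export
top_loading_atlases <- function(solution, factor, max_n = 5,
                                min_abs_loading = 0.3) {
  L <- solution$loadings
  j <- if (is.character(factor)) match(factor, colnames(L)) else factor
  if (is.na(j) || j < 1 || j > ncol(L)) stop("invalid factor")
  lam <- abs(L[, j])
  ord <- order(lam, decreasing = TRUE)
  keep <- ord[seq_len(min(max_n, length(ord)))]
  keep <- keep[lam[keep] >= min_abs_loading]
  solution$marker_names[keep]
}
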