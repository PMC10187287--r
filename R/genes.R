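#' Mean developmental expression trajectory of a gene set
#'
#' Unweighted mean across the set's available genes per subject; single
#' genes pass through unchanged. Listed genes absent from the table are
#' skipped with a warning.
#'
#' @param table a `dev_expression_table` (see [simulate_expression()]).
#' @param genes character vector of gene symbols.
#' @return list with `ages` and `values` (one mean expression per subject).
#' @export
geneset_trajectory <- function(table, genes) {
  stopifnot(inherits(table, "dev_expression_table"))
  genes <- unique(as.character(genes))
  present <- genes[genes %in% table$genes]
  absent <- setdiff(genes, present)
  if (length(absent))
    warning("gene(s) not in expression table, skipped: ",
            paste(absent, collapse = ", "))
  if (!length(present)) stop("no listed gene found in the expression table")
  vals <- colMeans(table$x[present, , drop = FALSE])
  list(ages = table$ages, values = as.vector(vals), genes = present)
}

#' LOESS fit of an age series on a dense grid
#'
#' Tricube-weighted local polynomial regression evaluated on a uniform grid
#' spanning the observed ages.
#'
#' @param series list with `ages` and `values` (from
#'   [geneset_trajectory()]), or a numeric vector with ages in `ages`.
#' @param ages subject ages if `series` is a bare numeric vector.
#' @param span LOESS span (default 0.75).
#' @param degree local polynomial degree (default 2).
#' @param n_grid number of grid points.
#' @return list with `age_grid` and `fit`.
#' @export
loess_fit <- function(series, ages = NULL, span = 0.75, degree = 2,
                      n_grid = 100) {
  if (is.list(series)) {
    ages <- series$ages
    y <- series$values
  } else y <- as.numeric(series)
  n <- length(y)
  if (n < max(5, degree + 2)) stop("need >= max(5, degree + 2) subjects")
  if (span * n < degree + 1)
    stop("span too small for local fits at n = ", n)
  fit <- tryCatch(
    loess(y ~ ages, span = span, degree = degree,
          control = loess.control(surface = "direct")),
    error = function(e) stop("LOESS fit failed: ", conditionMessage(e)))
  grid <- seq(min(ages), max(ages), length.out = n_grid)
  list(age_grid = grid, fit = as.vector(predict(fit, newdata = grid)))
}

# Smooth curve for each column group mean; x = genes x subjects matrix rows.
.period_stats <- function(curve, grid, period) {
  inside <- grid >= period[1] & grid <= period[2]
  if (!any(inside)) stop("period does not overlap the observed age range")
  if (all(inside)) stop("empty outside-period support")
  mean_in <- mean(curve[inside])
  mean_out <- mean(curve[!inside])
  c(mean_in = mean_in, mean_out = mean_out, ratio = mean_in / mean_out)
}

#' Developmental period test against non-brain null gene sets
#'
#' Fits a LOESS trajectory to the observed gene set and to `n_null`
#' same-sized sets sampled (without replacement within a set) from the
#' non-brain-flagged genes, computes the mean expression during and outside
#' the period on the smooth curves, and derives positive-sided empirical
#' p-values for the in-period mean (`p_mean`) and the in/out ratio
#' (`p_ratio`) via `(1 + k) / (1 + N)`. A significant mean indicates raised
#' expression during the period relative to non-brain genes; a significant
#' ratio indicates that expression peaks within it.
#'
#' @param table a `dev_expression_table` with non-brain genes flagged.
#' @param gene_set character vector of observed gene symbols.
#' @param period numeric length-2 `(start, end)` in years.
#' @param n_null number of null gene sets (default 10000).
#' @param seed RNG seed for null sampling.
#' @param span,degree,n_grid LOESS settings.
#' @return object of class `period_test_result`: `gene_set`, `period`,
#'   `mean_in`, `mean_out`, `ratio`, `null_means`, `null_ratios`, `p_mean`,
#'   `p_ratio`.
#' @export
period_test <- function(table, gene_set, period, n_null = 10000, seed = 1L,
                        span = 0.75, degree = 2, n_grid = 100) {
  stopifnot(inherits(table, "dev_expression_table"))
  pool <- table$genes[table$non_brain]
  if (length(pool) < 2L) stop("need >= 2 non-brain genes for null sampling")
  tr <- geneset_trajectory(table, gene_set)
  size <- length(tr$genes)
  if (size > length(pool))
    stop("null pool smaller than the observed gene set")
  obs_fit <- loess_fit(tr, span = span, degree = degree, n_grid = n_grid)
  obs <- .period_stats(obs_fit$fit, obs_fit$age_grid, period)
  pool_idx <- match(pool, table$genes)
  nulls <- local_seed(seed, {
    vapply(seq_len(n_null), function(k) {
      rows <- pool_idx[sample.int(length(pool), size)]
      vals <- colMeans(table$x[rows, , drop = FALSE])
      f <- loess_fit(list(ages = table$ages, values = vals), span = span,
                     degree = degree, n_grid = n_grid)
      .period_stats(f$fit, f$age_grid, period)
    }, c(mean_in = 0, mean_out = 0, ratio = 0))
  })
  structure(list(gene_set = tr$genes, period = period,
                 mean_in = obs["mean_in"], mean_out = obs["mean_out"],
                 ratio = obs["ratio"],
                 null_means = nulls["mean_in", ],
                 null_ratios = nulls["ratio", ],
                 p_mean = empirical_p(obs["mean_in"], nulls["mean_in", ]),
                 p_ratio = empirical_p(obs["ratio"], nulls["ratio", ])),
            class = "period_test_result")
}

#' Run several period tests and FDR-correct across all of them
#'
#' @param table a `dev_expression_table`.
#' @param gene_sets named list of gene symbol vectors.
#' @param periods named list of `(start, end)` periods (names matching
#'   `gene_sets`), or a single period recycled for all sets.
#' @param ... forwarded to [period_test()] (`n_null`, `seed`, LOESS
#'   settings); each test gets its own derived seed.
#' @param seed base RNG seed.
#' @return data.frame with one row per (gene set, statistic): columns
#'   `gene_set`, `statistic`, `value`, `p`, `q` (BH across all tests).
#' @export
period_scan <- function(table, gene_sets, periods, seed = 1L, ...) {
  if (is.numeric(periods)) periods <- rep(list(periods), length(gene_sets))
  if (is.null(names(periods)) || !all(names(gene_sets) %in% names(periods)))
    periods <- setNames(rep_len(periods, length(gene_sets)),
                        names(gene_sets))
  rows <- list()
  for (i in seq_along(gene_sets)) {
    nm <- names(gene_sets)[i]
    res <- period_test(table, gene_sets[[i]], periods[[nm]],
                       seed = seed + i - 1L, ...)
    rows[[length(rows) + 1L]] <- data.frame(
      gene_set = nm, statistic = c("mean", "ratio"),
      value = c(unname(res$mean_in), unname(res$ratio)),
      p = c(res$p_mean, res$p_ratio), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$q <- fdr_bh(out$p)
  out
}
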