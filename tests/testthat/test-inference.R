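test_that("spatial R2 matches closed forms and the adjustment formula", {
  mk <- fix_markers(60)$markers
  y <- 2 * mk$x[, 1] + 1
  r <- spatial_r2(y, marker_set(mk$x[, 1, drop = FALSE]))
  expect_equal(r$r2, 1, tolerance = 1e-12)
  # residualized target is exactly orthogonal to the predictor
  set.seed(3)
  y2 <- residuals(lm(rnorm(60) ~ mk$x[, 1]))
  r2 <- spatial_r2(y2, marker_set(mk$x[, 1, drop = FALSE]))
  expect_equal(r2$r2, 0, tolerance = 1e-12)
  # adjusted R2 formula: r2 = 0.5, n = 148, p = 21
  expect_equal(ctcoloc:::.adjust_r2(0.5, 148, 21), 1 - 0.5 * 147 / 126)
  expect_lte(r$adjusted_r2, r$r2)
  # affine invariance of R2
  set.seed(4)
  y3 <- rnorm(60)
  a <- spatial_r2(y3, mk)$r2
  mk2 <- mk; mk2$x <- sweep(mk2$x * 3, 2, rnorm(6))
  expect_equal(spatial_r2(5 - 2 * y3, mk2)$r2, a, tolerance = 1e-10)
  # collinear designs are refused with the offending column named
  bad <- marker_set(cbind(a = mk$x[, 1], b = 2 * mk$x[, 1]))
  expect_error(spatial_r2(y3, bad), "collinear")
})

test_that("empirical p follows the (1+k)/(1+N) convention with ties", {
  expect_equal(empirical_p(10, 1:9), 0.1)
  expect_equal(empirical_p(0, 1:9), 1.0)
  # ties count against the observation: 3 ties + 0 above among 9
  nulls <- c(5, 5, 5, 1, 2, 3, 4, 0, -1)
  expect_equal(empirical_p(5, nulls), 0.4)
  expect_equal(empirical_p(5, nulls, side = "negative"), 1.0)
  expect_error(empirical_p(1, numeric(0)), "empty")
})

test_that("BH correction is family-isolated and matches hand application", {
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(fdr_bh(0.2), 0.2)
  p <- c(0.01, 0.5, 0.02, 0.6)
  fam <- c("x", "y", "x", "y")
  q <- fdr_bh(p, fam)
  expect_equal(q[fam == "x"], fdr_bh(p[fam == "x"]))
  expect_equal(q[fam == "y"], fdr_bh(p[fam == "y"]))
  # permuting family blocks leaves q unchanged
  ord <- c(2, 4, 1, 3)
  expect_equal(fdr_bh(p[ord], fam[ord]), q[ord])
  expect_error(fdr_bh(c(0.5, 1.2)), "\\[0, 1\\]")
  # q >= p and q monotone in p within a family
  set.seed(5)
  pp <- runif(50)
  qq <- fdr_bh(pp)
  expect_true(all(qq >= pp - 1e-12))
  expect_true(all(diff(qq[order(pp)]) >= -1e-12))
})

test_that("scan_windows emits one row per window and marker with families", {
  sim <- fix_grid(60)
  mk <- fix_markers(60)$markers
  mk$modality[4:6] <- "mrna_expression"
  ens <- fix_ensembles(60, 6, n = 30)
  wins <- sliding_windows(step = 10, extra = NULL)  # 9 windows
  tab <- scan_windows(sim$grid, mk, wins, ens, mode = "univariate",
                      n_null = 30)
  expect_identical(nrow(tab), 6L * 9L)
  expect_setequal(unique(tab$family),
                  c("univariate_nuclear_imaging", "univariate_mrna_expression"))
  expect_true(all(tab$q >= tab$p - 1e-12))
  expect_true(all(tab$p > 0 & tab$p <= 1))
  # multivariate-by-modality: one combined model per modality per window
  tab2 <- scan_windows(sim$grid, mk, wins, ens,
                       mode = "multivariate_by_modality", n_null = 30)
  expect_identical(nrow(tab2), 2L * 9L)
  expect_true(all(tab2$family == "multivariate"))
  # the planted window shows up: combined model on (5, 30)
  tab3 <- scan_windows(sim$grid, mk, list(c(5, 30)), ens,
                       mode = "multivariate_all", n_null = 30)
  expect_gte(tab3$r2, 0.4)
  expect_equal(tab3$p, 1 / 31, tolerance = 1e-12)
  expect_error(scan_windows(sim$grid, mk, wins, ens[1:3]),
               "missing surrogate ensemble")
})

test_that("a full univariate scan yields one model per marker and window", {
  sim <- fix_grid(60)
  g <- fix_geom(60)
  set.seed(77)
  # 21 markers as in a full nuclear-imaging + cell-type + microstructure set
  X <- crossprod(ctcoloc:::.grf_chol(g, 0.3), matrix(rnorm(60 * 21), 60))
  colnames(X) <- sprintf("a%02d", 1:21)
  rownames(X) <- g$labels
  mk21 <- zscore_parcels(marker_set(X))
  ens21 <- marker_surrogates(mk21, g, n = 5, seed = 78)
  tab <- scan_windows(sim$grid, mk21, sliding_windows(extra = NULL), ens21,
                      mode = "univariate", n_null = 5)
  expect_identical(nrow(tab), 21L * 81L)
  expect_identical(anyDuplicated(tab[, c("window_start", "marker")]), 0L)
})

test_that("baseline correction residualizes the target, not the design", {
  sim <- fix_grid(60)
  mk <- fix_markers(60)$markers
  ens <- fix_ensembles(60, 6, n = 30)
  plain <- scan_windows(sim$grid, mk, list(c(5, 30)), ens, n_null = 30)
  corrected <- scan_windows(sim$grid, mk, list(c(5, 30)), ens, n_null = 30,
                            baseline_correct = TRUE)
  expect_identical(nrow(corrected), nrow(plain))
  expect_false(isTRUE(all.equal(corrected$r2, plain$r2)))
  # residualizing on a marker makes that marker's own R2 exactly zero
  cm <- ct_change(sim$grid, 5, 30)
  cov_m1 <- marker_set(mk$x[, 1, drop = FALSE], labels = mk$labels)
  killed <- scan_change_maps(cm, mk, ens, covariates = cov_m1, n_null = 5)
  expect_lt(killed$r2[killed$marker == mk$marker_names[1]], 1e-12)
  expect_gt(max(killed$r2), 1e-3)
})

test_that("scan reruns are bit-identical given the constant null set", {
  sim <- fix_grid(60)
  mk <- fix_markers(60)$markers
  ens <- fix_ensembles(60, 6, n = 30)
  wins <- list(c(5, 30), c(40, 45))
  t1 <- scan_windows(sim$grid, mk, wins, ens, n_null = 30)
  t2 <- scan_windows(sim$grid, mk, wins, ens, n_null = 30)
  expect_identical(t1, t2)
})

test_that("confound correlations behave like Spearman on window series", {
  set.seed(6)
  r2s <- runif(20)
  expect_equal(confound_correlation(r2s, r2s)$rho, 1)
  expect_equal(confound_correlation(r2s, -r2s)$rho, -1)
  expect_error(confound_correlation(r2s, rep(1, 20)), "constant")
  expect_error(confound_correlation(r2s[1:3], r2s[1:3]), ">= 4")
  set.seed(7)
  indep <- replicate(60, abs(confound_correlation(runif(20), runif(20))$rho))
  expect_gte(mean(indep < 0.45), 0.9)
})
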