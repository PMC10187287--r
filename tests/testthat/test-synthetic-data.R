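test_that("synthetic geometry is a valid two-cap sphere layout", {
  g <- make_geometry(148, seed = 1)
  d <- g$distances
  expect_identical(dim(d), c(148L, 148L))
  expect_true(isSymmetric(unname(d)))
  expect_true(all(diag(d) == 0))
  expect_true(all(d[upper.tri(d)] > 0))
  # centroids on the unit sphere; antipodal pairs reach chord distance ~2
  expect_equal(unname(sqrt(rowSums(g$centroids^2))), rep(1, 148),
               tolerance = 1e-12)
  expect_error(make_geometry(2), ">= 3")
  # determinism
  g2 <- make_geometry(148, seed = 1)
  expect_identical(g$centroids, g2$centroids)
  # antipodal construction check on an explicit geometry
  xyz <- rbind(c(0, 0, 1), c(0, 0, -1), c(1, 0, 0))
  ge <- parcel_geometry(centroids = xyz, labels = c("n", "s", "e"))
  expect_equal(ge$distances["n", "s"], 2)
})

test_that("simulated markers carry the planted latent structure", {
  g <- fix_geom(60)
  # noise 0, single latent, loading 1: marker equals the standardized field
  s1 <- simulate_markers(g, 1, matrix(1), noise_sd = 0, seed = 7)
  expect_equal(unname(s1$markers$x[, 1]),
               unname(zscore_parcels(as.vector(s1$truth$latent_factors))),
               tolerance = 1e-12)
  # two markers sharing one latent, noise 0: correlation 1
  s2 <- simulate_markers(g, 1, matrix(c(1, 1), 2, 1), noise_sd = 0, seed = 8)
  expect_equal(unname(cor(s2$markers$x)[1, 2]), 1, tolerance = 1e-12)
  # determinism
  s3 <- simulate_markers(g, 3, diag(3), seed = 9)
  s4 <- simulate_markers(g, 3, diag(3), seed = 9)
  expect_identical(s3$markers$x, s4$markers$x)
})

test_that("spatially autocorrelated fields beat iid noise on Moran statistic", {
  g <- fix_geom(60)
  ch <- ctcoloc:::.grf_chol(g, 1)
  set.seed(11)
  wins <- replicate(100, {
    grf <- as.vector(crossprod(ch, rnorm(60)))
    moran_stat(grf, g) > moran_stat(rnorm(60), g)
  })
  expect_gte(sum(wins), 95)
})

test_that("planted CT trajectories obey the multiplicative integration", {
  sim <- fix_grid(60)
  grid <- sim$grid
  expect_identical(length(grid$ages), 171L)
  for (tw in sim$truth$windows) {
    cm <- ct_change(grid, tw$window[1], tw$window[2])
    expect_equal(cm$values, tw$delta, tolerance = 1e-12)
  }
  # zero weights + zero amplitude: flat CT, every window change exactly 0
  mk <- fix_markers(60)$markers
  flat <- simulate_ct_trajectories(
    fix_geom(60), mk,
    list(list(window = c(5, 90), weights = NULL)),
    delta_mean = 0, delta_sd = 0, seed = 3)
  expect_equal(ct_change(flat$grid, 5, 90)$values, rep(0, 60),
               tolerance = 1e-12)
  expect_equal(ct_change(flat$grid, 20, 70)$values, rep(0, 60),
               tolerance = 1e-10)
})

test_that("target_r2 = 1 is exact and planted weights are recoverable", {
  g <- fix_geom(60)
  mk <- fix_markers(60, p = 6)$markers
  w <- setNames(c(1, 0.5, 0.25), mk$marker_names[1:3])
  sim <- simulate_ct_trajectories(
    g, mk, list(list(window = c(5, 90), weights = w)), target_r2 = 1,
    seed = 5)
  cm <- ct_change(sim$grid, 5, 90)
  s <- as.vector(mk$x %*% sim$truth$windows[[1]]$weights)
  expect_equal(cor(cm$values, s)^2, 1, tolerance = 1e-10)
  # coefficient recovery up to scale at noise 0
  co <- spatial_r2(cm, mk)$coefficients
  expect_gte(cor(co[1:3], w), 0.999)
  expect_error(simulate_ct_trajectories(
    g, mk, list(list(window = c(5, 90), weights = w)), target_r2 = 1.5,
    seed = 5), "target_r2")
  expect_error(simulate_ct_trajectories(
    g, mk, list(list(window = c(5, 90), weights = w)), delta_mean = -2,
    seed = 5), "non-positive")
})

test_that("OLS on the emitted grid recovers the realized window R2", {
  sim <- fix_grid(148, p = 9, n_active = 3, target_r2 = 0.5)
  mk <- fix_markers(148, 9)$markers
  tw <- sim$truth$windows[[1]]
  cm <- ct_change(sim$grid, tw$window[1], tw$window[2])
  active <- names(tw$weights)[tw$weights != 0]
  r2_active <- spatial_r2(cm, marker_set(mk$x[, active]))$r2
  expect_equal(r2_active, tw$realized_r2, tolerance = 0.02)
})

test_that("simulated subjects inherit the population curve", {
  sim <- fix_grid(60)
  g <- fix_geom(60)
  # zero noise, no sites: every subject equals the population curve
  s0 <- simulate_subjects(sim$grid, g, 3, sessions = c(T0 = 10, T2 = 12),
                          age_jitter = 0, subject_noise_sd = 0,
                          session_noise_sd = 0, site_sd = 0, seed = 1)
  pop10 <- ctcoloc:::.ct_slice(sim$grid, 10, 50, "average")
  row1 <- as.numeric(s0[s0$session == "T0", ][1, -(1:6)])
  expect_equal(row1, unname(pop10), tolerance = 1e-12)
  expect_identical(
    simulate_subjects(sim$grid, g, 5, seed = 2),
    simulate_subjects(sim$grid, g, 5, seed = 2))
  expect_error(simulate_subjects(sim$grid, g, 3, sessions = c(T0 = 10)),
               ">=2 sessions")
})

test_that("cohort-average change converges to the population change", {
  sim <- fix_grid(40, p = 6)
  g <- fix_geom(40)
  subs <- simulate_subjects(sim$grid, g, 1000, sessions = c(T0 = 10, T2 = 12),
                            age_jitter = 0, seed = 3)
  ch <- subject_changes(subs)
  Y <- ctcoloc:::.changes_matrix(ch)
  pop <- (ctcoloc:::.ct_slice(sim$grid, 12, 50, "average") -
          ctcoloc:::.ct_slice(sim$grid, 10, 50, "average")) /
    ctcoloc:::.ct_slice(sim$grid, 10, 50, "average")
  tstat <- (rowMeans(Y) - pop) / (apply(Y, 1, sd) / sqrt(ncol(Y)))
  expect_gte(mean(abs(tstat) < 3), 0.95)
})

test_that("expression generator plants age-localized bumps", {
  e <- simulate_expression(seed = 1)
  expect_identical(length(e$ages), 33L)
  expect_true(all(e$ages >= 0.33 & e$ages <= 82.05))
  expect_identical(simulate_expression(seed = 4)$x,
                   simulate_expression(seed = 4)$x)
  expect_error(simulate_expression(signal_genes = list(G = c(10, 0, 1))),
               "width")
  # amplitude 0: signal genes indistinguishable from nulls
  set.seed(12)
  rejections <- replicate(60, {
    ee <- simulate_expression(signal_genes = list(G = c(10, 5, 0)),
                              n_null_genes = 50,
                              seed = sample.int(1e6, 1))
    t.test(ee$x[1, ], as.vector(ee$x[-1, ]))$p.value < 0.05
  })
  expect_lte(mean(rejections), 0.10)
})
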