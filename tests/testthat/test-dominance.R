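test_that("single-predictor dominance is the squared correlation", {
  set.seed(11)
  x <- rnorm(100)
  e <- residuals(lm(rnorm(100) ~ x))
  # construct y with cor(x, y) = 0.6 exactly
  y <- 0.6 * scale(x)[, 1] + sqrt(1 - 0.36) * scale(e)[, 1]
  labs <- sprintf("p%03d", 1:100)
  dd <- dominance_decompose(setNames(y, labs),
                            marker_set(cbind(x = x), labels = labs))
  expect_equal(unname(dd$total_dominance["x"]), 0.36, tolerance = 1e-10)
  expect_equal(dd$full_r2, 0.36, tolerance = 1e-10)
})

test_that("orthogonal designs decompose into univariate r-squared", {
  set.seed(12)
  n <- 80
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(n * 2), n, 2))))[, 2:3]
  e <- residuals(lm(rnorm(n) ~ Q))
  y <- sqrt(0.2) * Q[, 1] * sqrt(n - 1) + sqrt(0.3) * Q[, 2] * sqrt(n - 1) +
    sqrt(0.5) * scale(e)[, 1]
  labs <- sprintf("p%03d", 1:n)
  dd <- dominance_decompose(setNames(y, labs),
                            marker_set(cbind(a = Q[, 1], b = Q[, 2]),
                                       labels = labs))
  r2a <- cor(y, Q[, 1])^2
  r2b <- cor(y, Q[, 2])^2
  expect_equal(unname(dd$total_dominance), c(r2a, r2b), tolerance = 1e-10)
  expect_equal(dd$full_r2, r2a + r2b, tolerance = 1e-10)
})

test_that("dominance shares sum to the full R2 on random instances", {
  set.seed(13)
  for (i in 1:25) {
    p <- sample(2:8, 1)
    n <- 60
    X <- matrix(rnorm(n * p), n, p, dimnames = list(sprintf("p%03d", 1:n),
                                                    paste0("m", 1:p)))
    y <- setNames(rnorm(n), rownames(X))
    dd <- dominance_decompose(y, marker_set(X))
    expect_lt(abs(sum(dd$total_dominance) - dd$full_r2), 1e-10)
    expect_true(all(dd$total_dominance >= -1e-12))
  }
})

test_that("the subset kernel equals the literal all-subsets oracle", {
  set.seed(14)
  for (p in 2:6) {
    n <- 50
    X <- matrix(rnorm(n * p), n, p, dimnames = list(sprintf("p%03d", 1:n),
                                                    paste0("m", 1:p)))
    y <- setNames(as.vector(X %*% runif(p, -1, 1) + rnorm(n)), rownames(X))
    dd <- dominance_decompose(y, marker_set(X))
    expect_equal(unname(dd$total_dominance), naive_dominance(y, X),
                 tolerance = 1e-10)
  }
})

test_that("dominance is invariant to predictor order and affine rescaling", {
  set.seed(15)
  n <- 70
  X <- matrix(rnorm(n * 4), n, 4, dimnames = list(sprintf("p%03d", 1:n),
                                                  paste0("m", 1:4)))
  y <- setNames(rnorm(n), rownames(X))
  d1 <- dominance_decompose(y, marker_set(X))
  ord <- c(3, 1, 4, 2)
  d2 <- dominance_decompose(y, marker_set(X[, ord]))
  expect_equal(d2$total_dominance[paste0("m", 1:4)],
               d1$total_dominance[paste0("m", 1:4)], tolerance = 1e-12)
  X3 <- X; X3[, 2] <- -5 * X3[, 2] + 7
  d3 <- dominance_decompose(y, marker_set(X3))
  expect_equal(unname(d3$total_dominance), unname(d1$total_dominance),
               tolerance = 1e-10)
  dup <- cbind(X, X)
  colnames(dup) <- paste0("m", 1:8)
  expect_error(dominance_decompose(y, marker_set(dup)), "rank-deficient")
  big <- matrix(rnorm(n * 16), n, 16, dimnames = list(rownames(X), NULL))
  expect_error(dominance_decompose(y, marker_set(big)), "15 predictors")
})

test_that("dominance scan forms a single FDR family of (1+p) x windows", {
  sim <- fix_grid(60)
  mk <- fix_markers(60)$markers
  ens <- fix_ensembles(60, 6, n = 20)
  wins <- sliding_windows(step = 20, extra = list(c(5, 30)))  # 5 + 1
  tab <- dominance_scan(sim$grid, mk, wins, ens, n_null = 20)
  expect_identical(nrow(tab), 6L * 7L)  # (full + 6 markers) x 6 windows
  expect_identical(unique(tab$family), "dominance")
  # per-window sum identity holds in the emitted table
  for (w in seq_along(wins)) {
    rows <- tab[tab$window_start == wins[[w]][1] &
                tab$window_end == wins[[w]][2], ]
    expect_equal(sum(rows$r2[rows$marker != "full_model"]),
                 rows$r2[rows$marker == "full_model"], tolerance = 1e-10)
  }
  # directionality: spearman rho present for markers, not the full model
  expect_true(all(is.na(tab$spearman_rho[tab$marker == "full_model"])))
  expect_all_finite(tab$spearman_rho[tab$marker != "full_model"])
})

test_that("a 9-marker dominance scan forms one 82 + 82 x 9 p-value family", {
  sim <- fix_grid(60, p = 9, n_active = 3)
  mk9 <- fix_markers(60, 9)$markers
  ens9 <- fix_ensembles(60, 9, n = 5, seed = 49)
  tab <- dominance_scan(sim$grid, mk9, sliding_windows(), ens9, n_null = 5)
  expect_identical(nrow(tab), 82L + 82L * 9L)  # one shared FDR family
  expect_identical(unique(tab$family), "dominance")
  expect_identical(sum(tab$marker == "full_model"), 82L)
})

test_that("regional influence matches a direct two-model refit", {
  set.seed(16)
  mk <- fix_markers(60, p = 3)$markers
  y <- setNames(mk$x[, 1] + 0.3 * rnorm(60), mk$labels)
  infl <- region_influence(y, mk)
  expect_identical(dim(infl$delta_pe), c(60L, 3L))
  # oracle: per predictor, |resid reduced| - |resid full| via lm()
  df <- data.frame(y = y, mk$x)
  full <- lm(y ~ ., data = df)
  for (j in 1:3) {
    red <- lm(y ~ ., data = df[, -(j + 1)])
    expect_equal(unname(infl$delta_pe[, j]),
                 unname(abs(residuals(red)) - abs(residuals(full))),
                 tolerance = 1e-10)
  }
  # a predictor orthogonal to everything contributes a ~zero column
  e <- residuals(lm(rnorm(60) ~ y + mk$x))
  mk2 <- marker_set(cbind(mk$x, orth = e), labels = mk$labels)
  infl2 <- region_influence(y, mk2)
  expect_lt(max(abs(infl2$delta_pe[, "orth"])), 1e-10)
  # perfect-fit case: removing the true predictor leaves positive dPE
  y3 <- setNames(mk$x[, 2], mk$labels)
  infl3 <- region_influence(y3, marker_set(mk$x[, 1:2]))
  red_resid <- residuals(lm(y3 ~ mk$x[, 1]))
  expect_true(all(infl3$delta_pe[abs(red_resid) > 1e-8, 2] > 0))
})

test_that("small worked influence example matches hand computation", {
  # 4 regions, one predictor + intercept: closed-form residuals
  labs <- paste0("r", 1:4)
  x <- c(0, 1, 2, 3)
  y <- c(0, 1, 1, 2)
  infl <- region_influence(setNames(y, labs),
                           marker_set(cbind(x = x, z = c(1, -1, 1, -1)),
                                      labels = labs))
  full <- lm(y ~ x + c(1, -1, 1, -1))
  red <- lm(y ~ c(1, -1, 1, -1))
  expect_equal(unname(infl$delta_pe[, "x"]),
               abs(residuals(red)) - abs(residuals(full)), tolerance = 1e-12,
               ignore_attr = TRUE)
})
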