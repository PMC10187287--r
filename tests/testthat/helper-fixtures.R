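# Shared fixtures (memoized; all generated in code, no stored data) and
# independent oracles used across the suite.

.fix <- new.env()

fix_geom <- function(n = 60, seed = 42) {
  key <- paste0("geom", n, "_", seed)
  if (is.null(.fix[[key]])) .fix[[key]] <- make_geometry(n, seed = seed)
  .fix[[key]]
}

fix_markers <- function(n_parcels = 60, p = 6, seed = 43, noise_sd = 0.1) {
  key <- paste0("mk", n_parcels, "_", p, "_", seed)
  if (is.null(.fix[[key]]))
    .fix[[key]] <- simulate_markers(fix_geom(n_parcels), p, diag(p),
                                    noise_sd = noise_sd, seed = seed)
  .fix[[key]]
}

# Planted-colocalization grid over a geometry, single tiling window so the
# change map between the extreme ages equals the planted map exactly.
fix_grid <- function(n_parcels = 60, p = 6, n_active = 3, target_r2 = 0.5,
                     seed = 44) {
  key <- paste0("grid", n_parcels, "_", p, "_", n_active, "_",
                round(100 * target_r2), "_", seed)
  if (is.null(.fix[[key]])) {
    mk <- fix_markers(n_parcels, p)
    w <- setNames(seq(1, 0.4, length.out = n_active),
                  mk$markers$marker_names[seq_len(n_active)])
    .fix[[key]] <- simulate_ct_trajectories(
      fix_geom(n_parcels), mk$markers,
      list(list(window = c(5, 30), weights = w),
           list(window = c(30, 60), weights = w / 2),
           list(window = c(60, 90), weights = -w)),
      target_r2 = target_r2, seed = seed)
  }
  .fix[[key]]
}

fix_ensembles <- function(n_parcels = 60, p = 6, n = 30, seed = 45) {
  key <- paste0("ens", n_parcels, "_", p, "_", n, "_", seed)
  if (is.null(.fix[[key]]))
    .fix[[key]] <- marker_surrogates(fix_markers(n_parcels, p)$markers,
                                     fix_geom(n_parcels), n = n, seed = seed)
  .fix[[key]]
}

# Literal all-subsets dominance oracle via lm(); independent of the
# cross-moment kernel under test.
naive_dominance <- function(y, X) {
  p <- ncol(X)
  r2_of <- function(S) {
    if (!length(S)) return(0)
    summary(lm(y ~ X[, S, drop = FALSE]))$r.squared
  }
  subsets <- list(integer(0))
  for (s in seq_len(p - 1))
    subsets <- c(subsets, combn(p, s, simplify = FALSE))
  vapply(seq_len(p), function(x) {
    use <- !vapply(subsets, function(S) x %in% S, TRUE)
    incs <- vapply(subsets[use], function(S) r2_of(c(S, x)) - r2_of(S), 0)
    sizes <- vapply(subsets[use], length, 0L)
    mean(tapply(incs, sizes, mean))
  }, 0)
}

# Moran-style spatial autocorrelation statistic with inverse-distance weights.
moran_stat <- function(v, geom) {
  W <- 1 / geom$distances
  diag(W) <- 0
  z <- v - mean(v)
  (length(v) / sum(W)) * sum(W * outer(z, z)) / sum(z^2)
}

expect_all_finite <- function(x) expect_true(all(is.finite(x)))
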