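#' Parcel geometry: centroids and inter-parcel distances
#'
#' @param centroids n x 3 matrix of parcel centroid coordinates (arbitrary
#'   length units), or `NULL` if only distances are available.
#' @param distances n x n symmetric distance matrix with zero diagonal;
#'   computed from the centroids (Euclidean) when omitted.
#' @param labels parcel labels.
#' @return an object of class `parcel_geometry`.
#' @export
parcel_geometry <- function(centroids = NULL, distances = NULL,
                            labels = NULL) {
  if (is.null(distances)) {
    if (is.null(centroids)) stop("need centroids or distances")
    distances <- as.matrix(dist(centroids))
  }
  distances <- as.matrix(distances)
  n <- nrow(distances)
  if (is.null(labels))
    labels <- rownames(distances) %||% sprintf("p%03d", seq_len(n))
  if (!isSymmetric(unname(distances), tol = 1e-8))
    stop("distance matrix must be symmetric")
  if (any(abs(diag(distances)) > 1e-12)) stop("distance diagonal must be zero")
  off <- distances[upper.tri(distances)]
  if (any(off <= 0)) stop("off-diagonal distances must be strictly positive")
  dimnames(distances) <- list(labels, labels)
  structure(list(labels = as.character(labels), centroids = centroids,
                 distances = distances),
            class = "parcel_geometry")
}

#' @export
print.parcel_geometry <- function(x, ...) {
  cat(sprintf("parcel_geometry: %d parcels, distances in [%.3g, %.3g]\n",
              length(x$labels), min(x$distances[upper.tri(x$distances)]),
              max(x$distances)))
  invisible(x)
}

# Fibonacci spiral on a spherical cap of half-angle `half_angle` around +z.
.fib_cap <- function(n, half_angle) {
  i <- seq_len(n) - 0.5
  zmin <- cos(half_angle)
  z <- 1 - (1 - zmin) * i / n
  r <- sqrt(pmax(0, 1 - z * z))
  golden <- pi * (3 - sqrt(5))
  theta <- golden * (seq_len(n) - 1)
  cbind(r * cos(theta), r * sin(theta), z)
}

#' Synthesize cortical-like parcel geometry
#'
#' Places parcels quasi-uniformly on a unit sphere as two hemispheric caps
#' (left cap around -x, right around +x) using a Fibonacci spiral plus a
#' small seeded angular jitter, and returns Euclidean (chord) distances.
#'
#' @param n_parcels number of parcels (>= 3); split as evenly as possible
#'   across the two hemispheres.
#' @param seed RNG seed for the jitter.
#' @param jitter angular jitter SD in radians.
#' @return a [parcel_geometry()].
#' @export
make_geometry <- function(n_parcels, seed = 1L, jitter = 0.02) {
  if (n_parcels < 3L) stop("n_parcels must be >= 3")
  local_seed(seed, {
    nl <- ceiling(n_parcels / 2)
    nr <- n_parcels - nl
    cap <- 80 * pi / 180
    left <- .fib_cap(nl, cap)[, c(3, 1, 2), drop = FALSE]  # cap axis -> +x
    left[, 1] <- -left[, 1]
    right <- .fib_cap(max(nr, 1L), cap)[, c(3, 1, 2), drop = FALSE]
    if (nr == 0L) right <- right[0, , drop = FALSE]
    xyz <- rbind(left, right[seq_len(nr), , drop = FALSE])
    xyz <- xyz + matrix(rnorm(length(xyz), sd = jitter), ncol = 3)
    xyz <- xyz / sqrt(rowSums(xyz^2))
    labels <- c(sprintf("L_%03d", seq_len(nl)), sprintf("R_%03d", seq_len(nr)))
    rownames(xyz) <- labels
    parcel_geometry(centroids = xyz, labels = labels)
  })
}

# Cholesky factor of the exponential spatial covariance exp(-d/rho), with
# escalating diagonal jitter; errors if the kernel stays non-positive-definite.
.grf_chol <- function(geom, rho) {
  if (rho <= 0) stop("spatial range rho must be > 0")
  K <- exp(-geom$distances / rho)
  for (j in c(0, 1e-10, 1e-8, 1e-6)) {
    ch <- tryCatch(chol(K + diag(j, nrow(K))), error = function(e) NULL)
    if (!is.null(ch)) return(ch)
  }
  stop("spatial covariance not positive definite after jitter")
}

# Draw n Gaussian random fields (columns) with covariance exp(-d/rho).
# Uses the caller's RNG stream.
.grf_draw <- function(chol_k, n) {
  p <- nrow(chol_k)
  crossprod(chol_k, matrix(rnorm(p * n), p, n))
}
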