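#' Normative cortical-thickness trajectory grid
#'
#' CT values (mm) over parcel x age x percentile x sex, as extracted from a
#' normative reference model. The default grid spans 5-90 years in 0.5-year
#' steps (171 timepoints).
#'
#' @param ct 4-d array with dims (parcel, age, percentile, sex) and complete
#'   dimnames; all values must be > 0.
#' @param labels,ages,percentiles,sexes optional dimension overrides.
#' @return an object of class `trajectory_grid`.
#' @export
trajectory_grid <- function(ct, labels = dimnames(ct)[[1]],
                            ages = as.numeric(dimnames(ct)[[2]]),
                            percentiles = as.numeric(dimnames(ct)[[3]]),
                            sexes = dimnames(ct)[[4]]) {
  stopifnot(length(dim(ct)) == 4L)
  if (any(!is.finite(ct)) || any(ct <= 0))
    stop("CT values must be finite and > 0")
  if (is.unsorted(ages, strictly = TRUE))
    stop("ages must be strictly increasing")
  dimnames(ct) <- list(labels, format(ages, trim = TRUE),
                       format(percentiles, trim = TRUE), sexes)
  structure(list(labels = as.character(labels), ages = ages,
                 percentiles = percentiles, sexes = sexes, ct = ct),
            class = "trajectory_grid")
}

#' @export
print.trajectory_grid <- function(x, ...) {
  cat(sprintf(
    "trajectory_grid: %d parcels x %d ages (%.1f-%.1f) x %d percentiles x %s\n",
    length(x$labels), length(x$ages), min(x$ages), max(x$ages),
    length(x$percentiles), paste(x$sexes, collapse = "/")))
  invisible(x)
}

#' Default extraction ages: 5 to 90 years in 0.5-year steps
#' @return numeric vector of 171 ages.
#' @export
default_age_grid <- function() seq(5, 90, by = 0.5)

#' Default extracted percentiles
#' @return numeric vector c(1, 5, 25, 50, 75, 95, 99).
#' @export
default_percentiles <- function() c(1, 5, 25, 50, 75, 95, 99)

.age_index <- function(grid, age) {
  i <- which(abs(grid$ages - age) < 1e-8)
  if (!length(i))
    stop(sprintf("age %.6g is not on the trajectory grid (no interpolation)",
                 age))
  i
}

# CT slice (parcel vector) at one age/percentile/sex; sex = "average" is the
# unweighted mean of the female and male curves.
.ct_slice <- function(grid, age, percentile, sex) {
  ai <- .age_index(grid, age)
  pi <- which(abs(grid$percentiles - percentile) < 1e-8)
  if (!length(pi)) stop("percentile ", percentile, " not in grid")
  if (identical(sex, "average")) {
    if (!all(c("female", "male") %in% grid$sexes))
      stop("sex='average' needs both female and male curves")
    (grid$ct[, ai, pi, "female"] + grid$ct[, ai, pi, "male"]) / 2
  } else {
    if (!sex %in% grid$sexes) stop("sex '", sex, "' not in grid")
    grid$ct[, ai, pi, sex]
  }
}

#' Relative CT change between two grid ages
#'
#' Computes the unitless relative change `(CT_j - CT_i) / CT_i` per parcel
#' from the trajectory grid. Ages must lie exactly on the grid; interpolation
#' is refused. `sex = "average"` averages the female and male curves before
#' differencing.
#'
#' @param grid a [trajectory_grid()].
#' @param i,j window start and end ages in years (`i < j`).
#' @param percentile CT percentile curve to use (default median).
#' @param sex `"female"`, `"male"` or `"average"`.
#' @return an object of class `change_map`.
#' @export
ct_change <- function(grid, i, j, percentile = 50, sex = "average") {
  if (!(i < j)) stop("window start must precede end (i < j)")
  ct_i <- .ct_slice(grid, i, percentile, sex)
  ct_j <- .ct_slice(grid, j, percentile, sex)
  if (any(ct_i == 0)) stop("CT at window start is zero")
  change_map((ct_j - ct_i) / ct_i, labels = grid$labels,
             window = c(i, j), percentile = percentile, sex = sex)
}

#' Per-parcel relative change map
#'
#' @param delta numeric vector of relative changes (unitless).
#' @param labels parcel labels.
#' @param window numeric length-2 (start, end) in years.
#' @param percentile,sex provenance of the underlying CT curves.
#' @return an object of class `change_map` (also a [parcel_map()]).
#' @export
change_map <- function(delta, labels = names(delta), window = c(NA, NA),
                       percentile = NA, sex = NA) {
  if (!all(is.finite(delta))) stop("delta must be finite")
  m <- parcel_map(delta, labels = labels,
                  name = sprintf("dCT(%s,%s)", window[1], window[2]),
                  modality = "derived")
  m$window <- window
  m$percentile <- percentile
  m$sex <- sex
  class(m) <- c("change_map", class(m))
  m
}

#' Enumerate sliding age windows
#'
#' Windows `(i, i + length)` for `i = start, start + step, ...` while the end
#' stays within `stop`. The defaults (5-90 years, 1-year steps, 5-year
#' length) yield 81 sliding windows; the default extra window (5, 30) -
#' covering the main postnatal developmental period - is appended without
#' deduplication, for 82 in total.
#'
#' @param start,stop age range in years.
#' @param step window step in years.
#' @param length window length in years.
#' @param extra list of extra windows (length-2 numerics) to append, or
#'   `NULL` for none.
#' @return list of numeric length-2 windows.
#' @export
sliding_windows <- function(start = 5, stop = 90, step = 1, length = 5,
                            extra = list(c(5, 30))) {
  stopifnot(start < stop, step > 0, length > 0)
  starts <- seq(start, stop - length, by = step)
  wins <- lapply(starts, function(i) c(i, i + length))
  c(wins, extra)
}

#' Lifespan colocalization trajectory of a marker
#'
#' Spearman correlation between each marker map and cross-sectional CT at
#' every grid age and percentile (pairwise-complete), Fisher z-transformed,
#' with a LOESS smooth fitted to all percentiles pooled and its year-to-year
#' change along the age grid.
#'
#' @param markers a [marker_set()] (or [parcel_map()]).
#' @param grid a [trajectory_grid()].
#' @param percentiles percentiles to include (default: all in the grid).
#' @param sex CT curve sex, default `"average"`.
#' @param loess_span,loess_degree LOESS parameters for the pooled smooth.
#' @return list of per-marker `coloc_trajectory` objects, each with fields
#'   `ages`, `rho` (age x percentile), `z`, `smooth`, `yearly_change`.
#' @export
coloc_trajectory <- function(markers, grid, percentiles = NULL,
                             sex = "average", loess_span = 0.75,
                             loess_degree = 2) {
  if (inherits(markers, "parcel_map"))
    markers <- marker_set(matrix(markers$values, ncol = 1,
                                 dimnames = list(markers$labels, markers$name)),
                          modality = markers$modality)
  al <- align_and_mask(list(markers), policy = "pairwise")
  keep <- intersect(grid$labels, al$labels)
  if (length(keep) < 3L) stop("need >=3 overlapping parcels")
  percentiles <- percentiles %||% grid$percentiles
  gidx <- match(keep, grid$labels)
  midx <- match(keep, al$sets[[1]]$labels)
  X <- al$sets[[1]]$x[midx, , drop = FALSE]
  out <- lapply(colnames(X), function(m) {
    rho <- sapply(percentiles, function(p) {
      sapply(grid$ages, function(a) {
        ct <- .ct_slice(grid, a, p, sex)[gidx]
        suppressWarnings(cor(X[, m], ct, method = "spearman",
                             use = "pairwise.complete.obs"))
      })
    })
    rho <- matrix(rho, nrow = length(grid$ages),
                  dimnames = list(NULL, format(percentiles, trim = TRUE)))
    z <- atanh(rho)
    pooled_age <- rep(grid$ages, times = length(percentiles))
    pooled_z <- as.vector(z)
    fin <- is.finite(pooled_z)
    sm <- loess(pooled_z[fin] ~ pooled_age[fin], span = loess_span,
                degree = loess_degree,
                control = loess.control(surface = "direct"))
    smooth <- predict(sm, newdata = grid$ages)
    structure(list(marker_name = m, ages = grid$ages, percentiles = percentiles,
                   rho = rho, z = z, smooth = smooth,
                   yearly_change = diff(smooth) / diff(grid$ages)),
              class = "coloc_trajectory")
  })
  names(out) <- colnames(X)
  out
}

#' @importFrom stats loess.control
NULL

#' Read a long-format trajectory grid CSV
#'
#' Columns `parcel, age, percentile, sex, ct`; every (parcel, age,
#' percentile, sex) combination must be present exactly once.
#'
#' @param path CSV/TSV file path.
#' @return a [trajectory_grid()].
#' @export
read_trajectory_grid <- function(path) {
  df <- .read_delim_auto(path)
  need <- c("parcel", "age", "percentile", "sex", "ct")
  if (!all(need %in% names(df)))
    stop("trajectory grid needs columns: ", paste(need, collapse = ", "))
  labels <- unique(df$parcel)
  ages <- sort(unique(as.numeric(df$age)))
  pct <- sort(unique(as.numeric(df$percentile)))
  sexes <- sort(unique(df$sex))
  arr <- array(NA_real_, dim = c(length(labels), length(ages), length(pct),
                                 length(sexes)))
  idx <- cbind(match(df$parcel, labels), match(as.numeric(df$age), ages),
               match(as.numeric(df$percentile), pct), match(df$sex, sexes))
  arr[idx] <- as.numeric(df$ct)
  if (anyNA(arr)) stop("trajectory grid is incomplete")
  trajectory_grid(arr, labels = labels, ages = ages, percentiles = pct,
                  sexes = sexes)
}

#' Write a trajectory grid as long-format CSV
#' @param grid a [trajectory_grid()].
#' @param path output CSV path.
#' @export
write_trajectory_grid <- function(grid, path) {
  d <- dim(grid$ct)
  df <- expand.grid(parcel = grid$labels, age = grid$ages,
                    percentile = grid$percentiles, sex = grid$sexes,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$ct <- sprintf("%.17g", as.vector(grid$ct))
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
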