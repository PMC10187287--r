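.subject_parcels <- function(table) {
  attr(table, "parcel_labels") %||%
    setdiff(names(table), c("subject", "session", "age", "sex", "site",
                            "defect_count"))
}

#' QC filter on surface-defect counts (Q3 + 1.5 x IQR rule)
#'
#' Q3 and IQR of the defect counts are computed over ALL sessions pooled
#' within the sample (quantiles by linear interpolation, type 7); a subject
#' is excluded if any of its sessions exceeds `Q3 + 1.5 * IQR`
#' (`level = "subject"`, the default) or, with `level = "session"`, only the
#' offending sessions are dropped. Subjects in `manual_fail` are excluded
#' regardless of their counts.
#'
#' @param table a subject table (see [simulate_subjects()]).
#' @param manual_fail optional character vector of subject ids failing manual
#'   quality ratings.
#' @param level exclusion granularity.
#' @return an object of class `qc_result`: `q3`, `iqr`, `threshold`,
#'   `keep_mask` (named per subject), `keep_rows` (logical per table row),
#'   `n_excluded`.
#' @export
qc_filter <- function(table, manual_fail = NULL,
                      level = c("subject", "session")) {
  level <- match.arg(level)
  if (!"defect_count" %in% names(table)) stop("defect counts are required")
  d <- table$defect_count
  if (length(d) < 4L) stop("need >= 4 sessions for stable quantiles")
  q3 <- quantile(d, 0.75, names = FALSE, type = 7)
  iqr <- q3 - quantile(d, 0.25, names = FALSE, type = 7)
  thr <- q3 + 1.5 * iqr
  over <- d > thr
  manual <- table$subject %in% (manual_fail %||% character())
  if (level == "subject") {
    bad_sub <- unique(table$subject[over | manual])
    keep_rows <- !(table$subject %in% bad_sub)
  } else {
    keep_rows <- !(over | manual)
  }
  subs <- unique(table$subject)
  keep_mask <- setNames(vapply(subs, function(s)
    any(keep_rows[table$subject == s]), TRUE), subs)
  structure(list(q3 = q3, iqr = iqr, threshold = thr,
                 keep_mask = keep_mask, keep_rows = keep_rows,
                 n_excluded = sum(!keep_mask)),
            class = "qc_result")
}

#' Per-subject relative CT change maps
#'
#' `delta = (CT_to - CT_from) / CT_from` per parcel for each subject with
#' both sessions present; subjects missing a session are skipped with a
#' message.
#'
#' @param table a subject table.
#' @param session_pairs list of `c(from, to)` session label pairs.
#' @return data.frame of class `subject_changes`: columns `subject`, `from`,
#'   `to`, `age_from`, `age_to`, then one delta column per parcel.
#' @export
subject_changes <- function(table, session_pairs = list(c("T0", "T2"))) {
  parcels <- .subject_parcels(table)
  ct_all <- as.matrix(table[, parcels, drop = FALSE])
  blocks <- list()
  for (pair in session_pairs) {
    from <- pair[1]; to <- pair[2]
    subs <- unique(table$subject)
    ri <- match(paste(subs, from), paste(table$subject, table$session))
    rj <- match(paste(subs, to), paste(table$subject, table$session))
    ok <- !is.na(ri) & !is.na(rj)
    for (s in subs[!ok])
      message("subject ", s, " lacks session pair ", from, "-", to,
              "; skipped")
    if (!any(ok)) next
    ct_i <- ct_all[ri[ok], , drop = FALSE]
    ct_j <- ct_all[rj[ok], , drop = FALSE]
    if (any(ct_i == 0)) {
      bad <- which(ct_i == 0, arr.ind = TRUE)[1, ]
      stop("zero CT at session ", from, " for subject ", subs[ok][bad[1]],
           ", parcel ", parcels[bad[2]])
    }
    blk <- data.frame(subject = subs[ok], from = from, to = to,
                      age_from = table$age[ri[ok]],
                      age_to = table$age[rj[ok]],
                      (ct_j - ct_i) / ct_i, check.names = FALSE,
                      stringsAsFactors = FALSE)
    names(blk)[-(1:5)] <- parcels
    blocks[[length(blocks) + 1L]] <- blk
  }
  if (!length(blocks)) stop("no subject has a complete session pair")
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  attr(out, "parcel_labels") <- parcels
  class(out) <- c("subject_changes", class(out))
  out
}

.changes_matrix <- function(changes) {
  parcels <- attr(changes, "parcel_labels") %||%
    setdiff(names(changes), c("subject", "from", "to", "age_from", "age_to"))
  t(as.matrix(changes[, parcels, drop = FALSE]))
}

#' Per-subject (and cohort-average) dominance analysis
#'
#' Runs the dominance decomposition of each subject's change map on the
#' marker set; map-valued covariates are residualized from each subject's
#' change map across parcels beforehand. With `cohort_average = TRUE` a
#' single decomposition of the across-subject mean change map is returned
#' instead.
#'
#' @param changes a [subject_changes()] data.frame.
#' @param markers a [marker_set()] (<= 15 markers).
#' @param covariates optional [marker_set()] of per-parcel nuisance maps.
#' @param cohort_average decompose the mean change map instead.
#' @return for subjects: data.frame with one row per subject x (full model +
#'   marker); for the cohort average: a `dominance_result`.
#' @export
subject_dominance_scan <- function(changes, markers, covariates = NULL,
                                   cohort_average = FALSE) {
  stopifnot(inherits(markers, "marker_set"))
  Y <- .changes_matrix(changes)  # parcels x subjects
  keep <- intersect(rownames(Y), markers$labels)
  Y <- Y[keep, , drop = FALSE]
  X <- markers$x[keep, , drop = FALSE]
  .check_dom_design(X)
  if (!is.null(covariates)) {
    Zc <- covariates$x[match(keep, covariates$labels), , drop = FALSE]
    Y <- apply(Y, 2L, .residualize, Z = Zc)
  }
  if (cohort_average) {
    avg <- rowMeans(Y)
    return(dominance_decompose(
      parcel_map(avg, labels = keep, name = "cohort_mean"),
      marker_set(X, modality = markers$modality)))
  }
  res <- .dominance_multi(X, Y)
  subs <- changes$subject
  rows <- list()
  for (j in seq_along(subs)) {
    rows[[length(rows) + 1L]] <- data.frame(
      subject = subs[j], marker = c("full_model", colnames(X)),
      r2 = c(res$full_r2[j], res$dominance[, j]),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "full_r2") <- setNames(as.vector(res$full_r2), subs)
  attr(out, "dominance") <- res$dominance
  class(out) <- c("subject_dominance", class(out))
  out
}

#' Group-mean permutation test of subject-level dominance
#'
#' Tests whether the across-subject mean full-model R-squared (and, with
#' `include_markers = TRUE`, each predictor's mean total dominance) is
#' higher than in null analyses where every subject's dominance is recomputed
#' with all markers jointly replaced by their k-th surrogates; one constant
#' ensemble serves all subjects and iterations. Positive-sided empirical
#' p-values via `(1 + k) / (1 + N)`.
#'
#' @param changes a [subject_changes()] data.frame (>= 2 subjects).
#' @param markers a [marker_set()].
#' @param ensembles constant per-marker surrogate ensembles of size >=
#'   `n_null`.
#' @param n_null number of null analyses (default 1000).
#' @param include_markers also test per-marker mean dominance (requires the
#'   2^p subset enumeration per null; `FALSE` tests the full model only).
#' @param covariates optional per-parcel nuisance maps (see
#'   [subject_dominance_scan()]).
#' @return list with `p_full`, `observed_mean_full_r2`, `null_mean_full_r2`,
#'   and (if requested) `p_markers`, `observed_mean_dominance`.
#' @export
group_null_test <- function(changes, markers, ensembles, n_null = 1000,
                            include_markers = TRUE, covariates = NULL) {
  stopifnot(inherits(markers, "marker_set"))
  if (length(unique(changes$subject)) < 2L) stop("need >= 2 subjects")
  sizes <- vapply(ensembles[markers$marker_names],
                  function(e) ncol(e$maps), 0L)
  if (any(is.na(sizes)) || any(sizes < n_null))
    stop("surrogate ensembles shorter than n_null")
  Y <- .changes_matrix(changes)
  keep <- intersect(rownames(Y), markers$labels)
  Y <- Y[keep, , drop = FALSE]
  X <- markers$x[keep, , drop = FALSE]
  .check_dom_design(X)
  if (!is.null(covariates)) {
    Zc <- covariates$x[match(keep, covariates$labels), , drop = FALSE]
    Y <- apply(Y, 2L, .residualize, Z = Zc)
  }
  Yc <- sweep(Y, 2L, colMeans(Y))
  p <- ncol(X)
  if (include_markers) {
    obs <- .dominance_multi(X, Y)
    obs_full <- mean(obs$full_r2)
    obs_dom <- rowMeans(obs$dominance)
    null_full <- numeric(n_null)
    null_dom <- matrix(NA_real_, p, n_null)
    for (k in seq_len(n_null)) {
      Xk <- .null_predictors(ensembles[markers$marker_names], k, keep)
      nk <- .dominance_multi(Xk, Y)
      null_full[k] <- mean(nk$full_r2)
      null_dom[, k] <- rowMeans(nk$dominance)
    }
    list(p_full = empirical_p(obs_full, null_full),
         p_markers = setNames(vapply(seq_len(p), function(x)
           empirical_p(obs_dom[x], null_dom[x, ]), 0), colnames(X)),
         observed_mean_full_r2 = obs_full,
         observed_mean_dominance = setNames(obs_dom, colnames(X)),
         null_mean_full_r2 = null_full)
  } else {
    Xall <- matrix(NA_real_, length(keep), p * (n_null + 1L))
    Xall[, seq_len(p)] <- X
    for (k in seq_len(n_null))
      Xall[, k * p + seq_len(p)] <-
        .null_predictors(ensembles[markers$marker_names], k, keep)
    Xall <- sweep(Xall, 2L, colMeans(Xall))
    r2 <- cpp_block_r2(Xall, Yc, p)  # (n_null + 1) x subjects
    means <- rowMeans(r2)
    list(p_full = empirical_p(means[1], means[-1]),
         observed_mean_full_r2 = means[1],
         null_mean_full_r2 = means[-1])
  }
}
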