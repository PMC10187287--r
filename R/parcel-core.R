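#' Parcellated brain map
#'
#' The atom of all spatial analysis in this package: one real value per
#' cortical parcel, keyed by a unique parcel label. Values may be `NA`
#' (missing), never silently zero-filled.
#'
#' @param values numeric vector, one value per parcel.
#' @param labels character vector of unique parcel labels; defaults to
#'   `names(values)`.
#' @param name map name (e.g. the atlas it came from).
#' @param modality one of `"nuclear_imaging"`, `"mrna_expression"`,
#'   `"mri_microstructure"`, `"derived"`.
#' @return an object of class `parcel_map`.
#' @export
parcel_map <- function(values, labels = names(values), name = "map",
                       modality = c("derived", "nuclear_imaging",
                                    "mrna_expression", "mri_microstructure")) {
  modality <- match.arg(modality)
  if (is.null(labels)) stop("parcel labels are required")
  labels <- as.character(labels)
  if (anyDuplicated(labels))
    stop("duplicate parcel labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  if (length(values) != length(labels))
    stop("values and labels differ in length")
  structure(list(labels = labels, values = as.numeric(values),
                 name = name, modality = modality),
            class = "parcel_map")
}

#' @export
print.parcel_map <- function(x, ...) {
  cat(sprintf("parcel_map '%s' (%s): %d parcels, %d missing\n",
              x$name, x$modality, length(x$values), sum(is.na(x$values))))
  invisible(x)
}

#' Parcel-by-marker matrix of neurobiological predictors
#'
#' @param x numeric matrix, parcels in rows (rownames = parcel labels),
#'   markers in columns (colnames = marker names).
#' @param labels,marker_names optional overrides for dimnames.
#' @param modality character scalar or vector (one per marker).
#' @return an object of class `marker_set`.
#' @export
marker_set <- function(x, labels = rownames(x), marker_names = colnames(x),
                       modality = "derived") {
  x <- as.matrix(x)
  if (is.null(labels)) stop("parcel labels are required")
  if (is.null(marker_names))
    marker_names <- paste0("m", seq_len(ncol(x)))
  labels <- as.character(labels)
  if (anyDuplicated(labels))
    stop("duplicate parcel labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  if (anyDuplicated(marker_names))
    stop("duplicate marker names: ",
         paste(unique(marker_names[duplicated(marker_names)]), collapse = ", "))
  if (ncol(x) < 1L) stop("at least one marker column is required")
  storage.mode(x) <- "double"
  dimnames(x) <- list(labels, marker_names)
  modality <- rep_len(modality, ncol(x))
  structure(list(labels = labels, x = x, marker_names = marker_names,
                 modality = setNames(modality, marker_names)),
            class = "marker_set")
}

#' @export
print.marker_set <- function(x, ...) {
  cat(sprintf("marker_set: %d parcels x %d markers (%s)\n",
              nrow(x$x), ncol(x$x),
              paste(unique(x$modality), collapse = "/")))
  invisible(x)
}

#' Gene-by-parcel expression table
#'
#' @param x numeric matrix, genes in rows, parcels in columns.
#' @param genes,labels optional dimname overrides.
#' @return an object of class `gene_parcel_expression`.
#' @export
gene_parcel_expression <- function(x, genes = rownames(x),
                                   labels = colnames(x)) {
  x <- as.matrix(x)
  genes <- as.character(genes)
  labels <- as.character(labels)
  if (anyDuplicated(genes))
    stop("duplicate gene symbols: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  if (anyDuplicated(labels)) stop("duplicate parcel labels")
  storage.mode(x) <- "double"
  dimnames(x) <- list(genes, labels)
  structure(list(genes = genes, labels = labels, x = x),
            class = "gene_parcel_expression")
}

.read_delim_auto <- function(path) {
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  read.csv(path, sep = sep, check.names = FALSE, stringsAsFactors = FALSE,
           colClasses = "character")
}

.as_numeric_strict <- function(df, what = "marker") {
  out <- matrix(NA_real_, nrow(df), ncol(df),
                dimnames = list(rownames(df), colnames(df)))
  for (j in seq_len(ncol(df))) {
    raw <- df[[j]]
    blank <- is.na(raw) | raw == "" | toupper(raw) == "NA"
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val) & !blank)
    if (length(bad))
      stop(sprintf("non-numeric cell in %s column '%s', row %d ('%s')",
                   what, colnames(df)[j], bad[1], raw[bad[1]]))
    out[, j] <- val
  }
  out
}

#' Read a parcel table (CSV/TSV) into a marker set
#'
#' Expects a `parcel` label column plus one numeric column per marker
#' (`orientation = "parcels_in_rows"`), or the transpose with a leading
#' `marker` column. Missing cells stay missing; they are never zero-filled.
#'
#' @param path file path; `.tsv`/`.txt` are read tab-separated, else comma.
#' @param orientation table layout.
#' @param modality modality tag(s) for the resulting markers.
#' @return a [marker_set()].
#' @export
read_parcel_table <- function(path,
                              orientation = c("parcels_in_rows",
                                              "parcels_in_cols"),
                              modality = "derived") {
  orientation <- match.arg(orientation)
  df <- .read_delim_auto(path)
  if (ncol(df) < 2L) stop("expected a label column plus >=1 data column")
  ids <- df[[1]]
  if (anyDuplicated(ids))
    stop("duplicate parcel labels in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  mat <- .as_numeric_strict(df[, -1, drop = FALSE])
  rownames(mat) <- ids
  if (orientation == "parcels_in_cols") mat <- t(mat)
  marker_set(mat, modality = modality)
}

#' Write a marker set as a parcel table
#'
#' Inverse of [read_parcel_table()]; a round trip reproduces values
#' bit-identically (values are serialized with full double precision).
#'
#' @param set a [marker_set()].
#' @param path output path; `.tsv` writes tab-separated.
#' @export
write_parcel_table <- function(set, path) {
  stopifnot(inherits(set, "marker_set"))
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  df <- data.frame(parcel = set$labels, check.names = FALSE,
                   stringsAsFactors = FALSE)
  for (m in set$marker_names)
    df[[m]] <- sprintf("%.17g", set$x[, m])
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a gene-by-parcel expression table
#'
#' CSV/TSV with a `gene` column followed by one column per parcel.
#'
#' @param path file path.
#' @return a [gene_parcel_expression()].
#' @export
read_expression_table <- function(path) {
  df <- .read_delim_auto(path)
  genes <- df[[1]]
  mat <- .as_numeric_strict(df[, -1, drop = FALSE], what = "parcel")
  rownames(mat) <- genes
  gene_parcel_expression(mat)
}

.zscore <- function(v) {
  ok <- !is.na(v)
  if (sum(ok) < 2L) stop("need >=2 non-missing values to standardize")
  s <- sd(v[ok])
  if (!is.finite(s) || s == 0) stop("zero variance: cannot Z-standardize")
  v[ok] <- (v[ok] - mean(v[ok])) / s
  v
}

#' Z-standardize a map across parcels
#'
#' Centers and scales to sample SD 1 (n-1 denominator) across non-missing
#' parcels; missing entries are preserved. Idempotent to machine precision.
#'
#' @param map a [parcel_map()], [marker_set()] (column-wise), or numeric vector.
#' @return the same type, standardized.
#' @export
zscore_parcels <- function(map) {
  if (inherits(map, "parcel_map")) {
    map$values <- .zscore(map$values)
    map
  } else if (inherits(map, "marker_set")) {
    map$x <- apply(map$x, 2L, .zscore)
    map
  } else .zscore(as.numeric(map))
}

#' Build a cell-type map from marker-gene expression
#'
#' Each available marker gene's expression is Z-standardized across parcels
#' (sample SD), then the unweighted average across genes is taken; this
#' removes per-gene scale and offset before pooling.
#'
#' @param expr a [gene_parcel_expression()].
#' @param marker_genes character vector of gene symbols defining the cell type.
#' @param cell_name name of the resulting map.
#' @return a [parcel_map()] with modality `mrna_expression`.
#' @export
build_celltype_map <- function(expr, marker_genes, cell_name) {
  stopifnot(inherits(expr, "gene_parcel_expression"))
  marker_genes <- unique(as.character(marker_genes))
  present <- marker_genes[marker_genes %in% expr$genes]
  absent <- setdiff(marker_genes, present)
  if (length(absent))
    warning(sprintf("%d marker gene(s) not in expression data, skipped: %s",
                    length(absent), paste(absent, collapse = ", ")))
  if (!length(present))
    stop("no marker gene of '", cell_name, "' found in the expression table")
  zs <- matrix(NA_real_, length(present), length(expr$labels))
  keep <- logical(length(present))
  for (i in seq_along(present)) {
    v <- expr$x[present[i], ]
    s <- sd(v, na.rm = TRUE)
    if (!is.finite(s) || s == 0) {
      warning("gene '", present[i], "' has zero variance across parcels; excluded")
      next
    }
    zs[i, ] <- (v - mean(v, na.rm = TRUE)) / s
    keep[i] <- TRUE
  }
  if (!any(keep)) stop("all marker genes of '", cell_name,
                       "' have zero variance")
  parcel_map(colMeans(zs[keep, , drop = FALSE]), labels = expr$labels,
             name = cell_name, modality = "mrna_expression")
}

.labels_of <- function(obj) {
  if (inherits(obj, c("parcel_map", "marker_set"))) obj$labels
  else stop("expected parcel_map or marker_set")
}

.values_matrix <- function(obj) {
  if (inherits(obj, "parcel_map"))
    matrix(obj$values, ncol = 1, dimnames = list(obj$labels, obj$name))
  else obj$x
}

#' Align maps and marker sets on a shared parcel ordering
#'
#' Intersects parcel labels across all inputs (ordering follows the first
#' input) and, under the `listwise` policy, drops every parcel that is
#' missing in any input. `pairwise` keeps missing values in place for
#' downstream pairwise-complete correlation.
#'
#' @param ... one or more [parcel_map()] / [marker_set()] objects.
#' @param policy missing-data policy.
#' @return list with `sets` (aligned inputs), `labels` (shared ordering) and
#'   `mask` (named logical over the first input's labels).
#' @export
align_and_mask <- function(..., policy = c("listwise", "pairwise")) {
  policy <- match.arg(policy)
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]]) &&
      !inherits(sets[[1]], c("parcel_map", "marker_set")))
    sets <- sets[[1]]
  if (!length(sets)) stop("no inputs")
  labs <- lapply(sets, .labels_of)
  common <- Reduce(intersect, labs[-1], labs[[1]])
  common <- labs[[1]][labs[[1]] %in% common]  # first input's order
  if (!length(common)) stop("empty parcel-label intersection across inputs")
  take <- function(obj, keep) {
    if (inherits(obj, "parcel_map")) {
      obj$values <- obj$values[match(keep, obj$labels)]
      obj$labels <- keep
    } else {
      obj$x <- obj$x[match(keep, obj$labels), , drop = FALSE]
      obj$labels <- keep
    }
    obj
  }
  aligned <- lapply(sets, take, keep = common)
  if (policy == "listwise") {
    ok <- rep(TRUE, length(common))
    for (a in aligned) ok <- ok & complete.cases(.values_matrix(a))
    if (!any(ok)) stop("no complete parcels under listwise alignment")
    aligned <- lapply(aligned, take, keep = common[ok])
    common <- common[ok]
  }
  mask <- setNames(labs[[1]] %in% common, labs[[1]])
  list(sets = aligned, labels = common, mask = mask)
}
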