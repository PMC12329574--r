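#' Labeled parcel-level feature matrix
#'
#' Container for the classification input: one row per statistic map
#' (subject x condition), one column per parcel, with the fixed label
#' encoding SpE_VisE = 0, SpE_VisH = 1, SpH_VisE = 2, SpH_VisH = 3.
#'
#' @param values Numeric matrix (maps x parcels), no missing values.
#' @param subject Subject identifier per row.
#' @param condition Condition label per row (one of
#'   [dual_task_conditions]).
#' @param parcel_ids Sorted positive integer ids aligned to columns.
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, subject, condition,
                           parcel_ids = seq_len(ncol(values))) {
  values <- as.matrix(values)
  stopifnot(is.numeric(values), nrow(values) == length(subject),
            nrow(values) == length(condition),
            ncol(values) == length(parcel_ids))
  if (any(!is.finite(values))) stop("feature matrix contains missing values")
  if (anyDuplicated(parcel_ids)) stop("parcel_ids must be unique")
  labels <- condition_code(condition)
  if (length(unique(table(labels))) > 1L) {
    stop("label counts must be equal across classes")
  }
  if (anyDuplicated(paste(subject, condition))) {
    stop("duplicate (subject, condition) pair")
  }
  rownames(values) <- NULL
  colnames(values) <- paste0("parcel_", parcel_ids)
  structure(list(values = values, labels = labels,
                 subject = subject, condition = condition,
                 parcel_ids = as.integer(parcel_ids)),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d maps x %d parcels (%d per class)\n",
              nrow(x$values), ncol(x$values), nrow(x$values) / 4L))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' Integer-labeled parcel atlas
#'
#' @param label_volume Integer array; 0 marks background.
#' @param parcel_ids Sorted positive parcel ids; defaults to the nonzero
#'   labels present in the volume. Every nonzero label in the volume must
#'   appear in `parcel_ids`.
#' @param names Optional per-parcel names.
#' @return An object of class `parcel_atlas`.
#' @export
parcel_atlas <- function(label_volume, parcel_ids = NULL, names = NULL) {
  lv <- as.integer(label_volume)
  if (any(lv < 0, na.rm = TRUE)) stop("labels must be non-negative")
  present <- sort(unique(lv[lv > 0L]))
  if (is.null(parcel_ids)) parcel_ids <- present
  parcel_ids <- as.integer(parcel_ids)
  if (anyDuplicated(parcel_ids)) stop("parcel_ids must be unique")
  if (!all(present %in% parcel_ids)) {
    stop("label volume contains ids absent from parcel_ids")
  }
  if (!is.null(names) && length(names) != length(parcel_ids)) {
    stop("names must align with parcel_ids")
  }
  structure(list(label_volume = array(lv, dim = dim(label_volume)),
                 parcel_ids = sort(parcel_ids), names = names),
            class = "parcel_atlas")
}

#' Reduce a statistic volume to parcel means
#'
#' The value for parcel `p` is the arithmetic mean of all voxels whose
#' atlas label equals `p`; background (label 0) is excluded. A parcel id
#' with no voxels in the volume is an error unless `allow_missing = TRUE`,
#' in which case it yields an explicit `NA` rather than a silent zero.
#'
#' @param volume Numeric array, same shape as the atlas label volume.
#' @param atlas A [parcel_atlas()].
#' @param allow_missing Emit `NA` for empty parcels instead of erroring.
#' @return Named numeric vector indexed by parcel id.
#' @export
parcel_reduce <- function(volume, atlas, allow_missing = FALSE) {
  stopifnot(inherits(atlas, "parcel_atlas"))
  if (!identical(dim(volume), dim(atlas$label_volume))) {
    stop("volume and atlas label volume differ in shape")
  }
  lab <- as.vector(atlas$label_volume)
  val <- as.vector(volume)
  keep <- lab > 0L
  sums <- rowsum(val[keep], lab[keep])
  counts <- rowsum(rep(1, sum(keep)), lab[keep])
  means <- setNames(rep(NA_real_, length(atlas$parcel_ids)),
                    atlas$parcel_ids)
  means[rownames(sums)] <- sums[, 1] / counts[, 1]
  if (anyNA(means) && !allow_missing) {
    stop("parcel(s) with no voxels in the volume: ",
         paste(names(means)[is.na(means)], collapse = ", "))
  }
  means
}

#' Assemble parcel vectors into a labeled feature matrix
#'
#' @param vectors List of per-map parcel vectors (all sharing the same
#'   parcel ids, as produced by [parcel_reduce()]).
#' @param subject,condition Per-map row metadata.
#' @return A [feature_matrix()] with rows ordered by (subject, condition)
#'   and columns by sorted parcel id.
#' @export
assemble_matrix <- function(vectors, subject, condition) {
  stopifnot(is.list(vectors), length(vectors) == length(subject),
            length(vectors) == length(condition))
  ids <- names(vectors[[1L]])
  for (v in vectors) {
    if (!identical(names(v), ids)) stop("inconsistent parcel sets across maps")
  }
  ord_cols <- order(as.integer(ids))
  values <- do.call(rbind, lapply(vectors, function(v) v[ord_cols]))
  ord_rows <- order(subject, condition_code(condition))
  feature_matrix(values[ord_rows, , drop = FALSE],
                 subject = subject[ord_rows],
                 condition = condition[ord_rows],
                 parcel_ids = as.integer(ids)[ord_cols])
}

#' Subset the parcels (columns) of a feature matrix
#'
#' @param fm A [feature_matrix()].
#' @param cols Column indices (positions, not parcel ids).
#' @return A [feature_matrix()] restricted to those parcels.
#' @export
subset_parcels <- function(fm, cols) {
  stopifnot(inherits(fm, "feature_matrix"))
  feature_matrix(fm$values[, cols, drop = FALSE], fm$subject, fm$condition,
                 fm$parcel_ids[cols])
}

#' Serialize a feature matrix to TSV
#'
#' @param fm A [feature_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  df <- data.frame(subject = fm$subject, condition = fm$condition,
                   label = fm$labels, fm$values, check.names = FALSE)
  write_tsv(df, path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#' @param path TSV path.
#' @return A [feature_matrix()].
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  pc <- grep("^parcel_", names(df), value = TRUE)
  feature_matrix(as.matrix(df[, pc, drop = FALSE]),
                 subject = df$subject, condition = df$condition,
                 parcel_ids = as.integer(sub("^parcel_", "", pc)))
}
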