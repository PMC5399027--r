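# The central data container: a samples x features intensity matrix with
# sample and feature metadata.  Missing values (NA) mean "peak not
# detected"; a recorded 0 is an observed zero.  Intensities must be
# non-negative wherever observed.

SAMPLE_TYPES <- c("study", "qc", "blank")

#' Construct a peak table
#'
#' Bundles a samples x features intensity matrix with its sample and feature
#' metadata and validates the cross-references.
#'
#' @param intensities Numeric matrix, rows = samples, columns = features,
#'   with row and column names.  `NA` encodes a non-detected peak; observed
#'   values must be non-negative.
#' @param sample_meta Data frame with columns `sample_id`, `group`,
#'   `animal_id`, `day`, `sample_type` (one of `"study"`, `"qc"`,
#'   `"blank"`).  Rows are matched to `intensities` by `sample_id`.
#' @param feature_meta Optional data frame with columns `feature_id` and
#'   `platform`; defaults to a single unknown platform.
#' @return An object of class `peak_table`.
#' @export
peak_table <- function(intensities, sample_meta, feature_meta = NULL) {
  if (!is.matrix(intensities) || !is.numeric(intensities)) {
    stop("`intensities` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(intensities)) || is.null(colnames(intensities))) {
    stop("`intensities` must have sample row names and feature column names",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(intensities)) || anyDuplicated(colnames(intensities))) {
    stop("duplicate sample or feature ids", call. = FALSE)
  }
  obs <- !is.na(intensities)
  if (any(intensities[obs] < 0)) {
    stop("observed intensities must be non-negative", call. = FALSE)
  }
  sample_meta <- as.data.frame(sample_meta, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "animal_id", "day", "sample_type")
  if (!all(need %in% names(sample_meta))) {
    stop("`sample_meta` must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(sample_meta$sample_id)) {
    stop("duplicate sample ids in `sample_meta`", call. = FALSE)
  }
  if (!setequal(sample_meta$sample_id, rownames(intensities))) {
    stop("`sample_meta` does not match the intensity matrix rows", call. = FALSE)
  }
  if (!all(sample_meta$sample_type %in% SAMPLE_TYPES)) {
    stop("`sample_type` must be one of ", paste(SAMPLE_TYPES, collapse = ", "),
         call. = FALSE)
  }
  sample_meta <- sample_meta[match(rownames(intensities), sample_meta$sample_id), ,
                             drop = FALSE]
  rownames(sample_meta) <- NULL
  if (is.null(feature_meta)) {
    feature_meta <- data.frame(feature_id = colnames(intensities),
                               platform = "unknown",
                               stringsAsFactors = FALSE)
  }
  feature_meta <- as.data.frame(feature_meta, stringsAsFactors = FALSE)
  if (!all(c("feature_id", "platform") %in% names(feature_meta))) {
    stop("`feature_meta` must have columns feature_id, platform", call. = FALSE)
  }
  if (!setequal(feature_meta$feature_id, colnames(intensities)) ||
      anyDuplicated(feature_meta$feature_id)) {
    stop("`feature_meta` does not match the intensity matrix columns", call. = FALSE)
  }
  feature_meta <- feature_meta[match(colnames(intensities), feature_meta$feature_id), ,
                               drop = FALSE]
  rownames(feature_meta) <- NULL
  structure(
    list(intensities = intensities, sample_meta = sample_meta,
         feature_meta = feature_meta),
    class = "peak_table"
  )
}

#' @export
print.peak_table <- function(x, ...) {
  tab <- table(x$sample_meta$sample_type)
  cat(sprintf("peak_table: %d samples x %d features (%s)\n",
              nrow(x$intensities), ncol(x$intensities),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' @export
dim.peak_table <- function(x) dim(x$intensities)

sample_ids_of_type <- function(table, type) {
  table$sample_meta$sample_id[table$sample_meta$sample_type == type]
}

#' Subset a peak table
#'
#' @param table A `peak_table`.
#' @param samples,features Optional character vectors of ids to keep (order
#'   preserved as given).
#' @return The subset `peak_table`.
#' @export
pt_subset <- function(table, samples = NULL, features = NULL) {
  stopifnot(inherits(table, "peak_table"))
  ints <- table$intensities
  if (!is.null(samples)) {
    missing_ids <- setdiff(samples, rownames(ints))
    if (length(missing_ids)) {
      stop("unknown sample id(s): ", paste(missing_ids, collapse = ", "),
           call. = FALSE)
    }
    ints <- ints[samples, , drop = FALSE]
  }
  if (!is.null(features)) {
    missing_ids <- setdiff(features, colnames(ints))
    if (length(missing_ids)) {
      stop("unknown feature id(s): ", paste(missing_ids, collapse = ", "),
           call. = FALSE)
    }
    ints <- ints[, features, drop = FALSE]
  }
  sm <- table$sample_meta[match(rownames(ints), table$sample_meta$sample_id), ,
                          drop = FALSE]
  fm <- table$feature_meta[match(colnames(ints), table$feature_meta$feature_id), ,
                           drop = FALSE]
  rownames(sm) <- rownames(fm) <- NULL
  structure(list(intensities = ints, sample_meta = sm, feature_meta = fm),
            class = "peak_table")
}

#' Remove features from a peak table
#'
#' Drops the named feature columns; the sample set is unchanged.
#'
#' @param table A `peak_table`.
#' @param ids Character vector of feature ids to remove (may be empty).
#' @return The reduced `peak_table`.
#' @export
remove_features <- function(table, ids) {
  stopifnot(inherits(table, "peak_table"))
  ids <- as.character(ids)
  unknown <- setdiff(ids, colnames(table$intensities))
  if (length(unknown)) {
    stop("unknown feature id(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  keep <- setdiff(colnames(table$intensities), ids)
  pt_subset(table, features = keep)
}

#' Fill non-detected values for multivariate modelling
#'
#' Multivariate decompositions require a complete matrix; preprocessing
#' itself never imputes, so the fill happens once, explicitly, at the
#' modelling boundary.  Each feature's missing entries are replaced by half
#' its minimum observed value (the conventional detection-limit surrogate);
#' a feature with no observed value at all is filled with 0.
#'
#' @param table A `peak_table`.
#' @return A `peak_table` with a complete intensity matrix.
#' @export
fill_missing <- function(table) {
  stopifnot(inherits(table, "peak_table"))
  ints <- table$intensities
  for (j in seq_len(ncol(ints))) {
    nas <- is.na(ints[, j])
    if (!any(nas)) next
    obs <- ints[!nas, j]
    ints[nas, j] <- if (length(obs)) min(obs) / 2 else 0
  }
  table$intensities <- ints
  table
}
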