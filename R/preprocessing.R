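# Preprocessing chain for raw peak tables: background filtering against
# blanks, the 80% rule, pooled-QC RSD filtering, total-ion-intensity
# normalization, ion fusion and Pareto scaling.  Every filter returns the
# reduced table together with a FilterReport row (stage, removed,
# retained); none of them imputes missing values.

filter_report <- function(stage, removed, retained) {
  data.frame(stage = stage, removed = removed, retained = retained,
             stringsAsFactors = FALSE)
}

#' Background-peak filtering against blank injections
#'
#' A feature is retained iff its mean observed intensity across study
#' samples is at least `min_sample_to_blank_ratio` times its mean blank
#' intensity (non-detected blank values count as 0, so a feature absent
#' from every blank is always retained).
#'
#' @param table A `peak_table` containing at least one blank sample.
#' @param min_sample_to_blank_ratio Ratio threshold, must exceed 1;
#'   default 3.
#' @return A list with `table` (filtered) and `report` (one-row filter
#'   report).
#' @export
filter_background <- function(table, min_sample_to_blank_ratio = 3) {
  stopifnot(inherits(table, "peak_table"))
  stop_if_not_scalar_number(min_sample_to_blank_ratio, "min_sample_to_blank_ratio")
  if (min_sample_to_blank_ratio <= 1) {
    stop("`min_sample_to_blank_ratio` must exceed 1", call. = FALSE)
  }
  blanks <- sample_ids_of_type(table, "blank")
  if (!length(blanks)) stop("no blank samples present", call. = FALSE)
  study <- sample_ids_of_type(table, "study")
  bl <- table$intensities[blanks, , drop = FALSE]
  bl[is.na(bl)] <- 0
  blank_mean <- colMeans(bl)
  st <- table$intensities[study, , drop = FALSE]
  study_mean <- colMeans(st, na.rm = TRUE)
  study_mean[!is.finite(study_mean)] <- 0  # feature unobserved in every study sample
  keep <- study_mean >= min_sample_to_blank_ratio * blank_mean
  out <- pt_subset(table, features = colnames(table$intensities)[keep])
  list(table = out,
       report = filter_report("background", sum(!keep), sum(keep)))
}

#' The 80% rule
#'
#' A feature is retained iff it is observed (non-missing) in at least
#' `fraction` of the samples of at least one study group.  QC and blank
#' samples are excluded from the counts.
#'
#' @param table A `peak_table` with at least one study group.
#' @param fraction Required within-group detection fraction; default 0.8.
#' @return A list with `table` and `report`.
#' @export
apply_80_rule <- function(table, fraction = 0.8) {
  stopifnot(inherits(table, "peak_table"))
  stop_if_not_scalar_number(fraction, "fraction", lower = 0, upper = 1)
  sm <- table$sample_meta
  study <- sm$sample_id[sm$sample_type == "study"]
  if (!length(study)) stop("no study samples present", call. = FALSE)
  groups <- split(study, sm$group[match(study, sm$sample_id)])
  obs <- !is.na(table$intensities)
  keep <- rep(FALSE, ncol(obs))
  for (ids in groups) {
    frac <- colMeans(obs[ids, , drop = FALSE])
    keep <- keep | (frac >= fraction)
  }
  out <- pt_subset(table, features = colnames(table$intensities)[keep])
  list(table = out,
       report = filter_report("rule80", sum(!keep), sum(keep)))
}

#' QC relative-standard-deviation filter
#'
#' A feature is retained iff its RSD (sample standard deviation divided by
#' mean) over the pooled-QC injections does not exceed `max_rsd`.
#'
#' @param table A `peak_table` with at least two QC samples.
#' @param max_rsd Maximum tolerated RSD as a fraction; default 0.15.
#' @return A list with `table` and `report`.
#' @export
qc_rsd_filter <- function(table, max_rsd = 0.15) {
  stopifnot(inherits(table, "peak_table"))
  stop_if_not_scalar_number(max_rsd, "max_rsd", lower = 0)
  qcs <- sample_ids_of_type(table, "qc")
  if (length(qcs) < 2L) stop("at least two QC samples are required", call. = FALSE)
  q <- table$intensities[qcs, , drop = FALSE]
  m <- colMeans(q, na.rm = TRUE)
  s <- apply(q, 2, stats::sd, na.rm = TRUE)
  rsd <- s / m
  keep <- is.finite(rsd) & rsd <= max_rsd
  out <- pt_subset(table, features = colnames(table$intensities)[keep])
  list(table = out,
       report = filter_report("qc_rsd", sum(!keep), sum(keep)))
}

#' Total-ion-intensity normalization
#'
#' Divides each sample's observed intensities by that sample's total
#' observed intensity, so every row of observed values sums to 1.  Missing
#' values stay missing.
#'
#' @param table A `peak_table` in which every sample has a positive total
#'   observed intensity.
#' @return The normalized `peak_table`.
#' @export
normalize_total_intensity <- function(table) {
  stopifnot(inherits(table, "peak_table"))
  totals <- rowSums(table$intensities, na.rm = TRUE)
  if (any(totals <= 0)) {
    bad <- rownames(table$intensities)[totals <= 0]
    stop("sample(s) with non-positive total observed intensity: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  table$intensities <- table$intensities / totals
  table
}

#' Ion fusion
#'
#' Merges redundant features (adducts or isotopes of one metabolite) inside
#' a declared grouping window.  Within each window, features whose pairwise
#' Pearson correlation across study samples reaches `min_correlation` are
#' joined by single linkage into one fused feature carrying the summed
#' intensity.  Features in different windows are never merged.
#'
#' @param table A `peak_table`.
#' @param grouping Named character/integer vector mapping every feature id
#'   to a window label, or `NULL` to use a `fusion_window` column of the
#'   feature metadata; with neither present the table is returned
#'   unchanged.
#' @param min_correlation Correlation threshold in (0, 1]; default 0.9.
#' @return A list with `table`, `report`, and `merges` (list of merged id
#'   sets).
#' @export
fuse_ions <- function(table, grouping = NULL, min_correlation = 0.9) {
  stopifnot(inherits(table, "peak_table"))
  stop_if_not_scalar_number(min_correlation, "min_correlation")
  if (min_correlation <= 0 || min_correlation > 1) {
    stop("`min_correlation` must be in (0, 1]", call. = FALSE)
  }
  fids <- colnames(table$intensities)
  if (is.null(grouping)) {
    if ("fusion_window" %in% names(table$feature_meta)) {
      grouping <- stats::setNames(table$feature_meta$fusion_window,
                                  table$feature_meta$feature_id)
    } else {
      return(list(table = table,
                  report = filter_report("ion_fusion", 0L, length(fids)),
                  merges = list()))
    }
  }
  if (!all(fids %in% names(grouping))) {
    stop("`grouping` must cover every feature id", call. = FALSE)
  }
  study <- sample_ids_of_type(table, "study")
  ints <- table$intensities
  st <- ints[study, , drop = FALSE]

  clusters <- list()  # each element: character vector of feature ids to fuse
  for (win in split(fids, as.character(grouping[fids]))) {
    if (length(win) == 1L) { clusters <- c(clusters, list(win)); next }
    # single-linkage components of the graph {corr >= threshold}
    parent <- seq_along(win)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (a in seq_along(win)[-length(win)]) {
      for (b in (a + 1L):length(win)) {
        r <- suppressWarnings(
          stats::cor(st[, win[a]], st[, win[b]], use = "pairwise.complete.obs")
        )
        if (!is.na(r) && r >= min_correlation) {
          ra <- find(a); rb <- find(b)
          if (ra != rb) parent[rb] <- ra
        }
      }
    }
    roots <- vapply(seq_along(win), find, integer(1))
    clusters <- c(clusters, unname(split(win, roots)))
  }

  merges <- Filter(function(cl) length(cl) > 1L, clusters)
  new_cols <- lapply(clusters, function(cl) {
    if (length(cl) == 1L) return(ints[, cl])
    block <- ints[, cl, drop = FALSE]
    s <- rowSums(block, na.rm = TRUE)
    s[rowSums(!is.na(block)) == 0L] <- NA_real_
    s
  })
  new_ids <- vapply(clusters, function(cl) paste(cl, collapse = "+"), character(1))
  fused <- do.call(cbind, new_cols)
  colnames(fused) <- new_ids
  rownames(fused) <- rownames(ints)
  # keep original feature order by first member
  ord <- order(match(vapply(clusters, `[`, character(1), 1L), fids))
  fused <- fused[, ord, drop = FALSE]
  clusters <- clusters[ord]
  fm <- table$feature_meta[match(vapply(clusters, `[`, character(1), 1L),
                                 table$feature_meta$feature_id), , drop = FALSE]
  fm$feature_id <- colnames(fused)
  rownames(fm) <- NULL
  out <- peak_table(fused, table$sample_meta, fm)
  list(table = out,
       report = filter_report("ion_fusion",
                              length(fids) - ncol(fused), ncol(fused)),
       merges = merges)
}

#' Pareto scaling
#'
#' Centers each column by its mean and divides by the square root of its
#' sample standard deviation.  After scaling, each column has mean 0 and
#' variance equal to the original standard deviation.
#'
#' @param x Numeric matrix with at least two rows, no missing values and no
#'   constant column.
#' @return A list with `scaled` (the scaled matrix), `center` (column
#'   means) and `sd` (column standard deviations).
#' @export
pareto_scale <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) stop("`x` must be a numeric matrix", call. = FALSE)
  if (nrow(x) < 2L) stop("at least two rows are required", call. = FALSE)
  if (anyNA(x)) stop("missing values are not allowed; fill them first", call. = FALSE)
  mu <- colMeans(x)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant column(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "), call. = FALSE)
  }
  scaled <- sweep(sweep(x, 2, mu, "-"), 2, sqrt(sds), "/")
  list(scaled = scaled, center = mu, sd = sds)
}

#' Apply previously fitted Pareto scaling parameters
#'
#' Transforms new rows (for example pooled-QC samples) with centering and
#' scaling parameters fitted on the study samples.
#'
#' @param x Numeric matrix whose columns match the fitted parameters.
#' @param center,sd Column means and standard deviations from
#'   [pareto_scale()].
#' @return The scaled matrix.
#' @export
pareto_apply <- function(x, center, sd) {
  stopifnot(is.matrix(x), length(center) == ncol(x), length(sd) == ncol(x))
  sweep(sweep(x, 2, center, "-"), 2, sqrt(sd), "/")
}
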