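# RAUC: per-metabolite fold-change curves relative to the same-day control
# mean, and the area of their absolute value over the delayed-toxicity
# window (days 4-10 by default).  Deviation in either direction means
# dissimilarity to control, so the area is taken on |relative level|; the
# lower a group's RAUC, the closer it is to control.

#' Relative fold-change curves versus the control group
#'
#' For every study sample in the day window, computes the per-metabolite
#' relative level against the same-day control-group mean:
#' `log2(intensity / control mean)` by default (control is the zero
#' level), or `intensity / control mean - 1` with `scale = "fc_minus_1"`.
#'
#' @param table A `peak_table` with positive intensities for the chosen
#'   metabolites.
#' @param control_group Control group label; must be sampled at every
#'   window day.
#' @param metabolites Feature ids to trace.
#' @param window_days Days of the window; default `c(4, 7, 10)`.
#' @param scale `"log2"` (default) or `"fc_minus_1"`.
#' @return An object of class `relative_curves`: a long data frame with
#'   `animal_id`, `group`, `day`, `feature_id`, `rel`, plus the window and
#'   scale as attributes.
#' @export
relative_curves <- function(table, control_group = "C", metabolites,
                            window_days = c(4, 7, 10),
                            scale = c("log2", "fc_minus_1")) {
  stopifnot(inherits(table, "peak_table"))
  scale <- match.arg(scale)
  metabolites <- as.character(metabolites)
  unknown <- setdiff(metabolites, colnames(table$intensities))
  if (length(unknown)) {
    stop("unknown metabolite id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  sm <- table$sample_meta
  study <- sm[sm$sample_type == "study", , drop = FALSE]
  rows <- list()
  for (d in window_days) {
    ctrl_ids <- study$sample_id[study$group == control_group & study$day == d]
    if (!length(ctrl_ids)) {
      stop(sprintf("control group not sampled at day %s", d), call. = FALSE)
    }
    ctrl_mean <- colMeans(table$intensities[ctrl_ids, metabolites, drop = FALSE],
                          na.rm = TRUE)
    if (any(!is.finite(ctrl_mean)) || any(ctrl_mean <= 0)) {
      stop(sprintf("zero or absent control mean at day %s", d), call. = FALSE)
    }
    day_ids <- study$sample_id[study$day == d]
    ints <- table$intensities[day_ids, metabolites, drop = FALSE]
    rel <- switch(scale,
      log2 = log2(sweep(ints, 2, ctrl_mean, "/")),
      fc_minus_1 = sweep(ints, 2, ctrl_mean, "/") - 1
    )
    idx <- match(day_ids, study$sample_id)
    rows[[length(rows) + 1L]] <- data.frame(
      animal_id = rep(study$animal_id[idx], times = length(metabolites)),
      group = rep(study$group[idx], times = length(metabolites)),
      day = d,
      feature_id = rep(metabolites, each = length(day_ids)),
      rel = as.vector(rel),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("relative_curves", "data.frame"),
            window_days = sort(window_days), scale = scale,
            control_group = control_group)
}

#' RAUC: area of the absolute relative curve over the window
#'
#' Per animal and metabolite, the trapezoidal area of `|relative level|`
#' across the window days; group medians; and per-metabolite Mann-Whitney
#' tests of every group against the toxin-only group on the per-animal
#' areas (unadjusted p-values).  A metabolite counts as re-regulated in a
#' group iff its RAUC distribution is significantly lower than the toxin
#' group's (`p < alpha` and a lower group median).
#'
#' @param curves A `relative_curves` object.
#' @param toxin_group Toxin-only group label; default `"T"`.
#' @param alpha Unadjusted significance level for re-regulation calls;
#'   default 0.05.
#' @return An object of class `rauc_result` with `per_animal`
#'   (`animal_id`, `group`, `feature_id`, `rauc`), `group_summary`
#'   (median RAUC per group and metabolite), and `tests` (`group`,
#'   `feature_id`, `U`, `p`, `reregulated`).
#' @export
compute_rauc <- function(curves, toxin_group = "T", alpha = 0.05) {
  stopifnot(inherits(curves, "relative_curves"))
  window <- attr(curves, "window_days")
  if (length(window) < 2L) stop("the window must span at least two days", call. = FALSE)
  df <- as.data.frame(curves)
  key <- paste(df$animal_id, df$feature_id, sep = "\r")
  per_animal <- do.call(rbind, lapply(split(df, key), function(d) {
    d <- d[order(d$day), , drop = FALSE]
    ok <- !is.na(d$rel)
    if (sum(ok) < 2L) {
      return(data.frame(animal_id = d$animal_id[1], group = d$group[1],
                        feature_id = d$feature_id[1], rauc = NA_real_,
                        stringsAsFactors = FALSE))
    }
    data.frame(animal_id = d$animal_id[1], group = d$group[1],
               feature_id = d$feature_id[1],
               rauc = trapezoid_auc(abs(d$rel[ok]), d$day[ok]),
               stringsAsFactors = FALSE)
  }))
  rownames(per_animal) <- NULL
  if (!any(per_animal$group == toxin_group)) {
    stop("toxin group absent from the curves", call. = FALSE)
  }
  group_summary <- stats::aggregate(
    list(rauc_median = per_animal$rauc),
    by = list(group = per_animal$group, feature_id = per_animal$feature_id),
    FUN = function(v) stats::median(v, na.rm = TRUE))
  other_groups <- setdiff(unique(per_animal$group), toxin_group)
  tests <- do.call(rbind, lapply(other_groups, function(g) {
    do.call(rbind, lapply(unique(per_animal$feature_id), function(j) {
      a <- per_animal$rauc[per_animal$group == g & per_animal$feature_id == j]
      b <- per_animal$rauc[per_animal$group == toxin_group &
                             per_animal$feature_id == j]
      a <- a[!is.na(a)]; b <- b[!is.na(b)]
      if (length(a) < 2L || length(b) < 2L) {
        return(data.frame(group = g, feature_id = j, U = NA_real_,
                          p = NA_real_, reregulated = FALSE,
                          stringsAsFactors = FALSE))
      }
      mw <- mann_whitney(a, b)
      data.frame(group = g, feature_id = j, U = mw$statistic, p = mw$p_value,
                 reregulated = mw$p_value < alpha &&
                   stats::median(a) < stats::median(b),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(tests) <- NULL
  structure(list(per_animal = per_animal, group_summary = group_summary,
                 tests = tests, toxin_group = toxin_group,
                 window_days = window, alpha = alpha),
            class = "rauc_result")
}

#' @export
print.rauc_result <- function(x, ...) {
  cat(sprintf("rauc_result: %d metabolites, window days %s, %d re-regulation calls\n",
              length(unique(x$per_animal$feature_id)),
              paste(x$window_days, collapse = "-"),
              sum(x$tests$reregulated, na.rm = TRUE)))
  invisible(x)
}

#' Common re-regulated metabolites across group sets
#'
#' For each requested set of groups, intersects the per-group lists of
#' re-regulated metabolites (those whose RAUC is significantly lower than
#' the toxin group's).
#'
#' @param rauc A `rauc_result`.
#' @param group_sets Named list of character vectors, each with at least
#'   two group labels.
#' @return A named list of metabolite id vectors, with a `table` attribute
#'   in long form (`set_label`, `metabolite`).
#' @export
common_reregulated <- function(rauc, group_sets) {
  stopifnot(inherits(rauc, "rauc_result"), is.list(group_sets))
  per_group <- split(rauc$tests$feature_id[rauc$tests$reregulated],
                     rauc$tests$group[rauc$tests$reregulated])
  out <- lapply(group_sets, function(gs) {
    if (length(gs) < 2L) stop("each group set needs at least two groups", call. = FALSE)
    lists <- lapply(as.character(gs), function(g) {
      v <- per_group[[g]]
      if (is.null(v)) character() else v
    })
    sort(Reduce(intersect, lists))
  })
  tab <- do.call(rbind, lapply(names(out), function(lbl) {
    if (!length(out[[lbl]])) return(NULL)
    data.frame(set_label = lbl, metabolite = out[[lbl]], stringsAsFactors = FALSE)
  }))
  if (is.null(tab)) {
    tab <- data.frame(set_label = character(), metabolite = character(),
                      stringsAsFactors = FALSE)
  }
  attr(out, "table") <- tab
  out
}
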