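# Screening cascade: removal of exogenous (decoction-originated) features,
# per-day OPLS-DA + Mann-Whitney biomarker selection with BH adjustment,
# union across comparisons, and the phenotype-anchored Spearman filter.

# Pareto-scaled, missing-filled modelling matrix for a set of samples;
# constant columns are dropped (they carry no discriminating information
# and break scaling).
modelling_matrix <- function(table, sample_ids) {
  filled <- fill_missing(pt_subset(table, samples = sample_ids))
  x <- filled$intensities
  sds <- apply(x, 2, stats::sd)
  x <- x[, sds > 0, drop = FALSE]
  if (ncol(x) == 0L) stop("no variable features in the selected samples", call. = FALSE)
  pareto_scale(x)$scaled
}

#' Detect exogenous (decoction-originated) features
#'
#' Pools the control and toxin-only groups into a reference (`CT`) that
#' lacks decoction exposure, fits an OPLS-DA of the treated group against
#' CT, and flags as exogenous every feature observed in fewer than
#' `absence_fraction` of CT study samples while observed in at least
#' `1 - absence_fraction` of the treated group's study samples.  Flagged
#' ids are returned ranked by decreasing `|pcorr|` with the predictive
#' score (the S-plot ordering an analyst would inspect).
#'
#' @param table A `peak_table`.
#' @param treated_group,control_group,toxin_group Group labels, all present
#'   among the study samples.
#' @param absence_fraction Observation fraction below which a feature
#'   counts as absent; default 0.1.
#' @param n_orth Orthogonal components for the ranking model; default 1.
#' @return Character vector of exogenous feature ids (possibly empty), with
#'   a `detail` attribute holding the per-feature observation fractions and
#'   correlations.
#' @export
detect_exogenous <- function(table, treated_group, control_group = "C",
                             toxin_group = "T", absence_fraction = 0.1,
                             n_orth = 1L) {
  stopifnot(inherits(table, "peak_table"))
  stop_if_not_scalar_number(absence_fraction, "absence_fraction",
                            lower = 0, upper = 0.5)
  sm <- table$sample_meta
  study <- sm[sm$sample_type == "study", , drop = FALSE]
  ct_ids <- study$sample_id[study$group %in% c(control_group, toxin_group)]
  tr_ids <- study$sample_id[study$group == treated_group]
  if (!length(ct_ids) || !length(tr_ids) ||
      !any(study$group == control_group) || !any(study$group == toxin_group)) {
    stop("control, toxin and treated groups must all have study samples",
         call. = FALSE)
  }
  obs <- !is.na(table$intensities)
  obs_ct <- colMeans(obs[ct_ids, , drop = FALSE])
  obs_tr <- colMeans(obs[tr_ids, , drop = FALSE])
  flagged <- obs_ct < absence_fraction & obs_tr >= 1 - absence_fraction
  detail <- data.frame(feature_id = colnames(table$intensities),
                       obs_ct = obs_ct, obs_tr = obs_tr,
                       flagged = flagged, pcorr = NA_real_,
                       stringsAsFactors = FALSE, row.names = NULL)
  ids <- detail$feature_id[flagged]
  if (length(ids)) {
    x <- modelling_matrix(table, c(tr_ids, ct_ids))
    y <- ifelse(rownames(x) %in% tr_ids, treated_group, "CT")
    fit <- fit_oplsda(x, y, n_orth = n_orth, positive_class = treated_group)
    detail$pcorr[match(fit$s_plot$feature_id, detail$feature_id)] <-
      fit$s_plot$pcorr
    ranked <- detail[detail$flagged, , drop = FALSE]
    ids <- ranked$feature_id[order(-abs(ranked$pcorr), ranked$feature_id,
                                   na.last = TRUE)]
  }
  structure(ids, detail = detail)
}

#' Select discriminating features between two groups at one time point
#'
#' Fits an OPLS-DA between the toxin group and one other group restricted
#' to the study samples of a single day, computes VIP, and tests each
#' feature with a two-sided Mann-Whitney U test whose p-values are
#' BH-adjusted within the comparison.  A feature is a marker iff
#' `VIP > vip_threshold` and the (adjusted, by default) p-value is below
#' `p_threshold`.
#'
#' @param table A `peak_table`.
#' @param toxin_group,other_group Group labels, both sampled at `day`.
#' @param day Sampling day of the comparison.
#' @param vip_threshold VIP cutoff; default 1.0.
#' @param p_threshold Significance cutoff; default 0.05.
#' @param adjust Apply the threshold to BH-adjusted p-values (default);
#'   `FALSE` uses raw p-values.
#' @param n_orth Orthogonal components; `NULL` (default) selects by
#'   cross-validation via [choose_n_orth()].
#' @param seed Seed for the cross-validation folds.
#' @return Data frame with one row per testable feature: `feature_id`,
#'   `comparison`, `day`, `vip`, `p_raw`, `p_adj`, `selected`.
#' @export
select_biomarkers <- function(table, toxin_group, other_group, day,
                              vip_threshold = 1, p_threshold = 0.05,
                              adjust = TRUE, n_orth = NULL, seed = 1L) {
  stopifnot(inherits(table, "peak_table"))
  sm <- table$sample_meta
  sel <- sm$sample_type == "study" & sm$day == day &
    sm$group %in% c(toxin_group, other_group)
  sel[is.na(sel)] <- FALSE
  ids <- sm$sample_id[sel]
  groups <- sm$group[sel]
  if (!any(groups == toxin_group) || !any(groups == other_group)) {
    stop(sprintf("both groups must be sampled at day %s", day), call. = FALSE)
  }
  x <- modelling_matrix(table, ids)
  y <- sm$group[match(rownames(x), sm$sample_id)]
  if (is.null(n_orth)) {
    n_orth <- choose_n_orth(x, y, max_orth = 2L, seed = seed,
                            positive_class = toxin_group)$n_orth
  }
  fit <- fit_oplsda(x, y, n_orth = n_orth, positive_class = toxin_group)
  vip <- fit$vip

  # rank tests run on the detection-limit-filled values so that censored
  # observations rank lowest (dropping them would discard exactly the
  # most informative measurements of a down-regulated feature); the exact
  # null distribution is used whenever a feature is tie-free, since the
  # FDR step depends on the deep tail the normal approximation truncates
  filled <- fill_missing(pt_subset(table, samples = ids))
  ints <- filled$intensities[, names(vip), drop = FALSE]
  tox_rows <- filled$sample_meta$group == toxin_group
  p_raw <- vapply(names(vip), function(j) {
    a <- ints[tox_rows, j]
    b <- ints[!tox_rows, j]
    mode <- if (anyDuplicated(c(a, b))) "approx" else "exact"
    mann_whitney(a, b, mode = mode)$p_value
  }, numeric(1))
  ok <- !is.na(p_raw)
  p_adj <- rep(NA_real_, length(p_raw))
  p_adj[ok] <- bh_fdr(p_raw[ok])
  p_use <- if (adjust) p_adj else p_raw
  selected <- ok & vip > vip_threshold & p_use < p_threshold
  data.frame(feature_id = names(vip),
             comparison = paste(toxin_group, "vs", other_group),
             day = day, vip = unname(vip), p_raw = unname(p_raw),
             p_adj = unname(p_adj), selected = unname(selected),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Union of per-comparison biomarker records
#'
#' Combines marker records from all comparisons and days into a single
#' biomarker set: the set union of selected ids, with every record's
#' evidence retained.
#'
#' @param records A data frame from [select_biomarkers()] or a list of
#'   them.
#' @return An object of class `biomarker_set` with `features` (sorted
#'   unique selected ids) and `evidence` (all records).
#' @export
union_biomarkers <- function(records) {
  if (is.data.frame(records)) records <- list(records)
  if (!length(records)) stop("at least one record set is required", call. = FALSE)
  evidence <- do.call(rbind, records)
  rownames(evidence) <- NULL
  structure(
    list(features = sort(unique(evidence$feature_id[evidence$selected])),
         evidence = evidence),
    class = "biomarker_set"
  )
}

#' @export
print.biomarker_set <- function(x, ...) {
  cat(sprintf("biomarker_set: %d selected features from %d comparison records\n",
              length(x$features), nrow(x$evidence)))
  if (!is.null(x$spearman)) {
    cat(sprintf("  Spearman filter applied: %d retained\n",
                sum(x$spearman$retained)))
  }
  invisible(x)
}

#' Phenotype-anchored Spearman filter
#'
#' For each selected marker, correlates its per-sample intensity with the
#' matched animal's same-day diarrhea score and relative body weight
#' (Spearman, average ranks).  A marker is retained iff `|rho| >= cutoff`
#' against at least one phenotype.
#'
#' @param set A `biomarker_set`.
#' @param table The `peak_table` the markers refer to.
#' @param phenotypes Data frame with `animal_id`, `day`, `ds`, `rbw`.
#' @param cutoff Correlation magnitude cutoff; default 0.5.
#' @return The filtered `biomarker_set`, with a `spearman` data frame
#'   (`feature_id`, `rho_ds`, `rho_rbw`, `retained`) and the pre-filter ids
#'   in `features_prefilter`.
#' @export
spearman_filter <- function(set, table, phenotypes, cutoff = 0.5) {
  stopifnot(inherits(set, "biomarker_set"), inherits(table, "peak_table"))
  stop_if_not_scalar_number(cutoff, "cutoff", lower = 0, upper = 1)
  if (!all(c("animal_id", "day", "ds", "rbw") %in% names(phenotypes))) {
    stop("`phenotypes` must have columns animal_id, day, ds, rbw", call. = FALSE)
  }
  sm <- table$sample_meta
  study <- sm[sm$sample_type == "study", , drop = FALSE]
  key_s <- paste(study$animal_id, study$day)
  key_p <- paste(phenotypes$animal_id, phenotypes$day)
  hit <- match(key_s, key_p)
  if (!any(!is.na(hit))) stop("no matched animal-days", call. = FALSE)
  matched <- !is.na(hit)
  ds <- phenotypes$ds[hit[matched]]
  rbw <- phenotypes$rbw[hit[matched]]
  rows <- study$sample_id[matched]

  rho1 <- function(v, ph) {
    ok <- !is.na(v)
    if (sum(ok) < 3L || stats::sd(v[ok]) == 0 || stats::sd(ph[ok]) == 0) {
      return(NA_real_)
    }
    spearman_rho(v[ok], ph[ok])
  }
  res <- do.call(rbind, lapply(set$features, function(j) {
    v <- table$intensities[rows, j]
    data.frame(feature_id = j, rho_ds = rho1(v, ds), rho_rbw = rho1(v, rbw),
               stringsAsFactors = FALSE)
  }))
  if (is.null(res)) {
    res <- data.frame(feature_id = character(), rho_ds = numeric(),
                      rho_rbw = numeric(), stringsAsFactors = FALSE)
  }
  keep_ds <- !is.na(res$rho_ds) & abs(res$rho_ds) >= cutoff
  keep_rbw <- !is.na(res$rho_rbw) & abs(res$rho_rbw) >= cutoff
  res$retained <- keep_ds | keep_rbw
  set$features_prefilter <- set$features
  set$features <- res$feature_id[res$retained]
  set$spearman <- res
  set
}
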