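# End-to-end orchestration: per-platform preprocessing, feature-wise merge
# of the platform matrices, exogenous removal, biomarker screening,
# trajectory, MDS and RAUC, with every intermediate written to CSV and a
# manifest recording config fingerprint, seed and stage dimensions.

#' Pipeline configuration
#'
#' Collects every tunable of the pipeline with validated defaults.  Where a
#' published convention exists (VIP > 1, p < 0.05, QC RSD 15%, Spearman
#' cutoff 0.5, RAUC window days 4-10) it is the default; the remaining
#' defaults are the package's documented choices.
#'
#' @param design A [study_design()] used when the pipeline simulates its
#'   input.
#' @param perturbation A [perturbation_spec()] for simulation.
#' @param seed Integer master seed; all randomness (generation and
#'   cross-validation folds) derives from it.
#' @param background_min_ratio Study/blank mean ratio for
#'   [filter_background()].
#' @param rule80_fraction Detection fraction for [apply_80_rule()].
#' @param qc_max_rsd QC RSD bound for [qc_rsd_filter()].
#' @param fusion_enabled,fusion_min_correlation Ion fusion switch and
#'   threshold for [fuse_ions()].
#' @param vip_threshold,p_threshold,adjust_p Selection thresholds for
#'   [select_biomarkers()].
#' @param spearman_cutoff Phenotype correlation cutoff for
#'   [spearman_filter()].
#' @param absence_fraction Absence quantification for
#'   [detect_exogenous()].
#' @param pc_var_target Variance fraction defining the reduced space of
#'   the principal curve.
#' @param curve_span,curve_tol,curve_max_iter Principal-curve smoother
#'   span, stopping tolerance and iteration cap.
#' @param rauc_window Two-element day window (inclusive) for the RAUC
#'   statistic.
#' @param rauc_scale `"log2"` or `"fc_minus_1"` relative level.
#' @param rauc_alpha Unadjusted significance level for re-regulation.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(design = study_design(),
                            perturbation = perturbation_spec(),
                            seed = 1L,
                            background_min_ratio = 3,
                            rule80_fraction = 0.8,
                            qc_max_rsd = 0.15,
                            fusion_enabled = FALSE,
                            fusion_min_correlation = 0.9,
                            vip_threshold = 1,
                            p_threshold = 0.05,
                            adjust_p = TRUE,
                            spearman_cutoff = 0.5,
                            absence_fraction = 0.1,
                            pc_var_target = 0.85,
                            curve_span = 0.3,
                            curve_tol = 1e-3,
                            curve_max_iter = 50L,
                            rauc_window = c(4, 10),
                            rauc_scale = "log2",
                            rauc_alpha = 0.05) {
  stopifnot(inherits(design, "study_design"),
            inherits(perturbation, "perturbation_spec"))
  stop_if_not_scalar_number(rule80_fraction, "rule80_fraction", 0, 1)
  stop_if_not_scalar_number(qc_max_rsd, "qc_max_rsd", 0, 10)
  stop_if_not_scalar_number(vip_threshold, "vip_threshold", 0)
  stop_if_not_scalar_number(p_threshold, "p_threshold", 0, 1)
  stop_if_not_scalar_number(spearman_cutoff, "spearman_cutoff", 0, 1)
  stop_if_not_scalar_number(pc_var_target, "pc_var_target", 0.1, 1)
  if (length(rauc_window) != 2L || rauc_window[1] >= rauc_window[2]) {
    stop("`rauc_window` must be an increasing pair of days", call. = FALSE)
  }
  if (!any(design$days >= rauc_window[1] & design$days <= rauc_window[2])) {
    stop("`rauc_window` covers no sampling day", call. = FALSE)
  }
  structure(
    list(design = design, perturbation = perturbation, seed = as.integer(seed),
         background_min_ratio = background_min_ratio,
         rule80_fraction = rule80_fraction, qc_max_rsd = qc_max_rsd,
         fusion_enabled = isTRUE(fusion_enabled),
         fusion_min_correlation = fusion_min_correlation,
         vip_threshold = vip_threshold, p_threshold = p_threshold,
         adjust_p = isTRUE(adjust_p), spearman_cutoff = spearman_cutoff,
         absence_fraction = absence_fraction, pc_var_target = pc_var_target,
         curve_span = curve_span, curve_tol = curve_tol,
         curve_max_iter = as.integer(curve_max_iter),
         rauc_window = as.numeric(rauc_window), rauc_scale = rauc_scale,
         rauc_alpha = rauc_alpha),
    class = "pipeline_config"
  )
}

config_fingerprint <- function(config) {
  fnv1a32(jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA,
                           force = TRUE))
}

#' Preprocess a raw peak table
#'
#' Runs the filter chain per platform (background filter, 80% rule, QC RSD
#' filter, total-ion-intensity normalization, optional ion fusion) and
#' merges the platform matrices feature-wise.  Normalization is
#' per-platform because total ion intensity is platform-specific.  Blank
#' samples are dropped after the background filter (they have served their
#' purpose and carry no retained features).
#'
#' @param table Raw `peak_table` with `platform` feature metadata.
#' @param config A `pipeline_config`.
#' @return A list with `table` (merged, normalized) and `report` (stacked
#'   filter reports, stage names prefixed by platform).
#' @export
preprocess_table <- function(table, config = pipeline_config()) {
  stopifnot(inherits(table, "peak_table"))
  platforms <- unique(table$feature_meta$platform)
  sample_order <- table$sample_meta$sample_id
  keep_samples <- sample_order[table$sample_meta$sample_type != "blank"]
  parts <- list(); reports <- list()
  for (pf in platforms) {
    fids <- table$feature_meta$feature_id[table$feature_meta$platform == pf]
    sub <- pt_subset(table, features = fids)
    bg <- filter_background(sub, config$background_min_ratio)
    r80 <- apply_80_rule(bg$table, config$rule80_fraction)
    qc <- qc_rsd_filter(r80$table, config$qc_max_rsd)
    cleaned <- pt_subset(qc$table, samples = keep_samples)
    cleaned <- normalize_total_intensity(cleaned)
    rep_pf <- rbind(bg$report, r80$report, qc$report)
    if (config$fusion_enabled) {
      fu <- fuse_ions(cleaned, min_correlation = config$fusion_min_correlation)
      cleaned <- fu$table
      rep_pf <- rbind(rep_pf, fu$report)
    }
    rep_pf$stage <- paste(pf, rep_pf$stage, sep = ".")
    parts[[pf]] <- cleaned
    reports[[pf]] <- rep_pf
  }
  # feature-wise merge; all parts share the same sample rows by construction
  ints <- do.call(cbind, lapply(parts, function(p) {
    p$intensities[keep_samples, , drop = FALSE]
  }))
  fm <- do.call(rbind, lapply(parts, function(p) p$feature_meta))
  rownames(fm) <- NULL
  sm <- table$sample_meta[match(keep_samples, table$sample_meta$sample_id), ,
                          drop = FALSE]
  merged <- peak_table(ints, sm, fm)
  list(table = merged, report = do.call(rbind, c(reports, make.row.names = FALSE)))
}

write_pipeline_csv <- function(df, outdir, name) {
  utils::write.csv(df, file.path(outdir, name), row.names = FALSE, na = "")
}

#' Run the full evaluation pipeline
#'
#' Executes the complete scheme: (simulate or accept a study) -> per-
#' platform preprocessing and merge -> exogenous-feature removal ->
#' per-day biomarker selection and Spearman filter -> PCA trajectory ->
#' principal-curve MDS with per-animal AUCs -> RAUC with re-regulation
#' calls.  Every intermediate table is written as CSV into `outdir`
#' together with a `manifest.json`; identical config and seed reproduce
#' all outputs.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory (created if needed).
#' @param study Optional study (as from [generate_study()] or
#'   [read_study()]); when `NULL` a study is simulated from the config's
#'   design, perturbation spec and seed.
#' @return Invisibly, a list with every intermediate object (`study`,
#'   `preprocessed`, `exogenous`, `markers`, `pca`, `trajectory`, `curve`,
#'   `mds`, `mds_auc`, `rauc`, `common`, `manifest`).
#' @export
run_pipeline <- function(config = pipeline_config(), outdir, study = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  design <- config$design
  stage <- "simulate"
  result <- tryCatch({
    if (is.null(study)) {
      study <- generate_study(design, config$perturbation, config$seed)
      write_study(study, file.path(outdir, "input"))
    }
    table_raw <- study$table
    phenotype <- study$phenotype

    stage <- "preprocess"
    pp <- preprocess_table(table_raw, config)
    write_pipeline_csv(pp$report, outdir, "filter_report.csv")
    tab <- pp$table

    stage <- "exogenous_removal"
    treated <- setdiff(design$groups, c(design$control_group, design$toxin_group))
    exo_by_group <- lapply(treated, function(g) {
      detect_exogenous(tab, g, design$control_group, design$toxin_group,
                       config$absence_fraction)
    })
    names(exo_by_group) <- treated
    exo_ids <- sort(unique(unlist(lapply(exo_by_group, as.character))))
    exo_df <- do.call(rbind, lapply(treated, function(g) {
      ids <- as.character(exo_by_group[[g]])
      if (!length(ids)) return(NULL)
      data.frame(group = g, feature_id = ids, stringsAsFactors = FALSE)
    }))
    if (is.null(exo_df)) {
      exo_df <- data.frame(group = character(), feature_id = character())
    }
    write_pipeline_csv(exo_df, outdir, "exogenous_features.csv")
    tab_endo <- remove_features(tab, exo_ids)

    stage <- "biomarker_screen"
    others <- setdiff(design$groups, design$toxin_group)
    records <- list()
    cv_seed <- config$seed
    for (d in design$days) {
      for (g in others) {
        cv_seed <- (cv_seed + 7919L) %% 2147483647L
        records[[length(records) + 1L]] <- select_biomarkers(
          tab_endo, design$toxin_group, g, d,
          vip_threshold = config$vip_threshold,
          p_threshold = config$p_threshold,
          adjust = config$adjust_p, seed = cv_seed)
      }
    }
    markers <- union_biomarkers(records)
    write_pipeline_csv(markers$evidence, outdir, "biomarkers.csv")
    markers <- spearman_filter(markers, tab_endo, phenotype,
                               config$spearman_cutoff)
    write_pipeline_csv(markers$spearman, outdir, "spearman.csv")

    stage <- "trajectory"
    study_ids <- sample_ids_of_type(tab_endo, "study")
    x_all <- modelling_matrix(tab_endo, study_ids)
    n_comp <- min(2L, nrow(x_all) - 1L, ncol(x_all))
    pca <- fit_pca(x_all, n_components = n_comp)
    pca_q2 <- cross_validate("pca", x_all, k_folds = 7L,
                             seed = (config$seed + 104729L) %% 2147483647L,
                             n_components = n_comp)$q2
    trajectory <- compute_trajectory(pca, tab_endo$sample_meta)
    write_pipeline_csv(as.data.frame(trajectory), outdir, "trajectory.csv")

    stage <- "mds"
    mds_features <- markers$features
    if (length(mds_features) < 3L) mds_features <- markers$features_prefilter
    if (length(mds_features) < 3L) {
      stop("fewer than three biomarkers available for the MDS stage")
    }
    x_mark <- x_all[, intersect(colnames(x_all), mds_features), drop = FALSE]
    healthy <- tab_endo$sample_meta$sample_id[
      tab_endo$sample_meta$sample_type == "study" &
        tab_endo$sample_meta$group == design$control_group]
    curve <- fit_principal_curve(x_mark, healthy_ids = healthy,
                                 var_target = config$pc_var_target,
                                 span = config$curve_span,
                                 tol = config$curve_tol,
                                 max_iter = config$curve_max_iter)
    mds <- compute_mds(curve, x_mark, tab_endo$sample_meta)
    write_pipeline_csv(mds$scores, outdir, "mds.csv")
    auc <- mds_auc(mds)
    write_pipeline_csv(auc$per_animal, outdir, "mds_auc.csv")
    write_pipeline_csv(auc$tests, outdir, "mds_tests.csv")

    stage <- "rauc"
    wdays <- design$days[design$days >= config$rauc_window[1] &
                           design$days <= config$rauc_window[2]]
    # non-detects are below-detection-limit values; fill them so a
    # censored day contributes its (large) deviation instead of vanishing
    curves <- relative_curves(fill_missing(tab_endo), design$control_group,
                              intersect(colnames(tab_endo$intensities),
                                        mds_features),
                              window_days = wdays, scale = config$rauc_scale)
    rauc <- compute_rauc(curves, design$toxin_group, config$rauc_alpha)
    write_pipeline_csv(rauc$per_animal, outdir, "rauc.csv")
    write_pipeline_csv(rauc$tests, outdir, "rauc_tests.csv")
    group_sets <- default_group_sets(design)
    common <- common_reregulated(rauc, group_sets)
    write_pipeline_csv(attr(common, "table"), outdir, "rauc_common.csv")

    stage <- "manifest"
    manifest <- list(
      package_version = as.character(utils::packageVersion("metabodereg")),
      seed = config$seed,
      config_fingerprint = config_fingerprint(config),
      stages = list(
        raw = dim(table_raw$intensities),
        preprocessed = dim(tab$intensities),
        exogenous_removed = length(exo_ids),
        markers_selected = length(markers$features_prefilter),
        markers_retained = length(markers$features),
        pca_r2x = pca$r2x, pca_q2 = pca_q2,
        mds_curve_length = curve$length,
        rauc_window = wdays
      )
    )
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    list(study = study, preprocessed = pp, exogenous = exo_by_group,
         markers = markers, pca = pca, pca_q2 = pca_q2,
         trajectory = trajectory, curve = curve, mds = mds, mds_auc = auc,
         rauc = rauc, common = common, manifest = manifest)
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
  invisible(result)
}

# Group sets for the common-re-regulation intersections: all treated groups
# pairwise-anchored on the first treated group, mirroring the "formula and
# its dissections" reading; with fewer than two treated groups the stage is
# skipped gracefully.
default_group_sets <- function(design) {
  treated <- setdiff(design$groups, c(design$control_group, design$toxin_group))
  sets <- list()
  if (length(treated) >= 3L) {
    sets[[paste(treated[1:3], collapse = "&")]] <- treated[1:3]
  }
  if (length(treated) >= 4L) {
    sets[[paste(treated[c(1, 4)], collapse = "&")]] <- treated[c(1, 4)]
  }
  if (!length(sets) && length(treated) >= 2L) {
    sets[[paste(treated[1:2], collapse = "&")]] <- treated[1:2]
  }
  sets
}
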