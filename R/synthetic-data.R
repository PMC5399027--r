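# Synthetic study generator.  Emulates a six-group rodent toxicity study
# sampled over several days: a toxin perturbation of a subset of serum
# metabolites that peaks mid-course and resolves, graded attenuation of
# that perturbation in treated groups, decoction-only exogenous features,
# background (blank-visible) features, pooled-QC injections, and per-animal
# phenotype series (diarrhea score and relative body weight) driven by the
# same latent deregulation.  Full ground truth is returned so every
# downstream stage can be scored.

#' Study design for the synthetic generator
#'
#' Defaults reproduce the emulated study layout: six groups (control `C`,
#' toxin-only `T`, and four treated groups), 63 animals in total, sampled
#' at days -1, 1, 4, 7 and 10, with pooled-QC and blank injections.
#'
#' @param groups Character vector of group labels.
#' @param n_per_group Integer animal counts, one per group.
#' @param days Strictly increasing integer sampling days (may be negative).
#' @param control_group,toxin_group Labels of the control and toxin-only
#'   groups; both must occur in `groups`.
#' @param n_qc,n_blank Pooled-QC and blank injection counts.
#' @return An object of class `study_design`.
#' @export
study_design <- function(groups = c("C", "T", "T/HQD", "T/SS", "T/BB", "T/SF"),
                         n_per_group = c(10L, 11L, 12L, 10L, 10L, 10L),
                         days = c(-1L, 1L, 4L, 7L, 10L),
                         control_group = "C",
                         toxin_group = "T",
                         n_qc = 8L,
                         n_blank = 3L) {
  groups <- as.character(groups)
  n_per_group <- as.integer(n_per_group)
  days <- as.integer(days)
  if (anyDuplicated(groups)) stop("duplicate group labels", call. = FALSE)
  if (length(n_per_group) != length(groups)) {
    stop("`n_per_group` must have one count per group", call. = FALSE)
  }
  if (any(n_per_group < 1L) || n_qc < 1L || n_blank < 1L) {
    stop("all counts must be at least 1", call. = FALSE)
  }
  if (length(days) < 2L || any(diff(days) <= 0L)) {
    stop("`days` must be strictly increasing with at least two entries", call. = FALSE)
  }
  if (!control_group %in% groups || !toxin_group %in% groups ||
      control_group == toxin_group) {
    stop("`groups` must contain one control and one distinct toxin-only label",
         call. = FALSE)
  }
  structure(
    list(groups = groups, n_per_group = stats::setNames(n_per_group, groups),
         days = days, control_group = control_group, toxin_group = toxin_group,
         n_qc = as.integer(n_qc), n_blank = as.integer(n_blank)),
    class = "study_design"
  )
}

#' Perturbation specification for the synthetic generator
#'
#' Controls the planted signal.  The toxin shifts `n_perturbed` features on
#' the log2 scale by `sign * delta_j * effect_profile[day] *
#' group_attenuation[group]`, where `delta_j` is the per-feature peak
#' magnitude.  The default profile peaks at day 4 and is resolved by day
#' 10; the default attenuations grade the four treated groups between
#' control (0) and toxin-only (1).
#'
#' @param n_features_total Total feature count.
#' @param n_perturbed Number of toxin-responsive features.
#' @param effect_profile Named per-day multiplier (dimensionless, 0 at the
#'   baseline day, peak 1).
#' @param group_attenuation Named per-group factor in \[0, 1\]; must be 0
#'   for the control group and 1 for the toxin-only group.
#' @param effect_size Peak log2 shift in the toxin-only group.
#' @param effect_size_jitter Relative half-range of per-feature magnitudes:
#'   `delta_j ~ Uniform(effect_size * (1 - j), effect_size * (1 + j))`.
#' @param n_exogenous_per_group Decoction-only features planted per treated
#'   group (observed in that group only).
#' @param n_background Features also present in blank injections.
#' @param noise_sd Residual log2 standard deviation.
#' @param animal_sd Per-animal-by-feature random intercept SD (log2).
#' @param qc_noise_sd Log2 SD of QC replicate noise.
#' @param missing_rate Per-feature fraction of lowest study intensities
#'   recorded as missing (left-censoring).
#' @param ds_noise_sd,rbw_noise_sd Phenotype noise SDs (score units, %).
#' @param rbw_growth_per_day Baseline body-weight growth (% per day).
#' @param rbw_max_loss Peak body-weight loss (%) at full deregulation.
#' @return An object of class `perturbation_spec`.
#' @export
perturbation_spec <- function(n_features_total = 150L,
                              n_perturbed = 40L,
                              effect_profile = c("-1" = 0, "1" = 0.6, "4" = 1,
                                                 "7" = 0.25, "10" = 0.05),
                              group_attenuation = c("C" = 0, "T" = 1,
                                                    "T/HQD" = 0.25, "T/SS" = 0.35,
                                                    "T/BB" = 0.5, "T/SF" = 0.75),
                              effect_size = 1.5,
                              effect_size_jitter = 0.5,
                              n_exogenous_per_group = 8L,
                              n_background = 10L,
                              noise_sd = 0.4,
                              animal_sd = 0.15,
                              qc_noise_sd = 0.05,
                              missing_rate = 0.05,
                              ds_noise_sd = 0.25,
                              rbw_noise_sd = 2,
                              rbw_growth_per_day = 1.2,
                              rbw_max_loss = 35) {
  stop_if_not_scalar_number(n_features_total, "n_features_total", lower = 1)
  stop_if_not_scalar_number(n_perturbed, "n_perturbed", lower = 0)
  if (n_perturbed > n_features_total) {
    stop("`n_perturbed` cannot exceed `n_features_total`", call. = FALSE)
  }
  if (any(group_attenuation < 0) || any(group_attenuation > 1)) {
    stop("`group_attenuation` must lie in [0, 1]", call. = FALSE)
  }
  stop_if_not_scalar_number(noise_sd, "noise_sd", lower = 1e-12)
  stop_if_not_scalar_number(missing_rate, "missing_rate", lower = 0, upper = 0.999)
  stop_if_not_scalar_number(effect_size_jitter, "effect_size_jitter",
                            lower = 0, upper = 1)
  structure(
    list(n_features_total = as.integer(n_features_total),
         n_perturbed = as.integer(n_perturbed),
         effect_profile = effect_profile,
         group_attenuation = group_attenuation,
         effect_size = effect_size,
         effect_size_jitter = effect_size_jitter,
         n_exogenous_per_group = as.integer(n_exogenous_per_group),
         n_background = as.integer(n_background),
         noise_sd = noise_sd, animal_sd = animal_sd,
         qc_noise_sd = qc_noise_sd, missing_rate = missing_rate,
         ds_noise_sd = ds_noise_sd, rbw_noise_sd = rbw_noise_sd,
         rbw_growth_per_day = rbw_growth_per_day, rbw_max_loss = rbw_max_loss),
    class = "perturbation_spec"
  )
}

check_spec_against_design <- function(design, spec) {
  if (!all(as.character(design$days) %in% names(spec$effect_profile))) {
    stop("`effect_profile` must name every sampling day", call. = FALSE)
  }
  if (!all(design$groups %in% names(spec$group_attenuation))) {
    stop("`group_attenuation` must name every group", call. = FALSE)
  }
  if (spec$group_attenuation[[design$control_group]] != 0) {
    stop("attenuation of the control group must be 0", call. = FALSE)
  }
  if (spec$group_attenuation[[design$toxin_group]] != 1) {
    stop("attenuation of the toxin-only group must be 1", call. = FALSE)
  }
  baseline <- as.character(design$days[1])
  if (spec$effect_profile[[baseline]] != 0) {
    stop("`effect_profile` must be 0 at the baseline day", call. = FALSE)
  }
  treated <- setdiff(design$groups, c(design$control_group, design$toxin_group))
  need <- spec$n_background + spec$n_perturbed +
    spec$n_exogenous_per_group * length(treated)
  if (need > spec$n_features_total) {
    stop("background + perturbed + exogenous features exceed `n_features_total`",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Generate a synthetic study
#'
#' Draws a complete study — peak table (study samples, pooled QCs, blanks),
#' phenotype series, and ground truth — from the generative model described
#' in [perturbation_spec()].  Identical seeds reproduce the output
#' bit-for-bit.
#'
#' @param design A [study_design()].
#' @param spec A [perturbation_spec()].
#' @param seed Integer seed for the single RNG stream.
#' @return A list of class `synthetic_study` with elements `table`
#'   (a [peak_table()]), `phenotype` (data frame `animal_id`, `day`, `ds`,
#'   `rbw`), and `truth` (perturbed ids with signed log2 peak effects,
#'   exogenous ids per treated group, background ids, per-sample latent
#'   deregulation).
#' @export
generate_study <- function(design, spec = perturbation_spec(), seed = 1L) {
  stopifnot(inherits(design, "study_design"), inherits(spec, "perturbation_spec"))
  check_spec_against_design(design, spec)
  with_seed(seed, {
    p <- spec$n_features_total
    feature_ids <- sprintf("F%03d", seq_len(p))
    treated <- setdiff(design$groups, c(design$control_group, design$toxin_group))

    pool <- sample(feature_ids)  # one shuffle assigns all special roles
    take <- function(n) {
      if (n == 0L) return(character(0))
      out <- pool[seq_len(n)]
      pool <<- pool[-seq_len(n)]
      out
    }
    background_ids <- sort(take(spec$n_background))
    exogenous_ids <- stats::setNames(
      lapply(treated, function(g) sort(take(spec$n_exogenous_per_group))), treated)
    perturbed_ids <- sort(take(spec$n_perturbed))

    platform <- sample(c("lcms_pos", "lcms_neg", "gcms"), p, replace = TRUE,
                       prob = c(0.375, 0.375, 0.25))
    # post-detection peak tables have a compressed dynamic range (faint
    # peaks never make it past detection); log-normal around 2^14 counts
    base_log2 <- stats::rnorm(p, 14, 0.8)
    # dosed decoction constituents circulate well above the detection
    # limit (that visibility is why they must be removed)
    exo_all <- unlist(exogenous_ids, use.names = FALSE)
    base_log2[match(exo_all, feature_ids)] <-
      stats::rnorm(length(exo_all), 15, 0.5)
    names(base_log2) <- feature_ids
    delta <- stats::setNames(numeric(p), feature_ids)
    jit <- spec$effect_size_jitter
    delta[perturbed_ids] <-
      sample(c(-1, 1), length(perturbed_ids), replace = TRUE) *
      stats::runif(length(perturbed_ids),
                   spec$effect_size * (1 - jit), spec$effect_size * (1 + jit))

    # sample sheet ------------------------------------------------------
    animals <- unlist(lapply(design$groups, function(g) {
      sprintf("%s_a%02d", gsub("/", "", g), seq_len(design$n_per_group[[g]]))
    }))
    animal_group <- rep(design$groups, design$n_per_group)
    names(animal_group) <- animals
    sm <- expand.grid(animal_id = animals, day = design$days,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    sm <- sm[order(match(sm$animal_id, animals), sm$day), ]
    sm$group <- animal_group[sm$animal_id]
    sm$sample_type <- "study"
    sm$sample_id <- sprintf("S%03d", seq_len(nrow(sm)))
    n_study <- nrow(sm)

    dereg <- spec$group_attenuation[sm$group] *
      spec$effect_profile[as.character(sm$day)]
    names(dereg) <- sm$sample_id

    # study intensities (log2) ------------------------------------------
    animal_fx <- matrix(stats::rnorm(length(animals) * p, 0, spec$animal_sd),
                        nrow = length(animals), ncol = p,
                        dimnames = list(animals, feature_ids))
    log2x <- matrix(rep(base_log2, each = n_study), nrow = n_study,
                    dimnames = list(sm$sample_id, feature_ids))
    log2x <- log2x + animal_fx[sm$animal_id, , drop = FALSE]
    log2x <- log2x + outer(dereg, delta)
    log2x <- log2x + matrix(stats::rnorm(n_study * p, 0, spec$noise_sd),
                            nrow = n_study)
    ints <- 2^log2x

    # exogenous features: observed only in their treated group ----------
    for (g in treated) {
      out_rows <- sm$sample_id[sm$group != g]
      ints[out_rows, exogenous_ids[[g]]] <- NA_real_
    }

    # left-censoring below a global detection threshold: overall
    # `missing_rate` of study values fall under it, concentrated in the
    # low-abundance features (high-abundance peaks lose nothing)
    if (spec$missing_rate > 0) {
      thr <- stats::quantile(ints, spec$missing_rate, na.rm = TRUE, names = FALSE)
      ints[!is.na(ints) & ints < thr] <- NA_real_
    }

    # QCs: pooled aliquot of all study samples (absent peaks pool as 0)
    pool_mean <- colMeans(replace(ints, is.na(ints), 0))
    qc_ids <- sprintf("QC%02d", seq_len(design$n_qc))
    qc <- t(vapply(qc_ids, function(id) {
      pool_mean * 2^stats::rnorm(p, 0, spec$qc_noise_sd)
    }, numeric(p)))
    rownames(qc) <- qc_ids

    # blanks: background features only ----------------------------------
    blank_ids <- sprintf("BL%02d", seq_len(design$n_blank))
    blank <- matrix(NA_real_, nrow = design$n_blank, ncol = p,
                    dimnames = list(blank_ids, feature_ids))
    for (id in blank_ids) {
      blank[id, background_ids] <-
        2^(base_log2[background_ids] + stats::rnorm(length(background_ids), 0,
                                                    spec$noise_sd))
    }

    all_ints <- rbind(ints, qc, blank)
    sample_meta <- rbind(
      sm[, c("sample_id", "group", "animal_id", "day", "sample_type")],
      data.frame(sample_id = qc_ids, group = "QC", animal_id = NA_character_,
                 day = NA_integer_, sample_type = "qc",
                 stringsAsFactors = FALSE),
      data.frame(sample_id = blank_ids, group = "BLANK",
                 animal_id = NA_character_, day = NA_integer_,
                 sample_type = "blank", stringsAsFactors = FALSE)
    )
    feature_meta <- data.frame(feature_id = feature_ids, platform = platform,
                               is_background = feature_ids %in% background_ids,
                               stringsAsFactors = FALSE)
    table <- peak_table(all_ints, sample_meta, feature_meta)

    # phenotype series ----------------------------------------------------
    ph <- sm[, c("animal_id", "day", "group")]
    d <- spec$group_attenuation[ph$group] * spec$effect_profile[as.character(ph$day)]
    ph$ds <- clamp(3 * d + stats::rnorm(nrow(ph), 0, spec$ds_noise_sd), 0, 3)
    ph$rbw <- 100 + spec$rbw_growth_per_day * (ph$day - design$days[1]) -
      spec$rbw_max_loss * d + stats::rnorm(nrow(ph), 0, spec$rbw_noise_sd)
    phenotype <- ph[, c("animal_id", "day", "ds", "rbw")]
    rownames(phenotype) <- NULL

    truth <- list(
      perturbed = data.frame(feature_id = perturbed_ids,
                             delta_log2 = unname(delta[perturbed_ids]),
                             stringsAsFactors = FALSE),
      exogenous = exogenous_ids,
      background = background_ids,
      deregulation = data.frame(sample_id = sm$sample_id, group = sm$group,
                                day = sm$day, deregulation = unname(dereg),
                                stringsAsFactors = FALSE)
    )
    structure(list(table = table, phenotype = phenotype, truth = truth,
                   design = design, spec = spec, seed = as.integer(seed)),
              class = "synthetic_study")
  })
}

#' Write a synthetic study to CSV files
#'
#' Serializes the peak table (`intensities.csv`, `samples.csv`,
#' `features.csv`), phenotype series (`phenotype.csv`) and ground truth
#' (`truth.json`) into a directory.  Missing intensities are written as
#' empty fields, never as zeros.
#'
#' @param study A `synthetic_study` (or a list with `table`, `phenotype`,
#'   `truth`).
#' @param directory Output directory; created if absent.
#' @return Invisibly, the named vector of file paths.
#' @export
write_study <- function(study, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  tab <- study$table
  stopifnot(inherits(tab, "peak_table"))
  paths <- c(
    intensities = file.path(directory, "intensities.csv"),
    samples = file.path(directory, "samples.csv"),
    features = file.path(directory, "features.csv"),
    phenotype = file.path(directory, "phenotype.csv"),
    truth = file.path(directory, "truth.json")
  )
  ints <- data.frame(sample_id = rownames(tab$intensities),
                     tab$intensities, check.names = FALSE,
                     stringsAsFactors = FALSE)
  utils::write.csv(ints, paths[["intensities"]], row.names = FALSE, na = "")
  utils::write.csv(tab$sample_meta, paths[["samples"]], row.names = FALSE, na = "")
  utils::write.csv(tab$feature_meta, paths[["features"]], row.names = FALSE, na = "")
  utils::write.csv(study$phenotype, paths[["phenotype"]], row.names = FALSE, na = "")
  jsonlite::write_json(study$truth, paths[["truth"]], digits = NA,
                       auto_unbox = FALSE, pretty = TRUE)
  invisible(paths)
}

#' Read a study written by [write_study()]
#'
#' Round-trips the CSV/JSON serialization: empty intensity fields are read
#' back as missing values, not zeros, and metadata types are restored.
#'
#' @param directory Directory containing the study files.
#' @return A list with `table`, `phenotype` and (if present) `truth`.
#' @export
read_study <- function(directory) {
  read1 <- function(name) {
    path <- file.path(directory, name)
    if (!file.exists(path)) stop("missing file: ", path, call. = FALSE)
    cols <- switch(name,
      "samples.csv" = c(sample_id = "character", group = "character",
                        animal_id = "character", day = "integer",
                        sample_type = "character"),
      "features.csv" = c(feature_id = "character", platform = "character"),
      "phenotype.csv" = c(animal_id = "character", day = "integer",
                          ds = "numeric", rbw = "numeric"),
      NA)
    utils::read.csv(path, check.names = FALSE, na.strings = "",
                    stringsAsFactors = FALSE, colClasses = cols)
  }
  ints_df <- read1("intensities.csv")
  if (names(ints_df)[1] != "sample_id") {
    stop("malformed intensities.csv: first column must be sample_id", call. = FALSE)
  }
  if (anyDuplicated(ints_df$sample_id)) {
    stop("duplicated sample id in intensities.csv", call. = FALSE)
  }
  ints <- as.matrix(ints_df[, -1, drop = FALSE])
  storage.mode(ints) <- "double"
  rownames(ints) <- ints_df$sample_id
  sm <- read1("samples.csv")
  sm$animal_id <- as.character(sm$animal_id)
  fm <- read1("features.csv")
  table <- peak_table(ints, sm, fm)
  phenotype <- read1("phenotype.csv")
  truth_path <- file.path(directory, "truth.json")
  truth <- if (file.exists(truth_path)) {
    jsonlite::read_json(truth_path, simplifyVector = TRUE)
  }
  list(table = table, phenotype = phenotype, truth = truth)
}
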