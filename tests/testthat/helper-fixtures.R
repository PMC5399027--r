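# Fixtures built in code: small hand-made peak tables and scaled-down
# synthetic study settings shared across test files.

# A tiny peak table with explicit study / QC / blank samples.  `values` is
# a samples x features matrix (may contain NA); groups default to two
# study groups of equal size.
make_toy_table <- function(values, groups = NULL, days = NULL,
                           qc = NULL, blank = NULL, platform = "lcms_pos") {
  n <- nrow(values)
  if (is.null(groups)) groups <- rep(c("A", "B"), length.out = n)
  if (is.null(days)) days <- rep(1L, n)
  ids <- sprintf("S%02d", seq_len(n))
  rownames(values) <- ids
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("F%02d", seq_len(ncol(values)))
  }
  sm <- data.frame(sample_id = ids, group = groups,
                   animal_id = sprintf("a%02d", seq_len(n)),
                   day = days, sample_type = "study",
                   stringsAsFactors = FALSE)
  mat <- values
  if (!is.null(qc)) {
    qids <- sprintf("QC%02d", seq_len(nrow(qc)))
    rownames(qc) <- qids
    colnames(qc) <- colnames(values)
    mat <- rbind(mat, qc)
    sm <- rbind(sm, data.frame(sample_id = qids, group = "QC",
                               animal_id = NA, day = NA,
                               sample_type = "qc", stringsAsFactors = FALSE))
  }
  if (!is.null(blank)) {
    bids <- sprintf("BL%02d", seq_len(nrow(blank)))
    rownames(blank) <- bids
    colnames(blank) <- colnames(values)
    mat <- rbind(mat, blank)
    sm <- rbind(sm, data.frame(sample_id = bids, group = "BLANK",
                               animal_id = NA, day = NA,
                               sample_type = "blank", stringsAsFactors = FALSE))
  }
  fm <- data.frame(feature_id = colnames(values), platform = platform,
                   stringsAsFactors = FALSE)
  peak_table(mat, sm, fm)
}

# Scaled-down six-group study: full group structure, fewer animals and
# features, for tests that need the whole design quickly.
small_design <- function(n = 5L) {
  study_design(n_per_group = rep(n, 6L), n_qc = 4L, n_blank = 2L)
}

small_spec <- function(...) {
  perturbation_spec(n_features_total = 40L, n_perturbed = 12L,
                    n_exogenous_per_group = 3L, n_background = 5L, ...)
}

# Two-group (control vs toxin) study at the stated recovery conditions:
# n = 10 per group, effects at 1.5 noise SDs, no exogenous features.
recovery_design <- function() {
  study_design(groups = c("C", "T"), n_per_group = c(10L, 10L),
               n_qc = 3L, n_blank = 2L)
}

recovery_spec <- function(effect = 0.6, ...) {
  perturbation_spec(n_features_total = 80L, n_perturbed = 20L,
                    effect_size = effect, effect_size_jitter = 0,
                    n_exogenous_per_group = 0L, n_background = 5L, ...)
}
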