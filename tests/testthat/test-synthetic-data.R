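# The study generator: structure, determinism, planted-signal fidelity,
# serialization round trips.

test_that("the default design yields the emulated study layout", {
  st <- generate_study(study_design(), small_spec(), seed = 3)
  sm <- st$table$sample_meta
  study <- sm[sm$sample_type == "study", ]
  # 63 animals, one sample per animal per day
  expect_equal(sum(table(study$day)[1] == table(study$day)), 5)
  expect_true(all(table(study$day) == 63))
  expect_equal(nrow(study), 63 * 5)
  expect_equal(unname(table(study$group)[c("C", "T", "T/HQD", "T/SS", "T/BB", "T/SF")]),
               c(10, 11, 12, 10, 10, 10) * 5, ignore_attr = TRUE)
  expect_equal(sum(sm$sample_type == "qc"), 8)
  expect_equal(sum(sm$sample_type == "blank"), 3)
  # phenotype covers every animal-day
  expect_equal(nrow(st$phenotype), 63 * 5)
  expect_true(all(st$phenotype$ds >= 0 & st$phenotype$ds <= 3))
  expect_true(all(st$phenotype$rbw > 0))
})

test_that("generation is bit-for-bit reproducible per seed and leaves the RNG alone", {
  set.seed(123)
  before <- rnorm(1)
  set.seed(123)
  a <- generate_study(small_design(), small_spec(), seed = 9)
  after <- rnorm(1)
  b <- generate_study(small_design(), small_spec(), seed = 9)
  c <- generate_study(small_design(), small_spec(), seed = 10)
  expect_identical(a, b)
  expect_false(identical(a$table$intensities, c$table$intensities))
  expect_equal(before, after)  # generator did not consume the caller's stream
})

test_that("structural invariants hold: positivity, exogenous absence, blanks, QC stability", {
  st <- generate_study(small_design(), small_spec(), seed = 5)
  ints <- st$table$intensities
  expect_true(all(ints[!is.na(ints)] > 0))
  sm <- st$table$sample_meta
  # exogenous features missing outside their own treated group
  for (g in names(st$truth$exogenous)) {
    out_rows <- sm$sample_id[sm$sample_type == "study" & sm$group != g]
    in_rows <- sm$sample_id[sm$sample_type == "study" & sm$group == g]
    block_out <- ints[out_rows, st$truth$exogenous[[g]], drop = FALSE]
    expect_true(all(is.na(block_out)))
    expect_gt(mean(!is.na(ints[in_rows, st$truth$exogenous[[g]]])), 0.9)
  }
  # role id sets are disjoint
  ids <- c(st$truth$perturbed$feature_id, unlist(st$truth$exogenous),
           st$truth$background)
  expect_equal(anyDuplicated(ids), 0L)
  # blanks carry only background features
  bl <- ints[sm$sample_id[sm$sample_type == "blank"], , drop = FALSE]
  non_bg <- setdiff(colnames(ints), st$truth$background)
  expect_true(all(is.na(bl[, non_bg])))
  expect_true(all(!is.na(bl[, st$truth$background])))
  # QC RSD per feature stays below the default QC filter bound
  qc <- ints[sm$sample_id[sm$sample_type == "qc"], , drop = FALSE]
  rsd <- apply(qc, 2, sd) / colMeans(qc)
  expect_true(all(rsd < 0.15))
  # deregulation is zero for every control sample
  dg <- st$truth$deregulation
  expect_true(all(dg$deregulation[dg$group == "C"] == 0))
})

test_that("observed day-4 log2 fold change recovers the planted effect", {
  des <- recovery_design()
  sp <- recovery_spec(missing_rate = 0)
  st <- generate_study(des, sp, seed = 17)
  sm <- st$table$sample_meta
  iT <- sm$sample_id[sm$sample_type == "study" & sm$group == "T" & sm$day == 4]
  iC <- sm$sample_id[sm$sample_type == "study" & sm$group == "C" & sm$day == 4]
  tr <- st$truth$perturbed
  lfc <- vapply(tr$feature_id, function(j) {
    mean(log2(st$table$intensities[iT, j])) -
      mean(log2(st$table$intensities[iC, j]))
  }, numeric(1))
  resid <- lfc - tr$delta_log2
  # Monte-Carlo error of a 10-vs-10 mean difference at noise sd ~0.43
  expect_lt(abs(mean(resid)), 0.12)
  expect_lt(max(abs(resid)), 0.6)
  expect_gt(cor(lfc, tr$delta_log2), 0.9)
})

test_that("a zero effect profile makes groups exchangeable at the nominal test level", {
  null_profile <- c("-1" = 0, "1" = 0, "4" = 0, "7" = 0, "10" = 0)
  rates <- vapply(1:6, function(s) {
    st <- generate_study(recovery_design(),
                         recovery_spec(effect_profile = null_profile),
                         seed = 100 + s)
    sm <- st$table$sample_meta
    iT <- sm$sample_id[sm$sample_type == "study" & sm$group == "T" & sm$day == 4]
    iC <- sm$sample_id[sm$sample_type == "study" & sm$group == "C" & sm$day == 4]
    p <- vapply(colnames(st$table$intensities), function(j) {
      a <- st$table$intensities[iT, j]; b <- st$table$intensities[iC, j]
      a <- a[!is.na(a)]; b <- b[!is.na(b)]
      if (length(a) < 3 || length(b) < 3) return(NA_real_)
      mann_whitney(a, b)$p_value
    }, numeric(1))
    mean(p < 0.05, na.rm = TRUE)
  }, numeric(1))
  expect_lt(mean(rates), 0.10)
  expect_gt(mean(rates), 0.005)
})

test_that("expected day-4 group deviations are ordered like the planted attenuations", {
  # average absolute log2 deviation from control, per group, averaged over
  # seeds; the ordering must match the attenuation ordering
  groups <- c("T/HQD", "T/SS", "T/BB", "T/SF", "T")
  dev_sum <- setNames(numeric(5), groups)
  n_seeds <- 20
  for (s in seq_len(n_seeds)) {
    st <- generate_study(small_design(4L),
                         perturbation_spec(n_features_total = 30L,
                                           n_perturbed = 10L,
                                           n_exogenous_per_group = 0L,
                                           n_background = 2L,
                                           missing_rate = 0),
                         seed = 500 + s)
    sm <- st$table$sample_meta
    ints <- log2(st$table$intensities)
    iC <- sm$sample_id[sm$sample_type == "study" & sm$group == "C" & sm$day == 4]
    ctrl <- colMeans(ints[iC, st$truth$perturbed$feature_id, drop = FALSE])
    for (g in groups) {
      ig <- sm$sample_id[sm$sample_type == "study" & sm$group == g & sm$day == 4]
      gm <- colMeans(ints[ig, st$truth$perturbed$feature_id, drop = FALSE])
      dev_sum[g] <- dev_sum[g] + mean(abs(gm - ctrl))
    }
  }
  expect_equal(names(sort(dev_sum)), groups)
})

test_that("the control group is day-stationary up to noise", {
  n_sig <- 0L
  n_seeds <- 15
  for (s in seq_len(n_seeds)) {
    st <- generate_study(small_design(4L),
                         perturbation_spec(n_features_total = 25L,
                                           n_perturbed = 8L,
                                           n_exogenous_per_group = 0L,
                                           n_background = 2L),
                         seed = 700 + s)
    sm <- st$table$sample_meta
    ctrl <- sm[sm$sample_type == "study" & sm$group == "C", ]
    m <- rowMeans(log2(st$table$intensities[ctrl$sample_id, , drop = FALSE]),
                  na.rm = TRUE)
    p <- kruskal.test(m, factor(ctrl$day))$p.value
    if (p < 0.05) n_sig <- n_sig + 1L
  }
  expect_lte(n_sig / n_seeds, 0.2)
})

test_that("write/read round-trips a study including missing-value encoding", {
  st <- generate_study(small_design(3L), small_spec(), seed = 2)
  dir <- withr::local_tempdir()
  write_study(st, dir)
  back <- read_study(dir)
  expect_equal(back$table$intensities, st$table$intensities)
  expect_equal(back$table$sample_meta, st$table$sample_meta)
  expect_equal(back$table$feature_meta, st$table$feature_meta)
  expect_equal(back$phenotype, st$phenotype, tolerance = 1e-12)
  expect_equal(back$truth$perturbed$feature_id, st$truth$perturbed$feature_id)
  # missing values written as empty fields, read back as NA (never 0)
  raw <- readLines(file.path(dir, "intensities.csv"))
  expect_true(any(grepl(",,", raw, fixed = TRUE)))
  expect_identical(which(is.na(back$table$intensities)),
                   which(is.na(st$table$intensities)))
})

test_that("malformed study files are rejected", {
  st <- generate_study(small_design(3L), small_spec(), seed = 2)
  dir <- withr::local_tempdir()
  write_study(st, dir)
  path <- file.path(dir, "intensities.csv")
  lines <- readLines(path)
  writeLines(c(lines, lines[2]), path)  # duplicate a sample row
  expect_error(read_study(dir), "duplicated sample id")
  expect_error(generate_study(small_design(3L),
                              small_spec(group_attenuation = c(
                                "C" = 0.2, "T" = 1, "T/HQD" = 0.3, "T/SS" = 0.3,
                                "T/BB" = 0.3, "T/SF" = 0.3)),
                              seed = 1),
               "control")
  expect_error(study_design(days = c(1, 1, 4)), "strictly increasing")
  expect_error(study_design(n_per_group = c(0L, rep(10L, 5))), "at least 1")
})
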