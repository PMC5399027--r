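# The filter chain: each rule on hand-made toys, plus bookkeeping,
# idempotence and no-imputation invariants.

test_that("background filtering applies the sample-to-blank ratio rule", {
  vals <- cbind(F01 = c(150, 150, 150, 150),  # blank mean 100 -> 1.5x, removed
                F02 = c(400, 400, 400, 400),  # blank mean 100 -> 4x, kept
                F03 = c(5, 6, 7, 8))          # absent in blanks, kept
  blank <- cbind(c(100, 100), c(100, 100), c(NA, NA))
  tab <- make_toy_table(vals, blank = blank)
  out <- filter_background(tab, 3)
  expect_setequal(colnames(out$table$intensities), c("F02", "F03"))
  expect_equal(out$report$removed, 1)
  expect_equal(out$report$retained, 2)
  # idempotent
  again <- filter_background(out$table, 3)
  expect_equal(again$table$intensities, out$table$intensities)
  # empty feature set in -> empty out, zero counts
  empty <- pt_subset(tab, features = character(0))
  out0 <- filter_background(empty, 3)
  expect_equal(ncol(out0$table$intensities), 0)
  expect_equal(out0$report$removed, 0)
  # no blanks is an error
  expect_error(filter_background(make_toy_table(vals), 3), "blank")
  expect_error(filter_background(tab, 1), "exceed 1")
})

test_that("the 80% rule counts per-group presence on study samples only", {
  # 10 samples of group A, 10 of B
  m <- matrix(1, 20, 3, dimnames = list(NULL, c("F01", "F02", "F03")))
  m[1:2, 1] <- NA          # F01: 8/10 in A (boundary), absent elsewhere
  m[11:20, 1] <- NA
  m[c(1:3), 2] <- NA       # F02: 7/10 in both groups -> removed
  m[c(11:13), 2] <- NA
  tab <- make_toy_table(m, groups = rep(c("A", "B"), each = 10),
                        qc = matrix(NA_real_, 2, 3))
  # QC missingness must not influence the rule
  out <- apply_80_rule(tab, 0.8)
  expect_setequal(colnames(out$table$intensities), c("F01", "F03"))
  # brute-force oracle on a random toy
  set.seed(8)
  m2 <- matrix(rnorm(60, 10), 12, 5,
               dimnames = list(NULL, sprintf("F%02d", 1:5)))
  m2[sample(length(m2), 25)] <- NA
  grp <- rep(c("A", "B", "C"), each = 4)
  tab2 <- make_toy_table(m2, groups = grp)
  out2 <- apply_80_rule(tab2, 0.8)
  keep_oracle <- vapply(seq_len(5), function(j) {
    any(vapply(unique(grp), function(g) {
      mean(!is.na(m2[grp == g, j])) >= 0.8
    }, logical(1)))
  }, logical(1))
  expect_setequal(colnames(out2$table$intensities),
                  sprintf("F%02d", which(keep_oracle)))
  expect_equal(out2$report$removed + out2$report$retained, 5)
})

test_that("QC RSD filtering uses the n-1 standard deviation and the 15% default", {
  vals <- matrix(10, 4, 3, dimnames = list(NULL, c("F01", "F02", "F03")))
  qc <- cbind(c(100, 100, 100),   # RSD 0 -> kept
              c(50, 100, 150),    # RSD 0.5 -> removed
              c(95, 100, 105))    # RSD 0.05 -> kept
  tab <- make_toy_table(vals, qc = qc)
  out <- qc_rsd_filter(tab)  # default bound
  expect_setequal(colnames(out$table$intensities), c("F01", "F03"))
  # hand value: sd(50,100,150) = 50, mean 100
  expect_equal(sd(c(50, 100, 150)) / 100, 0.5)
  expect_error(qc_rsd_filter(make_toy_table(vals)), "QC")
})

test_that("total-intensity normalization makes observed rows sum to one", {
  m <- rbind(c(2, 3, 5), c(2, NA, 8))
  colnames(m) <- c("F01", "F02", "F03")
  tab <- make_toy_table(m)
  out <- normalize_total_intensity(tab)
  expect_equal(unname(out$intensities[1, ]), c(0.2, 0.3, 0.5))
  expect_equal(unname(out$intensities[2, ]), c(0.2, NA, 0.8))
  expect_equal(unname(rowSums(out$intensities, na.rm = TRUE)), c(1, 1))
  m_bad <- rbind(c(1, 2, 3), c(NA, NA, NA))
  colnames(m_bad) <- colnames(m)
  expect_error(normalize_total_intensity(make_toy_table(m_bad)), "non-positive")
})

test_that("ion fusion merges correlated features within a window by single linkage", {
  set.seed(12)
  base <- rnorm(10, 100, 10)
  m <- cbind(F01 = base, F02 = 2 * base, F03 = rnorm(10, 100, 10),
             F04 = rnorm(10, 100, 10))
  tab <- make_toy_table(m)
  grouping <- c(F01 = "w1", F02 = "w1", F03 = "w1", F04 = "w2")
  out <- fuse_ions(tab, grouping, min_correlation = 0.9)
  expect_true("F01+F02" %in% colnames(out$table$intensities))
  expect_equal(unname(out$table$intensities[, "F01+F02"]), base + 2 * base)
  expect_true(all(c("F03", "F04") %in% colnames(out$table$intensities)))
  expect_equal(out$report$removed, 1)
  # uncorrelated features in one window stay apart
  out2 <- fuse_ions(make_toy_table(m[, 3:4]),
                    c(F03 = "w1", F04 = "w1"), 0.9)
  expect_equal(ncol(out2$table$intensities), 2)
  # brute-force single-linkage oracle on a 4-feature toy
  m3 <- cbind(F01 = base, F02 = base + rnorm(10, 0, 1),
              F03 = 200 - base + rnorm(10, 0, 1), F04 = abs(rnorm(10, 5)))
  grouping3 <- c(F01 = "w", F02 = "w", F03 = "w", F04 = "w")
  thr <- 0.9
  cors <- cor(m3)
  adj <- cors >= thr
  # oracle: connected components by repeated expansion
  comp <- seq_len(4)
  for (i in 1:4) for (j in 1:4) {
    if (adj[i, j]) comp[comp == comp[j]] <- comp[i]
  }
  oracle_sizes <- sort(as.vector(table(comp)))
  out3 <- fuse_ions(make_toy_table(m3), grouping3, thr)
  got_sizes <- sort(vapply(strsplit(colnames(out3$table$intensities), "\\+"),
                           length, integer(1)))
  expect_equal(got_sizes, oracle_sizes)
  # no grouping declared: identity
  out4 <- fuse_ions(tab, NULL, 0.9)
  expect_identical(out4$table$intensities, tab$intensities)
})

test_that("Pareto scaling centers and divides by the root standard deviation", {
  x <- cbind(a = c(6, 10, 14), b = c(1, 2, 3))
  ps <- pareto_scale(x)
  # column a: mean 10, sd 4 -> value 14 maps to (14-10)/2 = 2
  expect_equal(unname(ps$scaled[3, "a"]), 2)
  expect_equal(unname(colMeans(ps$scaled)), c(0, 0), tolerance = 1e-12)
  set.seed(13)
  y <- matrix(rnorm(15, 5, 2), 5, 3, dimnames = list(NULL, letters[1:3]))
  psy <- pareto_scale(y)
  expect_equal(unname(apply(psy$scaled, 2, var)), unname(apply(y, 2, sd)),
               tolerance = 1e-12)
  expect_error(pareto_scale(cbind(a = rep(1, 4), b = 1:4)), "constant")
  # QC rows transformed with study-fitted parameters
  qc <- matrix(c(10, 2), 1, 2, dimnames = list("q", c("a", "b")))
  expect_equal(unname(pareto_apply(qc, ps$center, ps$sd)[1, ]),
               c(0, 0), tolerance = 1e-12)
})

test_that("filters keep exact bookkeeping, are idempotent and never impute", {
  st <- generate_study(small_design(3L), small_spec(), seed = 6)
  tab <- st$table
  n0 <- ncol(tab$intensities)
  bg <- filter_background(tab)
  r80 <- apply_80_rule(bg$table)
  qc <- qc_rsd_filter(r80$table)
  reports <- rbind(bg$report, r80$report, qc$report)
  expect_equal(sum(reports$removed) + ncol(qc$table$intensities), n0)
  for (res in list(bg, r80, qc)) {
    expect_equal(res$report$removed + res$report$retained,
                 res$report$removed + ncol(res$table$intensities))
  }
  # idempotence
  expect_equal(apply_80_rule(r80$table)$table$intensities,
               r80$table$intensities)
  expect_equal(qc_rsd_filter(qc$table)$table$intensities,
               qc$table$intensities)
  # missingness pattern survives every filter and normalization untouched
  norm <- normalize_total_intensity(pt_subset(
    qc$table,
    samples = qc$table$sample_meta$sample_id[qc$table$sample_meta$sample_type != "blank"]))
  kept <- colnames(norm$intensities)
  rows <- rownames(norm$intensities)
  expect_identical(is.na(norm$intensities), is.na(tab$intensities[rows, kept]))
})
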