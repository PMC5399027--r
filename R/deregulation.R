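# Global deregulation quantification: PCA group-day trajectories, and a
# principal-curve Metabolites Deregulation Score (MDS) with per-animal
# time areas.  The curve follows the Hastie-Stuetzle iteration (project /
# smooth / reparametrize by arc length) in a reduced PC space, and the MDS
# of a sample is its normalized arc-length position along the curve,
# anchored so the healthy (control) end is 0 — the Pathifier convention.

#' Group-day trajectory in the PC1-PC2 plane
#'
#' Averages the first two PCA score columns by group and day (study
#' samples only) and reports each group's Euclidean displacement from its
#' own baseline (earliest) day.
#'
#' @param pca A `pca_model` fitted on the study samples (scores must have
#'   row names matching sample ids).
#' @param sample_meta Sample metadata with `sample_id`, `group`, `day`,
#'   `sample_type`.
#' @return An object of class `trajectory`: a data frame with `group`,
#'   `day`, `pc1`, `pc2`, `displacement`.
#' @export
compute_trajectory <- function(pca, sample_meta) {
  stopifnot(inherits(pca, "pca_model"))
  if (ncol(pca$scores) < 2L) stop("at least two PCA components are required", call. = FALSE)
  sm <- sample_meta[sample_meta$sample_type == "study", , drop = FALSE]
  idx <- match(sm$sample_id, rownames(pca$scores))
  if (anyNA(idx)) stop("every study sample must have a PCA score", call. = FALSE)
  sc <- pca$scores[idx, 1:2, drop = FALSE]
  agg <- stats::aggregate(sc, by = list(group = sm$group, day = sm$day), FUN = mean)
  names(agg)[3:4] <- c("pc1", "pc2")
  counts <- stats::aggregate(list(n = sm$sample_id),
                             by = list(group = sm$group, day = sm$day),
                             FUN = length)
  expected <- expand.grid(group = unique(sm$group), day = unique(sm$day),
                          stringsAsFactors = FALSE)
  have <- paste(counts$group, counts$day)
  miss <- !paste(expected$group, expected$day) %in% have
  if (any(miss)) {
    stop("group-day stratum with zero samples: ",
         paste(paste(expected$group[miss], expected$day[miss]), collapse = ", "),
         call. = FALSE)
  }
  agg <- agg[order(agg$group, agg$day), , drop = FALSE]
  agg$displacement <- NA_real_
  for (g in unique(agg$group)) {
    rows <- which(agg$group == g)
    base <- rows[which.min(agg$day[rows])]
    agg$displacement[rows] <- sqrt((agg$pc1[rows] - agg$pc1[base])^2 +
                                   (agg$pc2[rows] - agg$pc2[base])^2)
  }
  rownames(agg) <- NULL
  structure(agg, class = c("trajectory", "data.frame"))
}

# Project points onto a polyline; returns arc-length positions and squared
# orthogonal distances.
project_polyline <- function(pts, vertices, cum_len) {
  n <- nrow(pts)
  best_d2 <- rep(Inf, n)
  best_lambda <- numeric(n)
  for (k in seq_len(nrow(vertices) - 1L)) {
    a <- vertices[k, ]
    d <- vertices[k + 1L, ] - a
    seg2 <- sum(d^2)
    if (seg2 == 0) next
    diff_a <- sweep(pts, 2, a, "-")
    tt <- clamp(drop(diff_a %*% d) / seg2, 0, 1)
    proj <- outer(tt, d)
    d2 <- rowSums((diff_a - proj)^2)
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    best_lambda[upd] <- cum_len[k] + tt[upd] * sqrt(seg2)
  }
  list(lambda = best_lambda, dist2 = best_d2)
}

# Running-mean smoother of y against the ordering of lambda, with a window
# spanning `span` of the points.
running_mean_smooth <- function(y, ord, span) {
  n <- length(y)
  h <- max(1L, floor(span * n / 2))
  ys <- y[ord]
  cs <- cumsum(ys)
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  out <- (cs[hi] - c(0, cs)[lo]) / (hi - lo + 1L)
  out
}

#' Fit a principal curve through a sample cloud
#'
#' Hastie-Stuetzle principal curve in the space of the top principal
#' components: initialize at the first PC, then alternate projecting every
#' sample to its nearest curve point (arc-length parameter), smoothing each
#' coordinate against the parameter with a running-mean smoother, and
#' reparametrizing by arc length, until the total squared projection
#' distance stabilizes.  The curve is oriented so the mean parameter of the
#' healthy samples sits at the low (zero) end.
#'
#' @param x Numeric matrix (samples x features, e.g. the Pareto-scaled
#'   biomarker matrix) with row names; at least 3 rows.
#' @param healthy_ids Row names of the healthy (control) samples used to
#'   anchor the orientation.
#' @param n_pcs Dimensionality of the reduced space; `NULL` (default)
#'   chooses the smallest number of PCs explaining at least `var_target`
#'   of the variance.
#' @param var_target Variance fraction for the automatic `n_pcs` choice;
#'   default 0.85.
#' @param span Smoother span as a fraction of the points; default 0.3.
#' @param tol Relative change in total squared projection distance that
#'   stops the iteration; default 1e-3.
#' @param max_iter Iteration cap; default 50.  Non-convergence is reported
#'   as a warning with diagnostics and the last iterate is returned.
#' @return An object of class `principal_curve_fit` with curve `vertices`,
#'   `cum_len`, total `length`, per-sample `lambda` (arc-length positions)
#'   and `dist2`, the PCA `center`/`rotation` defining the reduced space,
#'   and convergence diagnostics.
#' @export
fit_principal_curve <- function(x, healthy_ids, n_pcs = NULL,
                                var_target = 0.85, span = 0.3,
                                tol = 1e-3, max_iter = 50L) {
  if (!is.matrix(x) || nrow(x) < 3L) {
    stop("`x` must be a matrix with at least 3 rows", call. = FALSE)
  }
  if (is.null(rownames(x))) stop("`x` must have sample row names", call. = FALSE)
  if (!length(healthy_ids) || !all(healthy_ids %in% rownames(x))) {
    stop("`healthy_ids` must be non-empty row names of `x`", call. = FALSE)
  }
  stop_if_not_scalar_number(span, "span", lower = 0.01, upper = 1)
  pr <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  total_var <- sum(pr$sdev^2)
  if (total_var == 0) stop("degenerate zero-variance input", call. = FALSE)
  if (is.null(n_pcs)) {
    cumfrac <- cumsum(pr$sdev^2) / total_var
    n_pcs <- which(cumfrac >= var_target)[1]
    if (is.na(n_pcs)) n_pcs <- length(pr$sdev)
  }
  n_pcs <- max(1L, min(as.integer(n_pcs), ncol(pr$rotation)))
  z <- pr$x[, seq_len(n_pcs), drop = FALSE]
  n <- nrow(z)

  lambda <- z[, 1]
  d2_prev <- Inf
  converged <- FALSE
  iter <- 0L
  vertices <- NULL; cum_len <- NULL
  for (iter in seq_len(max_iter)) {
    ord <- order(lambda)
    vertices <- vapply(seq_len(ncol(z)),
                       function(j) running_mean_smooth(z[, j], ord, span),
                       numeric(n))
    vertices <- matrix(vertices, nrow = n)
    # drop consecutive duplicate vertices (flat smoother stretches)
    keep <- c(TRUE, rowSums(abs(diff(vertices))) > 1e-12)
    vertices <- vertices[keep, , drop = FALSE]
    if (nrow(vertices) < 2L) {
      stop("degenerate curve: smoothing collapsed to a point", call. = FALSE)
    }
    seg_len <- sqrt(rowSums(diff(vertices)^2))
    cum_len <- c(0, cumsum(seg_len))
    proj <- project_polyline(z, vertices, cum_len)
    d2 <- sum(proj$dist2)
    lambda <- proj$lambda
    if (is.finite(d2_prev) && abs(d2_prev - d2) <= tol * max(d2_prev, 1e-12)) {
      converged <- TRUE
      d2_prev <- d2
      break
    }
    d2_prev <- d2
  }
  if (!converged) {
    warning(sprintf(
      "principal curve did not converge in %d iterations (last total squared distance %.4g)",
      max_iter, d2_prev))
  }
  total_len <- cum_len[length(cum_len)]
  if (total_len <= 0) stop("degenerate zero-length curve", call. = FALSE)
  names(lambda) <- rownames(z)
  # orient: healthy mean parameter at the low end
  if (mean(lambda[healthy_ids]) > total_len / 2) {
    lambda <- total_len - lambda
    vertices <- vertices[rev(seq_len(nrow(vertices))), , drop = FALSE]
    cum_len <- total_len - rev(cum_len)
  }
  structure(
    list(vertices = vertices, cum_len = cum_len, length = total_len,
         lambda = lambda, dist2 = proj$dist2,
         center = pr$center,
         rotation = pr$rotation[, seq_len(n_pcs), drop = FALSE],
         n_pcs = n_pcs, converged = converged, n_iter = iter,
         healthy_ids = healthy_ids),
    class = "principal_curve_fit"
  )
}

#' @export
print.principal_curve_fit <- function(x, ...) {
  cat(sprintf(
    "principal_curve_fit: %d vertices in %d PCs, length %.3f, %s after %d iterations\n",
    nrow(x$vertices), x$n_pcs, x$length,
    if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

#' Metabolites Deregulation Score
#'
#' Projects samples onto a fitted principal curve; the MDS of a sample is
#' the arc-length position of its projection divided by the total curve
#' length, a number in \[0, 1\] with 0 at the healthy end.  The orthogonal
#' projection residual is returned as a diagnostic.
#'
#' @param curve A `principal_curve_fit`.
#' @param x Matrix of samples: either in the original feature space the
#'   curve was fitted on (reduced internally) or already in the curve's
#'   reduced space.
#' @param sample_meta Optional metadata (`sample_id`, `group`, `day`) to
#'   attach and summarize by group and day.
#' @return An object of class `mds_result`: a list with `scores` (data
#'   frame `sample_id`, `mds`, `residual`, plus metadata columns when
#'   given) and `group_day` (mean and SD of MDS per group-day, when
#'   metadata is given).
#' @export
compute_mds <- function(curve, x, sample_meta = NULL) {
  stopifnot(inherits(curve, "principal_curve_fit"), is.matrix(x))
  if (curve$length <= 0) stop("zero-length curve", call. = FALSE)
  if (ncol(x) == length(curve$center)) {
    z <- sweep(x, 2, curve$center, "-") %*% curve$rotation
  } else if (ncol(x) == curve$n_pcs) {
    z <- x
  } else {
    stop("`x` must be in the curve's feature space or reduced space", call. = FALSE)
  }
  proj <- project_polyline(z, curve$vertices, curve$cum_len)
  scores <- data.frame(sample_id = rownames(x),
                       mds = proj$lambda / curve$length,
                       residual = sqrt(proj$dist2),
                       stringsAsFactors = FALSE)
  group_day <- NULL
  if (!is.null(sample_meta)) {
    idx <- match(scores$sample_id, sample_meta$sample_id)
    scores$group <- sample_meta$group[idx]
    scores$day <- sample_meta$day[idx]
    scores$animal_id <- sample_meta$animal_id[idx]
    group_day <- stats::aggregate(list(mds_mean = scores$mds),
                                  by = list(group = scores$group, day = scores$day),
                                  FUN = mean)
    group_day$mds_sd <- stats::aggregate(list(sd = scores$mds),
                                         by = list(group = scores$group,
                                                   day = scores$day),
                                         FUN = stats::sd)$sd
    group_day <- group_day[order(group_day$group, group_day$day), , drop = FALSE]
    rownames(group_day) <- NULL
  }
  structure(list(scores = scores, group_day = group_day, curve_length = curve$length),
            class = "mds_result")
}

#' @export
print.mds_result <- function(x, ...) {
  cat(sprintf("mds_result: %d samples, MDS range [%.3f, %.3f]\n",
              nrow(x$scores), min(x$scores$mds), max(x$scores$mds)))
  invisible(x)
}

#' Per-animal MDS time areas and group comparisons
#'
#' Trapezoidal area of each animal's MDS-versus-day curve, with pairwise
#' Mann-Whitney tests between groups on the per-animal areas.
#'
#' @param result An `mds_result` carrying `group`, `day` and `animal_id`
#'   columns (i.e. [compute_mds()] was called with metadata).
#' @param days Optional day window to restrict the curves to.
#' @return A list of class `mds_auc_result` with `per_animal`
#'   (`animal_id`, `group`, `auc`), `group_summary` (mean/median per
#'   group), and `tests` (`group_a`, `group_b`, `U`, `p`).
#' @export
mds_auc <- function(result, days = NULL) {
  stopifnot(inherits(result, "mds_result"))
  sc <- result$scores
  if (is.null(sc$animal_id) || is.null(sc$day)) {
    stop("`result` must carry animal and day metadata", call. = FALSE)
  }
  if (!is.null(days)) sc <- sc[sc$day %in% days, , drop = FALSE]
  per_animal <- do.call(rbind, lapply(split(sc, sc$animal_id), function(d) {
    d <- d[order(d$day), , drop = FALSE]
    if (nrow(d) < 2L) {
      stop("animal sampled at fewer than two days: ", d$animal_id[1], call. = FALSE)
    }
    data.frame(animal_id = d$animal_id[1], group = d$group[1],
               auc = trapezoid_auc(d$mds, d$day), stringsAsFactors = FALSE)
  }))
  rownames(per_animal) <- NULL
  group_summary <- stats::aggregate(list(auc_mean = per_animal$auc),
                                    by = list(group = per_animal$group), FUN = mean)
  group_summary$auc_median <- stats::aggregate(
    list(m = per_animal$auc), by = list(group = per_animal$group),
    FUN = stats::median)$m
  groups <- sort(unique(per_animal$group))
  tests <- NULL
  if (length(groups) > 1L) {
    pairs <- utils::combn(groups, 2L)
    tests <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
      a <- per_animal$auc[per_animal$group == pairs[1, i]]
      b <- per_animal$auc[per_animal$group == pairs[2, i]]
      mw <- mann_whitney(a, b)
      data.frame(group_a = pairs[1, i], group_b = pairs[2, i],
                 U = mw$statistic, p = mw$p_value, stringsAsFactors = FALSE)
    }))
    rownames(tests) <- NULL
  }
  structure(list(per_animal = per_animal, group_summary = group_summary,
                 tests = tests),
            class = "mds_auc_result")
}
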