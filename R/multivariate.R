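# Multivariate decompositions: PCA (via prcomp) and a NIPALS O-PLS-DA for
# a single binary response, with k-fold cross-validated Q2, VIP and S-plot
# coordinates.  These engines sit behind every selection and trajectory
# stage of the pipeline.

#' Principal component analysis of a preprocessed matrix
#'
#' Column-centered PCA (no further scaling — the caller is expected to have
#' Pareto-scaled already).  Scores are the centered data projected on the
#' orthonormal loadings.
#'
#' @param x Numeric matrix (samples x features), at least two rows, no
#'   missing values.
#' @param n_components Number of components, at most `min(nrow - 1, ncol)`.
#' @return An object of class `pca_model` with `scores`, `loadings`,
#'   `explained` (per-component variance fractions), `r2x` (their sum),
#'   `center`, `sdev`.
#' @export
fit_pca <- function(x, n_components = 2L) {
  if (!is.matrix(x) || !is.numeric(x)) stop("`x` must be a numeric matrix", call. = FALSE)
  if (anyNA(x)) stop("missing values are not allowed; fill them first", call. = FALSE)
  if (nrow(x) < 2L) stop("at least two rows are required", call. = FALSE)
  kmax <- min(nrow(x) - 1L, ncol(x))
  if (n_components < 1L || n_components > kmax) {
    stop("`n_components` must be between 1 and min(nrow - 1, ncol)", call. = FALSE)
  }
  pr <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  total_var <- sum(pr$sdev^2)
  if (total_var == 0) stop("degenerate all-constant matrix", call. = FALSE)
  k <- seq_len(n_components)
  structure(
    list(scores = pr$x[, k, drop = FALSE],
         loadings = pr$rotation[, k, drop = FALSE],
         explained = pr$sdev[k]^2 / total_var,
         r2x = sum(pr$sdev[k]^2) / total_var,
         center = pr$center,
         sdev = pr$sdev),
    class = "pca_model"
  )
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("pca_model: %d components, R2X = %.3f (%s)\n",
              ncol(x$scores), x$r2x,
              paste(sprintf("%.1f%%", 100 * x$explained), collapse = " + ")))
  invisible(x)
}

#' Project new samples into a fitted PCA space
#'
#' @param object A `pca_model`.
#' @param newdata Matrix with the same columns as the training data.
#' @param ... Unused.
#' @return Score matrix of `newdata`.
#' @export
predict.pca_model <- function(object, newdata, ...) {
  stopifnot(is.matrix(newdata), ncol(newdata) == length(object$center))
  sweep(newdata, 2, object$center, "-") %*% object$loadings
}

encode_response <- function(y, positive_class = NULL) {
  y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) != 2L) {
    stop("`y` must contain exactly two classes", call. = FALSE)
  }
  # tie-break: the lexicographically first class label maps to +1 unless
  # the caller names the positive class (the toxin/treated group) itself
  if (is.null(positive_class)) positive_class <- classes[1]
  if (!positive_class %in% classes) {
    stop("`positive_class` must be one of the observed labels", call. = FALSE)
  }
  list(values = ifelse(y == positive_class, 1, -1),
       classes = classes, positive_class = positive_class)
}

#' Fit an OPLS-DA model
#'
#' Orthogonal projection to latent structures discriminant analysis for a
#' binary response: one predictive component plus `n_orth` Y-orthogonal
#' components, fitted by NIPALS on the column-centered matrix.  With
#' `n_orth = 0` the predictive component equals the one-component PLS1
#' solution.  Orthogonal score vectors are exactly uncorrelated with the
#' response by construction.  Reported scores are sign-fixed so that
#' `positive_class` has positive mean predictive score.
#'
#' @param x Numeric matrix (samples x features), preprocessed and complete.
#' @param y Binary class labels, one per row of `x`.
#' @param n_orth Number of orthogonal components (>= 0).
#' @param positive_class Label mapped to +1 (default: lexicographically
#'   first label).
#' @return An object of class `opls_model` with predictive scores `t`,
#'   weights `w`, loadings `p`, orthogonal `t_orth`/`w_orth`/`p_orth`,
#'   `r2x`, `r2y`, `vip`, and S-plot coordinates `s_plot`.
#' @export
fit_oplsda <- function(x, y, n_orth = 1L, positive_class = NULL) {
  if (!is.matrix(x) || !is.numeric(x)) stop("`x` must be a numeric matrix", call. = FALSE)
  if (anyNA(x)) stop("missing values are not allowed; fill them first", call. = FALSE)
  if (nrow(x) != length(y)) stop("`y` must have one label per row of `x`", call. = FALSE)
  if (n_orth < 0L) stop("`n_orth` must be >= 0", call. = FALSE)
  enc <- encode_response(y, positive_class)
  yv <- enc$values
  y_mean <- mean(yv)
  yc <- yv - y_mean
  if (sum(yc^2) == 0) stop("`y` must contain both classes", call. = FALSE)
  x_center <- colMeans(x)
  E <- sweep(x, 2, x_center, "-")
  ssx_total <- sum(E^2)
  if (ssx_total == 0) stop("degenerate all-constant matrix", call. = FALSE)

  p_feat <- ncol(x)
  W_o <- P_o <- matrix(0, nrow = p_feat, ncol = 0)
  T_o <- matrix(0, nrow = nrow(x), ncol = 0)
  n_orth_used <- 0L
  for (o in seq_len(n_orth)) {
    w <- drop(crossprod(E, yc))
    w <- w / sqrt(sum(w^2))
    t_pred <- drop(E %*% w)
    p_load <- drop(crossprod(E, t_pred)) / sum(t_pred^2)
    w_orth <- p_load - drop(crossprod(w, p_load)) * w
    nrm <- sqrt(sum(w_orth^2))
    if (nrm < 1e-10) break  # no Y-orthogonal structure left
    w_orth <- w_orth / nrm
    t_orth <- drop(E %*% w_orth)
    p_orth <- drop(crossprod(E, t_orth)) / sum(t_orth^2)
    E <- E - tcrossprod(t_orth, p_orth)
    W_o <- cbind(W_o, w_orth)
    P_o <- cbind(P_o, p_orth)
    T_o <- cbind(T_o, t_orth)
    n_orth_used <- n_orth_used + 1L
  }
  w <- drop(crossprod(E, yc))
  w_norm <- sqrt(sum(w^2))
  if (w_norm == 0) stop("response carries no covariance with the matrix", call. = FALSE)
  w <- w / w_norm
  t_pred <- drop(E %*% w)
  p_load <- drop(crossprod(E, t_pred)) / sum(t_pred^2)
  c_coef <- sum(t_pred * yc) / sum(t_pred^2)

  # sign fix: positive class on the positive side of the predictive score
  pos <- yv == 1
  if (mean(t_pred[pos]) < mean(t_pred[!pos])) {
    w <- -w; t_pred <- -t_pred; p_load <- -p_load; c_coef <- -c_coef
  }

  resid <- E - tcrossprod(t_pred, p_load)
  r2x <- 1 - sum(resid^2) / ssx_total
  y_hat <- t_pred * c_coef
  r2y <- 1 - sum((yc - y_hat)^2) / sum(yc^2)
  ssy_pred <- sum(y_hat^2)

  model <- structure(
    list(t = t_pred, w = w, p = p_load, c = c_coef,
         t_orth = T_o, w_orth = W_o, p_orth = P_o,
         n_orth = n_orth_used, x_center = x_center,
         y_mean = y_mean, classes = enc$classes,
         positive_class = enc$positive_class, y = yv,
         r2x = r2x, r2y = r2y, ssy_pred = ssy_pred,
         feature_ids = colnames(x)),
    class = "opls_model"
  )
  model$vip <- compute_vip(model)
  # tolerant internal S-plot: columns constant in this (sub)sample get NA
  sds <- apply(x, 2, stats::sd)
  p_cov <- rep(NA_real_, ncol(x)); p_corr <- rep(NA_real_, ncol(x))
  ok <- sds > 0
  p_cov[ok] <- drop(stats::cov(t_pred, x[, ok, drop = FALSE]))
  p_corr[ok] <- drop(stats::cor(t_pred, x[, ok, drop = FALSE]))
  model$s_plot <- data.frame(feature_id = colnames(x), p = p_cov,
                             pcorr = p_corr, stringsAsFactors = FALSE,
                             row.names = NULL)
  model
}

#' @export
print.opls_model <- function(x, ...) {
  cat(sprintf(
    "opls_model: 1 predictive + %d orthogonal, R2X = %.3f, R2Y = %.3f (+1 = %s)\n",
    x$n_orth, x$r2x, x$r2y, x$positive_class))
  invisible(x)
}

#' Predict class scores for new samples from an OPLS-DA model
#'
#' Removes the fitted orthogonal components from the new rows and scores
#' the predictive component.
#'
#' @param object An `opls_model`.
#' @param newdata Matrix with the training columns.
#' @param ... Unused.
#' @return A list with `t` (predictive scores), `y_hat` (numeric response
#'   on the ±1 scale) and `class` (predicted labels).
#' @export
predict.opls_model <- function(object, newdata, ...) {
  stopifnot(is.matrix(newdata), ncol(newdata) == length(object$x_center))
  E <- sweep(newdata, 2, object$x_center, "-")
  for (o in seq_len(object$n_orth)) {
    t_orth <- drop(E %*% object$w_orth[, o])
    E <- E - tcrossprod(t_orth, object$p_orth[, o])
  }
  t_new <- drop(E %*% object$w)
  y_hat <- t_new * object$c + object$y_mean
  other <- setdiff(object$classes, object$positive_class)
  list(t = t_new, y_hat = y_hat,
       class = ifelse(y_hat >= object$y_mean, object$positive_class, other))
}

#' Variable importance in the projection
#'
#' VIP over the predictive plus orthogonal components with SSY weights:
#' `VIP_j = sqrt(p * sum_a SSY_a (w_aj / ||w_a||)^2 / sum_a SSY_a)`.
#' Y-orthogonal components explain no response variance, so their weight is
#' zero and the squared VIPs sum exactly to the feature count.
#'
#' @param model A fitted `opls_model`.
#' @return Named numeric vector of VIP values.
#' @export
compute_vip <- function(model) {
  stopifnot(inherits(model, "opls_model"))
  if (model$ssy_pred <= 0) stop("zero explained response variance", call. = FALSE)
  p_feat <- length(model$w)
  w_all <- cbind(model$w, model$w_orth)
  ssy <- c(model$ssy_pred, rep(0, model$n_orth))
  w_unit2 <- sweep(w_all^2, 2, colSums(w_all^2), "/")
  vip <- sqrt(p_feat * drop(w_unit2 %*% ssy) / sum(ssy))
  stats::setNames(vip, model$feature_ids)
}

#' S-plot coordinates
#'
#' Per-feature covariance `p = cov(t, x_j)` and correlation
#' `pcorr = cor(t, x_j)` with the predictive score — the classical display
#' for spotting extreme discriminators.
#'
#' @param model A fitted `opls_model`.
#' @param x The matrix the model refers to (training matrix or any matrix
#'   in the same column space); constant columns are an error.
#' @return Data frame with `feature_id`, `p`, `pcorr`.
#' @export
s_plot <- function(model, x) {
  stopifnot(inherits(model, "opls_model"), is.matrix(x))
  if (nrow(x) != length(model$t)) {
    stop("`x` must have one row per model score", call. = FALSE)
  }
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant feature column(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "), call. = FALSE)
  }
  t_score <- model$t
  p_cov <- drop(stats::cov(t_score, x))
  p_corr <- drop(stats::cor(t_score, x))
  data.frame(feature_id = colnames(x), p = p_cov, pcorr = p_corr,
             stringsAsFactors = FALSE, row.names = NULL)
}

make_folds <- function(n, k_folds, strata = NULL, seed = 1L) {
  if (k_folds < 2L || k_folds > n) {
    stop("`k_folds` must be between 2 and the number of samples", call. = FALSE)
  }
  with_seed(seed, {
    fold <- integer(n)
    if (is.null(strata)) {
      fold <- sample(rep_len(seq_len(k_folds), n))
    } else {
      for (cls in unique(strata)) {
        idx <- which(strata == cls)
        fold[idx] <- sample(rep_len(seq_len(k_folds), length(idx)))
      }
    }
    fold
  })
}

#' Cross-validated predictive ability (Q2)
#'
#' k-fold cross-validation.  For `method = "oplsda"` folds are stratified
#' by class and `Q2 = 1 - PRESS / SS` over held-out response predictions;
#' for `method = "pca"` held-out rows are reconstructed from loadings fit
#' on the training rows and PRESS is the reconstruction error.
#' Deterministic given `seed` (or an explicit `folds` assignment).
#'
#' @param method `"pca"` or `"oplsda"`.
#' @param x Numeric matrix.
#' @param y Class labels (required for `"oplsda"`).
#' @param k_folds Number of folds (default 7, the usual software
#'   convention).
#' @param seed Seed for the fold assignment.
#' @param folds Optional explicit integer fold assignment per row.
#' @param n_components PCA components (default 2).
#' @param n_orth OPLS-DA orthogonal components (default 0).
#' @param positive_class Passed to [fit_oplsda()].
#' @return A list with `q2`, `press`, `ss`, `folds`, and for supervised
#'   models `r2y` of the full fit.
#' @export
cross_validate <- function(method = c("pca", "oplsda"), x, y = NULL,
                           k_folds = 7L, seed = 1L, folds = NULL,
                           n_components = 2L, n_orth = 0L,
                           positive_class = NULL) {
  method <- match.arg(method)
  n <- nrow(x)
  if (is.null(folds)) {
    strata <- if (method == "oplsda") as.character(y)
    k_eff <- min(k_folds, if (is.null(strata)) n else min(table(strata)))
    if (k_eff < 2L) stop("too few samples per class for cross-validation", call. = FALSE)
    folds <- make_folds(n, k_eff, strata, seed)
  }
  stopifnot(length(folds) == n)
  press <- 0; ss <- 0
  if (method == "pca") {
    for (f in sort(unique(folds))) {
      train <- x[folds != f, , drop = FALSE]
      test <- x[folds == f, , drop = FALSE]
      ctr <- colMeans(train)
      k_use <- min(n_components, nrow(train) - 1L, ncol(train))
      v <- stats::prcomp(train, center = TRUE, scale. = FALSE)$rotation[, seq_len(k_use), drop = FALSE]
      tc <- sweep(test, 2, ctr, "-")
      recon <- tc %*% v %*% t(v)
      press <- press + sum((tc - recon)^2)
      ss <- ss + sum(tc^2)
    }
    list(q2 = 1 - press / ss, press = press, ss = ss, folds = folds)
  } else {
    if (is.null(y)) stop("`y` is required for supervised cross-validation", call. = FALSE)
    enc <- encode_response(y, positive_class)
    r2y_full <- fit_oplsda(x, y, n_orth = n_orth,
                           positive_class = enc$positive_class)$r2y
    for (f in sort(unique(folds))) {
      tr <- folds != f
      if (length(unique(y[tr])) < 2L || !any(!tr)) {
        stop("a fold lacks both classes", call. = FALSE)
      }
      fit <- fit_oplsda(x[tr, , drop = FALSE], y[tr], n_orth = n_orth,
                        positive_class = enc$positive_class)
      pred <- predict(fit, x[!tr, , drop = FALSE])
      y_test <- enc$values[!tr]
      press <- press + sum((y_test - pred$y_hat)^2)
      ss <- ss + sum((y_test - mean(enc$values[tr]))^2)
    }
    list(q2 = 1 - press / ss, r2y = r2y_full, press = press, ss = ss,
         folds = folds)
  }
}

#' Choose the number of orthogonal components by cross-validation
#'
#' Starts at 0 and adds orthogonal components while the cross-validated Q2
#' improves by more than `tol`.
#'
#' @param x,y Matrix and labels as in [fit_oplsda()].
#' @param max_orth Upper bound on orthogonal components.
#' @param tol Minimum Q2 improvement to accept another component
#'   (default 0.01).
#' @param k_folds,seed,positive_class Passed to [cross_validate()].
#' @return A list with `n_orth` and `q2`.
#' @export
choose_n_orth <- function(x, y, max_orth = 2L, tol = 0.01, k_folds = 7L,
                          seed = 1L, positive_class = NULL) {
  best_n <- 0L
  best_q2 <- cross_validate("oplsda", x, y, k_folds = k_folds, seed = seed,
                            n_orth = 0L, positive_class = positive_class)$q2
  for (n_o in seq_len(max_orth)) {
    q2 <- cross_validate("oplsda", x, y, k_folds = k_folds, seed = seed,
                         n_orth = n_o, positive_class = positive_class)$q2
    if (q2 > best_q2 + tol) {
      best_n <- n_o; best_q2 <- q2
    } else break
  }
  list(n_orth = best_n, q2 = best_q2)
}
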