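#' Construct a laminar profile
#'
#' @param metric Metric name.
#' @param values Numeric length-3 (superficial, middle, deep); NA marks a
#'   layer where the metric is undefined.
#' @param n_voxels Voxels actually used per layer.
#' @return A data.frame of class `laminar_profile` with columns `metric`,
#'   `layer`, `value`, `n_voxels`.
#' @export
laminar_profile <- function(metric, values, n_voxels) {
  stopifnot(length(values) == 3, length(n_voxels) == 3)
  structure(data.frame(metric = metric,
                       layer = factor(layer_names(), levels = layer_names()),
                       value = as.numeric(values),
                       n_voxels = as.integer(n_voxels),
                       stringsAsFactors = FALSE),
            class = c("laminar_profile", "data.frame"))
}

per_layer <- function(layers, f) {
  vapply(layer_names(), function(l) f(which(layers == l)), numeric(1))
}

layer_counts <- function(layers) {
  vapply(layer_names(), function(l) sum(layers == l), numeric(1))
}

#' Voxel-ratio metric
#'
#' Mean over voxels of the per-voxel ratio TaskD+/TaskD-. Voxels with a
#' zero TaskD- denominator are excluded; no other outlier handling is
#' applied (the metric's heavy-tailed instability is a finding, not a bug).
#'
#' @param contrasts A `contrast_estimates`.
#' @param layers Layer factor (one entry per voxel).
#' @return A `laminar_profile`.
#' @export
metric_voxel_ratio <- function(contrasts, layers) {
  vals <- per_layer(layers, function(idx) {
    if (!length(idx)) return(NA_real_)
    keep <- idx[contrasts$taskdminus[idx] != 0]
    if (!length(keep)) return(NA_real_)
    mean(contrasts$taskdplus[keep] / contrasts$taskdminus[keep])
  })
  n <- per_layer(layers, function(idx) sum(contrasts$taskdminus[idx] != 0))
  laminar_profile("voxel_ratio", vals, n)
}

#' ROI-ratio metric
#'
#' Ratio of the layer-summed TaskD+ contrast to the layer-summed TaskD-
#' contrast; robust to individual near-zero denominators but requires a
#' regional-mean preference.
#'
#' @inheritParams metric_voxel_ratio
#' @return A `laminar_profile`.
#' @export
metric_roi_ratio <- function(contrasts, layers) {
  vals <- per_layer(layers, function(idx) {
    if (!length(idx)) return(NA_real_)
    den <- sum(contrasts$taskdminus[idx])
    if (den == 0) return(NA_real_)
    sum(contrasts$taskdplus[idx]) / den
  })
  laminar_profile("roi_ratio", vals, layer_counts(layers))
}

#' Deming (errors-in-variables) regression slope
#'
#' Closed-form slope of `y` on `x` when both carry measurement error with
#' error-variance ratio `delta`; `delta = 1` is orthogonal regression,
#' minimizing summed squared perpendicular distances.
#'
#' @param x,y Numeric vectors.
#' @param delta Error-variance ratio var(err_y)/var(err_x) (default 1).
#' @return Slope, or NA when the sample covariance of x and y is zero.
#' @export
deming_slope <- function(x, y, delta = 1) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) return(NA_real_)
  sxx <- stats::var(x); syy <- stats::var(y); sxy <- stats::cov(x, y)
  if (sxy == 0) return(NA_real_)
  (syy - delta * sxx + sqrt((syy - delta * sxx)^2 + 4 * delta * sxy^2)) /
    (2 * sxy)
}

#' Deming-regression metric
#'
#' Per layer, the Deming slope of TaskD+ regressed on TaskD-. The TaskD+
#' and TaskD- estimates come from interleaved runs of the same session, so
#' their error variances are assumed equal (`delta = 1`). Unlike the ratio
#' metrics this does not require a regional-mean preference.
#'
#' @inheritParams metric_voxel_ratio
#' @param delta Deming error-variance ratio (default 1).
#' @return A `laminar_profile`.
#' @export
metric_deming <- function(contrasts, layers, delta = 1) {
  stopifnot(delta > 0)
  vals <- per_layer(layers, function(idx)
    deming_slope(contrasts$taskdminus[idx], contrasts$taskdplus[idx],
                 delta = delta))
  laminar_profile("deming", vals, layer_counts(layers))
}

#' Z-scoring metric
#'
#' Z-scores each distractor-present run's timeseries per voxel, refits the
#' per-condition GLM, and averages the attend-face minus attend-house
#' contrast over runs and then over voxels per layer. Zero-variance voxels
#' are treated as missing.
#'
#' @param session A `simulated_session` (or compatible list of runs).
#' @param layers Layer factor.
#' @param preference_sign +1 face-preferring, -1 house-preferring.
#' @return A `laminar_profile`.
#' @export
metric_zscore <- function(session, layers, preference_sign = 1) {
  dplus <- Filter(function(r) r$schedule$context == "TaskD+", session$runs)
  if (!length(dplus)) stop("no TaskD+ runs in session")
  per_run <- vapply(dplus, function(run) {
    z <- zscore_timeseries(run$y)
    X <- build_design_matrix(run$schedule, session$kernel, "per_condition")
    y <- z$y
    y[z$degenerate, ] <- 0   # fit zeros, restore NA afterwards
    cvals <- per_run_contrast(fit_glm(y, X), preference_sign)
    cvals[z$degenerate] <- NA_real_
    cvals
  }, numeric(nrow(dplus[[1]]$y)))
  cpv <- rowMeans(per_run)
  vals <- per_layer(layers, function(idx) {
    if (!any(is.finite(cpv[idx]))) return(NA_real_)
    mean(cpv[idx], na.rm = TRUE)
  })
  n <- per_layer(layers, function(idx) sum(is.finite(cpv[idx])))
  laminar_profile("zscore", vals, n)
}

#' L2-normalization metric
#'
#' Per distractor-present run, each voxel's four condition betas are divided
#' by their L2 norm; the attend-face minus attend-house contrast is then
#' recomputed on the normalized betas, averaged across runs and over voxels
#' per layer. Zero-norm voxels are excluded.
#'
#' @param fits_dplus List of per-condition GLM fits for the TaskD+ runs.
#' @param layers Layer factor.
#' @param preference_sign Contrast sign.
#' @return A `laminar_profile`.
#' @export
metric_l2norm <- function(fits_dplus, layers, preference_sign = 1) {
  per_run <- vapply(fits_dplus, function(fit) {
    cond <- fit$betas[, c("H45", "H135", "F45", "F135"), drop = FALSE]
    nrm <- sqrt(rowSums(cond^2))
    cond <- cond / nrm
    cvals <- preference_sign *
      drop(cond %*% face_contrast_vector(colnames(cond)))
    cvals[nrm == 0] <- NA_real_
    cvals
  }, numeric(nrow(fits_dplus[[1]]$betas)))
  cpv <- rowMeans(per_run)
  vals <- per_layer(layers, function(idx) {
    if (!any(is.finite(cpv[idx]))) return(NA_real_)
    mean(cpv[idx], na.rm = TRUE)
  })
  n <- per_layer(layers, function(idx) sum(is.finite(cpv[idx])))
  laminar_profile("l2norm", vals, n)
}

#' SVM decoding metric
#'
#' Leave-one-run-out classification of the attended category from per-block
#' beta patterns of the distractor-present runs: a linear soft-margin SVM
#' (C = 1) is trained per layer on three runs (60 block patterns) and tested
#' on the held-out run (20 patterns); the value is mean accuracy over the
#' four folds.
#'
#' @param block_betas List (one per TaskD+ run) of matrices voxels x blocks
#'   from the per-block GLM.
#' @param block_labels List of per-run attended-category label vectors.
#' @param layers Layer factor.
#' @return A `laminar_profile` with accuracies in `[0, 1]`.
#' @export
metric_svm <- function(block_betas, block_labels, layers) {
  n_runs <- length(block_betas)
  stopifnot(n_runs >= 2, length(block_labels) == n_runs)
  vals <- per_layer(layers, function(idx) {
    if (!length(idx)) return(NA_real_)
    acc <- vapply(seq_len(n_runs), function(test_run) {
      train_x <- do.call(rbind, lapply(setdiff(seq_len(n_runs), test_run),
                                       function(r) t(block_betas[[r]][idx, ,
                                                                      drop = FALSE])))
      train_y <- unlist(block_labels[-test_run])
      if (length(unique(train_y)) < 2) stop("degenerate single-class fold")
      fit <- svm_train(train_x, train_y, C = 1)
      pred <- predict(fit, t(block_betas[[test_run]][idx, , drop = FALSE]))
      mean(pred == block_labels[[test_run]])
    }, numeric(1))
    mean(acc)
  })
  laminar_profile("svm", vals, layer_counts(layers))
}

#' Ledoit-Wolf shrinkage covariance toward the diagonal
#'
#' Sample covariance blended with its own diagonal, the shrinkage intensity
#' chosen analytically from the variance of the off-diagonal entries
#' (Ledoit-Wolf / Schaefer-Strimmer style). Guarantees a well-conditioned
#' estimate when samples are fewer than variables.
#'
#' @param x Matrix samples x variables (rows are observations).
#' @return List with `sigma` (shrunk covariance) and `lambda` (intensity).
#' @export
shrink_cov_diag <- function(x) {
  x <- as.matrix(x)
  t_n <- nrow(x)
  x <- sweep(x, 2, colMeans(x))
  s <- crossprod(x) / t_n
  y <- x^2
  # var-hat of each covariance entry: 1/t * (mean of squared products - s^2)
  v <- (crossprod(y) / t_n - s^2) / t_n
  offdiag <- !diag(ncol(s))
  den <- sum(s[offdiag]^2)
  lambda <- if (den <= 0) 1 else max(0, min(1, sum(v[offdiag]) / den))
  sigma <- (1 - lambda) * s
  diag(sigma) <- diag(s)
  list(sigma = sigma, lambda = lambda)
}

run_condition_contrast <- function(fit, preference_sign) {
  cond <- fit$betas[, c("H45", "H135", "F45", "F135"), drop = FALSE]
  # mean face beta minus mean house beta
  preference_sign * drop(cond %*% (face_contrast_vector(colnames(cond)) / 2))
}

#' Linear discriminant contrast (LDC) metric
#'
#' Cross-validated, noise-normalized multivariate distance: per layer and
#' leave-one-run-out fold, the training discriminant is the mean attend-face
#' minus attend-house beta pattern over the training runs, whitened by the
#' inverse shrinkage covariance of the pooled training residuals; the
#' statistic is its dot product with the held-out run's contrast pattern.
#' Fold averages are normalized by the square root of the layer's voxel
#' count.
#'
#' @param fits_dplus List of per-condition GLM fits (betas and residuals)
#'   for the TaskD+ runs.
#' @param layers Layer factor.
#' @param preference_sign Contrast sign.
#' @return A `laminar_profile`; attribute `lambda` records the mean
#'   shrinkage intensity per layer.
#' @export
metric_ldc <- function(fits_dplus, layers, preference_sign = 1) {
  n_runs <- length(fits_dplus)
  stopifnot(n_runs >= 2)
  contrasts_by_run <- lapply(fits_dplus, run_condition_contrast,
                             preference_sign = preference_sign)
  lambdas <- numeric(0)
  vals <- per_layer(layers, function(idx) {
    if (!length(idx)) return(NA_real_)
    stat <- vapply(seq_len(n_runs), function(test_run) {
      train <- setdiff(seq_len(n_runs), test_run)
      c_train <- rowMeans(vapply(train,
                                 function(r) contrasts_by_run[[r]][idx],
                                 numeric(length(idx))))
      res <- do.call(rbind, lapply(train, function(r)
        t(fits_dplus[[r]]$residuals[idx, , drop = FALSE])))
      sc <- shrink_cov_diag(res)
      lambdas <<- c(lambdas, sc$lambda)
      w <- drop(solve(sc$sigma, c_train))
      sum(w * contrasts_by_run[[test_run]][idx])
    }, numeric(1))
    mean(stat) / sqrt(length(idx))
  })
  out <- laminar_profile("ldc", vals, layer_counts(layers))
  attr(out, "lambda") <- mean(lambdas)
  out
}

#' Raw (uncorrected) laminar contrast profile
#'
#' Mean TaskD+ contrast per layer -- the measured BOLD response before any
#' bias correction; with a decreasing superficial-bias profile it decreases
#' with depth.
#'
#' @inheritParams metric_voxel_ratio
#' @return A `laminar_profile`.
#' @export
raw_contrast_profile <- function(contrasts, layers) {
  vals <- per_layer(layers, function(idx) mean(contrasts$taskdplus[idx]))
  laminar_profile("raw_contrast", vals, layer_counts(layers))
}

#' Superficial-bias and attentional-modulation contribution scores
#'
#' The 3-layer profile is normalized by its mean and projected onto the
#' fixed vectors `c(1, 0, -1)` (monotone superficial bias) and `c(0.5, -1, 0.5)`
#' (V-shaped attentional modulation) by elementwise multiplication and
#' summation. A flat profile scores (0, 0).
#'
#' @param profile A `laminar_profile` (or numeric length-3 vector, ordered
#'   superficial, middle, deep).
#' @param tol Profiles with |mean| below `tol` times the value spread are
#'   flagged as missing.
#' @return Named numeric vector `c(bias=, attention=)`.
#' @export
contribution_scores <- function(profile, tol = 1e-12) {
  v <- if (inherits(profile, "laminar_profile")) profile$value else
    as.numeric(profile)
  stopifnot(length(v) == 3)
  m <- mean(v)
  if (!is.finite(m) || abs(m) <= tol * max(abs(v), 1)) {
    return(c(bias = NA_real_, attention = NA_real_))
  }
  nv <- v / m
  c(bias = sum(nv * c(1, 0, -1)),
    attention = sum(nv * c(0.5, -1, 0.5)))
}
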