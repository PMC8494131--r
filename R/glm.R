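#' Build a GLM design matrix for one run
#'
#' Condition (or per-block) boxcars convolved with the HRF kernel, plus four
#' nuisance columns emulating the high-pass filtering applied to real data:
#' intercept, linear trend, and first-order sine and cosine over the run
#' duration.
#'
#' @param schedule A `block_schedule`.
#' @param kernel HRF kernel from [hrf_kernel()].
#' @param mode `"per_condition"` (one regressor per condition, 4 + 4
#'   columns) or `"per_block"` (one regressor per block, 20 + 4 columns for
#'   the default design).
#' @param conditions Condition labels, fixing the column order.
#' @return Matrix volumes x regressors with column names; attribute
#'   `condition_cols` marks the task regressors.
#' @export
build_design_matrix <- function(schedule, kernel,
                                mode = c("per_condition", "per_block"),
                                conditions = c("H45", "H135", "F45", "F135")) {
  mode <- match.arg(mode)
  n <- schedule$n_volumes
  if (mode == "per_condition") {
    task <- sapply(conditions, function(cc)
      convolve_with_hrf(condition_boxcar(schedule, condition = cc), kernel))
    colnames(task) <- conditions
  } else {
    task <- sapply(seq_len(nrow(schedule$blocks)), function(b)
      convolve_with_hrf(condition_boxcar(schedule, block_index = b), kernel))
    colnames(task) <- paste0("block", seq_len(ncol(task)), "_",
                             schedule$blocks$condition)
  }
  t_sec <- (seq_len(n) - 1) * schedule$tr
  total <- n * schedule$tr
  nuis <- cbind(intercept = 1,
                linear = seq_len(n) - (n + 1) / 2,
                sin1 = sin(2 * pi * t_sec / total),
                cos1 = cos(2 * pi * t_sec / total))
  X <- cbind(task, nuis)
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  attr(X, "condition_cols") <- seq_len(ncol(task))
  X
}

#' Fit an ordinary least squares GLM to one run
#'
#' @param y Data matrix voxels x volumes.
#' @param X Design matrix volumes x regressors.
#' @return List with `betas` (voxels x regressors) and `residuals`
#'   (voxels x volumes).
#' @export
fit_glm <- function(y, X) {
  stopifnot(ncol(y) == nrow(X))
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) stop("singular design matrix")
  betas <- t(qr.coef(qrx, t(y)))
  colnames(betas) <- colnames(X)
  list(betas = betas, residuals = y - betas %*% t(X))
}

face_contrast_vector <- function(labels) {
  cf <- as.numeric(labels %in% c("F45", "F135")) -
    as.numeric(labels %in% c("H45", "H135"))
  cf
}

per_run_contrast <- function(fit, preference_sign = 1) {
  labels <- colnames(fit$betas)
  cf <- face_contrast_vector(labels)
  preference_sign * drop(fit$betas %*% cf)
}

#' Per-voxel TaskD+/TaskD- contrast estimates
#'
#' For each run, the attend-face minus attend-house contrast of condition
#' betas, `(bF45 + bF135) - (bH45 + bH135)`, with the sign flipped for a
#' house-preferring region; averaged separately over the distractor-present
#' and distractor-absent runs.
#'
#' @param fits List of per-run GLM fits (per-condition mode), in the same
#'   order as the schedules.
#' @param schedules The matching list of `block_schedule`.
#' @param preference_sign `+1` for a face-preferring region, `-1` for a
#'   house-preferring one.
#' @return Object of class `contrast_estimates`: list with numeric vectors
#'   `taskdplus`, `taskdminus`.
#' @export
contrast_estimates <- function(fits, schedules, preference_sign = 1) {
  stopifnot(length(fits) == length(schedules))
  ctx <- vapply(schedules, function(s) s$context, character(1))
  if (!any(ctx == "TaskD+") || !any(ctx == "TaskD-")) {
    stop("need runs in both the TaskD+ and TaskD- contexts")
  }
  per_run <- vapply(fits, per_run_contrast, numeric(nrow(fits[[1]]$betas)),
                    preference_sign = preference_sign)
  structure(list(
    taskdplus = rowMeans(per_run[, ctx == "TaskD+", drop = FALSE]),
    taskdminus = rowMeans(per_run[, ctx == "TaskD-", drop = FALSE])),
    class = "contrast_estimates")
}

#' Z-score a run's timeseries per voxel
#'
#' Subtracts the temporal mean and divides by the temporal sd, voxel by
#' voxel. Zero-variance voxels cannot be normalized and are returned as NA
#' rows with their indices flagged.
#'
#' @param y Matrix voxels x volumes.
#' @return List with `y` (normalized matrix) and `degenerate` (integer
#'   indices of zero-variance voxels).
#' @export
zscore_timeseries <- function(y) {
  m <- rowMeans(y)
  s <- sqrt(rowSums((y - m)^2) / (ncol(y) - 1))
  bad <- which(s == 0)
  z <- (y - m) / s
  if (length(bad)) z[bad, ] <- NA_real_
  list(y = z, degenerate = bad)
}

#' Diagnostic t-statistics for the TaskD+ contrast
#'
#' The run-averaged contrast divided by its OLS standard error, with the
#' residual variance pooled over the runs entering the average:
#' `SE^2 = sigma2_pooled / R^2 * sum_r c' (Xr' Xr)^-1 c`.
#'
#' @param fits Per-run GLM fits (per-condition mode) for the runs to pool.
#' @param Xs The matching design matrices.
#' @param preference_sign Contrast sign (see [contrast_estimates()]).
#' @return Numeric vector of per-voxel t values.
#' @export
contrast_tstats <- function(fits, Xs, preference_sign = 1) {
  stopifnot(length(fits) == length(Xs))
  R <- length(fits)
  cbar <- rowMeans(vapply(fits, per_run_contrast,
                          numeric(nrow(fits[[1]]$betas)),
                          preference_sign = preference_sign))
  rss <- Reduce(`+`, lapply(fits, function(f) rowSums(f$residuals^2)))
  df <- sum(vapply(seq_len(R), function(r)
    nrow(Xs[[r]]) - ncol(Xs[[r]]), numeric(1)))
  if (df <= 0) stop("no residual degrees of freedom")
  sigma2 <- rss / df
  if (all(sigma2 == 0)) stop("zero residual variance (noiseless fit)")
  quad <- sum(vapply(Xs, function(X) {
    cf <- numeric(ncol(X))
    cf[seq_along(face_contrast_vector(colnames(X)))] <-
      face_contrast_vector(colnames(X))
    drop(t(cf) %*% chol2inv(chol(crossprod(X))) %*% cf)
  }, numeric(1)))
  cbar / sqrt(sigma2 * quad / R^2)
}
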