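#' Linear soft-margin SVM via dual coordinate descent
#'
#' Solves the L1-loss (hinge) linear SVM dual with box constraint `C`,
#' following the coordinate-descent scheme used by LIBLINEAR. The bias term
#' is handled by augmenting each pattern with a constant-1 feature, which is
#' the standard large-margin approximation to an unregularized intercept.
#' The Gram matrix is precomputed so each coordinate update costs O(n)
#' regardless of the feature count; sweeps are deterministic and cyclic, so
#' results are reproducible.
#'
#' @param x Matrix samples x features.
#' @param y Labels; any two-level vector/factor. The first sorted unique
#'   level is coded -1, the second +1.
#' @param C Soft-margin cost (default 1, matching common fMRI practice).
#' @param max_sweeps Maximum full passes over the data.
#' @param tol Convergence tolerance on the largest projected gradient.
#' @return Object of class `linear_svm` with `w` (weights), `b` (bias),
#'   `levels`.
#' @export
svm_train <- function(x, y, C = 1, max_sweeps = 2000L, tol = 1e-6) {
  x <- as.matrix(x)
  lev <- sort(unique(as.character(y)))
  if (length(lev) != 2) stop("svm_train needs exactly two classes")
  yy <- ifelse(as.character(y) == lev[2], 1, -1)
  n <- nrow(x)
  Q <- (tcrossprod(x) + 1) * tcrossprod(yy)   # +1: augmented bias feature
  qd <- diag(Q)
  alpha <- numeric(n)
  qa <- numeric(n)                            # Q %*% alpha, kept incrementally
  for (sweep in seq_len(max_sweeps)) {
    max_pg <- 0
    for (i in seq_len(n)) {
      g <- qa[i] - 1
      pg <- g
      if (alpha[i] <= 0) pg <- min(g, 0)
      if (alpha[i] >= C) pg <- max(g, 0)
      if (abs(pg) > 1e-12) {
        a_new <- min(max(alpha[i] - g / qd[i], 0), C)
        d <- a_new - alpha[i]
        if (d != 0) {
          qa <- qa + d * Q[, i]
          alpha[i] <- a_new
        }
      }
      max_pg <- max(max_pg, abs(pg))
    }
    if (max_pg < tol) break
  }
  coef <- alpha * yy
  structure(list(w = drop(crossprod(x, coef)), b = sum(coef), levels = lev),
            class = "linear_svm")
}

#' Predict class labels from a linear SVM
#' @param object A `linear_svm`.
#' @param newdata Matrix samples x features.
#' @param ... Unused.
#' @return Character vector of predicted labels (ties go to the second
#'   level).
#' @export
predict.linear_svm <- function(object, newdata, ...) {
  score <- as.matrix(newdata) %*% object$w + object$b
  ifelse(drop(score) >= 0, object$levels[2], object$levels[1])
}
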