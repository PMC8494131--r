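ce <- function(dplus, dminus) {
  structure(list(taskdplus = dplus, taskdminus = dminus),
            class = "contrast_estimates")
}

test_that("voxel ratio averages per-voxel ratios and is tail-sensitive", {
  layers <- factor(rep(layer_names(), each = 2), levels = layer_names())
  c1 <- ce(c(2, 4, 2, 4, 2, 4), c(3, 6, 4, 8, 3, 6))
  p <- metric_voxel_ratio(c1, layers)
  expect_s3_class(p, "laminar_profile")
  expect_equal(p$value, c(2/3, 1/2, 2/3))
  # a denominator near zero dominates the layer mean
  c2 <- ce(c(1, 1, rep(1, 4)), c(1, 1e-6, rep(1, 4)))
  expect_equal(metric_voxel_ratio(c2, layers)$value[1], (1 + 1e6) / 2)
  # exact-zero denominators are excluded, with the count reported
  c3 <- ce(c(1, 1, rep(1, 4)), c(2, 0, rep(1, 4)))
  p3 <- metric_voxel_ratio(c3, layers)
  expect_equal(p3$value[1], 0.5)
  expect_equal(p3$n_voxels, c(1L, 2L, 2L))
  # all-zero denominators flag the layer as missing
  c4 <- ce(rep(1, 6), c(0, 0, rep(1, 4)))
  expect_true(is.na(metric_voxel_ratio(c4, layers)$value[1]))
})

test_that("ROI ratio divides layer sums and is scale invariant", {
  layers <- factor(rep(layer_names(), each = 2), levels = layer_names())
  c1 <- ce(c(2, 4, 1, 1, 3, 3), c(3, 6, 2, 2, 4, 4))
  expect_equal(metric_roi_ratio(c1, layers)$value, c(2/3, 1/2, 3/4))
  ck <- ce(c1$taskdplus * 7.3, c1$taskdminus * 7.3)
  expect_equal(metric_roi_ratio(ck, layers)$value, c(2/3, 1/2, 3/4))
  c0 <- ce(rep(1, 6), c(1, -1, 1, 1, 1, 1))
  expect_true(is.na(metric_roi_ratio(c0, layers)$value[1]))
})

test_that("Deming slope matches the perpendicular-SSE oracle", {
  # exact line
  x <- c(1, 2, 3, 4.5)
  expect_equal(deming_slope(x, 0.5 * x + 2), 0.5, tolerance = 1e-12)
  # delta = 1 symmetry: swapping axes inverts the slope
  set.seed(19)
  x <- rnorm(40); y <- 0.7 * x + rnorm(40, sd = 0.3)
  expect_equal(deming_slope(x, y), 1 / deming_slope(y, x), tolerance = 1e-12)
  # translation invariance
  expect_equal(deming_slope(x + 13, y - 4), deming_slope(x, y),
               tolerance = 1e-12)
  # brute-force oracle on 20 random 10-point instances
  for (i in 1:20) {
    set.seed(100 + i)
    x <- rnorm(10, sd = runif(1, 0.5, 3))
    y <- runif(1, -2, 2) * x + rnorm(10, sd = runif(1, 0.2, 2)) + runif(1, -5, 5)
    expect_equal(deming_slope(x, y), deming_oracle(x, y), tolerance = 1e-6)
  }
  # zero covariance is flagged missing
  expect_true(is.na(deming_slope(c(1, 2, 3), c(1, 1, 1))))
})

test_that("ratio-family metrics are invariant to per-layer rescaling", {
  set.seed(20)
  layers <- factor(rep(layer_names(), each = 30), levels = layer_names())
  dminus <- rnorm(90, 2); dplus <- 0.6 * dminus + rnorm(90, sd = 0.2)
  base <- list(vr = metric_voxel_ratio(ce(dplus, dminus), layers)$value,
               rr = metric_roi_ratio(ce(dplus, dminus), layers)$value,
               dm = metric_deming(ce(dplus, dminus), layers)$value)
  scale <- c(3, 2, 1)[as.integer(layers)]  # the layer-bias mechanism
  scaled <- ce(dplus * scale, dminus * scale)
  expect_equal(metric_voxel_ratio(scaled, layers)$value, base$vr)
  expect_equal(metric_roi_ratio(scaled, layers)$value, base$rr)
  expect_equal(metric_deming(scaled, layers)$value, base$dm)
})

test_that("L2 normalization rescales condition betas per voxel", {
  layers <- factor(rep(layer_names(), each = 1), levels = layer_names())
  b <- rbind(c(3, 4, 0, 0), c(1, 1, 1, 1), c(0.2, 0.2, 0.4, 0.2))
  colnames(b) <- c("H45", "H135", "F45", "F135")
  p <- metric_l2norm(list(fake_fit(b)), layers)
  # betas [3,4,0,0] normalize to [0.6,0.8,0,0]; contrast F - H = -1.4
  expect_equal(p$value[1], 0 + 0 - 0.6 - 0.8)
  # per-voxel rescale leaves the metric unchanged
  p2 <- metric_l2norm(list(fake_fit(b * c(10, 0.3, 2))), layers)
  expect_equal(p2$value, p$value)
  # zero-norm voxels are excluded
  b0 <- b; b0[2, ] <- 0
  p0 <- metric_l2norm(list(fake_fit(b0)), layers)
  expect_true(is.na(p0$value[2]))
})

test_that("SVM metric is perfect on separable patterns, chance on labels", {
  set.seed(21)
  layers <- factor(rep(layer_names(), each = 4), levels = layer_names())
  n_blocks <- 8
  make_run <- function(sep) {
    lab <- sample(rep(c("face", "house"), n_blocks / 2))
    betas <- matrix(rnorm(12 * n_blocks, sd = 0.5), 12, n_blocks)
    betas[, lab == "face"] <- betas[, lab == "face"] + sep
    list(betas = betas, labels = lab)
  }
  runs <- replicate(4, make_run(sep = 10), simplify = FALSE)
  p <- metric_svm(lapply(runs, `[[`, "betas"),
                  lapply(runs, `[[`, "labels"), layers)
  expect_equal(p$value, c(1, 1, 1))
  # permuted labels: accuracy near chance over repeats
  accs <- replicate(60, {
    runs <- replicate(4, make_run(sep = 0), simplify = FALSE)
    metric_svm(lapply(runs, `[[`, "betas"),
               lapply(runs, `[[`, "labels"), layers)$value[1]
  })
  expect_lt(abs(mean(accs) - 0.5), 0.06)
  expect_true(all(accs >= 0 & accs <= 1))
})

test_that("svm_train solves the margin problem on a hand-checkable case", {
  # two points per class on a line: maximum margin boundary at x = 0
  x <- matrix(c(-2, -1, 1, 2), ncol = 1)
  y <- c("a", "a", "b", "b")
  fit <- svm_train(x, y, C = 1)
  expect_equal(predict(fit, matrix(c(-0.5, 0.5), ncol = 1)), c("a", "b"))
  expect_equal(fit$b / fit$w, 0, tolerance = 1e-4)
  expect_error(svm_train(x, rep("a", 4)), "two classes")
})

test_that("LDC reduces to the whitened pattern product", {
  layers <- factor(rep(layer_names(), each = 2), levels = layer_names())
  cond <- c("H45", "H135", "F45", "F135")
  # residuals whose (centered) sample covariance is exactly the identity:
  # orthonormal mean-zero columns scaled by sqrt(t_n)
  res_unit <- function(n_vox, t_n = 40) {
    r <- matrix(rnorm(n_vox * t_n), t_n, n_vox)
    q <- qr.Q(qr(cbind(1, r)))[, -1, drop = FALSE]
    t(q * sqrt(t_n))
  }
  # identical contrast pattern in train and test
  cpat <- c(2, -1)
  mk_fit <- function() {
    b <- matrix(0, 6, 4, dimnames = list(NULL, cond))
    b[, c("F45", "F135")] <- rep(cpat, 3)   # face - house mean = cpat
    fake_fit(b, rbind(res_unit(2), res_unit(2), res_unit(2)))
  }
  fits <- replicate(4, mk_fit(), simplify = FALSE)
  p <- metric_ldc(fits, layers)
  expect_equal(p$value, rep(sum(cpat^2) / sqrt(2), 3), tolerance = 1e-8)
  # zero test pattern gives zero statistic: all-zero betas
  zfits <- replicate(4, fake_fit(matrix(0, 6, 4,
                                        dimnames = list(NULL, cond)),
                                 rbind(res_unit(2), res_unit(2),
                                       res_unit(2))),
                     simplify = FALSE)
  expect_equal(metric_ldc(zfits, layers)$value, rep(0, 3))
})

test_that("LDC matches a dense small-instance oracle", {
  set.seed(22)
  layers <- factor(rep("superficial", 5), levels = layer_names())
  cond <- c("H45", "H135", "F45", "F135")
  fits <- replicate(4, {
    b <- matrix(rnorm(5 * 4), 5, 4, dimnames = list(NULL, cond))
    fake_fit(b, matrix(rnorm(5 * 30), 5, 30))
  }, simplify = FALSE)
  p <- metric_ldc(fits, layers)
  # independent dense recomputation
  con <- lapply(fits, function(f)
    (f$betas[, "F45"] + f$betas[, "F135"]) / 2 -
      (f$betas[, "H45"] + f$betas[, "H135"]) / 2)
  stats <- sapply(1:4, function(te) {
    tr <- setdiff(1:4, te)
    ct <- Reduce(`+`, con[tr]) / 3
    res <- do.call(rbind, lapply(tr, function(r) t(fits[[r]]$residuals)))
    sg <- shrink_cov_diag(res)$sigma
    drop(t(ct) %*% solve(sg) %*% con[[te]])
  })
  expect_equal(p$value[1], mean(stats) / sqrt(5), tolerance = 1e-10)
  expect_true(all(is.na(p$value[2:3])) || all(p$n_voxels[2:3] == 0))
})

test_that("shrinkage covariance is well-conditioned and sensible", {
  set.seed(23)
  # more variables than samples: raw covariance singular, shrunk invertible
  x <- matrix(rnorm(20 * 40), 20, 40)
  sc <- shrink_cov_diag(x)
  expect_gte(sc$lambda, 0); expect_lte(sc$lambda, 1)
  expect_no_error(solve(sc$sigma))
  expect_equal(diag(sc$sigma), diag(crossprod(sweep(x, 2, colMeans(x))) / 20))
  # truly diagonal covariance: full shrinkage to the diagonal is optimal
  x1 <- matrix(rnorm(5000 * 3), 5000, 3)
  sc1 <- shrink_cov_diag(x1)
  expect_gt(sc1$lambda, 0.5)
  expect_equal(sc1$sigma, diag(3), tolerance = 0.08)
  # strongly correlated truth with many samples: little shrinkage
  truth <- matrix(0.7, 3, 3); diag(truth) <- 1
  x2 <- matrix(rnorm(20000 * 3), 20000, 3) %*% chol(truth)
  sc2 <- shrink_cov_diag(x2)
  expect_lt(sc2$lambda, 0.05)
  expect_equal(sc2$sigma, truth, tolerance = 0.05)
})

test_that("raw contrast profile reflects uncorrected layer means", {
  layers <- factor(rep(layer_names(), each = 2), levels = layer_names())
  c1 <- ce(c(9, 11, 4, 6, 1, 3), rep(1, 6))
  expect_equal(raw_contrast_profile(c1, layers)$value, c(10, 5, 2))
  expect_equal(raw_contrast_profile(ce(rep(0, 6), rep(0, 6)), layers)$value,
               c(0, 0, 0))
})

test_that("contribution scores project the mean-normalized profile", {
  s <- contribution_scores(c(3, 2, 3))
  expect_equal(s, c(bias = 0, attention = 0.375))
  expect_equal(contribution_scores(c(3, 2, 1)),
               c(bias = 1, attention = 0))
  expect_equal(contribution_scores(c(4.2, 4.2, 4.2)),
               c(bias = 0, attention = 0))
  expect_true(all(is.na(contribution_scores(c(1, 0, -1)))))
  p <- laminar_profile("deming", c(3, 2, 3), c(10, 10, 10))
  expect_equal(contribution_scores(p), c(bias = 0, attention = 0.375))
})
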