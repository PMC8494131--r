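test_that("design matrices have the decided layout", {
  d <- make_default_design()
  sch <- generate_schedules(d, seed = 12)
  k <- hrf_kernel(hrf_params(), d$tr)
  Xc <- build_design_matrix(sch[[1]], k, "per_condition")
  expect_equal(ncol(Xc), 4 + 4)
  expect_equal(nrow(Xc), 160)
  expect_equal(attr(Xc, "condition_cols"), 1:4)
  Xb <- build_design_matrix(sch[[1]], k, "per_block")
  expect_equal(ncol(Xb), 20 + 4)
  expect_equal(qr(Xb)$rank, 24)
  # nuisance block is schedule-independent
  Xc2 <- build_design_matrix(sch[[3]], k, "per_condition")
  expect_equal(Xc[, 5:8], Xc2[, 5:8], ignore_attr = TRUE)
})

test_that("OLS fit matches the normal-equations oracle", {
  set.seed(13)
  X <- cbind(rnorm(30), rnorm(30), 1)
  colnames(X) <- c("r1", "r2", "intercept")
  y <- matrix(rnorm(5 * 30), 5, 30)
  fit <- fit_glm(y, X)
  oracle <- t(solve(crossprod(X), crossprod(X, t(y))))
  expect_equal(unname(fit$betas), unname(oracle), tolerance = 1e-10)
  # residuals orthogonal to the design
  expect_lt(max(abs(fit$residuals %*% X)), 1e-9)
  # exact recovery in a noiseless fit
  y0 <- outer(c(5, -2), X[, 1])
  fit0 <- fit_glm(y0, X)
  expect_equal(unname(fit0$betas[, 1]), c(5, -2))
  expect_equal(max(abs(fit0$residuals)), 0, tolerance = 1e-10)
  # constant offsets go to the intercept only
  fit1 <- fit_glm(y + 7, X)
  expect_equal(fit1$betas[, 1:2], fit$betas[, 1:2], tolerance = 1e-10)
  expect_equal(fit1$betas[, 3], fit$betas[, 3] + 7, tolerance = 1e-10)
})

test_that("nuisance regressors absorb trends and slow sinusoids", {
  d <- tiny_design()
  sch <- generate_schedules(d, seed = 14)
  attn <- attention_profile(c(3, 2, 3))
  vox <- make_vox(c(1.2, 0.5), c(0.3, 0.9), c("superficial", "deep"))
  ses <- simulate_session(vox, attn, sch,
                          noise = noise_params(sigma_p = 0, sigma_t = 0))
  X <- build_design_matrix(sch[[1]], ses$kernel, "per_condition")
  base <- fit_glm(ses$runs[[1]]$y, X)
  t_sec <- (seq_len(sch[[1]]$n_volumes) - 1) * d$tr
  drift <- 0.8 * t_sec + 5 * sin(2 * pi * t_sec / max(t_sec + d$tr)) + 3
  fit <- fit_glm(sweep(ses$runs[[1]]$y, 2, -drift), X)
  expect_equal(fit$betas[, 1:4], base$betas[, 1:4], tolerance = 1e-6)
})

test_that("contrast estimates recover the selectivity exactly without noise", {
  d <- tiny_design()
  sub <- local({
    set.seed(15)
    scales <- c(sd_face = 1.1, sd_house = 0.5)
    vox <- sample_voxels(30, scales)
    sch <- generate_schedules(d)
    ses <- simulate_session(vox, attention_profile(c(3, 2, 3)), sch,
                            bias = layer_bias(c(3, 2, 1)),
                            noise = noise_params(sigma_p = 0, sigma_t = 0))
    Xs <- lapply(sch, build_design_matrix, kernel = ses$kernel,
                 mode = "per_condition")
    fits <- lapply(seq_along(sch), function(r) fit_glm(ses$runs[[r]]$y, Xs[[r]]))
    list(ce = contrast_estimates(fits, sch), vox = vox, fits = fits, sch = sch)
  })
  a <- c(3, 2, 3)[as.integer(sub$vox$layer)]
  ok <- sub$vox$n_face != sub$vox$n_house
  expect_equal(sub$ce$taskdplus[ok] / sub$ce$taskdminus[ok], 1 - 1 / a[ok],
               tolerance = 1e-9)
  # flipping the preference sign flips both contrasts
  ce2 <- contrast_estimates(sub$fits, sub$sch, preference_sign = -1)
  expect_equal(ce2$taskdplus, -sub$ce$taskdplus)
  # zero data give zero contrasts
  zfits <- lapply(seq_along(sub$sch), function(r) {
    X <- build_design_matrix(sub$sch[[r]],
                             hrf_kernel(hrf_params(), d$tr), "per_condition")
    fit_glm(matrix(0, 3, sub$sch[[r]]$n_volumes), X)
  })
  cez <- contrast_estimates(zfits, sub$sch)
  expect_equal(cez$taskdplus, rep(0, 3))
})

test_that("GLM betas are unbiased under the full noise model", {
  d <- tiny_design()
  set.seed(16)
  sch <- generate_schedules(d)
  vox <- make_vox(1.5, 0.2, "superficial")
  attn <- attention_profile(c(3, 2, 3))
  truth <- simulate_session(vox, attn, sch[1],
                            noise = noise_params(sigma_p = 0, sigma_t = 0),
                            bias = layer_bias(c(1, 1, 1)), keep_clean = TRUE)
  X <- build_design_matrix(sch[[1]], truth$kernel, "per_condition")
  beta_true <- fit_glm(truth$runs[[1]]$h, X)$betas
  noisy <- replicate(300, {
    ses <- simulate_session(vox, attn, sch[1], bias = layer_bias(c(1, 1, 1)))
    fit_glm(ses$runs[[1]]$y, X)$betas[1, 1:4]
  })
  # mean over simulations close to truth within Monte-Carlo error (~3 SEM)
  sem <- apply(noisy, 1, sd) / sqrt(ncol(noisy))
  expect_true(all(abs(rowMeans(noisy) - beta_true[1, 1:4]) < 4 * sem + 0.05))
})

test_that("z-scoring normalizes per voxel and flags degenerate series", {
  set.seed(17)
  y <- matrix(rnorm(5 * 40, mean = 3, sd = 2), 5, 40)
  z <- zscore_timeseries(y)
  expect_equal(rowMeans(z$y), rep(0, 5), tolerance = 1e-12)
  expect_equal(apply(z$y, 1, sd), rep(1, 5), tolerance = 1e-12)
  expect_length(z$degenerate, 0)
  # scale invariance
  z10 <- zscore_timeseries(y * 10)
  expect_equal(z10$y, z$y)
  # constant voxel flagged
  y[2, ] <- 4
  z2 <- zscore_timeseries(y)
  expect_equal(z2$degenerate, 2L)
  expect_true(all(is.na(z2$y[2, ])))
})

test_that("contrast t-statistics match the textbook OLS formula", {
  d <- tiny_design()
  set.seed(18)
  sch <- generate_schedules(d)
  vox <- make_vox(c(1.4, 0.2), c(0.1, 0.8), c("superficial", "deep"))
  ses <- simulate_session(vox, attention_profile(c(3, 2, 3)), sch)
  X <- build_design_matrix(sch[[1]], ses$kernel, "per_condition")
  fit <- fit_glm(ses$runs[[1]]$y, X)
  tt <- contrast_tstats(list(fit), list(X))
  # oracle: lm() with the same design, voxel 1
  df <- data.frame(y = ses$runs[[1]]$y[1, ], X[, -5])
  lmfit <- stats::lm(y ~ . , data = df)
  # intercept first in lm; then H45, H135, F45, F135, linear, sin1, cos1
  cvec <- c(0, -1, -1, 1, 1, 0, 0, 0)
  est <- sum(cvec * stats::coef(lmfit))
  se <- sqrt(drop(t(cvec) %*% stats::vcov(lmfit) %*% cvec))
  expect_equal(tt[1], est / se, tolerance = 1e-8)
  # degenerate cases
  expect_error(contrast_tstats(list(fake_fit(fit$betas,
                                             fit$residuals * 0)), list(X)),
               "zero residual variance")
})
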