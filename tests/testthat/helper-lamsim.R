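# Shared fixtures and oracles, built in code.

# A small design keeping unit tests fast: 2 runs of 4 blocks, 2 trials/block.
tiny_design <- function() {
  design_spec(n_taskdplus_runs = 1L, n_taskdminus_runs = 1L,
              blocks_per_run = 4L, trials_per_block = 2L)
}

# Hand-built voxel population for exact-value tests.
make_vox <- function(n_face, n_house, layer) {
  stopifnot(length(n_face) == length(n_house),
            length(layer) == length(n_face))
  structure(list(n_face = as.numeric(n_face),
                 n_house = as.numeric(n_house),
                 layer = factor(layer, levels = layer_names()),
                 n_voxels = length(n_face)),
            class = "voxel_population")
}

# Fake per-condition GLM fit for metric-level tests.
fake_fit <- function(betas, residuals = NULL) {
  if (is.null(residuals)) residuals <- matrix(0, nrow(betas), 2)
  list(betas = betas, residuals = residuals)
}

# Independent Deming oracle: numeric minimizer of the summed squared
# perpendicular distances. The minimizing line passes through the centroid,
# so parameterize it by its angle, scan a fine grid, and refine the best
# bracket with 1-D optimization. Stays independent of the closed form.
deming_oracle <- function(x, y) {
  xc <- x - mean(x); yc <- y - mean(y)
  perp_sse <- function(theta) sum((-sin(theta) * xc + cos(theta) * yc)^2)
  grid <- seq(0, pi, length.out = 2001)
  i <- which.min(vapply(grid, perp_sse, numeric(1)))
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  theta <- stats::optimize(perp_sse, c(lo, hi), tol = 1e-14)$minimum
  tan(theta)
}

# Memoized Monte-Carlo runs shared between acceptance criteria (the
# selective-scenario summary feeds both the metric-ranking and the
# high-noise convergence checks).
.acceptance_cache <- new.env(parent = emptyenv())

acceptance_mc <- function(name, n_voxels, metrics, n_iterations = 200L) {
  key <- paste(name, n_voxels, paste(metrics, collapse = "+"), n_iterations)
  if (!is.null(.acceptance_cache[[key]])) return(.acceptance_cache[[key]])
  sm <- run_monte_carlo(scenario(name, n_voxels = n_voxels),
                        n_iterations = n_iterations, base_seed = 1L,
                        metrics = metrics)
  .acceptance_cache[[key]] <- sm
  sm
}

median_profile <- function(sm, metric) {
  p <- sm$profiles[sm$profiles$metric == metric, ]
  p$median[match(layer_names(), p$layer)]
}

median_bias <- function(sm, metric) {
  sm$scores$bias_median[sm$scores$metric == metric]
}

median_attention <- function(sm, metric) {
  sm$scores$attention_median[sm$scores$metric == metric]
}

layer_iqr <- function(sm, metric) {
  it <- sm$iterations[sm$iterations$metric == metric, ]
  vapply(layer_names(), function(l)
    stats::IQR(it$value[it$layer == l], na.rm = TRUE), numeric(1))
}
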