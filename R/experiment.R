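#' Simulation scenario
#'
#' Bundles the generative parameters for one named regime:
#' * `selective`: the defaults -- attention gains `c(3, 2, 3)`, half-normal
#'   scales 1.1 (face) / 0.5 (house), sigma_p 11, sigma_t 15, 2500 voxels.
#' * `no_preference`: both categories folded-normal(0, 0.7), so the region
#'   has no mean category preference; otherwise defaults.
#' * `high_noise`: sigma_p 20, sigma_t 30; otherwise defaults.
#' * `noiseless`: sigma_p = sigma_t = 0; otherwise defaults.
#' * `custom`: start from defaults, then override.
#'
#' @param name Scenario name.
#' @param attn,pop,noise,bias,design Optional overrides (see
#'   [attention_profile()], [population_params()], [noise_params()],
#'   [layer_bias()], [design_spec()]).
#' @param n_voxels Number of voxels (default 2500).
#' @param preference_sign +1 for a face-preferring region.
#' @return An object of class `scenario`.
#' @export
scenario <- function(name = c("selective", "no_preference", "high_noise",
                              "noiseless", "custom"),
                     attn = NULL, pop = NULL, noise = NULL, bias = NULL,
                     design = NULL, n_voxels = 2500L, preference_sign = 1) {
  name <- match.arg(name)
  if (is.null(noise)) {
    noise <- switch(name,
                    high_noise = noise_params(sigma_p = 20, sigma_t = 30),
                    noiseless = noise_params(sigma_p = 0, sigma_t = 0),
                    noise_params())
  }
  if (is.null(pop)) {
    pop <- if (name == "no_preference") population_params_no_preference()
           else population_params()
  }
  structure(list(name = name,
                 attn = if (is.null(attn)) attention_profile() else attn,
                 pop = pop,
                 noise = noise,
                 bias = if (is.null(bias)) layer_bias() else bias,
                 design = if (is.null(design)) make_default_design() else design,
                 n_voxels = as.integer(n_voxels),
                 preference_sign = preference_sign),
            class = "scenario")
}

#' Simulate one subject and fit the GLMs
#'
#' One Monte-Carlo iteration's data pipeline up to the contrast estimates:
#' sample subject scales and the voxel population, draw randomized block
#' schedules, simulate the 8-run session, fit per-condition GLMs to every
#' run, and average the face-house contrast over runs per context.
#'
#' @param scn A `scenario`.
#' @param seed Integer seed making the subject fully reproducible.
#' @return List with `session`, `schedules`, `fits` (per-condition GLM per
#'   run), `Xs`, `contrasts` (a `contrast_estimates`), `layers`, `scales`.
#' @export
simulate_subject <- function(scn, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  scales <- sample_subject_scales(scn$pop)
  vox <- sample_voxels(scn$n_voxels, scales)
  schedules <- generate_schedules(scn$design)
  session <- simulate_session(vox, scn$attn, schedules,
                              bias = scn$bias, noise = scn$noise)
  Xs <- lapply(schedules, build_design_matrix, kernel = session$kernel,
               mode = "per_condition")
  fits <- lapply(seq_along(schedules), function(r)
    fit_glm(session$runs[[r]]$y, Xs[[r]]))
  contrasts <- contrast_estimates(fits, schedules, scn$preference_sign)
  list(session = session, schedules = schedules, fits = fits, Xs = Xs,
       contrasts = contrasts, layers = vox$layer, scales = scales)
}

#' Names of the laminar profiles computed per iteration
#'
#' The seven bias-correction metrics plus the uncorrected raw contrast
#' baseline.
#' @return Character vector of metric identifiers.
#' @export
all_metric_names <- function() {
  c("raw_contrast", "voxel_ratio", "roi_ratio", "deming", "zscore",
    "l2norm", "svm", "ldc")
}

#' Run one Monte-Carlo iteration (one simulated subject)
#'
#' @param scn A `scenario`.
#' @param seed Integer seed.
#' @param metrics Which metrics to compute (default all eight profiles,
#'   including the uncorrected raw contrast).
#' @return List of class `iteration_result` with `seed`, `profiles` (stacked
#'   `laminar_profile` rows) and `scores` (per-metric bias/attention
#'   contribution scores).
#' @export
run_iteration <- function(scn, seed, metrics = all_metric_names()) {
  stopifnot(all(metrics %in% all_metric_names()))
  sub <- simulate_subject(scn, seed)
  dplus_idx <- which(vapply(sub$schedules, function(s) s$context,
                            character(1)) == "TaskD+")
  profiles <- list()
  if ("raw_contrast" %in% metrics) {
    profiles$raw_contrast <- raw_contrast_profile(sub$contrasts, sub$layers)
  }
  if ("voxel_ratio" %in% metrics) {
    profiles$voxel_ratio <- metric_voxel_ratio(sub$contrasts, sub$layers)
  }
  if ("roi_ratio" %in% metrics) {
    profiles$roi_ratio <- metric_roi_ratio(sub$contrasts, sub$layers)
  }
  if ("deming" %in% metrics) {
    profiles$deming <- metric_deming(sub$contrasts, sub$layers)
  }
  if ("zscore" %in% metrics) {
    profiles$zscore <- metric_zscore(sub$session, sub$layers,
                                     scn$preference_sign)
  }
  if ("l2norm" %in% metrics) {
    profiles$l2norm <- metric_l2norm(sub$fits[dplus_idx], sub$layers,
                                     scn$preference_sign)
  }
  if ("svm" %in% metrics) {
    bb <- lapply(dplus_idx, function(r) {
      X <- build_design_matrix(sub$schedules[[r]], sub$session$kernel,
                               mode = "per_block")
      fit <- fit_glm(sub$session$runs[[r]]$y, X)
      fit$betas[, attr(X, "condition_cols"), drop = FALSE]
    })
    labels <- lapply(dplus_idx, function(r)
      sub$schedules[[r]]$blocks$attended_category)
    profiles$svm <- metric_svm(bb, labels, sub$layers)
  }
  if ("ldc" %in% metrics) {
    profiles$ldc <- metric_ldc(sub$fits[dplus_idx], sub$layers,
                               scn$preference_sign)
  }
  scores <- do.call(rbind, lapply(names(profiles), function(m) {
    cs <- contribution_scores(profiles[[m]])
    data.frame(metric = m, bias = cs[["bias"]], attention = cs[["attention"]],
               stringsAsFactors = FALSE)
  }))
  structure(list(seed = seed,
                 profiles = do.call(rbind, unname(profiles)),
                 scores = scores),
            class = "iteration_result")
}

#' Derive per-iteration child seeds from a base seed
#' @param base_seed Integer.
#' @param n Number of seeds.
#' @return Integer vector; depends only on `(base_seed, n index)`, so
#'   summaries are invariant to execution order or worker count.
#' @export
iteration_seeds <- function(base_seed, n) {
  set.seed(base_seed)
  sample.int(.Machine$integer.max, n)
}

#' Monte-Carlo benchmark of the bias-correction metrics
#'
#' Repeats [run_iteration()] over independently seeded simulated subjects
#' and summarizes each metric's laminar profile and contribution scores by
#' the median and 25th/75th percentiles.
#'
#' @param scn A `scenario`.
#' @param n_iterations Number of simulated subjects (reference setting
#'   10000; desk default 200).
#' @param base_seed Base seed for the deterministic seed ladder.
#' @param metrics Metrics to compute (see [run_iteration()]).
#' @param workers Parallel workers via `parallel::mclapply`; results do not
#'   depend on this.
#' @return Object of class `monte_carlo_summary`: list with `profiles`
#'   (metric x layer medians and quartiles), `scores` (per-metric bias and
#'   attention score quantiles), `iterations` (long per-iteration table),
#'   `n_iterations`, `scenario_name`.
#' @export
run_monte_carlo <- function(scn, n_iterations = 200L, base_seed = 1L,
                            metrics = all_metric_names(), workers = 1L) {
  stopifnot(n_iterations >= 1)
  seeds <- iteration_seeds(base_seed, n_iterations)
  runner <- function(i) run_iteration(scn, seeds[i], metrics = metrics)
  iters <- if (workers > 1L) {
    parallel::mclapply(seq_len(n_iterations), runner, mc.cores = workers)
  } else {
    lapply(seq_len(n_iterations), runner)
  }
  long <- do.call(rbind, lapply(seq_along(iters), function(i)
    cbind(iteration = i, iters[[i]]$profiles)))
  score_long <- do.call(rbind, lapply(seq_along(iters), function(i)
    cbind(iteration = i, iters[[i]]$scores)))
  q <- function(x) stats::quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE,
                                   names = FALSE)
  prof <- do.call(rbind, lapply(split(long, long[c("metric", "layer")]),
                                function(d) {
    if (!nrow(d)) return(NULL)
    qq <- q(d$value)
    data.frame(metric = d$metric[1], layer = d$layer[1],
               p25 = qq[1], median = qq[2], p75 = qq[3],
               stringsAsFactors = FALSE)
  }))
  rownames(prof) <- NULL
  sc <- do.call(rbind, lapply(split(score_long, score_long$metric),
                              function(d) {
    qb <- q(d$bias); qa <- q(d$attention)
    data.frame(metric = d$metric[1],
               bias_p25 = qb[1], bias_median = qb[2], bias_p75 = qb[3],
               attention_p25 = qa[1], attention_median = qa[2],
               attention_p75 = qa[3], stringsAsFactors = FALSE)
  }))
  rownames(sc) <- NULL
  structure(list(profiles = prof, scores = sc, iterations = long,
                 iteration_scores = score_long,
                 n_iterations = n_iterations, base_seed = base_seed,
                 scenario_name = scn$name),
            class = "monte_carlo_summary")
}

#' Pooled Deming slope over all voxels (layers ignored)
#'
#' The slope of the best-fit orthogonal-regression line through the
#' TaskD+ vs TaskD- scatter of one simulated subject, pooled over the whole
#' region. With the default selective parameters this reproduces the
#' simulated scatter gradient of about 0.65.
#'
#' @param scn A `scenario`.
#' @param seed Integer seed.
#' @param delta Deming error-variance ratio.
#' @return A single slope value.
#' @export
pooled_deming_slope <- function(scn, seed = NULL, delta = 1) {
  sub <- simulate_subject(scn, seed)
  deming_slope(sub$contrasts$taskdminus, sub$contrasts$taskdplus,
               delta = delta)
}

#' Sweep scenario parameters over a grid
#'
#' @param base A `scenario` to start from.
#' @param grid Named list of vectors over any of `sigma_p`, `sigma_t`,
#'   `a_middle`, `a_outer`, `sd_face`, `sd_house`, `n_voxels`; the full
#'   cross product is run.
#' @param n_iterations Iterations per grid cell.
#' @param base_seed Base seed (reused for every cell so cells differ only by
#'   parameters).
#' @param metrics Metrics to compute.
#' @return Long-format data.frame: one row per cell x metric x layer with
#'   quartiles, plus the cell's parameter columns.
#' @export
parameter_sweep <- function(base, grid, n_iterations = 50L, base_seed = 1L,
                            metrics = c("raw_contrast", "voxel_ratio",
                                        "roi_ratio", "deming")) {
  allowed <- c("sigma_p", "sigma_t", "a_middle", "a_outer", "sd_face",
               "sd_house", "n_voxels")
  stopifnot(all(names(grid) %in% allowed), length(grid) >= 1)
  cells <- expand.grid(grid, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(cells)), function(i) {
    cell <- cells[i, , drop = FALSE]
    scn <- base
    if (!is.null(cell$sigma_p)) scn$noise$sigma_p <- cell$sigma_p
    if (!is.null(cell$sigma_t)) scn$noise$sigma_t <- cell$sigma_t
    if (!is.null(cell$a_outer) || !is.null(cell$a_middle)) {
      a <- unclass(scn$attn)
      if (!is.null(cell$a_outer)) a[c(1, 3)] <- cell$a_outer
      if (!is.null(cell$a_middle)) a[2] <- cell$a_middle
      scn$attn <- attention_profile(a)
    }
    if (!is.null(cell$sd_face)) scn$pop$sd_face <- cell$sd_face
    if (!is.null(cell$sd_house)) scn$pop$sd_house <- cell$sd_house
    if (!is.null(cell$n_voxels)) scn$n_voxels <- as.integer(cell$n_voxels)
    sm <- run_monte_carlo(scn, n_iterations, base_seed, metrics = metrics)
    cbind(cell, sm$profiles, row.names = NULL)
  })
  do.call(rbind, out)
}

#' Load real (or exported) per-voxel contrast estimates from CSV
#'
#' The univariate entry point for applying the ratio and Deming metrics to
#' measured data: a tidy table with columns `voxel_id`, `layer`,
#' `taskdplus`, `taskdminus` and layers labeled superficial/middle/deep.
#'
#' @param path CSV path.
#' @return List with `contrasts` (a `contrast_estimates`) and `layers`
#'   (factor).
#' @export
load_real_contrasts <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("voxel_id", "layer", "taskdplus", "taskdminus")
  if (!all(need %in% names(df))) {
    stop("contrast CSV must have columns: ", paste(need, collapse = ", "))
  }
  if (!all(df$layer %in% layer_names())) {
    stop("unknown layer labels: ",
         paste(setdiff(unique(df$layer), layer_names()), collapse = ", "))
  }
  if (!all(layer_names() %in% df$layer)) {
    stop("missing layers: ",
         paste(setdiff(layer_names(), unique(df$layer)), collapse = ", "))
  }
  if (!all(is.finite(df$taskdplus)) || !all(is.finite(df$taskdminus))) {
    stop("contrast values must be finite")
  }
  list(contrasts = structure(list(taskdplus = df$taskdplus,
                                  taskdminus = df$taskdminus),
                             class = "contrast_estimates"),
       layers = factor(df$layer, levels = layer_names()))
}

#' Export per-voxel contrast estimates as tidy CSV
#'
#' @param contrasts A `contrast_estimates`.
#' @param layers Layer factor.
#' @param path Output CSV path.
#' @return Invisibly, the exported data.frame.
#' @export
export_contrasts <- function(contrasts, layers, path) {
  df <- data.frame(voxel_id = seq_along(contrasts$taskdplus),
                   layer = as.character(layers),
                   taskdplus = contrasts$taskdplus,
                   taskdminus = contrasts$taskdminus,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Write Monte-Carlo outputs to a directory
#'
#' Emits `iterations.csv` (iteration, metric, layer, value), `summary.csv`,
#' `summary.json` and `run_metadata.json`.
#'
#' @param summary A `monte_carlo_summary`.
#' @param dir Output directory (created if needed).
#' @param scn The `scenario` that produced it (recorded in the metadata).
#' @return Invisibly, the directory.
#' @export
write_summary <- function(summary, dir, scn = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(summary$iterations[c("iteration", "metric", "layer",
                                        "value")],
                   file.path(dir, "iterations.csv"), row.names = FALSE)
  utils::write.csv(summary$profiles, file.path(dir, "summary.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(profiles = summary$profiles,
                            scores = summary$scores,
                            n_iterations = summary$n_iterations,
                            scenario = summary$scenario_name),
                       file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  meta <- list(scenario = summary$scenario_name,
               n_iterations = summary$n_iterations,
               base_seed = summary$base_seed,
               package_version = as.character(utils::packageVersion("lamsim")))
  if (!is.null(scn)) {
    meta$parameters <- list(
      attention = as.numeric(scn$attn),
      layer_bias = as.numeric(scn$bias),
      sigma_p = scn$noise$sigma_p, sigma_t = scn$noise$sigma_t,
      sd_face = scn$pop$sd_face, sd_house = scn$pop$sd_house,
      subject_sd = scn$pop$subject_sd,
      distribution_kind = scn$pop$distribution_kind,
      n_voxels = scn$n_voxels)
  }
  jsonlite::write_json(meta, file.path(dir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a flat key/value configuration file
#'
#' One `key: value` pair per line (a minimal YAML subset); `#` starts a
#' comment. Values are parsed as numeric where possible. Recognized keys
#' mirror the `scenario` fields: `scenario`, `n_voxels`, `sigma_p`,
#' `sigma_t`, `a_superficial`, `a_middle`, `a_deep`, `bias_superficial`,
#' `bias_middle`, `bias_deep`, `sd_face`, `sd_house`, `subject_sd`,
#' `n_iterations`, `seed`.
#'
#' @param path Config file path.
#' @return Named list of values.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    if (!grepl(":", ln, fixed = TRUE)) stop("bad config line: ", ln)
    key <- trimws(sub(":.*$", "", ln))
    val <- trimws(sub("^[^:]*:", "", ln))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

#' Build a scenario from a parsed configuration
#' @param cfg Named list from [read_config()].
#' @return A `scenario`.
#' @export
scenario_from_config <- function(cfg) {
  name <- if (is.null(cfg$scenario)) "selective" else cfg$scenario
  scn <- scenario(name)
  if (!is.null(cfg$n_voxels)) scn$n_voxels <- as.integer(cfg$n_voxels)
  if (!is.null(cfg$sigma_p)) scn$noise$sigma_p <- cfg$sigma_p
  if (!is.null(cfg$sigma_t)) scn$noise$sigma_t <- cfg$sigma_t
  a <- as.numeric(scn$attn)
  if (!is.null(cfg$a_superficial)) a[1] <- cfg$a_superficial
  if (!is.null(cfg$a_middle)) a[2] <- cfg$a_middle
  if (!is.null(cfg$a_deep)) a[3] <- cfg$a_deep
  scn$attn <- attention_profile(a)
  b <- as.numeric(scn$bias)
  if (!is.null(cfg$bias_superficial)) b[1] <- cfg$bias_superficial
  if (!is.null(cfg$bias_middle)) b[2] <- cfg$bias_middle
  if (!is.null(cfg$bias_deep)) b[3] <- cfg$bias_deep
  scn$bias <- layer_bias(b)
  if (!is.null(cfg$sd_face)) scn$pop$sd_face <- cfg$sd_face
  if (!is.null(cfg$sd_house)) scn$pop$sd_house <- cfg$sd_house
  if (!is.null(cfg$subject_sd)) scn$pop$subject_sd <- cfg$subject_sd
  scn
}
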