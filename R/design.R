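#' Experimental design specification
#'
#' Describes the blocked sustained-attention paradigm: four conditions
#' (attend houses / attend faces at one of two diagonal locations), run in
#' two contexts -- distractor present (`TaskD+`) and distractor absent
#' (`TaskD-`). All timings are in seconds and every block starts in sync
#' with a volume acquisition.
#'
#' @param tr Repetition time (s).
#' @param n_taskdplus_runs,n_taskdminus_runs Number of runs per context.
#' @param blocks_per_run Number of blocks in one run; must be a multiple of
#'   the number of conditions so the design is balanced.
#' @param trials_per_block Same/different trials per block.
#' @param cue_duration,post_cue_fixation Cue timing (s).
#' @param stim_duration,post_stim_fixation Per-trial timing (s).
#' @param rest_duration Fixation rest between blocks (s).
#' @param conditions Ordered condition labels.
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(tr = 2.39,
                        n_taskdplus_runs = 4L,
                        n_taskdminus_runs = 4L,
                        blocks_per_run = 20L,
                        trials_per_block = 10L,
                        cue_duration = 0.35,
                        post_cue_fixation = 0.55,
                        stim_duration = 0.95,
                        post_stim_fixation = 0.55,
                        rest_duration = 1.56,
                        conditions = c("H45", "H135", "F45", "F135")) {
  durations <- c(tr, cue_duration, post_cue_fixation, stim_duration,
                 post_stim_fixation, rest_duration)
  if (any(durations <= 0)) stop("all durations must be > 0")
  counts <- c(n_taskdplus_runs, n_taskdminus_runs, blocks_per_run,
              trials_per_block)
  if (any(counts <= 0)) stop("all counts must be > 0")
  if (blocks_per_run %% length(conditions) != 0L) {
    stop("blocks_per_run must be a multiple of the number of conditions")
  }
  structure(
    list(tr = tr,
         n_taskdplus_runs = as.integer(n_taskdplus_runs),
         n_taskdminus_runs = as.integer(n_taskdminus_runs),
         blocks_per_run = as.integer(blocks_per_run),
         trials_per_block = as.integer(trials_per_block),
         cue_duration = cue_duration,
         post_cue_fixation = post_cue_fixation,
         stim_duration = stim_duration,
         post_stim_fixation = post_stim_fixation,
         rest_duration = rest_duration,
         conditions = conditions),
    class = "design_spec")
}

#' Default design
#'
#' The default paradigm: TR 2.39 s, four `TaskD+` and four `TaskD-` runs of
#' 20 blocks each, blocks of 10 trials (0.35 s cue, 0.55 s fixation, then
#' 10 x (0.95 s stimulus + 0.55 s fixation)) and 1.56 s rest between blocks.
#'
#' @return A `design_spec`.
#' @export
make_default_design <- function() design_spec()

#' Active (modeled) duration of one block in seconds
#'
#' Cue + post-cue fixation + trials; excludes the inter-block rest.
#'
#' @param design A `design_spec`.
#' @return Duration in seconds (15.9 s for the default design).
#' @export
block_active_duration <- function(design) {
  design$cue_duration + design$post_cue_fixation +
    design$trials_per_block * (design$stim_duration + design$post_stim_fixation)
}

#' Volumes allotted to one block (active + rest), rounded up to whole TRs
#'
#' The printed block timing (15.9 s active + 1.56 s rest) is not an integer
#' number of TRs, yet every block starts in sync with a volume acquisition;
#' the slot is therefore rounded up to the next whole TR.
#'
#' @param design A `design_spec`.
#' @return Integer number of volumes per block slot.
#' @export
block_slot_volumes <- function(design) {
  as.integer(ceiling((block_active_duration(design) + design$rest_duration) /
                       design$tr))
}

attended_category <- function(condition) {
  ifelse(substr(condition, 1, 1) == "F", "face", "house")
}

#' Generate randomized block schedules for all runs
#'
#' One schedule per run. Within each run the conditions are shuffled in a
#' balanced order (each condition appears `blocks_per_run / n_conditions`
#' times), independently for every run. Block onsets sit on the TR grid.
#'
#' @param design A `design_spec`.
#' @param seed Optional integer seed; when `NULL` the current RNG state is
#'   used.
#' @return A list of `block_schedule` objects of length
#'   `n_taskdplus_runs + n_taskdminus_runs` (`TaskD+` runs first). Each has
#'   fields `run_id`, `context`, `blocks` (data.frame with `condition`,
#'   `attended_category`, `onset`, `duration`) and `n_volumes`.
#' @export
generate_schedules <- function(design, seed = NULL) {
  if (!inherits(design, "design_spec")) stop("design must be a design_spec")
  if (!is.null(seed)) set.seed(seed)
  n_cond <- length(design$conditions)
  reps <- design$blocks_per_run %/% n_cond
  slot <- block_slot_volumes(design)
  active <- block_active_duration(design)
  contexts <- c(rep("TaskD+", design$n_taskdplus_runs),
                rep("TaskD-", design$n_taskdminus_runs))
  lapply(seq_along(contexts), function(r) {
    order <- sample(rep(design$conditions, reps))
    onsets <- (seq_len(design$blocks_per_run) - 1L) * slot * design$tr
    blocks <- data.frame(
      condition = order,
      attended_category = attended_category(order),
      onset = onsets,
      duration = active,
      stringsAsFactors = FALSE)
    structure(
      list(run_id = r,
           context = contexts[r],
           blocks = blocks,
           tr = design$tr,
           slot_volumes = slot,
           n_volumes = design$blocks_per_run * slot),
      class = "block_schedule")
  })
}

#' Export a schedule as a BIDS-style events table
#'
#' @param schedule A `block_schedule`.
#' @param path Optional path; when given, written as tab-separated values.
#' @return Invisibly, a data.frame with columns `onset`, `duration`,
#'   `trial_type`.
#' @export
schedule_to_events <- function(schedule, path = NULL) {
  ev <- data.frame(onset = schedule$blocks$onset,
                   duration = schedule$blocks$duration,
                   trial_type = schedule$blocks$condition,
                   stringsAsFactors = FALSE)
  if (!is.null(path)) {
    utils::write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(ev)
}
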