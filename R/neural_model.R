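#' Population parameters for voxel neural counts
#'
#' Each voxel contains two purely selective neural populations (face-coding
#' and house-coding). Population counts are drawn from a half-normal
#' distribution whose scale controls category selectivity; in the
#' no-preference regime both categories share a folded-normal(0, 0.7)
#' distribution (identical to a half-normal with scale 0.7). Per-subject
#' scales are resampled from a truncated Gaussian around the population
#' value to emulate inter-subject variability.
#'
#' @param sd_face,sd_house Half-normal scales for a face-selective region
#'   (defaults 1.1 and 0.5).
#' @param subject_sd Standard deviation of the truncated Gaussian used to
#'   draw per-subject scales (default 0.25).
#' @param distribution_kind `"half_normal"` or `"folded_normal"`.
#' @param folded_mean Mean of the folded normal (0 in the no-preference
#'   scenario; only used for `"folded_normal"`).
#' @return An object of class `population_params`.
#' @export
population_params <- function(sd_face = 1.1, sd_house = 0.5,
                              subject_sd = 0.25,
                              distribution_kind = c("half_normal",
                                                    "folded_normal"),
                              folded_mean = 0) {
  distribution_kind <- match.arg(distribution_kind)
  stopifnot(sd_face >= 0, sd_house >= 0, subject_sd >= 0)
  structure(list(sd_face = sd_face, sd_house = sd_house,
                 subject_sd = subject_sd,
                 distribution_kind = distribution_kind,
                 folded_mean = folded_mean),
            class = "population_params")
}

#' No-preference population: folded normal(0, 0.7) for both categories
#' @param subject_sd Inter-subject scale sd (default 0.25).
#' @return A `population_params`.
#' @export
population_params_no_preference <- function(subject_sd = 0.25) {
  population_params(sd_face = 0.7, sd_house = 0.7, subject_sd = subject_sd,
                    distribution_kind = "folded_normal", folded_mean = 0)
}

#' Laminar attention profile
#'
#' Attention multiplies the response of neurons coding the attended category
#' by a gain `a >= 1` that varies by cortical layer. The default `c(3, 2, 3)`
#' (superficial, middle, deep) encodes a V-shaped profile: stronger
#' modulation in superficial and deep layers, as expected from feedback
#' connectivity.
#'
#' @param a Numeric length-3 vector of gains, ordered superficial, middle,
#'   deep.
#' @return A named numeric vector of class `attention_profile`.
#' @export
attention_profile <- function(a = c(3, 2, 3)) {
  stopifnot(length(a) == 3, all(is.finite(a)), all(a >= 1))
  structure(stats::setNames(as.numeric(a), layer_names()),
            class = "attention_profile")
}

#' Canonical layer labels, superficial first
#' @return Character vector `c("superficial", "middle", "deep")`.
#' @export
layer_names <- function() c("superficial", "middle", "deep")

#' Draw per-subject half-normal scales
#'
#' Each subject's scale is Gaussian around the population value with sd
#' `subject_sd`, truncated (by rejection) to `[0, 2 * population value]`.
#' With `subject_sd = 0` the population values are returned unchanged.
#'
#' @param pop A `population_params`.
#' @return Named numeric vector `c(sd_face=, sd_house=)`.
#' @export
sample_subject_scales <- function(pop) {
  draw <- function(mu) {
    if (pop$subject_sd == 0) return(mu)
    repeat {
      x <- stats::rnorm(1, mu, pop$subject_sd)
      if (x >= 0 && x <= 2 * mu) return(x)
    }
  }
  c(sd_face = draw(pop$sd_face), sd_house = draw(pop$sd_house))
}

#' Assign voxels to layers in contiguous near-equal thirds
#'
#' @param n_voxels Number of voxels.
#' @return Factor of length `n_voxels` with levels superficial, middle, deep.
#'   Any remainder voxels go to the earliest layers (2500 -> 834/833/833).
#' @export
assign_layers <- function(n_voxels) {
  base <- n_voxels %/% 3L
  rem <- n_voxels %% 3L
  sizes <- base + (seq_len(3L) <= rem)
  factor(rep(layer_names(), times = sizes), levels = layer_names())
}

#' Sample a voxel population
#'
#' Face and house neural counts are drawn i.i.d. per voxel from a
#' half-normal with the given subject scales (equivalently `|N(0, scale)|`;
#' the folded-normal no-preference mode with mean 0 reduces to the same
#' construction). Counts are kept continuous. Layers are assigned
#' deterministically in contiguous near-equal thirds.
#'
#' @param n_voxels Number of voxels (default 2500).
#' @param scales Named vector from [sample_subject_scales()] (or any
#'   `c(sd_face=, sd_house=)`).
#' @return An object of class `voxel_population` with fields `n_face`,
#'   `n_house` (numeric vectors), `layer` (factor) and `n_voxels`.
#' @export
sample_voxels <- function(n_voxels = 2500L, scales) {
  stopifnot(all(scales >= 0))
  structure(
    list(n_face = abs(stats::rnorm(n_voxels, 0, scales[["sd_face"]])),
         n_house = abs(stats::rnorm(n_voxels, 0, scales[["sd_house"]])),
         layer = assign_layers(n_voxels),
         n_voxels = as.integer(n_voxels)),
    class = "voxel_population")
}

#' Per-voxel attentional gain vector
#' @param vox A `voxel_population`.
#' @param attn An `attention_profile`.
#' @return Numeric vector: the gain of each voxel's layer.
#' @keywords internal
voxel_gains <- function(vox, attn) {
  unname(unclass(attn))[as.integer(vox$layer)]
}

#' Block response amplitude for every voxel
#'
#' The neural response summed over category populations: presented
#' categories fire at rate 1, the attended category's neurons are multiplied
#' by the layer's attentional gain. In the `TaskD+` context both categories
#' are presented; in `TaskD-` only the attended one.
#'
#' @param vox A `voxel_population`.
#' @param context `"TaskD+"` or `"TaskD-"`.
#' @param attended `"face"` or `"house"`.
#' @param attn An `attention_profile`.
#' @return Numeric vector of per-voxel amplitudes.
#' @export
block_amplitude <- function(vox, context, attended, attn) {
  stopifnot(context %in% c("TaskD+", "TaskD-"),
            attended %in% c("face", "house"))
  a <- voxel_gains(vox, attn)
  f_face <- if (context == "TaskD+") 1 else as.numeric(attended == "face")
  f_house <- if (context == "TaskD+") 1 else as.numeric(attended == "house")
  g_face <- if (attended == "face") a else 1
  g_house <- if (attended == "house") a else 1
  f_face * vox$n_face * g_face + f_house * vox$n_house * g_house
}

#' Noise-free ground-truth contrasts
#'
#' The attend-face minus attend-house difference of block amplitudes:
#' `r_dplus = (a - 1) (n_face - n_house)` in the distractor-present context
#' and `r_dminus = a (n_face - n_house)` in the distractor-absent context,
#' with `a` the voxel layer's gain. Their ratio is the selectivity
#' `S = 1 - 1/a` wherever `n_face != n_house`.
#'
#' @param vox A `voxel_population`.
#' @param attn An `attention_profile`.
#' @return List with numeric vectors `r_dplus` and `r_dminus`.
#' @export
true_contrasts <- function(vox, attn) {
  list(r_dplus = block_amplitude(vox, "TaskD+", "face", attn) -
         block_amplitude(vox, "TaskD+", "house", attn),
       r_dminus = block_amplitude(vox, "TaskD-", "face", attn) -
         block_amplitude(vox, "TaskD-", "house", attn))
}
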