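#' Configuration of a synthetic spine scene
#'
#' Describes the population of dendritic spines the generator emulates:
#' how many spines, the probability that a spine receives thalamocortical
#' (VGluT2+) input, the distribution of the number of trans-synaptically
#' aligned PSD-95/Bassoon nanomodules per spine for each input class, the
#' true cleft offset between paired PSD-95 and Bassoon centres, and the
#' spine volume model. Defaults reproduce the layer-5 basal-dendrite
#' population quantities used throughout the package's recovery
#' experiments: P(TC) = 68/507, corticocortical nanomodule-count pmf
#' (308, 107, 20, 4)/439 and thalamocortical pmf (44, 21, 3, 0)/68 over
#' counts 1..4, and a 140 nm cleft offset.
#'
#' @param n_spines number of spines to place.
#' @param p_tc probability that a spine is VGluT2+ (thalamocortical).
#' @param nanomodule_pmf_cc,nanomodule_pmf_tc probability vectors over
#'   nanomodule counts 1..4 for CC and TC spines; each must sum to 1.
#' @param cleft_offset_nm true centre separation of each PSD-95/Bassoon
#'   pair.
#' @param cleft_axis_mix fraction of pairs whose offset is axially
#'   dominant (Type B); the rest are laterally dominant (Type A). Within
#'   each type the polar angle is uniform on its 45-degree band and the
#'   azimuth is uniform.
#' @param cleft_theta_deg optional fixed polar angle (degrees from the
#'   optical axis) for every cleft offset, overriding `cleft_axis_mix`:
#'   90 gives pure-lateral pairs, 0 pure-axial.
#' @param nc_diameter_nm mean and sd of the intrinsic (pre-PSF) nanocluster
#'   FWHM; draws are clamped to \[80, 220\] nm.
#' @param spine_volume_base_um3,spine_volume_per_module_um3 linear spine
#'   volume model: `base + increment * nanomodule count` plus a positive
#'   lognormal perturbation.
#' @param spine_volume_noise_meanlog,spine_volume_noise_sdlog parameters of
#'   the additive lognormal volume noise.
#' @param exact_class_counts if `TRUE`, exactly `round(n_spines * p_tc)`
#'   spines are TC (class labels randomly permuted) instead of i.i.d.
#'   Bernoulli draws; used when emulating an observed population
#'   composition.
#' @param min_gap_nm minimum gap between spine head surfaces.
#' @param nc_margin_nm nanomodules are placed in the head interior at
#'   least this far from the head surface, so that a segmented
#'   nanocluster's thresholded footprint stays inside the spine mask on
#'   every grid (the package does not model the PSF-dilated morphology
#'   mask that makes this true for membrane-apposed PSDs in real data).
#' @param nc_min_separation_nm minimum centre separation between
#'   nanomodules within one spine.
#' @param vg_diameter_nm intrinsic FWHM of the presynaptic VGluT bouton
#'   blob rendered in the confocal channels.
#' @param seed RNG seed; identical (config, seed) pairs generate
#'   bit-identical scenes.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(n_spines = 50,
                         p_tc = 68 / 507,
                         nanomodule_pmf_cc = c(308, 107, 20, 4) / 439,
                         nanomodule_pmf_tc = c(44, 21, 3, 0) / 68,
                         cleft_offset_nm = 140,
                         cleft_axis_mix = 0.5,
                         cleft_theta_deg = NULL,
                         nc_diameter_nm = c(mean = 150, sd = 25),
                         spine_volume_base_um3 = 0.10,
                         spine_volume_per_module_um3 = 0.20,
                         spine_volume_noise_meanlog = log(0.04),
                         spine_volume_noise_sdlog = 0.5,
                         exact_class_counts = FALSE,
                         min_gap_nm = 500,
                         nc_margin_nm = 330,
                         nc_min_separation_nm = 300,
                         vg_diameter_nm = 300,
                         seed = 1L) {
  cfg <- list(n_spines = as.integer(n_spines), p_tc = p_tc,
              nanomodule_pmf_cc = nanomodule_pmf_cc,
              nanomodule_pmf_tc = nanomodule_pmf_tc,
              cleft_offset_nm = cleft_offset_nm,
              cleft_axis_mix = cleft_axis_mix,
              cleft_theta_deg = cleft_theta_deg,
              nc_diameter_nm = nc_diameter_nm,
              spine_volume_base_um3 = spine_volume_base_um3,
              spine_volume_per_module_um3 = spine_volume_per_module_um3,
              spine_volume_noise_meanlog = spine_volume_noise_meanlog,
              spine_volume_noise_sdlog = spine_volume_noise_sdlog,
              exact_class_counts = isTRUE(exact_class_counts),
              min_gap_nm = min_gap_nm, nc_margin_nm = nc_margin_nm,
              nc_min_separation_nm = nc_min_separation_nm,
              vg_diameter_nm = vg_diameter_nm,
              seed = as.integer(seed))
  validate_scene_config(cfg)
  structure(cfg, class = "scene_config")
}

validate_scene_config <- function(cfg) {
  stopifnot(cfg$n_spines >= 0,
            cfg$p_tc >= 0, cfg$p_tc <= 1,
            length(cfg$nanomodule_pmf_cc) == 4,
            length(cfg$nanomodule_pmf_tc) == 4,
            all(cfg$nanomodule_pmf_cc >= 0),
            all(cfg$nanomodule_pmf_tc >= 0),
            abs(sum(cfg$nanomodule_pmf_cc) - 1) < 1e-8,
            abs(sum(cfg$nanomodule_pmf_tc) - 1) < 1e-8,
            cfg$cleft_offset_nm >= 0,
            cfg$cleft_axis_mix >= 0, cfg$cleft_axis_mix <= 1,
            cfg$nc_diameter_nm[["mean"]] > 0,
            cfg$spine_volume_base_um3 > 0,
            cfg$spine_volume_per_module_um3 >= 0,
            cfg$min_gap_nm >= 0)
  invisible(cfg)
}

#' @export
print.scene_config <- function(x, ...) {
  cat(sprintf("scene_config: %d spines, P(TC) = %.3f, cleft offset %g nm, seed %d\n",
              x$n_spines, x$p_tc, x$cleft_offset_nm, x$seed))
  invisible(x)
}
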