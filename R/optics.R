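#' Optical model of one imaging channel
#'
#' The point-spread function is modelled as a separable 3D Gaussian,
#' parameterised by its lateral and axial full width at half maximum.
#' Detection is photon counting: the expected photon count at an isolated
#' emitter's peak voxel is `peak_photons`, a uniform `background_photons`
#' is added per voxel, and the recorded image is Poisson-distributed
#' around that expectation (no read noise).
#'
#' @param lateral_fwhm lateral (XY) PSF FWHM in nm.
#' @param axial_fwhm axial (Z) PSF FWHM in nm.
#' @param peak_photons expected photons in the peak voxel of an isolated
#'   emitter of unit amplitude.
#' @param background_photons expected background photons per voxel.
#' @return An object of class `optics_model`.
#' @export
optics_model <- function(lateral_fwhm, axial_fwhm, peak_photons = 8,
                         background_photons = 1) {
  stopifnot(lateral_fwhm > 0, axial_fwhm > 0, peak_photons > 0,
            background_photons >= 0)
  structure(list(lateral_fwhm = lateral_fwhm, axial_fwhm = axial_fwhm,
                 peak_photons = peak_photons,
                 background_photons = background_photons),
            class = "optics_model")
}

#' @export
print.optics_model <- function(x, ...) {
  cat(sprintf(paste0("optics_model: PSF %g nm lateral / %g nm axial FWHM, ",
                     "%g peak + %g background photons/voxel\n"),
              x$lateral_fwhm, x$axial_fwhm, x$peak_photons,
              x$background_photons))
  invisible(x)
}

#' Default STED-resolution optics (~50 nm lateral FWHM)
#'
#' The near-zero default background reflects lifetime-gated STED
#' acquisition: the simulated stacks are already background-removed, as
#' the analysis expects.
#'
#' @inheritParams optics_model
#' @return An `optics_model`.
#' @export
sted_optics <- function(peak_photons = 8, background_photons = 0.02)
  optics_model(50, 90, peak_photons, background_photons)

#' Default confocal optics (~250 nm lateral FWHM)
#' @inheritParams optics_model
#' @return An `optics_model`.
#' @export
confocal_optics <- function(peak_photons = 30, background_photons = 1)
  optics_model(250, 600, peak_photons, background_photons)
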