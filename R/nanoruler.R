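#' Nano-ruler calibration phantom
#'
#' Simulates DNA-origami nano-ruler beads: pairs of point emitters at a
#' designed spacing along a lateral or axial direction, placed at least
#' 1 um apart, rendered through the channel optics exactly as scene
#' emitters are. Each realised spacing is the designed spacing plus an
#' optional manufacturing jitter (the commercial rulers are specified to
#' +/- 5 nm).
#'
#' @param spacing_nm designed centre separation of each pair (>= 0; a
#'   spacing of 0 produces a single merged spot, which downstream peak
#'   separation must report as unresolved).
#' @param axis `"lateral"` (along x) or `"axial"` (along z).
#' @param n_pairs number of ruler pairs.
#' @param grid [voxel_grid()] to render on; defaults to a 20 nm XY grid
#'   with a 150 nm z-step for lateral rulers and a 50 nm z-step for axial
#'   rulers (the finer calibration sampling needed to resolve a ~90 nm
#'   axial spacing; see the methods vignette).
#' @param optics an [optics_model()]; defaults to STED resolution.
#' @param jitter_sd_nm SD of the Gaussian manufacturing jitter added to
#'   each realised spacing (0 disables it).
#' @param noise logical, Poisson noise on/off.
#' @param seed RNG seed.
#' @return List with `img` (array), `grid`, `optics`, and `truth` (data
#'   frame: pair id, designed and realised spacing, axis, pair centre).
#' @export
build_nanoruler_phantom <- function(spacing_nm, axis = c("lateral", "axial"),
                                    n_pairs = 40, grid = NULL,
                                    optics = sted_optics(),
                                    jitter_sd_nm = 2.5, noise = TRUE,
                                    seed = 1L) {
  axis <- match.arg(axis)
  stopifnot(spacing_nm >= 0, n_pairs >= 1)
  pitch <- 1000 + spacing_nm # pairs at least 1 um apart
  ncols <- ceiling(sqrt(n_pairs))
  nrows <- ceiling(n_pairs / ncols)
  if (is.null(grid)) {
    dz <- if (axis == "axial") 50 else 150
    zext <- if (axis == "axial") spacing_nm + 1200 else 900
    grid <- voxel_grid(c(ceiling(zext / dz),
                         ceiling((nrows * pitch + 1000) / 20),
                         ceiling((ncols * pitch + 1000) / 20)),
                       c(dz, 20, 20))
  }
  if (axis == "axial" && grid$shape[["z"]] < 5)
    stop("axial phantom needs at least 5 z-planes")

  with_seed(seed, {
    id <- seq_len(n_pairs)
    col <- (id - 1) %% ncols
    row <- (id - 1) %/% ncols
    # sub-voxel dither so pairs sample all grid phases
    cx <- 500 + (col + 0.5) * pitch + runif(n_pairs, -10, 10)
    cy <- 500 + (row + 0.5) * pitch + runif(n_pairs, -10, 10)
    zmid <- grid$origin[["z"]] + (grid$shape[["z"]] - 1) * grid$spacing[["z"]] / 2
    cz <- zmid + runif(n_pairs, -grid$spacing[["z"]] / 2, grid$spacing[["z"]] / 2)
    realized <- spacing_nm + if (jitter_sd_nm > 0)
      rnorm(n_pairs, 0, jitter_sd_nm) else 0
    realized <- pmax(0, realized)
    ux <- if (axis == "lateral") 1 else 0
    uz <- if (axis == "axial") 1 else 0
    emitters <- data.frame(
      channel = "ruler",
      x = c(cx - realized / 2 * ux, cx + realized / 2 * ux),
      y = c(cy, cy),
      z = c(cz - realized / 2 * uz, cz + realized / 2 * uz),
      size_nm = 0, amplitude = 1,
      spine_id = NA_integer_, module_id = c(id, id),
      stringsAsFactors = FALSE)
    r <- render_emitters(grid, emitters, optics)
    img <- r$img
    if (noise) {
      img[] <- rpois(length(img), img + optics$background_photons)
    } else {
      img <- img + optics$background_photons
    }
    truth <- data.frame(pair = id, designed_nm = spacing_nm,
                        realized_nm = realized, axis = axis,
                        x = cx, y = cy, z = cz, stringsAsFactors = FALSE)
    list(img = img, grid = grid, optics = optics, truth = truth,
         emitters = emitters)
  })
}
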