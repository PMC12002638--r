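#' Render a scene into noisy multi-channel image stacks
#'
#' Each emitter is rendered as an anisotropic Gaussian whose per-axis
#' variance is the quadrature sum of the emitter's intrinsic size and the
#' channel PSF; the Gaussian is integrated over each voxel (not point
#' sampled), scaled so an isolated emitter's brightest voxel has expected
#' count `amplitude * peak_photons`, background is added, and the stack
#' is Poisson sampled. The morphology channel (`yfp`) renders the spine
#' masks and a dendritic shaft, blurred by the channel PSF.
#'
#' @param scene a [build_scene()] result.
#' @param grids named list of [voxel_grid()]s per channel, or a list with
#'   elements `sted`/`confocal` as returned by [scene_grids()] (STED
#'   grids are used for `psd95`/`bassoon`, confocal for the rest).
#' @param optics named list of [optics_model()]s per channel, or a list
#'   with elements `sted`/`confocal`.
#' @param channels which channels to render; default all present in the
#'   scene plus `yfp`.
#' @param noise logical; `FALSE` returns the expected (noise-free) image.
#' @param seed RNG seed for the Poisson sampling; defaults to the scene
#'   seed.
#' @return Named list of channels; each element is a list with `img`
#'   (array `(nz, ny, nx)`), `grid`, `optics` and `emitter_integrals`
#'   (expected total photons contributed by each rendered emitter).
#' @export
render_channels <- function(scene, grids = scene_grids(scene),
                            optics = list(sted = sted_optics(),
                                          confocal = confocal_optics()),
                            channels = NULL, noise = TRUE, seed = NULL) {
  sted_ch <- c("psd95", "bassoon")
  if (is.null(channels))
    channels <- unique(c(as.character(scene$emitters$channel), "yfp"))
  seed <- seed %||% scene$config$seed
  out <- list()
  for (ci in seq_along(channels)) {
    ch <- channels[ci]
    g <- grids[[ch]] %||% (if (ch %in% sted_ch) grids$sted else grids$confocal)
    op <- optics[[ch]] %||% (if (ch %in% sted_ch) optics$sted else optics$confocal)
    if (is.null(g) || is.null(op))
      stop("no grid/optics provided for channel '", ch, "'")
    em <- if (ch == "yfp") morphology_emitters(scene, g) else
      scene$emitters[scene$emitters$channel == ch, , drop = FALSE]
    r <- render_emitters(g, em, op)
    if (noise) {
      r$img[] <- with_seed(derive_seed(seed, ci),
                           rpois(length(r$img), r$img + op$background_photons))
    } else {
      r$img <- r$img + op$background_photons
    }
    out[[ch]] <- list(img = r$img, grid = g, optics = op,
                      emitter_integrals = r$integrals)
  }
  out
}

# Mask voxels of every spine plus a dendritic shaft, as unit point
# emitters on the morphology grid.
morphology_emitters <- function(scene, grid) {
  idx <- integer(0)
  for (id in scene$spines$id)
    idx <- c(idx, spine_mask_indices(scene, id, grid))
  # shaft: 400 nm radius cylinder along x mid-box, below the spine plane
  zc <- scene$box_nm[["z"]] / 2
  yc <- scene$box_nm[["y"]] / 2
  ii <- seq_len(grid$shape[["x"]])
  jj <- which(abs(grid$origin[["y"]] + (seq_len(grid$shape[["y"]]) - 1) *
                    grid$spacing[["y"]] - yc) <= 400)
  kk <- which(abs(grid$origin[["z"]] + (seq_len(grid$shape[["z"]]) - 1) *
                    grid$spacing[["z"]] - zc) <= 400)
  if (length(jj) && length(kk)) {
    sh <- expand.grid(k = kk, j = jj, i = ii, KEEP.OUT.ATTRS = FALSE)
    idx <- c(idx, as.integer(sh$k + grid$shape[["z"]] *
                               ((sh$j - 1) + grid$shape[["y"]] * (sh$i - 1))))
  }
  idx <- unique(idx)
  if (!length(idx)) return(empty_emitters())
  xyz <- voxel_coords(grid, idx)
  data.frame(channel = "yfp", x = xyz[, "x"], y = xyz[, "y"], z = xyz[, "z"],
             size_nm = 0, amplitude = 1, spine_id = NA_integer_,
             module_id = NA_integer_, stringsAsFactors = FALSE)
}

# Core renderer: voxel-integrated separable Gaussians.
render_emitters <- function(grid, emitters, optics) {
  img <- array(0, dim = unname(grid$shape))
  n <- nrow(emitters)
  integrals <- numeric(n)
  if (n == 0) return(list(img = img, integrals = integrals))

  s_lat <- fwhm_to_sigma(sqrt(emitters$size_nm^2 + optics$lateral_fwhm^2))
  s_ax <- fwhm_to_sigma(sqrt(emitters$size_nm^2 + optics$axial_fwhm^2))
  # reject emitters whose rendered footprint would not span a voxel
  fw_lat <- sigma_to_fwhm(s_lat)
  fw_ax <- sigma_to_fwhm(s_ax)
  if (any(fw_lat < 0.5 * grid$spacing[["x"]] |
          fw_lat < 0.5 * grid$spacing[["y"]] |
          fw_ax < 0.5 * grid$spacing[["z"]]))
    stop("emitter footprint below half a voxel: grid too coarse")

  ax_weights <- function(c0, sigma, axis) {
    # voxel-integrated 1D Gaussian over an index window (may exceed grid)
    sp <- grid$spacing[[axis]]
    o <- grid$origin[[axis]]
    half <- ceiling((4 * sigma + sp) / sp)
    c_idx <- round((c0 - o) / sp) + 1
    idx <- seq.int(c_idx - half, c_idx + half)
    lo <- o + (idx - 1.5) * sp
    w <- pnorm((lo + sp - c0) / sigma) - pnorm((lo - c0) / sigma)
    list(idx = idx, w = w)
  }
  nzd <- grid$shape[["z"]]; nyd <- grid$shape[["y"]]; nxd <- grid$shape[["x"]]
  for (e in seq_len(n)) {
    wz <- ax_weights(emitters$z[e], s_ax[e], "z")
    wy <- ax_weights(emitters$y[e], s_lat[e], "y")
    wx <- ax_weights(emitters$x[e], s_lat[e], "x")
    peak <- max(wz$w) * max(wy$w) * max(wx$w)
    scale <- emitters$amplitude[e] * optics$peak_photons / peak
    integrals[e] <- scale * sum(wz$w) * sum(wy$w) * sum(wx$w)
    kz <- which(wz$idx >= 1 & wz$idx <= nzd & wz$w > 0)
    ky <- which(wy$idx >= 1 & wy$idx <= nyd & wy$w > 0)
    kx <- which(wx$idx >= 1 & wx$idx <= nxd & wx$w > 0)
    if (!length(kz) || !length(ky) || !length(kx)) next
    blk <- scale * (wz$w[kz] %o% wy$w[ky] %o% wx$w[kx])
    img[wz$idx[kz], wy$idx[ky], wx$idx[kx]] <-
      img[wz$idx[kz], wy$idx[ky], wx$idx[kx]] + blk
  }
  list(img = img, integrals = integrals)
}
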