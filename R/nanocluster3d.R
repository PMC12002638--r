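#' Parameters of the 3D nanocluster segmentation
#'
#' Defaults reproduce the standard DiAna-style settings for 20 nm / 150 nm
#' STED stacks: local maxima searched in an ellipsoid of 5 pixels (100 nm)
#' laterally and 2 pixels axially, a global frame threshold of
#' mean + 2 SD, a per-seed relative threshold placed at 1.5 SD of a
#' Gaussian profile (`peak * exp(-1.5^2 / 2)`), a maximum region radius of
#' 20 pixels, and a 3..20000 voxel size band.
#'
#' @param maxima_radius_xy,maxima_radius_z local-maxima neighbourhood
#'   radii in voxels.
#' @param global_k SD multiplier of the global frame threshold.
#' @param gaussfit_sd Gaussian SD multiplier defining the per-seed
#'   relative threshold `exp(-gaussfit_sd^2/2)` of the seed peak.
#' @param max_radius maximum region radius in XY voxels (Chebyshev); the
#'   axial limit is scaled by `dx/dz` so the physical constraint is
#'   near-isotropic.
#' @param min_voxels,max_voxels inclusive voxel-count band for a cluster.
#' @param smooth_sigma_px light per-slice lateral Gaussian blur (in
#'   pixels) applied to the analysis image before thresholding and seed
#'   detection, matching the 0.8-pixel smoothing of the standard
#'   processing chain; 0 disables it.
#' @param min_threshold_photons floor on the intensity threshold: for
#'   photon-counting data a cut below the single-photon level is
#'   meaningless (on a sparse frame the mean + k SD statistic can fall
#'   below it, turning every stray photon into a seed). Inactive on
#'   frames dense enough that the frame statistic exceeds it.
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(maxima_radius_xy = 5, maxima_radius_z = 2,
                                global_k = 2, gaussfit_sd = 1.5,
                                max_radius = 20, min_voxels = 3,
                                max_voxels = 20000, smooth_sigma_px = 0.8,
                                min_threshold_photons = 1) {
  stopifnot(maxima_radius_xy > 0, maxima_radius_z > 0, global_k >= 0,
            gaussfit_sd > 0, max_radius > 0, min_voxels > 0,
            min_voxels <= max_voxels, smooth_sigma_px >= 0,
            min_threshold_photons >= 0)
  structure(list(maxima_radius_xy = maxima_radius_xy,
                 maxima_radius_z = maxima_radius_z, global_k = global_k,
                 gaussfit_sd = gaussfit_sd, max_radius = max_radius,
                 min_voxels = min_voxels, max_voxels = max_voxels,
                 smooth_sigma_px = smooth_sigma_px,
                 min_threshold_photons = min_threshold_photons),
            class = "segmentation_params")
}

#' Per-slice lateral Gaussian smoothing
#'
#' Separable Gaussian blur along y and x only (each z-plane smoothed
#' independently), with reflective boundaries.
#'
#' @param stack numeric array `(nz, ny, nx)`.
#' @param sigma_px Gaussian sigma in pixels; 0 returns the input.
#' @return Smoothed array of the same shape.
#' @export
smooth_stack <- function(stack, sigma_px) {
  if (sigma_px <= 0) return(stack)
  out <- cpp_blur_lateral(as.numeric(stack), dim(stack), sigma_px)
  array(out, dim(stack))
}

#' Segment 3D nanoclusters by local maxima with per-seed thresholds
#'
#' The segmentation follows the local-maxima method with user-defined
#' thresholds: (1) a global threshold `T_g = frame mean + global_k * SD`;
#' (2) seeds are voxels above `T_g` that are strict maxima within the
#' ellipsoidal neighbourhood (ties broken toward the lower linear index);
#' (3) each seed grows a 26-connected region of voxels with intensity
#' strictly above `max(T_g, peak * exp(-gaussfit_sd^2/2))`, within
#' `max_radius` voxels of the seed (axially scaled), contested voxels
#' resolved by seeded watershed on inverted intensity; (4) components
#' outside the voxel-count band are discarded.
#'
#' @param stack numeric array `(nz, ny, nx)`.
#' @param grid a [voxel_grid()].
#' @param params a [segmentation_params()].
#' @param channel optional channel label copied to the output.
#' @param threshold optional override of the global threshold (used for
#'   per-spine ROI-statistics segmentation).
#' @return Object of class `nanoclusters`: data frame with one row per
#'   cluster (id, channel, n_voxels, volume um^3, intensity-weighted
#'   centroid x/y/z nm, peak intensity, 0-based peak voxel index) plus a
#'   list column `voxels` of 1-based linear indices; attributes `grid`
#'   and `threshold`.
#' @examples
#' g <- voxel_grid(c(5, 32, 32), c(150, 20, 20))
#' img <- array(0, unname(g$shape))
#' img[3, 16, 16] <- 10; img[3, 16, 17] <- 6
#' ncs <- segment_nanoclusters(img, g)
#' ncs$n_voxels
#' @export
segment_nanoclusters <- function(stack, grid, params = segmentation_params(),
                                 channel = NA_character_, threshold = NULL) {
  stopifnot(length(dim(stack)) == 3,
            all(dim(stack) == unname(grid$shape)))
  stack <- smooth_stack(stack, params$smooth_sigma_px)
  t_g <- threshold %||% (mean(stack) + params$global_k * sd(as.numeric(stack)))
  t_g <- max(t_g, params$min_threshold_photons)
  empty <- function() {
    out <- data.frame(id = integer(), channel = character(),
                      n_voxels = integer(), volume_um3 = numeric(),
                      cx = numeric(), cy = numeric(), cz = numeric(),
                      peak = numeric(), peak_index0 = integer())
    out$voxels <- list()
    attr(out, "grid") <- grid
    attr(out, "threshold") <- t_g
    class(out) <- c("nanoclusters", class(out))
    out
  }
  if (length(stack) == 0) return(empty())
  dim3 <- dim(stack)
  seeds <- cpp_local_maxima(as.numeric(stack), dim3, params$maxima_radius_xy,
                            params$maxima_radius_z, t_g)
  if (!length(seeds)) return(empty())
  peaks <- stack[seeds]
  thr_s <- pmax(t_g, peaks * exp(-params$gaussfit_sd^2 / 2))
  maxr_z <- params$max_radius * grid$spacing[["x"]] / grid$spacing[["z"]]
  labels <- cpp_flood(as.numeric(stack), dim3, seeds, thr_s,
                      params$max_radius, maxr_z)
  on <- which(labels > 0)
  sets <- split(on, labels[on])
  set_thr <- thr_s[as.integer(names(sets))]
  sizes <- lengths(sets)
  keep <- sizes >= params$min_voxels & sizes <= params$max_voxels
  sets <- sets[keep]
  set_thr <- set_thr[keep]
  n <- length(sets)
  if (n == 0) return(empty())
  vol <- voxel_volume_um3(grid)
  rows <- lapply(seq_len(n), function(i) {
    idx <- sets[[i]]
    v <- stack[idx]
    # centroid weights are background-subtracted (intensity above the
    # region's admission threshold): robust to the flat pedestal shared
    # with an overlapping partner cluster
    w <- v - set_thr[i]
    xyz <- voxel_coords(grid, idx)
    pk <- which.max(v)
    data.frame(id = i, channel = channel, n_voxels = length(idx),
               volume_um3 = length(idx) * vol,
               cx = sum(w * xyz[, "x"]) / sum(w),
               cy = sum(w * xyz[, "y"]) / sum(w),
               cz = sum(w * xyz[, "z"]) / sum(w),
               peak = v[pk], peak_index0 = idx[pk] - 1L)
  })
  out <- do.call(rbind, rows)
  out$voxels <- unname(sets)
  attr(out, "grid") <- grid
  attr(out, "threshold") <- t_g
  class(out) <- c("nanoclusters", class(out))
  out
}

#' Nearest-neighbour distances between two centre sets
#'
#' For each object in A, the minimum 3D Euclidean distance to any object
#' in B (asymmetric by design, A to B).
#'
#' @param centers_a,centers_b matrices (or data frames with columns
#'   `cx`, `cy`, `cz`) of physical nm coordinates.
#' @return Numeric vector, one distance per row of A.
#' @export
nearest_neighbor_distances <- function(centers_a, centers_b) {
  a <- as_center_matrix(centers_a)
  b <- as_center_matrix(centers_b)
  if (nrow(a) == 0) return(numeric(0))
  if (nrow(b) == 0) stop("channel-2 object set is empty: no neighbours")
  d2 <- outer(rowSums(a^2), rep(1, nrow(b))) +
    outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * a %*% t(b)
  sqrt(pmax(0, apply(d2, 1, min)))
}

as_center_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x[, c("cx", "cy", "cz")])
  x <- rbind(x)
  stopifnot(ncol(x) == 3)
  x
}

#' Trans-synaptic nanocluster pairs
#'
#' All cross-channel cluster pairs sharing at least `min_overlap_vox`
#' voxels, with the centre-to-centre distance and an orientation class:
#' `A` if the lateral centroid offset dominates
#' (`sqrt(dx^2+dy^2) >= |dz|`), `B` otherwise.
#'
#' @param ncs_a,ncs_b [segment_nanoclusters()] outputs on the same grid
#'   (conventionally A = PSD-95, B = Bassoon).
#' @param min_overlap_vox minimum shared voxels (default 1).
#' @return List with `pairs` (data frame: a, b, overlap_vox, distance_nm,
#'   orientation) and `pct_a_paired`, the percentage of channel-A
#'   clusters with at least one partner.
#' @export
trans_synaptic_pairs <- function(ncs_a, ncs_b, min_overlap_vox = 1) {
  ga <- attr(ncs_a, "grid"); gb <- attr(ncs_b, "grid")
  if (!is.null(ga) && !is.null(gb) && !grids_identical(ga, gb))
    stop("nanocluster sets are on different grids")
  g <- ga %||% gb
  if (is.null(g)) stop("nanocluster sets carry no grid")
  ov <- overlap_pairs(ncs_a$voxels, ncs_b$voxels, prod(g$shape),
                      min_overlap_vox)
  pairs <- if (nrow(ov)) {
    dx <- ncs_b$cx[ov$b] - ncs_a$cx[ov$a]
    dy <- ncs_b$cy[ov$b] - ncs_a$cy[ov$a]
    dz <- ncs_b$cz[ov$b] - ncs_a$cz[ov$a]
    lat <- sqrt(dx^2 + dy^2)
    data.frame(a = ov$a, b = ov$b, overlap_vox = ov$overlap,
               distance_nm = sqrt(lat^2 + dz^2),
               orientation = ifelse(lat >= abs(dz), "A", "B"))
  } else {
    data.frame(a = integer(), b = integer(), overlap_vox = integer(),
               distance_nm = numeric(), orientation = character())
  }
  list(pairs = pairs,
       pct_a_paired = if (nrow(ncs_a))
         100 * length(unique(pairs$a)) / nrow(ncs_a) else NA_real_)
}


# All (a, b) index pairs whose cell sets share >= min_overlap cells.
# Fast path via a label array when the B sets are disjoint (segmented
# objects always are); exhaustive pairwise intersection otherwise.
overlap_pairs <- function(sets_a, sets_b, n_cells, min_overlap) {
  none <- data.frame(a = integer(), b = integer(), overlap = integer())
  if (!length(sets_a) || !length(sets_b)) return(none)
  lab_b <- integer(n_cells)
  disjoint <- TRUE
  for (j in seq_along(sets_b)) {
    if (any(lab_b[sets_b[[j]]] > 0)) {
      disjoint <- FALSE
      break
    }
    lab_b[sets_b[[j]]] <- j
  }
  rows <- list()
  if (disjoint) {
    for (i in seq_along(sets_a)) {
      hits <- lab_b[sets_a[[i]]]
      hits <- hits[hits > 0]
      if (!length(hits)) next
      tb <- table(hits)
      ok <- as.integer(names(tb))[tb >= min_overlap]
      if (length(ok))
        rows[[length(rows) + 1]] <-
          data.frame(a = i, b = ok, overlap = as.integer(tb)[tb >= min_overlap])
    }
  } else {
    for (i in seq_along(sets_a))
      for (j in seq_along(sets_b)) {
        n_shared <- length(intersect(sets_a[[i]], sets_b[[j]]))
        if (n_shared >= min_overlap)
          rows[[length(rows) + 1]] <- data.frame(a = i, b = j,
                                                 overlap = n_shared)
      }
  }
  if (length(rows)) do.call(rbind, rows) else none
}
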