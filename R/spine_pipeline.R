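#' Derive per-spine regions of interest
#'
#' Three sources are supported, in order of preference: the generator's
#' ground truth (synthetic mode: masks identical to the true spine
#' masks), a provided label image (one integer label per spine), or a
#' mean + k SD threshold of the morphology channel split into
#' 26-connected components. Each spine's orientation class is taken from
#' the principal axis of its mask: `A` if the axis is XY-dominant, `B`
#' if Z-dominant.
#'
#' @param morphology optional numeric array (required for threshold mode).
#' @param grid the morphology [voxel_grid()].
#' @param k SD multiplier for threshold mode (default 2).
#' @param scene optional [build_scene()] truth.
#' @param labels optional integer array of spine labels.
#' @param min_voxels components smaller than this are dropped in
#'   threshold mode.
#' @return List of `spine_record` objects (id, mask voxel indices, grid,
#'   volume um^3, orientation, centroid; synthetic mode adds the true
#'   class and nanomodule count). Empty list with a warning when nothing
#'   is found.
#' @export
derive_spine_rois <- function(morphology = NULL, grid, k = 2, scene = NULL,
                              labels = NULL, min_voxels = 10) {
  recs <- list()
  if (!is.null(scene)) {
    for (i in seq_len(nrow(scene$spines))) {
      s <- scene$spines[i, ]
      idx <- spine_mask_indices(scene, s$id, grid)
      recs[[length(recs) + 1]] <- new_spine_record(
        id = s$id, mask = idx, grid = grid,
        true_class = s$class, true_n_modules = s$n_modules,
        true_volume_um3 = s$volume_um3)
    }
  } else if (!is.null(labels)) {
    ids <- sort(unique(labels[labels > 0]))
    for (id in ids) {
      idx <- which(labels == id)
      recs[[length(recs) + 1]] <- new_spine_record(id = id, mask = idx,
                                                   grid = grid)
    }
  } else {
    stopifnot(!is.null(morphology))
    thr <- mean(morphology) + k * sd(as.numeric(morphology))
    comp <- cpp_label_components(as.logical(morphology > thr),
                                 dim(morphology))
    on <- which(comp > 0)
    sets <- split(on, comp[on])
    sets <- sets[lengths(sets) >= min_voxels]
    for (i in seq_along(sets))
      recs[[length(recs) + 1]] <- new_spine_record(id = i, mask = sets[[i]],
                                                   grid = grid)
  }
  if (!length(recs)) warning("no spines found")
  recs
}

new_spine_record <- function(id, mask, grid, true_class = NA_character_,
                             true_n_modules = NA_integer_,
                             true_volume_um3 = NA_real_) {
  mask <- sort(as.integer(mask))
  structure(list(id = id, mask = mask, grid = grid,
                 volume_um3 = length(mask) * voxel_volume_um3(grid),
                 orientation = spine_orientation(mask, grid),
                 true_class = true_class,
                 true_n_modules = true_n_modules,
                 true_volume_um3 = true_volume_um3),
            class = "spine_record")
}

#' @export
print.spine_record <- function(x, ...) {
  cat(sprintf("spine_record %s: %d voxels, %.3f um^3, orientation %s\n",
              format(x$id), length(x$mask), x$volume_um3, x$orientation))
  invisible(x)
}

# Principal-axis orientation of a voxel mask: "A" when the leading
# eigenvector of the coordinate covariance is XY-dominant, "B" when
# Z-dominant.
spine_orientation <- function(mask_idx, grid) {
  if (length(mask_idx) < 2) return(NA_character_)
  xyz <- voxel_coords(grid, mask_idx)
  v <- eigen(stats::cov(xyz), symmetric = TRUE)$vectors[, 1]
  if (sqrt(v[1]^2 + v[2]^2) >= abs(v[3])) "A" else "B"
}

# Physical bounding box of a spine mask, padded, as index ranges on
# another grid.
spine_bbox_on <- function(spine, grid, pad_nm = 300) {
  xyz <- voxel_coords(spine$grid, spine$mask)
  lo <- apply(xyz, 2, min) - pad_nm
  hi <- apply(xyz, 2, max) + pad_nm
  rng <- function(axis, a, b) {
    c(max(1L, floor((a - grid$origin[[axis]]) / grid$spacing[[axis]]) + 1),
      min(grid$shape[[axis]],
          ceiling((b - grid$origin[[axis]]) / grid$spacing[[axis]]) + 1))
  }
  list(k = rng("z", lo[["z"]], hi[["z"]]),
       j = rng("y", lo[["y"]], hi[["y"]]),
       i = rng("x", lo[["x"]], hi[["x"]]))
}

# Does each physical point (matrix x,y,z) fall inside the spine mask?
points_in_spine <- function(spine, xyz) {
  idx <- coords_to_index(spine$grid, xyz)
  !is.na(idx) & idx %in% spine$mask
}

#' Identify discrete nanoclusters within one spine
#'
#' Re-runs the 3D segmentation on the spine's neighbourhood with the
#' threshold computed from the ROI statistics (`ROI mean + k_local * SD`
#' over the imaging voxels that fall inside the spine mask), the
#' per-spine criterion used to discriminate discrete nanoclusters.
#'
#' @param stack the STED channel array.
#' @param grid its [voxel_grid()].
#' @param spine a `spine_record`.
#' @param params [segmentation_params()].
#' @param k_local ROI SD multiplier (default 1.5).
#' @param bbox optional precomputed [spine_bbox_on()]-style index ranges
#'   (pass the same box for both channels so their voxel index spaces
#'   coincide).
#' @param min_roi_voxels spines whose ROI maps to fewer imaging voxels
#'   than this are skipped with a warning.
#' @return A `nanoclusters` table on the padded sub-grid (physical
#'   coordinates are global), or `NULL` when the spine is skipped.
#' @export
identify_spine_ncs <- function(stack, grid, spine,
                               params = segmentation_params(),
                               k_local = 1.5, bbox = NULL,
                               min_roi_voxels = 10) {
  bbox <- bbox %||% spine_bbox_on(spine, grid)
  sub <- stack[bbox$k[1]:bbox$k[2], bbox$j[1]:bbox$j[2],
               bbox$i[1]:bbox$i[2], drop = FALSE]
  sg <- subgrid(grid, bbox$k, bbox$j, bbox$i)
  centers <- voxel_coords(sg, seq_len(length(sub)))
  inside <- points_in_spine(spine, centers)
  if (sum(inside) < min_roi_voxels) {
    warning(sprintf("spine %s: ROI below %d voxels on the imaging grid; skipped",
                    format(spine$id), min_roi_voxels))
    return(NULL)
  }
  # smooth once, compute the ROI-statistics threshold on the analysis
  # image, then segment that image directly
  sub <- smooth_stack(sub, params$smooth_sigma_px)
  params$smooth_sigma_px <- 0
  roi_vals <- sub[inside]
  thr <- mean(roi_vals) + k_local * sd(roi_vals)
  segment_nanoclusters(sub, sg, params, threshold = thr)
}

#' Assign PSD-95 nanoclusters to a spine
#'
#' A cluster is assigned iff every one of its voxel centres lies inside
#' the spine head ROI; a cluster straddling the boundary is not assigned.
#'
#' @param spine a `spine_record`.
#' @param ncs a `nanoclusters` table (any grid; tested in physical
#'   coordinates).
#' @return Integer vector of assigned cluster ids.
#' @export
assign_psd95 <- function(spine, ncs) {
  if (is.null(ncs) || nrow(ncs) == 0) return(integer(0))
  g <- attr(ncs, "grid")
  ok <- vapply(seq_len(nrow(ncs)), function(i) {
    all(points_in_spine(spine, voxel_coords(g, ncs$voxels[[i]])))
  }, logical(1))
  ncs$id[ok]
}

#' Associate Bassoon nanoclusters with a spine
#'
#' A cluster is associated iff at least one voxel centre lies inside the
#' spine head ROI (partial overlap) or its centroid is within
#' `proximity_nm` of the ROI surface (presynaptic clusters abutting the
#' spine).
#'
#' @inheritParams assign_psd95
#' @param proximity_nm centroid-to-ROI proximity (default 200 nm,
#'   matching the 0.15-0.2 um presynaptic assignment band). The distance
#'   is measured from the cluster centroid to the nearest point of the
#'   mask's voxel boxes, i.e. to the ROI surface rather than to voxel
#'   centres.
#' @return Integer vector of associated cluster ids.
#' @export
assign_bassoon <- function(spine, ncs, proximity_nm = 200) {
  if (is.null(ncs) || nrow(ncs) == 0) return(integer(0))
  g <- attr(ncs, "grid")
  mask_xyz <- voxel_coords(spine$grid, spine$mask)
  half <- spine$grid$spacing / 2
  ok <- vapply(seq_len(nrow(ncs)), function(i) {
    if (any(points_in_spine(spine, voxel_coords(g, ncs$voxels[[i]]))))
      return(TRUE)
    cen <- c(ncs$cx[i], ncs$cy[i], ncs$cz[i])
    dx <- pmax(0, abs(mask_xyz[, 1] - cen[1]) - half[["x"]])
    dy <- pmax(0, abs(mask_xyz[, 2] - cen[2]) - half[["y"]])
    dz <- pmax(0, abs(mask_xyz[, 3] - cen[3]) - half[["z"]])
    min(dx^2 + dy^2 + dz^2) <= proximity_nm^2
  }, logical(1))
  ncs$id[ok]
}

#' Count nanomodules in a spine
#'
#' A nanomodule is an assigned PSD-95 nanocluster with at least one
#' trans-synaptic Bassoon partner; the count is keyed on PSD-95, so one
#' Bassoon cluster aligned with two PSD-95 clusters yields a count of 2.
#'
#' @param spine a `spine_record` (unused beyond documentation of intent;
#'   kept for a uniform signature).
#' @param pairs result of [trans_synaptic_pairs()] computed over the
#'   spine's assigned PSD-95 and associated Bassoon clusters.
#' @return Integer nanomodule count.
#' @export
count_nanomodules <- function(spine, pairs) {
  length(unique(pairs$pairs$a))
}

#' Classify a spine's presynaptic input
#'
#' A spine is thalamocortical (TC) iff VGluT2 overlaps its projected mask
#' by more than one pixel and VGluT1 does not; corticocortical (CC) for
#' the converse. If both markers overlap, the class follows the marker
#' overlapping the spine's aligned nanomodule footprint; if still tied,
#' the marker with the larger overlap wins; with no marker the spine is
#' unclassified.
#'
#' @param spine_px integer linear pixel indices of the spine mask
#'   projected onto the confocal 2D grid.
#' @param vg1_puncta,vg2_puncta [extract_puncta()] results for the VGluT1
#'   and VGluT2 channels.
#' @param nanomodule_px optional pixel indices of the spine's aligned
#'   nanomodule footprint on the same 2D grid (used only for the
#'   dual-innervation tie-break).
#' @param min_overlap_px strict overlap minimum (default 2 pixels, i.e.
#'   "> 1 pixel").
#' @return List with `class` (`"CC"`, `"TC"` or `"unclassified"`) and the
#'   pixel overlaps that produced it.
#' @export
classify_input <- function(spine_px, vg1_puncta, vg2_puncta,
                           nanomodule_px = NULL, min_overlap_px = 2) {
  px_union <- function(p) {
    if (is.null(p) || nrow(p) == 0) integer(0) else
      unique(unlist(p$pixels, use.names = FALSE))
  }
  u1 <- px_union(vg1_puncta)
  u2 <- px_union(vg2_puncta)
  ov1 <- length(intersect(u1, spine_px))
  ov2 <- length(intersect(u2, spine_px))
  has1 <- ov1 >= min_overlap_px
  has2 <- ov2 >= min_overlap_px
  cls <- if (has2 && !has1) "TC"
  else if (has1 && !has2) "CC"
  else if (!has1 && !has2) "unclassified"
  else {
    on1 <- length(intersect(u1, nanomodule_px %||% integer(0)))
    on2 <- length(intersect(u2, nanomodule_px %||% integer(0)))
    if (on2 > on1) "TC"
    else if (on1 > on2) "CC"
    else if (ov2 > ov1) "TC"
    else if (ov1 > ov2) "CC"
    else "unclassified"
  }
  list(class = cls, overlap_vg1_px = ov1, overlap_vg2_px = ov2,
       dual = has1 && has2)
}

#' Per-spine PSD-95 volume metrics
#'
#' @param spine a `spine_record`.
#' @param nc_volumes_um3 volumes of the spine's counted (aligned) PSD-95
#'   nanoclusters.
#' @return List with `volume_um3` (spine mask volume),
#'   `total_psd95_volume_um3` and `mean_nc_volume_um3` (both `NA` when no
#'   nanocluster is counted: undefined, not zero).
#' @export
spine_metrics <- function(spine, nc_volumes_um3) {
  n <- length(nc_volumes_um3)
  list(volume_um3 = spine$volume_um3,
       n_ncs = n,
       total_psd95_volume_um3 = if (n) sum(nc_volumes_um3) else NA_real_,
       mean_nc_volume_um3 = if (n) mean(nc_volumes_um3) else NA_real_)
}

# Project a spine mask (morphology grid) onto the 2D pixel space of a
# confocal grid; returns unique linear indices into an (ny, nx) matrix.
project_mask_px <- function(spine, grid2) {
  xyz <- voxel_coords(spine$grid, spine$mask)
  j <- round((xyz[, "y"] - grid2$origin[["y"]]) / grid2$spacing[["y"]]) + 1
  i <- round((xyz[, "x"] - grid2$origin[["x"]]) / grid2$spacing[["x"]]) + 1
  ok <- j >= 1 & j <= grid2$shape[["y"]] & i >= 1 & i <= grid2$shape[["x"]]
  unique(as.integer(j[ok] + (i[ok] - 1) * grid2$shape[["y"]]))
}

#' Run the full per-spine analysis on a rendered scene
#'
#' Ties the stages together the way the per-spine STED analysis is done:
#' ground-truth spine ROIs, ROI-statistics nanocluster identification in
#' the PSD-95 and Bassoon channels, strict PSD-95 containment and
#' partial/proximity Bassoon association, trans-synaptic pairing and
#' nanomodule counting, VGluT1/VGluT2 input classification from the
#' confocal channels (when rendered), and volume metrics.
#'
#' @param scene a [build_scene()] truth.
#' @param stacks a [render_channels()] result containing at least the
#'   `psd95` and `bassoon` channels.
#' @param params [segmentation_params()].
#' @param k_local per-spine ROI SD multiplier (default 1.5).
#' @param proximity_nm Bassoon association band (default 200).
#' @param morph_grid grid for the ground-truth spine masks; defaults to
#'   the grid of a rendered confocal channel, else the scene's default
#'   confocal grid.
#' @return Object of class `spine_table`: data frame with one row per
#'   spine (true and recovered class and nanomodule count, assignment
#'   counts, mean pair distance, volume metrics, orientation).
#' @export
analyze_spines <- function(scene, stacks, params = segmentation_params(),
                           k_local = 1.5, proximity_nm = 200,
                           morph_grid = NULL) {
  stopifnot(all(c("psd95", "bassoon") %in% names(stacks)))
  sted_grid <- stacks$psd95$grid
  conf <- intersect(c("vglut1", "vglut2"), names(stacks))
  morph_grid <- morph_grid %||%
    (if (length(conf)) stacks[[conf[1]]]$grid else scene_grids(scene)$confocal)
  spines <- derive_spine_rois(grid = morph_grid, scene = scene)

  vg_puncta <- list()
  grid2 <- NULL
  for (ch in conf) {
    proj <- max_project(stacks[[ch]]$img, stacks[[ch]]$grid)
    vg_puncta[[ch]] <- extract_puncta(threshold_mask(proj, 2),
                                      grid = stacks[[ch]]$grid)
    grid2 <- stacks[[ch]]$grid
  }

  rows <- vector("list", length(spines))
  for (si in seq_along(spines)) {
    sp <- spines[[si]]
    bbox <- spine_bbox_on(sp, sted_grid)
    ncs_p <- identify_spine_ncs(stacks$psd95$img, sted_grid, sp, params,
                                k_local, bbox)
    ncs_b <- identify_spine_ncs(stacks$bassoon$img, sted_grid, sp, params,
                                k_local, bbox)
    assigned <- assign_psd95(sp, ncs_p)
    associated <- if (is.null(ncs_b)) integer(0) else
      assign_bassoon(sp, ncs_b, proximity_nm)
    count <- 0L
    mean_dist <- NA_real_
    counted_ids <- integer(0)
    if (length(assigned) && length(associated)) {
      pa <- ncs_p[match(assigned, ncs_p$id), , drop = FALSE]
      attr(pa, "grid") <- attr(ncs_p, "grid")
      class(pa) <- class(ncs_p)
      pb <- ncs_b[match(associated, ncs_b$id), , drop = FALSE]
      attr(pb, "grid") <- attr(ncs_b, "grid")
      class(pb) <- class(ncs_b)
      prs <- trans_synaptic_pairs(pa, pb)
      count <- count_nanomodules(sp, prs)
      counted_ids <- pa$id[unique(prs$pairs$a)]
      if (nrow(prs$pairs)) mean_dist <- mean(prs$pairs$distance_nm)
    }
    met <- spine_metrics(sp, if (length(counted_ids))
      ncs_p$volume_um3[match(counted_ids, ncs_p$id)] else numeric(0))

    cls <- NA_character_
    dual <- NA
    if (length(conf) && !is.null(grid2)) {
      spine_px <- project_mask_px(sp, grid2)
      nm_px <- NULL
      if (length(counted_ids) && !is.null(ncs_p)) {
        g <- attr(ncs_p, "grid")
        vox <- unlist(ncs_p$voxels[match(counted_ids, ncs_p$id)],
                      use.names = FALSE)
        xyz <- voxel_coords(g, vox)
        j <- round((xyz[, "y"] - grid2$origin[["y"]]) / grid2$spacing[["y"]]) + 1
        i <- round((xyz[, "x"] - grid2$origin[["x"]]) / grid2$spacing[["x"]]) + 1
        ok <- j >= 1 & j <= grid2$shape[["y"]] & i >= 1 & i <= grid2$shape[["x"]]
        nm_px <- unique(as.integer(j[ok] + (i[ok] - 1) * grid2$shape[["y"]]))
      }
      cl <- classify_input(spine_px, vg_puncta[["vglut1"]],
                           vg_puncta[["vglut2"]], nm_px)
      cls <- cl$class
      dual <- cl$dual
    }

    rows[[si]] <- data.frame(
      id = sp$id, true_class = sp$true_class,
      true_n_modules = sp$true_n_modules,
      input_class = cls, dual_overlap = dual,
      n_modules = count,
      n_psd95_assigned = length(assigned),
      n_bassoon_associated = length(associated),
      mean_pair_distance_nm = mean_dist,
      volume_um3 = met$volume_um3,
      true_volume_um3 = sp$true_volume_um3,
      total_psd95_volume_um3 = met$total_psd95_volume_um3,
      mean_nc_volume_um3 = met$mean_nc_volume_um3,
      orientation = sp$orientation,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("spine_table", class(out))
  out
}
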