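# Independent brute-force reference implementations. These restate the
# documented rules in the plainest possible code (nested loops, repeated
# scans) and are kept deliberately separate from the package internals.

oracle_max_project <- function(stack) {
  d <- dim(stack)
  out <- matrix(-Inf, d[2], d[3])
  for (k in seq_len(d[1]))
    for (j in seq_len(d[2]))
      for (i in seq_len(d[3]))
        out[j, i] <- max(out[j, i], stack[k, j, i])
  out
}

# 8-connected 2D labelling by repeated flood fill
oracle_label2d <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nxt <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      rc <- arrayInd(v, dim(mask))
      for (dj in -1:1) for (di in -1:1) {
        j <- rc[1] + dj; i <- rc[2] + di
        if (j < 1 || j > nrow(mask) || i < 1 || i > ncol(mask)) next
        u <- j + (i - 1) * nrow(mask)
        if (mask[u] && lab[u] == 0) {
          lab[u] <- nxt
          queue <- c(queue, u)
        }
      }
    }
  }
  lab
}

# exhaustive pairwise pixel-set intersection
oracle_cocluster_pairs <- function(sets_a, sets_b, min_overlap) {
  out <- NULL
  for (i in seq_along(sets_a))
    for (j in seq_along(sets_b)) {
      ov <- length(intersect(sets_a[[i]], sets_b[[j]]))
      if (ov >= min_overlap) out <- rbind(out, c(i, j, ov))
    }
  out
}

oracle_nn <- function(a, b) {
  sapply(seq_len(nrow(a)), function(i) {
    best <- Inf
    for (j in seq_len(nrow(b)))
      best <- min(best, sqrt(sum((a[i, ] - b[j, ])^2)))
    best
  })
}

# Brute-force 3D segmentation implementing the documented rules directly:
# strict ellipsoidal local maxima (ties to the lower linear index), then
# repeated scans assigning, at each step, the globally brightest unlabelled
# voxel that (a) is 26-adjacent to a labelled voxel, (b) strictly exceeds
# that region's threshold and (c) lies within the region's radius box; the
# voxel joins the region owning its brightest labelled neighbour.
oracle_segment_labels <- function(stack, params, grid) {
  d <- dim(stack)
  n <- length(stack)
  tg <- max(mean(stack) + params$global_k * sd(as.numeric(stack)),
            params$min_threshold_photons)
  ind <- arrayInd(seq_len(n), d) # k, j, i
  rxy <- params$maxima_radius_xy; rz <- params$maxima_radius_z
  seeds <- integer(0)
  for (v in seq_len(n)) {
    if (!(stack[v] > tg)) next
    ok <- TRUE
    for (u in seq_len(n)) {
      if (u == v) next
      dk <- ind[u, 1] - ind[v, 1]
      dj <- ind[u, 2] - ind[v, 2]
      di <- ind[u, 3] - ind[v, 3]
      if ((di^2 + dj^2) / rxy^2 + dk^2 / rz^2 > 1) next
      if (stack[u] > stack[v] || (stack[u] == stack[v] && u < v)) {
        ok <- FALSE
        break
      }
    }
    if (ok) seeds <- c(seeds, v)
  }
  lab <- integer(n)
  lab[seeds] <- seq_along(seeds)
  thr <- pmax(tg, stack[seeds] * exp(-params$gaussfit_sd^2 / 2))
  maxr_xy <- params$max_radius
  maxr_z <- params$max_radius * grid$spacing[["x"]] / grid$spacing[["z"]]
  adjacent26 <- function(v, u) {
    dk <- abs(ind[u, 1] - ind[v, 1])
    dj <- abs(ind[u, 2] - ind[v, 2])
    di <- abs(ind[u, 3] - ind[v, 3])
    max(dk, dj, di) == 1
  }
  repeat {
    best_v <- 0
    for (v in seq_len(n)) {
      if (lab[v] != 0) next
      admissible <- FALSE
      for (u in seq_len(n)) {
        if (lab[u] == 0 || !adjacent26(v, u)) next
        s <- lab[u]
        sv <- seeds[s]
        if (!(stack[v] > thr[s])) next
        if (abs(ind[v, 3] - ind[sv, 3]) > maxr_xy ||
            abs(ind[v, 2] - ind[sv, 2]) > maxr_xy ||
            abs(ind[v, 1] - ind[sv, 1]) > maxr_z) next
        admissible <- TRUE
        break
      }
      if (!admissible) next
      if (best_v == 0 || stack[v] > stack[best_v]) best_v <- v
    }
    if (best_v == 0) break
    # best labelled neighbour (brightest, tie lower index)
    bn <- 0
    for (u in seq_len(n)) {
      if (lab[u] == 0 || !adjacent26(best_v, u)) next
      s <- lab[u]
      sv <- seeds[s]
      if (!(stack[best_v] > thr[s])) next
      if (abs(ind[best_v, 3] - ind[sv, 3]) > maxr_xy ||
          abs(ind[best_v, 2] - ind[sv, 2]) > maxr_xy ||
          abs(ind[best_v, 1] - ind[sv, 1]) > maxr_z) next
      if (bn == 0 || stack[u] > stack[bn]) bn <- u
    }
    lab[best_v] <- lab[bn]
  }
  sizes <- tabulate(lab, max(lab, 1))
  for (s in seq_along(sizes))
    if (sizes[s] < params$min_voxels || sizes[s] > params$max_voxels)
      lab[lab == s] <- 0L
  array(lab, d)
}

# noiseless rendering of a single isolated emitter, via the package
render_single <- function(size_nm, optics, spacing = c(150, 20, 20),
                          extent_nm = 1600) {
  grid <- voxel_grid(c(max(9, ceiling(extent_nm / spacing[1])),
                       ceiling(extent_nm / spacing[2]),
                       ceiling(extent_nm / spacing[3])), spacing)
  # exact voxel centre, so rendered blobs are grid-symmetric
  center <- c(floor((grid$shape[["x"]] - 1) / 2) * spacing[3],
              floor((grid$shape[["y"]] - 1) / 2) * spacing[2],
              floor((grid$shape[["z"]] - 1) / 2) * spacing[1])
  scene <- structure(list(
    config = scene_config(n_spines = 0),
    box_nm = c(x = extent_nm, y = extent_nm, z = extent_nm),
    spines = synapsenano:::empty_spines(),
    emitters = data.frame(channel = "psd95", x = center[1], y = center[2],
                          z = center[3], size_nm = size_nm, amplitude = 1,
                          spine_id = NA_integer_, module_id = 1L)),
    class = "synthetic_scene")
  st <- render_channels(scene, grids = list(psd95 = grid),
                        optics = list(psd95 = optics),
                        channels = "psd95", noise = FALSE)
  list(img = st$psd95$img, grid = grid, center = center,
       integrals = st$psd95$emitter_integrals)
}

analytic_profile <- function(mu, sigma, amp = 100, offset = 2,
                             step = 5, half = 300) {
  x <- seq(-half, half, by = step)
  structure(data.frame(position_nm = x,
                       intensity = offset + amp * exp(-(x - mu)^2 /
                                                        (2 * sigma^2))),
            class = c("line_profile", "data.frame"))
}
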