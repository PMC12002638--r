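sted_grid_small <- function(shape = c(9, 48, 48))
  voxel_grid(shape, c(150, 20, 20))

test_that("a single noiseless blob segments to one cluster at its centre", {
  optics <- sted_optics()
  r <- render_single(150, optics, extent_nm = 1800)
  ncs <- segment_nanoclusters(r$img, r$grid)
  expect_equal(nrow(ncs), 1)
  expect_lt(abs(ncs$cx - r$center[1]), r$grid$spacing[["x"]] / 2)
  expect_lt(abs(ncs$cy - r$center[2]), r$grid$spacing[["y"]] / 2)
  expect_lt(abs(ncs$cz - r$center[3]), r$grid$spacing[["z"]] / 2)
  expect_equal(ncs$volume_um3, ncs$n_voxels * voxel_volume_um3(r$grid))
})

test_that("two blobs resolve at 400 nm and merge at 40 nm", {
  grid <- sted_grid_small(c(9, 64, 64))
  mid <- c(630, 630, 600)
  two_blob <- function(sep_nm) {
    scene <- structure(list(
      config = scene_config(n_spines = 0),
      box_nm = c(x = 1280, y = 1280, z = 1350),
      spines = synapsenano:::empty_spines(),
      emitters = data.frame(channel = "psd95",
                            x = mid[1] + c(-sep_nm / 2, sep_nm / 2),
                            y = mid[2], z = mid[3], size_nm = 100,
                            amplitude = 1, spine_id = NA_integer_,
                            module_id = 1:2)),
      class = "synthetic_scene")
    st <- render_channels(scene, grids = list(psd95 = grid),
                          optics = list(psd95 = sted_optics()),
                          channels = "psd95", noise = FALSE)
    segment_nanoclusters(st$psd95$img, grid)
  }
  expect_equal(nrow(two_blob(400)), 2)
  expect_equal(nrow(two_blob(40)), 1)
})

test_that("an all-background stack yields an empty cluster list", {
  img <- array(1, c(5, 16, 16))
  ncs <- segment_nanoclusters(img, sted_grid_small(c(5, 16, 16)))
  expect_equal(nrow(ncs), 0)
})

test_that("segmentation matches the brute-force oracle on random stacks", {
  set.seed(11)
  params <- segmentation_params(maxima_radius_xy = 2, maxima_radius_z = 1,
                                max_radius = 6, smooth_sigma_px = 0)
  grid <- voxel_grid(c(6, 12, 12), c(150, 20, 20))
  for (rep in 1:12) {
    img <- array(rpois(6 * 12 * 12, 1), c(6, 12, 12))
    # a few bright spots
    for (s in 1:3) {
      at <- c(sample(2:5, 1), sample(3:10, 1), sample(3:10, 1))
      img[at[1], at[2], at[3]] <- img[at[1], at[2], at[3]] + sample(8:15, 1)
      img[at[1], at[2] + 1, at[3]] <- img[at[1], at[2] + 1, at[3]] + 4
    }
    ncs <- segment_nanoclusters(img, grid, params)
    want <- oracle_segment_labels(img, params, grid)
    got <- array(0L, dim(img))
    for (i in seq_len(nrow(ncs))) got[ncs$voxels[[i]]] <- i
    # same voxel partition (label ids may differ)
    expect_equal(got > 0, want > 0)
    if (any(got > 0)) {
      key_got <- split(which(got > 0), got[got > 0])
      key_want <- split(which(want > 0), want[want > 0])
      expect_equal(sort(unname(vapply(key_got, paste, "", collapse = ","))),
                   sort(unname(vapply(key_want, paste, "", collapse = ","))))
    }
  }
})

test_that("clusters within a channel never share voxels", {
  set.seed(12)
  grid <- voxel_grid(c(6, 20, 20), c(150, 20, 20))
  for (rep in 1:5) {
    img <- array(rpois(6 * 20 * 20, 2), c(6, 20, 20))
    img[3, 8, 8] <- 30; img[4, 14, 14] <- 25
    ncs <- segment_nanoclusters(img, grid,
                                segmentation_params(smooth_sigma_px = 0))
    vox <- unlist(ncs$voxels)
    expect_equal(anyDuplicated(vox), 0)
  }
})

test_that("lateral smoothing matches a direct convolution oracle", {
  set.seed(13)
  img <- array(rpois(4 * 10 * 10, 3), c(4, 10, 10))
  sm <- smooth_stack(img, 0.8)
  half <- ceiling(3 * 0.8)
  kern <- exp(-0.5 * (-half:half)^2 / 0.8^2)
  kern <- kern / sum(kern)
  refl <- function(i, n) ifelse(i < 1, 1 - i, ifelse(i > n, 2 * n + 1 - i, i))
  for (pt in list(c(2, 5, 5), c(1, 1, 1), c(4, 10, 3))) {
    acc <- 0
    for (dj in -half:half) for (di in -half:half) {
      j <- refl(pt[2] + dj, 10); i <- refl(pt[3] + di, 10)
      acc <- acc + kern[dj + half + 1] * kern[di + half + 1] * img[pt[1], j, i]
    }
    expect_equal(sm[pt[1], pt[2], pt[3]], acc, tolerance = 1e-12)
  }
  expect_identical(smooth_stack(img, 0), img)
})

test_that("nearest-neighbour distances are the A-to-B minima", {
  a <- rbind(c(0, 0, 0))
  b <- rbind(c(0, 0, 100), c(0, 300, 0))
  expect_equal(nearest_neighbor_distances(a, b), 100)
  expect_equal(nearest_neighbor_distances(b, b), c(0, 0))
  expect_error(nearest_neighbor_distances(a, matrix(0, 0, 3)), "empty")

  set.seed(14)
  ra <- matrix(runif(30, 0, 1000), 10, 3)
  rb <- matrix(runif(45, 0, 1000), 15, 3)
  expect_equal(nearest_neighbor_distances(ra, rb), oracle_nn(ra, rb))
})

test_that("trans-synaptic pairs follow the overlap and orientation rules", {
  grid <- voxel_grid(c(4, 8, 8), c(150, 20, 20))
  mk <- function(vox_list, centers) {
    n <- length(vox_list)
    out <- data.frame(id = seq_len(n), channel = "x",
                      n_voxels = lengths(vox_list),
                      volume_um3 = lengths(vox_list) * voxel_volume_um3(grid),
                      cx = centers[, 1], cy = centers[, 2],
                      cz = centers[, 3], peak = 1,
                      peak_index0 = vapply(vox_list, `[`, 0L, 1) - 1L)
    out$voxels <- vox_list
    attr(out, "grid") <- grid
    class(out) <- c("nanoclusters", class(out))
    out
  }
  a <- mk(list(1:6, 101:104), rbind(c(0, 0, 0), c(500, 0, 0)))
  b_disjoint <- mk(list(7:9), rbind(c(0, 100, 0)))
  expect_equal(nrow(trans_synaptic_pairs(a, b_disjoint)$pairs), 0)
  expect_equal(trans_synaptic_pairs(a, b_disjoint)$pct_a_paired, 0)

  self <- trans_synaptic_pairs(a, a)
  expect_equal(nrow(self$pairs), 2)
  expect_true(all(self$pairs$distance_nm == 0))
  expect_equal(self$pct_a_paired, 100)

  # orientation: lateral-dominant offset is class A, axial-dominant B
  b_lat <- mk(list(4:8), rbind(c(120, 40, 50)))
  expect_equal(trans_synaptic_pairs(a, b_lat)$pairs$orientation, "A")
  b_ax <- mk(list(4:8), rbind(c(40, 40, 150)))
  expect_equal(trans_synaptic_pairs(a, b_ax)$pairs$orientation, "B")
})

test_that("trans-synaptic pairing matches the exhaustive oracle", {
  set.seed(15)
  grid <- voxel_grid(c(4, 10, 10), c(150, 20, 20))
  for (rep in 1:20) {
    mk_rand <- function(n) {
      vox <- lapply(seq_len(n), function(i) sort(sample(400, sample(3:20, 1))))
      centers <- matrix(runif(3 * n, 0, 500), n, 3)
      out <- data.frame(id = seq_len(n), channel = "x",
                        n_voxels = lengths(vox),
                        volume_um3 = 1, cx = centers[, 1], cy = centers[, 2],
                        cz = centers[, 3], peak = 1, peak_index0 = 0L)
      out$voxels <- vox
      attr(out, "grid") <- grid
      class(out) <- c("nanoclusters", class(out))
      out
    }
    a <- mk_rand(3)
    b <- mk_rand(3)
    for (mo in 1:3) {
      got <- trans_synaptic_pairs(a, b, min_overlap_vox = mo)$pairs
      want <- oracle_cocluster_pairs(a$voxels, b$voxels, mo)
      expect_equal(nrow(got), NROW(want))
      if (NROW(want)) {
        o <- order(got$a, got$b)
        expect_equal(as.matrix(got[o, c("a", "b", "overlap_vox")]),
                     want[order(want[, 1], want[, 2]), , drop = FALSE],
                     ignore_attr = TRUE)
      }
    }
  }
})

test_that("pure-lateral and pure-axial cleft offsets recover their
          orientation class", {
  lat <- recover_cleft_distance(60, seed = 31, chunk = 20,
                                config_args = list(cleft_theta_deg = 90))
  expect_gte(100 * mean(lat$orientation == "A"), 95)
  ax <- recover_cleft_distance(60, seed = 31, chunk = 20,
                               config_args = list(cleft_theta_deg = 0))
  expect_gte(100 * mean(ax$orientation == "B"), 95)
})

test_that("cleft-offset recovery is accurate across the 80-200 nm range", {
  # range endpoints; the 140 nm mid-range case is the acceptance check
  for (off in c(80, 200)) {
    r <- recover_cleft_distance(200, cleft_offset_nm = off, seed = 21)
    se <- sd(r$distances_nm) / sqrt(r$n_pairs)
    # 2 SE plus a 4% allowance for the sub-Nyquist axial quantisation and
    # overlap-selection bias discussed in the methods vignette
    expect_lt(abs(r$mean_distance_nm - off), 2 * se + 0.04 * off)
    expect_gte(r$n_pairs, 200)
  }
})

test_that("bead volumes are reproducible across seeds", {
  vols <- vapply(1:5, function(s) {
    ph <- build_nanoruler_phantom(0, "lateral", n_pairs = 40,
                                  seed = 100 + s, jitter_sd_nm = 0)
    mean(segment_nanoclusters(ph$img, ph$grid)$volume_um3)
  }, 0)
  expect_lt(sd(vols) / mean(vols), 0.15)
})
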