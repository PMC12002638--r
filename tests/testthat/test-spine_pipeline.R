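scene_small <- build_scene(scene_config(n_spines = 4, p_tc = 0.5,
                                        exact_class_counts = TRUE, seed = 21))
conf_grid <- scene_grids(scene_small)$confocal

test_that("truth-mode ROIs reproduce the generator masks", {
  recs <- derive_spine_rois(grid = conf_grid, scene = scene_small)
  expect_length(recs, 4)
  for (r in recs)
    expect_identical(r$mask,
                     spine_mask_indices(scene_small, r$id, conf_grid))
})

test_that("threshold-mode ROIs find rendered spines", {
  st <- render_channels(scene_small, channels = "yfp", noise = FALSE)
  recs <- derive_spine_rois(st$yfp$img, st$yfp$grid, k = 2)
  # spines merge with the shaft into components; at least one is found
  expect_gte(length(recs), 1)
  expect_warning(derive_spine_rois(array(1, c(3, 8, 8)), conf_grid),
                 "no spines")
})

test_that("spine orientation follows the principal axis of the mask", {
  sc <- build_scene(scene_config(n_spines = 9, seed = 33))
  recs <- derive_spine_rois(grid = scene_grids(sc)$confocal, scene = sc)
  got <- vapply(recs, `[[`, "", "orientation")
  expect_equal(got, sc$spines$orientation)
})

test_that("PSD-95 assignment demands full containment", {
  recs <- derive_spine_rois(grid = conf_grid, scene = scene_small)
  sp <- recs[[1]]
  s <- scene_small$spines[1, ]
  sted <- scene_grids(scene_small)$sted
  mk_nc <- function(center, half_nm) {
    xs <- seq(center[1] - half_nm, center[1] + half_nm, by = 20)
    ys <- seq(center[2] - half_nm, center[2] + half_nm, by = 20)
    g <- expand.grid(x = xs, y = ys)
    idx <- coords_to_index(sted, cbind(g$x, g$y, center[3]))
    out <- data.frame(id = 1L, channel = "psd95",
                      n_voxels = length(idx), volume_um3 = 1,
                      cx = center[1], cy = center[2], cz = center[3],
                      peak = 10, peak_index0 = idx[1] - 1L)
    out$voxels <- list(sort(idx))
    attr(out, "grid") <- sted
    class(out) <- c("nanoclusters", class(out))
    out
  }
  interior <- mk_nc(c(s$x, s$y, s$z), 60)
  expect_equal(assign_psd95(sp, interior), 1L)
  # centred on the head surface: part of the footprint leaves the mask
  straddle <- mk_nc(c(s$x + s$head_radius_nm, s$y, s$z), 120)
  expect_length(assign_psd95(sp, straddle), 0)
  # but a straddling Bassoon is associated via partial overlap
  expect_equal(assign_bassoon(sp, straddle), 1L)
  # far away: neither assigned nor associated
  far <- mk_nc(c(s$x + s$head_radius_nm + 700, s$y, s$z), 60)
  expect_length(assign_psd95(sp, far), 0)
  expect_length(assign_bassoon(sp, far), 0)
  # no overlap but centroid within the proximity band (placement leaves
  # room for the ~1-voxel rasterisation slack of the mask surface)
  near <- mk_nc(c(s$x + s$head_radius_nm + 120, s$y, s$z), 20)
  expect_equal(assign_bassoon(sp, near, proximity_nm = 200), 1L)
  expect_length(assign_bassoon(sp, near, proximity_nm = 50), 0)
})

test_that("containment matches an exhaustive point-in-mask oracle", {
  set.seed(22)
  recs <- derive_spine_rois(grid = conf_grid, scene = scene_small)
  sp <- recs[[2]]
  s <- scene_small$spines[2, ]
  sted <- scene_grids(scene_small)$sted
  for (rep in 1:20) {
    center <- c(s$x, s$y, s$z) + runif(3, -600, 600)
    pts <- cbind(center[1] + runif(8, -80, 80),
                 center[2] + runif(8, -80, 80),
                 center[3] + runif(8, -150, 150))
    idx <- coords_to_index(sted, pts)
    if (anyNA(idx)) next
    nc <- data.frame(id = 1L, channel = "psd95", n_voxels = length(idx),
                     volume_um3 = 1, cx = center[1], cy = center[2],
                     cz = center[3], peak = 1, peak_index0 = idx[1] - 1L)
    nc$voxels <- list(idx)
    attr(nc, "grid") <- sted
    class(nc) <- c("nanoclusters", class(nc))
    vox_xyz <- voxel_coords(sted, idx)
    inside <- vapply(seq_len(nrow(vox_xyz)), function(i) {
      m <- coords_to_index(conf_grid, vox_xyz[i, , drop = FALSE])
      !is.na(m) && m %in% sp$mask
    }, logical(1))
    expect_equal(length(assign_psd95(sp, nc)) == 1, all(inside))
  }
})

test_that("nanomodule counting is keyed on PSD-95", {
  pairs1 <- list(pairs = data.frame(a = 1L, b = 1L))
  expect_equal(count_nanomodules(NULL, pairs1), 1)
  # two PSD-95 aligned with the same Bassoon count as 2
  pairs2 <- list(pairs = data.frame(a = c(1L, 2L), b = c(1L, 1L)))
  expect_equal(count_nanomodules(NULL, pairs2), 2)
  expect_equal(count_nanomodules(NULL, list(pairs = data.frame(a = integer(),
                                                               b = integer()))),
               0)
})

test_that("input classification implements the dual-innervation tie-break", {
  mkp <- function(pixsets) {
    n <- length(pixsets)
    out <- data.frame(id = seq_len(n), n_px = lengths(pixsets),
                      area_um2 = 1, cx = 0, cy = 0, mean_intensity = NA)
    out$pixels <- pixsets
    attr(out, "mask_dim") <- c(30L, 30L)
    class(out) <- c("puncta", class(out))
    out
  }
  spine_px <- 1:20
  vg1 <- mkp(list(15:25))        # 6 px overlap
  vg2 <- mkp(list(40:60))        # none
  expect_equal(classify_input(spine_px, vg1, vg2)$class, "CC")
  expect_equal(classify_input(spine_px, vg2, vg1)$class, "TC")
  expect_equal(classify_input(spine_px, NULL, NULL)$class, "unclassified")
  # single-pixel overlap is not colocalization
  vg_1px <- mkp(list(20:30))
  expect_equal(classify_input(spine_px, vg_1px, vg2)$class, "unclassified")
  # dual overlap, tie broken by the nanomodule footprint
  vg2_dual <- mkp(list(10:18))
  r <- classify_input(spine_px, vg1, vg2_dual, nanomodule_px = 10:14)
  expect_true(r$dual)
  expect_equal(r$class, "TC")
  r2 <- classify_input(spine_px, vg1, vg2_dual, nanomodule_px = 16:19)
  expect_equal(r2$class, "CC")
  # still tied on the footprint: larger overlap wins
  r3 <- classify_input(spine_px, vg1, vg2_dual)
  expect_equal(r3$class, "TC") # 9 px vs 6 px
})

test_that("spine metrics sum assigned volumes and stay undefined at zero", {
  sp <- list(volume_um3 = 0.5)
  m <- spine_metrics(sp, c(0.01, 0.02))
  expect_equal(m$total_psd95_volume_um3, 0.03)
  expect_equal(m$mean_nc_volume_um3, 0.015)
  m0 <- spine_metrics(sp, numeric(0))
  expect_true(is.na(m0$total_psd95_volume_um3))
  expect_true(is.na(m0$mean_nc_volume_um3))
})

test_that("recovered nanomodule counts match the generated distribution", {
  r <- recover_nanomodule_fraction(300, seed = 51)
  pos <- r$counts[r$counts >= 1]
  obs <- tabulate(pos, 4)
  expected <- scene_config()$nanomodule_pmf_cc * length(pos)
  # chi-square goodness of fit against the generator pmf at alpha 0.01
  keep <- expected > 0
  chi2 <- sum((obs[keep] - expected[keep])^2 / expected[keep])
  expect_gt(pchisq(chi2, df = sum(keep) - 1, lower.tail = FALSE), 0.01)
  # and per-spine agreement with the truth is nearly perfect
  expect_gt(mean(r$counts == r$true_counts), 0.95)
})

test_that("input classification is near-perfect at default noise and exact
          without it", {
  r <- recover_input_fraction(120, seed = 52)
  expect_gte(r$accuracy, 0.95)
  expect_lt(r$pct_dual, 5)

  # noiseless limit: every spine classified correctly
  sc <- build_scene(scene_config(n_spines = 12, p_tc = 0.5,
                                 exact_class_counts = TRUE, seed = 53))
  st <- render_channels(sc, channels = c("vglut1", "vglut2"), noise = FALSE)
  g2 <- st$vglut1$grid
  recs <- derive_spine_rois(grid = g2, scene = sc)
  pu <- lapply(st, function(s)
    extract_puncta(threshold_mask(max_project(s$img, s$grid), 2),
                   grid = s$grid))
  cl <- vapply(recs, function(sp)
    classify_input(synapsenano:::project_mask_px(sp, g2),
                   pu$vglut1, pu$vglut2)$class, "")
  expect_equal(cl, sc$spines$class)
})

test_that("spine volume scales with recovered nanomodule count at the
          generated increment", {
  res <- NULL
  for (i in 1:6) {
    sc <- build_scene(scene_config(n_spines = 25, p_tc = 0, seed = 400 + i))
    st <- render_channels(sc, channels = c("psd95", "bassoon"))
    res <- rbind(res, analyze_spines(sc, st))
  }
  keep <- res$n_modules > 0
  f <- fit_size_scaling(res$n_modules[keep], res$volume_um3[keep])
  incr <- scene_config()$spine_volume_per_module_um3
  expect_lt(abs(f$slope - incr), 2 * f$slope_se)
})
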