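test_that("empty and degenerate configurations behave as documented", {
  empty <- build_scene(scene_config(n_spines = 0))
  expect_equal(nrow(empty$spines), 0)
  expect_equal(nrow(empty$emitters), 0)

  cfg <- scene_config(n_spines = 8, p_tc = 1,
                      nanomodule_pmf_tc = c(1, 0, 0, 0), seed = 4)
  sc <- build_scene(cfg)
  expect_true(all(sc$spines$class == "TC"))
  expect_true(all(sc$spines$n_modules == 1))
  expect_equal(sum(sc$emitters$channel == "psd95"), 8)
  expect_equal(sum(sc$emitters$channel == "bassoon"), 8)
  expect_equal(sum(sc$emitters$channel == "vglut2"), 8)
  expect_equal(sum(sc$emitters$channel == "vglut1"), 0)
})

test_that("identical seeds give bit-identical scenes, different seeds differ", {
  cfg <- scene_config(n_spines = 6, seed = 7)
  a <- build_scene(cfg)
  b <- build_scene(cfg)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  c <- build_scene(scene_config(n_spines = 6, seed = 8))
  expect_false(identical(a$spines$x, c$spines$x))
})

test_that("rendering is deterministic under a fixed seed", {
  sc <- build_scene(scene_config(n_spines = 3, seed = 5))
  s1 <- render_channels(sc, channels = "psd95", seed = 11)
  s2 <- render_channels(sc, channels = "psd95", seed = 11)
  s3 <- render_channels(sc, channels = "psd95", seed = 12)
  expect_identical(s1$psd95$img, s2$psd95$img)
  expect_false(identical(s1$psd95$img, s3$psd95$img))
})

test_that("ground truth is internally consistent", {
  sc <- build_scene(scene_config(n_spines = 10, seed = 2))
  grids <- scene_grids(sc)
  masks <- lapply(sc$spines$id, spine_mask_indices, scene = sc,
                  grid = grids$confocal)
  psd <- sc$emitters[sc$emitters$channel == "psd95", ]
  bas <- sc$emitters[sc$emitters$channel == "bassoon", ]
  # each PSD-95 emitter lies inside exactly one spine mask
  for (e in seq_len(nrow(psd))) {
    idx <- coords_to_index(grids$confocal,
                           cbind(psd$x[e], psd$y[e], psd$z[e]))
    hits <- vapply(masks, function(m) idx %in% m, logical(1))
    expect_equal(sum(hits), 1)
    expect_true(which(hits) == psd$spine_id[e])
  }
  # paired Bassoon separation equals the cleft offset exactly
  sep <- sqrt((psd$x - bas$x)^2 + (psd$y - bas$y)^2 + (psd$z - bas$z)^2)
  expect_true(all(abs(sep - sc$config$cleft_offset_nm) < 1e-6))
  # all emitters inside the scene box
  expect_true(all(sc$emitters$x >= 0 & sc$emitters$x <= sc$box_nm[["x"]]))
  expect_true(all(sc$emitters$z >= 0 & sc$emitters$z <= sc$box_nm[["z"]]))
})

test_that("noiseless renders conserve photons", {
  sc <- build_scene(scene_config(n_spines = 4, seed = 9))
  st <- render_channels(sc, channels = c("psd95", "bassoon"), noise = FALSE)
  for (ch in names(st)) {
    got <- sum(st[[ch]]$img)
    bg <- st[[ch]]$optics$background_photons * length(st[[ch]]$img)
    want <- sum(st[[ch]]$emitter_integrals) + bg
    expect_lt(abs(got - want) / want, 0.001)
  }
})

test_that("Poisson sampling is unbiased: mean of many renders matches the
          noiseless expectation", {
  sc <- build_scene(scene_config(n_spines = 1, seed = 3))
  clean <- render_channels(sc, channels = "psd95", noise = FALSE)$psd95
  hot <- clean$img > 0.5
  acc <- 0
  n_rep <- 100
  for (r in seq_len(n_rep))
    acc <- acc + render_channels(sc, channels = "psd95",
                                 seed = 1000 + r)$psd95$img[hot]
  mu <- clean$img[hot]
  se <- sqrt(mu / n_rep)
  expect_gt(mean(abs(acc / n_rep - mu) <= 3 * se), 0.98)
})

test_that("rendered image FWHM obeys the quadrature law across sizes", {
  set.seed(42)
  optics <- sted_optics()
  for (a in runif(10, 0, 200)) {
    r <- render_single(a, optics)
    proj <- max_project(r$img, r$grid)
    prof <- line_profile(proj, r$grid, r$center[1:2], direction = c(1, 0),
                         length_nm = 1200, step_nm = 10)
    f <- fit_fwhm(prof)
    expect_true(f$converged)
    expect_lt(abs(f$fwhm_nm - sqrt(a^2 + optics$lateral_fwhm^2)),
              r$grid$spacing[["x"]] / 2)
  }
})

test_that("rendering rejects grids too coarse for the footprint", {
  sc <- build_scene(scene_config(n_spines = 1, seed = 3))
  coarse <- voxel_grid(c(4, 10, 10), c(400, 500, 500))
  expect_error(render_channels(sc, grids = list(psd95 = coarse),
                               optics = list(psd95 = sted_optics()),
                               channels = "psd95"),
               "too coarse")
})

test_that("nanoruler phantoms record designed and realised spacings", {
  ph <- build_nanoruler_phantom(50, "lateral", n_pairs = 43, seed = 6)
  expect_equal(nrow(ph$truth), 43)
  expect_equal(unique(ph$truth$designed_nm), 50)
  expect_true(all(abs(ph$truth$realized_nm - 50) < 15))
  expect_gt(sd(ph$truth$realized_nm), 0) # jitter on by default

  ph0 <- build_nanoruler_phantom(0, "lateral", n_pairs = 3,
                                 jitter_sd_nm = 0, seed = 6, noise = FALSE)
  expect_true(all(ph0$truth$realized_nm == 0))

  # axial pairs at 90 nm on a 150 nm grid cannot be contained in a
  # single z-plane: every pair deposits light in at least two planes
  g <- voxel_grid(c(9, 216, 270), c(150, 20, 20))
  pha <- build_nanoruler_phantom(90, "axial", n_pairs = 10, grid = g,
                                 jitter_sd_nm = 0, seed = 1, noise = FALSE)
  for (p in unique(pha$truth$pair)) {
    pr <- axial_profile(pha$img, pha$grid,
                        c(pha$truth$x[p], pha$truth$y[p]), radius_nm = 150)
    bg <- pha$optics$background_photons * sum(pr$intensity > -Inf)
    expect_gte(sum(pr$intensity > max(pr$intensity) / 10), 2)
  }
  expect_error(build_nanoruler_phantom(90, "axial", n_pairs = 2,
                                       grid = voxel_grid(c(3, 60, 60),
                                                         c(150, 20, 20))),
               "z-planes")
})

test_that("scene placement constraints are enforced", {
  cfg <- scene_config(n_spines = 9, seed = 1)
  expect_error(build_scene(cfg, box_nm = c(3000, 3000, 2000)),
               "cannot place")
  sc <- build_scene(cfg)
  d <- as.matrix(dist(sc$spines[, c("x", "y", "z")]))
  diag(d) <- Inf
  gaps <- d - outer(sc$spines$head_radius_nm, sc$spines$head_radius_nm, "+")
  expect_true(all(gaps > sc$config$min_gap_nm - 101)) # placement jitter
})
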