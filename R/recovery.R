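#' Parameter-recovery experiments
#'
#' Each `recover_*` function generates synthetic data under the study
#' conditions encoded in the generator defaults, runs the corresponding
#' analysis stage end-to-end, and returns the recovered quantity next to
#' the ground truth. They are the package's calibration suite: if a
#' stage is wrong, the recovered value drifts from the generated one.
#'
#' @name recovery
NULL

#' Recover the nanomodule-count distribution of a VGluT1+ population
#'
#' Generates VGluT1+ spines whose nanomodule counts follow the basal
#' corticocortical count distribution, renders the PSD-95 and Bassoon
#' STED channels at default optics and noise, runs per-spine nanocluster
#' identification, assignment, trans-synaptic pairing and counting, and
#' reports the fraction of spines (among those with at least one aligned
#' nanomodule) recovered with exactly one.
#'
#' @param n_spines total spines to simulate (default 500).
#' @param seed RNG seed.
#' @param chunk spines per rendered field (memory/time trade-off).
#' @param config_args overrides passed to [scene_config()].
#' @return List with `single_pct`, the recovered and true count tables,
#'   `n_spines`, and `n_zero` (spines with no aligned module, excluded
#'   from the fraction's denominator and reported separately).
#' @export
recover_nanomodule_fraction <- function(n_spines = 500, seed = 1,
                                        chunk = 25, config_args = list()) {
  counts <- integer(0)
  truth <- integer(0)
  done <- 0
  i <- 0
  while (done < n_spines) {
    i <- i + 1
    k <- min(chunk, n_spines - done)
    cfg <- do.call(scene_config, modifyList(
      list(n_spines = k, p_tc = 0, seed = derive_seed(seed, i)),
      config_args))
    scene <- build_scene(cfg)
    stacks <- render_channels(scene, channels = c("psd95", "bassoon"))
    tab <- analyze_spines(scene, stacks)
    counts <- c(counts, tab$n_modules)
    truth <- c(truth, tab$true_n_modules)
    done <- done + k
  }
  pos <- counts[counts >= 1]
  list(single_pct = 100 * mean(pos == 1),
       n_spines = n_spines, n_zero = sum(counts == 0),
       recovered = tabulate(pos, 8), truth = tabulate(truth, 8),
       counts = counts, true_counts = truth)
}

#' Recover the TC fraction of a mixed VGluT1/VGluT2 population
#'
#' Generates a spine population whose TC/CC identities follow the target
#' composition exactly, renders the VGluT1 and VGluT2 confocal channels,
#' classifies each spine from marker overlap with its projected mask,
#' and reports the recovered TC percentage.
#'
#' @param n_spines total spines (default 507).
#' @param p_tc TC proportion (default 68/507).
#' @param seed RNG seed.
#' @param chunk spines per rendered field.
#' @param config_args overrides passed to [scene_config()].
#' @return List with `tc_pct`, per-class confusion counts, `accuracy`,
#'   and `n_spines`.
#' @export
recover_input_fraction <- function(n_spines = 507, p_tc = 68 / 507,
                                   seed = 1, chunk = 25,
                                   config_args = list()) {
  n_tc_total <- round(n_spines * p_tc)
  sizes <- rep(chunk, n_spines %/% chunk)
  if (n_spines %% chunk) sizes <- c(sizes, n_spines %% chunk)
  tc_per <- diff(round(cumsum(c(0, sizes)) / n_spines * n_tc_total))
  res <- list()
  for (i in seq_along(sizes)) {
    cfg <- do.call(scene_config, modifyList(
      list(n_spines = sizes[i], p_tc = tc_per[i] / sizes[i],
           exact_class_counts = TRUE, seed = derive_seed(seed, i)),
      config_args))
    scene <- build_scene(cfg)
    stacks <- render_channels(scene, channels = c("vglut1", "vglut2"))
    grid2 <- stacks$vglut1$grid
    spines <- derive_spine_rois(grid = grid2, scene = scene)
    puncta <- lapply(stacks, function(s)
      extract_puncta(threshold_mask(max_project(s$img, s$grid), 2),
                     grid = s$grid))
    cl <- lapply(spines, function(sp) {
      classify_input(project_mask_px(sp, grid2),
                     puncta$vglut1, puncta$vglut2)
    })
    res[[i]] <- data.frame(true = scene$spines$class,
                           recovered = vapply(cl, `[[`, "", "class"),
                           dual = vapply(cl, `[[`, NA, "dual"),
                           stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, res)
  classified <- df$recovered %in% c("CC", "TC")
  list(tc_pct = 100 * sum(df$recovered == "TC") / n_spines,
       accuracy = mean(df$true == df$recovered),
       n_spines = n_spines,
       n_unclassified = sum(!classified),
       pct_dual = 100 * mean(df$dual),
       confusion = table(truth = df$true, recovered = df$recovered))
}

#' Recover the trans-synaptic cleft offset
#'
#' Generates spines carrying exactly one PSD-95/Bassoon pair at the
#' configured cleft offset with the default lateral/axial orientation
#' mix, segments both STED channels over the whole frame, forms
#' >= 1-voxel-overlap pairs, and reports the pooled mean centre-to-centre
#' distance.
#'
#' @param n_pairs minimum number of pooled pairs (default 200).
#' @param cleft_offset_nm true offset (default 140).
#' @param seed RNG seed.
#' @param chunk spines per rendered field.
#' @param config_args overrides passed to [scene_config()].
#' @return List with `mean_distance_nm`, `n_pairs`, the pooled distances
#'   and orientation classes, and the true offset.
#' @export
recover_cleft_distance <- function(n_pairs = 200, cleft_offset_nm = 140,
                                   seed = 1, chunk = 25,
                                   config_args = list()) {
  dist <- numeric(0)
  orient <- character(0)
  i <- 0
  while (length(dist) < n_pairs) {
    i <- i + 1
    cfg <- do.call(scene_config, modifyList(
      list(n_spines = chunk, p_tc = 0,
           nanomodule_pmf_cc = c(1, 0, 0, 0),
           cleft_offset_nm = cleft_offset_nm,
           seed = derive_seed(seed, i)),
      config_args))
    scene <- build_scene(cfg)
    stacks <- render_channels(scene, channels = c("psd95", "bassoon"))
    ncs_p <- segment_nanoclusters(stacks$psd95$img, stacks$psd95$grid,
                                  channel = "psd95")
    ncs_b <- segment_nanoclusters(stacks$bassoon$img, stacks$bassoon$grid,
                                  channel = "bassoon")
    prs <- trans_synaptic_pairs(ncs_p, ncs_b)
    dist <- c(dist, prs$pairs$distance_nm)
    orient <- c(orient, prs$pairs$orientation)
  }
  list(mean_distance_nm = mean(dist), n_pairs = length(dist),
       distances_nm = dist, orientation = orient,
       true_offset_nm = cleft_offset_nm)
}

#' Recover the axial nano-ruler spacing
#'
#' Simulates axially spaced two-point rulers on the calibration z-grid,
#' extracts the laterally integrated axial profile of each pair, fits a
#' two-Gaussian model with the PSF-derived width held fixed, and reports
#' the mean fitted separation over resolved pairs.
#'
#' @param n_pairs number of simulated pairs (default 100).
#' @param spacing_nm designed axial spacing (default 90).
#' @param seed RNG seed.
#' @param optics channel optics.
#' @param z_step_nm calibration z sampling (default 50).
#' @return List with `mean_distance_nm`, `n_resolved`, `n_pairs` and the
#'   per-pair distances.
#' @export
recover_axial_ruler <- function(n_pairs = 100, spacing_nm = 90, seed = 1,
                                optics = sted_optics(), z_step_nm = 50) {
  ph <- build_nanoruler_phantom(spacing_nm, "axial", n_pairs,
                                optics = optics, seed = seed)
  if (abs(ph$grid$spacing[["z"]] - z_step_nm) > 1e-9) {
    zext <- spacing_nm + 1200
    grid <- voxel_grid(c(ceiling(zext / z_step_nm),
                         ph$grid$shape[["y"]], ph$grid$shape[["x"]]),
                       c(z_step_nm, ph$grid$spacing[["y"]],
                         ph$grid$spacing[["x"]]))
    ph <- build_nanoruler_phantom(spacing_nm, "axial", n_pairs, grid = grid,
                                  optics = optics, seed = seed)
  }
  sig <- sqrt(fwhm_to_sigma(optics$axial_fwhm)^2 +
                ph$grid$spacing[["z"]]^2 / 12)
  d <- vapply(seq_len(n_pairs), function(i) {
    pr <- axial_profile(ph$img, ph$grid,
                        c(ph$truth$x[i], ph$truth$y[i]), radius_nm = 150)
    ps <- peak_separation(pr, sigma_fixed = sig)
    if (ps$two_peak_preferred) ps$distance_nm else NA_real_
  }, 0)
  list(mean_distance_nm = mean(d, na.rm = TRUE),
       n_resolved = sum(!is.na(d)), n_pairs = n_pairs,
       distances_nm = d, designed_nm = spacing_nm)
}

#' Recover the lateral nano-ruler spacing and Rayleigh dip
#'
#' Simulates laterally spaced two-point rulers on the 20 nm STED grid,
#' takes a line profile along each pair's axis (averaged over a narrow
#' perpendicular band for signal-to-noise), fits the two-Gaussian model,
#' and reports the mean fitted peak-to-peak distance and dip of resolved
#' pairs.
#'
#' @param n_pairs number of simulated pairs (default 43).
#' @param spacing_nm designed lateral spacing (default 50).
#' @param seed RNG seed.
#' @param optics channel optics.
#' @return List with `mean_distance_nm`, `mean_dip_percent`,
#'   `n_resolved`, `n_pairs` and per-pair values.
#' @export
recover_lateral_ruler <- function(n_pairs = 43, spacing_nm = 50, seed = 1,
                                  optics = sted_optics()) {
  ph <- build_nanoruler_phantom(spacing_nm, "lateral", n_pairs,
                                optics = optics, seed = seed)
  sig <- sqrt(fwhm_to_sigma(optics$lateral_fwhm)^2 +
                ph$grid$spacing[["x"]]^2 / 12)
  # z-sum projection keeps all photons of each bead
  d3 <- dim(ph$img)
  proj <- matrix(colSums(matrix(ph$img, nrow = d3[1])), d3[2], d3[3])
  res <- lapply(seq_len(n_pairs), function(i) {
    # 5-line band average perpendicular to the pair axis
    prof <- NULL
    for (dy in c(-40, -20, 0, 20, 40)) {
      p <- line_profile(proj, ph$grid,
                        c(ph$truth$x[i], ph$truth$y[i] + dy),
                        direction = c(1, 0), length_nm = 600, step_nm = 20)
      prof <- if (is.null(prof)) p else
        within(prof, intensity <- intensity + p$intensity)
    }
    peak_separation(prof, sigma_fixed = sig)
  })
  ok <- vapply(res, function(r) isTRUE(r$resolved), logical(1))
  d <- vapply(res[ok], function(r) r$distance_nm, 0)
  dip <- vapply(res[ok], function(r) r$dip_percent, 0)
  list(mean_distance_nm = mean(d), mean_dip_percent = mean(dip),
       n_resolved = sum(ok), n_pairs = n_pairs,
       distances_nm = d, designed_nm = spacing_nm)
}

#' Recover the FWHM of isolated nanoclusters
#'
#' Renders isolated clusters whose intrinsic size convolved with the PSF
#' gives a target image-domain FWHM, segments them, profiles each
#' cluster through its centroid, fits the Gaussian FWHM, and reports the
#' mean over well-fit clusters.
#'
#' @param n_clusters number of clusters (default 100).
#' @param target_fwhm_nm target image-domain FWHM (default 126, the
#'   tau-STED nanobody-labelled cluster size).
#' @param seed RNG seed.
#' @param optics channel optics.
#' @return List with `mean_fwhm_nm`, `n_fit`, `n_clusters`, per-cluster
#'   values and the intrinsic size used.
#' @export
recover_fwhm <- function(n_clusters = 100, target_fwhm_nm = 126, seed = 1,
                         optics = sted_optics()) {
  stopifnot(target_fwhm_nm > optics$lateral_fwhm)
  intrinsic <- sqrt(target_fwhm_nm^2 - optics$lateral_fwhm^2)
  pitch <- 1500
  ncols <- ceiling(sqrt(n_clusters))
  nrows <- ceiling(n_clusters / ncols)
  grid <- voxel_grid(c(7, ceiling((nrows * pitch + 1000) / 20),
                       ceiling((ncols * pitch + 1000) / 20)),
                     c(150, 20, 20))
  with_seed(seed, {
    id <- seq_len(n_clusters)
    cx <- 500 + ((id - 1) %% ncols + 0.5) * pitch + runif(n_clusters, -10, 10)
    cy <- 500 + ((id - 1) %/% ncols + 0.5) * pitch + runif(n_clusters, -10, 10)
    zmid <- (grid$shape[["z"]] - 1) * grid$spacing[["z"]] / 2
    cz <- zmid + runif(n_clusters, -75, 75)
    em <- data.frame(channel = "psd95", x = cx, y = cy, z = cz,
                     size_nm = intrinsic, amplitude = 1,
                     spine_id = NA_integer_, module_id = id)
    r <- render_emitters(grid, em, optics)
    img <- r$img
    img[] <- rpois(length(img), img + optics$background_photons)
    ncs <- segment_nanoclusters(img, grid)
    proj <- max_project(img, grid)
    # one cluster per designed emitter: the brightest segmented cluster
    # whose centroid falls within 300 nm of the true position
    fw <- vapply(seq_len(n_clusters), function(i) {
      d2 <- (ncs$cx - cx[i])^2 + (ncs$cy - cy[i])^2
      cand <- which(d2 <= 300^2)
      if (!length(cand)) return(NA_real_)
      j <- cand[which.max(ncs$peak[cand])]
      f <- tryCatch(
        fit_fwhm(line_profile(proj, grid, c(ncs$cx[j], ncs$cy[j]),
                              direction = c(1, 0), length_nm = 800,
                              step_nm = 20)),
        error = function(e) list(converged = FALSE))
      if (isTRUE(f$converged) && !isTRUE(f$at_boundary)) f$fwhm_nm else
        NA_real_
    }, 0)
    list(mean_fwhm_nm = mean(fw, na.rm = TRUE), n_fit = sum(!is.na(fw)),
         n_clusters = n_clusters, fwhm_nm = fw,
         intrinsic_fwhm_nm = intrinsic, target_fwhm_nm = target_fwhm_nm)
  })
}
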