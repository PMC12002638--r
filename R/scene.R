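#' Build a ground-truth synthetic spine scene
#'
#' Draws a population of dendritic spines with known input class
#' (corticocortical VGluT1+ or thalamocortical VGluT2+), a known number of
#' trans-synaptically aligned PSD-95/Bassoon nanomodules each, and known
#' emitter positions and sizes. Spine heads are spheres on a square
#' lattice (surface gap at least `min_gap_nm`) with a short cylindrical
#' neck along the spine axis; each nanomodule contributes one PSD-95
#' emitter inside the head and one Bassoon emitter displaced by exactly
#' `cleft_offset_nm` along a direction drawn from the configured
#' lateral/axial mix; one VGluT emitter of the spine's class abuts the
#' head surface. The returned truth is the recovery oracle for every
#' downstream stage.
#'
#' @param config a [scene_config()].
#' @param box_nm optional scene box override, `c(x, y, z)` extents in nm;
#'   an error is raised if the spine lattice cannot be placed inside it
#'   without violating the minimum gap.
#' @return An object of class `synthetic_scene`: list with `config`,
#'   `box_nm`, `spines` (data frame: id, class, n_modules, centre,
#'   head radius, axis, orientation class, true volume), and `emitters`
#'   (data frame: channel, position nm, intrinsic FWHM nm, amplitude,
#'   spine and module ids).
#' @examples
#' sc <- build_scene(scene_config(n_spines = 4, seed = 1))
#' sc$spines[, c("id", "class", "n_modules")]
#' @export
build_scene <- function(config, box_nm = NULL) {
  validate_scene_config(config)
  n <- config$n_spines

  if (n == 0) {
    return(structure(list(config = config, box_nm = c(x = 2000, y = 2000, z = 2000),
                          spines = empty_spines(), emitters = empty_emitters()),
                     class = "synthetic_scene"))
  }

  with_seed(config$seed, {
    # input classes
    cls <- if (config$exact_class_counts) {
      k <- round(n * config$p_tc)
      sample(rep(c("TC", "CC"), c(k, n - k)))
    } else {
      ifelse(runif(n) < config$p_tc, "TC", "CC")
    }
    # nanomodule counts per class-specific pmf
    nmod <- integer(n)
    is_tc <- cls == "TC"
    if (any(is_tc))
      nmod[is_tc] <- sample.int(4, sum(is_tc), replace = TRUE,
                                prob = config$nanomodule_pmf_tc)
    if (any(!is_tc))
      nmod[!is_tc] <- sample.int(4, sum(!is_tc), replace = TRUE,
                                 prob = config$nanomodule_pmf_cc)
    # volumes and head radii
    vol <- config$spine_volume_base_um3 +
      config$spine_volume_per_module_um3 * nmod +
      rlnorm(n, config$spine_volume_noise_meanlog,
             config$spine_volume_noise_sdlog)
    r_nm <- (3 * vol / (4 * pi))^(1 / 3) * 1000

    # lattice placement
    rmax <- max(r_nm)
    # the pitch leaves the minimum surface gap plus room for spine necks
    pitch <- 2 * rmax + config$min_gap_nm + 700
    ncols <- ceiling(sqrt(n))
    nrows <- ceiling(n / ncols)
    edge <- rmax + 700 # room for PSF skirt, neck, and presynaptic blobs
    auto_box <- c(x = ncols * pitch + 2 * edge,
                  y = nrows * pitch + 2 * edge,
                  z = 2 * rmax + 1500)
    if (is.null(box_nm)) {
      box_nm <- auto_box
    } else {
      box_nm <- setNames(as.numeric(box_nm), c("x", "y", "z"))
      if (any(box_nm < auto_box - 1e-9))
        stop(sprintf(paste0("cannot place %d spines with >= %g nm surface gap ",
                            "in a %g x %g x %g nm box (needs %g x %g x %g)"),
                     n, config$min_gap_nm, box_nm[1], box_nm[2], box_nm[3],
                     auto_box[1], auto_box[2], auto_box[3]))
    }
    col <- ((seq_len(n) - 1) %% ncols)
    row <- ((seq_len(n) - 1) %/% ncols)
    # sub-voxel placement jitter: spines sample all grid phases
    cx <- edge + (col + 0.5) * pitch + runif(n, -50, 50)
    cy <- edge + (row + 0.5) * pitch + runif(n, -50, 50)
    cz <- box_nm[["z"]] / 2 + runif(n, -150, 150)

    # spine axis: mostly in-plane (Type A), some along the optical axis
    axis_type <- ifelse(runif(n) < 0.8, "A", "B")
    phi_ax <- runif(n, 0, 2 * pi)
    ax <- ifelse(axis_type == "A", cos(phi_ax), 0)
    ay <- ifelse(axis_type == "A", sin(phi_ax), 0)
    az <- ifelse(axis_type == "A", 0, sample(c(-1, 1), n, replace = TRUE))

    spines <- data.frame(id = seq_len(n), class = cls, n_modules = nmod,
                         x = cx, y = cy, z = cz, head_radius_nm = r_nm,
                         axis_x = ax, axis_y = ay, axis_z = az,
                         orientation = axis_type, volume_um3 = vol,
                         stringsAsFactors = FALSE)

    # nanomodule emitters: ring in the head equatorial plane, offset pairs
    em <- vector("list", n + 1)
    for (s in seq_len(n)) {
      k <- nmod[s]
      rho <- max(0, r_nm[s] - config$nc_margin_nm)
      if (k >= 2) {
        chord <- 2 * rho * sin(pi / k)
        if (chord < config$nc_min_separation_nm)
          stop(sprintf(paste0("spine %d (head radius %.0f nm) is too small to hold ",
                              "%d nanomodules %g nm apart"),
                       s, r_nm[s], k, config$nc_min_separation_nm))
      }
      ang <- runif(1, 0, 2 * pi) + 2 * pi * (seq_len(k) - 1) / k
      zjit <- runif(k, -30, 30)
      px <- cx[s] + rho * cos(ang)
      py <- cy[s] + rho * sin(ang)
      pz <- cz[s] + zjit
      # cleft offset direction: Type B (axially dominant) with prob mix,
      # or a fixed polar angle when cleft_theta_deg is set
      typeb <- runif(k) < config$cleft_axis_mix
      u <- runif(k)
      theta <- if (!is.null(config$cleft_theta_deg))
        rep(config$cleft_theta_deg * pi / 180, k)
      else
        ifelse(typeb, u * pi / 4, pi / 4 + u * pi / 4) # polar from z
      zsign <- sample(c(-1, 1), k, replace = TRUE)
      psi <- runif(k, 0, 2 * pi)
      dx <- sin(theta) * cos(psi)
      dy <- sin(theta) * sin(psi)
      dz <- cos(theta) * zsign
      sz <- pmin(220, pmax(80, rnorm(2 * k, config$nc_diameter_nm[["mean"]],
                                     config$nc_diameter_nm[["sd"]])))
      em[[s]] <- data.frame(
        channel = rep(c("psd95", "bassoon"), each = k),
        x = c(px, px + config$cleft_offset_nm * dx),
        y = c(py, py + config$cleft_offset_nm * dy),
        z = c(pz, pz + config$cleft_offset_nm * dz),
        size_nm = sz, amplitude = 1,
        spine_id = s, module_id = rep(seq_len(k), 2),
        stringsAsFactors = FALSE)
    }
    # presynaptic VGluT blob on the head surface, one per spine
    psi_v <- runif(n, 0, 2 * pi)
    em[[n + 1]] <- data.frame(
      channel = ifelse(cls == "TC", "vglut2", "vglut1"),
      x = cx + r_nm * cos(psi_v), y = cy + r_nm * sin(psi_v), z = cz,
      size_nm = config$vg_diameter_nm, amplitude = 1,
      spine_id = seq_len(n), module_id = NA_integer_,
      stringsAsFactors = FALSE)
    emitters <- do.call(rbind, em)
    rownames(emitters) <- NULL

    structure(list(config = config, box_nm = box_nm, spines = spines,
                   emitters = emitters),
              class = "synthetic_scene")
  })
}

empty_spines <- function() {
  data.frame(id = integer(), class = character(), n_modules = integer(),
             x = numeric(), y = numeric(), z = numeric(),
             head_radius_nm = numeric(), axis_x = numeric(),
             axis_y = numeric(), axis_z = numeric(),
             orientation = character(), volume_um3 = numeric(),
             stringsAsFactors = FALSE)
}

empty_emitters <- function() {
  data.frame(channel = character(), x = numeric(), y = numeric(),
             z = numeric(), size_nm = numeric(), amplitude = numeric(),
             spine_id = integer(), module_id = integer(),
             stringsAsFactors = FALSE)
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("synthetic_scene: %d spines (%d TC), %d emitters, box %.1f x %.1f x %.1f um\n",
              nrow(x$spines), sum(x$spines$class == "TC"), nrow(x$emitters),
              x$box_nm[["x"]] / 1000, x$box_nm[["y"]] / 1000,
              x$box_nm[["z"]] / 1000))
  invisible(x)
}

#' Default voxel grids covering a scene
#'
#' STED channels are sampled at 20 nm laterally and 150 nm axially;
#' confocal channels (morphology and VGluT markers) at 100 nm laterally
#' and 300 nm axially.
#'
#' @param scene a [build_scene()] result.
#' @param sted_spacing,confocal_spacing `(dz, dy, dx)` spacings in nm.
#' @return Named list of [voxel_grid()]s: `sted` and `confocal`.
#' @export
scene_grids <- function(scene, sted_spacing = c(150, 20, 20),
                        confocal_spacing = c(300, 100, 100)) {
  mk <- function(sp) {
    voxel_grid(c(ceiling(scene$box_nm[["z"]] / sp[1]),
                 ceiling(scene$box_nm[["y"]] / sp[2]),
                 ceiling(scene$box_nm[["x"]] / sp[3])), sp)
  }
  list(sted = mk(sted_spacing), confocal = mk(confocal_spacing))
}

#' Ground-truth spine mask on a grid
#'
#' Voxels whose centres fall inside the spine head sphere or the neck
#' cylinder (120 nm radius, 600 nm long, along the spine axis away from
#' the head).
#'
#' @param scene a [build_scene()] result.
#' @param id spine id.
#' @param grid the [voxel_grid()] to rasterise onto (normally the
#'   morphology/confocal grid).
#' @return Integer vector of 1-based linear voxel indices.
#' @export
spine_mask_indices <- function(scene, id, grid) {
  s <- scene$spines[scene$spines$id == id, ]
  stopifnot(nrow(s) == 1)
  r <- s$head_radius_nm
  neck_len <- 600
  neck_rad <- 120
  reach <- r + neck_len + max(grid$spacing)
  # bounding index ranges
  rng <- function(axis, c0) {
    lo <- max(1L, floor((c0 - reach - grid$origin[[axis]]) / grid$spacing[[axis]]) + 1)
    hi <- min(grid$shape[[axis]],
              ceiling((c0 + reach - grid$origin[[axis]]) / grid$spacing[[axis]]) + 1)
    if (lo > hi) integer(0) else seq.int(lo, hi)
  }
  ks <- rng("z", s$z); js <- rng("y", s$y); is <- rng("x", s$x)
  if (!length(ks) || !length(js) || !length(is)) return(integer(0))
  zc <- grid$origin[["z"]] + (ks - 1) * grid$spacing[["z"]] - s$z
  yc <- grid$origin[["y"]] + (js - 1) * grid$spacing[["y"]] - s$y
  xc <- grid$origin[["x"]] + (is - 1) * grid$spacing[["x"]] - s$x
  g <- expand.grid(dz = zc, dy = yc, dx = xc, KEEP.OUT.ATTRS = FALSE)
  in_head <- g$dx^2 + g$dy^2 + g$dz^2 <= r^2
  # neck: projection onto -axis in [r, r + neck_len], radial dist <= neck_rad
  t <- -(g$dx * s$axis_x + g$dy * s$axis_y + g$dz * s$axis_z)
  perp2 <- pmax(0, g$dx^2 + g$dy^2 + g$dz^2 - t^2)
  in_neck <- t >= r & t <= r + neck_len & perp2 <= neck_rad^2
  keep <- which(in_head | in_neck)
  if (!length(keep)) return(integer(0))
  kk <- rep(ks, times = length(js) * length(is))[keep]
  jj <- rep(rep(js, each = length(ks)), times = length(is))[keep]
  ii <- rep(is, each = length(ks) * length(js))[keep]
  sort(as.integer(kk + grid$shape[["z"]] *
                    ((jj - 1) + grid$shape[["y"]] * (ii - 1))))
}
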