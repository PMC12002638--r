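#' Maximum-intensity projection of a 3D stack
#'
#' @param stack array `(nz, ny, nx)` (a bare matrix is treated as a
#'   single-plane stack).
#' @param grid optional [voxel_grid()], carried onto the result as an
#'   attribute.
#' @return `(ny, nx)` matrix; attribute `grid` if one was given.
#' @export
max_project <- function(stack, grid = NULL) {
  if (is.matrix(stack)) stack <- array(stack, c(1, dim(stack)))
  stopifnot(length(dim(stack)) == 3, dim(stack)[1] >= 1)
  d <- dim(stack)
  m <- matrix(stack, nrow = d[1])
  out <- matrix(apply(m, 2, max), d[2], d[3])
  if (!is.null(grid)) attr(out, "grid") <- grid
  out
}

#' Threshold an image at mean + k standard deviations
#'
#' Statistics are computed over the full frame; a pixel enters the mask
#' iff its intensity strictly exceeds `mean + k * SD`. On a constant
#' image the SD is 0 and the mask is empty.
#'
#' @param image numeric matrix (or array).
#' @param k SD multiplier (>= 0); the pipeline default is 2.
#' @return Logical mask of the same shape with attributes `threshold`
#'   (the cut actually applied) and `grid` (carried over, if present).
#' @export
threshold_mask <- function(image, k = 2) {
  stopifnot(k >= 0)
  thr <- mean(image) + k * sd(as.numeric(image))
  mask <- image > thr
  attr(mask, "threshold") <- thr
  attr(mask, "grid") <- attr(image, "grid")
  mask
}

#' Extract 2D puncta from a binary mask
#'
#' 8-connected components of the mask; components smaller than
#' `min_px` or larger than `max_px` pixels are discarded (the standard
#' 3-100 pixel band for synaptic puncta on 100 nm confocal pixels).
#'
#' @param mask logical matrix.
#' @param grid [voxel_grid()] giving the pixel size (falls back to the
#'   mask's `grid` attribute).
#' @param image optional intensity image for per-punctum mean intensity.
#' @param min_px,max_px inclusive pixel-count bounds.
#' @return Object of class `puncta`: data frame with one row per punctum
#'   (id, n_px, area um^2, centroid nm, mean intensity) and a list column
#'   `pixels` of linear pixel indices; the mask dimensions and grid ride
#'   along as attributes.
#' @export
extract_puncta <- function(mask, grid = attr(mask, "grid"), image = NULL,
                           min_px = 3, max_px = 100) {
  stopifnot(is.logical(mask), is.matrix(mask))
  dim3 <- c(1L, nrow(mask), ncol(mask))
  labels <- cpp_label_components(as.logical(mask), dim3)
  px_area <- if (!is.null(grid))
    grid$spacing[["x"]] * grid$spacing[["y"]] / 1e6 else NA_real_
  on <- which(labels > 0)
  keep_sets <- list()
  if (length(on)) {
    sets <- split(on, labels[on])
    sizes <- lengths(sets)
    keep_sets <- sets[sizes >= min_px & sizes <= max_px]
  }
  n <- length(keep_sets)
  cen <- function(idx) {
    rc <- arrayInd(idx, dim(mask))
    if (is.null(grid)) return(c(NA_real_, NA_real_))
    c(grid$origin[["x"]] + (mean(rc[, 2]) - 1) * grid$spacing[["x"]],
      grid$origin[["y"]] + (mean(rc[, 1]) - 1) * grid$spacing[["y"]])
  }
  cents <- if (n) t(vapply(keep_sets, cen, numeric(2))) else
    matrix(numeric(0), 0, 2)
  out <- data.frame(id = seq_len(n),
                    n_px = if (n) unname(lengths(keep_sets)) else integer(0),
                    area_um2 = if (n) unname(lengths(keep_sets)) * px_area else numeric(0),
                    cx = cents[, 1][seq_len(n)], cy = cents[, 2][seq_len(n)],
                    mean_intensity = if (n && !is.null(image))
                      vapply(keep_sets, function(i) mean(image[i]), 0) else
                        rep(NA_real_, n))
  out$pixels <- unname(keep_sets)
  attr(out, "mask_dim") <- dim(mask)
  attr(out, "grid") <- grid
  class(out) <- c("puncta", class(out))
  out
}

#' Object-based co-clustering of two puncta sets
#'
#' All cross-channel pairs sharing at least `min_overlap_px` pixels (the
#' strict "> 1 pixel" overlap rule corresponds to the default of 2). One
#' punctum may appear in several pairs. Also reports the colocalised
#' fraction per channel: the percentage of puncta with at least one
#' partner.
#'
#' @param puncta_a,puncta_b [extract_puncta()] results on the same grid.
#' @param min_overlap_px minimum shared pixels (default 2).
#' @return List with `pairs` (data frame: a, b, overlap_px),
#'   `pct_a_colocalized`, `pct_b_colocalized`, and counts.
#' @export
cocluster <- function(puncta_a, puncta_b, min_overlap_px = 2) {
  da <- attr(puncta_a, "mask_dim")
  db <- attr(puncta_b, "mask_dim")
  if (!identical(da, db))
    stop("puncta sets are on different grids")
  ga <- attr(puncta_a, "grid"); gb <- attr(puncta_b, "grid")
  if (!is.null(ga) && !is.null(gb) && !grids_identical(ga, gb))
    stop("puncta sets are on different grids")
  ov <- overlap_pairs(puncta_a$pixels, puncta_b$pixels, prod(da),
                      min_overlap_px)
  pairs <- data.frame(a = ov$a, b = ov$b, overlap_px = ov$overlap)
  list(pairs = pairs,
       pct_a_colocalized = if (nrow(puncta_a))
         100 * length(unique(pairs$a)) / nrow(puncta_a) else NA_real_,
       pct_b_colocalized = if (nrow(puncta_b))
         100 * length(unique(pairs$b)) / nrow(puncta_b) else NA_real_,
       n_a = nrow(puncta_a), n_b = nrow(puncta_b))
}

#' Linear density of objects along a dendrite
#'
#' @param n_objects object count (or a `puncta` data frame).
#' @param dendrite_length_um dendrite length in um; lengths below
#'   `min_length_um` trigger a warning (the analysis convention requires
#'   at least 50 um of dendrite).
#' @param per_um report density per this many um of dendrite (default 10).
#' @param min_length_um minimum accepted dendrite length.
#' @return List with `density` (objects per `per_um` um), `count`, and
#'   `length_um`.
#' @export
linear_density <- function(n_objects, dendrite_length_um, per_um = 10,
                           min_length_um = 50) {
  if (is.data.frame(n_objects)) n_objects <- nrow(n_objects)
  if (dendrite_length_um <= 0) stop("dendrite length must be positive")
  if (dendrite_length_um < min_length_um)
    warning(sprintf("dendrite length %.1f um is below the %g um convention",
                    dendrite_length_um, min_length_um))
  list(density = n_objects / dendrite_length_um * per_um,
       count = n_objects, length_um = dendrite_length_um, per_um = per_um)
}
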