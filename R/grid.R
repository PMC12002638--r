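#' Anisotropic voxel grid
#'
#' A `voxel_grid` ties voxel indices to physical coordinates. Arrays are
#' stored with dimensions `(nz, ny, nx)`; the physical centre of voxel
#' `(k, j, i)` (1-based) is `origin + ((k-1) dz, (j-1) dy, (i-1) dx)` in
#' nanometres. Externally reported voxel indices are 0-based.
#'
#' @param shape integer vector `(nz, ny, nx)`, voxel counts per axis.
#' @param spacing numeric vector `(dz, dy, dx)` in nm, all positive.
#' @param origin physical nm coordinate `(z, y, x)` of the centre of voxel
#'   `(1, 1, 1)`.
#' @return An object of class `voxel_grid`.
#' @examples
#' g <- voxel_grid(c(10, 256, 256), c(150, 20, 20))
#' voxel_volume_um3(g)
#' @export
voxel_grid <- function(shape, spacing, origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  stopifnot(length(shape) == 3, length(spacing) == 3, length(origin) == 3,
            all(shape >= 1), all(spacing > 0))
  structure(list(shape = setNames(shape, c("z", "y", "x")),
                 spacing = setNames(spacing, c("z", "y", "x")),
                 origin = setNames(origin, c("z", "y", "x"))),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("voxel_grid: %d x %d x %d (z,y,x), spacing %g x %g x %g nm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' Physical volume of one voxel in cubic micrometres
#' @param grid a [voxel_grid()].
#' @return Scalar volume in um^3.
#' @export
voxel_volume_um3 <- function(grid) prod(grid$spacing) / 1e9

grids_identical <- function(a, b) {
  isTRUE(all.equal(a$shape, b$shape)) &&
    isTRUE(all.equal(a$spacing, b$spacing)) &&
    isTRUE(all.equal(a$origin, b$origin))
}

#' Physical centres of voxels
#'
#' @param grid a [voxel_grid()].
#' @param idx 1-based linear indices into the `(nz, ny, nx)` array.
#' @return Matrix with columns `x`, `y`, `z` in nm.
#' @export
voxel_coords <- function(grid, idx) {
  a <- arrayInd(idx, grid$shape)
  cbind(x = grid$origin[["x"]] + (a[, 3] - 1) * grid$spacing[["x"]],
        y = grid$origin[["y"]] + (a[, 2] - 1) * grid$spacing[["y"]],
        z = grid$origin[["z"]] + (a[, 1] - 1) * grid$spacing[["z"]])
}

# Map physical nm points (matrix cols x,y,z) to 1-based linear voxel
# indices of the nearest voxel centre; NA outside the grid.
coords_to_index <- function(grid, xyz) {
  xyz <- rbind(xyz) # tolerate a single point given as a vector
  i <- round((xyz[, 1] - grid$origin[["x"]]) / grid$spacing[["x"]]) + 1
  j <- round((xyz[, 2] - grid$origin[["y"]]) / grid$spacing[["y"]]) + 1
  k <- round((xyz[, 3] - grid$origin[["z"]]) / grid$spacing[["z"]]) + 1
  ok <- i >= 1 & i <= grid$shape[["x"]] &
        j >= 1 & j <= grid$shape[["y"]] &
        k >= 1 & k <= grid$shape[["z"]]
  out <- rep(NA_integer_, nrow(xyz))
  out[ok] <- as.integer(k[ok] + grid$shape[["z"]] *
                          ((j[ok] - 1) + grid$shape[["y"]] * (i[ok] - 1)))
  out
}

# Subgrid covering index ranges (inclusive, 1-based) of a parent grid.
subgrid <- function(grid, kr, jr, ir) {
  voxel_grid(c(diff(kr) + 1L, diff(jr) + 1L, diff(ir) + 1L),
             grid$spacing,
             c(grid$origin[["z"]] + (kr[1] - 1) * grid$spacing[["z"]],
               grid$origin[["y"]] + (jr[1] - 1) * grid$spacing[["y"]],
               grid$origin[["x"]] + (ir[1] - 1) * grid$spacing[["x"]]))
}
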