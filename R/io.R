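#' Write an image stack as TIFF plus sidecar metadata
#'
#' One plane per z-slice. Integer stacks with values in 0..65535 are
#' written losslessly through the 16-bit path; other stacks are written
#' as scaled 32-bit float. Voxel spacing, origin and the scaling are
#' recorded in a YAML sidecar (`<path>.yaml`), the authoritative
#' metadata for [load_stack()].
#'
#' @param path output TIFF path.
#' @param stack numeric array `(nz, ny, nx)`.
#' @param grid its [voxel_grid()].
#' @param channel optional channel name recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_stack <- function(path, stack, grid, channel = NA_character_) {
  stopifnot(length(dim(stack)) == 3, all(dim(stack) == unname(grid$shape)))
  ints <- all(stack >= 0) && all(stack == round(stack)) && max(stack) <= 65535
  if (ints) {
    scale <- 65535
    bits <- 16L
  } else {
    scale <- max(stack, 1e-12)
    bits <- 32L
  }
  planes <- lapply(seq_len(dim(stack)[1]),
                   function(k) stack[k, , , drop = TRUE] / scale)
  tiff::writeTIFF(planes, path, bits.per.sample = bits,
                  compression = "none", reduce = FALSE)
  meta <- list(format = "synapsenano-stack-v1",
               channel = channel,
               shape_zyx = as.integer(unname(grid$shape)),
               spacing_nm_zyx = as.numeric(unname(grid$spacing)),
               origin_nm_zyx = as.numeric(unname(grid$origin)),
               scale = scale, bits = bits)
  yaml::write_yaml(meta, paste0(path, ".yaml"))
  invisible(path)
}

#' Parse physical voxel sizes from an OME ImageDescription
#'
#' Extracts `PhysicalSizeX/Y/Z` (in micrometres, per the OME convention)
#' from an OME-XML string and returns nm spacings.
#'
#' @param xml OME-XML text.
#' @return Named numeric vector `(dz, dy, dx)` in nm; entries are `NA`
#'   when the corresponding attribute is absent.
#' @export
parse_ome_spacing <- function(xml) {
  doc <- xml2::read_xml(xml)
  px <- xml2::xml_find_first(doc, ".//*[local-name()='Pixels']")
  get <- function(a) {
    v <- xml2::xml_attr(px, a)
    if (is.na(v)) NA_real_ else as.numeric(v) * 1000
  }
  if (inherits(px, "xml_missing"))
    return(c(z = NA_real_, y = NA_real_, x = NA_real_))
  c(z = get("PhysicalSizeZ"), y = get("PhysicalSizeY"),
    x = get("PhysicalSizeX"))
}

#' Load an image stack with its voxel grid
#'
#' Reads a TIFF stack and its spacing metadata. Metadata sources, in
#' increasing precedence: an OME ImageDescription embedded in the TIFF
#' (if any), then the YAML sidecar (`<path>.yaml` or an explicit
#' `sidecar` path); when both exist and disagree, the sidecar wins and a
#' message logs the conflict. Missing spacing is a hard error: distances
#' are meaningless without it.
#'
#' @param path TIFF path.
#' @param sidecar optional explicit sidecar YAML path.
#' @return List with `img` (array `(nz, ny, nx)`) and `grid`.
#' @export
load_stack <- function(path, sidecar = NULL) {
  planes <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(planes)) planes <- list(planes)
  nz <- length(planes)
  ny <- nrow(planes[[1]])
  nx <- ncol(planes[[1]])

  ome <- NULL
  desc <- attr(planes[[1]], "description")
  if (!is.null(desc) && nzchar(desc) && grepl("<", desc, fixed = TRUE)) {
    ome <- tryCatch(parse_ome_spacing(desc), error = function(e) NULL)
    if (!is.null(ome) && anyNA(ome)) ome <- NULL
  }

  side_path <- sidecar %||% paste0(path, ".yaml")
  meta <- if (file.exists(side_path)) yaml::read_yaml(side_path) else NULL

  spacing <- origin <- NULL
  scale <- 1
  if (!is.null(meta)) {
    spacing <- as.numeric(meta$spacing_nm_zyx)
    origin <- as.numeric(meta$origin_nm_zyx %||% c(0, 0, 0))
    scale <- meta$scale %||% 1
    if (!is.null(ome) && any(abs(spacing - unname(ome)) > 1e-6))
      message("sidecar and embedded OME spacing disagree; using the sidecar")
  } else if (!is.null(ome)) {
    spacing <- unname(ome)
    origin <- c(0, 0, 0)
  }
  if (is.null(spacing) || anyNA(spacing) || length(spacing) != 3)
    stop("no voxel spacing metadata for '", path,
         "': provide a sidecar YAML or OME PhysicalSize attributes")

  img <- array(0, c(nz, ny, nx))
  for (k in seq_len(nz)) img[k, , ] <- planes[[k]] * scale
  if (!is.null(meta) && identical(meta$bits, 16L)) img <- round(img)
  list(img = img, grid = voxel_grid(c(nz, ny, nx), spacing, origin))
}

#' Write a nanocluster table as CSV
#'
#' One row per cluster: id, channel, voxel count, volume, centroid (nm),
#' peak intensity and 0-based peak voxel index.
#'
#' @param ncs a `nanoclusters` table.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_nanoclusters_csv <- function(ncs, path) {
  df <- as.data.frame(ncs[, setdiff(names(ncs), "voxels")])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Serialise scene ground truth to JSON
#' @param scene a [build_scene()] result.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(scene, path) {
  cfg <- unclass(scene$config)
  cfg$nc_diameter_nm <- as.list(cfg$nc_diameter_nm)
  jsonlite::write_json(
    list(config = cfg, box_nm = as.list(scene$box_nm),
         spines = scene$spines, emitters = scene$emitters),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
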