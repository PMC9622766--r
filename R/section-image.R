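#' Skin-section image with annotations
#'
#' Bundles an 8-bit RGB raster with the physical and anatomical metadata the
#' quantification pipeline needs: the pixel size in micrometers, the basal
#' epithelial layer traced as a polyline (the zero reference for all depth
#' measurements), an optional tissue mask, and the depth of the junction
#' between papillary and reticular dermis.
#'
#' Pixel coordinates are 0-based: `x` is the column index and `y` the row
#' index, both starting at 0 in the top-left corner.  The basal polyline is
#' ordered left-to-right.
#'
#' @param pixels integer array of dimension `H x W x 3` (R, G, B), values in
#'   `[0, 255]`.
#' @param pixel_size_um physical side length of one pixel, micrometers.
#' @param basal_polyline two-column matrix (`x`, `y`) of polyline vertices in
#'   0-based pixel coordinates, ordered by `x`.
#' @param tissue_mask optional logical `H x W` matrix; `TRUE` inside tissue.
#' @param junction_depth_um optional depth (micrometers below the basal layer)
#'   of the papillary/reticular dermis junction.
#' @return A `section_image` object.
#' @export
section_image <- function(pixels, pixel_size_um,
                          basal_polyline = NULL,
                          tissue_mask = NULL,
                          junction_depth_um = NULL) {
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("`pixels` must be an H x W x 3 array", call. = FALSE)
  if (min(pixels) < 0 || max(pixels) > 255)
    stop("pixel values must lie in [0, 255]", call. = FALSE)
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      pixel_size_um <= 0)
    stop("`pixel_size_um` must be a single positive number", call. = FALSE)
  if (!is.null(basal_polyline)) {
    basal_polyline <- as.matrix(basal_polyline)
    if (ncol(basal_polyline) != 2L)
      stop("`basal_polyline` must have two columns (x, y)", call. = FALSE)
    colnames(basal_polyline) <- c("x", "y")
    h <- dim(pixels)[1]; w <- dim(pixels)[2]
    if (any(basal_polyline[, 1] < 0) || any(basal_polyline[, 1] > w - 1) ||
        any(basal_polyline[, 2] < 0) || any(basal_polyline[, 2] > h - 1))
      stop("`basal_polyline` vertices must lie inside the image bounds",
           call. = FALSE)
  }
  if (!is.null(tissue_mask)) {
    tissue_mask <- as.matrix(tissue_mask) > 0
    if (!identical(dim(tissue_mask), dim(pixels)[1:2]))
      stop("`tissue_mask` dimensions must match the image", call. = FALSE)
  }
  structure(
    list(pixels = pixels, pixel_size_um = pixel_size_um,
         basal_polyline = basal_polyline, tissue_mask = tissue_mask,
         junction_depth_um = junction_depth_um),
    class = "section_image")
}

#' @export
print.section_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<section_image> %d x %d px @ %.3g um/px", d[1], d[2],
              x$pixel_size_um))
  if (!is.null(x$basal_polyline))
    cat(sprintf(", basal polyline (%d vertices)", nrow(x$basal_polyline)))
  if (!is.null(x$junction_depth_um))
    cat(sprintf(", PD/RD junction at %.4g um", x$junction_depth_um))
  cat("\n")
  invisible(x)
}

#' @export
dim.section_image <- function(x) dim(x$pixels)

#' Read a section image and its annotation from disk
#'
#' Images are 8-bit RGB PNG or TIFF; annotations are JSON files carrying
#' `pixel_size_um`, `basal_polyline` (list of `[x, y]` vertices, 0-based pixel
#' coordinates ordered left-to-right) and optionally `junction_depth_um`.
#'
#' @param image_path path to a `.png`, `.tif` or `.tiff` file.
#' @param annotation_path path to the JSON annotation; defaults to the image
#'   path with the extension replaced by `.json`.
#' @return A [section_image()].
#' @export
read_section_image <- function(image_path,
                               annotation_path = sub("\\.[^.]+$", ".json",
                                                     image_path)) {
  ext <- tolower(sub(".*\\.", "", image_path))
  raw <- switch(ext,
    png  = png::readPNG(image_path),
    tif  = ,
    tiff = tiff::readTIFF(image_path),
    stop("unsupported image format: .", ext, call. = FALSE))
  if (length(dim(raw)) == 2L) raw <- array(raw, c(dim(raw), 3L))
  if (dim(raw)[3] > 3L) raw <- raw[, , 1:3, drop = FALSE]
  pixels <- array(as.integer(round(raw * 255)), dim(raw))
  if (!file.exists(annotation_path))
    stop("annotation file not found: ", annotation_path, call. = FALSE)
  ann <- jsonlite::read_json(annotation_path, simplifyVector = TRUE)
  poly <- ann$basal_polyline
  if (!is.null(poly)) {
    poly <- if (is.matrix(poly) || is.data.frame(poly)) {
      as.matrix(poly)
    } else {
      matrix(as.numeric(unlist(poly)), ncol = 2, byrow = TRUE)
    }
  }
  section_image(pixels, pixel_size_um = ann$pixel_size_um,
                basal_polyline = poly,
                junction_depth_um = ann$junction_depth_um)
}

#' Write a section image and its annotation to disk
#'
#' @param image a [section_image()].
#' @param image_path output path (`.png`, `.tif`/`.tiff`).
#' @param annotation_path JSON annotation output path; defaults to the image
#'   path with the extension swapped for `.json`.
#' @return `image_path`, invisibly.
#' @export
write_section_image <- function(image, image_path,
                                annotation_path = sub("\\.[^.]+$", ".json",
                                                      image_path)) {
  stopifnot(inherits(image, "section_image"))
  arr <- image$pixels / 255
  ext <- tolower(sub(".*\\.", "", image_path))
  switch(ext,
    png  = png::writePNG(arr, image_path),
    tif  = ,
    tiff = tiff::writeTIFF(arr, image_path, bits.per.sample = 8L),
    stop("unsupported image format: .", ext, call. = FALSE))
  poly <- image$basal_polyline
  ann <- list(pixel_size_um = image$pixel_size_um,
              basal_polyline = lapply(seq_len(nrow(poly)), function(i)
                c(poly[i, 1], poly[i, 2])),
              junction_depth_um = image$junction_depth_um)
  jsonlite::write_json(ann, annotation_path, auto_unbox = TRUE, digits = NA)
  invisible(image_path)
}
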