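#' Excess-color contrast enhancement
#'
#' Per-pixel excess of one RGB channel over the other two: for channel R the
#' map is `2*R - G - B`, and analogously for G and B.  Gray pixels map to 0,
#' saturated single-channel pixels to 510, so a chromatic stain stands out
#' from a near-neutral tissue background regardless of overall brightness
#' (the transform is invariant to adding a constant to all three channels).
#' No clipping is applied; thresholding operates on the full [-510, 510]
#' range.
#'
#' @param image a [section_image()] or an `H x W x 3` array in `[0, 255]`.
#' @param channel which channel's excess to compute: `"R"`, `"G"` or `"B"`.
#' @return A numeric `H x W` matrix in `[-510, 510]`.
#' @export
excess_color <- function(image, channel = c("R", "G", "B")) {
  channel <- match.arg(channel)
  px <- if (inherits(image, "section_image")) image$pixels else image
  if (length(dim(px)) != 3L || dim(px)[3] != 3L)
    stop("`image` must be an H x W x 3 RGB array", call. = FALSE)
  i <- match(channel, c("R", "G", "B"))
  others <- setdiff(1:3, i)
  plane <- function(k) matrix(px[, , k], dim(px)[1], dim(px)[2])
  2 * plane(i) - plane(others[1]) - plane(others[2])
}

#' Automatic threshold by Otsu's criterion
#'
#' Picks the threshold that maximizes the between-class variance
#' `w0 * w1 * (mu0 - mu1)^2` of the two classes it induces, computed on the
#' histogram of map values inside the mask.  Integer-valued maps with at most
#' `max_exact_levels` distinct values (the usual case for excess-color maps)
#' are solved exactly on the unique-value histogram; denser maps fall back to
#' a fixed-bin histogram.  The returned threshold is the midpoint between the
#' optimal cut's two flanking levels, so it lies strictly between the minimum
#' and maximum of the masked values.
#'
#' @param map numeric matrix (e.g. from [excess_color()]).
#' @param mask optional logical matrix restricting the histogram; `NULL`
#'   (default) uses every pixel.
#' @param n_bins histogram bins for the fallback path (default 256).
#' @param max_exact_levels use the exact unique-value histogram when the map
#'   has at most this many distinct values (default 4096).
#' @return The threshold, a single number.
#' @export
auto_threshold <- function(map, mask = NULL, n_bins = 256L,
                           max_exact_levels = 4096L) {
  v <- if (is.null(mask)) as.numeric(map) else {
    mask <- as.matrix(mask) > 0
    if (!identical(dim(mask), dim(map)))
      stop("`mask` dimensions must match `map`", call. = FALSE)
    as.numeric(map[mask])
  }
  lev <- sort(unique(v))
  if (length(lev) < 2L)
    stop("degenerate histogram: the map is constant inside the mask ",
         "(a threshold requires at least two distinct values)",
         call. = FALSE)
  if (length(lev) <= max_exact_levels) {
    counts <- tabulate(match(v, lev))
    centers <- lev
  } else {
    br <- seq(min(v), max(v), length.out = n_bins + 1L)
    bin <- pmin(pmax(findInterval(v, br, all.inside = TRUE), 1L), n_bins)
    counts <- tabulate(bin, n_bins)
    centers <- (br[-1] + br[-(n_bins + 1L)]) / 2
    keep <- counts > 0
    counts <- counts[keep]; centers <- centers[keep]
  }
  p <- counts / sum(counts)
  w0 <- cumsum(p)
  m <- cumsum(p * centers)
  mt <- m[length(m)]
  # between-class variance for a cut after level k (k = 1 .. K-1)
  k <- seq_len(length(p) - 1L)
  w0k <- w0[k]; w1k <- 1 - w0k
  sigma_b <- (mt * w0k - m[k])^2 / (w0k * w1k)
  best <- which.max(sigma_b)
  (centers[best] + centers[best + 1L]) / 2
}

#' Binarize a contrast map into a stain mask
#'
#' A pixel is stained iff its map value is strictly greater than the
#' threshold (ties at the threshold are unstained).  When the image carries a
#' tissue mask, the stain mask is intersected with it.
#'
#' @param map numeric matrix.
#' @param threshold finite numeric threshold, e.g. from [auto_threshold()].
#' @param marker stain label: `"Lyve-1"`, `"POSTN"`, `"TNC"`, `"CD45"` or
#'   `"generic"`.
#' @param tissue_mask optional logical matrix; stained pixels outside it are
#'   dropped.
#' @return A `stain_mask` object: logical matrix `mask` plus `marker`,
#'   `threshold_used` and `manually_corrected` fields.
#' @export
binarize <- function(map, threshold, marker = "generic", tissue_mask = NULL) {
  if (!is.finite(threshold))
    stop("`threshold` must be finite", call. = FALSE)
  marker <- match.arg(marker,
                      c("generic", "Lyve-1", "POSTN", "TNC", "CD45"))
  m <- map > threshold
  if (!is.null(tissue_mask)) {
    tissue_mask <- as.matrix(tissue_mask) > 0
    if (!identical(dim(tissue_mask), dim(m)))
      stop("`tissue_mask` dimensions must match `map`", call. = FALSE)
    m <- m & tissue_mask
  }
  structure(list(mask = m, marker = marker, threshold_used = threshold,
                 manually_corrected = FALSE),
            class = "stain_mask")
}

#' @export
print.stain_mask <- function(x, ...) {
  cat(sprintf("<stain_mask> %s: %d stained px of %d (threshold %.4g%s)\n",
              x$marker, sum(x$mask), length(x$mask), x$threshold_used,
              if (x$manually_corrected) ", manually corrected" else ""))
  invisible(x)
}

#' Apply a reviewed manual correction to a stain mask
#'
#' Reproducible stand-in for the interactive clean-up step of computer-aided
#' stain quantification: explicit add and remove rasters are applied as
#' `(mask | add) & !remove`.  A pixel present in both rasters is an ambiguous
#' instruction and raises an error.
#'
#' @param stain a `stain_mask` from [binarize()].
#' @param add_mask,remove_mask logical matrices of the mask's dimensions (or
#'   `NULL` for no change).
#' @return The corrected `stain_mask`; `manually_corrected` is `TRUE` iff
#'   either raster is non-empty.
#' @export
apply_manual_correction <- function(stain, add_mask = NULL,
                                    remove_mask = NULL) {
  stopifnot(inherits(stain, "stain_mask"))
  dims <- dim(stain$mask)
  coerce <- function(m, what) {
    if (is.null(m)) return(matrix(FALSE, dims[1], dims[2]))
    m <- as.matrix(m) > 0
    if (!identical(dim(m), dims))
      stop("`", what, "` dimensions must match the mask", call. = FALSE)
    m
  }
  add <- coerce(add_mask, "add_mask")
  rem <- coerce(remove_mask, "remove_mask")
  if (any(add & rem))
    stop("ambiguous correction: ", sum(add & rem),
         " pixel(s) appear in both add_mask and remove_mask", call. = FALSE)
  stain$mask <- (stain$mask | add) & !rem
  stain$manually_corrected <- stain$manually_corrected || any(add) || any(rem)
  stain
}

#' Segment a stained section in one call
#'
#' Convenience wrapper chaining the three segmentation steps: excess-color
#' contrast enhancement on the chosen channel, automatic (Otsu) thresholding,
#' and binarization (with the tissue mask applied when present).
#'
#' @inheritParams excess_color
#' @inheritParams binarize
#' @param threshold_method currently only `"otsu"`.
#' @return A `stain_mask`.
#' @export
segment_stain <- function(image, channel = "R", marker = "generic",
                          threshold_method = "otsu") {
  threshold_method <- match.arg(threshold_method, "otsu")
  map <- excess_color(image, channel)
  tissue <- if (inherits(image, "section_image")) image$tissue_mask else NULL
  thr <- auto_threshold(map, mask = tissue)
  binarize(map, thr, marker = marker, tissue_mask = tissue)
}
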