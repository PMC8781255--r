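# Ion images: per-lipid intensity maps over a section's pixel grid, with
# common-intensity-scale series for temporal/exposure comparisons and
# deterministic PNG rendering through a perceptually uniform colormap.

#' Extract an ion image for a target m/z
#'
#' Per pixel of the section, the sum of the intensities of all features
#' within `tol_ppm` of the target m/z. Pixels with no matching
#' observation, and pixels dropped earlier (off-tissue), render as 0,
#' consistent with detection dropout.
#'
#' @param fm A [feature_matrix].
#' @param section_id Section to image.
#' @param target_mz Target m/z in Da.
#' @param tol_ppm Matching tolerance (default 35, the study alignment
#'   tolerance).
#' @return An object of class `ion_image`: `grid` (n_rows x n_cols),
#'   `target_mz`, `tol_ppm`, `scale_max`.
#' @export
ion_image <- function(fm, section_id, target_mz, tol_ppm = 35) {
  rows <- which(fm$pixel_meta$section_id == section_id)
  if (length(rows) == 0L)
    stop("section '", section_id, "' not present in the feature matrix",
         call. = FALSE)
  gs <- fm$grid_shapes[[section_id]]
  if (is.null(gs))
    gs <- c(max(fm$pixel_meta$y[rows]), max(fm$pixel_meta$x[rows]))
  feats <- which(abs(fm$feature_mz - target_mz) / target_mz * 1e6 <= tol_ppm)
  grid <- matrix(0, nrow = gs[1], ncol = gs[2])
  if (length(feats) == 0L) {
    warning(sprintf("no feature within %g ppm of m/z %.4f; empty image",
                    tol_ppm, target_mz))
  } else {
    v <- rowSums(fm$values[rows, feats, drop = FALSE], na.rm = TRUE)
    grid[cbind(fm$pixel_meta$y[rows], fm$pixel_meta$x[rows])] <- v
  }
  structure(list(grid = grid, target_mz = target_mz, tol_ppm = tol_ppm,
                 scale_max = max(grid)), class = "ion_image")
}

#' @export
print.ion_image <- function(x, ...) {
  cat(sprintf("<ion_image> m/z %.4f (+/- %g ppm), %dx%d, max %.3g (scale %.3g)\n",
              x$target_mz, x$tol_ppm, nrow(x$grid), ncol(x$grid),
              max(x$grid), x$scale_max))
  invisible(x)
}

#' Put a series of ion images on a common intensity scale
#'
#' Sets every image's `scale_max` to the global maximum so that the same
#' intensity renders as the same color across the series; pixel values
#' are untouched. Idempotent.
#'
#' @param images List of [ion_image] objects (>= 1).
#' @return The list with updated `scale_max` values.
#' @export
common_scale <- function(images) {
  m <- max(vapply(images, function(im) im$scale_max, numeric(1)))
  lapply(images, function(im) { im$scale_max <- m; im })
}

#' Render an ion image to a PNG file
#'
#' Linear intensity-to-color mapping over `[0, scale_max]` through a
#' perceptually uniform colormap (viridis by default). Output bytes are
#' deterministic for fixed input.
#'
#' @param image An [ion_image].
#' @param path Output PNG path.
#' @param colors Color ramp as hex strings (default 256-step viridis from
#'   [grDevices::hcl.colors()]).
#' @param scale Pixel edge length of one image pixel in the PNG
#'   (default 1).
#' @return `path`, invisibly.
#' @export
render_ion_image <- function(image, path,
                             colors = grDevices::hcl.colors(256, "viridis"),
                             scale = 1L) {
  smax <- if (image$scale_max > 0) image$scale_max else 1
  idx <- pmin(length(colors),
              pmax(1L, 1L + floor(image$grid / smax * (length(colors) - 1) + 0.5)))
  rgb <- grDevices::col2rgb(colors) / 255
  arr <- array(0, dim = c(nrow(image$grid), ncol(image$grid), 3))
  arr[, , 1] <- matrix(rgb[1, idx], nrow(image$grid))
  arr[, , 2] <- matrix(rgb[2, idx], nrow(image$grid))
  arr[, , 3] <- matrix(rgb[3, idx], nrow(image$grid))
  if (scale > 1L) {
    arr <- arr[rep(seq_len(dim(arr)[1]), each = scale),
               rep(seq_len(dim(arr)[2]), each = scale), , drop = FALSE]
  }
  png::writePNG(arr, target = path)
  invisible(path)
}

#' Dump an ion image grid as delimited text
#'
#' @param image An [ion_image].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_ion_image_grid <- function(image, path) {
  utils::write.table(image$grid, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
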