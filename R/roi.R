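# Regions of interest on the pixel grid. ROIs are declarative config
# objects (ellipses and polygons) rather than interactive selections; the
# phantom generator exports its geometries in the same schema so that
# annotation is testable against ground truth.
#
# Each ROI has a unique `id` and a `region` label (defaulting to the id):
# several ROIs may share a region (e.g. the individual egg discs all carry
# region "eggs") and are treated as a union; equal-depth overlap between
# *different* regions is a config error.

#' Elliptical region of interest
#'
#' @param id Unique ROI identifier.
#' @param center Numeric `c(x, y)` center in pixel coordinates.
#' @param semi_axes Numeric `c(a, b)` semi-axis lengths in pixels (> 0).
#' @param rotation Rotation in radians, counter-clockwise (default 0).
#' @param region Anatomical label (default `id`); one of tissue,
#'   appendages, eggs, eye, gut, brood_chamber in the standard study.
#' @param parent `id` of the enclosing ROI, or `NULL` for top level.
#' @return An object of class `roi`.
#' @export
roi_ellipse <- function(id, center, semi_axes, rotation = 0, region = id,
                        parent = NULL) {
  stopifnot(length(center) == 2, length(semi_axes) == 2)
  if (any(semi_axes <= 0)) stop("ellipse semi-axes must be > 0", call. = FALSE)
  structure(list(id = id, shape = "ellipse", center = as.numeric(center),
                 semi_axes = as.numeric(semi_axes), rotation = rotation,
                 region = region, parent = parent), class = "roi")
}

#' Polygonal region of interest
#'
#' @param id Unique ROI identifier.
#' @param vertices Two-column matrix or data frame of `(x, y)` vertices in
#'   order; the polygon must not self-intersect.
#' @param region Anatomical label (default `id`).
#' @param parent `id` of the enclosing ROI, or `NULL`.
#' @return An object of class `roi`.
#' @export
roi_polygon <- function(id, vertices, region = id, parent = NULL) {
  v <- as.matrix(vertices)
  if (nrow(v) < 3) stop("polygon needs at least 3 vertices", call. = FALSE)
  if (.self_intersects(v)) stop("polygon must not self-intersect", call. = FALSE)
  structure(list(id = id, shape = "polygon", vertices = v,
                 region = region, parent = parent), class = "roi")
}

.self_intersects <- function(v) {
  n <- nrow(v)
  seg <- cbind(v, v[c(2:n, 1), , drop = FALSE])
  inter <- function(a, b) {
    d1 <- a[3:4] - a[1:2]; d2 <- b[3:4] - b[1:2]
    den <- d1[1] * d2[2] - d1[2] * d2[1]
    if (abs(den) < 1e-12) return(FALSE)
    t <- ((b[1] - a[1]) * d2[2] - (b[2] - a[2]) * d2[1]) / den
    u <- ((b[1] - a[1]) * d1[2] - (b[2] - a[2]) * d1[1]) / den
    t > 1e-9 && t < 1 - 1e-9 && u > 1e-9 && u < 1 - 1e-9
  }
  for (i in seq_len(n - 2)) {
    for (j in seq.int(i + 2, n)) {
      if (i == 1 && j == n) next  # adjacent (wraparound)
      if (inter(seg[i, ], seg[j, ])) return(TRUE)
    }
  }
  FALSE
}

# Logical interior mask (rows = y, cols = x) for a ROI on a grid; boundary
# inclusive.
roi_mask <- function(grid_shape, roi) {
  nr <- grid_shape[1]; nc <- grid_shape[2]
  xs <- rep(seq_len(nc), each = nr)
  ys <- rep(seq_len(nr), times = nc)
  eps <- 1e-9
  if (roi$shape == "ellipse") {
    dx <- xs - roi$center[1]; dy <- ys - roi$center[2]
    ct <- cos(roi$rotation); st <- sin(roi$rotation)
    u <- (dx * ct + dy * st) / roi$semi_axes[1]
    v <- (-dx * st + dy * ct) / roi$semi_axes[2]
    inside <- u^2 + v^2 <= 1 + eps
  } else {
    inside <- .point_in_polygon(xs, ys, roi$vertices)
  }
  matrix(inside, nrow = nr, ncol = nc)
}

# Even-odd rule, boundary inclusive.
.point_in_polygon <- function(xs, ys, v) {
  n <- nrow(v)
  inside <- rep(FALSE, length(xs))
  on_edge <- rep(FALSE, length(xs))
  j <- n
  for (i in seq_len(n)) {
    xi <- v[i, 1]; yi <- v[i, 2]; xj <- v[j, 1]; yj <- v[j, 2]
    # boundary test: point on segment (i, j)
    cross <- (xj - xi) * (ys - yi) - (yj - yi) * (xs - xi)
    seg_len2 <- (xj - xi)^2 + (yj - yi)^2
    dot <- (xs - xi) * (xj - xi) + (ys - yi) * (yj - yi)
    on_edge <- on_edge |
      (abs(cross) < 1e-9 * max(1, sqrt(seg_len2)) & dot >= -1e-9 &
         dot <= seg_len2 + 1e-9)
    crosses <- ((yi > ys) != (yj > ys)) &
      (xs < (xj - xi) * (ys - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | on_edge
}

#' Pixels covered by a region of interest
#'
#' Pixel centers satisfying the shape's interior test: for ellipses the
#' quadratic form `<= 1` (boundary inclusive), for polygons the even-odd
#' rule with inclusive boundary.
#'
#' @param grid_shape Integer `c(n_rows, n_cols)`.
#' @param roi A [roi_ellipse()] or [roi_polygon()] object.
#' @return Data frame with columns `x`, `y` of covered pixel centers;
#'   empty (with a warning) when the ROI misses the grid entirely.
#' @export
pixels_in_roi <- function(grid_shape, roi) {
  m <- roi_mask(grid_shape, roi)
  idx <- which(m, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    warning(sprintf("ROI '%s' covers no pixel of the %dx%d grid", roi$id,
                    grid_shape[1], grid_shape[2]))
  data.frame(x = as.integer(idx[, 2]), y = as.integer(idx[, 1]))
}

roi_depth <- function(rois) {
  ids <- vapply(rois, `[[`, character(1), "id")
  depth <- integer(length(rois))
  for (k in seq_along(rois)) {
    d <- 0L; p <- rois[[k]]$parent
    while (!is.null(p)) {
      i <- match(p, ids)
      if (is.na(i)) stop(sprintf("ROI '%s' names missing parent '%s'",
                                 rois[[k]]$id, p), call. = FALSE)
      d <- d + 1L
      p <- rois[[i]]$parent
      if (d > length(rois)) stop("ROI parent cycle detected", call. = FALSE)
    }
    depth[k] <- d
  }
  depth
}

#' Annotate pixels with anatomical region labels
#'
#' Each pixel receives the region of the most specific (deepest-nested)
#' ROI containing it; child ROIs are only evaluated inside their parent
#' (the two-stage brood-chamber-then-eggs annotation). Ties between
#' different regions at equal depth are a configuration error. When a
#' `tissue` region is supplied, pixels falling in no ROI are dropped
#' (background removal); otherwise they are retained unlabeled.
#'
#' @param fm A [feature_matrix]; pixel coordinates and section grids come
#'   from its `pixel_meta` and `grid_shapes`.
#' @param rois List of [roi] objects with unique ids.
#' @return The [feature_matrix] with `region_label` filled in
#'   `pixel_meta`, background pixels dropped when a tissue ROI exists.
#' @export
annotate_pixels <- function(fm, rois) {
  ids <- vapply(rois, `[[`, character(1), "id")
  if (anyDuplicated(ids))
    stop("duplicate ROI ids: ", paste(ids[duplicated(ids)], collapse = ", "),
         call. = FALSE)
  depth <- roi_depth(rois)
  regions <- vapply(rois, `[[`, character(1), "region")
  have_tissue <- "tissue" %in% regions

  sec_ids <- unique(fm$pixel_meta$section_id)
  label <- rep(NA_character_, nrow(fm$pixel_meta))
  for (sid in sec_ids) {
    gs <- fm$grid_shapes[[sid]]
    if (is.null(gs)) {
      rows0 <- fm$pixel_meta$section_id == sid
      gs <- c(max(fm$pixel_meta$y[rows0]), max(fm$pixel_meta$x[rows0]))
    }
    masks <- lapply(rois, function(r) roi_mask(gs, r))
    names(masks) <- ids
    # restrict children to their parent's interior
    for (k in order(depth)) {
      p <- rois[[k]]$parent
      if (!is.null(p)) masks[[k]] <- masks[[k]] & masks[[p]]
    }
    rows <- which(fm$pixel_meta$section_id == sid)
    pix <- cbind(fm$pixel_meta$y[rows], fm$pixel_meta$x[rows])
    hit <- vapply(masks, function(m) m[pix], logical(length(rows)))
    if (length(rows) == 1L) hit <- matrix(hit, nrow = 1)
    for (i in seq_along(rows)) {
      h <- which(hit[i, ])
      if (length(h) == 0L) next
      dmax <- max(depth[h])
      cand <- unique(regions[h[depth[h] == dmax]])
      if (length(cand) > 1L)
        stop(sprintf(
          "pixel (x=%d, y=%d) in section %s lies in overlapping same-depth ROIs (%s); resolve in config",
          pix[i, 2], pix[i, 1], sid, paste(cand, collapse = " vs ")),
          call. = FALSE)
      label[rows[i]] <- cand
    }
  }
  fm$pixel_meta$region_label <- label
  if (have_tissue) fm <- subset_fm(fm, pixels = which(!is.na(label)))
  fm
}

## ---- ROI config I/O ------------------------------------------------------

#' Write a ROI configuration file
#'
#' @param rois List of [roi] objects.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_roi_config <- function(rois, path) {
  recs <- lapply(rois, function(r) {
    rec <- list(id = r$id, shape = r$shape, region = r$region)
    if (!is.null(r$parent)) rec$parent <- r$parent
    if (r$shape == "ellipse") {
      rec$center <- as.numeric(r$center)
      rec$semi_axes <- as.numeric(r$semi_axes)
      rec$rotation <- r$rotation
    } else {
      rec$vertices_x <- as.numeric(r$vertices[, 1])
      rec$vertices_y <- as.numeric(r$vertices[, 2])
    }
    rec
  })
  yaml::write_yaml(list(rois = recs), path)
  invisible(path)
}

#' Read a ROI configuration file
#'
#' @param path YAML file written by [write_roi_config()].
#' @return List of [roi] objects.
#' @export
read_roi_config <- function(path) {
  if (!file.exists(path)) stop("ROI config not found: ", path, call. = FALSE)
  recs <- yaml::read_yaml(path)$rois
  lapply(recs, function(r) {
    if (r$shape == "ellipse") {
      roi_ellipse(r$id, unlist(r$center), unlist(r$semi_axes),
                  rotation = if (is.null(r$rotation)) 0 else r$rotation,
                  region = r$region, parent = r$parent)
    } else {
      roi_polygon(r$id, cbind(unlist(r$vertices_x), unlist(r$vertices_y)),
                  region = r$region, parent = r$parent)
    }
  })
}
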