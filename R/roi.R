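# ROI geometry.  Regions live in physical coordinates (um from the top-left
# pixel center, x along columns, y along rows) and are rasterized by
# pixel-center membership.

#' Region constructors
#'
#' Regions are simple geometric primitives used to build a [roi_set()].
#'
#' @param center c(x, y) um.
#' @param radius disc radius, um.
#' @param xlim,ylim rectangle extents c(min, max), um.
#' @param x,y polygon vertex coordinates, um (closed implicitly).
#' @return a `frap_region` object.
#' @export
roi_disc <- function(center, radius) {
  stopifnot(length(center) == 2, radius > 0)
  structure(list(shape = "disc", center = as.numeric(center),
                 radius = radius), class = "frap_region")
}

#' @rdname roi_disc
#' @export
roi_rect <- function(xlim, ylim) {
  stopifnot(length(xlim) == 2, length(ylim) == 2,
            xlim[1] < xlim[2], ylim[1] < ylim[2])
  structure(list(shape = "rect", xlim = as.numeric(xlim),
                 ylim = as.numeric(ylim)), class = "frap_region")
}

#' @rdname roi_disc
#' @export
roi_polygon <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  structure(list(shape = "polygon", x = as.numeric(x), y = as.numeric(y)),
            class = "frap_region")
}

#' Bleach / reference / background ROI set
#'
#' The three regions of a FRAP analysis: the bleached disc, a non-bleached
#' reference region on the same cell (used to correct monitor bleaching), and
#' a cell-free background region.  Regions must be pairwise disjoint.
#'
#' @param bleach a `frap_region`, normally a disc.
#' @param reference a `frap_region` on the same cell, outside the bleach.
#' @param background a `frap_region` in a cell-free area.
#' @return object of class `frap_roi_set`.
#' @export
roi_set <- function(bleach, reference, background) {
  stopifnot(inherits(bleach, "frap_region"),
            inherits(reference, "frap_region"),
            inherits(background, "frap_region"))
  structure(list(bleach = bleach, reference = reference,
                 background = background), class = "frap_roi_set")
}

point_in_polygon <- function(px, py, vx, vy) {
  # even-odd crossing rule, vectorized over points
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Rasterize a region to a logical pixel mask
#'
#' A pixel belongs to the region when its center does.
#'
#' @param region a `frap_region`.
#' @param grid_shape c(ny, nx) pixels.
#' @param pixel_size um per pixel.
#' @return logical matrix (ny, nx).
#' @export
rasterize_roi <- function(region, grid_shape, pixel_size) {
  ny <- grid_shape[1]; nx <- grid_shape[2]
  xs <- pixel_coords(nx, pixel_size)
  ys <- pixel_coords(ny, pixel_size)
  mask <- switch(region$shape,
    disc = dist2_grid(ny, nx, pixel_size, region$center[1], region$center[2]) <=
      region$radius^2,
    rect = outer(ys >= region$ylim[1] & ys <= region$ylim[2],
                 xs >= region$xlim[1] & xs <= region$xlim[2], "&"),
    polygon = {
      g <- expand.grid(y = ys, x = xs)
      matrix(point_in_polygon(g$x, g$y, region$x, region$y), ny, nx)
    },
    stop("unknown region shape: ", region$shape)
  )
  mask
}

# Rasterize all three regions, enforcing the roi_set invariants.
rasterize_roi_set <- function(rois, grid_shape, pixel_size, min_pixels = 20) {
  stopifnot(inherits(rois, "frap_roi_set"))
  masks <- lapply(rois, rasterize_roi, grid_shape = grid_shape,
                  pixel_size = pixel_size)
  for (nm in names(masks)) {
    if (sum(masks[[nm]]) == 0)
      stop("ROI '", nm, "' rasterizes to zero pixels", call. = FALSE)
    if (sum(masks[[nm]]) < min_pixels)
      stop("ROI '", nm, "' covers fewer than ", min_pixels, " pixels",
           call. = FALSE)
  }
  if (any(masks$bleach & masks$reference) || any(masks$bleach & masks$background) ||
      any(masks$reference & masks$background))
    stop("ROIs must be pairwise disjoint", call. = FALSE)
  masks
}

#' Default ROI layout for a simulated stack
#'
#' Places the bleach disc at the configured bleach position, a 2 um reference
#' disc between the bleach disc and the field edge, and a rectangular
#' background ROI inside the simulated cell-free corner.
#'
#' @param config a [frap_sim_config()].
#' @return a `frap_roi_set`.
#' @export
default_roi_set <- function(config) {
  px <- config$pixel_size
  ext <- (config$grid_shape - 1) * px   # (y, x) extents
  bc <- config$bleach_center
  ref_r <- 2
  # direction away from both the bleach disc and the corner (which sits at
  # the origin): toward the bottom-right
  ref_c <- pmin(c(ext[2], ext[1]) - ref_r - 2 * px,
                bc + (config$bleach_radius + ref_r + 1.0) * c(1, 1) / sqrt(2) + 2)
  corner <- max(config$cell_free_corner, 4)
  bg <- roi_rect(c(0.6, corner - 1.4), c(0.6, corner - 1.4))
  roi_set(bleach = roi_disc(bc, config$bleach_radius),
          reference = roi_disc(ref_c, ref_r),
          background = bg)
}
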