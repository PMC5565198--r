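#' Scene geometry
#'
#' Calibration record tying pixel coordinates to degrees of visual angle and
#' luminance. The display convention is that the smaller side of the scene
#' spans 13 degrees, scenes span a 4-60 cd/m2 luminance range against a
#' 32 cd/m2 gray background.
#'
#' @param height_px,width_px image size in pixels.
#' @param deg_per_px degrees of visual angle per pixel; defaults to
#'   \code{13 / min(height_px, width_px)}.
#' @param background_lum background luminance, cd/m2.
#' @param lum_range length-2 numeric, admissible luminance range in cd/m2.
#' @return An object of class \code{scene_geometry}.
#' @export
scene_geometry <- function(height_px, width_px,
                           deg_per_px = 13 / min(height_px, width_px),
                           background_lum = 32, lum_range = c(4, 60)) {
  stopifnot(height_px >= 1, width_px >= 1, deg_per_px > 0,
            length(lum_range) == 2, lum_range[1] < lum_range[2])
  structure(list(height_px = as.integer(height_px),
                 width_px = as.integer(width_px),
                 deg_per_px = deg_per_px,
                 background_lum = background_lum,
                 lum_range = lum_range),
            class = "scene_geometry")
}

#' @export
print.scene_geometry <- function(x, ...) {
  cat(sprintf("<scene_geometry> %d x %d px, %.4f deg/px (%.1f x %.1f deg)\n",
              x$height_px, x$width_px, x$deg_per_px,
              x$height_px * x$deg_per_px, x$width_px * x$deg_per_px))
  cat(sprintf("  background %.1f cd/m2, range [%.1f, %.1f] cd/m2\n",
              x$background_lum, x$lum_range[1], x$lum_range[2]))
  invisible(x)
}

## degrees -> pixels (not rounded)
deg2px <- function(deg, geometry) deg / geometry$deg_per_px

#' Grayscale scene image
#'
#' A 2-D luminance array (cd/m2) with attached geometry. On construction the
#' image is optionally contrast-energy normalized: the mean-removed part is
#' rescaled to a reference contrast energy and re-centered on the background
#' luminance, then clipped to the admissible range. This mirrors the display
#' convention that all scenes carry the same contrast energy.
#'
#' @param values numeric matrix of luminances (rows x cols).
#' @param geometry a [scene_geometry]; defaults to one derived from
#'   \code{dim(values)}.
#' @param normalize logical; apply contrast-energy normalization.
#' @param contrast_energy target root-mean-square contrast (fraction of the
#'   background luminance) used when \code{normalize} is TRUE.
#' @return An object of class \code{gray_image} (list with \code{values},
#'   \code{geometry}).
#' @export
gray_image <- function(values, geometry = NULL, normalize = TRUE,
                       contrast_energy = 0.2) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(geometry))
    geometry <- scene_geometry(nrow(values), ncol(values))
  stopifnot(nrow(values) == geometry$height_px,
            ncol(values) == geometry$width_px)
  if (normalize) {
    bg <- geometry$background_lum
    dev <- values - mean(values)
    rms <- sqrt(mean(dev^2))
    if (rms > 0) dev <- dev * (contrast_energy * bg / rms)
    values <- clip_lum(bg + dev, geometry)
  }
  structure(list(values = values, geometry = geometry), class = "gray_image")
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %d x %d px, lum [%.2f, %.2f] cd/m2\n",
              nrow(x$values), ncol(x$values), min(x$values), max(x$values)))
  invisible(x)
}

## clip to the admissible luminance range; count of clipped pixels kept as an
## attribute so rendering stages can log it
clip_lum <- function(values, geometry) {
  lo <- geometry$lum_range[1]; hi <- geometry$lum_range[2]
  n_clip <- sum(values < lo | values > hi)
  out <- pmin(pmax(values, lo), hi)
  attr(out, "n_clipped") <- n_clip
  out
}

## row/col coordinate grids (0-based), optionally centered on a point
coord_grids <- function(nr, nc, center = c(0, 0)) {
  list(row = matrix(seq_len(nr) - 1 - center[1], nr, nc),
       col = matrix(seq_len(nc) - 1 - center[2], nr, nc, byrow = TRUE))
}

## Euclidean pixel distance of every pixel from a (row, col) point (0-based)
dist_from_point <- function(nr, nc, point) {
  g <- coord_grids(nr, nc, center = point)
  sqrt(g$row^2 + g$col^2)
}

## raised-cosine step: 1 for r <= r0, 0 for r >= r0 + width, smooth between
raised_cosine_taper <- function(r, r0, width) {
  out <- numeric(length(r))
  out[r <= r0] <- 1
  band <- r > r0 & r < r0 + width
  out[band] <- 0.5 * (1 + cos(pi * (r[band] - r0) / width))
  dim(out) <- dim(r)
  out
}
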