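#' Camera field-of-view geometry
#'
#' Physical calibration of the imaged scene: the field of view spans
#' `fov_w` meters horizontally and `fov_h` meters vertically, imaged at
#' `width` x `height` pixels. There is no default: the physical extent
#' depends on the deployment (distance to subject, zoom) and must be
#' supplied by the user; all physical outputs carry the geometry used.
#'
#' @param fov_w,fov_h Physical width/height of the field of view, meters.
#' @param width,height Frame size in pixels.
#' @return A list of class `camera_geometry`.
#' @export
camera_geometry <- function(fov_w, fov_h, width, height) {
  vals <- c(fov_w = fov_w, fov_h = fov_h, width = width, height = height)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all camera_geometry fields must be strictly positive", call. = FALSE)
  }
  structure(list(fov_w = fov_w, fov_h = fov_h,
                 width = as.integer(width), height = as.integer(height)),
            class = "camera_geometry")
}

#' Physical area of a detected component
#'
#' A component of `N` pixels covers `S = N (W/width) (H/height)` square
#' meters: the pixel count times the physical footprint of one pixel.
#'
#' @param n_pixels Pixel count(s), integer `>= 0` (vectorized).
#' @param geom A [camera_geometry()].
#' @return Area(s) in square meters.
#' @export
component_area <- function(n_pixels, geom) {
  stopifnot(inherits(geom, "camera_geometry"))
  if (any(n_pixels < 0)) stop("`n_pixels` must be >= 0", call. = FALSE)
  n_pixels * (geom$fov_w / geom$width) * (geom$fov_h / geom$height)
}

#' Equivalent-sphere volume from projected area
#'
#' Approximates a plankton's 3D volume from its projected area alone: take
#' the circle of the same area (radius `r = sqrt(S/pi)`) and return the
#' volume of the sphere of that radius,
#' \deqn{V = \tfrac43\,\pi^{-1/2}\,S^{3/2}
#'         = \tfrac43\,\pi\,(\sqrt{S/\pi})^3.}
#' The two forms are algebraically identical; the closed form in `S` is
#' computed. V is strictly increasing in S and homogeneous of degree 3/2.
#'
#' @param S Projected area(s) in square meters, `>= 0` (vectorized).
#' @return Volume(s) in cubic meters.
#' @examples
#' equivalent_volume(pi)  # unit-radius sphere, 4*pi/3
#' @export
equivalent_volume <- function(S) {
  if (any(S < 0)) stop("area `S` must be >= 0", call. = FALSE)
  (4 / 3) * pi^(-1 / 2) * S^(3 / 2)
}

#' Aggregate per-frame count, area and volume series
#'
#' Per frame: the plankton count, the summed physical area of all
#' components, and the summed equivalent-sphere volume. Volume is computed
#' per component and then summed: the area-to-volume map is nonlinear
#' (degree 3/2), so pooling the areas first would instead report the volume
#' of one fictitious large organism, overstating the total for a community
#' of small ones.
#'
#' @param results List of [label_components()] results, ordered by frame.
#' @param geom A [camera_geometry()], or `NULL` for counts only (physical
#'   columns are then `NA`).
#' @return A data.frame of class `quant_series`: `frame_index`,
#'   `n_plankton`, `total_area_m2`, `total_volume_m3`.
#' @export
aggregate_series <- function(results, geom = NULL) {
  stopifnot(is.list(results))
  rows <- lapply(results, function(r) {
    stopifnot(inherits(r, "detection_result"))
    if (is.null(geom)) {
      area <- NA_real_; vol <- NA_real_
    } else {
      areas <- component_area(r$components$n_pixels, geom)
      area <- sum(areas)
      vol <- sum(equivalent_volume(areas))
    }
    data.frame(frame_index = r$frame_index, n_plankton = r$n_components,
               total_area_m2 = area, total_volume_m3 = vol)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("quant_series", class(out))
  attr(out, "geometry") <- geom
  out
}
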