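#' Screen geometry for a free-visual-exploration experiment
#'
#' Describes the stimulus picture and its angular extent at the participant's
#' eye, and fixes the foveal radius used throughout the package. The defaults
#' correspond to a 1,200 x 900 px picture viewed at 68 cm, subtending
#' 27 x 21 degrees of visual angle, with foveal vision modelled as a
#' 1 degree-radius disk around each fixation centre.
#'
#' Pixel coordinates are 0-based with the origin at the top-left corner:
#' `x_px` increases rightward, `y_px` downward. The picture centre is at
#' `((width_px - 1)/2, (height_px - 1)/2)`.
#'
#' @param width_px,height_px Picture size in pixels.
#' @param h_deg,v_deg Horizontal and vertical viewing angle in degrees.
#' @param distance_cm Viewing distance in cm (informational only).
#' @param foveal_radius_deg Radius of the foveal disk in degrees.
#'
#' @return An object of class `fve_geometry`.
#' @examples
#' geom <- screen_geometry()
#' foveal_radius_px(geom)  # 43
#' @export
screen_geometry <- function(width_px = 1200, height_px = 900,
                            h_deg = 27, v_deg = 21,
                            distance_cm = 68, foveal_radius_deg = 1) {
  stopifnot(
    is.numeric(width_px), length(width_px) == 1, width_px > 0,
    is.numeric(height_px), length(height_px) == 1, height_px > 0,
    is.numeric(h_deg), h_deg > 0,
    is.numeric(v_deg), v_deg > 0,
    is.numeric(foveal_radius_deg), foveal_radius_deg > 0
  )
  geom <- structure(
    list(
      width_px = as.integer(width_px),
      height_px = as.integer(height_px),
      h_deg = as.numeric(h_deg),
      v_deg = as.numeric(v_deg),
      distance_cm = as.numeric(distance_cm),
      foveal_radius_deg = as.numeric(foveal_radius_deg)
    ),
    class = "fve_geometry"
  )
  if (foveal_radius_px(geom) < 1) {
    stop("foveal radius is below one pixel; check geometry", call. = FALSE)
  }
  geom
}

#' @export
print.fve_geometry <- function(x, ...) {
  cat(sprintf(
    "<fve_geometry> %d x %d px, %.4g x %.4g deg (r_fovea = %.4g deg = %d px)\n",
    x$width_px, x$height_px, x$h_deg, x$v_deg,
    x$foveal_radius_deg, foveal_radius_px(x)
  ))
  invisible(x)
}

#' Pixels per degree of visual angle
#'
#' @param geometry A [screen_geometry()] object.
#' @param axis `"horizontal"` or `"vertical"`.
#' @return Pixels per degree along the requested axis.
#' @examples
#' px_per_degree(screen_geometry(), "vertical")  # 900/21
#' @export
px_per_degree <- function(geometry, axis = c("horizontal", "vertical")) {
  axis <- match.arg(axis)
  stopifnot(inherits(geometry, "fve_geometry"))
  if (axis == "horizontal") {
    geometry$width_px / geometry$h_deg
  } else {
    geometry$height_px / geometry$v_deg
  }
}

#' Foveal radius in pixels
#'
#' The foveal radius in degrees is converted with the *vertical*
#' pixels-per-degree scaling and rounded to the nearest integer (half away
#' from zero). For the default geometry this gives
#' `round(1 * 900/21) = 43` px; the horizontal scaling would give 44 px.
#' The choice of axis matters only for anisotropic pixels and can be
#' sidestepped by passing a geometry with equal scalings.
#'
#' @inheritParams px_per_degree
#' @return Integer number of pixels.
#' @export
foveal_radius_px <- function(geometry) {
  stopifnot(inherits(geometry, "fve_geometry"))
  as.integer(floor(geometry$foveal_radius_deg *
                     px_per_degree(geometry, "vertical") + 0.5))
}

#' Horizontal position in degrees from the picture centre
#'
#' Converts a horizontal pixel coordinate to signed degrees of visual angle
#' from the picture centre. Negative values lie in the left half of the
#' screen, positive values in the right half.
#'
#' @param x_px Horizontal pixel coordinate(s), 0-based.
#' @param geometry A [screen_geometry()] object.
#' @return Signed degrees, vectorised over `x_px`.
#' @examples
#' deg_from_center(599.5, screen_geometry())  # 0
#' @export
deg_from_center <- function(x_px, geometry) {
  stopifnot(inherits(geometry, "fve_geometry"))
  (x_px - (geometry$width_px - 1) / 2) / px_per_degree(geometry, "horizontal")
}

#' Read a screen geometry from a YAML or JSON config file
#'
#' The file may define any subset of the [screen_geometry()] fields
#' (`width_px`, `height_px`, `h_deg`, `v_deg`, `distance_cm`,
#' `foveal_radius_deg`); missing fields take the defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An `fve_geometry` object.
#' @export
read_geometry <- function(path) {
  if (!file.exists(path)) {
    stop("geometry config not found: ", path, call. = FALSE)
  }
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- c("width_px", "height_px", "h_deg", "v_deg",
             "distance_cm", "foveal_radius_deg")
  extra <- setdiff(names(cfg), known)
  if (length(extra)) {
    warning("ignoring unknown geometry fields: ",
            paste(extra, collapse = ", "), call. = FALSE)
  }
  do.call(screen_geometry, cfg[intersect(names(cfg), known)])
}
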