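#' Sample geometry of a plate-electrode sample
#'
#' Describes the cylindrical (or prismatic) tissue sample held between two
#' plate electrodes: the electrode gap `length` (l, metres) and the electrode
#' contact area `area` (S, square metres).  The ratio S/l converts bulk
#' properties (conductivity, permittivity) to terminal quantities
#' (conductance, capacitance).
#'
#' @param length Electrode gap l in metres.
#' @param area Electrode contact area S in square metres.
#' @return An object of class `sample_geometry` with fields `length` and
#'   `area` (and `radius`, `height` when built by [cylinder_geometry()]).
#' @seealso [cylinder_geometry()]
#' @export
#' @examples
#' sample_geometry(length = 5e-3, area = 2.688e-4)
sample_geometry <- function(length, area) {
  stopifnot(is.numeric(length), length(length) == 1L, is.finite(length),
            is.numeric(area), length(area) == 1L, is.finite(area))
  if (length <= 0) stop("electrode gap `length` must be positive")
  if (area <= 0) stop("electrode contact `area` must be positive")
  structure(list(length = length, area = area), class = "sample_geometry")
}

#' @describeIn sample_geometry Cylinder of given `radius` and `height`
#'   (metres); the electrode gap is the height and the contact area is
#'   pi * radius^2.
#' @param radius Cylinder radius in metres.
#' @param height Cylinder height (electrode gap) in metres.
#' @export
#' @examples
#' cylinder_geometry(radius = 9.25e-3, height = 5e-3)
cylinder_geometry <- function(radius, height) {
  stopifnot(radius > 0, height > 0)
  g <- sample_geometry(length = height, area = pi * radius^2)
  g$radius <- radius
  g$height <- height
  g
}

#' @export
print.sample_geometry <- function(x, ...) {
  cat("Plate-electrode sample geometry\n")
  if (!is.null(x$radius))
    cat(sprintf("  cylinder: radius %.4g mm, height %.4g mm\n",
                1e3 * x$radius, 1e3 * x$height))
  cat(sprintf("  gap l = %.6g m, area S = %.6g m^2 (S/l = %.6g m)\n",
              x$length, x$area, x$area / x$length))
  invisible(x)
}

#' Read or write a geometry JSON sidecar
#'
#' The sidecar holds either `{radius_m, height_m}` (cylinder) or
#' `{length_m, area_m2}`.
#'
#' @param path File path.
#' @return `read_geometry()` returns a [sample_geometry()].
#' @export
read_geometry <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(j$radius_m)) {
    cylinder_geometry(radius = j$radius_m, height = j$height_m)
  } else if (!is.null(j$length_m)) {
    sample_geometry(length = j$length_m, area = j$area_m2)
  } else {
    stop("geometry JSON must contain radius_m/height_m or length_m/area_m2")
  }
}

#' @rdname read_geometry
#' @param geometry A [sample_geometry()].
#' @export
write_geometry <- function(geometry, path) {
  j <- if (!is.null(geometry$radius))
    list(radius_m = geometry$radius, height_m = geometry$height)
  else
    list(length_m = geometry$length, area_m2 = geometry$area)
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
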