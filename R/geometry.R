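#' Wrap an angle into (-180, 180] degrees
#'
#' Ties at the branch cut resolve to +180.
#'
#' @param theta Numeric vector of angles in degrees.
#' @return Angles wrapped into the half-open interval (-180, 180].
#' @export
#' @examples
#' wrap_angle(c(190, -180, 720))
wrap_angle <- function(theta) {
  stopifnot(is.numeric(theta))
  theta - 360 * ceiling((theta - 180) / 360)
}

.deg2rad <- function(deg) deg * pi / 180
.rad2deg <- function(rad) rad * 180 / pi

## row-wise Euclidean norm of an n x 2 matrix (or a length-2 vector)
.vec_mag <- function(v) {
  if (is.matrix(v)) sqrt(rowSums(v^2)) else sqrt(sum(v^2))
}

## heading of a planar vector in degrees, in (-180, 180]
.vec_heading <- function(v) {
  if (is.matrix(v)) .rad2deg(atan2(v[, 2], v[, 1])) else .rad2deg(atan2(v[2], v[1]))
}

.check_planar <- function(v, what = "vector") {
  if (!is.numeric(v) || length(v) != 2 || !all(is.finite(v)))
    stop(sprintf("'%s' must be a finite numeric vector of length 2", what),
         call. = FALSE)
  invisible(v)
}

#' Ideal configural homing vector
#'
#' The return vector that closes the triangle exactly: if the walker is
#' guided along displacement `xA` and then `xB`, walking `-(xA + xB)`
#' returns them to the origin.
#'
#' @param xA,xB Guided displacement vectors, numeric length 2, in metres
#'   (east, north components).
#' @return A numeric length-2 vector, the ideal return displacement.
#' @export
#' @examples
#' ideal_homing_vector(c(10, 0), c(-5, 5 * sqrt(3)))
ideal_homing_vector <- function(xA, xB) {
  .check_planar(xA, "xA")
  .check_planar(xB, "xB")
  -(xA + xB)
}

#' Signed angular error of the homing response
#'
#' The difference between the turn the walker executed at the second
#' corner and the turn required to head back to the origin, both measured
#' from the direction of the second guided side and signed positive in the
#' required turn direction.  A positive value means the walker turned past
#' the correct heading (overshoot); negative means undershoot.
#'
#' @param xA,xB Guided displacement vectors (metres).
#' @param xD Response displacement vector (metres); must be non-zero.
#' @return Signed error in degrees, wrapped to (-180, 180].
#' @export
#' @examples
#' xA <- c(10, 0); xB <- c(-5, 5 * sqrt(3))
#' angle_error(xA, xB, ideal_homing_vector(xA, xB))  # 0
angle_error <- function(xA, xB, xD) {
  .check_planar(xA, "xA"); .check_planar(xB, "xB"); .check_planar(xD, "xD")
  if (.vec_mag(xD) == 0)
    stop("response vector has zero magnitude: heading undefined", call. = FALSE)
  xC <- ideal_homing_vector(xA, xB)
  hB <- .vec_heading(xB)
  required <- wrap_angle(.vec_heading(xC) - hB)
  executed <- wrap_angle(.vec_heading(xD) - hB)
  s <- if (required < 0) -1 else 1
  wrap_angle(s * (executed - required))
}

#' Distance error of the homing response
#'
#' Ratio of the walked return distance to the correct return distance
#' (the magnitude of the configural homing vector).  Values above 1 are
#' overshoots, below 1 undershoots.
#'
#' @inheritParams angle_error
#' @return Dimensionless ratio |xD| / |xC|.
#' @export
distance_error <- function(xA, xB, xD) {
  .check_planar(xA, "xA"); .check_planar(xB, "xB"); .check_planar(xD, "xD")
  magC <- .vec_mag(ideal_homing_vector(xA, xB))
  if (magC == 0)
    stop("degenerate trial: ideal return distance is zero", call. = FALSE)
  .vec_mag(xD) / magC
}

#' Position error of the homing response
#'
#' Distance from the walker's final position to the origin, i.e.
#' |xA + xB + xD| in metres.
#'
#' @inheritParams angle_error
#' @return Position error in metres.
#' @export
position_error <- function(xA, xB, xD) {
  .check_planar(xA, "xA"); .check_planar(xB, "xB"); .check_planar(xD, "xD")
  .vec_mag(xA + xB + xD)
}

#' Circular mean of angles
#'
#' Argument of the mean resultant vector of unit vectors at the given
#' angles.  Errors if the mean resultant length is (numerically) zero,
#' where the circular mean is undefined, e.g. `c(90, -90)`.
#'
#' @param angles Numeric vector of angles in degrees; must be non-empty.
#' @param tol Resultant length below which the mean is declared undefined.
#' @return The circular mean in degrees, in (-180, 180].
#' @export
#' @examples
#' circular_mean(c(170, -170))  # 180, across the wrap
circular_mean <- function(angles, tol = 1e-12) {
  if (!is.numeric(angles) || length(angles) == 0)
    stop("'angles' must be a non-empty numeric vector", call. = FALSE)
  if (anyNA(angles)) stop("'angles' contains NA", call. = FALSE)
  rad <- .deg2rad(angles)
  cbar <- mean(cos(rad)); sbar <- mean(sin(rad))
  if (sqrt(cbar^2 + sbar^2) < tol)
    stop("mean resultant length is zero: circular mean undefined", call. = FALSE)
  wrap_angle(.rad2deg(atan2(sbar, cbar)))
}
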