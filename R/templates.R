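#' Triangle template
#'
#' A template fixes one trial's guided geometry: the triangle's interior
#' angles, its side lengths, and the handedness of the guided path.  The
#' walker starts at the origin, walks side A to the first corner (G1),
#' turns, walks side B to the second corner (G2), and must return along
#' the unguided side C.  Interior angles are given at (origin, G1, G2);
#' the angle at G1 is the angle between the two guided sides, and side C
#' is opposite it.
#'
#' Side lengths may be given explicitly, or derived from the interior
#' angles via the law of sines by fixing either `side_C` or the
#' `perimeter`.
#'
#' @param label Short identifier, e.g. `"60-60-60"`.
#' @param angles Numeric length 3: interior angles in degrees at
#'   (origin, G1, G2); must sum to 180.
#' @param handedness `"left"` (counterclockwise turns) or `"right"`.
#' @param side_C Length of the unguided side in metres (mutually
#'   exclusive with `sides` and `perimeter`).
#' @param perimeter Total perimeter in metres (alternative scaling).
#' @param sides Numeric length 3 `(side_A, side_B, side_C)` in metres;
#'   must satisfy the law of sines with `angles`.
#' @return An object of class `tc_template`.
#' @export
#' @examples
#' triangle_template("60-60-60", c(60, 60, 60), "left", side_C = 10)
triangle_template <- function(label, angles, handedness = c("left", "right"),
                              side_C = NULL, perimeter = NULL, sides = NULL) {
  handedness <- match.arg(handedness)
  stopifnot(is.character(label), length(label) == 1L)
  if (!is.numeric(angles) || length(angles) != 3 || !all(is.finite(angles)))
    stop("'angles' must be three finite interior angles in degrees", call. = FALSE)
  if (abs(sum(angles) - 180) > 1e-9)
    stop("interior angles must sum to 180 degrees", call. = FALSE)
  if (any(angles <= 0))
    stop("interior angles must be positive", call. = FALSE)

  sin_ang <- sin(.deg2rad(angles))
  ## law of sines: side_A opposite the angle at G2, side_B opposite the
  ## angle at the origin, side_C opposite the angle at G1
  unit <- c(sin_ang[3], sin_ang[1], sin_ang[2])
  if (!is.null(sides)) {
    if (!is.numeric(sides) || length(sides) != 3 || any(sides <= 0))
      stop("'sides' must be three positive lengths", call. = FALSE)
  } else if (!is.null(side_C)) {
    stopifnot(is.numeric(side_C), length(side_C) == 1L, side_C > 0)
    sides <- unit / unit[3] * side_C
  } else if (!is.null(perimeter)) {
    stopifnot(is.numeric(perimeter), length(perimeter) == 1L, perimeter > 0)
    sides <- unit / sum(unit) * perimeter
  } else {
    stop("one of 'side_C', 'perimeter' or 'sides' is required", call. = FALSE)
  }

  ratio <- sides / unit
  if (max(abs(ratio - ratio[1])) > 1e-9 * ratio[1])
    stop("sides and angles do not satisfy the law of sines", call. = FALSE)
  if (sides[1] + sides[2] <= sides[3] ||
      sides[1] + sides[3] <= sides[2] ||
      sides[2] + sides[3] <= sides[1])
    stop("triangle inequality violated", call. = FALSE)

  structure(
    list(label = label,
         angles = as.numeric(angles),
         side_A = sides[1], side_B = sides[2], side_C = sides[3],
         handedness = handedness),
    class = "tc_template")
}

#' @export
print.tc_template <- function(x, ...) {
  cat(sprintf("<tc_template> %s (%s-handed)\n", x$label, x$handedness))
  cat(sprintf("  angles (origin, G1, G2): %s deg\n",
              paste(signif(x$angles, 6), collapse = ", ")))
  cat(sprintf("  sides A, B, C: %s m\n",
              paste(signif(c(x$side_A, x$side_B, x$side_C), 6), collapse = ", ")))
  invisible(x)
}

#' Mirror a template's handedness
#'
#' @param template A [triangle_template()].
#' @return The same geometry with handedness flipped.
#' @export
mirror_template <- function(template) {
  stopifnot(inherits(template, "tc_template"))
  template$handedness <- if (template$handedness == "left") "right" else "left"
  template
}

#' Walk a template's guided path
#'
#' Lays the template out in the trial frame: side A starts at the origin
#' along `start_heading`; at G1 the walker makes an exterior turn of
#' (180 - interior angle at G1), counterclockwise for left-handed
#' templates and clockwise for right-handed; side B follows the new
#' heading.  The ideal return vector closes the triangle.
#'
#' @param template A [triangle_template()].
#' @param start_heading Heading of side A in degrees (0 = +x, CCW).
#' @return A list with numeric length-2 vectors `xA`, `xB`, `xC` (metres).
#' @export
#' @examples
#' walk_template(triangle_template("eq", c(60, 60, 60), "left", side_C = 10))
walk_template <- function(template, start_heading = 0) {
  stopifnot(inherits(template, "tc_template"),
            is.numeric(start_heading), length(start_heading) == 1L,
            is.finite(start_heading))
  s <- if (template$handedness == "left") 1 else -1
  h1 <- start_heading
  h2 <- h1 + s * (180 - template$angles[2])
  xA <- template$side_A * c(cos(.deg2rad(h1)), sin(.deg2rad(h1)))
  xB <- template$side_B * c(cos(.deg2rad(h2)), sin(.deg2rad(h2)))
  list(xA = xA, xB = xB, xC = ideal_homing_vector(xA, xB))
}
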