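## Default interior-angle triples (origin, G1, G2) for the shape-varying
## design.  The unguided side C (opposite G1) is fixed at 10 m; the guided
## sides follow from the law of sines.  Composition: 1 equilateral,
## 1 isosceles, 1 isosceles-right, 1 right, 3 scalene.  The scalene and
## right triples are documented placeholders and fully configurable -- any
## triple summing to 180 is accepted.
.exp1_default_triples <- list(
  `60-60-60`  = c(60, 60, 60),
  `30-120-30` = c(30, 120, 30),
  `45-90-45`  = c(45, 90, 45),
  `30-90-60`  = c(30, 90, 60),
  `40-110-30` = c(40, 110, 30),
  `25-95-60`  = c(25, 95, 60),
  `50-70-60`  = c(50, 70, 60))

## Default scalene triple for the size-varying design (shape held fixed
## across all five perimeters).
.exp2_default_triple <- c(40, 80, 60)

## Perimeters (m) of the five size classes of the size-varying design.
.exp2_perimeters <- c(15.19, 25.32, 126.60, 253.20, 506.42)

## Per-size trial counts for the size-varying design (sum 34, split evenly
## between left- and right-handed trials within each size).
.exp2_counts <- c(10, 10, 8, 4, 2)

#' Templates of the shape-varying design
#'
#' Seven triangle templates sharing a fixed 10 m unguided side C while the
#' interior angles vary (equilateral, isosceles, right, isosceles-right
#' and three scalene shapes).  Guided sides A and B are derived from the
#' interior angles by the law of sines.
#'
#' @param angle_triples Named list of seven numeric length-3 interior-angle
#'   triples (degrees, at origin / G1 / G2); defaults documented in the
#'   package vignette.
#' @param side_C Unguided side length in metres (default 10).
#' @return A named list of seven left-handed [triangle_template()] objects.
#' @export
#' @examples
#' vapply(exp1_templates(), function(t) t$side_C, numeric(1))
exp1_templates <- function(angle_triples = NULL, side_C = 10) {
  if (is.null(angle_triples)) angle_triples <- .exp1_default_triples
  if (is.null(names(angle_triples)))
    names(angle_triples) <- vapply(
      angle_triples, function(a) paste(round(a), collapse = "-"), character(1))
  lapply(stats::setNames(names(angle_triples), names(angle_triples)),
         function(lbl) triangle_template(lbl, angle_triples[[lbl]],
                                         "left", side_C = side_C))
}

#' Templates of the size-varying design
#'
#' Five similar scalene triangles: one interior-angle triple scaled to
#' perimeters of 15.19, 25.32, 126.60, 253.20 and 506.42 metres, so the
#' turn angles are identical across sizes and only distance varies.
#'
#' @param angles One interior-angle triple (degrees); default is a
#'   documented placeholder scalene shape.
#' @param perimeters Perimeters in metres.
#' @param strict If `TRUE`, a non-scalene `angles` triple is an error;
#'   by default it only warns.
#' @return A named list of five left-handed [triangle_template()] objects.
#' @export
#' @examples
#' vapply(exp2_templates(), function(t) t$side_A + t$side_B + t$side_C,
#'        numeric(1))
exp2_templates <- function(angles = NULL, perimeters = NULL, strict = FALSE) {
  if (is.null(angles)) angles <- .exp2_default_triple
  if (is.null(perimeters)) perimeters <- .exp2_perimeters
  if (anyDuplicated(round(angles, 9))) {
    msg <- "size-varying design expects a scalene (all angles distinct) shape"
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  labels <- sprintf("P%.2f", perimeters)
  stats::setNames(
    lapply(seq_along(perimeters),
           function(i) triangle_template(labels[i], angles, "left",
                                         perimeter = perimeters[i])),
    labels)
}

#' Specify an experimental design
#'
#' Bundles templates with per-template, per-handedness trial counts.
#' The built-in `"exp1"` design has 28 trials (7 shapes x 4 repeats,
#' 14 left- and 14 right-handed); the built-in `"exp2"` design has
#' 34 trials over 5 sizes with per-size counts 10, 10, 8, 4, 2, split
#' evenly between handednesses.
#'
#' @param design_id `"exp1"`, `"exp2"` or `"custom"`.
#' @param templates Named list of [triangle_template()] objects (required
#'   for `"custom"`, defaults otherwise).
#' @param counts_left,counts_right Integer vectors, one entry per
#'   template: number of left-/right-handed trials of that shape.
#' @return An object of class `tc_design`.
#' @export
#' @examples
#' design_spec("exp1")
design_spec <- function(design_id = c("exp1", "exp2", "custom"),
                        templates = NULL,
                        counts_left = NULL, counts_right = NULL) {
  design_id <- match.arg(design_id)
  if (design_id == "exp1") {
    if (is.null(templates)) templates <- exp1_templates()
    if (is.null(counts_left)) counts_left <- rep(2L, length(templates))
    if (is.null(counts_right)) counts_right <- rep(2L, length(templates))
  } else if (design_id == "exp2") {
    if (is.null(templates)) templates <- exp2_templates()
    if (is.null(counts_left)) counts_left <- as.integer(ceiling(.exp2_counts / 2))
    if (is.null(counts_right)) counts_right <- as.integer(floor(.exp2_counts / 2))
  } else if (is.null(templates) || is.null(counts_left) || is.null(counts_right)) {
    stop("custom designs need templates, counts_left and counts_right",
         call. = FALSE)
  }
  if (!all(vapply(templates, inherits, logical(1), "tc_template")))
    stop("'templates' must be a list of tc_template objects", call. = FALSE)
  if (length(counts_left) != length(templates) ||
      length(counts_right) != length(templates))
    stop("counts must have one entry per template", call. = FALSE)
  if (any(counts_left < 0) || any(counts_right < 0) ||
      sum(counts_left) + sum(counts_right) == 0)
    stop("trial counts must be non-negative and not all zero", call. = FALSE)
  structure(
    list(design_id = design_id, templates = templates,
         counts_left = as.integer(counts_left),
         counts_right = as.integer(counts_right)),
    class = "tc_design")
}

#' @export
print.tc_design <- function(x, ...) {
  cat(sprintf("<tc_design> %s: %d templates, %d trials (%d left, %d right)\n",
              x$design_id, length(x$templates),
              sum(x$counts_left) + sum(x$counts_right),
              sum(x$counts_left), sum(x$counts_right)))
  invisible(x)
}

#' Build a session from a design (responses absent)
#'
#' Expands the design's per-template, per-handedness counts into a trial
#' list, lays each trial out in its own frame (start heading along +x)
#' and applies a seeded random permutation to the trial order.  The same
#' `(design, seed)` pair always yields the identical session.
#'
#' @param design A [design_spec()].
#' @param subject_id Character scalar recorded in the session.
#' @param seed Integer seed for the trial-order permutation.
#' @return A [new_session()] with empty responses.
#' @export
#' @examples
#' build_session(design_spec("exp1"), "s01", seed = 1)
build_session <- function(design, subject_id = "sim01", seed = 1L) {
  stopifnot(inherits(design, "tc_design"))
  rows <- list()
  for (i in seq_along(design$templates)) {
    tpl <- design$templates[[i]]
    for (h in c("left", "right")) {
      k <- if (h == "left") design$counts_left[i] else design$counts_right[i]
      if (k == 0) next
      t_h <- if (tpl$handedness == h) tpl else mirror_template(tpl)
      w <- walk_template(t_h, start_heading = 0)
      rows[[length(rows) + 1L]] <- data.frame(
        template_label = rep(tpl$label, k), handedness = rep(h, k),
        xA_x = w$xA[1], xA_y = w$xA[2], xB_x = w$xB[1], xB_y = w$xB[2],
        stringsAsFactors = FALSE)
    }
  }
  trials <- do.call(rbind, rows)
  set.seed(seed)
  trials <- trials[sample.int(nrow(trials)), , drop = FALSE]
  trials <- cbind(trial_index = seq_len(nrow(trials)), trials)
  rownames(trials) <- NULL
  new_session(subject_id,
              if (design$design_id %in% c("exp1", "exp2")) design$design_id
              else "custom",
              trials, seed = seed)
}
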