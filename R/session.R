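#' Construct a session of triangle-completion trials
#'
#' A session is one subject's ordered sequence of trials.  Each trial row
#' carries the guided displacement vectors `xA`, `xB` (laid out in the
#' trial's own frame) and, once simulated or observed, the response
#' vector `xD`.  Trial order matters: the history term of the
#' trial-history model accumulates over earlier trials.
#'
#' @param subject_id Character scalar.
#' @param design_id One of `"exp1"`, `"exp2"`, `"custom"`.
#' @param trials A data.frame with columns `trial_index`,
#'   `template_label`, `handedness`, `xA_x`, `xA_y`, `xB_x`, `xB_y` and
#'   optionally `xD_x`, `xD_y` (NA while responses are absent).
#' @param seed Integer seed recorded for provenance (may be NA).
#' @return An object of class `tc_session`.
#' @export
new_session <- function(subject_id, design_id = c("exp1", "exp2", "custom"),
                        trials, seed = NA_integer_) {
  design_id <- match.arg(design_id)
  stopifnot(is.character(subject_id), length(subject_id) == 1L,
            is.data.frame(trials))
  needed <- c("trial_index", "template_label", "handedness",
              "xA_x", "xA_y", "xB_x", "xB_y")
  missing_cols <- setdiff(needed, names(trials))
  if (length(missing_cols))
    stop("trials is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (!all(c("xD_x", "xD_y") %in% names(trials))) {
    trials$xD_x <- NA_real_
    trials$xD_y <- NA_real_
  }
  ## all-empty response columns read back from CSV arrive as logical NA
  trials$xD_x <- as.numeric(trials$xD_x)
  trials$xD_y <- as.numeric(trials$xD_y)
  n <- nrow(trials)
  if (n == 0) stop("session must contain at least one trial", call. = FALSE)
  if (!identical(as.integer(trials$trial_index), seq_len(n)))
    stop("trial_index must be consecutive 1..n (history depends on order)",
         call. = FALSE)
  if (!all(trials$handedness %in% c("left", "right")))
    stop("handedness must be 'left' or 'right'", call. = FALSE)
  vec_cols <- c("xA_x", "xA_y", "xB_x", "xB_y")
  if (!all(vapply(trials[vec_cols], is.numeric, logical(1))) ||
      !all(is.finite(as.matrix(trials[vec_cols]))))
    stop("guided-side components must be finite numerics", call. = FALSE)
  rownames(trials) <- NULL
  structure(
    list(subject_id = subject_id, design_id = design_id,
         trials = trials, seed = as.integer(seed)),
    class = "tc_session")
}

#' @export
print.tc_session <- function(x, ...) {
  nresp <- sum(stats::complete.cases(x$trials[, c("xD_x", "xD_y")]))
  cat(sprintf("<tc_session> subject %s, design %s: %d trials (%d with responses)\n",
              x$subject_id, x$design_id, nrow(x$trials), nresp))
  invisible(x)
}

## n x 2 matrices of the session's vectors; xC derived by closure
.session_mats <- function(session) {
  tr <- session$trials
  xA <- cbind(tr$xA_x, tr$xA_y)
  xB <- cbind(tr$xB_x, tr$xB_y)
  xD <- cbind(tr$xD_x, tr$xD_y)
  list(xA = xA, xB = xB, xC = -(xA + xB), xD = xD,
       path_mag = sqrt(rowSums(xA^2) + rowSums(xB^2)))
}

.has_responses <- function(session) {
  all(stats::complete.cases(session$trials[, c("xD_x", "xD_y")]))
}

#' Per-trial error metrics for a session
#'
#' Computes the three response error metrics for every trial with a
#' response: signed angular error (degrees, positive = turned past the
#' correct heading), distance error (walked / correct return distance)
#' and position error (metres from the origin at the end of the walk).
#'
#' @param session A [new_session()] object with responses.
#' @return A data.frame with one row per responded trial: `trial_index`,
#'   `template_label`, `handedness`, `angle_error`, `distance_error`,
#'   `position_error`, `mag_C`, `mag_D`.
#' @export
trial_errors <- function(session) {
  stopifnot(inherits(session, "tc_session"))
  tr <- session$trials
  keep <- stats::complete.cases(tr[, c("xD_x", "xD_y")])
  if (!any(keep)) stop("session has no responses", call. = FALSE)
  tr <- tr[keep, , drop = FALSE]
  n <- nrow(tr)
  ang <- dist <- pos <- magC <- magD <- numeric(n)
  for (i in seq_len(n)) {
    xA <- c(tr$xA_x[i], tr$xA_y[i])
    xB <- c(tr$xB_x[i], tr$xB_y[i])
    xD <- c(tr$xD_x[i], tr$xD_y[i])
    ang[i] <- angle_error(xA, xB, xD)
    dist[i] <- distance_error(xA, xB, xD)
    pos[i] <- position_error(xA, xB, xD)
    magC[i] <- .vec_mag(ideal_homing_vector(xA, xB))
    magD[i] <- .vec_mag(xD)
  }
  data.frame(trial_index = tr$trial_index,
             template_label = tr$template_label,
             handedness = tr$handedness,
             angle_error = ang, distance_error = dist,
             position_error = pos, mag_C = magC, mag_D = magD,
             stringsAsFactors = FALSE)
}
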