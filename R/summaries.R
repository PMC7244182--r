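#' Per-subject behavioural summary
#'
#' Circular mean of the per-trial angular errors, arithmetic mean of the
#' distance errors and mean position error, overall and broken down by
#' template.
#'
#' @param session A [new_session()] with responses.
#' @return A list of class `tc_subject_summary`: `subject_id`, `n_trials`,
#'   `angle_error_mean` (degrees, circular), `distance_error_mean`,
#'   `position_error_mean` (m) and a `by_template` data.frame.
#' @export
subject_summary <- function(session) {
  stopifnot(inherits(session, "tc_session"))
  err <- trial_errors(session)
  by_tpl <- do.call(rbind, lapply(split(err, err$template_label), function(d)
    data.frame(template_label = d$template_label[1], n = nrow(d),
               angle_error_mean = circular_mean(d$angle_error),
               distance_error_mean = mean(d$distance_error),
               position_error_mean = mean(d$position_error),
               stringsAsFactors = FALSE)))
  rownames(by_tpl) <- NULL
  structure(
    list(subject_id = session$subject_id, n_trials = nrow(err),
         angle_error_mean = circular_mean(err$angle_error),
         distance_error_mean = mean(err$distance_error),
         position_error_mean = mean(err$position_error),
         by_template = by_tpl),
    class = "tc_subject_summary")
}

#' @export
print.tc_subject_summary <- function(x, ...) {
  cat(sprintf("<tc_subject_summary> %s (%d trials)\n", x$subject_id, x$n_trials))
  cat(sprintf("  circular mean angle error: %.3f deg\n", x$angle_error_mean))
  cat(sprintf("  mean distance error:       %.4f\n", x$distance_error_mean))
  cat(sprintf("  mean position error:       %.3f m\n", x$position_error_mean))
  invisible(x)
}

#' Per-subject regression of walked on correct return distance
#'
#' Ordinary least-squares slope of the walked return distance |xD| on the
#' correct return distance |xC|, one line per subject.  A slope of 1
#' means unbiased scaling of the homing vector.
#'
#' @param sessions A `tc_session` or list of them.
#' @return A data.frame: `subject_id`, `slope`, `intercept`, `r_squared`,
#'   `n`.
#' @export
homing_regression <- function(sessions) {
  if (inherits(sessions, "tc_session")) sessions <- list(sessions)
  out <- do.call(rbind, lapply(sessions, function(s) {
    err <- trial_errors(s)
    if (diff(range(err$mag_C)) < 1e-9)
      stop(sprintf("subject %s: constant |xC|, regression degenerate",
                   s$subject_id), call. = FALSE)
    fit <- stats::lm(mag_D ~ mag_C, data = err)
    data.frame(subject_id = s$subject_id,
               slope = unname(stats::coef(fit)[2]),
               intercept = unname(stats::coef(fit)[1]),
               r_squared = summary(fit)$r.squared,
               n = nrow(err), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

## pooled per-trial errors with a size-group column (|xC| rounded to mm
## identifies the size class)
.pooled_errors <- function(sessions) {
  if (inherits(sessions, "tc_session")) sessions <- list(sessions)
  err <- do.call(rbind, lapply(sessions, function(s) {
    e <- trial_errors(s)
    e$subject_id <- s$subject_id
    e
  }))
  err$size_group <- round(err$mag_C, 3)
  err
}

#' Spread of walked distance as a function of return distance
#'
#' Groups trials by the correct return distance |xC| (one group per
#' triangle size), computes the pooled within-group sample standard
#' deviation of the walked distance |xD| and fits an OLS line of SD on
#' |xC|.  Groups with fewer than two trials are excluded with a warning.
#'
#' @param sessions A `tc_session` or list of them.
#' @return A list: `slope`, `intercept` (of SD vs |xC|), and a `groups`
#'   data.frame (`mag_C`, `sd_D`, `n`).
#' @export
sd_vs_distance <- function(sessions) {
  err <- .pooled_errors(sessions)
  groups <- do.call(rbind, lapply(split(err, err$size_group), function(d)
    data.frame(mag_C = mean(d$mag_C), sd_D = stats::sd(d$mag_D),
               n = nrow(d))))
  rownames(groups) <- NULL
  small <- groups$n < 2
  if (any(small)) {
    warning(sprintf("%d size group(s) with < 2 trials excluded", sum(small)),
            call. = FALSE)
    groups <- groups[!small, , drop = FALSE]
  }
  if (nrow(groups) < 2)
    stop("need at least 2 size groups to fit SD vs distance", call. = FALSE)
  fit <- stats::lm(sd_D ~ mag_C, data = groups)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       groups = groups)
}

#' Logarithmic fit of systematic distance error against return distance
#'
#' Computes the mean systematic error `1 - distance_error` per size group
#' and regresses it on `log(|xC|)`.  A positive slope means that
#' underestimation grows (logarithmically) with triangle size.
#'
#' @param sessions A `tc_session` or list of them.
#' @return A list: `intercept`, `slope` (per unit `log(m)`), `r_squared`,
#'   and a `groups` data.frame (`mag_C`, `systematic_error`, `n`).
#' @export
systematic_error_log_fit <- function(sessions) {
  err <- .pooled_errors(sessions)
  if (any(err$mag_C <= 0))
    stop("non-positive return distances", call. = FALSE)
  groups <- do.call(rbind, lapply(split(err, err$size_group), function(d)
    data.frame(mag_C = mean(d$mag_C),
               systematic_error = mean(1 - d$distance_error),
               n = nrow(d))))
  rownames(groups) <- NULL
  if (nrow(groups) < 3)
    stop("need at least 3 size groups for the logarithmic fit", call. = FALSE)
  fit <- stats::lm(systematic_error ~ log(mag_C), data = groups)
  list(intercept = unname(stats::coef(fit)[1]),
       slope = unname(stats::coef(fit)[2]),
       r_squared = summary(fit)$r.squared,
       groups = groups)
}
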