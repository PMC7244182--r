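## fixed float formatting: 12 significant digits, so the writer is
## bit-exact for a given table
.fmt_num <- function(x) {
  out <- ifelse(is.na(x), "", formatC(x, digits = 12, format = "g"))
  out
}

#' Write sessions to a trial-table CSV
#'
#' UTF-8, comma-separated, header row; columns `subject_id, trial_index,
#' design_id, template_label, handedness, xA_x, xA_y, xB_x, xB_y, xD_x,
#' xD_y` (metres, decimal point, empty cells for missing responses).
#' Numeric fields are written with 12 significant digits so the output is
#' byte-identical for identical inputs.
#'
#' @param sessions A `tc_session` or list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(sessions, path) {
  if (inherits(sessions, "tc_session")) sessions <- list(sessions)
  stopifnot(all(vapply(sessions, inherits, logical(1), "tc_session")))
  rows <- do.call(rbind, lapply(sessions, function(s) {
    tr <- s$trials
    data.frame(subject_id = s$subject_id, trial_index = tr$trial_index,
               design_id = s$design_id, template_label = tr$template_label,
               handedness = tr$handedness,
               xA_x = .fmt_num(tr$xA_x), xA_y = .fmt_num(tr$xA_y),
               xB_x = .fmt_num(tr$xB_x), xB_y = .fmt_num(tr$xB_y),
               xD_x = .fmt_num(tr$xD_x), xD_y = .fmt_num(tr$xD_y),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read sessions from a trial-table CSV
#'
#' @param path Path to a CSV written by [write_trial_table()] (or any
#'   file in the same dialect).
#' @return A named list of `tc_session` objects, one per subject, in
#'   first-appearance order.
#' @export
read_trial_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(subject_id = "character",
                                        template_label = "character",
                                        handedness = "character"),
                         fileEncoding = "UTF-8")
  needed <- c("subject_id", "trial_index", "design_id", "template_label",
              "handedness", "xA_x", "xA_y", "xB_x", "xB_y", "xD_x", "xD_y")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols))
    stop("trial table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  subjects <- unique(raw$subject_id)
  out <- lapply(subjects, function(sid) {
    d <- raw[raw$subject_id == sid, , drop = FALSE]
    d <- d[order(d$trial_index), , drop = FALSE]
    design <- unique(d$design_id)
    if (length(design) != 1)
      stop(sprintf("subject %s has multiple design_ids", sid), call. = FALSE)
    new_session(sid, design,
                d[, c("trial_index", "template_label", "handedness",
                      "xA_x", "xA_y", "xB_x", "xB_y", "xD_x", "xD_y")])
  })
  stats::setNames(out, subjects)
}

#' Validate a trial-table CSV
#'
#' Checks the header, column types, per-subject trial-index ordering and,
#' for the built-in designs, that the guided-side magnitudes match the
#' side lengths of the named template.  Returns a machine-readable report
#' rather than erroring on content problems (malformed CSV structure is
#' still an error).
#'
#' @param path Path to the CSV.
#' @param tol Geometry tolerance in metres.
#' @return A list: `valid` (logical) and `violations`, a data.frame with
#'   columns `row`, `subject_id`, `check`, `message`.
#' @export
validate_trial_table <- function(path, tol = 1e-6) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  viol <- list()
  note <- function(row, sid, check, message)
    viol[[length(viol) + 1L]] <<- data.frame(
      row = row, subject_id = sid, check = check, message = message,
      stringsAsFactors = FALSE)

  needed <- c("subject_id", "trial_index", "design_id", "template_label",
              "handedness", "xA_x", "xA_y", "xB_x", "xB_y", "xD_x", "xD_y")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols)) {
    note(0L, NA_character_, "header",
         paste("missing columns:", paste(missing_cols, collapse = ", ")))
    return(list(valid = FALSE, violations = do.call(rbind, viol)))
  }
  num_cols <- c("xA_x", "xA_y", "xB_x", "xB_y", "xD_x", "xD_y")
  for (cl in num_cols)
    if (!is.numeric(raw[[cl]]) && !all(is.na(raw[[cl]])))
      note(0L, NA_character_, "types", paste("non-numeric column:", cl))
  if (!all(raw$handedness %in% c("left", "right")))
    note(0L, NA_character_, "types", "handedness values outside {left, right}")

  ## reference side lengths for the built-in designs
  ref_sides <- list()
  for (tpl in c(exp1_templates(), exp2_templates()))
    ref_sides[[tpl$label]] <- c(A = tpl$side_A, B = tpl$side_B)

  for (sid in unique(raw$subject_id)) {
    d <- raw[raw$subject_id == sid, , drop = FALSE]
    idx <- d$trial_index
    if (!identical(as.integer(idx[order(idx)]), seq_along(idx)))
      note(0L, sid, "ordering",
           "trial_index not consecutive 1..n for subject")
    rows <- as.integer(rownames(d))
    for (i in seq_len(nrow(d))) {
      magA <- sqrt(d$xA_x[i]^2 + d$xA_y[i]^2)
      magB <- sqrt(d$xB_x[i]^2 + d$xB_y[i]^2)
      if (!is.finite(magA) || !is.finite(magB)) {
        note(rows[i], sid, "geometry", "non-finite guided-side components")
        next
      }
      ref <- ref_sides[[d$template_label[i]]]
      if (!is.null(ref) && d$design_id[i] %in% c("exp1", "exp2")) {
        if (abs(magA - ref["A"]) > tol)
          note(rows[i], sid, "geometry",
               sprintf("|xA| = %.6f differs from template side A = %.6f",
                       magA, ref["A"]))
        if (abs(magB - ref["B"]) > tol)
          note(rows[i], sid, "geometry",
               sprintf("|xB| = %.6f differs from template side B = %.6f",
                       magB, ref["B"]))
      }
    }
  }
  violations <- if (length(viol)) do.call(rbind, viol)
    else data.frame(row = integer(), subject_id = character(),
                    check = character(), message = character(),
                    stringsAsFactors = FALSE)
  list(valid = nrow(violations) == 0, violations = violations)
}

## ---------------------------------------------------------------------
## JSON serialisation of parameter sets and fits (schema versioned)
## ---------------------------------------------------------------------

.schema_version <- "1"

#' Serialise a parameter set to / from JSON
#'
#' @param params A `tc_params` object.
#' @param path Output (or input) file path.
#' @return `write_params` returns `path` invisibly; `read_params` returns
#'   the reconstructed `tc_params`.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "tc_params"))
  doc <- list(schema_version = .schema_version,
              model_id = params$model_id,
              parameters = params$values,
              bounds = default_bounds(params$model_id))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$model_id) || is.null(doc$parameters))
    stop("not a parameter-set document: ", path, call. = FALSE)
  .params_from_vector(doc$model_id, unlist(doc$parameters))
}

#' Serialise a fit to JSON
#'
#' One document per subject x model, including the seed, bounds and all
#' start diagnostics.
#'
#' @param fit A `tc_fit` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "tc_fit"))
  doc <- list(schema_version = .schema_version,
              subject_id = fit$subject_id, model_id = fit$model_id,
              parameters = fit$params$values,
              log_likelihood = fit$log_likelihood,
              n_trials = fit$n_trials, k_params = fit$k_params,
              n_starts = fit$n_starts, seed = fit$seed,
              bounds = fit$bounds, starts = fit$starts)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
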