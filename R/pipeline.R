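## default generative parameter sets per design: the group-mean weights
## with a moderate Weber noise coefficient (0.1) and mid-range history
## decay (0.5); see the methods vignette for the rationale
.default_generating <- function(design_id) {
  if (design_id == "exp1")
    list(model_id = "model1",
         params = model1_params(0.3, 0.813, 0.1), n_subjects = 22L)
  else
    list(model_id = "model2",
         params = model2_params(0.488, 0.562, 0.015, 0.5, 0.1),
         n_subjects = 17L)
}

#' Run the full modelling pipeline
#'
#' Simulate sessions for a cohort of synthetic subjects, fit the
#' requested models to every subject, build the comparison table,
#' exceedance probabilities and behavioural summaries, optionally run a
#' model-recovery study, and write everything (with a manifest recording
#' seeds, the configuration and output checksums) to a directory.
#' Re-running with the same configuration reproduces byte-identical
#' outputs.
#'
#' @param config A named list, or the path of a YAML file holding one.
#'   Recognised fields (all optional): `design` (`"exp1"` or `"exp2"`),
#'   `n_subjects`, `generating_model`, `generating_params` (named list),
#'   `models` (character vector to fit), `n_starts`, `seed`, `out_dir`,
#'   `recover` (logical), `n_sims` (recovery simulations per model).
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  known <- c("design", "n_subjects", "generating_model", "generating_params",
             "models", "n_starts", "seed", "out_dir", "recover", "n_sims")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)

  design_id <- config$design %||% "exp1"
  if (!design_id %in% c("exp1", "exp2"))
    stop("config$design must be 'exp1' or 'exp2'", call. = FALSE)
  defaults <- .default_generating(design_id)
  n_subjects <- as.integer(config$n_subjects %||% defaults$n_subjects)
  gen_model <- config$generating_model %||% defaults$model_id
  if (!gen_model %in% c("model1", "model2", "eem"))
    stop("unknown generating model: ", gen_model, call. = FALSE)
  gen_params <- if (is.null(config$generating_params)) {
    if (gen_model == defaults$model_id) defaults$params
    else stop("generating_params required when generating_model differs from ",
              "the design default", call. = FALSE)
  } else .params_from_vector(gen_model, unlist(config$generating_params))
  models <- config$models %||% c("model1", "model2", "eem")
  bad <- setdiff(models, c("model1", "model2", "eem"))
  if (length(bad))
    stop("unknown model id(s): ", paste(bad, collapse = ", "), call. = FALSE)
  n_starts <- as.integer(config$n_starts %||% 20L)
  seed <- as.integer(config$seed %||% 1L)
  out_dir <- config$out_dir %||% stop("config$out_dir is required",
                                      call. = FALSE)
  recover <- isTRUE(config$recover)
  n_sims <- as.integer(config$n_sims %||% 100L)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "fits"), showWarnings = FALSE)
  design <- design_spec(design_id)

  ## stage seeds, all derived from the single config seed
  set.seed(seed)
  stage_seeds <- list(
    sessions = matrix(sample.int(.Machine$integer.max, 2 * n_subjects),
                      ncol = 2),
    fits = sample.int(.Machine$integer.max, n_subjects * length(models)),
    exceedance = sample.int(.Machine$integer.max, 1),
    recovery = sample.int(.Machine$integer.max, 1))

  ## --- simulate ---
  sessions <- lapply(seq_len(n_subjects), function(i)
    simulate_responses(
      build_session(design, sprintf("sub%02d", i),
                    seed = stage_seeds$sessions[i, 1]),
      gen_params, seed = stage_seeds$sessions[i, 2]))
  trials_path <- file.path(out_dir, "trials.csv")
  write_trial_table(sessions, trials_path)

  ## --- fit ---
  fits <- list()
  fi <- 0L
  for (s in sessions) {
    for (mid in models) {
      fi <- fi + 1L
      fit <- fit_mle(s, mid, n_starts = n_starts,
                     seed = stage_seeds$fits[fi])
      fits[[fi]] <- fit
      write_fit(fit, file.path(out_dir, "fits",
                               sprintf("%s_%s.json", s$subject_id, mid)))
    }
  }

  ## --- compare ---
  tbl <- comparison_table(fits)
  utils::write.csv(tbl, file.path(out_dir, "comparison.csv"),
                   row.names = FALSE)
  counts <- best_fit_counts(tbl)
  utils::write.csv(counts, file.path(out_dir, "best_fit_counts.csv"),
                   row.names = FALSE)
  xp <- NULL
  if (length(models) >= 2) {
    ev <- matrix(NA_real_, n_subjects, length(models),
                 dimnames = list(NULL, models))
    for (r in seq_len(nrow(tbl)))
      ev[match(tbl$subject_id[r], vapply(sessions, `[[`, "", "subject_id")),
         tbl$model_id[r]] <- -tbl$BIC[r] / 2
    xp <- exceedance_probabilities(ev, seed = stage_seeds$exceedance)
    jsonlite::write_json(
      list(exceedance = as.list(xp),
           expected_freq = as.list(attr(xp, "expected_freq"))),
      file.path(out_dir, "exceedance.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  }

  ## --- summarise ---
  summaries <- do.call(rbind, lapply(sessions, function(s) {
    ss <- subject_summary(s)
    data.frame(subject_id = ss$subject_id, n_trials = ss$n_trials,
               angle_error_mean = ss$angle_error_mean,
               distance_error_mean = ss$distance_error_mean,
               position_error_mean = ss$position_error_mean,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(summaries, file.path(out_dir, "summary.csv"),
                   row.names = FALSE)

  ## --- recover (optional) ---
  if (recover) {
    rec <- model_recovery(design, models, n_sims = n_sims,
                          seed = stage_seeds$recovery, n_starts = n_starts)
    utils::write.csv(as.data.frame(rec$aic),
                     file.path(out_dir, "confusion_aic.csv"))
    utils::write.csv(as.data.frame(rec$bic),
                     file.path(out_dir, "confusion_bic.csv"))
  }

  ## --- manifest ---
  outputs <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  outputs <- outputs[basename(outputs) != "manifest.json"]
  manifest <- list(
    package_version = as.character(utils::packageVersion("tricomp")),
    config = list(design = design_id, n_subjects = n_subjects,
                  generating_model = gen_model,
                  generating_params = gen_params$values,
                  models = models, n_starts = n_starts, seed = seed,
                  recover = recover, n_sims = if (recover) n_sims else NULL),
    stage_seeds = list(sessions = as.vector(stage_seeds$sessions),
                       fits = stage_seeds$fits,
                       exceedance = stage_seeds$exceedance,
                       recovery = if (recover) stage_seeds$recovery else NULL),
    checksums = as.list(stats::setNames(
      unname(tools::md5sum(outputs)),
      sub(paste0("^", out_dir, "/?"), "", outputs))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
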