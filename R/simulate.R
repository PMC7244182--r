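#' Simulate responses for a session from a generative model
#'
#' Walks the session's trials in order, computes each trial's mean
#' predicted return vector under the model (for the trial-history model
#' the history is fed by the responses actually simulated on earlier
#' trials) and adds independent isotropic Gaussian noise with standard
#' deviation [noise_scale()] to each component.  Deterministic given
#' `seed`.
#'
#' @param session A [new_session()] object (existing responses, if any,
#'   are overwritten).
#' @param params A `tc_params` object (see [model1_params()],
#'   [model2_params()], [eem_params()]).
#' @param seed Integer seed.
#' @return The session with `xD_x`, `xD_y` filled in.
#' @export
#' @examples
#' s <- build_session(design_spec("exp1"), "s01", seed = 1)
#' s <- simulate_responses(s, model1_params(0.87, 0.87, 0), seed = 2)
#' all.equal(unique(round(trial_errors(s)$distance_error, 9)), 0.87)
simulate_responses <- function(session, params, seed = 1L) {
  stopifnot(inherits(session, "tc_session"), inherits(params, "tc_params"))
  m <- .session_mats(session)
  n <- nrow(m$xA)
  v <- params$values
  set.seed(seed)
  xD <- matrix(NA_real_, n, 2)
  state <- history_init()
  hand <- session$trials$handedness
  for (t in seq_len(n)) {
    xA <- m$xA[t, ]; xB <- m$xB[t, ]
    mu <- switch(params$model_id,
      model1 = predict_model1(xA, xB, v$beta_A, v$beta_B),
      model2 = predict_model2(xA, xB, state, v$beta_A, v$beta_B,
                              v$beta_lambda),
      eem = predict_eem(xA, xB, hand[t], params))
    if (any(!is.finite(mu)))
      stop(sprintf("degenerate encoding on trial %d: %s", t,
                   "encoded quantities do not form a valid triangle"),
           call. = FALSE)
    sigma <- noise_scale(v$sigma_tilde, xA, xB)
    xD[t, ] <- mu + stats::rnorm(2, 0, sigma)
    if (params$model_id == "model2")
      state <- update_history(state, xA, xB, xD[t, ], v$alpha)
  }
  session$trials$xD_x <- xD[, 1]
  session$trials$xD_y <- xD[, 2]
  session$seed <- as.integer(seed)
  session
}

#' Simulate a session from a fitted model
#'
#' Convenience wrapper: builds a fresh session from `design` and
#' simulates it with the parameter set stored in a fit (see [fit_mle()]),
#' as used to regenerate summary figures from fitted values.
#'
#' @param design A [design_spec()].
#' @param fit A `tc_fit` object.
#' @param seed Integer seed (drives both trial order and noise).
#' @param subject_id Identifier for the simulated session; defaults to
#'   the fitted subject's id with a `"sim:"` prefix.
#' @return A simulated [new_session()].
#' @export
simulate_fitted <- function(design, fit, seed = 1L, subject_id = NULL) {
  stopifnot(inherits(design, "tc_design"), inherits(fit, "tc_fit"))
  if (is.null(subject_id)) subject_id <- paste0("sim:", fit$subject_id)
  s <- build_session(design, subject_id, seed = seed)
  simulate_responses(s, fit$params, seed = seed)
}
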