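## shared fixtures and oracle helpers, all built in code

## rotate a length-2 vector (or the rows of an n x 2 matrix) by deg CCW
rot2 <- function(v, deg) {
  r <- deg * pi / 180
  R <- matrix(c(cos(r), sin(r), -sin(r), cos(r)), 2)
  if (is.matrix(v)) v %*% t(R) else as.numeric(R %*% v)
}

## a tiny custom design: equilateral + right isosceles, 2 trials each side
tiny_design <- function() {
  design_spec("custom",
              templates = list(eq = triangle_template("eq", c(60, 60, 60),
                                                      "left", side_C = 10),
                               ri = triangle_template("ri", c(45, 90, 45),
                                                      "left", side_C = 10)),
              counts_left = c(1L, 1L), counts_right = c(1L, 1L))
}

## one-trial session from explicit vectors
one_trial_session <- function(xA, xB, xD = c(NA_real_, NA_real_),
                              handedness = "left", label = "t") {
  new_session("s1", "custom",
              data.frame(trial_index = 1L, template_label = label,
                         handedness = handedness,
                         xA_x = xA[1], xA_y = xA[2],
                         xB_x = xB[1], xB_y = xB[2],
                         xD_x = xD[1], xD_y = xD[2],
                         stringsAsFactors = FALSE))
}

## independent per-trial Gaussian density-product log-likelihood oracle
ll_oracle <- function(session, params) {
  tr <- session$trials
  v <- params$values
  state <- history_init()
  ll <- 0
  for (t in seq_len(nrow(tr))) {
    xA <- c(tr$xA_x[t], tr$xA_y[t]); xB <- c(tr$xB_x[t], tr$xB_y[t])
    xD <- c(tr$xD_x[t], tr$xD_y[t])
    mu <- switch(params$model_id,
      model1 = predict_model1(xA, xB, v$beta_A, v$beta_B),
      model2 = predict_model2(xA, xB, state, v$beta_A, v$beta_B,
                              v$beta_lambda),
      eem = predict_eem(xA, xB, tr$handedness[t], params))
    s <- noise_scale(v$sigma_tilde, xA, xB)
    ll <- ll + dnorm(xD[1], mu[1], s, log = TRUE) +
      dnorm(xD[2], mu[2], s, log = TRUE)
    if (params$model_id == "model2")
      state <- update_history(state, xA, xB, xD, v$alpha)
  }
  ll
}

## simulated exp1 session, defaults to the basic vector-addition generator
sim_exp1_session <- function(params = model1_params(0.3, 0.813, 0.1),
                             seed = 1L, subject_id = "s1") {
  s <- build_session(design_spec("exp1"), subject_id, seed = seed)
  simulate_responses(s, params, seed = seed + 1000L)
}
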