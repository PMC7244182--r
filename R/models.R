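## -------------------------------------------------------------------------
## Parameter sets
## -------------------------------------------------------------------------

#' Default parameter bounds for fitting
#'
#' Generous boxes around all plausible estimates: vector weights in
#' \[-2, 2\], history decay in \[0, 1\], Weber noise coefficient in
#' \[1e-4, 2\]; Encoding-Error slopes in \[0, 2\], distance intercept in
#' \[-5, 5\] m and turn intercept in \[-30, 30\] degrees.
#'
#' @param model_id `"model1"`, `"model2"` or `"eem"`.
#' @return A data.frame with columns `name`, `lower`, `upper`.
#' @export
default_bounds <- function(model_id = c("model1", "model2", "eem")) {
  model_id <- match.arg(model_id)
  b <- switch(model_id,
    model1 = data.frame(
      name = c("beta_A", "beta_B", "sigma_tilde"),
      lower = c(-2, -2, 1e-4), upper = c(2, 2, 2)),
    model2 = data.frame(
      name = c("beta_A", "beta_B", "beta_lambda", "alpha", "sigma_tilde"),
      lower = c(-2, -2, -2, 0, 1e-4), upper = c(2, 2, 2, 1, 2)),
    eem = data.frame(
      name = c("k0_left", "k1_left", "w0_left", "w1_left",
               "k0_right", "k1_right", "w0_right", "w1_right",
               "sigma_tilde"),
      lower = c(-5, 0, -30, 0, -5, 0, -30, 0, 1e-4),
      upper = c(5, 2, 30, 2, 5, 2, 30, 2, 2)))
  b$name <- as.character(b$name)
  b
}

.check_in_bounds <- function(values, model_id) {
  b <- default_bounds(model_id)
  for (i in seq_len(nrow(b))) {
    v <- values[[b$name[i]]]
    if (is.null(v) || !is.finite(v))
      stop(sprintf("parameter '%s' missing or non-finite", b$name[i]),
           call. = FALSE)
  }
  if (!is.null(values$alpha) && (values$alpha < 0 || values$alpha > 1))
    stop("alpha must lie in [0, 1]", call. = FALSE)
  if (values$sigma_tilde < 0)
    stop("sigma_tilde must be non-negative", call. = FALSE)
  invisible(values)
}

#' Parameter set for the vector-addition model
#'
#' The basic configural model predicts the return vector as a weighted
#' sum of the guided sides, `-(beta_A * xA + beta_B * xB)`, with
#' isotropic Gaussian response noise whose standard deviation follows
#' Weber scaling (see [noise_scale()]).
#'
#' @param beta_A,beta_B Dimensionless weights on the two guided sides.
#' @param sigma_tilde Dimensionless Weber noise coefficient (>= 0).
#' @return An object of class `tc_params`.
#' @export
#' @examples
#' model1_params(0.3, 0.813, 0.1)
model1_params <- function(beta_A, beta_B, sigma_tilde) {
  values <- list(beta_A = beta_A, beta_B = beta_B, sigma_tilde = sigma_tilde)
  .check_in_bounds(values, "model1")
  structure(list(model_id = "model1", values = values), class = "tc_params")
}

#' Parameter set for the trial-history model
#'
#' Extends the vector-addition model with an exponentially decaying
#' history of past trials' vectors: the prediction acquires the term
#' `-beta_lambda * (lambda_A + lambda_B - lambda_D)`, where each lambda
#' accumulates as `lambda <- x + alpha * lambda` after every trial
#' (zero vectors before the first trial).
#'
#' @inheritParams model1_params
#' @param beta_lambda Dimensionless weight on the history term.
#' @param alpha History decay in \[0, 1\]; 0 means only the immediately
#'   preceding trial contributes.
#' @return An object of class `tc_params`.
#' @export
#' @examples
#' model2_params(0.311, 0.698, 0.112, 0.5, 0.1)
model2_params <- function(beta_A, beta_B, beta_lambda, alpha, sigma_tilde) {
  values <- list(beta_A = beta_A, beta_B = beta_B, beta_lambda = beta_lambda,
                 alpha = alpha, sigma_tilde = sigma_tilde)
  .check_in_bounds(values, "model2")
  structure(list(model_id = "model2", values = values), class = "tc_params")
}

#' Parameter set for the Encoding-Error Model
#'
#' The Encoding-Error Model attributes all systematic error to linear
#' mis-encoding of the guided geometry: both guided side lengths are
#' encoded through the same function `s_r = k0 + k1 * s`, the interior
#' turn angle through `ab_r = w0 + w1 * ab`, and the return is computed
#' on the encoded triangle by the laws of cosines and sines.  Encoding
#' coefficients are kept separately per handedness (left/right guided
#' paths), matching how the model is fitted.
#'
#' @param left,right Numeric length-4 vectors `(k0, k1, w0, w1)`:
#'   distance-encoding intercept (m) and slope, turn-encoding intercept
#'   (degrees) and slope.
#' @param sigma_tilde Dimensionless Weber noise coefficient (>= 0).
#' @return An object of class `tc_params`.
#' @export
#' @examples
#' eem_params(c(0, 0.9, 0, 1), c(0, 0.9, 0, 1), 0.1)  # shrunken distances
eem_params <- function(left = c(0, 1, 0, 1), right = left, sigma_tilde) {
  stopifnot(is.numeric(left), length(left) == 4, all(is.finite(left)),
            is.numeric(right), length(right) == 4, all(is.finite(right)))
  values <- list(k0_left = left[1], k1_left = left[2],
                 w0_left = left[3], w1_left = left[4],
                 k0_right = right[1], k1_right = right[2],
                 w0_right = right[3], w1_right = right[4],
                 sigma_tilde = sigma_tilde)
  .check_in_bounds(values, "eem")
  structure(list(model_id = "eem", values = values), class = "tc_params")
}

#' @export
print.tc_params <- function(x, ...) {
  cat(sprintf("<tc_params> %s\n", x$model_id))
  v <- unlist(x$values)
  cat(paste(sprintf("  %s = %.6g", names(v), v), collapse = "\n"), "\n")
  invisible(x)
}

## number of free parameters of each model (EEM: two 4-coefficient
## encoding sets plus the shared noise coefficient)
.k_params <- function(model_id) {
  switch(model_id, model1 = 3L, model2 = 5L, eem = 9L,
         stop("unknown model_id: ", model_id, call. = FALSE))
}

## tc_params from a named parameter vector (used by the optimiser)
.params_from_vector <- function(model_id, par) {
  switch(model_id,
    model1 = model1_params(par[["beta_A"]], par[["beta_B"]],
                           par[["sigma_tilde"]]),
    model2 = model2_params(par[["beta_A"]], par[["beta_B"]],
                           par[["beta_lambda"]], par[["alpha"]],
                           par[["sigma_tilde"]]),
    eem = eem_params(c(par[["k0_left"]], par[["k1_left"]],
                       par[["w0_left"]], par[["w1_left"]]),
                     c(par[["k0_right"]], par[["k1_right"]],
                       par[["w0_right"]], par[["w1_right"]]),
                     par[["sigma_tilde"]]))
}

## -------------------------------------------------------------------------
## Noise scale and single-trial predictions
## -------------------------------------------------------------------------

#' Weber-scaled response noise standard deviation
#'
#' Response noise grows with the traversed path:
#' `sigma = sigma_tilde * sqrt(|xA|^2 + |xB|^2)` metres, so doubling the
#' triangle doubles the response spread (scalar variability).
#'
#' @param sigma_tilde Dimensionless noise coefficient (>= 0).
#' @param xA,xB Guided displacement vectors (metres).
#' @return Noise standard deviation in metres (applied per component).
#' @export
#' @examples
#' noise_scale(0.1, c(10, 0), c(0, 10))
noise_scale <- function(sigma_tilde, xA, xB) {
  stopifnot(is.numeric(sigma_tilde), length(sigma_tilde) == 1L)
  if (!is.finite(sigma_tilde) || sigma_tilde < 0)
    stop("sigma_tilde must be finite and non-negative", call. = FALSE)
  .check_planar(xA, "xA"); .check_planar(xB, "xB")
  sigma_tilde * sqrt(sum(xA^2) + sum(xB^2))
}

#' Vector-addition prediction of the return vector
#'
#' @param xA,xB Guided displacement vectors (metres).
#' @param beta_A,beta_B Weights on the guided sides.
#' @return Predicted mean return vector `-(beta_A*xA + beta_B*xB)`.
#' @export
#' @examples
#' predict_model1(c(10, 0), c(-5, 5 * sqrt(3)), 1, 1)  # ideal return
predict_model1 <- function(xA, xB, beta_A, beta_B) {
  .check_planar(xA, "xA"); .check_planar(xB, "xB")
  stopifnot(is.finite(beta_A), is.finite(beta_B))
  -(beta_A * xA + beta_B * xB)
}

#' Update the trial-history state
#'
#' After a trial with vectors `(xA, xB, xD)`, each history component is
#' updated as `lambda <- x + alpha * lambda`.  The state is the zero
#' vector triple before the first trial.
#'
#' @param state List with length-2 numeric `lambda_A`, `lambda_B`,
#'   `lambda_D` (use [history_init()] for the initial state).
#' @param xA,xB,xD The trial's guided and walked vectors (metres).
#' @param alpha History decay in \[0, 1\].
#' @return The updated state.
#' @export
update_history <- function(state, xA, xB, xD, alpha) {
  stopifnot(is.list(state),
            all(c("lambda_A", "lambda_B", "lambda_D") %in% names(state)))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha > 1)
    stop("alpha must lie in [0, 1]", call. = FALSE)
  .check_planar(xA, "xA"); .check_planar(xB, "xB"); .check_planar(xD, "xD")
  list(lambda_A = xA + alpha * state$lambda_A,
       lambda_B = xB + alpha * state$lambda_B,
       lambda_D = xD + alpha * state$lambda_D)
}

#' @rdname update_history
#' @export
history_init <- function() {
  list(lambda_A = c(0, 0), lambda_B = c(0, 0), lambda_D = c(0, 0))
}

#' Trial-history prediction of the return vector
#'
#' @inheritParams predict_model1
#' @param state History state through the previous trial (see
#'   [update_history()]).
#' @param beta_lambda Weight on the history term.
#' @return Predicted mean return vector
#'   `-(beta_A*xA + beta_B*xB + beta_lambda*(lambda_A + lambda_B - lambda_D))`.
#' @export
predict_model2 <- function(xA, xB, state, beta_A, beta_B, beta_lambda) {
  .check_planar(xA, "xA"); .check_planar(xB, "xB")
  stopifnot(is.finite(beta_A), is.finite(beta_B), is.finite(beta_lambda))
  hist_vec <- state$lambda_A + state$lambda_B - state$lambda_D
  -(beta_A * xA + beta_B * xB + beta_lambda * hist_vec)
}

#' Encoding-Error Model prediction of the return vector
#'
#' Encodes the guided side lengths as `A_r = k0 + k1*A`,
#' `B_r = k0 + k1*B` (the same linear function for both sides) and the
#' interior angle between them as `ab_r = w0 + w1*ab`, computes the
#' encoded return distance `C_r` by the law of cosines and the encoded
#' interior angle at the second corner by the law of cosines on the
#' encoded triangle, and emits the response vector of length `C_r` at the
#' implied heading in the trial frame.  The prediction is independent of
#' trial history.
#'
#' @param xA,xB Guided displacement vectors (metres); the interior angle
#'   at the first corner is derived from them.
#' @param handedness `"left"` or `"right"` (selects the coefficient set
#'   and the turn direction of the return).
#' @param params An [eem_params()] object (noise coefficient unused here).
#' @return Predicted mean return vector, or a vector of `NA`s with
#'   attribute `"violation"` (positive distance from the feasible region)
#'   when the encoded quantities do not form a valid triangle.
#' @export
#' @examples
#' xA <- c(10, 0); xB <- c(-5, 5 * sqrt(3))
#' predict_eem(xA, xB, "left", eem_params(sigma_tilde = 0.1))  # identity = ideal
predict_eem <- function(xA, xB, handedness = c("left", "right"), params) {
  handedness <- match.arg(handedness)
  .check_planar(xA, "xA"); .check_planar(xB, "xB")
  stopifnot(inherits(params, "tc_params"), params$model_id == "eem")
  v <- params$values
  co <- if (handedness == "left")
    c(v$k0_left, v$k1_left, v$w0_left, v$w1_left)
  else
    c(v$k0_right, v$k1_right, v$w0_right, v$w1_right)

  A <- .vec_mag(xA); B <- .vec_mag(xB)
  ## interior angle at the first corner: between -xA and xB
  ab <- .rad2deg(acos(max(-1, min(1,
    sum(-xA * xB) / (A * B)))))

  A_r <- co[1] + co[2] * A
  B_r <- co[1] + co[2] * B
  ab_r <- co[3] + co[4] * ab

  ## feasibility: positive encoded sides, encoded angle inside (0, 180)
  viol <- max(0, -A_r) + max(0, -B_r) +
    max(0, -ab_r) + max(0, ab_r - 180)
  if (viol > 0 || A_r == 0 || B_r == 0 || ab_r == 0 || ab_r == 180) {
    out <- c(NA_real_, NA_real_)
    attr(out, "violation") <- max(viol, 1e-9)
    return(out)
  }

  C_r <- sqrt(A_r^2 + B_r^2 - 2 * A_r * B_r * cos(.deg2rad(ab_r)))
  if (C_r <= 0) {
    out <- c(NA_real_, NA_real_)
    attr(out, "violation") <- 1e-9
    return(out)
  }
  ## encoded interior angle at the second corner, law of cosines
  cos_bc <- (B_r^2 + C_r^2 - A_r^2) / (2 * B_r * C_r)
  bc_r <- .rad2deg(acos(max(-1, min(1, cos_bc))))
  ## exterior turn at the second corner, same turn direction as at G1
  s <- if (handedness == "left") 1 else -1
  heading <- .vec_heading(xB) + s * (180 - bc_r)
  C_r * c(cos(.deg2rad(heading)), sin(.deg2rad(heading)))
}

## -------------------------------------------------------------------------
## Session-level mean predictions
## -------------------------------------------------------------------------

#' Mean model predictions for every trial of a session
#'
#' Computes the model's noise-free predicted return vector for each trial.
#' For the trial-history model the history state is propagated from the
#' session's recorded responses (one-step-ahead prediction), so the
#' session must contain responses; trials with missing responses
#' contribute nothing to the history but the decay still applies.
#'
#' @param session A [new_session()] object.
#' @param params A `tc_params` object.
#' @return An n x 2 matrix of predicted response vectors (rows may be NA
#'   for infeasible Encoding-Error encodings, flagged in attribute
#'   `"violation"`).
#' @export
predict_responses <- function(session, params) {
  stopifnot(inherits(session, "tc_session"), inherits(params, "tc_params"))
  m <- .session_mats(session)
  n <- nrow(m$xA)
  v <- params$values
  out <- matrix(NA_real_, n, 2)
  total_viol <- 0

  if (params$model_id == "model1") {
    out <- -(v$beta_A * m$xA + v$beta_B * m$xB)
  } else if (params$model_id == "model2") {
    state <- history_init()
    for (t in seq_len(n)) {
      xA <- m$xA[t, ]; xB <- m$xB[t, ]
      out[t, ] <- predict_model2(xA, xB, state, v$beta_A, v$beta_B,
                                 v$beta_lambda)
      xD <- m$xD[t, ]
      if (all(is.finite(xD))) {
        state <- update_history(state, xA, xB, xD, v$alpha)
      } else {
        ## no contribution from an unresponded trial; decay still applies
        state <- lapply(state, function(l) v$alpha * l)
      }
    }
  } else {
    hand <- session$trials$handedness
    for (t in seq_len(n)) {
      p <- predict_eem(m$xA[t, ], m$xB[t, ], hand[t], params)
      out[t, ] <- p
      if (!is.null(attr(p, "violation")))
        total_viol <- total_viol + attr(p, "violation")
    }
  }
  if (total_viol > 0) attr(out, "violation") <- total_viol
  out
}
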