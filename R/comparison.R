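#' Akaike and Bayesian information criteria
#'
#' `aic(LL, k) = 2k - 2LL`; `bic(LL, k, n) = k*log(n) - 2LL`.  Lower is
#' better.
#'
#' @param log_likelihood Maximised log-likelihood in nats.
#' @param k Number of free parameters (>= 0).
#' @param n Number of observations (>= 1; one per trial).
#' @return The criterion value.
#' @export
#' @examples
#' aic(-100, 3)       # 206
#' bic(-100, 3, 28)   # 3*log(28) + 200
aic <- function(log_likelihood, k) {
  stopifnot(is.numeric(log_likelihood), is.numeric(k), all(k >= 0))
  2 * k - 2 * log_likelihood
}

#' @rdname aic
#' @export
bic <- function(log_likelihood, k, n) {
  stopifnot(is.numeric(log_likelihood), is.numeric(k), all(k >= 0),
            is.numeric(n), all(n >= 1))
  k * log(n) - 2 * log_likelihood
}

#' Comparison table from a list of fits
#'
#' @param fits A list of `tc_fit` objects (typically subjects x models).
#' @return A data.frame with one row per fit: `subject_id`, `model_id`,
#'   `log_likelihood`, `k`, `n`, `AIC`, `BIC`.
#' @export
comparison_table <- function(fits) {
  stopifnot(is.list(fits), length(fits) > 0,
            all(vapply(fits, inherits, logical(1), "tc_fit")))
  out <- do.call(rbind, lapply(fits, function(f)
    data.frame(subject_id = f$subject_id, model_id = f$model_id,
               log_likelihood = f$log_likelihood,
               k = f$k_params, n = f$n_trials,
               AIC = aic(f$log_likelihood, f$k_params),
               BIC = bic(f$log_likelihood, f$k_params, f$n_trials),
               stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

#' Random-effects exceedance probabilities
#'
#' Group-level Bayesian model selection treating the data-generating
#' model as a random effect across subjects: a variational Dirichlet
#' update over model frequencies (uniform Dirichlet prior; iterate
#' posterior subject-model assignments and Dirichlet counts to
#' convergence), followed by Monte-Carlo estimation of each model's
#' probability of being the most frequent one in the population.
#'
#' @param log_evidence Numeric matrix, subjects x models, of per-subject
#'   log model evidences (e.g. `-BIC/2`); columns may be named.
#' @param n_draws Monte-Carlo draws from the posterior Dirichlet.
#' @param seed Integer seed for the draws.
#' @param tol Convergence tolerance on the Dirichlet counts.
#' @return Named numeric vector of exceedance probabilities (sums to 1),
#'   with the posterior Dirichlet counts in attribute `"alpha"` and
#'   expected model frequencies in attribute `"expected_freq"`.
#' @export
#' @examples
#' L <- cbind(m1 = c(-10, -11, -9), m2 = c(-14, -15, -13))
#' exceedance_probabilities(L, n_draws = 1e4, seed = 1)
exceedance_probabilities <- function(log_evidence, n_draws = 1e5, seed = 1L,
                                     tol = 1e-6) {
  log_evidence <- as.matrix(log_evidence)
  if (!is.numeric(log_evidence) || !all(is.finite(log_evidence)))
    stop("'log_evidence' must be a finite numeric matrix", call. = FALSE)
  n_sub <- nrow(log_evidence); n_mod <- ncol(log_evidence)
  if (n_mod < 2) stop("need at least two models", call. = FALSE)
  model_names <- colnames(log_evidence)
  if (is.null(model_names)) model_names <- paste0("model", seq_len(n_mod))

  alpha0 <- rep(1, n_mod)
  alpha <- alpha0
  for (iter in seq_len(10000)) {
    ## E-step: posterior assignment of each subject to each model
    u <- log_evidence + matrix(digamma(alpha) - digamma(sum(alpha)),
                               n_sub, n_mod, byrow = TRUE)
    u <- exp(u - apply(u, 1, max))
    g <- u / rowSums(u)
    alpha_new <- alpha0 + colSums(g)
    if (max(abs(alpha_new - alpha)) < tol) {
      alpha <- alpha_new
      break
    }
    alpha <- alpha_new
  }

  ## quantile-transform sampling keeps the draw for column k a
  ## deterministic function of (U[, k], alpha[k]), so permuting model
  ## columns permutes the result exactly
  set.seed(seed)
  u <- matrix(stats::runif(n_draws * n_mod), nrow = n_draws)
  draws <- matrix(stats::qgamma(u, shape = rep(alpha, each = n_draws)),
                  nrow = n_draws)
  winner <- max.col(draws, ties.method = "first")
  xp <- tabulate(winner, nbins = n_mod) / n_draws
  names(xp) <- model_names
  attr(xp, "alpha") <- stats::setNames(alpha, model_names)
  attr(xp, "expected_freq") <- stats::setNames(alpha / sum(alpha), model_names)
  xp
}

#' Default parameter sampler for model recovery
#'
#' Draws one random generative parameter set: vector weights uniform on
#' \[0, 1.2\], history decay uniform on \[0, 1\], noise coefficient
#' uniform on \[0.05, 0.3\], Encoding-Error slopes uniform on
#' \[0.7, 1.1\] with intercepts near zero.
#'
#' @param model_id `"model1"`, `"model2"` or `"eem"`.
#' @return A `tc_params` object (draws from the RNG in the current state).
#' @export
default_param_sampler <- function(model_id) {
  u <- function(lo, hi) stats::runif(1, lo, hi)
  switch(model_id,
    model1 = model1_params(u(0, 1.2), u(0, 1.2), u(0.05, 0.3)),
    model2 = model2_params(u(0, 1.2), u(0, 1.2), u(0, 1.2), u(0, 1),
                           u(0.05, 0.3)),
    eem = {
      enc <- function() c(u(-0.5, 0.5), u(0.7, 1.1), u(-3, 3), u(0.7, 1.1))
      eem_params(enc(), enc(), u(0.05, 0.3))
    },
    stop("unknown model_id: ", model_id, call. = FALSE))
}

#' Model-recovery confusion matrices
#'
#' Validates the comparison procedure: for each generating model,
#' simulates `n_sims` synthetic subjects on the design with parameters
#' drawn from `param_sampler`, fits every candidate model to each
#' simulated session, and tabulates how often each fitting model wins
#' under AIC and under BIC.  Rows (generating models) sum to 1.  Fully
#' seeded and reproducible.
#'
#' @param design A [design_spec()].
#' @param models Character vector of model ids to simulate and fit.
#' @param n_sims Simulated subjects per generating model.
#' @param param_sampler Function `(model_id) -> tc_params`; defaults to
#'   [default_param_sampler()].
#' @param seed Integer seed.
#' @param n_starts Starts per fit (passed to [fit_mle()]).
#' @return A list with matrices `aic` and `bic` (generating rows x
#'   fitting columns) and `n_failures`, the count of simulations dropped
#'   because every candidate fit failed.
#' @export
model_recovery <- function(design, models = c("model1", "model2", "eem"),
                           n_sims = 100L, param_sampler = NULL, seed = 1L,
                           n_starts = 20L) {
  stopifnot(inherits(design, "tc_design"), n_sims >= 1)
  if (is.null(param_sampler)) param_sampler <- default_param_sampler
  n_mod <- length(models)
  conf_aic <- conf_bic <- matrix(0, n_mod, n_mod,
                                 dimnames = list(generating = models,
                                                 fitting = models))
  n_failures <- 0L
  set.seed(seed)
  sub_seeds <- matrix(sample.int(.Machine$integer.max, 3 * n_mod * n_sims),
                      ncol = 3)
  row_i <- 0L
  for (g in seq_along(models)) {
    for (s in seq_len(n_sims)) {
      row_i <- row_i + 1L
      set.seed(sub_seeds[row_i, 1])
      params <- param_sampler(models[g])
      sess <- build_session(design, sprintf("rec_%s_%03d", models[g], s),
                            seed = sub_seeds[row_i, 2])
      sess <- simulate_responses(sess, params, seed = sub_seeds[row_i, 3])
      aics <- bics <- rep(NA_real_, n_mod)
      for (f in seq_along(models)) {
        fit <- tryCatch(
          fit_mle(sess, models[f], n_starts = n_starts,
                  seed = sub_seeds[row_i, 1] %% 1000003L + f),
          error = function(e) NULL)
        if (!is.null(fit)) {
          aics[f] <- aic(fit$log_likelihood, fit$k_params)
          bics[f] <- bic(fit$log_likelihood, fit$k_params, fit$n_trials)
        }
      }
      if (all(is.na(aics))) {
        n_failures <- n_failures + 1L
        next
      }
      conf_aic[g, which.min(aics)] <- conf_aic[g, which.min(aics)] + 1
      conf_bic[g, which.min(bics)] <- conf_bic[g, which.min(bics)] + 1
    }
  }
  list(aic = conf_aic / rowSums(conf_aic),
       bic = conf_bic / rowSums(conf_bic),
       n_failures = n_failures)
}

#' Best-fit counts per model
#'
#' For each criterion (log-likelihood, AIC, BIC), counts the subjects for
#' which each model is strictly best.  Exact ties are reported in a
#' separate `ties` column, never assigned to a model.
#'
#' @param table A [comparison_table()] data.frame.
#' @return A data.frame with rows LL / AIC / BIC and one count column per
#'   model plus `ties`.
#' @export
best_fit_counts <- function(table) {
  stopifnot(is.data.frame(table),
            all(c("subject_id", "model_id", "log_likelihood", "AIC", "BIC")
                %in% names(table)))
  models <- sort(unique(table$model_id))
  subjects <- unique(table$subject_id)
  crit <- list(LL = function(d) d$model_id[d$log_likelihood ==
                                             max(d$log_likelihood)],
               AIC = function(d) d$model_id[d$AIC == min(d$AIC)],
               BIC = function(d) d$model_id[d$BIC == min(d$BIC)])
  out <- data.frame(criterion = names(crit), stringsAsFactors = FALSE)
  for (m in models) out[[m]] <- 0L
  out$ties <- 0L
  for (ci in seq_along(crit)) {
    for (s in subjects) {
      d <- table[table$subject_id == s, , drop = FALSE]
      best <- crit[[ci]](d)
      if (length(best) == 1) out[ci, best] <- out[ci, best] + 1L
      else out$ties[ci] <- out$ties[ci] + 1L
    }
  }
  out
}
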