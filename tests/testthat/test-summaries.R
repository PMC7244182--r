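test_that("subject summaries aggregate per-trial errors correctly", {
  d <- design_spec("exp1")
  s <- simulate_responses(build_session(d, "s", seed = 1),
                          model1_params(1, 1, 0), seed = 2)
  ss <- subject_summary(s)
  expect_equal(ss$angle_error_mean, 0, tolerance = 1e-9)
  expect_equal(ss$distance_error_mean, 1, tolerance = 1e-12)
  expect_equal(ss$position_error_mean, 0, tolerance = 1e-9)
  expect_equal(nrow(ss$by_template), 7)

  s87 <- simulate_responses(build_session(d, "s", seed = 1),
                            model1_params(0.87, 0.87, 0), seed = 2)
  expect_equal(subject_summary(s87)$distance_error_mean, 0.87,
               tolerance = 1e-12)

  ## symmetric +/- angular errors cancel in the circular mean
  w <- walk_template(triangle_template("eq", c(60, 60, 60), "left",
                                       side_C = 10))
  tr <- data.frame(trial_index = 1:2, template_label = "eq",
                   handedness = "left",
                   xA_x = w$xA[1], xA_y = w$xA[2],
                   xB_x = w$xB[1], xB_y = w$xB[2],
                   xD_x = c(rot2(w$xC, 10)[1], rot2(w$xC, -10)[1]),
                   xD_y = c(rot2(w$xC, 10)[2], rot2(w$xC, -10)[2]))
  s2 <- new_session("p", "custom", tr)
  expect_equal(subject_summary(s2)$angle_error_mean, 0, tolerance = 1e-9)
})

test_that("summaries are invariant to per-trial frame rotation", {
  s <- sim_exp1_session(model1_params(0.4, 0.9, 0.1), seed = 5)
  base <- subject_summary(s)
  sr <- s
  set.seed(6)
  th <- runif(nrow(s$trials), -180, 180)  # a different rotation per trial
  for (i in seq_len(nrow(s$trials))) {
    for (cols in list(c("xA_x", "xA_y"), c("xB_x", "xB_y"),
                      c("xD_x", "xD_y"))) {
      v <- rot2(c(s$trials[[cols[1]]][i], s$trials[[cols[2]]][i]), th[i])
      sr$trials[[cols[1]]][i] <- v[1]; sr$trials[[cols[2]]][i] <- v[2]
    }
  }
  rot <- subject_summary(sr)
  expect_equal(rot$angle_error_mean, base$angle_error_mean, tolerance = 1e-9)
  expect_equal(rot$distance_error_mean, base$distance_error_mean,
               tolerance = 1e-9)
  expect_equal(rot$position_error_mean, base$position_error_mean,
               tolerance = 1e-9)
})

test_that("homing regression recovers exact and noisy linear relations", {
  d2 <- design_spec("exp2")
  s <- simulate_responses(build_session(d2, "s", seed = 1),
                          model1_params(1, 1, 0), seed = 2)
  expect_equal(suppressWarnings(homing_regression(s))$slope, 1,
               tolerance = 1e-9)
  s87 <- simulate_responses(build_session(d2, "s", seed = 1),
                            model1_params(0.87, 0.87, 0), seed = 2)
  expect_equal(suppressWarnings(homing_regression(s87))$slope, 0.87,
               tolerance = 1e-9)

  ## noisy data against the closed-form normal-equations oracle
  sn <- simulate_responses(build_session(d2, "s", seed = 3),
                           model1_params(0.8, 0.9, 0.1), seed = 4)
  err <- trial_errors(sn)
  slope_oracle <- sum((err$mag_C - mean(err$mag_C)) *
                        (err$mag_D - mean(err$mag_D))) /
    sum((err$mag_C - mean(err$mag_C))^2)
  expect_equal(homing_regression(sn)$slope, slope_oracle, tolerance = 1e-9)

  ## constant |xC| is degenerate
  s1 <- sim_exp1_session(seed = 5)  # all templates share side C = 10
  expect_error(homing_regression(s1), "degenerate")
})

test_that("response spread grows with return distance as the noise dictates", {
  d2 <- design_spec("exp2")
  ## noiseless: all group SDs zero, slope zero
  s0 <- simulate_responses(build_session(d2, "s", seed = 1),
                           model1_params(0.9, 0.9, 0), seed = 2)
  sv0 <- sd_vs_distance(s0)
  expect_equal(sv0$groups$sd_D, rep(0, 5), tolerance = 1e-9)
  expect_equal(sv0$slope, 0, tolerance = 1e-9)

  ## Weber-noise simulation: fitted slope close to the per-group
  ## prediction sd(|xD|) ~ sigma_tilde * sqrt(|xA|^2+|xB|^2)
  sessions <- lapply(1:40, function(i)
    simulate_responses(build_session(d2, paste0("s", i), seed = 100 + i),
                       model1_params(1, 1, 0.1), seed = 200 + i))
  sv <- sd_vs_distance(sessions)
  tpls <- exp2_templates()
  pred <- vapply(tpls, function(t) {
    w <- walk_template(t)
    noise_scale(0.1, w$xA, w$xB)
  }, numeric(1))
  magC <- vapply(tpls, function(t) t$side_C, numeric(1))
  pred_slope <- stats::coef(stats::lm(pred ~ magC))[2]
  expect_equal(sv$slope, unname(pred_slope), tolerance = 0.1)
})

test_that("logarithmic systematic-error fit solves a constructed inverse problem", {
  ## constant systematic error across sizes: log-slope 0
  d2 <- design_spec("exp2")
  s87 <- simulate_responses(build_session(d2, "s", seed = 1),
                            model1_params(0.87, 0.87, 0), seed = 2)
  lf0 <- suppressWarnings(systematic_error_log_fit(s87))
  expect_equal(lf0$slope, 0, tolerance = 1e-9)
  expect_equal(lf0$intercept, 0.13, tolerance = 1e-9)

  ## construct responses with error = a + b*log(d) exactly, recover (a, b)
  a <- 0.02; b <- 0.05
  s <- build_session(d2, "s", seed = 3)
  m <- tricomp:::.session_mats(s)
  magC <- sqrt(rowSums(m$xC^2))
  scale <- 1 - (a + b * log(magC))
  s$trials$xD_x <- m$xC[, 1] * scale
  s$trials$xD_y <- m$xC[, 2] * scale
  lf <- suppressWarnings(systematic_error_log_fit(s))
  expect_equal(lf$intercept, a, tolerance = 1e-9)
  expect_equal(lf$slope, b, tolerance = 1e-9)
  expect_equal(lf$r_squared, 1, tolerance = 1e-9)
})
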