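test_that("shape-varying templates all share the 10 m unguided side", {
  tpls <- exp1_templates()
  expect_length(tpls, 7)
  expect_true(all(vapply(tpls, function(t) t$side_C, numeric(1)) == 10))
  expect_true(all(c("60-60-60", "30-120-30", "45-90-45") %in% names(tpls)))
  expect_equal(tpls[["60-60-60"]]$side_A, 10)
  expect_equal(tpls[["30-120-30"]]$side_A, 10 * sin(pi / 6) / sin(2 * pi / 3),
               tolerance = 1e-12)
  expect_equal(round(tpls[["30-120-30"]]$side_A, 4), 5.7735)
  expect_equal(round(tpls[["45-90-45"]]$side_A, 4), 7.0711)
  ## walking each template returns to the origin at distance 10
  for (tpl in tpls) {
    w <- walk_template(tpl)
    expect_equal(sqrt(sum(w$xC^2)), 10, tolerance = 1e-9)
  }
  expect_error(exp1_templates(list(bad = c(60, 60, 70))), "sum to 180")
})

test_that("size-varying templates are similar triangles at the set perimeters", {
  tpls <- exp2_templates()
  perims <- vapply(tpls, function(t) t$side_A + t$side_B + t$side_C,
                   numeric(1))
  expect_equal(unname(perims), c(15.19, 25.32, 126.60, 253.20, 506.42),
               tolerance = 1e-6)
  ## identical angles, sides scale with perimeter
  for (t in tpls) expect_equal(t$angles, tpls[[1]]$angles)
  ratios <- vapply(tpls, function(t) t$side_A, numeric(1)) /
    tpls[[1]]$side_A
  expect_equal(unname(ratios), unname(perims / perims[1]), tolerance = 1e-9)
  expect_warning(exp2_templates(angles = c(60, 60, 60)), "scalene")
  expect_error(exp2_templates(angles = c(60, 60, 60), strict = TRUE),
               "scalene")
})

test_that("built sessions honour trial counts, balance and determinism", {
  s1 <- build_session(design_spec("exp1"), "a", seed = 5)
  expect_equal(nrow(s1$trials), 28)
  expect_equal(sum(s1$trials$handedness == "left"), 14)
  expect_equal(sum(s1$trials$handedness == "right"), 14)
  expect_equal(as.integer(table(s1$trials$template_label)), rep(4L, 7))
  expect_identical(s1$trials, build_session(design_spec("exp1"), "a",
                                            seed = 5)$trials)
  expect_false(identical(s1$trials$template_label,
                         build_session(design_spec("exp1"), "a",
                                       seed = 6)$trials$template_label))

  s2 <- build_session(design_spec("exp2"), "b", seed = 5)
  counts <- table(s2$trials$template_label)
  expect_equal(sort(as.integer(counts), decreasing = TRUE),
               c(10L, 10L, 8L, 4L, 2L))
  expect_equal(sum(s2$trials$handedness == "left"), 17)

  ## closure invariant on every constructed trial
  tr <- s2$trials
  for (i in seq_len(nrow(tr))) {
    xA <- c(tr$xA_x[i], tr$xA_y[i]); xB <- c(tr$xB_x[i], tr$xB_y[i])
    xC <- ideal_homing_vector(xA, xB)
    expect_equal(xA + xB + xC, c(0, 0), tolerance = 1e-9)
  }
})

test_that("noiseless equal-weight simulation scales the homing vector", {
  d <- design_spec("exp1")
  s <- simulate_responses(build_session(d, "s", seed = 1),
                          model1_params(1, 1, 0), seed = 2)
  e <- trial_errors(s)
  expect_equal(e$distance_error, rep(1, 28))
  expect_equal(e$angle_error, rep(0, 28))

  s87 <- simulate_responses(build_session(d, "s", seed = 1),
                            model1_params(0.87, 0.87, 0), seed = 2)
  e87 <- trial_errors(s87)
  expect_equal(e87$distance_error, rep(0.87, 28), tolerance = 1e-12)
  expect_equal(e87$angle_error, rep(0, 28), tolerance = 1e-9)

  ## direction-preserving scaling holds for any common weight
  for (b in c(0.4, 1.3)) {
    sb <- simulate_responses(build_session(d, "s", seed = 3),
                             model1_params(b, b, 0), seed = 4)
    expect_equal(trial_errors(sb)$distance_error, rep(b, 28),
                 tolerance = 1e-12)
  }
})

test_that("simulated noise follows the Weber scale", {
  ## 10^4 replicate simulations of a single trial
  w <- walk_template(triangle_template("eq", c(60, 60, 60), "left",
                                       side_C = 10))
  base <- one_trial_session(w$xA, w$xB)
  sigma_expected <- noise_scale(0.1, w$xA, w$xB)
  n <- 1e4
  resp <- matrix(NA_real_, n, 2)
  p <- model1_params(1, 1, 0.1)
  for (i in seq_len(n)) {
    s <- simulate_responses(base, p, seed = i)
    resp[i, ] <- c(s$trials$xD_x, s$trials$xD_y)
  }
  expect_equal(mean(resp[, 1]), w$xC[1], tolerance = 4 * sigma_expected / sqrt(n) / abs(w$xC[1]))
  expect_equal(sd(resp[, 1]), sigma_expected, tolerance = 0.05)
  expect_equal(sd(resp[, 2]), sigma_expected, tolerance = 0.05)

  ## doubling the template doubles the response SD (same seeds, same draws)
  w2 <- list(xA = 2 * w$xA, xB = 2 * w$xB)
  base2 <- one_trial_session(w2$xA, w2$xB)
  resp2 <- matrix(NA_real_, 500, 2)
  resp1 <- matrix(NA_real_, 500, 2)
  for (i in 1:500) {
    s1 <- simulate_responses(base, p, seed = i)
    s2 <- simulate_responses(base2, p, seed = i)
    resp1[i, ] <- c(s1$trials$xD_x, s1$trials$xD_y)
    resp2[i, ] <- c(s2$trials$xD_x, s2$trials$xD_y)
  }
  dev1 <- resp1 - matrix(w$xC, 500, 2, byrow = TRUE)
  dev2 <- resp2 - matrix(2 * w$xC, 500, 2, byrow = TRUE)
  expect_equal(dev2, 2 * dev1, tolerance = 1e-12)
})

test_that("session generation is reproducible to the byte", {
  d <- design_spec("exp2")
  p <- model2_params(0.5, 0.5, 0.1, 0.5, 0.1)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_trial_table(simulate_responses(build_session(d, "s", seed = 9), p,
                                       seed = 10), f1)
  write_trial_table(simulate_responses(build_session(d, "s", seed = 9), p,
                                       seed = 10), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})
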