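test_that("ideal homing vector closes the triangle", {
  expect_equal(ideal_homing_vector(c(0, 0), c(0, 0)), c(0, 0))
  ## equilateral, 10 m sides
  xC <- ideal_homing_vector(c(10, 0), c(-5, 10 * sin(pi / 3)))
  expect_equal(xC, c(-5, -10 * sin(pi / 3)))
  expect_equal(sqrt(sum(xC^2)), 10)
  ## right isosceles
  xC2 <- ideal_homing_vector(c(10 / sqrt(2), 0), c(0, 10 / sqrt(2)))
  expect_equal(xC2, -c(10 / sqrt(2), 10 / sqrt(2)))
  expect_equal(sqrt(sum(xC2^2)), 10)
  expect_error(ideal_homing_vector(c(NA, 0), c(0, 0)), "finite")
})

test_that("template construction validates angles, sides and law of sines", {
  tpl <- triangle_template("30-120-30", c(30, 120, 30), "left", side_C = 10)
  expect_equal(tpl$side_A, 10 * sin(pi / 6) / sin(2 * pi / 3))
  expect_equal(tpl$side_B, tpl$side_A)
  expect_error(triangle_template("bad", c(60, 60, 61), "left", side_C = 10),
               "sum to 180")
  expect_error(triangle_template("bad", c(60, 60, 60), "left",
                                 sides = c(10, 10, 5)), "law of sines")
  expect_error(triangle_template("bad", c(60, 60, 60), "left"), "required")
})

test_that("walk_template lays out the guided path with the exterior turn", {
  eq <- triangle_template("eq", c(60, 60, 60), "left", side_C = 10)
  w <- walk_template(eq, 0)
  expect_equal(w$xA, c(10, 0))
  expect_equal(w$xB, c(-5, 10 * sin(pi / 3)))
  expect_equal(sqrt(sum(w$xC^2)), 10)

  iso <- triangle_template("iso", c(30, 120, 30), "left", side_C = 10)
  wi <- walk_template(iso, 0)
  ## 60 degree exterior turn: xB = side_B * (cos 60, sin 60)
  expect_equal(wi$xB, iso$side_B * c(cos(pi / 3), sin(pi / 3)))
  expect_equal(sqrt(sum(wi$xC^2)), 10)

  ## right-handed mirror: xC reflected across the start-heading axis
  wr <- walk_template(mirror_template(iso), 0)
  expect_equal(wr$xC, wi$xC * c(1, -1))

  ## magnitudes reproduce the side lengths for arbitrary templates/headings
  for (ang in list(c(20, 135, 25), c(50, 70, 60), c(45, 90, 45))) {
    tpl <- triangle_template("t", ang, "right", side_C = 7.3)
    w2 <- walk_template(tpl, start_heading = 37.5)
    expect_equal(sqrt(sum(w2$xA^2)), tpl$side_A, tolerance = 1e-12)
    expect_equal(sqrt(sum(w2$xB^2)), tpl$side_B, tolerance = 1e-12)
    expect_equal(sqrt(sum(w2$xC^2)), tpl$side_C, tolerance = 1e-12)
    expect_equal(w2$xA + w2$xB + w2$xC, c(0, 0), tolerance = 1e-9)
  }
})

test_that("angle error is signed positive past the required turn", {
  eq <- walk_template(triangle_template("eq", c(60, 60, 60), "left",
                                        side_C = 10))
  expect_equal(angle_error(eq$xA, eq$xB, eq$xC), 0)
  expect_equal(angle_error(eq$xA, eq$xB, 2.5 * eq$xC), 0)  # magnitude-free
  ## left-handed required turn is CCW: rotating further CCW = overshoot
  expect_equal(angle_error(eq$xA, eq$xB, rot2(eq$xC, 10)), 10)
  expect_equal(angle_error(eq$xA, eq$xB, rot2(eq$xC, -10)), -10)
  ## right-handed: overshoot is further CW
  wr <- walk_template(triangle_template("eq", c(60, 60, 60), "right",
                                        side_C = 10))
  expect_equal(angle_error(wr$xA, wr$xB, rot2(wr$xC, -10)), 10)
  expect_equal(angle_error(wr$xA, wr$xB, rot2(wr$xC, 10)), -10)
  expect_error(angle_error(eq$xA, eq$xB, c(0, 0)), "zero magnitude")
})

test_that("distance and position errors follow their definitions", {
  w <- walk_template(triangle_template("eq", c(60, 60, 60), "left",
                                       side_C = 10))
  expect_equal(distance_error(w$xA, w$xB, w$xC), 1.0)
  expect_equal(distance_error(w$xA, w$xB, 0.5 * w$xC), 0.5)
  expect_equal(distance_error(w$xA, w$xB, 0.87 * w$xC), 0.87)
  expect_equal(position_error(w$xA, w$xB, w$xC), 0)
  expect_equal(position_error(w$xA, w$xB, c(0, 0) + .Machine$double.eps),
               sqrt(sum(w$xC^2)), tolerance = 1e-9)
  expect_equal(position_error(w$xA, w$xB, w$xC + c(3, 4)), 5)
})

test_that("error metrics are invariant to common rotation and mirror", {
  set.seed(7)
  for (i in 1:20) {
    ang <- c(20, 40, 120) + 0  # fixed shape, random rotations/responses
    tpl <- triangle_template("t", ang, sample(c("left", "right"), 1),
                             side_C = runif(1, 2, 40))
    w <- walk_template(tpl, runif(1, -180, 180))
    xD <- rot2(w$xC * runif(1, 0.5, 1.5), runif(1, -40, 40))
    theta <- runif(1, -180, 180)
    expect_equal(angle_error(rot2(w$xA, theta), rot2(w$xB, theta),
                             rot2(xD, theta)),
                 angle_error(w$xA, w$xB, xD), tolerance = 1e-9)
    expect_equal(distance_error(rot2(w$xA, theta), rot2(w$xB, theta),
                                rot2(xD, theta)),
                 distance_error(w$xA, w$xB, xD), tolerance = 1e-9)
    expect_equal(position_error(rot2(w$xA, theta), rot2(w$xB, theta),
                                rot2(xD, theta)),
                 position_error(w$xA, w$xB, xD), tolerance = 1e-9)
    ## mirror across x axis flips handedness, leaves all metrics unchanged
    mir <- function(v) v * c(1, -1)
    expect_equal(angle_error(mir(w$xA), mir(w$xB), mir(xD)),
                 angle_error(w$xA, w$xB, xD), tolerance = 1e-9)
    expect_equal(distance_error(mir(w$xA), mir(w$xB), mir(xD)),
                 distance_error(w$xA, w$xB, xD), tolerance = 1e-9)
  }
})

test_that("circular mean uses the resultant vector and wraps correctly", {
  expect_equal(circular_mean(c(30, 30, 30)), 30)
  expect_equal(circular_mean(c(0, 90)), 45)
  expect_equal(circular_mean(c(170, -170)), 180)
  expect_equal(circular_mean(c(10, -10)), 0)
  expect_error(circular_mean(c(90, -90)), "undefined")
  expect_error(circular_mean(numeric(0)), "non-empty")
  expect_equal(wrap_angle(c(190, -180, 540, 180)), c(-170, 180, 180, 180))
})
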