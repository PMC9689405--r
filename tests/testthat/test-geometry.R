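test_that("reference line passes through both tuberosities with canonical direction", {
  ref <- make_reference_line(c(0, 100), c(200, 100))
  expect_equal(unname(ref$anchor), c(0, 100))
  expect_equal(ref$direction, c(1, 0))

  ref2 <- make_reference_line(c(0, 100), c(200, 110))
  expect_equal(ref2$direction, c(200, 10) / sqrt(200^2 + 10^2), tolerance = 1e-12)
  expect_equal(sqrt(sum(ref2$direction^2)), 1, tolerance = 1e-12)
  ## swapping the points gives the same canonical orientation
  ref3 <- make_reference_line(c(200, 110), c(0, 100))
  expect_equal(ref3$direction, ref2$direction)

  expect_error(make_reference_line(c(50, 50), c(50, 50)), "tuberosity")
})

test_that("signed perpendicular offset is positive superior and matches projection oracle", {
  ref <- make_reference_line(c(0, 100), c(200, 100))
  expect_identical(signed_perpendicular_offset(c(123, 100), ref), 0)
  expect_equal(signed_perpendicular_offset(c(10, 40), ref), 60)
  expect_equal(signed_perpendicular_offset(c(10, 160), ref), -60)

  ref_t <- make_reference_line(c(0, 100), c(200, 110))
  for (p in list(c(100, 80), c(50, 130), c(0, 100), c(180, 20))) {
    expect_equal(signed_perpendicular_offset(p, ref_t),
                 offset_oracle(p, ref_t$anchor, ref_t$direction),
                 tolerance = 1e-12)
  }
})

test_that("circle fit recovers exact circles and rejects degenerate input", {
  cf <- fit_circle_least_squares(rbind(c(1, 0), c(0, 1), c(-1, 0)))
  expect_equal(unname(cf$center), c(0, 0), tolerance = 1e-12)
  expect_equal(cf$radius, 1, tolerance = 1e-12)
  expect_equal(cf$rms_residual, 0, tolerance = 1e-12)

  th <- seq(0, 2 * pi, length.out = 9)[-9]
  pts <- cbind(120 + 55 * cos(th), 340 + 55 * sin(th))
  cf8 <- fit_circle_least_squares(pts)
  expect_equal(unname(cf8$center), c(120, 340), tolerance = 1e-9)
  expect_equal(cf8$radius, 55, tolerance = 1e-9)

  expect_error(fit_circle_least_squares(rbind(c(0, 0), c(1, 1))), "at least 3")
  expect_error(fit_circle_least_squares(cbind(1:10, 2 * (1:10) + 3)), "collinear")
})

test_that("circle fit on noisy points matches brute-force grid-search oracle", {
  set.seed(71)
  for (rep in 1:3) {
    th <- sort(runif(20, 0, 2 * pi))
    r_true <- 50
    cen <- c(200, 300) + runif(2, -20, 20)
    pts <- cbind(cen[1] + (r_true + runif(20, -1, 1)) * cos(th),
                 cen[2] + (r_true + runif(20, -1, 1)) * sin(th))
    cf <- fit_circle_least_squares(pts)
    oracle <- grid_circle_oracle(pts)
    tol <- attr(oracle, "resolution") * 2
    expect_equal(unname(cf$center[1]), oracle[["cx"]], tolerance = tol)
    expect_equal(unname(cf$center[2]), oracle[["cy"]], tolerance = tol)
    expect_equal(cf$radius, oracle[["r"]], tolerance = tol)
  }
})

test_that("LCEA sign convention: positive lateral, zero on the perpendicular", {
  ref <- make_reference_line(c(0, 100), c(200, 100))
  ## sourcil exactly on the superior perpendicular
  expect_equal(compute_lcea(c(100, 100), c(100, 60), ref, "right")$angle_deg, 0)
  ## right hip: 10 px lateral (-x) and 10 px superior -> +45
  expect_equal(compute_lcea(c(100, 100), c(90, 90), ref, "right")$angle_deg, 45)
  ## same displacement read as a left hip is medial -> -45
  expect_equal(compute_lcea(c(100, 100), c(90, 90), ref, "left")$angle_deg, -45)
  ## medial sourcil for the right hip -> negative
  expect_equal(compute_lcea(c(100, 100), c(110, 90), ref, "right")$angle_deg, -45)
  expect_error(compute_lcea(c(100, 100), c(100, 100), ref, "right"), "coincides")
  ## inferior sourcil still yields a value, with a flag
  res <- compute_lcea(c(100, 100), c(90, 110), ref, "right")
  expect_length(res$flags, 1)
  expect_equal(res$angle_deg, 135)
})

test_that("LCEA is invariant to rotating the whole scene", {
  base <- list(cfh = c(100, 100), sourcil = c(88, 87))
  ref0 <- make_reference_line(c(0, 100), c(200, 100))
  a0 <- compute_lcea(base$cfh, base$sourcil, ref0, "right")$angle_deg
  rot <- function(p, deg) {
    R <- matrix(c(cos(deg * pi / 180), sin(deg * pi / 180),
                  -sin(deg * pi / 180), cos(deg * pi / 180)), 2, 2)
    as.vector(R %*% p)
  }
  for (deg in c(-17, 5, 10, 33)) {
    ref_r <- make_reference_line(rot(c(0, 100), deg), rot(c(200, 100), deg))
    a_r <- compute_lcea(rot(base$cfh, deg), rot(base$sourcil, deg), ref_r, "right")$angle_deg
    expect_equal(a_r, a0, tolerance = 1e-9)
  }
})

test_that("AIA sign convention: positive when the roof slopes up laterally", {
  ref <- make_reference_line(c(0, 100), c(200, 100))
  ## equal perpendicular offsets -> flat roof, 0 degrees
  expect_equal(compute_aia(c(100, 90), c(80, 90), ref, "right")$angle_deg, 0)
  ## right hip: lateral sourcil 10 px lateral (-x), 10 px superior -> +45
  expect_equal(compute_aia(c(100, 100), c(90, 90), ref, "right")$angle_deg, 45)
  ## lateral inferior by the same offset -> -45
  expect_equal(compute_aia(c(100, 100), c(90, 110), ref, "right")$angle_deg, -45)
  ## mirrored placement on the left side
  expect_equal(compute_aia(c(100, 100), c(110, 90), ref, "left")$angle_deg, 45)
  expect_error(compute_aia(c(100, 100), c(100, 100), ref, "right"), "coincide")
})

test_that("polygon width profile: rectangle has constant width, 13 lines", {
  ref <- make_reference_line(c(0, 0), c(10, 0))
  rect <- rbind(c(20, 50), c(80, 50), c(80, 80), c(20, 80))
  wp <- polygon_width_profile(rect, ref)
  expect_length(wp$widths, 13)
  expect_equal(wp$widths, rep(60, 13))
  expect_equal(wp$max_width, 60)
  ## offsets run superior -> inferior
  expect_true(all(diff(wp$offsets) < 0))
})

test_that("FOI is the right/left max-width ratio with guarded errors", {
  expect_equal(compute_foi(60, 60), 1.0)
  expect_equal(compute_foi(48, 60), 0.8)
  expect_error(compute_foi(60, 0), "zero|positive")
  expect_error(compute_foi(0, 60), "positive")
})

test_that("measure_hips round-trips phantom truth and is deterministic", {
  spec <- phantom_spec(true_lcea_right = 25.4, true_aia_right = 4.7,
                       true_lcea_left = 31.2, true_aia_left = -3.5,
                       true_foi = 0.93)
  m <- measure_hips(landmarks_from_truth(spec))
  expect_equal(unname(m$lcea["right"]), 25.4, tolerance = 1e-9)
  expect_equal(unname(m$aia["right"]), 4.7, tolerance = 1e-9)
  expect_equal(unname(m$lcea["left"]), 31.2, tolerance = 1e-9)
  expect_equal(unname(m$aia["left"]), -3.5, tolerance = 1e-9)
  expect_equal(m$foi, 0.93, tolerance = 1e-9)

  ## symmetric phantom -> FOI exactly 1
  msym <- measure_hips(landmarks_from_truth(phantom_spec(true_foi = 1)))
  expect_equal(msym$foi, 1, tolerance = 1e-12)

  ## identical input -> bit-identical serialized output
  lm <- landmarks_from_truth(spec)
  expect_identical(serialize(measure_hips(lm), NULL),
                   serialize(measure_hips(lm), NULL))
})

test_that("angles are invariant to rigid motion and uniform scale; widths scale", {
  lm <- landmarks_from_truth(phantom_spec(true_lcea_right = 18.2,
                                          true_aia_left = 12.1, true_foi = 1.07))
  m0 <- measure_hips(lm)
  set.seed(5)
  for (i in 1:4) {
    lm_t <- transform_landmarks(lm, deg = runif(1, -25, 25),
                                center = runif(2, 0, 1024),
                                shift = runif(2, -300, 300))
    m1 <- measure_hips(lm_t)
    expect_equal(m1$lcea, m0$lcea, tolerance = 1e-9)
    expect_equal(m1$aia, m0$aia, tolerance = 1e-9)
    expect_equal(m1$foi, m0$foi, tolerance = 1e-12)
  }
  lm_s <- transform_landmarks(lm, scale = 2.5)
  m_s <- measure_hips(lm_s)
  expect_equal(m_s$lcea, m0$lcea, tolerance = 1e-9)
  expect_equal(m_s$aia, m0$aia, tolerance = 1e-9)
  expect_equal(m_s$foi, m0$foi, tolerance = 1e-12)
  expect_equal(m_s$foramen_width, 2.5 * m0$foramen_width, tolerance = 1e-9)
})

test_that("mirroring the scene swaps sides exactly and inverts FOI", {
  lm <- landmarks_from_truth(phantom_spec(true_lcea_right = 20.3,
                                          true_lcea_left = 33.0,
                                          true_aia_right = 8.0,
                                          true_aia_left = -2.0,
                                          true_foi = 0.9))
  m0 <- measure_hips(lm)
  axis <- mean(c(lm$tuberosity_inferior_right[1], lm$tuberosity_inferior_left[1]))
  m1 <- measure_hips(mirror_landmarks(lm, axis))
  expect_equal(unname(m1$lcea["right"]), unname(m0$lcea["left"]), tolerance = 1e-9)
  expect_equal(unname(m1$lcea["left"]), unname(m0$lcea["right"]), tolerance = 1e-9)
  expect_equal(unname(m1$aia["right"]), unname(m0$aia["left"]), tolerance = 1e-9)
  expect_equal(unname(m1$aia["left"]), unname(m0$aia["right"]), tolerance = 1e-9)
  expect_equal(m1$foi, 1 / m0$foi, tolerance = 1e-12)
})

test_that("missing mandatory landmarks are reported by name; one-sided failure spares the other side", {
  lm <- landmarks_from_truth(phantom_spec())
  lm_no_tub <- lm
  lm_no_tub$tuberosity_inferior_left <- NULL
  expect_error(measure_hips(lm_no_tub), "tuberosity_inferior_left")
  lm$sourcil_lateral_right <- NULL
  m <- measure_hips(lm)
  expect_true(is.na(m$lcea["right"]))
  expect_false(is.na(m$lcea["left"]))
  expect_match(paste(m$flags, collapse = " "), "sourcil_lateral_right")
})
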