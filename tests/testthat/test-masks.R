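blank <- function(nr = 200, nc = 200) matrix(0L, nr, nc)

test_that("tuberosity extraction picks the most inferior pixel per side with tie rules", {
  m <- blank()
  m[118:120, 40:42] <- 1L    # image-left blob, lowest row 120
  m[120:122, 160:162] <- 1L  # image-right blob, lowest row 122
  tp <- extract_tuberosity_points(m, midline_col = 100)
  ## patient right displays on image left
  expect_equal(unname(tp$right), c(42, 120))   # row tie -> most medial (closest to midline)
  expect_equal(unname(tp$left), c(160, 122))

  flat <- blank()
  flat[130, 30:60] <- 1L     # flat bottom: whole row ties
  flat[140, 150] <- 1L
  tpf <- extract_tuberosity_points(flat, midline_col = 100)
  expect_equal(unname(tpf$right), c(60, 130)) # most medial of the tied row

  empty_side <- blank(); empty_side[50, 150] <- 1L
  expect_error(extract_tuberosity_points(empty_side, 100), "patient-right")
})

test_that("head contour from a rasterized disc supports accurate circle fits", {
  m <- blank()
  xs <- col(m); ys <- row(m)
  m[(xs - 100)^2 + (ys - 100)^2 <= 40^2] <- 1L
  ct <- extract_head_contour(m)
  expect_equal(nrow(ct), 64)
  cf <- fit_circle_least_squares(ct)
  expect_equal(unname(cf$center), c(100, 100), tolerance = 0.5)
  expect_equal(cf$radius, 40, tolerance = 0.5)

  ## n_points = 8 gives roughly equiangular samples
  ct8 <- extract_head_contour(m, n_points = 8)
  ang <- sort(atan2(ct8[, 2] - 100, ct8[, 1] - 100))
  gaps <- diff(c(ang, ang[1] + 2 * pi))
  expect_true(all(gaps > 0.3) && all(gaps < 1.3))  # ~pi/4 each

  ## second small component is ignored with a flag
  m2 <- m; m2[5:8, 5:8] <- 1L
  ct2 <- extract_head_contour(m2)
  expect_match(attr(ct2, "flags"), "largest")
  expect_equal(fit_circle_least_squares(ct2)$radius, 40, tolerance = 0.5)

  expect_error(extract_head_contour(blank()), "empty")
})

test_that("sourcil extents are extremal along the reference direction", {
  ref <- make_reference_line(c(20, 180), c(180, 180))
  m <- blank()
  m[90, 80:120] <- 1L   # horizontal 1-px arc, right side of a midline at 160
  ext <- extract_sourcil_extents(m, ref, side = "right")
  expect_equal(unname(ext$medial), c(120, 90))
  expect_equal(unname(ext$lateral), c(80, 90))

  ## left side swaps the roles
  extl <- extract_sourcil_extents(m, ref, side = "left")
  expect_equal(unname(extl$medial), c(80, 90))
  expect_equal(unname(extl$lateral), c(120, 90))

  single <- blank(); single[90, 100] <- 1L
  exts <- extract_sourcil_extents(single, ref, "right")
  expect_match(exts$flags, "single-pixel")
  expect_error(extract_sourcil_extents(blank(), ref, "right"), "empty")
})

test_that("sourcil extraction is tilt-safe: rotated scene picks the same anatomy", {
  ## rasterized phantom with a rotated scene: extracted sourcil pixels stay
  ## within ~1 px of the rotated true endpoints
  spec <- phantom_spec(canvas = c(768L, 768L), rotation_deg = 5)
  ms <- rasterize_phantom(spec)
  lm_true <- landmarks_from_truth(spec)
  tubs <- extract_tuberosity_points(ms$masks$pelvis, spec$midline_x)
  ref <- make_reference_line(tubs$right, tubs$left)
  for (side in c("right", "left")) {
    ext <- extract_sourcil_extents(ms$masks[[paste0("sourcil_", side)]], ref, side)
    expect_lt(sqrt(sum((ext$medial - lm_true[[paste0("sourcil_medial_", side)]])^2)), 1.6)
    expect_lt(sqrt(sum((ext$lateral - lm_true[[paste0("sourcil_lateral_", side)]])^2)), 1.6)
  }
})

test_that("foramen width profile: rectangle, analytic ellipse, rotation", {
  ref <- make_reference_line(c(10, 190), c(190, 190))
  rect <- blank()
  rect[60:89, 70:129] <- 1L           # 60 wide x 30 tall
  wp <- foramen_width_profile(rect, ref)
  expect_length(wp$widths, 13)
  expect_equal(wp$widths, rep(60, 13), tolerance = 0.02)
  expect_equal(wp$max_width, 60, tolerance = 0.02)

  ## ellipse semi-axes a = 40 (horizontal), b = 25
  ell <- blank()
  xs <- col(ell); ys <- row(ell)
  inside <- ((xs - 100) / 40)^2 + ((ys - 100) / 25)^2 <= 1
  ell[inside] <- 1L
  wpe <- foramen_width_profile(ell, ref)
  expect_equal(wpe$max_width, 80, tolerance = 1)
  b_eff <- (max(wpe$offsets) - min(wpe$offsets)) / 2
  mid_v <- mean(range(wpe$offsets))
  for (i in seq_along(wpe$offsets)) {
    expect_equal(wpe$widths[i],
                 ellipse_width_oracle(40, b_eff, wpe$offsets[i] - mid_v),
                 tolerance = 1.5)
  }

  ## rotating scene and reference by 10 degrees preserves the max width
  spec0 <- phantom_spec(canvas = c(768L, 768L))
  spec10 <- phantom_spec(canvas = c(768L, 768L), rotation_deg = 10)
  get_w <- function(spec) {
    ms <- rasterize_phantom(spec)
    tubs <- extract_tuberosity_points(ms$masks$pelvis, spec$midline_x)
    ref <- make_reference_line(tubs$right, tubs$left)
    foramen_width_profile(ms$masks$foramen_right, ref)$max_width
  }
  expect_equal(get_w(spec10), get_w(spec0), tolerance = 1.5)

  expect_error(foramen_width_profile(blank(), ref), "empty")
})

test_that("dilating a foramen mask never decreases the max width", {
  ref <- make_reference_line(c(10, 190), c(190, 190))
  ell <- blank()
  xs <- col(ell); ys <- row(ell)
  ell[((xs - 100) / 35)^2 + ((ys - 100) / 20)^2 <= 1] <- 1L
  w0 <- foramen_width_profile(ell, ref)$max_width
  dil <- ell
  dil[((xs - 100) / 38)^2 + ((ys - 100) / 22)^2 <= 1] <- 1L
  expect_gte(foramen_width_profile(dil, ref)$max_width, w0)
})

test_that("extraction is invariant to padding the canvas", {
  spec <- phantom_spec(canvas = c(512L, 512L))
  ms <- rasterize_phantom(spec)
  pad <- function(m, extra = 40L) {
    out <- matrix(0L, nrow(m) + extra, ncol(m) + extra)
    out[seq_len(nrow(m)), seq_len(ncol(m))] <- m
    out
  }
  ms_pad <- mask_set(lapply(ms$masks, pad), image_id = ms$image_id)
  m0 <- measure_hips_from_masks(ms)
  m1 <- measure_hips_from_masks(ms_pad)
  expect_equal(m1$lcea, m0$lcea, tolerance = 1e-9)
  expect_equal(m1$aia, m0$aia, tolerance = 1e-9)
  expect_equal(m1$foi, m0$foi, tolerance = 1e-12)
})

test_that("mask round trip through PNG files is lossless", {
  spec <- phantom_spec(canvas = c(256L, 256L))
  ms <- rasterize_phantom(spec)
  dir <- withr::local_tempdir()
  write_mask_set(ms, dir)
  ms2 <- read_mask_set(dir, ms$image_id)
  expect_setequal(names(ms2$masks), names(ms$masks))
  for (nm in names(ms$masks))
    expect_identical(ms2$masks[[nm]], ms$masks[[nm]])
})
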