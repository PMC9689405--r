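## Evaluate expr with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Specify a synthetic pelvic phantom
#'
#' Encodes the ground-truth measurement values (LCEA and AIA per side, FOI)
#' together with the scene geometry from which landmarks and masks are
#' synthesized by closed-form inverse geometry. Geometric defaults scale with
#' the canvas and place the structures in anatomically plausible positions on
#' an AP radiograph (patient right on image left).
#'
#' @param true_lcea_right,true_lcea_left True lateral center edge angles
#'   (degrees, |angle| < 90).
#' @param true_aia_right,true_aia_left True acetabular index angles (degrees).
#' @param true_foi True foramen obturator index (> 0).
#' @param canvas `c(rows, cols)` of the synthetic image.
#' @param head_radius Femoral head radius in pixels.
#' @param rotation_deg Rigid rotation of the whole scene about the canvas
#'   center (emulates radiograph tilt; measurements are invariant to it).
#' @param noise_px Amplitude (pixels) of smooth boundary jitter applied when
#'   rasterizing (0 = clean shapes).
#' @param seed Integer seed controlling the boundary jitter.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(true_lcea_right = 25.4, true_lcea_left = 25.9,
                         true_aia_right = 4.7, true_aia_left = 4.0,
                         true_foi = 1.0,
                         canvas = c(1024L, 1024L),
                         head_radius = 0.095 * canvas[2],
                         rotation_deg = 0,
                         noise_px = 0,
                         seed = 1L) {
  stopifnot(length(canvas) == 2L, all(canvas >= 64))
  if (head_radius <= 0) stop("head_radius must be positive")
  if (true_foi <= 0) stop("true_foi must be positive")
  for (a in c(true_lcea_right, true_lcea_left))
    if (!is.finite(a) || abs(a) >= 90)
      stop("true LCEA must satisfy |LCEA| < 90 degrees (lateral sourcil superior to CFH)")
  for (a in c(true_aia_right, true_aia_left))
    if (!is.finite(a) || abs(a) >= 90)
      stop("true AIA must satisfy |AIA| < 90 degrees")
  rows <- canvas[1]; cols <- canvas[2]
  spec <- list(
    true_lcea = c(right = true_lcea_right, left = true_lcea_left),
    true_aia = c(right = true_aia_right, left = true_aia_left),
    true_foi = true_foi,
    canvas = c(rows = as.integer(rows), cols = as.integer(cols)),
    head_radius = head_radius,
    midline_x = (cols + 1) / 2,
    head_dx = 0.22 * cols,          # head center offset from midline
    head_y = 0.42 * rows,
    tub_dx = 0.15 * cols,           # tuberosity offset from midline
    tub_y = 0.68 * rows,
    tub_blob_radius = 0.04 * rows,  # ischial blob in the pelvis mask
    sourcil_rho = 1.25 * head_radius,   # CFH -> lateral sourcil distance
    sourcil_len = 1.35 * head_radius,   # medial-lateral sourcil chord
    sourcil_halfwidth = 0.7,        # capsule radius when rasterized
    foramen_dx = 0.105 * cols,
    foramen_y = 0.60 * rows,
    foramen_a_left = 0.055 * cols,  # horizontal semi-axis, left
    foramen_b = 0.07 * rows,        # vertical semi-axis, both sides
    rotation_deg = rotation_deg,
    noise_px = noise_px,
    seed = as.integer(seed)
  )
  spec$foramen_a_right <- spec$true_foi * spec$foramen_a_left
  class(spec) <- "phantom_spec"
  spec
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> %d x %d px; LCEA %.2f/%.2f, AIA %.2f/%.2f deg, FOI %.3f, rotation %.1f deg\n",
              x$canvas["rows"], x$canvas["cols"],
              x$true_lcea["right"], x$true_lcea["left"],
              x$true_aia["right"], x$true_aia["left"],
              x$true_foi, x$rotation_deg))
  invisible(x)
}

rotmat <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
}

rotate_about <- function(pts, center, deg) {
  R <- rotmat(deg)
  sweep(sweep(pts, 2, center) %*% t(R), 2, center, `+`)
}

## Unrotated scene primitives implied by a phantom spec. All point coordinates
## here are in the unrotated frame; the scene rotation is applied afterwards.
phantom_geometry <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  mid <- spec$midline_x
  g <- list(
    tub = list(right = c(mid - spec$tub_dx, spec$tub_y),
               left = c(mid + spec$tub_dx, spec$tub_y)),
    head = list(), sourcil = list(), foramen = list(),
    center = c((spec$canvas["cols"] + 1) / 2, (spec$canvas["rows"] + 1) / 2),
    rotation_deg = spec$rotation_deg
  )
  for (side in c("right", "left")) {
    lat_x <- if (side == "right") -1 else 1   # lateral = away from midline
    cfh <- c(mid + lat_x * spec$head_dx, spec$head_y)
    lcea <- spec$true_lcea[side] * pi / 180
    aia <- spec$true_aia[side] * pi / 180
    lat_s <- c(cfh[1] + lat_x * spec$sourcil_rho * sin(lcea),
               cfh[2] - spec$sourcil_rho * cos(lcea))
    med_s <- c(lat_s[1] - lat_x * spec$sourcil_len * cos(aia),
               lat_s[2] + spec$sourcil_len * sin(aia))
    a <- if (side == "right") spec$foramen_a_right else spec$foramen_a_left
    g$head[[side]] <- list(center = cfh, radius = spec$head_radius)
    g$sourcil[[side]] <- list(medial = med_s, lateral = lat_s)
    g$foramen[[side]] <- list(center = c(mid + lat_x * spec$foramen_dx, spec$foramen_y),
                              a = a, b = spec$foramen_b)
  }
  g
}

#' Landmarks with exactly known ground truth
#'
#' Places sourcil points, femoral-head contours, tuberosity points and
#' foramen outlines by closed-form inverse geometry so that [measure_hips()]
#' returns exactly the spec's angles and FOI (round-trip error below 1e-9
#' degrees), for any scene rotation.
#'
#' @param spec A `phantom_spec`.
#' @param n_contour_points Points on each femoral-head contour.
#' @param n_ellipse_vertices Vertices on each foramen outline.
#' @return A `landmark_set`.
#' @export
landmarks_from_truth <- function(spec, n_contour_points = 48L,
                                 n_ellipse_vertices = 64L) {
  g <- phantom_geometry(spec)
  rot <- function(p) {
    m <- if (is.matrix(p)) p else matrix(p, 1)
    out <- rotate_about(m, g$center, g$rotation_deg)
    if (is.matrix(p)) out else out[1, ]
  }
  ellipse_poly <- function(f) {
    th <- seq(0, 2 * pi, length.out = n_ellipse_vertices + 1L)[-(n_ellipse_vertices + 1L)]
    cbind(x = f$center[1] + f$a * cos(th), y = f$center[2] + f$b * sin(th))
  }
  lm <- landmark_set(
    tuberosity_inferior_right = rot(g$tub$right),
    tuberosity_inferior_left = rot(g$tub$left),
    femoral_head_contour_right = rot(circle_points(g$head$right$center,
                                                   g$head$right$radius, n_contour_points)),
    femoral_head_contour_left = rot(circle_points(g$head$left$center,
                                                  g$head$left$radius, n_contour_points)),
    sourcil_medial_right = rot(g$sourcil$right$medial),
    sourcil_lateral_right = rot(g$sourcil$right$lateral),
    sourcil_medial_left = rot(g$sourcil$left$medial),
    sourcil_lateral_left = rot(g$sourcil$left$lateral),
    foramen_outline_right = rot(ellipse_poly(g$foramen$right)),
    foramen_outline_left = rot(ellipse_poly(g$foramen$left)),
    image_id = sprintf("phantom_seed%d", spec$seed)
  )
  check_on_canvas(lm, spec)
  lm
}

check_on_canvas <- function(lm, spec) {
  pts <- list(lm$tuberosity_inferior_right, lm$tuberosity_inferior_left,
              lm$sourcil_medial_right, lm$sourcil_lateral_right,
              lm$sourcil_medial_left, lm$sourcil_lateral_left)
  all_xy <- rbind(do.call(rbind, pts),
                  lm$femoral_head_contour_right, lm$femoral_head_contour_left,
                  lm$foramen_outline_right, lm$foramen_outline_left)
  if (any(all_xy[, 1] < 1) || any(all_xy[, 1] > spec$canvas["cols"]) ||
      any(all_xy[, 2] < 1) || any(all_xy[, 2] > spec$canvas["rows"]))
    stop("phantom geometry falls outside the canvas; ",
         "enlarge the canvas or moderate the true angles")
  invisible(lm)
}

## Smooth periodic boundary jitter: low-order Fourier series in the polar
## angle with amplitude noise_px, coefficients drawn from the spec seed.
jitter_fun <- function(noise_px, seed, tag) {
  if (noise_px <= 0) return(function(theta) 0)
  coefs <- with_seed(seed + tag, list(a = stats::rnorm(4, 0, noise_px / 2),
                                      phi = stats::runif(4, 0, 2 * pi)))
  function(theta) {
    out <- 0
    for (k in 1:4) out <- out + coefs$a[k] * sin(k * theta + coefs$phi[k])
    out
  }
}

#' Rasterize a phantom into per-structure binary masks
#'
#' Draws filled discs for the femoral heads, thin capsules for the sourcils,
#' filled ellipses for the obturator foramina and ischial blobs (whose most
#' inferior points are the tuberosity landmarks) for the pelvis, all rotated
#' by the scene rotation. Deterministic given the spec (the seed drives only
#' the optional boundary jitter).
#'
#' @param spec A `phantom_spec`.
#' @return A `mask_set` with structures `pelvis`, `femoral_head_right/left`,
#'   `sourcil_right/left`, `foramen_right/left`.
#' @export
rasterize_phantom <- function(spec) {
  g <- phantom_geometry(spec)
  nr <- spec$canvas["rows"]; nc <- spec$canvas["cols"]
  rot_deg <- g$rotation_deg; ctr <- g$center

  ## membership test runs in the unrotated frame: inverse-rotate pixel centers
  fill <- function(test, bbox) {
    m <- matrix(0L, nr, nc)
    corners <- expand.grid(x = bbox[c(1, 2)], y = bbox[c(3, 4)])
    rc <- rotate_about(as.matrix(corners), ctr, rot_deg)
    cols_in <- max(1L, floor(min(rc[, 1]))):min(nc, ceiling(max(rc[, 1])))
    rows_in <- max(1L, floor(min(rc[, 2]))):min(nr, ceiling(max(rc[, 2])))
    X <- matrix(cols_in, length(rows_in), length(cols_in), byrow = TRUE)
    Y <- matrix(rows_in, length(rows_in), length(cols_in))
    P <- rotate_about(cbind(as.vector(X), as.vector(Y)), ctr, -rot_deg)
    inside <- test(P[, 1], P[, 2])
    m[rows_in, cols_in] <- matrix(as.integer(inside), length(rows_in))
    m
  }
  disc <- function(cen, r, jit) {
    mar <- r + spec$noise_px + 2
    fill(function(x, y) {
      dx <- x - cen[1]; dy <- y - cen[2]
      sqrt(dx^2 + dy^2) <= r + jit(atan2(dy, dx))
    }, c(cen[1] - mar, cen[1] + mar, cen[2] - mar, cen[2] + mar))
  }
  ellipse <- function(f, jit) {
    mar_a <- f$a + spec$noise_px + 2; mar_b <- f$b + spec$noise_px + 2
    fill(function(x, y) {
      dx <- x - f$center[1]; dy <- y - f$center[2]
      rr <- sqrt((dx / f$a)^2 + (dy / f$b)^2)
      scale <- 1 + jit(atan2(dy, dx)) / sqrt(f$a * f$b)
      rr <= scale
    }, c(f$center[1] - mar_a, f$center[1] + mar_a,
         f$center[2] - mar_b, f$center[2] + mar_b))
  }
  capsule <- function(p1, p2, hw) {
    mar <- hw + 2
    fill(function(x, y) {
      d <- p2 - p1; len2 <- sum(d^2)
      t <- pmin(1, pmax(0, ((x - p1[1]) * d[1] + (y - p1[2]) * d[2]) / len2))
      sqrt((x - (p1[1] + t * d[1]))^2 + (y - (p1[2] + t * d[2]))^2) <= hw
    }, c(min(p1[1], p2[1]) - mar, max(p1[1], p2[1]) + mar,
         min(p1[2], p2[2]) - mar, max(p1[2], p2[2]) + mar))
  }

  tub_blob <- function(tp, jit) {
    cen <- c(tp[1], tp[2] - spec$tub_blob_radius)
    disc(cen, spec$tub_blob_radius, jit)
  }
  masks <- list(
    pelvis = pmax(tub_blob(g$tub$right, jitter_fun(spec$noise_px, spec$seed, 1L)),
                  tub_blob(g$tub$left, jitter_fun(spec$noise_px, spec$seed, 2L))),
    femoral_head_right = disc(g$head$right$center, g$head$right$radius,
                              jitter_fun(spec$noise_px, spec$seed, 3L)),
    femoral_head_left = disc(g$head$left$center, g$head$left$radius,
                             jitter_fun(spec$noise_px, spec$seed, 4L)),
    sourcil_right = capsule(g$sourcil$right$medial, g$sourcil$right$lateral,
                            spec$sourcil_halfwidth),
    sourcil_left = capsule(g$sourcil$left$medial, g$sourcil$left$lateral,
                           spec$sourcil_halfwidth),
    foramen_right = ellipse(g$foramen$right, jitter_fun(spec$noise_px, spec$seed, 5L)),
    foramen_left = ellipse(g$foramen$left, jitter_fun(spec$noise_px, spec$seed, 6L))
  )
  if (any(vapply(masks, sum, numeric(1)) == 0))
    stop("rasterization produced an empty structure mask; geometry off canvas?")
  mask_set(masks, image_id = sprintf("phantom_seed%d", spec$seed))
}

#' Draw a batch of phantom specs with realistic truth values
#'
#' Truth distributions reflect adult AP-radiograph measurement populations:
#' LCEA ~ Normal(25.4, 7.0^2) degrees, AIA ~ Normal(4.7, 5.7^2) degrees (both
#' truncated to geometrically feasible ranges), FOI ~ Normal(1, 0.05^2)
#' truncated positive.
#'
#' @param n Number of phantoms.
#' @param seed Integer seed.
#' @param canvas Canvas size `c(rows, cols)` for every phantom.
#' @param rotation_sd SD (degrees) of the random scene rotation (0 = upright).
#' @param noise_px Boundary jitter amplitude passed to each spec.
#' @return List with `specs` (list of `phantom_spec`) and `truth` (data frame
#'   of the true values, one row per phantom).
#' @export
phantom_batch <- function(n, seed = 1L, canvas = c(1024L, 1024L),
                          rotation_sd = 0, noise_px = 0) {
  rtrunc <- function(n, mean, sd, lo, hi) {
    x <- stats::rnorm(n, mean, sd)
    while (any(bad <- x < lo | x > hi))
      x[bad] <- stats::rnorm(sum(bad), mean, sd)
    x
  }
  with_seed(seed, {
    lcea_r <- rtrunc(n, 25.4, 7.0, -10, 55)
    lcea_l <- rtrunc(n, 25.4, 7.0, -10, 55)
    aia_r <- rtrunc(n, 4.7, 5.7, -20, 30)
    aia_l <- rtrunc(n, 4.7, 5.7, -20, 30)
    foi <- rtrunc(n, 1, 0.05, 0.7, 1.3)
    rot <- if (rotation_sd > 0) stats::rnorm(n, 0, rotation_sd) else numeric(n)
    specs <- lapply(seq_len(n), function(i)
      phantom_spec(true_lcea_right = lcea_r[i], true_lcea_left = lcea_l[i],
                   true_aia_right = aia_r[i], true_aia_left = aia_l[i],
                   true_foi = foi[i], canvas = canvas,
                   rotation_deg = rot[i], noise_px = noise_px,
                   seed = seed + i))
    list(specs = specs,
         truth = data.frame(phantom = seq_len(n),
                            lcea_right = lcea_r, lcea_left = lcea_l,
                            aia_right = aia_r, aia_left = aia_l,
                            foi = foi, rotation_deg = rot))
  })
}
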