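## Independent oracles used across the suite. None of these share code with
## the package implementation.

## Brute-force grid search for the circle minimising the sum of squared
## radial deviations; refined over shrinking grids. Resolution of the final
## grid is returned as an attribute.
grid_circle_oracle <- function(pts, span = 10, steps = 3, k = 21) {
  obj <- function(cx, cy, r) {
    sum((sqrt((pts[, 1] - cx)^2 + (pts[, 2] - cy)^2) - r)^2)
  }
  best <- c(mean(pts[, 1]), mean(pts[, 2]), 0)
  best[3] <- mean(sqrt((pts[, 1] - best[1])^2 + (pts[, 2] - best[2])^2))
  res <- span
  for (s in seq_len(steps)) {
    g <- expand.grid(cx = seq(best[1] - res, best[1] + res, length.out = k),
                     cy = seq(best[2] - res, best[2] + res, length.out = k),
                     r = seq(best[3] - res, best[3] + res, length.out = k))
    vals <- mapply(obj, g$cx, g$cy, g$r)
    best <- as.numeric(g[which.min(vals), ])
    res <- res * 2 / (k - 1)       # keep neighbours of the best cell
  }
  structure(best, names = c("cx", "cy", "r"), resolution = res)
}

## Closed-form projection oracle for the signed perpendicular offset: rotate
## the frame so the reference line is horizontal, then compare y values.
offset_oracle <- function(p, anchor, direction) {
  theta <- atan2(direction[2], direction[1])
  R <- matrix(c(cos(-theta), sin(-theta), -sin(-theta), cos(-theta)), 2, 2)
  rel <- R %*% (p - anchor)
  -rel[2]          # y-down: superior offsets are negative y in the flat frame
}

## Analytic half-width of an axis-aligned ellipse at vertical offset dy from
## its center: full width = 2 a sqrt(1 - (dy/b)^2).
ellipse_width_oracle <- function(a, b, dy) {
  if (abs(dy) >= b) 0 else 2 * a * sqrt(1 - (dy / b)^2)
}

## Closed-form ANOVA (method-of-moments) variance components for a balanced
## crossed patient x reader table with one observation per cell.
anova_varcomp_oracle <- function(tab) {
  p <- factor(tab$patient_id); r <- factor(tab$reader_id)
  np <- nlevels(p); nr <- nlevels(r)
  stopifnot(nrow(tab) == np * nr)
  fit <- stats::aov(value ~ p + r, data = data.frame(value = tab$value, p = p, r = r))
  ms <- summary(fit)[[1]][["Mean Sq"]]
  names(ms) <- c("p", "r", "resid")
  c(patient = (ms[["p"]] - ms[["resid"]]) / nr,
    reader = (ms[["r"]] - ms[["resid"]]) / np,
    residual = ms[["resid"]])
}

## Balanced patient x reader x occasion method-of-moments components from
## sequential ANOVA mean squares (every patient measured on every occasion).
mom_varcomp_oracle <- function(tab) {
  p <- factor(tab$patient_id); r <- factor(tab$reader_id)
  k <- factor(tab$replicate)
  np <- nlevels(p); nr <- nlevels(r); nk <- nlevels(k)
  occ <- interaction(p, k)
  fit <- stats::aov(value ~ p + r + occ,
                    data = data.frame(value = tab$value, p = p, r = r, occ = occ))
  ms <- summary(fit)[[1]][["Mean Sq"]]
  names(ms) <- c("p", "r", "occ", "resid")
  ve <- ms[["resid"]]
  vc <- (ms[["occ"]] - ve) / nr
  vp <- (ms[["p"]] - nr * vc - ve) / (nr * nk)
  vr <- (ms[["r"]] - ve) / (np * nk)
  c(patient = vp, reader = vr, repeat_ = vc, residual = ve)
}

## Rigid transform of a landmark set: rotate by deg about a center, then
## translate; returns a new landmark_set with identical labels.
transform_landmarks <- function(lm, deg = 0, center = c(0, 0), shift = c(0, 0),
                                scale = 1) {
  R <- matrix(c(cos(deg * pi / 180), sin(deg * pi / 180),
                -sin(deg * pi / 180), cos(deg * pi / 180)), 2, 2)
  tf <- function(v) {
    if (is.null(v)) return(NULL)
    m <- if (is.matrix(v)) v else matrix(v, 1)
    out <- sweep(scale * sweep(m, 2, center) %*% t(R), 2, center + shift, `+`)
    if (is.matrix(v)) out else out[1, ]
  }
  landmark_set(
    tuberosity_inferior_right = tf(lm$tuberosity_inferior_right),
    tuberosity_inferior_left = tf(lm$tuberosity_inferior_left),
    femoral_head_contour_right = tf(lm$femoral_head_contour_right),
    femoral_head_contour_left = tf(lm$femoral_head_contour_left),
    sourcil_medial_right = tf(lm$sourcil_medial_right),
    sourcil_lateral_right = tf(lm$sourcil_lateral_right),
    sourcil_medial_left = tf(lm$sourcil_medial_left),
    sourcil_lateral_left = tf(lm$sourcil_lateral_left),
    foramen_outline_right = tf(lm$foramen_outline_right),
    foramen_outline_left = tf(lm$foramen_outline_left),
    laterality_convention = lm$laterality_convention,
    image_id = lm$image_id
  )
}

## Mirror a landmark set across the vertical line x = axis and swap the
## right/left labels (what a true left-right reflection of the scene does).
mirror_landmarks <- function(lm, axis) {
  mf <- function(v) {
    if (is.null(v)) return(NULL)
    m <- if (is.matrix(v)) v else matrix(v, 1)
    m[, 1] <- 2 * axis - m[, 1]
    if (is.matrix(v)) m else m[1, ]
  }
  landmark_set(
    tuberosity_inferior_right = mf(lm$tuberosity_inferior_left),
    tuberosity_inferior_left = mf(lm$tuberosity_inferior_right),
    femoral_head_contour_right = mf(lm$femoral_head_contour_left),
    femoral_head_contour_left = mf(lm$femoral_head_contour_right),
    sourcil_medial_right = mf(lm$sourcil_medial_left),
    sourcil_lateral_right = mf(lm$sourcil_lateral_left),
    sourcil_medial_left = mf(lm$sourcil_medial_right),
    sourcil_lateral_left = mf(lm$sourcil_lateral_right),
    foramen_outline_right = mf(lm$foramen_outline_left),
    foramen_outline_left = mf(lm$foramen_outline_right),
    laterality_convention = lm$laterality_convention,
    image_id = lm$image_id
  )
}
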