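#' @keywords internal
"_PACKAGE"

## Image coordinate convention used throughout: x = column, y = row, with y
## increasing downward (raster convention). "Superior" on a radiograph is
## therefore towards smaller y. All angle measurements are taken relative to
## the inter-ischial reference line, never the image axes, so a tilted
## radiograph tilts the whole frame consistently.

#' Construct a 2-D point
#'
#' @param x,y Coordinates in pixels; x is the image column, y the image row
#'   (y grows downward).
#' @return Named numeric vector `c(x, y)`.
#' @export
pt2 <- function(x, y) {
  p <- c(x = as.numeric(x), y = as.numeric(y))
  if (!all(is.finite(p))) stop("point coordinates must be finite")
  p
}

as_pt2 <- function(p, what = "point") {
  p <- as.numeric(p)
  if (length(p) != 2L || !all(is.finite(p)))
    stop(sprintf("%s must be a finite length-2 (x, y) coordinate", what))
  names(p) <- c("x", "y")
  p
}

#' Reference line through the inferior ischial tuberosity points
#'
#' The horizontal reference of an AP pelvic radiograph joins the most inferior
#' points of the two ischial tuberosities. The returned direction is unit
#' length and canonically oriented with a non-negative x component (and
#' positive y if exactly vertical), so the same two points always produce the
#' same line object regardless of argument order.
#'
#' @param right_tub,left_tub Most inferior tuberosity points, `c(x, y)`.
#' @return Object of class `hip_refline` with fields `anchor` and `direction`.
#' @export
make_reference_line <- function(right_tub, left_tub) {
  a <- as_pt2(right_tub, "right tuberosity")
  b <- as_pt2(left_tub, "left tuberosity")
  d <- b - a
  len <- sqrt(sum(d^2))
  if (len == 0)
    stop("degenerate geometry: right and left tuberosity points coincide")
  d <- d / len
  if (d[1] < 0 || (d[1] == 0 && d[2] < 0)) d <- -d
  structure(list(anchor = a, direction = unname(d)),
            class = "hip_refline")
}

#' @export
print.hip_refline <- function(x, ...) {
  cat(sprintf("<reference line> anchor (%.2f, %.2f), direction (%.5f, %.5f)\n",
              x$anchor[1], x$anchor[2], x$direction[1], x$direction[2]))
  invisible(x)
}

## Coordinates of p in the reference-line frame: u along the line (canonical
## direction), v the signed perpendicular offset, positive superior (-y side).
ref_frame <- function(p, ref) {
  stopifnot(inherits(ref, "hip_refline"))
  d <- ref$direction
  n <- c(d[2], -d[1])            # superior normal under y-down convention
  rel <- as_pt2(p) - ref$anchor
  c(u = sum(rel * d), v = sum(rel * n))
}

#' Signed perpendicular offset from the reference line
#'
#' Positive when the point lies superior to the line (towards smaller image
#' rows for the canonical line orientation), negative when inferior.
#'
#' @param p Point `c(x, y)`.
#' @param ref A `hip_refline`.
#' @return Offset in pixels.
#' @export
signed_perpendicular_offset <- function(p, ref) {
  unname(ref_frame(p, ref)["v"])
}

#' Least-squares circle fit (Kasa algebraic method)
#'
#' Fits a circle to contour points by minimising the algebraic residual
#' sum((x^2 + y^2 + D x + E y + F)^2), the standard closed-form least-squares
#' parameterisation used for femoral-head circles. Optionally refines the
#' solution with a geometric (Gauss-Newton) fit minimising the true radial
#' residuals; refinement is off by default so that repeated runs are
#' bit-identical.
#'
#' @param points Numeric matrix (n x 2) of (x, y) contour points, or a list of
#'   length-2 points. At least 3 non-collinear points.
#' @param refine Logical; run geometric refinement after the algebraic fit.
#' @return Object of class `circle_fit`: `center` (c(x, y)), `radius`,
#'   `rms_residual` (RMS of radial deviations), `n_points`.
#' @export
fit_circle_least_squares <- function(points, refine = FALSE) {
  pts <- to_point_matrix(points)
  n <- nrow(pts)
  if (n < 3L) stop("circle fit requires at least 3 points")
  x <- pts[, 1]; y <- pts[, 2]
  A <- cbind(x, y, 1)
  b <- -(x^2 + y^2)
  qrA <- qr(A)
  if (qrA$rank < 3L)
    stop("circle fit failed: points are collinear (or coincident)")
  coef <- qr.coef(qrA, b)              # (D, E, F)
  cx <- -coef[1] / 2; cy <- -coef[2] / 2
  r2 <- cx^2 + cy^2 - coef[3]
  if (!is.finite(r2) || r2 <= 0)
    stop("circle fit failed: degenerate configuration")
  cen <- c(cx, cy); r <- sqrt(r2)
  if (refine) {
    obj <- function(par) {
      sum((sqrt((x - par[1])^2 + (y - par[2])^2) - par[3])^2)
    }
    opt <- stats::optim(c(cen, r), obj, method = "BFGS",
                        control = list(reltol = 1e-14, maxit = 500))
    cen <- opt$par[1:2]; r <- opt$par[3]
  }
  resid <- sqrt((x - cen[1])^2 + (y - cen[2])^2) - r
  structure(list(center = c(x = unname(cen[1]), y = unname(cen[2])),
                 radius = unname(r),
                 rms_residual = sqrt(mean(resid^2)),
                 n_points = n),
            class = "circle_fit")
}

#' @export
print.circle_fit <- function(x, ...) {
  cat(sprintf("<circle fit> center (%.3f, %.3f), radius %.3f px, rms residual %.4f px (n = %d)\n",
              x$center[1], x$center[2], x$radius, x$rms_residual, x$n_points))
  invisible(x)
}

to_point_matrix <- function(points) {
  if (is.matrix(points)) {
    m <- points
  } else if (is.data.frame(points)) {
    m <- as.matrix(points[, 1:2])
  } else if (is.list(points)) {
    m <- do.call(rbind, lapply(points, as_pt2))
  } else {
    stop("points must be an n x 2 matrix, data frame, or list of (x, y)")
  }
  storage.mode(m) <- "double"
  if (ncol(m) != 2L || anyNA(m) || !all(is.finite(m)))
    stop("points must be finite (x, y) pairs")
  colnames(m) <- c("x", "y")
  m
}

## Sign of the lateral direction along u for a given side. With the
## radiographic convention (patient right displayed on image left) the
## patient's right hip is at smaller u, so "lateral" (away from the body
## midline) is -u for the right side and +u for the left side. The flipped
## convention mirrors this.
lateral_u_sign <- function(side, convention = "right_on_left") {
  side <- match.arg(side, c("right", "left"))
  convention <- match.arg(convention, c("right_on_left", "right_on_right"))
  s <- if (side == "right") -1 else 1
  if (convention == "right_on_right") s <- -s
  s
}

#' Lateral center edge angle of Wiberg
#'
#' Angle at the femoral-head center (CFH) between the perpendicular to the
#' reference line (pointing superior) and the ray from the CFH to the lateral
#' sourcil. Positive when the sourcil lies lateral to the perpendicular for
#' the given side, negative when medial, so dysplastic under-coverage yields
#' small or negative values.
#'
#' @param cfh Center of the femoral head, `c(x, y)`.
#' @param lateral_sourcil Lateral extent of the acetabular sourcil, `c(x, y)`.
#' @param ref A `hip_refline`.
#' @param side `"right"` or `"left"` (patient side).
#' @param convention Laterality display convention; `"right_on_left"`
#'   (radiographic default) or `"right_on_right"`.
#' @return List with `angle_deg` and character vector `flags` (warns when the
#'   sourcil is not superior to the CFH; the angle is still computed because
#'   abnormal anatomy must still be reported).
#' @export
compute_lcea <- function(cfh, lateral_sourcil, ref, side,
                         convention = "right_on_left") {
  c0 <- ref_frame(cfh, ref)
  s0 <- ref_frame(lateral_sourcil, ref)
  du <- s0["u"] - c0["u"]; dv <- s0["v"] - c0["v"]
  if (du == 0 && dv == 0)
    stop("lateral sourcil coincides with the femoral head center")
  slat <- lateral_u_sign(side, convention)
  angle <- atan2(slat * du, dv) * 180 / pi
  flags <- character()
  if (dv < 0)
    flags <- sprintf("lcea_%s: lateral sourcil inferior to femoral head center", side)
  list(angle_deg = unname(angle), flags = flags)
}

#' Acetabular index angle
#'
#' Angle between the reference-line-parallel through the medial sourcil and
#' the line joining the medial and lateral sourcils. Positive when the lateral
#' sourcil is superior to the medial one (up-sloping acetabular roof),
#' negative when the roof slopes downward laterally.
#'
#' @param medial_sourcil,lateral_sourcil Sourcil extent points, `c(x, y)`.
#' @inheritParams compute_lcea
#' @return List with `angle_deg` and `flags` (flags when the lateral sourcil
#'   projects medial to the medial sourcil).
#' @export
compute_aia <- function(medial_sourcil, lateral_sourcil, ref, side,
                        convention = "right_on_left") {
  m <- ref_frame(medial_sourcil, ref)
  l <- ref_frame(lateral_sourcil, ref)
  du <- l["u"] - m["u"]; dv <- l["v"] - m["v"]
  if (du == 0 && dv == 0)
    stop("medial and lateral sourcil points coincide")
  slat <- lateral_u_sign(side, convention)
  angle <- atan2(dv, slat * du) * 180 / pi
  flags <- character()
  if (slat * du <= 0)
    flags <- sprintf("aia_%s: lateral sourcil not lateral to medial sourcil", side)
  list(angle_deg = unname(angle), flags = flags)
}

#' Width profile of a polygon along lines parallel to the reference line
#'
#' Lays `n_lines` equidistant lines parallel to the reference line across the
#' polygon's full perpendicular extent (line 1 at the superior extent, the
#' last at the inferior extent) and measures, on each line, the caliper-style
#' outermost-crossing width of the polygon. This mirrors how obturator foramen
#' widths are taken on a radiograph.
#'
#' @param polygon Closed polygon as an n x 2 matrix of (x, y) vertices (first
#'   vertex need not be repeated).
#' @param ref A `hip_refline`.
#' @param n_lines Number of parallel lines (default 13).
#' @return Object of class `width_profile`: `offsets` (perpendicular positions,
#'   superior first), `widths`, `max_width` (all in pixels).
#' @export
polygon_width_profile <- function(polygon, ref, n_lines = 13L) {
  poly <- to_point_matrix(polygon)
  if (nrow(poly) < 3L) stop("polygon needs at least 3 vertices")
  uv <- t(apply(poly, 1, ref_frame, ref = ref))
  u <- uv[, "u"]; v <- uv[, "v"]
  offs <- seq(max(v), min(v), length.out = n_lines)
  widths <- vapply(offs, function(v0) polyline_width(u, v, v0), numeric(1))
  structure(list(offsets = offs, widths = widths, max_width = max(widths)),
            class = "width_profile")
}

## Outermost-crossing width of the (closed) polygon (u, v) along the line
## v = v0. Vertices lying exactly on the line contribute their own u, which
## handles edges collinear with the line (e.g. the flat top of a rectangle).
polyline_width <- function(u, v, v0) {
  n <- length(u)
  j <- c(seq_len(n)[-1], 1L)
  crossings <- numeric(0)
  on_line <- abs(v - v0) < 1e-12
  if (any(on_line)) crossings <- u[on_line]
  v1 <- v; v2 <- v[j]; u1 <- u; u2 <- u[j]
  str <- (v1 - v0) * (v2 - v0) < 0
  if (any(str)) {
    t <- (v0 - v1[str]) / (v2[str] - v1[str])
    crossings <- c(crossings, u1[str] + t * (u2[str] - u1[str]))
  }
  if (length(crossings) == 0) return(0)
  max(crossings) - min(crossings)
}

#' Foramen obturator index
#'
#' Ratio of the maximum right obturator-foramen width to the maximum left
#' width, both measured parallel to the reference line; an index of pelvic
#' rotation (about 1 for an unrotated pelvis).
#'
#' @param right,left `width_profile` objects (or numbers giving max widths).
#' @return The ratio right/left.
#' @export
compute_foi <- function(right, left) {
  wr <- if (inherits(right, "width_profile")) right$max_width else as.numeric(right)
  wl <- if (inherits(left, "width_profile")) left$max_width else as.numeric(left)
  if (!is.finite(wr) || !is.finite(wl) || wr <= 0)
    stop("foramen widths must be positive and finite")
  if (wl <= 0) stop("left foramen width is zero; FOI undefined")
  wr / wl
}
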