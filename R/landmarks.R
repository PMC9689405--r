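#' Assemble a landmark set for one AP pelvic radiograph
#'
#' Container for all anatomical inputs the measurement engine needs: the most
#' inferior ischial tuberosity points (defining the reference line), per-hip
#' femoral-head contours (or precomputed circle fits), the medial and lateral
#' sourcil extents, and optionally the obturator foramen outlines.
#'
#' @param tuberosity_inferior_right,tuberosity_inferior_left `c(x, y)` points.
#' @param femoral_head_contour_right,femoral_head_contour_left n x 2 matrices
#'   of contour points (>= 3), or `circle_fit` objects.
#' @param sourcil_medial_right,sourcil_lateral_right `c(x, y)` points.
#' @param sourcil_medial_left,sourcil_lateral_left `c(x, y)` points.
#' @param foramen_outline_right,foramen_outline_left Optional closed polygons
#'   (n x 2 matrices) outlining the obturator foramina.
#' @param pixel_spacing_mm Optional scalar, mm per pixel; when present, widths
#'   are reported in mm.
#' @param laterality_convention `"right_on_left"` (radiographic default:
#'   patient right displayed on image left) or `"right_on_right"`.
#' @param image_id Identifier carried into reports.
#' @return Object of class `landmark_set`.
#' @export
landmark_set <- function(tuberosity_inferior_right,
                         tuberosity_inferior_left,
                         femoral_head_contour_right = NULL,
                         femoral_head_contour_left = NULL,
                         sourcil_medial_right = NULL,
                         sourcil_lateral_right = NULL,
                         sourcil_medial_left = NULL,
                         sourcil_lateral_left = NULL,
                         foramen_outline_right = NULL,
                         foramen_outline_left = NULL,
                         pixel_spacing_mm = NULL,
                         laterality_convention = "right_on_left",
                         image_id = "image") {
  laterality_convention <- match.arg(laterality_convention,
                                     c("right_on_left", "right_on_right"))
  lm <- structure(list(
    image_id = image_id,
    tuberosity_inferior_right = as_pt2(tuberosity_inferior_right, "tuberosity_inferior_right"),
    tuberosity_inferior_left = as_pt2(tuberosity_inferior_left, "tuberosity_inferior_left"),
    femoral_head_contour_right = norm_contour(femoral_head_contour_right),
    femoral_head_contour_left = norm_contour(femoral_head_contour_left),
    sourcil_medial_right = norm_opt_point(sourcil_medial_right, "sourcil_medial_right"),
    sourcil_lateral_right = norm_opt_point(sourcil_lateral_right, "sourcil_lateral_right"),
    sourcil_medial_left = norm_opt_point(sourcil_medial_left, "sourcil_medial_left"),
    sourcil_lateral_left = norm_opt_point(sourcil_lateral_left, "sourcil_lateral_left"),
    foramen_outline_right = norm_polygon(foramen_outline_right),
    foramen_outline_left = norm_polygon(foramen_outline_left),
    pixel_spacing_mm = if (is.null(pixel_spacing_mm)) NULL else as.numeric(pixel_spacing_mm),
    laterality_convention = laterality_convention
  ), class = "landmark_set")
  lm
}

norm_opt_point <- function(p, what) if (is.null(p)) NULL else as_pt2(p, what)

norm_contour <- function(x) {
  if (is.null(x) || inherits(x, "circle_fit")) return(x)
  m <- to_point_matrix(x)
  if (nrow(m) < 3L) stop("femoral head contour needs at least 3 points")
  m
}

norm_polygon <- function(x) {
  if (is.null(x)) return(NULL)
  m <- to_point_matrix(x)
  if (nrow(m) < 3L) stop("foramen outline needs at least 3 vertices")
  m
}

#' @export
print.landmark_set <- function(x, ...) {
  have <- names(x)[!vapply(x, is.null, logical(1))]
  cat(sprintf("<landmark_set> %s: %s\n", x$image_id,
              paste(setdiff(have, c("image_id", "laterality_convention")),
                    collapse = ", ")))
  invisible(x)
}

## Names required to measure one side's angles.
side_required <- function(side) {
  c(sprintf("femoral_head_contour_%s", side),
    sprintf("sourcil_medial_%s", side),
    sprintf("sourcil_lateral_%s", side))
}

#' Measure LCEA, AIA and foramen widths from a landmark set
#'
#' Builds the inter-ischial reference line, fits the femoral-head circles,
#' and computes the lateral center edge angle and acetabular index angle for
#' each hip plus the obturator foramen width profiles and foramen obturator
#' index when outlines are present. Fully deterministic: the same landmark set
#' always yields bit-identical output. A failure on one side is recorded as a
#' flag and the other side is still measured; missing mandatory landmarks
#' raise an error naming them.
#'
#' @param lm A `landmark_set`.
#' @param n_width_lines Number of parallel lines for the foramen width
#'   profiles (default 13).
#' @return Object of class `hip_measurements`: per-side `lcea`, `aia`
#'   (degrees), `foramen_width` (pixels, or mm if `pixel_spacing_mm` was
#'   given), `foi`, the `circle_fit`s, the reference line and quality flags.
#' @export
measure_hips <- function(lm, n_width_lines = 13L) {
  stopifnot(inherits(lm, "landmark_set"))
  missing <- c("tuberosity_inferior_right", "tuberosity_inferior_left")
  missing <- missing[vapply(missing, function(nm) is.null(lm[[nm]]), logical(1))]
  if (length(missing))
    stop("missing mandatory landmarks: ", paste(missing, collapse = ", "))
  ref <- make_reference_line(lm$tuberosity_inferior_right,
                             lm$tuberosity_inferior_left)
  conv <- lm$laterality_convention
  flags <- character()
  out <- list(image_id = lm$image_id, reference = ref,
              lcea = c(right = NA_real_, left = NA_real_),
              aia = c(right = NA_real_, left = NA_real_),
              foramen_width = c(right = NA_real_, left = NA_real_),
              foi = NA_real_, cfh = list(right = NULL, left = NULL),
              width_unit = if (is.null(lm$pixel_spacing_mm)) "px" else "mm",
              flags = character())

  for (side in c("right", "left")) {
    req <- side_required(side)
    absent <- req[vapply(req, function(nm) is.null(lm[[nm]]), logical(1))]
    if (length(absent)) {
      flags <- c(flags, sprintf("%s: missing landmarks: %s", side,
                                paste(absent, collapse = ", ")))
      next
    }
    res <- tryCatch({
      contour <- lm[[sprintf("femoral_head_contour_%s", side)]]
      cf <- if (inherits(contour, "circle_fit")) contour else
        fit_circle_least_squares(contour)
      lcea <- compute_lcea(cf$center, lm[[sprintf("sourcil_lateral_%s", side)]],
                           ref, side, conv)
      aia <- compute_aia(lm[[sprintf("sourcil_medial_%s", side)]],
                         lm[[sprintf("sourcil_lateral_%s", side)]],
                         ref, side, conv)
      list(cf = cf, lcea = lcea, aia = aia)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      flags <- c(flags, sprintf("%s: measurement failed: %s", side,
                                conditionMessage(res)))
      next
    }
    out$cfh[[side]] <- res$cf
    out$lcea[side] <- res$lcea$angle_deg
    out$aia[side] <- res$aia$angle_deg
    flags <- c(flags, res$lcea$flags, res$aia$flags)
  }

  scale <- if (is.null(lm$pixel_spacing_mm)) 1 else lm$pixel_spacing_mm
  for (side in c("right", "left")) {
    poly <- lm[[sprintf("foramen_outline_%s", side)]]
    if (!is.null(poly)) {
      wp <- polygon_width_profile(poly, ref, n_width_lines)
      out$foramen_width[side] <- wp$max_width * scale
    }
  }
  if (all(is.finite(out$foramen_width)))
    out$foi <- compute_foi(out$foramen_width["right"], out$foramen_width["left"])

  out$flags <- flags
  structure(out, class = "hip_measurements")
}

#' @export
print.hip_measurements <- function(x, ...) {
  cat(sprintf("<hip_measurements> %s\n", x$image_id))
  cat(sprintf("  LCEA  right %8.3f  left %8.3f deg\n", x$lcea["right"], x$lcea["left"]))
  cat(sprintf("  AIA   right %8.3f  left %8.3f deg\n", x$aia["right"], x$aia["left"]))
  cat(sprintf("  Foramen width right %.2f  left %.2f %s;  FOI %.4f\n",
              x$foramen_width["right"], x$foramen_width["left"],
              x$width_unit, x$foi))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Long-format report rows for one measured radiograph
#'
#' @param x A `hip_measurements` object.
#' @param ... Unused.
#' @return Data frame with columns `image_id`, `metric`, `value`, `unit`,
#'   `flags` (all flags joined with `"; "`).
#' @export
as.data.frame.hip_measurements <- function(x, ...) {
  metrics <- c(lcea_right = unname(x$lcea["right"]),
               lcea_left = unname(x$lcea["left"]),
               aia_right = unname(x$aia["right"]),
               aia_left = unname(x$aia["left"]),
               foramen_width_right = unname(x$foramen_width["right"]),
               foramen_width_left = unname(x$foramen_width["left"]),
               foi = x$foi)
  units <- c(rep("deg", 4), rep(x$width_unit, 2), "ratio")
  data.frame(image_id = x$image_id,
             metric = names(metrics),
             value = unname(metrics),
             unit = units,
             flags = paste(x$flags, collapse = "; "),
             stringsAsFactors = FALSE)
}

#' Read a landmark set from JSON
#'
#' Schema: top-level `image_id`, optional `pixel_spacing_mm`,
#' `laterality_convention`, and `landmarks`, a named object mapping each
#' landmark name (`tuberosity_inferior_right/left`,
#' `femoral_head_contour_right/left`, `sourcil_medial_right/left`,
#' `sourcil_lateral_right/left`, `foramen_outline_right/left`) to an `[x, y]`
#' pair or a list of pairs.
#'
#' @param path File path.
#' @return A `landmark_set`.
#' @export
read_landmarks_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  lms <- j$landmarks
  get <- function(nm) {
    v <- lms[[nm]]
    if (is.null(v)) return(NULL)
    if (is.list(v)) v <- do.call(rbind, v)
    if (is.matrix(v)) v else as.numeric(v)
  }
  landmark_set(
    tuberosity_inferior_right = get("tuberosity_inferior_right"),
    tuberosity_inferior_left = get("tuberosity_inferior_left"),
    femoral_head_contour_right = get("femoral_head_contour_right"),
    femoral_head_contour_left = get("femoral_head_contour_left"),
    sourcil_medial_right = get("sourcil_medial_right"),
    sourcil_lateral_right = get("sourcil_lateral_right"),
    sourcil_medial_left = get("sourcil_medial_left"),
    sourcil_lateral_left = get("sourcil_lateral_left"),
    foramen_outline_right = get("foramen_outline_right"),
    foramen_outline_left = get("foramen_outline_left"),
    pixel_spacing_mm = j$pixel_spacing_mm,
    laterality_convention = if (is.null(j$laterality_convention))
      "right_on_left" else j$laterality_convention,
    image_id = if (is.null(j$image_id)) basename(path) else j$image_id
  )
}

#' Write a landmark set to JSON
#'
#' @param lm A `landmark_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_landmarks_json <- function(lm, path) {
  stopifnot(inherits(lm, "landmark_set"))
  pack <- function(v) {
    if (is.null(v)) return(NULL)
    if (inherits(v, "circle_fit"))
      v <- circle_points(v$center, v$radius, max(v$n_points, 16L))
    if (is.matrix(v)) unname(lapply(seq_len(nrow(v)), function(i) unname(v[i, ])))
    else unname(v)
  }
  nm <- c("tuberosity_inferior_right", "tuberosity_inferior_left",
          "femoral_head_contour_right", "femoral_head_contour_left",
          "sourcil_medial_right", "sourcil_lateral_right",
          "sourcil_medial_left", "sourcil_lateral_left",
          "foramen_outline_right", "foramen_outline_left")
  lms <- lapply(nm, function(n) pack(lm[[n]]))
  names(lms) <- nm
  lms <- lms[!vapply(lms, is.null, logical(1))]
  obj <- list(image_id = lm$image_id,
              pixel_spacing_mm = lm$pixel_spacing_mm,
              laterality_convention = lm$laterality_convention,
              landmarks = lms)
  obj <- obj[!vapply(obj, is.null, logical(1))]
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

## n points on a circle, equiangular starting at angle 0.
circle_points <- function(center, radius, n) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(x = center[1] + radius * cos(th), y = center[2] + radius * sin(th))
}
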