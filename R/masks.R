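#' Assemble per-structure binary masks for one radiograph
#'
#' @param masks Named list of binary matrices (same shape, foreground > 0).
#'   Recognised names: `pelvis`, `femoral_head_right`, `femoral_head_left`,
#'   `sourcil_right`, `sourcil_left`, `foramen_right`, `foramen_left`.
#' @param image_id Identifier carried into reports.
#' @param pixel_spacing_mm Optional mm-per-pixel scale.
#' @return Object of class `mask_set`.
#' @export
mask_set <- function(masks, image_id = "image", pixel_spacing_mm = NULL) {
  stopifnot(is.list(masks), length(masks) > 0, !is.null(names(masks)))
  dims <- unique(lapply(masks, dim))
  if (length(dims) != 1L)
    stop("all masks must share one image shape")
  masks <- lapply(masks, function(m) {
    m <- (m > 0) * 1L
    storage.mode(m) <- "integer"
    m
  })
  structure(list(masks = masks, shape = dims[[1]], image_id = image_id,
                 pixel_spacing_mm = pixel_spacing_mm),
            class = "mask_set")
}

#' @export
print.mask_set <- function(x, ...) {
  cat(sprintf("<mask_set> %s: %d x %d px; structures: %s\n", x$image_id,
              x$shape[1], x$shape[2], paste(names(x$masks), collapse = ", ")))
  invisible(x)
}

#' Read / write a binary mask as 8-bit PNG
#'
#' Foreground is any value > 0. Files follow the
#' `<image_id>__<structure>.png` naming convention.
#'
#' @param path PNG file path.
#' @return `read_mask_png`: integer 0/1 matrix (rows x cols).
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  m <- (img > 0.5) * 1L
  storage.mode(m) <- "integer"
  m
}

#' @rdname read_mask_png
#' @param mask Binary matrix.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG((mask > 0) * 1, path)
  invisible(path)
}

#' Read a full mask set from a directory
#'
#' Expects files named `<image_id>__<structure>.png`.
#'
#' @param dir Directory containing the PNG masks.
#' @param image_id Image identifier (file name prefix).
#' @param pixel_spacing_mm Optional mm-per-pixel scale.
#' @return A `mask_set`.
#' @export
read_mask_set <- function(dir, image_id, pixel_spacing_mm = NULL) {
  files <- list.files(dir, pattern = paste0("^", image_id, "__.*\\.png$"),
                      full.names = TRUE)
  if (length(files) == 0)
    stop("no mask files found for image_id '", image_id, "' in ", dir)
  structures <- sub("\\.png$", "", sub(paste0("^", image_id, "__"), "", basename(files)))
  masks <- lapply(files, read_mask_png)
  names(masks) <- structures
  mask_set(masks, image_id = image_id, pixel_spacing_mm = pixel_spacing_mm)
}

#' Write a mask set to a directory
#'
#' @param ms A `mask_set`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_mask_set <- function(ms, dir) {
  stopifnot(inherits(ms, "mask_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(ms$masks))
    write_mask_png(ms$masks[[nm]], file.path(dir, sprintf("%s__%s.png", ms$image_id, nm)))
  invisible(dir)
}

## Keep only the largest connected component (8-connectivity). Returns the
## mask plus a logical attribute "multiple" when components were discarded.
largest_component <- function(mask) {
  if (sum(mask) == 0) stop("mask is empty")
  lab <- EBImage::bwlabel(mask)
  tab <- tabulate(lab[lab > 0])
  keep <- which.max(tab)
  out <- (lab == keep) * 1L
  attr(out, "multiple") <- length(tab) > 1L
  out
}

## Sub-pixel outer boundary polygons of a binary mask via marching squares
## (grDevices::contourLines at level 0.5 on the zero-padded raster). Pixel
## centers sit at integer (x = column, y = row) coordinates, so the contour
## runs half a pixel outside the foreground centers. Returns a list of closed
## polygons (n x 2, columns x, y), largest area first.
mask_polygons <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  padded <- matrix(0, nr + 2L, nc + 2L)
  padded[2:(nr + 1L), 2:(nc + 1L)] <- mask
  cl <- grDevices::contourLines(x = 0:(nr + 1L), y = 0:(nc + 1L),
                                z = padded, levels = 0.5)
  if (length(cl) == 0) stop("mask has no boundary (empty mask)")
  polys <- lapply(cl, function(ct) {
    p <- cbind(x = ct$y, y = ct$x)       # contourLines x follows rows
    if (nrow(p) > 1L && all(p[1, ] == p[nrow(p), ])) p <- p[-nrow(p), , drop = FALSE]
    p
  })
  areas <- vapply(polys, polygon_area, numeric(1))
  polys[order(areas, decreasing = TRUE)]
}

polygon_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  j <- c(seq_len(nrow(p))[-1], 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Most inferior ischial tuberosity points from a pelvis mask
#'
#' Per side of the midline column, returns the foreground pixel with the
#' largest row (most inferior). Row ties are broken towards the most medial
#' pixel (closest to the midline), then the lowest column index.
#'
#' @param pelvis_mask Binary matrix.
#' @param midline_col Column of the body midline.
#' @param convention Laterality display convention (see [landmark_set()]).
#' @return List with `right` and `left` points `c(x, y)`.
#' @export
extract_tuberosity_points <- function(pelvis_mask, midline_col,
                                      convention = "right_on_left") {
  convention <- match.arg(convention, c("right_on_left", "right_on_right"))
  idx <- which(pelvis_mask > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("pelvis mask is empty")
  pick <- function(sub, side) {
    if (nrow(sub) == 0)
      stop("pelvis mask has no foreground on the ", side, " side of the midline")
    sub <- sub[sub[, "row"] == max(sub[, "row"]), , drop = FALSE]
    d <- abs(sub[, "col"] - midline_col)
    sub <- sub[d == min(d), , drop = FALSE]
    sub <- sub[which.min(sub[, "col"]), ]
    pt2(sub["col"], sub["row"])
  }
  left_cols <- idx[, "col"] < midline_col
  img_left <- idx[left_cols, , drop = FALSE]
  img_right <- idx[!left_cols, , drop = FALSE]
  if (convention == "right_on_left")
    list(right = pick(img_left, "patient-right"),
         left = pick(img_right, "patient-left"))
  else
    list(right = pick(img_right, "patient-right"),
         left = pick(img_left, "patient-left"))
}

#' Ordered sub-pixel femoral-head contour from a mask
#'
#' Takes the outer boundary of the largest connected component and resamples
#' it to `n_points` positions equally spaced in arc length.
#'
#' @param head_mask Binary matrix.
#' @param n_points Number of contour points (default 64).
#' @return n x 2 matrix of (x, y) boundary points; attribute `flags` carries a
#'   warning when multiple components were present.
#' @export
extract_head_contour <- function(head_mask, n_points = 64L) {
  comp <- largest_component(head_mask)
  poly <- mask_polygons(comp)[[1]]
  pts <- resample_closed(poly, n_points)
  flags <- character()
  if (isTRUE(attr(comp, "multiple")))
    flags <- "femoral head mask had multiple components; largest used"
  attr(pts, "flags") <- flags
  pts
}

## Resample a closed polygon at n points equally spaced along its perimeter.
resample_closed <- function(poly, n) {
  p <- rbind(poly, poly[1, , drop = FALSE])
  seg <- sqrt(rowSums(diff(p)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  at <- seq(0, total, length.out = n + 1L)[-(n + 1L)]
  cbind(x = stats::approx(s, p[, 1], xout = at)$y,
        y = stats::approx(s, p[, 2], xout = at)$y)
}

#' Medial and lateral sourcil extents from a sourcil mask
#'
#' Extremal foreground pixels measured along the reference-line direction
#' (not raw image columns), so a tilted radiograph selects the same
#' anatomical pixels once the reference line is recomputed. Among pixels
#' within half a pixel of the extremal position, the one with the median
#' perpendicular offset is taken, which centres the landmark inside the
#' sourcil band thickness.
#'
#' @param sourcil_mask Binary matrix.
#' @param ref A `hip_refline`.
#' @param side `"right"` or `"left"` (patient side).
#' @param convention Laterality display convention.
#' @return List with `medial`, `lateral` points `c(x, y)` and `flags`
#'   (flags a single-pixel sourcil, for which the roof angle is undefined
#'   downstream).
#' @export
extract_sourcil_extents <- function(sourcil_mask, ref, side,
                                    convention = "right_on_left") {
  idx <- which(sourcil_mask > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("sourcil mask is empty")
  x <- idx[, "col"]; y <- idx[, "row"]
  d <- ref$direction; nvec <- c(d[2], -d[1])
  u <- (x - ref$anchor[1]) * d[1] + (y - ref$anchor[2]) * d[2]
  v <- (x - ref$anchor[1]) * nvec[1] + (y - ref$anchor[2]) * nvec[2]
  s_med <- -lateral_u_sign(side, convention)   # medial = towards midline
  pick_extremal <- function(sgn) {
    score <- sgn * u
    cand <- which(score >= max(score) - 0.5)
    cand <- cand[order(v[cand], score[cand], x[cand])]
    i <- cand[ceiling(length(cand) / 2)]
    pt2(x[i], y[i])
  }
  medial <- pick_extremal(s_med)
  lateral <- pick_extremal(-s_med)
  flags <- character()
  if (all(medial == lateral))
    flags <- sprintf("sourcil_%s: single-pixel sourcil; extents coincide", side)
  list(medial = medial, lateral = lateral, flags = flags)
}

#' Obturator foramen width profile from a mask
#'
#' Width of the foramen measured on 13 (by default) equidistant lines
#' parallel to the reference line, spanning the foramen's own perpendicular
#' extent endpoints included; widths are outermost-crossing (caliper)
#' distances on the sub-pixel mask boundary.
#'
#' @param foramen_mask Binary matrix.
#' @param ref A `hip_refline`.
#' @param n_lines Number of measurement lines.
#' @return A `width_profile`.
#' @export
foramen_width_profile <- function(foramen_mask, ref, n_lines = 13L) {
  comp <- largest_component(foramen_mask)
  poly <- mask_polygons(comp)[[1]]
  polygon_width_profile(poly, ref, n_lines)
}

#' Derive a landmark set from per-structure masks
#'
#' Implements the post-segmentation landmark logic: tuberosity points from
#' the pelvis mask, femoral-head contours, sourcil extents measured in the
#' reference-line frame, and foramen outlines. The midline column is the mean
#' x of the two femoral-head circle centers when both heads are present,
#' otherwise the image center column.
#'
#' @param ms A `mask_set`.
#' @param n_contour_points Contour points per femoral head.
#' @param convention Laterality display convention.
#' @return A `landmark_set` (foramen outlines as sub-pixel boundary polygons).
#' @export
landmarks_from_masks <- function(ms, n_contour_points = 64L,
                                 convention = "right_on_left") {
  stopifnot(inherits(ms, "mask_set"))
  m <- ms$masks
  if (is.null(m$pelvis)) stop("missing mandatory mask: pelvis")

  contours <- list()
  for (side in c("right", "left")) {
    hm <- m[[sprintf("femoral_head_%s", side)]]
    if (!is.null(hm) && sum(hm) > 0)
      contours[[side]] <- extract_head_contour(hm, n_contour_points)
  }
  if (length(contours) == 2L) {
    centers <- vapply(contours, function(ct)
      fit_circle_least_squares(ct)$center[1], numeric(1))
    midline <- mean(centers)
  } else {
    midline <- (ms$shape[2] + 1) / 2
  }

  tubs <- extract_tuberosity_points(m$pelvis, midline, convention)
  ref <- make_reference_line(tubs$right, tubs$left)

  sourcils <- list()
  for (side in c("right", "left")) {
    sm <- m[[sprintf("sourcil_%s", side)]]
    if (!is.null(sm) && sum(sm) > 0)
      sourcils[[side]] <- extract_sourcil_extents(sm, ref, side, convention)
  }
  foramina <- list()
  for (side in c("right", "left")) {
    fm <- m[[sprintf("foramen_%s", side)]]
    if (!is.null(fm) && sum(fm) > 0)
      foramina[[side]] <- mask_polygons(largest_component(fm))[[1]]
  }

  landmark_set(
    tuberosity_inferior_right = tubs$right,
    tuberosity_inferior_left = tubs$left,
    femoral_head_contour_right = contours$right,
    femoral_head_contour_left = contours$left,
    sourcil_medial_right = sourcils$right$medial,
    sourcil_lateral_right = sourcils$right$lateral,
    sourcil_medial_left = sourcils$left$medial,
    sourcil_lateral_left = sourcils$left$lateral,
    foramen_outline_right = foramina$right,
    foramen_outline_left = foramina$left,
    pixel_spacing_mm = ms$pixel_spacing_mm,
    laterality_convention = convention,
    image_id = ms$image_id
  )
}

#' Measure a radiograph directly from its masks
#'
#' Convenience composition of [landmarks_from_masks()] and [measure_hips()].
#'
#' @inheritParams landmarks_from_masks
#' @return A `hip_measurements`.
#' @export
measure_hips_from_masks <- function(ms, n_contour_points = 64L,
                                    convention = "right_on_left") {
  measure_hips(landmarks_from_masks(ms, n_contour_points, convention))
}
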