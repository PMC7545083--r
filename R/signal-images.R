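# Procedurally drawn stand-in signal images ------------------------------
#
# The pipeline needs two face-like and two flower-like grayscale signal
# images. Photographic originals are not redistributable, so the package
# ships synthetic stand-ins: schematic line-art rasterised directly at the
# standardised signal size (height 150 px; width 110 px for faces, 120 px
# for flowers at defaults). They carry the features that matter for the
# pipeline -- bilateral symmetry, dark configural strokes on a mid-grey
# ground, category-distinct layout -- not photographic realism.

# Rasterise a set of ink marks onto a grey ground. Marks are lists with a
# signed distance-like membership test evaluated on normalised coordinates
# (x in [-1, 1] across width, y in [-1, 1] down height).
rasterize_marks <- function(height, width, marks,
                            background = 150, ink = 55) {
  xs <- seq(-1, 1, length.out = width)
  ys <- seq(-1, 1, length.out = height)
  x <- matrix(xs, height, width, byrow = TRUE)
  y <- matrix(ys, height, width)
  img <- matrix(background, height, width)
  for (m in marks) img[m(x, y)] <- ink
  img
}

ellipse_ring <- function(cx, cy, rx, ry, thickness = 0.08) {
  function(x, y) {
    d <- sqrt(((x - cx) / rx)^2 + ((y - cy) / ry)^2)
    abs(d - 1) < thickness
  }
}

ellipse_fill <- function(cx, cy, rx, ry) {
  function(x, y) ((x - cx) / rx)^2 + ((y - cy) / ry)^2 <= 1
}

arc_stroke <- function(cx, cy, rx, ry, thickness, ymin, ymax) {
  function(x, y) {
    d <- sqrt(((x - cx) / rx)^2 + ((y - cy) / ry)^2)
    abs(d - 1) < thickness & y >= ymin & y <= ymax
  }
}

bar_stroke <- function(x0, x1, y0, y1) {
  function(x, y) x >= x0 & x <= x1 & y >= y0 & y <= y1
}

# Rotated-ellipse petal around a centre, at angle theta (radians).
petal_fill <- function(cx, cy, len, wid, theta) {
  function(x, y) {
    u <- cos(theta) * (x - cx) + sin(theta) * (y - cy)
    v <- -sin(theta) * (x - cx) + cos(theta) * (y - cy)
    ((u - len / 2) / (len / 2))^2 + (v / (wid / 2))^2 <= 1
  }
}

draw_face <- function(height, width, identity) {
  eye_dx <- if (identity == 1L) 0.38 else 0.30
  eye_ry <- if (identity == 1L) 0.055 else 0.075
  mouth_w <- if (identity == 1L) 0.42 else 0.34
  marks <- list(
    ellipse_ring(0, 0, 0.88, 0.92, thickness = 0.05),
    ellipse_fill(-eye_dx, -0.28, 0.13, eye_ry),
    ellipse_fill(+eye_dx, -0.28, 0.13, eye_ry),
    ellipse_ring(-eye_dx, -0.30, 0.22, 0.14, thickness = 0.12),
    ellipse_ring(+eye_dx, -0.30, 0.22, 0.14, thickness = 0.12),
    bar_stroke(-0.035, 0.035, -0.18, 0.16),
    arc_stroke(0, 0.12, mouth_w, 0.38, 0.05, ymin = 0.34, ymax = 0.60)
  )
  rasterize_marks(height, width, marks)
}

draw_flower <- function(height, width, identity) {
  n_petals <- if (identity == 1L) 5L else 6L
  rot0 <- if (identity == 1L) -pi / 2 else -pi / 2 + pi / 6
  marks <- list()
  for (k in seq_len(n_petals)) {
    theta <- rot0 + (k - 1) * 2 * pi / n_petals
    marks[[length(marks) + 1L]] <-
      petal_fill(0, -0.30, len = 1.05, wid = 0.36, theta = theta)
  }
  # petal interiors lightened by re-inking rings on top
  rings <- lapply(seq_len(n_petals), function(k) {
    theta <- rot0 + (k - 1) * 2 * pi / n_petals
    m <- petal_fill(0, -0.30, len = 0.80, wid = 0.22, theta = theta)
    function(x, y) m(x, y)
  })
  img <- rasterize_marks(height, width, marks)
  for (m in rings) img[m(matrix(seq(-1, 1, length.out = width),
                                height, width, byrow = TRUE),
                        matrix(seq(-1, 1, length.out = height),
                               height, width))] <- 120
  centre <- ellipse_fill(0, -0.30, 0.20, 0.16)
  stalk <- bar_stroke(-0.04, 0.04, -0.30, 0.95)
  for (m in list(stalk, centre)) {
    img[m(matrix(seq(-1, 1, length.out = width), height, width, byrow = TRUE),
          matrix(seq(-1, 1, length.out = height), height, width))] <- 55
  }
  img
}

#' Synthetic stand-in signal images
#'
#' Draws the package's four synthetic signal images (two schematic faces,
#' two schematic flowers) as grayscale matrices at the requested signal
#' height, with category-dependent widths scaled in proportion (110:150
#' for faces, 120:150 for flowers at the default geometry).
#'
#' @param height Signal image height in pixels.
#' @param face_width,flower_width Category widths in pixels.
#' @return A named list of four numeric matrices:
#'   `face_1`, `face_2`, `flower_1`, `flower_2`.
#' @examples
#' imgs <- make_signal_images(height = 60, face_width = 44, flower_width = 48)
#' dim(imgs$face_1)
#' @export
make_signal_images <- function(height = 150L,
                               face_width = round(height * 110 / 150),
                               flower_width = round(height * 120 / 150)) {
  height <- as.integer(height)
  list(
    face_1 = draw_face(height, as.integer(face_width), 1L),
    face_2 = draw_face(height, as.integer(face_width), 2L),
    flower_1 = draw_flower(height, as.integer(flower_width), 1L),
    flower_2 = draw_flower(height, as.integer(flower_width), 2L)
  )
}

# Separable bilinear resampling of a matrix to new dimensions.
bilinear_resize <- function(img, new_height, new_width) {
  h <- nrow(img); w <- ncol(img)
  if (new_height == h && new_width == w) return(img)
  row_pos <- if (h == 1L) rep(1, new_height) else
    seq(1, h, length.out = new_height)
  col_pos <- if (w == 1L) rep(1, new_width) else
    seq(1, w, length.out = new_width)
  tmp <- apply(img, 2, function(colv) {
    if (h == 1L) rep(colv, new_height) else
      stats::approx(seq_len(h), colv, xout = row_pos)$y
  })
  tmp <- matrix(tmp, nrow = new_height)
  out <- t(apply(tmp, 1, function(rowv) {
    if (w == 1L) rep(rowv, new_width) else
      stats::approx(seq_len(w), rowv, xout = col_pos)$y
  }))
  matrix(out, nrow = new_height)
}

#' Standardise a raw signal image
#'
#' Prepares a grayscale signal image for embedding: rescales it (bilinear,
#' aspect-preserving) to exactly `target_height` pixels high and shifts its
#' luminance so the mean matches `reference_mean` -- conventionally the
#' average mean of all signal images in the set, so no image is detectable
#' by overall luminance.
#'
#' @param raw Non-empty numeric matrix (grayscale image).
#' @param target_height Output height in pixels.
#' @param reference_mean Target mean luminance.
#' @return Numeric matrix of height `target_height` with mean
#'   `reference_mean` (to well within 0.5 grey levels).
#' @examples
#' img <- prepare_signal_image(matrix(runif(100, 0, 255), 10), 20, 128)
#' nrow(img); mean(img)
#' @export
prepare_signal_image <- function(raw, target_height = 150L,
                                 reference_mean = 128) {
  stop_if_not_matrix(raw, "raw")
  target_height <- as.integer(target_height)
  if (target_height < 1L) abort("`target_height` must be at least 1.")
  new_width <- max(1L, as.integer(round(ncol(raw) * target_height / nrow(raw))))
  out <- bilinear_resize(raw, target_height, new_width)
  out + (reference_mean - mean(out))
}

#' Prepared default signal images
#'
#' The four stand-in signal images at the geometry's standardised height,
#' mean-luminance matched to their cross-image average (mirroring how a
#' photographic set would be normalised before embedding).
#'
#' @inheritParams angular_size
#' @return Named list of four matrices, all with equal mean luminance.
#' @export
default_signal_images <- function(geometry = geometry_config()) {
  h <- geometry$signal_height_px
  raw <- make_signal_images(height = h)
  reference <- mean(vapply(raw, mean, numeric(1)))
  lapply(raw, prepare_signal_image, target_height = h,
         reference_mean = reference)
}
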