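#' Construct a 68-point facial landmark set
#'
#' Landmarks follow the standard 68-point annotation scheme used by common
#' landmark detectors: jaw 1-17, eyebrows 18-27, nose 28-36, eyes 37-48
#' (right eye 37-42, left eye 43-48, "left"/"right" being the subject's),
#' mouth 49-68. Coordinates are in full-image pixels with the origin at the
#' top-left corner, x growing rightwards and y downwards. Indexing in the
#' public API is 1-based and matches that scheme.
#'
#' @param points numeric 68 x 2 matrix (columns x, y) or a length-136 vector
#'   ordered x1, y1, ..., x68, y68.
#' @return A `landmark_set`: a 68 x 2 numeric matrix with columns `x`, `y`.
#' @export
landmark_set <- function(points) {
  if (is.numeric(points) && is.null(dim(points))) {
    if (length(points) != 136L)
      stop_gaze("landmark vector must have length 136, got %d", length(points),
                class = "landmark_error")
    points <- matrix(points, ncol = 2L, byrow = TRUE)
  }
  points <- as.matrix(points)
  if (!is.numeric(points) || nrow(points) != 68L || ncol(points) != 2L)
    stop_gaze("landmarks must be a 68 x 2 numeric matrix",
              class = "landmark_error")
  if (!all(is.finite(points)))
    stop_gaze("landmarks contain non-finite coordinates",
              class = "landmark_error")
  if (any(points < 0))
    stop_gaze("landmark coordinates must be non-negative (origin is top-left)",
              class = "landmark_error")
  dimnames(points) <- list(NULL, c("x", "y"))
  structure(points, class = c("landmark_set", "matrix", "array"))
}

#' @export
print.landmark_set <- function(x, ...) {
  cat("<landmark_set> 68 points, x in [", round(min(x[, 1]), 1), ",",
      round(max(x[, 1]), 1), "], y in [", round(min(x[, 2]), 1), ",",
      round(max(x[, 2]), 1), "]\n")
  invisible(x)
}

# Landmark index groups of the 68-point scheme.
LM_JAW <- 1:17
LM_BROWS <- 18:27
LM_NOSE <- 28:36
LM_RIGHT_EYE <- 37:42
LM_LEFT_EYE <- 43:48
LM_EYES <- 37:48
LM_MOUTH <- 49:68
LM_STABLE_DEFAULT <- 1:36  # jaw + brows + nose; 68 - 12 eye - 20 mouth points

#' Read / write per-frame landmark CSV files
#'
#' One row per frame: `frame_id`, then `x1,y1,...,x68,y68` in scheme order.
#' A header is required.
#'
#' @param path file path.
#' @return `read_landmarks_csv()`: a named list of `landmark_set` objects,
#'   names are the frame ids.
#' @export
read_landmarks_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) != 137L)
    stop_gaze("landmark CSV must have 137 columns (frame_id + 68 x,y pairs), got %d",
              ncol(df), class = "landmark_error")
  out <- lapply(seq_len(nrow(df)), function(i)
    landmark_set(as.numeric(df[i, -1L])))
  names(out) <- as.character(df[[1L]])
  out
}

#' @rdname read_landmarks_csv
#' @param landmarks named list of `landmark_set` objects (names = frame ids).
#' @export
write_landmarks_csv <- function(landmarks, path) {
  stopifnot(is.list(landmarks), length(landmarks) > 0L)
  rows <- t(vapply(landmarks, function(lm) as.numeric(t(unclass(lm))),
                   numeric(136L)))
  df <- data.frame(frame_id = names(landmarks), rows, check.names = FALSE)
  names(df)[-1L] <- as.vector(rbind(paste0("x", 1:68), paste0("y", 1:68)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Convert an image to a grayscale matrix
#'
#' Accepts a numeric matrix (already gray, any range), or an H x W x 3 array
#' (RGB in \[0,1\] or \[0,255\]). Color is converted with ITU-R BT.601 luma
#' weights (0.299, 0.587, 0.114). Output is a matrix indexed
#' `[row = y, col = x]` on the 0-255 gray scale.
#'
#' @param image matrix or 3-channel array.
#' @export
as_gray <- function(image) {
  if (is.matrix(image)) {
    g <- image
  } else if (is.array(image) && length(dim(image)) == 3L && dim(image)[3] >= 3L) {
    g <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  } else {
    stop_gaze("image must be a matrix or an H x W x 3 array", class = "image_error")
  }
  if (max(g, na.rm = TRUE) <= 1) g <- g * 255
  g
}

#' Extract and preprocess an eye region of interest
#'
#' The ROI rectangle is taken from the twelve eye landmarks: for the
#' subject's left eye the horizontal bounds are the x-coordinates of points
#' 43 (inner corner) and 46 (outer corner); the vertical bounds are
#' `min(P44y, P45y) - 3` and `max(P47y, P48y) + 3`. The right eye uses
#' points 37/40 and 38,39/41,42 analogously. The 3-pixel vertical margins
#' are applied in original-image pixels, before magnification. The crop is
#' converted to gray, magnified by `scale` (bilinear by default), and then
#' grayscale-eroded with a 1-pixel-radius disk element (the 3 x 3 cross) to
#' suppress isolated bright noise such as specular glints.
#'
#' @param image full image (matrix or RGB array; see [as_gray()]).
#' @param landmarks a [landmark_set()].
#' @param side `"left"` or `"right"` (the subject's side).
#' @param scale integer magnification factor, default 2.
#' @param interp `"bilinear"` (default) or `"nearest"` magnification filter.
#' @param erode apply the 1-pixel disk grayscale erosion (default `TRUE`).
#' @return An `eye_roi` object: list with `image` (magnified, eroded gray
#'   matrix), `side`, `origin` (x, y of the ROI's top-left in full-image
#'   pixels), `scale`, `N` (width, px, post-magnification), `M` (height).
#' @export
extract_eye_roi <- function(image, landmarks, side = c("left", "right"),
                            scale = 2L, interp = c("bilinear", "nearest"),
                            erode = TRUE) {
  side <- match.arg(side)
  interp <- match.arg(interp)
  stopifnot(inherits(landmarks, "landmark_set"), scale >= 1L)
  g <- as_gray(image)
  H <- nrow(g); W <- ncol(g)
  p <- unclass(landmarks)

  if (side == "left") {
    xl <- p[43, 1]; xr <- p[46, 1]
    yt <- min(p[44, 2], p[45, 2]) - 3
    yb <- max(p[47, 2], p[48, 2]) + 3
  } else {
    xl <- p[37, 1]; xr <- p[40, 1]
    yt <- min(p[38, 2], p[39, 2]) - 3
    yb <- max(p[41, 2], p[42, 2]) + 3
  }
  if (xr <= xl || yb <= yt)
    stop_gaze("degenerate %s-eye ROI: x [%0.1f, %0.1f], y [%0.1f, %0.1f]",
              side, xl, xr, yt, yb, class = "roi_error")

  ix <- c(max(1L, floor(xl)), min(W, ceiling(xr)))
  iy <- c(max(1L, floor(yt)), min(H, ceiling(yb)))
  if (ix[1] > floor(xl) || ix[2] < ceiling(xr) ||
      iy[1] > floor(yt) || iy[2] < ceiling(yb))
    warning(sprintf("%s-eye ROI clipped to image bounds", side))
  crop <- g[iy[1]:iy[2], ix[1]:ix[2], drop = FALSE]

  roi_img <- magnify_gray(crop, scale, interp)
  if (erode) roi_img <- erode_gray(roi_img)

  eye_roi(roi_img, side = side, origin = c(ix[1], iy[1]), scale = scale)
}

#' Construct an eye ROI object from a prepared image
#'
#' Low-level constructor used by [extract_eye_roi()] and by the synthetic
#' fixtures (which render ROI-resolution images directly, `scale = 1`).
#'
#' @param image gray matrix, 0-255, indexed `[y, x]`.
#' @param side `"left"` or `"right"`.
#' @param origin ROI top-left corner in full-image pixels `(x, y)`.
#' @param scale magnification factor relating ROI pixels to image pixels.
#' @export
eye_roi <- function(image, side = "left", origin = c(1, 1), scale = 1L) {
  stopifnot(is.matrix(image), is_point(origin), scale >= 1L)
  if (nrow(image) < 1L || ncol(image) < 1L)
    stop_gaze("empty ROI image", class = "roi_error")
  structure(list(image = image, side = side, origin = as.numeric(origin),
                 scale = as.numeric(scale),
                 N = ncol(image), M = nrow(image)),
            class = "eye_roi")
}

#' @export
print.eye_roi <- function(x, ...) {
  cat(sprintf("<eye_roi> %s eye, %d x %d px (x%g), origin (%g, %g)\n",
              x$side, x$N, x$M, x$scale, x$origin[1], x$origin[2]))
  invisible(x)
}

# Magnify a gray matrix by an integer factor. EBImage stores images [x, y],
# our matrices are [y, x]; transpose on the way in and out.
magnify_gray <- function(mat, scale, interp = "bilinear") {
  if (scale == 1L) return(mat)
  img <- EBImage::Image(t(mat) / 255)
  out <- EBImage::resize(img, w = ncol(mat) * scale, h = nrow(mat) * scale,
                         filter = if (interp == "nearest") "none" else "bilinear")
  t(EBImage::imageData(out)) * 255
}

# Grayscale erosion with the radius-1 Euclidean disk (3 x 3 cross).
erode_gray <- function(mat) {
  img <- EBImage::Image(t(mat) / 255)
  t(EBImage::imageData(EBImage::erode(img, EBImage::makeBrush(3, "diamond")))) * 255
}

#' Map ROI coordinates back to full-image coordinates
#'
#' Iris centers are found in the magnified ROI but eye vectors live in
#' full-image pixels: `p_image = origin + p_roi / scale`.
#'
#' @param roi an `eye_roi`.
#' @param p_roi point `(x, y)` in ROI pixels.
#' @export
roi_to_image_coords <- function(roi, p_roi) {
  stopifnot(inherits(roi, "eye_roi"), is_point(p_roi))
  roi$origin + p_roi / roi$scale
}

#' @rdname roi_to_image_coords
#' @param p_image point `(x, y)` in full-image pixels.
#' @export
image_to_roi_coords <- function(roi, p_image) {
  stopifnot(inherits(roi, "eye_roi"), is_point(p_image))
  (p_image - roi$origin) * roi$scale
}

#' Compute the stable anchor point
#'
#' The anchor point is the arithmetic mean of a subset of facial landmarks
#' chosen to be rigid: by default the 36 jaw, brow and nose points (all 68
#' minus the 12 eye and 20 mouth points, which move with eye rotation and
#' speech). Being an average of many points, it is much less sensitive to
#' per-landmark jitter than a single eye-corner reference, and it stays
#' defined when individual landmarks are occluded by head rotation.
#'
#' @param landmarks a [landmark_set()].
#' @param stable_idx indices of the stable subset (default 1-36).
#' @return An `anchor_point`: numeric `(x, y)` with attribute `n`.
#' @export
compute_anchor <- function(landmarks, stable_idx = LM_STABLE_DEFAULT) {
  stopifnot(inherits(landmarks, "landmark_set"))
  stable_idx <- as.integer(stable_idx)
  if (length(stable_idx) < 3L)
    stop_gaze("need at least 3 stable landmarks, got %d", length(stable_idx),
              class = "anchor_error")
  if (any(stable_idx < 1L | stable_idx > 68L))
    stop_gaze("stable landmark indices out of range 1..68", class = "anchor_error")
  p <- unclass(landmarks)[stable_idx, , drop = FALSE]
  structure(colMeans(p), n = length(stable_idx), class = "anchor_point")
}

#' @export
print.anchor_point <- function(x, ...) {
  cat(sprintf("<anchor_point> (%0.2f, %0.2f), n = %d landmarks\n",
              x[1], x[2], attr(x, "n")))
  invisible(x)
}

#' Read / write grayscale PNG images
#'
#' Thin wrappers over the png codec mapping between files and the package's
#' 0-255 gray matrix convention (`[row = y, col = x]`).
#'
#' @param path file path; @param image gray matrix 0-255.
#' @export
write_gray_png <- function(image, path) {
  png::writePNG(clamp(image, 0, 255) / 255, path)
  invisible(path)
}

#' @rdname write_gray_png
#' @export
read_gray_png <- function(path) {
  as_gray(png::readPNG(path))
}
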