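#' Specification of a synthetic eye ROI image
#'
#' Describes a low-resolution eye crop the way the iris locator sees one: a
#' dark iris disk on a lighter sclera/skin background, optionally occluded
#' from above by an eyelid band, with Gaussian pixel noise and an optional
#' specular highlight. The default iris radius is a quarter of the ROI
#' width, matching adult eye anatomy (iris radius about 7 mm against an
#' eye-region width close to the 24-26 mm eyeball diameter).
#'
#' @param width,height ROI size in pixels.
#' @param center true iris center `(x, y)`, pixels (1-based pixel centers).
#' @param iris_radius iris radius, px; default `round(0.25 * width)`.
#' @param sclera_level,iris_level gray levels 0-255; iris must be darker.
#' @param eyelid_cover_fraction fraction of the iris' vertical extent
#'   occluded from the top, in \[0, 1\].
#' @param eyelid_level gray level of the lid band (default: sclera level).
#' @param noise_sigma Gaussian noise standard deviation, gray levels.
#' @param specular_dot add a small saturated highlight inside the iris.
#' @param antialias soft 1-px rim on the iris edge instead of a hard edge.
#' @param seed RNG seed; all stochastic draws flow from it.
#' @export
eye_spec <- function(width = 60L, height = 36L,
                     center = c(width / 2, height / 2),
                     iris_radius = round_half_up(0.25 * width),
                     sclera_level = 200, iris_level = 60,
                     eyelid_cover_fraction = 0, eyelid_level = sclera_level,
                     noise_sigma = 0, specular_dot = FALSE,
                     antialias = FALSE, seed = 1L) {
  spec <- list(width = as.integer(width), height = as.integer(height),
               center = as.numeric(center), iris_radius = as.numeric(iris_radius),
               sclera_level = sclera_level, iris_level = iris_level,
               eyelid_cover_fraction = eyelid_cover_fraction,
               eyelid_level = eyelid_level,
               noise_sigma = noise_sigma, specular_dot = isTRUE(specular_dot),
               antialias = isTRUE(antialias), seed = as.integer(seed))
  if (spec$iris_level >= spec$sclera_level)
    stop_gaze("iris must be darker than the sclera (%g >= %g)",
              spec$iris_level, spec$sclera_level, class = "spec_error")
  if (spec$iris_radius <= 0 || spec$iris_radius >= spec$width / 2)
    stop_gaze("iris radius %g out of (0, width/2)", spec$iris_radius,
              class = "spec_error")
  if (spec$center[1] < 1 || spec$center[1] > spec$width ||
      spec$center[2] < 1 || spec$center[2] > spec$height)
    stop_gaze("true center (%g, %g) outside the %d x %d image",
              spec$center[1], spec$center[2], spec$width, spec$height,
              class = "spec_error")
  if (spec$eyelid_cover_fraction < 0 || spec$eyelid_cover_fraction > 1)
    stop_gaze("eyelid_cover_fraction must be in [0, 1]", class = "spec_error")
  structure(spec, class = "eye_spec")
}

#' Render a synthetic eye ROI
#'
#' Deterministic for a fixed seed. Gray levels are clamped to \[0, 255\].
#'
#' @param spec an [eye_spec()].
#' @return list with `image` (gray matrix `[y, x]`), `true_center` `(x, y)`
#'   and the `spec`.
#' @export
render_eye_roi <- function(spec) {
  stopifnot(inherits(spec, "eye_spec"))
  N <- spec$width; M <- spec$height
  x0 <- spec$center[1]; y0 <- spec$center[2]; r <- spec$iris_radius
  xs <- matrix(seq_len(N), M, N, byrow = TRUE)
  ys <- matrix(seq_len(M), M, N)
  d <- sqrt((xs - x0)^2 + (ys - y0)^2)
  if (spec$antialias) {
    w <- clamp(r + 0.5 - d, 0, 1)  # approximate 1-px linear coverage ramp
    img <- spec$sclera_level + (spec$iris_level - spec$sclera_level) * w
  } else {
    img <- matrix(spec$sclera_level, M, N)
    img[d <= r] <- spec$iris_level
  }
  if (spec$eyelid_cover_fraction > 0) {
    lid_to <- floor(y0 - r + 2 * r * spec$eyelid_cover_fraction)
    if (lid_to >= 1) img[seq_len(min(lid_to, M)), ] <- spec$eyelid_level
  }
  if (spec$specular_dot) {
    sx <- round(x0 + r / 3); sy <- round(y0 - r / 3)
    px <- clamp(sx + 0:1, 1, N); py <- clamp(sy + 0:1, 1, M)
    img[py, px] <- 255
  }
  if (spec$noise_sigma > 0) {
    img <- with_seed(spec$seed,
                     img + matrix(stats::rnorm(M * N, 0, spec$noise_sigma), M, N))
  }
  list(image = clamp(img, 0, 255), true_center = spec$center, spec = spec)
}

#' Synthetic iris-localization benchmark
#'
#' Generates `n` items, each a left/right pair of eye ROIs with known true
#' centers placed in a common virtual full-image frame (so the normalized
#' error, which divides by the inter-center distance, is well defined).
#' Geometry is drawn per item: iris radius ratio in \[0.23, 0.27\] of the
#' ROI width, center within the middle of the ROI and within 2 px of the
#' vertical centerline (as in real tight eye crops), inter-center distance
#' around 60 full-image px.
#'
#' @param n number of items.
#' @param noise_sigma,eyelid_cover_fraction passed to every [eye_spec()].
#' @param seed master seed; item seeds are derived from it.
#' @return list of items: `left`/`right` ([eye_roi()]), `truth_left`/
#'   `truth_right` (full-image px), `d` (inter-center distance).
#' @export
make_iris_benchmark <- function(n = 50, noise_sigma = 0,
                                eyelid_cover_fraction = 0, seed = 1L) {
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      N <- sample(52:68, 1); M <- sample(32:42, 1)
      mk <- function(side, ox) {
        ctr <- c(stats::runif(1, 0.4 * N, 0.6 * N),
                 floor(M / 2) + stats::runif(1, -2, 2))
        sp <- eye_spec(N, M, center = ctr,
                       iris_radius = round_half_up(stats::runif(1, 0.23, 0.27) * N),
                       noise_sigma = noise_sigma,
                       eyelid_cover_fraction = eyelid_cover_fraction,
                       seed = sample.int(.Machine$integer.max, 1))
        rnd <- render_eye_roi(sp)
        roi <- eye_roi(rnd$image, side = side, origin = c(ox, 0), scale = 1L)
        list(roi = roi, truth = roi_to_image_coords(roi, rnd$true_center))
      }
      d <- stats::runif(1, 55, 70)
      l <- mk("left", 0); r <- mk("right", d)
      list(left = l$roi, right = r$roi,
           truth_left = l$truth, truth_right = r$truth,
           d = vnorm(l$truth - r$truth))
    })
  })
}

#' Generic 68-point 3D face template
#'
#' A schematic rigid face in the head frame of [default_face_model()]
#' (mm; nose tip at the origin, x right, y down, z away from the camera).
#' Rows 9, 31, 37, 46, 49 and 55 coincide exactly with the six-point pose
#' model. Used to project ground-truth landmark layouts for pose and
#' pipeline round-trip tests; it is a plausible geometry, not a measured
#' head.
#'
#' @return 68 x 3 matrix (columns x, y, z).
#' @export
face_template_3d <- function() {
  P <- matrix(NA_real_, 68, 3)
  six <- default_face_model()
  # jaw 1-17: ellipse arc through the chin, ears swept back
  tt <- (1:17 - 9) / 8
  P[1:17, ] <- cbind(65 * sin(tt * pi / 2), 63.6 * cos(tt * pi / 2),
                     12.5 + 40 * tt^2)
  # brows 18-27
  bx <- c(-52, -43, -34, -26, -18)
  by <- c(-46, -48, -49, -48, -46)
  P[18:22, ] <- cbind(bx, by, 20)
  P[23:27, ] <- cbind(-rev(bx), rev(by), 20)
  # nose bridge 28-31 and base 32-36
  P[28:31, ] <- cbind(0, c(-27, -18, -9, 0), c(10, 6, 3, 0))
  P[32:36, ] <- cbind(c(-12, -6, 0, 6, 12), c(8, 10, 11, 10, 8),
                      c(8, 6, 5, 6, 8))
  # right eye 37-42 (image left), left eye 43-48
  P[37:42, ] <- cbind(c(-45, -38, -28, -20, -28, -37),
                      c(-34.5, -38, -38, -33, -30, -30), 27.5)
  P[43:48, ] <- cbind(c(20, 28, 38, 45, 37, 28),
                      c(-33, -38, -38, -34.5, -30, -30), 27.5)
  # mouth: outer ring 49-60, inner ring 61-68
  th <- seq(180, -150, by = -30) * pi / 180  # 49..60
  P[49:60, ] <- cbind(27.5 * cos(th), 33.5 - 10 * sin(th), 10)
  ti <- seq(180, -135, by = -45) * pi / 180  # 61..68
  P[61:68, ] <- cbind(17 * cos(ti), 33.5 - 4 * sin(ti), 12)
  P[POSE_LANDMARKS, ] <- six
  colnames(P) <- c("x", "y", "z")
  P
}

#' Project the face template to a ground-truth landmark layout
#'
#' @param pose a [head_pose()] (its translation places the head; depth must
#'   be positive).
#' @param camera a [camera_model()]; default: 640 x 480 webcam intrinsics.
#' @param template 68 x 3 template, default [face_template_3d()].
#' @return a [landmark_set()] consistent with the pose.
#' @export
render_face_landmarks <- function(pose, camera = camera_from_image_size(640, 480),
                                  template = face_template_3d()) {
  stopifnot(inherits(pose, "head_pose"))
  if (pose$t[3] <= 0)
    stop_gaze("translation depth must be positive to keep the face in front of the camera",
              class = "projection_error")
  landmark_set(project_points(template, pose, camera))
}
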