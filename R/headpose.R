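#' Pinhole camera model
#'
#' Zero-distortion pinhole intrinsics. For an uncalibrated webcam the usual
#' approximation is focal length = image width (in pixels) and principal
#' point = image center; [camera_from_image_size()] builds that.
#'
#' @param f focal length, px.
#' @param cx,cy principal point, px.
#' @export
camera_model <- function(f, cx, cy) {
  stopifnot(f > 0, is.finite(cx), is.finite(cy))
  structure(list(f = f, cx = cx, cy = cy), class = "camera_model")
}

#' @rdname camera_model
#' @param width,height image size in pixels.
#' @export
camera_from_image_size <- function(width, height) {
  camera_model(f = width, cx = width / 2, cy = height / 2)
}

# Indices of the six rigid landmarks used for pose: chin, nose tip,
# subject-right outer eye corner, subject-left outer eye corner, and the
# two mouth corners.
POSE_LANDMARKS <- c(9L, 31L, 37L, 46L, 49L, 55L)

#' Generic rigid 3D face model for the six pose landmarks
#'
#' Coordinates in mm, head frame aligned with the camera frame at identity
#' pose: x to the camera's right, y down, z away from the camera. The nose
#' tip is the origin; all other points lie behind it (positive z). The
#' model is bilaterally symmetric about the x = 0 plane. Values are
#' rounded averages of adult facial anthropometry; the pose solver only
#' needs a rigid shape of roughly correct proportions.
#'
#' @return 6 x 3 matrix, rows named by landmark index
#'   (9, 31, 37, 46, 49, 55), columns `x`, `y`, `z`.
#' @export
default_face_model <- function() {
  m <- rbind(
    `9`  = c(0, 63.6, 12.5),      # chin
    `31` = c(0, 0, 0),            # nose tip
    `37` = c(-45, -34.5, 27.5),   # subject-right outer eye corner
    `46` = c(45, -34.5, 27.5),    # subject-left outer eye corner
    `49` = c(-27.5, 33.5, 10),    # mouth corner (image left)
    `55` = c(27.5, 33.5, 10)      # mouth corner (image right)
  )
  colnames(m) <- c("x", "y", "z")
  m
}

#' Rotation matrix from pitch/yaw/roll Euler angles
#'
#' Convention (fixed throughout the package): intrinsic rotations applied
#' in the order pitch about x, then yaw about y, then roll about z, i.e.
#' `R = Rx(pitch) %*% Ry(yaw) %*% Rz(roll)`, in the camera frame with x
#' right, y down, z forward. Angles in degrees.
#'
#' @param pitch,yaw,roll angles in degrees.
#' @export
euler_to_rotmat <- function(pitch, yaw, roll) {
  p <- deg2rad(pitch); y <- deg2rad(yaw); r <- deg2rad(roll)
  Rx <- rbind(c(1, 0, 0), c(0, cos(p), -sin(p)), c(0, sin(p), cos(p)))
  Ry <- rbind(c(cos(y), 0, sin(y)), c(0, 1, 0), c(-sin(y), 0, cos(y)))
  Rz <- rbind(c(cos(r), -sin(r), 0), c(sin(r), cos(r), 0), c(0, 0, 1))
  Rx %*% Ry %*% Rz
}

#' Construct a head pose
#'
#' @param pitch,yaw,roll Euler angles in degrees (see [euler_to_rotmat()]),
#'   each normalized to (-180, 180].
#' @param t translation (mm, camera frame), length 3.
#' @param rmse reprojection root-mean-square error in pixels (optional).
#' @export
head_pose <- function(pitch, yaw, roll, t = c(0, 0, 600), rmse = NA_real_) {
  wrap <- function(a) { a <- (a + 180) %% 360 - 180; if (a == -180) 180 else a }
  structure(list(pitch = wrap(pitch), yaw = wrap(yaw), roll = wrap(roll),
                 t = as.numeric(t), rmse = rmse),
            class = "head_pose")
}

#' @export
print.head_pose <- function(x, ...) {
  cat(sprintf("<head_pose> pitch %0.2f, yaw %0.2f, roll %0.2f deg; t = (%0.1f, %0.1f, %0.1f) mm; RMSE %s px\n",
              x$pitch, x$yaw, x$roll, x$t[1], x$t[2], x$t[3],
              ifelse(is.na(x$rmse), "NA", sprintf("%0.3f", x$rmse))))
  invisible(x)
}

#' Project 3D model points through a camera
#'
#' `p_cam = R X + t`, `u = f x/z + cx`, `v = f y/z + cy`.
#'
#' @param points3d n x 3 matrix (mm).
#' @param pose a [head_pose()].
#' @param camera a [camera_model()].
#' @return n x 2 matrix of pixel coordinates.
#' @export
project_points <- function(points3d, pose, camera) {
  stopifnot(inherits(pose, "head_pose"), inherits(camera, "camera_model"))
  R <- euler_to_rotmat(pose$pitch, pose$yaw, pose$roll)
  pc <- t(R %*% t(points3d)) + matrix(pose$t, nrow(points3d), 3, byrow = TRUE)
  if (any(pc[, 3] <= 0))
    stop_gaze("model points at or behind the camera (z <= 0); check translation depth",
              class = "projection_error")
  cbind(camera$f * pc[, 1] / pc[, 3] + camera$cx,
        camera$f * pc[, 2] / pc[, 3] + camera$cy)
}

#' Estimate head pose from six facial landmarks
#'
#' Solves the 2D-3D point-correspondence problem for the six rigid
#' landmarks (chin 9, nose tip 31, outer eye corners 37/46, mouth corners
#' 49/55) against [default_face_model()]: Levenberg-Marquardt nonlinear
#' least squares on the reprojection residuals over (pitch, yaw, roll, t),
#' initialized from a weak-perspective guess (identity rotation, depth from
#' the ratio of model to image inter-ocular distance). Deterministic for a
#' fixed input.
#'
#' @param landmarks a [landmark_set()], or a 6 x 2 matrix of the six pose
#'   landmarks in scheme order (9, 31, 37, 46, 49, 55).
#' @param camera a [camera_model()].
#' @param model 6 x 3 model matrix, default [default_face_model()].
#' @return A [head_pose()] with the reprojection RMSE filled in.
#' @export
estimate_head_pose <- function(landmarks, camera, model = default_face_model()) {
  stopifnot(inherits(camera, "camera_model"))
  if (inherits(landmarks, "landmark_set")) {
    obs <- unclass(landmarks)[POSE_LANDMARKS, , drop = FALSE]
  } else {
    obs <- as.matrix(landmarks)
  }
  stopifnot(nrow(obs) == 6L, ncol(obs) == 2L)
  if (!all(is.finite(obs)))
    stop_gaze("non-finite pose landmarks", class = "pose_error")

  # degenerate (collinear) configurations have no pose information
  cen <- scale(obs, scale = FALSE)
  sv <- svd(cen, nu = 0, nv = 0)$d
  if (sv[2] < 1e-8 * max(sv[1], 1))
    stop_gaze("the six pose landmarks are collinear; pose is unobservable",
              class = "pose_error")

  # weak-perspective init: depth from inter-ocular distance ratio
  d_img <- vnorm(obs[4, ] - obs[3, ])
  d_mod <- vnorm(model[4, 1:2] - model[3, 1:2])
  tz0 <- camera$f * d_mod / max(d_img, 1e-6)
  tx0 <- (mean(obs[, 1]) - camera$cx) * tz0 / camera$f - mean(model[, 1])
  ty0 <- (mean(obs[, 2]) - camera$cy) * tz0 / camera$f - mean(model[, 2])

  resid <- function(par) {
    pose <- head_pose(par[1], par[2], par[3], t = par[4:6])
    proj <- tryCatch(project_points(model, pose, camera),
                     error = function(e) NULL)
    if (is.null(proj)) return(rep(1e6, 12))
    as.numeric(proj - obs)
  }
  fit <- minpack.lm::nls.lm(par = c(0, 0, 0, tx0, ty0, tz0), fn = resid,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200, ftol = 1e-15, ptol = 1e-12))
  par <- fit$par
  rmse <- sqrt(mean(resid(par)^2))
  if (!is.finite(rmse) || rmse > 1e5)
    stop_gaze("head-pose estimation diverged (RMSE = %g px)", rmse,
              class = "pose_error")
  head_pose(par[1], par[2], par[3], t = par[4:6], rmse = rmse)
}
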