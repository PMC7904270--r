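#' Screen geometry in the camera frame
#'
#' An affine description of the physical screen: a 3D origin (the screen
#' point with screen coordinates (0, 0), conventionally the top-left
#' corner), two unit axis vectors in mm, and a scale in mm per screen unit.
#' The default places a 520 x 320 mm screen in the z = 0 plane, centered
#' horizontally under the camera.
#'
#' @param origin 3D point (mm, camera frame) of screen coordinate (0, 0).
#' @param ex,ey unit vectors of the screen's horizontal/vertical axes.
#' @param mm_per_unit scale of the session's screen coordinates.
#' @param size screen extent `(width, height)` in screen units.
#' @export
screen_geometry <- function(origin = c(-260, 20, 0),
                            ex = c(1, 0, 0), ey = c(0, 1, 0),
                            mm_per_unit = 1, size = c(520, 320)) {
  stopifnot(length(origin) == 3, length(ex) == 3, length(ey) == 3,
            mm_per_unit > 0)
  ex <- ex / vnorm(ex); ey <- ey / vnorm(ey)
  structure(list(origin = as.numeric(origin), ex = as.numeric(ex),
                 ey = as.numeric(ey), mm_per_unit = mm_per_unit,
                 size = as.numeric(size)),
            class = "screen_geometry")
}

#' Map a point of regard to its 3D screen point
#'
#' `p = origin + g_h * mm_per_unit * ex + g_v * mm_per_unit * ey`.
#'
#' @param por `c(g_h, g_v)` in screen units.
#' @param geometry a [screen_geometry()].
#' @return 3D point (mm, camera frame).
#' @export
por_to_screen_3d <- function(por, geometry) {
  if (!inherits(geometry, "screen_geometry"))
    stop_gaze("missing or invalid screen geometry", class = "geometry_error")
  geometry$origin + por[1] * geometry$mm_per_unit * geometry$ex +
    por[2] * geometry$mm_per_unit * geometry$ey
}

#' @rdname por_to_screen_3d
#' @param p 3D point on the screen plane.
#' @export
screen_3d_to_por <- function(p, geometry) {
  if (!inherits(geometry, "screen_geometry"))
    stop_gaze("missing or invalid screen geometry", class = "geometry_error")
  d <- as.numeric(p) - geometry$origin
  c(g_h = sum(d * geometry$ex), g_v = sum(d * geometry$ey)) / geometry$mm_per_unit
}

#' Specification of a simulated gaze session
#'
#' Emulates a calibration/test recording: per-frame screen targets drawn
#' uniformly on the screen, per-eye eye vectors consistent with known
#' ground-truth mapping coefficients, a smooth head-pose trajectory, and
#' 3D eyeball/screen geometry for angular-error evaluation. Eye vectors are
#' generated in mapping space - the forward model is the same polynomial
#' family the fitting stage uses - so that coefficient recovery on
#' noise-free sessions is exact by construction.
#'
#' @param n_calib_frames,n_test_frames session phase lengths.
#' @param geometry a [screen_geometry()]; targets are drawn uniformly on
#'   `[0, size[1]] x [0, size[2]]`.
#' @param eyeballs list with `left`/`right` 3D eyeball centers (mm, camera
#'   frame). Subject's left eye is on the camera's +x side.
#' @param preset_h,preset_v generating presets per axis.
#' @param coeffs ground-truth coefficients: nested list
#'   `coeffs[[side]][[axis]]`, each a named vector over the preset's terms.
#'   Default: [default_true_coeffs()] for each side/axis.
#' @param head_pose_trajectory `n x 3` matrix (pitch, yaw, roll in degrees)
#'   or `NULL` for the default smooth sinusoidal sweep (amplitudes 10, 15,
#'   6 degrees with incommensurate periods).
#' @param pixel_noise_sigma Gaussian noise added to each eye-vector
#'   component, px.
#' @param undetected_fraction fraction of frames flagged as face-detection
#'   failures (excluded from calibration/testing, counted in TF only).
#' @param seed RNG seed.
#' @export
session_spec <- function(n_calib_frames = 1000L, n_test_frames = 500L,
                         geometry = screen_geometry(),
                         eyeballs = list(left = c(32, -30, 600),
                                         right = c(-32, -30, 600)),
                         preset_h = 4, preset_v = 2, coeffs = NULL,
                         head_pose_trajectory = NULL,
                         pixel_noise_sigma = 0, undetected_fraction = 0,
                         seed = 1L) {
  stopifnot(inherits(geometry, "screen_geometry"),
            n_calib_frames >= 1, n_test_frames >= 1,
            pixel_noise_sigma >= 0,
            undetected_fraction >= 0, undetected_fraction < 1)
  if (is.null(coeffs))
    coeffs <- list(
      left = list(h = default_true_coeffs(preset_h, "h", "left", geometry),
                  v = default_true_coeffs(preset_v, "v", "left", geometry)),
      right = list(h = default_true_coeffs(preset_h, "h", "right", geometry),
                   v = default_true_coeffs(preset_v, "v", "right", geometry)))
  for (side in c("left", "right")) for (ax in c("h", "v")) {
    terms <- mapping_terms(if (ax == "h") preset_h else preset_v)
    cf <- coeffs[[side]][[ax]]
    if (is.null(cf) || !all(terms %in% names(cf)))
      stop_gaze("coefficients for %s/%s do not cover the preset terms (%s): underdetermined",
                side, ax, paste(terms, collapse = ", "), class = "spec_error")
    if (!all(c("eh", "ev") %in% terms))
      stop_gaze("generating preset must include the linear eye-vector terms",
                class = "spec_error")
  }
  n_terms <- max(length(mapping_terms(preset_h)), length(mapping_terms(preset_v)))
  if (n_calib_frames < n_terms)
    stop_gaze("n_calib_frames (%d) below the number of mapping terms (%d): underdetermined",
              n_calib_frames, n_terms, class = "spec_error")
  structure(list(n_calib_frames = as.integer(n_calib_frames),
                 n_test_frames = as.integer(n_test_frames),
                 geometry = geometry, eyeballs = eyeballs,
                 preset_h = preset_h, preset_v = preset_v, coeffs = coeffs,
                 head_pose_trajectory = head_pose_trajectory,
                 pixel_noise_sigma = pixel_noise_sigma,
                 undetected_fraction = undetected_fraction,
                 seed = as.integer(seed)),
            class = "session_spec")
}

#' Default ground-truth mapping coefficients for simulation
#'
#' Chosen so that eye vectors span a realistic few tens of pixels over the
#' screen (dominant linear gains of 8-9 screen-mm per pixel), with small
#' quadratic/interaction curvature and moderate head-pose gains. The right
#' eye gets slightly different gains and intercept than the left so the two
#' eyes are genuinely distinct models.
#'
#' @param preset generating preset (1-6 or term list).
#' @param axis `"h"` or `"v"`; @param side `"left"` or `"right"`.
#' @param geometry a [screen_geometry()] (for the intercept at mid-screen).
#' @return named coefficient vector over the preset's terms.
#' @export
default_true_coeffs <- function(preset, axis = c("h", "v"),
                                side = c("left", "right"),
                                geometry = screen_geometry()) {
  axis <- match.arg(axis); side <- match.arg(side)
  base_h <- c(`1` = geometry$size[1] / 2, eh = 9, ev = 0.4, eh_ev = 0.012,
              eh2 = 0.02, ev2 = 0.01, hp = 0.3, hy = 2.0, hr = 0.2,
              hp2 = 0.004, hy2 = 0.006, hr2 = 0.002)
  base_v <- c(`1` = geometry$size[2] / 2, eh = 0.3, ev = 8, eh_ev = 0.01,
              eh2 = 0.01, ev2 = 0.025, hp = 1.5, hy = 0.3, hr = 0.2,
              hp2 = 0.005, hy2 = 0.003, hr2 = 0.002)
  cf <- if (axis == "h") base_h else base_v
  if (side == "right") {
    cf[c("eh", "ev")] <- cf[c("eh", "ev")] * 1.06
    cf["1"] <- cf["1"] + 4
  }
  cf[mapping_terms(preset)]
}

default_head_trajectory <- function(n) {
  i <- seq_len(n)
  cbind(pitch = 10 * sin(2 * pi * i / 97),
        yaw = 15 * sin(2 * pi * i / 131 + 1),
        roll = 6 * sin(2 * pi * i / 73 + 2))
}

# Invert the forward polynomial mapping for one frame: find (e_h, e_v)
# with g_h(e, h) = target_h and g_v(e, h) = target_v, by Newton iteration
# from the linear-terms inverse. The defaults' curvature is small relative
# to the linear gains, so this converges in a handful of steps.
solve_eye_vector <- function(target, hpose, coef_h, coef_v, terms_h, terms_v,
                             tol = 1e-12, maxit = 60L) {
  Fe <- function(e) {
    c(sum(coef_h * mapping_term_values(terms_h, e[1], e[2],
                                       hpose[1], hpose[2], hpose[3])),
      sum(coef_v * mapping_term_values(terms_v, e[1], e[2],
                                       hpose[1], hpose[2], hpose[3]))) - target
  }
  A <- rbind(c(coef_h[match("eh", terms_h)], coef_h[match("ev", terms_h)]),
             c(coef_v[match("eh", terms_v)], coef_v[match("ev", terms_v)]))
  A[is.na(A)] <- 0
  e <- as.numeric(solve(A, -Fe(c(0, 0))))
  for (k in seq_len(maxit)) {
    f <- Fe(e)
    if (max(abs(f)) < tol) break
    J <- rbind(coef_h %*% mapping_term_grad(terms_h, e[1], e[2]),
               coef_v %*% mapping_term_grad(terms_v, e[1], e[2]))
    e <- e - as.numeric(solve(J, f))
  }
  e
}

#' Simulate a gaze session
#'
#' Targets are drawn uniformly on the screen; per-eye eye vectors are
#' solved frame by frame from the ground-truth coefficients (Newton
#' inversion of the forward mapping, residual below 1e-12 screen units),
#' then Gaussian pixel noise is added. 3D screen-target coordinates and
#' eyeball centers are recorded for angular-error evaluation. Deterministic
#' for a fixed seed.
#'
#' @param spec a [session_spec()].
#' @return A `gaze_session`: list with `frames` (data frame: frame_id,
#'   detected, target_h/v, target 3D, per-eye eye vectors, head pose),
#'   `geometry`, `eyeballs`, and `meta` (spec echoes incl. the true
#'   coefficients).
#' @export
simulate_session <- function(spec) {
  stopifnot(inherits(spec, "session_spec"))
  n <- spec$n_calib_frames + spec$n_test_frames
  traj <- spec$head_pose_trajectory
  if (is.null(traj)) traj <- default_head_trajectory(n)
  if (nrow(traj) < n)
    stop_gaze("head-pose trajectory has %d rows but %d frames requested",
              nrow(traj), n, class = "spec_error")
  th <- mapping_terms(spec$preset_h); tv <- mapping_terms(spec$preset_v)

  with_seed(spec$seed, {
    tgt <- cbind(stats::runif(n, 0, spec$geometry$size[1]),
                 stats::runif(n, 0, spec$geometry$size[2]))
    detected <- if (spec$undetected_fraction > 0)
      stats::runif(n) >= spec$undetected_fraction else rep(TRUE, n)
    ev <- array(NA_real_, c(n, 2, 2),
                dimnames = list(NULL, c("left", "right"), c("eh", "ev")))
    for (i in seq_len(n)) {
      for (side in c("left", "right")) {
        e <- solve_eye_vector(tgt[i, ], traj[i, ],
                              spec$coeffs[[side]]$h[th], spec$coeffs[[side]]$v[tv],
                              th, tv)
        ev[i, side, ] <- e
      }
    }
    if (spec$pixel_noise_sigma > 0)
      ev <- ev + array(stats::rnorm(length(ev), 0, spec$pixel_noise_sigma), dim(ev))
    t3 <- t(apply(tgt, 1, por_to_screen_3d, geometry = spec$geometry))
    frames <- data.frame(
      frame_id = seq_len(n), detected = detected,
      target_h = tgt[, 1], target_v = tgt[, 2],
      target_x = t3[, 1], target_y = t3[, 2], target_z = t3[, 3],
      e_lh = ev[, "left", "eh"], e_lv = ev[, "left", "ev"],
      e_rh = ev[, "right", "eh"], e_rv = ev[, "right", "ev"],
      h_p = traj[seq_len(n), 1], h_y = traj[seq_len(n), 2],
      h_r = traj[seq_len(n), 3])
    gaze_session(frames, spec$geometry, spec$eyeballs,
                 meta = list(seed = spec$seed, preset_h = spec$preset_h,
                             preset_v = spec$preset_v,
                             pixel_noise_sigma = spec$pixel_noise_sigma,
                             n_calib_frames = spec$n_calib_frames,
                             true_coeffs = spec$coeffs))
  })
}

#' Construct a gaze session container
#'
#' @param frames data frame with one row per video frame (see
#'   [simulate_session()] for the column contract).
#' @param geometry a [screen_geometry()].
#' @param eyeballs list with `left`/`right` 3D eyeball centers (mm).
#' @param meta free-form metadata list.
#' @export
gaze_session <- function(frames, geometry, eyeballs, meta = list()) {
  need <- c("frame_id", "detected", "target_h", "target_v",
            "target_x", "target_y", "target_z",
            "e_lh", "e_lv", "e_rh", "e_rv", "h_p", "h_y", "h_r")
  miss <- setdiff(need, names(frames))
  if (length(miss))
    stop_gaze("session frames missing columns: %s", paste(miss, collapse = ", "),
              class = "session_error")
  structure(list(frames = frames, geometry = geometry, eyeballs = eyeballs,
                 meta = meta,
                 TF = nrow(frames), DF = sum(frames$detected)),
            class = "gaze_session")
}

#' @export
print.gaze_session <- function(x, ...) {
  cat(sprintf("<gaze_session> %d frames (%d detected, %.1f%%), screen %g x %g units\n",
              x$TF, x$DF, 100 * x$DF / x$TF,
              x$geometry$size[1], x$geometry$size[2]))
  invisible(x)
}

#' Write / read a gaze session directory
#'
#' Native plain-text layout: `frames.csv` (one row per frame) plus
#' `meta.json` (screen geometry, eyeball centers, metadata). Round-trip
#' safe at full precision.
#'
#' @param session a `gaze_session`; @param dir directory path.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "gaze_session"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(format(session$frames, digits = 17, trim = TRUE),
                   file.path(dir, "frames.csv"), row.names = FALSE,
                   quote = FALSE)
  g <- session$geometry
  jsonlite::write_json(
    list(geometry = list(origin = g$origin, ex = g$ex, ey = g$ey,
                         mm_per_unit = g$mm_per_unit, size = g$size),
         eyeballs = session$eyeballs,
         meta = session$meta[setdiff(names(session$meta), "true_coeffs")]),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_session
#' @export
read_session <- function(dir) {
  fpath <- file.path(dir, "frames.csv"); mpath <- file.path(dir, "meta.json")
  if (!file.exists(fpath) || !file.exists(mpath))
    stop_gaze("session directory %s lacks frames.csv/meta.json", dir,
              class = "session_error")
  frames <- utils::read.csv(fpath)
  frames$detected <- as.logical(frames$detected)
  m <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  geometry <- screen_geometry(m$geometry$origin, m$geometry$ex, m$geometry$ey,
                              m$geometry$mm_per_unit, m$geometry$size)
  gaze_session(frames, geometry,
               lapply(m$eyeballs, as.numeric),
               meta = as.list(m$meta))
}
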