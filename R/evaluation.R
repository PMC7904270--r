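#' Normalized iris-center localization error
#'
#' The standard worst-eye measure for eye-center benchmarks:
#' `e = max(d_left, d_right) / d`, where `d_left` and `d_right` are the
#' Euclidean distances between the estimated and labeled iris centers of
#' each eye, and `d` is the distance between the two labeled centers.
#' `e <= 0.05` corresponds to an estimate inside the pupil and is the usual
#' benchmark threshold. The measure is invariant under any similarity
#' transform (translation, rotation, uniform scaling) applied to all four
#' points.
#'
#' @param est_left,est_right estimated centers `(x, y)`, px.
#' @param gt_left,gt_right labeled centers `(x, y)`, px.
#' @return scalar `e >= 0`.
#' @export
normalized_error <- function(est_left, est_right, gt_left, gt_right) {
  stopifnot(is_point(est_left), is_point(est_right),
            is_point(gt_left), is_point(gt_right))
  d <- vnorm(gt_left - gt_right)
  if (d == 0)
    stop_gaze("labeled iris centers coincide; normalized error undefined",
              class = "metric_error")
  max(vnorm(est_left - gt_left), vnorm(est_right - gt_right)) / d
}

#' Horizontal / vertical / combined angular gaze errors
#'
#' The gaze ray is measured from the 3D eyeball center. With unit gaze
#' vectors `v = normalize(p - eyeball)` for the true target and the
#' estimate, the horizontal error H is the unsigned angle between the two
#' rays' projections onto the camera's horizontal (x-z) plane (an
#' azimuth difference, computed wrap-free), the vertical error V is the
#' unsigned difference of their elevations `asin(v_y)`, and the combined
#' error is the root sum of squares `C = sqrt(H^2 + V^2)`. All in degrees.
#'
#' @param eyeball 3D eyeball center (mm, camera frame).
#' @param target true 3D screen point (mm).
#' @param estimate estimated 3D screen point (mm).
#' @return named vector `c(H, V, C)` in degrees.
#' @export
angular_errors <- function(eyeball, target, estimate) {
  v_t <- as.numeric(target) - as.numeric(eyeball)
  v_e <- as.numeric(estimate) - as.numeric(eyeball)
  if (vnorm(v_t) == 0 || vnorm(v_e) == 0)
    stop_gaze("eyeball coincides with a screen point; gaze ray undefined",
              class = "metric_error")
  v_t <- v_t / vnorm(v_t); v_e <- v_e / vnorm(v_e)
  # azimuth difference via the 2D cross/dot of the x-z projections
  a <- c(v_t[1], v_t[3]); b <- c(v_e[1], v_e[3])
  H <- abs(rad2deg(atan2(a[1] * b[2] - a[2] * b[1], sum(a * b))))
  V <- abs(rad2deg(asin(clamp(v_e[2], -1, 1)) - asin(clamp(v_t[2], -1, 1))))
  c(H = H, V = V, C = sqrt(H^2 + V^2))
}

#' Evaluate a gaze session with the calibration/test protocol
#'
#' Splits the detected frames into a calibration phase (the first
#' `n_calib` detected frames) and a testing phase (the remaining detected
#' frames); undetected frames count toward the total only. Per-eye
#' horizontal and vertical mapping models are fitted on the calibration
#' frames, then each test frame is scored three ways: left eye only
#' (`w = 1`), right eye only (`w = 0`), and fused with the configured
#' weight. Each point of regard is mapped to its 3D screen point and
#' compared with the true 3D target as an angular error from the matching
#' eyeball center; the fused estimate uses the `w`-weighted combination of
#' the two eyeball centers, so `w = 1` and `w = 0` reproduce the pure
#' single-eye pipelines exactly.
#'
#' @param session a `gaze_session` whose frames carry per-eye eye vectors
#'   and head pose (as produced by [simulate_session()] or assembled from
#'   images via the feature pipeline).
#' @param n_calib number of detected frames used for calibration
#'   (default 1000).
#' @param preset_h,preset_v mapping presets per axis (defaults 4 and 2).
#' @param w fusion weight on the left eye; length 2 for per-axis weights.
#' @return An `error_report`: list with `per_frame` (data frame of H/V/C
#'   for L, R, fused per test frame), `means`, `TF`, `DF`, `n_calib`,
#'   `models`, `config`.
#' @export
evaluate_session <- function(session, n_calib = 1000L, preset_h = 4,
                             preset_v = 2, w = 0.5) {
  stopifnot(inherits(session, "gaze_session"))
  fr <- session$frames
  det <- which(fr$detected)
  if (length(det) < n_calib + 1L)
    stop_gaze("need at least n_calib + 1 = %d detected frames, have %d of %d total",
              n_calib + 1L, length(det), nrow(fr), class = "session_error")
  calib <- det[seq_len(n_calib)]
  test <- det[-seq_len(n_calib)]

  mkframes <- function(rows, eh, ev) {
    lapply(rows, function(i) list(e = c(fr[[eh]][i], fr[[ev]][i]),
                                  h = c(fr$h_p[i], fr$h_y[i], fr$h_r[i])))
  }
  models <- list(
    left = list(
      h = fit_mapping(mkframes(calib, "e_lh", "e_lv"), fr$target_h[calib],
                      preset_h, "h"),
      v = fit_mapping(mkframes(calib, "e_lh", "e_lv"), fr$target_v[calib],
                      preset_v, "v")),
    right = list(
      h = fit_mapping(mkframes(calib, "e_rh", "e_rv"), fr$target_h[calib],
                      preset_h, "h"),
      v = fit_mapping(mkframes(calib, "e_rh", "e_rv"), fr$target_v[calib],
                      preset_v, "v")))

  wf <- if (length(w) == 1L) c(w, w) else as.numeric(w)
  eb_l <- as.numeric(session$eyeballs$left)
  eb_r <- as.numeric(session$eyeballs$right)
  eb_f <- mean(wf) * eb_l + (1 - mean(wf)) * eb_r

  rows <- lapply(test, function(i) {
    h <- c(fr$h_p[i], fr$h_y[i], fr$h_r[i])
    por_l <- predict_por(models$left$h, models$left$v,
                         c(fr$e_lh[i], fr$e_lv[i]), h)
    por_r <- predict_por(models$right$h, models$right$v,
                         c(fr$e_rh[i], fr$e_rv[i]), h)
    por_f <- fuse_por(por_l, por_r, wf)
    tgt3 <- c(fr$target_x[i], fr$target_y[i], fr$target_z[i])
    g <- session$geometry
    e_l <- angular_errors(eb_l, tgt3, por_to_screen_3d(por_l, g))
    e_r <- angular_errors(eb_r, tgt3, por_to_screen_3d(por_r, g))
    e_f <- angular_errors(eb_f, tgt3, por_to_screen_3d(por_f, g))
    c(frame_id = fr$frame_id[i],
      H_L = e_l["H"], V_L = e_l["V"], C_L = e_l["C"],
      H_R = e_r["H"], V_R = e_r["V"], C_R = e_r["C"],
      H_F = e_f["H"], V_F = e_f["V"], C_F = e_f["C"])
  })
  per_frame <- as.data.frame(do.call(rbind, rows))
  names(per_frame) <- c("frame_id", "H_L", "V_L", "C_L",
                        "H_R", "V_R", "C_R", "H_F", "V_F", "C_F")
  means <- colMeans(per_frame[, -1L, drop = FALSE])
  structure(list(per_frame = per_frame, means = means,
                 TF = session$TF, DF = session$DF,
                 n_calib = as.integer(n_calib), n_test = length(test),
                 models = models,
                 config = list(preset_h = preset_h, preset_v = preset_v, w = w)),
            class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  m <- round(x$means, 1)  # reports round to one decimal degree
  cat(sprintf("<error_report> %d calib + %d test frames (DF/TF = %d/%d = %.1f%%)\n",
              x$n_calib, x$n_test, x$DF, x$TF, 100 * x$DF / x$TF))
  cat(sprintf("  left : H %.1f  V %.1f  C %.1f deg\n", m["H_L"], m["V_L"], m["C_L"]))
  cat(sprintf("  right: H %.1f  V %.1f  C %.1f deg\n", m["H_R"], m["V_R"], m["C_R"]))
  cat(sprintf("  fused: H %.1f  V %.1f  C %.1f deg (w = %s)\n",
              m["H_F"], m["V_F"], m["C_F"],
              paste(x$config$w, collapse = "/")))
  invisible(x)
}

#' Parameter sweep for the iris localization benchmark
#'
#' Re-runs [locate_iris()] over a grid of (alpha, beta, delta) on a
#' synthetic benchmark (see [make_iris_benchmark()]) and tabulates, per
#' grid point, the number and rate of items whose normalized error is at
#' or below the threshold. The default grids are alpha 0.21-0.25 in steps
#' of 0.01, beta 1.32-1.52 in steps of 0.04 and delta 1-4.
#'
#' @param benchmark list of benchmark items.
#' @param alphas,betas,deltas grid values.
#' @param e_threshold normalized-error acceptance threshold (default 0.05).
#' @return data frame: alpha, beta, delta, count, rate.
#' @export
sweep_localization <- function(benchmark,
                               alphas = seq(0.21, 0.25, by = 0.01),
                               betas = seq(1.32, 1.52, by = 0.04),
                               deltas = 1:4, e_threshold = 0.05) {
  grid <- expand.grid(alpha = alphas, beta = betas, delta = deltas)
  if (nrow(grid) == 0L || length(benchmark) == 0L)
    stop_gaze("empty sweep grid or benchmark", class = "sweep_error")
  res <- vapply(seq_len(nrow(grid)), function(k) {
    a <- grid$alpha[k]; b <- grid$beta[k]; dl <- grid$delta[k]
    hits <- vapply(benchmark, function(item) {
      el <- locate_iris(item$left, a, b, dl)$center_image
      er <- locate_iris(item$right, a, b, dl)$center_image
      normalized_error(el, er, item$truth_left, item$truth_right) <= e_threshold
    }, logical(1))
    sum(hits)
  }, numeric(1))
  grid$count <- res
  grid$rate <- res / length(benchmark)
  grid
}

#' Fusion-weight sweep on a gaze session
#'
#' Evaluates the session for each weight in `ws` (default 0 to 1 in steps
#' of 0.1) and tabulates the mean H/V/C errors of the fused estimate.
#'
#' @param session a `gaze_session`.
#' @param ws weights to try.
#' @param ... passed to [evaluate_session()].
#' @return data frame: w, H, V, C.
#' @export
sweep_fusion_weight <- function(session, ws = seq(0, 1, by = 0.1), ...) {
  if (length(ws) == 0L)
    stop_gaze("empty weight grid", class = "sweep_error")
  rows <- lapply(ws, function(w) {
    m <- evaluate_session(session, w = w, ...)$means
    c(w = w, H = unname(m["H_F"]), V = unname(m["V_F"]), C = unname(m["C_F"]))
  })
  as.data.frame(do.call(rbind, rows))
}

#' Published benchmark gaze-error tables
#'
#' Reported mean angular gaze errors of this tracking approach on the
#' EYEDIAP screen-target video benchmark, shipped as plain CSVs. Two
#' tables: per-mapping-preset mean errors (columns preset, delta, H, V, C,
#' degrees) and per-participant errors on the head-movement clips (columns
#' clip_type, participant, TF, DF, plus H/V/C for left, right and fused).
#' Used by the test-suite to validate the error-aggregation arithmetic
#' (C = sqrt(H^2 + V^2) and column averaging at the tables' one-decimal
#' rounding).
#'
#' @return list of two data frames, `by_preset` and `by_participant`.
#' @export
reference_error_tables <- function() {
  d <- system.file("extdata", package = "gazetrackr")
  list(by_preset = utils::read.csv(file.path(d, "benchmark_errors_by_preset.csv")),
       by_participant = utils::read.csv(file.path(d, "benchmark_errors_by_participant.csv")))
}
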