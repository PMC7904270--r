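#' Eye vector from iris center and anchor point
#'
#' The regression input for gaze mapping: the 2D displacement from the
#' anchor point to the iris center, both in full-image pixels.
#'
#' @param iris_center `(x, y)` iris center in full-image pixels (use the
#'   `center_image` field of [locate_iris()]'s result, not ROI pixels).
#' @param anchor an [compute_anchor()] result or `(x, y)` point.
#' @param side `"left"` or `"right"`.
#' @return An `eye_vector`: list with `e_h`, `e_v`, `side`.
#' @export
eye_vector <- function(iris_center, anchor, side = "left") {
  if (!is_point(iris_center) || !is_point(as.numeric(anchor)))
    stop_gaze("iris center and anchor must be finite 2D points in the same full-image frame",
              class = "frame_error")
  a <- as.numeric(anchor)
  structure(list(e_h = iris_center[1] - a[1], e_v = iris_center[2] - a[2],
                 side = side),
            class = "eye_vector")
}

# Monomial vocabulary over the eye vector (e_h, e_v) and head pose
# (h_p, h_y, h_r). Each preset is a named term list; values of each term
# are computed by mapping_term_value().
MAPPING_TERMS <- c("1", "eh", "ev", "eh_ev", "eh2", "ev2",
                   "hp", "hy", "hr", "hp2", "hy2", "hr2")

#' Mapping-function presets
#'
#' Six nested polynomial families from (eye vector, head pose) to one
#' screen coordinate. Presets 1 and 2 use the linear and squared eye-vector
#' terms only; presets 3-6 add the head-pose angles (and, for 5-6, their
#' squares):
#'
#' * No.1: `{1, e_h, e_v}`
#' * No.2: `{1, e_h, e_v, e_h*e_v, e_h^2, e_v^2}`
#' * No.3: No.1 + `{h_p, h_y, h_r}`
#' * No.4: No.2 + `{h_p, h_y, h_r}`
#' * No.5: No.3 + `{h_p^2, h_y^2, h_r^2}`
#' * No.6: No.4 + `{h_p^2, h_y^2, h_r^2}`
#'
#' The benchmark defaults are preset 4 for the horizontal axis and preset 2
#' for the vertical axis.
#'
#' @param preset integer 1-6, or a character vector of term names from
#'   `{"1","eh","ev","eh_ev","eh2","ev2","hp","hy","hr","hp2","hy2","hr2"}`.
#' @return character vector of term names.
#' @export
mapping_terms <- function(preset) {
  if (is.character(preset)) {
    bad <- setdiff(preset, MAPPING_TERMS)
    if (length(bad))
      stop_gaze("unknown mapping terms: %s", paste(bad, collapse = ", "),
                class = "preset_error")
    return(unique(c("1", preset)))
  }
  if (!is.numeric(preset) || length(preset) != 1L || !preset %in% 1:6)
    stop_gaze("preset must be 1..6 or a term list", class = "preset_error")
  lin <- c("1", "eh", "ev")
  sq <- c(lin, "eh_ev", "eh2", "ev2")
  pose <- c("hp", "hy", "hr")
  pose2 <- c("hp2", "hy2", "hr2")
  switch(preset, lin, sq, c(lin, pose), c(sq, pose),
         c(lin, pose, pose2), c(sq, pose, pose2))
}

mapping_term_values <- function(terms, eh, ev, hp = 0, hy = 0, hr = 0) {
  vals <- c(unname(c(1, eh, ev, eh * ev, eh^2, ev^2)),
            unname(c(hp, hy, hr, hp^2, hy^2, hr^2)))
  names(vals) <- MAPPING_TERMS
  unname(vals[terms])
}

# d(term)/d(eh) and d(term)/d(ev); used by the session simulator's Newton
# inversion of the forward mapping.
mapping_term_grad <- function(terms, eh, ev) {
  d_eh <- c(`1` = 0, eh = 1, ev = 0, eh_ev = ev, eh2 = 2 * eh, ev2 = 0,
            hp = 0, hy = 0, hr = 0, hp2 = 0, hy2 = 0, hr2 = 0)
  d_ev <- c(`1` = 0, eh = 0, ev = 1, eh_ev = eh, eh2 = 0, ev2 = 2 * ev,
            hp = 0, hy = 0, hr = 0, hp2 = 0, hy2 = 0, hr2 = 0)
  cbind(d_eh = unname(d_eh[terms]), d_ev = unname(d_ev[terms]))
}

#' Design row for one frame
#'
#' Evaluates the monomials of a preset at one (eye vector, head pose)
#' observation. The constant term is always included.
#'
#' @param e an [eye_vector()] or `c(e_h, e_v)`.
#' @param h a [head_pose()], or `c(h_p, h_y, h_r)` in degrees, or `NULL`
#'   (treated as zero angles, allowed for the pose-free presets 1-2).
#' @inheritParams mapping_terms
#' @return named numeric vector of term values.
#' @export
design_row <- function(e, h = NULL, preset = 4) {
  terms <- mapping_terms(preset)
  if (inherits(e, "eye_vector")) e <- c(e$e_h, e$e_v)
  if (inherits(h, "head_pose")) h <- c(h$pitch, h$yaw, h$roll)
  if (is.null(h)) h <- c(0, 0, 0)
  out <- mapping_term_values(terms, e[1], e[2], h[1], h[2], h[3])
  names(out) <- terms
  out
}

#' Fit a gaze mapping function by least squares
#'
#' Ordinary least squares of one screen coordinate on the preset's
#' monomials over the calibration frames. QR-based, deterministic; the
#' residual RMS and the design-matrix condition number are stored as fit
#' diagnostics.
#'
#' @param frames list of `list(e = eye_vector-or-c(eh, ev), h = head_pose-or-
#'   c(hp, hy, hr))` observations, one per calibration frame.
#' @param targets numeric vector: the screen coordinate of the calibration
#'   target on this axis, one per frame (screen units; the fit is
#'   unit-agnostic).
#' @param preset preset id or term list (see [mapping_terms()]).
#' @param axis `"h"` or `"v"` (metadata only).
#' @return A `mapping_model`: list with `terms`, `coefficients`, `axis`,
#'   `preset`, `rms`, `kappa`, `n_frames`.
#' @export
fit_mapping <- function(frames, targets, preset = 4, axis = c("h", "v")) {
  axis <- match.arg(axis)
  terms <- mapping_terms(preset)
  n <- length(frames)
  if (n != length(targets))
    stop_gaze("%d frames but %d targets", n, length(targets), class = "fit_error")
  if (n < length(terms))
    stop_gaze("need at least %d frames to fit %d terms, got %d",
              length(terms), length(terms), n, class = "fit_error")
  X <- t(vapply(frames, function(fr) design_row(fr$e, fr$h, terms),
                numeric(length(terms))))
  qrX <- qr(X)
  if (qrX$rank < length(terms)) {
    dep <- terms[qrX$pivot[(qrX$rank + 1):length(terms)]]
    stop_gaze("rank-deficient calibration design (rank %d < %d); collinear terms: %s",
              qrX$rank, length(terms), paste(dep, collapse = ", "),
              class = "fit_error")
  }
  coef <- qr.coef(qrX, targets)
  rms <- sqrt(mean((X %*% coef - targets)^2))
  structure(list(terms = terms, coefficients = as.numeric(coef),
                 axis = axis,
                 preset = if (is.numeric(preset)) as.integer(preset) else NA_integer_,
                 rms = rms, kappa = kappa(X, exact = TRUE), n_frames = n),
            class = "mapping_model")
}

#' @export
print.mapping_model <- function(x, ...) {
  cat(sprintf("<mapping_model> axis %s, preset %s, %d terms, fit on %d frames (RMS %0.3g, kappa %0.3g)\n",
              x$axis, ifelse(is.na(x$preset), "custom", x$preset),
              length(x$terms), x$n_frames, x$rms, x$kappa))
  invisible(x)
}

predict_axis <- function(model, e, h) {
  stopifnot(inherits(model, "mapping_model"))
  sum(model$coefficients * design_row(e, h, model$terms))
}

#' Predict the point of regard for one frame
#'
#' `g = a . phi_h(e, h)` horizontally and `g = b . phi_v(e, h)` vertically,
#' where `phi` are the fitted presets' monomials (default preset 4
#' horizontal, preset 2 vertical).
#'
#' @param model_h,model_v fitted [fit_mapping()] models for the horizontal
#'   and vertical screen axes.
#' @param e eye vector; @param h head pose (may be `NULL` for pose-free
#'   presets).
#' @return `c(g_h, g_v)` in screen units.
#' @export
predict_por <- function(model_h, model_v, e, h = NULL) {
  if (!inherits(model_h, "mapping_model") || !inherits(model_v, "mapping_model"))
    stop_gaze("both axis models must be fitted mapping_model objects",
              class = "predict_error")
  c(g_h = predict_axis(model_h, e, h), g_v = predict_axis(model_v, e, h))
}

#' Fuse the left- and right-eye points of regard
#'
#' Weighted binocular combination: `g_f = w * g_left + (1 - w) * g_right`,
#' elementwise on the horizontal and vertical coordinates. `w = 1` is the
#' pure left eye, `w = 0` the pure right eye, `w = 0.5` the binocular
#' average. If one eye is flagged unavailable (e.g. occluded by a large
#' head rotation), the weight collapses onto the other eye and a message is
#' emitted.
#'
#' @param left,right `c(g_h, g_v)` per-eye points of regard.
#' @param w weight on the left eye, in \[0, 1\]. A length-2 `w` applies
#'   separate weights to the horizontal and vertical axes.
#' @param left_ok,right_ok availability flags.
#' @return `c(g_fh, g_fv)`.
#' @export
fuse_por <- function(left, right, w = 0.5, left_ok = TRUE, right_ok = TRUE) {
  if (any(w < 0) || any(w > 1))
    stop_gaze("fusion weight w must lie in [0, 1], got %s",
              paste(w, collapse = ", "), class = "fusion_error")
  if (!left_ok && !right_ok)
    stop_gaze("both eyes flagged unavailable", class = "fusion_error")
  if (!left_ok) { message("left eye unavailable; w set to 0"); w <- 0 }
  if (!right_ok) { message("right eye unavailable; w set to 1"); w <- 1 }
  if (length(w) == 1L) w <- c(w, w)
  out <- w * as.numeric(left) + (1 - w) * as.numeric(right)
  names(out) <- c("g_fh", "g_fv")
  out
}

#' Write / read a mapping model as JSON
#'
#' Round-trip safe: coefficients are serialized at full precision.
#'
#' @param model a `mapping_model`; @param path file path.
#' @export
write_mapping_json <- function(model, path) {
  stopifnot(inherits(model, "mapping_model"))
  obj <- unclass(model)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_mapping_json
#' @export
read_mapping_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(terms = as.character(obj$terms),
                 coefficients = as.numeric(obj$coefficients),
                 axis = obj$axis,
                 preset = if (is.null(obj$preset) || is.na(obj$preset))
                   NA_integer_ else as.integer(obj$preset),
                 rms = as.numeric(obj$rms), kappa = as.numeric(obj$kappa),
                 n_frames = as.integer(obj$n_frames)),
            class = "mapping_model")
}
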