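#' Snakuscule inner-radius initialization from eye anatomy
#'
#' A snakuscule is a minimal circular active contour: an inner disk and a
#' concentric outer annulus, scored by the gray-level contrast between the
#' two regions. Rather than letting the probe grow or shrink iteratively,
#' its inner radius is fixed from anatomy: the iris radius is close to 7 mm
#' for most adults while the eyeball diameter (which the landmark-derived
#' ROI width approximates) is 24-26 mm, so the iris radius is a roughly
#' constant fraction `alpha` of the ROI width `N`:
#'
#'   `r = round(alpha * N)`, clamped to at least 1 px.
#'
#' The default `alpha = 0.25` is the optimum of the localization benchmark
#' sweep (see [sweep_localization()]).
#'
#' @param N eye ROI width in pixels (post-magnification).
#' @param alpha iris-radius to ROI-width ratio, in (0, 0.5).
#' @return integer radius in pixels.
#' @export
init_radius <- function(N, alpha = 0.25) {
  stopifnot(N >= 8, alpha > 0, alpha < 0.5)
  max(1L, as.integer(round_half_up(alpha * N)))
}

#' Construct a snakuscule probe
#'
#' @param center `(x, y)` center in pixels.
#' @param r inner radius, px (`>= 1`).
#' @param beta ratio of outer to inner radius (`> 1`); the disk is
#'   `{q : |q - p| <= r}` and the annulus `{q : r < |q - p| <= beta * r}`.
#' @export
snakuscule <- function(center, r, beta = 1.4) {
  stopifnot(is_point(center), r >= 1, beta > 1)
  structure(list(center = as.numeric(center), r = as.numeric(r),
                 beta = as.numeric(beta)),
            class = "snakuscule")
}

# Integer pixel offsets of the disk and annulus regions for radius r and
# ratio beta. Membership is decided by the Euclidean distance of the pixel
# center, with no fractional border weighting, so the exhaustive oracle in
# the tests can reproduce the sums exactly. Eye ROIs are wide and short, so
# the probe is kept fully inside the image laterally (the scan range does
# that) but is truncated at the top/bottom rows: region means are taken
# over the in-image pixels only.
snk_offsets <- function(r, beta) {
  R <- floor(beta * r)
  g <- expand.grid(dx = -R:R, dy = -R:R)  # row-major in dy blocks
  d <- sqrt(g$dx^2 + g$dy^2)
  list(disk = as.matrix(g[d <= r, , drop = FALSE]),
       ann  = as.matrix(g[d > r & d <= beta * r, , drop = FALSE]),
       reach = R)
}

snk_energy_at <- function(img, x, y, offs) {
  M <- nrow(img)
  yd <- y + offs$disk[, 2]
  kd <- yd >= 1L & yd <= M
  ya <- y + offs$ann[, 2]
  ka <- ya >= 1L & ya <= M
  di <- (x + offs$disk[kd, 1] - 1L) * M + yd[kd]
  ai <- (x + offs$ann[ka, 1] - 1L) * M + ya[ka]
  mean(img[ai]) - mean(img[di])
}

#' Snakuscule gray-difference energy
#'
#' `G = mean(annulus) - mean(disk)`, where each region mean is taken over
#' the image pixels whose centers fall in the region. A dark iris on a
#' lighter sclera maximizes `G` when the disk sits on the iris. The energy
#' is invariant under adding a constant to the image and scales linearly
#' with the pixel values.
#'
#' Eye ROIs are much wider than tall, so the probe must fit inside the
#' image horizontally (a `boundary_error` otherwise) but its regions are
#' truncated at the top and bottom ROI rows, exactly as a circular probe
#' behaves inside a tight eye crop.
#'
#' @param image gray matrix (0-255), indexed `[y, x]`.
#' @param s a [snakuscule()].
#' @return scalar energy `G`.
#' @export
snk_energy <- function(image, s) {
  stopifnot(is.matrix(image), inherits(s, "snakuscule"))
  offs <- snk_offsets(s$r, s$beta)
  x <- s$center[1]; y <- s$center[2]
  if (x - offs$reach < 1 || x + offs$reach > ncol(image) ||
      y < 1 || y > nrow(image))
    stop_gaze("snakuscule (outer radius %0.1f) extends outside the %d x %d image at (%g, %g)",
              s$beta * s$r, ncol(image), nrow(image), x, y,
              class = "boundary_error")
  snk_energy_at(image, as.integer(x), as.integer(y), offs)
}

#' Rough iris center by a horizontal centerline scan
#'
#' Evaluates the snakuscule energy at every integer x along the horizontal
#' centerline `y = floor(M / 2)` of the ROI, keeping the probe fully inside
#' the image, and returns the position with maximum energy (ties broken
#' toward the smallest x). Because the eye ROI is cut tightly around the
#' eye, the iris always straddles the centerline, so a 1-D scan finds a
#' candidate within a couple of pixels of the center.
#'
#' @param roi an [eye_roi()].
#' @param r inner radius, px.
#' @param beta outer/inner radius ratio.
#' @return list with `p_rc` (x, y) and `G` (energy at `p_rc`).
#' @export
scan_rough <- function(roi, r, beta = 1.4) {
  stopifnot(inherits(roi, "eye_roi"))
  img <- roi$image
  offs <- snk_offsets(r, beta)
  R <- offs$reach
  x_lo <- R + 1L; x_hi <- roi$N - R
  y <- as.integer(floor(roi$M / 2))
  if (x_lo > x_hi || y < 1L || y > roi$M)
    stop_gaze("scan range empty: ROI %d x %d too small for outer radius %0.1f; use a larger ROI or smaller beta/alpha",
              roi$N, roi$M, beta * r, class = "scan_error")
  xs <- x_lo:x_hi
  G <- vapply(xs, function(x) snk_energy_at(img, x, y, offs), numeric(1))
  i <- which.max(G)  # first maximum = smallest x
  list(p_rc = c(xs[i], y), G = G[i])
}

#' Refine the iris center over a square candidate grid
#'
#' Evaluates the energy at the `(2*delta + 1)^2` integer candidate points
#' `p_rc + [-delta, delta]^2` (clipped, with a warning, to positions where
#' the probe stays inside the ROI) and returns the argmax. Ties are broken
#' by the smallest Euclidean distance to `p_rc`, then by row-major order of
#' the grid, so the result is deterministic.
#'
#' @param roi an [eye_roi()].
#' @param p_rc rough center `(x, y)` from [scan_rough()].
#' @param r,beta snakuscule geometry.
#' @param delta half-width of the candidate grid, px (`>= 0`).
#' @return list with `p_c` (x, y) and `G`.
#' @export
refine_center <- function(roi, p_rc, r, beta = 1.4, delta = 2L) {
  stopifnot(inherits(roi, "eye_roi"), is_point(p_rc), delta >= 0)
  img <- roi$image
  offs <- snk_offsets(r, beta)
  R <- offs$reach
  g <- expand.grid(dx = -delta:delta, dy = -delta:delta)  # row-major
  cx <- as.integer(p_rc[1] + g$dx); cy <- as.integer(p_rc[2] + g$dy)
  ok <- cx - R >= 1L & cx + R <= roi$N & cy >= 1L & cy <= roi$M
  if (!any(ok))
    stop_gaze("no refinement candidate keeps the probe inside the ROI",
              class = "scan_error")
  if (!all(ok)) {
    warning("refinement grid clipped to the valid probe area")
    cx <- cx[ok]; cy <- cy[ok]
  }
  G <- vapply(seq_along(cx), function(i) snk_energy_at(img, cx[i], cy[i], offs),
              numeric(1))
  gmax <- max(G)
  tie <- which(G == gmax)
  if (length(tie) > 1L) {
    d2 <- (cx[tie] - p_rc[1])^2 + (cy[tie] - p_rc[2])^2
    tie <- tie[d2 == min(d2)]  # then row-major: first of the remaining
  }
  i <- tie[1L]
  list(p_c = c(cx[i], cy[i]), G = G[i])
}

#' Locate the iris center in an eye ROI
#'
#' Full snakuscule pipeline: radius initialization from the ROI width
#' ([init_radius()]), rough localization by the horizontal centerline scan
#' ([scan_rough()]), and refinement over the `(2*delta + 1)^2` candidate
#' grid ([refine_center()]). The defaults `alpha = 0.25`, `beta = 1.4`,
#' `delta = 2` are the benchmark sweep optimum.
#'
#' @param roi an [eye_roi()].
#' @param alpha iris-radius / ROI-width ratio.
#' @param beta outer/inner radius ratio.
#' @param delta refinement half-width, px.
#' @return An `iris_result`: list with `rough_center`, `final_center` (ROI
#'   px), `center_image` (full-image px), energies `G_rough`, `G_final`,
#'   and the parameters used.
#' @export
locate_iris <- function(roi, alpha = 0.25, beta = 1.4, delta = 2L) {
  stopifnot(inherits(roi, "eye_roi"))
  r <- init_radius(roi$N, alpha)
  rough <- scan_rough(roi, r, beta)
  fine <- refine_center(roi, rough$p_rc, r, beta, delta)
  structure(list(rough_center = rough$p_rc, final_center = fine$p_c,
                 center_image = roi_to_image_coords(roi, fine$p_c),
                 G_rough = rough$G, G_final = fine$G,
                 params = list(alpha = alpha, beta = beta,
                               delta = as.integer(delta), r = r)),
            class = "iris_result")
}

#' @export
print.iris_result <- function(x, ...) {
  cat(sprintf(paste0("<iris_result> center (ROI) = (%g, %g), G = %0.2f ",
                     "[rough (%g, %g), G = %0.2f; r = %d, alpha = %g, beta = %g, delta = %d]\n"),
              x$final_center[1], x$final_center[2], x$G_final,
              x$rough_center[1], x$rough_center[2], x$G_rough,
              x$params$r, x$params$alpha, x$params$beta, x$params$delta))
  invisible(x)
}
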