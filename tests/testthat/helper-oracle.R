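# Independent brute-force oracles. These deliberately avoid the package's
# offset-list energy implementation: region membership is recomputed per
# candidate from a full-image distance matrix, so any indexing slip in the
# fast path would show up as a disagreement.

oracle_energy <- function(img, cx, cy, r, beta) {
  xs <- matrix(seq_len(ncol(img)), nrow(img), ncol(img), byrow = TRUE)
  ys <- matrix(seq_len(nrow(img)), nrow(img), ncol(img))
  d <- sqrt((xs - cx)^2 + (ys - cy)^2)
  mean(img[d > r & d <= beta * r]) - mean(img[d <= r])
}

# Exhaustive argmax over the centerline scan positions.
oracle_scan <- function(img, r, beta) {
  N <- ncol(img); M <- nrow(img)
  R <- floor(beta * r)
  xs <- (R + 1L):(N - R)
  y <- floor(M / 2)
  G <- vapply(xs, function(x) oracle_energy(img, x, y, r, beta), numeric(1))
  c(xs[which.max(G)], y)
}

# Exhaustive argmax over the (2*delta+1)^2 window around p_rc (valid
# probe positions only).
oracle_refine <- function(img, p_rc, r, beta, delta) {
  N <- ncol(img); M <- nrow(img)
  R <- floor(beta * r)
  g <- expand.grid(dx = -delta:delta, dy = -delta:delta)
  cx <- p_rc[1] + g$dx; cy <- p_rc[2] + g$dy
  ok <- cx - R >= 1 & cx + R <= N & cy >= 1 & cy <= M
  cx <- cx[ok]; cy <- cy[ok]
  G <- vapply(seq_along(cx), function(i)
    oracle_energy(img, cx[i], cy[i], r, beta), numeric(1))
  i <- which.max(G)
  c(cx[i], cy[i])
}

# A quick synthetic ROI wrapped as an eye_roi (scale 1, origin 0).
synth_roi <- function(..., seed = 1L) {
  rnd <- render_eye_roi(eye_spec(..., seed = seed))
  list(roi = eye_roi(rnd$image, origin = c(0, 0), scale = 1L),
       truth = rnd$true_center)
}

# Random plausible landmark set: the projected face template under a
# random moderate pose.
random_landmarks <- function() {
  pose <- head_pose(runif(1, -20, 20), runif(1, -20, 20), runif(1, -10, 10),
                    t = c(runif(1, -50, 50), runif(1, -30, 30), runif(1, 500, 800)))
  render_face_landmarks(pose)
}
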