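test_that("eye vectors are the iris-minus-anchor displacement", {
  e <- eye_vector(c(120, 51), c(110, 60))
  expect_equal(c(e$e_h, e$e_v), c(10, -9))
  e0 <- eye_vector(c(110, 60), c(110, 60))
  expect_equal(c(e0$e_h, e0$e_v), c(0, 0))
  # translating both points leaves the vector unchanged
  e2 <- eye_vector(c(120, 51) + c(7, -3), c(110, 60) + c(7, -3))
  expect_equal(c(e2$e_h, e2$e_v), c(10, -9))
  expect_error(eye_vector(c(NA, 1), c(0, 0)), class = "frame_error")
})

test_that("presets expand to the documented nested term lists", {
  expect_equal(mapping_terms(1), c("1", "eh", "ev"))
  expect_equal(mapping_terms(2), c("1", "eh", "ev", "eh_ev", "eh2", "ev2"))
  expect_equal(mapping_terms(4), c(mapping_terms(2), "hp", "hy", "hr"))
  expect_equal(mapping_terms(6), c(mapping_terms(4), "hp2", "hy2", "hr2"))
  expect_true(all(mapping_terms(1) %in% mapping_terms(3)))
  expect_true(all(mapping_terms(3) %in% mapping_terms(5)))
  expect_error(mapping_terms(7), class = "preset_error")
  expect_error(mapping_terms(c("eh", "bogus")), class = "preset_error")
})

test_that("design rows evaluate the monomials", {
  expect_equal(unname(design_row(c(2, 3), preset = 1)), c(1, 2, 3))
  expect_equal(unname(design_row(c(2, 3), preset = 2)), c(1, 2, 3, 6, 4, 9))
  r4 <- design_row(c(0, 0), c(0, 0, 0), preset = 4)
  expect_equal(unname(r4), c(1, rep(0, 8)))
  r6 <- design_row(c(1, -2), c(3, -4, 5), preset = 6)
  expect_equal(unname(r6), c(1, 1, -2, -2, 1, 4, 3, -4, 5, 9, 16, 25))
})

make_synth_frames <- function(n, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i)
    list(e = c(runif(1, -25, 25), runif(1, -18, 18)),
         h = c(runif(1, -12, 12), runif(1, -15, 15), runif(1, -8, 8))))
}

test_that("fit_mapping recovers generating coefficients exactly at zero noise", {
  for (preset in 1:6) {
    terms <- mapping_terms(preset)
    truth <- default_true_coeffs(preset, "h", "left")
    frames <- make_synth_frames(40, seed = preset)
    targets <- vapply(frames, function(fr)
      sum(truth * design_row(fr$e, fr$h, preset)), numeric(1))
    fit <- fit_mapping(frames, targets, preset, "h")
    expect_equal(fit$coefficients, unname(truth[terms]), tolerance = 1e-8)
    expect_lt(fit$rms, 1e-8)
  }
})

test_that("fitting a larger nested preset recovers zeros on the extra terms", {
  frames <- make_synth_frames(60, seed = 42)
  truth1 <- default_true_coeffs(1, "v", "left")
  targets <- vapply(frames, function(fr)
    sum(truth1 * design_row(fr$e, fr$h, 1)), numeric(1))
  fit2 <- fit_mapping(frames, targets, 2, "v")
  extra <- setdiff(mapping_terms(2), mapping_terms(1))
  expect_lt(max(abs(fit2$coefficients[match(extra, fit2$terms)])), 1e-6)
  fit4on3 <- fit_mapping(frames, vapply(frames, function(fr)
    sum(default_true_coeffs(3, "h", "left") * design_row(fr$e, fr$h, 3)),
    numeric(1)), 4, "h")
  extra34 <- setdiff(mapping_terms(4), mapping_terms(3))
  expect_lt(max(abs(fit4on3$coefficients[match(extra34, fit4on3$terms)])), 1e-6)
})

test_that("degenerate calibration designs are rejected with named terms", {
  one_point <- replicate(10, list(e = c(5, 5), h = c(1, 2, 3)), simplify = FALSE)
  err <- expect_error(fit_mapping(one_point, rep(100, 10), 2, "h"),
                      class = "fit_error")
  expect_match(conditionMessage(err), "collinear")
  expect_error(fit_mapping(make_synth_frames(4), rep(1, 4), 2, "h"),
               class = "fit_error")
})

test_that("coefficient noise shrinks like 1/sqrt(n) with calibration length", {
  truth <- default_true_coeffs(2, "h", "left")
  coef_rmse <- function(n) {
    errs <- vapply(1:12, function(k) {
      frames <- make_synth_frames(n, seed = 7000 + 13 * n + k)
      set.seed(8000 + 13 * n + k)
      targets <- vapply(frames, function(fr)
        sum(truth * design_row(fr$e, fr$h, 2)), numeric(1)) + rnorm(n, 0, 5)
      fit <- fit_mapping(frames, targets, 2, "h")
      sqrt(mean((fit$coefficients - unname(truth[mapping_terms(2)]))^2))
    }, numeric(1))
    mean(errs)
  }
  r <- coef_rmse(50) / coef_rmse(200)
  expect_gt(r, 1.4)  # ~2 expected for a 4x sample-size ratio
  expect_lt(r, 3.2)
})

test_that("prediction is linear in the coefficients and honors per-axis presets", {
  frames <- make_synth_frames(30, seed = 9)
  th <- default_true_coeffs(4, "h", "left"); tv <- default_true_coeffs(2, "v", "left")
  t_h <- vapply(frames, function(fr) sum(th * design_row(fr$e, fr$h, 4)), numeric(1))
  t_v <- vapply(frames, function(fr) sum(tv * design_row(fr$e, fr$h, 2)), numeric(1))
  mh <- fit_mapping(frames, t_h, 4, "h")
  mv <- fit_mapping(frames, t_v, 2, "v")
  fr <- frames[[3]]
  por <- predict_por(mh, mv, fr$e, fr$h)
  expect_equal(unname(por), c(t_h[3], t_v[3]), tolerance = 1e-8)

  m2 <- mh; m2$coefficients <- 2 * mh$coefficients
  expect_equal(predict_por(m2, mv, fr$e, fr$h)[["g_h"]], 2 * por[["g_h"]],
               tolerance = 1e-9)
  m0 <- mh; m0$coefficients <- 0 * mh$coefficients
  expect_equal(predict_por(m0, m0, fr$e, fr$h), c(g_h = 0, g_v = 0))
})

test_that("pose-free presets are invariant to shuffling head pose across frames", {
  frames <- make_synth_frames(50, seed = 10)
  truth <- default_true_coeffs(2, "h", "left")
  targets <- vapply(frames, function(fr)
    sum(truth * design_row(fr$e, fr$h, 2)), numeric(1))
  shuffled <- frames
  perm <- sample(seq_along(frames))
  for (i in seq_along(frames)) shuffled[[i]]$h <- frames[[perm[i]]]$h
  f1 <- fit_mapping(frames, targets, 2, "h")
  f2 <- fit_mapping(shuffled, targets, 2, "h")
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-10)
})

test_that("binocular fusion interpolates between the eyes", {
  expect_equal(unname(fuse_por(c(10, 20), c(20, 10), 1)), c(10, 20))
  expect_equal(unname(fuse_por(c(10, 20), c(20, 10), 0)), c(20, 10))
  expect_equal(unname(fuse_por(c(10, 20), c(20, 10), 0.5)), c(15, 15))
  # fused POR lies on the segment between the eyes for all w
  for (w in seq(0, 1, 0.1)) {
    f <- fuse_por(c(3, -2), c(9, 4), w)
    expect_gte(f[["g_fh"]], 3); expect_lte(f[["g_fh"]], 9)
    expect_equal((f[["g_fh"]] - 9) / (3 - 9), (f[["g_fv"]] - 4) / (-2 - 4),
                 tolerance = 1e-12)
  }
  expect_error(fuse_por(c(0, 0), c(1, 1), 1.2), class = "fusion_error")
  expect_message(f <- fuse_por(c(1, 1), c(5, 5), 0.5, left_ok = FALSE))
  expect_equal(unname(f), c(5, 5))
  expect_error(fuse_por(c(1, 1), c(5, 5), 0.5, left_ok = FALSE, right_ok = FALSE),
               class = "fusion_error")
})

test_that("mapping models round-trip through JSON at full precision", {
  frames <- make_synth_frames(30, seed = 11)
  truth <- default_true_coeffs(4, "h", "right")
  targets <- vapply(frames, function(fr)
    sum(truth * design_row(fr$e, fr$h, 4)), numeric(1))
  m <- fit_mapping(frames, targets, 4, "h")
  path <- withr::local_tempfile(fileext = ".json")
  write_mapping_json(m, path)
  back <- read_mapping_json(path)
  expect_identical(back$terms, m$terms)
  expect_equal(back$coefficients, m$coefficients, tolerance = 1e-13)
  expect_equal(back$rms, m$rms, tolerance = 1e-10)
  expect_identical(back$preset, m$preset)
})
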