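test_that("normalized error matches its defining arithmetic", {
  gt_l <- c(100, 100); gt_r <- c(200, 100)
  expect_equal(normalized_error(gt_l, gt_r, gt_l, gt_r), 0)
  # both eyes off by 5% of the inter-center distance
  expect_equal(normalized_error(gt_l + c(5, 0), gt_r + c(0, 5), gt_l, gt_r), 0.05)
  # one eye off by a 3-4-5 displacement, d = 100
  expect_equal(normalized_error(gt_l + c(3, 4), gt_r, gt_l, gt_r), 0.05)
  expect_error(normalized_error(gt_l, gt_r, gt_l, gt_l), class = "metric_error")
})

test_that("normalized error is invariant under similarity transforms", {
  set.seed(12)
  pts <- list(est_l = c(101, 99), est_r = c(198, 103),
              gt_l = c(100, 100), gt_r = c(200, 100))
  e0 <- do.call(normalized_error, pts)
  for (k in 1:200) {
    th <- runif(1, -pi, pi); s <- exp(runif(1, -1.5, 1.5))
    t <- runif(2, -500, 500)
    Rm <- s * rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
    tp <- lapply(pts, function(p) as.numeric(Rm %*% p) + t)
    expect_equal(do.call(normalized_error, tp), e0, tolerance = 1e-9)
  }
})

test_that("angular errors satisfy the H/V/C geometry", {
  eye <- c(0, 0, 600)
  tgt <- c(50, 100, 0)
  expect_equal(unname(angular_errors(eye, tgt, tgt)), c(0, 0, 0))
  # pure horizontal displacement: V = 0, C = H
  a <- angular_errors(eye, c(0, 0, 0), c(100, 0, 0))
  expect_equal(a[["V"]], 0, tolerance = 1e-9)
  expect_equal(a[["C"]], a[["H"]])
  expect_equal(a[["H"]], atan2(100, 600) * 180 / pi, tolerance = 1e-9)
  # C is the root sum of squares: a 3-4-5 check
  a2 <- c(H = 3, V = 4); C <- sqrt(sum(a2^2))
  expect_equal(C, 5)
  expect_error(angular_errors(eye, eye, tgt), class = "metric_error")
})

test_that("screen points map to 3D and back exactly", {
  g <- screen_geometry(origin = c(-260, 20, 0), mm_per_unit = 0.5,
                       size = c(1040, 640))
  expect_equal(por_to_screen_3d(c(0, 0), g), g$origin)
  p <- por_to_screen_3d(c(520, 320), g)
  expect_equal(p, c(0, 180, 0))  # screen center for the centered default
  for (por in list(c(0, 0), c(313.7, 41.2), c(1040, 640))) {
    expect_equal(unname(screen_3d_to_por(por_to_screen_3d(por, g), g)), por,
                 tolerance = 1e-10)
  }
  expect_error(por_to_screen_3d(c(1, 1), list()), class = "geometry_error")
})

test_that("zero-noise sessions evaluate to numerically zero gaze error", {
  ses <- simulate_session(session_spec(n_calib_frames = 60, n_test_frames = 30,
                                       seed = 21L))
  rep <- evaluate_session(ses, n_calib = 60)
  expect_lt(rep$means[["C_L"]], 1e-6)
  expect_lt(rep$means[["C_R"]], 1e-6)
  expect_lt(rep$means[["C_F"]], 1e-6)
  expect_equal(rep$n_test, 30)
})

test_that("w = 1 and w = 0 reproduce the single-eye pipelines bit-for-bit", {
  ses <- simulate_session(session_spec(n_calib_frames = 60, n_test_frames = 30,
                                       pixel_noise_sigma = 1, seed = 22L))
  repL <- evaluate_session(ses, n_calib = 60, w = 1)
  repR <- evaluate_session(ses, n_calib = 60, w = 0)
  expect_identical(repL$per_frame$H_F, repL$per_frame$H_L)
  expect_identical(repL$per_frame$V_F, repL$per_frame$V_L)
  expect_identical(repL$per_frame$C_F, repL$per_frame$C_L)
  expect_identical(repR$per_frame$H_F, repR$per_frame$H_R)
  expect_identical(repR$per_frame$C_F, repR$per_frame$C_R)
})

test_that("per-frame C equals sqrt(H^2 + V^2) and means are arithmetic", {
  ses <- simulate_session(session_spec(n_calib_frames = 60, n_test_frames = 30,
                                       pixel_noise_sigma = 1.5, seed = 23L))
  rep <- evaluate_session(ses, n_calib = 60)
  pf <- rep$per_frame
  expect_equal(pf$C_L, sqrt(pf$H_L^2 + pf$V_L^2), tolerance = 1e-12)
  expect_equal(pf$C_F, sqrt(pf$H_F^2 + pf$V_F^2), tolerance = 1e-12)
  expect_equal(rep$means[["C_F"]], mean(pf$C_F))
})

test_that("undetected frames are excluded from both phases but counted in TF", {
  ses <- simulate_session(session_spec(n_calib_frames = 80, n_test_frames = 60,
                                       undetected_fraction = 0.15, seed = 24L))
  expect_lt(ses$DF, ses$TF)
  rep <- evaluate_session(ses, n_calib = 60)
  expect_equal(rep$TF, ses$TF)
  expect_equal(rep$DF, ses$DF)
  expect_equal(rep$n_test, ses$DF - 60)
  # all scored frames were detected ones
  expect_true(all(ses$frames$detected[match(rep$per_frame$frame_id,
                                            ses$frames$frame_id)]))
  # detection-rate bookkeeping is recomputable from the frame table
  expect_equal(rep$DF / rep$TF, mean(ses$frames$detected))
  expect_error(evaluate_session(ses, n_calib = ses$DF),
               class = "session_error")
})

test_that("the localization sweep tabulates hit counts over the grid", {
  bench <- make_iris_benchmark(n = 6, noise_sigma = 4, seed = 31L)
  tab <- sweep_localization(bench, alphas = c(0.23, 0.25), betas = c(1.36, 1.4),
                            deltas = c(1, 2))
  expect_equal(nrow(tab), 8)
  expect_true(all(tab$count >= 0 & tab$count <= 6))
  expect_equal(tab$rate, tab$count / 6)
  # the argmax row is at least as good as every other row, by definition
  expect_true(all(max(tab$count) >= tab$count))
  expect_error(sweep_localization(bench, alphas = numeric(0)),
               class = "sweep_error")
})

test_that("the fusion-weight sweep is flat on a zero-noise session", {
  ses <- simulate_session(session_spec(n_calib_frames = 60, n_test_frames = 20,
                                       seed = 32L))
  tab <- sweep_fusion_weight(ses, ws = c(0, 0.5, 1), n_calib = 60)
  expect_equal(nrow(tab), 3)
  expect_lt(max(tab$C), 1e-6)  # all weights equal when both eyes are exact
})

test_that("sessions round-trip through the directory format", {
  ses <- simulate_session(session_spec(n_calib_frames = 30, n_test_frames = 10,
                                       pixel_noise_sigma = 0.5,
                                       undetected_fraction = 0.1, seed = 33L))
  dir <- withr::local_tempdir()
  write_session(ses, dir)
  back <- read_session(dir)
  expect_equal(back$frames$e_lh, ses$frames$e_lh, tolerance = 1e-12)
  expect_equal(back$frames$detected, ses$frames$detected)
  expect_equal(back$geometry$origin, ses$geometry$origin)
  expect_equal(back$eyeballs$left, as.numeric(ses$eyeballs$left))
  expect_equal(back$TF, ses$TF); expect_equal(back$DF, ses$DF)
  # evaluation of the round-tripped session matches the original
  r1 <- evaluate_session(ses, n_calib = 25)
  r2 <- evaluate_session(back, n_calib = 25)
  expect_equal(r1$means, r2$means, tolerance = 1e-9)
})

test_that("published benchmark tables are internally consistent", {
  tabs <- reference_error_tables()
  expect_equal(nrow(tabs$by_preset), 12)
  expect_equal(nrow(tabs$by_participant), 28)
  # spot-check the best-preset row: H 5.7, V 4.0 combine to C 7.0
  r <- subset(tabs$by_preset, preset == 4 & delta == 2)
  expect_equal(round(sqrt(r$H^2 + r$V^2), 1), 7.0)
})
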