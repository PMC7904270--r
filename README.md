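# gazetrackr

Feature-based gaze tracking for a single camera under natural light, in R.

Remote eye trackers usually rely on infrared illumination; a plain webcam
gives none of that, only a low-resolution face image. `gazetrackr`
implements the classic regression pipeline for this setting, aimed at
eye-movement researchers who want an inspectable, fully testable reference
implementation of each stage:

1. **Eye-ROI extraction.** The twelve eye landmarks of the standard
   68-point annotation define a tight rectangle per eye (with a 3 px
   vertical margin); the crop is magnified ×2 and grayscale-eroded with a
   1-pixel disk to suppress specular glints.
2. **Iris-center localization by snakuscule.** A snakuscule is a minimal
   circular active contour — an inner disk and a concentric outer annulus
   with radius ratio β — scored by the gray contrast
   `G(p) = mean(annulus) − mean(disk)`. Instead of iterating a snake, the
   inner radius is fixed from anatomy, `r = round(αN)` with α ≈ 0.25 the
   iris-radius/ROI-width ratio, and `G` is maximized by an integer scan of
   `x ∈ [βr, N − βr]` along the horizontal centerline `y = ⌊M/2⌋`,
   followed by an exhaustive `(2δ+1)×(2δ+1)` refinement around the scan
   argmax. Defaults α = 0.25, β = 1.4, δ = 2.
3. **Anchor point.** The mean of the 36 stable landmarks (jaw, brows,
   nose; eyes and mouth excluded), a reference immune to eye rotation and
   far less noisy than a single eye corner. The eye vector is
   `e = p_iris − p_anchor`.
4. **Head pose.** Pitch/yaw/roll from six rigid landmarks (chin, nose
   tip, outer eye corners, mouth corners) by Levenberg–Marquardt
   minimization of the 2D–3D reprojection error against a generic face
   model.
5. **Gaze mapping.** Six nested polynomial presets map
   `(e_h, e_v, h_p, h_y, h_r)` to each screen coordinate, e.g. preset 4
   (horizontal default) uses
   `{1, e_h, e_v, e_h·e_v, e_h², e_v², h_p, h_y, h_r}` and preset 2
   (vertical default) the pose-free quadratic. Coefficients are fitted by
   least squares on a calibration phase (the first 1000 detected frames of
   a session, by protocol).
6. **Binocular fusion and metrics.** Left/right points of regard combine
   as `g_f = w·g_left + (1−w)·g_right` (default w = 0.5). Evaluation uses
   the normalized iris-center error `e = max(d_left, d_right)/d`
   (benchmark threshold e ≤ 0.05) and horizontal/vertical/combined angular
   gaze errors `C = sqrt(H² + V²)` measured from the 3D eyeball center.

Everything runs on synthetic data generated by the package itself:
rendered eye ROIs with known centers, projected landmark layouts with
known pose, and simulated calibration/test gaze sessions with known
mapping coefficients and 3D geometry.

## Worked example

```r
library(gazetrackr)

# a noisy 60x36 synthetic eye ROI with the iris truly at (29, 17)
rnd <- render_eye_roi(eye_spec(60, 36, center = c(29, 17),
                               noise_sigma = 8, seed = 42))
locate_iris(eye_roi(rnd$image))
#> <iris_result> center (ROI) = (29, 17), G = 139.87 [rough (29, 18),
#>   G = 126.42; r = 15, alpha = 0.25, beta = 1.4, delta = 2]
```

The centerline scan lands at (29, 18) — one pixel below the true center,
which sits slightly above the ROI midline — and the δ = 2 refinement
recovers (29, 17) exactly. `G ≈ 140` is the annulus−disk gray contrast at
the optimum (sclera 200, iris 60 in this rendering).

```r
ses <- simulate_session(session_spec(n_calib_frames = 200, n_test_frames = 80,
                                     pixel_noise_sigma = 1, seed = 1))
evaluate_session(ses, n_calib = 200)
#> <error_report> 200 calib + 80 test frames (DF/TF = 280/280 = 100.0%)
#>   left : H 0.7  V 0.5  C 1.0 deg
#>   right: H 0.8  V 0.5  C 1.0 deg
#>   fused: H 0.5  V 0.3  C 0.7 deg (w = 0.5)
```

With 1 px of eye-vector noise each eye alone tracks at about 1.0° combined
error; averaging the two points of regard (w = 0.5) cuts this to 0.7°,
the ~1/√2 variance reduction expected from fusing two similarly noisy
estimates.

```r
pose <- estimate_head_pose(
  render_face_landmarks(head_pose(10, -15, 5, t = c(0, 0, 650))),
  camera_from_image_size(640, 480))
#> <head_pose> pitch 10.00, yaw -15.00, roll 5.00 deg; ... RMSE 0.000 px
```

A command-line front end with `simulate`, `locate-iris`, `head-pose`,
`calibrate`, `track`, `evaluate` and `sweep-w` subcommands is installed at
`system.file("cli", "gazetool.R", package = "gazetrackr")`.

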