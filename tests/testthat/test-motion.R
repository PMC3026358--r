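# small single-object stream builder
make_stream <- function(tx, ty = 0 * tx, tz = 0 * tx,
                        rx = 0 * tx, ry = 0 * tx, rz = 0 * tx,
                        rate = 200, object = "obj") {
  n <- length(tx)
  motion_stream(data.frame(
    frame = seq_len(n), time_s = (seq_len(n) - 1) / rate, object = object,
    tx_mm = tx, ty_mm = ty, tz_mm = tz, rx = rx, ry = ry, rz = rz,
    visible_markers = "M1;M2;M3"), rate = rate)
}

test_that("convert_frame scales mm to cm and converts rotations", {
  s <- make_stream(100, rx = 0)
  poses <- convert_frame(s, 1)
  expect_equal(poses$obj$translation, c(10, 0, 0))
  expect_equal(unclass(poses$obj$rotation), c(w = 1, x = 0, y = 0, z = 0))
  poses1 <- convert_frame(s, 1, scale = 1)
  expect_equal(poses1$obj$translation, c(100, 0, 0))
})

test_that("scale 0.1 then 10 returns the original translation", {
  set.seed(61)
  s <- make_stream(rnorm(20, sd = 100), rnorm(20), rnorm(20))
  a <- convert_stream(s, scale = 0.1)
  b <- a$sx_cm * 10
  expect_equal(b, s$frames$tx_mm, tolerance = 1e-12)
})

test_that("stream conversion matches the rotation-matrix oracle and commutes with a fixed offset", {
  set.seed(67)
  n <- 30
  rv <- matrix(rnorm(3 * n), n, 3) * runif(n, 0, pi / sqrt(3))
  s <- make_stream(rnorm(n, sd = 50), rnorm(n, sd = 50), rnorm(n, sd = 50),
                   rv[, 1], rv[, 2], rv[, 3])
  conv <- convert_stream(s, scale = 0.1)
  off <- rigid_transform(matrix_to_quat(random_rotation_matrix()),
                         c(3, -2, 8))
  for (i in seq_len(n)) {
    q <- quaternion(conv$qw[i], conv$qx[i], conv$qy[i], conv$qz[i],
                    normalize = FALSE)
    expect_lt(rotmat_angle(quat_to_matrix(q), rodrigues_matrix(rv[i, ])),
              1e-9)
    # composing a fixed rigid offset commutes with the conversion
    pose_mm <- rigid_transform(q, c(s$frames$tx_mm[i], s$frames$ty_mm[i],
                                    s$frames$tz_mm[i]))
    comp <- compose_transform(off, pose_mm)
    R_direct <- rodrigues_matrix(quaternion_to_expmap(comp$rotation))
    R_oracle <- quat_to_matrix(off$rotation) %*% rodrigues_matrix(rv[i, ])
    expect_lt(rotmat_angle(R_direct, R_oracle), 1e-9)
  }
})

test_that("lowpass has unit DC gain and alpha = 1 is the identity", {
  s <- make_stream(rep(7, 50), rep(-2, 50), rz = rep(0.3, 50))
  for (a in c(0.1, 0.5, 1)) {
    f <- lowpass(s, a)
    expect_equal(f$frames$tx_mm, s$frames$tx_mm, tolerance = 1e-12)
    expect_equal(f$frames$rz, s$frames$rz, tolerance = 1e-12)
  }
  set.seed(71)
  s2 <- make_stream(rnorm(30), rnorm(30), rnorm(30), rnorm(30, sd = 0.3))
  f2 <- lowpass(s2, 1)
  expect_equal(f2$frames$tx_mm, s2$frames$tx_mm, tolerance = 1e-12)
  expect_equal(f2$frames$rx, s2$frames$rx, tolerance = 1e-9)
  expect_error(lowpass(s2, 0), class = "invalid_argument")
  expect_error(lowpass(s2, 1.2), class = "invalid_argument")
})

test_that("Nyquist attenuation matches the one-pole closed-form gain", {
  alpha <- 0.2
  n <- 400
  s <- make_stream(rep(c(1, -1), n / 2))
  f <- lowpass(s, alpha)
  steady <- abs(f$frames$tx_mm[n])
  expect_equal(steady, lowpass_gain(alpha, pi), tolerance = 1e-6)
  expect_equal(lowpass_gain(alpha, pi), alpha / (2 - alpha),
               tolerance = 1e-12)
  expect_equal(lowpass_gain(alpha, 0), 1, tolerance = 1e-12)
})

test_that("lowpass preserves length, timestamps, rate and unit rotations", {
  set.seed(73)
  s <- make_stream(cumsum(rnorm(40)), rx = cumsum(rnorm(40, sd = 0.02)))
  f <- lowpass(s, 0.3)
  expect_equal(nrow(f$frames), nrow(s$frames))
  expect_equal(f$frames$time_s, s$frames$time_s)
  expect_equal(f$rate, s$rate)
  conv <- convert_stream(f)
  expect_equal(sqrt(conv$qw^2 + conv$qx^2 + conv$qy^2 + conv$qz^2),
               rep(1, 40), tolerance = 1e-9)
})

test_that("filtering reduces noise RMSE on synthetic trajectories at every sigma", {
  for (sg in c(0.1, 0.5, 1.0)) {
    sim <- noisy_pose_stream(300, sg, seed = 79 + round(10 * sg))
    filt <- lowpass(sim$stream, tuned_alpha(sg))
    truth <- as.matrix(sim$truth[, c("tx_mm", "ty_mm", "tz_mm")])
    raw <- as.matrix(sim$stream$frames[, c("tx_mm", "ty_mm", "tz_mm")])
    sm <- as.matrix(filt$frames[, c("tx_mm", "ty_mm", "tz_mm")])
    rmse <- function(x) sqrt(mean((x - truth)^2))
    expect_lt(rmse(sm), rmse(raw))
  }
})

test_that("fill_occlusions interpolates interior gaps and reports the rest", {
  s <- make_stream(c(0, NA, 2, 5, NA, NA, NA, NA, NA, 8, 9))
  res <- fill_occlusions(s, max_gap = 3)
  expect_equal(res$stream$frames$tx_mm[2], 1)       # midpoint
  expect_true(all(is.na(res$stream$frames$tx_mm[5:9])))  # 5-frame gap kept
  expect_equal(nrow(res$unresolved_gaps), 1L)
  expect_equal(res$unresolved_gaps$length, 5L)
  expect_equal(res$unresolved_gaps$reason, "gap too long")
  # originally present frames never change
  ok <- !is.na(s$frames$tx_mm)
  expect_equal(res$stream$frames$tx_mm[ok], s$frames$tx_mm[ok])
})

test_that("rotation gaps are filled by slerp; boundary gaps stay unresolved", {
  s <- make_stream(c(0, NA, 0), rz = c(0, NA, pi / 2))
  res <- fill_occlusions(s, max_gap = 1)
  expect_equal(res$stream$frames$rz[2], pi / 4, tolerance = 1e-9)

  sb <- make_stream(c(NA, 1, 2))
  resb <- fill_occlusions(sb, max_gap = 5)
  expect_true(is.na(resb$stream$frames$tx_mm[1]))
  expect_equal(resb$unresolved_gaps$reason, "stream boundary")

  # idempotence
  clean <- make_stream(1:10)
  res1 <- fill_occlusions(clean, 3)
  expect_equal(res1$stream$frames, clean$frames)
  expect_equal(nrow(res1$unresolved_gaps), 0L)
  res2 <- fill_occlusions(fill_occlusions(s, 1)$stream, 1)
  expect_equal(res2$stream$frames, fill_occlusions(s, 1)$stream$frames)
})

test_that("orientation flips are flagged exactly where geodesic jumps exceed threshold", {
  # smooth 1-degree-per-frame rotation: no flips
  n <- 90
  s <- make_stream(rep(0, n), rz = (seq_len(n) - 1) * pi / 180)
  expect_equal(nrow(detect_orientation_flips(s)), 0L)

  # one injected 180-degree flip
  rz <- rep(0, 20); rz[10:20] <- pi
  s2 <- make_stream(rep(0, 20), rz = rz)
  flips <- detect_orientation_flips(s2)
  expect_equal(flips$frame, 10L)

  # random streams against a brute-force pairwise scan
  set.seed(83)
  for (rep_i in 1:5) {
    rv <- matrix(rnorm(60, sd = 1), 20, 3)
    s3 <- make_stream(rep(0, 20), rx = rv[, 1], ry = rv[, 2], rz = rv[, 3])
    got <- detect_orientation_flips(s3, angle_threshold = 1.0)$frame
    want <- integer(0)
    for (i in 2:20) {
      a <- rodrigues_matrix(rv[i - 1, ]); b <- rodrigues_matrix(rv[i, ])
      if (rotmat_angle(a, b) > 1.0) want <- c(want, i)
    }
    expect_equal(got, want, ignore_attr = TRUE)
  }
})

test_that("capture CSV round-trips streams including occlusions", {
  set.seed(89)
  ms <- gen_marker_cloud(4, seed = 89)
  sim <- gen_rigid_trajectory(
    trajectory_spec(n_frames = 40, noise_sigma = 0.2, dropout_rate = 0.2,
                    seed = 89), ms)
  f <- withr::local_tempfile(fileext = ".csv")
  write_capture_csv(sim$stream, f)
  s2 <- read_capture_csv(f)
  expect_equal(s2$rate, sim$stream$rate)
  expect_equal(s2$frames$tx_mm, sim$stream$frames$tx_mm, tolerance = 1e-6)
  expect_equal(is.na(s2$frames$rx), is.na(sim$stream$frames$rx))
  expect_equal(s2$frames$visible_markers, sim$stream$frames$visible_markers)
})

test_that("stream invariants are enforced", {
  df <- data.frame(frame = 1:2, time_s = c(0, 0), object = "o",
                   tx_mm = 0, ty_mm = 0, tz_mm = 0, rx = 0, ry = 0, rz = 0,
                   visible_markers = "")
  expect_error(motion_stream(df), class = "invalid_argument")
  expect_error(motion_stream(df[0, ]), class = "invalid_argument")
  df2 <- df; df2$time_s <- c(0, 0.005)
  expect_error(motion_stream(df2, rate = 0), class = "invalid_argument")
})
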