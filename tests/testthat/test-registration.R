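test_that("exact configurations are recovered exactly", {
  tri <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  r <- fit_rigid_transform(tri, tri)
  expect_equal(r$rms_residual, 0, tolerance = 1e-12)
  expect_equal(quat_to_matrix(r$transform$rotation), diag(3),
               tolerance = 1e-9)

  r <- fit_rigid_transform(tri, tri + matrix(5, 3, 3))
  expect_equal(r$transform$translation, c(5, 5, 5), tolerance = 1e-12)
  expect_equal(quat_to_matrix(r$transform$rotation), diag(3),
               tolerance = 1e-9)

  src <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  dst <- rbind(c(0, 1, 0), c(-1, 0, 0), c(0, 0, 1))
  r <- fit_rigid_transform(src, dst)
  Rz90 <- rodrigues_matrix(c(0, 0, pi / 2))
  expect_equal(r$rotation_matrix, Rz90, tolerance = 1e-9)
  expect_equal(r$transform$translation, c(0, 0, 0), tolerance = 1e-9)
  expect_lt(r$rms_residual, 1e-9)
})

test_that("minimum-marker law: fewer than 3 or collinear sets are underdetermined", {
  expect_error(fit_rigid_transform(rbind(c(0, 0, 0), c(1, 0, 0)),
                                   rbind(c(0, 0, 0), c(1, 0, 0))),
               class = "underdetermined_error")
  line <- rbind(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2))
  expect_error(fit_rigid_transform(line, line),
               class = "underdetermined_error")
  expect_error(fit_rigid_transform(diag(3), diag(3)[1:2, ]),
               class = "invalid_argument")
  # 3 non-collinear markers succeed
  expect_s3_class(fit_rigid_transform(rbind(c(0,0,0), c(10,0,0), c(0,10,0)),
                                      rbind(c(1,1,1), c(11,1,1), c(1,11,1))),
                  "registration_result")
})

test_that("noise-free recovery of random rigid transforms is exact, det(R) = +1", {
  set.seed(23)
  for (i in 1:50) {
    n <- sample(3:12, 1)
    repeat {
      src <- matrix(rnorm(3 * n, sd = 20), n, 3)
      if (n > 3 || abs(det(rbind(src[2, ] - src[1, ], src[3, ] - src[1, ],
                                 c(1, 1, 1)))) > 1e-3) break
    }
    R <- random_rotation_matrix()
    tr <- rnorm(3, sd = 50)
    dst <- src %*% t(R) + matrix(tr, n, 3, byrow = TRUE)
    fit <- fit_rigid_transform(src, dst)
    expect_lt(rotmat_angle(fit$rotation_matrix, R), 1e-9)
    expect_lt(max(abs(fit$transform$translation - tr)), 1e-9)
    expect_lt(fit$rms_residual, 1e-9)
    expect_equal(det(fit$rotation_matrix), 1, tolerance = 1e-9)
  }
})

test_that("reflection correction keeps det(R) = +1 on mirrored/noisy inputs", {
  set.seed(29)
  for (i in 1:20) {
    src <- matrix(rnorm(15), 5, 3)
    dst <- src %*% diag(c(-1, 1, 1)) + matrix(rnorm(15, sd = 0.05), 5, 3)
    fit <- fit_rigid_transform(src, dst)
    expect_equal(det(fit$rotation_matrix), 1, tolerance = 1e-9)
  }
})

test_that("noisy fits agree with the independent Horn quaternion oracle", {
  set.seed(31)
  for (i in 1:30) {
    n <- sample(4:8, 1)
    src <- matrix(rnorm(3 * n, sd = 10), n, 3)
    R <- random_rotation_matrix()
    dst <- src %*% t(R) + matrix(rnorm(3, sd = 5), n, 3, byrow = TRUE) +
      matrix(rnorm(3 * n, sd = 0.1), n, 3)
    fit <- fit_rigid_transform(src, dst)
    h <- horn_fit(src, dst)
    expect_lt(rotmat_angle(fit$rotation_matrix, h$R), 1e-9)
    expect_lt(max(abs(fit$transform$translation - h$t)), 1e-9)
  }
})

test_that("recovered rotation within 1 degree under sigma = 0.1 noise on 20 points", {
  set.seed(37)
  src <- matrix(rnorm(60, sd = 10), 20, 3)
  R <- random_rotation_matrix()
  dst <- src %*% t(R) + matrix(c(5, -3, 2), 20, 3, byrow = TRUE) +
    matrix(rnorm(60, sd = 0.1), 20, 3)
  fit <- fit_rigid_transform(src, dst)
  expect_lt(rotmat_angle(fit$rotation_matrix, R), pi / 180)
  expect_lt(fit$rms_residual, 0.1 * 3)  # rms of order sigma
  expect_gt(fit$rms_residual, 0)
})

test_that("rms residual is invariant under a common rigid motion of both clouds", {
  set.seed(41)
  src <- matrix(rnorm(18, sd = 5), 6, 3)
  dst <- src %*% t(random_rotation_matrix()) + matrix(rnorm(18, sd = 0.2), 6, 3)
  base <- fit_rigid_transform(src, dst)$rms_residual
  Q <- random_rotation_matrix(); s <- rnorm(3)
  move <- function(p) p %*% t(Q) + matrix(s, nrow(p), 3, byrow = TRUE)
  expect_equal(fit_rigid_transform(move(src), move(dst))$rms_residual, base,
               tolerance = 1e-9)
})

test_that("adding an exact pair never increases rms on noise-free data", {
  set.seed(43)
  R <- random_rotation_matrix(); tr <- c(1, 2, 3)
  src <- matrix(rnorm(30, sd = 10), 10, 3)
  dst <- src %*% t(R) + matrix(tr, 10, 3, byrow = TRUE)
  rms <- vapply(3:10, function(k)
    fit_rigid_transform(src[1:k, ], dst[1:k, ])$rms_residual, numeric(1))
  expect_true(all(diff(rms) <= 1e-12))
  expect_true(all(rms < 1e-9))
})

test_that("register_captured maps virtual points onto captured markers", {
  set.seed(47)
  virt <- rbind(c(0, 0, 0), c(20, 0, 0), c(0, 15, 0), c(0, 0, 10),
                c(8, 9, 2), c(-5, 4, 7))
  R <- random_rotation_matrix(); tr <- c(100, -50, 30)
  capd <- virt %*% t(R) + matrix(tr, 6, 3, byrow = TRUE)
  ms <- marker_set(capd)
  corr <- correspondence(paste0("M", 1:6), virt)
  res <- register_captured(ms, corr)
  expect_lt(res$rms_residual, 1e-9)
  expect_lt(rotmat_angle(res$rotation_matrix, R), 1e-9)
  # transform maps model frame -> capture frame
  expect_equal(apply_transform(res$transform, virt), capd, tolerance = 1e-9)

  # a single perturbed pair has the largest per-pair residual
  capd2 <- capd; capd2[4, ] <- capd2[4, ] + c(1, 0, 0)
  res2 <- register_captured(marker_set(capd2), corr)
  expect_equal(which.max(res2$per_pair_residuals), 4L,
               ignore_attr = TRUE)
  # brute-force residual of the perturbed pair matches the report
  fitted <- apply_transform(res2$transform, virt)
  expect_equal(unname(res2$per_pair_residuals),
               sqrt(rowSums((fitted - capd2)^2)), tolerance = 1e-12)

  expect_error(register_captured(ms, correspondence(c("M1", "M2", "ghost"),
                                                    virt[1:3, ])),
               class = "invalid_argument")
})

test_that("place_virtual_markers snaps picks and warns on crowding", {
  cube <- cube_mesh()
  # exact vertices pass through verbatim
  ms <- place_virtual_markers(cube, rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                              min_separation = 0.1)
  expect_equal(unname(ms$positions),
               rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)))
  # a pick slightly above a face is projected onto the face plane
  ms2 <- place_virtual_markers(cube, rbind(c(0.5, 0.5, 1.001), c(0, 0, 0),
                                           c(1, 1, 0)), snap_tol = 0.01,
                               min_separation = 0.1)
  expect_equal(unname(ms2$positions[1, ]), c(0.5, 0.5, 1), tolerance = 1e-12)
  # point-triangle projection oracle: distance to the nearest surface point
  expect_equal(closest_surface_point(cube, c(0.5, 0.5, 1.001))$distance,
               0.001, tolerance = 1e-12)
  # far picks are rejected
  expect_error(place_virtual_markers(cube, rbind(c(0.5, 0.5, 3), c(0, 0, 0),
                                                 c(1, 1, 0))),
               class = "invalid_pick_error")
  # crowded markers trigger the proximity warning
  expect_warning(place_virtual_markers(
    cube, rbind(c(0, 0, 0), c(0.1, 0, 0), c(0, 1, 0)), min_separation = 1),
    class = "marker_proximity_warning")
})
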