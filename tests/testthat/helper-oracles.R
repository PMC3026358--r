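# independent oracles and in-code fixtures used across the suite

# Rodrigues rotation-matrix oracle for an exponential-map vector
rodrigues_matrix <- function(r) {
  th <- sqrt(sum(r^2))
  if (th < 1e-14) return(diag(3))
  k <- r / th
  K <- matrix(c(0, -k[3], k[2],
                k[3], 0, -k[1],
                -k[2], k[1], 0), 3L, 3L, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# geodesic angle between two rotation matrices via the Frobenius chord
# identity ||R1 - R2||_F = 2 sqrt(2) |sin(theta/2)| (well conditioned at 0)
rotmat_angle <- function(R1, R2) {
  d <- sqrt(sum((R1 - R2)^2))
  2 * asin(min(1, d / (2 * sqrt(2))))
}

# Horn's closed-form absolute orientation: maximal eigenvector of the 4x4
# quaternion matrix built from the cross-covariance. Independent of the
# package's SVD path.
horn_fit <- function(src, dst) {
  cs <- colMeans(src); cd <- colMeans(dst)
  S <- crossprod(sweep(src, 2, cs), sweep(dst, 2, cd))
  N <- matrix(c(
    S[1,1]+S[2,2]+S[3,3], S[2,3]-S[3,2],        S[3,1]-S[1,3],        S[1,2]-S[2,1],
    S[2,3]-S[3,2],        S[1,1]-S[2,2]-S[3,3], S[1,2]+S[2,1],        S[3,1]+S[1,3],
    S[3,1]-S[1,3],        S[1,2]+S[2,1],       -S[1,1]+S[2,2]-S[3,3], S[2,3]+S[3,2],
    S[1,2]-S[2,1],        S[3,1]+S[1,3],        S[2,3]+S[3,2],       -S[1,1]-S[2,2]+S[3,3]
  ), 4L, 4L, byrow = TRUE)
  q <- eigen(N, symmetric = TRUE)$vectors[, 1L]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1-2*(y^2+z^2), 2*(x*y-w*z),   2*(x*z+w*y),
    2*(x*y+w*z),   1-2*(x^2+z^2), 2*(y*z-w*x),
    2*(x*z-w*y),   2*(y*z+w*x),   1-2*(x^2+y^2)), 3L, 3L, byrow = TRUE)
  list(R = R, t = cd - drop(R %*% cs))
}

# uniform random rotation (matrix) from a normalized Gaussian quaternion
random_rotation_matrix <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1-2*(y^2+z^2), 2*(x*y-w*z),   2*(x*z+w*y),
    2*(x*y+w*z),   1-2*(x^2+z^2), 2*(y*z-w*x),
    2*(x*z-w*y),   2*(y*z+w*x),   1-2*(x^2+y^2)), 3L, 3L, byrow = TRUE)
}

# slow rigid trajectory with iid Gaussian jitter added to the streamed pose
# translations (vibration-style noise on the delivered pose), plus ground
# truth -- the conditions of the low-pass smoothing study
noisy_pose_stream <- function(n_frames, sigma, seed, amplitude = 5) {
  spec <- trajectory_spec(n_frames = n_frames, amplitude_mm = amplitude,
                          noise_sigma = 0, seed = seed)
  ms <- marker_set(rbind(c(0, 0, 0), c(30, 0, 0), c(0, 30, 0), c(0, 0, 30)))
  sim <- gen_rigid_trajectory(spec, ms)
  set.seed(seed + 1)
  f <- sim$stream$frames
  f$tx_mm <- f$tx_mm + rnorm(n_frames, sd = sigma)
  f$ty_mm <- f$ty_mm + rnorm(n_frames, sd = sigma)
  f$tz_mm <- f$tz_mm + rnorm(n_frames, sd = sigma)
  list(stream = motion_stream(f, rate = spec$rate), truth = sim$truth)
}

# noise-matched smoothing factor for the one-pole filter: heavier noise
# affords heavier smoothing before the lag bias dominates
tuned_alpha <- function(sigma) {
  if (sigma <= 0.1) 0.7 else if (sigma <= 0.5) 0.4 else 0.3
}

# unit cube [0,1]^3, 12 triangles
cube_mesh <- function() {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  f <- rbind(
    c(1,3,2), c(2,3,4),   # z = 0
    c(5,6,7), c(6,8,7),   # z = 1
    c(1,2,5), c(2,6,5),   # y = 0
    c(3,7,4), c(4,7,8),   # y = 1
    c(1,5,3), c(3,5,7),   # x = 0
    c(2,4,6), c(4,8,6))   # x = 1
  surface_mesh(v, f)
}

# axial bar benchmark: block fixed with roller supports at x = 0 and a
# consistent uniform end traction F/A at x = L; closed-form tip
# displacement F*L/(E*A), uniform stress F/A
bar_mesh <- function(nx = 6, ny = 2, nz = 2, L = 60, w = 10, F = 50,
                     E = 1000, nu = 0.3) {
  m <- gen_block_tetmesh(nx, ny, nz, dims = c(L, w, w),
                         material = material(E, nu))
  nod <- m$nodes
  left <- which(nod[, 1] == 0)
  cons <- rbind(
    data.frame(node = left, dof = 1L, value = 0),
    data.frame(node = which(nod[, 1] == 0 & nod[, 2] == 0 & nod[, 3] == 0),
               dof = 2:3, value = 0),
    data.frame(node = which(nod[, 1] == 0 & nod[, 2] == w & nod[, 3] == 0),
               dof = 3L, value = 0))
  loads <- face_traction_loads(m, function(n) n[, 1] == L,
                               c(F / w^2, 0, 0))
  tet_mesh(m$nodes, m$elements, m$material, cons, loads)
}
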