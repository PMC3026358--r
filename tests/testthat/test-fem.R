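test_that("von Mises closed forms: uniaxial, hydrostatic, pure shear", {
  expect_equal(von_mises(c(100, 0, 0, 0, 0, 0)), 100)
  expect_equal(von_mises(diag(3) * 7), 0)
  tau <- 12
  expect_equal(von_mises(c(0, 0, 0, tau, 0, 0)), sqrt(3) * tau)
  expect_equal(von_mises(matrix(c(0, tau, 0, tau, 0, 0, 0, 0, 0), 3, 3)),
               sqrt(3) * tau)
  expect_error(von_mises(matrix(c(0, 1, 0, 0, 0, 0, 0, 0, 0), 3, 3)),
               class = "invalid_argument")
})

test_that("fully constrained mesh under zero load has zero displacement", {
  m <- gen_block_tetmesh(2, 2, 2, dims = c(10, 10, 10))
  m <- tet_mesh(m$nodes, m$elements, m$material,
                constraints = fix_nodes(seq_len(nrow(m$nodes))))
  res <- solve_static(m)
  expect_equal(max(abs(res$displacements)), 0)
  expect_equal(res$max_von_mises, 0)
})

test_that("axial bar reproduces the closed-form tip displacement and stress", {
  E <- 1000; L <- 60; w <- 10; F <- 50; A <- w^2
  m <- bar_mesh(L = L, w = w, F = F, E = E)
  res <- solve_static(m)
  tip <- max(res$displacements[m$nodes[, 1] == L, 1])
  expect_equal(tip, F * L / (E * A), tolerance = 0.02)
  expect_equal(res$max_von_mises, F / A, tolerance = 0.02)
})

test_that("patch test: prescribed uniform strain reproduces uniform stress to 1e-8", {
  E <- 500; nu <- 0.25; eps <- 1e-3
  m <- gen_block_tetmesh(2, 2, 2, dims = c(2, 2, 2),
                         material = material(E, nu))
  nod <- m$nodes
  boundary <- which(nod[, 1] %in% c(0, 2) | nod[, 2] %in% c(0, 2) |
                      nod[, 3] %in% c(0, 2))
  # prescribed field u = (eps * x, 0, 0) on every boundary node
  cons <- do.call(rbind, lapply(boundary, function(nd)
    data.frame(node = nd, dof = 1:3, value = c(eps * nod[nd, 1], 0, 0))))
  m <- tet_mesh(m$nodes, m$elements, m$material, constraints = cons)
  res <- solve_static(m)
  # analytic uniform-strain stress (only e_xx = eps non-zero)
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu)); mu <- E / (2 * (1 + nu))
  sxx <- (lam + 2 * mu) * eps; syy <- lam * eps
  expect_equal(unname(res$element_stress[, "xx"]),
               rep(sxx, nrow(res$element_stress)), tolerance = 1e-8)
  expect_equal(unname(res$element_stress[, "yy"]),
               rep(syy, nrow(res$element_stress)), tolerance = 1e-8)
  expect_equal(unname(res$element_stress[, "zz"]),
               rep(syy, nrow(res$element_stress)), tolerance = 1e-8)
  expect_lt(max(abs(res$element_stress[, c("xy", "yz", "zx")])),
            1e-8 * sxx)
  # interior node displacement follows the linear field
  interior <- setdiff(seq_len(nrow(nod)), boundary)
  expect_equal(unname(res$displacements[interior, 1]),
               unname(eps * nod[interior, 1]), tolerance = 1e-8)
})

test_that("global equilibrium: reactions balance applied loads", {
  m <- bar_mesh(F = 50)
  res <- solve_static(m)
  total_load <- c(sum(m$loads$fx), sum(m$loads$fy), sum(m$loads$fz))
  total_reaction <- colSums(res$reactions)
  expect_lt(max(abs(total_reaction + total_load)) / max(abs(total_load)),
            1e-8)
})

test_that("stiffness matrix is SPD after constraints; free-free has 6 rigid-body modes", {
  m <- gen_block_tetmesh(1, 1, 1, dims = c(1, 1, 1),
                         material = material(100, 0.3))
  K <- as.matrix(assemble_stiffness(m))
  expect_equal(K, t(K), tolerance = 1e-12)
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(ev < 1e-9 * max(ev)), 6L)       # exactly 6 zero-energy modes
  expect_true(all(ev > -1e-9 * max(ev)))
  # after eliminating one fixed face the reduced matrix is positive definite
  fixed <- which(m$nodes[, 1] == 0)
  cdof <- c(3 * (fixed - 1) + 1, 3 * (fixed - 1) + 2, 3 * (fixed - 1) + 3)
  Kff <- K[-cdof, -cdof]
  expect_gt(min(eigen(Kff, symmetric = TRUE, only.values = TRUE)$values), 0)
})

test_that("insufficient constraints raise a rigid-body-mode error naming the null space", {
  m <- gen_block_tetmesh(1, 1, 1, dims = c(1, 1, 1))
  m <- tet_mesh(m$nodes, m$elements, m$material,
                constraints = data.frame(node = 1L, dof = 1L, value = 0),
                loads = data.frame(node = 8L, fx = 1, fy = 0, fz = 0))
  err <- expect_error(solve_static(m), class = "rigid_body_mode_error")
  expect_match(conditionMessage(err), "null-space dimension [1-9]")
})

test_that("solution scales linearly with load magnitude", {
  m <- bar_mesh(F = 10)
  r1 <- solve_static(m)
  m2 <- m
  m2$loads[, c("fx", "fy", "fz")] <- m$loads[, c("fx", "fy", "fz")] * 3.5
  r2 <- solve_static(m2)
  expect_equal(r2$displacements, 3.5 * r1$displacements, tolerance = 1e-9)
  expect_equal(r2$von_mises, 3.5 * r1$von_mises, tolerance = 1e-9)
})

test_that("bar tip-displacement error decreases monotonically under refinement", {
  E <- 1000; L <- 60; w <- 10; F <- 50; A <- w^2
  exact <- F * L / (E * A)
  errs <- vapply(list(c(2, 1, 1), c(4, 2, 2), c(8, 3, 3)), function(nn) {
    # clamp all DOFs at x = 0 so the discrete solution is not exact and
    # refinement has something to converge
    m <- gen_block_tetmesh(nn[1], nn[2], nn[3], dims = c(L, w, w),
                           material = material(E, 0.3))
    cons <- fix_nodes(which(m$nodes[, 1] == 0))
    loads <- face_traction_loads(m, function(n) n[, 1] == L,
                                 c(F / A, 0, 0))
    res <- solve_static(tet_mesh(m$nodes, m$elements, m$material, cons,
                                 loads))
    abs(max(res$displacements[m$nodes[, 1] == L, 1]) - exact) / exact
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("critical force sweep: closed form, linearity, bisection agreement", {
  E <- 1000; L <- 60; w <- 10; A <- w^2; Y <- 2.5
  m <- bar_mesh(L = L, w = w, F = 1, E = E)    # unit (1 N) load pattern
  fc <- critical_force_sweep(m, yield_stress = Y)
  expect_equal(fc, Y * A, tolerance = 0.02)
  expect_equal(critical_force_sweep(m, yield_stress = 2 * Y), 2 * fc,
               tolerance = 1e-9)

  tol <- 0.05
  fb <- critical_force_sweep(m, yield_stress = Y, f_max = 1000, tol = tol,
                             method = "bisection")
  expect_equal(fb, fc, tolerance = tol / fc)

  # corner-loaded block: linear formula still matches the bisection oracle
  blk <- gen_block_tetmesh(2, 2, 2, dims = c(10, 10, 10),
                           material = material(1000, 0.3))
  corner <- which(blk$nodes[, 1] == 10 & blk$nodes[, 2] == 10 &
                    blk$nodes[, 3] == 10)
  blk <- tet_mesh(blk$nodes, blk$elements, blk$material,
                  constraints = fix_nodes(which(blk$nodes[, 3] == 0)),
                  loads = data.frame(node = corner, fx = 0, fy = 0, fz = -1))
  fl <- critical_force_sweep(blk, yield_stress = 5)
  fbb <- critical_force_sweep(blk, yield_stress = 5, f_max = 10 * fl,
                              tol = fl * 1e-3, method = "bisection")
  expect_equal(fbb, fl, tolerance = 1e-3)

  expect_error(critical_force_sweep(m, yield_stress = 1e9, f_max = 100),
               class = "no_critical_force_error")
})

test_that("critical region selection follows the stress quantile", {
  m <- bar_mesh(F = 50)
  res <- solve_static(m)
  expect_equal(identify_critical_region(res, fraction = 1),
               seq_along(res$von_mises))
  top <- identify_critical_region(res, fraction = 0.1)
  # matches a sorted-stress scan
  q <- quantile(res$von_mises, 0.9, names = FALSE)
  expect_equal(top, which(res$von_mises >= q))
  expect_true(all(res$von_mises[top] >= max(res$von_mises[-top])))
})

test_that("degenerate and inverted elements are handled at construction", {
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  # inverted ordering is repaired (positive volume after orientation fix)
  m <- tet_mesh(nodes, matrix(c(1, 2, 4, 3), 1), material(1, 0.3))
  p <- m$nodes[m$elements[1, ], ]
  expect_gt(det(cbind(p[2, ] - p[1, ], p[3, ] - p[1, ], p[4, ] - p[1, ])), 0)
  # zero-volume element is a mesh-quality error
  flat <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0))
  expect_error(tet_mesh(flat, matrix(1:4, 1), material(1, 0.3)),
               class = "mesh_quality_error")
})

test_that("VTK and MSH round-trip tet meshes; results serialize to VTK", {
  m <- bar_mesh(nx = 2, ny = 1, nz = 1)
  res <- solve_static(m)
  f <- withr::local_tempfile(fileext = ".vtk")
  write_vtk(m, f, res)
  m2 <- read_tet_mesh(f, m$material)
  expect_equal(m2$nodes, m$nodes, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(nrow(m2$elements), nrow(m$elements))
  txt <- readLines(f)
  expect_true(any(grepl("VECTORS displacement", txt)))
  expect_true(any(grepl("SCALARS von_mises", txt)))

  fm <- withr::local_tempfile(fileext = ".msh")
  nod <- m$nodes; el <- m$elements
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat",
               "$Nodes", nrow(nod),
               sprintf("%d %g %g %g", seq_len(nrow(nod)), nod[, 1],
                       nod[, 2], nod[, 3]),
               "$EndNodes", "$Elements", nrow(el),
               sprintf("%d 4 2 0 1 %d %d %d %d", seq_len(nrow(el)),
                       el[, 1], el[, 2], el[, 3], el[, 4]),
               "$EndElements"), fm)
  m3 <- read_tet_mesh(fm, m$material)
  expect_equal(m3$nodes, m$nodes, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(mesh_volume(m3), mesh_volume(m), tolerance = 1e-9)
})

test_that("material and constraint validation", {
  expect_error(material(-1, 0.3), class = "invalid_argument")
  expect_error(material(100, 0.5), class = "invalid_argument")
  m <- gen_block_tetmesh(1, 1, 1)
  expect_error(tet_mesh(m$nodes, m$elements, m$material,
                        constraints = data.frame(node = 1, dof = 4,
                                                 value = 0)),
               class = "invalid_argument")
  expect_warning(tet_mesh(m$nodes, m$elements, m$material,
                          constraints = fix_nodes(1),
                          loads = data.frame(node = 1, fx = 1, fy = 0,
                                             fz = 0)),
                 class = "constrained_load_warning")
})
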