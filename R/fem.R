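#' Isotropic linear-elastic material
#'
#' @param E Young's modulus (force / length^2; any consistent unit system —
#'   with node coordinates in mm and loads in N, give `E` in MPa and
#'   stresses come back in MPa).
#' @param nu Poisson's ratio, in `(-1, 0.5)`.
#' @return Object of class `"material"`.
#' @export
material <- function(E, nu) {
  if (!is.numeric(E) || length(E) != 1L || !is.finite(E) || E <= 0)
    abort_rt("Young's modulus must be a positive number", "invalid_argument")
  if (!is.numeric(nu) || length(nu) != 1L || nu <= -1 || nu >= 0.5)
    abort_rt("Poisson's ratio must lie in (-1, 0.5)", "invalid_argument")
  structure(list(E = E, nu = nu), class = "material")
}

# 6x6 isotropic elasticity matrix (engineering shear strains)
elasticity_matrix <- function(mat) {
  lam <- mat$E * mat$nu / ((1 + mat$nu) * (1 - 2 * mat$nu))
  mu <- mat$E / (2 * (1 + mat$nu))
  D <- diag(c(rep(lam + 2 * mu, 3), rep(mu, 3)))
  D[1:3, 1:3][upper.tri(diag(3)) | lower.tri(diag(3))] <- lam
  D
}

#' Fix all three DOFs of a set of nodes
#'
#' Convenience builder for the `constraints` slot of [tet_mesh]: each listed
#' node gets all three displacement components prescribed (default zero).
#'
#' @param nodes Integer node indices.
#' @param value Prescribed displacement 3-vector, default `c(0, 0, 0)`.
#' @return Constraint `data.frame` with columns `node`, `dof`, `value`.
#' @export
fix_nodes <- function(nodes, value = c(0, 0, 0)) {
  nodes <- as.integer(nodes)
  data.frame(node = rep(nodes, each = 3L),
             dof = rep(1:3, length(nodes)),
             value = rep(as.numeric(value), length(nodes)))
}

#' Tetrahedral solid mesh with material, constraints and loads
#'
#' Element orientation is fixed at construction (node order swapped when the
#' signed volume is negative); elements with vanishing volume raise a
#' mesh-quality error. Constraints are per-DOF Dirichlet conditions
#' (`data.frame` with `node`, `dof` in 1:3, `value`); loads are nodal point
#' forces (`data.frame` with `node`, `fx`, `fy`, `fz`). A node that is both
#' constrained and loaded is legal but warned about (the load is absorbed by
#' the reaction).
#'
#' @param nodes `n x 3` node coordinates (mm).
#' @param elements `m x 4` node-index quadruples.
#' @param material A [material].
#' @param constraints Constraint `data.frame` (see [fix_nodes]) or `NULL`.
#' @param loads Load `data.frame` or `NULL`.
#' @return Object of class `"tet_mesh"`.
#' @export
tet_mesh <- function(nodes, elements, material, constraints = NULL,
                     loads = NULL) {
  nodes <- as_points_matrix(nodes, "nodes")
  if (is.data.frame(elements)) elements <- as.matrix(elements)
  if (!is.matrix(elements) || ncol(elements) != 4L)
    abort_rt("`elements` must be an m x 4 index matrix", "invalid_argument")
  storage.mode(elements) <- "integer"
  if (min(elements) < 1L || max(elements) > nrow(nodes))
    abort_rt("element node indices out of range", "invalid_argument")
  if (!inherits(material, "material"))
    abort_rt("`material` must be a material object", "invalid_argument")
  scale <- max(vnorm(apply(nodes, 2, function(v) diff(range(v)))), 1)
  for (e in seq_len(nrow(elements))) {
    p <- nodes[elements[e, ], ]
    v6 <- det(cbind(p[2, ] - p[1, ], p[3, ] - p[1, ], p[4, ] - p[1, ]))
    if (abs(v6) < 1e-12 * scale^3)
      abort_rt(sprintf("degenerate element %d (near-zero volume)", e),
               "mesh_quality_error")
    if (v6 < 0) elements[e, 3:4] <- elements[e, 4:3]
  }
  if (!is.null(constraints)) {
    if (!all(c("node", "dof", "value") %in% names(constraints)))
      abort_rt("constraints need columns node, dof, value",
               "invalid_argument")
    if (any(constraints$dof < 1L | constraints$dof > 3L))
      abort_rt("constraint dof must be 1, 2 or 3", "invalid_argument")
    if (anyDuplicated(constraints[, c("node", "dof")]))
      abort_rt("duplicate constraint on the same node/DOF",
               "invalid_argument")
  }
  if (!is.null(loads)) {
    if (!all(c("node", "fx", "fy", "fz") %in% names(loads)))
      abort_rt("loads need columns node, fx, fy, fz", "invalid_argument")
    if (!is.null(constraints) &&
        length(intersect(loads$node, constraints$node)))
      warn_rt("some loaded nodes are also constrained; their loads are absorbed by the reactions",
              "constrained_load_warning")
  }
  structure(list(nodes = nodes, elements = elements, material = material,
                 constraints = constraints, loads = loads),
            class = "tet_mesh")
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat(sprintf(
    "<tet_mesh> %d nodes, %d tet4 elements, %d constrained DOF(s), %d loaded node(s)\n",
    nrow(x$nodes), nrow(x$elements),
    if (is.null(x$constraints)) 0L else nrow(x$constraints),
    if (is.null(x$loads)) 0L else nrow(x$loads)))
  cat(sprintf("  material: E = %g, nu = %g\n", x$material$E, x$material$nu))
  invisible(x)
}

#' Total mesh volume
#' @param mesh A [tet_mesh].
#' @return Sum of element volumes.
#' @export
mesh_volume <- function(mesh) {
  sum(vapply(seq_len(nrow(mesh$elements)), function(e) {
    p <- mesh$nodes[mesh$elements[e, ], ]
    abs(det(cbind(p[2, ] - p[1, ], p[3, ] - p[1, ], p[4, ] - p[1, ]))) / 6
  }, numeric(1)))
}

# constant strain-displacement matrix B (6 x 12) and volume of one tet
tet_b_matrix <- function(p) {
  A <- cbind(1, p)                 # 4 x 4
  V <- det(A) / 6
  C <- solve(A)                    # rows 2:4 are the shape-fn gradients
  B <- matrix(0, 6L, 12L)
  for (i in 1:4) {
    gx <- C[2, i]; gy <- C[3, i]; gz <- C[4, i]
    c0 <- 3L * (i - 1L)
    B[1, c0 + 1L] <- gx
    B[2, c0 + 2L] <- gy
    B[3, c0 + 3L] <- gz
    B[4, c0 + 1L] <- gy; B[4, c0 + 2L] <- gx
    B[5, c0 + 2L] <- gz; B[5, c0 + 3L] <- gy
    B[6, c0 + 1L] <- gz; B[6, c0 + 3L] <- gx
  }
  list(B = B, V = V)
}

#' Assemble the global stiffness matrix
#'
#' Linear 4-node (constant-strain) tetrahedra, `Ke = V * t(B) D B`. Exposed
#' for verification (eigenvalue scans of the free-free matrix).
#'
#' @param mesh A [tet_mesh].
#' @return A sparse symmetric `3n x 3n` [Matrix::sparseMatrix] (DOF order
#'   `(ux1, uy1, uz1, ux2, ...)`).
#' @export
assemble_stiffness <- function(mesh) {
  D <- elasticity_matrix(mesh$material)
  ne <- nrow(mesh$elements)
  ii <- integer(144L * ne); jj <- integer(144L * ne)
  xx <- numeric(144L * ne)
  pos <- 0L
  for (e in seq_len(ne)) {
    en <- mesh$elements[e, ]
    bv <- tet_b_matrix(mesh$nodes[en, ])
    Ke <- abs(bv$V) * crossprod(bv$B, D %*% bv$B)
    dofs <- as.vector(t(cbind(3L * en - 2L, 3L * en - 1L, 3L * en)))
    idx <- pos + seq_len(144L)
    ii[idx] <- rep(dofs, times = 12L)
    jj[idx] <- rep(dofs, each = 12L)
    xx[idx] <- as.vector(Ke)
    pos <- pos + 144L
  }
  ndof <- 3L * nrow(mesh$nodes)
  K <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(ndof, ndof))
  (K + Matrix::t(K)) / 2
}

#' Solve the static linear-elastic problem
#'
#' Solves `K u = f` for the constrained mesh: Dirichlet conditions are
#' imposed by row/column elimination (exact, well-conditioned), the reduced
#' symmetric positive-definite system is solved sparsely, and per-element
#' constant stresses are recovered as `sigma = D B u_e`.
#'
#' @param mesh A [tet_mesh] with enough constraints to remove all six
#'   rigid-body modes.
#' @return Object of class `"fem_result"`: `displacements` (`n x 3`),
#'   `element_stress` (`m x 6`, order `xx, yy, zz, xy, yz, zx`),
#'   `von_mises` (per element), `max_von_mises`, `max_displacement`
#'   (largest nodal displacement magnitude), and `reactions` (`n x 3`,
#'   non-zero only at constrained DOFs).
#' @export
solve_static <- function(mesh) {
  stopifnot(inherits(mesh, "tet_mesh"))
  ndof <- 3L * nrow(mesh$nodes)
  K <- assemble_stiffness(mesh)

  f <- numeric(ndof)
  if (!is.null(mesh$loads)) {
    ld <- mesh$loads
    for (i in seq_len(nrow(ld))) {
      n0 <- 3L * (ld$node[i] - 1L)
      f[n0 + 1:3] <- f[n0 + 1:3] + c(ld$fx[i], ld$fy[i], ld$fz[i])
    }
  }

  cdof <- integer(0); cval <- numeric(0)
  if (!is.null(mesh$constraints) && nrow(mesh$constraints)) {
    cdof <- 3L * (mesh$constraints$node - 1L) + mesh$constraints$dof
    cval <- mesh$constraints$value
  }
  free <- setdiff(seq_len(ndof), cdof)

  u <- numeric(ndof)
  u[cdof] <- cval
  if (length(free)) {
    Kff <- K[free, free, drop = FALSE]
    rhs <- f[free]
    if (length(cdof))
      rhs <- rhs - as.numeric(K[free, cdof, drop = FALSE] %*% cval)
    uf <- tryCatch(
      as.numeric(Matrix::solve(Matrix::Cholesky(Matrix::forceSymmetric(Kff),
                                                perm = TRUE), rhs)),
      error = function(e) NULL)
    # a semi-definite system can pass the factorization; verify the residual
    if (!is.null(uf)) {
      if (any(!is.finite(uf)) ||
          max(abs(as.numeric(Kff %*% uf) - rhs)) >
            1e-6 * max(1e-300, max(abs(rhs))))
        uf <- NULL
    }
    if (is.null(uf)) {
      nullspace_msg <- if (length(free) <= 1500L) {
        ev <- eigen(as.matrix(Kff), symmetric = TRUE, only.values = TRUE)
        nz <- sum(ev$values < 1e-9 * max(abs(ev$values)))
        sprintf("null-space dimension %d", nz)
      } else "null-space dimension not computed (system too large)"
    if (TRUE)
      abort_rt(paste0(
        "singular stiffness matrix: constraints leave unremoved rigid-body ",
        "modes (", nullspace_msg, ")"), "rigid_body_mode_error")
    }
    u[free] <- uf
  }

  D <- elasticity_matrix(mesh$material)
  ne <- nrow(mesh$elements)
  stress <- matrix(0, ne, 6L,
                   dimnames = list(NULL, c("xx", "yy", "zz", "xy", "yz", "zx")))
  for (e in seq_len(ne)) {
    en <- mesh$elements[e, ]
    bv <- tet_b_matrix(mesh$nodes[en, ])
    dofs <- as.vector(t(cbind(3L * en - 2L, 3L * en - 1L, 3L * en)))
    stress[e, ] <- as.numeric(D %*% (bv$B %*% u[dofs]))
  }
  vm <- von_mises(stress)

  react_full <- as.numeric(K %*% u) - f
  reactions <- matrix(0, nrow(mesh$nodes), 3L)
  if (length(cdof))
    reactions[cbind((cdof - 1L) %/% 3L + 1L, (cdof - 1L) %% 3L + 1L)] <-
      react_full[cdof]

  disp <- matrix(u, ncol = 3L, byrow = TRUE)
  structure(list(
    displacements = disp,
    element_stress = stress,
    von_mises = vm,
    max_von_mises = max(vm),
    max_displacement = max(sqrt(rowSums(disp^2))),
    reactions = reactions
  ), class = "fem_result")
}

#' @export
print.fem_result <- function(x, ...) {
  cat(sprintf(
    "<fem_result> %d nodes, %d elements; max |u| = %.6g, max von Mises = %.6g\n",
    nrow(x$displacements), length(x$von_mises),
    x$max_displacement, x$max_von_mises))
  invisible(x)
}

#' Von Mises equivalent stress
#'
#' `sqrt(0.5 * ((sxx - syy)^2 + (syy - szz)^2 + (szz - sxx)^2)
#'  + 3 * (sxy^2 + syz^2 + szx^2))` — the scalar stress measure used to
#' locate critical load regions.
#'
#' @param stress A symmetric 3 x 3 stress tensor, a length-6 vector
#'   `(xx, yy, zz, xy, yz, zx)`, or an `m x 6` matrix of such rows.
#' @return Scalar (or length-`m` vector) of equivalent stresses, `>= 0`.
#' @examples
#' von_mises(c(100, 0, 0, 0, 0, 0))    # uniaxial: 100
#' von_mises(diag(3) * 50)             # hydrostatic: 0
#' @export
von_mises <- function(stress) {
  if (is.matrix(stress) && all(dim(stress) == c(3L, 3L))) {
    if (max(abs(stress - t(stress))) > 1e-8 * max(1, max(abs(stress))))
      abort_rt("stress tensor must be symmetric", "invalid_argument")
    stress <- c(stress[1, 1], stress[2, 2], stress[3, 3],
                stress[1, 2], stress[2, 3], stress[1, 3])
  }
  if (is.null(dim(stress))) stress <- matrix(stress, nrow = 1L)
  if (ncol(stress) != 6L)
    abort_rt("stress must be 3x3, length 6, or m x 6", "invalid_argument")
  s <- stress
  out <- sqrt(0.5 * ((s[, 1] - s[, 2])^2 + (s[, 2] - s[, 3])^2 +
                       (s[, 3] - s[, 1])^2) +
                3 * (s[, 4]^2 + s[, 5]^2 + s[, 6]^2))
  if (length(out) == 1L) as.numeric(out) else as.numeric(out)
}

#' Boundary triangles of a tet mesh
#'
#' Triangular faces that belong to exactly one tetrahedron.
#'
#' @param mesh A [tet_mesh].
#' @return `k x 3` matrix of node-index triples.
#' @export
boundary_faces <- function(mesh) {
  el <- mesh$elements
  faces <- rbind(el[, c(1, 2, 3)], el[, c(1, 2, 4)],
                 el[, c(1, 3, 4)], el[, c(2, 3, 4)])
  key <- apply(t(apply(faces, 1L, sort)), 1L, paste, collapse = ",")
  faces[key %in% names(which(table(key) == 1L)), , drop = FALSE]
}

#' Consistent nodal loads for a uniform surface traction
#'
#' Converts a uniform traction (force per unit area) on part of the mesh
#' boundary into work-equivalent nodal point loads: each boundary triangle
#' whose three nodes satisfy `selector` contributes `area * traction / 3`
#' to each of its nodes.
#'
#' @param mesh A [tet_mesh].
#' @param selector Function taking the `n x 3` node matrix and returning
#'   the indices (or a logical mask) of nodes on the loaded surface.
#' @param traction Traction vector (force / length^2), length 3.
#' @return Load `data.frame` (`node`, `fx`, `fy`, `fz`) for [tet_mesh].
#' @export
face_traction_loads <- function(mesh, selector, traction) {
  sel <- selector(mesh$nodes)
  if (is.logical(sel)) sel <- which(sel)
  bf <- boundary_faces(mesh)
  on <- bf[rowSums(matrix(bf %in% sel, nrow(bf), 3L)) == 3L, ,
           drop = FALSE]
  if (nrow(on) == 0L)
    abort_rt("no boundary triangle lies entirely on the selected surface",
             "invalid_argument")
  f <- matrix(0, nrow(mesh$nodes), 3L)
  for (i in seq_len(nrow(on))) {
    p <- mesh$nodes[on[i, ], ]
    e1 <- p[2, ] - p[1, ]; e2 <- p[3, ] - p[1, ]
    cr <- c(e1[2] * e2[3] - e1[3] * e2[2],
            e1[3] * e2[1] - e1[1] * e2[3],
            e1[1] * e2[2] - e1[2] * e2[1])
    area <- 0.5 * vnorm(cr)
    for (nd in on[i, ]) f[nd, ] <- f[nd, ] + area * traction / 3
  }
  nz <- which(rowSums(abs(f)) > 0)
  data.frame(node = nz, fx = f[nz, 1], fy = f[nz, 2], fz = f[nz, 3])
}

scale_loads <- function(loads, s) {
  loads$fx <- loads$fx * s; loads$fy <- loads$fy * s; loads$fz <- loads$fz * s
  loads
}

#' Critical force of a loaded structure
#'
#' Finds the smallest load magnitude at which the maximum von Mises stress
#' reaches `yield_stress`, for the load distribution stored in the mesh
#' interpreted as a unit (1 N total or otherwise normalized) pattern. For
#' the linear problem the stress scales exactly with the load, so one solve
#' gives `F_crit = yield_stress / max_vm_per_unit_load`
#' (`method = "linear"`). A bisection search over `[0, f_max]` that
#' re-solves at each trial magnitude is provided (`method = "bisection"`)
#' as the fallback for future nonlinear extensions; on a linear problem the
#' two agree to within `tol`.
#'
#' @param mesh A constrained [tet_mesh] whose `loads` are the unit load
#'   pattern.
#' @param yield_stress Failure criterion: max von Mises stress (same units
#'   as `E`) above which the load is deemed critical. Supplied explicitly —
#'   there is no biologically meaningful default.
#' @param f_max Upper bound of the searched load magnitude (N).
#' @param tol Force tolerance of the bisection, N.
#' @param method `"linear"` (default) or `"bisection"`.
#' @return Critical force in Newtons (scalar).
#' @export
critical_force_sweep <- function(mesh, yield_stress, f_max = 1e6,
                                 tol = 1e-6, method = c("linear",
                                                        "bisection")) {
  method <- match.arg(method)
  stopifnot(inherits(mesh, "tet_mesh"))
  if (is.null(mesh$loads) || nrow(mesh$loads) == 0L)
    abort_rt("mesh carries no load pattern", "invalid_argument")
  if (!is.numeric(yield_stress) || yield_stress <= 0)
    abort_rt("`yield_stress` must be positive", "invalid_argument")
  unit <- solve_static(mesh)
  if (unit$max_von_mises <= 0)
    abort_rt("unit load produces zero stress; no critical force exists",
             "no_critical_force_error")
  f_lin <- yield_stress / unit$max_von_mises
  if (f_lin > f_max)
    abort_rt(sprintf(
      "critical force %.6g N exceeds the search bound f_max = %.6g N",
      f_lin, f_max), "no_critical_force_error")
  if (method == "linear") return(f_lin)
  lo <- 0; hi <- f_max
  for (i in seq_len(60L)) {
    mid <- (lo + hi) / 2
    m2 <- mesh
    m2$loads <- scale_loads(mesh$loads, mid)
    vm <- solve_static(m2)$max_von_mises
    if (vm >= yield_stress) hi <- mid else lo <- mid
    if ((hi - lo) < tol) break
  }
  (lo + hi) / 2
}

#' Elements in the critical stress region
#'
#' The highest-stressed fraction of the mesh — the region an analyst colors
#' red. Returns the elements whose von Mises stress is at or above the
#' `(1 - fraction)` quantile (so a uniform-stress field returns every
#' element and `fraction = 1` always does).
#'
#' @param result A `"fem_result"` from [solve_static].
#' @param fraction Top fraction to keep, in `(0, 1]`; default 0.05.
#' @return Integer vector of element indices.
#' @export
identify_critical_region <- function(result, fraction = 0.05) {
  stopifnot(inherits(result, "fem_result"))
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1)
    abort_rt("`fraction` must be in (0, 1]", "invalid_argument")
  q <- stats::quantile(result$von_mises, 1 - fraction, names = FALSE)
  which(result$von_mises >= q)
}
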