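#' @importFrom Matrix sparseMatrix Cholesky solve crossprod forceSymmetric
NULL

# Isotropic linear-elastic constitutive matrix (Voigt order
# xx, yy, zz, xy, yz, zx).
elastic_D <- function(E, nu) {
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D <- diag(c(rep(2 * mu, 3), rep(mu, 3)))
  D[1:3, 1:3] <- D[1:3, 1:3] + lam
  D
}

# Shape-function gradients and volume of one linear tetrahedron.
tet_gradients <- function(X) {
  J <- rbind(X[2, ] - X[1, ], X[3, ] - X[1, ], X[4, ] - X[1, ])
  detJ <- det(J)
  if (detJ <= 0) return(NULL)
  Jinv <- solve(J)
  dref <- rbind(c(-1, -1, -1), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  list(grads = dref %*% t(Jinv), volume = detJ / 6)
}

tet_B <- function(grads) {
  B <- matrix(0, 6, 12)
  for (i in 1:4) {
    g <- grads[i, ]
    c0 <- 3 * (i - 1)
    B[1, c0 + 1] <- g[1]
    B[2, c0 + 2] <- g[2]
    B[3, c0 + 3] <- g[3]
    B[4, c0 + 1] <- g[2]; B[4, c0 + 2] <- g[1]
    B[5, c0 + 2] <- g[3]; B[5, c0 + 3] <- g[2]
    B[6, c0 + 1] <- g[3]; B[6, c0 + 3] <- g[1]
  }
  B
}

#' Nodes in contact with the ground plane
#'
#' Dof indices of the nodes in the lowest `fraction` of the mesh z-range;
#' these are fixed in all three directions by default (the body rests on the
#' ground and no other boundary constraint is prescribed).
#'
#' @param model A `body_model`.
#' @param fraction Fraction of the z-range counted as ground contact
#'   (default 0.05).
#' @return Integer vector of constrained dof indices (3 per node).
#' @export
ground_fixed_dofs <- function(model, fraction = 0.05) {
  z <- model$nodes[, 3]
  nodes <- which(z <= min(z) + fraction * diff(range(z)))
  as.integer(sort(c(3 * nodes - 2, 3 * nodes - 1, 3 * nodes)))
}

#' Assemble the structural system
#'
#' Builds the global stiffness matrix from constant-strain linear
#' tetrahedra and a lumped (diagonal) mass matrix, for the structural stage
#' governed by `M x'' + C x' + K x = F(t)`. The primary analysis mode is
#' linear static (`K x = F`); damping defaults to zero.
#'
#' @param model A `body_model`.
#' @param materials Named list of [material_spec()] keyed by element label
#'   (default [rat_materials()]).
#' @param fixed_dofs Constrained dof indices; default fixes the ground-contact
#'   nodes via [ground_fixed_dofs()]. Use `integer(0)` for a free-floating
#'   system (e.g. to inspect rigid-body modes).
#' @return An object of class `structural_system` with the sparse symmetric
#'   stiffness `K` (3n x 3n, dof order ux1, uy1, uz1, ux2, ...), the lumped
#'   mass diagonal `M_diag`, `fixed_dofs`, and the model and materials.
#' @export
assemble <- function(model, materials = rat_materials(),
                     fixed_dofs = ground_fixed_dofs(model)) {
  stopifnot(inherits(model, "body_model"))
  missing <- setdiff(unique(model$material), names(materials))
  if (length(missing) > 0L)
    stop("no material_spec for label(s): ", paste(missing, collapse = ", "))
  m <- nrow(model$elements)
  n <- nrow(model$nodes)
  iidx <- integer(144L * m); jidx <- integer(144L * m); xval <- numeric(144L * m)
  M_diag <- numeric(3L * n)
  Dcache <- lapply(materials, function(mt) elastic_D(mt$elastic_modulus, mt$poisson_ratio))
  pos <- 0L
  blk_i <- rep(1:12, times = 12)
  blk_j <- rep(1:12, each = 12)
  for (e in seq_len(m)) {
    conn <- model$elements[e, ]
    tg <- tet_gradients(model$nodes[conn, , drop = FALSE])
    if (is.null(tg)) stop("inverted or degenerate element ", e)
    B <- tet_B(tg$grads)
    mt <- materials[[model$material[e]]]
    Ke <- tg$volume * crossprod(B, Dcache[[model$material[e]]] %*% B)
    edofs <- as.integer(rbind(3L * conn - 2L, 3L * conn - 1L, 3L * conn))
    rng <- pos + seq_len(144L)
    iidx[rng] <- edofs[blk_i]
    jidx[rng] <- edofs[blk_j]
    xval[rng] <- as.numeric(Ke)
    pos <- pos + 144L
    M_diag[edofs] <- M_diag[edofs] + mt$density * tg$volume / 4
  }
  K <- Matrix::sparseMatrix(i = iidx, j = jidx, x = xval, dims = c(3L * n, 3L * n))
  K <- Matrix::forceSymmetric((K + Matrix::t(K)) / 2)
  structure(list(K = K, M_diag = M_diag, fixed_dofs = as.integer(fixed_dofs),
                 n_nodes = n, model = model, materials = materials),
            class = "structural_system")
}

free_dofs <- function(system) {
  setdiff(seq_len(length(system$M_diag)), system$fixed_dofs)
}

#' Factor the constrained stiffness matrix
#'
#' Sparse Cholesky factorisation of the stiffness restricted to free dofs,
#' reusable across load cases (e.g. the five standoffs).
#'
#' @param system A [assemble()]d `structural_system`.
#' @return An opaque factor object for [solve_static()].
#' @export
factor_system <- function(system) {
  ff <- free_dofs(system)
  if (length(ff) == length(system$M_diag))
    stop("unconstrained system: fix dofs before factoring")
  Kff <- system$K[ff, ff, drop = FALSE]
  fac <- tryCatch(Matrix::Cholesky(Matrix::forceSymmetric(Kff), LDL = FALSE),
                  error = function(e) stop("singular constrained system: ", conditionMessage(e)))
  list(factor = fac, free = ff, Kff = Kff)
}

#' Solve the linear static problem
#'
#' Solves `K x = F` on the free dofs with a direct sparse Cholesky solver and
#' verifies the relative residual against `tol`.
#'
#' @param system A `structural_system`.
#' @param forces Global force vector (length 3n, dof order as in
#'   [assemble()]), e.g. from [surface_load_forces()].
#' @param factor Optional prefactorisation from [factor_system()].
#' @param tol Maximum admissible relative residual (default 1e-8).
#' @return Displacement vector of length 3n (fixed dofs exactly zero), with
#'   the relative residual in attribute `residual`. Reshape with
#'   [displacement_matrix()].
#' @export
solve_static <- function(system, forces, factor = NULL, tol = 1e-8) {
  stopifnot(inherits(system, "structural_system"),
            length(forces) == length(system$M_diag))
  if (is.null(factor)) factor <- factor_system(system)
  ff <- factor$free
  b <- forces[ff]
  u <- numeric(length(system$M_diag))
  x <- as.numeric(Matrix::solve(factor$factor, b))
  u[ff] <- x
  nb <- sqrt(sum(b^2))
  res <- if (nb > 0) sqrt(sum((as.numeric(factor$Kff %*% x) - b)^2)) / nb else 0
  if (res > tol) stop(sprintf("static solve residual %.3g exceeds tol %.3g", res, tol))
  attr(u, "residual") <- res
  u
}

#' Reshape a dof vector to an n x 3 displacement matrix
#' @param u Dof vector of length 3n.
#' @return n x 3 matrix with columns ux, uy, uz.
#' @export
displacement_matrix <- function(u) matrix(u, ncol = 3L, byrow = TRUE)

#' Consistent nodal forces from a surface pressure field
#'
#' Converts nodal peak pressures (kPa) on the exterior surface into the
#' consistent nodal force vector for linear triangles: each exterior face
#' carries its mean face pressure times its area along the inward normal,
#' split equally among its three vertices.
#'
#' @param model A `body_model`.
#' @param pressures A [surface_pressure_field()] or a numeric vector of
#'   pressures in kPa indexed by node.
#' @return Global force vector (length 3n) in N.
#' @export
surface_load_forces <- function(model, pressures) {
  n <- nrow(model$nodes)
  pnode <- numeric(n)
  if (inherits(pressures, "surface_pressure_field")) {
    pnode[pressures$node] <- pressures$peak_pressure_kpa
  } else {
    stopifnot(length(pressures) == n)
    pnode <- as.numeric(pressures)
  }
  f <- model$surface_faces
  p1 <- model$nodes[f[, 1], , drop = FALSE]
  p2 <- model$nodes[f[, 2], , drop = FALSE]
  p3 <- model$nodes[f[, 3], , drop = FALSE]
  nvec <- vec_cross(p2 - p1, p3 - p1) / 2 # outward, |.| = area
  pface <- (pnode[f[, 1]] + pnode[f[, 2]] + pnode[f[, 3]]) / 3 * 1000 # Pa
  fvec <- -nvec * pface # inward traction
  forces <- numeric(3L * n)
  for (c in 1:3) {
    s <- rowsum(fvec / 3, group = f[, c])
    idx <- as.integer(rownames(s))
    for (k in 1:3) forces[3L * (idx - 1L) + k] <- forces[3L * (idx - 1L) + k] + s[, k]
  }
  forces
}

# Per-element stress (Voigt, Pa) from a displacement dof vector.
element_stress <- function(u, system) {
  model <- system$model
  m <- nrow(model$elements)
  Dcache <- lapply(system$materials, function(mt)
    elastic_D(mt$elastic_modulus, mt$poisson_ratio))
  sig <- matrix(0, m, 6L)
  for (e in seq_len(m)) {
    conn <- model$elements[e, ]
    tg <- tet_gradients(model$nodes[conn, , drop = FALSE])
    B <- tet_B(tg$grads)
    edofs <- as.integer(rbind(3L * conn - 2L, 3L * conn - 1L, 3L * conn))
    sig[e, ] <- Dcache[[model$material[e]]] %*% (B %*% u[edofs])
  }
  sig
}

#' Von Mises equivalent stress per element
#'
#' Constant per linear tetrahedron; the deviatoric invariant
#' `sqrt(0.5 ((sxx-syy)^2 + (syy-szz)^2 + (szz-sxx)^2) + 3 (sxy^2 + syz^2 + szx^2))`,
#' zero for purely hydrostatic states and `|sigma|` for uniaxial stress.
#'
#' @param displacement Dof vector from [solve_static()].
#' @param system The `structural_system` that produced it.
#' @return Non-negative numeric vector, one value (Pa) per element.
#' @export
von_mises <- function(displacement, system) {
  s <- element_stress(displacement, system)
  sqrt(0.5 * ((s[, 1] - s[, 2])^2 + (s[, 2] - s[, 3])^2 + (s[, 3] - s[, 1])^2) +
       3 * (s[, 4]^2 + s[, 5]^2 + s[, 6]^2))
}

#' Sample the stress field at the lung monitor points
#'
#' Reads the von Mises stress at each named monitor point as the value of
#' the nearest lung-surface element (nearest-centroid rule) on that side.
#'
#' @param stress Per-element von Mises stress from [von_mises()].
#' @param model The `body_model` (with monitor points placed).
#' @return Data frame with columns `side`, `point_name`, `von_mises_pa`.
#' @export
sample_monitor_points <- function(stress, model) {
  if (is.null(model$monitor_points))
    stop("monitor points not placed; call place_monitor_points() first")
  out <- NULL
  for (side in c("L", "R")) {
    lrf <- lung_region_faces(model, side)
    surf_el <- unique(lrf$owner)
    ctr <- (model$nodes[model$elements[surf_el, 1], , drop = FALSE] +
            model$nodes[model$elements[surf_el, 2], , drop = FALSE] +
            model$nodes[model$elements[surf_el, 3], , drop = FALSE] +
            model$nodes[model$elements[surf_el, 4], , drop = FALSE]) / 4
    mp <- model$monitor_points[model$monitor_points$side == side, , drop = FALSE]
    for (i in seq_len(nrow(mp))) {
      d2 <- rowSums(sweep(ctr, 2L, as.numeric(mp[i, c("x", "y", "z")]))^2)
      j <- which.min(d2)
      if (sqrt(d2[j]) > 2 * model$resolution)
        stop("monitor point ", mp$name[i], " (", side,
             ") is farther than 2 element sizes from any lung-surface element")
      out <- rbind(out, data.frame(side = side, point_name = mp$name[i],
                                   von_mises_pa = stress[surf_el[j]]))
    }
  }
  rownames(out) <- NULL
  out
}

#' Transient Newmark time integration (optional mode)
#'
#' Average-acceleration Newmark integration of
#' `M x'' + C x' + K x = F(t)` with lumped mass and (optional)
#' mass-proportional damping `C = mass_damping * M`. Provided to honour the
#' full dynamic form of the structural stage; the primary analysis mode is
#' linear static.
#'
#' @param system A `structural_system`.
#' @param load Either a constant force vector (length 3n) or a function of
#'   time returning one.
#' @param dt Time step in s, > 0.
#' @param end_time End of integration in s.
#' @param beta,gamma Newmark parameters (defaults 1/4, 1/2: unconditionally
#'   stable average acceleration).
#' @param mass_damping Mass-proportional damping coefficient a0 in 1/s
#'   (C = a0 M); default 0.
#' @param store `"last"` (default) keeps only the final state, `"all"` the
#'   full trajectory.
#' @return List with `times`, final `displacement` and `velocity` dof
#'   vectors, and (if `store = "all"`) `history` (dofs x steps).
#' @export
solve_transient <- function(system, load, dt, end_time,
                            beta = 0.25, gamma = 0.5,
                            mass_damping = 0, store = c("last", "all")) {
  store <- match.arg(store)
  stopifnot(dt > 0, end_time > 0)
  ndof <- length(system$M_diag)
  loadfn <- if (is.function(load)) load else function(t) load
  ff <- free_dofs(system)
  Kff <- system$K[ff, ff, drop = FALSE]
  Mff <- system$M_diag[ff]
  if (any(Mff <= 0)) stop("mass matrix not positive definite on free dofs")
  Cff <- mass_damping * Mff
  a0 <- 1 / (beta * dt^2); a1 <- gamma / (beta * dt)
  Keff <- Kff + Matrix::Diagonal(x = a0 * Mff + a1 * Cff)
  fac <- Matrix::Cholesky(Matrix::forceSymmetric(Keff), LDL = FALSE)
  u <- numeric(length(ff)); v <- numeric(length(ff))
  a <- (loadfn(0)[ff] - Cff * v - as.numeric(Kff %*% u)) / Mff
  times <- seq(dt, end_time, by = dt)
  hist <- if (store == "all") matrix(0, ndof, length(times)) else NULL
  e0 <- NULL
  for (s in seq_along(times)) {
    t <- times[s]
    rhs <- loadfn(t)[ff] +
      Mff * (a0 * u + (1 / (beta * dt)) * v + (1 / (2 * beta) - 1) * a) +
      Cff * (a1 * u + (gamma / beta - 1) * v + dt * (gamma / (2 * beta) - 1) * a)
    unew <- as.numeric(Matrix::solve(fac, rhs))
    anew <- a0 * (unew - u) - (1 / (beta * dt)) * v - (1 / (2 * beta) - 1) * a
    vnew <- v + dt * ((1 - gamma) * a + gamma * anew)
    u <- unew; v <- vnew; a <- anew
    energy <- sum(Mff * v^2) / 2 + sum(u * as.numeric(Kff %*% u)) / 2
    if (!is.finite(energy)) stop("transient integration diverged at t = ", t)
    if (is.null(e0)) e0 <- max(energy, .Machine$double.eps)
    if (energy > 1e12 * e0)
      stop("divergent energy growth in transient integration at t = ", t)
    if (store == "all") hist[ff, s] <- u
  }
  uf <- numeric(ndof); uf[ff] <- u
  vf <- numeric(ndof); vf[ff] <- v
  out <- list(times = times, displacement = uf, velocity = vf)
  if (store == "all") out$history <- hist
  out
}
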