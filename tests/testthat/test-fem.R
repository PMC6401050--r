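test_that("element stiffness has the right rigid-body null space", {
  sys <- assemble(single_tet_model(), fixed_dofs = integer(0))
  K <- as.matrix(sys$K)
  expect_identical(dim(K), c(12L, 12L))
  expect_true(isSymmetric(K, tol = 1e-9))
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_identical(sum(abs(ev) < max(ev) * 1e-9), 6L)
  # two disconnected tetrahedra: six rigid modes per component
  sys2 <- assemble(two_tet_model(), fixed_dofs = integer(0))
  ev2 <- eigen(as.matrix(sys2$K), symmetric = TRUE, only.values = TRUE)$values
  expect_identical(sum(abs(ev2) < max(ev2) * 1e-9), 12L)
})

test_that("stiffness is linear in the elastic modulus", {
  mats <- rat_materials()
  sys1 <- assemble(single_tet_model(), mats, fixed_dofs = integer(0))
  mats2 <- lapply(mats, function(m) { m$elastic_modulus <- 2 * m$elastic_modulus; m })
  sys2 <- assemble(single_tet_model(), mats2, fixed_dofs = integer(0))
  expect_equal(as.matrix(sys2$K), 2 * as.matrix(sys1$K), tolerance = 1e-14)
})

test_that("uniaxial bar reproduces sigma l / E and passes the patch test", {
  bar <- mesh_box(dims = c(0.4, 0.1, 0.1), n = c(8, 2, 2))
  sys <- assemble(bar, fixed_dofs = roller_fixed_dofs(bar))
  sigma <- 1000 # Pa
  forces <- face_traction_forces(bar, axis = 1, value = 0.4, sigma = sigma)
  u <- solve_static(sys, forces)
  E <- rat_materials()$skin_muscle$elastic_modulus
  end_nodes <- which(abs(bar$nodes[, 1] - 0.4) < 1e-12)
  expect_equal(u[3 * end_nodes - 2], rep(sigma * 0.4 / E, length(end_nodes)),
               tolerance = 1e-6)
  # patch test: constant stress reproduced in EVERY element
  vm <- von_mises(u, sys)
  expect_equal(vm, rep(sigma, length(vm)), tolerance = 1e-6)
  # work-energy consistency
  expect_equal(sum(u * forces), as.numeric(u %*% (sys$K %*% u)),
               tolerance = 1e-9)
})

test_that("static solution is linear in the load and zero without one", {
  bar <- mesh_box(dims = c(0.2, 0.1, 0.1), n = c(4, 2, 2))
  sys <- assemble(bar, fixed_dofs = roller_fixed_dofs(bar))
  f <- face_traction_forces(bar, axis = 1, value = 0.2, sigma = 500)
  expect_true(all(solve_static(sys, numeric(length(f))) == 0))
  u1 <- solve_static(sys, f)
  u3 <- solve_static(sys, 3 * f)
  expect_equal(u3, 3 * u1, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("von Mises stress has the deviatoric invariance properties", {
  box <- mesh_box(dims = c(0.1, 0.1, 0.1), n = c(2, 2, 2))
  sys <- assemble(box, fixed_dofs = integer(0))
  # pure volumetric displacement field -> hydrostatic stress -> vm = 0
  uh <- as.numeric(t(box$nodes)) * 1e-3
  expect_equal(von_mises(uh, sys), rep(0, nrow(box$elements)),
               tolerance = 1e-9)
  # frame invariance: rotate mesh and displacements together
  set.seed(11)
  u <- rnorm(3 * nrow(box$nodes)) * 1e-4
  vm0 <- von_mises(u, sys)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  rot <- box
  rot$nodes <- box$nodes %*% t(R)
  dimnames(rot$nodes) <- dimnames(box$nodes)
  sysr <- assemble(rot, fixed_dofs = integer(0))
  ur <- as.numeric(t(matrix(u, ncol = 3, byrow = TRUE) %*% t(R)))
  expect_equal(von_mises(ur, sysr), vm0, tolerance = 1e-8)
})

test_that("stiffer tissue deforms less under the same load", {
  box <- mesh_box(dims = c(0.1, 0.1, 0.1), n = c(2, 2, 2), material = "lung_L")
  f <- face_traction_forces(box, axis = 1, value = 0.1, sigma = 100)
  fixed <- roller_fixed_dofs(box)
  u_lung <- solve_static(assemble(box, fixed_dofs = fixed), f)
  box$material <- rep("rib", nrow(box$elements))
  u_rib <- solve_static(assemble(box, fixed_dofs = fixed), f)
  expect_lt(max(abs(u_rib)), max(abs(u_lung)) * 1e-4)
})

test_that("Newmark integration matches the 1-dof oscillator", {
  k <- 400; m <- 1; F0 <- 2
  sys <- structure(list(K = Matrix::Matrix(k, 1, 1, sparse = TRUE),
                        M_diag = m, fixed_dofs = integer(0), n_nodes = NULL,
                        model = NULL, materials = NULL),
                   class = "structural_system")
  wn <- sqrt(k / m); Tn <- 2 * pi / wn
  out <- solve_transient(sys, load = F0, dt = Tn / 100, end_time = 2 * Tn,
                         store = "all")
  exact <- (F0 / k) * (1 - cos(wn * out$times))
  expect_lt(max(abs(out$history[1, ] - exact)), 0.01 * 2 * F0 / k)
  # zero load history stays identically zero
  out0 <- solve_transient(sys, load = 0, dt = Tn / 100, end_time = Tn, store = "all")
  expect_true(all(out0$history == 0))
})

test_that("heavily damped transient settles onto the static solution", {
  box <- mesh_box(dims = c(0.1, 0.05, 0.05), n = c(2, 1, 1), material = "lung_L")
  fixed <- sort(c(3 * which(abs(box$nodes[, 1]) < 1e-12) - 2,
                  3 * which(abs(box$nodes[, 1]) < 1e-12) - 1,
                  3 * which(abs(box$nodes[, 1]) < 1e-12)))
  sys <- assemble(box, fixed_dofs = as.integer(fixed))
  f <- face_traction_forces(box, axis = 1, value = 0.1, sigma = 50)
  u_static <- solve_static(sys, f)
  out <- solve_transient(sys, load = f, dt = 0.002, end_time = 4,
                         mass_damping = 60)
  expect_equal(out$displacement, u_static, tolerance = 1e-3,
               ignore_attr = TRUE)
  expect_lt(max(abs(out$velocity)), 1e-4 * max(abs(u_static)))
})

test_that("assembly rejects inverted elements and unknown materials", {
  tet <- single_tet_model()
  bad <- tet
  bad$elements <- matrix(c(1L, 3L, 2L, 4L), 1) # negative volume
  expect_error(assemble(bad, fixed_dofs = integer(0)), "inverted")
  unk <- tet
  unk$material <- "cartilage"
  expect_error(assemble(unk, fixed_dofs = integer(0)), "cartilage")
})
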