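# Shared fixtures, built once per test session.
.cache <- new.env(parent = emptyenv())

cached_rat <- function() {
  if (is.null(.cache$rat))
    .cache$rat <- place_monitor_points(build_synthetic_rat())
  .cache$rat
}

cached_pipeline <- function() {
  if (is.null(.cache$pipe))
    .cache$pipe <- run_blast_pipeline(model = cached_rat())
  .cache$pipe
}

# Single reference tetrahedron as a body_model.
single_tet_model <- function() {
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  dimnames(nodes) <- list(NULL, c("x", "y", "z"))
  elems <- matrix(1:4, 1)
  structure(list(nodes = nodes, elements = elems, material = "skin_muscle",
                 surface_faces = blastrat:::boundary_faces(nodes, elems)$faces,
                 monitor_points = NULL, body_dims = c(1, 1, 1),
                 resolution = 1, seed = 0L),
            class = "body_model")
}

# Two tetrahedra sharing no nodes.
two_tet_model <- function() {
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                 c(3, 0, 0), c(4, 0, 0), c(3, 1, 0), c(3, 0, 1))
  dimnames(nodes) <- list(NULL, c("x", "y", "z"))
  elems <- rbind(1:4, 5:8)
  structure(list(nodes = nodes, elements = elems,
                 material = rep("skin_muscle", 2),
                 surface_faces = blastrat:::boundary_faces(nodes, elems)$faces,
                 monitor_points = NULL, body_dims = c(4, 1, 1),
                 resolution = 1, seed = 0L),
            class = "body_model")
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

# Nodal forces for a uniform traction `sigma` (N/m^2, along +axis) applied to
# the boundary faces of `model` lying on the plane axis == value.
face_traction_forces <- function(model, axis, value, sigma, direction = axis) {
  nn <- model$nodes
  f <- model$surface_faces
  forces <- numeric(3 * nrow(nn))
  on_plane <- abs(matrix(nn[f, axis], nrow(f), 3) - value) < 1e-12
  for (fi in which(rowSums(on_plane) == 3L)) {
    tri <- f[fi, ]
    A <- 0.5 * sqrt(sum(cross3(nn[tri[2], ] - nn[tri[1], ],
                               nn[tri[3], ] - nn[tri[1], ])^2))
    dofs <- 3 * (tri - 1) + direction
    forces[dofs] <- forces[dofs] + sigma * A / 3
  }
  forces
}

# Roller boundary conditions compatible with a uniform uniaxial stress state:
# each coordinate plane through the origin is fixed in its own normal
# direction only.
roller_fixed_dofs <- function(model) {
  nn <- model$nodes
  sort(c(3 * which(abs(nn[, 1]) < 1e-12) - 2,
         3 * which(abs(nn[, 2]) < 1e-12) - 1,
         3 * which(abs(nn[, 3]) < 1e-12)))
}
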