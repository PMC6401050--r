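#' @importFrom stats rnorm quantile sd pt cor t.test integrate
NULL

# Canonical monitor-point names, in the conventional order 1..6.
monitor_point_names <- c("apex_pulmonis", "middle_lateral", "lower_lateral",
                         "lower_interior", "lower_anterior", "interior")

# Parametric anatomy of the synthetic rat: all internal layers are nested
# ellipsoids expressed as fixed fractions of the outer body semi-axes.
# Frame: ground plane z = 0, body long axis along y (head at +y), the
# charge-facing left flank at -x. Documented in the methods vignette.
rat_anatomy <- function() {
  list(
    thorax_center_frac = 0.25,   # thorax centre at y = 0.25 * (length/2), head-ward
    thorax_halfwidth_frac = 0.32, # thoracic band half-width as fraction of length/2
    rib_inner_frac = 0.56,       # rib shell: rib_inner < rho <= rib_outer
    rib_outer_frac = 0.78,       # (rho = elliptic radial coordinate in the x-z plane)
    rib_period = 0.025,          # m, intercostal perforation period along y
    rib_gap_cos = -0.45,         # keep rib where cos(2 pi y'/period) > this
    lung_scale = 0.90,           # lung ellipsoid semi-axes = scale * rib_inner * (ax, az)
    lung_y_semi = 0.030,         # m, lung half-length along the body axis
    lung_gap = 0.003,            # m, mediastinal half-gap between the two lungs
    heart_offset = c(0, -0.006, -0.004), # from (0, y_thorax, z_centre), m
    heart_semi = c(0.014, 0.016, 0.015)  # m
  )
}

# Split the cubes of a structured grid into 6 positively oriented Kuhn
# tetrahedra each; `keep` is a logical vector over cubes in (ix, iy, iz)
# lexicographic order (x fastest). Returns compacted nodes and elements.
tet_grid <- function(n, h, origin, keep) {
  nx <- n[1]; ny <- n[2]; nz <- n[3]
  idx <- which(keep) - 1L
  if (length(idx) == 0L) stop("empty mesh: no cubes retained")
  ix <- idx %% nx
  iy <- (idx %/% nx) %% ny
  iz <- idx %/% (nx * ny)
  nid <- function(i, j, k) (k * (ny + 1L) + j) * (nx + 1L) + i + 1L
  corner <- function(bit) nid(ix + bit[1], iy + bit[2], iz + bit[3])
  bits <- rbind(c(0L,0L,0L), c(1L,0L,0L), c(0L,1L,0L), c(1L,1L,0L),
                c(0L,0L,1L), c(1L,0L,1L), c(0L,1L,1L), c(1L,1L,1L))
  # monotone lattice paths 000 -> 111 (Kuhn subdivision, conforming across cubes)
  paths <- rbind(c(1L,2L,4L,8L), c(1L,2L,6L,8L), c(1L,3L,4L,8L),
                 c(1L,3L,7L,8L), c(1L,5L,6L,8L), c(1L,5L,7L,8L))
  # orient each pattern positively on the reference cube
  ref <- bits * rep(h, each = 8L)
  for (p in seq_len(6L)) {
    v <- ref[paths[p, ], ]
    if (det(rbind(v[2, ] - v[1, ], v[3, ] - v[1, ], v[4, ] - v[1, ])) < 0)
      paths[p, c(3L, 4L)] <- paths[p, c(4L, 3L)]
  }
  elems <- matrix(0L, nrow = 6L * length(idx), ncol = 4L)
  for (p in seq_len(6L)) {
    rows <- seq.int(p, by = 6L, length.out = length(idx))
    for (c in seq_len(4L)) elems[rows, c] <- corner(bits[paths[p, c], ])
  }
  used <- sort(unique(as.vector(elems)))
  remap <- integer((nx + 1L) * (ny + 1L) * (nz + 1L))
  remap[used] <- seq_along(used)
  elems[] <- remap[elems]
  u0 <- used - 1L
  gi <- u0 %% (nx + 1L)
  gj <- (u0 %/% (nx + 1L)) %% (ny + 1L)
  gk <- u0 %/% ((nx + 1L) * (ny + 1L))
  nodes <- cbind(x = origin[1] + gi * h[1],
                 y = origin[2] + gj * h[2],
                 z = origin[3] + gk * h[3])
  list(nodes = nodes, elements = elems)
}

tet_volumes <- function(nodes, elements) {
  a <- nodes[elements[, 1], , drop = FALSE]
  b <- nodes[elements[, 2], , drop = FALSE] - a
  c_ <- nodes[elements[, 3], , drop = FALSE] - a
  d <- nodes[elements[, 4], , drop = FALSE] - a
  (b[, 1] * (c_[, 2] * d[, 3] - c_[, 3] * d[, 2]) -
   b[, 2] * (c_[, 1] * d[, 3] - c_[, 3] * d[, 1]) +
   b[, 3] * (c_[, 1] * d[, 2] - c_[, 2] * d[, 1])) / 6
}

# Boundary faces of an element subset, outward-oriented, with the owning
# element (row index into `elements`) of each boundary face.
boundary_faces <- function(nodes, elements) {
  local <- rbind(c(2L, 3L, 4L), c(1L, 4L, 3L), c(1L, 2L, 4L), c(1L, 3L, 2L))
  m <- nrow(elements)
  faces <- matrix(0L, 4L * m, 3L)
  opp <- integer(4L * m)
  owner <- integer(4L * m)
  for (f in seq_len(4L)) {
    rows <- seq.int(f, by = 4L, length.out = m)
    faces[rows, ] <- elements[, local[f, ], drop = FALSE]
    opp[rows] <- elements[, f]
    owner[rows] <- seq_len(m)
  }
  srt <- cbind(pmin.int(faces[, 1], faces[, 2], faces[, 3]),
               faces[, 1] + faces[, 2] + faces[, 3],
               pmax.int(faces[, 1], faces[, 2], faces[, 3]))
  key <- paste(srt[, 1], srt[, 2], srt[, 3])
  cnt <- table(key)
  bd <- which(cnt[key] == 1L)
  faces <- faces[bd, , drop = FALSE]
  opp <- opp[bd]
  owner <- owner[bd]
  # flip faces whose normal points toward the opposite vertex
  p1 <- nodes[faces[, 1], , drop = FALSE]
  p2 <- nodes[faces[, 2], , drop = FALSE]
  p3 <- nodes[faces[, 3], , drop = FALSE]
  n <- vec_cross(p2 - p1, p3 - p1)
  ctr <- (p1 + p2 + p3) / 3
  flip <- rowSums(n * (ctr - nodes[opp, , drop = FALSE])) < 0
  faces[flip, c(2L, 3L)] <- faces[flip, c(3L, 2L)]
  list(faces = faces, owner = owner)
}

vec_cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# Material label for each element centroid, given body dims in the
# canonical frame (width wx along x, length wy along y, height wz along z).
assign_materials <- function(ctr, wx, wy, wz) {
  an <- rat_anatomy()
  ax <- wx / 2; by <- wy / 2; az <- wz / 2
  cz0 <- az
  y_t <- an$thorax_center_frac * by
  x <- ctr[, 1]; y <- ctr[, 2]; z <- ctr[, 3]
  rho <- sqrt((x / ax)^2 + ((z - cz0) / az)^2)
  thorax <- abs(y - y_t) <= an$thorax_halfwidth_frac * by
  lab <- rep("skin_muscle", nrow(ctr))
  rib <- thorax & rho > an$rib_inner_frac & rho <= an$rib_outer_frac &
    cos(2 * pi * (y - y_t) / an$rib_period) > an$rib_gap_cos
  lab[rib] <- "rib"
  hc <- c(0, y_t, cz0) + an$heart_offset
  hs <- an$heart_semi
  heart <- ((x - hc[1]) / hs[1])^2 + ((y - hc[2]) / hs[2])^2 +
    ((z - hc[3]) / hs[3])^2 <= 1
  lx <- an$lung_scale * an$rib_inner_frac * ax
  lz <- an$lung_scale * an$rib_inner_frac * az
  lung <- (x / lx)^2 + ((y - y_t) / an$lung_y_semi)^2 + ((z - cz0) / lz)^2 <= 1
  lab[lung & !heart & x <= -an$lung_gap] <- "lung_L"
  lab[lung & !heart & x >= an$lung_gap] <- "lung_R"
  lab[heart] <- "heart"
  lab
}

#' Build the synthetic layered rat body
#'
#' Generates a tetrahedral stand-in for a CT-derived rat model: an outer
#' skin+muscle ellipsoid (20.11 cm long, 10.32 cm wide, 10.04 cm tall by
#' default, limbs excluded) containing a perforated rib shell around the
#' thorax, a heart ellipsoid, and two lung half-ellipsoids separated by a
#' mediastinal gap. The body rests on the ground plane z = 0 with its long
#' axis along y (head at +y); the charge-facing left flank is at -x. Cubes of
#' a structured grid whose centres fall inside the outer ellipsoid are each
#' split into 6 tetrahedra; element materials are assigned by centroid
#' containment in the nested regions. Construction is fully deterministic:
#' the same dims, resolution and seed always yield identical arrays.
#'
#' @param body_dims Body (length, width, height) in m.
#' @param resolution Target element edge length in m (default 0.01). Must be
#'   finer than a quarter of the smallest body dimension and fine enough to
#'   resolve every anatomical layer.
#' @param seed Integer recorded in the model for provenance; the construction
#'   itself is deterministic.
#' @return An object of class `body_model` with fields `nodes` (n x 3 m),
#'   `elements` (m x 4 node indices, positive orientation), `material`
#'   (label per element), `surface_faces` (outward-oriented exterior
#'   triangles), `monitor_points` (NULL until [place_monitor_points()]),
#'   `body_dims`, `resolution`, `seed`.
#' @examples
#' model <- build_synthetic_rat(resolution = 0.02)
#' table(model$material)
#' @export
build_synthetic_rat <- function(body_dims = c(0.2011, 0.1032, 0.1004),
                                resolution = 0.01, seed = 1L) {
  stopifnot(length(body_dims) == 3L, all(body_dims > 0), resolution > 0)
  if (resolution >= min(body_dims) / 4)
    stop("resolution must be finer than a quarter of the smallest body dimension")
  wy <- body_dims[1]; wx <- body_dims[2]; wz <- body_dims[3]
  an <- rat_anatomy()
  layer_thickness <- c(
    skin_muscle = (1 - an$rib_outer_frac) * min(wx, wz) / 2,
    rib = (an$rib_outer_frac - an$rib_inner_frac) * min(wx, wz) / 2,
    lung = an$lung_scale * an$rib_inner_frac * wx / 2 - an$lung_gap,
    heart = 2 * min(an$heart_semi)
  )
  too_coarse <- names(layer_thickness)[layer_thickness < resolution]
  if (length(too_coarse) > 0L)
    stop("resolution ", resolution, " m too coarse to resolve layer(s): ",
         paste(too_coarse, collapse = ", "))
  n <- pmax(1L, as.integer(round(c(wx, wy, wz) / resolution)))
  h <- c(wx, wy, wz) / n
  origin <- c(-wx / 2, -wy / 2, 0)
  # cube centres
  cx <- origin[1] + (seq_len(n[1]) - 0.5) * h[1]
  cy <- origin[2] + (seq_len(n[2]) - 0.5) * h[2]
  cz <- origin[3] + (seq_len(n[3]) - 0.5) * h[3]
  gx <- rep(cx, times = n[2] * n[3])
  gy <- rep(rep(cy, each = n[1]), times = n[3])
  gz <- rep(cz, each = n[1] * n[2])
  keep <- (gx / (wx / 2))^2 + (gy / (wy / 2))^2 + ((gz - wz / 2) / (wz / 2))^2 <= 1
  grid <- tet_grid(n, h, origin, keep)
  ctr <- (grid$nodes[grid$elements[, 1], ] + grid$nodes[grid$elements[, 2], ] +
          grid$nodes[grid$elements[, 3], ] + grid$nodes[grid$elements[, 4], ]) / 4
  material <- assign_materials(ctr, wx, wy, wz)
  missing <- setdiff(c("lung_L", "lung_R", "heart", "rib", "skin_muscle"),
                     unique(material))
  if (length(missing) > 0L)
    stop("resolution too coarse to resolve layer(s): ",
         paste(missing, collapse = ", "))
  structure(list(nodes = grid$nodes,
                 elements = grid$elements,
                 material = material,
                 surface_faces = boundary_faces(grid$nodes, grid$elements)$faces,
                 monitor_points = NULL,
                 body_dims = body_dims,
                 resolution = resolution,
                 seed = as.integer(seed)),
            class = "body_model")
}

#' @export
print.body_model <- function(x, ...) {
  cat(sprintf("<body_model> %d nodes, %d tetrahedra, %d surface faces\n",
              nrow(x$nodes), nrow(x$elements), nrow(x$surface_faces)))
  print(table(x$material))
  if (!is.null(x$monitor_points))
    cat(sprintf("  %d monitor points placed\n", nrow(x$monitor_points)))
  invisible(x)
}

# Boundary faces of one lung region (interface of lung-labelled elements with
# anything else, including the mediastinum), with face centroids and the
# owning element index.
lung_region_faces <- function(model, side) {
  lab <- paste0("lung_", side)
  el <- which(model$material == lab)
  if (length(el) == 0L) stop("model has no elements for lung side ", side)
  bf <- boundary_faces(model$nodes, model$elements[el, , drop = FALSE])
  ctr <- (model$nodes[bf$faces[, 1], , drop = FALSE] +
          model$nodes[bf$faces[, 2], , drop = FALSE] +
          model$nodes[bf$faces[, 3], , drop = FALSE]) / 3
  list(faces = bf$faces, centroids = ctr, owner = el[bf$owner], elements = el)
}

#' Place the six lung monitor points per side
#'
#' Places the canonical monitor points (apex pulmonis, middle lateral, lower
#' lateral, lower interior, lower anterior, interior) on each lung surface at
#' fixed parametric positions of the lung bounding box (medial-lateral,
#' tail-head, bottom-top fractions), snapped to the nearest lung-surface face
#' centroid. The parametric fractions are a documented convention of this
#' package; only the names and the qualitative anatomy are prescribed.
#'
#' @param model A [build_synthetic_rat()] model containing both lung sides.
#' @return The model with `monitor_points` set: a data frame with columns
#'   `name`, `side`, `x`, `y`, `z` (12 rows, 6 per side).
#' @export
place_monitor_points <- function(model) {
  stopifnot(inherits(model, "body_model"))
  # fractions: medial(0)->lateral(1), tail(0)->head(1), bottom(0)->top(1)
  frac <- rbind(
    apex_pulmonis = c(0.50, 0.50, 1.00),
    middle_lateral = c(1.00, 0.50, 0.55),
    lower_lateral = c(1.00, 0.50, 0.15),
    lower_interior = c(0.00, 0.35, 0.15),
    lower_anterior = c(0.50, 0.95, 0.15),
    interior = c(0.00, 0.55, 0.30)
  )
  out <- NULL
  for (side in c("L", "R")) {
    lrf <- lung_region_faces(model, side)
    lung_nodes <- model$nodes[unique(as.vector(
      model$elements[lrf$elements, , drop = FALSE])), , drop = FALSE]
    bb <- apply(lung_nodes, 2L, range)
    # medial edge is toward x = 0
    if (side == "L") { xm <- bb[2, 1]; xl <- bb[1, 1] } else { xm <- bb[1, 1]; xl <- bb[2, 1] }
    used <- integer(0)
    for (nm in monitor_point_names) {
      f <- frac[nm, ]
      target <- c(xm + f[1] * (xl - xm),
                  bb[1, 2] + f[2] * (bb[2, 2] - bb[1, 2]),
                  bb[1, 3] + f[3] * (bb[2, 3] - bb[1, 3]))
      d2 <- rowSums(sweep(lrf$centroids, 2L, target)^2)
      d2[used] <- Inf
      pick <- which.min(d2)
      used <- c(used, pick)
      out <- rbind(out, data.frame(name = nm, side = side,
                                   x = lrf$centroids[pick, 1],
                                   y = lrf$centroids[pick, 2],
                                   z = lrf$centroids[pick, 3]))
    }
  }
  rownames(out) <- NULL
  model$monitor_points <- out
  model
}

#' Utility: tetrahedral mesh of a rectangular box
#'
#' Structured Kuhn tetrahedralisation of a box with one corner at the origin,
#' used for solver verification (patch tests, uniaxial bars).
#'
#' @param dims Box edge lengths (x, y, z) in m.
#' @param n Number of cube cells along each axis.
#' @param material Single material label applied to every element.
#' @return A `body_model` (no monitor points, single material).
#' @export
mesh_box <- function(dims = c(1, 1, 1), n = c(2L, 2L, 2L),
                     material = "skin_muscle") {
  stopifnot(length(dims) == 3L, all(dims > 0), length(n) == 3L, all(n >= 1))
  n <- as.integer(n)
  grid <- tet_grid(n, dims / n, c(0, 0, 0), rep(TRUE, prod(n)))
  structure(list(nodes = grid$nodes,
                 elements = grid$elements,
                 material = rep(material, nrow(grid$elements)),
                 surface_faces = boundary_faces(grid$nodes, grid$elements)$faces,
                 monitor_points = NULL,
                 body_dims = dims,
                 resolution = max(dims / n),
                 seed = 0L),
            class = "body_model")
}
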