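#' Explosion field configuration
#'
#' Geometry of the simulated explosion field: the charge hangs `charge_height`
#' above the ground plane (z = 0) and the body centre sits `standoff` metres
#' from the explosion centre, charge-facing flank toward it. The domain is
#' the 2 m cube of the field description; only its half-width is retained
#' since the simplified model needs no discretised air domain.
#'
#' @param charge A [charge_spec()].
#' @param ambient An [ambient_state()].
#' @param standoff Distance L from the explosion centre to the body centre,
#'   in m (study values 0.40, 0.50, 0.60, 0.70, 0.80).
#' @param domain_half_width Half-width of the air domain in m (default 1.0).
#' @param charge_height Height H of the charge above the ground in m
#'   (default 0.10).
#' @return An object of class `explosion_field`.
#' @export
explosion_field <- function(charge = charge_spec(),
                            ambient = ambient_state(),
                            standoff = 0.40,
                            domain_half_width = 1.0,
                            charge_height = 0.10) {
  stopifnot(inherits(charge, "charge_spec"), inherits(ambient, "ambient_state"))
  if (!(standoff > charge$initial_wave_radius))
    stop("standoff must exceed the initial-wave radius")
  if (!(charge_height > 0)) stop("charge must sit above the ground")
  structure(list(charge = charge, ambient = ambient, standoff = standoff,
                 domain_half_width = domain_half_width,
                 charge_height = charge_height),
            class = "explosion_field")
}

#' Incident (side-on) peak overpressure at range
#'
#' Evaluates the scaled-distance law at an arbitrary range from the charge:
#' `peak_overpressure(scaled_distance(distance, W))`. This is the single
#' shared code path for the empirical law; the zero-mass limit returns 0.
#'
#' @param charge A [charge_spec()].
#' @param distance Range from the explosion centre in m (vectorised); must be
#'   at least the initial-wave radius.
#' @return Incident peak overpressure in kPa.
#' @examples
#' incident_overpressure(charge_spec(), 0.70)  # ~71.8 kPa
#' @export
incident_overpressure <- function(charge, distance) {
  stopifnot(inherits(charge, "charge_spec"))
  if (any(distance < charge$initial_wave_radius))
    stop("distance lies inside the initial-wave sphere")
  if (charge$tnt_equiv_mass == 0) return(rep(0, length(distance)))
  peak_overpressure(scaled_distance(distance, charge$tnt_equiv_mass))
}

#' Shock reflection coefficient
#'
#' Ratio of reflected to incident overpressure at a rigid surface. At normal
#' incidence (`incidence_cosine = 1`) the gamma = 1.4 Rankine-Hugoniot normal
#' reflection factor `2 (7 P0 + 4 Ps) / (7 P0 + Ps)` is used, which runs from
#' 2 in the acoustic limit (incident -> 0) to 8 in the strong-shock limit.
#' The factor blends linearly in the incidence cosine down to 1 (pure side-on
#' loading) at grazing incidence.
#'
#' @param incident Incident peak overpressure in kPa (vectorised), >= 0.
#' @param ambient An [ambient_state()].
#' @param incidence_cosine Cosine of the angle between the surface normal and
#'   the direction to the charge, in \[0, 1\].
#' @return Dimensionless multiplier applied to the incident overpressure.
#' @examples
#' reflection_coefficient(0, ambient_state(), 1)     # acoustic limit: 2
#' reflection_coefficient(1e9, ambient_state(), 1)   # strong-shock limit: ~8
#' @export
reflection_coefficient <- function(incident, ambient, incidence_cosine) {
  stopifnot(inherits(ambient, "ambient_state"))
  if (any(incident < 0)) stop("incident overpressure must be >= 0")
  if (any(incidence_cosine < 0 | incidence_cosine > 1))
    stop("incidence_cosine must lie in [0, 1]")
  g <- ambient$ratio_of_specific_heats
  p0 <- ambient$pressure / 1000 # kPa
  normal <- 2 + (g + 1) * incident / ((g - 1) * incident + 2 * g * p0)
  1 + (normal - 1) * incidence_cosine
}

# Charge position for a field and a body centred at `center` (3-vector):
# on the -x side, at height charge_height, with straight-line distance to
# the body centre equal to the standoff.
charge_position <- function(field, center) {
  dz <- field$charge_height - center[3]
  if (field$standoff <= abs(dz))
    stop("standoff too small for the charge height / body centre geometry")
  c(center[1] - sqrt(field$standoff^2 - dz^2), center[2], field$charge_height)
}

# Area-weighted outward node normals over the exterior surface.
surface_node_normals <- function(model) {
  f <- model$surface_faces
  p1 <- model$nodes[f[, 1], , drop = FALSE]
  p2 <- model$nodes[f[, 2], , drop = FALSE]
  p3 <- model$nodes[f[, 3], , drop = FALSE]
  n <- vec_cross(p2 - p1, p3 - p1) / 2 # area-weighted
  if (any(rowSums(n^2) == 0))
    stop("degenerate surface normal on face ", which(rowSums(n^2) == 0)[1])
  acc <- matrix(0, nrow(model$nodes), 3L)
  s <- rowsum(rbind(n, n, n), group = c(f[, 1], f[, 2], f[, 3]))
  acc[as.integer(rownames(s)), ] <- s
  len <- sqrt(rowSums(acc^2))
  surface <- len > 0
  acc[surface, ] <- acc[surface, ] / len[surface]
  list(normals = acc, is_surface = surface)
}

#' Peak pressure on the body surface
#'
#' Simplified loading model standing in for the CFD stage: each exterior
#' surface node receives the incident overpressure at its own range from the
#' charge, amplified on charge-facing nodes by the acoustic-limit reflection
#' factor `1 + cos(theta)` (the source ramps over 750 ms, so the loading is
#' quasi-static rather than a sharp shock; see the methods vignette), plus an
#' additive ground-reflected contribution from a mirror charge below z = 0
#' weighted by the grazing cosine of the ground bounce. Shadowed nodes
#' (normal pointing away from the charge) receive side-on incident pressure
#' only.
#'
#' @param model A `body_model`.
#' @param field An [explosion_field()].
#' @param include_ground If `FALSE`, drop the ground-image term (used to
#'   check that the ground reflection only ever adds pressure).
#' @return An object of class `surface_pressure_field`: a data frame with
#'   columns `node`, `x`, `y`, `z`, `peak_pressure_kpa` (one row per exterior
#'   surface node), with the standoff and charge attached as attributes.
#' @export
surface_pressure_field <- function(model, field, include_ground = TRUE) {
  stopifnot(inherits(model, "body_model"), inherits(field, "explosion_field"))
  sn <- surface_node_normals(model)
  idx <- which(sn$is_surface)
  pts <- model$nodes[idx, , drop = FALSE]
  nrm <- sn$normals[idx, , drop = FALSE]
  if (field$charge$tnt_equiv_mass == 0) {
    p <- rep(0, length(idx))
  } else {
    center <- c(mean(range(model$nodes[, 1])), mean(range(model$nodes[, 2])),
                mean(range(model$nodes[, 3])))
    cpos <- charge_position(field, center)
    to_charge <- sweep(pts, 2L, cpos, "-") * -1
    d <- sqrt(rowSums(to_charge^2))
    pi_dir <- incident_overpressure(field$charge, d)
    cosi <- pmax(0, rowSums(nrm * to_charge / d))
    # quasi-static (acoustic-limit) facing amplification
    p <- pi_dir * reflection_coefficient(rep(0, length(idx)), field$ambient, cosi)
    if (include_ground) {
      ipos <- c(cpos[1], cpos[2], -field$charge_height)
      to_img <- sweep(pts, 2L, ipos, "-") * -1
      di <- sqrt(rowSums(to_img^2))
      pi_img <- incident_overpressure(field$charge, di)
      graze <- (pts[, 3] + field$charge_height) / di
      p <- p + pi_img * graze
    }
  }
  out <- data.frame(node = idx, x = pts[, 1], y = pts[, 2], z = pts[, 3],
                    peak_pressure_kpa = p)
  attr(out, "standoff") <- field$standoff
  attr(out, "charge") <- field$charge
  class(out) <- c("surface_pressure_field", "data.frame")
  out
}

#' Head-to-tail axial pressure profile
#'
#' Maximum surface pressure in `n_bins` equal-width bins along the body's
#' long axis (y), ordered head first (head at +y). Bins containing no
#' surface node are reported as `NA`.
#'
#' @param field A [surface_pressure_field()].
#' @param model The `body_model` the field was computed on.
#' @param n_bins Number of axial bins, >= 2.
#' @return Numeric vector of length `n_bins` (kPa), head first.
#' @export
axial_profile <- function(field, model, n_bins) {
  stopifnot(inherits(field, "surface_pressure_field"), n_bins >= 2)
  rng <- range(model$nodes[, 2])
  brk <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  bin <- cut(field$y, breaks = brk, include.lowest = TRUE, labels = FALSE)
  prof <- rep(NA_real_, n_bins)
  agg <- tapply(field$peak_pressure_kpa, bin, max)
  prof[as.integer(names(agg))] <- agg
  rev(prof) # head (+y) first
}
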