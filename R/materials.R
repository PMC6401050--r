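#' Linear-elastic material specification
#'
#' @param name Material label.
#' @param elastic_modulus Young's modulus E in Pa.
#' @param poisson_ratio Poisson's ratio, in (0, 0.5).
#' @param density Mass density in kg/m^3; used only by the lumped mass matrix
#'   of the transient mode.
#' @return An object of class `material_spec`.
#' @export
material_spec <- function(name, elastic_modulus, poisson_ratio, density = 1000) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!(elastic_modulus > 0)) stop("elastic_modulus must be > 0")
  if (!(poisson_ratio > 0 && poisson_ratio < 0.5))
    stop("poisson_ratio must lie strictly between 0 and 0.5")
  if (!(density > 0)) stop("density must be > 0")
  structure(list(name = name, elastic_modulus = elastic_modulus,
                 poisson_ratio = poisson_ratio, density = density),
            class = "material_spec")
}

#' Default rat tissue materials
#'
#' Literature material constants used by the structural stage: lung
#' parenchyma E = 1.2e4 Pa, nu = 0.32 (gas-filled alveolar tissue treated as
#' a soft elastic continuum); rib cortical bone E = 6.6 GPa, nu = 0.3; skin,
#' muscle and heart lumped as one soft-tissue material with E = 480 MPa,
#' nu = 0.45. Densities are nominal (1000 kg/m^3 soft tissue, 1500 kg/m^3
#' bone) and matter only for the transient mass matrix.
#'
#' @return Named list of [material_spec()] objects keyed by the element
#'   labels `lung_L`, `lung_R`, `heart`, `rib`, `skin_muscle`.
#' @export
rat_materials <- function() {
  list(
    lung_L = material_spec("lung_L", 1.2e4, 0.32, 1000),
    lung_R = material_spec("lung_R", 1.2e4, 0.32, 1000),
    heart = material_spec("heart", 480e6, 0.45, 1000),
    rib = material_spec("rib", 6.6e9, 0.30, 1500),
    skin_muscle = material_spec("skin_muscle", 480e6, 0.45, 1000)
  )
}
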