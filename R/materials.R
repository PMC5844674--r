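#' Neo-Hookean material
#'
#' Hyperelastic constitutive model with strain-energy density
#' W = (mu/2)(I1 - 3) + (1/d)(J - 1)^2, where I1 is the deviatoric first
#' invariant, J the volume ratio, mu the shear-type material constant (Pa)
#' and d the incompressibility parameter (1/Pa). Used for the epithelium and
#' connective-tissue layers of the airway wall.
#'
#' @param mu Shear-type material constant, Pa (> 0).
#' @param d Incompressibility parameter, 1/Pa (> 0). The default corresponds
#'   to a near-incompressible response (effective Poisson ratio ~0.49) via
#'   d = 2/K with K the small-strain bulk modulus.
#' @return Object of class \code{material_neo_hookean}.
#' @export
#' @examples
#' neo_hookean(5e6)
neo_hookean <- function(mu, d = incompressibility_d(mu)) {
  stopifnot(is.finite(mu), mu > 0, is.finite(d), d > 0)
  structure(list(mu = mu, d = d), class = "material_neo_hookean")
}

#' Incompressibility parameter for a target effective Poisson ratio
#'
#' d = 2/K with bulk modulus K = 2 mu (1 + nu) / (3 (1 - 2 nu)).
#'
#' @param mu Shear constant, Pa.
#' @param nu Effective small-strain Poisson ratio (default 0.49).
#' @return d in 1/Pa.
#' @export
incompressibility_d <- function(mu, nu = 0.49) {
  stopifnot(nu >= 0, nu < 0.5)
  k <- 2 * mu * (1 + nu) / (3 * (1 - 2 * nu))
  2 / k
}

#' Linear elastic material (plane strain)
#'
#' @param young_modulus Young's modulus E, Pa (> 0).
#' @param poisson Poisson ratio in [0, 0.5).
#' @return Object of class \code{material_linear}.
#' @export
linear_elastic <- function(young_modulus, poisson = 0.45) {
  stopifnot(is.finite(young_modulus), young_modulus > 0,
            poisson >= 0, poisson < 0.5)
  structure(list(E = young_modulus, nu = poisson), class = "material_linear")
}

#' Neo-Hookean strain-energy density
#'
#' W = (mu/2)(I1 - 3) + (1/d)(J - 1)^2.
#'
#' @param I1 First deviatoric invariant of the deformation.
#' @param J Jacobian (volume ratio); must be > 0.
#' @param m A \code{\link{neo_hookean}} material.
#' @return Energy density in Pa.
#' @export
#' @examples
#' neo_hookean_energy(3, 1, neo_hookean(5e6))  # undeformed: 0
neo_hookean_energy <- function(I1, J, m) {
  stopifnot(inherits(m, "material_neo_hookean"))
  if (any(J <= 0)) stop("inverted element: J must be > 0")
  m$mu / 2 * (I1 - 3) + (1 / m$d) * (J - 1)^2
}

#' Small-strain linearization of a material
#'
#' For a Neo-Hookean material the small-strain moduli are shear G = mu and
#' bulk K = 2/d, giving E = 9KG/(3K + G) and nu = (3K - 2G)/(2(3K + G)).
#' Linear materials are returned unchanged. Used to compare the nonlinear
#' solver against the layered Lame closed form in the small-pressure limit.
#'
#' @param m A material object.
#' @return A \code{material_linear}.
#' @export
linearize_material <- function(m) {
  if (inherits(m, "material_linear")) return(m)
  stopifnot(inherits(m, "material_neo_hookean"))
  g <- m$mu
  k <- 2 / m$d
  linear_elastic(9 * k * g / (3 * k + g), (3 * k - 2 * g) / (2 * (3 * k + g)))
}

#' Inflammation-driven stiffening of a Neo-Hookean material
#'
#' The fibrosis fraction reported by the cellular stage stiffens the tissue:
#' mu' = mu (1 + alpha f); the incompressibility parameter is unchanged.
#'
#' @param material A \code{\link{neo_hookean}} material.
#' @param fibrosis_fraction Fraction of the epithelial population in the
#'   fibrotic state, in [0, 1].
#' @param alpha Stiffening gain (>= 0).
#' @return A stiffened \code{material_neo_hookean}.
#' @export
stiffen <- function(material, fibrosis_fraction, alpha = 1) {
  stopifnot(inherits(material, "material_neo_hookean"), alpha >= 0)
  if (!is.finite(fibrosis_fraction) ||
      fibrosis_fraction < 0 || fibrosis_fraction > 1) {
    stop("fibrosis_fraction must lie in [0, 1]")
  }
  neo_hookean(material$mu * (1 + alpha * fibrosis_fraction), material$d)
}

#' Default wall materials
#'
#' Epithelium: Neo-Hookean with mu = 5 MPa; connective tissue: Neo-Hookean
#' with mu = 0.5 MPa (inner/middle stiffness ratio 10); airway smooth muscle:
#' linear elastic with E = 99 MPa (the organ-scale tissue modulus), nu = 0.45.
#' All overridable through the simulation config.
#'
#' @return Named list with elements \code{epithelium}, \code{connective},
#'   \code{asm}.
#' @export
default_materials <- function() {
  list(epithelium = neo_hookean(5e6),
       connective = neo_hookean(5e5),
       asm = linear_elastic(99e6, 0.45))
}
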