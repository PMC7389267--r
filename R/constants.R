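#' Physical constants used throughout the package
#'
#' All mechanical quantities in this package are expressed in the natural AFM
#' units: forces in piconewtons (pN), lengths in nanometres (nm), times in
#' seconds.  In these units the Boltzmann constant is
#' \eqn{k_B = 0.0138065} pN nm K\eqn{^{-1}}, so the thermal energy at 20 degC
#' (293.15 K) is \eqn{k_B T \approx 4.05} pN nm.
#'
#' @return A named list with components
#'   \describe{
#'     \item{k_B}{Boltzmann constant, pN nm / K.}
#'     \item{gamma_euler}{Euler-Mascheroni constant as used in the
#'       Friddle-Noy-de Yoreo mean rupture force expression (0.577).}
#'     \item{kcal_per_mol_to_pN_nm}{Energy conversion factor: 1 kcal/mol
#'       expressed in pN nm per molecule (6.9477).}
#'   }
#' @examples
#' const <- afm_constants()
#' const$k_B * 293.15   # thermal energy at 20 degC, pN nm
#' @export
afm_constants <- function() {
  list(
    k_B = 0.0138065,
    gamma_euler = 0.577,
    kcal_per_mol_to_pN_nm = 6.9477
  )
}

# Thermal energy k_B * T in pN nm.
kBT <- function(temperature_K) 0.0138065 * temperature_K
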