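#' Physical constants and unit conventions
#'
#' Energy is carried in micro-electronvolts (ueV), time in picoseconds (ps),
#' length in Angstrom (A), momentum transfer Q in 1/A and temperature in
#' kelvin throughout the package. Diffusion coefficients are handled
#' internally in A^2/ps; the conventional reporting unit for water diffusion
#' is 1e-10 m^2/s, and 1 A^2/ps = 100 x 1e-10 m^2/s. With these conventions
#' the jump-diffusion product D*Q^2*tau0 is dimensionless with no hidden
#' factors.
#'
#' @format A named list with elements:
#' \describe{
#'   \item{hbar_ueV_ps}{Reduced Planck constant, 658.212 ueV ps.}
#'   \item{kB_ueV_K}{Boltzmann constant, 86.173 ueV/K.}
#'   \item{A2ps_to_1e10m2s}{Conversion factor from A^2/ps to 1e-10 m^2/s (= 100).}
#' }
#' @export
#' @examples
#' qens_constants$hbar_ueV_ps / 142.2  # high-Q saturation width for tau0 = 142.2 ps
qens_constants <- list(
  hbar_ueV_ps = 658.212,
  kB_ueV_K = 86.173,
  A2ps_to_1e10m2s = 100
)
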