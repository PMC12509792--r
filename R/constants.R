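#' Physical constants used throughout the package
#'
#' CODATA values for the classical electron radius, Planck's constant and
#' the speed of light, the electron density of water, and the product
#' \eqn{hc} expressed in keV m (so that \eqn{\lambda = hc/E} with E in keV
#' gives metres).
#'
#' @return Named list with elements `r0` (m), `h` (J s), `c` (m/s),
#'   `hc_keV_m` (keV m), `rho_e_water` (electrons per m^3).
#' @export
#' @examples
#' physical_constants()$hc_keV_m / 38  # wavelength at 38 keV, in m
physical_constants <- function() {
  list(
    r0 = 2.8179403262e-15,       # classical electron radius, m
    h = 6.62607015e-34,          # Planck constant, J s
    c = 2.99792458e8,            # speed of light, m/s
    hc_keV_m = 1.239841984e-9,   # h*c, keV m
    rho_e_water = 3.343e29       # electron density of water, m^-3
  )
}

#' X-ray wavelength for a photon energy
#'
#' @param E_keV photon energy in keV.
#' @return Wavelength in metres.
#' @export
#' @examples
#' wavelength(38)       # ~3.263e-11 m
#' wavelength(12.3984)  # 1 Angstrom
wavelength <- function(E_keV) {
  stopifnot(all(E_keV > 0))
  physical_constants()$hc_keV_m / E_keV
}
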