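# Material models: linear attenuation tables and refractive index decrements.
#
# The packaged tables (inst/extdata/mu_*.csv) are computed from atomic cross
# sections (photoelectric from Cromer-Liberman f'', incoherent from
# Klein-Nishina with a Waller-Hartree binding correction, coherent from IT92
# form factors) for the elemental compositions of each material; see the
# provenance headers in the CSV files. Phase-contrast Hounsfield values HUp
# relate each tissue's electron density to water's.

.material_cache <- new.env(parent = emptyenv())

#' Construct a material from explicit data
#'
#' @param name material identifier.
#' @param energy_keV energies of the attenuation table (keV), increasing.
#' @param mu_per_cm linear attenuation coefficients (1/cm), positive.
#' @param density_g_cm3 mass density (g/cm3), optional.
#' @param hu_p phase-contrast Hounsfield value (electron density relative to
#'   water on a per-mille scale); `NA` if the material has no refraction
#'   model.
#' @param electron_density electron density in m^-3; derived from `hu_p`
#'   when missing.
#' @return An object of class `bct_material`.
#' @export
material <- function(name, energy_keV, mu_per_cm, density_g_cm3 = NA_real_,
                     hu_p = NA_real_, electron_density = NA_real_) {
  stopifnot(length(energy_keV) == length(mu_per_cm),
            !is.unsorted(energy_keV), all(mu_per_cm > 0))
  if (is.na(electron_density) && !is.na(hu_p)) {
    electron_density <- (1 + hu_p / 1000) * physical_constants()$rho_e_water
  }
  structure(
    list(name = name, energy_keV = as.numeric(energy_keV),
         mu_per_cm = as.numeric(mu_per_cm), density = density_g_cm3,
         hu_p = hu_p, electron_density = electron_density),
    class = "bct_material")
}

#' @export
print.bct_material <- function(x, ...) {
  cat(sprintf("<bct_material> %s: mu table %g-%g keV (%d points)",
              x$name, min(x$energy_keV), max(x$energy_keV),
              length(x$energy_keV)))
  if (!is.na(x$hu_p)) cat(sprintf(", HUp = %+g", x$hu_p))
  cat("\n")
  invisible(x)
}

#' Load a packaged material
#'
#' Materials shipped with the package: `"adipose"`, `"fibroglandular"`,
#' `"tumor"`, `"breast"` (whole-breast average used for dose and beam
#' hardening), `"water"`, `"gold"`, `"aluminium"`, `"silicon"`,
#' `"tungsten"`.
#'
#' @param name material name.
#' @return A `bct_material`.
#' @export
#' @examples
#' mu(bct_material("water"), 50)
bct_material <- function(name) {
  if (!is.null(.material_cache[[name]])) return(.material_cache[[name]])
  path <- system.file("extdata", paste0("mu_", name, ".csv"),
                      package = "gibct")
  if (path == "") stop("unknown packaged material: ", name)
  tab <- utils::read.csv(path, comment.char = "#")
  meta <- utils::read.csv(system.file("extdata", "materials.csv",
                                      package = "gibct"),
                          comment.char = "#")
  row <- meta[meta$name == name, ]
  m <- material(name, tab$energy_keV, tab$mu_per_cm,
                density_g_cm3 = row$density_g_cm3,
                hu_p = if (is.na(row$hu_p)) NA_real_ else row$hu_p)
  .material_cache[[name]] <- m
  m
}

#' List packaged materials
#' @return Data frame of names, densities, and HUp values.
#' @export
list_materials <- function() {
  utils::read.csv(system.file("extdata", "materials.csv", package = "gibct"),
                  comment.char = "#")
}

#' Linear attenuation coefficient at given energies
#'
#' Log-log linear interpolation of the material's attenuation table; none of
#' the packaged materials has an absorption edge in the 20-70 keV working
#' range, so the interpolation is smooth there.
#'
#' @param mat a `bct_material`.
#' @param E_keV energies in keV; must lie within the table support.
#' @return Attenuation coefficients in 1/cm.
#' @export
mu <- function(mat, E_keV) {
  stopifnot(inherits(mat, "bct_material"))
  rng <- range(mat$energy_keV)
  if (any(E_keV < rng[1] | E_keV > rng[2])) {
    stop(sprintf("energy outside table support [%g, %g] keV for '%s'",
                 rng[1], rng[2], mat$name))
  }
  exp(stats::approx(log(mat$energy_keV), log(mat$mu_per_cm),
                    xout = log(E_keV))$y)
}

#' Refractive index decrement at given energies
#'
#' \eqn{\delta(E) = r_0 \lambda^2 \rho_e / (2\pi)} with the electron density
#' \eqn{\rho_e = (1 + HU_p/1000)\,\rho_{e,\mathrm{water}}}. Equivalent to
#' \eqn{r_0 h^2 c^2 \rho_e / (2\pi E^2)}; the decrement falls with the
#' inverse square of the photon energy.
#'
#' @param mat a `bct_material` carrying `hu_p` or an electron density.
#' @param E_keV energies in keV.
#' @return Dimensionless decrements.
#' @export
#' @examples
#' delta(bct_material("water"), 38)  # ~1.6e-7
delta <- function(mat, E_keV) {
  stopifnot(inherits(mat, "bct_material"), all(E_keV > 0))
  if (is.na(mat$electron_density)) {
    stop("material '", mat$name, "' has no electron density / HUp")
  }
  k <- physical_constants()
  lam <- k$hc_keV_m / E_keV
  k$r0 * lam^2 * mat$electron_density / (2 * pi)
}
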