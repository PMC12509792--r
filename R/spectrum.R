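# X-ray tube spectra on a fixed 1 keV energy grid, spectral hardening, and
# spectrum-weighted effective contrasts.

#' Construct a spectrum object
#'
#' @param energies energy grid in keV, uniform 1 keV spacing.
#' @param weights photons per bin (arbitrary absolute scale), nonnegative;
#'   must vanish above `kvp`.
#' @param kvp tube voltage in kV.
#' @param filter_mm_al aluminium filtration in mm (provenance only).
#' @return Object of class `bct_spectrum`.
#' @export
spectrum <- function(energies, weights, kvp, filter_mm_al = 0) {
  stopifnot(length(energies) == length(weights), all(weights >= 0))
  if (length(energies) > 1 &&
      max(abs(diff(energies) - 1)) > 1e-9) {
    stop("spectrum grid must have uniform 1 keV spacing")
  }
  if (any(weights[energies > kvp] > 0)) {
    stop("weights must be zero above the tube voltage")
  }
  structure(list(energies = as.numeric(energies),
                 weights = as.numeric(weights),
                 kvp = kvp, filter_mm_al = filter_mm_al),
            class = "bct_spectrum")
}

#' @export
print.bct_spectrum <- function(x, ...) {
  cat(sprintf("<bct_spectrum> %g kVp, %g mm Al, %g-%g keV, mean %.2f keV\n",
              x$kvp, x$filter_mm_al, min(x$energies), max(x$energies),
              mean_energy(x)))
  invisible(x)
}

#' Generate a filtered tungsten-anode spectrum
#'
#' Analytic bremsstrahlung model: a Kramers photon-number spectrum
#' \eqn{w(E) \propto (kVp/E - 1)} attenuated by energy-dependent anode
#' self-filtration and by the external aluminium filter. Self-filtration
#' follows the Thomson-Whiddington depth argument: photons of energy E are
#' generated down to the depth where the electron beam has slowed to E, so
#' the mean escape path through tungsten is
#' \eqn{(kVp^2 - E^2) / (2 \rho C \sin\theta)} with take-off angle
#' \eqn{\theta}. Characteristic K emission is not modelled; the K shell of
#' tungsten (69.5 keV) is barely excited over the 25-70 kVp range used here,
#' and the L lines (8-11 keV) are removed by millimetres of aluminium.
#'
#' @param kvp tube voltage in kV (25-120).
#' @param filter_mm_al aluminium filtration in mm.
#' @param emin lowest tabulated energy in keV (default 8; below that a 3 mm
#'   Al filter transmits essentially nothing).
#' @param anode_angle_deg anode take-off angle in degrees.
#' @param tw_constant Thomson-Whiddington constant in keV^2 cm^2/g.
#' @return A normalized `bct_spectrum` (weights sum to 1).
#' @export
#' @examples
#' s <- generate_spectrum(50, 3)
#' mean_energy(s)
generate_spectrum <- function(kvp, filter_mm_al = 3, emin = 8,
                              anode_angle_deg = 12, tw_constant = 7e5) {
  if (kvp < 25 || kvp > 120) stop("kvp outside supported range 25-120 kV")
  stopifnot(filter_mm_al >= 0)
  E <- seq(emin, floor(kvp))
  w <- pmax(kvp / E - 1, 0)
  # anode self-filtration: mean escape path through tungsten in cm
  # (Thomson-Whiddington depth over the take-off sine)
  wmat <- bct_material("tungsten")
  path_cm <- (kvp^2 - E^2) / (2 * wmat$density * tw_constant *
                                sin(anode_angle_deg * pi / 180))
  w <- w * exp(-mu(wmat, E) * path_cm)
  al <- bct_material("aluminium")
  w <- w * exp(-mu(al, E) * filter_mm_al / 10)
  spectrum(E, w / sum(w), kvp = kvp, filter_mm_al = filter_mm_al)
}

#' Load a spectrum from a two-column CSV file
#'
#' Accepts externally generated spectra (columns `energy_keV`, `weight`) so
#' reference-generator output can be substituted bit-exactly.
#'
#' @param path CSV path.
#' @param kvp tube voltage; defaults to the highest energy with nonzero
#'   weight.
#' @param filter_mm_al filtration provenance tag.
#' @return A `bct_spectrum`.
#' @export
load_spectrum_csv <- function(path, kvp = NULL, filter_mm_al = NA_real_) {
  tab <- utils::read.csv(path, comment.char = "#")
  stopifnot(all(c("energy_keV", "weight") %in% names(tab)))
  if (is.null(kvp)) kvp <- max(tab$energy_keV[tab$weight > 0])
  spectrum(tab$energy_keV, tab$weight, kvp = kvp,
           filter_mm_al = filter_mm_al)
}

#' Write a spectrum to CSV
#' @param s a `bct_spectrum`.
#' @param path output path.
#' @export
write_spectrum_csv <- function(s, path) {
  utils::write.csv(data.frame(energy_keV = s$energies, weight = s$weights),
                   path, row.names = FALSE)
  invisible(path)
}

#' Mean energy of a spectrum
#' @param s a `bct_spectrum`.
#' @return keV.
#' @export
mean_energy <- function(s) {
  sum(s$energies * s$weights) / sum(s$weights)
}

#' Normalize spectrum weights to unit sum
#' @param s a `bct_spectrum`.
#' @return A `bct_spectrum` with weights summing to 1.
#' @export
normalize_spectrum <- function(s) {
  tot <- sum(s$weights)
  if (tot <= 0) stop("cannot normalize an all-zero spectrum")
  s$weights <- s$weights / tot
  s
}

#' Harden a spectrum through an attenuator
#'
#' Multiplies the weights by \eqn{\exp(-\mu(E) t)} and renormalizes to unit
#' sum. Composable: hardening through several layers in sequence equals
#' hardening through their sum.
#'
#' @param s a `bct_spectrum`.
#' @param mat a `bct_material` (or a function E -> mu in 1/cm).
#' @param thickness_cm attenuator thickness in cm.
#' @return A normalized `bct_spectrum`.
#' @export
harden <- function(s, mat, thickness_cm) {
  stopifnot(thickness_cm >= 0)
  mu_e <- if (is.function(mat)) mat(s$energies) else mu(mat, s$energies)
  w <- s$weights * exp(-mu_e * thickness_cm)
  if (sum(w) <= 0 || !any(w > 1e-300)) {
    stop("attenuator is opaque: hardened spectrum is identically zero")
  }
  s$weights <- w / sum(w)
  s
}

# transmission of a grating: open half passes freely, lamella half is
# attenuated through the full structure height
grating_transmission <- function(E_keV, mat, height_um, duty = 0.5) {
  duty + (1 - duty) * exp(-mu(mat, E_keV) * height_um * 1e-4)
}

#' Spectrum-weighted effective contrasts between two materials
#'
#' \eqn{\Delta\mu_{eff} = \sum_E w(E) \Delta\mu(E)} and
#' \eqn{\Delta\delta_{eff} = \sum_E w(E) V(E) \Delta\delta(E) /
#' \sum_E w(E) V(E)}: the attenuation contrast is weighted by the spectrum
#' alone, the refraction contrast additionally by the visibility spectrum
#' (energies that do not contribute fringe modulation do not carry phase
#' signal).
#'
#' @param s a normalized `bct_spectrum` (typically hardened by the gratings
#'   and the breast).
#' @param vis visibility-vs-energy on the same grid (see
#'   [visibility_spectrum()]).
#' @param matA,matB the two materials (contrast is A minus B).
#' @return List with `delta_mu_eff` (1/cm) and `delta_delta_eff`
#'   (dimensionless).
#' @export
effective_contrast <- function(s, vis, matA, matB) {
  stopifnot(length(vis) == length(s$energies))
  w <- s$weights / sum(s$weights)
  dmu <- mu(matA, s$energies) - mu(matB, s$energies)
  ddel <- delta(matA, s$energies) - delta(matB, s$energies)
  wv <- w * vis
  den <- sum(wv)
  if (den <= 0) stop("visibility vanishes over the whole spectrum")
  list(delta_mu_eff = sum(w * dmu),
       delta_delta_eff = sum(wv * ddel) / den)
}
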