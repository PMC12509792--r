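# The joint optimization metric: analytic sphere signals, noise terms, dose
# and intensity proxies, opening angles, and the contrast-to-noise ratio
# weighted by dose (CNRD).
#
# All dose/intensity quantities are relative proxies: absolute prefactors
# common to every design cancel in rankings and are kept explicit only where
# unit tests pin them down.

#' Imaging-task specification
#'
#' @param breast_diameter_cm breast diameter t in cm.
#' @param malignancy_radius_mm malignancy (sphere) radius in mm.
#' @param tissue_pair character vector of two packaged material names;
#'   default compares fibroglandular tissue against tumor, the hardest
#'   clinical discrimination.
#' @param dose_exponent exponent q of the dose normalization
#'   \eqn{CNRD = CNR / Dose^q}. The default 0.5 makes the metric independent
#'   of the absolute number of incident photons (CNR grows with the square
#'   root of the photon count while dose grows linearly); `1` divides by the
#'   full dose as a stricter penalty.
#' @return Object of class `bct_task`.
#' @export
task_spec <- function(breast_diameter_cm, malignancy_radius_mm,
                      tissue_pair = c("fibroglandular", "tumor"),
                      dose_exponent = 0.5) {
  stopifnot(breast_diameter_cm > 0, malignancy_radius_mm > 0,
            length(tissue_pair) == 2, dose_exponent %in% c(0.5, 1))
  structure(list(t_cm = breast_diameter_cm,
                 r_mm = malignancy_radius_mm,
                 tissue_pair = tissue_pair,
                 dose_exponent = dose_exponent), class = "bct_task")
}

#' Total attenuation signal of a spherical lesion
#'
#' The integrated absorption signal over all detector pixels is the sphere
#' volume weighted by the attenuation contrast:
#' \eqn{S_T = \frac{4}{3}\pi r^3 \Delta\mu}.
#'
#' @param r_cm sphere radius in cm.
#' @param delta_mu attenuation contrast in 1/cm.
#' @return Signal (cm^2 scale, arbitrary prefactor convention).
#' @export
sphere_attenuation_signal <- function(r_cm, delta_mu) {
  stopifnot(all(r_cm >= 0))
  (4 / 3) * pi * r_cm^3 * delta_mu
}

#' Total refraction signal of a spherical lesion
#'
#' The integrated differential-phase signal scales with the sphere surface
#' area, the interferometer sensitivity \eqn{d/p_2} and the refraction
#' contrast: \eqn{S_\phi = 4\pi r^2 (d/p_2) \Delta\delta}. Refraction is a
#' surface effect, which is why small lesions favour the phase channel.
#'
#' @param r_cm sphere radius in cm.
#' @param d_sens_m rotation-centre-to-G2 distance in m.
#' @param p2_um analyzer pitch in micrometres.
#' @param delta_delta refraction contrast (dimensionless).
#' @return Signal (cm^2 scale).
#' @export
sphere_refraction_signal <- function(r_cm, d_sens_m, p2_um, delta_delta) {
  stopifnot(all(r_cm >= 0), d_sens_m > 0, p2_um > 0)
  4 * pi * r_cm^2 * (d_sens_m / (p2_um * 1e-6)) * delta_delta
}

#' Noise of the retrieved transmission and phase signals
#'
#' \eqn{\sigma_T = 1/\sqrt{I_D}} and
#' \eqn{\sigma_\phi = 1/(\sqrt{I_D}\, V_{eff})}: phase noise is attenuation
#' noise amplified by the inverse visibility.
#'
#' @param i_d detected photon count (proxy), positive.
#' @param v_eff effective visibility in (0, 1].
#' @return List with `sigma_t` and `sigma_phi`.
#' @export
noise_terms <- function(i_d, v_eff) {
  stopifnot(i_d > 0, v_eff > 0, v_eff <= 1)
  list(sigma_t = 1 / sqrt(i_d), sigma_phi = 1 / (sqrt(i_d) * v_eff))
}

#' Fan and azimuthal opening angles for a centred cylindrical sample
#'
#' The fan angle is twice the angle between the central ray and the ray
#' tangent to the sample cylinder; the azimuthal angle is a configured
#' constant since the illuminated sample height is fixed.
#'
#' @param t_cm sample (breast) diameter in cm.
#' @param source_to_sample_m source-to-rotation-centre distance in m.
#' @param beta_rad fixed azimuthal opening angle in rad (default 0.1; it
#'   rescales the dose proxy uniformly and cancels in design rankings).
#' @return List with `alpha` and `beta` in rad.
#' @export
opening_angles <- function(t_cm, source_to_sample_m, beta_rad = 0.1) {
  half <- t_cm / 200
  if (half >= source_to_sample_m) {
    stop("sample larger than the source-to-sample distance allows")
  }
  list(alpha = 2 * asin(half / source_to_sample_m), beta = beta_rad)
}

#' Dose proxy for a cylindrical sample
#'
#' \eqn{Dose = \alpha \beta \sum_E w(E) (1 - e^{-\mu_{breast}(E) t}) E}: the
#' energy absorbed in the (central part of the) breast cylinder per unit
#' incident spectrum scale. The spectrum passed in should already carry the
#' hardening of the optics upstream of the sample (G0 and G1); weights are
#' used at their given absolute scale so that flux losses upstream register.
#'
#' @param s a `bct_spectrum` (not renormalized internally).
#' @param mat_breast breast material for \eqn{\mu(E)}.
#' @param t_cm breast diameter in cm.
#' @param alpha,beta opening angles in rad.
#' @return Relative dose (keV-weighted absorbed fraction).
#' @export
dose_proxy <- function(s, mat_breast, t_cm, alpha, beta) {
  stopifnot(t_cm >= 0)
  absorbed <- 1 - exp(-mu(mat_breast, s$energies) * t_cm)
  alpha * beta * sum(s$weights * absorbed * s$energies)
}

#' Detected-intensity proxy behind the sample
#'
#' \eqn{I_D = S_{total}^{-2} \sum_E w(E) e^{-\mu_{breast}(E) t}}: photons
#' surviving the breast, diluted by the inverse square of the total system
#' length. For a grating system the spectrum should carry the G0, G1 and G2
#' transmissions (the beam is further hardened, and attenuated, by G2).
#'
#' @param s a `bct_spectrum` (not renormalized internally).
#' @param mat_breast breast material.
#' @param t_cm breast diameter in cm.
#' @param s_total_m total source-to-G2 length in m.
#' @return Relative detected photon count.
#' @export
detected_intensity <- function(s, mat_breast, t_cm, s_total_m) {
  stopifnot(t_cm >= 0, s_total_m > 0)
  trans <- exp(-mu(mat_breast, s$energies) * t_cm)
  sum(s$weights * trans) / s_total_m^2
}

# silicon height giving a pi phase shift at the design energy
pi_shift_height_um <- function(Ed_keV) {
  lam <- wavelength(Ed_keV)
  d_si <- delta(si_material(), Ed_keV)
  lam / (2 * d_si) * 1e6
}

# silicon with electron density from bulk density (no HUp): 2.33 g/cm3,
# Z/A = 0.4985 -> 6.99e29 m^-3
si_material <- function() {
  m <- bct_material("silicon")
  if (is.na(m$electron_density)) m$electron_density <- 6.99e29
  m
}

#' Full signal budget and CNRD for one design, task and voltage
#'
#' Chains the complete analytic model: tube spectrum, grating transmissions
#' (absorbers G0/G2 as half-open gold combs of height \eqn{h_g}, phase
#' grating G1 as a half-covered silicon comb of pi-shift height), breast
#' hardening, effective contrasts, effective visibility after the sample,
#' dose and detected-intensity proxies, and the metric
#' \deqn{CNRD = \Big(\frac{S_T}{\sigma_T} + \frac{S_\phi}{\sigma_\phi}\Big)
#'       \Big/ Dose^{q},}
#' with both signal terms evaluated with the magnitudes of the effective
#' contrasts. For a gratingless (absorption-only) system the refraction term
#' is zero and no grating transmission or visibility enters.
#'
#' @param geom a `bct_geometry`, or `NULL` for a gratingless system.
#' @param task a `bct_task`.
#' @param kvp acceleration voltage in kV.
#' @param constraints a `bct_constraints`.
#' @param Q visibility quality factor.
#' @param s_total_m total system length override for gratingless systems, m.
#' @param source_to_sample_m source-to-sample override for gratingless
#'   systems, m.
#' @param filter_mm_al aluminium filtration in mm.
#' @param spectrum_fun spectrum generator, by default [generate_spectrum()];
#'   replace to evaluate the budget under an externally supplied spectrum
#'   model.
#' @return Object of class `bct_budget`: all intermediate components plus
#'   `cnrd`.
#' @export
#' @examples
#' g <- solve_geometry(design_point(5.3, 3, 38))
#' b <- signal_budget(g, task_spec(14, 0.25), kvp = 50)
#' b$cnrd
signal_budget <- function(geom, task, kvp, constraints = constraint_set(),
                          Q = 0.65, s_total_m = NULL,
                          source_to_sample_m = NULL, filter_mm_al = 3,
                          spectrum_fun = generate_spectrum) {
  stopifnot(inherits(task, "bct_task"))
  gratingless <- is.null(geom)
  s0 <- spectrum_fun(kvp, filter_mm_al)
  breast <- bct_material("breast")
  matA <- bct_material(task$tissue_pair[1])
  matB <- bct_material(task$tissue_pair[2])
  r_cm <- task$r_mm / 10
  if (gratingless) {
    stopifnot(!is.null(s_total_m), !is.null(source_to_sample_m))
    ang <- opening_angles(task$t_cm, source_to_sample_m)
    dose <- dose_proxy(s0, breast, task$t_cm, ang$alpha, ang$beta)
    i_d <- detected_intensity(s0, breast, task$t_cm, s_total_m)
    weff <- harden(s0, breast, task$t_cm)
    dmu_eff <- sum(weff$weights * (mu(matA, weff$energies) -
                                     mu(matB, weff$energies)))
    st <- sphere_attenuation_signal(r_cm, abs(dmu_eff))
    nt <- noise_terms(i_d, 1)
    cnrd <- (st / nt$sigma_t) / dose^task$dose_exponent
    return(structure(list(
      s_t = st, s_phi = 0, sigma_t = nt$sigma_t, sigma_phi = Inf,
      i_d = i_d, dose = dose, alpha = ang$alpha, beta = ang$beta,
      delta_mu_eff = dmu_eff, delta_delta_eff = 0, v_eff = 0,
      term_attenuation = st / nt$sigma_t, term_refraction = 0,
      kvp = kvp, cnrd = cnrd), class = "bct_budget"))
  }
  stopifnot(inherits(geom, "bct_geometry"))
  au <- bct_material("gold")
  hg <- min_height(geom$Ed_keV)
  h1 <- pi_shift_height_um(geom$Ed_keV)
  E <- s0$energies
  t_g0 <- grating_transmission(E, au, hg)
  t_g1 <- grating_transmission(E, si_material(), h1)
  t_g2 <- grating_transmission(E, au, hg)
  # upstream of the sample: G0 and G1 (inverse geometry)
  w_pre <- s0; w_pre$weights <- s0$weights * t_g0 * t_g1
  ang <- opening_angles(task$t_cm, geom$source_to_sample)
  dose <- dose_proxy(w_pre, breast, task$t_cm, ang$alpha, ang$beta)
  # at the detector: additionally G2
  w_det <- s0; w_det$weights <- w_pre$weights * t_g2
  i_d <- detected_intensity(w_det, breast, task$t_cm, geom$total_length)
  # effective contrasts under the breast-hardened detector spectrum
  weff <- harden(w_det, breast, task$t_cm)
  vis <- visibility_spectrum(geom$Ed_keV, geom$TO, E)
  ec <- effective_contrast(weff, vis, matA, matB)
  v_eff <- effective_visibility(vis, weff, hg, Q = Q)
  st <- sphere_attenuation_signal(r_cm, abs(ec$delta_mu_eff))
  sphi <- sphere_refraction_signal(r_cm, geom$d_sens, geom$p2_um,
                                   abs(ec$delta_delta_eff))
  nt <- noise_terms(i_d, max(v_eff, .Machine$double.eps))
  term_a <- st / nt$sigma_t
  term_r <- sphi / nt$sigma_phi
  structure(list(
    s_t = st, s_phi = sphi, sigma_t = nt$sigma_t, sigma_phi = nt$sigma_phi,
    i_d = i_d, dose = dose, alpha = ang$alpha, beta = ang$beta,
    delta_mu_eff = ec$delta_mu_eff, delta_delta_eff = ec$delta_delta_eff,
    v_eff = v_eff, term_attenuation = term_a, term_refraction = term_r,
    kvp = kvp, cnrd = (term_a + term_r) / dose^task$dose_exponent),
    class = "bct_budget")
}

#' @export
print.bct_budget <- function(x, ...) {
  cat(sprintf(paste0(
    "<bct_budget> %g kVp: CNRD = %.4g\n",
    "  attenuation term %.4g, refraction term %.4g, Veff %.3f\n",
    "  dmu_eff %.4g /cm, ddelta_eff %.3g, dose %.4g, ID %.4g\n"),
    x$kvp, x$cnrd, x$term_attenuation, x$term_refraction, x$v_eff,
    x$delta_mu_eff, x$delta_delta_eff, x$dose, x$i_d))
  invisible(x)
}
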