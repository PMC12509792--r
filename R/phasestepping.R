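# Phase-stepping simulation with Poisson noise, Fourier signal retrieval,
# dose-to-photon budgeting, and the phase-noise floor check.

#' Photon budget for a requested dose
#'
#' Simplified calorimetric calibration: the energy absorbed over the whole
#' scan in the water-equivalent cylinder of diameter t (one detector-row
#' slice high) must equal the requested dose times the slice mass. This
#' fixes the entrance fluence at the rotation-centre plane; detected flat
#' counts per pixel and phase step follow after the mean transmission of
#' the gratings (for the gratingless system no grating loss applies).
#'
#' @param dose_mGy requested mean glandular-equivalent dose in mGy.
#' @param s tube `bct_spectrum` (normalized internally).
#' @param t_cm breast diameter in cm.
#' @param geom a `bct_fan_geometry`.
#' @param n_proj,n_steps projections and phase steps sharing the budget.
#' @param system a `bct_system` (for the grating transmissions); `NULL`
#'   for a bare beam.
#' @return List: `counts_per_step` (mean detected flat counts per detector
#'   pixel per step), `entrance_per_pixel` (photons per rotation-centre
#'   pixel per projection-step before the sample), `fluence_cm2`.
#' @export
photons_for_dose <- function(dose_mGy, s, t_cm, geom, n_proj,
                             n_steps = 1, system = NULL) {
  stopifnot(dose_mGy > 0, t_cm > 0)
  w <- s$weights / sum(s$weights)
  E <- s$energies
  water <- bct_material("water")
  keV_J <- 1.602176634e-16
  absorbed_keV <- sum(w * (1 - exp(-mu(water, E) * t_cm)) * E)
  h <- geom$iso_pixel_cm                       # slice height, cm
  mass_kg <- 1.0 * pi * (t_cm / 2)^2 * h * 1e-3  # water density 1 g/cm3
  # dose [Gy] = n_exposures * fluence * (t*h) * absorbed_E / mass
  n_exp <- n_proj * n_steps
  fluence <- dose_mGy * 1e-3 * mass_kg /
    (n_exp * t_cm * h * absorbed_keV * keV_J)  # photons/cm2 per exposure
  entrance <- fluence * geom$iso_pixel_cm * h  # per iso-pixel area
  t_grating <- 1
  if (!is.null(system) && !system$gratingless) {
    au <- bct_material("gold")
    hg <- min_height(system$geometry$Ed_keV)
    h1 <- pi_shift_height_um(system$geometry$Ed_keV)
    t_grating <- sum(w * grating_transmission(E, au, hg)^2 *
                       grating_transmission(E, si_material(), h1))
  }
  list(counts_per_step = entrance * t_grating,
       entrance_per_pixel = entrance, fluence_cm2 = fluence)
}

#' Simulate phase-stepping curves with Poisson noise
#'
#' Models the stepped intensity
#' \eqn{I_k = P_\mu\,\bar c\,(1 + V D_{\delta''} \cos(P_\delta + 2\pi k/N))}
#' per detector pixel, projection and step, and draws Poisson counts.
#'
#' @param sinos a `bct_sinograms` (grating system).
#' @param counts_per_step mean flat counts per pixel per step.
#' @param n_steps number of phase steps N (at least 3).
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @param poisson draw Poisson noise (`TRUE`) or return expected counts.
#' @return Object of class `bct_psc`: `counts` array
#'   `[n_det, n_proj, n_steps]`, `counts_per_step`, `n_steps`, and the
#'   noiseless flat-field parameters.
#' @export
simulate_phase_stepping <- function(sinos, counts_per_step, n_steps = 5,
                                    seed = NULL, poisson = TRUE) {
  stopifnot(n_steps >= 3)
  Pmu <- sinos$transmission
  Pdelta <- if (is.null(sinos$dpc)) array(0, dim(Pmu)) else sinos$dpc
  V <- if (is.null(sinos$visibility)) array(0, dim(Pmu)) else
    sinos$visibility
  red <- if (is.null(sinos$reduction)) 1 else sinos$reduction
  if (any(V * red > 1 + 1e-9)) stop("modulation amplitude exceeds 1")
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
  }
  dims <- c(dim(Pmu), n_steps)
  counts <- array(0, dims)
  for (k in seq_len(n_steps)) {
    expected <- Pmu * counts_per_step *
      (1 + V * red * cos(Pdelta + 2 * pi * (k - 1) / n_steps))
    counts[, , k] <- if (poisson) {
      array(stats::rpois(length(expected), expected), dim(expected))
    } else expected
  }
  structure(list(counts = counts, counts_per_step = counts_per_step,
                 n_steps = n_steps,
                 flat_visibility = sinos$visibility),
            class = "bct_psc")
}

#' Retrieve transmission, phase and visibility from phase-stepping curves
#'
#' Discrete Fourier analysis over the step index: the mean gives the
#' transmission (normalized by the flat-field mean), the first harmonic
#' gives phase and visibility. The phase convention is fixed so that
#' retrieval inverts [simulate_phase_stepping()] exactly on noiseless
#' input; phases are reported in (-pi, pi].
#'
#' @param psc a `bct_psc`.
#' @param flat_counts_per_step flat-field mean counts per step used for
#'   normalization (defaults to the stored value).
#' @return List of matrices `transmission`, `dpc`, `visibility`.
#' @export
retrieve <- function(psc, flat_counts_per_step = NULL) {
  N <- psc$n_steps
  if (is.null(flat_counts_per_step)) flat_counts_per_step <-
    psc$counts_per_step
  ph <- 2 * pi * (seq_len(N) - 1) / N
  a0 <- apply(psc$counts, c(1, 2), mean)
  re <- im <- matrix(0, dim(psc$counts)[1], dim(psc$counts)[2])
  for (k in seq_len(N)) {
    re <- re + psc$counts[, , k] * cos(ph[k])
    im <- im - psc$counts[, , k] * sin(ph[k])
  }
  a1 <- complex(real = re, imaginary = im) / N
  a1 <- matrix(a1, nrow(a0), ncol(a0))
  if (any(a0 <= 0)) {
    # zero-count pixels carry no information; phase undefined -> 0
    bad <- a0 <= 0
    a0[bad] <- .Machine$double.eps
  }
  dpc <- Arg(a1)
  dpc[dpc <= -pi] <- pi
  list(transmission = a0 / flat_counts_per_step,
       dpc = dpc,
       visibility = 2 * Mod(a1) / a0)
}

#' Phase-noise floor check
#'
#' At vanishing counts the retrieved phase is uniform on (-pi, pi] with
#' standard deviation \eqn{\pi/\sqrt 3}; reliable retrieval requires the
#' predicted phase noise \eqn{\sigma_\phi = 1/(V\sqrt{N \bar c})} to stay
#' at or below the empirical threshold \eqn{(\pi/\sqrt 3)/2.5}.
#'
#' @param v_eff effective visibility.
#' @param counts_per_step mean counts per pixel per step.
#' @param n_steps number of phase steps.
#' @return `TRUE` if the phase-noise floor is respected (inclusive).
#' @export
phase_noise_floor_ok <- function(v_eff, counts_per_step, n_steps) {
  total <- n_steps * counts_per_step
  if (total <= 0 || v_eff <= 0) return(FALSE)
  sigma_phi <- 1 / (v_eff * sqrt(total))
  sigma_phi <= (pi / sqrt(3)) / 2.5
}
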