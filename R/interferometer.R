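# Talbot-Lau geometry solver, manufacturability constraints, analytic
# visibility spectrum, and effective visibility.
#
# Inverse geometry: the finest pitch p0 sits at the source grating G0, the
# sample is downstream of the pi-shifting phase grating G1, and the analyzer
# G2 sits in front of the detector. G0 and G2 are gold absorption gratings
# of equal height; G1 is a silicon phase grating.

#' Design point of the grid search
#'
#' @param p0_um G0 pitch in micrometres.
#' @param TO Talbot order, odd (1, 3, 5 or 7).
#' @param Ed_keV design energy in keV.
#' @param kvp acceleration voltage in kV (optional at geometry stage).
#' @return Object of class `bct_design`.
#' @export
design_point <- function(p0_um, TO, Ed_keV, kvp = NA_real_) {
  stopifnot(p0_um > 0, TO %% 2 == 1, Ed_keV > 0)
  structure(list(p0_um = p0_um, TO = TO, Ed_keV = Ed_keV, kvp = kvp),
            class = "bct_design")
}

#' Constraint set for feasibility checks
#'
#' Defaults: gold-lamella aspect ratio (height over half pitch) at most 50,
#' total system length (source to G2) at most 1.45 m, source-G0 distance
#' 0.15 m, field of view 0.20 m.
#'
#' @param ar_max maximum aspect ratio.
#' @param total_length_max maximum source-to-G2 length in m.
#' @param source_g0 source-to-G0 distance in m.
#' @param fov field of view in m; the rotation centre sits `fov/2`
#'   downstream of G1 so a full-FOV sample clears the grating.
#' @return Object of class `bct_constraints`.
#' @export
constraint_set <- function(ar_max = 50, total_length_max = 1.45,
                           source_g0 = 0.15, fov = 0.20) {
  stopifnot(ar_max > 0, total_length_max > 0, source_g0 >= 0, fov > 0)
  structure(list(ar_max = ar_max, total_length_max = total_length_max,
                 source_g0 = source_g0, fov = fov),
            class = "bct_constraints")
}

#' G0-G1 distance of the symmetric Talbot-Lau solution
#'
#' At \eqn{L = TO\,p_0^2/(4\lambda)} the interferometer is symmetric:
#' \eqn{D = L}, \eqn{S = 2L} and all three pitches are equal.
#'
#' @param p0_um G0 pitch in micrometres.
#' @param TO Talbot order.
#' @param Ed_keV design energy in keV.
#' @return L in metres.
#' @export
symmetric_length <- function(p0_um, TO, Ed_keV) {
  TO * (p0_um * 1e-6)^2 / (4 * wavelength(Ed_keV))
}

#' Solve the Talbot-Lau geometry
#'
#' Given the G0 pitch, the G0-G1 distance L, the Talbot order and the design
#' energy, the remaining interferometer parameters follow from the
#' fractional-Talbot condition:
#' \deqn{S = \frac{L \cdot TO \cdot p_0^2}{TO \cdot p_0^2 - 2\lambda L},
#'       \quad D = S - L, \quad p_1 = 2 D p_0 / S, \quad p_2 = p_0 D / L.}
#'
#' @param dp a `bct_design`.
#' @param L_m G0-G1 distance in metres; defaults to the symmetric solution.
#' @param constraints a `bct_constraints` (supplies source-G0 distance and
#'   the rotation-centre offset fov/2).
#' @return Object of class `bct_geometry` with pitches (um), distances (m),
#'   the design wavelength, the total length, the source-to-rotation-centre
#'   distance and the rotation-centre-to-G2 distance `d_sens`.
#' @export
#' @examples
#' g <- solve_geometry(design_point(5.3, 3, 38))
#' round(100 * g$source_to_sample, 1)  # 89.6 cm
#' round(100 * g$d_sens, 1)            # 54.6 cm
solve_geometry <- function(dp, L_m = NULL, constraints = constraint_set()) {
  stopifnot(inherits(dp, "bct_design"))
  if (is.null(L_m)) L_m <- symmetric_length(dp$p0_um, dp$TO, dp$Ed_keV)
  lam <- wavelength(dp$Ed_keV)
  p0 <- dp$p0_um * 1e-6
  den <- dp$TO * p0^2 - 2 * lam * L_m
  if (den <= 0) {
    stop("infeasible geometry: L at or beyond the Talbot asymptote")
  }
  S <- L_m * dp$TO * p0^2 / den
  D <- S - L_m
  off <- constraints$fov / 2
  d_sens <- D - off
  if (d_sens <= 0) stop("rotation centre would sit behind G2")
  structure(list(
    p0_um = dp$p0_um, p1_um = 2 * D * dp$p0_um / S, p2_um = dp$p0_um * D / L_m,
    L = L_m, D = D, S = S, lambda_d = lam, Ed_keV = dp$Ed_keV, TO = dp$TO,
    source_g0 = constraints$source_g0,
    total_length = constraints$source_g0 + S,
    sample_offset = off,
    source_to_sample = constraints$source_g0 + L_m + off,
    d_sens = d_sens), class = "bct_geometry")
}

#' @export
print.bct_geometry <- function(x, ...) {
  cat(sprintf(paste0(
    "<bct_geometry> TO %d @ %g keV\n",
    "  pitches p0/p1/p2: %.3f / %.3f / %.3f um\n",
    "  L %.4f m, D %.4f m, S %.4f m (total %.4f m)\n",
    "  source-sample %.4f m, sample-G2 %.4f m\n"),
    x$TO, x$Ed_keV, x$p0_um, x$p1_um, x$p2_um, x$L, x$D, x$S,
    x$total_length, x$source_to_sample, x$d_sens))
  invisible(x)
}

#' Minimum absorption-grating height
#'
#' Height of a gold lamella attenuating the design energy by a factor
#' \eqn{e^{-3}}, i.e. \eqn{h_g = 3/\mu_{Au}(E_d)}: at least 95% photon
#' absorption, so the interference pattern is not degraded by grating
#' transparency.
#'
#' @param Ed_keV design energy in keV.
#' @return Height in micrometres.
#' @export
min_height <- function(Ed_keV) {
  3 / mu(bct_material("gold"), Ed_keV) * 1e4
}

#' Check a design against the manufacturing and length constraints
#'
#' Gates, in the order of the search flowchart: the gold height
#' \eqn{h_g = 3/\mu_{Au}(E_d)} must respect the aspect-ratio cap at the G0
#' pitch; the geometry must solve (L below the Talbot asymptote); the G2
#' pitch must also respect the aspect-ratio cap and, for the inverse
#' geometry, must not be finer than p0; and the total length must stay
#' within the cap.
#'
#' @param dp a `bct_design`.
#' @param L_m G0-G1 distance in metres (default symmetric).
#' @param constraints a `bct_constraints`.
#' @param check_g2 also gate on the analyzer grating (aspect ratio at p2 and
#'   p2 >= p0); `TRUE` by default.
#' @return Data frame with one row per gate (`constraint`, `pass`) and
#'   attribute `feasible` (all gates passed), also returned by
#'   `attr(, "feasible")`.
#' @export
feasible <- function(dp, L_m = NULL, constraints = constraint_set(),
                     check_g2 = TRUE) {
  hg <- min_height(dp$Ed_keV)
  ar_g0 <- hg <= constraints$ar_max * dp$p0_um / 2
  geom <- tryCatch(solve_geometry(dp, L_m, constraints),
                   error = function(e) NULL)
  solvable <- !is.null(geom)
  ar_g2 <- solvable && hg <= constraints$ar_max * geom$p2_um / 2
  pitch_order <- solvable && geom$p2_um >= dp$p0_um - 1e-12
  len <- solvable && geom$total_length <= constraints$total_length_max + 1e-12
  rows <- data.frame(
    constraint = c("ar_g0", "geometry_solvable", "ar_g2", "pitch_order",
                   "total_length"),
    pass = c(ar_g0, solvable, ar_g2, pitch_order, len))
  if (!check_g2) rows <- rows[!rows$constraint %in% c("ar_g2", "pitch_order"), ]
  attr(rows, "feasible") <- all(rows$pass)
  attr(rows, "geometry") <- geom
  rows
}

#' Analytic visibility spectrum of a Talbot-Lau interferometer
#'
#' Upper-limit visibility of an ideal pi-shifting interferometer with
#' rectangular 50% duty-cycle gratings:
#' \deqn{V(E) = \frac{2}{\pi}\sin^2\!\Big(\frac{\pi E_d}{2E}\Big)
#'       \Big|\sin\!\Big(\frac{\pi\,TO\,E_d}{2E}\Big)\Big|,}
#' clipped to \eqn{[0, 2/\pi]}. At the design energy V equals \eqn{2/\pi}
#' for any odd Talbot order.
#'
#' @param Ed_keV design energy in keV.
#' @param TO odd Talbot order.
#' @param energies evaluation grid in keV.
#' @return Visibility values in `[0, 2/pi]`.
#' @export
visibility_spectrum <- function(Ed_keV, TO, energies) {
  stopifnot(TO %% 2 == 1)
  v <- (2 / pi) * sin(pi * Ed_keV / (2 * energies))^2 *
    abs(sin(pi * TO * Ed_keV / (2 * energies)))
  pmin(pmax(v, 0), 2 / pi)
}

#' Effective visibility under a polychromatic spectrum
#'
#' Spectrum-weighted visibility with the finite-grating-height transmission
#' penalty and an empirical quality factor:
#' \deqn{V_{eff} = Q \sum_E V(E)\, w_N(E)\, (1 - e^{-\mu_{Au}(E) h_g})^2.}
#' The squared term reflects the two absorption gratings (G0 and G2); Q
#' folds in grating imperfections relative to the analytic upper limit.
#'
#' @param vis visibility-vs-energy (from [visibility_spectrum()]).
#' @param s a normalized `bct_spectrum` (with or without sample hardening).
#' @param hg_um absorption-grating height in micrometres.
#' @param Q quality factor in (0, 1]; default 0.65.
#' @return Effective visibility (dimensionless).
#' @export
#' @examples
#' s <- generate_spectrum(50, 3)
#' v <- visibility_spectrum(38, 3, s$energies)
#' effective_visibility(v, s, min_height(38))  # ~0.2 for the default model
effective_visibility <- function(vis, s, hg_um, Q = 0.65) {
  stopifnot(length(vis) == length(s$energies), Q > 0, Q <= 1)
  w <- s$weights / sum(s$weights)
  pen <- (1 - exp(-mu(bct_material("gold"), s$energies) * hg_um * 1e-4))^2
  Q * sum(vis * w * pen)
}
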