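# Exhaustive enumeration of the constrained design space, best-design-per-
# voltage curves, and the pinned benchmark systems.

#' Design-space definition for the grid search
#'
#' Defaults: G0 pitch 3-10 um in 0.1 um steps, G0-G1 distance 10-100 cm in
#' 500 um steps, design energy 20-46 keV in 1 keV steps, Talbot orders
#' {1, 3, 5, 7}, acceleration voltage 25-70 kV in 1 kV steps. Grids are
#' generated by integer index to avoid floating-point accumulation.
#'
#' @param p0_um,L_m,Ed_keV,TO,kvp grid vectors.
#' @return Object of class `bct_space`.
#' @export
search_space <- function(p0_um = 3 + (0:70) * 0.1,
                         L_m = 0.10 + (0:1800) * 5e-4,
                         Ed_keV = 20:46,
                         TO = c(1, 3, 5, 7),
                         kvp = 25:70) {
  stopifnot(all(p0_um > 0), all(L_m > 0), all(Ed_keV > 0),
            all(TO %% 2 == 1))
  structure(list(p0_um = p0_um, L_m = L_m, Ed_keV = Ed_keV, TO = TO,
                 kvp = kvp), class = "bct_space")
}

# analytic feasible-L window for one (Ed, p0, TO):
# S = a L / (a - L) with a = TO p0^2 / (2 lambda); the length cap S <= M
# gives L <= M a/(a+M); the analyzer gates demand D/L >= c, i.e.
# L >= c a/(1+c), with c = max(1, 2 hg / (ar_max p0)) when G2 is checked.
feasible_L_window <- function(p0_um, TO, Ed_keV, constraints, check_g2) {
  a <- TO * (p0_um * 1e-6)^2 / (2 * wavelength(Ed_keV))
  M <- constraints$total_length_max - constraints$source_g0
  hi <- M * a / (a + M)
  lo <- 0
  if (check_g2) {
    hg <- min_height(Ed_keV)
    cc <- pmax(1, (2 * hg / constraints$ar_max) / p0_um)
    lo <- a * cc / (1 + cc)
  }
  list(lo = lo, hi = hi, a = a)
}

#' Enumerate the feasible design space
#'
#' Walks the search grid in the flowchart order (design energy, then pitch
#' under the height/aspect-ratio gate, then geometry under the length gate)
#' and returns every surviving design, deterministically ordered by
#' (Ed, p0, TO).
#'
#' Two counting modes exist because the space contains a free length
#' parameter: `"per_design"` keeps, for each feasible (Ed, p0, TO), the
#' single sensitivity-maximizing G0-G1 distance on the L grid (sensitivity
#' d/p2 grows monotonically with L, so this is the largest feasible L);
#' `"per_tuple"` counts every feasible (Ed, p0, TO, L) grid tuple. Use
#' [count_feasible()] for the counts alone.
#'
#' @param space a `bct_space`.
#' @param constraints a `bct_constraints`.
#' @param mode `"per_design"` (default) or `"per_tuple"` (the latter only
#'   affects the reported `n_L` column; one row per design is returned
#'   either way).
#' @param check_g2 gate on the analyzer grating as well (aspect ratio at p2
#'   and p2 >= p0, the inverse-geometry pitch ordering); default `TRUE`.
#' @return Data frame with one row per feasible design: grid coordinates,
#'   solved geometry columns, the gold height `hg_um`, sensitivity
#'   `d_over_p2`, and `n_L` (number of feasible L grid points).
#' @export
enumerate_feasible <- function(space, constraints = constraint_set(),
                               mode = c("per_design", "per_tuple"),
                               check_g2 = TRUE) {
  mode <- match.arg(mode)
  grid <- expand.grid(TO = space$TO, p0_um = space$p0_um,
                      Ed_keV = space$Ed_keV, KEEP.OUT.ATTRS = FALSE)
  # order: Ed, then p0, then TO
  grid <- grid[order(grid$Ed_keV, grid$p0_um, grid$TO), ]
  hg <- min_height(grid$Ed_keV)
  ar_ok <- hg <= constraints$ar_max * grid$p0_um / 2
  win <- feasible_L_window(grid$p0_um, grid$TO, grid$Ed_keV, constraints,
                           check_g2)
  L_min <- min(space$L_m); L_max <- max(space$L_m)
  step <- if (length(space$L_m) > 1) space$L_m[2] - space$L_m[1] else 0
  lo <- pmax(win$lo, L_min)
  hi <- pmin(win$hi, L_max)
  if (step > 0) {
    i_lo <- ceiling((lo - L_min) / step - 1e-9)
    i_hi <- floor((hi - L_min) / step + 1e-9)
    n_L <- pmax(i_hi - i_lo + 1, 0)
    L_best <- L_min + i_hi * step
  } else {
    n_L <- as.integer(lo <= L_min & L_min <= hi)
    L_best <- rep(L_min, nrow(grid))
  }
  keep <- ar_ok & n_L > 0
  out <- grid[keep, , drop = FALSE]
  out$hg_um <- hg[keep]
  out$L_m <- L_best[keep]
  out$n_L <- n_L[keep]
  a <- if (length(win$a) == 1) rep(win$a, sum(keep)) else win$a[keep]
  out$S_m <- a * out$L_m / (a - out$L_m)
  out$D_m <- out$S_m - out$L_m
  out$p1_um <- 2 * out$D_m * out$p0_um / out$S_m
  out$p2_um <- out$p0_um * out$D_m / out$L_m
  out$total_length_m <- constraints$source_g0 + out$S_m
  out$source_to_sample_m <- constraints$source_g0 + out$L_m +
    constraints$fov / 2
  out$d_sens_m <- out$D_m - constraints$fov / 2
  out$d_over_p2 <- out$d_sens_m / (out$p2_um * 1e-6)
  ok <- out$d_sens_m > 0
  out <- out[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "mode") <- mode
  out
}

#' Count feasible combinations in the design space
#'
#' @inheritParams enumerate_feasible
#' @return Integer count: number of feasible designs (`per_design`) or of
#'   feasible (Ed, p0, TO, L) grid tuples (`per_tuple`).
#' @export
count_feasible <- function(space, constraints = constraint_set(),
                           mode = c("per_design", "per_tuple"),
                           check_g2 = TRUE) {
  mode <- match.arg(mode)
  res <- enumerate_feasible(space, constraints, mode, check_g2)
  if (mode == "per_design") nrow(res) else sum(res$n_L)
}

#' CNRD of every feasible design at every acceleration voltage
#'
#' Vectorized evaluation of the full signal budget across the design table,
#' caching all per-(Ed, TO) spectral integrals. Used by
#' [best_per_voltage()].
#'
#' @param designs data frame from [enumerate_feasible()].
#' @param task a `bct_task`.
#' @param kvps voltages to evaluate (kV).
#' @param constraints a `bct_constraints`.
#' @param Q visibility quality factor.
#' @param filter_mm_al aluminium filtration in mm.
#' @return Matrix `[design, kvp]` of CNRD values.
#' @export
cnrd_matrix <- function(designs, task, kvps = 25:70,
                        constraints = constraint_set(), Q = 0.65,
                        filter_mm_al = 3) {
  stopifnot(nrow(designs) > 0, inherits(task, "bct_task"))
  E <- seq(8, max(kvps))
  nE <- length(E)
  W <- vapply(kvps, function(v) {
    s <- generate_spectrum(v, filter_mm_al)
    w <- numeric(nE)
    idx <- match(s$energies, E)
    w[idx[!is.na(idx)]] <- s$weights[!is.na(idx)]
    w
  }, numeric(nE))
  au <- bct_material("gold"); br <- bct_material("breast")
  matA <- bct_material(task$tissue_pair[1])
  matB <- bct_material(task$tissue_pair[2])
  mu_au <- mu(au, E); mu_br <- mu(br, E)
  dmu <- mu(matA, E) - mu(matB, E)
  ddel <- delta(matA, E) - delta(matB, E)
  B <- exp(-mu_br * task$t_cm)
  r_cm <- task$r_mm / 10
  q <- task$dose_exponent
  cache <- new.env(parent = emptyenv())
  out <- matrix(NA_real_, nrow(designs), length(kvps))
  for (i in seq_len(nrow(designs))) {
    d <- designs[i, ]
    key <- paste(d$Ed_keV, d$TO)
    if (is.null(cache[[key]])) {
      hg <- d$hg_um
      t_abs <- grating_transmission(E, au, hg)
      t_ph <- grating_transmission(E, si_material(),
                                   pi_shift_height_um(d$Ed_keV))
      pen <- (1 - exp(-mu_au * hg * 1e-4))^2
      V <- visibility_spectrum(d$Ed_keV, d$TO, E)
      Wpre <- W * (t_abs * t_ph)
      Wdet <- Wpre * t_abs
      dose_core <- colSums(Wpre * (1 - B) * E)
      weffU <- Wdet * B                    # unnormalized detector spectrum
      det_core <- colSums(weffU)
      dmu_eff <- colSums(weffU * dmu) / det_core
      wv <- weffU * V
      den <- colSums(wv)
      ddel_eff <- colSums(wv * ddel) / den
      veff <- Q * colSums(wv * pen) / det_core
      cache[[key]] <- list(dose_core = dose_core, det_core = det_core,
                           dmu_eff = dmu_eff, ddel_eff = ddel_eff,
                           veff = veff)
    }
    cc <- cache[[key]]
    alpha <- 2 * asin((task$t_cm / 200) / d$source_to_sample_m)
    dose <- alpha * 0.1 * cc$dose_core
    i_d <- cc$det_core / d$total_length_m^2
    st <- sphere_attenuation_signal(r_cm, abs(cc$dmu_eff))
    sphi <- sphere_refraction_signal(r_cm, d$d_sens_m, d$p2_um,
                                     abs(cc$ddel_eff))
    out[i, ] <- (st * sqrt(i_d) + sphi * sqrt(i_d) * cc$veff) / dose^q
  }
  colnames(out) <- kvps
  out
}

#' Best design at each acceleration voltage
#'
#' For every voltage, the CNRD-maximizing feasible design. Ties are broken
#' deterministically towards smaller design energy, then smaller pitch,
#' then shorter system (the iteration order of the design table).
#'
#' @param designs data frame from [enumerate_feasible()].
#' @param task a `bct_task`.
#' @param kvps voltages (kV).
#' @param ... passed to [cnrd_matrix()].
#' @return Data frame with one row per voltage: `kvp`, `cnrd`, and the
#'   argmax design columns.
#' @export
best_per_voltage <- function(designs, task, kvps = 25:70, ...) {
  cm <- cnrd_matrix(designs, task, kvps, ...)
  idx <- apply(cm, 2, which.max)
  res <- designs[idx, , drop = FALSE]
  res$kvp <- kvps
  res$cnrd <- cm[cbind(idx, seq_along(kvps))]
  rownames(res) <- NULL
  res[, c("kvp", "cnrd", setdiff(names(res), c("kvp", "cnrd")))]
}

#' Benchmark system fixtures
#'
#' The three systems compared in the simulation study, as pinned
#' configurations: the grid-search-optimized GI-BCT (symmetric geometry,
#' 5.3 um pitches, third Talbot order, 38 keV design energy, 50 kVp), the
#' earlier Optica-2023 interferometer (4.2 um pitches, fifth order, 46 keV,
#' 70 kVp, longer geometry), and the commercial absorption-only AB-CT
#' scanner (no gratings, 60 kVp, 65 cm total length). The gratingless
#' system carries no visibility and no analyzer dose penalty.
#'
#' @return Named list of `bct_system` objects with elements `name`,
#'   `geometry` (`NULL` for the gratingless system), `kvp`, `Q`,
#'   `veff_nominal`, `gratingless`, `source_to_sample`, `d_sens`,
#'   `total_length` (m), `det_pixel_mm`, `n_proj`.
#' @export
benchmark_systems <- function() {
  cs <- constraint_set()
  gi_geom <- solve_geometry(design_point(5.3, 3, 38), constraints = cs)
  optica <- structure(list(
    p0_um = 4.2, p1_um = 4.2, p2_um = 4.2,
    L = 0.768, D = 0.818, S = 1.586, lambda_d = wavelength(46),
    Ed_keV = 46, TO = 5, source_g0 = 0.15, total_length = 1.736,
    sample_offset = 0.10, source_to_sample = 1.018, d_sens = 0.718),
    class = "bct_geometry")
  sys <- function(name, geometry, kvp, veff, gratingless = FALSE,
                  source_to_sample = NULL, d_sens = NULL,
                  total_length = NULL) {
    structure(list(
      name = name, geometry = geometry, kvp = kvp, Q = 0.65,
      veff_nominal = veff, gratingless = gratingless,
      source_to_sample = if (is.null(geometry)) source_to_sample
                         else geometry$source_to_sample,
      d_sens = if (is.null(geometry)) d_sens else geometry$d_sens,
      total_length = if (is.null(geometry)) total_length
                     else geometry$total_length,
      det_pixel_mm = 0.2, n_proj = 1000), class = "bct_system")
  }
  list(
    gi_bct = sys("GI-BCT", gi_geom, 50, 0.23),
    optica_2023 = sys("Optica-2023", optica, 70, 0.10),
    ab_ct = sys("AB-CT", NULL, 60, NA_real_, gratingless = TRUE,
                source_to_sample = 0.50, d_sens = 0.15,
                total_length = 0.65))
}

#' @export
print.bct_system <- function(x, ...) {
  cat(sprintf("<bct_system> %s: %g kVp, source-sample %.3f m%s\n",
              x$name, x$kvp, x$source_to_sample,
              if (x$gratingless) " (no gratings)"
              else sprintf(", TO %d @ %g keV, Veff %.0f%%",
                           x$geometry$TO, x$geometry$Ed_keV,
                           100 * x$veff_nominal)))
  invisible(x)
}
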