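# forward projection, phase stepping, retrieval, photon budgeting

test_that("projection of an empty phantom is the identity signal", {
  ph <- empty_phantom()
  geom <- test_geometry(det_pixel_mm = 0.8, n_proj = 8)
  path <- project_pathlengths(ph, geom)
  expect_true(all(path == 0))
  s <- mono_spectrum(30)
  expect_true(all(project_attenuation(path, ph$materials, s) == 1))
  pr <- project_refraction(path, ph$materials, s, geom, 38, 3, 5.3,
                           min_height(38))
  expect_true(all(pr$dpc == 0))
})

test_that("disc transmission matches the analytic chord formula", {
  ph <- disc_phantom("water", 6, 0.125)
  geom <- test_geometry(det_pixel_mm = 0.4, n_proj = 4)
  path <- project_pathlengths(ph, geom, step_factor = 0.25)
  s <- mono_spectrum(38)
  trans <- project_attenuation(path, ph$materials, s)
  muw <- mu(bct_material("water"), 38)
  # compare against exact fan-ray chords through a 3 cm-radius disc
  u <- (seq_len(geom$n_det) - (geom$n_det + 1) / 2) * geom$det_pixel_cm
  R <- geom$R_s; Rsd <- geom$R_sd
  sin_t <- abs(u) / sqrt(Rsd^2 + u^2)
  h <- R * sin_t                 # distance of the ray from the centre
  inside <- h < 2.8
  chord <- 2 * sqrt(pmax(3^2 - h^2, 0))
  expect_lt(max(abs(trans[inside, 1] - exp(-muw * chord[inside]))), 5e-3)
})

test_that("polychromatic transmission exceeds the mean-energy value", {
  ph <- disc_phantom("water", 6, 0.5)
  geom <- test_geometry(det_pixel_mm = 0.8, n_proj = 2)
  path <- project_pathlengths(ph, geom)
  s <- generate_spectrum(50, 3)
  poly <- project_attenuation(path, ph$materials, s)
  ctr <- (geom$n_det + 1) / 2
  # Jensen: the polychromatic transmission strictly exceeds Beer-Lambert
  # at the spectrum-weighted attenuation coefficient over the same path
  mubar <- sum(s$weights * mu(bct_material("water"), s$energies))
  expect_gt(poly[ctr, 1], exp(-mubar * path[ctr, 1, 1]))
})

test_that("dpc projection is antisymmetric and exact when monochromatic", {
  ph <- disc_phantom("water", 4, 0.25)
  geom <- test_geometry(det_pixel_mm = 0.4, n_proj = 2)
  path <- project_pathlengths(ph, geom, step_factor = 0.25)
  s <- mono_spectrum(38)
  pr <- project_refraction(path, ph$materials, s, geom, 38, 3, 5.3,
                           min_height(38))
  # monochromatic: the phasor argument equals the single-energy phase
  de <- delta(bct_material("water"), 38)
  dint <- path[, 1, 1] * de
  grad <- c(0, diff(dint, lag = 2) / (2 * geom$iso_pixel_cm), 0)
  phi <- 2 * pi * (geom$R_d / 100) / (5.3e-6) * grad
  mid <- 10:(geom$n_det - 10)
  expect_equal(pr$dpc[mid, 1], phi[mid], tolerance = 1e-9)
  # odd profile across the disc centre
  d <- pr$dpc[, 1]
  expect_lt(max(abs(d + rev(d))), 1e-8)
})

test_that("resolution-matching blur shrinks edge amplitude only", {
  ph <- disc_phantom("water", 4, 0.25)
  geom <- test_geometry(det_pixel_mm = 0.4, n_proj = 2)
  path <- project_pathlengths(ph, geom, step_factor = 0.25)
  pr <- project_refraction(path, ph$materials, mono_spectrum(38), geom,
                           38, 3, 5.3, min_height(38))
  expect_equal(mtf_matching_blur(pr$dpc, 0), pr$dpc)
  amp <- vapply(c(0, 1, 2, 4), function(f)
    max(abs(mtf_matching_blur(pr$dpc, f)[, 1])), numeric(1))
  expect_true(all(diff(amp) < 0))
  # antisymmetry (zero at the centre) survives blurring
  b <- mtf_matching_blur(pr$dpc, 2)[, 1]
  expect_lt(max(abs(b + rev(b))), 1e-8)
})

test_that("visibility reduction dips only where phase curvature lives", {
  flat <- matrix(0.3, 64, 2)
  expect_true(all(visibility_reduction(flat) == 1))
  edge <- matrix(0, 64, 1); edge[33:64, ] <- 1
  red <- visibility_reduction(edge, c_r = 1)
  expect_lt(min(red), 0.9)
  expect_equal(red[10, 1], 1)
  expect_true(all(visibility_reduction(edge, c_r = 0) == 1))
})

test_that("photon budget is linear in dose and penalized by gratings", {
  geom <- test_geometry()
  s <- generate_spectrum(50, 3)
  b1 <- photons_for_dose(10, s, 12, geom, 320, 5, benchmark_systems()$gi_bct)
  b2 <- photons_for_dose(20, s, 12, geom, 320, 5, benchmark_systems()$gi_bct)
  expect_equal(b2$counts_per_step / b1$counts_per_step, 2, tolerance = 1e-12)
  # the gratingless system detects more photons at equal dose
  ab <- photons_for_dose(10, generate_spectrum(60, 3), 12, geom, 320, 5,
                         benchmark_systems()$ab_ct)
  expect_gt(ab$counts_per_step / ab$entrance_per_pixel,
            b1$counts_per_step / b1$entrance_per_pixel)
  # at fixed entrance fluence, transmitted counts fall with diameter
  w <- bct_material("water")
  trans <- vapply(c(9, 12, 18), function(t)
    sum(s$weights * exp(-mu(w, s$energies) * t)), numeric(1))
  expect_true(all(diff(trans) < 0))
})

test_that("phase stepping conserves flux and retrieval inverts it", {
  sin1 <- psc_inputs(4, trans = 0.5, dpc = 0.3, vis = 0.2)
  for (N in c(3, 4, 5, 8)) {
    psc <- simulate_phase_stepping(sin1, 1e4, N, poisson = FALSE)
    # the cosine averages out over a full period
    expect_equal(apply(psc$counts, c(1, 2), mean),
                 matrix(0.5 * 1e4, 4, 1), tolerance = 1e-10)
    r <- retrieve(psc)
    expect_equal(r$transmission, matrix(0.5, 4, 1), tolerance = 1e-12)
    expect_equal(r$dpc, matrix(0.3, 4, 1), tolerance = 1e-12)
    expect_equal(r$visibility, matrix(0.2, 4, 1), tolerance = 1e-12)
  }
  # V = 0 gives a flat curve
  psc0 <- simulate_phase_stepping(psc_inputs(2, vis = 0), 1e3, 5,
                                  poisson = FALSE)
  expect_equal(psc0$counts[, , 1], psc0$counts[, , 3], tolerance = 1e-12)
  # phase pi stays pi under the wrap convention
  pscpi <- simulate_phase_stepping(psc_inputs(2, dpc = pi), 1e4, 5,
                                   poisson = FALSE)
  expect_equal(retrieve(pscpi)$dpc[1, 1], pi, tolerance = 1e-9)
})

test_that("Poisson sampling matches the analytic mean", {
  n <- 4000
  psc <- simulate_phase_stepping(psc_inputs(n, trans = 0.8, dpc = 0.4,
                                            vis = 0.25), 500, 5, seed = 9)
  exp_k1 <- 0.8 * 500 * (1 + 0.25 * cos(0.4))
  m <- mean(psc$counts[, , 1])
  expect_lt(abs(m - exp_k1), 3 * sqrt(exp_k1 / n))
})

test_that("retrieved phase noise scales as 1/(V sqrt I) then saturates", {
  n <- 1e4
  # counting regime: sd = sqrt(2)/(V sqrt(N c)) from first-harmonic
  # perturbation
  cps <- 3000
  r <- retrieve(simulate_phase_stepping(psc_inputs(n), cps, 5, seed = 7))
  pred <- sqrt(2) / (0.23 * sqrt(5 * cps))
  expect_lt(abs(stats::sd(r$dpc) / pred - 1), 0.1)
  # quadrupling the counts halves the noise
  r2 <- retrieve(simulate_phase_stepping(psc_inputs(n), 4 * cps, 5,
                                         seed = 8))
  expect_lt(abs(stats::sd(r2$dpc) / stats::sd(r$dpc) - 0.5), 0.05)
  # starved regime: uniform phase on (-pi, pi], sd -> pi/sqrt(3)
  rs <- retrieve(simulate_phase_stepping(psc_inputs(n, vis = 0.02), 20, 5,
                                         seed = 9))
  expect_lt(abs(stats::sd(rs$dpc) / (pi / sqrt(3)) - 1), 0.08)
})

test_that("phase-noise floor threshold is inclusive and monotone", {
  expect_true(phase_noise_floor_ok(0.23, 2000, 5))
  expect_false(phase_noise_floor_ok(0.23, 0, 5))
  # boundary: sigma exactly at the threshold passes
  v <- 0.23; N <- 5
  c_star <- (2.5 / (pi / sqrt(3)))^2 / (v^2 * N)
  expect_true(phase_noise_floor_ok(v, c_star, N))
  expect_false(phase_noise_floor_ok(v, c_star * 0.99, N))
})
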