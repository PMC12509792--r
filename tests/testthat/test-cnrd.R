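# sphere signals, noise terms, dose/intensity proxies, CNRD

test_that("sphere signals carry the right geometry scalings", {
  expect_equal(sphere_attenuation_signal(0, 0.1), 0)
  expect_equal(sphere_attenuation_signal(0.05, 0.1), 5.236e-5,
               tolerance = 1e-4)
  expect_equal(sphere_attenuation_signal(0.2, 0.1) /
                 sphere_attenuation_signal(0.1, 0.1), 8)
  expect_equal(sphere_refraction_signal(0, 0.5, 5.3, 1e-9), 0)
  expect_equal(sphere_refraction_signal(0.2, 0.5, 5.3, 1e-9) /
                 sphere_refraction_signal(0.1, 0.5, 5.3, 1e-9), 4)
  expect_equal(sphere_refraction_signal(0.1, 1.0, 5.3, 1e-9) /
                 sphere_refraction_signal(0.1, 0.5, 5.3, 1e-9), 2)
})

test_that("noise terms follow inverse-sqrt counting statistics", {
  nt <- noise_terms(1e4, 1)
  expect_equal(nt$sigma_t, 0.01)
  expect_equal(nt$sigma_phi, 0.01)
  expect_equal(noise_terms(1e4, 0.23)$sigma_phi, 1 / (100 * 0.23))
  nt4 <- noise_terms(4e4, 0.5)
  expect_equal(nt4$sigma_t / noise_terms(1e4, 0.5)$sigma_t, 0.5)
  expect_error(noise_terms(0, 0.5))
})

test_that("opening angles are geometric", {
  expect_equal(opening_angles(1e-9, 0.896)$alpha, 0, tolerance = 1e-8)
  expect_equal(opening_angles(12, 0.896)$alpha, 2 * asin(0.06 / 0.896))
  a <- vapply(c(6, 10, 14, 18), function(t)
    opening_angles(t, 0.896)$alpha, numeric(1))
  expect_true(all(diff(a) > 0))
  expect_error(opening_angles(300, 0.896), "larger")
})

test_that("dose and intensity proxies have the right limits", {
  s <- generate_spectrum(50, 3)
  br <- bct_material("breast")
  expect_equal(dose_proxy(s, br, 0, 0.1, 0.1), 0)
  # total absorption limit
  expect_equal(dose_proxy(s, br, 500, 0.1, 0.1),
               0.01 * sum(s$weights * s$energies), tolerance = 1e-6)
  d <- vapply(c(2, 6, 10, 16), function(t)
    dose_proxy(s, br, t, 0.1, 0.1), numeric(1))
  expect_true(all(diff(d) > 0))
  expect_equal(detected_intensity(s, br, 0, 1.3),
               sum(s$weights) / 1.3^2)
  expect_equal(detected_intensity(s, br, 10, 2.6) /
                 detected_intensity(s, br, 10, 1.3), 0.25)
  i <- vapply(c(2, 6, 10, 16), function(t)
    detected_intensity(s, br, t, 1.3), numeric(1))
  expect_true(all(diff(i) < 0))
})

test_that("CNRD vanishes for identical tissues and is finite otherwise", {
  g <- solve_geometry(design_point(5.3, 3, 38))
  same <- task_spec(14, 0.25, tissue_pair = c("tumor", "tumor"))
  expect_equal(signal_budget(g, same, 50)$cnrd, 0)
  b <- signal_budget(g, task_spec(14, 0.25), 50)
  for (f in c("s_t", "s_phi", "i_d", "dose", "v_eff", "cnrd")) {
    expect_true(is.finite(b[[f]]) && b[[f]] > 0)
  }
})

test_that("CNRD scales as c^(1/2 - q) with the spectrum intensity", {
  g <- solve_geometry(design_point(5.3, 3, 38))
  for (q in c(0.5, 1)) {
    task <- task_spec(14, 0.5, dose_exponent = q)
    b1 <- signal_budget(g, task, 50)
    scaled <- function(kvp, filter_mm_al = 3) {
      s <- generate_spectrum(kvp, filter_mm_al)
      s$weights <- s$weights * 16
      s
    }
    b2 <- signal_budget(g, task, 50, spectrum_fun = scaled)
    expect_equal(b2$cnrd / b1$cnrd, 16^(0.5 - q), tolerance = 1e-9)
  }
})

test_that("refraction dominates small lesions, attenuation large ones", {
  g <- solve_geometry(design_point(5.3, 3, 38))
  b_small <- signal_budget(g, task_spec(14, 0.25), 50)
  b_large <- signal_budget(g, task_spec(14, 0.75), 50)
  expect_gt(b_small$term_refraction, b_small$term_attenuation)
  expect_gt(b_large$term_attenuation, b_large$term_refraction)
  # the term ratio scales as 1/r, so a crossing radius exists between
  ratio <- function(r) {
    b <- signal_budget(g, task_spec(14, r), 50)
    b$term_refraction / b$term_attenuation
  }
  expect_equal(ratio(0.25) / ratio(0.75), 3, tolerance = 1e-6)
  # higher sensitivity (longer d) shifts the crossing to larger radii
  g_long <- g; g_long$d_sens <- 2 * g$d_sens
  b_long <- signal_budget(g_long, task_spec(14, 0.75), 50)
  expect_equal(b_long$term_refraction / b_long$term_attenuation,
               2 * b_large$term_refraction / b_large$term_attenuation,
               tolerance = 1e-9)
})

test_that("the gratingless budget ignores visibility and grating height", {
  task <- task_spec(14, 0.5)
  b1 <- signal_budget(NULL, task, 60, s_total_m = 0.65,
                      source_to_sample_m = 0.5)
  b2 <- signal_budget(NULL, task, 60, s_total_m = 0.65,
                      source_to_sample_m = 0.5, Q = 0.1)
  expect_equal(b1$cnrd, b2$cnrd)
  expect_equal(b1$s_phi, 0)
  expect_equal(b1$v_eff, 0)
  expect_gt(b1$cnrd, 0)
})
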