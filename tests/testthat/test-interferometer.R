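# geometry solver, constraints, visibility

test_that("wavelength conversion is exact", {
  expect_equal(wavelength(38), 3.263e-11, tolerance = 1e-4)
  expect_equal(wavelength(12.3984), 1e-10, tolerance = 1e-4)
  expect_equal(wavelength(20) / wavelength(40), 2)
})

test_that("symmetric solution gives equal arms and equal pitches", {
  dp <- design_point(5.3, 3, 38)
  L_sym <- symmetric_length(5.3, 3, 38)
  g <- solve_geometry(dp, L_sym)
  expect_equal(g$D, g$L, tolerance = 1e-12)
  expect_equal(g$S, 2 * g$L, tolerance = 1e-12)
  expect_equal(g$p1_um, 5.3, tolerance = 1e-12)
  expect_equal(g$p2_um, 5.3, tolerance = 1e-12)
  # the symmetric system reproduces the published distances
  expect_equal(round(100 * g$source_to_sample, 1), 89.6)
  expect_equal(round(100 * g$d_sens, 1), 54.6)
})

test_that("geometry round-trips and rejects the degenerate branch", {
  # resubstituting the solved pitches reproduces S for asymmetric L too
  for (Lf in c(0.6, 0.85, 1.1)) {
    dp <- design_point(6.1, 5, 30, kvp = 50)
    L <- Lf * symmetric_length(6.1, 5, 30)
    g <- solve_geometry(dp, L)
    expect_equal(g$p2_um, g$p0_um * g$D / g$L, tolerance = 1e-10)
    expect_equal(g$p1_um, 2 * g$D * g$p0_um / g$S, tolerance = 1e-10)
    # fractional Talbot condition: D = TO p1^2 / (8 lambda) * (S/(S-D))...
    # equivalent check: S reconstructed from the defining equation
    lam <- wavelength(30)
    S2 <- g$L * 5 * (6.1e-6)^2 / (5 * (6.1e-6)^2 - 2 * lam * g$L)
    expect_equal(g$S, S2, tolerance = 1e-10)
  }
  # L at/beyond the asymptote is infeasible
  dp <- design_point(5.3, 3, 38)
  L_asym <- 2 * symmetric_length(5.3, 3, 38)
  expect_error(solve_geometry(dp, L_asym * 1.01), "asymptote")
})

test_that("minimum grating height guarantees 95% absorption", {
  au <- bct_material("gold")
  for (Ed in c(20, 30, 38, 46)) {
    hg <- min_height(Ed)
    absorbed <- 1 - exp(-mu(au, Ed) * hg * 1e-4)
    expect_equal(absorbed, 1 - exp(-3), tolerance = 1e-12)
    expect_gte(absorbed, 0.95)
  }
  # arithmetic: mu = 300/cm corresponds to 100 um
  fake <- material("dense", c(10, 100), c(300, 300))
  expect_equal(3 / mu(fake, 38) * 1e4, 100)
  # height grows as gold becomes more transparent
  expect_true(all(diff(min_height(20:46)) > 0))
})

test_that("feasibility gates match the constraint definitions", {
  ok <- feasible(design_point(5.3, 3, 38))
  expect_true(attr(ok, "feasible"))
  # required aspect ratio at 5.3 um / 38 keV is comfortably below 50
  expect_lt(min_height(38) / (5.3 / 2), 50)
  # small pitch at high design energy fails the aspect-ratio gate
  bad <- feasible(design_point(3, 3, 46))
  expect_false(attr(bad, "feasible"))
  expect_false(bad$pass[bad$constraint == "ar_g0"])
  expect_gt(min_height(46), 75)
  # over-long systems fail the length gate
  long <- feasible(design_point(9, 7, 40),
                   L_m = symmetric_length(9, 7, 40))
  if (attr(long, "geometry")$total_length > 1.45) {
    expect_false(long$pass[long$constraint == "total_length"])
  }
})

test_that("visibility spectrum has the analytic shape and bounds", {
  for (TO in c(1, 3, 5, 7)) {
    expect_equal(visibility_spectrum(38, TO, 38), 2 / pi)
  }
  E <- seq(10, 120, by = 0.5)
  v <- visibility_spectrum(38, 3, E)
  expect_true(all(v >= 0 & v <= 2 / pi + 1e-12))
  expect_lt(visibility_spectrum(38, 3, 5000), 1e-3)
})

test_that("effective visibility obeys its limits and monotonicities", {
  s <- generate_spectrum(50, 3)
  v <- visibility_spectrum(38, 3, s$energies)
  # infinite height: no transmission penalty
  full <- effective_visibility(v, s, 1e9, Q = 0.65)
  expect_equal(full, 0.65 * sum(v * s$weights), tolerance = 1e-9)
  # linear in Q
  expect_equal(effective_visibility(v, s, 150, Q = 0.3) /
                 effective_visibility(v, s, 150, Q = 0.6), 0.5)
  # monotone non-decreasing in height, bounded by Q * 2/pi
  hs <- c(30, 60, 120, 240, 480)
  ve <- vapply(hs, function(h) effective_visibility(v, s, h), numeric(1))
  expect_true(all(diff(ve) > 0))
  expect_true(all(ve <= 0.65 * 2 / pi))
})
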