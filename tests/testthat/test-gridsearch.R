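# design-space enumeration, best-per-voltage selection, benchmarks

test_that("enumeration is deterministic and honours the gates", {
  sp <- search_space(p0_um = c(5, 6, 7), L_m = seq(0.3, 0.9, by = 0.05),
                     Ed_keV = c(30, 38), TO = c(1, 3))
  a <- enumerate_feasible(sp)
  b <- enumerate_feasible(sp)
  expect_identical(a, b)
  expect_gt(nrow(a), 0)
  # every returned design re-checks as feasible at its chosen L
  for (i in seq_len(nrow(a))) {
    fz <- feasible(design_point(a$p0_um[i], a$TO[i], a$Ed_keV[i]),
                   L_m = a$L_m[i])
    expect_true(attr(fz, "feasible"))
  }
  # the chosen L maximizes sensitivity: the next grid step is infeasible
  for (i in seq_len(min(nrow(a), 4))) {
    fz <- feasible(design_point(a$p0_um[i], a$TO[i], a$Ed_keV[i]),
                   L_m = a$L_m[i] + 0.05)
    expect_false(attr(fz, "feasible"))
  }
})

test_that("toy space with one infeasible corner counts correctly", {
  # Ed = 46 keV requires p0 >= 2*hg/50 ~ 6.9 um: the 5 um corner drops
  sp <- search_space(p0_um = c(5, 7), L_m = seq(0.15, 1, by = 0.005),
                     Ed_keV = c(30, 46), TO = 1)
  res <- enumerate_feasible(sp)
  expect_equal(nrow(res), 3)
  expect_false(any(res$Ed_keV == 46 & res$p0_um == 5))
})

test_that("empty or fully infeasible spaces yield empty results", {
  sp <- search_space(p0_um = 3, L_m = 0.9, Ed_keV = 46, TO = 7)
  expect_equal(nrow(enumerate_feasible(sp)), 0)
  expect_equal(count_feasible(sp), 0)
})

test_that("relaxing the length cap never reduces the feasible count", {
  sp <- search_space(p0_um = seq(4, 8, by = 0.5),
                     L_m = seq(0.2, 1, by = 0.02),
                     Ed_keV = c(25, 35, 45), TO = c(1, 3, 5))
  n1 <- count_feasible(sp, constraint_set(total_length_max = 1.2),
                       mode = "per_tuple")
  n2 <- count_feasible(sp, constraint_set(total_length_max = 1.45),
                       mode = "per_tuple")
  n3 <- count_feasible(sp, constraint_set(total_length_max = 2.0),
                       mode = "per_tuple")
  expect_true(n1 <= n2 && n2 <= n3)
})

test_that("per-design and per-tuple counts nest as expected", {
  sp <- search_space(p0_um = seq(4, 7, by = 0.5),
                     L_m = seq(0.2, 1, by = 0.05),
                     Ed_keV = c(30, 38), TO = c(1, 3))
  nd <- count_feasible(sp, mode = "per_design")
  nt <- count_feasible(sp, mode = "per_tuple")
  expect_gte(nt, nd)
  # dropping the analyzer gates can only widen the space
  expect_gte(count_feasible(sp, check_g2 = FALSE), nd)
})

test_that("best-per-voltage selection handles degenerate cases", {
  sp <- search_space(p0_um = 5.3, L_m = symmetric_length(5.3, 3, 38),
                     Ed_keV = 38, TO = 3)
  designs <- enumerate_feasible(sp)
  expect_equal(nrow(designs), 1)
  best <- best_per_voltage(designs, task_spec(14, 0.5), kvps = c(40, 50, 60))
  expect_equal(nrow(best), 3)
  expect_true(all(best$p0_um == 5.3))
  expect_true(all(best$cnrd > 0))
})

test_that("optimal voltage does not decrease with breast diameter", {
  sp <- search_space(p0_um = seq(4, 9, by = 1),
                     L_m = seq(0.2, 1, by = 0.05),
                     Ed_keV = seq(24, 46, by = 2), TO = c(1, 3, 5))
  designs <- enumerate_feasible(sp)
  kvps <- seq(26, 70, by = 2)
  argmax_kvp <- vapply(c(9, 18), function(t) {
    best <- best_per_voltage(designs, task_spec(t, 0.25), kvps = kvps)
    best$kvp[which.max(best$cnrd)]
  }, numeric(1))
  expect_lte(argmax_kvp[1], argmax_kvp[2])
})

test_that("benchmark fixtures carry the published parameters", {
  bm <- benchmark_systems()
  expect_equal(bm$gi_bct$geometry$TO, 3)
  expect_equal(bm$gi_bct$geometry$Ed_keV, 38)
  expect_equal(bm$gi_bct$kvp, 50)
  expect_equal(round(100 * bm$gi_bct$source_to_sample, 1), 89.6)
  expect_equal(bm$optica_2023$geometry$TO, 5)
  expect_equal(bm$optica_2023$geometry$Ed_keV, 46)
  expect_equal(bm$optica_2023$kvp, 70)
  expect_equal(round(100 * bm$optica_2023$source_to_sample, 1), 101.8)
  expect_true(bm$ab_ct$gratingless)
  expect_equal(bm$ab_ct$kvp, 60)
  expect_equal(bm$ab_ct$total_length, 0.65)
})
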