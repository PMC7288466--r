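test_that("Williams cumulative time satisfies its limit identities", {
  for (T in c(8.5, 10.5, 24)) {
    expect_equal(williams_time(0, T), 0)
    expect_equal(williams_time(1, T), T, tolerance = 1e-12)
  }
  expect_error(williams_time(-0.1, 24), class = "orimin_error_domain")
  expect_error(williams_time(1.1, 24), class = "orimin_error_domain")
})

test_that("Williams cumulative time matches the closed form and is monotone", {
  # x = -ln(1 - y/2) / alpha at y = 0.95, T = 24 h
  expect_equal(williams_time(0.95, 24), 22.310656, tolerance = 1e-6)
  y <- seq(0, 1, by = 0.01)
  expect_true(all(diff(williams_time(y, 24)) > 0))
})

test_that("cytokinesis duration follows from the fraction in cytokinesis", {
  expect_equal(duration_cytokinesis(0, 24), 0)
  expect_equal(duration_cytokinesis(0.05, 24), 1.689344, tolerance = 1e-6)
  # strictly increasing in the observed fraction
  f <- seq(0, 0.5, by = 0.05)
  cc <- vapply(f, duration_cytokinesis, numeric(1), growth = 24)
  expect_true(all(diff(cc) > 0))
  # a population entirely in cytokinesis is degenerate, not C = T
  expect_error(duration_cytokinesis(1, 24), class = "orimin_error_domain")
})

test_that("mitosis duration subtracts cytokinesis from the M+C window", {
  cc <- duration_cytokinesis(0.05, 24)
  # no pure-mitosis cells: f_MC = f_C gives M = 0
  expect_equal(duration_mitosis(0.05, cc, 24), 0)
  # closed form: (T - x(1 - f_MC)) - C with ln(0.55) inside Williams
  expect_equal(duration_mitosis(0.10, cc, 24), 1.610741, tolerance = 1e-6)
  # M+C window shorter than C alone is contradictory
  expect_error(duration_mitosis(0.02, cc, 24),
               class = "orimin_error_inconsistent")
  expect_error(duration_mitosis(0.02, cc, 24), "frac_mitosis_cyto")
})

test_that("G2 is the two-nuclei chase time minus mitosis", {
  expect_equal(duration_g2(0.75, 0.75), 0)
  expect_equal(duration_g2(2.0, 0.75), 1.25)
  expect_error(duration_g2(0.5, 0.75), class = "orimin_error_inconsistent")
})

test_that("Stanners-Till S-phase inverts its forward labeling model", {
  # L = e^{alpha (S+Z+t)} - e^{alpha Z} followed by duration_s is the
  # identity in S, across a grid of (T, S, Z, t)
  for (T in c(8.5, 10.5, 24)) {
    al <- log(2) / T
    for (s_frac in c(0.15, 0.3, 0.45)) {
      for (z_frac in c(0.1, 0.25, 0.4)) {
        s_true <- s_frac * T
        z <- z_frac * T
        for (t in c(0.1, 0.25 * z)) {
          L <- exp(al * (s_true + z + t)) - exp(al * z)
          if (L <= 1) {
            expect_equal(duration_s(L, z, t, T), s_true, tolerance = 1e-9)
          }
        }
      }
    }
  }
})

test_that("Stanners-Till S-phase example and edge cases", {
  expect_equal(duration_s(0.442378, 8.23, 0.5, 24), 9.86, tolerance = 1e-4)
  # zero labeling cannot support a positive S phase
  expect_error(duration_s(0, 8.23, 0.5, 24), class = "orimin_error_labeling")
  # full labeling (L = 2 - e^{alpha Z}) with a vanishing pulse: S -> T - Z
  T <- 24; al <- log(2) / T; z <- 8
  L <- 2 - exp(al * z)
  expect_equal(duration_s(L, z, 1e-9, T), T - z, tolerance = 1e-6)
  # S strictly increasing in the labeled fraction at fixed Z, t
  Ls <- seq(0.2, 0.6, by = 0.05)
  ss <- vapply(Ls, duration_s, numeric(1), z = 8.23, pulse = 0.5, growth = 24)
  expect_true(all(diff(ss) > 0))
})

test_that("G1 fills the remainder of the doubling time", {
  expect_equal(duration_g1(10, 14, 24), 0)
  expect_equal(duration_g1(9.86, 8.23, 24), 5.91, tolerance = 1e-10)
  expect_equal(duration_g1(2.31, 2.82, 8.5), 3.37, tolerance = 1e-10)
  expect_error(duration_g1(20, 10, 24), class = "orimin_error_inconsistent")
})

test_that("phase_durations enforces the tiling invariant", {
  p <- phase_durations(5.91, 9.86, 5.43, 1.2, 1.6)
  expect_s3_class(p, "orimin_phases")
  expect_equal(attr(p, "doubling_time"), 24)
  expect_equal(attr(p, "z"), 8.23)
  expect_error(phase_durations(5, 9, 5, 1, 1, doubling_time = 24),
               class = "orimin_error_inconsistent")
  expect_error(phase_durations(-1, 9, 5, 1, 1), class = "orimin_error_domain")
})

test_that("ccu breakdown divides by the doubling time and sums to one", {
  p <- to_ccu(phase_durations(5.91, 9.86, 5.43, 1.2, 1.6))
  expect_equal(sum(p$ccu), 1, tolerance = 1e-9)
  expect_equal(round(p$ccu[p$phase == "S"], 3), 0.411)
  p2 <- to_ccu(phase_durations(3.37, 2.31, 1.41, 0.705, 0.705))
  expect_equal(round(p2$ccu[p2$phase == "S"], 3), 0.272)
  expect_equal(sum(p2$ccu), 1, tolerance = 1e-9)
  # a phase spanning the whole cycle has ccu exactly 1
  p3 <- to_ccu(phase_durations(0, 24, 0, 0, 0))
  expect_equal(p3$ccu[p3$phase == "S"], 1)
})

test_that("estimate_phases composes the stages and reports the failing stage", {
  snap <- population_snapshot(0.05, 0.10, 0.442378, pulse = 0.5,
                              two_nuclei_time = 2.0)
  est <- estimate_phases(snap, 24)
  h <- setNames(est$hours, as.character(est$phase))
  expect_equal(unname(h["C"]), 1.689344, tolerance = 1e-6)
  expect_equal(unname(h["M"]), 1.610741, tolerance = 1e-6)
  expect_equal(unname(h["G2"]), 2.0 - 1.610741, tolerance = 1e-6)
  expect_equal(sum(est$hours), 24, tolerance = 1e-9)
  expect_equal(sum(est$ccu), 1, tolerance = 1e-9)

  # degenerate population: nothing dividing, nothing labeled
  degenerate <- population_snapshot(0, 0, 0, pulse = 0.5,
                                    two_nuclei_time = 2.0)
  err <- tryCatch(estimate_phases(degenerate, 24), condition = function(e) e)
  expect_s3_class(err, "orimin_error")
  expect_match(conditionMessage(err), "while estimating S")
})

test_that("snapshot construction rejects contradictory fractions", {
  expect_error(population_snapshot(0.10, 0.05, 0.4, 0.5, 2),
               class = "orimin_error_inconsistent")
  expect_error(population_snapshot(0.05, 0.10, 1.2, 0.5, 2),
               class = "orimin_error_domain")
  expect_error(population_snapshot(0.05, 0.10, 0.4, 0, 2),
               class = "orimin_error_domain")
})
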