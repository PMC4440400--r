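test_that("energy equations reproduce the canonical limiting cases", {
  # H2S + 0.5 O2 -> S0 + H2O
  e1 <- energy_equation("sulfide", "aerobic", 1)
  expect_equal(coef_of(e1, "O2"), -0.5)
  expect_equal(coef_of(e1, "S0"), 1)
  expect_equal(coef_of(e1, "H2O"), 1)
  expect_equal(coef_of(e1, "SO4"), 0)
  # H2S + 2 O2 -> SO4^2- + 2 H+
  e0 <- energy_equation("sulfide", "aerobic", 0)
  expect_equal(coef_of(e0, "O2"), -2)
  expect_equal(coef_of(e0, "SO4"), 1)
  expect_equal(coef_of(e0, "H+"), 2)
  # generic x: O2 coefficient 2 - 1.5x, H2O x, H+ 2 - 2x
  ex <- energy_equation("sulfide", "aerobic", 0.4)
  expect_equal(coef_of(ex, "O2"), -(2 - 1.5 * 0.4))
  expect_equal(coef_of(ex, "H2O"), 0.4)
  expect_equal(coef_of(ex, "H+"), 2 - 2 * 0.4)
  # sulfide denitrification at x = 0 (element/charge balance oracle):
  # H2S + 1.6 NO3- -> SO4^2- + 0.8 N2 + 0.8 H2O + 0.4 H+
  ed <- energy_equation("sulfide", "denitrification", 0)
  expect_equal(coef_of(ed, "NO3"), -1.6)
  expect_equal(coef_of(ed, "N2"), 0.8)
  expect_equal(coef_of(ed, "H2O"), 0.8)
  expect_equal(coef_of(ed, "H+"), 0.4)
  # sulfide DNRA at x = 0: H2S + NO3- + H2O -> SO4^2- + NH4+
  en <- energy_equation("sulfide", "dnra", 0)
  expect_equal(coef_of(en, "NO3"), -1)
  expect_equal(coef_of(en, "NH4"), 1)
  expect_equal(coef_of(en, "H2O"), -1)
  expect_equal(coef_of(en, "H+"), 0)
})

test_that("assimilation equations mirror the energy step with CO2", {
  a0 <- assimilation_equation("sulfide", 0)
  expect_equal(coef_of(a0, "CO2"), -2)
  expect_equal(coef_of(a0, "CH2O"), 2)
  expect_equal(coef_of(a0, "H+"), 2)
  a1 <- assimilation_equation("sulfide", 1)
  expect_equal(coef_of(a1, "CO2"), -0.5)
  expect_equal(coef_of(a1, "CH2O"), 0.5)
  # thiosulfate, complete oxidation (balance oracle):
  # S2O3^2- + 2 CO2 + 3 H2O -> 2 SO4^2- + 2 CH2O + 2 H+
  at <- assimilation_equation("thiosulfate", 0)
  expect_equal(coef_of(at, "CO2"), -2)
  expect_equal(coef_of(at, "H2O"), -3)
  expect_equal(coef_of(at, "SO4"), 2)
  expect_equal(coef_of(at, "CH2O"), 2)
  expect_equal(coef_of(at, "H+"), 2)
  # nu_CO2 = nu_orgC everywhere
  for (x in c(-1, 0, 0.5, 1)) {
    a <- assimilation_equation("sulfide", x)
    expect_equal(-coef_of(a, "CO2"), coef_of(a, "CH2O"))
  }
})

test_that("RET equations carry the pathway's electron fractions", {
  # sulfide/Calvin: (4 - 3x) NADH, (6 - 5x) H+
  r <- ret_equation("sulfide", "calvin", 0)
  expect_equal(coef_of(r, "NADH"), 4)
  expect_equal(coef_of(r, "NAD+"), -4)
  expect_equal(coef_of(r, "H+"), 6)
  r1 <- ret_equation("sulfide", "calvin", 1)
  expect_equal(coef_of(r1, "NADH"), 1)
  expect_equal(coef_of(r1, "H+"), 1)
  # sulfide/rTCA at x = 1: 0.5 NADH + 0.67 Fd_red + 0.17 FADH2
  rt1 <- ret_equation("sulfide", "rtca", 1)
  expect_equal(coef_of(rt1, "NADH"), 0.5)
  expect_equal(coef_of(rt1, "Fd_red"), 2 / 3, tolerance = 1e-12)
  expect_equal(coef_of(rt1, "FADH2"), 1 / 6, tolerance = 1e-12)
  # sulfide/rTCA generic x: 2 - 1.5x NADH, 8/3 - 2x Fd, 2/3 - x/2 FADH2
  rt <- ret_equation("sulfide", "rtca", 0.4)
  expect_equal(coef_of(rt, "NADH"), 2 - 1.5 * 0.4)
  expect_equal(coef_of(rt, "Fd_red"), 8 / 3 - 2 * 0.4)
  expect_equal(coef_of(rt, "FADH2"), 2 / 3 - 0.5 * 0.4)
  expect_equal(coef_of(rt, "H+"), 20 / 3 - 5.5 * 0.4)
  # carrier electrons equal the substrate's electron yield
  for (x in c(-0.5, 0, 0.6, 1)) {
    for (pw in c("calvin", "rtca")) {
      rr <- ret_equation("sulfide", pw, x)
      carried <- 2 * coef_of(rr, "NADH") + 2 * coef_of(rr, "FADH2") +
        coef_of(rr, "Fd_red")
      expect_equal(carried, 8 - 6 * x, tolerance = 1e-12)
    }
  }
})

test_that("overall equation is the y-weighted sum of its parts", {
  for (substrate in c("sulfide", "thiosulfate")) {
    for (tea in c("aerobic", "denitrification")) {
      for (x in x_grid_for(substrate, 5)) {
        for (y in c(0, 0.3, 0.825, 1)) {
          ov <- suppressWarnings(overall_equation(substrate, tea, x, y))
          en <- suppressWarnings(energy_equation(substrate, tea, x))
          as <- suppressWarnings(assimilation_equation(substrate, x))
          manual <- soxtherm:::.merge_coef(y * en$coefficients,
                                           (1 - y) * as$coefficients)
          for (sp in names(ov$coefficients)) {
            expect_equal(coef_of(ov, sp), unname(manual[sp]),
                         tolerance = 1e-12)
          }
        }
      }
    }
  }
  # published worked example: x = 0, y = 0.825
  ov <- overall_equation("sulfide", "aerobic", 0, 0.825)
  expect_equal(coef_of(ov, "O2"), -1.65)
  expect_equal(coef_of(ov, "CO2"), -0.35)
  expect_equal(coef_of(ov, "SO4"), 1)
  expect_equal(coef_of(ov, "H+"), 2)
  expect_equal(coef_of(ov, "H2O"), -0.35)
  # symbiont example with stored-S0 co-oxidation: x = -1.12, y = 0.375
  ovr <- suppressWarnings(
    overall_equation("sulfide", "aerobic", -1.12, 0.375))
  expect_equal(coef_of(ovr, "S0"), -1.12)
  expect_equal(coef_of(ovr, "SO4"), 2.12)
  expect_equal(coef_of(ovr, "O2"), -1.38)
  expect_equal(coef_of(ovr, "CO2"), -2.3)
  expect_equal(coef_of(ovr, "H+"), 4.24)
  expect_equal(coef_of(ovr, "H2O"), -3.42)
  # pure energy limit reduces to complete oxidation
  expect_equal(overall_equation("sulfide", "aerobic", 0, 1)$coefficients,
               energy_equation("sulfide", "aerobic", 0)$coefficients)
})

test_that("every builder output is element- and charge-balanced", {
  for (i in seq_len(nrow(all_combos))) {
    substrate <- all_combos$substrate[i]
    tea <- all_combos$tea[i]
    for (x in x_grid_for(substrate)) {
      suppressWarnings({
        eqs <- list(
          energy_equation(substrate, tea, x),
          assimilation_equation(substrate, x),
          ret_equation(substrate, "calvin", x),
          ret_equation(substrate, "rtca", x),
          overall_equation(substrate, tea, x, 0.6)
        )
      })
      for (eq in eqs) {
        rep <- check_balance(eq)
        expect_true(attr(rep, "passed"))
        expect_lt(max(abs(rep$residual)), 1e-9)
      }
    }
  }
  # a corrupted coefficient is flagged
  bad <- energy_equation("sulfide", "aerobic", 0)
  bad$coefficients[["O2"]] <- bad$coefficients[["O2"]] + 0.1
  expect_false(attr(check_balance(bad), "passed"))
})

test_that("electron conservation holds in overall equations", {
  for (x in c(-0.8, 0, 0.5, 1)) {
    for (y in c(0.2, 0.7)) {
      ov <- suppressWarnings(overall_equation("sulfide", "aerobic", x, y))
      expect_equal(4 * abs(coef_of(ov, "O2")) + 4 * abs(coef_of(ov, "CO2")),
                   8 - 6 * x, tolerance = 1e-12)
      ovd <- suppressWarnings(
        overall_equation("sulfide", "denitrification", x, y))
      expect_equal(5 * abs(coef_of(ovd, "NO3")) +
                     4 * abs(coef_of(ovd, "CO2")), 8 - 6 * x,
                   tolerance = 1e-12)
      ovn <- suppressWarnings(overall_equation("sulfide", "dnra", x, y))
      expect_equal(8 * abs(coef_of(ovn, "NO3")) +
                     4 * abs(coef_of(ovn, "CO2")), 8 - 6 * x,
                   tolerance = 1e-12)
    }
  }
})

test_that("x outside the admissible domain is rejected, with bounds named", {
  expect_error(energy_equation("sulfide", "aerobic", 1.2), "\\[-10, 1\\]")
  expect_error(energy_equation("thiosulfate", "aerobic", -0.1),
               "\\[0, 1\\]")
  expect_warning(energy_equation("sulfide", "aerobic", -3), "stored-S0")
  expect_error(overall_equation("sulfide", "aerobic", 0, 1.01), "y")
})

test_that("solve_xy inverts the published rate ratios", {
  s <- solve_xy(c(tea = 1.65, co2 = 0.35))
  expect_equal(s$x, 0)
  expect_equal(s$y, 0.825)
  expect_warning(s2 <- solve_xy(c(tea = 1.38, co2 = 2.3)), "stored")
  expect_equal(s2$x, -1.12, tolerance = 1e-12)
  expect_equal(s2$y, 0.375, tolerance = 1e-12)
  s3 <- solve_xy(c(tea = 2, co2 = 0))
  expect_equal(s3$x, 0)
  expect_equal(s3$y, 1)
  expect_error(solve_xy(c(tea = 0, co2 = 0)), "non-positive")
  # thiosulfate cannot run on stored sulfur: negative x is inadmissible
  expect_error(solve_xy(c(tea = 3, co2 = 3), "thiosulfate"), "admissible")
  # an absurd electron flow pushes even sulfide past its bound
  expect_error(solve_xy(c(tea = 20, co2 = 0)), "admissible")
})

test_that("solve_xy is the exact inverse of overall_equation", {
  for (substrate in c("sulfide", "thiosulfate")) {
    for (tea in c("aerobic", "denitrification", "dnra")) {
      acc <- tea_process(tea)
      for (x in x_grid_for(substrate, 5)) {
        for (y in c(0.15, 0.5, 0.9)) {
          ov <- suppressWarnings(overall_equation(substrate, tea, x, y))
          r <- abs(coef_of(ov, acc$species))
          co2 <- abs(coef_of(ov, "CO2"))
          s <- suppressWarnings(
            solve_xy(c(tea = r, co2 = co2), substrate, tea))
          expect_equal(s$x, x, tolerance = 1e-12)
          expect_equal(s$y, y, tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("host-respiration correction follows the O2/CO2 bookkeeping", {
  r <- rate_set(c(H2S = 6.75, O2 = 12.4, CO2 = 12.45))
  adj <- adjust_for_host(r, 0.25, 1)
  expect_equal(unname(adj$rates[["O2"]]), 9.3)
  expect_equal(unname(adj$rates[["CO2"]]), 15.55)
  # f = 0 leaves rates unchanged
  expect_equal(adjust_for_host(r, 0)$rates, r$rates)
  adj2 <- adjust_for_host(rate_set(c(H2S = 1, O2 = 10, CO2 = 0)), 0.5, 1)
  expect_equal(unname(adj2$rates[["O2"]]), 5)
  expect_equal(unname(adj2$rates[["CO2"]]), 5)
  expect_error(adjust_for_host(r, 1), "host_o2_fraction")
})
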