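test_that("traditional efficiency matches the published worked examples", {
  expect_equal(efficiency_traditional(0, 0.825), 0.037,
               tolerance = 0.001 / 0.037)
  expect_equal(efficiency_traditional(0, 0.833, "thiosulfate"), 0.0314,
               tolerance = 0.0005 / 0.0314)
  expect_equal(efficiency_traditional(0, 0.844, "thiosulfate"), 0.0290,
               tolerance = 0.0005 / 0.0290)
  expect_equal(efficiency_traditional(0, 1), 0)
  expect_error(efficiency_traditional(0, 0), "y = 0")
})

test_that("carrier-explicit efficiency matches the published values", {
  expect_equal(100 * efficiency_new(0, 0.825), 9.60, tolerance = 0.15 / 9.6)
  expect_equal(100 * efficiency_new(0, 0.844, "thiosulfate", "aerobic",
                                    "calvin"), 7.96,
               tolerance = 0.5 / 7.96)
  expect_equal(100 * efficiency_new(0, 0.833, "thiosulfate", "aerobic",
                                    "rtca"), 7.99, tolerance = 0.5 / 7.99)
  expect_equal(efficiency_new(0, 1), 0)
})

test_that("factorization yields the published minimum partial efficiencies", {
  tv <- factorize_efficiency(0, 0.844, "thiosulfate", "aerobic", "calvin")
  expect_equal(tv$epsilon_so_min, 0.1030, tolerance = 0.005 / 0.103)
  expect_equal(tv$epsilon_t_min, tv$epsilon_so_min)
  expect_equal(tv$epsilon_ret_min, 0.052, tolerance = 0.002 / 0.052)
  sd <- factorize_efficiency(0, 0.833, "thiosulfate", "aerobic", "rtca")
  expect_equal(sd$epsilon_so_min, 0.0818, tolerance = 0.005 / 0.0818)
  expect_equal(sd$epsilon_ret_min, 0.051, tolerance = 0.002 / 0.051)
  ms <- factorize_efficiency(0, 0.825)
  expect_equal(100 * ms$epsilon_so_min, 12.33, tolerance = 0.15 / 12.33)
})

test_that("the two closed forms of the minimum SO efficiency agree", {
  for (substrate in c("sulfide", "thiosulfate")) {
    for (x in x_grid_for(substrate, 4)) {
      for (y in c(0.3, 0.8)) {
        br <- suppressWarnings(
          factorize_efficiency(x, y, substrate, "aerobic", "rtca"))
        direct <- (1 - y) * (br$dg_ret + br$de_fix_total) /
          (-y * br$dg_energy)
        expect_equal(br$epsilon_so_min, direct, tolerance = 1e-12)
        # eq: eps_so_min = eps_II * [alpha/eps_co2 + (1 - alpha)]
        expect_equal(br$epsilon_so_min,
                     br$epsilon_II * (br$alpha / br$epsilon_co2 +
                                        1 - br$alpha),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("pathway fixation efficiencies are the known constants", {
  pc <- pathway_energetics("calvin")
  expect_equal(pc$de_fix, 123)
  expect_equal(pc$epsilon_co2, 69.7 / 123, tolerance = 1e-12)
  expect_equal(round(pc$epsilon_co2, 2), 0.57)
  pr <- pathway_energetics("rtca")
  expect_equal(pr$de_fix, 5 / 3 * 41)
  expect_equal(pr$epsilon_co2, 64.3 / 68.3, tolerance = 1e-3)
  expect_equal(round(pr$epsilon_co2, 2), 0.94)
})

test_that("the carrier-explicit efficiency dominates the traditional one", {
  ys <- seq(0.05, 0.95, length.out = 10)
  for (i in seq_len(nrow(all_combos))) {
    substrate <- all_combos$substrate[i]
    tea <- all_combos$tea[i]
    pw <- if (substrate == "thiosulfate") "rtca" else "calvin"
    for (x in x_grid_for(substrate, 5)) {
      prev <- NULL
      for (y in ys) {
        br <- suppressWarnings(
          factorize_efficiency(x, y, substrate, tea, pw))
        expect_gt(br$epsilon_II, br$epsilon_I)
        expect_gt(br$epsilon_so_min, br$epsilon_I)
        expect_true(br$alpha > 0 && br$alpha < 1)
        expect_gt(br$epsilon_I, 0)
        # conservation cannot exceed unity once y is large enough for
        # the energy reaction to pay for the conserving one
        if (y >= 0.8) expect_lt(br$epsilon_II, 1)
        if (!is.null(prev)) expect_lt(br$epsilon_II, prev$epsilon_II)
        if (!is.null(prev)) expect_lt(br$epsilon_I, prev$epsilon_I)
        prev <- br
      }
    }
  }
})

test_that("CO2 : TEA yield is (1 - y)/y scaled by the acceptor electrons", {
  expect_equal(round(co2_tea_ratio(0.710), 2), 0.41)
  expect_equal(round(co2_tea_ratio(0.825), 2), 0.21)
  expect_equal(co2_tea_ratio(1), 0)
  expect_error(co2_tea_ratio(0), "y")
  # denitrification: 5 electrons per nitrate vs 4 per O2
  expect_equal(co2_tea_ratio(0.775, "denitrification"),
               (1 - 0.775) / 0.775 * 1.25, tolerance = 1e-12)
  expect_equal(round(co2_tea_ratio(0.775, "denitrification"), 2), 0.36)
  expect_equal(co2_tea_ratio(0.5, "dnra"), 2)
})

test_that("efficiencies refuse thermodynamically inverted conditions", {
  # sulfate so scarce that net CO2 reduction turns exergonic
  cnd <- conditions(c(SO4 = 1e-40), warn_missing = FALSE)
  expect_error(efficiency_traditional(0, 0.8, cond = cnd), "endergonic")
})
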