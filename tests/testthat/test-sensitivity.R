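test_that("triangular sampling matches its closed-form distribution", {
  expect_error(sample_triangular(1, 1, 0.5, 2), "low <= mode <= high")
  expect_equal(sample_triangular(5, 3, 3, 3), rep(3, 5))
  set.seed(123)
  x <- sample_triangular(1e5, 0, 0, 1)
  # CDF is 1 - (1 - x)^2, so P(X <= 0.5) = 0.75
  phat <- mean(x <= 0.5)
  expect_lt(abs(phat - 0.75), 3 * sqrt(0.75 * 0.25 / 1e5))
  y <- sample_triangular(1e5, 3, 4.5, 6)
  expect_true(all(y >= 3 & y <= 6))
  # mean is (low + mode + high) / 3, variance by the standard formula
  se <- sqrt((9 + 20.25 + 36 - 3 * 4.5 - 3 * 6 - 4.5 * 6) / 18 / 1e5)
  expect_lt(abs(mean(y) - 4.5), 3 * se)
})

test_that("tornado evaluates each quantity at its range bounds", {
  p <- load_parameters(list(discount_from = 1))
  tor <- one_way_tornado(p)
  expect_equal(nrow(tor), 7)
  expect_setequal(tor$parameter,
                  c("p_stroke_aspirin", "rr_stroke_warfarin",
                    "p_bleed_warfarin", "rr_bleed_aspirin",
                    "cost_genetic_test", "cost_multiplier",
                    "utility_multiplier"))
  # high stroke rate makes the test strategy dominate
  row <- tor[tor$parameter == "p_stroke_aspirin", ]
  expect_equal(row$high, 0.06)
  expect_equal(row$label_high, "test_dominates")
  expect_equal(row$label_low, "icer_defined")
  # bleed-related and utility bounds stay far below the base-case ICER
  expect_lt(tor[tor$parameter == "p_bleed_warfarin", "icer_high"], 20000)
  expect_true(all(tor[tor$parameter == "utility_multiplier",
                      c("icer_low", "icer_high")] < 20000))
})

test_that("degenerate and missing ranges are handled", {
  p <- load_parameters(list(discount_from = 1))
  p$ranges$cost_genetic_test <- c(100, 100)
  tor <- one_way_tornado(p)
  row <- tor[tor$parameter == "cost_genetic_test", ]
  expect_equal(row$bar_width, 0)
  expect_equal(row$icer_low, row$icer_high)
  expect_equal(row$label_low, row$label_high)
  p$ranges$p_stroke_aspirin <- NULL
  expect_error(one_way_tornado(p), "no sensitivity range")
  expect_error(run_psa(p, n_draws = 2, seed = 1), "no sensitivity range")
})

test_that("CHADS2 stratification reproduces the dominance pattern", {
  p <- load_parameters(list(discount_from = 1))
  grid <- default_chads2_grid()
  expect_equal(grid$label, as.character(0:6))
  ch <- chads2_sweep(p, grid)
  # scores of 3 and greater: the test strategy dominates
  expect_true(all(ch$label_cea[ch$label %in% c("3", "4", "5", "6")] ==
                    "test_dominates"))
  expect_true(all(ch$label_cea[ch$label %in% c("0", "1")] == "icer_defined"))
  # QALY gains grow with the underlying stroke risk
  expect_true(all(diff(ch$qalys_gained) > 0))
  # a level at the base rate reproduces the base-case comparison
  base_cmp <- evaluate_comparison(p, 0.0525)
  ch0 <- chads2_sweep(p, data.frame(label = "base",
                                    p_stroke_aspirin = 0.045))
  expect_equal(ch0$qalys_gained, base_cmp$d_qaly, tolerance = 1e-12)
  expect_equal(ch0$cost_saving, -base_cmp$d_cost, tolerance = 1e-9)
})

test_that("PSA is reproducible from its seed and spans its supports", {
  p <- default_parameters()
  a <- run_psa(p, n_draws = 200, adherence = 0.20, seed = 42)
  b <- run_psa(p, n_draws = 200, adherence = 0.20, seed = 42)
  expect_identical(a$draws, b$draws)
  expect_identical(a$d_cost, b$d_cost)
  expect_identical(a$quadrants, b$quadrants)
  d <- run_psa(p, n_draws = 200, adherence = 0.20, seed = 43)
  expect_false(identical(a$d_cost, d$d_cost))
  for (key in colnames(a$draws)) {
    rng <- p$ranges[[key]]
    expect_true(all(a$draws[, key] >= rng[1] & a$draws[, key] <= rng[2]))
  }
  expect_equal(sum(a$quadrants), 1)
  expect_equal(sum(a$shares), 1, tolerance = 1e-12)
})

test_that("a zero-variance PSA collapses to the base-case point", {
  p <- default_parameters()
  for (key in names(p$ranges)) p$ranges[[key]] <- rep(p[[key]], 2)
  psa <- run_psa(p, n_draws = 20, adherence = 0.20, seed = 1)
  cmp <- evaluate_comparison(p, 0.20)
  expect_equal(unique(psa$d_cost), cmp$d_cost, tolerance = 1e-9)
  expect_equal(unique(psa$d_qaly), cmp$d_qaly, tolerance = 1e-12)
  expect_true(all(is.na(psa$shares)))
})

test_that("variance shares recover analytic R2 decompositions", {
  p <- default_parameters()
  # only one parameter varied: its share is 1
  for (key in names(p$ranges)) p$ranges[[key]] <- rep(p[[key]], 2)
  p$ranges$cost_genetic_test <- c(50, 200)
  psa <- run_psa(p, n_draws = 100, adherence = 0.20, seed = 2)
  expect_equal(unname(psa$shares["cost_genetic_test"]), 1, tolerance = 1e-9)

  # synthetic linear outcome y = 2 x1 + x2: shares 0.8 / 0.2
  set.seed(9)
  draws <- cbind(x1 = rnorm(2e4), x2 = rnorm(2e4))
  fake <- list(draws = draws, nmb = 2 * draws[, 1] + draws[, 2])
  sh <- variance_contributions(fake)
  expect_equal(unname(sh), c(0.8, 0.2), tolerance = 0.02)
  expect_error(variance_contributions(list(draws = draws[1, , drop = FALSE],
                                           nmb = 1)), "at least 2")
})
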