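test_that("empty configuration reproduces the base case", {
  p <- load_parameters(NULL)
  expect_s3_class(p, "af_params")
  expect_equal(p$p_stroke_aspirin, 0.045)
  expect_equal(p$rr_stroke_warfarin, 0.48)
  expect_equal(p$p_bleed_warfarin, 0.025)
  expect_equal(p$rr_bleed_aspirin, 0.59)
  expect_equal(p$u_ich, 0.4)
  expect_equal(p$u_recurrent_stroke, 0.12)
  expect_equal(p$cost_ich_once, 31810)
  expect_equal(p$cohort_size, 1000)
  expect_equal(p$horizon_cycles, 5)
  expect_equal(p$discount_rate, 0.03)
  expect_equal(p$test_positive_fraction, 0.40)
  expect_equal(p$p_convert_base, 0.025)
  expect_identical(attr(p, "provenance")$supplied, character(0))
  # packaged YAML restates the same base case
  p_file <- load_parameters(system.file("extdata", "base_case.yaml",
                                        package = "afcea"))
  for (key in setdiff(names(unclass(p)), "ranges")) {
    expect_identical(p[[key]], p_file[[key]], label = key)
  }
})

test_that("overrides apply and are recorded in provenance", {
  p <- load_parameters(list(discount_rate = 0))
  expect_equal(p$discount_rate, 0)
  expect_equal(p$p_stroke_aspirin, 0.045)
  expect_true("discount_rate" %in% attr(p, "provenance")$supplied)
  expect_true("p_stroke_aspirin" %in% attr(p, "provenance")$defaulted)
  # percent strings normalize on load
  expect_equal(load_parameters(list(p_stroke_aspirin = "4.5%"))$p_stroke_aspirin,
               0.045)
})

test_that("invalid configurations fail with named violations", {
  expect_error(load_parameters(list(p_stroke_aspirin = 1.2)),
               "probability in \\[0, 1\\]")
  expect_error(load_parameters(list(not_a_key = 1)), "unknown key")
  expect_error(load_parameters(list(cost_warfarin_annual = -1)),
               "non-negative cost")
  expect_error(load_parameters(list(u_ich = 1.5)), "utility in \\[0, 1\\]")
  expect_error(load_parameters(list(rr_stroke_warfarin = 0)), "> 0")
  expect_error(
    load_parameters(list(ranges = list(p_stroke_aspirin = c(0.05, 0.04)))),
    "ordered")
})

test_that("parameter sets round-trip through YAML bit-exactly", {
  p <- load_parameters(list(p_stroke_aspirin = 1 / 3,
                            cost_ich_monthly = 4690.123456789,
                            discount_rate = 0.0299999999))
  f <- withr::local_tempfile(fileext = ".yaml")
  write_parameters(p, f)
  p2 <- load_parameters(f)
  for (key in setdiff(names(unclass(p)), "ranges")) {
    expect_identical(p[[key]], p2[[key]], label = key)
  }
  expect_identical(p$ranges, p2$ranges)
})

test_that("therapy rates derive as products of the printed values", {
  r <- derive_therapy_rates(default_parameters())
  expect_equal(r$warfarin$p_stroke, 0.0216)   # 0.045 * 0.48
  expect_equal(r$aspirin$p_bleed, 0.01475)    # 0.025 * 0.59
  expect_equal(r$aspirin$frac_fatal_stroke, 0.179)
  expect_equal(r$warfarin$frac_fatal_stroke, 0.082)
  expect_equal(r$aspirin$frac_fatal_ich, r$warfarin$frac_fatal_ich)
  # unit relative risk equalises the therapies
  r1 <- derive_therapy_rates(params_with(rr_stroke_warfarin = 1))
  expect_equal(r1$warfarin$p_stroke, r1$aspirin$p_stroke)
})

test_that("derived warfarin stroke risk is monotone in the relative risk", {
  rrs <- seq(0.37, 0.63, length.out = 11)
  ps <- vapply(rrs, function(rr)
    derive_therapy_rates(params_with(rr_stroke_warfarin = rr))$warfarin$p_stroke,
    numeric(1))
  expect_true(all(diff(ps) > 0))
})

test_that("every boundary point of the declared ranges validates", {
  base <- default_parameters()
  for (key in names(base$ranges)) {
    for (bound in base$ranges[[key]]) {
      p <- unclass(base)
      p[[key]] <- bound
      p$ranges[[key]] <- range(c(p$ranges[[key]], bound))
      class(p) <- "af_params"
      expect_silent(validate_parameters(p))
      # the transition model stays feasible there too
      expect_s3_class(
        build_transition_model(derive_therapy_rates(p), p$p_convert_base, p),
        "af_transition_model")
    }
  }
})
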