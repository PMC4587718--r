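test_that("discount factor follows the annual convention", {
  expect_equal(discount_factor(0.03, 0), 1.0)
  expect_equal(discount_factor(0.0, 4), 1.0)
  expect_equal(discount_factor(0.03, 1), 1 / 1.03)
  expect_equal(discount_factor(0.03, 0:2), c(1, 1 / 1.03, 1 / 1.03^2))
  expect_error(discount_factor(0.03, -1), "non-negative")
  expect_error(discount_factor(-0.01, 1), "non-negative")
})

test_that("transition rows are stochastic and DEAD is absorbing", {
  p <- default_parameters()
  m <- build_transition_model(derive_therapy_rates(p), p$p_convert_base, p)
  expect_equal(unname(rowSums(m$P)), rep(1, 8), tolerance = 1e-12)
  expect_true(all(m$P >= 0))
  dead <- m$P["DEAD", ]
  expect_equal(unname(dead[names(dead) == "DEAD"]), 1)
  expect_equal(sum(dead), 1)
})

test_that("base-case WELL_ASPIRIN row encodes the printed event split", {
  p <- default_parameters()
  m <- build_transition_model(derive_therapy_rates(p), p$p_convert_base, p)
  # fatal mass: stroke + ICH + extracranial bleed fatality fractions
  expect_equal(m$P["WELL_ASPIRIN", "DEAD"],
               0.045 * 0.179 + 0.01475 * (0.2 * 0.364 + 0.8 * 0.049),
               tolerance = 1e-12)
  expect_equal(m$P["WELL_ASPIRIN", "DEAD"], 0.0097070, tolerance = 1e-7)
  # conversion is an unconditioned competing annual outcome
  expect_equal(m$P["WELL_ASPIRIN", "WELL_WARFARIN"], 0.025)
  # stroke survivors on aspirin convert to warfarin
  expect_equal(m$P["WELL_ASPIRIN", "POST_STROKE_WARFARIN"],
               0.045 * (1 - 0.179))
  # extracranial bleed survivors spend one cycle in POST_BLEED
  expect_equal(m$P["WELL_ASPIRIN", "POST_BLEED"],
               0.01475 * 0.8 * (1 - 0.049))
  expect_equal(m$P["POST_BLEED", "WELL_ASPIRIN"],
               1 - 0.045 - 0.01475)
})

test_that("null dynamics give identity transitions on live states", {
  p <- params_with(p_stroke_aspirin = 0, p_bleed_warfarin = 0,
                   p_convert_base = 0)
  m <- build_transition_model(derive_therapy_rates(p), 0, p)
  # every state is inert except POST_BLEED, whose survivors return to
  # WELL_ASPIRIN after their one event year by construction
  expected <- diag(8)
  dimnames(expected) <- dimnames(m$P)
  expected["POST_BLEED", "POST_BLEED"] <- 0
  expected["POST_BLEED", "WELL_ASPIRIN"] <- 1
  expect_equal(m$P, expected, tolerance = 1e-15)
})

test_that("infeasible event probabilities are rejected", {
  p <- params_with(p_stroke_aspirin = 0.7, p_bleed_warfarin = 0.5,
                   rr_bleed_aspirin = 0.8,
                   ranges = list(p_stroke_aspirin = c(0.03, 0.7),
                                 p_bleed_warfarin = c(0.02, 0.5),
                                 rr_bleed_aspirin = c(0.5, 0.8)))
  expect_error(build_transition_model(derive_therapy_rates(p), 0.025, p),
               "infeasible")
})

test_that("step_cohort conserves persons and reports expected events", {
  p <- default_parameters()
  m <- build_transition_model(derive_therapy_rates(p), p$p_convert_base, p)
  init <- stats::setNames(numeric(8), af_states())
  init["DEAD"] <- 1000
  s <- step_cohort(init, m)
  expect_equal(unname(s$state[names(s$state) == "DEAD"]), 1000)
  expect_equal(sum(s$events), 0)

  init[] <- 0; init["WELL_ASPIRIN"] <- 1000
  s <- step_cohort(init, m)
  expect_equal(sum(s$state), 1000)
  expect_equal(s$events[["stroke_fatal"]] + s$events[["stroke_nonfatal"]], 45)
  expect_error(step_cohort(numeric(3), m), "length")
  expect_error(step_cohort(rep(-1, 8), m), ">= 0")
})

test_that("run_cohort matches closed forms without event dynamics", {
  p0 <- params_with(p_stroke_aspirin = 0, p_bleed_warfarin = 0,
                    p_convert_base = 0, discount_rate = 0)
  m <- build_transition_model(derive_therapy_rates(p0), 0, p0)
  init <- stats::setNames(numeric(8), af_states())
  init["WELL_ASPIRIN"] <- 1000
  tr <- run_cohort(init, m, p0)
  expect_equal(tr$totals$qaly, 1000 * 5 * 0.998)
  expect_equal(tr$totals$cost, 1000 * 5 * 10)

  p3 <- params_with(p_stroke_aspirin = 0, p_bleed_warfarin = 0,
                    p_convert_base = 0)
  m3 <- build_transition_model(derive_therapy_rates(p3), 0, p3)
  tr3 <- run_cohort(init, m3, p3)
  expect_equal(tr3$totals$qaly, 998 * sum(1.03^-(0:4)), tolerance = 1e-12)
  expect_equal(tr3$totals$qaly, 4707.66, tolerance = 1e-5)
})

test_that("live plus dead mass is conserved at every cycle", {
  set.seed(42)
  for (i in 1:5) {
    p <- params_with(p_stroke_aspirin = runif(1, 0, 0.3),
                     p_bleed_warfarin = runif(1, 0, 0.2),
                     p_convert_base = runif(1, 0, 0.5))
    m <- build_transition_model(derive_therapy_rates(p), p$p_convert_base, p)
    init <- stats::setNames(runif(8, 0, 500), af_states())
    tr <- run_cohort(init, m, p)
    expect_equal(unname(rowSums(tr$occupancy)), rep(sum(init), 6),
                 tolerance = 1e-9)
    # cumulative tallies never decrease
    expect_true(all(apply(tr$cumulative_events, 2, diff) >= -1e-12))
    expect_equal(sum(tr$cycle_cost), tr$totals$cost)
  }
})

test_that("raising the aspirin stroke rate never reduces total strokes", {
  strokes <- vapply(seq(0.01, 0.06, by = 0.01), function(ps) {
    p <- params_with(p_stroke_aspirin = ps, p_convert_base = 0)
    m <- build_transition_model(derive_therapy_rates(p), 0, p)
    init <- stats::setNames(numeric(8), af_states())
    init["WELL_ASPIRIN"] <- 1000
    tr <- run_cohort(init, m, p)
    tr$totals$events[["stroke_fatal"]] + tr$totals$events[["stroke_nonfatal"]]
  }, numeric(1))
  expect_true(all(diff(strokes) > 0))
})

test_that("run_cohort is linear in the initial state vector", {
  p <- default_parameters()
  m <- build_transition_model(derive_therapy_rates(p), p$p_convert_base, p)
  set.seed(7)
  v1 <- stats::setNames(runif(8, 0, 100), af_states())
  v2 <- stats::setNames(runif(8, 0, 100), af_states())
  t1 <- run_cohort(v1, m, p)
  t2 <- run_cohort(v2, m, p)
  t12 <- run_cohort(v1 + 2 * v2, m, p)
  expect_equal(t12$totals$cost, t1$totals$cost + 2 * t2$totals$cost,
               tolerance = 1e-9)
  expect_equal(t12$totals$qaly, t1$totals$qaly + 2 * t2$totals$qaly,
               tolerance = 1e-9)
  expect_equal(unname(t12$totals$events),
               unname(t1$totals$events + 2 * t2$totals$events),
               tolerance = 1e-9)
})

test_that("engine equals exhaustive path enumeration for short horizons", {
  for (cfg in list(default_parameters(),
                   params_with(discount_from = 1),
                   params_with(p_stroke_aspirin = 0.06,
                               p_bleed_warfarin = 0.04))) {
    for (cycles in 1:3) {
      cfg$horizon_cycles <- cycles
      m <- build_transition_model(derive_therapy_rates(cfg),
                                  cfg$p_convert_base, cfg)
      for (start in c("WELL_ASPIRIN", "WELL_WARFARIN", "POST_ICH")) {
        init <- stats::setNames(numeric(8), af_states())
        init[start] <- 1
        tr <- run_cohort(init, m, cfg)
        oracle <- oracle_expectation(m, cfg, start, cycles)
        expect_equal(tr$totals$cost, oracle[["cost"]], tolerance = 1e-9)
        expect_equal(tr$totals$qaly, oracle[["qaly"]], tolerance = 1e-9)
      }
    }
  }
})

test_that("trace exports a tidy per-cycle table with totals block", {
  p <- default_parameters()
  m <- build_transition_model(derive_therapy_rates(p), p$p_convert_base, p)
  init <- stats::setNames(numeric(8), af_states())
  init["WELL_ASPIRIN"] <- 1000
  tr <- run_cohort(init, m, p)
  df <- as.data.frame(tr)
  expect_equal(nrow(df), 6 * 8)
  expect_equal(df$occupancy[df$cycle == 0 & df$state == "WELL_ASPIRIN"], 1000)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(tr, f)
  lines <- readLines(f)
  expect_true(any(grepl("^total_disc_cost,", lines)))
})
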