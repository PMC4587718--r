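# Care strategies: usual care vs 4q25 genetic-test strategy, as initial
# cohort splits with arm-specific conversion rates and test costs.

#' Usual-care strategy arm
#'
#' All patients who declined warfarin receive aspirin; event-free patients
#' convert to warfarin at the background annual rate.  No genetic test is
#' performed.
#'
#' @param params A validated `af_params` object.
#' @return An object of class `af_arm`: the arm label, one sub-cohort
#'   (`cohort_size` persons in `WELL_ASPIRIN` with conversion probability
#'   `p_convert_base`), and a zero per-person test cost.
#' @export
build_usual_care_arm <- function(params) {
  structure(list(
    label = "usual_care",
    subcohorts = list(
      list(n = params$cohort_size, state = "WELL_ASPIRIN",
           conversion = params$p_convert_base, group = "untested")
    ),
    test_cost = 0
  ), class = "af_arm")
}

#' Genetic-test strategy arm
#'
#' Every patient is genotyped at the 4q25 locus (one-time per-person test
#' cost at time zero).  A fraction `adherence` of the test-positive
#' patients is motivated to adhere and starts in `WELL_WARFARIN`.  The
#' remaining test-positive decliners stay on aspirin with the background
#' conversion rate scaled up by `conv_mult_test_positive` (2-fold at
#' base); test-negative decliners stay on aspirin with the rate scaled by
#' `conv_mult_test_negative` (2-fold less likely at base).
#'
#' @param params A validated `af_params` object.
#' @param adherence Fraction of test-positive patients who adhere to
#'   warfarin, in \[0, 1\].
#' @return An `af_arm` with three sub-cohorts (adherent test-positives on
#'   warfarin; test-positive decliners; test-negative decliners) and the
#'   per-person test cost.
#' @export
#' @examples
#' arm <- build_test_arm(default_parameters(), adherence = 0.20)
#' vapply(arm$subcohorts, `[[`, numeric(1), "n")
build_test_arm <- function(params, adherence) {
  if (!is.numeric(adherence) || length(adherence) != 1 ||
      is.na(adherence) || adherence < 0 || adherence > 1) {
    stop("adherence must be a single fraction in [0, 1]", call. = FALSE)
  }
  n <- params$cohort_size
  n_pos <- n * params$test_positive_fraction
  n_adhere <- n_pos * adherence
  conv_pos <- min(1, params$p_convert_base * params$conv_mult_test_positive)
  conv_neg <- min(1, params$p_convert_base * params$conv_mult_test_negative)
  structure(list(
    label = "test",
    adherence = adherence,
    subcohorts = list(
      list(n = n_adhere, state = "WELL_WARFARIN",
           conversion = 0, group = "positive_adherent"),
      list(n = n_pos - n_adhere, state = "WELL_ASPIRIN",
           conversion = conv_pos, group = "positive_decliner"),
      list(n = n - n_pos, state = "WELL_ASPIRIN",
           conversion = conv_neg, group = "negative_decliner")
    ),
    test_cost = params$cost_genetic_test
  ), class = "af_arm")
}

#' Evaluate a strategy arm with the cohort engine
#'
#' Runs the Markov cohort once per sub-cohort (each with its own
#' conversion probability), sums the discounted costs, QALYs and event
#' tallies, and adds the one-time per-person genetic-test cost,
#' undiscounted, at time zero (testing precedes the first cycle).
#'
#' @param arm An `af_arm` from [build_usual_care_arm()] or
#'   [build_test_arm()].
#' @param params A validated `af_params` object.
#' @return An object of class `af_arm_result`: `label`, total discounted
#'   `cost` (USD), total discounted `qaly`, named event totals `events`,
#'   and the per-sub-cohort traces in `traces`.
#' @export
evaluate_arm <- function(arm, params) {
  rates <- derive_therapy_rates(params)
  states <- af_states()
  total_cost <- 0
  total_qaly <- 0
  ev <- stats::setNames(numeric(length(af_event_types())), af_event_types())
  index_strokes <- 0
  traces <- list()
  n_total <- 0
  for (sc in arm$subcohorts) {
    n_total <- n_total + sc$n
    if (sc$n <= 0) next
    model <- build_transition_model(rates, sc$conversion, params)
    init <- stats::setNames(numeric(length(states)), states)
    init[sc$state] <- sc$n
    trace <- run_cohort(init, model, params)
    total_cost <- total_cost + trace$totals$cost
    total_qaly <- total_qaly + trace$totals$qaly
    ev <- ev + trace$totals$events
    index_strokes <- index_strokes + trace$totals$index_strokes
    traces[[sc$group]] <- trace
  }
  total_cost <- total_cost + arm$test_cost * n_total
  structure(list(
    label = arm$label,
    cost = total_cost,
    qaly = total_qaly,
    events = ev,
    index_strokes = index_strokes,
    n = n_total,
    traces = traces
  ), class = "af_arm_result")
}

#' Two-row strategy summary table
#'
#' @param usual,test `af_arm_result` objects for the two strategies.
#' @return A `data.frame` with one row per strategy: discounted cost,
#'   discounted QALYs, and event totals (per modelled cohort).
#' @export
strategy_table <- function(usual, test) {
  row <- function(r) {
    data.frame(strategy = r$label, cost = r$cost, qaly = r$qaly,
               strokes = r$events[["stroke_fatal"]] + r$events[["stroke_nonfatal"]],
               fatal_strokes = r$events[["stroke_fatal"]],
               ich = r$events[["ich_fatal"]] + r$events[["ich_nonfatal"]],
               extracranial_bleeds = r$events[["bleed_fatal"]] + r$events[["bleed_nonfatal"]],
               conversions = r$events[["convert"]],
               stringsAsFactors = FALSE)
  }
  rbind(row(usual), row(test))
}

#' @export
print.af_arm_result <- function(x, ...) {
  cat(sprintf("<af_arm_result> %s: cost $%.0f, QALYs %.2f (n = %g)\n",
              x$label, x$cost, x$qaly, x$n))
  ev <- x$events
  cat("  events:", paste(sprintf("%s=%.2f", names(ev), ev), collapse = ", "),
      "\n")
  invisible(x)
}
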