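# Markov engine: health-state space, annual transition model, cycle stepping,
# discounted cost/QALY accrual.

#' Health-state labels of the Markov model
#'
#' The eight states of the model, in canonical order.  `WELL_*` states are
#' event-free atrial-fibrillation patients on the named therapy;
#' `POST_STROKE_*` states hold survivors of a first ischemic stroke (on the
#' named current therapy); `POST_ICH` holds survivors of an intracranial
#' hemorrhage (warfarin permanently discontinued); `POST_BLEED` holds
#' survivors of an extracranial major hemorrhage for the year of the event
#' (warfarin discontinued; survivors return to `WELL_ASPIRIN`);
#' `RECURRENT_STROKE` holds patients with a second ischemic stroke; `DEAD`
#' is absorbing.
#'
#' @return Character vector of the eight state labels.
#' @export
af_states <- function() {
  c("WELL_ASPIRIN", "WELL_WARFARIN", "POST_STROKE_WARFARIN",
    "POST_STROKE_ASPIRIN", "POST_ICH", "POST_BLEED",
    "RECURRENT_STROKE", "DEAD")
}

# current therapy implied by each state (NA for DEAD)
af_state_therapy <- function() {
  c(WELL_ASPIRIN = "aspirin", WELL_WARFARIN = "warfarin",
    POST_STROKE_WARFARIN = "warfarin", POST_STROKE_ASPIRIN = "aspirin",
    POST_ICH = "aspirin", POST_BLEED = "aspirin",
    RECURRENT_STROKE = "warfarin", DEAD = NA_character_)
}

# annotated event types carried on transitions
af_event_types <- function() {
  c("stroke_fatal", "stroke_nonfatal", "ich_fatal", "ich_nonfatal",
    "bleed_fatal", "bleed_nonfatal", "convert")
}

#' Discount factor for an annual cycle
#'
#' Present-value weight `(1 + rate)^(-cycle_index)` applied to the costs
#' and utilities accrued in a model cycle.  Cycle index 0 is the first
#' model year, so the first year is undiscounted by default; the engine's
#' `discount_from` switch shifts the exponent by one for the alternative
#' convention.
#'
#' @param rate Annual discount rate (fraction/yr, >= 0).
#' @param cycle_index Integer cycle index (>= 0); vectorised.
#' @return Positive discount weight(s).
#' @export
#' @examples
#' discount_factor(0.03, 0:4)
discount_factor <- function(rate, cycle_index) {
  if (!is.numeric(rate) || any(rate < 0)) {
    stop("rate must be non-negative", call. = FALSE)
  }
  if (!is.numeric(cycle_index) || any(cycle_index < 0)) {
    stop("cycle_index must be a non-negative integer", call. = FALSE)
  }
  (1 + rate)^(-cycle_index)
}

#' Build the annual transition model for one sub-cohort
#'
#' Encodes, for every live state, the mutually exclusive annual index
#' events under that state's current therapy: ischemic stroke at the
#' therapy-specific probability (split fatal/non-fatal by the
#' therapy-specific fatality fraction) and major hemorrhage at the
#' therapy-specific probability (split intracranial/extracranial, each
#' split fatal/non-fatal).  Warfarin decliners on aspirin additionally
#' convert to warfarin at the supplied annual probability; conversion is a
#' competing annual outcome, mutually exclusive with the index events and
#' with additive probability (the same convention used for stroke vs
#' hemorrhage).  Destinations
#' follow the care rules: stroke on aspirin or warfarin leads to
#' `POST_STROKE_WARFARIN` (decliners convert after a stroke), a second
#' stroke leads to `RECURRENT_STROKE`, intracranial hemorrhage to
#' `POST_ICH`, extracranial major hemorrhage to `POST_BLEED` (whose
#' survivors return to `WELL_ASPIRIN` after one cycle), and every fatal
#' event to the absorbing `DEAD` state.  Stroke survivors among `POST_ICH`
#' patients remain on aspirin (`POST_STROKE_ASPIRIN`), warfarin being
#' permanently discontinued after an intracranial bleed.
#'
#' @param rates An `af_therapy_rates` pair from [derive_therapy_rates()].
#' @param conversion Annual probability that an event-free aspirin decliner
#'   converts to warfarin.
#' @param params A validated `af_params` object (supplies fatality
#'   fractions, costs, utilities and the grouped multipliers).
#' @return An object of class `af_transition_model`: the state list, the
#'   row-stochastic annual transition matrix `P`, per-state expected event
#'   rates and one-time event costs, per-state annual drug cost, utility
#'   and monthly follow-up cost vectors, and the full annotated flow table
#'   (`$flows`).
#' @export
build_transition_model <- function(rates, conversion, params) {
  if (!is.numeric(conversion) || length(conversion) != 1 ||
      conversion < 0 || conversion > 1) {
    stop("conversion must be a probability in [0, 1]", call. = FALSE)
  }
  states <- af_states()
  ns <- length(states)
  idx <- stats::setNames(seq_len(ns), states)
  therapy <- af_state_therapy()
  cm <- params$cost_multiplier
  um <- params$utility_multiplier

  p_stroke <- c(aspirin = rates$aspirin$p_stroke,
                warfarin = rates$warfarin$p_stroke)
  f_stroke <- c(aspirin = rates$aspirin$frac_fatal_stroke,
                warfarin = rates$warfarin$frac_fatal_stroke)
  p_bleed <- c(aspirin = rates$aspirin$p_bleed,
               warfarin = rates$warfarin$p_bleed)
  fi <- params$frac_ich
  ffi <- params$frac_fatal_ich
  ffb <- params$frac_fatal_bleed_excl_ich

  if (any(p_stroke + p_bleed > 1 + 1e-12)) {
    stop("infeasible model: p_stroke + p_bleed exceeds 1 for ",
         paste(names(which(p_stroke + p_bleed > 1)), collapse = ", "),
         call. = FALSE)
  }

  one_time_cost <- function(ev, th) {
    cm * switch(ev,
      stroke_fatal = params$cost_fatal_stroke_once,
      stroke_nonfatal = if (identical(th, "warfarin"))
        params$cost_stroke_once_warfarin else params$cost_stroke_once_aspirin,
      ich_fatal = params$cost_ich_once,
      ich_nonfatal = params$cost_ich_once,
      bleed_fatal = params$cost_bleed_excl_ich_once,
      bleed_nonfatal = params$cost_bleed_excl_ich_once,
      0)
  }

  fr <- character(0); to <- character(0)
  pr <- numeric(0); ev <- character(0); c1 <- numeric(0)
  add <- function(from, dest, p, event) {
    if (p <= 0) return(invisible(NULL))
    fr <<- c(fr, from); to <<- c(to, dest); pr <<- c(pr, p); ev <<- c(ev, event)
    c1 <<- c(c1, one_time_cost(event, therapy[[from]]))
    invisible(NULL)
  }

  stroke_dest <- c(WELL_ASPIRIN = "POST_STROKE_WARFARIN",
                   WELL_WARFARIN = "POST_STROKE_WARFARIN",
                   POST_STROKE_WARFARIN = "RECURRENT_STROKE",
                   POST_STROKE_ASPIRIN = "RECURRENT_STROKE",
                   POST_ICH = "POST_STROKE_ASPIRIN",
                   POST_BLEED = "POST_STROKE_WARFARIN",
                   RECURRENT_STROKE = "RECURRENT_STROKE")
  conv_dest <- c(WELL_ASPIRIN = "WELL_WARFARIN",
                 POST_STROKE_ASPIRIN = "POST_STROKE_WARFARIN")
  stay_dest <- c(WELL_ASPIRIN = "WELL_ASPIRIN",
                 WELL_WARFARIN = "WELL_WARFARIN",
                 POST_STROKE_WARFARIN = "POST_STROKE_WARFARIN",
                 POST_STROKE_ASPIRIN = "POST_STROKE_ASPIRIN",
                 POST_ICH = "POST_ICH",
                 POST_BLEED = "WELL_ASPIRIN",
                 RECURRENT_STROKE = "RECURRENT_STROKE")

  for (s in setdiff(states, "DEAD")) {
    th <- therapy[[s]]
    ps <- p_stroke[[th]]; fs <- f_stroke[[th]]; pb <- p_bleed[[th]]
    conv <- if (s %in% names(conv_dest)) conversion else 0
    if (ps + pb + conv > 1 + 1e-12) {
      stop("infeasible model: event plus conversion probabilities exceed 1 ",
           "in state ", s, call. = FALSE)
    }
    add(s, "DEAD", ps * fs, "stroke_fatal")
    add(s, stroke_dest[[s]], ps * (1 - fs), "stroke_nonfatal")
    add(s, "DEAD", pb * fi * ffi, "ich_fatal")
    add(s, "POST_ICH", pb * fi * (1 - ffi), "ich_nonfatal")
    add(s, "DEAD", pb * (1 - fi) * ffb, "bleed_fatal")
    add(s, "POST_BLEED", pb * (1 - fi) * (1 - ffb), "bleed_nonfatal")
    if (conv > 0) add(s, conv_dest[[s]], conv, "convert")
    add(s, stay_dest[[s]], 1 - ps - pb - conv, "none")
  }
  add("DEAD", "DEAD", 1, "none")

  P <- matrix(0, ns, ns, dimnames = list(states, states))
  etypes <- af_event_types()
  event_rate <- matrix(0, ns, length(etypes), dimnames = list(states, etypes))
  onetime_rate <- stats::setNames(numeric(ns), states)
  for (j in seq_along(fr)) {
    a <- idx[[fr[j]]]; b <- idx[[to[j]]]
    P[a, b] <- P[a, b] + pr[j]
    if (ev[j] != "none") event_rate[a, ev[j]] <- event_rate[a, ev[j]] + pr[j]
    onetime_rate[a] <- onetime_rate[a] + pr[j] * c1[j]
  }
  stopifnot(all(abs(rowSums(P) - 1) < 1e-12))

  drug_cost <- cm * ifelse(is.na(therapy), 0,
                           ifelse(therapy == "warfarin",
                                  params$cost_warfarin_annual,
                                  params$cost_aspirin_annual))
  names(drug_cost) <- states
  # utility multiplier applies to the non-fatal event states only (the
  # healthy-state utilities are held fixed in the sensitivity analyses)
  utility <- c(
    WELL_ASPIRIN = params$u_well_aspirin,
    WELL_WARFARIN = params$u_well_warfarin,
    POST_STROKE_WARFARIN = min(1, um * params$u_stroke_warfarin),
    POST_STROKE_ASPIRIN = min(1, um * params$u_stroke_aspirin),
    POST_ICH = min(1, um * params$u_ich),
    POST_BLEED = params$u_well_aspirin,
    RECURRENT_STROKE = min(1, um * params$u_recurrent_stroke),
    DEAD = params$u_dead)
  monthly_cost <- cm * c(
    WELL_ASPIRIN = 0, WELL_WARFARIN = 0,
    POST_STROKE_WARFARIN = params$cost_stroke_monthly_warfarin,
    POST_STROKE_ASPIRIN = params$cost_stroke_monthly_aspirin,
    POST_ICH = params$cost_ich_monthly,
    POST_BLEED = 0,
    RECURRENT_STROKE = params$cost_stroke_monthly_warfarin,
    DEAD = 0)

  structure(list(
    states = states, P = P, event_rate = event_rate,
    onetime_rate = onetime_rate, drug_cost = drug_cost,
    utility = utility, monthly_cost = monthly_cost,
    conversion = conversion,
    flows = structure(list(from = fr, to = to, prob = pr, event = ev,
                           one_time_cost = c1),
                      class = "data.frame",
                      row.names = seq_along(fr))
  ), class = "af_transition_model")
}

#' Advance a cohort state vector by one annual cycle
#'
#' Multiplies the expected state-occupancy vector by the annual transition
#' matrix and reports the expected number of each annotated event (state
#' mass times transition probability) incurred during the cycle.  Total
#' persons (live plus dead) are conserved.
#'
#' @param state Numeric occupancy vector over [af_states()] (expected
#'   person-counts, non-negative).
#' @param model An `af_transition_model`.
#' @return A list with `state` (next-cycle occupancy) and `events` (named
#'   expected event counts).
#' @export
step_cohort <- function(state, model) {
  state <- af_check_state_vector(state, model)
  list(state = drop(state %*% model$P),
       events = drop(state %*% model$event_rate))
}

af_check_state_vector <- function(state, model) {
  ns <- length(model$states)
  if (length(state) != ns) {
    stop("state vector must have length ", ns, " (one entry per state)",
         call. = FALSE)
  }
  if (any(state < 0)) stop("state vector entries must be >= 0", call. = FALSE)
  state <- as.numeric(state)
  names(state) <- model$states
  state
}

#' Run the Markov cohort over the model horizon
#'
#' Iterates [step_cohort()] for `params$horizon_cycles` one-year cycles.
#' Each cycle accrues (a) per-state annual drug cost weighted by the
#' start-of-cycle occupancy (the event year is charged the pre-event
#' therapy's drug cost), (b) one-time event costs on the cycle's incident
#' events, (c) twelve times the monthly follow-up cost for the mid-cycle
#' occupancy (the average of start- and end-of-cycle occupancy) of the
#' post-stroke, recurrent-stroke and post-ICH states -- events occur
#' mid-year on average, so the event year accrues half a year of
#' follow-up cost -- and (d) utility weighted by the end-of-cycle
#' occupancy (the event year is valued at the destination state's
#' utility).  Costs and utilities of cycle `t` are discounted by
#' `discount_factor(discount_rate, t + discount_from)`; the dead accrue
#' neither costs nor utility.
#'
#' @param initial Initial occupancy vector over [af_states()].
#' @param model An `af_transition_model`.
#' @param params A validated `af_params` object (horizon, discount rate,
#'   `discount_from` switch).
#' @return An object of class `af_trace`: per-cycle occupancy (rows 0..T),
#'   per-cycle discounted cost and QALYs, per-cycle and cumulative event
#'   counts (including `index_strokes`, strokes incident from states with
#'   no prior ischemic stroke), and `totals` (discounted cost, discounted
#'   QALYs, event totals).
#' @export
run_cohort <- function(initial, model, params) {
  v <- af_check_state_vector(initial, model)
  T_ <- as.integer(params$horizon_cycles)
  stopifnot(T_ >= 1)
  etypes <- colnames(model$event_rate)

  # strokes from these states are a patient's first ischemic stroke
  no_prior_stroke <- !(model$states %in%
    c("POST_STROKE_WARFARIN", "POST_STROKE_ASPIRIN", "RECURRENT_STROKE"))
  index_stroke_rate <- ifelse(no_prior_stroke,
                              model$event_rate[, "stroke_fatal"] +
                                model$event_rate[, "stroke_nonfatal"], 0)

  occupancy <- matrix(NA_real_, T_ + 1, length(v),
                      dimnames = list(0:T_, model$states))
  occupancy[1, ] <- v
  cycle_cost <- numeric(T_)
  cycle_qaly <- numeric(T_)
  index_strokes <- numeric(T_)
  events <- matrix(0, T_, length(etypes),
                   dimnames = list(seq_len(T_), etypes))

  for (t in seq_len(T_)) {
    vn <- drop(v %*% model$P)
    ev <- drop(v %*% model$event_rate)
    d <- discount_factor(params$discount_rate, t - 1 + params$discount_from)
    cost_t <- sum(v * model$drug_cost) + sum(v * model$onetime_rate) +
      6 * sum((v + vn) * model$monthly_cost)
    qaly_t <- sum(vn * model$utility)
    cycle_cost[t] <- d * cost_t
    cycle_qaly[t] <- d * qaly_t
    events[t, ] <- ev
    index_strokes[t] <- sum(v * index_stroke_rate)
    v <- vn
    occupancy[t + 1, ] <- v
  }

  structure(list(
    states = model$states,
    occupancy = occupancy,
    cycle_cost = cycle_cost,
    cycle_qaly = cycle_qaly,
    events = events,
    index_strokes = index_strokes,
    cumulative_events = apply(events, 2, cumsum),
    totals = list(cost = sum(cycle_cost), qaly = sum(cycle_qaly),
                  events = colSums(events),
                  index_strokes = sum(index_strokes))
  ), class = "af_trace")
}

#' Tidy per-cycle export of a cohort trace
#'
#' One row per cycle x state with the occupancy at the end of the cycle
#' (cycle 0 is the initial occupancy), plus per-cycle discounted cost and
#' QALY columns repeated on each state row for convenience.
#'
#' @param x An `af_trace`.
#' @param ... Unused.
#' @return A `data.frame` with columns `cycle`, `state`, `occupancy`,
#'   `disc_cost`, `disc_qaly`.
#' @export
as.data.frame.af_trace <- function(x, ...) {
  T_ <- length(x$cycle_cost)
  cycles <- rep(0:T_, each = length(x$states))
  data.frame(
    cycle = cycles,
    state = rep(x$states, T_ + 1),
    occupancy = as.vector(t(x$occupancy)),
    disc_cost = c(rep(NA_real_, length(x$states)),
                  rep(x$cycle_cost, each = length(x$states))),
    disc_qaly = c(rep(NA_real_, length(x$states)),
                  rep(x$cycle_qaly, each = length(x$states))),
    stringsAsFactors = FALSE
  )
}

#' Write a cohort trace to CSV
#'
#' Writes the tidy per-cycle table of [as.data.frame.af_trace()] followed
#' by a totals block (total discounted cost, total discounted QALYs, and
#' each cumulative event tally).
#'
#' @param trace An `af_trace`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  df <- as.data.frame(trace)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  totals <- c(total_disc_cost = trace$totals$cost,
              total_disc_qaly = trace$totals$qaly,
              trace$totals$events)
  lines <- c("", "quantity,value",
             paste(names(totals), format(totals, trim = TRUE, digits = 15),
                   sep = ","))
  cat(lines, file = path, sep = "\n", append = TRUE)
  invisible(path)
}

#' @export
print.af_trace <- function(x, ...) {
  cat("<af_trace>", length(x$cycle_cost), "cycles,",
      sprintf("total cost $%.0f, total QALYs %.2f\n",
              x$totals$cost, x$totals$qaly))
  ev <- x$totals$events
  cat("  events:", paste(sprintf("%s=%.2f", names(ev), ev), collapse = ", "),
      "\n")
  invisible(x)
}
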