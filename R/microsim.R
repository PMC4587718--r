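# Individual-level microsimulation: random patient trajectories under the
# identical annual event process, serving as a brute-force validation
# oracle for the cohort engine (the cohort model is its expectation).

# per-state sampling tables for one transition model: cumulative flow
# probabilities with destinations, event labels and one-time costs
af_flow_tables <- function(model) {
  states <- model$states
  idx <- stats::setNames(seq_along(states), states)
  lapply(states, function(s) {
    fl <- model$flows[model$flows$from == s, , drop = FALSE]
    list(cum = cumsum(fl$prob), dest = unname(idx[fl$to]),
         event = fl$event, one_time_cost = fl$one_time_cost)
  })
}

# uniforms for patients 1..n: one block of (horizon + 1) consecutive
# uniforms per patient from a single seeded stream, so enlarging the
# cohort never perturbs earlier patients' draws
af_patient_uniforms <- function(n, horizon, seed) {
  set.seed(as.integer(seed))
  matrix(stats::runif(n * (horizon + 1)), nrow = n, ncol = horizon + 1,
         byrow = TRUE)
}

#' Simulate one patient trajectory
#'
#' Draws a single synthetic patient: sub-cohort membership from the arm's
#' initial split, then one categorical draw per annual cycle over the
#' exact transition flows of the cohort model (fatal/non-fatal stroke,
#' fatal/non-fatal intracranial or extracranial hemorrhage, conversion to
#' warfarin, or no event), accruing the same discounted costs and
#' utilities as the cohort engine: origin-state drug cost, one-time event
#' costs, half a year of follow-up cost at each of the origin and
#' destination states' monthly rates, and the destination state's
#' utility.  Patient `id` consumes the `id`-th block of uniforms from the
#' seeded stream, so the trajectory is identical whether simulated alone
#' or inside [simulate_cohort()].
#'
#' @param arm An `af_arm`.
#' @param params A validated `af_params` object.
#' @param seed Integer RNG seed.
#' @param id Patient index (>= 1).
#' @return An object of class `af_patient_history`: `id`, `group`
#'   (sub-cohort label), a per-cycle `data.frame` `history` (cycle, state
#'   at start, event, state at end, discounted cost and QALY accrued),
#'   `death_cycle` (`NA` if alive), and discounted `cost`/`qaly` totals
#'   (including the time-zero test cost).
#' @export
simulate_patient <- function(arm, params, seed, id = 1) {
  stopifnot(id >= 1)
  T_ <- as.integer(params$horizon_cycles)
  u <- af_patient_uniforms(id, T_, seed)[id, ]
  rates <- derive_therapy_rates(params)
  ns <- length(af_states())

  sizes <- vapply(arm$subcohorts, `[[`, numeric(1), "n")
  props <- sizes / sum(sizes)
  g <- min(findInterval(u[1], cumsum(props)) + 1, length(props))
  sc <- arm$subcohorts[[g]]
  model <- build_transition_model(rates, sc$conversion, params)
  tables <- af_flow_tables(model)
  idx <- stats::setNames(seq_len(ns), model$states)
  therapy <- af_state_therapy()

  s <- idx[[sc$state]]
  cost <- arm$test_cost
  qaly <- 0
  death_cycle <- NA_integer_
  rows <- vector("list", T_)
  for (t in seq_len(T_)) {
    tb <- tables[[s]]
    j <- min(findInterval(u[t + 1], tb$cum) + 1, length(tb$dest))
    dest <- tb$dest[j]
    d <- discount_factor(params$discount_rate,
                         t - 1 + params$discount_from)
    c_t <- model$drug_cost[s] + tb$one_time_cost[j] +
      6 * (model$monthly_cost[s] + model$monthly_cost[dest])
    q_t <- model$utility[dest]
    if (model$states[s] == "DEAD") {
      c_t <- 0; q_t <- 0
    }
    cost <- cost + d * c_t
    qaly <- qaly + d * q_t
    rows[[t]] <- data.frame(
      cycle = t, state = model$states[s],
      therapy = therapy[[model$states[s]]] %||% NA_character_,
      event = tb$event[j], state_next = model$states[dest],
      disc_cost = unname(d * c_t), disc_qaly = unname(d * q_t),
      stringsAsFactors = FALSE)
    if (model$states[dest] == "DEAD" && model$states[s] != "DEAD" &&
        is.na(death_cycle)) {
      death_cycle <- t
    }
    s <- dest
  }
  structure(list(
    id = as.integer(id), group = sc$group,
    history = do.call(rbind, rows),
    death_cycle = death_cycle,
    cost = unname(cost), qaly = unname(qaly)
  ), class = "af_patient_history")
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

#' Simulate a cohort of independent patients
#'
#' Runs [simulate_patient()]'s event process for `n` independent synthetic
#' patients (vectorised over the cohort) and aggregates to the scale of
#' the modelled cohort: mean per-patient discounted cost and QALYs times
#' `cohort_size`, event totals per `cohort_size` patients, and Monte-Carlo
#' standard errors on the same scale.  By the law of large numbers these
#' estimates converge to the cohort engine's expectations, which is the
#' package's central validation property.
#'
#' @param n Number of simulated patients (>= 1); independent of
#'   `params$cohort_size`, which only sets the reporting scale.
#' @param seed Integer RNG seed.
#' @param arm An `af_arm`.
#' @param params A validated `af_params` object.
#' @return An object of class `af_microsim`: `cost`, `qaly`, `events`
#'   (named totals incl. `index_strokes`), their standard errors
#'   (`cost_se`, `qaly_se`, `events_se`), `n`, `seed`, and the per-patient
#'   `patient_cost`/`patient_qaly` vectors.
#' @export
simulate_cohort <- function(n, seed, arm, params) {
  stopifnot(n >= 1)
  T_ <- as.integer(params$horizon_cycles)
  u <- af_patient_uniforms(n, T_, seed)
  rates <- derive_therapy_rates(params)
  states <- af_states()
  ns <- length(states)
  post_stroke <- states %in% c("POST_STROKE_WARFARIN",
                               "POST_STROKE_ASPIRIN", "RECURRENT_STROKE")

  sizes <- vapply(arm$subcohorts, `[[`, numeric(1), "n")
  props <- sizes / sum(sizes)
  grp <- pmin(findInterval(u[, 1], cumsum(props)) + 1, length(props))

  models <- lapply(arm$subcohorts, function(sc)
    build_transition_model(rates, sc$conversion, params))
  tables <- lapply(models, af_flow_tables)
  idx <- stats::setNames(seq_len(ns), states)
  init_state <- vapply(arm$subcohorts, function(sc) idx[[sc$state]],
                       integer(1))

  state <- init_state[grp]
  cost <- rep(arm$test_cost, n)
  qaly <- numeric(n)
  etypes <- c(af_event_types(), "index_strokes")
  ev_count <- matrix(0, n, length(etypes), dimnames = list(NULL, etypes))

  for (t in seq_len(T_)) {
    d <- discount_factor(params$discount_rate, t - 1 + params$discount_from)
    state_next <- state
    for (g in seq_along(arm$subcohorts)) {
      m <- models[[g]]
      for (s in seq_len(ns)) {
        if (states[s] == "DEAD") next
        sel <- which(grp == g & state == s)
        if (length(sel) == 0) next
        tb <- tables[[g]][[s]]
        j <- pmin(findInterval(u[sel, t + 1], tb$cum) + 1, length(tb$dest))
        dest <- tb$dest[j]
        cost[sel] <- cost[sel] + d * (m$drug_cost[s] + tb$one_time_cost[j] +
          6 * (m$monthly_cost[s] + m$monthly_cost[dest]))
        qaly[sel] <- qaly[sel] + d * m$utility[dest]
        evj <- tb$event[j]
        real <- evj != "none"
        if (any(real)) {
          ii <- cbind(sel[real], match(evj[real], etypes))
          ev_count[ii] <- ev_count[ii] + 1
          is_stroke <- evj %in% c("stroke_fatal", "stroke_nonfatal") &
            !post_stroke[s]
          if (any(is_stroke)) {
            kk <- cbind(sel[is_stroke], match("index_strokes", etypes))
            ev_count[kk] <- ev_count[kk] + 1
          }
        }
        state_next[sel] <- dest
      }
    }
    state <- state_next
  }

  scale <- params$cohort_size
  structure(list(
    n = as.integer(n), seed = as.integer(seed), label = arm$label,
    cost = mean(cost) * scale,
    qaly = mean(qaly) * scale,
    events = colMeans(ev_count) * scale,
    cost_se = stats::sd(cost) / sqrt(n) * scale,
    qaly_se = stats::sd(qaly) / sqrt(n) * scale,
    events_se = apply(ev_count, 2, stats::sd) / sqrt(n) * scale,
    patient_cost = cost, patient_qaly = qaly
  ), class = "af_microsim")
}

#' Export simulated patient trajectories to CSV
#'
#' Writes one row per patient-cycle (patient id, group, cycle, state,
#' event, next state, discounted cost and QALY accrued) for a small
#' demonstration cohort.
#'
#' @param arm An `af_arm`.
#' @param params A validated `af_params` object.
#' @param n Number of patients to export.
#' @param seed Integer RNG seed.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectories_csv <- function(arm, params, n, seed, path) {
  rows <- lapply(seq_len(n), function(i) {
    h <- simulate_patient(arm, params, seed, id = i)
    cbind(id = h$id, group = h$group, h$history)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @export
print.af_microsim <- function(x, ...) {
  cat(sprintf("<af_microsim> %s: %d patients (seed %d)\n",
              x$label, x$n, x$seed))
  cat(sprintf("  cost $%.0f (se %.0f), QALYs %.2f (se %.3f) per cohort\n",
              x$cost, x$cost_se, x$qaly, x$qaly_se))
  invisible(x)
}
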