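# Independent brute-force oracle: expected discounted cost and QALYs for a
# single person by exhaustive enumeration of all event paths through the
# annotated flow table (no matrix algebra; recursion over flows).
oracle_expectation <- function(model, params, start_state, cycles) {
  fl <- model$flows
  rec <- function(s, t) {
    if (t > cycles) return(c(cost = 0, qaly = 0))
    d <- (1 + params$discount_rate)^(-(t - 1 + params$discount_from))
    rows <- which(fl$from == s)
    out <- c(cost = 0, qaly = 0)
    for (j in rows) {
      dest <- fl$to[j]
      c_t <- model$drug_cost[[s]] + fl$one_time_cost[j] +
        6 * (model$monthly_cost[[s]] + model$monthly_cost[[dest]])
      q_t <- model$utility[[dest]]
      out <- out + fl$prob[j] *
        (c(cost = d * c_t, qaly = d * q_t) + rec(dest, t + 1))
    }
    out
  }
  rec(start_state, 1)
}

# parameter set with overrides, as a plain helper
params_with <- function(...) {
  load_parameters(list(...))
}

# total strokes / extracranial bleeds from an arm result
n_strokes <- function(r) r$events[["stroke_fatal"]] + r$events[["stroke_nonfatal"]]
n_bleeds <- function(r) r$events[["bleed_fatal"]] + r$events[["bleed_nonfatal"]]
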