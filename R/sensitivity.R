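# Sensitivity analyses: one-way tornado, CHADS2 stroke-rate stratification,
# triangular sampling, probabilistic sensitivity analysis, variance shares.

# the seven varied quantities (grouped cost and utility multipliers count
# as one quantity each, varied simultaneously across their members)
af_varied_parameters <- function() {
  c("p_stroke_aspirin", "rr_stroke_warfarin", "p_bleed_warfarin",
    "rr_bleed_aspirin", "cost_genetic_test", "cost_multiplier",
    "utility_multiplier")
}

af_set_param <- function(params, key, value) {
  params[[key]] <- value
  params
}

#' One-way (tornado) sensitivity analysis
#'
#' Re-evaluates the test-vs-usual-care comparison with each varied
#' quantity set to the low and then the high bound of its declared range,
#' all other parameters held at base.  The seven varied quantities are the
#' aspirin stroke rate, the warfarin stroke relative risk, the warfarin
#' major-bleed rate, the aspirin bleed relative risk, the genetic-test
#' cost, and the grouped cost and utility multipliers (every event/drug
#' cost varied simultaneously by +/-50\%; every non-fatal-event-state
#' utility by +/-20\%).  The default adherence of 5.25\% is the rate at
#' which the base-case comparison is approximately cost neutral, so the
#' bars show how far each parameter alone can push the ICER.
#'
#' @param params A validated `af_params` object with ranges for all seven
#'   varied quantities.
#' @param adherence Test-positive adherence fraction at which the
#'   comparison is evaluated.
#' @return A `data.frame` (one row per varied quantity) with the low/high
#'   input values, the ICER or dominance label at each bound, and the bar
#'   width `|icer_high - icer_low|` where both ICERs are defined.
#' @export
one_way_tornado <- function(params, adherence = 0.0525) {
  varied <- af_varied_parameters()
  missing_rng <- setdiff(varied, names(params$ranges))
  if (length(missing_rng) > 0) {
    stop("configuration error: no sensitivity range declared for: ",
         paste(missing_rng, collapse = ", "), call. = FALSE)
  }
  rows <- lapply(varied, function(key) {
    rng <- params$ranges[[key]]
    at <- function(value) {
      evaluate_comparison(af_set_param(params, key, value), adherence)
    }
    lo <- at(rng[1]); hi <- at(rng[2])
    data.frame(
      parameter = key, low = rng[1], high = rng[2],
      icer_low = lo$icer, icer_high = hi$icer,
      label_low = lo$label, label_high = hi$label,
      bar_width = if (is.na(lo$icer) || is.na(hi$icer)) NA_real_
                  else abs(hi$icer - lo$icer),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Default CHADS2 stroke-rate grid
#'
#' Annual ischemic-stroke rates on aspirin by CHADS2 score, read from the
#' packaged configuration file.  The packaged defaults are the widely used
#' published per-score rates from the CHADS2 validation literature; they
#' are an external-sourced default and can be replaced by any
#' `(label, rate)` grid.
#'
#' @param path Optional path to a YAML file with a `levels` list of
#'   `{label, p_stroke_aspirin}` entries; defaults to the packaged grid.
#' @return A `data.frame` with columns `label` and `p_stroke_aspirin`.
#' @export
default_chads2_grid <- function(path = system.file("extdata",
                                                   "chads2_stroke_rates.yaml",
                                                   package = "afcea")) {
  cfg <- yaml::read_yaml(path)
  do.call(rbind, lapply(cfg$levels, function(lv) {
    data.frame(label = as.character(lv$label),
               p_stroke_aspirin = af_normalize_value("p_stroke_aspirin",
                                                     lv$p_stroke_aspirin),
               stringsAsFactors = FALSE)
  }))
}

#' CHADS2 stroke-rate stratification
#'
#' Re-runs the test-vs-usual-care comparison with the aspirin stroke rate
#' replaced by each level of a CHADS2 stroke-rate grid, reporting QALYs
#' gained per cohort and the ICER or dominance label per level.  The
#' default adherence matches the tornado's cost-neutral 5.25\%, at which
#' the strategy switches from ICER-positive to dominating as the
#' underlying stroke risk rises.
#'
#' @param params A validated `af_params` object.
#' @param grid A `data.frame` with columns `label` (CHADS2 score) and
#'   `p_stroke_aspirin` (annual fraction); defaults to
#'   [default_chads2_grid()].
#' @param adherence Test-positive adherence fraction.
#' @return A `data.frame` with one row per grid level: `label`,
#'   `p_stroke_aspirin`, `qalys_gained`, `cost_saving`, `icer`, `label_cea`.
#' @export
chads2_sweep <- function(params, grid = default_chads2_grid(),
                         adherence = 0.0525) {
  stopifnot(all(c("label", "p_stroke_aspirin") %in% names(grid)))
  if (any(grid$p_stroke_aspirin <= 0)) {
    stop("stroke rates in the CHADS2 grid must be positive", call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    p <- af_set_param(params, "p_stroke_aspirin", grid$p_stroke_aspirin[i])
    # keep the range bracketing the replaced base value
    p$ranges$p_stroke_aspirin <- range(c(p$ranges$p_stroke_aspirin,
                                         grid$p_stroke_aspirin[i]))
    cmp <- evaluate_comparison(p, adherence)
    data.frame(label = grid$label[i],
               p_stroke_aspirin = grid$p_stroke_aspirin[i],
               qalys_gained = cmp$d_qaly,
               cost_saving = -cmp$d_cost,
               icer = cmp$icer,
               label_cea = cmp$label,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Draw from a triangular distribution
#'
#' Inverse-CDF sampling from the triangular distribution on
#' `[low, high]` with mode `mode`.  Degenerate edges (`low == mode`,
#' `mode == high`, or a single point) are handled exactly.
#'
#' @param n Number of draws.
#' @param low,mode,high Distribution support and mode, `low <= mode <=
#'   high`.
#' @return Numeric vector of `n` draws.
#' @export
#' @examples
#' set.seed(1)
#' mean(sample_triangular(1e4, 3, 4.5, 6))  # ~ (3 + 4.5 + 6) / 3
sample_triangular <- function(n, low, mode, high) {
  if (!(low <= mode && mode <= high)) {
    stop("triangular distribution requires low <= mode <= high",
         call. = FALSE)
  }
  if (low == high) return(rep(low, n))
  u <- stats::runif(n)
  fc <- (mode - low) / (high - low)
  ifelse(u < fc,
         low + sqrt(u * (high - low) * (mode - low)),
         high - sqrt((1 - u) * (high - low) * (high - mode)))
}

#' Probabilistic sensitivity analysis
#'
#' Monte-Carlo propagation of parameter uncertainty: each trial draws the
#' seven varied quantities independently from triangular distributions
#' (mode at the base-case value, bounds at the declared ranges), evaluates
#' the incremental cost and QALY differential of the test strategy at the
#' given adherence, and accumulates the cost-effectiveness-plane sample.
#' Reproducible from the seed.
#'
#' @param params A validated `af_params` object.
#' @param n_draws Number of Monte-Carlo trials (>= 1).
#' @param adherence Test-positive adherence fraction; the default 0.20
#'   matches the reporting convention for the dominant-quadrant fraction.
#' @param seed Integer RNG seed.
#' @param wtp Willingness-to-pay used for the net-monetary-benefit outcome
#'   of the variance decomposition.
#' @return An object of class `af_psa`: the draw matrix (`n_draws` x 7),
#'   per-draw `d_cost` and `d_qaly`, net monetary benefit `nmb`, quadrant
#'   fractions of the cost-effectiveness plane (`quadrants`, summing to
#'   1; `frac_dominant` is the fraction with lower cost and more QALYs),
#'   per-parameter variance-contribution `shares`, and the `seed`.
#' @export
run_psa <- function(params, n_draws = 10000, adherence = 0.20,
                    seed = 1, wtp = params$wtp_per_qaly) {
  stopifnot(n_draws >= 1)
  varied <- af_varied_parameters()
  missing_rng <- setdiff(varied, names(params$ranges))
  if (length(missing_rng) > 0) {
    stop("configuration error: no sensitivity range declared for: ",
         paste(missing_rng, collapse = ", "), call. = FALSE)
  }
  set.seed(as.integer(seed))
  draws <- vapply(varied, function(key) {
    rng <- params$ranges[[key]]
    sample_triangular(n_draws, rng[1], params[[key]], rng[2])
  }, numeric(n_draws))
  draws <- matrix(draws, nrow = n_draws,
                  dimnames = list(NULL, varied))

  d_cost <- numeric(n_draws)
  d_qaly <- numeric(n_draws)
  for (i in seq_len(n_draws)) {
    p <- params
    for (key in varied) p[[key]] <- unname(draws[i, key])
    cmp <- evaluate_comparison(p, adherence)
    d_cost[i] <- cmp$d_cost
    d_qaly[i] <- cmp$d_qaly
  }
  nmb <- wtp * d_qaly - d_cost
  quadrants <- c(
    dominant = mean(d_cost < 0 & d_qaly > 0),
    costly_effective = mean(d_cost >= 0 & d_qaly > 0),
    dominated = mean(d_cost >= 0 & d_qaly <= 0),
    cheap_ineffective = mean(d_cost < 0 & d_qaly <= 0)
  )
  res <- structure(list(
    draws = draws, d_cost = d_cost, d_qaly = d_qaly, nmb = nmb,
    quadrants = quadrants, frac_dominant = quadrants[["dominant"]],
    adherence = adherence, wtp = wtp, seed = as.integer(seed)
  ), class = "af_psa")
  res$shares <- variance_contributions(res)
  res
}

#' Variance contributions of the PSA parameters
#'
#' Attributes the spread of the PSA outcome (incremental net monetary
#' benefit at the analysis willingness-to-pay) to the varied parameters:
#' each parameter's share is its squared Pearson correlation with the
#' outcome across draws, normalized so the shares sum to 1.  For
#' independent draws and an approximately linear outcome this equals the
#' first-order variance decomposition.
#'
#' @param result An `af_psa` object with at least 2 draws.
#' @return Named numeric vector of shares in \[0, 1\] summing to 1, or an
#'   all-`NA` vector if the outcome has zero variance.
#' @export
variance_contributions <- function(result) {
  if (length(result$nmb) < 2) {
    stop("variance decomposition needs at least 2 draws", call. = FALSE)
  }
  out <- stats::setNames(rep(NA_real_, ncol(result$draws)),
                         colnames(result$draws))
  if (stats::var(result$nmb) <= 0) return(out)
  r2 <- vapply(colnames(result$draws), function(key) {
    x <- result$draws[, key]
    if (stats::var(x) <= 0) return(0)
    stats::cor(x, result$nmb)^2
  }, numeric(1))
  if (sum(r2) == 0) return(out)
  r2 / sum(r2)
}

#' @export
print.af_psa <- function(x, ...) {
  cat(sprintf("<af_psa> %d draws at adherence %.1f%% (seed %d)\n",
              length(x$d_cost), 100 * x$adherence, x$seed))
  cat(sprintf("  dominant quadrant (cheaper & more QALYs): %.1f%%\n",
              100 * x$frac_dominant))
  sh <- sort(x$shares, decreasing = TRUE)
  cat("  variance shares:",
      paste(sprintf("%s=%.2f", names(sh), sh), collapse = ", "), "\n")
  invisible(x)
}
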