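# Incremental cost-effectiveness arithmetic, dominance classification,
# adherence-threshold searches, and the adherence sweep.

#' Incremental cost-effectiveness comparison of two evaluated arms
#'
#' Computes the cost differential, QALY differential and, where a ratio is
#' meaningful, the incremental cost-effectiveness ratio of the test
#' strategy relative to usual care.  When the test strategy costs less and
#' yields more QALYs it dominates and no ICER is reported; the converse
#' labels usual care dominant.
#'
#' @param test,usual `af_arm_result` objects evaluated under the same
#'   parameter set.
#' @param tol Differences smaller than `tol` in absolute value are treated
#'   as zero when classifying dominance.
#' @return An object of class `af_cea`: `d_cost`, `d_qaly`, `icer` (`NA`
#'   unless the label is `icer_defined`), and `label` in
#'   `test_dominates`, `usual_dominates`, `icer_defined`, `equivalent`.
#' @export
#' @examples
#' p <- default_parameters()
#' cmp <- compute_icer(evaluate_arm(build_test_arm(p, 0.021), p),
#'                     evaluate_arm(build_usual_care_arm(p), p))
#' cmp$icer
compute_icer <- function(test, usual, tol = 1e-9) {
  d_cost <- test$cost - usual$cost
  d_qaly <- test$qaly - usual$qaly
  zc <- abs(d_cost) <= tol
  zq <- abs(d_qaly) <= tol
  if (zc && zq) {
    label <- "equivalent"; icer <- NA_real_
  } else if (d_cost <= tol && d_qaly >= -tol) {
    label <- "test_dominates"; icer <- NA_real_
  } else if (d_cost >= -tol && d_qaly <= tol) {
    label <- "usual_dominates"; icer <- NA_real_
  } else {
    label <- "icer_defined"; icer <- d_cost / d_qaly
  }
  structure(list(d_cost = d_cost, d_qaly = d_qaly, icer = icer,
                 label = label), class = "af_cea")
}

#' Evaluate the test-vs-usual-care comparison at one adherence rate
#'
#' Convenience wrapper: builds both arms from the parameter set, evaluates
#' each with the cohort engine, and returns their incremental comparison
#' with the arm results attached.
#'
#' @param params A validated `af_params` object.
#' @param adherence Fraction of test-positive patients adhering to
#'   warfarin.
#' @return An `af_cea` with `$test` and `$usual` arm results attached.
#' @export
evaluate_comparison <- function(params, adherence) {
  usual <- evaluate_arm(build_usual_care_arm(params), params)
  test <- evaluate_arm(build_test_arm(params, adherence), params)
  cmp <- compute_icer(test, usual)
  cmp$test <- test
  cmp$usual <- usual
  cmp
}

# bisection on [0, 1] for f(a) <= 0, assuming a single crossing
af_bisect_adherence <- function(f, tol = 1e-5) {
  lo <- 0; hi <- 1
  flo <- f(lo); fhi <- f(hi)
  if (flo <= 0) return(0)
  if (fhi > 0) return(NA_real_)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) <= 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Smallest adherence at which the test strategy is cost-effective
#'
#' Finds, by bisection to absolute tolerance `tol`, the smallest fraction
#' of adhering test-positive patients at which the test strategy's ICER
#' against usual care falls at or below the willingness-to-pay threshold
#' (or the test strategy dominates).  Because the incremental cost and
#' QALY differentials are affine in adherence, the crossing is unique.
#'
#' @param params A validated `af_params` object.
#' @param wtp Willingness-to-pay threshold (USD/QALY); defaults to
#'   `params$wtp_per_qaly`.
#' @param tol Absolute bisection tolerance on the adherence fraction.
#' @return The threshold adherence fraction, or `NA` if no adherence in
#'   \[0, 1\] qualifies.
#' @export
find_cost_effective_adherence <- function(params, wtp = params$wtp_per_qaly,
                                          tol = 1e-5) {
  if (!is.numeric(wtp) || wtp <= 0) stop("wtp must be positive", call. = FALSE)
  # ICER <= wtp (with d_qaly > 0), and dominance, are both equivalent to a
  # non-negative incremental net monetary benefit
  f <- function(a) {
    cmp <- evaluate_comparison(params, a)
    cmp$d_cost - wtp * cmp$d_qaly
  }
  af_bisect_adherence(f, tol)
}

#' Break-even adherence: smallest adherence making the test strategy cost
#' saving
#'
#' Finds, by bisection to absolute tolerance `tol`, the adherence fraction
#' at which the test strategy's total discounted cost equals usual
#' care's.  Above this fraction the test strategy saves money outright.
#'
#' @inheritParams find_cost_effective_adherence
#' @return The break-even adherence fraction, or `NA` if incremental cost
#'   does not change sign on \[0, 1\].
#' @export
find_breakeven_adherence <- function(params, tol = 1e-5) {
  f <- function(a) evaluate_comparison(params, a)$d_cost
  af_bisect_adherence(f, tol)
}

#' Adherence sweep of savings and QALY gains
#'
#' Evaluates the test-vs-usual-care comparison over a grid of adherence
#' rates and tabulates, per modelled cohort, the signed cost saving
#' (positive = the test strategy saves money), the QALYs gained, and the
#' ICER or dominance label.
#'
#' @param params A validated `af_params` object.
#' @param adherence Vector of adherence fractions; the default grid is
#'   1--50\%.
#' @return A `data.frame` with columns `adherence_pct`, `cost_saving`,
#'   `qalys_gained`, `icer`, `label`.
#' @export
#' @examples
#' adherence_sweep(default_parameters(), adherence = c(0.01, 0.20))
adherence_sweep <- function(params,
                            adherence = c(0.01, 0.02, 0.03, 0.04, 0.05,
                                          0.075, 0.10, 0.15, 0.20, 0.25,
                                          0.30, 0.40, 0.50)) {
  rows <- lapply(adherence, function(a) {
    cmp <- evaluate_comparison(params, a)
    data.frame(adherence_pct = 100 * a,
               cost_saving = -cmp$d_cost,
               qalys_gained = cmp$d_qaly,
               icer = if (is.na(cmp$icer)) NA_real_ else cmp$icer,
               label = cmp$label,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
print.af_cea <- function(x, ...) {
  cat(sprintf("<af_cea> d_cost $%.0f, d_QALY %.3f: %s",
              x$d_cost, x$d_qaly, x$label))
  if (!is.na(x$icer)) cat(sprintf(" (ICER $%.0f/QALY)", x$icer))
  cat("\n")
  invisible(x)
}
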