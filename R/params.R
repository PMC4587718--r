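# Model parameters: definition, loading, validation, derived therapy rates.

af_param_defaults <- function() {
  list(
    # annual event probabilities and relative risks
    p_stroke_aspirin = 0.045,
    rr_stroke_warfarin = 0.48,
    p_bleed_warfarin = 0.025,
    rr_bleed_aspirin = 0.59,
    frac_ich = 0.2,
    frac_fatal_stroke_warfarin = 0.082,
    frac_fatal_stroke_aspirin = 0.179,
    frac_fatal_ich = 0.364,
    frac_fatal_bleed_excl_ich = 0.049,
    # costs, 2005 USD
    cost_warfarin_annual = 180,
    cost_aspirin_annual = 10,
    cost_fatal_stroke_once = 12130,
    cost_stroke_once_warfarin = 9667,
    cost_stroke_monthly_warfarin = 2652,
    cost_stroke_once_aspirin = 9610,
    cost_stroke_monthly_aspirin = 2168,
    cost_ich_once = 31810,
    cost_ich_monthly = 4690,
    cost_bleed_excl_ich_once = 3620,
    cost_genetic_test = 100,
    # utilities
    u_well_warfarin = 0.987,
    u_well_aspirin = 0.998,
    u_stroke_warfarin = 0.476,
    u_stroke_aspirin = 0.426,
    u_ich = 0.4,
    u_recurrent_stroke = 0.12,
    u_dead = 0,
    # structural constants
    cohort_size = 1000,
    horizon_cycles = 5,
    discount_rate = 0.03,
    test_positive_fraction = 0.40,
    p_convert_base = 0.025,
    conv_mult_test_positive = 2.0,
    conv_mult_test_negative = 0.5,
    wtp_per_qaly = 50000,
    # grouped sensitivity multipliers (1 = base case)
    cost_multiplier = 1.0,
    utility_multiplier = 1.0,
    # structural calibration switch: first-cycle discount exponent (0 or 1)
    discount_from = 0,
    # sensitivity ranges: low/high bounds, mode at the base-case value
    ranges = list(
      p_stroke_aspirin = c(0.03, 0.06),
      rr_stroke_warfarin = c(0.37, 0.63),
      p_bleed_warfarin = c(0.02, 0.04),
      rr_bleed_aspirin = c(0.50, 0.70),
      cost_genetic_test = c(50, 200),
      cost_multiplier = c(0.5, 1.5),
      utility_multiplier = c(0.8, 1.2)
    )
  )
}

# keys whose values the config may express as percent strings ("4.5%")
af_percent_ok_keys <- function() {
  c("p_stroke_aspirin", "p_bleed_warfarin", "frac_ich",
    "frac_fatal_stroke_warfarin", "frac_fatal_stroke_aspirin",
    "frac_fatal_ich", "frac_fatal_bleed_excl_ich",
    "test_positive_fraction", "p_convert_base", "discount_rate")
}

af_normalize_value <- function(key, value) {
  if (is.character(value)) {
    value <- trimws(value)
    if (grepl("%$", value)) {
      num <- suppressWarnings(as.numeric(sub("%$", "", value)))
      if (is.na(num)) {
        stop("configuration error: key '", key, "' has unparseable value '",
             value, "'", call. = FALSE)
      }
      return(num / 100)
    }
    num <- suppressWarnings(as.numeric(value))
    if (is.na(num)) {
      stop("configuration error: key '", key, "' has unparseable value '",
           value, "'", call. = FALSE)
    }
    return(num)
  }
  if (!is.numeric(value)) {
    stop("configuration error: key '", key, "' must be numeric", call. = FALSE)
  }
  as.numeric(value)  # YAML integers become doubles, like the defaults
}

#' Base-case model parameters
#'
#' Returns the fully populated base-case parameter set: annual event
#' probabilities and relative risks for stroke and major hemorrhage under
#' aspirin and warfarin, event fatality fractions, 2005-USD costs, state
#' utilities, structural constants (cohort of 1000 patients, 5 one-year
#' cycles, 3\% annual discount, 40\% test-positive fraction, 2.5\%/yr
#' background conversion to warfarin with 2-fold multipliers by test
#' result), and the sensitivity ranges used by the one-way and
#' probabilistic analyses.
#'
#' @return An object of class `af_params`: a named list of parameter values
#'   plus a `ranges` sub-list of `(low, high)` bounds for the varied
#'   quantities.
#' @seealso [load_parameters()] to override values from a configuration
#'   file, [derive_therapy_rates()] for the therapy-specific rates.
#' @export
#' @examples
#' p <- default_parameters()
#' p$p_stroke_aspirin
default_parameters <- function() {
  params <- af_param_defaults()
  class(params) <- "af_params"
  attr(params, "provenance") <- list(supplied = character(0),
                                     defaulted = setdiff(names(params), "ranges"))
  validate_parameters(params)
  params
}

#' Load model parameters from a configuration source
#'
#' Builds a validated parameter set from a flat key-value configuration,
#' filling any missing key with its base-case default.  The configuration
#' may be `NULL` (pure defaults), a named list, or the path to a YAML file
#' whose keys mirror the fields of [default_parameters()], with an optional
#' `ranges` sub-table of `(low, high)` bounds.  Probability-like keys
#' accept percent strings (`"4.5%"` is read as 0.045), a convenience for
#' hand-edited files.
#'
#' @param config `NULL`, a named list, or a YAML file path.
#' @return A validated `af_params` object.  The `"provenance"` attribute
#'   records which keys were supplied and which were defaulted.
#' @export
#' @examples
#' p <- load_parameters(list(discount_rate = 0))
#' attr(p, "provenance")$supplied
load_parameters <- function(config = NULL) {
  if (is.null(config)) {
    return(default_parameters())
  }
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      stop("configuration error: file '", config, "' not found", call. = FALSE)
    }
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  if (!is.list(config)) {
    stop("configuration error: config must be NULL, a named list, ",
         "or a YAML file path", call. = FALSE)
  }
  defaults <- af_param_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    stop("configuration error: unknown key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  params <- defaults
  for (key in setdiff(names(config), "ranges")) {
    params[[key]] <- af_normalize_value(key, config[[key]])
  }
  if (!is.null(config$ranges)) {
    if (!is.list(config$ranges)) {
      stop("configuration error: 'ranges' must be a table of ",
           "(low, high) pairs", call. = FALSE)
    }
    bad <- setdiff(names(config$ranges), names(defaults$ranges))
    if (length(bad) > 0) {
      stop("configuration error: unknown range key(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    for (key in names(config$ranges)) {
      rng <- as.numeric(unlist(config$ranges[[key]]))
      if (length(rng) != 2L || any(is.na(rng))) {
        stop("configuration error: range for '", key,
             "' must be two numbers (low, high)", call. = FALSE)
      }
      params$ranges[[key]] <- rng
    }
  }
  # an overridden base value may fall outside the default sensitivity
  # range; widen ranges not explicitly supplied so they keep bracketing it
  explicit_ranges <- names(config$ranges)
  for (key in setdiff(names(params$ranges), explicit_ranges)) {
    base <- params[[key]]
    if (is.numeric(base) && length(base) == 1 && !is.na(base)) {
      params$ranges[[key]] <- c(min(params$ranges[[key]][1], base),
                                max(params$ranges[[key]][2], base))
    }
  }
  class(params) <- "af_params"
  attr(params, "provenance") <- list(
    supplied = intersect(names(config), names(defaults)),
    defaulted = setdiff(setdiff(names(defaults), "ranges"), names(config))
  )
  validate_parameters(params)
  params
}

# base value corresponding to a range key (multipliers have base 1)
af_range_base <- function(params, key) {
  params[[key]]
}

#' Validate a parameter set
#'
#' Checks every invariant of the parameter set: probabilities, fractions
#' and utilities in \[0, 1\]; relative risks positive; costs non-negative;
#' derived therapy-specific probabilities in \[0, 1\]; each sensitivity
#' range ordered around its base value; structural constants positive.
#' All violations are collected and reported together.
#'
#' @param params An `af_params` object (or plain named list with the same
#'   fields).
#' @return `params`, invisibly, if valid; otherwise an error listing every
#'   violated invariant.
#' @export
validate_parameters <- function(params) {
  bad <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) bad <<- c(bad, msg)

  prob_keys <- c("p_stroke_aspirin", "p_bleed_warfarin", "frac_ich",
                 "frac_fatal_stroke_warfarin", "frac_fatal_stroke_aspirin",
                 "frac_fatal_ich", "frac_fatal_bleed_excl_ich",
                 "test_positive_fraction", "p_convert_base")
  for (key in prob_keys) {
    v <- params[[key]]
    chk(is.numeric(v) && length(v) == 1 && v >= 0 && v <= 1,
        paste0(key, " must be a probability in [0, 1] (got ",
               format(params[[key]]), ")"))
  }
  for (key in c("rr_stroke_warfarin", "rr_bleed_aspirin",
                "conv_mult_test_positive", "conv_mult_test_negative")) {
    v <- params[[key]]
    chk(is.numeric(v) && length(v) == 1 && v > 0,
        paste0(key, " must be > 0"))
  }
  cost_keys <- grep("^cost_", names(af_param_defaults()), value = TRUE)
  for (key in cost_keys) {
    v <- params[[key]]
    chk(is.numeric(v) && length(v) == 1 && v >= 0,
        paste0(key, " must be a non-negative cost"))
  }
  util_keys <- grep("^u_", names(af_param_defaults()), value = TRUE)
  for (key in util_keys) {
    v <- params[[key]]
    chk(is.numeric(v) && length(v) == 1 && v >= 0 && v <= 1,
        paste0(key, " must be a utility in [0, 1]"))
  }
  chk(params$cohort_size > 0, "cohort_size must be positive")
  chk(params$horizon_cycles >= 1, "horizon_cycles must be at least 1")
  chk(params$discount_rate >= 0, "discount_rate must be non-negative")
  chk(params$discount_from %in% c(0, 1), "discount_from must be 0 or 1")
  chk(params$cost_multiplier >= 0, "cost_multiplier must be non-negative")
  chk(params$utility_multiplier >= 0, "utility_multiplier must be non-negative")
  chk(params$wtp_per_qaly > 0, "wtp_per_qaly must be positive")

  # derived probabilities stay in [0, 1]
  if (is.numeric(params$p_stroke_aspirin) && is.numeric(params$rr_stroke_warfarin)) {
    d <- params$p_stroke_aspirin * params$rr_stroke_warfarin
    chk(d >= 0 && d <= 1,
        "derived p_stroke_warfarin = p_stroke_aspirin * rr_stroke_warfarin must lie in [0, 1]")
  }
  if (is.numeric(params$p_bleed_warfarin) && is.numeric(params$rr_bleed_aspirin)) {
    d <- params$p_bleed_warfarin * params$rr_bleed_aspirin
    chk(d >= 0 && d <= 1,
        "derived p_bleed_aspirin = p_bleed_warfarin * rr_bleed_aspirin must lie in [0, 1]")
  }

  for (key in names(params$ranges)) {
    rng <- params$ranges[[key]]
    base <- af_range_base(params, key)
    chk(length(rng) == 2 && is.numeric(rng) && rng[1] <= rng[2],
        paste0("range for ", key, " must be an ordered (low, high) pair"))
    if (length(rng) == 2 && is.numeric(rng) && is.numeric(base)) {
      chk(rng[1] <= base && base <= rng[2],
          paste0("range for ", key, " must bracket its base value ",
                 format(base)))
    }
  }

  if (length(bad) > 0) {
    stop("invalid parameters:\n  - ", paste(bad, collapse = "\n  - "),
         call. = FALSE)
  }
  invisible(params)
}

#' Derive therapy-specific annual event rates
#'
#' Expands the parameter set into per-therapy annual rates: warfarin's
#' stroke probability is the aspirin stroke probability scaled by the
#' stroke relative risk of warfarin (base 0.045 x 0.48 = 0.0216), and
#' aspirin's major-hemorrhage probability is warfarin's scaled by the
#' hemorrhage relative risk of aspirin (base 0.025 x 0.59 = 0.01475).
#' Stroke fatality fractions are therapy-specific; bleed fatality
#' fractions are event-type-specific (intracranial vs extracranial) and
#' shared between therapies.
#'
#' @param params A validated `af_params` object.
#' @return An object of class `af_therapy_rates`: a list with `aspirin`
#'   and `warfarin` components, each holding `p_stroke`,
#'   `frac_fatal_stroke`, `p_bleed`, `frac_ich`, `frac_fatal_ich` and
#'   `frac_fatal_bleed_excl_ich`.
#' @export
#' @examples
#' derive_therapy_rates(default_parameters())$warfarin$p_stroke
derive_therapy_rates <- function(params) {
  p_stroke_w <- params$p_stroke_aspirin * params$rr_stroke_warfarin
  p_bleed_a <- params$p_bleed_warfarin * params$rr_bleed_aspirin
  if (p_stroke_w < 0 || p_stroke_w > 1) {
    stop("derived warfarin stroke probability ", format(p_stroke_w),
         " outside [0, 1]", call. = FALSE)
  }
  if (p_bleed_a < 0 || p_bleed_a > 1) {
    stop("derived aspirin hemorrhage probability ", format(p_bleed_a),
         " outside [0, 1]", call. = FALSE)
  }
  mk <- function(label, p_stroke, frac_fatal_stroke, p_bleed) {
    list(therapy = label, p_stroke = p_stroke,
         frac_fatal_stroke = frac_fatal_stroke, p_bleed = p_bleed,
         frac_ich = params$frac_ich,
         frac_fatal_ich = params$frac_fatal_ich,
         frac_fatal_bleed_excl_ich = params$frac_fatal_bleed_excl_ich)
  }
  out <- list(
    aspirin = mk("aspirin", params$p_stroke_aspirin,
                 params$frac_fatal_stroke_aspirin, p_bleed_a),
    warfarin = mk("warfarin", p_stroke_w,
                  params$frac_fatal_stroke_warfarin, params$p_bleed_warfarin)
  )
  class(out) <- "af_therapy_rates"
  out
}

#' Serialize a parameter set to YAML
#'
#' Writes every parameter field (including the `ranges` table) to a YAML
#' file that [load_parameters()] reads back bit-exactly, using full
#' double precision.
#'
#' @param params An `af_params` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  x <- unclass(params)
  attr(x, "provenance") <- NULL
  yaml::write_yaml(x, path, precision = 17)
  invisible(path)
}

#' @export
print.af_params <- function(x, ...) {
  cat("<af_params> base-case model parameters\n")
  cat(sprintf("  cohort %d patients, %d one-year cycles, %.1f%% discount\n",
              as.integer(x$cohort_size), as.integer(x$horizon_cycles),
              100 * x$discount_rate))
  cat(sprintf("  stroke on aspirin %.3f/yr (RR warfarin %.2f); major bleed on warfarin %.3f/yr (RR aspirin %.2f)\n",
              x$p_stroke_aspirin, x$rr_stroke_warfarin,
              x$p_bleed_warfarin, x$rr_bleed_aspirin))
  cat(sprintf("  test-positive fraction %.2f, conversion %.3f/yr (x%.1f pos, x%.1f neg), test cost $%g\n",
              x$test_positive_fraction, x$p_convert_base,
              x$conv_mult_test_positive, x$conv_mult_test_negative,
              x$cost_genetic_test))
  cat(sprintf("  %d sensitivity ranges declared\n", length(x$ranges)))
  invisible(x)
}
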