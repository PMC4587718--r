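# Run orchestration and report generation: one command per analysis, each
# writing its artifact(s) plus a run manifest.

af_manifest <- function(command, params, extra = list()) {
  c(list(
    command = command,
    package_version = as.character(utils::packageVersion("afcea")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    parameters = {
      x <- unclass(params)
      attr(x, "provenance") <- NULL
      x
    },
    provenance = attr(params, "provenance")
  ), extra)
}

af_write_artifacts <- function(name, manifest, tables = list(),
                               json = NULL, out_dir = NULL) {
  if (is.null(out_dir)) return(invisible(NULL))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  jsonlite::write_json(manifest,
                       file.path(out_dir, paste0(name, "_manifest.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (nm in names(tables)) {
    utils::write.csv(tables[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                     row.names = FALSE, quote = FALSE)
  }
  if (!is.null(json)) {
    jsonlite::write_json(json, file.path(out_dir, paste0(name, ".json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(NULL)
}

#' Base-case comparison report
#'
#' Evaluates both strategies at one adherence rate and reports the
#' incremental comparison (cost and QALY differentials, ICER or dominance
#' label), the cost-effectiveness and break-even adherence thresholds,
#' and the two-row strategy table.
#'
#' @param config `NULL`, a named list, or a YAML config path (see
#'   [load_parameters()]).
#' @param adherence Test-positive adherence fraction.
#' @param wtp Willingness-to-pay (USD/QALY) for the threshold search;
#'   defaults to the configured value.
#' @param out_dir Optional directory to write `base_case.json`, the
#'   strategy table CSV and a run manifest.
#' @return A list with the `af_cea` comparison, thresholds (fractions and
#'   percent rounded to 0.1), and the strategy table, invisibly when
#'   writing files.
#' @export
cmd_base_case <- function(config = NULL, adherence = 0.021, wtp = NULL,
                          out_dir = NULL) {
  params <- load_parameters(config)
  if (!is.null(wtp)) params$wtp_per_qaly <- wtp
  cmp <- evaluate_comparison(params, adherence)
  a_ce <- find_cost_effective_adherence(params)
  a_be <- find_breakeven_adherence(params)
  tab <- strategy_table(cmp$usual, cmp$test)
  report <- list(
    adherence = adherence,
    d_cost = cmp$d_cost, d_qaly = cmp$d_qaly,
    icer = cmp$icer, label = cmp$label,
    cost_effective_adherence = a_ce,
    cost_effective_adherence_pct = round(100 * a_ce, 1),
    breakeven_adherence = a_be,
    breakeven_adherence_pct = round(100 * a_be, 1),
    wtp_per_qaly = params$wtp_per_qaly
  )
  af_write_artifacts("base_case",
                     af_manifest("base_case", params,
                                 list(adherence = adherence)),
                     tables = list(strategy_table = tab),
                     json = report, out_dir = out_dir)
  out <- list(comparison = cmp, report = report, strategy_table = tab,
              params = params)
  if (is.null(out_dir)) out else invisible(out)
}

#' Adherence sweep report
#'
#' Evaluates the comparison over a grid of adherence rates and emits the
#' sweep table (adherence \%, cost saving (loss) in USD, QALYs gained).
#'
#' @inheritParams cmd_base_case
#' @param adherence Vector of adherence fractions (default 1--50\%).
#' @return The sweep `data.frame` (invisibly when writing files).
#' @export
cmd_sweep <- function(config = NULL,
                      adherence = c(0.01, 0.02, 0.03, 0.04, 0.05, 0.075,
                                    0.10, 0.15, 0.20, 0.25, 0.30, 0.40,
                                    0.50),
                      out_dir = NULL) {
  params <- load_parameters(config)
  sweep <- if (length(adherence) == 0) {
    data.frame(adherence_pct = numeric(0), cost_saving = numeric(0),
               qalys_gained = numeric(0), icer = numeric(0),
               label = character(0), stringsAsFactors = FALSE)
  } else {
    adherence_sweep(params, adherence)
  }
  af_write_artifacts("adherence_sweep",
                     af_manifest("sweep", params,
                                 list(adherence = adherence)),
                     tables = list(adherence_sweep = sweep),
                     out_dir = out_dir)
  if (is.null(out_dir)) sweep else invisible(sweep)
}

#' Tornado report
#'
#' @inheritParams cmd_base_case
#' @param adherence Adherence fraction for the one-way analysis (default
#'   the cost-neutral 5.25\%).
#' @return The tornado `data.frame` (invisibly when writing files).
#' @export
cmd_tornado <- function(config = NULL, adherence = 0.0525, out_dir = NULL) {
  params <- load_parameters(config)
  tor <- one_way_tornado(params, adherence)
  af_write_artifacts("tornado",
                     af_manifest("tornado", params,
                                 list(adherence = adherence)),
                     tables = list(tornado = tor), out_dir = out_dir)
  if (is.null(out_dir)) tor else invisible(tor)
}

#' Probabilistic sensitivity analysis report
#'
#' Runs the seeded Monte-Carlo PSA and emits the cost-effectiveness-plane
#' sample (one row per draw), the quadrant fractions and the
#' variance-contribution shares.
#'
#' @inheritParams cmd_base_case
#' @param n_draws Number of Monte-Carlo trials.
#' @param adherence Adherence fraction (default 0.20).
#' @param seed Integer RNG seed (always recorded in the manifest).
#' @return The `af_psa` object (invisibly when writing files).
#' @export
cmd_psa <- function(config = NULL, n_draws = 10000, adherence = 0.20,
                    seed = 1, out_dir = NULL) {
  params <- load_parameters(config)
  psa <- run_psa(params, n_draws = n_draws, adherence = adherence,
                 seed = seed)
  plane <- data.frame(draw = seq_along(psa$d_cost),
                      d_cost = psa$d_cost, d_qaly = psa$d_qaly)
  af_write_artifacts("psa",
                     af_manifest("psa", params,
                                 list(n_draws = n_draws,
                                      adherence = adherence, seed = seed)),
                     tables = list(ce_plane = plane),
                     json = list(quadrants = as.list(psa$quadrants),
                                 frac_dominant = psa$frac_dominant,
                                 shares = as.list(psa$shares),
                                 seed = psa$seed),
                     out_dir = out_dir)
  if (is.null(out_dir)) psa else invisible(psa)
}

#' CHADS2 stratification report
#'
#' @inheritParams cmd_base_case
#' @param grid CHADS2 stroke-rate grid (default the packaged one).
#' @param adherence Adherence fraction (default the cost-neutral 5.25\%).
#' @return The stratification `data.frame` (invisibly when writing files).
#' @export
cmd_chads2 <- function(config = NULL, grid = default_chads2_grid(),
                       adherence = 0.0525, out_dir = NULL) {
  params <- load_parameters(config)
  ch <- chads2_sweep(params, grid, adherence)
  af_write_artifacts("chads2",
                     af_manifest("chads2", params,
                                 list(adherence = adherence)),
                     tables = list(chads2 = ch), out_dir = out_dir)
  if (is.null(out_dir)) ch else invisible(ch)
}
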