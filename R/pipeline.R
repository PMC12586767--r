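#' Full pipeline configuration
#'
#' Collects every knob of the analysis in one validated object: input and
#' output paths, the spline, the radix, the YLL horizon, the attribution
#' map, the scenario list, Monte-Carlo settings and report rounding.
#'
#' @param input path to a counts CSV, or `NULL` to generate the synthetic
#'   reference cohort in memory.
#' @param output_dir directory for result files (created if needed).
#' @param spline a [spline_spec()].
#' @param radix life-table radix, default 100 000.
#' @param horizon premature-death horizon, fixed at the end of the age
#'   range (70).
#' @param attribution an [attribution_map()].
#' @param scenarios named list of [scenario_spec()]s (first should be the
#'   baseline).
#' @param n_sims Monte-Carlo simulations (0 disables the CI stage).
#' @param seed master seed for the Monte-Carlo stage.
#' @param report_digits digits kept when formatting report tables (internal
#'   files always carry full precision).
#' @param column_map optional column mapping for [read_counts_csv()].
#' @param causes declared cause categories.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, output_dir = tempfile("lifedecomp-"),
                            spline = spline_spec(), radix = 1e5,
                            horizon = HORIZON,
                            attribution = default_attribution(),
                            scenarios = default_scenarios(),
                            n_sims = 1000L, seed = 1L,
                            report_digits = 1L, column_map = NULL,
                            causes = default_causes()) {
  stopifnot(inherits(spline, "spline_spec"),
            inherits(attribution, "attribution_map"),
            radix > 0, n_sims >= 0)
  if (horizon != AGE_END + 1L) {
    stop("horizon must equal the end of the modelled age range (70)")
  }
  if (!is.null(input) && !file.exists(input)) {
    stop("input file does not exist: ", input)
  }
  structure(list(input = input, output_dir = output_dir, spline = spline,
                 radix = radix, age_start = AGE_START, age_end = horizon,
                 horizon = horizon, attribution = attribution,
                 scenarios = scenarios, n_sims = as.integer(n_sims),
                 seed = as.integer(seed),
                 report_digits = as.integer(report_digits),
                 column_map = column_map, causes = causes),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a JSON or YAML file
#'
#' Recognised keys mirror the arguments of [pipeline_config()]; `spline`
#' may be given as `{"degrees_of_freedom": 3}`, `attribution` as a mapping
#' of exposure to cause-fraction mappings, and `scenarios` as a mapping of
#' label to the list of eliminated exposures.
#'
#' @param path config file; `.json` parsed with jsonlite, `.yml`/`.yaml`
#'   with the yaml package if installed.
#' @param ... overrides passed on to [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
load_config <- function(path, ...) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the yaml package is needed to read YAML configs")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  args <- list(...)
  take <- function(key, default) {
    if (!is.null(args[[key]])) args[[key]] else
      if (!is.null(raw[[key]])) raw[[key]] else default
  }
  spline <- raw$spline
  spline <- if (is.null(spline)) spline_spec() else
    spline_spec(degrees_of_freedom = spline$degrees_of_freedom %||% 3L)
  attribution <- if (is.null(raw$attribution)) default_attribution() else
    attribution_map(lapply(raw$attribution, unlist))
  scenarios <- if (is.null(raw$scenarios)) default_scenarios() else {
    out <- lapply(names(raw$scenarios), function(lab) {
      scenario_spec(lab, unlist(raw$scenarios[[lab]]))
    })
    stats::setNames(out, names(raw$scenarios))
  }
  pipeline_config(
    input = take("input", NULL),
    output_dir = take("output_dir", tempfile("lifedecomp-")),
    spline = spline, radix = take("radix", 1e5),
    attribution = attribution, scenarios = scenarios,
    n_sims = take("n_sims", 1000L), seed = take("seed", 1L),
    report_digits = take("report_digits", 1L),
    column_map = unlist(raw$column_map),
    causes = take("causes", default_causes())
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the whole analysis and write a report bundle
#'
#' Executes every stage — read (or synthesize) counts, fit the rate
#' models, check additivity, build the baseline and counterfactual life
#' tables, attribute the burden, difference the scenarios, and (if
#' `n_sims >= 2`) compute Monte-Carlo CIs — and writes plain CSV/JSON
#' outputs to `config$output_dir`:
#'
#' * `rates.csv` — observed and modelled rates per age and cause;
#' * `lifetable_<scenario>.csv` — survivors, deaths, cumulative risk;
#' * `burden.csv` — per-scenario, per-bucket risk, mean YLL and shares,
#'   with CI columns when the Monte-Carlo stage ran;
#' * `changes.csv` — per-bucket changes against the baseline;
#' * `ci.csv` — every Monte-Carlo parameter with its interval;
#' * `run_log.json` — config echo, seed, package/R versions, input
#'   checksum, and per-stage wall time.
#'
#' Re-running with the same config and seed reproduces every number.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with the fitted curves, additivity gap, life
#'   tables, burden summaries, comparisons, CI table and file paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  stages <- list()
  tick <- function(name) {
    t1 <- proc.time()[["elapsed"]]
    stages[[name]] <<- round(t1 - t0, 3)
    t0 <<- t1
  }

  table <- if (is.null(config$input)) {
    reference_counts()
  } else {
    read_counts_csv(config$input, causes = config$causes,
                    column_map = config$column_map)
  }
  tick("read")

  curves <- fit_all(table, config$spline, causes = config$causes)
  additivity <- check_rate_consistency(curves)
  hazards <- apportion_hazards(curves)
  utils::write.csv(rates_to_df(table, curves),
                   file.path(config$output_dir, "rates.csv"), row.names = FALSE)
  tick("fit")

  burdens <- lapply(config$scenarios, function(sp) {
    scenario_burden(hazards, config$attribution, sp, radix = config$radix)
  })
  tables <- lapply(config$scenarios, function(sp) {
    build_life_table(cause_curves = apply_elimination(hazards,
                                                      config$attribution, sp),
                     radix = config$radix)
  })
  for (s in names(tables)) {
    utils::write.csv(lifetable_to_df(tables[[s]]),
                     file.path(config$output_dir,
                               sprintf("lifetable_%s.csv", s)),
                     row.names = FALSE)
  }
  comparisons <- if ("baseline" %in% names(burdens)) {
    lapply(burdens[setdiff(names(burdens), "baseline")],
           function(b) decompose_change(burdens$baseline, b))
  }
  tick("lifetables")

  ci <- NULL
  if (config$n_sims >= 2L) {
    ci <- monte_carlo(table, config$spline, config$attribution,
                      config$scenarios, config$radix,
                      n_sims = config$n_sims, seed = config$seed,
                      causes = config$causes)
    utils::write.csv(ci, file.path(config$output_dir, "ci.csv"),
                     row.names = FALSE)
  }
  tick("monte_carlo")

  burden_df <- do.call(rbind, lapply(burdens, burden_to_df))
  if (!is.null(ci)) {
    key <- with(burden_df, paste(scenario, "risk", bucket, sep = "."))
    burden_df$risk_lower <- ci$lower[match(key, ci$parameter)]
    burden_df$risk_upper <- ci$upper[match(key, ci$parameter)]
    key <- with(burden_df, paste(scenario, "yll", bucket, sep = "."))
    burden_df$yll_lower <- ci$lower[match(key, ci$parameter)]
    burden_df$yll_upper <- ci$upper[match(key, ci$parameter)]
  }
  utils::write.csv(burden_df, file.path(config$output_dir, "burden.csv"),
                   row.names = FALSE)
  changes_df <- if (!is.null(comparisons)) {
    do.call(rbind, lapply(comparisons, function(ch) {
      data.frame(counterfactual = ch$counterfactual,
                 bucket = names(ch$risk_change_ppt),
                 risk_change_ppt = unname(ch$risk_change_ppt),
                 yll_change = unname(ch$yll_change), row.names = NULL)
    }))
  }
  if (!is.null(changes_df)) {
    utils::write.csv(changes_df, file.path(config$output_dir, "changes.csv"),
                     row.names = FALSE)
  }
  log <- list(
    package = "lifedecomp",
    version = as.character(utils::packageVersion("lifedecomp")),
    r_version = R.version.string,
    seed = config$seed, n_sims = config$n_sims, radix = config$radix,
    spline_df = config$spline$degrees_of_freedom,
    causes = config$causes,
    input = config$input %||% "synthetic reference cohort",
    input_md5 = if (!is.null(config$input))
      unname(tools::md5sum(config$input)) else NA,
    additivity_gap = additivity,
    stage_seconds = stages
  )
  jsonlite::write_json(log, file.path(config$output_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(table = table, curves = curves, additivity = additivity,
                 hazards = hazards, life_tables = tables, burdens = burdens,
                 comparisons = comparisons, ci = ci,
                 output_dir = config$output_dir))
}

#' Command-line entry point
#'
#' Verbs: `simulate` (write a synthetic counts CSV), `fit` (rate models and
#' additivity check), `run` (full pipeline without CIs), `ci` (Monte-Carlo
#' intervals only) and `report` (full pipeline including CIs and a
#' formatted summary printed to stdout). Flags `--config`, `--input`,
#' `--out`, `--seed` and `--n-sims` override the config file. An
#' executable launcher ships in `inst/cli/lifedecomp`.
#'
#' @param args character vector, default the command line.
#' @return Invisibly, the value of the executed stage.
#' @export
lifedecomp_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  verbs <- c("simulate", "fit", "run", "ci", "report")
  if (!length(args) || !args[1] %in% verbs) {
    stop("usage: lifedecomp <", paste(verbs, collapse = "|"), "> [options]")
  }
  verb <- args[1]
  parser <- optparse::OptionParser(option_list = list(
    optparse::make_option("--config", type = "character", default = NULL),
    optparse::make_option("--input", type = "character", default = NULL),
    optparse::make_option("--out", type = "character", default = "lifedecomp-out"),
    optparse::make_option("--seed", type = "integer", default = NULL),
    optparse::make_option("--n-sims", type = "integer", default = NULL,
                          dest = "n_sims")
  ))
  opt <- optparse::parse_args(parser, args = args[-1])
  config <- if (!is.null(opt$config)) {
    load_config(opt$config,
                input = opt$input,
                seed = opt$seed %||% NULL,
                n_sims = opt$n_sims %||% NULL)
  } else {
    pipeline_config(input = opt$input, output_dir = opt$out,
                    seed = opt$seed %||% 1L,
                    n_sims = opt$n_sims %||% 1000L)
  }
  config$output_dir <- opt$out

  switch(verb,
    simulate = {
      table <- generate_counts(seed = config$seed)
      dir.create(dirname(file.path(opt$out, ".")), showWarnings = FALSE,
                 recursive = TRUE)
      path <- if (dir.exists(opt$out)) {
        file.path(opt$out, "synthetic_counts.csv")
      } else opt$out
      write_counts_csv(table, path)
      message("wrote ", path)
      invisible(path)
    },
    fit = {
      table <- if (is.null(config$input)) reference_counts() else
        read_counts_csv(config$input, causes = config$causes,
                        column_map = config$column_map)
      curves <- fit_all(table, config$spline, causes = config$causes)
      dir.create(opt$out, showWarnings = FALSE, recursive = TRUE)
      utils::write.csv(rates_to_df(table, curves),
                       file.path(opt$out, "rates.csv"), row.names = FALSE)
      message(sprintf("additivity gap: %.4f", check_rate_consistency(curves)))
      invisible(curves)
    },
    run = {
      config$n_sims <- 0L
      invisible(run_pipeline(config))
    },
    ci = {
      table <- if (is.null(config$input)) reference_counts() else
        read_counts_csv(config$input, causes = config$causes,
                        column_map = config$column_map)
      ci <- monte_carlo(table, config$spline, config$attribution,
                        config$scenarios, config$radix,
                        n_sims = max(config$n_sims, 2L), seed = config$seed,
                        causes = config$causes)
      dir.create(opt$out, showWarnings = FALSE, recursive = TRUE)
      utils::write.csv(ci, file.path(opt$out, "ci.csv"), row.names = FALSE)
      invisible(ci)
    },
    report = {
      bundle <- run_pipeline(config)
      for (b in bundle$burdens) print(b)
      if (!is.null(bundle$comparisons)) for (ch in bundle$comparisons) print(ch)
      invisible(bundle)
    }
  )
}
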