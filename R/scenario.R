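#' Scenario-grid configuration
#'
#' Bundles everything that defines a comparison run: the strategy arms, the
#' starting ages and sexes, cohort size, horizon, execution mode, seed, and
#' the adherence settings. Defaults reproduce the packaged study grid:
#' conventional screening colonoscopy, conventional biennial FIT (cut-off
#' 17), and gateopener screening at cut-offs 17, 10, 8, 6, 4 and 3 ug/g,
#' for cohorts of 100,000 previously unscreened women and men aged 50, 60
#' or 70, followed for 10 years.
#'
#' @param strategies List of [strategy] objects (the no-screening reference
#'   is always run and need not be listed).
#' @param ages Starting ages.
#' @param sexes Sexes to simulate (always run separately; pooled summaries
#'   are derived afterwards).
#' @param cohort_size Persons per arm.
#' @param horizon_years Follow-up horizon.
#' @param mode `"expectation"` or `"microsim"`.
#' @param seed Global seed, expanded into independent per-arm substreams
#'   keyed by arm identity (so adding arms never perturbs existing arms).
#' @param adherence An [adherence_params] (or a named preset overlay:
#'   `"base"`, `"adherence60"`, `"dropout30"`).
#' @param colo_params A [colonoscopy_params].
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(strategies = default_strategies(),
                            ages = c(50, 60, 70),
                            sexes = c("female", "male"),
                            cohort_size = 100000,
                            horizon_years = 10,
                            mode = c("expectation", "microsim"),
                            seed = 1,
                            adherence = adherence_params(),
                            colo_params = colonoscopy_params()) {
  mode <- match.arg(mode)
  if (is.character(adherence)) adherence <- adherence_overlay(adherence)
  stopifnot(inherits(adherence, "adherence_params"),
            inherits(colo_params, "colonoscopy_params"),
            all(vapply(strategies, inherits, logical(1), "strategy")))
  if (mode == "microsim" && is.null(seed)) {
    stop_crc("microsim mode requires a seed", "crcscreen_config_error")
  }
  structure(list(strategies = strategies, ages = ages, sexes = sexes,
                 cohort_size = cohort_size, horizon_years = horizon_years,
                 mode = mode, seed = seed, adherence = adherence,
                 colo_params = colo_params),
            class = "scenario_config")
}

#' @rdname scenario_config
#' @export
default_strategies <- function() {
  c(list(strategy("colonoscopy_q10y"), strategy("biennial_fit")),
    lapply(c(17, 10, 8, 6, 4, 3), function(ct) strategy("gateopener", ct)))
}

#' Named adherence presets for sensitivity analyses
#'
#' `"base"`: defaults (15% colonoscopy uptake, 50% FIT uptake, 40% drop-out,
#' 80% diagnostic compliance). `"adherence60"`: 60% FIT uptake for biennial
#' FIT and gateopener screening. `"dropout30"`: drop-out reduced to 30%.
#'
#' @param name Preset name.
#' @return An [adherence_params].
#' @export
adherence_overlay <- function(name = c("base", "adherence60", "dropout30")) {
  name <- match.arg(name)
  switch(name,
         base = adherence_params(),
         adherence60 = adherence_params(p_fit_first = 0.60),
         dropout30 = adherence_params(dropout = 0.30))
}

#' Run the full scenario grid
#'
#' For each age/sex stratum, runs the no-screening reference plus every
#' configured strategy arm under a shared natural-history parameter set, and
#' summarises each arm against its reference. Optionally writes the
#' summaries, the league table and a run manifest (configuration hash, seed,
#' package version) to `out_dir`.
#'
#' @param config A [scenario_config].
#' @param params An [nh_params]; defaults to the synthetic generator seeded
#'   from the config seed.
#' @param out_dir Optional directory for CSV/JSON output.
#' @return List of class `scenario_grid` with elements `summaries` (stacked
#'   [outcome_summary] rows), `pooled` (sex-pooled summaries), `league` (long
#'   comparison table), `references` (no-screening trajectories by stratum)
#'   and `manifest`.
#' @export
run_scenario_grid <- function(config = scenario_config(), params = NULL,
                              out_dir = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  params <- params %||%
    generate_natural_history_params(seed = arm_seed(config$seed, "params"))
  profiles <- list()
  for (st in config$strategies) {
    if (uses_fit(st) && is.null(profiles[[as.character(st$cutoff)]])) {
      profiles[[as.character(st$cutoff)]] <-
        decompose_to_per_state(builtin_characteristics(st$cutoff),
                               blitz_group_counts())
    }
  }
  summaries <- list()
  references <- list()
  for (sex in config$sexes) {
    for (age in config$ages) {
      stratum <- sprintf("age%d_%s", age, sex)
      ref_sc <- list(age = age, sex = sex, n = config$cohort_size,
                     horizon = config$horizon_years, mode = config$mode,
                     seed = arm_seed(config$seed,
                                     paste0("no_screening_", stratum)))
      ref <- run_arm(params, ref_sc, strategy("no_screening"))
      references[[stratum]] <- ref
      for (st in config$strategies) {
        sc <- ref_sc
        sc$seed <- arm_seed(config$seed,
                            paste0(strategy_label(st), "_", stratum))
        traj <- run_arm(params, sc, st, adherence = config$adherence,
                        profile = if (uses_fit(st))
                          profiles[[as.character(st$cutoff)]],
                        colo_params = config$colo_params)
        summaries[[length(summaries) + 1]] <- outcome_summary(traj, ref)
      }
    }
  }
  summaries <- do.call(rbind, summaries)
  rownames(summaries) <- NULL
  pooled <- if (!is.null(summaries) && length(config$sexes) > 1) {
    pool_sexes(summaries)
  }
  league <- if (!is.null(summaries) &&
                any(summaries$strategy %in% c("colonoscopy_q10y",
                                              "biennial_fit")) &&
                nrow(summaries) >= 2) {
    league_table(summaries)
  }
  manifest <- list(
    config_hash = rlang::hash(config),
    params_hash = rlang::hash(params),
    seed = config$seed,
    mode = config$mode,
    package_version = as.character(utils::packageVersion("crcscreen"))
  )
  out <- structure(list(summaries = summaries, pooled = pooled,
                        league = league, references = references,
                        manifest = manifest, config = config),
                   class = "scenario_grid")
  if (!is.null(out_dir)) write_scenario_grid(out, out_dir)
  out
}

#' Write scenario-grid results to disk
#'
#' Emits `summaries.csv`, `pooled.csv`, `league.csv` (long/tidy, stable
#' column names; counts are per cohort of the configured size) and
#' `manifest.json` into `dir`.
#'
#' @param grid A `scenario_grid`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_scenario_grid <- function(grid, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(grid$summaries, file.path(dir, "summaries.csv"),
                   row.names = FALSE)
  if (!is.null(grid$pooled)) {
    utils::write.csv(grid$pooled, file.path(dir, "pooled.csv"),
                     row.names = FALSE)
  }
  if (!is.null(grid$league)) {
    utils::write.csv(grid$league, file.path(dir, "league.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(grid$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Run the sensitivity-analysis suite
#'
#' Executes the base grid plus the four packaged variants: all starting
#' prevalences and transition rates at their lower or upper 95% CI bounds,
#' 60% FIT adherence, and 30% biennial-FIT drop-out.
#'
#' @param config A [scenario_config] for the base case.
#' @param params Base-case [nh_params]; defaults as in [run_scenario_grid()].
#' @param variants Subset of `c("base", "ci_lower", "ci_upper",
#'   "adherence60", "dropout30")`.
#' @return Named list of `scenario_grid` objects, one per variant.
#' @export
run_sensitivity_suite <- function(config = scenario_config(), params = NULL,
                                  variants = c("base", "ci_lower", "ci_upper",
                                               "adherence60", "dropout30")) {
  variants <- match.arg(variants, several.ok = TRUE)
  params <- params %||%
    generate_natural_history_params(seed = arm_seed(config$seed, "params"))
  out <- list()
  for (v in variants) {
    vp <- params
    vc <- config
    if (v == "ci_lower") vp <- perturb_to_ci_bound(params, "lower")
    if (v == "ci_upper") vp <- perturb_to_ci_bound(params, "upper")
    if (v == "adherence60") vc$adherence <- adherence_overlay("adherence60")
    if (v == "dropout30") vc$adherence <- adherence_overlay("dropout30")
    out[[v]] <- run_scenario_grid(vc, vp)
  }
  out
}

#' Read / write a scenario configuration as YAML
#'
#' Plain-text round-trip of a [scenario_config]; strategies are encoded as
#' `kind`/`cutoff` pairs, adherence and colonoscopy parameters as named
#' blocks. A commented template ships in the package's `extdata`.
#'
#' @param path YAML file path.
#' @param config A [scenario_config].
#' @return `read_scenario_config()` returns a [scenario_config];
#'   `write_scenario_config()` returns `path` invisibly.
#' @export
read_scenario_config <- function(path) {
  y <- yaml::read_yaml(path)
  strategies <- lapply(y$strategies, function(s) {
    strategy(s$kind, cutoff = s$cutoff %||% NULL)
  })
  adh <- if (is.character(y$adherence)) adherence_overlay(y$adherence)
         else do.call(adherence_params, y$adherence %||% list())
  colo <- do.call(colonoscopy_params, y$colonoscopy %||% list())
  scenario_config(
    strategies = strategies,
    ages = y$ages %||% c(50, 60, 70),
    sexes = y$sexes %||% c("female", "male"),
    cohort_size = y$cohort_size %||% 100000,
    horizon_years = y$horizon_years %||% 10,
    mode = y$mode %||% "expectation",
    seed = y$seed %||% 1,
    adherence = adh,
    colo_params = colo
  )
}

#' @rdname read_scenario_config
#' @export
write_scenario_config <- function(config, path) {
  y <- list(
    strategies = lapply(config$strategies, function(s) {
      c(list(kind = s$kind),
        if (!is.null(s$cutoff)) list(cutoff = s$cutoff))
    }),
    ages = config$ages, sexes = config$sexes,
    cohort_size = config$cohort_size,
    horizon_years = config$horizon_years,
    mode = config$mode, seed = config$seed,
    adherence = unclass(config$adherence),
    colonoscopy = unclass(config$colo_params)
  )
  yaml::write_yaml(y, path)
  invisible(path)
}
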