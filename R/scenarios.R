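#' @title Scenario transforms and the bundled scenario library
#' @name scenario_engine
#' @description
#' A scenario names the levers pulled relative to current care: which
#' intervention profiles and diagnostic gates are scaled up (and in which
#' settings), whether diagnosed cases are referred to a higher level of
#' care, and any override of the delivery-location mix. Every scenario is
#' evaluated at two improvement levels: the *incremental change* model adds
#' 20 percentage points to penetration and utilization (capped at the
#' coverage cap), and the *universal coverage* model sets them to the cap
#' (98%). Efficacies are never changed by a scenario.
NULL

INCREMENTAL_STEP <- 0.20

#' Load the bundled scenario library
#'
#' Thirty named scenarios in two groups: one set scored on deaths from the
#' direct complications RDS, IVH, and NEC; the other on sepsis, birth
#' asphyxia, and low birth weight. Scenario 1 of each group is the shared
#' current-care baseline. The library is data, not code: it lives in a YAML
#' file under `inst/extdata/` that users can copy and extend.
#'
#' @param path Optional path to a custom scenario library YAML.
#' @return A tibble with one row per scenario: `id`, `table`, `number`,
#'   `description`, `mode` (`"none"` for baselines, `"levers"` otherwise),
#'   list-columns `interventions` and `gates` (each a list of
#'   `list(name, settings)`), `transfer_gates` (character), and
#'   `delivery_override` (named numeric or `NULL`), plus the `subconditions`
#'   scored by the scenario's group.
#' @export
#' @examples
#' scenario_library()
scenario_library <- function(path = NULL) {
  path <- path %||% system.file("extdata", "scenarios_ssa_2015.yaml",
                                package = "pretermcascade", mustWork = TRUE)
  raw <- yaml::read_yaml(path)
  purrr::map_dfr(raw, function(s) {
    group <- if (identical(s$group, "direct")) c("RDS", "IVH", "NEC") else
      c("sepsis", "birth_asphyxia", "LBW_only")
    tibble(
      id = s$id,
      table = as.integer(s$table),
      number = as.integer(s$number),
      description = s$description,
      mode = s$mode %||% "levers",
      interventions = list(s$interventions %||% list()),
      gates = list(s$gates %||% list()),
      transfer_gates = list(as.character(unlist(s$transfer %||% list()))),
      delivery_override = list(
        if (is.null(s$delivery_override)) NULL else
          setNames(as.numeric(unlist(s$delivery_override)[SETTINGS]) / 100, SETTINGS)
      ),
      subconditions = list(group)
    )
  })
}

scenario_row <- function(spec) {
  if (is.character(spec)) abort("pass a scenario row (one row of scenario_library())")
  if (inherits(spec, "data.frame")) {
    if (nrow(spec) != 1) abort("`spec` must be a single scenario row")
    spec <- as.list(spec)
    for (col in c("interventions", "gates", "transfer_gates",
                  "delivery_override", "subconditions")) {
      spec[[col]] <- spec[[col]][[1]]
    }
  }
  spec
}

boost_parameter_set <- function(p, spec, level_fun, transfer_level) {
  spec <- scenario_row(spec)
  if (identical(spec$mode, "none")) return(p)

  for (b in spec$interventions) {
    i <- p$interventions$intervention == b$name &
      p$interventions$setting %in% unlist(b$settings)
    if (!any(p$interventions$intervention == b$name)) {
      abort(paste0("scenario boosts unknown intervention: ", b$name))
    }
    p$interventions$penetration[i] <- level_fun(p$interventions$penetration[i])
    p$interventions$utilization[i] <- level_fun(p$interventions$utilization[i])
  }
  for (b in spec$gates) {
    i <- p$diagnostics$gate == b$name &
      p$diagnostics$setting %in% unlist(b$settings)
    if (!any(p$diagnostics$gate == b$name)) {
      abort(paste0("scenario boosts unknown gate: ", b$name))
    }
    p$diagnostics$penetration[i] <- level_fun(p$diagnostics$penetration[i])
    p$diagnostics$utilization[i] <- level_fun(p$diagnostics$utilization[i])
  }
  for (g in spec$transfer_gates) {
    i <- p$transfer$probabilities$gate == g
    if (!any(i)) abort(paste0("scenario enables transfer for unknown gate: ", g))
    p$transfer$probabilities$probability[i] <-
      transfer_level(p$transfer$probabilities$probability[i])
  }
  if (!is.null(spec$delivery_override)) {
    p$delivery_mix <- spec$delivery_override
  }
  p
}

#' Apply the incremental-change transform
#'
#' Adds 20 percentage points to the penetration and utilization of every
#' boosted profile and gate in its listed settings, capped at the coverage
#' cap (98%); enables referral transfer for the scenario's gates at the same
#' incremental level (0.20 above the zero baseline). Efficacies and
#' non-boosted profiles are untouched; the input parameter set is not
#' modified. With `incremental_mode = "relative"` in the parameter set, the
#' alternative multiply-by-1.2 reading is applied instead (a sensitivity
#' switch; the additive reading is the default because scale-up from a
#' zero-coverage baseline must be able to produce nonzero coverage).
#'
#' @param p A validated `preterm_params` object.
#' @param spec One row of [scenario_library()] (or an equivalent list).
#' @return A new `preterm_params` object.
#' @export
apply_incremental <- function(p, spec) {
  cap <- p$coverage_cap
  f <- if (p$incremental_mode == "additive") {
    function(x) pmin(x + INCREMENTAL_STEP, cap)
  } else {
    function(x) pmin(x * (1 + INCREMENTAL_STEP), cap)
  }
  boost_parameter_set(p, spec, f, f)
}

#' Apply the universal-coverage transform
#'
#' Sets penetration and utilization to the coverage cap (98%) for every
#' boosted profile and gate in its listed settings; settings a scenario does
#' not list (e.g. surfactant outside hospital) are left at baseline.
#' Referral transfer for the scenario's gates is likewise set to the cap.
#' Idempotent: applying it twice equals applying it once.
#'
#' @inheritParams apply_incremental
#' @return A new `preterm_params` object.
#' @export
apply_universal <- function(p, spec) {
  cap <- p$coverage_cap
  boost_parameter_set(p, spec, function(x) rep(cap, length(x)),
                      function(x) rep(cap, length(x)))
}

#' Run one scenario at both improvement levels
#'
#' Applies the incremental-change and universal-coverage transforms to the
#' parameter set, runs the cohort cascade for each, and returns both
#' mortality results tagged with the scenario's provenance and the
#' subcondition group it is scored on.
#'
#' @inheritParams apply_incremental
#' @param trace Passed through to [run_cohort()].
#' @return A list of class `preterm_scenario` with elements `spec`,
#'   `incremental`, and `universal` (both `preterm_mortality` objects).
#' @export
#' @examples
#' lib <- scenario_library()
#' p <- baseline_parameters()
#' run_scenario(lib[lib$id == "t3s03", ], p)
run_scenario <- function(spec, p, trace = FALSE) {
  spec <- scenario_row(spec)
  inc <- run_cohort(apply_incremental(p, spec), trace = trace)
  uni <- run_cohort(apply_universal(p, spec), trace = trace)
  attr(inc, "scenario") <- paste0(spec$id, " (incremental)")
  attr(uni, "scenario") <- paste0(spec$id, " (universal)")
  structure(list(spec = spec, incremental = inc, universal = uni),
            class = "preterm_scenario")
}

#' Deaths prevented relative to a baseline
#'
#' @param baseline,scenario `preterm_mortality` objects covering the same
#'   subcondition set.
#' @param subconditions Optional subcondition filter applied to both totals
#'   (the scored group of a scenario table).
#' @return A tibble with `baseline_deaths`, `scenario_deaths`, `prevented`
#'   (baseline minus scenario), and `percent` (of baseline, 0-100 scale),
#'   all unrounded.
#' @export
deaths_prevented <- function(baseline, scenario, subconditions = NULL) {
  b <- total_deaths(baseline, subconditions)
  s <- total_deaths(scenario, subconditions)
  if (b <= 0) abort("baseline deaths are zero; percent prevented is undefined")
  tibble(baseline_deaths = b, scenario_deaths = s,
         prevented = b - s, percent = 100 * (b - s) / b)
}

#' Run a scenario suite against its current-care baseline
#'
#' Runs every scenario in `scenarios` (optionally restricted to one table)
#' at both improvement levels and scores each against the current-care
#' baseline of its subcondition group.
#'
#' @param p A validated `preterm_params` object (current care).
#' @param scenarios A scenario library tibble; defaults to the bundled one.
#' @param table Optionally restrict to one scenario group (3 or 4).
#' @return A tibble with one row per scenario: identification columns,
#'   unrounded `baseline_deaths`, `incremental_deaths`,
#'   `incremental_prevented`, `incremental_percent`, and the same for the
#'   universal level. Pass to [build_report()] for the rounded presentation.
#' @export
#' @examples
#' \donttest{
#' suite <- run_scenario_suite(baseline_parameters(), table = 3)
#' build_report(suite)
#' }
run_scenario_suite <- function(p, scenarios = scenario_library(), table = NULL) {
  if (!is.null(table)) scenarios <- filter(scenarios, .data$table %in% !!table)
  base_res <- run_cohort(p)
  purrr::map_dfr(seq_len(nrow(scenarios)), function(i) {
    spec <- scenario_row(scenarios[i, ])
    res <- run_scenario(spec, p)
    inc <- deaths_prevented(base_res, res$incremental, spec$subconditions)
    uni <- deaths_prevented(base_res, res$universal, spec$subconditions)
    tibble(
      id = spec$id, table = spec$table, number = spec$number,
      description = spec$description,
      subcondition_group = paste(spec$subconditions, collapse = "+"),
      baseline_deaths = inc$baseline_deaths,
      incremental_deaths = inc$scenario_deaths,
      incremental_prevented = inc$prevented,
      incremental_percent = inc$percent,
      universal_deaths = uni$scenario_deaths,
      universal_prevented = uni$prevented,
      universal_percent = uni$percent
    )
  })
}
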