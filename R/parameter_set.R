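#' @title Model parameter sets
#' @name parameter_set
#' @description
#' A parameter set bundles everything the cohort cascade needs: the size of
#' the preterm cohort and where births and antenatal care happen; the
#' prevalence and untreated case-fatality rate of each subcondition; the
#' per-setting penetration, utilization, and efficacy of each diagnostic gate
#' and each preventive/treatment intervention; referral-transfer
#' probabilities; and the coverage cap applied by scale-up scenarios.
#'
#' All proportions are stored internally on the 0-1 scale. Config files may
#' state values either as percent or as proportions, declared by a mandatory
#' top-level `units` key.
NULL

param_top_keys <- c("name", "units", "coverage_cap", "anc_weighting",
                    "incremental_mode", "population", "subconditions",
                    "diagnostics", "interventions", "transfer")

#' Load a parameter set from a YAML or JSON config
#'
#' Reads a model configuration, converts all coverage values to proportions,
#' validates every invariant, and returns a `preterm_params` object. Any
#' violation aborts with a message naming the offending field; use
#' [validate_parameter_set()] to collect violations as data instead.
#'
#' @param source Path to a YAML or JSON file, a literal YAML string (anything
#'   containing a newline is treated as YAML text), or an already-parsed list.
#' @return A validated `preterm_params` object.
#' @seealso [baseline_parameters()], [write_parameter_set()],
#'   [validate_parameter_set()]
#' @export
#' @examples
#' p <- baseline_parameters()
#' p$n_preterm_births
load_parameter_set <- function(source) {
  raw <- parse_config(source)
  unknown <- setdiff(names(raw), param_top_keys)
  if (length(unknown) > 0) {
    abort(paste0("unknown top-level config key(s): ",
                 paste(unknown, collapse = ", ")))
  }
  units <- raw$units %||% abort("config must declare `units: percent` or `units: proportion`")
  if (!units %in% c("percent", "proportion")) {
    abort("`units` must be \"percent\" or \"proportion\"")
  }
  sc <- if (units == "percent") 1 / 100 else 1

  pop <- raw$population %||% abort("config is missing `population`")
  unknown <- setdiff(names(pop), c("n_preterm_births", "delivery_mix", "anc_mix"))
  if (length(unknown) > 0) {
    abort(paste0("unknown population key(s): ", paste(unknown, collapse = ", ")))
  }

  p <- structure(list(
    name = raw$name %||% "unnamed",
    n_preterm_births = as.numeric(pop$n_preterm_births %||% NA_real_),
    delivery_mix = setting_vector(pop$delivery_mix, sc, "population.delivery_mix"),
    anc_mix = setting_vector(pop$anc_mix, sc, "population.anc_mix"),
    subconditions = parse_subconditions(raw$subconditions, sc),
    diagnostics = parse_diagnostics(raw$diagnostics, sc),
    interventions = parse_interventions(raw$interventions, sc)$coverage,
    efficacies = parse_interventions(raw$interventions, sc)$efficacy,
    transfer = parse_transfer(raw$transfer, sc),
    coverage_cap = as.numeric(raw$coverage_cap %||% 98) * sc,
    anc_weighting = raw$anc_weighting %||% "anc",
    incremental_mode = raw$incremental_mode %||% "additive"
  ), class = "preterm_params")

  viol <- validate_parameter_set(p)
  if (nrow(viol) > 0) {
    abort(paste0("invalid parameter set:\n", paste0(
      "  - [", viol$type, "] ", viol$field, ": ", viol$rule, collapse = "\n")))
  }
  p
}

parse_config <- function(source) {
  if (is.list(source)) return(source)
  if (!is.character(source) || length(source) != 1) {
    abort("`source` must be a file path, a YAML string, or a list")
  }
  if (!grepl("\n", source) && file.exists(source)) {
    if (grepl("\\.json$", source)) {
      return(jsonlite::read_json(source, simplifyVector = FALSE))
    }
    return(yaml::read_yaml(source))
  }
  if (!grepl("\n", source)) {
    abort(paste0("config file not found: ", source))
  }
  yaml::yaml.load(source)
}

setting_vector <- function(x, sc, field) {
  if (is.null(x)) abort(paste0(field, " is missing"))
  x <- unlist(x)
  if (!all(SETTINGS %in% names(x)) || length(x) != 3) {
    abort(paste0(field, " must name exactly home, clinic, hospital"))
  }
  setNames(as.numeric(x[SETTINGS]) * sc, SETTINGS)
}

parse_subconditions <- function(x, sc) {
  if (is.null(x)) abort("config is missing `subconditions`")
  purrr::map_dfr(x, function(row) {
    unknown <- setdiff(names(row), c("name", "prevalence", "untreated_cfr"))
    if (length(unknown) > 0) {
      abort(paste0("unknown subcondition key(s): ", paste(unknown, collapse = ", ")))
    }
    tibble(
      subcondition = row$name,
      prevalence = as.numeric(row$prevalence) * sc,
      untreated_cfr = as.numeric(row$untreated_cfr) * sc
    )
  })
}

parse_diagnostics <- function(x, sc) {
  if (is.null(x)) abort("config is missing `diagnostics`")
  purrr::map_dfr(x, function(row) {
    unknown <- setdiff(names(row), c("gate", "penetration", "utilization", "efficacy"))
    if (length(unknown) > 0) {
      abort(paste0("unknown diagnostic key(s): ", paste(unknown, collapse = ", ")))
    }
    tibble(
      gate = row$gate,
      setting = SETTINGS,
      penetration = as.numeric(unlist(row$penetration)[SETTINGS]) * sc,
      utilization = as.numeric(unlist(row$utilization)[SETTINGS]) * sc,
      efficacy = as.numeric(unlist(row$efficacy)[SETTINGS]) * sc
    )
  })
}

parse_interventions <- function(x, sc) {
  if (is.null(x)) abort("config is missing `interventions`")
  cov <- purrr::map_dfr(x, function(row) {
    unknown <- setdiff(names(row), c("name", "role", "timing", "requires_diagnosis",
                                     "gate", "penetration", "utilization", "efficacy"))
    if (length(unknown) > 0) {
      abort(paste0("unknown intervention key(s) in ", row$name %||% "?", ": ",
                   paste(unknown, collapse = ", ")))
    }
    tibble(
      intervention = row$name,
      role = row$role %||% "treatment",
      timing = row$timing %||% "postnatal",
      requires_diagnosis = isTRUE(row$requires_diagnosis),
      gate = row$gate %||% "target",
      setting = SETTINGS,
      penetration = as.numeric(unlist(row$penetration)[SETTINGS]) * sc,
      utilization = as.numeric(unlist(row$utilization)[SETTINGS]) * sc
    )
  })
  eff <- purrr::map_dfr(x, function(row) {
    e <- unlist(row$efficacy)
    tibble(intervention = row$name, target = names(e), efficacy = as.numeric(e) * sc)
  })
  list(coverage = cov, efficacy = eff)
}

parse_transfer <- function(x, sc) {
  destination <- (x %||% list())$destination %||% "hospital"
  grid <- tidyr::expand_grid(gate = GATES, origin = c("home", "clinic")) %>%
    mutate(probability = 0)
  for (row in (x %||% list())$probabilities %||% list()) {
    i <- grid$gate == row$gate & grid$origin == row$origin
    if (!any(i)) abort(paste0("transfer entry for unknown gate/origin: ",
                              row$gate, "/", row$origin))
    grid$probability[i] <- as.numeric(row$probability) * sc
  }
  list(destination = destination, probabilities = grid)
}

#' Validate a parameter set
#'
#' Checks every structural and range invariant of a `preterm_params` object
#' and returns the violations as data (an empty tibble means the set is
#' valid). Violations never raise conditions here, so the function can be
#' used to audit hand-edited configs.
#'
#' @param p A `preterm_params` object (not necessarily valid).
#' @return A tibble with columns `type` (which component), `field`, and
#'   `rule` (the invariant violated), one row per violation.
#' @export
#' @examples
#' validate_parameter_set(baseline_parameters())  # 0 rows
validate_parameter_set <- function(p) {
  v <- list()
  bad <- function(type, field, rule) {
    v[[length(v) + 1]] <<- tibble(type = type, field = field, rule = rule)
  }
  in01 <- function(x) all(is.finite(x) & x >= 0 & x <= 1)

  if (!is.numeric(p$n_preterm_births) || is.na(p$n_preterm_births) ||
      p$n_preterm_births <= 0) {
    bad("PopulationSpec", "n_preterm_births", "must be a positive count")
  }
  for (mix in c("delivery_mix", "anc_mix")) {
    m <- p[[mix]]
    if (!in01(m)) bad("PopulationSpec", mix, "entries must lie in [0, 1]")
    else if (abs(sum(m) - 1) > 1e-9) {
      bad("PopulationSpec", mix, sprintf("must sum to 1 (got %.6f)", sum(m)))
    }
  }

  sub <- p$subconditions
  if (!setequal(sub$subcondition, SUBCONDITIONS) || nrow(sub) != 6) {
    bad("SubconditionSpec", "subconditions",
        "must contain exactly the six named subconditions")
  }
  if (!in01(sub$prevalence)) bad("SubconditionSpec", "prevalence", "must lie in [0, 1]")
  if (!in01(sub$untreated_cfr)) bad("SubconditionSpec", "untreated_cfr", "must lie in [0, 1]")

  d <- p$diagnostics
  for (col in c("penetration", "utilization", "efficacy")) {
    if (!in01(d[[col]])) {
      for (i in which(!(is.finite(d[[col]]) & d[[col]] >= 0 & d[[col]] <= 1))) {
        bad("CoverageProfile", paste0("diagnostics.", d$gate[i], ".", col,
                                      ".", d$setting[i]), "must lie in [0, 1]")
      }
    }
  }

  iv <- p$interventions
  for (col in c("penetration", "utilization")) {
    for (i in which(!(is.finite(iv[[col]]) & iv[[col]] >= 0 & iv[[col]] <= 1))) {
      bad("CoverageProfile", paste0("interventions.", iv$intervention[i], ".",
                                    col, ".", iv$setting[i]), "must lie in [0, 1]")
    }
  }
  if (!all(iv$timing %in% c("antenatal", "delivery", "postnatal"))) {
    bad("CoverageProfile", "interventions.timing",
        "must be antenatal, delivery, or postnatal")
  }
  eff <- p$efficacies
  if (!in01(eff$efficacy)) {
    for (i in which(!(is.finite(eff$efficacy) & eff$efficacy >= 0 & eff$efficacy <= 1))) {
      bad("CoverageProfile", paste0("efficacy.", eff$intervention[i], ".",
                                    eff$target[i]), "must lie in [0, 1]")
    }
  }
  for (nm in unique(iv$intervention)) {
    if (!nm %in% eff$intervention) {
      bad("CoverageProfile", paste0("interventions.", nm),
          "must name at least one target subcondition")
    }
  }
  if (!all(eff$target %in% SUBCONDITIONS)) {
    bad("CoverageProfile", "efficacy.target", "targets must be known subconditions")
  }

  # completeness: every gate a diagnosis-requiring treatment refers to exists
  gated <- distinct(iv, .data$intervention, .data$requires_diagnosis, .data$gate)
  for (i in seq_len(nrow(gated))) {
    if (!gated$requires_diagnosis[i]) next
    need <- if (gated$gate[i] == "target") {
      unname(SUBCONDITION_GATE[eff$target[eff$intervention == gated$intervention[i]]])
    } else gated$gate[i]
    missing <- setdiff(need, unique(d$gate))
    if (length(missing) > 0) {
      bad("ParameterSet", paste0("interventions.", gated$intervention[i]),
          paste0("references missing diagnostic gate(s): ",
                 paste(missing, collapse = ", ")))
    }
  }

  tr <- p$transfer$probabilities
  if (!in01(tr$probability)) bad("TransferSpec", "transfer", "must lie in [0, 1]")
  if (any(tr$origin == "hospital")) {
    bad("TransferSpec", "transfer", "no transfer out of hospital")
  }
  if (!p$transfer$destination %in% SETTINGS) {
    bad("TransferSpec", "transfer.destination", "must be a known setting")
  }
  if (!in01(p$coverage_cap)) bad("ParameterSet", "coverage_cap", "must lie in [0, 1]")
  if (!p$anc_weighting %in% c("anc", "delivery")) {
    bad("ParameterSet", "anc_weighting", "must be \"anc\" or \"delivery\"")
  }
  if (!p$incremental_mode %in% c("additive", "relative")) {
    bad("ParameterSet", "incremental_mode", "must be \"additive\" or \"relative\"")
  }

  if (length(v) == 0) {
    return(tibble(type = character(), field = character(), rule = character()))
  }
  bind_rows(v)
}

#' Bundled sub-Saharan Africa 2015 baseline parameterization
#'
#' Loads the parameter set shipped with the package: 3,988,000 preterm births
#' with a 50/35/15 home/clinic/hospital delivery mix, 30/65/5 antenatal-care
#' mix, the six subcondition prevalence and untreated case-fatality rates,
#' per-setting diagnostic performance for each gate, and per-setting
#' penetration/utilization (plus per-target efficacy) for the eleven modelled
#' interventions, at current-care levels.
#'
#' @return A validated `preterm_params` object.
#' @export
#' @examples
#' baseline_parameters()
baseline_parameters <- function() {
  load_parameter_set(system.file("extdata", "baseline_ssa_2015.yaml",
                                 package = "pretermcascade", mustWork = TRUE))
}

#' Write a parameter set to YAML
#'
#' Serializes a `preterm_params` object so that
#' `load_parameter_set(write_parameter_set(p, path))` reproduces `p`
#' exactly. Values are written as proportions (`units: proportion`).
#'
#' @param p A validated `preterm_params` object.
#' @param path File to write.
#' @return `path`, invisibly.
#' @export
write_parameter_set <- function(p, path) {
  iv_names <- unique(p$interventions$intervention)
  as_map <- function(x) as.list(setNames(x, SETTINGS))
  cfg <- list(
    name = p$name,
    units = "proportion",
    coverage_cap = p$coverage_cap,
    anc_weighting = p$anc_weighting,
    incremental_mode = p$incremental_mode,
    population = list(
      n_preterm_births = p$n_preterm_births,
      delivery_mix = as.list(p$delivery_mix),
      anc_mix = as.list(p$anc_mix)
    ),
    subconditions = purrr::pmap(p$subconditions, function(subcondition, prevalence, untreated_cfr) {
      list(name = subcondition, prevalence = prevalence, untreated_cfr = untreated_cfr)
    }),
    diagnostics = purrr::map(unique(p$diagnostics$gate), function(g) {
      rows <- filter(p$diagnostics, .data$gate == g)
      list(gate = g,
           penetration = as_map(rows$penetration),
           utilization = as_map(rows$utilization),
           efficacy = as_map(rows$efficacy))
    }),
    interventions = purrr::map(iv_names, function(nm) {
      rows <- filter(p$interventions, .data$intervention == nm)
      effs <- filter(p$efficacies, .data$intervention == nm)
      list(name = nm,
           role = rows$role[1], timing = rows$timing[1],
           requires_diagnosis = rows$requires_diagnosis[1],
           gate = rows$gate[1],
           penetration = as_map(rows$penetration),
           utilization = as_map(rows$utilization),
           efficacy = as.list(setNames(effs$efficacy, effs$target)))
    }),
    transfer = list(
      destination = p$transfer$destination,
      probabilities = purrr::pmap(p$transfer$probabilities, function(gate, origin, probability) {
        list(gate = gate, origin = origin, probability = probability)
      })
    )
  )
  yaml::write_yaml(cfg, path, precision = 12)
  invisible(path)
}

#' @export
print.preterm_params <- function(x, ...) {
  cat("<preterm_params> ", x$name, "\n", sep = "")
  cat("  preterm births: ", format(x$n_preterm_births, big.mark = ","), "\n", sep = "")
  cat("  delivery mix:   ", paste(sprintf("%s %.0f%%", SETTINGS, 100 * x$delivery_mix),
                                  collapse = ", "), "\n", sep = "")
  cat("  subconditions:  ", nrow(x$subconditions),
      " | gates: ", length(unique(x$diagnostics$gate)),
      " | interventions: ", length(unique(x$interventions$intervention)), "\n", sep = "")
  invisible(x)
}
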