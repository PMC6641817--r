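#' @title The deterministic cohort cascade
#' @name cohort_cascade
#' @description
#' The engine allocates the preterm cohort across delivery settings and
#' subconditions, pushes every stratum through diagnosis, optional referral
#' transfer, and treatment, and accumulates expected deaths. All quantities
#' are expected values over the cohort; the computation is purely arithmetic
#' and bit-reproducible. Interventions combine as independent multiplicative
#' reductions of the residual case-fatality rate:
#' `cfr_effective = cfr_untreated * prod(1 - coverage_i * efficacy_i)`.
NULL

setting_rank <- function(s) match(s, SETTINGS)

#' Allocate the preterm cohort into strata
#'
#' Splits the cohort into one stratum per subcondition and delivery setting:
#' `n_cases = n_preterm_births * delivery_mix[setting] * prevalence`.
#' Prevalences partition the cohort (they sum to 1 in the bundled
#' parameterization), so strata case counts sum to the number of preterm
#' births.
#'
#' @param p A validated `preterm_params` object.
#' @return A tibble with columns `subcondition`, `origin_setting`, `setting`
#'   (equal to the origin before any transfer), `n_cases`, plus the transfer
#'   bookkeeping columns `pl_transferred` (relocated to hospital on a
#'   preterm-labor diagnosis) and `own_diag` (diagnosis status for the
#'   stratum's own gate: `NA` = evaluate the diagnostic probability at the
#'   setting of care, 0/1 = resolved by an explicit transfer split).
#' @export
#' @examples
#' allocate_cohort(baseline_parameters())
allocate_cohort <- function(p) {
  tidyr::expand_grid(
    subcondition = p$subconditions$subcondition,
    origin_setting = SETTINGS
  ) %>%
    left_join(p$subconditions, by = "subcondition") %>%
    mutate(
      setting = .data$origin_setting,
      n_cases = p$n_preterm_births *
        unname(p$delivery_mix[.data$origin_setting]) * .data$prevalence,
      pl_transferred = FALSE,
      own_diag = NA_real_
    ) %>%
    select("subcondition", "origin_setting", "setting", "n_cases",
           "pl_transferred", "own_diag")
}

#' Probability that a condition is diagnosed
#'
#' The diagnosis cascade at a setting is the product of the gate's
#' penetration (the diagnostic is on hand), utilization (it is applied), and
#' diagnostic efficacy (it identifies the condition) at that setting.
#'
#' @param p A `preterm_params` object.
#' @param gate Diagnostic gate name (e.g. `"sepsis"`, `"preterm_labor"`).
#' @param setting Care setting; vectorized.
#' @return Numeric vector of diagnosis probabilities.
#' @export
#' @examples
#' diagnosis_probability(baseline_parameters(), "sepsis", "home")  # 0.534375
diagnosis_probability <- function(p, gate, setting) {
  if (!all(gate %in% p$diagnostics$gate)) {
    abort(paste0("not a diagnostic gate: ",
                 paste(setdiff(gate, p$diagnostics$gate), collapse = ", ")))
  }
  d <- p$diagnostics
  i <- match(paste(gate, setting), paste(d$gate, d$setting))
  d$penetration[i] * d$utilization[i] * d$efficacy[i]
}

#' Probability that a treatment is received
#'
#' A diagnosis-gated treatment reaches the fraction
#' `diagnosed * penetration * utilization` of cases at a setting. Universal
#' newborn-care profiles (drying and stimulation, cord care, breastfeeding,
#' kangaroo mother care) do not require a prior diagnosis; for those,
#' `diagnosed` is forced to 1.
#'
#' @param p A `preterm_params` object.
#' @param intervention Intervention name.
#' @param setting Care setting; vectorized.
#' @param diagnosed Probability the case was diagnosed (ignored for ungated
#'   profiles).
#' @return Numeric vector of receipt probabilities.
#' @export
#' @examples
#' p <- baseline_parameters()
#' treatment_probability(p, "sepsis_antibiotics", "hospital",
#'                       diagnosed_probability = 0.7695)
treatment_probability <- function(p, intervention, setting,
                                  diagnosed_probability = 1) {
  iv <- p$interventions
  if (!all(intervention %in% iv$intervention)) {
    if (any(intervention %in% p$diagnostics$gate)) {
      abort("diagnostic gates have no treatment probability; use diagnosis_probability()")
    }
    abort(paste0("unknown intervention: ", paste(intervention, collapse = ", ")))
  }
  i <- match(paste(intervention, setting), paste(iv$intervention, iv$setting))
  gated <- iv$requires_diagnosis[i]
  ifelse(gated, diagnosed_probability, 1) * iv$penetration[i] * iv$utilization[i]
}

#' Combine interventions into an effective case-fatality rate
#'
#' Each intervention reduces mortality by its efficacy in the covered
#' fraction of cases; interventions act independently, so the residual risk
#' is the product of the per-intervention residuals:
#' `cfr * prod(1 - coverage * efficacy)`.
#'
#' @param untreated_cfr Case-fatality rate absent any intervention.
#' @param efficacy,coverage Equal-length numeric vectors in `[0, 1]`, one
#'   entry per intervention reaching the stratum.
#' @return The effective case-fatality rate, guaranteed to lie in
#'   `[0, untreated_cfr]`.
#' @export
#' @examples
#' combined_residual_cfr(0.35, efficacy = 0.5, coverage = 0.5)  # 0.2625
combined_residual_cfr <- function(untreated_cfr, efficacy = numeric(),
                                  coverage = numeric()) {
  stopifnot(length(efficacy) == length(coverage),
            all(efficacy >= 0 & efficacy <= 1),
            all(coverage >= 0 & coverage <= 1))
  untreated_cfr * prod(1 - coverage * efficacy)
}

# Fraction of the whole cohort relocated to the transfer destination on a
# preterm-labor diagnosis, plus antenatal coverage for stayers/movers.
antenatal_plan <- function(p) {
  mix <- if (p$anc_weighting == "anc") p$anc_mix else p$delivery_mix
  tr <- p$transfer$probabilities
  dest <- p$transfer$destination
  d_a <- diagnosis_probability(p, "preterm_labor", SETTINGS)
  t_a <- vapply(SETTINGS, function(s) {
    if (setting_rank(s) >= setting_rank(dest)) return(0)
    i <- tr$gate == "preterm_labor" & tr$origin == s
    if (any(i)) tr$probability[i] else 0
  }, numeric(1))
  moved <- sum(mix * d_a * t_a)

  ante <- filter(p$interventions, .data$timing == "antenatal")
  cov <- purrr::map_dfr(unique(ante$intervention), function(nm) {
    rows <- filter(ante, .data$intervention == nm)
    pu <- setNames(rows$penetration * rows$utilization, rows$setting)[SETTINGS]
    stay_cov <- if (moved < 1) {
      sum(mix * d_a * (1 - t_a) * pu) / (1 - moved)
    } else 0
    tibble(intervention = nm, coverage_stay = stay_cov,
           coverage_moved = unname(pu[dest]))
  })
  list(moved_fraction = moved, antenatal_coverage = cov, destination = dest)
}

#' Apply referral transfer to allocated strata
#'
#' Two referral mechanisms operate on diagnosed cases when a scenario sets a
#' positive transfer probability. A preterm-labor transfer relocates the
#' diagnosed fraction of mothers (recognised at their antenatal-care setting)
#' to the destination for delivery, so every subcondition stratum is
#' affected. A subcondition-gate transfer moves the diagnosed fraction of a
#' stratum from its setting of care to the destination, splitting the stratum
#' into undiagnosed stayers, diagnosed stayers, and diagnosed movers so the
#' downstream treatment arithmetic matches the individual-level tree exactly.
#' Case counts are conserved.
#'
#' @param strata Output of [allocate_cohort()].
#' @param p The `preterm_params` the strata were allocated from.
#' @return A strata tibble with the same columns, possibly more rows.
#' @export
apply_transfer <- function(strata, p) {
  tr <- p$transfer$probabilities
  dest <- p$transfer$destination

  # stage 1: preterm-labor relocation (changes the delivery setting)
  m <- antenatal_plan(p)$moved_fraction
  if (m > 0) {
    moved <- strata %>%
      mutate(n_cases = .data$n_cases * m, setting = dest, pl_transferred = TRUE)
    strata <- strata %>%
      mutate(n_cases = .data$n_cases * (1 - m)) %>%
      bind_rows(moved)
  }

  # stage 2: per-subcondition gate transfer from the current setting of care
  out <- purrr::pmap_dfr(strata, function(subcondition, origin_setting, setting,
                                          n_cases, pl_transferred, own_diag) {
    row <- tibble(subcondition, origin_setting, setting, n_cases,
                  pl_transferred, own_diag)
    if (setting_rank(setting) >= setting_rank(dest)) return(row)
    g <- SUBCONDITION_GATE[[subcondition]]
    i <- tr$gate == g & tr$origin == setting
    t_prob <- if (any(i)) tr$probability[i] else 0
    if (t_prob <= 0) return(row)
    d <- diagnosis_probability(p, g, setting)
    bind_rows(
      mutate(row, n_cases = n_cases * (1 - d), own_diag = 0),
      mutate(row, n_cases = n_cases * d * (1 - t_prob), own_diag = 1),
      mutate(row, n_cases = n_cases * d * t_prob, own_diag = 1, setting = dest)
    )
  })
  filter(out, .data$n_cases > 0 | (.data$origin_setting == .data$setting &
                                     !.data$pl_transferred & is.na(.data$own_diag)))
}

# Per-stratum, per-intervention coverage and residual factors.
cascade_trace <- function(p, strata) {
  plan <- antenatal_plan(p)
  strata$stratum_id <- seq_len(nrow(strata))

  long <- strata %>%
    left_join(p$efficacies, by = c(subcondition = "target"),
              relationship = "many-to-many") %>%
    filter(!is.na(.data$intervention)) %>%
    left_join(p$interventions,
              by = c("intervention", "setting")) %>%
    left_join(plan$antenatal_coverage, by = "intervention")

  long <- long %>%
    mutate(
      gate_used = dplyr::case_when(
        .data$timing == "antenatal" ~ NA_character_,
        !.data$requires_diagnosis ~ NA_character_,
        .data$gate == "target" ~ unname(SUBCONDITION_GATE[.data$subcondition]),
        TRUE ~ .data$gate
      ),
      gate_prob = dplyr::case_when(
        is.na(.data$gate_used) ~ NA_real_,
        !is.na(.data$own_diag) & .data$gate_used ==
          unname(SUBCONDITION_GATE[.data$subcondition]) ~ .data$own_diag,
        TRUE ~ diagnosis_probability(
          p, dplyr::coalesce(.data$gate_used, "preterm_labor"), .data$setting)
      ),
      # coverage given the diagnosis branch (gated) or unconditionally
      coverage = dplyr::case_when(
        .data$timing == "antenatal" & .data$pl_transferred ~ .data$coverage_moved,
        .data$timing == "antenatal" ~ .data$coverage_stay,
        TRUE ~ .data$penetration * .data$utilization
      ),
      branch_factor = 1 - .data$coverage * .data$efficacy
    ) %>%
    select("stratum_id", "subcondition", "origin_setting", "setting",
           "n_cases", "intervention", "efficacy", "gate_used", "gate_prob",
           "coverage", "branch_factor")
  list(strata = strata, trace = long)
}

# Residual CFR multiplier per stratum: ungated (and antenatal) profiles
# multiply independently; profiles sharing a diagnostic gate hang off one
# diagnosis node, so the stratum mixes over that branch:
#   (1 - d) + d * prod_gated(1 - pen*util*efficacy)
stratum_residuals <- function(trace) {
  ungated <- trace %>%
    filter(is.na(.data$gate_used)) %>%
    group_by(.data$stratum_id) %>%
    summarise(residual = prod(.data$branch_factor), .groups = "drop")
  gated <- trace %>%
    filter(!is.na(.data$gate_used)) %>%
    group_by(.data$stratum_id, .data$gate_used) %>%
    summarise(d = .data$gate_prob[1],
              treated = prod(.data$branch_factor), .groups = "drop") %>%
    mutate(factor = (1 - .data$d) + .data$d * .data$treated) %>%
    group_by(.data$stratum_id) %>%
    summarise(residual = prod(.data$factor), .groups = "drop")
  bind_rows(ungated, gated) %>%
    group_by(.data$stratum_id) %>%
    summarise(residual = prod(.data$residual), .groups = "drop")
}

#' Run the full cohort cascade
#'
#' Executes the whole decision tree on a parameter set: cohort allocation,
#' diagnosis, referral transfer, treatment, and mortality. Identical inputs
#' give bit-identical results.
#'
#' @param p A validated `preterm_params` object (already transformed by a
#'   scenario, if any).
#' @param trace If `TRUE`, attach a per-stratum, per-intervention audit table
#'   (diagnosis probability, coverage, residual factor) as the `"trace"`
#'   attribute.
#' @return A `preterm_mortality` object: a tibble with one row per stratum
#'   (`subcondition`, `origin_setting`, `setting`, `n_cases`,
#'   `effective_cfr`, `deaths`) carrying the parameter-set name as
#'   provenance. Use [glance()] for totals and [tidy()] for a
#'   subcondition-by-setting summary.
#' @export
#' @examples
#' res <- run_cohort(baseline_parameters())
#' glance(res)
run_cohort <- function(p, trace = FALSE) {
  strata <- apply_transfer(allocate_cohort(p), p)
  ct <- cascade_trace(p, strata)
  strata <- ct$strata

  factors <- stratum_residuals(ct$trace)

  out <- strata %>%
    left_join(factors, by = "stratum_id") %>%
    left_join(p$subconditions, by = "subcondition") %>%
    mutate(
      residual = dplyr::coalesce(.data$residual, 1),
      effective_cfr = .data$untreated_cfr * .data$residual,
      deaths = .data$n_cases * .data$effective_cfr
    ) %>%
    select("subcondition", "origin_setting", "setting", "n_cases",
           "effective_cfr", "deaths")

  structure(out,
            class = c("preterm_mortality", class(out)),
            params = p$name,
            scenario = NA_character_,
            n_preterm_births = p$n_preterm_births,
            trace = if (trace) select(ct$trace, -"stratum_id") else NULL)
}

#' Total expected deaths, optionally restricted to subconditions
#'
#' @param x A `preterm_mortality` object.
#' @param subconditions Optional character vector restricting the total to a
#'   cause-of-death group (e.g. `c("RDS", "IVH", "NEC")`).
#' @return Total expected deaths (unrounded).
#' @export
total_deaths <- function(x, subconditions = NULL) {
  stopifnot(inherits(x, "preterm_mortality"))
  if (!is.null(subconditions)) x <- filter(x, .data$subcondition %in% subconditions)
  sum(x$deaths)
}

#' @method tidy preterm_mortality
#' @export
tidy.preterm_mortality <- function(x, ...) {
  x %>%
    as_tibble() %>%
    group_by(.data$subcondition, .data$setting) %>%
    summarise(n_cases = sum(.data$n_cases), deaths = sum(.data$deaths),
              .groups = "drop") %>%
    mutate(effective_cfr = if_else(.data$n_cases > 0,
                                   .data$deaths / .data$n_cases, 0))
}

#' @method glance preterm_mortality
#' @export
glance.preterm_mortality <- function(x, ...) {
  tibble(
    params = attr(x, "params"),
    scenario = attr(x, "scenario"),
    n_preterm_births = attr(x, "n_preterm_births"),
    total_cases = sum(x$n_cases),
    total_deaths = sum(x$deaths)
  )
}

#' @export
print.preterm_mortality <- function(x, ...) {
  cat("<preterm_mortality> params:", attr(x, "params"),
      if (!is.na(attr(x, "scenario"))) paste0("scenario: ", attr(x, "scenario")),
      "\n")
  cat("  total deaths:", format(round(sum(x$deaths)), big.mark = ","),
      "of", format(round(sum(x$n_cases)), big.mark = ","), "cases\n")
  NextMethod()
}

#' Serialize a mortality result
#'
#' Writes the subcondition-by-setting summary to CSV (`.csv` path) or JSON
#' (`.json` path), with the total appended in the JSON form.
#'
#' @param x A `preterm_mortality` object.
#' @param path Output file; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_mortality_result <- function(x, path) {
  td <- tidy(x)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(list(
      params = attr(x, "params"),
      total_deaths = sum(x$deaths),
      by_stratum = td
    ), path, auto_unbox = TRUE, digits = NA)
  } else {
    write.csv(td, path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname run_cohort
#' @param object,... `preterm_mortality` object and ignored arguments, for
#'   the `autoplot` method.
#' @method autoplot preterm_mortality
#' @export
autoplot.preterm_mortality <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$subcondition, y = .data$deaths,
                                   fill = .data$setting)) +
    ggplot2::geom_col() +
    ggplot2::scale_y_continuous(labels = function(b) format(b, big.mark = ",")) +
    ggplot2::labs(x = NULL, y = "Expected preterm deaths",
                  fill = "Setting of care",
                  title = "Expected preterm deaths by subcondition") +
    ggplot2::theme_minimal()
}
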