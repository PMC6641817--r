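#' @title Random parameter sets and the microsimulation oracle
#' @name synthetic_params
#' @description
#' Property tests need many valid parameter sets, and the deterministic
#' cascade needs an independent check. [random_parameter_set()] draws
#' fully-valid random parameterizations of the model's fixed structure (six
#' subconditions, seven diagnostic gates, eleven interventions), and
#' [microsim_oracle()] re-expresses the same decision tree as an
#' individual-level Monte Carlo simulation: every availability, use,
#' diagnosis, transfer, and death event is a separate Bernoulli draw. The
#' oracle shares none of the cascade's expected-value arithmetic, so
#' agreement between the two (within Monte Carlo error) validates the
#' engine end to end.
NULL

#' Configuration for the synthetic-parameter generator
#'
#' Sampling intervals for every class of model quantity, all within
#' `[0, 1]`. Defaults span the full range so property tests exercise corner
#' regions; untreated case-fatality rates default to a realistic 1%-60%
#' band. Sampled values are rounded to 6 decimals so that YAML round-trips
#' are exact.
#'
#' @param seed Integer RNG seed; the generator is deterministic given it.
#' @param n_individuals Default microsimulation cohort size.
#' @param penetration_range,utilization_range,efficacy_range,cfr_range
#'   Length-2 sampling intervals within `[0, 1]`.
#' @param n_preterm_births Cohort size for generated sets.
#' @return A `synthetic_config` list.
#' @export
#' @examples
#' synthetic_config(seed = 7)
synthetic_config <- function(seed = 1L, n_individuals = 2e6,
                             penetration_range = c(0, 1),
                             utilization_range = c(0, 1),
                             efficacy_range = c(0, 1),
                             cfr_range = c(0.01, 0.6),
                             n_preterm_births = 3988000) {
  cfg <- list(seed = as.integer(seed), n_individuals = n_individuals,
              penetration_range = penetration_range,
              utilization_range = utilization_range,
              efficacy_range = efficacy_range, cfr_range = cfr_range,
              n_preterm_births = n_preterm_births)
  for (r in c("penetration_range", "utilization_range", "efficacy_range",
              "cfr_range")) {
    x <- cfg[[r]]
    if (length(x) != 2 || any(x < 0 | x > 1) || x[1] > x[2]) {
      abort(paste0(r, " must be an interval within [0, 1]"))
    }
  }
  if (cfg$n_individuals < 1) abort("n_individuals must be >= 1")
  structure(cfg, class = "synthetic_config")
}

# integer composition of 1e6 proportional to w, so proportions sum to 1
# exactly in decimal (and within floating slack as doubles)
integer_mix <- function(w) {
  k <- floor(w / sum(w) * 1e6)
  k[1] <- k[1] + (1e6 - sum(k))
  k / 1e6
}

#' Draw a random valid parameter set
#'
#' Samples every coverage, efficacy, prevalence, and case-fatality value of
#' the model's fixed structure from the configured intervals. Prevalences
#' and location mixes are renormalised to sum to 1, transfer probabilities
#' start at 0 (current care), and the result always passes
#' [validate_parameter_set()]. Deterministic given `cfg$seed`.
#'
#' @param cfg A [synthetic_config()].
#' @return A validated `preterm_params` object.
#' @export
#' @examples
#' random_parameter_set(synthetic_config(seed = 42))
random_parameter_set <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  template <- baseline_parameters()
  withr::with_seed(cfg$seed, {
    r01 <- function(n, range) round(runif(n, range[1], range[2]), 6)
    p <- template
    p$name <- sprintf("synthetic_seed_%d", cfg$seed)
    p$n_preterm_births <- cfg$n_preterm_births
    p$delivery_mix <- setNames(integer_mix(runif(3, 0.05, 1)), SETTINGS)
    p$anc_mix <- setNames(integer_mix(runif(3, 0.05, 1)), SETTINGS)
    p$subconditions$prevalence <- integer_mix(runif(6, 0.05, 1))
    p$subconditions$untreated_cfr <- r01(6, cfg$cfr_range)
    nd <- nrow(p$diagnostics)
    p$diagnostics$penetration <- r01(nd, cfg$penetration_range)
    p$diagnostics$utilization <- r01(nd, cfg$utilization_range)
    p$diagnostics$efficacy <- r01(nd, cfg$efficacy_range)
    ni <- nrow(p$interventions)
    p$interventions$penetration <- r01(ni, cfg$penetration_range)
    p$interventions$utilization <- r01(ni, cfg$utilization_range)
    p$efficacies$efficacy <- r01(nrow(p$efficacies), cfg$efficacy_range)
    p$transfer$probabilities$probability <- 0
    p
  })
}

# inverse-CDF draw of one category per individual from per-individual or
# shared probability vectors (columns = categories)
draw_category <- function(u, probs) {
  pmin(findInterval(u, cumsum(probs), left.open = TRUE) + 1, length(probs))
}

#' Individual-level Monte Carlo oracle for the cohort cascade
#'
#' Simulates `n_individuals` neonates through the same decision tree the
#' deterministic engine evaluates in expectation: antenatal-care location,
#' preterm-labor recognition and (if enabled) referral for delivery,
#' antenatal prophylaxis receipt, delivery location, subcondition,
#' subcondition recognition, referral, per-intervention availability and
#' use, and finally death at the residual case-fatality rate. Every stage is
#' its own Bernoulli/categorical draw; uniform variates are consumed in a
#' fixed stage order, so running two parameter sets under one seed gives
#' common-random-number coupling (useful for testing monotonicity
#' stochastically).
#'
#' @param p A validated `preterm_params` object (already scenario-transformed
#'   if a scenario is being checked, or use `scenario`/`level`).
#' @param n_individuals Number of simulated neonates.
#' @param seed Integer seed; always explicit in the output.
#' @param scenario Optional scenario row from [scenario_library()]; applied
#'   to `p` before simulating.
#' @param level `"incremental"` or `"universal"` transform when `scenario`
#'   is given.
#' @param subconditions Optional cause-of-death filter for the estimate.
#' @return A one-row tibble: `estimate` (deaths scaled to the cohort), `se`
#'   (binomial standard error on that scale), `deaths_simulated`,
#'   `n_individuals`, and `seed`.
#' @export
#' @examples
#' microsim_oracle(baseline_parameters(), n_individuals = 1e4, seed = 17)
microsim_oracle <- function(p, n_individuals = 2e6, seed = 1L,
                            scenario = NULL, level = c("universal", "incremental"),
                            subconditions = NULL) {
  if (!is.null(scenario)) {
    level <- match.arg(level)
    p <- if (level == "universal") apply_universal(p, scenario) else
      apply_incremental(p, scenario)
  }
  n <- as.integer(n_individuals)
  dest <- p$transfer$destination
  dest_rank <- setting_rank(dest)

  # flat per-(gate|intervention, setting) lookup matrices for fast indexing
  gate_names <- unique(p$diagnostics$gate)
  as_mat <- function(df, key, col) {
    m <- matrix(df[[col]], nrow = length(unique(df[[key]])), ncol = 3,
                byrow = TRUE,
                dimnames = list(unique(df[[key]]), SETTINGS))
    m
  }
  pen_d <- as_mat(p$diagnostics, "gate", "penetration")
  util_d <- as_mat(p$diagnostics, "gate", "utilization")
  eff_d <- as_mat(p$diagnostics, "gate", "efficacy")
  iv_names <- unique(p$interventions$intervention)
  pen_i <- as_mat(p$interventions, "intervention", "penetration")
  util_i <- as_mat(p$interventions, "intervention", "utilization")

  tmat <- matrix(0, nrow = length(gate_names), ncol = 3,
                 dimnames = list(gate_names, SETTINGS))
  tr <- p$transfer$probabilities
  for (i in seq_len(nrow(tr))) {
    if (setting_rank(tr$origin[i]) < dest_rank) {
      tmat[tr$gate[i], tr$origin[i]] <- tr$probability[i]
    }
  }

  dcol <- function(gate, setting_idx, which) {
    m <- switch(which, penetration = pen_d, utilization = util_d, efficacy = eff_d)
    m[cbind(match(gate, gate_names), setting_idx)]
  }
  ivcol <- function(name, setting_idx, which) {
    m <- switch(which, penetration = pen_i, utilization = util_i)
    m[cbind(match(name, iv_names), setting_idx)]
  }
  tprob <- function(gate, setting_idx) tmat[cbind(match(gate, gate_names), setting_idx)]

  iv_meta <- distinct(p$interventions, .data$intervention, .data$timing,
                      .data$requires_diagnosis, .data$gate)
  ante_names <- iv_meta$intervention[iv_meta$timing == "antenatal"]
  post_names <- iv_meta$intervention[iv_meta$timing != "antenatal"]

  withr::with_seed(seed, {
    mix <- if (p$anc_weighting == "anc") p$anc_mix else p$delivery_mix
    anc <- draw_category(runif(n), mix)

    pl_diag <- (runif(n) < dcol("preterm_labor", anc, "penetration")) &
      (runif(n) < dcol("preterm_labor", anc, "utilization")) &
      (runif(n) < dcol("preterm_labor", anc, "efficacy"))
    pl_move <- pl_diag & (runif(n) < tprob("preterm_labor", anc))

    ante_setting <- ifelse(pl_move, dest_rank, anc)
    ante_received <- lapply(ante_names, function(nm) {
      rec <- (runif(n) < ivcol(nm, ante_setting, "penetration")) &
        (runif(n) < ivcol(nm, ante_setting, "utilization"))
      gated <- iv_meta$requires_diagnosis[iv_meta$intervention == nm]
      if (gated) rec & pl_diag else rec
    })
    names(ante_received) <- ante_names

    delivery <- draw_category(runif(n), p$delivery_mix)
    setting <- ifelse(pl_move, dest_rank, delivery)

    sub_tab <- p$subconditions
    sub_idx <- draw_category(runif(n), sub_tab$prevalence)
    subc <- sub_tab$subcondition[sub_idx]
    own_gate <- unname(SUBCONDITION_GATE[subc])

    own_diag <- (runif(n) < dcol(own_gate, setting, "penetration")) &
      (runif(n) < dcol(own_gate, setting, "utilization")) &
      (runif(n) < dcol(own_gate, setting, "efficacy"))
    own_move <- own_diag & (runif(n) < tprob(own_gate, setting))
    setting <- ifelse(own_move, dest_rank, setting)

    p_death <- sub_tab$untreated_cfr[sub_idx]
    eff <- p$efficacies
    for (nm in c(ante_names, post_names)) {
      if (nm %in% ante_names) {
        received <- ante_received[[nm]]
      } else {
        received <- (runif(n) < ivcol(nm, setting, "penetration")) &
          (runif(n) < ivcol(nm, setting, "utilization"))
        gated <- iv_meta$requires_diagnosis[iv_meta$intervention == nm]
        if (gated) received <- received & own_diag
      }
      e <- eff$efficacy[eff$intervention == nm][
        match(subc, eff$target[eff$intervention == nm])]
      e[is.na(e)] <- 0
      p_death <- p_death * ifelse(received, 1 - e, 1)
    }
    died <- runif(n) < p_death

    counted <- if (is.null(subconditions)) died else died & (subc %in% subconditions)
    phat <- mean(counted)
    tibble(
      estimate = phat * p$n_preterm_births,
      se = sqrt(phat * (1 - phat) / n) * p$n_preterm_births,
      deaths_simulated = sum(counted),
      n_individuals = n,
      seed = as.integer(seed)
    )
  })
}
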