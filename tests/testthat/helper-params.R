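# Shared fixtures, built in code.

baseline <- baseline_parameters()

# Baseline with every intervention (but not diagnostics) switched off.
zero_coverage_params <- function(p = baseline) {
  p$interventions$penetration <- 0
  p$interventions$utilization <- 0
  p$name <- "zero_coverage"
  p
}

# Closed-form no-intervention death total: sum over subconditions of
# births * prevalence * untreated CFR. Independent of the cascade code.
no_intervention_total <- function(p = baseline) {
  sum(p$n_preterm_births * p$subconditions$prevalence *
        p$subconditions$untreated_cfr)
}

direct_group <- c("RDS", "IVH", "NEC")
indirect_group <- c("sepsis", "birth_asphyxia", "LBW_only")

# Nudge one randomly chosen coverage/efficacy parameter upward; returns the
# modified set (used by monotonicity property tests).
perturb_up <- function(p, delta = 0.1) {
  slot <- sample(c("d_pen", "d_util", "d_eff", "i_pen", "i_util", "eff"), 1)
  if (slot == "d_pen") {
    i <- sample(nrow(p$diagnostics), 1)
    p$diagnostics$penetration[i] <- min(1, p$diagnostics$penetration[i] + delta)
  } else if (slot == "d_util") {
    i <- sample(nrow(p$diagnostics), 1)
    p$diagnostics$utilization[i] <- min(1, p$diagnostics$utilization[i] + delta)
  } else if (slot == "d_eff") {
    i <- sample(nrow(p$diagnostics), 1)
    p$diagnostics$efficacy[i] <- min(1, p$diagnostics$efficacy[i] + delta)
  } else if (slot == "i_pen") {
    i <- sample(nrow(p$interventions), 1)
    p$interventions$penetration[i] <- min(1, p$interventions$penetration[i] + delta)
  } else if (slot == "i_util") {
    i <- sample(nrow(p$interventions), 1)
    p$interventions$utilization[i] <- min(1, p$interventions$utilization[i] + delta)
  } else {
    i <- sample(nrow(p$efficacies), 1)
    p$efficacies$efficacy[i] <- min(1, p$efficacies$efficacy[i] + delta)
  }
  p
}
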