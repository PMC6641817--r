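test_that("cohort allocation partitions births by setting and subcondition", {
  strata <- allocate_cohort(baseline)
  home_rds <- dplyr::filter(strata, subcondition == "RDS", setting == "home")
  expect_equal(home_rds$n_cases, 3988000 * 0.50 * 0.20)  # 398,800
  expect_equal(sum(strata$n_cases), 3988000)

  # degenerate prevalence: everything in one channel
  p <- baseline
  p$subconditions$prevalence <- ifelse(p$subconditions$subcondition == "LBW_only", 1, 0)
  s2 <- allocate_cohort(p)
  expect_equal(sum(s2$n_cases[s2$subcondition == "LBW_only"]), 3988000)
  expect_equal(sum(s2$n_cases[s2$subcondition != "LBW_only"]), 0)
})

test_that("diagnosis probability is the penetration x utilization x efficacy product", {
  expect_equal(diagnosis_probability(baseline, "sepsis", "home"),
               0.95 * 0.75 * 0.75)  # 0.534375
  expect_equal(diagnosis_probability(baseline, "RDS", "hospital"),
               0.90 * 0.95 * 0.95)  # 0.81225
  p <- baseline
  p$diagnostics$utilization[p$diagnostics$gate == "NEC"] <- 0
  expect_equal(diagnosis_probability(p, "NEC", c("home", "clinic", "hospital")),
               c(0, 0, 0))
  expect_error(diagnosis_probability(baseline, "surfactant", "home"),
               "not a diagnostic gate")
})

test_that("treatment receipt is gated on diagnosis unless the profile is universal care", {
  expect_equal(
    treatment_probability(baseline, "sepsis_antibiotics", "hospital",
                          diagnosed_probability = 0.7695),
    0.7695 * 0.95 * 0.75)
  expect_equal(
    treatment_probability(baseline, "sepsis_antibiotics", "clinic",
                          diagnosed_probability = 0),
    0)
  # chlorhexidine has zero baseline penetration everywhere
  expect_equal(treatment_probability(baseline, "cord_care", "home"), 0)
  # ungated universal newborn care ignores the diagnosis argument
  expect_equal(
    treatment_probability(baseline, "breastfeeding", "clinic",
                          diagnosed_probability = 0),
    0.99 * 0.40)
  expect_error(treatment_probability(baseline, "sepsis", "home"),
               "diagnostic gates")
})

test_that("interventions combine multiplicatively on residual risk", {
  expect_equal(combined_residual_cfr(0.17), 0.17)  # empty product
  expect_equal(combined_residual_cfr(0.8, efficacy = 1, coverage = 1), 0)
  expect_equal(combined_residual_cfr(0.35, efficacy = 0.5, coverage = 0.5),
               0.35 * (1 - 0.25))  # 0.2625
  expect_equal(
    combined_residual_cfr(0.4, efficacy = c(0.5, 0.2), coverage = c(0.3, 1)),
    0.4 * (1 - 0.15) * (1 - 0.2))
})

test_that("the all-coverage-zero run matches the closed-form death total", {
  res <- run_cohort(zero_coverage_params())
  expect_equal(total_deaths(res), no_intervention_total(), tolerance = 1e-12)
  # hand value: 279,160 + 20,937 + 9,970 + 143,568 + 159,520 + 36,011.64
  expect_equal(no_intervention_total(), 649166.64)
})

test_that("zero efficacy means coverage is irrelevant", {
  p <- baseline
  p$efficacies$efficacy <- 0
  expect_equal(total_deaths(run_cohort(p)), no_intervention_total(),
               tolerance = 1e-12)
})

test_that("case counts are conserved through every pipeline stage", {
  lib <- scenario_library()
  for (id in c("t3s06", "t3s10", "t4s15", "t4s18")) {
    p <- apply_universal(baseline, lib[lib$id == id, ])
    strata <- allocate_cohort(p)
    expect_equal(sum(strata$n_cases), p$n_preterm_births, label = id)
    after <- apply_transfer(strata, p)
    expect_equal(sum(after$n_cases), p$n_preterm_births, label = id)
    res <- run_cohort(p)
    expect_equal(sum(res$n_cases), p$n_preterm_births, label = id)
  }
})

test_that("transfer splits move diagnosed cases and conserve the cohort", {
  p <- baseline
  strata <- allocate_cohort(p)
  # zero transfer: strata unchanged
  expect_equal(apply_transfer(strata, p), strata)

  # certain diagnosis + certain transfer from clinic empties the clinic stratum
  p2 <- baseline
  p2$diagnostics$penetration[p2$diagnostics$gate == "sepsis"] <- 1
  p2$diagnostics$utilization[p2$diagnostics$gate == "sepsis"] <- 1
  p2$diagnostics$efficacy[p2$diagnostics$gate == "sepsis"] <- 1
  p2$transfer$probabilities$probability[
    p2$transfer$probabilities$gate == "sepsis"] <- 1
  after <- apply_transfer(allocate_cohort(p2), p2)
  clinic_sepsis <- dplyr::filter(after, subcondition == "sepsis",
                                 setting == "clinic")
  expect_equal(sum(clinic_sepsis$n_cases), 0)
  moved <- dplyr::filter(after, subcondition == "sepsis", setting == "hospital",
                         origin_setting == "clinic")
  expect_equal(sum(moved$n_cases), 3988000 * 0.35 * 0.09)
  expect_equal(sum(after$n_cases), 3988000)
})

test_that("mortality results satisfy their structural invariants", {
  res <- run_cohort(baseline)
  expect_true(all(res$deaths >= 0))
  expect_equal(sum(res$deaths), total_deaths(res), tolerance = 1e-6)
  # per subcondition, deaths never exceed the untreated expectation
  by_sub <- dplyr::summarise(dplyr::group_by(tibble::as_tibble(res), subcondition),
                             deaths = sum(deaths), .groups = "drop")
  untreated <- baseline$n_preterm_births * baseline$subconditions$prevalence *
    baseline$subconditions$untreated_cfr
  names(untreated) <- baseline$subconditions$subcondition
  expect_true(all(by_sub$deaths <= untreated[by_sub$subcondition] + 1e-9))
})

test_that("the cascade is deterministic and its results tidy cleanly", {
  r1 <- run_cohort(baseline)
  r2 <- run_cohort(baseline)
  expect_identical(r1$deaths, r2$deaths)

  td <- tidy(r1)
  expect_setequal(names(td),
                  c("subcondition", "setting", "n_cases", "deaths", "effective_cfr"))
  gl <- glance(r1)
  expect_equal(gl$total_deaths, sum(r1$deaths))
  expect_equal(gl$total_cases, 3988000)
})

test_that("trace output localizes per-intervention coverage decisions", {
  res <- run_cohort(baseline, trace = TRUE)
  tr <- attr(res, "trace")
  expect_true(all(c("intervention", "gate_used", "gate_prob", "coverage",
                    "branch_factor") %in% names(tr)))
  # surfactant at home has zero penetration, hence zero coverage
  surf_home <- dplyr::filter(tr, intervention == "surfactant", setting == "home")
  expect_true(all(surf_home$coverage == 0))
  # sepsis antibiotics at home are gated by the home sepsis recognition cascade
  abx_home <- dplyr::filter(tr, intervention == "sepsis_antibiotics",
                            setting == "home")
  expect_equal(unique(abx_home$gate_prob), 0.534375)
})

test_that("mortality results serialize to CSV and JSON", {
  res <- run_cohort(baseline)
  csv <- withr::local_tempfile(fileext = ".csv")
  json <- withr::local_tempfile(fileext = ".json")
  write_mortality_result(res, csv)
  write_mortality_result(res, json)
  back <- utils::read.csv(csv)
  expect_equal(sum(back$deaths), sum(res$deaths), tolerance = 1e-8)
  j <- jsonlite::read_json(json)
  expect_equal(j$total_deaths, sum(res$deaths), tolerance = 1e-8)
})
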