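lib <- scenario_library()

test_that("the bundled library covers both scenario groups completely", {
  expect_equal(nrow(lib), 30)
  expect_equal(sum(lib$table == 3), 12)
  expect_equal(sum(lib$table == 4), 18)
  expect_false(any(duplicated(lib$id)))
  expect_equal(lib$mode[lib$number == 1], c("none", "none"))
  expect_equal(lib$subconditions[lib$id == "t3s05"][[1]], c("RDS", "IVH", "NEC"))
  expect_equal(lib$subconditions[lib$id == "t4s05"][[1]],
               c("sepsis", "birth_asphyxia", "LBW_only"))
})

test_that("incremental scale-up adds 20 points, capped, touching only named levers", {
  spec <- lib[lib$id == "t4s08", ]  # cord care at home and clinic
  p2 <- apply_incremental(baseline, spec)
  cc <- dplyr::filter(p2$interventions, intervention == "cord_care")
  expect_equal(setNames(cc$penetration, cc$setting),
               c(home = 0.20, clinic = 0.20, hospital = 0))
  expect_equal(setNames(cc$utilization, cc$setting),
               c(home = 0.20, clinic = 0.20, hospital = 0))
  # untouched profile
  expect_equal(dplyr::filter(p2$interventions, intervention == "ppv"),
               dplyr::filter(baseline$interventions, intervention == "ppv"))
  # efficacy never changes
  expect_equal(p2$efficacies, baseline$efficacies)

  # cap at 98%: KMC penetration 95 -> 98
  spec5 <- lib[lib$id == "t4s05", ]
  p3 <- apply_incremental(baseline, spec5)
  kmc <- dplyr::filter(p3$interventions, intervention == "kangaroo_mother_care")
  expect_equal(unique(kmc$penetration), 0.98)
})

test_that("the relative incremental reading is available as a sensitivity switch", {
  p <- baseline
  p$incremental_mode <- "relative"
  spec <- lib[lib$id == "t4s06", ]
  p2 <- apply_incremental(p, spec)
  abx <- dplyr::filter(p2$interventions, intervention == "sepsis_antibiotics")
  expect_equal(setNames(abx$penetration, abx$setting),
               c(home = 0.10 * 1.2, clinic = 0.98, hospital = 0.98))  # capped
  # from a zero baseline the relative reading cannot move coverage
  spec8 <- lib[lib$id == "t4s08", ]
  p3 <- apply_incremental(p, spec8)
  expect_equal(sum(dplyr::filter(p3$interventions,
                                 intervention == "cord_care")$penetration), 0)
})

test_that("universal scale-up sets named levers to the cap and is idempotent", {
  spec <- lib[lib$id == "t3s02", ]  # surfactant, hospitals only
  p2 <- apply_universal(baseline, spec)
  surf <- dplyr::filter(p2$interventions, intervention == "surfactant")
  expect_equal(setNames(surf$penetration, surf$setting),
               c(home = 0, clinic = 0.01, hospital = 0.98))
  expect_equal(setNames(surf$utilization, surf$setting),
               c(home = 0, clinic = 0.50, hospital = 0.98))
  expect_equal(apply_universal(p2, spec), p2)  # idempotence

  # baseline scenarios are the identity transform
  expect_equal(apply_universal(baseline, lib[lib$id == "t3s01", ]), baseline)
  expect_equal(apply_incremental(baseline, lib[lib$id == "t4s01", ]), baseline)
})

test_that("scenario transforms never mutate their input parameter set", {
  before <- baseline_parameters()
  for (i in seq_len(nrow(lib))) {
    invisible(apply_incremental(before, lib[i, ]))
    invisible(apply_universal(before, lib[i, ]))
  }
  expect_identical(before, baseline_parameters())
})

test_that("transfer-enabled scenarios raise referral probabilities with coverage", {
  spec <- lib[lib$id == "t4s12", ]  # sepsis diagnosis + referral
  inc <- apply_incremental(baseline, spec)
  uni <- apply_universal(baseline, spec)
  tp <- function(p) p$transfer$probabilities$probability[
    p$transfer$probabilities$gate == "sepsis"]
  expect_equal(tp(inc), c(0.20, 0.20))
  expect_equal(tp(uni), c(0.98, 0.98))
  expect_equal(sum(inc$transfer$probabilities$probability[
    inc$transfer$probabilities$gate != "sepsis"]), 0)
})

test_that("the hospital-delivery scenario overrides the location mix", {
  spec <- lib[lib$id == "t3s12", ]
  p2 <- apply_universal(baseline, spec)
  expect_equal(unname(p2$delivery_mix), c(0, 0, 1))
  ancs <- dplyr::filter(p2$interventions,
                        intervention == "antenatal_corticosteroids")
  expect_equal(setNames(ancs$penetration, ancs$setting),
               c(home = 0, clinic = 0.10, hospital = 0.98))
})

test_that("running a scenario returns both improvement levels with provenance", {
  res <- run_scenario(lib[lib$id == "t3s03", ], baseline)
  expect_s3_class(res$incremental, "preterm_mortality")
  expect_s3_class(res$universal, "preterm_mortality")
  expect_match(attr(res$universal, "scenario"), "t3s03")
  # baseline scenario reproduces the unmodified run exactly
  base_run <- run_scenario(lib[lib$id == "t3s01", ], baseline)
  expect_equal(total_deaths(base_run$incremental), total_deaths(run_cohort(baseline)))
  expect_equal(total_deaths(base_run$universal), total_deaths(run_cohort(baseline)))
})

test_that("deaths prevented and percent reduction follow the published arithmetic", {
  base_res <- run_cohort(baseline)
  res <- run_scenario(lib[lib$id == "t4s06", ], baseline)
  dp <- deaths_prevented(base_res, res$universal, indirect_group)
  expect_equal(dp$prevented, dp$baseline_deaths - dp$scenario_deaths)
  expect_equal(dp$percent, 100 * dp$prevented / dp$baseline_deaths)
  expect_true(dp$prevented > 0)
  # identical results: nothing prevented
  dp0 <- deaths_prevented(base_res, base_res)
  expect_equal(dp0$prevented, 0)
  expect_equal(dp0$percent, 0)
})

test_that("packaged scenarios do at least as well as their best component", {
  suite <- run_scenario_suite(baseline, lib, table = 4)
  d <- function(id, col) suite[suite$id == id, ][[col]]
  for (col in c("incremental_deaths", "universal_deaths")) {
    expect_lte(d("t4s18", col), min(d("t4s16", col), d("t4s17", col)))
    expect_lte(d("t4s16", col), min(d("t4s04", col), d("t4s14", col)))
    expect_lte(d("t4s17", col), min(d("t4s08", col), d("t4s15", col)))
  }
})

test_that("referral to better-equipped hospitals never increases deaths", {
  # hospital coverage dominates the origin settings for every profile in the
  # baseline set, so enabling transfer can only help
  for (id in c("t3s06", "t4s10", "t4s12")) {
    spec <- scenario_library()[scenario_library()$id == id, ]
    with_tr <- apply_universal(baseline, spec)
    no_tr <- with_tr
    no_tr$transfer$probabilities$probability <- 0
    expect_lte(total_deaths(run_cohort(with_tr)),
               total_deaths(run_cohort(no_tr)) + 1e-9, label = id)
  }
})
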