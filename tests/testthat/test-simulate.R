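small_cfg <- function(...) scenario_config(
  n_species = 400,
  deteriorations = list(`1980` = c(disease = 24, habitat_loss_degradation = 12,
                                   over_exploitation = 3, climate_change = 1),
    `2004` = c(disease = 6, habitat_loss_degradation = 9,
               climate_change = 10)),
  improvements = list(`1980` = c(conservation = 3, unaided = 2),
                      `2004` = c(conservation = 3, unaided = 3)),
  ...)

test_that("identical config and seed give identical output", {
  s1 <- generate_scenario(small_cfg(seed = 123))
  s2 <- generate_scenario(small_cfg(seed = 123))
  expect_identical(s1, s2)
  s3 <- generate_scenario(small_cfg(seed = 124))
  expect_false(identical(s1$assessments, s3$assessments))
})

test_that("generated tables validate cleanly and DD species never change", {
  s <- generate_scenario(small_cfg(seed = 9))
  expect_equal(nrow(validate_assessments(s$assessments, s$threats)), 0L)
  dd <- s$assessments$species_id[s$assessments$cat_2022 == "DD"]
  expect_false(any(s$ledger$species_id %in% dd))
  expect_true(all(s$assessments$cat_1980[s$assessments$cat_2022 == "DD"] ==
                    "DD"))
})

test_that("the null scenario yields no changes and a flat RLI", {
  cfg <- scenario_config(
    n_species = 200,
    deteriorations = list(`1980` = c(disease = 0), `2004` = c(disease = 0)),
    improvements = list(`1980` = c(conservation = 0, unaided = 0),
                        `2004` = c(conservation = 0, unaided = 0)),
    seed = 3)
  s <- generate_scenario(cfg)
  expect_equal(nrow(s$ledger), 0L)
  ch <- derive_changes(s$assessments, s$ledger)
  expect_equal(sum(ch$genuine), 0L)
  ser <- rli_series(s$assessments, "global")
  expect_equal(length(unique(ser$rli)), 1L)
})

test_that("scripted marginals are hit exactly", {
  s <- generate_scenario(small_cfg(seed = 21))
  ch <- derive_changes(s$assessments, s$ledger)
  tab <- tabulate_changes(ch)
  det80 <- sum(tab$n[tab$direction == "deterioration" &
                       tab$epoch_from == 1980])
  expect_equal(det80, 40L)
  det04 <- sum(tab$n[tab$direction == "deterioration" &
                       tab$epoch_from == 2004])
  expect_equal(det04, 25L)
  expect_equal(unname(improvement_breakdown(ch)),
               c(6L, 5L))
  sh <- driver_shares(ch, 1980L)
  expect_equal(sh$n[sh$driver_group == "disease"], 24L)
})

test_that("the default scenario reproduces the study-scale marginals", {
  s <- generate_scenario(scenario_config(seed = 2))
  expect_equal(nrow(s$assessments), 8011L)
  ch <- derive_changes(s$assessments, s$ledger)
  tab <- tabulate_changes(ch)
  expect_equal(sum(tab$n[tab$direction == "deterioration"]), 788L)
  expect_equal(sum(tab$n[tab$direction == "improvement"]), 120L)
  cc <- category_counts(s$assessments)
  expect_equal(cc$total, rep(8011L, 3))
  expect_equal(cc$DD[3], 909L)
  expect_equal(unname(threatened_fraction(cc, 2022)$percent["best"]), 40.7)
})

test_that("infeasible scenarios are refused", {
  cfg <- scenario_config(
    n_species = 10, category_dist = c(LC = 1),
    deteriorations = list(`1980` = c(disease = 0), `2004` = c(disease = 5)),
    improvements = list(`1980` = c(conservation = 0, unaided = 0),
                        `2004` = c(conservation = 0, unaided = 0)),
    seed = 1)
  # all-LC species cannot have deteriorated into LC
  expect_error(generate_scenario(cfg), "infeasible-scenario")
  cfg2 <- scenario_config(
    n_species = 10, category_dist = c(`CR(PE)` = 1),
    deteriorations = list(`1980` = c(disease = 0), `2004` = c(disease = 0)),
    improvements = list(`1980` = c(conservation = 0, unaided = 0),
                        `2004` = c(conservation = 5, unaided = 0)),
    seed = 1)
  # improvement would require a state above the category ladder
  expect_error(generate_scenario(cfg2), "infeasible-scenario")
})

test_that("stochastic hazards are recovered within 3 binomial SEs", {
  hz <- c(disease = 0.04, habitat_loss_degradation = 0.02,
          climate_change = 0.01)
  for (seed in 1:3) {
    cfg <- scenario_config(
      n_species = 2000, mode = "stochastic",
      category_dist = c(NT = 0.5, VU = 0.3, EN = 0.2),
      det_hazards = list(`1980` = hz, `2004` = hz * 0),
      imp_hazard = 0, improvements = NULL, deteriorations = NULL,
      seed = seed)
    s <- generate_scenario(cfg)
    ch <- derive_changes(s$assessments, s$ledger)
    det <- ch[ch$direction == "deterioration" & ch$epoch_from == 1980, ]
    n_elig <- 2000                       # all species start eligible
    for (g in names(hz)) {
      p <- hz[[g]]
      se <- sqrt(p * (1 - p) / n_elig)
      expect_lt(abs(nrow(det[det$driver_group == g, ]) / n_elig - p),
                3 * se + 1e-9)
    }
  }
})

test_that("generated tables round-trip losslessly through the CSV dialect", {
  s <- generate_scenario(small_cfg(seed = 33))
  td <- withr::local_tempdir()
  write_assessments(s$assessments, file.path(td, "a.csv"))
  write_ledger(s$ledger, file.path(td, "l.csv"))
  a2 <- read_assessments(file.path(td, "a.csv"))
  l2 <- read_ledger(file.path(td, "l.csv"))
  expect_equal(a2, s$assessments)
  expect_equal(l2, s$ledger)
})
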