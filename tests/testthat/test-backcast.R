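test_that("backcasting copies states backward and pins DD at every epoch", {
  a <- make_assessments(c("EN", "DD"))
  bc <- apply_backcast(a)
  expect_equal(bc$cat_1980, c("EN", "DD"))
  expect_equal(bc$cat_2004, c("EN", "DD"))
  expect_equal(bc$cat_2022, c("EN", "DD"))
})

test_that("declarations set the state at the interval start, composing backward", {
  a <- make_assessments("CR(PE)")
  led <- make_decl("s001", 1980L, "LC")
  bc <- apply_backcast(a, led)
  expect_equal(unlist(bc[1, c("cat_1980", "cat_2004", "cat_2022")],
                      use.names = FALSE),
               c("LC", "CR(PE)", "CR(PE)"))
  # both intervals declared: deteriorate then deteriorate again
  led2 <- rbind(make_decl("s001", 1980L, "LC"),
                make_decl("s001", 2004L, "EN"))
  bc2 <- apply_backcast(a, led2)
  expect_equal(unlist(bc2[1, c("cat_1980", "cat_2004", "cat_2022")],
                      use.names = FALSE),
               c("LC", "EN", "CR(PE)"))
})

test_that("backcast matches exhaustive enumeration of the stated rules", {
  # oracle: for every (current, optional declaration in one interval),
  # apply the rules literally — DD pinned, else copy back, declaration
  # overrides at its start epoch
  ladder <- c("LC", "NT", "VU", "EN", "CR", "CR(PE)", "EW", "EX", "DD")
  for (cur in ladder) {
    for (decl_from in c(NA, "LC", "VU", "CR")) {
      for (iv in c(1980L, 2004L)) {
        a <- make_assessments(cur)
        led <- if (is.na(decl_from)) empty_ledger() else
          make_decl("s001", iv, decl_from)
        expected <- rep(cur, 3)
        if (cur == "DD") {
          expected <- rep("DD", 3)
          if (!is.na(decl_from)) {
            expect_error(apply_backcast(a, led), "DD species")
            next
          }
        } else if (!is.na(decl_from)) {
          expected[if (iv == 1980L) 1 else 1:2] <- decl_from
        }
        bc <- apply_backcast(a, led)
        expect_equal(unlist(bc[1, paste0("cat_", c(1980, 2004, 2022))],
                            use.names = FALSE), expected,
                     info = paste(cur, decl_from, iv))
      }
    }
  }
})

test_that("conflicting and resurrecting declarations are rejected", {
  a <- make_assessments("EN")
  dup <- rbind(make_decl("s001", 1980L, "LC"),
               make_decl("s001", 1980L, "VU"))
  expect_error(apply_backcast(a, dup), "conflicting-ledger")
  ex <- make_assessments("EN")
  expect_error(apply_backcast(ex, make_decl("s001", 1980L, "EX")),
               "resurrection")
})

test_that("change direction follows rank, with CR(PE)->EX carved out", {
  a <- make_assessments(c("EN", "EX", "CR(PE)"))
  led <- rbind(make_decl("s001", 1980L, "LC"),
               make_decl("s002", 2004L, "CR(PE)"),
               make_decl("s003", 2004L, "CR"))
  bc <- apply_backcast(a, led)
  ch <- derive_changes(bc, led)
  r1 <- ch[ch$species_id == "s001", ]
  expect_equal(r1$direction, "deterioration")
  expect_true(r1$genuine)
  r2 <- ch[ch$species_id == "s002", ]          # CR(PE) -> EX
  expect_equal(r2$direction, "none")
  expect_true(r2$became_extinct)
  r3 <- ch[ch$species_id == "s003", ]          # CR -> CR(PE)
  expect_equal(r3$direction, "deterioration")
  expect_false(r3$became_extinct)
  # configurable: include CR(PE)->EX as a deterioration
  ch2 <- derive_changes(bc, led, crpe_ex_tally = "include")
  expect_equal(ch2$direction[ch2$species_id == "s002"], "deterioration")
})

test_that("non-genuine rank changes are flagged and excluded from tabulation", {
  # a timeline change without a covering declaration is not genuine
  a <- make_assessments("EN")
  a$cat_1980 <- "LC"; a$cat_2004 <- "EN"; # hand-built timeline
  ch <- derive_changes(a, empty_ledger())
  expect_equal(nrow(ch), 1L)
  expect_false(ch$genuine)
  expect_equal(nrow(tabulate_changes(ch)), 0L)
})

test_that("deriving changes from an emitted timeline is idempotent", {
  set.seed(42)
  s <- generate_scenario(scenario_config(
    n_species = 300,
    deteriorations = list(`1980` = c(disease = 20, climate_change = 5),
                          `2004` = c(habitat_loss_degradation = 10)),
    improvements = list(`1980` = c(conservation = 3, unaided = 2),
                        `2004` = c(conservation = 0, unaided = 0)),
    seed = 11))
  ch1 <- derive_changes(s$assessments, s$ledger)
  bc2 <- apply_backcast(s$assessments, s$ledger)   # re-backcast the output
  ch2 <- derive_changes(bc2, s$ledger)
  expect_identical(ch1, ch2)
})

test_that("primary drivers collapse into the six analysis groups", {
  habitat <- c("agriculture", "mining/energy production",
               "infrastructure development", "human disturbance",
               "timber and plant harvesting", "anthropogenic fire",
               "water management", "native species", "pollution",
               "geological events")
  expect_true(all(group_primary_driver(habitat) == "habitat_loss_degradation"))
  expect_equal(group_primary_driver("disease"), "disease")
  expect_equal(group_primary_driver("over-exploitation"), "over_exploitation")
  expect_equal(group_primary_driver("climate change effects"),
               "climate_change")
  expect_equal(group_primary_driver("undetermined"), "undetermined")
  expect_equal(group_primary_driver("disease", n_codrivers = 2), "numerous")
  expect_warning(g <- group_primary_driver("introduced species"),
                 "unexpected-driver")
  expect_equal(g, "undetermined")
  expect_error(group_primary_driver("volcanic winter"), "unknown primary")
})

test_that("tabulated marginals partition the genuine change set", {
  led <- rbind(
    make_decl(sprintf("d%02d", 1:6), 1980L, "LC", "disease"),
    make_decl(sprintf("h%02d", 1:4), 1980L, "LC", "agriculture"))
  a <- make_assessments(rep("EN", 10), ids = c(sprintf("d%02d", 1:6),
                                               sprintf("h%02d", 1:4)))
  bc <- apply_backcast(a, led)
  ch <- derive_changes(bc, led)
  tab <- tabulate_changes(ch)
  expect_equal(sum(tab$n), 10L)
  expect_equal(sum(tab$n[tab$driver_group == "disease"]), 6L)
  sh <- driver_shares(ch, 1980L)
  expect_equal(sh$percent[sh$driver_group == "disease"], 60)
  expect_identical(nrow(tabulate_changes(ch[0, ])), 0L)
})
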