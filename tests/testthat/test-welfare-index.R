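test_that("domain scores reproduce the published formulas", {
  # hand-evaluated: (0.30*2 + 0.25*1 + 0.25*2 + 0.20*0) / 2 * 100 = 67.5
  d <- domain_score("behaviour_mental", c(S_D = 2, S_HAR = 1, S_SW = 2,
                                          S_St = 0))
  expect_equal(d$value, 67.5)
  # best and worst anchor the 0-100 range exactly, in every domain
  reg <- load_registry()
  members <- reg$indicators[!is.na(reg$indicators$index_weight), ]
  for (dom in unique(members$domain)) {
    syms <- members$symbol[members$domain == dom]
    expect_equal(domain_score(dom, setNames(rep(2, length(syms)), syms))$value,
                 100)
    expect_equal(domain_score(dom, setNames(rep(0, length(syms)), syms))$value,
                 0)
  }
  # scores may be addressed by registry id as well as symbol
  d2 <- domain_score("nutrition", c(rumen_fill = 1, bcs = 2, skin_pinch = 0))
  expect_equal(d2$value, (0.40 * 1 + 0.35 * 2 + 0.25 * 0) / 2 * 100)
  expect_error(domain_score("nutrition", c(S_Ru = 1, S_BCS = 2)),
               class = "asrwi_validation_error", regexp = "S_Sk")
  expect_error(domain_score("nutrition", c(S_Ru = 1, S_BCS = 2, S_Sk = 5)),
               class = "asrwi_range_error")
})

test_that("composite index is the fixed weighted sum of domain scores", {
  expect_equal(asrwi_score(c(behaviour_mental = 100, environment = 50,
                             nutrition = 80, health = 90)), 78)
  expect_equal(asrwi_score(c(behaviour_mental = 100, environment = 100,
                             nutrition = 100, health = 100)), 100)
  expect_equal(asrwi_score(c(behaviour_mental = 0, environment = 0,
                             nutrition = 0, health = 0)), 0)
  expect_error(asrwi_score(c(behaviour_mental = 50, environment = 50,
                             nutrition = 50)),
               class = "asrwi_validation_error", regexp = "health")
})

test_that("selection gate keeps kappa >= 0.35 and index membership", {
  dec <- select_indicators(pilot_reliability())
  # boundary case: goat Social Withdrawal at exactly 0.35 passes
  sw <- dec[dec$indicator_id == "social_withdrawal" & dec$species == "goat", ]
  expect_true(sw$passed_reliability)
  expect_true(sw$included)
  # every published kappa passes the gate; all 16 members included per species
  expect_true(all(dec$passed_reliability))
  expect_equal(sum(dec$included), 32)
  expect_equal(sum(dec$relevance_retained), 32)
  # below-threshold and undefined kappas fail with reasons
  fake <- tibble::tibble(indicator_id = c("panting", "bcs"),
                         species = "goat", kappa = c(0.34, NA))
  dec2 <- select_indicators(fake)
  expect_false(any(dec2$passed_reliability))
  expect_false(any(dec2$included))
  expect_match(dec2$reason[1], "below threshold")
  expect_equal(dec2$reason[2], "kappa undefined")
})

test_that("perfect and worst-case herds hit the index bounds exactly", {
  reg <- load_registry()
  ids <- reg$indicators$id
  best <- tibble::tibble(
    animal_id = rep(c("a1", "a2"), each = 2 * length(ids)),
    species = "goat",
    assessor_id = rep(rep(c("r1", "r2"), each = length(ids)), 2),
    indicator_id = rep(ids, 4),
    score = 2L
  )
  res <- welfare_index(best)
  expect_equal(res$asrwi, 100)
  for (d in res$domain_scores) expect_equal(d$value, 100)
  worst <- best
  worst$score <- 0L
  res0 <- welfare_index(worst)
  expect_equal(res0$asrwi, 0)
  # measured-only indicators surface in the appendix, never in the formula
  expect_equal(nrow(res$appendix), 8)
  expect_true(all(c("equipment", "respiratory") %in%
                    res$appendix$indicator_id))
})

test_that("herd index agrees with a brute-force flat evaluator", {
  sheet <- generate_sheet(synthetic_config(seed = 21))
  res <- welfare_index(sheet)
  expect_equal(res$asrwi, brute_force_asrwi(sheet), tolerance = 1e-12)
  # and per species
  for (sp in c("sheep", "goat")) {
    expect_equal(welfare_index(sheet, species = sp)$asrwi,
                 brute_force_asrwi(sheet[sheet$species == sp, ]),
                 tolerance = 1e-12)
  }
})

test_that("raising any single encoded score never lowers the index", {
  sheet <- generate_sheet(synthetic_config(
    n_sheep = 3, n_goats = 3, n_raters = 3, seed = 13))
  base <- welfare_index(sheet)$asrwi
  withr::with_seed(4, idx <- sample(which(sheet$score < 2), 25))
  for (i in idx) {
    bumped <- sheet
    bumped$score[i] <- bumped$score[i] + 1L
    expect_gte(welfare_index(bumped)$asrwi, base - 1e-12)
  }
})

test_that("consensus is the rounded median, half-scores toward worse welfare", {
  expect_equal(asrwi:::consensus_score(c(2L, 1L)), 1L)       # 1.5 -> 1
  expect_equal(asrwi:::consensus_score(c(0L, 1L)), 0L)       # 0.5 -> 0
  expect_equal(asrwi:::consensus_score(c(0L, 2L)), 1L)       # exact median
  expect_equal(asrwi:::consensus_score(c(2L, 2L, 0L)), 2L)   # odd panel
  expect_equal(asrwi:::consensus_score(rep(1L, 8)), 1L)
})

test_that("per-animal mode scores each fully assessed animal", {
  sheet <- generate_sheet(synthetic_config(
    n_sheep = 2, n_goats = 2, n_raters = 3, seed = 31))
  res <- welfare_index(sheet, scope = "animal")
  expect_equal(nrow(res), 4)
  expect_true(all(res$asrwi >= 0 & res$asrwi <= 100))
  expect_equal(res$asrwi,
               0.20 * res$behaviour_mental + 0.30 * res$environment +
                 0.20 * res$nutrition + 0.30 * res$health,
               tolerance = 1e-12)
})
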