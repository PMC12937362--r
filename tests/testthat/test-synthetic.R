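test_that("default configuration reproduces the study design", {
  cfg <- synthetic_config()
  expect_equal(cfg$n_sheep, 46L)
  expect_equal(cfg$n_goats, 54L)
  expect_equal(cfg$n_raters, 8L)
  expect_equal(length(cfg$indicators), 24)
  sheet <- generate_sheet(cfg)
  expect_equal(nrow(sheet), 19200)
  expect_equal(length(unique(sheet$animal_id)), 100)
  # generated sheets are valid against the registry
  expect_equal(nrow(validation_report(validate_records(sheet))), 0)
})

test_that("generation is deterministic in the seed, and seeds differ", {
  cfg <- synthetic_config(seed = 42, indicators = c("demeanour", "panting"))
  s1 <- generate_sheet(cfg)
  s2 <- generate_sheet(cfg)
  expect_identical(s1, s2)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_sheets(s1, f1); write_sheets(s2, f2)
  expect_identical(readLines(f1), readLines(f2))
  s3 <- generate_sheet(synthetic_config(seed = 43,
                                        indicators = c("demeanour", "panting")))
  expect_false(identical(s1$score, s3$score))
})

test_that("config validation rejects impossible settings", {
  expect_error(synthetic_config(indicators = "nope"),
               class = "asrwi_config_error")
  expect_error(synthetic_config(error_rate = 1.2),
               class = "asrwi_config_error")
  expect_error(
    synthetic_config(indicators = "demeanour",
                     true_score_distribution = c(0.5, 0.6)),
    class = "asrwi_config_error")
  expect_error(synthetic_config(n_sheep = 0, n_goats = 0),
               class = "asrwi_config_error")
  expect_error(synthetic_config(n_raters = 1),
               class = "asrwi_config_error")
})

test_that("error-free raters agree perfectly; saturating error scrambles", {
  cfg0 <- synthetic_config(indicators = "demeanour", error_rate = 0, seed = 2)
  sheet <- generate_sheet(cfg0)
  m <- build_rating_matrix(sheet, "demeanour")
  expect_equal(fleiss_kappa(m)$kappa, 1)
  # raters reproduce the latent truth exactly
  truth <- attr(sheet, "truth")
  merged <- merge(sheet, truth, by = c("animal_id", "indicator_id"))
  expect_true(all(merged$score == merged$true_score))

  # at eps = (k-1)/k ratings are independent of truth: kappa near 0
  ks <- vapply(1:20, function(s) {
    cfg <- synthetic_config(indicators = "demeanour", error_rate = 2 / 3,
                            seed = s)
    fleiss_kappa(build_rating_matrix(generate_sheet(cfg), "demeanour"))$kappa
  }, numeric(1))
  expect_lt(abs(mean(ks)), 0.02)
})

test_that("closed-form agreement matches its derivation anchors", {
  expect_equal(expected_agreement(error_rate = 0, k = 3)$p_bar, 1)
  # k = 2, eps = 1: the single wrong category is shared, so agreement is 1
  expect_equal(expected_agreement(error_rate = 1, k = 2)$p_bar, 1)
  # truth-independent regime: expected kappa 0
  ea <- expected_agreement(error_rate = 2 / 3, k = 3,
                           probs = c(0.1, 0.25, 0.65))
  expect_equal(ea$kappa, 0, tolerance = 1e-12)
  expect_equal(ea$p_bar, ea$pe_bar, tolerance = 1e-12)
})

test_that("empirical pairwise agreement matches the closed form (3 MC SEs)", {
  eps <- 0.3
  probs <- c(0.1, 0.25, 0.65)
  ana <- expected_agreement(error_rate = eps, k = 3, probs = probs)$p_bar
  # pool per-subject agreements: 10,000 subjects across seeds
  p_is <- unlist(lapply(1:10, function(s) {
    cfg <- synthetic_config(n_sheep = 0, n_goats = 1000, n_raters = 8,
                            indicators = "demeanour", error_rate = eps,
                            true_score_distribution = probs, seed = 100 + s)
    m <- build_rating_matrix(generate_sheet(cfg), "demeanour")
    fleiss_kappa(m)$per_subject_agreement
  }))
  se <- stats::sd(p_is) / sqrt(length(p_is))
  expect_lt(abs(mean(p_is) - ana), 3 * se)
})

test_that("calibrated error rates invert the expected-kappa map", {
  for (target in c(0.35, 0.55, 0.8, 0.95)) {
    eps <- calibrate_error_rate(target, k = 3)
    expect_equal(expected_agreement(error_rate = eps, k = 3,
                                    probs = c(0.10, 0.25, 0.65))$kappa,
                 target, tolerance = 1e-6)
  }
  expect_equal(calibrate_error_rate(1, k = 3), 0)
})

test_that("estimated kappa converges to the analytic value as panels grow", {
  eps <- 0.2
  ana <- expected_agreement(error_rate = eps, k = 3,
                            probs = c(0.10, 0.25, 0.65))$kappa
  # 4-sigma envelopes from the estimator's sampling spread at each size
  envelope <- c(`50` = 0.23, `500` = 0.08, `5000` = 0.02)
  for (N in c(50, 500, 5000)) {
    for (s in 1:3) {
      cfg <- synthetic_config(n_sheep = 0, n_goats = N, n_raters = 8,
                              indicators = "demeanour", error_rate = eps,
                              seed = 200 + s)
      k_hat <- fleiss_kappa(
        build_rating_matrix(generate_sheet(cfg), "demeanour"))$kappa
      expect_lt(abs(k_hat - ana), envelope[[as.character(N)]])
    }
  }
})

test_that("empirical kappa decreases in the error rate (paired seeds)", {
  worse <- 0L
  total <- 40L
  for (s in seq_len(total)) {
    ks <- vapply(c(0.05, 0.3), function(eps) {
      cfg <- synthetic_config(n_sheep = 46, n_goats = 54, n_raters = 8,
                              indicators = "demeanour", error_rate = eps,
                              seed = 300 + s)
      fleiss_kappa(build_rating_matrix(generate_sheet(cfg), "demeanour"))$kappa
    }, numeric(1))
    if (ks[1] <= ks[2]) worse <- worse + 1L
  }
  expect_lte(worse, 1L)  # monotone in all but at most one paired replicate
})
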