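test_that("offer schedules follow the strategy and horizon", {
  expect_equal(schedule_offers(strategy("biennial_fit"), 10), c(0L, 2L, 4L, 6L, 8L))
  expect_equal(schedule_offers(strategy("gateopener", 8), 10), 0L)
  expect_equal(schedule_offers(strategy("colonoscopy_q10y"), 10), 0L)
  expect_equal(schedule_offers(strategy("no_screening"), 10), integer(0))
  expect_equal(schedule_offers(strategy("biennial_fit"), 0), integer(0))
})

test_that("strategy construction validates cut-offs", {
  expect_error(strategy("gateopener"), class = "crcscreen_config_error")
  expect_error(strategy("biennial_fit", cutoff = 10),
               class = "crcscreen_config_error")
  expect_error(strategy("colonoscopy_q10y", cutoff = 17),
               class = "crcscreen_config_error")
  expect_equal(strategy("biennial_fit")$cutoff, 17)
})

test_that("per-round participation declines with the retention rule", {
  adh <- adherence_params()  # 0.50 first offer, 40% cumulative drop-out
  rates <- round_participation_rates(strategy("biennial_fit"), adh, 10)
  expect_length(rates, 5)
  expect_equal(rates[1], 0.5)
  # final-round participation equals first-offer uptake times (1 - drop-out)
  expect_equal(rates[5], 0.5 * 0.6)
  # constant retention ratio between consecutive rounds
  expect_equal(diff(log(rates)), rep(log(0.6) / 4, 4), tolerance = 1e-12)
  expect_true(all(diff(rates) < 0))

  one <- round_participation_rates(strategy("gateopener", 3), adh, 10)
  expect_equal(one, 0.5)
  expect_equal(round_participation_rates(strategy("colonoscopy_q10y"), adh, 10),
               0.15)
})

test_that("participation draws honour enrolment and absorbing drop-out", {
  st <- strategy("biennial_fit")
  full <- adherence_params(p_fit_first = 1, dropout = 0)
  h <- list(enrolled = FALSE, dropped = FALSE)
  withr::with_seed(1, {
    for (k in 1:5) {
      res <- participation(k, st, full, h, n_rounds = 5)
      expect_true(res$participates)
      h <- res$history
    }
  })
  never <- adherence_params(p_colonoscopy = 0)
  withr::with_seed(1, {
    res <- participation(1, strategy("colonoscopy_q10y"), never)
    expect_false(res$participates)
    # a first-offer refuser never enters later rounds
    res2 <- participation(2, st, adherence_params(p_fit_first = 0),
                          list(enrolled = FALSE, dropped = TRUE))
    expect_false(res2$participates)
  })
})

test_that("FIT application follows the state-conditional profile", {
  all_pos <- per_state_profile(1, 1, 1, 1)
  expect_true(apply_fit("no_neoplasm", all_pos))
  expect_error(apply_fit("clinical_crc", all_pos),
               class = "crcscreen_contract_error")

  profile8 <- decompose_to_per_state(builtin_characteristics(8),
                                     blitz_group_counts())
  p <- profile8$p_positive[["advanced_adenoma"]]
  withr::with_seed(42, {
    hits <- sum(vapply(1:100000, function(i) apply_fit("advanced_adenoma", profile8),
                       logical(1)))
  })
  se <- sqrt(p * (1 - p) / 100000)
  expect_lt(abs(hits / 100000 - p), 4 * se)
})

test_that("colonoscopy removes adenomas and diagnoses preclinical cancer", {
  no_miss <- colonoscopy_params(0, 0, 0)
  expect_equal(apply_colonoscopy("advanced_adenoma", no_miss)$state, "no_neoplasm")
  expect_equal(apply_colonoscopy("nonadvanced_adenoma", no_miss)$state, "no_neoplasm")
  res <- apply_colonoscopy("no_neoplasm", no_miss)
  expect_equal(res$state, "no_neoplasm")
  expect_false(res$detected)
  res <- apply_colonoscopy("preclinical_crc", no_miss)
  expect_equal(res$state, "clinical_crc")
  expect_true(res$detected)
  # certain miss leaves the state unchanged
  near_miss <- colonoscopy_params(0.99, 0.99, 0.99)
  withr::with_seed(2, {
    expect_equal(apply_colonoscopy("advanced_adenoma", near_miss)$state,
                 "advanced_adenoma")
  })
  expect_error(colonoscopy_params(0.1, 0.05, 0.2),
               class = "crcscreen_validation_error")  # CRC missed more than adenomas
})

test_that("off-schedule years and no-screening leave the trajectory unchanged", {
  params <- shared_params()
  tr <- initialize_cohort(params, 60, "male", 1000, mode = "microsim", seed = 5)
  tr$meta$horizon <- 10L
  before <- tr$internal$state
  tr2 <- execute_strategy_year(tr, 1, strategy("biennial_fit"),
                               profile = per_state_profile(1, 1, 1, 1))
  expect_identical(tr2$internal$state, before)
  tr3 <- execute_strategy_year(tr, 0, strategy("no_screening"))
  expect_identical(tr3$internal$state, before)
  expect_error(execute_strategy_year(tr, 0, strategy("gateopener", 8)),
               class = "crcscreen_config_error")  # missing profile
})

test_that("gateopener with an all-positive profile reproduces full-adherence colonoscopy", {
  params <- shared_params()
  sc <- list(age = 60, sex = "female", n = 1000, horizon = 10,
             mode = "expectation")
  go <- run_arm(params, sc, strategy("gateopener", 3),
                adherence = adherence_params(p_fit_first = 1,
                                             p_diag_colonoscopy = 1),
                profile = per_state_profile(1, 1, 1, 1))
  colo <- run_arm(params, sc, strategy("colonoscopy_q10y"),
                  adherence = adherence_params(p_colonoscopy = 1))
  keep <- setdiff(names(go$occupancy), "fits")
  expect_equal(go$occupancy[, keep], colo$occupancy[, keep], tolerance = 1e-12)
  expect_equal(utils::tail(go$occupancy$fits, 1), 1000)
})

test_that("an all-negative profile reduces any FIT strategy to no screening", {
  params <- shared_params()
  sc <- list(age = 50, sex = "male", n = 1000, horizon = 10,
             mode = "expectation")
  none <- run_arm(params, sc, strategy("no_screening"))
  for (st in list(strategy("gateopener", 8), strategy("biennial_fit"))) {
    null_fit <- run_arm(params, sc, st,
                        profile = per_state_profile(0, 0, 0, 0))
    keep <- setdiff(names(none$occupancy), "fits")
    expect_equal(null_fit$occupancy[, keep], none$occupancy[, keep],
                 tolerance = 1e-12)
    expect_gt(utils::tail(null_fit$occupancy$fits, 1), 0)
  }
})

test_that("lowering the gateopener cut-off never decreases prevented cases", {
  params <- shared_params()
  sc <- list(age = 60, sex = "male", n = 50000, horizon = 10,
             mode = "expectation")
  ref <- run_arm(params, sc, strategy("no_screening"))
  prevented <- vapply(c(17, 10, 8, 6, 4, 3), function(ct) {
    tr <- run_arm(params, sc, strategy("gateopener", ct))
    prevented_events(tr, ref)$prevented_cases
  }, numeric(1))
  expect_true(all(diff(prevented) > 0))
})

test_that("resource counters equal the number of test applications", {
  # deterministic microsim: full uptake, all-positive FIT, full compliance,
  # no mortality, so every participant takes one FIT and one colonoscopy
  p <- toy_params(prev = c(0.2, 0.1, 0.05))
  sc <- list(age = 60, sex = "male", n = 2000, horizon = 10,
             mode = "microsim", seed = 8)
  tr <- run_arm(p, sc, strategy("gateopener", 3),
                adherence = adherence_params(p_fit_first = 1,
                                             p_diag_colonoscopy = 1),
                profile = per_state_profile(1, 1, 1, 1),
                colo_params = colonoscopy_params(0, 0, 0))
  expect_equal(utils::tail(tr$occupancy$fits, 1), 2000)
  expect_equal(utils::tail(tr$occupancy$colonoscopies, 1), 2000)
  # and the screening colonoscopy arm with full adherence examines everyone once
  tr2 <- run_arm(p, sc, strategy("colonoscopy_q10y"),
                 adherence = adherence_params(p_colonoscopy = 1),
                 colo_params = colonoscopy_params(0, 0, 0))
  expect_equal(utils::tail(tr2$occupancy$colonoscopies, 1), 2000)
  expect_equal(utils::tail(tr2$occupancy$fits, 1), 0)
  # no-screening arms use no resources
  tr3 <- run_arm(p, sc, strategy("no_screening"))
  expect_equal(utils::tail(tr3$occupancy$colonoscopies, 1), 0)
})
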