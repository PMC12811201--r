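test_that("parameter validation rejects out-of-range inputs", {
  expect_s3_class(toy_params(t = c(0.1, 0.1, 0.1, 0.2), om = 0.01), "nh_params")
  expect_error(toy_params(t = c(0.9, 0, 0, 0), om = 0.2),
               class = "crcscreen_validation_error")  # outgoing sum > 1
  expect_error(toy_params(prev = c(0.6, 0.3, 0.2)),
               class = "crcscreen_validation_error")  # lesions sum > 1
  p <- toy_params(t = c(0.1, 0.1, 0.1, 0.2))
  p$transitions[1, 1, 1, "lower"] <- 0.5  # bound above point
  expect_error(validate_nh_params(p), class = "crcscreen_validation_error")
})

test_that("cohort initialization splits baseline occupancy correctly", {
  # all mass in no-neoplasm
  p <- toy_params(prev = c(0, 0, 0))
  tr <- initialize_cohort(p, 60, "male", 100000, mode = "expectation")
  expect_equal(tr$occupancy$no_neoplasm, 100000)
  expect_equal(tr$occupancy$clinical_crc_screen + tr$occupancy$clinical_crc_symptom, 0)

  # deterministic proportional split
  p2 <- toy_params(prev = c(0.2, 0.08, 0.02))
  tr2 <- initialize_cohort(p2, 60, "female", 100000, mode = "expectation")
  expect_equal(tr2$occupancy$no_neoplasm, 70000)
  expect_equal(tr2$occupancy$nonadvanced_adenoma, 20000)
  expect_equal(tr2$occupancy$advanced_adenoma, 8000)
  expect_equal(tr2$occupancy$preclinical_crc, 2000)

  # microsimulation draw within 4 binomial SD of expectation
  tr3 <- initialize_cohort(p2, 60, "female", 100000, mode = "microsim", seed = 3)
  for (col in c("nonadvanced_adenoma", "advanced_adenoma", "preclinical_crc")) {
    expv <- tr2$occupancy[[col]]
    sd <- sqrt(expv * (1 - expv / 100000))
    expect_lt(abs(tr3$occupancy[[col]] - expv), 4 * sd)
  }
  expect_error(initialize_cohort(p2, 60, "female", 100, mode = "microsim"),
               class = "crcscreen_config_error")  # seed mandatory
})

test_that("a cycle with zero rates is the identity", {
  p <- toy_params(prev = c(0.2, 0.1, 0.05))
  tr <- initialize_cohort(p, 60, "male", 1000, mode = "expectation")
  tr <- advance_one_year(tr, p)
  expect_equal(unlist(tr$occupancy[2, 2:9]), unlist(tr$occupancy[1, 2:9]),
               ignore_attr = TRUE)
})

test_that("certain background mortality empties all alive states in one cycle", {
  p <- toy_params(om = 1, prev = c(0.2, 0.1, 0.05))
  tr <- initialize_cohort(p, 60, "male", 1000, mode = "expectation")
  tr <- advance_one_year(tr, p)
  expect_equal(tr$occupancy$dead_other[2], 1000)
})

test_that("expectation-mode occupancy matches the matrix-power oracle", {
  t <- c(0.1, 0.1, 0.1, 0.1)
  p <- toy_params(t = t, prev = c(0.2, 0.1, 0.05))
  tr <- initialize_cohort(p, 60, "male", 10000, mode = "expectation")
  for (k in 1:3) tr <- advance_one_year(tr, p)
  v <- chain_matrix_power(t, c(0.65, 0.2, 0.1, 0.05, 0) * 10000, 3)
  got <- unlist(tr$occupancy[4, c("no_neoplasm", "nonadvanced_adenoma",
                                  "advanced_adenoma", "preclinical_crc")])
  expect_equal(unname(got), v[1:4], tolerance = 1e-12)
  clin <- tr$occupancy$clinical_crc_screen[4] + tr$occupancy$clinical_crc_symptom[4]
  expect_equal(clin, v[5], tolerance = 1e-12)
  # natural-course detections are symptom-detected
  expect_equal(tr$occupancy$clinical_crc_screen[4], 0)
})

test_that("case-fatality lookup respects mode, hazard transform and extrapolation", {
  cf <- c(0.12, 0.08, 0.05)
  same <- toy_params(cf_sym = cf, cf_scr = cf)
  expect_equal(crc_death_probability(1, "screen_detected", same),
               crc_death_probability(1, "symptom_detected", same))

  # screen-detected row generated through a hazard ratio of 0.5, applied by hand
  hr <- 0.5
  scr <- 1 - (1 - cf)^hr
  trans <- toy_params(cf_sym = cf, cf_scr = scr)
  for (y in 0:2) {
    expect_equal(crc_death_probability(y, "screen_detected", trans),
                 1 - (1 - crc_death_probability(y, "symptom_detected", trans))^hr)
    expect_lte(crc_death_probability(y, "screen_detected", trans),
               crc_death_probability(y, "symptom_detected", trans))
  }

  # beyond the table: flat extrapolation with a notice
  expect_message(v <- crc_death_probability(10, "symptom_detected", trans),
                 "last row")
  expect_equal(v, cf[3])
})

test_that("an inert cohort produces no cases and no deaths", {
  p <- toy_params()
  sc <- list(age = 50, sex = "female", n = 5000, horizon = 10,
             mode = "expectation")
  tr <- run_arm(p, sc, strategy("no_screening"))
  last <- tr$occupancy[nrow(tr$occupancy), ]
  expect_equal(last$cum_cases, 0)
  expect_equal(last$cum_deaths, 0)
  expect_equal(last$colonoscopies, 0)
  expect_equal(last$fits, 0)
})

test_that("microsimulation is bit-reproducible under a fixed seed", {
  params <- shared_params()
  sc <- list(age = 60, sex = "male", n = 5000, horizon = 10,
             mode = "microsim", seed = 99)
  a <- run_arm(params, sc, strategy("biennial_fit"))
  b <- run_arm(params, sc, strategy("biennial_fit"))
  expect_identical(a$occupancy, b$occupancy)
})

test_that("occupancy is conserved and death states are absorbing", {
  params <- shared_params()
  for (mode in c("expectation", "microsim")) {
    sc <- list(age = 60, sex = "female", n = 20000, horizon = 10,
               mode = mode, seed = 21)
    tr <- run_arm(params, sc, strategy("gateopener", cutoff = 4))
    occ <- tr$occupancy
    sums <- rowSums(occ[, c("no_neoplasm", "nonadvanced_adenoma",
                            "advanced_adenoma", "preclinical_crc",
                            "clinical_crc_screen", "clinical_crc_symptom",
                            "dead_crc", "dead_other")])
    expect_equal(sums, rep(20000, nrow(occ)), tolerance = 1e-9)
    expect_true(all(diff(occ$dead_crc) >= 0))
    expect_true(all(diff(occ$dead_other) >= 0))
    expect_true(all(diff(occ$cum_cases) >= 0))
    expect_true(all(diff(occ$colonoscopies) >= 0))
  }
})

test_that("raising any progression rate never lowers 10-year incidence", {
  base_t <- c(0.02, 0.03, 0.05, 0.2)
  sc <- list(age = 55, sex = "male", n = 10000, horizon = 10,
             mode = "expectation")
  incidence <- function(t) {
    p <- toy_params(t = t, prev = c(0.15, 0.05, 0.01), om = 0.01)
    tr <- run_arm(p, sc, strategy("no_screening"))
    utils::tail(tr$occupancy$cum_cases, 1)
  }
  base <- incidence(base_t)
  for (k in 1:4) {
    up <- base_t
    up[k] <- up[k] * 1.5
    expect_gte(incidence(up), base)
  }
})

test_that("screen detection with a favourable hazard ratio lowers deaths", {
  # same diagnoses, fatality mode benefit only: removing the screen-detection
  # survival advantage must not decrease cumulative CRC deaths
  cf <- c(0.12, 0.08, 0.05, 0.04, 0.03)
  mk <- function(cf_scr) {
    toy_params(t = c(0.02, 0.04, 0.06, 0.25), om = 0.01,
               cf_sym = cf, cf_scr = cf_scr, prev = c(0.15, 0.06, 0.02))
  }
  sc <- list(age = 60, sex = "male", n = 50000, horizon = 10,
             mode = "expectation")
  st <- strategy("colonoscopy_q10y")
  adh <- adherence_params(p_colonoscopy = 1)
  with_benefit <- run_arm(mk(1 - (1 - cf)^0.5), sc, st, adherence = adh)
  without <- run_arm(mk(cf), sc, st, adherence = adh)
  expect_lt(utils::tail(with_benefit$occupancy$cum_deaths, 1),
            utils::tail(without$occupancy$cum_deaths, 1))
  # identical case counts: the detection pattern is unchanged
  expect_equal(utils::tail(with_benefit$occupancy$cum_cases, 1),
               utils::tail(without$occupancy$cum_cases, 1), tolerance = 1e-9)
})

test_that("parameter tampering is caught before stepping", {
  p <- toy_params(t = c(0.3, 0, 0, 0), om = 0.01)
  tr <- initialize_cohort(p, 60, "male", 100, mode = "expectation")
  p$other_cause_mortality[, ] <- 0.9  # now 0.3 + 0.9 > 1
  expect_error(advance_one_year(tr, p), class = "crcscreen_validation_error")
})

test_that("natural-history parameters round-trip through CSV", {
  params <- shared_params()
  path <- withr::local_tempfile(fileext = ".csv")
  write_nh_params(params, path)
  back <- read_nh_params(path)
  expect_equal(back$prevalence, params$prevalence, tolerance = 1e-12)
  expect_equal(back$transitions, params$transitions, tolerance = 1e-12)
  expect_equal(back$other_cause_mortality, params$other_cause_mortality,
               tolerance = 1e-12)
  expect_equal(back$case_fatality, params$case_fatality, tolerance = 1e-12)
})
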