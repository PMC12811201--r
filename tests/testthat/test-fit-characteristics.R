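test_that("packaged characteristics return the reference rows verbatim", {
  c17 <- builtin_characteristics(17)
  expect_equal(c17$positivity, 0.10)
  expect_equal(c17$sens_any_neoplasm, 0.196)
  expect_equal(c17$sens_advanced_neoplasm, 0.394)
  expect_equal(c17$sens_preclinical_crc, 0.907)
  expect_equal(c17$spec_no_advanced, 0.933)

  c3 <- builtin_characteristics(3)
  expect_equal(c3$positivity, 0.51)
  expect_equal(c3$sens_advanced_neoplasm, 0.727)
  expect_equal(c3$sens_preclinical_crc, 0.981)
  expect_equal(c3$spec_no_advanced, 0.511)

  expect_error(builtin_characteristics(5), class = "crcscreen_unsupported_cutoff")
})

test_that("reference table rows are monotone in the cut-off", {
  tab <- fit_reference_table()  # sorted by decreasing cut-off
  expect_true(all(diff(tab$positivity) >= 0))
  expect_true(all(diff(tab$sens_any_neoplasm) >= 0))
  expect_true(all(diff(tab$sens_advanced_neoplasm) >= 0))
  expect_true(all(diff(tab$sens_preclinical_crc) >= 0))
  expect_true(all(diff(tab$spec_no_advanced) <= 0))
  # within-row sensitivity ordering
  expect_true(all(tab$sens_preclinical_crc >= tab$sens_advanced_neoplasm))
  expect_true(all(tab$sens_advanced_neoplasm >= tab$sens_any_neoplasm))
})

test_that("group counts validate nesting and derive exclusive counts", {
  gc <- blitz_group_counts()
  expect_equal(gc$n_no_advanced + gc$n_advanced_neoplasm, 7398)
  expect_equal(gc$n_no_neoplasm, 7398 - 2115)
  expect_equal(gc$n_no_neoplasm + gc$n_nonadvanced_adenoma +
                 gc$n_advanced_adenoma + gc$n_preclinical_crc, gc$n_total)
  expect_error(group_counts(100, 50, 60, 5), class = "crcscreen_validation_error")
  expect_error(group_counts(100, 50, 20, 5, n_no_advanced = 70),
               class = "crcscreen_validation_error")
})

test_that("decomposition recovers the hand-solved per-state positivities", {
  # expected values solved by hand from the cut-off 17 aggregates and the
  # reference group counts (three linear equations, inside-out)
  p <- decompose_to_per_state(builtin_characteristics(17), blitz_group_counts())
  expect_lt(abs(p$p_positive[["nonadvanced_adenoma"]] - 0.0921), 1e-3)
  expect_lt(abs(p$p_positive[["advanced_adenoma"]] - 0.3529), 1e-3)
  expect_lt(abs(p$p_positive[["no_neoplasm"]] - 0.0604), 1e-3)
  expect_equal(unname(p$p_positive[["preclinical_crc"]]), 0.907)
})

test_that("decomposition handles homogeneous and degenerate inputs", {
  gc <- blitz_group_counts()
  s <- 0.3
  hom <- fit_characteristics(10, s, s, s, s, 1 - s)
  p <- decompose_to_per_state(hom, gc)
  expect_equal(unname(p$p_positive), rep(s, 4))

  null <- fit_characteristics(10, 0, 0, 0, 0, 1)
  p0 <- decompose_to_per_state(null, gc)
  expect_equal(unname(p0$p_positive), rep(0, 4))

  degen <- group_counts(100, 10, 10, 10)  # no advanced adenomas
  expect_error(decompose_to_per_state(hom, degen),
               class = "crcscreen_degenerate_counts")

  # inconsistent rounded aggregates force clamping with a warning
  bad <- fit_characteristics(10, 0.1, 0.01, 0.02, 0.99, 0.99)
  expect_warning(decompose_to_per_state(bad, gc), "clamped")
})

test_that("decompose then re-aggregate round-trips within 0.5 pp at all cut-offs", {
  gc <- blitz_group_counts()
  for (ct in fit_reference_table()$cutoff) {
    agg <- builtin_characteristics(ct)
    back <- aggregate_per_state(decompose_to_per_state(agg, gc), gc, ct)
    for (f in c("positivity", "sens_any_neoplasm", "sens_advanced_neoplasm",
                "sens_preclinical_crc", "spec_no_advanced")) {
      expect_lt(abs(back[[f]] - agg[[f]]), 0.005)
    }
  }
})

test_that("record counting matches the exhaustive tally oracle", {
  rec <- fixture_records()
  for (ct in c(17, 8, 4, 150)) {
    got <- characteristics_from_records(rec, ct)
    want <- tally_oracle(rec, ct)
    for (f in names(want)) expect_equal(got[[f]], want[[f]], info = paste("cutoff", ct))
  }
  # frozen hand tally at cut-off 17: positives are records with hb 20, 30, 100
  got <- characteristics_from_records(rec, 17)
  expect_equal(got$positivity, 0.3)
  expect_equal(got$sens_any_neoplasm, 2 / 6)
  expect_equal(got$sens_advanced_neoplasm, 2 / 4)
  expect_equal(got$sens_preclinical_crc, 1 / 2)
  expect_equal(got$spec_no_advanced, 5 / 6)

  # oracle equivalence on random record sets of up to 50 records
  withr::with_seed(11, {
    for (rep in 1:5) {
      n <- sample(5:50, 1)
      rnd <- data.frame(
        hb_value = ifelse(runif(n) < 0.3, 0, rlnorm(n, 1.5, 1.2)),
        finding = sample(c("no_neoplasm", "nonadvanced_adenoma",
                           "advanced_adenoma", "preclinical_crc"),
                         n, replace = TRUE),
        stringsAsFactors = FALSE)
      for (ct in c(12, 5)) {
        got <- suppressWarnings(characteristics_from_records(rnd, ct))
        want <- tally_oracle(rnd, ct)
        for (f in names(want)) expect_equal(got[[f]], want[[f]])
      }
    }
  })
})

test_that("cut-off zero makes every record positive", {
  got <- characteristics_from_records(fixture_records(), 0)
  expect_equal(got$positivity, 1)
  expect_equal(got$spec_no_advanced, 0)
  expect_equal(got$sens_preclinical_crc, 1)
})

test_that("empty diseased subgroup reports an undefined sensitivity", {
  rec <- data.frame(hb_value = c(0, 5, 30),
                    finding = rep("no_neoplasm", 3),
                    stringsAsFactors = FALSE)
  got <- characteristics_from_records(rec, 8)
  expect_true(is.na(got$sens_any_neoplasm))
  expect_true(is.na(got$sens_preclinical_crc))
  expect_false(is.na(got$positivity))
})

test_that("sensitivity-positivity curve behaves across cut-off grids", {
  rec <- fixture_records()
  one <- sensitivity_positivity_curve(rec, 8)
  direct <- characteristics_from_records(rec, 8)
  expect_equal(nrow(one), 1)
  expect_equal(one$positivity, direct$positivity)
  expect_equal(one$sens_advanced_neoplasm, direct$sens_advanced_neoplasm)

  expect_message(out <- sensitivity_positivity_curve(rec, c(3, 17)), "sorting")
  expect_equal(out$cutoff, c(17, 3))

  dup <- sensitivity_positivity_curve(rec, c(17, 17))
  expect_equal(dup[1, ], dup[2, ], ignore_attr = TRUE)
})

test_that("lowering the cut-off never decreases positivity or sensitivities", {
  m <- default_hb_model()
  rec <- generate_fit_cohort(m, 3000, seed = 5)
  curve <- sensitivity_positivity_curve(rec, c(17, 10, 8, 6, 4, 3))
  expect_true(all(diff(curve$positivity) >= 0))
  expect_true(all(diff(curve$sens_any_neoplasm) >= 0))
  expect_true(all(diff(curve$sens_advanced_neoplasm) >= 0))
  expect_true(all(diff(curve$sens_preclinical_crc) >= 0))
  expect_true(all(diff(curve$spec_no_advanced) <= 0))
})

test_that("FIT records round-trip through CSV", {
  rec <- fixture_records()
  path <- withr::local_tempfile(fileext = ".csv")
  write_fit_records(rec, path)
  back <- read_fit_records(path)
  expect_equal(back$hb_value, rec$hb_value)
  expect_equal(back$finding, rec$finding)
  expect_error(validate_fit_records(data.frame(hb_value = 1, finding = "cyst")),
               class = "crcscreen_validation_error")
})
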