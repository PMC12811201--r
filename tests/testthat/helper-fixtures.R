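# Shared fixtures and independent oracles, all built in code.

# Constant-rate natural-history parameter set for hand-checkable toys.
toy_params <- function(t = c(0, 0, 0, 0), om = 0,
                       cf_sym = rep(0, 5), cf_scr = cf_sym,
                       prev = c(0, 0, 0), ages = 50:80, ci_rel = 0) {
  na <- length(ages)
  mk4 <- function(vals, third_names, nm3) {
    arr <- array(NA_real_, dim = c(na, 2, length(third_names), 3),
                 dimnames = list(age = ages, sex = c("female", "male"),
                                 third_names, bound = c("point", "lower", "upper")))
    names(dimnames(arr))[3] <- nm3
    for (k in seq_along(third_names)) {
      arr[, , k, "point"] <- vals[k]
      arr[, , k, "lower"] <- vals[k] * (1 - ci_rel)
      arr[, , k, "upper"] <- min(1, vals[k] * (1 + ci_rel))
    }
    arr
  }
  prevalence <- mk4(prev, c("nonadvanced_adenoma", "advanced_adenoma",
                            "preclinical_crc"), "lesion")
  transitions <- mk4(t, c("no_to_nonadv", "nonadv_to_adv", "adv_to_preclin",
                          "preclin_to_clinical"), "transition")
  om_mat <- array(om, dim = c(na, 2),
                  dimnames = list(age = ages, sex = c("female", "male")))
  cf <- array(NA_real_, dim = c(length(cf_sym), 2, 3),
              dimnames = list(year_since_dx = seq_along(cf_sym) - 1,
                              mode = c("screen_detected", "symptom_detected"),
                              bound = c("point", "lower", "upper")))
  for (b in c("point", "lower", "upper")) {
    cf[, "symptom_detected", b] <- cf_sym
    cf[, "screen_detected", b] <- cf_scr
  }
  nh_params(ages, prevalence, transitions, om_mat, cf)
}

# Hand-built 10-record FIT fixture; tallies verified by tally_oracle().
fixture_records <- function() {
  data.frame(
    hb_value = c(0, 2, 20, 5, 0, 30, 8, 100, 15, 3),
    finding = c("no_neoplasm", "no_neoplasm", "no_neoplasm",
                "nonadvanced_adenoma", "nonadvanced_adenoma",
                "advanced_adenoma", "advanced_adenoma",
                "preclinical_crc", "preclinical_crc", "no_neoplasm"),
    sex = rep(c("female", "male"), 5),
    age = rep(55:59, 2),
    stringsAsFactors = FALSE
  )
}

# Exhaustive per-record tally: the brute-force oracle for
# characteristics_from_records, written independently of the implementation.
tally_oracle <- function(records, cutoff) {
  n <- nrow(records)
  n_pos <- 0
  g <- list(any = c(0, 0), adv = c(0, 0), crc = c(0, 0), noadv = c(0, 0))
  for (i in seq_len(n)) {
    pos <- records$hb_value[i] >= cutoff
    f <- records$finding[i]
    if (pos) n_pos <- n_pos + 1
    bump <- function(key) {
      g[[key]][1] <<- g[[key]][1] + 1
      if (pos) g[[key]][2] <<- g[[key]][2] + 1
    }
    if (f != "no_neoplasm") bump("any")
    if (f %in% c("advanced_adenoma", "preclinical_crc")) bump("adv") else bump("noadv")
    if (f == "preclinical_crc") bump("crc")
  }
  rate <- function(key) if (g[[key]][1] == 0) NA_real_ else g[[key]][2] / g[[key]][1]
  list(positivity = n_pos / n,
       sens_any_neoplasm = rate("any"),
       sens_advanced_neoplasm = rate("adv"),
       sens_preclinical_crc = rate("crc"),
       spec_no_advanced = 1 - rate("noadv"))
}

# 5-state transition-matrix oracle (no mortality): no neoplasm, non-advanced
# adenoma, advanced adenoma, preclinical CRC, clinical CRC.
chain_matrix_power <- function(t, v0, years) {
  Tm <- diag(5)
  for (s in 1:4) {
    Tm[s, s] <- 1 - t[s]
    Tm[s, s + 1] <- t[s]
  }
  v <- v0
  for (k in seq_len(years)) v <- as.vector(v %*% Tm)
  v
}

# Minimal stand-in trajectory for outcome arithmetic tests.
fake_trajectory <- function(cases, deaths, colos = 0, fits = 0,
                            strategy_obj = strategy("no_screening"),
                            age = 60, sex = "male", n = 1000, horizon = 10L,
                            params_hash = "toy") {
  occ <- data.frame(year = horizon, no_neoplasm = n, nonadvanced_adenoma = 0,
                    advanced_adenoma = 0, preclinical_crc = 0,
                    clinical_crc_screen = 0, clinical_crc_symptom = 0,
                    dead_crc = 0, dead_other = 0,
                    cum_cases = cases, cum_deaths = deaths,
                    colonoscopies = colos, fits = fits)
  structure(list(meta = list(strategy = strategy_obj, age = age, sex = sex,
                             n = n, mode = "expectation", seed = NULL,
                             horizon = horizon, params_hash = params_hash),
                 occupancy = occ),
            class = "cohort_trajectory")
}

# Default synthetic parameter set shared across tests (seeded, cached).
shared_params <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_natural_history_params(seed = 7)
    cache
  }
})
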