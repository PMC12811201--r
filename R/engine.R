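# Multistate engine. Two execution modes share one cycle structure:
#  (1) screening events of the year, (2) one-step disease progression,
#  (3) other-cause death on all alive states, (4) CRC death on clinical
#  cases by time since diagnosis and detection mode, (5) time-since-diagnosis
#  and age increment.
#
# Expectation mode propagates cohort mass deterministically, stratified into
# participation classes (enrolment and drop-out are decided per person, not
# per event, so they correlate screening exposure across rounds; splitting
# the cohort by participation pattern keeps the propagation exact).
# Microsimulation samples individuals with a seeded RNG.

occupancy_cols <- c("no_neoplasm", "nonadvanced_adenoma", "advanced_adenoma",
                    "preclinical_crc", "clinical_crc_screen",
                    "clinical_crc_symptom", "dead_crc", "dead_other")

#' Initialize a cohort trajectory at year 0
#'
#' Assigns the starting occupancy of a previously unscreened cohort from the
#' sex- and age-specific baseline prevalences: proportionally in expectation
#' mode, by a multinomial draw in microsimulation mode. Nobody has clinical
#' CRC or is dead at baseline, and all counters start at zero.
#'
#' @param params An [nh_params] object.
#' @param age Starting age (the packaged scenario grid uses 50, 60, 70).
#' @param sex `"female"` or `"male"`.
#' @param n Cohort size (>= 1).
#' @param mode `"expectation"` or `"microsim"`.
#' @param seed Integer seed; mandatory in microsimulation mode.
#' @return An object of class `cohort_trajectory` holding the year-0
#'   occupancy and the internal engine state.
#' @export
initialize_cohort <- function(params, age, sex, n,
                              mode = c("expectation", "microsim"),
                              seed = NULL) {
  mode <- match.arg(mode)
  sex <- match.arg(sex, sexes)
  stopifnot(n >= 1)
  validate_nh_params(params)
  prev <- lookup_prevalence(params, age, sex)
  if (abs(sum(prev) - 1) > 1e-9) {
    stop_crc("starting prevalences must sum to 1", "crcscreen_validation_error")
  }
  if (mode == "microsim" && is.null(seed)) {
    stop_crc("microsimulation mode requires a seed", "crcscreen_config_error")
  }
  internal <- if (mode == "expectation") {
    list(classes = list(list(weight = 1, offer_years = integer(0),
                             m = n * prev,
                             C = NULL, dead_crc = 0, dead_other = 0)))
  } else {
    withr::local_seed(seed)
    counts <- as.vector(stats::rmultinom(1, n, prev))
    st <- rep.int(1:4, counts)[sample.int(n)]
    list(state = st, det_mode = integer(n), ysd = integer(n),
         active = logical(n), rng = .Random.seed)
  }
  occ <- data.frame(year = 0L,
                    no_neoplasm = sum_state(internal, 1L, mode),
                    nonadvanced_adenoma = sum_state(internal, 2L, mode),
                    advanced_adenoma = sum_state(internal, 3L, mode),
                    preclinical_crc = sum_state(internal, 4L, mode),
                    clinical_crc_screen = 0, clinical_crc_symptom = 0,
                    dead_crc = 0, dead_other = 0,
                    cum_cases = 0, cum_deaths = 0,
                    colonoscopies = 0, fits = 0)
  structure(list(
    meta = list(strategy = strategy("no_screening"), age = age, sex = sex,
                n = n, mode = mode, seed = seed, horizon = NA_integer_,
                params_hash = rlang::hash(params)),
    occupancy = occ,
    internal = internal
  ), class = "cohort_trajectory")
}

sum_state <- function(internal, code, mode) {
  if (mode == "expectation") {
    sum(vapply(internal$classes, function(cl) cl$m[code], numeric(1)))
  } else {
    sum(internal$state == code)
  }
}

#' @export
print.cohort_trajectory <- function(x, ...) {
  m <- x$meta
  cat(sprintf("Cohort trajectory: %s, age %d, %s, n = %d (%s mode)\n",
              strategy_label(m$strategy), m$age, m$sex, m$n, m$mode))
  last <- x$occupancy[nrow(x$occupancy), ]
  cat(sprintf("  years simulated: %d\n", last$year))
  cat(sprintf("  cumulative CRC cases:  %.1f\n", last$cum_cases))
  cat(sprintf("  cumulative CRC deaths: %.1f\n", last$cum_deaths))
  cat(sprintf("  colonoscopies: %.1f, FITs: %.1f\n", last$colonoscopies,
              last$fits))
  invisible(x)
}

current_year <- function(traj) {
  traj$occupancy$year[nrow(traj$occupancy)]
}

# Split the expectation-mode cohort into participation classes for a
# strategy. Class masses are absolute (weight * baseline occupancy).
setup_participation <- function(traj, strategy, adherence, horizon) {
  stopifnot(traj$meta$mode == "expectation")
  offers <- schedule_offers(strategy, horizon)
  base <- traj$internal$classes[[1]]
  K <- horizon + 1L
  mk <- function(weight, offer_years) {
    list(weight = weight, offer_years = offer_years,
         m = base$m * weight, C = matrix(0, 2, K,
                                         dimnames = list(detection_modes, NULL)),
         dead_crc = 0, dead_other = 0)
  }
  classes <- if (!length(offers)) {
    list(mk(1, integer(0)))
  } else if (strategy$kind %in% c("colonoscopy_q10y", "gateopener")) {
    p <- if (strategy$kind == "colonoscopy_q10y") adherence$p_colonoscopy
         else adherence$p_fit_first
    list(mk(p, offers), mk(1 - p, integer(0)))
  } else {  # biennial_fit
    nr <- length(offers)
    r <- round_retention(adherence, nr)
    p1 <- adherence$p_fit_first
    cls <- list(mk(1 - p1, integer(0)))
    for (d in seq_len(nr)) {
      w <- if (d < nr) p1 * r^(d - 1) * (1 - r) else p1 * r^(nr - 1)
      cls[[d + 1]] <- mk(w, offers[seq_len(d)])
    }
    cls
  }
  classes <- Filter(function(cl) cl$weight > 0, classes)
  traj$internal$classes <- classes
  traj
}

#' Apply the screening events of one year to a trajectory
#'
#' On an offer year, participants of the scheduled round receive the
#' strategy's test: a screening colonoscopy directly, or a FIT whose
#' positives proceed to diagnostic colonoscopy with the diagnostic-compliance
#' probability. Colonoscopy acts on the true state (so a false-positive FIT
#' still removes incidentally present lesions), removing adenomas unless
#' missed and diagnosing preclinical cancer as screen-detected clinical CRC
#' unless missed. Off-schedule years and `no_screening` are no-ops. One FIT
#' kit is counted per participation; screening and diagnostic colonoscopies
#' are pooled in the colonoscopy counter.
#'
#' @param traj A [cohort_trajectory] (positioned at the start of `year`).
#' @param year Calendar year of the cycle (0-based).
#' @param strategy A [strategy].
#' @param adherence An [adherence_params].
#' @param profile A [per_state_profile]; required for FIT-bearing strategies.
#' @param colo_params A [colonoscopy_params].
#' @return The trajectory with updated internal state and resource/case
#'   deltas recorded for [advance_one_year()] to commit.
#' @export
execute_strategy_year <- function(traj, year, strategy,
                                  adherence = adherence_params(),
                                  profile = NULL,
                                  colo_params = colonoscopy_params()) {
  if (strategy$kind == "no_screening") return(traj)
  horizon <- traj$meta$horizon
  offers <- schedule_offers(strategy,
                            if (is.na(horizon)) 10L else horizon)
  if (!(year %in% offers)) return(traj)
  if (uses_fit(strategy) && is.null(profile)) {
    stop_crc("FIT-bearing strategy needs a per-state positivity profile",
             "crcscreen_config_error")
  }
  round_k <- match(year, offers)
  delta <- list(fits = 0, colos = 0, cases = 0)
  miss <- c(0, colo_params$miss_nonadvanced, colo_params$miss_advanced,
            colo_params$miss_preclinical_crc)

  if (traj$meta$mode == "expectation") {
    for (j in seq_along(traj$internal$classes)) {
      cl <- traj$internal$classes[[j]]
      if (!(year %in% cl$offer_years)) next
      m <- cl$m
      if (strategy$kind == "colonoscopy_q10y") {
        delta$colos <- delta$colos + sum(m)
        exam <- m
      } else {
        delta$fits <- delta$fits + sum(m)
        pos <- m * profile$p_positive
        exam <- pos * adherence$p_diag_colonoscopy
        delta$colos <- delta$colos + sum(exam)
      }
      removed <- exam[2:3] * (1 - miss[2:3])
      detected <- exam[4] * (1 - miss[4])
      m[1] <- m[1] + sum(removed)
      m[2:3] <- m[2:3] - removed
      m[4] <- m[4] - detected
      cl$C["screen_detected", 1] <- cl$C["screen_detected", 1] + detected
      delta$cases <- delta$cases + detected
      cl$m <- m
      traj$internal$classes[[j]] <- cl
    }
  } else {
    it <- traj$internal
    n <- length(it$state)
    nr <- length(offers)
    if (round_k == 1) {
      p <- if (strategy$kind == "colonoscopy_q10y") adherence$p_colonoscopy
           else adherence$p_fit_first
      it$active <- stats::runif(n) < p
    } else {
      r <- round_retention(adherence, nr)
      it$active <- it$active & (stats::runif(n) < r)
    }
    eligible <- it$active & it$state <= 4L
    if (strategy$kind == "colonoscopy_q10y") {
      delta$colos <- sum(eligible)
      exam <- eligible
    } else {
      delta$fits <- sum(eligible)
      p_pos <- c(profile$p_positive, 0, 0, 0)[it$state]
      pos <- eligible & (stats::runif(n) < p_pos)
      exam <- pos & (stats::runif(n) < adherence$p_diag_colonoscopy)
      delta$colos <- sum(exam)
    }
    found <- exam & (stats::runif(n) >= miss[pmin(it$state, 4L)])
    rem <- found & it$state %in% 2:3
    det <- found & it$state == 4L
    it$state[rem] <- 1L
    it$state[det] <- 5L
    it$det_mode[det] <- 1L  # screen_detected
    it$ysd[det] <- 0L
    delta$cases <- sum(det)
    traj$internal <- it
  }
  traj$internal$pending <- Map(`+`, traj$internal$pending %||%
                                 list(fits = 0, colos = 0, cases = 0), delta)
  traj
}

#' Advance a cohort trajectory by one annual cycle
#'
#' Executes one model year in the fixed within-cycle order: screening events
#' (if a strategy is supplied), one-step progression along the
#' adenoma-carcinoma chain (the natural preclinical-to-clinical transition is
#' symptom-detected), other-cause death on all alive states, CRC death on
#' clinical cases by time since diagnosis and detection mode, then the
#' time-since-diagnosis and age increments. Appends the new occupancy row.
#'
#' @param traj A [cohort_trajectory].
#' @param params An [nh_params] object.
#' @param strategy Optional [strategy] whose events run first in the cycle.
#' @param adherence,profile,colo_params Passed to [execute_strategy_year()].
#' @return The advanced trajectory.
#' @export
advance_one_year <- function(traj, params, strategy = NULL,
                             adherence = adherence_params(),
                             profile = NULL,
                             colo_params = colonoscopy_params()) {
  year <- current_year(traj)
  horizon <- traj$meta$horizon
  if (!is.na(horizon) && year >= horizon) {
    stop_crc("trajectory already at its horizon", "crcscreen_contract_error")
  }
  age <- traj$meta$age + year
  sex <- traj$meta$sex
  tr <- lookup_transitions(params, age, sex)
  om <- lookup_om(params, age, sex)
  if (any(tr + om > 1 + 1e-9)) {
    stop_crc("outgoing probabilities exceed 1 for the current age",
             "crcscreen_validation_error")
  }
  if (!is.null(strategy)) {
    traj <- execute_strategy_year(traj, year, strategy, adherence, profile,
                                  colo_params)
  }
  pending <- traj$internal$pending %||% list(fits = 0, colos = 0, cases = 0)
  traj$internal$pending <- NULL
  nysd <- dim(params$case_fatality)[1]

  new_cases <- pending$cases
  new_deaths <- 0

  if (traj$meta$mode == "expectation") {
    for (j in seq_along(traj$internal$classes)) {
      cl <- traj$internal$classes[[j]]
      if (is.null(cl$C)) {
        cl$C <- matrix(0, 2, max(1L, if (is.na(horizon)) 11L else horizon + 1L),
                       dimnames = list(detection_modes, NULL))
      }
      m <- cl$m
      f <- m * tr
      m <- m + c(-f[1], f[1] - f[2], f[2] - f[3], f[3] - f[4])
      cl$C["symptom_detected", 1] <- cl$C["symptom_detected", 1] + f[4]
      new_cases <- new_cases + f[4]
      # other-cause death on all alive states
      cl$dead_other <- cl$dead_other + om * (sum(m) + sum(cl$C))
      m <- m * (1 - om)
      cl$C <- cl$C * (1 - om)
      # CRC death by years since diagnosis and detection mode
      K <- ncol(cl$C)
      idx <- pmin(seq_len(K), nysd)
      d <- rbind(cl$C["screen_detected", ] *
                   params$case_fatality[idx, "screen_detected", "point"],
                 cl$C["symptom_detected", ] *
                   params$case_fatality[idx, "symptom_detected", "point"])
      cl$dead_crc <- cl$dead_crc + sum(d)
      new_deaths <- new_deaths + sum(d)
      cl$C <- cl$C - d
      # increment years since diagnosis (last column accumulates)
      if (K > 1) {
        shifted <- cbind(0, cl$C[, -K, drop = FALSE])
        shifted[, K] <- shifted[, K] + cl$C[, K]
        cl$C <- shifted
      }
      cl$m <- m
      traj$internal$classes[[j]] <- cl
    }
  } else {
    it <- traj$internal
    n <- length(it$state)
    old <- it$state
    u <- stats::runif(n)
    move <- old <= 4L & u < tr[pmin(old, 4L)]
    it$state[move] <- old[move] + 1L
    sym <- move & old == 4L
    it$det_mode[sym] <- 2L  # symptom_detected
    it$ysd[sym] <- 0L
    new_cases <- new_cases + sum(sym)
    alive <- it$state <= 5L
    die_o <- alive & stats::runif(n) < om
    it$state[die_o] <- 7L
    cc <- it$state == 5L
    if (any(cc)) {
      p_cf <- params$case_fatality[
        cbind(pmin(it$ysd[cc] + 1L, nysd), it$det_mode[cc], 1L)]
      die_c <- stats::runif(sum(cc)) < p_cf
      idx_cc <- which(cc)
      it$state[idx_cc[die_c]] <- 6L
      new_deaths <- new_deaths + sum(die_c)
      surv <- idx_cc[!die_c]
      it$ysd[surv] <- it$ysd[surv] + 1L
    }
    traj$internal <- it
  }

  prev_row <- traj$occupancy[nrow(traj$occupancy), ]
  mode <- traj$meta$mode
  row <- data.frame(
    year = year + 1L,
    no_neoplasm = sum_state(traj$internal, 1L, mode),
    nonadvanced_adenoma = sum_state(traj$internal, 2L, mode),
    advanced_adenoma = sum_state(traj$internal, 3L, mode),
    preclinical_crc = sum_state(traj$internal, 4L, mode),
    clinical_crc_screen = clinical_mass(traj$internal, "screen_detected", mode),
    clinical_crc_symptom = clinical_mass(traj$internal, "symptom_detected", mode),
    dead_crc = dead_mass(traj$internal, "dead_crc", mode),
    dead_other = dead_mass(traj$internal, "dead_other", mode),
    cum_cases = prev_row$cum_cases + new_cases,
    cum_deaths = prev_row$cum_deaths + new_deaths,
    colonoscopies = prev_row$colonoscopies + pending$colos,
    fits = prev_row$fits + pending$fits
  )
  traj$occupancy <- rbind(traj$occupancy, row)
  rownames(traj$occupancy) <- NULL
  traj
}

clinical_mass <- function(internal, mode_name, mode) {
  if (mode == "expectation") {
    sum(vapply(internal$classes, function(cl) {
      if (is.null(cl$C)) 0 else sum(cl$C[mode_name, ])
    }, numeric(1)))
  } else {
    code <- match(mode_name, detection_modes)
    sum(internal$state == 5L & internal$det_mode == code)
  }
}

dead_mass <- function(internal, which, mode) {
  if (mode == "expectation") {
    sum(vapply(internal$classes, function(cl) cl[[which]], numeric(1)))
  } else {
    sum(internal$state == if (which == "dead_crc") 6L else 7L)
  }
}

#' Run one scenario arm over the full horizon
#'
#' Initializes a cohort and advances it year by year under the given
#' strategy, returning the complete trajectory with cumulative cases,
#' deaths and resource counters. Fully reproducible: in microsimulation mode
#' the seed determines every draw; expectation mode is deterministic.
#'
#' @param params An [nh_params] object.
#' @param scenario List with `age`, `sex`, `n` (cohort size), `horizon`
#'   (years), `mode` (`"expectation"` or `"microsim"`) and, for
#'   microsimulation, `seed`. See [scenario_config()].
#' @param strategy A [strategy].
#' @param adherence An [adherence_params].
#' @param profile A [per_state_profile] for FIT-bearing strategies; defaults
#'   to the decomposition of the packaged characteristics at the strategy's
#'   cut-off.
#' @param colo_params A [colonoscopy_params].
#' @return A [cohort_trajectory] covering years 0 to `horizon`.
#' @examples
#' params <- generate_natural_history_params(seed = 7)
#' sc <- list(age = 60, sex = "male", n = 10000, horizon = 10,
#'            mode = "expectation")
#' run_arm(params, sc, strategy("gateopener", cutoff = 8))
#' @export
run_arm <- function(params, scenario, strategy,
                    adherence = adherence_params(),
                    profile = NULL,
                    colo_params = colonoscopy_params()) {
  stopifnot(inherits(strategy, "strategy"))
  horizon <- scenario$horizon %||% 10L
  mode <- scenario$mode %||% "expectation"
  if (uses_fit(strategy) && is.null(profile)) {
    profile <- decompose_to_per_state(builtin_characteristics(strategy$cutoff),
                                      blitz_group_counts())
  }
  if (mode == "microsim") {
    withr::local_seed(scenario$seed %||%
                        stop_crc("microsim mode requires scenario$seed",
                                 "crcscreen_config_error"))
  }
  traj <- initialize_cohort(params, scenario$age, scenario$sex, scenario$n,
                            mode = mode, seed = scenario$seed %||% 1L)
  traj$meta$strategy <- strategy
  traj$meta$horizon <- as.integer(horizon)
  if (mode == "expectation") {
    traj <- setup_participation(traj, strategy, adherence, horizon)
  }
  for (year in seq_len(horizon) - 1L) {
    traj <- advance_one_year(traj, params, strategy, adherence, profile,
                             colo_params)
  }
  traj$internal <- NULL  # trajectory is complete; drop engine state
  traj
}
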