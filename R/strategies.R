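#' Screening strategy definition
#'
#' The four policies compared by the simulator: no screening; conventional
#' screening colonoscopy offered once per 10-year horizon; conventional
#' biennial FIT at the manufacturer preset cut-off (17 ug/g); and gateopener
#' screening, a single low-threshold FIT per 10-year horizon whose positives
#' are invited to screening colonoscopy.
#'
#' @param kind One of `"no_screening"`, `"colonoscopy_q10y"`,
#'   `"biennial_fit"`, `"gateopener"`.
#' @param cutoff Hemoglobin cut-off for FIT-bearing strategies. Biennial FIT
#'   is fixed at 17 ug/g; gateopener accepts any of the packaged cut-offs
#'   (17, 10, 8, 6, 4, 3).
#' @return An object of class `strategy`.
#' @export
strategy <- function(kind = c("no_screening", "colonoscopy_q10y",
                              "biennial_fit", "gateopener"),
                     cutoff = NULL) {
  kind <- match.arg(kind)
  if (kind == "biennial_fit") {
    if (is.null(cutoff)) cutoff <- 17
    if (cutoff != 17) {
      stop_crc("biennial FIT uses the manufacturer preset cut-off 17 ug/g",
               "crcscreen_config_error")
    }
  } else if (kind == "gateopener") {
    if (is.null(cutoff)) {
      stop_crc("gateopener strategy requires a cut-off", "crcscreen_config_error")
    }
  } else if (!is.null(cutoff)) {
    stop_crc(sprintf("strategy '%s' takes no cut-off", kind),
             "crcscreen_config_error")
  }
  structure(list(kind = kind, cutoff = cutoff), class = "strategy")
}

strategy_label <- function(strategy) {
  if (is.null(strategy$cutoff)) strategy$kind
  else sprintf("%s_%g", strategy$kind, strategy$cutoff)
}

uses_fit <- function(strategy) {
  strategy$kind %in% c("biennial_fit", "gateopener")
}

#' Adherence and drop-out parameters
#'
#' Participation behaviour of the invited population: uptake of the 10-yearly
#' colonoscopy offer (default 15%, as observed for the German
#' screening-eligible population), first-offer FIT participation (default
#' 50%), cumulative drop-out over the biennial FIT rounds within the horizon
#' (default 40%, capturing the sporadic nature of repeat FIT adherence), and
#' compliance with diagnostic colonoscopy after a positive FIT (default 80%).
#'
#' @param p_colonoscopy Probability of using the 10-yearly colonoscopy offer.
#' @param p_fit_first First-offer FIT participation probability.
#' @param dropout Cumulative drop-out fraction over the biennial rounds.
#' @param p_diag_colonoscopy Compliance with colonoscopy after positive FIT.
#' @return An object of class `adherence_params`.
#' @export
adherence_params <- function(p_colonoscopy = 0.15, p_fit_first = 0.50,
                             dropout = 0.40, p_diag_colonoscopy = 0.80) {
  assert_prob(c(p_colonoscopy, p_fit_first, dropout, p_diag_colonoscopy),
              "adherence parameters")
  structure(list(p_colonoscopy = p_colonoscopy, p_fit_first = p_fit_first,
                 dropout = dropout, p_diag_colonoscopy = p_diag_colonoscopy),
            class = "adherence_params")
}

#' Colonoscopy miss probabilities per lesion state
#'
#' True miss rates at colonoscopy are unknown; defaults approximate
#' meta-analytic estimates (about a quarter of non-advanced adenomas, far
#' fewer advanced adenomas, and very few preclinical cancers are missed).
#' The preclinical-CRC miss rate must not exceed the adenoma miss rates.
#'
#' @param miss_nonadvanced,miss_advanced,miss_preclinical_crc Probabilities
#'   in \[0, 1) that the lesion is missed at colonoscopy.
#' @return An object of class `colonoscopy_params`.
#' @export
colonoscopy_params <- function(miss_nonadvanced = 0.26, miss_advanced = 0.09,
                               miss_preclinical_crc = 0.05) {
  m <- c(miss_nonadvanced, miss_advanced, miss_preclinical_crc)
  assert_prob(m, "miss probabilities")
  if (any(m >= 1)) {
    stop_crc("miss probabilities must be < 1", "crcscreen_validation_error")
  }
  if (miss_preclinical_crc > min(miss_nonadvanced, miss_advanced)) {
    stop_crc("preclinical CRC miss rate must not exceed adenoma miss rates",
             "crcscreen_validation_error")
  }
  structure(list(miss_nonadvanced = miss_nonadvanced,
                 miss_advanced = miss_advanced,
                 miss_preclinical_crc = miss_preclinical_crc),
            class = "colonoscopy_params")
}

#' Offer years of a screening strategy within the horizon
#'
#' Colonoscopy and gateopener screening are offered in 10-year intervals, so
#' within a 10-year horizon they are offered once, at year 0. Biennial FIT is
#' offered every other year starting at year 0 (years 0, 2, 4, 6, 8 for a
#' 10-year horizon). No screening has no offers.
#'
#' @param strategy A [strategy].
#' @param horizon_years Follow-up horizon (>= 0).
#' @return Integer vector of offer years (possibly empty).
#' @export
schedule_offers <- function(strategy, horizon_years = 10) {
  stopifnot(horizon_years >= 0)
  if (horizon_years == 0 || strategy$kind == "no_screening") return(integer(0))
  if (strategy$kind == "biennial_fit") {
    return(seq(0L, horizon_years - 1L, by = 2L))
  }
  0L
}

# Per-round retention for biennial FIT: solved so the cumulative drop-out over
# the scheduled rounds equals `dropout`, i.e. final-round participation is
# p_fit_first * (1 - dropout).
round_retention <- function(adherence, n_rounds) {
  if (n_rounds <= 1) return(1)
  (1 - adherence$dropout)^(1 / (n_rounds - 1))
}

#' Unconditional per-round participation probabilities
#'
#' For biennial FIT, first-round participation is `p_fit_first`; enrolled
#' participants are retained round-to-round with a constant retention
#' probability chosen so that the cumulative drop-out across the scheduled
#' rounds equals `dropout` (final-round participation
#' `p_fit_first * (1 - dropout)`). Drop-out is absorbing, and first-offer
#' refusers do not enter later rounds. For one-off offers the single entry is
#' the respective uptake probability.
#'
#' @param strategy A [strategy].
#' @param adherence An [adherence_params].
#' @param horizon_years Horizon defining the offer schedule.
#' @return Numeric vector, one probability per scheduled offer.
#' @export
round_participation_rates <- function(strategy, adherence,
                                      horizon_years = 10) {
  offers <- schedule_offers(strategy, horizon_years)
  if (!length(offers)) return(numeric(0))
  switch(strategy$kind,
    colonoscopy_q10y = adherence$p_colonoscopy,
    gateopener = adherence$p_fit_first,
    biennial_fit = {
      r <- round_retention(adherence, length(offers))
      adherence$p_fit_first * r^(seq_along(offers) - 1)
    })
}

#' Draw one participation decision
#'
#' Single-participant participation draw for one offer round, threading the
#' participant's enrolment history: once enrolled, a biennial-FIT participant
#' is retained each subsequent round with the constant retention probability;
#' once dropped out (or never enrolled at the first offer), they never
#' participate again.
#'
#' @param round_index 1-based index of the offer round within the schedule.
#' @param strategy A [strategy].
#' @param adherence An [adherence_params].
#' @param history List with logicals `enrolled` and `dropped` (initial state
#'   `list(enrolled = FALSE, dropped = FALSE)`).
#' @param n_rounds Total number of scheduled rounds (for the retention solve).
#' @return List with `participates` (logical) and the updated `history`.
#' @export
participation <- function(round_index, strategy, adherence,
                          history = list(enrolled = FALSE, dropped = FALSE),
                          n_rounds = 5) {
  if (strategy$kind == "no_screening") {
    return(list(participates = FALSE, history = history))
  }
  if (round_index == 1) {
    p <- if (strategy$kind == "colonoscopy_q10y") adherence$p_colonoscopy
         else adherence$p_fit_first
    enrolled <- stats::runif(1) < p
    return(list(participates = enrolled,
                history = list(enrolled = enrolled, dropped = !enrolled)))
  }
  if (!history$enrolled || history$dropped) {
    return(list(participates = FALSE, history = history))
  }
  r <- round_retention(adherence, n_rounds)
  stay <- stats::runif(1) < r
  list(participates = stay,
       history = list(enrolled = TRUE, dropped = !stay))
}

state_codes <- c(no_neoplasm = 1L, nonadvanced_adenoma = 2L,
                 advanced_adenoma = 3L, preclinical_crc = 4L,
                 clinical_crc = 5L, dead_crc = 6L, dead_other = 7L)

#' Apply a FIT to one person
#'
#' Returns a positive/negative result drawn with the state-conditional
#' positivity. Clinically diagnosed and dead persons are outside the
#' screening pool; passing one in is a contract violation.
#'
#' @param state Disease state name (one of the four screen-eligible states).
#' @param profile A [per_state_profile].
#' @return Logical: test positive?
#' @export
apply_fit <- function(state, profile) {
  if (!state %in% finding_levels) {
    stop_crc(sprintf("apply_fit: state '%s' is not in the screening pool", state),
             "crcscreen_contract_error")
  }
  stats::runif(1) < profile$p_positive[[state]]
}

#' Apply a colonoscopy to one person
#'
#' Adenomas are removed (the person moves back to no neoplasm) unless the
#' lesion is missed; preclinical cancer is diagnosed (moves to clinical CRC,
#' screen-detected) unless missed; a person without neoplasm is unchanged.
#' The caller counts the colonoscopy regardless of finding.
#'
#' @param state Disease state name (screen-eligible states only).
#' @param colo_params A [colonoscopy_params].
#' @return List with `state` (new state name) and `detected` (logical: was a
#'   preclinical cancer diagnosed?).
#' @export
apply_colonoscopy <- function(state, colo_params) {
  if (!state %in% finding_levels) {
    stop_crc(sprintf("apply_colonoscopy: state '%s' is not in the screening pool",
                     state), "crcscreen_contract_error")
  }
  miss <- switch(state,
                 no_neoplasm = 0,
                 nonadvanced_adenoma = colo_params$miss_nonadvanced,
                 advanced_adenoma = colo_params$miss_advanced,
                 preclinical_crc = colo_params$miss_preclinical_crc)
  if (state == "no_neoplasm") {
    return(list(state = state, detected = FALSE))
  }
  if (stats::runif(1) < miss) {
    return(list(state = state, detected = FALSE))
  }
  if (state == "preclinical_crc") {
    list(state = "clinical_crc", detected = TRUE)
  } else {
    list(state = "no_neoplasm", detected = FALSE)
  }
}
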