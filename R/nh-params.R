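#' Natural-history parameter set for the multistate CRC model
#'
#' Container for everything the disease engine needs: sex- and age-specific
#' starting prevalences of the three lesion states (the no-neoplasm share is
#' the remainder), annual transition probabilities along the
#' adenoma-carcinoma sequence, other-cause (background) mortality, and CRC
#' case-fatality by year since diagnosis and mode of detection. Starting
#' prevalences and transition rates carry lower/upper 95% CI bounds for
#' sensitivity analyses.
#'
#' @param ages Integer vector of ages covered (contiguous); lookups for ages
#'   beyond the range use the nearest covered age (band/flat extrapolation).
#' @param prevalence Array `[age, sex, lesion, bound]` with lesions
#'   `nonadvanced_adenoma`, `advanced_adenoma`, `preclinical_crc` and bounds
#'   `point`, `lower`, `upper`.
#' @param transitions Array `[age, sex, transition, bound]` with transitions
#'   `no_to_nonadv`, `nonadv_to_adv`, `adv_to_preclin`, `preclin_to_clinical`.
#' @param other_cause_mortality Matrix `[age, sex]` of annual probabilities.
#' @param case_fatality Array `[year_since_dx, mode, bound]` with modes
#'   `screen_detected`, `symptom_detected`; row k is the annual CRC death
#'   probability in the k-th year after diagnosis (flat extrapolation beyond).
#' @return A validated object of class `nh_params`.
#' @export
nh_params <- function(ages, prevalence, transitions, other_cause_mortality,
                      case_fatality) {
  params <- structure(list(
    ages = as.integer(ages),
    prevalence = prevalence,
    transitions = transitions,
    other_cause_mortality = other_cause_mortality,
    case_fatality = case_fatality
  ), class = "nh_params")
  validate_nh_params(params)
  params
}

sexes <- c("female", "male")
lesion_states <- c("nonadvanced_adenoma", "advanced_adenoma", "preclinical_crc")
transition_names <- c("no_to_nonadv", "nonadv_to_adv", "adv_to_preclin",
                      "preclin_to_clinical")
detection_modes <- c("screen_detected", "symptom_detected")

#' Validate a natural-history parameter set
#'
#' Checks: all probabilities in \[0, 1\]; lesion prevalences (with the
#' implied no-neoplasm remainder) form a distribution; CI bounds bracket
#' point estimates; per-state total annual exit probability (progression plus
#' background mortality) does not exceed 1 at any age.
#'
#' @param params An `nh_params` object.
#' @return `params`, invisibly; raises a validation error otherwise.
#' @export
validate_nh_params <- function(params) {
  p <- params
  all_probs <- c(p$prevalence, p$transitions, p$other_cause_mortality,
                 p$case_fatality)
  if (any(!is.finite(all_probs)) || any(all_probs < 0) || any(all_probs > 1)) {
    stop_crc("all parameters must be probabilities in [0, 1]",
             "crcscreen_validation_error")
  }
  for (arr in list(p$prevalence, p$transitions, p$case_fatality)) {
    pt <- slice_bound(arr, "point")
    lo <- slice_bound(arr, "lower")
    up <- slice_bound(arr, "upper")
    if (any(lo > pt + 1e-12) || any(up < pt - 1e-12)) {
      stop_crc("CI bounds must bracket point estimates",
               "crcscreen_validation_error")
    }
  }
  prev_sum <- apply(slice_bound(p$prevalence, "point"), c(1, 2), sum)
  if (any(prev_sum > 1 + 1e-9)) {
    stop_crc("lesion prevalences must sum to <= 1 (no-neoplasm is the remainder)",
             "crcscreen_validation_error")
  }
  tr <- slice_bound(p$transitions, "point")
  dim(tr) <- dim(p$transitions)[1:3]
  for (k in seq_along(transition_names)) {
    tot <- tr[, , k] + p$other_cause_mortality
    if (any(tot > 1 + 1e-9)) {
      stop_crc(sprintf(
        "outgoing probability (transition %s + background mortality) exceeds 1",
        transition_names[k]), "crcscreen_validation_error")
    }
  }
  invisible(params)
}

slice_bound <- function(arr, bound) {
  nd <- length(dim(arr))
  idx <- rep(list(quote(expr = )), nd)
  idx[[nd]] <- bound
  do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
}

age_index <- function(params, age) {
  # band lookup with flat extrapolation at the edges
  min(max(age, params$ages[1]), params$ages[length(params$ages)]) -
    params$ages[1] + 1L
}

lookup_prevalence <- function(params, age, sex) {
  i <- age_index(params, age)
  lesions <- params$prevalence[i, sex, , "point"]
  c(no_neoplasm = 1 - sum(lesions), lesions)
}

lookup_transitions <- function(params, age, sex) {
  params$transitions[age_index(params, age), sex, , "point"]
}

lookup_om <- function(params, age, sex) {
  params$other_cause_mortality[age_index(params, age), sex]
}

#' Annual CRC death probability by time since diagnosis and detection mode
#'
#' Looks up the case-fatality table; years beyond the table range use the
#' last available row (flat extrapolation, with a notice). Screen-detected
#' values are bounded above by symptom-detected values at the same time since
#' diagnosis (hazard ratio below 1 for screen detection).
#'
#' @param years_since_dx Completed years since diagnosis (>= 0).
#' @param mode `"screen_detected"` or `"symptom_detected"`.
#' @param params An [nh_params] object.
#' @return Annual death probability.
#' @export
crc_death_probability <- function(years_since_dx, mode, params) {
  stopifnot(years_since_dx >= 0)
  mode <- match.arg(mode, detection_modes)
  n <- dim(params$case_fatality)[1]
  if (years_since_dx + 1 > n) {
    message(sprintf(
      "years since diagnosis %d beyond case-fatality table (%d rows); using last row",
      years_since_dx, n))
  }
  params$case_fatality[min(years_since_dx + 1, n), mode, "point"]
}

#' Specification for the synthetic natural-history parameter generator
#'
#' Defines base age curves, sex effects and uncertainty settings from which
#' [generate_natural_history_params()] draws a complete, schema-valid
#' parameter set. The defaults emulate the German screening-eligible
#' population: lesion prevalences and transition rates rising with age,
#' higher in men; Gompertz-like background mortality; CRC case-fatality
#' declining with time since diagnosis, reduced for screen-detected cases by
#' a hazard ratio below 1.
#'
#' @param ages Ages to cover.
#' @param prevalence_base Named list per lesion and sex of `c(at50, slope)`:
#'   prevalence at age 50 and per-year increase.
#' @param transition_base Named vector of annual transition probabilities at
#'   age 50 (sex-neutral).
#' @param transition_age_slope Relative increase per year of age for the
#'   three lesion transitions (the preclinical-to-clinical rate is flat).
#' @param sex_multiplier Multiplier on lesion transitions for men; women get
#'   `2 - sex_multiplier`.
#' @param mortality_coef `c(intercept, slope)` of log annual other-cause
#'   mortality in age, per sex.
#' @param case_fatality_symptom Annual death probabilities for
#'   symptom-detected CRC by year since diagnosis.
#' @param screen_hr Hazard ratio applied to symptom-detected fatality to get
#'   the screen-detected row (`p_screen = 1 - (1 - p_symptom)^hr`).
#' @param jitter Half-width of the relative uniform jitter applied to
#'   prevalences and transition rates when generating (0 = deterministic).
#' @param ci_halfwidth Relative half-width of the 95% CI bounds attached to
#'   prevalences and transition rates.
#' @return An object of class `synthetic_param_spec`.
#' @export
synthetic_param_spec <- function(
    ages = 50:85,
    prevalence_base = list(
      nonadvanced_adenoma = list(female = c(0.120, 0.0040),
                                 male = c(0.180, 0.0060)),
      advanced_adenoma = list(female = c(0.033, 0.0018),
                              male = c(0.050, 0.0025)),
      preclinical_crc = list(female = c(0.0020, 0.00025),
                             male = c(0.0030, 0.00035))
    ),
    transition_base = c(no_to_nonadv = 0.010, nonadv_to_adv = 0.025,
                        adv_to_preclin = 0.040, preclin_to_clinical = 0.22),
    transition_age_slope = 0.015,
    sex_multiplier = 1.12,
    mortality_coef = list(female = c(-10.85, 0.093), male = c(-10.35, 0.089)),
    case_fatality_symptom = c(0.12, 0.09, 0.06, 0.045, 0.035,
                              0.030, 0.025, 0.020, 0.020, 0.020),
    screen_hr = 0.55,
    jitter = 0.10,
    ci_halfwidth = 0.20) {
  if (jitter < 0 || ci_halfwidth < 0 || screen_hr <= 0 || screen_hr > 1) {
    stop_crc("spec ranges inverted or out of bounds (jitter, ci_halfwidth >= 0; 0 < screen_hr <= 1)",
             "crcscreen_validation_error")
  }
  structure(as.list(environment()), class = "synthetic_param_spec")
}

#' Generate a synthetic natural-history parameter set
#'
#' Draws a complete [nh_params] object from a [synthetic_param_spec]:
#' age-increasing lesion prevalences and transition rates with a
#' multiplicative sex effect, uniform relative jitter (seeded; zero jitter
#' gives the deterministic midpoints), and 95% CI bounds at the requested
#' relative half-width. Background mortality and case fatality are
#' deterministic functions of the spec.
#'
#' @param spec A [synthetic_param_spec].
#' @param seed Integer seed for the jitter draws.
#' @return A validated [nh_params] object.
#' @export
generate_natural_history_params <- function(spec = synthetic_param_spec(),
                                            seed = 1) {
  stopifnot(inherits(spec, "synthetic_param_spec"))
  withr::local_seed(seed)
  ages <- spec$ages
  na <- length(ages)
  jit <- function(n) {
    if (spec$jitter == 0) rep(1, n)
    else stats::runif(n, 1 - spec$jitter, 1 + spec$jitter)
  }
  with_bounds <- function(point, dimn) {
    arr <- array(NA_real_, dim = c(dim(point), 3),
                 dimnames = c(dimn, list(bound = c("point", "lower", "upper"))))
    arr[, , , "point"] <- point
    arr[, , , "lower"] <- clamp01(point * (1 - spec$ci_halfwidth))
    arr[, , , "upper"] <- clamp01(point * (1 + spec$ci_halfwidth))
    arr
  }

  prev_pt <- array(NA_real_, dim = c(na, 2, 3),
                   dimnames = list(age = ages, sex = sexes,
                                   lesion = lesion_states))
  for (les in lesion_states) {
    for (sx in sexes) {
      b <- spec$prevalence_base[[les]][[sx]]
      prev_pt[, sx, les] <- clamp01((b[1] + b[2] * (ages - 50)) * jit(na))
    }
  }
  prevalence <- with_bounds(prev_pt, list(age = ages, sex = sexes,
                                          lesion = lesion_states))

  sexmul <- c(female = 2 - spec$sex_multiplier, male = spec$sex_multiplier)
  tr_pt <- array(NA_real_, dim = c(na, 2, 4),
                 dimnames = list(age = ages, sex = sexes,
                                 transition = transition_names))
  for (k in seq_along(transition_names)) {
    tn <- transition_names[k]
    agecurve <- if (tn == "preclin_to_clinical") rep(1, na)
                else 1 + spec$transition_age_slope * (ages - 50)
    for (sx in sexes) {
      mul <- if (tn == "preclin_to_clinical") 1 else sexmul[[sx]]
      tr_pt[, sx, k] <- clamp01(spec$transition_base[[tn]] * agecurve * mul *
                                  jit(na))
    }
  }
  transitions <- with_bounds(tr_pt, list(age = ages, sex = sexes,
                                         transition = transition_names))

  om <- sapply(sexes, function(sx) {
    cf <- spec$mortality_coef[[sx]]
    clamp01(exp(cf[1] + cf[2] * ages))
  })
  dimnames(om) <- list(age = ages, sex = sexes)

  cf_sym <- spec$case_fatality_symptom
  cf_scr <- 1 - (1 - cf_sym)^spec$screen_hr
  case_fatality <- array(
    NA_real_, dim = c(length(cf_sym), 2, 3),
    dimnames = list(year_since_dx = seq_along(cf_sym) - 1,
                    mode = detection_modes,
                    bound = c("point", "lower", "upper")))
  for (b in c("point", "lower", "upper")) {
    case_fatality[, "symptom_detected", b] <- cf_sym
    case_fatality[, "screen_detected", b] <- cf_scr
  }

  nh_params(ages, prevalence, transitions, om, case_fatality)
}

#' Replace point estimates by a 95% CI bound
#'
#' Substitutes every starting-prevalence and transition-rate point estimate
#' by its lower or upper 95% CI bound, leaving background mortality and case
#' fatality untouched (the parameter-uncertainty sensitivity analysis
#' perturbs disease dynamics, not mortality tables).
#'
#' @param params An [nh_params] object with CI bounds present.
#' @param which `"lower"` or `"upper"`.
#' @return A new [nh_params] object.
#' @export
perturb_to_ci_bound <- function(params, which = c("lower", "upper")) {
  which <- match.arg(which)
  missing_at <- function(arr) any(!is.finite(slice_bound(arr, which)))
  offenders <- c("prevalence", "transitions")[
    c(missing_at(params$prevalence), missing_at(params$transitions))]
  if (length(offenders)) {
    stop_crc(sprintf("missing %s CI bounds in: %s", which,
                     paste(offenders, collapse = ", ")),
             "crcscreen_validation_error")
  }
  out <- params
  out$prevalence[, , , "point"] <- params$prevalence[, , , which]
  out$transitions[, , , "point"] <- params$transitions[, , , which]
  validate_nh_params(out)
  out
}

#' Read / write natural-history parameters as long-format CSV
#'
#' Plain-text interchange with columns `quantity` (prevalence, transition,
#' other_cause_mortality, case_fatality), `age` (or year since diagnosis for
#' case fatality), `sex` (or detection mode), `name`, `point`, `lower`,
#' `upper`. The schema is validated on load.
#'
#' @param params An [nh_params] object.
#' @param path File path.
#' @return `read_nh_params()` returns an [nh_params]; `write_nh_params()`
#'   returns `path` invisibly.
#' @export
write_nh_params <- function(params, path) {
  rows <- list()
  add <- function(quantity, age, sex, name, pt, lo, up) {
    rows[[length(rows) + 1]] <<- data.frame(
      quantity = quantity, age = age, sex = sex, name = name,
      point = pt, lower = lo, upper = up, stringsAsFactors = FALSE)
  }
  for (sx in sexes) for (a in params$ages) {
    i <- a - params$ages[1] + 1
    for (les in lesion_states) {
      add("prevalence", a, sx, les,
          params$prevalence[i, sx, les, "point"],
          params$prevalence[i, sx, les, "lower"],
          params$prevalence[i, sx, les, "upper"])
    }
    for (tn in transition_names) {
      add("transition", a, sx, tn,
          params$transitions[i, sx, tn, "point"],
          params$transitions[i, sx, tn, "lower"],
          params$transitions[i, sx, tn, "upper"])
    }
    add("other_cause_mortality", a, sx, "annual",
        params$other_cause_mortality[i, sx],
        params$other_cause_mortality[i, sx],
        params$other_cause_mortality[i, sx])
  }
  nysd <- dim(params$case_fatality)[1]
  for (md in detection_modes) for (y in seq_len(nysd) - 1) {
    add("case_fatality", y, md, "annual",
        params$case_fatality[y + 1, md, "point"],
        params$case_fatality[y + 1, md, "lower"],
        params$case_fatality[y + 1, md, "upper"])
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_nh_params
#' @export
read_nh_params <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("quantity", "age", "sex", "name", "point", "lower", "upper")
  if (!all(need %in% names(tab))) {
    stop_crc(sprintf("parameter file must have columns: %s",
                     paste(need, collapse = ", ")), "crcscreen_io_error")
  }
  prev <- tab[tab$quantity == "prevalence", ]
  trans <- tab[tab$quantity == "transition", ]
  om_tab <- tab[tab$quantity == "other_cause_mortality", ]
  cf_tab <- tab[tab$quantity == "case_fatality", ]
  if (!nrow(prev) || !nrow(trans) || !nrow(om_tab) || !nrow(cf_tab)) {
    stop_crc("parameter file is missing one of: prevalence, transition, other_cause_mortality, case_fatality",
             "crcscreen_io_error")
  }
  ages <- sort(unique(prev$age))
  na <- length(ages)
  fill <- function(sub, third, third_names) {
    arr <- array(NA_real_, dim = c(na, 2, length(third_names), 3),
                 dimnames = list(age = ages, sex = sexes, name = third_names,
                                 bound = c("point", "lower", "upper")))
    for (r in seq_len(nrow(sub))) {
      i <- match(sub$age[r], ages)
      arr[i, sub$sex[r], sub$name[r], ] <-
        c(sub$point[r], sub$lower[r], sub$upper[r])
    }
    if (any(!is.finite(arr))) {
      stop_crc(sprintf("incomplete %s table in parameter file", third),
               "crcscreen_io_error")
    }
    arr
  }
  prevalence <- fill(prev, "prevalence", lesion_states)
  names(dimnames(prevalence))[3] <- "lesion"
  transitions <- fill(trans, "transition", transition_names)
  names(dimnames(transitions))[3] <- "transition"
  om <- array(NA_real_, dim = c(na, 2), dimnames = list(age = ages, sex = sexes))
  for (r in seq_len(nrow(om_tab))) {
    om[match(om_tab$age[r], ages), om_tab$sex[r]] <- om_tab$point[r]
  }
  ysd <- sort(unique(cf_tab$age))
  cf <- array(NA_real_, dim = c(length(ysd), 2, 3),
              dimnames = list(year_since_dx = ysd, mode = detection_modes,
                              bound = c("point", "lower", "upper")))
  for (r in seq_len(nrow(cf_tab))) {
    cf[match(cf_tab$age[r], ysd), cf_tab$sex[r], ] <-
      c(cf_tab$point[r], cf_tab$lower[r], cf_tab$upper[r])
  }
  if (any(!is.finite(om)) || any(!is.finite(cf))) {
    stop_crc("incomplete mortality tables in parameter file", "crcscreen_io_error")
  }
  nh_params(ages, prevalence, transitions, om, cf)
}
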