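#' Zero-inflated log-normal mixture model for fecal hemoglobin, per state
#'
#' Parametric stand-in for the quantitative FIT measurements of a
#' screening-colonoscopy cohort. Each mutually exclusive disease state gets a
#' point mass at zero (no detectable hemoglobin) plus a two-component
#' log-normal mixture for detectable values (a low-level baseline component
#' and a bleeding component; one component is not flexible enough to follow
#' the observed kink between the mid and low cut-offs). The states are mixed
#' with the cohort's state composition. Only the cut-off-thresholded
#' positivities matter downstream, so the family is judged by how well its
#' implied operating characteristics match calibration targets, not by
#' density fit.
#'
#' @param states Named list (one entry per finding state, in the order
#'   no_neoplasm, nonadvanced_adenoma, advanced_adenoma, preclinical_crc) of
#'   lists with elements `p_zero` (mass at zero), `w` (weight of the first
#'   log-normal component), `meanlog1`, `sdlog1`, `meanlog2`, `sdlog2`.
#' @param weights Mixture weights over the four states (sum to 1).
#' @return An object of class `hb_model`.
#' @seealso [calibrate_hb_model()], [generate_fit_cohort()]
#' @export
hb_model <- function(states, weights) {
  stopifnot(identical(names(states), finding_levels),
            identical(names(weights), finding_levels))
  if (abs(sum(weights) - 1) > 1e-9) {
    stop_crc("mixture weights must sum to 1", "crcscreen_validation_error")
  }
  for (s in states) {
    assert_prob(s$p_zero, "p_zero")
    assert_prob(s$w, "w")
    stopifnot(is.finite(s$meanlog1), is.finite(s$sdlog1), s$sdlog1 > 0,
              is.finite(s$meanlog2), is.finite(s$sdlog2), s$sdlog2 > 0)
  }
  structure(list(states = states, weights = weights), class = "hb_model")
}

state_survival <- function(s, cutoff) {
  s$w * stats::plnorm(cutoff, s$meanlog1, s$sdlog1, lower.tail = FALSE) +
    (1 - s$w) * stats::plnorm(cutoff, s$meanlog2, s$sdlog2, lower.tail = FALSE)
}

#' Per-state positivity implied by an hb_model at a cut-off
#'
#' @param model An [hb_model].
#' @param cutoff Hemoglobin cut-off (ug/g), must be positive (all supported
#'   cut-offs exceed the assay limit of detection).
#' @return A [per_state_profile].
#' @export
implied_profile <- function(model, cutoff) {
  stopifnot(cutoff > 0)
  p <- vapply(model$states, function(s) {
    (1 - s$p_zero) * state_survival(s, cutoff)
  }, numeric(1))
  per_state_profile(p[[1]], p[[2]], p[[3]], p[[4]])
}

#' Aggregate characteristics implied by an hb_model at a cut-off
#'
#' @inheritParams implied_profile
#' @param counts A [group_counts] giving the cohort composition.
#' @return A [fit_characteristics].
#' @export
implied_characteristics <- function(model, cutoff, counts) {
  aggregate_per_state(implied_profile(model, cutoff), counts, cutoff = cutoff)
}

# Sum of squared deviations between implied and target positivity for one
# state across cut-offs; theta = (qlogis(p_zero), qlogis(w),
# meanlog1, log(sdlog1), meanlog2, log(sdlog2)).
state_objective <- function(theta, cutoffs, target) {
  s <- theta_to_state(theta)
  implied <- (1 - s$p_zero) * state_survival(s, cutoffs)
  sum((implied - target)^2)
}

theta_to_state <- function(theta) {
  list(p_zero = stats::plogis(theta[1]), w = stats::plogis(theta[2]),
       meanlog1 = theta[3], sdlog1 = exp(theta[4]),
       meanlog2 = theta[5], sdlog2 = exp(theta[6]))
}

#' Calibrate the hemoglobin model against FIT characteristics targets
#'
#' Fits, per disease state, the zero-mass and log-normal mixture parameters
#' so that the cut-off-thresholded positivities reproduce the targets.
#' Targets are given as aggregate characteristics (one per cut-off) together
#' with the cohort group counts; they are first decomposed into per-state
#' positivities ([decompose_to_per_state()]) and each state is then fitted by
#' minimising the summed squared deviation of implied versus target
#' positivity over all cut-offs (Nelder-Mead from a deterministic grid of
#' starting values; the fit is deterministic).
#'
#' The fit must reproduce every aggregate characteristic at every target
#' cut-off within `tol` (default 2 percentage points); otherwise an error
#' carrying the best-achieved deviations is raised.
#'
#' @param targets List of [fit_characteristics] objects at distinct cut-offs
#'   (at least 3), e.g. rows of the packaged reference table.
#' @param counts A [group_counts] for the target cohort.
#' @param tol Maximum tolerated absolute deviation of any implied aggregate
#'   characteristic from its target.
#' @return An [hb_model] with attribute `deviations` (matrix of implied minus
#'   target aggregates, characteristics x cut-offs) and `fit_sse` (per-state
#'   objective values).
#' @examples
#' targets <- lapply(c(17, 10, 8, 6, 4, 3), builtin_characteristics)
#' m <- calibrate_hb_model(targets, blitz_group_counts())
#' implied_characteristics(m, 8, blitz_group_counts())
#' @export
calibrate_hb_model <- function(targets, counts, tol = 0.02) {
  stopifnot(length(targets) >= 3)
  cutoffs <- vapply(targets, function(t) t$cutoff, numeric(1))
  stopifnot(!anyDuplicated(cutoffs))
  target_mat <- vapply(targets, function(t) {
    decompose_to_per_state(t, counts)$p_positive
  }, numeric(4))  # 4 states x n cut-offs

  starts <- expand.grid(lp0 = stats::qlogis(c(0.02, 0.2, 0.5)),
                        lw = stats::qlogis(c(0.3, 0.7)),
                        m1 = log(c(2, 6)), ls1 = log(c(0.5, 1)),
                        m2 = log(c(15, 60)), ls2 = log(c(0.8, 1.5)))
  states <- list()
  sse <- numeric(4)
  for (i in seq_along(finding_levels)) {
    tgt <- target_mat[i, ]
    best <- NULL
    for (j in seq_len(nrow(starts))) {
      fit <- stats::optim(as.numeric(starts[j, ]), state_objective,
                          cutoffs = cutoffs, target = tgt,
                          method = "Nelder-Mead",
                          control = list(maxit = 5000, reltol = 1e-14))
      if (is.null(best) || fit$value < best$value) best <- fit
    }
    # polish the winner from its own optimum
    best <- stats::optim(best$par, state_objective, cutoffs = cutoffs,
                         target = tgt, method = "Nelder-Mead",
                         control = list(maxit = 8000, reltol = 1e-15))
    states[[finding_levels[i]]] <- theta_to_state(best$par)
    sse[i] <- best$value
  }
  w <- c(counts$n_no_neoplasm, counts$n_nonadvanced_adenoma,
         counts$n_advanced_adenoma, counts$n_preclinical_crc) / counts$n_total
  names(w) <- finding_levels
  model <- hb_model(states, w)

  chars <- c("positivity", "sens_any_neoplasm", "sens_advanced_neoplasm",
             "sens_preclinical_crc", "spec_no_advanced")
  dev <- vapply(seq_along(targets), function(k) {
    imp <- implied_characteristics(model, cutoffs[k], counts)
    unlist(imp[chars]) - unlist(targets[[k]][chars])
  }, numeric(5))
  dimnames(dev) <- list(chars, cutoffs)
  if (max(abs(dev)) > tol) {
    stop_crc(sprintf(
      "hemoglobin model calibration did not reach %.3g tolerance (worst deviation %.4f)",
      tol, max(abs(dev))),
      "crcscreen_calibration_error", deviations = dev)
  }
  attr(model, "deviations") <- dev
  attr(model, "fit_sse") <- sse
  model
}

#' Cached hemoglobin model calibrated to the packaged reference table
#'
#' Convenience accessor: runs [calibrate_hb_model()] against all six
#' packaged cut-offs and the reference cohort counts, memoising the result
#' for the session (the fit is deterministic).
#'
#' @return An [hb_model].
#' @export
default_hb_model <- function() {
  if (is.null(.crcscreen_cache$hb_model)) {
    targets <- lapply(fit_reference_table()$cutoff, builtin_characteristics)
    .crcscreen_cache$hb_model <- calibrate_hb_model(targets, blitz_group_counts())
  }
  .crcscreen_cache$hb_model
}

.crcscreen_cache <- new.env(parent = emptyenv())

#' Generate a synthetic FIT record cohort from a hemoglobin model
#'
#' Draws a reproducible cohort of FIT records whose composition follows the
#' model's mixture weights exactly (largest-remainder apportionment, removing
#' composition noise) and whose hemoglobin values are sampled from the
#' per-state zero-inflated log-normal mixtures. Values below the assay limit
#' of detection (1.7 ug/g) are floored to 0; all supported cut-offs lie
#' above it, so thresholded classifications are unaffected. Sex and age
#' columns are decorative covariates (balanced sexes, ages 50-79).
#'
#' @param model An [hb_model].
#' @param n Number of records (>= 1).
#' @param seed Integer seed; the same seed yields identical records.
#' @param lod Limit of detection below which values are floored to zero.
#' @return A data.frame of FIT records (`hb_value`, `finding`, `sex`, `age`).
#' @export
generate_fit_cohort <- function(model, n, seed, lod = 1.7) {
  stopifnot(n >= 1)
  withr::local_seed(seed)
  # exact apportionment of states by largest remainder
  raw <- model$weights * n
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    add <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[add] <- base[add] + 1
  }
  finding <- rep(finding_levels, times = base)
  hb <- numeric(n)
  for (i in seq_along(finding_levels)) {
    s <- model$states[[i]]
    idx <- which(finding == finding_levels[i])
    k <- length(idx)
    comp1 <- stats::runif(k) < s$w
    v <- ifelse(comp1,
                stats::rlnorm(k, s$meanlog1, s$sdlog1),
                stats::rlnorm(k, s$meanlog2, s$sdlog2))
    v[stats::runif(k) < s$p_zero] <- 0
    hb[idx] <- v
  }
  hb[hb < lod] <- 0
  perm <- sample.int(n)
  rec <- data.frame(
    hb_value = hb[perm],
    finding = finding[perm],
    sex = sample(c("female", "male"), n, replace = TRUE),
    age = sample(50:79, n, replace = TRUE),
    stringsAsFactors = FALSE
  )
  validate_fit_records(rec)
  rec
}
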