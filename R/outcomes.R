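#' Prevented CRC cases and deaths versus a reference arm
#'
#' Difference in cumulative 10-year incident clinical CRC cases and CRC
#' deaths between a reference arm (typically no screening) and an
#' intervention arm run under the same scenario. Negative values (the
#' intervention doing worse) are reported as-is.
#'
#' @param intervention,reference [cohort_trajectory] objects with matching
#'   age, sex, cohort size, horizon and parameter set.
#' @return Named list `prevented_cases`, `prevented_deaths`.
#' @export
prevented_events <- function(intervention, reference) {
  check_comparable(intervention, reference)
  li <- utils::tail(intervention$occupancy, 1)
  lr <- utils::tail(reference$occupancy, 1)
  list(prevented_cases = lr$cum_cases - li$cum_cases,
       prevented_deaths = lr$cum_deaths - li$cum_deaths)
}

check_comparable <- function(a, b) {
  ma <- a$meta; mb <- b$meta
  same <- identical(ma$age, mb$age) && identical(ma$sex, mb$sex) &&
    identical(ma$n, mb$n) && identical(ma$horizon, mb$horizon) &&
    identical(ma$params_hash, mb$params_hash)
  if (!same) {
    stop_crc("arms are not comparable: age, sex, cohort size, horizon and parameter set must match",
             "crcscreen_comparison_error")
  }
  invisible(TRUE)
}

#' Summarise one intervention arm against its reference
#'
#' Collects cumulative cases, deaths and resource counters of the
#' intervention arm, the prevented events versus the reference, and the
#' resource-efficiency ratios.
#'
#' @inheritParams prevented_events
#' @return A one-row data.frame of class `outcome_summary` with columns
#'   `strategy`, `cutoff`, `age`, `sex`, `n`, `crc_cases`, `crc_deaths`,
#'   `colonoscopies`, `fits`, `prevented_cases`, `prevented_deaths`, and the
#'   four efficiency ratios (`NA` where undefined).
#' @export
outcome_summary <- function(intervention, reference) {
  prev <- prevented_events(intervention, reference)
  li <- utils::tail(intervention$occupancy, 1)
  m <- intervention$meta
  out <- data.frame(
    strategy = m$strategy$kind,
    cutoff = m$strategy$cutoff %||% NA_real_,
    age = m$age, sex = m$sex, n = m$n,
    crc_cases = li$cum_cases, crc_deaths = li$cum_deaths,
    colonoscopies = li$colonoscopies, fits = li$fits,
    prevented_cases = prev$prevented_cases,
    prevented_deaths = prev$prevented_deaths,
    stringsAsFactors = FALSE
  )
  ratios <- efficiency_ratios(out)
  out <- cbind(out, ratios)
  class(out) <- c("outcome_summary", class(out))
  out
}

#' Resource-efficiency ratios
#'
#' Colonoscopies and FITs per prevented CRC case and per prevented CRC
#' death. A ratio is undefined (`NA`, not an error) when the corresponding
#' prevented count is zero or negative; such rows are excluded from league
#' tables rather than reported as spurious numbers.
#'
#' @param summary A data.frame (or one-row [outcome_summary]) with columns
#'   `colonoscopies`, `fits`, `prevented_cases`, `prevented_deaths`.
#' @return data.frame with columns `colonoscopies_per_prevented_case`,
#'   `colonoscopies_per_prevented_death`, `fits_per_prevented_case`,
#'   `fits_per_prevented_death`.
#' @export
efficiency_ratios <- function(summary) {
  ratio <- function(resource, prevented) {
    ifelse(prevented > 0, resource / prevented, NA_real_)
  }
  data.frame(
    colonoscopies_per_prevented_case =
      ratio(summary$colonoscopies, summary$prevented_cases),
    colonoscopies_per_prevented_death =
      ratio(summary$colonoscopies, summary$prevented_deaths),
    fits_per_prevented_case = ratio(summary$fits, summary$prevented_cases),
    fits_per_prevented_death = ratio(summary$fits, summary$prevented_deaths)
  )
}

#' Relative difference between two metric values, in percent
#'
#' `100 * (a - b) / b`: by how many percent metric `a` exceeds (positive) or
#' falls short of (negative) baseline `b`. Undefined (`NA`) for a
#' non-positive baseline.
#'
#' @param metric_a Intervention value.
#' @param metric_b Baseline value (> 0 for a defined result).
#' @return Percent difference (not rounded; league tables round to integer).
#' @export
relative_difference <- function(metric_a, metric_b) {
  ifelse(metric_b > 0, 100 * (metric_a - metric_b) / metric_b, NA_real_)
}

#' Long-format league table across a grid of outcome summaries
#'
#' Stacks outcome summaries into a tidy long table, one row per
#' (strategy, cut-off, age, sex, metric), with each metric value accompanied
#' by its relative difference (integer percent) versus the conventional
#' screening colonoscopy arm and versus the conventional biennial FIT arm of
#' the same age/sex stratum. Row order is deterministic.
#'
#' @param summaries A list of [outcome_summary] rows or a data.frame of
#'   stacked summaries covering, per age/sex stratum, the reference
#'   strategies `colonoscopy_q10y` and `biennial_fit` next to any gateopener
#'   arms.
#' @param metrics Metric columns to report.
#' @return A tidy data.frame with columns `strategy`, `cutoff`, `age`, `sex`,
#'   `metric`, `value`, `rel_vs_colonoscopy`, `rel_vs_biennial_fit`.
#' @export
league_table <- function(summaries,
                         metrics = c("crc_cases", "crc_deaths",
                                     "prevented_cases", "prevented_deaths",
                                     "colonoscopies", "fits",
                                     "colonoscopies_per_prevented_case",
                                     "colonoscopies_per_prevented_death")) {
  if (is.list(summaries) && !is.data.frame(summaries)) {
    summaries <- do.call(rbind, lapply(summaries, as.data.frame))
  }
  if (nrow(summaries) < 2) {
    stop_crc("league table needs at least two arms (a reference to compare against)",
             "crcscreen_comparison_error")
  }
  strata <- unique(summaries[, c("age", "sex")])
  rows <- list()
  for (s in seq_len(nrow(strata))) {
    sub <- summaries[summaries$age == strata$age[s] &
                       summaries$sex == strata$sex[s], , drop = FALSE]
    ref_colo <- sub[sub$strategy == "colonoscopy_q10y", , drop = FALSE]
    ref_fit <- sub[sub$strategy == "biennial_fit", , drop = FALSE]
    if (nrow(ref_colo) == 0 && nrow(ref_fit) == 0) {
      stop_crc("no reference arm (colonoscopy_q10y or biennial_fit) in stratum",
               "crcscreen_comparison_error")
    }
    for (i in seq_len(nrow(sub))) {
      for (met in metrics) {
        v <- sub[[met]][i]
        rel1 <- if (nrow(ref_colo)) {
          round(relative_difference(v, ref_colo[[met]][1]))
        } else NA_real_
        rel2 <- if (nrow(ref_fit)) {
          round(relative_difference(v, ref_fit[[met]][1]))
        } else NA_real_
        rows[[length(rows) + 1]] <- data.frame(
          strategy = sub$strategy[i], cutoff = sub$cutoff[i],
          age = sub$age[i], sex = sub$sex[i], metric = met, value = v,
          rel_vs_colonoscopy = rel1, rel_vs_biennial_fit = rel2,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$age, out$sex, out$strategy, out$cutoff, out$metric,
            na.last = TRUE), , drop = FALSE]
}

#' Pool the two sexes of a scenario grid
#'
#' Sums counts (cases, deaths, resources, prevented events) across the
#' female and male arms of the same strategy/age cell and recomputes the
#' efficiency ratios on the pooled counts. Headline comparisons pool sexes;
#' sex-split results remain available in the unpooled summaries.
#'
#' @param summaries data.frame of stacked outcome summaries with both sexes.
#' @return data.frame of pooled summaries with `sex = "pooled"`.
#' @export
pool_sexes <- function(summaries) {
  key <- paste(summaries$strategy,
               ifelse(is.na(summaries$cutoff), "none", summaries$cutoff),
               summaries$age)
  pooled <- lapply(split(summaries, key), function(sub) {
    out <- sub[1, , drop = FALSE]
    out$sex <- "pooled"
    for (cn in c("n", "crc_cases", "crc_deaths", "colonoscopies", "fits",
                 "prevented_cases", "prevented_deaths")) {
      out[[cn]] <- sum(sub[[cn]])
    }
    out[, c("colonoscopies_per_prevented_case",
            "colonoscopies_per_prevented_death",
            "fits_per_prevented_case", "fits_per_prevented_death")] <-
      efficiency_ratios(out)
    out
  })
  res <- do.call(rbind, pooled)
  rownames(res) <- NULL
  res
}
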