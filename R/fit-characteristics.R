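#' Aggregate diagnostic characteristics of a quantitative FIT at one cut-off
#'
#' Bundles the population-level operating characteristics of a fecal
#' immunochemical test (FIT) evaluated at a single hemoglobin cut-off:
#' the positivity rate among all tested persons, sensitivities for any
#' neoplasm (any adenoma or cancer), any advanced neoplasm (advanced adenoma
#' or cancer) and preclinical colorectal cancer, and the specificity in the
#' no-advanced-neoplasm group.
#'
#' All values are stored as fractions in \[0, 1\]. Within one instance the
#' sensitivities are expected to be ordered
#' `sens_preclinical_crc >= sens_advanced_neoplasm >= sens_any_neoplasm`
#' (cancers bleed more than advanced adenomas, which bleed more than the
#' average neoplasm); a violation raises a warning rather than an error,
#' since small samples can break the ordering by chance.
#'
#' @param cutoff Hemoglobin cut-off in micrograms Hb per gram feces.
#' @param positivity Fraction of all tested persons with a positive result.
#' @param sens_any_neoplasm,sens_advanced_neoplasm,sens_preclinical_crc
#'   Fractions of the respective diseased group testing positive. May be `NA`
#'   when the group was empty (undefined, not zero).
#' @param spec_no_advanced Fraction of the no-advanced-neoplasm group testing
#'   negative.
#' @return An object of class `fit_characteristics`.
#' @seealso [builtin_characteristics()], [characteristics_from_records()]
#' @export
fit_characteristics <- function(cutoff, positivity, sens_any_neoplasm,
                                sens_advanced_neoplasm, sens_preclinical_crc,
                                spec_no_advanced) {
  stopifnot(is.numeric(cutoff), length(cutoff) == 1, cutoff >= 0)
  vals <- c(positivity = positivity,
            sens_any_neoplasm = sens_any_neoplasm,
            sens_advanced_neoplasm = sens_advanced_neoplasm,
            sens_preclinical_crc = sens_preclinical_crc,
            spec_no_advanced = spec_no_advanced)
  for (nm in names(vals)) {
    if (!is.na(vals[[nm]])) assert_prob(vals[[nm]], nm)
  }
  s <- vals[c("sens_any_neoplasm", "sens_advanced_neoplasm",
              "sens_preclinical_crc")]
  s <- s[!is.na(s)]
  if (length(s) > 1 && any(diff(s) < -1e-12)) {
    warning("sensitivity ordering any <= advanced <= preclinical CRC violated; ",
            "plausible only for small samples", call. = FALSE)
  }
  structure(c(list(cutoff = cutoff), as.list(vals)),
            class = "fit_characteristics")
}

#' @export
print.fit_characteristics <- function(x, ...) {
  cat(sprintf(
    "FIT characteristics at cut-off %g ug Hb/g feces\n", x$cutoff))
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.1f%%", 100 * v)
  cat(sprintf("  positivity:                 %s\n", fmt(x$positivity)))
  cat(sprintf("  sensitivity, any neoplasm:  %s\n", fmt(x$sens_any_neoplasm)))
  cat(sprintf("  sensitivity, advanced:      %s\n", fmt(x$sens_advanced_neoplasm)))
  cat(sprintf("  sensitivity, preclin. CRC:  %s\n", fmt(x$sens_preclinical_crc)))
  cat(sprintf("  specificity, no advanced:   %s\n", fmt(x$spec_no_advanced)))
  invisible(x)
}

#' Packaged reference table of FIT characteristics
#'
#' Reads the packaged table of diagnostic characteristics of the SENTiFIT-FOB
#' Gold quantitative FIT at hemoglobin cut-offs 17, 10, 8, 6, 4 and 3 ug/g
#' feces, derived from a German screening-colonoscopy cohort (n = 7398).
#' A different table with the same column layout can be supplied via `path`
#' to override the packaged defaults.
#'
#' @param path Optional path to a CSV with columns `cutoff, positivity,
#'   sens_any_neoplasm, sens_advanced_neoplasm, sens_preclinical_crc,
#'   spec_no_advanced` (fractions).
#' @return A data.frame, one row per cut-off, sorted by decreasing cut-off.
#' @export
fit_reference_table <- function(path = NULL) {
  path <- path %||% system.file("extdata", "sentifit_table1.csv",
                                package = "crcscreen", mustWork = TRUE)
  tab <- utils::read.csv(path)
  need <- c("cutoff", "positivity", "sens_any_neoplasm",
            "sens_advanced_neoplasm", "sens_preclinical_crc",
            "spec_no_advanced")
  if (!all(need %in% names(tab))) {
    stop_crc(sprintf("FIT reference table must have columns: %s",
                     paste(need, collapse = ", ")),
             "crcscreen_io_error")
  }
  tab[order(-tab$cutoff), , drop = FALSE]
}

#' Look up the packaged FIT characteristics at a supported cut-off
#'
#' Returns the packaged operating characteristics at one of the supported
#' hemoglobin cut-offs verbatim. No interpolation is performed between
#' cut-offs: the dose-response shape between thresholds is unknown, so
#' arbitrary cut-offs are only served by re-counting records
#' ([characteristics_from_records()]).
#'
#' @param cutoff One of the cut-offs present in `table` (packaged default:
#'   17, 10, 8, 6, 4, 3 ug/g).
#' @param table Reference table as returned by [fit_reference_table()].
#' @return A [fit_characteristics] object.
#' @examples
#' builtin_characteristics(17)
#' @export
builtin_characteristics <- function(cutoff, table = fit_reference_table()) {
  i <- which(table$cutoff == cutoff)
  if (length(i) != 1) {
    stop_crc(sprintf(
      "unsupported cut-off %g; packaged cut-offs are {%s} and no interpolation is done",
      cutoff, paste(sort(table$cutoff, decreasing = TRUE), collapse = ", ")),
      "crcscreen_unsupported_cutoff")
  }
  r <- table[i, ]
  fit_characteristics(r$cutoff, r$positivity, r$sens_any_neoplasm,
                      r$sens_advanced_neoplasm, r$sens_preclinical_crc,
                      r$spec_no_advanced)
}

#' Participant counts by colonoscopy finding group
#'
#' Holds the nested group counts used as denominators of FIT operating
#' characteristics: any neoplasm (any adenoma or cancer), any advanced
#' neoplasm (advanced adenoma or preclinical cancer), preclinical cancer,
#' and their complement (no advanced neoplasm). The mutually exclusive
#' state counts (no neoplasm, non-advanced adenoma, advanced adenoma,
#' preclinical CRC) are derived from these.
#'
#' @param n_total Total participants.
#' @param n_any_neoplasm Participants with any adenoma or cancer.
#' @param n_advanced_neoplasm Participants with advanced adenoma or cancer.
#' @param n_preclinical_crc Participants with preclinical CRC.
#' @param n_no_advanced Participants without advanced neoplasm; defaults to
#'   `n_total - n_advanced_neoplasm` and is checked against it.
#' @return An object of class `group_counts` with derived exclusive counts
#'   `n_no_neoplasm`, `n_nonadvanced_adenoma`, `n_advanced_adenoma`.
#' @seealso [blitz_group_counts()] for the packaged reference cohort counts.
#' @export
group_counts <- function(n_total, n_any_neoplasm, n_advanced_neoplasm,
                         n_preclinical_crc,
                         n_no_advanced = n_total - n_advanced_neoplasm) {
  if (n_no_advanced + n_advanced_neoplasm != n_total) {
    stop_crc("n_no_advanced + n_advanced_neoplasm must equal n_total",
             "crcscreen_validation_error")
  }
  if (!(n_any_neoplasm >= n_advanced_neoplasm &&
        n_advanced_neoplasm >= n_preclinical_crc)) {
    stop_crc("group counts must be nested: any >= advanced >= preclinical CRC",
             "crcscreen_validation_error")
  }
  out <- list(
    n_total = n_total,
    n_any_neoplasm = n_any_neoplasm,
    n_advanced_neoplasm = n_advanced_neoplasm,
    n_preclinical_crc = n_preclinical_crc,
    n_no_advanced = n_no_advanced,
    n_no_neoplasm = n_total - n_any_neoplasm,
    n_nonadvanced_adenoma = n_any_neoplasm - n_advanced_neoplasm,
    n_advanced_adenoma = n_advanced_neoplasm - n_preclinical_crc
  )
  if (any(unlist(out) < 0)) {
    stop_crc("derived exclusive counts must be non-negative",
             "crcscreen_validation_error")
  }
  structure(out, class = "group_counts")
}

#' Reference screening-colonoscopy cohort group counts
#'
#' Group sizes of the German screening-colonoscopy cohort (quantitative FIT
#' before colonoscopy, n = 7398) underlying the packaged FIT reference table:
#' 2115 with any neoplasm, 728 with any advanced neoplasm, 54 with preclinical
#' cancer, 6670 without advanced neoplasm.
#'
#' @return A [group_counts] object.
#' @export
blitz_group_counts <- function() {
  group_counts(n_total = 7398L, n_any_neoplasm = 2115L,
               n_advanced_neoplasm = 728L, n_preclinical_crc = 54L,
               n_no_advanced = 6670L)
}

#' State-conditional FIT positivity profile
#'
#' Probability of a positive FIT conditional on the true, mutually exclusive
#' disease state. This is the form the simulation engine consumes: aggregate
#' sensitivities are defined over nested groups (e.g. "any advanced neoplasm"
#' mixes advanced adenomas and cancers), whereas the multistate engine needs
#' one positivity per state.
#'
#' @param p_pos_no_neoplasm,p_pos_nonadvanced_adenoma,p_pos_advanced_adenoma,p_pos_preclinical_crc
#'   Probabilities in \[0, 1\].
#' @return An object of class `per_state_profile`.
#' @export
per_state_profile <- function(p_pos_no_neoplasm, p_pos_nonadvanced_adenoma,
                              p_pos_advanced_adenoma, p_pos_preclinical_crc) {
  p <- c(no_neoplasm = p_pos_no_neoplasm,
         nonadvanced_adenoma = p_pos_nonadvanced_adenoma,
         advanced_adenoma = p_pos_advanced_adenoma,
         preclinical_crc = p_pos_preclinical_crc)
  assert_prob(p, "per-state positivity")
  structure(list(p_positive = p), class = "per_state_profile")
}

#' @export
print.per_state_profile <- function(x, ...) {
  cat("Per-state FIT positivity profile\n")
  for (nm in names(x$p_positive)) {
    cat(sprintf("  %-22s %.3f\n", nm, x$p_positive[[nm]]))
  }
  invisible(x)
}

#' Decompose aggregate FIT characteristics into per-state positivities
#'
#' Solves the mixture arithmetic that links group-level sensitivities and
#' specificity to state-conditional positivities. The nested groups are
#' peeled from the inside out: preclinical cancers keep their own
#' sensitivity; the advanced-adenoma positivity is what remains of the
#' advanced-neoplasm sensitivity after removing the cancer contribution;
#' similarly for non-advanced adenomas; and the no-neoplasm positivity
#' absorbs the remainder of the false-positive rate in the
#' no-advanced-neoplasm group.
#'
#' Published aggregates are rounded, so the linear solve can land slightly
#' outside \[0, 1\]; results are clamped with a warning in that case.
#'
#' @param agg A [fit_characteristics] object.
#' @param counts A [group_counts] object for the cohort the aggregates were
#'   measured in.
#' @return A [per_state_profile] object.
#' @examples
#' decompose_to_per_state(builtin_characteristics(17), blitz_group_counts())
#' @export
decompose_to_per_state <- function(agg, counts) {
  stopifnot(inherits(agg, "fit_characteristics"),
            inherits(counts, "group_counts"))
  n_crc <- counts$n_preclinical_crc
  n_adv <- counts$n_advanced_neoplasm
  n_any <- counts$n_any_neoplasm
  n_advA <- counts$n_advanced_adenoma
  n_nona <- counts$n_nonadvanced_adenoma
  n_none <- counts$n_no_neoplasm
  if (n_advA == 0 || n_nona == 0 || n_none == 0 || n_crc == 0) {
    stop_crc("degenerate group counts: a subgroup denominator is zero",
             "crcscreen_degenerate_counts")
  }
  p_crc <- agg$sens_preclinical_crc
  p_advA <- (agg$sens_advanced_neoplasm * n_adv - p_crc * n_crc) / n_advA
  p_nona <- (agg$sens_any_neoplasm * n_any -
               agg$sens_advanced_neoplasm * n_adv) / n_nona
  p_none <- ((1 - agg$spec_no_advanced) * counts$n_no_advanced -
               p_nona * n_nona) / n_none
  p <- c(p_none, p_nona, p_advA, p_crc)
  if (any(p < 0 | p > 1)) {
    warning(sprintf(
      "per-state positivities clamped to [0, 1] (raw: %s); rounded aggregates",
      paste(sprintf("%.4f", p), collapse = ", ")), call. = FALSE)
    p <- clamp01(p)
  }
  per_state_profile(p[1], p[2], p[3], p[4])
}

#' Re-aggregate a per-state profile into group-level characteristics
#'
#' Count-weighted inverse of [decompose_to_per_state()]: mixes the
#' state-conditional positivities back into positivity, nested-group
#' sensitivities and the no-advanced specificity. Useful to verify the
#' decomposition round-trip and to compute the characteristics implied by a
#' calibrated hemoglobin model.
#'
#' @param profile A [per_state_profile].
#' @param counts A [group_counts].
#' @param cutoff Cut-off label carried into the result.
#' @return A [fit_characteristics] object.
#' @export
aggregate_per_state <- function(profile, counts, cutoff = NA_real_) {
  p <- profile$p_positive
  pos_none <- p[["no_neoplasm"]] * counts$n_no_neoplasm
  pos_nona <- p[["nonadvanced_adenoma"]] * counts$n_nonadvanced_adenoma
  pos_advA <- p[["advanced_adenoma"]] * counts$n_advanced_adenoma
  pos_crc <- p[["preclinical_crc"]] * counts$n_preclinical_crc
  fit_characteristics(
    cutoff = if (is.na(cutoff)) 0 else cutoff,
    positivity = (pos_none + pos_nona + pos_advA + pos_crc) / counts$n_total,
    sens_any_neoplasm = (pos_nona + pos_advA + pos_crc) / counts$n_any_neoplasm,
    sens_advanced_neoplasm = (pos_advA + pos_crc) / counts$n_advanced_neoplasm,
    sens_preclinical_crc = p[["preclinical_crc"]],
    spec_no_advanced = 1 - (pos_none + pos_nona) / counts$n_no_advanced
  )
}

finding_levels <- c("no_neoplasm", "nonadvanced_adenoma",
                    "advanced_adenoma", "preclinical_crc")

#' Validate a table of individual FIT records
#'
#' A FIT record couples a quantitative fecal hemoglobin value with the
#' participant's colonoscopy finding category (the true disease state).
#'
#' @param records data.frame with columns `hb_value` (ug Hb/g feces, >= 0) and
#'   `finding` (one of `no_neoplasm`, `nonadvanced_adenoma`,
#'   `advanced_adenoma`, `preclinical_crc`); optional `sex`, `age`.
#' @return The validated data.frame (invisibly classed `fit_records`).
#' @export
validate_fit_records <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0) {
    stop_crc("records must be a non-empty data.frame", "crcscreen_validation_error")
  }
  if (!all(c("hb_value", "finding") %in% names(records))) {
    stop_crc("records need columns `hb_value` and `finding`",
             "crcscreen_validation_error")
  }
  if (any(!is.finite(records$hb_value)) || any(records$hb_value < 0)) {
    stop_crc("hb_value must be finite and >= 0", "crcscreen_validation_error")
  }
  bad <- setdiff(unique(as.character(records$finding)), finding_levels)
  if (length(bad)) {
    stop_crc(sprintf("unknown finding categories: %s",
                     paste(bad, collapse = ", ")),
             "crcscreen_validation_error")
  }
  class(records) <- unique(c("fit_records", class(records)))
  invisible(records)
}

#' Compute FIT characteristics by counting records at a cut-off
#'
#' Counts positives (hemoglobin at or above the cut-off; the lower bound is
#' closed) in each finding group: any neoplasm is any adenoma or cancer,
#' advanced neoplasm is advanced adenoma or cancer, and the specificity
#' denominator is the complement of the advanced-neoplasm group. An empty
#' diseased group yields an undefined (`NA`) sensitivity, never zero.
#'
#' @param records A data.frame of FIT records (see [validate_fit_records()]).
#' @param cutoff Hemoglobin cut-off (ug/g); a record is positive when
#'   `hb_value >= cutoff`.
#' @return A [fit_characteristics] object.
#' @export
characteristics_from_records <- function(records, cutoff) {
  validate_fit_records(records)
  stopifnot(is.numeric(cutoff), length(cutoff) == 1)
  f <- as.character(records$finding)
  pos <- records$hb_value >= cutoff
  grp_rate <- function(keep) {
    n <- sum(keep)
    if (n == 0) NA_real_ else sum(pos & keep) / n
  }
  any_g <- f != "no_neoplasm"
  adv_g <- f %in% c("advanced_adenoma", "preclinical_crc")
  fit_characteristics(
    cutoff = cutoff,
    positivity = mean(pos),
    sens_any_neoplasm = grp_rate(any_g),
    sens_advanced_neoplasm = grp_rate(adv_g),
    sens_preclinical_crc = grp_rate(f == "preclinical_crc"),
    spec_no_advanced = {
      r <- grp_rate(!adv_g)
      if (is.na(r)) NA_real_ else 1 - r
    }
  )
}

#' Sensitivity and positivity across a grid of cut-offs
#'
#' Recomputes [characteristics_from_records()] at each cut-off. Cut-offs are
#' expected in decreasing order (the direction in which positivity and
#' sensitivities rise); unsorted input is sorted internally with a message.
#' Duplicated cut-offs yield duplicated identical rows.
#'
#' @inheritParams characteristics_from_records
#' @param cutoffs Numeric vector of cut-offs, decreasing.
#' @return data.frame with one row per cut-off: `cutoff`, `positivity`,
#'   `sens_any_neoplasm`, `sens_advanced_neoplasm`, `sens_preclinical_crc`,
#'   `spec_no_advanced`.
#' @export
sensitivity_positivity_curve <- function(records, cutoffs) {
  stopifnot(length(cutoffs) >= 1)
  if (is.unsorted(rev(cutoffs), strictly = FALSE)) {
    message("cut-offs not in decreasing order; sorting internally")
    cutoffs <- sort(cutoffs, decreasing = TRUE)
  }
  rows <- lapply(cutoffs, function(ct) {
    ch <- characteristics_from_records(records, ct)
    as.data.frame(ch[c("cutoff", "positivity", "sens_any_neoplasm",
                       "sens_advanced_neoplasm", "sens_preclinical_crc",
                       "spec_no_advanced")])
  })
  do.call(rbind, rows)
}

#' Read / write FIT records as CSV
#'
#' Delimited-text interchange for FIT record cohorts: columns `hb_value`,
#' `finding`, `sex`, `age`.
#'
#' @param path File path.
#' @param records data.frame of FIT records.
#' @return `read_fit_records()` returns a validated data.frame;
#'   `write_fit_records()` returns `path` invisibly.
#' @export
read_fit_records <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_fit_records(rec)
  rec
}

#' @rdname read_fit_records
#' @export
write_fit_records <- function(records, path) {
  validate_fit_records(records)
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}
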