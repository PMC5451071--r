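#' Stimulation index
#'
#' SI is the ratio of the mean treated signal to the mean baseline signal
#' for one (donor, compound, readout): `mean(treated) / mean(baseline)`.
#' Using the ratio of replicate means (rather than the mean of per-well
#' ratios) keeps SI well defined when replicate counts differ.
#'
#' @param treated Numeric vector of treated-well values (cpm or spw).
#' @param baseline Numeric vector of untreated-well values.
#' @param baseline_floor `NULL` (strict: a non-positive baseline mean is an
#'   error) or a positive number substituted for the baseline mean when it
#'   is not positive (floor mode; the result carries attribute
#'   `floored = TRUE`).
#' @return The stimulation index, a non-negative scalar.
#' @examples
#' stimulation_index(c(9, 9, 9), c(3, 3, 3)) # 3
#' @export
stimulation_index <- function(treated, baseline, baseline_floor = NULL) {
  if (!length(treated) || !length(baseline))
    stop("treated and baseline must both be non-empty")
  mb <- mean(baseline)
  floored <- FALSE
  if (mb <= 0) {
    if (is.null(baseline_floor))
      stop("baseline mean is not positive; supply baseline_floor to proceed")
    stopifnot(baseline_floor > 0)
    mb <- baseline_floor
    floored <- TRUE
  }
  si <- mean(treated) / mb
  if (floored) attr(si, "floored") <- TRUE
  si
}

#' Two-tailed unpaired Student t-test p-value
#'
#' Classical equal-variance two-sample t-test:
#' `t = (m1 - m2) / (s_p * sqrt(1/n1 + 1/n2))` with pooled variance
#' `s_p^2` and `df = n1 + n2 - 2`; the p-value is the two-tailed tail
#' probability. Degenerate limits: zero pooled variance with equal means
#' gives p = 1; zero pooled variance with unequal means gives p = 0 (the
#' limiting value, flagged with attribute `degenerate = TRUE`).
#'
#' @param treated,baseline Numeric vectors, each of length >= 2.
#' @return Two-tailed p-value in `[0, 1]`.
#' @examples
#' two_tailed_unpaired_t(c(10, 12, 14), c(10, 12, 14)) # 1
#' @export
two_tailed_unpaired_t <- function(treated, baseline) {
  n1 <- length(treated); n2 <- length(baseline)
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 values")
  m1 <- mean(treated); m2 <- mean(baseline)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * stats::var(treated) +
          (n2 - 1) * stats::var(baseline)) / df
  if (sp2 <= 0) {
    p <- if (isTRUE(all.equal(m1, m2)) || m1 == m2) 1 else 0
    attr(p, "degenerate") <- TRUE
    return(p)
  }
  stats::t.test(treated, baseline, var.equal = TRUE)$p.value
}

#' Per-readout positivity call
#'
#' Combines [stimulation_index()] and [two_tailed_unpaired_t()] and applies
#' the dual criterion: a readout is positive when SI strictly exceeds the
#' cutoff *and* p is strictly below alpha. Boundary values (SI exactly 2,
#' p exactly 0.05) are negative.
#'
#' @param treated,baseline Numeric vectors of well values.
#' @param thresholds An [assay_thresholds()] object.
#' @param baseline_floor Passed to [stimulation_index()].
#' @return One-row `data.frame`: `si, p_value, n_treated, n_baseline,
#'   positive`.
#' @export
readout_call <- function(treated, baseline, thresholds = assay_thresholds(),
                         baseline_floor = NULL) {
  si <- stimulation_index(treated, baseline, baseline_floor = baseline_floor)
  p <- two_tailed_unpaired_t(treated, baseline)
  data.frame(si = as.numeric(si), p_value = as.numeric(p),
             n_treated = length(treated), n_baseline = length(baseline),
             positive = as.numeric(si) > thresholds$si_cutoff &
                        as.numeric(p) < thresholds$alpha)
}

#' Donor-level responder classification for one compound
#'
#' A donor responds to a compound when at least one available readout
#' (day-6 proliferation, day-8 proliferation and/or IL-2 ELISpot) is
#' positive — the OR combination over readouts. Missing readouts are
#' tolerated so partial cohorts can be analysed.
#'
#' @param readout_summaries `data.frame` with a logical `positive` column,
#'   one row per available readout (1 to 3 rows).
#' @return Logical: is the donor a responder for this compound?
#' @export
classify_donor <- function(readout_summaries) {
  if (is.null(nrow(readout_summaries)) || nrow(readout_summaries) == 0)
    stop("at least one readout summary is required")
  any(readout_summaries$positive)
}

#' Classify every (donor, compound) pair in a cohort
#'
#' Runs the full per-readout and donor-level classification over a well
#' table: for each (donor, compound, readout) the treated wells are
#' compared against that donor's day-matched BASELINE wells of the same
#' readout, yielding SI, the Student t p-value and the dual-criterion
#' positivity; the donor-level responder flag is the OR over available
#' readouts and is repeated on each row.
#'
#' @param wells Well `data.frame` (see [read_wells()]).
#' @param thresholds An [assay_thresholds()] object.
#' @param baseline_floor Passed to [stimulation_index()].
#' @return `data.frame` with columns `donor_id, compound, readout, si,
#'   p_value, n_treated, n_baseline, positive, responder`.
#' @examples
#' sim <- simulate_cohort(cohort_preset("reference"))
#' calls <- classify_wells(sim$wells)
#' responder_frequency(calls, "natalizumab")
#' @export
classify_wells <- function(wells, thresholds = assay_thresholds(),
                           baseline_floor = NULL) {
  .check_wells(wells)
  treated <- wells[wells$compound != BASELINE, ]
  base <- wells[wells$compound == BASELINE, ]
  if (nrow(treated) == 0) stop("no treated wells in input")
  cells <- unique(treated[, c("donor_id", "compound", "readout")])
  cells <- cells[order(cells$donor_id, cells$compound, cells$readout), ]
  rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    d <- cells$donor_id[i]; cp <- cells$compound[i]; ro <- cells$readout[i]
    tv <- treated$value[treated$donor_id == d & treated$compound == cp &
                        treated$readout == ro]
    bv <- base$value[base$donor_id == d & base$readout == ro]
    if (!length(bv))
      stop("no BASELINE wells for donor ", d, ", readout ", ro)
    rc <- readout_call(tv, bv, thresholds, baseline_floor = baseline_floor)
    rows[[i]] <- cbind(data.frame(donor_id = d, compound = cp, readout = ro,
                                  stringsAsFactors = FALSE), rc)
  }
  calls <- do.call(rbind, rows)
  key <- paste(calls$donor_id, calls$compound, sep = "\r")
  resp <- tapply(calls$positive, key, any)
  calls$responder <- as.logical(resp[key])
  rownames(calls) <- NULL
  calls
}

#' Cohort responder frequency for one compound
#'
#' Percentage of donors classified as responders, reported to one decimal
#' place (e.g. 7 of 26 donors gives 26.9).
#'
#' @param calls Output of [classify_wells()] (or any `data.frame` with
#'   `donor_id`, `compound` and `responder` columns).
#' @param compound Compound name to summarise.
#' @return Percentage in `[0, 100]`, rounded to one decimal.
#' @export
responder_frequency <- function(calls, compound) {
  sub <- calls[calls$compound == compound, c("donor_id", "responder")]
  sub <- unique(sub)
  if (nrow(sub) == 0) stop("no calls for compound ", compound)
  round(100 * sum(sub$responder) / nrow(sub), 1)
}
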