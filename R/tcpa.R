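#' Fit the T cell:PBMC immunogenicity analysis to a cohort
#'
#' The front door of the package: takes a well-level assay table and runs
#' the complete analysis — per-readout stimulation indices and Student
#' t-tests, dual-criterion (SI > 2 and p < 0.05) positivity, donor-level
#' responder classification (OR over available readouts), Poisson
#' limiting-dilution precursor-frequency estimates from the pooled day-6
#' and day-8 proliferation wells, and cohort summaries. Optionally, an
#' HLA genotype table and a reference allele-frequency table add a
#' population-representativeness check of the cohort.
#'
#' @param wells Well `data.frame` (see [read_wells()]) or a path to a
#'   wells CSV.
#' @param thresholds An [assay_thresholds()] object.
#' @param hla Optional genotype table ([read_hla_table()]) or CSV path.
#' @param reference_freq Optional reference allele-frequency table
#'   ([read_allele_frequencies()]) or CSV path, compared against the
#'   cohort's `hla_locus` spectrum.
#' @param hla_locus Locus used for the population comparison. Default
#'   `"DRB1"`.
#' @param baseline_floor Passed to [stimulation_index()] and
#'   [score_wells()]; `NULL` means strict (error on non-positive
#'   baseline).
#' @return An object of class `"tcpa"` with components `calls`,
#'   `frequencies`, `report`, `validation`, `thresholds`, and (when
#'   supplied) `hla_frequencies` and `hla_comparison`.
#' @examples
#' sim <- simulate_cohort(cohort_preset("reference"))
#' fit <- tcpa(sim$wells)
#' coef(fit)
#' summary(fit)
#' @export
tcpa <- function(wells, thresholds = assay_thresholds(), hla = NULL,
                 reference_freq = NULL, hla_locus = "DRB1",
                 baseline_floor = NULL) {
  if (is.character(wells)) wells <- read_wells(wells)
  validation <- validate_cohort(wells)
  calls <- classify_wells(wells, thresholds, baseline_floor = baseline_floor)
  freqs <- estimate_frequencies(wells, thresholds,
                                baseline_floor = baseline_floor)
  fit <- list(calls = calls, frequencies = freqs, validation = validation,
              thresholds = thresholds, n_donors = length(unique(calls$donor_id)))
  if (!is.null(hla)) {
    if (is.character(hla)) hla <- read_hla_table(hla)
    fit$hla_frequencies <- hla_allele_frequencies(hla, hla_locus)
    if (!is.null(reference_freq)) {
      if (is.character(reference_freq))
        reference_freq <- read_allele_frequencies(reference_freq)
      fit$hla_comparison <- population_correlation(fit$hla_frequencies,
                                                   reference_freq)
    }
  }
  fit$report <- build_report(calls, freqs, fit$hla_comparison)
  class(fit) <- "tcpa"
  fit
}

#' @export
print.tcpa <- function(x, ...) {
  cat(sprintf("T cell:PBMC assay analysis: %d donors, %d compounds\n",
              x$n_donors, length(unique(x$calls$compound))))
  print(coef(x))
  invisible(x)
}

#' Per-compound responder percentages of a fitted analysis
#'
#' @param object A `"tcpa"` fit.
#' @param ... Unused.
#' @return Named numeric vector: percent responding donors per compound.
#' @export
coef.tcpa <- function(object, ...) {
  tab <- object$report$immunogenicity_plot_table
  stats::setNames(tab$pct_responders, tab$compound)
}

#' Summarise a fitted T cell:PBMC analysis
#'
#' @param object A `"tcpa"` fit.
#' @param ... Unused.
#' @return Object of class `"summary.tcpa"`: the per-compound table
#'   (percent responders, mean responder SI, precursor-frequency mean and
#'   SEM per 1e6 cells) plus validation and HLA headlines.
#' @export
summary.tcpa <- function(object, ...) {
  tab <- object$report$immunogenicity_plot_table
  freq <- lapply(tab$compound, function(cp) {
    e <- object$report$compounds[[cp]]
    c(mean = e$mean_freq_per_million %||% NA_real_,
      sem = e$sem_freq_per_million %||% NA_real_)
  })
  freq <- do.call(rbind, freq)
  out <- list(table = data.frame(tab,
                                 mean_freq_per_million = freq[, "mean"],
                                 sem_freq_per_million = freq[, "sem"]),
              n_flags = nrow(object$validation),
              hla = object$hla_comparison)
  class(out) <- "summary.tcpa"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.summary.tcpa <- function(x, ...) {
  cat("Cohort immunogenicity summary\n")
  tab <- x$table
  tab$mean_si_responders <- round(tab$mean_si_responders, 2)
  tab$mean_freq_per_million <- round(tab$mean_freq_per_million, 1)
  tab$sem_freq_per_million <- round(tab$sem_freq_per_million, 2)
  print.data.frame(tab, row.names = FALSE)
  cat(sprintf("validation flags: %d\n", x$n_flags))
  if (!is.null(x$hla)) print(x$hla)
  invisible(x)
}

#' Risk plot of a fitted analysis
#'
#' Percent responding donors against the mean stimulation index of the
#' responders' positive readouts, one point per compound; compounds in
#' the upper right have the higher immunogenicity potential.
#'
#' @param x A `"tcpa"` fit.
#' @param ... Passed to [graphics::plot()].
#' @return The plotted coordinate table, invisibly.
#' @export
plot.tcpa <- function(x, ...) {
  tab <- x$report$immunogenicity_plot_table
  keep <- !is.na(tab$mean_si_responders)
  graphics::plot(tab$pct_responders[keep], tab$mean_si_responders[keep],
                 log = "y", pch = 19,
                 xlab = "responding donors (%)",
                 ylab = "mean SI of responders (positive readouts)", ...)
  graphics::text(tab$pct_responders[keep], tab$mean_si_responders[keep],
                 labels = tab$compound[keep], pos = 3, cex = 0.8)
  invisible(tab)
}
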