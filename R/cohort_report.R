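#' Mean stimulation index per (compound, readout) over all donors
#'
#' The magnitude view of the cohort: arithmetic mean of SI across every
#' donor (responders and non-responders alike), one value per compound
#' and readout.
#'
#' @param calls Output of [classify_wells()].
#' @return `data.frame` with columns `compound, readout, mean_si, n`.
#' @export
magnitude_table <- function(calls) {
  key <- interaction(calls$compound, calls$readout, drop = TRUE, sep = "\r")
  agg <- tapply(calls$si, key, mean)
  n <- tapply(calls$si, key, length)
  parts <- do.call(rbind, strsplit(names(agg), "\r", fixed = TRUE))
  out <- data.frame(compound = parts[, 1], readout = parts[, 2],
                    mean_si = as.numeric(agg), n = as.integer(n),
                    stringsAsFactors = FALSE)
  out <- out[order(out$compound, out$readout), ]
  rownames(out) <- NULL
  out
}

#' Percent responders vs mean responder SI, per compound
#'
#' The coordinates of the risk plot: for each compound, the percentage of
#' responding donors (abscissa) against the mean SI computed over the
#' *positive* readouts of responding donors only (ordinate). Compounds
#' with no responders get `NA` for the ordinate.
#'
#' @param calls Output of [classify_wells()].
#' @return `data.frame` with columns `compound, pct_responders,
#'   mean_si_responders, n_responders, n_donors`.
#' @export
immunogenicity_plot_table <- function(calls) {
  compounds <- sort(unique(calls$compound))
  rows <- lapply(compounds, function(cp) {
    sub <- calls[calls$compound == cp, ]
    donors <- unique(sub[, c("donor_id", "responder")])
    pos <- sub[sub$responder & sub$positive, ]
    data.frame(compound = cp,
               pct_responders = responder_frequency(calls, cp),
               mean_si_responders = if (nrow(pos)) mean(pos$si) else NA_real_,
               n_responders = sum(donors$responder),
               n_donors = nrow(donors),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Allele frequencies of a cohort at one HLA locus
#'
#' Tabulates chromosome counts from a genotype table and converts them to
#' frequencies. A missing second allele is handled by convention:
#' `"HOMOZYGOUS"` (the default typing-report reading) duplicates the
#' reported allele (2 chromosomes); `"SINGLE"` counts it once (treating
#' the blank as a typing failure).
#'
#' @param genotypes Output of [read_hla_table()].
#' @param locus Locus to tabulate (e.g. `"DRB1"`).
#' @param convention `"HOMOZYGOUS"` or `"SINGLE"`.
#' @return `data.frame` with columns `allele, count, frequency`, carrying
#'   attributes `locus`, `convention` and `n_chromosomes`; frequencies sum
#'   to 1.
#' @examples
#' hla <- read_hla_table(system.file("extdata", "cohort_hla.csv",
#'                                   package = "tcellpbmc"))
#' hla_allele_frequencies(hla, "DRB1")
#' @export
hla_allele_frequencies <- function(genotypes, locus,
                                   convention = c("HOMOZYGOUS", "SINGLE")) {
  convention <- match.arg(convention)
  sub <- genotypes[genotypes$locus == locus, ]
  if (nrow(sub) == 0) stop("no genotypes at locus ", locus)
  a2 <- ifelse(is.na(sub$allele_2),
               if (convention == "HOMOZYGOUS") sub$allele_1 else NA_character_,
               sub$allele_2)
  alleles <- c(sub$allele_1, a2[!is.na(a2)])
  tab <- table(alleles)
  out <- data.frame(allele = names(tab), count = as.integer(tab),
                    frequency = as.numeric(tab) / sum(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(out$allele), ]
  rownames(out) <- NULL
  attr(out, "locus") <- locus
  attr(out, "convention") <- convention
  attr(out, "n_chromosomes") <- sum(tab)
  out
}

#' Read a reference allele-frequency table
#'
#' CSV with columns `allele, frequency` (and optionally `locus`); an
#' `OTHER` row may absorb the remainder so that frequencies sum to at
#' most 1.
#'
#' @param path CSV path.
#' @return `data.frame` with columns `allele, frequency`.
#' @export
read_allele_frequencies <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("allele", "frequency") %in% names(df)))
    stop("need columns allele, frequency")
  df$frequency <- as.numeric(df$frequency)
  if (any(!is.finite(df$frequency)) || any(df$frequency < 0) ||
      sum(df$frequency) > 1 + 1e-8)
    stop("frequencies must be in [0,1] and sum to <= 1")
  df
}

#' Pearson comparison of cohort vs reference allele frequencies
#'
#' Pairs the two frequency vectors over the union of alleles present in
#' either table (an allele absent from one table contributes frequency 0;
#' any `OTHER` remainder bucket is dropped) and computes the Pearson
#' correlation coefficient with its two-tailed p-value. With zero
#' variance in either vector the correlation is undefined and reported as
#' `NA` with a flag.
#'
#' @param cohort,reference `data.frame`s with columns `allele,
#'   frequency` (see [hla_allele_frequencies()],
#'   [read_allele_frequencies()]).
#' @return List of class `"hla_comparison"`: `alleles`, `cohort_freq`,
#'   `reference_freq`, `pearson_r`, `p_value`, `n_alleles` and optional
#'   `flag`.
#' @export
population_correlation <- function(cohort, reference) {
  drop_other <- function(x) x[x$allele != "OTHER", ]
  cohort <- drop_other(cohort); reference <- drop_other(reference)
  alleles <- sort(union(cohort$allele, reference$allele))
  if (length(alleles) < 3)
    stop("need at least 3 alleles in the union")
  cv <- stats::setNames(rep(0, length(alleles)), alleles)
  rv <- cv
  cv[cohort$allele] <- cohort$frequency
  rv[reference$allele] <- reference$frequency
  out <- list(alleles = alleles, cohort_freq = unname(cv),
              reference_freq = unname(rv), n_alleles = length(alleles))
  if (stats::sd(cv) == 0 || stats::sd(rv) == 0) {
    out$pearson_r <- NA_real_
    out$p_value <- NA_real_
    out$flag <- "zero variance in a frequency vector; r undefined"
  } else {
    ct <- stats::cor.test(cv, rv, method = "pearson")
    out$pearson_r <- unname(ct$estimate)
    out$p_value <- ct$p.value
  }
  structure(out, class = "hla_comparison")
}

#' @export
print.hla_comparison <- function(x, ...) {
  cat(sprintf("HLA allele-frequency comparison over %d alleles\n",
              x$n_alleles))
  if (is.na(x$pearson_r)) {
    cat("  Pearson r undefined:", x$flag, "\n")
  } else {
    cat(sprintf("  Pearson r = %.3f, two-tailed p = %.4g\n",
                x$pearson_r, x$p_value))
  }
  invisible(x)
}

#' Build a machine-readable cohort summary
#'
#' Assembles the cohort-level deliverable: per-compound summaries (percent
#' responders, mean SI per readout over all donors, mean SI of responders'
#' positive readouts, precursor-frequency mean and SEM), the plot-ready
#' magnitude and risk tables, and — when genotype comparisons are supplied
#' — an HLA section.
#'
#' @param calls Output of [classify_wells()].
#' @param frequencies Output of [estimate_frequencies()], or `NULL`.
#' @param hla_comparison Output of [population_correlation()], or `NULL`.
#' @return A nested list (serialisable with [write_report()]).
#' @export
build_report <- function(calls, frequencies = NULL, hla_comparison = NULL) {
  plot_tab <- immunogenicity_plot_table(calls)
  mag <- magnitude_table(calls)
  compounds <- plot_tab$compound
  per_compound <- lapply(compounds, function(cp) {
    row <- plot_tab[plot_tab$compound == cp, ]
    msi <- function(ro) {
      v <- mag$mean_si[mag$compound == cp & mag$readout == ro]
      if (length(v)) v else NA_real_
    }
    entry <- list(compound = cp,
                  pct_responders = row$pct_responders,
                  n_responders = row$n_responders,
                  n_donors = row$n_donors,
                  mean_si_prolif_d6 = msi("prolif_d6"),
                  mean_si_prolif_d8 = msi("prolif_d8"),
                  mean_si_elispot = msi("elispot"),
                  mean_si_responders = row$mean_si_responders)
    if (!is.null(frequencies)) {
      sub <- frequencies[frequencies$compound == cp, ]
      if (nrow(sub)) {
        cs <- cohort_frequency_summary(sub)
        entry$mean_freq_per_million <- cs$mean_per_million
        entry$sem_freq_per_million <- cs$sem_per_million
      }
    }
    entry
  })
  names(per_compound) <- compounds
  report <- list(compounds = per_compound,
                 magnitude_table = mag,
                 immunogenicity_plot_table = plot_tab)
  if (!is.null(hla_comparison))
    report$hla <- list(n_alleles = hla_comparison$n_alleles,
                       pearson_r = hla_comparison$pearson_r,
                       p_value = hla_comparison$p_value,
                       alleles = hla_comparison$alleles,
                       cohort_freq = hla_comparison$cohort_freq,
                       reference_freq = hla_comparison$reference_freq)
  report
}

#' Write a cohort summary to JSON
#'
#' @param report Output of [build_report()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows", na = "null")
  invisible(path)
}
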