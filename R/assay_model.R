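#' Readout kinds of the T cell:PBMC assay
#'
#' The assay measures each (donor, compound) pair through up to three
#' readouts: 3H-thymidine proliferation at day 6 and day 8 (values are
#' counts per minute, cpm) and IL-2 ELISpot (values are spots per well,
#' spw).
#'
#' @return Character vector of the three readout identifiers:
#'   `"prolif_d6"`, `"prolif_d8"`, `"elispot"`.
#' @export
readout_kinds <- function() c("prolif_d6", "prolif_d8", "elispot")

#' Reserved compound token for untreated baseline wells
#'
#' Untreated (medium only) wells are stored as ordinary rows whose
#' `compound` column equals this token, so a single table carries a full
#' cohort.
#'
#' @format Character scalar `"BASELINE"`.
#' @export
BASELINE <- "BASELINE"

#' Default cells seeded per well, by readout
#'
#' Proliferation wells receive 1e5 CD4+ T cells, ELISpot wells 5e5.
#'
#' @return Named numeric vector keyed by readout kind.
#' @export
default_cells_per_well <- function() {
  c(prolif_d6 = 1e5, prolif_d8 = 1e5, elispot = 5e5)
}

#' Default replicate counts per readout
#'
#' Sextuplicate proliferation wells at each of day 6 and day 8, and
#' triplicate ELISpot wells.
#'
#' @return Named integer vector keyed by readout kind.
#' @export
default_replicates <- function() {
  c(prolif_d6 = 6L, prolif_d8 = 6L, elispot = 3L)
}

#' Decision thresholds for responder calling and well scoring
#'
#' Bundles the tunable cutoffs of the analysis: a readout is positive when
#' the stimulation index strictly exceeds `si_cutoff` and the two-tailed
#' unpaired Student t-test p-value is strictly below `alpha`; individual
#' proliferation wells are scored positive for limiting-dilution counting
#' when they strictly exceed `well_score_multiplier` times the baseline
#' mean; and when every well scores positive the negative-well count is
#' replaced by `zero_negative_substitute` so the log formula stays finite.
#'
#' @param si_cutoff Stimulation-index cutoff (strict `>`). Default 2.
#' @param alpha Significance level (strict `<`). Default 0.05.
#' @param well_score_multiplier Multiple of the baseline mean a well must
#'   strictly exceed to score positive. Default 2.
#' @param zero_negative_substitute Value substituted for a raw negative-well
#'   count of zero. Default 0.1.
#' @return An object of class `"tcpa_thresholds"` (a named list).
#' @examples
#' assay_thresholds()
#' assay_thresholds(alpha = 0.01)
#' @export
assay_thresholds <- function(si_cutoff = 2, alpha = 0.05,
                             well_score_multiplier = 2,
                             zero_negative_substitute = 0.1) {
  vals <- c(si_cutoff = si_cutoff, alpha = alpha,
            well_score_multiplier = well_score_multiplier,
            zero_negative_substitute = zero_negative_substitute)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all thresholds must be strictly positive and finite")
  structure(as.list(vals), class = "tcpa_thresholds")
}

#' @export
print.tcpa_thresholds <- function(x, ...) {
  cat("T cell:PBMC assay thresholds\n")
  cat(sprintf("  positive readout: SI > %g and p < %g (strict)\n",
              x$si_cutoff, x$alpha))
  cat(sprintf("  well scored positive: value > %g x baseline mean\n",
              x$well_score_multiplier))
  cat(sprintf("  zero-negative substitute: %g\n", x$zero_negative_substitute))
  invisible(x)
}

.well_columns <- c("donor_id", "compound", "readout", "replicate",
                   "value", "cells_per_well")

#' Assemble a well table from vectors
#'
#' Convenience constructor used by the simulator and by tests; checks the
#' same invariants as [read_wells()].
#'
#' @param donor_id,compound,readout,replicate,value,cells_per_well Column
#'   vectors, recycled to a common length.
#' @return A `data.frame` with one row per well.
#' @export
assay_wells <- function(donor_id, compound, readout, replicate, value,
                        cells_per_well) {
  df <- data.frame(donor_id = as.character(donor_id),
                   compound = as.character(compound),
                   readout = as.character(readout),
                   replicate = as.integer(replicate),
                   value = as.numeric(value),
                   cells_per_well = as.numeric(cells_per_well),
                   stringsAsFactors = FALSE)
  .check_wells(df)
  df
}

.check_wells <- function(df) {
  missing <- setdiff(.well_columns, names(df))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  bad <- which(!df$readout %in% readout_kinds())
  if (length(bad))
    stop("unknown readout in row(s) ", paste(utils::head(bad, 5), collapse = ", "))
  bad <- which(!is.finite(df$value))
  if (length(bad))
    stop("non-numeric or non-finite value in row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  bad <- which(df$value < 0)
  if (length(bad))
    stop("negative value in row(s) ", paste(utils::head(bad, 5), collapse = ", "))
  bad <- which(!is.finite(df$cells_per_well) | df$cells_per_well <= 0)
  if (length(bad))
    stop("cells_per_well must be a positive integer; bad row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  bad <- which(!is.finite(df$replicate) | df$replicate < 1)
  if (length(bad))
    stop("replicate must be a positive integer; bad row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  key <- paste(df$donor_id, df$compound, df$readout, df$replicate, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup))
    stop("duplicate replicate index in row(s) ",
         paste(utils::head(dup, 5), collapse = ", "))
  invisible(df)
}

#' Read well-level assay data from CSV
#'
#' Expects a header with columns `donor_id, compound, readout, replicate,
#' value, cells_per_well`; one row per measured well. `value` is cpm for
#' proliferation readouts and spots/well for ELISpot; untreated wells carry
#' the compound token [BASELINE]. Any malformed row (missing column,
#' non-numeric or negative value, duplicate replicate index within a
#' (donor, compound, readout)) is a hard error naming the row.
#'
#' @param path Path to a CSV file.
#' @return A `data.frame` of wells.
#' @seealso [write_wells()], [validate_cohort()]
#' @export
read_wells <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  missing <- setdiff(.well_columns, names(df))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  df <- df[, .well_columns]
  num <- function(col) {
    x <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(x) & nzchar(df[[col]]))
    if (length(bad))
      stop("non-numeric ", col, " in row(s) ",
           paste(utils::head(bad, 5), collapse = ", "))
    x
  }
  out <- data.frame(donor_id = df$donor_id,
                    compound = df$compound,
                    readout = df$readout,
                    replicate = as.integer(num("replicate")),
                    value = num("value"),
                    cells_per_well = num("cells_per_well"),
                    stringsAsFactors = FALSE)
  .check_wells(out)
  out
}

#' Write well-level assay data to CSV
#'
#' Inverse of [read_wells()]: `read_wells(write_wells(x, f))` reproduces
#' `x` up to floating-point formatting.
#'
#' @param wells A well `data.frame`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_wells <- function(wells, path) {
  .check_wells(wells)
  utils::write.csv(wells[, .well_columns], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Validate a cohort of wells against the assay design
#'
#' Report-only check of the structural expectations: every (donor,
#' compound, readout) cell is compared against the design replicate counts
#' (by default 6/6/3), every treated (donor, readout) must have matching
#' BASELINE wells, `cells_per_well` must be constant within (donor,
#' readout), and in strict mode ELISpot values must be whole spot counts.
#'
#' @param wells A well `data.frame`.
#' @param design Expected replicate count per readout; default
#'   [default_replicates()].
#' @param strict If `TRUE`, any flag raised becomes an error and ELISpot
#'   values are additionally required to be integers.
#' @return An object of class `"tcpa_validation"`: a `data.frame` of flags
#'   with columns `donor_id, compound, readout, issue` (zero rows when the
#'   cohort matches the design).
#' @examples
#' cfg <- cohort_preset("null", n_donors = 2)
#' sim <- simulate_cohort(cfg)
#' validate_cohort(sim$wells)
#' @export
validate_cohort <- function(wells, design = default_replicates(),
                            strict = FALSE) {
  .check_wells(wells)
  flags <- list()
  add <- function(donor, compound, readout, issue) {
    flags[[length(flags) + 1L]] <<- data.frame(
      donor_id = donor, compound = compound, readout = readout,
      issue = issue, stringsAsFactors = FALSE)
  }

  cell <- interaction(wells$donor_id, wells$compound, wells$readout,
                      drop = TRUE, sep = "\r")
  for (k in levels(cell)) {
    rows <- wells[cell == k, ]
    d <- rows$donor_id[1]; cp <- rows$compound[1]; ro <- rows$readout[1]
    expect <- design[[ro]]
    if (!is.null(expect) && nrow(rows) != expect)
      add(d, cp, ro, sprintf("expected %d replicates, found %d",
                             expect, nrow(rows)))
    if (strict && ro == "elispot" &&
        any(abs(rows$value - round(rows$value)) > 1e-8))
      add(d, cp, ro, "non-integer ELISpot spot count")
  }

  dr <- unique(wells[, c("donor_id", "readout")])
  for (i in seq_len(nrow(dr))) {
    sel <- wells$donor_id == dr$donor_id[i] & wells$readout == dr$readout[i]
    rows <- wells[sel, ]
    if (any(rows$compound != BASELINE) && !any(rows$compound == BASELINE))
      add(dr$donor_id[i], BASELINE, dr$readout[i], "missing BASELINE wells")
    if (length(unique(rows$cells_per_well)) > 1L)
      add(dr$donor_id[i], "*", dr$readout[i],
          "cells_per_well not constant within (donor, readout)")
  }

  flags <- if (length(flags)) do.call(rbind, flags) else
    data.frame(donor_id = character(), compound = character(),
               readout = character(), issue = character(),
               stringsAsFactors = FALSE)
  flags <- flags[order(flags$donor_id, flags$compound, flags$readout), ,
                 drop = FALSE]
  rownames(flags) <- NULL
  if (strict && nrow(flags))
    stop("cohort validation failed: ", nrow(flags), " flag(s); first: ",
         flags$issue[1])
  structure(flags, class = c("tcpa_validation", "data.frame"))
}

#' @export
print.tcpa_validation <- function(x, ...) {
  if (nrow(x) == 0) {
    cat("Cohort validation: no flags\n")
  } else {
    cat("Cohort validation:", nrow(x), "flag(s)\n")
    print.data.frame(x, ...)
  }
  invisible(x)
}

.allele_pattern <- "^\\*\\d{2}:\\d{2}$"

#' Read an HLA genotype table
#'
#' Parses a CSV in typing-report layout: a `Donor` column followed by
#' paired allele columns per locus named `<LOCUS>-1`, `<LOCUS>-2` (e.g.
#' `DRB1-1`, `DRB1-2`). Alleles are 4-digit strings such as `*15:01`; a
#' `-` entry denotes an absent/unreported second allele and is returned as
#' `NA`.
#'
#' @param path Path to the CSV file.
#' @return A `data.frame` with one row per (donor, locus) that has at
#'   least one typed allele: columns `donor_id, locus, allele_1, allele_2`
#'   (`allele_2` is `NA` when unreported).
#' @examples
#' hla <- read_hla_table(system.file("extdata", "cohort_hla.csv",
#'                                   package = "tcellpbmc"))
#' head(hla)
#' @export
read_hla_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                         colClasses = "character")
  empty <- data.frame(donor_id = character(), locus = character(),
                      allele_1 = character(), allele_2 = character(),
                      stringsAsFactors = FALSE)
  if (nrow(raw) == 0) return(empty)
  donor_col <- grep("^donor", names(raw), ignore.case = TRUE, value = TRUE)[1]
  if (is.na(donor_col)) stop("no Donor column found")
  pair_cols <- grep("-[12]$", names(raw), value = TRUE)
  loci <- unique(sub("-[12]$", "", pair_cols))
  out <- empty
  clean <- function(x) {
    x <- trimws(x)
    x[x %in% c("", "-")] <- NA_character_
    x
  }
  for (locus in loci) {
    a1 <- clean(raw[[paste0(locus, "-1")]])
    a2 <- if (paste0(locus, "-2") %in% names(raw))
      clean(raw[[paste0(locus, "-2")]]) else rep(NA_character_, nrow(raw))
    keep <- !is.na(a1) | !is.na(a2)
    # a lone second allele is promoted so allele_1 is always present
    swap <- is.na(a1) & !is.na(a2)
    a1[swap] <- a2[swap]; a2[swap] <- NA_character_
    vals <- c(a1[keep], a2[keep])
    bad <- vals[!is.na(vals) & !grepl(.allele_pattern, vals)]
    if (length(bad))
      stop("malformed allele string(s) at locus ", locus, ": ",
           paste(unique(bad), collapse = ", "))
    out <- rbind(out, data.frame(donor_id = raw[[donor_col]][keep],
                                 locus = locus,
                                 allele_1 = a1[keep], allele_2 = a2[keep],
                                 stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}
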