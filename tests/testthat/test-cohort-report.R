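make_calls <- function(donors, compound, si, positive,
                       readout = "prolif_d6") {
  df <- data.frame(donor_id = donors, compound = compound, readout = readout,
                   si = si, p_value = 0.5, n_treated = 6L, n_baseline = 6L,
                   positive = positive, stringsAsFactors = FALSE)
  key <- paste(df$donor_id, df$compound)
  resp <- tapply(df$positive, key, any)
  df$responder <- as.logical(resp[key])
  df
}

test_that("magnitude table averages SI over all donors", {
  calls <- make_calls(sprintf("D%02d", 1:4), "x", si = 1, positive = FALSE)
  mt <- magnitude_table(calls)
  expect_equal(mt$mean_si, 1.0)
  expect_identical(mt$n, 4L)

  calls2 <- make_calls(sprintf("D%02d", 1:4), "y", si = c(1, 2, 3, 6),
                       positive = FALSE)
  expect_equal(magnitude_table(calls2)$mean_si, 3.0)
})

test_that("null-simulation magnitudes sit near SI = 1", {
  sim <- simulate_cohort(cohort_preset("null", seed = 19))
  mt <- magnitude_table(classify_wells(sim$wells))
  prolif <- mt[mt$readout != "elispot", ]
  expect_true(all(abs(prolif$mean_si - 1) < 0.1))
  expect_true(all(abs(mt$mean_si - 1) < 0.35))  # ELISpot is noisier (n = 3)
})

test_that("calibrated cohort puts the control antigens above the antibodies", {
  sim <- simulate_cohort(cohort_preset("reference"))
  mt <- magnitude_table(classify_wells(sim$wells))
  for (ro in readout_kinds()) {
    sub <- mt[mt$readout == ro, ]
    ctrl <- min(sub$mean_si[sub$compound %in% c("KLH", "CMV")])
    bp <- max(sub$mean_si[!sub$compound %in% c("KLH", "CMV")])
    expect_gt(ctrl, bp)
  }
})

test_that("risk-plot coordinates use responders' positive readouts only", {
  donors <- sprintf("D%02d", 1:4)
  none <- make_calls(donors, "x", si = 3, positive = FALSE)
  tab <- immunogenicity_plot_table(none)
  expect_equal(tab$pct_responders, 0.0)
  expect_true(is.na(tab$mean_si_responders))

  one <- make_calls(donors, "x", si = c(4, 1, 1, 1),
                    positive = c(TRUE, FALSE, FALSE, FALSE))
  tab <- immunogenicity_plot_table(one)
  expect_equal(tab$pct_responders, 25.0)
  expect_equal(tab$mean_si_responders, 4.0)

  # a responder's negative readout must not enter the ordinate
  two_ro <- rbind(make_calls(donors, "x", si = c(4, 1, 1, 1),
                             positive = c(TRUE, FALSE, FALSE, FALSE)),
                  make_calls(donors, "x", si = c(10, 1, 1, 1),
                             positive = FALSE, readout = "elispot"))
  key <- paste(two_ro$donor_id, two_ro$compound)
  two_ro$responder <- as.logical(tapply(two_ro$positive, key, any)[key])
  expect_equal(immunogenicity_plot_table(two_ro)$mean_si_responders, 4.0)
})

test_that("calibrated cohort orders compounds as published", {
  sim <- simulate_cohort(cohort_preset("reference"))
  tab <- immunogenicity_plot_table(classify_wells(sim$wells))
  pct <- setNames(tab$pct_responders, tab$compound)
  expect_true(pct["natalizumab"] > pct["rituximab"] &&
              pct["rituximab"] > pct["adalimumab"] &&
              pct["adalimumab"] > pct["infliximab"])
  expect_equal(unname(pct[c("natalizumab", "rituximab", "adalimumab",
                            "infliximab")]), c(26.9, 19.2, 7.7, 3.8))
})

test_that("DRB1 allele frequencies match the hand-tallied cohort counts", {
  hla <- read_hla_table(fixture_path("cohort_hla.csv"))
  tab <- hla_allele_frequencies(hla, "DRB1", convention = "HOMOZYGOUS")
  # hand tally of the 26-donor genotype table, lone allele doubled
  counts <- c("*01:01" = 5L, "*01:02" = 1L, "*03:01" = 5L, "*04:01" = 4L,
              "*04:04" = 7L, "*04:07" = 1L, "*07:01" = 6L, "*10:01" = 1L,
              "*11:01" = 2L, "*12:01" = 1L, "*13:01" = 3L, "*13:02" = 5L,
              "*14:01" = 3L, "*15:01" = 8L)
  expect_identical(setNames(tab$count, tab$allele), counts)
  expect_identical(attr(tab, "n_chromosomes"), 52L)
  expect_equal(sum(tab$frequency), 1)
  expect_equal(tab$frequency[tab$allele == "*15:01"], 8 / 52)

  single <- hla_allele_frequencies(hla, "DRB1", convention = "SINGLE")
  expect_identical(single$count[single$allele == "*15:01"], 7L)
  expect_identical(attr(single, "n_chromosomes"), 51L)
})

test_that("homozygote convention on a toy table", {
  g <- data.frame(donor_id = c("a", "b"), locus = "DRB1",
                  allele_1 = "*01:01", allele_2 = c("*02:01", NA),
                  stringsAsFactors = FALSE)
  h <- hla_allele_frequencies(g, "DRB1", "HOMOZYGOUS")
  expect_equal(setNames(h$frequency, h$allele),
               c("*01:01" = 0.75, "*02:01" = 0.25))
  s <- hla_allele_frequencies(g, "DRB1", "SINGLE")
  expect_equal(setNames(s$frequency, s$allele),
               c("*01:01" = 2 / 3, "*02:01" = 1 / 3))

  both <- data.frame(donor_id = c("a", "b"), locus = "DRB1",
                     allele_1 = "*01:01", allele_2 = "*02:01",
                     stringsAsFactors = FALSE)
  b <- hla_allele_frequencies(both, "DRB1")
  expect_equal(setNames(b$frequency, b$allele),
               c("*01:01" = 0.5, "*02:01" = 0.5))
})

test_that("population correlation matches the frozen Pearson oracle", {
  cohort <- data.frame(allele = c("A", "B"), frequency = c(0.5, 0.5))
  ref <- data.frame(allele = c("A", "B", "C"), frequency = c(0.1, 0.9, 0.0))
  cmp <- population_correlation(cohort, ref)
  # frozen reference values computed with scipy.stats.pearsonr on the
  # union-aligned vectors (0.5, 0.5, 0) vs (0.1, 0.9, 0)
  expect_equal(cmp$pearson_r, 0.5852057359806528, tolerance = 1e-12)
  expect_equal(cmp$p_value, 0.6020274928395157, tolerance = 1e-9)
  expect_identical(cmp$n_alleles, 3L)

  ident <- population_correlation(ref, ref)
  expect_equal(ident$pearson_r, 1)
})

test_that("Pearson comparison is symmetric, scale- and label-invariant", {
  set.seed(4)
  a <- data.frame(allele = sprintf("*%02d:01", 1:8),
                  frequency = as.numeric(prop.table(runif(8))))
  b <- data.frame(allele = sprintf("*%02d:01", 3:10),
                  frequency = as.numeric(prop.table(runif(8))))
  r_ab <- population_correlation(a, b)$pearson_r
  expect_equal(population_correlation(b, a)$pearson_r, r_ab)

  a2 <- a; b2 <- b
  a2$frequency <- a2$frequency * 0.4
  b2$frequency <- b2$frequency * 0.4
  expect_equal(population_correlation(a2, b2)$pearson_r, r_ab)

  perm <- setNames(sprintf("Z%02d", seq_len(10)),
                   sprintf("*%02d:01", 1:10))
  a3 <- a; a3$allele <- unname(perm[a3$allele])
  b3 <- b; b3$allele <- unname(perm[b3$allele])
  expect_equal(population_correlation(a3, b3)$pearson_r, r_ab)
})

test_that("degenerate frequency vectors are flagged, not crashed", {
  flat <- data.frame(allele = c("A", "B", "C"), frequency = c(1, 1, 1) / 3)
  other <- data.frame(allele = c("A", "B", "C"),
                      frequency = c(0.2, 0.3, 0.5))
  cmp <- population_correlation(flat, other)
  expect_true(is.na(cmp$pearson_r))
  expect_match(cmp$flag, "zero variance")
  expect_error(population_correlation(
    data.frame(allele = c("A", "B"), frequency = c(0.5, 0.5)),
    data.frame(allele = c("A", "B"), frequency = c(0.4, 0.6))),
    "at least 3")
})

test_that("the report is a single source of truth and omits absent sections", {
  sim <- simulate_cohort(cohort_preset("reference", n_donors = 6))
  calls <- classify_wells(sim$wells)
  freqs <- estimate_frequencies(sim$wells)
  rep1 <- build_report(calls, freqs)
  rep2 <- build_report(calls, freqs)
  expect_identical(rep1, rep2)
  expect_null(rep1$hla)

  for (cp in names(rep1$compounds))
    expect_identical(rep1$compounds[[cp]]$pct_responders,
                     responder_frequency(calls, cp))

  hla <- read_hla_table(fixture_path("cohort_hla.csv"))
  cmp <- population_correlation(
    hla_allele_frequencies(hla, "DRB1"),
    read_allele_frequencies(fixture_path("reference_allele_freq_synthetic.csv")))
  rep3 <- build_report(calls, freqs, cmp)
  expect_identical(rep3$hla$pearson_r, cmp$pearson_r)

  f <- withr::local_tempfile(fileext = ".json")
  write_report(rep3, f)
  parsed <- jsonlite::read_json(f)
  expect_identical(names(parsed$compounds), names(rep1$compounds))
  expect_equal(parsed$hla$pearson_r, cmp$pearson_r, tolerance = 1e-12)
})

test_that("adding a non-responding donor can only lower responder percentages", {
  donors <- sprintf("D%02d", 1:5)
  calls <- make_calls(donors, "x", si = c(4, 4, 1, 1, 1),
                      positive = c(TRUE, TRUE, FALSE, FALSE, FALSE))
  before <- responder_frequency(calls, "x")
  extra <- make_calls("D99", "x", si = 1, positive = FALSE)
  after <- responder_frequency(rbind(calls, extra), "x")
  expect_lt(after, before)
  expect_equal(immunogenicity_plot_table(rbind(calls, extra))$mean_si_responders,
               immunogenicity_plot_table(calls)$mean_si_responders)
})
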