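# Builders for small in-memory well tables used across the suite.

make_wells <- function(donor = "D01", compound = "KLH", readout = "prolif_d6",
                       values, cells = 1e5) {
  assay_wells(donor_id = donor, compound = compound, readout = readout,
              replicate = seq_along(values), value = values,
              cells_per_well = cells)
}

# one donor, one compound + BASELINE, full 6/6/3 design with chosen
# per-readout treated/baseline values (recycled across replicates)
make_donor_design <- function(donor = "D01", compound = "KLH",
                              treated = c(prolif_d6 = 3000, prolif_d8 = 3000,
                                          elispot = 30),
                              baseline = c(prolif_d6 = 1000, prolif_d8 = 1000,
                                           elispot = 5)) {
  reps <- default_replicates()
  cells <- default_cells_per_well()
  out <- list()
  for (ro in readout_kinds()) {
    out[[length(out) + 1L]] <- make_wells(donor, BASELINE, ro,
                                          rep_len(baseline[[ro]], reps[[ro]]),
                                          cells[[ro]])
    out[[length(out) + 1L]] <- make_wells(donor, compound, ro,
                                          rep_len(treated[[ro]], reps[[ro]]),
                                          cells[[ro]])
  }
  do.call(rbind, out)
}

fixture_path <- function(name) {
  system.file("extdata", name, package = "tcellpbmc", mustWork = TRUE)
}
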