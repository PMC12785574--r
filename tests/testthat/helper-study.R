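# Shared fixtures: a three-ion toy panel and small study designs so tests
# stay fast. All data are generated in code; nothing is read from disk
# except the bundled reference panel.

tinyPanel <- function() {
  data.frame(
    mz = c(100.1, 300.5, 500.25),
    annotation = c("toy A", "toy B", "toy C"),
    ion_class = c("amino_acid", "lipid", "lipid"),
    mean_LEAN = c(2e-3, 1e-3, 5e-4),
    mean_P1 = c(3e-3, 5e-4, 6e-4),
    mean_P2 = c(2.5e-3, 8e-4, 5.5e-4),
    stringsAsFactors = FALSE)
}

smallDesign <- function(px = 16L, seed = 1L, ...) {
  StudyDesign(imageWidthPx = px, imageHeightPx = px, seed = seed, ...)
}

# peak table built directly from a matrix of intensities
makePeakTable <- function(values, ions = tinyPanel(),
                          groups = rep(c("LEAN", "P1", "P2"),
                                       each = ncol(values) / 3)) {
  samples <- data.frame(
    sample_id = paste0("s", seq_len(ncol(values))),
    group = groups,
    animal = paste0("s", seq_len(ncol(values))),
    replicate = 1L, stringsAsFactors = FALSE)
  PeakTable(values, ions, samples)
}
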