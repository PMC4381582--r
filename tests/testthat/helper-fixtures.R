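# Small in-code fixtures shared across test files.

# One 96-well plate per line: nGenes x 3 siRNAs of sample wells plus controls.
tinyScreen <- function(nGenes = 20, seed = 11, ...) {
  simulateScreen(screenSimConfig(nGenes = nGenes, nPlanted = min(2, nGenes),
                                 ...), seed = seed)
}

# Hand-built single-plate well table (8 sample + 3 neg controls).
handPlate <- function(readings = c(0.5, 1, 1, 1, 1, 1.5, 0.9, 1.1),
                      neg = c(0.8, 1.0, 1.2), plate = "P1", line = "L1") {
  n <- length(readings)
  samp <- data.frame(plate_id = plate, row = "A", col = seq_len(n),
                     cell_line = line,
                     sirna_id = paste0("G", seq_len(n), "_si1"),
                     gene = paste0("G", seq_len(n)),
                     role = "sample", reading = readings,
                     stringsAsFactors = FALSE)
  ctrl <- data.frame(plate_id = plate, row = "B", col = seq_along(neg),
                     cell_line = line, sirna_id = "", gene = "",
                     role = "neg_control", reading = neg,
                     stringsAsFactors = FALSE)
  newScreenDataset(rbind(samp, ctrl))
}
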