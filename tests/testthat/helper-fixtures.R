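# Small fixtures built in code; no files on disk.

# A 4x4 toy annotation: organoid occupies all 16 pixels (NC), with a 2x2
# VZLS (id 2) in rows 1:2, cols 1:2 (0-based rows/cols 0:1 x 0:1).
# Apical contour along the left edge of the VZLS, basal along its right.
toy_annotation <- function(pixel_size_um = 1) {
  lab <- matrix(1L, 4, 4)
  lab[1:2, 1:2] <- 2L
  boundaries <- rbind(
    data.frame(vzls_id = 0L, boundary = "outer",
               x_px = c(0, 3, 3, 0), y_px = c(0, 0, 3, 3)),
    data.frame(vzls_id = 2L, boundary = "apical",
               x_px = c(0, 0), y_px = c(0, 1)),
    data.frame(vzls_id = 2L, boundary = "basal",
               x_px = c(1, 1), y_px = c(0, 1)))
  section_annotation(lab, boundaries, pixel_size_um)
}

# Straight-walled (band) section: rho should grow linearly down the band.
band_section <- function(seed = 1, height = 128L, width = 96L, ...) {
  gen_section(section_truth(n_vzls = 1, shape = "band", seed = seed,
                            width = width, height = height,
                            pixel_size_um = 1, ...))
}

# Shared pathway layout for bulk simulations: 5 disjoint 40-gene pathways
# in a 2000-gene transcriptome.
bulk_pathways <- function(n_pathways = 5L, size = 40L) {
  setNames(lapply(seq_len(n_pathways) - 1L, function(i)
    paste0("gene_", (i * size + 1):((i + 1) * size))),
    paste0("P", seq_len(n_pathways)))
}

lnfc_matrix <- function(pathways,
                        groups = c("ctrl", "mock", "comp50", "comp60")) {
  matrix(0, length(pathways), length(groups),
         dimnames = list(names(pathways), groups))
}

# Run the full per-organoid section intensity workflow used by the
# fold-change simulations: one organoid = one section, VZLS-scope mean.
organoid_mean_intensity <- function(truth, condition) {
  sec <- gen_section(truth, condition, compute_distances = FALSE)
  tab <- annotate_pixels(sec$annotation, sec$intensity)
  intensity_summary(tab, scope = "VZLS")
}
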