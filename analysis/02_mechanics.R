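#!/usr/bin/env Rscript
# Rheometer compression analysis: segment each recording into its three
# loading/unloading cycles, compute per-cycle peak forces, the mean maximum
# peak force and the nominal stress per organoid, then test whether the
# viscoelastic peak decay is consistent across organoids (cycle-to-cycle
# correlations) and whether peak force predicts the SOX2-like intensity.

suppressPackageStartupMessages(library(mechanoquant))
out <- "results"
syn <- file.path(out, "synthetic")
stopifnot(dir.exists(file.path(syn, "traces")))

truth <- read.delim(file.path(syn, "trace_truth.tsv"))
summaries <- list()
peaks <- list()
for (i in seq_len(nrow(truth))) {
  tr <- read_force_trace(file.path(syn, "traces",
                                   sprintf("trace_%s.csv",
                                           truth$organoid_id[i])),
                         organoid_id = truth$organoid_id[i])
  s <- summarize_compression(tr, n_cycles = 3, diameter_mm = 3,
                             compression_level = truth$level[i])
  summaries[[i]] <- s
  peaks[[i]] <- attr(s, "cycles")$peak_force_N
}
summaries <- do.call(rbind, summaries)
write.table(summaries, file.path(out, "compression_summaries.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)

cat(sprintf("mean maximum peak forces span %.1f-%.1f mN -> nominal stress %d-%d Pa\n",
            min(summaries$mean_max_peak_N) * 1e3,
            max(summaries$mean_max_peak_N) * 1e3,
            min(nominal_stress_pa(summaries$mean_max_peak_N, 3)),
            max(nominal_stress_pa(summaries$mean_max_peak_N, 3))))

## Cycle-to-cycle peak correlations: decay factors are shared across
## organoids, so peaks should correlate near-perfectly between cycles.
pk <- do.call(rbind, peaks)
cc <- cycle_peak_correlation(pk)
write.table(round(cc$r, 4), file.path(out, "cycle_peak_correlation.tsv"),
            sep = "\t", quote = FALSE)
cat("off-diagonal cycle correlations:",
    paste(round(cc$r[upper.tri(cc$r)], 3), collapse = ", "), "\n")

## Force-intensity regression: per-organoid VZLS mean intensity from the
## matching compressed sections against the mean maximum peak force.
manifest <- read.delim(file.path(syn, "section_manifest.tsv"))
compressed <- manifest[manifest$condition %in% c("comp40", "comp50", "comp60"), ]
shared <- intersect(compressed$organoid_id, summaries$organoid_id)
intens <- vapply(shared, function(oid) {
  cond <- compressed$condition[compressed$organoid_id == oid]
  ann <- read_section_annotation(
    file.path(syn, sprintf("section_%s_labels.tif", oid)),
    file.path(syn, sprintf("section_%s_boundaries.csv", oid)),
    pixel_size_um = 2)
  img <- read_intensity_image(file.path(syn,
                                        sprintf("section_%s_intensity.tif",
                                                oid)))
  intensity_summary(annotate_pixels(ann, img), scope = "VZLS")
}, numeric(1))
force <- summaries$mean_max_peak_N[match(shared, summaries$organoid_id)]
reg <- force_intensity_regression(force, intens)
cat(sprintf("force-intensity regression: slope %.1f, r^2 %.3f, p %.2g\n",
            reg$slope, reg$r_squared, reg$p))
write.table(data.frame(slope = reg$slope, intercept = reg$intercept,
                       r_squared = reg$r_squared, p = reg$p),
            file.path(out, "force_intensity_regression.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)
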