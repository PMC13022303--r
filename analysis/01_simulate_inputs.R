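#!/usr/bin/env Rscript
# Generate every synthetic input the downstream analyses consume, with
# recorded ground truth: organoid sections across five compression
# conditions, rheometer traces per organoid, a bulk RNA-seq count matrix
# with planted pathway effects, and a single-cell dataset with planted
# QC violators and a cluster-specific regulon shift.

suppressPackageStartupMessages(library(mechanoquant))
seed <- 20260930L
out <- "results/synthetic"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

conditions <- c(ctrl = 1, mock = 1, comp40 = 1.2, comp50 = 1.35, comp60 = 1.5)
# compression also expands the SOX2-positive area fraction
pos_frac <- c(ctrl = 0.30, mock = 0.30, comp40 = 0.35, comp50 = 0.40,
              comp60 = 0.45)
n_per_group <- 7L

## Sections: one per organoid, 7 organoids per condition. The ctrl/mock
## multipliers are 1 (uncompressed); compressed conditions carry graded
## SOX2-like intensity fold changes.
manifest <- list()
i <- 0L
for (cond in names(conditions)) {
  for (rep in seq_len(n_per_group)) {
    i <- i + 1L
    fc <- c(uncompressed = 1)
    if (!cond %in% c("ctrl", "mock")) fc[cond] <- conditions[[cond]]
    st <- section_truth(n_vzls = 2, seed = seed + i, fc_per_condition = fc,
                        positive_fraction = pos_frac[[cond]],
                        noise_sd = 50, width = 128, height = 128)
    use_cond <- if (cond %in% c("ctrl", "mock")) "uncompressed" else cond
    sec <- gen_section(st, use_cond)
    paths <- write_section(sec, out, sprintf("section_%s_%02d", cond, rep))
    manifest[[i]] <- data.frame(organoid_id = sprintf("%s_%02d", cond, rep),
                                condition = cond, seed = seed + i)
  }
}
write.table(do.call(rbind, manifest), file.path(out, "section_manifest.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)
cat("sections:", i, "written\n")

## Rheometer traces: compressed organoids only, with per-organoid peak
## forces spanning the 2-14 mN range and viscoelastic decay across cycles.
trace_dir <- file.path(out, "traces")
dir.create(trace_dir, showWarnings = FALSE)
levels <- c(comp40 = 0.4, comp50 = 0.5, comp60 = 0.6)
trace_truths <- list()
j <- 0L
for (cond in names(levels)) {
  for (rep in seq_len(n_per_group)) {
    j <- j + 1L
    # deeper compression produces larger peak forces (2-14 mN overall)
    rng <- switch(cond, comp40 = c(2e-3, 6e-3), comp50 = c(5e-3, 9e-3),
                  comp60 = c(9e-3, 14e-3))
    p1 <- withr::with_seed(seed + 500L + j, runif(1, rng[1], rng[2]))
    tt <- trace_truth(peak_forces_N = p1 * c(1, 0.8, 0.7),
                      compression_level = levels[[cond]],
                      noise_sd_N = 1e-4, seed = seed + 500L + j)
    tr <- gen_force_trace(tt, organoid_id = sprintf("%s_%02d", cond, rep))
    write_force_trace(tr, file.path(trace_dir,
                                    sprintf("trace_%s_%02d.csv", cond, rep)))
    trace_truths[[j]] <- data.frame(
      organoid_id = sprintf("%s_%02d", cond, rep), condition = cond,
      level = levels[[cond]], peak1_N = p1)
  }
}
write.table(do.call(rbind, trace_truths),
            file.path(out, "trace_truth.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)
cat("traces:", j, "written\n")

## Bulk counts: 5 disjoint 40-gene pathways; P1 responds in both compressed
## groups, P2 only at 60%, the rest are null.
pw <- setNames(lapply(0:5, function(k)
  paste0("gene_", (k * 40 + 1):((k + 1) * 40))), paste0("P", 1:6))
lnfc <- matrix(0, 6, 4, dimnames = list(names(pw),
                                        c("ctrl", "mock", "comp50", "comp60")))
lnfc["P1", c("comp50", "comp60")] <- c(0.4, 0.7)
lnfc["P2", "comp60"] <- -0.5
# P6 responds strongly enough to clear the |log2FC| > 2 DE gate
lnfc["P6", c("comp50", "comp60")] <- c(1.6, 1.8)
bt <- bulk_truth(n_genes = 2000, n_samples_per_group = 6, pathways = pw,
                 pathway_lnfc = lnfc, seed = seed + 900L)
b <- gen_bulk_counts(bt)
write_bulk_counts(b$counts, b$design, file.path(out, "bulk_counts.tsv"),
                  file.path(out, "bulk_design.tsv"))
write_gmt(pw, file.path(out, "pathways.gmt"))
write.table(data.frame(pathway = rep(rownames(lnfc), ncol(lnfc)),
                       group = rep(colnames(lnfc), each = nrow(lnfc)),
                       lnfc = as.vector(lnfc)),
            file.path(out, "bulk_truth_lnfc.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)
cat("bulk counts:", nrow(b$counts), "genes x", ncol(b$counts), "samples\n")

## Single cell: mock vs comp50, 4 clusters, SOX2-like regulon activated in
## cluster 2 under compression, planted QC violators, and a pseudotime
## trend on a second gene set.
gs <- list(SOX2_targets = paste0("gene_", 1:30),
           ATP_synthesis = paste0("gene_", 31:50))
baseline <- expand.grid(set = "SOX2_targets", cluster = 1:4,
                        condition = c("mock", "comp50"))
baseline$delta <- 0.8
extra <- data.frame(set = "SOX2_targets", cluster = 2, condition = "comp50",
                    delta = 0.5)
sct <- sc_truth(n_cells = 2000, n_genes = 500, n_clusters = 4,
                gene_sets = gs, set_shift = rbind(baseline, extra),
                pseudotime_slope = c(ATP_synthesis = -0.8),
                qc_violation_counts = list(n_genes = 5, counts_low = 4,
                                           counts_high = 3, mito = 6,
                                           gene_floor = 4),
                seed = seed + 1000L)
scd <- gen_sc_matrix(sct)
write_sc_matrix(scd$expr, scd$meta, out)
write_gmt(gs, file.path(out, "gene_sets.gmt"))
writeLines(unlist(scd$violators), file.path(out, "sc_planted_violators.txt"))
cat("single cell:", nrow(scd$expr), "genes x", ncol(scd$expr), "cells\n")
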