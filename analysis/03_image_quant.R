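#!/usr/bin/env Rscript
# Section quantification: per-pixel compartment annotation, nearest-boundary
# distances, apico-basal binning, SOX2-like fold-change statistics across
# conditions (whole section, VZLS, and per bin), positive-area fractions,
# and lineage-marker fractions from a synthetic cell table.

suppressPackageStartupMessages(library(mechanoquant))
out <- "results"
syn <- file.path(out, "synthetic")
manifest <- read.delim(file.path(syn, "section_manifest.tsv"))

per_organoid <- list()
bin_rows <- list()
for (i in seq_len(nrow(manifest))) {
  oid <- manifest$organoid_id[i]
  ann <- read_section_annotation(
    file.path(syn, sprintf("section_%s_labels.tif", oid)),
    file.path(syn, sprintf("section_%s_boundaries.csv", oid)),
    pixel_size_um = 2)
  img <- read_intensity_image(file.path(syn,
                                        sprintf("section_%s_intensity.tif",
                                                oid)))
  tab <- bin_pixels(boundary_distances(annotate_pixels(ann, img), ann))
  # positivity mask: fixed threshold between the background mode (~80) and
  # the dimmest positive mode (~500); recorded alongside the fractions
  pos <- tab$intensity > 250
  per_organoid[[i]] <- data.frame(
    organoid_id = oid, condition = manifest$condition[i],
    whole = intensity_summary(tab, "whole", positive_only = TRUE,
                              positive_mask = pos),
    vzls = intensity_summary(tab, "VZLS", positive_only = TRUE,
                             positive_mask = pos),
    nc = intensity_summary(tab, "NC", positive_only = TRUE,
                           positive_mask = pos),
    pos_frac = as.numeric(positive_area_fraction(tab, threshold = 250)))
  prof <- intensity_summary(tab, "bin", positive_only = TRUE,
                            positive_mask = pos)
  prof$organoid_id <- oid
  prof$condition <- manifest$condition[i]
  bin_rows[[i]] <- prof
}
per_organoid <- do.call(rbind, per_organoid)
bins <- do.call(rbind, bin_rows)
write.table(per_organoid, file.path(out, "section_means.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)

## Fold changes vs the uncompressed (ctrl + mock) reference, with two-sided
## rank-sum tests per compressed condition.
for (scope in c("whole", "vzls")) {
  vals <- data.frame(organoid_id = per_organoid$organoid_id,
                     condition = per_organoid$condition,
                     value = per_organoid[[scope]])
  res <- fold_change(vals)
  write.table(res$stats, file.path(out, paste0("fc_", scope, ".tsv")),
              sep = "\t", row.names = FALSE, quote = FALSE)
  cat(sprintf("%s-section FC:\n", scope))
  print(res$stats, digits = 3)
}

## Per-bin fold changes along the apico-basal axis (bin 0 most apical).
bin_vals <- data.frame(organoid_id = bins$organoid_id,
                       condition = bins$condition, bin = bins$bin,
                       value = bins$mean_intensity)
bin_fc <- fold_change(bin_vals)
write.table(bin_fc$stats, file.path(out, "fc_bins.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("per-bin FC range (comp60):",
    round(range(bin_fc$stats$mean_fc[bin_fc$stats$condition == "comp60"]), 3),
    "\n")

## Positive-area fractions per condition
cat("positive-area fraction by condition:\n")
print(aggregate(pos_frac ~ condition, per_organoid, mean), digits = 3)

## Lineage fractions: BrdU/NEUN double positives among BrdU+, and triple
## positives among double positives, from a planted cell table.
orgs <- expand.grid(rep = 1:5,
                    condition = c("ctrl", "mock", "comp50", "comp60"))
orgs$organoid_id <- sprintf("%s_%d", orgs$condition, orgs$rep)
orgs$n_cells <- 200L
orgs$p_brdu <- 0.4
orgs$p_neun <- ifelse(orgs$condition %in% c("comp50", "comp60"), 0.65, 0.5)
orgs$p_ccas3 <- 0.1
ct <- gen_cell_table(orgs[, c("organoid_id", "condition", "n_cells",
                              "p_brdu", "p_neun", "p_ccas3")],
                     seed = 20260931L)
neur <- lineage_fractions(ct$cells, c("BrdU", "NEUN"), "BrdU")
apop <- lineage_fractions(ct$cells, c("BrdU", "NEUN", "cCAS3"),
                          c("BrdU", "NEUN"))
write.table(neur$stats, file.path(out, "lineage_brdu_neun.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(apop$stats, file.path(out, "lineage_ccas3.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("BrdU/NEUN fraction FC vs uncompressed:\n")
print(neur$stats, digits = 3)
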