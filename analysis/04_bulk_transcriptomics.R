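#!/usr/bin/env Rscript
# Bulk transcriptomics: CPM normalisation, rank-sum differential expression
# with the p < 0.01 / FDR < 0.01 / |log2FC| > 2 gate, DE-set intersections,
# per-sample pathway transcriptional-deviation scores with ANOVA + Tukey
# post-hoc contrasts, and term over-representation with the
# p < 0.05 / >= 5 DE genes filter.

suppressPackageStartupMessages(library(mechanoquant))
out <- "results"
syn <- file.path(out, "synthetic")
b <- read_bulk_counts(file.path(syn, "bulk_counts.tsv"),
                      file.path(syn, "bulk_design.tsv"))
pathways <- read_gmt(file.path(syn, "pathways.gmt"))

logcpm <- cpm_log_normalize(b$counts)

## DE per compressed condition vs uncompressed
de_sets <- list()
for (cond in c("comp50", "comp60")) {
  res <- de_genes(logcpm, b$design, list(cond, c("ctrl", "mock")))
  de_sets[[cond]] <- res$gene[res$pass]
  write.table(res[res$pass, ], file.path(out, paste0("de_", cond, ".tsv")),
              sep = "\t", row.names = FALSE, quote = FALSE)
  cat(sprintf("%s vs uncompressed: %d genes pass the DE gate\n",
              cond, sum(res$pass)))
}

## Exclusive intersections of the DE sets (upset decomposition)
if (all(lengths(de_sets) >= 0)) {
  ix <- set_intersections(de_sets)
  write.table(ix, file.path(out, "de_intersections.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  print(ix)
}

## Pathway transcriptional deviation: per-sample scores, ANOVA + Tukey tiers
dv <- pathway_deviation(b$counts, b$design, pathways)
write.table(round(dv$scores, 4), file.path(out, "pathway_deviation.tsv"),
            sep = "\t", quote = FALSE)
write.table(dv$tests, file.path(out, "pathway_deviation_tests.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)
cat("pathway deviation significance tiers:\n")
print(dv$tests[, c("pathway", "tier")])
# Null pathways can reach significance here through CPM compositionality:
# strongly induced genes (P6) inflate compressed-sample library sizes, which
# depresses every other gene's CPM and shifts null-pathway scores slightly
# negative. Quantify that shift for the three pathways with no injected
# effect so the tier table can be read against it.
null_shift <- mean(dv$scores[c("P3", "P4", "P5"),
                             b$design$group == "comp60"])
cat(sprintf(paste0("mean comp60 deviation of null pathways: %.3f ",
                   "(compositional shift from CPM normalisation)\n"),
            null_shift))

## Term enrichment on the comp60 DE genes, GO-style gate and top-15 report
universe <- rownames(b$counts)
terms <- c(pathways,
           list(combined_P1_P2 = unlist(pathways[c("P1", "P2")],
                                        use.names = FALSE)))
enr <- term_enrichment(de_sets$comp60, universe, terms)
write.table(enr, file.path(out, "term_enrichment.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("top enriched terms:\n")
print(top_terms(enr), digits = 3)
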