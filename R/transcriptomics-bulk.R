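#' Counts-per-million normalisation with log2 transform
#'
#' `CPM = counts / library_size * 1e6`; returns `log2(CPM + pseudocount)`.
#'
#' @param counts Nonnegative genes x samples count matrix.
#' @param pseudocount Added before the log (default 1).
#' @param log If `FALSE`, return linear CPM without pseudocount.
#' @return A matrix of the same shape.
#' @export
cpm_log_normalize <- function(counts, pseudocount = 1, log = TRUE) {
  lib <- colSums(counts)
  if (any(lib <= 0)) stop("zero library size in sample(s): ",
                          paste(colnames(counts)[lib <= 0], collapse = ", "))
  cpm <- sweep(counts, 2, lib, "/") * 1e6
  if (log) log2(cpm + pseudocount) else cpm
}

#' Two-group differential expression with rank-sum test and gate filters
#'
#' Per-gene two-sided Wilcoxon rank-sum test on log2-CPM values between two
#' sample groups, Benjamini-Hochberg FDR across genes, and the pass gate
#' `p < p_max` AND `FDR < fdr_max` AND `|log2FC| > lfc_min` (set
#' `two_sided_fc = FALSE` to gate on the signed log2FC instead). log2FC is
#' the difference of group means on the log2-CPM scale.
#'
#' @param logexpr Genes x samples log2-CPM matrix.
#' @param design Data frame with columns `sample_id`, `group`.
#' @param contrast Length-2 list or character vector: the two group labels
#'   (each may be a vector of groups to pool, e.g. `c("ctrl", "mock")`).
#' @param p_max,fdr_max,lfc_min Gate thresholds (defaults 0.01, 0.01, 2).
#' @param two_sided_fc Gate on `|log2FC|` (default) or on `log2FC`.
#' @return Data frame `gene`, `log2fc`, `p`, `fdr`, `pass`.
#' @export
de_genes <- function(logexpr, design, contrast,
                     p_max = 0.01, fdr_max = 0.01, lfc_min = 2,
                     two_sided_fc = TRUE) {
  g1 <- design$sample_id[design$group %in% contrast[[1]]]
  g2 <- design$sample_id[design$group %in% contrast[[2]]]
  if (length(g1) < 2 || length(g2) < 2)
    stop("each contrasted group needs >= 2 samples")
  x1 <- logexpr[, g1, drop = FALSE]
  x2 <- logexpr[, g2, drop = FALSE]
  p <- vapply(seq_len(nrow(logexpr)), function(i)
    .ranksum_p(x1[i, ], x2[i, ]), numeric(1))
  lfc <- rowMeans(x1) - rowMeans(x2)
  fdr <- p.adjust(p, "BH")
  mag <- if (two_sided_fc) abs(lfc) else lfc
  data.frame(gene = rownames(logexpr), log2fc = lfc, p = p, fdr = fdr,
             pass = p < p_max & fdr < fdr_max & mag > lfc_min,
             row.names = NULL)
}

#' Exclusive intersection counts of named gene sets
#'
#' Decomposes the union of several differential-expression gene sets into
#' exclusive membership combinations (the counts behind an upset plot): for
#' every nonempty subset of set names, the number of genes belonging to
#' exactly those sets.
#'
#' @param sets Named list (>= 2) of gene-id vectors; empty sets allowed.
#' @return Data frame `combination` (set names joined by `&`), `degree`,
#'   `count`, covering combinations with nonzero count.
#' @export
set_intersections <- function(sets) {
  if (length(sets) < 2) stop("need at least 2 sets")
  if (is.null(names(sets))) stop("sets must be named")
  genes <- unique(unlist(sets))
  if (length(genes) == 0)
    return(data.frame(combination = character(0), degree = integer(0),
                      count = integer(0)))
  member <- vapply(sets, function(s) genes %in% s, logical(length(genes)))
  if (length(genes) == 1L) member <- matrix(member, nrow = 1L,
                                            dimnames = list(NULL, names(sets)))
  key <- apply(member, 1, function(m) paste(names(sets)[m], collapse = "&"))
  tab <- table(key)
  data.frame(combination = names(tab),
             degree = lengths(strsplit(names(tab), "&", fixed = TRUE)),
             count = as.integer(tab), row.names = NULL)
}

#' Per-sample pathway transcriptional-deviation scores
#'
#' For each pathway P and sample s, the deviation score is the sum over the
#' pathway's genes (restricted to genes present in the dataset) of the
#' natural log of the sample's fold change over the mean expression in the
#' uncompressed reference samples, divided by the number of those genes:
#' `D[P, s] = (1/n_P) * sum_g ln((x[g, s] + eps) / (mu_g + eps))`,
#' on CPM-normalised expression with pseudocount `eps`. Each pathway is
#' then tested by one-way ANOVA over the groups (ctrl and mock merged into
#' "uncompressed") with Tukey HSD post-hoc contrasts of uncompressed
#' against each compressed group, and assigned a significance tier at
#' `alpha` from the two Tukey p-values: `ns`, `50-only`, `60-only`, `both`.
#'
#' @param counts Genes x samples count matrix (or linear CPM with
#'   `normalize = FALSE`).
#' @param design Data frame `sample_id`, `group` with groups among ctrl,
#'   mock, comp50, comp60.
#' @param pathways Named list of gene-id vectors; pathways with no gene in
#'   the dataset are dropped with a warning.
#' @param reference Group labels pooled into the reference mean (default
#'   `c("ctrl", "mock")`, the uncompressed samples; set to `"ctrl"` to use
#'   ctrl only).
#' @param eps Pseudocount on the CPM scale (default 0.5).
#' @param alpha Tier significance level (default 0.05).
#' @param normalize CPM-normalise `counts` first (default `TRUE`).
#' @param p_adjust_anova If `TRUE`, add BH-adjusted ANOVA p-values across
#'   pathways (off by default; per-pathway values are reported raw).
#' @return A list of class `deviation_result`: `scores` (pathways x
#'   samples), `tests` (per pathway: `p_anova`, `p_unc_vs_comp50`,
#'   `p_unc_vs_comp60`, `tier`).
#' @export
pathway_deviation <- function(counts, design, pathways,
                              reference = c("ctrl", "mock"),
                              eps = 0.5, alpha = 0.05, normalize = TRUE,
                              p_adjust_anova = FALSE) {
  stopifnot(all(design$sample_id %in% colnames(counts)))
  expr <- if (normalize) cpm_log_normalize(counts, log = FALSE) else counts
  expr <- expr[, design$sample_id, drop = FALSE]
  ref_samples <- design$sample_id[design$group %in% reference]
  if (length(ref_samples) == 0) stop("reference group is empty")
  mu <- rowMeans(expr[, ref_samples, drop = FALSE])
  keep <- vapply(pathways, function(p) length(intersect(p, rownames(expr))),
                 integer(1))
  if (any(keep == 0)) {
    warning("dropping pathway(s) with no gene in the dataset: ",
            paste(names(pathways)[keep == 0], collapse = ", "))
    pathways <- pathways[keep > 0]
  }
  if (length(pathways) == 0) stop("no pathway has genes in the dataset")
  lr <- log((expr + eps) / (mu + eps))
  scores <- t(vapply(pathways, function(p) {
    g <- intersect(p, rownames(expr))
    colMeans(lr[g, , drop = FALSE])
  }, numeric(ncol(expr))))
  dimnames(scores) <- list(names(pathways), design$sample_id)

  grp <- ifelse(design$group %in% c("ctrl", "mock"), "uncompressed",
                design$group)
  grp <- factor(grp)
  tests <- do.call(rbind, lapply(rownames(scores), function(p) {
    d <- data.frame(score = scores[p, ], group = grp)
    fit <- aov(score ~ group, data = d)
    p_anova <- summary(fit)[[1]][["Pr(>F)"]][1]
    tk <- TukeyHSD(fit)$group
    get_p <- function(a, b) {
      rn <- rownames(tk)
      hit <- rn == paste(a, b, sep = "-") | rn == paste(b, a, sep = "-")
      if (any(hit)) tk[hit, "p adj"][1] else NA_real_
    }
    p50 <- get_p("uncompressed", "comp50")
    p60 <- get_p("uncompressed", "comp60")
    sig50 <- isTRUE(p50 < alpha); sig60 <- isTRUE(p60 < alpha)
    tier <- if (sig50 && sig60) "both" else if (sig60) "60-only" else
      if (sig50) "50-only" else "ns"
    data.frame(pathway = p, p_anova = p_anova,
               p_unc_vs_comp50 = p50, p_unc_vs_comp60 = p60, tier = tier)
  }))
  rownames(tests) <- NULL
  if (p_adjust_anova) tests$p_anova_adj <- p.adjust(tests$p_anova, "BH")
  structure(list(scores = scores, tests = tests),
            class = "deviation_result")
}

#' Over-representation test of terms in a DE gene list
#'
#' One-sided Fisher exact test (the upper hypergeometric tail) on the 2x2
#' table of term membership against differential expression, per term, with
#' the filter: a term passes iff `p < alpha` and it contains at least
#' `min_de` differentially expressed genes. Term memberships are restricted
#' to the gene universe before testing.
#'
#' @param de Character vector of DE gene ids (must be within `universe`).
#' @param universe Character vector: all genes considered.
#' @param terms Named list of term gene-id vectors.
#' @param alpha P-value filter (default 0.05).
#' @param min_de Minimum DE genes in a passing term (default 5).
#' @return Data frame `term`, `n_term`, `n_de_in_term`, `p`, `pass`,
#'   ordered by `p`.
#' @export
term_enrichment <- function(de, universe, terms, alpha = 0.05, min_de = 5L) {
  if (length(universe) == 0) stop("empty gene universe")
  if (!all(de %in% universe)) stop("DE genes must be a subset of the universe")
  de <- unique(de)
  N <- length(unique(universe)); K <- length(de)
  rows <- lapply(names(terms), function(tn) {
    tg <- intersect(terms[[tn]], universe)
    n <- length(tg)
    k <- length(intersect(tg, de))
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tn, n_term = n, n_de_in_term = k, p = p,
               pass = p < alpha & k >= min_de)
  })
  out <- do.call(rbind, rows)
  out[order(out$p), , drop = FALSE]
}

#' @rdname term_enrichment
#' @param enrichment A `term_enrichment()` result.
#' @param n Number of top terms (default 15).
#' @return `top_terms()`: the `n` passing terms with the smallest p-values.
#' @export
top_terms <- function(enrichment, n = 15L) {
  head(enrichment[enrichment$pass, , drop = FALSE], n)
}

#' Read and write gene sets in GMT format
#'
#' One set per line: name, description, then member ids, tab-separated.
#'
#' @param path File path.
#' @return `read_gmt()`: a named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1L)
  sets
}

#' @rdname read_gmt
#' @param sets Named list of gene-id vectors.
#' @param description Description field written per set.
#' @export
write_gmt <- function(sets, path, description = "na") {
  lines <- vapply(names(sets), function(n)
    paste(c(n, description, sets[[n]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}
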