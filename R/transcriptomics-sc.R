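#' Single-cell quality-control filter
#'
#' Removes cells failing any of the stated rules — fewer than `min_genes`
#' detected genes, fewer than `min_counts` or more than `max_counts` UMIs,
#' or a mitochondrial fraction above `max_mito` — then removes genes
#' expressed (nonzero) in fewer than `min_cells` of the remaining cells.
#' A cell failing several rules is counted once per rule but removed once.
#' The filter is idempotent.
#'
#' @param expr Genes x cells expression matrix.
#' @param meta Per-cell data frame with columns `cell_id`, `n_genes`,
#'   `n_counts`, `mito_frac` (an absent covariate is an error naming it).
#' @param min_genes,min_counts,max_counts,max_mito,min_cells Thresholds
#'   (defaults 2500, 5000, 25000, 0.07, 10).
#' @return A list: `expr`, `meta` (filtered), `removed` (per-rule cell
#'   counts plus `genes_removed`), `removed_cells`, `removed_genes`.
#' @export
qc_filter <- function(expr, meta,
                      min_genes = 2500L, min_counts = 5000L,
                      max_counts = 25000L, max_mito = 0.07,
                      min_cells = 10L) {
  need <- c("cell_id", "n_genes", "n_counts", "mito_frac")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop("missing QC covariate(s): ", paste(miss, collapse = ", "))
  stopifnot(ncol(expr) == nrow(meta))
  fail_genes <- meta$n_genes < min_genes
  fail_clow <- meta$n_counts < min_counts
  fail_chigh <- meta$n_counts > max_counts
  fail_mito <- meta$mito_frac > max_mito
  fail_any <- fail_genes | fail_clow | fail_chigh | fail_mito
  expr2 <- expr[, !fail_any, drop = FALSE]
  meta2 <- meta[!fail_any, , drop = FALSE]
  expressed_in <- rowSums(expr2 != 0)
  gene_drop <- expressed_in < min_cells
  list(expr = expr2[!gene_drop, , drop = FALSE],
       meta = meta2,
       removed = list(n_genes = sum(fail_genes),
                      counts_low = sum(fail_clow),
                      counts_high = sum(fail_chigh),
                      mito = sum(fail_mito),
                      cells_total = sum(fail_any),
                      genes_removed = sum(gene_drop)),
       removed_cells = meta$cell_id[fail_any],
       removed_genes = rownames(expr2)[gene_drop])
}

#' Gene-set activity score with an expression-matched reference
#'
#' Per-cell score of a gene set: the mean expression of the set's genes
#' minus the mean expression of a reference gene pool matched for overall
#' expression level. Genes are binned into `n_bins` quantile bins of their
#' mean expression across cells; for every set gene, `ref_size` genes are
#' sampled (without replacement, excluding set genes) from its bin, and
#' their union forms the reference pool. Sampling is seeded, so the score
#' is deterministic given the seed.
#'
#' @param expr Genes x cells log-expression matrix.
#' @param set Character vector of gene ids; members absent from the matrix
#'   are dropped (an empty effective set is an error).
#' @param n_bins Number of expression bins (default 10: deciles).
#' @param ref_size Reference genes drawn per set gene (default 50; capped
#'   at bin occupancy).
#' @param seed Mandatory RNG seed for the reference draw.
#' @param ref_genes Optional explicit reference pool overriding the matched
#'   draw.
#' @return Named numeric vector of per-cell scores, with the reference pool
#'   in attribute `"reference"`.
#' @export
gene_set_score <- function(expr, set, n_bins = 10L, ref_size = 50L, seed,
                           ref_genes = NULL) {
  set <- intersect(set, rownames(expr))
  if (length(set) == 0) stop("no gene of the set is present in the matrix")
  if (is.null(ref_genes)) {
    if (missing(seed)) stop("`seed` is required for the reference draw")
    gene_means <- rowMeans(expr)
    br <- unique(quantile(gene_means, probs = seq(0, 1, length.out = n_bins + 1)))
    bin <- cut(gene_means, breaks = br, include.lowest = TRUE, labels = FALSE)
    names(bin) <- rownames(expr)
    candidates <- setdiff(rownames(expr), set)
    ref_genes <- with_seed(seed, {
      drawn <- lapply(set, function(g) {
        pool <- candidates[bin[candidates] == bin[[g]]]
        if (length(pool) == 0) return(character(0))
        sample(pool, min(ref_size, length(pool)))
      })
      unique(unlist(drawn))
    })
    if (length(ref_genes) == 0)
      stop("expression-matched reference pool is empty")
  } else {
    ref_genes <- intersect(ref_genes, rownames(expr))
    if (length(ref_genes) == 0) stop("explicit reference pool is empty")
  }
  score <- colMeans(expr[set, , drop = FALSE]) -
    colMeans(expr[ref_genes, , drop = FALSE])
  attr(score, "reference") <- ref_genes
  score
}

#' Per-cluster regulon-activity fold change between conditions
#'
#' Normalises each cell's gene-set (regulon) score to the mean score of the
#' uncompressed cells in its cluster, averages the normalised scores per
#' cluster and condition, and tests each cluster's condition difference
#' with a two-sided Mann-Whitney U test. Clusters missing a condition, or
#' whose uncompressed mean score is zero, are skipped with a warning.
#'
#' @param scores Named per-cell score vector (from [gene_set_score()]).
#' @param meta Per-cell data frame with `cell_id`, `cluster`, `condition`.
#' @param reference Condition label(s) forming the uncompressed reference
#'   (default `"mock"`).
#' @return Data frame with one row per retained cluster x condition:
#'   `cluster`, `condition`, `n_cells`, `mean_fc`, and the per-cluster
#'   Mann-Whitney `p` (repeated across the cluster's rows).
#' @export
regulon_fc_by_cluster <- function(scores, meta, reference = "mock") {
  stopifnot(length(scores) == nrow(meta))
  conditions <- unique(meta$condition)
  comp <- setdiff(conditions, reference)
  if (length(comp) != 1)
    stop("expected exactly one non-reference condition, found: ",
         paste(comp, collapse = ", "))
  rows <- list()
  for (cl in sort(unique(meta$cluster))) {
    in_cl <- meta$cluster == cl
    ref_scores <- scores[in_cl & meta$condition %in% reference]
    cmp_scores <- scores[in_cl & meta$condition == comp]
    if (length(ref_scores) == 0 || length(cmp_scores) == 0) {
      warning("cluster ", cl, " is absent from one condition; skipped")
      next
    }
    m0 <- mean(ref_scores)
    if (m0 == 0) {
      warning("cluster ", cl, " has zero mean reference score; skipped")
      next
    }
    p <- .ranksum_p(cmp_scores, ref_scores)
    rows[[length(rows) + 1L]] <- data.frame(
      cluster = cl,
      condition = c("uncompressed", comp),
      n_cells = c(length(ref_scores), length(cmp_scores)),
      mean_fc = c(mean(ref_scores / m0), mean(cmp_scores / m0)),
      p = p)
  }
  if (length(rows) == 0) stop("no cluster retained")
  do.call(rbind, rows)
}

#' Linear trend of a gene-set score over pseudotime
#'
#' Ordinary least-squares fit of per-cell score against pseudotime,
#' separately per condition, with a bootstrap 95 percent confidence band
#' for the fitted line (cells resampled with replacement, seeded).
#'
#' @param scores Per-cell score vector.
#' @param tau Per-cell pseudotime in `[0, 1]`; must be non-constant.
#' @param condition Per-cell condition labels.
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Seed for the bootstrap.
#' @param grid Pseudotime grid for the band (default 25 points spanning the
#'   observed range).
#' @return A list per condition, each with `slope`, `intercept`,
#'   `slope_ci` (percentile 95 percent CI), and `band` (data frame `tau`,
#'   `fit`, `lower`, `upper`).
#' @export
score_over_pseudotime <- function(scores, tau, condition, n_boot = 1000L,
                                  seed = 1L, grid = NULL) {
  stopifnot(length(scores) == length(tau),
            length(scores) == length(condition))
  if (is.null(grid))
    grid <- seq(min(tau), max(tau), length.out = 25L)
  out <- list()
  for (cond in unique(condition)) {
    sel <- condition == cond
    if (sum(sel) < 10) stop("condition '", cond, "' has fewer than 10 cells")
    x <- tau[sel]; y <- scores[sel]
    if (var(x) == 0) stop("pseudotime is constant in condition '", cond, "'")
    slope <- cov(x, y) / var(x)
    intercept <- mean(y) - slope * mean(x)
    boots <- with_seed(seed, {
      n <- length(x)
      vapply(seq_len(n_boot), function(b) {
        idx <- sample.int(n, n, replace = TRUE)
        xb <- x[idx]; yb <- y[idx]
        vb <- var(xb)
        if (vb == 0) return(c(NA_real_, NA_real_))
        sb <- cov(xb, yb) / vb
        c(sb, mean(yb) - sb * mean(xb))
      }, numeric(2))
    })
    boots <- boots[, !is.na(boots[1, ]), drop = FALSE]
    fits <- outer(boots[2, ], rep(1, length(grid))) +
      outer(boots[1, ], grid)
    band <- data.frame(
      tau = grid,
      fit = intercept + slope * grid,
      lower = apply(fits, 2, quantile, probs = 0.025),
      upper = apply(fits, 2, quantile, probs = 0.975))
    out[[cond]] <- list(slope = slope, intercept = intercept,
                        slope_ci = unname(quantile(boots[1, ],
                                                   c(0.025, 0.975))),
                        band = band)
  }
  out
}
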