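#' Ground-truth parameters for a synthetic single-cell dataset
#'
#' Log-normalised expression drawn as Gaussian noise around per-cluster
#' gene baselines, with three kinds of planted structure: additive
#' log-expression shifts for chosen (gene set, cluster, condition) triples,
#' a monotone pseudotime trend per gene set (set-gene expression gains
#' `slope * tau`), and QC covariates constructed so that exactly the
#' requested numbers of cells violate each QC rule.
#'
#' @param n_cells,n_genes,n_clusters Dataset dimensions (`n_clusters >= 1`).
#'   Gene ids are `gene_1..gene_n`; cluster labels are `1..n_clusters`.
#' @param condition_labels Condition labels assigned uniformly to cells
#'   (default `c("mock", "comp50")`).
#' @param gene_sets Named list of gene-id vectors.
#' @param set_shift Data frame with columns `set`, `cluster`, `condition`,
#'   `delta`: log-expression added to the set's genes in cells of that
#'   cluster and condition.
#' @param pseudotime_slope Named numeric vector (per gene set) of
#'   expression slope against pseudotime.
#' @param qc_violation_counts Named list of planted QC violators:
#'   `n_genes` (cells with < 2500 detected genes), `counts_low` (< 5000
#'   UMIs), `counts_high` (> 25000 UMIs), `mito` (> 7 percent
#'   mitochondrial), `gene_floor` (genes expressed in < 10 cells).
#' @param baseline_mean,cluster_sd,noise_sd Gaussian baseline parameters.
#' @param seed Mandatory RNG seed.
#' @return An object of class `sc_truth`.
#' @export
sc_truth <- function(n_cells = 2000L, n_genes = 500L, n_clusters = 4L,
                     condition_labels = c("mock", "comp50"),
                     gene_sets = list(),
                     set_shift = NULL,
                     pseudotime_slope = NULL,
                     qc_violation_counts = list(),
                     baseline_mean = 1.5, cluster_sd = 0.4, noise_sd = 0.4,
                     seed) {
  if (missing(seed)) stop("`seed` is a mandatory argument")
  if (n_clusters < 1) stop("n_clusters must be >= 1")
  gene_ids <- paste0("gene_", seq_len(n_genes))
  if (length(gene_sets)) {
    unknown <- setdiff(unlist(gene_sets), gene_ids)
    if (length(unknown))
      stop("gene-set member(s) not among the generated genes: ",
           paste(head(unknown, 5), collapse = ", "))
  }
  if (is.null(set_shift))
    set_shift <- data.frame(set = character(0), cluster = integer(0),
                            condition = character(0), delta = numeric(0))
  if (nrow(set_shift)) {
    if (!all(set_shift$set %in% names(gene_sets)))
      stop("set_shift references unknown gene set(s)")
    if (!all(set_shift$cluster %in% seq_len(n_clusters)))
      stop("set_shift references unknown cluster(s)")
    if (!all(set_shift$condition %in% condition_labels))
      stop("set_shift references unknown condition(s)")
  }
  if (!is.null(pseudotime_slope) &&
      !all(names(pseudotime_slope) %in% names(gene_sets)))
    stop("pseudotime_slope references unknown gene set(s)")
  qc_defaults <- list(n_genes = 0L, counts_low = 0L, counts_high = 0L,
                      mito = 0L, gene_floor = 0L)
  bad <- setdiff(names(qc_violation_counts), names(qc_defaults))
  if (length(bad)) stop("unknown QC rule(s): ", paste(bad, collapse = ", "))
  qc <- utils::modifyList(qc_defaults, qc_violation_counts)
  n_cell_violators <- qc$n_genes + qc$counts_low + qc$counts_high + qc$mito
  if (n_cell_violators > n_cells)
    stop("more planted QC violators than cells")
  structure(list(n_cells = as.integer(n_cells),
                 n_genes = as.integer(n_genes), gene_ids = gene_ids,
                 n_clusters = as.integer(n_clusters),
                 condition_labels = condition_labels,
                 gene_sets = gene_sets, set_shift = set_shift,
                 pseudotime_slope = pseudotime_slope,
                 qc_violation_counts = qc,
                 baseline_mean = baseline_mean, cluster_sd = cluster_sd,
                 noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "sc_truth")
}

#' Generate a synthetic single-cell expression matrix with metadata
#'
#' @param truth An [sc_truth()] object.
#' @return A list with `expr` (genes x cells log-expression matrix), `meta`
#'   (per cell: `cell_id`, `condition`, `cluster`, `pseudotime`,
#'   `n_genes`, `n_counts`, `mito_frac`) and `violators` (cell ids planted
#'   to fail each QC rule; `gene_floor` holds gene ids).
#' @export
gen_sc_matrix <- function(truth) {
  stopifnot(inherits(truth, "sc_truth"))
  with_seed(truth$seed, {
    n <- truth$n_cells; g <- truth$n_genes
    cell_ids <- paste0("cell_", seq_len(n))
    cluster <- sample(seq_len(truth$n_clusters), n, replace = TRUE)
    condition <- sample(truth$condition_labels, n, replace = TRUE)
    tau <- runif(n)
    # per-cluster gene baselines
    mu0 <- rnorm(g, truth$baseline_mean, 0.3)
    base <- matrix(rnorm(g * truth$n_clusters, 0, truth$cluster_sd),
                   nrow = g) + mu0
    expr <- base[, cluster, drop = FALSE] +
      matrix(rnorm(g * n, 0, truth$noise_sd), nrow = g)
    dimnames(expr) <- list(truth$gene_ids, cell_ids)
    # planted (set, cluster, condition) shifts
    if (nrow(truth$set_shift)) {
      for (i in seq_len(nrow(truth$set_shift))) {
        s <- truth$set_shift[i, ]
        cells <- which(cluster == s$cluster & condition == s$condition)
        genes <- truth$gene_sets[[s$set]]
        expr[genes, cells] <- expr[genes, cells] + s$delta
      }
    }
    # monotone pseudotime trends
    if (!is.null(truth$pseudotime_slope)) {
      for (s in names(truth$pseudotime_slope)) {
        genes <- truth$gene_sets[[s]]
        expr[genes, ] <- expr[genes, ] +
          rep(truth$pseudotime_slope[[s]] * tau, each = length(genes))
      }
    }
    # QC covariates: compliant by default, violators planted on disjoint cells
    n_genes_cov <- round(runif(n, 3000, 6000))
    n_counts_cov <- round(runif(n, 6000, 20000))
    mito_cov <- runif(n, 0, 0.05)
    qc <- truth$qc_violation_counts
    pool <- seq_len(n)
    take <- function(k) {
      if (k == 0L) return(integer(0))
      idx <- pool[seq_len(k)]
      pool <<- pool[-seq_len(k)]
      idx
    }
    v_genes <- take(qc$n_genes)
    v_clow <- take(qc$counts_low)
    v_chigh <- take(qc$counts_high)
    v_mito <- take(qc$mito)
    n_genes_cov[v_genes] <- round(runif(qc$n_genes, 500, 2499))
    n_counts_cov[v_clow] <- round(runif(qc$counts_low, 1000, 4999))
    n_counts_cov[v_chigh] <- round(runif(qc$counts_high, 25001, 40000))
    mito_cov[v_mito] <- runif(qc$mito, 0.08, 0.30)
    # genes expressed (nonzero) in < 10 surviving cells
    floor_genes <- character(0)
    if (qc$gene_floor > 0) {
      surviving <- setdiff(seq_len(n), c(v_genes, v_clow, v_chigh, v_mito))
      if (length(surviving) < 10)
        stop("too few surviving cells to plant gene-floor violators")
      floor_genes <- utils::tail(truth$gene_ids, qc$gene_floor)
      for (gf in floor_genes) {
        keep_cells <- sample(surviving, 9L)
        expr[gf, ] <- 0
        expr[gf, keep_cells] <- abs(rnorm(9L, 1, 0.2))
      }
    }
    meta <- data.frame(cell_id = cell_ids, condition = condition,
                       cluster = cluster, pseudotime = tau,
                       n_genes = n_genes_cov, n_counts = n_counts_cov,
                       mito_frac = mito_cov)
    list(expr = expr, meta = meta,
         violators = list(n_genes = cell_ids[v_genes],
                          counts_low = cell_ids[v_clow],
                          counts_high = cell_ids[v_chigh],
                          mito = cell_ids[v_mito],
                          gene_floor = floor_genes))
  })
}
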