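#' Ground-truth parameters for synthetic bulk RNA-seq counts
#'
#' Negative-binomial counts for a ctrl / mock / comp50 / comp60 design with
#' pathway-level natural-log fold-change effects: gene g in sample s has
#' mean `library_size * w_g * exp(lnfc(pathway(g), group(s)))`, where `w_g`
#' are log-normal relative-abundance weights normalised to sum to one, and
#' the dispersion is shared across genes. ctrl and mock carry no effect by
#' construction (uncompressed reference).
#'
#' @param n_genes Number of genes (> 0). Gene ids are `gene_1..gene_n`.
#' @param n_samples_per_group Samples per group (>= 2 when ANOVA is run
#'   downstream).
#' @param group_names Group labels; default
#'   `c("ctrl", "mock", "comp50", "comp60")`.
#' @param pathways Named list of gene-id vectors (a gene-set collection);
#'   every member must exist among the `n_genes` gene ids. Pathways must not
#'   overlap (each gene carries at most one pathway effect).
#' @param pathway_lnfc Numeric matrix of natural-log fold changes, rows =
#'   pathway names, columns = group names. ctrl and mock columns must be 0.
#' @param nb_dispersion Negative-binomial dispersion (> 0); variance is
#'   `mu + dispersion * mu^2`. The default 0.05 (biological coefficient of
#'   variation ~0.22) is typical of bulk RNA-seq biological replicates.
#' @param library_size Expected library size per sample.
#' @param seed Mandatory RNG seed.
#' @return An object of class `bulk_truth`.
#' @export
bulk_truth <- function(n_genes = 2000L,
                       n_samples_per_group = 6L,
                       group_names = c("ctrl", "mock", "comp50", "comp60"),
                       pathways = list(),
                       pathway_lnfc = NULL,
                       nb_dispersion = 0.05,
                       library_size = 1e6,
                       seed) {
  if (missing(seed)) stop("`seed` is a mandatory argument")
  if (n_genes < 1) stop("n_genes must be >= 1")
  if (n_samples_per_group < 2)
    stop("need >= 2 samples per group for downstream ANOVA")
  gene_ids <- paste0("gene_", seq_len(n_genes))
  if (length(pathways)) {
    if (is.null(names(pathways)) || any(names(pathways) == ""))
      stop("pathways must be a named list")
    unknown <- setdiff(unlist(pathways), gene_ids)
    if (length(unknown))
      stop("pathway member(s) not among the generated genes: ",
           paste(head(unknown, 5), collapse = ", "))
    if (anyDuplicated(unlist(pathways)))
      stop("pathways must not overlap")
  }
  if (is.null(pathway_lnfc)) {
    pathway_lnfc <- matrix(0, nrow = length(pathways),
                           ncol = length(group_names),
                           dimnames = list(names(pathways), group_names))
  }
  if (!setequal(colnames(pathway_lnfc), group_names) ||
      !setequal(rownames(pathway_lnfc), names(pathways)))
    stop("pathway_lnfc must be pathways x groups")
  ref <- intersect(c("ctrl", "mock"), group_names)
  if (length(ref) && any(pathway_lnfc[, ref, drop = FALSE] != 0))
    stop("ctrl and mock ln fold changes must be 0 by construction")
  if (nb_dispersion <= 0) stop("nb_dispersion must be > 0")
  structure(list(n_genes = as.integer(n_genes), gene_ids = gene_ids,
                 n_samples_per_group = as.integer(n_samples_per_group),
                 group_names = group_names,
                 pathways = pathways,
                 pathway_lnfc = pathway_lnfc,
                 nb_dispersion = nb_dispersion,
                 library_size = library_size,
                 seed = as.integer(seed)),
            class = "bulk_truth")
}

#' Generate synthetic bulk counts and their sample design
#'
#' @param truth A [bulk_truth()] object.
#' @return A list with `counts` (genes x samples integer matrix) and
#'   `design` (data frame `sample_id`, `group`).
#' @export
gen_bulk_counts <- function(truth) {
  stopifnot(inherits(truth, "bulk_truth"))
  groups <- rep(truth$group_names, each = truth$n_samples_per_group)
  sample_ids <- paste0(groups, "_",
                       rep(seq_len(truth$n_samples_per_group),
                           times = length(truth$group_names)))
  pathway_of <- setNames(rep(NA_character_, truth$n_genes), truth$gene_ids)
  for (p in names(truth$pathways)) pathway_of[truth$pathways[[p]]] <- p
  with_seed(truth$seed, {
    w <- rlnorm(truth$n_genes, meanlog = 0, sdlog = 1)
    w <- w / sum(w)
    mu0 <- truth$library_size * w
    lnfc <- matrix(0, nrow = truth$n_genes, ncol = length(groups))
    has_p <- !is.na(pathway_of)
    for (j in seq_along(groups)) {
      lnfc[has_p, j] <- truth$pathway_lnfc[pathway_of[has_p], groups[j]]
    }
    mu <- mu0 * exp(lnfc)
    counts <- matrix(rnbinom(length(mu), mu = mu,
                             size = 1 / truth$nb_dispersion),
                     nrow = truth$n_genes,
                     dimnames = list(truth$gene_ids, sample_ids))
    list(counts = counts,
         design = data.frame(sample_id = sample_ids, group = groups))
  })
}
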