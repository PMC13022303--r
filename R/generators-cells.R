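#' Generate a synthetic lineage-marker cell table with exact fractions
#'
#' Builds per-cell boolean marker calls (BrdU, NEUN, cCAS3) for a set of
#' organoids with the marker fractions planted exactly: each organoid gets
#' `round(n_cells * p_brdu)` BrdU-positive cells, of which
#' `round(. * p_neun)` are also NEUN-positive, of which `round(. * p_ccas3)`
#' are additionally cCAS3-positive, so downstream lineage fractions recover
#' the rounded planted ratios exactly. Row order is shuffled under the seed.
#'
#' @param organoids Data frame with one row per organoid: `organoid_id`,
#'   `condition`, `n_cells`, `p_brdu`, `p_neun`, `p_ccas3` (conditional
#'   fractions as described).
#' @param seed Mandatory RNG seed (used only to shuffle rows).
#' @return A list with `cells` (data frame `cell_id`, `organoid_id`,
#'   `condition`, `BrdU`, `NEUN`, `cCAS3`) and `truth` (the organoid table
#'   with the realised counts `n_brdu`, `n_brdu_neun`, `n_triple`).
#' @export
gen_cell_table <- function(organoids, seed) {
  if (missing(seed)) stop("`seed` is a mandatory argument")
  need <- c("organoid_id", "condition", "n_cells", "p_brdu", "p_neun",
            "p_ccas3")
  miss <- setdiff(need, names(organoids))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  rows <- list()
  truth <- organoids
  truth$n_brdu <- truth$n_brdu_neun <- truth$n_triple <- NA_integer_
  for (i in seq_len(nrow(organoids))) {
    o <- organoids[i, ]
    n <- o$n_cells
    n_brdu <- round(n * o$p_brdu)
    n_bn <- round(n_brdu * o$p_neun)
    n_tri <- round(n_bn * o$p_ccas3)
    brdu <- c(rep(TRUE, n_brdu), rep(FALSE, n - n_brdu))
    neun <- c(rep(TRUE, n_bn), rep(FALSE, n - n_bn))
    ccas3 <- c(rep(TRUE, n_tri), rep(FALSE, n - n_tri))
    rows[[i]] <- data.frame(
      cell_id = paste0(o$organoid_id, "_c", seq_len(n)),
      organoid_id = o$organoid_id, condition = o$condition,
      BrdU = brdu, NEUN = neun, cCAS3 = ccas3)
    truth$n_brdu[i] <- n_brdu
    truth$n_brdu_neun[i] <- n_bn
    truth$n_triple[i] <- n_tri
  }
  cells <- do.call(rbind, rows)
  cells <- with_seed(seed, cells[sample.int(nrow(cells)), ])
  rownames(cells) <- NULL
  list(cells = cells, truth = truth)
}
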