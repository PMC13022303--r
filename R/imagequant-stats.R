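# Two-sided Wilcoxon rank-sum p-value with the small-sample convention used
# throughout the section statistics: exact enumeration when the combined
# sample size is <= `exact_cutoff` and there are no ties, normal
# approximation with tie correction otherwise.
.ranksum_p <- function(x, y, exact_cutoff = 20L) {
  use_exact <- (length(x) + length(y)) <= exact_cutoff
  suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = use_exact,
                correct = TRUE)$p.value)
}

#' Mean intensity of a section at a chosen scope
#'
#' Arithmetic mean of pixel intensities over the whole section, the VZLS
#' compartment, the NC compartment, or per apico-basal bin. An empty
#' selection yields `NA` with a warning, never a silent zero.
#'
#' @param table A `pixel_table`; bins must be filled for `scope = "bin"`.
#' @param scope One of `"whole"`, `"VZLS"`, `"NC"`, `"bin"`.
#' @param positive_only If `TRUE`, restrict to positive pixels as defined by
#'   `positive_mask` (logical vector over table rows) or, when missing, an
#'   Otsu threshold computed on the table intensities.
#' @param positive_mask Optional logical vector marking positive pixels.
#' @return For scalar scopes, a single mean. For `scope = "bin"`, a data
#'   frame with columns `bin`, `mean_intensity`, `n_pixels`.
#' @export
intensity_summary <- function(table,
                              scope = c("whole", "VZLS", "NC", "bin"),
                              positive_only = FALSE,
                              positive_mask = NULL) {
  scope <- match.arg(scope)
  keep <- switch(scope,
                 whole = rep(TRUE, nrow(table)),
                 VZLS = table$vzls_id >= 2L,
                 NC = table$vzls_id == 0L,
                 bin = !is.na(table$bin))
  if (positive_only) {
    if (is.null(positive_mask)) {
      positive_mask <- table$intensity > .otsu_threshold(table$intensity)
    }
    stopifnot(length(positive_mask) == nrow(table))
    keep <- keep & positive_mask
  }
  if (!any(keep)) {
    warning("empty selection for scope '", scope, "'; returning NA")
    if (scope == "bin")
      return(data.frame(bin = integer(0), mean_intensity = numeric(0),
                        n_pixels = integer(0)))
    return(NA_real_)
  }
  if (scope == "bin") {
    sub <- table[keep, ]
    agg <- aggregate(sub$intensity, by = list(bin = sub$bin), FUN = mean)
    n <- aggregate(sub$intensity, by = list(bin = sub$bin), FUN = length)
    data.frame(bin = agg$bin, mean_intensity = agg$x, n_pixels = n$x)
  } else {
    mean(table$intensity[keep])
  }
}

#' Fold change of per-organoid means against an uncompressed reference
#'
#' Computes, for each organoid, its value divided by the mean of the
#' reference-group values (the uncompressed ctrl + mock organoids by
#' default), and a two-sided Wilcoxon rank-sum p-value for each
#' non-reference condition against the pooled reference. When a `bin`
#' column is present, the reference mean is computed within the same bin, so
#' each bin has its own baseline.
#'
#' @param values Data frame with columns `organoid_id`, `condition`,
#'   `value`, and optionally `bin`.
#' @param reference Character vector of condition labels forming the
#'   reference group (default `c("ctrl", "mock")`).
#' @param p_adjust If `TRUE`, Benjamini-Hochberg-adjust the per-contrast
#'   p-values (off by default; the per-contrast values are reported raw).
#' @return A list with `fc` (the input rows plus an `fc` column) and
#'   `stats` (one row per non-reference condition x bin: `condition`,
#'   `bin`, `n`, `n_ref`, `mean_fc`, `p`).
#' @export
fold_change <- function(values, reference = c("ctrl", "mock"),
                        p_adjust = FALSE) {
  need <- c("organoid_id", "condition", "value")
  if (!all(need %in% names(values)))
    stop("values must have columns ", paste(need, collapse = ", "))
  has_bin <- "bin" %in% names(values)
  if (!has_bin) values$bin <- 0L
  is_ref <- values$condition %in% reference
  if (!any(is_ref)) stop("reference group is empty")
  out <- values
  out$fc <- NA_real_
  stats_rows <- list()
  for (b in sort(unique(values$bin))) {
    in_bin <- values$bin == b
    ref_vals <- values$value[in_bin & is_ref]
    if (length(ref_vals) == 0)
      stop("reference group is empty in bin ", b)
    ref_mean <- mean(ref_vals)
    if (!is.finite(ref_mean) || ref_mean == 0)
      stop("reference group mean is zero or non-finite in bin ", b)
    out$fc[in_bin] <- values$value[in_bin] / ref_mean
    for (cond in setdiff(unique(values$condition[in_bin]), reference)) {
      grp <- values$value[in_bin & values$condition == cond]
      stats_rows[[length(stats_rows) + 1L]] <- data.frame(
        condition = cond, bin = b,
        n = length(grp), n_ref = length(ref_vals),
        mean_fc = mean(grp) / ref_mean,
        p = .ranksum_p(grp, ref_vals))
    }
  }
  stats <- if (length(stats_rows)) do.call(rbind, stats_rows) else
    data.frame(condition = character(0), bin = integer(0), n = integer(0),
               n_ref = integer(0), mean_fc = numeric(0), p = numeric(0))
  if (p_adjust && nrow(stats)) stats$p_adj <- p.adjust(stats$p, "BH")
  if (!has_bin) {
    out$bin <- NULL
    stats$bin <- NULL
  }
  list(fc = out, stats = stats)
}

# Otsu threshold on raw intensities: rescale into [0, 1], delegate to
# EBImage, map back to the intensity scale.
.otsu_threshold <- function(intensity, levels = 256L) {
  rng <- range(intensity)
  if (rng[1] == rng[2]) return(rng[1])
  scaled <- matrix((intensity - rng[1]) / (rng[2] - rng[1]), ncol = 1L)
  t01 <- EBImage::otsu(scaled, range = c(0, 1), levels = levels)
  rng[1] + t01 * (rng[2] - rng[1])
}

#' Positive-area fraction of a section
#'
#' Fraction of in-scope pixels whose intensity exceeds a positivity
#' threshold: Otsu's threshold computed on the in-scope intensities
#' (default) or a fixed value. The threshold used is recorded in the
#' `"threshold"` attribute of the result.
#'
#' @param table A `pixel_table`.
#' @param threshold `"otsu"` or a fixed numeric threshold.
#' @param scope One of `"whole"`, `"VZLS"`, `"NC"`.
#' @return Fraction in `[0, 1]` with attribute `threshold`.
#' @export
positive_area_fraction <- function(table, threshold = "otsu",
                                   scope = c("whole", "VZLS", "NC")) {
  scope <- match.arg(scope)
  keep <- switch(scope,
                 whole = rep(TRUE, nrow(table)),
                 VZLS = table$vzls_id >= 2L,
                 NC = table$vzls_id == 0L)
  if (!any(keep)) stop("empty scope '", scope, "'")
  x <- table$intensity[keep]
  if (identical(threshold, "otsu")) {
    t <- .otsu_threshold(x)
  } else {
    stopifnot(is.numeric(threshold), length(threshold) == 1L)
    t <- threshold
    if (t < min(x))
      warning("fixed threshold ", t, " lies below the minimum intensity; ",
              "every in-scope pixel is positive")
  }
  frac <- mean(x > t)
  attr(frac, "threshold") <- t
  frac
}

#' Lineage-marker fractions per organoid
#'
#' Fraction of cells positive for all numerator markers among cells positive
#' for all denominator markers (e.g. BrdU+NEUN+ among BrdU+), per organoid,
#' with fold change versus the uncompressed reference and a two-sided
#' Wilcoxon rank-sum p per condition. The numerator marker set must contain
#' the denominator set; organoids with zero denominator-positive cells are
#' excluded with a warning.
#'
#' @param cells Data frame with columns `organoid_id`, `condition`, and one
#'   logical column per marker.
#' @param numerator,denominator Character vectors of marker column names.
#' @param reference Reference condition labels (default `c("ctrl", "mock")`).
#' @return A list with `fractions` (per organoid) and `stats`
#'   (per condition), as in [fold_change()].
#' @export
lineage_fractions <- function(cells, numerator, denominator,
                              reference = c("ctrl", "mock")) {
  if (!all(denominator %in% numerator))
    stop("numerator markers must be a superset of denominator markers")
  miss <- setdiff(union(numerator, denominator),
                  names(cells))
  if (length(miss)) stop("missing marker column(s): ",
                         paste(miss, collapse = ", "))
  all_pos <- function(markers, rows) {
    if (length(markers) == 0) return(rep(TRUE, sum(rows)))
    Reduce(`&`, lapply(markers, function(m) cells[[m]][rows]))
  }
  orgs <- unique(cells[, c("organoid_id", "condition")])
  orgs$value <- NA_real_
  drop <- logical(nrow(orgs))
  for (i in seq_len(nrow(orgs))) {
    rows <- cells$organoid_id == orgs$organoid_id[i]
    den <- sum(all_pos(denominator, rows))
    if (den == 0) {
      warning("organoid ", orgs$organoid_id[i],
              " has no denominator-positive cells; excluded")
      drop[i] <- TRUE
      next
    }
    orgs$value[i] <- sum(all_pos(numerator, rows)) / den
  }
  orgs <- orgs[!drop, ]
  fcres <- fold_change(orgs, reference = reference)
  list(fractions = fcres$fc, stats = fcres$stats)
}
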