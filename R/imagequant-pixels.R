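#' Section annotation: label map plus boundary polylines
#'
#' Container for the compartment annotation of one organoid section: an
#' integer label map (0 = background, 1 = neuronal compartment NC,
#' 2..k+1 = VZLS ids), ordered boundary polylines (one apical and one basal
#' contour per VZLS, one outer organoid contour), and the physical pixel
#' size. Polyline coordinates are pixel-centre coordinates: pixel
#' `(row, col)` (0-based) sits at `x = col`, `y = row`.
#'
#' @param label_map Integer matrix of compartment labels.
#' @param boundaries Data frame with columns `vzls_id` (0 for the outer
#'   contour), `boundary` (`"apical"`, `"basal"` or `"outer"`), `x_px`,
#'   `y_px`, ordered along each contour.
#' @param pixel_size_um Physical pixel size in micrometres (> 0).
#' @return An object of class `section_annotation`.
#' @export
section_annotation <- function(label_map, boundaries, pixel_size_um) {
  stopifnot(is.matrix(label_map), pixel_size_um > 0)
  need <- c("vzls_id", "boundary", "x_px", "y_px")
  if (!all(need %in% names(boundaries)))
    stop("boundaries must have columns ", paste(need, collapse = ", "))
  bad <- !boundaries$boundary %in% c("apical", "basal", "outer")
  if (any(bad)) stop("unknown boundary kind: ",
                     paste(unique(boundaries$boundary[bad]), collapse = ", "))
  h <- nrow(label_map); w <- ncol(label_map)
  if (any(boundaries$x_px < -0.5 | boundaries$x_px > w - 0.5 |
          boundaries$y_px < -0.5 | boundaries$y_px > h - 0.5))
    stop("boundary polyline coordinates fall outside the image bounds")
  vz_ids <- sort(unique(as.integer(label_map[label_map >= 2L])))
  for (id in vz_ids) {
    for (kind in c("apical", "basal")) {
      if (!any(boundaries$vzls_id == id & boundaries$boundary == kind))
        stop("VZLS ", id, " has no ", kind, " polyline")
    }
  }
  structure(list(label_map = label_map,
                 boundaries = boundaries,
                 pixel_size_um = pixel_size_um),
            class = "section_annotation")
}

# Densify every contour of an annotation to <= `max_spacing` px spacing.
# Returns list(outer = list(x, y), apical = named list by VZLS id, basal = ...).
.densified_boundaries <- function(annotation, max_spacing = 0.5) {
  b <- annotation$boundaries
  dense_one <- function(sel, closed) {
    densify_polyline(b$x_px[sel], b$y_px[sel], max_spacing, closed = closed)
  }
  out <- list(apical = list(), basal = list())
  sel_outer <- b$vzls_id == 0L & b$boundary == "outer"
  if (any(sel_outer)) out$outer <- dense_one(sel_outer, closed = TRUE)
  for (id in unique(b$vzls_id[b$vzls_id > 0L])) {
    for (kind in c("apical", "basal")) {
      sel <- b$vzls_id == id & b$boundary == kind
      if (!any(sel)) next
      pts <- b[sel, ]
      closed <- isTRUE(all.equal(c(pts$x_px[1], pts$y_px[1]),
                                 c(pts$x_px[nrow(pts)], pts$y_px[nrow(pts)]))) ||
        sqrt((pts$x_px[1] - pts$x_px[nrow(pts)])^2 +
             (pts$y_px[1] - pts$y_px[nrow(pts)])^2) <= 2
      out[[kind]][[as.character(id)]] <- dense_one(sel, closed = closed)
    }
  }
  out
}

#' Annotate every in-tissue pixel with its compartment
#'
#' Builds the per-pixel table underlying all section statistics: one row per
#' nonzero-label pixel, carrying the pixel's 0-based coordinates, its raw
#' intensity (copied unmodified) and its compartment. Background pixels are
#' excluded.
#'
#' @param annotation A [section_annotation()].
#' @param intensity Numeric matrix of pixel intensities, same dimensions as
#'   the label map.
#' @return A data frame (`pixel_table`) with columns `row`, `col`,
#'   `intensity`, `vzls_id` (0 for NC), `compartment`, and placeholder
#'   distance columns (`d_apical_um`, `d_basal_um`, `d_outer_um`, `rho`,
#'   `bin`) filled by [boundary_distances()] and [bin_pixels()].
#' @export
annotate_pixels <- function(annotation, intensity) {
  stopifnot(inherits(annotation, "section_annotation"))
  if (!identical(dim(intensity), dim(annotation$label_map)))
    stop("intensity image (", paste(dim(intensity), collapse = "x"),
         ") and label map (", paste(dim(annotation$label_map), collapse = "x"),
         ") dimensions differ")
  lab <- annotation$label_map
  idx <- which(lab > 0L)
  h <- nrow(lab)
  r0 <- (idx - 1L) %% h          # 0-based row
  c0 <- (idx - 1L) %/% h         # 0-based col
  vz <- as.integer(lab[idx])
  n <- length(idx)
  tab <- data.frame(
    row = r0, col = c0,
    intensity = as.numeric(intensity[idx]),
    vzls_id = ifelse(vz >= 2L, vz, 0L),
    compartment = ifelse(vz >= 2L, paste0("VZLS_", vz), "NC"),
    d_apical_um = rep(NA_real_, n), d_basal_um = rep(NA_real_, n),
    d_outer_um = rep(NA_real_, n), rho = rep(NA_real_, n),
    bin = rep(NA_integer_, n))
  class(tab) <- c("pixel_table", "data.frame")
  tab
}

#' Nearest-boundary distances for every pixel
#'
#' Fills `d_apical_um`, `d_basal_um` and `d_outer_um`: the minimum Euclidean
#' distance from each pixel centre to the densified (<= 0.5 px spacing)
#' point set of, respectively, the apical and basal contour of the pixel's
#' own VZLS and the outer organoid contour, converted to micrometres.
#' NC pixels receive only `d_outer_um`; apical/basal distances are defined
#' only inside a VZLS. The compiled search is contractually equal to
#' exhaustive all-pairs search.
#'
#' @param table A `pixel_table` from [annotate_pixels()].
#' @param annotation The matching [section_annotation()].
#' @param max_spacing Polyline densification spacing in px (default 0.5).
#' @return The table with distance columns filled.
#' @export
boundary_distances <- function(table, annotation, max_spacing = 0.5) {
  stopifnot(inherits(annotation, "section_annotation"))
  dens <- .densified_boundaries(annotation, max_spacing)
  um <- annotation$pixel_size_um
  if (!is.null(dens$outer)) {
    table$d_outer_um <- nearest_dist(table$col, table$row,
                                     dens$outer$x, dens$outer$y) * um
  }
  for (id in sort(unique(table$vzls_id[table$vzls_id >= 2L]))) {
    key <- as.character(id)
    if (is.null(dens$apical[[key]]) || is.null(dens$basal[[key]]))
      stop("VZLS ", id, " has pixels but no apical/basal boundary polylines")
    sel <- table$vzls_id == id
    table$d_apical_um[sel] <- nearest_dist(table$col[sel], table$row[sel],
                                           dens$apical[[key]]$x,
                                           dens$apical[[key]]$y) * um
    table$d_basal_um[sel] <- nearest_dist(table$col[sel], table$row[sel],
                                          dens$basal[[key]]$x,
                                          dens$basal[[key]]$y) * um
  }
  table
}

#' Bin VZLS pixels along the apico-basal axis
#'
#' Relative mode divides the apico-basal axis of each VZLS into `n_bins`
#' equally sized bins: `rho = d_apical / (d_apical + d_basal)`,
#' `bin = floor(n_bins * rho)` with `rho = 1` clamped into the last bin, so
#' bin 0 is the most apical and bin `n_bins - 1` the most basal. Width mode
#' bins by absolute apical distance: `bin = floor(d_apical / bin_width_um)`,
#' capped at `max_bin`. Pixels with `d_apical + d_basal == 0` cannot be
#' placed on the axis; they are flagged (`bin = NA`) and counted in a
#' warning. NC pixels are never binned.
#'
#' @param table A `pixel_table` with distances filled.
#' @param mode `"relative"` (default) or `"width"`.
#' @param n_bins Number of relative bins (default 10).
#' @param bin_width_um Width-mode bin size in micrometres (default 20).
#' @param max_bin Width-mode cap on the bin index (default `Inf`).
#' @return The table with `rho` and `bin` filled for VZLS pixels.
#' @export
bin_pixels <- function(table, mode = c("relative", "width"),
                       n_bins = 10L, bin_width_um = 20, max_bin = Inf) {
  mode <- match.arg(mode)
  vz <- table$vzls_id >= 2L
  if (any(vz & (is.na(table$d_apical_um) | is.na(table$d_basal_um))))
    stop("apical/basal distances must be filled before binning; ",
         "run boundary_distances() first")
  dsum <- table$d_apical_um + table$d_basal_um
  degenerate <- vz & dsum == 0
  if (any(degenerate))
    warning(sum(degenerate), " VZLS pixel(s) with d_apical + d_basal = 0 ",
            "flagged and excluded from profiles")
  ok <- vz & !degenerate
  table$rho[ok] <- table$d_apical_um[ok] / dsum[ok]
  if (mode == "relative") {
    b <- floor(n_bins * table$rho[ok])
    b[table$rho[ok] >= 1] <- n_bins - 1L
    table$bin[ok] <- as.integer(b)
  } else {
    b <- floor(table$d_apical_um[ok] / bin_width_um)
    table$bin[ok] <- as.integer(pmin(b, max_bin))
  }
  attr(table, "bin_mode") <- mode
  table
}
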