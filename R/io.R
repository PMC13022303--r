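#' Write a synthetic section to disk
#'
#' Writes the intensity image as 16-bit grayscale TIFF (values scaled by
#' `intensity_max`), the label map as 16-bit integer TIFF (label / 65535),
#' the boundary polylines as CSV (`vzls_id`, `boundary`, `x_px`, `y_px`,
#' ordered) and the ground-truth pixel table as TSV.
#'
#' @param section A `synthetic_section` from [gen_section()].
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix.
#' @param intensity_max Full-scale intensity mapped to 65535.
#' @return Invisibly, the named vector of file paths.
#' @export
write_section <- function(section, dir, prefix = "section",
                          intensity_max = 65535) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    intensity = file.path(dir, paste0(prefix, "_intensity.tif")),
    labels = file.path(dir, paste0(prefix, "_labels.tif")),
    boundaries = file.path(dir, paste0(prefix, "_boundaries.csv")),
    truth = file.path(dir, paste0(prefix, "_truth.tsv")))
  tiff::writeTIFF(pmin(section$intensity / intensity_max, 1),
                  paths["intensity"], bits.per.sample = 16L)
  tiff::writeTIFF(section$annotation$label_map / 65535,
                  paths["labels"], bits.per.sample = 16L)
  write.csv(section$annotation$boundaries, paths["boundaries"],
            row.names = FALSE)
  write.table(section$truth, paths["truth"], sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(paths)
}

#' Read a section annotation from label TIFF and boundary CSV
#'
#' Inverse of the annotation half of [write_section()].
#'
#' @param label_path 16-bit label-map TIFF (integer labels scaled by 1/65535).
#' @param boundary_path Boundary CSV with columns `vzls_id`, `boundary`,
#'   `x_px`, `y_px`.
#' @param pixel_size_um Physical pixel size.
#' @return A [section_annotation()].
#' @export
read_section_annotation <- function(label_path, boundary_path,
                                    pixel_size_um) {
  lab <- round(tiff::readTIFF(label_path) * 65535)
  storage.mode(lab) <- "integer"
  boundaries <- read.csv(boundary_path)
  section_annotation(lab, boundaries, pixel_size_um)
}

#' Read a 16-bit intensity TIFF back to its intensity scale
#'
#' @param path TIFF path.
#' @param intensity_max Full-scale intensity that was mapped to 65535.
#' @return Numeric matrix.
#' @export
read_intensity_image <- function(path, intensity_max = 65535) {
  tiff::readTIFF(path) * intensity_max
}

#' Write and read bulk counts with their sample design
#'
#' Counts as TSV (genes x samples, gene ids in the first column), design as
#' TSV (`sample_id`, `group`).
#'
#' @param counts Genes x samples matrix.
#' @param design Data frame `sample_id`, `group`.
#' @param counts_path,design_path File paths.
#' @return `read_bulk_counts()`: list with `counts` and `design`.
#' @export
write_bulk_counts <- function(counts, design, counts_path, design_path) {
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE)
  write.table(df, counts_path, sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(design, design_path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(c(counts_path, design_path))
}

#' @rdname write_bulk_counts
#' @export
read_bulk_counts <- function(counts_path, design_path) {
  df <- read.delim(counts_path, check.names = FALSE)
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df[[1]]
  list(counts = counts, design = read.delim(design_path))
}

#' Write and read a single-cell matrix as MatrixMarket plus metadata
#'
#' The expression matrix is written as MTX (genes x cells) with gene and
#' cell ids as sidecar TSVs and the per-cell metadata as TSV.
#'
#' @param expr Genes x cells matrix.
#' @param meta Per-cell metadata data frame.
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @return `read_sc_matrix()`: list with `expr` (dense matrix) and `meta`.
#' @export
write_sc_matrix <- function(expr, meta, dir, prefix = "sc") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(mtx = file.path(dir, paste0(prefix, "_matrix.mtx")),
             genes = file.path(dir, paste0(prefix, "_genes.tsv")),
             cells = file.path(dir, paste0(prefix, "_cells.tsv")),
             meta = file.path(dir, paste0(prefix, "_meta.tsv")))
  Matrix::writeMM(methods::as(methods::as(Matrix::Matrix(expr), "CsparseMatrix"),
                              "generalMatrix"), paths["mtx"])
  writeLines(rownames(expr), paths["genes"])
  writeLines(colnames(expr), paths["cells"])
  write.table(meta, paths["meta"], sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(paths)
}

#' @rdname write_sc_matrix
#' @export
read_sc_matrix <- function(dir, prefix = "sc") {
  expr <- as.matrix(Matrix::readMM(file.path(dir, paste0(prefix, "_matrix.mtx"))))
  rownames(expr) <- readLines(file.path(dir, paste0(prefix, "_genes.tsv")))
  colnames(expr) <- readLines(file.path(dir, paste0(prefix, "_cells.tsv")))
  list(expr = expr, meta = read.delim(file.path(dir, paste0(prefix, "_meta.tsv"))))
}
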