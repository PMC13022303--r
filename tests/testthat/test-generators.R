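test_that("noiseless flat sections have a single VZLS intensity and exact FC by construction", {
  st <- section_truth(n_vzls = 2, fc_per_condition = c(uncompressed = 1, comp60 = 1.5),
                      noise_sd = 0, gradient_slope = 0, seed = 42,
                      width = 96, height = 96)
  unc <- gen_section(st, "uncompressed", compute_distances = FALSE)
  cmp <- gen_section(st, "comp60", compute_distances = FALSE)
  vz <- unc$truth$vzls_id >= 2
  expect_length(unique(unc$truth$intensity[vz]), 1L)
  # same truth seed -> identical geometry, so the mean ratio is exact
  expect_identical(cmp$truth$vzls_id, unc$truth$vzls_id)
  expect_equal(mean(cmp$truth$intensity[vz]) / mean(unc$truth$intensity[vz]),
               1.5)
})

test_that("gradient sections encode intensity = base * (1 + rho) with rho from the exhaustive oracle", {
  st <- section_truth(n_vzls = 1, gradient_slope = 1, noise_sd = 0,
                      seed = 9, width = 80, height = 80, pixel_size_um = 1,
                      base_intensity = 1)
  sec <- gen_section(st)
  vz <- which(sec$truth$vzls_id >= 2)
  dens <- mechanoquant:::.densified_boundaries(sec$annotation)
  id <- as.character(sec$truth$vzls_id[vz[1]])
  d_a <- nearest_dist_exhaustive(sec$truth$col[vz], sec$truth$row[vz],
                                 dens$apical[[id]]$x, dens$apical[[id]]$y)
  d_b <- nearest_dist_exhaustive(sec$truth$col[vz], sec$truth$row[vz],
                                 dens$basal[[id]]$x, dens$basal[[id]]$y)
  rho <- d_a / (d_a + d_b)
  expect_equal(sec$truth$intensity[vz], 1 + rho)
})

test_that("section geometry is a valid partition with lumen-facing apical contours", {
  for (seed in c(1, 2, 3)) {
    st <- section_truth(n_vzls = 3, seed = seed, width = 128, height = 128)
    sec <- gen_section(st, compute_distances = FALSE)
    lab <- sec$annotation$label_map
    ids <- sort(unique(as.integer(lab)))
    expect_true(all(ids %in% c(0L, 1L, 2:(2 + st$n_vzls - 1L))))
    b <- sec$annotation$boundaries
    for (id in ids[ids >= 2]) {
      ap <- b[b$vzls_id == id & b$boundary == "apical", ]
      ba <- b[b$vzls_id == id & b$boundary == "basal", ]
      expect_gt(nrow(ap), 0)
      expect_gt(nrow(ba), 0)
      # apical contour lies strictly inside the basal contour polygon
      expect_true(all(point_in_polygon(ap$x_px, ap$y_px, ba$x_px, ba$y_px)))
    }
  }
})

test_that("section generation fails cleanly when the geometry cannot fit", {
  expect_error(gen_section(section_truth(n_vzls = 40, seed = 1,
                                         width = 64, height = 64)),
               "cannot fit")
})

test_that("generators are deterministic: same seed and parameters give identical output", {
  st <- section_truth(n_vzls = 2, noise_sd = 20, positive_fraction = 0.7,
                      seed = 5, width = 80, height = 80)
  expect_identical(gen_section(st, compute_distances = FALSE),
                   gen_section(st, compute_distances = FALSE))
  tt <- trace_truth(noise_sd_N = 1e-4, seed = 5)
  expect_identical(gen_force_trace(tt), gen_force_trace(tt))
  bt <- bulk_truth(n_genes = 200, seed = 5)
  expect_identical(gen_bulk_counts(bt), gen_bulk_counts(bt))
  sct <- sc_truth(n_cells = 100, n_genes = 50, seed = 5)
  expect_identical(gen_sc_matrix(sct), gen_sc_matrix(sct))
})

test_that("noiseless force traces reproduce the per-cycle peaks exactly", {
  tt <- trace_truth(peak_forces_N = c(10e-3, 8e-3, 6e-3), noise_sd_N = 0,
                    seed = 1)
  cy <- extract_cycles(gen_force_trace(tt), 3)
  expect_equal(cy$peak_force_N, c(10e-3, 8e-3, 6e-3))
  one <- trace_truth(n_cycles = 1, peak_forces_N = 5e-3, seed = 2)
  expect_equal(nrow(extract_cycles(gen_force_trace(one), 1)), 1L)
})

test_that("noisy trace peak recovery stays within 3 noise SDs of the truth", {
  sd_n <- 2e-4
  tt <- trace_truth(noise_sd_N = sd_n, seed = 31)
  cy <- extract_cycles(gen_force_trace(tt), 3)
  expect_true(all(abs(cy$peak_force_N - tt$peak_forces_N) <= 3 * sd_n))
})

test_that("trace generation validates the compression level", {
  expect_error(trace_truth(compression_level = 1.2, seed = 1), "0, 1")
  expect_error(trace_truth(compression_level = 0, seed = 1), "0, 1")
})

test_that("null bulk counts at tiny dispersion and large libraries have near-equal group means", {
  bt <- bulk_truth(n_genes = 100, n_samples_per_group = 50,
                   nb_dispersion = 1e-4, library_size = 1e7, seed = 8)
  b <- gen_bulk_counts(bt)
  for (gname in c("ctrl", "comp60")) {
    m <- rowMeans(b$counts[, b$design$group == gname])
    ref <- rowMeans(b$counts[, b$design$group == "mock"])
    expect_true(all(abs(m / ref - 1) < 0.01))
  }
})

test_that("bulk generator validates pathway membership and gene count", {
  expect_error(bulk_truth(n_genes = 0, seed = 1), "n_genes")
  expect_error(bulk_truth(n_genes = 10, seed = 1,
                          pathways = list(P = "gene_11")),
               "not among")
  pw <- list(P = "gene_1")
  lnfc <- matrix(0.5, 1, 4,
                 dimnames = list("P", c("ctrl", "mock", "comp50", "comp60")))
  expect_error(bulk_truth(n_genes = 10, seed = 1, pathways = pw,
                          pathway_lnfc = lnfc),
               "ctrl and mock")
})

test_that("planted QC violators are produced in exactly the requested numbers", {
  sct <- sc_truth(n_cells = 300, n_genes = 80, seed = 3,
                  qc_violation_counts = list(mito = 3, n_genes = 2,
                                             counts_low = 4, counts_high = 1,
                                             gene_floor = 2))
  sc <- gen_sc_matrix(sct)
  expect_equal(sum(sc$meta$mito_frac > 0.07), 3L)
  expect_equal(sum(sc$meta$n_genes < 2500), 2L)
  expect_equal(sum(sc$meta$n_counts < 5000), 4L)
  expect_equal(sum(sc$meta$n_counts > 25000), 1L)
  expect_length(sc$violators$gene_floor, 2L)
})

test_that("sc generator rejects shifts that reference unknown sets or clusters", {
  gs <- list(S = paste0("gene_", 1:5))
  expect_error(sc_truth(n_cells = 50, n_genes = 20, gene_sets = gs, seed = 1,
                        set_shift = data.frame(set = "nope", cluster = 1,
                                               condition = "mock",
                                               delta = 1)),
               "unknown gene set")
  expect_error(sc_truth(n_cells = 50, n_genes = 20, gene_sets = gs, seed = 1,
                        set_shift = data.frame(set = "S", cluster = 99,
                                               condition = "mock",
                                               delta = 1)),
               "unknown cluster")
})

test_that("planted cell-table marker fractions are recovered exactly", {
  orgs <- data.frame(organoid_id = c("o1", "o2", "o3", "o4"),
                     condition = c("ctrl", "mock", "comp60", "comp60"),
                     n_cells = c(100, 120, 80, 90),
                     p_brdu = c(0.5, 0.4, 0.5, 0.6),
                     p_neun = c(0.4, 0.5, 0.7, 0.8),
                     p_ccas3 = c(0.1, 0.1, 0.2, 0.25))
  ct <- gen_cell_table(orgs, seed = 4)
  lf <- lineage_fractions(ct$cells, numerator = c("BrdU", "NEUN"),
                          denominator = "BrdU")
  got <- lf$fractions[order(lf$fractions$organoid_id), ]
  expect_equal(got$value, ct$truth$n_brdu_neun / ct$truth$n_brdu)
})

test_that("synthetic data round-trips through the disk formats", {
  dir <- withr::local_tempdir()
  st <- section_truth(n_vzls = 1, seed = 6, width = 64, height = 64,
                      noise_sd = 10)
  sec <- gen_section(st, compute_distances = FALSE)
  paths <- write_section(sec, dir)
  ann <- read_section_annotation(paths["labels"], paths["boundaries"],
                                 st$pixel_size_um)
  expect_identical(ann$label_map, sec$annotation$label_map)
  img <- read_intensity_image(paths["intensity"])
  expect_lt(max(abs(img - sec$intensity)), 1)  # 16-bit quantisation step
  tr <- gen_force_trace(trace_truth(seed = 6))
  f <- file.path(dir, "trace.csv")
  write_force_trace(tr, f)
  expect_equal(read_force_trace(f)$force_N, tr$force_N)
  b <- gen_bulk_counts(bulk_truth(n_genes = 50, seed = 6))
  write_bulk_counts(b$counts, b$design, file.path(dir, "c.tsv"),
                    file.path(dir, "d.tsv"))
  rb <- read_bulk_counts(file.path(dir, "c.tsv"), file.path(dir, "d.tsv"))
  expect_equal(rb$counts, b$counts)
  expect_equal(rb$design, b$design)
  sc <- gen_sc_matrix(sc_truth(n_cells = 30, n_genes = 20, seed = 6))
  write_sc_matrix(sc$expr, sc$meta, dir)
  rs <- read_sc_matrix(dir)
  expect_equal(rs$expr, sc$expr, tolerance = 1e-12)
  sets <- list(A = c("g1", "g2"), B = c("g3"))
  write_gmt(sets, file.path(dir, "s.gmt"))
  expect_equal(read_gmt(file.path(dir, "s.gmt")), sets)
})
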