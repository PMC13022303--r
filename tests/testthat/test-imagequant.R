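test_that("pixel annotation copies intensities and assigns compartments from the label map", {
  ann <- toy_annotation()
  img <- matrix(seq_len(16), 4, 4)
  tab <- annotate_pixels(ann, img)
  expect_equal(nrow(tab), 16L)
  expect_equal(sum(tab$vzls_id == 2L), 4L)
  expect_equal(sum(tab$compartment == "NC"), 12L)
  expect_equal(tab$intensity[order(tab$row, tab$col)],
               as.numeric(t(img)))
  expect_error(annotate_pixels(ann, matrix(0, 3, 3)), "dimensions differ")
  # all-background map yields an empty table
  empty <- section_annotation(matrix(0L, 4, 4), ann$boundaries, 1)
  expect_equal(nrow(annotate_pixels(empty, img)), 0L)
})

test_that("synthetic-section compartments match the generator truth per pixel", {
  sec <- gen_section(section_truth(n_vzls = 2, seed = 13, width = 96,
                                   height = 96),
                     compute_distances = FALSE)
  tab <- annotate_pixels(sec$annotation, sec$intensity)
  key <- function(d) d[order(d$row, d$col), ]
  expect_equal(key(tab)$compartment, key(sec$truth)$compartment)
})

test_that("boundary distances follow pixel-centre Euclidean geometry", {
  ann <- toy_annotation()
  tab <- boundary_distances(annotate_pixels(ann, matrix(0, 4, 4)), ann)
  px <- tab[tab$row == 1 & tab$col == 1, ]
  expect_equal(px$d_apical_um, 1)  # apical edge at x = 0
  expect_equal(px$d_basal_um, 0)   # basal edge passes through (1, 1)
  on_b <- tab[tab$row == 0 & tab$col == 1, ]
  expect_equal(on_b$d_basal_um, 0)
  expect_equal(nearest_dist_exhaustive(3, 4, 0, 0), 5)
  expect_equal(mechanoquant:::nearest_dist(3, 4, 0, 0), 5)
})

test_that("distance computation fails when a VZLS lacks boundaries", {
  ann <- toy_annotation()
  ann$boundaries <- ann$boundaries[ann$boundaries$vzls_id != 2L, ]
  tab <- annotate_pixels(toy_annotation(), matrix(0, 4, 4))
  expect_error(boundary_distances(tab, ann), "VZLS 2")
})

test_that("compiled nearest-boundary distances equal exhaustive search on random sections", {
  for (seed in 1:3) {
    st <- section_truth(n_vzls = 2, seed = seed, width = 64, height = 64,
                        pixel_size_um = 2)
    sec <- gen_section(st)
    tab <- boundary_distances(annotate_pixels(sec$annotation, sec$intensity),
                              sec$annotation)
    m <- merge(tab, sec$truth, by = c("row", "col"))
    expect_identical(m$d_outer_um.x, m$d_outer_um.y)
    expect_identical(m$d_apical_um.x, m$d_apical_um.y)
    expect_identical(m$d_basal_um.x, m$d_basal_um.y)
  }
})

test_that("relative and width binning follow the stated arithmetic", {
  tab <- data.frame(row = 0:4, col = 0, intensity = 1, vzls_id = 2L,
                    compartment = "VZLS_2",
                    d_apical_um = c(0.5, 9.5, 10, 30, 5),
                    d_basal_um = c(9.5, 0.5, 0, 10, 5),
                    d_outer_um = 1, rho = NA_real_, bin = NA_integer_)
  out <- bin_pixels(tab, "relative")
  expect_equal(out$rho, c(0.05, 0.95, 1, 0.75, 0.5))
  expect_equal(out$bin, c(0L, 9L, 9L, 7L, 5L))
  outw <- bin_pixels(tab, "width", bin_width_um = 20)
  expect_equal(outw$bin[4], 1L)  # d_apical 30 um -> second 20 um bin
  # degenerate rows are flagged with a warning and excluded from profiles
  tab$d_apical_um[1] <- 0; tab$d_basal_um[1] <- 0
  expect_warning(out2 <- bin_pixels(tab), "flagged")
  expect_true(is.na(out2$bin[1]))
})

test_that("rho is monotone along straight-walled VZLS and hits 0/1 on the contours", {
  sec <- band_section(seed = 2)
  tab <- bin_pixels(boundary_distances(
    annotate_pixels(sec$annotation, sec$intensity), sec$annotation))
  vz <- tab[tab$vzls_id == 2L, ]
  for (cc in unique(vz$col)) {
    colpx <- vz[vz$col == cc, ]
    colpx <- colpx[order(colpx$row), ]
    expect_true(all(diff(colpx$rho) > 0))
  }
  top <- vz[vz$row == min(vz$row), ]
  bot <- vz[vz$row == max(vz$row), ]
  expect_true(all(top$rho == 0))
  expect_true(all(bot$rho == 1))
  # straight walls fill relative bins near-uniformly
  counts <- table(vz$bin)
  expect_lte(max(counts) / min(counts), 1.2)
})

test_that("intensity summaries honour scopes and warn on empty selections", {
  ann <- toy_annotation()
  img <- matrix(3, 4, 4); img[1:2, 1:2] <- 7
  tab <- annotate_pixels(ann, img)
  expect_equal(intensity_summary(tab, "VZLS"), 7)
  expect_equal(intensity_summary(tab, "NC"), 3)
  expect_equal(intensity_summary(tab, "whole"), (4 * 7 + 12 * 3) / 16)
  expect_warning(res <- intensity_summary(tab[tab$vzls_id == 2L, ], "NC"),
                 "empty selection")
  expect_true(is.na(res))
})

test_that("bin-scoped means of a linear gradient match the closed-form bin centres", {
  sec <- band_section(seed = 3, gradient_slope = 1, base_intensity = 1)
  tab <- bin_pixels(boundary_distances(
    annotate_pixels(sec$annotation, sec$intensity), sec$annotation))
  prof <- intensity_summary(tab, "bin")
  # uniform pixel density over rho in [0,1]: bin k mean = 1 + (k + 0.5) / 10
  expect_equal(prof$mean_intensity, 1 + (prof$bin + 0.5) / 10,
               tolerance = 0.02)
})

test_that("fold change is 1 on the reference group, scale-invariant, and p = 1 for identical groups", {
  vals <- data.frame(organoid_id = paste0("o", 1:12),
                     condition = rep(c("ctrl", "mock", "comp60"), each = 4),
                     value = c(10, 11, 9, 10, 10.5, 9.5, 10, 10, 15, 16,
                               14, 15))
  res <- fold_change(vals)
  ref <- res$fc$condition %in% c("ctrl", "mock")
  expect_equal(mean(res$fc$fc[ref]), 1)
  scaled <- vals; scaled$value <- scaled$value * 37
  expect_equal(fold_change(scaled)$fc$fc, res$fc$fc)
  same <- data.frame(organoid_id = paste0("o", 1:8),
                     condition = rep(c("mock", "comp60"), each = 4),
                     value = rep(c(1, 2, 3, 4), 2))
  expect_equal(fold_change(same)$stats$p, 1)
  expect_error(fold_change(data.frame(organoid_id = "a", condition = "comp60",
                                      value = 1)),
               "reference group is empty")
})

test_that("per-bin fold change uses the matching bin's reference mean", {
  vals <- expand.grid(organoid_id = paste0("o", 1:4), bin = 0:1)
  vals$condition <- rep(c("mock", "mock", "comp60", "comp60"), 2)
  vals$value <- c(10, 10, 20, 20, 100, 100, 300, 300)
  res <- fold_change(vals)
  expect_equal(res$stats$mean_fc[res$stats$bin == 0], 2)
  expect_equal(res$stats$mean_fc[res$stats$bin == 1], 3)
})

test_that("positive-area fractions handle fixed thresholds, Otsu and bounds", {
  tab <- data.frame(row = 0, col = 0:9, intensity = c(rep(0, 5), rep(10, 5)),
                    vzls_id = 0L, compartment = "NC",
                    d_apical_um = NA, d_basal_um = NA, d_outer_um = NA,
                    rho = NA, bin = NA)
  expect_equal(as.numeric(positive_area_fraction(tab, threshold = 5)), 0.5)
  zero <- tab; zero$intensity <- 0
  expect_equal(as.numeric(positive_area_fraction(zero, threshold = 1)), 0)
  expect_warning(f1 <- positive_area_fraction(tab, threshold = -1),
                 "below the minimum")
  expect_equal(as.numeric(f1), 1)
  # monotone nonincreasing in the fixed threshold
  sec <- gen_section(section_truth(n_vzls = 1, seed = 21, width = 64,
                                   height = 64, positive_fraction = 0.6,
                                   noise_sd = 30),
                     compute_distances = FALSE)
  stab <- annotate_pixels(sec$annotation, sec$intensity)
  ts <- seq(0, 1200, by = 100)
  fr <- vapply(ts, function(t)
    as.numeric(positive_area_fraction(stab, threshold = t)), numeric(1))
  expect_true(all(diff(fr) <= 0))
  expect_true(all(fr >= 0 & fr <= 1))
})

test_that("Otsu thresholding recovers the planted positive fraction within 0.02", {
  for (seed in c(5, 6, 7)) {
    f <- 0.35
    sec <- gen_section(section_truth(n_vzls = 2, seed = seed, width = 96,
                                     height = 96, positive_fraction = f,
                                     noise_sd = 30),
                       compute_distances = FALSE)
    tab <- annotate_pixels(sec$annotation, sec$intensity)
    est <- as.numeric(positive_area_fraction(tab, "otsu"))
    truth_f <- mean(sec$truth$positive)
    expect_lte(abs(est - truth_f), 0.02)
  }
})

test_that("lineage fractions divide numerator by denominator positives with exclusions", {
  cells <- data.frame(
    cell_id = 1:20, organoid_id = rep(c("a", "b"), each = 10),
    condition = rep(c("mock", "comp60"), each = 10),
    BrdU = c(rep(TRUE, 10), rep(c(TRUE, FALSE), 5)),
    NEUN = c(rep(c(TRUE, FALSE, FALSE, FALSE, FALSE), 2),
             rep(TRUE, 10)))
  res <- lineage_fractions(cells, c("BrdU", "NEUN"), "BrdU")
  a <- res$fractions[res$fractions$organoid_id == "a", ]
  expect_equal(a$value, 0.2)
  expect_error(lineage_fractions(cells, "BrdU", c("BrdU", "NEUN")),
               "superset")
  none <- cells; none$BrdU[none$organoid_id == "b"] <- FALSE
  expect_warning(r2 <- lineage_fractions(none, c("BrdU", "NEUN"), "BrdU",
                                         reference = "mock"),
                 "no denominator-positive")
  expect_false("b" %in% r2$fractions$organoid_id)
})
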