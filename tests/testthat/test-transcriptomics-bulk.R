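test_that("CPM log-normalisation follows the stated arithmetic and is depth-invariant", {
  m <- matrix(c(10, 0), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  out <- cpm_log_normalize(m)
  expect_equal(out["g1", 1], log2(1e6 + 1))
  expect_equal(out["g2", 1], 0)
  counts <- matrix(rpois(40, 50), 10, 4,
                   dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
  doubled <- counts; doubled[, 2] <- doubled[, 2] * 2L
  expect_equal(cpm_log_normalize(doubled)[, 2], cpm_log_normalize(counts)[, 2])
  zero <- counts; zero[, 3] <- 0L
  expect_error(cpm_log_normalize(zero), "zero library")
})

test_that("DE gating: identical groups pass nothing; spiked genes pass; FC gate blocks small effects", {
  design <- data.frame(sample_id = paste0("s", 1:16),
                       group = rep(c("A", "B"), each = 8))
  base <- withr::with_seed(1, matrix(rnorm(1000 * 16, 8, 0.2), 1000, 16,
                                     dimnames = list(paste0("g", 1:1000),
                                                     design$sample_id)))
  same <- de_genes(base, design, list("A", "B"))
  expect_equal(sum(same$pass), 0L)
  spiked <- base
  spiked[1:50, design$group == "B"] <- spiked[1:50, design$group == "B"] + 4
  res <- de_genes(spiked, design, list("B", "A"))
  expect_gte(sum(res$pass[1:50]), 45L)
  expect_equal(sum(res$pass[-(1:50)]), 0L)
  # strong but sub-threshold fold change fails the FC gate
  mild <- base
  mild[1, design$group == "B"] <- mild[1, design$group == "B"] + 1.5
  r1 <- de_genes(mild, design, list("B", "A"))[1, ]
  expect_lt(r1$p, 0.01)
  expect_false(r1$pass)
  expect_error(de_genes(base, design[1:9, ], list("A", "B")), ">= 2 samples")
})

test_that("DE triple gate controls type I error on pure-null simulations", {
  design <- data.frame(sample_id = paste0("s", 1:12),
                       group = rep(c("A", "B"), each = 6))
  passes <- vapply(1:20, function(s) {
    m <- withr::with_seed(s, matrix(rnorm(1000 * 12, 8, 0.5), 1000, 12,
                                    dimnames = list(paste0("g", 1:1000),
                                                    design$sample_id)))
    sum(de_genes(m, design, list("A", "B"))$pass)
  }, numeric(1))
  expect_lt(mean(passes), 1)
})

test_that("exclusive set intersections match per-gene enumeration", {
  res <- set_intersections(list(A = c("a", "b", "c"), B = c("b", "c", "d")))
  expect_equal(res$count[res$combination == "A"], 1L)
  expect_equal(res$count[res$combination == "B"], 1L)
  expect_equal(res$count[res$combination == "A&B"], 2L)
  dis <- set_intersections(list(A = "a", B = "b"))
  expect_false("A&B" %in% dis$combination)
  # brute-force oracle on random sets
  sets <- withr::with_seed(7, lapply(1:3, function(i)
    sample(paste0("g", 1:40), 15)))
  names(sets) <- c("X", "Y", "Z")
  res3 <- set_intersections(sets)
  genes <- unique(unlist(sets))
  oracle <- table(vapply(genes, function(g)
    paste(names(sets)[vapply(sets, function(s) g %in% s, logical(1))],
          collapse = "&"), character(1)))
  expect_equal(sum(res3$count), length(genes))
  for (comb in names(oracle))
    expect_equal(res3$count[res3$combination == comb],
                 as.integer(oracle[[comb]]))
  expect_error(set_intersections(list(A = "a")), "2 sets")
})

test_that("pathway deviation is 0 at the reference mean and exactly ln(k) under global scaling", {
  pw <- list(P1 = paste0("gene_", 1:5), P2 = paste0("gene_", 6:9))
  design <- data.frame(sample_id = paste0("s", 1:6),
                       group = rep(c("ctrl", "mock", "comp60"), each = 2))
  expr <- withr::with_seed(2, matrix(runif(10 * 6, 50, 150), 10, 6,
                                     dimnames = list(paste0("gene_", 1:10),
                                                     design$sample_id)))
  mu <- rowMeans(expr[, 1:4])
  # a sample equal to the uncompressed mean scores 0 in every pathway
  expr[, 5] <- mu
  # a sample with every gene multiplied by e scores exactly 1
  expr[, 6] <- mu * exp(1)
  dv <- pathway_deviation(expr, design, pw, eps = 0, normalize = FALSE)
  expect_equal(unname(dv$scores[, "s5"]), c(0, 0))
  expect_equal(unname(dv$scores[, "s6"]), c(1, 1))
  # invariance to pathway gene ordering
  pw_rev <- lapply(pw, rev)
  dv2 <- pathway_deviation(expr, design, pw_rev, eps = 0, normalize = FALSE)
  expect_equal(dv2$scores, dv$scores)
  # multiplying one sample by k shifts its scores by ln(k)
  scaled <- expr; scaled[, 6] <- scaled[, 6] * 3
  dv3 <- pathway_deviation(scaled, design, pw, eps = 0, normalize = FALSE)
  expect_equal(unname(dv3$scores[, "s6"] - dv$scores[, "s6"]),
               rep(log(3), 2))
})

test_that("pathway deviation recovers injected ln fold changes from NB counts with significant Tukey contrasts", {
  pw <- bulk_pathways()
  lnfc <- lnfc_matrix(pw)
  lnfc["P1", "comp60"] <- 0.7
  hits <- 0L
  for (s in 1:10) {
    bt <- bulk_truth(n_genes = 2000, n_samples_per_group = 6, pathways = pw,
                     pathway_lnfc = lnfc, seed = s)
    b <- gen_bulk_counts(bt)
    dv <- pathway_deviation(b$counts, b$design, pw)
    d60 <- mean(dv$scores["P1", b$design$group == "comp60"])
    p60 <- dv$tests$p_unc_vs_comp60[dv$tests$pathway == "P1"]
    tier <- dv$tests$tier[dv$tests$pathway == "P1"]
    if (abs(d60 - 0.7) <= 0.1 && p60 < 0.05) hits <- hits + 1L
    expect_true(tier %in% c("60-only", "both"))
  }
  expect_gte(hits, 10L * 0.95 - 1L)
})

test_that("pathways without dataset genes are dropped with a warning", {
  design <- data.frame(sample_id = paste0("s", 1:8),
                       group = rep(c("ctrl", "mock", "comp50", "comp60"),
                                   each = 2))
  expr <- withr::with_seed(5,
    matrix(runif(3 * 8, 5, 15), 3, 8,
           dimnames = list(paste0("gene_", 1:3), design$sample_id)))
  expect_warning(
    dv <- pathway_deviation(expr, design,
                            list(ok = "gene_1", gone = "gene_99"),
                            normalize = FALSE),
    "gone")
  expect_equal(rownames(dv$scores), "ok")
})

test_that("term enrichment equals the hypergeometric tail and applies both gates", {
  universe <- paste0("g", 1:100)
  de <- paste0("g", 1:20)
  # a term equal to the whole universe is never enriched
  full <- term_enrichment(de, universe, list(all = universe))
  expect_equal(full$p, 1)
  # significant p but fewer than 5 DE genes fails the count gate
  small <- term_enrichment(de, universe, list(t = paste0("g", 1:4)))
  expect_lt(small$p, 0.05)
  expect_false(small$pass)
  # random tables against fisher.test and an explicit lchoose enumeration
  for (s in 1:20) {
    tbl <- withr::with_seed(s, {
      pick <- function(x) x[sample.int(length(x), 1)]
      N <- pick(10:30); K <- pick(0:N); n <- pick(0:N)
      k <- pick(max(0, K + n - N):min(K, n))
      c(N = N, K = K, n = n, k = k)
    })
    universe_s <- paste0("u", seq_len(tbl["N"]))
    de_s <- universe_s[seq_len(tbl["K"])]
    term_s <- universe_s[c(seq_len(tbl["k"]),
                           setdiff(seq_len(tbl["N"]), seq_len(tbl["K"]))[
                             seq_len(tbl["n"] - tbl["k"])])]
    p_pkg <- term_enrichment(de_s, universe_s, list(t = term_s))$p
    js <- max(0, tbl["K"] + tbl["n"] - tbl["N"])
    je <- min(tbl["K"], tbl["n"])
    enum <- sum(vapply(tbl["k"]:je, function(j)
      exp(lchoose(tbl["K"], j) + lchoose(tbl["N"] - tbl["K"], tbl["n"] - j) -
            lchoose(tbl["N"], tbl["n"])), numeric(1)))
    expect_equal(p_pkg, min(enum, 1), tolerance = 1e-12)
    ft <- fisher.test(matrix(c(tbl["k"], tbl["K"] - tbl["k"],
                               tbl["n"] - tbl["k"],
                               tbl["N"] - tbl["K"] - tbl["n"] + tbl["k"]),
                             2, 2), alternative = "greater")
    expect_equal(p_pkg, ft$p.value, tolerance = 1e-9)
  }
  expect_error(term_enrichment(de, character(0), list()), "empty")
  expect_error(term_enrichment("zzz", universe, list()), "subset")
})

test_that("top_terms returns the best passing terms only", {
  universe <- paste0("g", 1:200)
  de <- paste0("g", 1:30)
  terms <- withr::with_seed(3, c(list(hit = paste0("g", 1:10)),
             setNames(lapply(1:20, function(i)
               paste0("g", sample(31:200, 10))), paste0("null", 1:20))))
  res <- term_enrichment(de, universe, terms)
  tops <- top_terms(res, 15)
  expect_lte(nrow(tops), 15)
  expect_true(all(tops$pass))
  expect_equal(tops$term[1], "hit")
})
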