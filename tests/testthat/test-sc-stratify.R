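make_counts <- function(m, genes = NULL, cells = NULL) {
  genes <- genes %||% sprintf("g%03d", seq_len(nrow(m)))
  cells <- cells %||% sprintf("c%03d", seq_len(ncol(m)))
  dimnames(m) <- list(genes, cells)
  expr_matrix(m, layer = "counts")
}

test_that("qc_filter applies the detected-gene and mitochondrial rules strictly", {
  # 6 cells engineered so exactly 4 pass with min_genes = 3, max_genes = 5,
  # max_mito = 0.10:
  #  c1: 4 detected, no mito          -> keep
  #  c2: 2 detected (< 3)             -> drop
  #  c3: 5 detected (boundary)        -> keep
  #  c4: 3 detected (boundary)        -> keep
  #  c5: mito fraction 0.12 (> 0.10)  -> drop
  #  c6: mito fraction exactly 0.10   -> keep (boundary)
  m <- matrix(0L, 6, 6)
  m[1:4, 1] <- 5L
  m[1:2, 2] <- 5L
  m[1:5, 3] <- 5L
  m[1:3, 4] <- 5L
  m[c(1, 2, 6), 5] <- c(22L, 22L, 6L)   # mito g006 = 6/50 = 0.12
  m[c(1, 2, 6), 6] <- c(27L, 18L, 5L)   # mito g006 = 5/50 = 0.10
  counts <- make_counts(m)
  kept <- qc_filter(counts, mito_genes = "g006", min_genes = 3, max_genes = 5,
                    max_mito_frac = 0.10)
  expect_length(kept, 4L)
  expect_setequal(kept, c("c001", "c003", "c004", "c006"))
})

test_that("qc_filter matches the published cell-level thresholds", {
  # a cell with 450 detected genes is excluded; 500 exactly is kept
  m <- matrix(0L, 600, 3)
  m[1:450, 1] <- 1L
  m[1:500, 2] <- 1L
  m[1:550, 3] <- 1L
  counts <- make_counts(m)
  kept <- qc_filter(counts, mito_genes = character(0))
  expect_setequal(kept, c("c002", "c003"))
  expect_warning(qc_filter(make_counts(matrix(0L, 5, 2)),
                           mito_genes = character(0)),
                 "no cell")
})

test_that("lognormalize matches the closed-form transform", {
  m <- matrix(c(10L, 990L, 1000L, 0L), 2, 2)
  em <- lognormalize(make_counts(m))
  expect_equal(em$layer, "lognorm")
  # count 10 of total 1000 at scale 10000: ln(101)
  expect_equal(as.numeric(em$values[1, 1]), log(101), tolerance = 1e-10)
  expect_equal(round(as.numeric(em$values[1, 1]), 5), 4.61512)
  # count = total: ln(1 + 10000)
  expect_equal(as.numeric(em$values[1, 2]), log(10001), tolerance = 1e-10)
  expect_equal(round(as.numeric(em$values[1, 2]), 5), 9.21044)
  # zero count stays zero
  expect_equal(as.numeric(em$values[2, 2]), 0)

  z <- make_counts(matrix(c(1L, 0L, 0L, 0L), 2, 2))
  expect_error(lognormalize(z), class = "mrmediate_domain_error")
})

test_that("module_score is zero on a constant matrix and detects activity", {
  # constant matrix: control mean always equals set mean
  m <- matrix(3L, 60, 20)
  em <- lognormalize(make_counts(m))
  sc <- suppressWarnings(module_score(em, gene_set = c("g001", "g002"),
                                      n_bins = 5, n_ctrl = 10, seed = 1))
  expect_true(all(sc$score == 0))

  # elevated gene set in a known half of cells
  sim <- simulate_expression(400, 200, gene_set = sprintf("gene%04d", 1:15),
                             activity_effect = 2, seed = 4)
  ln <- lognormalize(sim$counts)
  sc2 <- suppressWarnings(module_score(ln, sprintf("gene%04d", 1:15),
                                       n_ctrl = 20, seed = 5))
  active <- sc2$barcode %in% sim$truth$active_cells
  expect_gt(mean(sc2$score[active]), mean(sc2$score[!active]))

  expect_error(module_score(ln, c("absent1", "absent2"), seed = 1),
               class = "mrmediate_domain_error")
})

test_that("module_score is reproducible and location-invariant", {
  sim <- simulate_expression(300, 100, gene_set = sprintf("gene%04d", 1:10),
                             activity_effect = 2, seed = 9)
  ln <- lognormalize(sim$counts)
  a <- suppressWarnings(module_score(ln, sprintf("gene%04d", 1:10),
                                     n_ctrl = 15, seed = 42))
  b <- suppressWarnings(module_score(ln, sprintf("gene%04d", 1:10),
                                     n_ctrl = 15, seed = 42))
  expect_identical(a$score, b$score)

  shifted <- expr_matrix(as.matrix(ln$values) + 1.5, layer = "lognorm")
  c <- suppressWarnings(module_score(shifted, sprintf("gene%04d", 1:10),
                                     n_ctrl = 15, seed = 42))
  expect_equal(c$score, a$score, tolerance = 1e-12)
})

test_that("stratify_by_median uses strict-majority labelling with ties to low", {
  g <- stratify_by_median(c(1, 2, 3, 4))
  expect_equal(as.character(g), c("low", "low", "high", "high"))
  g3 <- stratify_by_median(c(1, 2, 3))
  expect_equal(as.character(g3), c("low", "low", "high"))
  expect_warning(ge <- stratify_by_median(c(2, 2, 2)), "median")
  expect_true(all(ge == "low"))
  expect_error(stratify_by_median(1), class = "mrmediate_domain_error")
})

test_that("wilcoxon_deg finds no genes under a label permutation and all spiked ones", {
  sim <- simulate_expression(500, 300, gene_set = character(0),
                             activity_effect = 1, n_deg = 5, deg_fold = 4,
                             seed = 13)
  ln <- lognormalize(sim$counts)
  truth_high <- colnames(ln$values) %in% sim$truth$active_cells

  # true labels: exactly the spiked genes pass
  deg <- wilcoxon_deg(ln, ifelse(truth_high, "high", "low"))
  expect_setequal(deg$gene[deg$pass], sim$truth$deg_genes)

  # permuted labels: nothing passes
  set.seed(3)
  perm <- sample(ifelse(truth_high, "high", "low"))
  deg0 <- wilcoxon_deg(ln, perm)
  expect_equal(sum(deg0$pass), 0L)

  # constant gene (equal library sizes) never passes and reports p = 1
  m <- matrix(2L, 30, 40)
  cm <- lognormalize(make_counts(m))
  degc <- wilcoxon_deg(cm, rep(c("high", "low"), each = 20), min_pct = 0)
  expect_equal(degc$pval[1], 1)
  expect_false(degc$pass[1])

  expect_error(wilcoxon_deg(ln, rep("high", ncol(ln$values))),
               class = "mrmediate_domain_error")
})

test_that("rank-sum p-values agree with the reference test and are null-uniform", {
  # oracle: stats::wilcox.test normal approximation with tie correction
  set.seed(8)
  x <- rpois(60, 3)
  grp <- rep(c("high", "low"), each = 30)
  m <- matrix(x, 1, 60, dimnames = list("g1", sprintf("c%02d", 1:60)))
  em <- expr_matrix(log1p(m), layer = "lognorm")
  ours <- wilcoxon_deg(em, grp, min_pct = 0)$pval[1]
  ref <- wilcox.test(log1p(x[grp == "high"]), log1p(x[grp == "low"]),
                     exact = FALSE, correct = FALSE)$p.value
  expect_equal(ours, ref, tolerance = 1e-10)

  # permuted-label null over many genes: p-values approximately uniform
  sim <- simulate_expression(2000, 200, gene_set = character(0),
                             activity_effect = 1, seed = 17)
  ln <- lognormalize(sim$counts)
  set.seed(11)
  labels <- sample(rep(c("high", "low"), each = 100))
  pv <- wilcoxon_deg(ln, labels)$pval
  pv <- pv[!is.na(pv)]
  ks <- suppressWarnings(ks.test(pv, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("QC plus stratification conserves cell counts", {
  sim <- simulate_expression(600, 150, gene_set = sprintf("gene%04d", 1:10),
                             activity_effect = 2, seed = 21)
  kept <- qc_filter(sim$counts, mito_genes = character(0), min_genes = 50,
                    max_genes = 600)
  ln <- lognormalize(sim$counts)
  keep_idx <- colnames(ln$values) %in% kept
  sub <- expr_matrix(ln$values[, keep_idx], layer = "lognorm")
  sc <- suppressWarnings(module_score(sub, sprintf("gene%04d", 1:10),
                                      n_ctrl = 20, seed = 2))
  g <- stratify_by_median(sc)
  expect_equal(sum(g == "high") + sum(g == "low"), length(kept))
})

test_that("expression matrices round-trip through MatrixMarket files", {
  sim <- simulate_expression(50, 20, gene_set = character(0), seed = 30)
  dir <- withr::local_tempdir()
  write_expression_mtx(sim$counts, dir)
  back <- read_expression_mtx(dir)
  expect_equal(as.matrix(back$values), as.matrix(sim$counts$values))
  expect_equal(rownames(back$values), rownames(sim$counts$values))
})
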