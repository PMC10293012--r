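test_that("low-depth sample exclusion respects the strict one-million boundary", {
  counts <- cbind(A = c(999999, 0), B = c(1e6, 0), C = c(2e6, 0))
  rownames(counts) <- c("G1", "G2")
  m <- make_expr(counts)
  out <- suppressMessages(qc_min_counts(m))
  expect_identical(colnames(out$counts), c("B", "C"))
  expect_identical(attr(out, "excluded"), "A")

  counts2 <- rbind(c(2e6, 5e5, 1.5e6))
  rownames(counts2) <- "G1"; colnames(counts2) <- c("S1", "S2", "S3")
  out2 <- suppressMessages(qc_min_counts(make_expr(counts2)))
  expect_equal(ncol(out2$counts), 2)

  expect_error(suppressMessages(qc_min_counts(make_expr(counts2), 1e9)),
               "all samples")
})

test_that("TMM factors are unity for identical or purely depth-scaled samples", {
  set.seed(1)
  x <- rpois(60, 50) + 1
  m <- cbind(A = x, B = x)
  rownames(m) <- sprintf("G%02d", 1:60)
  expect_equal(unname(tmm_factors(m)), c(1, 1))
  m2 <- cbind(A = x, B = 2 * x)
  rownames(m2) <- rownames(m)
  expect_equal(unname(tmm_factors(m2)), c(1, 1))
})

test_that("TMM factors match the direct trim-and-weight oracle and edgeR", {
  set.seed(42)
  for (rep in 1:5) {
    counts <- matrix(rpois(50 * 3, 60) + 1, 50, 3,
                     dimnames = list(sprintf("G%02d", 1:50), c("A", "B", "C")))
    infl <- sample(50, 3)                       # ~5% of genes 10-fold inflated
    counts[infl, 2] <- counts[infl, 2] * 10
    f <- tmm_factors(counts)
    expect_equal(unname(f), oracle_tmm(counts), tolerance = 1e-12)
    f_edger <- edgeR::calcNormFactors(counts, method = "TMM")
    expect_equal(unname(f), unname(f_edger), tolerance = 1e-10)
  }
})

test_that("log-CPM follows its closed form and is depth-invariant", {
  m <- matrix(c(0, 999.5), 2, 1, dimnames = list(c("G1", "G2"), "S1"))
  m[2, 1] <- 999.5
  lib_fill <- 1e6 - sum(m)                       # pad to an exact 1e6 library
  m <- rbind(m, G3 = lib_fill)
  lc <- log_cpm(m, factors = 1)
  expect_equal(lc["G1", 1], log2(0.5))
  expect_equal(lc["G2", 1], log2(1000))

  set.seed(2)
  x <- matrix(rpois(40, 30), 20, 2,
              dimnames = list(sprintf("G%02d", 1:20), c("A", "B")))
  expect_equal(log_cpm(2 * x, prior_count = 0), log_cpm(x, prior_count = 0))
})

test_that("expression filter equals direct evaluation of the stated rule", {
  groups <- rep(c("a", "b"), c(5, 3))
  zero <- matrix(0, 1, 8, dimnames = list("GZ", sprintf("S%d", 1:8)))
  expect_length(filter_by_expression(zero, groups), 0)

  ten <- matrix(c(rep(0, 5), rep(10, 3)), 1, 8,
                dimnames = list("GT", sprintf("S%d", 1:8)))
  expect_identical(filter_by_expression(ten, groups), "GT")  # total 30 >= 15

  set.seed(7)
  counts <- matrix(rpois(50 * 8, rep(c(2, 8, 15), length.out = 50)), 50, 8,
                   dimnames = list(sprintf("G%02d", 1:50), sprintf("S%d", 1:8)))
  kept <- filter_by_expression(counts, groups)
  expect_identical(kept, oracle_filter_by_expression(counts, groups))
  expect_gt(length(kept), 0)
  expect_lt(length(kept), 50)
})

test_that("differential expression is antisymmetric under group swap", {
  set.seed(3)
  counts <- matrix(rnbinom(200 * 8, size = 10, mu = 100), 200, 8,
                   dimnames = list(sprintf("G%03d", 1:200), sprintf("S%d", 1:8)))
  m <- make_expr(counts)
  d1 <- dea_two_group(m, 1:4, 5:8)
  d2 <- dea_two_group(m, 5:8, 1:4)
  expect_equal(d1$log2fc, -d2$log2fc)
  expect_equal(d1$p, d2$p)
})

test_that("a planted eight-fold effect is detected with low dispersion", {
  set.seed(4)
  mu <- rep(100, 300)
  counts_a <- matrix(rnbinom(300 * 6, size = 50, mu = mu), 300, 6)
  mu_b <- mu; mu_b[1] <- mu[1] * 8
  counts_b <- matrix(rnbinom(300 * 6, size = 50, mu = mu_b), 300, 6)
  counts <- cbind(counts_a, counts_b)
  dimnames(counts) <- list(sprintf("G%03d", 1:300), sprintf("S%02d", 1:12))
  res <- dea_two_group(make_expr(counts), 7:12, 1:6)
  expect_true(res$pass[res$gene == "G001"])
  expect_gt(res$log2fc[res$gene == "G001"], log2(2))
})

test_that("fold-change cut of 1 degenerates to FDR-only filtering", {
  set.seed(5)
  counts <- matrix(rnbinom(100 * 8, size = 10, mu = 80), 100, 8,
                   dimnames = list(sprintf("G%03d", 1:100), sprintf("S%d", 1:8)))
  res <- dea_two_group(make_expr(counts), 1:4, 5:8, fc_cut = 1)
  expect_identical(res$pass, res$fdr < 0.05 & abs(res$log2fc) > 0)
})

test_that("null label permutations stay calibrated at the nominal FDR", {
  set.seed(6)
  rates <- replicate(20, {
    counts <- matrix(rnbinom(500 * 10, size = 5, mu = 100), 500, 10,
                     dimnames = list(sprintf("G%03d", 1:500),
                                     sprintf("S%02d", 1:10)))
    res <- dea_two_group(make_expr(counts), 1:5, 6:10)
    mean(res$pass)
  })
  expect_lte(mean(rates), 0.05)
})

test_that("contamination filter recovers planted tumor genes on the cohort", {
  co <- default_cohort(1)
  bulk <- suppressMessages(qc_min_counts(co$bulk))
  t_cells <- subset_expr(bulk, samples = which(bulk$meta$population %in% c("CD4", "CD8")))
  cd45neg <- subset_expr(bulk, samples = which(bulk$meta$population == "CD45neg"))
  res <- contamination_filter(t_cells, cd45neg)
  planted <- co$truth$contamination_genes
  expect_gte(length(intersect(res$removed, planted)) / length(planted), 0.9)
  expect_lte(length(setdiff(res$removed, planted)), 5)
  expect_false(any(res$removed %in% rownames(res$filtered$counts)))
  ## removed-set size is bounded by n_top per disease group
  expect_lte(length(res$removed), 250 * 2)
})

test_that("contamination filter intersection logic spares balanced and low-rank genes", {
  ## 30 genes; G01 massively tumor-enriched and highly expressed (removed);
  ## G02 tumor-enriched but lowly expressed so outside the top-n (kept);
  ## G03 highly expressed but balanced between populations (kept)
  set.seed(8)
  n_g <- 30
  mu_t <- rep(100, n_g); mu_c <- rep(100, n_g)
  mu_c[1] <- 50000; mu_t[1] <- 100
  mu_c[2] <- 20;    mu_t[2] <- 0.1
  base <- function(mu, n) matrix(rnbinom(n_g * n, size = 50, mu = mu), n_g, n)
  tc <- base(mu_t, 6); cc <- base(mu_c, 4)
  dimnames(tc) <- list(sprintf("G%02d", 1:n_g), sprintf("T%d", 1:6))
  dimnames(cc) <- list(sprintf("G%02d", 1:n_g), sprintf("C%d", 1:4))
  t_m <- expression_matrix(tc, data.frame(
    patient = sprintf("P%d", 1:6), compartment = rep(c("blood", "tumor"), 3),
    population = "CD8", disease = "glioma"))
  c_m <- expression_matrix(cc, data.frame(
    patient = sprintf("P%d", 1:4), compartment = "tumor",
    population = "CD45neg", disease = "glioma"))
  res <- contamination_filter(t_m, c_m, n_top = 5)
  expect_true("G01" %in% res$removed)
  expect_false("G02" %in% res$removed)   # fails the top-n expression step
  expect_false("G03" %in% res$removed)   # fails the enrichment step
})

test_that("top variable genes equal exhaustive variance ranking with ID tie-break", {
  const <- matrix(5, 10, 4, dimnames = list(sprintf("G%02d", 10:1), NULL))
  colnames(const) <- sprintf("S%d", 1:4)
  expect_identical(top_variable_genes(const, 3), c("G01", "G02", "G03"))

  one <- const; one["G05", ] <- c(0, 10, 0, 10)
  expect_identical(top_variable_genes(one, 1), "G05")

  set.seed(9)
  x <- matrix(rnorm(200), 50, 4,
              dimnames = list(sprintf("G%02d", 1:50), sprintf("S%d", 1:4)))
  v <- apply(x, 1, var)
  expect_identical(top_variable_genes(x, 10),
                   names(sort(v, decreasing = TRUE))[1:10])
  expect_error(top_variable_genes(x, 51), "exceeds")
})

test_that("BH adjustment agrees with the textbook step-up procedure", {
  set.seed(10)
  for (i in 1:5) {
    p <- runif(sample(5:60, 1))^2
    expect_equal(p.adjust(p, method = "BH"), oracle_bh(p), tolerance = 1e-12)
  }
})
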