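test_that("configuration validation rejects impossible study conditions", {
  expect_error(sim_config(ptrt_high_rate_brm = 1.2), "probability")
  expect_error(sim_config(contamination_rate = -0.1), "probability")
  expect_error(sim_config(n_genes = 0), "positive integer")
  expect_error(sim_config(n_vessels = 2.5), "positive integer")
  expect_error(sim_config(ptrt_frac_low = c(27, 33),
                          ptrt_frac_high = c(3, 57)), "must exceed")
  expect_error(sim_config(noise_dispersion = 0), "positive")
  expect_s3_class(sim_config(), "sim_config")
})

test_that("degenerate rates yield the promised degenerate cohorts", {
  co0 <- simulate_cohort(sim_config(n_patients = 6, n_cells_per_sample = 40,
                                    n_genes = 200, n_events_per_sample = 120,
                                    n_spatial_cells = 100,
                                    ptrt_high_rate_brm = 0, seed = 3))
  expect_equal(sum(co0$truth$patients$ptrt_label == "high"), 0)

  coc <- simulate_cohort(sim_config(n_patients = 4, n_cells_per_sample = 40,
                                    n_genes = 200, n_events_per_sample = 120,
                                    n_spatial_cells = 100,
                                    contamination_rate = 0, seed = 3))
  t_samples <- coc$bulk$meta$population %in% c("CD4", "CD8")
  contam_counts <- coc$bulk$counts[coc$truth$contamination_genes, t_samples]
  expect_true(all(contam_counts == 0))
})

test_that("planted identifiers all exist in the emitted data", {
  co <- default_cohort(1)
  expect_true(all(co$truth$signature_genes %in% rownames(co$sc$counts)))
  expect_true(all(co$truth$contamination_genes %in% rownames(co$bulk$counts)))
  excl <- co$truth$tumor_exclusive_clones
  tum <- co$clonotypes[co$clonotypes$compartment == "tumor", ]
  expect_true(all(paste(excl$patient, excl$junction_aa) %in%
                    paste(tum$patient, tum$junction_aa)))
  blood <- co$clonotypes[co$clonotypes$compartment == "blood", ]
  expect_true(all(co$truth$viral_clones %in% blood$junction_aa))
  expect_true(all(co$truth$viral_clones %in%
                    co$antigen_db$junction_aa[co$antigen_db$score >= 1]))
})

test_that("planted tumor-exclusive clones are absent from matched blood", {
  co <- default_cohort(1)
  excl <- co$truth$tumor_exclusive_clones
  blood <- co$clonotypes[co$clonotypes$compartment == "blood", ]
  expect_false(any(paste(excl$patient, excl$junction_aa) %in%
                     paste(blood$patient, blood$junction_aa)))
})

test_that("identical configuration gives byte-identical cohort files", {
  cfg <- sim_config(n_patients = 4, n_cells_per_sample = 50, n_genes = 250,
                    n_events_per_sample = 150, n_spatial_cells = 150, seed = 11)
  d1 <- file.path(tempdir(), "cohort_a")
  d2 <- file.path(tempdir(), "cohort_b")
  on.exit(unlink(c(d1, d2), recursive = TRUE))
  m1 <- write_cohort(simulate_cohort(cfg), d1)
  m2 <- write_cohort(simulate_cohort(cfg), d2)
  expect_identical(m1$file, m2$file)
  expect_identical(m1$md5, m2$md5)
})

test_that("cohort round-trips through disk exactly", {
  cfg <- sim_config(n_patients = 3, n_cells_per_sample = 40, n_genes = 220,
                    n_events_per_sample = 150, n_spatial_cells = 150, seed = 5)
  co <- simulate_cohort(cfg)
  dir <- file.path(tempdir(), "cohort_rt")
  on.exit(unlink(dir, recursive = TRUE))
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(as.matrix(back$sc$counts), as.matrix(co$sc$counts))
  expect_equal(back$sc$cells, co$sc$cells, ignore_attr = TRUE)
  expect_equal(back$bulk$counts, as.matrix(co$bulk$counts))
  expect_equal(back$clonotypes, co$clonotypes, ignore_attr = TRUE)
  expect_equal(back$events, co$events, ignore_attr = TRUE)
  for (p in names(co$scenes)) {
    expect_equal(back$scenes[[p]]$cells, co$scenes[[p]]$cells,
                 ignore_attr = TRUE)
    expect_equal(back$scenes[[p]]$vessels, co$scenes[[p]]$vessels,
                 ignore_attr = TRUE)
  }
  expect_equal(back$truth$patients, co$truth$patients, ignore_attr = TRUE)
})

test_that("manifest checksum changes when any table cell changes", {
  cfg <- sim_config(n_patients = 2, n_cells_per_sample = 30, n_genes = 200,
                    n_events_per_sample = 120, n_spatial_cells = 120, seed = 9)
  dir <- file.path(tempdir(), "cohort_md5")
  on.exit(unlink(dir, recursive = TRUE))
  manifest <- write_cohort(simulate_cohort(cfg), dir)
  path <- file.path(dir, "clonotypes.tsv")
  tab <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  tab$duplicate_count[1] <- tab$duplicate_count[1] + 1L
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  new_md5 <- unname(tools::md5sum(path))
  old_md5 <- manifest$md5[manifest$file == "clonotypes.tsv"]
  expect_false(identical(new_md5, old_md5))
  ## untouched files keep their checksums
  other <- manifest$file != "clonotypes.tsv"
  expect_identical(unname(tools::md5sum(file.path(dir, manifest$file[other]))),
                   manifest$md5[other])
})

test_that("an empty cohort writes a header-only manifest", {
  co <- simulate_cohort(sim_config(n_patients = 0, seed = 1))
  dir <- file.path(tempdir(), "cohort_empty")
  on.exit(unlink(dir, recursive = TRUE))
  manifest <- write_cohort(co, dir)
  expect_equal(nrow(manifest), 0)
  expect_true(file.exists(file.path(dir, "manifest.tsv")))
})

test_that("empirical pTRT cluster fraction concentrates around the truth", {
  co <- simulate_cohort(sim_config(n_patients = 2, disease_mix = c(glioma = 0, BrM = 1),
                                   ptrt_high_rate_brm = 1,
                                   n_cells_per_sample = 2000, n_genes = 200,
                                   n_events_per_sample = 120,
                                   n_spatial_cells = 120, seed = 21))
  for (p in co$truth$patients$patient) {
    cells <- co$sc$cells[co$sc$cells$patient == p &
                           co$sc$cells$compartment == "tumor", ]
    f_hat <- mean(cells$cluster_id == "C3")
    f <- co$truth$patients$true_frac_tumor[co$truth$patients$patient == p]
    expect_lt(abs(f_hat - f), 3 * sqrt(f * (1 - f) / 2000))
  }
})

test_that("stronger planted signatures raise pTRT module scores monotonically", {
  diffs <- sapply(1:10, function(s) {
    sapply(c(0.5, 2), function(fc) {
      co <- simulate_cohort(sim_config(n_patients = 2,
                                       disease_mix = c(glioma = 0, BrM = 1),
                                       ptrt_high_rate_brm = 1,
                                       signature_log2fc = fc,
                                       n_cells_per_sample = 80, n_genes = 240,
                                       n_events_per_sample = 120,
                                       n_spatial_cells = 120, seed = 100 + s))
      lnorm <- log1p(as.matrix(co$sc$counts))
      sc <- module_score(lnorm, co$truth$signature_genes, seed = 1)
      is_ptrt <- co$sc$cells$cluster_id == "C3"
      mean(sc[is_ptrt]) - mean(sc[!is_ptrt])
    })
  })
  expect_true(mean(diffs[2, ] - diffs[1, ]) > 0)
  expect_gt(mean(diffs[2, ] > diffs[1, ]), 0.8)
})
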