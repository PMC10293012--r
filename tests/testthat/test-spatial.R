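make_scene <- function(cells, vessels = data.frame(cx = 500, cy = 500, r = 10),
                       window = c(xmin = 0, xmax = 1000, ymin = 0, ymax = 1000)) {
  defaults <- data.frame(diameter = 8, probability = 0.9,
                         phenotype = "nonimmune")
  for (col in names(defaults))
    if (is.null(cells[[col]])) cells[[col]] <- defaults[[col]]
  spatial_scene(cells, vessels, window, patient = "Pt")
}

test_that("cell-level spatial QC applies strict diameter and probability bounds", {
  cells <- data.frame(x = 1:6 * 10, y = 1:6 * 10,
                      diameter = c(13, 8, 8, 4, 12.5, 8),
                      probability = c(0.9, 0.65, 0.9, 0.9, 0.9, 0.66),
                      phenotype = "pTRT")
  sc <- make_scene(cells)
  out <- qc_cells_spatial(sc)
  ## 13 um out; p = 0.65 out (strict); 4 and 12.5 out (strict); kept: rows 3, 6
  expect_equal(out$cells$x, c(30, 60))
})

test_that("scene-level QC requires 30 CD8 cells", {
  mk <- function(n_cd8) {
    cells <- data.frame(x = seq_len(n_cd8 + 5), y = seq_len(n_cd8 + 5),
                        phenotype = rep(c("pTRT", "MG"), c(n_cd8, 5)))
    make_scene(cells)
  }
  expect_false(qc_scene(mk(29)))
  expect_true(qc_scene(mk(30)))
  empty <- make_scene(data.frame(x = numeric(), y = numeric(),
                                 diameter = numeric(), probability = numeric(),
                                 phenotype = character()))
  expect_false(qc_scene(empty))
})

test_that("vessel distances follow disc geometry and the brute-force oracle", {
  ves <- data.frame(cx = 0, cy = 0, r = 5)
  win <- c(xmin = -100, xmax = 100, ymin = -100, ymax = 100)
  cells <- data.frame(x = c(0, 1), y = c(18, 1), diameter = 8,
                      probability = 0.9, phenotype = "pTRT")
  sc <- spatial_scene(cells, ves, win, "Pt")
  d <- vessel_distance(sc)
  expect_equal(d[1], 13.0)
  expect_equal(d[2], 0.0)       # inside the disc

  set.seed(60)
  cells_r <- data.frame(x = runif(100, 0, 1000), y = runif(100, 0, 1000),
                        diameter = 8, probability = 0.9, phenotype = "pTRT")
  ves_r <- data.frame(cx = runif(10, 0, 1000), cy = runif(10, 0, 1000),
                      r = runif(10, 5, 30))
  sc_r <- make_scene(cells_r, ves_r)
  d_r <- vessel_distance(sc_r)
  for (i in seq_len(100))
    expect_equal(d_r[i], oracle_vessel_distance(cells_r$x[i], cells_r$y[i],
                                                ves_r), tolerance = 1e-12)
  expect_error(vessel_distance(cells_r, ves_r[0, ]), "no vessels")
})

test_that("PVN membership is boundary-inclusive at 15 um", {
  ves <- data.frame(cx = 0, cy = 0, r = 5)
  cells <- data.frame(x = c(0, 0, 20), y = c(18, 25, 0))   # d = 13, 20, 15
  expect_identical(pvn_membership(cells, ves), c(TRUE, FALSE, TRUE))
})

test_that("distance computations are translation- and rotation-invariant", {
  set.seed(61)
  cells <- data.frame(x = runif(50, 200, 800), y = runif(50, 200, 800))
  ves <- data.frame(cx = runif(5, 200, 800), cy = runif(5, 200, 800),
                    r = runif(5, 5, 20))
  d0 <- vessel_distance(cells, ves)
  ## translation
  d_t <- vessel_distance(transform(cells, x = x + 37, y = y - 12),
                         transform(ves, cx = cx + 37, cy = cy - 12))
  expect_equal(d_t, d0, tolerance = 1e-9)
  ## rotation about the window center
  th <- 0.7; cx0 <- 500; cy0 <- 500
  rot <- function(x, y) list(x = cx0 + cos(th) * (x - cx0) - sin(th) * (y - cy0),
                             y = cy0 + sin(th) * (x - cx0) + cos(th) * (y - cy0))
  rc <- rot(cells$x, cells$y); rv <- rot(ves$cx, ves$cy)
  d_r <- vessel_distance(data.frame(x = rc$x, y = rc$y),
                         data.frame(cx = rv$x, cy = rv$y, r = ves$r))
  expect_equal(d_r, d0, tolerance = 1e-9)
})

test_that("neighborhood composition equals the exhaustive pairwise check", {
  ## hand-built: index pTRT cell at origin with 2 nonimmune + 1 MG within 20
  cells <- data.frame(
    x = c(0, 5, -5, 0, 100, 300), y = c(0, 5, 5, -10, 0, 300),
    phenotype = c("pTRT", "nonimmune", "nonimmune", "MG", "MDM", "pTRT"))
  sc <- make_scene(cells, window = c(xmin = -50, xmax = 500,
                                     ymin = -50, ymax = 500))
  res <- neighborhood_composition(sc)
  expect_equal(unname(res$per_cell[1, "nonimmune"]), 2)
  expect_equal(unname(res$per_cell[1, "MG"]), 1)
  expect_equal(sum(res$per_cell[2, ]), 0)        # isolated index cell
  expect_equal(unname(res$composition[c("nonimmune", "MG")]), c(2 / 3, 1 / 3))

  set.seed(62)
  cells_r <- data.frame(
    x = runif(120, 0, 200), y = runif(120, 0, 200),
    phenotype = sample(c("pTRT", "nonPTRT_CD8", "MG", "MDM", "other_immune",
                         "nonimmune"), 120, TRUE))
  sc_r <- make_scene(cells_r, window = c(xmin = 0, xmax = 200,
                                         ymin = 0, ymax = 200))
  res_r <- neighborhood_composition(sc_r, radius = 25)
  idx <- which(cells_r$phenotype == "pTRT")
  for (k in seq_along(idx)) {
    i <- idx[k]
    for (ph in colnames(res_r$per_cell)) {
      n_manual <- 0
      for (j in seq_len(nrow(cells_r))) {
        if (j != i && cells_r$phenotype[j] == ph &&
            sqrt((cells_r$x[j] - cells_r$x[i])^2 +
                   (cells_r$y[j] - cells_r$y[i])^2) <= 25)
          n_manual <- n_manual + 1
      }
      expect_equal(unname(res_r$per_cell[k, ph]), n_manual)
    }
  }
  ## reverse query against a manual count
  cd8 <- which(cells_r$phenotype %in% c("pTRT", "nonPTRT_CD8"))
  manual <- mean(sapply(cd8, function(i) {
    any(sapply(which(cells_r$phenotype %in% c("MG", "MDM")), function(j)
      sqrt((cells_r$x[j] - cells_r$x[i])^2 +
             (cells_r$y[j] - cells_r$y[i])^2) <= 25))
  }))
  expect_equal(res_r$cd8_near_tam_fraction, manual)
})

test_that("nearest-phenotype distances match brute force and the 3-4-5 case", {
  cells <- data.frame(x = c(0, 3, 10), y = c(0, 4, 0),
                      phenotype = c("pTRT", "MG", "MG"))
  sc <- make_scene(cells)
  res <- nearest_phenotype_distance(sc, "pTRT", "MG")
  expect_equal(res$distances$distance, 5.0)

  cells2 <- data.frame(x = c(7, 7), y = c(7, 7),
                       phenotype = c("pTRT", "MG"))
  res2 <- nearest_phenotype_distance(make_scene(cells2), "pTRT", "MG")
  expect_equal(res2$distances$distance, 0.0)   # coincident but distinct cells

  set.seed(63)
  cells_r <- data.frame(
    x = runif(80, 0, 300), y = runif(80, 0, 300),
    phenotype = sample(c("pTRT", "nonPTRT_CD8", "MG", "MDM"), 80, TRUE))
  sc_r <- make_scene(cells_r, window = c(xmin = 0, xmax = 300,
                                         ymin = 0, ymax = 300))
  res_r <- nearest_phenotype_distance(sc_r, c("pTRT", "nonPTRT_CD8"),
                                      c("MG", "MDM"))
  src <- which(cells_r$phenotype %in% c("pTRT", "nonPTRT_CD8"))
  tgt <- which(cells_r$phenotype %in% c("MG", "MDM"))
  for (k in seq_along(src)) {
    i <- src[k]
    dd <- Inf
    for (j in setdiff(tgt, i))
      dd <- min(dd, sqrt((cells_r$x[j] - cells_r$x[i])^2 +
                           (cells_r$y[j] - cells_r$y[i])^2))
    expect_equal(res_r$distances$distance[k], dd, tolerance = 1e-12)
  }
})

test_that("uniformly placed cells match the PVN area fraction", {
  set.seed(64)
  ves <- data.frame(cx = runif(6, 100, 900), cy = runif(6, 100, 900),
                    r = runif(6, 10, 30))
  win <- c(xmin = 0, xmax = 1000, ymin = 0, ymax = 1000)
  p_area <- pvn_area_fraction(ves, win, n_grid = 1500)
  n <- 10000
  pts <- data.frame(x = runif(n, 0, 1000), y = runif(n, 0, 1000))
  p_hat <- mean(pvn_membership(pts, ves))
  se <- sqrt(p_area * (1 - p_area) / n)
  expect_lt(abs(p_hat - p_area), 2.576 * se + 2e-3)  # 99% CI + grid error
})

test_that("planted perivascular enrichment raises the within-PVN fraction", {
  wins <- 0
  for (s in 1:20) {
    base_cfg <- function(enr, seed) sim_config(
      n_patients = 1, disease_mix = c(glioma = 0, BrM = 1),
      ptrt_high_rate_brm = 1, n_cells_per_sample = 20, n_genes = 200,
      n_events_per_sample = 120, n_spatial_cells = 2000, n_vessels = 8,
      pvn_enrichment = enr, seed = seed)
    f <- sapply(c(1, 4), function(enr) {
      co <- simulate_cohort(base_cfg(enr, 200 + s))
      scn <- co$scenes[[1]]
      ptrt <- scn$cells[scn$cells$phenotype == "pTRT", ]
      mean(pvn_membership(ptrt, scn$vessels))
    })
    wins <- wins + (f[2] > f[1])
  }
  expect_gte(wins / 20, 0.95)
})
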