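# Independent brute-force oracles used to cross-check the package
# implementations. Written deliberately naively (loops, literal formulas),
# never sharing code with R/.

oracle_chao1 <- function(counts) {
  f1 <- 0; f2 <- 0
  for (c in counts) {
    if (c == 1) f1 <- f1 + 1
    if (c == 2) f2 <- f2 + 1
  }
  length(counts) + f1 * (f1 - 1) / (2 * (f2 + 1))
}

oracle_morisita <- function(u, v) {
  all_j <- union(u$junction_aa, v$junction_aa)
  num <- 0; dp <- 0; dq <- 0
  for (j in all_j) {
    p <- 0; q <- 0
    if (j %in% u$junction_aa)
      p <- u$duplicate_count[u$junction_aa == j] / sum(u$duplicate_count)
    if (j %in% v$junction_aa)
      q <- v$duplicate_count[v$junction_aa == j] / sum(v$duplicate_count)
    num <- num + p * q; dp <- dp + p^2; dq <- dq + q^2
  }
  2 * num / (dp + dq)
}

# Textbook Benjamini-Hochberg step-up with enforced monotonicity
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (i in n:1) {
    val <- min(prev, p[o[i]] * n / i)
    adj[o[i]] <- val
    prev <- val
  }
  adj
}

# Direct evaluation of the trim-and-weight TMM formula
oracle_tmm <- function(counts, logratio_trim = 0.3, sum_trim = 0.05) {
  lib <- colSums(counts)
  f75 <- numeric(ncol(counts))
  for (j in seq_len(ncol(counts)))
    f75[j] <- quantile(counts[, j], 0.75) / lib[j]
  ref <- which.min(abs(f75 - mean(f75)))
  f <- numeric(ncol(counts))
  for (j in seq_len(ncol(counts))) {
    M <- c(); A <- c(); w <- c()
    for (g in seq_len(nrow(counts))) {
      o <- counts[g, j]; r <- counts[g, ref]
      if (o > 0 && r > 0) {
        M <- c(M, log2((o / lib[j]) / (r / lib[ref])))
        A <- c(A, 0.5 * log2((o / lib[j]) * (r / lib[ref])))
        w <- c(w, (lib[j] - o) / (lib[j] * o) + (lib[ref] - r) / (lib[ref] * r))
      }
    }
    if (length(M) == 0 || max(abs(M)) < 1e-6) { f[j] <- 1; next }
    n <- length(M)
    loL <- floor(n * logratio_trim) + 1; hiL <- n + 1 - loL
    loS <- floor(n * sum_trim) + 1; hiS <- n + 1 - loS
    rM <- rank(M); rA <- rank(A)
    keep <- rM >= loL & rM <= hiL & rA >= loS & rA <= hiS
    f[j] <- 2^(sum((M[keep] / w[keep])) / sum(1 / w[keep]))
  }
  f / exp(mean(log(f)))
}

# Literal running-sum GSEA enrichment score
oracle_gsea_es <- function(ranks, set, weight = 1) {
  ord <- order(ranks, decreasing = TRUE)
  genes <- names(ranks)[ord]
  stat <- unname(ranks[ord])
  hit <- genes %in% set
  nh <- sum(hit)
  n <- length(genes)
  denom <- sum(abs(stat[hit])^weight)
  run <- 0; best <- 0
  for (i in seq_len(n)) {
    if (hit[i]) {
      run <- run + if (denom > 0) abs(stat[i])^weight / denom else 1 / nh
    } else {
      run <- run - 1 / (n - nh)
    }
    if (abs(run) > abs(best)) best <- run
  }
  best
}

oracle_clone_category <- function(freq) {
  if (freq <= 1e-4) "Rare"
  else if (freq <= 1e-3) "Small"
  else if (freq <= 1e-2) "Medium"
  else if (freq <= 1e-1) "Large"
  else "Hyperexpanded"
}

oracle_vessel_distance <- function(x, y, vessels) {
  best <- Inf
  for (j in seq_len(nrow(vessels))) {
    d <- sqrt((x - vessels$cx[j])^2 + (y - vessels$cy[j])^2) - vessels$r[j]
    if (d < 0) d <- 0
    if (d < best) best <- d
  }
  best
}

oracle_filter_by_expression <- function(counts, groups,
                                        min_count = 10, min_total = 15) {
  n_min <- min(table(groups))
  keep <- character(0)
  for (g in seq_len(nrow(counts))) {
    n_ok <- sum(counts[g, ] >= min_count)
    if (n_ok >= n_min && sum(counts[g, ]) >= min_total)
      keep <- c(keep, rownames(counts)[g])
  }
  keep
}

# --- fixture builders ------------------------------------------------------

make_unit <- function(counts, patient = "P01", compartment = "tumor",
                      junctions = NULL) {
  if (is.null(junctions))
    junctions <- sprintf("CASS%04dQYF", seq_along(counts))
  data.frame(patient = patient, compartment = compartment,
             junction_aa = junctions,
             v_call = "TRBV2", j_call = "TRBJ1-1",
             duplicate_count = as.integer(counts), stringsAsFactors = FALSE)
}

make_expr <- function(counts, population = "CD8", compartment = "tumor",
                      disease = "unknown") {
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("G%03d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("S%02d", seq_len(ncol(counts)))
  n <- ncol(counts)
  expression_matrix(counts, data.frame(
    patient = sprintf("P%02d", seq_len(n)),
    compartment = rep_len(compartment, n),
    population = rep_len(population, n),
    disease = rep_len(disease, n), stringsAsFactors = FALSE))
}

# Cached default cohort so several test files can share one simulation
.cohort_cache <- new.env()
default_cohort <- function(seed = 1) {
  key <- as.character(seed)
  if (is.null(.cohort_cache[[key]]))
    .cohort_cache[[key]] <- simulate_cohort(sim_config(seed = seed))
  .cohort_cache[[key]]
}
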