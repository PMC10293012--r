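#' Configuration for the synthetic multi-modal cohort
#'
#' Defines the study conditions under which the whole pipeline is exercised:
#' a cohort of glioma and brain-metastasis (BrM) patients in which each BrM
#' patient is either pTRT-high (potentially tumor-reactive CD8+ T cells above
#' 30% of CD8+ TILs) or pTRT-low (below 15%), with matched single-cell counts,
#' sorted-population bulk counts, TCR beta repertoires, flow-cytometry events
#' and segmented tissue scenes, all carrying planted ground truth.
#'
#' @param n_patients number of patients (0 allowed for degenerate cohorts).
#' @param disease_mix named proportions over `c(glioma=, BrM=)`.
#' @param ptrt_high_rate_brm fraction of BrM patients that are pTRT-high; the
#'   cohort is stratified, i.e. `round(n_BrM * rate)` patients are high.
#' @param ptrt_frac_low,ptrt_frac_high Beta shape pairs for the true pTRT
#'   fraction of CD8+ TILs; draws are truncated to `< 0.15` (low) and
#'   `> 0.30` (high), the defining bands of the two groups.
#' @param n_genes,n_signature_genes,n_contamination_genes gene universe size,
#'   planted pTRT signature size, planted tumor-contamination gene count.
#' @param signature_log2fc log2 fold change of signature genes in pTRT cells.
#' @param contamination_rate fraction of tumor-cell (CD45-) transcripts
#'   admixed into sorted tumor T cell bulk profiles.
#' @param clone_zipf_exponent exponent of the Zipf clone-size law in tumor
#'   repertoires (blood uses 0.7x this exponent, a flatter tail).
#' @param ptrt_clonality_boost added to the tumor Zipf exponent in pTRT-high
#'   patients, reproducing their lower repertoire diversity and stronger
#'   clonal expansion; 0 disables the contrast.
#' @param n_cells_per_sample CD8+ cells per patient x compartment (scRNA).
#' @param n_events_per_sample flow events per patient x compartment.
#' @param n_spatial_cells,n_vessels segmented cells and vessel discs per scene.
#' @param pvn_enrichment odds multiplier for placing pTRT cells within 15 um
#'   of a vessel boundary (1 = uniform placement).
#' @param noise_dispersion negative-binomial dispersion of single-cell counts
#'   (size = 1/dispersion).
#' @param seed integer master seed; expanded into independent per-modality
#'   substreams.
#'
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_patients = 24,
                       disease_mix = c(glioma = 1 / 3, BrM = 2 / 3),
                       ptrt_high_rate_brm = 0.5,
                       ptrt_frac_low = c(3, 57),
                       ptrt_frac_high = c(27, 33),
                       n_genes = 1000,
                       n_signature_genes = 30,
                       n_contamination_genes = 20,
                       signature_log2fc = 2,
                       contamination_rate = 0.1,
                       clone_zipf_exponent = 1.5,
                       ptrt_clonality_boost = 0.5,
                       n_cells_per_sample = 200,
                       n_events_per_sample = 2000,
                       n_spatial_cells = 1500,
                       n_vessels = 8,
                       pvn_enrichment = 3,
                       noise_dispersion = 0.5,
                       seed = 1) {
  stop_if(!is.numeric(n_patients) || length(n_patients) != 1L ||
            n_patients < 0 || n_patients != round(n_patients),
          "'n_patients' must be a single non-negative integer")
  stop_if(length(disease_mix) != 2L || is.null(names(disease_mix)) ||
            !setequal(names(disease_mix), c("glioma", "BrM")) ||
            any(disease_mix < 0) || abs(sum(disease_mix) - 1) > 1e-8,
          "'disease_mix' must be named proportions over glioma and BrM summing to 1")
  check_prob(ptrt_high_rate_brm, "ptrt_high_rate_brm")
  check_prob(contamination_rate, "contamination_rate")
  stop_if(length(ptrt_frac_low) != 2L || any(ptrt_frac_low <= 0) ||
            length(ptrt_frac_high) != 2L || any(ptrt_frac_high <= 0),
          "Beta shape parameters must be positive pairs")
  mean_low <- ptrt_frac_low[1] / sum(ptrt_frac_low)
  mean_high <- ptrt_frac_high[1] / sum(ptrt_frac_high)
  stop_if(mean_high <= mean_low,
          "mean of 'ptrt_frac_high' must exceed mean of 'ptrt_frac_low'")
  for (nm in c("n_genes", "n_signature_genes", "n_contamination_genes",
               "n_cells_per_sample", "n_events_per_sample",
               "n_spatial_cells", "n_vessels"))
    check_count(get(nm), nm)
  stop_if(n_signature_genes + n_contamination_genes >= n_genes,
          "planted gene sets must fit inside the gene universe")
  stop_if(signature_log2fc < 0, "'signature_log2fc' must be non-negative")
  stop_if(clone_zipf_exponent <= 0, "'clone_zipf_exponent' must be positive")
  stop_if(ptrt_clonality_boost < 0, "'ptrt_clonality_boost' must be non-negative")
  stop_if(pvn_enrichment <= 0, "'pvn_enrichment' must be positive")
  stop_if(noise_dispersion <= 0, "'noise_dispersion' must be positive")
  stop_if(!is.numeric(seed) || length(seed) != 1L || seed != round(seed),
          "'seed' must be a single integer")
  structure(list(
    n_patients = as.integer(n_patients), disease_mix = disease_mix,
    ptrt_high_rate_brm = ptrt_high_rate_brm,
    ptrt_frac_low = ptrt_frac_low, ptrt_frac_high = ptrt_frac_high,
    n_genes = as.integer(n_genes),
    n_signature_genes = as.integer(n_signature_genes),
    n_contamination_genes = as.integer(n_contamination_genes),
    signature_log2fc = signature_log2fc,
    contamination_rate = contamination_rate,
    clone_zipf_exponent = clone_zipf_exponent,
    ptrt_clonality_boost = ptrt_clonality_boost,
    n_cells_per_sample = as.integer(n_cells_per_sample),
    n_events_per_sample = as.integer(n_events_per_sample),
    n_spatial_cells = as.integer(n_spatial_cells),
    n_vessels = as.integer(n_vessels),
    pvn_enrichment = pvn_enrichment,
    noise_dispersion = noise_dispersion,
    seed = as.integer(seed)), class = "sim_config")
}

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Zipf clone-size probabilities
#' @noRd
zipf_probs <- function(n, s) {
  p <- (seq_len(n))^(-s)
  p / sum(p)
}

#' Random CDR3beta-like junctions, unique and disjoint from `existing`
#' @noRd
gen_junctions <- function(n, existing = character()) {
  out <- character(0)
  while (length(out) < n) {
    need <- n - length(out)
    len <- sample(6:10, need, replace = TRUE)
    cand <- vapply(len, function(l)
      paste0("CASS", paste(sample(AA_ALPHABET, l, replace = TRUE),
                           collapse = ""), "QYF"), character(1))
    cand <- setdiff(unique(cand), c(existing, out))
    out <- c(out, cand)
  }
  out[seq_len(n)]
}

FLOW_MARKERS <- c("CD39", "CCR7", "PD1", "TIM3", "CD103", "CXCL13",
                  "Ki67", "CD45RO")

SPATIAL_PHENOTYPES <- c("pTRT", "nonPTRT_CD8", "MG", "MDM",
                        "other_immune", "nonimmune")

#' Simulate a matched multi-modal brain-tumor cohort
#'
#' Generates, under one master seed expanded into independent per-modality
#' substreams, (i) single-cell CD8 counts with a planted pTRT cluster ("C3")
#' overexpressing the signature genes, (ii) sorted-population bulk counts in
#' which tumor T cell samples carry a configurable admixture of the CD45-
#' (tumor) profile, (iii) TCR beta repertoires with Zipf clone sizes and
#' tumor-exclusive expansion in pTRT-high patients, (iv) flow events with
#' elevated CD39 and reduced CCR7 in pTRT cells, and (v) spatial scenes with
#' pTRT cells preferentially placed within 15 um of vessel boundaries.
#'
#' @param config a [sim_config()].
#' @return A list of class `"ptrt_cohort"` with elements `sc` (sparse counts
#'   plus cell annotations), `bulk` (an [expression_matrix()]),
#'   `clonotypes`, `antigen_db`, `events`, `gates`, `scenes`, `signatures`
#'   (named gene-set list), `truth` (planted ground truth) and `config`.
#' @export
simulate_cohort <- function(config) {
  stop_if(!inherits(config, "sim_config"), "config must come from sim_config()")
  cfg <- config
  streams <- with_seed(cfg$seed, sample.int(.Machine$integer.max - 1L, 7L))

  ## ---- patients and planted labels -------------------------------------
  truth_patients <- with_seed(streams[1], {
    n <- cfg$n_patients
    if (n == 0L) {
      data.frame(patient = character(), disease = character(),
                 ptrt_label = character(), true_frac_tumor = numeric(),
                 true_frac_blood = numeric(), stringsAsFactors = FALSE)
    } else {
      ids <- sprintf("P%02d", seq_len(n))
      n_glioma <- round(n * cfg$disease_mix[["glioma"]])
      disease <- rep("BrM", n)
      disease[sample.int(n, n_glioma)] <- "glioma"
      label <- rep("low", n)
      brm <- which(disease == "BrM")
      n_high <- round(length(brm) * cfg$ptrt_high_rate_brm)
      if (n_high > 0) label[sample(brm, n_high)] <- "high"
      draw_frac <- function(shape, keep) {
        repeat {
          x <- rbeta(1, shape[1], shape[2])
          if (keep(x)) return(x)
        }
      }
      frac <- vapply(label, function(l) {
        if (l == "high") draw_frac(cfg$ptrt_frac_high, function(x) x > 0.30)
        else draw_frac(cfg$ptrt_frac_low, function(x) x < 0.15)
      }, numeric(1))
      data.frame(patient = ids, disease = disease, ptrt_label = label,
                 true_frac_tumor = round(frac, 6),
                 true_frac_blood = 0.005, stringsAsFactors = FALSE)
    }
  })
  tp <- truth_patients
  disease_group <- ifelse(tp$disease == "glioma", "glioma",
                          paste0("BrM-pTRT-", tp$ptrt_label))

  ## ---- gene universe and planted gene programs -------------------------
  genes <- with_seed(streams[2], {
    ids <- sprintf("G%04d", seq_len(cfg$n_genes))
    base_mu <- exp(rnorm(cfg$n_genes, -0.5, 1.2))
    sig <- sort(sample(ids, cfg$n_signature_genes))
    contam <- sort(sample(setdiff(ids, sig), cfg$n_contamination_genes))
    base_mu[match(contam, ids)] <- 0      # contamination-only genes: silent in T cells
    mu_cd45 <- base_mu * exp(rnorm(cfg$n_genes, 0, 0.25))
    mu_cd45[match(contam, ids)] <- exp(rnorm(cfg$n_contamination_genes, log(60), 0.3))
    pool <- setdiff(ids, c(sig, contam))
    mk <- sample(pool, 16)
    list(ids = ids, base_mu = base_mu, mu_cd45 = mu_cd45,
         signature = sig, contamination = contam,
         markers_c1 = mk[1:8], markers_c2 = mk[9:16])
  })

  mu_cluster <- list(C1 = genes$base_mu, C2 = genes$base_mu, C3 = genes$base_mu)
  mu_cluster$C1[match(genes$markers_c1, genes$ids)] <-
    mu_cluster$C1[match(genes$markers_c1, genes$ids)] * 2
  mu_cluster$C2[match(genes$markers_c2, genes$ids)] <-
    mu_cluster$C2[match(genes$markers_c2, genes$ids)] * 2
  mu_cluster$C3[match(genes$signature, genes$ids)] <-
    mu_cluster$C3[match(genes$signature, genes$ids)] * 2^cfg$signature_log2fc

  ## ---- single-cell counts ----------------------------------------------
  sc <- with_seed(streams[3], {
    cells <- do.call(rbind, lapply(seq_len(nrow(tp)), function(i) {
      do.call(rbind, lapply(c("blood", "tumor"), function(comp) {
        n <- cfg$n_cells_per_sample
        frac <- if (comp == "tumor") tp$true_frac_tumor[i] else tp$true_frac_blood[i]
        is_ptrt <- runif(n) < frac
        cl <- ifelse(is_ptrt, "C3", ifelse(runif(n) < 0.6, "C1", "C2"))
        data.frame(cell_id = sprintf("%s_%s_c%04d", tp$patient[i], comp, seq_len(n)),
                   patient = tp$patient[i], compartment = comp,
                   lineage = "CD8", cluster_id = cl, stringsAsFactors = FALSE)
      }))
    }))
    if (is.null(cells))
      cells <- data.frame(cell_id = character(), patient = character(),
                          compartment = character(), lineage = character(),
                          cluster_id = character(), stringsAsFactors = FALSE)
    n_cells <- nrow(cells)
    counts <- matrix(0L, cfg$n_genes, n_cells,
                     dimnames = list(genes$ids, cells$cell_id))
    size <- 1 / cfg$noise_dispersion
    for (k in c("C1", "C2", "C3")) {
      idx <- which(cells$cluster_id == k)
      if (!length(idx)) next
      counts[, idx] <- rnbinom(cfg$n_genes * length(idx), size = size,
                               mu = mu_cluster[[k]])
    }
    ## QC metadata emulate full-transcriptome statistics (the count matrix is
    ## a reduced gene universe, so detected-gene counts are drawn, not derived)
    cells$features <- if (n_cells) as.integer(round(rlnorm(n_cells, log(1100), 0.6)))
                      else integer()
    cells$mito <- if (n_cells) round(rbeta(n_cells, 4, 60), 6) else numeric()
    list(counts = methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"),
         cells = cells)
  })

  ## ---- bulk sorted-population counts ------------------------------------
  bulk <- with_seed(streams[4], {
    p_c <- genes$mu_cd45 / sum(genes$mu_cd45)
    p_cd4 <- genes$base_mu / sum(genes$base_mu)
    size_bulk <- 20   # gene-level NB dispersion 0.05 on bulk profiles
    cols <- list(); meta <- list()
    for (i in seq_len(nrow(tp))) {
      pat <- tp$patient[i]
      for (combo in list(c("CD8", "blood"), c("CD8", "tumor"),
                        c("CD4", "blood"), c("CD4", "tumor"),
                        c("CD45neg", "tumor"))) {
        popn <- combo[1]; comp <- combo[2]
        p <- if (popn == "CD45neg") {
          p_c
        } else {
          base <- if (popn == "CD8") {
            sel <- sc$cells$patient == pat & sc$cells$compartment == comp
            prof <- as.numeric(Matrix::rowSums(sc$counts[, sel, drop = FALSE]))
            if (sum(prof) == 0) genes$base_mu else prof
          } else genes$base_mu
          pt <- base / sum(base)
          if (comp == "tumor")
            (pt + cfg$contamination_rate * p_c) / (1 + cfg$contamination_rate)
          else pt
        }
        lib <- round(runif(1, 2e6, 6e6))
        cnt <- rnbinom(cfg$n_genes, size = size_bulk, mu = p * lib)
        cols[[length(cols) + 1L]] <- cnt
        meta[[length(meta) + 1L]] <- data.frame(
          patient = pat, compartment = comp, population = popn,
          disease = disease_group[i], stringsAsFactors = FALSE)
      }
    }
    if (!length(cols)) {
      counts <- matrix(0L, cfg$n_genes, 0, dimnames = list(genes$ids, character()))
      meta <- data.frame(patient = character(), compartment = character(),
                         population = character(), disease = character())
    } else {
      counts <- do.call(cbind, cols)
      meta <- do.call(rbind, meta)
      colnames(counts) <- sprintf("%s_%s_%s", meta$patient, meta$population,
                                  meta$compartment)
      rownames(counts) <- genes$ids
    }
    expression_matrix(counts, meta)
  })

  ## ---- TCR repertoires ---------------------------------------------------
  tcrsim <- with_seed(streams[5], {
    v_genes <- sprintf("TRBV%d", 2:30)
    j_genes <- sprintf("TRBJ%d-%d", rep(1:2, each = 3), 1:3)
    viral <- gen_junctions(5)
    used <- viral
    recs <- list()
    excl <- list()
    for (i in seq_len(nrow(tp))) {
      pat <- tp$patient[i]
      n_ct <- 150L; n_cb <- 250L
      jt <- gen_junctions(n_ct, used); used <- c(used, jt)
      s_tumor <- cfg$clone_zipf_exponent +
        if (tp$ptrt_label[i] == "high") cfg$ptrt_clonality_boost else 0
      ct <- as.integer(rmultinom(1, 1200, zipf_probs(n_ct, s_tumor)))
      keep <- ct > 0
      jt <- jt[keep]; ct <- ct[keep]
      ord <- order(-ct, jt)
      jt <- jt[ord]; ct <- ct[ord]
      top15 <- jt[seq_len(min(15L, length(jt)))]
      ## blood repertoire: shares the tumor tail; in pTRT-low patients the
      ## top tumor clones recirculate, in pTRT-high they are tumor-exclusive
      fresh <- gen_junctions(n_cb, used); used <- c(used, fresh)
      if (tp$ptrt_label[i] == "low") {
        jb <- c(top15, viral, jt[seq(min(30, length(jt)), length(jt))][1:10],
                fresh)[seq_len(n_cb)]
      } else {
        shared_tail <- jt[jt %in% setdiff(jt, top15)][seq_len(min(10, max(0, length(jt) - 15)))]
        jb <- c(viral, shared_tail, fresh)[seq_len(n_cb)]
        excl[[pat]] <- top15
      }
      jb <- jb[!is.na(jb)]
      cb <- as.integer(rmultinom(1, 1200, zipf_probs(length(jb),
                                                     0.7 * cfg$clone_zipf_exponent)))
      keepb <- cb > 0
      jb <- jb[keepb]; cb <- cb[keepb]
      recs[[length(recs) + 1L]] <- data.frame(
        patient = pat, compartment = "tumor", junction_aa = jt,
        v_call = sample(v_genes, length(jt), replace = TRUE),
        j_call = sample(j_genes, length(jt), replace = TRUE),
        duplicate_count = ct, stringsAsFactors = FALSE)
      recs[[length(recs) + 1L]] <- data.frame(
        patient = pat, compartment = "blood", junction_aa = jb,
        v_call = sample(v_genes, length(jb), replace = TRUE),
        j_call = sample(j_genes, length(jb), replace = TRUE),
        duplicate_count = cb, stringsAsFactors = FALSE)
    }
    clono <- if (length(recs)) do.call(rbind, recs) else
      data.frame(patient = character(), compartment = character(),
                 junction_aa = character(), v_call = character(),
                 j_call = character(), duplicate_count = integer(),
                 stringsAsFactors = FALSE)
    decoys <- if (nrow(clono)) sample(setdiff(unique(clono$junction_aa), viral),
                                      min(5, nrow(clono))) else character()
    novel <- gen_junctions(20, used)
    db <- data.frame(
      junction_aa = c(viral, decoys, novel),
      species = sample(c("CMV", "EBV", "InfluenzaA"),
                       length(viral) + length(decoys) + 20, replace = TRUE),
      score = c(sample(1:3, length(viral), replace = TRUE),
                rep(0L, length(decoys)),
                sample(1:3, 20, replace = TRUE)),
      stringsAsFactors = FALSE)
    excl_df <- if (length(excl)) data.frame(
      patient = rep(names(excl), lengths(excl)),
      junction_aa = unlist(excl, use.names = FALSE), stringsAsFactors = FALSE)
    else data.frame(patient = character(), junction_aa = character(),
                    stringsAsFactors = FALSE)
    list(clonotypes = clono, db = db, viral = viral, exclusive = excl_df)
  })

  ## ---- flow-cytometry events ----------------------------------------------
  flowsim <- with_seed(streams[6], {
    rlog <- function(n, m, s) round(rlnorm(n, log(m), s), 4)
    draw_events <- function(n, is_ptrt) {
      np <- sum(is_ptrt); nn <- n - np
      e <- data.frame(matrix(0, n, length(FLOW_MARKERS),
                             dimnames = list(NULL, FLOW_MARKERS)))
      e$CD39[is_ptrt] <- rlog(np, 900, 0.35)
      e$CD39[!is_ptrt] <- rlog(nn, 60, 0.5)
      ccr7_hi <- runif(nn) < 0.5
      e$CCR7[is_ptrt] <- rlog(np, 25, 0.4)
      e$CCR7[!is_ptrt] <- ifelse(ccr7_hi, rlog(nn, 500, 0.4), rlog(nn, 40, 0.5))
      e$PD1[is_ptrt] <- rlog(np, 700, 0.4); e$PD1[!is_ptrt] <- rlog(nn, 90, 0.5)
      e$TIM3[is_ptrt] <- rlog(np, 500, 0.4); e$TIM3[!is_ptrt] <- rlog(nn, 70, 0.5)
      e$CD103[is_ptrt] <- rlog(np, 600, 0.4); e$CD103[!is_ptrt] <- rlog(nn, 80, 0.5)
      e$CXCL13[is_ptrt] <- rlog(np, 300, 0.5); e$CXCL13[!is_ptrt] <- rlog(nn, 40, 0.5)
      ki_p <- runif(np) < 0.30; ki_n <- runif(nn) < 0.05
      e$Ki67[is_ptrt] <- ifelse(ki_p, rlog(np, 400, 0.4), rlog(np, 50, 0.5))
      e$Ki67[!is_ptrt] <- ifelse(ki_n, rlog(nn, 400, 0.4), rlog(nn, 50, 0.5))
      ro_n <- runif(nn) < 0.5
      e$CD45RO[is_ptrt] <- rlog(np, 800, 0.4)
      e$CD45RO[!is_ptrt] <- ifelse(ro_n, rlog(nn, 700, 0.4), rlog(nn, 60, 0.5))
      e
    }
    evs <- list()
    for (i in seq_len(nrow(tp))) {
      for (comp in c("blood", "tumor")) {
        n <- cfg$n_events_per_sample
        frac <- if (comp == "tumor") tp$true_frac_tumor[i] else tp$true_frac_blood[i]
        is_ptrt <- runif(n) < frac
        e <- draw_events(n, is_ptrt)
        evs[[length(evs) + 1L]] <- cbind(
          data.frame(sample_id = sprintf("%s_%s", tp$patient[i], comp),
                     patient = tp$patient[i], compartment = comp,
                     cd3 = TRUE, cd8 = TRUE, stringsAsFactors = FALSE), e)
      }
    }
    events <- if (length(evs)) do.call(rbind, evs) else
      cbind(data.frame(sample_id = character(), patient = character(),
                       compartment = character(), cd3 = logical(),
                       cd8 = logical()),
            data.frame(matrix(numeric(), 0, length(FLOW_MARKERS),
                              dimnames = list(NULL, FLOW_MARKERS))))
    gates <- data.frame(marker = c("CD39", "CCR7"), op = c(">", "<"),
                        threshold = round(asinh(c(250, 150) / 150), 6),
                        stringsAsFactors = FALSE)
    list(events = events, gates = gates)
  })

  ## ---- spatial scenes -------------------------------------------------------
  scenes <- with_seed(streams[7], {
    window <- c(xmin = 0, xmax = 1000, ymin = 0, ymax = 1000)
    lapply(seq_len(nrow(tp)), function(i) {
      vessels <- data.frame(cx = round(runif(cfg$n_vessels, 50, 950), 4),
                            cy = round(runif(cfg$n_vessels, 50, 950), 4),
                            r = round(runif(cfg$n_vessels, 8, 25), 4))
      cd8_tot <- if (tp$ptrt_label[i] == "high") 0.18 else 0.08
      f <- tp$true_frac_tumor[i]
      probs <- c(pTRT = cd8_tot * f, nonPTRT_CD8 = cd8_tot * (1 - f),
                 MG = 0.10, MDM = 0.08, other_immune = 0.12, nonimmune = 0)
      probs["nonimmune"] <- 1 - sum(probs)
      n_by <- as.integer(rmultinom(1, cfg$n_spatial_cells, probs))
      names(n_by) <- SPATIAL_PHENOTYPES
      place_uniform <- function(n) cbind(runif(n, window["xmin"], window["xmax"]),
                                         runif(n, window["ymin"], window["ymax"]))
      place_enriched <- function(n, odds) {
        if (n == 0) return(matrix(numeric(), 0, 2))
        out <- matrix(NA_real_, 0, 2)
        wmax <- max(odds, 1)
        while (nrow(out) < n) {
          cand <- place_uniform(2L * n + 20L)
          d <- dist_to_vessels(cand[, 1], cand[, 2], vessels)
          w <- ifelse(d <= 15, odds, 1) / wmax
          out <- rbind(out, cand[runif(nrow(cand)) < w, , drop = FALSE])
        }
        out[seq_len(n), , drop = FALSE]
      }
      xy <- lapply(SPATIAL_PHENOTYPES, function(ph) {
        n <- n_by[[ph]]
        if (ph == "pTRT") place_enriched(n, cfg$pvn_enrichment)
        else place_uniform(n)
      })
      xy <- do.call(rbind, xy)
      n_tot <- nrow(xy)
      cells <- data.frame(
        x = round(xy[, 1], 4), y = round(xy[, 2], 4),
        diameter = round(pmax(rnorm(n_tot, 8.5, 2.2), 1), 4),
        probability = round(rbeta(n_tot, 12, 2), 4),
        phenotype = rep(SPATIAL_PHENOTYPES, n_by),
        stringsAsFactors = FALSE)
      spatial_scene(cells, vessels, window, patient = tp$patient[i])
    })
  })
  if (nrow(tp)) names(scenes) <- tp$patient

  truth <- list(
    patients = truth_patients,
    disease_group = disease_group,
    signature_genes = genes$signature,
    contamination_genes = genes$contamination,
    cluster_markers = list(C1 = genes$markers_c1, C2 = genes$markers_c2,
                           C3 = genes$signature),
    tumor_exclusive_clones = tcrsim$exclusive,
    viral_clones = tcrsim$viral,
    pvn_enrichment = cfg$pvn_enrichment)

  structure(list(
    config = cfg, sc = sc, bulk = bulk,
    clonotypes = tcrsim$clonotypes, antigen_db = tcrsim$db,
    events = flowsim$events, gates = flowsim$gates,
    scenes = scenes,
    signatures = list(pTRT_signature = genes$signature),
    truth = truth), class = "ptrt_cohort")
}

#' @export
print.ptrt_cohort <- function(x, ...) {
  tpat <- x$truth$patients
  cat(sprintf("ptrt_cohort: %d patients (%d glioma, %d BrM; %d pTRT-high)\n",
              nrow(tpat), sum(tpat$disease == "glioma"),
              sum(tpat$disease == "BrM"), sum(tpat$ptrt_label == "high")))
  cat(sprintf("  sc: %d genes x %d cells | bulk: %d samples | clonotypes: %d\n",
              nrow(x$sc$counts), ncol(x$sc$counts), ncol(x$bulk$counts),
              nrow(x$clonotypes)))
  cat(sprintf("  flow events: %d | scenes: %d\n", nrow(x$events),
              length(x$scenes)))
  invisible(x)
}
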