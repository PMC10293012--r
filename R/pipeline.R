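#' Run the full pTRT stratification pipeline on a simulated cohort
#'
#' Executes every stage end to end: bulk sample QC and tumor-contamination
#' filtering, bulk hierarchical signature classification, single-cell QC and
#' pTRT-cluster abundance, flow-cytometry transform/downsampling/gating,
#' spatial QC with perivascular and density readouts, TCR repertoire
#' statistics, the cross-modality consensus call, and the imputed-versus-
#' measured correlation.
#'
#' @param cohort a [simulate_cohort()] result (or the equivalent list from
#'   [read_cohort()], with a `config` attached).
#' @param if_density_cut CD103+PD1+ (pTRT) cells per square millimeter above
#'   which the IF modality calls a sample high.
#' @param run_gsea also run preranked enrichment of the signature set on the
#'   high-versus-low CD8 tumor DE ranking.
#' @param n_perm permutations for the optional GSEA.
#' @return list with per-stage results: `contamination`, `bulk` (classifier
#'   table), `sc` (abundance + labels), `flow`, `spatial`, `tcr`,
#'   `consensus` (a [consensus_call()] result), `validation`
#'   (an [impute_vs_measured()] report), and optionally `gsea`.
#' @export
run_ptrt_pipeline <- function(cohort, if_density_cut = 40, run_gsea = FALSE,
                              n_perm = 500) {
  cfg <- cohort$config
  seed <- if (!is.null(cfg)) cfg$seed else 1L
  truth <- cohort$truth$patients

  ## ---- bulk: QC, decontamination, signature classifier -------------------
  bulk <- qc_min_counts(cohort$bulk)
  is_t <- bulk$meta$population %in% c("CD4", "CD8")
  t_cells <- subset_expr(bulk, samples = which(is_t))
  cd45neg <- subset_expr(bulk, samples = which(bulk$meta$population == "CD45neg"))
  contam <- contamination_filter(t_cells, cd45neg)
  cd8_tumor <- subset_expr(contam$filtered,
                           samples = which(contam$filtered$meta$population == "CD8" &
                                             contam$filtered$meta$compartment == "tumor"))
  fac <- tmm_factors(cd8_tumor)
  lcpm <- log_cpm(cd8_tumor, fac)
  signature <- cohort$signatures[[1]]
  bulk_class <- bulk_signature_classifier(lcpm, signature)
  bulk_class$patient <- cd8_tumor$meta$patient[match(bulk_class$sample,
                                                    colnames(cd8_tumor$counts))]

  ## ---- single cell: QC, abundance, classification ------------------------
  cells <- qc_cells(cohort$sc$cells)
  ab <- cluster_abundance(cells)
  c3 <- ab[ab$cluster_id == "C3" & ab$compartment == "tumor" &
             ab$lineage == "CD8", , drop = FALSE]
  sc_frac <- stats::setNames(c3$fraction, c3$patient)
  sc_frac <- sc_frac[truth$patient]
  sc_frac[is.na(sc_frac)] <- 0   # patients with no C3 cell at all
  names(sc_frac) <- truth$patient
  sc_label <- classify_by_cluster_fraction(sc_frac)

  ## ---- flow: transform, QC/downsample, gate, classify --------------------
  ev <- transform_events(cohort$events, markers = FLOW_MARKERS)
  ev <- qc_and_downsample(ev, seed = seed)
  gate <- cohort$gates
  gf <- gate_fraction(ev[ev$compartment == "tumor", , drop = FALSE], gate)
  gf$patient <- sub("_tumor$", "", gf$sample_id)
  flow_frac <- stats::setNames(gf$fraction, gf$patient)[truth$patient]
  names(flow_frac) <- truth$patient
  flow_label <- rep(NA_character_, nrow(truth))
  ok <- !is.na(flow_frac)
  flow_label[ok] <- classify_by_gate_fraction(flow_frac[ok])

  ## ---- spatial: QC, density and PVN readouts -----------------------------
  sp <- lapply(cohort$scenes, function(s) {
    sq <- qc_cells_spatial(s)
    if (!qc_scene(sq)) return(NULL)
    area_mm2 <- diff(sq$window[c("xmin", "xmax")]) *
      diff(sq$window[c("ymin", "ymax")]) / 1e6
    ptrt <- sq$cells[sq$cells$phenotype == "pTRT", , drop = FALSE]
    pvn <- if (nrow(ptrt)) mean(pvn_membership(ptrt, sq$vessels)) else NA_real_
    data.frame(patient = sq$patient,
               ptrt_density = nrow(ptrt) / area_mm2,
               pvn_fraction = pvn, stringsAsFactors = FALSE)
  })
  sp <- do.call(rbind, sp[!vapply(sp, is.null, logical(1))])
  if_density <- stats::setNames(sp$ptrt_density, sp$patient)[truth$patient]
  names(if_density) <- truth$patient
  if_label <- rep(NA_character_, nrow(truth))
  ok <- !is.na(if_density)
  if_label[ok] <- ifelse(if_density[ok] > if_density_cut, "high", "low")

  ## ---- TCR repertoire statistics -----------------------------------------
  rep_qc <- qc_repertoire(cohort$clonotypes)
  units <- repertoire_units(rep_qc)
  tcr_stats <- do.call(rbind, lapply(names(units), function(nm) {
    u <- units[[nm]]
    cs <- clone_size_categories(u$duplicate_count)
    data.frame(patient = u$patient[1], compartment = u$compartment[1],
               n_clonotypes = nrow(u), chao1 = chao1(u$duplicate_count),
               expanded_fraction = cs$expanded_fraction,
               stringsAsFactors = FALSE)
  }))
  paired <- do.call(rbind, lapply(truth$patient, function(p) {
    b <- rep_qc[rep_qc$patient == p & rep_qc$compartment == "blood", , drop = FALSE]
    t <- rep_qc[rep_qc$patient == p & rep_qc$compartment == "tumor", , drop = FALSE]
    if (nrow(b) == 0 || nrow(t) == 0) return(NULL)
    data.frame(patient = p,
               top15_tumor_exclusive = as.numeric(top_expanded_tumor_exclusive(b, t)),
               morisita = morisita_overlap(b, t), stringsAsFactors = FALSE)
  }))
  vdj <- match_antigen_db(rep_qc, cohort$antigen_db)

  ## ---- consensus and validation ------------------------------------------
  bulk_label <- stats::setNames(bulk_class$label, bulk_class$patient)[truth$patient]
  calls <- rbind(
    data.frame(patient = truth$patient, modality = "sc", label = sc_label,
               stringsAsFactors = FALSE),
    data.frame(patient = truth$patient, modality = "bulk",
               label = unname(bulk_label), stringsAsFactors = FALSE),
    data.frame(patient = truth$patient, modality = "flow", label = flow_label,
               stringsAsFactors = FALSE),
    data.frame(patient = truth$patient, modality = "if", label = if_label,
               stringsAsFactors = FALSE))
  calls <- calls[!is.na(calls$label), , drop = FALSE]
  consensus <- consensus_call(calls)
  validation <- impute_vs_measured(
    stats::setNames(bulk_class$score, bulk_class$patient), sc_frac)

  out <- list(
    contamination = contam,
    bulk = bulk_class,
    sc = list(abundance = ab, fraction = sc_frac, label = sc_label),
    flow = list(fraction = flow_frac, label = flow_label, table = gf),
    spatial = sp,
    tcr = list(per_unit = tcr_stats, paired = paired, vdj = vdj),
    consensus = consensus,
    validation = validation)

  if (run_gsea) {
    high <- truth$patient[truth$ptrt_label == "high"]
    low <- truth$patient[truth$ptrt_label == "low"]
    cols_h <- which(cd8_tumor$meta$patient %in% high)
    cols_l <- which(cd8_tumor$meta$patient %in% low)
    if (length(cols_h) >= 2 && length(cols_l) >= 2) {
      dea <- dea_two_group(cd8_tumor, cols_h, cols_l)
      ranks <- stats::setNames(dea$t, dea$gene)
      out$gsea <- preranked_gsea(ranks, cohort$signatures, n_perm = n_perm,
                                 seed = seed)
      out$dea <- dea
    }
  }
  out
}
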