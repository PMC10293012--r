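#' Single-cell quality filter
#'
#' Retains cells with a mitochondrial fraction strictly below 10% and a
#' feature (detected gene) count between 250 and 3,000 inclusive.
#'
#' @param cells data.frame of cell annotations with columns `mito`
#'   (fraction in `[0,1]`) and `features`.
#' @param max_mito strict upper bound on the mitochondrial fraction.
#' @param min_features,max_features inclusive feature-count bounds.
#' @return the retained rows of `cells`.
#' @export
qc_cells <- function(cells, max_mito = 0.10, min_features = 250,
                     max_features = 3000) {
  stop_if(!all(c("mito", "features") %in% names(cells)),
          "cells needs 'mito' and 'features' columns")
  stop_if(any(cells$mito < 0 | cells$mito > 1), "mito must lie in [0,1]")
  keep <- cells$mito < max_mito &
    cells$features >= min_features & cells$features <= max_features
  cells[keep, , drop = FALSE]
}

#' Cluster marker genes
#'
#' Per cluster versus all other cells: genes whose log fold change (difference
#' of mean log1p-normalized expression) exceeds `fc_cut` and that are detected
#' (count > 0) in at least `min_pct` of the cluster's cells, tested with the
#' Wilcoxon rank-sum test and BH-adjusted within each cluster.
#'
#' @param counts gene x cell count matrix (dense or sparse).
#' @param clusters cluster label per cell.
#' @param fc_cut log fold-change threshold (natural-log scale of the log1p
#'   normalized expression).
#' @param min_pct minimum detection fraction within the cluster.
#' @param scale_factor library-size normalization target before `log1p`.
#' @return data.frame with `cluster`, `gene`, `log_fc`, `pct_in`, `pct_out`,
#'   `p`, `fdr`.
#' @export
cluster_markers <- function(counts, clusters, fc_cut = 0.25, min_pct = 0.25,
                            scale_factor = 1e4) {
  counts <- as.matrix(counts)
  stop_if(length(clusters) != ncol(counts), "one cluster label per cell")
  stop_if(length(unique(clusters)) < 2, "need at least 2 clusters")
  lib <- colSums(counts)
  stop_if(any(lib == 0), "cells with zero counts are not allowed")
  norm <- log1p(sweep(counts, 2, lib, "/") * scale_factor)
  out <- list()
  for (cl in sort(unique(clusters))) {
    idx <- clusters == cl
    if (sum(idx) < 3) {
      warning("cluster '", cl, "' has fewer than 3 cells; skipped")
      next
    }
    m_in <- rowMeans(norm[, idx, drop = FALSE])
    m_out <- rowMeans(norm[, !idx, drop = FALSE])
    lfc <- m_in - m_out
    pct_in <- rowMeans(counts[, idx, drop = FALSE] > 0)
    pct_out <- rowMeans(counts[, !idx, drop = FALSE] > 0)
    cand <- which(lfc > fc_cut & pct_in >= min_pct)
    if (!length(cand)) next
    ## ties are expected on count-derived values; the rank-sum test falls
    ## back to its normal approximation there, which is the convention
    p <- vapply(cand, function(g)
      suppressWarnings(stats::wilcox.test(norm[g, idx],
                                          norm[g, !idx])$p.value), numeric(1))
    out[[as.character(cl)]] <- data.frame(
      cluster = cl, gene = rownames(counts)[cand], log_fc = lfc[cand],
      pct_in = pct_in[cand], pct_out = pct_out[cand], p = p,
      fdr = stats::p.adjust(p, method = "BH"),
      row.names = NULL, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(cluster = character(), gene = character(),
                      log_fc = numeric(), pct_in = numeric(),
                      pct_out = numeric(), p = numeric(), fdr = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Per-sample cluster abundance
#'
#' Fractions of each cluster among a patient x compartment x lineage unit's
#' cells; fractions sum to one within each unit.
#'
#' @param cells QC'd cell annotations with columns `patient`, `compartment`,
#'   `lineage`, `cluster_id`.
#' @return data.frame with `patient`, `compartment`, `lineage`, `cluster_id`,
#'   `n_cells`, `fraction`.
#' @export
cluster_abundance <- function(cells) {
  need <- c("patient", "compartment", "lineage", "cluster_id")
  stop_if(!all(need %in% names(cells)), "missing annotation columns")
  if (nrow(cells) == 0)
    return(data.frame(patient = character(), compartment = character(),
                      lineage = character(), cluster_id = character(),
                      n_cells = integer(), fraction = numeric(),
                      stringsAsFactors = FALSE))
  tab <- as.data.frame(table(patient = cells$patient,
                             compartment = cells$compartment,
                             lineage = cells$lineage,
                             cluster_id = cells$cluster_id),
                       stringsAsFactors = FALSE)
  names(tab)[names(tab) == "Freq"] <- "n_cells"
  unit <- interaction(tab$patient, tab$compartment, tab$lineage, drop = FALSE)
  tot <- stats::ave(tab$n_cells, unit, FUN = sum)
  tab <- tab[tot > 0, , drop = FALSE]
  tot <- tot[tot > 0]
  tab$fraction <- tab$n_cells / tot
  tab[order(tab$patient, tab$compartment, tab$lineage, tab$cluster_id), ,
      drop = FALSE]
}

#' Classify a sample by its pTRT-cluster fraction
#'
#' @param fraction fraction of CD8+ cells in the pTRT cluster, in `[0,1]`.
#' @param high_cut strict lower bound for `"high"` (fraction > 0.30).
#' @param low_cut strict upper bound for `"low"` (fraction < 0.15).
#' @return character vector of labels in `{"high","low","indeterminate"}`;
#'   the band between the cutoffs is labelled explicitly because the source
#'   cohort contained no such samples.
#' @export
classify_by_cluster_fraction <- function(fraction, high_cut = 0.30,
                                         low_cut = 0.15) {
  stop_if(any(is.na(fraction)) || any(fraction < 0 | fraction > 1),
          "fraction must lie in [0,1]")
  ifelse(fraction > high_cut, "high",
         ifelse(fraction < low_cut, "low", "indeterminate"))
}
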