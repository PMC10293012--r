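#' Bulk hierarchical-clustering pTRT classifier
#'
#' Z-scores each signature gene across samples, clusters the samples
#' (Euclidean distance, complete linkage), cuts the tree at k = 2 and labels
#' the cluster with the higher mean signature z-score as pTRT-high. When a
#' cut yields a singleton cluster the classifier falls back to thresholding
#' the per-sample mean z at 0, with a warning.
#'
#' @param lcpm_cd8 gene x sample log2-CPM matrix of CD8 samples.
#' @param c3_genes signature gene IDs (the pTRT-cluster markers).
#' @return data.frame with `sample`, `score` (mean signature z) and `label`
#'   (`"high"`/`"low"`).
#' @export
bulk_signature_classifier <- function(lcpm_cd8, c3_genes) {
  lcpm_cd8 <- as.matrix(lcpm_cd8)
  stop_if(ncol(lcpm_cd8) < 4, "need at least 4 samples")
  sig <- intersect(c3_genes, rownames(lcpm_cd8))
  stop_if(length(sig) < 2, "need at least 2 signature genes in the matrix")
  x <- lcpm_cd8[sig, , drop = FALSE]
  mu <- rowMeans(x)
  sd <- apply(x, 1, stats::sd)
  stop_if(all(sd == 0), "all samples identical: degenerate clustering")
  z <- (x - mu) / ifelse(sd > 0, sd, 1)
  z[sd == 0, ] <- 0
  score <- colMeans(z)
  ## deterministic ordering: hclust ties resolved by sample ID order
  ord <- order(colnames(lcpm_cd8))
  hc <- stats::hclust(stats::dist(t(z[, ord, drop = FALSE])),
                      method = "complete")
  grp <- stats::cutree(hc, k = 2)[order(ord)]   # back to input order
  if (min(table(grp)) == 1) {
    warning("k = 2 cut yields a singleton cluster; thresholding mean z at 0")
    label <- ifelse(score > 0, "high", "low")
  } else {
    m1 <- mean(score[grp == 1]); m2 <- mean(score[grp == 2])
    high_grp <- if (m1 >= m2) 1 else 2
    label <- ifelse(grp == high_grp, "high", "low")
  }
  data.frame(sample = colnames(lcpm_cd8), score = score, label = label,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Imputed-versus-measured validation
#'
#' Pearson correlation between a per-sample bulk signature score and a
#' directly measured pTRT fraction (single-cell, flow or IF), over the
#' samples carrying both values.
#'
#' @param scores named numeric vector (e.g. mean signature z per sample).
#' @param measured named numeric vector of measured pTRT fractions.
#' @return list with `r`, `r2`, `p`, `n_pairs`, `n_dropped`.
#' @export
impute_vs_measured <- function(scores, measured) {
  stop_if(is.null(names(scores)) || is.null(names(measured)),
          "both vectors must be named")
  common <- intersect(names(scores), names(measured))
  x <- scores[common]; y <- measured[common]
  ok <- is.finite(x) & is.finite(y)
  n_dropped <- length(union(names(scores), names(measured))) - sum(ok)
  x <- x[ok]; y <- y[ok]
  stop_if(length(x) < 3, "need at least 3 paired samples")
  stop_if(stats::sd(x) == 0 || stats::sd(y) == 0,
          "correlation undefined: a vector is constant")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), r2 = unname(ct$estimate)^2,
       p = ct$p.value, n_pairs = length(x), n_dropped = n_dropped)
}

#' Consensus pTRT call across modalities
#'
#' Per patient: unanimity among the informative (high/low) modality labels
#' gives that label; any disagreement gives `"discordant"`; patients with
#' only indeterminate (or no) labels are `"insufficient"`. The concordance
#' rate is the fraction of patients with two or more informative modalities
#' whose labels are unanimous. The result is invariant to modality order.
#'
#' @param calls data.frame with columns `patient`, `modality`, `label`
#'   (`"high"`, `"low"`, `"indeterminate"` or `NA`).
#' @return list of class `"ptrt_callset"`: `calls` (wide per-patient table
#'   with per-modality labels, `consensus` and `n_informative`) and
#'   `concordance_rate`.
#' @export
consensus_call <- function(calls) {
  stop_if(!all(c("patient", "modality", "label") %in% names(calls)),
          "calls needs patient, modality, label columns")
  stop_if(anyDuplicated(calls[, c("patient", "modality")]) > 0,
          "one label per patient and modality")
  patients <- sort(unique(calls$patient))
  modalities <- sort(unique(calls$modality))
  wide <- data.frame(patient = patients, stringsAsFactors = FALSE)
  for (m in modalities)
    wide[[m]] <- calls$label[match(paste(patients, m),
                                   paste(calls$patient, calls$modality))]
  consensus <- character(length(patients))
  n_inf <- integer(length(patients))
  for (i in seq_along(patients)) {
    labs <- unlist(wide[i, modalities], use.names = FALSE)
    inf <- labs[!is.na(labs) & labs %in% c("high", "low")]
    n_inf[i] <- length(inf)
    consensus[i] <- if (length(inf) == 0) "insufficient"
    else if (length(unique(inf)) == 1) inf[1]
    else "discordant"
  }
  wide$n_informative <- n_inf
  wide$consensus <- consensus
  multi <- n_inf >= 2
  structure(list(
    calls = wide,
    concordance_rate = if (any(multi))
      mean(consensus[multi] %in% c("high", "low")) else NA_real_),
    class = "ptrt_callset")
}

#' @export
print.ptrt_callset <- function(x, ...) {
  cat(sprintf("ptrt_callset: %d patients | consensus: %s | concordance %.1f%%\n",
              nrow(x$calls),
              paste(names(table(x$calls$consensus)),
                    table(x$calls$consensus), sep = "=", collapse = ", "),
              100 * x$concordance_rate))
  invisible(x)
}
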