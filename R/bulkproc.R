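#' Exclude low-depth bulk samples
#'
#' Samples whose total count is below `min_total` (default one million) are
#' removed; the threshold is strict, so a sample at exactly `min_total` is
#' retained.
#'
#' @param m an [expression_matrix()].
#' @param min_total minimum library size.
#' @return the filtered `expr_matrix`; excluded sample IDs are reported via
#'   `message()` and attached as attribute `"excluded"`.
#' @export
qc_min_counts <- function(m, min_total = 1e6) {
  stop_if(!inherits(m, "expr_matrix"), "m must be an expression_matrix")
  tot <- colSums(m$counts)
  keep <- tot >= min_total
  stop_if(!any(keep), "all samples fall below the minimum total count")
  if (any(!keep))
    message("excluding ", sum(!keep), " sample(s): ",
            paste(colnames(m$counts)[!keep], collapse = ", "))
  out <- subset_expr(m, samples = which(keep))
  attr(out, "excluded") <- colnames(m$counts)[!keep]
  out
}

#' Pairwise TMM factor against a reference column
#' @noRd
tmm_pair <- function(obs, ref, lib_obs, lib_ref,
                     logratio_trim = 0.3, sum_trim = 0.05) {
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  log_r <- log2((obs / lib_obs) / (ref / lib_ref))
  abs_e <- (log2(obs / lib_obs) + log2(ref / lib_ref)) / 2
  v <- (lib_obs - obs) / (lib_obs * obs) + (lib_ref - ref) / (lib_ref * ref)
  fin <- is.finite(log_r) & is.finite(abs_e)
  log_r <- log_r[fin]; abs_e <- abs_e[fin]; v <- v[fin]
  if (length(log_r) == 0 || max(abs(log_r)) < 1e-6) return(1)
  n <- length(log_r)
  lo_l <- floor(n * logratio_trim) + 1; hi_l <- n + 1 - lo_l
  lo_s <- floor(n * sum_trim) + 1; hi_s <- n + 1 - lo_s
  keep2 <- rank(log_r) >= lo_l & rank(log_r) <= hi_l &
    rank(abs_e) >= lo_s & rank(abs_e) <= hi_s
  f <- sum(log_r[keep2] / v[keep2], na.rm = TRUE) /
    sum(1 / v[keep2], na.rm = TRUE)
  if (!is.finite(f)) f <- 0
  2^f
}

#' Trimmed-mean-of-M-values normalization factors
#'
#' Library-composition scaling factors: the reference is the sample whose
#' 75th-percentile count fraction is closest to the cohort mean; each sample's
#' factor is the precision-weighted mean of gene-wise log2 ratios against the
#' reference after trimming 30% of extreme log-ratios and 5% of extreme
#' average intensities, and factors are rescaled to geometric mean 1.
#'
#' @param m an [expression_matrix()] or a count matrix.
#' @param logratio_trim,sum_trim trim fractions on the M and A scales.
#' @return named numeric vector of per-sample factors.
#' @export
tmm_factors <- function(m, logratio_trim = 0.3, sum_trim = 0.05) {
  counts <- if (inherits(m, "expr_matrix")) as.matrix(m$counts) else as.matrix(m)
  stop_if(ncol(counts) < 2, "TMM needs at least 2 samples")
  lib <- colSums(counts)
  stop_if(any(lib == 0), "all-zero samples are not allowed")
  f75 <- apply(counts, 2, function(x) stats::quantile(x, 0.75)) / lib
  ref <- which.min(abs(f75 - mean(f75)))
  f <- vapply(seq_len(ncol(counts)), function(j)
    tmm_pair(counts[, j], counts[, ref], lib[j], lib[ref],
             logratio_trim, sum_trim), numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  f
}

#' Log2 counts per million
#'
#' `log2((count + prior_count) / (library size x factor) * 1e6)`.
#'
#' @param m an [expression_matrix()] or count matrix.
#' @param factors per-sample scaling factors (default all 1).
#' @param prior_count pseudo-count added to every entry.
#' @return real matrix of the same dimension.
#' @export
log_cpm <- function(m, factors = NULL, prior_count = 0.5) {
  counts <- if (inherits(m, "expr_matrix")) as.matrix(m$counts) else as.matrix(m)
  if (is.null(factors)) factors <- rep(1, ncol(counts))
  stop_if(length(factors) != ncol(counts),
          "factors must have one entry per sample")
  eff <- colSums(counts) * factors
  stop_if(any(eff <= 0), "zero effective library size")
  log2(sweep(counts + prior_count, 2, eff, "/") * 1e6)
}

#' Expression filter for differential testing
#'
#' Keeps genes with a count of at least `min_count` in at least as many
#' samples as the smallest group, and a total count of at least `min_total`
#' (an emulation of the standard count-filter defaults; the source analysis
#' states no constants).
#'
#' @param m an [expression_matrix()] or count matrix.
#' @param groups group label per sample.
#' @param min_count,min_total the two filter constants.
#' @return character vector of retained gene IDs.
#' @export
filter_by_expression <- function(m, groups, min_count = 10, min_total = 15) {
  counts <- if (inherits(m, "expr_matrix")) as.matrix(m$counts) else as.matrix(m)
  stop_if(length(groups) != ncol(counts), "groups must label every sample")
  tab <- table(groups)
  stop_if(length(tab) == 0 || any(tab == 0), "empty groups")
  n_min <- min(tab)
  keep <- rowSums(counts >= min_count) >= n_min & rowSums(counts) >= min_total
  rownames(counts)[keep]
}

#' Inverse of the trigamma function (for variance-shrinkage fitting)
#' @noRd
trigamma_inverse <- function(y) {
  if (y > trigamma(1e-8 / 2)) return(1e-8)
  if (y < trigamma(1e9 / 2)) return(1e9)
  stats::uniroot(function(d) trigamma(d / 2) - y,
                 lower = 1e-8, upper = 1e9, tol = 1e-10)$root
}

#' Two-group differential expression with moderated variance
#'
#' Ordinary two-sample tests on log2-CPM with empirical-Bayes variance
#' moderation: gene-wise residual variances are shrunk toward a pooled prior
#' fitted by method of moments on the log variances, and the t statistic uses
#' the augmented degrees of freedom. This is a documented emulation of
#' precision-weighted linear modelling; its contract is calibration (null
#' pass rate at or below the nominal FDR) and recovery of planted effects.
#'
#' @param m an [expression_matrix()] of counts.
#' @param group_a,group_b sample IDs (or indices) of the two groups; the
#'   reported log2 fold change is `mean(A) - mean(B)`.
#' @param fc_cut,fdr_cut significance cutoffs; a gene passes when
#'   `|log2FC| > log2(fc_cut)` and `FDR < fdr_cut`.
#' @param filter apply [filter_by_expression()] before testing (default TRUE).
#' @return data.frame with columns `gene`, `log2fc`, `mean_a`, `mean_b`
#'   (mean log2-CPM per group), `t`, `df_total`, `p`, `fdr`, `pass`.
#' @export
dea_two_group <- function(m, group_a, group_b, fc_cut = 2, fdr_cut = 0.05,
                          filter = TRUE) {
  stop_if(!inherits(m, "expr_matrix"), "m must be an expression_matrix")
  ids <- colnames(m$counts)
  a <- if (is.character(group_a)) match(group_a, ids) else as.integer(group_a)
  b <- if (is.character(group_b)) match(group_b, ids) else as.integer(group_b)
  stop_if(anyNA(a) || anyNA(b), "unknown sample IDs")
  stop_if(length(intersect(a, b)) > 0, "groups overlap")
  na <- length(a); nb <- length(b)
  stop_if(na < 2 || nb < 2, "each group needs at least 2 samples")
  df_resid <- na + nb - 2
  stop_if(df_resid < 1, "zero residual degrees of freedom")
  sub <- subset_expr(m, samples = c(a, b))
  if (filter) {
    grp <- rep(c("A", "B"), c(na, nb))
    keep <- filter_by_expression(sub, grp)
    stop_if(length(keep) == 0, "no genes pass the expression filter")
    sub <- subset_expr(sub, genes = keep)
  }
  fac <- tmm_factors(sub)
  lcpm <- log_cpm(sub, fac)
  xa <- lcpm[, seq_len(na), drop = FALSE]
  xb <- lcpm[, na + seq_len(nb), drop = FALSE]
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  ss <- rowSums((xa - ma)^2) + rowSums((xb - mb)^2)
  s2 <- ss / df_resid
  ## method-of-moments fit of the scaled inverse-chi-square prior on log s2
  pos <- s2 > 0
  z <- log(s2[pos])
  evar <- stats::var(z) - trigamma(df_resid / 2)
  if (is.na(evar) || evar <= 0) {
    d0 <- Inf
    s02 <- exp(mean(z) - digamma(df_resid / 2) + log(df_resid / 2))
  } else {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(mean(z) - digamma(df_resid / 2) + log(df_resid / 2) +
                 digamma(d0 / 2) - log(d0 / 2))
  }
  s2_post <- if (is.infinite(d0)) rep(s02, length(s2)) else
    (d0 * s02 + df_resid * s2) / (d0 + df_resid)
  lfc <- ma - mb
  tstat <- lfc / sqrt(s2_post * (1 / na + 1 / nb))
  df_total <- df_resid + d0
  p <- if (is.infinite(df_total)) 2 * stats::pnorm(-abs(tstat)) else
    2 * stats::pt(-abs(tstat), df_total)
  fdr <- stats::p.adjust(p, method = "BH")
  res <- data.frame(gene = rownames(lcpm), log2fc = lfc, mean_a = ma,
                    mean_b = mb, t = tstat, df_total = df_total, p = p,
                    fdr = fdr,
                    pass = abs(lfc) > log2(fc_cut) & fdr < fdr_cut,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(res, "prior") <- c(d0 = d0, s02 = s02)
  res
}

#' Four-step tumor-contamination gene filter
#'
#' Removes genes attributable to tumor-cell (CD45-) contamination of sorted
#' T cell profiles. Per disease group: (1) take the `n_top` genes with the
#' highest mean log2-CPM in CD45- samples, (2) run differential expression
#' between CD45- samples and all T cells (blood and tumor pooled),
#' (3) keep genes higher in CD45- with fold change above `fc_cut` and FDR
#' below `fdr_cut` (the fold-change cut is applied as `log2FC > log2(fc_cut)`),
#' (4) intersect (1) and (3). The removed set is the union over disease
#' groups.
#'
#' @param t_cells,cd45neg [expression_matrix()] objects sharing a gene
#'   universe; disease groups are read from `meta$disease` with pTRT suffixes
#'   collapsed (e.g. `"BrM-pTRT-high"` -> `"BrM"`).
#' @param n_top,fc_cut,fdr_cut filter constants.
#' @return list with `removed` (gene IDs), `filtered` (T cell matrix without
#'   them) and `per_group` (step-4 set per disease group).
#' @export
contamination_filter <- function(t_cells, cd45neg, n_top = 250, fc_cut = 3,
                                 fdr_cut = 0.001) {
  stop_if(!inherits(t_cells, "expr_matrix") || !inherits(cd45neg, "expr_matrix"),
          "inputs must be expression_matrix objects")
  stop_if(!identical(rownames(t_cells$counts), rownames(cd45neg$counts)),
          "matrices must share the same gene universe")
  major <- function(d) sub("-pTRT-(high|low)$", "", d)
  groups <- sort(unique(major(t_cells$meta$disease)))
  per_group <- list()
  for (g in groups) {
    t_idx <- which(major(t_cells$meta$disease) == g)
    c_idx <- which(major(cd45neg$meta$disease) == g)
    if (length(c_idx) < 2) {
      warning("disease group '", g, "' has <2 CD45- samples; skipped")
      next
    }
    comb <- expression_matrix(
      cbind(cd45neg$counts[, c_idx, drop = FALSE],
            t_cells$counts[, t_idx, drop = FALSE]),
      rbind(cd45neg$meta[c_idx, , drop = FALSE],
            t_cells$meta[t_idx, , drop = FALSE]))
    ## step 1: most highly expressed genes in the CD45- compartment
    fac_c <- tmm_factors(comb$counts[, seq_along(c_idx), drop = FALSE])
    lcpm_c <- log_cpm(comb$counts[, seq_along(c_idx), drop = FALSE], fac_c)
    avg <- rowMeans(lcpm_c)
    top <- rownames(comb$counts)[order(-avg, rownames(comb$counts))][seq_len(min(n_top, nrow(comb$counts)))]
    ## steps 2-3: stringent DEA, CD45- versus all T cells
    dea <- dea_two_group(comb, seq_along(c_idx),
                         length(c_idx) + seq_along(t_idx),
                         fc_cut = fc_cut, fdr_cut = fdr_cut)
    up <- dea$gene[dea$log2fc > log2(fc_cut) & dea$fdr < fdr_cut]
    ## step 4: intersection
    per_group[[g]] <- sort(intersect(top, up))
  }
  removed <- sort(unique(unlist(per_group, use.names = FALSE)))
  keep <- setdiff(rownames(t_cells$counts), removed)
  list(removed = removed,
       filtered = subset_expr(t_cells, genes = keep),
       per_group = per_group)
}

#' Most variable genes
#'
#' @param lcpm log2-CPM matrix (genes x samples).
#' @param n number of genes to return; ties broken by gene ID.
#' @return character vector of `n` gene IDs with maximal variance.
#' @export
top_variable_genes <- function(lcpm, n = 250) {
  lcpm <- as.matrix(lcpm)
  stop_if(n > nrow(lcpm), "n exceeds the number of genes")
  mu <- rowMeans(lcpm)
  v <- rowSums((lcpm - mu)^2) / (ncol(lcpm) - 1)
  rownames(lcpm)[order(-v, rownames(lcpm))][seq_len(n)]
}
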