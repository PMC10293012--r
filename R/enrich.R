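#' Read gene sets from a GMT file
#'
#' @param path GMT file: one set per line, tab-separated
#'   `name<TAB>description<TAB>gene1<TAB>gene2...`.
#' @return named list of character vectors; descriptions kept as attribute
#'   `"provenance"`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[`, character(1), 1L)
  attr(sets, "provenance") <- vapply(parts, `[`, character(1), 2L)
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of gene ID vectors.
#' @param path output path.
#' @param note provenance string written to the description column.
#' @export
write_gmt <- function(sets, path, note = "") {
  stop_if(is.null(names(sets)) || any(!nzchar(names(sets))),
          "sets must be a named list")
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, note, sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
}

#' Expression-bin assignment by average expression
#' @noRd
expr_bins <- function(avg, n_bins) {
  r <- rank(avg, ties.method = "first")
  as.integer(ceiling(r / (length(avg) / n_bins)))
}

#' Binned-control module score
#'
#' For each cell, the mean expression of the signature genes minus the mean
#' expression of a pooled control set: every signature gene contributes
#' `n_ctrl` control genes drawn (with replacement) from its average-expression
#' bin, so the control matches the signature's expression distribution.
#'
#' @param expr gene x cell real matrix (any monotone expression scale).
#' @param signature character vector of gene IDs.
#' @param n_bins number of average-expression bins.
#' @param n_ctrl control genes drawn per signature gene.
#' @param seed integer fixing the control draws.
#' @return named numeric vector of per-cell scores.
#' @export
module_score <- function(expr, signature, n_bins = 24, n_ctrl = 100,
                         seed = 1) {
  expr <- as.matrix(expr)
  stop_if(nrow(expr) < n_bins, "need at least n_bins genes")
  sig <- intersect(signature, rownames(expr))
  stop_if(length(sig) == 0, "signature has no genes in the matrix")
  avg <- rowMeans(expr)
  bins <- expr_bins(avg, n_bins)
  names(bins) <- rownames(expr)
  ctrl <- with_seed(seed, {
    unlist(lapply(sig, function(g) {
      pool <- rownames(expr)[bins == bins[[g]]]
      sample(pool, n_ctrl, replace = TRUE)
    }), use.names = FALSE)
  })
  sig_mean <- colMeans(expr[sig, , drop = FALSE])
  ctrl_mean <- colMeans(expr[ctrl, , drop = FALSE])
  sig_mean - ctrl_mean
}

#' Preranked gene-set enrichment with permutation p-values
#'
#' Weighted Kolmogorov-Smirnov enrichment: walking down the ranking, set
#' members increment the running sum proportionally to `|statistic|^weight`
#' and non-members decrement it uniformly; the score is the signed extremum.
#' P-values come from gene-label permutation (random sets of the same size),
#' two-sided on `|ES|`, floored at `1/(n_perm + 1)`; sets outside
#' `[min_size, max_size]` after intersecting with the ranked genes are
#' flagged excluded.
#'
#' @param ranks named numeric vector of per-gene statistics (e.g. moderated-t).
#' @param sets named list of gene ID vectors.
#' @param min_size,max_size set-size bounds after intersection.
#' @param n_perm number of permutations.
#' @param weight exponent on `|statistic|` for hit increments.
#' @param seed integer seed for the permutations.
#' @return data.frame with one row per set: `set`, `size`, `es`, `nes`,
#'   `p`, `fdr`, `excluded`.
#' @export
preranked_gsea <- function(ranks, sets, min_size = 15, max_size = 500,
                           n_perm = 1000, weight = 1, seed = 1) {
  stop_if(is.null(names(ranks)) || anyDuplicated(names(ranks)) > 0,
          "ranks must be named with unique gene IDs")
  stop_if(any(!is.finite(ranks)), "ranks must be finite")
  ord <- order(ranks, decreasing = TRUE)
  stat_sorted <- ranks[ord]
  genes_sorted <- names(ranks)[ord]
  n <- length(ranks)
  wstat <- abs(stat_sorted)^weight
  sizes <- vapply(sets, function(s) length(intersect(s, genes_sorted)),
                  integer(1))
  excluded <- sizes < min_size | sizes > max_size
  es <- rep(NA_real_, length(sets))
  p <- rep(NA_real_, length(sets))
  nes <- rep(NA_real_, length(sets))
  perm_cache <- new.env()
  with_seed(seed, {
    for (i in seq_along(sets)) {
      if (excluded[i]) next
      hit <- genes_sorted %in% sets[[i]]
      es[i] <- gsea_es_weighted(wstat, hit)
      key <- as.character(sizes[i])
      if (is.null(perm_cache[[key]])) {
        perm_cache[[key]] <- vapply(seq_len(n_perm), function(k) {
          h <- logical(n)
          h[sample.int(n, sizes[i])] <- TRUE
          gsea_es_weighted(wstat, h)
        }, numeric(1))
      }
      perm <- perm_cache[[key]]
      p[i] <- (1 + sum(abs(perm) >= abs(es[i]))) / (n_perm + 1)
      same_sign <- if (es[i] >= 0) perm[perm > 0] else -perm[perm < 0]
      nes[i] <- if (length(same_sign)) es[i] / mean(abs(same_sign)) else NA_real_
    }
  })
  fdr <- rep(NA_real_, length(sets))
  fdr[!excluded] <- stats::p.adjust(p[!excluded], method = "BH")
  data.frame(set = names(sets), size = sizes, es = es, nes = nes, p = p,
             fdr = fdr, excluded = excluded, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Running-sum extremum on pre-weighted statistics
#' @noRd
gsea_es_weighted <- function(wstat, hit) {
  n <- length(wstat)
  nh <- sum(hit)
  denom <- sum(wstat[hit])
  step <- numeric(n)
  step[hit] <- if (denom > 0) wstat[hit] / denom else 1 / nh
  step[!hit] <- -1 / (n - nh)
  run <- cumsum(step)
  run[which.max(abs(run))]
}

#' Per-sample signature score as mean z
#'
#' Z-scores every gene across samples, then averages the z-scores of the set
#' genes within each sample. A monotone per-sample set score used for group
#' comparisons and as the bulk evidence channel of the pTRT caller; genes
#' with zero variance contribute z = 0.
#'
#' @param lcpm gene x sample matrix (log2-CPM).
#' @param sets named list of gene ID vectors.
#' @return sample x set numeric matrix of scores.
#' @export
per_sample_signature_enrichment <- function(lcpm, sets) {
  lcpm <- as.matrix(lcpm)
  stop_if(ncol(lcpm) < 2, "z-scores are undefined for a single sample")
  mu <- rowMeans(lcpm)
  sd <- apply(lcpm, 1, stats::sd)
  z <- (lcpm - mu) / ifelse(sd > 0, sd, 1)
  z[sd == 0, ] <- 0
  out <- vapply(sets, function(s) {
    s <- intersect(s, rownames(z))
    stop_if(length(s) == 0, "a set has no genes in the matrix")
    colMeans(z[s, , drop = FALSE])
  }, numeric(ncol(lcpm)))
  out <- matrix(out, ncol = length(sets),
                dimnames = list(colnames(lcpm), names(sets)))
  out
}
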