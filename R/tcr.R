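#' Split a clonotype table into patient x compartment units
#' @noRd
repertoire_units <- function(t) {
  split(t, interaction(t$patient, t$compartment, drop = TRUE, sep = ":"))
}

#' Repertoire-level quality filter
#'
#' Drops patient x compartment units with fewer than `min_unique` distinct
#' clonotypes (strict threshold: a unit with exactly `min_unique` is kept).
#'
#' @param t clonotype data.frame with columns `patient`, `compartment`,
#'   `junction_aa`, `duplicate_count`.
#' @param min_unique minimum number of distinct clonotypes.
#' @return the retained rows of `t`.
#' @export
qc_repertoire <- function(t, min_unique = 20) {
  if (nrow(t) == 0) return(t)
  units <- repertoire_units(t)
  keep <- vapply(units, function(u) length(unique(u$junction_aa)) >= min_unique,
                 logical(1))
  out <- do.call(rbind, units[keep])
  rownames(out) <- NULL
  if (is.null(out)) t[0, , drop = FALSE] else out
}

#' Chao1 lower-bound richness estimate
#'
#' Bias-corrected form `S_obs + f1 (f1 - 1) / (2 (f2 + 1))`, where `f1`/`f2`
#' are the numbers of clonotypes seen exactly once/twice; well-defined when
#' no doubletons exist.
#'
#' @param counts positive integer clone sizes of one repertoire unit.
#' @return the Chao1 estimate (numeric scalar).
#' @export
chao1 <- function(counts) {
  stop_if(length(counts) == 0, "empty repertoire unit")
  stop_if(any(counts < 1), "clone counts must be >= 1")
  s_obs <- length(counts)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

CLONE_BINS <- c(Rare = 1e-4, Small = 1e-3, Medium = 1e-2, Large = 1e-1,
                Hyperexpanded = 1)

#' Five-category clone-size binning
#'
#' Assigns each clonotype of a unit to a frequency category with right-closed
#' bins Rare (0, 1e-4], Small (1e-4, 1e-3], Medium (1e-3, 1e-2], Large
#' (1e-2, 1e-1], Hyperexpanded (1e-1, 1], and reports per-category cell
#' fractions plus the substantially-expanded fraction (Large +
#' Hyperexpanded).
#'
#' @param counts positive clone sizes of one unit; frequencies are computed
#'   within the unit.
#' @param bins named upper bin edges (right-closed), defaults above.
#' @return list with `clonotypes` (data.frame `count`, `frequency`,
#'   `category`), `cell_fractions` (named, sums to 1) and
#'   `expanded_fraction`.
#' @export
clone_size_categories <- function(counts, bins = CLONE_BINS) {
  stop_if(length(counts) == 0, "empty repertoire unit")
  freq <- counts / sum(counts)
  stop_if(any(freq <= 0 | freq > 1), "frequencies must lie in (0,1]")
  edges <- c(0, unname(bins))
  cat <- names(bins)[findInterval(freq, edges, left.open = TRUE,
                                  rightmost.closed = TRUE)]
  cf <- vapply(names(bins), function(b) sum(freq[cat == b]), numeric(1))
  list(clonotypes = data.frame(count = counts, frequency = freq,
                               category = cat, stringsAsFactors = FALSE),
       cell_fractions = cf,
       expanded_fraction = unname(cf["Large"] + cf["Hyperexpanded"]))
}

#' Join blood and tumor units of one patient by clonotype
#' @noRd
join_units <- function(blood, tumor) {
  stop_if(length(unique(c(blood$patient, tumor$patient))) > 1,
          "blood and tumor units must come from the same patient")
  all_j <- union(blood$junction_aa, tumor$junction_aa)
  b <- blood$duplicate_count[match(all_j, blood$junction_aa)]
  t <- tumor$duplicate_count[match(all_j, tumor$junction_aa)]
  data.frame(junction_aa = all_j,
             blood_count = ifelse(is.na(b), 0L, b),
             tumor_count = ifelse(is.na(t), 0L, t),
             stringsAsFactors = FALSE)
}

#' Blood-tumor expansion classes
#'
#' A clonotype counts as expanded in a compartment when its count there is at
#' least `expand_min_count`; clonotypes absent from a compartment have count
#' zero. The four classes combine the two indicators.
#'
#' @param blood,tumor clonotype data.frames of one patient's two
#'   compartments.
#' @param expand_min_count expansion threshold (count scale).
#' @return data.frame with `junction_aa`, `blood_count`, `tumor_count`,
#'   `class` in `{"not expanded","tumor-only expanded","blood-only
#'   expanded","dually expanded"}`; threshold kept as attribute
#'   `"expand_min_count"`.
#' @export
expansion_classes <- function(blood, tumor, expand_min_count = 2) {
  j <- join_units(blood, tumor)
  eb <- j$blood_count >= expand_min_count
  et <- j$tumor_count >= expand_min_count
  j$class <- ifelse(eb & et, "dually expanded",
                    ifelse(et, "tumor-only expanded",
                           ifelse(eb, "blood-only expanded", "not expanded")))
  attr(j, "expand_min_count") <- expand_min_count
  j
}

#' Tumor exclusivity of the most-expanded clones
#'
#' Ranks tumor clonotypes by descending count (ties broken by junction
#' sequence) and reports the proportion of the top `k` that are absent from
#' the patient's blood.
#'
#' @param blood,tumor clonotype data.frames of one patient.
#' @param k number of top clones (all are used, with a warning, if the tumor
#'   unit has fewer).
#' @return numeric proportion in `[0,1]` with attribute `"k_used"`.
#' @export
top_expanded_tumor_exclusive <- function(blood, tumor, k = 15) {
  stop_if(nrow(tumor) == 0, "empty tumor unit")
  ord <- order(-tumor$duplicate_count, tumor$junction_aa)
  if (nrow(tumor) < k) {
    warning("tumor unit has fewer than ", k, " clonotypes; using all")
    k <- nrow(tumor)
  }
  top <- tumor$junction_aa[ord][seq_len(k)]
  prop <- mean(!(top %in% blood$junction_aa))
  attr(prop, "k_used") <- k
  prop
}

#' Morisita-Horn repertoire overlap
#'
#' `2 sum(p q) / (sum(p^2) + sum(q^2))` over the union of clonotypes, with
#' `p`, `q` the within-unit frequencies. Symmetric, in `[0,1]`, invariant to
#' rescaling either unit's counts.
#'
#' @param u,v clonotype data.frames (columns `junction_aa`,
#'   `duplicate_count`).
#' @return overlap index in `[0,1]`.
#' @export
morisita_overlap <- function(u, v) {
  stop_if(nrow(u) == 0 || nrow(v) == 0, "empty repertoire unit")
  all_j <- union(u$junction_aa, v$junction_aa)
  cu <- u$duplicate_count[match(all_j, u$junction_aa)]
  cv <- v$duplicate_count[match(all_j, v$junction_aa)]
  p <- ifelse(is.na(cu), 0, cu); p <- p / sum(p)
  q <- ifelse(is.na(cv), 0, cv); q <- q / sum(q)
  2 * sum(p * q) / (sum(p^2) + sum(q^2))
}

#' Match clonotypes against an antigen database
#'
#' Exact CDR3beta amino-acid matches against database entries with a
#' confidence score of at least `min_score`; V/J calls are annotation only
#' and do not enter the match.
#'
#' @param t clonotype data.frame.
#' @param db data.frame with `junction_aa`, `species`, `score`.
#' @param min_score minimum database confidence score (default 1, so
#'   score-0 entries never match).
#' @param group optional column name of `t` used for the per-group unique
#'   match counts (default `"patient"`).
#' @return list with `matches` (unique matched clonotypes with species) and
#'   `counts` (unique matches per group).
#' @export
match_antigen_db <- function(t, db, min_score = 1, group = "patient") {
  stop_if(nrow(db) == 0, "empty antigen database")
  stop_if(!group %in% names(t), sprintf("no '%s' column in t", group))
  db <- db[db$score >= min_score, , drop = FALSE]
  hit <- t$junction_aa %in% db$junction_aa
  m <- t[hit, , drop = FALSE]
  m <- m[!duplicated(m[, c(group, "junction_aa")]), , drop = FALSE]
  if (nrow(m)) {
    sp <- db$species[match(m$junction_aa, db$junction_aa)]
    m$species <- sp
  } else m$species <- character(0)
  counts <- if (nrow(m)) as.data.frame(table(group = m[[group]]),
                                       stringsAsFactors = FALSE)
  else data.frame(group = character(), Freq = integer(),
                  stringsAsFactors = FALSE)
  names(counts) <- c(group, "n_matched")
  rownames(m) <- NULL
  list(matches = m, counts = counts)
}
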