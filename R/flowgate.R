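#' Arcsinh transform of cytometry intensities
#'
#' `asinh(x / cofactor)`, the standard variance-stabilizing transform for
#' compensated cytometry data.
#'
#' @param x numeric intensities.
#' @param cofactor positive divisor applied before `asinh` (default 150).
#' @return transformed intensities.
#' @export
arcsinh_transform <- function(x, cofactor = 150) {
  stop_if(!is.numeric(cofactor) || length(cofactor) != 1L || cofactor <= 0,
          "cofactor must be a single positive number")
  asinh(x / cofactor)
}

#' Apply the arcsinh transform to the marker columns of an event table
#'
#' @param events event data.frame.
#' @param markers marker column names (default: every numeric column except
#'   metadata).
#' @param cofactor see [arcsinh_transform()].
#' @return the event table with transformed marker columns.
#' @export
transform_events <- function(events, markers = NULL, cofactor = 150) {
  if (is.null(markers))
    markers <- setdiff(names(events)[vapply(events, is.numeric, logical(1))],
                       c("sample_id", "patient", "compartment"))
  stop_if(!all(markers %in% names(events)), "unknown marker name")
  events[markers] <- lapply(events[markers], arcsinh_transform,
                            cofactor = cofactor)
  events
}

#' Per-sample event QC and downsampling
#'
#' Samples with fewer than `min_events` lineage-gated events are excluded
#' (strict threshold); samples larger than `n_keep` are downsampled to
#' exactly `n_keep` events without replacement under `seed`; smaller samples
#' are kept whole.
#'
#' @param events event data.frame with a `sample_id` column.
#' @param min_events minimum events per sample.
#' @param n_keep downsampling target.
#' @param seed integer seed for the subsampling.
#' @return the retained events; excluded sample IDs in attribute
#'   `"excluded"`.
#' @export
qc_and_downsample <- function(events, min_events = 100, n_keep = 1500,
                              seed = 1) {
  stop_if(!"sample_id" %in% names(events), "events needs a 'sample_id' column")
  n_per <- table(events$sample_id)
  drop <- names(n_per)[n_per < min_events]
  events <- events[!(events$sample_id %in% drop), , drop = FALSE]
  kept <- with_seed(seed, {
    idx <- unlist(lapply(sort(unique(events$sample_id)), function(s) {
      rows <- which(events$sample_id == s)
      if (length(rows) > n_keep) sort(sample(rows, n_keep)) else rows
    }), use.names = FALSE)
    events[idx, , drop = FALSE]
  })
  rownames(kept) <- NULL
  attr(kept, "excluded") <- drop
  kept
}

#' Build a threshold gate definition
#'
#' @param ... named comparisons, e.g. `flow_gate(CD39 = c(">", 1.1),
#'   CCR7 = c("<", 0.9))`; each value is `c(operator, threshold)` with
#'   operator one of `>`, `<`, `>=`, `<=`.
#' @return data.frame with columns `marker`, `op`, `threshold`.
#' @export
flow_gate <- function(...) {
  args <- list(...)
  stop_if(length(args) == 0 || is.null(names(args)), "supply named comparisons")
  data.frame(marker = names(args),
             op = vapply(args, function(a) as.character(a[1]), character(1)),
             threshold = vapply(args, function(a) as.numeric(a[2]), numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Evaluate a gate on an event table
#' @noRd
gate_mask <- function(events, gate) {
  stop_if(!all(gate$marker %in% names(events)),
          "unknown marker name in gate: ",
          paste(setdiff(gate$marker, names(events)), collapse = ", "))
  ok <- rep(TRUE, nrow(events))
  for (i in seq_len(nrow(gate))) {
    x <- events[[gate$marker[i]]]
    ok <- ok & switch(gate$op[i],
                      ">" = x > gate$threshold[i],
                      "<" = x < gate$threshold[i],
                      ">=" = x >= gate$threshold[i],
                      "<=" = x <= gate$threshold[i],
                      stop("unsupported operator: ", gate$op[i]))
  }
  ok
}

#' Per-sample gated fraction
#'
#' Fraction of each sample's lineage events satisfying every predicate of the
#' gate (a conjunction of per-marker thresholds on transformed intensities),
#' optionally with the median transformed intensity of requested markers
#' within the gate.
#'
#' @param events transformed event table.
#' @param gate a [flow_gate()] (or data.frame `marker`, `op`, `threshold`).
#' @param median_markers optional marker names whose in-gate median is
#'   reported per sample.
#' @return data.frame with `sample_id`, `n_events`, `n_gated`, `fraction`
#'   and one `median_<marker>` column per requested marker.
#' @export
gate_fraction <- function(events, gate, median_markers = NULL) {
  ok <- gate_mask(events, gate)
  samples <- sort(unique(events$sample_id))
  out <- do.call(rbind, lapply(samples, function(s) {
    rows <- events$sample_id == s
    n <- sum(rows); ng <- sum(ok & rows)
    row <- data.frame(sample_id = s, n_events = n, n_gated = ng,
                      fraction = ng / n, stringsAsFactors = FALSE)
    for (mk in median_markers) {
      stop_if(!mk %in% names(events), "unknown marker name: ", mk)
      row[[paste0("median_", mk)]] <-
        if (ng > 0) stats::median(events[[mk]][ok & rows]) else NA_real_
    }
    row
  }))
  rownames(out) <- NULL
  out
}

#' Classify a sample by its gated pTRT fraction
#'
#' @param fraction gated fraction of CD8+ events, in `[0,1]`.
#' @param high_cut strict threshold: `"high"` iff `fraction > high_cut`.
#' @return character vector of `"high"`/`"low"` labels.
#' @export
classify_by_gate_fraction <- function(fraction, high_cut = 0.30) {
  stop_if(any(is.na(fraction)) || any(fraction < 0 | fraction > 1),
          "fraction must lie in [0,1]")
  ifelse(fraction > high_cut, "high", "low")
}
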