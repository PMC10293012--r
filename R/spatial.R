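#' Segmented tissue scene
#'
#' One multiplexed-IF tissue section: segmented cells (centroid coordinates
#' in micrometers, diameter, detection probability, phenotype) plus vessel
#' discs and the bounding window.
#'
#' @param cells data.frame with columns `x`, `y`, `diameter`, `probability`,
#'   `phenotype` (one of `pTRT`, `nonPTRT_CD8`, `MG`, `MDM`, `other_immune`,
#'   `nonimmune`).
#' @param vessels data.frame of discs with columns `cx`, `cy`, `r`.
#' @param window named numeric `c(xmin=, xmax=, ymin=, ymax=)`.
#' @param patient optional patient/scene identifier.
#' @return object of class `"spatial_scene"`.
#' @export
spatial_scene <- function(cells, vessels, window, patient = NA_character_) {
  stop_if(!all(c("x", "y", "diameter", "probability", "phenotype") %in%
                 names(cells)), "missing cell columns")
  stop_if(!all(c("cx", "cy", "r") %in% names(vessels)),
          "missing vessel columns")
  stop_if(length(window) != 4 ||
            !all(c("xmin", "xmax", "ymin", "ymax") %in% names(window)),
          "window must be c(xmin=, xmax=, ymin=, ymax=)")
  stop_if(any(vessels$r <= 0), "vessel radii must be positive")
  stop_if(!all(cells$phenotype %in% SPATIAL_PHENOTYPES),
          "unknown phenotype label")
  stop_if(nrow(cells) > 0 &&
            (any(cells$x < window["xmin"] | cells$x > window["xmax"]) ||
               any(cells$y < window["ymin"] | cells$y > window["ymax"])),
          "all cells must lie inside the window")
  rownames(cells) <- NULL
  structure(list(cells = cells, vessels = vessels,
                 window = window[c("xmin", "xmax", "ymin", "ymax")],
                 patient = patient),
            class = "spatial_scene")
}

#' @export
print.spatial_scene <- function(x, ...) {
  cat(sprintf("spatial_scene (%s): %d cells, %d vessels, window %g x %g um\n",
              x$patient, nrow(x$cells), nrow(x$vessels),
              diff(x$window[c("xmin", "xmax")]),
              diff(x$window[c("ymin", "ymax")])))
  print(table(x$cells$phenotype))
  invisible(x)
}

#' Distance of points to the nearest vessel boundary (vectorized)
#' @noRd
dist_to_vessels <- function(x, y, vessels) {
  stop_if(nrow(vessels) == 0, "scene has no vessels")
  d <- matrix(Inf, length(x), nrow(vessels))
  for (j in seq_len(nrow(vessels)))
    d[, j] <- pmax(0, sqrt((x - vessels$cx[j])^2 + (y - vessels$cy[j])^2) -
                     vessels$r[j])
  apply(d, 1, min)
}

#' Cell-level spatial quality filter
#'
#' Keeps cells with diameter strictly between `d_min` and `d_max` micrometers
#' and detection probability strictly above `p_min`.
#'
#' @param scene a [spatial_scene()].
#' @param d_min,d_max,p_min filter thresholds (all strict).
#' @return the filtered scene.
#' @export
qc_cells_spatial <- function(scene, d_min = 4, d_max = 12.5, p_min = 0.65) {
  stop_if(!inherits(scene, "spatial_scene"), "not a spatial_scene")
  keep <- scene$cells$diameter > d_min & scene$cells$diameter < d_max &
    scene$cells$probability > p_min
  spatial_scene(scene$cells[keep, , drop = FALSE], scene$vessels,
                scene$window, scene$patient)
}

#' Scene-level quality decision
#'
#' A scene is kept only if it contains at least `min_cd8` CD8+ cells
#' (pTRT plus non-pTRT CD8) after cell-level QC.
#'
#' @param scene a QC'd [spatial_scene()].
#' @param min_cd8 minimum CD8+ cell count.
#' @return logical: `TRUE` to keep the scene.
#' @export
qc_scene <- function(scene, min_cd8 = 30) {
  stop_if(!inherits(scene, "spatial_scene"), "not a spatial_scene")
  sum(scene$cells$phenotype %in% c("pTRT", "nonPTRT_CD8")) >= min_cd8
}

#' Distance to the nearest vessel boundary
#'
#' `min over vessels of max(0, ||cell - center|| - radius)`; cells inside a
#' disc have distance zero.
#'
#' @param cells data.frame with `x`, `y` (or a [spatial_scene()], in which
#'   case its cells and vessels are used).
#' @param vessels disc data.frame `cx`, `cy`, `r` (ignored when `cells` is a
#'   scene).
#' @return numeric distances in micrometers.
#' @export
vessel_distance <- function(cells, vessels = NULL) {
  if (inherits(cells, "spatial_scene")) {
    vessels <- cells$vessels
    cells <- cells$cells
  }
  stop_if(is.null(vessels) || nrow(vessels) == 0, "no vessels supplied")
  dist_to_vessels(cells$x, cells$y, vessels)
}

#' Perivascular-niche membership
#'
#' A cell belongs to the PVN when its distance to the nearest vessel boundary
#' is at most `pvn_radius` (boundary inclusive: the niche is the closed
#' 15-um expansion of the vessels).
#'
#' @inheritParams vessel_distance
#' @param pvn_radius niche radius in micrometers.
#' @return logical vector.
#' @export
pvn_membership <- function(cells, vessels = NULL, pvn_radius = 15) {
  vessel_distance(cells, vessels) <= pvn_radius
}

#' PVN area fraction of the window
#'
#' Deterministic grid quadrature of the fraction of the window covered by
#' the closed `pvn_radius` expansion of the vessel discs; the uniform-
#' placement expectation for PVN membership.
#'
#' @param vessels disc data.frame `cx`, `cy`, `r`.
#' @param window named numeric `c(xmin=, xmax=, ymin=, ymax=)`.
#' @param pvn_radius expansion radius in micrometers.
#' @param n_grid grid points per axis.
#' @return area fraction in `[0,1]`.
#' @export
pvn_area_fraction <- function(vessels, window, pvn_radius = 15,
                              n_grid = 1000) {
  gx <- seq(window["xmin"], window["xmax"], length.out = n_grid)
  gy <- seq(window["ymin"], window["ymax"], length.out = n_grid)
  inside <- rep(FALSE, n_grid * n_grid)
  xx <- rep(gx, times = n_grid)
  yy <- rep(gy, each = n_grid)
  for (j in seq_len(nrow(vessels))) {
    r2 <- (vessels$r[j] + pvn_radius)^2
    inside <- inside | ((xx - vessels$cx[j])^2 + (yy - vessels$cy[j])^2 <= r2)
  }
  mean(inside)
}

#' Neighborhood composition around index cells
#'
#' For every index-phenotype cell, counts the phenotypes of all cells whose
#' center-to-center distance is at most `radius` (the index cell itself
#' excluded), plus the pooled composition over all index cells and the
#' reverse query: the fraction of CD8+ cells with at least one TAM (MG or
#' MDM) within the radius.
#'
#' @param scene a QC'd [spatial_scene()].
#' @param index_phenotype phenotype of the index cells (default `"pTRT"`).
#' @param radius neighborhood radius in micrometers.
#' @return list with `per_cell` (index cell x phenotype count matrix),
#'   `composition` (pooled phenotype fractions over neighbors of all index
#'   cells), `n_index`, and `cd8_near_tam_fraction`.
#' @export
neighborhood_composition <- function(scene, index_phenotype = "pTRT",
                                     radius = 20) {
  stop_if(!inherits(scene, "spatial_scene"), "not a spatial_scene")
  cells <- scene$cells
  idx <- which(cells$phenotype == index_phenotype)
  phenos <- SPATIAL_PHENOTYPES
  if (length(idx) == 0) {
    warning("no index cells with phenotype '", index_phenotype, "'")
    return(list(per_cell = matrix(0, 0, length(phenos),
                                  dimnames = list(NULL, phenos)),
                composition = stats::setNames(rep(NA_real_, length(phenos)),
                                              phenos),
                n_index = 0L, cd8_near_tam_fraction = NA_real_))
  }
  per_cell <- matrix(0L, length(idx), length(phenos),
                     dimnames = list(NULL, phenos))
  for (k in seq_along(idx)) {
    i <- idx[k]
    d2 <- (cells$x - cells$x[i])^2 + (cells$y - cells$y[i])^2
    nb <- which(d2 <= radius^2)
    nb <- nb[nb != i]
    if (length(nb))
      per_cell[k, ] <- as.integer(table(factor(cells$phenotype[nb],
                                               levels = phenos)))
  }
  tot <- colSums(per_cell)
  composition <- if (sum(tot) > 0) tot / sum(tot) else
    stats::setNames(rep(NA_real_, length(phenos)), phenos)
  ## reverse query: CD8 cells with >=1 TAM within the radius
  cd8 <- which(cells$phenotype %in% c("pTRT", "nonPTRT_CD8"))
  tam <- which(cells$phenotype %in% c("MG", "MDM"))
  near <- if (length(cd8) && length(tam)) {
    vapply(cd8, function(i) {
      any((cells$x[tam] - cells$x[i])^2 +
            (cells$y[tam] - cells$y[i])^2 <= radius^2)
    }, logical(1))
  } else logical(0)
  list(per_cell = per_cell, composition = composition,
       n_index = length(idx),
       cd8_near_tam_fraction = if (length(near)) mean(near) else NA_real_)
}

#' Nearest-neighbor distance between phenotypes
#'
#' Per source cell, the Euclidean distance to the nearest target cell
#' (coincident but distinct cells have distance zero), with group means
#' stratified by whether the source cell is a pTRT cell.
#'
#' @param scene a QC'd [spatial_scene()].
#' @param from_phenotype source phenotype(s).
#' @param to_phenotype target phenotype(s).
#' @return list with `distances` (data.frame `x`, `y`, `phenotype`,
#'   `distance`) and `stratified` (mean distance per source phenotype).
#' @export
nearest_phenotype_distance <- function(scene, from_phenotype,
                                       to_phenotype) {
  stop_if(!inherits(scene, "spatial_scene"), "not a spatial_scene")
  cells <- scene$cells
  src <- which(cells$phenotype %in% from_phenotype)
  tgt <- which(cells$phenotype %in% to_phenotype)
  if (length(tgt) == 0) {
    warning("no target cells with phenotype ",
            paste(to_phenotype, collapse = "/"))
    d <- rep(NA_real_, length(src))
  } else {
    d <- vapply(src, function(i) {
      cand <- tgt[tgt != i]
      if (!length(cand)) return(NA_real_)
      sqrt(min((cells$x[cand] - cells$x[i])^2 +
                 (cells$y[cand] - cells$y[i])^2))
    }, numeric(1))
  }
  out <- data.frame(x = cells$x[src], y = cells$y[src],
                    phenotype = cells$phenotype[src], distance = d,
                    stringsAsFactors = FALSE)
  strat <- tapply(out$distance, out$phenotype, mean, na.rm = TRUE)
  list(distances = out, stratified = strat)
}
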