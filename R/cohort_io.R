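write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

#' Write a simulated cohort to disk
#'
#' Emits the cohort in the plain-text exchange formats the pipeline consumes:
#' Matrix Market (MTX) plus gene/barcode TSVs for single-cell counts, dense
#' TSV for bulk counts, AIRR-style TSV for clonotypes, CSV for flow events and
#' spatial tables, and a `manifest.tsv` listing every file with its MD5
#' checksum.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the manifest data.frame (`file`, `md5`, `bytes`).
#' @export
write_cohort <- function(cohort, out_dir) {
  stop_if(!inherits(cohort, "ptrt_cohort"), "cohort must come from simulate_cohort()")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stop_if(!dir.exists(out_dir), sprintf("cannot create '%s'", out_dir))
  files <- character(0)
  put <- function(fn, writer) {
    path <- file.path(out_dir, fn)
    writer(path)
    files <<- c(files, fn)
  }
  if (nrow(cohort$truth$patients) > 0) {
    put("sc_counts.mtx", function(p) Matrix::writeMM(cohort$sc$counts, p))
    put("sc_genes.tsv", function(p)
      write_tsv(data.frame(gene_id = rownames(cohort$sc$counts)), p))
    put("sc_cells.tsv", function(p) write_tsv(cohort$sc$cells, p))
    put("bulk_counts.tsv", function(p)
      write_tsv(cbind(data.frame(gene_id = rownames(cohort$bulk$counts)),
                      as.data.frame(as.matrix(cohort$bulk$counts))), p))
    put("bulk_samples.tsv", function(p)
      write_tsv(cbind(data.frame(sample_id = colnames(cohort$bulk$counts)),
                      cohort$bulk$meta), p))
    put("clonotypes.tsv", function(p) {
      airr <- cohort$clonotypes
      names(airr)[names(airr) == "patient"] <- "patient_id"
      write_tsv(airr, p)
    })
    put("antigen_db.tsv", function(p) write_tsv(cohort$antigen_db, p))
    put("events.csv", function(p)
      utils::write.csv(cohort$events, p, row.names = FALSE, quote = FALSE))
    put("gates.tsv", function(p) write_tsv(cohort$gates, p))
    put("spatial_cells.csv", function(p) {
      cells <- do.call(rbind, lapply(cohort$scenes, function(s)
        cbind(data.frame(patient = s$patient, stringsAsFactors = FALSE), s$cells)))
      utils::write.csv(cells, p, row.names = FALSE, quote = FALSE)
    })
    put("vessels.csv", function(p) {
      ves <- do.call(rbind, lapply(cohort$scenes, function(s)
        cbind(data.frame(patient = s$patient, stringsAsFactors = FALSE), s$vessels)))
      utils::write.csv(ves, p, row.names = FALSE, quote = FALSE)
    })
    put("window.tsv", function(p) {
      w <- cohort$scenes[[1]]$window
      write_tsv(data.frame(xmin = w["xmin"], xmax = w["xmax"],
                           ymin = w["ymin"], ymax = w["ymax"]), p)
    })
    put("signatures.gmt", function(p)
      write_gmt(cohort$signatures, p, note = "planted synthetic signature"))
    put("patients.tsv", function(p) write_tsv(cohort$truth$patients, p))
    put("truth_genes.tsv", function(p) write_tsv(data.frame(
      gene_id = c(cohort$truth$signature_genes, cohort$truth$contamination_genes),
      role = rep(c("signature", "contamination"),
                 c(length(cohort$truth$signature_genes),
                   length(cohort$truth$contamination_genes)))), p))
    put("exclusive_clones.tsv", function(p)
      write_tsv(cohort$truth$tumor_exclusive_clones, p))
  }
  manifest <- data.frame(
    file = files,
    md5 = if (length(files)) unname(tools::md5sum(file.path(out_dir, files)))
          else character(),
    bytes = if (length(files)) unname(file.size(file.path(out_dir, files)))
            else numeric(),
    stringsAsFactors = FALSE)
  write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
  invisible(manifest)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing the cohort files.
#' @return A list with the same table components as the in-memory cohort
#'   (`sc`, `bulk`, `clonotypes`, `antigen_db`, `events`, `gates`, `scenes`,
#'   `truth`).
#' @export
read_cohort <- function(dir) {
  stop_if(!file.exists(file.path(dir, "manifest.tsv")),
          sprintf("no manifest.tsv under '%s'", dir))
  manifest <- read_tsv(file.path(dir, "manifest.tsv"))
  if (nrow(manifest) == 0)
    return(list(manifest = manifest))
  counts <- methods::as(Matrix::readMM(file.path(dir, "sc_counts.mtx")),
                        "CsparseMatrix")
  genes <- read_tsv(file.path(dir, "sc_genes.tsv"))$gene_id
  cells <- read_tsv(file.path(dir, "sc_cells.tsv"))
  dimnames(counts) <- list(genes, cells$cell_id)
  bulk_tab <- read_tsv(file.path(dir, "bulk_counts.tsv"))
  bulk_counts <- as.matrix(bulk_tab[, -1, drop = FALSE])
  rownames(bulk_counts) <- bulk_tab$gene_id
  bulk_meta <- read_tsv(file.path(dir, "bulk_samples.tsv"))
  bulk <- expression_matrix(bulk_counts, bulk_meta[, -1, drop = FALSE])
  clono <- read_tsv(file.path(dir, "clonotypes.tsv"))
  names(clono)[names(clono) == "patient_id"] <- "patient"
  events <- utils::read.csv(file.path(dir, "events.csv"),
                            stringsAsFactors = FALSE)
  sp_cells <- utils::read.csv(file.path(dir, "spatial_cells.csv"),
                              stringsAsFactors = FALSE)
  vessels <- utils::read.csv(file.path(dir, "vessels.csv"),
                             stringsAsFactors = FALSE)
  wtab <- read_tsv(file.path(dir, "window.tsv"))
  window <- c(xmin = wtab$xmin, xmax = wtab$xmax,
              ymin = wtab$ymin, ymax = wtab$ymax)
  patients <- read_tsv(file.path(dir, "patients.tsv"))
  scenes <- lapply(patients$patient, function(pat)
    spatial_scene(sp_cells[sp_cells$patient == pat,
                           setdiff(names(sp_cells), "patient"), drop = FALSE],
                  vessels[vessels$patient == pat,
                          setdiff(names(vessels), "patient"), drop = FALSE],
                  window, patient = pat))
  names(scenes) <- patients$patient
  truth_genes <- read_tsv(file.path(dir, "truth_genes.tsv"))
  list(
    sc = list(counts = counts, cells = cells),
    bulk = bulk,
    clonotypes = clono,
    antigen_db = read_tsv(file.path(dir, "antigen_db.tsv")),
    events = events,
    gates = read_tsv(file.path(dir, "gates.tsv")),
    scenes = scenes,
    signatures = read_gmt(file.path(dir, "signatures.gmt")),
    truth = list(
      patients = patients,
      signature_genes = truth_genes$gene_id[truth_genes$role == "signature"],
      contamination_genes = truth_genes$gene_id[truth_genes$role == "contamination"],
      tumor_exclusive_clones = read_tsv(file.path(dir, "exclusive_clones.tsv"))),
    manifest = manifest)
}
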