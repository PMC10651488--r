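# Readers and writers for the pipeline's plain-text interchange formats:
# panel counts as CSV + sample sheet, UMI matrices as a Matrix Market trio
# (matrix.mtx, features.tsv, barcodes.tsv) with a metadata CSV, gene lists
# as headed plain text, stress summaries as CSV, and fields as legacy-ASCII
# VTK. Writers emit a provenance header (seed/parameters) where the format
# tolerates comments; integer data round-trips bit-identically.

provenance_lines <- function(params = list()) {
  c(sprintf("# fbrmech %s | %s",
            as.character(utils::packageVersion("fbrmech")),
            format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    if (length(params))
      sprintf("# %s", paste(names(params), unlist(params), sep = "=",
                            collapse = " ")))
}

#' Write / read a panel count matrix as CSV plus sample sheet
#'
#' `counts.csv` holds gene x sample integer counts (first column `gene`,
#' comment header lines starting with `#`); `samples.csv` holds
#' `sample_id,group`.
#'
#' @param cm An `fbr_counts`.
#' @param dir Output directory (created if needed).
#' @param params Named list recorded in the provenance header.
#' @return `dir`, invisibly.
#' @export
write_panel_csv <- function(cm, dir, params = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cpath <- file.path(dir, "counts.csv")
  writeLines(provenance_lines(params), cpath)
  df <- as.data.frame(cm$counts)
  df <- cbind(gene = cm$gene_ids, df)
  suppressWarnings(utils::write.table(df, cpath, sep = ",", row.names = FALSE,
                                      quote = FALSE, append = TRUE))
  readr::write_csv(tibble(sample_id = cm$sample_ids, group = cm$group),
                   file.path(dir, "samples.csv"))
  invisible(dir)
}

#' @rdname write_panel_csv
#' @export
read_panel_csv <- function(dir) {
  df <- readr::read_csv(file.path(dir, "counts.csv"), comment = "#",
                        show_col_types = FALSE)
  ss <- readr::read_csv(file.path(dir, "samples.csv"), show_col_types = FALSE)
  counts <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(counts) <- "integer"
  rownames(counts) <- df$gene
  counts <- counts[, ss$sample_id, drop = FALSE]
  count_matrix(counts, gene_ids = df$gene, sample_ids = ss$sample_id,
               group = ss$group)
}

#' Write / read a UMI matrix as a 10x-style Matrix Market trio
#'
#' Writes `matrix.mtx` (genes x cells, as in the 10x convention),
#' `features.tsv` (gene id, with a `mito` flag column), `barcodes.tsv` and
#' `metadata.csv`, plus a `provenance.yaml` with the recorded parameters.
#'
#' @param umi An `fbr_umi`.
#' @param dir Output directory.
#' @param params Named list recorded in `provenance.yaml`.
#' @return `dir`, invisibly.
#' @export
write_umi_mtx <- function(umi, dir, params = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(Matrix::t(umi$counts), file.path(dir, "matrix.mtx"))
  utils::write.table(
    data.frame(gene = umi$gene_ids,
               mito = as.integer(umi$gene_ids %in% umi$mito_gene_ids)),
    file.path(dir, "features.tsv"), sep = "\t", row.names = FALSE,
    col.names = FALSE, quote = FALSE)
  writeLines(umi$cell_ids, file.path(dir, "barcodes.tsv"))
  readr::write_csv(umi$cell_metadata, file.path(dir, "metadata.csv"))
  yaml::write_yaml(c(list(package = "fbrmech"), params),
                   file.path(dir, "provenance.yaml"))
  invisible(dir)
}

#' @rdname write_umi_mtx
#' @export
read_umi_mtx <- function(dir) {
  m <- Matrix::t(Matrix::readMM(file.path(dir, "matrix.mtx")))
  feats <- utils::read.table(file.path(dir, "features.tsv"), sep = "\t",
                             col.names = c("gene", "mito"))
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  meta_path <- file.path(dir, "metadata.csv")
  meta <- if (file.exists(meta_path)) {
    readr::read_csv(meta_path, show_col_types = FALSE)
  } else NULL
  umi_matrix(m, cell_ids = barcodes, gene_ids = feats$gene,
             cell_metadata = meta,
             mito_gene_ids = feats$gene[feats$mito == 1])
}

#' Write / read an ordered gene list with header metadata
#'
#' Plain text: `#`-prefixed header lines (direction, length, provenance),
#' then one gene id per line in rank order.
#'
#' @param sig An `fbr_signature`.
#' @param path Output file.
#' @param params Named list recorded in the header.
#' @return `path`, invisibly.
#' @export
write_gene_list <- function(sig, path, params = list()) {
  writeLines(c(provenance_lines(params),
               sprintf("# direction=%s k=%d", sig$direction, sig$k),
               sig$gene_ids), path)
  invisible(path)
}

#' @rdname write_gene_list
#' @export
read_gene_list <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  genes <- lines[!grepl("^#", lines) & nzchar(lines)]
  direction <- sub(".*direction=(\\S+).*", "\\1",
                   grep("direction=", meta, value = TRUE)[1])
  if (is.na(direction)) direction <- "up_in_group2"
  structure(list(gene_ids = genes, direction = direction,
                 k = length(genes)),
            class = "fbr_signature")
}

#' Write a stress summary (plus optional convergence report) to CSV
#'
#' @param summary An `fbr_stress_summary`.
#' @param path Output CSV path.
#' @param model Optional model label column.
#' @return `path`, invisibly.
#' @export
write_stress_summary_csv <- function(summary, path, model = NA_character_) {
  df <- tidy(summary)
  df <- cbind(tibble(model = model), df)
  readr::write_csv(df, path)
  invisible(path)
}

#' Export a mesh (and optional solution fields) as legacy-ASCII VTK
#'
#' Unstructured-grid VTK v2.0: tetrahedral connectivity, region labels as
#' cell data, node-set membership as point data; with a solution,
#' displacement vectors (point data) and the stress tensor components plus
#' Sx (cell data) are appended. Readable by ParaView/VisIt.
#'
#' @param mesh An `fbr_mesh`.
#' @param path Output `.vtk` path.
#' @param solution Optional `fbr_solution` on the same mesh.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(mesh, path, solution = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  nn <- nrow(mesh$nodes); ne <- nrow(mesh$elems)
  writeLines(c("# vtk DataFile Version 2.0",
               "fbrmech layered implant model",
               "ASCII", "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nn)), con)
  utils::write.table(format(mesh$nodes, scientific = TRUE, digits = 9),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELLS %d %d", ne, 5L * ne), con)
  utils::write.table(cbind(4L, mesh$elems - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELL_TYPES %d", ne), con)
  writeLines(as.character(rep(10L, ne)), con)
  region_id <- as.integer(factor(mesh$region)) - 1L
  writeLines(c(sprintf("CELL_DATA %d", ne),
               "SCALARS region int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(region_id), con)
  if (!is.null(solution)) {
    writeLines(c("SCALARS Sx double 1", "LOOKUP_TABLE default"), con)
    writeLines(format(solution$element_stress[, 1L], digits = 9), con)
    writeLines("TENSORS stress double", con)
    s <- solution$element_stress
    full <- cbind(s[, 1], s[, 4], s[, 6],
                  s[, 4], s[, 2], s[, 5],
                  s[, 6], s[, 5], s[, 3])
    utils::write.table(format(full, digits = 9), con, row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  }
  writeLines(c(sprintf("POINT_DATA %d", nn),
               "SCALARS bottom_fixed int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(
    as.integer(seq_len(nn) %in% mesh$node_sets$bottom_fixed)), con)
  writeLines(c("SCALARS interface int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(
    as.integer(seq_len(nn) %in% mesh$node_sets$interface)), con)
  if (!is.null(solution)) {
    writeLines("VECTORS displacement double", con)
    utils::write.table(format(solution$displacements, digits = 9), con,
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
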