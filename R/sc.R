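# Single-cell workflow: QC filtering, log-normalization (scale factor 10,000,
# natural-log pseudocount 1), mitochondrial-fraction regression, PCA over the
# standardized matrix, seeded k-means clustering, one-vs-rest ROC (AUC)
# marker detection, cross-species signature scoring and cluster-composition
# tables.

cell_mito_fraction <- function(umi) {
  lib <- Matrix::rowSums(umi$counts)
  if (length(umi$mito_gene_ids) == 0L) return(setNames(rep(0, length(lib)),
                                                       umi$cell_ids))
  mito <- Matrix::rowSums(umi$counts[, umi$mito_gene_ids, drop = FALSE])
  setNames(ifelse(lib > 0, mito / lib, 0), umi$cell_ids)
}

#' Quality-control filter on cells
#'
#' Keeps cells with at least `min_genes` detected genes (count > 0; the bound
#' is inclusive) and a mitochondrial count fraction strictly below
#' `max_mito`. Genes are left untouched. A per-cell filter report is attached
#' as attribute `"qc_report"`.
#'
#' @param umi An `fbr_umi`.
#' @param min_genes Minimum detected genes per cell (default 200, inclusive).
#' @param max_mito Mitochondrial-fraction cutoff (default 0.10, strict).
#' @return The filtered `fbr_umi`; errors if no cell survives.
#' @export
qc_filter <- function(umi, min_genes = 200, max_mito = 0.10) {
  if (!inherits(umi, "fbr_umi")) {
    abort("`umi` must be an fbr_umi.", class = "fbrmech_param_error")
  }
  detected <- Matrix::rowSums(umi$counts > 0)
  mfrac <- cell_mito_fraction(umi)
  keep <- detected >= min_genes & mfrac < max_mito
  report <- tibble(cell_id = umi$cell_ids,
                   n_genes_detected = as.integer(detected),
                   mito_fraction = as.numeric(mfrac),
                   kept = as.logical(keep))
  if (!any(keep)) {
    abort(sprintf(
      "No cell passes QC (>= %d genes detected, mito fraction < %g).",
      min_genes, max_mito), class = "fbrmech_sc_error")
  }
  out <- umi_matrix(umi$counts[keep, , drop = FALSE],
                    cell_ids = umi$cell_ids[keep],
                    gene_ids = umi$gene_ids,
                    cell_metadata = umi$cell_metadata[keep, , drop = FALSE],
                    mito_gene_ids = umi$mito_gene_ids)
  attr(out, "qc_report") <- report
  out
}

#' Log-normalize UMI counts
#'
#' Each count is scaled to 10,000 UMIs per cell and natural-log transformed
#' with a pseudocount of 1: `x -> ln(1 + 10^4 * x / library_size)`. Zeros stay
#' zero, so sparsity is preserved.
#'
#' @param umi An `fbr_umi` (post-QC; every cell must have a positive library).
#' @param scale_factor Scale factor (default 10,000).
#' @return An `fbr_norm`: sparse `data` (cells x genes), `library_size`,
#'   `mito_fraction`, ids and metadata.
#' @export
lognormalize <- function(umi, scale_factor = 1e4) {
  if (!inherits(umi, "fbr_umi")) {
    abort("`umi` must be an fbr_umi.", class = "fbrmech_param_error")
  }
  lib <- Matrix::rowSums(umi$counts)
  if (any(lib <= 0)) {
    abort("Every cell must have positive library size (run qc_filter first).",
          class = "fbrmech_sc_error")
  }
  norm <- umi$counts
  norm@x <- log1p(scale_factor * norm@x / lib[norm@i + 1L])
  structure(list(data = norm,
                 library_size = setNames(as.numeric(lib), umi$cell_ids),
                 mito_fraction = cell_mito_fraction(umi),
                 cell_ids = umi$cell_ids, gene_ids = umi$gene_ids,
                 cell_metadata = umi$cell_metadata),
            class = "fbr_norm")
}

#' @export
print.fbr_norm <- function(x, ...) {
  cat(sprintf("<fbr_norm> %d cells x %d genes, median library %.0f UMIs\n",
              nrow(x$data), ncol(x$data), median(x$library_size)))
  invisible(x)
}

#' Regress the mitochondrial fraction out of normalized expression
#'
#' Per gene, ordinary least squares of normalized expression on the per-cell
#' mitochondrial fraction; the residuals are then standardized per gene (zero
#' mean, unit variance; zero-variance genes are set to 0). When the
#' mitochondrial fraction is constant the regressor is degenerate and the
#' residuals reduce to centred expression.
#'
#' @param nm An `fbr_norm`.
#' @return Dense cells x genes matrix of standardized residuals, with the
#'   cell ids/metadata carried in attributes `"cell_ids"`/`"cell_metadata"`.
#' @export
regress_out_mito <- function(nm) {
  if (!inherits(nm, "fbr_norm")) {
    abort("`nm` must be an fbr_norm.", class = "fbrmech_param_error")
  }
  X <- as.matrix(nm$data)
  n <- nrow(X)
  if (n < 2L) {
    abort("Regression needs at least two cells.", class = "fbrmech_sc_error")
  }
  m <- nm$mito_fraction
  mc <- m - mean(m)
  vm <- sum(mc^2)
  Xc <- sweep(X, 2L, colMeans(X))
  if (vm > 0) {
    slope <- as.numeric(crossprod(mc, Xc)) / vm
    R <- Xc - outer(mc, slope)
  } else {
    R <- Xc
  }
  sdv <- sqrt(colSums(R^2) / (n - 1L))
  # zero-variance detection up to regression round-off
  keep <- sdv > 1e-10 * max(sdv, 0)
  R[, keep] <- sweep(R[, keep, drop = FALSE], 2L, sdv[keep], "/")
  R[, !keep] <- 0
  dimnames(R) <- dimnames(X)
  attr(R, "cell_ids") <- nm$cell_ids
  attr(R, "cell_metadata") <- nm$cell_metadata
  R
}

#' PCA embedding of a standardized expression matrix
#'
#' Singular value decomposition of the column-centred matrix; the scores of
#' the leading `n_components` components are returned. Component signs follow
#' a fixed convention -- the largest-magnitude gene loading of each component
#' is made positive -- so the embedding is reproducible up to machine
#' precision. If the matrix rank is lower than requested, the available
#' components are returned with a warning.
#'
#' @param matrix Cells x genes numeric matrix (typically
#'   [regress_out_mito()] output).
#' @param n_components Number of components (default 15).
#' @return Cells x components score matrix; singular values in attribute
#'   `"d"`, loadings in `"rotation"`.
#' @export
pca_embed <- function(matrix, n_components = 15) {
  n_components <- check_count(n_components, "n_components")
  if (n_components > min(dim(matrix))) {
    abort("`n_components` must not exceed min(cells, genes).",
          class = "fbrmech_param_error")
  }
  X <- sweep(as.matrix(matrix), 2L, colMeans(matrix))
  sv <- La.svd(X, nu = n_components, nv = n_components)
  d <- sv$d[seq_len(n_components)]
  tol <- max(dim(X)) * .Machine$double.eps * sv$d[1]
  rank <- sum(d > tol)
  if (rank < n_components) {
    warn(sprintf("Matrix rank %d < %d requested components; returning %d.",
                 rank, n_components, rank))
    d <- d[seq_len(rank)]
  }
  V <- t(sv$vt)[, seq_along(d), drop = FALSE]
  flip <- vapply(seq_along(d), function(j) {
    sign(V[which.max(abs(V[, j])), j])
  }, 0)
  flip[flip == 0] <- 1
  V <- sweep(V, 2L, flip, "*")
  scores <- X %*% V
  colnames(scores) <- paste0("PC", seq_along(d))
  rownames(scores) <- rownames(matrix)
  attr(scores, "d") <- d
  attr(scores, "rotation") <- V
  scores
}

#' Seeded k-means clustering of the PCA embedding
#'
#' Deterministic for fixed (embedding, k, seed): the RNG state is pinned
#' around `stats::kmeans` (Hartigan-Wong, 25 random starts).
#'
#' @param embedding Cells x components score matrix from [pca_embed()].
#' @param k Number of clusters (>= 1, at most the number of cells).
#' @param seed Integer seed.
#' @return Integer factor of cluster labels (`"c0" ... "c<k-1>"`), named by
#'   cell where the embedding has rownames.
#' @export
cluster_cells <- function(embedding, k, seed = 1) {
  k <- check_count(k, "k")
  if (k > nrow(embedding)) {
    abort("`k` must not exceed the number of cells.",
          class = "fbrmech_param_error")
  }
  labels <- with_seed(seed, {
    if (k == 1L) rep(1L, nrow(embedding))
    else kmeans(embedding, centers = k, nstart = 25, iter.max = 100)$cluster
  })
  out <- factor(paste0("c", labels - 1L),
                levels = paste0("c", seq_len(k) - 1L))
  names(out) <- rownames(embedding)
  out
}

# AUC of `x` as a classifier of `positive` membership, by the rank statistic
# (Mann-Whitney U with midranks for ties)
rank_auc <- function(x, positive) {
  n1 <- sum(positive)
  n2 <- sum(!positive)
  r <- rank(x)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' One-vs-rest ROC marker detection
#'
#' For every cluster with at least `min_cells` cells, computes the
#' natural-log fold change of mean de-logged expression,
#' `ln((mean(expm1(in)) + 1) / (mean(expm1(out)) + 1))`, keeps genes with
#' `|lfc| >= lfc_threshold`, and scores each kept gene by the AUC of its
#' normalized expression as a classifier of cluster membership (Mann-Whitney
#' rank statistic, midranks on ties). Results are ranked by descending AUC
#' within cluster.
#'
#' @param nm An `fbr_norm` (or dense cells x genes matrix of normalized
#'   expression).
#' @param clusters Cluster factor from [cluster_cells()].
#' @param lfc_threshold Log-fold-change gate (default 0.25).
#' @param min_cells Minimum cluster size (default 3); smaller clusters are
#'   skipped with a warning.
#' @return An `fbr_markers` tibble: `cluster`, `gene`, `auc`,
#'   `log_fold_change`, `pct_in`, `pct_out`.
#' @export
find_markers <- function(nm, clusters, lfc_threshold = 0.25, min_cells = 3) {
  X <- if (inherits(nm, "fbr_norm")) as.matrix(nm$data) else as.matrix(nm)
  clusters <- as.factor(clusters)
  if (length(clusters) != nrow(X)) {
    abort("`clusters` must label every cell.", class = "fbrmech_param_error")
  }
  if (nlevels(droplevels(clusters)) < 2L) {
    abort("Need >= 2 clusters for one-vs-rest comparisons.",
          class = "fbrmech_param_error")
  }
  expm1X <- expm1(X)
  res <- purrr::map(levels(droplevels(clusters)), function(cl) {
    inc <- clusters == cl
    if (sum(inc) < min_cells) {
      warn(sprintf("Cluster %s has < %d cells; skipped.", cl, min_cells))
      return(NULL)
    }
    mean_in <- colMeans(expm1X[inc, , drop = FALSE])
    mean_out <- colMeans(expm1X[!inc, , drop = FALSE])
    lfc <- log((mean_in + 1) / (mean_out + 1))
    keep <- which(abs(lfc) >= lfc_threshold)
    if (length(keep) == 0L) return(NULL)
    auc <- vapply(keep, function(j) rank_auc(X[, j], inc), 0)
    tibble(cluster = cl, gene = colnames(X)[keep], auc = unname(auc),
           log_fold_change = unname(lfc[keep]),
           pct_in = unname(colMeans(X[inc, keep, drop = FALSE] > 0)),
           pct_out = unname(colMeans(X[!inc, keep, drop = FALSE] > 0))) |>
      dplyr::arrange(dplyr::desc(.data$auc))
  })
  out <- dplyr::bind_rows(res)
  class(out) <- c("fbr_markers", class(out))
  out
}

#' Per-cell mean-expression score of a gene signature
#'
#' Maps the signature's gene ids into the target dataset (explicit two-column
#' ortholog table, or case-insensitive symbol match by default -- the
#' human-to-mouse convention SYMBOL -> Symbol), drops unmapped genes with a
#' report, and returns each cell's arithmetic mean of normalized expression
#' over the mapped genes.
#'
#' @param nm An `fbr_norm`.
#' @param sig An `fbr_signature` or character vector of gene ids.
#' @param ortholog_map Optional data frame with columns `from`, `to` mapping
#'   signature ids to target gene ids.
#' @return Tibble `cell_id`, `score`, with the mapping report in attribute
#'   `"mapping"`; errors (listing the ids) if nothing maps.
#' @export
signature_score <- function(nm, sig, ortholog_map = NULL) {
  if (!inherits(nm, "fbr_norm")) {
    abort("`nm` must be an fbr_norm.", class = "fbrmech_param_error")
  }
  ids <- if (inherits(sig, "fbr_signature")) sig$gene_ids else as.character(sig)
  if (length(ids) == 0L) {
    abort("Signature is empty.", class = "fbrmech_param_error")
  }
  if (!is.null(ortholog_map)) {
    if (!all(c("from", "to") %in% names(ortholog_map))) {
      abort("`ortholog_map` needs columns `from` and `to`.",
            class = "fbrmech_param_error")
    }
    mapped_to <- ortholog_map$to[match(ids, ortholog_map$from)]
  } else {
    mapped_to <- nm$gene_ids[match(tolower(ids), tolower(nm$gene_ids))]
  }
  present <- !is.na(mapped_to) & mapped_to %in% nm$gene_ids
  if (!any(present)) {
    abort(paste0("No signature gene maps into the dataset. Unmapped: ",
                 paste(ids, collapse = ", ")),
          class = "fbrmech_sc_error")
  }
  genes <- unique(mapped_to[present])
  score <- Matrix::rowMeans(nm$data[, genes, drop = FALSE])
  out <- tibble(cell_id = nm$cell_ids, score = as.numeric(score))
  attr(out, "mapping") <- tibble(from = ids, to = mapped_to,
                                 mapped = present)
  out
}

#' Cluster-composition table by condition (and optional time point)
#'
#' Cross-tabulates cluster labels against cell metadata and normalizes each
#' row to fractions summing to 1.
#'
#' @param clusters Cluster labels (one per cell).
#' @param cell_metadata Data frame with one row per cell; must contain the
#'   `by` columns.
#' @param by Metadata column(s) defining the rows (default `"condition"`).
#' @return An `fbr_composition` tibble: one row per condition/time, one
#'   column per cluster, entries are fractions.
#' @export
composition_table <- function(clusters, cell_metadata, by = "condition") {
  if (!all(by %in% names(cell_metadata))) {
    abort(sprintf("Metadata lacks column(s): %s",
                  paste(setdiff(by, names(cell_metadata)), collapse = ", ")),
          class = "fbrmech_param_error")
  }
  if (nrow(cell_metadata) != length(clusters)) {
    abort("`clusters` and `cell_metadata` must align per cell.",
          class = "fbrmech_param_error")
  }
  df <- as_tibble(cell_metadata[, by, drop = FALSE])
  df$cluster <- as.character(clusters)
  out <- df |>
    dplyr::count(dplyr::across(dplyr::all_of(c(by, "cluster")))) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::mutate(fraction = .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::select(-"n") |>
    tidyr::pivot_wider(names_from = "cluster", values_from = "fraction",
                       values_fill = 0)
  class(out) <- c("fbr_composition", class(out))
  out
}
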