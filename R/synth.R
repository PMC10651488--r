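# Seeded generators for every input class the pipeline consumes: two-group
# negative-binomial panel counts and sparse UMI matrices with planted
# population structure. All generators are pure functions of (parameters,
# seed): the RNG state is saved and restored around each call.

with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) ||
      seed != round(seed)) {
    abort("`seed` must be a single integer.", class = "fbrmech_param_error")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

check_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) ||
      x < min) {
    abort(sprintf("`%s` must be an integer >= %g.", name, min),
          class = "fbrmech_param_error")
  }
  as.integer(x)
}

#' Construct a panel count matrix container
#'
#' @param counts genes x samples matrix of nonnegative integer counts.
#' @param gene_ids,sample_ids Row/column identifiers.
#' @param group Per-sample label with exactly two levels, both nonempty.
#' @return An `fbr_counts` object.
#' @export
count_matrix <- function(counts, gene_ids = rownames(counts),
                         sample_ids = colnames(counts), group) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("Counts must be nonnegative integers.",
          class = "fbrmech_param_error")
  }
  if (is.null(gene_ids)) gene_ids <- sprintf("g%05d", seq_len(nrow(counts)))
  if (is.null(sample_ids)) sample_ids <- sprintf("s%03d", seq_len(ncol(counts)))
  group <- as.character(group)
  if (length(group) != ncol(counts) || length(unique(group)) != 2L) {
    abort("`group` must label every sample with exactly two levels.",
          class = "fbrmech_param_error")
  }
  dimnames(counts) <- list(gene_ids, sample_ids)
  structure(list(counts = counts, gene_ids = gene_ids,
                 sample_ids = sample_ids, group = group),
            class = "fbr_counts")
}

#' @export
print.fbr_counts <- function(x, ...) {
  cat(sprintf("<fbr_counts> %d genes x %d samples (groups: %s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s n=%d", names(table(x$group)), table(x$group)),
                    collapse = ", ")))
  invisible(x)
}

#' Simulate a two-group biomarker-panel count matrix
#'
#' Draws negative-binomial counts (variance = mu + phi mu^2) for a two-group
#' design emulating a targeted expression panel: per-gene baseline means are
#' log-normal across four orders of magnitude, per-sample library-size
#' factors are log-normal(0, 0.2), and a planted fraction of genes carries a
#' log2 fold change between the groups. With `dispersion = 0` the counts are
#' Poisson.
#'
#' @param n_genes,n_per_group Positive integer dimensions.
#' @param frac_de Fraction of genes carrying the planted change, in `[0, 1]`.
#' @param lfc Planted log2 fold change (group2 over group1).
#' @param dispersion Common NB dispersion phi >= 0.
#' @param seed Integer seed; identical (seed, params) give identical output.
#' @param lib_sdlog Log-sd of the library-size factors (default 0.2).
#' @return List with `counts` (an `fbr_counts`) and `truth` (a `PanelTruth`
#'   list: `de_gene_ids`, `log2_fold_changes`, `dispersion`, `group_sizes`).
#' @examples
#' sim <- simulate_panel_counts(200, 10, frac_de = 0.1, lfc = 2,
#'                              dispersion = 0.2, seed = 1)
#' length(sim$truth$de_gene_ids)  # 20
#' @export
simulate_panel_counts <- function(n_genes, n_per_group, frac_de = 0.05,
                                  lfc = 1, dispersion = 0.1, seed = 1,
                                  lib_sdlog = 0.2) {
  n_genes <- check_count(n_genes, "n_genes")
  n_per_group <- check_count(n_per_group, "n_per_group", min = 2)
  if (!is.numeric(frac_de) || frac_de < 0 || frac_de > 1) {
    abort("`frac_de` must lie in [0, 1].", class = "fbrmech_param_error")
  }
  if (!is.numeric(dispersion) || dispersion < 0) {
    abort("`dispersion` must be >= 0.", class = "fbrmech_param_error")
  }
  with_seed(seed, {
    gene_ids <- sprintf("g%05d", seq_len(n_genes))
    n <- 2L * n_per_group
    sample_ids <- sprintf("s%03d", seq_len(n))
    group <- rep(c("group1", "group2"), each = n_per_group)
    base_mu <- rlnorm(n_genes, meanlog = log(100), sdlog = 1.3)
    lib <- rlnorm(n, meanlog = 0, sdlog = lib_sdlog)
    n_de <- round(frac_de * n_genes)
    de_idx <- if (n_de > 0) sort(sample.int(n_genes, n_de)) else integer(0)
    mu <- matrix(base_mu, n_genes, n) * rep(lib, each = n_genes)
    if (n_de > 0) {
      g2 <- group == "group2"
      mu[de_idx, g2] <- mu[de_idx, g2] * 2^lfc
    }
    counts <- if (dispersion == 0) {
      matrix(rpois(length(mu), lambda = mu), n_genes, n)
    } else {
      matrix(rnbinom(length(mu), mu = mu, size = 1 / dispersion), n_genes, n)
    }
    storage.mode(counts) <- "integer"
    truth <- list(de_gene_ids = gene_ids[de_idx],
                  log2_fold_changes = rep(lfc, n_de),
                  dispersion = rep(dispersion, n_genes),
                  group_sizes = c(n_per_group, n_per_group),
                  lib_factors = lib)
    list(counts = count_matrix(counts, gene_ids, sample_ids, group),
         truth = truth)
  })
}

#' Construct a single-cell UMI matrix container
#'
#' @param counts Sparse (or dense) cells x genes nonnegative integer matrix.
#' @param cell_ids,gene_ids Identifiers (defaults from dimnames).
#' @param cell_metadata Data frame with one row per cell (must include
#'   `cell_id`; typically `condition` and `timepoint`).
#' @param mito_gene_ids Character vector of mitochondrial gene ids (may be
#'   empty).
#' @return An `fbr_umi` object.
#' @export
umi_matrix <- function(counts, cell_ids = rownames(counts),
                       gene_ids = colnames(counts),
                       cell_metadata = NULL, mito_gene_ids = character()) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  if (any(counts@x < 0) || any(counts@x != round(counts@x))) {
    abort("UMI counts must be nonnegative integers.",
          class = "fbrmech_param_error")
  }
  if (is.null(cell_ids)) cell_ids <- sprintf("cell%05d", seq_len(nrow(counts)))
  if (is.null(gene_ids)) gene_ids <- sprintf("gene%05d", seq_len(ncol(counts)))
  dimnames(counts) <- list(cell_ids, gene_ids)
  if (is.null(cell_metadata)) {
    cell_metadata <- tibble(cell_id = cell_ids)
  }
  cell_metadata <- as_tibble(cell_metadata)
  if (!"cell_id" %in% names(cell_metadata) ||
      !setequal(cell_metadata$cell_id, cell_ids) ||
      nrow(cell_metadata) != length(cell_ids)) {
    abort("`cell_metadata` must cover every cell exactly once (column cell_id).",
          class = "fbrmech_param_error")
  }
  cell_metadata <- cell_metadata[match(cell_ids, cell_metadata$cell_id), ]
  if (!all(mito_gene_ids %in% gene_ids)) {
    abort("All `mito_gene_ids` must appear in `gene_ids`.",
          class = "fbrmech_param_error")
  }
  structure(list(counts = counts, cell_ids = cell_ids, gene_ids = gene_ids,
                 cell_metadata = cell_metadata,
                 mito_gene_ids = mito_gene_ids),
            class = "fbr_umi")
}

#' @export
print.fbr_umi <- function(x, ...) {
  cat(sprintf("<fbr_umi> %d cells x %d genes, %.2f%% nonzero, %d mito genes\n",
              nrow(x$counts), ncol(x$counts),
              100 * length(x$counts@x) / prod(dim(x$counts)),
              length(x$mito_gene_ids)))
  invisible(x)
}

#' Simulate a sparse UMI matrix with planted population structure
#'
#' Emulates the statistical structure the single-cell pipeline assumes:
#' several cell populations with distinct expression profiles, per-cell
#' library-size variation, a mitochondrial gene block whose per-cell count
#' fraction is drawn from `mito_frac_range`, and one designated
#' signature-high population (the last one) whose signature genes are
#' multiplicatively uplifted by `exp(planted_uplift)` on the mean scale.
#' Cells carry an `"SM"`/`"MSI"` condition label; the signature-high
#' population is sampled preferentially from the `"MSI"` condition so that
#' downstream composition tables can recover the enrichment.
#'
#' @param n_cells_per_pop Integer vector of cells per population (>= 2 pops
#'   for any planted contrast to be meaningful, but one population is valid).
#' @param n_genes Total genes including the mitochondrial block.
#' @param signature_size Number of signature genes (disjoint from mito genes).
#' @param planted_uplift Log-scale uplift >= 0 of signature genes in the
#'   designated population (0 = null).
#' @param mito_frac_range Length-2 interval in `[0, 1]` for per-cell
#'   mitochondrial fractions (default `c(0.01, 0.08)`, i.e. passing QC).
#' @param seed Integer seed.
#' @param n_mito_genes Size of the mitochondrial block (default 10).
#' @param mean_umi Target mean library size (default 2500).
#' @param msi_prob_signature,msi_prob_other P(condition = "MSI") for cells of
#'   the signature-high vs other populations (defaults 0.75 / 0.35).
#' @return List with `umi` (an `fbr_umi`) and `truth` (an `ScTruth` list:
#'   `population_labels`, `signature_gene_ids`, `planted_uplift`,
#'   `condition_labels`, `mito_gene_ids`).
#' @export
simulate_umi_matrix <- function(n_cells_per_pop, n_genes, signature_size,
                                planted_uplift, mito_frac_range = c(0.01, 0.08),
                                seed = 1, n_mito_genes = 10, mean_umi = 2500,
                                msi_prob_signature = 0.75,
                                msi_prob_other = 0.35) {
  n_cells_per_pop <- vapply(n_cells_per_pop, check_count, 1L,
                            name = "n_cells_per_pop")
  n_genes <- check_count(n_genes, "n_genes")
  n_mito_genes <- check_count(n_mito_genes, "n_mito_genes", min = 0)
  signature_size <- check_count(signature_size, "signature_size")
  if (signature_size + n_mito_genes > n_genes) {
    abort("signature_size + n_mito_genes must not exceed n_genes.",
          class = "fbrmech_param_error")
  }
  if (!is.numeric(planted_uplift) || planted_uplift < 0) {
    abort("`planted_uplift` must be >= 0 (downshift not modelled).",
          class = "fbrmech_param_error")
  }
  if (length(mito_frac_range) != 2L || any(mito_frac_range < 0) ||
      any(mito_frac_range > 1) || mito_frac_range[1] > mito_frac_range[2]) {
    abort("`mito_frac_range` must be an interval within [0, 1].",
          class = "fbrmech_param_error")
  }
  with_seed(seed, {
    n_pop <- length(n_cells_per_pop)
    n_cells <- sum(n_cells_per_pop)
    cell_ids <- sprintf("cell%05d", seq_len(n_cells))
    gene_ids <- c(sprintf("gene%05d", seq_len(n_genes - n_mito_genes)),
                  if (n_mito_genes > 0) sprintf("mt-gene%02d",
                                                seq_len(n_mito_genes)))
    mito_ids <- gene_ids[grepl("^mt-", gene_ids)]
    n_nuc <- n_genes - n_mito_genes
    sig_idx <- seq_len(signature_size)  # first nuclear genes
    pop <- rep(sprintf("pop%d", seq_len(n_pop)), times = n_cells_per_pop)
    sig_pop <- sprintf("pop%d", n_pop)
    # per-population nuclear profiles: shared log-normal base with
    # population-specific jitter so populations separate in PCA space
    base <- rlnorm(n_nuc, meanlog = log(1), sdlog = 1.2)
    prof <- sapply(seq_len(n_pop), function(p) {
      base * rlnorm(n_nuc, 0, 0.4)
    })
    prof <- matrix(prof, nrow = n_nuc)
    # signature rows are identical across populations (the uplift is the only
    # planted signature contrast), and the non-signature mass is equalized so
    # the signature fraction is exactly equal at uplift 0
    prof[sig_idx, ] <- base[sig_idx]
    nonsig <- setdiff(seq_len(n_nuc), sig_idx)
    if (length(nonsig)) {
      ns_sum <- colSums(prof[nonsig, , drop = FALSE])
      prof[nonsig, ] <- sweep(prof[nonsig, , drop = FALSE], 2,
                              ns_sum / mean(ns_sum), "/")
    }
    prof[sig_idx, n_pop] <- prof[sig_idx, n_pop] * exp(planted_uplift)
    prof <- sweep(prof, 2, colSums(prof), "/")
    mito_prof <- if (n_mito_genes > 0) {
      w <- rlnorm(n_mito_genes, 0, 0.5); w / sum(w)
    } else numeric(0)
    lib <- rlnorm(n_cells, meanlog = log(mean_umi), sdlog = 0.3)
    mfrac <- runif(n_cells, mito_frac_range[1], mito_frac_range[2])
    pop_i <- match(pop, sprintf("pop%d", seq_len(n_pop)))
    mu_nuc <- t(prof[, pop_i, drop = FALSE]) * (lib * (1 - mfrac))
    counts <- matrix(rnbinom(n_cells * n_nuc, mu = mu_nuc, size = 10),
                     n_cells, n_nuc)
    if (n_mito_genes > 0) {
      mu_mt <- outer(lib * mfrac, mito_prof)
      counts <- cbind(counts,
                      matrix(rnbinom(n_cells * n_mito_genes, mu = mu_mt,
                                     size = 10), n_cells, n_mito_genes))
    }
    p_msi <- ifelse(pop == sig_pop, msi_prob_signature, msi_prob_other)
    condition <- ifelse(runif(n_cells) < p_msi, "MSI", "SM")
    meta <- tibble(cell_id = cell_ids, condition = condition,
                   population = pop)
    truth <- list(population_labels = pop,
                  signature_gene_ids = gene_ids[sig_idx],
                  planted_uplift = planted_uplift,
                  condition_labels = condition,
                  mito_gene_ids = mito_ids,
                  signature_population = sig_pop)
    list(umi = umi_matrix(counts, cell_ids, gene_ids, meta, mito_ids),
         truth = truth)
  })
}
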