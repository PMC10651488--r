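# Pipeline entry points tying the stages together. Each run_* function takes
# a config (named list, or path to a YAML file with the same keys), rejects
# unknown keys, writes its outputs plus the fully resolved config next to
# them, and returns its main result invisibly. Log messages go to stderr.

read_run_config <- function(config, defaults) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) {
    abort("`config` must be a named list or a YAML file path.",
          class = "fbrmech_config_error")
  }
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    abort(sprintf("Unknown config key(s): %s",
                  paste(unknown, collapse = ", ")),
          class = "fbrmech_config_error")
  }
  modifyList(defaults, config)
}

write_resolved_config <- function(cfg, out_dir, name) {
  keep <- !vapply(cfg, is.null, TRUE)
  yaml::write_yaml(c(list(schema_version = 1L), cfg[keep]),
                   file.path(out_dir, name))
}

log_msg <- function(...) message("[fbrmech] ", sprintf(...))

#' Run the implant stress model
#'
#' Mesh -> solve -> interface stress summary (and optionally a convergence
#' sweep) for a preset or explicit domain config. Writes `stress_summary.csv`,
#' `model.vtk`, optionally `convergence.csv`, and `stress_config.yaml`.
#'
#' Config keys: `preset` (or `domain` = raw domain config list), `overrides`,
#' `edge_length` (mm), `edge_lengths` (sweep; triggers a convergence report),
#' `convergence_tol`, `out_dir`.
#'
#' @param config Named list or YAML path.
#' @return The `fbr_stress_summary`, invisibly.
#' @export
run_stress <- function(config = list()) {
  cfg <- read_run_config(config, list(
    preset = NULL, domain = NULL, overrides = NULL, edge_length = NULL,
    edge_lengths = NULL, convergence_tol = 0.1, out_dir = "."))
  spec <- if (!is.null(cfg$domain)) domain_from_config(cfg$domain)
          else if (!is.null(cfg$preset)) preset_domains(cfg$preset, cfg$overrides)
          else abort("Config needs `preset` or `domain`.",
                     class = "fbrmech_config_error")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  edge <- cfg$edge_length %||% attr(spec, "edge_length")
  log_msg("solving %s model at edge length %.3g mm",
          cfg$preset %||% "custom", edge)
  sm <- solve_domain(spec, edge_length = edge)
  write_stress_summary_csv(sm$summary,
                           file.path(cfg$out_dir, "stress_summary.csv"),
                           model = cfg$preset %||% "custom")
  write_vtk(sm$mesh, file.path(cfg$out_dir, "model.vtk"), sm$solution)
  if (!is.null(cfg$edge_lengths)) {
    conv <- mesh_convergence_check(spec, unlist(cfg$edge_lengths),
                                   tol = cfg$convergence_tol)
    readr::write_csv(conv, file.path(cfg$out_dir, "convergence.csv"))
  }
  write_resolved_config(cfg, cfg$out_dir, "stress_config.yaml")
  log_msg("max |Sx| = %.4g kPa", sm$summary$max_abs_sx)
  invisible(sm$summary)
}

#' Run the two-group panel differential-expression stage
#'
#' Reads a panel directory (counts.csv + samples.csv), runs size-factor
#' normalization, dispersion estimation, the NB likelihood-ratio test and BH
#' correction, and writes `de_table.csv` plus top-k signatures in both
#' directions (defaults 100 and 25).
#'
#' Config keys: `counts_dir` (or `counts` = an fbr_counts), `top_k`
#' (vector), `p_threshold`, `out_dir`.
#'
#' @param config Named list or YAML path.
#' @return The `fbr_de` table, invisibly.
#' @export
run_de <- function(config = list()) {
  cfg <- read_run_config(config, list(
    counts_dir = NULL, counts = NULL, top_k = c(100L, 25L),
    p_threshold = 0.05, out_dir = "."))
  cm <- cfg$counts %||% (if (!is.null(cfg$counts_dir))
    read_panel_csv(cfg$counts_dir)
    else abort("Config needs `counts_dir` or `counts`.",
               class = "fbrmech_config_error"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_msg("testing %d genes, %d + %d samples", nrow(cm$counts),
          sum(cm$group == unique(cm$group)[1]),
          sum(cm$group == unique(cm$group)[2]))
  factors <- normalize_library_sizes(cm)
  disp <- estimate_dispersion(cm, factors)
  de <- nb_two_group_test(cm, factors, disp)
  readr::write_csv(tidy(de), file.path(cfg$out_dir, "de_table.csv"))
  for (k in cfg$top_k) {
    for (dirn in c("up_in_group2", "up_in_group1")) {
      sig <- suppressWarnings(
        rank_and_signature(de, k, dirn, cfg$p_threshold))
      write_gene_list(sig, file.path(
        cfg$out_dir, sprintf("signature_top%d_%s.txt", k, dirn)),
        params = list(k = k, direction = dirn))
    }
  }
  cfg$counts <- NULL
  write_resolved_config(cfg, cfg$out_dir, "de_config.yaml")
  invisible(de)
}

#' Run the single-cell stage
#'
#' QC -> log-normalization -> mitochondrial regression -> PCA -> k-means ->
#' ROC markers -> optional signature scoring -> composition tables. Writes
#' `qc_report.csv`, `clusters.csv`, `markers.csv`, `scores.csv` (if a
#' signature is given), `composition.csv` and a machine-readable
#' `sc_run.yaml` with the seed.
#'
#' Config keys: `umi_dir` (MTX trio; or `umi` = an fbr_umi), `signature_file`
#' (or `signature`), `ortholog_map_file` (two-column from,to CSV), `k`
#' (clusters), `n_components`, `seed`, `min_genes`, `max_mito`,
#' `lfc_threshold`, `composition_by`, `out_dir`.
#'
#' @param config Named list or YAML path.
#' @return List of stage results, invisibly.
#' @export
run_sc <- function(config = list()) {
  cfg <- read_run_config(config, list(
    umi_dir = NULL, umi = NULL, signature_file = NULL, signature = NULL,
    ortholog_map_file = NULL, k = 4L, n_components = 15L, seed = 1L,
    min_genes = 200, max_mito = 0.10, lfc_threshold = 0.25,
    composition_by = "condition", out_dir = "."))
  umi <- cfg$umi %||% (if (!is.null(cfg$umi_dir)) read_umi_mtx(cfg$umi_dir)
    else abort("Config needs `umi_dir` or `umi`.",
               class = "fbrmech_config_error"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  filtered <- qc_filter(umi, min_genes = cfg$min_genes,
                        max_mito = cfg$max_mito)
  readr::write_csv(attr(filtered, "qc_report"),
                   file.path(cfg$out_dir, "qc_report.csv"))
  log_msg("QC kept %d / %d cells", nrow(filtered$counts), nrow(umi$counts))
  nm <- lognormalize(filtered)
  resid <- regress_out_mito(nm)
  ncomp <- min(cfg$n_components, dim(resid) - 1L)
  emb <- suppressWarnings(pca_embed(resid, n_components = ncomp))
  clusters <- cluster_cells(emb, k = cfg$k, seed = cfg$seed)
  readr::write_csv(tibble(cell_id = nm$cell_ids,
                          cluster = as.character(clusters)),
                   file.path(cfg$out_dir, "clusters.csv"))
  markers <- suppressWarnings(
    find_markers(nm, clusters, lfc_threshold = cfg$lfc_threshold))
  readr::write_csv(markers, file.path(cfg$out_dir, "markers.csv"))
  scores <- NULL
  sig <- cfg$signature %||% (if (!is.null(cfg$signature_file))
    read_gene_list(cfg$signature_file) else NULL)
  if (!is.null(sig)) {
    omap <- if (!is.null(cfg$ortholog_map_file)) {
      readr::read_csv(cfg$ortholog_map_file, show_col_types = FALSE)
    } else NULL
    scores <- signature_score(nm, sig, omap)
    readr::write_csv(scores, file.path(cfg$out_dir, "scores.csv"))
  }
  comp <- composition_table(clusters, nm$cell_metadata,
                            by = cfg$composition_by)
  readr::write_csv(comp, file.path(cfg$out_dir, "composition.csv"))
  cfg$umi <- NULL; cfg$signature <- NULL
  write_resolved_config(cfg, cfg$out_dir, "sc_run.yaml")
  invisible(list(umi = filtered, normalized = nm, embedding = emb,
                 clusters = clusters, markers = markers, scores = scores,
                 composition = comp))
}

#' Generate fixture datasets
#'
#' Invokes the seeded generators and writes their outputs in the formats the
#' other stages read: a panel-count directory and a UMI MTX trio.
#'
#' Config keys: `seed`, `out_dir`, `panel` (list of
#' [simulate_panel_counts()] args), `umi` (list of [simulate_umi_matrix()]
#' args). Either block may be omitted.
#'
#' @param config Named list or YAML path.
#' @return List with the generated objects, invisibly.
#' @export
run_synth <- function(config = list()) {
  cfg <- read_run_config(config, list(
    seed = 1L, out_dir = ".", panel = NULL, umi = NULL))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- list()
  if (!is.null(cfg$panel)) {
    args <- modifyList(list(n_genes = 2549L, n_per_group = 10L,
                            frac_de = 0.05, lfc = 1, dispersion = 0.1,
                            seed = cfg$seed), cfg$panel)
    sim <- do.call(simulate_panel_counts, args)
    write_panel_csv(sim$counts, file.path(cfg$out_dir, "panel"),
                    params = args[c("n_genes", "n_per_group", "frac_de",
                                    "lfc", "dispersion", "seed")])
    out$panel <- sim
  }
  if (!is.null(cfg$umi)) {
    args <- modifyList(list(n_cells_per_pop = c(150L, 150L, 100L),
                            n_genes = 500L, signature_size = 25L,
                            planted_uplift = 1, seed = cfg$seed), cfg$umi)
    sim <- do.call(simulate_umi_matrix, args)
    write_umi_mtx(sim$umi, file.path(cfg$out_dir, "umi"),
                  params = args[c("n_genes", "signature_size",
                                  "planted_uplift", "seed")])
    out$umi <- sim
  }
  write_resolved_config(cfg, cfg$out_dir, "synth_config.yaml")
  invisible(out)
}
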