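
test_that("QC boundaries are >= 200 genes inclusive and < 10% mito strict", {
  toy <- qc_toy()
  detected <- Matrix::rowSums(toy$counts > 0)
  mito <- as.numeric(toy$counts[, "mt-1"] / Matrix::rowSums(toy$counts))
  expect_equal(unname(detected), c(200, 150, 244))
  expect_equal(mito[3], 0.10)
  kept <- qc_filter(toy)
  expect_equal(kept$cell_ids, "A")
  report <- attr(kept, "qc_report")
  expect_equal(report$kept, c(TRUE, FALSE, FALSE))
  # genes unchanged
  expect_equal(kept$gene_ids, toy$gene_ids)
})

test_that("log-normalization matches hand-computed values and keeps zeros", {
  counts <- matrix(0L, 2, 3, dimnames = list(c("a", "b"),
                                             c("g1", "g2", "g3")))
  counts["a", ] <- c(5L, 9995L, 0L)        # library exactly 10^4
  counts["b", ] <- c(10L, 19990L, 0L)      # same composition, 2x depth
  nm <- lognormalize(umi_matrix(counts))
  expect_equal(nm$data["a", "g1"], log(6))
  expect_equal(nm$data["a", "g3"], 0)
  # scaling all counts of a cell leaves its normalized vector unchanged
  expect_equal(as.numeric(nm$data["a", ]), as.numeric(nm$data["b", ]))
  # zero-library cell rejected
  counts0 <- rbind(counts, c(0L, 0L, 0L))
  rownames(counts0)[3] <- "c"
  expect_error(lognormalize(umi_matrix(counts0)), class = "fbrmech_sc_error")
})

test_that("mitochondrial regression residuals match hand OLS", {
  # 4 cells, known mito fractions; one gene exactly linear in mito
  counts <- matrix(1L, 4, 3)
  umi <- umi_matrix(counts)
  nm <- lognormalize(umi)
  m <- c(0.02, 0.04, 0.06, 0.08)
  nm$mito_fraction <- setNames(m, nm$cell_ids)
  y <- c(1.0, 2.1, 2.9, 4.2)
  dense <- cbind(g1 = y, g2 = 3 + 5 * m, g3 = rep(2, 4))
  nm$data <- Matrix::Matrix(dense, sparse = TRUE,
                            dimnames = list(nm$cell_ids,
                                            c("g1", "g2", "g3")))
  nm$gene_ids <- c("g1", "g2", "g3")
  R <- regress_out_mito(nm)
  # closed-form OLS for g1
  fit <- lm(y ~ m)
  r_expected <- unname(resid(fit))
  r_expected <- r_expected / sd(r_expected)
  expect_equal(unname(R[, "g1"]), r_expected, tolerance = 1e-10)
  # gene exactly linear in mito -> residuals 0
  expect_equal(unname(R[, "g2"]), rep(0, 4))
  # constant gene -> zero variance -> 0
  expect_equal(unname(R[, "g3"]), rep(0, 4))
  # constant mito fraction: residuals are centred expression
  nm$mito_fraction[] <- 0.05
  R2 <- regress_out_mito(nm)
  centred <- y - mean(y)
  expect_equal(unname(R2[, "g1"]), centred / sd(centred), tolerance = 1e-10)
})

test_that("PCA embedding is orthogonal with a fixed sign convention", {
  set.seed(8)
  X <- matrix(rnorm(60 * 20), 60, 20)
  S <- pca_embed(X, 5)
  G <- crossprod(S)
  expect_equal(G - diag(diag(G)), matrix(0, 5, 5), tolerance = 1e-8,
               ignore_attr = TRUE)
  # rank-1 matrix: PC1 explains > 99% of the variance
  u <- rnorm(60); v <- rnorm(20)
  X1 <- outer(u, v) + matrix(rnorm(60 * 20, sd = 1e-3), 60, 20)
  S1 <- pca_embed(X1, 3)
  d <- attr(S1, "d")
  expect_gt(d[1]^2 / sum(d^2), 0.99)
  # permutation of cells permutes scores (sign convention is load-based)
  perm <- sample(60)
  S_perm <- pca_embed(X[perm, ], 5)
  expect_equal(S_perm, S[perm, ], tolerance = 1e-8, ignore_attr = TRUE)
  # requesting more components than rank warns and truncates
  expect_warning(pca_embed(outer(u, v), 3), regexp = "rank")
  expect_error(pca_embed(X, 100), class = "fbrmech_param_error")
})

test_that("seeded k-means recovers well-separated blobs deterministically", {
  set.seed(9)
  emb <- rbind(matrix(rnorm(50 * 2, mean = 0), ncol = 2),
               matrix(rnorm(50 * 2, mean = 8), ncol = 2))
  truth <- rep(c(1, 2), each = 50)
  cl <- cluster_cells(emb, k = 2, seed = 4)
  expect_equal(adjusted_rand(cl, truth), 1)
  expect_identical(cl, cluster_cells(emb, k = 2, seed = 4))
  expect_equal(nlevels(cluster_cells(emb, k = 1, seed = 1)), 1)
  expect_error(cluster_cells(emb, k = 200, seed = 1),
               class = "fbrmech_param_error")
})

test_that("marker AUCs equal enumeration on toys and rank separating genes first", {
  # 4-cell toy: values (3,2) in-cluster vs (1,0) out -> AUC 1;
  # values (2,1) vs (1,2) -> AUC 0.5 by midrank tie counting
  x_sep <- c(3, 2, 1, 0)
  x_tie <- c(2, 1, 1, 2)
  inc <- c(TRUE, TRUE, FALSE, FALSE)
  expect_equal(fbrmech:::rank_auc(x_sep, inc), 1)
  expect_equal(fbrmech:::rank_auc(x_tie, inc), 0.5)
  expect_equal(fbrmech:::rank_auc(x_sep, inc), auc_pair_counting(x_sep, inc))
  expect_equal(fbrmech:::rank_auc(x_tie, inc), auc_pair_counting(x_tie, inc))
  set.seed(10)
  for (i in 1:20) {
    x <- sample(0:4, 15, replace = TRUE)
    pos <- sample(c(TRUE, FALSE), 15, replace = TRUE)
    if (!any(pos) || all(pos)) next
    expect_equal(fbrmech:::rank_auc(x, pos), auc_pair_counting(x, pos))
  }
})

test_that("find_markers flags cluster-exclusive genes with AUC 1", {
  set.seed(12)
  n <- 40
  counts <- matrix(rpois(n * 30, 5), n, 30)
  counts[1:20, 1] <- rpois(20, 50)   # gene 1 high in cluster A
  counts[21:40, 1] <- 0L
  umi <- umi_matrix(counts)
  nm <- lognormalize(umi)
  clusters <- factor(rep(c("cA", "cB"), each = 20))
  mk <- find_markers(nm, clusters)
  g1 <- mk[mk$cluster == "cA" & mk$gene == nm$gene_ids[1], ]
  expect_equal(g1$auc, 1)
  expect_gt(g1$log_fold_change, 0.25)
  # results ranked by AUC within cluster
  for (cl in unique(mk$cluster)) {
    expect_true(all(diff(mk$auc[mk$cluster == cl]) <= 1e-12))
  }
  # tiny cluster skipped with warning
  cl3 <- factor(c(rep("cA", 38), "cB", "cB"))
  expect_warning(find_markers(nm, cl3), regexp = "cB")
  expect_error(find_markers(nm, factor(rep("cA", n))),
               class = "fbrmech_param_error")
})

test_that("signature scores are gene-order invariant means with mapping", {
  sim <- simulate_umi_matrix(c(60, 60), 200, signature_size = 10,
                             planted_uplift = 1, seed = 19)
  nm <- lognormalize(sim$umi)
  sig <- sim$truth$signature_gene_ids
  s1 <- signature_score(nm, sig)
  s2 <- signature_score(nm, rev(sig))
  expect_equal(s1$score, s2$score)
  # single-gene signature equals that gene's normalized expression
  s_one <- signature_score(nm, sig[1])
  expect_equal(s_one$score, as.numeric(nm$data[, sig[1]]))
  # union linearity over disjoint signatures
  a <- sig[1:4]; b <- sig[5:10]
  su <- signature_score(nm, c(a, b))
  sa <- signature_score(nm, a); sb <- signature_score(nm, b)
  expect_equal(su$score,
               (length(a) * sa$score + length(b) * sb$score) /
                 (length(a) + length(b)))
  # case-insensitive default mapping (human SYMBOL -> mouse Symbol style)
  s_upper <- signature_score(nm, toupper(sig))
  expect_equal(s_upper$score, s1$score)
  # explicit ortholog table
  omap <- data.frame(from = paste0("HS_", sig), to = sig)
  s_map <- signature_score(nm, paste0("HS_", sig), ortholog_map = omap)
  expect_equal(s_map$score, s1$score)
  expect_error(signature_score(nm, c("NOPE1", "NOPE2")),
               class = "fbrmech_sc_error")
})

test_that("composition tables are row-normalized and recover planted enrichment", {
  t1 <- composition_table(rep("c0", 5),
                          tibble::tibble(cell_id = 1:5,
                                         condition = rep("SM", 5)))
  expect_equal(as.numeric(t1$c0), 1)
  set.seed(20)
  # population B drawn 3x more often in condition MSI
  n <- 3000
  cond <- rep(c("SM", "MSI"), each = n / 2)
  pop <- ifelse(cond == "MSI",
                ifelse(runif(n) < 0.6, "B", "A"),
                ifelse(runif(n) < 0.2, "B", "A"))
  tab <- composition_table(pop, tibble::tibble(cell_id = seq_len(n),
                                               condition = cond))
  expect_equal(rowSums(tab[, c("A", "B")]), c(1, 1), tolerance = 1e-12,
               ignore_attr = TRUE)
  b_msi <- tab$B[tab$condition == "MSI"]
  b_sm <- tab$B[tab$condition == "SM"]
  expect_equal(b_msi / b_sm, 3, tolerance = 0.2)
})

test_that("end-to-end: planted signature cluster is top scoring and MSI enriched", {
  sim <- simulate_umi_matrix(c(150, 150, 120), 600, signature_size = 25,
                             planted_uplift = 1.5, seed = 23)
  res <- run_sc(list(umi = sim$umi,
                     signature = sim$truth$signature_gene_ids,
                     k = 3, seed = 23, out_dir = tempfile("scrun")))
  scores <- res$scores$score
  cl <- res$clusters
  mean_by_cl <- tapply(scores, cl, mean)
  top_cluster <- names(which.max(mean_by_cl))
  # the top-scoring cluster is the planted population
  kept <- match(res$normalized$cell_ids, sim$umi$cell_ids)
  planted <- sim$truth$population_labels[kept] == sim$truth$signature_population
  expect_gt(mean(cl[planted] == top_cluster), 0.95)
  # and it is enriched in the MSI condition
  cond <- res$normalized$cell_metadata$condition
  in_top <- cl == top_cluster
  expect_lt(wilcox.test(scores[cond == "MSI"], scores[cond == "SM"],
                        alternative = "greater")$p.value, 0.01)
  comp <- composition_table(in_top, res$normalized$cell_metadata)
  frac_msi <- comp$`TRUE`[comp$condition == "MSI"]
  frac_sm <- comp$`TRUE`[comp$condition == "SM"]
  expect_gt(frac_msi, frac_sm)
})
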