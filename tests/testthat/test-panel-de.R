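make_counts <- function(mat, group = rep(c("group1", "group2"),
                                         each = ncol(mat) / 2)) {
  count_matrix(mat, group = group)
}

test_that("size factors are 1 for identical samples and track depth", {
  base <- matrix(rep(c(10L, 50L, 100L, 200L, 400L), 6), nrow = 5)
  cm <- make_counts(base)
  expect_equal(unname(normalize_library_sizes(cm)), rep(1, 6))
  # one sample scaled x2: its factor ~ 2 relative to the rest
  doubled <- base
  doubled[, 2] <- 2L * doubled[, 2]
  f <- normalize_library_sizes(make_counts(doubled))
  expect_equal(unname(f[2] / median(f[-2])), 2, tolerance = 1e-9)
  # invariant to gene order permutation
  set.seed(1)
  sim <- simulate_panel_counts(400, 5, frac_de = 0.1, lfc = 2, seed = 2)
  perm <- sample(400)
  f1 <- normalize_library_sizes(sim$counts)
  shuffled <- count_matrix(sim$counts$counts[perm, ],
                           gene_ids = sim$counts$gene_ids[perm],
                           group = sim$counts$group)
  expect_equal(f1, normalize_library_sizes(shuffled))
  # all-zero sample rejected
  zeroed <- base; zeroed[, 1] <- 0L
  expect_error(normalize_library_sizes(make_counts(zeroed)),
               class = "fbrmech_param_error")
})

test_that("dispersion estimation recovers the simulation truth", {
  # constant gene: raw moment estimate is exactly 0
  mat <- rbind(rep(7L, 8), matrix(rpois(8 * 20, 50), 20))
  cm <- make_counts(mat)
  disp <- estimate_dispersion(cm, factors = setNames(rep(1, 8),
                                                     cm$sample_ids))
  expect_equal(disp$dispersion_raw[1], 0)
  # Poisson truth: shrunken estimates concentrate near zero
  pois <- simulate_panel_counts(1500, 50, frac_de = 0, dispersion = 0,
                                seed = 31)
  dp <- estimate_dispersion(pois$counts)
  expect_lt(median(dp$dispersion), 0.05)
  # NB truth phi = 0.4 at n = 50/group
  nb <- simulate_panel_counts(1500, 50, frac_de = 0, dispersion = 0.4,
                              seed = 32)
  dn <- estimate_dispersion(nb$counts)
  expect_gt(median(dn$dispersion), 0.3)
  expect_lt(median(dn$dispersion), 0.5)
})

test_that("identical groups give exactly zero log fold changes", {
  set.seed(4)
  half <- matrix(rpois(100 * 4, 60), 100)
  cm <- count_matrix(cbind(half, half),
                     group = rep(c("group1", "group2"), each = 4))
  de <- nb_two_group_test(cm)
  expect_equal(de$log2_fold_change, rep(0, 100))
  expect_true(all(de$p_value >= 1 - 1e-8))
})

test_that("all-zero genes follow the documented convention", {
  mat <- rbind(matrix(rpois(50 * 8, 30), 50), rep(0L, 8))
  cm <- make_counts(mat)
  de <- nb_two_group_test(cm)
  expect_equal(de$p_value[51], 1)
  expect_equal(de$log2_fold_change[51], 0)
})

test_that("planted fold changes are recovered by the NB test", {
  sim <- simulate_panel_counts(800, 10, frac_de = 0.1, lfc = 2,
                               dispersion = 0.15, seed = 41)
  de <- nb_two_group_test(sim$counts)
  planted <- de$gene %in% sim$truth$de_gene_ids
  expect_equal(median(de$log2_fold_change[planted]), 2, tolerance = 0.25)
  expect_true(all(abs(de$log2_fold_change[planted] - 2) < 1.5))
  # q-values dominate p-values and are monotone in p-rank
  expect_true(all(de$q_value >= de$p_value - 1e-12))
  o <- order(de$p_value)
  expect_true(all(diff(de$q_value[o]) >= -1e-12))
})

test_that("test results are invariant to sample and gene order", {
  sim <- simulate_panel_counts(200, 6, frac_de = 0.1, lfc = 1.5,
                               dispersion = 0.2, seed = 51)
  de <- nb_two_group_test(sim$counts)
  set.seed(52)
  sp <- sample(ncol(sim$counts$counts))
  gp <- sample(nrow(sim$counts$counts))
  shuffled <- count_matrix(sim$counts$counts[gp, sp],
                           gene_ids = sim$counts$gene_ids[gp],
                           sample_ids = sim$counts$sample_ids[sp],
                           group = sim$counts$group[sp])
  de2 <- nb_two_group_test(shuffled)
  ord <- match(de$gene, de2$gene)
  expect_equal(de$p_value, de2$p_value[ord], tolerance = 1e-8)
  expect_equal(de$log2_fold_change, de2$log2_fold_change[ord],
               tolerance = 1e-8)
})

test_that("null p-values are approximately uniform", {
  sim <- simulate_panel_counts(4000, 10, frac_de = 0, dispersion = 0.1,
                               seed = 61)
  de <- nb_two_group_test(sim$counts)
  expressed <- de$mean_expression > 1
  ks <- suppressWarnings(ks.test(de$p_value[expressed], "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("BH step-up equals the brute-force definition and p.adjust", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(71)
  for (i in 1:25) {
    p <- switch(1 + i %% 3,
                runif(sample(1:40, 1)),
                rbeta(sample(1:40, 1), 0.3, 4),
                round(runif(sample(1:40, 1)), 2))  # heavy ties
    expect_equal(bh_adjust(p), bh_brute_force(p), tolerance = 1e-12)
    expect_equal(bh_adjust(p), p.adjust(p, method = "BH"), tolerance = 1e-12)
  }
  expect_error(bh_adjust(c(0.1, 1.2)), class = "fbrmech_param_error")
  expect_error(bh_adjust(c(-0.1)), class = "fbrmech_param_error")
})

test_that("signature ranking follows p, then |logFC|, then gene id", {
  de <- tibble::tibble(
    gene = c("gB", "gA", "gC", "gD", "gE"),
    log2_fold_change = c(1, 2, -3, 1.5, 0.5),
    p_value = c(0.01, 0.01, 0.001, 0.2, 0.04),
    q_value = c(0.02, 0.02, 0.005, 0.25, 0.05),
    mean_expression = rep(10, 5), dispersion = rep(0.1, 5))
  class(de) <- c("fbr_de", class(de))
  sig <- rank_and_signature(de, 10, "up_in_group2")
  # gD excluded (p >= 0.05 gate fails: p = 0.2); gC excluded (down)
  expect_equal(sig$gene_ids, c("gA", "gB", "gE"))
  sig2 <- rank_and_signature(de, 2, "up_in_group2")
  expect_equal(sig2$gene_ids, c("gA", "gB"))
  down <- rank_and_signature(de, 5, "up_in_group1")
  expect_equal(down$gene_ids, "gC")
  expect_warning(
    empty <- rank_and_signature(de[de$p_value > 0.5, ], 5, "up_in_group2"))
  expect_equal(empty$k, 0)
})

test_that("strong planted signals populate the top-k signature", {
  sim <- simulate_panel_counts(1000, 10, frac_de = 0.025, lfc = 3,
                               dispersion = 0.1, seed = 81)
  de <- nb_two_group_test(sim$counts)
  k <- length(sim$truth$de_gene_ids)
  sig <- rank_and_signature(de, k, "up_in_group2")
  overlap <- length(intersect(sig$gene_ids, sim$truth$de_gene_ids)) / k
  expect_gte(overlap, 0.9)
})

test_that("NB test agrees with edgeR on effect direction for strong signals", {
  skip_if_not_installed("edgeR")
  sim <- simulate_panel_counts(300, 8, frac_de = 0.1, lfc = 2,
                               dispersion = 0.1, seed = 91)
  de <- nb_two_group_test(sim$counts)
  y <- edgeR::DGEList(counts = sim$counts$counts,
                      group = sim$counts$group)
  y <- edgeR::calcNormFactors(y)
  y <- edgeR::estimateDisp(y)
  et <- edgeR::exactTest(y)$table
  planted <- sim$counts$gene_ids %in% sim$truth$de_gene_ids
  # same genes called at q < 0.05, overwhelmingly
  ours <- de$q_value < 0.05
  theirs <- p.adjust(et$PValue, "BH") < 0.05
  expect_gt(mean(ours[planted] & theirs[planted]), 0.8)
  # log fold changes agree closely on planted genes
  expect_equal(de$log2_fold_change[planted], et$logFC[planted],
               tolerance = 0.2)
})
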