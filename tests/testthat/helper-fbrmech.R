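# Shared fixtures and independent oracles, all built in code.

# homogeneous block domain (no implant), L mm cube
unit_block <- function(E = 1e5, nu = 0, L = 10, name = "tissue") {
  domain_spec(layers = list(layer_spec(name, L, material_spec(name, E, nu))),
              lateral_extent = L)
}

# small two-region domain with a disc implant, cheap to solve
toy_implant_domain <- function(E_tissue = 5e3, E_implant = 5e5,
                               load = load_spec("static_force", 0.05),
                               lateral = 12, nu = 0.45) {
  domain_spec(
    layers = list(
      layer_spec("base", 3, material_spec("base", 1e5, nu)),
      layer_spec("mid", 6, material_spec("fat", E_tissue, nu)),
      layer_spec("top", 3, material_spec("skin", 1e5, nu))),
    implant = list(radius = 4, height = 4,
                   material = material_spec("implant", E_implant, nu)),
    lateral_extent = lateral, implant_layer = "mid", load = load)
}

# --- independent element-stiffness oracle -----------------------------------
# B'CB integrated by Monte-Carlo quadrature with finite-difference shape
# gradients: shares no code with element_stiffness().
element_stiffness_oracle <- function(tet_coords_mm, E, nu, n_mc = 2000,
                                     seed = 42) {
  co <- tet_coords_mm * 1e-3
  # shape function a_i + b_i x + c_i y + d_i z via 4x4 solve
  A <- cbind(1, co)
  coeff <- solve(A, diag(4))  # column i = coefficients of N_i
  Nfun <- function(x) as.numeric(t(coeff) %*% c(1, x))
  h <- 1e-6
  grad_fd <- function(i, x) {
    vapply(1:3, function(d) {
      e <- numeric(3); e[d] <- h
      (Nfun(x + e)[i] - Nfun(x - e)[i]) / (2 * h)
    }, 0)
  }
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  C <- matrix(0, 6, 6)
  C[1:3, 1:3] <- lam; diag(C)[1:3] <- lam + 2 * mu; diag(C)[4:6] <- mu
  vol <- abs(det(cbind(co[2, ] - co[1, ], co[3, ] - co[1, ],
                       co[4, ] - co[1, ]))) / 6
  set.seed(seed)
  # sample points uniformly in the tet via sorted-uniform barycentrics
  acc <- matrix(0, 12, 12)
  for (s in seq_len(n_mc)) {
    w <- diff(c(0, sort(runif(3)), 1))
    x <- as.numeric(t(co) %*% w)
    B <- matrix(0, 6, 12)
    for (a in 1:4) {
      g <- grad_fd(a, x)
      cols <- (3 * (a - 1) + 1):(3 * a)
      B[1, cols[1]] <- g[1]; B[2, cols[2]] <- g[2]; B[3, cols[3]] <- g[3]
      B[4, cols[1]] <- g[2]; B[4, cols[2]] <- g[1]
      B[5, cols[2]] <- g[3]; B[5, cols[3]] <- g[2]
      B[6, cols[1]] <- g[3]; B[6, cols[3]] <- g[1]
    }
    acc <- acc + t(B) %*% C %*% B
  }
  vol * acc / n_mc
}

# --- dense brute-force elasticity solve -------------------------------------
# assembles from element_stiffness() blocks into a dense matrix and solves
# with base::solve; independent of the sparse vectorized assembly.
brute_force_solve <- function(problem) {
  mesh <- problem$mesh
  nn <- nrow(mesh$nodes)
  stopifnot(3 * nn <= 300)
  K <- matrix(0, 3 * nn, 3 * nn)
  for (e in seq_len(nrow(mesh$elems))) {
    nodes <- mesh$elems[e, ]
    mat <- problem$material_map[[mesh$region[e]]]
    Ke <- element_stiffness(mesh$nodes[nodes, , drop = FALSE],
                            mat$youngs_modulus, mat$poisson_ratio)
    dofs <- as.vector(t(outer(nodes, 0:2, function(n, d) 3 * (n - 1) + d + 1)))
    K[dofs, dofs] <- K[dofs, dofs] + Ke
  }
  f <- numeric(3 * nn)
  if (is.matrix(problem$load)) {
    f[seq(1, 3 * nn, 3)] <- problem$load[, 1]
    f[seq(2, 3 * nn, 3)] <- problem$load[, 2]
    f[seq(3, 3 * nn, 3)] <- problem$load[, 3]
  }
  fixed <- as.vector(t(outer(problem$dirichlet, 0:2,
                             function(n, d) 3 * (n - 1) + d + 1)))
  free <- setdiff(seq_len(3 * nn), fixed)
  u <- numeric(3 * nn)
  u[free] <- solve(K[free, free], f[free])
  matrix(u, ncol = 3, byrow = TRUE)
}

# --- brute-force BH step-up from the definition -----------------------------
bh_brute_force <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    vals <- vapply(i:m, function(j) m * p[o[j]] / j, 0)
    q[o[i]] <- min(1, min(vals))
  }
  q
}

# --- brute-force AUC by pair counting (ties count 1/2) ----------------------
auc_pair_counting <- function(x, positive) {
  xi <- x[positive]; xo <- x[!positive]
  total <- 0
  for (a in xi) for (b in xo) {
    total <- total + (a > b) + 0.5 * (a == b)
  }
  total / (length(xi) * length(xo))
}

# adjusted Rand index between two labelings
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  (sum_ij - expected) / (maxi - expected)
}

# 3-cell toy with controlled detected-gene counts and mito fractions:
# cell A: exactly 200 detected genes, mito 0.05  -> kept (>= 200 inclusive)
# cell B: 150 detected genes, mito 0.05          -> removed (too few genes)
# cell C: 250 detected genes, mito exactly 0.10  -> removed (< 0.10 strict)
qc_toy <- function() {
  n_genes <- 260
  gene_ids <- c(sprintf("gene%03d", seq_len(n_genes - 1)), "mt-1")
  counts <- matrix(0L, 3, n_genes,
                   dimnames = list(c("A", "B", "C"), gene_ids))
  counts["A", 1:199] <- 1L      # + mito gene: 200 detected, mito 11/210 < 0.10
  counts["A", n_genes] <- 11L
  counts["B", 1:149] <- 2L      # 150 detected genes
  counts["B", n_genes] <- 10L
  counts["C", 1:243] <- 2L      # 244 detected, mito 54/540 = 0.10 exactly
  counts["C", n_genes] <- 54L
  umi_matrix(counts, mito_gene_ids = "mt-1")
}
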