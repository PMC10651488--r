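ref_tet <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)) * 1000  # 1 m

test_that("element stiffness is symmetric, PSD with 6 rigid modes, linear in E", {
  set.seed(3)
  tet <- matrix(rnorm(12, sd = 5), 4, 3) + 10
  if (det(cbind(tet[2, ] - tet[1, ], tet[3, ] - tet[1, ],
                tet[4, ] - tet[1, ])) < 0) tet <- tet[c(1, 2, 4, 3), ]
  K <- element_stiffness(tet, E = 2e5, nu = 0.3)
  expect_equal(K, t(K), tolerance = 1e-12)
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(abs(ev) < max(ev) * 1e-9), 6)
  expect_true(all(ev > -max(ev) * 1e-9))
  expect_equal(element_stiffness(tet, 4e5, 0.3), 2 * K, tolerance = 1e-12)
  expect_error(element_stiffness(rbind(tet[1, ], tet[1, ], tet[3, ], tet[4, ]),
                                 1e5, 0.3), class = "fbrmech_fem_error")
})

test_that("element stiffness matches an independent quadrature oracle", {
  K <- element_stiffness(ref_tet, E = 1, nu = 0.25)
  K_oracle <- element_stiffness_oracle(ref_tet, E = 1, nu = 0.25)
  expect_equal(K, K_oracle, tolerance = 1e-4)
})

test_that("zero load gives zero displacement and stress", {
  m <- generate_mesh(unit_block(), 5)
  sol <- assemble_and_solve(elasticity_problem(m, load = NULL))
  expect_equal(max(abs(sol$displacements)), 0)
  expect_equal(max(abs(sol$element_stress)), 0)
})

test_that("uniaxial patch test is exact for linear tetrahedra", {
  E <- 1e5; t <- 2000; L <- 10
  m <- generate_mesh(unit_block(E = E, nu = 0, L = L), 2.5)
  f <- traction_load(m, "z_max", c(0, 0, t))
  sol <- assemble_and_solve(elasticity_problem(m, load = f))
  expect_equal(max(abs(sol$element_stress[, 3] - t)) / t, 0, tolerance = 1e-10)
  off <- sol$element_stress[, -3]
  expect_lt(max(abs(off)) / t, 1e-10)
  tip <- which(abs(m$nodes[, 3] - L) < 1e-9)
  u_exact <- t / E * (L * 1e-3)
  expect_equal(sol$displacements[tip, 3], rep(u_exact, length(tip)),
               tolerance = 1e-10)
})

test_that("two-layer bar in series matches the series-spring closed form", {
  E1 <- 2e5; E2 <- 5e4; t <- 1000; L1 <- 6; L2 <- 4
  d <- domain_spec(
    layers = list(layer_spec("a", L1, material_spec("a", E1, 0)),
                  layer_spec("b", L2, material_spec("b", E2, 0))),
    lateral_extent = 10)
  m <- generate_mesh(d, 2)
  f <- traction_load(m, "z_max", c(0, 0, t))
  sol <- assemble_and_solve(elasticity_problem(m, load = f))
  u_exact <- t * (L1 * 1e-3 / E1 + L2 * 1e-3 / E2)
  tip <- which(abs(m$nodes[, 3] - (L1 + L2)) < 1e-9)
  expect_equal(sol$displacements[tip, 3], rep(u_exact, length(tip)),
               tolerance = 1e-10)
  expect_equal(sol$element_stress[, 3], rep(t, nrow(m$elems)),
               tolerance = 1e-10)
})

test_that("stress recovery reproduces Hooke's law on prescribed fields", {
  E <- 1e5
  m <- generate_mesh(unit_block(E = E, nu = 0), 5)
  pr <- elasticity_problem(m, load = NULL)
  # uniform strain exx = 0.01 (displacements in metres, coordinates in mm)
  sol <- structure(list(problem = pr,
                        displacements = cbind(0.01 * m$nodes[, 1] * 1e-3, 0, 0)),
                   class = "fbr_solution")
  s <- recover_stress(sol)
  expect_equal(s[, 1], rep(0.01 * E, nrow(s)), tolerance = 1e-10)
  expect_lt(max(abs(s[, -1])), 1e-10 * E)
  # rigid-body translation: zero stress
  rigid <- structure(list(problem = pr,
                          displacements = matrix(c(1e-3, 2e-3, -5e-4),
                                                 nrow(m$nodes), 3,
                                                 byrow = TRUE)),
                     class = "fbr_solution")
  expect_lt(max(abs(recover_stress(rigid))), 1e-12 * E)
  # uniform shear u_x = gamma * z -> sigma_xy... sigma_xz = mu * gamma
  nu <- 0.3; gam <- 0.02
  m3 <- generate_mesh(unit_block(E = E, nu = nu), 5)
  pr3 <- elasticity_problem(m3, load = NULL)
  shear <- structure(list(problem = pr3,
                          displacements = cbind(gam * m3$nodes[, 3] * 1e-3,
                                                0, 0)),
                     class = "fbr_solution")
  s3 <- recover_stress(shear)
  expect_equal(s3[, 6], rep(E / (2 * (1 + nu)) * gam, nrow(s3)),
               tolerance = 1e-10)
})

test_that("sparse solve agrees with dense brute force below 300 DOF", {
  E <- 8e4
  m <- generate_mesh(unit_block(E = E, nu = 0.3, L = 10), 5)  # 27 nodes, 81 DOF
  expect_lte(3 * nrow(m$nodes), 300)
  f <- traction_load(m, "z_max", c(500, 0, 1500))
  pr <- elasticity_problem(m, load = f)
  u_sparse <- assemble_and_solve(pr)$displacements
  u_dense <- brute_force_solve(pr)
  expect_equal(u_sparse, u_dense, tolerance = 1e-9)
})

test_that("solution scales linearly with the load", {
  d <- toy_implant_domain()
  m <- generate_mesh(d, 2)
  pr1 <- elasticity_problem(m, load = load_spec("static_force", 0.05))
  pr3 <- elasticity_problem(m, load = load_spec("static_force", 0.15))
  u1 <- assemble_and_solve(pr1)$displacements
  u3 <- assemble_and_solve(pr3)$displacements
  expect_equal(u3, 3 * u1, tolerance = 1e-10)
})

test_that("interface summary matches far field for a homogeneous 'implant'", {
  E <- 1e5; t <- 2000
  mat <- material_spec("m", E, 0)
  d <- domain_spec(
    layers = list(layer_spec("lo", 4, mat), layer_spec("mid", 4, mat),
                  layer_spec("hi", 4, mat)),
    implant = list(radius = 6, height = 4, material = mat),
    lateral_extent = 12, implant_layer = "mid")
  m <- generate_mesh(d, 2)
  f <- traction_load(m, "z_max", c(0, 0, t))
  sol <- assemble_and_solve(elasticity_problem(m, load = f))
  # Sx here is the transverse stress (zero); check the loaded component via
  # the full element field: all elements carry sigma_zz = t exactly
  expect_equal(sol$element_stress[, 3], rep(t, nrow(m$elems)),
               tolerance = 1e-10)
  sm <- interface_stress_summary(sol)
  expect_equal(sm$max_abs_sx, max(abs(sol$element_stress[, 1])) / 1e3,
               tolerance = 1e-6)
})

test_that("stiff inclusion under +x load compresses ahead, stretches behind", {
  sm <- solve_domain(toy_implant_domain(), edge_length = 2)
  summary <- sm$summary
  expect_gt(summary$max_tensile_sx, 0)
  expect_lt(summary$max_compressive_sx, 0)
  expect_equal(summary$max_abs_sx,
               max(abs(c(summary$max_tensile_sx, summary$max_compressive_sx))))
  # locate extremal elements: compression on the load-facing (+x) side
  mesh <- sm$mesh
  tissue <- mesh$region != "implant"
  touches <- matrix(mesh$elems %in% mesh$node_sets$interface, ncol = 4)
  sel <- which(tissue & rowSums(touches) > 0)
  sx <- sm$solution$element_stress[sel, 1]
  cx <- rowMeans(matrix(mesh$nodes[mesh$elems[sel, ], 1], ncol = 4))
  expect_gt(cx[which.min(sx)], 0)  # most compressive element ahead of implant
  expect_lt(cx[which.max(sx)], 0)  # most tensile element behind
})

test_that("empty interface is an error", {
  m <- generate_mesh(unit_block(), 5)
  sol <- assemble_and_solve(elasticity_problem(m, load = NULL))
  expect_error(interface_stress_summary(sol), class = "fbrmech_param_error")
})

test_that("mesh refinement report flags convergence", {
  # homogeneous patch: identical stress at all resolutions
  d <- unit_block(E = 1e5, nu = 0)
  # give the block an implant-free summary? use the toy implant domain instead
  d2 <- toy_implant_domain()
  conv <- mesh_convergence_check(d2, c(3, 2), tol = Inf)
  expect_true(all(conv$converged[-1]))
  expect_equal(nrow(conv), 2)
  expect_true(all(diff(conv$n_elements) > 0))
  expect_error(mesh_convergence_check(d2, 3), class = "fbrmech_param_error")
})

test_that("harmonic steady state reduces to statics at and near zero frequency", {
  d <- toy_implant_domain()
  m <- generate_mesh(d, 2)
  load <- load_spec("static_force", 0.05)
  pr <- elasticity_problem(m, load = load)
  static <- assemble_and_solve(pr)
  h0 <- harmonic_steady_state(pr, 0)
  expect_equal(h0$displacements, static$displacements)
  h_low <- harmonic_steady_state(pr, 1)
  rel <- max(abs(h_low$displacements - static$displacements)) /
    max(abs(static$displacements))
  expect_lt(rel, 0.05)
})

test_that("global stiffness is symmetric with nonnegative energy", {
  m <- generate_mesh(unit_block(E = 1e5, nu = 0.3), 5)
  mats <- fbrmech:::element_materials(m, list(tissue = material_spec("t", 1e5, 0.3)))
  K <- fbrmech:::assemble_stiffness(m, mats)
  expect_equal(as.matrix(K), t(as.matrix(K)), tolerance = 1e-12)
  set.seed(5)
  for (i in 1:5) {
    u <- rnorm(nrow(m$nodes) * 3)
    expect_gte(as.numeric(t(u) %*% (K %*% u)), -1e-8)
  }
  # rigid translation has zero energy before constraints
  u_rigid <- rep(c(1, 0, 0), nrow(m$nodes))
  expect_lt(abs(as.numeric(t(u_rigid) %*% (K %*% u_rigid))),
            1e-9 * max(abs(K@x)))
})
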