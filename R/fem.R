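# Small-strain linear elasticity on linear (constant-strain) tetrahedra.
# Geometry enters in mm and is converted to metres here; displacements are in
# metres and stresses in pascal. Voigt order: xx, yy, zz, xy, yz, xz with
# engineering shear strains.

lame_parameters <- function(E, nu) {
  list(lambda = E * nu / ((1 + nu) * (1 - 2 * nu)),
       mu = E / (2 * (1 + nu)))
}

isotropic_C <- function(E, nu) {
  lp <- lame_parameters(E, nu)
  C <- matrix(0, 6, 6)
  C[1:3, 1:3] <- lp$lambda
  diag(C)[1:3] <- lp$lambda + 2 * lp$mu
  diag(C)[4:6] <- lp$mu
  C
}

# shape-function gradients of a single tet (rows = 4 nodes), coords in metres
tet_gradients <- function(coords_m) {
  a <- coords_m[2, ] - coords_m[1, ]
  b <- coords_m[3, ] - coords_m[1, ]
  cc <- coords_m[4, ] - coords_m[1, ]
  cr <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                         u[3] * v[1] - u[1] * v[3],
                         u[1] * v[2] - u[2] * v[1])
  det <- sum(a * cr(b, cc))  # 6 V (signed)
  g2 <- cr(b, cc) / det
  g3 <- cr(cc, a) / det
  g4 <- cr(a, b) / det
  g1 <- -(g2 + g3 + g4)
  list(grads = rbind(g1, g2, g3, g4), volume = det / 6)
}

# 6 x 12 strain-displacement matrix from 4 x 3 gradients
tet_B <- function(grads) {
  B <- matrix(0, 6, 12)
  for (a in 1:4) {
    cols <- (3 * (a - 1) + 1):(3 * a)
    g <- grads[a, ]
    B[1, cols[1]] <- g[1]
    B[2, cols[2]] <- g[2]
    B[3, cols[3]] <- g[3]
    B[4, cols[1]] <- g[2]; B[4, cols[2]] <- g[1]
    B[5, cols[2]] <- g[3]; B[5, cols[3]] <- g[2]
    B[6, cols[1]] <- g[3]; B[6, cols[3]] <- g[1]
  }
  B
}

#' Stiffness block of one linear tetrahedron
#'
#' Exact one-point integration of `V * B' C B` for the constant-strain
#' tetrahedron with isotropic elasticity `C(E, nu)`. The block is symmetric
#' positive-semidefinite with exactly six zero eigenvalues (rigid-body modes)
#' and is linear in `E`.
#'
#' @param tet_coords 4 x 3 node coordinate matrix in mm.
#' @param E Young's modulus, Pa.
#' @param nu Poisson ratio in `[0, 0.5)`.
#' @return 12 x 12 stiffness matrix (N/m per DOF ordering x1,y1,z1,...,z4).
#' @export
element_stiffness <- function(tet_coords, E, nu) {
  if (!is.matrix(tet_coords) || !all(dim(tet_coords) == c(4L, 3L))) {
    abort("`tet_coords` must be a 4 x 3 matrix (mm).",
          class = "fbrmech_param_error")
  }
  if (nu < 0 || nu >= 0.5) {
    abort("`nu` must lie in [0, 0.5).", class = "fbrmech_param_error")
  }
  tg <- tet_gradients(tet_coords * 1e-3)
  if (abs(tg$volume) < 1e-30) {
    abort("Degenerate (zero-volume) tetrahedron.", class = "fbrmech_fem_error")
  }
  B <- tet_B(tg$grads)
  abs(tg$volume) * t(B) %*% isotropic_C(E, nu) %*% B
}

#' Pose an elasticity problem on a mesh
#'
#' @param mesh An `fbr_mesh`.
#' @param material_map Named list: region label -> [material_spec()]. Defaults
#'   to the materials carried by the mesh's domain spec.
#' @param dirichlet Node indices with prescribed zero displacement (all three
#'   components); defaults to the mesh's `bottom_fixed` set. Must be nonempty.
#' @param load Either an n x 3 matrix of nodal forces in N, or an
#'   [load_spec()] of kind `static_force` (resultant distributed over implant
#'   nodes by lumped-volume share) or `body_force` (per-mass force over the
#'   implant region). Vibration loads must first be converted with
#'   [peak_quasistatic_load()].
#' @return An `fbr_problem`.
#' @export
elasticity_problem <- function(mesh, material_map = NULL, dirichlet = NULL,
                               load = NULL) {
  if (!inherits(mesh, "fbr_mesh")) {
    abort("`mesh` must be an fbr_mesh.", class = "fbrmech_param_error")
  }
  if (is.null(material_map)) material_map <- default_material_map(mesh$spec)
  regions <- unique(mesh$region)
  missing <- setdiff(regions, names(material_map))
  if (length(missing)) {
    abort(paste0("No material for region(s): ", paste(missing, collapse = ", ")),
          class = "fbrmech_param_error")
  }
  material_map <- lapply(material_map, as_material)
  if (is.null(dirichlet)) dirichlet <- mesh$node_sets$bottom_fixed
  if (length(dirichlet) == 0L) {
    abort("Dirichlet set must be nonempty (rigid-body motion unconstrained).",
          class = "fbrmech_param_error")
  }
  structure(list(mesh = mesh, material_map = material_map,
                 dirichlet = sort(unique(as.integer(dirichlet))),
                 load = load),
            class = "fbr_problem")
}

default_material_map <- function(spec) {
  mm <- lapply(spec$layers, function(ly) as_material(ly$material))
  names(mm) <- vapply(spec$layers, `[[`, "", "name")
  if (!is.null(spec$implant)) mm$implant <- as_material(spec$implant$material)
  mm
}

# per-element E, nu, lambda, mu, rho vectors from the material map
element_materials <- function(mesh, material_map) {
  E <- vapply(material_map, `[[`, 0, "youngs_modulus")
  nu <- vapply(material_map, `[[`, 0, "poisson_ratio")
  rho <- vapply(material_map, `[[`, 0, "density")
  i <- match(mesh$region, names(material_map))
  lp <- lame_parameters(unname(E[i]), unname(nu[i]))
  list(E = unname(E[i]), nu = unname(nu[i]), lambda = lp$lambda, mu = lp$mu,
       rho = unname(rho[i]))
}

# vectorized per-element shape gradients; coordinates converted to metres
mesh_gradients <- function(mesh) {
  nodes <- mesh$nodes * 1e-3
  el <- mesh$elems
  p1 <- nodes[el[, 1L], , drop = FALSE]
  a <- nodes[el[, 2L], , drop = FALSE] - p1
  b <- nodes[el[, 3L], , drop = FALSE] - p1
  cc <- nodes[el[, 4L], , drop = FALSE] - p1
  crs <- function(u, v) cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                              u[, 3] * v[, 1] - u[, 1] * v[, 3],
                              u[, 1] * v[, 2] - u[, 2] * v[, 1])
  bc <- crs(b, cc); ca <- crs(cc, a); ab <- crs(a, b)
  det <- rowSums(a * bc)
  g <- array(0, dim = c(nrow(el), 4L, 3L))
  g[, 2L, ] <- bc / det
  g[, 3L, ] <- ca / det
  g[, 4L, ] <- ab / det
  g[, 1L, ] <- -(g[, 2L, ] + g[, 3L, ] + g[, 4L, ])
  list(grads = g, volume = det / 6)
}

# sparse global stiffness (3n x 3n, dsCMatrix) from vectorized block formula
# K_ab = V [ lambda g_a g_b' + mu g_b g_a' + mu (g_a . g_b) I ]
assemble_stiffness <- function(mesh, mats, geom = NULL) {
  if (is.null(geom)) geom <- mesh_gradients(mesh)
  g <- geom$grads
  V <- abs(geom$volume)
  ne <- nrow(mesh$elems)
  nn <- nrow(mesh$nodes)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  blocks_i <- vector("list", 144L)
  blocks_j <- vector("list", 144L)
  blocks_x <- vector("list", 144L)
  bi <- 0L
  for (a in 1:4) {
    ga <- g[, a, ]
    na <- mesh$elems[, a]
    for (b in 1:4) {
      gb <- g[, b, ]
      nb <- mesh$elems[, b]
      dot <- rowSums(ga * gb)
      for (i in 1:3) {
        for (j in 1:3) {
          val <- V * (mats$lambda * ga[, i] * gb[, j] +
                      mats$mu * ga[, j] * gb[, i] +
                      (if (i == j) mats$mu * dot else 0))
          bi <- bi + 1L
          blocks_i[[bi]] <- 3L * (na - 1L) + i
          blocks_j[[bi]] <- 3L * (nb - 1L) + j
          blocks_x[[bi]] <- val
        }
      }
    }
  }
  K <- Matrix::sparseMatrix(i = unlist(blocks_i), j = unlist(blocks_j),
                            x = unlist(blocks_x), dims = c(3L * nn, 3L * nn))
  Matrix::forceSymmetric((K + Matrix::t(K)) / 2)
}

# build the 3n nodal force vector (N) from the problem's load description
build_force_vector <- function(problem, geom) {
  mesh <- problem$mesh
  nn <- nrow(mesh$nodes)
  f <- numeric(3L * nn)
  load <- problem$load
  if (is.null(load)) return(f)
  if (is.matrix(load)) {
    if (!all(dim(load) == c(nn, 3L))) {
      abort("Nodal force matrix must be n_nodes x 3 (N).",
            class = "fbrmech_param_error")
    }
    f[seq(1, 3 * nn, by = 3)] <- load[, 1]
    f[seq(2, 3 * nn, by = 3)] <- load[, 2]
    f[seq(3, 3 * nn, by = 3)] <- load[, 3]
    return(f)
  }
  if (!inherits(load, "fbr_load")) {
    abort("`load` must be a nodal force matrix or an fbr_load.",
          class = "fbrmech_param_error")
  }
  if (load$kind == "vibration") {
    abort("Convert vibration loads with peak_quasistatic_load() first.",
          class = "fbrmech_param_error")
  }
  imp_el <- which(mesh$region == "implant")
  if (length(imp_el) == 0L) {
    abort("Implant loads require implant-labeled elements in the mesh.",
          class = "fbrmech_fem_error")
  }
  # lumped nodal volumes over implant elements (m^3)
  vols <- abs(geom$volume)[imp_el] / 4
  node_ids <- as.vector(mesh$elems[imp_el, , drop = FALSE])
  nodal_vol <- numeric(nn)
  acc <- rowsum(rep(vols, times = 4L), group = node_ids)
  nodal_vol[as.integer(rownames(acc))] <- acc[, 1L]
  if (load$kind == "static_force") {
    weights <- nodal_vol / sum(nodal_vol)
    fvec <- load$magnitude * load$direction
  } else {  # body_force, N/kg: include motor mass spread by volume share
    mats <- element_materials(mesh, problem$material_map)
    rho <- mats$rho[imp_el][1]
    motor <- mesh$spec$implant$motor_mass %||% 0
    nodal_mass <- nodal_vol * rho + motor * nodal_vol / sum(nodal_vol)
    weights <- nodal_mass
    fvec <- load$magnitude * load$direction
  }
  nz <- which(weights > 0)
  for (d in 1:3) f[3L * (nz - 1L) + d] <- weights[nz] * fvec[d]
  f
}

#' Consistent nodal loads for a uniform traction on a boundary face
#'
#' Finds the boundary triangles of the mesh lying on the requested bounding
#' plane and distributes `traction * area / 3` of each triangle to its nodes
#' -- the consistent load vector for linear elements, under which uniform
#' stress states are reproduced exactly (patch test).
#'
#' @param mesh An `fbr_mesh`.
#' @param face One of `"x_min"`, `"x_max"`, `"y_min"`, `"y_max"`, `"z_min"`,
#'   `"z_max"`.
#' @param traction Length-3 traction vector, Pa.
#' @return n x 3 nodal force matrix (N) usable as the `load` of
#'   [elasticity_problem()].
#' @export
traction_load <- function(mesh, face, traction) {
  axis <- match(substr(face, 1, 1), c("x", "y", "z"))
  if (is.na(axis) || !grepl("_(min|max)$", face)) {
    abort("`face` must be one of x/y/z _min/_max.",
          class = "fbrmech_param_error")
  }
  coord <- mesh$nodes[, axis]
  val <- if (grepl("max$", face)) max(coord) else min(coord)
  tol <- 1e-9 * max(1, diff(range(coord)))
  on_plane <- abs(coord - val) <= tol
  f <- matrix(0, nrow(mesh$nodes), 3L)
  faces <- rbind(c(1L, 2L, 3L), c(1L, 2L, 4L), c(1L, 3L, 4L), c(2L, 3L, 4L))
  el_on <- matrix(on_plane[mesh$elems], ncol = 4L)
  for (k in 1:4) {
    tri_el <- which(rowSums(el_on[, faces[k, ], drop = FALSE]) == 3L)
    if (!length(tri_el)) next
    tri <- mesh$elems[tri_el, faces[k, ], drop = FALSE]
    p1 <- mesh$nodes[tri[, 1L], , drop = FALSE] * 1e-3
    e1 <- mesh$nodes[tri[, 2L], , drop = FALSE] * 1e-3 - p1
    e2 <- mesh$nodes[tri[, 3L], , drop = FALSE] * 1e-3 - p1
    cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
    cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
    cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
    area <- sqrt(cx^2 + cy^2 + cz^2) / 2
    for (v in 1:3) {
      acc <- rowsum(area / 3, group = tri[, v])
      ids <- as.integer(rownames(acc))
      for (d in 1:3) f[ids, d] <- f[ids, d] + acc[, 1L] * traction[d]
    }
  }
  f
}

#' Assemble and solve the linear elastic problem
#'
#' Assembles the global sparse stiffness, eliminates the Dirichlet DOFs
#' (prescribed zero displacement), solves the reduced symmetric
#' positive-definite system by sparse Cholesky factorization, verifies the
#' relative residual (<= 1e-8) and recovers per-element stresses.
#'
#' @param problem An [elasticity_problem()].
#' @return An `fbr_solution` with `displacements` (n x 3, metres),
#'   `element_stress` (m x 6 Voigt, Pa), the relative residual, and the
#'   problem reference.
#' @export
assemble_and_solve <- function(problem) {
  if (!inherits(problem, "fbr_problem")) {
    abort("`problem` must come from elasticity_problem().",
          class = "fbrmech_param_error")
  }
  mesh <- problem$mesh
  geom <- mesh_gradients(mesh)
  if (any(abs(geom$volume) < 1e-30)) {
    abort("Mesh contains degenerate tetrahedra.", class = "fbrmech_fem_error")
  }
  mats <- element_materials(mesh, problem$material_map)
  K <- assemble_stiffness(mesh, mats, geom)
  f <- build_force_vector(problem, geom)
  nn <- nrow(mesh$nodes)
  fixed_dofs <- as.vector(t(outer(problem$dirichlet, 0:2,
                                  function(n, d) 3L * (n - 1L) + d + 1L)))
  free <- setdiff(seq_len(3L * nn), fixed_dofs)
  Kff <- K[free, free, drop = FALSE]
  u <- numeric(3L * nn)
  if (sum(abs(f)) > 0) {
    # Jacobi equilibration + iterative refinement: a metal implant in soft
    # tissue gives stiffness contrasts ~1e7 that a plain factorization
    # resolves to only ~1e-5 relative residual
    dscale <- 1 / sqrt(Matrix::diag(Kff))
    Ds <- Matrix::Diagonal(x = dscale)
    Ks <- Ds %*% Kff %*% Ds
    ch <- tryCatch(
      Matrix::Cholesky(Matrix::forceSymmetric(Ks), LDL = FALSE),
      error = function(e) abort(
        paste0("Singular reduced system (insufficient constraints?): ",
               conditionMessage(e)),
        class = "fbrmech_fem_error"))
    b <- f[free]
    bs <- b * dscale
    ys <- as.numeric(Matrix::solve(ch, bs))
    bnorm <- sqrt(sum(bs^2))
    res <- Inf
    for (it in 1:20) {
      r <- bs - as.numeric(Ks %*% ys)
      res <- sqrt(sum(r^2)) / bnorm
      if (res <= 1e-10) break
      ys <- ys + as.numeric(Matrix::solve(ch, r))
    }
    uf <- ys * dscale
    # normwise backward error ||r|| / (||K|| ||u|| + ||f||): the measure that
    # stays meaningful under extreme stiffness contrast
    rfin <- as.numeric(Kff %*% uf) - b
    normK <- max(Matrix::rowSums(abs(Kff)))
    res <- sqrt(sum(rfin^2)) /
      (normK * sqrt(sum(uf^2)) + sqrt(sum(b^2)))
    if (!is.finite(res) || res > 1e-8) {
      abort(sprintf("Solver backward error %.3g exceeds 1e-8.", res),
            class = "fbrmech_fem_error")
    }
    u[free] <- uf
  } else {
    res <- 0
  }
  disp <- matrix(u, ncol = 3L, byrow = TRUE)
  sol <- structure(
    list(problem = problem,
         displacements = disp,
         element_stress = NULL,
         residual = res),
    class = "fbr_solution")
  sol$element_stress <- recover_stress(sol)
  sol
}

#' Recover constant per-element stress tensors from displacements
#'
#' Linear tetrahedra carry constant strain; the stress is `C(E, nu) : eps`
#' per element with the region's isotropic stiffness. Compression is
#' negative. Returned (and stored on the solution) as an m x 6 matrix in
#' Voigt order xx, yy, zz, xy, yz, xz (Pa).
#'
#' @param solution An `fbr_solution` (with displacements).
#' @return m x 6 stress matrix, Pa.
#' @export
recover_stress <- function(solution) {
  problem <- solution$problem
  mesh <- problem$mesh
  geom <- mesh_gradients(mesh)
  mats <- element_materials(mesh, problem$material_map)
  u <- solution$displacements
  # displacement gradient H = sum_a u_a (x) g_a ; eps = sym(H)
  H <- matrix(0, nrow(mesh$elems), 9L)
  for (a in 1:4) {
    ua <- u[mesh$elems[, a], , drop = FALSE]
    ga <- geom$grads[, a, ]
    k <- 0L
    for (i in 1:3) for (j in 1:3) {
      k <- k + 1L
      H[, k] <- H[, k] + ua[, i] * ga[, j]
    }
  }
  exx <- H[, 1]; eyy <- H[, 5]; ezz <- H[, 9]
  gxy <- H[, 2] + H[, 4]
  gyz <- H[, 6] + H[, 8]
  gxz <- H[, 3] + H[, 7]
  tr <- exx + eyy + ezz
  s <- cbind(
    xx = mats$lambda * tr + 2 * mats$mu * exx,
    yy = mats$lambda * tr + 2 * mats$mu * eyy,
    zz = mats$lambda * tr + 2 * mats$mu * ezz,
    xy = mats$mu * gxy,
    yz = mats$mu * gyz,
    xz = mats$mu * gxz)
  s
}

#' Summarize horizontal stress at the implant-tissue interface
#'
#' Takes the extrema of the per-element horizontal normal stress Sx over
#' tissue-side elements adjacent to interface nodes and reports them in kPa.
#' `max_tensile_sx` is the largest nonnegative Sx, `max_compressive_sx` the
#' most negative (reported <= 0), and `max_abs_sx` their absolute maximum --
#' the single "maximal interface stress" quoted for a model.
#'
#' @param solution An `fbr_solution`.
#' @param interface Interface node set; defaults to the mesh's.
#' @return An `fbr_stress_summary` (also a one-row tibble via [tidy()]).
#' @export
interface_stress_summary <- function(solution, interface = NULL) {
  mesh <- solution$problem$mesh
  if (is.null(interface)) interface <- mesh$node_sets$interface
  if (length(interface) == 0L) {
    abort("Interface node set is empty.", class = "fbrmech_param_error")
  }
  tissue <- mesh$region != "implant"
  touches <- matrix(mesh$elems %in% interface, ncol = 4L)
  sel <- which(tissue & rowSums(touches) > 0L)
  if (length(sel) == 0L) {
    abort("No tissue elements adjacent to the interface.",
          class = "fbrmech_fem_error")
  }
  sx <- solution$element_stress[sel, 1L]
  max_t <- max(c(sx, 0))
  max_c <- min(c(sx, 0))
  which_t <- sel[which.max(sx)]
  which_c <- sel[which.min(sx)]
  structure(
    list(max_abs_sx = max(abs(c(max_t, max_c))) / 1e3,
         max_tensile_sx = max_t / 1e3,
         max_compressive_sx = max_c / 1e3,
         location_node_ids = sort(unique(as.vector(
           mesh$elems[c(which_t, which_c), ]))),
         n_elements = length(sel)),
    class = "fbr_stress_summary")
}

#' @export
print.fbr_stress_summary <- function(x, ...) {
  cat(sprintf(paste0("<fbr_stress_summary> max |Sx| = %.4g kPa ",
                     "(tensile %.4g, compressive %.4g) over %d tissue elements\n"),
              x$max_abs_sx, x$max_tensile_sx, x$max_compressive_sx,
              x$n_elements))
  invisible(x)
}

#' @export
tidy.fbr_stress_summary <- function(x, ...) {
  tibble(max_abs_sx_kpa = x$max_abs_sx,
         max_tensile_sx_kpa = x$max_tensile_sx,
         max_compressive_sx_kpa = x$max_compressive_sx,
         n_interface_elements = x$n_elements)
}

#' Tidy nodal displacement table
#' @param x An `fbr_solution`.
#' @param ... Unused.
#' @return Tibble of node id, coordinates (mm) and displacement (m).
#' @export
tidy.fbr_solution <- function(x, ...) {
  nodes <- x$problem$mesh$nodes
  tibble(node = seq_len(nrow(nodes)),
         x = nodes[, 1], y = nodes[, 2], z = nodes[, 3],
         ux = x$displacements[, 1],
         uy = x$displacements[, 2],
         uz = x$displacements[, 3])
}

#' @export
glance.fbr_solution <- function(x, ...) {
  tibble(n_nodes = nrow(x$problem$mesh$nodes),
         n_elements = nrow(x$problem$mesh$elems),
         residual = x$residual,
         max_displacement_m = max(sqrt(rowSums(x$displacements^2))))
}

#' Mesh-refinement convergence check on the interface stress
#'
#' Re-solves the preset at a decreasing sequence of edge lengths and reports
#' the maximal absolute interface Sx per resolution together with the
#' successive relative change; converged when that change drops below `tol`.
#'
#' @param spec A validated `fbr_domain` with a load.
#' @param edge_lengths Decreasing vector (>= 2) of edge lengths, mm.
#' @param tol Relative-change tolerance (fraction), default 0.1.
#' @return An `fbr_convergence` tibble: `edge_length`, `n_elements`,
#'   `max_abs_sx` (kPa), `rel_change`, `converged`.
#' @export
mesh_convergence_check <- function(spec, edge_lengths, tol = 0.1) {
  if (length(edge_lengths) < 2L || is.unsorted(rev(edge_lengths))) {
    abort("`edge_lengths` must be a decreasing vector of length >= 2.",
          class = "fbrmech_param_error")
  }
  rows <- purrr::map(edge_lengths, function(h) {
    sm <- solve_domain(spec, edge_length = h)
    tibble(edge_length = h,
           n_elements = nrow(sm$solution$problem$mesh$elems),
           max_abs_sx = sm$summary$max_abs_sx)
  })
  out <- dplyr::bind_rows(rows)
  out$rel_change <- c(NA_real_,
                      abs(diff(out$max_abs_sx)) /
                        pmax(abs(out$max_abs_sx[-nrow(out)]), 1e-300))
  out$converged <- !is.na(out$rel_change) & out$rel_change < tol
  class(out) <- c("fbr_convergence", class(out))
  out
}

#' Mesh, solve and summarize a domain in one call
#'
#' Convenience wrapper: generates the mesh, converts a vibration load to its
#' quasi-static peak using the implant mass (disc + motor), solves, and
#' summarizes the interface stress.
#'
#' @param spec A validated `fbr_domain` (with a load).
#' @param edge_length Mesh edge length, mm; defaults to the preset's.
#' @return List with `mesh`, `solution`, `summary`.
#' @export
solve_domain <- function(spec, edge_length = NULL) {
  edge_length <- edge_length %||% attr(spec, "edge_length")
  if (is.null(edge_length)) {
    abort("No edge length given and none attached to the spec.",
          class = "fbrmech_param_error")
  }
  mesh <- generate_mesh(spec, edge_length)
  load <- spec$load
  if (inherits(load, "fbr_load") && load$kind == "vibration") {
    load <- peak_quasistatic_load(load, spec$derived$implant_mass_kg)
  }
  problem <- elasticity_problem(mesh, load = load)
  solution <- assemble_and_solve(problem)
  list(mesh = mesh, solution = solution,
       summary = interface_stress_summary(solution))
}

#' Undamped harmonic steady-state response (optional dynamic mode)
#'
#' Solves `(K - omega^2 M) u = F` with a lumped (row-sum consistent with
#' nodal volumes) mass matrix, giving the displacement amplitude field of the
#' structure vibrating at `frequency`. At frequency 0 this is the static
#' solution; at a resonance the system is singular and an error is raised.
#'
#' @param problem An [elasticity_problem()] whose materials carry densities.
#' @param frequency Driving frequency, Hz.
#' @return An `fbr_solution` (amplitude field).
#' @export
harmonic_steady_state <- function(problem, frequency) {
  if (frequency < 0) {
    abort("`frequency` must be nonnegative.", class = "fbrmech_param_error")
  }
  if (frequency == 0) return(assemble_and_solve(problem))
  mesh <- problem$mesh
  geom <- mesh_gradients(mesh)
  mats <- element_materials(mesh, problem$material_map)
  K <- assemble_stiffness(mesh, mats, geom)
  nn <- nrow(mesh$nodes)
  # lumped nodal masses: a quarter of each element's mass to each node
  elmass <- abs(geom$volume) * mats$rho / 4
  nodal_mass <- numeric(nn)
  acc <- rowsum(rep(elmass, times = 4L), group = as.vector(mesh$elems))
  nodal_mass[as.integer(rownames(acc))] <- acc[, 1L]
  motor <- mesh$spec$implant$motor_mass %||% 0
  if (motor > 0) {
    imp_nodes <- unique(as.vector(
      mesh$elems[mesh$region == "implant", , drop = FALSE]))
    nodal_mass[imp_nodes] <- nodal_mass[imp_nodes] + motor / length(imp_nodes)
  }
  Mdiag <- rep(nodal_mass, each = 3L)
  f <- build_force_vector(problem, geom)
  fixed_dofs <- as.vector(t(outer(problem$dirichlet, 0:2,
                                  function(n, d) 3L * (n - 1L) + d + 1L)))
  free <- setdiff(seq_len(3L * nn), fixed_dofs)
  omega <- 2 * pi * frequency
  A <- K[free, free, drop = FALSE] -
    omega^2 * Matrix::Diagonal(x = Mdiag[free])
  u <- numeric(3L * nn)
  sol <- tryCatch(Matrix::solve(A, f[free]),
                  error = function(e) abort(
                    sprintf("Harmonic system singular near %.4g Hz (resonance).",
                            frequency),
                    class = "fbrmech_fem_error"))
  u[free] <- as.numeric(sol)
  out <- structure(
    list(problem = problem,
         displacements = matrix(u, ncol = 3L, byrow = TRUE),
         element_stress = NULL,
         residual = NA_real_,
         frequency = frequency),
    class = "fbr_solution")
  out$element_stress <- recover_stress(out)
  out
}
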