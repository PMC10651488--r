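# Structured hexahedral grid conforming to layer interfaces (and the implant's
# vertical extent), with each hexahedron split into 6 tetrahedra around the
# main corner diagonal. The same split pattern in every cell makes shared quad
# faces conform (both sides cut along the matching diagonal).

# local corner offsets of a unit hexahedron, VTK ordering
.hex_corners <- matrix(c(
  0, 0, 0,  1, 0, 0,  1, 1, 0,  0, 1, 0,
  0, 0, 1,  1, 0, 1,  1, 1, 1,  0, 1, 1), ncol = 3, byrow = TRUE)

# 6-tet decomposition around diagonal v1-v7 (1-based corner ids)
.hex_tets <- matrix(c(
  1, 2, 3, 7,
  1, 3, 4, 7,
  1, 4, 8, 7,
  1, 8, 5, 7,
  1, 5, 6, 7,
  1, 6, 2, 7), ncol = 4, byrow = TRUE)

# breaks for one axis segment: cut [lo, hi] into ceil(len/edge) even pieces
segment_breaks <- function(lo, hi, edge) {
  n <- max(1L, ceiling((hi - lo) / edge - 1e-9))
  seq(lo, hi, length.out = n + 1L)
}

#' Generate a labeled tetrahedral mesh of a layered implant domain
#'
#' Lays a structured grid over the block: x/y subdivided evenly at (at most)
#' the target edge length, z subdivided within each layer (and, inside the
#' host layer, conforming to the implant's top and bottom faces). Every
#' hexahedral cell is split into 6 positively oriented tetrahedra with a fixed
#' diagonal pattern, so the mesh is deterministic and conforming. Cells whose
#' centers fall inside the disc (center radius and vertical extent) are
#' labeled `"implant"`; all others carry their layer name. The disc's curved
#' boundary is therefore voxel-approximated; its geometric error shrinks with
#' the edge length (region volumes converge to the analytic disc volume).
#'
#' @param spec A validated `fbr_domain` (see [build_layered_domain()]).
#' @param target_edge_length Target element edge length in mm; must be
#'   positive and no larger than the thinnest layer.
#' @return An `fbr_mesh`: node coordinates (mm), 4-column tetrahedron
#'   connectivity, per-element `region` labels, and `node_sets`
#'   (`bottom_fixed`, `interface`, `implant_interior`), each sorted ascending.
#' @examples
#' d <- preset_domains("mouse_standard")
#' m <- generate_mesh(d, target_edge_length = 3)
#' table(m$region)
#' @export
generate_mesh <- function(spec, target_edge_length) {
  if (!inherits(spec, "fbr_domain") || is.null(spec$derived)) {
    spec <- build_layered_domain(spec)
  }
  if (!is.numeric(target_edge_length) || length(target_edge_length) != 1L ||
      target_edge_length <= 0) {
    abort("`target_edge_length` must be a positive length in mm.",
          class = "fbrmech_param_error")
  }
  lz <- spec$derived$layer_z
  thinnest <- which.min(lz$thickness)
  if (target_edge_length > lz$thickness[thinnest] + 1e-9) {
    abort(sprintf(
      "Edge length %.3g mm too coarse to resolve layer '%s' (%.3g mm thick).",
      target_edge_length, lz$name[thinnest], lz$thickness[thinnest]),
      class = "fbrmech_mesh_error")
  }
  L <- spec$lateral_extent
  xb <- segment_breaks(-L / 2, L / 2, target_edge_length)
  yb <- xb
  # z breaks: per layer, conforming to implant top/bottom inside the host layer
  zb <- 0
  zcell_layer <- character()
  box <- spec$derived$implant_box
  for (i in seq_len(nrow(lz))) {
    cuts <- c(lz$z_bottom[i], lz$z_top[i])
    if (!is.null(box) && identical(lz$name[i], spec$implant_layer)) {
      cuts <- sort(unique(c(cuts, box$z_bottom, box$z_top)))
    }
    for (s in seq_len(length(cuts) - 1L)) {
      seg <- segment_breaks(cuts[s], cuts[s + 1L], target_edge_length)
      zb <- c(zb, seg[-1L])
      zcell_layer <- c(zcell_layer, rep(lz$name[i], length(seg) - 1L))
    }
  }
  nx <- length(xb); ny <- length(yb); nz <- length(zb)
  nodes <- cbind(rep(xb, times = ny * nz),
                 rep(rep(yb, each = nx), times = nz),
                 rep(zb, each = nx * ny))
  idx <- function(i, j, k) i + nx * (j - 1L) + nx * ny * (k - 1L)
  # hex cell corner indices, vectorized over all cells
  ci <- rep(seq_len(nx - 1L), times = (ny - 1L) * (nz - 1L))
  cj <- rep(rep(seq_len(ny - 1L), each = nx - 1L), times = nz - 1L)
  ck <- rep(seq_len(nz - 1L), each = (nx - 1L) * (ny - 1L))
  corner <- matrix(0L, nrow = length(ci), ncol = 8L)
  for (c8 in 1:8) {
    off <- .hex_corners[c8, ]
    corner[, c8] <- idx(ci + off[1], cj + off[2], ck + off[3])
  }
  # region by cell center
  cx <- (xb[ci] + xb[ci + 1L]) / 2
  cy <- (yb[cj] + yb[cj + 1L]) / 2
  cz <- (zb[ck] + zb[ck + 1L]) / 2
  region_hex <- zcell_layer[ck]
  if (!is.null(box)) {
    inside <- (cx^2 + cy^2 <= box$radius^2) &
      (cz > box$z_bottom) & (cz < box$z_top)
    region_hex[inside] <- "implant"
  }
  n_hex <- length(ci)
  elems <- matrix(0L, nrow = 6L * n_hex, ncol = 4L)
  for (t in 1:6) {
    rows <- seq.int(t, by = 6L, length.out = n_hex)
    elems[rows, ] <- corner[, .hex_tets[t, ], drop = FALSE]
  }
  region <- rep(region_hex, each = 6L)
  # enforce positive orientation (swap last two nodes where volume < 0)
  v <- tet_volumes(nodes, elems)
  neg <- which(v < 0)
  if (length(neg)) {
    tmp <- elems[neg, 3L]
    elems[neg, 3L] <- elems[neg, 4L]
    elems[neg, 4L] <- tmp
  }
  mesh <- structure(
    list(nodes = nodes, elems = elems, region = region,
         node_sets = NULL, spec = spec,
         edge_length = target_edge_length),
    class = "fbr_mesh"
  )
  mesh$node_sets <- extract_node_sets(mesh)
  mesh
}

#' Signed tetrahedron volumes
#'
#' @param nodes n x 3 coordinate matrix.
#' @param elems m x 4 connectivity matrix.
#' @return Numeric vector of signed volumes (same length unit cubed as
#'   `nodes`).
#' @export
tet_volumes <- function(nodes, elems) {
  a <- nodes[elems[, 2L], , drop = FALSE] - nodes[elems[, 1L], , drop = FALSE]
  b <- nodes[elems[, 3L], , drop = FALSE] - nodes[elems[, 1L], , drop = FALSE]
  cc <- nodes[elems[, 4L], , drop = FALSE] - nodes[elems[, 1L], , drop = FALSE]
  cx <- b[, 2L] * cc[, 3L] - b[, 3L] * cc[, 2L]
  cy <- b[, 3L] * cc[, 1L] - b[, 1L] * cc[, 3L]
  cz <- b[, 1L] * cc[, 2L] - b[, 2L] * cc[, 1L]
  (a[, 1L] * cx + a[, 2L] * cy + a[, 3L] * cz) / 6
}

#' Extract the named boundary/interface node sets of a mesh
#'
#' `bottom_fixed` is every node at the minimal z coordinate (the fixed support
#' at the bottom of the muscle/bone layer); `interface` is every node shared by
#' an implant-labeled and a tissue-labeled element (empty when no implant);
#' `implant_interior` is every node used only by implant elements. All sets
#' are ascending integer vectors and depend on geometry/labels only.
#'
#' @param mesh An `fbr_mesh`.
#' @return Named list of sorted node index vectors.
#' @export
extract_node_sets <- function(mesh) {
  zmin <- min(mesh$nodes[, 3L])
  tol <- 1e-9 * max(1, diff(range(mesh$nodes[, 3L])))
  bottom <- which(mesh$nodes[, 3L] <= zmin + tol)
  imp <- mesh$region == "implant"
  imp_nodes <- sort(unique(as.vector(mesh$elems[imp, , drop = FALSE])))
  tis_nodes <- sort(unique(as.vector(mesh$elems[!imp, , drop = FALSE])))
  interface <- intersect(imp_nodes, tis_nodes)
  list(bottom_fixed = sort(bottom),
       interface = sort(interface),
       implant_interior = sort(setdiff(imp_nodes, tis_nodes)))
}

#' Per-region mesh volumes
#'
#' @param mesh An `fbr_mesh`.
#' @return Tibble with `region` and `volume` (mm^3).
#' @export
mesh_region_volumes <- function(mesh) {
  v <- tet_volumes(mesh$nodes, mesh$elems)
  out <- aggregate(v, by = list(region = mesh$region), FUN = sum)
  tibble(region = out$region, volume = out$x)
}

#' @export
print.fbr_mesh <- function(x, ...) {
  cat(sprintf("<fbr_mesh> %d nodes, %d tetrahedra (edge %.3g mm)\n",
              nrow(x$nodes), nrow(x$elems), x$edge_length))
  tb <- table(x$region)
  cat("  regions:", paste(sprintf("%s (%d)", names(tb), tb), collapse = ", "), "\n")
  cat(sprintf("  node sets: bottom_fixed %d, interface %d, implant_interior %d\n",
              length(x$node_sets$bottom_fixed), length(x$node_sets$interface),
              length(x$node_sets$implant_interior)))
  invisible(x)
}

#' Tidy node table of a mesh
#' @param x An `fbr_mesh`.
#' @param ... Unused.
#' @return Tibble of node id, coordinates and set membership flags.
#' @export
tidy.fbr_mesh <- function(x, ...) {
  tibble(node = seq_len(nrow(x$nodes)),
         x = x$nodes[, 1L], y = x$nodes[, 2L], z = x$nodes[, 3L],
         bottom_fixed = seq_len(nrow(x$nodes)) %in% x$node_sets$bottom_fixed,
         interface = seq_len(nrow(x$nodes)) %in% x$node_sets$interface)
}
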