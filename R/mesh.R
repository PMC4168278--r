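# Structured tetrahedral meshing: an axis-aligned box is divided into a
# regular hexahedral grid and every cell is split into six tetrahedra by the
# Kuhn (Freudenthal) subdivision along the cell's main diagonal. The
# subdivision is conforming across cells, every tet has volume hx*hy*hz/6,
# and point location reduces to integer arithmetic plus a coordinate sort.

# Axis orderings of the six Kuhn tets, one row per tet: row (p1,p2,p3) holds
# the points whose cell-local fractional coordinates satisfy
# f[p1] >= f[p2] >= f[p3]. Row order is load-bearing: element ids, point
# location and interpolation all index into it.
.kuhn_perms <- rbind(
  c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
  c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)
)
# parity of each permutation (+1 even, -1 odd); odd tets are stored with the
# last two vertices swapped so all signed volumes are positive
.kuhn_parity <- c(1L, -1L, -1L, 1L, 1L, -1L)

#' Build a structured tetrahedral box mesh
#'
#' Meshes the box `[0, extent[1]] x [0, extent[2]] x [0, extent[3]]` (mm)
#' with a regular grid of hexahedral cells, each split into 6 tetrahedra.
#' The number of cells per axis is `round(extent / h)` (at least 1), so the
#' realized spacing can differ slightly from `h` when it does not divide the
#' extent. Boundary triangles are tagged `"top"` (z = extent_z), `"bottom"`
#' (z = 0) and `"side"` (the four lateral faces).
#'
#' @param extent numeric length-3, box dimensions in mm.
#' @param h target edge length in mm (scalar or length-3).
#' @param region single region label applied to every element
#'   (default `"WM"`); [build_slab_mesh()] relabels by tissue.
#' @param coords optional list of three strictly increasing node-coordinate
#'   vectors (mm, starting at 0), giving a rectilinear grid; overrides
#'   `extent`/`h`. Used e.g. for nested refinement along one axis.
#' @return A `labeled_tet_mesh`; see [build_slab_mesh()] for the fields.
#' @export
build_box_mesh <- function(extent, h, region = "WM", coords = NULL) {
  if (is.null(coords)) {
    stopifnot(length(extent) == 3, all(extent > 0), all(h > 0))
    h <- rep_len(as.numeric(h), 3L)
    n <- pmax(1L, as.integer(round(extent / h)))
    coords <- lapply(1:3, function(ax)
      seq(0, extent[ax], length.out = n[ax] + 1L))
  } else {
    stopifnot(length(coords) == 3,
              all(vapply(coords, function(g)
                length(g) >= 2 && g[1] == 0 && all(diff(g) > 0), TRUE)))
    extent <- vapply(coords, function(g) g[length(g)], 0)
    n <- vapply(coords, length, 0L) - 1L
  }
  hreal <- extent / n
  nx <- n[1]; ny <- n[2]; nz <- n[3]
  npx <- nx + 1L; npy <- ny + 1L; npz <- nz + 1L

  gx <- coords[[1]]
  gy <- coords[[2]]
  gz <- coords[[3]]
  nodes <- cbind(
    x = rep(gx, times = npy * npz),
    y = rep(rep(gy, each = npx), times = npz),
    z = rep(gz, each = npx * npy)
  )

  # corner node of every cell (i fastest, then j, then k)
  ii <- rep(seq_len(nx), times = ny * nz)
  jj <- rep(rep(seq_len(ny), each = nx), times = nz)
  kk <- rep(seq_len(nz), each = nx * ny)
  corner <- ii + (jj - 1L) * npx + (kk - 1L) * npx * npy
  step <- c(1L, npx, npx * npy)             # node-index offset per +1 along axis

  ncell <- nx * ny * nz
  tets <- matrix(0L, nrow = 6L * ncell, ncol = 4L)
  for (p in 1:6) {
    ax <- .kuhn_perms[p, ]
    v0 <- corner
    v1 <- v0 + step[ax[1]]
    v2 <- v1 + step[ax[2]]
    v3 <- v2 + step[ax[3]]
    rows <- seq.int(p, by = 6L, length.out = ncell)
    if (.kuhn_parity[p] > 0L) {
      tets[rows, ] <- cbind(v0, v1, v2, v3)
    } else {
      tets[rows, ] <- cbind(v0, v1, v3, v2)
    }
  }
  # strided writes above lay rows out as (cell1 perm1..6, cell2 perm1..6, ...),
  # so element id = (cell - 1) * 6 + perm
  mesh <- structure(list(
    nodes = nodes,
    tets = tets,
    region = factor(rep(region, 6L * ncell), levels = unique(region)),
    boundary = .box_boundary(nx, ny, nz, npx, npy),
    grid = list(origin = c(0, 0, 0), h = hreal, n = n, extent = extent,
                coords = list(gx, gy, gz),
                hmin = min(vapply(coords, function(g) min(diff(g)), 0)))
  ), class = "labeled_tet_mesh")
  mesh
}

# boundary triangulation of the structured box, consistent with the Kuhn
# face diagonals (each quad face is split by the diagonal from its minimal
# to its maximal corner)
.box_boundary <- function(nx, ny, nz, npx, npy) {
  nid <- function(i, j, k) i + (j - 1L) * npx + (k - 1L) * npx * npy
  quads <- function(c00, c10, c01, c11) {
    # split each quad along its (0,0)-(1,1) diagonal, matching the Kuhn faces
    rbind(cbind(c00, c10, c11), cbind(c00, c11, c01))
  }
  i <- rep(seq_len(nx), times = ny); j <- rep(seq_len(ny), each = nx)
  bot <- quads(nid(i, j, 1L), nid(i + 1L, j, 1L),
               nid(i, j + 1L, 1L), nid(i + 1L, j + 1L, 1L))
  top <- quads(nid(i, j, nz + 1L), nid(i + 1L, j, nz + 1L),
               nid(i, j + 1L, nz + 1L), nid(i + 1L, j + 1L, nz + 1L))
  j2 <- rep(seq_len(ny), times = nz); k2 <- rep(seq_len(nz), each = ny)
  sx0 <- quads(nid(1L, j2, k2), nid(1L, j2 + 1L, k2),
               nid(1L, j2, k2 + 1L), nid(1L, j2 + 1L, k2 + 1L))
  sx1 <- quads(nid(npx, j2, k2), nid(npx, j2 + 1L, k2),
               nid(npx, j2, k2 + 1L), nid(npx, j2 + 1L, k2 + 1L))
  i3 <- rep(seq_len(nx), times = nz); k3 <- rep(seq_len(nz), each = nx)
  sy0 <- quads(nid(i3, 1L, k3), nid(i3 + 1L, 1L, k3),
               nid(i3, 1L, k3 + 1L), nid(i3 + 1L, 1L, k3 + 1L))
  sy1 <- quads(nid(i3, npy, k3), nid(i3 + 1L, npy, k3),
               nid(i3, npy, k3 + 1L), nid(i3 + 1L, npy, k3 + 1L))
  facets <- rbind(bot, top, sx0, sx1, sy0, sy1)
  tag <- c(rep("bottom", nrow(bot)), rep("top", nrow(top)),
           rep("side", nrow(sx0) + nrow(sx1) + nrow(sy0) + nrow(sy1)))
  list(facets = facets, tag = tag)
}

#' @export
print.labeled_tet_mesh <- function(x, ...) {
  cat("labeled_tet_mesh:", nrow(x$nodes), "nodes,", nrow(x$tets), "tets\n")
  cat("  grid:", paste(x$grid$n, collapse = " x "), "cells, h =",
      paste(signif(x$grid$h, 4), collapse = "/"), "mm\n")
  cat("  regions:", paste(sprintf("%s=%d", levels(x$region),
                                  tabulate(x$region, nbins = nlevels(x$region))),
                          collapse = ", "), "\n")
  cat("  boundary tags:", paste(unique(x$boundary$tag), collapse = ", "), "\n")
  invisible(x)
}

#' Signed volumes of all tetrahedra (mm^3)
#'
#' @param mesh a `labeled_tet_mesh`.
#' @return numeric vector, one signed volume per element.
#' @export
tet_volumes <- function(mesh) {
  nd <- mesh$nodes; tt <- mesh$tets
  p1 <- nd[tt[, 1], , drop = FALSE]
  u <- nd[tt[, 2], , drop = FALSE] - p1
  v <- nd[tt[, 3], , drop = FALSE] - p1
  w <- nd[tt[, 4], , drop = FALSE] - p1
  (u[, 1] * (v[, 2] * w[, 3] - v[, 3] * w[, 2]) -
   u[, 2] * (v[, 1] * w[, 3] - v[, 3] * w[, 1]) +
   u[, 3] * (v[, 1] * w[, 2] - v[, 2] * w[, 1])) / 6
}

#' Element centroids (mm)
#' @param mesh a `labeled_tet_mesh`.
#' @return numeric matrix, elements x 3.
#' @export
tet_centroids <- function(mesh) {
  nd <- mesh$nodes; tt <- mesh$tets
  (nd[tt[, 1], , drop = FALSE] + nd[tt[, 2], , drop = FALSE] +
   nd[tt[, 3], , drop = FALSE] + nd[tt[, 4], , drop = FALSE]) / 4
}

# cell-local fractional x/z offsets of the 6 tet centroids; used to label
# extruded geometry on the unique (x, z, perm) set instead of per element
.kuhn_centroid_offsets <- function() {
  off <- matrix(0, 6, 3)
  for (p in 1:6) {
    ax <- .kuhn_perms[p, ]
    e <- diag(3)
    off[p, ] <- (3 * e[ax[1], ] + 2 * e[ax[2], ] + e[ax[3], ]) / 4
  }
  off
}

#' Locate points in a structured tet mesh
#'
#' Maps arbitrary points to the element containing them together with the
#' P1 interpolation stencil (4 node ids and barycentric weights). Points are
#' clamped to the closed box, so queries on the boundary are valid.
#'
#' @param mesh a structured `labeled_tet_mesh`.
#' @param pts numeric matrix, points x 3, in mm.
#' @return list with `element` (integer vector), `nodes` (points x 4 node
#'   ids) and `weights` (points x 4 barycentric weights).
#' @export
locate_points <- function(mesh, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  g <- mesh$grid
  n <- g$n
  npx <- n[1] + 1L; npy <- n[2] + 1L
  cell <- matrix(0L, nrow(pts), 3)
  fr <- matrix(0, nrow(pts), 3)
  for (ax in 1:3) {
    gax <- g$coords[[ax]]
    i <- pmin(pmax(findInterval(pts[, ax], gax), 1L), n[ax])
    cell[, ax] <- i - 1L
    fr[, ax] <- pmin(pmax((pts[, ax] - gax[i]) / (gax[i + 1L] - gax[i]), 0), 1)
  }

  fx <- fr[, 1]; fy <- fr[, 2]; fz <- fr[, 3]
  # rank the fractional coordinates (descending); ties resolved toward the
  # lower permutation index, consistent with >= in the containment rule
  ge_xy <- fx >= fy; ge_yz <- fy >= fz; ge_xz <- fx >= fz
  perm <- integer(nrow(fr))
  perm[ge_xy & ge_yz] <- 1L                       # x >= y >= z
  perm[ge_xz & !ge_yz & ge_xy] <- 2L              # x >= z >  y
  perm[!ge_xy & ge_yz & ge_xz] <- 3L              # y >  x >= z
  perm[!ge_xy & ge_yz & !ge_xz] <- 4L             # y >= z >  x  (y>x, z>x)
  perm[!ge_xz & ge_xy] <- 5L                      # z >  x >= y
  perm[!ge_xz & !ge_xy & !ge_yz] <- 6L            # z >  y >  x
  # fill any unset (degenerate tie patterns) by direct ordering
  if (any(perm == 0L)) {
    idx <- which(perm == 0L)
    for (q in idx) {
      o <- order(fr[q, ], decreasing = TRUE)
      perm[q] <- which(apply(.kuhn_perms, 1, identical, y = as.integer(o)))[1]
    }
  }

  ax1 <- .kuhn_perms[perm, 1]; ax2 <- .kuhn_perms[perm, 2]; ax3 <- .kuhn_perms[perm, 3]
  m <- nrow(fr)
  pick <- function(ax) fr[cbind(seq_len(m), ax)]
  s1 <- pick(ax1); s2 <- pick(ax2); s3 <- pick(ax3)
  weights <- cbind(1 - s1, s1 - s2, s2 - s3, s3)

  step <- c(1L, npx, npx * npy)
  v0 <- (cell[, 1] + 1L) + cell[, 2] * npx + cell[, 3] * npx * npy
  v1 <- v0 + step[ax1]; v2 <- v1 + step[ax2]; v3 <- v2 + step[ax3]
  cellid <- cell[, 1] + cell[, 2] * n[1] + cell[, 3] * n[1] * n[2]
  list(element = cellid * 6L + perm,
       nodes = cbind(v0, v1, v2, v3),
       weights = weights)
}

#' Interpolate a nodal field at arbitrary points
#'
#' Evaluates the piecewise-linear finite-element interpolant of nodal values
#' at the given points (used e.g. to compare solutions across refinement
#' levels).
#'
#' @param mesh a structured `labeled_tet_mesh`.
#' @param values numeric vector of nodal values.
#' @param pts numeric matrix, points x 3, mm.
#' @return numeric vector of interpolated values.
#' @export
interpolate_nodal <- function(mesh, values, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  out <- numeric(nrow(pts))
  # chunked to bound the transient memory of the location stencils
  for (s in seq(1L, nrow(pts), by = 1000000L)) {
    sel <- s:min(s + 999999L, nrow(pts))
    loc <- locate_points(mesh, pts[sel, , drop = FALSE])
    out[sel] <- rowSums(matrix(values[loc$nodes], ncol = 4) * loc$weights)
  }
  out
}

# owning tet of each listed boundary facet, found by nudging the facet
# centroid into the domain along the inward normal of its tagged box face
.boundary_owner <- function(mesh, facet_ids) {
  b <- mesh$boundary
  nd <- mesh$nodes
  f <- b$facets[facet_ids, , drop = FALSE]
  cen <- (nd[f[, 1], , drop = FALSE] + nd[f[, 2], , drop = FALSE] +
          nd[f[, 3], , drop = FALSE]) / 3
  ext <- mesh$grid$extent
  eps <- mesh$grid$hmin * 1e-3
  inward <- matrix(0, nrow(cen), 3)
  tag <- b$tag[facet_ids]
  inward[tag == "bottom", 3] <- eps
  inward[tag == "top", 3] <- -eps
  side <- which(!(tag %in% c("top", "bottom")))
  if (length(side)) {
    cs <- cen[side, , drop = FALSE]
    dx <- ifelse(cs[, 1] < eps, eps, ifelse(cs[, 1] > ext[1] - eps, -eps, 0))
    dy <- ifelse(cs[, 2] < eps, eps, ifelse(cs[, 2] > ext[2] - eps, -eps, 0))
    inward[side, 1] <- dx; inward[side, 2] <- dy
  }
  locate_points(mesh, cen + inward)$element
}

# areas (mm^2) of the listed boundary facets
.facet_areas <- function(mesh, facet_ids) {
  f <- mesh$boundary$facets[facet_ids, , drop = FALSE]
  nd <- mesh$nodes
  u <- nd[f[, 2], , drop = FALSE] - nd[f[, 1], , drop = FALSE]
  v <- nd[f[, 3], , drop = FALSE] - nd[f[, 1], , drop = FALSE]
  cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  sqrt(cx^2 + cy^2 + cz^2) / 2
}

# outward unit normals of the listed boundary facets (axis-aligned box faces)
.facet_outward_normals <- function(mesh, facet_ids) {
  nd <- mesh$nodes
  f <- mesh$boundary$facets[facet_ids, , drop = FALSE]
  cen <- (nd[f[, 1], , drop = FALSE] + nd[f[, 2], , drop = FALSE] +
          nd[f[, 3], , drop = FALSE]) / 3
  ext <- mesh$grid$extent
  eps <- mesh$grid$hmin * 1e-6
  nrm <- matrix(0, nrow(cen), 3)
  nrm[abs(cen[, 3]) < eps, 3] <- -1
  nrm[abs(cen[, 3] - ext[3]) < eps, 3] <- 1
  nrm[abs(cen[, 1]) < eps, 1] <- -1
  nrm[abs(cen[, 1] - ext[1]) < eps, 1] <- 1
  nrm[abs(cen[, 2]) < eps, 2] <- -1
  nrm[abs(cen[, 2] - ext[2]) < eps, 2] <- 1
  nrm
}

#' Nested depth-axis refinement of a structured mesh
#'
#' Splits the selected z-layers of the rectilinear grid in two, producing a
#' mesh whose cells nest exactly inside the parent's: every tissue label is
#' inherited from the parent element containing the new element, so the
#' refined mesh discretizes exactly the same piecewise-constant material
#' model, and the top-surface triangulation (hence any electrode patch) is
#' unchanged. With a fraction `f` of layers split, the element count grows
#' by the factor `1 + f`.
#'
#' @param mesh a structured `labeled_tet_mesh`.
#' @param layers integer indices of z-layers to split (1 = bottom); default
#'   splits the topmost two thirds of the layers, growing the element count
#'   by about 1.67x.
#' @return the refined `labeled_tet_mesh` (keeps `mesh$spec` if present).
#' @export
refine_mesh_z <- function(mesh, layers = NULL) {
  g <- mesh$grid
  nz <- g$n[3]
  if (is.null(layers)) layers <- seq.int(nz - floor(2 * nz / 3) + 1L, nz)
  stopifnot(all(layers >= 1), all(layers <= nz))
  gz <- g$coords[[3]]
  mids <- (gz[layers] + gz[layers + 1L]) / 2
  gz2 <- sort(c(gz, mids))
  fine <- build_box_mesh(coords = list(g$coords[[1]], g$coords[[2]], gz2))
  cen <- tet_centroids(fine)
  lab <- integer(nrow(cen))
  for (s in seq(1L, nrow(cen), by = 1000000L)) {
    sel <- s:min(s + 999999L, nrow(cen))
    parent <- locate_points(mesh, cen[sel, , drop = FALSE])$element
    lab[sel] <- as.integer(mesh$region[parent])
  }
  fine$region <- factor(levels(mesh$region)[lab],
                        levels = levels(mesh$region))
  fine$spec <- mesh$spec
  fine
}
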