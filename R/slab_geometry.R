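# Parametric extruded-slab model of the precentral gyrus region: a box with
# a CSF layer on top, a gray-matter sheet of constant thickness draped over
# a cosine-walled gyrus/sulcus profile (extruded along y), and white matter
# underneath. All lengths in mm.

#' Specification of the gyral slab geometry
#'
#' Defaults describe a desk-scale volume around a human precentral gyrus:
#' 60 x 60 x 40 mm extent, 12 mm gyral crowns separated by 3 mm sulci of
#' 15 mm depth, a 2.5 mm cortical sheet and 2 mm of CSF between cortex and
#' the (subdural) top surface where electrodes sit.
#'
#' @param extent_x,extent_y,extent_z slab dimensions, mm. The gyral folds
#'   run along y (the extrusion axis); z is up, the top surface lies at
#'   `z = extent_z`.
#' @param gyral_width width of a gyral crown, mm.
#' @param sulcal_width width of the sulcal groove, mm.
#' @param sulcal_depth depth of the sulcal fold below the crown surface, mm.
#' @param gm_thickness cortical (gray-matter) sheet thickness, mm.
#' @param csf_thickness CSF layer between cortical crown and top surface, mm.
#' @param resolution_h target mesh edge length, mm; must not exceed
#'   `gm_thickness` so the cortical sheet is resolved.
#' @return object of class `slab_spec`.
#' @export
slab_spec <- function(extent_x = 60, extent_y = 60, extent_z = 40,
                      gyral_width = 12, sulcal_width = 3, sulcal_depth = 15,
                      gm_thickness = 2.5, csf_thickness = 2,
                      resolution_h = 0.8) {
  spec <- list(extent_x = extent_x, extent_y = extent_y, extent_z = extent_z,
               gyral_width = gyral_width, sulcal_width = sulcal_width,
               sulcal_depth = sulcal_depth, gm_thickness = gm_thickness,
               csf_thickness = csf_thickness, resolution_h = resolution_h)
  vals <- unlist(spec)
  if (!all(is.finite(vals)) || any(vals <= 0))
    stop("all slab_spec fields must be strictly positive", call. = FALSE)
  if (gm_thickness >= sulcal_depth)
    stop("gm_thickness must be smaller than sulcal_depth", call. = FALSE)
  if (sulcal_depth + csf_thickness >= extent_z)
    stop("sulcal_depth + csf_thickness must be smaller than extent_z",
         call. = FALSE)
  if (resolution_h > gm_thickness)
    stop("resolution_h exceeds gm_thickness: the gray-matter sheet would ",
         "not be resolved by at least one element layer", call. = FALSE)
  structure(spec, class = "slab_spec")
}

#' @export
print.slab_spec <- function(x, ...) {
  cat("slab_spec (mm):\n")
  for (nm in names(x)) cat(sprintf("  %-13s %g\n", nm, x[[nm]]))
  invisible(x)
}

# sulcal depression depth d(x) >= 0 of the cortical surface below the crown
# level: periodic with period gyral_width + sulcal_width, gyrus centered at
# x = extent_x / 2, cosine^2 walls across the sulcal groove (C1 smooth)
.sulcal_depth_profile <- function(x, spec) {
  P <- spec$gyral_width + spec$sulcal_width
  u <- (x - spec$extent_x / 2) %% P
  u <- pmin(u, P - u)                    # distance to nearest gyral center, in [0, P/2]
  w <- spec$sulcal_width
  d <- numeric(length(x))
  inside <- u > (P / 2 - w / 2)
  d[inside] <- spec$sulcal_depth * cos(pi * (u[inside] - P / 2) / w)^2
  d
}

# cortical surface height z_c(x) (CSF/GM interface)
.cortical_surface <- function(x, spec) {
  spec$extent_z - spec$csf_thickness - .sulcal_depth_profile(x, spec)
}

# classify (x, z) points of the extruded section: CSF above the cortical
# surface, GM within gm_thickness (2-D Euclidean distance in the x-z plane)
# of the surface curve, WM below. Vectorized; exact windowed distance search
# (a point within gm_thickness of the curve has its nearest curve sample
# within gm_thickness horizontally).
.classify_xz <- function(x, z, spec, ds = 0.02) {
  zc <- .cortical_surface(x, spec)
  lab <- rep.int(3L, length(x))                  # 3 = WM
  lab[z > zc] <- 1L                              # 1 = CSF
  below <- which(lab == 3L)
  if (length(below)) {
    xs <- seq(0, spec$extent_x, by = ds)
    zs <- .cortical_surface(xs, spec)
    win <- ceiling((spec$gm_thickness + ds) / ds)
    ctr <- pmin(pmax(round(x[below] / ds) + 1L, 1L), length(xs))
    gm2 <- spec$gm_thickness^2
    # chunked windowed nearest-distance search along the curve
    chunk <- max(1L, floor(4e6 / (2L * win + 1L)))
    for (s in seq(1L, length(below), by = chunk)) {
      sel <- s:min(s + chunk - 1L, length(below))
      idx <- outer(ctr[sel], (-win):win, "+")
      idx[idx < 1L] <- 1L
      idx[idx > length(xs)] <- length(xs)
      dx <- matrix(xs[idx], nrow = length(sel)) - x[below[sel]]
      dz <- matrix(zs[idx], nrow = length(sel)) - z[below[sel]]
      d2 <- dx * dx + dz * dz
      mind2 <- do.call(pmin, as.data.frame(d2))
      lab[below[sel][mind2 <= gm2]] <- 2L        # 2 = GM
    }
  }
  lab
}

# reference cross-section areas (mm^2) of CSF/GM/WM in the x-z plane by fine
# quadrature of the same classifier; multiplied by extent_y this gives the
# region volumes the mesh labeling converges to
.slab_section_areas <- function(spec, ds = 0.02) {
  xs <- seq(ds / 2, spec$extent_x - ds / 2, by = ds)
  zs <- seq(ds / 2, spec$extent_z - ds / 2, by = ds)
  counts <- c(0, 0, 0)
  for (zb in split(zs, ceiling(seq_along(zs) / 50))) {
    x <- rep(xs, times = length(zb))
    z <- rep(zb, each = length(xs))
    lab <- .classify_xz(x, z, spec, ds = ds)
    counts <- counts + tabulate(lab, 3L)
  }
  stats::setNames(counts * ds * ds, c("CSF", "GM", "WM"))
}

#' Build the labeled slab mesh
#'
#' Meshes the slab with a structured grid at `spec$resolution_h` (six
#' tetrahedra per hexahedral cell) and labels every element CSF, GM or WM by
#' its centroid: CSF above the cortical surface, GM within `gm_thickness`
#' (Euclidean distance in the fold cross-section) of the surface, WM below.
#' Boundary triangles carry tags `top`, `bottom` and `side`.
#'
#' @param spec a [slab_spec()].
#' @return object of class `labeled_tet_mesh` with fields `nodes` (mm),
#'   `tets` (node indices, positively oriented), `region` (factor CSF/GM/WM
#'   per element), `boundary` (`facets`, `tag`) and `grid` (structured-grid
#'   metadata). The generating `spec` is attached as `mesh$spec`.
#' @export
build_slab_mesh <- function(spec) {
  stopifnot(inherits(spec, "slab_spec"))
  ext <- c(spec$extent_x, spec$extent_y, spec$extent_z)
  mesh <- build_box_mesh(ext, spec$resolution_h)
  n <- mesh$grid$n
  gx <- mesh$grid$coords[[1]]; gz <- mesh$grid$coords[[3]]

  # centroid (x, z) coordinates depend only on (i, k, perm): classify that
  # unique set and replicate along the extrusion axis y
  off <- .kuhn_centroid_offsets()
  i <- rep(seq_len(n[1]), times = n[3] * 6L)
  k <- rep(rep(seq_len(n[3]), each = n[1]), times = 6L)
  p <- rep(1:6, each = n[1] * n[3])
  xu <- gx[i] + off[p, 1] * (gx[i + 1L] - gx[i])
  zu <- gz[k] + off[p, 3] * (gz[k + 1L] - gz[k])
  labu <- .classify_xz(xu, zu, spec)
  # unique-set index is [i, k, p]; element id e -> cell (i,j,k), perm p
  lab_ikp <- array(labu, dim = c(n[1], n[3], 6L))
  ncell <- prod(n)
  e <- seq_len(6L * ncell)
  cell <- (e - 1L) %/% 6L
  pe <- (e - 1L) %% 6L + 1L
  ie <- cell %% n[1] + 1L
  ke <- cell %/% (n[1] * n[2]) + 1L
  lab <- lab_ikp[cbind(ie, ke, pe)]

  lev <- c("CSF", "GM", "WM")
  mesh$region <- factor(lev[lab], levels = lev)
  if (any(tabulate(mesh$region, 3L) == 0L))
    stop("slab labeling degenerate: at least one of CSF/GM/WM received no ",
         "elements; refine resolution_h or revisit the geometry parameters",
         call. = FALSE)
  mesh$spec <- spec
  mesh
}

#' Construct the 5-contact paddle layout
#'
#' A quincunx layout: one middle contact surrounded by four corner contacts
#' at `contact_spacing` (center-to-center) from the middle, forming a
#' square rotated by `orientation`. The middle contact is the third center,
#' so `electrode_3` is the contact reused in single-electrode mode.
#'
#' @param center length-2, (x, y) of the middle contact on the top surface, mm.
#' @param contact_spacing middle-to-corner center distance, mm.
#' @param orientation in-plane rotation of the corner square, radians.
#' @param diameter contact diameter used for the overlap check, mm.
#' @return object of class `paddle_layout` with a 5 x 2 `centers` matrix.
#' @export
paddle_layout <- function(center, contact_spacing = 10, orientation = 0,
                          diameter = 4) {
  stopifnot(length(center) == 2, contact_spacing > 0)
  ang <- orientation + pi / 4 + (0:3) * pi / 2
  corners <- cbind(center[1] + contact_spacing * cos(ang),
                   center[2] + contact_spacing * sin(ang))
  centers <- rbind(corners[1:2, , drop = FALSE], center,
                   corners[3:4, , drop = FALSE])
  dmin <- min(stats::dist(centers))
  if (dmin < diameter)
    stop(sprintf("paddle contacts overlap: min center distance %.2f mm < diameter %.2f mm",
                 dmin, diameter), call. = FALSE)
  structure(list(centers = centers, contact_spacing = contact_spacing,
                 orientation = orientation), class = "paddle_layout")
}

# connectivity of a facet set via shared edges (BFS); patches must be single
# connected components
.facets_connected <- function(facets) {
  nf <- nrow(facets)
  if (nf <= 1) return(TRUE)
  edges <- rbind(facets[, c(1, 2)], facets[, c(2, 3)], facets[, c(1, 3)])
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  fid <- rep(seq_len(nf), 3)
  adj <- split(fid, key)
  comp <- integer(nf)
  comp[1] <- 1L
  queue <- 1L
  nbr <- vector("list", nf)
  for (g in adj) if (length(g) > 1) for (f in g) nbr[[f]] <- c(nbr[[f]], setdiff(g, f))
  while (length(queue)) {
    f <- queue[1]; queue <- queue[-1]
    new <- nbr[[f]][comp[nbr[[f]]] == 0L]
    comp[new] <- 1L
    queue <- c(queue, new)
  }
  all(comp == 1L)
}

#' Place a subdural disc electrode on the top surface
#'
#' Selects the top-surface boundary triangles whose centroids fall within
#' the disc. Only the contact face of the electrode is modelled (the disc is
#' a boundary patch, not a metal volume): it becomes an equipotential
#' Dirichlet patch in the solve.
#'
#' @param mesh a `labeled_tet_mesh`.
#' @param center length-2 (x, y) position of the disc center on the top
#'   surface, mm (a z coordinate, if given, is ignored).
#' @param diameter disc diameter, mm (default 4).
#' @param tag tag for the patch (default `"electrode"`).
#' @return object of class `electrode_patch`: `tag`, `center` (3-D point on
#'   the top surface), `normal` (outward), `diameter`, `facet_ids` into
#'   `mesh$boundary`, `node_ids`, and realized `area` in mm^2.
#' @export
place_disc_electrode <- function(mesh, center, diameter = 4,
                                 tag = "electrode") {
  stopifnot(diameter > 0)
  ext <- mesh$grid$extent
  cx <- center[1]; cy <- center[2]
  if (cx < 0 || cx > ext[1] || cy < 0 || cy > ext[2])
    stop("disc center lies outside the top surface", call. = FALSE)
  top <- which(mesh$boundary$tag == "top")
  f <- mesh$boundary$facets[top, , drop = FALSE]
  nd <- mesh$nodes
  cen <- (nd[f[, 1], 1:2, drop = FALSE] + nd[f[, 2], 1:2, drop = FALSE] +
          nd[f[, 3], 1:2, drop = FALSE]) / 3
  inside <- (cen[, 1] - cx)^2 + (cen[, 2] - cy)^2 <= (diameter / 2)^2
  if (!any(inside))
    stop("no top-surface facet centroid falls inside the disc: the mesh ",
         "resolution is too coarse for this electrode diameter/position",
         call. = FALSE)
  fid <- top[inside]
  sel <- mesh$boundary$facets[fid, , drop = FALSE]
  if (!.facets_connected(sel))
    stop("disc patch is not edge-connected at this resolution", call. = FALSE)
  # the equipotential (Dirichlet) node set is the top-surface nodes inside
  # the disc itself, not every vertex of the selected facets: facet vertices
  # outside the rim would grow the effective disc radius by up to one cell
  # and bias the spreading resistance low
  top_nodes <- unique(as.vector(mesh$boundary$facets[top, , drop = FALSE]))
  nc <- mesh$nodes[top_nodes, 1:2, drop = FALSE]
  r2 <- (diameter / 2)^2 * (1 + 1e-12)
  in_disc <- (nc[, 1] - cx)^2 + (nc[, 2] - cy)^2 <= r2
  if (!any(in_disc))
    stop("no top-surface node falls inside the disc: the mesh resolution ",
         "is too coarse for this electrode diameter/position", call. = FALSE)
  structure(list(
    tag = tag,
    center = c(cx, cy, ext[3]),
    normal = c(0, 0, 1),
    diameter = diameter,
    facet_ids = fid,
    node_ids = sort(top_nodes[in_disc]),
    area = sum(.facet_areas(mesh, fid))
  ), class = "electrode_patch")
}

#' @export
print.electrode_patch <- function(x, ...) {
  cat(sprintf("electrode_patch '%s': d = %g mm at (%g, %g, %g); %d facets, area %.3f mm^2\n",
              x$tag, x$diameter, x$center[1], x$center[2], x$center[3],
              length(x$facet_ids), x$area))
  invisible(x)
}

#' Place the 5-contact paddle array
#'
#' Places five disc contacts at the layout centers, tagged
#' `electrode_1` ... `electrode_5`; `electrode_3` is the middle contact
#' (single-electrode stimulation reuses exactly this patch). Patches must be
#' pairwise disjoint.
#'
#' @param mesh a `labeled_tet_mesh`.
#' @param layout a [paddle_layout()]; default centers the paddle on the top
#'   surface.
#' @param diameter contact diameter, mm (default 4).
#' @return list of 5 `electrode_patch` objects.
#' @export
place_paddle_array <- function(mesh, layout = NULL, diameter = 4) {
  ext <- mesh$grid$extent
  if (is.null(layout)) layout <- paddle_layout(center = ext[1:2] / 2,
                                               diameter = diameter)
  stopifnot(inherits(layout, "paddle_layout"))
  if (min(stats::dist(layout$centers)) < diameter)
    stop("paddle contacts overlap for this diameter", call. = FALSE)
  patches <- lapply(1:5, function(k)
    place_disc_electrode(mesh, layout$centers[k, ], diameter,
                         tag = paste0("electrode_", k)))
  all_f <- unlist(lapply(patches, `[[`, "facet_ids"))
  if (anyDuplicated(all_f))
    stop("paddle contact patches overlap on the discretized surface",
         call. = FALSE)
  patches
}

#' Designate grounded (reference) boundary surfaces
#'
#' Collects the boundary facets and nodes of the given tags to be held at
#' 0 V; the slab default grounds the side and bottom surfaces, providing the
#' distant unipolar return.
#'
#' @param mesh a `labeled_tet_mesh`.
#' @param surfaces character vector of boundary tags (default
#'   `c("side", "bottom")`).
#' @return object of class `reference_set` with `tags`, `facet_ids`,
#'   `node_ids`.
#' @export
designate_reference <- function(mesh, surfaces = c("side", "bottom")) {
  if (length(surfaces) == 0)
    stop("a grounded reference surface is required for a unipolar solve",
         call. = FALSE)
  known <- unique(mesh$boundary$tag)
  bad <- setdiff(surfaces, known)
  if (length(bad))
    stop("unknown boundary tag(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  fid <- which(mesh$boundary$tag %in% surfaces)
  nodes <- sort(unique(as.vector(mesh$boundary$facets[fid, , drop = FALSE])))
  structure(list(tags = surfaces, facet_ids = fid, node_ids = nodes),
            class = "reference_set")
}
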