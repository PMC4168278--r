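# Synthetic inputs: white-matter fiber fields standing in for DTI principal
# directions, and analytic benchmark problems (bar, half-space disc) with
# closed-form impedances used to validate the solver. All generators are
# deterministic given (mesh, pattern, seed).

# run code with a temporary RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, code) {
  has <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Generate a white-matter fiber direction field
#'
#' Emulates what a diffusion-tensor acquisition provides: one principal
#' fiber direction per white-matter element (and optionally raw
#' eigenvalues). Patterns:
#' \describe{
#'   \item{uniform}{a single constant direction everywhere.}
#'   \item{u_fiber}{directions normal to (a smoothed copy of) the cortical
#'     fold surface, so fibers run up the gyral stalk into the crown and
#'     bend outward under the sulcal walls; requires a mesh built by
#'     [build_slab_mesh()]. The surface is smoothed with a Gaussian kernel
#'     (`smoothing` mm standard deviation) before taking normals so the
#'     field turns over a realistic fiber-curvature scale instead of
#'     following the sharp sulcal wall.}
#'   \item{random_smooth}{a spatially correlated random field: seeded
#'     standard-normal 3-vectors on a coarse control grid (`corr_length` mm
#'     spacing), interpolated to element centroids and normalized.}
#' }
#'
#' @param mesh a `labeled_tet_mesh` with WM elements.
#' @param pattern `"uniform"`, `"u_fiber"` or `"random_smooth"`.
#' @param seed RNG seed (only `random_smooth` consumes randomness).
#' @param direction unit direction for `"uniform"`.
#' @param smoothing Gaussian smoothing of the fold surface for `"u_fiber"`,
#'   mm.
#' @param corr_length control-grid spacing for `"random_smooth"`, mm.
#' @param diffusion_shape if non-`NULL`, length-3 positive values stored as
#'   raw per-element eigenvalues (longitudinal first); the default prolate
#'   shape `(1.2, 0.4, 0.4) * 1e-3` mimics typical white-matter diffusion
#'   eigenvalues. Only eigenvalue ratios survive volume-constraint
#'   normalization; these are synthetic stand-ins, not measurements.
#' @return object of class `fiber_field`: `element` (WM element ids),
#'   `directions` (unit vectors), optional `eigenvalues`, `pattern`, `seed`.
#' @export
generate_fiber_field <- function(mesh, pattern = c("uniform", "u_fiber",
                                                   "random_smooth"),
                                 seed = 20140917,
                                 direction = c(1, 0, 0),
                                 smoothing = 5, corr_length = 5,
                                 diffusion_shape = c(1.2, 0.4, 0.4) * 1e-3) {
  pattern <- match.arg(pattern)
  wm <- which(mesh$region == "WM")
  if (!length(wm)) stop("mesh has no white-matter elements", call. = FALSE)
  cen <- tet_centroids(mesh)[wm, , drop = FALSE]

  dirs <- switch(pattern,
    uniform = {
      d <- direction / sqrt(sum(direction^2))
      matrix(d, nrow = length(wm), ncol = 3, byrow = TRUE)
    },
    u_fiber = {
      spec <- mesh$spec
      if (is.null(spec))
        stop("u_fiber requires a mesh built by build_slab_mesh()",
             call. = FALSE)
      ds <- 0.05
      xs <- seq(-4 * smoothing, spec$extent_x + 4 * smoothing, by = ds)
      depth <- .sulcal_depth_profile(xs, spec)
      kern <- stats::dnorm(seq(-4 * smoothing, 4 * smoothing, by = ds),
                           sd = smoothing)
      kern <- kern / sum(kern)
      pad <- (length(kern) - 1) / 2
      sm <- stats::filter(depth, kern, sides = 2)
      keep <- xs >= 0 & xs <= spec$extent_x & !is.na(sm)
      slope <- stats::approxfun(xs[keep],
                                c(0, diff(sm[keep])) / ds, rule = 2)
      dd <- slope(cen[, 1])
      nrm <- sqrt(dd^2 + 1)
      cbind(dd / nrm, 0, 1 / nrm)
    },
    random_smooth = {
      ext <- mesh$grid$extent
      nctl <- pmax(2L, as.integer(ceiling(ext / corr_length)) + 1L)
      ctl <- .with_seed(seed, array(stats::rnorm(prod(nctl) * 3),
                                    dim = c(nctl, 3)))
      gx <- seq(0, ext[1], length.out = nctl[1])
      gy <- seq(0, ext[2], length.out = nctl[2])
      gz <- seq(0, ext[3], length.out = nctl[3])
      comp <- function(c3) .trilinear(gx, gy, gz, ctl[, , , c3], cen)
      d <- cbind(comp(1), comp(2), comp(3))
      nn <- sqrt(rowSums(d^2))
      nn[nn < 1e-12] <- 1
      d / nn
    })

  ev <- NULL
  if (!is.null(diffusion_shape)) {
    stopifnot(length(diffusion_shape) == 3, all(diffusion_shape > 0))
    ev <- matrix(diffusion_shape, nrow = length(wm), ncol = 3, byrow = TRUE)
  }
  structure(list(element = wm, directions = dirs, eigenvalues = ev,
                 pattern = pattern, seed = seed),
            class = "fiber_field")
}

# trilinear interpolation of a gridded scalar at arbitrary points
.trilinear <- function(gx, gy, gz, vals, pts) {
  ix <- pmin(pmax(findInterval(pts[, 1], gx), 1L), length(gx) - 1L)
  iy <- pmin(pmax(findInterval(pts[, 2], gy), 1L), length(gy) - 1L)
  iz <- pmin(pmax(findInterval(pts[, 3], gz), 1L), length(gz) - 1L)
  fx <- (pts[, 1] - gx[ix]) / (gx[ix + 1L] - gx[ix])
  fy <- (pts[, 2] - gy[iy]) / (gy[iy + 1L] - gy[iy])
  fz <- (pts[, 3] - gz[iz]) / (gz[iz + 1L] - gz[iz])
  v <- function(dx, dy, dz) vals[cbind(ix + dx, iy + dy, iz + dz)]
  (1 - fx) * ((1 - fy) * ((1 - fz) * v(0L, 0L, 0L) + fz * v(0L, 0L, 1L)) +
              fy * ((1 - fz) * v(0L, 1L, 0L) + fz * v(0L, 1L, 1L))) +
  fx * ((1 - fy) * ((1 - fz) * v(1L, 0L, 0L) + fz * v(1L, 0L, 1L)) +
        fy * ((1 - fz) * v(1L, 1L, 0L) + fz * v(1L, 1L, 1L)))
}

#' @export
print.fiber_field <- function(x, ...) {
  cat(sprintf("fiber_field: pattern '%s', %d WM elements, seed %s\n",
              x$pattern, length(x$element), format(x$seed)))
  invisible(x)
}

#' Construct an analytic solver benchmark
#'
#' Two geometries with closed-form impedance:
#' \describe{
#'   \item{bar}{a homogeneous box of length `L` (along x) and cross-section
#'     `A`, one end at the applied potential and the other grounded, sides
#'     insulated; `R = L / (sigma A)`. P1 elements reproduce the linear
#'     potential exactly.}
#'   \item{halfspace_disc}{a disc electrode (radius `a`) centered on the top
#'     of a large homogeneous block with side and bottom faces grounded;
#'     the spreading resistance of a disc on a half-space is
#'     `R = 1 / (4 sigma a)`. Valid only when the block is large relative
#'     to the disc (at least 10x the radius from disc center to every
#'     grounded face).}
#' }
#'
#' @param case `"bar"` or `"halfspace_disc"`.
#' @param resolution target mesh edge length, mm.
#' @param L,A bar length (mm) and cross-section area (mm^2).
#' @param a disc radius, mm.
#' @param block length-3 block dimensions for `halfspace_disc`, mm.
#' @param sigma conductivity, S/m.
#' @return list with `mesh`, `active` (electrode patch or active node set),
#'   `reference` (reference_set), `expected_impedance` (ohm), and the
#'   parameters.
#' @export
make_benchmark <- function(case = c("bar", "halfspace_disc"),
                           resolution = 1,
                           L = 10, A = 100, a = 2,
                           block = c(44, 44, 22), sigma = 0.126) {
  case <- match.arg(case)
  if (case == "bar") {
    side <- sqrt(A)
    mesh <- build_box_mesh(c(L, side, side), resolution)
    # active = x = 0 face, ground = x = L face; both are "side"-tagged, so
    # pick facets by coordinate
    nd <- mesh$nodes
    f <- mesh$boundary$facets
    cen_x <- (nd[f[, 1], 1] + nd[f[, 2], 1] + nd[f[, 3], 1]) / 3
    eps <- 1e-9 * L
    fid_in <- which(mesh$boundary$tag == "side" & cen_x < eps)
    fid_out <- which(mesh$boundary$tag == "side" & cen_x > L - eps)
    active <- structure(list(
      tag = "bar_inlet", center = c(0, side / 2, side / 2),
      normal = c(-1, 0, 0), diameter = NA_real_, facet_ids = fid_in,
      node_ids = sort(unique(as.vector(f[fid_in, ]))),
      area = sum(.facet_areas(mesh, fid_in))), class = "electrode_patch")
    reference <- structure(list(
      tags = "bar_outlet", facet_ids = fid_out,
      node_ids = sort(unique(as.vector(f[fid_out, ])))),
      class = "reference_set")
    expected <- L / (sigma * A) * 1000      # mm/(S/m * mm^2) -> ohm
  } else {
    if (any(block[1:2] < 2 * 10 * a) || block[3] < 10 * a)
      stop("block too small for the half-space assumption: need at least ",
           "10 disc radii from the disc to every grounded face",
           call. = FALSE)
    mesh <- build_box_mesh(block, resolution)
    active <- place_disc_electrode(mesh, block[1:2] / 2, diameter = 2 * a,
                                   tag = "disc")
    reference <- designate_reference(mesh, c("side", "bottom"))
    expected <- 1 / (4 * sigma * a / 1000)  # a in m
  }
  tab <- conductivity_table(WM = sigma)
  list(case = case, mesh = mesh, active = active, reference = reference,
       table = tab, sigma = sigma, expected_impedance = expected)
}

#' Solve a benchmark and report its impedance
#'
#' Convenience wrapper: isotropic assembly, 1 V solve, residual-method
#' current, impedance.
#'
#' @param bench result of [make_benchmark()].
#' @param V0 applied voltage.
#' @param solver passed to [solve_potential()].
#' @return list with `impedance`, `expected`, `relative_error`, `solution`,
#'   `system`, `current`.
#' @export
solve_benchmark <- function(bench, V0 = 1, solver = "auto") {
  field <- build_conductivity_field(bench$mesh, bench$table,
                                    anisotropy_model("isotropic"))
  sys <- assemble_system(bench$mesh, field)
  bc <- boundary_conditions(bench$active, bench$reference, V0 = V0)
  sol <- solve_potential(sys, bc, solver = solver)
  i <- electrode_current(sol, sys, bench$active)
  z <- estimate_impedance(V0, i)
  list(impedance = z, expected = bench$expected_impedance,
       relative_error = abs(z - bench$expected_impedance) /
         bench$expected_impedance,
       solution = sol, system = sys, current = i)
}
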