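# First-order (P1) tetrahedral finite elements for the quasi-static
# conduction problem div(sigma grad V) = 0 with Dirichlet electrode/ground
# patches and insulating (natural) boundaries elsewhere. Unit bookkeeping:
# lengths in mm and sigma in S/m make stiffness entries milli-siemens, so
# K %*% V yields nodal currents in mA; the electric field is converted to
# V/m and current density to A/m^2 when fields are recovered.

# per-element shape-function gradients (1/mm) and volumes (mm^3)
.element_gradients <- function(mesh, rows = NULL) {
  nd <- mesh$nodes
  tt <- if (is.null(rows)) mesh$tets else mesh$tets[rows, , drop = FALSE]
  p1 <- nd[tt[, 1], , drop = FALSE]
  u <- nd[tt[, 2], , drop = FALSE] - p1
  v <- nd[tt[, 3], , drop = FALSE] - p1
  w <- nd[tt[, 4], , drop = FALSE] - p1
  cvw <- cbind(v[, 2] * w[, 3] - v[, 3] * w[, 2],
               v[, 3] * w[, 1] - v[, 1] * w[, 3],
               v[, 1] * w[, 2] - v[, 2] * w[, 1])
  cwu <- cbind(w[, 2] * u[, 3] - w[, 3] * u[, 2],
               w[, 3] * u[, 1] - w[, 1] * u[, 3],
               w[, 1] * u[, 2] - w[, 2] * u[, 1])
  cuv <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
               u[, 3] * v[, 1] - u[, 1] * v[, 3],
               u[, 1] * v[, 2] - u[, 2] * v[, 1])
  det <- rowSums(u * cvw)
  if (any(det <= 0)) stop("mesh contains non-positively-oriented tets",
                          call. = FALSE)
  g2 <- cvw / det
  g3 <- cwu / det
  g4 <- cuv / det
  g1 <- -(g2 + g3 + g4)
  list(g = list(g1, g2, g3, g4), vol = det / 6)
}

# sigma %*% g for tensors stored as (xx, yy, zz, xy, xz, yz) rows
.tensor_apply <- function(tn, g) {
  cbind(tn[, 1] * g[, 1] + tn[, 4] * g[, 2] + tn[, 5] * g[, 3],
        tn[, 4] * g[, 1] + tn[, 2] * g[, 2] + tn[, 6] * g[, 3],
        tn[, 5] * g[, 1] + tn[, 6] * g[, 2] + tn[, 3] * g[, 3])
}

#' Assemble the finite-element stiffness system
#'
#' Builds the sparse symmetric stiffness matrix
#' `K[a, b] = sum_e vol_e grad(phi_a) . (sigma_e grad(phi_b))` over linear
#' tetrahedral elements. Row sums are zero before constraints (constant
#' potentials lie in the null space). With mm geometry and S/m tensors the
#' entries are in mS, so `K %*% V` is a nodal current vector in mA.
#'
#' @param mesh a `labeled_tet_mesh`.
#' @param field a `conductivity_field` with one tensor per element.
#' @return object of class `fem_system` with the sparse matrix `K`, the
#'   `mesh` and the `field`.
#' @export
assemble_system <- function(mesh, field) {
  stopifnot(inherits(mesh, "labeled_tet_mesh"),
            inherits(field, "conductivity_field"))
  tn <- field$tensors
  if (nrow(tn) != nrow(mesh$tets))
    stop("conductivity field does not match the mesh element count",
         call. = FALSE)
  # SPD check via leading principal minors
  m1 <- tn[, 1]
  m2 <- tn[, 1] * tn[, 2] - tn[, 4]^2
  m3 <- tn[, 1] * (tn[, 2] * tn[, 3] - tn[, 6]^2) -
        tn[, 4] * (tn[, 4] * tn[, 3] - tn[, 6] * tn[, 5]) +
        tn[, 5] * (tn[, 4] * tn[, 6] - tn[, 2] * tn[, 5])
  bad <- which(m1 <= 0 | m2 <= 0 | m3 <= 0)
  if (length(bad))
    stop("conductivity tensor not symmetric positive definite at element ",
         bad[1], call. = FALSE)

  m <- nrow(mesh$tets)
  nn <- nrow(mesh$nodes)
  # assemble in element chunks and accumulate sparse partial sums: keeps the
  # peak at one chunk of triplet buffers instead of 16 x m entries at once
  chunk <- 1000000L
  K <- NULL
  for (s in seq(1L, m, by = chunk)) {
    rows <- s:min(s + chunk - 1L, m)
    eg <- .element_gradients(mesh, rows)
    g <- eg$g; vol <- eg$vol
    tts <- mesh$tets[rows, , drop = FALSE]
    tns <- tn[rows, , drop = FALSE]
    mc <- length(rows)
    iv <- integer(16L * mc); jv <- integer(16L * mc); xv <- numeric(16L * mc)
    idx <- 0L
    for (b in 1:4) {
      sgb <- .tensor_apply(tns, g[[b]])
      for (a in 1:4) {
        rng <- idx + seq_len(mc)
        iv[rng] <- tts[, a]
        jv[rng] <- tts[, b]
        xv[rng] <- vol * rowSums(g[[a]] * sgb)
        idx <- idx + mc
      }
    }
    rm(eg, g, sgb, tts, tns)
    Kc <- Matrix::sparseMatrix(i = iv, j = jv, x = xv, dims = c(nn, nn))
    rm(iv, jv, xv); gc(FALSE)
    K <- if (is.null(K)) Kc else K + Kc
  }
  structure(list(K = K, mesh = mesh, field = field), class = "fem_system")
}

#' Boundary conditions for a unipolar stimulation solve
#'
#' @param active list of `electrode_patch` objects driven at the applied
#'   potential (all paddle contacts are wired together at the same value),
#'   or a single patch.
#' @param reference a `reference_set` from [designate_reference()], held at
#'   0 V.
#' @param V0 applied electrode potential, volts.
#' @return object of class `boundary_conditions`.
#' @export
boundary_conditions <- function(active, reference, V0 = 1) {
  if (inherits(active, "electrode_patch")) active <- list(active)
  stopifnot(length(active) >= 1, inherits(reference, "reference_set"),
            is.finite(V0))
  an <- sort(unique(unlist(lapply(active, `[[`, "node_ids"))))
  if (length(intersect(an, reference$node_ids)))
    stop("active and reference boundary sets overlap", call. = FALSE)
  structure(list(active = active, reference = reference, V0 = V0,
                 active_nodes = an), class = "boundary_conditions")
}

# --- geometric multigrid preconditioner -------------------------------------
# The structured grid gives a natural hierarchy: coarse grids halve the cell
# count per axis, prolongation is trilinear interpolation between the nested
# node lattices, and coarse operators are Galerkin products t(P) A P.
# Dirichlet nodes are handled by zeroing the corresponding prolongation rows
# on the finest level, so corrections vanish where values are prescribed.

# trilinear prolongation from the decimated (every-other-node) coarse grid
# to `grid`; works on rectilinear coordinate vectors
.mg_prolongation <- function(grid) {
  n <- grid$n
  dec <- function(g) {
    idx <- unique(c(seq(1L, length(g), by = 2L), length(g)))
    g[idx]
  }
  cc <- lapply(grid$coords, dec)
  nc <- vapply(cc, length, 0L) - 1L
  if (all(nc == n)) return(NULL)
  npx <- n[1] + 1L; npy <- n[2] + 1L; npz <- n[3] + 1L
  ncx <- nc[1] + 1L; ncy <- nc[2] + 1L; ncz <- nc[3] + 1L
  ax <- function(gf, gc) {
    i0 <- pmin(pmax(findInterval(gf, gc), 1L), length(gc) - 1L) - 1L
    w1 <- (gf - gc[i0 + 1L]) / (gc[i0 + 2L] - gc[i0 + 1L])
    list(i0 = i0, w1 = pmin(pmax(w1, 0), 1))
  }
  X <- ax(grid$coords[[1]], cc[[1]])
  Y <- ax(grid$coords[[2]], cc[[2]])
  Z <- ax(grid$coords[[3]], cc[[3]])
  nfine <- npx * npy * npz
  fid <- seq_len(nfine)
  ix <- (fid - 1L) %% npx
  iy <- ((fid - 1L) %/% npx) %% npy
  iz <- (fid - 1L) %/% (npx * npy)
  x0 <- X$i0[ix + 1L]; wx <- X$w1[ix + 1L]
  y0 <- Y$i0[iy + 1L]; wy <- Y$w1[iy + 1L]
  z0 <- Z$i0[iz + 1L]; wz <- Z$w1[iz + 1L]
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) wx else 1 - wx) * (if (dy) wy else 1 - wy) *
         (if (dz) wz else 1 - wz)
    keep <- w > 1e-14
    if (!any(keep)) next
    cj <- (x0 + dx) + (y0 + dy) * ncx + (z0 + dz) * ncx * ncy + 1L
    ii <- c(ii, fid[keep]); jj <- c(jj, cj[keep]); xx <- c(xx, w[keep])
  }
  list(P = Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                                dims = c(nfine, ncx * ncy * ncz)),
       grid = list(origin = grid$origin, h = grid$extent / nc, n = nc,
                   extent = grid$extent, coords = cc))
}

# build the multigrid hierarchy for the constrained full-lattice operator
.mg_setup <- function(A, grid, fixed, coarse_max = 4000L) {
  levels <- list()
  lvl <- list(A = A, dinv = 1 / Matrix::diag(A))
  repeat {
    pr <- .mg_prolongation(grid)
    if (nrow(lvl$A) <= coarse_max || is.null(pr)) break
    P <- pr$P
    if (any(fixed)) {
      # no interpolation into constrained nodes
      Tp <- as(P, "TsparseMatrix")
      keep <- !fixed[Tp@i + 1L]
      P <- Matrix::sparseMatrix(i = Tp@i[keep] + 1L, j = Tp@j[keep] + 1L,
                                x = Tp@x[keep], dims = dim(P))
      fixed <- logical(0)   # coarser levels carry no explicit constraints
    }
    Ac <- Matrix::t(P) %*% lvl$A %*% P
    dg <- Matrix::diag(Ac)
    dead <- which(dg <= 0 | abs(dg) < 1e-300)
    if (length(dead)) {
      Ac <- Ac + Matrix::sparseMatrix(i = dead, j = dead,
                                      x = rep(1, length(dead)),
                                      dims = dim(Ac))
      dg[dead] <- 1
    }
    lvl$P <- P
    levels[[length(levels) + 1L]] <- lvl
    lvl <- list(A = Ac, dinv = 1 / dg)
    grid <- pr$grid
  }
  lvl$chol <- Matrix::Cholesky(Matrix::forceSymmetric(lvl$A), LDL = FALSE,
                               perm = TRUE)
  levels[[length(levels) + 1L]] <- lvl
  levels
}

# one V-cycle with damped-Jacobi smoothing
.mg_vcycle <- function(levels, b, l = 1L, nu = 2L, omega = 0.7) {
  lvl <- levels[[l]]
  if (l == length(levels))
    return(as.numeric(Matrix::solve(lvl$chol, b, system = "A")))
  x <- numeric(length(b))
  for (s in seq_len(nu))
    x <- x + omega * lvl$dinv * (b - as.numeric(lvl$A %*% x))
  r <- b - as.numeric(lvl$A %*% x)
  xc <- .mg_vcycle(levels, as.numeric(Matrix::t(lvl$P) %*% r), l + 1L,
                   nu, omega)
  x <- x + as.numeric(lvl$P %*% xc)
  for (s in seq_len(nu))
    x <- x + omega * lvl$dinv * (b - as.numeric(lvl$A %*% x))
  x
}

# multigrid-preconditioned conjugate gradients
.mg_pcg <- function(levels, b, tol = 1e-8, maxit = 400L) {
  A <- levels[[1]]$A
  x <- numeric(length(b))
  r <- b
  bnorm <- sqrt(sum(b * b))
  if (bnorm == 0) return(list(x = x, iters = 0L))
  z <- .mg_vcycle(levels, r)
  p <- z
  rz <- sum(r * z)
  for (it in seq_len(maxit)) {
    Ap <- as.numeric(A %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    if (sqrt(sum(r * r)) <= tol * bnorm) return(list(x = x, iters = it))
    z <- .mg_vcycle(levels, r)
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  stop(sprintf("multigrid CG did not converge in %d iterations (relative residual %.3e)",
               maxit, sqrt(sum(r * r)) / bnorm), call. = FALSE)
}

# Jacobi-preconditioned conjugate gradients on an SPD sparse matrix
.pcg <- function(A, b, tol = 1e-8, maxit = 20000L) {
  x <- numeric(length(b))
  r <- b
  dinv <- 1 / Matrix::diag(A)
  z <- dinv * r
  p <- z
  rz <- sum(r * z)
  bnorm <- sqrt(sum(b * b))
  if (bnorm == 0) return(list(x = x, iters = 0L))
  for (it in seq_len(maxit)) {
    Ap <- as.numeric(A %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    if (sqrt(sum(r * r)) <= tol * bnorm) return(list(x = x, iters = it))
    z <- dinv * r
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  stop(sprintf("CG did not converge in %d iterations (relative residual %.3e)",
               maxit, sqrt(sum(r * r)) / bnorm), call. = FALSE)
}

#' Solve the constrained potential problem
#'
#' Eliminates the Dirichlet rows/columns symmetrically (active nodes at
#' `V0`, reference nodes at 0 V) and solves the reduced symmetric
#' positive-definite system with a sparse Cholesky factorization (default)
#' or Jacobi-preconditioned conjugate gradients. Constrained nodes carry
#' exactly their prescribed values. The element electric field (V/m) and
#' current density (A/m^2) are recovered immediately.
#'
#' @param system a `fem_system` from [assemble_system()].
#' @param bc a [boundary_conditions()].
#' @param solver `"auto"` (direct below ~80k unknowns, multigrid above),
#'   `"cholesky"` (supernodal sparse Cholesky on the reduced system),
#'   `"mg"` (geometric-multigrid-preconditioned conjugate gradients) or
#'   `"cg"` (Jacobi-preconditioned conjugate gradients).
#' @param tol relative residual tolerance for the iterative solvers.
#' @return object of class `potential_solution`: nodal `V` (volts), element
#'   `E` (V/m), `J` (A/m^2), `Jmag`, `residual` (relative, on the reduced
#'   system), `V0`, the boundary sets, and measured electrode currents via
#'   [electrode_current()].
#' @export
solve_potential <- function(system, bc, solver = c("auto", "cholesky",
                                                   "mg", "cg"),
                            tol = 1e-8) {
  solver <- match.arg(solver)
  stopifnot(inherits(system, "fem_system"), inherits(bc, "boundary_conditions"))
  K <- system$K
  nn <- nrow(K)
  fixed <- c(bc$active_nodes, bc$reference$node_ids)
  if (length(bc$reference$node_ids) == 0)
    stop("no reference (ground) nodes: the unipolar system is singular",
         call. = FALSE)
  vfix <- c(rep(bc$V0, length(bc$active_nodes)),
            rep(0, length(bc$reference$node_ids)))
  if (solver == "auto")
    solver <- if (nn - length(fixed) > 80000L) "mg" else "cholesky"
  V <- numeric(nn)
  V[fixed] <- vfix

  if (solver == "mg") {
    # constrained full-lattice operator: Dirichlet rows/columns zeroed with
    # a unit diagonal; the solution is the correction on top of the lift
    isfix <- logical(nn); isfix[fixed] <- TRUE
    Tm <- as(K, "TsparseMatrix")
    ti <- Tm@i + 1L; tj <- Tm@j + 1L
    keep <- !isfix[ti] & !isfix[tj]
    Kt <- Matrix::sparseMatrix(i = c(ti[keep], fixed), j = c(tj[keep], fixed),
                               x = c(Tm@x[keep], rep(1, length(fixed))),
                               dims = c(nn, nn))
    rm(Tm, ti, tj, keep)
    b <- -as.numeric(K %*% V)
    b[fixed] <- 0
    levels <- .mg_setup(Kt, system$mesh$grid, isfix)
    res <- .mg_pcg(levels, b, tol = tol)
    V <- V + res$x
    rnorm <- sqrt(sum((as.numeric(Kt %*% res$x) - b)^2))
    bnorm <- sqrt(sum(b^2))
  } else {
    free <- setdiff(seq_len(nn), fixed)
    Kff <- K[free, free, drop = FALSE]
    rhs <- -as.numeric(K[free, fixed, drop = FALSE] %*% vfix)
    x <- if (solver == "cholesky") {
      # supernodal CHOLMOD factorization: much faster than the simplicial
      # default on 3-D stiffness matrices of this size
      ch <- Matrix::Cholesky(Matrix::forceSymmetric(Kff), LDL = FALSE,
                             perm = TRUE, super = TRUE)
      as.numeric(Matrix::solve(ch, rhs, system = "A"))
    } else {
      .pcg(Kff, rhs, tol = tol)$x
    }
    V[free] <- x
    rnorm <- sqrt(sum((as.numeric(Kff %*% x) - rhs)^2))
    bnorm <- sqrt(sum(rhs^2))
  }
  sol <- structure(list(V = V, V0 = bc$V0, bc = bc,
                        residual = if (bnorm > 0) rnorm / bnorm else 0,
                        solver = solver),
                   class = "potential_solution")
  compute_current_density(sol, system)
}

#' Recover element fields from a solved potential
#'
#' Computes the per-element (constant) electric field `E = -grad V` in V/m
#' and current density `J = sigma E` in A/m^2.
#'
#' @param solution a `potential_solution` (the nodal potential is used).
#' @param system the `fem_system` the potential was solved on (supplies the
#'   mesh and conductivity field).
#' @return the solution with `E`, `J` (elements x 3) and `Jmag` filled in.
#' @export
compute_current_density <- function(solution, system) {
  mesh <- system$mesh
  eg <- .element_gradients(mesh)
  tt <- mesh$tets
  V <- solution$V
  gradV <- eg$g[[1]] * V[tt[, 1]] + eg$g[[2]] * V[tt[, 2]] +
           eg$g[[3]] * V[tt[, 3]] + eg$g[[4]] * V[tt[, 4]]
  E <- -1000 * gradV                       # V/mm -> V/m
  J <- .tensor_apply(system$field$tensors, E)
  solution$E <- E
  solution$J <- J
  solution$Jmag <- sqrt(rowSums(J^2))
  solution
}

#' Current through an electrode patch or reference set
#'
#' Integrates the normal current over the patch. The default `"residual"`
#' method sums the nodal reactions `(K V)_i` over the patch nodes, the
#' consistent discrete flux (conservative to round-off); `"integral"` sums
#' the facet areas times the adjacent-element `J . n`. Sign convention:
#' current entering the domain through an active electrode and current
#' leaving through the reference are both positive, so for a solved anode
#' both electrode and reference report the same positive current.
#'
#' @param solution a solved `potential_solution`.
#' @param system the `fem_system` it was solved on.
#' @param patch an `electrode_patch`, a list of patches (summed), or a
#'   `reference_set`.
#' @param method `"residual"` or `"integral"`.
#' @return current in amperes.
#' @export
electrode_current <- function(solution, system, patch,
                              method = c("residual", "integral")) {
  method <- match.arg(method)
  is_ref <- inherits(patch, "reference_set")
  if (inherits(patch, "electrode_patch")) patch <- list(patch)
  if (!is_ref && (!length(patch) || !length(unlist(lapply(patch, `[[`, "facet_ids")))))
    stop("empty electrode patch", call. = FALSE)
  mesh <- system$mesh
  if (method == "residual") {
    r <- as.numeric(system$K %*% solution$V)   # nodal currents, mA
    nodes <- if (is_ref) patch$node_ids else
      sort(unique(unlist(lapply(patch, `[[`, "node_ids"))))
    i_mA <- sum(r[nodes])
    # reactions are positive where current enters (active patch), negative
    # where it leaves (reference); report both as positive magnitudes of the
    # through-going current
    if (is_ref) i_mA <- -i_mA
    return(i_mA / 1000)
  }
  fid <- if (is_ref) patch$facet_ids else
    unlist(lapply(patch, `[[`, "facet_ids"))
  own <- .boundary_owner(mesh, fid)
  nrm <- .facet_outward_normals(mesh, fid)
  ar <- .facet_areas(mesh, fid)               # mm^2
  Jn <- rowSums(solution$J[own, , drop = FALSE] * nrm)  # A/m^2 outward
  flux <- sum(Jn * ar) * 1e-6                 # A
  if (is_ref) flux else -flux
}

#' @export
print.potential_solution <- function(x, ...) {
  cat(sprintf("potential_solution: V0 = %g V, solver %s, relative residual %.2e\n",
              x$V0, x$solver, x$residual))
  cat(sprintf("  V range [%.4g, %.4g] V; max |J| = %.4g A/m^2\n",
              min(x$V), max(x$V), max(x$Jmag)))
  invisible(x)
}
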