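# Tissue conductivity assignment. Non-white-matter tissue is isotropic;
# white matter can carry a symmetric positive-definite 3x3 tensor per
# element, built from a fiber eigensystem by either the volume-constraint
# normalization of measured (diffusion) eigenvalues or a fixed
# longitudinal:transverse ratio. Units: S/m throughout.

#' Isotropic tissue conductivities (S/m)
#'
#' White matter 0.126, skull 0.01 and scalp/body 0.465 S/m follow standard
#' reported values for quasi-static head models; gray matter 0.276 and CSF
#' 1.65 S/m are conventional literature defaults. Only the labels present in
#' a mesh are consulted.
#'
#' @param WM,GM,CSF,skull,body conductivities in S/m.
#' @param ... further named tissue conductivities.
#' @return named numeric vector of class `conductivity_table`.
#' @export
conductivity_table <- function(WM = 0.126, GM = 0.276, CSF = 1.65,
                               skull = 0.01, body = 0.465, ...) {
  tab <- c(WM = WM, GM = GM, CSF = CSF, skull = skull, body = body, ...)
  if (any(!is.finite(tab)) || any(tab <= 0))
    stop("all conductivities must be positive and finite", call. = FALSE)
  structure(tab, class = "conductivity_table")
}

#' Anisotropy model for white matter
#'
#' @param method `"isotropic"` (scalar white matter), `"normalized"`
#'   (volume-constraint scaling of supplied raw eigenvalues), or
#'   `"fixed_ratio"` (prescribed longitudinal:transverse ratio `r`).
#' @param r ratio coefficient for `fixed_ratio` (1:2, 1:5, 1:10 correspond
#'   to `r` = 2, 5, 10); must be >= 1.
#' @param sigma_iso isotropic white-matter reference conductivity, S/m.
#' @return object of class `anisotropy_model`.
#' @export
anisotropy_model <- function(method = c("isotropic", "normalized", "fixed_ratio"),
                             r = 1, sigma_iso = 0.126) {
  method <- match.arg(method)
  if (sigma_iso <= 0) stop("sigma_iso must be positive", call. = FALSE)
  if (method == "fixed_ratio" && r < 1)
    stop("ratio coefficient r must be >= 1", call. = FALSE)
  structure(list(method = method, r = r, sigma_iso = sigma_iso),
            class = "anisotropy_model")
}

#' Conductivity tensor from an eigensystem
#'
#' Reconstructs `S diag(eigenvalues) t(S)` from orthonormal eigenvectors
#' (longitudinal first) and eigenvalues; the result is symmetric and its
#' eigendecomposition recovers the inputs.
#'
#' @param S 3x3 matrix of orthonormal column eigenvectors.
#' @param eigenvalues length-3 nonnegative eigenvalues, S/m.
#' @return symmetric 3x3 conductivity tensor, S/m.
#' @export
tensor_from_eigensystem <- function(S, eigenvalues) {
  stopifnot(is.matrix(S), all(dim(S) == c(3, 3)), length(eigenvalues) == 3)
  if (max(abs(crossprod(S) - diag(3))) > 1e-8)
    stop("S is not orthonormal", call. = FALSE)
  if (any(eigenvalues < 0))
    stop("eigenvalues must be nonnegative", call. = FALSE)
  T <- S %*% diag(eigenvalues) %*% t(S)
  (T + t(T)) / 2
}

#' Volume-constraint normalization of raw eigenvalues
#'
#' Scales raw (diffusion-tensor) eigenvalues so the geometric mean of the
#' resulting conductivity eigenvalues equals `sigma_iso`:
#' `sigma_i = sigma_iso * lambda_i / (lambda_1 lambda_2 lambda_3)^(1/3)`.
#' The tensor volume (determinant) then matches the isotropic reference
#' while the anisotropy shape of the input is preserved.
#'
#' @param eigenvalues length-3 positive raw eigenvalues (rows of a matrix
#'   for many elements at once); units cancel.
#' @param sigma_iso isotropic reference conductivity, S/m.
#' @return conductivity eigenvalues in S/m, same shape as the input.
#' @export
normalize_volume_constraint <- function(eigenvalues, sigma_iso = 0.126) {
  ev <- if (is.matrix(eigenvalues)) eigenvalues else matrix(eigenvalues, nrow = 1)
  stopifnot(ncol(ev) == 3)
  if (any(ev <= 0))
    stop("raw eigenvalues must be strictly positive (degenerate tensor)",
         call. = FALSE)
  gm <- (ev[, 1] * ev[, 2] * ev[, 3])^(1 / 3)
  out <- sigma_iso * ev / gm
  if (!is.matrix(eigenvalues)) out <- drop(out)
  out
}

#' Fixed-ratio white-matter eigenvalues
#'
#' Longitudinal and transverse eigenvalues with prescribed ratio
#' `sigma_long / sigma_trans = r` under the volume constraint
#' `sigma_long * sigma_trans^2 = sigma_iso^3`, i.e.
#' `sigma_long = r^(2/3) sigma_iso`, `sigma_trans = r^(-1/3) sigma_iso`.
#'
#' @param sigma_iso isotropic reference conductivity, S/m.
#' @param r ratio coefficient, >= 1.
#' @return named numeric `c(long = , trans = )`, S/m.
#' @export
fixed_ratio_eigenvalues <- function(sigma_iso = 0.126, r) {
  if (r < 1) stop("ratio coefficient r must be >= 1", call. = FALSE)
  if (sigma_iso <= 0) stop("sigma_iso must be positive", call. = FALSE)
  c(long = r^(2 / 3) * sigma_iso, trans = r^(-1 / 3) * sigma_iso)
}

#' Fractional anisotropy of a tensor eigenvalue triple
#'
#' `FA = sqrt(1/2) sqrt((l1-l2)^2 + (l2-l3)^2 + (l1-l3)^2) /
#' sqrt(l1^2 + l2^2 + l3^2)`, in `[0, 1]`; 0 for isotropic tensors, 1 in
#' the fully anisotropic limit.
#'
#' @param eigenvalues length-3 nonnegative eigenvalues, or an elements x 3
#'   matrix.
#' @return FA value(s) in `[0, 1]`.
#' @export
fractional_anisotropy <- function(eigenvalues) {
  ev <- if (is.matrix(eigenvalues)) eigenvalues else matrix(eigenvalues, nrow = 1)
  stopifnot(ncol(ev) == 3)
  if (any(ev < 0)) stop("eigenvalues must be nonnegative", call. = FALSE)
  ss <- rowSums(ev^2)
  if (any(ss == 0)) stop("all-zero eigenvalues have undefined FA", call. = FALSE)
  fa <- sqrt(0.5 * ((ev[, 1] - ev[, 2])^2 + (ev[, 2] - ev[, 3])^2 +
                    (ev[, 1] - ev[, 3])^2) / ss)
  if (!is.matrix(eigenvalues)) fa <- drop(fa)
  fa
}

# batched rank-1 tensor construction: lam_t * I + sum_i (lam_i - lam_t) u_i u_i^T
# for axially symmetric tensors only the principal direction is needed; for
# three distinct eigenvalues a deterministic orthonormal completion of the
# principal direction is used as the transverse basis
.tensors_from_fibers <- function(dirs, ev) {
  n <- nrow(dirs)
  ux <- dirs[, 1]; uy <- dirs[, 2]; uz <- dirs[, 3]
  l1 <- ev[, 1]; l2 <- ev[, 2]; l3 <- ev[, 3]
  out <- matrix(0, n, 6)
  colnames(out) <- c("xx", "yy", "zz", "xy", "xz", "yz")
  if (all(abs(l2 - l3) < 1e-14)) {
    d <- l1 - l2
    out[, "xx"] <- l2 + d * ux * ux
    out[, "yy"] <- l2 + d * uy * uy
    out[, "zz"] <- l2 + d * uz * uz
    out[, "xy"] <- d * ux * uy
    out[, "xz"] <- d * ux * uz
    out[, "yz"] <- d * uy * uz
    return(out)
  }
  # deterministic transverse basis: v = normalize(u x a), a = least-aligned axis
  a <- matrix(0, n, 3)
  amin <- max.col(-abs(dirs), ties.method = "first")
  a[cbind(seq_len(n), amin)] <- 1
  vx <- uy * a[, 3] - uz * a[, 2]
  vy <- uz * a[, 1] - ux * a[, 3]
  vz <- ux * a[, 2] - uy * a[, 1]
  vn <- sqrt(vx^2 + vy^2 + vz^2)
  vx <- vx / vn; vy <- vy / vn; vz <- vz / vn
  wx <- uy * vz - uz * vy
  wy <- uz * vx - ux * vz
  wz <- ux * vy - uy * vx
  out[, "xx"] <- l1 * ux * ux + l2 * vx * vx + l3 * wx * wx
  out[, "yy"] <- l1 * uy * uy + l2 * vy * vy + l3 * wy * wy
  out[, "zz"] <- l1 * uz * uz + l2 * vz * vz + l3 * wz * wz
  out[, "xy"] <- l1 * ux * uy + l2 * vx * vy + l3 * wx * wy
  out[, "xz"] <- l1 * ux * uz + l2 * vx * vz + l3 * wx * wz
  out[, "yz"] <- l1 * uy * uz + l2 * vy * vz + l3 * wy * wz
  out
}

#' Build the per-element conductivity field
#'
#' Assigns every element a symmetric 3x3 tensor (stored as six unique
#' components per row: xx, yy, zz, xy, xz, yz). Non-white-matter elements
#' always get isotropic values from the table; white-matter elements get
#' tensors from the anisotropy model, aligned with the supplied fiber field
#' for the `normalized` and `fixed_ratio` methods.
#'
#' @param mesh a `labeled_tet_mesh`.
#' @param table a [conductivity_table()].
#' @param model an [anisotropy_model()].
#' @param fibers a `fiber_field` (see [generate_fiber_field()]); required
#'   unless `model$method == "isotropic"`. The `normalized` method further
#'   requires raw eigenvalues in the fiber field.
#' @return object of class `conductivity_field` with `tensors`
#'   (elements x 6) and the generating `model`.
#' @export
build_conductivity_field <- function(mesh, table = conductivity_table(),
                                     model = anisotropy_model(),
                                     fibers = NULL) {
  stopifnot(inherits(mesh, "labeled_tet_mesh"))
  labs <- levels(mesh$region)
  missing_lab <- setdiff(labs, names(table))
  if (length(missing_lab))
    stop("no conductivity for region(s): ", paste(missing_lab, collapse = ", "),
         call. = FALSE)
  m <- nrow(mesh$tets)
  sig <- unname(table[as.character(mesh$region)])
  tensors <- matrix(0, m, 6)
  colnames(tensors) <- c("xx", "yy", "zz", "xy", "xz", "yz")
  tensors[, 1:3] <- sig

  wm <- which(mesh$region == "WM")
  if (model$method != "isotropic") {
    if (is.null(fibers))
      stop("fiber field required for anisotropic white matter", call. = FALSE)
    if (!all(wm %in% fibers$element))
      stop("fiber field does not cover every white-matter element",
           call. = FALSE)
    idx <- match(wm, fibers$element)
    dirs <- fibers$directions[idx, , drop = FALSE]
    ev <- switch(model$method,
      fixed_ratio = {
        lt <- fixed_ratio_eigenvalues(model$sigma_iso, model$r)
        matrix(c(lt["long"], lt["trans"], lt["trans"]), nrow = length(wm),
               ncol = 3, byrow = TRUE)
      },
      normalized = {
        if (is.null(fibers$eigenvalues))
          stop("normalized model requires raw eigenvalues in the fiber field",
               call. = FALSE)
        normalize_volume_constraint(fibers$eigenvalues[idx, , drop = FALSE],
                                    model$sigma_iso)
      })
    tensors[wm, ] <- .tensors_from_fibers(dirs, ev)
  }
  structure(list(tensors = tensors, model = model, table = table),
            class = "conductivity_field")
}

#' @export
print.conductivity_field <- function(x, ...) {
  cat(sprintf("conductivity_field: %d elements, method '%s'", nrow(x$tensors),
              x$model$method))
  if (x$model$method == "fixed_ratio") cat(sprintf(" (r = %g)", x$model$r))
  cat("\n")
  invisible(x)
}

#' Per-element fractional anisotropy of a conductivity field
#'
#' @param field a `conductivity_field`.
#' @return numeric vector of FA values (0 for isotropic elements).
#' @export
field_fa <- function(field) {
  ev <- tensor_eigenvalues(field)
  fractional_anisotropy(ev)
}

#' Eigenvalues of every element tensor
#'
#' Closed-form eigenvalues of the symmetric 3x3 tensors (descending per row).
#'
#' @param field a `conductivity_field`.
#' @return elements x 3 matrix of eigenvalues, S/m.
#' @export
tensor_eigenvalues <- function(field) {
  tn <- field$tensors
  # analytic symmetric 3x3 eigenvalues (Smith's trigonometric method)
  a <- tn[, "xx"]; b <- tn[, "yy"]; c <- tn[, "zz"]
  d <- tn[, "xy"]; e <- tn[, "xz"]; f <- tn[, "yz"]
  p1 <- d^2 + e^2 + f^2
  q <- (a + b + c) / 3
  p2 <- (a - q)^2 + (b - q)^2 + (c - q)^2 + 2 * p1
  p <- sqrt(pmax(p2 / 6, 0))
  ev <- matrix(q, nrow(tn), 3)
  nz <- p > 1e-300
  if (any(nz)) {
    aa <- (a - q) / p; bb <- (b - q) / p; cc <- (c - q) / p
    dd <- d / p; ee <- e / p; ff <- f / p
    detB <- aa * (bb * cc - ff^2) - dd * (dd * cc - ff * ee) +
            ee * (dd * ff - bb * ee)
    r <- pmin(pmax(detB / 2, -1), 1)
    phi <- acos(r) / 3
    l1 <- q + 2 * p * cos(phi)
    l3 <- q + 2 * p * cos(phi + 2 * pi / 3)
    l2 <- 3 * q - l1 - l3
    ev[nz, ] <- cbind(l1, l2, l3)[nz, , drop = FALSE]
  }
  colnames(ev) <- c("l1", "l2", "l3")
  ev
}

#' Fiber eigensystem from a voxel tensor volume (NIfTI)
#'
#' Reads a 4-D NIfTI volume holding the six unique symmetric tensor
#' components per voxel (xx, yy, zz, xy, xz, yz along the 4th dimension),
#' samples the nearest voxel at every white-matter element centroid, and
#' eigendecomposes to a per-element principal direction and eigenvalue
#' triple. The result plugs into [build_conductivity_field()] like any
#' generated fiber field; the `normalized` model then applies the
#' volume-constraint scaling to the voxel eigenvalues.
#'
#' Requires the suggested package `RNifti`. Voxel-to-world mapping uses the
#' image's stored transform; mesh coordinates (mm) are interpreted in the
#' same world space.
#'
#' @param mesh a `labeled_tet_mesh` with WM elements.
#' @param path path to the NIfTI file (possibly gzipped).
#' @return a `fiber_field` with `directions`, `eigenvalues` and pattern
#'   `"voxel_tensor"`.
#' @export
fiber_field_from_nifti <- function(mesh, path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("fiber_field_from_nifti requires the 'RNifti' package",
         call. = FALSE)
  img <- RNifti::readNifti(path)
  dm <- dim(img)
  if (length(dm) != 4 || dm[4] != 6)
    stop("expected a 4-D volume with 6 tensor components, got dimensions ",
         paste(dm, collapse = "x"), call. = FALSE)
  wm <- which(mesh$region == "WM")
  if (!length(wm)) stop("mesh has no white-matter elements", call. = FALSE)
  cen <- tet_centroids(mesh)[wm, , drop = FALSE]
  vox <- round(RNifti::worldToVoxel(cen, img))
  for (ax in 1:3) vox[, ax] <- pmin(pmax(vox[, ax], 1), dm[ax])
  key <- (vox[, 1] - 1) + (vox[, 2] - 1) * dm[1] +
         (vox[, 3] - 1) * dm[1] * dm[2]
  arr <- array(as.numeric(img), dim = c(prod(dm[1:3]), 6L))
  uk <- sort(unique(key))
  idx <- match(key, uk)
  dirs_u <- matrix(0, length(uk), 3)
  ev_u <- matrix(0, length(uk), 3)
  for (q in seq_along(uk)) {
    t6 <- arr[uk[q] + 1L, ]
    A <- matrix(t6[c(1, 4, 5, 4, 2, 6, 5, 6, 3)], 3, 3)
    e <- eigen(A, symmetric = TRUE)
    if (any(e$values <= 0))
      stop("non-positive-definite tensor at voxel ", uk[q] + 1L,
           call. = FALSE)
    dirs_u[q, ] <- e$vectors[, 1]
    ev_u[q, ] <- e$values
  }
  structure(list(element = wm, directions = dirs_u[idx, , drop = FALSE],
                 eigenvalues = ev_u[idx, , drop = FALSE],
                 pattern = "voxel_tensor", seed = NA_integer_),
            class = "fiber_field")
}
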