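rot_z <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)

test_that("tensor reconstruction from an eigensystem round-trips", {
  expect_equal(tensor_from_eigensystem(diag(3), rep(0.126, 3)),
               0.126 * diag(3))
  # rotation invariance for equal eigenvalues
  R <- rot_z(0.7) %*% matrix(c(1, 0, 0, 0, cos(1.1), sin(1.1),
                               0, -sin(1.1), cos(1.1)), 3, 3)
  expect_equal(tensor_from_eigensystem(R, rep(0.3, 3)), 0.3 * diag(3),
               tolerance = 1e-12)
  # 45-degree rotation about z: re-diagonalization recovers the inputs
  S <- rot_z(pi / 4)
  T <- tensor_from_eigensystem(S, c(0.5, 0.05, 0.05))
  ev <- eigen(T, symmetric = TRUE)
  expect_equal(ev$values, c(0.5, 0.05, 0.05), tolerance = 1e-10)
  expect_equal(abs(sum(ev$vectors[, 1] * S[, 1])), 1, tolerance = 1e-10)
  expect_error(tensor_from_eigensystem(matrix(1, 3, 3), c(1, 1, 1)),
               "orthonormal")
})

test_that("volume-constraint normalization preserves the tensor volume", {
  # isotropic raw input maps to the isotropic white-matter value
  expect_equal(normalize_volume_constraint(c(7e-4, 7e-4, 7e-4), 0.126),
               rep(0.126, 3))
  # frozen closed-form example: divide by the geometric mean, scale by sigma_iso
  got <- normalize_volume_constraint(c(4e-4, 1e-4, 1e-4), 0.126)
  expect_equal(got, 0.126 * c(4e-4, 1e-4, 1e-4) / (4e-12)^(1 / 3),
               tolerance = 1e-10)
  expect_equal(got, c(0.31750, 0.07938, 0.07938), tolerance = 1e-4)
  # volume constraint holds for random positive inputs
  set.seed(42)
  ev <- matrix(stats::rlnorm(300, -8, 0.5), ncol = 3)
  out <- normalize_volume_constraint(ev, 0.126)
  expect_equal(out[, 1] * out[, 2] * out[, 3], rep(0.126^3, 100),
               tolerance = 1e-10)
  expect_error(normalize_volume_constraint(c(1e-4, 0, 1e-4)), "positive")
})

test_that("fixed-ratio eigenvalues satisfy both ratio and volume constraints", {
  expect_equal(unname(fixed_ratio_eigenvalues(0.126, 1)), c(0.126, 0.126))
  lt <- fixed_ratio_eigenvalues(0.126, 10)
  expect_equal(unname(lt), c(0.58485, 0.058485), tolerance = 1e-4)
  for (r in c(2, 5, 10)) {
    lt <- fixed_ratio_eigenvalues(0.126, r)
    expect_equal(unname(lt["long"] / lt["trans"]), r, tolerance = 1e-12)
    expect_equal(unname(lt["long"] * lt["trans"]^2), 0.126^3,
                 tolerance = 1e-12)
  }
  expect_error(fixed_ratio_eigenvalues(0.126, 0.5), ">= 1")
})

test_that("fractional anisotropy matches its defining formula", {
  expect_equal(fractional_anisotropy(c(0.2, 0.2, 0.2)), 0)
  expect_equal(fractional_anisotropy(c(1, 0, 0)), 1)
  # brute-force formula oracle
  fa_oracle <- function(l) sqrt(0.5) *
    sqrt((l[1] - l[2])^2 + (l[2] - l[3])^2 + (l[1] - l[3])^2) /
    sqrt(sum(l^2))
  expect_equal(fractional_anisotropy(c(10, 1, 1)), fa_oracle(c(10, 1, 1)))
  expect_equal(fractional_anisotropy(c(10, 1, 1)), 0.89118, tolerance = 1e-4)
  set.seed(7)
  for (i in 1:20) {
    l <- stats::runif(3)
    expect_equal(fractional_anisotropy(l), fa_oracle(l), tolerance = 1e-12)
  }
  expect_error(fractional_anisotropy(c(0, 0, 0)), "all-zero")
  # FA of fixed-ratio tensors depends only on r and grows with it
  fa_r <- vapply(c(2, 5, 10), function(r) {
    lt <- fixed_ratio_eigenvalues(0.126, r)
    fractional_anisotropy(c(lt["long"], lt["trans"], lt["trans"]))
  }, 0)
  expect_true(all(diff(fa_r) > 0))
})

test_that("conductivity fields assign isotropic tissue and WM tensors correctly", {
  mesh <- small_slab_mesh()
  tab <- conductivity_table()
  iso <- build_conductivity_field(mesh, tab)
  # every element scalar: WM elements 0.126 * identity
  wm <- mesh$region == "WM"
  expect_true(all(iso$tensors[wm, 1:3] == 0.126))
  expect_true(all(iso$tensors[, 4:6] == 0))
  expect_true(all(iso$tensors[mesh$region == "CSF", 1] == tab[["CSF"]]))
  expect_true(all(iso$tensors[mesh$region == "GM", 1] == tab[["GM"]]))

  fib <- generate_fiber_field(mesh, "random_smooth", seed = 11)
  # fixed_ratio with r = 1 degenerates to the isotropic field
  r1 <- build_conductivity_field(mesh, tab,
                                 anisotropy_model("fixed_ratio", r = 1), fib)
  expect_equal(max(abs(r1$tensors - iso$tensors)), 0, tolerance = 1e-12)
  # normalized with isotropic synthetic diffusion input is a fixed point
  fib_iso <- generate_fiber_field(mesh, "random_smooth", seed = 11,
                                  diffusion_shape = c(7e-4, 7e-4, 7e-4))
  nrm <- build_conductivity_field(mesh, tab, anisotropy_model("normalized"),
                                  fib_iso)
  expect_equal(max(abs(nrm$tensors - iso$tensors)), 0, tolerance = 1e-12)
  # anisotropy restricted to WM
  r10 <- build_conductivity_field(mesh, tab,
                                  anisotropy_model("fixed_ratio", r = 10), fib)
  expect_true(all(r10$tensors[!wm, 4:6] == 0))
  expect_gt(max(abs(r10$tensors[wm, 4:6])), 0)
  # missing fibers for an anisotropic model error out
  expect_error(build_conductivity_field(mesh, tab,
                                        anisotropy_model("fixed_ratio", r = 2)),
               "fiber")
})

test_that("anisotropic WM tensors preserve determinant and recover eigenvalues", {
  mesh <- small_slab_mesh()
  fib <- generate_fiber_field(mesh, "u_fiber")
  wm <- mesh$region == "WM"
  for (mdl in list(anisotropy_model("fixed_ratio", r = 5),
                   anisotropy_model("normalized"))) {
    fld <- build_conductivity_field(mesh, conductivity_table(), mdl, fib)
    ev <- tensor_eigenvalues(fld)
    expect_equal(unname(apply(ev[wm, ], 1, prod)),
                 rep(0.126^3, sum(wm)), tolerance = 1e-8)
    expect_true(all(ev > 0))
  }
  # fixed-ratio element eigenvalue ratio equals r
  fld5 <- build_conductivity_field(mesh, conductivity_table(),
                                   anisotropy_model("fixed_ratio", r = 5), fib)
  ev <- tensor_eigenvalues(fld5)
  expect_equal(unname(ev[wm, 1] / ev[wm, 3]), rep(5, sum(wm)),
               tolerance = 1e-6)
})

test_that("scalar outputs are invariant under a joint frame rotation", {
  # rotating the fiber directions and evaluating FA/det must not change them
  set.seed(3)
  dirs <- matrix(stats::rnorm(60), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  ev <- matrix(rep(c(0.4, 0.08, 0.08), each = 20), ncol = 3)
  tA <- sucsim:::.tensors_from_fibers(dirs, ev)
  R <- rot_z(0.9)
  tB <- sucsim:::.tensors_from_fibers(dirs %*% t(R), ev)
  to_mat <- function(row) matrix(row[c(1, 4, 5, 4, 2, 6, 5, 6, 3)], 3, 3)
  for (i in c(1, 7, 20)) {
    evA <- eigen(to_mat(tA[i, ]), symmetric = TRUE, only.values = TRUE)$values
    evB <- eigen(to_mat(tB[i, ]), symmetric = TRUE, only.values = TRUE)$values
    expect_equal(evA, evB, tolerance = 1e-10)
  }
})

test_that("voxel tensor volumes sample onto WM elements by nearest voxel", {
  skip_if_not_installed("RNifti")
  mesh <- build_box_mesh(c(8, 8, 8), 1)
  # synthetic tensor volume: prolate tensors along +x for x < 4, along +z
  # beyond; components ordered xx, yy, zz, xy, xz, yz
  dm <- c(8L, 8L, 8L)
  arr <- array(0, dim = c(dm, 6L))
  lam <- c(1.2e-3, 4e-4)
  for (i in 1:8) {
    along_x <- (i - 0.5) < 4
    arr[i, , , 1] <- if (along_x) lam[1] else lam[2]
    arr[i, , , 2] <- lam[2]
    arr[i, , , 3] <- if (along_x) lam[2] else lam[1]
  }
  img <- RNifti::asNifti(arr)
  path <- file.path(tempdir(), "synthetic_tensor.nii.gz")
  RNifti::writeNifti(img, path)
  fib <- fiber_field_from_nifti(mesh, path)
  expect_identical(length(fib$element), nrow(mesh$tets))
  cen <- tet_centroids(mesh)[fib$element, ]
  vx <- round(RNifti::worldToVoxel(cen, img))[, 1]
  is_x <- (vx - 0.5) < 4
  expect_true(all(abs(fib$directions[is_x, 1]) > 0.999))
  expect_true(all(abs(fib$directions[!is_x, 3]) > 0.999))
  expect_equal(unname(fib$eigenvalues[, 1]), rep(lam[1], length(fib$element)),
               tolerance = 1e-8)
  # plugs into the normalized model end to end
  fld <- build_conductivity_field(mesh, conductivity_table(),
                                  anisotropy_model("normalized"), fib)
  ev <- tensor_eigenvalues(fld)
  expect_equal(unname(ev[, 1] * ev[, 2] * ev[, 3]),
               rep(0.126^3, nrow(ev)), tolerance = 1e-10)
})
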