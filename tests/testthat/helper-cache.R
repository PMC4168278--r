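# memoized fixtures shared across test files; everything is generated in
# code, deterministically

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) assign(key, force(expr), .fixture_cache)
  get(key, .fixture_cache)
}

# a reduced slab that keeps every geometric feature (two sulci flanking a
# central gyral crown, CSF sheet, resolved GM) at test-scale cost
small_slab_spec <- function(h = 1) {
  slab_spec(extent_x = 30, extent_y = 24, extent_z = 24,
            gyral_width = 12, sulcal_width = 3, sulcal_depth = 10,
            gm_thickness = 2.5, csf_thickness = 2, resolution_h = h)
}

small_slab_mesh <- function() cached("small_mesh", build_slab_mesh(small_slab_spec()))

# solved small slab, single middle electrode, isotropic, 1 V
small_slab_solved <- function() cached("small_solved", {
  mesh <- small_slab_mesh()
  paddle <- place_paddle_array(mesh)
  ref <- designate_reference(mesh)
  field <- build_conductivity_field(mesh)
  sys <- assemble_system(mesh, field)
  sol <- solve_potential(sys, boundary_conditions(paddle[3], ref, V0 = 1))
  list(mesh = mesh, paddle = paddle, ref = ref, field = field, sys = sys,
       sol = sol, current = electrode_current(sol, sys, paddle[3]))
})

# generic watertightness scan: face multiset of all tets
face_multiplicities <- function(mesh) {
  tt <- mesh$tets
  f <- rbind(tt[, c(1, 2, 3)], tt[, c(1, 2, 4)],
             tt[, c(1, 3, 4)], tt[, c(2, 3, 4)])
  f <- t(apply(f, 1, sort))
  key <- paste(f[, 1], f[, 2], f[, 3])
  table(table(key))
}
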