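# End-to-end experiment orchestration: one config describes geometry,
# electrode mode, conductivity model, stimulation mode and amplitude grids;
# a run produces a summary CSV, solution fields (VTU), and a log, all
# deterministic given the config.

#' Experiment configuration
#'
#' @param slab a [slab_spec()] (default slab if `NULL`).
#' @param electrode_mode `"paddle"` (five contacts wired together) or
#'   `"single"` (the middle contact alone).
#' @param conductivity_model `"isotropic"`, `"normalized"`, `"ratio_2"`,
#'   `"ratio_5"` or `"ratio_10"`.
#' @param fiber_pattern fiber-field pattern for anisotropic models.
#' @param seed fiber-field seed.
#' @param stimulation_mode `"voltage"`, `"current"` or `"both"` (which
#'   amplitude grids the summary covers).
#' @param voltage_grid voltages, V.
#' @param current_grid currents, mA.
#' @param mct motor current-density threshold, A/m^2.
#' @param contact_spacing paddle middle-to-corner spacing, mm.
#' @param electrode_diameter contact diameter, mm.
#' @param solver,solver_tol passed to [solve_potential()].
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(slab = NULL,
                              electrode_mode = c("paddle", "single"),
                              conductivity_model = c("isotropic", "normalized",
                                                     "ratio_2", "ratio_5",
                                                     "ratio_10"),
                              fiber_pattern = "u_fiber",
                              seed = 20140917,
                              stimulation_mode = "both",
                              voltage_grid = seq(0.5, 5, by = 0.5),
                              current_grid = seq(1, 16, by = 2),
                              mct = 2.5,
                              contact_spacing = 10,
                              electrode_diameter = 4,
                              solver = "auto", solver_tol = 1e-8) {
  if (is.null(slab)) slab <- slab_spec()
  electrode_mode <- match.arg(electrode_mode)
  conductivity_model <- match.arg(conductivity_model)
  stopifnot(stimulation_mode %in% c("voltage", "current", "both"))
  structure(list(slab = slab, electrode_mode = electrode_mode,
                 conductivity_model = conductivity_model,
                 fiber_pattern = fiber_pattern, seed = seed,
                 stimulation_mode = stimulation_mode,
                 voltage_grid = voltage_grid, current_grid = current_grid,
                 mct = mct, contact_spacing = contact_spacing,
                 electrode_diameter = electrode_diameter,
                 solver = solver, solver_tol = solver_tol),
            class = "experiment_config")
}

.config_model <- function(config) {
  switch(config$conductivity_model,
    isotropic = anisotropy_model("isotropic"),
    normalized = anisotropy_model("normalized"),
    ratio_2 = anisotropy_model("fixed_ratio", r = 2),
    ratio_5 = anisotropy_model("fixed_ratio", r = 5),
    ratio_10 = anisotropy_model("fixed_ratio", r = 10))
}

#' Write / read an experiment config as YAML
#'
#' @param config an `experiment_config`.
#' @param path file path.
#' @return `read_experiment_config` returns an `experiment_config`.
#' @export
write_experiment_config <- function(config, path) {
  lst <- unclass(config)
  lst$slab <- unclass(lst$slab)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(path) {
  lst <- yaml::read_yaml(path)
  slab <- do.call(slab_spec, lst$slab)
  lst$slab <- NULL
  do.call(experiment_config, c(list(slab = slab), lst))
}

# build mesh + electrodes + conductivity + 1 V solve for a config; the
# reusable core of run_experiment and the comparison/convergence drivers
.solve_config <- function(config, slab = config$slab, mesh = NULL,
                          slim = FALSE) {
  if (is.null(mesh)) mesh <- build_slab_mesh(slab)
  paddle <- place_paddle_array(mesh,
    paddle_layout(center = mesh$grid$extent[1:2] / 2,
                  contact_spacing = config$contact_spacing,
                  diameter = config$electrode_diameter),
    diameter = config$electrode_diameter)
  active <- if (config$electrode_mode == "paddle") paddle else paddle[3]
  model <- .config_model(config)
  fibers <- NULL
  if (model$method != "isotropic")
    fibers <- generate_fiber_field(mesh, config$fiber_pattern,
                                   seed = config$seed)
  field <- build_conductivity_field(mesh, conductivity_table(), model, fibers)
  sys <- assemble_system(mesh, field)
  ref <- designate_reference(mesh)
  bc <- boundary_conditions(active, ref, V0 = 1)
  sol <- solve_potential(sys, bc, solver = config$solver,
                         tol = config$solver_tol)
  i <- electrode_current(sol, sys, active)
  out <- list(mesh = mesh, field = field, system = sys, solution = sol,
              active = active, middle = paddle[[3]], reference = ref,
              current = i, impedance = estimate_impedance(1, i))
  if (slim) {
    # keep only what sweeps/convergence consume; frees the stiffness matrix
    # and vector fields of large runs
    out$system <- NULL
    out$field <- NULL
    out$solution$E <- NULL
    out$solution$J <- NULL
    gc(FALSE)
  }
  out
}

#' Run one end-to-end experiment
#'
#' Builds the slab, places the electrodes, assigns conductivity, solves at
#' 1 V, and writes to `outdir`: `summary.csv` (one row per amplitude with
#' the stimulation metrics), `field_1V.vtu` (potential, current density,
#' region; plus FA for anisotropic models), `log.txt` (mesh and solver
#' statistics) and `config.yaml` (the archived configuration). Reruns with
#' the same config produce byte-identical tables.
#'
#' @param config an [experiment_config()].
#' @param outdir output directory (created if needed).
#' @param write_fields write the VTU field file (default TRUE; tables and
#'   log are always written).
#' @return invisibly, a list with the run directory, the summary table and
#'   the solved objects.
#' @export
run_experiment <- function(config, outdir, write_fields = TRUE) {
  stopifnot(inherits(config, "experiment_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  run <- .solve_config(config)
  cfg <- mct_config(mct = config$mct)
  vg <- if (config$stimulation_mode %in% c("voltage", "both"))
    config$voltage_grid else NULL
  cg <- if (config$stimulation_mode %in% c("current", "both"))
    config$current_grid else NULL
  sweep <- sweep_metrics(run$solution, run$mesh, run$middle, I0 = run$current,
                         cfg = cfg, voltage_grid = vg, current_grid = cg)
  sweep <- cbind(model = "slab",
                 conductivity_model = config$conductivity_model,
                 electrode_config = config$electrode_mode,
                 sweep,
                 impedance_ohm = run$impedance,
                 output_current_mA = 1000 * run$current)
  utils::write.csv(sweep, file.path(outdir, "summary.csv"),
                   row.names = FALSE)
  write_experiment_config(config, file.path(outdir, "config.yaml"))
  if (write_fields) {
    cd <- list(region = as.integer(run$mesh$region),
               Jmag = run$solution$Jmag)
    if (config$conductivity_model != "isotropic")
      cd$FA <- field_fa(run$field)
    write_vtu(file.path(outdir, "field_1V.vtu"), run$mesh,
              point_data = list(V = run$solution$V), cell_data = cd)
  }
  vols <- tet_volumes(run$mesh)
  log_lines <- c(
    sprintf("mesh: %d nodes, %d elements", nrow(run$mesh$nodes),
            nrow(run$mesh$tets)),
    sprintf("element volume range: %.3e to %.3e mm^3 (mean %.3e)",
            min(vols), max(vols), mean(vols)),
    sprintf("regions: %s", paste(sprintf("%s=%d", levels(run$mesh$region),
            tabulate(run$mesh$region, 3L)), collapse = ", ")),
    sprintf("solver: %s, relative residual %.3e", config$solver,
            run$solution$residual),
    sprintf("impedance: %.4f ohm; output current at 1 V: %.4f mA",
            run$impedance, 1000 * run$current))
  writeLines(log_lines, file.path(outdir, "log.txt"))
  invisible(list(outdir = outdir, summary = sweep, run = run))
}

#' Mesh-convergence study
#'
#' Solves the same physical model on successively refined meshes and
#' reports per level the mesh size, impedance, and the maximum relative
#' difference in solved voltage against the previous (coarser) level: the
#' coarse solution is interpolated at the fine-mesh nodes and
#' `max |V_fine - V_coarse| / V0` is expressed in percent.
#'
#' Refinement is nested (see [refine_mesh_z()]): each level splits the
#' upper portion of the depth-axis layers of the previous mesh in two, so
#' all levels discretize the identical conductivity geometry and carry the
#' identical electrode surface. This isolates discretization error — with
#' re-voxelized geometry or re-discretized electrode patches, the maximum
#' nodal difference would be dominated by the shifted material interfaces
#' and electrode rim rather than by mesh resolution.
#'
#' @param config an [experiment_config()].
#' @param levels number of mesh levels (at least 2).
#' @param growth target element-count growth factor per level (default
#'   5/3, i.e. the top two thirds of the z-layers are split).
#' @return data.frame with columns level, n_nodes, n_elements,
#'   impedance_ohm, max_rel_diff_pct (NA for the first level).
#' @export
run_convergence <- function(config, levels = 2, growth = 5 / 3) {
  stopifnot(levels >= 2, growth > 1, growth <= 2)
  base <- .solve_config(config, slim = TRUE)
  mesh <- base$mesh
  out <- list(data.frame(level = 1L, n_nodes = nrow(mesh$nodes),
                         n_elements = nrow(mesh$tets),
                         impedance_ohm = base$impedance,
                         max_rel_diff_pct = NA_real_))
  prev <- base
  for (lv in seq_len(levels - 1L) + 1L) {
    nz <- prev$mesh$grid$n[3]
    nsplit <- max(1L, min(nz, round((growth - 1) * nz)))
    mesh_f <- refine_mesh_z(prev$mesh, seq.int(nz - nsplit + 1L, nz))
    run <- .solve_config(config, mesh = mesh_f, slim = TRUE)
    vc <- interpolate_nodal(prev$mesh, prev$solution$V, mesh_f$nodes)
    diff_pct <- 100 * max(abs(run$solution$V - vc)) / run$solution$V0
    out[[lv]] <- data.frame(level = lv, n_nodes = nrow(mesh_f$nodes),
                            n_elements = nrow(mesh_f$tets),
                            impedance_ohm = run$impedance,
                            max_rel_diff_pct = diff_pct)
    prev <- run
  }
  do.call(rbind, out)
}

#' Compare stimulation models side by side
#'
#' Runs (or takes) several configurations sharing the same threshold and
#' amplitude grids and joins their sweep tables, adding ratio columns of
#' effective volume and depth relative to the first configuration.
#'
#' @param configs list of [experiment_config()] objects.
#' @param sweeps optional list of precomputed summary tables (as returned in
#'   `run_experiment()$summary`); computed from `configs` when `NULL`.
#' @param labels names for the configurations.
#' @return data.frame in long format with `label`, the sweep columns, and
#'   `volume_ratio` / `depth_ratio` columns (vs the first configuration).
#' @export
compare_models <- function(configs, sweeps = NULL, labels = NULL) {
  n <- if (is.null(sweeps)) length(configs) else length(sweeps)
  stopifnot(n >= 2)
  if (is.null(labels)) labels <- paste0("config_", seq_len(n))
  if (is.null(sweeps)) {
    same_mct <- length(unique(vapply(configs, `[[`, 0, "mct"))) == 1
    grids_ok <- all(vapply(configs, function(cf)
      identical(cf$voltage_grid, configs[[1]]$voltage_grid) &&
      identical(cf$current_grid, configs[[1]]$current_grid), TRUE))
    if (!same_mct || !grids_ok)
      stop("configurations must share mct and amplitude grids", call. = FALSE)
    sweeps <- lapply(configs, function(cf) {
      run <- .solve_config(cf)
      sw <- sweep_metrics(run$solution, run$mesh, run$middle,
                          I0 = run$current, cfg = mct_config(mct = cf$mct),
                          voltage_grid = cf$voltage_grid,
                          current_grid = cf$current_grid)
      cbind(conductivity_model = cf$conductivity_model,
            electrode_config = cf$electrode_mode, sw,
            impedance_ohm = run$impedance,
            output_current_mA = 1000 * run$current)
    })
  }
  base <- sweeps[[1]]
  key <- function(s) paste(s$mode, s$amplitude)
  for (s in sweeps[-1])
    if (!identical(key(s), key(base)))
      stop("sweep tables have mismatched amplitude grids", call. = FALSE)
  out <- do.call(rbind, Map(function(s, lb) cbind(label = lb, s),
                            sweeps, labels))
  bvol <- base$effective_volume_cm3[match(key(out), key(base))]
  bdep <- base$effective_depth_cm[match(key(out), key(base))]
  out$volume_ratio <- ifelse(bvol > 0, out$effective_volume_cm3 / bvol, NA)
  out$depth_ratio <- ifelse(bdep > 0, out$effective_depth_cm / bdep, NA)
  rownames(out) <- NULL
  out
}
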