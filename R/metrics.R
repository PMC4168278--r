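# Quantitative stimulation-effect measures: effective volume (tissue with
# current density above the motor current-density threshold), effective
# penetration depth along the electrode's inward normal, impedance, and the
# voltage/current sweep tables. One linear solve per configuration: all
# amplitudes follow by linearity.

#' Motor current-density threshold configuration
#'
#' @param mct threshold current-density magnitude, A/m^2. The default
#'   2.5 A/m^2 is a motor-cortex excitation threshold for low-frequency
#'   (50 Hz) stimulation; the solver itself is quasi-static, the frequency
#'   is metadata.
#' @param eligible_regions tissue labels counted toward the metrics;
#'   defaults to gray and white matter (CSF carries high current density
#'   but contains no excitable tissue).
#' @return object of class `mct_config`.
#' @export
mct_config <- function(mct = 2.5, eligible_regions = c("GM", "WM")) {
  if (!is.finite(mct) || mct <= 0) stop("mct must be positive", call. = FALSE)
  if (!length(eligible_regions))
    stop("eligible_regions must be non-empty", call. = FALSE)
  structure(list(mct = mct, eligible_regions = eligible_regions),
            class = "mct_config")
}

#' Effective stimulation volume
#'
#' Total volume of eligible-region elements whose current-density magnitude
#' reaches the threshold (inclusive at equality), in cm^3.
#'
#' @param solution a solved `potential_solution` (with `Jmag`).
#' @param mesh the mesh it was solved on.
#' @param cfg an [mct_config()].
#' @return effective volume in cm^3.
#' @export
effective_volume <- function(solution, mesh, cfg = mct_config()) {
  eligible <- mesh$region %in% cfg$eligible_regions
  hit <- eligible & solution$Jmag >= cfg$mct
  if (!any(hit)) return(0)
  sum(tet_volumes(mesh)[hit]) / 1000        # mm^3 -> cm^3
}

# ray samples used for depth: distances t (mm) from the start point plus
# element id and region at each sample; samples lie at a fixed 0.1 mm grid
# plus both sides of every grid-plane crossing
.depth_ray_samples <- function(mesh, start, direction, step = 0.1) {
  dirn <- direction / sqrt(sum(direction^2))
  ext <- mesh$grid$extent
  # ray-box exit distance
  tmax <- Inf
  for (ax in 1:3) {
    if (dirn[ax] > 1e-12) tmax <- min(tmax, (ext[ax] - start[ax]) / dirn[ax])
    if (dirn[ax] < -1e-12) tmax <- min(tmax, (0 - start[ax]) / dirn[ax])
    if (abs(dirn[ax]) <= 1e-12 && (start[ax] < 0 || start[ax] > ext[ax]))
      tmax <- -Inf
  }
  if (!is.finite(tmax) || tmax <= 0)
    stop("ray does not intersect the mesh", call. = FALSE)
  t <- seq(0, tmax, by = step)
  # crossings of the structured grid planes along the ray
  eps <- 1e-6
  for (ax in 1:3) {
    if (abs(dirn[ax]) > 1e-12) {
      planes <- mesh$grid$coords[[ax]]
      tc <- (planes - start[ax]) / dirn[ax]
      tc <- tc[tc > 0 & tc < tmax]
      t <- c(t, tc - eps, tc + eps)
    }
  }
  t <- sort(unique(pmin(pmax(t, 0), tmax)))
  pts <- cbind(start[1] + t * dirn[1], start[2] + t * dirn[2],
               start[3] + t * dirn[3])
  el <- locate_points(mesh, pts)$element
  list(t = t, element = el, region = mesh$region[el])
}

#' Effective penetration depth
#'
#' Distance from the electrode center along the inward surface normal to
#' the farthest point (in an eligible region) where the current-density
#' magnitude reaches the threshold. The ray is sampled at every structured
#' grid-plane crossing plus a fixed 0.1 mm step; returns 0 when no sample
#' is suprathreshold.
#'
#' @param solution a solved `potential_solution`.
#' @param mesh the mesh it was solved on.
#' @param electrode_center 3-D point on the electrode surface, mm.
#' @param inward_normal direction into the tissue (default `c(0, 0, -1)`,
#'   the slab's top-surface inward normal).
#' @param cfg an [mct_config()].
#' @return effective depth in cm.
#' @export
effective_depth <- function(solution, mesh, electrode_center,
                            inward_normal = c(0, 0, -1),
                            cfg = mct_config()) {
  s <- .depth_ray_samples(mesh, electrode_center, inward_normal)
  ok <- (s$region %in% cfg$eligible_regions) &
        (solution$Jmag[s$element] >= cfg$mct)
  if (!any(ok)) return(0)
  max(s$t[ok]) / 10                         # mm -> cm
}

#' Impedance from applied voltage and measured current
#'
#' Ohm's law: `impedance = V0 / I`, the conversion the model uses to map
#' between voltage-controlled and current-controlled stimulation.
#'
#' @param V0 applied voltage, volts.
#' @param total_current total electrode current, amperes.
#' @return impedance in ohms.
#' @export
estimate_impedance <- function(V0, total_current) {
  if (!is.finite(total_current) || total_current <= 0)
    stop("total current must be positive", call. = FALSE)
  V0 / total_current
}

#' Rescale a solved field to another stimulation amplitude
#'
#' By linearity of the conduction problem, the solution at any amplitude is
#' a scalar multiple of the solved one: voltage mode scales by
#' `amplitude / V0`; current mode (amplitude in mA) scales by
#' `amplitude / (1000 * I0)` where `I0` is the measured current in A.
#'
#' @param solution a solved `potential_solution`.
#' @param mode `"voltage"` or `"current"`.
#' @param amplitude target amplitude: volts for voltage mode, mA for
#'   current mode.
#' @param I0 measured total current (A) of `solution`; required for
#'   current mode.
#' @return the rescaled `potential_solution` (fields `V`, `E`, `J`, `Jmag`,
#'   `V0` scaled; `amplitude` and `mode` recorded).
#' @export
convert_mode <- function(solution, mode = c("voltage", "current"),
                         amplitude, I0 = NULL) {
  mode <- match.arg(mode)
  if (!is.finite(amplitude) || amplitude <= 0)
    stop("amplitude must be positive", call. = FALSE)
  k <- if (mode == "voltage") {
    amplitude / solution$V0
  } else {
    if (is.null(I0)) stop("current mode requires the measured current I0",
                          call. = FALSE)
    (amplitude / 1000) / I0
  }
  solution$V <- solution$V * k
  solution$E <- solution$E * k
  solution$J <- solution$J * k
  solution$Jmag <- solution$Jmag * k
  solution$V0 <- solution$V0 * k
  solution$mode <- mode
  solution$amplitude <- amplitude
  solution
}

#' Stimulation metrics of one solved configuration
#'
#' @param solution a solved `potential_solution`.
#' @param mesh the mesh it was solved on.
#' @param electrode the patch depth is measured from (for the paddle, the
#'   middle contact).
#' @param I0 measured total current in amperes.
#' @param cfg an [mct_config()].
#' @return one-row data.frame: amplitude (V), effective volume (cm^3),
#'   effective depth (cm), impedance (ohm), output current (mA).
#' @export
stimulation_metrics <- function(solution, mesh, electrode, I0,
                                cfg = mct_config()) {
  data.frame(
    applied_voltage_V = solution$V0,
    effective_volume_cm3 = effective_volume(solution, mesh, cfg),
    effective_depth_cm = effective_depth(solution, mesh, electrode$center,
                                         -electrode$normal, cfg),
    impedance_ohm = estimate_impedance(solution$V0, I0),
    output_current_mA = 1000 * I0
  )
}

#' Amplitude sweep by threshold rescaling
#'
#' Computes effective volume and depth over voltage and current amplitude
#' grids from a single solve: at scale factor `k` the suprathreshold set of
#' the scaled field equals the set where the solved field exceeds
#' `mct / k`, so no re-solve is needed. Default grids are 0.5-5.0 V in
#' 0.5 V steps and 1-16 mA in 2 mA steps.
#'
#' @param solution a solved `potential_solution` (typically at 1 V).
#' @param mesh the mesh it was solved on.
#' @param electrode patch the depth ray starts from.
#' @param I0 measured total current, A (needed for the current grid).
#' @param cfg an [mct_config()].
#' @param voltage_grid voltages, V (`NULL` to skip).
#' @param current_grid currents, mA (`NULL` to skip).
#' @return data.frame with columns mode, amplitude, effective_volume_cm3,
#'   effective_depth_cm.
#' @export
sweep_metrics <- function(solution, mesh, electrode, I0 = NULL,
                          cfg = mct_config(),
                          voltage_grid = seq(0.5, 5, by = 0.5),
                          current_grid = seq(1, 16, by = 2)) {
  vols <- tet_volumes(mesh)
  eligible <- mesh$region %in% cfg$eligible_regions
  ray <- .depth_ray_samples(mesh, electrode$center, -electrode$normal)
  ray_ok <- ray$region %in% cfg$eligible_regions
  jm <- solution$Jmag

  one <- function(mode, amplitude, k) {
    thr <- cfg$mct / k
    hit <- eligible & jm >= thr
    ok <- ray_ok & jm[ray$element] >= thr
    data.frame(mode = mode, amplitude = amplitude,
               effective_volume_cm3 = sum(vols[hit]) / 1000,
               effective_depth_cm = if (any(ok)) max(ray$t[ok]) / 10 else 0)
  }
  rows <- list()
  for (a in voltage_grid)
    rows[[length(rows) + 1L]] <- one("voltage", a, a / solution$V0)
  if (length(current_grid)) {
    if (is.null(I0))
      stop("current-mode sweep requires the measured current I0", call. = FALSE)
    for (a in current_grid)
      rows[[length(rows) + 1L]] <- one("current", a, (a / 1000) / I0)
  }
  do.call(rbind, rows)
}
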