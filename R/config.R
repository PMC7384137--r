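# Scenario configuration: defaults, YAML loading, validation, unit
# conversion. Configuration values use the field-natural units stated in
# the key names (um, cm/s, g/cm^3, Bq/mg); everything is converted to SI
# when the simulation objects are built.

#' Reference simulation configuration
#'
#' Defaults reproduce the integration-test scenario: a 30 x 8 um capillary
#' segment on a 750 x 200 grid, inlet 0.03 cm/s, blood density
#' 1.025 g/cm^3, viscosity 4e-3 Pa.s, dt 1e-5 s over 0.1 s, 158 sources of
#' radius 0.2 um carrying Bi-213 at a specific activity of 1.184e8 Bq/mg,
#' two perivascular targets at (-75, 22) and (105, 22) um, and 50000
#' Monte Carlo samples per spectrum.
#'
#' @param desk logical; `TRUE` returns the scaled-down desk configuration
#'   (150 x 40 grid, dt 1e-4 s over 0.01 s, 20 sources) that preserves the
#'   physics regimes at a fraction of the cost.
#' @return A nested list of configuration values.
#' @export
default_config <- function(desk = FALSE) {
  cfg <- list(
    grid = list(nx = 750L, ny = 200L, Lx_um = 30, Ly_um = 8),
    fluid = list(density_g_cm3 = 1.025, viscosity_Pa_s = 4.0e-3),
    bc = list(u_in_cm_s = 0.03),
    time = list(dt_s = 1.0e-5, t_end_s = 0.1),
    sources = list(count = 158L, radius_um = 0.2,
                   specific_activity_Bq_mg = 1.184e8,
                   first = c(7.25, 4.0),
                   x_range = c(3, 25), y_range = c(1, 7),
                   min_gap_um = 0.1, seed = 20201L,
                   positions = NULL,
                   restitution = 1, drag = "stokes"),
    chain = "bi213_simple",
    targets = list(
      list(x_um = -75, y_um = 22, cell_radius_um = 5, nucleus_radius_um = 4),
      list(x_um = 105, y_um = 22, cell_radius_um = 5, nucleus_radius_um = 4)
    ),
    mc = list(n_samples = 50000L, seed = 11L, recompute_distance_um = 0.5),
    flow = list(tol = 0.5e-6, max_iter = 5000L, relax_u = 0.7, relax_p = 0.3),
    output = list(dir = NULL, snapshot_every = 0L, trajectory_every = 1L)
  )
  if (desk) {
    cfg$grid$nx <- 150L; cfg$grid$ny <- 40L
    cfg$time$dt_s <- 1.0e-4; cfg$time$t_end_s <- 0.01
    cfg$sources$count <- 20L
  }
  cfg
}

# Recursive merge that rejects keys absent from the reference structure.
merge_config <- function(base, user, path = "") {
  if (is.null(user)) return(base)
  if (!is.list(user)) return(user)
  unknown <- setdiff(names(user), names(base))
  if (length(unknown) > 0L)
    stop_config("load_config: unknown key(s): %s",
                paste0(sub("^\\.", "", paste0(path, ".", unknown)),
                       collapse = ", "))
  for (k in names(user)) {
    base[[k]] <- if (is.list(base[[k]]) && !is.null(names(base[[k]])) &&
                     k != "targets" && k != "positions") {
      merge_config(base[[k]], user[[k]], paste0(path, ".", k))
    } else {
      user[[k]]
    }
  }
  base
}

validate_config <- function(cfg) {
  bad <- character(0)
  chk <- function(ok, key) if (!isTRUE(ok)) bad <<- c(bad, key)
  chk(cfg$grid$nx >= 4 && cfg$grid$ny >= 4, "grid.nx/grid.ny (>= 4)")
  chk(cfg$grid$Lx_um > 0 && cfg$grid$Ly_um > 0, "grid.Lx_um/grid.Ly_um (> 0)")
  chk(cfg$fluid$density_g_cm3 > 0, "fluid.density_g_cm3 (> 0)")
  chk(cfg$fluid$viscosity_Pa_s > 0, "fluid.viscosity_Pa_s (> 0)")
  chk(cfg$bc$u_in_cm_s >= 0, "bc.u_in_cm_s (>= 0)")
  chk(is.numeric(cfg$time$dt_s) && cfg$time$dt_s > 0, "time.dt_s (> 0)")
  chk(cfg$time$t_end_s >= cfg$time$dt_s, "time.t_end_s (>= dt_s)")
  chk(cfg$sources$count >= 1, "sources.count (>= 1)")
  chk(cfg$sources$radius_um > 0, "sources.radius_um (> 0)")
  chk(cfg$sources$specific_activity_Bq_mg >= 0,
      "sources.specific_activity_Bq_mg (>= 0)")
  chk(cfg$sources$min_gap_um >= 0, "sources.min_gap_um (>= 0)")
  chk(cfg$sources$restitution >= 0 && cfg$sources$restitution <= 1,
      "sources.restitution (in [0, 1])")
  chk(cfg$sources$drag %in% c("stokes", "tracer"), "sources.drag")
  chk(cfg$chain %in% c("bi213_simple", "bi213_full"), "chain")
  chk(length(cfg$targets) >= 1, "targets (>= 1 entry)")
  for (tg in cfg$targets)
    chk(tg$nucleus_radius_um > 0 && tg$nucleus_radius_um <= tg$cell_radius_um,
        "targets.nucleus_radius_um (in (0, cell_radius_um])")
  chk(cfg$mc$n_samples >= 1, "mc.n_samples (>= 1)")
  chk(cfg$mc$recompute_distance_um >= 0, "mc.recompute_distance_um (>= 0)")
  chk(cfg$flow$tol > 0, "flow.tol (> 0)")
  chk(cfg$flow$max_iter >= 1, "flow.max_iter (>= 1)")
  if (length(bad) > 0L)
    stop_config("invalid configuration value(s) for: %s",
                paste(bad, collapse = "; "))
  cfg
}

#' Load and validate a simulation configuration
#'
#' Reads a YAML file, merges it over the reference defaults (an empty file
#' yields the reference scenario), rejects unknown keys, validates every
#' value, and attaches the SI conversions used by the solvers
#' (`density` kg/m^3, `u_in` m/s).
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @param overrides optional nested list merged on top of the file.
#' @param desk start from the desk-scale defaults (see [default_config()]).
#' @return A validated list of class `simulation_config` with an `si`
#'   element holding the converted values.
#' @export
load_config <- function(path = NULL, overrides = NULL, desk = FALSE) {
  cfg <- default_config(desk = desk)
  if (!is.null(path)) {
    if (!file.exists(path)) stop_config("load_config: no such file: %s", path)
    user <- yaml::read_yaml(path)
    cfg <- merge_config(cfg, user)
  }
  if (!is.null(overrides)) cfg <- merge_config(cfg, overrides)
  cfg <- validate_config(cfg)
  cfg$si <- list(
    density = cfg$fluid$density_g_cm3 * 1000,   # g/cm^3 -> kg/m^3
    viscosity = cfg$fluid$viscosity_Pa_s,
    u_in = cfg$bc$u_in_cm_s * 1e-2              # cm/s -> m/s
  )
  class(cfg) <- "simulation_config"
  cfg
}

#' Derived scenario quantities
#'
#' Head-of-run bookkeeping derived from the configuration: the
#' water-equivalent conjugate mass of the lumen (a cylinder of radius
#' `Ly/2` and length `Lx`), the total administered activity it carries,
#' the per-source activity, the total number of payload atoms, and the
#' cumulated activity the sources would deliver over the simulation window
#' if motionless.
#'
#' The mass conversion uses a water-equivalent density of 1000 kg/m^3,
#' consistent with modelling all tissue and the conjugate as water; for
#' the reference scenario this gives 1.508e-6 mg, 178.5 Bq total,
#' 1.13 Bq per source, 7.05e5 atoms and 17.85 Bq.s motionless cumulated
#' activity.
#'
#' @param config a [load_config()] result.
#' @param equivalent_density_kg_m3 density used for the conjugate-mass
#'   conversion (water by default).
#' @return A list of named scalars.
#' @export
derive_scenario_quantities <- function(config,
                                       equivalent_density_kg_m3 = 1000) {
  stopifnot(inherits(config, "simulation_config"))
  Lx <- um(config$grid$Lx_um); Ly <- um(config$grid$Ly_um)
  vol <- pi * (Ly / 2)^2 * Lx                     # m^3
  mass_mg <- vol * equivalent_density_kg_m3 * 1e6  # kg -> mg
  total_A <- config$sources$specific_activity_Bq_mg * mass_mg
  per_source_A <- total_A / config$sources$count
  chain <- builtin_decay_chain(config$chain)
  parent <- chain$nuclides[[1L]]
  lam <- decay_constant(parent$half_life)
  list(
    equivalent_mass_mg = mass_mg,
    total_activity_Bq = total_A,
    per_source_activity_Bq = per_source_A,
    total_atoms = atoms_from_activity(total_A, lam),
    parent_nuclide = parent$name,
    decay_constant_per_s = lam,
    motionless_cumulated_activity_Bq_s =
      cumulated_activity(total_A, lam, 0, config$time$t_end_s)
  )
}
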