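#' Load and validate a run configuration
#'
#' Configurations are YAML with blocks \code{scenario}, \code{geometry},
#' \code{fluid}, \code{particle}, \code{acoustic}, \code{numerics} and
#' \code{output}.  Defaults are filled from \code{\link{focusingDefaults}}
#' where applicable; validation failures name the offending key, and a
#' derived relaxation time at or below 1/2 is a stability error.
#'
#' @param path path to a YAML config file.
#' @return a validated \code{run_config} list.
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) .stop_config(sprintf("config file '%s' not found", path))
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$scenario) ||
      !cfg$scenario %in% c("poiseuille", "cavity", "cylinder", "focus", "sweep"))
    .stop_config("config key 'scenario' must be one of poiseuille, cavity, cylinder, focus, sweep")
  d <- focusingDefaults()
  cfg$fluid <- modifyList(list(density = d$rho_f, viscosity = d$nu_phys,
                               compressibility = d$beta_f,
                               lattice_viscosity = d$nu_lbm), cfg$fluid %||% list())
  tau <- cfg$fluid$lattice_viscosity * 3 + 0.5
  if (tau <= 0.5 + 1e-12)
    .stop_stability(sprintf(
      "numerics: lattice viscosity %g gives tau = %g <= 0.5 (nu = cs^2 (tau - 1/2))",
      cfg$fluid$lattice_viscosity, tau))
  if (cfg$scenario %in% c("focus", "sweep")) {
    cfg$geometry <- modifyList(list(width = d$width, ny = d$ny, nx = d$nx,
                                    re = d$re), cfg$geometry %||% list())
    if (is.null(cfg$acoustic) || is.null(cfg$acoustic$wavelength))
      .stop_config("missing required key 'acoustic.wavelength' for the focusing scenario")
    cfg$acoustic <- modifyList(list(energy_density = d$energy_density,
                                    phase_offset = cfg$acoustic$wavelength / 4,
                                    active = TRUE), cfg$acoustic)
    cfg$particle <- modifyList(list(radius = 5e-6, density = 1050,
                                    compressibility = 2.49e-10),
                               cfg$particle %||% list())
    for (nm in c("radius", "density", "compressibility"))
      if (cfg$particle[[nm]] <= 0)
        .stop_config(sprintf("config key 'particle.%s' must be > 0", nm))
    u_lat <- cfg$geometry$re * cfg$fluid$lattice_viscosity / cfg$geometry$ny
    if (u_lat >= 0.1)
      .stop_stability("geometry: lattice Mach number exceeds 0.1; reduce Re or refine the grid")
  }
  cfg$numerics <- modifyList(list(max_steps = d$max_steps,
                                  steady_tol = d$steady_tol,
                                  steady_window = d$steady_window),
                             cfg$numerics %||% list())
  cfg$output <- modifyList(list(dir = ".", snapshot_every = 0),
                           cfg$output %||% list())
  structure(cfg, class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Execute a validated configuration
#'
#' Dispatches to the scenario drivers and writes the configured outputs
#' (trajectory CSV, field snapshot, JSON run summary).
#'
#' @param cfg a \code{run_config} from \code{\link{loadConfig}}.
#' @param out_dir output directory (overrides the config's output block).
#' @return the scenario result, invisibly.
#' @export
runScenario <- function(cfg, out_dir = NULL) {
  if (!inherits(cfg, "run_config")) .stop_config("expected a run_config")
  dir <- out_dir %||% cfg$output$dir
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  res <- switch(cfg$scenario,
    poiseuille = runPoiseuille(),
    cavity = runCavity(),
    cylinder = runCylinder(),
    focus = ,
    sweep = {
      d <- modifyList(focusingDefaults(),
                      c(cfg$geometry[c("width", "ny", "nx", "re")],
                        list(nu_lbm = cfg$fluid$lattice_viscosity,
                             rho_f = cfg$fluid$density,
                             beta_f = cfg$fluid$compressibility,
                             energy_density = cfg$acoustic$energy_density,
                             wavelength = cfg$acoustic$wavelength,
                             max_steps = cfg$numerics$max_steps,
                             steady_tol = cfg$numerics$steady_tol,
                             steady_window = cfg$numerics$steady_window)))
      part <- particleSpec(cfg$particle$radius, cfg$particle$density,
                           cfg$particle$compressibility)
      ac <- acousticConfig(wavelength = cfg$acoustic$wavelength,
                           energy_density = cfg$acoustic$energy_density,
                           phase_offset = cfg$acoustic$phase_offset,
                           active = cfg$acoustic$active %||% TRUE,
                           fluid_density = cfg$fluid$density,
                           fluid_compressibility = cfg$fluid$compressibility)
      if (cfg$scenario == "focus") {
        tr <- runFocusing(particle = part, acoustic = ac,
                          initial_y = cfg$geometry$initial_y %||% 70e-6,
                          defaults = d)
        writeTrajectory(tr, file.path(dir, "trajectory.csv"))
        writeSnapshot(attr(tr, "field"), file.path(dir, "snapshot.vtk"),
                      attr(tr, "membrane"))
        writeRunSummary(list(settled = attr(tr, "settled"),
                             settle_time_s = attr(tr, "settle_time_s"),
                             steady_y_um = 1e6 * attr(tr, "steady_y_m"),
                             config = attr(tr, "config"),
                             units = attr(tr, "units")),
                        file.path(dir, "summary.json"))
        tr
      } else {
        sw <- sweepFocusing(cfg$sweep$parameter, unlist(cfg$sweep$values),
                            particle = part, acoustic = ac, defaults = d)
        for (nm in names(sw))
          writeTrajectory(sw[[nm]],
                          file.path(dir, sprintf("trajectory_%s.csv", nm)))
        sw
      }
    })
  if (cfg$scenario %in% c("poiseuille", "cavity", "cylinder"))
    writeRunSummary(list(scenario = cfg$scenario,
                         error_norm = res$error_norm,
                         reference = res$reference_id),
                    file.path(dir, "summary.json"))
  invisible(res)
}
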