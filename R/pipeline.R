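#' Pipeline configuration
#'
#' Bundles everything one virtual-surgery comparison needs: the candidate
#' designs, the anatomical layout, the rest boundary set, the exercise levels
#' to simulate, solver settings, grid spacing and particle-tracking settings.
#'
#' @param designs list of [conduit_design()]s (>= 1).
#' @param layout an [anatomical_layout()].
#' @param boundaries the rest [boundary_set()]; exercise levels are derived
#'   from it with [apply_protocol()].
#' @param levels character vector of exercise levels to run (>= 1).
#' @param solver a [solver_config()]. The advective time step is divided by
#'   the IVC flow multiplier at each exercise level so the CFL bound holds as
#'   velocities scale up.
#' @param spacing voxel spacing, mm.
#' @param particles list: `per_step` tracers per release event (0 disables
#'   tracking), `dt` integration step (s), `drain_cycles`, and
#'   `snapshots_per_cycle` stored for interpolation.
#' @param seed integer seed for particle seeding.
#' @param outdir output directory.
#' @param write_fields also export cycle-averaged fields as VTK (large).
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(designs, layout = anatomical_layout(),
                            boundaries = default_boundaries(),
                            levels = c("rest", "light", "moderate", "heavy"),
                            solver = solver_config(),
                            spacing = 1.5,
                            particles = list(per_step = 50, dt = 0.005,
                                             drain_cycles = 2,
                                             snapshots_per_cycle = 24),
                            seed = 20260920, outdir = tempfile("fontanflow"),
                            write_fields = FALSE) {
  if (length(designs) < 1) validation_error("need at least one design")
  if (!all(vapply(designs, inherits, TRUE, "conduit_design")))
    validation_error("designs must be conduit_design objects")
  if (length(levels) < 1) validation_error("need at least one exercise level")
  for (lv in levels) exercise_protocol(lv)  # validates names up front
  labs <- vapply(designs, `[[`, "", "label")
  if (anyDuplicated(labs)) validation_error("design labels must be unique")
  structure(list(designs = setNames(designs, labs), layout = layout,
                 boundaries = boundaries, levels = levels, solver = solver,
                 spacing = spacing, particles = particles,
                 seed = as.integer(seed), outdir = outdir,
                 write_fields = isTRUE(write_fields)),
            class = "pipeline_config")
}

#' Desk-scale demonstration configuration
#'
#' The four reference designs (20 mm T; 20-10, 20-12, 20-14 mm Y) under all
#' four exercise levels with the study's cycle settings (2.54 s period,
#' 0.001 s step), at desk scale: 1.5 mm grid, 2 simulated cycles with the
#' final cycle averaged, 50 tracer particles per release event.
#'
#' @param outdir output directory.
#' @param seed particle-seeding seed.
#' @return a [pipeline_config()].
#' @export
make_demo_config <- function(outdir = tempfile("fontanflow"),
                             seed = 20260920) {
  pipeline_config(
    designs = reference_designs(),
    layout = anatomical_layout(),
    boundaries = default_boundaries(),
    levels = c("rest", "light", "moderate", "heavy"),
    solver = solver_config(time_step = 0.001, cycle_period = 2.54,
                           n_cycles = 2, pressure_tolerance = 1e-5),
    spacing = 1.5,
    particles = list(per_step = 50, dt = 0.005, drain_cycles = 2,
                     snapshots_per_cycle = 24),
    seed = seed, outdir = outdir
  )
}

# Peak-speed factor of a design relative to its inlet: a Y-graft whose
# branch cross-sections sum to less than the trunk accelerates the flow by
# the area contraction (2 for the diameter-preserving 20-10-10 graft).
design_speed_factor <- function(design) {
  if (design$topology != "Y") return(1)
  max(1, design$trunk_diameter^2 / (2 * design$branch_diameter^2))
}

# Time step scaled down with the peak speeds so the advective CFL bound
# keeps holding: local jet speeds reach roughly twice the peak inlet speed,
# exercise multiplies the inflow, and narrow Y-branches add their area
# contraction; the QUICK/AB2 scheme is stable to about CFL 0.5.
level_solver_config <- function(solver, protocol, design = NULL) {
  mult <- max(protocol$ivc_flow_multiplier, protocol$svc_flow_multiplier)
  fac <- if (is.null(design)) 1 else design_speed_factor(design)
  div <- if (solver$advection_scheme == "quick") 2 * mult * fac
         else mult * fac
  if (div <= 1) return(solver)
  nsteps <- ceiling(solver$cycle_period / (solver$time_step / div))
  solver_config(time_step = solver$cycle_period / nsteps,
                cycle_period = solver$cycle_period,
                n_cycles = solver$n_cycles,
                pressure_tolerance = solver$pressure_tolerance,
                advection_scheme = solver$advection_scheme,
                cfl_limit = solver$cfl_limit,
                cg_maxiter = solver$cg_maxiter,
                outlet_relax = solver$outlet_relax)
}

#' Build, voxelize and simulate one design at one exercise level
#'
#' Convenience wrapper around [build_design()], [voxelize()],
#' [apply_protocol()] and [solve_cycles()] with the same CFL-driven time-step
#' scaling the pipeline uses.
#'
#' @param design a [conduit_design()].
#' @param level exercise level name.
#' @param layout an [anatomical_layout()].
#' @param boundaries the rest [boundary_set()].
#' @param solver reference [solver_config()].
#' @param spacing voxel spacing, mm.
#' @param snapshots_per_cycle snapshots stored for particle tracking.
#' @return list with `tree`, `mask` and the solved `series`.
#' @export
simulate_design <- function(design, level = "rest",
                            layout = anatomical_layout(),
                            boundaries = default_boundaries(),
                            solver = solver_config(n_cycles = 2,
                                                   pressure_tolerance = 1e-5),
                            spacing = 1.5, snapshots_per_cycle = 0) {
  tree <- build_design(design, layout)
  mask <- voxelize(tree, spacing)
  b <- apply_protocol(boundaries, level)
  scfg <- level_solver_config(solver, b$protocol, design)
  series <- solve_cycles(mask, b, fluid_properties(), scfg,
                         snapshots_per_cycle = snapshots_per_cycle)
  list(tree = tree, mask = mask, series = series)
}

#' Run the full virtual-surgery comparison
#'
#' For every design x exercise level: builds and voxelizes the geometry,
#' solves the pulsatile cycles, computes the hemodynamic indicators and
#' (when enabled) the particle flow split; then scores all designs and
#' selects the winner. All outputs are written under `config$outdir` and
#' listed in the run manifest.
#'
#' @param config a [pipeline_config()].
#' @param progress print per-stage progress lines.
#' @return list with `reports` (data.frame), `card` (the [rank_and_score()]
#'   score card), `splits`, and `manifest`.
#' @export
run_pipeline <- function(config, progress = FALSE) {
  if (!inherits(config, "pipeline_config"))
    validation_error("config must be a pipeline_config")
  for (lv in config$levels) exercise_protocol(lv)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  reports <- list()
  splits <- list()
  with_stage <- function(stage, design, level, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed for design %s, level %s: %s",
                   stage, design, level, conditionMessage(e)), call. = FALSE)
    })
  }
  run_idx <- 0L
  for (dg in names(config$designs)) {
    design <- config$designs[[dg]]
    tree <- with_stage("geometry", dg, "-",
                       build_design(design, config$layout))
    mask <- with_stage("voxelize", dg, "-", voxelize(tree, config$spacing))
    gf <- with_stage("export", dg, "-",
                     export_geometry(tree, mask, config$outdir))
    files <- c(files, gf)
    for (lv in config$levels) {
      run_idx <- run_idx + 1L
      if (progress)
        message(sprintf("[%s @ %s] solving ...", dg, lv))
      b <- apply_protocol(config$boundaries, lv)
      scfg <- level_solver_config(config$solver, b$protocol, design)
      nsnap <- if (config$particles$per_step > 0)
        config$particles$snapshots_per_cycle else 0
      series <- with_stage("simulate", dg, lv,
                           solve_cycles(mask, b, fluid_properties(), scfg,
                                        snapshots_per_cycle = nsnap))
      split <- NULL
      if (config$particles$per_step > 0) {
        split <- with_stage("particles", dg, lv,
                            track_ivc_split(
                              series, per_step = config$particles$per_step,
                              seed = config$seed + run_idx,
                              dt = config$particles$dt,
                              drain_cycles = config$particles$drain_cycles))
        splits[[paste(dg, lv, sep = ".")]] <- split
      }
      rep <- with_stage("metrics", dg, lv,
                        hemodynamic_report(series, tree, lv, split))
      reports[[paste(dg, lv, sep = ".")]] <- rep
      if (config$write_fields) {
        fv <- file.path(config$outdir, sprintf("%s_%s_fields.vtk", dg, lv))
        spd <- array(cell_speed(series$avg, mask$dim, seq_len(prod(mask$dim))),
                     dim = mask$dim)
        write_vtk_image(list(speed = spd, pressure = series$avg$p),
                        mask$spacing, mask$origin, fv)
        files <- c(files, fv)
      }
    }
  }
  reports <- do.call(rbind, reports)
  rownames(reports) <- NULL
  rf <- file.path(config$outdir, "reports.csv")
  write.csv(format(reports, digits = 12), rf, row.names = FALSE)
  files <- c(files, rf)

  card <- NULL
  if (length(config$designs) >= 2 && config$particles$per_step > 0) {
    tab <- indicator_table(reports)
    card <- rank_and_score(tab)
    cf <- file.path(config$outdir, "scorecard.json")
    jsonlite::write_json(list(scores = as.data.frame(card$scores),
                              totals = as.list(card$totals),
                              selected = card$selected),
                         cf, auto_unbox = TRUE, digits = NA)
    files <- c(files, cf)
  }
  manifest <- run_manifest(config, files)
  mf <- file.path(config$outdir, "manifest.json")
  jsonlite::write_json(unclass(manifest), mf, auto_unbox = TRUE, digits = NA,
                      force = TRUE)
  list(reports = reports, card = card, splits = splits, manifest = manifest)
}

#' Read a pipeline configuration from JSON or YAML
#'
#' The file mirrors [pipeline_config()]: `designs` (list of conduit-design
#' fields), optional `layout`, `waveforms` (port, base mean velocity m/s,
#' period, optional modulation harmonics), `resistances` (port, Pa s/m^3),
#' `levels`, `solver`, `spacing`, `particles`, `seed`, `outdir`. Missing
#' entries fall back to the package defaults.
#'
#' @param path a `.json`, `.yml` or `.yaml` file.
#' @return a validated [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      validation_error("reading YAML configs needs the 'yaml' package")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  }
  designs <- lapply(raw$designs, function(d)
    conduit_design(d$label, d$topology,
                   trunk_diameter = d$trunk_diameter,
                   branch_diameter = d$branch_diameter %||% NA_real_,
                   left_anastomosis_offset = d$left_anastomosis_offset %||% -15,
                   right_anastomosis_offset = d$right_anastomosis_offset %||% 15,
                   svc_offset = d$svc_offset %||%
                     if (d$topology == "T") 15 else 0))
  layout <- do.call(anatomical_layout, raw$layout %||% list())
  period <- raw$solver$cycle_period %||% 2.54
  waveforms <- if (is.null(raw$waveforms)) {
    default_boundaries(period = period)$waveforms
  } else {
    lapply(raw$waveforms, function(w)
      inlet_waveform(w$port, w$base_mean_velocity, period,
                     modulation = w$modulation %||%
                       list(list(harmonic = 1, amplitude = 0.3, phase = 0))))
  }
  resistances <- if (is.null(raw$resistances)) {
    default_boundaries(period = period)$resistances
  } else {
    lapply(raw$resistances, function(r)
      outlet_resistance(r$port, r$resistance %||% 1.888e7,
                        r$reference_pressure %||% 0))
  }
  solver <- do.call(solver_config, raw$solver %||% list())
  pipeline_config(
    designs = designs, layout = layout,
    boundaries = boundary_set(unname(waveforms), unname(resistances)),
    levels = raw$levels %||% c("rest", "light", "moderate", "heavy"),
    solver = solver, spacing = raw$spacing %||% 1.5,
    particles = modifyList(list(per_step = 50, dt = 0.005, drain_cycles = 2,
                                snapshots_per_cycle = 24),
                           raw$particles %||% list()),
    seed = raw$seed %||% 20260920,
    outdir = raw$outdir %||% tempfile("fontanflow"))
}

#' Write a pipeline configuration as JSON
#'
#' @param config a [pipeline_config()].
#' @param path output `.json` file.
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  plain <- list(
    designs = lapply(unname(config$designs), unclass),
    layout = unclass(config$layout),
    waveforms = lapply(unname(config$boundaries$waveforms), unclass),
    resistances = lapply(unname(config$boundaries$resistances), unclass),
    levels = config$levels,
    solver = unclass(config$solver)[c("time_step", "cycle_period", "n_cycles",
                                      "pressure_tolerance",
                                      "advection_scheme", "cfl_limit")],
    spacing = config$spacing, particles = config$particles,
    seed = config$seed, outdir = config$outdir)
  jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", force = TRUE)
  invisible(path)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  plain <- rapply(unclass(config), unclass, how = "replace")
  plain$outdir <- NULL  # location must not change the run identity
  jsonlite::write_json(plain, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Run manifest
#'
#' Provenance record of a pipeline run: a hash of the configuration
#' (excluding the output location), the seed, grid spacing, package version
#' and the sorted index of output files. Re-running an identical
#' configuration yields an identical manifest.
#'
#' @param config the [pipeline_config()] that was run.
#' @param files character vector of files written.
#' @return a list of class `run_manifest`.
#' @export
run_manifest <- function(config, files) {
  structure(list(
    config_hash = config_hash(config),
    seed = config$seed,
    spacing_mm = config$spacing,
    package_version = as.character(packageVersion("fontanflow")),
    files = sort(unname(basename(files)))
  ), class = "run_manifest")
}
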