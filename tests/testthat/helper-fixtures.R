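# Shared fixtures and a session cache for the expensive simulations.
# Everything is generated in code; nothing is read from disk.

.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache)) {
    assign(key, force(expr), envir = .sim_cache)
  }
  get(key, envir = .sim_cache)
}

# straight tube tree along x with an IVC inlet (x = 0) and RPA outlet (x = L)
make_tube_tree <- function(diameter = 10, length = 40) {
  r <- diameter / 2
  seg <- fontanflow:::new_segment("tube", c(0, 0, 0), c(length, 0, 0), r,
                                  cap0 = "port", cap1 = "port")
  structure(list(
    design = conduit_design("tube", "T", diameter),
    layout = NULL,
    segments = list(seg),
    ports = list(
      IVC = fontanflow:::new_port(c(0, 0, 0), c(-1, 0, 0), r, "tube"),
      RPA = fontanflow:::new_port(c(length, 0, 0), c(1, 0, 0), r, "tube")
    )
  ), class = "vessel_tree")
}

# all-fluid rectangular box mask with plug IVC inlet / RPA outlet on x faces
make_box_mask <- function(n = c(16L, 8L, 8L), spacing = 1) {
  lumen <- array(TRUE, dim = n)
  port <- array(0L, dim = n)
  port[1, , ] <- match("IVC", fontanflow:::PORT_NAMES)
  port[n[1], , ] <- match("RPA", fontanflow:::PORT_NAMES)
  domain_mask(lumen, port, spacing, origin = c(0, 0, 0),
              ports = list(IVC = list(axis = 1, dir = -1, radius = NA),
                           RPA = list(axis = 1, dir = +1, radius = NA)))
}

# all-fluid box with no ports at all (pure advection playground)
make_closed_box_mask <- function(n = c(24L, 24L, 5L), spacing = 1) {
  lumen <- array(TRUE, dim = n)
  domain_mask(lumen, array(0L, dim = n), spacing, origin = c(0, 0, 0),
              ports = list())
}

# minimal flow_series-like object around analytic steady fields (SI units)
synthetic_series <- function(mask, ufun = NULL, vfun = NULL, wfun = NULL,
                             period = 1) {
  d <- mask$dim
  h <- mask$spacing * 1e-3
  o <- mask$origin * 1e-3
  face_grid <- function(fd, ax) {
    i <- (seq_len(fd[1]) - 1)
    j <- (seq_len(fd[2]) - 1)
    k <- (seq_len(fd[3]) - 1)
    off <- c(0.5, 0.5, 0.5); off[ax] <- 0
    list(x = o[1] + (rep(i, times = fd[2] * fd[3]) + off[1]) * h,
         y = o[2] + (rep(rep(j, each = fd[1]), times = fd[3]) + off[2]) * h,
         z = o[3] + (rep(k, each = fd[1] * fd[2]) + off[3]) * h)
  }
  mk <- function(fun, fd, ax) {
    a <- array(0, dim = fd)
    if (!is.null(fun)) {
      g <- face_grid(fd, ax)
      a[] <- fun(g$x, g$y, g$z)
    }
    a
  }
  fdu <- c(d[1] + 1L, d[2], d[3])
  fdv <- c(d[1], d[2] + 1L, d[3])
  fdw <- c(d[1], d[2], d[3] + 1L)
  structure(list(
    mask = mask,
    config = solver_config(time_step = 0.001, cycle_period = period,
                           n_cycles = 1),
    props = fluid_properties(),
    boundaries = NULL,
    avg = list(u = mk(ufun, fdu, 1), v = mk(vfun, fdv, 2),
               w = mk(wfun, fdw, 3), p = array(0, dim = d)),
    snapshots = NULL
  ), class = "flow_series")
}

# compact symmetric Y junction for symmetry / particle / efficiency checks
small_layout <- function() {
  anatomical_layout(pa_diameter = 16, pa_half_length = 62,
                    svc_diameter = 14, svc_length = 30,
                    ivc_port_depth = 45, bifurcation_standoff = 25)
}

small_y_design <- function() {
  conduit_design("Y-small", "Y", trunk_diameter = 20, branch_diameter = 14,
                 left_anastomosis_offset = -10, right_anastomosis_offset = 10,
                 svc_offset = 0)
}

steady_boundaries <- function(ivc = 0.30, svc = 0.25,
                              r_lpa = 1.888e7, r_rpa = 1.888e7) {
  boundary_set(
    list(inlet_waveform("IVC", ivc, modulation = list()),
         inlet_waveform("SVC", svc, modulation = list())),
    list(outlet_resistance("LPA", r_lpa), outlet_resistance("RPA", r_rpa))
  )
}

# Steady-state run of the compact Y. Two "cycles": the first absorbs the
# spin-up transient, only the second is averaged — otherwise the averaged
# pressure field keeps the start-up acceleration head rho*du/dt.
run_small_y <- function(key = "small_y", r_lpa = 1.888e7, r_rpa = 1.888e7,
                        flow_mult = 1, snapshots = 0,
                        t_settle = 0.35 / max(1, flow_mult / 2)) {
  cached(key, {
    mask <- voxelize(build_design(small_y_design(), small_layout()), 2)
    dt <- 5e-4 / flow_mult
    per <- round(t_settle / dt) * dt
    cfg <- solver_config(time_step = dt, cycle_period = per, n_cycles = 2,
                         pressure_tolerance = 1e-5)
    svc_mult <- if (flow_mult >= 4) 1.5 else 1   # SVC rises only at heavy
    b <- steady_boundaries(ivc = 0.30 * flow_mult, svc = 0.25 * svc_mult,
                           r_lpa = r_lpa, r_rpa = r_rpa)
    suppressWarnings(solve_cycles(mask, b, fluid_properties(), cfg,
                                  snapshots_per_cycle = snapshots))
  })
}

# pulsatile rest run of one reference design at acceptance settings
run_rest_design <- function(label) {
  cached(paste0("rest_", label), {
    simulate_design(reference_designs()[[label]], "rest")$series
  })
}

# steady heavy-exercise analogue of one reference design; the time step
# shrinks with the design's branch-contraction jet factor
run_heavy_design <- function(label) {
  cached(paste0("heavy_", label), {
    design <- reference_designs()[[label]]
    tree <- build_design(design, anatomical_layout())
    mask <- voxelize(tree, 1.5)
    fac <- fontanflow:::design_speed_factor(design)
    dt <- 5e-4 / (4 * fac)
    per <- round(0.15 / dt) * dt    # settle one window, average the second
    cfg <- solver_config(time_step = dt, cycle_period = per, n_cycles = 2,
                         pressure_tolerance = 1e-5)
    b <- steady_boundaries(ivc = 0.30 * 4, svc = 0.25 * 1.5,
                           r_lpa = 1.888e7 * 0.85, r_rpa = 1.888e7 * 0.85)
    list(tree = tree, mask = mask,
         series = suppressWarnings(solve_cycles(mask, b, fluid_properties(),
                                                cfg)))
  })
}

# compact 4-design pipeline run used for the counting/determinism contracts
tiny_config <- function(outdir = tempfile("ffrun"), seed = 123) {
  pipeline_config(
    designs = list(
      conduit_design("A-20T", "T", 20, left_anastomosis_offset = -10,
                     right_anastomosis_offset = 10, svc_offset = 10),
      conduit_design("B-16Y", "Y", 20, 16, -10, 10, 0),
      conduit_design("C-17Y", "Y", 20, 17, -10, 10, 0),
      conduit_design("D-18Y", "Y", 20, 18, -10, 10, 0)
    ),
    layout = small_layout(),
    boundaries = default_boundaries(period = 0.12),
    levels = c("rest", "light", "moderate", "heavy"),
    solver = solver_config(time_step = 1e-3, cycle_period = 0.12,
                           n_cycles = 1, pressure_tolerance = 1e-4),
    spacing = 2,
    particles = list(per_step = 2, dt = 0.004, drain_cycles = 2,
                     snapshots_per_cycle = 6),
    seed = seed, outdir = outdir
  )
}

run_tiny_pipeline <- function() {
  cached("tiny_pipeline", {
    cfg <- tiny_config()
    list(cfg = cfg, res = run_pipeline(cfg))
  })
}

# Poiseuille validation run: elevated viscosity so the parabola develops
# quickly; Re ~ 13 (laminar, well under the Re <= 500 regime of the check)
run_poiseuille <- function() {
  cached("poiseuille", {
    tree <- make_tube_tree(diameter = 10, length = 40)
    mask <- voxelize(tree, 0.5)
    props <- fluid_properties(density = 1060, dynamic_viscosity = 0.04)
    b <- boundary_set(
      list(inlet_waveform("IVC", 0.05, modulation = list())),
      list(outlet_resistance("RPA", 1e7)))
    cfg <- solver_config(time_step = 5e-4, cycle_period = 0.7, n_cycles = 2,
                         pressure_tolerance = 1e-6)
    list(tree = tree, mask = mask, props = props,
         series = suppressWarnings(solve_cycles(mask, b, props, cfg)))
  })
}
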