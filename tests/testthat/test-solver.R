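test_that("zero inflow leaves the zero field identically zero", {
  mask <- make_box_mask(c(10L, 6L, 6L), 1)
  b <- boundary_set(list(inlet_waveform("IVC", 0, modulation = list())),
                    list(outlet_resistance("RPA")))
  st <- flow_state(mask)
  cfg <- solver_config(time_step = 1e-3, cycle_period = 0.01, n_cycles = 1)
  for (i in 1:5) st <- advance(st, mask, b, fluid_properties(), cfg)
  expect_true(all(st$u == 0) && all(st$v == 0) && all(st$w == 0))
  expect_true(all(st$p == 0))
})

test_that("a uniform along-axis field is a fixed point of pure advection", {
  mask <- make_box_mask(c(16L, 8L, 8L), 1)
  s <- 0.2
  b <- boundary_set(list(inlet_waveform("IVC", s, modulation = list())),
                    list(outlet_resistance("RPA")))
  props <- fluid_properties(dynamic_viscosity = 1e-12)  # advection only
  cfg <- solver_config(time_step = 1e-3, cycle_period = 0.01, n_cycles = 1)
  st <- flow_state(mask)
  st$u[] <- s
  for (i in 1:5) st <- advance(st, mask, b, props, cfg)
  expect_equal(max(abs(st$u - s)), 0, tolerance = 1e-10)
  expect_equal(max(abs(st$v)), 0, tolerance = 1e-12)
  expect_equal(max(abs(st$w)), 0, tolerance = 1e-12)
})

test_that("a CFL violation aborts with an error naming the time step", {
  mask <- make_box_mask(c(12L, 6L, 6L), 1)
  b <- boundary_set(list(inlet_waveform("IVC", 0.4, modulation = list())),
                    list(outlet_resistance("RPA")))
  cfg <- solver_config(time_step = 2e-3, cycle_period = 0.02, n_cycles = 1)
  st <- flow_state(mask)
  st$maxvel <- 2                      # pretend the field already moves fast
  expect_error(advance(st, mask, b, fluid_properties(), cfg),
               regexp = "0.002", class = "fontanflow_cfl_error")
})

test_that("steady tube flow reproduces Hagen-Poiseuille within 5%", {
  run <- run_poiseuille()
  s <- run$series
  Q <- port_flux(s, "RPA")$flow
  mu <- run$props$dynamic_viscosity

  # interior pressure drop over 16 mm, past the ~13 mm entrance region
  p1 <- section_mean_pressure(s, "x", 16)
  p2 <- section_mean_pressure(s, "x", 32)
  v <- section_mean_velocity(s, "x", 24)
  A <- attr(v, "area")
  R_eff <- sqrt(A / pi)               # radius of the voxelized cross-section
  dp_analytic <- 8 * mu * 0.016 * Q / (pi * R_eff^4)
  expect_lt(abs((p1 - p2) - dp_analytic) / dp_analytic, 0.05)

  # axial profile vs the parabola 2*ubar*(1 - r^2/R^2), L2 over the section
  mask <- run$mask
  cells <- fontanflow:::slab_cells(mask, "x", 24)
  sp <- fontanflow:::cell_speed(s$avg, mask$dim, cells)
  e <- cells - 1L
  cy <- (e %/% mask$dim[1]) %% mask$dim[2]
  cz <- e %/% (mask$dim[1] * mask$dim[2])
  h <- mask$spacing * 1e-3
  y <- mask$origin[2] * 1e-3 + (cy + 0.5) * h
  z <- mask$origin[3] * 1e-3 + (cz + 0.5) * h
  r2 <- y^2 + z^2
  ubar <- Q / A
  ref <- pmax(2 * ubar * (1 - r2 / R_eff^2), 0)
  expect_lt(sqrt(sum((sp - ref)^2) / sum(ref^2)), 0.05)

  # global mass balance and discrete divergence
  expect_lt(mass_balance_error(s), 0.01)
  expect_lt(s$diagnostics$max_div * h / s$diagnostics$final_maxvel, 1e-4)

  # energy efficiency closes against the port-to-port pressure drop
  eff <- energy_efficiency(s)
  dp_ports <- port_flux(s, "IVC")$pressure - port_flux(s, "RPA")$pressure
  expect_equal(eff$efficiency, 1 - dp_ports * Q / eff$influx,
               tolerance = 0.04)
  expect_gt(eff$efficiency, 0)
  expect_lte(eff$efficiency, 1)
})

test_that("a mirror-symmetric Y splits its outflow evenly", {
  s <- run_small_y()
  qL <- abs(port_flux(s, "LPA")$flow)
  qR <- abs(port_flux(s, "RPA")$flow)
  expect_lt(abs(qL - qR) / (qL + qR), 0.01)
  expect_equal(port_flux(s, "LPA")$pressure, port_flux(s, "RPA")$pressure,
               tolerance = 0.02)
  expect_lt(mass_balance_error(s), 0.01)
})

test_that("kinetic energy stays bounded over several pulsatile cycles", {
  tree <- make_tube_tree(diameter = 10, length = 30)
  mask <- voxelize(tree, 1)
  b <- boundary_set(list(inlet_waveform("IVC", 0.3, period = 0.25)),
                    list(outlet_resistance("RPA")))
  cfg <- solver_config(time_step = 1e-3, cycle_period = 0.25, n_cycles = 4)
  s <- solve_cycles(mask, b, fluid_properties(), cfg)
  ke <- s$diagnostics$ke_per_cycle
  expect_true(all(is.finite(ke)))
  # after spin-up the end-of-cycle energy is periodic, not growing
  expect_lt(abs(ke[4] - ke[3]) / ke[3], 0.05)
  expect_lt(s$diagnostics$final_maxvel, 5)
})

test_that("the junction pressure gradient is grid-insensitive at the tested levels", {
  # a well-resolved symmetric Y (>= 12 cells across every vessel at the
  # coarser level); one spacing halving changes PG by under 10%
  lay <- anatomical_layout(pa_diameter = 24, pa_half_length = 62,
                           svc_diameter = 18, svc_length = 30,
                           ivc_port_depth = 45, bifurcation_standoff = 25)
  tree <- build_design(conduit_design("Y-big", "Y", 28, 20, -12, 12, 0), lay)
  b <- steady_boundaries()
  pg <- vapply(c(2, 1), function(h) {
    mask <- voxelize(tree, h)
    dt <- 5e-4 * h / 2
    cfg <- solver_config(time_step = dt, cycle_period = round(0.35 / dt) * dt,
                         n_cycles = 2, pressure_tolerance = 1e-5)
    pressure_gradient(suppressWarnings(
      solve_cycles(mask, b, fluid_properties(), cfg)))
  }, 0)
  expect_lt(abs(pg[2] - pg[1]) / pg[1], 0.10)
})
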