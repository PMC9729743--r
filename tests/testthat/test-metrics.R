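test_that("the pressure gradient is the halved inlet-outlet pressure difference", {
  p0 <- 1200
  eq <- setNames(rep(p0, 4), c("SVC", "IVC", "LPA", "RPA"))
  expect_equal(pressure_gradient(eq), 0)
  # inlets at P + delta, outlets at P: PG = delta (in mmHg)
  delta <- 266.644  # 2 mmHg
  up <- eq + c(SVC = delta, IVC = delta, LPA = 0, RPA = 0)
  expect_equal(pressure_gradient(up), 2)
  expect_error(pressure_gradient(eq[c("SVC", "IVC", "LPA")]),
               class = "fontanflow_validation_error")
})

test_that("PG matches the closed form of a parallel-tube resistance network", {
  # two Poiseuille tubes from a common caval pressure node to resistive
  # outlets: P_in = Q_i * (R_tube_i + R_out_i), Q_1 + Q_2 = Q_total
  mu <- 0.0035
  L <- 0.06
  r1 <- 0.005; r2 <- 0.007
  Rt1 <- 8 * mu * L / (pi * r1^4)
  Rt2 <- 8 * mu * L / (pi * r2^4)
  Ro <- 1.8e7
  Q <- 1.0e-4
  # flows solve the two-node network exactly
  G <- 1 / (Rt1 + Ro) + 1 / (Rt2 + Ro)
  Pin <- Q / G
  Q1 <- Pin / (Rt1 + Ro); Q2 <- Pin / (Rt2 + Ro)
  pres <- c(SVC = Pin, IVC = Pin, LPA = Q1 * Ro, RPA = Q2 * Ro)
  pg_expected <- ((2 * Pin) - (Q1 * Ro + Q2 * Ro)) / 2 / 133.322
  expect_equal(pressure_gradient(pres), pg_expected)
  expect_equal(Q1 + Q2, Q, tolerance = 1e-12)
})

test_that("energy flux reduces to its plug-flow closed form", {
  mask <- make_box_mask(c(10L, 6L, 6L), 1)
  u <- 0.25; p <- 800
  rho <- 1060
  flds <- list(u = array(u, dim = c(11, 6, 6)),
               v = array(0, dim = c(10, 7, 6)),
               w = array(0, dim = c(10, 6, 7)),
               p = array(p, dim = c(10, 6, 6)))
  A <- 36 * (1e-3)^2
  expect_equal(energy_flux(flds, "RPA", mask), (p + 0.5 * rho * u^2) * u * A)
  expect_equal(energy_flux(flds, "IVC", mask), -(p + 0.5 * rho * u^2) * u * A)
  flds0 <- flds; flds0$u[] <- 0
  expect_equal(energy_flux(flds0, "RPA", mask), 0)
})

test_that("a parabolic profile carries twice the plug kinetic-energy flux", {
  # fine tube section; kinetic-energy correction factor of the parabola = 2
  tree <- make_tube_tree(diameter = 10, length = 4)
  mask <- voxelize(tree, 0.25)
  pf <- fontanflow:::port_faces_of_mask(mask)$RPA
  h <- mask$spacing * 1e-3
  A <- length(pf$idx) * h^2
  R <- sqrt(A / pi)
  ubar <- 0.2; p0 <- 500; rho <- 1060
  d <- mask$dim
  flds <- list(u = array(0, dim = c(d[1] + 1, d[2], d[3])),
               v = array(0, dim = c(d[1], d[2] + 1, d[3])),
               w = array(0, dim = c(d[1], d[2], d[3] + 1)),
               p = array(p0, dim = d))
  e <- pf$idx - 1L
  fy <- (e %/% (d[1] + 1L)) %% d[2]
  fz <- e %/% ((d[1] + 1L) * d[2])
  y <- mask$origin[2] * 1e-3 + (fy + 0.5) * h
  z <- mask$origin[3] * 1e-3 + (fz + 0.5) * h
  flds$u[pf$idx] <- pmax(2 * ubar * (1 - (y^2 + z^2) / R^2), 0)
  E <- energy_flux(flds, "RPA", mask)
  Q <- sum(flds$u[pf$idx]) * h^2
  ub <- Q / A
  # pressure work p*ubar*A plus kinetic term 2 * (rho/2 ub^2) * ub * A
  E_analytic <- p0 * ub * A + 2 * (0.5 * rho * ub^2) * ub * A
  expect_equal(E, E_analytic, tolerance = 0.03)
})

test_that("energy efficiency handles ideal, degenerate and dissipative cases", {
  ideal <- energy_efficiency(0.5, 0.5)
  expect_equal(ideal$efficiency, 1)
  expect_equal(ideal$dissipated_power, 0)
  expect_error(energy_efficiency(0, 0.1),
               class = "fontanflow_validation_error")
  lossy <- energy_efficiency(0.5, 0.45)
  expect_lt(lossy$efficiency, 1)
  expect_gt(lossy$dissipated_power, 0)
})

test_that("section velocities are mass-consistent with the port fluxes", {
  s <- run_small_y()
  mask <- s$mask
  Q_ivc <- abs(port_flux(s, "IVC")$flow)
  # trunk section well below the bifurcation: velocity * area = inflow
  v_tr <- section_mean_velocity(s, "z", -40)
  expect_equal(as.numeric(v_tr) * attr(v_tr, "area"), Q_ivc,
               tolerance = 0.03)
  # plug sanity: the synthetic plug field returns the plug speed
  box <- make_box_mask(c(10L, 6L, 6L), 1)
  ss <- synthetic_series(box, ufun = function(x, y, z) 0.4)
  expect_equal(as.numeric(section_mean_velocity(ss, "x", 5)), 0.4)
  expect_error(section_mean_velocity(ss, "x", 99),
               class = "fontanflow_validation_error")
})

test_that("branch sections carry the trunk flow after the slant correction", {
  s <- run_small_y()
  Q_ivc <- abs(port_flux(s, "IVC")$flow)
  des <- small_y_design(); lay <- small_layout()
  zsec <- -lay$bifurcation_standoff + 15   # between split and PA
  v_br <- section_mean_velocity(s, "z", zsec, region = list(x = c(-25, 25)))
  # horizontal cuts through the slanted branches widen by 1/cos(theta)
  theta <- atan(abs(des$left_anastomosis_offset) / lay$bifurcation_standoff)
  Q_sections <- as.numeric(v_br) * attr(v_br, "area") * cos(theta)
  expect_equal(Q_sections, Q_ivc, tolerance = 0.10)
})

test_that("hemodynamic reports assemble the four indicators", {
  run <- run_heavy_design("D")
  rep <- hemodynamic_report(run$series, run$tree, "heavy")
  expect_s3_class(rep, "hemodynamic_report")
  expect_true(is.finite(rep$pg_mmhg))
  expect_gt(rep$efficiency, 0)
  expect_lte(rep$efficiency, 1)
  expect_gt(rep$section_velocity_ms, 0)
  expect_lt(rep$mass_balance, 0.01)
})
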