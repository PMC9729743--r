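#' Fluid properties of blood
#'
#' Blood is treated as an incompressible Newtonian fluid (laminar venous
#' flow); defaults are density 1060 kg/m^3 and dynamic viscosity 0.0035 Pa s.
#'
#' @param density kg/m^3.
#' @param dynamic_viscosity Pa s.
#' @return an object of class `fluid_properties`.
#' @export
fluid_properties <- function(density = 1060, dynamic_viscosity = 0.0035) {
  if (density <= 0 || dynamic_viscosity <= 0)
    validation_error("density and dynamic_viscosity must be positive")
  structure(list(density = density, dynamic_viscosity = dynamic_viscosity),
            class = "fluid_properties")
}

#' Solver configuration
#'
#' Settings for the staggered-grid projection solver. The cycle period must
#' be an integer number of time steps (2.54 s / 0.001 s = 2,540 by default).
#'
#' @param time_step s.
#' @param cycle_period s; the respiratory cycle driving the inlets.
#' @param n_cycles number of cycles to run; fields are averaged over the
#'   final cycle.
#' @param pressure_tolerance relative residual of the pressure solve.
#' @param advection_scheme `"quick"` (default; third-order upwind-biased
#'   advective derivative with Adams-Bashforth-2 time integration, falling
#'   back to first-order upwind where a wall cuts the stencil) or
#'   `"upwind1"` (first-order upwind, forward Euler; more dissipative but
#'   maximally robust).
#' @param cfl_limit advective CFL bound `max|u| dt / dx`; exceeding it stops
#'   the run with an error naming the offending time step. The QUICK/AB2
#'   combination is stable to roughly CFL 0.5.
#' @param cg_maxiter cap on conjugate-gradient iterations per step.
#' @param outlet_relax under-relaxation of the per-step outlet-flow network
#'   update (1 = no relaxation).
#' @return an object of class `solver_config`.
#' @export
solver_config <- function(time_step = 0.001, cycle_period = 2.54,
                          n_cycles = 3, pressure_tolerance = 1e-6,
                          advection_scheme = c("quick", "upwind1"),
                          cfl_limit = 0.5, cg_maxiter = 5000,
                          outlet_relax = 0.8) {
  advection_scheme <- match.arg(advection_scheme)
  if (time_step <= 0) validation_error("time_step must be positive")
  spc <- cycle_period / time_step
  if (abs(spc - round(spc)) > 1e-8)
    validation_error("cycle_period must be an integer multiple of time_step")
  structure(list(time_step = time_step, cycle_period = cycle_period,
                 n_cycles = n_cycles,
                 steps_per_cycle = as.integer(round(spc)),
                 pressure_tolerance = pressure_tolerance,
                 advection_scheme = advection_scheme,
                 cfl_limit = cfl_limit, cg_maxiter = cg_maxiter,
                 outlet_relax = outlet_relax),
            class = "solver_config")
}

# ---- static solver context ------------------------------------------------

# Precomputes, in SI units, everything the per-step kernel needs:
# face classifications, active-face lists, fluid-cell neighbour table for the
# pressure CG, and per-port boundary-face tables.
solver_context <- function(mask, boundaries, props, config) {
  dims <- mask$dim
  h <- mask$spacing * 1e-3
  lum <- as.integer(mask$lumen)
  ft <- .classify_faces_cpp(lum, dims)
  ftu <- ft$ftu; ftv <- ft$ftv; ftw <- ft$ftw

  fidx <- which(mask$lumen)             # 1-based grid indices of lumen cells
  nf <- length(fidx)
  posmap <- integer(prod(dims))
  posmap[fidx] <- seq_len(nf)
  e0 <- fidx - 1L
  ci <- e0 %% dims[1]
  rr <- e0 %/% dims[1]
  cj <- rr %% dims[2]
  ck <- rr %/% dims[2]
  nbr_of <- function(di, dj, dk) {
    i2 <- ci + di; j2 <- cj + dj; k2 <- ck + dk
    ok <- i2 >= 0 & i2 < dims[1] & j2 >= 0 & j2 < dims[2] &
      k2 >= 0 & k2 < dims[3]
    out <- rep(-1L, nf)
    gi <- 1L + i2[ok] + dims[1] * (j2[ok] + dims[2] * k2[ok])
    out[ok] <- posmap[gi] - 1L   # posmap is 0 off-lumen, giving -1
    out
  }
  # 6 x nf, one column per fluid cell (contiguous per-cell access in the CG)
  fnbr <- rbind(nbr_of(-1L, 0L, 0L), nbr_of(1L, 0L, 0L),
                nbr_of(0L, -1L, 0L), nbr_of(0L, 1L, 0L),
                nbr_of(0L, 0L, -1L), nbr_of(0L, 0L, 1L))
  storage.mode(fnbr) <- "integer"

  fdu <- c(dims[1] + 1L, dims[2], dims[3])
  fdv <- c(dims[1], dims[2] + 1L, dims[3])
  fdw <- c(dims[1], dims[2], dims[3] + 1L)

  port_tab <- list()
  for (nm in names(mask$ports)) {
    pm <- mask$ports[[nm]]
    cells <- pm$cells
    e <- cells - 1L
    i <- e %% dims[1]; r2 <- e %/% dims[1]
    j <- r2 %% dims[2]; k <- r2 %/% dims[2]
    ax <- pm$axis; dir <- pm$dir
    if (ax == 1L) {
      fi <- if (dir < 0) i else i + 1L
      idx0 <- fi + fdu[1] * (j + fdu[2] * k)
      comp <- 0L; ftarr <- "ftu"
    } else if (ax == 2L) {
      fj <- if (dir < 0) j else j + 1L
      idx0 <- i + fdv[1] * (fj + fdv[2] * k)
      comp <- 1L; ftarr <- "ftv"
    } else {
      fk <- if (dir < 0) k else k + 1L
      idx0 <- i + fdw[1] * (j + fdw[2] * fk)
      comp <- 2L; ftarr <- "ftw"
    }
    stride <- switch(ax, 1L, fdv[1], fdw[1] * fdw[2])
    port_tab[[nm]] <- list(
      comp = rep.int(comp, length(cells)),
      idx0 = as.integer(idx0),
      int0 = as.integer(idx0 - dir * stride),  # in-line interior face
      sign = rep.int(as.integer(dir), length(cells)),
      cellpos0 = posmap[cells] - 1L,
      area = length(cells) * h^2,
      axis = ax, dir = dir
    )
    if (ftarr == "ftu") ftu[idx0 + 1L] <- 2L
    if (ftarr == "ftv") ftv[idx0 + 1L] <- 2L
    if (ftarr == "ftw") ftw[idx0 + 1L] <- 2L
  }

  inlets <- intersect(names(boundaries$waveforms), names(port_tab))
  outlets <- intersect(names(boundaries$resistances), names(port_tab))
  uncovered <- setdiff(names(port_tab), c(inlets, outlets))
  if (length(uncovered))
    validation_error(sprintf("no boundary condition for port(s): %s",
                             paste(uncovered, collapse = ", ")))

  nu <- props$dynamic_viscosity / props$density
  # AB2's real-axis stability interval is half of forward Euler's
  dt_visc <- h^2 / (if (config$advection_scheme == "quick") 12 else 6) / nu
  if (config$time_step > dt_visc)
    validation_error(sprintf(
      "time_step %.3g s exceeds the explicit diffusion limit %.3g s at %.3g mm spacing",
      config$time_step, dt_visc, mask$spacing))

  area_min <- if (length(outlets))
    min(vapply(outlets, function(nm) port_tab[[nm]]$area, 0)) else NA_real_
  inertance <- props$density * max(dims) * h / area_min  # rho*L/A, Pa s^2/m^3

  active <- list(which(ftu == 1L) - 1L, which(ftv == 1L) - 1L,
                 which(ftw == 1L) - 1L)
  out_res <- vapply(names(port_tab), function(nm)
    if (nm %in% outlets) boundaries$resistances[[nm]]$resistance
    else NA_real_, 0)
  out_pref <- vapply(names(port_tab), function(nm)
    if (nm %in% outlets) boundaries$resistances[[nm]]$reference_pressure
    else 0, 0)

  list(dims = dims, h = h, origin = mask$origin * 1e-3, inertance = inertance,
       ftu = ftu, ftv = ftv, ftw = ftw, active = active,
       stencil = .build_stencil_cpp(ftu, ftv, ftw, active, dims),
       fcell0 = fidx - 1L, fidx = fidx, fnbr = fnbr,
       ports = port_tab, inlets = inlets, outlets = outlets,
       pf_comp = lapply(port_tab, `[[`, "comp"),
       pf_idx = lapply(port_tab, `[[`, "idx0"),
       pf_sign = lapply(port_tab, `[[`, "sign"),
       pf_int = lapply(port_tab, `[[`, "int0"),
       pf_cell = lapply(port_tab, `[[`, "cellpos0"),
       out_res = out_res, out_pref = out_pref,
       fdu = fdu, fdv = fdv, fdw = fdw)
}

#' Initial flow state
#'
#' Zero velocity and zero gauge pressure on the staggered grid of a mask.
#'
#' @param mask a [domain_mask()].
#' @return an object of class `flow_state` holding face-centred velocity
#'   components (m/s), cell-centred pressure (Pa) and the time `t` (s).
#' @export
flow_state <- function(mask) {
  d <- mask$dim
  structure(list(
    u = array(0, dim = c(d[1] + 1L, d[2], d[3])),
    v = array(0, dim = c(d[1], d[2] + 1L, d[3])),
    w = array(0, dim = c(d[1], d[2], d[3] + 1L)),
    p = array(0, dim = d),
    t = 0,
    port = NULL,      # last per-port flux/pressure/energy records
    Qout = NULL,      # outlet flows carried between steps
    maxvel = 0, maxdiv = 0, ke = 0
  ), class = "flow_state")
}

# per-step boundary values: inlet plug speeds from the waveforms, outlet
# plug speeds from the lumped-resistance network closed by exact mass balance
step_port_values <- function(ctx, boundaries, state, t_new, config) {
  ports <- ctx$ports
  values <- setNames(rep(NA_real_, length(ports)), names(ports))
  qin <- 0
  for (nm in ctx$inlets) {
    s <- waveform_value(boundaries$waveforms[[nm]], t_new)
    qin <- qin + s * ports[[nm]]$area
    values[nm] <- -ports[[nm]]$dir * s   # inward plug velocity component
  }
  res <- vapply(ctx$outlets, function(nm)
    boundaries$resistances[[nm]]$resistance, 0)
  pref <- vapply(ctx$outlets, function(nm)
    boundaries$resistances[[nm]]$reference_pressure, 0)
  pprev <- vapply(ctx$outlets, function(nm) {
    pp <- state$port
    if (is.null(pp)) 0 else pp$pressure[[nm]] %||% 0
  }, 0)
  if (any(res <= 0)) {
    qout <- rep(qin / length(ctx$outlets), length(ctx$outlets))
  } else {
    # junction constant c with sum((P_i + c - Pref_i)/R_i) = Q_in
    cc <- (qin - sum((pprev - pref) / res)) / sum(1 / res)
    qout <- pmax((pprev + cc - pref) / res, 0)
    if (sum(qout) > 0) qout <- qout * qin / sum(qout) else
      qout <- rep(qin / length(ctx$outlets), length(ctx$outlets))
  }
  names(qout) <- ctx$outlets
  if (!is.null(state$Qout)) {
    # The port pressure reacts to a per-step outflow change through the fluid
    # column's inertance Z ~ rho*L/(A*dt), which typically dwarfs R; damp the
    # network fixed-point iteration accordingly or it oscillates.
    gain <- if (all(res > 0)) ctx$inertance / (config$time_step * sum(res))
            else Inf
    th <- min(config$outlet_relax, 1 / (1 + gain))
    qout <- th * qout + (1 - th) * state$Qout[ctx$outlets]
    if (qin > 0 && sum(qout) > 0) qout <- qout * qin / sum(qout)
  }
  # outlets: pass the target outward flux; the kernel rescales the interior
  # profile onto the port faces (convective outflow)
  mode <- setNames(integer(length(ports)), names(ports))
  for (nm in ctx$outlets) {
    values[nm] <- qout[[nm]]
    mode[nm] <- 1L
  }
  list(values = values, mode = mode, qin = qin, qout = qout)
}

advance_step <- function(ctx, state, boundaries, props, config,
                         avg = NULL, avg_weight = 0) {
  dt <- config$time_step
  cfl <- state$maxvel * dt / ctx$h
  if (cfl > config$cfl_limit)
    ff_stop(sprintf(
      "CFL violation: max|u| dt/dx = %.2f > %.2f; reduce time_step = %.4g s",
      cfl, config$cfl_limit, dt), "fontanflow_cfl_error")
  t_new <- state$t + dt
  bv <- step_port_values(ctx, boundaries, state, t_new, config)
  scratch <- attr(state, "scratch")
  if (is.null(scratch))
    scratch <- list(us = state$u * 0, vs = state$v * 0, ws = state$w * 0,
                    fu = state$u * 0, fv = state$v * 0, fw = state$w * 0,
                    plast = numeric(length(ctx$fidx)),
                    zero = numeric(1), nstep = 0L)
  if (is.null(avg)) avg <- list(u = scratch$zero, v = scratch$zero,
                                w = scratch$zero, p = scratch$zero)
  res <- .advance_cpp(state$u, state$v, state$w, state$p,
                      scratch$us, scratch$vs, scratch$ws,
                      scratch$fu, scratch$fv, scratch$fw,
                      if (config$advection_scheme == "quick") 1L else 0L,
                      if (scratch$nstep > 0L) 1L else 0L,
                      ctx$ftu, ctx$ftv, ctx$ftw,
                      ctx$active, as.integer(ctx$dims),
                      as.integer(ctx$fcell0), ctx$fnbr,
                      ctx$pf_comp, ctx$pf_idx, ctx$pf_sign, ctx$pf_int,
                      ctx$pf_cell, bv$mode, bv$values,
                      ctx$out_res, ctx$out_pref,
                      scratch$plast, if (scratch$nstep > 0L) 1L else 0L,
                      avg$u, avg$v, avg$w, avg$p, avg_weight,
                      ctx$stencil,
                      ctx$h, dt, props$density, props$dynamic_viscosity,
                      config$pressure_tolerance, config$cg_maxiter)
  if (res$iters >= config$cg_maxiter)
    ff_stop(sprintf(
      "pressure solve did not converge: relative residual %.2e after %d iterations",
      res$relres, res$iters), "fontanflow_pressure_error")

  pn <- names(ctx$ports)
  state$t <- t_new
  state$port <- list(flow = setNames(as.list(res$portQ), pn),
                     pressure = setNames(as.list(res$portP), pn),
                     energy = setNames(as.list(res$portE), pn))
  state$Qout <- bv$qout
  state$maxvel <- res$maxvel
  state$maxdiv <- res$maxdiv
  state$ke <- res$ke
  state$cg <- c(iters = res$iters, relres = res$relres)
  scratch$nstep <- scratch$nstep + 1L
  attr(state, "scratch") <- scratch
  state
}

#' Advance the flow by one time step
#'
#' One Chorin projection step: explicit upwind advection and diffusion,
#' prescribed inlet/outlet plug velocities, then a pressure Poisson solve
#' (matrix-free conjugate gradients) whose gradient re-enforces a
#' divergence-free field on every lumen cell. No-slip is imposed on all wall
#' faces via the stair-step immersed boundary.
#'
#' @param state a [flow_state()].
#' @param mask the [domain_mask()] the state lives on.
#' @param boundaries a [boundary_set()].
#' @param props [fluid_properties()].
#' @param config [solver_config()].
#' @return the updated `flow_state` at `t + time_step`.
#' @export
advance <- function(state, mask, boundaries, props = fluid_properties(),
                    config = solver_config()) {
  ctx <- attr(state, "ctx")
  if (is.null(ctx))
    ctx <- solver_context(mask, boundaries, props, config)
  state <- advance_step(ctx, state, boundaries, props, config)
  attr(state, "ctx") <- ctx
  state
}

#' Run the pulsatile simulation over full respiratory cycles
#'
#' Starts from rest (zero velocity, zero gauge pressure), runs
#' `config$n_cycles` cycles, and averages fields and per-port records over
#' the final cycle. Cycle-to-cycle periodic convergence is reported as the
#' relative change of cycle-mean port flows; lack of periodic convergence is
#' a warning, not an error.
#'
#' @param mask a [domain_mask()].
#' @param boundaries a [boundary_set()] covering every port of the mask.
#' @param props [fluid_properties()].
#' @param config [solver_config()].
#' @param snapshots_per_cycle store this many velocity snapshots over the
#'   final cycle (0 = none) for particle tracking.
#' @param progress print a line per cycle.
#' @param retry_on_cfl if a CFL violation occurs, restart with the time step
#'   halved, up to this many times (0 = fail immediately).
#' @return an object of class `flow_series`: cycle-averaged fields (`avg`),
#'   the per-step port flux table (`flux`), optional `snapshots`, solver
#'   `diagnostics`, and the solver context used.
#' @export
solve_cycles <- function(mask, boundaries, props = fluid_properties(),
                         config = solver_config(), snapshots_per_cycle = 0,
                         progress = FALSE, retry_on_cfl = 2) {
  repeat {
    res <- tryCatch(
      solve_cycles_once(mask, boundaries, props, config,
                        snapshots_per_cycle, progress),
      fontanflow_cfl_error = function(e) e)
    if (!inherits(res, "condition")) return(res)
    if (retry_on_cfl <= 0) stop(res)
    retry_on_cfl <- retry_on_cfl - 1
    config <- solver_config(time_step = config$time_step / 2,
                            cycle_period = config$cycle_period,
                            n_cycles = config$n_cycles,
                            pressure_tolerance = config$pressure_tolerance,
                            advection_scheme = config$advection_scheme,
                            cfl_limit = config$cfl_limit,
                            cg_maxiter = config$cg_maxiter,
                            outlet_relax = config$outlet_relax)
    message(sprintf("CFL violation: restarting with time_step = %.3g s",
                    config$time_step))
  }
}

solve_cycles_once <- function(mask, boundaries, props, config,
                              snapshots_per_cycle, progress) {
  ctx <- solver_context(mask, boundaries, props, config)
  state <- flow_state(mask)
  spc <- config$steps_per_cycle
  nsteps <- spc * config$n_cycles
  pn <- names(ctx$ports)
  flux_Q <- matrix(0, nsteps, length(pn), dimnames = list(NULL, pn))
  flux_P <- flux_Q; flux_E <- flux_Q
  avg <- list(u = state$u * 0, v = state$v * 0, w = state$w * 0,
              p = state$p * 0)
  nsnap <- as.integer(snapshots_per_cycle)
  snap <- NULL
  if (nsnap > 0) {
    stride <- max(1L, spc %/% nsnap)
    snap <- list(times = numeric(0),
                 u = matrix(0, length(state$u), 0),
                 v = matrix(0, length(state$v), 0),
                 w = matrix(0, length(state$w), 0), stride = stride)
  }
  ke_trace <- numeric(config$n_cycles)
  maxdiv <- 0
  cyc_mean_Q <- matrix(0, config$n_cycles, length(pn))

  for (step in seq_len(nsteps)) {
    cyc <- (step - 1L) %/% spc + 1L
    instep <- step - (cyc - 1L) * spc
    wavg <- if (cyc == config$n_cycles) 1 / spc else 0
    state <- advance_step(ctx, state, boundaries, props, config, avg, wavg)
    flux_Q[step, ] <- unlist(state$port$flow)[pn]
    flux_P[step, ] <- unlist(state$port$pressure)[pn]
    flux_E[step, ] <- unlist(state$port$energy)[pn]
    maxdiv <- max(maxdiv, state$maxdiv)
    if (cyc == config$n_cycles) {
      if (!is.null(snap) && instep %% snap$stride == 0L) {
        snap$times <- c(snap$times, state$t)
        snap$u <- cbind(snap$u, as.numeric(state$u))
        snap$v <- cbind(snap$v, as.numeric(state$v))
        snap$w <- cbind(snap$w, as.numeric(state$w))
      }
    }
    if (instep == spc) {
      ke_trace[cyc] <- state$ke
      cyc_mean_Q[cyc, ] <- colMeans(
        abs(flux_Q[((cyc - 1L) * spc + 1L):step, , drop = FALSE]))
      if (progress)
        message(sprintf("cycle %d/%d: KE %.3e J, max|div| %.2e 1/s",
                        cyc, config$n_cycles, state$ke, state$maxdiv))
    }
  }
  periodicity <- NA_real_
  if (config$n_cycles >= 2) {
    a <- cyc_mean_Q[config$n_cycles - 1L, ]
    b <- cyc_mean_Q[config$n_cycles, ]
    periodicity <- max(abs(b - a) / pmax(abs(a), 1e-12))
    if (periodicity > 0.02)
      warning(sprintf(
        "cycle-mean port flows changed %.1f%% over the last cycle; consider more cycles",
        100 * periodicity), call. = FALSE)
  }
  tgrid <- seq_len(nsteps) * config$time_step
  structure(list(
    mask = mask, config = config, props = props, boundaries = boundaries,
    ctx = ctx, avg = avg,
    flux = list(time = tgrid, Q = flux_Q, P = flux_P, E = flux_E),
    snapshots = snap,
    diagnostics = list(max_div = maxdiv, ke_per_cycle = ke_trace,
                       periodicity = periodicity,
                       final_cg = state$cg, final_maxvel = state$maxvel),
    state = state
  ), class = "flow_series")
}

#' @export
print.flow_series <- function(x, ...) {
  cat(sprintf(
    "<flow_series> %d cycles x %d steps (dt %.4g s) on %d lumen cells\n",
    x$config$n_cycles, x$config$steps_per_cycle, x$config$time_step,
    length(x$ctx$fcell0)))
  fl <- port_fluxes(x)
  for (nm in names(x$ctx$ports))
    cat(sprintf("  %s: Q %.3g L/min, P %.3g mmHg\n", nm,
                fl[[nm]]$flow * 6e4, pa_to_mmhg(fl[[nm]]$pressure)))
  invisible(x)
}

#' Volumetric flow and area-mean pressure at a port
#'
#' For a `flow_series` the values are averages over the final cycle; for a
#' `flow_state` they are the instantaneous values of the last step. Flux is
#' signed with outward normals (inflow is negative).
#'
#' @param x a `flow_series` or `flow_state`.
#' @param port port name.
#' @return list with `flow` (m^3/s), `pressure` (Pa), `energy` (W, total
#'   energy flux through the port) and `area` (m^2).
#' @export
port_flux <- function(x, port) {
  fl <- port_fluxes(x)
  if (!port %in% names(fl))
    validation_error(sprintf("unknown port '%s'", port))
  fl[[port]]
}

#' All per-port cycle-mean records of a run
#'
#' @param x a `flow_series` or `flow_state`.
#' @return named list of [port_flux()] records.
#' @export
port_fluxes <- function(x) {
  if (inherits(x, "flow_series")) {
    pn <- colnames(x$flux$Q)
    last <- (nrow(x$flux$Q) - x$config$steps_per_cycle + 1):nrow(x$flux$Q)
    out <- lapply(pn, function(nm) list(
      flow = mean(x$flux$Q[last, nm]),
      pressure = mean(x$flux$P[last, nm]),
      energy = mean(x$flux$E[last, nm]),
      area = x$ctx$ports[[nm]]$area))
    return(setNames(out, pn))
  }
  if (inherits(x, "flow_state")) {
    if (is.null(x$port))
      validation_error("flow_state has not been advanced yet")
    pn <- names(x$port$flow)
    ctx <- attr(x, "ctx")
    out <- lapply(pn, function(nm) list(
      flow = x$port$flow[[nm]], pressure = x$port$pressure[[nm]],
      energy = x$port$energy[[nm]],
      area = if (!is.null(ctx)) ctx$ports[[nm]]$area else NA_real_))
    return(setNames(out, pn))
  }
  validation_error("x must be a flow_series or flow_state")
}

#' Global mass balance of a run
#'
#' @param series a `flow_series`.
#' @return the magnitude of the signed sum of cycle-mean port fluxes as a
#'   fraction of total inflow.
#' @export
mass_balance_error <- function(series) {
  fl <- port_fluxes(series)
  q <- vapply(fl, `[[`, 0, "flow")
  inflow <- sum(abs(q[q < 0]))
  if (inflow == 0) return(0)
  abs(sum(q)) / inflow
}
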