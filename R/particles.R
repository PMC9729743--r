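#' Particle release schedule
#'
#' Massless tracers are released at the IVC inlet in equal batches every time
#' step over one respiratory cycle: `per_step` particles per step, for
#' `period / dt` steps (400 per 0.001 s over 2.54 s gives 2,540 release
#' events and 1,016,000 particles).
#'
#' @param period release window, s (one cycle).
#' @param dt interval between release events, s; must divide `period`.
#' @param per_step particles per event, >= 1.
#' @return an object of class `release_schedule` with `n_events`, `total`
#'   and the event times (relative to the window start).
#' @examples
#' release_schedule(2.54, 0.001, 400)$total  # 1,016,000
#' @export
release_schedule <- function(period = 2.54, dt = 0.001, per_step = 400) {
  if (per_step < 1) validation_error("per_step must be >= 1")
  ne <- period / dt
  if (abs(ne - round(ne)) > 1e-8)
    validation_error("dt must divide the release period into whole steps")
  ne <- as.integer(round(ne))
  structure(list(period = period, dt = dt, per_step = as.integer(per_step),
                 n_events = ne, total = as.integer(per_step) * ne,
                 times = (seq_len(ne) - 1L) * dt),
            class = "release_schedule")
}

PARTICLE_STATUS <- c(active = 0L, captured_LPA = 1L, captured_RPA = 2L,
                     escaped = 3L)

snapshot_stack <- function(series) {
  sn <- series$snapshots
  if (!is.null(sn) && length(sn$times) > 1) {
    list(u = sn$u, v = sn$v, w = sn$w, times = sn$times,
         period = series$config$cycle_period)
  } else {
    list(u = matrix(as.numeric(series$avg$u), ncol = 1),
         v = matrix(as.numeric(series$avg$v), ncol = 1),
         w = matrix(as.numeric(series$avg$w), ncol = 1),
         times = 0, period = series$config$cycle_period)
  }
}

#' Seed a particle ensemble at an inlet port
#'
#' Seeding positions are drawn across the inlet plane proportionally to the
#' local face influx (flux-weighted; uniform for a plug inlet), one batch per
#' release event, with uniform jitter inside each seeded cell. Reproducible
#' under `set.seed()`.
#'
#' @param series a `flow_series` (supplies geometry and fields).
#' @param schedule a [release_schedule()].
#' @param port inlet port to seed, default `"IVC"`.
#' @param t0 window start time, s; defaults to the first stored snapshot
#'   time (steady runs: 0).
#' @return an object of class `particle_ensemble`.
#' @export
seed_particles <- function(series, schedule, port = "IVC", t0 = NULL) {
  mask <- series$mask
  if (!port %in% names(mask$ports))
    validation_error(sprintf("unknown seeding port '%s'", port))
  stack <- snapshot_stack(series)
  t0 <- t0 %||% stack$times[1]
  pf <- port_faces_of_mask(mask)[[port]]
  h <- mask$spacing * 1e-3
  wgt <- abs(stack[[pf$comp]][pf$idx, 1])
  if (sum(wgt) <= 0) wgt <- rep(1, length(pf$idx))
  d <- mask$dim
  e <- pf$cells - 1L
  ci <- e %% d[1]; r2 <- e %/% d[1]
  cj <- r2 %% d[2]; ck <- r2 %/% d[2]
  ctr <- cbind(mask$origin[1] * 1e-3 + (ci + 0.5) * h,
               mask$origin[2] * 1e-3 + (cj + 0.5) * h,
               mask$origin[3] * 1e-3 + (ck + 0.5) * h)
  ax <- mask$ports[[port]]$axis
  n <- schedule$total
  pick <- sample.int(length(pf$idx), n, replace = TRUE, prob = wgt)
  pos <- ctr[pick, , drop = FALSE]
  for (b in setdiff(1:3, ax))
    pos[, b] <- pos[, b] + runif(n, -0.5, 0.5) * h
  # nudge off the port plane into the domain
  pos[, ax] <- pos[, ax] - mask$ports[[port]]$dir * 0.25 * h
  release <- t0 + rep(schedule$times, each = schedule$per_step)
  structure(list(pos = pos, release = release,
                 status = rep(PARTICLE_STATUS[["active"]], n),
                 t_capture = rep(NA_real_, n),
                 port = port, schedule = schedule, t0 = t0),
            class = "particle_ensemble")
}

#' @export
print.particle_ensemble <- function(x, ...) {
  tb <- table(factor(x$status, levels = PARTICLE_STATUS,
                     labels = names(PARTICLE_STATUS)))
  cat("<particle_ensemble>", nrow(x$pos), "particles:",
      paste(sprintf("%s %d", names(tb), tb), collapse = ", "), "\n")
  invisible(x)
}

#' Advect a particle ensemble through the solved flow
#'
#' Fourth-order Runge-Kutta integration with trilinear interpolation of the
#' staggered snapshot fields (linear and cycle-periodic in time; the cycle
#' average is used when no snapshots were stored). A particle is captured at
#' the first crossing of an outlet port plane; crossing an inlet plane or the
#' domain box elsewhere marks it escaped.
#'
#' @param ensemble a [seed_particles()] ensemble.
#' @param series the `flow_series` to advect through.
#' @param dt particle integration step, s.
#' @param t_end end of the tracking window, s; default: release window plus
#'   two drain cycles.
#' @return the updated `particle_ensemble`.
#' @export
advect <- function(ensemble, series, dt = 0.005, t_end = NULL) {
  mask <- series$mask
  stack <- snapshot_stack(series)
  t_end <- t_end %||%
    (ensemble$t0 + ensemble$schedule$period + 2 * series$config$cycle_period)
  plane_axis <- integer(0); plane_coord <- numeric(0)
  plane_dir <- integer(0); plane_code <- integer(0)
  for (nm in names(mask$ports)) {
    pm <- mask$ports[[nm]]
    code <- switch(nm, LPA = PARTICLE_STATUS[["captured_LPA"]],
                   RPA = PARTICLE_STATUS[["captured_RPA"]],
                   PARTICLE_STATUS[["escaped"]])
    plane_axis <- c(plane_axis, pm$axis - 1L)
    plane_coord <- c(plane_coord, pm$coord * 1e-3)
    plane_dir <- c(plane_dir, pm$dir)
    plane_code <- c(plane_code, code)
  }
  pos <- ensemble$pos + 0    # the kernel updates positions in place
  res <- .advect_particles_cpp(
    pos, ensemble$release, as.integer(ensemble$status),
    stack$u, stack$v, stack$w, stack$times, stack$period,
    as.integer(mask$dim), mask$origin * 1e-3, mask$spacing * 1e-3,
    plane_axis, plane_coord, plane_dir, as.integer(plane_code),
    t_end, dt)
  st <- res$status
  n_stranded <- sum(st == -1L)
  st[st == -1L] <- PARTICLE_STATUS[["escaped"]]
  ensemble$pos <- res$pos
  ensemble$status <- st
  ensemble$t_capture <- ifelse(is.na(ensemble$t_capture), res$t_capture,
                               ensemble$t_capture)
  attr(ensemble, "n_left_domain") <- n_stranded
  ensemble
}

#' IVC flow split from captured particles
#'
#' Percentages of captured particles at the left and right pulmonary artery
#' outlets. Particles still in transit at the end of the tracking window are
#' counted as escaped and excluded from the percentages.
#'
#' @param ensemble an advected [particle_ensemble].
#' @return an object of class `flow_split`: released/captured counts, LPA and
#'   RPA counts and percentages (summing to 100 over captured).
#' @export
flow_split <- function(ensemble) {
  st <- ensemble$status
  n_lpa <- sum(st == PARTICLE_STATUS[["captured_LPA"]])
  n_rpa <- sum(st == PARTICLE_STATUS[["captured_RPA"]])
  captured <- n_lpa + n_rpa
  if (captured == 0)
    validation_error("no particles captured; flow split undefined")
  structure(list(
    released = length(st), captured = captured,
    captured_lpa = n_lpa, captured_rpa = n_rpa,
    lpa_pct = 100 * n_lpa / captured, rpa_pct = 100 * n_rpa / captured,
    escaped = sum(st == PARTICLE_STATUS[["escaped"]]),
    active = sum(st == PARTICLE_STATUS[["active"]])
  ), class = "flow_split")
}

#' @export
print.flow_split <- function(x, ...) {
  cat(sprintf(
    "<flow_split> LPA %.1f%% / RPA %.1f%% (%d of %d released captured)\n",
    x$lpa_pct, x$rpa_pct, x$captured, x$released))
  invisible(x)
}

#' Release, advect and count in one call
#'
#' Convenience wrapper: seeds `per_step` particles per release event over one
#' cycle at the IVC, advects them through the stored fields with two drain
#' cycles, and returns the [flow_split()].
#'
#' @param series a `flow_series`.
#' @param per_step particles per release event.
#' @param seed RNG seed for the flux-weighted seeding positions.
#' @param dt particle integration step, s.
#' @param drain_cycles extra cycles of advection after the release window.
#' @param release_dt interval between release events, s; defaults to the
#'   solver time step.
#' @return a [flow_split()].
#' @export
track_ivc_split <- function(series, per_step = 50, seed = 1, dt = 0.005,
                            drain_cycles = 2,
                            release_dt = series$config$time_step) {
  sched <- release_schedule(series$config$cycle_period, release_dt, per_step)
  set.seed(seed)
  ens <- seed_particles(series, sched, "IVC")
  ens <- advect(ens, series, dt = dt,
                t_end = ens$t0 + sched$period +
                  drain_cycles * series$config$cycle_period)
  flow_split(ens)
}
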