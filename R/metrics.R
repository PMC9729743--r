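#' Caval-to-pulmonary pressure gradient
#'
#' PG = [(P_SVC + P_IVC) - (P_LPA + P_RPA)] / 2, converted to mmHg. The port
#' pressures are cycle-averaged area-mean pressures at the inlet planes and
#' at the pulmonary hilum planes (after the 50 mm branch extensions).
#'
#' @param x a `flow_series`, or a named list of [port_flux()] records, or a
#'   named numeric vector of port pressures in Pa. All four ports are
#'   required.
#' @return pressure gradient in mmHg.
#' @export
pressure_gradient <- function(x) {
  if (inherits(x, "flow_series")) x <- port_fluxes(x)
  if (is.list(x) && !is.null(names(x)) && all(vapply(x, is.list, TRUE)))
    x <- vapply(x, `[[`, 0, "pressure")
  missing <- setdiff(PORT_NAMES, names(x))
  if (length(missing))
    validation_error(sprintf("pressure gradient needs all four ports; missing %s",
                             paste(missing, collapse = ", ")))
  pa_to_mmhg(((x[["SVC"]] + x[["IVC"]]) - (x[["LPA"]] + x[["RPA"]])) / 2)
}

# port boundary-face table straight from a mask (mm units; h in m)
port_faces_of_mask <- function(mask) {
  dims <- mask$dim
  out <- list()
  for (nm in names(mask$ports)) {
    pm <- mask$ports[[nm]]
    e <- pm$cells - 1L
    i <- e %% dims[1]; r2 <- e %/% dims[1]
    j <- r2 %% dims[2]; k <- r2 %/% dims[2]
    if (pm$axis == 1L) {
      fd <- c(dims[1] + 1L, dims[2], dims[3])
      fi <- if (pm$dir < 0) i else i + 1L
      idx <- 1L + fi + fd[1] * (j + fd[2] * k)
      comp <- "u"
    } else if (pm$axis == 2L) {
      fd <- c(dims[1], dims[2] + 1L, dims[3])
      fj <- if (pm$dir < 0) j else j + 1L
      idx <- 1L + i + fd[1] * (fj + fd[2] * k)
      comp <- "v"
    } else {
      fd <- c(dims[1], dims[2], dims[3] + 1L)
      fk <- if (pm$dir < 0) k else k + 1L
      idx <- 1L + i + fd[1] * (j + fd[2] * fk)
      comp <- "w"
    }
    out[[nm]] <- list(comp = comp, idx = idx, sign = pm$dir, cells = pm$cells)
  }
  out
}

#' Total-energy flux through a port
#'
#' Discrete surface integral of \eqn{(p + \tfrac12 \rho |u|^2)\, u \cdot n}
#' over the port plane with outward normal: positive values are energy
#' leaving the domain. For a `flow_series` the value is the cycle mean of the
#' instantaneous flux recorded at every step; the field-based form evaluates
#' the integral on supplied snapshot fields.
#'
#' @param x a `flow_series`, or a list `list(u=,v=,w=,p=)` of staggered-grid
#'   arrays (SI units) when `mask` is given.
#' @param port port name.
#' @param mask the [domain_mask()] (field-based form only).
#' @param props [fluid_properties()].
#' @return energy flux in W.
#' @export
energy_flux <- function(x, port, mask = NULL,
                        props = fluid_properties()) {
  if (inherits(x, "flow_series")) {
    fl <- port_flux(x, port)
    return(fl$energy)
  }
  if (is.null(mask))
    validation_error("field-based energy_flux needs the domain mask")
  pf <- port_faces_of_mask(mask)
  if (!port %in% names(pf))
    validation_error(sprintf("unknown port '%s'", port))
  tab <- pf[[port]]
  h <- mask$spacing * 1e-3
  uf <- x[[tab$comp]][tab$idx]
  pc <- x$p[tab$cells]
  sum((pc + 0.5 * props$density * uf^2) * (tab$sign * uf) * h^2)
}

#' Energy efficiency of the connection
#'
#' The ratio of total-energy outflux at the pulmonary outlets to
#' total-energy influx at the caval inlets; its complement (times the
#' influx) is the dissipated power. Efficiency lies in (0, 1] for
#' dissipative flow and falls as exercise raises the flow rate.
#'
#' @param x a `flow_series`, or the inlet energy influx in W (positive).
#' @param outflux outlet energy outflux in W (used with the numeric form).
#' @return list with `efficiency` (fraction), `dissipated_power` (W),
#'   `influx` and `outflux` (W).
#' @export
energy_efficiency <- function(x, outflux = NULL) {
  if (inherits(x, "flow_series")) {
    fl <- port_fluxes(x)
    en <- vapply(fl, `[[`, 0, "energy")
    inl <- intersect(names(x$boundaries$waveforms), names(en))
    out <- intersect(names(x$boundaries$resistances), names(en))
    influx <- -sum(en[inl])   # outward-normal integral is negative at inlets
    outflx <- sum(en[out])
  } else {
    influx <- x
    outflx <- outflux
  }
  if (!is.finite(influx) || influx <= 0)
    validation_error("inlet energy influx must be positive; efficiency undefined")
  list(efficiency = abs(outflx) / abs(influx),
       dissipated_power = influx - outflx,
       influx = influx, outflux = outflx)
}

slab_cells <- function(mask, axis, coord, region = NULL) {
  ax <- match(axis, c("x", "y", "z"))
  if (is.na(ax)) validation_error("axis must be 'x', 'y' or 'z'")
  h <- mask$spacing
  slab <- as.integer(floor((coord - mask$origin[ax]) / h)) + 1L
  if (slab < 1L || slab > mask$dim[ax])
    validation_error("section plane lies outside the domain")
  d <- mask$dim
  idx <- switch(ax, which(mask$lumen[slab, , , drop = FALSE]),
                which(mask$lumen[, slab, , drop = FALSE]),
                which(mask$lumen[, , slab, drop = FALSE]))
  if (length(idx) == 0) validation_error("section plane misses the lumen")
  full <- slab_to_full(idx, slab, ax, d)
  if (!is.null(region)) {
    e <- full - 1L
    ci <- e %% d[1]; r2 <- e %/% d[1]
    cj <- r2 %% d[2]; ck <- r2 %/% d[2]
    ctr <- cbind(mask$origin[1] + (ci + 0.5) * h,
                 mask$origin[2] + (cj + 0.5) * h,
                 mask$origin[3] + (ck + 0.5) * h)
    keep <- rep(TRUE, length(full))
    for (b in names(region)) {
      bx <- match(b, c("x", "y", "z"))
      keep <- keep & ctr[, bx] >= region[[b]][1] & ctr[, bx] <= region[[b]][2]
    }
    full <- full[keep]
    if (length(full) == 0) validation_error("section region misses the lumen")
  }
  full
}

cell_speed <- function(fields, dims, cells) {
  e <- cells - 1L
  i <- e %% dims[1]; r2 <- e %/% dims[1]
  j <- r2 %% dims[2]; k <- r2 %/% dims[2]
  fdu <- c(dims[1] + 1L, dims[2], dims[3])
  fdv <- c(dims[1], dims[2] + 1L, dims[3])
  fdw <- c(dims[1], dims[2], dims[3] + 1L)
  lu <- function(ii, jj, kk) fields$u[1L + ii + fdu[1] * (jj + fdu[2] * kk)]
  lv <- function(ii, jj, kk) fields$v[1L + ii + fdv[1] * (jj + fdv[2] * kk)]
  lw <- function(ii, jj, kk) fields$w[1L + ii + fdw[1] * (jj + fdw[2] * kk)]
  uc <- 0.5 * (lu(i, j, k) + lu(i + 1L, j, k))
  vc <- 0.5 * (lv(i, j, k) + lv(i, j + 1L, k))
  wc <- 0.5 * (lw(i, j, k) + lw(i, j, k + 1L))
  sqrt(uc^2 + vc^2 + wc^2)
}

#' Area-weighted mean velocity magnitude over a section plane
#'
#' Cycle-averaged velocity magnitude averaged over the lumen cells the
#' axis-aligned plane intersects (uniform cells, so a plain mean). The
#' conduit measurement plane of the design comparison sits one trunk
#' diameter downstream of the Y bifurcation, and at the same height for the
#' T conduit.
#'
#' @param series a `flow_series`.
#' @param axis `"x"`, `"y"` or `"z"` (plane normal).
#' @param coord plane coordinate, mm.
#' @param region optional named list of `c(lo, hi)` bounds (mm) restricting
#'   the section in the other axes.
#' @return mean speed, m/s. The matching section area (m^2) is attached as
#'   attribute `"area"`.
#' @export
section_mean_velocity <- function(series, axis, coord, region = NULL) {
  mask <- series$mask
  cells <- slab_cells(mask, axis, coord, region)
  sp <- cell_speed(series$avg, mask$dim, cells)
  structure(mean(sp), area = length(cells) * (mask$spacing * 1e-3)^2)
}

#' Mean pressure over a section plane
#'
#' @inheritParams section_mean_velocity
#' @return mean cycle-averaged pressure, Pa.
#' @export
section_mean_pressure <- function(series, axis, coord, region = NULL) {
  cells <- slab_cells(series$mask, axis, coord, region)
  mean(series$avg$p[cells])
}

#' Hemodynamic indicator report for one run
#'
#' Gathers the four indicators of the design comparison from a solved run:
#' pressure gradient, section velocity at the conduit measurement plane,
#' energy efficiency (with dissipated power), and, when supplied, the
#' particle-derived IVC flow split.
#'
#' @param series a `flow_series` for one design at one exercise level.
#' @param tree the [build_design()] tree the run simulated.
#' @param level exercise level name.
#' @param split optional [flow_split()] result.
#' @return an object of class `hemodynamic_report` (one-row data.frame).
#' @export
hemodynamic_report <- function(series, tree, level, split = NULL) {
  design <- tree$design
  lay <- tree$layout
  zsec <- -lay$bifurcation_standoff + design$trunk_diameter
  if (design$topology == "T") {
    xr <- design$left_anastomosis_offset + c(-1, 1) * design$trunk_diameter
  } else {
    xr <- range(design$left_anastomosis_offset,
                design$right_anastomosis_offset) +
      c(-1, 1) * design$branch_diameter
  }
  vel <- section_mean_velocity(series, "z", zsec, region = list(x = xr))
  eff <- energy_efficiency(series)
  pg <- pressure_gradient(series)
  out <- data.frame(
    design = design$label, level = level,
    pg_mmhg = pg,
    section_velocity_ms = as.numeric(vel),
    efficiency = eff$efficiency,
    dissipated_power_w = eff$dissipated_power,
    lpa_pct = if (is.null(split)) NA_real_ else split$lpa_pct,
    rpa_pct = if (is.null(split)) NA_real_ else split$rpa_pct,
    mass_balance = mass_balance_error(series),
    stringsAsFactors = FALSE
  )
  class(out) <- c("hemodynamic_report", "data.frame")
  out
}
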