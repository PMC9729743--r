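#' Idealized anatomical layout of the cavopulmonary junction
#'
#' The synthetic junction stands in for patient-specific anatomy: the
#' pulmonary artery (PA) is a straight tube along the x axis, the caval axes
#' are perpendicular to it (cranio-caudal = z), and units are mm throughout.
#' The right-handed frame puts the left hilum at negative x.
#'
#' @param pa_diameter pulmonary-artery diameter, mm.
#' @param pa_half_length PA half length from midline to each hilum port, mm.
#'   Must leave at least 50 mm of PA beyond the outermost anastomosis, which
#'   stabilises the outlet flow before it reaches the measurement plane.
#' @param svc_diameter,svc_length superior vena cava diameter and length
#'   above the PA axis, mm.
#' @param ivc_port_depth distance of the IVC inlet plane below the PA axis, mm.
#' @param bifurcation_standoff distance below the PA axis at which a Y-graft
#'   trunk splits into its two branches, mm.
#' @return an object of class `anatomical_layout`.
#' @export
anatomical_layout <- function(pa_diameter = 16, pa_half_length = 70,
                              svc_diameter = 14, svc_length = 45,
                              ivc_port_depth = 60,
                              bifurcation_standoff = 30) {
  vals <- c(pa_diameter, pa_half_length, svc_diameter, svc_length,
            ivc_port_depth, bifurcation_standoff)
  if (any(!is.finite(vals)) || any(vals <= 0))
    validation_error("all layout dimensions must be positive finite lengths (mm)")
  if (bifurcation_standoff >= ivc_port_depth)
    validation_error("bifurcation_standoff must be smaller than ivc_port_depth")
  structure(list(
    pa_diameter = pa_diameter, pa_half_length = pa_half_length,
    svc_diameter = svc_diameter, svc_length = svc_length,
    ivc_port_depth = ivc_port_depth,
    bifurcation_standoff = bifurcation_standoff
  ), class = "anatomical_layout")
}

new_segment <- function(name, p0, p1, r0, r1 = r0,
                        cap0 = "round", cap1 = "round") {
  list(name = name, p0 = as.numeric(p0), p1 = as.numeric(p1),
       r0 = r0, r1 = r1, cap0 = cap0, cap1 = cap1)
}

new_port <- function(origin, normal, radius, segment) {
  list(origin = as.numeric(origin), normal = as.numeric(normal),
       radius = radius, segment = segment)
}

#' Build the vessel tree for a conduit design
#'
#' Assembles the four-port junction (SVC and IVC inlets, LPA and RPA hilum
#' outlets) as a union of straight circular segments: the PA tube, the SVC,
#' and either a single T conduit or a Y-graft trunk plus two branches.
#' Anastomoses are smooth tube unions; the lumen is the union of the
#' segment capsules.
#'
#' @param design a [conduit_design()].
#' @param layout an [anatomical_layout()].
#' @return an object of class `vessel_tree` with `segments` and four named
#'   `ports` (plane origin, outward unit normal, radius in mm).
#' @examples
#' tree <- build_design(reference_designs()$D, anatomical_layout())
#' port_area(tree, "IVC")
#' @export
build_design <- function(design, layout = anatomical_layout()) {
  if (!inherits(design, "conduit_design"))
    validation_error("design must be a conduit_design")
  if (!inherits(layout, "anatomical_layout"))
    validation_error("layout must be an anatomical_layout")
  offs <- c(design$left_anastomosis_offset, design$right_anastomosis_offset,
            design$svc_offset)
  ext <- layout$pa_half_length - max(abs(offs))
  if (ext < 50)
    geometry_error(sprintf(
      "pulmonary branches extend only %.1f mm beyond the outermost anastomosis (need >= 50)",
      ext))
  r_pa <- layout$pa_diameter / 2
  r_svc <- layout$svc_diameter / 2
  r_tr <- design$trunk_diameter / 2
  L <- layout$pa_half_length

  segs <- list(
    new_segment("PA", c(-L, 0, 0), c(L, 0, 0), r_pa,
                cap0 = "port", cap1 = "port"),
    new_segment("SVC", c(design$svc_offset, 0, layout$svc_length),
                c(design$svc_offset, 0, 0), r_svc, cap0 = "port")
  )
  if (design$topology == "T") {
    segs <- c(segs, list(
      new_segment("conduit",
                  c(design$left_anastomosis_offset, 0, -layout$ivc_port_depth),
                  c(design$left_anastomosis_offset, 0, 0),
                  r_tr, cap0 = "port")
    ))
    ivc_seg <- "conduit"
    ivc_origin <- c(design$left_anastomosis_offset, 0, -layout$ivc_port_depth)
  } else {
    r_br <- design$branch_diameter / 2
    bif <- c(design$svc_offset, 0, -layout$bifurcation_standoff)
    segs <- c(segs, list(
      new_segment("trunk",
                  c(design$svc_offset, 0, -layout$ivc_port_depth), bif,
                  r_tr, cap0 = "port"),
      new_segment("branch_L", bif,
                  c(design$left_anastomosis_offset, 0, 0), r_br),
      new_segment("branch_R", bif,
                  c(design$right_anastomosis_offset, 0, 0), r_br)
    ))
    ivc_seg <- "trunk"
    ivc_origin <- c(design$svc_offset, 0, -layout$ivc_port_depth)
  }

  ports <- list(
    SVC = new_port(c(design$svc_offset, 0, layout$svc_length), c(0, 0, 1),
                   r_svc, "SVC"),
    IVC = new_port(ivc_origin, c(0, 0, -1), r_tr, ivc_seg),
    LPA = new_port(c(-L, 0, 0), c(-1, 0, 0), r_pa, "PA"),
    RPA = new_port(c(L, 0, 0), c(1, 0, 0), r_pa, "PA")
  )
  structure(list(design = design, layout = layout, segments = segs,
                 ports = ports),
            class = "vessel_tree")
}

#' @export
print.vessel_tree <- function(x, ...) {
  cat(sprintf("<vessel_tree> %s: %d segments, ports %s\n",
              x$design$label %||% "?", length(x$segments),
              paste(names(x$ports), collapse = "/")))
  for (s in x$segments)
    cat(sprintf("  %-9s (%.0f,%.0f,%.0f) -> (%.0f,%.0f,%.0f)  r %.1f mm\n",
                s$name, s$p0[1], s$p0[2], s$p0[3], s$p1[1], s$p1[2], s$p1[3],
                s$r0))
  invisible(x)
}

#' Cross-sectional area of a port plane
#'
#' @param tree a [build_design()] vessel tree.
#' @param port one of `"SVC"`, `"IVC"`, `"LPA"`, `"RPA"`.
#' @return area in mm^2 (`pi * r^2` of the circular port plane).
#' @export
port_area <- function(tree, port) {
  if (!port %in% names(tree$ports))
    validation_error(sprintf("unknown port '%s'", port))
  pi * tree$ports[[port]]$radius^2
}
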