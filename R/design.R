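#' Parametric description of an extracardiac conduit design
#'
#' A conduit design describes how the inferior vena cava (IVC) is routed to
#' the pulmonary arteries in a total cavopulmonary connection: either a
#' single straight conduit (`"T"` topology, the classical TCPC) or a
#' bifurcated Y-graft (`"Y"` topology, YCPC) whose two branches anastomose to
#' the left and right pulmonary artery with the superior vena cava (SVC)
#' joining between them.
#'
#' Anastomosis offsets are signed distances in mm along the pulmonary-artery
#' axis, measured from the midline; negative is towards the left hilum.
#'
#' @param label short text identifier, e.g. `"A-20T"` or `"D-14Y"`.
#' @param topology `"T"` (single conduit) or `"Y"` (bifurcated graft).
#' @param trunk_diameter conduit trunk diameter, mm.
#' @param branch_diameter Y-branch diameter, mm; ignored for `"T"`.
#' @param left_anastomosis_offset,right_anastomosis_offset signed offsets of
#'   the branch (or, for `"T"`, the single conduit via the left offset)
#'   anastomoses along the pulmonary artery, mm.
#' @param svc_offset signed offset of the SVC anastomosis, mm.
#' @return an object of class `conduit_design`.
#' @examples
#' conduit_design("D-14Y", "Y", trunk_diameter = 20, branch_diameter = 14)
#' @export
conduit_design <- function(label, topology = c("T", "Y"),
                           trunk_diameter,
                           branch_diameter = NA_real_,
                           left_anastomosis_offset = -15,
                           right_anastomosis_offset = 15,
                           svc_offset = if (match.arg(topology) == "T") 15 else 0) {
  topology <- match.arg(topology)
  if (!is.numeric(trunk_diameter) || length(trunk_diameter) != 1 ||
      !is.finite(trunk_diameter) || trunk_diameter <= 0)
    validation_error("trunk_diameter must be a single positive length (mm)")
  if (topology == "Y") {
    if (!is.numeric(branch_diameter) || length(branch_diameter) != 1 ||
        !is.finite(branch_diameter) || branch_diameter <= 0)
      validation_error("Y topology requires a positive branch_diameter (mm)")
    if (branch_diameter >= trunk_diameter)
      validation_error("branch_diameter must be smaller than trunk_diameter")
    if (abs(left_anastomosis_offset - right_anastomosis_offset) <= branch_diameter)
      geometry_error("branch anastomoses overlap: |left - right| must exceed branch_diameter")
    lo <- min(left_anastomosis_offset, right_anastomosis_offset)
    hi <- max(left_anastomosis_offset, right_anastomosis_offset)
    if (svc_offset <= lo || svc_offset >= hi)
      geometry_error("SVC anastomosis must lie strictly between the two branch anastomoses")
  }
  structure(list(
    label = label,
    topology = topology,
    trunk_diameter = trunk_diameter,
    branch_diameter = if (topology == "Y") branch_diameter else NA_real_,
    left_anastomosis_offset = left_anastomosis_offset,
    right_anastomosis_offset = right_anastomosis_offset,
    svc_offset = svc_offset
  ), class = "conduit_design")
}

#' @export
print.conduit_design <- function(x, ...) {
  cat(sprintf("<conduit_design> %s: %s, trunk %g mm", x$label,
              if (x$topology == "T") "T (single conduit)" else "Y (bifurcated graft)",
              x$trunk_diameter))
  if (x$topology == "Y") cat(sprintf(", branches %g mm", x$branch_diameter))
  cat(sprintf("\n  anastomoses L %+g / R %+g mm, SVC %+g mm\n",
              x$left_anastomosis_offset, x$right_anastomosis_offset,
              x$svc_offset))
  invisible(x)
}

#' Area- and diameter-preservation predicates for Y-grafts
#'
#' A Y-graft is *area-preserving* when the two branch cross-sections sum to
#' the trunk cross-section, i.e. `|2 r_b^2 - r_t^2| / r_t^2 <= tol`
#' (a 20-14-14 mm graft: 2*7^2/10^2 = 0.98). It is *diameter-preserving*
#' when the branch diameters sum exactly to the trunk diameter (20-10-10 mm).
#'
#' @param design a [conduit_design()] with `"Y"` topology.
#' @param tol relative tolerance on the area ratio (default 0.05).
#' @return logical scalar. `FALSE` for `"T"` topology.
#' @export
is_area_preserving <- function(design, tol = 0.05) {
  if (design$topology != "Y") return(FALSE)
  rt <- design$trunk_diameter / 2
  rb <- design$branch_diameter / 2
  abs(2 * rb^2 - rt^2) / rt^2 <= tol
}

#' @rdname is_area_preserving
#' @export
is_diameter_preserving <- function(design) {
  design$topology == "Y" &&
    isTRUE(all.equal(2 * design$branch_diameter, design$trunk_diameter))
}

#' The four candidate conduit designs of the virtual-surgery comparison
#'
#' Group A: conventional 20 mm T conduit (IVC anastomosed near the left
#' hilum, SVC near the right hilum). Groups B-D: Y-grafts with a 20 mm trunk
#' and 10 / 12 / 14 mm branches; B is diameter-preserving, D is
#' area-preserving, C is intermediate. Branches anastomose near the left and
#' right hilum with the SVC joining midway between them.
#'
#' @param branch_offsets length-2 signed offsets (mm) of the Y branches
#'   (and, reused, of the T conduit / SVC for group A).
#' @return named list of four [conduit_design()] objects `A`, `B`, `C`, `D`.
#' @export
reference_designs <- function(branch_offsets = c(-15, 15)) {
  lo <- branch_offsets[1]; ro <- branch_offsets[2]
  list(
    A = conduit_design("A-20T", "T", 20,
                       left_anastomosis_offset = lo,
                       right_anastomosis_offset = ro, svc_offset = ro),
    B = conduit_design("B-10Y", "Y", 20, 10, lo, ro, 0),
    C = conduit_design("C-12Y", "Y", 20, 12, lo, ro, 0),
    D = conduit_design("D-14Y", "Y", 20, 14, lo, ro, 0)
  )
}
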