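#' Low-level domain-mask constructor
#'
#' Wraps a voxelized lumen indicator into the mask object the solver
#' consumes. Normally produced by [voxelize()]; exposed so that simple
#' rectangular or analytic test domains can be built programmatically.
#'
#' @param lumen logical (or 0/1) 3-d array; `TRUE` marks lumen cells.
#' @param port integer 3-d array, 0 = none, otherwise the position of the
#'   port name in `c("SVC","IVC","LPA","RPA")`.
#' @param spacing uniform grid spacing, mm.
#' @param origin coordinates of the lower box corner, mm (length 3).
#' @param ports named list giving, per labelled port, `axis` (1=x,2=y,3=z),
#'   `dir` (+1 upper box face, -1 lower) and `radius` (mm, may be `NA`).
#' @return an object of class `domain_mask`.
#' @export
domain_mask <- function(lumen, port, spacing, origin, ports) {
  lumen <- array(as.logical(lumen), dim = dim(lumen))
  storage.mode(port) <- "integer"
  if (!identical(dim(lumen), dim(port)))
    validation_error("lumen and port arrays must share dimensions")
  dims <- dim(lumen)
  for (nm in names(ports)) {
    pid <- match(nm, PORT_NAMES)
    if (is.na(pid)) validation_error(sprintf("unknown port name '%s'", nm))
    cells <- which(port == pid)
    if (length(cells) == 0L)
      geometry_error(sprintf("port %s has no labelled cells", nm))
    if (any(!lumen[cells]))
      validation_error(sprintf("port %s labels non-lumen cells", nm))
    ax <- ports[[nm]]$axis; dir <- ports[[nm]]$dir
    ports[[nm]]$coord <- origin[ax] +
      if (dir > 0) dims[ax] * spacing else 0
    ports[[nm]]$cells <- cells
    ports[[nm]]$id <- pid
  }
  structure(list(spacing = spacing, origin = as.numeric(origin), dim = dims,
                 lumen = lumen, port = port, ports = ports),
            class = "domain_mask")
}

#' @export
print.domain_mask <- function(x, ...) {
  cat(sprintf("<domain_mask> %d x %d x %d cells at %.3g mm, %d lumen cells\n",
              x$dim[1], x$dim[2], x$dim[3], x$spacing, sum(x$lumen)))
  for (nm in names(x$ports))
    cat(sprintf("  port %s: %d cells\n", nm, length(x$ports[[nm]]$cells)))
  invisible(x)
}

#' Voxelize a vessel tree onto a uniform Cartesian grid
#'
#' Rasterises the union of segment capsules/frustums onto a uniform lattice
#' (stair-step immersed boundary). Port planes are snapped to the lattice so
#' that every port lies exactly on a box face; the port-capped segment ends
#' are cut flat at those planes. The lumen must come out as a single
#' 6-connected component.
#'
#' @param tree a [build_design()] vessel tree.
#' @param spacing grid spacing, mm. Must not exceed one third of the
#'   smallest segment radius, otherwise a resolution error is raised.
#' @return a [domain_mask()] object.
#' @examples
#' tree <- build_design(reference_designs()$A, anatomical_layout())
#' mask <- voxelize(tree, spacing = 2)
#' voxel_volume(mask)
#' @export
voxelize <- function(tree, spacing) {
  if (!inherits(tree, "vessel_tree"))
    validation_error("tree must be a vessel_tree")
  if (length(tree$segments) == 0)
    validation_error("vessel tree has no segments")
  rmin <- min(vapply(tree$segments, function(s) min(s$r0, s$r1), 0))
  if (spacing > rmin / 3)
    resolution_error(sprintf(
      "spacing %.3g mm too coarse for smallest radius %.3g mm (need <= r/3 = %.3g)",
      spacing, rmin, rmin / 3))
  h <- spacing

  # snap port planes to the lattice and cut the owning segment ends there
  segs <- tree$segments
  ports <- tree$ports
  for (nm in names(ports)) {
    pt <- ports[[nm]]
    ax <- which(pt$normal != 0)
    dir <- sign(pt$normal[ax])
    coord <- round(pt$origin[ax] / h) * h
    ports[[nm]]$origin[ax] <- coord
    ports[[nm]]$axis <- ax
    ports[[nm]]$dir <- dir
    ports[[nm]]$coord <- coord
    si <- which(vapply(segs, function(s) s$name, "") == pt$segment)
    for (ii in si) {
      s <- segs[[ii]]
      if (s$cap0 == "port" && max(abs(s$p0 - pt$origin)) < 1e-6)
        segs[[ii]]$p0[ax] <- coord
      if (s$cap1 == "port" && max(abs(s$p1 - pt$origin)) < 1e-6)
        segs[[ii]]$p1[ax] <- coord
    }
  }

  ext_lo <- rep(Inf, 3); ext_hi <- rep(-Inf, 3)
  for (s in segs) {
    r <- max(s$r0, s$r1)
    ext_lo <- pmin(ext_lo, pmin(s$p0, s$p1) - r)
    ext_hi <- pmax(ext_hi, pmax(s$p0, s$p1) + r)
  }
  lo <- floor(ext_lo / h - 1) * h
  hi <- ceiling(ext_hi / h + 1) * h
  for (nm in names(ports)) {
    pt <- ports[[nm]]
    if (pt$dir < 0) lo[pt$axis] <- pt$coord else hi[pt$axis] <- pt$coord
  }
  dims <- as.integer(round((hi - lo) / h))
  if (any(dims < 2)) geometry_error("degenerate voxel grid")

  cx <- lo[1] + (seq_len(dims[1]) - 0.5) * h
  cy <- lo[2] + (seq_len(dims[2]) - 0.5) * h
  cz <- lo[3] + (seq_len(dims[3]) - 0.5) * h
  X <- rep(cx, times = dims[2] * dims[3])
  Y <- rep(rep(cy, each = dims[1]), times = dims[3])
  Z <- rep(cz, each = dims[1] * dims[2])

  lumen <- rep(FALSE, prod(dims))
  for (s in segs) {
    d <- s$p1 - s$p0
    L2 <- sum(d^2)
    px <- X - s$p0[1]; py <- Y - s$p0[2]; pz <- Z - s$p0[3]
    t <- (px * d[1] + py * d[2] + pz * d[3]) / L2
    tc <- pmin(pmax(t, 0), 1)
    r <- s$r0 + (s$r1 - s$r0) * tc
    dist2 <- (px - tc * d[1])^2 + (py - tc * d[2])^2 + (pz - tc * d[3])^2
    inside <- dist2 <= r^2
    # flat cuts at port-capped ends (half-cell tolerance keeps the cap layer)
    if (s$cap0 == "port") inside <- inside & (t >= -0.5 * h / sqrt(L2))
    if (s$cap1 == "port") inside <- inside & (t <= 1 + 0.5 * h / sqrt(L2))
    lumen <- lumen | inside
  }
  dim(lumen) <- dims

  comp <- .flood_fill_cpp(as.integer(lumen), dims)
  ncomp <- attr(comp, "n_components")
  if (ncomp == 0) geometry_error("voxelized lumen is empty")
  if (ncomp > 1) {
    sizes <- tabulate(comp[comp > 0], nbins = ncomp)
    # discard droplets from capsule blends but refuse truly split lumens
    if (sort(sizes, decreasing = TRUE)[2] > 0.01 * max(sizes))
      geometry_error("voxelized lumen is not a single connected component")
    keep <- which.max(sizes)
    lumen <- array(comp == keep, dim = dims)
  }

  port <- array(0L, dim = dims)
  pmeta <- list()
  for (nm in names(ports)) {
    pt <- ports[[nm]]
    pid <- match(nm, PORT_NAMES)
    slab <- if (pt$dir < 0) 1L else dims[pt$axis]
    idx <- switch(pt$axis,
                  which(lumen[slab, , , drop = FALSE]),
                  which(lumen[, slab, , drop = FALSE]),
                  which(lumen[, , slab, drop = FALSE]))
    if (length(idx) == 0)
      geometry_error(sprintf("port %s has no lumen cells on its plane", nm))
    full <- slab_to_full(idx, slab, pt$axis, dims)
    port[full] <- pid
    pmeta[[nm]] <- list(axis = pt$axis, dir = pt$dir, radius = pt$radius)
  }
  domain_mask(lumen, port, h, lo, pmeta)
}

# expand linear indices within an axis-slab to full-array linear indices
slab_to_full <- function(idx, slab, axis, dims) {
  idx <- idx - 1L
  if (axis == 1L) {
    j <- idx %% dims[2]; k <- idx %/% dims[2]
    i <- slab - 1L
  } else if (axis == 2L) {
    i <- idx %% dims[1]; k <- idx %/% dims[1]
    j <- slab - 1L
  } else {
    i <- idx %% dims[1]; j <- idx %/% dims[1]
    k <- slab - 1L
  }
  1L + i + dims[1] * (j + dims[2] * k)
}

#' Total lumen volume of a voxel mask
#'
#' @param mask a [domain_mask()].
#' @return volume in mm^3 (`n_lumen * spacing^3`); converges to the analytic
#'   union-of-capsules volume as spacing shrinks.
#' @export
voxel_volume <- function(mask) sum(mask$lumen) * mask$spacing^3
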