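#' Extract the boundary surface of a voxel mask as triangles
#'
#' Each lumen cell face exposed to the outside (wall or domain boundary)
#' contributes two triangles, giving a watertight stair-step surface.
#'
#' @param mask a [domain_mask()].
#' @return list with `vertices` (n x 3, mm) and `normals` (per triangle).
#' @keywords internal
mask_surface <- function(mask) {
  d <- mask$dim; h <- mask$spacing; o <- mask$origin
  lum <- mask$lumen
  verts <- list(); norms <- list()
  shift <- function(a, ax, by) {
    out <- array(FALSE, dim = dim(a))
    n <- dim(a)[ax]
    idx_src <- seq_len(n - abs(by))
    if (by > 0) {
      if (ax == 1) out[idx_src + by, , ] <- a[idx_src, , ]
      if (ax == 2) out[, idx_src + by, ] <- a[, idx_src, ]
      if (ax == 3) out[, , idx_src + by] <- a[, , idx_src]
    } else {
      if (ax == 1) out[idx_src, , ] <- a[idx_src - by, , ]
      if (ax == 2) out[, idx_src, ] <- a[, idx_src - by, ]
      if (ax == 3) out[, , idx_src] <- a[, , idx_src - by]
    }
    out
  }
  axes <- list(c(2, 3), c(1, 3), c(1, 2))
  for (ax in 1:3) for (dir in c(-1, 1)) {
    nb <- shift(lum, ax, -dir) # neighbour cell in +dir direction of each cell
    exposed <- which(lum & !nb)
    if (length(exposed) == 0) next
    e0 <- exposed - 1L
    i <- e0 %% d[1]; r <- e0 %/% d[1]; j <- r %% d[2]; k <- r %/% d[2]
    ctr <- cbind(o[1] + (i + 0.5) * h, o[2] + (j + 0.5) * h,
                 o[3] + (k + 0.5) * h)
    face_ctr <- ctr
    face_ctr[, ax] <- face_ctr[, ax] + dir * h / 2
    t1 <- axes[[ax]][1]; t2 <- axes[[ax]][2]
    mk <- function(s1, s2) {
      v <- face_ctr
      v[, t1] <- v[, t1] + s1 * h / 2
      v[, t2] <- v[, t2] + s2 * h / 2
      v
    }
    a <- mk(-1, -1); b <- mk(1, -1); cc <- mk(1, 1); dd <- mk(-1, 1)
    if (dir > 0) {
      tri <- rbind_interleave(a, b, cc, a, cc, dd)
    } else {
      tri <- rbind_interleave(a, cc, b, a, dd, cc)
    }
    nrm <- matrix(0, nrow(tri) / 3, 3)
    nrm[, ax] <- dir
    verts[[length(verts) + 1]] <- tri
    norms[[length(norms) + 1]] <- nrm
  }
  list(vertices = do.call(rbind, verts), normals = do.call(rbind, norms))
}

rbind_interleave <- function(...) {
  ms <- list(...)
  n <- nrow(ms[[1]]); k <- length(ms)
  out <- matrix(0, n * k, 3)
  for (q in seq_len(k)) out[seq(q, n * k, by = k), ] <- ms[[q]]
  out
}

#' Write and read ASCII STL surfaces
#'
#' Plain-text STL keeps the exported surfaces human-readable and
#' round-trippable with [read_stl()].
#'
#' @param surface list with `vertices` (3 rows per triangle) and `normals`.
#' @param path output file.
#' @param name solid name recorded in the file.
#' @return `path`, invisibly.
#' @export
write_stl <- function(surface, path, name = "fontanflow") {
  v <- surface$vertices
  nrm <- surface$normals
  ntri <- nrow(v) / 3
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("solid %s", name), con)
  i1 <- seq(1, nrow(v), by = 3)
  blocks <- sprintf(
    "facet normal %g %g %g\n outer loop\n  vertex %g %g %g\n  vertex %g %g %g\n  vertex %g %g %g\n endloop\nendfacet",
    nrm[, 1], nrm[, 2], nrm[, 3],
    v[i1, 1], v[i1, 2], v[i1, 3],
    v[i1 + 1, 1], v[i1 + 1, 2], v[i1 + 1, 3],
    v[i1 + 2, 1], v[i1 + 2, 2], v[i1 + 2, 3])
  writeLines(blocks, con)
  writeLines(sprintf("endsolid %s", name), con)
  invisible(path)
}

#' @rdname write_stl
#' @return `read_stl`: list with `vertices` and `normals` as in the input.
#' @export
read_stl <- function(path) {
  lines <- readLines(path)
  vl <- grep("^\\s*vertex", lines, value = TRUE)
  nl <- grep("^\\s*facet normal", lines, value = TRUE)
  parse3 <- function(x, skip) {
    m <- do.call(rbind, strsplit(trimws(x), "\\s+"))
    matrix(as.numeric(m[, skip + (1:3)]), ncol = 3)
  }
  list(vertices = parse3(vl, 1), normals = parse3(nl, 2))
}

#' Write and read legacy-VTK structured-points files
#'
#' ASCII `STRUCTURED_POINTS` datasets carrying one or more cell-centred
#' scalar fields; readable by ParaView and by [read_vtk_image()].
#'
#' @param fields named list of 3-d arrays sharing one dimension.
#' @param spacing grid spacing (mm).
#' @param origin lower box corner (mm).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vtk_image <- function(fields, spacing, origin, path) {
  d <- dim(fields[[1]])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "fontanflow field", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", d[1] + 1, d[2] + 1, d[3] + 1),
               sprintf("ORIGIN %g %g %g", origin[1], origin[2], origin[3]),
               sprintf("SPACING %g %g %g", spacing, spacing, spacing),
               sprintf("CELL_DATA %d", prod(d))), con)
  for (nm in names(fields)) {
    writeLines(c(sprintf("SCALARS %s double 1", nm),
                 "LOOKUP_TABLE default"), con)
    writeLines(paste(format(as.vector(fields[[nm]]), trim = TRUE,
                            digits = 10), collapse = " "), con)
  }
  invisible(path)
}

#' @rdname write_vtk_image
#' @return `read_vtk_image`: list with `fields`, `spacing`, `origin`, `dim`.
#' @export
read_vtk_image <- function(path) {
  lines <- readLines(path)
  dimln <- strsplit(grep("^DIMENSIONS", lines, value = TRUE), "\\s+")[[1]]
  d <- as.integer(dimln[2:4]) - 1L
  org <- as.numeric(strsplit(grep("^ORIGIN", lines, value = TRUE),
                             "\\s+")[[1]][2:4])
  sp <- as.numeric(strsplit(grep("^SPACING", lines, value = TRUE),
                            "\\s+")[[1]][2])
  sc <- grep("^SCALARS", lines)
  fields <- list()
  for (s in sc) {
    nm <- strsplit(lines[s], "\\s+")[[1]][2]
    vals <- as.numeric(strsplit(trimws(lines[s + 2]), "\\s+")[[1]])
    fields[[nm]] <- array(vals, dim = d)
  }
  list(fields = fields, spacing = sp, origin = org, dim = d)
}

#' Export a design's geometry artefacts
#'
#' Writes the stair-step lumen surface as ASCII STL, the voxel mask (lumen
#' and port labels) as legacy VTK, and the conduit-design parameters as JSON.
#'
#' @param tree a [build_design()] vessel tree.
#' @param mask the matching [voxelize()] mask.
#' @param dir output directory (created if missing).
#' @param stem file-name stem; defaults to the design label.
#' @return named character vector of the files written.
#' @export
export_geometry <- function(tree, mask, dir, stem = NULL) {
  if (!inherits(tree, "vessel_tree") || length(tree$segments) == 0)
    validation_error("cannot export an empty vessel tree")
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    validation_error(sprintf("cannot create output directory '%s'", dir))
  stem <- stem %||% gsub("[^A-Za-z0-9_.-]", "_", tree$design$label)
  stl <- file.path(dir, paste0(stem, ".stl"))
  vtk <- file.path(dir, paste0(stem, "_mask.vtk"))
  jsn <- file.path(dir, paste0(stem, "_design.json"))
  write_stl(mask_surface(mask), stl, name = stem)
  write_vtk_image(list(lumen = mask$lumen + 0, port = mask$port + 0),
                  mask$spacing, mask$origin, vtk)
  jsonlite::write_json(unclass(tree$design), jsn, auto_unbox = TRUE,
                       digits = NA, null = "null")
  c(stl = stl, vtk = vtk, design = jsn)
}
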