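test_that("build_design assembles all four reference trees from one layout", {
  lay <- anatomical_layout()
  refs <- reference_designs()
  for (nm in names(refs)) {
    tree <- build_design(refs[[nm]], lay)
    expect_s3_class(tree, "vessel_tree")
    expect_named(tree$ports, c("SVC", "IVC", "LPA", "RPA"))
    # hilum extensions: >= 50 mm of PA beyond the outermost anastomosis
    offs <- c(refs[[nm]]$left_anastomosis_offset,
              refs[[nm]]$right_anastomosis_offset, refs[[nm]]$svc_offset)
    expect_gte(lay$pa_half_length - max(abs(offs)), 50)
    expect_true(all(vapply(tree$segments, function(s) min(s$r0, s$r1), 0) > 0))
  }
  # group A: one conduit segment of radius 10 mm, offset anastomoses
  trA <- build_design(refs$A, lay)
  con <- Filter(function(s) s$name == "conduit", trA$segments)[[1]]
  expect_equal(con$r0, 10)
  expect_equal(con$p1[1], refs$A$left_anastomosis_offset)
  # group D: area ratio 2 rb^2 / rt^2 = 2*7^2/10^2 = 0.98
  expect_equal(2 * (refs$D$branch_diameter / 2)^2 /
                 (refs$D$trunk_diameter / 2)^2, 0.98)

  expect_error(build_design(refs$A, anatomical_layout(pa_half_length = 60)),
               class = "fontanflow_geometry_error")
})

test_that("port areas are the circular plane areas", {
  tree <- build_design(reference_designs()$D, anatomical_layout())
  expect_equal(port_area(tree, "IVC"), pi * 10^2, tolerance = 1e-12) # 314.16
  d14 <- pi * 7^2                                                    # 153.94
  expect_equal(round(d14, 2), 153.94)
  expect_equal(2 * d14 / port_area(tree, "IVC"), 0.98)
  expect_error(port_area(tree, "AORTA"),
               class = "fontanflow_validation_error")
})

test_that("voxelization reproduces analytic volumes and refines monotonically", {
  tube <- make_tube_tree(diameter = 20, length = 100)
  vol_exact <- pi * 10^2 * 100                    # 31,416 mm^3
  m <- voxelize(tube, 0.5)
  expect_lt(abs(voxel_volume(m) - vol_exact) / vol_exact, 0.02)
  # halving the spacing never grows, and overall shrinks, the volume error
  errs <- vapply(c(2, 1, 0.5, 0.25), function(h)
    abs(voxel_volume(voxelize(tube, h)) - vol_exact), 0)
  expect_true(all(diff(errs) <= 0))
  expect_lt(errs[4], 0.1 * errs[1])
})

test_that("voxelize validates its inputs and labels ports on the boundary", {
  tube <- make_tube_tree(diameter = 10, length = 30)
  expect_error(voxelize(tube, 2.5), class = "fontanflow_resolution_error")
  empty <- structure(list(design = conduit_design("e", "T", 20),
                          segments = list(), ports = list()),
                     class = "vessel_tree")
  expect_error(voxelize(empty, 1), class = "fontanflow_validation_error")

  m <- voxelize(tube, 1)
  for (nm in names(m$ports)) {
    cells <- m$ports[[nm]]$cells
    expect_gt(length(cells), 0)
    expect_true(all(m$lumen[cells]))          # port cells are lumen cells
    ax <- m$ports[[nm]]$axis
    e <- cells - 1L
    pos <- switch(ax, e %% m$dim[1],
                  (e %/% m$dim[1]) %% m$dim[2],
                  e %/% (m$dim[1] * m$dim[2]))
    slab <- if (m$ports[[nm]]$dir < 0) 0L else m$dim[ax] - 1L
    expect_true(all(pos == slab))             # ... on the domain boundary
  }
  # the lumen is one connected component
  comp <- fontanflow:::.flood_fill_cpp(as.integer(m$lumen), m$dim)
  expect_equal(attr(comp, "n_components"), 1L)
})
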