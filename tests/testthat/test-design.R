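test_that("conduit designs enforce their geometric invariants", {
  d <- conduit_design("D-14Y", "Y", trunk_diameter = 20, branch_diameter = 14)
  expect_s3_class(d, "conduit_design")
  expect_identical(d$topology, "Y")

  expect_error(conduit_design("bad", "T", trunk_diameter = -2),
               class = "fontanflow_validation_error")
  expect_error(conduit_design("bad", "Y", 20, branch_diameter = 0),
               class = "fontanflow_validation_error")
  expect_error(conduit_design("bad", "Y", 20, branch_diameter = 22),
               class = "fontanflow_validation_error")
  # branch anastomoses closer than one branch diameter overlap
  expect_error(conduit_design("bad", "Y", 20, 14,
                              left_anastomosis_offset = -5,
                              right_anastomosis_offset = 5),
               class = "fontanflow_geometry_error")
  # the SVC must join between the two branches
  expect_error(conduit_design("bad", "Y", 20, 14,
                              left_anastomosis_offset = -15,
                              right_anastomosis_offset = 15,
                              svc_offset = 20),
               class = "fontanflow_geometry_error")
})

test_that("area- and diameter-preservation predicates match the design family", {
  refs <- reference_designs()
  # 20-14-14: 2 * 7^2 / 10^2 = 0.98, inside the 5% area-preserving band
  expect_true(is_area_preserving(refs$D))
  expect_false(is_area_preserving(refs$B))
  expect_false(is_area_preserving(refs$C))
  # 20-10-10: branch diameters sum exactly to the trunk diameter
  expect_true(is_diameter_preserving(refs$B))
  expect_false(is_diameter_preserving(refs$D))
  expect_false(is_area_preserving(refs$A))   # T topology: neither applies
  expect_false(is_diameter_preserving(refs$A))
})

test_that("the reference family has the expected labels and diameters", {
  refs <- reference_designs()
  expect_named(refs, c("A", "B", "C", "D"))
  expect_equal(refs$A$topology, "T")
  expect_equal(refs$A$trunk_diameter, 20)
  expect_equal(vapply(refs[c("B", "C", "D")], `[[`, 0, "branch_diameter"),
               c(B = 10, C = 12, D = 14))
  expect_true(all(vapply(refs, `[[`, 0, "trunk_diameter") == 20))
})
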