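# Synthetic geometries: biventricle, sphere shell, cylinder, bifurcation.

test_that("default biventricle matches the analytic truncated ellipsoid", {
  mesh <- fixture("bv_default", function() make_biventricle(bv_spec()))
  expect_lt(abs(mesh$cavity_volumes[["LV"]] - mesh$lv_volume_analytic) /
              mesh$lv_volume_analytic, 0.02)
  expect_equal(mesh$cavity_volumes[["RV"]], bv_spec()$rv_volume_ml,
               tolerance = 1e-3)
  # every cell has exactly one region label
  expect_true(all(mesh$region %in% c("LVFW", "SEPTUM", "RVFW")))
  expect_equal(length(mesh$region), nrow(mesh$tets))
  expect_true(all(table(mesh$region) > 0))
  # all tets positively oriented, no degenerate cells
  v6 <- vacoupler:::.tet_vol6(mesh$nodes, mesh$tets)
  expect_true(all(v6 > 0))
})

test_that("refining the biventricle changes the cavity volume by < 1%", {
  mesh <- fixture("bv_default", function() make_biventricle(bv_spec()))
  fine <- fixture("bv_fine", function()
    make_biventricle(bv_spec(n_theta = 64, n_s = 32)))
  expect_lt(abs(fine$cavity_volumes[["LV"]] - mesh$cavity_volumes[["LV"]]) /
              mesh$cavity_volumes[["LV"]], 0.01)
})

test_that("rule-based fibers interpolate the helix angle transmurally", {
  expect_equal(helix_angle(0), 60)
  expect_equal(helix_angle(1), -60)
  expect_equal(helix_angle(0.5), 0)
  mesh <- coarse_bv_fixture()$mesh
  f <- mesh$fibers
  # orthonormal right-handed basis everywhere
  expect_lt(max(abs(rowSums(f$f * f$s))), 1e-10)
  expect_lt(max(abs(rowSums(f$f^2) - 1)), 1e-10)
  expect_lt(max(abs(rowSums(f$n^2) - 1)), 1e-10)
  # angles at cell depths follow the linear rule
  expect_equal(mesh$fiber_angles, helix_angle(mesh$depth), tolerance = 1e-10)
  # neighbouring layers differ smoothly: reassigning with equal angles
  # makes the field purely circumferential
  m2 <- assign_transmural_fibers(mesh, 0, 0)
  expect_lt(max(abs(rowSums(m2$fibers$f * m2$frame$e_l))), 1e-10)
})

test_that("mesh generation is deterministic", {
  a <- make_biventricle(bv_spec_coarse())
  b <- make_biventricle(bv_spec_coarse())
  expect_identical(a$nodes, b$nodes)
  expect_identical(a$tets, b$tets)
  c1 <- make_cylinder(10, 60)
  c2 <- make_cylinder(10, 60)
  expect_identical(c1$nodes, c2$nodes)
})

test_that("a refined sphere surface volume converges to the analytic ball", {
  mesh <- make_sphere_shell(20, 2, n_theta = 64, n_s = 32, n_xi = 1)
  expect_gte(nrow(mesh$cavities$LV), 2000)
  va <- 4 / 3 * pi * 20^3 / 1000
  expect_lt(abs(mesh$cavity_volumes[["LV"]] - va) / va, 0.005)
})

test_that("cavity volume scales with the cube of a radial dilation", {
  mesh <- make_sphere_shell(20, 4, n_theta = 24, n_s = 12, n_xi = 1)
  v1 <- cavity_volume(mesh, NULL, "LV")
  u <- mesh$nodes            # displacement that doubles every radius
  v2 <- cavity_volume(mesh, u, "LV")
  expect_equal(v2 / v1, 8, tolerance = 1e-10)
  expect_error(cavity_volume(mesh, NULL, "XX"), "unknown chamber")
})

test_that("cylinder reference volume and frames are exact", {
  cy <- make_cylinder(radius = 10, length = 60, n_theta = 32, n_z = 10)
  expect_lt(abs(cy$ref_volume - pi * 100 * 60 / 1000) / (pi * 6), 0.01)
  expect_lt(max(abs(rowSums(cy$frames$e_l * cy$frames$e_c))), 1e-8)
  expect_equal(length(cy$rings), 2)
})

test_that("bifurcation has three rings and orthonormal local frames", {
  bf <- fixture("bifurcation", function() make_bifurcation())
  expect_equal(length(bf$rings), 3)
  expect_lt(max(abs(rowSums(bf$frames$e_l * bf$frames$e_c))), 1e-8)
  expect_lt(max(abs(rowSums(bf$frames$e_c^2) - 1)), 1e-8)
  expect_gt(bf$ref_volume, 0)
  expect_true("junction" %in% bf$region)
  # watertight: every edge of the closed tube surface shared by 2 triangles
  ed <- rbind(bf$tris[, 1:2], bf$tris[, 2:3], bf$tris[, c(3, 1)])
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  cnt <- table(key)
  ring_edges <- sum(vapply(bf$rings, function(r) length(r$nodes), numeric(1)))
  expect_equal(sum(cnt == 1), ring_edges)   # boundary = the three rings
  expect_true(all(cnt <= 2))
})

test_that("slice diameters follow similarity and area equivalence", {
  cy <- make_cylinder(radius = 10, length = 60, n_theta = 40, n_z = 8)
  d0 <- diameter_at_slice(cy, NULL, "mid")
  expect_equal(d0, 20, tolerance = 0.01 * 20)
  u <- cbind(0.1 * cy$nodes[, 1], 0.1 * cy$nodes[, 2], 0)
  expect_equal(diameter_at_slice(cy, u, "mid") / d0, 1.1, tolerance = 1e-6)
  # elliptical section a = 13, b = 8 -> 2 sqrt(ab)
  u2 <- cbind(0.3 * cy$nodes[, 1], -0.2 * cy$nodes[, 2], 0)
  expect_equal(diameter_at_slice(cy, u2, "mid"), 2 * sqrt(13 * 8),
               tolerance = 0.01 * 2 * sqrt(13 * 8))
  expect_error(diameter_at_slice(cy, NULL, list(point = c(0, 0, 1000),
                                                normal = c(0, 0, 1))),
               "closed curve")
})

test_that("vessel spec dispatches to both generators", {
  cy <- make_vessel(vessel_spec("cylinder", radius = 8, length = 40,
                                n_theta = 12, n_z = 4))
  expect_s3_class(cy, "vessel_mesh")
  bf <- make_vessel(vessel_spec("bifurcation", n_theta = 12, n_z = 4))
  expect_equal(length(bf$rings), 3)
  expect_error(vessel_spec("cylinder", n_theta = 10), "n_theta")
})

test_that("meshes export to legacy VTK", {
  f <- tempfile(fileext = ".vtk")
  write_mesh_vtk(coarse_bv_fixture()$mesh, f)
  txt <- readLines(f, n = 5)
  expect_match(txt[1], "vtk DataFile")
  expect_true(file.size(f) > 1000)
  unlink(f)
})
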