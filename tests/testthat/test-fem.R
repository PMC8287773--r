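test_that("meshes are conforming, tagged and scale as expected", {
  g <- geometry_model()
  m1 <- build_mesh(g, 1.2)
  expect_s3_class(m1, "fem_mesh")
  expect_true(all(table(m1$tissue)[c("bone", "cartilage", "meniscus")] > 0))
  for (tag in c("support_nodes", "axis_nodes", "load_nodes",
                "slave_nodes", "master_nodes")) {
    expect_gt(length(m1$tags[[tag]]), 0)
  }
  # halving the element size roughly quadruples the element count in 2-D
  m2 <- build_mesh(g, 0.6)
  ratio <- nrow(m2$elems) / nrow(m1$elems)
  expect_gt(ratio, 3); expect_lt(ratio, 5)
  # boundary tags live on the boundary they claim
  expect_true(all(abs(m1$nodes[m1$tags$axis_nodes, 1]) < 1e-9))
  expect_true(all(abs(m1$nodes[m1$tags$support_nodes, 2] -
                        min(m1$nodes[, 2])) < 1e-9))
  # assembly validates every element Jacobian
  expect_silent(assemble_unit_stiffness(m1, nu_map(material_set(10), m1)))
})

test_that("uniaxial column matches the closed form to solver precision", {
  g <- column_geometry(area_mm2 = 100, height_mm = 4)
  m <- build_mesh(g, 1)
  for (nu in c(0, 0.3)) {
    res <- solve_contact(m, material_set(soft_E = 10, cartilage_nu = nu),
                         load_case(400, 5))
    expect_equal(res$delta_z_mm, 400 * 4 / (100 * 10), tolerance = 1e-6)
    expect_equal(res$reaction_n, 400, tolerance = 1e-9)
  }
})

test_that("without contact the response is exactly linear in F and 1/E", {
  m <- build_mesh(column_geometry(), 1)
  base <- solve_contact(m, material_set(soft_E = 10), load_case(100, 5))
  dbl_F <- solve_contact(m, material_set(soft_E = 10), load_case(200, 5))
  dbl_E <- solve_contact(m, material_set(soft_E = 20), load_case(100, 5))
  expect_equal(dbl_F$delta_z_mm, 2 * base$delta_z_mm, tolerance = 1e-12)
  expect_equal(dbl_E$delta_z_mm, base$delta_z_mm / 2, tolerance = 1e-12)
})

test_that("rigid-sphere indentation agrees with the Hertz closed form", {
  m <- build_mesh(halfspace_geometry(sphere_radius = 20, domain_mm = 200),
                  0.5)
  E <- 20
  res <- solve_contact(m, material_set(soft_E = E), load_case(400, 5))
  hz <- hertz_indentation(400, 20, E, 0.45)
  expect_lt(abs(res$delta_z_mm - hz) / hz, 0.05)
  expect_lt(abs(res$reaction_n - 400) / 400, 0.005)
  # frictionless, no adhesion: multipliers are non-negative and sum to
  # (approximately) the transmitted load
  expect_true(all(res$contact$lambda >= 0))
  expect_lt(abs(res$contact$total_force_n - 400) / 400, 0.02)
})

test_that("knee contact solve balances load and respects penetration limits", {
  m <- build_mesh(geometry_model(), 1.2)
  res <- solve_contact(m, material_set(soft_E = 10), load_case(400, 5))
  expect_lt(abs(res$reaction_n - 400) / 400, 0.005)
  expect_gt(res$delta_z_mm, 0)
  expect_true(all(res$contact$lambda >= 0))
  # large-deflection path runs and deforms more at low stiffness
  res2 <- solve_contact(m, material_set(soft_E = 2), load_case(400, 5, TRUE))
  expect_gt(res2$delta_z_mm, res$delta_z_mm)
  expect_lt(abs(res2$reaction_n - 400) / 400, 0.005)
})

test_that("adaptive refinement reports a signed deformation change", {
  # the column is represented exactly at any mesh size: zero change
  ans <- adaptive_solve(column_geometry(), material_set(soft_E = 10),
                        load_case(400, 5), base_size = 2)
  expect_lt(abs(ans$convergence_error_pct), 1e-9)
  expect_equal(nrow(ans$trace), 2L)
  # impossible tolerance exhausts the loop cap with an error trace
  expect_error(
    adaptive_solve(geometry_model(), material_set(soft_E = 10),
                   load_case(400, 5), max_error_pct = 1e-8,
                   max_loops = 1L, base_size = 2),
    "refinement")
})

test_that("a short stiffness sweep is monotone and near the flat-punch law", {
  # rigid bone isolates the soft-tissue scaling: flat geometry then
  # obeys delta ~ 1/E, i.e. b = -1, to high accuracy
  g <- geometry_model(condyle_radius = Inf, meniscus_inner_radius = NULL)
  m <- build_mesh(g, 1.2)
  grid <- c(5, 10, 20, 50)
  dz <- vapply(grid, function(E) {
    solve_contact(m, material_set(soft_E = E, bone_E = 1e7),
                  load_case(400, 5))$delta_z_mm
  }, numeric(1))
  expect_true(all(diff(dz) < 0))
  fit <- fit_power_law(data.frame(stiffness_mpa = grid, strain = dz / 6))
  expect_equal(fit$b, -1, tolerance = 0.01)
})

test_that("sweep tables round-trip through CSV", {
  tab <- data.frame(stiffness_mpa = c(1, 5, 50),
                    deformation_mm = c(2, 1, 0.3),
                    strain = c(0.33, 0.17, 0.05),
                    convergence_error_pct = c(-0.5, 0.1, NA))
  path <- tempfile(fileext = ".csv")
  write_sweep_table(tab, path)
  back <- read_sweep_table(path)
  expect_equal(back$stiffness_mpa, tab$stiffness_mpa)
  expect_equal(back$strain, tab$strain)
  expect_error(read_sweep_table({
    p2 <- tempfile(fileext = ".csv")
    utils::write.csv(data.frame(x = 1), p2, row.names = FALSE)
    p2
  }), "must have columns")
})
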