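test_that("shape parameter validation names the offending field", {
  expect_error(aaa_shape_params(proximal_radius = -1), "proximal_radius")
  expect_error(aaa_shape_params(n_circumferential = 6), "n_circumferential")
  expect_error(aaa_shape_params(n_axial = 10), "n_axial")
  expect_error(aaa_shape_params(ilt_free_sector = c(1, 1)), "ilt_free_sector")
  expect_error(aaa_shape_params(max_radius = 5), "max_radius")
  expect_error(aaa_shape_params(ilt_max_thickness = 50), "ilt_max_thickness")
})

test_that("no thrombus means vertex-identical lumen and inner wall", {
  p <- aaa_shape_params(ilt_max_thickness = 0)
  s <- generate_aaa_surfaces(p)
  expect_identical(s$lumen$vertices, s$inner_wall$vertices)
  expect_identical(s$lumen$triangles, s$inner_wall$triangles)
})

test_that("radius profile decays to the proximal radius in the Gaussian tail", {
  p <- aaa_shape_params(tube_length = 200, bulge_center = 100,
                        bulge_width = 20)
  z_far <- c(0, 10, 190, 200)  # |z - z0| >= 4w
  expect_true(all(abs(aaa_radius_profile(z_far, p) - p$proximal_radius)
                  < 1e-4))
})

test_that("surfaces coincide exactly over the ILT-free sector", {
  s <- default_surfaces()
  p <- default_params()
  nc <- p$n_circumferential
  theta <- 2 * pi * (seq_len(nc) - 1) / nc
  theta_w <- atan2(sin(theta), cos(theta))
  free <- theta_w >= p$ilt_free_sector[1] & theta_w <= p$ilt_free_sector[2]
  idx <- as.vector(outer((seq_len(p$n_axial + 1) - 1) * nc, which(free), "+"))
  d <- sqrt(rowSums((s$lumen$vertices[idx, ] - s$inner_wall$vertices[idx, ])^2))
  expect_lt(max(d), 1e-9)
})

test_that("maximum lumen-to-wall distance matches the peak ILT thickness", {
  s <- default_surfaces()
  p <- default_params()
  d <- cpp_dist_to_surface(s$lumen$vertices, s$inner_wall$vertices,
                           s$inner_wall$triangles)$dist
  # brute-force point-to-surface distance against the analytic tau field
  expect_equal(max(d), p$ilt_max_thickness, tolerance = 0.05)
})

test_that("centerline passes through wall cross-section centroids", {
  s <- default_surfaces()
  p <- default_params()
  nc <- p$n_circumferential
  for (i in c(1, 10, 20)) {
    ring <- s$inner_wall$vertices[(i - 1) * nc + seq_len(nc), ]
    expect_equal(colMeans(ring), unname(s$centerline[i, ]), tolerance = 1e-8)
  }
})

test_that("regeneration with the same parameters is bit-identical", {
  a <- generate_aaa_surfaces(default_params())
  b <- generate_aaa_surfaces(default_params())
  expect_identical(a$lumen$vertices, b$lumen$vertices)
  expect_identical(a$inner_wall$vertices, b$inner_wall$vertices)
})

test_that("surfaces are outward-wound without self-intersections", {
  s <- default_surfaces()
  g <- aaamech:::triangle_geometry(s$inner_wall)
  p <- default_params()
  radial <- g$centroid - aaa_centerline_point(g$centroid[, 3], p)
  radial[, 3] <- 0
  expect_true(all(rowSums(g$normal * radial) > 0))
  expect_identical(surface_diagnostics(s$inner_wall)$self_intersections, 0L)
  expect_identical(surface_diagnostics(s$lumen)$self_intersections, 0L)
})

test_that("cylinder fixture encloses the closed-form annular volume", {
  fix <- generate_cylinder_fixture(5, 6, 40, resolution = c(64L, 40L))
  bodies <- assemble_closed_bodies(NULL, NULL, fix$inner, fix$outer)
  v <- surface_diagnostics(bodies$wall_body,
                           check_self_intersections = FALSE)$enclosed_volume_mm3
  expect_equal(v, pi * (36 - 25) * 40, tolerance = 0.01)
  expect_equal(fix$centerline[1, ], c(0, 0, 0))
  expect_equal(fix$centerline[nrow(fix$centerline), ], c(0, 0, 40))
})

test_that("cylinder fixture rejects out-of-order radii", {
  expect_error(generate_cylinder_fixture(6, 6, 40), "inner_radius")
  expect_error(generate_cylinder_fixture(7, 6, 40), "inner_radius")
})

test_that("patch fixture is the 6-tet Kuhn cube", {
  m <- generate_patch_fixture()
  expect_identical(nrow(m$tets), 6L)
  expect_identical(nrow(m$nodes), 8L)
  expect_equal(sum(tet_volumes(m)), 1, tolerance = 1e-12)
  expect_true(all(tet_volumes(m) > 0))
  expect_identical(mesh_quality(m)$inverted_count, 0L)
  for (fs in m$face_sets) expect_identical(nrow(fs), 2L)
})
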