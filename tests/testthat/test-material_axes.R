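test_that("centerline resampling is uniform with exact endpoints", {
  seg <- cbind(0, 0, seq(0, 90, length.out = 7))
  cl <- resample_centerline(seg, 90)
  expect_identical(nrow(cl$points), 90L)
  expect_equal(diff(cl$arclength), rep(90 / 89, 89))
  expect_equal(cl$points[1, ], c(0, 0, 0))
  expect_equal(cl$points[90, ], c(0, 0, 90))
  expect_error(resample_centerline(seg, 1), "n")
  expect_error(resample_centerline(seg[1, , drop = FALSE]), "2 points")
})

test_that("semicircle midpoint is recovered by arclength resampling", {
  r <- 10
  th <- seq(0, pi, length.out = 721)
  arc <- cbind(r * cos(th), r * sin(th), 0)
  cl <- resample_centerline(arc, 3)
  expect_equal(cl$points[2, ], c(0, r, 0), tolerance = 1e-5 * r)
})

test_that("straight cylinder recovers exact cylindrical axes", {
  fix <- generate_cylinder_fixture(5, 6, 40, resolution = c(32L, 20L))
  bodies <- assemble_closed_bodies(NULL, NULL, fix$inner, fix$outer)
  mesh <- tetrahedralize(NULL, bodies$wall_body)
  fr <- assign_local_frames(mesh, resample_centerline(fix$centerline, 30))
  cen <- aaamech:::tet_centroids(mesh)
  rad <- cbind(cen[, 1], cen[, 2], 0)
  rad <- rad / sqrt(rowSums(rad^2))
  tang <- cbind(-rad[, 2], rad[, 1], 0)
  # e2 axial and e1/e3 in the cross-section plane exactly; e1/e3 agree with
  # the smooth tangent/radial directions up to the facet angle
  expect_lt(max(abs(fr$e3[, 3])), 1e-6)
  expect_lt(max(abs(abs(fr$e2[, 3]) - 1)), 1e-6)
  expect_lt(max(abs(fr$e1[, 3])), 1e-6)
  expect_gt(min(abs(rowSums(fr$e3 * rad))), cos(2 * pi / 32))
  expect_gt(min(abs(rowSums(fr$e1 * tang))), cos(2 * pi / 32))
})

test_that("frames are orthonormal and right-handed to 1e-10", {
  fr <- default_frames()
  expect_lt(max(abs(rowSums(fr$e1^2) - 1)), 1e-12)
  expect_lt(max(abs(rowSums(fr$e2^2) - 1)), 1e-12)
  expect_lt(max(abs(rowSums(fr$e3^2) - 1)), 1e-12)
  expect_lt(max(abs(rowSums(fr$e1 * fr$e2))), 1e-10)
  expect_lt(max(abs(rowSums(fr$e1 * fr$e3))), 1e-10)
  expect_lt(max(abs(rowSums(fr$e2 * fr$e3))), 1e-10)
  cr <- aaamech:::cross_rows(fr$e1, fr$e2)
  expect_lt(max(abs(cr - fr$e3)), 1e-10)
})

test_that("axial frames align with the bowed centerline tangents", {
  # a gently bulged, strongly bowed tube: e2 (the in-surface axial axis)
  # must follow the curved centerline direction; on the default AAA the
  # bulge meridian tilts up to ~50 degrees from the axis, so the mild
  # geometry isolates the bowing behavior
  p <- aaa_shape_params(max_radius = 13, anterior_offset = 10,
                        ilt_max_thickness = 4)
  surf <- generate_aaa_surfaces(p)
  lab <- detect_ilt_free_region(surf$lumen, surf$inner_wall)
  fr <- fragment_surfaces(surf$lumen, surf$inner_wall, lab)
  outer <- offset_surface(surf$inner_wall, 1)
  bodies <- assemble_closed_bodies(fr$luminal_ilt, fr$wall_ilt_covered,
                                   fr$wall_ilt_free, outer)
  mesh <- tetrahedralize(bodies$ilt_body, bodies$wall_body)
  frames <- assign_local_frames(mesh,
                                resample_centerline(surf$centerline))
  cen <- aaamech:::tet_centroids(mesh)
  h <- 1e-5
  tang <- aaa_centerline_point(cen[, 3] + h, p) -
    aaa_centerline_point(cen[, 3] - h, p)
  tang <- tang / sqrt(rowSums(tang^2))
  ext <- frames$external
  expect_gt(mean(abs(rowSums(frames$e2[ext, ] * tang[ext, ]))), 0.95)
})

test_that("frame field is equivariant under rigid rotation", {
  set.seed(11)
  Q <- random_rotation()
  fix <- generate_cylinder_fixture(5, 6, 20, resolution = c(24L, 12L))
  bodies <- assemble_closed_bodies(NULL, NULL, fix$inner, fix$outer)
  mesh <- tetrahedralize(NULL, bodies$wall_body)
  fr <- assign_local_frames(mesh, resample_centerline(fix$centerline, 20))
  mesh_rot <- mesh
  mesh_rot$nodes <- mesh$nodes %*% t(Q)
  cl_rot <- fix$centerline %*% t(Q)
  fr_rot <- assign_local_frames(mesh_rot, resample_centerline(cl_rot, 20))
  expect_equal(fr_rot$e1, fr$e1 %*% t(Q), tolerance = 1e-9)
  expect_equal(fr_rot$e2, fr$e2 %*% t(Q), tolerance = 1e-9)
  expect_equal(fr_rot$e3, fr$e3 %*% t(Q), tolerance = 1e-9)
})

test_that("fiber directions are symmetric about the circumferential axis", {
  fr <- default_frames()
  fb0 <- fiber_directions(fr, 0)
  expect_equal(fb0$M4, fr$e1)
  expect_equal(fb0$M6, fr$e1)
  fb90 <- fiber_directions(fr, 90)
  expect_equal(fb90$M4, fr$e2)
  expect_equal(fb90$M6, -fr$e2)
  fb <- fiber_directions(fr, 5.6)
  expect_equal(rowSums(fb$M4 * fr$e1), rep(cos(5.6 * pi / 180), nrow(fb$M4)))
  expect_equal(max(abs(rowSums(fb$M4 * fr$e3))), 0, tolerance = 1e-10)
  # M4 + M6 parallel to e1, M4 - M6 parallel to e2 for any alpha
  fb2 <- fiber_directions(fr, 37)
  sum_dir <- fb2$M4 + fb2$M6
  dif_dir <- fb2$M4 - fb2$M6
  expect_lt(max(abs(aaamech:::cross_rows(sum_dir, fr$e1))), 1e-10)
  expect_lt(max(abs(aaamech:::cross_rows(dif_dir, fr$e2))), 1e-10)
})
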