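test_that("matched octagon rings stitch into a 16-triangle annulus", {
  th <- 2 * pi * (0:7) / 8
  a <- cbind(cos(th), sin(th), 0)
  b <- cbind(2 * cos(th), 2 * sin(th), 1)
  band <- stitch_loops(a, b)
  expect_identical(nrow(band$new_triangles), 16L)
  surf <- band_surface(band, a, b)
  d <- surface_diagnostics(surf, check_self_intersections = FALSE)
  expect_identical(d$euler_characteristic, 0L)  # topological annulus
  # every loop vertex used
  expect_identical(sort(unique(as.vector(band$new_triangles))), 1:16)
  # no degenerate triangles
  g <- aaamech:::triangle_geometry(surf)
  expect_true(all(g$area > 1e-12))
})

test_that("identical loops cannot be stitched", {
  th <- 2 * pi * (0:7) / 8
  a <- cbind(cos(th), sin(th), 0)
  expect_error(stitch_loops(a, a), "coincide|intersect")
})

test_that("open chains stitch with pinned endpoints", {
  a <- cbind(seq(0, 10, length.out = 11), 0, 0)
  b <- cbind(seq(0, 10, length.out = 9), 1, 0)
  band <- stitch_loops(a, b, closed = FALSE)
  expect_identical(nrow(band$new_triangles), 11L + 9L - 2L)
  surf <- band_surface(band, a, b)
  expect_identical(surface_diagnostics(surf, FALSE)$euler_characteristic, 1L)
})

test_that("assembled bodies are watertight with the expected topology", {
  b <- default_bodies()
  dw <- surface_diagnostics(b$wall_body, check_self_intersections = FALSE)
  di <- surface_diagnostics(b$ilt_body, check_self_intersections = FALSE)
  expect_identical(dw$boundary_edge_count, 0L)
  expect_identical(di$boundary_edge_count, 0L)
  # thrombus body is a topological sphere; the wall of an unbranched tube is
  # a genus-1 shell (hollow cylinder), whose closed surface has chi = 0
  expect_identical(di$euler_characteristic, 2L)
  expect_identical(dw$euler_characteristic, 0L)
  expect_gt(di$enclosed_volume_mm3, 0)
  expect_gt(dw$enclosed_volume_mm3, 0)
})

test_that("interface facets equal the covered wall fragment verbatim", {
  b <- default_bodies()
  fr <- default_fragments()$frag
  expect_identical(b$interface_facets, fr$wall_ilt_covered$triangles)
  # and they appear in both bodies with identical vertex indices
  ik <- aaamech:::face_key(b$interface_facets)
  expect_true(all(ik %in% aaamech:::face_key(b$wall_body$triangles)))
  expect_true(all(ik %in% aaamech:::face_key(b$ilt_body$triangles)))
})

test_that("wall body volume matches the thin-shell estimate", {
  b <- default_bodies()
  s <- default_surfaces()
  area <- sum(aaamech:::triangle_geometry(s$inner_wall)$area)
  vol <- surface_diagnostics(b$wall_body, FALSE)$enclosed_volume_mm3
  expect_equal(vol, area * 1, tolerance = 0.05)
})
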