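test_that("tet volumes conserve the enclosed body volumes", {
  b <- default_bodies()
  mesh <- default_mesh()
  vt <- tet_volumes(mesh)
  vw <- surface_diagnostics(b$wall_body, FALSE)$enclosed_volume_mm3
  vi <- surface_diagnostics(b$ilt_body, FALSE)$enclosed_volume_mm3
  expect_equal(sum(vt[mesh$body == "WALL"]), vw, tolerance = 0.005)
  expect_equal(sum(vt[mesh$body == "ILT"]), vi, tolerance = 0.005)
  expect_identical(mesh_quality(mesh)$inverted_count, 0L)
})

test_that("interface faces are shared verbatim by a WALL and an ILT tet", {
  mesh <- default_mesh()
  tt <- mesh$tets
  allf <- rbind(tt[, c(1,3,2)], tt[, c(1,2,4)], tt[, c(1,4,3)], tt[, c(2,3,4)])
  owner <- rep(seq_len(nrow(tt)), 4)
  fk <- aaamech:::face_key(allf)
  ik <- aaamech:::face_key(mesh$face_sets$INTERFACE)
  for (k in sample(length(ik), 25)) {
    own <- owner[fk == ik[k]]
    expect_identical(sort(unique(mesh$body[own])), c("ILT", "WALL"))
  }
  # node sets intersect exactly on interface nodes
  wn <- unique(as.vector(tt[mesh$body == "WALL", ]))
  ino <- unique(as.vector(tt[mesh$body == "ILT", ]))
  shared <- intersect(wn, ino)
  iface_nodes <- unique(as.vector(mesh$face_sets$INTERFACE))
  expect_setequal(shared, iface_nodes)
})

test_that("unit-cube body meshes to exactly unit volume", {
  m <- generate_patch_fixture()
  expect_equal(sum(tet_volumes(m)), 1, tolerance = 1e-9)
})

test_that("smaller target element volumes give monotone element counts", {
  fix <- generate_cylinder_fixture(5, 6, 20, resolution = c(24L, 12L))
  bodies <- assemble_closed_bodies(NULL, NULL, fix$inner, fix$outer)
  counts <- vapply(c(2, 0.05, 0.013), function(mv) {
    nrow(tetrahedralize(NULL, bodies$wall_body,
                        max_element_volume = mv)$tets)
  }, numeric(1))
  expect_true(all(diff(counts) > 0))
})

test_that("thick-wall cylinder mesh volume matches the closed form", {
  fix <- generate_cylinder_fixture(5, 6, 40, resolution = c(64L, 40L))
  bodies <- assemble_closed_bodies(NULL, NULL, fix$inner, fix$outer)
  mesh <- tetrahedralize(NULL, bodies$wall_body, nr_wall = 2L)
  expect_equal(sum(tet_volumes(mesh)), pi * (36 - 25) * 40, tolerance = 0.01)
})

test_that("mesh quality flags degenerate elements", {
  reg <- tet_mesh(rbind(c(1,1,1), c(1,-1,-1), c(-1,-1,1), c(-1,1,-1)),
                  matrix(c(1,2,3,4), 1), body = "WALL")
  q <- mesh_quality(reg)
  expect_equal(q$min_dihedral_deg, acos(1/3) * 180 / pi, tolerance = 1e-9)
  sliver <- list(nodes = rbind(c(0,0,0), c(1,0,0), c(0,1,0),
                               c(0.5, 0.5, 1e-3)),
                 tets = matrix(c(1,2,3,4), 1))
  qs <- mesh_quality(sliver)
  expect_lt(qs$min_dihedral_deg, 5)
  # meshing arbitrary unstructured bodies is out of scope
  blob <- tri_surface(rbind(c(0,0,0), c(1,0,0), c(0,1,0), c(0,0,1)),
                      rbind(c(1,3,2), c(1,2,4), c(1,4,3), c(2,3,4)))
  expect_error(tetrahedralize(NULL, blob), "lattice")
})
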