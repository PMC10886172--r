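test_that("pressure loads self-equilibrate on a closed cavity", {
  m <- generate_patch_fixture()
  all_faces <- do.call(rbind, m$face_sets)
  f <- apply_pressure(m, all_faces, 1)
  expect_lt(max(abs(colSums(f))), 1e-10)
  expect_equal(apply_pressure(m, all_faces, 0), matrix(0, 8, 3))
  # single square face of 1 mm^2 under 0.016 MPa carries 0.016 N
  f1 <- apply_pressure(m, m$face_sets$ZMAX, 0.016)
  expect_equal(sum(abs(f1[, 3])), 0.016, tolerance = 1e-12)
  expect_equal(sum(abs(f1[, 1:2])), 0)
  expect_error(apply_pressure(m, matrix(c(1L, 2L, 7L), 1), 1),
               "non-boundary")
})

test_that("tied contact force is linear in the gap", {
  g <- c(0.1, -0.2, 0.05)
  expect_equal(tied_contact_force(c(0, 0, 0), 5), c(0, 0, 0))
  expect_equal(tied_contact_force(g, 10), 2 * tied_contact_force(g, 5))
})

test_that("zero pressure step returns the initial state in one iteration", {
  m <- generate_patch_fixture()
  bc <- patch_roller_bc(m)
  st <- solve_increment(m, list(WALL = material_linear_elastic(1, 0.3)),
                        bc = bc, pressure_step = 0)
  expect_true(st$converged)
  expect_identical(st$iterations, 1L)
  expect_equal(max(abs(st$displacements)), 0)
})

test_that("single-element patch test is exact for SVK", {
  m <- generate_patch_fixture()
  bc <- patch_roller_bc(m, pressure_faces = "ZMAX")
  p <- 0.02
  st <- solve_increment(m, list(WALL = material_linear_elastic(1, 0.3)),
                        bc = bc, pressure_step = p / MMHG_TO_MPA,
                        control = solver_control(rel_tol = 1e-12,
                                                 abs_tol = 1e-14))
  expect_true(st$converged)
  # homogeneous uniaxial Cauchy stress equal to the follower traction
  for (e in 1:6) {
    sig <- matrix(st$cauchy_stress[e, ], 3, 3)
    expect_equal(sig[3, 3], -p, tolerance = 1e-9)
    expect_lt(max(abs(sig[upper.tri(sig)])), 1e-9)
    expect_lt(max(abs(diag(sig)[1:2])), 1e-9)
  }
  # all elements share one homogeneous deformation
  expect_lt(max(apply(st$green_strain, 2, function(x) diff(range(x)))), 1e-9)
})

test_that("Newton converges quadratically on a thick-wall cylinder step", {
  fix <- generate_cylinder_fixture(5, 6, 20, resolution = c(24L, 10L))
  bodies <- assemble_closed_bodies(NULL, NULL, fix$inner, fix$outer)
  mesh <- tetrahedralize(NULL, bodies$wall_body)
  bc <- boundary_conditions(mesh)
  materials <- list(WALL = material_linear_elastic(1, 0.3))
  model <- fe_model(mesh, materials, bc = bc)
  ctrl <- solver_control()
  u <- numeric(3 * nrow(mesh$nodes))
  p <- 5e-4
  hist <- numeric(0)
  for (it in 1:8) {
    asm <- aaamech:::model_assemble(model, u, p, TRUE, TRUE)
    rn <- max(abs(asm$resid))
    hist <- c(hist, rn)
    if (rn < 1e-11) break
    du <- aaamech:::solve_linear(model, asm$x, -asm$resid)
    u[model$free_pos] <- u[model$free_pos] + du
  }
  n <- length(hist)
  expect_gt(n, 2)
  expect_lt(hist[n] / hist[n - 1], 0.1)
  expect_lt(hist[n - 1] / hist[n - 2], 0.1)
})

test_that("degenerate pressure program reproduces the initial state", {
  m <- generate_patch_fixture()
  bc <- patch_roller_bc(m)
  sol <- run_quasistatic(m, list(WALL = material_linear_elastic(1, 0.3)),
                         bc = bc, program = pressure_program(0, 0, 3),
                         record = "all")
  for (st in sol$states) {
    expect_true(st$converged)
    expect_equal(max(abs(st$displacements)), 0)
  }
})

test_that("solution is objective under rigid rotation of the problem", {
  m <- generate_patch_fixture()
  bc <- patch_roller_bc(m, pressure_faces = "ZMAX")
  p <- 100
  st <- solve_increment(m, list(WALL = material_linear_elastic(1, 0.3)),
                        bc = bc, pressure_step = p)
  set.seed(21)
  Q <- random_rotation()
  m2 <- m
  m2$nodes <- m$nodes %*% t(Q)
  # rotate the roller constraints: constrain rotated normal directions is
  # not expressible with axis rollers, so fix the three anchor nodes the
  # equivalent way: compare stress invariants from fully fixed base instead
  bcf <- boundary_conditions(m, fixed_sets = "ZMIN", pressure_faces = "ZMAX")
  stf <- solve_increment(m, list(WALL = material_linear_elastic(1, 0.3)),
                         bc = bcf, pressure_step = p)
  bcf2 <- boundary_conditions(m2, fixed_sets = "ZMIN", pressure_faces = "ZMAX")
  stf2 <- solve_increment(m2, list(WALL = material_linear_elastic(1, 0.3)),
                          bc = bcf2, pressure_step = p)
  s1 <- aaamech:::field_sigma1(stf$cauchy_stress)
  s2 <- aaamech:::field_sigma1(stf2$cauchy_stress)
  expect_equal(s1, s2, tolerance = 1e-8)
})

test_that("penalty tie converges to the merged solution with growing scale", {
  p <- aaa_shape_params(n_circumferential = 16, n_axial = 20,
                        tube_length = 60, bulge_center = 30, bulge_width = 12,
                        anterior_offset = 0, max_radius = 18,
                        ilt_max_thickness = 6)
  surf <- generate_aaa_surfaces(p)
  lab <- detect_ilt_free_region(surf$lumen, surf$inner_wall)
  frag <- fragment_surfaces(surf$lumen, surf$inner_wall, lab)
  outer <- offset_surface(surf$inner_wall, 1)
  bodies <- assemble_closed_bodies(frag$luminal_ilt, frag$wall_ilt_covered,
                                   frag$wall_ilt_free, outer)
  mats <- list(WALL = material_mooney_rivlin(), ILT = material_preset("ilt_linear"))
  run1 <- function(mesh, contact) {
    bc <- boundary_conditions(mesh)
    st <- solve_increment(mesh, mats, bc = bc, contact = contact,
                          pressure_step = 20)
    st
  }
  mesh_m <- tetrahedralize(bodies$ilt_body, bodies$wall_body, nr_ilt = 1L)
  st_m <- run1(mesh_m, tied_contact("merged"))
  mesh_p <- tetrahedralize(bodies$ilt_body, bodies$wall_body, nr_ilt = 1L,
                           interface_mode = "penalty")
  st_lo <- run1(mesh_p, tied_contact("penalty", penalty_scale = 1e1))
  st_hi <- run1(mesh_p, tied_contact("penalty", penalty_scale = 1e4))
  expect_true(st_m$converged && st_lo$converged && st_hi$converged)
  umax_m <- max(abs(st_m$displacements))
  # gap shrinks with the penalty scale
  gap <- function(st, mesh) {
    pr <- mesh$contact_pairs
    max(abs(st$displacements[pr[, 1], ] - st$displacements[pr[, 2], ]))
  }
  expect_lt(gap(st_hi, mesh_p), gap(st_lo, mesh_p))
  # high-penalty solution close to the merged one
  nw <- nrow(mesh_m$nodes)
  diff_hi <- max(abs(st_hi$displacements[seq_len(nw), ] - st_m$displacements))
  expect_lt(diff_hi, 0.01 * umax_m)
})
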