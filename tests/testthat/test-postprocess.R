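test_that("principal stresses are sorted eigenvalues", {
  expect_equal(principal_stresses(2 * diag(3)), c(2, 2, 2))
  expect_equal(principal_stresses(diag(c(3, 1, 2))), c(3, 2, 1))
  set.seed(8)
  for (k in 1:20) {
    A <- matrix(rnorm(9), 3, 3)
    S <- A + t(A)
    ps <- principal_stresses(S)
    # oracle: roots of the characteristic polynomial
    ch <- sort(Re(polyroot(c(-det(S),
                             (sum(diag(S))^2 - sum(S * S)) / 2,
                             -sum(diag(S)), 1))), decreasing = TRUE)
    expect_equal(ps, ch, tolerance = 1e-10)
  }
  expect_error(principal_stresses(matrix(c(1, 2, 0, 0, 1, 0, 0, 0, 1), 3)),
               "symmetric")
})

test_that("equivalent strain follows the deviatoric convention", {
  expect_equal(equivalent_strain(0.3 * diag(3)), 0)
  expect_equal(equivalent_strain(matrix(0, 3, 3)), 0)
  e <- 0.04
  expect_equal(equivalent_strain(diag(c(e, -e / 2, -e / 2))), e)
})

test_that("wall strength limit reproduces the worked value", {
  expect_equal(round(uts_wall(0.0593, 0.0895), 3), 0.079)
  expect_equal(uts_wall(0.05, 0.05), 0.05)
  expect_equal(uts_wall(1, 0), 1)
  # symmetry and degree-1 homogeneity
  expect_equal(uts_wall(0.3, 0.7), uts_wall(0.7, 0.3))
  expect_equal(uts_wall(3 * 0.0593, 3 * 0.0895),
               3 * uts_wall(0.0593, 0.0895))
  lim <- strength_limits()
  expect_equal(lim$mpa[lim$quantity == "sigma_uts_ilt"], 0.085)
})

test_that("wall regions partition the element set", {
  mesh <- default_mesh()
  labs <- classify_wall_regions(mesh)
  expect_false(anyNA(labs))
  expect_identical(length(labs), nrow(mesh$tets))
  expect_true(all(labs[mesh$body == "ILT"] == "ILT"))
  expect_true(all(labs[mesh$body == "WALL"] %in%
                    c("WALL_ILT_FREE", "WALL_ILT_COVERED")))
  # covered fraction close to the analytic sector area fraction: the ILT
  # spans everything outside the free sector and its tapers where thickness
  # clears the contact tolerance
  p <- default_params()
  frac <- mean(labs[mesh$body == "WALL"] == "WALL_ILT_COVERED")
  # analytic bound: free sector pi/2 of 2*pi plus tapers
  expect_gt(frac, 0.5)
  expect_lt(frac, 0.85)
  # no-ILT geometry: all wall free
  p0 <- aaa_shape_params(ilt_max_thickness = 0)
  s0 <- generate_aaa_surfaces(p0)
  lab0 <- detect_ilt_free_region(s0$lumen, s0$inner_wall)
  fr0 <- fragment_surfaces(s0$lumen, s0$inner_wall, lab0)
  b0 <- assemble_closed_bodies(fr0$luminal_ilt, fr0$wall_ilt_covered,
                               fr0$wall_ilt_free,
                               offset_surface(s0$inner_wall, 1))
  m0 <- tetrahedralize(NULL, b0$wall_body)
  expect_true(all(classify_wall_regions(m0) == "WALL_ILT_FREE"))
})

test_that("regional summaries are volume-weighted with max >= avg", {
  mesh <- default_mesh()
  labs <- classify_wall_regions(mesh)
  ne <- nrow(mesh$tets)
  # synthetic uniform field: avg equals max in every region
  st <- structure(list(cauchy_stress = matrix(rep(c(0.05, 0, 0, 0, 0.02, 0,
                                                    0, 0, 0.01), each = ne),
                                              ne, 9),
                       green_strain = matrix(rep(diag(3) * 0.01, each = ne),
                                             ne, 9),
                       vol0 = tet_volumes(mesh)),
                  class = "solution_state")
  rs <- regional_summary(st, labs)
  expect_equal(rs$avg_sigma1, rs$max_sigma1, tolerance = 1e-12)
  # hand-computed 3-element check
  st3 <- structure(list(
    cauchy_stress = rbind(c(1, 0, 0, 0, 0, 0, 0, 0, 0),
                          c(2, 0, 0, 0, 0, 0, 0, 0, 0),
                          c(3, 0, 0, 0, 0, 0, 0, 0, 0)),
    green_strain = matrix(0, 3, 9), vol0 = c(1, 2, 1)),
    class = "solution_state")
  rs3 <- regional_summary(st3, rep("ILT", 3))
  row <- rs3[rs3$region == "ILT", ]
  expect_equal(row$avg_sigma1, (1 * 1 + 2 * 2 + 3 * 1) / 4)
  expect_equal(row$max_sigma1, 3)
  # doubling the field doubles the summaries
  st3b <- st3
  st3b$cauchy_stress <- 2 * st3$cauchy_stress
  rs3b <- regional_summary(st3b, rep("ILT", 3))
  expect_equal(rs3b$avg_sigma1[rs3b$region == "ILT"], 2 * row$avg_sigma1)
  # empty regions report NA statistics, not an error
  expect_true(is.na(rs3$avg_sigma1[rs3$region == "WALL_ILT_FREE"]))
})

test_that("volume metrics reproduce the printed arithmetic", {
  pre <- volume_metrics(412, 96)
  post <- volume_metrics(639, 183, previous = pre)
  expect_equal(round(pre$ilt_percent, 1), 23.3)
  expect_equal(round(post$ilt_percent, 1), 28.6)
  expect_equal(round(post$aaa_growth_percent), 55)
  expect_equal(round(post$ilt_growth_percent), 91)
  expect_equal(volume_metrics(100, 0)$ilt_percent, 0)
  expect_error(volume_metrics(100, 120), "exceeds")
  # open surfaces are a topology error
  s <- default_surfaces()
  expect_error(volume_metrics(s$inner_wall, NULL), "watertight")
  # capped tube + thrombus body from the synthetic geometry
  b <- default_bodies()
  vm <- volume_metrics(cap_ends(s$inner_wall), b$ilt_body)
  expect_gt(vm$ilt_percent, 0)
  expect_lt(vm$ilt_percent, 100)
  # invariance of the ratio under rigid motion
  rot <- b$ilt_body
  set.seed(2)
  Q <- random_rotation()
  rot$vertices <- b$ilt_body$vertices %*% t(Q)
  capped <- cap_ends(s$inner_wall)
  capped$vertices <- capped$vertices %*% t(Q)
  vm2 <- volume_metrics(capped, rot)
  expect_equal(vm2$ilt_percent, vm$ilt_percent, tolerance = 1e-9)
})

test_that("mesh sensitivity deviations follow the |v - ref| / ref rule", {
  rep3 <- mesh_sensitivity_report(c(0.0808, 0.0826, 0.0837))
  expect_equal(rep3$deviation_percent[1], 2.18, tolerance = 0.005)
  expect_equal(rep3$deviation_percent[3], 1.33, tolerance = 0.005)
  expect_true(is.na(rep3$deviation_percent[2]))
  expect_equal(mesh_sensitivity_report(c(1, 1, 1))$deviation_percent[c(1, 3)],
               c(0, 0))
  expect_error(mesh_sensitivity_report(0.08), "at least 2")
})
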