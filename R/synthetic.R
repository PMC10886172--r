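#' Shape parameters for the idealized AAA geometry
#'
#' Defines a fusiform abdominal aortic aneurysm as a Gaussian-bulged tube of
#' length `tube_length` (mm): the inner-wall radius profile is
#' `R(z) = r0 + (Rmax - r0) * exp(-((z - z0)/w)^2)`, the centerline bows
#' toward the anterior (+x) side by a Gaussian of amplitude `anterior_offset`,
#' and a non-uniform intraluminal thrombus (ILT) of thickness
#' `tau(theta, z)` lines the wall everywhere except an anterior ILT-free
#' angular sector. The angular profile rises from zero at the sector edges to
#' one over `ilt_taper_width` with a C1 cosine taper; the axial profile is
#' `floor + (1 - floor) * exp(-((z - z0)/w)^2)` so the thrombus spans the full
#' segment, thin near the neck and bifurcation and thickest at the bulge.
#'
#' Defaults mimic a large aneurysm: 75 mm peak transverse diameter
#' (`max_radius` 37.5 mm) and a thrombus reaching 14 mm.
#'
#' @param proximal_radius healthy (neck) inner-wall radius r0, mm.
#' @param max_radius peak bulge inner-wall radius Rmax, mm.
#' @param bulge_center axial position z0 of the bulge apex, mm.
#' @param bulge_width Gaussian width w of the bulge, mm.
#' @param tube_length total axial length, mm.
#' @param anterior_offset centerline bowing amplitude toward +x, mm.
#' @param ilt_free_sector angular interval (radians, around +x = anterior)
#'   with zero thrombus thickness.
#' @param ilt_max_thickness peak thrombus thickness, mm.
#' @param wall_thickness aortic wall thickness, mm (constant).
#' @param n_circumferential,n_axial lattice resolution (>= 12 and >= 20).
#' @param ilt_taper_width angular width of the cosine taper at each sector
#'   edge, radians.
#' @param ilt_axial_floor fraction of `ilt_max_thickness` retained far from
#'   the bulge (thrombus lines the whole segment).
#' @param seed integer stored with the geometry; generation is deterministic.
#' @return A validated list of class `aaa_shape_params`.
#' @export
aaa_shape_params <- function(proximal_radius = 10,
                             max_radius = 37.5,
                             bulge_center = 60,
                             bulge_width = 20,
                             tube_length = 120,
                             anterior_offset = 8,
                             ilt_free_sector = c(-pi / 4, pi / 4),
                             ilt_max_thickness = 14,
                             wall_thickness = 1,
                             n_circumferential = 36,
                             n_axial = 30,
                             ilt_taper_width = pi / 6,
                             ilt_axial_floor = 0.1,
                             seed = 1L) {
  fail <- function(field, msg) {
    stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
  }
  if (!(proximal_radius > 0)) fail("proximal_radius", "must be positive")
  if (max_radius < proximal_radius) {
    fail("max_radius", "must be >= proximal_radius")
  }
  if (!(wall_thickness > 0)) fail("wall_thickness", "must be positive")
  if (ilt_max_thickness < 0) fail("ilt_max_thickness", "must be >= 0")
  if (!(bulge_width > 0)) fail("bulge_width", "must be positive")
  if (!(tube_length > 0)) fail("tube_length", "must be positive")
  if (length(ilt_free_sector) != 2L ||
      !(ilt_free_sector[2] > ilt_free_sector[1]) ||
      diff(ilt_free_sector) >= 2 * pi) {
    fail("ilt_free_sector", "must be an increasing interval of width < 2*pi")
  }
  if (n_circumferential < 12) fail("n_circumferential", "must be >= 12")
  if (n_axial < 20) fail("n_axial", "must be >= 20")
  if (!(ilt_taper_width > 0)) fail("ilt_taper_width", "must be positive")
  if (ilt_axial_floor < 0 || ilt_axial_floor > 1) {
    fail("ilt_axial_floor", "must lie in [0, 1]")
  }
  p <- structure(
    list(proximal_radius = proximal_radius, max_radius = max_radius,
         bulge_center = bulge_center, bulge_width = bulge_width,
         tube_length = tube_length, anterior_offset = anterior_offset,
         ilt_free_sector = as.numeric(ilt_free_sector),
         ilt_max_thickness = ilt_max_thickness,
         wall_thickness = wall_thickness,
         n_circumferential = as.integer(n_circumferential),
         n_axial = as.integer(n_axial),
         ilt_taper_width = ilt_taper_width,
         ilt_axial_floor = ilt_axial_floor, seed = as.integer(seed)),
    class = "aaa_shape_params"
  )
  # lumen must stay open everywhere: R(z) - tau(theta, z) > 0
  zs <- seq(0, tube_length, length.out = 101)
  ths <- seq(0, 2 * pi, length.out = 181)
  rmin <- min(outer(zs, ths, function(z, th) {
    aaa_radius_profile(z, p) - aaa_ilt_thickness(th, z, p)
  }))
  if (rmin <= 0) {
    fail("ilt_max_thickness", "thrombus would close the lumen (R - tau <= 0)")
  }
  p
}

#' Inner-wall radius profile R(z) of the idealized AAA
#' @param z axial coordinate(s), mm.
#' @param params an [aaa_shape_params()].
#' @return Radius in mm.
#' @export
aaa_radius_profile <- function(z, params) {
  params$proximal_radius +
    (params$max_radius - params$proximal_radius) *
      exp(-((z - params$bulge_center) / params$bulge_width)^2)
}

#' Analytic ILT thickness field tau(theta, z)
#' @param theta angle(s), radians, measured from the anterior (+x) axis.
#' @param z axial coordinate(s), mm.
#' @param params an [aaa_shape_params()].
#' @return Thrombus thickness in mm (0 inside the ILT-free sector).
#' @export
aaa_ilt_thickness <- function(theta, z, params) {
  s <- sector_taper(theta, params$ilt_free_sector, params$ilt_taper_width)
  ax <- params$ilt_axial_floor + (1 - params$ilt_axial_floor) *
    exp(-((z - params$bulge_center) / params$bulge_width)^2)
  params$ilt_max_thickness * s * ax
}

# C1 angular taper: 0 inside the free sector, cosine rise to 1 over `width`
sector_taper <- function(theta, sector, width) {
  mid <- mean(sector)
  half <- diff(sector) / 2
  # signed angular distance from the sector midline, wrapped to (-pi, pi]
  d <- abs(((theta - mid + pi) %% (2 * pi)) - pi)
  u <- (d - half) / width
  s <- ifelse(u <= 0, 0, ifelse(u >= 1, 1, 0.5 * (1 - cos(pi * u))))
  s
}

#' Centerline of the idealized AAA (anterior bowing)
#' @param z axial coordinate(s), mm.
#' @param params an [aaa_shape_params()].
#' @return Matrix of 3D points, one row per z.
#' @export
aaa_centerline_point <- function(z, params) {
  out <- cbind(params$anterior_offset *
                 exp(-((z - params$bulge_center) / params$bulge_width)^2),
               0, z)
  dimnames(out) <- NULL
  out
}

# ---- lattice surface construction -------------------------------------------

# Build a structured open tube: rho is an (nz+1) x nc matrix of radii about
# the centerline, sampled at theta_j = 2*pi*(j-1)/nc and the given z stations.
# Quads split along the (i,j)->(i+1,j+1) diagonal (Kuhn-compatible), winding
# outward.
lattice_tube <- function(rho, z, params_or_center) {
  nz1 <- nrow(rho)
  nc <- ncol(rho)
  theta <- 2 * pi * (seq_len(nc) - 1) / nc
  center <- if (is.matrix(params_or_center)) {
    params_or_center
  } else {
    aaa_centerline_point(z, params_or_center)
  }
  vid <- function(i, j) (i - 1L) * nc + ((j - 1L) %% nc) + 1L
  verts <- matrix(0, nz1 * nc, 3)
  for (i in seq_len(nz1)) {
    verts[vid(i, seq_len(nc)), ] <-
      cbind(center[i, 1] + rho[i, ] * cos(theta),
            center[i, 2] + rho[i, ] * sin(theta),
            center[i, 3])
  }
  tris <- matrix(0L, 2L * (nz1 - 1L) * nc, 3)
  k <- 1L
  for (i in seq_len(nz1 - 1L)) {
    for (j in seq_len(nc)) {
      v00 <- vid(i, j); v01 <- vid(i, j + 1L)
      v10 <- vid(i + 1L, j); v11 <- vid(i + 1L, j + 1L)
      tris[k, ] <- c(v00, v01, v11)       # outward winding, diagonal v00-v11
      tris[k + 1L, ] <- c(v00, v11, v10)
      k <- k + 2L
    }
  }
  s <- tri_surface(verts, tris)
  attr(s, "grid") <- list(ni = nz1, nj = nc)
  s
}

copy_grid_attr <- function(to, from) {
  attr(to, "grid") <- attr(from, "grid")
  to
}

# cell index (i, j) -> the two triangle row indices it produced
lattice_cell_tris <- function(grid, i, j) {
  k <- 2L * ((i - 1L) * grid$nj + (j - 1L))
  c(k + 1L, k + 2L)
}

#' Generate the idealized AAA boundary surfaces
#'
#' Produces the two segmentation-style open surfaces — the blood lumen and the
#' inner aortic wall (which encloses lumen plus thrombus) — sampled on a
#' shared (theta, z) lattice, together with the bowed centerline. The two
#' surfaces coincide vertex-wise over the ILT-free sector where the thrombus
#' thickness is exactly zero.
#'
#' @param params an [aaa_shape_params()].
#' @return A list with `lumen` and `inner_wall` ([tri_surface()]s), and
#'   `centerline` (matrix of points ordered distal (z = 0) to proximal).
#' @export
generate_aaa_surfaces <- function(params) {
  if (!inherits(params, "aaa_shape_params")) {
    params <- do.call(aaa_shape_params, as.list(params))
  }
  nc <- params$n_circumferential
  nz <- params$n_axial
  z <- seq(0, params$tube_length, length.out = nz + 1)
  theta <- 2 * pi * (seq_len(nc) - 1) / nc
  R <- matrix(aaa_radius_profile(z, params), nz + 1, nc)
  tau <- outer(z, theta, function(zz, th) aaa_ilt_thickness(th, zz, params))
  inner_wall <- lattice_tube(R, z, params)
  lumen <- lattice_tube(R - tau, z, params)
  centerline <- aaa_centerline_point(z, params)
  attr(inner_wall, "aaa_params") <- params
  attr(lumen, "aaa_params") <- params
  list(lumen = lumen, inner_wall = inner_wall, centerline = centerline)
}

#' Coaxial cylinder benchmark fixture
#'
#' Two coaxial open cylinders (plus the straight centerline), suitable for
#' stitching and meshing into a thick-walled tube — the analytic benchmark
#' body for the Lame pressurized-cylinder solution.
#'
#' @param inner_radius,outer_radius radii in mm (0 < inner < outer).
#' @param length axial length, mm.
#' @param resolution integer 2-vector: circumferential and axial counts.
#' @return List with `inner`, `outer` ([tri_surface()]s) and `centerline`.
#' @export
generate_cylinder_fixture <- function(inner_radius, outer_radius, length,
                                      resolution = c(64L, 40L)) {
  if (!(inner_radius > 0) || !(inner_radius < outer_radius)) {
    stop("invalid `inner_radius`: need 0 < inner_radius < outer_radius",
         call. = FALSE)
  }
  nc <- as.integer(resolution[1])
  nz <- as.integer(resolution[2])
  z <- seq(0, length, length.out = nz + 1)
  center <- cbind(0, 0, z)
  dimnames(center) <- NULL
  inner <- lattice_tube(matrix(inner_radius, nz + 1, nc), z, center)
  outer <- lattice_tube(matrix(outer_radius, nz + 1, nc), z, center)
  list(inner = inner, outer = outer, centerline = center)
}

#' Unit-cube patch-test mesh
#'
#' Kuhn (Freudenthal) subdivision of the unit cube into 6 tetrahedra sharing
#' the main diagonal, with boundary-face sets named XMIN/XMAX/YMIN/YMAX/
#' ZMIN/ZMAX for Dirichlet and pressure patch tests.
#'
#' @return A [tet_mesh()] with 8 nodes and 6 positively oriented tetrahedra.
#' @export
generate_patch_fixture <- function() {
  corners <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  id <- function(x, y, z) 1L + x + 2L * y + 4L * z
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  tets <- matrix(0L, 6, 4)
  for (k in seq_along(perms)) {
    p <- perms[[k]]
    v <- matrix(0L, 4, 3)
    v[2, p[1]] <- 1L
    v[3, p[1]] <- 1L; v[3, p[2]] <- 1L
    v[4, ] <- 1L
    tets[k, ] <- id(v[, 1], v[, 2], v[, 3])
  }
  # fix orientation: positive volume
  for (k in seq_len(6)) {
    x <- corners[tets[k, ], ]
    if (det(rbind(x[2, ] - x[1, ], x[3, ] - x[1, ], x[4, ] - x[1, ])) < 0) {
      tets[k, ] <- tets[k, c(1, 2, 4, 3)]
    }
  }
  m <- tet_mesh(corners, tets, body = rep("WALL", 6))
  bf <- boundary_faces(m)
  coord <- list(XMIN = c(1, 0), XMAX = c(1, 1), YMIN = c(2, 0),
                YMAX = c(2, 1), ZMIN = c(3, 0), ZMAX = c(3, 1))
  m$face_sets <- lapply(coord, function(cw) {
    on <- apply(bf, 1, function(f) all(abs(corners[f, cw[1]] - cw[2]) < 1e-12))
    bf[on, , drop = FALSE]
  })
  m
}
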