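#' Resample a centerline polyline at equal arclength spacing
#'
#' @param points ordered matrix of 3D points, distal end first (the convention
#'   used throughout: the centerline vector points distal to proximal).
#' @param n number of output points (default 90, the resampling used for the
#'   vessel centerline).
#' @return An object of class `centerline`: list with `points` (n x 3) and
#'   `arclength` (cumulative, mm). Endpoints are preserved exactly.
#' @export
resample_centerline <- function(points, n = 90L) {
  points <- as.matrix(points)
  if (nrow(points) < 2L) stop("centerline needs at least 2 points")
  if (n < 2L) stop("invalid `n`: need at least 2 output points")
  seg <- sqrt(rowSums(diff(points)^2))
  if (any(seg == 0)) stop("consecutive centerline points must be distinct")
  s <- c(0, cumsum(seg))
  st <- seq(0, s[length(s)], length.out = n)
  out <- vapply(1:3, function(d) stats::approx(s, points[, d], xout = st)$y,
                numeric(n))
  out <- matrix(out, n, 3)
  out[1, ] <- points[1, ]
  out[n, ] <- points[nrow(points), ]
  structure(list(points = out, arclength = st), class = "centerline")
}

#' Per-element local material frames from the centerline
#'
#' Builds the local Cartesian coordinate system of every element of the
#' aortic wall: for each outer-surface triangle the radial axis e3 is its
#' outward unit normal; the centerline vector a_centr is the unit vector
#' between the consecutive centerline points nearest the face centroid
#' (directed distal to proximal); the circumferential axis is
#' e1 = normalize(a_centr x e3) and the axial axis e2 = e3 x e1. Interior
#' elements (and thrombus elements) copy the frame of the nearest external
#' wall tetrahedron (squared Euclidean centroid distance, lowest index on
#' ties). Where the centerline tangent is parallel to the normal (degenerate
#' cross product) the frame of the nearest non-degenerate external element is
#' reused, with a warning.
#'
#' @param mesh a [tet_mesh()] with an `OUTER` face set.
#' @param centerline a [resample_centerline()] result (or a point matrix,
#'   resampled to 90 points).
#' @return An object of class `local_frame_field`: list of per-element unit
#'   3-vector matrices `e1` (circumferential), `e2` (axial), `e3` (radial).
#' @export
assign_local_frames <- function(mesh, centerline) {
  if (!inherits(centerline, "centerline")) {
    centerline <- resample_centerline(centerline)
  }
  outer <- mesh$face_sets$OUTER
  if (is.null(outer) || nrow(outer) == 0L) {
    stop("mesh has no OUTER face labels")
  }
  cp <- centerline$points
  np <- nrow(cp)

  # owner tet of each outer face
  tt <- mesh$tets
  allf <- rbind(tt[, c(1, 3, 2)], tt[, c(1, 2, 4)],
                tt[, c(1, 4, 3)], tt[, c(2, 3, 4)])
  owner <- rep(seq_len(nrow(tt)), 4L)
  fk <- face_key(allf)
  ok <- face_key(outer)
  face_owner <- owner[match(ok, fk)]

  g <- triangle_geometry(tri_surface(mesh$nodes, outer))
  idx <- cpp_nearest_index(g$centroid, cp)
  seg_lo <- pmin(idx, np - 1L)
  a <- cp[seg_lo + 1L, , drop = FALSE] - cp[seg_lo, , drop = FALSE]
  a <- a / sqrt(rowSums(a^2))
  e3 <- g$normal
  e1 <- cross_rows(a, e3)
  n1 <- sqrt(rowSums(e1^2))
  degen <- n1 < 1e-6
  e1 <- e1 / pmax(n1, .Machine$double.xmin)
  e2 <- cross_rows(e3, e1)

  ne <- nrow(tt)
  E1 <- matrix(NA_real_, ne, 3)
  E2 <- E1
  E3 <- E1
  ext <- rep(FALSE, ne)
  # first face wins where a tet owns several outer faces
  for (f in order(face_owner)) {
    tet <- face_owner[f]
    if (ext[tet] || degen[f]) next
    ext[tet] <- TRUE
    E1[tet, ] <- e1[f, ]
    E2[tet, ] <- e2[f, ]
    E3[tet, ] <- e3[f, ]
  }
  if (any(degen)) {
    warning(sprintf(
      "%d outer faces have a centerline tangent parallel to the normal; %s",
      sum(degen), "their elements reuse the nearest non-degenerate frame"))
  }
  if (!any(ext)) stop("no usable external frames")
  cen <- tet_centroids(mesh)
  ext_ids <- which(ext)
  rest <- which(!ext)
  if (length(rest)) {
    nn <- cpp_nearest_index(cen[rest, , drop = FALSE],
                            cen[ext_ids, , drop = FALSE])
    src <- ext_ids[nn]
    E1[rest, ] <- E1[src, ]
    E2[rest, ] <- E2[src, ]
    E3[rest, ] <- E3[src, ]
  }
  structure(list(e1 = E1, e2 = E2, e3 = E3, external = ext),
            class = "local_frame_field")
}

tet_centroids <- function(mesh) {
  (mesh$nodes[mesh$tets[, 1], , drop = FALSE] +
     mesh$nodes[mesh$tets[, 2], , drop = FALSE] +
     mesh$nodes[mesh$tets[, 3], , drop = FALSE] +
     mesh$nodes[mesh$tets[, 4], , drop = FALSE]) / 4
}

#' Collagen fiber directions from the local frames
#'
#' The two fiber families lie in the wall tangent plane, symmetric about the
#' circumferential axis by `alpha` degrees:
#' `M4 = cos(a) e1 + sin(a) e2`, `M6 = cos(a) e1 - sin(a) e2`.
#'
#' @param frames a [assign_local_frames()] result.
#' @param alpha fiber angle in degrees (Table-of-parameters default 5.6).
#' @return An object of class `fiber_field`: list with unit-vector matrices
#'   `M4` and `M6`.
#' @export
fiber_directions <- function(frames, alpha) {
  a <- alpha * pi / 180
  structure(list(M4 = cos(a) * frames$e1 + sin(a) * frames$e2,
                 M6 = cos(a) * frames$e1 - sin(a) * frames$e2,
                 alpha_deg = alpha),
            class = "fiber_field")
}
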