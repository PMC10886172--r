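#' Taubin smoothing (shrink-free two-pass Laplacian)
#'
#' Deterministic replacement for interactive brush smoothing: each iteration
#' applies a uniform-weight Laplacian step with positive factor
#' `shrink_factor` followed by a negative step `inflate_factor`, which keeps
#' the enclosed volume nearly unchanged. Boundary vertices are held fixed so
#' open tube ends and shared end rings stay put; connectivity is never
#' modified.
#'
#' @param surface a [tri_surface()].
#' @param iterations number of shrink/inflate passes.
#' @param shrink_factor positive step, in (0, 1).
#' @param inflate_factor negative step, typically slightly larger in
#'   magnitude than `shrink_factor` (default -0.53).
#' @return The smoothed surface (same class, same connectivity).
#' @export
taubin_smooth <- function(surface, iterations = 20, shrink_factor = 0.5,
                          inflate_factor = -0.53) {
  if (!(shrink_factor > 0 && shrink_factor < 1)) {
    stop("`shrink_factor` must lie in (0, 1)")
  }
  if (!(inflate_factor < 0)) stop("`inflate_factor` must be negative")
  ed <- surface_edges(surface)
  if (any(ed$count > 2L)) {
    stop("non-manifold surface: an edge is shared by more than 2 triangles")
  }
  if (iterations == 0) return(surface)
  n <- nrow(surface$vertices)
  # undirected neighbor structure from unique edges
  keys <- unique(ed$key)
  lo <- floor(keys / 2^31)
  hi <- keys - lo * 2^31
  ii <- c(lo, hi)
  jj <- c(hi, lo)
  deg <- tabulate(ii, nbins = n)
  bnd_keys <- as.numeric(names(ed$count)[ed$count == 1L])
  bnd_v <- unique(c(floor(bnd_keys / 2^31), bnd_keys %% 2^31))
  interior <- setdiff(which(deg > 0), bnd_v)
  v <- surface$vertices
  lap_step <- function(v, fac) {
    s <- rowsum(v[jj, , drop = FALSE], group = ii)
    mean_nb <- matrix(0, n, 3)
    mean_nb[as.integer(rownames(s)), ] <- s / deg[as.integer(rownames(s))]
    d <- mean_nb - v
    v[interior, ] <- v[interior, ] + fac * d[interior, , drop = FALSE]
    v
  }
  for (it in seq_len(iterations)) {
    v <- lap_step(v, shrink_factor)
    v <- lap_step(v, inflate_factor)
  }
  out <- surface
  out$vertices <- v
  out
}

#' Thickness analysis: label where lumen and inner wall coincide
#'
#' For every lumen triangle the distance from its centroid to the inner-wall
#' surface is computed (exact point-to-triangle distances); triangles closer
#' than `distance_tol` are labeled `"wall_contact"` (the ILT-free region
#' where the two segmentation surfaces coincide), all others `"ilt"`. Labels
#' are then transferred to the inner wall by nearest-centroid matching.
#'
#' @param lumen,inner_wall [tri_surface()]s.
#' @param distance_tol coincidence tolerance in mm (default 0.2).
#' @return A list with character vectors `lumen` and `inner_wall` (one label
#'   per triangle) plus the raw lumen `distance` vector.
#' @export
detect_ilt_free_region <- function(lumen, inner_wall, distance_tol = 0.2) {
  if (nrow(lumen$triangles) == 0L || nrow(inner_wall$triangles) == 0L) {
    stop("empty surface passed to thickness analysis")
  }
  gl <- triangle_geometry(lumen)
  gw <- triangle_geometry(inner_wall)
  d <- cpp_dist_to_surface(gl$centroid, inner_wall$vertices,
                           inner_wall$triangles)$dist
  lab_lumen <- ifelse(d <= distance_tol, "wall_contact", "ilt")
  nearest <- cpp_nearest_index(gw$centroid, gl$centroid)
  lab_wall <- lab_lumen[nearest]
  list(lumen = lab_lumen, inner_wall = lab_wall, distance = d,
       distance_tol = distance_tol)
}

#' Fragment the lumen and inner-wall surfaces along the thrombus boundary
#'
#' Reproduces the boundary-surface fragmentation: the part of the lumen in
#' contact with the wall is discarded (leaving the luminal ILT surface), and
#' a strip of inner-wall triangles along the ILT boundary is erased, creating
#' the discontinuity that separates the ILT-covered from the ILT-free wall.
#' The strip is taken from the covered side, `n` adjacency rings deep where
#' `n = max(1, round(strip_width / (2 * median edge length)))`.
#'
#' @param lumen,inner_wall [tri_surface()]s on the same lattice.
#' @param contact_labels result of [detect_ilt_free_region()].
#' @param strip_width target erased-strip width in mm; default two median
#'   edge lengths.
#' @return List with `luminal_ilt`, `wall_ilt_covered`, `wall_ilt_free`,
#'   `strip` ([tri_surface()]s sharing the parent vertex arrays, original
#'   triangle rows in attribute `tri_rows`) and `open_loops`, the boundary
#'   loops of the three retained fragments.
#' @export
fragment_surfaces <- function(lumen, inner_wall, contact_labels,
                              strip_width = NULL) {
  if (is.null(contact_labels$lumen) || is.null(contact_labels$inner_wall)) {
    stop("`contact_labels` must carry lumen and inner_wall label fields")
  }
  keep_lum <- contact_labels$lumen == "ilt"
  luminal_ilt <- subset_triangles(lumen, keep_lum)
  attr(luminal_ilt, "tri_rows") <- which(keep_lum)
  attr(luminal_ilt, "distance_tol") <- contact_labels$distance_tol
  luminal_ilt <- copy_grid_attr(luminal_ilt, lumen)

  covered0 <- contact_labels$inner_wall == "ilt"
  free <- !covered0
  t <- inner_wall$triangles
  # median edge length sets the ring count of the erased strip
  co <- tri_corners(inner_wall)
  el <- c(sqrt(rowSums((co$a - co$b)^2)), sqrt(rowSums((co$b - co$c)^2)),
          sqrt(rowSums((co$c - co$a)^2)))
  med <- stats::median(el)
  if (is.null(strip_width)) strip_width <- 2 * med
  n_rings <- max(1L, as.integer(round(strip_width / (2 * med))))

  grid <- attr(inner_wall, "grid")
  if (is.null(grid)) {
    stop("fragmentation needs the lattice grid attribute on `inner_wall`")
  }
  # cell-based strip: erase the covered triangles of every mixed-label cell
  # and of covered cells within `n_rings` (8-neighborhood) of the boundary,
  # which guarantees the re-stitched chains share no vertices
  nc_i <- grid$ni - 1L
  nc_j <- grid$nj
  cell_of <- (seq_len(nrow(t)) - 1L) %/% 2L  # 0-based cell index
  cellc <- matrix(0L, nc_i, nc_j)
  for (k in which(covered0)) {
    q <- cell_of[k]
    cellc[q %/% nc_j + 1L, q %% nc_j + 1L] <-
      cellc[q %/% nc_j + 1L, q %% nc_j + 1L] + 1L
  }
  shift8 <- function(m) {
    out <- matrix(FALSE, nrow(m), ncol(m))
    for (di in -1:1) {
      ii <- pmin(pmax(seq_len(nrow(m)) + di, 1L), nrow(m))
      for (dj in -1:1) {
        jj <- ((seq_len(ncol(m)) + dj - 1L) %% ncol(m)) + 1L
        out <- out | m[ii, jj, drop = FALSE]
      }
    }
    out
  }
  strip_cells <- cellc == 1L
  front <- cellc == 2L & shift8(cellc <= 1L)
  for (r in seq_len(n_rings)) {
    strip_cells <- strip_cells | front
    front <- cellc == 2L & !strip_cells & shift8(strip_cells)
  }
  in_strip_cell <- strip_cells[cbind(cell_of %/% nc_j + 1L,
                                     cell_of %% nc_j + 1L)]
  strip <- covered0 & in_strip_cell
  covered <- covered0 & !strip

  frag <- function(keep) {
    s <- subset_triangles(inner_wall, keep)
    attr(s, "tri_rows") <- which(keep)
    copy_grid_attr(s, inner_wall)
  }
  wall_ilt_covered <- frag(covered)
  wall_ilt_free <- frag(free)
  strip_surf <- frag(strip)

  loops <- c(
    luminal_ilt = list(surface_boundary_loops(luminal_ilt)),
    wall_ilt_covered = list(surface_boundary_loops(wall_ilt_covered)),
    wall_ilt_free = list(surface_boundary_loops(wall_ilt_free))
  )
  list(luminal_ilt = luminal_ilt, wall_ilt_covered = wall_ilt_covered,
       wall_ilt_free = wall_ilt_free, strip = strip_surf, open_loops = loops)
}

#' Offset a surface along its vertex normals
#'
#' Displaces every vertex along its area-weighted pseudo-normal by
#' `thickness` (mm); used to create the outer aortic-wall surface at the
#' constant 1 mm wall thickness. Connectivity is preserved. When the face
#' normals around a vertex spread by more than 60 degrees (sharp crease or
#' curvature radius comparable to the offset) a warning is emitted, since the
#' averaged-normal offset may locally distort distances there.
#'
#' @param inner_wall a [tri_surface()] with outward-consistent winding.
#' @param thickness offset distance in mm (0 returns the input unchanged).
#' @return The offset surface.
#' @export
offset_surface <- function(inner_wall, thickness) {
  if (thickness == 0) return(inner_wall)
  vn <- vertex_normals(inner_wall)
  # crease check: angle between face normals and vertex pseudo-normal
  g <- triangle_geometry(inner_wall)
  worst <- 0
  for (k in 1:3) {
    cosang <- rowSums(g$normal * vn[inner_wall$triangles[, k], , drop = FALSE])
    worst <- max(worst, max(acos(pmin(1, pmax(-1, cosang)))))
  }
  if (worst > pi / 3) {
    warning("normal spread exceeds 60 degrees; offset clamped to averaged normals")
  }
  out <- inner_wall
  out$vertices <- inner_wall$vertices + thickness * vn
  copy_grid_attr(out, inner_wall)
}
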