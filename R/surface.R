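#' Oriented triangle surface
#'
#' Lightweight container for a triangulated boundary surface: a matrix of
#' vertex coordinates (mm), a matrix of 1-based vertex-index triples
#' (counter-clockwise winding = outward normal), and an optional per-triangle
#' region label. All surface-processing steps of the pipeline (smoothing,
#' thickness analysis, fragmentation, offsetting, stitching, assembly) operate
#' on this class.
#'
#' @param vertices numeric matrix, one row per vertex, columns x/y/z in mm.
#' @param triangles integer matrix, one row per triangle, 1-based vertex ids.
#' @param region optional character or integer vector, one label per triangle.
#' @return An object of class `tri_surface`.
#' @export
tri_surface <- function(vertices, triangles, region = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  if (ncol(vertices) != 3L) stop("`vertices` must have 3 columns")
  if (ncol(triangles) != 3L) stop("`triangles` must have 3 columns")
  if (nrow(triangles) > 0L &&
      (min(triangles) < 1L || max(triangles) > nrow(vertices))) {
    stop("triangle indices out of range")
  }
  if (!is.null(region) && length(region) != nrow(triangles)) {
    stop("`region` must have one entry per triangle")
  }
  structure(
    list(vertices = vertices, triangles = triangles, region = region),
    class = "tri_surface"
  )
}

#' @export
print.tri_surface <- function(x, ...) {
  cat(sprintf(
    "<tri_surface> %d vertices, %d triangles%s\n",
    nrow(x$vertices), nrow(x$triangles),
    if (!is.null(x$region)) {
      sprintf(", regions: %s", paste(unique(x$region), collapse = ", "))
    } else ""
  ))
  invisible(x)
}

# ---- elementary per-triangle quantities -------------------------------------

tri_corners <- function(surface) {
  v <- surface$vertices
  t <- surface$triangles
  list(a = v[t[, 1], , drop = FALSE],
       b = v[t[, 2], , drop = FALSE],
       c = v[t[, 3], , drop = FALSE])
}

cross_rows <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

#' Triangle centroids, areas and unit normals
#' @param surface a [tri_surface()].
#' @return A list with `centroid` (matrix), `area` (vector, mm^2) and
#'   `normal` (matrix of unit normals following the winding).
#' @keywords internal
triangle_geometry <- function(surface) {
  co <- tri_corners(surface)
  n2 <- cross_rows(co$b - co$a, co$c - co$a)
  area2 <- sqrt(rowSums(n2^2))
  normal <- n2 / pmax(area2, .Machine$double.xmin)
  list(centroid = (co$a + co$b + co$c) / 3, area = area2 / 2, normal = normal)
}

edge_key <- function(i, j) {
  lo <- pmin(i, j)
  hi <- pmax(i, j)
  lo * 2^31 + hi  # exact in doubles for < 2^21 vertices
}

surface_edges <- function(surface) {
  t <- surface$triangles
  i <- c(t[, 1], t[, 2], t[, 3])
  j <- c(t[, 2], t[, 3], t[, 1])
  key <- edge_key(i, j)
  cnt <- table(key)
  list(from = i, to = j, key = key, count = cnt)
}

#' Boundary loops of a triangle surface
#'
#' Boundary edges (edges used by exactly one triangle) are chained into closed
#' vertex cycles, following the triangle winding so loop orientation is
#' consistent with the surface orientation.
#'
#' @param surface a [tri_surface()].
#' @return A list of integer vectors, each an ordered closed cycle of vertex
#'   indices (first vertex not repeated at the end). Empty list for a closed
#'   surface.
#' @export
surface_boundary_loops <- function(surface) {
  ed <- surface_edges(surface)
  once <- names(ed$count)[ed$count == 1L]
  if (length(once) == 0L) return(list())
  is_bnd <- as.character(ed$key) %in% once
  # undirected walk (winding of freshly stitched bands may be inconsistent)
  a <- pmin(ed$from[is_bnd], ed$to[is_bnd])
  b <- pmax(ed$from[is_bnd], ed$to[is_bnd])
  m <- length(a)
  used <- rep(FALSE, m)
  inc <- split(rep(seq_len(m), 2L), c(a, b))
  other <- function(e, v) if (a[e] == v) b[e] else a[e]
  loops <- list()
  for (s in order(a, b)) {
    if (used[s]) next
    start <- a[s]
    loop <- integer(0)
    v <- start
    e <- s
    repeat {
      used[e] <- TRUE
      loop <- c(loop, v)
      v <- other(e, v)
      if (v == start) break
      cands <- inc[[as.character(v)]]
      cands <- cands[!used[cands]]
      if (length(cands) == 0L) stop("boundary edges do not close into a loop")
      e <- min(cands)  # lowest-index tie-break at non-manifold pinches
    }
    loops[[length(loops) + 1L]] <- loop
  }
  loops
}

#' Surface diagnostics
#'
#' Topology and volume census used throughout the pipeline: boundary-edge
#' count, Euler characteristic, optional self-intersection count, and the
#' enclosed volume (divergence theorem), defined only for closed surfaces.
#' Diagnostics never throw.
#'
#' @param surface a [tri_surface()].
#' @param check_self_intersections logical; the triangle-triangle census is
#'   quadratic with a bounding-box prefilter, so it can be skipped for speed.
#' @return A list: `boundary_edge_count`, `euler_characteristic`,
#'   `self_intersections` (NA if not checked), `closed`, `enclosed_volume_mm3`
#'   and `enclosed_volume` in mL (1 mL = 1000 mm^3); volumes are `NA` for open
#'   surfaces.
#' @export
surface_diagnostics <- function(surface, check_self_intersections = TRUE) {
  ed <- surface_edges(surface)
  n_bnd <- sum(ed$count == 1L)
  nv <- length(unique(as.vector(surface$triangles)))
  ne <- length(ed$count)
  nf <- nrow(surface$triangles)
  chi <- nv - ne + nf
  closed <- n_bnd == 0L
  vol <- if (closed) signed_volume(surface) else NA_real_
  si <- if (isTRUE(check_self_intersections)) {
    cpp_self_intersections(surface$vertices, surface$triangles)
  } else NA_integer_
  list(
    boundary_edge_count = n_bnd,
    euler_characteristic = chi,
    self_intersections = si,
    closed = closed,
    enclosed_volume_mm3 = vol,
    enclosed_volume = vol / 1000
  )
}

#' Signed enclosed volume (mm^3) of a closed surface via the divergence theorem
#' @keywords internal
signed_volume <- function(surface) {
  co <- tri_corners(surface)
  sum(rowSums(co$a * cross_rows(co$b, co$c))) / 6
}

# ---- orientation ------------------------------------------------------------

#' Make triangle winding globally consistent (and outward for closed surfaces)
#'
#' Flood-fills orientation across shared edges per connected component; for a
#' closed surface the global sign is then fixed so the signed volume is
#' positive (outward normals).
#'
#' @param surface a [tri_surface()].
#' @return The reoriented surface.
#' @export
orient_surface <- function(surface) {
  t <- surface$triangles
  nt <- nrow(t)
  if (nt == 0L) return(surface)
  keys <- matrix(edge_key(cbind(t[, 1], t[, 2], t[, 3]),
                          cbind(t[, 2], t[, 3], t[, 1])), ncol = 3)
  # adjacency via shared undirected edges
  ek <- as.vector(keys)
  tid <- rep(seq_len(nt), 3L)
  byedge <- split(tid, ek)
  adj <- vector("list", nt)
  for (tris in byedge) {
    if (length(tris) == 2L) {
      adj[[tris[1]]] <- c(adj[[tris[1]]], tris[2])
      adj[[tris[2]]] <- c(adj[[tris[2]]], tris[1])
    }
  }
  dir_edges <- function(tri) rbind(tri[c(1, 2)], tri[c(2, 3)], tri[c(3, 1)])
  flipped <- rep(FALSE, nt)
  seen <- rep(FALSE, nt)
  for (root in seq_len(nt)) {
    if (seen[root]) next
    queue <- root
    seen[root] <- TRUE
    while (length(queue)) {
      cur <- queue[1]
      queue <- queue[-1]
      ce <- dir_edges(if (flipped[cur]) rev(t[cur, ]) else t[cur, ])
      for (nb in adj[[cur]]) {
        if (seen[nb]) next
        nbe <- dir_edges(t[nb, ])
        same_dir <- FALSE
        for (a in 1:3) for (b in 1:3) {
          if (all(ce[a, ] == nbe[b, ])) same_dir <- TRUE
        }
        # consistent orientation traverses a shared edge in opposite directions
        flipped[nb] <- same_dir
        seen[nb] <- TRUE
        queue <- c(queue, nb)
      }
    }
  }
  t[flipped, ] <- t[flipped, c(1, 3, 2)]
  out <- surface
  out$triangles <- t
  d <- surface_diagnostics(out, check_self_intersections = FALSE)
  if (d$closed && !is.na(d$enclosed_volume_mm3) && d$enclosed_volume_mm3 < 0) {
    out$triangles <- out$triangles[, c(1, 3, 2)]
  }
  out
}

# ---- subsetting / combining -------------------------------------------------

#' Keep a subset of triangles (vertex array and indexing are preserved)
#' @keywords internal
subset_triangles <- function(surface, keep) {
  tri_surface(surface$vertices, surface$triangles[keep, , drop = FALSE],
              region = if (!is.null(surface$region)) surface$region[keep])
}

#' Area-weighted vertex normals
#' @keywords internal
vertex_normals <- function(surface) {
  co <- tri_corners(surface)
  n2 <- cross_rows(co$b - co$a, co$c - co$a)  # length = 2*area
  vn <- matrix(0, nrow(surface$vertices), 3)
  for (k in 1:3) {
    idx <- surface$triangles[, k]
    for (j in 1:3) {
      vn[, j] <- vn[, j] + unname(tapply_sum(n2[, j], idx, nrow(vn)))
    }
    # tapply_sum accumulates once per corner slot
  }
  len <- sqrt(rowSums(vn^2))
  vn / pmax(len, .Machine$double.xmin)
}

tapply_sum <- function(x, index, n) {
  out <- numeric(n)
  s <- rowsum(x, group = index)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}
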