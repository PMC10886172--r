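#' Stitch two boundary loops with a triangle band
#'
#' Joins two ordered boundary polylines (closed rings by default, open chains
#' with pinned endpoints otherwise) by a greedy minimal-area advancing front
#' after arclength alignment: at each step the front edge advances along the
#' loop whose candidate triangle has the smaller area, ties going to the
#' first loop. Every vertex of both loops is used exactly once; the resulting
#' band is a topological annulus (closed case) or strip (open case) that is
#' watertight with the parent surfaces.
#'
#' @param loopA,loopB ordered coordinate matrices (one row per loop vertex;
#'   for closed loops the first vertex is not repeated).
#' @param closed logical: rings (TRUE, default) or open chains.
#' @return An object of class `stitch_band`: list with `new_triangles`
#'   (indices 1..nA refer to `loopA` rows, nA+1..nA+nB to `loopB` rows),
#'   `nA`, `nB` and `provenance`.
#' @export
stitch_loops <- function(loopA, loopB, closed = TRUE) {
  loopA <- as.matrix(loopA)
  loopB <- as.matrix(loopB)
  nA <- nrow(loopA)
  nB <- nrow(loopB)
  if (nA < 2L || nB < 2L) stop("loops must have at least 2 vertices")
  # identical / touching loops cannot be stitched
  dmin <- min(as.matrix(stats::dist(rbind(loopA, loopB)))[seq_len(nA),
                                                          nA + seq_len(nB)])
  if (dmin < 1e-9) {
    stop("loops intersect or coincide: minimum inter-loop distance is zero")
  }

  if (closed) {
    score_ord <- function(ord) {
      B <- loopB[ord, , drop = FALSE]
      s <- which.min(rowSums((B - matrix(loopA[1, ], nB, 3, byrow = TRUE))^2))
      ord2 <- ord[c(s:nB, seq_len(s - 1L))]
      B2 <- loopB[ord2, , drop = FALSE]
      tA <- arclength_param(loopA, closed = TRUE)
      tB <- arclength_param(B2, closed = TRUE)
      idx <- vapply(tA, function(t) which.min(abs(tB - t)), integer(1))
      list(ord = ord2,
           val = sum(sqrt(rowSums((loopA - B2[idx, , drop = FALSE])^2))))
    }
    fwd <- score_ord(seq_len(nB))
    bwd <- score_ord(rev(seq_len(nB)))
    ordB <- if (fwd$val <= bwd$val) fwd$ord else bwd$ord
  } else {
    d_same <- sum((loopA[1, ] - loopB[1, ])^2) +
      sum((loopA[nA, ] - loopB[nB, ])^2)
    d_rev <- sum((loopA[1, ] - loopB[nB, ])^2) +
      sum((loopA[nA, ] - loopB[1, ])^2)
    ordB <- if (d_same <= d_rev) seq_len(nB) else rev(seq_len(nB))
  }
  B <- loopB[ordB, , drop = FALSE]

  tri_area <- function(p, q, r) {
    u <- q - p
    v <- r - p
    w <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
           u[1] * v[2] - u[2] * v[1])
    0.5 * sqrt(sum(w^2))
  }
  steps_A <- 0L
  steps_B <- 0L
  i <- 1L
  j <- 1L
  tris <- matrix(0L, nA + nB - if (closed) 0L else 2L, 3)
  k <- 0L
  nextA <- function(i) if (closed) (i %% nA) + 1L else i + 1L
  nextB <- function(j) if (closed) (j %% nB) + 1L else j + 1L
  maxA <- if (closed) nA else nA - 1L
  maxB <- if (closed) nB else nB - 1L
  # per-step normalized arclength: the front advances the loop that lags,
  # so the zip stays balanced; areas only break near-ties
  lenA <- sqrt(rowSums((loopA[vapply(seq_len(maxA), nextA, 1L), ,
                              drop = FALSE] -
                          loopA[seq_len(maxA), , drop = FALSE])^2))
  lenB <- sqrt(rowSums((B[vapply(seq_len(maxB), nextB, 1L), , drop = FALSE] -
                          B[seq_len(maxB), , drop = FALSE])^2))
  pA <- 0
  pB <- 0
  while (steps_A < maxA || steps_B < maxB) {
    canA <- steps_A < maxA
    canB <- steps_B < maxB
    qA <- if (canA) pA + lenA[steps_A + 1L] / sum(lenA) else Inf
    qB <- if (canB) pB + lenB[steps_B + 1L] / sum(lenB) else Inf
    adv_A <- if (abs(qA - qB) > 1e-9) qA < qB else {
      aA <- if (canA) tri_area(loopA[i, ], loopA[nextA(i), ], B[j, ]) else Inf
      aB <- if (canB) tri_area(loopA[i, ], B[nextB(j), ], B[j, ]) else Inf
      aA <= aB  # tie advances the first loop
    }
    k <- k + 1L
    if (adv_A) {
      tris[k, ] <- c(i, nextA(i), nA + j)
      i <- nextA(i)
      steps_A <- steps_A + 1L
      pA <- qA
    } else {
      tris[k, ] <- c(i, nA + nextB(j), nA + j)
      j <- nextB(j)
      steps_B <- steps_B + 1L
      pB <- qB
    }
  }
  structure(list(new_triangles = tris[seq_len(k), , drop = FALSE],
                 nA = nA, nB = nB, closed = closed, orderB = ordB,
                 provenance = c(loopA = "A", loopB = "B")),
            class = "stitch_band")
}

arclength_param <- function(pts, closed = TRUE) {
  n <- nrow(pts)
  seg <- sqrt(rowSums((pts[c(2:n, 1), , drop = FALSE] - pts)^2))
  if (!closed) seg <- seg[-n]
  tot <- sum(seg)
  c(0, cumsum(seg))[seq_len(n)] / tot
}

#' Stitch band as a standalone surface (for diagnostics)
#' @param band a [stitch_loops()] result.
#' @param loopA,loopB the coordinate matrices the band was built from.
#' @return A [tri_surface()] over the concatenated loop vertices.
#' @export
band_surface <- function(band, loopA, loopB) {
  B <- as.matrix(loopB)[band$orderB, , drop = FALSE]
  tri_surface(rbind(as.matrix(loopA), B), band$new_triangles)
}

# remap band triangles into a global vertex index space
remap_band <- function(band, idsA, idsB) {
  idsB <- idsB[band$orderB]
  tr <- band$new_triangles
  out <- tr
  out[tr <= band$nA] <- idsA[tr[tr <= band$nA]]
  out[tr > band$nA] <- idsB[tr[tr > band$nA] - band$nA]
  out
}

# split a closed boundary loop (vertex ids on a lattice surface) into maximal
# chains of edges that are not end-ring edges (both endpoints on lattice row 1
# or both on the last row)
split_loop_chains <- function(loop, grid) {
  row_of <- function(v) (v - 1L) %/% grid$nj + 1L
  n <- length(loop)
  r <- row_of(loop)
  nxt <- c(2:n, 1L)
  is_end <- (r == 1L & r[nxt] == 1L) | (r == grid$ni & r[nxt] == grid$ni)
  if (all(!is_end)) return(list(closed = TRUE, chains = list(loop)))
  # rotate so position 1 starts right after an end-ring edge
  start <- which(is_end)[1] %% n + 1L
  ord <- c(start:n, seq_len(start - 1L))
  loop2 <- loop[ord]
  is_end2 <- is_end[ord]
  chains <- list()
  cur <- loop2[1]
  for (k in seq_len(n)) {
    if (!is_end2[k]) {
      cur <- c(cur, loop2[k %% n + 1L])
    } else {
      if (length(cur) > 1L) chains[[length(chains) + 1L]] <- cur
      cur <- loop2[k %% n + 1L]
    }
  }
  if (length(cur) > 1L) chains[[length(chains) + 1L]] <- cur
  list(closed = FALSE, chains = chains)
}

#' Assemble the two watertight bodies (thrombus and aortic wall)
#'
#' Combines the surface fragments into one shared vertex space and closes the
#' two solids: the ILT body from the luminal ILT surface, the ILT-covered
#' inner wall and a ring stitch between their boundary loops; the wall body
#' from the fragmented inner wall (covered + free re-joined by open-chain
#' stitches across the erased strips), the offset outer wall, and closed end
#' stitches between the inner and outer end rings. Both bodies reference the
#' same vertex array, so the interface facets (the ILT-covered inner-wall
#' triangles) appear in both with identical vertex indices.
#'
#' @param luminal_ilt,wall_ilt_covered,wall_ilt_free fragments from
#'   [fragment_surfaces()] (`NULL` luminal/covered parts for a thrombus-free
#'   tube).
#' @param outer_wall the [offset_surface()] result (same lattice as the
#'   inner wall).
#' @param stitches optional precomputed stitch list (recomputed when `NULL`).
#' @param min_ilt_thickness minimum corner thickness (mm) for a lattice cell
#'   to be meshed as solid thrombus; defaults to half the thickness-analysis
#'   tolerance recorded on the fragments. Sub-resolution films thinner than
#'   this are treated as coincidence, as in the segmentation workflow.
#' @return List with `ilt_body`, `wall_body` ([tri_surface()]s over a common
#'   vertex array, oriented outward), `interface_facets` (triangle matrix),
#'   `stitches`, and the generalized-cylinder lattice attached to both bodies
#'   for downstream meshing.
#' @export
assemble_closed_bodies <- function(luminal_ilt, wall_ilt_covered,
                                   wall_ilt_free, outer_wall,
                                   stitches = NULL,
                                   min_ilt_thickness = NULL) {
  if (is.null(min_ilt_thickness)) {
    tol <- attr(luminal_ilt, "distance_tol")
    min_ilt_thickness <- if (is.null(tol)) 0.1 else 0.5 * tol
  }
  has_ilt <- !is.null(luminal_ilt) && nrow(luminal_ilt$triangles) > 0L
  grid <- attr(wall_ilt_free, "grid")
  if (is.null(grid)) grid <- attr(outer_wall, "grid")
  if (is.null(grid)) stop("fragments carry no lattice grid information")
  Vw <- wall_ilt_free$vertices
  Vo <- outer_wall$vertices
  nW <- nrow(Vw)
  nO <- nrow(Vo)
  Vl <- if (has_ilt) luminal_ilt$vertices else NULL
  V <- rbind(Vw, Vo, if (has_ilt) Vl)
  off_o <- nW
  off_l <- nW + nO

  bands <- list()
  # --- strip stitches re-joining covered and free inner wall parts ----------
  inner_tris <- rbind(if (has_ilt) wall_ilt_covered$triangles,
                      wall_ilt_free$triangles)
  if (has_ilt && nrow(wall_ilt_covered$triangles) > 0L) {
    loops_cov <- surface_boundary_loops(wall_ilt_covered)
    loops_fre <- surface_boundary_loops(wall_ilt_free)
    ch_cov <- unlist(lapply(loops_cov, function(l) {
      split_loop_chains(l, grid)$chains
    }), recursive = FALSE)
    ch_fre <- unlist(lapply(loops_fre, function(l) {
      split_loop_chains(l, grid)$chains
    }), recursive = FALSE)
    # free chains on the outer wall boundary rings are not strip sides; keep
    # only free chains that face a covered chain (nearest centroid pairing)
    cen <- function(ids) colMeans(Vw[ids, , drop = FALSE])
    for (cc in ch_cov) {
      dists <- vapply(ch_fre, function(cf) sum((cen(cc) - cen(cf))^2),
                      numeric(1))
      cf <- ch_fre[[which.min(dists)]]
      band <- stitch_loops(Vw[cc, , drop = FALSE], Vw[cf, , drop = FALSE],
                           closed = FALSE)
      tri <- remap_band(band, cc, cf)
      bands[[length(bands) + 1L]] <- list(kind = "strip", triangles = tri)
      inner_tris <- rbind(inner_tris, tri)
    }
  }

  # --- end stitches: assembled inner wall rings to outer wall rings ---------
  inner_surface <- tri_surface(V, inner_tris)
  in_loops <- surface_boundary_loops(inner_surface)
  out_loops <- lapply(surface_boundary_loops(outer_wall),
                      function(l) l + off_o)
  if (length(in_loops) != length(out_loops)) {
    stop(sprintf(
      "topology error: inner wall has %d boundary loops, outer wall %d",
      length(in_loops), length(out_loops)))
  }
  wall_tris <- rbind(inner_tris, outer_wall$triangles + off_o)
  for (il in in_loops) {
    zi <- mean(V[il, 3])
    zo <- vapply(out_loops, function(l) mean(V[l, 3]), numeric(1))
    ol <- out_loops[[which.min(abs(zo - zi))]]
    band <- stitch_loops(V[il, , drop = FALSE], V[ol, , drop = FALSE],
                         closed = TRUE)
    tri <- remap_band(band, il, ol)
    bands[[length(bands) + 1L]] <- list(kind = "end_ring", triangles = tri)
    wall_tris <- rbind(wall_tris, tri)
  }
  wall_body <- orient_surface(tri_surface(V, wall_tris))

  # --- ILT body: luminal surface + covered wall + one ring stitch -----------
  ilt_body <- NULL
  interface_facets <- matrix(integer(0), 0, 3)
  if (has_ilt) {
    lum_loops <- lapply(surface_boundary_loops(luminal_ilt),
                        function(l) l + off_l)
    cov_loops <- surface_boundary_loops(wall_ilt_covered)
    if (length(lum_loops) != length(cov_loops)) {
      stop(sprintf(
        "topology error: luminal ILT has %d loops, covered wall %d",
        length(lum_loops), length(cov_loops)))
    }
    ilt_tris <- rbind(luminal_ilt$triangles + off_l,
                      wall_ilt_covered$triangles)
    for (ll in lum_loops) {
      ci <- colMeans(V[ll, , drop = FALSE])
      dd <- vapply(cov_loops, function(l) {
        sum((ci - colMeans(Vw[l, , drop = FALSE]))^2)
      }, numeric(1))
      cl <- cov_loops[[which.min(dd)]]
      band <- stitch_loops(V[ll, , drop = FALSE], Vw[cl, , drop = FALSE],
                           closed = TRUE)
      tri <- remap_band(band, ll, cl)
      bands[[length(bands) + 1L]] <- list(kind = "ilt_ring", triangles = tri)
      ilt_tris <- rbind(ilt_tris, tri)
    }
    ilt_body <- orient_surface(tri_surface(V, ilt_tris))
    interface_facets <- wall_ilt_covered$triangles
  }

  for (nm in c("wall_body", "ilt_body")) {
    b <- get(nm)
    if (is.null(b)) next
    d <- surface_diagnostics(b, check_self_intersections = FALSE)
    if (d$boundary_edge_count > 0L) {
      stop(sprintf("topology error: %s has %d boundary edges in %d loops",
                   nm, d$boundary_edge_count,
                   length(surface_boundary_loops(b))))
    }
  }

  used_inner <- unique(as.vector(rbind(
    if (has_ilt) wall_ilt_covered$triangles, wall_ilt_free$triangles)))
  lat <- build_gc_lattice(grid, Vw, Vo, Vl, luminal_ilt, used_inner,
                          min_ilt_thickness)
  attr(wall_body, "gc_lattice") <- lat
  if (!is.null(ilt_body)) attr(ilt_body, "gc_lattice") <- lat
  list(ilt_body = ilt_body, wall_body = wall_body,
       interface_facets = interface_facets, stitches = bands)
}

# lattice provenance for the structured mesher: vertex grids of the inner
# wall (W), outer wall (O) and lumen (L), plus the per-cell thrombus mask.
# Inner-wall vertices interior to the erased strips (referenced by no kept
# inner-wall triangle) are flattened onto the chord between the bounding
# stitch chains, so the structured mesh matches the stitched body geometry.
build_gc_lattice <- function(grid, Vw, Vo, Vl, luminal_ilt,
                             used_inner = NULL, min_ilt_thickness = 0.1) {
  ni <- grid$ni
  nj <- grid$nj
  if (!is.null(used_inner) && length(used_inner) < ni * nj) {
    unused <- setdiff(seq_len(ni * nj), used_inner)
    for (v in unused) {
      i <- (v - 1L) %/% nj + 1L
      j <- (v - 1L) %% nj + 1L
      row_ids <- (i - 1L) * nj + seq_len(nj)
      row_used <- row_ids %in% used_inner
      if (!any(row_used)) next
      dl <- dr <- NA_integer_
      for (s in seq_len(nj)) {  # nearest used column left/right (wrapped)
        jl <- ((j - 1L - s) %% nj) + 1L
        if (is.na(dl) && row_used[jl]) dl <- s
        jr <- ((j - 1L + s) %% nj) + 1L
        if (is.na(dr) && row_used[jr]) dr <- s
        if (!is.na(dl) && !is.na(dr)) break
      }
      jl <- ((j - 1L - dl) %% nj) + 1L
      jr <- ((j - 1L + dr) %% nj) + 1L
      wgt <- dl / (dl + dr)
      Vw[v, ] <- (1 - wgt) * Vw[row_ids[jl], ] + wgt * Vw[row_ids[jr], ]
    }
  }
  mask <- matrix(FALSE, ni - 1L, nj)
  if (!is.null(Vl) && !is.null(luminal_ilt)) {
    rows <- attr(luminal_ilt, "tri_rows")
    present <- rep(FALSE, 2L * (ni - 1L) * nj)
    present[rows] <- TRUE
    vid <- function(i, j) (i - 1L) * nj + ((j - 1L) %% nj) + 1L
    for (i in seq_len(ni - 1L)) {
      for (j in seq_len(nj)) {
        tr <- lattice_cell_tris(grid, i, j)
        if (present[tr[1]] && present[tr[2]]) {
          corners <- c(vid(i, j), vid(i, j + 1L), vid(i + 1L, j),
                       vid(i + 1L, j + 1L))
          # signed thickness along the outward (wall-to-outer) direction:
          # strip flattening can pull W inside L on coarse lattices, which
          # must not become an (inverted) thrombus prism
          d_out <- Vo[corners, , drop = FALSE] - Vw[corners, , drop = FALSE]
          d_out <- d_out / sqrt(rowSums(d_out^2))
          tau <- rowSums((Vw[corners, , drop = FALSE] -
                            Vl[corners, , drop = FALSE]) * d_out)
          mask[i, j] <- all(tau > min_ilt_thickness)
        }
      }
    }
  }
  list(ni = ni, nj = nj, W = Vw, O = Vo, L = Vl, ilt_cell = mask)
}
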