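#' 4-node tetrahedral mesh with body and boundary-face labels
#'
#' @param nodes numeric matrix of node coordinates (mm).
#' @param tets integer matrix (1-based node quadruples, positive orientation).
#' @param body character vector per tet, `"WALL"` or `"ILT"`.
#' @param face_sets named list of boundary-face triangle matrices
#'   (`LUMINAL`, `OUTER`, `PROXIMAL_RING`, `DISTAL_RING`, `INTERFACE`, ...).
#' @param contact_pairs optional matrix of duplicated interface node pairs
#'   (penalty tied-contact mode) with tributary areas in `pair_area`.
#' @param pair_area numeric vector, mm^2 per contact pair.
#' @return An object of class `tet_mesh`.
#' @export
tet_mesh <- function(nodes, tets, body, face_sets = list(),
                     contact_pairs = NULL, pair_area = NULL) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  tets <- as.matrix(tets)
  storage.mode(tets) <- "integer"
  if (ncol(tets) != 4L) stop("`tets` must have 4 columns")
  if (length(body) != nrow(tets)) stop("`body` must label every tet")
  v <- tet_volumes_raw(nodes, tets)
  if (any(v <= 0)) {
    stop(sprintf("%d tetrahedra have non-positive volume", sum(v <= 0)))
  }
  structure(list(nodes = nodes, tets = tets, body = body,
                 face_sets = face_sets, contact_pairs = contact_pairs,
                 pair_area = pair_area),
            class = "tet_mesh")
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat(sprintf("<tet_mesh> %d nodes, %d tets (%s)\n  face sets: %s\n",
              nrow(x$nodes), nrow(x$tets),
              paste(sprintf("%s: %d", names(table(x$body)), table(x$body)),
                    collapse = ", "),
              paste(sprintf("%s[%d]", names(x$face_sets),
                            vapply(x$face_sets, nrow, 1L)), collapse = " ")))
  invisible(x)
}

tet_volumes_raw <- function(nodes, tets) {
  a <- nodes[tets[, 2], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  b <- nodes[tets[, 3], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  d <- nodes[tets[, 4], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  rowSums(cross_rows(a, b) * d) / 6
}

#' Per-element volumes (mm^3)
#' @param mesh a [tet_mesh()].
#' @return Numeric vector.
#' @export
tet_volumes <- function(mesh) tet_volumes_raw(mesh$nodes, mesh$tets)

face_key <- function(tri) {
  s <- t(apply(tri, 1, sort))
  paste(s[, 1], s[, 2], s[, 3], sep = "_")
}

#' Outward-oriented boundary faces of (a subset of) a tet mesh
#' @param mesh a [tet_mesh()].
#' @param subset optional logical/integer tet subset (e.g. one body).
#' @return Integer triangle matrix, wound outward.
#' @export
boundary_faces <- function(mesh, subset = NULL) {
  tets <- mesh$tets
  if (!is.null(subset)) tets <- tets[subset, , drop = FALSE]
  f <- rbind(tets[, c(1, 3, 2)], tets[, c(1, 2, 4)],
             tets[, c(1, 4, 3)], tets[, c(2, 3, 4)])
  key <- face_key(f)
  cnt <- table(key)
  f[key %in% names(cnt)[cnt == 1L], , drop = FALSE]
}

# Kuhn (Freudenthal) subdivision pattern of the unit box, parity-corrected so
# all six tets are positively oriented in a right-handed (x, y, z) cell.
kuhn_pattern <- function() {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  parity <- c(1, -1, -1, 1, 1, -1)
  out <- matrix(0L, 6, 4)
  code <- function(v) v[1] + 2L * v[2] + 4L * v[3]
  for (k in 1:6) {
    p <- perms[[k]]
    v1 <- c(0L, 0L, 0L)
    v2 <- v1; v2[p[1]] <- 1L
    v3 <- v2; v3[p[2]] <- 1L
    v4 <- c(1L, 1L, 1L)
    tet <- c(code(v1), code(v2), code(v3), code(v4))
    if (parity[k] < 0) tet <- tet[c(1, 2, 4, 3)]
    out[k, ] <- tet
  }
  out
}

# refine a generalized-cylinder lattice by integer factor s, piecewise-linear
# on the triangulated quads so refined surfaces stay exactly on the input
refine_lattice <- function(lat, s) {
  if (s <= 1L) return(lat)
  ni <- lat$ni; nj <- lat$nj
  ni2 <- s * (ni - 1L) + 1L
  nj2 <- s * nj
  vid <- function(i, j, nj_) (i - 1L) * nj_ + ((j - 1L) %% nj_) + 1L
  interp <- function(A) {
    out <- matrix(0, ni2 * nj2, 3)
    for (i2 in seq_len(ni2)) {
      ci <- min((i2 - 1L) %/% s + 1L, ni - 1L)
      u <- (i2 - 1L) / s - (ci - 1L)
      for (j2 in seq_len(nj2)) {
        cj <- (j2 - 1L) %/% s + 1L
        v <- (j2 - 1L) / s - (cj - 1L)
        c00 <- A[vid(ci, cj, nj), ]
        c10 <- A[vid(ci + 1L, cj, nj), ]
        c01 <- A[vid(ci, cj + 1L, nj), ]
        c11 <- A[vid(ci + 1L, cj + 1L, nj), ]
        out[vid(i2, j2, nj2), ] <- if (v <= u) {
          c00 * (1 - u) + c10 * (u - v) + c11 * v
        } else {
          c00 * (1 - v) + c01 * (v - u) + c11 * u
        }
      }
    }
    out
  }
  mask2 <- matrix(FALSE, ni2 - 1L, nj2)
  for (i2 in seq_len(ni2 - 1L)) {
    for (j2 in seq_len(nj2)) {
      mask2[i2, j2] <- lat$ilt_cell[(i2 - 1L) %/% s + 1L, (j2 - 1L) %/% s + 1L]
    }
  }
  list(ni = ni2, nj = nj2, W = interp(lat$W), O = interp(lat$O),
       L = if (!is.null(lat$L)) interp(lat$L), ilt_cell = mask2)
}

#' Conforming tetrahedral meshing of the assembled bodies
#'
#' Meshes the thrombus and wall solids with 4-node tetrahedra on the
#' generalized-cylinder lattice the bodies carry from
#' [assemble_closed_bodies()]: each (theta, z) cell is extruded radially
#' (lumen-to-wall layers for the ILT, wall-to-outer layers for the wall) and
#' split by the Kuhn 6-tet pattern, which tiles conformingly across cells.
#' In the default merged mode the interface faces are shared verbatim (same
#' node indices) by a WALL and an ILT tetrahedron; in penalty mode the
#' interface nodes are duplicated and returned as contact pairs with
#' tributary areas. Bodies without lattice provenance (arbitrary external
#' STL) are rejected: the mesher is structured, not a constrained-Delaunay
#' code.
#'
#' @param ilt_body,wall_body bodies from [assemble_closed_bodies()]
#'   (`ilt_body` may be `NULL` for a thrombus-free tube).
#' @param interface_facets ignored in structured mode (the interface is
#'   recovered from the lattice mask); kept for interface compatibility.
#' @param max_element_volume optional target tet volume (mm^3); the lattice
#'   is subdivided by the smallest integer factor that reaches it.
#' @param quality_bound optional radius-edge ratio bound; exceeding elements
#'   trigger a warning (the structured mesher does not refine for quality).
#' @param nr_wall,nr_ilt radial element layers through the wall and thrombus.
#' @param interface_mode `"merged"` (shared nodes) or `"penalty"`
#'   (duplicated interface nodes + spring pairs).
#' @return A [tet_mesh()] with `LUMINAL`, `OUTER`, `PROXIMAL_RING`,
#'   `DISTAL_RING` and `INTERFACE` face sets.
#' @export
tetrahedralize <- function(ilt_body = NULL, wall_body = NULL,
                           interface_facets = NULL,
                           max_element_volume = NULL, quality_bound = NULL,
                           nr_wall = 1L, nr_ilt = 2L,
                           interface_mode = c("merged", "penalty")) {
  interface_mode <- match.arg(interface_mode)
  lat <- attr(wall_body, "gc_lattice")
  if (is.null(lat)) lat <- attr(ilt_body, "gc_lattice")
  if (is.null(lat)) {
    stop("meshing error: bodies carry no generalized-cylinder lattice; ",
         "only bodies assembled by this pipeline can be meshed")
  }
  has_ilt <- any(lat$ilt_cell)

  if (!is.null(max_element_volume)) {
    # median baseline tet volume from the wall layer
    vq <- quad_areas(lat) * wall_mean_thickness(lat) / (6 * nr_wall)
    s <- max(1L, ceiling((stats::median(vq) / max_element_volume)^(1 / 3)))
    lat <- refine_lattice(lat, s)
  }

  ni <- lat$ni; nj <- lat$nj
  vid <- function(i, j) (i - 1L) * nj + ((j - 1L) %% nj) + 1L
  nvert <- ni * nj
  n_wall_nodes <- (nr_wall + 1L) * nvert
  w_id <- function(i, j, k) k * nvert + vid(i, j)

  # wall node block
  frac <- seq(0, 1, length.out = nr_wall + 1L)
  nodes <- matrix(0, n_wall_nodes, 3)
  for (k in 0:nr_wall) {
    nodes[k * nvert + seq_len(nvert), ] <-
      lat$W + frac[k + 1L] * (lat$O - lat$W)
  }

  # thrombus node block (layers 0..nr_ilt-1 measured from the lumen)
  mask <- lat$ilt_cell
  cellm <- function(ci, cj) mask[ci, ((cj - 1L) %% nj) + 1L]
  ilt_id <- NULL
  if (has_ilt) {
    vert_incident <- matrix(FALSE, ni, nj)
    for (ci in seq_len(ni - 1L)) {
      for (cj in seq_len(nj)) {
        if (mask[ci, cj]) {
          jj <- c(cj, (cj %% nj) + 1L)
          vert_incident[ci, jj] <- TRUE
          vert_incident[ci + 1L, jj] <- TRUE
        }
      }
    }
    inc <- which(t(vert_incident))  # vid order
    ilt_id <- matrix(0L, nvert, nr_ilt)
    extra <- matrix(0, length(inc) * nr_ilt, 3)
    nn <- 0L
    for (l in 0:(nr_ilt - 1L)) {
      fl <- l / nr_ilt
      for (vv in inc) {
        nn <- nn + 1L
        ilt_id[vv, l + 1L] <- n_wall_nodes + nn
        extra[nn, ] <- lat$L[vv, ] + fl * (lat$W[vv, ] - lat$L[vv, ])
      }
    }
    nodes <- rbind(nodes, extra[seq_len(nn), , drop = FALSE])
  }

  # penalty mode: duplicate the wall-side interface nodes for the ILT body
  dup_id <- NULL
  if (has_ilt && interface_mode == "penalty") {
    inc <- which(ilt_id[, 1] > 0L)
    dup_id <- integer(nvert)
    dup_id[inc] <- nrow(nodes) + seq_along(inc)
    nodes <- rbind(nodes, lat$W[inc, , drop = FALSE])
  }
  ilt_top <- function(i, j) {
    if (!is.null(dup_id)) dup_id[vid(i, j)] else w_id(i, j, 0L)
  }

  kuhn <- kuhn_pattern()
  tets <- list()
  body <- list()
  lab_tri <- list()
  lab_name <- list()
  add_quad <- function(n00, n10, n11, n01, label) {
    # both diagonals recorded; the boundary census picks the realized one
    lab_tri[[length(lab_tri) + 1L]] <<- rbind(
      c(n00, n10, n11), c(n00, n11, n01), c(n00, n10, n01), c(n10, n11, n01))
    lab_name[[length(lab_name) + 1L]] <<- rep(label, 4L)
  }
  emit_hex <- function(nid, tag) {
    # nid: function(x, y, z) -> node id, right-handed local axes
    corners <- integer(8)
    for (z in 0:1) for (y in 0:1) for (x in 0:1) {
      corners[1L + x + 2L * y + 4L * z] <- nid(x, y, z)
    }
    tets[[length(tets) + 1L]] <<- matrix(corners[kuhn + 1L], 6, 4)
    body[[length(body) + 1L]] <<- rep(tag, 6L)
  }

  for (ci in seq_len(ni - 1L)) {
    for (cj in seq_len(nj)) {
      # wall stack: local x = circumferential, y = axial, z = radial outward
      for (k in 0:(nr_wall - 1L)) {
        emit_hex(function(x, y, z) w_id(ci + y, cj + x, k + z), "WALL")
        if (k == 0L) {
          add_quad(w_id(ci, cj, 0L), w_id(ci, cj + 1L, 0L),
                   w_id(ci + 1L, cj + 1L, 0L), w_id(ci + 1L, cj, 0L),
                   if (cellm(ci, cj)) "INTERFACE" else "LUMINAL")
        }
        if (k == nr_wall - 1L) {
          add_quad(w_id(ci, cj, nr_wall), w_id(ci, cj + 1L, nr_wall),
                   w_id(ci + 1L, cj + 1L, nr_wall), w_id(ci + 1L, cj, nr_wall),
                   "OUTER")
        }
        if (ci == 1L) {
          add_quad(w_id(1L, cj, k), w_id(1L, cj + 1L, k),
                   w_id(1L, cj + 1L, k + 1L), w_id(1L, cj, k + 1L),
                   "DISTAL_RING")
        }
        if (ci == ni - 1L) {
          add_quad(w_id(ni, cj, k), w_id(ni, cj + 1L, k),
                   w_id(ni, cj + 1L, k + 1L), w_id(ni, cj, k + 1L),
                   "PROXIMAL_RING")
        }
      }
      if (!has_ilt || !mask[ci, cj]) next
      # thrombus stack: z runs lumen -> wall
      iid <- function(i, j, layer) {
        if (layer < nr_ilt) ilt_id[vid(i, j), layer + 1L] else ilt_top(i, j)
      }
      for (l in 0:(nr_ilt - 1L)) {
        emit_hex(function(x, y, z) iid(ci + y, cj + x, l + z), "ILT")
        if (l == 0L) {
          add_quad(iid(ci, cj, 0L), iid(ci, cj + 1L, 0L),
                   iid(ci + 1L, cj + 1L, 0L), iid(ci + 1L, cj, 0L), "LUMINAL")
        }
        if (l == nr_ilt - 1L && !is.null(dup_id)) {
          # ILT side of the duplicated interface (penalty mode)
          add_quad(iid(ci, cj, nr_ilt), iid(ci, cj + 1L, nr_ilt),
                   iid(ci + 1L, cj + 1L, nr_ilt), iid(ci + 1L, cj, nr_ilt),
                   "INTERFACE")
        }
        side <- function(i1, j1, i2, j2, label) {
          add_quad(iid(i1, j1, l), iid(i2, j2, l),
                   iid(i2, j2, l + 1L), iid(i1, j1, l + 1L), label)
        }
        if (!cellm(ci, cj - 1L)) side(ci, cj, ci + 1L, cj, "LUMINAL")
        if (!cellm(ci, cj + 1L)) side(ci, cj + 1L, ci + 1L, cj + 1L, "LUMINAL")
        if (ci == 1L) {
          side(1L, cj, 1L, cj + 1L, "DISTAL_RING")
        } else if (!mask[ci - 1L, cj]) {
          side(ci, cj, ci, cj + 1L, "LUMINAL")
        }
        if (ci == ni - 1L) {
          side(ni, cj, ni, cj + 1L, "PROXIMAL_RING")
        } else if (!mask[ci + 1L, cj]) {
          side(ci + 1L, cj, ci + 1L, cj + 1L, "LUMINAL")
        }
      }
    }
  }
  tets <- do.call(rbind, tets)
  body <- unlist(body)

  # label dictionary and per-body boundary censuses
  dict_tri <- do.call(rbind, lab_tri)
  dict_lab <- unlist(lab_name)
  dict <- stats::setNames(dict_lab, face_key(dict_tri))
  mesh0 <- list(nodes = nodes, tets = tets)
  bf_wall <- boundary_faces(structure(mesh0, class = "tet_mesh"),
                            subset = body == "WALL")
  bf_ilt <- if (has_ilt) {
    boundary_faces(structure(mesh0, class = "tet_mesh"),
                   subset = body == "ILT")
  } else matrix(integer(0), 0, 3)
  lab_of <- function(bf) unname(dict[face_key(bf)])
  lw <- lab_of(bf_wall)
  li <- if (nrow(bf_ilt)) lab_of(bf_ilt) else character(0)
  if (anyNA(lw) || anyNA(li)) stop("meshing error: unlabeled boundary face")
  face_sets <- list(
    LUMINAL = rbind(bf_wall[lw == "LUMINAL", , drop = FALSE],
                    bf_ilt[li == "LUMINAL", , drop = FALSE]),
    OUTER = bf_wall[lw == "OUTER", , drop = FALSE],
    PROXIMAL_RING = rbind(bf_wall[lw == "PROXIMAL_RING", , drop = FALSE],
                          bf_ilt[li == "PROXIMAL_RING", , drop = FALSE]),
    DISTAL_RING = rbind(bf_wall[lw == "DISTAL_RING", , drop = FALSE],
                        bf_ilt[li == "DISTAL_RING", , drop = FALSE]),
    INTERFACE = bf_wall[lw == "INTERFACE", , drop = FALSE]
  )

  contact_pairs <- NULL
  pair_area <- NULL
  if (!is.null(dup_id)) {
    inc <- which(dup_id > 0L)
    contact_pairs <- cbind(inc, dup_id[inc])  # wall node, ILT duplicate
    # tributary area: 1/3 of adjacent interface faces
    itri <- face_sets$INTERFACE
    g <- triangle_geometry(tri_surface(nodes, itri))
    acc <- numeric(nrow(nodes))
    for (k in 1:3) {
      acc <- acc + tapply_sum(g$area / 3, itri[, k], nrow(nodes))
    }
    # interface faces reference wall-side ids; duplicates get the same area
    pair_area <- acc[inc]
  }

  m <- tet_mesh(nodes, tets, body, face_sets, contact_pairs, pair_area)
  if (!is.null(quality_bound)) {
    q <- mesh_quality(m)
    if (q$max_radius_edge > quality_bound) {
      warning(sprintf(
        "max radius-edge ratio %.2f exceeds quality bound %.2f",
        q$max_radius_edge, quality_bound))
    }
  }
  m
}

quad_areas <- function(lat) {
  ni <- lat$ni; nj <- lat$nj
  vid <- function(i, j) (i - 1L) * nj + ((j - 1L) %% nj) + 1L
  i <- rep(seq_len(ni - 1L), each = nj)
  j <- rep(seq_len(nj), ni - 1L)
  a <- lat$W[vid(i, j), , drop = FALSE]
  b <- lat$W[vid(i, j + 1L), , drop = FALSE]
  d <- lat$W[vid(i + 1L, j), , drop = FALSE]
  e <- lat$W[vid(i + 1L, j + 1L), , drop = FALSE]
  0.5 * sqrt(rowSums(cross_rows(b - a, d - a)^2)) +
    0.5 * sqrt(rowSums(cross_rows(b - e, d - e)^2))
}

wall_mean_thickness <- function(lat) {
  mean(sqrt(rowSums((lat$O - lat$W)^2)))
}

#' Mesh quality metrics
#'
#' Minimum dihedral angle (degrees), maximum circumradius-to-shortest-edge
#' ratio, and the count of inverted (non-positive volume) elements; the
#' latter must be zero for solver admission.
#'
#' @param mesh a [tet_mesh()] (or a list with `nodes` and `tets`).
#' @return A list: `min_dihedral_deg`, `max_radius_edge`, `inverted_count`.
#' @export
mesh_quality <- function(mesh) {
  nd <- mesh$nodes
  tt <- mesh$tets
  p <- lapply(1:4, function(k) nd[tt[, k], , drop = FALSE])
  vol <- tet_volumes_raw(nd, tt)
  # outward-ish face normals (consistent for positive tets)
  n1 <- cross_rows(p[[3]] - p[[2]], p[[4]] - p[[2]])  # face (2,3,4)
  n2 <- cross_rows(p[[4]] - p[[1]], p[[3]] - p[[1]])  # face (1,4,3)
  n3 <- cross_rows(p[[2]] - p[[1]], p[[4]] - p[[1]])  # face (1,2,4)
  n4 <- cross_rows(p[[3]] - p[[1]], p[[2]] - p[[1]])  # face (1,3,2)
  ns <- list(n1, n2, n3, n4)
  pairs <- utils::combn(4, 2)
  min_dih <- Inf
  for (k in seq_len(ncol(pairs))) {
    a <- ns[[pairs[1, k]]]
    b <- ns[[pairs[2, k]]]
    cosang <- -rowSums(a * b) /
      pmax(sqrt(rowSums(a^2)) * sqrt(rowSums(b^2)), .Machine$double.xmin)
    min_dih <- min(min_dih, acos(pmin(1, pmax(-1, cosang))) * 180 / pi)
  }
  # circumradius / shortest edge
  a <- p[[2]] - p[[1]]; b <- p[[3]] - p[[1]]; cc <- p[[4]] - p[[1]]
  bxc <- cross_rows(b, cc); cxa <- cross_rows(cc, a); axb <- cross_rows(a, b)
  denom <- 2 * rowSums(a * bxc)
  O <- (rowSums(a^2) * bxc + rowSums(b^2) * cxa + rowSums(cc^2) * axb) /
    ifelse(abs(denom) < .Machine$double.xmin, NA, denom)
  R <- sqrt(rowSums(O^2))
  emin <- pmin(
    sqrt(rowSums(a^2)), sqrt(rowSums(b^2)), sqrt(rowSums(cc^2)),
    sqrt(rowSums((p[[3]] - p[[2]])^2)), sqrt(rowSums((p[[4]] - p[[2]])^2)),
    sqrt(rowSums((p[[4]] - p[[3]])^2)))
  list(min_dihedral_deg = min_dih,
       max_radius_edge = max(R / emin, na.rm = TRUE),
       inverted_count = sum(vol <= 0))
}
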