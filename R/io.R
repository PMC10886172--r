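#' Write a triangle surface to ASCII STL
#'
#' STL carries no attributes, so region labels are persisted separately with
#' [write_surface_labels()].
#'
#' @param surface a [tri_surface()].
#' @param path output file.
#' @param name solid name in the file header.
#' @return `path`, invisibly.
#' @export
write_stl <- function(surface, path, name = "surface") {
  g <- triangle_geometry(surface)
  co <- tri_corners(surface)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("solid %s", name), con)
  nt <- nrow(surface$triangles)
  fmt <- function(m) sprintf("%.17g %.17g %.17g", m[, 1], m[, 2], m[, 3])
  lines <- character(7 * nt)
  lines[seq(1, 7 * nt, 7)] <- sprintf("  facet normal %s", fmt(g$normal))
  lines[seq(2, 7 * nt, 7)] <- "    outer loop"
  lines[seq(3, 7 * nt, 7)] <- sprintf("      vertex %s", fmt(co$a))
  lines[seq(4, 7 * nt, 7)] <- sprintf("      vertex %s", fmt(co$b))
  lines[seq(5, 7 * nt, 7)] <- sprintf("      vertex %s", fmt(co$c))
  lines[seq(6, 7 * nt, 7)] <- "    endloop"
  lines[seq(7, 7 * nt, 7)] <- "  endfacet"
  writeLines(lines, con)
  writeLines(sprintf("endsolid %s", name), con)
  invisible(path)
}

#' Read an ASCII STL file
#'
#' Vertices listed with identical coordinates are merged into shared indices.
#'
#' @param path STL file.
#' @return A [tri_surface()].
#' @export
read_stl <- function(path) {
  lines <- readLines(path)
  vl <- grep("^\\s*vertex", lines, value = TRUE)
  xyz <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(p) {
    as.numeric(p[2:4])
  }))
  if (nrow(xyz) %% 3 != 0) stop("malformed STL: vertex count not divisible by 3")
  key <- paste(xyz[, 1], xyz[, 2], xyz[, 3])
  uk <- !duplicated(key)
  verts <- xyz[uk, , drop = FALSE]
  idx <- match(key, key[uk])
  tris <- matrix(idx, ncol = 3, byrow = TRUE)
  tri_surface(verts, tris)
}

#' Persist per-triangle region labels for an STL surface
#' @param labels character/integer vector, one per triangle.
#' @param path output TSV (columns `triangle`, `label`).
#' @return `path`, invisibly.
#' @export
write_surface_labels <- function(labels, path) {
  utils::write.table(
    data.frame(triangle = seq_along(labels), label = labels),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_surface_labels
#' @export
read_surface_labels <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)$label
}

#' Read / write a centerline as a plain-text 3-column point list
#' @param points matrix of 3D points (distal first).
#' @param path file path.
#' @return `path` (write) or the point matrix (read).
#' @export
write_centerline <- function(points, path) {
  if (inherits(points, "centerline")) points <- points$points
  utils::write.table(format(points, digits = 17), path,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_centerline
#' @export
read_centerline <- function(path) {
  as.matrix(utils::read.table(path, header = FALSE))
}

face_label_codes <- c(LUMINAL = 1L, OUTER = 2L, PROXIMAL_RING = 3L,
                      DISTAL_RING = 4L, INTERFACE = 5L)

#' Write a tetrahedral mesh (plus fields) as legacy ASCII VTK
#'
#' The unstructured grid holds the tetrahedra followed by the labeled
#' boundary triangles; integer cell-data arrays `body` (1 = WALL, 2 = ILT,
#' 0 for faces) and `face_label` (codes LUMINAL = 1, OUTER = 2,
#' PROXIMAL_RING = 3, DISTAL_RING = 4, INTERFACE = 5; 0 for tets) carry the
#' labels. Additional per-tet scalar/vector cell data and per-node point
#' data are padded with zeros on face cells.
#'
#' @param mesh a [tet_mesh()].
#' @param path output `.vtk` file.
#' @param cell_data named list of per-tet vectors (scalars) or 3-column
#'   matrices (vectors).
#' @param point_data named list of per-node vectors or 3-column matrices.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(mesh, path, cell_data = list(), point_data = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(mesh$nodes)
  nt <- nrow(mesh$tets)
  faces <- do.call(rbind, mesh$face_sets)
  # face-set codes: the standard names keep their fixed codes, any other
  # sets get codes from 11 up; the name->code map lives in the title line
  codes <- face_label_codes[names(mesh$face_sets)]
  extra <- which(is.na(codes))
  codes[extra] <- 10L + seq_along(extra)
  names(codes) <- names(mesh$face_sets)
  flab <- rep(unname(codes), vapply(mesh$face_sets, nrow, 1L))
  nf <- if (is.null(faces)) 0L else nrow(faces)
  title <- paste0("aaamech mesh faces:",
                  paste(sprintf("%s=%d", names(codes), codes),
                        collapse = ","))
  writeLines(c("# vtk DataFile Version 3.0", title, "ASCII",
               "DATASET UNSTRUCTURED_GRID"), con)
  writeLines(sprintf("POINTS %d double", n), con)
  writeLines(sprintf("%.17g %.17g %.17g", mesh$nodes[, 1], mesh$nodes[, 2],
                     mesh$nodes[, 3]), con)
  writeLines(sprintf("CELLS %d %d", nt + nf, 5L * nt + 4L * nf), con)
  writeLines(sprintf("4 %d %d %d %d", mesh$tets[, 1] - 1L,
                     mesh$tets[, 2] - 1L, mesh$tets[, 3] - 1L,
                     mesh$tets[, 4] - 1L), con)
  if (nf > 0L) {
    writeLines(sprintf("3 %d %d %d", faces[, 1] - 1L, faces[, 2] - 1L,
                       faces[, 3] - 1L), con)
  }
  writeLines(sprintf("CELL_TYPES %d", nt + nf), con)
  writeLines(as.character(c(rep(10L, nt), rep(5L, nf))), con)
  writeLines(sprintf("CELL_DATA %d", nt + nf), con)
  writeLines(c("SCALARS body int 1", "LOOKUP_TABLE default"), con)
  body_code <- ifelse(mesh$body == "WALL", 1L, 2L)
  writeLines(as.character(c(body_code, rep(0L, nf))), con)
  writeLines(c("SCALARS face_label int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(c(rep(0L, nt), flab)), con)
  for (nm in names(cell_data)) {
    v <- cell_data[[nm]]
    if (is.matrix(v) && ncol(v) == 3L) {
      writeLines(sprintf("VECTORS %s double", nm), con)
      v <- rbind(v, matrix(0, nf, 3))
      writeLines(sprintf("%.17g %.17g %.17g", v[, 1], v[, 2], v[, 3]), con)
    } else {
      writeLines(c(sprintf("SCALARS %s double 1", nm),
                   "LOOKUP_TABLE default"), con)
      writeLines(sprintf("%.17g", c(as.numeric(v), rep(0, nf))), con)
    }
  }
  if (length(point_data)) {
    writeLines(sprintf("POINT_DATA %d", n), con)
    for (nm in names(point_data)) {
      v <- point_data[[nm]]
      if (is.matrix(v) && ncol(v) == 3L) {
        writeLines(sprintf("VECTORS %s double", nm), con)
        writeLines(sprintf("%.17g %.17g %.17g", v[, 1], v[, 2], v[, 3]), con)
      } else {
        writeLines(c(sprintf("SCALARS %s double 1", nm),
                     "LOOKUP_TABLE default"), con)
        writeLines(sprintf("%.17g", as.numeric(v)), con)
      }
    }
  }
  invisible(path)
}

#' Read a legacy ASCII VTK unstructured grid written by [write_vtk()]
#'
#' @param path `.vtk` file.
#' @return A list: `mesh` (a [tet_mesh()] with face sets recovered from the
#'   `face_label` array), `cell_data` and `point_data` named lists.
#' @export
read_vtk <- function(path) {
  lines <- readLines(path)
  num <- function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  i_pts <- grep("^POINTS", lines)
  n <- as.integer(strsplit(lines[i_pts], "\\s+")[[1]][2])
  pts <- matrix(as.numeric(unlist(strsplit(trimws(
    lines[(i_pts + 1):(i_pts + n)]), "\\s+"))), n, 3, byrow = TRUE)
  i_cells <- grep("^CELLS", lines)
  ncell <- as.integer(strsplit(lines[i_cells], "\\s+")[[1]][2])
  cell_rows <- lapply(lines[(i_cells + 1):(i_cells + ncell)], num)
  i_types <- grep("^CELL_TYPES", lines)
  types <- as.integer(lines[(i_types + 1):(i_types + ncell)])
  tets <- do.call(rbind, lapply(cell_rows[types == 10L],
                                function(r) r[2:5] + 1L))
  tris <- do.call(rbind, lapply(cell_rows[types == 5L],
                                function(r) r[2:4] + 1L))
  read_array <- function(start, count) {
    vals <- character(0)
    k <- start
    while (length(vals) < count && k <= length(lines)) {
      vals <- c(vals, strsplit(trimws(lines[k]), "\\s+")[[1]])
      k <- k + 1
    }
    as.numeric(vals[seq_len(count)])
  }
  parse_block <- function(i_hdr, count) {
    out <- list()
    k <- i_hdr + 1
    while (k <= length(lines)) {
      l <- lines[k]
      if (grepl("^SCALARS", l)) {
        nm <- strsplit(l, "\\s+")[[1]][2]
        out[[nm]] <- read_array(k + 2, count)
        k <- k + 2 + count
      } else if (grepl("^VECTORS", l)) {
        nm <- strsplit(l, "\\s+")[[1]][2]
        out[[nm]] <- matrix(read_array(k + 1, 3 * count), count, 3,
                            byrow = TRUE)
        k <- k + 1 + count
      } else if (grepl("^(CELL_DATA|POINT_DATA)", l)) {
        break
      } else {
        k <- k + 1
      }
    }
    out
  }
  i_cd <- grep("^CELL_DATA", lines)
  cd <- if (length(i_cd)) parse_block(i_cd[1], ncell) else list()
  i_pd <- grep("^POINT_DATA", lines)
  pd <- if (length(i_pd)) parse_block(i_pd[1], n) else list()

  nt <- sum(types == 10L)
  body <- ifelse(cd$body[seq_len(nt)] == 1, "WALL", "ILT")
  codes <- face_label_codes
  if (grepl("faces:", lines[2])) {
    map <- strsplit(sub(".*faces:", "", lines[2]), ",")[[1]]
    kv <- strsplit(map, "=")
    codes <- stats::setNames(vapply(kv, function(x) as.integer(x[2]), 1L),
                             vapply(kv, function(x) x[1], ""))
  }
  face_sets <- list()
  if (!is.null(tris) && !is.null(cd$face_label)) {
    fl <- cd$face_label[types == 5L]
    for (nm in names(codes)) {
      sel <- fl == codes[[nm]]
      if (any(sel)) face_sets[[nm]] <- tris[sel, , drop = FALSE]
    }
  }
  cd_tets <- lapply(cd[setdiff(names(cd), c("body", "face_label"))],
                    function(v) {
                      if (is.matrix(v)) v[seq_len(nt), , drop = FALSE]
                      else v[seq_len(nt)]
                    })
  list(mesh = tet_mesh(pts, tets, body, face_sets),
       cell_data = cd_tets, point_data = pd)
}

#' Export per-step solution fields to VTK files
#'
#' One unstructured-grid file per recorded state with the array schema
#' `sigma1`, `eq_strain`, `region` (cell data), `e1`/`e2`/`e3` frame vectors
#' when supplied, and the nodal `displacement` vector.
#'
#' @param mesh a [tet_mesh()].
#' @param states list of `solution_state`s (an `aaa_solution$states`).
#' @param path output directory (created if missing).
#' @param frames optional [assign_local_frames()] field.
#' @param labels optional region labels from [classify_wall_regions()].
#' @return Character vector of file paths.
#' @export
export_fields <- function(mesh, states, path, frames = NULL, labels = NULL) {
  if (inherits(states, "aaa_solution")) states <- states$states
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (is.null(labels)) labels <- classify_wall_regions(mesh)
  region_code <- c(WALL_ILT_FREE = 1L, WALL_ILT_COVERED = 2L, ILT = 3L)
  files <- character(length(states))
  for (k in seq_along(states)) {
    st <- states[[k]]
    cd <- list(sigma1 = field_sigma1(st$cauchy_stress),
               eq_strain = field_eq_strain(st$green_strain),
               region = as.numeric(region_code[labels]))
    if (!is.null(frames)) {
      cd$e1 <- frames$e1
      cd$e2 <- frames$e2
      cd$e3 <- frames$e3
    }
    files[k] <- file.path(path, sprintf("step_%03d.vtk", k))
    write_vtk(mesh, files[k], cell_data = cd,
              point_data = list(displacement = st$displacements))
  }
  files
}
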