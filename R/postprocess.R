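#' Principal stresses of a symmetric tensor
#'
#' @param sigma symmetric 3x3 stress tensor (MPa); asymmetry beyond 1e-8
#'   (relative) is a validation error.
#' @return Numeric vector `(sigma1, sigma2, sigma3)` sorted descending.
#' @export
principal_stresses <- function(sigma) {
  sigma <- as.matrix(sigma)
  scale <- max(abs(sigma), 1e-300)
  if (max(abs(sigma - t(sigma))) > 1e-8 * scale) {
    stop("stress tensor is not symmetric")
  }
  sort(eigen((sigma + t(sigma)) / 2, symmetric = TRUE,
             only.values = TRUE)$values, decreasing = TRUE)
}

#' Von Mises equivalent strain
#'
#' `eps_eq = sqrt(2/3 dev(eps) : dev(eps))`, evaluated on the (symmetric)
#' strain tensor; zero for purely hydrostatic strain.
#'
#' @param eps symmetric 3x3 strain tensor.
#' @return Scalar equivalent strain.
#' @export
equivalent_strain <- function(eps) {
  eps <- as.matrix(eps)
  dev <- eps - diag(3) * sum(diag(eps)) / 3
  sqrt(2 / 3 * sum(dev * dev))
}

# batched versions over per-element row-major 3x3 fields
field_sigma1 <- function(stress9) {
  vapply(seq_len(nrow(stress9)), function(e) {
    s <- matrix(stress9[e, ], 3, 3)
    max(eigen((s + t(s)) / 2, symmetric = TRUE, only.values = TRUE)$values)
  }, numeric(1))
}

field_eq_strain <- function(strain9) {
  tr <- (strain9[, 1] + strain9[, 5] + strain9[, 9]) / 3
  dev <- strain9
  dev[, c(1, 5, 9)] <- dev[, c(1, 5, 9)] - tr
  sqrt(2 / 3 * rowSums(dev^2))
}

#' Wall tensile-strength limit (plane Von Mises)
#'
#' `sqrt(sc^2 - sc * sa + sa^2)` from the circumferential and axial mean
#' strength limits. Symmetric in its arguments and homogeneous of degree 1.
#'
#' @param sigma_circ,sigma_axial strength limits, MPa.
#' @return Strength limit in MPa (unrounded).
#' @export
uts_wall <- function(sigma_circ, sigma_axial) {
  if (any(c(sigma_circ, sigma_axial) < 0)) stop("strength inputs must be >= 0")
  sqrt(sigma_circ^2 - sigma_circ * sigma_axial + sigma_axial^2)
}

#' Tissue strength limits
#'
#' The ultimate tensile strength thresholds used for post-hoc comparison:
#' thrombus 0.085 MPa; aneurysmal wall from the axial (0.0895 MPa) and
#' circumferential (0.0593 MPa) mean limits combined by [uts_wall()].
#'
#' @return A tibble with one row per limit (MPa).
#' @export
strength_limits <- function() {
  tibble::tibble(
    quantity = c("sigma_uts_ilt", "sigma_axial", "sigma_circ",
                 "sigma_uts_wall"),
    mpa = c(0.085, 0.0895, 0.0593, uts_wall(0.0593, 0.0895))
  )
}

#' Classify wall elements by thrombus coverage
#'
#' Wall elements whose inner-surface face lies on the interface are
#' `WALL_ILT_COVERED`; those with a luminal face are `WALL_ILT_FREE`;
#' interior wall elements inherit the label of the nearest labeled wall
#' element. Thrombus elements are labeled `ILT`.
#'
#' @param mesh a labeled [tet_mesh()].
#' @return Character vector, one region label per element.
#' @export
classify_wall_regions <- function(mesh) {
  if (is.null(mesh$face_sets$LUMINAL) && is.null(mesh$face_sets$INTERFACE)) {
    stop("mesh has no LUMINAL/INTERFACE face labels")
  }
  tt <- mesh$tets
  allf <- rbind(tt[, c(1, 3, 2)], tt[, c(1, 2, 4)],
                tt[, c(1, 4, 3)], tt[, c(2, 3, 4)])
  owner <- rep(seq_len(nrow(tt)), 4L)
  fk <- face_key(allf)
  lab <- rep(NA_character_, nrow(tt))
  wall <- mesh$body == "WALL"
  mark <- function(set_name, value) {
    fs <- mesh$face_sets[[set_name]]
    if (is.null(fs) || nrow(fs) == 0L) return()
    own <- owner[match(face_key(fs), fk)]
    own <- own[!is.na(own) & wall[own]]
    lab[own] <<- value
  }
  mark("LUMINAL", "WALL_ILT_FREE")
  mark("INTERFACE", "WALL_ILT_COVERED")
  lab[!wall] <- "ILT"
  rest <- which(is.na(lab))
  if (length(rest)) {
    seeded <- which(!is.na(lab) & wall)
    cen <- tet_centroids(mesh)
    nn <- cpp_nearest_index(cen[rest, , drop = FALSE],
                            cen[seeded, , drop = FALSE])
    lab[rest] <- lab[seeded[nn]]
  }
  lab
}

#' Regional stress/strain summary
#'
#' Element-volume-weighted average and maximum of the first principal Cauchy
#' stress and the Von Mises equivalent (Green-Lagrange) strain per region —
#' the ILT-covered versus ILT-free wall comparison that quantifies the
#' thrombus cushioning effect.
#'
#' @param state a converged `solution_state`.
#' @param labels region labels from [classify_wall_regions()].
#' @return A tibble with one row per region: `avg_sigma1`, `max_sigma1`,
#'   `avg_eq_strain`, `max_eq_strain`, `element_count`. Empty regions get NA
#'   statistics rather than an error.
#' @export
regional_summary <- function(state, labels) {
  s1 <- field_sigma1(state$cauchy_stress)
  eq <- field_eq_strain(state$green_strain)
  vol <- state$vol0
  regions <- c("WALL_ILT_FREE", "WALL_ILT_COVERED", "ILT")
  rows <- lapply(regions, function(r) {
    sel <- labels == r
    if (!any(sel)) {
      return(tibble::tibble(region = r, avg_sigma1 = NA_real_,
                            max_sigma1 = NA_real_, avg_eq_strain = NA_real_,
                            max_eq_strain = NA_real_, element_count = 0L))
    }
    w <- vol[sel] / sum(vol[sel])
    tibble::tibble(region = r,
                   avg_sigma1 = sum(w * s1[sel]),
                   max_sigma1 = max(s1[sel]),
                   avg_eq_strain = sum(w * eq[sel]),
                   max_eq_strain = max(eq[sel]),
                   element_count = sum(sel))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("regional_summary", class(out))
  out
}

#' Close the open ends of a tube surface with centroid fans
#'
#' Each boundary loop is capped by a triangle fan around its centroid, so the
#' enclosed volume of an open vessel segment is well defined.
#'
#' @param surface an open [tri_surface()].
#' @return A closed, consistently oriented surface.
#' @export
cap_ends <- function(surface) {
  loops <- surface_boundary_loops(surface)
  if (length(loops) == 0L) return(surface)
  V <- surface$vertices
  tris <- surface$triangles
  for (lp in loops) {
    cen <- colMeans(V[lp, , drop = FALSE])
    V <- rbind(V, cen)
    ci <- nrow(V)
    n <- length(lp)
    fan <- cbind(lp, c(lp[-1], lp[1]), ci)
    tris <- rbind(tris, fan)
  }
  orient_surface(tri_surface(V, tris))
}

#' Aneurysm and thrombus volume metrics
#'
#' `ilt_percent = 100 * ilt / aaa`; with a previous measurement the growth
#' percentages are reported as well. Inputs may be closed surfaces (volumes
#' computed by the divergence theorem, reported in mL) or volumes in mL.
#'
#' @param aaa either a closed [tri_surface()] of the inner wall (cap an open
#'   tube with [cap_ends()] first) or a volume in mL.
#' @param ilt the thrombus body surface or its volume in mL.
#' @param previous optional earlier [volume_metrics()] result.
#' @return A one-row tibble: `aaa_volume`, `ilt_volume` (mL), `ilt_percent`,
#'   and `aaa_growth_percent` / `ilt_growth_percent` when `previous` given.
#' @export
volume_metrics <- function(aaa, ilt, previous = NULL) {
  vol_of <- function(x, what) {
    if (is.numeric(x)) return(x)
    d <- surface_diagnostics(x, check_self_intersections = FALSE)
    if (!d$closed) {
      stop(sprintf("topology error: %s surface is not watertight", what))
    }
    d$enclosed_volume
  }
  va <- vol_of(aaa, "aneurysm")
  vi <- if (is.null(ilt)) 0 else vol_of(ilt, "thrombus")
  if (vi > va) stop("thrombus volume exceeds aneurysm volume")
  out <- tibble::tibble(
    aaa_volume = va, ilt_volume = vi,
    ilt_percent = if (va > 0) 100 * vi / va else 0
  )
  if (!is.null(previous)) {
    out$aaa_growth_percent <- 100 * (va - previous$aaa_volume) /
      previous$aaa_volume
    out$ilt_growth_percent <- 100 * (vi - previous$ilt_volume) /
      previous$ilt_volume
  }
  out
}

#' Mesh-sensitivity deviation table
#'
#' Absolute percent deviation of the maximum principal stress at each
#' resolution against a reference resolution (the three-level
#' coarse/fine/finer protocol).
#'
#' @param results numeric vector of maximum sigma1 values (MPa), one per
#'   resolution, coarse to finer; optionally named.
#' @param reference_index which entry is the reference (default: middle).
#' @param element_counts optional element counts per level.
#' @return A tibble with `level`, `elements`, `max_sigma1` and
#'   `deviation_percent` (NA at the reference).
#' @export
mesh_sensitivity_report <- function(results,
                                    reference_index = ceiling(length(results) / 2),
                                    element_counts = NULL) {
  if (length(results) < 2L) {
    stop("mesh sensitivity needs at least 2 resolutions")
  }
  ref <- results[reference_index]
  dev <- abs(results - ref) / ref * 100
  dev[reference_index] <- NA_real_
  tibble::tibble(
    level = if (!is.null(names(results))) names(results) else
      paste0("level", seq_along(results)),
    elements = if (is.null(element_counts)) NA_integer_ else
      as.integer(element_counts),
    max_sigma1 = as.numeric(results),
    deviation_percent = dev
  )
}
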