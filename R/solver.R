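#' Conversion factor: millimetres of mercury to MPa
#' @export
MMHG_TO_MPA <- 1.333224e-4

#' Boundary conditions for the quasi-static solve
#'
#' Fixes the proximal and distal end rings in all three degrees of freedom
#' (the tethering of the aneurysm to the arterial tree), selects the
#' pressurized face set, and optionally adds fine-grained prescribed
#' displacements (node, dof, value) for benchmark problems.
#'
#' @param mesh a [tet_mesh()].
#' @param fixed_sets names of face sets whose nodes are fully fixed
#'   (default the two end rings; use `character(0)` for none).
#' @param prescribed optional data frame with columns `node`, `dof` (1 = x,
#'   2 = y, 3 = z) and `value` (mm, ramped with the load factor).
#' @param pressure_faces face-set name (default `"LUMINAL"`) or a triangle
#'   matrix; must be boundary faces.
#' @return An object of class `aaa_bc`.
#' @export
boundary_conditions <- function(mesh,
                                fixed_sets = c("PROXIMAL_RING", "DISTAL_RING"),
                                prescribed = NULL,
                                pressure_faces = "LUMINAL") {
  fixed_nodes <- integer(0)
  for (s in fixed_sets) {
    fs <- mesh$face_sets[[s]]
    if (is.null(fs)) stop(sprintf("mesh has no face set `%s`", s))
    fixed_nodes <- c(fixed_nodes, unique(as.vector(fs)))
  }
  fixed_nodes <- sort(unique(fixed_nodes))
  if (length(fixed_sets) > 0L && length(fixed_nodes) == 0L) {
    stop("fixed node sets are empty")
  }
  pf <- if (is.character(pressure_faces)) {
    out <- mesh$face_sets[[pressure_faces]]
    if (is.null(out)) stop(sprintf("mesh has no face set `%s`", pressure_faces))
    out
  } else as.matrix(pressure_faces)
  if (nrow(pf) > 0L) {
    bf <- do.call(rbind, lapply(unique(mesh$body), function(b) {
      boundary_faces(mesh, subset = mesh$body == b)
    }))
    if (!all(face_key(pf) %in% face_key(bf))) {
      stop("pressure faces include non-boundary faces")
    }
  }
  fix <- data.frame(node = rep(fixed_nodes, each = 3L),
                    dof = rep(1:3, length(fixed_nodes)),
                    value = rep(0, 3L * length(fixed_nodes)))
  if (!is.null(prescribed)) {
    stopifnot(all(c("node", "dof", "value") %in% names(prescribed)))
    fix <- rbind(fix, prescribed[, c("node", "dof", "value")])
  }
  fix <- fix[!duplicated(fix[, c("node", "dof")]), , drop = FALSE]
  structure(list(fixed = fix, pressure_faces = pf), class = "aaa_bc")
}

#' Incremental intraluminal pressure program
#'
#' The load ramps from `start_pressure` to `target_pressure` (mmHg) in
#' `n_steps` equal increments; the start pressure itself is reached by an
#' automatic pre-ramp from zero in `ceiling(start / dp)` sub-steps of the
#' same increment, since the reconstruction is treated as stress-free.
#'
#' @param start_pressure mmHg (default 80).
#' @param target_pressure mmHg (default 120; 200 for the hypertensive case).
#' @param n_steps number of equal main increments (default 40).
#' @return An object of class `pressure_program`.
#' @export
pressure_program <- function(start_pressure = 80, target_pressure = 120,
                             n_steps = 40L) {
  if (!(target_pressure >= start_pressure && start_pressure >= 0)) {
    stop("need target_pressure >= start_pressure >= 0")
  }
  if (n_steps < 1L) stop("`n_steps` must be >= 1")
  structure(list(start_pressure = start_pressure,
                 target_pressure = target_pressure,
                 n_steps = as.integer(n_steps),
                 mmHg_to_MPa = MMHG_TO_MPA),
            class = "pressure_program")
}

#' Tied wall-thrombus interface specification
#'
#' `"merged"` relies on the conforming mesh sharing interface nodes;
#' `"penalty"` ties duplicated interface nodes with springs
#' `f = eps_p g` where `g` is the interface gap and the stiffness per unit
#' area `eps_p = penalty_scale * K_local / h_local` is computed automatically
#' from the local bulk modulus and element size.
#'
#' @param mode `"merged"` or `"penalty"`.
#' @param penalty_scale dimensionless spring scale (default 10).
#' @return An object of class `tied_contact_spec`.
#' @export
tied_contact <- function(mode = c("merged", "penalty"), penalty_scale = 10) {
  mode <- match.arg(mode)
  if (mode == "penalty" && !(penalty_scale > 0)) {
    stop("`penalty_scale` must be positive")
  }
  structure(list(mode = mode, penalty_scale = penalty_scale),
            class = "tied_contact_spec")
}

#' Penalty tied-contact force
#' @param gap 3-vector (or matrix of) interface gap(s), mm.
#' @param epsilon_p spring stiffness (force per unit gap).
#' @return Force vector `epsilon_p * gap`.
#' @export
tied_contact_force <- function(gap, epsilon_p) epsilon_p * gap

#' Nodal forces from pressure on a face set
#'
#' Follower load: the force per face is `-p * (deformed area) * (deformed
#' outward normal)`, distributed equally to its three nodes. On a closed
#' pressurized cavity the total force vanishes.
#'
#' @param mesh a [tet_mesh()].
#' @param face_set face-set name or triangle matrix (boundary faces).
#' @param pressure pressure in MPa.
#' @param displacements optional n x 3 displacement matrix (deformed
#'   configuration); reference configuration when `NULL`.
#' @return n x 3 matrix of nodal forces (N).
#' @export
apply_pressure <- function(mesh, face_set, pressure, displacements = NULL) {
  pf <- if (is.character(face_set)) mesh$face_sets[[face_set]] else
    as.matrix(face_set)
  if (is.null(pf)) stop("unknown face set")
  bf <- do.call(rbind, lapply(unique(mesh$body), function(b) {
    boundary_faces(mesh, subset = mesh$body == b)
  }))
  if (nrow(pf) > 0L && !all(face_key(pf) %in% face_key(bf))) {
    stop("pressure faces include non-boundary faces")
  }
  coords <- mesh$nodes
  if (!is.null(displacements)) coords <- coords + displacements
  cpp_pressure_forces(coords, pf, pressure)
}

#' Newton solver controls
#'
#' Relative residual 1e-6, absolute 1e-9 N, at most 25 iterations per
#' increment with a factor-0.5 backtracking line search; failed increments
#' are bisected up to 4 times. Pressure acts as a follower load by default
#' (a dead-load option exists for linear verification problems).
#'
#' @param rel_tol,abs_tol residual tolerances.
#' @param max_iter Newton iteration cap per increment.
#' @param ls_max maximum line-search halvings.
#' @param max_bisect maximum step bisections.
#' @param follower logical: deformed-configuration pressure.
#' @return List of class `solver_control`.
#' @export
solver_control <- function(rel_tol = 1e-6, abs_tol = 1e-9, max_iter = 25L,
                           ls_max = 8L, max_bisect = 4L, follower = TRUE) {
  structure(list(rel_tol = rel_tol, abs_tol = abs_tol,
                 max_iter = as.integer(max_iter), ls_max = as.integer(ls_max),
                 max_bisect = as.integer(max_bisect), follower = follower),
            class = "solver_control")
}

#' Assembled finite-element model (advanced)
#'
#' Precomputes shape gradients, the free-DOF sparse pattern and per-element
#' material tables so repeated Newton solves only refill the stiffness
#' values.
#'
#' @param mesh a [tet_mesh()].
#' @param materials named list mapping body labels to `aaa_material`s, e.g.
#'   `list(WALL = material_preset("wall_hgo_niestrawska"),
#'   ILT = material_preset("ilt_linear"))`.
#' @param frames optional [assign_local_frames()] result (needed for HGO).
#' @param fibers optional [fiber_directions()] result; computed from
#'   `frames` and the HGO `alpha` when missing.
#' @param bc an [boundary_conditions()] object.
#' @param contact a [tied_contact()] spec.
#' @return An object of class `fe_model`.
#' @export
fe_model <- function(mesh, materials, frames = NULL, fibers = NULL, bc,
                     contact = tied_contact()) {
  ne <- nrow(mesh$tets)
  n <- nrow(mesh$nodes)
  mtype <- integer(ne)
  mparams <- matrix(0, ne, 6)
  needs_fibers <- FALSE
  for (b in unique(mesh$body)) {
    mat <- materials[[b]]
    if (is.null(mat)) stop(sprintf("no material for body `%s`", b))
    sel <- mesh$body == b
    mtype[sel] <- mat$type
    mparams[sel, ] <- matrix(mat$params, sum(sel), 6, byrow = TRUE)
    if (mat$type == 3L) needs_fibers <- TRUE
  }
  if (needs_fibers && is.null(fibers)) {
    if (is.null(frames)) stop("the HGO wall model needs frames (or fibers)")
    alpha <- NULL
    for (b in unique(mesh$body)) {
      if (materials[[b]]$type == 3L) alpha <- materials[[b]]$alpha
    }
    fibers <- fiber_directions(frames, alpha)
  }
  M4 <- if (!is.null(fibers)) fibers$M4 else
    matrix(rep(c(1, 0, 0), each = ne), ne, 3)
  M6 <- if (!is.null(fibers)) fibers$M6 else M4

  # DOF map: 0-based free index or -1 (constrained)
  fixed_idx <- (bc$fixed$node - 1L) * 3L + bc$fixed$dof
  constrained <- rep(FALSE, 3L * n)
  constrained[fixed_idx] <- TRUE
  dofmap <- rep(-1L, 3L * n)
  dofmap[!constrained] <- seq_len(sum(!constrained)) - 1L
  u_fix <- numeric(3L * n)
  u_fix[fixed_idx] <- bc$fixed$value

  pairs <- matrix(0L, 0, 2)
  pair_stiff <- numeric(0)
  if (contact$mode == "penalty") {
    if (is.null(mesh$contact_pairs)) {
      stop("penalty tied contact needs a mesh built with ",
           "interface_mode = \"penalty\"")
    }
    pairs <- mesh$contact_pairs
    storage.mode(pairs) <- "integer"
    bulk <- max(vapply(materials, function(m) {
      if (!is.null(m$bulk_modulus)) m$bulk_modulus else
        m$lambda_lame + 2 * m$mu_lame / 3
    }, numeric(1)))
    h <- sqrt(mesh$pair_area)
    eps_p <- contact$penalty_scale * bulk / h
    pair_stiff <- eps_p * mesh$pair_area
  } else if (!is.null(mesh$contact_pairs)) {
    stop("mesh has duplicated interface nodes; use tied_contact(\"penalty\")")
  }

  faces <- bc$pressure_faces
  storage.mode(faces) <- "integer"
  prep <- cpp_fe_setup(mesh$nodes, mesh$tets, dofmap, faces, pairs)
  nf <- prep$nf
  Ktmpl <- Matrix::sparseMatrix(i = prep$i, p = prep$p,
                                x = numeric(as.integer(prep$nnz)),
                                dims = c(nf, nf), index1 = FALSE)
  free_pos <- which(dofmap >= 0L)[order(dofmap[dofmap >= 0L])]
  structure(list(mesh = mesh, mtype = mtype, mparams = mparams,
                 M4 = M4, M6 = M6, dofmap = dofmap, u_fix = u_fix,
                 faces = faces, pairs = pairs, pair_stiff = pair_stiff,
                 prep = prep, Ktmpl = Ktmpl, free_pos = free_pos,
                 cache = new.env(parent = emptyenv())),
            class = "fe_model")
}

model_assemble <- function(model, u, pressure, follower, want_matrix,
                           symmetrize = TRUE, load_stiffness = TRUE) {
  cpp_fe_assemble(model$prep, model$mesh$nodes, model$mesh$tets, u,
                  model$dofmap, model$mtype, model$mparams, model$M4,
                  model$M6, model$faces, pressure, follower, model$pairs,
                  model$pair_stiff, want_matrix, symmetrize, load_stiffness)
}

solve_linear <- function(model, xvals, b) {
  K <- model$Ktmpl
  K@x <- xvals
  A <- Matrix::forceSymmetric(K)
  nf <- nrow(A)
  dbar <- mean(abs(Matrix::diag(A)))
  # fast path: supernodal LL' of A + tau*dbar*I. tau = 0 when the
  # symmetrized tangent is positive definite; otherwise a small cached
  # diagonal shift (damped Newton) keeps the supernodal factorization
  # usable, which is several times faster than simplicial LDL' here.
  taus <- unique(c(model$cache$shift, 0, 1e-6, 1e-4, 1e-2))
  taus <- taus[!is.na(taus)]
  for (tau in taus) {
    Ash <- if (tau > 0) A + (tau * dbar) * Matrix::Diagonal(nf) else A
    notpd <- FALSE
    sol <- tryCatch(
      withCallingHandlers({
        ch <- model$cache$chol_ll
        ch <- if (is.null(ch)) {
          Matrix::Cholesky(Ash, LDL = FALSE, super = TRUE)
        } else {
          Matrix::update(ch, Ash)
        }
        model$cache$chol_ll <- ch
        as.numeric(Matrix::solve(ch, b))
      }, warning = function(w) {
        if (grepl("positive definite", conditionMessage(w))) notpd <<- TRUE
        invokeRestart("muffleWarning")
      }),
      error = function(e) NULL)
    if (!notpd && !is.null(sol) && all(is.finite(sol))) {
      model$cache$shift <- tau
      model$cache$use_ldl <- FALSE
      return(sol)
    }
  }
  # exact indefinite path: simplicial LDL', then sparse LU
  sol <- tryCatch(
    suppressWarnings({
      ch <- model$cache$chol_ldl
      ch <- if (is.null(ch)) Matrix::Cholesky(A, LDL = TRUE, super = FALSE)
            else Matrix::update(ch, A)
      model$cache$chol_ldl <- ch
      as.numeric(Matrix::solve(ch, b))
    }),
    error = function(e) NULL)
  if (!is.null(sol) && all(is.finite(sol)) &&
      max(abs(A %*% sol - b)) <= 1e-8 * max(abs(b), 1e-300)) {
    model$cache$use_ldl <- TRUE
    return(sol)
  }
  as.numeric(Matrix::solve(K, b))
}

# solve with the factorization left by the previous solve_linear call
solve_cached <- function(model, b) {
  ch <- if (isTRUE(model$cache$use_ldl)) model$cache$chol_ldl else
    model$cache$chol_ll
  if (is.null(ch)) return(NULL)
  sol <- tryCatch(suppressWarnings(as.numeric(Matrix::solve(ch, b))),
                  error = function(e) NULL)
  if (!is.null(sol) && !all(is.finite(sol))) sol <- NULL
  sol
}

newton_solve <- function(model, u, pressure, load_factor, control) {
  cons <- model$dofmap < 0L
  u[cons] <- load_factor * model$u_fix[cons]
  rnorm_prev <- Inf
  r0 <- NA_real_
  fresh <- TRUE  # modified Newton: refactor only while progress is poor
  for (iter in seq_len(control$max_iter)) {
    asm <- model_assemble(model, u, pressure, control$follower, fresh)
    if (asm$inverted) {
      return(list(u = u, converged = FALSE, inverted = TRUE,
                  iterations = iter, residual = Inf))
    }
    r <- asm$resid
    rnorm <- if (length(r)) max(abs(r)) else 0
    if (iter == 1L) r0 <- rnorm
    tol <- max(control$abs_tol,
               control$rel_tol * max(asm$fext_max, r0, na.rm = TRUE))
    if (rnorm <= tol) {
      return(list(u = u, converged = TRUE, inverted = FALSE,
                  iterations = iter, residual = rnorm))
    }
    du <- NULL
    if (!fresh) du <- solve_cached(model, -r)
    if (is.null(du)) {
      if (!fresh) {
        asm <- model_assemble(model, u, pressure, control$follower, TRUE)
      }
      du <- solve_linear(model, asm$x, -r)
      fresh <- TRUE
    }
    alpha <- 1
    for (ls in seq_len(control$ls_max + 1L)) {
      u_try <- u
      u_try[model$free_pos] <- u[model$free_pos] + alpha * du
      asm2 <- model_assemble(model, u_try, pressure, control$follower, FALSE)
      rtry <- if (asm2$inverted) Inf else
        if (length(asm2$resid)) max(abs(asm2$resid)) else 0
      if (!is.finite(rtry)) rtry <- Inf  # overflowing trial state
      if (rtry < rnorm || ls > control$ls_max) break
      alpha <- alpha / 2
    }
    if (!is.finite(rtry)) {
      return(list(u = u, converged = FALSE, inverted = TRUE,
                  iterations = iter, residual = rnorm))
    }
    u <- u_try
    # give up early (step bisection is cheaper than grinding): residual
    # above its starting value after several iterations, or a collapsing
    # line search twice in a row
    tiny_alpha <- alpha < 1 / 128
    if ((iter >= 6 && rtry > r0) ||
        (tiny_alpha && isTRUE(model$cache$last_tiny))) {
      model$cache$last_tiny <- FALSE
      return(list(u = u, converged = FALSE, inverted = FALSE,
                  iterations = iter, residual = rtry))
    }
    model$cache$last_tiny <- tiny_alpha
    # reuse the factorization while the iteration contracts well
    fresh <- !(alpha == 1 && rtry < 0.2 * rnorm)
    rnorm_prev <- rnorm
  }
  list(u = u, converged = FALSE, inverted = FALSE,
       iterations = control$max_iter, residual = rnorm)
}

make_state <- function(model, u, pressure_mpa, load_factor, converged,
                       iterations, residual) {
  fld <- cpp_element_fields(model$mesh$nodes, model$mesh$tets, u,
                            model$mtype, model$mparams, model$M4, model$M6)
  structure(list(load_factor = load_factor,
                 pressure = pressure_mpa / MMHG_TO_MPA,
                 pressure_mpa = pressure_mpa,
                 displacements = matrix(u, ncol = 3, byrow = TRUE),
                 cauchy_stress = fld$sigma, green_strain = fld$green,
                 J = fld$J, vol0 = fld$vol0,
                 converged = converged, iterations = iterations,
                 residual = residual),
            class = "solution_state")
}

#' Solve a single pressure increment
#'
#' One Newton solve (consistent tangent, backtracking line search) from the
#' undeformed state to the given pressure. Returns a non-converged state
#' rather than raising when the iteration cap is reached.
#'
#' @param mesh,materials,frames,fibers,bc,contact as in [fe_model()].
#' @param pressure_step pressure in mmHg.
#' @param control a [solver_control()].
#' @return A `solution_state` with displacements, per-element Cauchy stress
#'   and Green-Lagrange strain.
#' @export
solve_increment <- function(mesh, materials, frames = NULL, fibers = NULL,
                            bc, contact = tied_contact(), pressure_step,
                            control = solver_control()) {
  model <- fe_model(mesh, materials, frames, fibers, bc, contact)
  p <- pressure_step * MMHG_TO_MPA
  res <- newton_solve(model, numeric(3L * nrow(mesh$nodes)), p, 1, control)
  make_state(model, res$u, p, 1, res$converged, res$iterations, res$residual)
}

#' Quasi-static incremental analysis
#'
#' Runs the full pressure program: an automatic pre-ramp from the stress-free
#' state to the start pressure followed by the equal main increments, with
#' step bisection on divergence or element inversion. One converged
#' `solution_state` is recorded per main step (see `record`).
#'
#' @inheritParams fe_model
#' @param program a [pressure_program()].
#' @param control a [solver_control()].
#' @param record `"main"` (default) records the main program steps,
#'   `"last"` only the final state, `"all"` also the pre-ramp.
#' @param verbose print per-step convergence lines.
#' @return An object of class `aaa_solution`: list of states plus metadata.
#' @export
run_quasistatic <- function(mesh, materials, frames = NULL, fibers = NULL,
                            bc, program, contact = tied_contact(),
                            control = solver_control(), record = "main",
                            verbose = FALSE) {
  model <- fe_model(mesh, materials, frames, fibers, bc, contact)
  p_start <- program$start_pressure * MMHG_TO_MPA
  p_target <- program$target_pressure * MMHG_TO_MPA
  dp <- (p_target - p_start) / program$n_steps
  # the whole schedule is parameterized by the load factor lambda in [0, 1]:
  # pressure = lambda * target; prescribed displacements scale with lambda
  if (dp > 0) {
    n_pre <- ceiling(p_start / dp)
    lam_pre <- if (n_pre > 0) {
      seq_len(n_pre) / n_pre * (p_start / p_target)
    } else numeric(0)
    lam_main <- (p_start + seq_len(program$n_steps) * dp) / p_target
  } else {
    lam_pre <- numeric(0)
    lam_main <- seq_len(program$n_steps) / program$n_steps
  }
  schedule <- c(lam_pre, lam_main)
  is_main <- c(rep(FALSE, length(lam_pre)), rep(TRUE, length(lam_main)))
  p_of <- function(lam) if (dp > 0) lam * p_target else p_target

  u <- numeric(3L * nrow(mesh$nodes))
  states <- list()
  lam_cur <- 0
  for (k in seq_along(schedule)) {
    lam_t <- schedule[k]
    # bisection sub-stepping toward lam_t
    queue <- lam_t
    depth <- 0L
    ok <- TRUE
    while (length(queue)) {
      lt <- queue[1]
      res <- newton_solve(model, u, p_of(lt), lt, control)
      if (res$converged) {
        u <- res$u
        lam_cur <- lt
        queue <- queue[-1]
        if (verbose) {
          message(sprintf("  p = %7.2f mmHg: %d iterations, residual %.2e",
                          p_of(lt) / MMHG_TO_MPA, res$iterations,
                          res$residual))
        }
      } else {
        depth <- depth + 1L
        if (depth > control$max_bisect) { ok <- FALSE; break }
        queue <- c((lam_cur + lt) / 2, queue)
      }
    }
    if (!ok) {
      warning(sprintf(
        "step %d (%.1f mmHg) failed after %d bisections; partial results kept",
        k, p_of(lam_t) / MMHG_TO_MPA, control$max_bisect))
      states[[length(states) + 1L]] <-
        make_state(model, u, p_of(lam_cur), lam_cur, FALSE, res$iterations,
                   res$residual)
      break
    }
    keep <- switch(record, all = TRUE, main = is_main[k],
                   last = k == length(schedule))
    if (keep) {
      states[[length(states) + 1L]] <-
        make_state(model, u, p_of(lam_cur), lam_cur, TRUE, res$iterations,
                   res$residual)
    }
  }
  structure(list(states = states, mesh = mesh, program = program,
                 materials = materials, record = record),
            class = "aaa_solution")
}

#' @export
print.aaa_solution <- function(x, ...) {
  n <- length(x$states)
  last <- x$states[[n]]
  cat(sprintf(
    "<aaa_solution> %d recorded states, final pressure %.1f mmHg (%s)\n",
    n, last$pressure, if (last$converged) "converged" else "NOT converged"))
  invisible(x)
}
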