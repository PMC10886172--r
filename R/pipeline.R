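#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis in one validated list;
#' values can come from a YAML file (`file =`) with individual overrides as
#' named arguments. Exactly one wall material is selected per run.
#'
#' @param geometry named list of [aaa_shape_params()] arguments.
#' @param level mesh resolution level: `"coarse"`, `"fine"` or `"finer"`
#'   (the lattice sampling of the same smooth geometry is scaled by
#'   `level_scales`).
#' @param level_scales named numeric scales applied to the circumferential
#'   and axial counts per level.
#' @param smoothing_iterations Taubin iterations applied to the generated
#'   surfaces (0 by default: the synthetic surfaces are already smooth).
#' @param distance_tol thickness-analysis coincidence tolerance, mm.
#' @param strip_width erased-strip width, mm (`NULL` = two median edges).
#' @param nr_wall,nr_ilt radial element layers.
#' @param wall_model `"hgo"` or `"mooney_rivlin"`.
#' @param pressure named list: `start`, `target` (mmHg), `n_steps`.
#' @param contact `"merged"` or `"penalty"`; `penalty_scale` spring scale.
#' @param n_centerline resampled centerline point count (default 90).
#' @param record which states to keep (see [run_quasistatic()]).
#' @param outdir artifact directory.
#' @param seed integer seed recorded in the run log and geometry.
#' @param file optional YAML file with any of the above keys.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(geometry = list(),
                            level = "coarse",
                            level_scales = c(coarse = 1, fine = 1.25,
                                             finer = 1.5),
                            smoothing_iterations = 0L,
                            distance_tol = 0.2,
                            strip_width = NULL,
                            nr_wall = 1L, nr_ilt = 2L,
                            wall_model = c("hgo", "mooney_rivlin"),
                            pressure = list(start = 80, target = 120,
                                            n_steps = 40L),
                            contact = "merged", penalty_scale = 10,
                            n_centerline = 90L,
                            record = "main",
                            outdir = tempfile("aaamech_run_"),
                            seed = 1L,
                            file = NULL) {
  cfg <- as.list(environment())
  cfg$file <- NULL
  if (!is.null(file)) {
    y <- yaml::read_yaml(file)
    for (nm in names(y)) cfg[[nm]] <- y[[nm]]
  }
  cfg$wall_model <- match.arg(cfg$wall_model[1], c("hgo", "mooney_rivlin"))
  if (!cfg$level %in% names(cfg$level_scales)) {
    stop(sprintf("unknown level `%s`", cfg$level))
  }
  if (!cfg$contact %in% c("merged", "penalty")) {
    stop("`contact` must be \"merged\" or \"penalty\"")
  }
  structure(cfg, class = "pipeline_config")
}

config_params <- function(cfg) {
  geo <- cfg$geometry
  geo$seed <- cfg$seed
  p <- do.call(aaa_shape_params, geo)
  sc <- cfg$level_scales[[cfg$level]]
  p$n_circumferential <- as.integer(round(p$n_circumferential * sc))
  p$n_axial <- as.integer(round(p$n_axial * sc))
  p
}

#' Build the labeled mesh for a configuration (geometry to tetrahedra)
#'
#' Runs the surface chain — generation, optional smoothing, thickness
#' analysis, fragmentation, offsetting, stitching, assembly — and meshes the
#' two bodies. Exposed separately so several material models can share one
#' identical mesh.
#'
#' @param cfg a [pipeline_config()].
#' @return List with `mesh`, `bodies`, `fragments`, `labels`, `surfaces`,
#'   `params` and the resampled `centerline`.
#' @export
build_pipeline_mesh <- function(cfg) {
  params <- config_params(cfg)
  surf <- generate_aaa_surfaces(params)
  if (cfg$smoothing_iterations > 0) {
    surf$lumen <- taubin_smooth(surf$lumen, cfg$smoothing_iterations)
    surf$inner_wall <- taubin_smooth(surf$inner_wall,
                                     cfg$smoothing_iterations)
  }
  labels <- detect_ilt_free_region(surf$lumen, surf$inner_wall,
                                   distance_tol = cfg$distance_tol)
  frag <- fragment_surfaces(surf$lumen, surf$inner_wall, labels,
                            strip_width = cfg$strip_width)
  outer <- offset_surface(surf$inner_wall, params$wall_thickness)
  bodies <- assemble_closed_bodies(frag$luminal_ilt, frag$wall_ilt_covered,
                                   frag$wall_ilt_free, outer)
  mesh <- tetrahedralize(bodies$ilt_body, bodies$wall_body,
                         bodies$interface_facets,
                         nr_wall = cfg$nr_wall, nr_ilt = cfg$nr_ilt,
                         interface_mode = cfg$contact)
  centerline <- resample_centerline(surf$centerline, cfg$n_centerline)
  list(mesh = mesh, bodies = bodies, fragments = frag, labels = labels,
       surfaces = surf, params = params, centerline = centerline)
}

#' Run the full analysis pipeline
#'
#' Geometry, surface processing, meshing, local frames, quasi-static FE
#' solve and post-processing, with every intermediate artifact written under
#' `cfg$outdir` (STL surfaces, VTK mesh and per-step fields, regional and
#' volume summary tables, and a YAML run log capturing the configuration in
#' effect).
#'
#' @param cfg a [pipeline_config()].
#' @param keep_fields write per-step VTK field files (default TRUE).
#' @return Invisibly, a list with `solution`, `summary`, `volumes`, `mesh`,
#'   `frames`, `labels` and `outdir`.
#' @export
run_pipeline <- function(cfg = pipeline_config(), keep_fields = TRUE) {
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- "geometry/meshing"
  res <- tryCatch({
    pm <- build_pipeline_mesh(cfg)
    write_stl(pm$surfaces$lumen, file.path(cfg$outdir, "lumen.stl"))
    write_stl(pm$surfaces$inner_wall,
              file.path(cfg$outdir, "inner_wall.stl"))
    write_surface_labels(pm$labels$lumen,
                         file.path(cfg$outdir, "lumen_labels.tsv"))
    write_centerline(pm$centerline, file.path(cfg$outdir, "centerline.txt"))
    write_vtk(pm$mesh, file.path(cfg$outdir, "mesh.vtk"))

    stage <- "frames"
    frames <- assign_local_frames(pm$mesh, pm$centerline)

    stage <- "solve"
    wall <- switch(cfg$wall_model,
                   hgo = material_preset("wall_hgo_niestrawska"),
                   mooney_rivlin = material_preset("wall_mooney_rivlin"))
    materials <- list(WALL = wall, ILT = material_preset("ilt_linear"))
    bc <- boundary_conditions(pm$mesh)
    program <- pressure_program(cfg$pressure$start, cfg$pressure$target,
                                cfg$pressure$n_steps)
    sol <- run_quasistatic(pm$mesh, materials, frames = frames, bc = bc,
                           program = program,
                           contact = tied_contact(cfg$contact,
                                                  cfg$penalty_scale),
                           record = cfg$record)

    stage <- "postprocess"
    labels_el <- classify_wall_regions(pm$mesh)
    final <- sol$states[[length(sol$states)]]
    summ <- regional_summary(final, labels_el)
    utils::write.csv(summ, file.path(cfg$outdir, "regional_summary.csv"),
                     row.names = FALSE)
    vols <- volume_metrics(cap_ends(pm$surfaces$inner_wall),
                           pm$bodies$ilt_body)
    utils::write.csv(vols, file.path(cfg$outdir, "volume_metrics.csv"),
                     row.names = FALSE)
    if (keep_fields) {
      export_fields(pm$mesh, sol, file.path(cfg$outdir, "fields"),
                    frames = frames, labels = labels_el)
    }
    log <- list(package_version = as.character(utils::packageVersion("aaamech")),
                r_version = R.version.string,
                seed = cfg$seed,
                config = unclass(cfg)[setdiff(names(cfg),
                                              c("level_scales"))],
                n_elements = nrow(pm$mesh$tets),
                n_nodes = nrow(pm$mesh$nodes),
                converged = final$converged)
    log$config$outdir <- NULL
    yaml::write_yaml(log, file.path(cfg$outdir, "run_log.yaml"))
    list(solution = sol, summary = summ, volumes = vols, mesh = pm$mesh,
         frames = frames, labels = labels_el, outdir = cfg$outdir,
         pipeline_mesh = pm)
  }, error = function(e) {
    stop(sprintf("pipeline stage `%s` failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(res)
}

#' Analytic verification suite
#'
#' Machine-checkable oracles for the load-bearing arithmetic and mechanics:
#' Lame conversion, the wall strength-limit worked value, the dispersed
#' fiber strain, thrombus volume-ratio arithmetic, the stress/energy
#' consistency of all three constitutive models, and a single-element
#' uniaxial patch solve. Failures are report rows, never errors.
#'
#' @param tolerances optional named overrides of the per-check tolerances
#'   (a perturbed tolerance makes the corresponding check fail by name).
#' @return A tibble with `check`, `value`, `expected`, `tol`, `pass`.
#' @export
verify_oracles <- function(tolerances = list()) {
  tol <- function(name, default) {
    if (!is.null(tolerances[[name]])) tolerances[[name]] else default
  }
  rows <- list()
  add <- function(check, value, expected, tl) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      check = check, value = value, expected = expected, tol = tl,
      pass = abs(value - expected) <= tl)
  }
  lam <- lame_from_modulus(0.11, 0.45)
  add("lame_lambda", lam$lambda_lame, 0.11 * 0.45 / (1.45 * 0.1),
      tol("lame_lambda", 1e-12))
  add("lame_mu", lam$mu_lame, 0.11 / 2.9, tol("lame_mu", 1e-12))
  add("uts_wall_worked_value", round(uts_wall(0.0593, 0.0895), 3), 0.079,
      tol("uts_wall_worked_value", 5e-4))
  add("fiber_strain_arithmetic", fiber_strain(3.05, 1.02, 0.1010), 0.018990,
      tol("fiber_strain_arithmetic", 1e-12))
  vm <- volume_metrics(412, 96)
  add("ilt_percent_arithmetic", round(vm$ilt_percent, 1), 23.3,
      tol("ilt_percent_arithmetic", 0.05))
  # energy/stress consistency on a random state, one per model
  set.seed(42)
  F <- diag(3) + 0.02 * matrix(stats::runif(9, -1, 1), 3, 3)
  fb <- list(M4 = c(1, 0, 0), M6 = c(cos(1), sin(1), 0))
  for (m in list(material_preset("ilt_linear"),
                 material_preset("wall_mooney_rivlin"),
                 material_preset("wall_hgo_niestrawska"))) {
    sig <- cauchy_stress(m, F, fb)
    fd <- fd_cauchy_from_energy(m, F, fb)
    add(paste0("stress_energy_consistency_", m$model),
        max(abs(sig - fd)) / max(abs(sig)), 0,
        tol(paste0("stress_energy_consistency_", m$model), 1e-6))
  }
  # single-element uniaxial patch solve with follower pressure p on the top
  # face: homogeneous state with Cauchy sigma_zz = -p
  mesh <- generate_patch_fixture()
  p_mpa <- 0.01
  bcp <- patch_roller_bc(mesh, pressure_faces = "ZMAX")
  st <- solve_increment(mesh, list(WALL = material_linear_elastic(1, 0.3)),
                        bc = bcp, pressure_step = p_mpa / MMHG_TO_MPA,
                        control = solver_control(rel_tol = 1e-12,
                                                 abs_tol = 1e-14))
  szz <- mean(st$cauchy_stress[, 9])
  add("patch_uniaxial_sigma_zz", szz, -p_mpa,
      tol("patch_uniaxial_sigma_zz", 1e-8))
  dplyr::bind_rows(rows)
}

#' Roller boundary conditions for cube patch tests
#'
#' Zero normal displacement on the XMIN/YMIN/ZMIN faces and pressure on a
#' chosen face of the unit-cube fixture.
#'
#' @param mesh the [generate_patch_fixture()] mesh.
#' @param pressure_faces face-set name to pressurize.
#' @return An [boundary_conditions()] object.
#' @export
patch_roller_bc <- function(mesh, pressure_faces = "ZMAX") {
  pre <- do.call(rbind, lapply(list(c("XMIN", 1), c("YMIN", 2), c("ZMIN", 3)),
                               function(sd) {
    nodes <- unique(as.vector(mesh$face_sets[[sd[1]]]))
    data.frame(node = nodes, dof = as.integer(sd[2]), value = 0)
  }))
  boundary_conditions(mesh, fixed_sets = character(0), prescribed = pre,
                      pressure_faces = pressure_faces)
}

# central-difference Cauchy stress from the strain energy (oracle route):
# P_ij = dW/dF_ij, sigma = J^-1 P F'
fd_cauchy_from_energy <- function(model, F, fibers = NULL, h = 1e-6) {
  P <- matrix(0, 3, 3)
  for (i in 1:3) {
    for (j in 1:3) {
      Fp <- F
      Fm <- F
      Fp[i, j] <- Fp[i, j] + h
      Fm[i, j] <- Fm[i, j] - h
      P[i, j] <- (strain_energy(model, Fp, fibers) -
                    strain_energy(model, Fm, fibers)) / (2 * h)
    }
  }
  P %*% t(F) / det(F)
}
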