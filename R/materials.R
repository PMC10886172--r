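#' Lame parameters from elastic modulus and Poisson ratio
#'
#' `lambda = E nu / ((1 + nu)(1 - 2 nu))`, `mu = E / (2 (1 + nu))`.
#'
#' @param E elastic modulus, MPa.
#' @param nu Poisson ratio, in (-1, 0.5).
#' @return Named list with `lambda_lame` and `mu_lame` (MPa).
#' @export
lame_from_modulus <- function(E, nu) {
  if (!(E > 0)) stop("invalid `E`: must be positive")
  if (!(nu > -1 && nu < 0.5)) stop("invalid `nu`: must lie in (-1, 0.5)")
  if (0.5 - nu < 1e-9) stop("`nu` too close to 0.5: Lame lambda overflows")
  list(lambda_lame = E * nu / ((1 + nu) * (1 - 2 * nu)),
       mu_lame = E / (2 * (1 + nu)))
}

#' Linear-elastic material at large strain
#'
#' Isotropic linear elasticity extended to finite deformation. Two standard
#' extensions are provided, both reducing to the same linear law for small
#' strains: `"svk"`, the Saint Venant-Kirchhoff form on the Green-Lagrange
#' strain (`W = lambda/2 tr(E)^2 + mu E:E`), and `"neo_hookean"`, the
#' compressible neo-Hookean form
#' `W = mu/2 (I1 - 3) - mu ln J + lambda/2 (ln J)^2`. The latter is
#' polyconvex with a volumetric barrier, so it remains stable where tissue
#' is strongly compressed (the thrombus margin is crushed locally under
#' pressure, where the SVK form loses material stability); it is the form
#' used by the thrombus preset.
#'
#' @param E elastic modulus, MPa.
#' @param nu Poisson ratio.
#' @param form `"svk"` or `"neo_hookean"`.
#' @return Material object of class `aaa_material`.
#' @export
material_linear_elastic <- function(E = 0.11, nu = 0.45,
                                    form = c("svk", "neo_hookean")) {
  form <- match.arg(form)
  lam <- lame_from_modulus(E, nu)
  structure(list(model = if (form == "svk") "linear_elastic" else
                   "linear_elastic_nh",
                 E = E, nu = nu,
                 lambda_lame = lam$lambda_lame, mu_lame = lam$mu_lame,
                 form = form,
                 type = if (form == "svk") 1L else 4L,
                 params = c(lam$lambda_lame, lam$mu_lame, 0, 0, 0, 0)),
            class = "aaa_material")
}

#' Two-parameter Mooney-Rivlin material (decoupled, near-incompressible)
#'
#' Isochoric energy `c1 (I1b - 3) + c2 (I2b - 3)` on the modified invariants
#' plus the volumetric penalty `K/2 (ln J)^2`. The default bulk modulus is
#' 100x the small-strain shear modulus `2 (c1 + c2)`.
#'
#' @param c1,c2 material parameters, MPa (`c1 + c2 > 0`).
#' @param bulk_modulus volumetric penalty modulus K, MPa.
#' @return Material object of class `aaa_material`.
#' @export
material_mooney_rivlin <- function(c1 = 0.174, c2 = 1.881,
                                   bulk_modulus = 200 * (c1 + c2)) {
  if (!(c1 + c2 > 0)) stop("invalid parameters: need c1 + c2 > 0")
  if (!(bulk_modulus > 0)) stop("invalid `bulk_modulus`: must be positive")
  structure(list(model = "mooney_rivlin", c1 = c1, c2 = c2,
                 bulk_modulus = bulk_modulus, type = 2L,
                 params = c(c1, c2, bulk_modulus, 0, 0, 0)),
            class = "aaa_material")
}

#' Holzapfel-Gasser-Ogden material with dispersed tension-only fibers
#'
#' Neo-Hookean ground matrix `c/2 (I1 - 3)` plus two exponential collagen
#' families `k1/(2 k2) [exp(k2 <E_a>^2) - 1]` with the dispersed fiber strain
#' `E_a = kappa (I1 - 3) + (1 - 3 kappa) (I4 - 1)` (Macaulay brackets switch
#' compressed fibers off), and the volumetric penalty `K/2 (ln J)^2`.
#' By default the isochoric (modified) invariants are used; `invariants =
#' "full"` evaluates the same energy on the unmodified invariants.
#'
#' @param c ground-matrix parameter, MPa.
#' @param k1 fiber stiffness, MPa; `k2` dimensionless exponent (> 0).
#' @param kappa dispersion, in \[0, 1/3\] (0 aligned, 1/3 isotropic).
#' @param alpha fiber angle from the circumferential axis, degrees.
#' @param bulk_modulus volumetric penalty modulus K, MPa (default 100 c).
#' @param invariants `"isochoric"` (default) or `"full"`.
#' @return Material object of class `aaa_material`.
#' @export
material_hgo <- function(c = 0.30055, k1 = 0.01632, k2 = 1768.15,
                         kappa = 0.1010, alpha = 5.6,
                         bulk_modulus = 100 * c,
                         invariants = c("isochoric", "full")) {
  invariants <- match.arg(invariants)
  if (!(k2 > 0)) stop("invalid `k2`: must be positive")
  if (kappa < 0 || kappa > 1 / 3) stop("invalid `kappa`: must lie in [0, 1/3]")
  if (!(bulk_modulus > 0)) stop("invalid `bulk_modulus`: must be positive")
  structure(list(model = "hgo", c = c, k1 = k1, k2 = k2, kappa = kappa,
                 alpha = alpha, bulk_modulus = bulk_modulus,
                 invariants = invariants, type = 3L,
                 params = c(c, k1, k2, kappa, bulk_modulus,
                            as.numeric(invariants == "full"))),
            class = "aaa_material")
}

#' @export
print.aaa_material <- function(x, ...) {
  cat(sprintf("<aaa_material> %s: %s\n", x$model,
              paste(sprintf("%s=%.5g",
                            setdiff(names(x), c("model", "type", "params",
                                                "invariants")),
                            unlist(x[setdiff(names(x),
                                             c("model", "type", "params",
                                               "invariants"))])),
                    collapse = ", ")))
  invisible(x)
}

#' Named material presets
#'
#' The parameter sets used throughout: `"ilt_linear"` (thrombus,
#' E = 0.11 MPa, nu = 0.45), `"wall_hgo_niestrawska"` (aneurysmal wall HGO:
#' c = 0.30055 MPa, k1 = 0.01632 MPa, k2 = 1768.15, kappa = 0.1010,
#' alpha = 5.6 deg) and `"wall_mooney_rivlin"` (c1 = 0.174, c2 = 1.881 MPa).
#'
#' @param name preset name.
#' @return An `aaa_material`.
#' @export
material_preset <- function(name = c("ilt_linear", "wall_hgo_niestrawska",
                                     "wall_mooney_rivlin")) {
  name <- match.arg(name)
  switch(name,
         ilt_linear = material_linear_elastic(0.11, 0.45,
                                              form = "neo_hookean"),
         wall_hgo_niestrawska = material_hgo(),
         wall_mooney_rivlin = material_mooney_rivlin())
}
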