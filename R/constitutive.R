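#' Deformation state from a deformation gradient
#'
#' Collects the kinematic quantities the material models consume: the right
#' Cauchy-Green tensor `C = F'F`, the Green-Lagrange strain
#' `E = (C - I)/2`, `J = det F`, the isotropic invariants I1, I2, and (when
#' fiber directions are supplied) the fiber invariants `I4 = M.C.M`.
#'
#' @param F 3x3 deformation gradient with positive determinant.
#' @param M4,M6 optional unit fiber direction vectors.
#' @return An object of class `deformation_state`.
#' @export
deformation_state <- function(F, M4 = NULL, M6 = NULL) {
  F <- as.matrix(F)
  J <- det(F)
  if (J <= 0) stop("invalid deformation state: det F must be positive")
  C <- t(F) %*% F
  E <- (C - diag(3)) / 2
  I1 <- sum(diag(C))
  I2 <- 0.5 * (I1^2 - sum(C * t(C)))
  st <- list(F = F, J = J, C = C, E_green = E, I1 = I1, I2 = I2)
  if (!is.null(M4)) st$I4_4 <- drop(t(M4) %*% C %*% M4)
  if (!is.null(M6)) st$I4_6 <- drop(t(M6) %*% C %*% M6)
  structure(st, class = "deformation_state")
}

#' Dispersed fiber strain
#'
#' `E_alpha = kappa (I1 - 3) + (1 - 3 kappa) (I4 - 1)`; at `kappa = 1/3` the
#' fiber strain becomes isotropic (independent of I4), at `kappa = 0`
#' perfectly aligned.
#'
#' @param I1 first invariant (scalar or vector).
#' @param I4 fiber invariant.
#' @param kappa dispersion parameter in \[0, 1/3\].
#' @return Fiber strain (same shape as the inputs).
#' @export
fiber_strain <- function(I1, I4, kappa) {
  kappa * (I1 - 3) + (1 - 3 * kappa) * (I4 - 1)
}

default_fibers <- function(fibers) {
  if (is.null(fibers)) list(M4 = c(1, 0, 0), M6 = c(1, 0, 0)) else fibers
}

#' Strain-energy density
#'
#' @param model an `aaa_material`.
#' @param state a [deformation_state()] (or a 3x3 deformation gradient).
#' @param fibers optional list with unit vectors `M4`, `M6` (required
#'   behavior only for the HGO model; ignored by the isotropic models).
#' @return Energy density in MPa (zero at the reference state).
#' @export
strain_energy <- function(model, state, fibers = NULL) {
  F <- if (inherits(state, "deformation_state")) state$F else as.matrix(state)
  fb <- default_fibers(fibers)
  cpp_energy(F, model$type, model$params, fb$M4, fb$M6)
}

#' Cauchy stress (analytic)
#'
#' Second Piola-Kirchhoff stress `S = 2 dW/dC` evaluated in closed form and
#' pushed forward: `sigma = J^-1 F S F'`.
#'
#' @inheritParams strain_energy
#' @return Symmetric 3x3 Cauchy stress, MPa.
#' @export
cauchy_stress <- function(model, state, fibers = NULL) {
  F <- if (inherits(state, "deformation_state")) state$F else as.matrix(state)
  fb <- default_fibers(fibers)
  cpp_cauchy(F, model$type, model$params, fb$M4, fb$M6)
}

#' Second Piola-Kirchhoff stress (analytic)
#' @inheritParams strain_energy
#' @return Symmetric 3x3 PK2 stress, MPa.
#' @export
pk2_stress <- function(model, state, fibers = NULL) {
  C <- if (inherits(state, "deformation_state")) state$C else {
    F <- as.matrix(state)
    t(F) %*% F
  }
  fb <- default_fibers(fibers)
  cpp_pk2(C, model$type, model$params, fb$M4, fb$M6)
}

#' Material elasticity tensor
#'
#' Fourth-order tangent `A_ijkl = dS_ij / dE_kl` (minor and major
#' symmetries), obtained by complex-step differentiation of the analytic PK2
#' stress — exact to machine precision, so it serves as the consistent
#' linearization for the Newton solver.
#'
#' @inheritParams strain_energy
#' @return A 3x3x3x3 numeric array (MPa).
#' @export
material_tangent <- function(model, state, fibers = NULL) {
  C <- if (inherits(state, "deformation_state")) state$C else {
    F <- as.matrix(state)
    t(F) %*% F
  }
  fb <- default_fibers(fibers)
  D <- cpp_tangent6(C, model$type, model$params, fb$M4, fb$M6)
  vi <- c(1, 2, 3, 1, 2, 1)
  vj <- c(1, 2, 3, 2, 3, 3)
  voigt_of <- matrix(0L, 3, 3)
  for (r in 1:6) {
    voigt_of[vi[r], vj[r]] <- r
    voigt_of[vj[r], vi[r]] <- r
  }
  A <- array(0, c(3, 3, 3, 3))
  for (i in 1:3) for (j in 1:3) for (k in 1:3) for (l in 1:3) {
    A[i, j, k, l] <- D[voigt_of[i, j], voigt_of[k, l]]
  }
  A
}
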