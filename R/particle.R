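#' Langevin function
#'
#' `L(x) = coth(x) - 1/x`, the equilibrium magnetization law of an ensemble
#' of thermally agitated magnetic moments. Odd, strictly increasing, bounded
#' by (-1, 1). A Taylor branch `x/3 - x^3/45 + 2 x^5/945` is used for
#' `|x| < 1e-4` where the direct form loses precision by cancellation.
#'
#' @param x Numeric vector (dimensionless field-to-thermal-energy ratio).
#' @return `L(x)`, same shape as `x`.
#' @export
langevin <- function(x) {
  stopifnot(all(is.finite(x)))
  out <- numeric(length(x))
  small <- abs(x) < 1e-4
  xs <- x[small]
  out[small] <- xs / 3 - xs^3 / 45 + 2 * xs^5 / 945
  xl <- x[!small]
  out[!small] <- 1 / tanh(xl) - 1 / xl
  dim(out) <- dim(x)
  out
}

#' Thermal Langevin steepness of a particle core
#'
#' The argument scale `beta` of the Langevin law `M = Ms L(beta |H|)`:
#' `beta = mu0 * Ms * V_core / (kB * T)` (m/A), the magnetic moment of the
#' core divided by the thermal energy.
#'
#' @param spec A [particle_spec].
#' @return `beta` in (A/m)^-1.
#' @export
langevin_beta <- function(spec) {
  stopifnot(inherits(spec, "particle_spec"))
  Ms <- spec$core_material$Ms
  if (is.na(Ms) || Ms <= 0) stop("core material has no saturation magnetization")
  MU0 * Ms * spec$v_core / (KB * spec$temperature)
}

#' Equilibrium (superparamagnetic) magnetization of the core
#'
#' `M = Ms * L(beta |H_eff|) * H_eff / |H_eff|`, the thermal-equilibrium
#' magnetization of the magnetic core along the effective field. The zero
#' field maps to the zero vector.
#'
#' @param H_eff Effective magnetic field, length-3 vector (A/m).
#' @param spec A [particle_spec]; requires core `Ms > 0`.
#' @param beta Optional explicit steepness (A/m)^-1 overriding the thermal
#'   value from [langevin_beta], e.g. to match an empirically traced M-H
#'   curve.
#' @return Length-3 magnetization vector (A/m) of the core material.
#' @export
equilibrium_magnetization <- function(H_eff, spec, beta = NULL) {
  H_eff <- as.numeric(H_eff)
  stopifnot(length(H_eff) == 3L)
  if (spec$v_core == 0) {
    warning("zero core volume: magnetization is identically zero")
    return(c(0, 0, 0))
  }
  if (is.null(beta)) beta <- langevin_beta(spec)
  h <- sqrt(sum(H_eff^2))
  if (h == 0) return(c(0, 0, 0))
  spec$core_material$Ms * langevin(beta * h) * H_eff / h
}

#' Volume-averaged particle magnetization
#'
#' The shell is taken as magnetically inert, so the particle-average
#' magnetization is the core magnetization scaled by the core volume
#' fraction `f_core = (r_core / r_total)^3`.
#'
#' @param spec A [particle_spec].
#' @param M_core Core magnetization vector (A/m).
#' @return Particle-averaged magnetization vector (A/m).
#' @export
composite_magnetization <- function(spec, M_core) {
  stopifnot(inherits(spec, "particle_spec"))
  spec$f_core * as.numeric(M_core)
}

# deviator of a 3x3 tensor
dev3 <- function(S) S - diag(3) * sum(diag(S)) / 3

#' Magnetostrictive strain tensor
#'
#' `eps_me = (3/2) (lambda_s / Ms^2) dev(M (x) M)`: the traceless strain a
#' magnetostrictive material develops at magnetization `M`. Invariant under
#' `M -> -M` (quadratic in M).
#'
#' @param M Magnetization vector (A/m).
#' @param mat [material_props] with `Ms > 0` and `lambda_s` set.
#' @return 3 x 3 symmetric traceless strain tensor (dimensionless).
#' @export
magnetostrictive_strain <- function(M, mat) {
  M <- as.numeric(M)
  stopifnot(length(M) == 3L)
  if (is.na(mat$Ms) || mat$Ms <= 0) stop("Ms must be > 0 for magnetostriction")
  if (is.na(mat$lambda_s)) stop("material has no saturation magnetostriction")
  1.5 * mat$lambda_s / mat$Ms^2 * dev3(outer(M, M))
}

# Voigt 6-vector (11,22,33,23,13,12) <-> symmetric 3x3 tensor.
voigt_to_tensor <- function(v) {
  stopifnot(length(v) == 6L)
  matrix(c(v[1], v[6], v[5],
           v[6], v[2], v[4],
           v[5], v[4], v[3]), 3, 3)
}
tensor_to_voigt <- function(S) {
  c(S[1, 1], S[2, 2], S[3, 3], S[2, 3], S[1, 3], S[1, 2])
}

#' Piezoelectric stress from an applied electric field
#'
#' Lumped zero-strain (clamped) evaluation of the linear piezoelectric
#' constitutive law: in Voigt form `S = S0 - t(e) %*% E`, where `e` is the
#' 3 x 6 stress-coupling matrix of the shell material. Voigt order is
#' 11, 22, 33, 23, 13, 12.
#'
#' @param E Electric field vector (V/m).
#' @param mat [material_props] carrying `coupling_voigt` (the shell).
#' @param S0 Initial stress, 3 x 3 tensor (Pa); default zero.
#' @return 3 x 3 stress tensor (Pa).
#' @export
piezo_stress <- function(E, mat, S0 = matrix(0, 3, 3)) {
  E <- as.numeric(E)
  stopifnot(length(E) == 3L)
  if (is.null(mat$coupling_voigt)) {
    stop("material '", mat$name, "' has no piezoelectric coupling matrix")
  }
  sv <- tensor_to_voigt(S0) - as.numeric(crossprod(mat$coupling_voigt, E))
  voigt_to_tensor(sv)
}

#' Stress-dependent effective magnetic field
#'
#' `H_eff = H + 3 lambda_s / (mu0 Ms^2) * dev(S) %*% M`: the applied field
#' plus the magnetoelastic correction from the deviatoric stress acting on
#' the magnetization. With `lambda_s = 0` or hydrostatic stress the applied
#' field is returned unchanged.
#'
#' @param H Applied field vector (A/m).
#' @param S Stress tensor, 3 x 3 (Pa).
#' @param M Magnetization vector (A/m).
#' @param mat [material_props] with `Ms > 0` (the magnetic core).
#' @return Effective field vector (A/m).
#' @export
effective_field <- function(H, S, M, mat) {
  H <- as.numeric(H); M <- as.numeric(M)
  stopifnot(length(H) == 3L, length(M) == 3L, all(dim(S) == c(3L, 3L)))
  if (is.na(mat$Ms) || mat$Ms <= 0) stop("Ms must be > 0")
  lam <- mat$lambda_s
  if (is.na(lam)) lam <- 0
  H + 3 * lam / (MU0 * mat$Ms^2) * as.numeric(dev3(S) %*% M)
}

#' Self-consistent lumped magnetoelectric state
#'
#' Damped fixed-point solution of the zero-dimensional core-shell coupling:
#' the applied electric field generates piezoelectric stress in the shell,
#' transmitted to the core with transfer factor `kappa`; the deviatoric
#' stress tilts the effective field; and the magnetization relaxes to the
#' Langevin equilibrium in that field.
#'
#' Two closures for the magnetostrictive self-stress are provided.
#' `"free"` (default): the particle is suspended in fluid with
#' traction-free surfaces, so the core strain accommodates the
#' magnetostrictive strain and no self-stress develops - only the
#' shell-transmitted piezoelectric stress acts. `"clamped"`: zero total
#' strain, giving back-stress `-C : eps_me(M)` with an isotropic stiffness
#' from the core's Young's modulus and Poisson ratio; this feedback is
#' strong and the fixed point may need many iterations.
#'
#' @param spec [particle_spec] with a piezoelectric shell (or `E_applied`
#'   zero).
#' @param H_applied Applied magnetic field vector (A/m).
#' @param E_applied Applied electric field vector (V/m); default zero.
#' @param kappa Shell-to-core stress transfer factor in `[0, 1]`; default 1.
#' @param closure `"free"` or `"clamped"` (see Details).
#' @param damping Fixed-point damping in (0, 1]; default 0.5.
#' @param tol Relative convergence tolerance on `|dM| / Ms`; default 1e-10.
#' @param max_iter Iteration cap; default 500.
#' @param M_init Optional initial magnetization guess (A/m).
#' @param strict Error (rather than flag) on non-convergence.
#' @return A `lumped_state` list: `M` (core magnetization, A/m),
#'   `M_particle` (volume-averaged, A/m), `S` (stress, Pa), `E`, `H`,
#'   `H_eff`, `eps_me`, `converged`, `iterations`.
#' @export
solve_lumped_me <- function(spec, H_applied, E_applied = c(0, 0, 0),
                            kappa = 1, closure = c("free", "clamped"),
                            damping = 0.5, tol = 1e-10,
                            max_iter = 500L, M_init = NULL, strict = FALSE) {
  closure <- match.arg(closure)
  stopifnot(inherits(spec, "particle_spec"), tol > 0,
            kappa >= 0, kappa <= 1, damping > 0, damping <= 1)
  core <- spec$core_material
  Ms <- core$Ms
  H_applied <- as.numeric(H_applied); E_applied <- as.numeric(E_applied)
  lam <- core$lambda_s
  if (is.na(lam)) lam <- 0

  S_piezo <- matrix(0, 3, 3)
  if (any(E_applied != 0)) {
    if (is.null(spec$shell_material)) stop("E applied but particle has no shell")
    S_piezo <- kappa * piezo_stress(E_applied, spec$shell_material)
  }
  C_core <- if (!is.na(core$youngs) && !is.na(core$poisson)) {
    isotropic_stiffness(core$youngs, core$poisson)
  } else NULL

  M <- if (is.null(M_init)) equilibrium_magnetization(H_applied, spec)
       else as.numeric(M_init)
  S <- S_piezo
  eps_me <- matrix(0, 3, 3)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    if (lam != 0) {
      eps_me <- magnetostrictive_strain(M, core)
      S_mag <- if (closure == "free" || is.null(C_core)) matrix(0, 3, 3) else {
        -voigt_to_tensor(as.numeric(C_core %*% tensor_to_voigt(eps_me)))
      }
      S <- S_piezo + S_mag
    }
    H_eff <- effective_field(H_applied, S, M, core)
    M_new <- equilibrium_magnetization(H_eff, spec)
    M_next <- M + damping * (M_new - M)
    if (sqrt(sum((M_next - M)^2)) / Ms < tol) {
      M <- M_next
      converged <- TRUE
      break
    }
    M <- M_next
  }
  if (!converged && strict) {
    stop("lumped magnetoelectric solver did not converge in ", max_iter,
         " iterations")
  }
  H_eff <- effective_field(H_applied, S, M, core)
  structure(list(M = M, M_particle = composite_magnetization(spec, M),
                 S = S, E = E_applied, H = H_applied, H_eff = H_eff,
                 eps_me = eps_me, converged = converged, iterations = it),
            class = "lumped_state")
}

#' Sample an M-H curve
#'
#' Evaluates the equilibrium (optionally volume-averaged) magnetization
#' magnitude along a fixed direction over a range of applied field
#' magnitudes. The curve is odd-symmetric by construction.
#'
#' @param spec [particle_spec].
#' @param H_max Maximum field magnitude (A/m).
#' @param n_points Number of samples (>= 2), symmetric about zero.
#' @param composite Volume-average over the whole particle (default `TRUE`).
#' @param beta Optional explicit Langevin steepness.
#' @return An `mh_curve` data.frame with columns `H`, `M` (both A/m) and
#'   attributes recording the particle.
#' @export
mh_curve <- function(spec, H_max, n_points = 201L, composite = TRUE,
                     beta = NULL) {
  stopifnot(n_points >= 2L, H_max > 0)
  H <- seq(-H_max, H_max, length.out = n_points)
  Ms <- spec$core_material$Ms
  if (is.null(beta)) beta <- langevin_beta(spec)
  M <- Ms * langevin(beta * H)
  if (composite) M <- spec$f_core * M
  structure(data.frame(H = H, M = M),
            class = c("mh_curve", "data.frame"),
            particle = sprintf("%s core r=%.3g nm / r_total=%.3g nm, T=%g K",
                               spec$core_material$name, spec$r_core * 1e9,
                               spec$r_total * 1e9, spec$temperature),
            beta = beta)
}

#' Write an M-H curve as two-column text
#'
#' @param curve An `mh_curve`.
#' @param path Output file.
#' @export
write_mh_curve <- function(curve, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# ", attr(curve, "particle")),
               "# H_A_per_m M_A_per_m"), con)
  utils::write.table(curve, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Magnetic flux density of a uniformly magnetized sphere
#'
#' Analytic surrogate for the field map around a single particle: inside
#' the sphere the flux density is the uniform `(2/3) mu0 M`; outside it is
#' the point-dipole field of moment `M * V`. The normal component of `B` is
#' continuous at the surface.
#'
#' @param M Magnetization vector (A/m).
#' @param r_particle Sphere radius (m).
#' @param points N x 3 matrix of evaluation coordinates (m), origin at the
#'   sphere center.
#' @return N x 3 matrix of `B` vectors (T).
#' @export
sphere_dipole_field <- function(M, r_particle, points) {
  M <- as.numeric(M)
  points <- matrix(as.numeric(points), ncol = 3L)
  r <- sqrt(rowSums(points^2))
  B <- matrix(0, nrow(points), 3L)
  inside <- r <= r_particle
  if (any(inside)) {
    B[inside, ] <- matrix(2 / 3 * MU0 * M, sum(inside), 3, byrow = TRUE)
  }
  out <- !inside
  if (any(out)) {
    m <- M * 4 / 3 * pi * r_particle^3
    rr <- r[out]
    rhat <- points[out, , drop = FALSE] / rr
    mdotr <- as.numeric(rhat %*% m)
    B[out, ] <- MU0 / (4 * pi) *
      (3 * mdotr * rhat - matrix(m, sum(out), 3, byrow = TRUE)) / rr^3
  }
  B
}
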