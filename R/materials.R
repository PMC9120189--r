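# Physical constants (SI)
MU0 <- 4e-7 * pi        # vacuum permeability, T m/A
KB  <- 1.380649e-23     # Boltzmann constant, J/K
N_AVOGADRO <- 6.02214076e23

#' Material properties for the particle model
#'
#' Bundles the physical constants of one material (magnetostrictive core,
#' piezoelectric shell, or surrounding electrolyte). Fields that do not
#' apply to a material are `NA`/`NULL` (e.g. the electrolyte has no
#' piezoelectric coupling matrix).
#'
#' @param name Label, e.g. `"cobalt_ferrite"`.
#' @param sigma Electrical conductivity (S/m).
#' @param chi0 Initial magnetic susceptibility (dimensionless), or `NA`.
#' @param lambda_s Saturation magnetostriction (dimensionless; a ppm value
#'   must be divided by 1e6 before it is passed here), or `NA`.
#' @param density Mass density (kg/m^3).
#' @param Ms Saturation magnetization (A/m), or `NA`.
#' @param poisson Poisson's ratio, or `NA`.
#' @param eps_r Relative permittivity, length-3 diagonal.
#' @param youngs Young's modulus (Pa), or `NA`.
#' @param elasticity_voigt 6 x 6 stiffness matrix (Pa), or `NULL`.
#' @param coupling_voigt 3 x 6 piezoelectric stress-coupling matrix e
#'   (C/m^2), or `NULL`.
#' @return An object of class `material_props`.
#' @export
material_props <- function(name, sigma, chi0 = NA_real_, lambda_s = NA_real_,
                           density, Ms = NA_real_, poisson = NA_real_,
                           eps_r = c(1, 1, 1), youngs = NA_real_,
                           elasticity_voigt = NULL, coupling_voigt = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.na(Ms) && Ms < 0) stop("Ms must be >= 0")
  if (!is.numeric(density) || density <= 0) stop("density must be > 0")
  eps_r <- as.numeric(eps_r)
  if (length(eps_r) != 3L || any(eps_r < 1)) {
    stop("eps_r must be a length-3 vector with components >= 1")
  }
  if (!is.null(elasticity_voigt)) {
    elasticity_voigt <- as.matrix(elasticity_voigt)
    if (!all(dim(elasticity_voigt) == c(6L, 6L))) {
      stop("elasticity_voigt must be 6 x 6")
    }
    if (max(abs(elasticity_voigt - t(elasticity_voigt))) >
        1e-8 * max(abs(elasticity_voigt))) {
      stop("elasticity_voigt must be symmetric")
    }
    ev <- eigen(elasticity_voigt, symmetric = TRUE, only.values = TRUE)$values
    attr(elasticity_voigt, "psd") <- min(ev) >= -1e-8 * max(abs(ev))
  }
  if (!is.null(coupling_voigt)) {
    coupling_voigt <- as.matrix(coupling_voigt)
    if (!all(dim(coupling_voigt) == c(3L, 6L))) {
      stop("coupling_voigt must be 3 x 6")
    }
  }
  structure(list(name = name, sigma = sigma, chi0 = chi0,
                 lambda_s = lambda_s, density = density, Ms = Ms,
                 poisson = poisson, eps_r = eps_r, youngs = youngs,
                 elasticity_voigt = elasticity_voigt,
                 coupling_voigt = coupling_voigt),
            class = "material_props")
}

#' Load the bundled materials database
#'
#' Reads the declarative materials file shipped with the package (or a
#' user-supplied file of the same layout) and returns a named list of
#' [material_props] objects. File units follow the conventional tabulation
#' (ppm magnetostriction, GPa moduli); values are converted to SI here.
#'
#' The 21 flat elasticity entries fill the upper triangle of the symmetric
#' 6 x 6 Voigt matrix column by column: (1,1), (1,2), (2,2), (1,3), ...,
#' (6,6), with Voigt order 11, 22, 33, 23, 13, 12 and engineering shear.
#'
#' @param path Optional path to a materials YAML file; defaults to the
#'   bundled database.
#' @return Named list of `material_props`.
#' @export
load_materials <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "materials.yaml", package = "menpsim")
  }
  raw <- yaml::read_yaml(path)
  out <- lapply(names(raw), function(nm) {
    m <- raw[[nm]]
    elast <- NULL
    if (!is.null(m$elasticity_voigt_GPa)) {
      elast <- voigt_from_flat(as.numeric(m$elasticity_voigt_GPa)) * 1e9
    }
    coup <- NULL
    if (!is.null(m$coupling_voigt)) {
      coup <- matrix(unlist(m$coupling_voigt), nrow = 3L, byrow = TRUE)
    }
    material_props(
      name = nm,
      sigma = as.numeric(m$sigma),
      chi0 = if (is.null(m$chi0)) NA_real_ else as.numeric(m$chi0),
      lambda_s = if (is.null(m$lambda_s_ppm)) NA_real_
                 else as.numeric(m$lambda_s_ppm) * 1e-6,
      density = as.numeric(m$density),
      Ms = if (is.null(m$Ms)) NA_real_ else as.numeric(m$Ms),
      poisson = if (is.null(m$poisson)) NA_real_ else as.numeric(m$poisson),
      eps_r = as.numeric(m$eps_r),
      youngs = if (is.null(m$youngs_GPa)) NA_real_
               else as.numeric(m$youngs_GPa) * 1e9,
      elasticity_voigt = elast,
      coupling_voigt = coup
    )
  })
  names(out) <- names(raw)
  out
}

# Expand 21 upper-triangle entries (column-major) into a symmetric 6x6.
voigt_from_flat <- function(x) {
  stopifnot(length(x) == 21L)
  m <- matrix(0, 6, 6)
  k <- 0L
  for (j in 1:6) {
    for (i in 1:j) {
      k <- k + 1L
      m[i, j] <- x[k]
      m[j, i] <- x[k]
    }
  }
  m
}

# Isotropic stiffness matrix (Voigt, engineering shear) from E and nu.
isotropic_stiffness <- function(youngs, poisson) {
  lam <- youngs * poisson / ((1 + poisson) * (1 - 2 * poisson))
  mu <- youngs / (2 * (1 + poisson))
  m <- matrix(0, 6, 6)
  m[1:3, 1:3] <- lam
  diag(m)[1:3] <- lam + 2 * mu
  diag(m)[4:6] <- mu
  m
}

#' Core-shell particle specification
#'
#' Geometry and materials of one core-shell particle: a magnetostrictive
#' core of radius `r_core` inside a shell of outer radius `r_total`. A pure
#' single-phase particle (e.g. a superparamagnetic iron oxide surrogate) is
#' expressed with `r_core == r_total`.
#'
#' @param r_total Outer radius (m).
#' @param r_core Core radius (m), `0 <= r_core <= r_total`.
#' @param core_material,shell_material [material_props] objects. For a
#'   single-phase particle `shell_material` may be `NULL`.
#' @param temperature Absolute temperature (K); default 300 K.
#' @return An object of class `particle_spec` with derived fields
#'   `f_core` (core volume fraction) and `v_core` (core volume, m^3).
#' @export
particle_spec <- function(r_total, r_core = r_total, core_material,
                          shell_material = NULL, temperature = 300) {
  stopifnot(r_total > 0, r_core >= 0, r_core <= r_total, temperature > 0)
  stopifnot(inherits(core_material, "material_props"))
  structure(list(r_total = r_total, r_core = r_core,
                 core_material = core_material,
                 shell_material = shell_material,
                 temperature = temperature,
                 f_core = (r_core / r_total)^3,
                 v_core = 4 / 3 * pi * r_core^3),
            class = "particle_spec")
}

#' @export
print.particle_spec <- function(x, ...) {
  cat(sprintf("particle_spec: r_total = %.3g nm, r_core = %.3g nm (f_core = %.3f)\n",
              x$r_total * 1e9, x$r_core * 1e9, x$f_core))
  cat(sprintf("  core: %s (Ms = %s A/m), shell: %s, T = %g K\n",
              x$core_material$name,
              format(x$core_material$Ms),
              if (is.null(x$shell_material)) "none" else x$shell_material$name,
              x$temperature))
  invisible(x)
}

#' Preset particles used throughout the package
#'
#' `"spion"`: a 30 nm single-phase superparamagnetic particle with
#' saturation magnetization 347.1 kA/m (the MPI tracer surrogate).
#' `"menp"`: a 30 nm core-shell particle with a 12 nm cobalt ferrite core
#' and barium titanate shell, materials from the bundled database.
#'
#' @param name `"spion"` or `"menp"`.
#' @param temperature Kelvin.
#' @param r_core_nm Core radius in nm (menp preset only; default 12).
#' @return A [particle_spec].
#' @export
particle_preset <- function(name = c("spion", "menp"), temperature = 300,
                            r_core_nm = 12) {
  name <- match.arg(name)
  mats <- load_materials()
  if (name == "spion") {
    spion_mat <- material_props("spion_iron_oxide", sigma = 0,
                                density = 5170, Ms = 347100,
                                lambda_s = NA_real_)
    particle_spec(r_total = 15e-9, r_core = 15e-9,
                  core_material = spion_mat, temperature = temperature)
  } else {
    particle_spec(r_total = 15e-9, r_core = r_core_nm * 1e-9,
                  core_material = mats$cobalt_ferrite,
                  shell_material = mats$barium_titanate,
                  temperature = temperature)
  }
}
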