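#' Core-size to magnetoelectric-slope table
#'
#' Tabulates the linear coupling slope (magnetization change per unit
#' extracellular electric field) as a function of core radius for a 30 nm
#' core-shell particle. The two anchors are the working constants of the
#' forward model: 0.02 A/m per 50 mV/mm at a 12 nm core (0.4 mA/V) and
#' 0.497 mA/V at 14 nm. Intermediate radii follow a power law through the
#' anchors (exponent `log(0.497/0.4) / log(14/12)`), which gives the
#' monotone, convex increase of sensitivity with core size; the table is a
#' configuration default, not an asserted physical law, and can be replaced
#' by a user-supplied table.
#'
#' @param radii_nm Core radii (nm) to tabulate; default 5..14.
#' @param slopes Optional explicit slopes ((A/m) per (V/m)) matching
#'   `radii_nm`; overrides the default power law.
#' @return An `me_coupling_table` data.frame with columns `r_core_nm` and
#'   `slope` ((A/m)/(V/m); numerically equal to mA/V).
#' @export
me_coupling_table <- function(radii_nm = 5:14, slopes = NULL) {
  stopifnot(all(radii_nm > 0), !is.unsorted(radii_nm, strictly = TRUE))
  if (is.null(slopes)) {
    p <- log(0.497e-3 / 0.4e-3) / log(14 / 12)
    slopes <- 0.4e-3 * (radii_nm / 12)^p
  }
  stopifnot(length(slopes) == length(radii_nm), all(slopes >= 0),
            !is.unsorted(slopes))
  structure(data.frame(r_core_nm = as.numeric(radii_nm),
                       slope = as.numeric(slopes)),
            class = c("me_coupling_table", "data.frame"))
}

#' Coupling slope for one core radius
#'
#' Linear interpolation in an [me_coupling_table]. Outside the tabulated
#' span the nearest entry is used, or an error is raised in strict mode.
#'
#' @param r_core_nm Core radius (nm), >= 0.
#' @param table An [me_coupling_table]; default table if missing.
#' @param strict Error when `r_core_nm` is outside the table span.
#' @return Slope in (A/m) per (V/m).
#' @export
slope_for_core <- function(r_core_nm, table = me_coupling_table(),
                           strict = FALSE) {
  stopifnot(is.numeric(r_core_nm), r_core_nm >= 0)
  rng <- range(table$r_core_nm)
  if (r_core_nm < rng[1] || r_core_nm > rng[2]) {
    if (strict) stop("core radius ", r_core_nm, " nm outside the table span [",
                     rng[1], ", ", rng[2], "] nm")
  }
  stats::approx(table$r_core_nm, table$slope, xout = r_core_nm, rule = 2)$y
}

#' Angular model of the field-direction dependence
#'
#' The magnetoelectric response depends on the angle `theta` between the
#' extracellular electric field and the applied bias (H) field, maximal for
#' parallel/antiparallel fields and reduced to a floor at 90 degrees:
#' `g(theta) = f_min + (1 - f_min) |cos(theta)|`, period 180 degrees,
#' mirror-symmetric about 90 degrees. Default floors are the ratios of the
#' printed angular extremes for the two observables: electric field
#' 35.62 / 539.82, flux density 0.13 / 10.14.
#'
#' @param f_min Floor factor at 90 degrees, in `[0, 1]`.
#' @return An `angular_model` list.
#' @export
angular_model <- function(f_min = 35.62 / 539.82) {
  stopifnot(f_min >= 0, f_min <= 1)
  structure(list(f_min = f_min), class = "angular_model")
}

#' Angular attenuation factor
#'
#' @param theta_deg Angle(s) between E and the bias field, degrees.
#' @param model An [angular_model].
#' @return `g(theta)` in `[f_min, 1]`, vectorized.
#' @export
angular_factor <- function(theta_deg, model = angular_model()) {
  model$f_min + (1 - model$f_min) * abs(cos(theta_deg * pi / 180))
}

#' Magnetization change from an extracellular electric field
#'
#' The linear magnetoelectric mapping at the heart of the forward model:
#' the component of the magnetization change along the bias-field direction
#' `h_hat` produced by an extracellular field `E` at a particle with the
#' given core radius.
#'
#' Two conventions are provided. `"signed_projection"` (default):
#' `dM = slope * (E . h_hat)` - linear and odd in E, producing bipolar
#' magnetization maps. `"magnitude_floor"`: `dM = slope * |E| * g(theta) *
#' sign(E . h_hat)` with the angular floor model, reproducing the
#' never-fully-nulled angular profile.
#'
#' @param E Electric field vector (V/m), or an N x 3 matrix of vectors.
#' @param h_hat Bias-field unit direction (normalized with a warning if
#'   not unit length).
#' @param r_core_nm Core radius (nm).
#' @param table [me_coupling_table].
#' @param model [angular_model] (used by the magnitude convention).
#' @param convention `"signed_projection"` or `"magnitude_floor"`.
#' @return Scalar (or length-N vector) dM along `h_hat` (A/m).
#' @export
delta_magnetization <- function(E, h_hat, r_core_nm = 12,
                                table = me_coupling_table(),
                                model = angular_model(),
                                convention = c("signed_projection",
                                               "magnitude_floor")) {
  convention <- match.arg(convention)
  h_hat <- as.numeric(h_hat)
  stopifnot(length(h_hat) == 3L)
  nh <- sqrt(sum(h_hat^2))
  if (abs(nh - 1) > 1e-8) {
    warning("h_hat is not unit length; normalizing")
    h_hat <- h_hat / nh
  }
  Em <- if (is.matrix(E)) E else matrix(as.numeric(E), ncol = 3L)
  slope <- slope_for_core(r_core_nm, table)
  proj <- as.numeric(Em %*% h_hat)
  if (convention == "signed_projection") {
    out <- slope * proj
  } else {
    Emag <- sqrt(rowSums(Em^2))
    ct <- ifelse(Emag > 0, proj / Emag, 0)
    theta <- acos(pmin(1, pmax(-1, ct))) * 180 / pi
    out <- slope * Emag * angular_factor(theta, model) * sign(proj)
  }
  if (!is.matrix(E)) out[1] else out
}

#' Particle concentration bookkeeping
#'
#' Converts between mass concentration, particle number density and
#' particle molarity under a first-principles convention: the per-particle
#' mass is the core volume times the core density plus the shell volume
#' times the shell density; number density is mass concentration divided by
#' per-particle mass; molarity is number density over Avogadro's number.
#'
#' The preset `"paper_fig4"` returns the literature working triple
#' (117.5 uM, 27.495 ug/mL, 1415 particles/um^3) verbatim with
#' `consistent = FALSE`: that triple does not satisfy the per-particle mass
#' arithmetic for a 30 nm particle and is carried only as a labelled
#' reference condition.
#'
#' @param spec [particle_spec] providing geometry and densities.
#' @param mass_conc_ug_ml Mass concentration (ug/mL); give exactly one of
#'   the three quantities.
#' @param number_density_um3 Particles per um^3.
#' @param molarity_uM Particle molarity (umol/L).
#' @param preset `"paper_fig4"` to return the reference triple.
#' @return A `concentration_spec` list with all three quantities, the
#'   per-particle mass (g), and a `consistent` flag.
#' @export
concentration_convert <- function(spec = NULL, mass_conc_ug_ml = NULL,
                                  number_density_um3 = NULL,
                                  molarity_uM = NULL, preset = NULL) {
  if (!is.null(preset)) {
    stopifnot(preset == "paper_fig4")
    return(structure(list(molarity_uM = 117.5, mass_conc_ug_ml = 27.495,
                          number_density_um3 = 1415,
                          particle_mass_g = NA_real_,
                          consistent = FALSE, preset = preset),
                     class = "concentration_spec"))
  }
  stopifnot(inherits(spec, "particle_spec"))
  v_core <- spec$v_core                                  # m^3
  v_shell <- 4 / 3 * pi * spec$r_total^3 - v_core
  rho_core <- spec$core_material$density
  rho_shell <- if (is.null(spec$shell_material)) rho_core
               else spec$shell_material$density
  m_p_kg <- v_core * rho_core + v_shell * rho_shell
  m_p_g <- m_p_kg * 1e3
  given <- c(mass = !is.null(mass_conc_ug_ml),
             num = !is.null(number_density_um3),
             mol = !is.null(molarity_uM))
  if (sum(given) != 1L) stop("give exactly one concentration quantity")
  if (given["mass"]) {
    # ug/mL -> g/um^3: 1 ug = 1e-6 g, 1 mL = 1e12 um^3
    number_density_um3 <- mass_conc_ug_ml * 1e-6 / 1e12 / m_p_g
  } else if (given["mol"]) {
    # umol/L -> particles/um^3: 1 L = 1e15 um^3
    number_density_um3 <- molarity_uM * 1e-6 * N_AVOGADRO / 1e15
  }
  mass_conc_ug_ml <- number_density_um3 * m_p_g * 1e12 * 1e6
  molarity_uM <- number_density_um3 * 1e15 / N_AVOGADRO * 1e6
  structure(list(molarity_uM = molarity_uM,
                 mass_conc_ug_ml = mass_conc_ug_ml,
                 number_density_um3 = number_density_um3,
                 particle_mass_g = m_p_g,
                 consistent = TRUE, preset = NULL),
            class = "concentration_spec")
}

#' Apply the magnetoelectric mapping over a field grid
#'
#' Elementwise [delta_magnetization] at every lattice site and time frame
#' of a populated field grid, scaled by a concentration factor. Linear in
#' the electric field.
#'
#' @param grid A `field_grid` with E populated (see [efield_from_potential]).
#' @param h_hat Bias-field unit direction.
#' @param r_core_nm Core radius (nm).
#' @param table,model,convention As in [delta_magnetization].
#' @param scale Concentration scale factor (dimensionless); default 1.
#' @return A `magnetization_field`: list with `coords` (um), `t` (ms),
#'   `dM` (sites x time matrix, A/m), `dims`, `spacing`.
#' @export
voxel_magnetization <- function(grid, h_hat = c(1, 0, 0), r_core_nm = 12,
                                table = me_coupling_table(),
                                model = angular_model(),
                                convention = "signed_projection",
                                scale = 1) {
  stopifnot(inherits(grid, "field_grid"), !is.null(grid$E))
  nt <- length(grid$t)
  n <- nrow(grid$coords)
  dM <- matrix(0, n, nt)
  for (j in seq_len(nt)) {
    dM[, j] <- scale * delta_magnetization(grid$E[, , j], h_hat, r_core_nm,
                                           table, model, convention)
  }
  structure(list(coords = grid$coords, t = grid$t, dM = dM,
                 dims = grid$dims, spacing = grid$spacing,
                 h_hat = h_hat, convention = convention),
            class = "magnetization_field")
}
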