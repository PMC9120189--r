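# Biphasic zero-integral current template: Gaussian derivative with peak
# `amplitude` and lobe width `width`, centered 4 widths after t = 0 so the
# truncated left tail is negligible.
ap_template <- function(t_ms, width_ms = 0.5, amplitude = 1) {
  u <- (t_ms - 4 * width_ms) / width_ms
  -amplitude * sqrt(2 * exp(1)) * u * exp(-u^2)
}

#' Action-potential transmembrane current source
#'
#' Template-based surrogate for membrane biophysics: a biphasic,
#' zero-integral current waveform is injected at the soma and propagated
#' along axonal and dendritic paths with a conduction delay
#' (`path distance / speed`) and exponential amplitude attenuation. At
#' every time sample the summed current over the cell is balanced to zero
#' by a distributed return current weighted by compartment membrane area
#' (current conservation: a neuron is electrically closed).
#'
#' The default waveform is the derivative of a Gaussian (depolarizing then
#' repolarizing lobe, peak `amplitude_nA`, lobe width `width_ms`, centered
#' `4 * width_ms` after onset), which integrates to zero analytically.
#'
#' @param morph A `morphology`.
#' @param t_ms Time axis (ms), regular.
#' @param onset_ms Waveform onset at the soma (ms); default 2.
#' @param amplitude_nA Peak soma current (nA); default 1.
#' @param width_ms Gaussian lobe width (ms); default 0.5.
#' @param speed_um_ms Conduction speed (um/ms); default 500.
#' @param lambda_um Attenuation length constant (um); default 300.
#' @param waveform Optional function `t_ms -> nA` replacing the default;
#'   must integrate to ~0 over `t_ms`.
#' @return A `segment_currents` list: `t_ms`, `I` (nodes x time matrix,
#'   nA; row order matches `morph`), `morph`.
#' @export
ap_current_source <- function(morph, t_ms, onset_ms = 2, amplitude_nA = 1,
                              width_ms = 0.5, speed_um_ms = 500,
                              lambda_um = 300, waveform = NULL) {
  stopifnot(inherits(morph, "morphology"), length(t_ms) > 1)
  if (is.null(waveform)) {
    waveform <- function(t) ap_template(t, width_ms, amplitude_nA)
  }
  dt <- t_ms[2] - t_ms[1]
  w_int <- sum(waveform(seq(0, 20, by = dt / 4))) * dt / 4
  w_peak <- max(abs(waveform(seq(0, 20, by = dt / 4))))
  if (w_peak > 0 && abs(w_int) > 1e-6 * w_peak * 20) {
    stop("waveform does not integrate to zero over its support")
  }
  n <- nrow(morph)
  pd <- node_path_dist(morph)
  I <- matrix(0, n, length(t_ms))
  for (i in seq_len(n)) {
    delay <- pd[i] / speed_um_ms
    att <- exp(-pd[i] / lambda_um)
    I[i, ] <- att * waveform(t_ms - onset_ms - delay)
  }
  # distributed return current, area-weighted, enforcing sum_i I_i(t) = 0
  area <- morph$radius^2
  area <- area / sum(area)
  net <- colSums(I)
  I <- I - outer(area, net)
  structure(list(t_ms = t_ms, I = I, morph = morph),
            class = "segment_currents")
}

#' Extracellular potential of compartmental current sources
#'
#' Volume-conductor forward model in an infinite homogeneous medium of
#' conductivity `sigma_ext`. Soma nodes (SWC type 1) are point sources,
#' `phi = I / (4 pi sigma r)`; neurite compartments use the standard
#' line-source kernel integrating a uniform current density along the
#' parent-to-node segment. Distances are clamped to the compartment radius
#' to avoid the singularity at the membrane.
#'
#' @param morph A `morphology`.
#' @param currents A `segment_currents` for `morph` (nA).
#' @param sites N x 3 matrix of recording coordinates (um).
#' @param sigma_ext Extracellular conductivity (S/m); default 0.3.
#' @return N x T matrix of potentials (mV).
#' @export
extracellular_potential <- function(morph, currents, sites,
                                    sigma_ext = 0.3) {
  stopifnot(sigma_ext > 0)
  sites <- matrix(as.numeric(sites), ncol = 3L)
  n_sites <- nrow(sites)
  I <- currents$I                              # nodes x time, nA
  # geometry kernel G (sites x nodes): phi_mV = G %*% I_nA
  # units: nA / (S/m x um) = 1e-9 A / (1e-6 S) = 1e-3 V = mV, so the
  # closed forms below in (nA, um, S/m) yield mV directly.
  idx <- match(morph$parent, morph$id)
  G <- matrix(0, n_sites, nrow(morph))
  for (i in seq_len(nrow(morph))) {
    if (morph$type[i] == 1L || is.na(idx[i])) {
      # point source at the node (soma or root)
      r <- sqrt((sites[, 1] - morph$x[i])^2 + (sites[, 2] - morph$y[i])^2 +
                (sites[, 3] - morph$z[i])^2)
      r <- pmax(r, morph$radius[i])
      G[, i] <- 1 / (4 * pi * sigma_ext * r)
    } else {
      p0 <- c(morph$x[idx[i]], morph$y[idx[i]], morph$z[idx[i]])
      p1 <- c(morph$x[i], morph$y[i], morph$z[i])
      ds <- sqrt(sum((p1 - p0)^2))
      if (ds == 0) {
        r <- sqrt(rowSums(sweep(sites, 2, p1)^2))
        r <- pmax(r, morph$radius[i])
        G[, i] <- 1 / (4 * pi * sigma_ext * r)
        next
      }
      u <- (p1 - p0) / ds
      rel <- sweep(sites, 2, p1)               # from distal end
      h <- as.numeric(rel %*% u)               # longitudinal, from end
      r2 <- rowSums(rel^2) - h^2
      r2 <- pmax(r2, morph$radius[i]^2)
      l <- h + ds
      num <- sqrt(h^2 + r2) - h
      den <- sqrt(l^2 + r2) - l
      bad <- num <= 0 | den <= 0
      if (any(bad)) stop("recording site coincides with a source line")
      G[, i] <- log(num / den) / (4 * pi * sigma_ext * ds)
    }
  }
  G %*% I
}

#' Regular recording lattice and field container
#'
#' Builds the inclusive lattice of recording sites over a rectangular
#' voxel: each axis has `dim / spacing + 1` planes including both
#' boundaries.
#'
#' @param dims_um Length-3 voxel dimensions (um); must be divisible by
#'   `spacing_um`.
#' @param spacing_um Lattice spacing (um).
#' @param origin Length-3 lower corner (um); default 0.
#' @param t_ms Optional time axis (ms).
#' @return A `field_grid` list: `coords` (N x 3 um, x fastest), `dims`
#'   (planes per axis), `spacing`, `origin`, `t`, and slots `phi`
#'   (N x T, mV) and `E` (N x 3 x T, V/m) populated later.
#' @export
field_grid <- function(dims_um, spacing_um, origin = c(0, 0, 0),
                       t_ms = NULL) {
  stopifnot(length(dims_um) == 3L, spacing_um > 0)
  rem <- dims_um %% spacing_um
  if (any(abs(rem) > 1e-9 & abs(rem - spacing_um) > 1e-9)) {
    stop("voxel dimensions must be divisible by the spacing; nearest valid ",
         "spacings divide ", paste(dims_um, collapse = " x "), " um exactly")
  }
  n_axis <- as.integer(round(dims_um / spacing_um)) + 1L
  ax <- lapply(1:3, function(k) origin[k] + spacing_um * (seq_len(n_axis[k]) - 1L))
  coords <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]],
                                  KEEP.OUT.ATTRS = FALSE))
  dimnames(coords) <- NULL
  structure(list(coords = coords, dims = n_axis, spacing = spacing_um,
                 origin = origin, t = t_ms, phi = NULL, E = NULL,
                 sigma_ext = NA_real_),
            class = "field_grid")
}

#' Number and coordinates of lattice sites
#'
#' Convenience wrapper returning the site coordinates of the inclusive
#' lattice (see [field_grid]); `n_sites` of the default cortical voxel
#' (200 x 700 x 200 um at 5 um) is 41 x 141 x 41 = 237,021.
#'
#' @inheritParams field_grid
#' @return Matrix of site coordinates with attribute `n_axis`.
#' @export
grid_sites <- function(dims_um, spacing_um, origin = c(0, 0, 0)) {
  g <- field_grid(dims_um, spacing_um, origin)
  structure(g$coords, n_axis = g$dims)
}

#' Populate the electric field from the lattice potential
#'
#' `E = -grad(phi)` by second-order central differences on the regular
#' lattice (one-sided differences at the boundary planes). Potentials in
#' mV on a um lattice convert to V/m with a factor 1000
#' (1 mV/um = 1000 V/m), applied here.
#'
#' @param grid A `field_grid` with `phi` populated (N x T, mV).
#' @return The grid with `E` (N x 3 x T, V/m) populated.
#' @export
efield_from_potential <- function(grid) {
  stopifnot(inherits(grid, "field_grid"), !is.null(grid$phi))
  d <- grid$dims
  if (any(d < 3L)) stop("need at least 3 lattice planes per axis for gradients")
  nt <- ncol(grid$phi)
  n <- nrow(grid$coords)
  E <- array(0, c(n, 3L, nt))
  h <- grid$spacing
  grad1 <- function(a) {
    # d/dx along the first dimension of a 3-d array, central in the
    # interior, one-sided at the two boundary planes
    np <- dim(a)[1]
    g <- a
    g[2:(np - 1), , ] <- (a[3:np, , , drop = FALSE] -
                          a[1:(np - 2), , , drop = FALSE]) / (2 * h)
    g[1, , ] <- (a[2, , ] - a[1, , ]) / h
    g[np, , ] <- (a[np, , ] - a[np - 1, , ]) / h
    g
  }
  for (j in seq_len(nt)) {
    phi <- array(grid$phi[, j], dim = d)     # x fastest, matches expand.grid
    for (ax in 1:3) {
      perm <- c(ax, setdiff(1:3, ax))
      g <- aperm(grad1(aperm(phi, perm)), order(perm))
      E[, ax, j] <- -as.numeric(g) * 1000    # mV/um -> V/m
    }
  }
  grid$E <- E
  grid
}

#' Classify lattice sites by nearest neuronal compartment
#'
#' Labels each site by the type of the nearest compartment whose distance
#' is within the inclusion zone; ties across types at identical distance
#' are broken by the precedence soma > axon > dendrite. Sites beyond every
#' zone are `"none"`.
#'
#' @param morph A `morphology`.
#' @param sites N x 3 matrix (um).
#' @param zone_radius_um Inclusion zone radius (um); default 20.
#' @return Factor of length N with levels somatic/axonal/dendritic/none.
#' @export
classify_sites <- function(morph, sites, zone_radius_um = 20) {
  stopifnot(zone_radius_um > 0)
  sites <- matrix(as.numeric(sites), ncol = 3L)
  segs <- morph_segments(morph)
  # distance site -> each compartment (soma nodes as points, neurites as
  # segments)
  types <- c(somatic = 1L, axonal = 2L, dendritic = 3L)
  best <- matrix(Inf, nrow(sites), 3L)
  soma <- morph[morph$type == 1L, , drop = FALSE]
  for (i in seq_len(nrow(soma))) {
    d <- sqrt((sites[, 1] - soma$x[i])^2 + (sites[, 2] - soma$y[i])^2 +
              (sites[, 3] - soma$z[i])^2)
    best[, 1] <- pmin(best[, 1], d)
  }
  for (i in seq_len(nrow(segs))) {
    if (segs$type[i] == 1L) next
    p0 <- c(segs$x0[i], segs$y0[i], segs$z0[i])
    p1 <- c(segs$x1[i], segs$y1[i], segs$z1[i])
    v <- p1 - p0
    L2 <- sum(v^2)
    rel <- sweep(sites, 2, p0)
    tpar <- if (L2 > 0) pmin(1, pmax(0, as.numeric(rel %*% v) / L2)) else 0
    dx <- rel - outer(tpar, v)
    d <- sqrt(rowSums(dx^2))
    col <- match(segs$type[i], types)
    if (!is.na(col)) best[, col] <- pmin(best[, col], d)
  }
  within <- best <= zone_radius_um
  lab <- rep("none", nrow(sites))
  hit <- which(rowSums(within) > 0)
  for (i in hit) {
    cand <- which(within[i, ])
    lab[i] <- names(types)[cand[which.min(best[i, cand])]]
    # exact-tie precedence: lower type index wins
    mins <- cand[abs(best[i, cand] - min(best[i, cand])) < 1e-12]
    lab[i] <- names(types)[min(mins)]
  }
  factor(lab, levels = c("somatic", "axonal", "dendritic", "none"))
}

#' Per-compartment-zone summary at the activity peak
#'
#' Finds the single time of maximal spatially integrated |dM| within the
#' analysis window and summarizes |dM| per site category at that time:
#' mean, quartiles, and Tukey outlier fences (Q1 - 1.5 IQR, Q3 + 1.5 IQR).
#'
#' @param mag_field A `magnetization_field` (see [voxel_magnetization]).
#' @param categories Factor from [classify_sites], length = number of
#'   sites.
#' @param window_ms Analysis window (ms); default `c(0, 20)`.
#' @return List with `peak_time_ms` and `summary`, a data.frame with one
#'   row per non-empty category.
#' @export
peak_window_summary <- function(mag_field, categories,
                                window_ms = c(0, 20)) {
  stopifnot(inherits(mag_field, "magnetization_field"),
            length(categories) == nrow(mag_field$dM))
  sel <- which(mag_field$t >= window_ms[1] & mag_field$t <= window_ms[2])
  if (length(sel) == 0L) stop("field does not cover the analysis window")
  tot <- colSums(abs(mag_field$dM[, sel, drop = FALSE]))
  jt <- sel[which.max(tot)]
  v <- abs(mag_field$dM[, jt])
  out <- lapply(levels(categories), function(cl) {
    x <- v[categories == cl]
    if (length(x) == 0L) return(NULL)
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- q[3] - q[1]
    data.frame(category = cl, n = length(x), mean = mean(x),
               q1 = q[1], median = q[2], q3 = q[3],
               fence_low = q[1] - 1.5 * iqr, fence_high = q[3] + 1.5 * iqr)
  })
  empty <- levels(categories)[vapply(out, is.null, logical(1))]
  if (length(empty) > 0) {
    message("empty categories omitted: ", paste(empty, collapse = ", "))
  }
  list(peak_time_ms = mag_field$t[jt],
       summary = do.call(rbind, out[!vapply(out, is.null, logical(1))]))
}
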