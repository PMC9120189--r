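#' Cortical layer specification
#'
#' One neocortical layer of the simulated 200 x 200 um column: its
#' thickness and its excitatory/inhibitory cell counts.
#'
#' @param name Layer label ("II", "III", "IV", ...).
#' @param thickness_um Layer depth extent (um).
#' @param n_exc,n_inh Cell counts, >= 0.
#' @return A `layer_spec` list.
#' @export
layer_spec <- function(name, thickness_um, n_exc, n_inh) {
  stopifnot(thickness_um > 0, n_exc >= 0, n_inh >= 0)
  structure(list(name = name, thickness_um = thickness_um,
                 n_exc = as.integer(n_exc), n_inh = as.integer(n_inh)),
            class = "layer_spec")
}

#' Default layered cortical column
#'
#' Layers II, III and IV with thicknesses 150, 350 and 200 um and
#' excitatory:inhibitory counts 895:95, 988:188 and 970:170 (totals 990,
#' 1176 and 1140), the reference composition of the simulated voxel.
#'
#' @param scale Multiply all cell counts by this factor (rounded); useful
#'   for reduced-size runs. Default 1.
#' @return List of three [layer_spec]s.
#' @export
default_layers <- function(scale = 1) {
  list(layer_spec("II", 150, round(895 * scale), round(95 * scale)),
       layer_spec("III", 350, round(988 * scale), round(188 * scale)),
       layer_spec("IV", 200, round(970 * scale), round(170 * scale)))
}

#' Synaptic kinetic parameters
#'
#' Bi-exponential synapse time constants and reversal potential. The
#' reference values (excitatory tau1 = 0.8 s, tau2 = 5.3 s, reversal 0 mV;
#' inhibitory tau1 = 0.6 s, tau2 = 8.5 s, reversal -75 mV) are carried as
#' printed in seconds; `tau_units = "ms"` reinterprets them as
#' milliseconds for users who consider second-scale receptor kinetics a
#' transcription artefact.
#'
#' @param tau1,tau2 Rise and decay time constants; `tau2 > tau1 > 0`.
#' @param v_rev Synaptic reversal potential (mV).
#' @param tau_units `"s"` (default) or `"ms"`.
#' @return A `synapse_params` list with taus in ms.
#' @export
synapse_params <- function(tau1, tau2, v_rev, tau_units = c("s", "ms")) {
  tau_units <- match.arg(tau_units)
  stopifnot(tau2 > tau1, tau1 > 0)
  f <- if (tau_units == "s") 1000 else 1
  structure(list(tau1_ms = tau1 * f, tau2_ms = tau2 * f, v_rev = v_rev,
                 tau_units = tau_units),
            class = "synapse_params")
}

#' Build the layered network
#'
#' Places cells uniformly at random within their layer slab of the
#' 200 x 200 um column (x, z in [0, 200] um; y is depth from the top of
#' layer II) and wires them by the reference rules: excitatory cells
#' project to all cells with probability 0.1 and weight `25 * y_norm`
#' (`y_norm = y / total depth` of the presynaptic cell); inhibitory cells
#' project to excitatory cells only, with distance-dependent probability
#' `0.4 * exp(-d / 150 um)` and weight 5. There are never
#' inhibitory-to-inhibitory connections. Reproducible per seed.
#'
#' @param layers List of [layer_spec]; default [default_layers()].
#' @param column_um Column cross-section side (um); default 200.
#' @param p_ee Excitatory connection probability; default 0.1.
#' @param w_e_max Excitatory weight scale (weight = `w_e_max * y_norm`);
#'   default 25.
#' @param w_i Inhibitory weight; default 5.
#' @param p_i_max,lambda_um Inhibitory probability amplitude and length
#'   constant; defaults 0.4 and 150 um.
#' @param seed RNG seed.
#' @return A `me_network` list: `cells` (data.frame id, type, layer, x, y,
#'   z, y_norm), `edges` (data.frame pre, post, weight, type), `depth_um`,
#'   and the rule parameters.
#' @export
build_network <- function(layers = default_layers(), column_um = 200,
                          p_ee = 0.1, w_e_max = 25, w_i = 5, p_i_max = 0.4,
                          lambda_um = 150, seed = 1L) {
  stopifnot(length(layers) >= 1L)
  set.seed(seed)
  depth_tot <- sum(vapply(layers, `[[`, numeric(1), "thickness_um"))
  y0 <- 0
  cells <- list()
  for (ly in layers) {
    n <- ly$n_exc + ly$n_inh
    if (n == 0L) stop("empty layer: ", ly$name)
    cells[[length(cells) + 1L]] <- data.frame(
      type = rep(c("E", "I"), c(ly$n_exc, ly$n_inh)),
      layer = ly$name,
      x = stats::runif(n, 0, column_um),
      y = stats::runif(n, y0, y0 + ly$thickness_um),
      z = stats::runif(n, 0, column_um))
    y0 <- y0 + ly$thickness_um
  }
  cells <- do.call(rbind, cells)
  cells$id <- seq_len(nrow(cells))
  cells$y_norm <- cells$y / depth_tot
  cells <- cells[, c("id", "type", "layer", "x", "y", "z", "y_norm")]

  e_ids <- cells$id[cells$type == "E"]
  i_ids <- cells$id[cells$type == "I"]
  n <- nrow(cells)
  edges <- vector("list", length(e_ids) + length(i_ids))
  k <- 0L
  for (pre in e_ids) {
    post <- which(stats::runif(n) < p_ee)
    post <- post[post != pre]
    if (length(post) > 0L) {
      k <- k + 1L
      edges[[k]] <- data.frame(pre = pre, post = post,
                               weight = w_e_max * cells$y_norm[pre],
                               type = "E")
    }
  }
  if (length(i_ids) > 0L && length(e_ids) > 0L) {
    ex <- cells[e_ids, c("x", "y", "z")]
    for (pre in i_ids) {
      d <- sqrt((ex$x - cells$x[pre])^2 + (ex$y - cells$y[pre])^2 +
                (ex$z - cells$z[pre])^2)
      post <- e_ids[stats::runif(length(e_ids)) < p_i_max * exp(-d / lambda_um)]
      if (length(post) > 0L) {
        k <- k + 1L
        edges[[k]] <- data.frame(pre = pre, post = post, weight = w_i,
                                 type = "I")
      }
    }
  }
  edges <- if (k > 0L) do.call(rbind, edges[seq_len(k)]) else
    data.frame(pre = integer(0), post = integer(0), weight = numeric(0),
               type = character(0))
  structure(list(cells = cells, edges = edges, depth_um = depth_tot,
                 column_um = column_um,
                 rules = list(p_ee = p_ee, w_e_max = w_e_max, w_i = w_i,
                              p_i_max = p_i_max, lambda_um = lambda_um),
                 seed = seed),
            class = "me_network")
}

#' @export
print.me_network <- function(x, ...) {
  cat(sprintf("me_network: %d cells (%d E, %d I), %d edges, depth %g um\n",
              nrow(x$cells), sum(x$cells$type == "E"),
              sum(x$cells$type == "I"), nrow(x$edges), x$depth_um))
  invisible(x)
}

#' Simulate the network with leaky integrate-and-fire dynamics
#'
#' Surrogate spiking dynamics on a built network: leaky integrate-and-fire
#' membranes with conductance-based bi-exponential synapses (reference
#' kinetics via [synapse_params]), spike-frequency adaptation (which
#' terminates population bursts), and a noisy external drive (which
#' re-ignites them). The default configuration is tuned to produce
#' recurring population bursts within a 140 ms window. Deterministic per
#' seed.
#'
#' @param net A `me_network`.
#' @param duration_ms Simulated time (ms); default 140.
#' @param dt_ms Integration step (ms); default 0.1 (100 us).
#' @param exc,inh [synapse_params] for the two synapse classes.
#' @param v_rest,v_th,v_reset Membrane parameters (mV); defaults -65, -50,
#'   -65.
#' @param tau_m_ms Membrane time constant; default 20 ms.
#' @param refract_ms Absolute refractory period; default 3 ms.
#' @param g_unit_e,g_unit_i Conductance increment per unit synaptic weight
#'   (dimensionless, relative to leak) for the slow (reference-kinetics)
#'   component; tuned defaults.
#' @param g_fast_e,g_fast_i Conductance increments of an additional fast
#'   synaptic component (exponential decay `tau_fast_e_ms`/`tau_fast_i_ms`,
#'   same reversal potentials and connectivity). The reference kinetics are
#'   second-scale and cannot regenerate activity within a millisecond-scale
#'   burst; the fast component supplies the within-burst recruitment that
#'   makes population bursts all-or-none. Set both to 0 to use the slow
#'   kinetics alone.
#' @param tau_fast_e_ms,tau_fast_i_ms Fast-component decay constants (ms).
#' @param adapt_b,adapt_tau_ms Adaptation increment per spike (mV
#'   equivalent) and decay time constant.
#' @param drive_mu,drive_sigma Mean and per-cell SD of the external drive
#'   (mV of steady-state depolarization).
#' @param drive_common_sigma,drive_common_tau_ms SD (mV) and correlation
#'   time of a population-wide Ornstein-Uhlenbeck drive component (shared
#'   background fluctuations).
#' @param burst_rate_hz,burst_pulse_mv,burst_pulse_ms Rate, amplitude and
#'   width of population-wide burst-initiation pulses (Poisson process,
#'   deterministic per seed), standing in for the external volleys that
#'   ignite cortical population bursts; each pulse is amplified into a
#'   synchronized network burst by the recurrent fast excitation and
#'   terminated by adaptation and refractoriness.
#' @param burn_in_ms Initial transient simulated and discarded before
#'   t = 0 (the random membrane initialization otherwise produces one
#'   artificially synchronized volley); default 30 ms.
#' @param rate_ceiling_hz Abort if the population rate exceeds this
#'   (instability guard); default 400 Hz.
#' @param seed RNG seed.
#' @return A `spike_raster` list: `spikes` (data.frame cell, t_ms, type,
#'   layer), `duration_ms`, `n_cells`, `net`.
#' @export
simulate_network <- function(net, duration_ms = 140, dt_ms = 0.1,
                             exc = synapse_params(0.8, 5.3, 0),
                             inh = synapse_params(0.6, 8.5, -75),
                             v_rest = -65, v_th = -50, v_reset = -65,
                             tau_m_ms = 20, refract_ms = 3,
                             g_unit_e = 5e-5, g_unit_i = 2e-4,
                             g_fast_e = 2.5e-3, g_fast_i = 0.05,
                             tau_fast_e_ms = 3, tau_fast_i_ms = 8,
                             adapt_b = 30, adapt_tau_ms = 15,
                             drive_mu = 13.5, drive_sigma = 3,
                             drive_common_sigma = 3,
                             drive_common_tau_ms = 5,
                             burst_rate_hz = 45, burst_pulse_mv = 30,
                             burst_pulse_ms = 3,
                             burn_in_ms = 30, rate_ceiling_hz = 400,
                             seed = 1L) {
  stopifnot(inherits(net, "me_network"), dt_ms <= 1, duration_ms > 0)
  set.seed(seed)
  n <- nrow(net$cells)
  steps <- round((duration_ms + burn_in_ms) / dt_ms)
  # sparse weight matrices, post x pre
  W_e <- W_i <- NULL
  ed <- net$edges
  if (nrow(ed) > 0) {
    ee <- ed[ed$type == "E", ]
    ii <- ed[ed$type == "I", ]
    W_e <- Matrix::sparseMatrix(i = ee$post, j = ee$pre, x = ee$weight,
                                dims = c(n, n))
    W_i <- Matrix::sparseMatrix(i = ii$post, j = ii$pre, x = ii$weight,
                                dims = c(n, n))
  }
  de1 <- exp(-dt_ms / exc$tau1_ms); de2 <- exp(-dt_ms / exc$tau2_ms)
  di1 <- exp(-dt_ms / inh$tau1_ms); di2 <- exp(-dt_ms / inh$tau2_ms)
  v <- rep(v_rest, n) + stats::runif(n, 0, v_th - v_rest) * 0.5
  xe1 <- xe2 <- xi1 <- xi2 <- xfe <- xfi <- numeric(n)
  w_ad <- stats::runif(n, 0, adapt_b)   # spread initial adaptation so the
  refr <- numeric(n)                    # first burst is not anomalously large
  common <- 0
  dfe <- exp(-dt_ms / tau_fast_e_ms); dfi <- exp(-dt_ms / tau_fast_i_ms)
  # burst-initiation pulse train (Poisson), drawn up front
  n_pulse <- stats::rpois(1, burst_rate_hz * (duration_ms + burn_in_ms) / 1000)
  pulse_t <- sort(stats::runif(n_pulse, -burn_in_ms, duration_ms))
  spk_cell <- integer(0); spk_t <- numeric(0)
  dad <- exp(-dt_ms / adapt_tau_ms)
  for (s in seq_len(steps)) {
    t_now <- s * dt_ms - burn_in_ms
    g_e <- (xe2 - xe1) * g_unit_e + xfe * g_fast_e
    g_i <- (xi2 - xi1) * g_unit_i + xfi * g_fast_i
    common <- common - dt_ms / drive_common_tau_ms * common +
      drive_common_sigma * sqrt(2 * dt_ms / drive_common_tau_ms) *
      stats::rnorm(1)
    pulse <- if (n_pulse > 0) {
      burst_pulse_mv * sum(t_now - pulse_t >= 0 &
                           t_now - pulse_t < burst_pulse_ms)
    } else 0
    I_syn <- g_e * (exc$v_rev - v) + g_i * (inh$v_rev - v)
    dv <- (-(v - v_rest) + drive_mu + common + pulse + I_syn * tau_m_ms -
           w_ad) / tau_m_ms
    noise <- drive_sigma * sqrt(2 * dt_ms / tau_m_ms) * stats::rnorm(n)
    act <- refr <= 0
    v[act] <- v[act] + dt_ms * dv[act] + noise[act]
    refr[!act] <- refr[!act] - dt_ms
    fired <- which(v >= v_th & act)
    if (length(fired) > 0L) {
      v[fired] <- v_reset
      refr[fired] <- refract_ms
      w_ad[fired] <- w_ad[fired] + adapt_b
      spk_cell <- c(spk_cell, fired)
      spk_t <- c(spk_t, rep(t_now, length(fired)))
      if (!is.null(W_e)) {
        inc <- numeric(n); inc[fired] <- 1
        we <- as.numeric(W_e %*% inc)
        wi <- as.numeric(W_i %*% inc)
        xe1 <- xe1 + we; xe2 <- xe2 + we; xfe <- xfe + we
        xi1 <- xi1 + wi; xi2 <- xi2 + wi; xfi <- xfi + wi
      }
    }
    xe1 <- xe1 * de1; xe2 <- xe2 * de2
    xi1 <- xi1 * di1; xi2 <- xi2 * di2
    xfe <- xfe * dfe; xfi <- xfi * dfi
    w_ad <- w_ad * dad
    if (t_now > 20 &&
        sum(spk_t >= 0) / n / (t_now / 1000) > rate_ceiling_hz) {
      stop("population rate exceeded ", rate_ceiling_hz,
           " Hz: unstable parameters")
    }
  }
  keep <- spk_t >= 0
  spk_cell <- spk_cell[keep]; spk_t <- spk_t[keep]
  spikes <- data.frame(cell = spk_cell, t_ms = spk_t,
                       type = net$cells$type[spk_cell],
                       layer = net$cells$layer[spk_cell])
  spikes <- spikes[order(spikes$t_ms, spikes$cell), ]
  rownames(spikes) <- NULL
  structure(list(spikes = spikes, duration_ms = duration_ms,
                 n_cells = n, net = net, seed = seed),
            class = "spike_raster")
}

#' Detect population bursts
#'
#' Bins the population firing rate, smooths it with a short moving
#' average, and returns the times of local maxima exceeding
#' `mean + 2 SD` of the smoothed rate, with a minimum separation of 10 ms
#' (higher peaks win).
#'
#' @param raster A `spike_raster` or a data.frame with columns `cell`,
#'   `t_ms`.
#' @param duration_ms Window length (required if `raster` is a plain
#'   data.frame).
#' @param bin_ms Rate bin (ms); default 1.
#' @param smooth_ms Moving-average width (ms); default 5.
#' @param min_sep_ms Minimum peak separation (ms); default 10.
#' @param n_sd Threshold in SDs above the mean; default 2.
#' @return Numeric vector of burst peak times (ms), possibly empty.
#' @export
detect_bursts <- function(raster, duration_ms = NULL, bin_ms = 1,
                          smooth_ms = 5, min_sep_ms = 10, n_sd = 2) {
  if (inherits(raster, "spike_raster")) {
    duration_ms <- raster$duration_ms
    spikes <- raster$spikes
  } else {
    spikes <- raster
    if (is.null(duration_ms)) duration_ms <- max(spikes$t_ms, 0)
  }
  if (nrow(spikes) == 0L) return(numeric(0))
  breaks <- seq(0, duration_ms + bin_ms, by = bin_ms)
  rate <- graphics::hist(spikes$t_ms, breaks = breaks, plot = FALSE)$counts
  k <- max(1L, round(smooth_ms / bin_ms))
  sm <- as.numeric(stats::filter(rate, rep(1 / k, k), sides = 2))
  sm[is.na(sm)] <- 0
  thr <- mean(sm) + n_sd * stats::sd(sm)
  centers <- breaks[-length(breaks)] + bin_ms / 2
  cand <- which(sm > thr)
  cand <- cand[sm[cand] >= c(-Inf, sm)[cand] & sm[cand] >= sm[pmin(cand + 1,
                                                        length(sm))]]
  if (length(cand) == 0L) return(numeric(0))
  cand <- cand[order(-sm[cand])]
  keep <- integer(0)
  for (i in cand) {
    if (all(abs(centers[i] - centers[keep]) >= min_sep_ms)) {
      keep <- c(keep, i)
    }
  }
  # localize each peak at the raw-rate maximum within the smoothing window
  half <- floor(k / 2)
  refined <- vapply(keep, function(i) {
    win <- max(1L, i - half):min(length(rate), i + half)
    centers[win[which.max(rate[win])]]
  }, numeric(1))
  sort(refined)
}

#' Point-source currents of network spikes
#'
#' Maps each point neuron onto a current dipole for the volume-conductor
#' solver: a biphasic zero-integral template at the soma position at each
#' spike time, with the opposite current at a counter-pole displaced
#' `dipole_um` along +y (distributed neurite return). The summed current
#' over the network is identically zero at every time.
#'
#' @param raster A `spike_raster`.
#' @param t_ms Output time axis (ms), regular.
#' @param amplitude_nA Template peak (nA); default 1.
#' @param width_ms Template lobe width (ms); default 0.5.
#' @param dipole_um Dipole length (um); default 100.
#' @return List: `positions` (2 n_active x 3 um), `I` (sources x time,
#'   nA), `t_ms`.
#' @export
network_source_currents <- function(raster, t_ms, amplitude_nA = 1,
                                    width_ms = 0.5, dipole_um = 100) {
  stopifnot(inherits(raster, "spike_raster"))
  cells <- raster$net$cells
  spikes <- raster$spikes
  active <- sort(unique(spikes$cell))
  n_a <- length(active)
  I_soma <- matrix(0, n_a, length(t_ms))
  template <- function(t) ap_template(t, width_ms, amplitude_nA)
  for (j in seq_len(n_a)) {
    ts <- spikes$t_ms[spikes$cell == active[j]]
    for (t0 in ts) I_soma[j, ] <- I_soma[j, ] + template(t_ms - t0)
  }
  positions <- rbind(as.matrix(cells[active, c("x", "y", "z")]),
                     as.matrix(cells[active, c("x", "y", "z")]) +
                       matrix(c(0, dipole_um, 0), n_a, 3, byrow = TRUE))
  dimnames(positions) <- NULL
  list(positions = positions, I = rbind(I_soma, -I_soma), t_ms = t_ms)
}

#' Extracellular potential of network point sources
#'
#' Superposed point-source potentials `I / (4 pi sigma r)` on the lattice,
#' chunked over sources to bound memory.
#'
#' @param sources Output of [network_source_currents].
#' @param grid A `field_grid`.
#' @param sigma_ext Extracellular conductivity (S/m); default 0.3.
#' @param min_dist_um Distance clamp (um); default 5.
#' @return The grid with `phi` (N x T, mV) populated and `t` set.
#' @export
network_potential <- function(sources, grid, sigma_ext = 0.3,
                              min_dist_um = 5) {
  stopifnot(inherits(grid, "field_grid"))
  n_sites <- nrow(grid$coords)
  phi <- matrix(0, n_sites, length(sources$t_ms))
  n_src <- nrow(sources$positions)
  chunk <- max(1L, floor(5e6 / n_sites))
  for (st in seq(1L, n_src, by = chunk)) {
    en <- min(st + chunk - 1L, n_src)
    P <- sources$positions[st:en, , drop = FALSE]
    G <- matrix(0, n_sites, en - st + 1L)
    for (j in seq_len(ncol(G))) {
      r <- sqrt((grid$coords[, 1] - P[j, 1])^2 +
                (grid$coords[, 2] - P[j, 2])^2 +
                (grid$coords[, 3] - P[j, 3])^2)
      G[, j] <- 1 / (4 * pi * sigma_ext * pmax(r, min_dist_um))
    }
    phi <- phi + G %*% sources$I[st:en, , drop = FALSE]
  }
  grid$phi <- phi
  grid$t <- sources$t_ms
  grid$sigma_ext <- sigma_ext
  grid
}

#' Summarize a voxel magnetization field
#'
#' Per-time mean and SD of the magnetization over all lattice sites, plus
#' the 2-D time-amplitude histogram of per-site values over the linear
#' regime [-1, 1] mA/m with 1 ms x 5 uA/m bins.
#'
#' @param mag_field A `magnetization_field` (dM in A/m).
#' @param bin_t_ms,bin_uAm Histogram bin sizes; defaults 1 ms and 5 uA/m.
#' @param range_uAm Amplitude range (uA/m); default `c(-1000, 1000)`.
#' @return A `voxel_signal` list: `t_ms`, `mean_uAm`, `sd_uAm`,
#'   `hist` (amplitude-bin x time-bin counts), `hist_breaks`.
#' @export
voxel_signal <- function(mag_field, bin_t_ms = 1, bin_uAm = 5,
                         range_uAm = c(-1000, 1000)) {
  stopifnot(inherits(mag_field, "magnetization_field"),
            nrow(mag_field$dM) > 0)
  dm_u <- mag_field$dM * 1e6                 # A/m -> uA/m
  mean_t <- colMeans(dm_u)
  sd_t <- apply(dm_u, 2, stats::sd)
  t_breaks <- seq(min(mag_field$t), max(mag_field$t) + bin_t_ms,
                  by = bin_t_ms)
  a_breaks <- seq(range_uAm[1], range_uAm[2], by = bin_uAm)
  t_bin <- findInterval(mag_field$t, t_breaks, rightmost.closed = TRUE)
  H <- matrix(0L, length(a_breaks) - 1L, length(t_breaks) - 1L)
  for (j in seq_along(mag_field$t)) {
    x <- dm_u[, j]
    x <- x[x >= range_uAm[1] & x <= range_uAm[2]]
    cnt <- graphics::hist(x, breaks = a_breaks, plot = FALSE)$counts
    H[, t_bin[j]] <- H[, t_bin[j]] + cnt
  }
  structure(list(t_ms = mag_field$t, mean_uAm = mean_t, sd_uAm = sd_t,
                 hist = H, hist_breaks = list(t = t_breaks, a = a_breaks)),
            class = "voxel_signal")
}

#' Write a spike raster as two-column text
#'
#' @param raster A `spike_raster`.
#' @param path Output file.
#' @export
write_raster <- function(raster, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# cell_id t_ms", con)
  writeLines(sprintf("%d %.4f", raster$spikes$cell, raster$spikes$t_ms), con)
  invisible(path)
}
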