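#' Drive-field definition
#'
#' A sinusoidal excitation field `H(t) = bias + amplitude * sin(2 pi f t)`
#' sampled on a regular time grid, as used in MPI spectroscopy.
#'
#' @param amplitude Oscillation amplitude (A/m), >= 0.
#' @param frequency Drive frequency (Hz).
#' @param bias Static offset field (A/m); default 0.
#' @param t_start,t_end Window (s).
#' @param dt Sampling step (s); default 1e-6 s.
#' @return A `drive_field` list.
#' @export
drive_field <- function(amplitude, frequency, bias = 0, t_start = 0,
                        t_end, dt = 1e-6) {
  stopifnot(amplitude >= 0, frequency > 0, dt > 0, t_end > t_start)
  structure(list(amplitude = amplitude, frequency = frequency, bias = bias,
                 t_start = t_start, t_end = t_end, dt = dt),
            class = "drive_field")
}

#' Sample a drive field
#'
#' @param d A [drive_field].
#' @return data.frame with columns `t` (s) and `H` (A/m).
#' @export
generate_drive <- function(d) {
  stopifnot(inherits(d, "drive_field"))
  if (d$dt > 1 / (4 * d$frequency)) {
    warning("dt exceeds a quarter period: the drive is undersampled")
  }
  t <- seq(d$t_start, d$t_end, by = d$dt)
  data.frame(t = t, H = d$bias + d$amplitude * sin(2 * pi * d$frequency * t))
}

#' Memoryless magnetization response to a drive
#'
#' Evaluates an M-H model pointwise on a sampled drive: `M(t) = M(H(t))`.
#' Hysteresis and relaxation are neglected (equilibrium response), which is
#' the appropriate regime for freely rotating particles at sub-MHz drive
#' frequencies.
#'
#' @param model Either a function `H -> M` (A/m to A/m), a [particle_spec]
#'   (thermal Langevin response, volume-averaged), or an `mh_curve`
#'   (linearly interpolated).
#' @param drive data.frame from [generate_drive].
#' @param strict Error if the drive leaves the range of a tabulated curve.
#' @return data.frame with columns `t`, `H`, `M`.
#' @export
magnetization_timeseries <- function(model, drive, strict = FALSE) {
  H <- drive$H
  if (inherits(model, "particle_spec")) {
    beta <- langevin_beta(model)
    M <- model$f_core * model$core_material$Ms * langevin(beta * H)
  } else if (inherits(model, "mh_curve")) {
    if (strict && (max(H) > max(model$H) || min(H) < min(model$H))) {
      stop("drive exceeds the tabulated M-H range")
    }
    M <- stats::approx(model$H, model$M, xout = H, rule = 2)$y
  } else if (is.function(model)) {
    M <- model(H)
  } else {
    stop("model must be a function, particle_spec or mh_curve")
  }
  data.frame(t = drive$t, H = H, M = M)
}

#' Harmonic spectrum of a periodic magnetization trace
#'
#' Amplitudes at integer multiples of the drive frequency, estimated by a
#' joint least-squares fit of an intercept plus cosine/sine pairs at
#' `k * f0`, `k = 1..K`, over the largest whole number of drive periods in
#' the trace. Fitting over whole periods makes the estimate leakage-free
#' regardless of the window length actually simulated.
#'
#' When the sampling step divides a whole number of periods exactly (e.g.
#' 1 us sampling of 25.25 kHz tiles 101 periods in 4000 samples), the
#' window is trimmed to that sample-exact tiling, which makes the harmonic
#' basis exactly orthogonal on the grid and drives even-harmonic leakage of
#' odd responses to machine precision. Otherwise the window is the largest
#' whole number of periods by time (half-open, so the repeated phase point
#' is not double-counted).
#'
#' @param M Magnetization samples (A/m), or a data.frame with columns `t`
#'   and `M`.
#' @param t Time axis (s), uniform; ignored if `M` is a data.frame.
#' @param f0 Fundamental (drive) frequency (Hz).
#' @param K Number of harmonics; default 9.
#' @return A `harmonic_spectrum` data.frame with columns `k`, `frequency`,
#'   `amplitude` (raw, A/m), and `normalized` (relative to `k = 1`).
#' @export
harmonic_spectrum <- function(M, t = NULL, f0, K = 9L) {
  if (is.data.frame(M)) {
    t <- M$t
    M <- M$M
  }
  stopifnot(length(M) == length(t), K >= 1L, f0 > 0)
  dt <- t[2] - t[1]
  cyc <- f0 * dt                       # cycles per sample
  len <- length(t)
  n_per_max <- floor((len - 1) * cyc + 1e-9)
  if (n_per_max < 1L) stop("trace must cover at least one full period of f0")
  keep_n <- NA_integer_
  for (np in n_per_max:1) {
    Nc <- round(np / cyc)
    if (Nc <= len && abs(Nc * cyc - np) < 1e-9) {
      keep_n <- Nc
      n_per <- np
      break
    }
  }
  if (is.na(keep_n)) {
    n_per <- n_per_max
    keep_n <- sum(t - t[1] <= n_per / f0 - dt / 2)
  }
  tt <- t[seq_len(keep_n)]; MM <- M[seq_len(keep_n)]
  X <- matrix(1, length(tt), 1L + 2L * K)
  for (k in seq_len(K)) {
    X[, 2L * k] <- cos(2 * pi * k * f0 * tt)
    X[, 2L * k + 1L] <- sin(2 * pi * k * f0 * tt)
  }
  b <- qr.coef(qr(X), MM)
  amp <- sqrt(b[2L * seq_len(K)]^2 + b[2L * seq_len(K) + 1L]^2)
  if (amp[1] == 0) stop("fundamental amplitude is zero: cannot normalize")
  structure(data.frame(k = seq_len(K), frequency = seq_len(K) * f0,
                       amplitude = unname(amp),
                       normalized = unname(amp / amp[1])),
            class = c("harmonic_spectrum", "data.frame"),
            f0 = f0, n_periods = n_per)
}

#' Harmonic suppression by a static bias field
#'
#' Runs the same particle under the same oscillating drive with and without
#' a static bias and reports both spectra plus the ratio of the raw
#' third-harmonic amplitudes (biased / unbiased). A bias that saturates the
#' particle pushes the operating point onto the flat part of the M-H curve
#' and suppresses the odd harmonics that MPI detects.
#'
#' @param model As in [magnetization_timeseries].
#' @param d A [drive_field] whose `bias` is the biased condition.
#' @param K Number of harmonics.
#' @return List with `unbiased`, `biased` (harmonic_spectrum) and
#'   `suppression_ratio_h3`.
#' @export
biased_harmonic_suppression <- function(model, d, K = 9L) {
  d0 <- drive_field(d$amplitude, d$frequency, bias = 0,
                    t_start = d$t_start, t_end = d$t_end, dt = d$dt)
  s0 <- harmonic_spectrum(magnetization_timeseries(model, generate_drive(d0)),
                          f0 = d$frequency, K = K)
  sb <- harmonic_spectrum(magnetization_timeseries(model, generate_drive(d)),
                          f0 = d$frequency, K = K)
  list(unbiased = s0, biased = sb,
       suppression_ratio_h3 = sb$amplitude[3] / s0$amplitude[3])
}

#' Write a harmonic spectrum as columnar text
#'
#' @param spectrum A `harmonic_spectrum`.
#' @param path Output file.
#' @export
write_spectrum <- function(spectrum, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# f0_Hz = %g, periods_fit = %d",
                     attr(spectrum, "f0"), attr(spectrum, "n_periods")), con)
  utils::write.table(format(spectrum, digits = 10), con,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
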