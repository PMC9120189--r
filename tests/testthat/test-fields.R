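test_that("action-potential currents conserve charge and propagate with delay", {
  m <- synth_morphology("ball_and_stick", n_dend = 2, seed = 1)
  t_ms <- seq(0, 20, by = 0.05)
  cur <- ap_current_source(m, t_ms, onset_ms = 2, speed_um_ms = 500)
  # net transmembrane current is zero at every sample (enforced balance)
  expect_lt(max(abs(colSums(cur$I))), 1e-6 * max(abs(cur$I)))
  # zero-amplitude waveform gives all-zero currents
  cur0 <- ap_current_source(m, t_ms, amplitude_nA = 0)
  expect_equal(max(abs(cur0$I)), 0)
  # distal axon peak lags the proximal axon by path distance / speed
  # (axon nodes carry a negligible share of the distributed return current,
  # so their template peaks are undistorted)
  pd <- menpsim:::node_path_dist(m)
  ax <- which(m$type == 2L)
  prox <- ax[which.min(pd[ax])]; distal <- ax[which.max(pd[ax])]
  lag_expect <- (pd[distal] - pd[prox]) / 500
  t_peak_prox <- t_ms[which.max(cur$I[prox, ])]
  t_peak_dist <- t_ms[which.max(cur$I[distal, ])]
  expect_equal(t_peak_dist - t_peak_prox, lag_expect, tolerance = 0.1)
  # unbalanced template is rejected
  expect_error(ap_current_source(m, t_ms,
                                 waveform = function(t) exp(-(t - 1)^2)),
               "integrate")
})

test_that("extracellular potential matches the point-source closed form and is linear", {
  p <- write_tiny_swc()
  m <- read_swc(p)
  soma_only <- m[1, , drop = FALSE]
  class(soma_only) <- class(m)
  t_ms <- c(0, 1)
  cur <- list(t_ms = t_ms, I = matrix(c(2, -3), 1, 2))  # nA
  sites <- rbind(c(30, 0, 0), c(0, 60, 0), c(0, 0, 120))
  phi <- extracellular_potential(soma_only, cur, sites, sigma_ext = 0.3)
  r <- c(30, 60, 120)
  expect_equal(phi[, 1], 2 / (4 * pi * 0.3 * r), tolerance = 1e-12)
  expect_equal(phi[, 2], -3 / (4 * pi * 0.3 * r), tolerance = 1e-12)
  # superposition / scaling over the full morphology
  curm <- ap_current_source(m, seq(0, 5, by = 0.5))
  phi1 <- extracellular_potential(m, curm, sites)
  curm2 <- curm; curm2$I <- 2 * curm$I
  expect_equal(extracellular_potential(m, curm2, sites), 2 * phi1,
               tolerance = 1e-12)
  # 1/r decay of a point source: log-log slope -1
  rr <- 10 * 2^(0:6)
  ph <- extracellular_potential(soma_only, cur,
                                cbind(rr, 0, 0))[, 1]
  fit <- stats::lm(log(ph) ~ log(rr))
  expect_equal(unname(stats::coef(fit)[2]), -1, tolerance = 0.01)
})

test_that("line source converges to a point source in the far field", {
  # single neurite segment of length 20 um along y
  m <- data.frame(id = 1:2, type = c(1L, 2L), x = 0, y = c(0, 20), z = 0,
                  radius = c(1, 1), parent = c(-1L, 1L))
  class(m) <- c("morphology", "data.frame")
  # suppress the soma point source by zero current there
  cur <- list(t_ms = 0, I = matrix(c(0, 1), 2, 1))
  d <- 2000   # 100 x segment length
  site <- rbind(c(d, 10, 0))
  phi_line <- extracellular_potential(m, cur, site)[1, 1]
  phi_point <- 1 / (4 * pi * 0.3 * d)
  expect_equal(phi_line, phi_point, tolerance = 1e-4)
})

test_that("lattice gradient is exact on affine potentials and second-order on smooth ones", {
  g <- field_grid(c(40, 40, 40), 5, t_ms = 0)
  g$phi <- matrix(7, nrow(g$coords), 1)
  g <- efield_from_potential(g)
  expect_equal(max(abs(g$E)), 0)
  # linear ramp phi = a x (mV, um): E_x = -a mV/um = -1000 a V/m exactly
  a <- 0.25
  g$phi <- matrix(a * g$coords[, 1], ncol = 1)
  g <- efield_from_potential(g)
  expect_equal(g$E[, 1, 1], rep(-a * 1000, nrow(g$coords)), tolerance = 1e-12)
  expect_equal(max(abs(g$E[, 2:3, 1])), 0)
  # point-source potential: central-difference error shrinks ~ h^2
  src <- c(-35, -35, -35)
  err_at <- function(h) {
    gg <- field_grid(c(40, 40, 40), h, t_ms = 0)
    r <- sqrt(rowSums(sweep(gg$coords, 2, src)^2))
    gg$phi <- matrix(1 / (4 * pi * 0.3 * r), ncol = 1)
    gg <- efield_from_potential(gg)
    interior <- rowSums(gg$coords %% 40 == 0) == 0
    Ean <- 1000 * sweep(gg$coords, 2, src) / (4 * pi * 0.3 * r^3)
    max(abs(gg$E[interior, , 1] - Ean[interior, ]) / max(abs(Ean[interior, ])))
  }
  e1 <- err_at(5); e2 <- err_at(2.5)
  expect_lt(e2, e1 / 2.5)        # at least ~2nd order shrinkage
  expect_lt(e1, 0.02)
})

test_that("site classification uses the inclusion zone with soma precedence", {
  p <- write_tiny_swc()
  m <- read_swc(p)    # soma at origin (r=10), axon to (0,-50,0), dend to (0,40,30)
  sites <- rbind(c(5, 0, 0),        # 5 um from soma center
                 c(200, 200, 200),  # far from everything
                 c(0, -45, 0),      # near axon tip
                 c(0, 36, 27))      # near dendrite
  cl <- classify_sites(m, sites, zone_radius_um = 20)
  expect_equal(as.character(cl),
               c("somatic", "none", "axonal", "dendritic"))
  # equidistant soma/axon: soma wins by precedence
  m2 <- data.frame(id = 1:2, type = c(1L, 2L),
                   x = c(0, 6), y = c(0, -8), z = 0,
                   radius = 1, parent = c(-1L, 1L))
  class(m2) <- c("morphology", "data.frame")
  # site 10 um from the soma node and exactly 10 um from the axon segment
  eq_site <- rbind(c(-10, 0, 0))
  cl2 <- classify_sites(m2, eq_site, zone_radius_um = 20)
  expect_equal(as.character(cl2), "somatic")
  # invariance to segment ordering
  m3 <- m[c(3, 1, 2), ]
  class(m3) <- c("morphology", "data.frame")
  expect_equal(classify_sites(m3, sites), cl)
})

test_that("peak-window summary recovers constructed per-category constants", {
  f <- two_zone_field(val_lo = 1e-6, val_hi = 5e-6)
  cats <- factor(ifelse(f$coords[, 2] > 20, "axonal", "somatic"),
                 levels = c("somatic", "axonal", "dendritic", "none"))
  out <- peak_window_summary(f, cats, window_ms = c(0, 20))
  s <- out$summary
  expect_equal(s$mean[s$category == "somatic"], 1e-6)
  expect_equal(s$mean[s$category == "axonal"], 5e-6)
  expect_equal(s$q1, s$q3)              # uniform within category: IQR = 0
  # uniform field: mean equals the value, peak time is the argmax
  u <- uniform_field(2e-6, t = 0:4)
  u$dM[, 3] <- 3e-6                     # spatially integrated max at t = 2
  cats_u <- factor(rep("somatic", nrow(u$dM)),
                   levels = c("somatic", "axonal", "dendritic", "none"))
  out_u <- peak_window_summary(u, cats_u, window_ms = c(0, 4))
  expect_equal(out_u$peak_time_ms, 2)
  expect_equal(out_u$summary$mean[1], 3e-6)
})
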