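test_that("inclusive lattice counts follow the closed form", {
  s <- grid_sites(c(200, 700, 200), 5)
  expect_equal(nrow(s), 237021L)
  expect_equal(attr(s, "n_axis"), c(41L, 141L, 41L))
  expect_equal(nrow(grid_sites(c(200, 700, 200), 100)), 3L * 8L * 3L)
  # spacing equal to the dimension gives two planes per axis
  expect_equal(attr(grid_sites(c(50, 50, 50), 50), "n_axis"), rep(2L, 3))
  expect_error(grid_sites(c(200, 700, 200), 3), "divisible")
  # brute-force enumeration oracle on a small lattice
  cnt <- 0L
  for (x in seq(0, 30, 10)) for (y in seq(0, 40, 10)) for (z in seq(0, 20, 10))
    cnt <- cnt + 1L
  expect_equal(nrow(grid_sites(c(30, 40, 20), 10)), cnt)
})

test_that("network construction matches the layer composition and wiring rules", {
  net <- build_network(default_layers(), seed = 11)
  cells <- net$cells
  expect_equal(nrow(cells), 990L + 1176L + 1140L)
  expect_equal(sum(cells$layer == "II"), 990L)
  expect_equal(sum(cells$layer == "III"), 1176L)
  expect_equal(sum(cells$layer == "IV"), 1140L)
  expect_equal(sum(cells$type == "E"), 895L + 988L + 970L)
  # layer slabs stack to the full 700 um depth
  expect_true(all(cells$y >= 0 & cells$y <= 700))
  expect_true(all(cells$y[cells$layer == "II"] <= 150))
  expect_true(all(cells$y[cells$layer == "IV"] >= 500))
  expect_equal(cells$y_norm, cells$y / 700)
  # never any I -> I edge
  itype <- cells$type[net$edges$pre] == "I"
  expect_true(all(cells$type[net$edges$post[itype]] == "E"))
  # excitatory weights scale with presynaptic depth
  ee <- net$edges[net$edges$type == "E", ]
  expect_equal(ee$weight, 25 * cells$y_norm[ee$pre])
  expect_true(all(net$edges$weight[net$edges$type == "I"] == 5))
  # reproducibility
  net2 <- build_network(default_layers(), seed = 11)
  expect_identical(net$edges, net2$edges)
})

test_that("empirical connection probabilities recover the wiring rules", {
  # E connection density: binomial check at ~2800 E cells (one seed)
  net <- build_network(default_layers(), seed = 3)
  n <- nrow(net$cells)
  nE <- sum(net$cells$type == "E")
  n_pairs <- nE * (n - 1)
  k <- sum(net$edges$type == "E")
  phat <- k / n_pairs
  ci <- 2.58 * sqrt(0.1 * 0.9 / n_pairs)   # 99% binomial CI
  expect_lt(abs(phat - 0.1), ci)
  # I -> E distance dependence: recover lambda within 10% on a 10-seed
  # ensemble of reduced columns (same rules, smaller populations)
  d_all <- conn_all <- numeric(0)
  for (sd in 1:10) {
    nets <- build_network(default_layers(scale = 0.35), seed = 100 + sd)
    cells <- nets$cells
    iid <- cells$id[cells$type == "I"]; eid <- cells$id[cells$type == "E"]
    ie <- nets$edges[nets$edges$type == "I", ]
    key_conn <- paste(ie$pre, ie$post)
    D <- as.matrix(stats::dist(cells[, c("x", "y", "z")]))[iid, eid]
    conn <- matrix(paste(rep(iid, times = length(eid)),
                         rep(eid, each = length(iid))) %in% key_conn,
                   nrow = length(iid))
    d_all <- c(d_all, as.numeric(D))
    conn_all <- c(conn_all, as.numeric(conn))
  }
  bins <- cut(d_all, breaks = seq(0, 400, by = 25))
  p_emp <- tapply(conn_all, bins, mean)
  d_mid <- seq(12.5, 387.5, by = 25)
  keep <- !is.na(p_emp) & p_emp > 0
  fit <- stats::lm(log(p_emp[keep]) ~ d_mid[keep])
  lambda_hat <- -1 / unname(stats::coef(fit)[2])
  expect_lt(abs(lambda_hat - 150) / 150, 0.10)
  p0_hat <- exp(unname(stats::coef(fit)[1]))
  expect_lt(abs(p0_hat - 0.4) / 0.4, 0.15)
})

test_that("network simulation is deterministic per seed and silent without drive", {
  net <- build_network(default_layers(scale = 0.1), seed = 5)
  quiet <- simulate_network(net, duration_ms = 50, drive_mu = 0,
                            drive_sigma = 0, drive_common_sigma = 0,
                            burst_rate_hz = 0, g_fast_e = 0, g_fast_i = 0,
                            g_unit_e = 0, g_unit_i = 0, seed = 1)
  expect_equal(nrow(quiet$spikes), 0L)
  r1 <- simulate_network(net, duration_ms = 60, seed = 9)
  r2 <- simulate_network(net, duration_ms = 60, seed = 9)
  expect_identical(r1$spikes, r2$spikes)
  r3 <- simulate_network(net, duration_ms = 60, seed = 10)
  expect_false(identical(r1$spikes, r3$spikes))
  expect_true(all(r1$spikes$t_ms >= 0 & r1$spikes$t_ms <= 60))
  expect_false(is.unsorted(r1$spikes$t_ms))
})

test_that("the default configuration produces recurring population bursts", {
  net <- build_network(default_layers(), seed = 1)
  n_bursts <- vapply(1:10, function(sd) {
    length(detect_bursts(simulate_network(net, seed = sd)))
  }, numeric(1))
  # recurring bursts in the 140 ms window for the clear majority of seeds
  expect_gte(sum(n_bursts >= 2), 7)
  expect_true(all(n_bursts >= 1))
})

test_that("burst detection recovers injected volleys and ignores empty rasters", {
  expect_equal(detect_bursts(data.frame(cell = integer(0),
                                        t_ms = numeric(0)),
                             duration_ms = 140), numeric(0))
  set.seed(21)
  volleys <- c(27, 59, 91, 119)
  n_cells <- 200
  bg <- data.frame(cell = sample.int(n_cells, 150, replace = TRUE),
                   t_ms = runif(150, 0, 140))
  volley_sp <- do.call(rbind, lapply(volleys, function(tv)
    data.frame(cell = sample.int(n_cells, 120),
               t_ms = pmin(pmax(rnorm(120, tv, 0.4), 0), 140))))
  raster <- rbind(bg, volley_sp)
  peaks <- detect_bursts(raster, duration_ms = 140)
  expect_equal(length(peaks), 4L)
  expect_true(all(abs(sort(peaks) - volleys) <= 1))
})

test_that("point-neuron dipole sources are charge balanced and drive the lattice solver", {
  net <- build_network(default_layers(scale = 0.05), seed = 2)
  r <- simulate_network(net, duration_ms = 60, seed = 3)
  skip_if(nrow(r$spikes) == 0)
  t_frames <- seq(0, 60, by = 1)
  src <- network_source_currents(r, t_frames)
  expect_lt(max(abs(colSums(src$I))), 1e-12)
  grid <- field_grid(c(200, 700, 200), 100)
  grid <- network_potential(src, grid)
  expect_equal(dim(grid$phi), c(nrow(grid$coords), length(t_frames)))
  # doubling all source currents doubles the potential (pipeline linearity)
  src2 <- src; src2$I <- 2 * src$I
  grid2 <- network_potential(src2, field_grid(c(200, 700, 200), 100))
  expect_equal(grid2$phi, 2 * grid$phi, tolerance = 1e-12)
  # through the full chain to the voxel trace
  g1 <- efield_from_potential(grid)
  g2 <- efield_from_potential(grid2)
  f1 <- voxel_magnetization(g1)
  f2 <- voxel_magnetization(g2)
  expect_equal(f2$dM, 2 * f1$dM, tolerance = 1e-12)
  v1 <- voxel_signal(f1); v2 <- voxel_signal(f2)
  expect_equal(v2$mean_uAm, 2 * v1$mean_uAm, tolerance = 1e-10)
})

test_that("voxel signal summarizes mean, SD and histogram consistently", {
  u <- uniform_field(3e-6, t = 0:3)
  v <- voxel_signal(u)
  expect_equal(v$mean_uAm, rep(3, 4))
  expect_equal(v$sd_uAm, rep(0, 4))
  # two-site field {+a, -a}: mean 0, SD a * sqrt(2) / sqrt(2 - 1) per sd()
  a <- 4e-6
  f2 <- uniform_field(a, dims = c(50, 50, 50), spacing = 50, t = 0)
  f2$dM[] <- rep(c(a, -a), length.out = nrow(f2$dM))
  v2 <- voxel_signal(f2)
  expect_equal(v2$mean_uAm, 0)
  expect_equal(v2$sd_uAm, stats::sd(f2$dM[, 1]) * 1e6)
  # histogram column sums equal the number of in-range sites per time bin
  expect_equal(unname(colSums(voxel_signal(u)$hist)[1:4]),
               rep(nrow(u$dM), 4))
})

test_that("synapse parameters keep printed units but allow millisecond reinterpretation", {
  s <- synapse_params(0.8, 5.3, 0)
  expect_equal(s$tau1_ms, 800)
  expect_equal(s$tau2_ms, 5300)
  sm <- synapse_params(0.8, 5.3, 0, tau_units = "ms")
  expect_equal(sm$tau1_ms, 0.8)
  expect_error(synapse_params(5.3, 0.8, 0))
})
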