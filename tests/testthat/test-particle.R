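test_that("Langevin function matches its closed form and limits", {
  expect_identical(langevin(0), 0)
  # coth(1) - 1 = 2 / (e^2 - 1), evaluated independently
  expect_equal(langevin(1), 2 / (exp(2) - 1), tolerance = 1e-14)
  expect_equal(langevin(700), 1, tolerance = 1e-2)
  expect_lt(langevin(500), 1)
  x <- seq(-500, 500, length.out = 4001)
  Lx <- langevin(x)
  # odd, strictly increasing, bounded
  expect_equal(Lx, -rev(Lx), tolerance = 1e-14)
  expect_true(all(diff(Lx) > 0))
  expect_true(all(abs(Lx) < 1))
  # against the direct form away from the series switchover
  xb <- x[abs(x) > 1e-3]
  expect_equal(langevin(xb), 1 / tanh(xb) - 1 / xb, tolerance = 1e-12)
})

test_that("equilibrium magnetization saturates, vanishes at H = 0, and has the thermal initial slope", {
  sp <- spion()
  expect_equal(equilibrium_magnetization(c(0, 0, 0), sp), c(0, 0, 0))
  beta <- langevin_beta(sp)
  m <- equilibrium_magnetization(c(0, 0, 80e3), sp)
  # oracle value: Ms * L(beta * 8e4) with the closed form
  expect_equal(m[3], 347100 * (1 / tanh(beta * 8e4) - 1 / (beta * 8e4)),
               tolerance = 1e-12)
  expect_equal(m[3] / 347100, 0.992, tolerance = 1e-3)
  # saturation
  msat <- equilibrium_magnetization(c(0, 0, 1e9), sp)
  expect_equal(msat[3] / 347100, 1, tolerance = 1e-4)
  # small-field initial susceptibility Ms * beta / 3
  h <- 0.005 / beta
  slope <- equilibrium_magnetization(c(0, 0, h), sp)[3] / h
  expect_equal(slope, 347100 * beta / 3, tolerance = 1e-3)
  # alignment with the field direction
  hv <- c(3, -2, 1) * 1e4
  mv <- equilibrium_magnetization(hv, sp)
  expect_equal(mv / sqrt(sum(mv^2)), hv / sqrt(sum(hv^2)), tolerance = 1e-12)
})

test_that("composite magnetization is exact volume averaging", {
  m <- menp12()
  expect_equal(composite_magnetization(m, c(0, 0, 181800))[3],
               (12 / 15)^3 * 181800)
  full <- particle_spec(15e-9, 15e-9, core_material = m$core_material)
  expect_equal(composite_magnetization(full, c(1, 2, 3)), c(1, 2, 3))
  none <- particle_spec(15e-9, 0, core_material = m$core_material)
  expect_equal(composite_magnetization(none, c(1, 2, 3)), c(0, 0, 0))
})

test_that("magnetostrictive strain is the traceless deviator form", {
  cfo <- load_materials()$cobalt_ferrite
  expect_equal(magnetostrictive_strain(c(0, 0, 0), cfo), matrix(0, 3, 3))
  # M = Ms z_hat: symbolic evaluation gives lambda_s * diag(-1/2,-1/2,1)
  eps <- magnetostrictive_strain(c(0, 0, cfo$Ms), cfo)
  expect_equal(eps, 315e-6 * diag(c(-0.5, -0.5, 1)), tolerance = 1e-12)
  set.seed(42)
  for (i in 1:10) {
    M <- rnorm(3) * 1e5
    e1 <- magnetostrictive_strain(M, cfo)
    expect_lt(abs(sum(diag(e1))), 1e-18)
    expect_equal(e1, magnetostrictive_strain(-M, cfo), tolerance = 1e-15)
  }
  bad <- load_materials()$barium_titanate
  expect_error(magnetostrictive_strain(c(1, 0, 0), bad))
})

test_that("piezoelectric stress is the Voigt contraction of the coupling matrix", {
  bto <- load_materials()$barium_titanate
  expect_equal(piezo_stress(c(0, 0, 0), bto), matrix(0, 3, 3))
  # oracle: direct matrix arithmetic with the tabulated 3 x 6 matrix
  e <- bto$coupling_voigt
  for (E in list(c(0, 0, 1), c(1, 0, 0), c(0.3, -0.7, 2))) {
    sv_expect <- -as.numeric(t(e) %*% E)
    S <- piezo_stress(E, bto)
    expect_equal(c(S[1, 1], S[2, 2], S[3, 3], S[2, 3], S[1, 3], S[1, 2]),
                 sv_expect, tolerance = 1e-12)
    expect_equal(S, t(S))
  }
  # linearity about S0
  S0 <- diag(c(1, 2, 3)) * 1e3
  E <- c(5, -1, 2)
  S1 <- piezo_stress(E, bto, S0 = S0)
  S2 <- piezo_stress(2 * E, bto, S0 = S0)
  expect_equal(S2, 2 * (S1 - S0) + S0, tolerance = 1e-9)
  expect_error(piezo_stress(c(1, 0, 0), load_materials()$cobalt_ferrite),
               "coupling")
})

test_that("effective field adds the deviatoric magnetoelastic term", {
  cfo <- load_materials()$cobalt_ferrite
  H <- c(0, 0, 4000)
  M <- c(0, 0, cfo$Ms)
  # hydrostatic stress has zero deviator
  expect_equal(effective_field(H, diag(3) * 1e6, M, cfo), H)
  # lambda_s = 0 material leaves H unchanged
  inert <- material_props("inert", sigma = 0, density = 1000, Ms = 1e5,
                          lambda_s = 0)
  expect_equal(effective_field(H, diag(c(1, 2, 3)) * 1e6, M, inert), H)
  # uniaxial S_zz = 1 MPa with M = Ms z_hat: direct arithmetic oracle
  S <- diag(c(0, 0, 1e6))
  mu0 <- 4e-7 * pi
  expect_z <- 4000 + 3 * 315e-6 / (mu0 * cfo$Ms^2) * (2 / 3 * 1e6) * cfo$Ms
  expect_equal(effective_field(H, S, M, cfo)[3], expect_z, tolerance = 1e-10)
})

test_that("lumped solver reduces to pure Langevin when decoupled and is initialization-independent", {
  m <- menp12()
  st <- solve_lumped_me(m, H_applied = c(0, 0, 4000))
  expect_true(st$converged)
  expect_equal(st$M, equilibrium_magnetization(c(0, 0, 4000), m),
               tolerance = 1e-10)
  # lambda_s = 0 core decouples entirely even with E applied
  inert_core <- material_props("cfo_no_striction", sigma = 4.2e-5,
                               density = 6060, Ms = 181800, lambda_s = 0,
                               poisson = 0.33, youngs = 188.4e9)
  m0 <- particle_spec(15e-9, 12e-9, core_material = inert_core,
                      shell_material = load_materials()$barium_titanate)
  st0 <- solve_lumped_me(m0, H_applied = c(0, 0, 4000),
                         E_applied = c(0, 0, 50))
  expect_equal(st0$M, equilibrium_magnetization(c(0, 0, 4000), m0),
               tolerance = 1e-10 * 181800)
  # fixed point independent of the initial guess
  args <- list(spec = m, H_applied = c(0, 0, 4000), E_applied = c(0, 0, 50))
  s1 <- do.call(solve_lumped_me, c(args, list(M_init = c(0, 0, 0))))
  s2 <- do.call(solve_lumped_me, c(args, list(M_init = c(1.8e5, 0, 0))))
  s3 <- do.call(solve_lumped_me, c(args, list(M_init = c(0, 0, 1.8e5))))
  expect_lt(max(abs(s1$M - s2$M)), 10 * 1e-10 * 181800)
  expect_lt(max(abs(s1$M - s3$M)), 10 * 1e-10 * 181800)
})

test_that("lumped solver responds linearly to small electric fields", {
  m <- menp12()
  es <- seq(-50, 50, by = 25)
  mags <- vapply(es, function(e) {
    sqrt(sum(solve_lumped_me(m, c(0, 0, 4000), c(0, 0, e))$M^2))
  }, numeric(1))
  slopes <- diff(mags) / diff(es)
  expect_gt(min(abs(slopes)), 0)
  expect_lt(diff(range(slopes)) / mean(abs(slopes)), 0.01)
})

test_that("M-H curves are odd-symmetric and approach the configured saturation", {
  sp <- spion()
  cur <- mh_curve(sp, H_max = 2e6, n_points = 201)
  expect_equal(cur$M, -rev(cur$M), tolerance = 1e-12)
  expect_true(all(diff(cur$M) >= 0))
  expect_equal(max(cur$M), 347100, tolerance = 1e-3)
  expect_true(all(abs(cur$M) < 347100))
  zero_mat <- material_props("void", sigma = 0, density = 1, Ms = 0)
  # zero core volume gives an all-zero curve
  mz <- particle_spec(15e-9, 0, core_material = spion()$core_material)
  expect_warning(m0 <- equilibrium_magnetization(c(0, 0, 1e4), mz), "zero core")
  expect_equal(m0, c(0, 0, 0))
})

test_that("uniformly magnetized sphere field: uniform interior, dipolar exterior", {
  M <- c(0, 0, 1e5)
  r <- 15e-9
  mu0 <- 4e-7 * pi
  expect_equal(sphere_dipole_field(c(0, 0, 0), r,
                                   rbind(c(0, 0, 1e-9), c(0, 0, 1e-7))),
               matrix(0, 2, 3))
  Bin <- sphere_dipole_field(M, r, rbind(c(0, 0, 0.5 * r)))
  expect_equal(Bin[1, ], 2 / 3 * mu0 * M, tolerance = 1e-12)
  # 1/r^3 decay on the axis: |B|(2r) / |B|(4r) = 8
  Bax <- sphere_dipole_field(M, r, rbind(c(0, 0, 2 * r), c(0, 0, 4 * r)))
  expect_equal(sqrt(sum(Bax[1, ]^2)) / sqrt(sum(Bax[2, ]^2)), 8,
               tolerance = 1e-12)
  # axial surface value continuous with the interior: mu0 * 2 M / 3
  Bsurf <- sphere_dipole_field(M, r, rbind(c(0, 0, r * (1 + 1e-12))))
  expect_equal(Bsurf[1, 3], mu0 * 2 * M[3] / 3, tolerance = 1e-6)
})
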