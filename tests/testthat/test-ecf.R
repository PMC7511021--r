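test_that("ecf_params composes tortuosity and enforces exclusivity", {
  e1 <- ecf_params(D_star = 0.5e-10)
  expect_equal(e1$D_star, 0.5e-10)
  e2 <- ecf_params(D = 1.25e-10, lambda = 1.6)
  expect_equal(e2$D_star, 1.25e-10 / 1.6^2, tolerance = 1e-15)
  expect_error(ecf_params(D_star = 1e-10, D = 1e-10, lambda = 1.6), "not both")
  expect_error(ecf_params(), "required")
})

test_that("equilibrium_bound matches the Langmuir isotherm", {
  # half occupancy at C = Kd; reference kinetics: Kd = 0.01 umol/L
  expect_equal(equilibrium_bound(0.01, 5e-2, 1, 1e-2), 0.025, tolerance = 1e-12)
  expect_equal(equilibrium_bound(0, 5e-2, 1, 1e-2), 0)
  expect_equal(equilibrium_bound(1e9, 5e-2, 1, 1e-2), 5e-2, tolerance = 1e-6)
  expect_equal(equilibrium_bound(0.3, 2, 0, 1), 0)  # kon = 0: no binding
  kd <- 1 / 1e-2  # non-specific sites: koff/kon = 100 umol/L
  expect_equal(equilibrium_bound(kd, 50, 1e-2, 1), 25, tolerance = 1e-12)
})

test_that("ecf_rhs vanishes in a homogeneous steady state", {
  mesh <- build_mesh(geometry_params(), 8)
  ne <- sum(!mesh$plasma)
  ecf <- ecf_params(D_star = 0.5e-10, v_ecf = 0)
  bind0 <- binding_params(B1max = 0, k1on = 0, k1off = 0, B2max = 0, k2on = 0, k2off = 0)
  r <- ecf_rhs(rep(1.3, ne), rep(0, ne), rep(0, ne), mesh, ecf, bind0)
  expect_lt(max(abs(r$dC_ecf)), 1e-12)  # rounding of the stencil row sums
  expect_equal(r$dB1, rep(0, ne))
  # with bulk flow a uniform field is stationary away from the capillaries;
  # the advection faces blocked by the BBB redistribute locally but the
  # volume-integrated rate cancels (equal inflow/outflow boundary areas)
  ecf2 <- ecf_params(D_star = 0.5e-10, v_ecf = 1e-6)
  r2 <- ecf_rhs(rep(1.3, ne), rep(0, ne), rep(0, ne), mesh, ecf2, bind0)
  vol_e <- mesh$vol[!mesh$plasma]
  expect_equal(sum(r2$dC_ecf * vol_e) / sum(vol_e * 1.3), 0, tolerance = 1e-12)
  expect_gt(max(abs(r2$dC_ecf)), 0)  # local redistribution at blocked faces
  expect_error(ecf_rhs(rep(1, ne - 1), rep(0, ne), rep(0, ne), mesh, ecf, bind0),
               class = "bu_shape_error")
})

test_that("binding relaxes to the closed-form exponential at clamped C", {
  # scalar ODE oracle: B(t) = Beq (1 - exp(-(kon C + koff) t))
  C <- 0.01
  bind <- binding_params()
  st <- solver_settings(n = 8, t_end = 600,
                        times = c(0, 25, 50, 100, 200, 400, 600),
                        clamp_ecf = C, audit = FALSE, rtol = 1e-10, atol = 1e-14)
  cfg <- t2_config()
  cfg$bbb$P <- 0  # decouple plasma
  res <- simulate(cfg, st)
  b1 <- probe_series(res, "ecf_middle", "B1")
  rate1 <- bind$k1on * C + bind$k1off
  beq1 <- bind$B1max * C / (C + bind$k1off / bind$k1on)
  expect_equal(b1$value_umol_per_L, beq1 * (1 - exp(-rate1 * b1$time_s)),
               tolerance = 1e-6)
  b2 <- probe_series(res, "ecf_middle", "B2")
  rate2 <- bind$k2on * C + bind$k2off
  beq2 <- bind$B2max * C / (C + bind$k2off / bind$k2on)
  expect_equal(b2$value_umol_per_L, beq2 * (1 - exp(-rate2 * b2$time_s)),
               tolerance = 1e-6)
})

test_that("free diffusion spreads a Gaussian bump with variance 2 D* t per axis", {
  # heat-kernel moment oracle before boundary effects; capillaries are
  # switched off by P = 0 so the ECF is a closed box
  g <- geometry_params()
  cfg <- t2_config()
  cfg$bbb$P <- 0
  cfg$ecf$v_ecf <- 0
  cfg$binding <- binding_params(B1max = 0, k1on = 0, k1off = 1,
                                B2max = 0, k2on = 0, k2off = 1)
  s0 <- 4e-6
  mid <- g$x_r / 2
  bump <- function(x, y, z) {
    exp(-((x - mid)^2 + (y - mid)^2 + (z - mid)^2) / (2 * s0^2))
  }
  D <- cfg$ecf$D_star
  t_out <- c(0, 100, 250, 500)
  st <- solver_settings(n = 24, t_end = 500, times = t_out, init_ecf = bump,
                        audit = FALSE, rtol = 1e-9, atol = 1e-13)
  res <- simulate(cfg, st)
  mesh <- res$mesh
  idx <- res$state_index
  xs <- mesh$coords[idx$ec, 1]
  vols <- mesh$vol[idx$ec]
  var_x <- function(k) {
    w <- res$state[k, 1L + idx$i_ce] * vols
    mu <- sum(w * xs) / sum(w)
    sum(w * (xs - mu)^2) / sum(w)
  }
  v0 <- var_x(1)
  for (k in 2:4) {
    expect_equal(var_x(k) - v0, 2 * D * t_out[k], tolerance = 0.04)
  }
})
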