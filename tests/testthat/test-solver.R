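test_that("solver settings validate the output grid", {
  expect_error(solver_settings(times = c(0, 10, 5)), "strictly increasing")
  expect_error(solver_settings(times = c(0, 10, 2e5), t_end = 1e5), "strictly increasing")
  s <- solver_settings(t_end = 100, times = c(1, 10, 100))
  expect_equal(s$times[1], 0)  # integration always starts at the zero state
  expect_error(solver_settings(plasma_forcing = "constant"), "forcing_value")
})

test_that("repeated runs are bit-identical (deterministic model)", {
  cfg <- t2_config()
  st <- solver_settings(n = 8, t_end = 1e3, times = c(0, 10, 100, 1e3))
  r1 <- simulate(cfg, st)
  r2 <- simulate(cfg, st)
  expect_identical(r1$state, r2$state)
  expect_identical(r1$probes, r2$probes)
  expect_identical(r1$meta$param_hash, r2$meta$param_hash)
})

test_that("probe snapping picks the documented locations", {
  cfg <- t2_config()
  st <- solver_settings(n = 18, t_end = 10, times = c(0, 10))
  res <- simulate(cfg, st)
  pi <- res$probe_info
  m <- res$mesh
  # the plasma probe sits exactly at the mid-rib cell centre
  ppl <- pi[pi$probe == "plasma_x1_mid", ]
  expect_equal(ppl$snap_dist, 0, tolerance = 1e-12)
  expect_equal(as.character(m$label[ppl$cell]), "PL_X1")
  # the ECF middle probe is exact for the default resolution
  pm <- pi[pi$probe == "ecf_middle", ]
  expect_equal(pm$snap_dist, 0, tolerance = 1e-12)
  expect_equal(as.character(m$label[pm$cell]), "ECF")
  # corner probes snap to nearby ECF cells, within one cell diagonal
  pc <- pi[pi$probe %in% c("corner1", "corner2", "edge"), ]
  expect_true(all(!m$plasma[pc$cell]))
  expect_true(all(pc$snap_dist < sqrt(3) * max(m$widths)))
})

test_that("axis-permuted probes agree when the flow is axis-symmetric", {
  # with v_ecf = 0 the geometry and capillary flow treat the three axes
  # symmetrically about the inlet-outlet diagonal
  cfg <- t2_config()
  cfg$ecf$v_ecf <- 0
  g <- cfg$geometry
  # off-lattice point chosen to snap to a unique nearest ECF cell, so the
  # three cyclic images land on cyclic images of the same cell
  cc <- 12e-6
  probes <- data.frame(
    probe = c("px", "py", "pz"), domain = "ecf",
    x = c(g$x_r / 2, cc, cc),
    y = c(cc, g$x_r / 2, cc),
    z = c(cc, cc, g$x_r / 2))
  st <- solver_settings(n = 12, t_end = 1e3, times = c(0, 10, 100, 1e3),
                        audit = FALSE)
  res <- simulate(cfg, st, probes = probes)
  vx <- probe_series(res, "px", "Cecf")$value_umol_per_L
  vy <- probe_series(res, "py", "Cecf")$value_umol_per_L
  vz <- probe_series(res, "pz", "Cecf")$value_umol_per_L
  expect_equal(vx, vy, tolerance = 1e-8)
  expect_equal(vx, vz, tolerance = 1e-8)
})

test_that("fields stay nonnegative and bound pools stay below capacity", {
  res <- sim_cached(t2_config(), sweep_settings())
  idx <- res$state_index
  tol <- 10 * res$settings$atol
  expect_gt(min(res$state[, 1L + idx$i_pl]), -tol)
  expect_gt(min(res$state[, 1L + idx$i_ce]), -tol)
  b <- res$config$binding
  expect_gt(min(res$state[, 1L + idx$i_b1]), -tol)
  expect_lt(max(res$state[, 1L + idx$i_b1]), b$B1max + 1e-6)
  expect_lt(max(res$state[, 1L + idx$i_b2]), b$B2max + 1e-3)
})

test_that("get_field reconstructs snapshots and rejects unknown times", {
  cfg <- t2_config()
  st <- solver_settings(n = 8, t_end = 100, times = c(0, 50, 100))
  res <- simulate(cfg, st)
  arr <- get_field(res, "Cecf", 100)
  expect_equal(dim(arr), rep(res$mesh$nc, 3))
  expect_equal(sum(!is.na(arr)), sum(!res$mesh$plasma))
  cpl <- get_field(res, "Cpl", 100)
  expect_equal(sum(!is.na(cpl)), sum(res$mesh$plasma))
  # inlet cell carries the forcing, outlet is clamped to zero
  expect_equal(cpl[res$mesh$in_id], bateman(100, cfg$pk))
  expect_equal(cpl[res$mesh$out_id], 0)
  expect_error(get_field(res, "Cecf", 73), "available")
})

test_that("nondimensionalization round-trips and the scaled cube edge is 1", {
  cfg <- t2_config()
  nd <- nondimensionalize(cfg)
  expect_equal(nd$config$geometry$x_r, 1, tolerance = 1e-15)
  expect_equal(nd$config$ecf$D_star, 1, tolerance = 1e-15)
  expect_equal(nd$scales$T_s, cfg$geometry$x_r^2 / cfg$ecf$D_star)
  back <- dimensionalize(nd$config, nd$scales)
  for (sec in c("geometry", "pk", "flow", "ecf", "binding")) {
    expect_equal(unlist(cfg[[sec]]), unlist(back[[sec]]), tolerance = 1e-12)
  }
  expect_equal(unlist(cfg$bbb[c("P", "Tm_in", "Km_in", "Tm_out", "Km_out", "SA_BBB")]),
               unlist(back$bbb[c("P", "Tm_in", "Km_in", "Tm_out", "Km_out", "SA_BBB")]),
               tolerance = 1e-12)
})

test_that("dimensional and nondimensional integration paths agree", {
  cfg <- t2_config()
  cfg$bbb$Tm_in <- 1e-7  # exercise the saturable terms under scaling too
  st <- solver_settings(n = 8, t_end = 2e4,
                        times = c(0, 10^seq(0, log10(2e4), length.out = 15)),
                        rtol = 1e-9, atol = 1e-13, audit = FALSE)
  r1 <- simulate(cfg, st)
  r2 <- simulate(cfg, st, nondimensional = TRUE)
  for (fld in c("Cecf", "B1", "B2")) {
    a <- probe_series(r1, "ecf_middle", fld)$value_umol_per_L
    b <- probe_series(r2, "ecf_middle", fld)$value_umol_per_L
    expect_equal(a, b, tolerance = 1e-5)
    # agreement relative to the series scale is much tighter than pointwise
    expect_lt(max(abs(a - b)) / max(a), 1e-6)
  }
})

test_that("integration failure reports the failing time", {
  cfg <- t2_config()
  st <- solver_settings(n = 8, t_end = 1e5, maxsteps = 2,
                        times = c(0, 1e4, 1e5))
  err <- tryCatch(suppressWarnings(simulate(cfg, st)), error = function(e) e)
  expect_s3_class(err, "bu_solver_error")
  expect_match(conditionMessage(err), "before t =")
})

test_that("mass audit closes the books and errors when disabled", {
  res <- sim_cached(t2_config(), sweep_settings())
  au <- mass_audit(res)
  s <- attr(au, "summary")
  expect_lt(s$rel_residual_plasma, 1e-6)
  expect_lt(s$rel_residual_ecf, 1e-6)
  # all drug in the ECF arrived through the BBB (plus the bulk-flow boundary
  # terms reported separately)
  expect_gt(s$cum_bbb, 0)
  r2 <- simulate(t2_config(), solver_settings(n = 8, t_end = 10,
                                              times = c(0, 10), audit = FALSE))
  expect_error(mass_audit(r2), "audit = TRUE")
})
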