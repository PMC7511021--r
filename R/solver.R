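# Coupled plasma/BBB/ECF method-of-lines system and its stiff time
# integration. The state vector is
#   [ C_pl on dynamic plasma cells | C_ECF | B1 | B2 | audit integrals ]
# with the inlet box clamped algebraically to the Bateman forcing and the
# outlet box (on the cube surface) clamped to zero. The binding kinetics make
# the system stiff, so an implicit sparse integrator (lsodes) is used.

#' Solver settings
#'
#' @param n Mesh resolution: grid lines per dimension (default 18).
#' @param t_end Final time (s).
#' @param times Output times (s), strictly increasing, within `[0, t_end]`.
#'   Default: 0 plus 51 logarithmically spaced points from 1 s to `t_end`.
#' @param rtol,atol Relative/absolute integration tolerances (lsodes).
#' @param audit Record the mass-audit integrals (see [mass_audit()]).
#' @param maxsteps Maximum internal integrator steps per output interval.
#' @param method `"lsodes"` (default): adaptive stiff integration with a
#'   sparse Jacobian, the right choice for the full time horizon.
#'   `"rk4"`: fixed-step explicit Runge-Kutta, cheaper for short horizons
#'   and fine meshes where the sparse LU dominates; the step obeys the
#'   advective/diffusive stability limit.
#' @param dt Fixed step (s) for `method = "rk4"`; default: 0.4 over the
#'   largest local rate of the discrete operator.
#' @param plasma_forcing `"bateman"` (single oral dose) or `"constant"`
#'   (fixed inlet concentration `forcing_value`, used for steady-state
#'   extraction experiments).
#' @param forcing_value Inlet concentration (umol/L) for constant forcing.
#' @param clamp_ecf If non-`NULL`, hold the free ECF concentration fixed at
#'   this value (umol/L) everywhere: used for binding-equilibrium and
#'   unidirectional-influx experiments.
#' @param init_ecf Initial free ECF concentration: scalar, vector (one value
#'   per ECF cell) or `function(x, y, z)`; default zero everywhere.
#' @return Object of class `bu_settings`.
#' @export
solver_settings <- function(n = 18, t_end = 1e5, times = NULL,
                            rtol = 1e-6, atol = 1e-10, audit = TRUE,
                            maxsteps = 20000,
                            method = c("lsodes", "rk4"), dt = NULL,
                            plasma_forcing = c("bateman", "constant"),
                            forcing_value = NULL, clamp_ecf = NULL,
                            init_ecf = NULL) {
  plasma_forcing <- match.arg(plasma_forcing)
  method <- match.arg(method)
  t_end <- .chk_num(t_end, "t_end", 0, allow_zero = FALSE)
  if (is.null(times)) {
    times <- c(0, 10^seq(log10(min(1, t_end)), log10(t_end), length.out = 51))
  }
  times <- unique(c(0, as.numeric(times)))
  if (any(diff(times) <= 0) || any(times < 0) || max(times) > t_end * (1 + 1e-12)) {
    stop("output times must be strictly increasing within [0, t_end]")
  }
  if (plasma_forcing == "constant" && is.null(forcing_value)) {
    stop("constant plasma forcing requires 'forcing_value'")
  }
  structure(list(n = n, t_end = t_end, times = times, rtol = rtol, atol = atol,
                 audit = audit, maxsteps = maxsteps, method = method, dt = dt,
                 plasma_forcing = plasma_forcing, forcing_value = forcing_value,
                 clamp_ecf = clamp_ecf, init_ecf = init_ecf),
            class = "bu_settings")
}

.aux_names <- c("cum_bbb", "cum_pl_in", "cum_pl_out", "cum_pl_junction",
                "cum_ecf_in", "cum_ecf_out", "cum_ecf_imbalance")

# classical fixed-step RK4 with exact landing on the requested output times
.integrate_rk4 <- function(rhs, y0, times, dt) {
  ny <- length(y0)
  out <- matrix(0, nrow = length(times), ncol = ny + 1L)
  out[, 1] <- times
  y <- y0
  out[1, -1] <- y
  for (k in seq_len(length(times) - 1L)) {
    t0 <- times[k]; t1 <- times[k + 1L]
    nsub <- max(1L, ceiling((t1 - t0) / dt))
    h <- (t1 - t0) / nsub
    for (s in seq_len(nsub)) {
      t <- t0 + (s - 1L) * h
      k1 <- rhs(t, y, NULL)[[1]]
      k2 <- rhs(t + h / 2, y + h / 2 * k1, NULL)[[1]]
      k3 <- rhs(t + h / 2, y + h / 2 * k2, NULL)[[1]]
      k4 <- rhs(t + h, y + h * k3, NULL)[[1]]
      y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    out[k + 1L, -1] <- y
  }
  out
}

# default probe locations; snapped to the nearest cell of the right domain
.default_probes <- function(geom) {
  xr <- geom$x_r; r <- geom$r
  data.frame(
    probe = c("plasma_x1_mid", "ecf_middle", "corner1", "corner2", "edge"),
    domain = c("plasma", "ecf", "ecf", "ecf", "ecf"),
    x = c(xr / 2, xr / 2, r, xr - r, 0),
    y = c(r / 2, xr / 2, r, xr - r, xr / 2),
    z = c(r / 2, xr / 2, r, xr - r, xr / 2),
    stringsAsFactors = FALSE
  )
}

.snap_probes <- function(mesh, probes) {
  cell <- integer(nrow(probes)); snap <- numeric(nrow(probes))
  for (i in seq_len(nrow(probes))) {
    cand <- if (probes$domain[i] == "plasma") which(mesh$plasma) else which(!mesh$plasma)
    d2 <- (mesh$coords[cand, 1] - probes$x[i])^2 +
      (mesh$coords[cand, 2] - probes$y[i])^2 +
      (mesh$coords[cand, 3] - probes$z[i])^2
    j <- cand[which.min(d2)]
    cell[i] <- j; snap[i] <- sqrt(min(d2))
  }
  probes$cell <- cell
  probes$snap_dist <- snap
  probes
}

#' Simulate the 3D brain unit
#'
#' Integrates the coupled capillary-plasma / BBB / brain-ECF system from the
#' all-zero initial state, with the inlet box following the plasma forcing.
#' Deterministic: identical configurations give identical results.
#'
#' @param config A [bu_config()] (e.g. `fixture("table2_default")`).
#' @param settings A [solver_settings()] object.
#' @param mesh Optional pre-built [build_mesh()] (must match the geometry).
#' @param probes Optional probe table (`data.frame` with columns `probe`,
#'   `domain` (`"plasma"`/`"ecf"`), `x`, `y`, `z`); defaults to the standard
#'   set: plasma mid-capillary, ECF middle, two corners, one edge midpoint.
#' @param nondimensional If `TRUE`, integrate the internally rescaled
#'   (dimensionless) system and map the outputs back to physical units;
#'   results agree with the dimensional path to integration accuracy.
#' @return Object of class `bu_result`: `times` (s), `probes` (long
#'   data.frame: `time_s`, `probe`, `field`, `value_umol_per_L`),
#'   `probe_info`, `audit` (see [mass_audit()]), `mesh`, `config`,
#'   `settings`, `meta`, and the full field matrix (`state`).
#' @export
simulate <- function(config, settings = solver_settings(), mesh = NULL,
                     probes = NULL, nondimensional = FALSE) {
  stopifnot(inherits(config, "bu_config"), inherits(settings, "bu_settings"))

  if (nondimensional) {
    nd <- nondimensionalize(config)
    sc <- nd$scales
    s2 <- settings
    s2$t_end <- settings$t_end / sc$T_s
    s2$times <- settings$times / sc$T_s
    s2$atol <- settings$atol / sc$C_s
    s2$audit <- FALSE
    if (!is.null(s2$forcing_value)) s2$forcing_value <- settings$forcing_value / sc$C_s
    if (!is.null(s2$clamp_ecf)) s2$clamp_ecf <- settings$clamp_ecf / sc$C_s
    if (!is.null(s2$init_ecf)) {
      s2$init_ecf <- if (is.function(settings$init_ecf)) {
        f <- settings$init_ecf
        function(x, y, z) f(x * sc$L_m, y * sc$L_m, z * sc$L_m) / sc$C_s
      } else settings$init_ecf / sc$C_s
    }
    res <- simulate(nd$config, s2, mesh = NULL, probes = probes,
                    nondimensional = FALSE)
    # map back to physical units
    res$times <- res$times * sc$T_s
    res$probes$time_s <- res$probes$time_s * sc$T_s
    res$probes$value_umol_per_L <- res$probes$value_umol_per_L * sc$C_s
    res$state[, -1] <- res$state[, -1] * sc$C_s
    res$state[, 1] <- res$state[, 1] * sc$T_s
    res$config <- config
    res$settings <- settings
    res$meta$nondimensional <- TRUE
    res$meta$scales <- sc
    return(res)
  }

  if (is.null(mesh)) mesh <- build_mesh(config$geometry, settings$n)
  stopifnot(inherits(mesh, "bu_mesh"))
  ops <- .mesh_operators(mesh)
  lc <- config$litre_conv
  np <- length(ops$pl_dyn); ne <- ops$ne
  pl_dyn <- ops$pl_dyn; ec <- ops$ec
  in_id <- mesh$in_id; out_id <- mesh$out_id

  pkp <- config$pk; vb <- config$flow$v_blood
  bbb <- config$bbb; ecfp <- config$ecf; bind <- config$binding
  forcing <- if (settings$plasma_forcing == "bateman") {
    function(t) bateman(t, pkp)
  } else {
    cval <- settings$forcing_value
    function(t) cval
  }

  clamp <- settings$clamp_ecf
  audit_on <- isTRUE(settings$audit)
  naux <- if (audit_on) length(.aux_names) else 0L

  # initial state (all fields zero unless overridden)
  Ce0 <- numeric(ne)
  if (!is.null(settings$init_ecf)) {
    Ce0 <- if (is.function(settings$init_ecf)) {
      settings$init_ecf(mesh$coords[ec, 1], mesh$coords[ec, 2], mesh$coords[ec, 3])
    } else rep_len(settings$init_ecf, ne)
  }
  if (!is.null(clamp)) Ce0 <- rep(clamp, ne)
  y0 <- c(numeric(np), Ce0, numeric(ne), numeric(ne), numeric(naux))

  i_pl <- seq_len(np)
  i_ce <- np + seq_len(ne)
  i_b1 <- np + ne + seq_len(ne)
  i_b2 <- np + 2L * ne + seq_len(ne)

  M <- ops$M; L <- ops$L; A <- ops$A
  Gp <- ops$Gp_raw; Ge <- ops$Ge_raw
  face_p <- ops$face_p; face_le <- ops$face_le; face_area <- ops$face_area
  D_star <- ecfp$D_star; ve <- ecfp$v_ecf
  P <- bbb$P; Tin <- bbb$Tm_in; Kin <- bbb$Km_in
  Tout <- bbb$Tm_out; Kout <- bbb$Km_out; SA <- bbb$SA_BBB
  k1on <- bind$k1on; k1off <- bind$k1off; B1max <- bind$B1max
  k2on <- bind$k2on; k2off <- bind$k2off; B2max <- bind$B2max
  in_a <- ops$in_faces$area; out_cells <- ops$out_faces$cells
  out_a <- ops$out_faces$area
  jw_pl <- ops$jw_pl; jw_ecf <- ops$jw_ecf
  bi_le <- ops$le_of[ops$ecf_bnd_in$cells]; bi_a <- ops$ecf_bnd_in$area
  bo_le <- ops$le_of[ops$ecf_bnd_out$cells]; bo_a <- ops$ecf_bnd_out$area
  Cfull <- numeric(mesh$ncell)

  rhs <- function(t, y, parms) {
    Cfull[pl_dyn] <- y[i_pl]
    Cfull[in_id] <- forcing(t)
    Cfull[out_id] <- 0
    Ce <- y[i_ce]; B1 <- y[i_b1]; B2 <- y[i_b2]

    u <- Cfull[face_p]; v <- Ce[face_le]
    # saturable terms evaluated at nonnegative concentrations (the stiff
    # integrator may undershoot zero by ~atol)
    phi <- lc * P * (u - v) +
      Tin * pmax(u, 0) / (SA * (Kin + pmax(u, 0))) -
      Tout * pmax(v, 0) / (SA * (Kout + pmax(v, 0)))

    dpl <- vb * as.numeric(M %*% Cfull)[pl_dyn] -
      as.numeric(Gp %*% phi)[pl_dyn] / lc

    r1 <- k1on * Ce * (B1max - B1) - k1off * B1
    r2 <- k2on * Ce * (B2max - B2) - k2off * B2
    dce <- if (is.null(clamp)) {
      D_star * as.numeric(L %*% Ce) + ve * as.numeric(A %*% Ce) +
        as.numeric(Ge %*% phi) / lc - r1 - r2
    } else numeric(ne)

    if (audit_on) {
      rate_in <- vb * lc * Cfull[in_id] * sum(in_a)
      rate_out <- vb * lc * sum(out_a * Cfull[out_cells])
      rate_junc <- vb * lc * sum(jw_pl * Cfull) - rate_in + rate_out
      rate_ei <- ve * lc * sum(bi_a * Ce[bi_le])
      rate_eo <- ve * lc * sum(bo_a * Ce[bo_le])
      rate_eimb <- ve * lc * sum(jw_ecf * Ce) - rate_ei + rate_eo
      daux <- c(sum(phi * face_area), rate_in, rate_out, rate_junc,
                rate_ei, rate_eo, rate_eimb)
      list(c(dpl, dce, r1, r2, daux))
    } else {
      list(c(dpl, dce, r1, r2))
    }
  }

  if (settings$method == "rk4") {
    dt <- settings$dt
    if (is.null(dt)) {
      # stability bound from the largest local rate of the discrete operator:
      # diffusion + ECF advection + capillary advection + binding kinetics
      rate <- max(D_star * max(abs(Matrix::diag(L))) +
                    ve * max(abs(Matrix::diag(A))),
                  if (np > 0) vb * max(abs(Matrix::diag(M))) else 0,
                  k1on * B1max + k1off, k2on * B2max + k2off)
      dt <- 0.4 / rate
    }
    out <- .integrate_rk4(rhs, y0, settings$times, dt)
  } else {
    jp <- .jac_pattern(ops, naux, clamp_ecf = !is.null(clamp))
    # work-array size must cover the sparse-LU fill-in, which lsodes cannot
    # grow by itself; start from an empirical bound and retry larger if needed
    lrw <- max(2e6, 60 * jp$nnz)
    out <- NULL
    for (attempt in 1:4) {
      out <- tryCatch(
        deSolve::lsodes(y = y0, times = settings$times, func = rhs,
                        parms = NULL, rtol = settings$rtol,
                        atol = settings$atol, sparsetype = "sparsejan",
                        inz = jp$inz, nnz = jp$nnz, lrw = lrw,
                        maxsteps = settings$maxsteps),
        error = function(e) e)
      if (!inherits(out, "error")) break
      if (attempt == 4L || !grepl("illegal input", conditionMessage(out))) {
        .stop_class(sprintf("integrator setup failed: %s", conditionMessage(out)),
                    "bu_solver_error")
      }
      lrw <- lrw * 4
    }
  }
  if (nrow(out) < length(settings$times)) {
    t_fail <- settings$times[nrow(out) + 1L]
    .stop_class(sprintf(
      "integration failed before t = %g s; consider relaxing rtol/atol (current %g/%g) or raising maxsteps",
      t_fail, settings$rtol, settings$atol), "bu_solver_error")
  }

  # probe series
  pinfo <- probes %||% .default_probes(config$geometry)
  pinfo <- .snap_probes(mesh, pinfo)
  times <- out[, 1]
  prb <- list()
  for (i in seq_len(nrow(pinfo))) {
    cell <- pinfo$cell[i]
    if (pinfo$domain[i] == "plasma") {
      vals <- if (cell == in_id) {
        vapply(times, forcing, numeric(1))
      } else if (cell == out_id) {
        numeric(length(times))
      } else {
        out[, 1L + match(cell, pl_dyn)]
      }
      prb[[length(prb) + 1L]] <- data.frame(
        time_s = times, probe = pinfo$probe[i], field = "Cpl",
        value_umol_per_L = as.numeric(vals))
    } else {
      leid <- match(cell, ec)
      for (fld in c("Cecf", "B1", "B2")) {
        col <- switch(fld, Cecf = i_ce[leid], B1 = i_b1[leid], B2 = i_b2[leid])
        prb[[length(prb) + 1L]] <- data.frame(
          time_s = times, probe = pinfo$probe[i], field = fld,
          value_umol_per_L = as.numeric(out[, 1L + col]))
      }
    }
  }
  probes_df <- do.call(rbind, prb)

  audit <- NULL
  if (audit_on) {
    vols <- mesh$vol
    S_pl <- lc * as.numeric(out[, 1L + i_pl, drop = FALSE] %*% vols[pl_dyn])
    S_ce <- lc * as.numeric(out[, 1L + i_ce, drop = FALSE] %*% vols[ec])
    S_b1 <- lc * as.numeric(out[, 1L + i_b1, drop = FALSE] %*% vols[ec])
    S_b2 <- lc * as.numeric(out[, 1L + i_b2, drop = FALSE] %*% vols[ec])
    aux <- out[, 1L + np + 3L * ne + seq_len(naux), drop = FALSE]
    colnames(aux) <- .aux_names
    audit <- data.frame(time_s = times, stored_plasma = S_pl,
                        stored_ecf_free = S_ce, stored_B1 = S_b1,
                        stored_B2 = S_b2, aux)
    audit$residual_plasma <- (S_pl - S_pl[1]) -
      (aux[, "cum_pl_in"] - aux[, "cum_pl_out"] +
         aux[, "cum_pl_junction"] - aux[, "cum_bbb"])
    S_tot <- S_ce + S_b1 + S_b2
    audit$residual_ecf <- if (is.null(clamp)) {
      (S_tot - S_tot[1]) -
        (aux[, "cum_bbb"] + aux[, "cum_ecf_in"] - aux[, "cum_ecf_out"] +
           aux[, "cum_ecf_imbalance"])
    } else NA_real_
  }

  sig <- .fnv1a(paste(c(format(unlist(config[c("geometry", "pk", "flow", "bbb",
                                               "ecf", "binding")]), digits = 17),
                        settings$n), collapse = ","))
  structure(list(
    times = times, probes = probes_df, probe_info = pinfo, audit = audit,
    state = out, state_index = list(i_pl = i_pl, i_ce = i_ce, i_b1 = i_b1,
                                    i_b2 = i_b2, pl_dyn = pl_dyn, ec = ec),
    mesh = mesh, config = config, settings = settings,
    meta = list(param_hash = sig, nondimensional = FALSE,
                package_version = as.character(utils::packageVersion("brainunit3d")))
  ), class = "bu_result")
}

#' @export
print.bu_result <- function(x, ...) {
  cat(sprintf("brain unit simulation: %d output times (t = %g..%g s), mesh n = %d\n",
              length(x$times), min(x$times), max(x$times), x$mesh$n))
  mid <- x$probes[x$probes$probe == "ecf_middle" & x$probes$field == "Cecf", ]
  if (nrow(mid)) {
    cat(sprintf("  peak C_ECF (middle): %.4g umol/L at t = %.4g s\n",
                max(mid$value_umol_per_L), mid$time_s[which.max(mid$value_umol_per_L)]))
  }
  cat(sprintf("  parameter hash: %s\n", x$meta$param_hash))
  invisible(x)
}

#' Extract one probe's concentration-time series
#'
#' @param result A [simulate()] result.
#' @param probe Probe name (see `result$probe_info`).
#' @param field One of `"Cpl"`, `"Cecf"`, `"B1"`, `"B2"`.
#' @return data.frame with `time_s` and `value_umol_per_L`.
#' @export
probe_series <- function(result, probe, field) {
  stopifnot(inherits(result, "bu_result"))
  df <- result$probes[result$probes$probe == probe & result$probes$field == field,
                      c("time_s", "value_umol_per_L")]
  if (!nrow(df)) stop(sprintf("no series for probe '%s', field '%s'", probe, field))
  rownames(df) <- NULL
  df
}

#' Extract a full field snapshot as a 3D array
#'
#' @param result A [simulate()] result.
#' @param field One of `"Cpl"`, `"Cecf"`, `"B1"`, `"B2"`.
#' @param time Requested output time (must be one of `result$times`).
#' @return 3D numeric array over the mesh cells; `NA` outside the field's
#'   domain (plasma cells for ECF fields and vice versa).
#' @export
get_field <- function(result, field = c("Cpl", "Cecf", "B1", "B2"), time) {
  stopifnot(inherits(result, "bu_result"))
  field <- match.arg(field)
  k <- match(TRUE, abs(result$times - time) <= 1e-9 * max(1, abs(time)))
  if (is.na(k)) {
    stop(sprintf("time %g s is not an output time; available: %s",
                 time, paste(signif(result$times, 6), collapse = ", ")))
  }
  idx <- result$state_index
  mesh <- result$mesh
  full <- rep(NA_real_, mesh$ncell)
  if (field == "Cpl") {
    full[idx$pl_dyn] <- result$state[k, 1L + idx$i_pl]
    full[mesh$in_id] <- if (result$settings$plasma_forcing == "bateman") {
      bateman(result$times[k], result$config$pk)
    } else result$settings$forcing_value
    full[mesh$out_id] <- 0
  } else {
    cols <- switch(field, Cecf = idx$i_ce, B1 = idx$i_b1, B2 = idx$i_b2)
    full[idx$ec] <- result$state[k, 1L + cols]
  }
  array(full, dim = rep(mesh$nc, 3))
}

#' Mass audit of a simulation
#'
#' Ledger equating changes in stored drug amount (umol) to time-integrated
#' interface and boundary fluxes, all integrated alongside the state to
#' solver accuracy: BBB exchange, inlet inflow, outlet outflow, the junction
#' mixing imbalance of the equal-velocity capillary network, and the ECF
#' bulk-flow boundary terms. `residual_plasma`/`residual_ecf` are the closure
#' errors; `rel_residual_ecf` is reported relative to the larger of the
#' cumulative BBB exchange and the peak stored ECF amount.
#'
#' @param result A [simulate()] result run with `audit = TRUE`.
#' @return Object of class `bu_audit`: the per-output-time ledger data.frame
#'   with a summary attribute.
#' @export
mass_audit <- function(result) {
  stopifnot(inherits(result, "bu_result"))
  if (is.null(result$audit)) {
    stop("simulation was run with audit = FALSE; re-run with solver_settings(audit = TRUE)")
  }
  a <- result$audit
  nlast <- nrow(a)
  denom_pl <- max(abs(a$cum_pl_in[nlast]), max(abs(a$stored_plasma - a$stored_plasma[1])),
                  .Machine$double.xmin)
  S_tot <- a$stored_ecf_free + a$stored_B1 + a$stored_B2
  denom_ecf <- max(abs(a$cum_bbb[nlast]), max(abs(S_tot)), .Machine$double.xmin)
  summary <- list(
    rel_residual_plasma = abs(a$residual_plasma[nlast]) / denom_pl,
    rel_residual_ecf = if (all(is.na(a$residual_ecf))) NA_real_ else
      abs(a$residual_ecf[nlast]) / denom_ecf,
    cum_bbb = a$cum_bbb[nlast], cum_pl_in = a$cum_pl_in[nlast],
    cum_pl_out = a$cum_pl_out[nlast], cum_pl_junction = a$cum_pl_junction[nlast]
  )
  structure(a, class = c("bu_audit", "data.frame"), summary = summary)
}

#' @export
print.bu_audit <- function(x, ...) {
  s <- attr(x, "summary")
  cat("mass audit (amounts in umol)\n")
  cat(sprintf("  cumulative: inlet %.4g, outlet %.4g, BBB exchange %.4g, junction imbalance %.4g\n",
              s$cum_pl_in, s$cum_pl_out, s$cum_bbb, s$cum_pl_junction))
  cat(sprintf("  relative closure residual: plasma %.3g, ECF %.3g\n",
              s$rel_residual_plasma, s$rel_residual_ecf))
  invisible(x)
}

# ---------------------------------------------------------------------------
# nondimensionalization

#' Nondimensionalize a configuration
#'
#' Rescales length by the unit edge `x_r`, time by the diffusion time
#' `x_r^2 / D*`, and concentration by the plasma scale `F Dose / Vd`, giving
#' a configuration whose cube edge, effective diffusivity and concentration
#' scale are all 1. [simulate()] integrates either form; the two paths agree
#' to integration accuracy (`nondimensional = TRUE`).
#'
#' @param config A [bu_config()] object.
#' @return List with `config` (the scaled `bu_config`) and `scales`
#'   (`L_m`, `T_s`, `C_s`, plus the originals needed for an exact round
#'   trip, see [dimensionalize()]).
#' @export
nondimensionalize <- function(config) {
  stopifnot(inherits(config, "bu_config"))
  if (config$ecf$D_star <= 0) stop("D_star must be positive to nondimensionalize")
  L <- config$geometry$x_r
  T_s <- L^2 / config$ecf$D_star
  C_s <- config$pk$F_bio * config$pk$Dose / config$pk$Vd
  if (C_s <= 0) C_s <- 1
  lc <- config$litre_conv
  pk <- config$pk
  scaled <- bu_config(
    geometry = geometry_params(config$geometry$d_cap / L, config$geometry$r / L),
    pk = plasma_pk_params(F_bio = pk$F_bio, Dose = pk$Dose / (C_s * pk$Vd),
                          Vd = 1, ka = pk$ka * T_s, ke = pk$ke * T_s),
    flow = flow_params(config$flow$v_blood * T_s / L),
    bbb = bbb_params(P = config$bbb$P * T_s / L,
                     Tm_in = config$bbb$Tm_in * T_s / (lc * C_s * L^3),
                     Km_in = config$bbb$Km_in / C_s,
                     Tm_out = config$bbb$Tm_out * T_s / (lc * C_s * L^3),
                     Km_out = config$bbb$Km_out / C_s,
                     SA_BBB = config$bbb$SA_BBB / L^2),
    ecf = ecf_params(D_star = 1, v_ecf = config$ecf$v_ecf * T_s / L),
    binding = binding_params(
      B1max = config$binding$B1max / C_s,
      k1on = config$binding$k1on * C_s * T_s, k1off = config$binding$k1off * T_s,
      B2max = config$binding$B2max / C_s,
      k2on = config$binding$k2on * C_s * T_s, k2off = config$binding$k2off * T_s),
    warn = FALSE)
  scaled$litre_conv <- 1
  list(config = scaled,
       scales = list(L_m = L, T_s = T_s, C_s = C_s,
                     Dose = pk$Dose, Vd = pk$Vd, litre_conv = lc))
}

#' Restore a nondimensionalized configuration
#'
#' Exact inverse of [nondimensionalize()] (to floating precision).
#'
#' @param scaled The scaled configuration.
#' @param scales The scale record returned by [nondimensionalize()].
#' @return The dimensional [bu_config()].
#' @export
dimensionalize <- function(scaled, scales) {
  stopifnot(inherits(scaled, "bu_config"))
  L <- scales$L_m; T_s <- scales$T_s; C_s <- scales$C_s; lc <- scales$litre_conv
  cfg <- bu_config(
    geometry = geometry_params(scaled$geometry$d_cap * L, scaled$geometry$r * L),
    pk = plasma_pk_params(F_bio = scaled$pk$F_bio, Dose = scales$Dose,
                          Vd = scales$Vd, ka = scaled$pk$ka / T_s,
                          ke = scaled$pk$ke / T_s),
    flow = flow_params(scaled$flow$v_blood * L / T_s),
    bbb = bbb_params(P = scaled$bbb$P * L / T_s,
                     Tm_in = scaled$bbb$Tm_in * lc * C_s * L^3 / T_s,
                     Km_in = scaled$bbb$Km_in * C_s,
                     Tm_out = scaled$bbb$Tm_out * lc * C_s * L^3 / T_s,
                     Km_out = scaled$bbb$Km_out * C_s,
                     SA_BBB = scaled$bbb$SA_BBB * L^2),
    ecf = ecf_params(D_star = scaled$ecf$D_star * L^2 / T_s,
                     v_ecf = scaled$ecf$v_ecf * L / T_s),
    binding = binding_params(
      B1max = scaled$binding$B1max * C_s,
      k1on = scaled$binding$k1on / (C_s * T_s),
      k1off = scaled$binding$k1off / T_s,
      B2max = scaled$binding$B2max * C_s,
      k2on = scaled$binding$k2on / (C_s * T_s),
      k2off = scaled$binding$k2off / T_s),
    warn = FALSE)
  cfg$litre_conv <- lc
  cfg
}
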