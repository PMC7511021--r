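# Experiment drivers: scripted parameter sweeps over the published
# sensitivity-analysis designs, spatial profiles along the inlet-to-outlet
# capillary pathway, and the Renkin-Crone extraction validation.

#' Describe a parameter sweep
#'
#' @param base Base configuration ([bu_config()]) or fixture name.
#' @param values A data.frame with one column per swept parameter path
#'   (e.g. `"flow.v_blood"`, `"bbb.Tm_in"`) and one row per run, or a named
#'   list of vectors which is crossed with [expand.grid()].
#' @param settings [solver_settings()] used for every member run.
#' @param probes Optional probe table passed to [simulate()].
#' @param label Optional name for printing.
#' @return Object of class `bu_sweep_spec`. Parameter values outside the
#'   physiological ranges are permitted; they are flagged per run in the
#'   sweep results (the published flow-velocity sweep deliberately reaches
#'   below the physiological range).
#' @export
sweep_spec <- function(base, values, settings = solver_settings(),
                       probes = NULL, label = NULL) {
  if (is.character(base)) base <- fixture(base)
  stopifnot(inherits(base, "bu_config"))
  if (!is.data.frame(values)) values <- expand.grid(values)
  stopifnot(nrow(values) >= 1L, ncol(values) >= 1L)
  structure(list(base = base, values = values, settings = settings,
                 probes = probes, label = label %||% "sweep"),
            class = "bu_sweep_spec")
}

#' @export
print.bu_sweep_spec <- function(x, ...) {
  cat(sprintf("sweep '%s': %d runs over {%s}\n", x$label, nrow(x$values),
              paste(names(x$values), collapse = ", ")))
  invisible(x)
}

#' Run a parameter sweep
#'
#' One deterministic simulation per row of the value grid. Probe series are
#' collated into a single tidy table; per-run derived quantities (peak free
#' ECF concentration and its time at the middle probe, and the duration the
#' specifically bound concentration stays at or above 90% of its maximum)
#' are summarized alongside.
#'
#' @param spec A [sweep_spec()] (or a fixture name resolving to one).
#' @param keep_results Keep the full `bu_result` objects (memory-heavy).
#' @return Object of class `bu_sweep`: `table` (columns: swept parameters,
#'   `run`, `time_s`, `probe`, `field`, `value_umol_per_L`), `derived`,
#'   `values` (with an `out_of_range` flag column), and optionally `results`.
#' @export
run_sweep <- function(spec, keep_results = FALSE) {
  if (is.character(spec)) spec <- fixture(spec)
  stopifnot(inherits(spec, "bu_sweep_spec"))
  vals <- spec$values
  tabs <- vector("list", nrow(vals))
  der <- vector("list", nrow(vals))
  results <- if (keep_results) vector("list", nrow(vals))
  flags <- character(nrow(vals))
  for (i in seq_len(nrow(vals))) {
    res <- tryCatch({
      cfg <- spec$base
      for (p in names(vals)) cfg <- set_param(cfg, p, vals[i, p])
      flags[i] <- paste(suppressWarnings(check_ranges(cfg, warn = FALSE))$param,
                        collapse = ";")
      simulate(cfg, spec$settings, probes = spec$probes)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      done <- list(table = do.call(rbind, tabs[seq_len(i - 1L)]),
                   derived = do.call(rbind, der[seq_len(i - 1L)]))
      cond <- structure(
        class = c("bu_sweep_error", "error", "condition"),
        list(message = sprintf(
          "sweep '%s' failed at run %d (%s): %s", spec$label, i,
          paste(sprintf("%s = %g", names(vals), unlist(vals[i, ])), collapse = ", "),
          conditionMessage(res)),
          call = sys.call(-1), partial = done))
      stop(cond)
    }
    tab <- res$probes
    names(tab)[names(tab) == "time_s"] <- "time_s"
    for (p in rev(names(vals))) tab[[p]] <- vals[i, p]
    tab$run <- i
    tabs[[i]] <- tab

    mid_c <- probe_series(res, "ecf_middle", "Cecf")
    mid_b1 <- probe_series(res, "ecf_middle", "B1")
    der[[i]] <- data.frame(
      run = i, vals[i, , drop = FALSE],
      peak_Cecf_mid = max(mid_c$value_umol_per_L),
      t_peak_Cecf_mid = mid_c$time_s[which.max(mid_c$value_umol_per_L)],
      dur_B1_above_90pct = duration_above(mid_b1$time_s, mid_b1$value_umol_per_L, 0.9),
      out_of_range = flags[i], row.names = NULL)
    if (keep_results) results[[i]] <- res
  }
  vals$out_of_range <- flags
  structure(list(table = do.call(rbind, tabs), derived = do.call(rbind, der),
                 values = vals, spec = spec, results = results),
            class = "bu_sweep")
}

#' @export
print.bu_sweep <- function(x, ...) {
  cat(sprintf("sweep '%s': %d runs completed\n", x$spec$label, nrow(x$values)))
  print(x$derived, digits = 4)
  invisible(x)
}

#' Duration a series spends at or above a fraction of its maximum
#'
#' Computes the total time with `value >= frac * max(value)` on the discrete
#' output grid, with linear interpolation at the threshold crossings.
#'
#' @param time Time points (s), increasing.
#' @param value Series values.
#' @param frac Threshold fraction of the maximum (default 0.9).
#' @return Duration (s); 0 if the series never reaches the threshold.
#' @export
duration_above <- function(time, value, frac = 0.9) {
  stopifnot(length(time) == length(value), !is.unsorted(time))
  m <- max(value)
  if (m <= 0) return(0)
  thr <- frac * m
  above <- value >= thr
  if (!any(above)) return(0)
  total <- 0
  for (k in seq_len(length(time) - 1L)) {
    t0 <- time[k]; t1 <- time[k + 1L]
    v0 <- value[k]; v1 <- value[k + 1L]
    if (above[k] && above[k + 1L]) {
      total <- total + (t1 - t0)
    } else if (above[k] != above[k + 1L] && v1 != v0) {
      tc <- t0 + (thr - v0) / (v1 - v0) * (t1 - t0)
      total <- total + if (above[k]) tc - t0 else t1 - tc
    }
  }
  total
}

#' The inlet-to-outlet capillary pathway
#'
#' The reference pathway runs from the inlet corner box along the x-directed
#' capillary at (y,z) = (0,0), turns at the cube vertex into the y-directed
#' capillary at x = x_r, z = 0, and again into the z-directed capillary at
#' x = x_r, y = y_r, ending at the outlet box. Distance is measured along the
#' capillary axis between the junction boxes, so the outlet lies at
#' `3 * d_cap` from the inlet (150 um for the default rat geometry).
#'
#' @param mesh A [build_mesh()] object.
#' @return data.frame of path cells: `cell`, `distance_m`, `label`.
#' @export
capillary_path <- function(mesh) {
  stopifnot(inherits(mesh, "bu_mesh"))
  g <- mesh$geom
  lab <- as.character(mesh$label)
  co <- mesh$coords
  seg <- function(labels, axis, d0) {
    ids <- which(lab %in% labels)
    ids <- ids[order(co[ids, axis])]
    data.frame(cell = ids,
               distance_m = d0 + pmin(pmax(co[ids, axis] - g$r, 0), g$d_cap),
               label = lab[ids])
  }
  rbind(
    data.frame(cell = mesh$in_id, distance_m = 0, label = "PL_IN"),
    seg(c("PL_X1"), 1, 0),
    seg(c("PL_Y2"), 2, g$d_cap),
    seg(c("PL_Z4"), 3, 2 * g$d_cap),
    data.frame(cell = mesh$out_id, distance_m = 3 * g$d_cap, label = "PL_OUT")
  )
}

#' Total capillary path length from inlet to outlet
#'
#' @param geom A [geometry_params()] object.
#' @return Path length (m): `3 * d_cap`.
#' @export
path_length <- function(geom) {
  stopifnot(inherits(geom, "bu_geometry"))
  3 * geom$d_cap
}

#' Concentration profile along the capillary pathway
#'
#' Returns the plasma (or adjacent-ECF) concentration versus path distance
#' from the inlet at the requested output times.
#'
#' @param result A [simulate()] result.
#' @param times Times (s); each must be one of `result$times`.
#' @param field `"Cpl"` (along the capillary cells) or `"Cecf"` (mean over
#'   the ECF cells sharing a BBB face with each capillary cell).
#' @return data.frame: `time_s`, `distance_m`, `distance_um`, `value_umol_per_L`.
#' @export
spatial_profile <- function(result, times, field = c("Cpl", "Cecf")) {
  stopifnot(inherits(result, "bu_result"))
  field <- match.arg(field)
  missing_t <- times[!vapply(times, function(t)
    any(abs(result$times - t) <= 1e-9 * max(1, abs(t))), logical(1))]
  if (length(missing_t)) {
    stop(sprintf("time(s) %s not stored; available output times: %s",
                 paste(missing_t, collapse = ", "),
                 paste(signif(result$times, 6), collapse = ", ")))
  }
  path <- capillary_path(result$mesh)
  faces <- result$mesh$faces
  out <- list()
  for (t in times) {
    if (field == "Cpl") {
      arr <- get_field(result, "Cpl", t)
      vals <- arr[path$cell]
    } else {
      arr <- get_field(result, "Cecf", t)
      vals <- vapply(path$cell, function(p) {
        nbrs <- faces$ecf[faces$plasma == p]
        if (!length(nbrs)) NA_real_ else mean(arr[nbrs])
      }, numeric(1))
    }
    out[[length(out) + 1L]] <- data.frame(
      time_s = t, distance_m = path$distance_m,
      distance_um = path$distance_m * 1e6, value_umol_per_L = vals)
  }
  do.call(rbind, out)
}

#' Validate capillary extraction against the Renkin-Crone equation
#'
#' Runs the unidirectional-influx configuration (free ECF concentration
#' clamped at zero, no active transport, constant inlet concentration) to
#' steady state for each permeability and compares the simulated extraction
#' fraction `E_sim = 1 - C_out/C0` (equivalently BBB influx per unit
#' capillary drug inflow along one flow path) with `E = 1 - exp(-PS/Q)`.
#' Here `S = 6 d_cap r` is the BBB surface area seen along one inlet-outlet
#' flow path (three rib segments, two exposed faces each) and `Q = v_blood
#' r^2` the volumetric flow of one capillary; both are reported so the
#' dimensionless group can be audited.
#'
#' @param config Base configuration (active transport is switched off).
#' @param P_values Permeabilities (m/s) to test.
#' @param C0 Inlet concentration (umol/L).
#' @param n Mesh resolution.
#' @param t_factor Integration horizon in units of the network transit time.
#' @param drift_tol Maximum relative drift of E over the final decade of
#'   integration time before the run is rejected as non-steady.
#' @return data.frame: `P`, `S_m2`, `Q_m3_per_s`, `PS_over_Q`, `E_sim`,
#'   `E_renkin_crone`, `rel_deviation`.
#' @export
renkin_crone_check <- function(config, P_values, C0 = 1, n = 18,
                               t_factor = 50, drift_tol = 1e-3) {
  stopifnot(inherits(config, "bu_config"), all(P_values >= 0))
  g <- config$geometry
  S <- 6 * g$d_cap * g$r
  Q <- config$flow$v_blood * g$r^2
  if (Q <= 0) stop("renkin_crone_check requires v_blood > 0")
  transit <- 3 * g$x_r / config$flow$v_blood
  rows <- list()
  for (P in P_values) {
    cfg <- config
    cfg$bbb$P <- P; cfg$bbb$Tm_in <- 0; cfg$bbb$Tm_out <- 0
    tt <- transit * t_factor
    st <- solver_settings(n = n, t_end = tt,
                          times = c(0, tt * 10^seq(-3, 0, length.out = 16)),
                          plasma_forcing = "constant", forcing_value = C0,
                          clamp_ecf = 0, audit = FALSE,
                          rtol = 1e-8, atol = 1e-10 * C0)
    res <- simulate(cfg, st)
    mesh <- res$mesh
    ops <- .mesh_operators(mesh)
    feeders <- ops$out_faces$cells
    idx <- match(feeders, res$state_index$pl_dyn)
    c_out_series <- rowMeans(res$state[, 1L + idx, drop = FALSE])
    E_series <- 1 - c_out_series / C0
    nT <- length(res$times)
    if (c_out_series[nT] < 1e-6 * C0) {
      .stop_class(sprintf(
        "no breakthrough at the outlet for P = %g within t_factor = %g transit times",
        P, t_factor), "bu_steady_error")
    }
    k10 <- which.min(abs(res$times - res$times[nT] / 10))
    drift <- abs(E_series[nT] - E_series[k10]) / max(abs(E_series[nT]), 1e-300)
    if (drift > drift_tol) {
      .stop_class(sprintf(
        "extraction not steady for P = %g (relative drift %.3g over the final decade)",
        P, drift), "bu_steady_error")
    }
    psq <- P * S / Q
    rows[[length(rows) + 1L]] <- data.frame(
      P = P, S_m2 = S, Q_m3_per_s = Q, PS_over_Q = psq,
      E_sim = E_series[nT], E_renkin_crone = renkin_crone(psq),
      rel_deviation = abs(E_series[nT] - renkin_crone(psq)) /
        max(renkin_crone(psq), 1e-300))
  }
  do.call(rbind, rows)
}
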