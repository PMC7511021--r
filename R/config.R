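# Full model configuration: bundles geometry, plasma PK, flow, BBB transport,
# ECF transport and binding parameters, validates them against the published
# physiological ranges (warning, not error, when outside: the sensitivity
# analyses deliberately probe beyond them), and provides the named fixtures.

# physiological ranges (rat brain); values outside are flagged, not rejected
.bu_ranges <- data.frame(
  param = c("pk.F_bio", "pk.Dose", "pk.Vd", "pk.ka", "pk.ke",
            "geometry.d_cap", "geometry.r", "flow.v_blood",
            "ecf.D_star", "ecf.v_ecf", "bbb.P",
            "bbb.Tm_in", "bbb.Km_in", "bbb.Tm_out", "bbb.Km_out",
            "binding.B1max", "binding.k1on", "binding.k1off",
            "binding.B2max", "binding.k2on", "binding.k2off"),
  lower = c(0, 1e-1, 0.05, 0, 5e-5,
            2e-5, 0.8e-6, 0.5e-4,
            1e-11, 5e-8, 1e-10,
            1e-8, 1e1, 1e-8, 1e1,
            1e-3, 1e-4, 1e-6,
            1e1, 1e-6, 1e-4),
  upper = c(1, 1e2, 5, 2e-3, 3e-2,
            7e-5, 4.8e-6, 50e-4,
            1e-10, 5e-6, 1e-5,
            1e-5, 1e4, 1e-5, 1e4,
            5e-1, 1e2, 1e1,
            5e3, 1e1, 1e3),
  zero_ok = c(TRUE, FALSE, FALSE, TRUE, FALSE,
              FALSE, FALSE, TRUE,
              FALSE, TRUE, TRUE,
              TRUE, FALSE, TRUE, FALSE,
              FALSE, FALSE, FALSE,
              FALSE, FALSE, FALSE),
  stringsAsFactors = FALSE
)

.get_path <- function(config, path) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  x <- config
  for (p in parts) x <- x[[p]]
  x
}

#' Set one parameter of a configuration by path
#'
#' @param config A [bu_config()] object.
#' @param path Dotted path, e.g. `"flow.v_blood"` or `"bbb.Tm_in"`.
#' @param value New numeric value.
#' @return The modified configuration (re-validated, without range warnings).
#' @export
set_param <- function(config, path, value) {
  stopifnot(inherits(config, "bu_config"))
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  if (length(parts) != 2L || is.null(config[[parts[1]]]) ||
      is.null(config[[parts[1]]][[parts[2]]])) {
    stop(sprintf("unknown parameter path '%s'", path))
  }
  config[[parts[1]]][[parts[2]]] <- value
  # re-run the section constructor so hard invariants (nonnegativity,
  # derived edge lengths) hold for swept values too
  config$geometry <- geometry_params(config$geometry$d_cap, config$geometry$r)
  p <- config$pk
  config$pk <- plasma_pk_params(p$F_bio, p$Dose, p$Vd, p$ka, p$ke)
  config$flow <- flow_params(config$flow$v_blood)
  b <- config$bbb
  config$bbb <- bbb_params(P = b$P, Tm_in = b$Tm_in, Km_in = b$Km_in,
                           Tm_out = b$Tm_out, Km_out = b$Km_out,
                           SA_BBB = b$SA_BBB)
  config$ecf <- ecf_params(D_star = config$ecf$D_star, v_ecf = config$ecf$v_ecf)
  bd <- config$binding
  config$binding <- binding_params(bd$B1max, bd$k1on, bd$k1off,
                                   bd$B2max, bd$k2on, bd$k2off)
  config
}

#' Assemble a full model configuration
#'
#' Defaults reproduce the reference default parameter set for a hypothetical
#' drug in rat brain (the `"table2_default"` fixture differs only in using
#' the alternatively printed BBB surface area, 1e-10 m^2).
#'
#' @param geometry A [geometry_params()] object.
#' @param pk A [plasma_pk_params()] object.
#' @param flow A [flow_params()] object.
#' @param bbb A [bbb_params()] object.
#' @param ecf An [ecf_params()] object.
#' @param binding A [binding_params()] object.
#' @param warn Emit warnings for parameters outside the physiological ranges.
#' @return Object of class `bu_config`.
#' @export
bu_config <- function(geometry = geometry_params(),
                      pk = plasma_pk_params(),
                      flow = flow_params(),
                      bbb = bbb_params(P = 1e-9),
                      ecf = ecf_params(D_star = 0.5e-10),
                      binding = binding_params(),
                      warn = TRUE) {
  stopifnot(inherits(geometry, "bu_geometry"), inherits(pk, "bu_pk"),
            inherits(flow, "bu_flow"), inherits(bbb, "bu_bbb"),
            inherits(ecf, "bu_ecf"), inherits(binding, "bu_binding"))
  cfg <- structure(list(geometry = geometry, pk = pk, flow = flow, bbb = bbb,
                        ecf = ecf, binding = binding, litre_conv = 1e3),
                   class = "bu_config")
  if (warn) check_ranges(cfg, warn = TRUE)
  cfg
}

#' Check a configuration against the physiological parameter ranges
#'
#' Parameters outside the tabulated rat-brain ranges are admissible (the
#' sensitivity analyses deliberately use sub-physiological flow velocities)
#' but are flagged. A value of exactly zero is accepted without flag for
#' parameters that switch a process off (`v_blood`, `v_ecf`, `P`, `Tm`,
#' `ka`, `F`).
#'
#' @param config A [bu_config()] object.
#' @param warn If `TRUE`, raise one warning per out-of-range parameter.
#' @return Invisibly, a data.frame of the out-of-range parameters (possibly
#'   empty) with columns `param`, `value`, `lower`, `upper`.
#' @export
check_ranges <- function(config, warn = TRUE) {
  stopifnot(inherits(config, "bu_config"))
  vals <- vapply(.bu_ranges$param, function(p) .get_path(config, p), numeric(1))
  ok <- (vals >= .bu_ranges$lower & vals <= .bu_ranges$upper) |
    (.bu_ranges$zero_ok & vals == 0)
  bad <- data.frame(param = .bu_ranges$param[!ok], value = vals[!ok],
                    lower = .bu_ranges$lower[!ok], upper = .bu_ranges$upper[!ok])
  if (warn && nrow(bad)) {
    for (i in seq_len(nrow(bad))) {
      warning(sprintf(
        "parameter %s = %g outside the physiological range [%g, %g]",
        bad$param[i], bad$value[i], bad$lower[i], bad$upper[i]), call. = FALSE)
    }
  }
  invisible(bad)
}

#' @export
print.bu_config <- function(x, ...) {
  cat("3D brain unit configuration\n")
  cat(sprintf("  geometry: d_cap = %g m, r = %g m (x_r = %g m)\n",
              x$geometry$d_cap, x$geometry$r, x$geometry$x_r))
  cat(sprintf("  plasma PK: F = %g, Dose = %g umol, Vd = %g L, ka = %g /s, ke = %g /s\n",
              x$pk$F_bio, x$pk$Dose, x$pk$Vd, x$pk$ka, x$pk$ke))
  cat(sprintf("  flow: v_blood = %g m/s; ECF: D* = %g m2/s, v_ecf = %g m/s\n",
              x$flow$v_blood, x$ecf$D_star, x$ecf$v_ecf))
  cat(sprintf("  BBB: P = %g m/s, Tm_in = %g, Tm_out = %g umol/s (Km %g / %g umol/L), SA = %g m2\n",
              x$bbb$P, x$bbb$Tm_in, x$bbb$Tm_out, x$bbb$Km_in, x$bbb$Km_out, x$bbb$SA_BBB))
  cat(sprintf("  binding: B1max = %g (k1on %g, k1off %g), B2max = %g (k2on %g, k2off %g)\n",
              x$binding$B1max, x$binding$k1on, x$binding$k1off,
              x$binding$B2max, x$binding$k2on, x$binding$k2off))
  invisible(x)
}

# ---------------------------------------------------------------------------
# fixtures

.fixtures <- function() {
  table2 <- function() bu_config(
    geometry = geometry_params(d_cap = 5e-5, r = 2.5e-6),
    pk = plasma_pk_params(F_bio = 1, Dose = 0.5, Vd = 0.2, ka = 2e-4, ke = 5e-5),
    flow = flow_params(v_blood = 5e-4),
    bbb = bbb_params(P = 0.1e-7, Tm_in = 0, Km_in = 1e2, Tm_out = 0, Km_out = 1e2,
                     SA_BBB = 1e-10),
    ecf = ecf_params(D_star = 0.5e-10, v_ecf = 0.5e-6),
    binding = binding_params(B1max = 5e-2, k1on = 1, k1off = 1e-2,
                             B2max = 5e1, k2on = 1e-2, k2off = 1),
    warn = FALSE)
  list(
    table2_default = table2,
    fig3_vblood_sweep = function() sweep_spec(
      base = table2(),
      values = expand.grid(flow.v_blood = c(0.05, 0.5, 5, 50, 500) * 1e-4,
                           bbb.P = c(0.1, 100) * 1e-7),
      label = "fig3_vblood_sweep"),
    fig5_influx_sweep = function() sweep_spec(
      base = table2(),
      values = data.frame(bbb.Tm_in = c(0, 1, 10, 100) * 1e-7),
      label = "fig5_influx_sweep"),
    fig6_efflux_sweep = function() sweep_spec(
      base = table2(),
      values = data.frame(bbb.Tm_out = c(0, 1, 10, 100) * 1e-7),
      label = "fig6_efflux_sweep"),
    fig7_interplay = function() sweep_spec(
      base = table2(),
      values = expand.grid(bbb.Tm_in = c(0, 1, 10, 100) * 1e-7,
                           bbb.P = c(0.1, 100) * 1e-7,
                           flow.v_blood = c(5, 0.5) * 1e-4),
      label = "fig7_interplay"),
    fig8_interplay = function() sweep_spec(
      base = table2(),
      values = expand.grid(bbb.Tm_out = c(0, 1, 10, 100) * 1e-7,
                           bbb.P = c(0.1, 100) * 1e-7,
                           flow.v_blood = c(5, 0.5) * 1e-4),
      label = "fig8_interplay"),
    fig10_grid = function() sweep_spec(
      base = table2(),
      values = expand.grid(bbb.P = c(0.01, 0.1, 1) * 1e-8,
                           flow.v_blood = c(0.5, 5, 50) * 1e-4),
      label = "fig10_grid")
  )
}

#' Named parameter fixtures
#'
#' `"table2_default"` returns the reference default configuration;
#' the `"fig*"` names return [sweep_spec()] objects describing the published
#' sensitivity-analysis designs (flow velocity, active influx/efflux, and
#' their interplay with passive permeability).
#'
#' @param name Fixture name; see [fixture_names()].
#' @return A `bu_config` or a `bu_sweep_spec`.
#' @export
fixture <- function(name) {
  reg <- .fixtures()
  if (!name %in% names(reg)) {
    stop(sprintf("unknown fixture '%s'; available: %s",
                 name, paste(names(reg), collapse = ", ")))
  }
  reg[[name]]()
}

#' @rdname fixture
#' @export
fixture_names <- function() names(.fixtures())

# ---------------------------------------------------------------------------
# YAML configuration files (explicit unit-bearing keys, no unit inference)

.yaml_keys <- list(
  geometry = c(d_cap_m = "d_cap", r_m = "r"),
  pk = c(F = "F_bio", Dose_umol = "Dose", Vd_L = "Vd",
         ka_per_s = "ka", ke_per_s = "ke"),
  flow = c(v_blood_m_per_s = "v_blood"),
  ecf = c(D_star_m2_per_s = "D_star", v_ecf_m_per_s = "v_ecf"),
  bbb = c(P_m_per_s = "P", Tm_in_umol_per_s = "Tm_in",
          Km_in_umol_per_L = "Km_in", Tm_out_umol_per_s = "Tm_out",
          Km_out_umol_per_L = "Km_out", SA_BBB_m2 = "SA_BBB"),
  binding = c(B1max_umol_per_L = "B1max", k1on_per_umol_L_s = "k1on",
              k1off_per_s = "k1off", B2max_umol_per_L = "B2max",
              k2on_per_umol_L_s = "k2on", k2off_per_s = "k2off")
)
# alternative (mutually exclusive) keys
.yaml_alt <- list(
  ecf = c(D_m2_per_s = "D", lambda = "lambda"),
  bbb = c(Ptrans_m_per_s = "P_trans", ftrans = "f_trans",
          Dpara_m2_per_s = "D_para", Wpcs_m = "W_PCS", fpara = "f_para")
)

#' Load a configuration from a YAML file
#'
#' Keys carry explicit units (e.g. `v_blood_m_per_s`); unknown keys are
#' rejected. Either `P_m_per_s` or the transcellular/paracellular quadruple
#' may be given (not both), and either `D_star_m2_per_s` or
#' (`D_m2_per_s`, `lambda`). Missing values are filled from the fixture named
#' by the top-level `fixture:` key (or the `fixture` argument); an empty file
#' plus `fixture: table2_default` reproduces the reference defaults exactly.
#' A top-level `mesh: {n: ...}` and `solver:` block (keys `t_end_s`, `rtol`,
#' `atol`) are honoured and returned as the `"settings"` attribute.
#'
#' @param path YAML file path.
#' @param fixture_name Fixture supplying defaults (default `"table2_default"`,
#'   overridden by a `fixture:` key in the file).
#' @return A [bu_config()]; solver/mesh settings, when present, are attached
#'   as attribute `"settings"` (a [solver_settings()] object).
#' @export
load_config <- function(path, fixture_name = "table2_default") {
  if (!file.exists(path)) stop(sprintf("config file '%s' not found", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.null(raw$fixture)) {
    fixture_name <- raw$fixture
    raw$fixture <- NULL
  }
  base <- fixture(fixture_name)
  if (!inherits(base, "bu_config")) stop("fixture must name a configuration fixture")

  known <- c(unlist(lapply(.yaml_keys, names)), unlist(lapply(.yaml_alt, names)))
  # YAML 1.1 reads a bare key `n` as the boolean FALSE; accept both spellings
  mesh_n <- raw$mesh$n %||% raw$mesh[["FALSE"]]
  solver <- raw$solver
  raw$mesh <- NULL; raw$solver <- NULL
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop(sprintf("unknown configuration keys: %s", paste(unknown, collapse = ", ")))
  }

  pick <- function(section) {
    keys <- .yaml_keys[[section]]
    vals <- lapply(names(keys), function(k) raw[[k]])
    names(vals) <- unname(keys)
    vals[!vapply(vals, is.null, logical(1))]
  }
  alt <- function(section) {
    keys <- .yaml_alt[[section]]
    if (is.null(keys)) return(list())
    vals <- lapply(names(keys), function(k) raw[[k]])
    names(vals) <- unname(keys)
    vals[!vapply(vals, is.null, logical(1))]
  }

  g <- utils::modifyList(base$geometry[c("d_cap", "r")], pick("geometry"))
  geometry <- geometry_params(g$d_cap, g$r)
  p <- utils::modifyList(unclass(base$pk), pick("pk"))
  pk <- plasma_pk_params(p$F_bio, p$Dose, p$Vd, p$ka, p$ke)
  fl <- utils::modifyList(unclass(base$flow), pick("flow"))
  flow <- flow_params(fl$v_blood)

  e_main <- pick("ecf"); e_alt <- alt("ecf")
  if ("D_star" %in% names(e_main) && length(intersect(names(e_alt), c("D", "lambda")))) {
    stop("give either D_star_m2_per_s or (D_m2_per_s, lambda), not both")
  }
  v_ecf <- e_main$v_ecf %||% base$ecf$v_ecf
  ecf <- if (length(intersect(names(e_alt), c("D", "lambda")))) {
    ecf_params(D = e_alt$D, lambda = e_alt$lambda, v_ecf = v_ecf)
  } else {
    ecf_params(D_star = e_main$D_star %||% base$ecf$D_star, v_ecf = v_ecf)
  }

  b_main <- pick("bbb"); b_alt <- alt("bbb")
  if ("P" %in% names(b_main) && length(b_alt)) {
    stop("give either P_m_per_s or the transcellular/paracellular quadruple, not both")
  }
  barg <- utils::modifyList(
    list(P = base$bbb$P, Tm_in = base$bbb$Tm_in, Km_in = base$bbb$Km_in,
         Tm_out = base$bbb$Tm_out, Km_out = base$bbb$Km_out,
         SA_BBB = base$bbb$SA_BBB),
    b_main[setdiff(names(b_main), "P")])
  bbb <- if (length(b_alt)) {
    do.call(bbb_params, c(b_alt, barg[setdiff(names(barg), "P")]))
  } else {
    do.call(bbb_params, utils::modifyList(barg, b_main["P" == names(b_main)]))
  }

  bd <- utils::modifyList(unclass(base$binding), pick("binding"))
  binding <- binding_params(bd$B1max, bd$k1on, bd$k1off, bd$B2max, bd$k2on, bd$k2off)

  cfg <- bu_config(geometry, pk, flow, bbb, ecf, binding, warn = TRUE)
  if (!is.null(mesh_n) || !is.null(solver)) {
    ss <- solver_settings(n = mesh_n %||% 18,
                          t_end = solver$t_end_s %||% 1e5,
                          rtol = solver$rtol %||% 1e-6,
                          atol = solver$atol %||% 1e-10)
    attr(cfg, "settings") <- ss
  }
  cfg
}

#' Write a configuration to a YAML file
#'
#' Inverse of [load_config()]: `load_config(write_config(cfg, path))`
#' reproduces `cfg` exactly.
#'
#' @param config A [bu_config()] object.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "bu_config"))
  out <- list()
  for (section in names(.yaml_keys)) {
    keys <- .yaml_keys[[section]]
    for (k in names(keys)) out[[k]] <- config[[section]][[keys[[k]]]]
  }
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}
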