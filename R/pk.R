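# Plasma pharmacokinetics: Bateman oral-absorption forcing at the inlet box
# and first-order upwind advection of C_pl along the capillary network.

#' Plasma pharmacokinetic parameters (single oral dose)
#'
#' @param F_bio Bioavailability (dimensionless, 0-1).
#' @param Dose Molar amount of orally administered drug (umol).
#' @param Vd Distribution volume (L).
#' @param ka Absorption rate constant (1/s).
#' @param ke Elimination rate constant (1/s).
#' @return Object of class `bu_pk`.
#' @export
plasma_pk_params <- function(F_bio = 1, Dose = 0.5, Vd = 0.2, ka = 2e-4, ke = 5e-5) {
  structure(list(
    F_bio = .chk_num(F_bio, "F_bio", 0, 1),
    Dose = .chk_num(Dose, "Dose", 0),
    Vd = .chk_num(Vd, "Vd", 0, allow_zero = FALSE),
    ka = .chk_num(ka, "ka", 0),
    ke = .chk_num(ke, "ke", 0)
  ), class = "bu_pk")
}

#' Capillary blood flow parameters
#'
#' One velocity for all capillaries: the brain capillary blood flow is
#' directed away from the inlet corner along every rib and is equal in all
#' capillaries.
#'
#' @param v_blood Capillary blood flow velocity (m/s).
#' @return Object of class `bu_flow`.
#' @export
flow_params <- function(v_blood = 5e-4) {
  structure(list(v_blood = .chk_num(v_blood, "v_blood", 0)), class = "bu_flow")
}

#' Bateman plasma concentration after a single oral dose
#'
#' `C(t) = F ka Dose / (Vd (ka - ke)) (exp(-ke t) - exp(-ka t))`, the
#' biexponential concentration-time curve for first-order absorption and
#' elimination. The degenerate case `ka = ke = k` uses the analytic limit
#' `F k Dose t exp(-k t) / Vd` (switched on at relative rate difference
#' below 1e-9, so the function is continuous in `ka`).
#'
#' @param t Time (s), scalar or vector; must be nonnegative.
#' @param pk A [plasma_pk_params()] object.
#' @return Concentration (umol/L), same length as `t`.
#' @examples
#' pk <- plasma_pk_params()
#' bateman(bateman_peak(pk)$t_peak, pk)  # peak concentration, ~1.57 umol/L
#' @export
bateman <- function(t, pk) {
  stopifnot(inherits(pk, "bu_pk"))
  if (any(t < 0)) .stop_class("bateman() requires t >= 0", "bu_domain_error")
  dk <- pk$ka - pk$ke
  if (pk$ka > 0 && abs(dk) / pk$ka < 1e-9) {
    pk$F_bio * pk$ka * pk$Dose * t * exp(-pk$ka * t) / pk$Vd
  } else {
    pk$F_bio * pk$ka * pk$Dose / (pk$Vd * dk) * (exp(-pk$ke * t) - exp(-pk$ka * t))
  }
}

#' Time and value of the Bateman peak
#'
#' Closed form `t* = ln(ka/ke) / (ka - ke)` (limit `1/k` when `ka = ke = k`).
#'
#' @param pk A [plasma_pk_params()] object.
#' @return List with `t_peak` (s) and `c_peak` (umol/L).
#' @export
bateman_peak <- function(pk) {
  stopifnot(inherits(pk, "bu_pk"))
  dk <- pk$ka - pk$ke
  t_peak <- if (pk$ka > 0 && abs(dk) / pk$ka < 1e-9) 1 / pk$ka
            else log(pk$ka / pk$ke) / dk
  list(t_peak = t_peak, c_peak = bateman(t_peak, pk))
}

#' Rate of change of the plasma concentration field
#'
#' First-order upwind discretization of the capillary advection equations
#' `dC_pl/dt = -v_blood dC_pl/dx` (per capillary axis), with the inlet box
#' clamped to the forcing concentration, the outlet box on the cube surface
#' clamped to zero, and the BBB exchange applied as a conservative sink on
#' interface-adjacent plasma cells. Where a capillary begins at a junction
#' corner box, the upwind value is the unweighted mean of the concentrations
#' in the adjacent plasma cells whose flow is directed into the box.
#'
#' @param C_pl Concentrations (umol/L) on all plasma cells of `mesh`, in mesh
#'   plasma-cell order (see `which(mesh$plasma)`), including the clamped
#'   inlet/outlet boxes.
#' @param mesh A [build_mesh()] object.
#' @param flow A [flow_params()] object.
#' @param coupling Optional BBB interface flux densities (umol m^-2 s^-1,
#'   positive into the ECF), one per row of `mesh$faces`; default zero.
#' @return Rates (umol/L/s) on plasma cells; zero on the clamped boxes.
#' @export
plasma_rhs <- function(C_pl, mesh, flow, coupling = NULL) {
  stopifnot(inherits(mesh, "bu_mesh"), inherits(flow, "bu_flow"))
  pl_ids <- which(mesh$plasma)
  if (length(C_pl) != length(pl_ids)) {
    .stop_class(sprintf("C_pl has length %d but the mesh has %d plasma cells",
                        length(C_pl), length(pl_ids)), "bu_shape_error")
  }
  ops <- .plasma_operator(mesh)
  full <- numeric(mesh$ncell)
  full[pl_ids] <- C_pl
  rate_full <- flow$v_blood * as.numeric(ops$M %*% full)
  rate <- rate_full[pl_ids]
  if (!is.null(coupling)) {
    if (length(coupling) != nrow(mesh$faces)) {
      .stop_class("coupling must have one flux per BBB face", "bu_shape_error")
    }
    sink_full <- as.numeric(ops$Gp %*% coupling)
    rate <- rate - sink_full[pl_ids]
  }
  rate[match(c(mesh$in_id, mesh$out_id), pl_ids)] <- 0
  rate
}
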