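# Brain-ECF dynamics: effective diffusion (tortuosity-corrected), x-directed
# bulk flow, and reversible binding to specific (target) and non-specific
# sites, each an immobile extracellular species.

#' Brain ECF transport parameters
#'
#' Give either the effective diffusion coefficient `D_star = D / lambda^2`
#' directly, or the free-medium diffusion coefficient `D` together with the
#' tortuosity `lambda` -- exactly one of the two forms.
#'
#' @param D_star Effective diffusion coefficient (m^2/s).
#' @param D Free-medium diffusion coefficient (m^2/s).
#' @param lambda Tortuosity (dimensionless, >= 1 in brain tissue).
#' @param v_ecf Brain ECF bulk flow velocity (m/s), directed along +x.
#' @return Object of class `bu_ecf`.
#' @export
ecf_params <- function(D_star = NULL, D = NULL, lambda = NULL, v_ecf = 0.5e-6) {
  if (!is.null(D_star) && (!is.null(D) || !is.null(lambda))) {
    stop("give either 'D_star' or the pair (D, lambda), not both")
  }
  if (is.null(D_star)) {
    if (is.null(D) || is.null(lambda)) stop("one of 'D_star' or (D, lambda) is required")
    D <- .chk_num(D, "D", 0, allow_zero = FALSE)
    lambda <- .chk_num(lambda, "lambda", 0, allow_zero = FALSE)
    D_star <- D / lambda^2
  } else {
    D_star <- .chk_num(D_star, "D_star", 0, allow_zero = FALSE)
  }
  structure(list(D_star = D_star, v_ecf = .chk_num(v_ecf, "v_ecf", 0)),
            class = "bu_ecf")
}

#' Binding-site kinetic parameters
#'
#' Specific sites are the pharmacological targets (high affinity, low
#' capacity); non-specific sites are other tissue components (low affinity,
#' high capacity). Both are immobile, evenly distributed and of constant
#' total concentration.
#'
#' @param B1max Total specific binding-site concentration (umol/L).
#' @param k1on Specific association rate constant ((umol/L)^-1 s^-1).
#' @param k1off Specific dissociation rate constant (1/s).
#' @param B2max,k2on,k2off The same for non-specific sites.
#' @return Object of class `bu_binding`.
#' @export
binding_params <- function(B1max = 5e-2, k1on = 1, k1off = 1e-2,
                           B2max = 5e1, k2on = 1e-2, k2off = 1) {
  structure(list(
    B1max = .chk_num(B1max, "B1max", 0),
    k1on = .chk_num(k1on, "k1on", 0),
    k1off = .chk_num(k1off, "k1off", 0),
    B2max = .chk_num(B2max, "B2max", 0),
    k2on = .chk_num(k2on, "k2on", 0),
    k2off = .chk_num(k2off, "k2off", 0)
  ), class = "bu_binding")
}

#' Langmuir equilibrium bound concentration
#'
#' Steady state of the binding kinetics at fixed free concentration `C`:
#' `B = Bmax C / (C + Kd)` with `Kd = koff / kon`. Returns 0 when `kon = 0`
#' (no binding).
#'
#' @param C Free concentration (umol/L), vectorized.
#' @param Bmax Total site concentration (umol/L).
#' @param kon Association rate constant ((umol/L)^-1 s^-1).
#' @param koff Dissociation rate constant (1/s).
#' @return Bound concentration (umol/L).
#' @examples
#' equilibrium_bound(0.01, 5e-2, 1, 1e-2)  # at C = Kd: half occupancy, 0.025
#' @export
equilibrium_bound <- function(C, Bmax, kon, koff) {
  stopifnot(all(C >= 0), Bmax >= 0, kon >= 0, koff >= 0)
  if (kon == 0) return(rep(0, length(C)))
  Kd <- koff / kon
  Bmax * C / (C + Kd)
}

#' Rate of change of the brain-ECF fields
#'
#' Finite-volume evaluation of the ECF system: effective diffusion and
#' x-directed upwind bulk-flow advection of the free concentration, the two
#' reversible binding reactions, the BBB interface source on
#' interface-adjacent ECF cells, and zero normal gradient on the outer cube
#' faces (which makes the bulk-flow inflow face advect drug in at the local
#' concentration; the mass audit of a full simulation reports the resulting
#' non-closure rather than suppressing it).
#'
#' @param C_ecf,B1,B2 Field values (umol/L) on the ECF cells of `mesh`, in
#'   mesh ECF-cell order (see `which(!mesh$plasma)`).
#' @param mesh A [build_mesh()] object.
#' @param ecf An [ecf_params()] object.
#' @param binding A [binding_params()] object.
#' @param coupling Optional BBB interface flux densities (umol m^-2 s^-1,
#'   positive into the ECF), one per row of `mesh$faces`; default zero.
#' @return List of rates `dC_ecf`, `dB1`, `dB2` (umol/L/s).
#' @export
ecf_rhs <- function(C_ecf, B1, B2, mesh, ecf, binding, coupling = NULL) {
  stopifnot(inherits(mesh, "bu_mesh"), inherits(ecf, "bu_ecf"),
            inherits(binding, "bu_binding"))
  ne <- sum(!mesh$plasma)
  if (length(C_ecf) != ne || length(B1) != ne || length(B2) != ne) {
    .stop_class(sprintf("ECF fields must have length %d (one value per ECF cell)", ne),
                "bu_shape_error")
  }
  ops <- .ecf_operator(mesh)
  dC <- ecf$D_star * as.numeric(ops$L %*% C_ecf) +
    ecf$v_ecf * as.numeric(ops$A %*% C_ecf)
  if (!is.null(coupling)) {
    if (length(coupling) != nrow(mesh$faces)) {
      .stop_class("coupling must have one flux per BBB face", "bu_shape_error")
    }
    dC <- dC + as.numeric(ops$Ge %*% coupling)
  }
  r1 <- binding$k1on * C_ecf * (binding$B1max - B1) - binding$k1off * B1
  r2 <- binding$k2on * C_ecf * (binding$B2max - B2) - binding$k2off * B2
  list(dC_ecf = dC - r1 - r2, dB1 = r1, dB2 = r2)
}
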