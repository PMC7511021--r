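# The BBB flux law: passive permeability (transcellular + paracellular
# composition) plus saturable Michaelis-Menten active influx/efflux,
# evaluated as an area flux density on every plasma/ECF interface face.

#' Compose the total passive BBB permeability
#'
#' `P = P_trans f_trans + (D_para / W_PCS) f_para`: the area-weighted sum of
#' the transcellular permeability and the paracellular permeability, the
#' latter being the paracellular diffusivity over the width of the
#' paracellular space.
#'
#' @param P_trans Transcellular permeability (m/s).
#' @param f_trans Area fraction occupied by endothelial cells.
#' @param D_para Paracellular diffusivity (m^2/s).
#' @param W_PCS Width of the paracellular space (m).
#' @param f_para Area fraction occupied by the paracellular space;
#'   `f_trans + f_para` must equal 1 (tolerance 1e-9).
#' @return Total passive permeability P (m/s).
#' @examples
#' compose_permeability(1e-8, 0.994, 1e-13, 1e-6, 0.006)
#' @export
compose_permeability <- function(P_trans, f_trans, D_para, W_PCS, f_para) {
  P_trans <- .chk_num(P_trans, "P_trans", 0)
  f_trans <- .chk_num(f_trans, "f_trans", 0, 1)
  D_para <- .chk_num(D_para, "D_para", 0)
  f_para <- .chk_num(f_para, "f_para", 0, 1)
  if (abs(f_trans + f_para - 1) > 1e-9) {
    stop("f_trans + f_para must equal 1 (tolerance 1e-9)")
  }
  if (W_PCS == 0) {
    if (D_para > 0) stop("W_PCS = 0 with D_para > 0: paracellular permeability undefined")
    P_para <- 0
  } else {
    W_PCS <- .chk_num(W_PCS, "W_PCS", 0)
    P_para <- D_para / W_PCS
  }
  P_trans * f_trans + P_para * f_para
}

#' BBB transport parameters
#'
#' Give either the total passive permeability `P` directly, or the
#' transcellular/paracellular quadruple (`P_trans`, `f_trans`, `D_para`,
#' `W_PCS`, with `f_para = 1 - f_trans`), from which `P` is composed via
#' [compose_permeability()] -- exactly one of the two forms.
#'
#' @param P Total passive BBB permeability (m/s).
#' @param P_trans,f_trans,D_para,W_PCS,f_para Split-route alternative to `P`.
#' @param Tm_in Maximal active influx rate (umol/s).
#' @param Km_in Half-saturation concentration for influx (umol/L).
#' @param Tm_out Maximal active efflux rate (umol/s).
#' @param Km_out Half-saturation concentration for efflux (umol/L).
#' @param SA_BBB BBB surface area of one capillary side (m^2). Default
#'   `1.25e-10` (the tabulated value `d_cap * r`); note the reference default
#'   parameter set prints `1e-10` instead, which the `"table2_default"`
#'   fixture reproduces as printed.
#' @return Object of class `bu_bbb`.
#' @export
bbb_params <- function(P = NULL, P_trans = NULL, f_trans = NULL, D_para = NULL,
                       W_PCS = NULL, f_para = NULL,
                       Tm_in = 0, Km_in = 100, Tm_out = 0, Km_out = 100,
                       SA_BBB = 1.25e-10) {
  quad <- list(P_trans = P_trans, f_trans = f_trans, D_para = D_para,
               W_PCS = W_PCS, f_para = f_para)
  quad_given <- any(!vapply(quad, is.null, logical(1)))
  if (!is.null(P) && quad_given) {
    stop("give either 'P' or the (P_trans, f_trans, D_para, W_PCS, f_para) quadruple, not both")
  }
  if (is.null(P)) {
    if (!quad_given) stop("one of 'P' or the split-route quadruple is required")
    f_para <- f_para %||% (1 - f_trans)
    P <- compose_permeability(P_trans, f_trans, D_para, W_PCS, f_para)
  } else {
    P <- .chk_num(P, "P", 0)
  }
  structure(list(
    P = P,
    Tm_in = .chk_num(Tm_in, "Tm_in", 0),
    Km_in = .chk_num(Km_in, "Km_in", 0, allow_zero = FALSE),
    Tm_out = .chk_num(Tm_out, "Tm_out", 0),
    Km_out = .chk_num(Km_out, "Km_out", 0, allow_zero = FALSE),
    SA_BBB = .chk_num(SA_BBB, "SA_BBB", 0, allow_zero = FALSE),
    split = if (quad_given) list(P_trans = P_trans, f_trans = f_trans,
                                 D_para = D_para, W_PCS = W_PCS, f_para = f_para)
  ), class = "bu_bbb")
}

#' BBB interface flux density
#'
#' `f(u, v) = P (u - v) + Tm_in u / (SA_BBB (Km_in + u))
#'                      - Tm_out v / (SA_BBB (Km_out + v))`,
#' the flux of unbound drug across the BBB per unit area, positive into the
#' brain ECF; `u` is the plasma-side and `v` the ECF-side concentration. The
#' passive term is converted to an area flux density via 1 L = 1e-3 m^3, so
#' all three terms share the unit umol m^-2 s^-1.
#'
#' @param u Plasma concentration (umol/L), vectorized.
#' @param v ECF concentration (umol/L), vectorized.
#' @param p A [bbb_params()] object.
#' @param details If `TRUE`, return a data.frame with the passive, active
#'   influx and active efflux terms separately alongside the total.
#' @return Flux density (umol m^-2 s^-1), or a data.frame when
#'   `details = TRUE`.
#' @examples
#' p <- bbb_params(P = 1e-9, Tm_in = 1e-7, Km_in = 100)
#' bbb_flux(100, 0, p)
#' @export
bbb_flux <- function(u, v, p, details = FALSE) {
  stopifnot(inherits(p, "bu_bbb"))
  if (any(u < 0) || any(v < 0)) {
    .stop_class("bbb_flux() requires nonnegative concentrations", "bu_domain_error")
  }
  # umol/L -> umol/m^3 for the passive term (1 L = 1e-3 m^3)
  passive <- 1e3 * p$P * (u - v)
  influx <- p$Tm_in * u / (p$SA_BBB * (p$Km_in + u))
  efflux <- p$Tm_out * v / (p$SA_BBB * (p$Km_out + v))
  if (details) {
    data.frame(passive = passive, active_influx = influx,
               active_efflux = efflux, total = passive + influx - efflux)
  } else {
    passive + influx - efflux
  }
}

#' Renkin-Crone extraction fraction
#'
#' `E = 1 - exp(-PS/Q)`: the fraction of drug extracted from capillary blood
#' in a single pass, for permeability-surface product `PS` and volumetric
#' blood flow `Q`.
#'
#' @param ps_over_q Dimensionless ratio PS/Q, vectorized.
#' @return Extraction fraction in `[0, 1)`.
#' @export
renkin_crone <- function(ps_over_q) {
  stopifnot(all(ps_over_q >= 0))
  1 - exp(-ps_over_q)
}
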