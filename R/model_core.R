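#' biofiltervoc: biofiltration of VOC mixtures in a packed-bed biofilter
#'
#' Steady-state reaction-diffusion modelling of the simultaneous
#' biodegradation of methanol (hydrophilic) and alpha-pinene (hydrophobic)
#' in a biofilter: Michaelis-Menten kinetics in the biofilm, plug-flow
#' advection in the gas phase, an Elman recurrent network surrogate trained
#' by Levenberg-Marquardt, and goodness-of-fit statistics for repeated
#' stochastic trainings.
#'
#' @section Model overview:
#' In the biofilm (depth coordinate `X* in [0,1]`, interface at `X* = 0`)
#' the dimensionless substrate saturation satisfies
#' `S'' = phi_eff * S / (1 + beta * S)` with `S(0) = 1` and `S'(1) = 0`,
#' where `phi_eff = phi` for methanol and `phi_eff = alpha * phi1` for
#' alpha-pinene; `alpha` is the inhibition exerted by methanol on pinene
#' degraders.  The interface flux `S'(0)` drives the gas-phase column
#' balance `dC*/dh* = A * S'(0)` along the dimensionless bed height.
#'
#' @keywords internal
"_PACKAGE"

REGIMES <- c("michaelis_menten", "first_order", "zero_order")

#' Methanol-on-pinene inhibition factor
#'
#' Multiplicative reduction of the alpha-pinene degradation rate caused by
#' the methanol concentration in the gas phase:
#' `alpha = 1 / (1 + (c_m / k_i)^2)`.  Equals 1 with no methanol and
#' decreases strictly as methanol accumulates.
#'
#' @param c_m Methanol concentration (same units as `k_i`), `>= 0`.
#' @param k_i Inhibition constant, `> 0`.
#' @return Dimensionless factor in `(0, 1]`.
#' @examples
#' inhibition_factor(0, 5)   # 1
#' inhibition_factor(3, 1)   # 0.1
#' @export
inhibition_factor <- function(c_m, k_i) {
  if (!is.numeric(c_m) || !is.numeric(k_i)) stop("`c_m` and `k_i` must be numeric")
  if (any(k_i <= 0)) stop("inhibition constant `k_i` must be > 0")
  if (any(c_m < 0)) stop("methanol concentration `c_m` must be >= 0")
  1 / (1 + (c_m / k_i)^2)
}

#' Dimensionless biofilm parameter set
#'
#' The dimensionless groups defining the two biofilm boundary value
#' problems: Thiele-type moduli `phi` (methanol) and `phi1` (alpha-pinene),
#' saturation parameters `beta = S_im / K_m` and `beta1 = S_ip / K_p`, and
#' the inhibition factor `alpha` multiplying the pinene modulus.
#'
#' `alpha` may be any positive constant when supplied directly (parameter
#' sweeps in the literature use values above 1); only the route through
#' [inhibition_factor()] is guaranteed to lie in `(0, 1]`.
#'
#' @param phi,beta Methanol modulus and saturation parameter, `>= 0`.
#' @param phi1,beta1 Alpha-pinene modulus and saturation parameter, `>= 0`.
#' @param alpha Inhibition factor, `> 0` (default 1).
#' @return Object of class `biofilm_params`.
#' @examples
#' biofilm_params(phi = 10, beta = 10)
#' @export
biofilm_params <- function(phi = 0, beta = 0, phi1 = 0, beta1 = 0, alpha = 1) {
  vals <- c(phi = phi, beta = beta, phi1 = phi1, beta1 = beta1, alpha = alpha)
  if (!all(is.finite(vals))) stop("biofilm parameters must be finite")
  if (any(vals[c("phi", "beta", "phi1", "beta1")] < 0))
    stop("phi, beta, phi1, beta1 must be >= 0")
  if (alpha <= 0) stop("alpha must be > 0")
  structure(as.list(vals), class = "biofilm_params")
}

#' @export
print.biofilm_params <- function(x, ...) {
  cat(sprintf(
    "<biofilm_params> phi=%g beta=%g phi1=%g beta1=%g alpha=%g\n",
    x$phi, x$beta, x$phi1, x$beta1, x$alpha))
  invisible(x)
}

#' Dimensionless gas-phase parameter set
#'
#' Column transfer groups `A` (methanol) and `A1` (alpha-pinene), plus
#' `gamma = C_mi / K_i`, the inlet-methanol-to-inhibition ratio used when
#' the inhibition factor is recomputed dynamically along the bed.
#'
#' @param A,A1 Transfer groups, `>= 0`.
#' @param gamma Inlet-methanol-to-inhibition ratio, `>= 0`; `0` means the
#'   inhibition factor stays constant along the column.
#' @return Object of class `gas_params`.
#' @export
gas_params <- function(A = 0, A1 = 0, gamma = 0) {
  vals <- c(A = A, A1 = A1, gamma = gamma)
  if (!all(is.finite(vals))) stop("gas parameters must be finite")
  if (any(vals < 0)) stop("A, A1, gamma must be >= 0")
  structure(as.list(vals), class = "gas_params")
}

#' @export
print.gas_params <- function(x, ...) {
  cat(sprintf("<gas_params> A=%g A1=%g gamma=%g\n", x$A, x$A1, x$gamma))
  invisible(x)
}

#' Dimensional biofilter parameter set
#'
#' Physical parameters of the biofilter from which the dimensionless groups
#' are derived once at the model boundary.  All fields must be strictly
#' positive; interface concentrations follow from the gas-biofilm partition,
#' `S_im = C_mi / m_m` and `S_ip = C_pi / m_p`.
#'
#' @param D_em,D_ep Effective diffusivities in the biofilm (area/time).
#' @param X Biomass density (mass/volume).
#' @param Y_m,Y_p Yield coefficients (dimensionless).
#' @param mu_max_m,mu_max_p Maximum specific growth rates (1/time).
#' @param K_m,K_p Half-saturation constants (mass/volume).
#' @param K_i Inhibition constant (mass/volume).
#' @param delta Biofilm thickness (length); may be 0 (no-film limit).
#' @param m_m,m_p Gas-biofilm partition coefficients (dimensionless).
#' @param U_g Superficial gas velocity (length/time).
#' @param A_s Specific surface area (1/length).
#' @param H Bed height (length).
#' @param C_mi,C_pi Inlet gas concentrations (mass/volume).
#' @return Object of class `dimensional_params`.
#' @export
dimensional_params <- function(D_em, D_ep, X, Y_m, Y_p, mu_max_m, mu_max_p,
                               K_m, K_p, K_i, delta, m_m, m_p,
                               U_g, A_s, H, C_mi, C_pi) {
  p <- list(D_em = D_em, D_ep = D_ep, X = X, Y_m = Y_m, Y_p = Y_p,
            mu_max_m = mu_max_m, mu_max_p = mu_max_p, K_m = K_m, K_p = K_p,
            K_i = K_i, delta = delta, m_m = m_m, m_p = m_p,
            U_g = U_g, A_s = A_s, H = H, C_mi = C_mi, C_pi = C_pi)
  v <- unlist(p)
  if (!all(is.finite(v))) stop("dimensional parameters must be finite")
  pos <- setdiff(names(p), "delta")
  bad <- pos[unlist(p[pos]) <= 0]
  if (length(bad)) stop("dimensional parameters must be strictly positive: ",
                        paste(bad, collapse = ", "))
  if (delta < 0) stop("biofilm thickness `delta` must be >= 0")
  structure(p, class = "dimensional_params")
}

#' Dimensionless biofilm groups from dimensional parameters
#'
#' Computes `beta = S_im / K_m`, `phi = (X mu_max_m / Y_m) delta^2 /
#' (D_em K_m)` and the analogous pinene groups `beta1`, `phi1`.  The
#' inhibition factor is left to the caller: supply a constant through
#' `alpha` or compute one with [inhibition_factor()].
#'
#' @param p A [dimensional_params()] object.
#' @param alpha Inhibition factor carried into the result (default 1).
#' @return A [biofilm_params()] object.
#' @examples
#' # phi = 1.1 * 0.2^2 / (0.004 * 10) = 1.1
#' p <- dimensional_params(D_em = 0.004, D_ep = 0.004, X = 1.1, Y_m = 1, Y_p = 1,
#'                         mu_max_m = 1, mu_max_p = 1, K_m = 10, K_p = 10,
#'                         K_i = 5, delta = 0.2, m_m = 1, m_p = 1,
#'                         U_g = 1, A_s = 1, H = 1, C_mi = 10, C_pi = 10)
#' nondimensionalize_biofilm(p)
#' @export
nondimensionalize_biofilm <- function(p, alpha = 1) {
  stopifnot(inherits(p, "dimensional_params"))
  s_im <- p$C_mi / p$m_m
  s_ip <- p$C_pi / p$m_p
  biofilm_params(
    phi   = (p$X * p$mu_max_m / p$Y_m) * p$delta^2 / (p$D_em * p$K_m),
    beta  = s_im / p$K_m,
    phi1  = (p$X * p$mu_max_p / p$Y_p) * p$delta^2 / (p$D_ep * p$K_p),
    beta1 = s_ip / p$K_p,
    alpha = alpha)
}

#' Dimensionless gas-phase groups from dimensional parameters
#'
#' Computes `A = H A_s D_em S_im / (U_g delta C_mi)`, the analogous `A1`
#' for alpha-pinene, and `gamma = C_mi / K_i`.
#'
#' @param p A [dimensional_params()] object.
#' @return A [gas_params()] object.
#' @export
nondimensionalize_gas <- function(p) {
  stopifnot(inherits(p, "dimensional_params"))
  if (p$delta <= 0) stop("gas-phase groups require biofilm thickness `delta` > 0")
  s_im <- p$C_mi / p$m_m
  s_ip <- p$C_pi / p$m_p
  gas_params(
    A     = p$H * p$A_s * p$D_em * s_im / (p$U_g * p$delta * p$C_mi),
    A1    = p$H * p$A_s * p$D_ep * s_ip / (p$U_g * p$delta * p$C_pi),
    gamma = p$C_mi / p$K_i)
}

match_regime <- function(regime) {
  match.arg(regime, REGIMES)
}

#' Pointwise dimensionless degradation rate
#'
#' The reaction term of the biofilm balance for each kinetic regime:
#' Michaelis-Menten `phi * s / (1 + beta * s)`, its unsaturated first-order
#' limit `phi * s` (`beta -> 0`) and its saturated zero-order limit
#' `phi / beta` (`beta * s >> 1`).
#'
#' @param s Dimensionless saturation, `>= 0` (vectorised).
#' @param phi Modulus, `>= 0`.
#' @param beta Saturation parameter, `>= 0` (`> 0` for `zero_order`).
#' @param regime One of `"michaelis_menten"`, `"first_order"`, `"zero_order"`.
#' @return Dimensionless rate, same length as `s`.
#' @examples
#' reaction_rate(1, phi = 10, beta = 10)            # 10/11
#' reaction_rate(0.3, phi = 4, beta = 0)            # = first-order 1.2
#' @export
reaction_rate <- function(s, phi, beta, regime = "michaelis_menten") {
  regime <- match_regime(regime)
  if (any(s < 0)) stop("saturation `s` must be >= 0")
  if (phi < 0 || beta < 0) stop("phi and beta must be >= 0")
  switch(regime,
    michaelis_menten = phi * s / (1 + beta * s),
    first_order = phi * s,
    zero_order = {
      if (beta <= 0) stop("zero-order regime requires beta > 0")
      rep_len(phi / beta, length(s))
    })
}
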