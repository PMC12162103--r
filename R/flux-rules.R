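#' Flux rules of the tumor-microenvironment model
#'
#' Elementary rate laws from which every equation of the model is built.
#' Cell states proliferate logistically, convert between states with
#' first-order kinetics, amplify each other's growth through saturating
#' (Hill-type) paracrine interactions, inhibit each other through
#' regulatory factors, eliminate each other by mass action, and die (or,
#' for molecular species, degrade) at first order.
#'
#' All rates are per day; populations are dimensionless cell counts and
#' concentrations are in arbitrary units.
#'
#' @name flux-rules
NULL

#' Logistic proliferation flux
#'
#' `Kprol * x * (1 - x / xmax)`. Zero at `x = 0` and at carrying capacity;
#' negative above capacity (decay back toward `xmax`).
#'
#' @param Kprol proliferation rate (per day), `>= 0`.
#' @param x population, `>= 0`.
#' @param xmax carrying capacity, `> 0`.
#' @return proliferation flux (population per day).
#' @examples
#' flux_proliferation(2, 5, 10) # 5
#' @export
flux_proliferation <- function(Kprol, x, xmax) {
  if (any(xmax <= 0)) stop("invalid parameter: carrying capacity must be > 0")
  if (any(Kprol < 0) || any(x < 0)) {
    stop("invalid parameter: Kprol and x must be nonnegative")
  }
  Kprol * x * (1 - x / xmax)
}

#' First-order conversion flux
#'
#' `Kconv * x_source`; subtracted from the source state and added to the
#' target state, so conversion conserves cell number at the flux level.
#'
#' @param Kconv conversion rate (per day), `>= 0`.
#' @param x_source source population, `>= 0`.
#' @return conversion flux (population per day).
#' @export
flux_conversion <- function(Kconv, x_source) {
  if (any(Kconv < 0) || any(x_source < 0)) {
    stop("invalid parameter: Kconv and x_source must be nonnegative")
  }
  Kconv * x_source
}

#' Paracrine proliferation multiplier
#'
#' `1 + Kpara * alpha * xi / (V + a * xi)`: a dimensionless gain applied to
#' the proliferation flux of the target cell state when a source species
#' `xi` promotes its growth. Bounded in `[1, 1 + Kpara * alpha / a)` and
#' monotone nondecreasing in `xi`.
#'
#' @param Kpara dimensionless paracrine gain, `>= 0`.
#' @param alpha spatial proximity index in `[0, 1]`.
#' @param V dissociation constant, `> 0`.
#' @param a saturation coefficient, `> 0` (default 1).
#' @param xi source population or concentration, `>= 0`.
#' @return dimensionless multiplier `>= 1`.
#' @examples
#' paracrine_multiplier(3, 1, 2, 1, 2) # 2.5
#' @export
paracrine_multiplier <- function(Kpara, alpha, V, a = 1, xi) {
  if (any(V <= 0)) stop("invalid parameter: dissociation constant V must be > 0")
  if (any(a <= 0)) stop("invalid parameter: saturation coefficient a must be > 0")
  if (any(alpha < 0) || any(alpha > 1)) {
    stop("invalid parameter: proximity index alpha must lie in [0, 1]")
  }
  if (any(xi < 0)) stop("invalid parameter: source xi must be nonnegative")
  1 + Kpara * alpha * xi / (V + a * xi)
}

#' Regulatory inhibition factor
#'
#' `1 / (Vreg + alpha * xi)`: a strictly decreasing factor in the inhibitor
#' level `xi`, applied to the proliferation, secretion, or elimination flux
#' of the inhibited species (the toggle-switch style inhibition term).
#'
#' @param Vreg dissociation constant, `> 0`.
#' @param alpha proximity/weight of the inhibitor, `>= 0`.
#' @param xi inhibitor population or concentration, `>= 0`.
#' @return dimensionless factor in `(0, 1/Vreg]`.
#' @export
regulatory_factor <- function(Vreg, alpha, xi) {
  if (any(Vreg <= 0)) stop("invalid parameter: Vreg must be > 0")
  if (any(alpha < 0) || any(xi < 0)) {
    stop("invalid parameter: alpha and xi must be nonnegative")
  }
  1 / (Vreg + alpha * xi)
}

#' Elimination flux
#'
#' `Kkill * alpha_ac * x_target * x_killer`: mass-action destruction of a
#' target population by a killer population, attenuated by the
#' accessibility factor `alpha_ac`. Subtracted from the target only (the
#' killer is not consumed).
#'
#' @param Kkill elimination rate (per killer cell per day), `>= 0`.
#' @param alpha_ac accessibility factor in `[0, 1]`.
#' @param x_target target population, `>= 0`.
#' @param x_killer killer population, `>= 0`.
#' @return elimination flux (population per day).
#' @export
flux_elimination <- function(Kkill, alpha_ac, x_target, x_killer) {
  if (any(c(Kkill, x_target, x_killer) < 0)) {
    stop("invalid parameter: elimination inputs must be nonnegative")
  }
  if (any(alpha_ac < 0) || any(alpha_ac > 1)) {
    stop("invalid parameter: alpha_ac must lie in [0, 1]")
  }
  Kkill * alpha_ac * x_target * x_killer
}

#' Death / degradation flux
#'
#' `KD * x`: first-order natural death (cell states) or degradation
#' (molecular species).
#'
#' @param KD death or degradation rate (per day), `>= 0`.
#' @param x population or concentration, `>= 0`.
#' @return flux (per day), subtracted from `x`.
#' @export
flux_death <- function(KD, x) {
  if (any(KD < 0) || any(x < 0)) {
    stop("invalid parameter: KD and x must be nonnegative")
  }
  KD * x
}

# Saturating occupancy factor x/(V + x): gates conversions that require a
# mediating species (e.g. a cytokine) or a co-requisite cell state.
occupancy <- function(x, V) x / (V + x)
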