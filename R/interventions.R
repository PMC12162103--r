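#' Apply anti-PD1 checkpoint inhibition
#'
#' Anti-PD1 removes the PD1 program from killer T cells: a conversion flux
#' `k_bind * dose * TKp` moves PD1+ killer T cells into the PD1- pool
#' (which is exhaustion-immune), and PD1- killer T cells gain elimination
#' edges against exposed PDL1+ tumor cells, which they now recognize as
#' antigen-presenting. The drug enters as a constant dose parameter; a
#' `dose` of zero returns the model unchanged.
#'
#' @param network a [network_spec()] (the HNSCC atlas).
#' @param params parameter registry.
#' @param dose anti-PD1 dose (arbitrary concentration units), `>= 0`.
#' @param k_bind binding rate (per concentration per day), `>= 0`.
#' @param exhaustion_block optional fraction in `[0, 1]` by which the drug
#'   also scales down the residual PD1+ exhaustion rate (default 0: the
#'   drug only converts).
#' @return list with elements `network` and `params`.
#' @export
apply_anti_pd1 <- function(network, params, dose,
                           k_bind = params[["k_bind_pd1"]],
                           exhaustion_block = 0) {
  if (dose < 0 || k_bind < 0) stop("dose and k_bind must be nonnegative")
  if (dose == 0) return(list(network = network, params = params))
  params[["dose_pd1"]] <- dose
  params[["k_bind_pd1"]] <- k_bind
  if (exhaustion_block > 0) {
    params[["Kconv_TKp_TEx"]] <-
      params[["Kconv_TKp_TEx"]] * (1 - exhaustion_block)
  }
  edges <- c(network$edges, list(
    edge_spec("conversion", "TKn", "TKp",
              params = c("k_bind_pd1", "dose_pd1")),
    edge_spec("elimination", "Cpos_E", "TKn",
              params = c(Kkill = "Kkill_Cpos", alpha_ac = "alpha_ac"))
  ))
  net <- network_spec(network$nodes, edges, pools = network$pools,
                      protected_map = network$protected_map,
                      accessibility = network$accessibility)
  list(network = net, params = params)
}

#' One-time IL-2 spike
#'
#' Returns the initial state with the IL-2 entry incremented by
#' `amplitude`; nothing else changes.
#'
#' @param x0 named initial state containing an `IL2` entry.
#' @param amplitude spike amplitude (concentration units), `>= 0`.
#' @return modified initial state.
#' @export
il2_spike <- function(x0, amplitude) {
  if (amplitude < 0) stop("amplitude must be nonnegative")
  x0[["IL2"]] <- x0[["IL2"]] + amplitude
  x0
}

#' Knock out (or down) a molecular species
#'
#' `production_zero` scales every secretion rate feeding the species by
#' `1 - fraction` (the "reduction rate" style intervention used for OPN and
#' LIF); `clamp_zero` adds an absorbing first-order sink (rate
#' `1e4 * fraction` per day) that pins the species near zero — an
#' idealized knockout. `fraction = 0` is the identity.
#'
#' @param network a [network_spec()].
#' @param params parameter registry.
#' @param species a molecular node name (e.g. `"OPN"`, `"LIF"`, `"Lac"`).
#' @param mode `"production_zero"` (default) or `"clamp_zero"`.
#' @param fraction knockout fraction in `[0, 1]`; 1 = full knockout.
#' @return list with elements `network` and `params`.
#' @export
knockout <- function(network, params, species,
                     mode = c("production_zero", "clamp_zero"),
                     fraction = 1) {
  mode <- match.arg(mode)
  if (fraction < 0 || fraction > 1) stop("fraction must lie in [0, 1]")
  role <- network$nodes$role[network$nodes$name == species]
  if (!length(role)) stop(sprintf("unknown node '%s'", species))
  if (role != "molecular_species") {
    stop(sprintf("invalid target: '%s' is a cell state, knockouts apply to molecular species",
                 species))
  }
  if (fraction == 0) return(list(network = network, params = params))
  if (mode == "production_zero") {
    keys <- unique(unlist(lapply(network$edges, function(e) {
      if (e$kind == "secretion" && e$target == species) e$params[["Ksec"]]
    })))
    params[keys] <- params[keys] * (1 - fraction)
  } else {
    kd_key <- vapply(Filter(function(e) {
      e$kind %in% c("degradation", "death") && e$target == species
    }, network$edges), function(e) e$params[["KD"]], character(1))[1]
    params[[kd_key]] <- params[[kd_key]] + 1e4 * fraction
  }
  list(network = network, params = params)
}
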