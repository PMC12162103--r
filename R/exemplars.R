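#' Representative registries for the five TME subtypes
#'
#' Hand-curated parameter sets, each a multiplicative tilt of the nominal
#' registry toward one of the five steady-state compositional subtypes.
#' They serve as reproducible entry points for the scenario runners and
#' the worked examples:
#'
#' * `desert` — killer-T proliferation below its survival threshold and a
#'   suppressed fibroblast-to-CAF program: both compartments collapse.
#' * `immune_desert` — a low-proliferation ("fibrotic only") desert:
#'   killer T cells cannot establish themselves, CAF thrives.
#' * `fibro_desert` — the immune/non-fibrotic composition: high
#'   cytotoxicity with a collapsed CAF compartment.
#' * `immune_dominated` — strong, weakly exhausted immunity with a CAF
#'   population below the killer-T population and high accessibility.
#' * `fibro_dominated` — fast CAF growth with a strong, wide barrier:
#'   very low immune accessibility, tumor cells mostly CAF-protected.
#'
#' @param base base registry (default [nominal_parameters()]).
#' @return named list of five 91-entry registries.
#' @export
subtype_exemplars <- function(base = nominal_parameters()) {
  tilt <- function(...) {
    f <- c(...)
    p <- base
    p[names(f)] <- p[names(f)] * f
    p
  }
  list(
    desert = tilt(Kprol_TKp = 0.3, Kprol_TKn = 0.3, Kconv_FWT_CAF = 0.02,
                  Kprol_CAF = 0.1, KD_CAF = 8),
    immune_desert = tilt(Kprol_TKp = 0.3, Kprol_TKn = 0.3),
    fibro_desert = tilt(Kkill_C0 = 4, Kkill_Cneg = 4, Kkill_Cpos = 4,
                        Kconv_FWT_CAF = 0.02, Kprol_CAF = 0.1, KD_CAF = 8),
    immune_dominated = tilt(Kkill_C0 = 4, Kkill_Cneg = 4, Kkill_Cpos = 4,
                            Kconv_TKp_TEx = 0.2, Kprol_TKp = 2,
                            Kprol_TKn = 2, KD_CAF = 2, Kconv_FWT_CAF = 0.4,
                            alpha_acc = 0.4),
    fibro_dominated = tilt(Kpara_OPN_CAF = 1.5, Kbr = 3, delta_br = 10,
                           Kconv_TKp_TEx = 5, Kpara_TEx_tumor = 0.01,
                           Kconv_M1_M2 = 0.5, Kmig = 0.05)
  )
}

#' Random valid model inputs for testing
#'
#' `random_parameter_set()` jitters every nominal registry entry by an
#' independent log-uniform factor in `[1/spread, spread]` (the anti-PD1
#' dose stays at its registry value, and bounded fractions are capped at
#' 1); `random_initial_state()` draws a nonnegative state with cell
#' populations uniform in `[0, half capacity]` and concentrations uniform
#' in `[0, 100]`.
#'
#' @param seed integer seed.
#' @param spread maximum multiplicative jitter (`> 1`).
#' @param base base registry.
#' @return a named parameter vector / named 24-state vector.
#' @export
random_parameter_set <- function(seed, spread = 2,
                                 base = nominal_parameters()) {
  stopifnot(spread > 1)
  set.seed(seed)
  fac <- exp(stats::runif(length(base), -log(spread), log(spread)))
  p <- base * fac
  p[["dose_pd1"]] <- base[["dose_pd1"]]
  for (k in c("alpha_prox", "alpha_ac", "alpha_acc")) {
    p[[k]] <- min(p[[k]], 1)
  }
  p
}

#' @rdname random_parameter_set
#' @param params registry the capacities are read from.
#' @export
random_initial_state <- function(seed, params = nominal_parameters()) {
  set.seed(seed)
  x0 <- stats::setNames(numeric(length(HNSCC_NODES)), HNSCC_NODES)
  caps <- c(C0_E = "xmax_tumor", C0_P = "xmax_tumor", Cneg_E = "xmax_tumor",
            Cneg_P = "xmax_tumor", Cpos_E = "xmax_tumor",
            Cpos_P = "xmax_tumor", TKp = "xmax_TK", TKn = "xmax_TK",
            THelp = "xmax_THelp", TReg = "xmax_TReg", TEx = "xmax_TEx",
            M1 = "xmax_M", M2 = "xmax_M", FWT = "xmax_F", CAF = "xmax_F")
  for (nd in names(caps)) {
    x0[[nd]] <- stats::runif(1, 0, 0.5 * params[[caps[[nd]]]])
  }
  for (m in HNSCC_MOLS) x0[[m]] <- stats::runif(1, 0, 100)
  x0
}
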