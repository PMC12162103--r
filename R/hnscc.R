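#' Immune accessibility index
#'
#' `Ia = 1 - tanh(alpha * CAF * Kbr)`: the ratio of the carrying capacities
#' of immune-accessible to CAF-protected tumor cells. `Ia = 1` means every
#' tumor cell is reachable by killer T cells (no CAF barrier); `Ia -> 0`
#' means the barrier is impenetrable.
#'
#' @param alpha fraction of CAFs located near the tumor cells, in `[0, 1]`.
#' @param Kbr barrier formation rate, `>= 0`.
#' @param caf CAF population, `>= 0`.
#' @return accessibility index in `(0, 1]`, monotone nonincreasing in `caf`.
#' @examples
#' accessibility_index(0.5, 1e-3, caf = 0) # exactly 1
#' @export
accessibility_index <- function(alpha, Kbr, caf) {
  if (any(caf < 0)) stop("invalid input: CAF population must be nonnegative")
  if (any(alpha < 0) || any(alpha > 1)) stop("alpha must lie in [0, 1]")
  if (any(Kbr < 0)) stop("Kbr must be nonnegative")
  1 - tanh(alpha * caf * Kbr)
}

#' Barrier penetration of the elimination rate
#'
#' `fcd * exp(-alpha^2 * delta * CAF^2)`: the effective kill rate against
#' tumor cells sitting behind the CAF barrier, where `delta` is the barrier
#' width. Always `<=` the base rate.
#'
#' @param fcd base elimination rate, `>= 0`.
#' @param alpha fraction of CAFs near the tumor cells.
#' @param delta width of the CAF barrier, `>= 0`.
#' @param caf CAF population, `>= 0`.
#' @return attenuated elimination rate.
#' @export
barrier_penetration <- function(fcd, alpha, delta, caf) {
  if (any(c(fcd, delta, caf) < 0)) {
    stop("invalid input: fcd, delta and caf must be nonnegative")
  }
  fcd * exp(-alpha^2 * delta * caf^2)
}

#' Partition the tumor carrying capacity by accessibility
#'
#' Solves `K_IA / K_FP = Ia` and `K_IA + K_FP = K_total`, giving
#' `K_IA = K_total * Ia / (1 + Ia)` and `K_FP = K_total / (1 + Ia)`.
#'
#' @param K_total total tumor carrying capacity, `> 0`.
#' @param Ia accessibility index in `[0, 1]`.
#' @return named vector `c(K_IA, K_FP)`.
#' @export
partition_capacities <- function(K_total, Ia) {
  if (K_total <= 0) stop("K_total must be > 0")
  if (Ia < 0 || Ia > 1) stop("Ia must lie in [0, 1]")
  if (Ia == 0) warning("Ia = 0: degenerate split, all capacity protected")
  c(K_IA = K_total * Ia / (1 + Ia), K_FP = K_total / (1 + Ia))
}

# node order of the 24-state system
HNSCC_NODES <- c("C0_E", "C0_P", "Cneg_E", "Cneg_P", "Cpos_E", "Cpos_P",
                 "TKp", "TKn", "THelp", "TReg", "TEx", "M1", "M2",
                 "FWT", "CAF",
                 "IL2", "IL8", "IL10", "LIF", "IFNG", "IRF8", "OPN",
                 "ICAM1", "Lac")
HNSCC_CELLS <- HNSCC_NODES[1:15]
HNSCC_MOLS <- HNSCC_NODES[16:24]
HNSCC_TUMOR <- HNSCC_NODES[1:6]

#' Build the HNSCC tumor-microenvironment network
#'
#' The fixed 24-node atlas: three tumor cell states (stem `C0`, `C_PDL1-`,
#' `C_PDL1+`), each split into a killer-T-exposed (`_E`) and a
#' CAF-protected (`_P`) compartment; PD1+ and PD1- killer T cells, helper,
#' regulatory and exhausted T cells; M1/M2 macrophages; wild-type
#' fibroblasts and CAFs; and nine molecular species (IL-2, IL-8, IL-10,
#' LIF, IFN-gamma, IRF8, OPN, ICAM1, lactate).
#'
#' Key wiring: IL-8 gates the stem to PDL1- transition and IFN-gamma the
#' PDL1- to PDL1+ transition; LIF gates the wild-type-fibroblast to CAF
#' conversion and OPN drives CAF autocrine proliferation; CAF paracrine
#' promotes tumor, regulatory-T and M2 growth; helper T cells (activated by
#' exposed PDL1- tumor cells and IFN-gamma), IL-2 and IFN-gamma promote
#' killer-T growth; regulatory T cells inhibit helper-T proliferation;
#' killer T cells eliminate exposed stem and PDL1- tumor cells, attenuated
#' by lactate; PD1+ killer T cells exhaust in the presence of exposed PDL1+
#' tumor cells and M2 macrophages; exhausted T cells feed tumor growth;
#' IRF8 (from M1) inhibits OPN secretion. Protected tumor compartments
#' carry no elimination edge — they are reached only through the
#' barrier-penetration mirror of the exposed-compartment fluxes.
#'
#' @return a [network_spec()] with 24 nodes.
#' @export
build_hnscc_network <- function() {
  nodes <- do.call(rbind, c(
    lapply(HNSCC_TUMOR, function(nd) {
      node_spec(nd, "cell_state",
                if (endsWith(nd, "_E")) "exposed" else "protected")
    }),
    lapply(HNSCC_CELLS[7:15], node_spec, role = "cell_state"),
    lapply(HNSCC_MOLS, node_spec, role = "molecular_species")
  ))

  kprol <- c(C0_E = "Kprol_C0", C0_P = "Kprol_C0",
             Cneg_E = "Kprol_Cneg", Cneg_P = "Kprol_Cneg",
             Cpos_E = "Kprol_Cpos", Cpos_P = "Kprol_Cpos",
             TKp = "Kprol_TKp", TKn = "Kprol_TKn", THelp = "Kprol_THelp",
             TReg = "Kprol_TReg", TEx = "Kprol_TEx", M1 = "Kprol_M1",
             M2 = "Kprol_M2", FWT = "Kprol_FWT", CAF = "Kprol_CAF")
  kd_cell <- c(C0_E = "KD_C0", C0_P = "KD_C0",
               Cneg_E = "KD_Cneg", Cneg_P = "KD_Cneg",
               Cpos_E = "KD_Cpos", Cpos_P = "KD_Cpos",
               TKp = "KD_TKp", TKn = "KD_TKn", THelp = "KD_THelp",
               TReg = "KD_TReg", TEx = "KD_TEx", M1 = "KD_M", M2 = "KD_M",
               FWT = "KD_FWT", CAF = "KD_CAF")

  edges <- list()
  add <- function(...) edges[[length(edges) + 1L]] <<- edge_spec(...)

  for (nd in HNSCC_CELLS) {
    add("proliferation", nd, params = c(Kprol = unname(kprol[nd])))
    add("death", nd, params = c(KD = unname(kd_cell[nd])))
  }
  for (m in HNSCC_MOLS) {
    add("degradation", m, params = c(KD = paste0("KD_", m)))
  }

  gate <- function(species, V = "V_conv_mol") list(list(species = species, V = V))
  for (cp in c("E", "P")) {
    add("conversion", paste0("Cneg_", cp), paste0("C0_", cp),
        params = c(Kconv = "Kconv_C0_Cneg"), gates = gate("IL8"))
    add("conversion", paste0("Cpos_", cp), paste0("Cneg_", cp),
        params = c(Kconv = "Kconv_Cneg_Cpos"), gates = gate("IFNG"))
  }
  add("conversion", "CAF", "FWT", params = c(Kconv = "Kconv_FWT_CAF"),
      gates = gate("LIF"))
  add("conversion", "M2", "M1", params = c(Kconv = "Kconv_M1_M2"),
      gates = gate("IL10"))
  add("conversion", "TEx", "TKp", params = c(Kconv = "Kconv_TKp_TEx"),
      gates = list(list(species = "Cpos_E", V = "V_exh_Cpos"),
                   list(species = "M2", V = "V_exh_M2")))

  para <- function(target, source, Kpara, V, prox = TRUE) {
    p <- c(Kpara = Kpara, V = V)
    if (prox) p <- c(p, alpha = "alpha_prox")
    add("paracrine", target, source, params = p)
  }
  for (nd in HNSCC_TUMOR) {
    para(nd, "CAF", "Kpara_CAF_tumor", "V_CAF_tumor")
    para(nd, "TEx", "Kpara_TEx_tumor", "V_TEx_tumor")
  }
  para("CAF", "OPN", "Kpara_OPN_CAF", "V_OPN_CAF", prox = FALSE)
  para("TReg", "CAF", "Kpara_CAF_TReg", "V_CAF_TReg")
  para("M2", "CAF", "Kpara_CAF_M2", "V_CAF_M2")
  para("THelp", "Cneg_E", "Kpara_Cneg_THelp", "V_Cneg_THelp")
  para("THelp", "IFNG", "Kpara_IFNG_T", "V_IFNG_T", prox = FALSE)
  for (tk in c("TKp", "TKn")) {
    para(tk, "THelp", "Kpara_THelp_TK", "V_THelp_TK")
    para(tk, "IFNG", "Kpara_IFNG_T", "V_IFNG_T", prox = FALSE)
    para(tk, "IL2", "Kpara_IL2_TK", "V_IL2_TK", prox = FALSE)
  }

  add("regulatory_inhibition", "THelp", "TReg", site = "proliferation",
      params = c(Vreg = "Vreg_TReg_THelp", alpha = "alpha_TReg_THelp"))
  add("regulatory_inhibition", "OPN", "IRF8", site = "secretion",
      params = c(Vreg = "Vreg_IRF8_OPN", alpha = "alpha_IRF8_OPN"))
  for (tk in c("TKp", "TKn")) {
    add("regulatory_inhibition", tk, "Lac", site = "elimination",
        params = c(Vreg = "Vreg_Lac_kill", alpha = "alpha_Lac_kill"))
  }

  for (tk in c("TKp", "TKn")) {
    add("elimination", "C0_E", tk,
        params = c(Kkill = "Kkill_C0", alpha_ac = "alpha_ac"))
    add("elimination", "Cneg_E", tk,
        params = c(Kkill = "Kkill_Cneg", alpha_ac = "alpha_ac"))
  }

  sec <- function(target, sources, Ksec) {
    for (s in sources) add("secretion", target, s, params = c(Ksec = Ksec))
  }
  t_sec <- c("TKp", "TKn", "THelp")
  # IL-2 comes from the killer compartment itself: in a depleted TME the
  # ambient IL-2 settles to near zero, which is what a one-time spike must
  # overcome
  sec("IL2", c("TKp", "TKn"), "Ksec_IL2_T")
  sec("IL8", c(HNSCC_TUMOR, "CAF", "M2"), "Ksec_IL8")
  sec("IL10", c(t_sec, "TReg"), "Ksec_IL10_T")
  sec("LIF", c(HNSCC_TUMOR, "FWT", "CAF"), "Ksec_LIF")
  sec("IFNG", t_sec, "Ksec_IFNG_T")
  sec("IRF8", "M1", "Ksec_IRF8_M1")
  sec("OPN", c(HNSCC_TUMOR, "CAF"), "Ksec_OPN")
  sec("ICAM1", t_sec, "Ksec_ICAM1_T")
  sec("Lac", HNSCC_TUMOR, "Ksec_Lac")

  pools <- list(
    list(members = HNSCC_TUMOR, cap_key = "xmax_tumor"),
    list(members = c("TKp", "TKn"), cap_key = "xmax_TK"),
    list(members = "THelp", cap_key = "xmax_THelp"),
    list(members = "TReg", cap_key = "xmax_TReg"),
    list(members = "TEx", cap_key = "xmax_TEx"),
    list(members = c("M1", "M2"), cap_key = "xmax_M"),
    # the two fibroblast phenotypes occupy distinct niches (quiescent
    # stroma vs remodeled matrix): each has the full fibroblast capacity
    list(members = "FWT", cap_key = "xmax_F"),
    list(members = "CAF", cap_key = "xmax_F")
  )
  protected_map <- c(C0_E = "C0_P", Cneg_E = "Cneg_P", Cpos_E = "Cpos_P")
  accessibility <- list(alpha = "alpha_acc", Kbr = "Kbr", delta = "delta_br",
                        caf = "CAF", mig_key = "Kmig")

  net <- network_spec(nodes, edges, pools = pools,
                      protected_map = protected_map,
                      accessibility = accessibility)
  stopifnot(nrow(net$nodes) == 24L)
  net
}

#' Nominal parameter registry
#'
#' The 91-entry named registry of the full HNSCC model: proliferation
#' rates, carrying capacities, conversion rates and their gate constants,
#' paracrine gains and dissociation constants, regulatory inhibition
#' constants, elimination rates, secretion and degradation rates,
#' accessibility hyperparameters and the anti-PD1 intervention parameters.
#' Time unit is days; populations are cell counts, concentrations
#' arbitrary units. Magnitudes follow the usual conventions of
#' tumor-immune population models: growth rates of order 0.1-1 per day,
#' capacities of order 1e3-1e4 cells, molecular turnover of order 1 per
#' day.
#'
#' @return named numeric vector of length 91.
#' @export
nominal_parameters <- function() {
  p <- c(
    # proliferation rates (per day)
    Kprol_C0 = 0.60, Kprol_Cneg = 0.55, Kprol_Cpos = 0.50,
    Kprol_TKp = 0.15, Kprol_TKn = 0.15, Kprol_THelp = 1.00,
    Kprol_TReg = 0.12, Kprol_TEx = 0.05, Kprol_M1 = 0.90,
    Kprol_M2 = 0.25, Kprol_FWT = 0.40, Kprol_CAF = 0.10,
    # carrying capacities (cells)
    xmax_tumor = 1e4, xmax_TK = 2e3, xmax_THelp = 1e3, xmax_TReg = 500,
    xmax_TEx = 1e3, xmax_M = 1e3, xmax_F = 2e3,
    # natural death rates (per day)
    KD_C0 = 0.05, KD_Cneg = 0.05, KD_Cpos = 0.05,
    KD_TKp = 0.18, KD_TKn = 0.18, KD_THelp = 0.12, KD_TReg = 0.15,
    KD_TEx = 0.20, KD_M = 0.05, KD_FWT = 0.04, KD_CAF = 0.12,
    # molecular degradation rates (per day)
    KD_IL2 = 1.0, KD_IL8 = 1.0, KD_IL10 = 1.0, KD_LIF = 0.5,
    KD_IFNG = 1.0, KD_IRF8 = 1.0, KD_OPN = 0.5, KD_ICAM1 = 1.0,
    KD_Lac = 2.0,
    # conversion rates (per day) and gate dissociation constants
    Kconv_C0_Cneg = 0.30, Kconv_Cneg_Cpos = 0.20, Kconv_FWT_CAF = 0.05,
    Kconv_M1_M2 = 0.10, Kconv_TKp_TEx = 0.30,
    V_conv_mol = 50, V_exh_Cpos = 500, V_exh_M2 = 1000,
    # exposed <-> protected migration rate (per day)
    Kmig = 0.10,
    # paracrine gains and dissociation constants
    Kpara_CAF_tumor = 2.0, V_CAF_tumor = 800,
    Kpara_TEx_tumor = 1.0, V_TEx_tumor = 500,
    Kpara_OPN_CAF = 4.0, V_OPN_CAF = 100,
    Kpara_CAF_TReg = 1.0, V_CAF_TReg = 800,
    Kpara_CAF_M2 = 2.0, V_CAF_M2 = 800,
    Kpara_Cneg_THelp = 2.0, V_Cneg_THelp = 2000,
    Kpara_THelp_TK = 3.0, V_THelp_TK = 300,
    Kpara_IFNG_T = 0.5, V_IFNG_T = 50,
    Kpara_IL2_TK = 2.0, V_IL2_TK = 30,
    alpha_prox = 0.8,
    # regulatory inhibition (dissociation constants and weights)
    Vreg_TReg_THelp = 1.0, alpha_TReg_THelp = 0.05,
    Vreg_IRF8_OPN = 1.0, alpha_IRF8_OPN = 0.02,
    Vreg_Lac_kill = 1.0, alpha_Lac_kill = 0.01,
    # elimination rates (per killer cell per day) and accessibility factor
    Kkill_C0 = 2e-3, Kkill_Cneg = 2e-3, Kkill_Cpos = 2e-3,
    alpha_ac = 0.9,
    # secretion rates (per secreting cell per day)
    Ksec_IL2_T = 0.02, Ksec_IL8 = 0.01, Ksec_IL10_T = 0.01,
    Ksec_LIF = 0.005, Ksec_IFNG_T = 0.02, Ksec_IRF8_M1 = 0.02,
    Ksec_OPN = 0.01, Ksec_ICAM1_T = 0.02, Ksec_Lac = 0.01,
    # accessibility hyperparameters
    alpha_acc = 0.5, Kbr = 1e-3, delta_br = 1e-6,
    # anti-PD1 intervention (binding rate, dose; dose 0 = untreated)
    k_bind_pd1 = 1.0, dose_pd1 = 0
  )
  stopifnot(length(p) == 91L)
  p
}

#' Default initial condition
#'
#' Small seed populations (1% of the relevant carrying capacity) for the
#' tumor stem cells (split evenly across compartments), wild-type
#' fibroblasts, M1 macrophages, PD1+ killer, helper and regulatory T
#' cells; all other states start at zero.
#'
#' @param params parameter registry (capacities are read from it).
#' @return named numeric vector of length 24.
#' @export
default_initial_state <- function(params = nominal_parameters()) {
  x0 <- stats::setNames(numeric(length(HNSCC_NODES)), HNSCC_NODES)
  x0["C0_E"] <- x0["C0_P"] <- 0.005 * params[["xmax_tumor"]]
  x0["TKp"] <- 0.01 * params[["xmax_TK"]]
  x0["THelp"] <- 0.01 * params[["xmax_THelp"]]
  x0["TReg"] <- 0.01 * params[["xmax_TReg"]]
  x0["M1"] <- 0.01 * params[["xmax_M"]]
  x0["FWT"] <- 0.01 * params[["xmax_F"]]
  x0
}
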