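# Independent hand-coded reference of the 24-equation HNSCC system.
# Written directly from the rate laws, without touching the network
# assembler; used to cross-check assemble_rhs() to near machine precision.

hnscc_rhs_reference <- function(state, params, anti_pd1 = FALSE) {
  y <- pmax(state, 0)
  p <- as.list(params)
  g <- function(nm) y[[nm]]

  caf <- g("CAF")
  Ia <- 1 - tanh(p$alpha_acc * caf * p$Kbr)
  pen <- exp(-p$alpha_acc^2 * p$delta_br * caf^2)
  fE <- 1 / (1 + Ia)   # migration weight out of the exposed pool
  fI <- Ia / (1 + Ia)  # migration weight out of the protected pool

  occ <- function(x, V) x / (V + x)
  pm <- function(K, V, xi, prox = p$alpha_prox) 1 + K * prox * xi / (V + xi)

  reg_lac <- 1 / (p$Vreg_Lac_kill + p$alpha_Lac_kill * g("Lac"))
  reg_treg <- 1 / (p$Vreg_TReg_THelp + p$alpha_TReg_THelp * g("TReg"))
  reg_irf8 <- 1 / (p$Vreg_IRF8_OPN + p$alpha_IRF8_OPN * g("IRF8"))

  tumor <- g("C0_E") + g("C0_P") + g("Cneg_E") + g("Cneg_P") +
    g("Cpos_E") + g("Cpos_P")
  occ_tumor <- tumor / p$xmax_tumor
  mult_tumor <- pm(p$Kpara_CAF_tumor, p$V_CAF_tumor, caf) *
    pm(p$Kpara_TEx_tumor, p$V_TEx_tumor, g("TEx"))

  occ_IL8 <- occ(g("IL8"), p$V_conv_mol)
  occ_IFNG <- occ(g("IFNG"), p$V_conv_mol)
  occ_LIF <- occ(g("LIF"), p$V_conv_mol)
  occ_IL10 <- occ(g("IL10"), p$V_conv_mol)

  TKtot <- g("TKp") + g("TKn")
  kill_E <- function(Kkill, x) Kkill * p$alpha_ac * reg_lac * x * TKtot
  kill_P <- function(Kkill, x) pen * kill_E(Kkill, x)
  mig <- function(e, pr) p$Kmig * (g(e) * fE - g(pr) * fI)

  mig_C0 <- mig("C0_E", "C0_P")
  mig_Cn <- mig("Cneg_E", "Cneg_P")
  mig_Cp <- mig("Cpos_E", "Cpos_P")

  dC0_E <- p$Kprol_C0 * g("C0_E") * (1 - occ_tumor) * mult_tumor -
    p$Kconv_C0_Cneg * occ_IL8 * g("C0_E") -
    kill_E(p$Kkill_C0, g("C0_E")) - p$KD_C0 * g("C0_E") - mig_C0
  dC0_P <- p$Kprol_C0 * g("C0_P") * (1 - occ_tumor) * mult_tumor -
    p$Kconv_C0_Cneg * occ_IL8 * g("C0_P") -
    kill_P(p$Kkill_C0, g("C0_P")) - p$KD_C0 * g("C0_P") + mig_C0

  dCneg_E <- p$Kprol_Cneg * g("Cneg_E") * (1 - occ_tumor) * mult_tumor +
    p$Kconv_C0_Cneg * occ_IL8 * g("C0_E") -
    p$Kconv_Cneg_Cpos * occ_IFNG * g("Cneg_E") -
    kill_E(p$Kkill_Cneg, g("Cneg_E")) - p$KD_Cneg * g("Cneg_E") - mig_Cn
  dCneg_P <- p$Kprol_Cneg * g("Cneg_P") * (1 - occ_tumor) * mult_tumor +
    p$Kconv_C0_Cneg * occ_IL8 * g("C0_P") -
    p$Kconv_Cneg_Cpos * occ_IFNG * g("Cneg_P") -
    kill_P(p$Kkill_Cneg, g("Cneg_P")) - p$KD_Cneg * g("Cneg_P") + mig_Cn

  dCpos_E <- p$Kprol_Cpos * g("Cpos_E") * (1 - occ_tumor) * mult_tumor +
    p$Kconv_Cneg_Cpos * occ_IFNG * g("Cneg_E") -
    p$KD_Cpos * g("Cpos_E") - mig_Cp
  dCpos_P <- p$Kprol_Cpos * g("Cpos_P") * (1 - occ_tumor) * mult_tumor +
    p$Kconv_Cneg_Cpos * occ_IFNG * g("Cneg_P") -
    p$KD_Cpos * g("Cpos_P") + mig_Cp
  if (anti_pd1) {
    kpos_E <- p$Kkill_Cpos * p$alpha_ac * reg_lac * g("Cpos_E") * g("TKn")
    kpos_P <- pen * p$Kkill_Cpos * p$alpha_ac * reg_lac * g("Cpos_P") *
      g("TKn")
    dCpos_E <- dCpos_E - kpos_E
    dCpos_P <- dCpos_P - kpos_P
  }

  occ_TK <- (g("TKp") + g("TKn")) / p$xmax_TK
  mult_TK <- pm(p$Kpara_THelp_TK, p$V_THelp_TK, g("THelp")) *
    pm(p$Kpara_IFNG_T, p$V_IFNG_T, g("IFNG"), prox = 1) *
    pm(p$Kpara_IL2_TK, p$V_IL2_TK, g("IL2"), prox = 1)
  exh <- p$Kconv_TKp_TEx * occ(g("Cpos_E"), p$V_exh_Cpos) *
    occ(g("M2"), p$V_exh_M2) * g("TKp")
  drug <- if (anti_pd1) p$k_bind_pd1 * p$dose_pd1 * g("TKp") else 0

  dTKp <- p$Kprol_TKp * g("TKp") * (1 - occ_TK) * mult_TK - exh - drug -
    p$KD_TKp * g("TKp")
  dTKn <- p$Kprol_TKn * g("TKn") * (1 - occ_TK) * mult_TK + drug -
    p$KD_TKn * g("TKn")

  mult_THelp <- pm(p$Kpara_Cneg_THelp, p$V_Cneg_THelp, g("Cneg_E")) *
    pm(p$Kpara_IFNG_T, p$V_IFNG_T, g("IFNG"), prox = 1)
  dTHelp <- p$Kprol_THelp * g("THelp") * (1 - g("THelp") / p$xmax_THelp) *
    mult_THelp * reg_treg - p$KD_THelp * g("THelp")

  dTReg <- p$Kprol_TReg * g("TReg") * (1 - g("TReg") / p$xmax_TReg) *
    pm(p$Kpara_CAF_TReg, p$V_CAF_TReg, caf) - p$KD_TReg * g("TReg")

  dTEx <- p$Kprol_TEx * g("TEx") * (1 - g("TEx") / p$xmax_TEx) + exh -
    p$KD_TEx * g("TEx")

  occ_M <- (g("M1") + g("M2")) / p$xmax_M
  conv_M <- p$Kconv_M1_M2 * occ_IL10 * g("M1")
  dM1 <- p$Kprol_M1 * g("M1") * (1 - occ_M) - conv_M - p$KD_M * g("M1")
  dM2 <- p$Kprol_M2 * g("M2") * (1 - occ_M) *
    pm(p$Kpara_CAF_M2, p$V_CAF_M2, caf) + conv_M - p$KD_M * g("M2")

  conv_F <- p$Kconv_FWT_CAF * occ_LIF * g("FWT")
  dFWT <- p$Kprol_FWT * g("FWT") * (1 - g("FWT") / p$xmax_F) - conv_F -
    p$KD_FWT * g("FWT")
  dCAF <- p$Kprol_CAF * caf * (1 - caf / p$xmax_F) *
    pm(p$Kpara_OPN_CAF, p$V_OPN_CAF, g("OPN"), prox = 1) + conv_F -
    p$KD_CAF * caf

  T3 <- g("TKp") + g("TKn") + g("THelp")
  dIL2 <- p$Ksec_IL2_T * (g("TKp") + g("TKn")) - p$KD_IL2 * g("IL2")
  dIL8 <- p$Ksec_IL8 * (tumor + caf + g("M2")) - p$KD_IL8 * g("IL8")
  dIL10 <- p$Ksec_IL10_T * (T3 + g("TReg")) - p$KD_IL10 * g("IL10")
  dLIF <- p$Ksec_LIF * (tumor + g("FWT") + caf) - p$KD_LIF * g("LIF")
  dIFNG <- p$Ksec_IFNG_T * T3 - p$KD_IFNG * g("IFNG")
  dIRF8 <- p$Ksec_IRF8_M1 * g("M1") - p$KD_IRF8 * g("IRF8")
  dOPN <- p$Ksec_OPN * (tumor + caf) * reg_irf8 - p$KD_OPN * g("OPN")
  dICAM1 <- p$Ksec_ICAM1_T * T3 - p$KD_ICAM1 * g("ICAM1")
  dLac <- p$Ksec_Lac * tumor - p$KD_Lac * g("Lac")

  c(C0_E = dC0_E, C0_P = dC0_P, Cneg_E = dCneg_E, Cneg_P = dCneg_P,
    Cpos_E = dCpos_E, Cpos_P = dCpos_P, TKp = dTKp, TKn = dTKn,
    THelp = dTHelp, TReg = dTReg, TEx = dTEx, M1 = dM1, M2 = dM2,
    FWT = dFWT, CAF = dCAF, IL2 = dIL2, IL8 = dIL8, IL10 = dIL10,
    LIF = dLIF, IFNG = dIFNG, IRF8 = dIRF8, OPN = dOPN, ICAM1 = dICAM1,
    Lac = dLac)
}
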