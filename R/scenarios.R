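#' Pre/post checkpoint-inhibition comparison
#'
#' Shared protocol of the scenario runners: integrate the untreated model
#' to its pre-therapy steady state, optionally re-seed the killer T cell
#' population and IL-2 concentration (an ICI trial presumes some killer T
#' cells reach the tumor), apply anti-PD1 at the given dose, and integrate
#' to the post-therapy steady state.
#'
#' @param network a [network_spec()].
#' @param params parameter registry.
#' @param dose anti-PD1 dose (0 = untreated; post equals pre).
#' @param seed_TK,seed_IL2 floors applied to the PD1+ killer T population
#'   and IL-2 concentration of the post-treatment initial condition.
#' @param x0 pre-therapy initial state.
#' @param freeze_Ia optional frozen accessibility index (both phases).
#' @param t_max,tol steady-state controls.
#' @return list with `pre` and `post` (`tme_steady` records) and the
#'   modified model.
#' @export
ici_response <- function(network, params, dose, seed_TK = 0, seed_IL2 = 0,
                         x0 = default_initial_state(params),
                         freeze_Ia = NULL, t_max = 4000, tol = 1e-5) {
  pre <- steady_state(network, params, x0, t_max = t_max, tol = tol,
                      freeze_Ia = freeze_Ia)
  x1 <- pre$state
  x1[["TKp"]] <- max(x1[["TKp"]], seed_TK)
  x1[["IL2"]] <- max(x1[["IL2"]], seed_IL2)
  mod <- apply_anti_pd1(network, params, dose)
  post <- steady_state(mod$network, mod$params, x1, t_max = t_max,
                       tol = tol, freeze_Ia = freeze_Ia)
  list(pre = pre, post = post, network = mod$network, params = mod$params)
}

#' Immune-desert diversity and ICI response
#'
#' Scans killer-T proliferation, exhaustion and CAF-to-regulatory-T
#' paracrine rates (as multiplicative factors on the base registry),
#' labels each pre-therapy steady state, distinguishes the three
#' immune-desert mechanisms — low proliferation, exhaustion-driven
#' (exhausted T cells abundant) and Treg-driven (regulatory T cells
#' abundant) — and reports which respond to anti-PD1 when the treatment
#' starts with a small killer-T / IL-2 seed.
#'
#' @param params base registry.
#' @param prolif_factors,exhaustion_factors,treg_factors multiplicative
#'   grids for `Kprol_TKp`, `Kconv_TKp_TEx` and `Kpara_CAF_TReg`.
#' @param dose anti-PD1 dose.
#' @param network the atlas.
#' @param t_max,tol steady-state controls.
#' @return data frame, one row per grid point: the factors, the pre-ICI
#'   label and desert mechanism, pre/post killer-T and tumor populations,
#'   and a `responds` flag (post-ICI killer T above pre by > 5%).
#' @export
scenario_immune_desert_variants <- function(params = nominal_parameters(),
                                            prolif_factors = c(0.1, 1),
                                            exhaustion_factors = c(1, 10),
                                            treg_factors = c(1, 10),
                                            dose = 1,
                                            network = build_hnscc_network(),
                                            t_max = 4000, tol = 1e-5) {
  if (!length(prolif_factors) || !length(exhaustion_factors) ||
      !length(treg_factors)) stop("grids must be non-empty")
  grid <- expand.grid(prolif = prolif_factors, exhaustion = exhaustion_factors,
                      treg = treg_factors)
  th <- default_thresholds(params)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    p <- params
    p[["Kprol_TKp"]] <- p[["Kprol_TKp"]] * grid$prolif[i]
    p[["Kprol_TKn"]] <- p[["Kprol_TKn"]] * grid$prolif[i]
    p[["Kconv_TKp_TEx"]] <- p[["Kconv_TKp_TEx"]] * grid$exhaustion[i]
    p[["Kpara_CAF_TReg"]] <- p[["Kpara_CAF_TReg"]] * grid$treg[i]
    res <- ici_response(network, p, dose,
                        seed_TK = 0.01 * p[["xmax_TK"]], seed_IL2 = 10,
                        t_max = t_max, tol = tol)
    lab <- classify_steady_state(res$pre, p)
    s <- res$pre$state
    # mechanism calls: Treg-driven by the regulatory population itself;
    # low proliferation when helper-supported growth (helper multiplier at
    # half saturation) cannot beat natural death; exhaustion by its flux
    # balance — once the killer-T pool has fully collapsed the exhausted
    # pool loses its influx and decays, so the steady state alone cannot
    # carry the exhaustion signature
    g_supported <- p[["Kprol_TKp"]] *
      (1 + 0.5 * p[["alpha_prox"]] * p[["Kpara_THelp_TK"]])
    mechanism <- if (!lab %in% c("desert", "immune_desert")) {
      "not_desert"
    } else if (s[["TReg"]] >= 0.3 * p[["xmax_TReg"]]) {
      "treg_driven"
    } else if (g_supported < p[["KD_TKp"]]) {
      "low_proliferation"
    } else if (p[["Kconv_TKp_TEx"]] >= p[["KD_TKp"]]) {
      "exhaustion_driven"
    } else {
      "other"
    }
    data.frame(prolif = grid$prolif[i], exhaustion = grid$exhaustion[i],
               treg = grid$treg[i], label = lab, mechanism = mechanism,
               pre_killer = res$pre$derived$killer_T_total,
               post_killer = res$post$derived$killer_T_total,
               pre_tumor = res$pre$derived$total_tumor,
               post_tumor = res$post$derived$total_tumor,
               pre_TEx = s[["TEx"]], pre_TReg = s[["TReg"]],
               responds = res$post$derived$killer_T_total >
                 1.05 * res$pre$derived$killer_T_total + th$eps_T * 0.01)
  })
  do.call(rbind, rows)
}

#' ICI response by TME subtype
#'
#' For each supplied representative parameter set (named by subtype),
#' reports pre/post anti-PD1 tumor, killer-T and CAF populations. For a
#' fibro-dominated set it additionally scans frozen accessibility indices
#' (post-ICI tumor vs Ia); for a fibro-desert (immune/non-fibrotic) set it
#' scans the tumor resource capacity (recurrence vs resource supply).
#'
#' @param params_by_subtype named list of registries; names are subtype
#'   labels.
#' @param dose anti-PD1 dose.
#' @param Ia_grid frozen accessibility indices for the fibro-dominated
#'   scan.
#' @param resource_factors multiplicative factors on `xmax_tumor` for the
#'   fibro-desert recurrence scan.
#' @param network,t_max,tol as elsewhere.
#' @return list with `summary` (one row per subtype) and the optional
#'   `ia_scan` and `resource_scan` data frames.
#' @export
scenario_ici_by_subtype <- function(params_by_subtype, dose = 1,
                                    Ia_grid = c(0.1, 0.3, 0.6, 0.9),
                                    resource_factors = c(0.5, 1, 2),
                                    network = build_hnscc_network(),
                                    t_max = 4000, tol = 1e-5) {
  summary_rows <- list()
  ia_scan <- NULL
  resource_scan <- NULL
  for (lab in names(params_by_subtype)) {
    p <- params_by_subtype[[lab]]
    res <- ici_response(network, p, dose, seed_TK = 0.01 * p[["xmax_TK"]],
                        seed_IL2 = 10, t_max = t_max, tol = tol)
    summary_rows[[lab]] <- data.frame(
      subtype = lab,
      pre_tumor = res$pre$derived$total_tumor,
      post_tumor = res$post$derived$total_tumor,
      pre_killer = res$pre$derived$killer_T_total,
      post_killer = res$post$derived$killer_T_total,
      pre_CAF = res$pre$derived$CAF, post_CAF = res$post$derived$CAF)
    if (lab == "fibro_dominated") {
      ia_scan <- do.call(rbind, lapply(Ia_grid, function(ia) {
        r <- ici_response(network, p, dose,
                          seed_TK = 0.01 * p[["xmax_TK"]], seed_IL2 = 10,
                          freeze_Ia = ia, t_max = t_max, tol = tol)
        data.frame(Ia = ia, post_tumor = r$post$derived$total_tumor,
                   pre_CAF = r$pre$derived$CAF,
                   post_CAF = r$post$derived$CAF)
      }))
    }
    if (lab == "fibro_desert") {
      resource_scan <- do.call(rbind, lapply(resource_factors, function(fc) {
        p2 <- p
        p2[["xmax_tumor"]] <- p[["xmax_tumor"]] * fc
        r <- ici_response(network, p2, dose,
                          seed_TK = 0.01 * p2[["xmax_TK"]], seed_IL2 = 10,
                          t_max = t_max, tol = tol)
        data.frame(resource_factor = fc,
                   post_tumor = r$post$derived$total_tumor)
      }))
    }
  }
  list(summary = do.call(rbind, summary_rows), ia_scan = ia_scan,
       resource_scan = resource_scan)
}

#' One-time IL-2 spike threshold
#'
#' Scans (then bisects, to 1% relative precision) the initial IL-2 spike
#' amplitude at which the steady state reached from an immune-desert
#' starting point leaves the desert labels. Returns `Inf` when no
#' amplitude on the grid escapes the desert — in particular when the
#' IL-2-driven killer-T proliferation gain is below the rescue floor.
#'
#' @param params registry of an immune-desert configuration.
#' @param amplitudes increasing amplitude grid (should span at least two
#'   decades).
#' @param network,t_max,tol as elsewhere.
#' @return list with `threshold` (amplitude, or `Inf`) and `scan` (data
#'   frame of amplitude, killer-T steady state, label).
#' @export
scenario_il2_threshold <- function(params,
                                   amplitudes = 10^seq(0, 4, length.out = 9),
                                   network = build_hnscc_network(),
                                   t_max = 4000, tol = 1e-5) {
  amplitudes <- sort(amplitudes)
  x0 <- default_initial_state(params)
  run_amp <- function(a) {
    rec <- steady_state(network, params, il2_spike(x0, a), t_max = t_max,
                        tol = tol)
    list(rec = rec, label = classify_steady_state(rec, params))
  }
  scan <- lapply(c(0, amplitudes), run_amp)
  labels <- vapply(scan, `[[`, character(1), "label")
  desert <- labels %in% c("desert", "immune_desert", "unlabeled")
  scan_df <- data.frame(amplitude = c(0, amplitudes),
                        killer_T = vapply(scan, function(s)
                          s$rec$derived$killer_T_total, numeric(1)),
                        label = labels)
  if (all(desert)) return(list(threshold = Inf, scan = scan_df))
  first_esc <- which(!desert)[1]
  if (first_esc == 1) return(list(threshold = 0, scan = scan_df))
  lo <- scan_df$amplitude[first_esc - 1]
  hi <- scan_df$amplitude[first_esc]
  while ((hi - lo) / hi > 0.01) {
    mid <- sqrt(max(lo, hi * 1e-3) * hi)
    if (run_amp(mid)$label %in% c("desert", "immune_desert", "unlabeled")) {
      lo <- mid
    } else {
      hi <- mid
    }
  }
  list(threshold = hi, scan = scan_df)
}

#' OPN / LIF knockout scan
#'
#' For each OPN reduction fraction, with LIF intact and with LIF knocked
#' out, reports the steady-state CAF population, accessibility index, the
#' inaccessible-to-accessible tumor cell ratio, and the subtype label.
#' The threshold fraction (steepest drop of the inaccessible/accessible
#' ratio) is located per LIF arm.
#'
#' @param params registry of a fibro-dominated configuration.
#' @param opn_fractions OPN knockout fractions in `[0, 1]`.
#' @param network,t_max,tol as elsewhere.
#' @return list with `scan` (data frame) and `thresholds` (named by LIF
#'   arm).
#' @export
scenario_opn_lif_knockout <- function(params,
                                      opn_fractions = seq(0, 1, by = 0.25),
                                      network = build_hnscc_network(),
                                      t_max = 4000, tol = 1e-5) {
  stopifnot(all(opn_fractions >= 0 & opn_fractions <= 1))
  # knockouts act on the established TME: start every arm from the
  # untreated baseline steady state
  baseline <- steady_state(network, params, default_initial_state(params),
                           t_max = t_max, tol = tol)
  arms <- c(lif_present = FALSE, lif_knockout = TRUE)
  rows <- list()
  for (arm in names(arms)) {
    for (f in opn_fractions) {
      mod <- knockout(network, params, "OPN", "production_zero", f)
      if (arms[[arm]]) {
        mod <- knockout(mod$network, mod$params, "LIF", "production_zero", 1)
      }
      rec <- steady_state(mod$network, mod$params, baseline$state,
                          t_max = t_max, tol = tol)
      s <- rec$state
      acc <- s[["C0_E"]] + s[["Cneg_E"]] + s[["Cpos_E"]]
      inacc <- s[["C0_P"]] + s[["Cneg_P"]] + s[["Cpos_P"]]
      rows[[length(rows) + 1L]] <- data.frame(
        arm = arm, opn_fraction = f, CAF = rec$derived$CAF,
        Ia = rec$derived$Ia,
        inacc_acc_ratio = if (acc > 0) inacc / acc else NA_real_,
        label = classify_steady_state(rec, mod$params))
    }
  }
  scan <- do.call(rbind, rows)
  thresholds <- vapply(names(arms), function(arm) {
    g <- scan[scan$arm == arm, ]
    g <- g[order(g$opn_fraction), ]
    if (nrow(g) < 2 || all(!is.finite(g$inacc_acc_ratio))) return(NA_real_)
    grad <- diff(g$inacc_acc_ratio) / diff(g$opn_fraction)
    g$opn_fraction[which.min(grad) + 1L]
  }, numeric(1))
  list(scan = scan, thresholds = thresholds)
}

#' Biomarker readouts across subtypes
#'
#' Pre/post anti-PD1 IL-8 and lactate levels for representative parameter
#' sets of each subtype, with the sign of the post-pre change (a 0.05%
#' relative dead band maps numerically unchanged levels to 0). The
#' treatment continues
#' from the pre-therapy steady state without re-seeding killer T cells,
#' so an immune desert with no effective killer T cells shows no change.
#'
#' @param params_by_subtype named list of registries.
#' @param dose anti-PD1 dose.
#' @param network,t_max,tol as elsewhere.
#' @return data frame: subtype, pre/post IL-8 and lactate, sign of each
#'   change.
#' @export
scenario_biomarkers <- function(params_by_subtype, dose = 1,
                                network = build_hnscc_network(),
                                t_max = 4000, tol = 1e-5) {
  band_sign <- function(pre, post) {
    if (abs(post - pre) <= 5e-4 * max(pre, 1e-12)) 0L
    else as.integer(sign(post - pre))
  }
  rows <- lapply(names(params_by_subtype), function(lab) {
    p <- params_by_subtype[[lab]]
    res <- ici_response(network, p, dose, t_max = t_max, tol = tol)
    s0 <- res$pre$state; s1 <- res$post$state
    data.frame(subtype = lab,
               IL8_pre = s0[["IL8"]], IL8_post = s1[["IL8"]],
               IL8_sign = band_sign(s0[["IL8"]], s1[["IL8"]]),
               Lac_pre = s0[["Lac"]], Lac_post = s1[["Lac"]],
               Lac_sign = band_sign(s0[["Lac"]], s1[["Lac"]]))
  })
  do.call(rbind, rows)
}

#' Medoid representative parameter sets per subtype
#'
#' Recomputes the sampled parameter sets of a sweep and returns, per
#' subtype, the sample whose (log tumor, log killer T, log CAF) summary is
#' closest to the group median — the group medoid.
#'
#' @param sweep a `tme_sweep` from [run_sweep()].
#' @return named list of parameter vectors (labels with no converged
#'   member are dropped).
#' @export
representative_parameters <- function(sweep) {
  psets <- sample_parameters(sweep$design)
  s <- sweep$samples
  s <- s[s$converged & s$label %in% SUBTYPE_LABELS, ]
  out <- list()
  for (lab in unique(s$label)) {
    g <- s[s$label == lab, ]
    m <- log1p(as.matrix(g[, c("total_tumor", "killer_T", "CAF")]))
    med <- apply(m, 2, stats::median)
    d <- rowSums((m - matrix(med, nrow(m), 3, byrow = TRUE))^2)
    out[[lab]] <- psets[[g$sample[which.min(d)]]]
  }
  out
}
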