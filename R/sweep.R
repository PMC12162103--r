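#' Sweep design
#'
#' Defines which registry parameters to vary (multiplicative ranges on a
#' log10 scale around the base registry), how many Latin-hypercube samples
#' to draw, and the seed.
#'
#' @param varied named list: for each varied parameter a length-2 numeric
#'   `c(low, high)` of multiplicative factors (e.g. `c(0.1, 10)`).
#' @param n_samples number of samples.
#' @param seed integer seed.
#' @param base base registry (default [nominal_parameters()]); parameters
#'   not varied are copied from it.
#' @return object of class `tme_sweep_design`.
#' @export
sweep_design <- function(varied = default_sweep_varied(), n_samples = 1000,
                         seed = 1, base = nominal_parameters()) {
  if (!length(varied)) stop("design error: empty varied parameter list")
  if (is.null(names(varied)) || !all(names(varied) %in% names(base))) {
    stop("design error: varied parameters must name registry entries")
  }
  if (any(vapply(varied, function(r) any(r <= 0) || length(r) != 2,
                 logical(1)))) {
    stop("design error: ranges must be positive length-2 vectors")
  }
  structure(list(varied = varied, n_samples = as.integer(n_samples),
                 seed = as.integer(seed), base = base),
            class = "tme_sweep_design")
}

#' Default varied-parameter set
#'
#' The 28 parameters with a direct bearing on the proliferation, death and
#' conversion fluxes of the tumor cells, killer T cells and CAF, plus the
#' accessibility hyperparameters; the remaining 63 registry entries stay at
#' their nominal values. Ranges are 0.1x-10x on a log scale, except the
#' CAF proximity fraction `alpha_acc`, which is capped so it stays in
#' `[0, 1]`.
#'
#' @return named list of multiplicative ranges.
#' @export
default_sweep_varied <- function() {
  nms <- c(
    "Kprol_C0", "Kprol_Cneg", "Kprol_Cpos", "KD_C0", "KD_Cneg", "KD_Cpos",
    "Kconv_C0_Cneg", "Kconv_Cneg_Cpos", "Kpara_CAF_tumor",
    "Kpara_TEx_tumor", "Kkill_C0", "Kkill_Cneg",
    "Kprol_TKp", "Kprol_TKn", "KD_TKp", "KD_TKn", "Kconv_TKp_TEx",
    "Kpara_THelp_TK", "Kpara_IL2_TK", "Kpara_IFNG_T",
    "Kprol_CAF", "KD_CAF", "Kconv_FWT_CAF", "Kpara_OPN_CAF", "Ksec_LIF",
    "alpha_acc", "Kbr", "delta_br"
  )
  v <- stats::setNames(rep(list(c(0.1, 10)), length(nms)), nms)
  v$alpha_acc <- c(0.1, 2) # nominal 0.5: keeps the fraction within [0, 1]
  v
}

#' Sample parameter sets from a sweep design
#'
#' Latin-hypercube samples on the log10 scale of the multiplicative
#' ranges, deterministic under the design seed.
#'
#' @param design a [sweep_design()].
#' @return list of `n_samples` named parameter vectors.
#' @export
sample_parameters <- function(design) {
  stopifnot(inherits(design, "tme_sweep_design"))
  k <- length(design$varied)
  set.seed(design$seed)
  u <- lhs::randomLHS(design$n_samples, k)
  lo <- log10(vapply(design$varied, `[`, numeric(1), 1))
  hi <- log10(vapply(design$varied, `[`, numeric(1), 2))
  nms <- names(design$varied)
  lapply(seq_len(design$n_samples), function(i) {
    p <- design$base
    fac <- 10^(lo + u[i, ] * (hi - lo))
    p[nms] <- p[nms] * fac
    p
  })
}

#' Proliferation-to-death balance metric
#'
#' For a cell state `x`, the maximum proliferation factor is
#' `Fmax = Kprol * prod_j (1 + Kpara_j)` over the incoming paracrine edges
#' of `x`; the balance is `zeta = log(Fmax / (sum Kkill + sum Kconv +
#' KD))` (natural log), the log ratio of the strongest possible growth to
#' the total kill, conversion and death rates. For the tumor as a whole
#' use [zeta_total_tumor()], the maximum over the tumor cell states.
#'
#' @param cell a cell-state node name.
#' @param network a [network_spec()].
#' @param params parameter registry.
#' @return dimensionless balance (natural log scale); `+Inf` with a
#'   warning when the cell has no kill, conversion or death rate.
#' @export
zeta <- function(cell, network, params) {
  if (!cell %in% network$nodes$name[network$nodes$role == "cell_state"]) {
    stop(sprintf("'%s' is not a cell-state node", cell))
  }
  fmax <- 0
  denom <- 0
  for (e in network$edges) {
    if (e$kind == "proliferation" && e$target == cell) {
      fmax <- unname(params[e$params[["Kprol"]]])
    }
  }
  for (e in network$edges) {
    if (e$kind == "paracrine" && e$target == cell) {
      fmax <- fmax * (1 + unname(params[e$params[["Kpara"]]]))
    } else if (e$kind == "elimination" && e$target == cell) {
      denom <- denom + unname(params[e$params[["Kkill"]]])
    } else if (e$kind == "conversion" && e$source == cell) {
      denom <- denom + prod(unname(params[e$params]))
    } else if (e$kind %in% c("death", "degradation") && e$target == cell) {
      denom <- denom + unname(params[e$params[["KD"]]])
    }
  }
  if (denom == 0) {
    warning(sprintf("zeta(%s): zero kill + conversion + death rate", cell))
    return(Inf)
  }
  log(fmax / denom)
}

#' @rdname zeta
#' @export
zeta_total_tumor <- function(network, params) {
  max(vapply(intersect(HNSCC_TUMOR, network$nodes$name), zeta,
             numeric(1), network = network, params = params))
}

SUBTYPE_LABELS <- c("desert", "immune_desert", "fibro_desert",
                    "immune_dominated", "fibro_dominated")

#' Classify a steady state into a TME subtype
#'
#' Rule-based five-way classification on the converged populations:
#' with killer-T below `eps_T` the state is a `desert` (CAF also low) or
#' `immune_desert` (CAF present; the "fibrotic only" subtype); with
#' killer-T present it is a `fibro_desert` (CAF low; the
#' "immune/non-fibrotic" subtype) or, with both present,
#' `fibro_dominated` when CAF outweighs the killer-T population and the
#' tumor burden is high, else `immune_dominated`. Thresholds default to 2%
#' of the respective carrying capacities.
#'
#' @param record a `tme_steady` (or any list with `converged` and
#'   `derived`).
#' @param params registry (used for default thresholds).
#' @param thresholds optional list `eps_T`, `eps_F`, `eps_C` overriding the
#'   defaults.
#' @return one of the five subtype labels, or `"unlabeled"` for a
#'   non-converged record.
#' @export
classify_steady_state <- function(record, params, thresholds = NULL) {
  th <- default_thresholds(params)
  th[names(thresholds)] <- thresholds
  if (!isTRUE(record$converged)) return("unlabeled")
  d <- record$derived
  tk <- d$killer_T_total; caf <- d$CAF; tumor <- d$total_tumor
  if (tk < th$eps_T) {
    if (caf < th$eps_F) "desert" else "immune_desert"
  } else if (caf < th$eps_F) {
    "fibro_desert"
  } else if (caf >= tk && tumor >= th$eps_C) {
    "fibro_dominated"
  } else {
    "immune_dominated"
  }
}

default_thresholds <- function(params) {
  list(eps_T = 0.02 * params[["xmax_TK"]],
       eps_F = 0.02 * params[["xmax_F"]],
       eps_C = 0.02 * params[["xmax_tumor"]])
}

#' Run a classification sweep
#'
#' For every sampled parameter set: integrate to steady state, derive
#' summaries, classify, and compute the zeta balances of the tumor, killer
#' T and CAF states. Aggregates group counts and group medians / quartiles
#' of the tumor, killer T and CAF populations. Fully reproducible under
#' the design seed.
#'
#' @param design a [sweep_design()].
#' @param network network to sweep (default the HNSCC atlas).
#' @param thresholds optional classifier thresholds.
#' @param t_max,tol steady-state controls (see [steady_state()]).
#' @param progress print a dot every 100 samples.
#' @return object of class `tme_sweep`: list with `samples` (one row per
#'   sample), `groups` (per-label counts, medians, quartiles),
#'   `n_converged`, and the design.
#' @export
run_sweep <- function(design, network = build_hnscc_network(),
                      thresholds = NULL, t_max = 1500, tol = 1e-6,
                      progress = FALSE) {
  psets <- sample_parameters(design)
  rows <- vector("list", length(psets))
  for (i in seq_along(psets)) {
    p <- psets[[i]]
    rec <- steady_state(network, p, default_initial_state(p),
                        t_max = t_max, tol = tol)
    lab <- classify_steady_state(rec, p, thresholds)
    d <- rec$derived
    rows[[i]] <- data.frame(
      sample = i, converged = rec$converged,
      total_tumor = d$total_tumor, killer_T = d$killer_T_total,
      CAF = d$CAF, Ia = d$Ia,
      pdl1_ratio = ifelse(d$pdl1_defined, d$pdl1_ratio, NA_real_),
      label = lab,
      zeta_tumor = zeta_total_tumor(network, p),
      zeta_TK = zeta("TKp", network, p),
      zeta_CAF = zeta("CAF", network, p))
    if (progress && i %% 100 == 0) cat(".")
  }
  if (progress) cat("\n")
  samples <- do.call(rbind, rows)
  conv <- samples[samples$converged & samples$label != "unlabeled", ]
  q <- function(v) stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
  groups <- do.call(rbind, lapply(SUBTYPE_LABELS, function(lab) {
    g <- conv[conv$label == lab, ]
    if (!nrow(g)) {
      data.frame(label = lab, n = 0L, tumor_q25 = NA, tumor_med = NA,
                 tumor_q75 = NA, killer_q25 = NA, killer_med = NA,
                 killer_q75 = NA, caf_q25 = NA, caf_med = NA, caf_q75 = NA)
    } else {
      qt <- q(g$total_tumor); qk <- q(g$killer_T); qc <- q(g$CAF)
      data.frame(label = lab, n = nrow(g), tumor_q25 = qt[1],
                 tumor_med = qt[2], tumor_q75 = qt[3], killer_q25 = qk[1],
                 killer_med = qk[2], killer_q75 = qk[3], caf_q25 = qc[1],
                 caf_med = qc[2], caf_q75 = qc[3])
    }
  }))
  structure(list(samples = samples, groups = groups,
                 n_converged = sum(samples$converged), design = design),
            class = "tme_sweep")
}

#' @export
print.tme_sweep <- function(x, ...) {
  cat(sprintf("tme_sweep: %d samples (%d converged)\n",
              nrow(x$samples), x$n_converged))
  print(x$groups[, c("label", "n", "tumor_med", "killer_med", "caf_med")],
        row.names = FALSE)
  invisible(x)
}

#' Local one-at-a-time sensitivity analysis
#'
#' Central-difference elasticities `d log(summary) / d log(parameter)` of
#' steady-state summaries with respect to fractional parameter
#' perturbations. When a baseline summary is zero the elasticity is
#' undefined and the signed absolute change is reported instead (flagged).
#'
#' @param network a [network_spec()].
#' @param params parameter registry.
#' @param parameters character vector of registry names to perturb.
#' @param targets summaries to track: derived-summary names
#'   (`"total_tumor"`, `"killer_T_total"`, `"CAF"`) or plain node names.
#' @param perturbation fractional perturbation (default 0.05).
#' @param x0,t_max,tol steady-state controls.
#' @return data frame with columns `parameter`, `target`, `value`
#'   (elasticity, or absolute change when flagged), `flagged`.
#' @export
local_sensitivity <- function(network, params,
                              parameters,
                              targets = c("total_tumor", "killer_T_total",
                                          "CAF"),
                              perturbation = 0.05,
                              x0 = default_initial_state(params),
                              t_max = 1500, tol = 1e-6) {
  if (perturbation <= 0) stop("perturbation must be > 0")
  extract <- function(rec, target) {
    if (target %in% names(rec$state)) rec$state[[target]]
    else rec$derived[[target]]
  }
  run <- function(p) steady_state(network, p, x0, t_max = t_max, tol = tol)
  base <- run(params)
  out <- list()
  for (pn in parameters) {
    up <- params; up[[pn]] <- params[[pn]] * (1 + perturbation)
    dn <- params; dn[[pn]] <- params[[pn]] * (1 - perturbation)
    ru <- run(up); rd <- run(dn)
    for (tg in targets) {
      s0 <- extract(base, tg); su <- extract(ru, tg); sd <- extract(rd, tg)
      if (s0 > 0 && su > 0 && sd > 0) {
        val <- (log(su) - log(sd)) / (log(1 + perturbation) -
                                        log(1 - perturbation))
        flag <- FALSE
      } else {
        val <- su - sd
        flag <- TRUE
      }
      out[[length(out) + 1L]] <- data.frame(parameter = pn, target = tg,
                                            value = val, flagged = flag)
    }
  }
  do.call(rbind, out)
}
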