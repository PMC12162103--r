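#' Assemble the time-derivative function of a flux network
#'
#' Compiles a [network_spec()] plus parameter registry into the
#' right-hand-side function of the ODE system. For each cell state the
#' derivative is
#'
#' proliferation flux (logistic over its capacity pool) x product of its
#' paracrine multipliers x product of its regulatory factors
#' + incoming conversion fluxes - outgoing conversion fluxes
#' - elimination fluxes - death flux,
#'
#' and for each molecular species it is the sum of first-order secretion
#' fluxes from the secreting cell states (optionally gated by a regulatory
#' factor) minus first-order degradation.
#'
#' When the network defines an accessibility block, the immune
#' accessibility index `Ia = 1 - tanh(alpha * CAF * Kbr)` is recomputed at
#' every evaluation from the instantaneous CAF population: it sets the
#' equilibrium of the conserving exposed/protected migration (the exposed
#' share of each tumor cell state relaxes to `Ia / (1 + Ia)`, the
#' accessibility partition of the shared capacity), and the barrier factor
#' `exp(-alpha^2 * delta * CAF^2)` attenuates the mirror of every
#' elimination flux onto the protected twin of its exposed target.
#'
#' @param network a [network_spec()].
#' @param params named numeric parameter vector; every key an edge consumes
#'   must resolve (see [validate_parameters()]).
#' @param freeze_Ia optional constant in `(0, 1]`: hold the accessibility
#'   index at this value instead of recomputing it from CAF (the barrier
#'   penetration factor is then also frozen at the consistent CAF level
#'   implied by the index).
#' @return a function `f(state, t = 0)` returning the named vector of time
#'   derivatives; evaluation at an all-zero state returns the zero vector
#'   (the model has no constant source terms).
#' @export
assemble_rhs <- function(network, params, freeze_Ia = NULL) {
  validate_parameters(network, params)
  nm <- network$nodes$name
  n <- length(nm)
  id <- function(x) {
    i <- match(x, nm)
    if (anyNA(i)) stop(sprintf("unknown node '%s'", x[is.na(i)][1]))
    i
  }
  pv <- function(key) unname(params[key])

  # accessibility block
  has_acc <- !is.null(network$accessibility)
  if (has_acc) {
    acc <- network$accessibility
    acc_alpha <- pv(acc$alpha); acc_Kbr <- pv(acc$Kbr)
    acc_delta <- pv(acc$delta); caf_idx <- id(acc$caf)
    mig_rate <- if (!is.null(acc$mig_key)) pv(acc$mig_key) else 0
  }
  if (!is.null(freeze_Ia)) {
    if (!has_acc) stop("freeze_Ia requires an accessibility block")
    if (freeze_Ia <= 0 || freeze_Ia > 1) stop("freeze_Ia must lie in (0, 1]")
    # CAF level consistent with the frozen index, for the barrier factor
    caf_frozen <- if (acc_alpha * acc_Kbr > 0) {
      atanh(1 - freeze_Ia) / (acc_alpha * acc_Kbr)
    } else 0
    pen_frozen <- exp(-acc_alpha^2 * acc_delta * caf_frozen^2)
  }

  # capacity pools (members compete for one fixed resource capacity)
  pools <- network$pools %||% list()
  pool_members <- lapply(pools, function(p) id(p$members))
  pool_cap <- vapply(pools, function(p) pv(p$cap_key), numeric(1))
  pool_of <- rep(NA_integer_, n)
  for (k in seq_along(pools)) pool_of[pool_members[[k]]] <- k

  by_kind <- split(network$edges,
                   vapply(network$edges, `[[`, character(1), "kind"))

  # proliferation
  pr <- by_kind$proliferation %||% list()
  pr_t <- vapply(pr, function(e) id(e$target), integer(1))
  pr_K <- vapply(pr, function(e) pv(e$params[["Kprol"]]), numeric(1))
  if (anyNA(pool_of[pr_t])) {
    stop(sprintf("proliferating node '%s' belongs to no capacity pool",
                 nm[pr_t[is.na(pool_of[pr_t])][1]]))
  }
  pr_pool <- pool_of[pr_t]

  # paracrine multipliers on the target's proliferation flux
  pa <- by_kind$paracrine %||% list()
  pa_t <- vapply(pa, function(e) id(e$target), integer(1))
  pa_s <- vapply(pa, function(e) id(e$source), integer(1))
  pa_K <- vapply(pa, function(e) pv(e$params[["Kpara"]]), numeric(1))
  pa_V <- vapply(pa, function(e) pv(e$params[["V"]]), numeric(1))
  pa_a <- vapply(pa, function(e) {
    if ("alpha" %in% names(e$params)) pv(e$params[["alpha"]]) else 1
  }, numeric(1))

  # regulatory factors, split by site
  rg <- by_kind$regulatory_inhibition %||% list()
  rg_site <- vapply(rg, `[[`, character(1), "site")
  rg_t <- vapply(rg, function(e) id(e$target), integer(1))
  rg_s <- vapply(rg, function(e) id(e$source), integer(1))
  rg_V <- vapply(rg, function(e) pv(e$params[["Vreg"]]), numeric(1))
  rg_a <- vapply(rg, function(e) pv(e$params[["alpha"]]), numeric(1))

  # conversions (rate = product of the edge's rate keys, times gates)
  cv <- by_kind$conversion %||% list()
  cv_s <- vapply(cv, function(e) id(e$source), integer(1))
  cv_t <- vapply(cv, function(e) id(e$target), integer(1))
  cv_r <- vapply(cv, function(e) prod(pv(e$params)), numeric(1))
  cv_g <- lapply(cv, function(e) {
    if (is.null(e$gates)) NULL
    else list(i = id(vapply(e$gates, `[[`, character(1), "species")),
              V = vapply(e$gates, function(g) pv(g$V), numeric(1)))
  })

  # eliminations, with protected-compartment mirrors
  el <- by_kind$elimination %||% list()
  pmap <- network$protected_map
  el_t <- integer(0); el_s <- integer(0)
  el_K <- numeric(0); el_aac <- numeric(0); el_pen <- logical(0)
  for (e in el) {
    K <- pv(e$params[["Kkill"]])
    aac <- if ("alpha_ac" %in% names(e$params)) pv(e$params[["alpha_ac"]]) else 1
    el_t <- c(el_t, id(e$target)); el_s <- c(el_s, id(e$source))
    el_K <- c(el_K, K); el_aac <- c(el_aac, aac); el_pen <- c(el_pen, FALSE)
    if (!is.null(pmap) && e$target %in% names(pmap)) {
      el_t <- c(el_t, id(pmap[[e$target]])); el_s <- c(el_s, id(e$source))
      el_K <- c(el_K, K); el_aac <- c(el_aac, aac); el_pen <- c(el_pen, TRUE)
    }
  }

  # secretions, aggregated through a dense incidence matrix
  se <- by_kind$secretion %||% list()
  se_s <- vapply(se, function(e) id(e$source), integer(1))
  se_t <- vapply(se, function(e) id(e$target), integer(1))
  se_K <- vapply(se, function(e) pv(e$params[["Ksec"]]), numeric(1))
  A_sec <- matrix(0, n, length(se))
  for (j in seq_along(se)) A_sec[se_t[j], j] <- 1

  # death / degradation
  de <- c(by_kind$death %||% list(), by_kind$degradation %||% list())
  de_t <- vapply(de, function(e) id(e$target), integer(1))
  de_K <- vapply(de, function(e) pv(e$params[["KD"]]), numeric(1))

  # migration pairs (exposed <-> protected)
  has_mig <- has_acc && !is.null(pmap) && mig_rate > 0
  if (has_mig) {
    mg_e <- id(names(pmap)); mg_p <- id(unname(pmap))
  }

  n_pool <- length(pools)
  n_pa <- length(pa); n_rg <- length(rg); n_cv <- length(cv)
  n_el <- length(el_t); n_se <- length(se)

  function(state, t = 0) {
    y <- pmax(as.numeric(state), 0)
    dx <- numeric(n)

    if (has_acc) {
      caf <- y[caf_idx]
      if (is.null(freeze_Ia)) {
        Ia <- 1 - tanh(acc_alpha * caf * acc_Kbr)
        pen <- exp(-acc_alpha^2 * acc_delta * caf^2)
      } else {
        Ia <- freeze_Ia
        pen <- pen_frozen
      }
    } else {
      Ia <- 1; pen <- 1
    }

    # regulatory factors per node and site
    regp <- rep.int(1, n); regs <- rep.int(1, n); regk <- rep.int(1, n)
    if (n_rg) {
      for (j in seq_len(n_rg)) {
        fac <- 1 / (rg_V[j] + rg_a[j] * y[rg_s[j]])
        tg <- rg_t[j]
        if (rg_site[j] == "proliferation") regp[tg] <- regp[tg] * fac
        else if (rg_site[j] == "secretion") regs[tg] <- regs[tg] * fac
        else regk[tg] <- regk[tg] * fac
      }
    }

    # paracrine multipliers
    mult <- rep.int(1, n)
    if (n_pa) {
      for (j in seq_len(n_pa)) {
        xi <- y[pa_s[j]]
        tg <- pa_t[j]
        mult[tg] <- mult[tg] * (1 + pa_K[j] * pa_a[j] * xi / (pa_V[j] + xi))
      }
    }

    # capacity pools
    if (n_pool) {
      psum <- numeric(n_pool)
      for (k in seq_len(n_pool)) psum[k] <- sum(y[pool_members[[k]]])
      if (length(pr_t)) {
        prol <- pr_K * y[pr_t] * (1 - psum[pr_pool] / pool_cap[pr_pool]) *
          mult[pr_t] * regp[pr_t]
        dx[pr_t] <- dx[pr_t] + prol
      }
    }

    # conversions
    if (n_cv) {
      for (j in seq_len(n_cv)) {
        r <- cv_r[j]
        g <- cv_g[[j]]
        if (!is.null(g)) {
          xg <- y[g$i]
          r <- r * prod(xg / (g$V + xg))
        }
        fl <- r * y[cv_s[j]]
        dx[cv_s[j]] <- dx[cv_s[j]] - fl
        dx[cv_t[j]] <- dx[cv_t[j]] + fl
      }
    }

    # eliminations (protected mirrors attenuated by the barrier factor)
    if (n_el) {
      for (j in seq_len(n_el)) {
        fl <- el_K[j] * el_aac[j] * y[el_t[j]] * y[el_s[j]] * regk[el_s[j]]
        if (el_pen[j]) fl <- fl * pen
        dx[el_t[j]] <- dx[el_t[j]] - fl
      }
    }

    # secretions
    if (n_se) {
      dx <- dx + as.numeric(A_sec %*% (se_K * y[se_s] * regs[se_t]))
    }

    # death / degradation
    if (length(de_t)) dx[de_t] <- dx[de_t] - de_K * y[de_t]

    # exposed <-> protected migration toward the accessibility partition
    if (has_mig) {
      fl <- mig_rate * (y[mg_e] / (1 + Ia) - y[mg_p] * Ia / (1 + Ia))
      dx[mg_e] <- dx[mg_e] - fl
      dx[mg_p] <- dx[mg_p] + fl
    }

    names(dx) <- nm
    dx
  }
}
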