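#' Integrate the model
#'
#' Runs a stiff-capable variable-step solver (deSolve) on the assembled
#' system. States are kept nonnegative: entries more negative than
#' `-tol_neg` raise an error, entries in `[-tol_neg, 0)` are clipped to
#' zero (stiff solvers may overshoot slightly near the origin).
#'
#' @param network a [network_spec()].
#' @param params parameter registry.
#' @param x0 nonnegative initial state (named, in network node order).
#' @param t_end end time in days, `> 0`.
#' @param times optional output time grid (default 201 points).
#' @param method deSolve method, default `"lsoda"` (`"bdf"` and `"radau"`
#'   are useful cross-checks).
#' @param rtol,atol relative / absolute solver tolerances.
#' @param tol_neg negative-overshoot clipping threshold.
#' @param freeze_Ia passed to [assemble_rhs()].
#' @return object of class `tme_trajectory`: list with `times`, `states`
#'   (matrix, one row per time), and `metadata`.
#' @export
integrate_tme <- function(network, params, x0, t_end, times = NULL,
                          method = "lsoda", rtol = 1e-6, atol = 1e-9,
                          tol_neg = 1e-6, freeze_Ia = NULL) {
  if (t_end <= 0) stop("t_end must be > 0")
  if (any(x0 < 0)) stop("initial state must be nonnegative")
  nm <- network$nodes$name
  if (!is.null(names(x0))) x0 <- x0[nm]
  if (length(x0) != length(nm)) stop("x0 length must match the node count")
  rhs <- assemble_rhs(network, params, freeze_Ia = freeze_Ia)
  f_desolve <- function(t, y, p) list(rhs(y, t))
  if (is.null(times)) times <- seq(0, t_end, length.out = 201)
  out <- deSolve::ode(y = stats::setNames(as.numeric(x0), nm),
                      times = times, func = f_desolve, parms = NULL,
                      method = method, rtol = rtol, atol = atol)
  if (attr(out, "istate")[1] < 0) {
    diag <- attr(out, "istate")
    stop(sprintf("integration failure (istate = %d); stiffest component near t = %g",
                 diag[1], max(out[, "time"])))
  }
  states <- unname(out[, -1, drop = FALSE])
  colnames(states) <- nm
  if (any(states < -tol_neg)) {
    stop(sprintf("state went below -tol_neg (min = %g)", min(states)))
  }
  states[states < 0] <- 0
  structure(list(times = out[, "time"], states = states,
                 metadata = list(method = method, rtol = rtol, atol = atol,
                                 freeze_Ia = freeze_Ia)),
            class = "tme_trajectory")
}

#' @export
print.tme_trajectory <- function(x, ...) {
  cat(sprintf("tme_trajectory: %d states over t = [%g, %g] days (%d samples)\n",
              ncol(x$states), min(x$times), max(x$times), length(x$times)))
  invisible(x)
}

#' Tidy long-format view of a trajectory
#'
#' @param x a `tme_trajectory`.
#' @param row.names,optional,... standard [as.data.frame()] arguments
#'   (unused).
#' @return data frame with columns `time`, `node`, `value`.
#' @export
as.data.frame.tme_trajectory <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  nm <- colnames(x$states)
  data.frame(time = rep(x$times, times = length(nm)),
             node = rep(nm, each = length(x$times)),
             value = as.vector(x$states))
}

#' Integrate to steady state
#'
#' Integrates in windows until the scaled residual
#' `max_i |dx_i/dt| / (1 + |x_i|)` drops below `tol` (per day) or `t_max`
#' is reached. Oscillatory or slow non-convergence yields a record with
#' `converged = FALSE`, never an error.
#'
#' @inheritParams integrate_tme
#' @param t_max maximum integration horizon (days).
#' @param tol steady-state residual tolerance (per day).
#' @param window window length (days) between convergence checks.
#' @return object of class `tme_steady`: list with `state`, `converged`,
#'   `residual`, `t_final`, and `derived` summaries (see
#'   [derived_summaries()]).
#' @export
steady_state <- function(network, params, x0 = default_initial_state(params),
                         t_max = 2000, tol = 1e-6, window = 100,
                         method = "lsoda", rtol = 1e-6, atol = 1e-9,
                         freeze_Ia = NULL) {
  nm <- network$nodes$name
  if (!is.null(names(x0))) x0 <- x0[nm]
  rhs <- assemble_rhs(network, params, freeze_Ia = freeze_Ia)
  f_desolve <- function(t, y, p) list(rhs(y, t))
  y <- stats::setNames(as.numeric(x0), nm)
  t_now <- 0
  residual <- Inf
  converged <- FALSE
  while (t_now < t_max) {
    t_next <- min(t_now + window, t_max)
    out <- try(deSolve::ode(y = y, times = c(t_now, t_next),
                            func = f_desolve, parms = NULL, method = method,
                            rtol = rtol, atol = atol), silent = TRUE)
    if (inherits(out, "try-error") || attr(out, "istate")[1] < 0) break
    y <- out[nrow(out), -1]
    y[y < 0] <- 0
    t_now <- t_next
    dy <- rhs(y, t_now)
    residual <- max(abs(dy) / (1 + abs(y)))
    if (residual < tol) {
      converged <- TRUE
      break
    }
  }
  y <- stats::setNames(as.numeric(y), nm)
  hnscc_like <- all(c(HNSCC_TUMOR, "TKp", "TKn", "CAF") %in% nm) &&
    all(c("alpha_acc", "Kbr") %in% names(params))
  structure(list(state = y, converged = converged, residual = residual,
                 t_final = t_now,
                 derived = if (hnscc_like) derived_summaries(y, params)),
            class = "tme_steady")
}

#' @export
print.tme_steady <- function(x, ...) {
  cat(sprintf("tme_steady: converged = %s (residual %.3g at t = %g d)\n",
              x$converged, x$residual, x$t_final))
  if (!is.null(x$derived)) {
    cat(sprintf("  tumor %.1f | killer T %.1f | CAF %.1f | Ia %.3f\n",
                x$derived$total_tumor, x$derived$killer_T_total,
                x$derived$CAF, x$derived$Ia))
  }
  invisible(x)
}

#' Derived summaries of a system state
#'
#' Totals used throughout the subtype analyses: total tumor burden (all
#' six tumor compartments), total killer T cells (PD1+ plus PD1-), CAF
#' population, the PDL1-/PDL1+ tumor ratio (a subtype biomarker; flagged
#' undefined when no PDL1+ cells are present), and the accessibility index
#' implied by the current CAF population.
#'
#' @param state named 24-vector (HNSCC node order).
#' @param params parameter registry (accessibility hyperparameters).
#' @return list with `total_tumor`, `killer_T_total`, `CAF`, `pdl1_ratio`,
#'   `pdl1_defined`, `Ia`.
#' @export
derived_summaries <- function(state, params) {
  s <- state
  cneg <- s[["Cneg_E"]] + s[["Cneg_P"]]
  cpos <- s[["Cpos_E"]] + s[["Cpos_P"]]
  list(
    total_tumor = sum(s[HNSCC_TUMOR]),
    killer_T_total = s[["TKp"]] + s[["TKn"]],
    CAF = s[["CAF"]],
    pdl1_ratio = if (cpos > 0) cneg / cpos else NA_real_,
    pdl1_defined = cpos > 0,
    Ia = accessibility_index(params[["alpha_acc"]], params[["Kbr"]],
                             s[["CAF"]])
  )
}
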