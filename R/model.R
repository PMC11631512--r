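# The 18-equation non-dimensional ODE system: endothelial cells, VEGF and
# oxygen coupled to the immune/cancer/adipocyte/cytokine network through two
# Hill-type hypoxia switches.

.tme_state_names <- c("EN", "V", "Ox", "TN", "Th", "Tc", "Tr", "DN", "D",
                      "MN", "M", "C", "N", "A", "H", "IL12", "IL10", "IL6")

# model cell variables (the 12 counted types) and the 8 immune ones
.tme_cell_names <- c("EN", "TN", "Th", "Tc", "Tr", "DN", "D", "MN", "M",
                     "C", "N", "A")
.tme_immune_names <- c("TN", "Th", "Tc", "Tr", "DN", "D", "MN", "M")

#' Names of the model state variables
#'
#' The 18 non-dimensional state variables in canonical order: endothelial
#' cells, VEGF, oxygen, naive/helper/cytotoxic/regulatory T cells,
#' naive/activated dendritic cells, naive/activated macrophages, cancer,
#' necrotic cells, adipocytes, HMGB1, IL-12, IL-10 and IL-6.
#'
#' @return Character vector of length 18.
#' @export
tme_state_names <- function() .tme_state_names

#' Decreasing Hill switch for hypoxia
#'
#' `hill_hypoxia(x, ox_crit, m)` returns
#' `ox_crit^m / (ox_crit^m + x^m)`: 1 at zero oxygen, 1/2 at the critical
#' threshold, and strictly decreasing in `x`. The model evaluates it at two
#' thresholds: the mild-hypoxia switch (HIF activation) and the severe-hypoxia
#' switch (cell-cycle arrest/death).
#'
#' @param x non-dimensional oxygen level(s), >= 0.
#' @param ox_crit critical oxygen threshold (> 0).
#' @param m Hill-like exponent (> 0).
#' @return Value(s) in (0, 1].
#' @export
#' @examples
#' hill_hypoxia(0, 0.02, 3)        # 1
#' hill_hypoxia(0.02, 0.02, 7)     # 0.5
hill_hypoxia <- function(x, ox_crit, m) {
  if (!is.numeric(ox_crit) || length(ox_crit) != 1L || !is.finite(ox_crit) ||
      ox_crit <= 0)
    stop("ox_crit must be a positive scalar")
  if (!is.numeric(m) || length(m) != 1L || !is.finite(m) || m <= 0)
    stop("Hill exponent m must be a positive scalar")
  if (any(x < 0)) stop("oxygen level must be non-negative")
  ox_crit^m / (ox_crit^m + x^m)
}

#' Right-hand side of the model ODE system
#'
#' Evaluates the time derivative of every state variable at a given state.
#' Mass-action production and inhibition terms, logistic growth with carrying
#' capacities for endothelial cells (VEGF-catalysed), cancer and adipocytes,
#' and hypoxia terms through the mild (`f1`) and severe (`f2`) Hill switches.
#' Differentiation fluxes balance exactly: the activation outflux from naive T
#' cells equals the summed influx into helper, cytotoxic and regulatory T
#' cells, and likewise for the dendritic-cell and macrophage pairs.
#'
#' @param t time in days (unused; the system is autonomous).
#' @param state named or unnamed numeric vector of the 18 state variables in
#'   canonical order (see [tme_state_names()]).
#' @param params a [tme_params()] vector.
#' @param hyp a [hypoxia_params()] object.
#' @return Numeric vector of 18 derivatives, named.
#' @export
tme_rhs <- function(t, state, params, hyp = hypoxia_params()) {
  if (length(state) != 18L)
    stop("state must have exactly 18 components")
  validate_tme_params(params)
  stopifnot(inherits(hyp, "tme_hypoxia"))
  s <- setNames(as.numeric(state), .tme_state_names)
  p <- as.list(unclass(params))
  f1 <- hill_hypoxia(s[["Ox"]], hyp$ox_crit1, hyp$m)
  f2 <- hill_hypoxia(s[["Ox"]], hyp$ox_crit2, hyp$m)
  with(c(p, as.list(s)), {
    act_Th <- lambda_ThH * H + lambda_ThD * D + lambda_ThIL12 * IL12
    act_Tc <- lambda_TcD * D + lambda_TcIL12 * IL12
    act_Tr <- lambda_TrD * D + lambda_TrOx * f1
    act_D  <- lambda_DC * C + lambda_DH * H + lambda_DOx * f1
    act_M  <- lambda_MIL10 * IL10 + lambda_MIL12 * IL12 + lambda_MTh * Th
    kill_C <- delta_CTc * Tc + delta_CTcOx * f1 * Tc + delta_COx * f2 +
      delta_C

    d <- c(
      EN = lambda_VEN * V * (1 - EN / EN0) * EN - delta_ENIL12 * IL12 * EN -
        (delta_EN + delta_ENOx * f2) * EN,
      V = lambda_VA * A + lambda_VM * M + lambda_VCOx * C * f1 +
        lambda_VOx * f1 - delta_V * V,
      Ox = lambda_OxEN * EN - delta_1 * (TN + Th + Tc + Tr) * Ox -
        delta_2 * (DN + D) * Ox - delta_3 * (MN + M) * Ox -
        delta_4 * C * Ox - delta_5 * A * Ox - delta_6 * EN * Ox -
        delta_Ox * Ox,
      TN = A_TN - (act_Th + act_Tc + act_Tr) * TN -
        (delta_TN + delta_TNOx * f2) * TN,
      Th = act_Th * TN - (delta_ThTr * Tr + delta_ThIL10 * IL10) * Th -
        (delta_Th + delta_ThOx * f2) * Th,
      Tc = act_Tc * TN - (delta_TcTr * Tr + delta_TcIL10 * IL10) * Tc -
        (delta_Tc + delta_TcOx * f2) * Tc,
      Tr = act_Tr * TN - (delta_Tr + delta_TrOx * f2) * Tr,
      DN = A_DN - act_D * DN - (delta_DN + delta_DNOx * f2) * DN,
      D = act_D * DN - (delta_DC * C + delta_D + delta_DNOx * f2) * D,
      MN = A_MN - (act_M + delta_MN) * MN,
      M = act_M * MN - delta_M * M,
      C = (lambda_C + lambda_CIL6 * IL6 + lambda_CA * A) * (1 - C / C0) * C -
        kill_C * C,
      N = alpha_NC * kill_C * C - delta_N * N,
      A = lambda_A * (1 - A / A0) * A - delta_A * A,
      H = lambda_HD * D + lambda_HN * N + lambda_HM * M + lambda_HTc * Tc +
        lambda_HC * C - delta_H * H,
      IL12 = lambda_IL12M * M + lambda_IL12D * D - delta_IL12 * IL12,
      IL10 = lambda_IL10M * M + lambda_IL10D * D + lambda_IL10Tr * Tr +
        lambda_IL10Th * Th + lambda_IL10Tc * Tc + lambda_IL10C * C +
        lambda_IL10Ox * f1 - delta_IL10 * IL10,
      IL6 = lambda_IL6A * A + lambda_IL6M * M + lambda_IL6MOx * M * f1 +
        lambda_IL6D * D + lambda_IL6Ox * f1 - delta_IL6 * IL6
    )
    d
  })
}

# deSolve-conformant wrapper around the R right-hand side; `parms` is the
# extended 91-vector so the R and compiled paths share one interface.
.tme_rhs_desolve <- function(t, y, parms) {
  sp <- tme_split_params(setNames(parms, tme_parameter_names(extended = TRUE)))
  y[3] <- max(y[3], 0)  # guard hill() against tiny negative solver excursions
  list(tme_rhs(t, y, sp$params, sp$hyp))
}

#' Integrate the model
#'
#' Solves the 18-equation system on a time grid with a stiff-capable
#' integrator (`deSolve::ode`, `lsoda`), by default through the compiled
#' right-hand side shipped with the package. Fast cytokine decay against slow
#' cell dynamics makes the system moderately stiff, hence the tight default
#' tolerances. Negative excursions smaller in magnitude than the absolute
#' tolerance are clipped to zero after integration.
#'
#' @param params a [tme_params()] vector.
#' @param hyp a [hypoxia_params()] object.
#' @param x0 initial state (18 values, canonical order); week 6 of tumour
#'   progression is the system's initial state, t = 0.
#' @param times ascending time grid in days, starting at 0.
#' @param rtol,atol relative / absolute solver tolerances.
#' @param method `deSolve` integration method.
#' @param use_compiled integrate through the compiled right-hand side
#'   (default) or the plain-R one.
#' @return A `"tme_trajectory"` object: list with `times`, `states` (matrix,
#'   one row per time, 18 named columns), `params`, `hyp`.
#' @export
#' @examples
#' p <- tme_params(c(lambda_A = 0.2, delta_A = 0.05, A0 = 1))
#' tr <- tme_simulate(p, x0 = tme_state(A = 0.1), times = 0:20)
#' tail(as.data.frame(tr), 3)
tme_simulate <- function(params, hyp = hypoxia_params(), x0,
                         times = seq(0, 150, by = 1),
                         rtol = 1e-8, atol = 1e-10, method = "lsoda",
                         use_compiled = TRUE) {
  validate_tme_params(params)
  stopifnot(inherits(hyp, "tme_hypoxia"))
  if (length(x0) != 18L) stop("x0 must have exactly 18 components")
  if (any(x0 < 0)) stop("initial state must be non-negative")
  if (is.unsorted(times, strictly = TRUE)) stop("times must be ascending")
  y0 <- setNames(as.numeric(x0), .tme_state_names)
  theta <- tme_extended_params(params, hyp)
  # logistic terms divide by the carrying capacities
  if (any(theta[.tme_capacity_names] <= 0))
    stop("carrying capacities EN0, C0, A0 must be positive")

  sol <- if (use_compiled) {
    deSolve::ode(y = y0, times = times, func = "tme_derivs", parms = theta,
                 dllname = "tmeode", initfunc = "tme_initmod",
                 method = method, rtol = rtol, atol = atol)
  } else {
    deSolve::ode(y = y0, times = times, func = .tme_rhs_desolve,
                 parms = theta, method = method, rtol = rtol, atol = atol)
  }
  if (nrow(sol) < length(times) || any(!is.finite(sol))) {
    ok <- if (nrow(sol) > 0) rowSums(!is.finite(sol)) == 0 else logical(0)
    t_fail <- if (any(ok)) max(sol[ok, "time"]) else times[1]
    cond <- structure(
      class = c("tme_integration_error", "error", "condition"),
      list(message = sprintf(
        "integration failed near t = %.3f days (stiffness or blow-up)",
        t_fail), call = sys.call(-1), time = t_fail))
    stop(cond)
  }
  states <- unname(sol[, -1, drop = FALSE])
  colnames(states) <- .tme_state_names
  states[states < 0 & abs(states) < atol] <- 0
  structure(list(times = as.numeric(times), states = states,
                 params = params, hyp = hyp),
            class = "tme_trajectory")
}

#' Build a state vector
#'
#' Convenience constructor for the 18-component state: named arguments set
#' individual variables, everything else defaults to `default`.
#'
#' @param ... named state values, e.g. `A = 0.1`.
#' @param default fill value for unset variables.
#' @return Named numeric vector of length 18.
#' @export
tme_state <- function(..., default = 0) {
  vals <- c(...)
  s <- setNames(rep(default, 18L), .tme_state_names)
  if (length(vals) > 0L) {
    bad <- setdiff(names(vals), .tme_state_names)
    if (length(bad) > 0L)
      stop("unknown state name(s): ", paste(bad, collapse = ", "))
    s[names(vals)] <- vals
  }
  s
}

#' @export
print.tme_trajectory <- function(x, ...) {
  cat("tme_trajectory: ", length(x$times), " time points on [",
      min(x$times), ", ", max(x$times), "] days, 18 state variables\n",
      sep = "")
  cat("final state (head): ",
      paste(sprintf("%s=%.4g", .tme_state_names[1:6],
                    x$states[nrow(x$states), 1:6]), collapse = ", "),
      ", ...\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.tme_trajectory <- function(x, ...) {
  data.frame(t_days = x$times, x$states, check.names = FALSE)
}

#' @export
plot.tme_trajectory <- function(x, vars = tme_state_names(), ...) {
  matplot(x$times, x$states[, vars, drop = FALSE], type = "l", lty = 1,
          xlab = "time (days)", ylab = "non-dimensional level", ...)
  legend("topright", legend = vars, col = seq_along(vars), lty = 1,
         cex = 0.6, bty = "n")
  invisible(x)
}

#' Export / import a trajectory as CSV
#'
#' Column `t_days` followed by one column per state variable in canonical
#' order.
#'
#' @param traj a `tme_trajectory`.
#' @param path file path.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "tme_trajectory"))
  write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  stopifnot(identical(names(df), c("t_days", .tme_state_names)))
  structure(list(times = df$t_days,
                 states = as.matrix(df[, .tme_state_names]),
                 params = NULL, hyp = NULL),
            class = "tme_trajectory")
}

#' Derived observable series of a trajectory
#'
#' Returns the cancer level, the total immune cell level
#' (TN + Th + Tc + Tr + DN + D + MN + M) and the total of all 12 cell
#' variables, aligned with the trajectory time grid.
#'
#' @param traj a `tme_trajectory`.
#' @return `data.frame` with columns `t_days`, `cancer`, `total_immune`,
#'   `total_cells`.
#' @export
tme_observables <- function(traj) {
  stopifnot(inherits(traj, "tme_trajectory"))
  s <- traj$states
  data.frame(
    t_days = traj$times,
    cancer = s[, "C"],
    total_immune = rowSums(s[, .tme_immune_names, drop = FALSE]),
    total_cells = rowSums(s[, .tme_cell_names, drop = FALSE])
  )
}
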