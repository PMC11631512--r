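# Practical identifiability by profile likelihood: scan one parameter over
# [0, 2 * estimate], re-optimizing the remaining free parameters at each
# grid point, and read identifiability off chi-square threshold crossings.

#' Perturbed synthetic dataset from a fit
#'
#' Simulates the fitted trajectories, samples them at the observation times
#' and applies independent multiplicative noise uniform in
#' `[1 - level, 1 + level]` to every entry. This is the synthetic-data
#' device used to probe practical identifiability around the estimate.
#'
#' @param fit a [fit_tme()] result.
#' @param level noise level as a fraction (>= 0); 0.05 means +/-5%.
#' @param seed RNG seed.
#' @return A [tme_dataset()] shaped like the fit's data.
#' @export
perturbed_synthetic <- function(fit, level = 0.05, seed = 1) {
  stopifnot(inherits(fit, "tme_fit"), level >= 0)
  set.seed(seed)
  mice <- fit$mouse %||% seq_len(dim(fit$data$values)[3])
  vals <- array(NA_real_, dim = c(length(fit$data$times), 18L,
                                  length(mice)),
                dimnames = list(NULL, tme_state_names(),
                                paste0("mouse", mice)))
  for (j in seq_along(mice)) {
    m <- mice[j]
    x0 <- fit$x0 %||% fit$data$values[1, , m]
    traj <- tme_simulate(fit$params, fit$hyp, x0 = x0,
                         times = fit$data$times)
    noise <- matrix(runif(length(traj$states), 1 - level, 1 + level),
                    nrow = nrow(traj$states))
    vals[, , j] <- traj$states * noise
  }
  tme_dataset(vals, times = fit$data$times)
}

#' Profile-curve container
#'
#' @param parameter scanned parameter name.
#' @param grid scan grid.
#' @param pl profile loss at each grid value (NA where re-optimization
#'   failed).
#' @param theta_hat the point estimate.
#' @param loss_hat the fitted minimum loss.
#' @return Object of class `"tme_profile"`.
#' @export
profile_curve <- function(parameter, grid, pl, theta_hat, loss_hat) {
  stopifnot(length(grid) == length(pl), length(grid) >= 3L)
  structure(list(parameter = parameter, grid = as.numeric(grid),
                 pl = as.numeric(pl), theta_hat = theta_hat,
                 loss_hat = loss_hat),
            class = "tme_profile")
}

#' @export
print.tme_profile <- function(x, ...) {
  cat("Profile likelihood for ", x$parameter, ": ", length(x$grid),
      " points on [", format(min(x$grid)), ", ", format(max(x$grid)),
      "], estimate ", format(x$theta_hat), ", minimum loss ",
      format(x$loss_hat), "\n", sep = "")
  invisible(x)
}

#' @export
plot.tme_profile <- function(x, alpha = 0.95, ...) {
  thr <- x$loss_hat + qchisq(alpha, df = 1)
  plot(x$grid, x$pl, type = "b", xlab = x$parameter,
       ylab = "profile loss", ...)
  abline(h = thr, lty = 2)
  abline(v = x$theta_hat, lty = 3)
  invisible(x)
}

#' Profile likelihood of one model parameter
#'
#' Scans `param` over `[0, 2 * estimate]` (the investigated neighbourhood);
#' at each grid value the parameter is held fixed and the loss is
#' re-minimized over the remaining free parameters by [local_refine()],
#' warm-started from the neighbouring grid point, sweeping outwards from the
#' estimate. With `reoptimize = FALSE` the other parameters stay at their
#' fitted values (an upper bound on the profile, useful as a fast screen).
#'
#' @param fit a [fit_tme()] result.
#' @param param name of the scanned parameter (must be in `fit$free`).
#' @param data dataset defining the loss (default: the fit's data).
#' @param grid_size number of scan points.
#' @param grid explicit scan grid overriding `grid_size`.
#' @param reoptimize re-optimize the remaining free parameters.
#' @param control optimizer control for the re-optimizations.
#' @return A [profile_curve()].
#' @export
profile_likelihood <- function(fit, param, data = fit$data, grid_size = 21,
                               grid = NULL, reoptimize = TRUE,
                               control = list(maxit = 100)) {
  stopifnot(inherits(fit, "tme_fit"))
  if (!param %in% fit$free)
    stop("param must be one of the fitted (free) parameters")
  theta_hat <- unname(fit$params[param])
  if (is.null(grid)) {
    if (theta_hat <= 0)
      stop("degenerate grid: the estimate is 0; supply `grid` explicitly")
    grid <- seq(0, 2 * theta_hat, length.out = grid_size)
  }
  if (length(unique(grid)) < 3L) stop("degenerate grid")
  nuisance <- setdiff(fit$free, param)
  lower <- rep_len(fit$config$lower, length(nuisance))
  upper <- rep_len(fit$config$upper, length(nuisance))
  lower[nuisance %in% .tme_capacity_names] <-
    pmax(lower[nuisance %in% .tme_capacity_names], 1e-3)

  loss_at <- function(value, nuis) {
    p <- fit$params
    p[param] <- value
    if (length(nuis) > 0) p[nuisance] <- nuis
    tme_loss(tme_params(unclass(p)), data, fit$hyp, mouse = fit$mouse,
             weights = fit$weights, x0 = fit$x0)
  }

  pl <- rep(NA_real_, length(grid))
  # sweep outward from the grid point nearest the estimate, warm-starting
  i0 <- which.min(abs(grid - theta_hat))
  order_idx <- c(i0:length(grid), if (i0 > 1) (i0 - 1):1)
  start0 <- unname(fit$params[nuisance])
  warm <- list(right = start0, left = start0)
  for (i in order_idx) {
    side <- if (i >= i0) "right" else "left"
    res <- tryCatch({
      if (reoptimize && length(nuisance) > 0) {
        r <- local_refine(warm[[side]],
                          function(n) loss_at(grid[i], n),
                          lower, upper, control = control)
        warm[[side]] <- r$par
        r$value
      } else {
        loss_at(grid[i], if (length(nuisance) > 0) start0 else NULL)
      }
    }, error = function(e) NA_real_)
    pl[i] <- res
  }
  profile_curve(param, grid, pl, theta_hat,
                loss_hat = min(fit$loss, min(pl, na.rm = TRUE)))
}

#' Classify a profile curve
#'
#' The threshold is the fitted minimum plus the `alpha`-quantile of the
#' chi-square distribution with one degree of freedom (pointwise confidence
#' interval). A parameter is `identifiable` when the profile crosses the
#' threshold on both sides of the estimate within the scanned range;
#' `practically_non_identifiable` when it fails to cross on at least one
#' side; and `flat` when, in addition, the whole profile varies by less than
#' `flat_tol` times the chi-square increment (suggesting local structural
#' non-identifiability).
#'
#' @param curve a [profile_curve()].
#' @param alpha confidence level for the chi-square quantile.
#' @param flat_tol flatness tolerance as a fraction of the threshold
#'   increment.
#' @return One of `"identifiable"`, `"practically_non_identifiable"`,
#'   `"flat"`.
#' @export
classify_profile <- function(curve, alpha = 0.95, flat_tol = 0.1) {
  stopifnot(inherits(curve, "tme_profile"))
  ok <- is.finite(curve$pl)
  if (sum(ok) < 3L) stop("degenerate grid: fewer than 3 finite profile values")
  delta <- qchisq(alpha, df = 1)
  thr <- curve$loss_hat + delta
  if (max(curve$pl[ok]) - min(curve$pl[ok]) < flat_tol * delta)
    return("flat")
  left <- ok & curve$grid < curve$theta_hat
  right <- ok & curve$grid > curve$theta_hat
  crosses_left <- any(curve$pl[left] > thr)
  crosses_right <- any(curve$pl[right] > thr)
  if (crosses_left && crosses_right) "identifiable"
  else "practically_non_identifiable"
}
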