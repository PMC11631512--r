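# Parameter estimation: sum-of-squares loss on the non-dimensional
# observations, a genetic algorithm with rank scaling, stochastic-universal
# line selection, elitism, scattered crossover and adaptive Gaussian
# mutation, followed by gradient-based local refinement (L-BFGS-B).

#' Sum-of-squares loss of a parameter set against observed data
#'
#' Sum over mice, variables and time points of the squared differences
#' between the simulated and the observed non-dimensional values. All
#' variables share the \[0, 1\] scale after non-dimensionalization, so the
#' default weights are equal; a weight matrix (time x variable) rescales
#' individual residuals. The initial condition of each mouse is its observed
#' week-6 (t = 0) state. Integration failures return a large finite penalty
#' so that global search can continue.
#'
#' @param params a [tme_params()] vector.
#' @param data a [tme_dataset()].
#' @param hyp a [hypoxia_params()] object.
#' @param mouse optional mouse index/indices to restrict the sum to.
#' @param weights optional weight matrix (times x 18) or per-variable vector.
#' @param x0 optional explicit initial state (overrides the observed t = 0
#'   state; single-mouse data only).
#' @param penalty loss value returned when integration fails.
#' @param use_compiled passed to [tme_simulate()].
#' @return Non-negative scalar.
#' @export
tme_loss <- function(params, data, hyp = hypoxia_params(), mouse = NULL,
                     weights = NULL, x0 = NULL, penalty = 1e6,
                     use_compiled = TRUE) {
  stopifnot(inherits(data, "tme_data"))
  n_mice <- dim(data$values)[3]
  mice <- if (is.null(mouse)) seq_len(n_mice) else mouse
  if (!is.null(x0) && length(mice) > 1L)
    stop("explicit x0 is only supported for single-mouse losses")
  w <- matrix(1, length(data$times), 18L)
  if (!is.null(weights)) {
    if (is.matrix(weights)) w[] <- weights
    else w <- matrix(weights, length(data$times), 18L, byrow = TRUE)
  }
  total <- 0
  for (m in mice) {
    obs <- data$values[, , m]
    start <- if (is.null(x0)) obs[1, ] else x0
    traj <- tryCatch(
      tme_simulate(params, hyp, x0 = start, times = data$times,
                   use_compiled = use_compiled),
      error = function(e) NULL)
    if (is.null(traj)) return(penalty)
    total <- total + sum(w * (traj$states - obs)^2)
  }
  total
}

#' Genetic-algorithm configuration
#'
#' Defaults: population 200, up to 500 generations, 5% elite carry-over,
#' crossover fraction 0.8, Gaussian mutation whose scale shrinks tenfold
#' over the run, stall limit 50 generations, function tolerance 1e-8 and
#' box bounds \[0, 2\] on every parameter.
#'
#' @param pop_size population size (>= 2).
#' @param max_generations generation cap.
#' @param elite_frac fraction of the population carried over unchanged.
#' @param crossover_frac fraction of the non-elite offspring produced by
#'   crossover (the rest by mutation).
#' @param mutation_scale initial mutation standard deviation, as a fraction
#'   of the box width.
#' @param stall_generations stop when the best loss improves by less than
#'   `fn_tol` over this many generations.
#' @param fn_tol function improvement tolerance.
#' @param lower,upper box bounds (scalar or per-parameter).
#' @param seed RNG seed making the whole run reproducible.
#' @return List of class `"ga_config"`.
#' @export
ga_config <- function(pop_size = 200, max_generations = 500,
                      elite_frac = 0.05, crossover_frac = 0.8,
                      mutation_scale = 0.1, stall_generations = 50,
                      fn_tol = 1e-8, lower = 0, upper = 2, seed = 1) {
  stopifnot(pop_size >= 2, max_generations >= 1,
            elite_frac >= 0, elite_frac <= 1,
            crossover_frac >= 0, crossover_frac <= 1,
            mutation_scale > 0, stall_generations >= 1, fn_tol >= 0)
  structure(list(pop_size = pop_size, max_generations = max_generations,
                 elite_frac = elite_frac, crossover_frac = crossover_frac,
                 mutation_scale = mutation_scale,
                 stall_generations = stall_generations, fn_tol = fn_tol,
                 lower = lower, upper = upper, seed = seed),
            class = "ga_config")
}

#' Genetic-algorithm minimizer
#'
#' One generation: evaluate raw fitness; scale it to rank-based expectation
#' values (expectation proportional to `1/sqrt(rank)`); select parents by
#' stochastic-universal sampling along a line whose segments are the scaled
#' expectations; carry the elite over unchanged; produce the remaining
#' offspring by scattered crossover of parent pairs or Gaussian mutation of
#' single parents, clipped to the box; replace the population. Stops at the
#' generation cap, at the stall limit, or when the improvement over the
#' stall window drops below the function tolerance.
#'
#' @param fn objective returning a finite scalar.
#' @param n_par number of decision variables.
#' @param config a [ga_config()].
#' @return List: `par`, `value`, `history` (per-generation best loss,
#'   non-increasing), `generations`, `evaluations`.
#' @export
ga_minimize <- function(fn, n_par, config = ga_config()) {
  set.seed(config$seed)
  np <- config$pop_size
  lower <- rep_len(config$lower, n_par)
  upper <- rep_len(config$upper, n_par)
  n_elite <- max(1L, min(np - 1L, ceiling(config$elite_frac * np)))
  pop <- matrix(runif(np * n_par, lower, upper), nrow = np, byrow = TRUE)
  fit <- apply(pop, 1, fn)
  evals <- np
  best_par <- pop[which.min(fit), ]
  best_val <- min(fit)
  history <- best_val
  gen <- 0L
  while (gen < config$max_generations) {
    gen <- gen + 1L
    ord <- order(fit)
    ranks <- integer(np); ranks[ord] <- seq_len(np)
    expect <- 1 / sqrt(ranks)

    n_child <- np - n_elite
    n_xover <- round(config$crossover_frac * n_child)
    n_mut <- n_child - n_xover
    n_parents <- 2L * n_xover + n_mut
    parents <- .sus_select(expect, n_parents)

    sigma <- config$mutation_scale * (upper - lower) *
      10^(-gen / config$max_generations)

    children <- matrix(NA_real_, n_child, n_par)
    if (n_xover > 0) {
      pa <- pop[parents[seq_len(n_xover)], , drop = FALSE]
      pb <- pop[parents[n_xover + seq_len(n_xover)], , drop = FALSE]
      mask <- matrix(runif(n_xover * n_par) < 0.5, n_xover, n_par)
      children[seq_len(n_xover), ] <- ifelse(mask, pa, pb)
    }
    if (n_mut > 0) {
      pm <- pop[parents[2L * n_xover + seq_len(n_mut)], , drop = FALSE]
      noise <- matrix(rnorm(n_mut * n_par), n_mut, n_par) *
        matrix(sigma, n_mut, n_par, byrow = TRUE)
      children[n_xover + seq_len(n_mut), ] <- pm + noise
    }
    children <- pmin(pmax(children,
                          matrix(lower, n_child, n_par, byrow = TRUE)),
                     matrix(upper, n_child, n_par, byrow = TRUE))

    elite_idx <- ord[seq_len(n_elite)]
    new_pop <- rbind(pop[elite_idx, , drop = FALSE], children)
    new_fit <- c(fit[elite_idx], apply(children, 1, fn))
    evals <- evals + n_child
    pop <- new_pop; fit <- new_fit

    if (min(fit) < best_val) {
      best_val <- min(fit)
      best_par <- pop[which.min(fit), ]
    }
    history <- c(history, best_val)

    stall <- config$stall_generations
    if (gen >= stall &&
        history[length(history) - stall] - best_val <= config$fn_tol)
      break
  }
  ord <- order(fit)
  list(par = best_par, value = best_val, history = history,
       generations = gen, evaluations = evals,
       population = pop[ord, , drop = FALSE], fitness = fit[ord])
}

# stochastic universal sampling on the expectation line
.sus_select <- function(expect, n) {
  if (n == 0L) return(integer(0))
  cum <- cumsum(expect)
  step <- cum[length(cum)] / n
  pts <- runif(1, 0, step) + step * (seq_len(n) - 1)
  idx <- findInterval(pts, cum) + 1L
  idx[sample.int(length(idx))]  # shuffle so pairing is unbiased
}

#' Gradient-based local refinement
#'
#' Constrained local minimization (L-BFGS-B with numerical gradients) from a
#' starting point inside the box. If the line search fails the starting
#' point is returned unchanged with a warning; the returned loss never
#' exceeds the starting loss.
#'
#' @param start numeric starting vector (within bounds).
#' @param fn objective.
#' @param lower,upper box bounds (recycled).
#' @param control passed to [stats::optim()].
#' @return List: `par`, `value`, `converged`.
#' @export
local_refine <- function(start, fn, lower = 0, upper = 2,
                         control = list(maxit = 1000)) {
  lower <- rep_len(lower, length(start))
  upper <- rep_len(upper, length(start))
  if (is.null(control$ndeps))
    control$ndeps <- rep(1e-7, length(start))
  if (is.null(control$factr)) control$factr <- 1e4
  f0 <- fn(start)
  res <- tryCatch(
    optim(start, fn, method = "L-BFGS-B", lower = lower, upper = upper,
          control = control),
    error = function(e) {
      warning("local refinement failed (", conditionMessage(e),
              "); returning the starting point")
      NULL
    })
  if (is.null(res) || !is.finite(res$value) || res$value > f0)
    return(list(par = start, value = f0, converged = FALSE))
  list(par = pmin(pmax(res$par, lower), upper), value = res$value,
       converged = res$convergence == 0)
}

#' Fit the model to observed data with the hybrid genetic algorithm
#'
#' Global search by [ga_minimize()] over the free parameters within the box
#' bounds, then local refinement of the best solution by [local_refine()].
#' Each mouse is normally fitted independently (`mouse` argument); the
#' initial condition is the mouse's observed t = 0 state unless
#' `x0_policy = "estimate"`, in which case the 18 initial values are
#' estimated alongside the parameters.
#'
#' @param data a [tme_dataset()].
#' @param free names of the parameters to estimate (default: the whole
#'   registry). Parameters not listed stay at their value in `start`.
#' @param start full baseline [tme_params()] vector supplying the fixed
#'   parameters (default: all rates zero, carrying capacities one).
#' @param mouse mouse index to fit (default: all mice jointly).
#' @param hyp a [hypoxia_params()] object (held fixed).
#' @param config a [ga_config()].
#' @param weights optional loss weights, see [tme_loss()].
#' @param x0_policy `"observed"` (default) or `"estimate"`.
#' @param refine run the local-refinement stage.
#' @return Object of class `"tme_fit"` with `print`, `summary`, `coef`,
#'   `predict`, `plot`, `residuals` and `simulate` methods.
#' @export
fit_tme <- function(data, free = tme_parameter_names(),
                    start = tme_params(c(EN0 = 1, C0 = 1, A0 = 1)),
                    mouse = NULL,
                    hyp = hypoxia_params(), config = ga_config(),
                    weights = NULL, x0_policy = c("observed", "estimate"),
                    refine = TRUE) {
  stopifnot(inherits(data, "tme_data"))
  x0_policy <- match.arg(x0_policy)
  bad <- setdiff(free, tme_parameter_names())
  if (length(bad) > 0L)
    stop("unknown free parameter(s): ", paste(bad, collapse = ", "))
  if (x0_policy == "estimate" &&
      (is.null(mouse) || length(mouse) != 1L) && dim(data$values)[3] > 1L)
    stop("x0 estimation requires a single mouse")

  n_free <- length(free)
  n_x0 <- if (x0_policy == "estimate") 18L else 0L
  lower <- rep_len(config$lower, n_free + n_x0)
  upper <- rep_len(config$upper, n_free + n_x0)
  # logistic capacities must stay positive
  lower[match(intersect(free, .tme_capacity_names), free)] <-
    pmax(lower[match(intersect(free, .tme_capacity_names), free)], 1e-3)
  cfg <- config
  cfg$lower <- lower
  cfg$upper <- upper

  obj <- function(theta) {
    p <- start
    p[free] <- theta[seq_len(n_free)]
    x0 <- if (n_x0 > 0) theta[n_free + seq_len(n_x0)] else NULL
    tme_loss(p, data, hyp, mouse = mouse, weights = weights, x0 = x0)
  }

  ga <- ga_minimize(obj, n_free + n_x0, cfg)
  theta <- ga$par
  value <- ga$value
  if (refine) {
    # screen the GA champion and the next best distinct candidates with a
    # short descent, then refine the screening winner to depth (the global
    # stage can park several basins near the optimum)
    starts <- unique(rbind(ga$par, head(ga$population, 6)))
    starts <- starts[seq_len(min(3, nrow(starts))), , drop = FALSE]
    screened <- lapply(seq_len(nrow(starts)), function(i)
      local_refine(starts[i, ], obj, lower, upper,
                   control = list(maxit = 60)))
    best <- screened[[which.min(vapply(screened, `[[`, numeric(1),
                                       "value"))]]
    ref <- local_refine(best$par, obj, lower, upper,
                        control = list(maxit = 400))
    if (ref$value < value) {
      theta <- ref$par
      value <- ref$value
    }
  }

  par_full <- start
  par_full[free] <- theta[seq_len(n_free)]
  x0_hat <- if (n_x0 > 0) setNames(theta[n_free + seq_len(n_x0)],
                                   tme_state_names()) else NULL
  structure(list(
    params = tme_params(unclass(par_full)),
    free = free,
    loss = value,
    ga_loss = ga$value,
    refine_delta = ga$value - value,
    history = ga$history,
    generations = ga$generations,
    evaluations = ga$evaluations,
    config = config,
    seed = config$seed,
    data = data,
    mouse = mouse,
    hyp = hyp,
    weights = weights,
    x0_policy = x0_policy,
    x0 = x0_hat
  ), class = "tme_fit")
}

#' @export
print.tme_fit <- function(x, ...) {
  cat("Hybrid-GA fit of the tumour microenvironment model\n")
  cat("  free parameters: ", length(x$free),
      if (x$x0_policy == "estimate") " (+ 18 initial values)" else "",
      "\n", sep = "")
  cat("  mice: ", if (is.null(x$mouse)) "all" else
    paste(x$mouse, collapse = ", "), "\n", sep = "")
  cat(sprintf("  GA best loss: %.6g over %d generations (%d evaluations)\n",
              x$ga_loss, x$generations, x$evaluations))
  cat(sprintf("  refined loss: %.6g (improvement %.3g)\n",
              x$loss, x$refine_delta))
  invisible(x)
}

#' @export
summary.tme_fit <- function(object, ...) {
  est <- object$params[object$free]
  out <- list(estimates = data.frame(parameter = object$free,
                                     estimate = unname(est)),
              loss = object$loss, ga_loss = object$ga_loss,
              generations = object$generations,
              history_range = range(object$history))
  class(out) <- "summary.tme_fit"
  out
}

#' @export
print.summary.tme_fit <- function(x, ...) {
  cat("Fitted parameters:\n")
  print(head(x$estimates, 20), row.names = FALSE)
  if (nrow(x$estimates) > 20) cat("  ...", nrow(x$estimates), "in total\n")
  cat(sprintf("loss %.6g (GA %.6g) after %d generations\n",
              x$loss, x$ga_loss, x$generations))
  invisible(x)
}

#' @export
coef.tme_fit <- function(object, all = TRUE, ...) {
  if (all) object$params else object$params[object$free]
}

#' @export
predict.tme_fit <- function(object, times = NULL, mouse = NULL, ...) {
  times <- times %||% object$data$times
  mice <- mouse %||% (object$mouse %||% seq_len(dim(object$data$values)[3]))
  out <- lapply(mice, function(m) {
    x0 <- object$x0 %||% object$data$values[1, , m]
    tme_simulate(object$params, object$hyp, x0 = x0, times = times)
  })
  names(out) <- paste0("mouse", mice)
  if (length(out) == 1L) out[[1]] else out
}

#' @export
residuals.tme_fit <- function(object, ...) {
  mice <- object$mouse %||% seq_len(dim(object$data$values)[3])
  res <- array(NA_real_,
               dim = c(length(object$data$times), 18L, length(mice)),
               dimnames = list(NULL, tme_state_names(),
                               paste0("mouse", mice)))
  for (j in seq_along(mice)) {
    m <- mice[j]
    x0 <- object$x0 %||% object$data$values[1, , m]
    traj <- tme_simulate(object$params, object$hyp, x0 = x0,
                         times = object$data$times)
    res[, , j] <- object$data$values[, , m] - traj$states
  }
  res
}

#' @export
plot.tme_fit <- function(x, mouse = NULL, vars = tme_state_names(), ...) {
  m <- (mouse %||% (x$mouse %||% 1))[1]
  traj <- predict(x, times = seq(min(x$data$times), max(x$data$times),
                                 length.out = 101), mouse = m)
  op <- par(mfrow = c(3, 6), mar = c(2.2, 2.2, 1.5, 0.5), mgp = c(1.2, 0.3, 0))
  on.exit(par(op))
  for (v in vars) {
    matplot(traj$times, traj$states[, v], type = "l", xlab = "days",
            ylab = "", main = v, ...)
    points(x$data$times, x$data$values[, v, m], pch = 19, col = 2)
  }
  invisible(x)
}

#' Simulate noisy replicate datasets from a fit
#'
#' Draws `nsim` perturbed synthetic datasets from the fitted trajectories
#' (see [perturbed_synthetic()]).
#'
#' @param object a `tme_fit`.
#' @param nsim number of replicates.
#' @param seed RNG seed.
#' @param level multiplicative noise level (fraction).
#' @param ... unused.
#' @return A list of [tme_dataset()] objects (a single object if
#'   `nsim = 1`).
#' @export
simulate.tme_fit <- function(object, nsim = 1, seed = 1, level = 0.05, ...) {
  out <- lapply(seq_len(nsim), function(i)
    perturbed_synthetic(object, level = level, seed = seed + i - 1))
  if (nsim == 1L) out[[1]] else out
}
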