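# Synthetic-data generation: ground-truth parameter sets, noisy observation
# arrays shaped like the stage tables, and fraction/volume/cytokine tables
# that close the data-preparation arithmetic exactly, so every pipeline
# stage is testable without external data.

#' Synthetic-data configuration
#'
#' The defaults are the study conditions: three mice observed at weeks
#' 6/8/10/12 (t = 0/14/28/42 days), multiplicative noise of 5%, a uniform
#' \[0, 2\] parameter prior and the reference stage volumes and per-gram
#' yields. The default initial state is the observed week-6 state of mouse 2
#' (the mean-anchored mouse).
#'
#' @param seed RNG seed.
#' @param n_mice number of mice (1-3; per-mouse anchors exist for three).
#' @param times observation times in days, ascending from 0.
#' @param noise multiplicative noise level (fraction, >= 0).
#' @param noise_model `"uniform"` (default; factors in
#'   `[1 - noise, 1 + noise]`) or `"lognormal"` (sdlog = noise).
#' @param prior_low,prior_high uniform prior bounds for the ground truth;
#'   scalars, or named vectors overriding the bound for individual
#'   parameters.
#' @param active optional character vector: parameters allowed to be
#'   non-zero in sampled truths (a sparsity mask); `NULL` keeps all.
#' @param x0 initial state for simulated observations (default: mouse 2,
#'   week 6, non-dimensional).
#' @param anchors stage anchors, see [stage_anchors()].
#' @param rescale re-scale simulated observations by their per-variable
#'   maxima (off by default so a noiseless dataset closes the estimation
#'   loop exactly).
#' @param retry_cap how many candidate truths may be rejected for failing
#'   to integrate before giving up.
#' @return List of class `"synth_config"`.
#' @export
synth_config <- function(seed = 1, n_mice = 3, times = c(0, 14, 28, 42),
                         noise = 0.05, noise_model = c("uniform",
                                                       "lognormal"),
                         prior_low = 0, prior_high = 2, active = NULL,
                         x0 = NULL, anchors = stage_anchors(),
                         rescale = FALSE, retry_cap = 20) {
  stopifnot(noise >= 0, n_mice >= 1, n_mice <= 3,
            times[1] == 0, !is.unsorted(times, strictly = TRUE))
  structure(list(seed = seed, n_mice = n_mice, times = times,
                 noise = noise, noise_model = match.arg(noise_model),
                 prior_low = prior_low, prior_high = prior_high,
                 active = active, x0 = x0, anchors = anchors,
                 rescale = rescale, retry_cap = retry_cap),
            class = "synth_config")
}

#' Default synthetic initial state
#'
#' The observed week-6 non-dimensional state of mouse 2.
#'
#' @return Named state vector of length 18.
#' @export
default_x0 <- function() {
  pymt_dataset()$values[1, , 2]
}

#' Sample a ground-truth parameter set
#'
#' Seeded draw from the uniform prior, with carrying capacities floored at
#' 1e-3 (the logistic terms divide by them) and optional sparsity via
#' `config$active`. The draw is guaranteed to integrate on \[0, 150\] from
#' the configured initial state; non-integrable candidates are re-drawn up
#' to the retry cap.
#'
#' @param config a [synth_config()].
#' @return A [tme_params()] vector.
#' @export
sample_ground_truth <- function(config = synth_config()) {
  set.seed(config$seed)
  x0 <- config$x0 %||% default_x0()
  nm <- tme_parameter_names()
  lo <- setNames(rep_len(if (is.null(names(config$prior_low)))
    config$prior_low else 0, length(nm)), nm)
  hi <- setNames(rep_len(if (is.null(names(config$prior_high)))
    config$prior_high else 2, length(nm)), nm)
  if (!is.null(names(config$prior_low)))
    lo[names(config$prior_low)] <- config$prior_low
  if (!is.null(names(config$prior_high)))
    hi[names(config$prior_high)] <- config$prior_high
  for (try in seq_len(config$retry_cap)) {
    theta <- runif(length(nm), lo, hi)
    names(theta) <- nm
    theta[.tme_capacity_names] <- pmax(theta[.tme_capacity_names], 1e-3)
    if (!is.null(config$active)) {
      off <- setdiff(nm, config$active)
      theta[setdiff(off, .tme_capacity_names)] <- 0
    }
    p <- tme_params(theta)
    ok <- tryCatch({
      tme_simulate(p, x0 = x0, times = seq(0, 150, by = 5))
      TRUE
    }, error = function(e) FALSE)
    if (ok) return(p)
  }
  stop("generation error: no integrable parameter set within ",
       config$retry_cap, " draws")
}

#' Simulate noisy observations from a ground truth
#'
#' Integrates the model at the ground truth, samples the observation times
#' and applies independent multiplicative noise per mouse replicate; values
#' are clipped at zero. With `config$rescale` the noisy array is divided by
#' its per-variable maxima (scale registry returned).
#'
#' @param truth a [tme_params()] ground truth.
#' @param config a [synth_config()].
#' @param hyp a [hypoxia_params()] object.
#' @return List: `data` (a [tme_dataset()]), `reference` (noiseless time x
#'   variable matrix), `scales` (per-variable maxima if rescaled, else
#'   `NULL`).
#' @export
make_observations <- function(truth, config = synth_config(),
                              hyp = hypoxia_params()) {
  set.seed(config$seed + 1L)
  x0 <- config$x0 %||% default_x0()
  traj <- tme_simulate(truth, hyp, x0 = x0, times = config$times)
  ref <- traj$states
  vals <- array(NA_real_, dim = c(length(config$times), 18L,
                                  config$n_mice))
  for (m in seq_len(config$n_mice)) {
    fac <- switch(config$noise_model,
                  uniform = matrix(runif(length(ref), 1 - config$noise,
                                         1 + config$noise), nrow(ref)),
                  lognormal = matrix(exp(rnorm(length(ref), 0,
                                               config$noise)), nrow(ref)))
    if (config$noise == 0) fac[] <- 1
    vals[, , m] <- pmax(ref * fac, 0)
  }
  scales <- NULL
  if (config$rescale) {
    flat <- matrix(aperm(vals, c(1, 3, 2)), ncol = 18L)
    colnames(flat) <- tme_state_names()
    nd <- nondimensionalize(flat)
    scales <- nd$scales
    for (m in seq_len(config$n_mice))
      vals[, , m] <- sweep(vals[, , m], 2, scales, "/")
  }
  list(data = tme_dataset(vals, times = config$times, scales = scales),
       reference = ref, scales = scales)
}

#' Synthetic per-mouse cell counts, fractions and cytokine tables
#'
#' Generates anchor-consistent absolute counts (cancer and TAM columns from
#' the per-gram yield arithmetic, necrotic = cancer / 2, random immune
#' counts, and non-immune counts filling the residual caliper volume with a
#' dominant epithelial absorber plus adipocytes and endothelial cells) and
#' inverts them into exactly the tables the data-preparation step consumes:
#' immune and non-immune fraction tables, TAM totals, caliper volumes and
#' cytokine/oxygen levels. Running [assemble_dataset()] on the emitted
#' tables reproduces the truth counts to integer precision.
#'
#' @param config a [synth_config()].
#' @return List: `fractions`, `cytokines`, `counts` (floored truth),
#'   `tam_totals`, `volumes`, `sizes`, `anchors`.
#' @export
make_fraction_tables <- function(config = synth_config()) {
  set.seed(config$seed + 2L)
  anchors <- config$anchors
  est <- stage_cell_estimates(anchors)
  sizes <- cell_sizes()
  vols <- model_cell_volumes(sizes, extra = "epithelial")
  immune <- c("TN", "Th", "Tc", "Tr", "DN", "D", "MN", "M")
  weeks <- anchors$weeks
  mice <- seq_len(config$n_mice)

  frac_rows <- list()
  count_rows <- list()
  tam_rows <- list()
  vol_rows <- list()
  cyt_rows <- list()
  for (m in mice) for (k in seq_along(weeks)) {
    w <- weeks[k]
    es <- est[est$week == w, ]
    C_cnt <- mouse_anchor(es$cancer_mean, es$cancer_sd, m)
    tam <- mouse_anchor(es$tam_mean, es$tam_sd, m)
    u <- runif(1, 0.35, 0.65)
    cc <- c(TN = runif(1, 0.8, 2.5) * 1e6, Th = runif(1, 0.3, 1) * 1e6,
            Tc = runif(1, 0.1, 0.6) * 1e6, Tr = runif(1, 0.05, 0.45) * 1e6,
            DN = runif(1, 1, 2.4) * 1e6, D = runif(1, 0.8, 1.7) * 1e6,
            MN = u * tam, M = (1 - u) * tam)
    used <- sum(cc * vols[immune]) + C_cnt * vols[["C"]]
    residual <- anchors$volumes[[k]] * 1e9 - used
    f_epi <- runif(1, 0.90, 0.96)
    f_A <- runif(1, 0.4, 0.7) * (1 - f_epi)
    f_EN <- 1 - f_epi - f_A
    f_non <- c(A = f_A, EN = f_EN, epithelial = f_epi)
    cc_non <- f_non * residual / sum(f_non * vols[names(f_non)])

    frac_rows[[length(frac_rows) + 1L]] <- rbind(
      data.frame(mouse = m, week = w, cell_type = names(cc),
                 fraction = unname(cc / sum(cc))),
      data.frame(mouse = m, week = w, cell_type = names(cc_non),
                 fraction = unname(cc_non / sum(cc_non))))
    count_rows[[length(count_rows) + 1L]] <- data.frame(
      mouse = m, week = w,
      as.list(floor(c(cc, C = C_cnt, N = C_cnt / 2, cc_non))))
    tam_rows[[length(tam_rows) + 1L]] <-
      data.frame(mouse = m, week = w, tam_total = tam)
    vol_rows[[length(vol_rows) + 1L]] <- data.frame(
      mouse = m, week = w,
      volume_mm3 = (used + sum(cc_non * vols[names(cc_non)])) / 1e9)
    cyt_rows[[length(cyt_rows) + 1L]] <- data.frame(
      mouse = m, week = w,
      H = runif(1, 780, 1550), IL12 = runif(1, 0, 63),
      IL10 = runif(1, 280, 720), IL6 = runif(1, 35, 385),
      V = runif(1, 310, 1080),
      Ox_ppm = c(50000, 10000, 1000, 10)[k])
  }
  list(fractions = do.call(rbind, frac_rows),
       cytokines = do.call(rbind, cyt_rows),
       counts = do.call(rbind, count_rows),
       tam_totals = do.call(rbind, tam_rows),
       volumes = do.call(rbind, vol_rows),
       sizes = sizes, anchors = anchors)
}

#' Parameter-recovery experiment on noiseless synthetic data
#'
#' Closes the whole pipeline: sample a ground truth, simulate observations,
#' and re-estimate a small free subset with the hybrid GA while all other
#' parameters stay fixed at the truth. On noiseless data the free
#' parameters should be recovered to within a few percent.
#'
#' @param seed seed driving the truth draw, the observations and the GA.
#' @param free names of the free parameters (default: ten rates with strong
#'   direct signatures in the observed series).
#' @param noise observation noise level.
#' @param ga a [ga_config()] (the default is sized for a ten-parameter
#'   search).
#' @param n_mice number of synthetic mice.
#' @return `data.frame` (parameter, truth, estimate, rel_error) with the
#'   fit attached as attribute `"fit"`.
#' @export
recovery_experiment <- function(seed = 1,
                                free = c("lambda_C", "delta_C",
                                         "lambda_A", "delta_A",
                                         "lambda_HC", "delta_H",
                                         "lambda_IL12M", "delta_IL12",
                                         "lambda_IL6A", "delta_IL6"),
                                noise = 0,
                                ga = ga_config(pop_size = 200,
                                               max_generations = 250,
                                               stall_generations = 80,
                                               seed = seed),
                                n_mice = 1) {
  cfg <- synth_config(seed = seed, n_mice = n_mice, noise = noise)
  truth <- sample_ground_truth(cfg)
  obs <- make_observations(truth, cfg)
  fit <- fit_tme(obs$data, free = free, start = truth, config = ga)
  est <- fit$params[free]
  tru <- truth[free]
  out <- data.frame(parameter = free, truth = unname(tru),
                    estimate = unname(est),
                    rel_error = unname(abs(est - tru) /
                                         pmax(abs(tru), 1e-12)))
  attr(out, "fit") <- fit
  out
}
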