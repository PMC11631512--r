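# Principal-component global sensitivity analysis: stack trajectory
# derivatives with respect to every parameter on a fine time grid, decompose
# the resulting Jacobian by SVD, and read principal sensitivity values,
# spectra, thresholded variable maps and scalar-output sensitivities off the
# factors.

.tme_output_series <- function(traj, outputs) {
  if (identical(outputs, "states")) return(traj$states)
  obs <- tme_observables(traj)
  as.matrix(obs[, outputs, drop = FALSE])
}

#' Trajectory sensitivity matrix
#'
#' Builds the `(n * K) x N` matrix `M` with entries `dX_k(t_i) / d theta_j`
#' by central finite differences, where `n` is the number of grid times, `K`
#' the number of output series (the 18 states, or a scalar observable) and
#' `N` the number of parameters (the full registry plus the hypoxia shape
#' parameters by default). Row blocks are ordered by output variable, then
#' time. The step for parameter `j` is `fd_rel_step * max(theta_j, fd_floor)`;
#' a failed integration at a perturbed point is retried with a halved step.
#' With `scaled = TRUE` column `j` is multiplied by `theta_j`, giving the
#' response to a relative (per-log) parameter change.
#'
#' @param params a [tme_params()] vector.
#' @param hyp a [hypoxia_params()] object.
#' @param x0 initial state.
#' @param times time grid in days (default daily on \[0, 150\]).
#' @param outputs `"states"` for all 18 variables, or a subset of
#'   `c("cancer", "total_immune", "total_cells")`.
#' @param parameters names of the parameters differentiated against.
#' @param fd_rel_step relative finite-difference step.
#' @param fd_floor absolute floor for the step base.
#' @param scaled multiply columns by the parameter values.
#' @param use_compiled passed to [tme_simulate()].
#' @return Matrix of class `"tme_sensmat"` with attributes `times`,
#'   `outputs`, `parameters`, `scaled`, `theta`.
#' @export
sensitivity_matrix <- function(params, hyp = hypoxia_params(), x0,
                               times = seq(0, 150, by = 1),
                               outputs = "states",
                               parameters = tme_parameter_names(TRUE),
                               fd_rel_step = 1e-4, fd_floor = 1e-6,
                               scaled = TRUE, use_compiled = TRUE) {
  theta0 <- tme_extended_params(params, hyp)
  if (!all(parameters %in% names(theta0)))
    stop("unknown parameter(s): ",
         paste(setdiff(parameters, names(theta0)), collapse = ", "))
  out_names <- if (identical(outputs, "states")) tme_state_names()
  else outputs
  sim_at <- function(theta) {
    sp <- tme_split_params(theta)
    .tme_output_series(tme_simulate(sp$params, sp$hyp, x0 = x0,
                                    times = times,
                                    use_compiled = use_compiled),
                       outputs)
  }
  n <- length(times); K <- length(out_names)
  M <- matrix(0, n * K, length(parameters))
  colnames(M) <- parameters
  for (j in seq_along(parameters)) {
    pj <- parameters[j]
    h <- fd_rel_step * max(theta0[[pj]], fd_floor)
    deriv <- NULL
    for (try in 1:4) {
      deriv <- tryCatch({
        tp <- theta0; tp[pj] <- theta0[[pj]] + h
        tm <- theta0; tm[pj] <- max(theta0[[pj]] - h, 0)
        (sim_at(tp) - sim_at(tm)) / (tp[[pj]] - tm[[pj]])
      }, error = function(e) NULL)
      if (!is.null(deriv)) break
      h <- h / 2
    }
    if (is.null(deriv))
      stop("sensitivity column for ", pj,
           " failed even after step halving")
    col <- as.vector(deriv)  # stacks variable blocks (column-major)
    if (scaled) col <- col * theta0[[pj]]
    M[, j] <- col
  }
  structure(M, times = times, outputs = out_names,
            parameters = parameters, scaled = scaled, theta = theta0,
            class = c("tme_sensmat", "matrix", "array"))
}

#' Singular value decomposition of a sensitivity matrix
#'
#' Thin SVD `M = U Sigma V^T`; the principal global sensitivity values are
#' `S_ij = sigma_i * V_ji`, so that the first-order response to a parameter
#' perturbation `dk` is `dX = sum_ij S_ij dk_j U_i = U S dk`.
#'
#' @param M a [sensitivity_matrix()].
#' @return Object of class `"tme_pcgsa"`: list with `u`, `d` (singular
#'   values, descending), `v`, `S` (rows = principal components, columns =
#'   parameters) and the matrix attributes.
#' @export
pc_decompose <- function(M) {
  if (any(!is.finite(M))) stop("sensitivity matrix has non-finite entries")
  sv <- svd(M)
  S <- diag(sv$d, length(sv$d)) %*% t(sv$v)
  colnames(S) <- colnames(M)
  structure(list(u = sv$u, d = sv$d, v = sv$v, S = S,
                 times = attr(M, "times"), outputs = attr(M, "outputs"),
                 parameters = attr(M, "parameters"),
                 theta = attr(M, "theta")),
            class = "tme_pcgsa")
}

#' @export
print.tme_pcgsa <- function(x, ...) {
  cat("PC global sensitivity decomposition: ", nrow(x$u), " x ",
      length(x$parameters), " Jacobian, top singular values: ",
      paste(format(head(x$d, 5), digits = 3), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' First-order response predicted by the decomposition
#'
#' @param dec a [pc_decompose()] result.
#' @param dk named or positional parameter perturbation vector.
#' @return Stacked response vector `M %*% dk` (same row order as the
#'   sensitivity matrix).
#' @export
linear_response <- function(dec, dk) {
  stopifnot(inherits(dec, "tme_pcgsa"))
  if (!is.null(names(dk))) dk <- dk[dec$parameters]
  as.vector(dec$u %*% (dec$S %*% dk))
}

#' Number of principal components above a spectrum cutoff
#'
#' Normalizes the singular values by the largest and returns the largest
#' index whose normalized value still reaches `cutoff` (default 20%).
#'
#' @param dec a [pc_decompose()] result.
#' @param cutoff fraction of the leading singular value, in (0, 1).
#' @return Integer PC count.
#' @export
singular_spectrum <- function(dec, cutoff = 0.2) {
  stopifnot(inherits(dec, "tme_pcgsa"))
  if (!(cutoff > 0 && cutoff < 1)) stop("cutoff must lie in (0, 1)")
  if (max(dec$d) <= 0) stop("degenerate spectrum: all singular values zero")
  rel <- dec$d / dec$d[1]
  max(which(rel >= cutoff))
}

#' Thresholded variable/time sensitivity map
#'
#' For each retained principal component, the sigma-scaled loadings
#' `sigma_i * U_i` are reshaped to (time x output variable); entries whose
#' magnitude reaches `threshold` times the global maximum over all retained
#' PCs, variables and times are reported, sorted by magnitude.
#'
#' @param dec a [pc_decompose()] result.
#' @param threshold fraction of the global maximum magnitude.
#' @param n_pc number of PCs retained (default: [singular_spectrum()] at
#'   the 20% cutoff).
#' @return `data.frame` with columns `pc`, `variable`, `time`, `loading`
#'   (signed), `magnitude`.
#' @export
variable_heatmap <- function(dec, threshold = 0.2, n_pc = NULL) {
  stopifnot(inherits(dec, "tme_pcgsa"))
  n_pc <- n_pc %||% singular_spectrum(dec)
  n <- length(dec$times); K <- length(dec$outputs)
  entries <- do.call(rbind, lapply(seq_len(n_pc), function(i) {
    load_i <- dec$d[i] * dec$u[, i]
    data.frame(pc = i,
               variable = rep(dec$outputs, each = n),
               time = rep(dec$times, K),
               loading = load_i)
  }))
  entries$magnitude <- abs(entries$loading)
  gmax <- max(entries$magnitude)
  out <- entries[entries$magnitude >= threshold * gmax, ]
  out[order(-out$magnitude), ]
}

#' Sensitivity of a scalar output to every parameter
#'
#' Builds the sensitivity matrix of one scalar series (cancer, total immune
#' cells or total cells), takes its first principal component — for a single
#' output the PC sensitivity and the classical global sensitivity coincide —
#' and reports signed first-PC sensitivities `S_1j`, oriented so that a
#' positive value means increasing the parameter raises the output overall.
#'
#' @param output one of `"cancer"`, `"total_immune"`, `"total_cells"`.
#' @param params,hyp,x0,times,... passed to [sensitivity_matrix()].
#' @return `data.frame` (parameter, sensitivity), ordered by decreasing
#'   magnitude, with the decomposition attached as attribute `"pcgsa"`.
#' @export
scalar_sensitivity <- function(output = c("cancer", "total_immune",
                                          "total_cells"),
                               params, hyp = hypoxia_params(), x0,
                               times = seq(0, 150, by = 1), ...) {
  output <- match.arg(output)
  M <- sensitivity_matrix(params, hyp, x0 = x0, times = times,
                          outputs = output, ...)
  dec <- pc_decompose(M)
  s1 <- dec$S[1, ]
  # orient the first PC so its time-course points "upward" overall
  if (sum(dec$u[, 1]) < 0) s1 <- -s1
  out <- data.frame(parameter = dec$parameters, sensitivity = unname(s1))
  out <- out[order(-abs(out$sensitivity)), ]
  rownames(out) <- NULL
  attr(out, "pcgsa") <- dec
  out
}

#' Top sensitive parameters of a scalar output
#'
#' @param sens result of [scalar_sensitivity()].
#' @param n how many parameters to keep (zero-sensitivity parameters are
#'   never reported).
#' @return Head of the ranked table.
#' @export
top_sensitivities <- function(sens, n = 10) {
  head(sens[sens$sensitivity != 0, ], n)
}

#' Parameter perturbation experiment
#'
#' Re-simulates the model with one parameter perturbed by each fraction in
#' `deltas` (clipped to the \[0, 2\] estimation box with a warning) and
#' returns the cancer and total-immune observable series of the family
#' together with their pointwise min/max envelope.
#'
#' @param param parameter name (registry or hypoxia shape).
#' @param deltas perturbation fractions, e.g. `c(-0.1, 0.1)` for +/-10%.
#' @param params,hyp,x0,times as in [tme_simulate()].
#' @return Object of class `"tme_perturbation"`: list with `param`,
#'   `deltas`, `baseline` (observables data.frame), `family` (list of
#'   observables data.frames) and `envelope` (data.frame with min/max
#'   columns for cancer and total immune cells).
#' @export
perturbation_experiment <- function(param, deltas, params,
                                    hyp = hypoxia_params(), x0,
                                    times = seq(0, 150, by = 1)) {
  theta0 <- tme_extended_params(params, hyp)
  if (!param %in% names(theta0)) stop("unknown parameter: ", param)
  base <- tme_observables(tme_simulate(params, hyp, x0 = x0, times = times))
  family <- lapply(deltas, function(d) {
    value <- theta0[[param]] * (1 + d)
    if (value < 0 || value > 2) {
      warning("perturbed ", param, " clipped to the [0, 2] box")
      value <- min(max(value, 0), 2)
    }
    th <- theta0; th[param] <- value
    sp <- tme_split_params(th)
    tme_observables(tme_simulate(sp$params, sp$hyp, x0 = x0, times = times))
  })
  names(family) <- paste0("delta_", deltas)
  cancer <- sapply(family, `[[`, "cancer")
  immune <- sapply(family, `[[`, "total_immune")
  cancer <- matrix(cancer, nrow = length(times))
  immune <- matrix(immune, nrow = length(times))
  env <- data.frame(
    t_days = times,
    cancer_min = apply(cancer, 1, min), cancer_max = apply(cancer, 1, max),
    immune_min = apply(immune, 1, min), immune_max = apply(immune, 1, max))
  structure(list(param = param, deltas = deltas, baseline = base,
                 family = family, envelope = env),
            class = "tme_perturbation")
}

#' @export
print.tme_perturbation <- function(x, ...) {
  cat("Perturbation of ", x$param, " by ",
      paste(sprintf("%+.0f%%", 100 * x$deltas), collapse = ", "),
      ": ", length(x$family), " trajectories on [",
      min(x$envelope$t_days), ", ", max(x$envelope$t_days), "] days\n",
      sep = "")
  invisible(x)
}

#' @export
plot.tme_perturbation <- function(x, which = c("cancer", "total_immune"),
                                  ...) {
  which <- match.arg(which)
  lo <- if (which == "cancer") x$envelope$cancer_min else x$envelope$immune_min
  hi <- if (which == "cancer") x$envelope$cancer_max else x$envelope$immune_max
  base <- x$baseline[[which]]
  t <- x$envelope$t_days
  plot(t, base, type = "n", ylim = range(lo, hi, base),
       xlab = "time (days)", ylab = which, ...)
  polygon(c(t, rev(t)), c(lo, rev(hi)), col = adjustcolor(4, 0.3),
          border = NA)
  lines(t, base, lwd = 2)
  invisible(x)
}
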