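# small sparse system reused across the sensitivity tests
sens_setup <- function(seed = 41) {
  cfg <- synth_config(seed = seed, n_mice = 1,
                      active = c("lambda_A", "delta_A", "A0", "lambda_C",
                                 "delta_C", "C0", "lambda_CA", "lambda_HC",
                                 "delta_H", "lambda_VA", "delta_V"))
  truth <- sample_ground_truth(cfg)
  list(truth = truth, x0 = default_x0())
}

test_that("a parameter multiplying an absent variable gives a zero column", {
  st <- sens_setup()
  # activated dendritic cells stay identically zero in this sparse system
  x0 <- st$x0; x0["D"] <- 0; x0["DN"] <- 0
  M <- sensitivity_matrix(st$truth, x0 = x0, times = seq(0, 30, 10),
                          parameters = c("delta_DC", "lambda_A"))
  expect_true(all(M[, "delta_DC"] == 0))
  expect_gt(max(abs(M[, "lambda_A"])), 0)
})

test_that("finite differences match the closed-form derivative of linear decay", {
  # pure cancer decay: C' = -delta_C * C gives dC(t)/d delta_C = -t C(t)
  k <- 0.21
  p <- tme_params(c(delta_C = k, EN0 = 1, C0 = 1, A0 = 1))
  x0 <- tme_state(C = 1)
  times <- seq(0, 40, 5)
  M <- sensitivity_matrix(p, x0 = x0, times = times,
                          parameters = "delta_C", scaled = FALSE)
  block <- M[(which(tme_state_names() == "C") - 1) * length(times) +
               seq_along(times), 1]
  expect_equal(block, -times * exp(-k * times), tolerance = 1e-6)
})

test_that("finite differences agree with the forward sensitivity ODE", {
  # two-state toy inside the model: logistic adipocytes feeding VEGF;
  # augmented system for s = dx/d lambda_A solved alongside the states
  la <- 0.3; da <- 0.1; A0 <- 1.2; lva <- 0.5; dv <- 0.2
  p <- tme_params(c(lambda_A = la, delta_A = da, A0 = A0,
                    lambda_VA = lva, delta_V = dv, EN0 = 1, C0 = 1))
  x0 <- tme_state(A = 0.2, V = 0.1)
  times <- seq(0, 60, 3)
  aug <- function(t, y, parms) {
    A <- y[1]; V <- y[2]; sA <- y[3]; sV <- y[4]
    dA <- la * (1 - A / A0) * A - da * A
    dV <- lva * A - dv * V
    # d/d lambda_A of the A and V equations
    dsA <- (1 - A / A0) * A + (la * (1 - 2 * A / A0) - da) * sA
    dsV <- lva * sA - dv * sV
    list(c(dA, dV, dsA, dsV))
  }
  sol <- deSolve::ode(c(0.2, 0.1, 0, 0), times, aug, NULL,
                      rtol = 1e-10, atol = 1e-12)
  M <- sensitivity_matrix(p, x0 = x0, times = times,
                          parameters = "lambda_A", scaled = FALSE)
  n <- length(times)
  blockA <- M[(which(tme_state_names() == "A") - 1) * n + seq_len(n), 1]
  blockV <- M[(which(tme_state_names() == "V") - 1) * n + seq_len(n), 1]
  expect_equal(blockA, unname(sol[, 4]), tolerance = 1e-5)
  expect_equal(blockV, unname(sol[, 5]), tolerance = 1e-5)
})

test_that("the SVD factors reconstruct the matrix and stay orthonormal", {
  st <- sens_setup()
  M <- sensitivity_matrix(st$truth, x0 = st$x0, times = seq(0, 60, 6),
                          parameters = c("lambda_A", "delta_A", "lambda_C",
                                         "delta_C", "lambda_HC", "delta_H",
                                         "ox_crit2"))
  dec <- pc_decompose(M)
  recon <- dec$u %*% diag(dec$d) %*% t(dec$v)
  expect_lt(norm(recon - M, "F"), 1e-10 * max(norm(M, "F"), 1))
  expect_equal(crossprod(dec$u), diag(ncol(dec$u)), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(crossprod(dec$v), diag(ncol(dec$v)), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_false(is.unsorted(rev(dec$d)))
  # S_ij = sigma_i V_ji
  expect_equal(dec$S, diag(dec$d) %*% t(dec$v), ignore_attr = TRUE)
  # rank-1 case: a single non-zero singular value
  r1 <- pc_decompose(structure(outer(1:6, c(2, -1, 3)),
                               times = 1:2, outputs = c("a", "b", "c"),
                               parameters = paste0("p", 1:3),
                               class = c("tme_sensmat", "matrix",
                                         "array")))
  expect_equal(sum(r1$d > 1e-10 * r1$d[1]), 1L)
})

test_that("the linearization matches direct perturbation with vanishing error", {
  st <- sens_setup()
  pars <- c("lambda_A", "delta_A", "lambda_C", "lambda_HC")
  times <- seq(0, 60, 6)
  M <- sensitivity_matrix(st$truth, x0 = st$x0, times = times,
                          parameters = pars, scaled = FALSE)
  dec <- pc_decompose(M)
  dir_vec <- c(1, -0.6, 0.8, 0.5)
  base <- tme_simulate(st$truth, x0 = st$x0, times = times)$states
  rel_err <- sapply(c(1e-2, 1e-3, 1e-4), function(eps) {
    dk <- eps * dir_vec
    p2 <- st$truth; p2[pars] <- pmax(p2[pars] + dk, 0)
    pert <- tme_simulate(tme_params(unclass(p2)), x0 = st$x0,
                         times = times)$states
    truth_resp <- as.vector(pert - base)
    lin <- linear_response(dec, dk)
    sqrt(sum((lin - truth_resp)^2)) / sqrt(sum(truth_resp^2))
  })
  expect_true(all(diff(rel_err) < 0))  # shrinks with the step
  expect_lt(rel_err[3], 1e-2)
})

test_that("the singular spectrum count is monotone in the cutoff", {
  fake <- function(d) {
    dec <- list(d = d, parameters = paste0("p", seq_along(d)))
    class(dec) <- "tme_pcgsa"
    dec
  }
  expect_equal(singular_spectrum(fake(c(1, 0.5, 0.19))), 2L)
  expect_equal(singular_spectrum(fake(1)), 1L)
  expect_error(singular_spectrum(fake(c(1, 0.5)), cutoff = 0), "0, 1")
  expect_error(singular_spectrum(fake(c(0, 0))), "degenerate")
  d <- c(1, 0.7, 0.45, 0.3, 0.12, 0.03)
  cuts <- c(0.9, 0.6, 0.4, 0.25, 0.1, 0.02)
  counts <- vapply(cuts, function(ct) singular_spectrum(fake(d), ct),
                   integer(1))
  expect_false(is.unsorted(counts))
})

test_that("the variable map reports the dominant variable above threshold", {
  st <- sens_setup()
  M <- sensitivity_matrix(st$truth, x0 = st$x0, times = seq(0, 60, 6),
                          parameters = c("lambda_A", "delta_A"))
  dec <- pc_decompose(M)
  hm <- variable_heatmap(dec, threshold = 0.2, n_pc = 1)
  expect_true(all(c("pc", "variable", "time", "magnitude") %in% names(hm)))
  expect_false(is.unsorted(rev(hm$magnitude)))
  # threshold 1 keeps only the single global maximum
  hm1 <- variable_heatmap(dec, threshold = 1, n_pc = 1)
  expect_equal(nrow(hm1), 1L)
  # in this block only adipocyte-coupled variables can appear, never e.g.
  # naive T cells, which the active parameters do not touch
  expect_false("TN" %in% hm$variable)
  expect_true(hm1$variable %in% c("A", "V", "C", "H", "IL6", "Ox"))
})

test_that("scalar sensitivities carry the sign of a direct perturbation", {
  st <- sens_setup()
  sens <- scalar_sensitivity("cancer", st$truth, x0 = st$x0,
                             times = seq(0, 60, 6),
                             parameters = c("lambda_C", "delta_C",
                                            "lambda_A", "delta_DC"))
  expect_gt(sens$sensitivity[sens$parameter == "lambda_C"], 0)
  expect_lt(sens$sensitivity[sens$parameter == "delta_C"], 0)
  # decoupled parameter: exactly zero and excluded from the top list
  expect_equal(sens$sensitivity[sens$parameter == "delta_DC"], 0)
  expect_false("delta_DC" %in% top_sensitivities(sens)$parameter)
  # signs agree with +/-10% perturbations of the output integral
  for (pn in c("lambda_C", "delta_C", "lambda_A")) {
    pe <- perturbation_experiment(pn, c(-0.1, 0.1), st$truth,
                                  x0 = st$x0, times = seq(0, 60, 6))
    direct <- sum(pe$family[[2]]$cancer - pe$family[[1]]$cancer)
    expect_equal(sign(direct),
                 sign(sens$sensitivity[sens$parameter == pn]))
  }
})

test_that("perturbation envelopes behave by construction", {
  st <- sens_setup()
  pe0 <- perturbation_experiment("lambda_VA", 0, st$truth, x0 = st$x0,
                                 times = seq(0, 40, 4))
  expect_equal(pe0$envelope$cancer_min, pe0$baseline$cancer)
  expect_equal(pe0$envelope$cancer_max, pe0$baseline$cancer)
  pe <- perturbation_experiment("lambda_A", c(-0.1, 0.1), st$truth,
                                x0 = st$x0, times = seq(0, 40, 4))
  # identical initial conditions: zero envelope width at t = 0
  expect_equal(pe$envelope$cancer_min[1], pe$envelope$cancer_max[1])
  expect_true(all(pe$envelope$cancer_min <= pe$baseline$cancer + 1e-10))
  expect_true(all(pe$envelope$cancer_max >= pe$baseline$cancer - 1e-10))
  expect_warning(
    perturbation_experiment("ox_crit1", 100, st$truth, x0 = st$x0,
                            times = c(0, 5)), "clipped")
})
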