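test_that("the system has 18 coupled equations over the parameter registry", {
  expect_length(tme_state_names(), 18L)
  expect_length(tme_rhs(0, random_state(), random_params()), 18L)
  expect_error(tme_rhs(0, rep(0.1, 17), random_params()), "18")
})

test_that("only innate production survives at the zero state", {
  p <- random_params()
  # switch off all pure hypoxia sources (f1(0) = 1 would otherwise feed in)
  p[c("lambda_VOx", "lambda_TrOx", "lambda_DOx", "lambda_IL10Ox",
      "lambda_IL6Ox", "lambda_IL6MOx")] <- 0
  d <- tme_rhs(0, rep(0, 18), p)
  expect_equal(unname(d[c("TN", "DN", "MN")]),
               unname(p[c("A_TN", "A_DN", "A_MN")]))
  expect_true(all(d[setdiff(tme_state_names(), c("TN", "DN", "MN"))] == 0))
})

test_that("an isolated adipocyte block reduces to the bare logistic law", {
  p <- tme_params(c(lambda_A = 0.7, delta_A = 0.2, A0 = 1.3,
                    EN0 = 1, C0 = 1))
  a <- 0.4
  d <- tme_rhs(0, tme_state(A = a), p)
  expect_equal(unname(d["A"]), 0.7 * (1 - a / 1.3) * a - 0.2 * a)
  expect_true(all(d[setdiff(tme_state_names(), "A")] == 0))
})

test_that("rhs matches the independent term-table expansion to 1e-12", {
  set.seed(7)
  hyps <- list(hypoxia_params(), hypoxia_params(0.3, 0.05, 2.5))
  for (i in 1:100) {
    s <- random_state()
    p <- random_params()
    hy <- hyps[[1 + i %% 2]]
    expect_equal(tme_rhs(0, s, p, hy), oracle_rhs(s, p, hy),
                 tolerance = 1e-12)
  }
})

test_that("differentiation fluxes balance between naive and activated pools", {
  set.seed(11)
  for (i in 1:25) {
    s <- random_state()
    p <- random_params()
    hy <- hypoxia_params(0.25, 0.03, 4)
    d <- tme_rhs(0, s, p, hy)
    f1 <- hill_hypoxia(s[3], hy$ox_crit1, hy$m)
    f2 <- hill_hypoxia(s[3], hy$ox_crit2, hy$m)
    st <- setNames(s, tme_state_names())
    # remove innate production and death; what is left of dTN must be the
    # negative of the activation influx into Th + Tc + Tr
    tn_act <- d[["TN"]] - p[["A_TN"]] +
      (p[["delta_TN"]] + p[["delta_TNOx"]] * f2) * st[["TN"]]
    th_in <- (p[["lambda_ThH"]] * st[["H"]] + p[["lambda_ThD"]] * st[["D"]] +
                p[["lambda_ThIL12"]] * st[["IL12"]]) * st[["TN"]]
    tc_in <- (p[["lambda_TcD"]] * st[["D"]] +
                p[["lambda_TcIL12"]] * st[["IL12"]]) * st[["TN"]]
    tr_in <- (p[["lambda_TrD"]] * st[["D"]] +
                p[["lambda_TrOx"]] * f1) * st[["TN"]]
    expect_equal(unname(tn_act), unname(-(th_in + tc_in + tr_in)),
                 tolerance = 1e-12)
    dn_act <- d[["DN"]] - p[["A_DN"]] +
      (p[["delta_DN"]] + p[["delta_DNOx"]] * f2) * st[["DN"]]
    d_in <- d[["D"]] + (p[["delta_DC"]] * st[["C"]] + p[["delta_D"]] +
                          p[["delta_DNOx"]] * f2) * st[["D"]]
    expect_equal(unname(dn_act), unname(-d_in), tolerance = 1e-12)
    mn_act <- d[["MN"]] - p[["A_MN"]] + p[["delta_MN"]] * st[["MN"]]
    m_in <- d[["M"]] + p[["delta_M"]] * st[["M"]]
    expect_equal(unname(mn_act), unname(-m_in), tolerance = 1e-12)
  }
})

test_that("zero parameters freeze the trajectory at its initial state", {
  p <- tme_params(default = 0)
  p[c("EN0", "C0", "A0")] <- 1
  x0 <- random_state()
  tr <- tme_simulate(p, x0 = x0, times = seq(0, 30, by = 5))
  expect_true(all(abs(sweep(tr$states, 2, x0)) < 1e-9))
})

test_that("the isolated adipocyte logistic matches its closed form", {
  p <- tme_params(c(lambda_A = 0.2, delta_A = 0.05, A0 = 1,
                    EN0 = 1, C0 = 1))
  times <- seq(0, 120, by = 1)
  tr <- tme_simulate(p, x0 = tme_state(A = 0.1), times = times)
  r <- 0.2 - 0.05
  K <- 1 * (1 - 0.05 / 0.2)
  closed <- K / (1 + (K / 0.1 - 1) * exp(-r * times))
  expect_equal(unname(tr$states[, "A"]), closed, tolerance = 1e-6)
})

test_that("a constant-source cytokine relaxes to its linear steady state", {
  cval <- 0.8
  p <- tme_params(c(lambda_HC = 0.5, delta_H = 0.3, EN0 = 1, C0 = 1,
                    A0 = 1))
  tr <- tme_simulate(p, x0 = tme_state(C = cval), times = seq(0, 80, 2))
  expect_equal(tr$states[nrow(tr$states), "H"],
               c(H = 0.5 * cval / 0.3), tolerance = 1e-5)
  # C itself has zero dynamics here
  expect_true(all(abs(tr$states[, "C"] - cval) < 1e-8))
})

test_that("compiled and plain-R integration agree", {
  set.seed(21)
  p <- random_params()
  x0 <- random_state()
  t1 <- tme_simulate(p, x0 = x0, times = seq(0, 42, 14))
  t2 <- tme_simulate(p, x0 = x0, times = seq(0, 42, 14),
                     use_compiled = FALSE)
  expect_equal(t1$states, t2$states, tolerance = 1e-7)
})

test_that("trajectories stay non-negative within solver tolerance", {
  set.seed(33)
  for (i in 1:5) {
    p <- random_params()
    tr <- tme_simulate(p, x0 = random_state(), times = seq(0, 150, 2))
    expect_true(all(tr$states > -1e-8))
  }
})

test_that("forcing both hypoxia switches to zero removes every oxygen coupling", {
  # with all hypoxia-dependent rates zeroed, the immune/cancer equations
  # must coincide with the oxygen-independent base model: the oxygen level
  # must not influence any other derivative
  p <- random_params()
  p[c("delta_ENOx", "lambda_VCOx", "lambda_VOx", "delta_TNOx",
      "delta_ThOx", "delta_TcOx", "delta_TrOx", "lambda_TrOx",
      "lambda_DOx", "delta_DNOx", "delta_CTcOx", "delta_COx",
      "lambda_IL10Ox", "lambda_IL6MOx", "lambda_IL6Ox")] <- 0
  s <- random_state()
  s_lo <- s; s_lo[3] <- 0
  s_hi <- s; s_hi[3] <- 1.4
  d_lo <- tme_rhs(0, s_lo, p)
  d_hi <- tme_rhs(0, s_hi, p)
  keep <- setdiff(tme_state_names(), "Ox")
  expect_equal(d_lo[keep], d_hi[keep], tolerance = 1e-12)
})

test_that("observables are the advertised sums", {
  p <- random_params()
  x0 <- rep(0.1, 18)
  tr <- tme_simulate(p, x0 = x0, times = seq(0, 20, 5))
  obs <- tme_observables(tr)
  imm <- c("TN", "Th", "Tc", "Tr", "DN", "D", "MN", "M")
  cells <- c(imm, "EN", "C", "N", "A")
  expect_equal(obs$total_immune, rowSums(tr$states[, imm]))
  expect_equal(obs$total_cells, rowSums(tr$states[, cells]))
  expect_equal(obs$cancer, unname(tr$states[, "C"]))
  # all immune components equal at t = 0 by construction
  expect_equal(obs$total_immune[1], 0.8)
  # a zero trajectory has zero observables
  p0 <- tme_params(); p0[c("EN0", "C0", "A0")] <- 1
  tr0 <- tme_simulate(p0, x0 = rep(0, 18), times = c(0, 5))
  expect_true(all(as.matrix(tme_observables(tr0)[, -1]) == 0))
})

test_that("simulate validates its inputs and reports integration failure", {
  p <- random_params()
  expect_error(tme_simulate(p, x0 = rep(0.1, 17)), "18")
  expect_error(tme_simulate(p, x0 = rep(-0.1, 18)), "non-negative")
  expect_error(tme_simulate(p, x0 = rep(0.1, 18), times = c(5, 1)),
               "ascending")
  pz <- tme_params()  # zero capacities
  expect_error(tme_simulate(pz, x0 = rep(0.1, 18), times = 0:1),
               "capacities")
})
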