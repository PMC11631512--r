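# Independent oracle for the model right-hand side: every equation is
# transcribed as a flat list of mass-action terms (one product each) and
# evaluated by a generic interpreter. This construction is deliberately
# different in structure from the package implementation (no shared
# sub-expressions, no grouping), so sign, sharing and grouping errors in
# either version show up as disagreements.

.term <- function(sign, pars, states = character(), f = NULL,
                  logistic = NULL) {
  list(sign = sign, pars = pars, states = states, f = f,
       logistic = logistic)
}

oracle_terms <- local({
  t <- .term
  list(
    EN = list(
      t(+1, "lambda_VEN", c("V", "EN"), logistic = "EN0"),
      t(-1, "delta_ENIL12", c("IL12", "EN")),
      t(-1, "delta_EN", "EN"),
      t(-1, "delta_ENOx", "EN", f = "f2")),
    V = list(
      t(+1, "lambda_VA", "A"),
      t(+1, "lambda_VM", "M"),
      t(+1, "lambda_VCOx", "C", f = "f1"),
      t(+1, "lambda_VOx", f = "f1"),
      t(-1, "delta_V", "V")),
    Ox = list(
      t(+1, "lambda_OxEN", "EN"),
      t(-1, "delta_1", c("TN", "Ox")), t(-1, "delta_1", c("Th", "Ox")),
      t(-1, "delta_1", c("Tc", "Ox")), t(-1, "delta_1", c("Tr", "Ox")),
      t(-1, "delta_2", c("DN", "Ox")), t(-1, "delta_2", c("D", "Ox")),
      t(-1, "delta_3", c("MN", "Ox")), t(-1, "delta_3", c("M", "Ox")),
      t(-1, "delta_4", c("C", "Ox")), t(-1, "delta_5", c("A", "Ox")),
      t(-1, "delta_6", c("EN", "Ox")), t(-1, "delta_Ox", "Ox")),
    TN = list(
      t(+1, "A_TN"),
      t(-1, "lambda_ThH", c("H", "TN")), t(-1, "lambda_ThD", c("D", "TN")),
      t(-1, "lambda_ThIL12", c("IL12", "TN")),
      t(-1, "lambda_TcD", c("D", "TN")),
      t(-1, "lambda_TcIL12", c("IL12", "TN")),
      t(-1, "lambda_TrD", c("D", "TN")),
      t(-1, "lambda_TrOx", "TN", f = "f1"),
      t(-1, "delta_TN", "TN"), t(-1, "delta_TNOx", "TN", f = "f2")),
    Th = list(
      t(+1, "lambda_ThH", c("H", "TN")), t(+1, "lambda_ThD", c("D", "TN")),
      t(+1, "lambda_ThIL12", c("IL12", "TN")),
      t(-1, "delta_ThTr", c("Tr", "Th")),
      t(-1, "delta_ThIL10", c("IL10", "Th")),
      t(-1, "delta_Th", "Th"), t(-1, "delta_ThOx", "Th", f = "f2")),
    Tc = list(
      t(+1, "lambda_TcD", c("D", "TN")),
      t(+1, "lambda_TcIL12", c("IL12", "TN")),
      t(-1, "delta_TcTr", c("Tr", "Tc")),
      t(-1, "delta_TcIL10", c("IL10", "Tc")),
      t(-1, "delta_Tc", "Tc"), t(-1, "delta_TcOx", "Tc", f = "f2")),
    Tr = list(
      t(+1, "lambda_TrD", c("D", "TN")),
      t(+1, "lambda_TrOx", "TN", f = "f1"),
      t(-1, "delta_Tr", "Tr"), t(-1, "delta_TrOx", "Tr", f = "f2")),
    DN = list(
      t(+1, "A_DN"),
      t(-1, "lambda_DC", c("C", "DN")), t(-1, "lambda_DH", c("H", "DN")),
      t(-1, "lambda_DOx", "DN", f = "f1"),
      t(-1, "delta_DN", "DN"), t(-1, "delta_DNOx", "DN", f = "f2")),
    D = list(
      t(+1, "lambda_DC", c("C", "DN")), t(+1, "lambda_DH", c("H", "DN")),
      t(+1, "lambda_DOx", "DN", f = "f1"),
      t(-1, "delta_DC", c("C", "D")), t(-1, "delta_D", "D"),
      t(-1, "delta_DNOx", "D", f = "f2")),
    MN = list(
      t(+1, "A_MN"),
      t(-1, "lambda_MIL10", c("IL10", "MN")),
      t(-1, "lambda_MIL12", c("IL12", "MN")),
      t(-1, "lambda_MTh", c("Th", "MN")),
      t(-1, "delta_MN", "MN")),
    M = list(
      t(+1, "lambda_MIL10", c("IL10", "MN")),
      t(+1, "lambda_MIL12", c("IL12", "MN")),
      t(+1, "lambda_MTh", c("Th", "MN")),
      t(-1, "delta_M", "M")),
    C = list(
      t(+1, "lambda_C", "C", logistic = "C0"),
      t(+1, "lambda_CIL6", c("IL6", "C"), logistic = "C0"),
      t(+1, "lambda_CA", c("A", "C"), logistic = "C0"),
      t(-1, "delta_CTc", c("Tc", "C")),
      t(-1, "delta_CTcOx", c("Tc", "C"), f = "f1"),
      t(-1, "delta_COx", "C", f = "f2"),
      t(-1, "delta_C", "C")),
    N = list(
      t(+1, c("alpha_NC", "delta_CTc"), c("Tc", "C")),
      t(+1, c("alpha_NC", "delta_CTcOx"), c("Tc", "C"), f = "f1"),
      t(+1, c("alpha_NC", "delta_COx"), "C", f = "f2"),
      t(+1, c("alpha_NC", "delta_C"), "C"),
      t(-1, "delta_N", "N")),
    A = list(
      t(+1, "lambda_A", "A", logistic = "A0"),
      t(-1, "delta_A", "A")),
    H = list(
      t(+1, "lambda_HD", "D"), t(+1, "lambda_HN", "N"),
      t(+1, "lambda_HM", "M"), t(+1, "lambda_HTc", "Tc"),
      t(+1, "lambda_HC", "C"), t(-1, "delta_H", "H")),
    IL12 = list(
      t(+1, "lambda_IL12M", "M"), t(+1, "lambda_IL12D", "D"),
      t(-1, "delta_IL12", "IL12")),
    IL10 = list(
      t(+1, "lambda_IL10M", "M"), t(+1, "lambda_IL10D", "D"),
      t(+1, "lambda_IL10Tr", "Tr"), t(+1, "lambda_IL10Th", "Th"),
      t(+1, "lambda_IL10Tc", "Tc"), t(+1, "lambda_IL10C", "C"),
      t(+1, "lambda_IL10Ox", f = "f1"),
      t(-1, "delta_IL10", "IL10")),
    IL6 = list(
      t(+1, "lambda_IL6A", "A"), t(+1, "lambda_IL6M", "M"),
      t(+1, "lambda_IL6MOx", "M", f = "f1"),
      t(+1, "lambda_IL6D", "D"),
      t(+1, "lambda_IL6Ox", f = "f1"),
      t(-1, "delta_IL6", "IL6"))
  )
})

.logistic_state <- c(EN0 = "EN", C0 = "C", A0 = "A")

oracle_rhs <- function(state, params, hyp) {
  s <- stats::setNames(as.numeric(state), tme_state_names())
  p <- unclass(params)
  hv <- function(crit) crit^hyp$m / (crit^hyp$m + s[["Ox"]]^hyp$m)
  fvals <- c(f1 = hv(hyp$ox_crit1), f2 = hv(hyp$ox_crit2))
  vapply(tme_state_names(), function(var) {
    sum(vapply(oracle_terms[[var]], function(tm) {
      val <- tm$sign * prod(p[tm$pars])
      if (length(tm$states) > 0) val <- val * prod(s[tm$states])
      if (!is.null(tm$f)) val <- val * fvals[[tm$f]]
      if (!is.null(tm$logistic))
        val <- val * (1 - s[[.logistic_state[[tm$logistic]]]] /
                        p[[tm$logistic]])
      val
    }, numeric(1)))
  }, numeric(1))
}

# random non-negative state and admissible random parameter set
random_state <- function() stats::runif(18, 0, 1.5)
random_params <- function() {
  th <- stats::runif(88, 0, 2)
  names(th) <- tme_parameter_names()
  th[c("EN0", "C0", "A0")] <- pmax(th[c("EN0", "C0", "A0")], 0.2)
  tme_params(th)
}
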