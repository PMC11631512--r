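# Parameter registry for the 18-state tumour microenvironment model.
#
# Naming follows the field's mass-action conventions: lambda_XY is the rate at
# which Y promotes production/proliferation of X, delta_XY the rate Y inhibits
# X, delta_XYOx an inhibition proportional to a hypoxia switch, delta_X a
# natural decay/death rate, A_X an innate production rate, delta_1..delta_6 the
# oxygen consumption rates of the six grouped cell types, and EN0/C0/A0 the
# logistic carrying capacities of endothelial cells, cancer and adipocytes.
# Rates shared between equations (e.g. the naive T-cell differentiation rates,
# which appear as outflux in TN and influx in Th/Tc/Tr) exist exactly once.

.tme_param_names <- c(
  ## endothelial cells (EN)
  "lambda_VEN", "delta_ENIL12", "delta_EN", "delta_ENOx", "EN0",
  ## VEGF (V)
  "lambda_VA", "lambda_VM", "lambda_VCOx", "lambda_VOx", "delta_V",
  ## oxygen (Ox)
  "lambda_OxEN", "delta_1", "delta_2", "delta_3", "delta_4", "delta_5",
  "delta_6", "delta_Ox",
  ## naive T cells (TN)
  "A_TN", "delta_TN", "delta_TNOx",
  ## helper T cells (Th)
  "lambda_ThH", "lambda_ThD", "lambda_ThIL12", "delta_ThTr", "delta_ThIL10",
  "delta_Th", "delta_ThOx",
  ## cytotoxic T cells (Tc)
  "lambda_TcD", "lambda_TcIL12", "delta_TcTr", "delta_TcIL10", "delta_Tc",
  "delta_TcOx",
  ## regulatory T cells (Tr)
  "lambda_TrD", "lambda_TrOx", "delta_Tr", "delta_TrOx",
  ## naive dendritic cells (DN)
  "A_DN", "lambda_DC", "lambda_DH", "lambda_DOx", "delta_DN", "delta_DNOx",
  ## activated dendritic cells (D)
  "delta_DC", "delta_D",
  ## naive macrophages (MN)
  "A_MN", "lambda_MIL10", "lambda_MIL12", "lambda_MTh", "delta_MN",
  ## activated macrophages (M)
  "delta_M",
  ## cancer cells (C)
  "lambda_C", "lambda_CIL6", "lambda_CA", "C0", "delta_CTc", "delta_CTcOx",
  "delta_COx", "delta_C",
  ## necrotic cells (N)
  "alpha_NC", "delta_N",
  ## adipocytes (A)
  "lambda_A", "A0", "delta_A",
  ## HMGB1 (H)
  "lambda_HD", "lambda_HN", "lambda_HM", "lambda_HTc", "lambda_HC", "delta_H",
  ## IL-12
  "lambda_IL12M", "lambda_IL12D", "delta_IL12",
  ## IL-10
  "lambda_IL10M", "lambda_IL10D", "lambda_IL10Tr", "lambda_IL10Th",
  "lambda_IL10Tc", "lambda_IL10C", "lambda_IL10Ox", "delta_IL10",
  ## IL-6
  "lambda_IL6A", "lambda_IL6M", "lambda_IL6MOx", "lambda_IL6D", "lambda_IL6Ox",
  "delta_IL6"
)

.tme_hypoxia_names <- c("ox_crit1", "ox_crit2", "m_hill")
.tme_capacity_names <- c("EN0", "C0", "A0")

#' Names of the model parameters
#'
#' The estimated-parameter registry holds every distinct rate constant and
#' carrying capacity appearing in the 18 model equations, each shared symbol
#' counted once. With `extended = TRUE` the three hypoxia shape parameters
#' (`ox_crit1`, `ox_crit2`, `m_hill`) are appended, giving the parameter axis
#' used by the sensitivity analysis.
#'
#' @param extended logical; append the hypoxia shape parameters.
#' @return Character vector of parameter names, in registry order.
#' @export
#' @examples
#' length(tme_parameter_names())
tme_parameter_names <- function(extended = FALSE) {
  if (extended) c(.tme_param_names, .tme_hypoxia_names) else .tme_param_names
}

#' Construct a model parameter set
#'
#' Builds the full named vector of non-dimensional rate constants and carrying
#' capacities. Unnamed construction fills every entry with `default`; a named
#' vector or list overrides individual entries. All values must be finite and
#' non-negative (the estimation bounds are \[0, 2\], but the container itself
#' only enforces non-negativity).
#'
#' @param values named numeric vector or list of parameter values to set.
#' @param default value used for parameters not named in `values`.
#' @return A named numeric vector of class `"tme_params"`.
#' @export
#' @examples
#' p <- tme_params(c(lambda_A = 0.2, delta_A = 0.05, A0 = 1))
#' p["lambda_A"]
tme_params <- function(values = NULL, default = 0) {
  stopifnot(is.numeric(default), length(default) == 1L)
  p <- setNames(rep(default, length(.tme_param_names)), .tme_param_names)
  if (!is.null(values)) {
    values <- unlist(values)
    bad <- setdiff(names(values), .tme_param_names)
    if (length(bad) > 0L)
      stop("unknown parameter name(s): ", paste(bad, collapse = ", "))
    p[names(values)] <- values
  }
  validate_tme_params(p)
  structure(p, class = "tme_params")
}

validate_tme_params <- function(p) {
  if (length(p) != length(.tme_param_names) ||
      !identical(names(p), .tme_param_names))
    stop("parameter set must contain exactly the ",
         length(.tme_param_names), " registry names, in order")
  if (any(!is.finite(p))) stop("parameter values must be finite")
  if (any(p < 0)) stop("parameter values must be non-negative")
  invisible(p)
}

#' @export
print.tme_params <- function(x, ...) {
  cat("Tumour microenvironment model parameters (", length(x), " entries)\n",
      sep = "")
  nz <- sum(x != 0)
  cat("  non-zero: ", nz, "; range [", format(min(x)), ", ",
      format(max(x)), "]\n", sep = "")
  invisible(x)
}

#' Hypoxia switch parameters
#'
#' The model uses two decreasing Hill switches of the non-dimensional oxygen
#' level: `f1` with threshold `ox_crit1` marks the transition from normoxia to
#' mild hypoxia (HIF-pathway activation, 0.1--1% O2), `f2` with threshold
#' `ox_crit2` the transition from mild to severe hypoxia (cell-cycle arrest
#' and hypoxic death, below 0.1% O2). `m` is the Hill-like exponent governing
#' how sharply each switch turns on. Defaults place the thresholds at 1% and
#' 0.1% O2 on the week-6 oxygen scale (50 000 ppm = 3.125 mol/l = 1): 1% O2 is
#' 10 000 ppm = 0.625 mol/l, i.e. 0.2 non-dimensional, and 0.1% is 0.02.
#'
#' @param ox_crit1 non-dimensional oxygen threshold, normoxia to mild hypoxia.
#' @param ox_crit2 non-dimensional oxygen threshold, mild to severe hypoxia.
#' @param m Hill-like exponent (> 0).
#' @return A list of class `"tme_hypoxia"`.
#' @export
hypoxia_params <- function(ox_crit1 = 0.2, ox_crit2 = 0.02, m = 5) {
  if (!is.numeric(ox_crit1) || !is.numeric(ox_crit2) || !is.numeric(m) ||
      length(ox_crit1) != 1L || length(ox_crit2) != 1L || length(m) != 1L)
    stop("hypoxia parameters must be numeric scalars")
  if (!is.finite(ox_crit1) || !is.finite(ox_crit2) || !is.finite(m))
    stop("hypoxia parameters must be finite")
  if (ox_crit2 <= 0) stop("ox_crit2 must be positive")
  if (ox_crit1 <= ox_crit2) stop("ox_crit1 must exceed ox_crit2")
  if (m <= 0) stop("Hill exponent m must be positive")
  structure(list(ox_crit1 = ox_crit1, ox_crit2 = ox_crit2, m = m),
            class = "tme_hypoxia")
}

#' @export
print.tme_hypoxia <- function(x, ...) {
  cat("Hypoxia switches: ox_crit1 =", x$ox_crit1, "(mild), ox_crit2 =",
      x$ox_crit2, "(severe), m =", x$m, "\n")
  invisible(x)
}

# Combined 91-entry vector (registry + hypoxia shapes) in the order the
# compiled right-hand side and the sensitivity parameter axis use.
tme_extended_params <- function(params, hyp) {
  validate_tme_params(params)
  stopifnot(inherits(hyp, "tme_hypoxia"))
  c(unclass(params),
    setNames(c(hyp$ox_crit1, hyp$ox_crit2, hyp$m), .tme_hypoxia_names))
}

# Inverse of tme_extended_params().
tme_split_params <- function(theta) {
  stopifnot(identical(names(theta), tme_parameter_names(extended = TRUE)))
  list(params = tme_params(theta[.tme_param_names]),
       hyp = hypoxia_params(theta[["ox_crit1"]], theta[["ox_crit2"]],
                            theta[["m_hill"]]))
}

#' Read / write a parameter set as flat JSON
#'
#' Parameter sets are serialized as a flat JSON object keyed by the registry
#' names (`"lambda_VEN"`, `"delta_ENIL12"`, `"A_TN"`, `"delta_1"` ...,
#' `"EN0"`, `"C0"`, `"A0"`, `"alpha_NC"`), optionally including the hypoxia
#' shape keys `"ox_crit1"`, `"ox_crit2"`, `"m_hill"`.
#'
#' @param params a `tme_params` vector.
#' @param path file path.
#' @param hyp optional `tme_hypoxia` object to serialize alongside.
#' @return `read_params_json` returns a list with elements `params` and `hyp`
#'   (`hyp` is `NULL` when the file carries no hypoxia keys).
#' @export
write_params_json <- function(params, path, hyp = NULL) {
  validate_tme_params(params)
  out <- as.list(unclass(params))
  if (!is.null(hyp)) {
    stopifnot(inherits(hyp, "tme_hypoxia"))
    out <- c(out, list(ox_crit1 = hyp$ox_crit1, ox_crit2 = hyp$ox_crit2,
                       m_hill = hyp$m))
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params_json
#' @export
read_params_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw <- unlist(raw)
  hyp <- NULL
  if (all(.tme_hypoxia_names %in% names(raw))) {
    hyp <- hypoxia_params(raw[["ox_crit1"]], raw[["ox_crit2"]],
                          raw[["m_hill"]])
    raw <- raw[setdiff(names(raw), .tme_hypoxia_names)]
  }
  list(params = tme_params(raw[.tme_param_names]), hyp = hyp)
}
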