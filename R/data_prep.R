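# Cell-count data preparation: caliper geometry, per-gram yield scaling,
# fraction-to-count conversion, the cell-size volume budget for non-immune
# cells, oxygen unit conversion and non-dimensionalization.

#' Caliper tumour volume
#'
#' Orthogonal caliper measurements give the volume convention `L * W^2 / 2`
#' with `L` the long and `W` the short diameter (mm).
#'
#' @param L,W diameters in mm (> 0).
#' @return Volume in mm^3.
#' @export
#' @examples
#' caliper_volume(10, 10)  # 500
caliper_volume <- function(L, W) {
  if (any(L <= 0) || any(W <= 0)) stop("diameters must be positive")
  L * W^2 / 2
}

#' Diameter from a caliper volume
#'
#' Assuming a near-spherical tumour (`L` close to `W`), a caliper volume
#' `V = L^3 / 2` inverts to a diameter `(2 V)^(1/3)`, truncated to 2
#' decimals (the truncation, rather than rounding, reproduces the published
#' stage diameters: volumes 200/400/700/1400 mm^3 give 7.36, 9.28, 11.18
#' and 14.09 mm, where rounding would give 7.37 and 11.19).
#'
#' @param V caliper volume(s) in mm^3 (> 0).
#' @return Diameter in mm, truncated to 2 decimals.
#' @export
diameter_from_caliper_volume <- function(V) {
  if (any(V <= 0)) stop("volume must be positive")
  trunc(round(100 * (2 * V)^(1 / 3), 9)) / 100
}

# Truncate (not round) to a number of significant figures; ties against
# floating-point representation noise are settled by a 1e-9 pre-round.
trunc_signif <- function(x, digits) {
  out <- x
  nz <- is.finite(x) & x != 0
  e <- floor(log10(abs(x[nz])))
  pow <- e - digits + 1
  out[nz] <- trunc(round(x[nz] / 10^pow, 9)) * 10^pow
  out
}

#' Per-stage cell count from a per-gram yield
#'
#' The reference protocol extracts a given cell yield from 1 g of tumour
#' tissue pooled from two tumours of about 10 mm diameter, i.e. half the
#' yield per 10 mm tumour. A stage with (rounded) diameter `d_stage` then
#' carries `(yield_per_gram / 2) * (d_stage / 10)` cells, truncated to
#' `sigfigs` significant figures. Means are reported to 3 significant
#' figures and standard deviations to 2, which reproduces every printed
#' stage estimate.
#'
#' @param yield_per_gram cells per gram from the reference protocol.
#' @param d_stage stage tumour diameter in mm, already rounded to 2 decimals.
#' @param sigfigs significant figures kept by the truncation.
#' @return Truncated cell count.
#' @export
#' @examples
#' stage_count(4.5e7, 7.36)   # 1.65e7 cancer cells at hyperplasia
#' stage_count(2.2e6, 14.09)  # 1.54e6 TAMs at late carcinoma
stage_count <- function(yield_per_gram, d_stage, sigfigs = 3) {
  if (any(yield_per_gram < 0)) stop("yield must be non-negative")
  if (any(d_stage <= 0)) stop("diameter must be positive")
  trunc_signif((yield_per_gram / 2) * (d_stage / 10), sigfigs)
}

#' Per-mouse count anchor from a mean and standard deviation
#'
#' The three mice spread around each stage estimate as
#' `mean + k * sd` with `k = -1, 0, +1` for mice 1, 2 and 3.
#'
#' @param mean,sd stage-level count estimate and its standard deviation
#'   (`mean > sd >= 0`).
#' @param mouse_id 1, 2 or 3.
#' @return Per-mouse count.
#' @export
#' @examples
#' mouse_anchor(1.65e7, 0.33e7, 1)  # 1.32e7
mouse_anchor <- function(mean, sd, mouse_id) {
  if (!mouse_id %in% 1:3) stop("mouse_id must be 1, 2 or 3")
  if (any(sd < 0) || any(mean <= sd)) stop("need mean > sd >= 0")
  mean + c(-1, 0, 1)[mouse_id] * sd
}

#' Stage anchors: caliper volumes and per-gram yields
#'
#' Tumour volumes at the four progression stages (hyperplasia, adenoma/MIN,
#' early carcinoma, late carcinoma; weeks 6/8/10/12 of age, t = 0/14/28/42
#' days) and the reference per-gram yields: 4.5±0.9e7 cancer cells and
#' 2.2±0.6e6 tumour-associated macrophages (TAMs) per gram.
#'
#' @return List with `volumes` (named, mm^3), `weeks`, `times` (days) and
#'   `yields` (list of `cancer` and `tam`, each `c(mean=, sd=)`).
#' @export
stage_anchors <- function() {
  list(
    volumes = c(hyperplasia = 200, adenoma = 400, early_carcinoma = 700,
                late_carcinoma = 1400),
    weeks = c(6, 8, 10, 12),
    times = c(0, 14, 28, 42),
    yields = list(cancer = c(mean = 4.5e7, sd = 0.9e7),
                  tam = c(mean = 2.2e6, sd = 0.6e6))
  )
}

#' Stage-level cancer and TAM estimates
#'
#' Applies [diameter_from_caliper_volume()] and [stage_count()] to the stage
#' anchors, giving the per-stage mean and standard deviation of the cancer
#' cell and TAM counts.
#'
#' @param anchors output of [stage_anchors()].
#' @return `data.frame` with one row per stage: `stage`, `week`,
#'   `volume_mm3`, `diameter_mm`, `cancer_mean`, `cancer_sd`, `tam_mean`,
#'   `tam_sd`.
#' @export
stage_cell_estimates <- function(anchors = stage_anchors()) {
  d <- diameter_from_caliper_volume(anchors$volumes)
  data.frame(
    stage = names(anchors$volumes),
    week = anchors$weeks,
    volume_mm3 = unname(anchors$volumes),
    diameter_mm = unname(d),
    cancer_mean = stage_count(anchors$yields$cancer[["mean"]], d, 3),
    cancer_sd = stage_count(anchors$yields$cancer[["sd"]], d, 2),
    tam_mean = stage_count(anchors$yields$tam[["mean"]], d, 3),
    tam_sd = stage_count(anchors$yields$tam[["sd"]], d, 2),
    row.names = NULL
  )
}

#' Characteristic cell sizes
#'
#' Characteristic cell lengths (um) in mice, midpoints of reported ranges,
#' and the corresponding caliper single-cell volume `L^3 / 2` (um^3). The
#' `epithelial` entry covers the luminal epithelial cells of the mammary
#' gland, the dominant non-immune volume absorber; stromal cells
#' (adipocyte/fibroblast intersection) are taken at 20 um.
#'
#' @return `data.frame` with columns `cell_type`, `length_um`, `volume_um3`.
#' @export
cell_sizes <- function() {
  tab <- data.frame(
    cell_type = c("dendritic", "macrophage", "granulocyte_monocyte",
                  "lymphocyte", "stem", "endothelial", "epithelial",
                  "cancer", "adipose_stem", "fibroblast", "adipocyte"),
    length_um = c(12.5, 21, 14, 12.5, 12, 20, 30, 12, 28, 15, 20)
  )
  tab$volume_um3 <- tab$length_um^3 / 2
  tab
}

# map model cell variables to the cell-size table entries
.tme_size_map <- c(TN = "lymphocyte", Th = "lymphocyte", Tc = "lymphocyte",
                   Tr = "lymphocyte", DN = "dendritic", D = "dendritic",
                   MN = "macrophage", M = "macrophage", C = "cancer",
                   N = "cancer", A = "adipocyte", EN = "endothelial")

#' Single-cell caliper volumes of the model cell variables
#'
#' @param sizes a cell-size table as returned by [cell_sizes()].
#' @param extra character vector of additional `cell_type` entries to append
#'   (e.g. `"epithelial"` for the non-immune volume absorber).
#' @return Named vector of single-cell volumes (um^3) for the 12 model cell
#'   variables (and any `extra` types).
#' @export
model_cell_volumes <- function(sizes = cell_sizes(), extra = character()) {
  v <- setNames(sizes$volume_um3, sizes$cell_type)
  out <- setNames(v[.tme_size_map], names(.tme_size_map))
  if (length(extra) > 0L) {
    if (!all(extra %in% names(v)))
      stop("unknown cell type(s): ",
           paste(setdiff(extra, names(v)), collapse = ", "))
    out <- c(out, v[extra])
  }
  out
}

#' Immune cell counts from panel fractions
#'
#' Knowing the total number of macrophages (TAMs, naive + activated), the
#' whole immune panel scales as `s = tam_total / fraction(macrophages)`;
#' each immune count is `s` times its fraction.
#'
#' @param fracs named fractions of the immune panel (should sum to 1).
#' @param tam_total total macrophage count.
#' @param mac_types names within `fracs` that constitute the macrophages.
#' @return Named counts, same names as `fracs`.
#' @export
immune_counts_from_fractions <- function(fracs, tam_total,
                                         mac_types = c("MN", "M")) {
  if (is.null(names(fracs))) stop("fracs must be named")
  mac <- intersect(mac_types, names(fracs))
  if (length(mac) == 0L) stop("no macrophage entry in fractions")
  f_mac <- sum(fracs[mac])
  if (f_mac <= 0) stop("degenerate input: macrophage fraction is zero")
  if (tam_total < 0) stop("tam_total must be non-negative")
  fracs * (tam_total / f_mac)
}

#' Non-immune cell counts from the tumour volume budget
#'
#' The counted cells must fill the (necrosis-free) caliper tumour volume:
#' `sum_i N_i V_i + sum_j M_j V_j + N_C V_C = total volume`, with `i` over
#' immune and `j` over non-immune types and `V` the single-cell caliper
#' volumes. Given immune and cancer counts, the residual volume is
#' distributed over the non-immune types proportionally to their fractions:
#' `M_j = f_j R / sum_j' f_j' V_j'`, the unique non-negative solution with
#' the prescribed relative proportions.
#'
#' @param total_volume_mm3 stage tumour volume in mm^3.
#' @param immune_counts named immune cell counts.
#' @param cancer_count number of cancer cells.
#' @param volumes named single-cell volumes (um^3) covering the immune
#'   names, `"C"`, and every non-immune type.
#' @param nonimmune_fracs named relative fractions of the non-immune types.
#' @return Named non-immune counts; their volume sum equals the residual.
#' @export
nonimmune_counts <- function(total_volume_mm3, immune_counts, cancer_count,
                             volumes, nonimmune_fracs) {
  if (is.null(names(nonimmune_fracs))) stop("nonimmune_fracs must be named")
  need <- c(names(immune_counts), "C", names(nonimmune_fracs))
  if (!all(need %in% names(volumes)))
    stop("volumes must cover immune, cancer and non-immune types")
  total_um3 <- total_volume_mm3 * 1e9
  used <- sum(immune_counts * volumes[names(immune_counts)]) +
    cancer_count * volumes[["C"]]
  residual <- total_um3 - used
  if (residual < -1e-6 * total_um3)
    stop("inconsistent input: immune + cancer volume exceeds the tumour ",
         "volume by ", format(-residual), " um^3")
  residual <- max(residual, 0)
  denom <- sum(nonimmune_fracs * volumes[names(nonimmune_fracs)])
  if (denom <= 0) {
    if (residual > 0) stop("degenerate non-immune fractions with a positive ",
                           "residual volume")
    return(setNames(rep(0, length(nonimmune_fracs)), names(nonimmune_fracs)))
  }
  nonimmune_fracs * residual / denom
}

#' Oxygen ppm to molarity
#'
#' Tissue oxygen reported in ppm is interpreted as mg per litre; with molar
#' mass 16 g/mol (the convention of the reference tables; set
#' `molar_mass = 32` for molecular O2) this gives `(ppm / 1000) / molar_mass`
#' mol/l. 50 000 ppm (normoxia) maps to 3.125 mol/l, 10 ppm (severe hypoxia)
#' to 0.000625 mol/l.
#'
#' @param ppm oxygen in parts per million (>= 0).
#' @param molar_mass grams per mole used in the conversion.
#' @return mol/l.
#' @export
o2_ppm_to_molar <- function(ppm, molar_mass = 16) {
  if (any(ppm < 0)) stop("ppm must be non-negative")
  (ppm / 1000) / molar_mass
}

#' Non-dimensionalize a table of observations
#'
#' Divides each variable (column) by its maximum across all rows (all mice
#' and stages), so every scaled variable has maximum exactly 1. Time is never
#' rescaled. The scale registry allows exact back-conversion.
#'
#' @param x numeric matrix or data.frame, columns = variables.
#' @return List with `scaled` (same shape) and `scales` (named maxima).
#' @export
nondimensionalize <- function(x) {
  m <- as.matrix(x)
  if (!is.numeric(m)) stop("x must be numeric")
  scales <- apply(m, 2, max)
  if (any(scales <= 0))
    stop("degenerate scale: variable(s) with no positive entry: ",
         paste(colnames(m)[scales <= 0], collapse = ", "))
  scaled <- sweep(m, 2, scales, "/")
  list(scaled = scaled, scales = scales)
}

#' @rdname nondimensionalize
#' @param scaled scaled matrix.
#' @param scales named scale registry from `nondimensionalize`.
#' @export
undimensionalize <- function(scaled, scales) {
  sweep(as.matrix(scaled), 2, scales, "*")
}

#' Observed dataset container
#'
#' Holds non-dimensional observations of the 18 model variables for one or
#' more mice on the stage time grid.
#'
#' @param values numeric array `[time, variable, mouse]`; variables must be
#'   the 18 canonical state names.
#' @param times observation times in days, ascending from 0.
#' @param scales optional named scale registry (per-variable maxima).
#' @param counts optional absolute-count table kept for provenance.
#' @return Object of class `"tme_data"`.
#' @export
tme_dataset <- function(values, times, scales = NULL, counts = NULL) {
  stopifnot(is.array(values), length(dim(values)) == 3L)
  if (dim(values)[2] != 18L) stop("values must have 18 variables")
  if (dim(values)[1] != length(times)) stop("times/values mismatch")
  if (is.unsorted(times, strictly = TRUE) || times[1] != 0)
    stop("times must be strictly increasing and start at 0")
  if (any(!is.finite(values)) || any(values < 0))
    stop("values must be finite and non-negative")
  dimnames(values) <- list(NULL, tme_state_names(),
                           dimnames(values)[[3]] %||%
                             paste0("mouse", seq_len(dim(values)[3])))
  structure(list(values = values, times = as.numeric(times),
                 scales = scales, counts = counts),
            class = "tme_data")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.tme_data <- function(x, ...) {
  d <- dim(x$values)
  cat("tme_data: ", d[3], " mice x 18 variables x ", d[1],
      " time points (t = ", paste(x$times, collapse = ", "), " days)\n",
      sep = "")
  invisible(x)
}

#' Reference MMTV-PyMT cell count and cytokine tables
#'
#' `pymt_cell_counts()` returns the reference per-mouse, per-stage absolute
#' counts of the 12 model cell variables (integer cutoffs; necrotic cells are
#' half of cancer cells). `pymt_cytokine_levels()` returns the HMGB1, IL-12,
#' IL-10, IL-6 and VEGF gene-expression levels and oxygen in mol/l.
#'
#' @return `data.frame` with columns `mouse`, `week` and the variables.
#' @export
pymt_cell_counts <- function() {
  df <- data.frame(
    mouse = rep(1:3, each = 4),
    week = rep(c(6, 8, 10, 12), 3),
    TN = c(1382527, 1615524, 2569211, 2199247,
           1441964, 1545885, 1311444, 2297591,
           1399198, 1467427, 2161705, 3171264),
    Th = c(663086, 641814, 689479, 937204,
           529513, 583058, 478978, 426244,
           430269, 507931, 340691, 963737),
    Tc = c(228615, 265967, 310204, 222401,
           128158, 589238, 183104, 127776,
           405214, 395476, 272777, 381975),
    Tr = c(92289, 176412, 292578, 147089,
           79395, 407590, 69789, 181325,
           79316, 81323, 188039, 162666),
    DN = c(1227231, 1574935, 1636578, 2324486,
           1115894, 1152659, 1243110, 1396820,
           1021227, 1268459, 1232740, 1909543),
    D = c(886534, 1057404, 1328095, 1686078,
          934727, 1411717, 859137, 1057303,
          924575, 836283, 1346494, 1177989),
    MN = c(389295, 577007, 612205, 787834,
           450621, 292503, 430970, 559029,
           395039, 439574, 554893, 658718),
    M = c(397821, 710944, 942441, 1171025,
          358170, 455659, 458725, 562339,
          435495, 575209, 664238, 884036),
    C = c(13200000, 16700000, 20100000, 25400000,
          16500000, 20800000, 30100000, 31700000,
          19800000, 24900000, 25100000, 38000000),
    N = c(6600000, 8350000, 10050000, 12700000,
          8250000, 10400000, 15050000, 15850000,
          9900000, 12450000, 12550000, 19000000),
    A = c(416120, 1582762, 2763480, 5222452,
          461103, 1080624, 2464786, 5578533,
          333365, 1514664, 2885384, 5437350),
    EN = c(915268, 916916, 769340, 3028739,
           493492, 185467, 931836, 1469427,
           366687, 785294, 1196948, 2937968)
  )
  df
}

#' @rdname pymt_cell_counts
#' @export
pymt_cytokine_levels <- function() {
  data.frame(
    mouse = rep(1:3, each = 4),
    week = rep(c(6, 8, 10, 12), 3),
    H = c(1000, 940, 1103, 1050, 1182, 932, 945, 807, 1521, 1549, 957, 779),
    IL12 = c(63, 41, 3, 2, 0, 16, 0, 4, 27, 22, 3, 10),
    IL10 = c(417, 351, 404, 455, 450, 723, 429, 319, 511, 566, 349, 278),
    IL6 = c(384, 197, 184, 193, 196, 35, 162, 127, 336, 312, 229, 163),
    V = c(776, 536, 494, 798, 775, 721, 313, 384, 1081, 1054, 565, 909),
    Ox = rep(c(3.125, 0.625, 0.0625, 0.000625), 3)
  )
}

#' The reference MMTV-PyMT observed dataset, non-dimensionalized
#'
#' Joins the reference cell counts and cytokine/oxygen levels into the
#' 18-variable observation array and scales each variable by its maximum
#' across all mice and stages, so data lie in \[0, 1\] with each variable
#' attaining 1 somewhere. Weeks 6/8/10/12 map to t = 0/14/28/42 days.
#'
#' @return A [tme_dataset()] for the three mice.
#' @export
pymt_dataset <- function() {
  counts <- pymt_cell_counts()
  cyt <- pymt_cytokine_levels()
  raw <- cbind(counts[, c("EN", "TN", "Th", "Tc", "Tr", "DN", "D", "MN",
                          "M", "C", "N", "A")],
               cyt[, c("V", "Ox", "H", "IL12", "IL10", "IL6")])
  full <- as.matrix(raw[, tme_state_names()])
  nd <- nondimensionalize(full)
  arr <- array(NA_real_, dim = c(4, 18, 3),
               dimnames = list(NULL, tme_state_names(),
                               paste0("mouse", 1:3)))
  for (m in 1:3) arr[, , m] <- nd$scaled[counts$mouse == m, ]
  tme_dataset(arr, times = c(0, 14, 28, 42), scales = nd$scales,
              counts = counts)
}

#' Assemble an observed dataset from fraction and cytokine tables
#'
#' Runs the full data-preparation arithmetic: stage diameters from caliper
#' volumes, cancer and TAM counts from per-gram yields (per-mouse anchors),
#' immune counts from the deconvolved immune fractions scaled by the TAM
#' total, necrotic cells as half the cancer cells (excluded from the volume
#' budget, since reported volumes are devoid of necrotic tissue), non-immune
#' counts from the residual volume, oxygen unit conversion, and joint
#' non-dimensionalization.
#'
#' @param fractions `data.frame` with columns `mouse`, `week`, `cell_type`,
#'   `fraction`; immune panel rows (the 8 immune variables) and non-immune
#'   panel rows (`A`, `EN` and optionally extra absorber types such as
#'   `epithelial`), each panel summing to 1 per mouse/week.
#' @param cytokines `data.frame` with columns `mouse`, `week`, `H`, `IL12`,
#'   `IL10`, `IL6`, `V`, `Ox_ppm`.
#' @param sizes cell-size table, see [cell_sizes()].
#' @param anchors stage anchors, see [stage_anchors()].
#' @return List: `data` (a [tme_dataset()]), `counts` (absolute counts,
#'   mouse x week x the 12 cell variables plus extra non-immune types),
#'   `scales`.
#' @export
assemble_dataset <- function(fractions, cytokines, sizes = cell_sizes(),
                             anchors = stage_anchors()) {
  stopifnot(all(c("mouse", "week", "cell_type", "fraction") %in%
                  names(fractions)))
  stopifnot(all(c("mouse", "week", "H", "IL12", "IL10", "IL6", "V",
                  "Ox_ppm") %in% names(cytokines)))
  immune <- c("TN", "Th", "Tc", "Tr", "DN", "D", "MN", "M")
  est <- stage_cell_estimates(anchors)
  mice <- sort(unique(fractions$mouse))
  weeks <- anchors$weeks
  extra_types <- setdiff(unique(fractions$cell_type), c(immune, "A", "EN"))
  vols <- model_cell_volumes(sizes, extra = extra_types)
  cell_cols <- c(names(.tme_size_map), extra_types)

  counts <- expand.grid(mouse = mice, week = weeks)
  counts <- counts[order(counts$mouse, counts$week), ]
  rownames(counts) <- NULL
  for (cc in cell_cols) counts[[cc]] <- NA_real_

  for (i in seq_len(nrow(counts))) {
    m <- counts$mouse[i]; w <- counts$week[i]
    es <- est[est$week == w, ]
    C_cnt <- mouse_anchor(es$cancer_mean, es$cancer_sd, m)
    tam <- mouse_anchor(es$tam_mean, es$tam_sd, m)
    fr <- fractions[fractions$mouse == m & fractions$week == w, ]
    f_imm <- setNames(fr$fraction[fr$cell_type %in% immune],
                      fr$cell_type[fr$cell_type %in% immune])
    if (length(f_imm) == 0L) stop("no immune fractions for mouse ", m,
                                  " week ", w)
    ic <- immune_counts_from_fractions(f_imm[immune[immune %in%
                                                      names(f_imm)]], tam)
    nonimm_types <- intersect(c("A", "EN", extra_types), fr$cell_type)
    f_non <- setNames(fr$fraction[match(nonimm_types, fr$cell_type)],
                      nonimm_types)
    nc <- nonimmune_counts(anchors$volumes[[which(weeks == w)]], ic, C_cnt,
                           vols, f_non)
    row <- c(ic, C = C_cnt, N = C_cnt / 2, nc)
    counts[i, names(row)] <- floor(row)
    counts[i, "N"] <- floor(C_cnt) / 2
  }

  cyt <- cytokines[order(cytokines$mouse, cytokines$week), ]
  ox <- o2_ppm_to_molar(cyt$Ox_ppm)
  full <- cbind(as.matrix(counts[, names(.tme_size_map)]),
                H = cyt$H, IL12 = cyt$IL12, IL10 = cyt$IL10, IL6 = cyt$IL6,
                V = cyt$V, Ox = ox)
  full <- full[, tme_state_names()]
  nd <- nondimensionalize(full)
  arr <- array(NA_real_, dim = c(length(weeks), 18, length(mice)),
               dimnames = list(NULL, tme_state_names(),
                               paste0("mouse", mice)))
  for (j in seq_along(mice))
    arr[, , j] <- nd$scaled[counts$mouse == mice[j], ]
  list(data = tme_dataset(arr, times = anchors$times, scales = nd$scales,
                          counts = counts),
       counts = counts, scales = nd$scales)
}
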