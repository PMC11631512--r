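test_that("caliper geometry reproduces the four stage diameters", {
  expect_equal(caliper_volume(10, 10), 500)
  expect_equal(caliper_volume(1, 1), 0.5)
  expect_equal(caliper_volume(14.09, 14.09), 1398.6, tolerance = 1e-4)
  expect_equal(diameter_from_caliper_volume(c(200, 400, 700, 1400)),
               c(7.36, 9.28, 11.18, 14.09))
  expect_equal(diameter_from_caliper_volume(500), 10)
  expect_error(caliper_volume(0, 1), "positive")
  expect_error(diameter_from_caliper_volume(-1), "positive")
})

test_that("caliper volume and diameter are mutually inverse up to truncation", {
  L <- c(0.37, 1, 2.5, 7.36, 10, 14.09, 31.4)
  d <- diameter_from_caliper_volume(caliper_volume(L, L))
  expect_true(all(abs(d - L) < 0.011))
  # exact for 2-decimal lengths
  expect_equal(d, trunc(round(L * 100, 9)) / 100)
})

test_that("stage counts reproduce all eight printed mean estimates", {
  d <- diameter_from_caliper_volume(c(200, 400, 700, 1400))
  expect_equal(stage_count(4.5e7, d),
               c(1.65e7, 2.08e7, 2.51e7, 3.17e7))
  expect_equal(stage_count(2.2e6, d),
               c(8.09e5, 1.02e6, 1.22e6, 1.54e6))
  expect_equal(stage_count(4.5e7, 10.00), 2.25e7)
})

test_that("stage-count standard deviations follow the printed truncation", {
  d <- diameter_from_caliper_volume(c(200, 400, 700, 1400))
  expect_equal(stage_count(0.9e7, d, sigfigs = 2),
               c(0.33e7, 0.41e7, 0.50e7, 0.63e7))
  # TAM SDs for the later stages (the hyperplasia TAM SD is internally
  # inconsistent in the reference data and not asserted)
  expect_equal(stage_count(0.6e6, d, sigfigs = 2)[2:4],
               c(0.27e6, 0.33e6, 0.42e6))
})

test_that("stage_count is linear in yield and diameter before truncation", {
  set.seed(2)
  y <- runif(20, 1e6, 9e7); d <- runif(20, 5, 15)
  raw <- function(y, d) (y / 2) * (d / 10)
  expect_equal(raw(3 * y, d), 3 * raw(y, d))
  expect_equal(raw(y, 2 * d), 2 * raw(y, d))
  # truncation never increases the value and keeps 3 significant figures
  tr <- stage_count(y, d)
  expect_true(all(tr <= raw(y, d) & tr > 0.99 * raw(y, d)))
})

test_that("mouse anchors spread as mean + {-1, 0, +1} sd", {
  expect_equal(mouse_anchor(1.65e7, 0.33e7, 1), 1.32e7)
  expect_equal(mouse_anchor(2.08e7, 0.41e7, 2), 2.08e7)
  expect_equal(mouse_anchor(3.17e7, 0.63e7, 3), 3.80e7)
  expect_error(mouse_anchor(1, 0.1, 4), "mouse_id")
  expect_error(mouse_anchor(1, 2, 1), "mean > sd")
})

test_that("the anchor arithmetic reproduces the reference cancer counts", {
  est <- stage_cell_estimates()
  counts <- pymt_cell_counts()
  # weeks 6, 8 and 12 follow the per-mouse rule exactly; at week 10 the
  # reference table swaps mice 2 and 3 (mouse 2 = mean + sd, mouse 3 = mean)
  for (w in c(6, 8, 12)) {
    e <- est[est$week == w, ]
    pred <- sapply(1:3, function(m) mouse_anchor(e$cancer_mean,
                                                 e$cancer_sd, m))
    expect_identical(pred, as.numeric(counts$C[counts$week == w]))
  }
  e10 <- est[est$week == 10, ]
  pred10 <- sapply(1:3, function(m) mouse_anchor(e10$cancer_mean,
                                                 e10$cancer_sd, m))
  expect_identical(pred10[c(1, 3, 2)],
                   as.numeric(counts$C[counts$week == 10]))
  # necrotic cells are exactly half the cancer cells everywhere
  expect_identical(counts$N, counts$C / 2)
})

test_that("immune counts scale from the macrophage total", {
  expect_equal(immune_counts_from_fractions(c(M = 0.5, TN = 0.5), 100),
               c(M = 100, TN = 100))
  expect_equal(sum(immune_counts_from_fractions(c(MN = 0.6, M = 0.4), 42)),
               42)
  expect_error(immune_counts_from_fractions(c(TN = 1), 10), "macrophage")
  expect_error(immune_counts_from_fractions(c(M = 0, TN = 1), 10),
               "degenerate")
})

test_that("non-immune counts solve the volume budget", {
  vols <- c(TN = 1000, C = 432, A = 4000, EN = 4000)
  # zero residual -> zero counts
  imm <- c(TN = 1e6)
  tot <- (1e6 * 1000 + 5e6 * 432) / 1e9
  out <- nonimmune_counts(tot, imm, 5e6, vols, c(A = 0.5, EN = 0.5))
  expect_equal(unname(out), c(0, 0))
  # one type: direct division
  out1 <- nonimmune_counts(tot + 4, imm, 5e6, vols, c(A = 1))
  expect_equal(unname(out1["A"]), 4e9 / 4000)
  # two types, equal fractions, volumes 4000/8000: counts 1:1, volume 1:2
  vols2 <- c(TN = 1000, C = 432, A = 4000, EN = 8000)
  out2 <- nonimmune_counts(tot + 12, imm, 5e6, vols2,
                           c(A = 0.5, EN = 0.5))
  expect_equal(unname(out2["A"]), unname(out2["EN"]))
  expect_equal(unname(out2["A"] * 4000 + out2["EN"] * 8000), 12e9)
  # inconsistent budget is reported, not clipped
  expect_error(nonimmune_counts(tot / 2, imm, 5e6, vols,
                                c(A = 0.5, EN = 0.5)), "inconsistent")
})

test_that("oxygen ppm conversion matches the published table entries", {
  expect_equal(o2_ppm_to_molar(50000), 3.125)
  expect_equal(o2_ppm_to_molar(10), 0.000625)
  expect_equal(o2_ppm_to_molar(0), 0)
  expect_equal(o2_ppm_to_molar(c(10000, 1000)), c(0.625, 0.0625))
  # physically-correct molecular oxygen flag
  expect_equal(o2_ppm_to_molar(50000, molar_mass = 32), 3.125 / 2)
  expect_error(o2_ppm_to_molar(-1), "non-negative")
})

test_that("non-dimensionalization scales every variable to max 1 and round-trips", {
  set.seed(5)
  x <- matrix(runif(60, 0, 7), 10, 6,
              dimnames = list(NULL, paste0("v", 1:6)))
  nd <- nondimensionalize(x)
  expect_equal(unname(apply(nd$scaled, 2, max)), rep(1, 6))
  expect_equal(undimensionalize(nd$scaled, nd$scales), x,
               tolerance = 1e-12)
  # the oxygen column of the published table scales to 1, 0.2, 0.02, 0.0002
  ox <- matrix(rep(c(3.125, 0.625, 0.0625, 0.000625), 3), ncol = 1,
               dimnames = list(NULL, "Ox"))
  expect_equal(unname(nondimensionalize(ox)$scaled[1:4, 1]),
               c(1, 0.2, 0.02, 0.0002))
  expect_error(nondimensionalize(cbind(a = rep(0, 3))), "degenerate")
})

test_that("the reference dataset is consistent and fully scaled", {
  d <- pymt_dataset()
  expect_s3_class(d, "tme_data")
  expect_equal(dim(d$values), c(4L, 18L, 3L))
  expect_equal(d$times, c(0, 14, 28, 42))
  expect_true(all(d$values >= 0 & d$values <= 1))
  # every variable attains its maximum 1 somewhere
  expect_equal(unname(apply(d$values, 2, max)), rep(1, 18))
  # scale registry holds the raw maxima
  expect_equal(unname(d$scales["C"]), 3.8e7)
  expect_equal(unname(d$scales["Ox"]), 3.125)
})

test_that("assemble_dataset reproduces the synthetic generator ground truth", {
  tabs <- make_fraction_tables(synth_config(seed = 17))
  asm <- assemble_dataset(tabs$fractions, tabs$cytokines)
  cols <- setdiff(intersect(names(tabs$counts), names(asm$counts)),
                  c("mouse", "week"))
  expect_equal(unname(as.matrix(asm$counts[cols])),
               unname(as.matrix(tabs$counts[cols])))
  # volume conservation: counted volumes fill the stage volume to 1e-6
  vols <- model_cell_volumes(extra = "epithelial")
  anchors <- stage_anchors()
  for (i in seq_len(nrow(asm$counts))) {
    w <- asm$counts$week[i]
    budget_types <- setdiff(cols, "N")  # necrotic cells excluded
    v <- sum(asm$counts[i, budget_types] * vols[budget_types]) / 1e9
    expect_equal(v, unname(anchors$volumes[[which(anchors$weeks == w)]]),
                 tolerance = 1e-6)
  }
  # non-dimensional output within [0, 1]
  expect_true(all(asm$data$values >= 0 & asm$data$values <= 1))
})

test_that("degenerate immune fractions leave only macrophages", {
  tabs <- make_fraction_tables(synth_config(seed = 2, n_mice = 3))
  fr <- tabs$fractions
  imm <- fr$cell_type %in% c("TN", "Th", "Tc", "Tr", "DN", "D")
  mac <- fr$cell_type %in% c("MN", "M")
  # zero the non-macrophage immune panel for mouse 1 only (the other mice
  # keep every variable positive so non-dimensionalization stays defined)
  fr$fraction[imm & fr$mouse == 1] <- 0
  for (w in unique(fr$week)) {
    sel <- fr$mouse == 1 & fr$week == w & mac
    fr$fraction[sel] <- fr$fraction[sel] / sum(fr$fraction[sel])
  }
  asm <- assemble_dataset(fr, tabs$cytokines)
  est <- stage_cell_estimates()
  m1 <- asm$counts[asm$counts$mouse == 1, ]
  for (i in seq_len(nrow(m1))) {
    e <- est[est$week == m1$week[i], ]
    tam <- mouse_anchor(e$tam_mean, e$tam_sd, 1)
    expect_true(all(m1[i, c("TN", "Th", "Tc", "Tr", "DN", "D")] == 0))
    expect_equal(m1$MN[i] + m1$M[i], tam, tolerance = 1)
  }
})
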