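# End-to-end orchestration: synth -> prep -> fit -> profile -> pcgsa ->
# perturb, with a manifest recording configuration, seeds, outputs and
# checksums so deterministic stages can be reproduced bit-identically.

#' Run the analysis pipeline
#'
#' Executes the requested stages in order, short-circuiting on the first
#' failure, and writes a JSON manifest with the configuration hash, the
#' per-stage seeds (derived from one master seed), output paths with MD5
#' checksums and timings.
#'
#' Config structure (list or YAML file path): `out_dir`, `seed`, `stages`
#' (subset of `"synth"`, `"prep"`, `"fit"`, `"profile"`, `"pcgsa"`,
#' `"perturb"` in that order), and optional per-stage blocks:
#' `synth = list(n_mice, noise)`,
#' `fit = list(free, pop_size, max_generations, mouse)`,
#' `profile = list(params, grid_size)`, `pcgsa = list(t_max, t_step,
#' cutoff)`, `perturb = list(param, deltas)`.
#'
#' @param config list or path to a YAML file.
#' @return The manifest (list), invisibly; also written to
#'   `out_dir/manifest.json`.
#' @export
tme_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$out_dir))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L
  stages <- config$stages %||% c("synth", "prep", "fit")
  cfg_file <- file.path(out_dir, "config.json")
  jsonlite::write_json(config, cfg_file, auto_unbox = TRUE, digits = NA,
                       null = "null")
  manifest <- list(
    package = "tmeode",
    version = as.character(utils::packageVersion("tmeode")),
    seed = seed,
    config_hash = unname(tools::md5sum(cfg_file)),
    stages = list()
  )
  state <- new.env(parent = emptyenv())

  record <- function(name, outputs, t0, status = "ok", message = NULL) {
    manifest$stages[[name]] <<- list(
      status = status, message = message,
      seconds = round(as.numeric(Sys.time()) - t0, 3),
      outputs = lapply(outputs, function(p)
        list(path = p, md5 = unname(tools::md5sum(p)))))
  }

  runners <- list(
    synth = function() {
      tabs <- make_fraction_tables(
        synth_config(seed = seed,
                     n_mice = config$synth$n_mice %||% 3,
                     noise = config$synth$noise %||% 0.05))
      paths <- file.path(out_dir, c("fractions.csv", "cytokines.csv",
                                    "sizes.csv", "truth_counts.csv"))
      write.csv(tabs$fractions, paths[1], row.names = FALSE)
      write.csv(tabs$cytokines, paths[2], row.names = FALSE)
      write.csv(tabs$sizes, paths[3], row.names = FALSE)
      write.csv(tabs$counts, paths[4], row.names = FALSE)
      state$tables <- tabs
      paths
    },
    prep = function() {
      fr <- read.csv(file.path(out_dir, "fractions.csv"))
      cy <- read.csv(file.path(out_dir, "cytokines.csv"))
      sz <- read.csv(file.path(out_dir, "sizes.csv"))
      asm <- assemble_dataset(fr, cy, sizes = sz)
      state$data <- asm$data
      paths <- file.path(out_dir, c("counts.csv", "nondim.csv"))
      write.csv(asm$counts, paths[1], row.names = FALSE)
      nd <- do.call(rbind, lapply(seq_len(dim(asm$data$values)[3]),
                                  function(m)
        data.frame(mouse = m, t_days = asm$data$times,
                   asm$data$values[, , m])))
      write.csv(nd, paths[2], row.names = FALSE)
      paths
    },
    fit = function() {
      free <- config$fit$free %||%
        c("lambda_C", "delta_C", "lambda_A", "delta_A", "lambda_HC",
          "delta_H", "lambda_IL12M", "delta_IL12", "lambda_IL6A",
          "delta_IL6")
      ga <- ga_config(pop_size = config$fit$pop_size %||% 40,
                      max_generations = config$fit$max_generations %||% 40,
                      seed = seed + 10L)
      fit <- fit_tme(state$data %||% pymt_dataset(), free = free,
                     mouse = config$fit$mouse %||% NULL, config = ga)
      state$fit <- fit
      path <- file.path(out_dir, "fit.json")
      jsonlite::write_json(
        list(free = fit$free, loss = fit$loss, ga_loss = fit$ga_loss,
             generations = fit$generations, seed = fit$seed,
             params = as.list(unclass(fit$params)),
             config = unclass(fit$config)),
        path, auto_unbox = TRUE, digits = NA, null = "null")
      path
    },
    profile = function() {
      stopifnot(!is.null(state$fit))
      params <- config$profile$params %||% state$fit$free[1:2]
      curves <- lapply(params, function(p)
        profile_likelihood(state$fit, p,
                           grid_size = config$profile$grid_size %||% 11))
      labels <- vapply(curves, classify_profile, character(1))
      path <- file.path(out_dir, "profiles.json")
      jsonlite::write_json(
        list(labels = as.list(setNames(labels, params)),
             label_counts = as.list(table(labels)),
             curves = lapply(curves, function(cv)
               list(parameter = cv$parameter, grid = cv$grid,
                    pl = cv$pl, theta_hat = cv$theta_hat,
                    loss_hat = cv$loss_hat))),
        path, auto_unbox = TRUE, digits = NA)
      path
    },
    pcgsa = function() {
      stopifnot(!is.null(state$fit))
      x0 <- state$fit$data$values[1, , 1]
      times <- seq(0, config$pcgsa$t_max %||% 150,
                   by = config$pcgsa$t_step %||% 5)
      M <- sensitivity_matrix(state$fit$params, state$fit$hyp, x0 = x0,
                              times = times)
      dec <- pc_decompose(M)
      npc <- singular_spectrum(dec, config$pcgsa$cutoff %||% 0.2)
      hm <- variable_heatmap(dec, n_pc = npc)
      paths <- file.path(out_dir, c("pcgsa.json", "heatmap.csv"))
      jsonlite::write_json(
        list(singular_values = dec$d, n_pc = npc,
             S_top = lapply(seq_len(min(3, npc)), function(i)
               as.list(setNames(dec$S[i, ], dec$parameters)))),
        paths[1], auto_unbox = TRUE, digits = NA)
      write.csv(hm, paths[2], row.names = FALSE)
      paths
    },
    perturb = function() {
      stopifnot(!is.null(state$fit))
      pe <- perturbation_experiment(
        config$perturb$param %||% "lambda_VEN",
        config$perturb$deltas %||% c(-0.1, 0.1),
        state$fit$params, state$fit$hyp,
        x0 = state$fit$data$values[1, , 1],
        times = seq(0, config$pcgsa$t_max %||% 150, by = 1))
      path <- file.path(out_dir, "perturb.csv")
      write.csv(cbind(pe$envelope,
                      cancer_base = pe$baseline$cancer,
                      immune_base = pe$baseline$total_immune),
                path, row.names = FALSE)
      path
    }
  )

  for (s in intersect(c("synth", "prep", "fit", "profile", "pcgsa",
                        "perturb"), stages)) {
    t0 <- as.numeric(Sys.time())
    res <- tryCatch(list(ok = TRUE, out = runners[[s]]()),
                    error = function(e)
                      list(ok = FALSE, msg = conditionMessage(e)))
    if (res$ok) record(s, as.list(res$out), t0)
    else {
      record(s, list(), t0, status = "error", message = res$msg)
      break
    }
  }
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}
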