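#' Read a run configuration file
#'
#' Configurations are flat YAML (or JSON) documents with a `stage` name,
#' an optional integer `seed`, and a `params` block whose fields are the
#' arguments of the corresponding stage; see [run_stage()] for the stage
#' list.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return A named list (the parsed configuration).
#' @export
read_run_config <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
}

.stage_names <- c("bifurcation", "mfpt", "scaling", "homeostasis",
                  "mutation", "two_compartment", "ghost", "wntfit", "synth")

#' Execute one analysis stage from a configuration
#'
#' Dispatches a validated configuration to the corresponding package
#' function, writes its tabular outputs (CSV/JSON) into `out_dir`, and
#' writes a `manifest.json` recording the resolved configuration, the
#' seed, the package version, and MD5 checksums of every output, so that
#' re-running the manifest's configuration reproduces the outputs
#' bit-identically.
#'
#' Stages: `bifurcation` (fold analysis; JSON with the critical values),
#' `mfpt` (exact/Kramers/empirical mean delay at `mu`, `xi`),
#' `scaling` (exponent of the delay scaling law), `homeostasis`,
#' `mutation`, `two_compartment` (population runs; trace CSV + summary
#' JSON), `ghost` (phase-duration CSV, binned mean-curve CSV, optional
#' perturbation outcome JSON), `wntfit` (per-condition summary CSV +
#' fit JSON), `synth` (per-cell dataset CSV).
#'
#' @param config a configuration list or a path accepted by
#'   [read_run_config()].
#' @param out_dir output directory (created if missing).
#' @return Invisibly, the manifest list.
#' @export
run_stage <- function(config, out_dir = ".") {
  if (is.character(config)) config <- read_run_config(config)
  if (is.null(config$stage) || !config$stage %in% .stage_names)
    stop("config error: 'stage' must be one of ",
         paste(.stage_names, collapse = ", "), call. = FALSE)
  if (!is.null(config$seed) &&
      (!is.numeric(config$seed) || config$seed != round(config$seed)))
    stop("config error: 'seed' must be an integer", call. = FALSE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  p <- config$params
  if (is.null(p)) p <- list()
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  emit_json <- function(obj, name) {
    f <- file.path(out_dir, name)
    jsonlite::write_json(obj, f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <<- c(files, f)
  }
  emit_csv <- function(df, name) {
    f <- file.path(out_dir, name)
    utils::write.csv(df, f, row.names = FALSE)
    files <<- c(files, f)
  }
  get_rb <- function() do.call(rb_params, p$rb %||% list())

  switch(config$stage,
    bifurcation = {
      bf <- find_bifurcation(get_rb())
      emit_json(unclass(bf), "bifurcation.json")
    },
    mfpt = {
      mu <- p$mu %||% 0; xi <- p$xi %||% 0.1
      out <- list(mu = mu, xi = xi,
                  exact = mfpt_exact(mu, xi),
                  kramers = if (mu < 0) mfpt_kramers(mu, xi) else NULL)
      if (!is.null(p$empirical_n)) {
        emp <- mfpt_empirical(mu, xi, n = p$empirical_n, seed = seed,
                              dt = p$dt %||% 0.01)
        out$empirical_mean <- emp$mean
        out$empirical_se <- emp$se
        out$empirical_censored <- emp$censored
      }
      emit_json(out, "mfpt.json")
    },
    scaling = {
      xi <- p$xi %||% 0.05
      grid <- p$mu_grid %||% seq(-0.6, -0.2, length.out = 20)
      sc <- scaling_exponent(xi, grid)
      emit_json(list(xi = xi, exponent = sc$exponent,
                     regime_ok = sc$regime_ok), "scaling.json")
      emit_csv(data.frame(mu = grid, xi = xi, log_T_exact = sc$log_T,
                          log_T_kramers = mfpt_kramers(grid, xi, log = TRUE)),
               "scaling_curve.csv")
    },
    homeostasis = ,
    mutation = ,
    two_compartment = {
      pp <- .params_from_config(p, seed, stage = config$stage)
      tr <- switch(config$stage,
                   homeostasis = run_homeostasis(pp),
                   mutation = run_mutation_experiment(pp),
                   two_compartment = run_two_compartment(pp))
      emit_csv(as.data.frame(tr), "trace.csv")
      summ <- list(long_run_mean_N = tr$long_run_mean_N,
                   extinct = tr$extinct,
                   extinction_time = tr$extinction_time)
      if (!is.null(tr$clone_summary))
        summ$final_mean_alpha <- tr$clone_summary$final_mean_alpha
      if (!is.null(tr$steady_state)) summ$steady_state <- tr$steady_state
      emit_json(summ, "summary.json")
    },
    ghost = {
      gp <- do.call(ghost_params, c(p$ghost %||% list(), list(seed = seed)))
      ens <- simulate_ghost_ensemble(gp, get_rb())
      emit_csv(ens$phases, "phase_durations.csv")
      bins <- align_and_bin(ens)
      curves <- do.call(rbind, lapply(bins, function(b)
        data.frame(bin = b$bin, time_h = b$times,
                   mean_activity = b$mean_activity)))
      emit_csv(curves, "binned_mean_curves.csv")
      if (isTRUE(p$perturb)) {
        pe <- perturbation_experiment(rb = get_rb(), seed = seed)
        emit_json(as.list(pe$counts), "perturbation_counts.json")
      }
    },
    wntfit = {
      obs_file <- p$observed_csv
      rb <- get_rb()
      model <- summarize_conditions(default_conditions(), rb, seed = seed)
      emit_csv(model, "condition_summaries.csv")
      if (!is.null(obs_file)) {
        cells <- utils::read.csv(obs_file)
        obs <- do.call(rbind, lapply(split(cells, cells$condition),
          function(d) cbind(data.frame(condition = d$condition[1],
                                       wnt_activity = d$wnt_activity[1]),
                            as.data.frame(summarize_condition(d$g1_hours)))))
        fit <- fit_r2(model[, c("condition", "wnt_activity",
                                "mean_g1", "var_g1")],
                      obs[, c("condition", "wnt_activity",
                              "mean_g1", "var_g1")])
        emit_json(unclass(fit), "fit.json")
      }
    },
    synth = {
      cfg <- generator_config(
        rb = get_rb(),
        measurement_noise_sd = p$measurement_noise_sd %||% 0,
        seed = seed)
      emit_csv(generate_dataset(cfg), "synthetic_cells.csv")
    })

  manifest <- list(stage = config$stage, seed = seed,
                   resolved_params = p,
                   package_version = as.character(utils::packageVersion("cyclecrit")),
                   outputs = as.list(tools::md5sum(files)))
  mf <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# build population_params from a config params block
.params_from_config <- function(p, seed, stage) {
  fb_args <- p$feedback %||% list()
  if (is.null(fb_args$variant))
    fb_args$variant <- switch(stage, two_compartment = "differentiated_pool",
                              "hyperbolic_RD")
  topo_args <- p$topology %||% list()
  if (is.null(topo_args$kind))
    topo_args$kind <- if (fb_args$variant %in%
                          c("hyperbolic_RD", "ligand_mitogen")) "RD" else "DR"
  mut <- if (stage == "mutation")
    do.call(mutation_spec, p$mutation %||% list()) else NULL
  population_params(
    rb = do.call(rb_params, p$rb %||% list()),
    feedback = do.call(feedback_spec, fb_args),
    topology = do.call(topology_spec, topo_args),
    mutation = mut,
    dt = p$dt %||% 0.1, T_baseline = p$T_baseline %||% 720,
    t_max = p$t_max %||% 5000, N0 = p$N0 %||% 100,
    capacity = p$capacity, record_every = p$record_every %||% 1,
    seed = seed, D0 = p$D0 %||% 0)
}
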