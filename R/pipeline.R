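#' Load and validate a pipeline configuration
#'
#' Configuration is a YAML (or already-parsed list) with the sections
#' `constants`, `baseline`, `fitting`, `coupling`, `paths`, `synthesize` and
#' `seed`. Unknown top-level keys are rejected so that typos fail loudly
#' before any stage runs. All sections are optional; defaults reproduce the
#' package's standard analysis settings.
#'
#' @param config path to a YAML file, or a list
#' @return validated configuration list of class `pipeline_config`
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  known <- c("constants", "baseline", "fitting", "coupling", "paths",
             "synthesize", "seed")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  defaults <- list(
    constants = list(temperature = 310.15, pH = 7.5, monovalent = 150, mg = 1),
    baseline = list(mode = "constant", k_ref = 1.7e-10),
    fitting = list(model = "auto", criterion = "aicc", fix_plateau = FALSE,
                   time_unit = "s"),
    coupling = list(group_by_linker = FALSE, hinge = TRUE, grid_res = 0.1,
                    exclude_wt = TRUE),
    paths = list(),
    synthesize = NULL,
    seed = 1L
  )
  for (k in known) {
    if (is.null(config[[k]])) {
      config[[k]] <- defaults[[k]]
    } else if (is.list(defaults[[k]]) && is.list(config[[k]])) {
      config[[k]] <- utils::modifyList(defaults[[k]], config[[k]])
    }
  }
  structure(config, class = c("pipeline_config", "list"))
}

write_stage_csv <- function(d, path) {
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Stage order mirrors the analysis: (1) obtain inputs (either the tables
#' named in `paths` or panels generated by the synthetic module under
#' `synthesize`), (2) kinetic fitting of any time courses, (3) optional Hill
#' analysis of a titration, (4) energetics ledger, (5) helix scoring when a
#' construct FASTA is supplied, (6) coupling regressions. Every stage writes
#' its own CSV/JSON under `out_dir` and no stage rewrites another stage's
#' files; a run manifest records configuration, constants, seed and the MD5
#' of every artifact, so a rerun with the same config and seed is
#' byte-identical.
#'
#' @param config a [pipeline_config()] (or path / list coercible to one)
#' @param out_dir output directory (created if missing)
#' @return invisibly, the manifest list
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- character()
  stages <- character()
  cond <- reaction_condition(cfg$constants$temperature, cfg$constants$pH,
                             cfg$constants$monovalent, cfg$constants$mg)
  log_msg <- function(stage, msg) {
    message(sprintf("[%s] %s", stage, msg))
  }

  ## stage 1: inputs
  records <- NULL
  timecourses <- list()
  titration <- NULL
  if (!is.null(cfg$synthesize)) {
    syn <- cfg$synthesize
    pp <- do.call(pinch_params, syn$pinch %||% list())
    ns <- noise_spec("lognormal_multiplicative",
                     sd = syn$noise_sd %||% 0, seed = cfg$seed)
    records <- gen_construct_ladder(syn$bp_range %||% 0:7,
                                    syn$mean_stack_dG %||% 0.81,
                                    pinch = pp, noise = ns)
    if (isTRUE(syn$titration)) {
      titration <- gen_titration(syn$n_true %||% 1.06,
                                 syn$K_half %||% 100,
                                 syn$k_max %||% 1,
                                 syn$mg_grid %||% exp(seq(log(0.1), log(3),
                                                          length.out = 8)),
                                 ns)
    }
    log_msg("inputs", sprintf("synthesized %d constructs (seed %d)",
                              nrow(records), cfg$seed))
  } else {
    if (!is.null(cfg$paths$timecourses)) {
      timecourses <- read_timecourse_table(cfg$paths$timecourses,
                                           time_unit = cfg$fitting$time_unit)
      log_msg("inputs", sprintf("read %d time courses", length(timecourses)))
    }
    if (!is.null(cfg$paths$titration)) {
      titration <- read_titration_table(cfg$paths$titration)
    }
    if (!is.null(cfg$paths$records)) {
      records <- utils::read.csv(cfg$paths$records, stringsAsFactors = FALSE)
    }
  }
  stages <- c(stages, "inputs")

  ## stage 2: kinetics
  if (length(timecourses)) {
    fits <- lapply(timecourses, function(tc) {
      fit_kinetics(tc, model = cfg$fitting$model,
                   fix_plateau = cfg$fitting$fix_plateau,
                   criterion = cfg$fitting$criterion)
    })
    ktab <- do.call(rbind, lapply(names(fits), function(nm) {
      f <- fits[[nm]]
      data.frame(construct_id = f$construct_id, n_components = f$n_components,
                 k_obs = f$k_obs, plateau = f$plateau, rss = f$rss)
    }))
    artifacts <- c(artifacts, write_stage_csv(ktab, file.path(out_dir, "kinetics.csv")))
    jsonlite::write_json(lapply(fits, exp_fit_as_list),
                         file.path(out_dir, "kinetics_fits.json"),
                         auto_unbox = TRUE, digits = NA)
    artifacts <- c(artifacts, file.path(out_dir, "kinetics_fits.json"))
    if (is.null(records)) {
      records <- construct_records(
        construct_id = ktab$construct_id,
        stability = NA_real_, k_obs = ktab$k_obs,
        E_a_apparent = NA_real_)
    }
  }
  stages <- c(stages, "kinetics")

  ## stage 3: Hill analysis (optional)
  if (!is.null(titration)) {
    hf_log <- fit_loglog_slope(titration)
    hf_nl <- fit_hill_nonlinear(titration)
    jsonlite::write_json(
      list(loglog = unclass(hf_log), nonlinear = unclass(hf_nl)),
      file.path(out_dir, "hill.json"), auto_unbox = TRUE, digits = NA)
    artifacts <- c(artifacts, file.path(out_dir, "hill.json"))
    log_msg("hill", sprintf("n(loglog) = %.3f, n(nonlinear) = %.3f",
                            hf_log$n, hf_nl$n))
  }
  stages <- c(stages, "hill")

  ## stage 4: energetics
  if (!is.null(records)) {
    bl <- uncat_model(cfg$baseline$mode, cfg$baseline$k_ref,
                      cfg$baseline$coefficients)
    ledger <- energy_ledger(records$construct_id, records$k_obs, bl, cond)
    records$E_a_apparent <- ledger$E_a_apparent
    artifacts <- c(artifacts,
                   write_stage_csv(ledger, file.path(out_dir, "energy_ledger.csv")),
                   write_stage_csv(records, file.path(out_dir, "construct_records.csv")))
  }
  stages <- c(stages, "energetics")

  ## stage 5: helix scoring (optional)
  if (!is.null(cfg$paths$construct_fasta)) {
    duplexes <- parse_construct_fasta(cfg$paths$construct_fasta)
    params <- nn_param_table()
    htab <- do.call(rbind, lapply(duplexes, function(h) {
      data.frame(construct_id = h$id, n_bp = h$n_bp,
                 bits = info_bits(h$n_bp),
                 dG37 = helix_dG37(h, params))
    }))
    artifacts <- c(artifacts,
                   write_stage_csv(htab, file.path(out_dir, "helix_energies.csv")))
  }
  stages <- c(stages, "helix_thermo")

  ## stage 6: coupling
  if (!is.null(records) && sum(!is.na(records$stability)) >= 3) {
    lin <- linear_coupling_fit(records,
                               group_by_linker = cfg$coupling$group_by_linker,
                               exclude_wt = cfg$coupling$exclude_wt)
    res <- list(linear = if (inherits(lin, "coupling_fit")) unclass(lin)
                else lapply(lin, unclass))
    if (isTRUE(cfg$coupling$hinge) && nrow(records) >= 5) {
      res$hinge <- unclass(hinge_fit(records, grid_res = cfg$coupling$grid_res,
                                     exclude_wt = cfg$coupling$exclude_wt))
    }
    if (any(!is.na(records$p12_bits))) {
      res$info_activity <- info_activity_fit(records,
                                             exclude_wt = cfg$coupling$exclude_wt)
    }
    jsonlite::write_json(res, file.path(out_dir, "coupling.json"),
                         auto_unbox = TRUE, digits = NA)
    artifacts <- c(artifacts, file.path(out_dir, "coupling.json"))
  }
  stages <- c(stages, "coupling")

  manifest <- list(
    package = "ribopinch",
    version = as.character(utils::packageVersion("ribopinch")),
    stages = stages,
    seed = cfg$seed,
    constants = cfg$constants,
    gas_constant_kcal = R_KCAL,
    artifacts = as.list(stats::setNames(
      unname(tools::md5sum(artifacts)), basename(artifacts)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
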