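#' Pipeline configuration
#'
#' End-to-end run: simulate a two-environment population, estimate the
#' genetic parameters (threshold fits per environment, a cross-environment
#' bivariate linear fit, production-trait fits), assemble the parameter
#' report, compute breeding-objective correlations and predict selection
#' responses for the reference schemes.
#'
#' The default simulation is a scaled-down population (about 1,200 kits)
#' so that a full run completes in minutes; the study-scale design of
#' [sim_config()] can be passed explicitly.
#'
#' @param sim A [sim_config()].
#' @param n_draws Draws for sampling-based SEs.
#' @param seed Master seed (stages derive their own sub-seeds).
#' @param objectives Named list of [breeding_objective()]s.
#' @param scheme A [scheme_config()].
#' @param scheme_params Parameter set for [predict_response()]; defaults to
#'   [default_scheme_params()].
#' @return A `cuni_pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(n_sires = 40, n_dams = 100,
                                             parities = 2,
                                             kits_per_litter = 6,
                                             n_batches = 10),
                            n_draws = 2000, seed = 1,
                            objectives = default_breeding_objectives(),
                            scheme = scheme_config(),
                            scheme_params = default_scheme_params()) {
  structure(as.list(environment()), class = "cuni_pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognized top-level keys: `seed`, `n_draws`, and a `sim` block whose
#' entries override [sim_config()] arguments.
#'
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  yml <- yaml::read_yaml(path)
  simargs <- yml$sim %||% list()
  cfg <- pipeline_config(sim = do.call(sim_config, simargs))
  if (!is.null(yml$seed)) cfg$seed <- yml$seed
  if (!is.null(yml$n_draws)) cfg$n_draws <- yml$n_draws
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes the stages simulate, fit, params, objectives and response in
#' order, writing plain-text outputs and a JSON manifest (seeds, file
#' checksums) to `out_dir`. Individual stages can be re-run from the
#' persisted intermediates by restricting `stages`.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @param stages Subset of `c("simulate", "fit", "params", "objectives",
#'   "response")`.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the stage results and the manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         stages = c("simulate", "fit", "params",
                                    "objectives", "response"),
                         quiet = FALSE) {
  stopifnot(inherits(config, "cuni_pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message("[cuniqg] ", ...)
  res <- list()
  run_stage <- function(name, fun) {
    say("stage ", name)
    tryCatch(fun(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  if ("simulate" %in% stages) {
    res$sim <- run_stage("simulate", function() {
      config$sim$seed <- config$seed
      sim <- simulate_population(config$sim)
      write_simulation(sim, out_dir)
      sim
    })
  }

  read_inputs <- function() {
    pf <- file.path(out_dir, "pedigree.csv")
    if (!file.exists(pf))
      stop("no persisted pedigree at ", pf, "; run the simulate stage first")
    ped <- load_pedigree(pf, quiet = TRUE)
    animals <- utils::read.csv(file.path(out_dir, "animals.csv"),
                               stringsAsFactors = FALSE)
    lf <- file.path(out_dir, "litters.csv")
    litters <- if (file.exists(lf)) utils::read.csv(lf, stringsAsFactors = FALSE)
               else NULL
    list(ped = ped, pheno = list(animals = animals, litters = litters))
  }

  if ("fit" %in% stages) {
    res$fits <- run_stage("fit", function() {
      inp <- read_inputs()
      ped <- inp$ped; pheno <- inp$pheno
      if (!is.null(pheno$litters))
        pheno$litters$parity_status <-
          paste0("P", pmin(pheno$litters$parity, 5L), "_",
                 pheno$litters$physiological_status)
      fits <- list()
      mt <- list()
      fits$resist_S <- fit_threshold_trait(build_design(
        model_spec("resist", fixed = c("batch", "sex"),
                   random = c("animal", "litter"), link = "logit",
                   environment = "S"), ped, pheno))
      fits$resist_Ch <- fit_threshold_trait(build_design(
        model_spec("resist", fixed = c("batch", "sex", "farm"),
                   random = c("animal", "litter"), link = "logit",
                   environment = "Ch"), ped, pheno))
      if (!is.null(pheno$litters))
        fits$nba <- reml_fit(build_design(
          model_spec("nba", fixed = c("year_season", "parity_status"),
                     random = c("animal", "perm_env"), unit = "litter"),
          ped, pheno))
      if ("ww" %in% names(pheno$animals))
        fits$ww <- reml_fit(build_design(
          model_spec("ww", fixed = c("batch", "sex", "parity"),
                     random = c("animal", "litter", "maternal_env",
                                "maternal_genetic")), ped, pheno))
      # cross-environment bivariate linear fit (residual covariance is
      # structurally constrained to zero: no animal is recorded in both)
      mt$resist_SxCh <- reml_fit(build_design(list(
        model_spec("resist", fixed = c("batch", "sex"),
                   random = c("animal", "litter"), environment = "S"),
        model_spec("resist", fixed = c("batch", "sex", "farm"),
                   random = c("animal", "litter"), environment = "Ch")),
        ped, pheno), vcov = FALSE)
      saveRDS_txt <- function(x, f) {
        con <- file(file.path(out_dir, f), "w")
        on.exit(close(con))
        dp <- utils::capture.output(print(x))
        writeLines(dp, con)
      }
      for (nm in names(fits)) saveRDS_txt(fits[[nm]], paste0("fit_", nm, ".txt"))
      for (nm in names(mt)) saveRDS_txt(mt[[nm]], paste0("fit_", nm, ".txt"))
      list(single = fits, multi = mt)
    })
  }

  if ("params" %in% stages && !is.null(res$fits)) {
    res$report <- run_stage("params", function() {
      rep <- assemble_report(res$fits$single, res$fits$multi,
                             n_draws = config$n_draws, seed = config$seed + 1)
      write_param_report(rep, out_dir)
      rep
    })
  }

  if ("objectives" %in% stages) {
    res$objective_correlations <- run_stage("objectives", function() {
      M <- objective_correlation_table(config$objectives,
                                       config$scheme_params$G)
      utils::write.csv(as.data.frame(round(M, 4)),
                       file.path(out_dir, "objective_correlations.csv"),
                       quote = FALSE)
      M
    })
  }

  if ("response" %in% stages) {
    res$responses <- run_stage("response", function() {
      tb <- response_table(config$objectives, config$scheme_params,
                           config$scheme)
      utils::write.csv(cbind(trait = rownames(tb), round(tb, 4)),
                       file.path(out_dir, "responses.csv"),
                       row.names = FALSE, quote = FALSE)
      tb
    })
  }

  # manifest: seeds + checksums of all text outputs
  files <- sort(list.files(out_dir, pattern = "\\.(csv|txt)$"))
  sums <- as.list(tools::md5sum(file.path(out_dir, files)))
  names(sums) <- files
  manifest <- list(package = "cuniqg", seed = config$seed,
                   n_draws = config$n_draws, stages = stages,
                   checksums = sums)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  res$manifest <- manifest
  invisible(res)
}
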