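#' Pipeline configuration
#'
#' Assembles every setting the staged pipeline needs. All randomness flows
#' from the single root `seed` (stage seeds are derived from it), so a rerun
#' with the same config reproduces every output byte-for-byte.
#'
#' @param seed Root integer seed.
#' @param outdir Output directory.
#' @param survey_dir Directory of survey CSVs ([read_survey()] layout);
#'   `NULL` means the `simulate` stage's output under `outdir` is used.
#' @param raster_path Path to a percent-cover `.asc` raster; `NULL` means
#'   the simulated raster is used.
#' @param sedimentation List of [sedimentation_config()] arguments.
#' @param gam List of [gam_config()] arguments (no seed; derived).
#' @param scaling List with `candidates` (predictor sets), `cutoff`,
#'   `folds`, `alpha`, `train_prop`.
#' @param simulation List of [simulation_config()] arguments (no seed).
#' @param lookups List of [lookup_tables()] arguments.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed, outdir = "reefcarb_out",
                            survey_dir = NULL, raster_path = NULL,
                            sedimentation = list(), gam = list(),
                            scaling = list(), simulation = list(),
                            lookups = list()) {
  if (missing(seed) || is.null(seed))
    stop("pipeline_config: a root seed is mandatory", call. = FALSE)
  gam_defaults <- list(n_knots = 5, chains = 3, iterations = 20000,
                       burn_in = 5000, thin = 5)
  scl_defaults <- list(
    candidates = list(c("lcc", "rugosity", "depth"), c("lcc", "rugosity"),
                      "lcc"),
    cutoff = 0.7, folds = 10, alpha = 0.05, train_prop = 0.7)
  cfg <- list(
    seed = as.integer(seed), outdir = outdir, survey_dir = survey_dir,
    raster_path = raster_path,
    sedimentation = sedimentation,
    gam = utils::modifyList(gam_defaults, gam),
    scaling = utils::modifyList(scl_defaults, scaling),
    simulation = simulation, lookups = lookups)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' One plain-text file holding the [pipeline_config()] fields; unknown
#' top-level keys are rejected.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("seed", "outdir", "survey_dir", "raster_path", "sedimentation",
             "gam", "scaling", "simulation", "lookups")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(pipeline_config, raw)
}

provenance <- function(config) {
  cfg <- unclass(config)
  list(config_hash = rlang::hash(cfg), seed = config$seed,
       package_version = as.character(utils::packageVersion("reefcarb")),
       r_version = paste(R.version$major, R.version$minor, sep = "."),
       timestamp = format(Sys.time(), tz = "UTC"))
}

#' Run the staged carbonate-budget pipeline
#'
#' Executes one stage or the full chain: `simulate` writes a synthetic
#' survey, its truth record, and a cover raster; `budget` computes the
#' per-transect and summary budget CSVs; `threshold` fits the Bayesian
#' cover-threshold model and writes the threshold table and diagnostics;
#' `upscale` runs the scaling model selection and predicts net production
#' (and accretion) over the cover raster. `all` chains them; a stage
#' failure skips the stages depending on it but preserves prior artifacts.
#' Every JSON artifact embeds provenance (config hash, seed, versions).
#'
#' @param stage One of `"simulate"`, `"budget"`, `"threshold"`,
#'   `"upscale"`, `"all"`.
#' @param config A [pipeline_config()].
#' @param survey Optionally, an in-memory [survey_dataset()] overriding
#'   `config$survey_dir` (used by tests and programmatic callers).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list of stage results, with `status` (`"ok"`,
#'   `"failed"`, or `"skipped"`) per requested stage.
#' @export
run_pipeline <- function(stage = c("all", "simulate", "budget", "threshold",
                                   "upscale"),
                         config, survey = NULL, quiet = FALSE) {
  stage <- match.arg(stage)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  stages <- if (stage == "all")
    c("simulate", "budget", "threshold", "upscale") else stage
  if (!is.null(survey) || !is.null(config$survey_dir))
    stages <- setdiff(stages, "simulate")
  res <- list(status = stats::setNames(rep("pending", length(stages)),
                                       stages))
  say <- function(...) if (!quiet) message("[reefcarb] ", ...)
  tables <- do.call(lookup_tables, config$lookups)
  sed <- do.call(sedimentation_config, config$sedimentation)
  failed <- FALSE

  run_stage <- function(name, fun) {
    if (failed) {
      res$status[[name]] <<- "skipped"
      say(name, ": skipped (earlier stage failed)")
      return(invisible(NULL))
    }
    out <- tryCatch(fun(), error = function(e) {
      failed <<- TRUE
      res$status[[name]] <<- "failed"
      warning("stage '", name, "' failed: ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
    if (!is.null(out)) res$status[[name]] <<- "ok"
    out
  }

  if ("simulate" %in% stages) {
    res$simulate <- run_stage("simulate", function() {
      sim_cfg <- do.call(simulation_config,
                         c(list(seed = config$seed), config$simulation))
      gen <- generate_survey(sim_cfg)
      write_survey(gen$survey, file.path(config$outdir, "survey"))
      truth <- gen$truth
      truth$provenance <- provenance(config)
      jsonlite::write_json(truth, file.path(config$outdir, "truth.json"),
                           auto_unbox = TRUE, digits = NA,
                           dataframe = "columns")
      ras <- generate_lcc_raster(sim_cfg)
      write_ascii_grid(ras$lcc, file.path(config$outdir, "lcc.asc"))
      write_ascii_grid(ras$net_truth,
                       file.path(config$outdir, "net_truth.asc"))
      say("simulate: ", nrow(gen$survey$transects), " transects written")
      gen
    })
  }

  get_survey <- function() {
    if (!is.null(survey)) return(survey)
    if (!is.null(config$survey_dir)) return(read_survey(config$survey_dir,
                                                        quiet = TRUE))
    read_survey(file.path(config$outdir, "survey"), quiet = TRUE)
  }

  if ("budget" %in% stages) {
    res$budget <- run_stage("budget", function() {
      sv <- get_survey()
      bud <- compute_budget(sv, tables, sed)
      readr::write_csv(bud, file.path(config$outdir, "budget.csv"),
                       progress = FALSE)
      summ <- aggregate_budget(bud)
      readr::write_csv(summ, file.path(config$outdir,
                                       "budget_summary.csv"),
                       progress = FALSE)
      say("budget: ", nrow(bud), " transects; overall mean net = ",
          round(mean(bud$net), 2), " kg m-2 y-1")
      bud
    })
  }

  get_budget <- function() {
    if (!is.null(res$budget)) return(res$budget)
    p <- file.path(config$outdir, "budget.csv")
    if (!file.exists(p))
      stop("no budget result; run the 'budget' stage first", call. = FALSE)
    out <- readr::read_csv(p, show_col_types = FALSE, progress = FALSE)
    class(out) <- c("budget_result", class(out))
    out
  }

  if ("threshold" %in% stages) {
    res$threshold <- run_stage("threshold", function() {
      bud <- get_budget()
      dat <- data.frame(net = bud$net, lcc = bud$lcc_percent,
                        depth = bud$depth_m, site = bud$site_id)
      gcfg <- do.call(gam_config,
                      c(config$gam, list(seed = config$seed + 1L)))
      fit <- fit_threshold_model(dat, gcfg)
      th <- coral_cover_thresholds(fit)
      readr::write_csv(th, file.path(config$outdir, "thresholds.csv"),
                       progress = FALSE)
      diag <- list(rhat = as.list(fit$rhat), converged = fit$converged,
                   n_draws = nrow(fit$draws),
                   provenance = provenance(config))
      jsonlite::write_json(diag,
                           file.path(config$outdir,
                                     "gam_diagnostics.json"),
                           auto_unbox = TRUE, digits = NA)
      say("threshold: average LCC threshold = ",
          round(th$threshold_lcc[th$depth_m == "average"], 2), "%")
      list(fit = fit, thresholds = th)
    })
  }

  if ("upscale" %in% stages) {
    res$upscale <- run_stage("upscale", function() {
      bud <- get_budget()
      ds <- as_scaling_dataset(bud)
      scr <- collinearity_screen(
        ds[, c("lcc", "rugosity", "depth", "algal_substrate")],
        priority = c("lcc", "depth", "rugosity", "algal_substrate"),
        cutoff = config$scaling$cutoff)
      flags <- cooks_outlier_filter(ds$net, ds[, scr$retained,
                                               drop = FALSE])
      ncomp <- if (length(scr$retained) >= 2)
        plsr_component_selection(ds$net[!flags],
                                 ds[!flags, scr$retained, drop = FALSE],
                                 folds = config$scaling$folds,
                                 seed = config$seed + 2L)
      else 1L
      cand <- lapply(config$scaling$candidates, intersect, y = scr$retained)
      cand <- unique(cand[lengths(cand) > 0])
      model <- fit_and_select(ds, cand, split_seed = config$seed + 3L,
                              outlier_flags = flags,
                              train_prop = config$scaling$train_prop,
                              alpha = config$scaling$alpha)
      readr::write_csv(model$metrics,
                       file.path(config$outdir, "scaling_metrics.csv"),
                       progress = FALSE)
      jsonlite::write_json(
        list(predictors = model$predictors,
             coefficients = as.list(model$coefficients),
             n_outliers = sum(flags), pls_components = as.integer(ncomp),
             collinearity_dropped = scr$dropped,
             provenance = provenance(config)),
        file.path(config$outdir, "scaling_model.json"),
        auto_unbox = TRUE, digits = NA)
      ras_path <- if (!is.null(config$raster_path)) config$raster_path
                  else file.path(config$outdir, "lcc.asc")
      preds <- NULL
      if (file.exists(ras_path) &&
          identical(model$predictors, "lcc")) {
        lcc <- read_ascii_grid(ras_path)
        preds <- predict_raster(model, lcc, accretion = TRUE)
        write_ascii_grid(preds$net,
                         file.path(config$outdir, "predicted_net.asc"))
        write_ascii_grid(preds$accretion,
                         file.path(config$outdir,
                                   "predicted_accretion.asc"))
        say("upscale: raster mean net = ",
            round(preds$summary$mean_net, 2), "; ",
            round(100 * preds$summary$prop_positive), "% pixels positive")
      }
      say("upscale: selected model net ~ ",
          paste(model$predictors, collapse = " + "))
      list(model = model, screen = scr, outlier_flags = flags,
           pls_components = ncomp, raster = preds)
    })
  }

  invisible(res)
}
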