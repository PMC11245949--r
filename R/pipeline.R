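# End-to-end pipeline: simulate or load -> preprocess -> full-spectrum
# PLSR CV -> wavelength selection -> optimized PLSR CV -> comparison.
# Configuration is a plain-text (JSON) document; every stochastic stage
# carries an explicit seed and the resolved configuration is copied
# beside the outputs for provenance.

#' Build a pipeline run configuration
#'
#' @param output_dir directory for all artifacts (created if missing).
#' @param response `"pH"` or `"TSS"`.
#' @param scenario named list of overrides for
#'   [fermentation_scenario()] (used when no input files are given).
#' @param spectra_file,reference_file optional CSV inputs; when absent
#'   the synthetic scenario is simulated instead.
#' @param sg_order,sg_window Savitzky-Golay parameters (window 3 with
#'   order 2 is the identity; use window 7 for actual smoothing).
#' @param ncomp PLSR components (`NULL` = per-fold inner CV search).
#' @param ncomp_max upper bound of the component search.
#' @param methods selection methods to run, subset of
#'   `c("beta", "vip", "cafs")`.
#' @param beta_n_keep,vip_threshold,cafs_params selector parameters;
#'   `cafs_params` is a named list merged over the [cafs_select()]
#'   defaults.
#' @param cv_K,cv_reps,cv_seed evaluation protocol settings.
#' @param selection_seed seed for the stochastic selector (CAFS).
#' @param simulation_seed seed for the synthetic scenario.
#' @return object of class `run_config` (a validated named list).
#' @export
run_config <- function(output_dir,
                       response = c("pH", "TSS"),
                       scenario = list(),
                       spectra_file = NULL,
                       reference_file = NULL,
                       sg_order = 2, sg_window = 3,
                       ncomp = 10, ncomp_max = 15,
                       methods = c("beta", "vip", "cafs"),
                       beta_n_keep = 15,
                       vip_threshold = 1,
                       cafs_params = list(),
                       cv_K = 5, cv_reps = 30, cv_seed = 1,
                       selection_seed = 1,
                       simulation_seed = 20240617) {
  response <- match.arg(response)
  methods <- match.arg(methods, several.ok = TRUE)
  cfg <- list(output_dir = output_dir, response = response,
              scenario = scenario, spectra_file = spectra_file,
              reference_file = reference_file, sg_order = sg_order,
              sg_window = sg_window, ncomp = ncomp, ncomp_max = ncomp_max,
              methods = methods, beta_n_keep = beta_n_keep,
              vip_threshold = vip_threshold, cafs_params = cafs_params,
              cv_K = cv_K, cv_reps = cv_reps, cv_seed = cv_seed,
              selection_seed = selection_seed,
              simulation_seed = simulation_seed)
  validate_config(cfg)
  structure(cfg, class = "run_config")
}

validate_config <- function(cfg) {
  needed_seeds <- c("cv_seed", "selection_seed", "simulation_seed")
  for (s in needed_seeds) {
    if (is.null(cfg[[s]]) || !is.numeric(cfg[[s]]) || !is.finite(cfg[[s]])) {
      stop(sprintf("config is missing an explicit seed: %s", s),
           call. = FALSE)
    }
  }
  if (is.null(cfg$output_dir)) stop("config needs output_dir", call. = FALSE)
  invisible(cfg)
}

#' Read a run configuration from a JSON file
#'
#' @param path JSON file produced by [write_run_config()] (or written
#'   by hand). Round-trips unchanged.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg$scenario <- as.list(cfg$scenario)
  cfg$cafs_params <- as.list(cfg$cafs_params)
  do.call(run_config, cfg)
}

#' Write a run configuration as JSON
#'
#' @param cfg a `run_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

# selector factory used by the optimized recipes
.make_selector <- function(cfg, method) {
  switch(
    method,
    beta = function(X, y, seed) {
      a <- min(cfg$ncomp %||% 10, ncol(X), nrow(X) - 1L)
      select_by_beta(fit_plsr(X, y, ncomp = a), n_keep = cfg$beta_n_keep)
    },
    vip = function(X, y, seed) {
      a <- min(cfg$ncomp %||% 10, ncol(X), nrow(X) - 1L)
      select_by_vip(compute_vip(fit_plsr(X, y, ncomp = a)),
                    threshold = cfg$vip_threshold)
    },
    cafs = function(X, y, seed) {
      args <- utils::modifyList(
        list(X = X, y = y, seed = cfg$selection_seed),
        cfg$cafs_params)
      do.call(cafs_select, args)
    }
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full pipeline
#'
#' Executes simulate/load, preprocessing (absorbance conversion +
#' Savitzky-Golay smoothing), full-spectrum repeated K-fold PLSR,
#' wavelength selection by each configured method (re-run inside every
#' training fold), optimized repeated K-fold PLSR, and the model
#' comparison. All intermediate tables, a log with every seed, and an
#' exact copy of the resolved configuration are written to
#' `cfg$output_dir`.
#'
#' @param cfg a [run_config()] (or a path to a JSON config).
#' @return invisibly, a list with the comparison data.frame, the CV
#'   reports and the whole-data selections.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  validate_config(cfg)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(cfg$output_dir, "log.txt")
  log_line <- function(...) {
    cat(sprintf(...), "\n", sep = "", file = log_path, append = TRUE)
  }
  cat("", file = log_path)
  write_run_config(cfg, file.path(cfg$output_dir, "config.json"))
  log_line("cafspec pipeline, package version %s",
           as.character(utils::packageVersion("cafspec")))
  log_line("seeds: simulation=%d selection=%d cv=%d",
           cfg$simulation_seed, cfg$selection_seed, cfg$cv_seed)

  # --- stage: simulate or load -------------------------------------
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  if (!is.null(cfg$spectra_file)) {
    spectra <- stage("load", read_spectra(cfg$spectra_file, "reflectance"))
    refs <- stage("load", read_reference(cfg$reference_file, cfg$response))
    log_line("loaded %d spectra from %s", nrow(spectra$values),
             cfg$spectra_file)
  } else {
    scen <- stage("simulate", do.call(fermentation_scenario,
                                      utils::modifyList(
                                        list(seed = cfg$simulation_seed),
                                        cfg$scenario)))
    bench <- stage("simulate", make_benchmark(scen))
    spectra <- bench$spectra
    refs <- if (cfg$response == "pH") bench$ph else bench$tss
    write_spectra(spectra, file.path(cfg$output_dir, "spectra.csv"))
    write_reference(refs, file.path(cfg$output_dir, "reference.csv"))
    log_line("simulated %d profiles", nrow(spectra$values))
  }

  # --- stage: preprocess -------------------------------------------
  pre <- stage("preprocess", {
    a <- reflectance_to_absorbance(spectra)
    sg_smooth(a, poly_order = cfg$sg_order, window = cfg$sg_window)
  })
  write_spectra(pre, file.path(cfg$output_dir, "preprocessed.csv"))
  ds <- stage("join", join_dataset(pre, refs))
  X <- ds$spectra$values
  y <- ds$y

  # --- stage: full-spectrum CV -------------------------------------
  full <- stage("full-cv", run_repeated_kfold(
    X, y, plsr_recipe(ncomp = cfg$ncomp, ncomp_max = cfg$ncomp_max,
                      label = "full"),
    K = cfg$cv_K, reps = cfg$cv_reps, base_seed = cfg$cv_seed))
  utils::write.csv(full$cells, file.path(cfg$output_dir, "cv_full.csv"),
                   row.names = FALSE)
  log_line("full model: R2=%.4f RMSE=%.4g RPD=%.3g",
           full$aggregate$mean["r2"], full$aggregate$mean["rmse"],
           full$aggregate$mean["rpd"])

  # --- stage: selection + optimized CV -----------------------------
  optimized <- list()
  selections <- list()
  for (method in cfg$methods) {
    selector <- .make_selector(cfg, method)
    sel_all <- stage(paste0("select-", method),
                     selector(X, y, cfg$selection_seed))
    selections[[method]] <- sel_all
    write_selection(sel_all,
                    file.path(cfg$output_dir,
                              sprintf("selection_%s.csv", method)),
                    wavelengths = ds$spectra$wavelengths)
    log_line("%s selected %d wavelengths (whole data)", method,
             length(sel_all$indices))
    optimized[[method]] <- stage(paste0("cv-", method), run_repeated_kfold(
      X, y, plsr_recipe(ncomp = cfg$ncomp, ncomp_max = cfg$ncomp_max,
                        selector = selector, label = method),
      K = cfg$cv_K, reps = cfg$cv_reps, base_seed = cfg$cv_seed))
    utils::write.csv(optimized[[method]]$cells,
                     file.path(cfg$output_dir,
                               sprintf("cv_%s.csv", method)),
                     row.names = FALSE)
  }

  # --- stage: compare ----------------------------------------------
  comparison <- stage("compare", compare_models(full, optimized))
  utils::write.csv(comparison, file.path(cfg$output_dir, "comparison.csv"),
                   row.names = FALSE)
  log_line("comparison written (%d rows)", nrow(comparison))

  invisible(list(comparison = comparison, full = full,
                 optimized = optimized, selections = selections,
                 dataset = ds))
}
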