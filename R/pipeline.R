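#' @title Pipeline orchestration
#' @description The end-to-end runner chains the full quality-control
#' workflow on synthetic data: simulate a training cohort, split it into
#' proper-training and calibration parts (grouped by subject), build the
#' Mondrian calibrator, simulate a baseline test set plus any number of
#' shift scenarios, form prediction regions at each requested confidence
#' specification, tally them, draw calibration curves, run the KS drift test
#' for every scenario and a subsampling power curve for every shifted
#' scenario. All artifacts are plain CSV/JSON files under one run directory,
#' and a manifest records seeds, configuration and file hashes so a run is
#' reproducible from the manifest alone.
#' @name cli_io
NULL

#' Derive a stage seed from the master seed
#'
#' The stage name and the decimal digits of the master seed are run through
#' one 31-ary rolling hash (mod 2^31 - 1), so adding a stage never perturbs
#' the seeds of existing stages and distinct (master, stage) pairs never
#' alias each other the way an additive fold would (master 1 + stage "x2"
#' versus master 2 + stage "x1").
#'
#' @param master_seed Integer master seed.
#' @param stage Stage name string.
#' @return Integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master_seed, stage) {
  m <- 2147483647
  h <- 0
  key <- paste0(stage, "#", format(as.integer(master_seed)))
  for (b in utf8ToInt(key)) h <- (h * 31 + b) %% m
  s <- (h * 48271) %% m
  as.integer(if (s == 0) 1 else s)
}

#' Assemble a pipeline configuration
#'
#' @param label_set A [label_set()].
#' @param n_train,n_test Cohort sizes: `n_train` is split 90/10 into
#'   proper-training and calibration by default; `n_test` is the size of the
#'   baseline test set and of each scenario set.
#' @param prevalence Class prevalences (or raw counts) for label generation.
#' @param discriminability,mode Passed to [synthetic_config()].
#' @param biopsies_per_subject Average rows per subject used to attach
#'   subject identifiers to the training cohort (grouped splitting).
#' @param calibration_fraction Calibration share of `n_train`; default 0.10.
#' @param confidences Named list of confidence specifications (each a scalar
#'   or a named per-class vector).
#' @param scenarios Named list of [shift_spec()] objects (may be empty).
#' @param drift_mode,drift_alpha KS drift-test settings.
#' @param power_grid,power_reps,power_threshold Power-curve settings;
#'   `power_grid = NULL` disables power curves.
#' @param smoothed Use smoothed (tie-randomized) p-values throughout?
#' @param master_seed Integer master seed from which all stage seeds derive.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(label_set, n_train = 2000L, n_test = 500L,
                            prevalence = NULL, discriminability = 4,
                            mode = "calibrated", biopsies_per_subject = 6,
                            calibration_fraction = 0.10,
                            confidences = list(global67 = 0.67),
                            scenarios = list(),
                            drift_mode = "labeled", drift_alpha = 0.05,
                            power_grid = NULL, power_reps = 200L,
                            power_threshold = 0.80, smoothed = FALSE,
                            master_seed = 1L) {
  assert_label_set(label_set)
  if (!is.null(prevalence))
    prevalence <- normalize_prevalence(prevalence, n_labels(label_set))
  if (!length(confidences) || is.null(names(confidences)))
    stop("`confidences` must be a non-empty named list", call. = FALSE)
  specs <- lapply(confidences, confidence_spec, label_set = label_set)
  if (length(scenarios)) {
    if (is.null(names(scenarios)))
      stop("`scenarios` must be named", call. = FALSE)
    ok <- vapply(scenarios, inherits, logical(1), "shift_spec")
    if (!all(ok)) stop("every scenario must be a shift_spec", call. = FALSE)
  }
  if (!is.null(power_grid) && max(power_grid) > n_test)
    stop("power_grid exceeds the scenario test size", call. = FALSE)
  structure(list(label_set = label_set, n_train = as.integer(n_train),
                 n_test = as.integer(n_test), prevalence = prevalence,
                 discriminability = discriminability, mode = mode,
                 biopsies_per_subject = biopsies_per_subject,
                 calibration_fraction = calibration_fraction,
                 confidences = specs, scenarios = scenarios,
                 drift_mode = drift_mode, drift_alpha = drift_alpha,
                 power_grid = power_grid, power_reps = as.integer(power_reps),
                 power_threshold = power_threshold, smoothed = smoothed,
                 master_seed = as.integer(master_seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Schema mirrors [pipeline_config()] arguments; see
#' `system.file("extdata", "demo_config.yaml", package = "conformalqc")` for
#' a commented example.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  ls <- label_set(y$labels, ordinal = isTRUE(y$ordinal))
  scen <- list()
  for (nm in names(y$scenarios)) {
    s <- y$scenarios[[nm]]
    scen[[nm]] <- shift_spec(s$kind, magnitude = s$magnitude %||% 1,
                             target_prevalence = s$target_prevalence)
  }
  conf <- lapply(y$confidences, function(cv) {
    if (is.list(cv)) unlist(cv) else cv
  })
  pipeline_config(
    label_set = ls,
    n_train = y$n_train %||% 2000L, n_test = y$n_test %||% 500L,
    prevalence = y$prevalence,
    discriminability = y$discriminability %||% 4,
    mode = y$mode %||% "calibrated",
    biopsies_per_subject = y$biopsies_per_subject %||% 6,
    calibration_fraction = y$calibration_fraction %||% 0.10,
    confidences = conf, scenarios = scen,
    drift_mode = y$drift_mode %||% "labeled",
    drift_alpha = y$drift_alpha %||% 0.05,
    power_grid = y$power_grid, power_reps = y$power_reps %||% 200L,
    power_threshold = y$power_threshold %||% 0.80,
    smoothed = isTRUE(y$smoothed),
    master_seed = y$master_seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full quality-control pipeline
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if absent).
#' @param quiet Suppress progress messages?
#' @return Invisibly, the manifest list (also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  if (!inherits(config, "pipeline_config"))
    stop("`config` must be a pipeline_config", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir))
    stop("cannot create output directory ", out_dir, call. = FALSE)
  say <- function(...) if (!quiet) message(...)
  ls <- config$label_set
  prev <- config$prevalence %||% rep(1, n_labels(ls))
  seeds <- list(train = derive_seed(config$master_seed, "train"),
                split = derive_seed(config$master_seed, "split"),
                regions = derive_seed(config$master_seed, "regions"),
                power = derive_seed(config$master_seed, "power"))

  # training cohort with subject structure
  train_cfg <- synthetic_config(config$n_train, prev,
                                config$discriminability, config$mode,
                                seed = seeds$train)
  train <- simulate_scores(train_cfg, ls, dataset_tag = "train")
  n_subj <- max(1L, round(config$n_train / config$biopsies_per_subject))
  train$subject_id <- sprintf("subj%05d",
                              1 + (seq_len(nrow(train)) %% n_subj))
  parts <- split_train_calibration(train, config$calibration_fraction,
                                   group_field = "subject_id",
                                   seed = seeds$split)
  say("calibration rows: ", nrow(parts$calibration), " of ", nrow(train))
  calibrator <- mondrian_calibrate(parts$calibration)
  say("per-class calibration counts: ",
      paste(sprintf("%s=%d", ls$labels, calibrator$n_per_class),
            collapse = ", "))
  write_calibrator(calibrator, file.path(out_dir, "calibrator.json"))
  write_score_table(parts$calibration,
                    file.path(out_dir, "calibration_scores.csv"))

  # test tables: baseline plus one per shift scenario
  tests <- list()
  base_cfg <- synthetic_config(config$n_test, prev, config$discriminability,
                               config$mode,
                               seed = derive_seed(config$master_seed,
                                                  "test_baseline"))
  tests$baseline <- simulate_scores(base_cfg, ls, dataset_tag = "baseline")
  for (nm in names(config$scenarios)) {
    cfg <- synthetic_config(config$n_test, prev, config$discriminability,
                            config$mode,
                            seed = derive_seed(config$master_seed,
                                               paste0("test_", nm)))
    tab <- simulate_scores(cfg, ls, dataset_tag = nm)
    tests[[nm]] <- apply_shift(tab, config$scenarios[[nm]],
                               seed = derive_seed(config$master_seed,
                                                  paste0("shift_", nm)))
  }

  for (nm in names(tests)) {
    tab <- tests[[nm]]
    write_score_table(tab, file.path(out_dir,
                                     paste0("scores_", nm, ".csv")))
    for (cn in names(config$confidences)) {
      reg <- predict_regions(calibrator, tab, config$confidences[[cn]],
                             smoothed = config$smoothed,
                             seed = seeds$regions)
      write_regions(reg, file.path(out_dir,
                                   paste0("regions_", nm, "_", cn, ".csv")))
      rep_ <- tally_regions(reg, truths = tab$true_label)
      write_report(rep_, file.path(out_dir,
                                   paste0("report_", nm, "_", cn, ".csv")))
      say(nm, " @ ", cn, ": efficiency ",
          round(100 * attr(rep_, "efficiency")[["all"]]), "%")
    }
    pv <- true_label_pvalues(calibrator, tab, smoothed = config$smoothed,
                             seed = seeds$regions)
    curve <- calibration_curve(pv)
    utils::write.csv(as.data.frame(curve),
                     file.path(out_dir, paste0("curve_", nm, ".csv")),
                     row.names = FALSE, quote = FALSE)
    dt <- drift_test(calibrator, tab, mode = config$drift_mode,
                     alpha = config$drift_alpha)
    jsonlite::write_json(unclass(dt),
                         file.path(out_dir, paste0("drift_", nm, ".json")),
                         auto_unbox = TRUE, digits = NA)
    say(nm, ": KS D = ", round(dt$ks_statistic, 4), ", p = ",
        format(dt$p_value, digits = 3))
    if (nm != "baseline" && !is.null(config$power_grid)) {
      pc <- power_curve(calibrator, tab, config$power_grid,
                        n_reps = config$power_reps,
                        alpha = config$drift_alpha,
                        power_threshold = config$power_threshold,
                        mode = config$drift_mode,
                        seed = derive_seed(config$master_seed,
                                           paste0("power_", nm)))
      write_power_curve(pc,
                        csv_path = file.path(out_dir,
                                             paste0("power_", nm, ".csv")),
                        json_path = file.path(out_dir,
                                              paste0("power_", nm, ".json")))
      say(nm, ": minimal detecting sample size ",
          attr(pc, "n_required"))
    }
  }

  files <- setdiff(list.files(out_dir), "manifest.json")
  manifest <- list(
    package = "conformalqc",
    version = as.character(utils::packageVersion("conformalqc")),
    master_seed = config$master_seed,
    stage_seeds = seeds,
    labels = ls$labels,
    n_train = config$n_train, n_test = config$n_test,
    mode = config$mode, smoothed = config$smoothed,
    files = as.list(tools::md5sum(file.path(out_dir, sort(files)))))
  names(manifest$files) <- sort(files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
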