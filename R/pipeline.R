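#' Pipeline configuration
#'
#' Builds the fully-populated configuration for the end-to-end validation
#' pipeline. Every parameter that embodies a methodological choice is
#' surfaced here with its default; unknown keys are rejected so typos fail
#' loudly.
#'
#' @param ... named overrides of the defaults, either top-level keys
#'   (`seed`, `output_dir`) or whole blocks (`simulation`, `filter`,
#'   `gravity`, `sync`, `segment`, `agreement`, `classification`) given as
#'   named lists of partial overrides.
#' @return object of class `pipeline_config` (nested named list).
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 1L,
    output_dir = NULL,
    simulation = list(
      n_participants = 20L, n_cycles = 10L, cycle_duration = 2,
      sampling_rate = 200, accel_noise_sd = 0.05, position_noise_sd = 5e-4,
      cycle_jitter = 0.05, lag_range = c(0L, 80L)
    ),
    filter = list(cutoff_hz = 6, order = 2L),
    gravity = list(enabled = TRUE, value = 9.81),
    sync = list(max_lag_s = 2),
    segment = list(n_bins = 10L),
    agreement = list(bonferroni_m = 8),
    classification = list(n_folds = 10L, C_grid = 10^(-3:3), n_perm = 100L,
                          retune = TRUE)
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) stop(sprintf("unknown config keys: %s", paste(unknown, collapse = ", ")))
  for (nm in names(overrides)) {
    if (is.list(defaults[[nm]]) && is.list(overrides[[nm]])) {
      bad <- setdiff(names(overrides[[nm]]), names(defaults[[nm]]))
      if (length(bad)) {
        stop(sprintf("unknown keys in config block '%s': %s", nm,
                     paste(bad, collapse = ", ")))
      }
      defaults[[nm]][names(overrides[[nm]])] <- overrides[[nm]]
    } else {
      defaults[nm] <- overrides[nm]
    }
  }
  structure(defaults, class = "pipeline_config")
}

#' Load a pipeline configuration file
#'
#' Accepts YAML (if the `yaml` package is installed), JSON, or flat
#' `block.key=value` pairs; values merge over [pipeline_config()] defaults.
#'
#' @param path config file; extension decides the parser (`.yaml`/`.yml`,
#'   `.json`, anything else is parsed as flat `key=value` lines).
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is needed to read YAML configs")
    }
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    lines <- trimws(readLines(path))
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    raw <- list()
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
      if (length(kv) != 2L) stop(sprintf("malformed config line: '%s'", ln))
      keys <- strsplit(trimws(kv[1L]), ".", fixed = TRUE)[[1L]]
      val <- utils::type.convert(trimws(kv[2L]), as.is = TRUE)
      if (length(keys) == 1L) raw[[keys]] <- val
      else raw[[keys[1L]]][[keys[2L]]] <- val
    }
    raw
  }
  do.call(pipeline_config, raw)
}

#' Run the end-to-end validation pipeline
#'
#' Simulates (or ingests) the paired study design, preprocesses both
#' modalities, synchronizes, segments and bins every recording, then runs
#' the agreement and classification analyses, including both directions of
#' cross-classification and (optionally) permutation tests. Fully
#' reproducible from `(config, seed)`.
#'
#' @param cfg a [pipeline_config()].
#' @param dataset optional pre-built [generate_dataset()]-style list; when
#'   `NULL`, the dataset is simulated from the config.
#' @param verbose print stage progress.
#' @return object of class `run_report`.
#' @export
run_validation_pipeline <- function(cfg = pipeline_config(), dataset = NULL,
                                    verbose = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  sim <- cfg$simulation
  if (is.null(dataset)) {
    say("simulating %d participants", sim$n_participants)
    dataset <- stage("simulate", generate_dataset(
      n_participants = sim$n_participants,
      movement_specs = default_movement_specs(cycle_duration = sim$cycle_duration,
                                              n_cycles = sim$n_cycles),
      cfg = sim_config(sampling_rate = sim$sampling_rate,
                       accel_noise_sd = sim$accel_noise_sd,
                       position_noise_sd = sim$position_noise_sd,
                       cycle_jitter = sim$cycle_jitter, seed = cfg$seed),
      lag_range = sim$lag_range))
  }
  gravity <- if (isTRUE(cfg$gravity$enabled)) cfg$gravity$value else 0
  say("preprocessing, synchronizing and binning %d recordings", length(dataset))
  pairs <- stage("preprocess/sync/segment", lapply(dataset, function(rec) {
    process_pair(rec$imu, rec$mocap, gravity = gravity,
                 cutoff = cfg$filter$cutoff_hz, order = cfg$filter$order,
                 max_lag = round(cfg$sync$max_lag_s * rec$imu$fs),
                 n_bins = cfg$segment$n_bins)
  }))
  cycles_kid <- bind_cycle_sets(lapply(pairs, `[[`, "kid"))
  cycles_mocap <- bind_cycle_sets(lapply(pairs, `[[`, "mocap"))
  say("agreement analysis")
  icc <- stage("agreement", agreement_analysis(cycles_kid, cycles_mocap,
                                               bonferroni_m = cfg$agreement$bonferroni_m))
  cl <- cfg$classification
  feat_kid <- build_features(cycles_kid)
  feat_mocap <- build_features(cycles_mocap)
  say("within-source classification")
  res_kid <- stage("classify kid",
                   nested_cv_svm(feat_kid, n_folds = cl$n_folds,
                                 C_grid = cl$C_grid, seed = cfg$seed))
  res_mocap <- stage("classify mocap",
                     nested_cv_svm(feat_mocap, n_folds = cl$n_folds,
                                   C_grid = cl$C_grid, seed = cfg$seed))
  say("cross-classification")
  res_cross_mk <- stage("cross-classify mocap->kid",
                        cross_classify(feat_mocap, feat_kid, C_grid = cl$C_grid,
                                       n_folds = cl$n_folds, seed = cfg$seed))
  res_cross_km <- stage("cross-classify kid->mocap",
                        cross_classify(feat_kid, feat_mocap, C_grid = cl$C_grid,
                                       n_folds = cl$n_folds, seed = cfg$seed))
  if (cl$n_perm > 0L) {
    say("permutation tests (%d permutations)", cl$n_perm)
    for (nm in c("res_kid", "res_mocap")) {
      res <- get(nm)
      tab <- if (nm == "res_kid") feat_kid else feat_mocap
      pt <- stage("permutation test",
                  permutation_test(tab, res$mean_accuracy, n_perm = cl$n_perm,
                                   seed = cfg$seed, n_folds = cl$n_folds,
                                   C_grid = cl$C_grid, retune = cl$retune))
      res$null_distribution <- pt$null_distribution
      res$p_perm <- pt$p
      assign(nm, res)
    }
  }
  report <- structure(list(
    icc = icc,
    classification = list(kid = res_kid, mocap = res_mocap,
                          cross_mocap_to_kid = res_cross_mk,
                          cross_kid_to_mocap = res_cross_km),
    lags = vapply(pairs, `[[`, numeric(1), "lag"),
    n_cycles = n_cycles(cycles_kid),
    provenance = list(seed = cfg$seed,
                      config = unclass(cfg),
                      package_version = as.character(utils::packageVersion("kidmotion")),
                      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  ), class = "run_report")
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
    write_report_json(report, file.path(cfg$output_dir, "report.json"))
    utils::write.csv(icc, file.path(cfg$output_dir, "icc.csv"), row.names = FALSE)
    write_cycle_set_csv(cycles_kid, file.path(cfg$output_dir, "cycles_kid.csv"))
    write_cycle_set_csv(cycles_mocap, file.path(cfg$output_dir, "cycles_mocap.csv"))
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d cycles, seed %s\n", x$n_cycles, x$provenance$seed))
  cat("ICC consistency by movement type:\n")
  print(stats::setNames(round(x$icc$consistency, 4), x$icc$movement_type))
  for (r in x$classification) print(r)
  invisible(x)
}

#' Serialize a run report to JSON
#'
#' @param report a `run_report`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "run_report"))
  ser_cls <- function(r) {
    list(label = r$label, fold_accuracies = r$fold_accuracies,
         mean_accuracy = r$mean_accuracy, sem = r$sem,
         confusion_percent = as.data.frame.matrix(r$confusion),
         chosen_C = r$chosen_C,
         null_distribution = r$null_distribution, p_perm = r$p_perm)
  }
  out <- list(schema_version = "1.0",
              icc = report$icc,
              classification = lapply(report$classification, ser_cls),
              lags = report$lags, n_cycles = report$n_cycles,
              provenance = report$provenance)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}
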