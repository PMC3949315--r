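#' @importFrom rlang .data
NULL

check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

read_checked_csv <- function(path, required, what) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  probs <- readr::problems(df)
  if (nrow(probs)) {
    stop(sprintf("parse error in %s at row %d: expected %s, got '%s'",
                 path, probs$row[1], probs$expected[1], probs$actual[1]),
         call. = FALSE)
  }
  check_columns(df, required, what)
  df
}

#' Read and write trial trajectories
#'
#' Long CSV schema with one row per sample: `trial_id`, `t`, `x`, `y`, `vx`,
#' `vy`, and optional hand-force columns `fx`, `fy`. SI units; header
#' mandatory.
#'
#' @param path CSV file path.
#' @param trajectories Long tibble of trajectory samples.
#' @return `read_trajectory_csv()` returns the tibble; the writer returns the
#'   path invisibly.
#' @export
read_trajectory_csv <- function(path) {
  read_checked_csv(path, c("trial_id", "t", "x", "y"), "trajectory CSV")
}

#' @rdname read_trajectory_csv
#' @export
write_trajectory_csv <- function(trajectories, path) {
  check_columns(trajectories, c("trial_id", "t", "x", "y"), "trajectory table")
  readr::write_csv(trajectories, path)
  invisible(path)
}

#' Read and write generalization datasets
#'
#' CSV schema: `subject_id`, `movement_id`, `adaptation` (normalized,
#' dimensionless).
#'
#' @param path CSV file path.
#' @param dataset Tibble with the dataset columns.
#' @return The tibble (reader) or the path, invisibly (writer).
#' @export
read_dataset_csv <- function(path) {
  df <- read_checked_csv(path, c("subject_id", "movement_id", "adaptation"),
                         "generalization dataset CSV")
  if (!nrow(df)) stop("dataset is empty", call. = FALSE)
  df
}

#' @rdname read_dataset_csv
#' @export
write_dataset_csv <- function(dataset, path) {
  check_columns(dataset, c("subject_id", "movement_id", "adaptation"),
                "generalization dataset")
  readr::write_csv(dataset, path)
  invisible(path)
}

#' Serialize a fitted model to JSON
#'
#' Writes every field of a `reachfit` (weights, decay rates, MSE, n, dof,
#' BIC, seed, convergence flag) at full precision; `read_fit_json()` restores
#' the object.
#'
#' @param fit A `reachfit` object.
#' @param path JSON file path.
#' @return The path (writer) or the restored `reachfit` (reader).
#' @export
write_fit_json <- function(fit, path) {
  payload <- list(
    components = fit$spec$components, decay = fit$spec$decay,
    k = as.list(fit$k), d = as.list(fit$d), mse = fit$mse, n = fit$n,
    dof = fit$dof, bic = fit$bic, seed = fit$seed, converged = fit$converged
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname write_fit_json
#' @export
read_fit_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- mixture_spec(p$components, p$decay)
  structure(
    list(k = unlist(p$k), d = unlist(p$d), mse = p$mse, n = p$n, dof = p$dof,
         bic = if (is.null(p$bic)) -Inf else p$bic, spec = spec,
         seed = p$seed, converged = p$converged),
    class = "reachfit"
  )
}

#' Read and write trial schedules
#'
#' @param schedule A schedule tibble from [make_schedule_exp1()] or
#'   [make_schedule_exp2()].
#' @param path CSV file path.
#' @return The tibble (reader) or the path, invisibly (writer).
#' @export
write_schedule_csv <- function(schedule, path) {
  check_columns(schedule, c("trial_id", "stage", "type"), "schedule")
  readr::write_csv(schedule, path)
  invisible(path)
}

#' @rdname write_schedule_csv
#' @export
read_schedule_csv <- function(path) {
  read_checked_csv(path, c("trial_id", "stage", "type"), "schedule CSV")
}

default_run_config <- function() {
  list(
    experiment = "1",
    arm = list(upper = 0.30, lower = 0.25, hand = 0.07),
    field = list(kind = "extrinsic",
                 B = list(c(-10.1, -11.2), c(-11.2, 11.1))),
    train_posture = list(shoulder = 35, elbow = 75, wrist = 12.3),
    models = c("joint", "cartesian", "object"),
    n_subjects = 9,
    truth = list(k = list(J = 1), sigma = 0.1),
    seed = 1
  )
}

#' Read and validate a run configuration
#'
#' A single hierarchical YAML file describing the experiment variant, arm
#' geometry, field matrix, training posture, model list, cohort size,
#' ground-truth parameters and seed. Unknown top-level keys are rejected;
#' missing keys fall back to the defaults.
#'
#' @param path YAML file path, or `NULL` for the default configuration.
#' @return A validated configuration list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown)) {
      stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
           call. = FALSE)
    }
    cfg[names(user)] <- user
  }
  arm <- cfg$arm
  if (!all(c("upper", "lower", "hand") %in% names(arm))) {
    stop("config `arm` must give upper, lower and hand lengths", call. = FALSE)
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1) {
    stop("config `seed` must be a single number", call. = FALSE)
  }
  cfg
}

config_arm <- function(cfg) {
  arm_model(cfg$arm$upper, cfg$arm$lower, cfg$arm$hand)
}

config_B <- function(cfg) {
  B <- do.call(rbind, cfg$field$B)
  if (!all(dim(B) == c(2, 2))) stop("config field B must be 2 x 2", call. = FALSE)
  B
}

config_posture <- function(cfg) {
  joint_posture(cfg$train_posture$shoulder, cfg$train_posture$elbow,
                cfg$train_posture$wrist, degrees = TRUE)
}

#' Pipeline: write coordinate-frame predictions
#'
#' Computes the per-sample predicted force series and the normalized
#' adaptation summary for every model and test movement described by the
#' configuration, and writes `forces.csv` (`movement_id`, `model`, `t`,
#' `f_perp`) and `summary.csv` (`movement_id`, `model`, `normalized_adaptation`)
#' to `out_dir`.
#'
#' @param config Configuration list from [read_run_config()].
#' @param out_dir Output directory (created if needed).
#' @return Paths of the written files, invisibly.
#' @export
run_predictions <- function(config = read_run_config(), out_dir = ".") {
  arm <- config_arm(config)
  B <- config_B(config)
  tp <- config_posture(config)
  movements <- test_movements(arm, tp)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  forces <- purrr::map_dfr(config$models, function(m) {
    purrr::map_dfr(seq_len(nrow(movements)), function(i) {
      fs <- predict_forces(arm, movements[i, ], model = m, B = B,
                           train_posture = tp)
      tibble::tibble(movement_id = movements$movement_id[i], model = m,
                     t = fs$t, f_perp = fs$f_perp)
    })
  })
  preds <- predict_generalization(arm, movements, config$models, B, tp)
  f_path <- file.path(out_dir, "forces.csv")
  s_path <- file.path(out_dir, "summary.csv")
  readr::write_csv(forces, f_path)
  readr::write_csv(
    dplyr::select(preds, "movement_id", "model",
                  normalized_adaptation = "adaptation"), s_path)
  invisible(c(f_path, s_path))
}

#' Pipeline: write a synthetic study to disk
#'
#' Runs [simulate_cohort()] under the configuration and writes the schedule,
#' simulated exposure trajectories, channel-trial dataset and a manifest
#' (seed included) to `out_dir`.
#'
#' @inheritParams run_predictions
#' @return Paths of the written files, invisibly.
#' @export
run_simulation <- function(config = read_run_config(), out_dir = ".") {
  if (!is.numeric(config$seed) || length(config$seed) != 1 ||
      !is.finite(config$seed)) {
    stop("config `seed` must be a finite number", call. = FALSE)
  }
  truth <- ground_truth_model(
    k = unlist(config$truth$k),
    d = if (!is.null(config$truth$d)) unlist(config$truth$d) else NULL,
    sigma = config$truth$sigma %||% 0.1
  )
  arm <- config_arm(config)
  movements <- test_movements(arm, config_posture(config))
  design <- generalization_design(arm, movements, config_B(config),
                                  config_posture(config))
  cohort <- simulate_cohort(truth, config$n_subjects, arm, design,
                            seed = config$seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    schedule = file.path(out_dir, "schedule.csv"),
    trajectories = file.path(out_dir, "trajectories.csv"),
    dataset = file.path(out_dir, "dataset.csv"),
    manifest = file.path(out_dir, "manifest.json")
  )
  write_schedule_csv(cohort$schedule, paths["schedule"])
  write_trajectory_csv(cohort$trajectories, paths["trajectories"])
  write_dataset_csv(cohort$dataset, paths["dataset"])
  jsonlite::write_json(
    list(seed = config$seed, n_subjects = config$n_subjects,
         truth = list(k = as.list(truth$k), d = as.list(truth$d),
                      sigma = truth$sigma)),
    paths["manifest"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Pipeline: fit the model family to a dataset on disk
#'
#' Reads a generalization-dataset CSV, fits all 14 mixture/decay models,
#' writes one JSON per fit plus a BIC comparison table (`comparison.csv`,
#' sorted ascending, with the BIC improvement over the no-generalization
#' reference).
#'
#' @param dataset_path CSV path (see [read_dataset_csv()]).
#' @param out_dir Output directory.
#' @param design Design tibble; defaults to the cached [default_design()].
#' @param seed Seed for the decay-rate restarts.
#' @return The comparison tibble, invisibly.
#' @export
run_fit <- function(dataset_path, out_dir = ".", design = default_design(),
                    seed = 1) {
  data <- read_dataset_csv(dataset_path)
  fits <- fit_all_models(data, design, seed = seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(fits)) {
    write_fit_json(fits[[nm]],
                   file.path(out_dir, paste0("fit_", gsub("[+ ]", "_", nm),
                                             ".json")))
  }
  cmp <- compare_models(fits, data)
  readr::write_csv(cmp, file.path(out_dir, "comparison.csv"))
  invisible(cmp)
}

#' Pipeline: metrics table for trajectories on disk
#'
#' @param trajectory_path Trajectory CSV path (see [read_trajectory_csv()]).
#' @param out_path Output CSV path.
#' @return The metrics tibble, invisibly.
#' @export
run_metrics <- function(trajectory_path, out_path = "metrics.csv") {
  traj <- read_trajectory_csv(trajectory_path)
  metrics <- trial_metrics(traj)
  readr::write_csv(metrics, out_path)
  invisible(metrics)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
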