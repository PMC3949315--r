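#' Test-movement grid for the generalization experiment
#'
#' Builds the 15 channel-trial test movements: 3 joint configurations
#' (shoulder/elbow of (35, 75), (35, 120) and (80, 75) degrees) crossed with 5
#' hand-orientation offsets (0 to -45 degrees in 11.25-degree steps applied at
#' the wrist, relative to the training wrist angle). Within a configuration
#' the wrist position and its translation are identical across the five
#' orientations, so only the hand orientation differs. The movement for
#' configuration 1 heads directly ahead (+y); configurations 2 and 3 share a
#' single direction. Its default (down-left, 225 degrees from the workspace
#' +x axis) is the direction, among the eight experiment directions, that
#' maximizes the minimum pairwise separation of the three coordinate-frame
#' model predictions over the full grid — i.e. the maximally informative
#' direction for distinguishing the models.
#'
#' @param arm An [arm_model()].
#' @param train_posture The training [joint_posture()].
#' @param reach Reach distance in meters (default 0.10).
#' @param directions Named list of unit 2-vectors giving the movement
#'   direction per configuration.
#' @return A tibble with one row per test movement: posture, start/target
#'   positions, channel geometry, and signed deviations from the training
#'   posture (joint angles in radians, hand position in meters, hand
#'   orientation in radians).
#' @export
test_movements <- function(arm = arm_model(),
                           train_posture = training_posture(),
                           reach = 0.10,
                           directions = list(`1` = c(0, 1),
                                             `2` = c(-1, -1) / sqrt(2),
                                             `3` = c(-1, -1) / sqrt(2))) {
  configs <- list(`1` = c(35, 75), `2` = c(35, 120), `3` = c(80, 75))
  offsets <- c(0, -11.25, -22.5, -33.75, -45)
  qt <- as.numeric(train_posture)
  fk_train <- forward_kinematics(arm, train_posture)

  grid <- tidyr::expand_grid(config = 1:3, orientation = offsets)
  rows <- purrr::pmap(grid, function(config, orientation) {
    qc <- configs[[as.character(config)]] * pi / 180
    q <- joint_posture(qc[1], qc[2], qt[3] + orientation * pi / 180)
    qv <- as.numeric(q)
    fk <- forward_kinematics(arm, q)
    u <- directions[[as.character(config)]]
    u <- u / sqrt(sum(u^2))
    start <- fk$position
    target <- start + reach * u
    tibble::tibble(
      config = config, orientation = orientation,
      q_s = qv[1], q_e = qv[2], q_w = qv[3],
      hand_orientation = sum(qv),
      start_x = start[1], start_y = start[2],
      target_x = target[1], target_y = target[2],
      dir_x = u[1], dir_y = u[2],
      dtheta_s = qv[1] - qt[1], dtheta_e = qv[2] - qt[2],
      dtheta_w = qv[3] - qt[3],
      dx = start[1] - fk_train$position[1],
      dy = start[2] - fk_train$position[2],
      dtheta_hand = sum(qv) - sum(qt)
    )
  })
  out <- dplyr::bind_rows(rows)
  dplyr::mutate(out, movement_id = dplyr::row_number(), .before = 1)
}

# minimum-jerk plan for one test movement, with the posture time series
# reconstructed at each sample from the hand position under the constant
# hand-orientation constraint
movement_plan <- function(arm, movement, duration = 0.4, dt = 0.001,
                          pad = 0.2) {
  plan <- min_jerk_trajectory(c(movement$start_x, movement$start_y),
                              c(movement$target_x, movement$target_y),
                              duration = duration, dt = dt, pad = pad)
  h <- movement$hand_orientation
  qs <- t(vapply(seq_len(nrow(plan)), function(i) {
    as.numeric(posture_from_hand(arm, c(plan$x[i], plan$y[i]), h))
  }, numeric(3)))
  plan$q_s <- qs[, 1]; plan$q_e <- qs[, 2]; plan$q_w <- qs[, 3]
  plan
}

rotation_matrix <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), nrow = 2)
}

#' Predicted channel-trial force series under one coordinate-frame model
#'
#' Predicts the hand force a fully adapted subject would produce on a channel
#' trial at a test movement, under each candidate representation of the
#' learned field:
#'
#' * `"cartesian"`: the field is represented in hand space, so the predicted
#'   force is `B v(t)` regardless of posture.
#' * `"object"`: the field is attached to the grasped handle and rotates with
#'   the hand orientation, `R(theta) B R(-theta) v(t)` where `theta` is the
#'   change in hand orientation in external space from the training posture.
#' * `"joint"`: the field is represented as a map from the three joint
#'   angular velocities to joint torques, `W = t(J_train) B J_train` (2 x 3
#'   Jacobian); the predicted hand force is the least-squares force
#'   equivalent of the predicted torques,
#'   `(J J^T)^-1 J W qdot(t)`, with the Jacobian re-evaluated every sample.
#' * `"virtual_segment"`: as `"joint"` but with 2 x 2 Jacobians built on the
#'   elbow-to-hand virtual segment, giving
#'   `B_gen = (J^T)^-1 t(J_train) B J_train J^-1`.
#'
#' @param arm An [arm_model()].
#' @param movement One row of [test_movements()].
#' @param model Coordinate-frame model name.
#' @param B Cartesian field matrix.
#' @param train_posture Training posture.
#' @param duration,dt,pad Movement plan parameters (seconds); the pad keeps
#'   the series sampled well past the 450 ms analysis window.
#' @return A tibble with `t`, `fx`, `fy`, `f_perp` (force projected on the
#'   channel normal) and `speed`.
#' @export
predict_forces <- function(arm, movement,
                           model = c("cartesian", "object", "joint",
                                     "virtual_segment"),
                           B = training_field_matrix(),
                           train_posture = training_posture(),
                           duration = 0.4, dt = 0.001, pad = 0.2) {
  model <- match.arg(model)
  plan <- movement_plan(arm, movement, duration, dt, pad)
  V <- rbind(plan$vx, plan$vy)
  Fmat <- switch(model,
    cartesian = B %*% V,
    object = {
      R <- rotation_matrix(movement$dtheta_hand)
      R %*% B %*% t(R) %*% V
    },
    joint = {
      J_train <- arm_jacobian(arm, train_posture, "three_joint")
      W <- joint_field_matrix(B, J_train)
      vapply(seq_len(ncol(V)), function(i) {
        q <- c(plan$q_s[i], plan$q_e[i], plan$q_w[i])
        qdot <- constrained_joint_velocities(arm, q, V[, i])
        J <- arm_jacobian(arm, q, "three_joint")
        M <- J %*% t(J)
        if (abs(det(M)) < 1e-12) {
          stop("singular J %*% t(J) along the movement plan", call. = FALSE)
        }
        as.numeric(solve(M, J %*% (W %*% qdot)))
      }, numeric(2))
    },
    virtual_segment = {
      J_train <- arm_jacobian(arm, train_posture, "virtual_segment")
      core <- t(J_train) %*% B %*% J_train
      vapply(seq_len(ncol(V)), function(i) {
        q <- c(plan$q_s[i], plan$q_e[i], plan$q_w[i])
        J <- arm_jacobian(arm, q, "virtual_segment")
        if (abs(det(J)) < 1e-12) {
          stop("singular virtual-segment Jacobian along the movement plan",
               call. = FALSE)
        }
        as.numeric(solve(t(J), core %*% solve(J, V[, i])))
      }, numeric(2))
    }
  )
  n <- c(-movement$dir_y, movement$dir_x) # +90 deg rotation of direction
  tibble::tibble(
    t = plan$t,
    fx = Fmat[1, ], fy = Fmat[2, ],
    f_perp = n[1] * Fmat[1, ] + n[2] * Fmat[2, ],
    speed = sqrt(plan$vx^2 + plan$vy^2)
  )
}

#' Windowed mean perpendicular force, normalized to the training posture
#'
#' The channel-trial adaptation measure: the perpendicular force is averaged
#' over 50-450 ms after movement onset (onset = speed first exceeding 0.5
#' cm/s), the pre-exposure baseline average is subtracted, and the result is
#' divided by the training-posture magnitude so the training movement scores
#' 1 by construction.
#'
#' @param forces A tibble from [predict_forces()] (or measured channel data
#'   with the same columns `t`, `f_perp`, `speed`).
#' @param baseline Baseline (pre-exposure) windowed mean to subtract, N.
#' @param training_magnitude Normalizing magnitude, N (use 1 to obtain the
#'   raw windowed mean).
#' @param onset_threshold Speed threshold defining movement onset, m/s.
#' @param window Averaging window relative to onset, seconds.
#' @return A single dimensionless adaptation value.
#' @export
perp_force_summary <- function(forces, baseline = 0, training_magnitude = 1,
                               onset_threshold = 0.005,
                               window = c(0.05, 0.45)) {
  onset_idx <- which(forces$speed > onset_threshold)[1]
  if (is.na(onset_idx)) stop("no movement onset found", call. = FALSE)
  t_rel <- forces$t - forces$t[onset_idx]
  if (max(t_rel) < window[2]) {
    stop(sprintf("series ends %.0f ms after onset; %.0f ms required",
                 1000 * max(t_rel), 1000 * window[2]), call. = FALSE)
  }
  sel <- t_rel >= window[1] & t_rel <= window[2]
  (mean(forces$f_perp[sel]) - baseline) / training_magnitude
}

#' Normalized generalization predictions for all test movements
#'
#' Runs every coordinate-frame model over the full test-movement grid,
#' summarizes each predicted force series with [perp_force_summary()], and
#' normalizes each model by its own training-posture magnitude (so every
#' model predicts exactly 1 at the training movement).
#'
#' @inheritParams predict_forces
#' @param movements Tibble from [test_movements()].
#' @param models Character vector of model names.
#' @return A tibble `movement_id`, `config`, `orientation`, `model`,
#'   `adaptation` (normalized), `raw` (windowed mean force, N).
#' @export
predict_generalization <- function(arm = arm_model(),
                                   movements = test_movements(arm),
                                   models = c("joint", "cartesian", "object"),
                                   B = training_field_matrix(),
                                   train_posture = training_posture(),
                                   duration = 0.4, dt = 0.001, pad = 0.2) {
  res <- purrr::map_dfr(models, function(m) {
    raw <- vapply(seq_len(nrow(movements)), function(i) {
      fs <- predict_forces(arm, movements[i, ], model = m, B = B,
                           train_posture = train_posture,
                           duration = duration, dt = dt, pad = pad)
      perp_force_summary(fs)
    }, numeric(1))
    tibble::tibble(movement_id = movements$movement_id,
                   config = movements$config,
                   orientation = movements$orientation,
                   model = m, raw = raw)
  })
  # training movement: configuration 1 at orientation offset 0
  res |>
    dplyr::group_by(.data$model) |>
    dplyr::mutate(adaptation = .data$raw /
                    .data$raw[.data$config == 1 & .data$orientation == 0]) |>
    dplyr::ungroup() |>
    dplyr::select("movement_id", "config", "orientation", "model",
                  "adaptation", "raw")
}

#' Design table for generalization model fitting
#'
#' One row per test movement with the three normalized single-coordinate
#' model predictions (`J`, `C`, `O`) and the squared deviations from the
#' training posture in each model's own metric: `dist_joint2` (rad^2, sum of
#' squared joint-angle changes), `dist_cart2` (m^2, squared Cartesian hand
#' displacement) and `dist_hand2` (rad^2, squared hand-orientation change).
#' This is the input the mixture/decay fitting stage needs.
#'
#' @inheritParams predict_generalization
#' @return A tibble with columns `movement_id`, `config`, `orientation`,
#'   `J`, `C`, `O`, `dist_joint2`, `dist_cart2`, `dist_hand2`.
#' @export
generalization_design <- function(arm = arm_model(),
                                  movements = test_movements(arm),
                                  B = training_field_matrix(),
                                  train_posture = training_posture(),
                                  duration = 0.4, dt = 0.001, pad = 0.2) {
  preds <- predict_generalization(arm, movements, c("joint", "cartesian",
                                                    "object"),
                                  B, train_posture, duration, dt, pad)
  wide <- preds |>
    dplyr::select("movement_id", "model", "adaptation") |>
    tidyr::pivot_wider(names_from = "model", values_from = "adaptation") |>
    dplyr::rename(J = "joint", C = "cartesian", O = "object")
  movements |>
    dplyr::transmute(
      .data$movement_id, .data$config, .data$orientation,
      dist_joint2 = .data$dtheta_s^2 + .data$dtheta_e^2 + .data$dtheta_w^2,
      dist_cart2 = .data$dx^2 + .data$dy^2,
      dist_hand2 = .data$dtheta_hand^2
    ) |>
    dplyr::left_join(wide, by = "movement_id") |>
    dplyr::select("movement_id", "config", "orientation", "J", "C", "O",
                  "dist_joint2", "dist_cart2", "dist_hand2")
}

the_design_cache <- new.env(parent = emptyenv())

#' Cached default design table
#'
#' [generalization_design()] with all defaults, computed once per session.
#' Convenient for fitting and simulation helpers that repeatedly need the
#' default predictions.
#'
#' @return See [generalization_design()].
#' @export
default_design <- function() {
  if (is.null(the_design_cache$design)) {
    the_design_cache$design <- generalization_design()
  }
  the_design_cache$design
}
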