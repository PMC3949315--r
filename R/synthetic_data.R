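#' Ground-truth generalization model for synthetic cohorts
#'
#' Defines the data-generating process for synthetic channel-trial datasets:
#' a mixture/decay model (the same family the fitting stage estimates), an
#' additive Gaussian noise level, and an optional per-subject scaling spread.
#'
#' @param k Named mixture weights over `c("J", "C", "O")` (nonnegative,
#'   sum 1); omitted components are zero.
#' @param d Named decay rates for the weighted components (rad^-2 for `J`/`O`,
#'   m^-2 for `C`), or `NULL` for a no-decay truth.
#' @param sigma Standard deviation of additive Gaussian noise on each
#'   adaptation value, as a fraction of the training-posture magnitude
#'   (adaptation values are normalized so that magnitude is 1).
#' @param subject_scale_sd Standard deviation of the per-subject multiplicative
#'   scaling factor (mean 1); default 0 (all subjects identical in
#'   expectation).
#' @return A `ground_truth_model` object.
#' @export
ground_truth_model <- function(k = c(J = 1), d = NULL, sigma = 0.1,
                               subject_scale_sd = 0) {
  full_k <- stats::setNames(rep(0, 3), c("J", "C", "O"))
  if (is.null(names(k))) stop("`k` must be named", call. = FALSE)
  full_k[names(k)] <- k
  if (any(full_k < 0) || abs(sum(full_k) - 1) > 1e-8) {
    stop("`k` must be nonnegative and sum to 1", call. = FALSE)
  }
  if (sigma < 0) stop("`sigma` must be >= 0", call. = FALSE)
  if (subject_scale_sd < 0) stop("`subject_scale_sd` must be >= 0", call. = FALSE)
  full_d <- stats::setNames(rep(0, 3), c("J", "C", "O"))
  decay <- !is.null(d)
  if (decay) {
    if (is.null(names(d))) stop("`d` must be named", call. = FALSE)
    if (any(d < 0)) stop("decay rates must be >= 0", call. = FALSE)
    full_d[names(d)] <- d
  }
  structure(list(k = full_k, d = full_d, decay = decay, sigma = sigma,
                 subject_scale_sd = subject_scale_sd),
            class = "ground_truth_model")
}

# noiseless prediction of a ground truth at every design row
truth_prediction <- function(truth, design) {
  comps <- names(truth$k)[truth$k > 0]
  spec <- mixture_spec(comps, decay = truth$decay)
  predict_mixture(design, spec, k = truth$k[comps],
                  d = if (truth$decay) truth$d[comps] else NULL)
}

#' Simulate a channel-trial generalization dataset
#'
#' Draws per-subject normalized adaptation values at every test movement from
#' a ground-truth mixture/decay model: `adaptation = scale_s * prediction +
#' noise`, with `scale_s ~ N(1, subject_scale_sd)` and Gaussian noise of
#' standard deviation `sigma`.
#'
#' @param truth A [ground_truth_model()].
#' @param n_subjects Number of synthetic subjects.
#' @param design Design tibble from [generalization_design()].
#' @param seed Integer seed; the dataset is reproducible given the seed.
#' @return A tibble `subject_id`, `movement_id`, `adaptation` with the truth
#'   attached as attribute `"truth"`.
#' @export
simulate_channel_dataset <- function(truth, n_subjects = 9,
                                     design = default_design(), seed = 1) {
  pred <- truth_prediction(truth, design)
  out <- withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n_subjects), function(s) {
      scale_s <- 1 + truth$subject_scale_sd * stats::rnorm(1)
      tibble::tibble(
        subject_id = sprintf("S%02d", s),
        movement_id = design$movement_id,
        adaptation = scale_s * pred +
          truth$sigma * stats::rnorm(nrow(design))
      )
    })
  })
  attr(out, "truth") <- truth
  out
}

#' Trial-by-trial adaptation level
#'
#' Single-rate exponential update of the learned compensation fraction toward
#' an asymptote: `lambda <- lambda + rate * (asymptote - lambda)` on every
#' field trial. Channel-trial force grows toward about 80% of full
#' compensation during training, which the default asymptote reproduces; the
#' update rule itself is scaffolding for qualitative learning curves, not an
#' estimated model.
#'
#' @param n_trials Number of field exposures.
#' @param rate Per-trial learning rate.
#' @param asymptote Asymptotic compensation fraction.
#' @param initial Starting fraction.
#' @return Numeric vector of compensation fractions after each trial.
#' @export
learning_curve <- function(n_trials, rate = 0.01, asymptote = 0.8,
                           initial = 0) {
  asymptote - (asymptote - initial) * (1 - rate)^seq_len(n_trials)
}

# random walk of 10-cm reaches in 8 directions (0 = straight ahead = +y,
# counterclockwise) confined to a square workspace; returns start/target
# positions and the direction for each of n steps
random_walk_targets <- function(n, center, half_width = 0.075, reach = 0.10) {
  dirs <- seq(0, 315, by = 45)
  # direction 0 is straight ahead (+y); angles increase counterclockwise
  vecs <- cbind(-sin(dirs * pi / 180), cos(dirs * pi / 180)) * reach
  pos <- center
  out <- matrix(NA_real_, n, 5)
  for (i in seq_len(n)) {
    cand <- sweep(vecs, 2, pos, `+`)
    ok <- which(abs(cand[, 1] - center[1]) <= half_width + 1e-12 &
                  abs(cand[, 2] - center[2]) <= half_width + 1e-12)
    if (!length(ok)) stop("random walk stranded outside the workspace",
                          call. = FALSE)
    pick <- ok[sample.int(length(ok), 1)]
    out[i, ] <- c(dirs[pick], pos, cand[pick, ])
    pos <- cand[pick, ]
  }
  tibble::tibble(direction = out[, 1], start_x = out[, 2], start_y = out[, 3],
                 target_x = out[, 4], target_y = out[, 5])
}

# interleave k marked items into n slots such that every marked item is
# immediately followed by an unmarked one (pair trick): k pairs + (n - 2k)
# singles, shuffled
interleave_followed <- function(n, k) {
  blocks <- c(rep(2L, k), rep(1L, n - 2L * k))
  blocks <- sample(blocks)
  starts <- cumsum(c(1L, utils::head(blocks, -1L)))
  marked <- starts[blocks == 2L]
  list(marked = marked, followers = marked + 1L)
}

#' Trial schedule for the posture-generalization experiment
#'
#' Generates the three-stage schedule: a 128-trial preexposure stage (113
#' null-field movements and 1 channel trial at each of the 15 test
#' movements), a 496-trial exposure stage, and a 600-trial generalization
#' stage mixing 525 exposure movements with 75 channel trials (5 repetitions
#' of each test movement). Training movements form a pseudorandom walk of
#' 10-cm reaches in 8 directions confined to the 15 x 15 cm training area;
#' every channel trial is immediately followed by a training-area movement.
#'
#' @param arm An [arm_model()].
#' @param movements Test-movement grid from [test_movements()].
#' @param seed Integer seed.
#' @param counts Stage sizes (change only for reduced test runs).
#' @return A tibble with one row per trial: `trial_id`, `stage`, `type`
#'   (`"null"`, `"field"` or `"channel"`), `movement_id` (channel trials),
#'   `direction`, `start_x/y`, `target_x/y`, `config`, `orientation`.
#' @export
make_schedule_exp1 <- function(arm = arm_model(),
                               movements = test_movements(arm),
                               seed = 1,
                               counts = list(pre_null = 113, pre_channel = 1,
                                             exposure = 496, gen_field = 525,
                                             gen_channel = 5)) {
  center <- forward_kinematics(arm, training_posture())$position
  n_mov <- nrow(movements)
  withr::with_seed(seed, {
    channel_rows <- function(reps) {
      ids <- sample(rep(movements$movement_id, reps))
      dplyr::left_join(tibble::tibble(movement_id = ids),
                       movements[, c("movement_id", "config", "orientation",
                                     "start_x", "start_y", "target_x",
                                     "target_y")],
                       by = "movement_id")
    }
    stage_tbl <- function(stage, n_walk, walk_type, n_channel_reps) {
      walk <- random_walk_targets(n_walk, center)
      walk$type <- walk_type
      if (n_channel_reps == 0) {
        walk$movement_id <- NA_integer_
        walk$config <- NA_integer_; walk$orientation <- NA_real_
        out <- walk
      } else {
        ch <- channel_rows(n_channel_reps)
        n_ch <- nrow(ch)
        n_tot <- n_walk + n_ch
        slots <- interleave_followed(n_tot, n_ch)
        out <- tibble::tibble(
          type = rep(walk_type, n_tot), movement_id = NA_integer_,
          direction = NA_real_, start_x = NA_real_, start_y = NA_real_,
          target_x = NA_real_, target_y = NA_real_,
          config = NA_integer_, orientation = NA_real_
        )
        out$type[slots$marked] <- "channel"
        out[slots$marked, c("movement_id", "config", "orientation",
                            "start_x", "start_y", "target_x", "target_y")] <-
          ch[, c("movement_id", "config", "orientation",
                 "start_x", "start_y", "target_x", "target_y")]
        walk_idx <- which(out$type == walk_type)
        out[walk_idx, c("direction", "start_x", "start_y",
                        "target_x", "target_y")] <-
          walk[, c("direction", "start_x", "start_y", "target_x", "target_y")]
        out
      }
      out$stage <- stage
      out
    }
    pre <- stage_tbl("preexposure", counts$pre_null, "null",
                     counts$pre_channel)
    expo <- stage_tbl("exposure", counts$exposure, "field", 0)
    gen <- stage_tbl("generalization", counts$gen_field, "field",
                     counts$gen_channel)
    out <- dplyr::bind_rows(pre, expo, gen)
    out$trial_id <- seq_len(nrow(out))
    dplyr::select(out, "trial_id", "stage", "type", "movement_id",
                  "direction", "start_x", "start_y", "target_x", "target_y",
                  "config", "orientation")
  })
}

#' Trial schedule for the workspace-transfer experiment
#'
#' Generates the schedule of the two-workspace experiment and its variants:
#' two 250-trial null-field baseline blocks (training then testing workspace,
#' 48 random no-vision trials each), two adaptation blocks of 500 field
#' trials in the training workspace (three blocks for variant `"2C"`) with 96
#' random no-vision trials per block of which half are null-field catch
#' trials, and an 80-trial generalization stage in the testing workspace made
#' of randomized center-out pairs (10 reaches per direction, all without
#' vision) with fields assigned by subgroup: `"mixed"` draws extrinsic (27),
#' intrinsic (27) and null (26) trials, `"dual"` splits extrinsic/intrinsic
#' 40/40. Variant `"2B"` is the same schedule with arm vision blocked.
#'
#' @param variant `"2"`, `"2B"` or `"2C"`.
#' @param group Training field: `"extrinsic"` or `"intrinsic"`.
#' @param subgroup Generalization field assignment: `"mixed"` or `"dual"`.
#' @param arm Two-joint arm (hand folded into the forearm; default lengths
#'   0.30 and 0.25 + 0.07 m).
#' @param train_center,test_center Workspace centers relative to the
#'   shoulder, m. Defaults place the training workspace center 15 cm right
#'   and 40 cm ahead of the shoulder; the testing workspace is reached by
#'   translating the shoulder 30 cm to the left.
#' @param seed Integer seed.
#' @return A tibble with one row per trial: `trial_id`, `stage`, `block`,
#'   `workspace`, `type` (`"null"`, `"field"`, `"catch"`), `field_kind`,
#'   `vision`, `arm_visible`, `direction`, `start_x/y`, `target_x/y`.
#' @export
make_schedule_exp2 <- function(variant = c("2", "2B", "2C"),
                               group = c("extrinsic", "intrinsic"),
                               subgroup = c("dual", "mixed"),
                               arm = arm_model(),
                               train_center = c(0.15, 0.40),
                               test_center = c(0.45, 0.40),
                               seed = 1) {
  variant <- match.arg(variant)
  group <- match.arg(group)
  subgroup <- match.arg(subgroup)
  n_adapt_blocks <- if (variant == "2C") 3L else 2L
  arm_visible <- variant != "2B"
  withr::with_seed(seed, {
    baseline_block <- function(block, workspace, center) {
      walk <- random_walk_targets(250, center)
      walk$vision <- TRUE
      walk$vision[sample(250, 48)] <- FALSE
      walk$stage <- "baseline"; walk$block <- block
      walk$workspace <- workspace
      walk$type <- "null"; walk$field_kind <- "null"
      walk
    }
    adapt_block <- function(block) {
      walk <- random_walk_targets(500, train_center)
      walk$vision <- TRUE
      no_vis <- sample(500, 96)
      walk$vision[no_vis] <- FALSE
      catch <- sample(no_vis, 48)
      walk$type <- "field"; walk$field_kind <- group
      walk$type[catch] <- "catch"; walk$field_kind[catch] <- "null"
      walk$stage <- "adaptation"; walk$block <- block
      walk$workspace <- "training"
      walk
    }
    gen_block <- function(block) {
      # 40 center-out pairs: 5 outward reaches per direction, each followed
      # by the return reach, in random pair order
      dirs <- sample(rep(seq(0, 315, by = 45), 5))
      reach <- 0.10
      rows <- purrr::map_dfr(dirs, function(d) {
        v <- reach * c(-sin(d * pi / 180), cos(d * pi / 180))
        tibble::tibble(
          direction = c(d, (d + 180) %% 360),
          start_x = c(test_center[1], test_center[1] + v[1]),
          start_y = c(test_center[2], test_center[2] + v[2]),
          target_x = c(test_center[1] + v[1], test_center[1]),
          target_y = c(test_center[2] + v[2], test_center[2])
        )
      })
      fields <- if (subgroup == "mixed") {
        sample(rep(c("extrinsic", "intrinsic", "null"), c(27, 27, 26)))
      } else {
        sample(rep(c("extrinsic", "intrinsic"), c(40, 40)))
      }
      rows$field_kind <- fields
      rows$type <- ifelse(fields == "null", "null", "field")
      rows$vision <- FALSE
      rows$stage <- "generalization"; rows$block <- block
      rows$workspace <- "testing"
      rows
    }
    out <- dplyr::bind_rows(
      baseline_block(1L, "training", train_center),
      baseline_block(2L, "testing", test_center),
      purrr::map_dfr(seq_len(n_adapt_blocks), function(b) adapt_block(2L + b)),
      gen_block(3L + n_adapt_blocks)
    )
    out$trial_id <- seq_len(nrow(out))
    out$arm_visible <- arm_visible
    dplyr::select(out, "trial_id", "stage", "block", "workspace", "type",
                  "field_kind", "vision", "arm_visible", "direction",
                  "start_x", "start_y", "target_x", "target_y")
  })
}

#' Simulate one reach under a force field
#'
#' Point-arm simulation of a planned reach: the hand (an effective point mass)
#' follows a minimum-jerk plan under the external field, a learned
#' feedforward compensation equal to `compensation` times the ideal opposing
#' force for the *learned* field along the plan, and a spring-damper feedback
#' controller tracking the plan. On a catch trial pass a null `field` while
#' keeping `learned_field` at the training field: the feedforward then drives
#' the mirror-image aftereffect. The controller is plan-tracking scaffolding,
#' not a biomechanical model.
#'
#' @param plan Minimum-jerk plan from [min_jerk_trajectory()].
#' @param field External [viscous_field()] applied by the robot.
#' @param learned_field Field the simulated subject has adapted to (defaults
#'   to `field`).
#' @param compensation Learned compensation fraction in \[0, 1\].
#' @param channel Optional [channel_model()]; when present its wall force is
#'   applied (channel trial).
#' @param kp,kd Feedback gains, N/m and N s/m.
#' @param mass Effective hand mass, kg.
#' @param noise_sd White motor-noise force, N (0 disables).
#' @param seed Seed used when `noise_sd > 0`.
#' @return A tibble `t`, `x`, `y`, `vx`, `vy`, `fx`, `fy` (external field +
#'   channel force actually applied).
#' @export
simulate_reach <- function(plan, field, learned_field = field,
                           compensation = 0, channel = NULL,
                           kp = 2000, kd = 40, mass = 2, noise_sd = 0,
                           seed = 1) {
  n <- nrow(plan)
  dt <- plan$t[2] - plan$t[1]
  noise <- if (noise_sd > 0) {
    withr::with_seed(seed, matrix(stats::rnorm(2 * n, sd = noise_sd), 2))
  } else matrix(0, 2, n)
  pos <- c(plan$x[1], plan$y[1])
  vel <- c(0, 0)
  X <- matrix(NA_real_, n, 6)
  for (i in seq_len(n)) {
    p_plan <- c(plan$x[i], plan$y[i])
    v_plan <- c(plan$vx[i], plan$vy[i])
    f_ext <- field_force(field, pos, vel)
    if (!is.null(channel)) f_ext <- f_ext + channel_force(channel, pos, vel)
    f_ff <- -compensation * field_force(learned_field, p_plan, v_plan)
    f_fb <- kp * (p_plan - pos) + kd * (v_plan - vel)
    acc <- (f_ext + f_ff + f_fb + noise[, i]) / mass
    if (!all(is.finite(acc)) || sum(acc^2) > 1e12) {
      stop(sprintf("reach simulation unstable (kp=%g, kd=%g, mass=%g)",
                   kp, kd, mass), call. = FALSE)
    }
    vel <- vel + acc * dt
    pos <- pos + vel * dt
    X[i, ] <- c(pos, vel, f_ext)
  }
  tibble::tibble(t = plan$t, x = X[, 1], y = X[, 2], vx = X[, 3], vy = X[, 4],
                 fx = X[, 5], fy = X[, 6])
}

#' Simulate a full synthetic cohort
#'
#' Composes the generators into a complete synthetic study for the
#' posture-generalization experiment: one trial schedule per subject, a
#' trial-by-trial learning curve, simulated exposure reaches (thinned by
#' `stride` to keep the volume manageable) including catch-style null
#' aftereffect probes, and a channel-trial generalization dataset drawn from
#' the ground-truth model.
#'
#' @param truth A [ground_truth_model()].
#' @param n_subjects Number of subjects.
#' @param arm An [arm_model()].
#' @param design Design tibble (see [generalization_design()]).
#' @param seed Integer seed.
#' @param stride Simulate every `stride`-th exposure movement of subject 1
#'   (trajectory output only; the learning curve covers every trial).
#' @param noise_sd Motor noise passed to [simulate_reach()].
#' @param rate,asymptote Learning-rule parameters ([learning_curve()]).
#' @return A list with `schedule` (subject 1), `exposure` (simulated reach
#'   metrics: `trial_id`, `compensation`, `mpe`, `signed_mpe`, `catch`),
#'   `trajectories` (long tibble of the simulated reaches), `dataset`
#'   (channel-trial generalization data for all subjects) and `truth`.
#' @export
simulate_cohort <- function(truth = ground_truth_model(),
                            n_subjects = 9, arm = arm_model(),
                            design = default_design(), seed = 1,
                            stride = 25, noise_sd = 0.2,
                            rate = 0.01, asymptote = 0.8) {
  schedule <- make_schedule_exp1(arm, seed = seed)
  field <- viscous_field("extrinsic")
  null_field <- viscous_field("null")
  expo <- schedule[schedule$stage == "exposure", ]
  lambda <- learning_curve(nrow(expo), rate, asymptote)
  sim_idx <- seq(1, nrow(expo), by = stride)
  sims <- purrr::map(seq_along(sim_idx), function(j) {
    i <- sim_idx[j]
    start <- c(expo$start_x[i], expo$start_y[i])
    target <- c(expo$target_x[i], expo$target_y[i])
    plan <- min_jerk_trajectory(start, target,
                                duration = 0.4, dt = 0.002, pad = 0.1)
    one <- function(catch, tag) {
      tr <- simulate_reach(plan,
                           field = if (catch) null_field else field,
                           learned_field = field,
                           compensation = lambda[i], noise_sd = noise_sd,
                           seed = seed * 1000L + 2L * i + catch)
      list(
        metrics = tibble::tibble(
          trial_id = expo$trial_id[i], direction = expo$direction[i],
          compensation = lambda[i], catch = catch,
          mpe = mpe(tr, start, target),
          signed_mpe = mpe(tr, start, target, signed = TRUE)
        ),
        # catch twins carry the negated id so trajectory rows stay per-trial
        trajectory = dplyr::mutate(tr,
                                   trial_id = (1L - 2L * catch) * expo$trial_id[i],
                                   catch = catch, .before = 1)
      )
    }
    out <- list(one(FALSE))
    # every 5th probe gets a matched null-field catch twin (same start and
    # plan), exposing the mirror-image aftereffect pairwise
    if (j %% 5 == 0) out <- c(out, list(one(TRUE)))
    out
  })
  sims <- purrr::flatten(sims)
  dataset <- simulate_channel_dataset(truth, n_subjects, design,
                                      seed = seed + 1)
  list(
    schedule = schedule,
    exposure = purrr::map_dfr(sims, "metrics"),
    trajectories = purrr::map_dfr(sims, "trajectory"),
    dataset = dataset,
    truth = truth
  )
}
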