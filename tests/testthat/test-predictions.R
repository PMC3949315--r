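test_that("the test-movement grid has the published structure", {
  mv <- test_movements()
  expect_equal(nrow(mv), 15)
  expect_equal(unique(mv$config), 1:3)
  expect_equal(sort(unique(mv$orientation)),
               c(-45, -33.75, -22.5, -11.25, 0))
  # all deviations vanish at the training movement
  tr <- mv[mv$config == 1 & mv$orientation == 0, ]
  expect_equal(unlist(tr[c("dtheta_s", "dtheta_e", "dtheta_w",
                           "dx", "dy", "dtheta_hand")]),
               c(dtheta_s = 0, dtheta_e = 0, dtheta_w = 0,
                 dx = 0, dy = 0, dtheta_hand = 0))
  # within a configuration the wrist position is shared by all orientations:
  # the start positions all sit on the circle of hand-segment radius around it
  arm <- arm_model()
  for (cfg in 1:3) {
    sub <- mv[mv$config == cfg, ]
    wrist <- t(vapply(seq_len(nrow(sub)), function(i) {
      c(sub$start_x[i], sub$start_y[i]) -
        0.07 * c(cos(sub$hand_orientation[i]), sin(sub$hand_orientation[i]))
    }, numeric(2)))
    expect_lt(max(dist(wrist)), 1e-12)
    # single movement direction per configuration
    expect_equal(length(unique(round(sub$dir_x, 12))), 1)
  }
  # configurations 2 and 3 share their movement direction
  expect_equal(mv$dir_x[mv$config == 2][1], mv$dir_x[mv$config == 3][1])
})

test_that("Cartesian predictions ignore posture and match the field pointwise", {
  arm <- arm_model()
  mv <- test_movements(arm)
  B <- training_field_matrix()
  # identical across the 5 orientations of a configuration
  sub <- mv[mv$config == 2, ]
  series <- lapply(seq_len(nrow(sub)), function(i) {
    predict_forces(arm, sub[i, ], "cartesian")$f_perp
  })
  for (i in 2:5) expect_equal(series[[i]], series[[1]], tolerance = 1e-12)
  # configurations 2 and 3 move in the same direction: identical predictions
  s3 <- predict_forces(arm, mv[mv$config == 3 & mv$orientation == 0, ],
                       "cartesian")
  expect_equal(s3$f_perp, series[[1]], tolerance = 1e-12)
  # trace equals the extrinsic field applied to the plan velocity
  m1 <- mv[1, ]
  fs <- predict_forces(arm, m1, "cartesian")
  plan <- min_jerk_trajectory(c(m1$start_x, m1$start_y),
                              c(m1$target_x, m1$target_y), 0.4, 0.001, 0.2)
  expect_equal(cbind(fs$fx, fs$fy), t(B %*% rbind(plan$vx, plan$vy)),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("object-centered predictions conjugate the field by the hand rotation", {
  B <- training_field_matrix()
  arm <- arm_model()
  mv <- test_movements(arm)
  # zero rotation: identical to Cartesian
  m1 <- mv[1, ]
  expect_equal(predict_forces(arm, m1, "object")$f_perp,
               predict_forces(arm, m1, "cartesian")$f_perp, tolerance = 1e-12)
  # 90-degree rotation of the printed matrix
  R <- matrix(c(0, 1, -1, 0), 2)
  expect_equal(R %*% B %*% t(R),
               matrix(c(11.1, 11.2, 11.2, -10.1), 2, byrow = TRUE),
               tolerance = 1e-12)
  # conjugation preserves eigenvalues for any rotation
  withr::with_seed(13, {
    for (rep in 1:10) {
      th <- stats::runif(1, -pi, pi)
      R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
      expect_equal(sort(eigen(R %*% B %*% t(R))$values),
                   sort(eigen(B)$values), tolerance = 1e-10)
    }
  })
})

test_that("the joint-based prediction collapses to the field at the training posture", {
  arm <- arm_model()
  tp <- training_posture()
  B <- training_field_matrix()
  # exact algebraic collapse where the test Jacobian equals the training one
  J <- arm_jacobian(arm, tp, "three_joint")
  W <- t(J) %*% B %*% J
  withr::with_seed(15, {
    for (rep in 1:10) {
      xdot <- stats::rnorm(2, sd = 0.3)
      qdot <- constrained_joint_velocities(arm, tp, xdot)
      F_pred <- solve(J %*% t(J)) %*% J %*% (W %*% qdot)
      expect_equal(as.numeric(F_pred), as.numeric(B %*% xdot),
                   tolerance = 1e-9)
    }
  })
  # along the training movement the posture drifts, so the series agree
  # closely near onset and only approximately later
  mv <- test_movements(arm)
  m1 <- mv[mv$config == 1 & mv$orientation == 0, ]
  ref <- predict_forces(arm, m1, "cartesian")$f_perp
  for (model in c("joint", "virtual_segment")) {
    got <- predict_forces(arm, m1, model)$f_perp
    expect_equal(got[1:20], ref[1:20], tolerance = 1e-3)
    expect_gt(stats::cor(got, ref), 0.95)
  }
})

test_that("the three-joint prediction equals a separate torque-then-force pipeline", {
  arm <- arm_model()
  tp <- training_posture()
  mv <- test_movements(arm)
  m <- mv[mv$config == 2 & mv$orientation == -22.5, ]
  fs <- predict_forces(arm, m, "joint")
  B <- training_field_matrix()
  J_train <- arm_jacobian(arm, tp, "three_joint")
  W <- t(J_train) %*% B %*% J_train
  plan <- min_jerk_trajectory(c(m$start_x, m$start_y),
                              c(m$target_x, m$target_y), 0.4, 0.001, 0.2)
  withr::with_seed(14, idx <- sample(nrow(plan), 12))
  for (i in idx) {
    # reconstruct the posture independently: wrist placed behind the hand
    # along the (constant) hand orientation, then two-link inverse kinematics
    h <- m$hand_orientation
    wrist <- c(plan$x[i], plan$y[i]) - 0.07 * c(cos(h), sin(h))
    r2 <- sum(wrist^2)
    qe <- acos((r2 - 0.30^2 - 0.25^2) / (2 * 0.30 * 0.25))
    qs <- atan2(wrist[2], wrist[1]) -
      atan2(0.25 * sin(qe), 0.30 + 0.25 * cos(qe))
    q <- c(qs, qe, h - qs - qe)
    J <- arm_jacobian(arm, joint_posture(q[1], q[2], q[3]), "three_joint")
    qdot <- solve(rbind(J, c(1, 1, 1)), c(plan$vx[i], plan$vy[i], 0))
    tau <- W %*% qdot
    F_oracle <- as.numeric(solve(J %*% t(J)) %*% J %*% tau)
    expect_equal(c(fs$fx[i], fs$fy[i]), F_oracle, tolerance = 1e-9)
  }
})

test_that("virtual-segment and three-joint models make very similar predictions", {
  arm <- arm_model()
  pg <- predict_generalization(arm, models = c("joint", "virtual_segment"))
  w <- tidyr::pivot_wider(pg[, c("movement_id", "model", "adaptation")],
                          names_from = "model", values_from = "adaptation")
  expect_gt(stats::cor(w$joint, w$virtual_segment), 0.97)
  expect_lt(max(abs(w$joint - w$virtual_segment)), 0.35)
})

test_that("virtual-segment conjugation matches a stepwise chain product", {
  arm <- arm_model()
  tp <- training_posture()
  B <- training_field_matrix()
  mv <- test_movements(arm)
  m <- mv[mv$config == 2 & mv$orientation == 0, ]
  fs <- predict_forces(arm, m, "virtual_segment")
  plan <- min_jerk_trajectory(c(m$start_x, m$start_y),
                              c(m$target_x, m$target_y), 0.4, 0.001, 0.2)
  i <- 200
  h <- m$hand_orientation
  wrist <- c(plan$x[i], plan$y[i]) - 0.07 * c(cos(h), sin(h))
  r2 <- sum(wrist^2)
  qe <- acos((r2 - 0.30^2 - 0.25^2) / (2 * 0.30 * 0.25))
  qs <- atan2(wrist[2], wrist[1]) -
    atan2(0.25 * sin(qe), 0.30 + 0.25 * cos(qe))
  q <- joint_posture(qs, qe, h - qs - qe)
  Jtr <- arm_jacobian(arm, tp, "virtual_segment")
  Jte <- arm_jacobian(arm, q, "virtual_segment")
  B_gen <- solve(t(Jte)) %*% t(Jtr) %*% B %*% Jtr %*% solve(Jte)
  expect_equal(c(fs$fx[i], fs$fy[i]),
               as.numeric(B_gen %*% c(plan$vx[i], plan$vy[i])),
               tolerance = 1e-9)
  # at the training movement the conjugation returns B itself
  m1 <- mv[1, ]
  Jte1 <- arm_jacobian(arm, tp, "virtual_segment")
  expect_equal(solve(t(Jte1)) %*% t(Jtr) %*% B %*% Jtr %*% solve(Jte1), B,
               tolerance = 1e-10)
})

test_that("the windowed perpendicular-force summary averages and normalizes correctly", {
  t <- seq(0, 0.6, by = 1e-3)
  # constant speed: onset at the first sample; linear force ramp
  forces <- tibble::tibble(t = t, f_perp = 2 * t, speed = 0.01)
  # trapezoid average of 2t over [0.05, 0.45] is 2 * 0.25
  expect_equal(perp_force_summary(forces), 0.5, tolerance = 1e-12)
  # baseline subtraction and normalization
  expect_equal(perp_force_summary(forces, baseline = 0.1,
                                  training_magnitude = 2), 0.2,
               tolerance = 1e-12)
  # zero force
  expect_equal(perp_force_summary(tibble::tibble(t = t, f_perp = 0,
                                                 speed = 0.01)), 0)
  # short series errors
  expect_error(perp_force_summary(tibble::tibble(t = t[t < 0.3], f_perp = 1,
                                                 speed = 0.01)), "ms")
  # no onset errors
  expect_error(perp_force_summary(tibble::tibble(t = t, f_perp = 1,
                                                 speed = 0)), "onset")
})

test_that("normalized generalization predictions honor the training contract", {
  pg <- predict_generalization(models = c("joint", "cartesian", "object"))
  tr <- pg[pg$config == 1 & pg$orientation == 0, ]
  expect_equal(tr$adaptation, rep(1, 3))
  # raw training magnitudes share sign and order of magnitude across models
  # (they differ somewhat because the posture drifts along the movement)
  expect_true(all(tr$raw > 0))
  expect_lt(diff(range(tr$raw)) / max(tr$raw), 0.5)
  # Cartesian adaptation is constant within a configuration
  cc <- pg[pg$model == "cartesian", ]
  for (cfg in 1:3) {
    expect_lt(diff(range(cc$adaptation[cc$config == cfg])), 1e-9)
  }
  # object-based adaptation depends only on the total hand rotation: config 2
  # and 3 share hand orientations, so their object predictions match
  oo <- pg[pg$model == "object", ]
  expect_equal(oo$adaptation[oo$config == 2], oo$adaptation[oo$config == 3],
               tolerance = 1e-9)
})

test_that("the design table carries predictions and squared distances", {
  d <- cached_design()
  expect_equal(names(d),
               c("movement_id", "config", "orientation", "J", "C", "O",
                 "dist_joint2", "dist_cart2", "dist_hand2"))
  tr <- d[d$config == 1 & d$orientation == 0, ]
  expect_equal(unlist(tr[c("J", "C", "O")]), c(J = 1, C = 1, O = 1))
  expect_equal(unlist(tr[c("dist_joint2", "dist_cart2", "dist_hand2")]),
               c(dist_joint2 = 0, dist_cart2 = 0, dist_hand2 = 0))
  # joint distance for config 1 is the squared wrist offset alone
  c1 <- d[d$config == 1, ]
  expect_equal(c1$dist_joint2, (c1$orientation * pi / 180)^2,
               tolerance = 1e-12)
})
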