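#' Planar arm model
#'
#' Describes a planar three-segment arm (upper arm, forearm, hand) moving in
#' the horizontal plane. All angles in this package are *relative* joint
#' angles: each segment's orientation is measured from the previous segment,
#' with the upper arm measured from the workspace +x axis. The hand
#' orientation in external space is therefore the sum of the three joint
#' angles.
#'
#' @param upper,lower,hand Segment lengths in meters. Defaults are the
#'   average adult arm used throughout: 0.30, 0.25 and 0.07 m.
#' @param shoulder Shoulder position in the workspace frame, meters.
#' @return An object of class `arm_model`.
#' @examples
#' arm <- arm_model()
#' forward_kinematics(arm, joint_posture(35, 75, 12.3, degrees = TRUE))
#' @export
arm_model <- function(upper = 0.30, lower = 0.25, hand = 0.07,
                      shoulder = c(0, 0)) {
  lengths <- c(upper = upper, lower = lower, hand = hand)
  if (!all(is.finite(lengths)) || any(lengths <= 0)) {
    stop("all link lengths must be finite and > 0", call. = FALSE)
  }
  if (length(shoulder) != 2 || !all(is.finite(shoulder))) {
    stop("`shoulder` must be a finite 2-vector", call. = FALSE)
  }
  structure(
    list(lengths = lengths, shoulder = as.numeric(shoulder)),
    class = "arm_model"
  )
}

#' @export
print.arm_model <- function(x, ...) {
  cat("<arm_model> links (m):",
      paste(sprintf("%s=%.3f", names(x$lengths), x$lengths), collapse = ", "),
      sprintf("; shoulder at (%.3f, %.3f)\n", x$shoulder[1], x$shoulder[2]))
  invisible(x)
}

#' Joint posture of the planar arm
#'
#' @param shoulder,elbow,wrist Relative joint angles (shoulder from the
#'   workspace +x axis, elbow from the upper arm, wrist from the forearm).
#'   Radians unless `degrees = TRUE`.
#' @param degrees If `TRUE`, angles are given in degrees and converted.
#' @return An object of class `joint_posture` (named numeric 3-vector of
#'   radians) with a `hand_orientation` attribute equal to the angle sum.
#' @export
joint_posture <- function(shoulder, elbow, wrist = 0, degrees = FALSE) {
  q <- c(shoulder = shoulder, elbow = elbow, wrist = wrist)
  if (!all(is.finite(q))) stop("joint angles must be finite", call. = FALSE)
  if (degrees) q <- q * pi / 180
  structure(q, hand_orientation = sum(q), class = "joint_posture")
}

#' @export
print.joint_posture <- function(x, ...) {
  cat(sprintf("<joint_posture> q = (%.2f, %.2f, %.2f) deg; hand orientation %.2f deg\n",
              x[1] * 180 / pi, x[2] * 180 / pi, x[3] * 180 / pi,
              attr(x, "hand_orientation") * 180 / pi))
  invisible(x)
}

#' The training posture used in the generalization experiment
#'
#' Shoulder 35 deg, elbow 75 deg; the wrist default of 12.3 deg is the group
#' mean wrist angle (it was set per subject in the experiment).
#'
#' @param wrist_deg Wrist angle in degrees.
#' @return A [joint_posture()].
#' @export
training_posture <- function(wrist_deg = 12.3) {
  joint_posture(35, 75, wrist_deg, degrees = TRUE)
}

as_posture <- function(q) {
  if (inherits(q, "joint_posture")) return(q)
  if (length(q) == 2) q <- c(q, 0)
  joint_posture(q[1], q[2], q[3])
}

cumulative_angles <- function(q) cumsum(as.numeric(q))

#' Forward kinematics of the planar arm
#'
#' @param arm An [arm_model()].
#' @param posture A [joint_posture()] (or a numeric 2- or 3-vector of radians).
#' @return A list with `position` (hand position, 2-vector in meters),
#'   `orientation` (hand orientation in external space, radians), `wrist`
#'   (wrist position) and `elbow` (elbow position).
#' @export
forward_kinematics <- function(arm, posture) {
  q <- as_posture(posture)
  a <- cumulative_angles(q)
  l <- arm$lengths
  elbow <- arm$shoulder + l[1] * c(cos(a[1]), sin(a[1]))
  wrist <- elbow + l[2] * c(cos(a[2]), sin(a[2]))
  hand <- wrist + l[3] * c(cos(a[3]), sin(a[3]))
  list(position = unname(hand), orientation = unname(a[3]),
       wrist = unname(wrist), elbow = unname(elbow))
}

# length and elbow-relative angle of the straight segment from elbow to hand
virtual_segment <- function(arm, q_wrist) {
  q_wrist <- unname(q_wrist)
  l2 <- arm$lengths[[2]]
  l3 <- arm$lengths[[3]]
  len <- sqrt(l2^2 + l3^2 + 2 * l2 * l3 * cos(q_wrist))
  ang <- atan2(l3 * sin(q_wrist), l2 + l3 * cos(q_wrist))
  c(length = len, angle = ang)
}

#' Arm Jacobian
#'
#' Analytic Jacobian mapping joint angular velocities (rad/s) to hand velocity
#' (m/s) at a posture. Three variants are supported:
#'
#' * `"three_joint"`: the 2 x 3 Jacobian in (shoulder, elbow, wrist).
#' * `"two_joint"`: a 2 x 2 Jacobian treating the forearm and hand as one
#'   straight segment of length `lower + hand` regardless of the wrist angle
#'   (the wrist treated as a fixed, extended joint).
#' * `"virtual_segment"`: a 2 x 2 Jacobian on the actual elbow-to-hand chord,
#'   whose length and orientation follow the current wrist angle.
#'
#' A warning is issued when the 2 x 2 shoulder/elbow sub-Jacobian is singular
#' (straight or folded arm) to double-precision tolerance.
#'
#' @inheritParams forward_kinematics
#' @param variant One of `"three_joint"`, `"two_joint"`, `"virtual_segment"`.
#' @return A 2 x 2 or 2 x 3 numeric matrix.
#' @export
arm_jacobian <- function(arm, posture,
                         variant = c("three_joint", "two_joint",
                                     "virtual_segment")) {
  variant <- match.arg(variant)
  q <- as_posture(posture)
  l <- arm$lengths
  J <- switch(variant,
    three_joint = {
      a <- cumulative_angles(q)
      # column j: sum over segments at or distal to joint j
      s <- l * sin(a); c_ <- l * cos(a)
      rbind(-rev(cumsum(rev(s))), rev(cumsum(rev(c_))))
    },
    two_joint = {
      planar_jacobian_2(c(l[[1]], l[[2]] + l[[3]]), c(q[1], q[2]))
    },
    virtual_segment = {
      vs <- virtual_segment(arm, q[3])
      # second joint angle measured to the chord
      planar_jacobian_2(c(l[[1]], vs[["length"]]),
                        c(q[1], q[2] + vs[["angle"]]))
    }
  )
  J2 <- if (ncol(J) == 2) J else J[, 1:2]
  if (abs(det(J2)) < 1e-9) {
    warning("posture is (near-)singular: |det| of the shoulder/elbow sub-Jacobian < 1e-9",
            call. = FALSE)
  }
  unname(J)
}

planar_jacobian_2 <- function(lengths, angles) {
  a <- cumsum(angles)
  s <- lengths * sin(a); c_ <- lengths * cos(a)
  rbind(-rev(cumsum(rev(s))), rev(cumsum(rev(c_))))
}

#' Joint velocities for a hand velocity under constant hand orientation
#'
#' The channel test movements require a constant hand orientation, so the
#' three joint angular velocities must sum to zero while the hand tracks the
#' commanded Cartesian velocity. This solves the 3 x 3 linear system stacking
#' the three-joint Jacobian on the orientation constraint row (1, 1, 1).
#'
#' @inheritParams forward_kinematics
#' @param xdot Hand velocity, 2-vector in m/s.
#' @return Joint angular velocities, 3-vector in rad/s, satisfying
#'   `J %*% qdot = xdot` and `sum(qdot) = 0`.
#' @export
constrained_joint_velocities <- function(arm, posture, xdot) {
  J <- arm_jacobian(arm, posture, "three_joint")
  A <- rbind(J, c(1, 1, 1))
  qdot <- tryCatch(solve(A, c(xdot, 0)), error = function(e) {
    q <- as_posture(posture)
    stop(sprintf(
      "constant-orientation velocity system is singular at posture (%.3f, %.3f, %.3f) rad",
      q[1], q[2], q[3]), call. = FALSE)
  })
  unname(qdot)
}

#' Two-joint inverse kinematics
#'
#' Elbow-positive (flexed, `elbow` in [0, pi]) solution for a planar two-link
#' arm. When `fold_hand = TRUE` the hand segment is folded straight into the
#' forearm, giving an effective lower link of `lower + hand` (the geometry
#' used when only shoulder and elbow are tracked).
#'
#' @inheritParams forward_kinematics
#' @param position Target hand position, 2-vector in meters (workspace frame).
#' @param fold_hand Fold the hand segment into the forearm (default `TRUE`).
#' @return A [joint_posture()] with zero wrist angle.
#' @export
inverse_kinematics_2joint <- function(arm, position, fold_hand = TRUE) {
  l1 <- arm$lengths[[1]]
  l2 <- arm$lengths[[2]] + if (fold_hand) arm$lengths[[3]] else 0
  p <- as.numeric(position) - arm$shoulder
  r <- sqrt(sum(p^2))
  if (r > l1 + l2 || r < abs(l1 - l2)) {
    deficit <- max(r - (l1 + l2), abs(l1 - l2) - r)
    stop(sprintf("target unreachable: outside the [%.3f, %.3f] m annulus by %.4f m",
                 abs(l1 - l2), l1 + l2, deficit), call. = FALSE)
  }
  ce <- (r^2 - l1^2 - l2^2) / (2 * l1 * l2)
  ce <- min(1, max(-1, ce))
  q_e <- acos(ce)
  q_s <- atan2(p[2], p[1]) - atan2(l2 * sin(q_e), l1 + l2 * cos(q_e))
  joint_posture(q_s, q_e, 0)
}

# inverse kinematics of the full 3-joint arm under a prescribed hand
# orientation: place the wrist, solve the 2-link problem, set the wrist angle
posture_from_hand <- function(arm, position, hand_orientation) {
  l3 <- arm$lengths[[3]]
  wrist_target <- as.numeric(position) -
    l3 * c(cos(hand_orientation), sin(hand_orientation))
  arm2 <- arm_model(arm$lengths[[1]], arm$lengths[[2]], arm$lengths[[3]],
                    arm$shoulder)
  q2 <- inverse_kinematics_2joint(arm2, wrist_target, fold_hand = FALSE)
  joint_posture(q2[1], q2[2], hand_orientation - q2[1] - q2[2])
}

#' Minimum-jerk point-to-point trajectory
#'
#' Fifth-order polynomial profile with zero velocity and acceleration at both
#' endpoints — the standard model for smooth point-to-point reaches, and the
#' profile used for the passive inter-trial transport in the experiments.
#'
#' @param start,end 2-vectors, meters.
#' @param duration Movement time in seconds.
#' @param dt Sample interval in seconds.
#' @param pad Additional rest time appended after the movement, seconds
#'   (position held at the endpoint with zero velocity).
#' @return A tibble with columns `t`, `x`, `y`, `vx`, `vy`, `ax`, `ay`.
#' @examples
#' plan <- min_jerk_trajectory(c(0, 0), c(0.1, 0), duration = 0.4)
#' max(sqrt(plan$vx^2 + plan$vy^2)) # 15 D / (8 T)
#' @export
min_jerk_trajectory <- function(start, end, duration = 0.4, dt = 0.001,
                                pad = 0) {
  if (duration <= 0) stop("`duration` must be > 0", call. = FALSE)
  if (dt <= 0 || dt >= duration) stop("`dt` must be in (0, duration)", call. = FALSE)
  t <- seq(0, duration + pad, by = dt)
  tau <- pmin(t / duration, 1)
  s <- 10 * tau^3 - 15 * tau^4 + 6 * tau^5
  sdot <- (30 * tau^2 - 60 * tau^3 + 30 * tau^4) / duration
  sddot <- (60 * tau - 180 * tau^2 + 120 * tau^3) / duration^2
  sdot[t > duration] <- 0
  sddot[t > duration] <- 0
  d <- as.numeric(end) - as.numeric(start)
  tibble::tibble(
    t = t,
    x = start[1] + s * d[1], y = start[2] + s * d[2],
    vx = sdot * d[1], vy = sdot * d[2],
    ax = sddot * d[1], ay = sddot * d[2]
  )
}
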