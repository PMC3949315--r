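#' The skew viscous field matrix
#'
#' The velocity-dependent field used in both experiments maps hand velocity to
#' hand force, `F = B v`. Unlike a curl field this matrix has unique axes
#' (one stable, one unstable), so different movement directions experience
#' different forces.
#'
#' @return The 2 x 2 matrix `B` in N s/m.
#' @export
training_field_matrix <- function() {
  matrix(c(-10.1, -11.2, -11.2, 11.1), nrow = 2, byrow = TRUE)
}

#' Viscous force-field specification
#'
#' @param kind `"extrinsic"` (forces defined in hand space, `F = B v`),
#'   `"intrinsic"` (torques defined in joint space, `tau = W qdot`, rendered
#'   at the hand), or `"null"` (zero forces).
#' @param B 2 x 2 Cartesian field matrix, N s/m.
#' @param arm [arm_model()]; required for intrinsic fields (two-joint context,
#'   hand folded into the forearm).
#' @param train_posture Posture at which the intrinsic field is defined; `W`
#'   is built from the Jacobian there so the two field kinds coincide at that
#'   posture.
#' @return A `viscous_field` object carrying `B`, `kind`, and for intrinsic
#'   fields the joint matrix `W` (N m s/rad) and the training posture.
#' @export
viscous_field <- function(kind = c("extrinsic", "intrinsic", "null"),
                          B = training_field_matrix(),
                          arm = NULL, train_posture = NULL) {
  kind <- match.arg(kind)
  if (!is.matrix(B) || !all(dim(B) == c(2, 2))) {
    stop("`B` must be a 2 x 2 matrix", call. = FALSE)
  }
  spec <- list(kind = kind, B = B)
  if (kind == "intrinsic") {
    if (is.null(arm) || is.null(train_posture)) {
      stop("intrinsic fields need `arm` and `train_posture`", call. = FALSE)
    }
    J <- arm_jacobian(arm, train_posture, "two_joint")
    spec$W <- joint_field_matrix(B, J)
    spec$train_posture <- as_posture(train_posture)
    spec$arm <- arm
  }
  structure(spec, class = "viscous_field")
}

#' Map a Cartesian field matrix into joint space
#'
#' `W = t(J) %*% B %*% J`: the joint-space analog of the Cartesian viscous
#' matrix, mapping joint angular velocities to joint torques through the
#' Jacobian at the training posture.
#'
#' @param B 2 x 2 Cartesian field matrix, N s/m.
#' @param J Jacobian at the training posture (2 x 2 or 2 x 3).
#' @return `W`, a square matrix matching `ncol(J)`, N m s/rad.
#' @export
joint_field_matrix <- function(B, J) {
  if (!is.matrix(B) || nrow(B) != 2 || ncol(B) != 2 || nrow(J) != 2) {
    stop("dimension mismatch: `B` must be 2 x 2 and `J` must have 2 rows",
         call. = FALSE)
  }
  t(J) %*% B %*% J
}

#' Hand force of the extrinsic (Cartesian) field
#'
#' @param field A [viscous_field()] of kind `"extrinsic"` or `"null"`.
#' @param xdot Hand velocity, 2-vector m/s.
#' @return Hand force, 2-vector N.
#' @export
extrinsic_force <- function(field, xdot) {
  if (field$kind == "null") return(c(0, 0))
  if (field$kind != "extrinsic") {
    stop("`extrinsic_force()` applies to extrinsic or null fields", call. = FALSE)
  }
  as.numeric(field$B %*% xdot)
}

#' Render the intrinsic (joint-defined) field at the hand
#'
#' The intrinsic field defines torques `tau = W qdot`; the equivalent hand
#' force at the current posture is `F = solve(t(J)) %*% W %*% qdot` with the
#' two-joint Jacobian re-evaluated at every sample. At the training posture
#' this collapses algebraically to the extrinsic field `B v`.
#'
#' @param field A [viscous_field()] of kind `"intrinsic"`.
#' @param posture Current posture (shoulder/elbow; wrist folded).
#' @param qdot Joint angular velocities, 2-vector rad/s. Alternatively supply
#'   `xdot` and the joint velocities are obtained through the Jacobian.
#' @param xdot Hand velocity, 2-vector m/s (used if `qdot` is missing).
#' @return Hand force, 2-vector N.
#' @export
intrinsic_force <- function(field, posture, qdot = NULL, xdot = NULL) {
  if (field$kind != "intrinsic") {
    stop("`intrinsic_force()` applies to intrinsic fields", call. = FALSE)
  }
  J <- arm_jacobian(field$arm, posture, "two_joint")
  if (abs(det(J)) < 1e-9) {
    q <- as_posture(posture)
    stop(sprintf("singular Jacobian at posture (%.3f, %.3f) rad", q[1], q[2]),
         call. = FALSE)
  }
  if (is.null(qdot)) {
    if (is.null(xdot)) stop("supply `qdot` or `xdot`", call. = FALSE)
    qdot <- solve(J, xdot)
  }
  as.numeric(solve(t(J), field$W %*% qdot))
}

#' Force of any field at a hand state
#'
#' Dispatcher used by the reach simulator: null and extrinsic fields depend
#' only on hand velocity; intrinsic fields also need the current posture,
#' recovered by two-joint inverse kinematics from the hand position.
#'
#' @param field A [viscous_field()].
#' @param position Hand position, 2-vector m (needed for intrinsic fields).
#' @param velocity Hand velocity, 2-vector m/s.
#' @return Hand force, 2-vector N.
#' @export
field_force <- function(field, position, velocity) {
  switch(field$kind,
    null = c(0, 0),
    extrinsic = as.numeric(field$B %*% velocity),
    intrinsic = {
      q <- inverse_kinematics_2joint(field$arm, position)
      intrinsic_force(field, q, xdot = velocity)
    }
  )
}

#' Mechanical force channel
#'
#' The channel constrains the hand to the straight start-target line with a
#' stiff one-dimensional spring-damper acting perpendicular to it; the wall
#' force measures the subject's predictive compensation.
#'
#' @param start,end Channel line endpoints, 2-vectors m.
#' @param stiffness Spring constant, N/m (default 5000).
#' @param damping Damping constant, N s/m (default 2).
#' @return A `channel_model` object.
#' @export
channel_model <- function(start, end, stiffness = 5000, damping = 2) {
  d <- as.numeric(end) - as.numeric(start)
  len <- sqrt(sum(d^2))
  if (len <= 0) stop("channel line must have nonzero length", call. = FALSE)
  u <- d / len
  structure(
    list(start = as.numeric(start), end = as.numeric(end),
         direction = u, normal = c(-u[2], u[1]),
         stiffness = stiffness, damping = damping),
    class = "channel_model"
  )
}

#' Channel wall force
#'
#' @param channel A [channel_model()].
#' @param position Hand position, 2-vector m.
#' @param velocity Hand velocity, 2-vector m/s.
#' @return Restoring force, 2-vector N, perpendicular to the channel line
#'   (zero component along it).
#' @export
channel_force <- function(channel, position, velocity) {
  n <- channel$normal
  lat <- sum((as.numeric(position) - channel$start) * n)
  lat_v <- sum(as.numeric(velocity) * n)
  -(channel$stiffness * lat + channel$damping * lat_v) * n
}
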