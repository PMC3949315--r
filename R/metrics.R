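#' Estimate hand velocity from sampled positions
#'
#' Central differences followed by a 20-Hz 3rd-order low-pass Butterworth
#' filter (applied forward and backward so the phase is preserved), the
#' standard pre-processing for 400-Hz robot position data. Filtering is
#' skipped when the sampling rate is too low for the requested cutoff.
#'
#' @param trial Tibble with columns `t`, `x`, `y` (uniform sampling).
#' @param cutoff_hz Low-pass cutoff, Hz.
#' @param order Filter order.
#' @return The trial with `vx`, `vy` columns added (overwritten if present).
#' @export
estimate_velocity <- function(trial, cutoff_hz = 20, order = 3) {
  n <- nrow(trial)
  if (n < 3) stop("need at least 3 samples", call. = FALSE)
  dt <- stats::median(diff(trial$t))
  cdiff <- function(p) {
    v <- numeric(n)
    v[2:(n - 1)] <- (p[3:n] - p[1:(n - 2)]) / (2 * dt)
    v[1] <- (p[2] - p[1]) / dt
    v[n] <- (p[n] - p[n - 1]) / dt
    v
  }
  vx <- cdiff(trial$x); vy <- cdiff(trial$y)
  fs <- 1 / dt
  if (fs > 2.5 * cutoff_hz && n > 3 * (order + 1)) {
    bf <- signal::butter(order, cutoff_hz / (fs / 2))
    vx <- as.numeric(signal::filtfilt(bf, vx))
    vy <- as.numeric(signal::filtfilt(bf, vy))
  }
  trial$vx <- vx; trial$vy <- vy
  trial
}

#' Align a trial to movement onset
#'
#' Translates the path so the position at onset is the origin and re-zeroes
#' time at the onset sample. Onset is the first sample where hand speed
#' reaches `threshold` (0.1 m/s for the workspace-transfer analyses; 0.005
#' m/s for the channel-trial analyses).
#'
#' @param trial Tibble with `t`, `x`, `y` and (optionally) `vx`, `vy`; if the
#'   velocity columns are absent they are estimated with
#'   [estimate_velocity()].
#' @param threshold Onset speed threshold, m/s.
#' @return The aligned trial, with rows before onset kept (negative `t`).
#' @export
align_trial <- function(trial, threshold = 0.1) {
  if (!all(c("vx", "vy") %in% names(trial))) trial <- estimate_velocity(trial)
  speed <- sqrt(trial$vx^2 + trial$vy^2)
  i <- which(speed >= threshold)[1]
  if (is.na(i)) stop("speed never reaches the onset threshold", call. = FALSE)
  trial$t <- trial$t - trial$t[i]
  trial$x <- trial$x - trial$x[i]
  trial$y <- trial$y - trial$y[i]
  trial
}

#' Maximum perpendicular error
#'
#' Largest perpendicular distance of the reach path from the straight line
#' between the start and target locations. The signed variant (positive on
#' the left of the start-to-target direction) exposes the mirror-image
#' aftereffect on catch trials.
#'
#' @param trial Tibble with `x`, `y`.
#' @param start,target 2-vectors, m.
#' @param signed Return the signed extreme value (the deviation of largest
#'   magnitude, with its side of the line as sign)?
#' @return MPE in meters.
#' @export
mpe <- function(trial, start, target, signed = FALSE) {
  d <- as.numeric(target) - as.numeric(start)
  len <- sqrt(sum(d^2))
  if (len <= 0) stop("start and target coincide", call. = FALSE)
  nrm <- c(-d[2], d[1]) / len
  dev <- (trial$x - start[1]) * nrm[1] + (trial$y - start[2]) * nrm[2]
  if (signed) dev[which.max(abs(dev))] else max(abs(dev))
}

#' Angular error at peak speed
#'
#' Signed angle (degrees, positive counterclockwise) between the ray from the
#' start position to the target and the ray from the start to the point on
#' the path where speed is maximal (first maximum on ties).
#'
#' @param trial Tibble with `x`, `y` and `vx`, `vy` (estimated if absent).
#' @inheritParams mpe
#' @return Angular error in degrees.
#' @export
angular_error <- function(trial, start, target) {
  if (!all(c("vx", "vy") %in% names(trial))) trial <- estimate_velocity(trial)
  speed <- sqrt(trial$vx^2 + trial$vy^2)
  i <- which.max(speed)
  p <- c(trial$x[i], trial$y[i]) - as.numeric(start)
  if (sqrt(sum(p^2)) < 1e-12) {
    stop("peak speed occurs at the start position", call. = FALSE)
  }
  u <- as.numeric(target) - as.numeric(start)
  ang <- atan2(u[1] * p[2] - u[2] * p[1], u[1] * p[1] + u[2] * p[2])
  ang * 180 / pi
}

#' Normalized path length
#'
#' Discretely integrated path length divided by the nominal reach distance
#' (10 cm); a perfectly straight full reach scores 1.
#'
#' @param trial Tibble with `x`, `y`.
#' @param reach_distance Nominal reach distance, m.
#' @return Dimensionless path length ratio.
#' @export
normalized_path_length <- function(trial, reach_distance = 0.10) {
  if (nrow(trial) < 2) stop("need at least 2 samples", call. = FALSE)
  sum(sqrt(diff(trial$x)^2 + diff(trial$y)^2)) / reach_distance
}

# window rows of an aligned trial, with coverage check
window_rows <- function(trial, window_s) {
  if (min(trial$t) > window_s[1] + 1e-9 || max(trial$t) < window_s[2] - 1e-9) {
    stop(sprintf("trial covers [%.0f, %.0f] ms around onset; [%.0f, %.0f] required",
                 1000 * min(trial$t), 1000 * max(trial$t),
                 1000 * window_s[1], 1000 * window_s[2]), call. = FALSE)
  }
  trial[trial$t >= window_s[1] - 1e-9 & trial$t <= window_s[2] + 1e-9, ]
}

#' Correlation between a trial and its baseline average
#'
#' Pearson correlation of the concatenated position and velocity channels
#' (x, y, vx, vy) over a window from 125 ms before to 750 ms after the
#' alignment point. Both traces must be aligned (see [align_trial()]) and
#' sampled on the same grid.
#'
#' @param trial,baseline Aligned tibbles with `t`, `x`, `y`, `vx`, `vy`.
#' @param window Window around the alignment point, seconds.
#' @return Correlation coefficient in \[-1, 1\].
#' @export
trajectory_correlation <- function(trial, baseline,
                                   window = c(-0.125, 0.750)) {
  a <- window_rows(trial, window)
  b <- window_rows(baseline, window)
  if (nrow(a) != nrow(b)) {
    stop("trial and baseline must be sampled on the same grid", call. = FALSE)
  }
  stats::cor(c(a$x, a$y, a$vx, a$vy), c(b$x, b$y, b$vx, b$vy))
}

#' Windowed inner-product similarity of velocity traces
#'
#' A running windowed average of the inner product between a trial's velocity
#' and the average baseline velocity trace for the same reach direction,
#' normalized by the same quantity computed for the baseline against itself,
#' so that `rho(baseline, baseline) = 1`. Velocities everywhere orthogonal to
#' the baseline give 0; a trial with velocity scaled by `a` gives `a`.
#'
#' @inheritParams trajectory_correlation
#' @param window_ms Sliding-window length, ms.
#' @return The similarity value (dimensionless).
#' @export
rho <- function(trial, baseline, window_ms = 100,
                window = c(-0.125, 0.750)) {
  a <- window_rows(trial, window)
  b <- window_rows(baseline, window)
  if (nrow(a) != nrow(b)) {
    stop("trial and baseline must be sampled on the same grid", call. = FALSE)
  }
  dt <- stats::median(diff(a$t))
  w <- max(1L, round(window_ms / 1000 / dt))
  if (w > nrow(a)) stop("window longer than the trace", call. = FALSE)
  run_mean <- function(z) {
    cs <- cumsum(c(0, z))
    (cs[(w + 1):length(cs)] - cs[1:(length(cs) - w)]) / w
  }
  num <- mean(run_mean(a$vx * b$vx + a$vy * b$vy))
  den <- mean(run_mean(b$vx^2 + b$vy^2))
  if (den < 1e-15) stop("baseline velocity is identically zero", call. = FALSE)
  num / den
}

#' Direction-wise baseline averages
#'
#' Averages aligned baseline trials by reach direction (and any other
#' grouping columns present, e.g. a vision flag), producing the reference
#' traces that [trajectory_correlation()] and [rho()] compare against.
#' Trials are expected to be aligned and sampled on a common grid.
#'
#' @param trials Tibble of aligned baseline samples with columns `trial_id`,
#'   `direction`, `t`, `x`, `y`, `vx`, `vy` and optionally `vision`.
#' @return A tibble of average traces keyed by `direction` (and `vision` if
#'   present) with the same trace columns.
#' @export
baseline_average <- function(trials) {
  keys <- intersect(c("direction", "vision"), names(trials))
  if (!length(keys)) stop("`trials` needs a `direction` column", call. = FALSE)
  trials |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(keys, "t")))) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(c("x", "y", "vx", "vy")),
                                   mean),
                     .groups = "drop")
}

#' Per-trial metrics table
#'
#' Computes MPE, angular error and normalized path length for every trial in
#' a long trajectory table, and (when aligned baseline averages are supplied)
#' the baseline correlation and rho.
#'
#' @param trajectories Long tibble with columns `trial_id`, `t`, `x`, `y` and
#'   optionally `vx`, `vy`; one block of rows per trial.
#' @param starts,targets Tibbles keyed by `trial_id` with `x`, `y` columns,
#'   or `NULL` to use each trial's first and last sample.
#' @param baseline Optional aligned baseline-average table from
#'   [baseline_average()] (requires a `direction` column in `trajectories`).
#' @param onset_threshold Alignment threshold, m/s.
#' @return A tibble with one row per trial.
#' @export
trial_metrics <- function(trajectories, starts = NULL, targets = NULL,
                          baseline = NULL, onset_threshold = 0.1) {
  trajectories |>
    dplyr::group_by(.data$trial_id) |>
    dplyr::group_modify(function(tr, key) {
      start <- if (is.null(starts)) c(tr$x[1], tr$y[1]) else {
        unlist(starts[starts$trial_id == key$trial_id, c("x", "y")])
      }
      target <- if (is.null(targets)) {
        c(tr$x[nrow(tr)], tr$y[nrow(tr)])
      } else {
        unlist(targets[targets$trial_id == key$trial_id, c("x", "y")])
      }
      if (!all(c("vx", "vy") %in% names(tr))) tr <- estimate_velocity(tr)
      out <- tibble::tibble(
        mpe_m = mpe(tr, start, target),
        angular_error_deg = angular_error(tr, start, target),
        norm_path_length = normalized_path_length(tr)
      )
      if (!is.null(baseline) && "direction" %in% names(tr)) {
        al <- align_trial(tr, onset_threshold)
        bl <- baseline[baseline$direction == tr$direction[1], ]
        out$correlation <- trajectory_correlation(al, bl)
        out$rho <- rho(al, bl)
      }
      out
    }) |>
    dplyr::ungroup()
}
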