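#' Mixture model specification
#'
#' A generalization model is a convex mixture of the joint-based (`J`),
#' Cartesian (`C`) and object-centered (`O`) single-coordinate predictions,
#' optionally with Gaussian decay of each component as a function of the
#' squared distance from the training posture measured in that component's
#' own metric. Degrees of freedom follow the convention used for model
#' comparison: no-decay mixtures of 1/2/3 components have 0/1/2 free
#' parameters (the weights lose one to the sum-to-one constraint); decay
#' mixtures add one decay rate per component, giving 1/3/5.
#'
#' @param components Subset of `c("J", "C", "O")`.
#' @param decay Include Gaussian decay terms?
#' @return A `mixture_spec` object with a `dof` field.
#' @export
mixture_spec <- function(components = c("J", "C", "O"), decay = FALSE) {
  components <- match.arg(components, c("J", "C", "O"), several.ok = TRUE)
  components <- unique(components)
  m <- length(components)
  dof <- (m - 1) + if (decay) m else 0
  structure(list(components = components, decay = decay, dof = dof),
            class = "mixture_spec")
}

#' @export
print.mixture_spec <- function(x, ...) {
  cat(sprintf("<mixture_spec> %s%s (dof %d)\n",
              paste(x$components, collapse = "+"),
              if (x$decay) " with decay" else "", x$dof))
  invisible(x)
}

spec_label <- function(spec) {
  paste0(paste(spec$components, collapse = "+"),
         if (spec$decay) " decay" else "")
}

# squared-distance column in the design for each component
dist_col <- c(J = "dist_joint2", C = "dist_cart2", O = "dist_hand2")

#' Predicted adaptation of a mixture/decay model
#'
#' The model prediction at each test movement is
#' `sum_m k_m * pred_m * exp(-d_m * dist_m^2)` over the included components,
#' where `pred_m` is the normalized single-coordinate prediction and
#' `dist_m^2` the squared deviation from the training posture in that
#' component's metric (joint space in rad^2, Cartesian hand space in m^2,
#' hand orientation in rad^2).
#'
#' @param design Design tibble from [generalization_design()].
#' @param spec A [mixture_spec()].
#' @param k Named (or spec-ordered) mixture weights; must be nonnegative and
#'   sum to 1 over the included components.
#' @param d Named (or spec-ordered) nonnegative decay rates (rad^-2 for `J`
#'   and `O`, m^-2 for `C`); ignored when `spec$decay` is `FALSE`.
#' @return Numeric vector of predicted adaptation, one per design row.
#' @export
predict_mixture <- function(design, spec, k, d = NULL) {
  comps <- spec$components
  k <- normalize_params(k, comps, "k")
  if (any(k < -1e-12)) stop("mixture weights must be nonnegative", call. = FALSE)
  if (abs(sum(k) - 1) > 1e-8) {
    stop("mixture weights must sum to 1", call. = FALSE)
  }
  if (spec$decay) {
    d <- normalize_params(d, comps, "d")
    if (any(d < 0)) stop("decay rates must be nonnegative", call. = FALSE)
  } else {
    d <- stats::setNames(rep(0, length(comps)), comps)
  }
  pred <- rep(0, nrow(design))
  for (m in comps) {
    pred <- pred + k[[m]] * design[[m]] * exp(-d[[m]] * design[[dist_col[[m]]]])
  }
  pred
}

normalize_params <- function(x, comps, what) {
  if (is.null(x)) stop(sprintf("`%s` is required", what), call. = FALSE)
  if (is.null(names(x))) {
    if (length(x) != length(comps)) {
      stop(sprintf("`%s` must have one value per component", what), call. = FALSE)
    }
    names(x) <- comps
  }
  x[comps]
}

# Exact simplex-constrained least squares: minimize ||y - X k||^2 subject to
# k >= 0, sum(k) = 1, by enumerating the faces of the simplex and solving the
# equality-constrained problem on each.
simplex_lsq <- function(X, y) {
  m <- ncol(X)
  best <- NULL
  for (size in seq_len(m)) {
    for (S in utils::combn(m, size, simplify = FALSE)) {
      XS <- X[, S, drop = FALSE]
      A <- rbind(cbind(2 * crossprod(XS), 1), c(rep(1, size), 0))
      rhs <- c(2 * crossprod(XS, y), 1)
      sol <- tryCatch(solve(A, rhs), error = function(e) NULL)
      if (is.null(sol)) next
      kS <- sol[seq_len(size)]
      if (any(kS < -1e-10)) next
      k <- rep(0, m); k[S] <- pmax(kS, 0); k <- k / sum(k)
      mse <- mean((y - as.numeric(X %*% k))^2)
      if (is.null(best) || mse < best$mse) best <- list(k = k, mse = mse)
    }
  }
  best
}

#' Fit a mixture/decay generalization model
#'
#' Minimizes the mean squared error between the model prediction and all
#' subjects' adaptation values (concatenated across subjects) under the
#' constraints that mixture weights are nonnegative and sum to 1 and decay
#' rates are nonnegative. Weights are solved exactly by active-set
#' enumeration over the simplex; for decay models this exact solve is nested
#' inside a Nelder-Mead search over log decay rates with seeded random
#' restarts (one restart pinned near zero decay, so the decayed optimum can
#' never be worse than the no-decay one).
#'
#' @param data Tibble with columns `subject_id`, `movement_id`, `adaptation`.
#' @param design Design tibble from [generalization_design()] (defaults to
#'   the cached [default_design()]).
#' @param spec A [mixture_spec()].
#' @param n_restarts Random restarts for the decay-rate search.
#' @param seed Seed for the restart draws (recorded in the result).
#' @return A `reachfit` object: weights `k` (named, all of J/C/O with zeros
#'   for excluded components), decay rates `d`, `mse`, `n`, `dof`, `bic`,
#'   `converged`, `spec`, `seed`.
#' @export
fit_mixture <- function(data, design = default_design(), spec = mixture_spec(),
                        n_restarts = 10, seed = 1) {
  stopifnot(all(c("subject_id", "movement_id", "adaptation") %in% names(data)))
  if (!all(is.finite(data$adaptation))) {
    stop("`adaptation` must be finite", call. = FALSE)
  }
  idx <- match(data$movement_id, design$movement_id)
  if (anyNA(idx)) stop("data contains movement ids absent from the design",
                       call. = FALSE)
  comps <- spec$components
  y <- data$adaptation
  n <- length(y)
  if (n < spec$dof + 1) {
    stop("fewer data points than free parameters", call. = FALSE)
  }
  P <- as.matrix(design[comps])[idx, , drop = FALSE]
  D2 <- as.matrix(design[dist_col[comps]])[idx, , drop = FALSE]

  if (!spec$decay) {
    sol <- simplex_lsq(P, y)
    k <- stats::setNames(sol$k, comps)
    d <- NULL
    mse <- sol$mse
    converged <- TRUE
  } else {
    obj <- function(logd) {
      Xd <- P * exp(-rep(exp(logd), each = n) * D2)
      simplex_lsq(Xd, y)$mse
    }
    m <- length(comps)
    starts <- withr::with_seed(seed, {
      s <- matrix(stats::runif(n_restarts * m, log(1e-2), log(1e3)),
                  nrow = n_restarts)
      s[1, ] <- rep(-12, m) # effectively no decay
      s
    })
    best <- NULL
    converged <- FALSE
    for (i in seq_len(n_restarts)) {
      fit <- if (m == 1) {
        o <- stats::optimize(function(ld) obj(ld), c(-14, 10), tol = 1e-10)
        list(par = o$minimum, value = o$objective, convergence = 0)
      } else {
        stats::optim(starts[i, ], obj, method = "Nelder-Mead",
                     control = list(reltol = 1e-12, maxit = 2000))
      }
      if (is.null(best) || fit$value < best$value) {
        best <- fit
        converged <- fit$convergence == 0
      }
      if (m == 1) break # 1-D search is global over the bracket
    }
    d <- stats::setNames(exp(best$par), comps)
    Xd <- P * exp(-rep(d, each = n) * D2)
    sol <- simplex_lsq(Xd, y)
    k <- stats::setNames(sol$k, comps)
    mse <- sol$mse
  }

  full_k <- stats::setNames(rep(0, 3), c("J", "C", "O"))
  full_k[comps] <- k
  full_d <- stats::setNames(rep(NA_real_, 3), c("J", "C", "O"))
  if (spec$decay) full_d[comps] <- d
  structure(
    list(k = full_k, d = full_d, mse = mse, n = n, dof = spec$dof,
         bic = compute_bic(mse, spec$dof, n), spec = spec, seed = seed,
         converged = converged),
    class = "reachfit"
  )
}

#' @export
print.reachfit <- function(x, ...) {
  cat(sprintf("<reachfit> %s: mse %.4g, bic %.1f (n = %d)\n",
              spec_label(x$spec), x$mse, x$bic, x$n))
  cat("  k:", paste(sprintf("%s=%.3f", names(x$k), x$k), collapse = " "), "\n")
  if (x$spec$decay) {
    cat("  d:", paste(sprintf("%s=%.3g", names(x$d), x$d), collapse = " "), "\n")
  }
  invisible(x)
}

#' Bayesian information criterion from a mean squared error
#'
#' `BIC = n * ln(MSE) + dof * ln(n)`; lower is better. A zero MSE returns
#' `-Inf` with a warning (a perfect fit dominates any comparison).
#'
#' @param mse Mean squared error of the fit (> 0).
#' @param dof Model degrees of freedom.
#' @param n Number of fitted points.
#' @return The BIC value.
#' @export
compute_bic <- function(mse, dof, n) {
  stopifnot(n >= 1, mse >= 0)
  if (mse == 0) {
    warning("MSE is exactly 0; BIC is -Inf", call. = FALSE)
    return(-Inf)
  }
  n * log(mse) + dof * log(n)
}

#' Compare fitted generalization models
#'
#' Ranks fits by BIC (ascending) and reports the BIC difference to the best
#' model, the approximate log Bayes factor (`0.5 * delta BIC`), and the BIC
#' improvement over a no-generalization reference model that predicts zero
#' force at every test posture (0 degrees of freedom). Ties in BIC are broken
#' in favor of fewer degrees of freedom, then lexicographic component order.
#'
#' @param fits A list of `reachfit` objects fitted to the same dataset.
#' @param data The dataset the fits were computed on (needed for the
#'   no-generalization reference MSE).
#' @return A tibble with one row per model: `model`, `dof`, `mse`, `bic`,
#'   `delta_bic`, `log_bayes_factor`, `bic_improvement` (over the
#'   no-generalization reference).
#' @export
compare_models <- function(fits, data) {
  if (inherits(fits, "reachfit")) fits <- list(fits)
  ns <- vapply(fits, function(f) f$n, numeric(1))
  if (length(unique(ns)) != 1 || unique(ns) != nrow(data)) {
    stop("all fits must come from the same dataset (equal n)", call. = FALSE)
  }
  mse0 <- mean(data$adaptation^2)
  bic0 <- compute_bic(mse0, 0, nrow(data))
  tab <- purrr::map_dfr(fits, function(f) {
    tibble::tibble(model = spec_label(f$spec), dof = f$dof, mse = f$mse,
                   bic = f$bic)
  })
  tab |>
    dplyr::mutate(delta_bic = .data$bic - min(.data$bic),
                  log_bayes_factor = 0.5 * .data$delta_bic,
                  bic_improvement = bic0 - .data$bic) |>
    dplyr::arrange(.data$bic, .data$dof, .data$model)
}

#' Leave-one-subject-out cross-validation
#'
#' For each subject, the model is fit to the per-movement average of all
#' remaining subjects and used to predict the held-out subject. Variance
#' explained is `1 - SSE/SST` on the held-out subject's values; it is
#' negative when the model predicts worse than the subject's own mean.
#'
#' @inheritParams fit_mixture
#' @return A tibble `subject_id`, `variance_explained`, plus the group mean
#'   as attribute `"mean_ve"`.
#' @export
loocv <- function(data, design = default_design(), spec = mixture_spec(),
                  n_restarts = 10, seed = 1) {
  subjects <- unique(data$subject_id)
  if (length(subjects) < 3) stop("need at least 3 subjects", call. = FALSE)
  ve <- vapply(subjects, function(s) {
    train <- data |>
      dplyr::filter(.data$subject_id != s) |>
      dplyr::group_by(.data$movement_id) |>
      dplyr::summarise(adaptation = mean(.data$adaptation), .groups = "drop") |>
      dplyr::mutate(subject_id = "average")
    fit <- fit_mixture(train, design, spec, n_restarts, seed)
    held <- dplyr::filter(data, .data$subject_id == s)
    pred <- predict_mixture(
      design[match(held$movement_id, design$movement_id), ], spec,
      k = fit$k[spec$components],
      d = if (spec$decay) fit$d[spec$components] else NULL
    )
    sst <- sum((held$adaptation - mean(held$adaptation))^2)
    if (sst < 1e-12) {
      warning(sprintf("subject %s has (near-)constant data; SST degenerate", s),
              call. = FALSE)
      return(NA_real_)
    }
    1 - sum((held$adaptation - pred)^2) / sst
  }, numeric(1))
  out <- tibble::tibble(subject_id = subjects,
                        variance_explained = unname(ve))
  attr(out, "mean_ve") <- mean(ve, na.rm = TRUE)
  out
}

#' Fit the full model family
#'
#' Fits all seven no-decay and seven decay mixtures (J, C, O, C+O, J+O, J+C,
#' J+C+O, each with and without decay): the 14 candidate generalization
#' models.
#'
#' @inheritParams fit_mixture
#' @param decay Logical vector of decay settings to include.
#' @return A named list of `reachfit` objects.
#' @export
fit_all_models <- function(data, design = default_design(),
                           decay = c(FALSE, TRUE), n_restarts = 10, seed = 1) {
  combos <- list("J", "C", "O", c("C", "O"), c("J", "O"), c("J", "C"),
                 c("J", "C", "O"))
  specs <- purrr::flatten(purrr::map(decay, function(dc) {
    purrr::map(combos, mixture_spec, decay = dc)
  }))
  fits <- purrr::map(specs, function(sp) {
    fit_mixture(data, design, sp, n_restarts, seed)
  })
  stats::setNames(fits, purrr::map_chr(specs, spec_label))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted generalization model
#'
#' @param x A `reachfit` object.
#' @param ... Unused.
#' @return A tibble with one row per parameter (`term`, `estimate`).
#' @method tidy reachfit
#' @export
tidy.reachfit <- function(x, ...) {
  comps <- x$spec$components
  out <- tibble::tibble(term = paste0("k_", tolower(comps)),
                        estimate = unname(x$k[comps]))
  if (x$spec$decay) {
    out <- dplyr::bind_rows(out,
      tibble::tibble(term = paste0("d_", tolower(comps)),
                     estimate = unname(x$d[comps])))
  }
  out
}

#' One-row model summary
#'
#' @param x A `reachfit` object.
#' @param ... Unused.
#' @return A tibble with `model`, `dof`, `mse`, `n`, `bic`, `converged`.
#' @method glance reachfit
#' @export
glance.reachfit <- function(x, ...) {
  tibble::tibble(model = spec_label(x$spec), dof = x$dof, mse = x$mse,
                 n = x$n, bic = x$bic, converged = x$converged)
}
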