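toy_design <- tibble::tibble(
  movement_id = 1:3,
  config = 1L, orientation = 0,
  J = c(1, 0.5, 0), C = c(1, 1, 1), O = c(1, 0, -1),
  dist_joint2 = c(0, 0.5, 1), dist_cart2 = c(0, 0.01, 0.04),
  dist_hand2 = c(0, 0.3, 0.6)
)

test_that("mixture predictions combine components and decay as specified", {
  spec <- mixture_spec(c("J", "C", "O"))
  # published three-component weights on the toy set: manual arithmetic
  k <- c(J = 0.66, C = 0.10, O = 0.24)
  expect_equal(predict_mixture(toy_design, spec, k),
               c(0.66 + 0.10 + 0.24, 0.33 + 0.10, 0.10 - 0.24),
               tolerance = 1e-12)
  # a single component with weight one returns its prediction verbatim
  expect_equal(predict_mixture(toy_design, mixture_spec("J"), c(J = 1)),
               toy_design$J)
  # zero decay rates reduce exactly to the no-decay mixture
  specd <- mixture_spec(c("J", "C", "O"), decay = TRUE)
  expect_equal(predict_mixture(toy_design, specd, k, d = c(J = 0, C = 0, O = 0)),
               predict_mixture(toy_design, spec, k), tolerance = 1e-15)
  # decay multiplies each component by its own Gaussian factor
  d <- c(J = 0.93, C = 365.88, O = 3.01)
  manual <- 0.66 * toy_design$J * exp(-0.93 * toy_design$dist_joint2) +
    0.10 * toy_design$C * exp(-365.88 * toy_design$dist_cart2) +
    0.24 * toy_design$O * exp(-3.01 * toy_design$dist_hand2)
  expect_equal(predict_mixture(toy_design, specd, k, d), manual,
               tolerance = 1e-12)
  # constraint violations are rejected
  expect_error(predict_mixture(toy_design, spec, c(J = 0.5, C = 0.5, O = 0.5)),
               "sum to 1")
  expect_error(predict_mixture(toy_design, spec,
                               c(J = 1.2, C = -0.2, O = 0)), "nonnegative")
  expect_error(predict_mixture(toy_design, specd, k,
                               d = c(J = -1, C = 0, O = 0)), "nonnegative")
})

test_that("dof accounting matches the model-comparison convention", {
  expect_equal(mixture_spec("J")$dof, 0)
  expect_equal(mixture_spec(c("J", "O"))$dof, 1)
  expect_equal(mixture_spec(c("J", "C", "O"))$dof, 2)
  expect_equal(mixture_spec("J", decay = TRUE)$dof, 1)
  expect_equal(mixture_spec(c("J", "O"), decay = TRUE)$dof, 3)
  expect_equal(mixture_spec(c("J", "C", "O"), decay = TRUE)$dof, 5)
})

test_that("noise-free data are fit exactly and parameters recovered", {
  design <- cached_design()
  # pure joint truth
  ds <- simulate_channel_dataset(ground_truth_model(k = c(J = 1), sigma = 0),
                                 n_subjects = 4, design = design, seed = 2)
  # perfect fits legitimately warn that the BIC degenerates to -Inf
  fit <- suppressWarnings(fit_mixture(ds, design, mixture_spec(c("J", "C", "O"))))
  expect_equal(unname(fit$k), c(1, 0, 0), tolerance = 1e-9)
  expect_lt(fit$mse, 1e-18)
  # published three-component weights
  truth <- ground_truth_model(k = c(J = 0.66, C = 0.10, O = 0.24), sigma = 0)
  ds2 <- simulate_channel_dataset(truth, 4, design, seed = 3)
  fit2 <- suppressWarnings(fit_mixture(ds2, design, mixture_spec(c("J", "C", "O"))))
  expect_equal(unname(fit2$k), c(0.66, 0.10, 0.24), tolerance = 1e-3)
  # decay truth: k_j = 1, d_j = 0.93 rad^-2
  truthd <- ground_truth_model(k = c(J = 1), d = c(J = 0.93), sigma = 0)
  ds3 <- simulate_channel_dataset(truthd, 4, design, seed = 4)
  fit3 <- suppressWarnings(fit_mixture(ds3, design, mixture_spec("J", decay = TRUE)))
  expect_equal(unname(fit3$d["J"]), 0.93, tolerance = 1e-4)
  expect_true(fit3$converged)
})

test_that("the constrained optimum matches a brute-force simplex grid", {
  design <- cached_design()
  withr::with_seed(55, {
    for (rep in 1:3) {
      w <- stats::runif(3); w <- w / sum(w)
      truth <- ground_truth_model(k = c(J = w[1], C = w[2], O = w[3]),
                                  sigma = 0.15)
      ds <- simulate_channel_dataset(truth, 5, design,
                                     seed = sample.int(1e6, 1))
      fit <- fit_mixture(ds, design, mixture_spec(c("J", "C", "O")))
      grid <- grid_search_mse(ds, design)
      expect_lte(fit$mse, grid$mse + 1e-12)
      expect_equal(fit$k[c("J", "C", "O")],
                   c(J = grid$k[1], C = grid$k[2], O = grid$k[3]),
                   tolerance = 0.02)
    }
  })
})

test_that("decayed fits never do worse than their no-decay counterparts", {
  design <- cached_design()
  truth <- ground_truth_model(k = c(J = 0.7, O = 0.3), sigma = 0.1)
  ds <- simulate_channel_dataset(truth, 6, design, seed = 9)
  for (comps in list("J", c("J", "O"))) {
    f0 <- fit_mixture(ds, design, mixture_spec(comps))
    f1 <- fit_mixture(ds, design, mixture_spec(comps, decay = TRUE))
    expect_lte(f1$mse, f0$mse + 1e-8)
  }
})

test_that("BIC follows its closed form with sensible edge behavior", {
  # ln(1) = 0: only the parameter penalty remains
  expect_equal(compute_bic(1, 3, 50), 3 * log(50))
  # dof 0: pure likelihood term
  expect_equal(compute_bic(0.5, 0, 10), 10 * log(0.5))
  # frozen independent arithmetic: 135 ln(0.5) + 2 ln(135)
  expect_equal(compute_bic(0.5, 2, 135), -83.7643224, tolerance = 1e-7)
  expect_warning(b0 <- compute_bic(0, 2, 10), "-Inf")
  expect_identical(b0, -Inf)
})

test_that("model comparison ranks by BIC with documented tie-breaking", {
  design <- cached_design()
  ds <- simulate_channel_dataset(ground_truth_model(k = c(J = 1), sigma = 0.1),
                                 5, design, seed = 12)
  fits <- list(fit_mixture(ds, design, mixture_spec("J")),
               fit_mixture(ds, design, mixture_spec(c("J", "C"))),
               fit_mixture(ds, design, mixture_spec(c("J", "C", "O"))))
  cmp <- compare_models(fits, ds)
  # manual sort oracle
  expect_equal(cmp$bic, sort(vapply(fits, function(f) f$bic, numeric(1))))
  expect_equal(cmp$delta_bic[1], 0)
  expect_equal(cmp$log_bayes_factor, 0.5 * cmp$delta_bic)
  # improvement over no generalization = BIC(zero model) - BIC(model)
  bic0 <- nrow(ds) * log(mean(ds$adaptation^2))
  expect_equal(cmp$bic_improvement, bic0 - cmp$bic)
  # equal MSE, different dof: fewer dof wins (lower BIC penalty), and on an
  # exact BIC tie the tie-break still prefers fewer dof
  n <- nrow(ds)
  f_a <- list(mse = 0.3, n = n, dof = 0, bic = compute_bic(0.3, 0, n),
              spec = mixture_spec("J"))
  f_b <- list(mse = 0.3, n = n, dof = 2, bic = compute_bic(0.3, 2, n),
              spec = mixture_spec(c("J", "C", "O")))
  class(f_a) <- class(f_b) <- "reachfit"
  cmp2 <- compare_models(list(f_b, f_a), ds)
  expect_equal(cmp2$model[1], "J")
  f_c <- f_b; f_c$bic <- f_a$bic
  cmp3 <- compare_models(list(f_c, f_a), ds)
  expect_equal(cmp3$model[1], "J")
  # mixed n rejected
  expect_error(compare_models(fits, ds[-1, ]), "same dataset")
})

test_that("leave-one-subject-out variance explained matches a direct computation", {
  design <- cached_design()
  truth <- ground_truth_model(k = c(J = 0.8, C = 0.2), sigma = 0.08)
  ds <- simulate_channel_dataset(truth, 4, design, seed = 21)
  spec <- mixture_spec(c("J", "C"))
  cv <- loocv(ds, design, spec)
  expect_equal(nrow(cv), 4)

  # independent recomputation for each subject
  for (s in unique(ds$subject_id)) {
    others <- ds[ds$subject_id != s, ]
    avg <- stats::aggregate(adaptation ~ movement_id, others, mean)
    avg$subject_id <- "avg"
    fit <- fit_mixture(tibble::as_tibble(avg), design, spec)
    held <- ds[ds$subject_id == s, ]
    pred <- predict_mixture(design[match(held$movement_id,
                                         design$movement_id), ],
                            spec, fit$k[c("J", "C")])
    ve_oracle <- 1 - sum((held$adaptation - pred)^2) /
      sum((held$adaptation - mean(held$adaptation))^2)
    expect_equal(cv$variance_explained[cv$subject_id == s], ve_oracle,
                 tolerance = 1e-10)
  }

  # a perfect model on a subject equal to the others' average explains all
  pred0 <- predict_mixture(design, mixture_spec("J"), c(J = 1))
  perfect <- purrr::map_dfr(1:3, function(s) {
    tibble::tibble(subject_id = paste0("P", s),
                   movement_id = design$movement_id, adaptation = pred0)
  })
  cvp <- suppressWarnings(loocv(perfect, design, mixture_spec("J")))
  expect_equal(cvp$variance_explained, rep(1, 3), tolerance = 1e-10)

  expect_error(loocv(ds[ds$subject_id %in% c("S01", "S02"), ], design, spec),
               "3 subjects")
})

test_that("the full model family yields 14 fits with tidy/glance accessors", {
  design <- cached_design()
  ds <- simulate_channel_dataset(
    ground_truth_model(k = c(J = 0.9, O = 0.1), sigma = 0.1), 4, design,
    seed = 30)
  fits <- fit_all_models(ds, design, n_restarts = 4)
  expect_length(fits, 14)
  expect_setequal(
    names(fits),
    c("J", "C", "O", "C+O", "J+O", "J+C", "J+C+O",
      paste0(c("J", "C", "O", "C+O", "J+O", "J+C", "J+C+O"), " decay")))
  td <- tidy(fits[["J+O decay"]])
  expect_equal(td$term, c("k_j", "k_o", "d_j", "d_o"))
  expect_equal(sum(td$estimate[1:2]), 1, tolerance = 1e-12)
  gl <- glance(fits[["J"]])
  expect_equal(gl$dof, 0)
  expect_equal(gl$n, nrow(ds))
})

test_that("fits round-trip through JSON at full precision", {
  design <- cached_design()
  ds <- simulate_channel_dataset(ground_truth_model(k = c(J = 1), sigma = 0.1),
                                 3, design, seed = 5)
  fit <- fit_mixture(ds, design, mixture_spec(c("J", "O"), decay = TRUE),
                     n_restarts = 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_fit_json(fit, path)
  back <- read_fit_json(path)
  expect_equal(back$k, fit$k)
  expect_equal(back$mse, fit$mse)
  expect_equal(back$bic, fit$bic)
  expect_equal(back$spec$components, fit$spec$components)
})
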