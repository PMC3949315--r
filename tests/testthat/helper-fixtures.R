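# shared fixtures: the default design table is moderately expensive (the
# joint-model force series re-evaluates the Jacobian at every sample), so it
# is computed once per test run
cached_design <- local({
  design <- NULL
  function() {
    if (is.null(design)) design <<- default_design()
    design
  }
})

# brute-force grid search over the weight simplex at a fixed resolution;
# independent oracle for the constrained mixture fit
grid_search_mse <- function(data, design, components = c("J", "C", "O"),
                            resolution = 0.01) {
  steps <- seq(0, 1, by = resolution)
  K <- expand.grid(k1 = steps, k2 = steps)
  K <- K[K$k1 + K$k2 <= 1 + 1e-12, ]
  K <- cbind(K$k1, K$k2, 1 - K$k1 - K$k2)
  idx <- match(data$movement_id, design$movement_id)
  P <- as.matrix(design[components])[idx, , drop = FALSE]
  pred <- P %*% t(K)
  mse <- colMeans((data$adaptation - pred)^2)
  list(mse = min(mse), k = K[which.min(mse), ])
}

random_posture <- function() {
  joint_posture(stats::runif(1, 10, 150), stats::runif(1, 20, 160),
                stats::runif(1, -45, 45), degrees = TRUE)
}
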