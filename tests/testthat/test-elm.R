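test_that("hidden layer has the configured shapes, ranges and seed behaviour", {
  cfg <- elm_config(3L, seed = 21L)
  m <- elm_init(cfg, 2L)
  expect_equal(dim(m$W), c(3L, 2L))
  expect_length(m$b, 3L)
  expect_true(all(m$W >= -1 & m$W <= 1))
  expect_true(all(m$b >= 0 & m$b <= 1))
  expect_null(m$beta)

  m2 <- elm_init(cfg, 2L)
  expect_identical(m$W, m2$W)
  expect_identical(m$b, m2$b)
  m3 <- elm_init(elm_config(3L, seed = 22L), 2L)
  expect_false(identical(m$W, m3$W))

  expect_error(elm_config(0L), "positive")
})

test_that("hidden activations follow the sigmoid exactly and stay in (0,1)", {
  m <- manual_elm(W = matrix(0, 4L, 3L), b = rep(0, 4L), beta = NULL)
  H <- hidden_activations(m, matrix(rnorm(15L), 5L, 3L))
  expect_equal(H, matrix(0.5, 5L, 4L))   # sigmoid(0) = 1/2

  # stable in the saturated limits, no overflow
  m1 <- manual_elm(W = matrix(1, 1L, 1L), b = 0, beta = NULL)
  expect_equal(hidden_activations(m1, matrix(0))[1L, 1L], 0.5)
  expect_equal(hidden_activations(m1, matrix(1000))[1L, 1L], 1)
  expect_equal(hidden_activations(m1, matrix(-1000))[1L, 1L], 0)
  H <- hidden_activations(m1, matrix(seq(-20, 20, length.out = 41L)))
  expect_true(all(diff(H[, 1L]) > 0))    # monotone in w.x + b
  expect_true(all(H > 0 & H < 1))

  expect_error(hidden_activations(m, matrix(0, 2L, 5L)), "columns")
})

test_that("identity hidden matrix returns the targets as weights", {
  Y <- matrix(c(3, -1, 2, 0, 7), 5L, 1L)
  expect_equal(elmeeg:::pinv_solve(diag(5L), Y), Y)
})

test_that("fitted weights solve the normal equations (random instance)", {
  set.seed(31L)
  H <- matrix(runif(150L), 30L, 5L)
  Y <- matrix(rnorm(30L), 30L, 1L)
  beta <- elmeeg:::pinv_solve(H, Y)
  # regularization-free least squares: H'H beta = H'Y
  beta_ne <- solve(crossprod(H), crossprod(H, Y))
  expect_equal(beta, beta_ne, tolerance = 1e-8)
  expect_lt(sqrt(sum((crossprod(H, H %*% beta - Y))^2)), 1e-8)
})

test_that("interpolation: L = n distinct rows gives 100% training accuracy", {
  set.seed(32L)
  X <- matrix(rnorm(20L * 4L), 20L, 4L)
  y <- rep_len(0:1, 20L)
  fit <- elm_train(X, y, elm_config(20L, seed = 33L))
  expect_identical(predict(fit, X), y)
  # scores reproduce the targets to solver tolerance
  expect_equal(decision_scores(fit, X)[, 1L], as.numeric(y),
               tolerance = 1e-8)
})

test_that("decision scores are a row-wise linear map of the activations", {
  tt <- tiny_trained_elm(seed = 41L)
  X <- tt$data$features
  zero <- tt$model
  zero$beta <- matrix(0, nrow(zero$W), 1L)
  expect_equal(decision_scores(zero, X), matrix(0, nrow(X), 1L))

  # invariant to row order
  perm <- sample(nrow(X))
  expect_equal(decision_scores(tt$model, X)[perm, , drop = FALSE],
               decision_scores(tt$model, X[perm, , drop = FALSE]))

  untrained <- elm_init(elm_config(3L), ncol(X))
  expect_error(decision_scores(untrained, X), "not trained")
})

test_that("prediction thresholds and argmax follow the documented conventions", {
  # one hidden node with zero pre-activation: H = 0.5 everywhere
  m <- manual_elm(W = matrix(0, 1L, 1L), b = 0, beta = matrix(1))
  expect_equal(decision_scores(m, matrix(0))[1L, 1L], 0.5)
  expect_equal(predict(m, matrix(0), threshold = 0.5), 1L)   # boundary -> 1
  expect_equal(predict(m, matrix(0), threshold = 0.6), 0L)

  # one-hot argmax with tie toward the lowest class index
  mo <- manual_elm(W = matrix(0, 1L, 1L), b = 0,
                   beta = matrix(c(0.8, 0.8, 0.2), 1L, 3L),
                   encoding = "onehot", classes = 1:3)
  expect_equal(predict(mo, matrix(0)), 1L)
  mo$beta <- matrix(c(0.4, 1.8, 0.2, 0, 0), 1L, 5L)
  mo$classes <- 1:5
  expect_equal(predict(mo, matrix(0)), 2L)

  expect_error(predict(m, matrix(0), threshold = Inf), "finite")
})

test_that("raising the threshold never increases predicted positives", {
  tt <- tiny_trained_elm(n = 80L, seed = 43L, margin = 1)
  X <- tt$data$features
  pos <- vapply(seq(-0.5, 1.5, by = 0.1),
                function(th) sum(predict(tt$model, X, threshold = th)),
                numeric(1L))
  expect_true(all(diff(pos) <= 0))
})

test_that("a duplicated training row leaves the fit unchanged when consistent", {
  set.seed(44L)
  X <- matrix(rnorm(20L * 3L), 20L, 3L)
  y <- rep_len(0:1, 20L)
  cfg <- elm_config(25L, seed = 45L)   # L > n: interpolating, consistent
  f1 <- elm_fit(elm_init(cfg, 3L), X, y)
  f2 <- elm_fit(elm_init(cfg, 3L), rbind(X, X[1L, ]), c(y, y[1L]))
  Xnew <- matrix(rnorm(30L), 10L, 3L)
  expect_equal(decision_scores(f1, Xnew), decision_scores(f2, Xnew),
               tolerance = 1e-6)
})

test_that("full determinism: seed, config and data fix every model artifact", {
  ds <- generate_separable(60L, 4L, 2, seed = 51L)
  f1 <- elm_train(ds$features, ds$labels, elm_config(12L, seed = 52L))
  f2 <- elm_train(ds$features, ds$labels, elm_config(12L, seed = 52L))
  expect_identical(f1$W, f2$W)
  expect_identical(f1$b, f2$b)
  expect_identical(f1$beta, f2$beta)
  expect_identical(predict(f1, ds$features), predict(f2, ds$features))
})

test_that("fit rejects degenerate input", {
  mod <- elm_init(elm_config(3L), 2L)
  expect_error(elm_fit(mod, matrix(0, 0L, 2L), integer(0L)), "empty")
  expect_error(elm_fit(mod, matrix(c(1, NA), 1L, 2L), 1L), "finite|missing")
  expect_error(elm_fit(mod, matrix(1, 2L, 2L), c(0L, 2L)), "binary|0/1")
})

test_that("hidden-neuron sweep returns the smallest best L from the grid", {
  ds <- generate_separable(300L, 6L, 3, seed = 61L)
  tr <- binary_view(ds$features[1:200, ], ds$labels[1:200])
  va <- binary_view(ds$features[201:300, ], ds$labels[201:300])

  sw1 <- sweep_hidden_neurons(tr, va, grid = 15L, seed = 62L)
  expect_equal(sw1$best_L, 15L)           # singleton grid

  grid <- c(5L, 10L, 20L, 40L)
  sw <- sweep_hidden_neurons(tr, va, grid = grid, seed = 62L)
  expect_true(sw$best_L %in% grid)        # closure
  expect_equal(nrow(sw$curve), length(grid))
  expect_equal(sw$best_accuracy, max(sw$curve$accuracy))
  # smallest maximizer wins
  expect_equal(sw$best_L, grid[which.max(sw$curve$accuracy)])
  # deterministic under the master seed
  expect_identical(sw, sweep_hidden_neurons(tr, va, grid = grid, seed = 62L))

  expect_warning(sweep_hidden_neurons(tr, va, grid = 10L * 200L + 1L,
                                      seed = 1L), "overparameterized")
  expect_error(sweep_hidden_neurons(tr, va, grid = integer(0L)), "non-empty")
})

test_that("the default sweep grid contains the heuristic anchor", {
  ds <- generate_separable(300L, 4L, 4, seed = 63L)
  tr <- binary_view(ds$features[1:200, ], ds$labels[1:200])
  va <- binary_view(ds$features[201:300, ], ds$labels[201:300])
  sw <- sweep_hidden_neurons(tr, va, seed = 64L)
  expect_true(default_n_hidden(200L) %in% sw$curve$L)   # 0.1 * n_train
  expect_equal(range(sw$curve$L), c(4L, 40L))           # 2%..20% of n_train
})

test_that("the one-per-ten-rows heuristic lands on the canonical sizes", {
  expect_equal(default_n_hidden(9200L), 920L)
  expect_equal(default_n_hidden(8050L), 805L)
  expect_equal(default_n_hidden(6900L), 690L)
})

test_that("model serialization round-trips bit-exactly", {
  tt <- tiny_trained_elm(seed = 71L)
  tt$model$rescaler <- fit_rescaler(tt$data$features)
  p <- tempfile(fileext = ".txt")
  write_elm(tt$model, p)
  m2 <- read_elm(p)
  expect_identical(m2$rescaler$center, unname(tt$model$rescaler$center))
  expect_identical(m2$rescaler$scale, unname(tt$model$rescaler$scale))
  expect_identical(m2$rescaler$keep, tt$model$rescaler$keep)
  expect_identical(m2$W, tt$model$W)
  expect_identical(m2$b, tt$model$b)
  expect_identical(m2$beta, tt$model$beta)
  expect_identical(m2$encoding, tt$model$encoding)
  expect_identical(predict(m2, tt$data$features),
                   predict(tt$model, tt$data$features))
})
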