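test_that("reader parses the canonical dialect and rejects malformed files", {
  p <- write_tiny_csv(n = 2L, m = 178L, labels = c(1L, 4L))
  ds <- read_eeg_csv(p)
  expect_s3_class(ds, "eeg_dataset")
  expect_equal(dim(ds$features), c(2L, 178L))
  expect_equal(colnames(ds$features), paste0("X", 1:178))
  expect_equal(ds$labels, c(1L, 4L))

  # label column missing
  df <- utils::read.csv(p)
  df$y <- NULL
  p2 <- tempfile(fileext = ".csv")
  utils::write.csv(df, p2, row.names = FALSE)
  expect_error(read_eeg_csv(p2), "label column")

  # non-numeric cell
  df <- utils::read.csv(p)
  df$X3 <- c("7", "oops")
  utils::write.csv(df, p2, row.names = FALSE)
  expect_error(read_eeg_csv(p2), "non-numeric")

  # blank cell
  df <- utils::read.csv(p)
  df$X5[2L] <- NA
  utils::write.csv(df, p2, row.names = FALSE)
  expect_error(read_eeg_csv(p2), "row 2")
})

test_that("reader auto-detects an unnamed leading id column", {
  p <- tempfile(fileext = ".csv")
  writeLines(c(",X1,X2,y",
               "X21.V1.791,3,-4,1",
               "X15.V1.87,0,12,5"), p)
  ds <- read_eeg_csv(p)
  expect_equal(ds$row_ids, c("X21.V1.791", "X15.V1.87"))
  expect_equal(dim(ds$features), c(2L, 2L))
  expect_equal(ds$labels, c(1L, 5L))
})

test_that("write/read round-trips integer tables exactly", {
  p <- write_tiny_csv(n = 6L, m = 10L)
  ds <- read_eeg_csv(p)
  p2 <- tempfile(fileext = ".csv")
  write_eeg_csv(ds, p2)
  ds2 <- read_eeg_csv(p2)
  expect_identical(ds2$features, ds$features)
  expect_identical(ds2$labels, ds$labels)
})

test_that("binarization maps ictal to 1 and everything else to 0", {
  x <- matrix(rnorm(20 * 4), 20L, 4L)
  ds <- eeg_dataset(x, rep_len(1:5, 20L))
  bin <- relabel_binary(ds)
  expect_s3_class(bin, "eeg_binary")
  expect_identical(bin$labels, as.integer(ds$labels == 1L))
  expect_identical(bin$features, ds$features)   # features untouched
  expect_equal(sum(bin$labels), 4L)             # one class of five positive
  # row order preserved
  expect_equal(which(bin$labels == 1L), which(ds$labels == 1L))
  # double application rejected
  expect_error(relabel_binary(bin), "already binary")
  # out-of-range labels rejected at construction
  expect_error(eeg_dataset(x, rep(7L, 20L)), "labels")
})

test_that("rescaler centers and scales to unit population variance", {
  # two-point column maps to -1, +1 (population sd = 1)
  r <- fit_rescaler(matrix(c(1, 3, 10, 30), 2L, 2L))
  expect_equal(apply_rescaler(r, matrix(c(1, 3, 10, 30), 2L, 2L)),
               matrix(c(-1, 1, -1, 1), 2L, 2L))

  set.seed(4L)
  x <- matrix(rnorm(50 * 6, mean = 3, sd = 7), 50L, 6L)
  r <- fit_rescaler(x)
  z <- apply_rescaler(r, x)
  expect_lt(max(abs(colMeans(z))), 1e-9)
  expect_lt(max(abs(colMeans(z^2) - 1)), 1e-9)

  # frozen parameters applied unchanged to new data
  x_new <- matrix(rnorm(10 * 6), 10L, 6L)
  expect_equal(apply_rescaler(r, x_new),
               sweep(sweep(x_new, 2L, r$center), 2L, r$scale, `/`))

  # applying twice is not idempotent (affine map with nonzero center)
  expect_false(isTRUE(all.equal(apply_rescaler(r, apply_rescaler(r, x)),
                                apply_rescaler(r, x))))
})

test_that("zero-variance columns are dropped by default or raise on request", {
  x <- cbind(a = c(5, 5, 5), b = c(1, 2, 3))
  expect_warning(r <- fit_rescaler(x), "zero-variance")
  expect_equal(r$keep, 2L)
  expect_equal(ncol(apply_rescaler(r, x)), 1L)
  expect_error(fit_rescaler(x, zero_variance = "error"), "zero-variance")
})

test_that("rescaler serializes to text and restores exactly", {
  set.seed(8L)
  r <- fit_rescaler(matrix(rnorm(40), 10L, 4L))
  p <- tempfile(fileext = ".txt")
  write_rescaler(r, p)
  r2 <- read_rescaler(p)
  expect_identical(r2$center, unname(r$center))
  expect_identical(r2$scale, unname(r$scale))
  expect_identical(r2$keep, r$keep)
})

test_that("splits have the protocol sizes and are disjoint, exhaustive, seeded", {
  x <- matrix(rnorm(1000 * 3), 1000L, 3L)
  ds <- binary_view(x, rep_len(c(1L, 0L, 0L, 0L, 0L), 1000L))
  sp <- split_dataset(ds, 0.8, seed = 5L)
  expect_equal(n_chunks(sp$train), 800L)
  expect_equal(n_chunks(sp$validation), 100L)
  expect_equal(n_chunks(sp$test), 100L)

  for (seed in 1:5) {
    sp <- split_dataset(ds, 0.7, seed = seed)
    idx <- c(sp$indices$train, sp$indices$validation, sp$indices$test)
    expect_equal(sort(idx), 1:1000)          # exhaustive
    expect_equal(anyDuplicated(idx), 0L)     # disjoint
    sp2 <- split_dataset(ds, 0.7, seed = seed)
    expect_identical(sp$indices, sp2$indices)  # reproducible
    # stratification keeps prevalence within rounding of the global 0.2
    expect_lte(abs(mean(sp$test$labels) - 0.2), 1 / n_chunks(sp$test))
  }

  # different seeds give different partitions
  expect_false(identical(split_dataset(ds, 0.8, seed = 1L)$indices,
                         split_dataset(ds, 0.8, seed = 2L)$indices))

  expect_error(split_dataset(ds, 1.0), "strictly between")
  expect_error(split_dataset(ds, 0), "strictly between")
  expect_error(split_dataset(binary_view(x[1:8, ], rep(0:1, 4L)), 0.8),
               "at least 10")
})

test_that("plain two-way split and training balancing behave as documented", {
  ds <- binary_view(matrix(rnorm(200 * 2), 200L, 2L),
                    rep_len(c(1L, 0L, 0L, 0L), 200L))
  sp <- split_dataset(ds, 0.6, halve_holdout = FALSE, seed = 3L)
  expect_null(sp$validation)
  expect_equal(n_chunks(sp$train), 120L)
  expect_equal(n_chunks(sp$test), 80L)

  spb <- split_dataset(ds, 0.8, seed = 3L, balance_train = TRUE)
  expect_equal(mean(spb$train$labels), 0.5)
})

test_that("split export writes all partitions with a split column", {
  ds <- binary_view(matrix(rnorm(60 * 2), 60L, 2L), rep_len(0:1, 60L))
  sp <- split_dataset(ds, 0.8, seed = 2L)
  p <- tempfile(fileext = ".csv")
  write_split_csv(sp, p)
  df <- utils::read.csv(p)
  expect_equal(nrow(df), 60L)
  expect_setequal(unique(df$split), c("train", "validation", "test"))
  expect_equal(sum(df$split == "train"), 48L)
})
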