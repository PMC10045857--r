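# Reading, relabeling, rescaling and splitting the tabular EEG chunk data.
#
# The canonical dialect is the one used by the UCI "Epileptic Seizure
# Recognition" export of the Bonn recordings: one row per one-second chunk,
# feature columns X1..X178 holding integer EEG amplitudes, and a label
# column y in {1..5} where 1 marks an ictal (seizure) chunk and 2-5 mark
# the four non-seizure conditions.

#' Construct a labeled EEG chunk dataset
#'
#' A light S3 container for a feature matrix of EEG chunk amplitudes plus a
#' per-row class label. Labels are the five-condition coding (1 = ictal,
#' 2 = pre-ictal, 3 = inter-ictal, 4 = healthy eyes closed, 5 = healthy eyes
#' open); use [relabel_binary()] to collapse to seizure vs non-seizure.
#'
#' @param features numeric matrix, one row per chunk, one column per sample
#'   within the chunk (178 in the canonical dialect).
#' @param labels integer vector of per-row class labels in `{1..5}`.
#' @param row_ids optional character vector of opaque row identifiers.
#' @return an object of class `eeg_dataset` with elements `features`,
#'   `labels`, `row_ids`.
#' @seealso [read_eeg_csv()], [relabel_binary()], [split_dataset()]
#' @export
eeg_dataset <- function(features, labels, row_ids = NULL) {
  features <- as.matrix(features)
  if (!is.numeric(features)) stop("`features` must be numeric", call. = FALSE)
  if (ncol(features) < 1L) stop("`features` needs at least one column", call. = FALSE)
  if (anyNA(features)) stop("`features` must not contain missing values", call. = FALSE)
  labels <- as.integer(labels)
  if (length(labels) != nrow(features)) {
    stop("`labels` length must equal the number of feature rows", call. = FALSE)
  }
  if (anyNA(labels) || !all(labels %in% 1:5)) {
    stop("all labels must lie in {1, 2, 3, 4, 5}", call. = FALSE)
  }
  if (!is.null(row_ids)) {
    row_ids <- as.character(row_ids)
    if (length(row_ids) != nrow(features)) {
      stop("`row_ids` length must equal the number of rows", call. = FALSE)
    }
  }
  structure(list(features = features, labels = labels, row_ids = row_ids),
            class = "eeg_dataset")
}

#' @export
print.eeg_dataset <- function(x, ...) {
  cat(sprintf("<%s> %d chunks x %d samples\n",
              class(x)[1L], nrow(x$features), ncol(x$features)))
  tab <- table(x$labels)
  cat("labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Number of rows / columns of an EEG dataset
#' @param ds an `eeg_dataset`.
#' @return integer count.
#' @export
n_chunks <- function(ds) nrow(ds$features)

# Row subset preserving class and ids.
ds_subset <- function(ds, idx) {
  out <- ds
  out$features <- ds$features[idx, , drop = FALSE]
  out$labels <- ds$labels[idx]
  if (!is.null(ds$row_ids)) out$row_ids <- ds$row_ids[idx]
  out
}

#' Read an EEG chunk table from CSV
#'
#' Reads the comma-separated dialect with a header row, feature columns (all
#' columns except the label column) and a label column named `y` (the column
#' written as `X179` in some exports is also accepted when named `y`). An
#' unnamed leading identifier column (row ids such as `"X21.V1.791"`) is
#' auto-detected and kept as `row_ids`.
#'
#' @param path path to a CSV file.
#' @param label_col name of the label column (default `"y"`).
#' @return an [eeg_dataset()].
#' @export
read_eeg_csv <- function(path, label_col = "y") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty dataset file", call. = FALSE)
  nm <- names(df)
  id <- NULL
  # auto-detect an unnamed / placeholder leading id column
  if (ncol(df) >= 2L && (nm[1L] == "" || nm[1L] == "X" || nm[1L] == "id" ||
                         (!is.numeric(df[[1L]]) && nm[1L] != label_col))) {
    id <- as.character(df[[1L]])
    df <- df[, -1L, drop = FALSE]
    nm <- names(df)
  }
  if (!label_col %in% nm) {
    stop(sprintf("format error: label column '%s' not found", label_col), call. = FALSE)
  }
  feat_cols <- setdiff(nm, label_col)
  if (length(feat_cols) < 1L) stop("format error: no feature columns", call. = FALSE)
  for (cn in feat_cols) {
    if (!is.numeric(df[[cn]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[cn]]))))[1L]
      stop(sprintf("parse error: non-numeric value in column '%s' (row %d)",
                   cn, if (is.na(bad)) 1L else bad), call. = FALSE)
    }
  }
  features <- as.matrix(df[, feat_cols, drop = FALSE])
  if (anyNA(features)) {
    bad <- which(rowSums(is.na(features)) > 0L)[1L]
    stop(sprintf("parse error: missing value in row %d", bad), call. = FALSE)
  }
  eeg_dataset(features, df[[label_col]], row_ids = id)
}

#' Write an EEG chunk table to CSV
#'
#' Inverse of [read_eeg_csv()]: writes the feature columns in order followed
#' by the label column. Integer-valued features round-trip exactly.
#'
#' @param ds an `eeg_dataset` (five-class or binary).
#' @param path output file path.
#' @param label_col label column name.
#' @param split optional character vector (length `n`) written as an extra
#'   `split` column, used when exporting train/validation/test partitions.
#' @return `path`, invisibly.
#' @export
write_eeg_csv <- function(ds, path, label_col = "y", split = NULL) {
  df <- as.data.frame(ds$features, check.names = FALSE)
  df[[label_col]] <- ds$labels
  if (!is.null(split)) df[["split"]] <- split
  if (!is.null(ds$row_ids)) {
    ids <- stats::setNames(data.frame(ds$row_ids, stringsAsFactors = FALSE), "")
    df <- cbind(ids, df)
    names(df)[1L] <- ""
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Collapse the five-condition labels to seizure vs non-seizure
#'
#' Maps the ictal class (label 1) to `1` ("recorded seizure") and every other
#' condition (labels 2-5) to `0` ("no recorded seizure"), leaving features
#' untouched. Applying it to an already-binary dataset is an error: the
#' five-class coding would be silently misread otherwise (class 1 means
#' "ictal" there but "seizure present" here).
#'
#' @param ds an `eeg_dataset` with labels in `{1..5}`.
#' @return an object of class `c("eeg_binary", "eeg_dataset")` whose
#'   `labels` are 0/1.
#' @export
relabel_binary <- function(ds) {
  if (inherits(ds, "eeg_binary")) {
    stop("dataset labels are already binary", call. = FALSE)
  }
  if (!all(ds$labels %in% 1:5)) {
    stop("labels must lie in {1..5} before binarization", call. = FALSE)
  }
  out <- ds
  out$labels <- as.integer(ds$labels == 1L)
  class(out) <- c("eeg_binary", "eeg_dataset")
  out
}

# Internal constructor for binary datasets produced by generators.
new_eeg_binary <- function(features, labels, row_ids = NULL) {
  features <- as.matrix(features)
  labels <- as.integer(labels)
  stopifnot(length(labels) == nrow(features), all(labels %in% 0:1))
  structure(list(features = features, labels = labels, row_ids = row_ids),
            class = c("eeg_binary", "eeg_dataset"))
}

#' Fit a per-column unit-variance rescaler
#'
#' Centers each column at its mean and scales to unit *population* variance
#' (divide by `n`, not `n - 1`), so a two-point column maps exactly to
#' `c(-1, +1)`. Fit this on the training partition only and apply the frozen
#' parameters to validation and test data to avoid leakage.
#'
#' @param x numeric matrix of training features (>= 2 rows).
#' @param zero_variance what to do with constant columns: `"drop"` (default,
#'   with a warning) or `"error"`.
#' @param variance `"population"` (default) or `"sample"` denominator.
#' @return an object of class `eeg_rescaler` with `center`, `scale`, `keep`
#'   (retained column indices) and the policy used.
#' @export
fit_rescaler <- function(x, zero_variance = c("drop", "error"),
                         variance = c("population", "sample")) {
  zero_variance <- match.arg(zero_variance)
  variance <- match.arg(variance)
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 rows to fit a rescaler", call. = FALSE)
  ctr <- colMeans(x)
  dev <- sweep(x, 2L, ctr)
  denom <- if (variance == "population") nrow(x) else nrow(x) - 1L
  scl <- sqrt(colSums(dev^2) / denom)
  tol <- .Machine$double.eps^0.5 * max(1, max(abs(x)))
  const <- scl <= tol
  if (any(const)) {
    if (zero_variance == "error") {
      stop(sprintf("%d zero-variance column(s); refusing to rescale", sum(const)),
           call. = FALSE)
    }
    warning(sprintf("dropping %d zero-variance column(s)", sum(const)),
            call. = FALSE)
  }
  keep <- unname(which(!const))
  structure(list(center = ctr[keep], scale = scl[keep], keep = keep,
                 n_input = ncol(x), zero_variance = zero_variance,
                 variance = variance),
            class = "eeg_rescaler")
}

#' Apply a fitted rescaler
#'
#' @param r an `eeg_rescaler` from [fit_rescaler()].
#' @param x numeric matrix with the same number of columns the rescaler was
#'   fitted on.
#' @return the rescaled matrix (dropped columns removed).
#' @export
apply_rescaler <- function(r, x) {
  stopifnot(inherits(r, "eeg_rescaler"))
  x <- as.matrix(x)
  if (ncol(x) != r$n_input) {
    stop(sprintf("rescaler was fitted on %d columns, got %d", r$n_input, ncol(x)),
         call. = FALSE)
  }
  x <- x[, r$keep, drop = FALSE]
  sweep(sweep(x, 2L, r$center), 2L, r$scale, `/`)
}

#' @export
print.eeg_rescaler <- function(x, ...) {
  cat(sprintf("<eeg_rescaler> %d/%d columns retained (%s variance)\n",
              length(x$keep), x$n_input, x$variance))
  invisible(x)
}

#' Serialize / restore a rescaler as a key-value text document
#'
#' @param r an `eeg_rescaler`.
#' @param path output text file.
#' @return `path` invisibly; `read_rescaler` returns the restored object.
#' @export
write_rescaler <- function(r, path) {
  stopifnot(inherits(r, "eeg_rescaler"))
  num <- function(v) paste(sprintf("%.17g", v), collapse = ",")
  lines <- c(
    sprintf("n_input: %d", r$n_input),
    sprintf("variance: %s", r$variance),
    sprintf("zero_variance: %s", r$zero_variance),
    sprintf("keep: %s", paste(r$keep, collapse = ",")),
    sprintf("center: %s", num(r$center)),
    sprintf("scale: %s", num(r$scale)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_rescaler
#' @export
read_rescaler <- function(path) {
  kv <- read_kv_file(path)
  structure(list(
    center = as.numeric(strsplit(kv[["center"]], ",")[[1L]]),
    scale = as.numeric(strsplit(kv[["scale"]], ",")[[1L]]),
    keep = as.integer(strsplit(kv[["keep"]], ",")[[1L]]),
    n_input = as.integer(kv[["n_input"]]),
    zero_variance = kv[["zero_variance"]],
    variance = kv[["variance"]]), class = "eeg_rescaler")
}

read_kv_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  pos <- regexpr(": ", lines, fixed = TRUE)
  keys <- substr(lines, 1L, pos - 1L)
  vals <- substr(lines, pos + 2L, nchar(lines))
  stats::setNames(as.list(vals), keys)
}

#' Split a dataset into train / validation / test partitions
#'
#' Implements the holdout protocols used in the canonical experiments:
#' `train_frac` of the rows (rounded) go to training and the remainder is,
#' by default, halved into equally sized validation and test partitions, so
#' the 80/20 protocol on 11,500 rows yields 9200 / 1150 / 1150 rows.
#' Splitting is stratified on the class label by default, keeping each
#' partition's prevalence within rounding of the full data's.
#'
#' @param ds an `eeg_dataset` or `eeg_binary`.
#' @param train_frac fraction of rows assigned to training, in (0, 1).
#' @param halve_holdout if `TRUE` (default) the holdout is divided equally
#'   into validation and test; if `FALSE`, all holdout rows form the test set
#'   and `validation` is `NULL`.
#' @param stratified sample within label classes (default `TRUE`).
#' @param seed integer seed; identical seeds give identical partitions.
#' @param balance_train optionally duplicate minority-class training rows
#'   until the training partition is 50/50 (off by default; only meaningful
#'   for binary labels).
#' @return object of class `eeg_split`: list with `train`, `validation`,
#'   `test` datasets and an `indices` list of the original row indices.
#' @export
split_dataset <- function(ds, train_frac = 0.8, halve_holdout = TRUE,
                          stratified = TRUE, seed = 1L,
                          balance_train = FALSE) {
  stopifnot_scalar_number(train_frac, "train_frac")
  if (train_frac <= 0 || train_frac >= 1) {
    stop("`train_frac` must lie strictly between 0 and 1", call. = FALSE)
  }
  n <- n_chunks(ds)
  if (n < 10L) stop("need at least 10 rows to split", call. = FALSE)

  idx <- with_local_seed(seed, {
    if (stratified) {
      split_indices_stratified(ds$labels, train_frac, halve_holdout)
    } else {
      split_indices_simple(n, train_frac, halve_holdout)
    }
  })
  required <- if (halve_holdout) c("train", "validation", "test") else
    c("train", "test")
  sizes <- vapply(idx[required], length, integer(1L))
  if (any(sizes == 0L)) {
    stop("a partition received zero rows; adjust `train_frac`", call. = FALSE)
  }
  train <- ds_subset(ds, idx$train)
  if (balance_train) {
    train <- with_local_seed(derive_seed(seed, 77L), balance_binary(train))
  }
  out <- list(
    train = train,
    validation = if (halve_holdout) ds_subset(ds, idx$validation) else NULL,
    test = ds_subset(ds, idx$test),
    indices = idx,
    train_frac = train_frac, halve_holdout = halve_holdout,
    stratified = stratified, seed = as.integer(seed))
  class(out) <- "eeg_split"
  out
}

split_indices_simple <- function(n, train_frac, halve_holdout) {
  n_train <- round(train_frac * n)
  perm <- sample.int(n)
  train <- perm[seq_len(n_train)]
  hold <- perm[-seq_len(n_train)]
  if (!halve_holdout) {
    return(list(train = sort(train), validation = NULL, test = sort(hold)))
  }
  n_val <- floor(length(hold) / 2)
  list(train = sort(train), validation = sort(hold[seq_len(n_val)]),
       test = sort(hold[-seq_len(n_val)]))
}

split_indices_stratified <- function(labels, train_frac, halve_holdout) {
  classes <- sort(unique(labels))
  train <- integer(0L); val <- integer(0L); test <- integer(0L)
  # largest-remainder correction keeps the global training size at
  # round(train_frac * n) while staying proportional per class
  n <- length(labels)
  n_train_target <- round(train_frac * n)
  exact <- vapply(classes, function(cl) train_frac * sum(labels == cl), numeric(1L))
  n_tr <- floor(exact)
  rem <- n_train_target - sum(n_tr)
  if (rem > 0L) {
    bump <- order(exact - n_tr, decreasing = TRUE)[seq_len(rem)]
    n_tr[bump] <- n_tr[bump] + 1L
  }
  for (ci in seq_along(classes)) {
    rows <- which(labels == classes[ci])
    rows <- rows[sample.int(length(rows))]
    k <- n_tr[ci]
    train <- c(train, rows[seq_len(k)])
    hold <- rows[-seq_len(k)]
    if (halve_holdout) {
      nv <- round(length(hold) / 2)
      val <- c(val, hold[seq_len(nv)])
      test <- c(test, hold[-seq_len(nv)])
    } else {
      test <- c(test, hold)
    }
  }
  list(train = sort(train),
       validation = if (halve_holdout) sort(val) else NULL,
       test = sort(test))
}

# Duplicate minority-class rows until classes are balanced (binary only).
balance_binary <- function(ds) {
  if (!all(ds$labels %in% 0:1)) {
    stop("`balance_train` requires binary labels", call. = FALSE)
  }
  tab <- table(factor(ds$labels, levels = 0:1))
  if (tab[1L] == tab[2L]) return(ds)
  minority <- as.integer(names(which.min(tab)))
  need <- abs(diff(as.integer(tab)))
  pool <- which(ds$labels == minority)
  extra <- pool[sample.int(length(pool), need, replace = TRUE)]
  ds_subset(ds, c(seq_len(n_chunks(ds)), extra))
}

#' @export
print.eeg_split <- function(x, ...) {
  cat(sprintf("<eeg_split> train=%d validation=%s test=%d (train_frac=%g%s)\n",
              n_chunks(x$train),
              if (is.null(x$validation)) "-" else n_chunks(x$validation),
              n_chunks(x$test), x$train_frac,
              if (x$stratified) ", stratified" else ""))
  invisible(x)
}

#' Export split partitions as a single CSV
#'
#' Writes all partitions into one file in the input dialect plus a `split`
#' column (`train` / `validation` / `test`).
#'
#' @param sp an `eeg_split`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_split_csv <- function(sp, path) {
  stopifnot(inherits(sp, "eeg_split"))
  parts <- Filter(Negate(is.null), sp[c("train", "validation", "test")])
  feats <- do.call(rbind, lapply(parts, function(d) d$features))
  labs <- unlist(lapply(parts, function(d) d$labels), use.names = FALSE)
  ids <- if (!is.null(parts[[1L]]$row_ids)) {
    unlist(lapply(parts, function(d) d$row_ids), use.names = FALSE)
  }
  ds <- if (all(labs %in% 0:1)) new_eeg_binary(feats, labs, ids) else
    eeg_dataset(feats, labs, ids)
  split_col <- rep(names(parts), vapply(parts, n_chunks, integer(1L)))
  write_eeg_csv(ds, path, split = split_col)
}
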