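# Shared fixtures, all built in code at test time.

# Minimal well-formed chunk-table CSV: n rows, m feature columns X1..Xm and
# a label column y; returns the path.
write_tiny_csv <- function(n = 2L, m = 178L, labels = NULL,
                           path = tempfile(fileext = ".csv")) {
  set.seed(99L)
  x <- matrix(sample(-50:50, n * m, replace = TRUE), n, m)
  colnames(x) <- paste0("X", seq_len(m))
  df <- as.data.frame(x)
  df$y <- if (is.null(labels)) rep_len(1:5, n) else labels
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# Wrap bare features/labels as the binary dataset view the high-level
# helpers expect.
binary_view <- function(features, labels) {
  structure(list(features = features, labels = as.integer(labels),
                 row_ids = NULL),
            class = c("eeg_binary", "eeg_dataset"))
}

# Small trained binary ELM on separable data.
tiny_trained_elm <- function(n = 60L, m = 5L, L = 10L, seed = 1L,
                             margin = 6) {
  ds <- generate_separable(n, m, margin, seed = seed)
  fit <- elm_train(ds$features, ds$labels, elm_config(L, seed = seed + 1L))
  list(model = fit, data = ds)
}

# Hand-built ELM with fully specified weights (bypasses the random draw) so
# scores are analytically known.
manual_elm <- function(W, b, beta, encoding = "binary",
                       classes = c(0L, 1L)) {
  structure(list(W = W, b = b, beta = beta, n_features = ncol(W),
                 encoding = encoding, classes = classes,
                 config = elm_config(nrow(W)), rescaler = NULL),
            class = "elm")
}

# Brute-force O(P*N) Mann-Whitney AUC with half-credit for ties; the
# independent oracle for the trapezoidal estimate.
auc_pairs_bruteforce <- function(y, s) {
  pos <- s[y == 1L]
  neg <- s[y == 0L]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}
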