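# Connection-weight feature selection for a trained ELM.
#
# The idea: although the input weights W are random, the learned output
# weights beta encode which hidden neurons matter, and back-projecting beta
# through the squashed input weights recovers, to first order, the learned
# discriminant direction in input space. Concretely, for input feature i and
# output node k the significance coefficient aggregates over hidden nodes j:
#
#   C[i, k] = sum_j beta[j, k] * (1 - exp(-W[j, i])) / (1 + exp(-W[j, i]))
#           = sum_j beta[j, k] * tanh(W[j, i] / 2)
#
# which is then squashed to a magnitude R = |tanh(C / 2)|, normalized per
# output node into influence shares S (each column sums to 1), and averaged
# over output nodes into a single weight per feature. Features with high
# weight are retained; low-weight features are discarded.

# (1 - e^{-x}) / (1 + e^{-x}) == tanh(x / 2); the tanh form is the
# numerically stable one and is used throughout.
squash_half_tanh <- function(x) tanh(x / 2)

#' Significance coefficients of input features
#'
#' For each (input feature i, output node k) pair, sums
#' `beta[j, k] * tanh(W[j, i] / 2)` over the hidden nodes j of a trained
#' ELM.
#'
#' @param model a trained [elm_init()]/[elm_fit()] model.
#' @return an m x K matrix `C` of signed significance coefficients.
#' @export
significance_matrix <- function(model) {
  stopifnot(inherits(model, "elm"))
  if (is.null(model$beta)) stop("model is not trained; call elm_fit()", call. = FALSE)
  # t(W) is m x L; squash entrywise, then contract over hidden nodes
  squash_half_tanh(t(model$W)) %*% model$beta
}

#' Index correlation (squashed significance magnitude)
#'
#' Maps signed significance coefficients to magnitudes in `[0, 1)`:
#' `R = |tanh(C / 2)|`. Symmetric in the sign of `C`, monotone in `|C|`.
#'
#' @param C significance matrix from [significance_matrix()].
#' @return matrix `R` of the same shape with entries in `[0, 1)`.
#' @export
index_correlation <- function(C) {
  if (!all(is.finite(C))) stop("`C` must be finite", call. = FALSE)
  abs(squash_half_tanh(C))
}

#' Absolute influence shares
#'
#' Normalizes each output node's column of `R` to sum to one, giving each
#' feature's share of that node's total (squashed) significance.
#'
#' @param R index-correlation matrix from [index_correlation()].
#' @return matrix `S` with non-negative entries; every column sums to 1.
#' @export
absolute_influence <- function(R) {
  R <- as.matrix(R)
  tot <- colSums(R)
  if (any(tot <= 0)) {
    stop("a column of R sums to zero: no informative features for that output",
         call. = FALSE)
  }
  sweep(R, 2L, tot, `/`)
}

#' Per-feature weights
#'
#' Averages each feature's influence share over the K output nodes, giving a
#' single weight per feature that sums to 1 across features. For a binary
#' (single-output) model this is just the `S` column itself.
#'
#' `printed_form = TRUE` instead averages each *column* of `S` over
#' features, which returns the constant `1/m` for every output node; it is
#' exposed only so the uninformative variant can be audited, and is never
#' used for selection.
#'
#' @param S influence matrix from [absolute_influence()].
#' @param printed_form return the degenerate feature-averaged variant.
#' @return numeric weight vector of length m (or K when `printed_form`).
#' @export
feature_weights <- function(S, printed_form = FALSE) {
  S <- as.matrix(S)
  if (printed_form) return(colSums(S) / nrow(S))
  rowMeans(S)
}

#' Select high-weight features
#'
#' `"threshold-mean"` (default, parameter-free) keeps every feature whose
#' weight is at least the mean weight; `"top-k"` keeps the `k` largest
#' (ties broken toward the lower feature index). Either way the selection is
#' returned in descending-weight order.
#'
#' @param w_feat per-feature weight vector from [feature_weights()].
#' @param policy `"threshold-mean"` or `"top-k"`.
#' @param k number of features for `"top-k"`.
#' @return integer vector of selected feature indices, highest weight first.
#' @export
select_features <- function(w_feat, policy = c("threshold-mean", "top-k"),
                            k = NULL) {
  policy <- match.arg(policy)
  if (!all(is.finite(w_feat))) stop("`w_feat` must be finite", call. = FALSE)
  m <- length(w_feat)
  ord <- order(-w_feat, seq_len(m))   # descending weight, ties by low index
  if (policy == "top-k") {
    if (is.null(k) || k < 1L || k > m) {
      stop("`k` must lie in [1, length(w_feat)] for the top-k policy",
           call. = FALSE)
    }
    ord[seq_len(as.integer(k))]
  } else {
    ord[w_feat[ord] >= mean(w_feat)]
  }
}

#' Run the full connection-weight selection pipeline
#'
#' Computes `C`, `R`, `S` and the per-feature weights from a trained ELM and
#' applies the selection policy.
#'
#' @param model a trained `elm`.
#' @param policy,k see [select_features()].
#' @return an object of class `elm_fs` with fields `C`, `R`, `S`, `w_feat`,
#'   `selected`, `policy`.
#' @export
elm_feature_selection <- function(model, policy = c("threshold-mean", "top-k"),
                                  k = NULL) {
  policy <- match.arg(policy)
  C <- significance_matrix(model)
  R <- index_correlation(C)
  S <- absolute_influence(R)
  w <- feature_weights(S)
  structure(list(C = C, R = R, S = S, w_feat = w,
                 selected = select_features(w, policy, k), policy = policy),
            class = "elm_fs")
}

#' @export
print.elm_fs <- function(x, ...) {
  cat(sprintf("<elm_fs> %d of %d features selected (%s policy)\n",
              length(x$selected), length(x$w_feat), x$policy))
  invisible(x)
}

#' Export a ranked feature table
#'
#' Writes one row per feature, ranked by weight, as tab-separated text:
#' feature index, name, significance `C`, index correlation `R`, influence
#' `S` (first output column of each), the feature weight, and a 0/1 selected
#' flag.
#'
#' @param fs an `elm_fs`.
#' @param path output TSV path.
#' @param feature_names optional feature names (default `X1..Xm`).
#' @return the table (a data frame), invisibly; written to `path`.
#' @export
write_fs_table <- function(fs, path, feature_names = NULL) {
  stopifnot(inherits(fs, "elm_fs"))
  m <- length(fs$w_feat)
  if (is.null(feature_names)) feature_names <- paste0("X", seq_len(m))
  ord <- order(-fs$w_feat, seq_len(m))
  tab <- data.frame(feature = ord, name = feature_names[ord],
                    C = fs$C[ord, 1L], R = fs$R[ord, 1L], S = fs$S[ord, 1L],
                    weight = fs$w_feat[ord],
                    selected = as.integer(ord %in% fs$selected))
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(tab)
}
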