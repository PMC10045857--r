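# Extreme Learning Machine: a single-hidden-layer feedforward network whose
# input weights W and biases b are drawn once at random and frozen, and whose
# output weights beta are solved analytically as the minimum-norm
# least-squares solution beta = H^+ Y, with H the sigmoid hidden-layer
# output matrix and H^+ its Moore-Penrose pseudoinverse. No backpropagation,
# no iterations: training is one linear solve.

#' ELM configuration
#'
#' @param n_hidden number of hidden neurons `L` (>= 1).
#' @param activation hidden activation; only `"sigmoid"` is provided (it is
#'   the reference choice for this architecture).
#' @param input_weight_range range of the uniform draw for the input weights
#'   `W` (default `[-1, 1]`).
#' @param bias_range range of the uniform draw for the hidden biases `b`
#'   (default `[0, 1]`).
#' @param seed integer seed controlling `W` and `b`.
#' @param pinv_rtol relative singular-value cutoff for the pseudoinverse;
#'   `NULL` (default) uses `max(n, L) * .Machine$double.eps`, the standard
#'   numerical-rank tolerance.
#' @param ridge optional Tikhonov term added to the normal equations; `0`
#'   (default) means the pure pseudoinverse solution.
#' @return a list of class `elm_config`.
#' @export
elm_config <- function(n_hidden, activation = "sigmoid",
                       input_weight_range = c(-1, 1), bias_range = c(0, 1),
                       seed = 1L, pinv_rtol = NULL, ridge = 0) {
  if (!is.numeric(n_hidden) || length(n_hidden) != 1L || n_hidden < 1) {
    stop("`n_hidden` must be a positive integer", call. = FALSE)
  }
  activation <- match.arg(activation, "sigmoid")
  stopifnot(length(input_weight_range) == 2L,
            input_weight_range[1L] < input_weight_range[2L],
            length(bias_range) == 2L, bias_range[1L] < bias_range[2L],
            is.null(pinv_rtol) || pinv_rtol >= 0, ridge >= 0)
  structure(list(n_hidden = as.integer(n_hidden), activation = activation,
                 input_weight_range = input_weight_range,
                 bias_range = bias_range, seed = as.integer(seed),
                 pinv_rtol = pinv_rtol, ridge = ridge),
            class = "elm_config")
}

#' Initialize the frozen random hidden layer
#'
#' Draws `W` (L x m) uniformly from `input_weight_range` and `b` (length L)
#' uniformly from `bias_range`; both remain frozen for the life of the
#' model. Output weights `beta` are `NULL` until [elm_fit()] is called.
#'
#' @param cfg an [elm_config()].
#' @param n_features number of input features `m`.
#' @param encoding target encoding: `"binary"` (one output column trained on
#'   0/1 targets, thresholded at 0.5) or `"onehot"` (one column per class,
#'   argmax decision).
#' @param classes for `"onehot"`, the class labels in column order; for
#'   `"binary"` ignored.
#' @return an untrained object of class `elm`.
#' @export
elm_init <- function(cfg, n_features, encoding = c("binary", "onehot"),
                     classes = NULL) {
  stopifnot(inherits(cfg, "elm_config"), n_features >= 1L)
  encoding <- match.arg(encoding)
  L <- cfg$n_hidden
  wb <- with_local_seed(cfg$seed, {
    list(W = matrix(stats::runif(L * n_features, cfg$input_weight_range[1L],
                                 cfg$input_weight_range[2L]),
                    nrow = L, ncol = n_features),
         b = stats::runif(L, cfg$bias_range[1L], cfg$bias_range[2L]))
  })
  structure(list(W = wb$W, b = wb$b, beta = NULL,
                 n_features = as.integer(n_features),
                 encoding = encoding,
                 classes = if (encoding == "onehot") classes else c(0L, 1L),
                 config = cfg, rescaler = NULL),
            class = "elm")
}

#' Hidden-layer activation matrix
#'
#' Computes `H[r, j] = sigmoid(w_j . x_r + b_j)` for every row of `X`; each
#' entry lies in (0, 1) and increases monotonically in the pre-activation.
#'
#' @param model an `elm`.
#' @param X numeric matrix with `model$n_features` columns.
#' @return the n x L activation matrix `H`.
#' @export
hidden_activations <- function(model, X) {
  stopifnot(inherits(model, "elm"))
  X <- as.matrix(X)
  if (ncol(X) != model$n_features) {
    stop(sprintf("X has %d columns; model expects %d", ncol(X),
                 model$n_features), call. = FALSE)
  }
  Z <- X %*% t(model$W)
  Z <- sweep(Z, 2L, model$b, `+`)
  sigmoid(Z)
}

# Minimum-norm least-squares solve beta = H^+ Y via SVD with a relative
# singular-value cutoff; optionally ridge-regularized normal equations.
pinv_solve <- function(H, Y, rtol = NULL, ridge = 0) {
  if (ridge > 0) {
    L <- ncol(H)
    return(solve(crossprod(H) + diag(ridge, L), crossprod(H, Y)))
  }
  sv <- svd(H)
  if (is.null(rtol)) rtol <- max(dim(H)) * .Machine$double.eps
  keep <- sv$d > rtol * sv$d[1L]
  if (!any(keep)) return(matrix(0, ncol(H), ncol(Y)))
  U <- sv$u[, keep, drop = FALSE]
  V <- sv$v[, keep, drop = FALSE]
  V %*% ((t(U) %*% Y) / sv$d[keep])
}

encode_targets <- function(y, encoding, classes) {
  if (encoding == "binary") {
    if (!all(y %in% 0:1)) {
      stop("binary encoding requires 0/1 labels; use relabel_binary()",
           call. = FALSE)
    }
    matrix(as.numeric(y), ncol = 1L)
  } else {
    if (is.null(classes)) classes <- sort(unique(y))
    Y <- matrix(0, length(y), length(classes))
    Y[cbind(seq_along(y), match(y, classes))] <- 1
    attr(Y, "classes") <- classes
    Y
  }
}

#' Train the output weights analytically
#'
#' Solves `min || H beta - Y ||` for the minimum-norm solution
#' `beta = H^+ Y`, where `H` is the hidden activation matrix of the training
#' rows and `Y` the encoded targets. This is the entire training procedure:
#' `W` and `b` are never touched.
#'
#' @param model an `elm` from [elm_init()].
#' @param X training feature matrix.
#' @param y training labels (0/1 for `"binary"` encoding; any discrete
#'   labels for `"onehot"`).
#' @return the trained `elm` (with `beta` set).
#' @export
elm_fit <- function(model, X, y) {
  stopifnot(inherits(model, "elm"))
  X <- as.matrix(X)
  if (nrow(X) == 0L) stop("empty training set", call. = FALSE)
  if (nrow(X) != length(y)) {
    stop("X and y must have the same number of rows", call. = FALSE)
  }
  if (!all(is.finite(X))) stop("non-finite values in training features", call. = FALSE)
  H <- hidden_activations(model, X)
  Y <- encode_targets(y, model$encoding, model$classes)
  if (model$encoding == "onehot") model$classes <- attr(Y, "classes")
  model$beta <- pinv_solve(H, Y, rtol = model$config$pinv_rtol,
                           ridge = model$config$ridge)
  model
}

#' Convenience one-call trainer
#'
#' Initializes the hidden layer and fits the output weights in one step.
#'
#' @inheritParams elm_init
#' @inheritParams elm_fit
#' @return a trained `elm`.
#' @export
elm_train <- function(X, y, cfg, encoding = c("binary", "onehot")) {
  encoding <- match.arg(encoding)
  model <- elm_init(cfg, ncol(as.matrix(X)), encoding = encoding)
  elm_fit(model, X, y)
}

#' Raw decision scores
#'
#' Returns `H beta`, the network output `f(x) = sum_j beta_j sigmoid(w_j . x
#' + b_j)` for every row. In binary mode this is the single real-valued
#' score used both for thresholding and for ROC analysis.
#'
#' @param model a trained `elm`.
#' @param X feature matrix.
#' @return n x K numeric score matrix (K = 1 in binary mode).
#' @export
decision_scores <- function(model, X) {
  stopifnot(inherits(model, "elm"))
  if (is.null(model$beta)) stop("model is not trained; call elm_fit()", call. = FALSE)
  hidden_activations(model, X) %*% model$beta
}

#' Predict class labels
#'
#' Binary mode labels a row `1` iff its score is `>= threshold` (the
#' boundary score itself counts as positive); one-hot mode takes the argmax
#' over output columns, ties broken toward the lowest class index.
#'
#' @param object a trained `elm`.
#' @param X feature matrix.
#' @param threshold decision threshold for binary mode (default 0.5, the
#'   midpoint of the 0/1 targets).
#' @param type `"class"` (default) or `"score"`.
#' @param ... unused.
#' @return integer labels, or the score matrix when `type = "score"`.
#' @export
predict.elm <- function(object, X, threshold = 0.5, type = c("class", "score"),
                        ...) {
  type <- match.arg(type)
  stopifnot_scalar_number(threshold, "threshold")
  scores <- decision_scores(object, X)
  if (type == "score") return(scores)
  if (object$encoding == "binary") {
    as.integer(scores[, 1L] >= threshold)
  } else {
    object$classes[apply(scores, 1L, which.max)]
  }
}

#' @export
print.elm <- function(x, ...) {
  cat(sprintf("<elm> %d features -> %d sigmoid hidden neurons -> %s output (%s)\n",
              x$n_features, x$config$n_hidden,
              if (x$encoding == "binary") "1" else length(x$classes),
              if (is.null(x$beta)) "untrained" else "trained"))
  invisible(x)
}

#' Default hidden-layer size heuristic
#'
#' One hidden neuron per ten training rows, the ratio at which the
#' validation-selected sizes for the canonical 80/70/60% protocols land
#' (920, 805 and 690 neurons for 9200, 8050 and 6900 training rows).
#'
#' @param n_train number of training rows.
#' @return an integer hidden-layer size.
#' @export
default_n_hidden <- function(n_train) max(1L, as.integer(round(0.1 * n_train)))

#' Validation sweep over hidden-layer sizes
#'
#' Trains one ELM per candidate size `L` — each with a fresh random hidden
#' layer seeded deterministically from `(seed, L)` — and scores it on the
#' validation partition. Returns the full accuracy curve and the smallest
#' `L` attaining the maximum (the cheapest adequate model).
#'
#' @param train,validation `eeg_binary` datasets (already rescaled
#'   features).
#' @param grid integer vector of candidate hidden-layer sizes; `NULL`
#'   (default) sweeps 2%..20% of the training size in 2% steps, which
#'   always contains the [default_n_hidden()] anchor (920 for a 9200-row
#'   training set).
#' @param seed integer master seed.
#' @param threshold binary decision threshold.
#' @return list with `best_L`, `best_accuracy` and `curve` (a data frame of
#'   `L` and validation `accuracy`).
#' @export
sweep_hidden_neurons <- function(train, validation, grid = NULL, seed = 1L,
                                 threshold = 0.5) {
  n_train <- n_chunks(train)
  if (is.null(grid)) {
    grid <- unique(pmax(1L, as.integer(round(seq(0.02, 0.2, by = 0.02) *
                                               n_train))))
  }
  if (length(grid) == 0L) stop("`grid` must be non-empty", call. = FALSE)
  grid <- as.integer(grid)
  if (any(grid >= 10L * n_train)) {
    warning("some grid values exceed 10x the training size (overparameterized)",
            call. = FALSE)
  }
  acc <- vapply(grid, function(L) {
    cfg <- elm_config(L, seed = derive_seed(seed, L))
    fit <- elm_train(train$features, train$labels, cfg)
    mean(predict(fit, validation$features, threshold = threshold) ==
           validation$labels)
  }, numeric(1L))
  best <- grid[which.max(acc)]   # which.max -> first (smallest L) maximizer
  list(best_L = best, best_accuracy = max(acc),
       curve = data.frame(L = grid, accuracy = acc))
}

#' Serialize / restore a trained model as a text document
#'
#' Writes every model component (`W`, `b`, `beta`, dimensions, encoding,
#' seed, config, and the attached rescaler if any) with 17 significant
#' digits, which round-trips IEEE doubles bit-exactly.
#'
#' @param model a (possibly trained) `elm`.
#' @param path output file.
#' @return `path` invisibly; `read_elm()` returns the restored model.
#' @export
write_elm <- function(model, path) {
  stopifnot(inherits(model, "elm"))
  num <- function(v) paste(sprintf("%.17g", v), collapse = ",")
  cfg <- model$config
  lines <- c(
    sprintf("n_features: %d", model$n_features),
    sprintf("n_hidden: %d", cfg$n_hidden),
    sprintf("encoding: %s", model$encoding),
    sprintf("classes: %s", paste(model$classes, collapse = ",")),
    sprintf("seed: %d", cfg$seed),
    sprintf("input_weight_range: %s", num(cfg$input_weight_range)),
    sprintf("bias_range: %s", num(cfg$bias_range)),
    sprintf("pinv_rtol: %s", if (is.null(cfg$pinv_rtol)) "default" else
      sprintf("%.17g", cfg$pinv_rtol)),
    sprintf("ridge: %.17g", cfg$ridge),
    sprintf("W: %s", num(model$W)),
    sprintf("b: %s", num(model$b)),
    sprintf("beta: %s", if (is.null(model$beta)) "untrained" else
      num(model$beta)),
    sprintf("beta_ncol: %s", if (is.null(model$beta)) "0" else ncol(model$beta)))
  if (!is.null(model$rescaler)) {
    r <- model$rescaler
    lines <- c(lines,
               sprintf("rescaler_n_input: %d", r$n_input),
               sprintf("rescaler_variance: %s", r$variance),
               sprintf("rescaler_zero_variance: %s", r$zero_variance),
               sprintf("rescaler_keep: %s", paste(r$keep, collapse = ",")),
               sprintf("rescaler_center: %s", num(r$center)),
               sprintf("rescaler_scale: %s", num(r$scale)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_elm
#' @export
read_elm <- function(path) {
  kv <- read_kv_file(path)
  nums <- function(k) as.numeric(strsplit(kv[[k]], ",")[[1L]])
  m <- as.integer(kv[["n_features"]])
  L <- as.integer(kv[["n_hidden"]])
  cfg <- elm_config(L, input_weight_range = nums("input_weight_range"),
                    bias_range = nums("bias_range"),
                    seed = as.integer(kv[["seed"]]),
                    pinv_rtol = if (kv[["pinv_rtol"]] == "default") NULL else
                      as.numeric(kv[["pinv_rtol"]]),
                    ridge = as.numeric(kv[["ridge"]]))
  beta <- if (kv[["beta"]] == "untrained") NULL else
    matrix(nums("beta"), nrow = L, ncol = as.integer(kv[["beta_ncol"]]))
  classes <- strsplit(kv[["classes"]], ",")[[1L]]
  classes <- if (!anyNA(suppressWarnings(as.integer(classes))))
    as.integer(classes) else classes
  resc <- NULL
  if (!is.null(kv[["rescaler_n_input"]])) {
    resc <- structure(list(
      center = nums("rescaler_center"), scale = nums("rescaler_scale"),
      keep = as.integer(strsplit(kv[["rescaler_keep"]], ",")[[1L]]),
      n_input = as.integer(kv[["rescaler_n_input"]]),
      zero_variance = kv[["rescaler_zero_variance"]],
      variance = kv[["rescaler_variance"]]), class = "eeg_rescaler")
  }
  structure(list(W = matrix(nums("W"), nrow = L, ncol = m), b = nums("b"),
                 beta = beta, n_features = m, encoding = kv[["encoding"]],
                 classes = classes, config = cfg, rescaler = resc),
            class = "elm")
}
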