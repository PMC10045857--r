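# Experiment orchestration: the canonical 80/20, 70/30 and 60/40 holdout
# protocols, hidden-neuron selection, optional connection-weight feature
# selection, optional off-the-shelf baselines, and report generation.

#' Experiment configuration
#'
#' @param dataset either a path to a chunk-table CSV in the canonical
#'   dialect, an `eeg_dataset`/`eeg_binary` object, or `NULL` to generate
#'   the default synthetic table from `synth`.
#' @param synth a [synth_config()] used when `dataset` is `NULL`; its seed
#'   is re-derived from `seed` so the whole run has one master seed.
#' @param train_fracs training fractions to run (default the canonical
#'   `c(0.8, 0.7, 0.6)`).
#' @param halve_holdout divide each holdout equally into validation and
#'   test (default `TRUE`, the protocol under which an 11,500-row table
#'   gives 1150-row validation and test partitions).
#' @param stratified stratify splits on the binary label (default `TRUE`).
#' @param balance_train duplicate minority training rows to a 50/50
#'   training prevalence (off by default).
#' @param n_hidden fixed hidden-layer size; `NULL` (default) uses the
#'   one-per-ten-training-rows heuristic [default_n_hidden()], which lands
#'   on 920/805/690 for the canonical protocols on 11,500 rows.
#' @param sweep_grid optional integer vector; when given, the size is
#'   instead chosen by validation sweep over this grid (requires
#'   `halve_holdout = TRUE`).
#' @param threshold binary decision threshold (default 0.5).
#' @param feature_selection run connection-weight feature selection and
#'   retrain on the selected subset (off by default: the canonical
#'   experiments use all 178 features).
#' @param fs_policy,fs_k selection policy, see [select_features()].
#' @param baselines character vector of baseline learners to append via
#'   [compare_baselines()]; subset of
#'   `c("knn", "nb", "lr", "dt", "rf", "ann")`.
#' @param seed master integer seed; every random stage derives its own
#'   sub-seed from it.
#' @return a list of class `experiment_config`.
#' @export
experiment_config <- function(dataset = NULL, synth = synth_config(),
                              train_fracs = c(0.8, 0.7, 0.6),
                              halve_holdout = TRUE, stratified = TRUE,
                              balance_train = FALSE, n_hidden = NULL,
                              sweep_grid = NULL, threshold = 0.5,
                              feature_selection = FALSE,
                              fs_policy = "threshold-mean", fs_k = NULL,
                              baselines = character(0L), seed = 1L) {
  stopifnot(length(train_fracs) >= 1L, all(train_fracs > 0),
            all(train_fracs < 1))
  if (!is.null(sweep_grid) && !halve_holdout) {
    stop("a validation sweep needs `halve_holdout = TRUE`", call. = FALSE)
  }
  known <- c("knn", "nb", "lr", "dt", "rf", "ann")
  if (length(baselines) > 0L && !all(baselines %in% known)) {
    stop(sprintf("unknown baseline(s); available: %s",
                 paste(known, collapse = ", ")), call. = FALSE)
  }
  structure(list(dataset = dataset, synth = synth, train_fracs = train_fracs,
                 halve_holdout = halve_holdout, stratified = stratified,
                 balance_train = balance_train, n_hidden = n_hidden,
                 sweep_grid = sweep_grid, threshold = threshold,
                 feature_selection = feature_selection,
                 fs_policy = fs_policy, fs_k = fs_k, baselines = baselines,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

load_experiment_dataset <- function(cfg) {
  ds <- cfg$dataset
  if (is.null(ds)) {
    synth <- cfg$synth
    synth$seed <- as.integer(derive_seed(cfg$seed, 1L))
    ds <- generate_bonn_like(synth)
  } else if (is.character(ds)) {
    ds <- read_eeg_csv(ds)
  }
  if (!inherits(ds, "eeg_dataset")) {
    stop("`dataset` must be a path, an eeg_dataset, or NULL", call. = FALSE)
  }
  if (!inherits(ds, "eeg_binary")) ds <- relabel_binary(ds)
  ds
}

metrics_row <- function(mr, model_name, division_pct, extras = list()) {
  base <- data.frame(
    Model = model_name, Split = mr$split_label,
    Accuracy_pct = 100 * mr$accuracy, Division_pct = division_pct,
    Samples = mr$n_samples, Prevalence = mr$prevalence,
    Precision = mr$precision, Recall = mr$recall, F1_Score = mr$f1,
    Specificity = mr$specificity, Sensitivity = mr$sensitivity,
    AUC = mr$auc, stringsAsFactors = FALSE)
  for (k in names(extras)) base[[k]] <- extras[[k]]
  base
}

#' Run the full experiment protocol
#'
#' For each training fraction: binarize labels, split (stratified, holdout
#' halved), fit the unit-variance rescaler on the training partition,
#' optionally select features by the connection-weight algorithm and
#' retrain, train the ELM (fixed, heuristic or validation-swept hidden
#' size), and evaluate on the training and test partitions. Emits one
#' training row and one testing row per fraction in the standard report
#' schema. All randomness derives from `cfg$seed`, so a rerun with the same
#' configuration reproduces the report byte for byte.
#'
#' @param cfg an [experiment_config()].
#' @param output_dir optional directory; when given, `report.csv`,
#'   `manifest.txt` and per-protocol ROC CSVs are written there.
#' @return an object of class `elm_experiment`: list with `report` (data
#'   frame), `models`, `rocs`, `sweeps` and `config`.
#' @export
run_experiment <- function(cfg, output_dir = NULL) {
  stopifnot(inherits(cfg, "experiment_config"))
  ds <- load_experiment_dataset(cfg)
  n_total <- n_chunks(ds)
  rows <- list()
  models <- list()
  rocs <- list()
  sweeps <- list()
  for (fi in seq_along(cfg$train_fracs)) {
    frac <- cfg$train_fracs[fi]
    t0 <- proc.time()[["elapsed"]]
    sp <- split_dataset(ds, train_frac = frac,
                        halve_holdout = cfg$halve_holdout,
                        stratified = cfg$stratified,
                        seed = derive_seed(cfg$seed, 10L + fi),
                        balance_train = cfg$balance_train)
    resc <- fit_rescaler(sp$train$features)
    xtr <- apply_rescaler(resc, sp$train$features)
    xte <- apply_rescaler(resc, sp$test$features)
    xva <- if (!is.null(sp$validation)) {
      apply_rescaler(resc, sp$validation$features)
    }

    L <- if (!is.null(cfg$sweep_grid)) {
      sw <- sweep_hidden_neurons(
        list(features = xtr, labels = sp$train$labels) |> as_binary_view(),
        list(features = xva, labels = sp$validation$labels) |> as_binary_view(),
        grid = cfg$sweep_grid, seed = derive_seed(cfg$seed, 20L + fi),
        threshold = cfg$threshold)
      sweeps[[sprintf("frac_%g", frac)]] <- sw
      sw$best_L
    } else if (!is.null(cfg$n_hidden)) {
      cfg$n_hidden
    } else {
      default_n_hidden(n_chunks(sp$train))
    }

    elm_cfg <- elm_config(L, seed = derive_seed(cfg$seed, 30L + fi))
    fit <- elm_train(xtr, sp$train$labels, elm_cfg)
    n_feat <- ncol(xtr)
    if (cfg$feature_selection) {
      fs <- elm_feature_selection(fit, policy = cfg$fs_policy, k = cfg$fs_k)
      sel <- sort(fs$selected)
      xtr <- xtr[, sel, drop = FALSE]
      xte <- xte[, sel, drop = FALSE]
      elm_cfg <- elm_config(L, seed = derive_seed(cfg$seed, 40L + fi))
      fit <- elm_train(xtr, sp$train$labels, elm_cfg)
      fit$feature_subset <- sel
      n_feat <- length(sel)
    }
    fit$rescaler <- resc
    elapsed <- proc.time()[["elapsed"]] - t0

    tag <- sprintf("frac_%g", frac)
    models[[tag]] <- fit
    tr_scores <- decision_scores(fit, xtr)[, 1L]
    te_scores <- decision_scores(fit, xte)[, 1L]
    tr_m <- classification_metrics(
      confusion_binary(sp$train$labels, as.integer(tr_scores >= cfg$threshold)),
      auc = roc_auc(sp$train$labels, tr_scores), split_label = "Training")
    te_m <- classification_metrics(
      confusion_binary(sp$test$labels, as.integer(te_scores >= cfg$threshold)),
      auc = roc_auc(sp$test$labels, te_scores), split_label = "Testing")
    rocs[[tag]] <- roc_curve(sp$test$labels, te_scores)

    extras <- list(Hidden_Neurons = L, Features = n_feat, Time_s = elapsed)
    rows[[length(rows) + 1L]] <- metrics_row(
      tr_m, "ELM", round(100 * n_chunks(sp$train) / n_total, 1L), extras)
    rows[[length(rows) + 1L]] <- metrics_row(
      te_m, "ELM", round(100 * n_chunks(sp$test) / n_total, 1L), extras)
  }
  report <- do.call(rbind, rows)
  out <- structure(list(report = report, models = models, rocs = rocs,
                        sweeps = sweeps, config = cfg), class = "elm_experiment")
  if (!is.null(output_dir)) export_experiment(out, output_dir)
  out
}

# sweep_hidden_neurons expects dataset-like lists with $features/$labels
as_binary_view <- function(x) {
  structure(list(features = x$features, labels = x$labels),
            class = c("eeg_binary", "eeg_dataset"))
}

#' @export
print.elm_experiment <- function(x, ...) {
  cat("<elm_experiment>\n")
  print(x$report[, c("Model", "Split", "Accuracy_pct", "Samples",
                     "Prevalence", "AUC")], row.names = FALSE)
  invisible(x)
}

export_experiment <- function(exp, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  write_report(exp$report, file.path(output_dir, "report.csv"))
  cfg <- exp$config
  manifest <- c(
    sprintf("package: elmeeg %s", as.character(utils::packageVersion("elmeeg"))),
    sprintf("seed: %d", cfg$seed),
    sprintf("train_fracs: %s", paste(cfg$train_fracs, collapse = ",")),
    sprintf("halve_holdout: %s", cfg$halve_holdout),
    sprintf("stratified: %s", cfg$stratified),
    sprintf("balance_train: %s", cfg$balance_train),
    sprintf("n_hidden: %s", if (is.null(cfg$n_hidden)) "heuristic" else cfg$n_hidden),
    sprintf("threshold: %g", cfg$threshold),
    sprintf("feature_selection: %s", cfg$feature_selection),
    sprintf("baselines: %s", if (length(cfg$baselines)) paste(cfg$baselines,
      collapse = ",") else "none"))
  writeLines(manifest, file.path(output_dir, "manifest.txt"))
  for (tag in names(exp$rocs)) {
    write_roc_csv(exp$rocs[[tag]], file.path(output_dir,
                                             sprintf("roc_%s.csv", tag)))
  }
  invisible(output_dir)
}

#' Write a report table as CSV
#'
#' Writes the report in the standard column order (model, split, accuracy
#' %, dataset division %, samples, prevalence, precision, recall, F1,
#' specificity, sensitivity, AUC, then any extra columns). Wall-clock
#' columns are dropped by default so identical runs produce byte-identical
#' files.
#'
#' @param report report data frame from [run_experiment()].
#' @param path output CSV path.
#' @param include_time keep the `Time_s` column (default `FALSE`).
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, include_time = FALSE) {
  if (nrow(report) == 0L) stop("empty report", call. = FALSE)
  if (!include_time) report$Time_s <- NULL
  lead <- c("Model", "Split", "Accuracy_pct", "Division_pct", "Samples",
            "Prevalence", "Precision", "Recall", "F1_Score", "Specificity",
            "Sensitivity", "AUC")
  report <- report[, c(intersect(lead, names(report)),
                       setdiff(names(report), lead))]
  utils::write.csv(report, path, row.names = FALSE)
  invisible(path)
}

#' Read back a written report
#' @param path CSV written by [write_report()].
#' @return data frame.
#' @export
read_report <- function(path) utils::read.csv(path, stringsAsFactors = FALSE)

# ---- baselines -------------------------------------------------------------

# Thin adapters around established implementations; each returns real-valued
# scores (probability of the positive class where available) for the train
# and test partitions. These are comparison points only, not part of the
# ELM method.
baseline_scores <- function(name, xtr, ytr, xte, seed) {
  need <- c(knn = "class", nb = "e1071", lr = "stats", dt = "rpart",
            rf = "randomForest", ann = "nnet")[[name]]
  if (!requireNamespace(need, quietly = TRUE)) {
    warning(sprintf("baseline '%s' skipped: package '%s' not installed",
                    name, need), call. = FALSE)
    return(NULL)
  }
  ytr_f <- factor(ytr, levels = 0:1)
  with_local_seed(seed, switch(
    name,
    knn = {
      p_te <- class::knn(xtr, xte, cl = ytr_f, k = 5L, prob = TRUE)
      p_tr <- class::knn(xtr, xtr, cl = ytr_f, k = 5L, prob = TRUE)
      as_pos <- function(pred) {
        pr <- attr(pred, "prob")
        ifelse(pred == "1", pr, 1 - pr)
      }
      list(train = as_pos(p_tr), test = as_pos(p_te))
    },
    nb = {
      fit <- e1071::naiveBayes(xtr, ytr_f)
      list(train = stats::predict(fit, xtr, type = "raw")[, "1"],
           test = stats::predict(fit, xte, type = "raw")[, "1"])
    },
    lr = {
      df_tr <- as.data.frame(xtr)
      fit <- suppressWarnings(stats::glm(ytr_f ~ ., data = df_tr,
                                         family = stats::binomial()))
      pr <- function(x) suppressWarnings(
        stats::predict(fit, newdata = as.data.frame(x), type = "response"))
      list(train = pr(xtr), test = pr(xte))
    },
    dt = {
      df_tr <- data.frame(.y = ytr_f, as.data.frame(xtr))
      fit <- rpart::rpart(.y ~ ., data = df_tr, method = "class")
      pr <- function(x) stats::predict(fit, as.data.frame(x))[, "1"]
      list(train = pr(xtr), test = pr(xte))
    },
    rf = {
      fit <- randomForest::randomForest(xtr, ytr_f, ntree = 100L)
      pr <- function(x) stats::predict(fit, x, type = "prob")[, "1"]
      list(train = pr(xtr), test = pr(xte))
    },
    ann = {
      fit <- nnet::nnet(xtr, as.numeric(ytr), size = 8L, maxit = 200L,
                        decay = 1e-4, trace = FALSE)
      pr <- function(x) as.numeric(stats::predict(fit, x))
      list(train = pr(xtr), test = pr(xte))
    }))
}

#' Append off-the-shelf baseline rows to an experiment
#'
#' Fits each requested baseline on exactly the partitions the ELM used (the
#' first training fraction of the configuration) and appends one training
#' and one testing row per baseline to the report. A baseline whose package
#' is unavailable is skipped with a warning; the ELM rows are never
#' affected.
#'
#' @param cfg an [experiment_config()] with a non-empty `baselines` field
#'   (an empty list reduces to [run_experiment()]).
#' @param output_dir optional output directory, as in [run_experiment()].
#' @return an `elm_experiment` whose report includes the baseline rows.
#' @export
compare_baselines <- function(cfg, output_dir = NULL) {
  stopifnot(inherits(cfg, "experiment_config"))
  exp <- run_experiment(cfg)
  if (length(cfg$baselines) > 0L) {
    ds <- load_experiment_dataset(cfg)
    n_total <- n_chunks(ds)
    frac <- cfg$train_fracs[1L]
    sp <- split_dataset(ds, train_frac = frac,
                        halve_holdout = cfg$halve_holdout,
                        stratified = cfg$stratified,
                        seed = derive_seed(cfg$seed, 11L),
                        balance_train = cfg$balance_train)
    resc <- fit_rescaler(sp$train$features)
    xtr <- apply_rescaler(resc, sp$train$features)
    xte <- apply_rescaler(resc, sp$test$features)
    for (bi in seq_along(cfg$baselines)) {
      nm <- cfg$baselines[bi]
      t0 <- proc.time()[["elapsed"]]
      sc <- baseline_scores(nm, xtr, sp$train$labels, xte,
                            seed = derive_seed(cfg$seed, 50L + bi))
      if (is.null(sc)) next
      elapsed <- proc.time()[["elapsed"]] - t0
      mk <- function(y, s, label) {
        classification_metrics(
          confusion_binary(y, as.integer(s >= cfg$threshold)),
          auc = roc_auc(y, s), split_label = label)
      }
      extras <- list(Hidden_Neurons = NA_integer_, Features = ncol(xtr),
                     Time_s = elapsed)
      exp$report <- rbind(
        exp$report,
        metrics_row(mk(sp$train$labels, sc$train, "Training"), toupper(nm),
                    round(100 * n_chunks(sp$train) / n_total, 1L), extras),
        metrics_row(mk(sp$test$labels, sc$test, "Testing"), toupper(nm),
                    round(100 * n_chunks(sp$test) / n_total, 1L), extras))
    }
  }
  if (!is.null(output_dir)) export_experiment(exp, output_dir)
  exp
}
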