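# Synthetic five-class EEG chunk generator.
#
# The generator reproduces the *shape* of the Bonn-derived chunk table —
# 5 classes x 100 subjects x 23 one-second chunks of 178 samples, amplitudes
# clipped to the published ADC range [-1415, 2047] — with an invented but
# learnable signal model: every class is AR(2)-filtered Gaussian noise at a
# class-specific amplitude scale, and the ictal class additionally carries
# high-amplitude ~3 Hz spike-wave bursts, giving it markedly higher per-row
# variance, as ictal EEG has. No physiological realism beyond that is
# attempted (no montage, no 1/f spectrum).

#' Configuration for the synthetic EEG chunk generator
#'
#' @param n_subjects_per_class subjects per condition (default 100).
#' @param chunks_per_subject one-second chunks per subject (default 23).
#' @param chunk_len samples per chunk (default 178, i.e. 178 Hz for 1 s).
#' @param seed integer seed; the table is fully determined by it.
#' @param class_scales innovation standard deviations (ADC units) for the
#'   AR(2) noise of classes 1..5. Class 1 (ictal) rides on top of bursts;
#'   classes 2-5 are plain filtered noise at distinct, decreasing scales.
#' @param ar_coef AR(2) filter coefficients (stable by default).
#' @param burst_amplitude peak amplitude (ADC units) of the ictal spike-wave
#'   component.
#' @param burst_freq spike-wave frequency in Hz (default 3, the classic
#'   generalized spike-wave rate).
#' @param clip_range two amplitudes; all values are clipped into this range
#'   and rounded to integers, matching the published data range.
#' @return a list of class `synth_config`.
#' @export
synth_config <- function(n_subjects_per_class = 100L,
                         chunks_per_subject = 23L,
                         chunk_len = 178L,
                         seed = 1L,
                         class_scales = c(60, 55, 45, 30, 18),
                         ar_coef = c(1.2, -0.36),
                         burst_amplitude = 600,
                         burst_freq = 3,
                         clip_range = c(-1415, 2047)) {
  stopifnot(n_subjects_per_class >= 1L, chunks_per_subject >= 1L,
            chunk_len >= 1L, length(class_scales) == 5L,
            all(class_scales > 0), length(clip_range) == 2L,
            clip_range[1L] < clip_range[2L], burst_amplitude >= 0,
            burst_freq > 0)
  structure(list(n_subjects_per_class = as.integer(n_subjects_per_class),
                 chunks_per_subject = as.integer(chunks_per_subject),
                 chunk_len = as.integer(chunk_len),
                 seed = as.integer(seed),
                 class_scales = class_scales, ar_coef = ar_coef,
                 burst_amplitude = burst_amplitude, burst_freq = burst_freq,
                 clip_range = clip_range),
            class = "synth_config")
}

#' Generate a synthetic five-class EEG chunk table
#'
#' Produces `5 * n_subjects_per_class * chunks_per_subject` rows of
#' `chunk_len` integer amplitudes plus the five-condition label, in the same
#' layout as the canonical chunk table (11,500 x 178 at the defaults).
#'
#' @param cfg a [synth_config()].
#' @return an [eeg_dataset()] with `row_ids` of the form `"S<subject>.C<chunk>"`.
#' @export
generate_bonn_like <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  with_local_seed(cfg$seed, {
    per_class <- cfg$n_subjects_per_class * cfg$chunks_per_subject
    m <- cfg$chunk_len
    t_sec <- (seq_len(m) - 1L) / m   # one-second chunk
    blocks <- vector("list", 5L)
    for (cl in 1:5) {
      # innovations as chunk_len x per_class matrix, AR(2)-filtered along time
      innov <- matrix(stats::rnorm(m * per_class, sd = cfg$class_scales[cl]),
                      nrow = m, ncol = per_class)
      x <- stats::filter(innov, filter = cfg$ar_coef, method = "recursive")
      x <- t(as.matrix(x))   # rows = chunks
      if (cl == 1L && cfg$burst_amplitude > 0) {
        # ~3 Hz spike-wave: slow wave plus a sharp spike each cycle, with a
        # random phase per chunk
        phase <- stats::runif(per_class, 0, 1)
        for (r in seq_len(per_class)) {
          ph <- (t_sec * cfg$burst_freq + phase[r]) %% 1
          wave <- sin(2 * pi * ph)
          spike <- exp(-((ph - 0.5) / 0.06)^2)
          x[r, ] <- x[r, ] + cfg$burst_amplitude * (wave + 1.5 * spike)
        }
      }
      blocks[[cl]] <- x
    }
    features <- do.call(rbind, blocks)
    features <- pmin(pmax(features, cfg$clip_range[1L]), cfg$clip_range[2L])
    features <- round(features)
    colnames(features) <- paste0("X", seq_len(m))
    labels <- rep(1:5, each = per_class)
    subj <- rep(rep(seq_len(5L * cfg$n_subjects_per_class),
                    each = cfg$chunks_per_subject), length.out = nrow(features))
    chunk <- rep(seq_len(cfg$chunks_per_subject), times = nrow(features) %/%
                   cfg$chunks_per_subject)
    ids <- sprintf("S%03d.C%02d", subj, chunk)
    eeg_dataset(features, labels, row_ids = ids)
  })
}

#' Write the generator manifest
#'
#' Records the full configuration and seed of a generated table as a plain
#' key-value text document next to the data, for provenance.
#'
#' @param cfg a [synth_config()].
#' @param path output text file.
#' @return `path`, invisibly.
#' @export
write_synth_manifest <- function(cfg, path) {
  stopifnot(inherits(cfg, "synth_config"))
  fmt <- function(v) paste(format(v, digits = 17L), collapse = ",")
  lines <- vapply(names(cfg), function(k) sprintf("%s: %s", k, fmt(cfg[[k]])),
                  character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Generate a separable two-class Gaussian dataset
#'
#' Two standard-normal clouds whose means are `margin` apart along a random
#' unit direction; used as an oracle fixture (a linear rule exists whenever
#' the margin is large, and `margin = 0` is an exact null). When
#' `informative` is given, the separating direction is supported on only
#' those features and uses equal-magnitude random-sign components, so every
#' planted feature carries the same known signal strength
#' `margin / sqrt(k)` — the right design for feature-selection recovery
#' experiments (a Gaussian direction would leave some "informative"
#' features with near-zero weight and hence genuinely undetectable).
#'
#' @param n total rows (even; half per class).
#' @param m number of features.
#' @param margin distance between the two class means.
#' @param seed integer seed.
#' @param informative either `NULL` (all features), an integer count `k`
#'   (features `1..k` carry the signal), or an integer vector of feature
#'   indices.
#' @return an `eeg_binary` dataset with balanced 0/1 labels; the informative
#'   index set is attached as `attr(, "informative")`.
#' @export
generate_separable <- function(n, m, margin, seed = 1L, informative = NULL) {
  stopifnot(m >= 1L, margin >= 0)
  if (n < 2L) stop("`n` must be at least 2", call. = FALSE)
  if (n %% 2L != 0L) stop("`n` must be even for balanced classes", call. = FALSE)
  info <- if (is.null(informative)) seq_len(m) else if (length(informative) == 1L &&
    informative <= m && is.numeric(informative) && informative >= 1) {
    seq_len(as.integer(informative))
  } else as.integer(informative)
  stopifnot(all(info >= 1L), all(info <= m))
  with_local_seed(seed, {
    u <- numeric(m)
    if (is.null(informative)) {
      d <- stats::rnorm(length(info))
      u[info] <- d / sqrt(sum(d^2))
    } else {
      u[info] <- sample(c(-1, 1), length(info), replace = TRUE) /
        sqrt(length(info))
    }
    x <- matrix(stats::rnorm(n * m), nrow = n, ncol = m)
    y <- rep(0:1, length.out = n)[sample.int(n)]
    x <- x + (y - 0.5) * margin * matrix(u, n, m, byrow = TRUE)
    colnames(x) <- paste0("X", seq_len(m))
    out <- new_eeg_binary(x, y)
    attr(out, "informative") <- info
    out
  })
}
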