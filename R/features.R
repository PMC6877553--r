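# Windowing and time-domain feature extraction.
#
# Feature definitions for a window x of length n (standard myoelectric-
# control definitions; the window is envelope-stage, hence non-negative):
#   VAR  = sum((x - mean(x))^2) / (n - 1)
#   WL   = sum(|x[i+1] - x[i]|)
#   IEMG = sum(|x[i]|)
#   MAV  = IEMG / n          ("moving average" read as per-window mean
#                             absolute value, one value per window)
#   RMS  = sqrt(sum(x^2) / n)
#   AR(2): Yule-Walker estimates (biased autocovariance) in the convention
#          x[t] = ar1 * x[t-1] + ar2 * x[t-2] + e[t]

#' Segment an envelope recording into sequential analysis windows
#'
#' Non-overlapping windows of `window_s` seconds are laid contiguously from
#' the first sample; the trailing partial window is discarded. Each window is
#' labelled by the majority per-sample label, with ties broken toward the
#' label whose run starts earliest in the window. Windows whose majority
#' label is swing (0) are dropped.
#'
#' @param rec An `emg_recording` at stage `"envelope"`.
#' @param labels Integer per-sample labels aligned with the recording.
#' @param window_s Window length in seconds (default 150 ms).
#' @return Data frame with columns `window`, `start`, `end`, `label`, one row
#'   per retained (non-swing) window, plus attributes `total_windows`,
#'   `window_samples` and `discarded_tail`.
#' @export
segment <- function(rec, labels, window_s = 0.150) {
  require_stage(rec, "envelope", "segment")
  n <- nrow(rec$data)
  if (length(labels) != n) {
    stop_config("labels length (%d) must match samples (%d)",
                length(labels), n)
  }
  n_win <- round(window_s * rec$sampling_rate)
  if (n_win < 4) stop_config("window too short: %d samples", n_win)
  k <- floor(n / n_win)
  rows <- if (k >= 1) {
    starts <- (seq_len(k) - 1L) * n_win + 1L
    lab <- vapply(starts, function(s) {
      window_label(labels[s:(s + n_win - 1L)])
    }, integer(1))
    data.frame(window = seq_len(k), start = starts,
               end = starts + n_win - 1L, label = lab)
  } else {
    data.frame(window = integer(), start = integer(), end = integer(),
               label = integer())
  }
  out <- rows[rows$label != SWING, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "total_windows") <- k
  attr(out, "window_samples") <- n_win
  attr(out, "discarded_tail") <- n - k * n_win
  out
}

# Majority label of a window; ties go to the label whose run starts earliest.
window_label <- function(lab) {
  tb <- tabulate(lab + 1L, nbins = 6L)  # bins: swing, classes 1..5
  mx <- max(tb)
  cand <- which(tb == mx) - 1L
  if (length(cand) > 1L) {
    first <- vapply(cand, function(v) match(v, lab), integer(1))
    cand <- cand[which.min(first)]
  }
  as.integer(cand)
}

# Yule-Walker AR(2) fit with biased autocovariances; returns c(ar1, ar2).
yule_walker2 <- function(x) {
  n <- length(x)
  xc <- x - mean(x)
  c0 <- sum(xc * xc) / n
  if (!is.finite(c0) || c0 <= 1e-24) return(c(0, 0))
  c1 <- sum(xc[-1L] * xc[-n]) / n
  c2 <- sum(xc[-(1:2)] * xc[seq_len(n - 2L)]) / n
  tryCatch(solve(matrix(c(c0, c1, c1, c0), 2), c(c1, c2)),
           error = function(e) {
             solve(matrix(c(c0 * (1 + 1e-9), c1, c1, c0 * (1 + 1e-9)), 2),
                   c(c1, c2))
           })
}

#' Time-domain features of one window
#'
#' @param x Numeric vector (one channel of one window), length >= 4.
#' @return Named vector `var`, `wl`, `iemg`, `ar1`, `ar2`, `rms`, `mav`.
#' @export
window_features <- function(x) {
  n <- length(x)
  if (n < 4) stop_config("window needs >= 4 samples for AR(2), got %d", n)
  iemg <- sum(abs(x))
  ar <- yule_walker2(x)
  c(var = stats::var(x), wl = sum(abs(diff(x))), iemg = iemg,
    ar1 = ar[1], ar2 = ar[2], rms = sqrt(sum(x * x) / n), mav = iemg / n)
}

PER_CHANNEL_FEATURES <- c("var", "wl", "iemg", "ar1", "ar2", "rms", "mav")

#' Feature-matrix column names for a feature subset
#'
#' Expands a subset of the six named features over the three channels;
#' `"ar"` expands to both autoregressive coefficients.
#'
#' @param features Subset of `c("var","wl","iemg","ar","rms","mav")`.
#' @return Character vector of column names such as `"ta_var"`, `"mg_ar1"`.
#' @export
feature_columns <- function(features = FEATURE_NAMES) {
  bad <- setdiff(features, FEATURE_NAMES)
  if (length(bad)) stop_config("unknown features: %s", paste(bad, collapse = ","))
  per <- unlist(lapply(features, function(f) if (f == "ar") c("ar1", "ar2") else f))
  as.vector(t(outer(EMG_CHANNELS, per, paste, sep = "_")))
}

#' Windowed feature table for one preprocessed trial
#'
#' Segments the envelope recording and computes, per window: the
#' deterministic-classifier aggregates `s_ta`, `s_mg`, `s_lg` (sums of the
#' unbiased normalized envelope samples over the window) and the 7 x 3
#' per-channel time-domain features. Channel bias gains, when supplied, are
#' applied to the envelope before feature computation only; the aggregates
#' are always computed from the unbiased envelope, because the deterministic
#' classifier consumes the conditioned signal itself rather than features.
#'
#' @param trial An `emg_trial` whose recording is at stage `"envelope"`.
#' @param bias Per-channel multiplicative gains (named or TA/MG/LG order).
#' @param window_s Window length in seconds.
#' @return Data frame with metadata columns (`participant`, `style`,
#'   `terrain`, `condition`, `trial`, `window`, `label`, `n_samples`), the
#'   aggregates and 21 feature columns.
#' @export
featurize <- function(trial, bias = c(ta = 1, mg = 1, lg = 1),
                      window_s = NULL) {
  if (!inherits(trial, "emg_trial")) stop_config("trial must be an emg_trial")
  window_s <- window_s %||% trial$meta$config$window_s %||% 0.150
  bias <- as.numeric(if (!is.null(names(bias))) bias[EMG_CHANNELS] else bias)
  if (length(bias) != 3 || anyNA(bias)) stop_config("bias must be 3 gains")
  win <- segment(trial$rec, trial$labels, window_s)
  n_w <- nrow(win)
  cols <- as.vector(t(outer(EMG_CHANNELS, PER_CHANNEL_FEATURES, paste,
                            sep = "_")))
  feat <- matrix(NA_real_, n_w, length(cols), dimnames = list(NULL, cols))
  s_agg <- matrix(NA_real_, n_w, 3,
                  dimnames = list(NULL, paste0("s_", EMG_CHANNELS)))
  for (i in seq_len(n_w)) {
    xw <- trial$rec$data[win$start[i]:win$end[i], , drop = FALSE]
    s_agg[i, ] <- colSums(xw)
    for (j in 1:3) {
      feat[i, ((j - 1L) * 7L + 1L):(j * 7L)] <- window_features(xw[, j] * bias[j])
    }
  }
  meta <- trial$meta
  p <- meta$participant
  cbind(data.frame(participant = p$id %||% NA_character_,
                   style = p$style %||% NA_character_,
                   terrain = meta$terrain, condition = meta$condition,
                   trial = meta$trial %||% NA_integer_,
                   window = win$window, label = win$label,
                   n_samples = attr(win, "window_samples"),
                   stringsAsFactors = FALSE),
        as.data.frame(s_agg), as.data.frame(feat))
}

#' Featurize a whole corpus
#'
#' Preprocesses (if needed) and featurizes every trial, binding the rows.
#'
#' @param corpus List of `emg_trial` objects.
#' @param ... Passed to [featurize()].
#' @return A window feature data frame.
#' @export
featurize_corpus <- function(corpus, ...) {
  do.call(rbind, lapply(corpus, function(tr) {
    if (tr$rec$stage == "raw") tr <- preprocess_trial(tr)
    featurize(tr, ...)
  }))
}

#' Exhaustive LDA feature-subset search
#'
#' For each of the 63 non-empty subsets of the six features, fits an LDA on a
#' stratified 70/30 split of the windows and reports held-out accuracy,
#' sorted in descending order. Runs whose training split misses a class (or
#' whose fit fails outright) are flagged rather than fatal.
#'
#' @param windows Window feature table ([featurize_corpus()] output).
#' @param features The feature universe to search over.
#' @param train_frac Fraction of windows used for training.
#' @param seed Optional seed for the stratified split.
#' @return Data frame with columns `rank`, `features`, `n_features`,
#'   `accuracy`, `flagged`.
#' @export
feature_subset_search <- function(windows, features = FEATURE_NAMES,
                                  train_frac = 0.7, seed = NULL) {
  if (length(unique(windows$label)) < 2) {
    stop_config("need >= 2 classes for the subset search")
  }
  with_seed(seed, {
    idx_train <- unlist(lapply(split(seq_len(nrow(windows)), windows$label),
                               function(ix) {
                                 sample(ix, max(1L, ceiling(train_frac * length(ix))))
                               }), use.names = FALSE)
    train <- windows[idx_train, , drop = FALSE]
    test <- windows[-idx_train, , drop = FALSE]
    masks <- lapply(seq_len(2^length(features) - 1), function(b) {
      features[bitwAnd(b, 2^(seq_along(features) - 1)) > 0]
    })
    rows <- lapply(masks, function(fs) {
      cols <- feature_columns(fs)
      acc <- NA_real_
      flagged <- length(unique(train$label)) < length(unique(windows$label))
      fit <- tryCatch(fit_lda(train[, cols, drop = FALSE], train$label),
                      error = function(e) NULL)
      if (is.null(fit)) {
        flagged <- TRUE
      } else if (nrow(test)) {
        acc <- mean(predict_lda(fit, test[, cols, drop = FALSE]) == test$label)
      }
      data.frame(features = paste(fs, collapse = "+"),
                 n_features = length(fs), accuracy = acc, flagged = flagged,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out <- out[order(-out$accuracy), , drop = FALSE]
    out <- cbind(rank = seq_len(nrow(out)), out)
    rownames(out) <- NULL
    out
  })
}
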