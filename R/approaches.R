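# Prediction approaches: generic (pooled), biased generic (channel-bias
# correction toward the optimum style), and walking style (style-specific
# models), plus walking-style identification.

#' Per-muscle mean stance envelope of a window table
#'
#' The mean over windows of the window-mean normalized envelope (aggregate
#' sum divided by window length). Swing windows are already excluded by
#' segmentation, so this is a stance-phase statistic.
#'
#' @param windows Window feature table ([featurize_corpus()] output).
#' @return Named vector `c(ta=, mg=, lg=)` in MVC-fraction units.
#' @export
stance_means <- function(windows) {
  if (!nrow(windows)) stop_config("no stance windows available")
  c(ta = mean(windows$s_ta / windows$n_samples),
    mg = mean(windows$s_mg / windows$n_samples),
    lg = mean(windows$s_lg / windows$n_samples))
}

#' Optimum-style reference activation pattern
#'
#' Built from the level-ground stance windows of the optimum-style training
#' participants: per-muscle mean stance envelope plus a per-class activation
#' template (for inspection and plotting).
#'
#' @param windows Training window table with `style` and `terrain` columns.
#' @return An object of class `style_reference`.
#' @export
style_reference <- function(windows) {
  lg_opt <- windows[windows$terrain == "level_ground" &
                      windows$style == "optimum", , drop = FALSE]
  if (!nrow(lg_opt)) {
    stop_config("no level-ground windows from optimum-style participants")
  }
  template <- t(vapply(split(lg_opt, lg_opt$label), stance_means, numeric(3)))
  structure(list(stance_mean = stance_means(lg_opt),
                 phase_template = template,
                 n_participants = length(unique(lg_opt$participant))),
            class = "style_reference")
}

#' @export
print.style_reference <- function(x, ...) {
  cat("<style_reference> stance means (MVC fraction):",
      paste(sprintf("%s=%.3f", names(x$stance_mean), x$stance_mean),
            collapse = " "),
      sprintf("(from %d participants)\n", x$n_participants))
  invisible(x)
}

#' Normative optimum-style reference template
#'
#' Builds the optimum reference from a long, variability-free simulation
#' (unit participant factors, no step jitter) of level-ground gait, mirroring
#' the idea of a normative activation template taken from the literature
#' rather than from a small, noisy cohort. Carrier noise is still present,
#' so the template lives in the same measured-envelope units as participant
#' data; the long duration averages it out.
#'
#' @param config A [sim_config()] providing rates and carrier settings.
#' @param profile Activation profile (generative ground truth).
#' @param n_steps,n_trials Length of the reference simulation.
#' @param seed Seed for the reference simulation.
#' @return A [style_reference()].
#' @export
normative_reference <- function(config = sim_config(),
                                profile = default_activation_profile(),
                                n_steps = 30, n_trials = 2, seed = 1) {
  cfg <- config
  cfg$terrain <- "level_ground"
  cfg$n_steps <- as.integer(n_steps)
  cfg$participant_sd <- 0
  cfg$step_sd[] <- 0
  with_seed(seed, {
    p <- participant("norm", "optimum", cfg, mvc = c(1, 1, 1))
    corpus <- simulate_corpus(list(p), cfg, terrains = "level_ground",
                              n_trials = n_trials, profile = profile)
    ref <- style_reference(featurize_corpus(corpus))
    ref$normative <- TRUE
    ref
  })
}

lg_stance <- function(windows) {
  out <- if ("terrain" %in% names(windows)) {
    windows[windows$terrain == "level_ground", , drop = FALSE]
  } else windows
  if (!nrow(out)) stop_config("no level-ground stance windows available")
  out
}

#' Identify a participant's walking style from level-ground gait
#'
#' Computes the relative deviation of each muscle's stance mean envelope from
#' the optimum reference, d_m = (mean_m - ref_m) / ref_m. If the largest
#' deviation reaches `hyper_threshold` the style is `hyper_<muscle>`;
#' otherwise, if the larger of the MG/LG deviations reaches
#' `moderate_threshold` the style is `moderate_<muscle>`; otherwise the
#' participant walks the optimum style. Ties resolve in channel order
#' TA, MG, LG. (There is no moderate TA style; sub-hyper TA deviations map to
#' optimum.)
#'
#' @param windows The participant's level-ground window table.
#' @param ref A [style_reference()].
#' @param hyper_threshold,moderate_threshold Deviation thresholds.
#' @return A walking-style string.
#' @export
identify_style <- function(windows, ref, hyper_threshold = 0.5,
                           moderate_threshold = 0.2) {
  m <- stance_means(lg_stance(windows))
  d <- (m - ref$stance_mean) / ref$stance_mean
  if (max(d) >= hyper_threshold) {
    return(paste0("hyper_", EMG_CHANNELS[which.max(d)]))
  }
  dml <- d[c("mg", "lg")]
  if (max(dml) >= moderate_threshold) {
    return(paste0("moderate_", names(dml)[which.max(dml)]))
  }
  "optimum"
}

#' Channel bias gains toward the optimum reference
#'
#' Multiplicative per-channel gains `ref_m / mean_m` that move the
#' participant's level-ground stance mean envelope onto the optimum
#' reference, clipped to [0.25, 4].
#'
#' @param windows The participant's level-ground window table.
#' @param ref A [style_reference()].
#' @return Named gain vector `c(ta=, mg=, lg=)`.
#' @export
compute_bias <- function(windows, ref) {
  m <- stance_means(lg_stance(windows))
  g <- ref$stance_mean / m
  bad <- !is.finite(g)
  if (any(bad)) {
    warning("zero stance mean envelope; bias gain clipped to maximum")
    g[bad] <- 4
  }
  pmin(pmax(g, 0.25), 4)
}

#' Apply bias gains to an envelope recording
#'
#' @param rec An `emg_recording` at stage `"envelope"`.
#' @param gains Per-channel gains from [compute_bias()].
#' @return The scaled recording (still at envelope stage).
#' @export
apply_bias <- function(rec, gains) {
  require_stage(rec, "envelope", "apply_bias")
  gains <- as.numeric(if (!is.null(names(gains))) gains[EMG_CHANNELS] else gains)
  rec$data <- rec$data * rep(gains, each = nrow(rec$data))
  rec
}

fit_pair <- function(windows, features) {
  cols <- feature_columns(features)
  list(lda = fit_lda(windows[, cols, drop = FALSE], windows$label),
       tree = fit_tree(windows[, cols, drop = FALSE], windows$label))
}

#' Build the generic approach bundle
#'
#' Fits one LDA and one CART on the pooled windows of all training
#' participants. The deterministic classifier needs no training. The bundle
#' records the training participant ids so evaluation can enforce the
#' leave-test-subject-out guard.
#'
#' @param windows Pooled training window table (>= 2 participants).
#' @param features Feature subset used by the machine-learning classifiers.
#' @return An object of class `approach_bundle` with `kind = "generic"`.
#' @export
build_generic <- function(windows, features = FEATURE_NAMES) {
  ids <- unique(windows$participant)
  if (length(ids) < 2) {
    stop_config("generic approach needs >= 2 training participants")
  }
  models <- fit_pair(windows, features)
  structure(list(kind = "generic", lda = models$lda, tree = models$tree,
                 features = features, train_ids = ids),
            class = "approach_bundle")
}

#' Build the biased generic approach bundle
#'
#' Same pooled models as the generic approach; at test time the new
#' participant's envelope is first biased toward the optimum reference
#' ([compute_bias()] from their level-ground trials), then featurized and fed
#' to the generic models.
#'
#' @param windows Pooled training window table.
#' @param ref A [style_reference()].
#' @param features Feature subset.
#' @return An `approach_bundle` with `kind = "biased"` carrying the
#'   reference.
#' @export
build_biased <- function(windows, ref, features = FEATURE_NAMES) {
  b <- build_generic(windows, features)
  b$kind <- "biased"
  b$ref <- ref
  b
}

#' Build the walking-style approach bundle
#'
#' Identifies each training participant's walking style from their own
#' level-ground windows, then fits one (LDA, tree) pair per represented
#' style. Styles absent from training fall back to the pooled generic models
#' (with a message at prediction time). The deterministic classifier is
#' shared.
#'
#' @param windows Pooled training window table.
#' @param ref A [style_reference()].
#' @param features Feature subset.
#' @param hyper_threshold,moderate_threshold Passed to [identify_style()].
#' @param style_windows Window table used for style identification; defaults
#'   to `windows`. Styles are always determined from level-ground gait, so
#'   when `windows` is an uneven-terrain (decoupled) slice, pass the full
#'   training table here.
#' @return An `approach_bundle` with `kind = "walking_style"`, a per-style
#'   model table and a generic fallback.
#' @export
build_walking_style <- function(windows, ref, features = FEATURE_NAMES,
                                hyper_threshold = 0.5,
                                moderate_threshold = 0.2,
                                style_windows = windows) {
  ids <- unique(windows$participant)
  if (length(ids) < 2) {
    stop_config("walking-style approach needs >= 2 training participants")
  }
  by_part <- split(windows, windows$participant)
  style_hat <- vapply(split(style_windows, style_windows$participant),
                      identify_style, character(1), ref = ref,
                      hyper_threshold = hyper_threshold,
                      moderate_threshold = moderate_threshold)[names(by_part)]
  table <- lapply(split(names(by_part), style_hat[names(by_part)]),
                  function(pids) {
                    w <- windows[windows$participant %in% pids, , drop = FALSE]
                    fit_pair(w, features)
                  })
  structure(list(kind = "walking_style", table = table,
                 fallback = fit_pair(windows, features),
                 identified_styles = style_hat, ref = ref,
                 features = features, train_ids = ids,
                 hyper_threshold = hyper_threshold,
                 moderate_threshold = moderate_threshold),
            class = "approach_bundle")
}

#' @export
print.approach_bundle <- function(x, ...) {
  cat("<approach_bundle>", x$kind, "-", length(x$train_ids),
      "training participants\n")
  if (x$kind == "walking_style") {
    cat("  styles:", paste(names(x$table), collapse = ", "), "\n")
  }
  invisible(x)
}

assert_no_leakage <- function(bundle, windows) {
  overlap <- intersect(bundle$train_ids, unique(windows$participant))
  if (length(overlap)) {
    stop_config("test participant(s) present in training pool: %s",
                paste(overlap, collapse = ", "))
  }
}

#' Classify the windows of one test participant under an approach
#'
#' Applies the leave-test-subject-out guard, selects the approach's models
#' (per-style models for the walking-style approach, with generic fallback
#' for unrepresented styles), and returns the four classifier outputs per
#' window. `windows` must already carry the approach's feature columns --
#' for the biased approach, features recomputed from the biased envelope
#' (the aggregates `s_*` stay unbiased by construction, so the deterministic
#' output is identical across approaches).
#'
#' @param bundle An `approach_bundle`.
#' @param windows One test participant's window table.
#' @param style For the walking-style approach, the participant's identified
#'   style (from their level-ground trials of the same electrode condition).
#' @return `windows` with columns `pred_lda`, `pred_tree`, `pred_det`,
#'   `pred_vote` appended.
#' @export
classify_windows <- function(bundle, windows, style = NULL) {
  assert_no_leakage(bundle, windows)
  models <- if (bundle$kind == "walking_style") {
    if (!is.null(style) && style %in% names(bundle$table)) {
      bundle$table[[style]]
    } else {
      message(sprintf("walking_style: no model for style '%s', using fallback",
                      style %||% "?"))
      bundle$fallback
    }
  } else {
    list(lda = bundle$lda, tree = bundle$tree)
  }
  cols <- feature_columns(bundle$features)
  x <- windows[, cols, drop = FALSE]
  windows$pred_lda <- predict_lda(models$lda, x)
  windows$pred_tree <- predict_tree(models$tree, x)
  windows$pred_det <- deterministic_classify(windows$s_ta, windows$s_mg,
                                             windows$s_lg)
  windows$pred_vote <- vote(windows$pred_lda, windows$pred_tree,
                            windows$pred_det)
  windows
}
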