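# Factorial evaluation: approach x classifier x electrode condition x
# data set, on a simulated training corpus (first-experiment analogue) and
# held-out test participants (second-experiment analogue).

APPROACHES <- c("generic", "biased", "walking_style")
CLASSIFIERS <- c("lda", "tree", "det", "vote")
CONDITIONS <- c("OE", "ES")
DATASETS <- c("combined", "decoupled_lg", "decoupled_ut")

dataset_terrains <- function(dataset) {
  switch(dataset,
         combined = c("level_ground", "uneven"),
         decoupled_lg = "level_ground",
         decoupled_ut = "uneven",
         stop_config("unknown dataset '%s'", dataset))
}

#' Default experiment configuration
#'
#' Six training participants (one per walking style) and ten test
#' participants (styles assigned round-robin) walk both terrains; the test
#' participants are additionally degraded into the electrode-shift condition.
#' Trial counts and steps per trial are desk-scale defaults; raise them (or
#' set `n_test = 3` for the original three-test-participant design) through
#' this configuration.
#'
#' @param n_test Number of test participants.
#' @param train_styles Styles of the training participants.
#' @param train_trials,test_trials Trials per participant and terrain.
#' @param sim A [sim_config()].
#' @param features Feature subset used by the ML classifiers.
#' @param hyper_threshold,moderate_threshold Style-identification thresholds.
#' @return A list of class `experiment_config`.
#' @export
default_experiment_config <- function(n_test = 10,
                                      train_styles = WALKING_STYLES,
                                      train_trials = 4, test_trials = 4,
                                      sim = sim_config(n_steps = 10),
                                      features = FEATURE_NAMES,
                                      hyper_threshold = 0.5,
                                      moderate_threshold = 0.2) {
  structure(list(n_test = as.integer(n_test), train_styles = train_styles,
                 test_styles = rep_len(WALKING_STYLES, n_test),
                 train_trials = as.integer(train_trials),
                 test_trials = as.integer(test_trials), sim = sim,
                 features = features, hyper_threshold = hyper_threshold,
                 moderate_threshold = moderate_threshold),
            class = "experiment_config")
}

#' Read an experiment configuration from YAML
#'
#' Scalar fields in the file override the defaults of
#' [default_experiment_config()]; fields under `sim:` override the simulator
#' defaults of [sim_config()].
#'
#' @param path Path to a YAML file.
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim %||% list()
  if (!is.null(sim_args$step_sd)) sim_args$step_sd <- unlist(sim_args$step_sd)
  sim <- do.call(sim_config, sim_args)
  args <- y[setdiff(names(y), "sim")]
  args$sim <- sim
  do.call(default_experiment_config, args)
}

confusion_matrix <- function(truth, pred) {
  table(true = factor(truth, levels = 1:5),
        predicted = factor(pred, levels = 1:5))
}

cm_accuracy <- function(cm) sum(diag(cm)) / sum(cm)

cm_macro_accuracy <- function(cm) {
  rs <- rowSums(cm)
  mean((diag(cm) / rs)[rs > 0])
}

#' Run the full factorial intent-prediction experiment
#'
#' Simulates a training corpus and held-out test participants, conditions
#' and featurizes every trial, builds the three approach bundles per data
#' set, and evaluates all four classifiers for every (approach, classifier,
#' electrode condition, data set) cell: 3 x 4 x 2 x 3 = 72 cells. Decoupled
#' data sets train and test within one terrain; the combined data set pools
#' both. The ES condition is the same walk with the style-dominant electrode
#' displaced. Training always uses optimally placed electrodes. Everything is
#' driven by `seed`, so a given (config, seed) pair reproduces the result
#' exactly.
#'
#' @param config An [default_experiment_config()].
#' @param seed Integer seed.
#' @return An object of class `emg_experiment`: `grid` (per-cell accuracy),
#'   `confusions` (per-cell 5x5 confusion matrices, rows = true class),
#'   `per_participant` (per-cell per-participant accuracies), `ttests`,
#'   `ref`, `styles` (true and identified test styles), `config`, `seed`.
#' @export
run_experiment <- function(config = default_experiment_config(), seed = 1) {
  if (!inherits(config, "experiment_config")) {
    stop_config("config must be an experiment_config")
  }
  with_seed(seed, {
    cfg <- config$sim
    train_parts <- make_participants(config$train_styles, cfg, prefix = "T")
    test_parts <- make_participants(config$test_styles, cfg, prefix = "P")
    train_corpus <- simulate_corpus(train_parts, cfg,
                                    n_trials = config$train_trials)
    test_corpus <- simulate_corpus(test_parts, cfg,
                                   n_trials = config$test_trials)
    test_es <- lapply(test_corpus, apply_electrode_shift)

    prep <- function(trials) lapply(trials, preprocess_trial)
    train_prep <- prep(train_corpus)
    test_prep <- list(OE = prep(test_corpus), ES = prep(test_es))

    train_w <- do.call(rbind, lapply(train_prep, featurize))
    test_w <- lapply(test_prep, function(trs) {
      do.call(rbind, lapply(trs, featurize))
    })

    ref <- style_reference(train_w)

    # per test participant and condition: bias gains and identified style
    # from their level-ground trials of that condition
    test_ids <- vapply(test_parts, `[[`, character(1), "id")
    part_info <- list()
    biased_w <- list()
    for (cond in CONDITIONS) {
      tw <- test_w[[cond]]
      for (id in test_ids) {
        lgw <- tw[tw$participant == id & tw$terrain == "level_ground", ,
                  drop = FALSE]
        gains <- compute_bias(lgw, ref)
        style_hat <- identify_style(lgw, ref, config$hyper_threshold,
                                    config$moderate_threshold)
        part_info[[paste(cond, id)]] <- list(gains = gains, style = style_hat)
        trs <- Filter(function(tr) tr$meta$participant$id == id,
                      test_prep[[cond]])
        biased_w[[paste(cond, id)]] <-
          do.call(rbind, lapply(trs, featurize, bias = gains))
      }
    }

    grid <- list()
    confusions <- list()
    per_part <- list()
    for (dataset in DATASETS) {
      terr <- dataset_terrains(dataset)
      trw <- train_w[train_w$terrain %in% terr, , drop = FALSE]
      bundles <- list(
        generic = build_generic(trw, config$features),
        biased = build_biased(trw, ref, config$features),
        walking_style = build_walking_style(trw, ref, config$features,
                                            config$hyper_threshold,
                                            config$moderate_threshold,
                                            style_windows = train_w))
      for (cond in CONDITIONS) {
        for (approach in APPROACHES) {
          preds <- lapply(test_ids, function(id) {
            info <- part_info[[paste(cond, id)]]
            w <- if (approach == "biased") {
              biased_w[[paste(cond, id)]]
            } else {
              tw <- test_w[[cond]]
              tw[tw$participant == id, , drop = FALSE]
            }
            w <- w[w$terrain %in% terr, , drop = FALSE]
            if (!nrow(w)) {
              stop_config("no test windows for cell (%s, %s, %s, %s)",
                          approach, cond, dataset, id)
            }
            classify_windows(bundles[[approach]], w, style = info$style)
          })
          preds <- do.call(rbind, preds)
          for (clf in CLASSIFIERS) {
            pr <- preds[[paste0("pred_", clf)]]
            cm <- confusion_matrix(preds$label, pr)
            key <- paste(approach, clf, cond, dataset, sep = ".")
            confusions[[key]] <- cm
            grid[[key]] <- data.frame(
              approach = approach, classifier = clf, condition = cond,
              dataset = dataset, accuracy = cm_accuracy(cm),
              macro_accuracy = cm_macro_accuracy(cm), n_windows = sum(cm),
              stringsAsFactors = FALSE)
            acc_by <- tapply(pr == preds$label, preds$participant, mean)
            per_part[[key]] <- data.frame(
              approach = approach, classifier = clf, condition = cond,
              dataset = dataset, participant = names(acc_by),
              accuracy = as.numeric(acc_by), stringsAsFactors = FALSE)
          }
        }
      }
    }
    grid <- do.call(rbind, grid)
    rownames(grid) <- NULL
    per_part <- do.call(rbind, per_part)
    rownames(per_part) <- NULL

    styles <- data.frame(
      participant = test_ids,
      true_style = config$test_styles,
      identified_OE = vapply(test_ids, function(id) {
        part_info[[paste("OE", id)]]$style
      }, character(1)),
      identified_ES = vapply(test_ids, function(id) {
        part_info[[paste("ES", id)]]$style
      }, character(1)),
      stringsAsFactors = FALSE)

    result <- structure(list(grid = grid, confusions = confusions,
                             per_participant = per_part, ref = ref,
                             styles = styles, config = config, seed = seed),
                        class = "emg_experiment")
    result$ttests <- experiment_ttests(result)
    result
  })
}

# Participant-mean accuracy over a slice of the per-participant table.
participant_means <- function(pp, ...) {
  filt <- list(...)
  for (nm in names(filt)) pp <- pp[pp[[nm]] %in% filt[[nm]], , drop = FALSE]
  out <- tapply(pp$accuracy, pp$participant, mean)
  out[sort(names(out))]
}

experiment_ttests <- function(result) {
  pp <- result$per_participant
  tt <- list()
  tt$electrode_OE_vs_ES <- paired_ttest(
    participant_means(pp, condition = "OE"),
    participant_means(pp, condition = "ES"))
  tt$dataset_decoupled_vs_combined <- paired_ttest(
    participant_means(pp, dataset = c("decoupled_lg", "decoupled_ut")),
    participant_means(pp, dataset = "combined"))
  combos <- utils::combn(APPROACHES, 2)
  tt$approaches <- apply(combos, 2, function(ab) {
    res <- paired_ttest(participant_means(pp, approach = ab[1]),
                        participant_means(pp, approach = ab[2]))
    res$comparison <- paste(ab, collapse = "_vs_")
    res
  })
  combos <- utils::combn(CLASSIFIERS, 2)
  tt$classifiers <- apply(combos, 2, function(ab) {
    res <- paired_ttest(participant_means(pp, classifier = ab[1]),
                        participant_means(pp, classifier = ab[2]))
    res$comparison <- paste(ab, collapse = "_vs_")
    res
  })
  tt
}

#' @export
print.emg_experiment <- function(x, ...) {
  cat("<emg_experiment>", nrow(x$grid), "cells, seed", x$seed, "\n")
  agg <- tapply(x$grid$accuracy,
                x$grid[c("condition", "dataset")], mean)
  cat("mean accuracy by condition x dataset:\n")
  print(round(agg, 3))
  invisible(x)
}

#' Two-tailed paired t-test
#'
#' Classical paired t on the per-participant differences. Degenerate cases
#' are reported rather than fatal: identical pairs give t = 0, p = 1;
#' zero-variance differences with non-zero mean give an infinite t and a
#' p-value reported at the machine-precision bound.
#'
#' @param a,b Paired accuracy vectors (same participants, same order).
#' @return A list of class `emg_ttest`: `t`, `df`, `p`, `mean_diff`, `n`.
#' @export
paired_ttest <- function(a, b) {
  if (length(a) != length(b)) stop_config("paired vectors differ in length")
  n <- length(a)
  if (n < 2) stop_config("need n >= 2 pairs")
  d <- a - b
  m <- mean(d)
  s <- stats::sd(d)
  if (s == 0) {
    if (m == 0) {
      t <- 0
      p <- 1
    } else {
      t <- sign(m) * Inf
      p <- .Machine$double.eps  # reported bound, not an exact p
    }
  } else {
    t <- m / (s / sqrt(n))
    p <- 2 * stats::pt(-abs(t), df = n - 1)
  }
  structure(list(t = t, df = n - 1L, p = p, mean_diff = m, n = n),
            class = "emg_ttest")
}

#' @export
print.emg_ttest <- function(x, ...) {
  cat(sprintf("paired t = %.4g, df = %d, p = %.4g (mean diff %.4g)\n",
              x$t, x$df, x$p, x$mean_diff))
  invisible(x)
}
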