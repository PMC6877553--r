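# Prediction approaches: style identification, channel bias, bundles.

ref0 <- structure(list(stance_mean = c(ta = 0.20, mg = 0.15, lg = 0.10)),
                  class = "style_reference")

test_that("zero deviation identifies the optimum style", {
  w <- fake_windows(0.20, 0.15, 0.10)
  expect_identical(identify_style(w, ref0), "optimum")
})

test_that("a doubled MG envelope identifies hyper MG; milder excess is moderate", {
  expect_identical(identify_style(fake_windows(0.20, 0.30, 0.10), ref0),
                   "hyper_mg")
  expect_identical(identify_style(fake_windows(0.20, 0.15 * 1.3, 0.10), ref0),
                   "moderate_mg")
  # sub-hyper TA deviation maps to optimum (no moderate TA style)
  expect_identical(identify_style(fake_windows(0.20 * 1.3, 0.15, 0.10), ref0),
                   "optimum")
  expect_identical(identify_style(fake_windows(0.20 * 1.6, 0.15, 0.10), ref0),
                   "hyper_ta")
})

test_that("style identification is duration-invariant and needs stance windows", {
  w <- fake_windows(0.20, 0.30, 0.10, n = 6)
  expect_identical(identify_style(rbind(w, w, w), ref0),
                   identify_style(w, ref0))
  none <- fake_windows(0.2, 0.2, 0.2, terrain = "uneven")
  expect_error(identify_style(none, ref0), "level-ground")
})

test_that("an optimum-style participant is recovered from seeded level-ground gait", {
  cfg <- sim_config(n_steps = 10)
  ref <- normative_reference(cfg, seed = 1)
  p <- with_seed(51, participant("O", "optimum", cfg))
  corpus <- simulate_corpus(list(p), cfg, terrains = "level_ground",
                            n_trials = 2, seed = 52)
  expect_identical(identify_style(featurize_corpus(corpus), ref), "optimum")
})

test_that("bias gains are the reciprocal deviation, clipped and warned on zeros", {
  expect_equal(compute_bias(fake_windows(0.20, 0.15, 0.10), ref0),
               c(ta = 1, mg = 1, lg = 1))
  expect_equal(compute_bias(fake_windows(0.20, 0.30, 0.10), ref0)[["mg"]],
               0.5)
  g <- expect_warning(compute_bias(fake_windows(0.20, 0, 0.10), ref0),
                      "clipped")
  g <- suppressWarnings(compute_bias(fake_windows(0.20, 1e-9, 0.10), ref0))
  expect_equal(g[["mg"]], 4)  # clip ceiling
  expect_equal(suppressWarnings(
    compute_bias(fake_windows(5, 0.15, 0.10), ref0))[["ta"]], 0.25)
})

test_that("bias round trip restores the reference on noise-free envelopes", {
  cfg <- sim_config(n_steps = 8, participant_sd = 0,
                    step_sd = c(level_ground = 0, uneven = 0))
  p_opt <- fixed_participant("optimum", cfg)
  p_hyp <- fixed_participant("hyper_mg", cfg)
  opt <- simulate_trial(p_opt, cfg, seed = 53)
  hyp <- simulate_trial(p_hyp, cfg, seed = 53)
  env_means <- function(tr) {
    stance <- tr$labels %in% 1:3
    colMeans(tr$env[stance, ])
  }
  ref <- structure(list(stance_mean = env_means(opt)),
                   class = "style_reference")
  m_hyp <- env_means(hyp)
  gains <- pmin(pmax(ref$stance_mean / m_hyp, 0.25), 4)
  corrected <- m_hyp * gains
  expect_true(all(abs(corrected - ref$stance_mean) / ref$stance_mean < 0.02))
})

test_that("apply_bias scales the envelope channels and nothing else", {
  cfg <- tiny_cfg()
  tr <- preprocess_trial(simulate_trial(fixed_participant(cfg = cfg), cfg,
                                        seed = 54))
  out <- apply_bias(tr$rec, c(ta = 1, mg = 0.5, lg = 2))
  expect_equal(out$data[, "mg"], tr$rec$data[, "mg"] * 0.5)
  expect_equal(out$data[, "ta"], tr$rec$data[, "ta"])
  expect_error(apply_bias(tr$rec$data, c(1, 1, 1)))
})

test_that("extreme bias gains never produce non-finite features", {
  cfg <- tiny_cfg()
  tr <- preprocess_trial(simulate_trial(fixed_participant(cfg = cfg), cfg,
                                        seed = 55))
  w <- featurize(tr, bias = c(ta = 4, mg = 0.25, lg = 4))
  expect_true(all(is.finite(as.matrix(w[, feature_columns()]))))
})

simulated_bundle_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- tiny_cfg()
      parts <- make_participants(c("optimum", "optimum", "hyper_mg"), cfg,
                                 seed = 56)
      corpus <- simulate_corpus(parts, cfg, terrains = "level_ground",
                                n_trials = 2, seed = 57)
      w <- featurize_corpus(corpus)
      test_p <- with_seed(58, participant("Z9", "optimum", cfg))
      test_w <- featurize_corpus(simulate_corpus(list(test_p), cfg,
                                                 terrains = "level_ground",
                                                 n_trials = 1, seed = 59))
      cache <<- list(train = w, test = test_w, ref = style_reference(w))
    }
    cache
  }
})

test_that("the generic bundle trains on pools and enforces the leakage guard", {
  fx <- simulated_bundle_fixture()
  bundle <- suppressMessages(build_generic(fx$train))
  preds <- suppressMessages(classify_windows(bundle, fx$test))
  expect_true(all(c("pred_lda", "pred_tree", "pred_det", "pred_vote") %in%
                    names(preds)))
  expect_true(all(preds$pred_vote %in% 1:5))
  expect_error(classify_windows(bundle, fx$train), "training pool")
  one <- fx$train[fx$train$participant == fx$train$participant[1], ]
  expect_error(build_generic(one), "2 training participants")
})

test_that("identity bias reproduces the generic predictions", {
  fx <- simulated_bundle_fixture()
  generic <- suppressMessages(build_generic(fx$train))
  biased <- suppressMessages(build_biased(fx$train, fx$ref))
  pg <- suppressMessages(classify_windows(generic, fx$test))
  pb <- suppressMessages(classify_windows(biased, fx$test))
  # identical feature table (identity bias upstream) => identical predictions
  expect_identical(pb$pred_lda, pg$pred_lda)
  expect_identical(pb$pred_tree, pg$pred_tree)
  expect_identical(pb$pred_det, pg$pred_det)
})

test_that("the walking-style table covers represented styles and falls back otherwise", {
  fx <- simulated_bundle_fixture()
  ws <- suppressMessages(build_walking_style(fx$train, fx$ref))
  expect_true(length(ws$table) >= 1)
  expect_named(ws$fallback, c("lda", "tree"))
  expect_message(classify_windows(ws, fx$test, style = "hyper_lg"),
                 "fallback")
  known <- names(ws$table)[1]
  expect_silent(preds <- classify_windows(ws, fx$test, style = known))
  expect_true(all(preds$pred_lda %in% 1:5))
})
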