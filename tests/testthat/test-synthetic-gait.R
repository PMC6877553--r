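# Synthetic gait generator: label schedules, EMG synthesis, electrode shift,
# reproducibility.

test_that("level-ground schedules contain only sagittal stance classes and swing", {
  cfg <- sim_config(n_steps = 5)
  sched <- with_seed(1, phase_schedule(cfg))
  expect_setequal(unique(sched), c(0L, 1L, 2L, 3L))
})

test_that("probability-one frontal events put an eversion or inversion in every step", {
  cfg <- sim_config(n_steps = 4, terrain = "uneven", frontal_event_prob = 1)
  sched <- with_seed(2, phase_schedule(cfg))
  step <- attr(sched, "step")
  for (k in unique(step)) {
    expect_true(any(sched[step == k] %in% c(4L, 5L)))
  }
})

test_that("frontal event rate matches the configured probability (binomial check)", {
  cfg <- sim_config(n_steps = 1000, terrain = "uneven", frontal_event_prob = 0.5)
  sched <- with_seed(3, phase_schedule(cfg))
  step <- attr(sched, "step")
  has_event <- vapply(split(sched, step), function(s) any(s %in% 4:5),
                      logical(1))
  expect_lt(abs(mean(has_event) - 0.5), 0.05)
})

test_that("uneven batches cover all five classes, level ground exactly three", {
  cfg <- sim_config(n_steps = 10, terrain = "uneven")
  p <- with_seed(4, participant("U", "optimum", cfg))
  tr <- simulate_trial(p, cfg, seed = 5)
  expect_setequal(setdiff(unique(tr$labels), 0L), 1:5)
  lg_cfg <- sim_config(n_steps = 10)
  tr_lg <- simulate_trial(p, lg_cfg, seed = 6)
  expect_setequal(setdiff(unique(tr_lg$labels), 0L), 1:3)
})

test_that("zero activation leaves pure zero-mean carrier noise", {
  cfg <- tiny_cfg()
  prof <- default_activation_profile(tonic = 0.5)
  prof$amplitude[] <- 0
  p <- fixed_participant(cfg = cfg)
  tr <- simulate_trial(p, cfg, profile = prof, seed = 7)
  # raw = tonic x carrier: window means vanish relative to the signal scale
  n_win <- 300
  k <- floor(nrow(tr$rec$data) / n_win)
  wm <- vapply(seq_len(k), function(i) {
    mean(tr$rec$data[((i - 1) * n_win + 1):(i * n_win), "ta"])
  }, numeric(1))
  expect_lt(max(abs(wm)), 0.1 * stats::sd(tr$rec$data[, "ta"]))
})

test_that("a hyper-MG style scales only the MG channel, by exactly the style gain", {
  cfg <- tiny_cfg()
  p_opt <- fixed_participant("optimum", cfg)
  p_hyp <- p_opt
  p_hyp$style <- "hyper_mg"
  a <- simulate_trial(p_opt, cfg, seed = 8)
  b <- simulate_trial(p_hyp, cfg, seed = 8)
  expect_identical(a$rec$data[, "ta"], b$rec$data[, "ta"])
  expect_identical(a$rec$data[, "lg"], b$rec$data[, "lg"])
  rms <- function(x) sqrt(mean(x^2))
  # envelope = tonic + gain x bump: RMS grows, bounded by the full gain
  ratio <- rms(b$rec$data[, "mg"]) / rms(a$rec$data[, "mg"])
  expect_gt(ratio, 1.5)
  expect_lt(ratio, 1.8 + 1e-9)
})

test_that("carrier energy is concentrated in the 20-450 Hz band", {
  cfg <- sim_config(n_steps = 10)  # ~11 s
  prof <- default_activation_profile(tonic = 1)
  prof$amplitude[] <- 0
  p <- fixed_participant(cfg = cfg)
  tr <- simulate_trial(p, cfg, profile = prof, seed = 9)
  frac <- band_energy_fraction(tr$rec$data[, "mg"], cfg$sampling_rate, 20, 450)
  expect_gte(frac, 0.95)
})

test_that("electrode shift with identity parameters is a no-op", {
  cfg <- tiny_cfg()
  p <- fixed_participant(cfg = cfg)
  tr <- simulate_trial(p, cfg, seed = 10)
  sh <- apply_electrode_shift(tr, "mg", attenuation = 1, crosstalk = 0)
  expect_identical(sh$rec$data, tr$rec$data)
  expect_identical(sh$labels, tr$labels)
  expect_identical(sh$meta$condition, "ES")
})

test_that("pure attenuation scales the shifted channel RMS linearly", {
  cfg <- tiny_cfg()
  p <- fixed_participant(cfg = cfg)
  tr <- simulate_trial(p, cfg, seed = 11)
  sh <- apply_electrode_shift(tr, "mg", attenuation = 0.6, crosstalk = 0)
  rms <- function(x) sqrt(mean(x^2))
  expect_equal(rms(sh$rec$data[, "mg"]), 0.6 * rms(tr$rec$data[, "mg"]),
               tolerance = 1e-12)
  expect_identical(sh$rec$data[, "lg"], tr$rec$data[, "lg"])
})

test_that("crosstalk from LG raises the MG/LG correlation", {
  cfg <- tiny_cfg()
  p <- fixed_participant(cfg = cfg)
  tr <- simulate_trial(p, cfg, seed = 12)
  sh <- apply_electrode_shift(tr, "mg", attenuation = 0.8, crosstalk = 0.2)
  r0 <- stats::cor(tr$rec$data[, "mg"], tr$rec$data[, "lg"])
  r1 <- stats::cor(sh$rec$data[, "mg"], sh$rec$data[, "lg"])
  expect_gt(r1, r0)
})

test_that("unknown shift channel and invalid terrain are rejected", {
  cfg <- tiny_cfg()
  p <- fixed_participant(cfg = cfg)
  tr <- simulate_trial(p, cfg, seed = 13)
  expect_error(apply_electrode_shift(tr, "soleus"), "unknown channel")
  expect_error(sim_config(terrain = "stairs"), "terrain")
})

test_that("identical config and seed reproduce a trial byte-for-byte through CSV", {
  cfg <- tiny_cfg(terrain = "uneven")
  p1 <- with_seed(14, participant("R", "moderate_lg", cfg))
  p2 <- with_seed(14, participant("R", "moderate_lg", cfg))
  a <- simulate_trial(p1, cfg, seed = 15)
  b <- simulate_trial(p2, cfg, seed = 15)
  expect_identical(a$rec$data, b$rec$data)
  expect_identical(a$labels, b$labels)
  fa <- tempfile(fileext = ".csv")
  fb <- tempfile(fileext = ".csv")
  write_trial_csv(a, fa)
  write_trial_csv(b, fb)
  expect_identical(readLines(fa), readLines(fb))
  back <- read_trial_csv(fa)
  expect_identical(back$labels, a$labels)
  expect_equal(back$rec$data, a$rec$data, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(back$rec$sampling_rate, a$rec$sampling_rate, tolerance = 1e-6)
})

test_that("noise-free envelopes respect the generative activation orderings", {
  cfg <- sim_config(n_steps = 8, terrain = "uneven", frontal_event_prob = 0.6,
                    participant_sd = 0,
                    step_sd = c(level_ground = 0, uneven = 0))
  p <- fixed_participant(cfg = cfg)
  tr <- simulate_trial(p, cfg, seed = 16)
  prof <- default_activation_profile()
  for (cls in 1:5) {
    sel <- tr$labels == cls
    if (!any(sel)) next
    m <- colMeans(tr$env[sel, , drop = FALSE])
    expect_identical(order(m, decreasing = TRUE),
                     order(prof$amplitude[cls + 1, ], decreasing = TRUE),
                     label = sprintf("envelope ordering for class %d", cls))
  }
})

test_that("manifest round trip preserves the corpus description", {
  cfg <- tiny_cfg()
  parts <- make_participants(c("optimum", "hyper_ta"), cfg, seed = 17)
  corpus <- simulate_corpus(parts, cfg, terrains = "level_ground",
                            n_trials = 1, seed = 18)
  dir <- tempfile()
  path <- write_manifest(corpus, dir, seed = 18)
  man <- read_manifest(path)
  expect_equal(man$seed, 18)
  expect_length(man$trials, 2)
  expect_setequal(vapply(man$trials, `[[`, character(1), "style"),
                  c("optimum", "hyper_ta"))
  expect_true(all(file.exists(file.path(dir, vapply(man$trials, `[[`,
                                                    character(1), "file")))))
})
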