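# Synthetic gait EMG generator.
#
# Generative model: per gait cycle, the stance phase is partitioned into
# sub-phases (dorsiflexion-controlled loading, foot flat, plantarflexion
# push-off) followed by a swing segment labelled with the sentinel 0. Each
# muscle's activation envelope is a raised-cosine bump per sub-phase, scaled
# by the activation profile, the walking-style gain, participant-level and
# step-level variability. The raw signal is envelope x carrier x MVC where
# the carrier is zero-mean Gaussian noise band-limited to 20-450 Hz.

# Stance sub-phase boundaries as fractions of the gait cycle.
PHASE_DF_END <- 0.15    # heel strike / loading, dorsiflexion control
PHASE_FLAT_END <- 0.42  # foot flat
PHASE_PUSH_END <- 0.62  # plantarflexion push-off; remainder is swing
FRONTAL_START <- 0.20   # frontal-plane event window within mid-stance
FRONTAL_END <- 0.38

#' Per-sample motion-label schedule for one trial
#'
#' Partitions each gait cycle into stance sub-phases (dorsiflexion, foot
#' flat, plantarflexion) and a swing segment (label 0). On uneven terrain,
#' each step's mid-stance is replaced by an eversion or inversion event with
#' probability `frontal_event_prob`; event steps alternate between eversion
#' and inversion. Uneven trials with at least 10 steps are guaranteed at
#' least two event steps (when the probability is positive) so that both
#' frontal classes are represented.
#'
#' Cycle lengths receive a small uniform jitter (plus or minus 3 percent), so
#' step durations vary around `cycle_duration * speed_factor`. Draws come
#' from the current RNG stream; seed the caller (see [simulate_trial()]).
#'
#' @param config A [sim_config()].
#' @param speed_factor Unitless multiplier on the cycle duration.
#' @return Integer vector of per-sample labels (0 = swing, 1-5 = motion
#'   classes) with attributes `step` (per-sample step index) and `frontal`
#'   (per-step frontal event class, 0 if none).
#' @export
phase_schedule <- function(config, speed_factor = 1) {
  if (!inherits(config, "sim_config")) {
    stop_config("config must be a sim_config object")
  }
  fs <- config$sampling_rate
  n_steps <- config$n_steps
  events <- rep(FALSE, n_steps)
  if (config$terrain == "uneven" && config$frontal_event_prob > 0) {
    events <- stats::runif(n_steps) < config$frontal_event_prob
    if (n_steps >= 10 && sum(events) < 2) {
      # coverage guarantee: promote the earliest non-event steps
      events[which(!events)[seq_len(2 - sum(events))]] <- TRUE
    }
  }
  frontal <- integer(n_steps)
  frontal[events] <- rep_len(c(MOTION_CLASSES[["eversion"]],
                               MOTION_CLASSES[["inversion"]]), sum(events))
  labs <- vector("list", n_steps)
  steps <- vector("list", n_steps)
  for (k in seq_len(n_steps)) {
    ns <- max(1L, round(fs * config$cycle_duration * speed_factor *
                          stats::runif(1, 0.97, 1.03)))
    frac <- (seq_len(ns) - 1) / ns
    lab <- rep(SWING, ns)
    lab[frac < PHASE_PUSH_END] <- MOTION_CLASSES[["plantarflexion"]]
    lab[frac < PHASE_FLAT_END] <- MOTION_CLASSES[["foot_flat"]]
    lab[frac < PHASE_DF_END] <- MOTION_CLASSES[["dorsiflexion"]]
    if (events[k]) {
      lab[frac >= FRONTAL_START & frac < FRONTAL_END] <- frontal[k]
    }
    labs[[k]] <- lab
    steps[[k]] <- rep.int(k, ns)
  }
  out <- unlist(labs, use.names = FALSE)
  attr(out, "step") <- unlist(steps, use.names = FALSE)
  attr(out, "frontal") <- frontal
  out
}

# Zero-mean Gaussian noise band-limited to 20-450 Hz, rescaled to exact sd.
band_limited_noise <- function(n, fs, sd) {
  x <- stats::rnorm(n)
  if (n >= 64) {
    bf <- signal::butter(4, c(20, 450) / (fs / 2), type = "pass")
    x <- signal::filtfilt(bf, x)
  }
  x * sd / stats::sd(x)
}

#' Synthesize a raw multichannel EMG trial from a label schedule
#'
#' Builds the per-muscle activation envelope implied by the schedule,
#' the activation profile, the participant's walking-style gains, and
#' participant- and step-level variability, then modulates band-limited
#' carrier noise and scales by the per-muscle MVC amplitude.
#'
#' @param schedule Label stream from [phase_schedule()].
#' @param participant An [participant()] object.
#' @param config The [sim_config()] used to build the schedule.
#' @param profile An [default_activation_profile()]-style object.
#' @return An object of class `emg_trial`: list with `rec` (raw
#'   [emg_recording()]), `labels`, `step`, `env` (the noise-free true
#'   envelope matrix, MVC fraction), and `meta`.
#' @export
synthesize_emg <- function(schedule, participant, config,
                           profile = default_activation_profile()) {
  fs <- config$sampling_rate
  n <- length(schedule)
  step <- attr(schedule, "step") %||% rep.int(1L, n)
  gains <- config$style_gains[[participant$style]]
  if (is.null(gains)) stop_config("no style gains for '%s'", participant$style)
  env <- matrix(profile$tonic, n, 3, dimnames = list(NULL, EMG_CHANNELS))
  ssd <- config$step_sd[[config$terrain]]
  n_steps <- max(step)
  step_gain <- matrix(stats::rlnorm(n_steps * 3, 0, ssd), n_steps, 3)
  seg_id <- cumsum(c(1L, (diff(as.integer(schedule)) != 0L) |
                       (diff(step) != 0L)))
  for (idx in split(seq_len(n), seg_id)) {
    cls <- schedule[idx[1L]]
    k <- step[idx[1L]]
    m <- length(idx)
    u <- (seq_len(m) - 0.5) / m
    bump <- 0.5 - 0.5 * cos(2 * pi * (u - profile$center + profile$width / 2) /
                              profile$width)
    amp <- profile$amplitude[cls + 1L, ] * gains * participant$act_var *
      step_gain[k, ]
    env[idx, ] <- env[idx, ] + outer(bump, amp)
  }
  carrier <- vapply(1:3, function(j) band_limited_noise(n, fs, config$noise_sd),
                    numeric(n))
  raw <- env * carrier * rep(participant$mvc, each = n)
  structure(list(rec = emg_recording(raw, fs, stage = "raw"),
                 labels = as.integer(schedule), step = step, env = env,
                 meta = list(participant = participant,
                             terrain = config$terrain, condition = "OE",
                             trial = NA_integer_, config = config,
                             frontal = attr(schedule, "frontal"))),
            class = "emg_trial")
}

#' @export
print.emg_trial <- function(x, ...) {
  cat("<emg_trial>", x$meta$participant$id, x$meta$terrain, x$meta$condition,
      "-", length(x$labels), "samples @", x$rec$sampling_rate, "Hz\n")
  invisible(x)
}

#' Degrade a trial with the electrode-shift (ES) condition
#'
#' Replaces the displaced channel with `attenuation` times its own signal plus
#' `crosstalk` times the anatomically adjacent channel (TA's neighbour is LG;
#' MG and LG neighbour each other). Labels are unchanged; both the raw signal
#' and the stored true envelope are mixed so that noise-free analyses see the
#' same degradation.
#'
#' @param trial An `emg_trial` (raw stage).
#' @param channel Channel to displace; defaults to the participant's dominant
#'   style muscle ([dominant_muscle()]).
#' @param attenuation,crosstalk Mixing weights; default from the trial's
#'   configuration.
#' @return The degraded `emg_trial` with `meta$condition = "ES"`.
#' @export
apply_electrode_shift <- function(trial, channel = NULL, attenuation = NULL,
                                  crosstalk = NULL) {
  if (!inherits(trial, "emg_trial")) stop_config("trial must be an emg_trial")
  cfg <- trial$meta$config
  channel <- channel %||% dominant_muscle(trial$meta$participant$style)
  if (!channel %in% EMG_CHANNELS) stop_config("unknown channel '%s'", channel)
  attenuation <- attenuation %||% cfg$shift_attenuation
  crosstalk <- crosstalk %||% cfg$shift_crosstalk
  neighbour <- c(ta = "lg", mg = "lg", lg = "mg")[[channel]]
  mix <- function(mat) {
    mat[, channel] <- attenuation * mat[, channel] +
      crosstalk * mat[, neighbour]
    mat
  }
  trial$rec$data <- mix(trial$rec$data)
  trial$env <- mix(trial$env)
  trial$meta$condition <- "ES"
  trial$meta$shifted_channel <- channel
  trial
}

#' Simulate one labelled trial
#'
#' @param participant An [participant()] object.
#' @param config A [sim_config()].
#' @param profile Activation profile (generative ground truth).
#' @param seed Optional seed; `NULL` draws from the current stream.
#' @return An `emg_trial`.
#' @export
simulate_trial <- function(participant, config,
                           profile = default_activation_profile(),
                           seed = NULL) {
  with_seed(seed, {
    schedule <- phase_schedule(config, participant$speed_factor)
    synthesize_emg(schedule, participant, config, profile)
  })
}

#' Simulate a corpus of trials over participants and terrains
#'
#' @param participants List of [participant()] objects.
#' @param config A [sim_config()]; its `terrain` field is overridden per
#'   terrain in `terrains`.
#' @param terrains Terrains to simulate for every participant.
#' @param n_trials Trials per participant and terrain.
#' @param profile Activation profile.
#' @param seed Optional seed for the whole corpus.
#' @return A flat list of `emg_trial` objects (class `emg_corpus`).
#' @export
simulate_corpus <- function(participants, config,
                            terrains = c("level_ground", "uneven"),
                            n_trials = config$n_trials,
                            profile = default_activation_profile(),
                            seed = NULL) {
  with_seed(seed, {
    out <- list()
    for (p in participants) {
      for (terr in terrains) {
        cfg <- config
        cfg$terrain <- terr
        for (t in seq_len(n_trials)) {
          tr <- simulate_trial(p, cfg, profile)
          tr$meta$trial <- t
          out[[length(out) + 1L]] <- tr
        }
      }
    }
    structure(out, class = "emg_corpus")
  })
}

#' Build a set of simulated participants
#'
#' @param styles Character vector of walking styles, one participant each.
#' @param config A [sim_config()].
#' @param prefix Identifier prefix.
#' @param seed Optional seed.
#' @return List of `emg_participant` objects.
#' @export
make_participants <- function(styles, config = sim_config(), prefix = "P",
                              seed = NULL) {
  with_seed(seed, {
    lapply(seq_along(styles), function(i) {
      participant(sprintf("%s%02d", prefix, i), styles[i], config)
    })
  })
}

#' Write and read a trial as CSV
#'
#' The on-disk format is a plain UTF-8 CSV with header
#' `time_s,ta,mg,lg,label`; labels are 1-5 for the motion classes and 0 for
#' swing. Values are written with 10 significant digits, so writing the same
#' trial twice is byte-identical.
#'
#' @param trial An `emg_trial` (raw stage).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(trial, path) {
  if (!inherits(trial, "emg_trial")) stop_config("trial must be an emg_trial")
  fs <- trial$rec$sampling_rate
  n <- nrow(trial$rec$data)
  num <- function(x) formatC(x, digits = 10, format = "g")
  lines <- paste(num((seq_len(n) - 1) / fs),
                 num(trial$rec$data[, "ta"]),
                 num(trial$rec$data[, "mg"]),
                 num(trial$rec$data[, "lg"]),
                 trial$labels, sep = ",")
  writeLines(c("time_s,ta,mg,lg,label", lines), path)
  invisible(path)
}

#' @rdname write_trial_csv
#' @param sampling_rate Optional sampling rate; inferred from the time column
#'   when omitted.
#' @return For `read_trial_csv`, an `emg_trial` with raw-stage recording,
#'   labels, and minimal metadata (no true envelope).
#' @export
read_trial_csv <- function(path, sampling_rate = NULL) {
  df <- utils::read.csv(path)
  need <- c("time_s", "ta", "mg", "lg", "label")
  if (!all(need %in% names(df))) {
    stop_config("trial CSV must have columns %s", paste(need, collapse = ","))
  }
  fs <- sampling_rate %||% 1 / stats::median(diff(df$time_s))
  raw <- as.matrix(df[, EMG_CHANNELS])
  structure(list(rec = emg_recording(raw, fs, stage = "raw"),
                 labels = as.integer(df$label), step = NULL, env = NULL,
                 meta = list(source = path, condition = NA_character_,
                             terrain = NA_character_)),
            class = "emg_trial")
}

#' Write and read a batch manifest
#'
#' The manifest is a JSON file listing participants (id, style, MVC, speed
#' factor) and their trial CSV paths, plus the master seed.
#'
#' @param corpus An `emg_corpus`.
#' @param dir Directory that receives one CSV per trial plus
#'   `manifest.json`.
#' @param seed Seed recorded in the manifest.
#' @return The manifest path, invisibly.
#' @export
write_manifest <- function(corpus, dir, seed = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- lapply(seq_along(corpus), function(i) {
    tr <- corpus[[i]]
    p <- tr$meta$participant
    file <- sprintf("trial_%s_%s_%s_%02d.csv", p$id, tr$meta$terrain,
                    tr$meta$condition, tr$meta$trial %||% i)
    write_trial_csv(tr, file.path(dir, file))
    list(participant = p$id, style = p$style, mvc = as.list(p$mvc),
         speed_factor = p$speed_factor, terrain = tr$meta$terrain,
         condition = tr$meta$condition, trial = tr$meta$trial, file = file)
  })
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(seed = seed, trials = entries), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_manifest
#' @param path Path to a `manifest.json`.
#' @return For `read_manifest`, the parsed manifest list.
#' @export
read_manifest <- function(path) {
  jsonlite::read_json(path, simplifyVector = FALSE)
}
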