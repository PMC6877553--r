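#' Configuration for the synthetic gait EMG generator
#'
#' Bundles every tunable of the simulator: acquisition parameters, gait
#' timing, terrain behaviour, walking-style gains, the electrode-shift
#' degradation model, and the carrier-noise scale. The same configuration
#' with the same seed always reproduces an identical recording.
#'
#' @param sampling_rate Sampling rate in Hz. Must exceed 900 Hz so the
#'   20--450 Hz carrier band is representable.
#' @param cycle_duration Nominal gait cycle duration in seconds.
#' @param n_steps Gait cycles per trial.
#' @param n_trials Trials per participant and terrain.
#' @param terrain `"level_ground"` or `"uneven"`.
#' @param frontal_event_prob Per-step probability, on uneven terrain, that
#'   mid-stance is replaced by a frontal-plane event (eversion or inversion,
#'   alternating across event steps). On uneven trials with at least 10 steps
#'   a minimum of two event steps is guaranteed so both frontal classes occur.
#' @param style_gains Named list mapping each walking style to per-muscle
#'   multiplicative envelope gains; see [default_style_gains()].
#' @param shift_attenuation Gain applied to the displaced channel's own signal
#'   under the electrode-shift (ES) condition.
#' @param shift_crosstalk Fraction of the anatomically adjacent channel mixed
#'   into the displaced channel under ES.
#' @param noise_sd Standard deviation of the band-limited carrier noise.
#' @param participant_sd Log-scale SD of per-participant, per-muscle
#'   activation variability.
#' @param step_sd Log-scale SD of per-step amplitude jitter, one value per
#'   terrain; uneven terrain is noisier.
#' @param tonic Baseline envelope level (MVC fraction) always present.
#' @param window_s Analysis window length in seconds (used downstream).
#' @param seed Optional default seed recorded in the configuration.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(sampling_rate = 2000, cycle_duration = 1.1,
                       n_steps = 10, n_trials = 8,
                       terrain = "level_ground", frontal_event_prob = 0.5,
                       style_gains = default_style_gains(),
                       shift_attenuation = 0.6, shift_crosstalk = 0.25,
                       noise_sd = 1, participant_sd = 0.08,
                       step_sd = c(level_ground = 0.05, uneven = 0.12),
                       tonic = 0.02, window_s = 0.150, seed = NULL) {
  if (!is.numeric(sampling_rate) || sampling_rate <= 900) {
    stop_config("sampling_rate must exceed 900 Hz (got %s)", sampling_rate)
  }
  if (!terrain %in% c("level_ground", "uneven")) {
    stop_config("terrain must be 'level_ground' or 'uneven' (got '%s')", terrain)
  }
  if (frontal_event_prob < 0 || frontal_event_prob > 1) {
    stop_config("frontal_event_prob must lie in [0, 1]")
  }
  if (any(unlist(style_gains) <= 0)) stop_config("all style gains must be > 0")
  if (shift_attenuation < 0 || shift_crosstalk < 0) {
    stop_config("shift parameters must be non-negative")
  }
  if (noise_sd <= 0) stop_config("noise_sd must be > 0")
  if (cycle_duration <= 0 || n_steps < 1 || n_trials < 1) {
    stop_config("cycle_duration, n_steps and n_trials must be positive")
  }
  structure(list(sampling_rate = sampling_rate, cycle_duration = cycle_duration,
                 n_steps = as.integer(n_steps), n_trials = as.integer(n_trials),
                 terrain = terrain, frontal_event_prob = frontal_event_prob,
                 style_gains = style_gains,
                 shift_attenuation = shift_attenuation,
                 shift_crosstalk = shift_crosstalk, noise_sd = noise_sd,
                 participant_sd = participant_sd, step_sd = step_sd,
                 tonic = tonic, window_s = window_s, seed = seed),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$sampling_rate, "Hz,", x$n_steps, "steps x",
      x$n_trials, "trials,", x$terrain, "\n")
  invisible(x)
}

#' Default per-style envelope gains
#'
#' A hyper style scales the named muscle's activation envelope by `hyper`;
#' a moderate style by `moderate`; the optimum style applies unit gains.
#' The defaults keep the styles separable from the optimum pattern yet
#' overlapping with the simulator's participant-level variability.
#'
#' @param hyper Gain for hyper styles.
#' @param moderate Gain for moderate styles.
#' @return Named list of per-muscle gain vectors, one per walking style.
#' @export
default_style_gains <- function(hyper = 1.8, moderate = 1.35) {
  g <- function(ta = 1, mg = 1, lg = 1) c(ta = ta, mg = mg, lg = lg)
  list(hyper_ta = g(ta = hyper), hyper_mg = g(mg = hyper),
       hyper_lg = g(lg = hyper), moderate_mg = g(mg = moderate),
       moderate_lg = g(lg = moderate), optimum = g())
}

#' Default activation profile used as generative ground truth
#'
#' Per motion class and muscle, the peak envelope amplitude (fraction of MVC)
#' of a raised-cosine activation bump spanning the labelled sub-phase
#' (`center`/`width` are in sub-phase-relative units). Amplitudes follow the
#' qualitative muscle-activation expectations of the deterministic rule
#' classifier's design table: e.g. dorsiflexion has TA maximal and MG minimal,
#' plantarflexion has TA minimal and MG maximal, eversion has TA maximal with
#' LG above MG, inversion has TA maximal with MG above LG.
#'
#' @param tonic Baseline envelope level added to every muscle at all times.
#' @return An object of class `activation_profile` with an `amplitude` matrix
#'   (rows: class codes 0 (swing) through 5), `tonic`, `center`, `width`.
#' @export
default_activation_profile <- function(tonic = 0.02) {
  amp <- rbind(
    swing          = c(ta = 0.25, mg = 0.03, lg = 0.03),
    dorsiflexion   = c(ta = 0.75, mg = 0.05, lg = 0.20),
    foot_flat      = c(ta = 0.55, mg = 0.30, lg = 0.10),
    plantarflexion = c(ta = 0.08, mg = 0.75, lg = 0.45),
    eversion       = c(ta = 0.70, mg = 0.08, lg = 0.35),
    inversion      = c(ta = 0.70, mg = 0.35, lg = 0.08))
  structure(list(amplitude = amp, tonic = tonic, center = 0.5, width = 1),
            class = "activation_profile")
}

#' Create a simulated participant
#'
#' Draws per-muscle maximum voluntary contraction (MVC) amplitudes and a
#' per-muscle activation variability factor from the current RNG stream.
#'
#' @param id Participant identifier.
#' @param style One of [walking_styles()].
#' @param config A [sim_config()] (supplies `participant_sd`).
#' @param mvc Optional fixed per-muscle MVC amplitudes (arbitrary units, > 0).
#' @param speed_factor Unitless multiplier on the cycle duration.
#' @return An object of class `emg_participant`.
#' @export
participant <- function(id, style, config = sim_config(), mvc = NULL,
                        speed_factor = 1) {
  if (!style %in% WALKING_STYLES) {
    stop_config("unknown walking style '%s'", style)
  }
  mvc <- mvc %||% stats::runif(3, 0.8, 1.2)
  mvc <- stats::setNames(as.numeric(mvc), EMG_CHANNELS)
  if (any(mvc <= 0)) stop_config("mvc must be > 0 for all muscles")
  act_var <- stats::setNames(stats::rlnorm(3, 0, config$participant_sd),
                             EMG_CHANNELS)
  structure(list(id = as.character(id), style = style, mvc = mvc,
                 speed_factor = speed_factor, act_var = act_var),
            class = "emg_participant")
}

#' Muscle displaced under the electrode-shift condition for a style
#'
#' The displaced electrode is the one over the participant's dominant
#' style muscle; optimum-style walkers have the MG electrode displaced.
#'
#' @param style One of [walking_styles()].
#' @return A channel name (`"ta"`, `"mg"` or `"lg"`).
#' @export
dominant_muscle <- function(style) {
  switch(style,
         hyper_ta = "ta", hyper_mg = "mg", hyper_lg = "lg",
         moderate_mg = "mg", moderate_lg = "lg", optimum = "mg",
         stop_config("unknown walking style '%s'", style))
}
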