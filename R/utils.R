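# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Sets the RNG seed, evaluates `code`, and restores the caller's RNG state so
#' that seeded helpers do not disturb an enclosing simulation stream. A `NULL`
#' seed evaluates `code` against the current stream unchanged.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

stop_config <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("emgintent_config_error", "error")))
}

stop_stage <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("emgintent_stage_error", "error")))
}

EMG_CHANNELS <- c("ta", "mg", "lg")

MOTION_CLASSES <- c(dorsiflexion = 1L, foot_flat = 2L, plantarflexion = 3L,
                    eversion = 4L, inversion = 5L)

SWING <- 0L

WALKING_STYLES <- c("hyper_ta", "hyper_mg", "hyper_lg",
                    "moderate_mg", "moderate_lg", "optimum")

FEATURE_NAMES <- c("var", "wl", "iemg", "ar", "rms", "mav")

#' Channel, class, and style enumerations
#'
#' The three recorded muscles (tibialis anterior, medial gastrocnemius,
#' lateral gastrocnemius), the five stance motion classes (code 0 is the
#' swing sentinel, never a classifier output), and the six walking styles.
#'
#' @return A character or named integer vector.
#' @export
emg_channels <- function() EMG_CHANNELS

#' @rdname emg_channels
#' @export
motion_classes <- function() MOTION_CLASSES

#' @rdname emg_channels
#' @export
walking_styles <- function() WALKING_STYLES
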