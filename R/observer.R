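#' A simulated subject for the candy-catching task
#'
#' An observer responds on each trial with a linear blend of the splash
#' centroid and the prior mean, `w * c + (1 - w) * mu`, plus Gaussian
#' motor noise, except on lapse trials where no task-driven response is
#' produced. The reliance weight `w` may differ per condition (a Bayesian
#' subject tracks the condition's uncertainties) or be one constant (a
#' heuristic subject); both are first-class.
#'
#' @param subject_id Identifier (coerced to character).
#' @param group Group label, typically `"CP"` or `"TD"`.
#' @param age Age in years.
#' @param weights Either a single weight in [0, 1] applied to every
#'   condition, or a named numeric vector with one weight per condition
#'   label of the design (names as in `conditions(design)$condition`).
#' @param motor_noise_sd SD of additive response noise (screen widths).
#' @param lapse_rate Probability that a trial is a lapse.
#' @param lapse_mode What a lapse looks like: `"net_init"` (the subject
#'   leaves the net at its random initial position — the default, so that
#'   downstream exclusion logic is exercised by realistic-looking rows) or
#'   `"timeout"` (no response within the window; recorded as missing).
#' @param match_id Optional pairing identifier for age-matched designs.
#' @return An object of class `observer`.
#' @seealso [simulate_cohort()], [simulate_response()]
#' @export
observer <- function(subject_id, group = "TD", age = 8,
                     weights = 0.8, motor_noise_sd = 0.03,
                     lapse_rate = 0,
                     lapse_mode = c("net_init", "timeout"),
                     match_id = NA_character_) {
  lapse_mode <- match.arg(lapse_mode)
  if (!is.numeric(weights) || anyNA(weights) ||
      any(weights < 0) || any(weights > 1))
    stop("'weights' must lie in [0, 1]", call. = FALSE)
  if (length(weights) > 1L && is.null(names(weights)))
    stop("per-condition 'weights' must be named by condition label",
         call. = FALSE)
  if (!is.numeric(lapse_rate) || lapse_rate < 0 || lapse_rate >= 1)
    stop("'lapse_rate' must lie in [0, 1)", call. = FALSE)
  if (!is.numeric(motor_noise_sd) || motor_noise_sd < 0)
    stop("'motor_noise_sd' must be non-negative", call. = FALSE)
  structure(
    list(subject_id = as.character(subject_id),
         group = as.character(group),
         age = as.numeric(age),
         weights = weights,
         motor_noise_sd = motor_noise_sd,
         lapse_rate = lapse_rate,
         lapse_mode = lapse_mode,
         match_id = as.character(match_id)),
    class = "observer")
}

#' @export
print.observer <- function(x, ...) {
  w <- if (length(x$weights) == 1L) format(x$weights) else
    paste0("per-condition (", paste(format(x$weights), collapse = ", "), ")")
  cat("Observer ", x$subject_id, " [", x$group, ", age ", format(x$age),
      "]\n  reliance weight: ", w,
      "\n  motor noise sd: ", format(x$motor_noise_sd),
      "; lapse rate: ", format(x$lapse_rate),
      " (", x$lapse_mode, ")\n", sep = "")
  invisible(x)
}

# Resolve an observer's weight for a condition label.
observer_weight <- function(obs, condition) {
  if (length(obs$weights) == 1L)
    return(rep(unname(obs$weights), length(condition)))
  w <- obs$weights[condition]
  if (anyNA(w))
    stop("observer has no weight for condition(s): ",
         paste(unique(condition[is.na(w)]), collapse = ", "), call. = FALSE)
  unname(w)
}
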