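#' Task design for the candy-catching estimation experiment
#'
#' Bundles the fixed parameters of the sensorimotor estimation task: a
#' Gaussian prior over horizontal target position, a Gaussian likelihood
#' ("splash") of `n_samples` visible dots centred on the hidden target, a
#' blocked trial schedule, and the catch rule. All positions and standard
#' deviations are in screen-width units: the screen spans [0, 1] and the
#' prior mean sits at its centre by default.
#'
#' The defaults reproduce the published design: prior SD 0.03 (Narrow) or
#' 0.1 (Wide); likelihood SD 0.025 (Narrow), 0.1 (Medium) or 0.25 (Wide);
#' 4 splash samples; 4 blocks of 120 trials blocked by prior; a 6-second
#' response window and 1-second stimulus. The net half-width of 0.01 makes
#' a uniformly placed net catch the target on about 2% of trials, the
#' task's chance level.
#'
#' @param prior_mean Mean of the target prior (screen widths).
#' @param prior_sds Named numeric vector of prior SDs, one per prior
#'   condition (names become condition labels).
#' @param likelihood_sds Named numeric vector of likelihood SDs, one per
#'   likelihood condition.
#' @param n_samples Number of splash dots shown per trial.
#' @param n_blocks,trials_per_block Schedule dimensions.
#' @param net_halfwidth Half-width of the catching net (screen widths); a
#'   trial is caught when |response - target| <= net_halfwidth.
#' @param response_window,stimulus_duration Timing, in seconds (metadata;
#'   the simulator does not model reaction times).
#'
#' @return An object of class `task_design`.
#' @examples
#' d <- task_design()
#' conditions(d)
#' @seealso [conditions()], [optimal_slope()], [chance_level()]
#' @export
task_design <- function(prior_mean = 0.5,
                        prior_sds = c(Narrow = 0.03, Wide = 0.1),
                        likelihood_sds = c(Narrow = 0.025, Medium = 0.1,
                                           Wide = 0.25),
                        n_samples = 4L,
                        n_blocks = 4L,
                        trials_per_block = 120L,
                        net_halfwidth = 0.01,
                        response_window = 6,
                        stimulus_duration = 1) {
  if (!is.numeric(prior_mean) || length(prior_mean) != 1L ||
      prior_mean < 0 || prior_mean > 1)
    stop("'prior_mean' must be a single number in [0, 1]", call. = FALSE)
  check_positive_sd(prior_sds, "prior_sds")
  check_positive_sd(likelihood_sds, "likelihood_sds")
  if (is.null(names(prior_sds))) names(prior_sds) <- paste0("P", seq_along(prior_sds))
  if (is.null(names(likelihood_sds))) names(likelihood_sds) <- paste0("L", seq_along(likelihood_sds))
  n_samples <- as.integer(n_samples)
  if (is.na(n_samples) || n_samples < 1L)
    stop("'n_samples' must be a positive integer", call. = FALSE)
  n_blocks <- as.integer(n_blocks)
  trials_per_block <- as.integer(trials_per_block)
  if (n_blocks < 1L || trials_per_block < 1L)
    stop("'n_blocks' and 'trials_per_block' must be positive integers",
         call. = FALSE)
  if (!is.numeric(net_halfwidth) || length(net_halfwidth) != 1L ||
      net_halfwidth < 0 || net_halfwidth >= 0.5)
    stop("'net_halfwidth' must lie in [0, 0.5)", call. = FALSE)
  structure(
    list(prior_mean = prior_mean,
         prior_sds = prior_sds,
         likelihood_sds = likelihood_sds,
         n_samples = n_samples,
         n_blocks = n_blocks,
         trials_per_block = trials_per_block,
         net_halfwidth = net_halfwidth,
         response_window = response_window,
         stimulus_duration = stimulus_duration),
    class = "task_design")
}

check_positive_sd <- function(x, what) {
  if (!is.numeric(x) || length(x) < 1L || anyNA(x) || any(x <= 0))
    stop("'", what, "' must be strictly positive numbers", call. = FALSE)
  invisible(x)
}

#' @export
print.task_design <- function(x, ...) {
  cat("Candy-catching task design (screen-width units)\n")
  cat("  prior: N(", format(x$prior_mean), ", sd in {",
      paste(format(x$prior_sds), collapse = ", "), "})\n", sep = "")
  cat("  likelihood sd: {", paste(format(x$likelihood_sds), collapse = ", "),
      "}; splash of ", x$n_samples, " samples\n", sep = "")
  cat("  schedule: ", x$n_blocks, " blocks x ", x$trials_per_block,
      " trials, blocked by prior\n", sep = "")
  cat("  net half-width: ", format(x$net_halfwidth),
      "; response window: ", format(x$response_window), " s\n", sep = "")
  invisible(x)
}

#' Condition grid of a task design
#'
#' Crosses the prior and likelihood conditions of a [task_design()] into
#' the experiment's condition grid (six conditions for the default design)
#' and attaches the Bayes-optimal reliance weight for each.
#'
#' @param design A `task_design`.
#' @return A data frame with one row per condition: `prior`, `likelihood`
#'   (factor labels), `prior_sd`, `likelihood_sd`, `condition` (combined
#'   label) and `optimal` (the ideal-observer reliance weight).
#' @export
conditions <- function(design = task_design()) {
  stopifnot(inherits(design, "task_design"))
  grid <- expand.grid(likelihood = names(design$likelihood_sds),
                      prior = names(design$prior_sds),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("prior", "likelihood")]
  grid$prior_sd <- unname(design$prior_sds[grid$prior])
  grid$likelihood_sd <- unname(design$likelihood_sds[grid$likelihood])
  grid$condition <- paste(grid$prior, grid$likelihood, sep = "-")
  grid$optimal <- optimal_slope(grid$prior_sd, grid$likelihood_sd,
                                design$n_samples)
  grid$prior <- factor(grid$prior, levels = names(design$prior_sds))
  grid$likelihood <- factor(grid$likelihood,
                            levels = names(design$likelihood_sds))
  rownames(grid) <- NULL
  grid
}
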