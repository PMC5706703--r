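#' Bayes-optimal reliance on the likelihood
#'
#' For a Gaussian prior N(mu, sigma_s^2) over target position and a splash
#' of `n_samples` independent dots from N(s, sigma_l^2), the posterior mean
#' is a precision-weighted average of the prior mean and the splash
#' centroid. The weight given to the centroid,
#' \deqn{w = \sigma_s^2 / (\sigma_s^2 + \sigma_l^2 / n),}
#' is the optimal estimation slope: 1 means pure reliance on the
#' likelihood, 0 pure reliance on the prior.
#'
#' @param prior_sd,likelihood_sd Standard deviations in screen widths;
#'   strictly positive (vectorised).
#' @param n_samples Number of splash dots (>= 1).
#' @return The optimal weight(s), strictly inside (0, 1).
#' @examples
#' optimal_slope(0.03, 0.025, 4)  # narrow prior, narrow likelihood: 0.852
#' optimal_slope(0.1, 0.1, 4)     # wide prior, medium likelihood: 0.8
#' @export
optimal_slope <- function(prior_sd, likelihood_sd, n_samples = 4L) {
  if (any(!is.finite(prior_sd)) || any(prior_sd <= 0))
    stop("'prior_sd' must be strictly positive", call. = FALSE)
  if (any(!is.finite(likelihood_sd)) || any(likelihood_sd <= 0))
    stop("'likelihood_sd' must be strictly positive", call. = FALSE)
  if (any(!is.finite(n_samples)) || any(n_samples < 1))
    stop("'n_samples' must be at least 1", call. = FALSE)
  prior_sd^2 / (prior_sd^2 + likelihood_sd^2 / n_samples)
}

#' Posterior over target position given a splash centroid
#'
#' Conjugate Gaussian update: combines the prior N(mu, sigma_s^2) with the
#' centroid likelihood N(c, sigma_l^2 / n). The posterior mean is the
#' convex combination `w * centroid + (1 - w) * prior_mean` with `w` from
#' [optimal_slope()]; the posterior variance `1 / (1/sigma_s^2 +
#' n/sigma_l^2)` is smaller than either source's variance.
#'
#' @inheritParams optimal_slope
#' @param prior_mean Prior mean (screen widths).
#' @param centroid Mean of the splash dots (screen widths).
#' @return A list of class `posterior_params` with elements `mean`,
#'   `variance` and `weight`.
#' @examples
#' posterior_params(0.5, 0.1, 0.6, 0.1, 4)  # mean 0.58, variance 0.002
#' @export
posterior_params <- function(prior_mean, prior_sd, centroid,
                             likelihood_sd, n_samples = 4L) {
  w <- optimal_slope(prior_sd, likelihood_sd, n_samples)
  structure(
    list(mean = w * centroid + (1 - w) * prior_mean,
         variance = 1 / (1 / prior_sd^2 + n_samples / likelihood_sd^2),
         weight = w),
    class = "posterior_params")
}

#' @export
print.posterior_params <- function(x, ...) {
  cat("Posterior over target position: N(", format(x$mean), ", ",
      format(x$variance), ")  [likelihood weight ", format(x$weight),
      "]\n", sep = "")
  invisible(x)
}

#' Centroid of a splash
#'
#' The arithmetic mean of the splash dots — the sufficient statistic for
#' the likelihood's location.
#'
#' @param splash Numeric vector of dot positions (screen widths), or a
#'   matrix with one trial per row.
#' @return The mean position; for a matrix, one centroid per row.
#' @export
splash_centroid <- function(splash) {
  if (is.matrix(splash)) {
    if (ncol(splash) < 1L || nrow(splash) < 1L)
      stop("empty splash", call. = FALSE)
    return(rowMeans(splash))
  }
  if (length(splash) < 1L) stop("empty splash", call. = FALSE)
  mean(splash)
}

#' Chance-level catch probability
#'
#' Monte-Carlo estimate of the probability that a net placed uniformly at
#' random on the screen catches a target drawn from the prior — the
#' performance floor a non-responding or randomly responding subject
#' attains. With the default net half-width of 0.01 this is about 2%.
#'
#' The wider prior condition is used (any prior SD well inside the screen
#' gives the same answer to within Monte-Carlo error, since the catch
#' probability is essentially 2 * net_halfwidth whenever the target is
#' more than a net-width away from the screen edges).
#'
#' @param design A [task_design()].
#' @param n_mc Number of Monte-Carlo trials.
#' @param seed Optional integer seed for reproducibility.
#' @return Estimated catch probability.
#' @export
chance_level <- function(design = task_design(), n_mc = 1e5, seed = NULL) {
  stopifnot(inherits(design, "task_design"))
  n_mc <- as.integer(n_mc)
  if (is.na(n_mc) || n_mc < 1L) stop("'n_mc' must be >= 1", call. = FALSE)
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_rng(old), add = TRUE)
    set.seed(seed)
  }
  sd_wide <- max(design$prior_sds)
  target <- stats::rnorm(n_mc, design$prior_mean, sd_wide)
  net <- stats::runif(n_mc)
  mean(abs(net - target) <= design$net_halfwidth)
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
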