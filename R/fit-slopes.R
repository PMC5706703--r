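#' Through-origin estimation-slope for one subject and condition
#'
#' The estimation slope measures a subject's reliance on the likelihood:
#' responses and splash centroids are centred at the prior mean (the
#' subject is assumed to have learned the prior's mean) and a
#' least-squares line through the origin is fitted,
#' \deqn{slope = \sum_i (c_i - \mu)(\hat s_i - \mu) / \sum_i (c_i - \mu)^2.}
#' A slope of 1 means the subject tracks the centroid; 0 means responses
#' ignore the splash and sit at the prior mean. Trials with a missing
#' response (timeouts) are excluded.
#'
#' @param centroid Splash centroids, one per trial.
#' @param response Responses; `NA` marks a timeout.
#' @param prior_mean The prior mean used for centring.
#' @param intercept If `TRUE`, fit a free intercept instead of centring
#'   through the origin (the slope is then the ordinary regression slope).
#' @return The fitted slope (a dimensionless weight).
#' @export
fit_slope <- function(centroid, response, prior_mean = 0.5,
                      intercept = FALSE) {
  keep <- !is.na(response)
  if (sum(keep) < 2L)
    stop("need at least 2 non-missing trials to fit a slope", call. = FALSE)
  x <- centroid[keep] - prior_mean
  y <- response[keep] - prior_mean
  if (intercept) {
    x <- x - mean(x)
    y <- y - mean(y)
  }
  sxx <- sum(x^2)
  if (sxx < .Machine$double.eps)
    stop("degenerate condition: centroids show no variation about the ",
         "prior mean", call. = FALSE)
  sum(x * y) / sxx
}

#' Percentile bootstrap confidence interval for an estimation slope
#'
#' Resamples trials with replacement `n_boot` times, refits the
#' through-origin slope on each resample, and returns the percentile
#' interval of the bootstrap distribution.
#'
#' @inheritParams fit_slope
#' @param n_boot Number of bootstrap resamples.
#' @param conf Confidence level.
#' @param seed Optional integer seed (the interval is deterministic given
#'   the seed).
#' @return Named numeric vector `c(ci_low, ci_high)`.
#' @export
boot_slope_ci <- function(centroid, response, prior_mean = 0.5,
                          n_boot = 1000L, conf = 0.95, seed = NULL,
                          intercept = FALSE) {
  keep <- !is.na(response)
  if (sum(keep) < 2L)
    stop("need at least 2 non-missing trials to bootstrap", call. = FALSE)
  x <- centroid[keep] - prior_mean
  y <- response[keep] - prior_mean
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_rng(old), add = TRUE)
    set.seed(seed)
  }
  n <- length(x)
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
  xb <- matrix(x[idx], nrow = n)
  yb <- matrix(y[idx], nrow = n)
  if (intercept) {
    xb <- sweep(xb, 2L, colMeans(xb))
    yb <- sweep(yb, 2L, colMeans(yb))
  }
  sxx <- colSums(xb^2)
  ok <- sxx > .Machine$double.eps
  slopes <- colSums(xb * yb)[ok] / sxx[ok]
  ci <- stats::quantile(slopes, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        names = FALSE, type = 7)
  c(ci_low = ci[1], ci_high = ci[2])
}

#' Proportion of targets caught
#'
#' Task performance p(correct): the proportion of trials on which the net
#' caught the target. Timeout trials (missing response) count as misses —
#' they enter the denominator.
#'
#' @param caught Logical vector of catch outcomes; `NA` marks a timeout.
#' @return Proportion caught, in [0, 1].
#' @export
p_correct <- function(caught) {
  if (length(caught) < 1L) stop("no trials", call. = FALSE)
  mean(caught %in% TRUE)
}

#' Fit estimation slopes for a cohort of subjects
#'
#' The package's central model fit. For every subject x condition cell it
#' fits the through-origin estimation slope of responses on splash
#' centroids (both centred at the prior mean), attaches a percentile
#' bootstrap confidence interval and the condition's Bayes-optimal weight,
#' and summarises each subject's task performance p(correct).
#'
#' Trials from the two blocks sharing a prior condition are pooled, so
#' each subject contributes one slope per condition (six for the default
#' design). Timeouts are excluded from the slope fits but count as misses
#' in p(correct). No outlier rejection is applied by default; set
#' `screen_filter = TRUE` to drop responses outside [0, 1].
#'
#' @param trials A trial data frame as produced by [simulate_cohort()] or
#'   [read_trials()].
#' @param design The [task_design()] the data came from (supplies the
#'   prior mean, condition labels and net width). Defaults to the design
#'   attached to `trials`, else the standard design.
#' @param n_boot Bootstrap resamples per cell (0 disables the CIs).
#' @param conf Confidence level for the bootstrap intervals.
#' @param seed Integer seed governing all bootstrap resampling.
#' @param intercept Fit a free intercept instead of centring through the
#'   origin.
#' @param screen_filter Drop responses outside the screen before fitting.
#' @return An object of class `estimation_fit`: a list with
#'   \describe{
#'     \item{slopes}{data frame of subject x condition slope estimates
#'       (`subject_id`, `group`, `prior`, `likelihood`, `condition`,
#'       `slope`, `ci_low`, `ci_high`, `optimal`, `n_trials_used`).}
#'     \item{performance}{data frame of per-subject p(correct).}
#'     \item{design}{the task design used.}
#'   }
#'   Supported methods: `print`, `summary`, `coef`, `predict`,
#'   `residuals`, `plot`, `simulate`.
#' @examples
#' trials <- simulate_cohort(n_per_group = 2, seed = 42)
#' fit <- estimation_fit(trials, n_boot = 200, seed = 1)
#' coef(fit)
#' summary(fit)
#' @export
estimation_fit <- function(trials, design = NULL, n_boot = 1000L,
                           conf = 0.95, seed = NULL, intercept = FALSE,
                           screen_filter = FALSE) {
  if (is.null(design)) design <- attr(trials, "design")
  if (is.null(design)) design <- task_design()
  stopifnot(inherits(design, "task_design"))
  trials <- as.data.frame(trials)
  need <- c("subject_id", "prior_sd", "likelihood_sd", "response")
  miss <- setdiff(need, names(trials))
  if (length(miss))
    stop("trial table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  splash_cols <- grep("^splash_[0-9]+$", names(trials), value = TRUE)
  if (length(splash_cols) < 1L)
    stop("trial table has no splash_* columns", call. = FALSE)
  mu <- design$prior_mean
  cond <- conditions(design)
  trials$.centroid <- rowMeans(as.matrix(trials[, splash_cols]))
  if (screen_filter) {
    off <- !is.na(trials$response) &
      (trials$response < 0 | trials$response > 1)
    trials$response[off] <- NA
  }
  # match each trial to its condition row by the SD pair
  key <- paste(signif(trials$prior_sd, 8), signif(trials$likelihood_sd, 8))
  ckey <- paste(signif(cond$prior_sd, 8), signif(cond$likelihood_sd, 8))
  ci <- match(key, ckey)
  if (anyNA(ci))
    stop("trials contain (prior_sd, likelihood_sd) pairs not in the design",
         call. = FALSE)
  trials$.cond <- ci

  subjects <- unique(trials$subject_id)
  has_group <- "group" %in% names(trials)
  rows <- vector("list", length(subjects) * nrow(cond))
  perf <- vector("list", length(subjects))
  r <- 0L
  for (si in seq_along(subjects)) {
    s <- subjects[si]
    st <- trials[trials$subject_id == s, ]
    grp <- if (has_group) st$group[1L] else NA_character_
    perf[[si]] <- data.frame(subject_id = s, group = grp,
                             p_correct = p_correct(if ("caught" %in% names(st))
                               st$caught else
                                 !is.na(st$response) &
                                 abs(st$response - st$target) <=
                                 design$net_halfwidth),
                             n_trials = nrow(st),
                             stringsAsFactors = FALSE)
    for (k in seq_len(nrow(cond))) {
      ct <- st[st$.cond == k, ]
      if (nrow(ct) == 0L) next
      r <- r + 1L
      used <- sum(!is.na(ct$response))
      slope <- ci_low <- ci_high <- NA_real_
      if (used >= 2L) {
        slope <- fit_slope(ct$.centroid, ct$response, mu,
                           intercept = intercept)
        if (n_boot > 0L) {
          bs <- boot_slope_ci(ct$.centroid, ct$response, mu,
                              n_boot = n_boot, conf = conf,
                              seed = if (is.null(seed)) NULL else
                                subject_seed(seed, 1000L * si + k),
                              intercept = intercept)
          ci_low <- bs[["ci_low"]]
          ci_high <- bs[["ci_high"]]
        }
      }
      rows[[r]] <- data.frame(subject_id = s, group = grp,
                              prior = as.character(cond$prior[k]),
                              likelihood = as.character(cond$likelihood[k]),
                              condition = cond$condition[k],
                              slope = slope, ci_low = ci_low,
                              ci_high = ci_high,
                              optimal = cond$optimal[k],
                              n_trials_used = used,
                              stringsAsFactors = FALSE)
    }
  }
  slopes <- do.call(rbind, rows[seq_len(r)])
  slopes$prior <- factor(slopes$prior, levels = levels(cond$prior))
  slopes$likelihood <- factor(slopes$likelihood,
                              levels = levels(cond$likelihood))
  structure(
    list(slopes = slopes,
         performance = do.call(rbind, perf),
         design = design,
         call = match.call(),
         intercept = intercept,
         n_boot = n_boot, conf = conf, seed = seed,
         trials = trials[, setdiff(names(trials), ".cond")]),
    class = "estimation_fit")
}

#' @export
print.estimation_fit <- function(x, ...) {
  ns <- length(unique(x$slopes$subject_id))
  cat("Estimation-slope fit: ", ns, " subject(s), ",
      nrow(x$slopes), " subject x condition slopes\n", sep = "")
  cat("Through-origin regression about prior mean ",
      format(x$design$prior_mean),
      if (x$intercept) " (free intercept)" else "", "\n", sep = "")
  if (x$n_boot > 0)
    cat("Bootstrap: ", x$n_boot, " resamples, ",
        round(100 * x$conf), "% percentile CIs\n", sep = "")
  cat("\nMean slope by condition (vs optimal):\n")
  agg <- stats::aggregate(slope ~ condition + optimal, data = x$slopes,
                          FUN = mean)
  agg <- agg[order(-agg$optimal), c("condition", "slope", "optimal")]
  print(format(agg, digits = 3), row.names = FALSE)
  invisible(x)
}

#' @export
coef.estimation_fit <- function(object, ...) {
  s <- object$slopes
  subjects <- unique(s$subject_id)
  conds <- unique(s$condition)
  m <- matrix(NA_real_, length(subjects), length(conds),
              dimnames = list(subjects, conds))
  m[cbind(match(s$subject_id, subjects), match(s$condition, conds))] <- s$slope
  m
}

#' @export
summary.estimation_fit <- function(object, ...) {
  s <- object$slopes
  by_grp <- !all(is.na(s$group))
  f <- if (by_grp) slope ~ group + condition + optimal else
    slope ~ condition + optimal
  tab <- stats::aggregate(f, data = s, FUN = function(v)
    c(mean = mean(v), sd = stats::sd(v), n = length(v)))
  tab <- do.call(data.frame, tab)
  names(tab) <- sub("^slope\\.", "", names(tab))
  perf <- object$performance
  pf <- if (by_grp)
    stats::aggregate(p_correct ~ group, perf, function(v)
      c(median = stats::median(v), mean = mean(v)))
  else data.frame(median = stats::median(perf$p_correct),
                  mean = mean(perf$p_correct))
  structure(list(slopes = tab, performance = do.call(data.frame, pf),
                 n_subjects = length(unique(s$subject_id))),
            class = "summary.estimation_fit")
}

#' @export
print.summary.estimation_fit <- function(x, ...) {
  cat("Estimation slopes by condition (", x$n_subjects, " subjects):\n",
      sep = "")
  print(format(x$slopes, digits = 3), row.names = FALSE)
  cat("\nTask performance p(correct):\n")
  print(format(x$performance, digits = 3), row.names = FALSE)
  invisible(x)
}

# fitted responses for a trial table, from the per-cell slopes
fitted_responses <- function(object, trials) {
  mu <- object$design$prior_mean
  splash_cols <- grep("^splash_[0-9]+$", names(trials), value = TRUE)
  cen <- if (".centroid" %in% names(trials)) trials$.centroid else
    rowMeans(as.matrix(trials[, splash_cols]))
  cond <- conditions(object$design)
  key <- paste(signif(trials$prior_sd, 8), signif(trials$likelihood_sd, 8))
  ckey <- paste(signif(cond$prior_sd, 8), signif(cond$likelihood_sd, 8))
  lab <- cond$condition[match(key, ckey)]
  s <- object$slopes
  idx <- match(paste(trials$subject_id, lab),
               paste(s$subject_id, s$condition))
  mu + s$slope[idx] * (cen - mu)
}

#' @export
predict.estimation_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$trials
  fitted_responses(object, as.data.frame(newdata))
}

#' @export
residuals.estimation_fit <- function(object, ...) {
  object$trials$response - fitted_responses(object, object$trials)
}

#' Simulate cohorts from a fitted estimation model
#'
#' Parametric resimulation: each subject is rebuilt as an [observer()]
#' whose per-condition weights are the fitted slopes (clamped to [0, 1])
#' and whose motor noise is the subject's residual standard deviation;
#' fresh sessions are then simulated. Useful for parametric-bootstrap
#' checks of downstream statistics.
#'
#' @param object An `estimation_fit`.
#' @param nsim Number of simulated cohorts.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return A list of `nsim` trial data frames.
#' @export
simulate.estimation_fit <- function(object, nsim = 1, seed = NULL, ...) {
  res <- residuals(object)
  s <- object$slopes
  subjects <- unique(s$subject_id)
  out <- vector("list", nsim)
  base_seed <- if (is.null(seed)) sample.int(2^30, 1) else seed
  for (i in seq_len(nsim)) {
    sims <- lapply(seq_along(subjects), function(si) {
      sub <- subjects[si]
      ss <- s[s$subject_id == sub, ]
      w <- clamp01(ss$slope)
      names(w) <- ss$condition
      rsd <- stats::sd(res[object$trials$subject_id == sub], na.rm = TRUE)
      obs <- observer(subject_id = sub, group = ss$group[1L],
                      weights = w,
                      motor_noise_sd = if (is.finite(rsd)) rsd else 0)
      simulate_subject(obs, object$design,
                       seed = subject_seed(base_seed, 1000L * i + si))
    })
    out[[i]] <- do.call(rbind, sims)
  }
  out
}

#' Plot estimation slopes against the ideal observer
#'
#' Mean fitted slope per condition (with the spread across subjects) for
#' each group, alongside the Bayes-optimal slope of every condition.
#'
#' @param x An `estimation_fit`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.estimation_fit <- function(x, ...) {
  s <- x$slopes
  cond <- conditions(x$design)
  groups <- unique(stats::na.omit(s$group))
  if (length(groups) == 0L) groups <- NA
  xi <- seq_len(nrow(cond))
  graphics::plot(xi, cond$optimal, type = "b", pch = 5, lty = 2,
                 col = "red3", ylim = c(0, 1), xaxt = "n",
                 xlab = "Condition", ylab = "Estimation slope", ...)
  graphics::axis(1, at = xi, labels = cond$condition, las = 2,
                 cex.axis = 0.7)
  cols <- c("black", "dodgerblue3", "darkgreen")
  for (gi in seq_along(groups)) {
    sel <- if (is.na(groups[gi])) s else s[s$group %in% groups[gi], ]
    m <- vapply(cond$condition, function(cc)
      mean(sel$slope[sel$condition == cc], na.rm = TRUE), numeric(1))
    se <- vapply(cond$condition, function(cc) {
      v <- sel$slope[sel$condition == cc]
      stats::sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v)))
    }, numeric(1))
    graphics::points(xi, m, type = "b", pch = 19, col = cols[gi])
    graphics::arrows(xi, m - 1.96 * se, xi, m + 1.96 * se, angle = 90,
                     code = 3, length = 0.03, col = cols[gi])
  }
  graphics::legend("topright", bty = "n",
                   legend = c(paste("group", groups), "optimal"),
                   col = c(cols[seq_along(groups)], "red3"),
                   pch = c(rep(19, length(groups)), 5),
                   lty = c(rep(1, length(groups)), 2))
  invisible(x)
}
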