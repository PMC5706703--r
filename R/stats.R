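#' Wilcoxon signed-rank test with exact small-sample p-values
#'
#' Signed-rank test for paired data or a one-sample location shift. Zero
#' differences are dropped; absolute differences are ranked with average
#' ranks for ties. The reported statistic is
#' \eqn{W = } the sum of the ranks of the *negative* differences (the
#' convention under which nine positive differences give W = 0), so small
#' W is evidence for a positive shift.
#'
#' For up to `exact_limit` nonzero differences the null distribution of W
#' is computed exactly over all 2^m equiprobable sign assignments (ties
#' included); beyond that a normal approximation with tie correction and
#' continuity correction is used.
#'
#' @param x Numeric vector (differences, or first sample).
#' @param y Optional second sample for a paired test (`x - y` is used).
#' @param mu Null location of the differences.
#' @param alternative `"two.sided"`, `"greater"` (location > mu) or
#'   `"less"`.
#' @param mode `"auto"` (exact when m <= `exact_limit`), `"exact"` or
#'   `"approx"`.
#' @param exact_limit Largest m for which the exact distribution is used
#'   in `"auto"` mode.
#' @return An object of class `catch_test` with fields `name`,
#'   `statistic` (W), `df` (`NA`), `p_value`, `p_adjusted` (`NA` until
#'   adjusted) and `method_notes`.
#' @examples
#' wilcoxon_signed_rank(rep(0.1, 9))  # W = 0, two-sided p = 2/512
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, mu = 0,
                                 alternative = c("two.sided", "greater",
                                                 "less"),
                                 mode = c("auto", "exact", "approx"),
                                 exact_limit = 20L) {
  alternative <- match.arg(alternative)
  mode <- match.arg(mode)
  d <- if (is.null(y)) x - mu else (x - y) - mu
  d <- d[!is.na(d)]
  d <- d[d != 0]
  m <- length(d)
  if (m < 1L)
    stop("all differences are zero or missing", call. = FALSE)
  r <- rank(abs(d))
  W <- sum(r[d < 0])
  use_exact <- mode == "exact" || (mode == "auto" && m <= exact_limit)
  if (use_exact) {
    # exact null distribution of the negative-rank sum over all 2^m sign
    # assignments, via convolution on doubled (integer) ranks
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    f <- numeric(total + 1L)  # f[k+1] = #assignments with doubled sum k
    f[1L] <- 1
    for (ri in r2) {
      g <- numeric(total + 1L)
      g[(ri + 1L):(total + 1L)] <- f[1L:(total + 1L - ri)]
      f <- f + g
    }
    probs <- f / 2^m
    W2 <- round(2 * W)
    p_le <- sum(probs[seq_len(W2 + 1L)])
    p_ge <- sum(probs[(W2 + 1L):(total + 1L)])
    method <- sprintf("exact enumeration of 2^%d sign assignments", m)
  } else {
    mean_W <- m * (m + 1) / 4
    tie_tab <- table(r)
    var_W <- m * (m + 1) * (2 * m + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    cc <- 0.5
    p_le <- stats::pnorm((W - mean_W + cc) / sqrt(var_W))
    p_ge <- stats::pnorm((W - mean_W - cc) / sqrt(var_W),
                         lower.tail = FALSE)
    method <- "normal approximation with tie and continuity correction"
  }
  p <- switch(alternative,
              greater = p_le,
              less = p_ge,
              two.sided = min(1, 2 * min(p_le, p_ge)))
  new_catch_test(name = "Wilcoxon signed-rank",
                 statistic = W, df = NA_real_, p_value = p,
                 method_notes = paste0(method, "; alternative = ",
                                       alternative, "; m = ", m))
}

#' Bonferroni correction for a family of p-values
#'
#' Multiplies each p-value by the number of comparisons and caps at 1
#' (via [stats::p.adjust()]).
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values, same length.
#' @export
adjust_bonferroni <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "bonferroni")
}

#' Scheirer-Ray-Hare rank test for factorial designs
#'
#' A Kruskal-Wallis-style test for crossed factorial layouts: all N
#' observations are ranked jointly (average ranks for ties), the
#' crossed-ANOVA sum-of-squares decomposition is computed on the ranks,
#' and each effect's statistic
#' \deqn{H = SS_{effect} / (SS_{total} / (N - 1))}
#' is referred to a chi-squared distribution with the effect's degrees of
#' freedom. Because the divisor is the variance of the realised ranks,
#' ties need no separate correction, and with a single factor H equals
#' the (tie-corrected) Kruskal-Wallis statistic exactly.
#'
#' The classical test is two-way; higher-order layouts (such as
#' group x prior x likelihood) use the same rank-then-ANOVA recipe. Each
#' observation is treated as independent — for the intended use (one
#' estimation slope per subject x condition) repeated measures within
#' subject are ignored, as the chi-squared reference implies.
#'
#' @param formula A formula such as `slope ~ group * prior * likelihood`
#'   (use `*` for all interactions, `+` for main effects only).
#' @param data Data frame holding the response and factor columns.
#' @return An object of class `srh` (also a data frame): one row per
#'   effect with `df`, `ss` (rank sum of squares), `H` and `p_value`.
#' @examples
#' d <- data.frame(y = rnorm(24), a = gl(2, 12), b = gl(3, 4, 24))
#' scheirer_ray_hare(y ~ a * b, d)
#' @export
scheirer_ray_hare <- function(formula, data) {
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.fail)
  y <- stats::model.response(mf)
  if (!is.numeric(y)) stop("response must be numeric", call. = FALSE)
  facs <- mf[-1L]
  if (length(facs) < 1L) stop("no factors in formula", call. = FALSE)
  facs[] <- lapply(facs, function(f) factor(f))
  # every cell of the crossed design must be populated
  cell <- interaction(facs, drop = FALSE)
  if (any(table(cell) == 0L)) {
    empty <- names(which(table(cell) == 0L))
    stop("empty design cell(s): ", paste(empty, collapse = ", "),
         call. = FALSE)
  }
  N <- length(y)
  r <- rank(y)
  dat <- data.frame(.rank = r, facs)
  rhs <- stats::terms(formula)
  f2 <- stats::reformulate(attr(rhs, "term.labels"), response = ".rank")
  aov_tab <- stats::anova(stats::lm(f2, data = dat))
  eff <- rownames(aov_tab) != "Residuals"
  ss_total <- sum(aov_tab[["Sum Sq"]])
  ms_total <- ss_total / (N - 1)
  H <- aov_tab[["Sum Sq"]][eff] / ms_total
  df <- aov_tab[["Df"]][eff]
  out <- data.frame(effect = rownames(aov_tab)[eff],
                    df = df, ss = aov_tab[["Sum Sq"]][eff],
                    H = H,
                    p_value = stats::pchisq(H, df, lower.tail = FALSE),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("srh", "data.frame")
  attr(out, "N") <- N
  attr(out, "ms_total") <- ms_total
  out
}

#' @export
print.srh <- function(x, ...) {
  cat("Scheirer-Ray-Hare rank test (N = ", attr(x, "N"), ")\n", sep = "")
  tab <- x
  tab$p_value <- format.pval(tab$p_value, digits = 3)
  print.data.frame(cbind(tab[1], round(tab[c("df", "ss", "H")], 3),
                         tab["p_value"]), row.names = FALSE)
  invisible(x)
}

new_catch_test <- function(name, statistic, df, p_value,
                           p_adjusted = NA_real_, method_notes = "") {
  structure(list(name = name, statistic = statistic, df = df,
                 p_value = p_value, p_adjusted = p_adjusted,
                 method_notes = method_notes),
            class = "catch_test")
}

#' @export
print.catch_test <- function(x, ...) {
  cat(x$name, ": statistic = ", format(x$statistic),
      if (!is.na(x$df)) paste0(", df = ", x$df) else "",
      ", p = ", format.pval(x$p_value, digits = 3),
      if (!is.na(x$p_adjusted))
        paste0(" (adjusted ", format.pval(x$p_adjusted, digits = 3), ")")
      else "", "\n  ", x$method_notes, "\n", sep = "")
  invisible(x)
}

#' Group-level inference on a fitted cohort
#'
#' Runs the analysis battery on an [estimation_fit()]:
#' \enumerate{
#'   \item each group's p(correct) against chance level (one-sided
#'     signed-rank, Bonferroni-corrected across groups);
#'   \item the between-group difference in p(correct) — by default a
#'     paired signed-rank over age-matched pairs (via `match_id`), with an
#'     unpaired Wilcoxon rank-sum as the alternative convention;
#'   \item the Scheirer-Ray-Hare test of group, prior and likelihood (all
#'     main effects and interactions) on the estimation slopes.
#' }
#'
#' @param fit An `estimation_fit` whose trials carry a `group` column.
#' @param chance Chance-level catch probability to test against.
#' @param paired Use the age-matched paired test for the group
#'   comparison; requires a `match_id` column in the trials (else falls
#'   back to unpaired with a message).
#' @param alternative Sidedness of the vs-chance tests.
#' @return A list of class `cohort_tests`: `vs_chance` (list of
#'   `catch_test`, Bonferroni-adjusted), `group_difference`
#'   (`catch_test`), `srh` (the rank-ANOVA table).
#' @export
cohort_tests <- function(fit, chance = 0.02, paired = TRUE,
                         alternative = "greater") {
  stopifnot(inherits(fit, "estimation_fit"))
  perf <- fit$performance
  if (all(is.na(perf$group)))
    stop("trials carry no 'group' column; group tests need one",
         call. = FALSE)
  groups <- sort(unique(perf$group))
  vs_chance <- lapply(groups, function(g)
    wilcoxon_signed_rank(perf$p_correct[perf$group == g], mu = chance,
                         alternative = alternative))
  names(vs_chance) <- groups
  adj <- adjust_bonferroni(vapply(vs_chance, `[[`, numeric(1), "p_value"))
  for (i in seq_along(vs_chance)) vs_chance[[i]]$p_adjusted <- adj[i]

  group_difference <- NULL
  if (length(groups) == 2L) {
    tr <- fit$trials
    has_match <- "match_id" %in% names(tr) && !anyNA(tr$match_id)
    if (paired && has_match) {
      mid <- tr$match_id[match(perf$subject_id, tr$subject_id)]
      g1 <- perf[perf$group == groups[1L], ]
      g2 <- perf[perf$group == groups[2L], ]
      m1 <- mid[perf$group == groups[1L]]
      m2 <- mid[perf$group == groups[2L]]
      pair <- match(m1, m2)
      if (anyNA(pair))
        stop("age-matched pairing incomplete: unmatched match_id values",
             call. = FALSE)
      group_difference <- wilcoxon_signed_rank(
        g1$p_correct, g2$p_correct[pair])
      group_difference$name <- paste0("Wilcoxon signed-rank (paired, ",
                                      groups[1L], " vs ", groups[2L], ")")
    } else {
      if (paired && !has_match)
        message("no complete 'match_id' pairing; using unpaired rank-sum")
      wt <- stats::wilcox.test(perf$p_correct[perf$group == groups[1L]],
                               perf$p_correct[perf$group == groups[2L]],
                               exact = FALSE)
      group_difference <- new_catch_test(
        name = paste0("Wilcoxon rank-sum (", groups[1L], " vs ",
                      groups[2L], ")"),
        statistic = unname(wt$statistic), df = NA_real_,
        p_value = wt$p.value,
        method_notes = "unpaired; stats::wilcox.test normal approximation")
    }
  }
  srh <- scheirer_ray_hare(slope ~ group * prior * likelihood,
                           data = fit$slopes)
  structure(list(vs_chance = vs_chance,
                 group_difference = group_difference,
                 srh = srh, chance = chance),
            class = "cohort_tests")
}

#' @export
print.cohort_tests <- function(x, ...) {
  cat("== Performance vs chance (", format(x$chance), ") ==\n", sep = "")
  for (g in names(x$vs_chance)) {
    cat("[", g, "] ", sep = "")
    print(x$vs_chance[[g]])
  }
  if (!is.null(x$group_difference)) {
    cat("== Between-group performance ==\n")
    print(x$group_difference)
  }
  cat("== Estimation slopes: Scheirer-Ray-Hare ==\n")
  print(x$srh)
  invisible(x)
}
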