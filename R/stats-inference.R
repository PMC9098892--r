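# Nonparametric bootstrap inference on neuron fractions (percentile CIs and
# two-sample difference tests), plus a thin facade over R's standard tests.

#' Percentile bootstrap confidence interval for a fraction
#'
#' Resamples the units (neurons by default) with replacement
#' `n_iterations` times, recomputing the fraction of positive labels each
#' time; the CI is the percentile interval of the bootstrap distribution.
#' The point estimate is the plug-in (observed) fraction.
#'
#' @param labels logical (or 0/1) outcomes, one per resampling unit.
#' @param n_iterations bootstrap iterations (default 10000).
#' @param level confidence level (default 0.95).
#' @param seed integer seed; identical seed and input give identical bounds.
#' @param resample_unit label recording what one unit is (metadata only;
#'   supply labels already collapsed to the chosen unit).
#' @return list of class `bootstrap_result`: `estimate`, `ci_low`,
#'   `ci_high`, `n_iterations`, `level`, `resample_unit`, `seed`, `n_units`.
#' @export
bootstrap_fraction_ci <- function(labels, n_iterations = 10000, level = 0.95,
                                  seed = 1L, resample_unit = "neuron") {
  abort_if(length(labels) == 0L, "labels must contain at least one unit")
  abort_if(anyNA(labels), "labels must not contain missing values")
  abort_if(!is_count(n_iterations) || n_iterations < 1,
           "n_iterations must be >= 1")
  abort_if(level <= 0 || level >= 1, "level must lie in (0, 1)")
  x <- as.numeric(as.logical(labels))
  n <- length(x)
  set.seed(seed)
  draws <- matrix(x[sample.int(n, n * n_iterations, replace = TRUE)],
                  nrow = n, ncol = n_iterations)
  fracs <- colMeans(draws)
  alpha <- 1 - level
  ci <- unname(stats::quantile(fracs, c(alpha / 2, 1 - alpha / 2), type = 7))
  structure(
    list(estimate = mean(x), ci_low = ci[1L], ci_high = ci[2L],
         n_iterations = as.integer(n_iterations), level = level,
         resample_unit = resample_unit, seed = as.integer(seed), n_units = n),
    class = "bootstrap_result"
  )
}

#' Bootstrap test for a difference between two fractions
#'
#' The statistic is `fraction(A) - fraction(B)`. Units are resampled with
#' replacement independently within each group; the two-sided p-value is
#' `2 * min(P(diff* <= 0), P(diff* >= 0))` over the bootstrap distribution
#' of the difference, clipped to `[2 / n_iterations, 1]` so a p-value of
#' exactly zero is never reported.
#'
#' @param labels_a,labels_b logical (or 0/1) outcomes per unit, one group
#'   each; both must be nonempty.
#' @inheritParams bootstrap_fraction_ci
#' @return a `bootstrap_result` whose `estimate` is the observed difference,
#'   with percentile CI bounds and a `p_value`.
#' @export
bootstrap_difference_test <- function(labels_a, labels_b,
                                      n_iterations = 10000, level = 0.95,
                                      seed = 1L, resample_unit = "neuron") {
  abort_if(length(labels_a) == 0L || length(labels_b) == 0L,
           "both groups must be nonempty")
  abort_if(anyNA(labels_a) || anyNA(labels_b),
           "labels must not contain missing values")
  a <- as.numeric(as.logical(labels_a))
  b <- as.numeric(as.logical(labels_b))
  na <- length(a); nb <- length(b)
  set.seed(seed)
  fa <- colMeans(matrix(a[sample.int(na, na * n_iterations, replace = TRUE)],
                        nrow = na))
  fb <- colMeans(matrix(b[sample.int(nb, nb * n_iterations, replace = TRUE)],
                        nrow = nb))
  diffs <- fa - fb
  alpha <- 1 - level
  ci <- unname(stats::quantile(diffs, c(alpha / 2, 1 - alpha / 2), type = 7))
  p <- 2 * min(mean(diffs <= 0), mean(diffs >= 0))
  p <- min(1, max(2 / n_iterations, p))
  structure(
    list(estimate = mean(a) - mean(b), ci_low = ci[1L], ci_high = ci[2L],
         p_value = p, n_iterations = as.integer(n_iterations), level = level,
         resample_unit = resample_unit, seed = as.integer(seed),
         n_units = c(a = na, b = nb)),
    class = "bootstrap_result"
  )
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("bootstrap (%d iterations, unit = %s)\n",
              x$n_iterations, x$resample_unit))
  cat(sprintf("  estimate %.4f, %g%% CI [%.4f, %.4f]\n",
              x$estimate, 100 * x$level, x$ci_low, x$ci_high))
  if (!is.null(x$p_value)) cat(sprintf("  two-sided p = %.4g\n", x$p_value))
  invisible(x)
}

#' Facade over the standard hypothesis tests
#'
#' Delegates each named test to the established R routine and returns its
#' statistic and p-value together with the routine's identity; no test
#' mathematics is re-implemented here.
#'
#' Expected `data` shapes:
#' \describe{
#'   \item{t_two_sided, mann_whitney, ks}{`list(x =, y =)`.}
#'   \item{friedman}{matrix subjects x conditions.}
#'   \item{rm_anova_oneway}{data.frame (`value`, `subject`, `time`).}
#'   \item{rm_anova_twoway}{data.frame (`value`, `subject`, `time`, `group`).}
#'   \item{anova_oneway, anova_dunnett, tukey}{data.frame (`value`,
#'     `group`); for Dunnett the first factor level of `group` is the
#'     control.}
#' }
#'
#' @param name test identifier (see shapes above).
#' @param data the test's input in the shape listed.
#' @return list (`method`, `statistic`, `p_value`, and `details` holding the
#'   full fitted object).
#' @export
standard_test <- function(name, data) {
  shape_error <- function(expected) {
    abort_if(TRUE, "test '%s' expects data as %s", name, expected)
  }
  two_sample <- function() {
    if (!is.list(data) || !all(c("x", "y") %in% names(data)))
      shape_error("list(x =, y =)")
    data
  }
  res <- switch(
    name,
    t_two_sided = {
      d <- two_sample()
      stats::t.test(d$x, d$y, alternative = "two.sided")
    },
    mann_whitney = {
      d <- two_sample()
      stats::wilcox.test(d$x, d$y, alternative = "two.sided", exact = FALSE)
    },
    ks = {
      d <- two_sample()
      stats::ks.test(d$x, d$y)
    },
    friedman = {
      if (!is.matrix(data)) shape_error("a subjects x conditions matrix")
      stats::friedman.test(data)
    },
    rm_anova_oneway = {
      if (!is.data.frame(data) ||
          !all(c("value", "subject", "time") %in% names(data)))
        shape_error("data.frame(value, subject, time)")
      stats::aov(value ~ time + Error(subject / time),
                 data = transform(data, subject = factor(subject),
                                  time = factor(time)))
    },
    rm_anova_twoway = {
      if (!is.data.frame(data) ||
          !all(c("value", "subject", "time", "group") %in% names(data)))
        shape_error("data.frame(value, subject, time, group)")
      stats::aov(value ~ time * group + Error(subject / time),
                 data = transform(data, subject = factor(subject),
                                  time = factor(time), group = factor(group)))
    },
    anova_oneway = ,
    anova_dunnett = ,
    tukey = {
      if (!is.data.frame(data) || !all(c("value", "group") %in% names(data)))
        shape_error("data.frame(value, group)")
      stats::aov(value ~ group, data = transform(data, group = factor(group)))
    },
    abort_if(TRUE, "unknown test name '%s'", name)
  )

  if (inherits(res, "htest")) {
    list(method = res$method, statistic = unname(res$statistic),
         p_value = res$p.value, details = res)
  } else if (name == "tukey") {
    tk <- stats::TukeyHSD(res)
    list(method = "Tukey HSD (stats::TukeyHSD)",
         statistic = NA_real_, p_value = tk$group[, "p adj"], details = tk)
  } else if (name == "anova_dunnett") {
    gl <- multcomp::glht(res, linfct = multcomp::mcp(group = "Dunnett"))
    sm <- summary(gl)
    list(method = "ANOVA + Dunnett (multcomp::glht)",
         statistic = unname(sm$test$tstat),
         p_value = as.numeric(sm$test$pvalues), details = sm)
  } else if (name == "anova_oneway") {
    s <- summary(res)[[1L]]
    list(method = "one-way ANOVA (stats::aov)",
         statistic = s[["F value"]][1L], p_value = s[["Pr(>F)"]][1L],
         details = res)
  } else {
    # repeated-measures aov: report the within-subject effect
    s <- summary(res)
    within <- s[[length(s)]][[1L]]
    list(method = sprintf("repeated-measures ANOVA (stats::aov, %s)", name),
         statistic = within[["F value"]][1L],
         p_value = within[["Pr(>F)"]][1L], details = res)
  }
}
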