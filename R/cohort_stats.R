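# Statistical layer: normality-gated two-group tests, ANOVA with Tukey
# contrasts, Kaplan-Meier curves with the Gehan-Breslow-Wilcoxon test,
# marker fold-change summaries, and biopsy-table percentages.

#' Significance decision and star labels
#'
#' The decision rule used throughout: p < 0.05 is significant, p < 0.075 is
#' a trend toward significance, anything else is not significant.  Stars
#' follow the usual figure convention (* < 0.05, ** < 0.01, *** < 0.001,
#' **** < 0.0001).
#'
#' @param p P value(s) in `[0, 1]`.
#' @return `significance_decision`: character vector of decisions.
#' @export
significance_decision <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  ifelse(p < 0.05, "significant",
         ifelse(p < 0.075, "trend", "not significant"))
}

#' @rdname significance_decision
#' @return `p_stars`: character vector of star labels (`"n.s."` when not
#'   significant).
#' @export
p_stars <- function(p) {
  ifelse(p < 1e-4, "****",
         ifelse(p < 1e-3, "***",
                ifelse(p < 1e-2, "**",
                       ifelse(p < 0.05, "*", "n.s."))))
}

test_result <- function(test, statistic, p_value, extra = list()) {
  structure(c(list(test = test, statistic = unname(statistic),
                   p_value = unname(p_value),
                   decision = significance_decision(p_value),
                   stars = p_stars(p_value)), extra),
            class = "osteorad_test")
}

#' @export
print.osteorad_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (%s %s)\n",
              x$test, x$statistic, x$p_value, x$decision, x$stars))
  invisible(x)
}

#' Normality gate for two-group comparisons
#'
#' Chooses between Welch's t test and the Mann-Whitney U test by testing
#' each sample for normality with a one-sample Kolmogorov-Smirnov test
#' against a normal distribution with the sample's own mean and SD.  If
#' either KS p value is below 0.05 (or a sample is degenerate, or too small
#' to test) the nonparametric test is chosen.  Note that using estimated
#' parameters makes the KS test conservative (Lilliefors effect); the gate
#' reproduces the published decision rule rather than a calibrated
#' normality test.
#'
#' @param sample_a,sample_b Numeric samples.
#' @return A list with `test` (`"welch_t"` or `"mann_whitney_u"`) and
#'   `ks_p` (the two KS p values, `NA` when inapplicable).
#' @export
normality_gate <- function(sample_a, sample_b) {
  ks1 <- function(x) {
    if (length(x) < 3 || stats::sd(x) == 0) return(NA_real_)
    suppressWarnings(
      stats::ks.test(x, "pnorm", mean(x), stats::sd(x))$p.value)
  }
  if (length(sample_a) < 3 || length(sample_b) < 3) {
    warning("fewer than 3 observations in a group: normality gate ",
            "inapplicable, defaulting to Mann-Whitney U")
    return(list(test = "mann_whitney_u", ks_p = c(NA_real_, NA_real_)))
  }
  p <- c(ks1(sample_a), ks1(sample_b))
  nonnormal <- any(is.na(p)) || any(p < 0.05)
  list(test = if (nonnormal) "mann_whitney_u" else "welch_t", ks_p = p)
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test: exact p value (via the null distribution of U)
#' for combined n <= 12 without ties, normal approximation with tie
#' correction otherwise.
#'
#' @param sample_a,sample_b Non-empty numeric samples.
#' @return An `osteorad_test` with the U statistic.
#' @export
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))  # U = 0, p = 0.10
mann_whitney_u <- function(sample_a, sample_b) {
  stopifnot(length(sample_a) >= 1, length(sample_b) >= 1)
  ties <- anyDuplicated(c(sample_a, sample_b)) > 0
  exact <- !ties && (length(sample_a) + length(sample_b)) <= 12
  res <- suppressWarnings(
    stats::wilcox.test(sample_a, sample_b, exact = exact))
  test_result("Mann-Whitney U", res$statistic, res$p.value,
              list(exact = exact))
}

#' Welch's t test
#'
#' Two-sided unequal-variance t test with Welch-Satterthwaite degrees of
#' freedom.
#'
#' @param sample_a,sample_b Samples with n >= 2 each; at least one must
#'   have nonzero variance.
#' @return An `osteorad_test` with the t statistic and a `df` field.
#' @export
welch_t <- function(sample_a, sample_b) {
  stopifnot(length(sample_a) >= 2, length(sample_b) >= 2)
  if (stats::var(sample_a) == 0 && stats::var(sample_b) == 0) {
    if (mean(sample_a) == mean(sample_b))
      return(test_result("Welch t", 0, 1, list(df = NA_real_)))
    stop("both samples have zero variance", call. = FALSE)
  }
  res <- stats::t.test(sample_a, sample_b, var.equal = FALSE)
  test_result("Welch t", res$statistic, res$p.value,
              list(df = unname(res$parameter)))
}

#' Gated two-group comparison
#'
#' Applies the [normality_gate()] and runs the chosen test.
#'
#' @param sample_a,sample_b Numeric samples.
#' @return An `osteorad_test` with a `gate` field recording the KS p
#'   values.
#' @export
two_group_test <- function(sample_a, sample_b) {
  gate <- normality_gate(sample_a, sample_b)
  res <- if (gate$test == "welch_t") welch_t(sample_a, sample_b)
         else mann_whitney_u(sample_a, sample_b)
  res$gate <- gate
  res
}

#' One-way ANOVA with Tukey post hoc contrasts
#'
#' @param values Numeric response.
#' @param groups Group labels (>= 2 groups, each with n >= 2).
#' @return A list with `anova` (an `osteorad_test` for the F test) and
#'   `pairs` (data frame of Tukey HSD contrasts with adjusted p values,
#'   decisions and stars).
#' @export
anova_tukey <- function(values, groups) {
  groups <- factor(groups)
  tab <- table(groups)
  if (length(tab) < 2) stop("need at least two groups", call. = FALSE)
  if (any(tab < 2))
    stop("every group needs n >= 2 for ANOVA", call. = FALSE)
  fit <- stats::aov(values ~ groups)
  an <- summary(fit)[[1]]
  fres <- test_result("one-way ANOVA F", an$`F value`[1], an$`Pr(>F)`[1],
                      list(df = an$Df))
  tk <- stats::TukeyHSD(fit)$groups
  pairs <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"],
                      decision = significance_decision(tk[, "p adj"]),
                      stars = p_stars(tk[, "p adj"]),
                      row.names = NULL)
  list(anova = fres, pairs = pairs)
}

#' Kaplan-Meier estimator
#'
#' Product-limit estimate of the survival function; right-continuous with
#' S(0) = 1.
#'
#' @param times Positive event/censoring times.
#' @param events Event indicator (1 = death observed, 0 = censored).
#' @return A list of class `km_fit` with the `survival::survfit` object
#'   (`fit`), a step function `surv(t)`, and the step table `table`.
#' @export
#' @examples
#' km <- km_estimator(c(3, 5, 7, 8), c(0, 1, 1, 0))
#' km$surv(5)  # 2/3
km_estimator <- function(times, events) {
  stopifnot(all(times > 0), all(events %in% c(0, 1)))
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  fun <- stats::stepfun(fit$time, c(1, fit$surv), right = FALSE)
  structure(list(fit = fit,
                 surv = fun,
                 table = data.frame(time = fit$time, n_risk = fit$n.risk,
                                    n_event = fit$n.event,
                                    surv = fit$surv)),
            class = "km_fit")
}

#' @export
print.km_fit <- function(x, ...) {
  cat("Kaplan-Meier fit:\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' @export
plot.km_fit <- function(x, ...) {
  plot(x$fit, xlab = "time", ylab = "survival", ...)
  invisible(x)
}

# Gehan scores: u_i = #{j definitely before i} - #{j definitely after i}
# under the usual censoring conventions.  The weighted-log-rank form of the
# test statistic (weight = number at risk) equals sum(u_i) over group 1,
# and Gehan's permutation variance is n1 n2 sum(u^2) / (n (n-1)).
gbw_scores <- function(time, event) {
  n <- length(time)
  u <- numeric(n)
  for (i in seq_len(n)) {
    before <- sum(time < time[i] & event == 1) +
      if (event[i] == 0) sum(time == time[i] & event == 1) else 0
    after <- if (event[i] == 1)
      sum(time > time[i]) + sum(time == time[i] & event == 0)
    else 0
    u[i] <- before - after
  }
  u
}

gbw_stat <- function(time, event, group1) {
  u <- gbw_scores(time, event)
  n <- length(u)
  n1 <- sum(group1)
  W <- sum(u[group1])
  V <- n1 * (n - n1) * sum(u ^ 2) / (n * (n - 1))
  list(W = W, V = V, chisq = if (V > 0) W ^ 2 / V else NA_real_)
}

#' Gehan-Breslow-Wilcoxon survival test
#'
#' Weighted log-rank test for two survival curves with weights equal to the
#' total number at risk at each event time, so early deaths carry more
#' weight than in the plain log-rank test.  The statistic is computed in
#' Gehan's score form (the score sum over group 1 equals the weighted
#' log-rank numerator) with Gehan's permutation variance, and the default
#' p value refers W^2/V to a chi-square with 1 df; with
#' `p_method = "permutation"` a group-label permutation p value is
#' computed instead (useful for the small group sizes typical of lifespan
#' studies).
#'
#' @param time1,event1 Times and event indicators (1 = death) for group 1.
#' @param time2,event2 Same for group 2.
#' @param p_method `"asymptotic"` (default) or `"permutation"`.
#' @param n_perm Number of label permutations.
#' @param seed Seed for the permutation draw.
#' @return An `osteorad_test` with the chi-square statistic and fields `W`
#'   (weighted score) and `V` (its variance); the permutation method also
#'   carries `p_mid`, the mid-p value (inclusive p minus half the atom at
#'   the observed statistic), which is what a continuous approximation to
#'   the discrete permutation null estimates.
#' @export
gehan_breslow_wilcoxon <- function(time1, event1, time2, event2,
                                   p_method = c("asymptotic", "permutation"),
                                   n_perm = 10000, seed = 1) {
  p_method <- match.arg(p_method)
  stopifnot(length(time1) >= 1, length(time2) >= 1,
            length(time1) == length(event1),
            length(time2) == length(event2))
  time <- c(time1, time2)
  event <- c(event1, event2)
  if (!any(event == 1))
    stop("no events in either group: test undefined", call. = FALSE)
  grp1 <- c(rep(TRUE, length(time1)), rep(FALSE, length(time2)))
  obs <- gbw_stat(time, event, grp1)
  extra <- list(W = obs$W, V = obs$V, p_method = p_method)
  if (p_method == "asymptotic") {
    p <- stats::pchisq(obs$chisq, df = 1, lower.tail = FALSE)
  } else {
    perm <- gbw_permutation_p(time, event, grp1, n_perm = n_perm,
                              seed = seed)
    p <- perm$p
    extra$p_mid <- perm$p_mid
  }
  test_result("Gehan-Breslow-Wilcoxon", obs$chisq, p, extra)
}

# Vectorized permutation p value for the GBW score W = sum of Gehan scores
# over group 1, under random relabeling of group membership (group sizes
# fixed).
gbw_permutation_p <- function(time, event, group1, n_perm = 10000,
                              seed = 1) {
  u <- gbw_scores(time, event)
  m <- length(u)
  n1 <- sum(group1)
  w_obs <- sum(u[group1])
  set.seed(seed)
  labs <- matrix(FALSE, nrow = m, ncol = n_perm)
  for (b in seq_len(n_perm)) labs[sample.int(m, n1), b] <- TRUE
  w_perm <- drop(crossprod(labs, u))
  p <- (1 + sum(abs(w_perm) >= abs(w_obs) - 1e-12)) / (n_perm + 1)
  # mid-p: half the probability atom at the observed |W| -- the quantity a
  # continuous tail approximation estimates for a discrete null
  atom <- mean(abs(abs(w_perm) - abs(w_obs)) < 1e-12)
  list(p = p, p_mid = p - atom / 2)
}

#' Marker fold change over time
#'
#' Summarizes each group's change in a longitudinal marker between an early
#' and a late time window: ratio of late to early group means, a direction
#' arrow (up/down/flat with a +-5% dead band), and the p value of the gated
#' early-versus-late comparison.
#'
#' @param cohort A cohort table as produced by [simulate_cohort()] (long
#'   format with columns `group`, `measurement`, `week`, `value`).
#' @param marker Measurement name to summarize.
#' @param early,late Two-element numeric windows `[from, to]` in weeks.
#' @return A data frame with one row per group: `group`, `marker`,
#'   `early_mean`, `late_mean`, `ratio`, `direction`, `p_value`.
#' @export
fold_change_over_time <- function(cohort, marker, early = c(2, 8),
                                  late = c(26, 32)) {
  stopifnot(is.data.frame(cohort),
            all(c("group", "measurement", "week", "value") %in%
                  names(cohort)))
  sub <- cohort[cohort$measurement == marker, ]
  if (!nrow(sub))
    stop(sprintf("no measurements named '%s'", marker), call. = FALSE)
  out <- lapply(split(sub, sub$group, drop = TRUE), function(g) {
    e <- g$value[g$week >= early[1] & g$week <= early[2]]
    l <- g$value[g$week >= late[1] & g$week <= late[2]]
    if (!length(e))
      stop(sprintf("group '%s': empty early window for %s",
                   g$group[1], marker), call. = FALSE)
    if (!length(l))
      stop(sprintf("group '%s': empty late window for %s",
                   g$group[1], marker), call. = FALSE)
    ratio <- mean(l) / mean(e)
    data.frame(group = as.character(g$group[1]), marker = marker,
               early_mean = mean(e), late_mean = mean(l), ratio = ratio,
               direction = if (ratio > 1.05) "up"
                           else if (ratio < 0.95) "down" else "flat",
               p_value = two_group_test(e, l)$p_value)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Biopsy-table percentages
#'
#' Percent incidence per finding and group, with male-only findings (e.g.
#' enlarged seminal vesicles) computed against the male denominators.
#' Percentages are rounded to one decimal.
#'
#' @param counts Matrix or data frame of finding counts (findings x
#'   groups).
#' @param group_n Total animals per group (length = number of columns).
#' @param male_only Logical per finding (row); `TRUE` rows use `male_n`.
#' @param male_n Male animals per group; required when any `male_only`.
#' @return A matrix of percentages with the same dimnames as `counts`.
#' @export
#' @examples
#' biopsy_percentages(matrix(7, 1, 1), 20)  # 35
biopsy_percentages <- function(counts, group_n,
                               male_only = rep(FALSE, nrow(as.matrix(counts))),
                               male_n = NULL) {
  counts <- as.matrix(counts)
  stopifnot(length(group_n) == ncol(counts), all(group_n > 0),
            length(male_only) == nrow(counts))
  if (any(male_only) && is.null(male_n))
    stop("male_n required for male-only findings", call. = FALSE)
  denom <- matrix(rep(group_n, each = nrow(counts)), nrow = nrow(counts))
  if (any(male_only))
    denom[male_only, ] <- matrix(rep(male_n, each = sum(male_only)),
                                 nrow = sum(male_only))
  if (any(counts > denom))
    stop("data error: count exceeds denominator", call. = FALSE)
  out <- round(100 * counts / denom, 1)
  dimnames(out) <- dimnames(counts)
  out
}
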