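# Shared statistics: unpaired t-test, one-way ANOVA with Dunnett's
# many-to-one and Tukey's all-pairs adjustments, Pearson correlation, and the
# behavioral scalar metrics (olfactory performance index, climbing ratio).

#' Two-tailed unpaired t-test
#'
#' Pooled-variance Student's test by default; Welch when
#' \code{equal_variance = FALSE}. Degenerate zero-variance inputs are handled
#' explicitly: equal means give p = 1 (the null holds exactly), unequal means
#' give p = 0 with a flag.
#'
#' @param x,y numeric samples, each of length >= 2.
#' @param equal_variance pool the variances (classic Student's test).
#' @return list(statistic, df, p_value, tails = "two", flags).
#' @export
t_test_unpaired <- function(x, y, equal_variance = TRUE) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  flags <- character()
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) {
      return(list(statistic = 0, df = length(x) + length(y) - 2, p_value = 1,
                  tails = "two", flags = "zero variance, equal means"))
    }
    return(list(statistic = Inf * sign(mean(x) - mean(y)),
                df = length(x) + length(y) - 2, p_value = 0, tails = "two",
                flags = "degenerate: zero variance, unequal means"))
  }
  tt <- stats::t.test(x, y, var.equal = equal_variance)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = unname(tt$p.value), tails = "two", flags = flags)
}

# shared one-way ANOVA bookkeeping
anova_parts <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2,
            all(vapply(groups, length, 1L) >= 2))
  n <- vapply(groups, length, 1L)
  means <- vapply(groups, mean, 1)
  N <- sum(n); k <- length(groups)
  mse <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1)) / (N - k)
  list(n = n, means = means, N = N, k = k, mse = mse, df = N - k)
}

#' One-way ANOVA with Dunnett's many-to-one comparisons
#'
#' Compares every group against the control group. Adjusted p-values are
#' computed from the joint multivariate-t null of the comparison statistics
#' (correlation lambda_i lambda_j with lambda_i = sqrt(n_i / (n_i + n_0)))
#' via \code{mvtnorm::pmvt} (Genz-Bretz quadrature, absolute tolerance 1e-5,
#' locally seeded so results are reproducible). With a single comparison the
#' adjusted p equals the unadjusted two-sample pooled-variance t-test p.
#'
#' @param groups list of numeric samples (each n >= 2).
#' @param control_index index of the control group in \code{groups}.
#' @return data.frame(comparison, estimate, statistic, df, p_raw, p_adj);
#'   the ANOVA F statistic and its p are attached as attributes.
#' @export
anova_dunnett <- function(groups, control_index = 1L) {
  a <- anova_parts(groups)
  idx <- setdiff(seq_len(a$k), control_index)
  n0 <- a$n[control_index]
  tstat <- (a$means[idx] - a$means[control_index]) /
    sqrt(a$mse * (1 / a$n[idx] + 1 / n0))
  lambda <- sqrt(a$n[idx] / (a$n[idx] + n0))
  corr <- outer(lambda, lambda)
  diag(corr) <- 1
  m <- length(idx)
  p_raw <- 2 * stats::pt(-abs(tstat), a$df)
  p_adj <- vapply(seq_len(m), function(i) {
    q <- abs(tstat[i])
    if (m == 1) return(p_raw[i])
    pr <- with_seed(290816L, mvtnorm::pmvt(
      lower = rep(-q, m), upper = rep(q, m), df = as.integer(a$df),
      corr = corr, algorithm = mvtnorm::GenzBretz(abseps = 1e-5)))
    max(0, min(1, 1 - as.numeric(pr)))
  }, numeric(1))
  grand <- sum(a$n * a$means) / a$N
  ss_b <- sum(a$n * (a$means - grand)^2)
  f <- (ss_b / (a$k - 1)) / a$mse
  out <- data.frame(
    comparison = paste0("group", idx, " - group", control_index),
    estimate = a$means[idx] - a$means[control_index],
    statistic = tstat, df = a$df, p_raw = p_raw, p_adj = pmax(p_adj, p_raw))
  attr(out, "F") <- f
  attr(out, "F_p") <- stats::pf(f, a$k - 1, a$df, lower.tail = FALSE)
  out
}

#' One-way ANOVA with Tukey's all-pairs comparisons
#'
#' Tukey-Kramer adjusted p-values from the studentized range distribution
#' (\code{stats::ptukey}, numerically exact to its quadrature tolerance).
#' With two groups the adjusted p reduces to the unadjusted pooled-variance
#' t-test p.
#'
#' @param groups list of numeric samples (each n >= 2).
#' @return data.frame(group_i, group_j, estimate, statistic, df, p_raw,
#'   p_adj), symmetric in pair order.
#' @export
anova_tukey <- function(groups) {
  a <- anova_parts(groups)
  pairs <- utils::combn(a$k, 2)
  est <- a$means[pairs[2, ]] - a$means[pairs[1, ]]
  se <- sqrt(a$mse * (1 / a$n[pairs[1, ]] + 1 / a$n[pairs[2, ]]))
  tstat <- est / se
  p_raw <- 2 * stats::pt(-abs(tstat), a$df)
  q <- abs(tstat) * sqrt(2)
  p_adj <- stats::ptukey(q, nmeans = a$k, df = a$df, lower.tail = FALSE)
  data.frame(group_i = pairs[1, ], group_j = pairs[2, ], estimate = est,
             statistic = tstat, df = a$df, p_raw = p_raw,
             p_adj = pmax(p_adj, p_raw))
}

#' Pearson correlation
#'
#' @param x,y numeric samples of equal length >= 3 with nonzero variance.
#' @return list(r, r_squared, p_value).
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: correlation undefined")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  r <- unname(ct$estimate)
  list(r = r, r_squared = r^2, p_value = unname(ct$p.value))
}

#' Olfactory T-maze performance index
#'
#' (n_cs_plus - n_cs_minus) / (n_cs_plus + n_cs_minus): the normalized
#' difference between flies choosing the shock-paired odor (CS+) and the
#' unpaired odor (CS-). In this operand order, learned avoidance of CS+
#' yields negative values; \code{convention = "avoidance"} flips the sign to
#' the avoidance-positive convention common in the field. Neither convention
#' is applied silently: the convention used is attached as an attribute.
#'
#' @param n_cs_plus,n_cs_minus fly counts choosing each odor (total > 0).
#' @param convention "as_written" (CS+ minus CS-) or "avoidance"
#'   (CS- minus CS+).
#' @return Performance index in [-1, 1].
#' @examples
#' performance_index(40, 60)  # -0.2
#' @export
performance_index <- function(n_cs_plus, n_cs_minus,
                              convention = c("as_written", "avoidance")) {
  convention <- match.arg(convention)
  stopifnot(n_cs_plus >= 0, n_cs_minus >= 0)
  total <- n_cs_plus + n_cs_minus
  if (total == 0) stop("total fly count is zero")
  pi <- (n_cs_plus - n_cs_minus) / total
  if (convention == "avoidance") pi <- -pi
  structure(pi, convention = convention)
}

#' Climbing assay ratio
#'
#' Fraction of flies climbing above the threshold line, averaged over trials
#' 2 to 6 (the first trial is a habituation trial and is excluded).
#'
#' @param trial_counts list of (above, total) pairs, one per trial, at least
#'   six trials; all totals > 0.
#' @return Mean ratio over trials 2..6.
#' @examples
#' climbing_ratio(rep(list(c(8, 10)), 6))  # 0.8
#' @export
climbing_ratio <- function(trial_counts) {
  stopifnot(is.list(trial_counts), length(trial_counts) >= 6)
  m <- do.call(rbind, lapply(trial_counts, function(tc) {
    stopifnot(length(tc) == 2, tc[2] > 0, tc[1] >= 0, tc[1] <= tc[2])
    c(above = tc[1], total = tc[2])
  }))
  mean(m[2:6, 1] / m[2:6, 2])
}
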