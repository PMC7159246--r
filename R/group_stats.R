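#' Shapiro-Wilk normality gate
#'
#' Two-sided p-value for the null hypothesis that the sample is normal,
#' delegated to [stats::shapiro.test()]. Used to decide whether the group
#' comparison falls back to rank-based tests.
#'
#' @param x Numeric sample, 3 <= n <= 5000, non-constant.
#' @return The p-value.
#' @export
normality_test <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 3) stop("normality test needs n >= 3")
  if (!all(is.finite(x))) stop("sample must be finite")
  if (stats::sd(x) == 0) stop("sample is constant; normality test undefined")
  stats::shapiro.test(x)$p.value
}

check_grouped <- function(groups) {
  if (!is.list(groups) || is.null(names(groups)) || any(names(groups) == ""))
    stop("groups must be a named list of numeric vectors")
  if (length(groups) < 2) stop("at least two groups are required")
  if (any(lengths(groups) == 0)) stop("empty group")
  v <- unlist(groups, use.names = FALSE)
  if (!all(is.finite(v))) stop("all values must be finite")
  invisible(v)
}

#' Kruskal-Wallis omnibus test
#'
#' Rank-based k-sample test on mid-ranks with tie correction; p-value from
#' the chi-square distribution with k - 1 degrees of freedom (delegated to
#' [stats::kruskal.test()]). If every value across all groups is identical,
#' the statistic is defined as 0 with p = 1.
#'
#' @param groups Named list of numeric vectors (>= 2 groups, total n >= 3).
#' @return List with `H` and `p`.
#' @export
kruskal_wallis <- function(groups) {
  v <- check_grouped(groups)
  if (length(v) < 3) stop("total sample size must be >= 3")
  if (length(unique(v)) == 1) return(list(H = 0, p = 1))
  g <- factor(rep(names(groups), lengths(groups)))
  kt <- stats::kruskal.test(v, g)
  list(H = unname(kt$statistic), p = kt$p.value)
}

#' Dunn's pairwise rank comparison
#'
#' Post hoc z-tests following a Kruskal-Wallis omnibus: values are ranked
#' once across the *whole* family of groups (mid-ranks), and for a pair
#' (i, j)
#' `z = (meanrank_i - meanrank_j) / sqrt((N(N+1)/12 - T) (1/n_i + 1/n_j))`
#' with the tie term `T = sum(t^3 - t) / (12 (N - 1))` over tied-value run
#' lengths t. Two-sided p-values come from the standard normal; `holm`
#' adjustment over the requested pairs is available (none by default, which
#' matches unadjusted pairwise reporting).
#'
#' @param groups Named list of numeric vectors; the full comparison family.
#' @param pairs List of length-2 character vectors naming the comparisons;
#'   a single pair may be given directly as `c("A", "B")`. Default: all pairs.
#' @param adjustment `"none"` (default) or `"holm"`.
#' @return data.frame with columns `group1`, `group2`, `z`, `p`, `p_adj`.
#' @export
dunn_pairwise <- function(groups, pairs = NULL, adjustment = c("none", "holm")) {
  adjustment <- match.arg(adjustment)
  v <- check_grouped(groups)
  lens <- lengths(groups)
  g <- rep(names(groups), lens)
  r <- rank(v)  # mid-ranks
  N <- length(v)
  tt <- table(v)
  tie_term <- sum(tt^3 - tt) / (12 * (N - 1))
  mean_rank <- tapply(r, g, mean)
  if (is.null(pairs)) {
    pairs <- utils::combn(names(groups), 2, simplify = FALSE)
  } else if (is.character(pairs) && length(pairs) == 2) {
    pairs <- list(pairs)
  }
  rows <- lapply(pairs, function(pr) {
    if (length(pr) != 2 || !all(pr %in% names(groups)))
      stop("pair not in the group family: ", paste(pr, collapse = " vs "))
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / lens[[pr[1]]] + 1 / lens[[pr[2]]]))
    z <- if (se > 0) (mean_rank[[pr[1]]] - mean_rank[[pr[2]]]) / se else 0
    data.frame(group1 = pr[1], group2 = pr[2], z = z,
               p = 2 * stats::pnorm(-abs(z)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- if (adjustment == "holm") stats::p.adjust(out$p, "holm") else out$p
  rownames(out) <- NULL
  out
}

#' Percent difference between two medians
#'
#' `100 (m_treated - m_control) / m_control`, with a signed denominator: a
#' negative quantity that shrinks in magnitude yields a negative percent, as
#' in the study's relative-stress-relaxation reporting.
#'
#' @param m_treated,m_control Medians; `m_control` must be nonzero.
#' @return Percent difference (vectorized).
#' @export
median_percent_difference <- function(m_treated, m_control) {
  if (any(m_control == 0)) stop("control median must be nonzero")
  100 * (m_treated - m_control) / m_control
}

#' A-priori sample size for a two-sample t-test
#'
#' Smallest group size n so that an independent-samples t-test detects a
#' relative difference `mid_fraction` at the given variability, significance
#' level and power. The standardized effect is
#' `d = mid_fraction / coefficient_of_variation`; the noncentral-t power
#' computation is delegated to [stats::power.t.test()]. The floor is n = 2,
#' the minimum allowing a variance estimate.
#'
#' @param mid_fraction Minimally important difference as a fraction of the
#'   control mean (e.g. 0.2 for 20%).
#' @param coefficient_of_variation Outcome SD divided by the mean.
#' @param alpha Two-sided significance level.
#' @param power Target power.
#' @return Required sample size per group (integer).
#' @export
required_sample_size <- function(mid_fraction, coefficient_of_variation,
                                 alpha = 0.05, power = 0.8) {
  if (!is.finite(mid_fraction) || !is.finite(coefficient_of_variation) ||
      coefficient_of_variation <= 0)
    stop("mid_fraction and coefficient_of_variation must be finite, cv > 0")
  if (alpha <= 0 || alpha >= 1 || power <= alpha || power >= 1)
    stop("alpha and power must satisfy 0 < alpha < power < 1")
  d <- abs(mid_fraction) / coefficient_of_variation
  if (d == 0) stop("zero effect size: required n is unbounded")
  p2 <- stats::power.t.test(n = 2, delta = d, sd = 1, sig.level = alpha)$power
  if (p2 >= power) return(2L)
  n <- stats::power.t.test(delta = d, sd = 1, sig.level = alpha, power = power)$n
  max(2L, as.integer(ceiling(n - 1e-9)))
}
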