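#' Pearson chi-squared test on proportions across groups
#'
#' Tests homogeneity of a shown / not-shown proportion across two or more
#' groups with the Pearson X^2 statistic on the 2 x g contingency table, with
#' g - 1 degrees of freedom and no continuity correction. Written out from
#' the textbook formula so the computation is transparent; it agrees with
#' `stats::chisq.test(correct = FALSE)` to numerical precision.
#'
#' @param k integer vector, birds showing the behaviour per group
#' @param n integer vector, birds observed per group (all > 0)
#' @return list with `statistic`, `df`, `p_value`
#' @export
#' @examples
#' chi_square_proportions(k = c(20, 35, 43), n = c(76, 63, 54))
chi_square_proportions <- function(k, n) {
  if (length(k) != length(n) || length(k) < 2)
    stop("need k and n for at least two groups")
  if (any(n <= 0)) stop("all group sizes must be positive")
  if (any(k < 0) || any(k > n)) stop("need 0 <= k <= n in every group")
  tot_k <- sum(k)
  tot <- sum(n)
  p_hat <- tot_k / tot
  obs <- rbind(k, n - k)
  exp <- rbind(n * p_hat, n * (1 - p_hat))
  if (p_hat == 0 || p_hat == 1)
    return(list(statistic = 0, df = length(k) - 1L, p_value = 1))
  statistic <- sum((obs - exp)^2 / exp)
  df <- length(k) - 1L
  list(statistic = statistic, df = df,
       p_value = stats::pchisq(statistic, df, lower.tail = FALSE))
}

#' Two-sample t test from summary statistics or raw samples
#'
#' Student's pooled-variance t (default) or Welch's unequal-variance variant,
#' computed either from the printed summary form (mean, sd, n per group) or
#' from raw sample vectors `x` and `y`.
#'
#' @param x,y optional raw numeric samples; when given, summaries are taken
#'   from them and the `mean1 ...` arguments are ignored
#' @param mean1,sd1,n1 first group summary (`n1 >= 2`, `sd1 > 0`)
#' @param mean2,sd2,n2 second group summary
#' @param variant `"pooled"` (Student) or `"welch"`
#' @return list with `t`, `df`, `p_value`, `mean_difference`, `variant`
#' @export
#' @examples
#' two_sample_t(mean1 = 25.7, sd1 = 7.0, n1 = 14,
#'              mean2 = 20.7, sd2 = 6.6, n2 = 9)
two_sample_t <- function(x = NULL, y = NULL,
                         mean1 = NULL, sd1 = NULL, n1 = NULL,
                         mean2 = NULL, sd2 = NULL, n2 = NULL,
                         variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (!is.null(x)) {
    if (is.null(y)) stop("raw-sample mode needs both x and y")
    mean1 <- mean(x); sd1 <- stats::sd(x); n1 <- length(x)
    mean2 <- mean(y); sd2 <- stats::sd(y); n2 <- length(y)
  }
  if (anyNA(c(mean1, sd1, n1, mean2, sd2, n2)) ||
      is.null(mean1) || is.null(sd1) || is.null(n1) ||
      is.null(mean2) || is.null(sd2) || is.null(n2))
    stop("need complete summaries (mean, sd, n) for both groups")
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2")
  if (sd1 <= 0 || sd2 <= 0) stop("each group needs sd > 0")
  d <- mean1 - mean2
  if (variant == "pooled") {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- sd1^2 / n1
    v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  t <- d / se
  list(t = t, df = df, p_value = 2 * stats::pt(-abs(t), df),
       mean_difference = d, variant = variant)
}
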