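#' Interpretation band for Cohen's d
#'
#' Maps an effect size to the conventional interpretation bands: |d| < 0.2
#' negligible, 0.2 to 0.5 small, 0.5 to 0.8 medium, above 0.8 large. Values
#' exactly at a cut-point fall in the higher band (0.2 is "small", 0.8 is
#' "large").
#'
#' @param d Numeric vector of effect sizes (sign is ignored).
#' @return Character vector in
#'   `c("negligible", "small", "medium", "large")`.
#' @export
cohens_band <- function(d) {
  ad <- abs(d)
  ifelse(ad < 0.2, "negligible",
         ifelse(ad < 0.5, "small",
                ifelse(ad < 0.8, "medium", "large")))
}

group_comparison_row <- function(group1, group2, n1, n2, m1, s1, m2, s2,
                                 t, df, p, d, method) {
  tibble::tibble(
    group1 = group1, group2 = group2, n1 = n1, n2 = n2,
    mean1 = m1, sd1 = s1, mean2 = m2, sd2 = s2,
    t = t, df = df, p = p, d = d, d_band = cohens_band(d),
    significant = is.finite(p) & p < 0.05, method = method
  )
}

#' Unpaired two-sample comparison with Cohen's d
#'
#' Student's two-sample t-test with pooled variance (df = n1 + n2 - 2,
#' two-sided p) plus the standardized mean difference
#' d = (mean1 - mean2) / pooled SD.
#'
#' @param x,y Numeric samples, each of size >= 2.
#' @param labels Length-2 character vector naming the groups.
#' @return A one-row tibble (`group1`, `group2`, `n1`, `n2`, `mean1`, `sd1`,
#'   `mean2`, `sd2`, `t`, `df`, `p`, `d`, `d_band`, `significant`, `method`).
#' @examples
#' unpaired_t_cohen(rnorm(20, 1), rnorm(20, 0))
#' @export
unpaired_t_cohen <- function(x, y, labels = c("group1", "group2")) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2L || length(y) < 2L) {
    stop("each sample needs at least 2 observations", call. = FALSE)
  }
  sp <- pooled_sd(stats::sd(x), length(x), stats::sd(y), length(y))
  if (sp == 0) {
    stop("degenerate variance: pooled standard deviation is zero", call. = FALSE)
  }
  tt <- stats::t.test(x, y, var.equal = TRUE)
  group_comparison_row(labels[1], labels[2], length(x), length(y),
                       mean(x), stats::sd(x), mean(y), stats::sd(y),
                       unname(tt$statistic), unname(tt$parameter), tt$p.value,
                       (mean(x) - mean(y)) / sp, "unpaired_t")
}

pooled_sd <- function(s1, n1, s2, n2) {
  sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
}

#' Unpaired comparison from summary statistics
#'
#' Same pooled-variance t statistic and Cohen's d as [unpaired_t_cohen()],
#' computed from group means, SDs and sizes. Intended for re-deriving effect
#' sizes from rounded values printed in publication tables.
#'
#' @param m1,s1,n1 Mean, SD (> 0) and size (>= 2) of the first group.
#' @param m2,s2,n2 Likewise for the second group.
#' @param labels Length-2 character vector naming the groups.
#' @return A one-row tibble as for [unpaired_t_cohen()].
#' @examples
#' # moderate-severe vs mild inflammation, middle attached gingiva L*
#' unpaired_t_cohen_from_summary(47.5, 3.6, 27, 54.0, 4.8, 16)
#' @export
unpaired_t_cohen_from_summary <- function(m1, s1, n1, m2, s2, n2,
                                          labels = c("group1", "group2")) {
  if (n1 < 2L || n2 < 2L) stop("group sizes must be >= 2", call. = FALSE)
  if (s1 < 0 || s2 < 0) stop("SDs must be non-negative", call. = FALSE)
  sp <- pooled_sd(s1, n1, s2, n2)
  if (sp == 0) {
    stop("degenerate variance: pooled standard deviation is zero", call. = FALSE)
  }
  se <- sp * sqrt(1 / n1 + 1 / n2)
  t <- (m1 - m2) / se
  df <- n1 + n2 - 2
  p <- 2 * stats::pt(-abs(t), df)
  group_comparison_row(labels[1], labels[2], n1, n2, m1, s1, m2, s2,
                       t, df, p, (m1 - m2) / sp, "unpaired_t_summary")
}

#' Paired pre/post comparison with Cohen's d
#'
#' Paired t-test on the within-subject differences `pre - post`, with
#' d = mean(difference) / SD(difference). The sign convention follows the
#' pre-minus-post difference, so an increase after treatment (e.g. gingiva
#' becoming lighter) yields negative t and d.
#'
#' @param pre,post Numeric samples of equal length (>= 2), aligned by
#'   subject.
#' @param labels Length-2 character vector naming the timepoints.
#' @return A one-row tibble as for [unpaired_t_cohen()] (`df` = n - 1).
#' @export
paired_t_cohen <- function(pre, post, labels = c("pre", "post")) {
  pre <- as.numeric(pre); post <- as.numeric(post)
  if (length(pre) != length(post)) {
    stop("pre and post must be aligned by subject (equal lengths)", call. = FALSE)
  }
  if (length(pre) < 2L) stop("need at least 2 paired observations", call. = FALSE)
  d <- pre - post
  if (stats::sd(d) == 0) {
    stop("degenerate variance: within-subject differences are constant",
         call. = FALSE)
  }
  tt <- stats::t.test(pre, post, paired = TRUE)
  group_comparison_row(labels[1], labels[2], length(pre), length(post),
                       mean(pre), stats::sd(pre), mean(post), stats::sd(post),
                       unname(tt$statistic), unname(tt$parameter), tt$p.value,
                       mean(d) / stats::sd(d), "paired_t")
}

#' Two-sample test of proportions
#'
#' Two-sided z-test on the difference of two independent proportions using
#' the pooled estimate: z = (p1 - p2) / sqrt(p(1-p)(1/n1 + 1/n2)) with
#' p = (k1 + k2) / (n1 + n2). No continuity correction. When the pooled
#' proportion is degenerate (all successes or all failures) the result is
#' flagged and p = 1.
#'
#' @param k1,n1 Successes and size of the first sample.
#' @param k2,n2 Successes and size of the second sample.
#' @return A one-row tibble: `p1`, `p2`, `z`, `p`, `degenerate`.
#' @examples
#' two_proportion_test(10, 10, 0, 10)
#' @export
two_proportion_test <- function(k1, n1, k2, n2) {
  if (n1 <= 0 || n2 <= 0 || k1 < 0 || k2 < 0 || k1 > n1 || k2 > n2) {
    stop("need 0 <= k <= n and n > 0 for both samples", call. = FALSE)
  }
  p1 <- k1 / n1; p2 <- k2 / n2
  pp <- (k1 + k2) / (n1 + n2)
  if (pp == 0 || pp == 1) {
    return(tibble::tibble(p1 = p1, p2 = p2, z = 0, p = 1, degenerate = TRUE))
  }
  z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  tibble::tibble(p1 = p1, p2 = p2, z = z, p = 2 * stats::pnorm(-abs(z)),
                 degenerate = FALSE)
}

#' McNemar's test for paired dichotomous outcomes
#'
#' Tests marginal homogeneity from the two discordant-pair counts. For
#' b + c >= 25 the chi-square form (|b - c| - correction)^2 / (b + c) with
#' df = 1 is used (continuity correction off by default); for smaller
#' discordant totals the exact binomial version (two-sided, Binomial(b + c,
#' 1/2)) is used. b + c = 0 gives a flagged result with p = 1.
#'
#' @param b,c Discordant counts (off-diagonal cells of the paired 2x2
#'   table).
#' @param correct Apply the continuity correction in the chi-square form?
#'   Default `FALSE`.
#' @param exact_below Discordant total under which the exact binomial
#'   variant is used. Default 25.
#' @return A one-row tibble: `b`, `c`, `statistic` (chi-square, `NA` for the
#'   exact variant), `p`, `method`, `degenerate`.
#' @export
mcnemar_test <- function(b, c, correct = FALSE, exact_below = 25) {
  if (b < 0 || c < 0) stop("discordant counts must be non-negative", call. = FALSE)
  n <- b + c
  if (n == 0) {
    return(tibble::tibble(b = b, c = c, statistic = 0, p = 1,
                          method = "degenerate", degenerate = TRUE))
  }
  if (n < exact_below) {
    p <- min(1, 2 * stats::pbinom(min(b, c), n, 0.5))
    return(tibble::tibble(b = b, c = c, statistic = NA_real_, p = p,
                          method = "exact_binomial", degenerate = FALSE))
  }
  m <- matrix(c(0, c, b, 0), nrow = 2)  # only discordant cells matter
  tt <- stats::mcnemar.test(m, correct = correct)
  tibble::tibble(b = b, c = c, statistic = unname(tt$statistic),
                 p = tt$p.value, method = "chi_square", degenerate = FALSE)
}
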