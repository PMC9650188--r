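# Group-comparison statistics for the cohort tables: 2x2 chi-square
# contrasts and per-period two-sided Mann-Whitney tests.

#' Pearson chi-square for a 2x2 group-by-category table
#'
#' Pearson chi-square on 1 degree of freedom without continuity
#' correction (the convention that reproduces the printed cohort-table
#' statistics for the categorical contrasts).
#'
#' @param table A 2x2 matrix of counts (groups in rows), or the four
#'   counts `a, b, c, d` given as a numeric vector of length 4
#'   (row-wise).
#' @return Tibble `statistic`, `p_value`.
#' @export
#' @examples
#' chisq_2x2(matrix(c(6, 25, 29, 39), nrow = 2, byrow = TRUE))
chisq_2x2 <- function(table) {
  if (!is.matrix(table)) table <- matrix(table, nrow = 2, byrow = TRUE)
  stopifnot(all(dim(table) == 2), all(table >= 0))
  if (sum(table) == 0) abort("empty table")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    abort("zero marginal in 2x2 table")
  }
  ct <- stats::chisq.test(table, correct = FALSE)
  tibble::tibble(statistic = unname(ct$statistic),
                 p_value = unname(ct$p.value))
}

#' Two-sided Mann-Whitney test with normal approximation
#'
#' Rank-sum test of two samples using the normal approximation with tie
#' correction. The z statistic is signed by the first sample's rank-sum
#' deficit: z is negative when sample `a` ranks lower than expected under
#' the null, matching the sign convention of cohort comparison tables.
#'
#' @param a,b Numeric samples (non-empty).
#' @return Tibble `u` (Mann-Whitney U of sample `a`), `z`, `p_value`.
#'   When every pooled value is tied the test is degenerate: `z = 0`,
#'   `p = 1`, with a warning.
#' @export
#' @examples
#' mannwhitney_period(c(1, 2, 3, 4), c(5, 6, 7, 8))
mannwhitney_period <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b)) abort("both samples must be non-empty")
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  r <- rank(c(a, b))
  ra <- sum(r[seq_len(n1)])
  u <- ra - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(c(a, b))
  tie_term <- sum(ties^3 - ties)
  sig2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  if (sig2 <= 0) {
    warn("all pooled values tied; Mann-Whitney degenerate")
    return(tibble::tibble(u = u, z = 0, p_value = 1))
  }
  z <- (u - mu) / sqrt(sig2)
  tibble::tibble(u = u, z = z, p_value = 2 * stats::pnorm(-abs(z)))
}

#' Per-period group comparison table
#'
#' Runs the two-sided Mann-Whitney test per time period, with group
#' summaries (mean +/- SD) and a significance flag at the given alpha,
#' mirroring the layout of per-period cohort tables. Periods are reported
#' unadjusted for multiple comparisons.
#'
#' @param data Tibble with one row per record-period observation.
#' @param value,group,period Column names (strings) of the value, the
#'   two-level group and the period label.
#' @param ref Level of `group` treated as sample `a` (the z sign
#'   reference).
#' @param alpha Significance level.
#' @return Tibble: period, per-group mean and sd, `z`, `p_value`,
#'   `significant`.
#' @export
compare_periods <- function(data, value, group, period, ref = NULL,
                            alpha = 0.05) {
  levels <- unique(data[[group]])
  if (length(levels) != 2) abort("`group` must have exactly two levels")
  if (!is.null(ref)) levels <- c(ref, setdiff(levels, ref))
  purrr::map_dfr(unique(data[[period]]), function(p) {
    d <- data[data[[period]] == p, ]
    va <- d[[value]][d[[group]] == levels[1]]
    vb <- d[[value]][d[[group]] == levels[2]]
    mw <- mannwhitney_period(va, vb)
    tibble::tibble(
      period = p,
      group_a = levels[1], mean_a = mean(va, na.rm = TRUE),
      sd_a = stats::sd(va, na.rm = TRUE),
      group_b = levels[2], mean_b = mean(vb, na.rm = TRUE),
      sd_b = stats::sd(vb, na.rm = TRUE),
      z = mw$z, p_value = mw$p_value,
      significant = mw$p_value < alpha
    )
  })
}
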