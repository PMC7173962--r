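#' Two-group comparison with a single declared testing policy
#'
#' Two-sided Mann-Whitney U (Wilcoxon rank-sum) test: exact when both
#' groups are small and tie-free, normal approximation with tie correction
#' otherwise. The effect size is the rank-biserial correlation
#' `2 * U / (nA * nB) - 1`. A Welch t-test is available behind the `test`
#' flag.
#'
#' @param a,b numeric samples (>= 3 observations each).
#' @param test `"mann-whitney"` (default) or `"welch"`.
#' @return a `group_comparison`: list with `test`, `statistic`, `p_value`,
#'   `effect_size` (rank-biserial; Cohen's d for Welch), `n` (per group).
#' @export
compare_groups <- function(a, b, test = c("mann-whitney", "welch")) {
  test <- match.arg(test)
  if (length(a) < 3L || length(b) < 3L) {
    stop("at least 3 observations per group are required (got ",
         length(a), " and ", length(b), ")")
  }
  if (test == "mann-whitney") {
    ht <- suppressWarnings(stats::wilcox.test(a, b, exact = NULL,
                                              correct = TRUE))
    u <- unname(ht$statistic)
    eff <- 2 * u / (length(a) * length(b)) - 1
    structure(list(test = "mann-whitney", statistic = u,
                   p_value = unname(ht$p.value), effect_size = eff,
                   n = c(length(a), length(b))),
              class = "group_comparison")
  } else {
    ht <- stats::t.test(a, b)
    sp <- sqrt((stats::var(a) + stats::var(b)) / 2)
    structure(list(test = "welch", statistic = unname(ht$statistic),
                   p_value = unname(ht$p.value),
                   effect_size = (mean(a) - mean(b)) / sp,
                   n = c(length(a), length(b))),
              class = "group_comparison")
  }
}
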