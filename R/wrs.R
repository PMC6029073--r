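# Rank-sum p-values. Small groups are scored by exhaustive enumeration of
# all assignments of the pooled (mid)ranks, which is exact in the presence
# of ties; larger groups use stats::wilcox.test (exact where it can be,
# normal approximation with continuity correction otherwise).
wrs_p <- function(x, y, alternative = c("greater", "two.sided"),
                  max_combos = 50000) {
  alternative <- match.arg(alternative)
  n <- length(x)
  m <- length(y)
  if (choose(n + m, n) <= max_combos) {
    pooled <- rank(c(x, y))
    obs <- sum(pooled[seq_len(n)])
    stats_all <- utils::combn(n + m, n, FUN = function(idx)
      sum(pooled[idx]))
    hi <- mean(stats_all >= obs - 1e-9)
    lo <- mean(stats_all <= obs + 1e-9)
    if (alternative == "greater") hi else min(1, 2 * min(hi, lo))
  } else {
    suppressWarnings(
      stats::wilcox.test(x, y, alternative = alternative)$p.value)
  }
}
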