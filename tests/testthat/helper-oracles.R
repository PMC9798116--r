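# Independent oracles, coded from first principles and kept separate from
# the package implementation paths they check.

# Textbook Welch two-sample t: statistic, Welch-Satterthwaite df, two-sided p.
welch_p_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- sum((a - mean(a))^2) / (na - 1)
  vb <- sum((b - mean(b))^2) / (nb - 1)
  se2 <- va / na + vb / nb
  tstat <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  2 * stats::pt(-abs(tstat), df)
}

# Exact Mann-Whitney two-sided p by enumerating every assignment of the
# pooled values into groups of the observed sizes (doubled one-sided tail,
# capped at 1).
mw_exact_p_oracle <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  u_stat <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  idx <- utils::combn(length(pooled), na)
  us <- apply(idx, 2, function(i) u_stat(pooled[i], pooled[-i]))
  u_obs <- u_stat(a, b)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# Brute-force Venn regions: a membership table over the union, patterns
# counted directly.
venn_regions_oracle <- function(sets) {
  universe <- sort(unique(unlist(lapply(sets, function(s) unique(trimws(s))))))
  pat <- vapply(universe, function(g) {
    paste(names(sets)[vapply(sets, function(s) g %in% trimws(s), logical(1))],
          collapse = "&")
  }, character(1))
  tab <- table(pat)
  out <- stats::setNames(as.integer(tab), names(tab))
  out[sort(names(out))]
}
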