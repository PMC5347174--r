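# Independent oracles used by the property tests. These deliberately avoid
# the package's own code paths (and stats::fisher.test / stats::wilcox.test),
# working instead from first principles on small inputs.

# Two-sided Fisher exact p for the 2x2 table [[oL, nL-oL], [oH, nH-oH]],
# by direct hypergeometric enumeration with choose(): sum the point
# probabilities of all tables with the same margins that are no more
# probable than the observed one.
oracle_fisher_p <- function(oL, nL, oH, nH) {
  k <- oL + oH
  support <- max(0L, k - nH):min(nL, k)
  logp <- lchoose(nL, support) + lchoose(nH, k - support) - lchoose(nL + nH, k)
  p_obs <- logp[match(oL, support)]
  sum(exp(logp[logp <= p_obs + 1e-7]))
}

# Exact two-sided Mann-Whitney p by complete enumeration of group labelings:
# the fraction of labelings whose U statistic is at least as far from the
# null mean n1*n2/2 as the observed one. Ties handled by the usual 0.5
# convention. Feasible for n1 + n2 <= 16.
oracle_mwu <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pool <- c(x, y)
  u_stat <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  u_obs <- u_stat(x, y)
  combos <- utils::combn(n1 + n2, n1)
  us <- apply(combos, 2L, function(idx) u_stat(pool[idx], pool[-idx]))
  mid <- n1 * n2 / 2
  p <- mean(abs(us - mid) >= abs(u_obs - mid) - 1e-9)
  list(u = u_obs, p = p)
}

# A tiny deterministic corpus pair for stats tests: moderately sized, no
# planted bias unless asked for.
make_test_corpora <- function(n = 120, mean_length = 40, seed = 101,
                              planted = NULL) {
  cfg <- generator_config(n_sequences = n, mean_length = mean_length,
                          seed = seed, planted_bias = planted)
  suppressWarnings(generate_corpora(cfg))
}
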