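# Independent individual-level oracle for the life table: each of n people
# walks through the one-year intervals, dying with probability
# q_a = 1 - exp(-m_all(a)) and drawing a cause in proportion to the
# cause-specific hazards. Implemented with binomial/multinomial draws,
# which is distributionally identical to simulating people one by one.
microsim <- function(hazards, n, seed) {
  set.seed(seed)
  m_all <- rowSums(hazards)
  q <- 1 - exp(-m_all)
  deaths <- matrix(0, nrow(hazards), ncol(hazards),
                   dimnames = dimnames(hazards))
  alive <- n
  for (i in seq_len(nrow(hazards))) {
    d <- stats::rbinom(1, alive, q[i])
    if (d > 0) {
      deaths[i, ] <- stats::rmultinom(1, d, hazards[i, ] / m_all[i])
    }
    alive <- alive - d
  }
  w <- 70 - lifedecomp::model_ages() - 0.5
  list(n = n,
       risk = sum(deaths) / n,
       deaths_by_cause = colSums(deaths),
       mean_yll = sum(rowSums(deaths) * w) / n)
}
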