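# Independent reference implementations used as oracles.

# Brute-force pairing under the opposite-strand / max-separation rule with
# greedy left-to-right nearest-partner assignment, written as a direct nested
# scan over the sorted breaks (no bookkeeping shared with the package code).
oracleCluster <- function(breaks, maxSep = 10L) {
  b <- breaks[order(breaks$genomic_pos, breaks$strand), , drop = FALSE]
  n <- nrow(b)
  taken <- rep(FALSE, n)
  pairs <- list()
  for (i in seq_len(n)) {
    if (taken[i]) next
    best <- NA_integer_; bestD <- Inf
    for (j in seq_len(n)) {
      if (j == i || taken[j]) next
      if (b$strand[j] == b$strand[i]) next
      dj <- abs(b$genomic_pos[j] - b$genomic_pos[i])
      if (dj > maxSep) next
      if (dj < bestD || (dj == bestD && j < best)) { best <- j; bestD <- dj }
    }
    if (!is.na(best)) {
      taken[i] <- taken[best] <- TRUE
      pairs[[length(pairs) + 1L]] <- sort(c(b$genomic_pos[i],
                                            b$genomic_pos[best]))
    }
  }
  list(nSites = length(pairs),
       pairs = pairs,
       nIsolated = sum(!taken))
}

# Closed-form win probability of transition 1 in a two-way exponential race
# with means (tau1, tau2): P = (1/tau1) / (1/tau1 + 1/tau2).
raceWinProb <- function(tau1, tau2) (1 / tau1) / (1 / tau1 + 1 / tau2)

# A tiny deterministic damage set: k sites at given positions.
fixedDamage <- function(pos, chromatin = "euchromatin", lesions = 0L) {
  n <- nrow(pos)
  new("DamageSet",
      sites = data.frame(site_id = seq_len(n),
                         x = pos[, 1], y = pos[, 2], z = pos[, 3],
                         chromatin = rep_len(chromatin, n),
                         lesions_a_base = rep_len(as.integer(lesions), n),
                         lesions_a_ssb = 0L,
                         lesions_b_base = 0L, lesions_b_ssb = 0L,
                         stringsAsFactors = FALSE),
      dose = 1, quality = "photon", let = NA_real_, seed = NA_integer_,
      nucleus = nucleus())
}
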