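# Shared fixtures: small, deterministic objects built in code.

# Row-stochastic 5-motif transition matrix with sticky diagonal.
fixture_transition_matrix <- function(seed = 1, k = 5, sticky = 2) {
  set.seed(seed)
  P <- matrix(stats::runif(k * k), k, k)
  diag(P) <- diag(P) + sticky
  P <- P / rowSums(P)
  dimnames(P) <- list(LETTERS[seq_len(k)], LETTERS[seq_len(k)])
  P
}

# Independent brute-force transition matrix: explicit frame loop, no table().
brute_transition <- function(labels, motifs) {
  k <- length(motifs)
  M <- matrix(0, k, k, dimnames = list(motifs, motifs))
  for (i in seq_len(length(labels) - 1)) {
    a <- labels[i]; b <- labels[i + 1]
    if (a != b) M[a, b] <- M[a, b] + 1
  }
  rs <- rowSums(M)
  P <- M / ifelse(rs > 0, rs, NA_real_)
  P[rs == 0, ] <- NA_real_
  diag(P) <- NA_real_
  P
}

# Closed-form chi-square survival function for even df = 2k (Erlang series),
# independent of pchisq().
chisq_sf_even <- function(x, k) {
  j <- 0:(k - 1)
  exp(-x / 2) * sum((x / 2)^j / factorial(j))
}

# Match detected events to planted events by temporal overlap.
match_events <- function(detected, planted) {
  vapply(seq_len(nrow(planted)), function(i) {
    any(detected$onset < planted$onset[i] + planted$duration[i] &
        detected$onset + detected$duration > planted$onset[i])
  }, logical(1))
}
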