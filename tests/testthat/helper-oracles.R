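# Independent brute-force oracles used across the suite.

# O(N^2) template-matching sample entropy (Chebyshev distance, self-matches
# excluded), written independently of the package kernel
sampen_bruteforce <- function(x, m, r) {
  n <- length(x)
  nt <- n - m
  A <- 0; B <- 0
  for (i in seq_len(nt - 1)) {
    for (j in (i + 1):nt) {
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= r) {
        B <- B + 1
        if (max(abs(x[i:(i + m)] - x[j:(j + m)])) <= r) A <- A + 1
      }
    }
  }
  if (B == 0) return(NA_real_)
  if (A == 0) return(Inf)
  -log(A / B)
}

# Benjamini-Hochberg adjusted p-values from the definition:
# q_(i) = min_{j >= i} min(1, m p_(j) / j)
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, m * p[o] / seq_len(m))
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# small shared lead field (built once per test run)
test_leadfield <- local({
  lf <- NULL
  function() {
    if (is.null(lf)) lf <<- make_lead_field(32, c(5, 5, 4), 6)
    lf
  }
})

# match each true event to the nearest detected event; signed errors (s)
event_errors <- function(detected, true) {
  vapply(true, function(t) {
    d <- detected - t
    d[which.min(abs(d))]
  }, 0)
}
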