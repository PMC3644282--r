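# Shared generators for the test suite. All randomness is seeded locally.

tri_states <- c(-1L, 0L, 1L)

# random trinary matrix with given marginals (DOWN, NOCHANGE, UP)
make_tri <- function(n_rows, n_samples, seed = 1L,
                     marginals = c(0.25, 0.5, 0.25),
                     row_ids = sprintf("G%03d", seq_len(n_rows)),
                     sample_ids = sprintf("s%03d", seq_len(n_samples))) {
  withr::with_seed(seed, {
    m <- matrix(sample(tri_states, n_rows * n_samples, replace = TRUE,
                       prob = marginals),
                n_rows, n_samples, dimnames = list(row_ids, sample_ids))
  })
  trinary_matrix(m)
}

# two-variable dataset: y copies x with probability rho, else independent
make_pair <- function(n, rho, seed = 1L) {
  withr::with_seed(seed, {
    x <- sample(tri_states, n, replace = TRUE)
    y <- sample(tri_states, n, replace = TRUE)
    copy <- runif(n) < rho
    y[copy] <- x[copy]
  })
  trinary_matrix(rbind(A = x, B = y),
                 c("A", "B"), sprintf("s%03d", seq_len(n)))
}

# brute-force hypergeometric upper tail by direct summation of the mass
hyper_tail_oracle <- function(k, K, N, n) {
  if (k <= 0) return(1)
  kk <- seq(k, min(K, n))
  if (!length(kk)) return(0)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# independent summarization oracle: strict r-majority + hypergeometric tail
summ_oracle <- function(states, bg_states, r, p_th) {
  m <- length(states)
  N <- length(bg_states)
  for (dir in c(1L, -1L)) {
    k <- sum(states == dir)
    K <- sum(bg_states == dir)
    if (k > r * m && hyper_tail_oracle(k, K, N, m) < p_th) {
      return(if (dir == 1L) "UP" else "DOWN")
    }
  }
  "NOCHANGE"
}

# Benjamini-Hochberg step-up, written independently of stats::p.adjust
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# small boolean toggle network with a period-2 attractor
toggle_net <- function() boolean_network(c(A = "NOT A", B = "A"))
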