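# Shared fixtures: tiny deterministic matrices and small simulated
# communities built in code at test time.

toy_counts <- function() {
  m <- matrix(c(5L, 0L, 1L, 2L, 0L, 7L), nrow = 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  m
}

# brute-force BH step-up, independent of p.adjust
bh_brute <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  cummin_rev <- rev(cummin(rev(p[o] * n / seq_len(n))))
  adj[o] <- pmin(1, cummin_rev)
  adj
}

# brute-force rho from the defining variance formula
rho_brute <- function(filtered) {
  lx <- log(filtered)
  clr <- sweep(lx, 2L, colMeans(lx), "-")
  n <- nrow(clr)
  out <- diag(1, n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j) {
    out[i, j] <- 1 - var(clr[i, ] - clr[j, ]) /
      (var(clr[i, ]) + var(clr[j, ]))
  }
  dimnames(out) <- list(rownames(filtered), rownames(filtered))
  out
}

# moment-arithmetic bimodality oracle (independent expression of the same
# corrected-moment definition)
bimod_brute <- function(x) {
  n <- length(x)
  if (n < 4 || var(x) == 0) return(NA_real_)
  m2 <- sum((x - mean(x))^2) / n
  m3 <- sum((x - mean(x))^3) / n
  m4 <- sum((x - mean(x))^4) / n
  skew <- (sqrt(n * (n - 1)) / (n - 2)) * m3 / m2^(3 / 2)
  kurt <- ((n + 1) * (m4 / m2^2 - 3) + 6) * (n - 1) / ((n - 2) * (n - 3))
  (skew^2 + 1) / (kurt + 3 * (n - 1)^2 / ((n - 2) * (n - 3)))
}

# small default community used by several suites
small_sim <- function(seed = 7, ...) {
  simulate_community(sim_config(seed = seed, n_lineages = 16,
                                lineage_sizes = rep(c(1L, 2L, 4L, 8L), 4),
                                n_samples = 24, n_sites = 12, n_events = 1,
                                depth = 20000, n_crt = 4, ...))
}
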