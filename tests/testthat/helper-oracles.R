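# Independent brute-force oracles used across test files. These deliberately
# avoid the package's own code paths.

# overlap width by explicit base-set intersection (0-based half-open)
bf_overlap_bases <- function(s1, e1, s2, e2) {
  length(intersect(seq.int(s1, e1 - 1), seq.int(s2, e2 - 1)))
}

# Benjamini-Hochberg step-up, written from the definition
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  running <- 1
  for (k in n:1) {
    running <- min(running, n * p[o[k]] / k)
    adj[o[k]] <- running
  }
  pmin(adj, 1)
}

# AUC via the Mann-Whitney U identity (ties get rank averages)
mw_auc <- function(scores, labels) {
  r <- rank(scores)
  n1 <- sum(labels)
  n0 <- sum(!labels)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# two-sided Fisher exact p by full hypergeometric enumeration
# table = matrix(c(a, b, c, d), 2, byrow = TRUE); rows A/notA, cols B/notB
hyper_fisher_p <- function(a, b, c, d) {
  r1 <- a + b
  c1 <- a + c
  n <- a + b + c + d
  ks <- max(0, r1 + c1 - n):min(r1, c1)
  pr <- dhyper(ks, c1, n - c1, r1)
  pobs <- dhyper(a, c1, n - c1, r1)
  sum(pr[pr <= pobs * (1 + 1e-7)])
}

# number of meaningful local maxima of a kernel density estimate; bumps
# below min_height (relative to the global mode) are ignored, e.g. the
# atom contributed by occasional zero counts
count_modes <- function(x, adjust = 1, min_height = 0.05) {
  d <- density(x, adjust = adjust)
  y <- d$y
  peaks <- which(diff(sign(diff(y))) == -2) + 1
  sum(y[peaks] >= min_height * max(y))
}
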