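# Independent oracles used to freeze expected values. These deliberately use
# slow scalar loops / textbook formulas, not the package's vectorized paths.

# one classical multiplicative weighted-Frobenius NMF step (all weights 1):
# W <- W * (X H') / (W H H'); H <- H * (W' X) / (W' W H), W first, H with
# the updated W, matching the package's Gauss-Seidel ordering.
oracle_nmf_step <- function(X, W, H) {
  W <- W * (X %*% t(H)) / ((W %*% H) %*% t(H))
  H <- H * (t(W) %*% X) / (t(W) %*% (W %*% H))
  list(W = W, H = H)
}

# scalar-loop evaluation of the five-term objective
oracle_objective <- function(X, W, H, K_G = NULL, K_C = NULL,
                             sigma = 1, alpha = 0, beta = 0, lam = 0) {
  WH <- W %*% H
  obj <- 0
  for (g in seq_len(nrow(X))) {
    for (c in seq_len(ncol(X))) {
      r <- X[g, c] - WH[g, c]
      if (X[g, c] != 0) {
        obj <- obj + 0.5 * r^2
      } else {
        obj <- obj + 0.5 * (1 - exp(-r^2 / (2 * sigma^2)))
        obj <- obj + lam / 2 * WH[g, c]^2
      }
    }
  }
  if (alpha > 0) obj <- obj + alpha / 2 * sum((K_G - W %*% t(W))^2)
  if (beta > 0) obj <- obj + beta / 2 * sum((K_C - t(H) %*% H)^2)
  obj
}

# brute-force pair-counting ARI: agreement over all n(n-1)/2 item pairs
oracle_ari_paircount <- function(a, b) {
  n <- length(a)
  s11 <- s00 <- s10 <- s01 <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      same_a <- a[i] == a[j]
      same_b <- b[i] == b[j]
      if (same_a && same_b) s11 <- s11 + 1
      else if (!same_a && !same_b) s00 <- s00 + 1
      else if (same_a) s10 <- s10 + 1
      else s01 <- s01 + 1
    }
  }
  total <- s11 + s00 + s10 + s01
  expected <- (s11 + s10) * (s11 + s01) / total
  max_index <- ((s11 + s10) + (s11 + s01)) / 2
  if (max_index == expected) return(1)
  (s11 - expected) / (max_index - expected)
}

# direct-definition NMI with arithmetic-mean normalization
oracle_nmi <- function(a, b) {
  n <- length(a)
  ua <- unique(a); ub <- unique(b)
  mi <- 0
  for (x in ua) for (y in ub) {
    pxy <- sum(a == x & b == y) / n
    if (pxy > 0) {
      mi <- mi + pxy * log(pxy / ((sum(a == x) / n) * (sum(b == y) / n)))
    }
  }
  ent <- function(z) {
    p <- table(z) / length(z)
    -sum(p * log(p))
  }
  d <- (ent(a) + ent(b)) / 2
  if (d == 0) 0 else mi / d
}

# monotone-within-tolerance check used for objective traces
is_nonincreasing <- function(trace, tol = 1e-8) {
  if (length(trace) < 2) return(TRUE)
  all(diff(trace) <= tol * pmax(1, abs(trace[-length(trace)])))
}
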