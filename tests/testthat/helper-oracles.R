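# Independent brute-force oracles used to audit the package's statistics.
# These deliberately avoid the code paths (and where possible the R
# functions) the implementation uses.

# Two-sided exact binomial p at p0 = 0.5 by full enumeration of outcome
# probabilities (minlike rule, R's relative tolerance).
oracle_binom_p <- function(x, n) {
  pr <- dbinom(0:n, n, 0.5)
  min(1, sum(pr[pr <= pr[x + 1] * (1 + 1e-7)]))
}

# Welch t statistic, Welch-Satterthwaite df and two-sided p from the
# textbook formulas.
oracle_welch <- function(a, b) {
  va <- sum((a - mean(a))^2) / (length(a) - 1)
  vb <- sum((b - mean(b))^2) / (length(b) - 1)
  se2 <- va / length(a) + vb / length(b)
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / length(a))^2 / (length(a) - 1) +
                   (vb / length(b))^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Hypergeometric upper/lower tail by term-wise enumeration.
oracle_hyper <- function(k, K, N, n) {
  pr <- vapply(0:n, function(i) {
    exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n))
  }, numeric(1))
  list(over = sum(pr[(0:n) >= k]), under = sum(pr[(0:n) <= k]))
}

# OLS coefficient p-values via explicit normal equations and the t CDF.
# X: predictor matrix without intercept. Returns p per predictor column.
oracle_ols_p <- function(y, X) {
  X <- as.matrix(X)
  Xm <- cbind(1, X)
  XtX <- t(Xm) %*% Xm
  beta <- solve(XtX, t(Xm) %*% y)
  res <- y - Xm %*% beta
  df <- length(y) - ncol(Xm)
  s2 <- sum(res^2) / df
  se <- sqrt(diag(solve(XtX)) * s2)
  tval <- beta / se
  p <- 2 * pt(-abs(tval), df)
  p[-1]
}

# Pearson r^2 from first principles.
oracle_r2 <- function(a, b) {
  ca <- a - mean(a); cb <- b - mean(b)
  (sum(ca * cb))^2 / (sum(ca^2) * sum(cb^2))
}

# Linkage-group clumping by brute-force transitive closure: sites are
# connected when <= gap apart; groups are connected components; the lead
# is the member with the lowest p (leftmost on ties).
oracle_clump <- function(pos, p, gap = 65) {
  n <- length(pos)
  adj <- abs(outer(pos, pos, "-")) <= gap
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (adj[i, j] && comp[j] != comp[i]) {
          new <- min(comp[i], comp[j])
          comp[comp == comp[i] | comp == comp[j]] <- new
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  lead <- logical(n)
  for (g in unique(comp)) {
    i <- which(comp == g)
    i <- i[order(p[i], pos[i])]
    lead[i[1]] <- TRUE
  }
  list(component = comp, is_lead = lead)
}

# Kinship by explicit double loop over centered genotypes.
oracle_kinship <- function(G) {
  n <- nrow(G)
  Z <- sweep(G, 2, colMeans(G))
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) K[i, j] <- sum(Z[i, ] * Z[j, ])
  }
  K / mean(diag(K))
}

# Derivative-free REML maximization over non-negative variance
# components, started from an equal split (independent of the AI path).
oracle_reml <- function(y, kinships) {
  nk <- length(kinships)
  v0 <- rep(var(y) / (nk + 1), nk + 1)
  o <- optim(v0, function(th) -reml_loglik(th, kinships, y),
             method = "L-BFGS-B", lower = 1e-10,
             control = list(factr = 1e2, maxit = 2000))
  o$par / sum(o$par)
}
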