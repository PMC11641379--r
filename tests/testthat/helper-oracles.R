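# Independent brute-force oracles used to validate the package's
# implementations. These deliberately avoid the code paths they check.

# regional MS by explicit double loop over the textbook Pearson formula
oracle_regional_ms <- function(feat) {
  z <- feat
  for (j in seq_len(ncol(z))) {
    z[, j] <- (feat[, j] - mean(feat[, j])) / sd(feat[, j])
  }
  R <- nrow(z)
  r <- matrix(1, R, R)
  for (i in seq_len(R - 1)) {
    for (j in (i + 1):R) {
      xi <- z[i, ]; xj <- z[j, ]
      num <- sum((xi - mean(xi)) * (xj - mean(xj)))
      den <- sqrt(sum((xi - mean(xi))^2) * sum((xj - mean(xj))^2))
      r[i, j] <- r[j, i] <- num / den
    }
  }
  out <- numeric(R)
  for (i in seq_len(R)) {
    s <- 0
    for (j in seq_len(R)) if (j != i) s <- s + abs(r[i, j])
    out[i] <- s / (R - 1)
  }
  out
}

# Benjamini-Hochberg step-up by explicit sort / cumulative minimum
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) adj[i] <- min(adj[i], adj[i + 1])
  q <- numeric(m)
  q[o] <- pmin(adj, 1)
  q
}

# hypergeometric upper-tail P(X >= a) by direct pmf summation
oracle_hyper_tail <- function(a, n_target, n_query, N) {
  ks <- a:min(n_query, n_target)
  if (a > min(n_query, n_target)) return(0)
  sum(choose(n_target, ks) * choose(N - n_target, n_query - ks) /
        choose(N, n_query))
}

# OLS group coefficient via explicit normal equations
oracle_ols_group <- function(y, X) {
  xtx_inv <- solve(t(X) %*% X)
  beta <- xtx_inv %*% t(X) %*% y
  res <- y - X %*% beta
  s2 <- sum(res^2) / (length(y) - ncol(X))
  se <- sqrt(s2 * diag(xtx_inv))
  list(beta = drop(beta), se = se, t = drop(beta) / se,
       df = length(y) - ncol(X))
}

# random raw feature table in the study's shape
random_feature_table <- function(R = 34, K = 13) {
  m <- matrix(rnorm(R * K, mean = 5, sd = 2), R, K)
  dimnames(m) <- list(if (R == 34) msntx::dk_rois() else paste0("r", 1:R),
                      if (K == 13) msntx::msn_features() else paste0("f", 1:K))
  m
}

# minimal valid subject table for the contrast model
random_subjects <- function(n, p_pos = 0.5) {
  grp <- c("NEG_NEG", "POS_POS")[1 + (runif(n) < p_pos)]
  # force both groups present
  grp[1] <- "NEG_NEG"; grp[2] <- "POS_POS"
  data.frame(subject_id = sprintf("S%03d", seq_len(n)), group = grp,
             age = rnorm(n, 73, 7), gender = sample(c("M", "F"), n, TRUE),
             education = rnorm(n, 16, 2.5),
             mmse = pmin(30, pmax(0, round(rnorm(n, 28, 2)))),
             stringsAsFactors = FALSE)
}
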