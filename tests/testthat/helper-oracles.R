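# Independent oracles and fixture builders shared across tests.  Each oracle
# is deliberately written by a different route than the implementation it
# checks (explicit refits, Newton solves, hand arithmetic).

random_compositions <- function(n, D = 4, kappa = 1440) {
  m <- matrix(exp(stats::rnorm(n * D, 0, 1)), n, D)
  colnames(m) <- if (D == 4) timeuse_parts() else paste0("part", seq_len(D))
  m * (kappa / rowSums(m))
}

# Aitchison distance via clr, independent of the pivot basis machinery
aitchison_dist <- function(x, y) {
  clr <- function(v) log(v) - mean(log(v))
  sqrt(sum((clr(x) - clr(y))^2))
}

# Newton solve of the symmetric-balance constraint system:
# a + b + (D-2) c = 0;  a^2 + b^2 + (D-2) c^2 = 1;  2ab + (D-2) c^2 = 0
solve_symmetric_balance <- function(D, start = c(0.9, -0.1, -0.3)) {
  f <- function(p) {
    a <- p[1]; b <- p[2]; c <- p[3]
    c(a + b + (D - 2) * c,
      a^2 + b^2 + (D - 2) * c^2 - 1,
      2 * a * b + (D - 2) * c^2)
  }
  J <- function(p) {
    a <- p[1]; b <- p[2]; c <- p[3]
    rbind(c(1, 1, D - 2),
          c(2 * a, 2 * b, 2 * (D - 2) * c),
          c(2 * b, 2 * a, 2 * (D - 2) * c))
  }
  p <- start
  for (it in 1:50) {
    step <- solve(J(p), f(p))
    p <- p - step
    if (max(abs(step)) < 1e-14) break
  }
  p
}

# Brute-force nested-model F-test by explicit refits of design matrices
brute_force_F <- function(X_base, X_full, y) {
  rss <- function(X) {
    fit <- stats::lm.fit(cbind(1, X), y)
    sum(fit$residuals^2)
  }
  rss1 <- rss(X_base)
  rss2 <- rss(X_full)
  df1 <- ncol(X_full) - ncol(X_base)
  df2 <- length(y) - ncol(X_full) - 1L
  Fst <- ((rss1 - rss2) / df1) / (rss2 / df2)
  list(F = Fst, df1 = df1, df2 = df2,
       p = stats::pf(Fst, df1, df2, lower.tail = FALSE))
}

# Hand step-up Benjamini-Hochberg
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 1
  for (i in m:1) {
    running <- min(running, p[o[i]] * m / i)
    adj[o[i]] <- running
  }
  adj
}

# Small cohort-like fixture with an exact linear data-generating process
make_fixture_cohort <- function(n = 60, seed = 11) {
  set.seed(seed)
  comp <- random_compositions(n)
  data.frame(
    age = stats::rnorm(n, 65, 3),
    sex = factor(sample(c("male", "female"), n, TRUE),
                 levels = c("male", "female")),
    education = stats::rnorm(n, 16, 3),
    as.data.frame(comp),
    roi = stats::rnorm(n),
    y = stats::rnorm(n)
  )
}
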