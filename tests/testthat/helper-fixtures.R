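# Shared fixture builders and independent oracles.

# Hand-checkable 2x2 design with two replicates per cell; y ordered by
# cells (1,1),(1,2),(2,1),(2,2). Cell means (2,3,6,7) are exactly additive.
fixture_2x2 <- function() {
  list(design = observation_design(sprintf("o%d", 1:8),
                                   f1 = rep(c("a1", "a2"), each = 4),
                                   f2 = rep(rep(c("b1", "b2"), each = 2), 2)),
       y = c(1, 3, 2, 4, 5, 7, 6, 8))
}

# Brute-force least-squares oracle: explicit pseudo-inverse via SVD plus
# direct residual sum of squares; independent of the package's QR path.
oracle_ols <- function(X, y, tol = 1e-10) {
  sv <- svd(X)
  pos <- sv$d > tol * max(sv$d)
  beta <- sv$v[, pos, drop = FALSE] %*%
    ((t(sv$u[, pos, drop = FALSE]) %*% y) / sv$d[pos])
  res <- y - X %*% beta
  list(rss = sum(res^2), rank = sum(pos), df_resid = length(y) - sum(pos))
}

oracle_f_test <- function(X_full, X_reduced, y) {
  f <- oracle_ols(X_full, y)
  r <- oracle_ols(X_reduced, y)
  df1 <- r$df_resid - f$df_resid
  stat <- ((r$rss - f$rss) / df1) / (f$rss / f$df_resid)
  list(statistic = stat, df1 = df1, df2 = f$df_resid,
       p = stats::pf(stat, df1, f$df_resid, lower.tail = FALSE))
}

# Step-up BH definition applied literally.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# Random two-way design with every factor level populated.
random_design <- function(I, J, n) {
  repeat {
    f1 <- sample(seq_len(I), n, replace = TRUE)
    f2 <- sample(seq_len(J), n, replace = TRUE)
    if (length(unique(f1)) == I && length(unique(f2)) == J) break
  }
  observation_design(sprintf("o%d", seq_len(n)),
                     f1 = paste0("a", f1), f2 = paste0("b", f2))
}

# Closed-form ML log-likelihood of a fixed-effect Gaussian model.
gaussian_ml_loglik <- function(rss, n) {
  -n / 2 * (log(2 * pi * rss / n) + 1)
}

# Small balanced three-way design (subjects nested in f2).
small_three_way_design <- function(I = 2, J = 2, K = 2, n_subjects = 4) {
  grid <- expand.grid(f3 = seq_len(K), f1 = seq_len(I),
                      subject = seq_len(n_subjects))
  grid$f2 <- rep_len(seq_len(J), n_subjects)[grid$subject]
  observation_design(sprintf("n%d.i%d.k%d", grid$subject, grid$f1, grid$f3),
                     f1 = paste0("s", grid$f1), f2 = paste0("p", grid$f2),
                     f3 = paste0("t", grid$f3),
                     subject = paste0("n", grid$subject))
}
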