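# Shared fixtures and independent oracles for the test suite.

# Brute-force least-squares oracle: explicit normal equations, nothing
# shared with the package's fitting path.
oracle_ls <- function(X, y) {
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  res <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  s2 <- sum(res^2) / df
  se <- sqrt(s2 * diag(solve(XtX)))
  list(beta = drop(beta), se = se, t = drop(beta) / se, df = df)
}

# A random full-rank factorial instance: replicated condition rows (all 8
# design points available) plus noise, guaranteed rank 8.
random_instance <- function(coding = "containment") {
  conds <- c("B", "F", "K", "BF", "BK", "FK", "BFK", "media")
  reps <- sample(1:4, 8, replace = TRUE)
  rows <- rep(conds, reps)
  X <- t(vapply(rows, cocomet::encode_condition, numeric(8), coding = coding))
  rownames(X) <- sprintf("s%02d", seq_along(rows))
  beta <- rnorm(8)
  y <- drop(X %*% beta) + rnorm(nrow(X))
  list(X = X, y = y, beta = beta)
}

# Wrap a raw design matrix as the package's design_matrix so fit_feature
# can consume hand-built instances.
as_design_matrix <- function(X, coding = "containment") {
  qr_x <- qr(X)
  structure(list(X = X, coding = coding, rank = qr_x$rank,
                 null_space = NULL, samples = rownames(X)),
            class = "design_matrix")
}

# Small two-series design without the generator: n replicates of each of
# the 7 conditions per series plus media blanks.
tiny_design <- function(n = 2) {
  cocomet::study_layout(n_replicates = n)
}

# Feature table built directly from areas (features x samples).
ft_from <- function(areas) {
  cocomet::feature_table(areas)
}
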