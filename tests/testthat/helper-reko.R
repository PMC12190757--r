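# Shared fixtures and independent oracles.

# Standardized random Gaussian matrix.
rand_std <- function(n, p, seed) {
  set.seed(seed)
  standardize(matrix(rnorm(n * p), n, p))
}

# Columns of +/-1 from a full factorial design are exactly orthogonal in
# floating point (products are +/-s^2 and cancel pairwise), giving an exactly
# orthogonal standardized matrix.
orthogonal_design <- function(k = 3L) {
  G <- as.matrix(expand.grid(rep(list(c(-1, 1)), k)))
  n <- nrow(G)
  s <- 1 / sd(G[, 1L])
  m <- G * s
  colnames(m) <- paste0("V", seq_len(k))
  m
}

# Two standardized columns with exact sample correlation r.
corr_pair <- function(n, r, seed) {
  set.seed(seed)
  x1 <- scale(rnorm(n))
  e <- scale(resid(lm(rnorm(n) ~ x1)))
  x2 <- r * x1 + sqrt(1 - r^2) * e
  standardize(cbind(a = as.numeric(x1), b = as.numeric(x2)))
}

# Brute-force reflection oracle: per-column normal equations, optionally with
# ghost rows diag(1/sigma_j) appended (ridge form).
reflect_oracle <- function(Xv, sigma2 = NULL) {
  n <- nrow(Xv); p <- ncol(Xv)
  A <- Xv
  if (!is.null(sigma2)) {
    if (length(sigma2) == 1L) sigma2 <- rep(sigma2, p)
    A <- rbind(Xv, diag(1 / sqrt(sigma2), p))
  }
  Y <- matrix(0, n, p)
  for (j in seq_len(p)) {
    b <- solve(crossprod(A[, -j, drop = FALSE]),
               crossprod(A[, -j, drop = FALSE], A[, j]))
    Y[, j] <- (2 * A[, -j, drop = FALSE] %*% b - A[, j])[seq_len(n)]
  }
  Y
}

# Brute-force knockoff threshold: scan every candidate t.
threshold_oracle <- function(W, q, variant) {
  cand <- sort(unique(abs(W[W != 0])))
  off <- if (variant == "knockoff_plus") 1 else 0
  for (t in cand) {
    if ((sum(W <= -t) + off) / max(sum(W >= t), 1) <= q) return(t)
  }
  Inf
}
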