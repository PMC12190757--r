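# Dense oracle for the profile likelihood: multivariate normal log density
# of the marginal covariance tau^-1 (sigma2 * G + I), maximized over tau on
# a fine grid.
dense_profile_oracle <- function(sigma2, G, x) {
  m <- length(x)
  S0 <- sigma2 * G + diag(m)
  taus <- exp(seq(-8, 8, length.out = 2000))
  best <- -Inf
  ch <- chol(S0)
  ldet <- 2 * sum(log(diag(ch)))
  qf <- sum(backsolve(ch, x, transpose = TRUE)^2)
  for (tau in taus) {
    ll <- (m / 2) * log(tau) - 0.5 * ldet - 0.5 * tau * qf
    if (ll > best) best <- ll
  }
  best
}

test_that("profile likelihood matches the dense covariance oracle", {
  set.seed(20)
  n <- 12; p <- 5
  Xm <- matrix(rnorm(n * p), n, p)
  G <- tcrossprod(Xm)
  x <- rnorm(n)
  ed <- eigen(G, symmetric = TRUE)
  u2 <- drop(crossprod(ed$vectors, x))^2
  d <- pmax(ed$values, 0)
  for (s2 in c(0.05, 0.3, 0.9)) {
    ours <- profile_loglik(s2, d, u2)
    oracle <- dense_profile_oracle(s2, G, x)
    # equal up to an additive constant independent of sigma2: compare deltas
    ours0 <- profile_loglik(0.5, d, u2)
    oracle0 <- dense_profile_oracle(0.5, G, x)
    expect_equal(ours - ours0, oracle - oracle0, tolerance = 1e-4)
  }
})

test_that("profile likelihood limits behave as stated", {
  u2 <- c(2, 1, 0.5)
  expect_equal(profile_loglik(0.3, rep(0, 3), u2),
               profile_loglik(0.9, rep(0, 3), u2))   # constant when d = 0
  d <- c(3, 1, 0)
  lim <- -(3 / 2) * log(sum(u2))
  expect_equal(profile_loglik(1e-12, d, u2), lim, tolerance = 1e-6)
  expect_error(profile_loglik(0.5, d, c(0, 0, 0)), "degenerate")
})

test_that("bisection maximizer agrees with a 1000-point grid search", {
  grid <- seq(1e-6, 1, length.out = 1000)
  for (seed in 1:30) {
    set.seed(seed)
    m <- 50
    d <- c(runif(10, 0, 40), rep(0, m - 10))
    u2 <- rchisq(m, 1) * c(rep(3, 10), rep(0.5, m - 10))
    est <- estimate_sigma_j(d, u2)
    gl <- vapply(grid, profile_loglik, numeric(1), d = d, u2 = u2)
    expect_lt(abs(as.numeric(est) - grid[which.max(gl)]), 1e-3)
  }
})

test_that("concentrating the response on high-eigenvalue coordinates raises sigma2", {
  set.seed(31)
  m <- 40
  d <- sort(rchisq(m, 3) * 10, decreasing = TRUE)
  # response energy flat across coordinates: no covariate signal, sigma2 low;
  # energy proportional to d: strong signal along the structure, sigma2 high
  lo <- as.numeric(estimate_sigma_j(d, rep(1, m)))
  hi <- as.numeric(estimate_sigma_j(d, d + 0.1))
  expect_gt(hi, lo)
})

test_that("flat likelihood (d = 0) is flagged", {
  est <- estimate_sigma_j(rep(0, 5), c(1, 2, 3, 1, 2))
  expect_identical(attr(est, "flag"), "flat")
})

test_that("rank-one downdate matches dense eigendecomposition", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(4:8, 1); p <- sample(3:6, 1)
    Xm <- matrix(rnorm(n * p), n, p)
    A <- tcrossprod(Xm)
    ed <- eigen(A, symmetric = TRUE)
    for (j in seq_len(p)) {
      up <- eigen_downdate(ed$values, ed$vectors, Xm[, j])
      dn <- eigen(A - tcrossprod(Xm[, j]), symmetric = TRUE,
                  only.values = TRUE)$values
      expect_lt(max(abs(up - dn) / pmax(abs(dn), max(abs(dn)) * 1e-8)), 1e-6)
      # interlacing: new values sit at or below the originals, and above the
      # next original eigenvalue
      lam <- sort(ed$values, decreasing = TRUE)
      expect_true(all(up <= lam + 1e-8 * max(abs(lam))))
      expect_true(all(up[-length(up)] >= lam[-1] - 1e-8 * max(abs(lam))))
    }
  }
})

test_that("downdating by a zero vector changes nothing", {
  set.seed(40)
  A <- crossprod(matrix(rnorm(30), 6, 5))
  ed <- eigen(A, symmetric = TRUE)
  expect_equal(eigen_downdate(ed$values, ed$vectors, rep(0, 5)), ed$values)
})

test_that("randomized SVD recovers leading eigenpairs", {
  set.seed(41)
  # exact low rank
  L <- matrix(rnorm(60 * 3), 60, 3) %*% matrix(rnorm(3 * 40), 3, 40)
  ev <- rsvd_topk(L, 3, seed = 1)
  dense <- eigen(tcrossprod(L), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(ev$values, dense[1:3], tolerance = 1e-6)
  # decaying spectrum: 1% relative accuracy
  n <- 80; p <- 60
  U <- qr.Q(qr(matrix(rnorm(n * p), n, p)))
  V <- qr.Q(qr(matrix(rnorm(p * p), p, p)))
  d <- 30 * 0.9^(0:(p - 1))
  Xd <- U %*% (d * t(V))
  ev2 <- rsvd_topk(Xd, 10, seed = 2)
  expect_lt(max(abs(ev2$values - d[1:10]^2) / d[1:10]^2), 0.01)
  # full-k falls back to the dense decomposition
  ev3 <- rsvd_topk(Xd, p, seed = 3)
  expect_equal(ev3$values, d^2, tolerance = 1e-8)
  # determinism
  expect_identical(rsvd_topk(Xd, 5, seed = 9), rsvd_topk(Xd, 5, seed = 9))
})

test_that("prior estimation modes agree and behave on unstructured features", {
  X <- rand_std(100, 15, seed = 42)
  pe_exact <- estimate_priors(X, mode = "exact")
  pe_r1u <- estimate_priors(X, mode = "rank-one-update")
  expect_lt(max(abs(pe_exact$sigma2 - pe_r1u$sigma2)), 0.05)
  expect_true(all(pe_r1u$sigma2 > 0 & pe_r1u$sigma2 <= 1))
  # independent features: little structure to explain, so most prior
  # variances collapse toward the lower boundary
  X2 <- rand_std(200, 10, seed = 43)
  pe2 <- estimate_priors(X2, mode = "exact")
  expect_gt(mean(pe2$sigma2 < 0.05), 0.5)
  # determinism
  expect_identical(estimate_priors(X, mode = "rank-one-update"),
                   estimate_priors(X, mode = "rank-one-update"))
  expect_identical(estimate_priors(X, mode = "rsvd", k = 10, seed = 7),
                   estimate_priors(X, mode = "rsvd", k = 10, seed = 7))
})

test_that("simulated ridge data recover the generating prior variance", {
  # data drawn from the hierarchical model with sigma2 = 0.25
  hits <- 0L
  for (seed in 1:15) {
    set.seed(seed)
    n <- 500; p <- 20
    Xm <- matrix(rnorm(n * p), n, p)
    b <- rnorm(p - 1, 0, sqrt(0.25))
    xj <- Xm[, -1] %*% b + rnorm(n)
    sv <- svd(Xm[, -1], nu = p - 1, nv = 0)
    u2 <- drop(crossprod(sv$u, xj))^2
    d <- c(sv$d^2, rep(0, n - (p - 1)))
    uu <- c(u2, max(0, sum(xj^2) - sum(u2)), rep(0, n - p))
    est <- as.numeric(estimate_sigma_j(d, uu))
    if (est > 0.1 && est < 0.6) hits <- hits + 1L
  }
  expect_gte(hits, 13L)
})
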