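#' Lasso coefficient importance for features and their knockoffs
#'
#' Fits an L1-penalized linear regression of the phenotype on the combined
#' matrix \code{[X, Xt]} and returns the absolute coefficients as importance
#' scores. The 2p columns are randomly interleaved (seeded) before fitting so
#' the coordinate-descent path order cannot systematically favor originals
#' over knockoffs, which would break the null sign-symmetry of the knockoff
#' statistics. The penalty is chosen by K-fold cross-validation unless a
#' fixed \code{lambda} is supplied.
#'
#' @param X Feature matrix (n x p) or \code{"feature_matrix"}.
#' @param Xt Knockoff matrix of the same shape.
#' @param y Numeric phenotype of length n (centered internally).
#' @param seed Optional integer seed (interleaving and CV folds).
#' @param nfolds Cross-validation folds (default 5).
#' @param lambda Optional fixed penalty; skips cross-validation.
#' @return Numeric vector of length 2p: absolute coefficients for the p
#'   original features followed by their p knockoffs.
#' @export
lasso_importance <- function(X, Xt, y, seed = NULL, nfolds = 5L, lambda = NULL) {
  X <- as_feature_matrix(X)
  if (!all(dim(Xt) == dim(X$values))) stop("Xt must match the shape of X")
  if (length(y) != X$n) stop("y must have length n = ", X$n)
  if (stats::var(y) <= 0) stop("phenotype has zero variance")
  y <- y - mean(y)
  p <- X$p
  W2p <- cbind(X$values, Xt)
  if (!is.null(seed)) set.seed(seed)
  perm <- sample.int(2L * p)
  Wp <- W2p[, perm, drop = FALSE]
  colnames(Wp) <- paste0("c", seq_len(2L * p))
  if (is.null(lambda)) {
    fit <- glmnet::cv.glmnet(Wp, y, standardize = FALSE, nfolds = nfolds)
    co <- stats::coef(fit, s = "lambda.min")
  } else {
    fit <- glmnet::glmnet(Wp, y, standardize = FALSE, lambda = lambda)
    co <- stats::coef(fit, s = lambda)
  }
  co <- abs(as.numeric(co)[-1L])   # drop intercept
  imp <- numeric(2L * p)
  imp[perm] <- co
  imp
}

#' Posterior inclusion probabilities from a spike-and-slab sampler
#'
#' Runs a Gibbs sampler for Bayesian variable selection regression of the
#' phenotype on \code{[X, Xt]}: each coefficient is zero with prior
#' probability \code{1 - pi0} or drawn from a Gaussian slab, the indicators
#' and coefficients are updated one column at a time against the running
#' residual, and the noise variance gets an inverse-gamma update. After each
#' sweep, every included column is additionally paired with a random other
#' column for a joint block update of the two indicators (both coefficients
#' integrated out), which lets inclusion migrate between highly correlated
#' columns — the model-averaging behavior that single-site updates alone
#' cannot mix into. The phenotype is standardized internally so the slab
#' variance is on a comparable scale. Returns the posterior inclusion
#' probability of each of the 2p columns.
#'
#' @inheritParams lasso_importance
#' @param mcmc List of sampler settings: \code{iters} (total sweeps, default
#'   2000), \code{burnin} (default 500), \code{pi0} (prior inclusion
#'   probability, default \code{1/p}), \code{slab_var} (slab variance,
#'   default 1).
#' @return Numeric vector of length 2p of PIPs in [0, 1], originals first.
#' @export
pip_importance <- function(X, Xt, y, mcmc = list(), seed = NULL) {
  X <- as_feature_matrix(X)
  if (!all(dim(Xt) == dim(X$values))) stop("Xt must match the shape of X")
  if (length(y) != X$n) stop("y must have length n = ", X$n)
  if (stats::var(y) <= 0) stop("phenotype has zero variance")
  p <- X$p; n <- X$n
  iters <- mcmc$iters %||% 2000L
  burnin <- mcmc$burnin %||% 500L
  pi0 <- mcmc$pi0 %||% (1 / p)
  v <- mcmc$slab_var %||% 1
  if (iters <= burnin) stop("iters must exceed burnin")

  y <- as.numeric(scale(y))
  W <- cbind(X$values, Xt)
  P2 <- 2L * p
  s <- colSums(W^2)
  if (!is.null(seed)) set.seed(seed)

  gam <- rep(FALSE, P2)
  b <- numeric(P2)
  r <- y
  sig2 <- 1
  logit0 <- log(pi0) - log1p(-pi0)
  hits <- numeric(P2)

  for (it in seq_len(iters)) {
    for (j in seq_len(P2)) {
      if (b[j] != 0) r <- r + W[, j] * b[j]
      mj <- sum(W[, j] * r)
      post_var <- 1 / (s[j] / sig2 + 1 / v)
      post_mean <- post_var * mj / sig2
      lo <- logit0 + 0.5 * (log(post_var) - log(v)) +
        0.5 * post_mean^2 / post_var
      if (stats::runif(1) < 1 / (1 + exp(-lo))) {
        b[j] <- stats::rnorm(1, post_mean, sqrt(post_var))
        gam[j] <- TRUE
        r <- r - W[, j] * b[j]
      } else {
        b[j] <- 0
        gam[j] <- FALSE
      }
    }
    # pairwise block updates: for each included column, join it with a random
    # partner and resample both indicators with coefficients integrated out
    inc <- which(gam)
    if (length(inc) > 0L && P2 > 1L) {
      for (j in inc[seq_len(min(length(inc), 25L))]) {
        k <- sample.int(P2 - 1L, 1L)
        if (k >= j) k <- k + 1L
        r0 <- r + W[, j] * b[j] + W[, k] * b[k]
        G <- crossprod(W[, c(j, k)])
        mvec <- drop(crossprod(W[, c(j, k)], r0))
        # relative log posterior of the four inclusion states
        lp <- numeric(4)                     # {}, {j}, {k}, {j,k}
        lodds <- logit0
        for (st in 2:4) {
          idx <- list(1L, 2L, 1:2)[[st - 1L]]
          Gs <- G[idx, idx, drop = FALSE]
          Ms <- Gs + diag(sig2 / v, length(idx))
          lp[st] <- length(idx) * lodds -
            0.5 * determinant(diag(length(idx)) + (v / sig2) * Gs)$modulus +
            0.5 * drop(crossprod(mvec[idx], solve(Ms, mvec[idx]))) / sig2
        }
        pr <- exp(lp - max(lp))
        st <- sample.int(4L, 1L, prob = pr)
        idx <- list(integer(0), 1L, 2L, 1:2)[[st]]
        bnew <- c(0, 0)
        if (length(idx)) {
          Prec <- G[idx, idx, drop = FALSE] / sig2 + diag(1 / v, length(idx))
          ch <- chol(Prec)
          mu <- backsolve(ch, backsolve(ch, mvec[idx] / sig2, transpose = TRUE))
          bnew[idx] <- mu + backsolve(ch, stats::rnorm(length(idx)))
        }
        gam[c(j, k)] <- c(1L, 2L) %in% idx
        b[c(j, k)] <- bnew
        r <- r0 - W[, c(j, k)] %*% bnew
      }
    }
    sig2 <- 1 / stats::rgamma(1, shape = 0.01 + n / 2,
                              rate = 0.01 + sum(r^2) / 2)
    if (it > burnin) hits <- hits + gam
  }
  hits / (iters - burnin)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Knockoff statistics from paired importance scores
#'
#' \code{W_j = importance(original j) - importance(knockoff j)}. Under the
#' null the two are exchangeable, so W_j is symmetric about zero.
#'
#' @param importance Numeric vector of length 2p, originals first (as
#'   returned by [lasso_importance()] or [pip_importance()]).
#' @return Numeric vector of length p.
#' @export
knockoff_stats <- function(importance) {
  l <- length(importance)
  if (l %% 2L != 0L || l < 2L) stop("importance must have even length 2p")
  p <- l %/% 2L
  importance[seq_len(p)] - importance[p + seq_len(p)]
}
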