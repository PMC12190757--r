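#' Profile log marginal likelihood of the per-feature prior variance
#'
#' Log marginal likelihood of the ridge-regression variance component
#' \code{sigma2}, after rotating the regression of one feature on the rest
#' into the eigenbasis of the Gram matrix of the remaining features and
#' profiling out the residual precision \code{tau} at its ML value:
#' \deqn{\ell(\sigma^2) = -\frac{m}{2}\log\sum_i \frac{u_i^2}{\sigma^2 d_i + 1}
#'       - \frac{1}{2}\sum_i \log(\sigma^2 d_i + 1)}
#' up to an additive constant independent of \code{sigma2}.
#'
#' @param sigma2 Positive scalar, the prior variance.
#' @param d Nonnegative eigenvalues of the Gram matrix (length m).
#' @param u2 Squared coordinates of the response in the eigenbasis (length m).
#' @return Scalar log likelihood (relative).
#' @export
profile_loglik <- function(sigma2, d, u2) {
  if (length(d) != length(u2)) stop("d and u2 must have the same length")
  if (sigma2 <= 0) stop("sigma2 must be positive")
  if (all(u2 == 0)) stop("degenerate response: all rotated coordinates are zero")
  m <- length(d)
  w <- sigma2 * d + 1
  -(m / 2) * log(sum(u2 / w)) - 0.5 * sum(log(w))
}

# derivative of profile_loglik w.r.t. sigma2
profile_score <- function(sigma2, d, u2) {
  m <- length(d)
  w <- sigma2 * d + 1
  A <- sum(u2 / w)
  (m / 2) * sum(u2 * d / w^2) / A - 0.5 * sum(d / w)
}

#' Maximum-likelihood prior variance for one feature by bisection
#'
#' Maximizes [profile_loglik()] over \code{sigma2} in \code{(lower, 1]} by
#' bisecting its derivative. The upper bound 1 is a practical cap that keeps
#' the search stable; features wanting more shrinkage freedom than that are
#' truncated at the cap. If the derivative has the same sign at both ends the
#' better endpoint is returned and flagged as a boundary solution; if the
#' likelihood carries no information about \code{sigma2} (all \code{d} zero)
#' the result is flagged \code{"flat"}.
#'
#' @inheritParams profile_loglik
#' @param tol Bisection tolerance on \code{sigma2}.
#' @param lower Lower end of the search interval.
#' @return The estimate, a scalar in \code{(0, 1]}, with attributes
#'   \code{"flag"} (\code{"interior"}, \code{"boundary"} or \code{"flat"}) and
#'   \code{"loglik"} (profile log likelihood at the estimate).
#' @export
estimate_sigma_j <- function(d, u2, tol = 1e-8, lower = 1e-6) {
  if (all(u2 == 0)) stop("degenerate response: all rotated coordinates are zero")
  if (all(d <= 0)) {
    out <- 1
    attr(out, "flag") <- "flat"
    attr(out, "loglik") <- profile_loglik(1, d, u2)
    return(out)
  }
  lo <- lower; hi <- 1
  glo <- profile_score(lo, d, u2)
  ghi <- profile_score(hi, d, u2)
  if (glo <= 0 || ghi >= 0) {
    # no interior sign change: the maximizer sits at an endpoint
    cand <- if (profile_loglik(lo, d, u2) >= profile_loglik(hi, d, u2)) lo else hi
    out <- cand
    attr(out, "flag") <- "boundary"
    attr(out, "loglik") <- profile_loglik(cand, d, u2)
    return(out)
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (profile_score(mid, d, u2) > 0) lo <- mid else hi <- mid
  }
  out <- (lo + hi) / 2
  attr(out, "flag") <- "interior"
  attr(out, "loglik") <- profile_loglik(out, d, u2)
  out
}

# Solve the secular equation for the eigenvalues of diag(lam) - z z^t,
# lam sorted decreasing. Roots mu_k interlace: lam_{k+1} <= mu_k <= lam_k,
# and the bottom root lies in [lam_m - ||z||^2, lam_m]. All roots are
# bisected simultaneously (vectorized over k). Coordinates with negligible
# z are deflated: their eigenvalues pass through unchanged.
secular_downdate <- function(lam, z, maxit = 90L) {
  m <- length(lam)
  z2 <- z^2
  znorm2 <- sum(z2)
  if (znorm2 == 0) return(lam)
  scale <- max(abs(lam[1L]), znorm2, 1e-300)
  active <- z2 > scale * 1e-14
  if (!any(active)) return(lam)
  la <- lam[active]
  za2 <- z2[active]
  ma <- length(la)
  zs <- sum(za2)

  lo <- c(la[-1L], la[ma] - zs)
  hi <- la
  # f(mu) = 1 - sum_i za2_i / (la_i - mu); decreasing from +Inf to -Inf on
  # each open bracket
  for (it in seq_len(maxit)) {
    mid <- (lo + hi) / 2
    fmid <- 1 - colSums(za2 / (outer(la, mid, "-")))
    up <- is.finite(fmid) & fmid > 0
    lo[up] <- mid[up]
    hi[!up] <- mid[!up]
    if (max(hi - lo) < 1e-15 * scale) break
  }
  roots <- (lo + hi) / 2
  out <- sort(c(roots, lam[!active]), decreasing = TRUE)
  out
}

# Downdated eigenvalues of diag(lam) - z z^t together with the squared
# projections of x (the vector whose rotated coordinates are z) onto the
# downdated eigenvectors. The eigenvector for root mu is proportional to
# (diag(lam) - mu)^{-1} z, and since the secular equation fixes
# sum z_i^2/(lam_i - mu) = 1, the squared projection collapses to
# 1 / sum_i z_i^2 / (lam_i - mu)^2. Deflated coordinates (negligible z_i)
# keep eigenvalue lam_i and projection z_i^2.
downdate_spectrum <- function(lam, z) {
  z2 <- z^2
  znorm2 <- sum(z2)
  scale <- max(abs(lam[1L]), znorm2, 1e-300)
  active <- z2 > scale * 1e-14
  if (znorm2 == 0 || !any(active)) {
    return(list(values = lam, u2 = z2))
  }
  la <- lam[active]
  za2 <- z2[active]
  roots <- secular_downdate(la, z[active])
  u2a <- vapply(roots, function(mu) {
    denom <- sum(za2 / (la - mu)^2)
    if (!is.finite(denom) || denom <= 0) 0 else 1 / denom
  }, numeric(1))
  vals <- c(roots, lam[!active])
  u2 <- c(u2a, z2[!active])
  ord <- order(vals, decreasing = TRUE)
  list(values = vals[ord], u2 = u2[ord])
}

#' Rank-one eigenvalue downdate via the secular equation
#'
#' Given the eigendecomposition of a symmetric matrix A (typically X X'),
#' returns the eigenvalues of \code{A - xj xj'} without re-decomposing:
#' rotating \code{xj} into the eigenbasis reduces the problem to a diagonal
#' minus rank-one matrix, whose eigenvalues are the roots of a secular
#' equation, each bracketed by interlacing and found by bisection. With exact
#' eigenvectors the result is exact up to root-finding tolerance. If the
#' secular solve fails its residual check, the dense eigendecomposition of
#' the downdated matrix is used as a fallback (and reported via a warning).
#'
#' @param eigvals Eigenvalues of A, decreasing.
#' @param eigvecs Matrix of matching eigenvectors (columns).
#' @param xj Vector conformable with the eigenvectors.
#' @return Numeric vector of updated eigenvalues, decreasing.
#' @export
eigen_downdate <- function(eigvals, eigvecs, xj) {
  if (length(xj) != nrow(eigvecs)) stop("xj length must match eigenvector rows")
  ord <- order(eigvals, decreasing = TRUE)
  lam <- eigvals[ord]
  z <- drop(crossprod(eigvecs[, ord, drop = FALSE], xj))
  out <- tryCatch(secular_downdate(lam, z), error = function(e) NULL)
  ok <- !is.null(out) && length(out) == length(lam) &&
    all(diff(out) <= 1e-8 * max(1, abs(lam[1L])))
  if (!ok) {
    warning("secular solve failed; falling back to dense eigendecomposition")
    out <- eigen(diag(lam, length(lam)) - tcrossprod(z), symmetric = TRUE,
                 only.values = TRUE)$values
  }
  out
}

#' Approximate leading eigenpairs of X X' by randomized SVD
#'
#' Randomized range finder with oversampling and power iterations: sketches
#' the column space of X with a Gaussian test matrix, orthonormalizes, and
#' recovers the top-k eigenpairs of X X' from the small projected problem.
#' When k reaches \code{min(n, p)} the dense SVD is used instead.
#'
#' @param X Numeric matrix (n x p) or \code{"feature_matrix"}.
#' @param k Number of leading eigenpairs.
#' @param seed Integer seed for the Gaussian test matrix.
#' @param oversample Extra sketch columns (default 10).
#' @param power_iter Power iterations sharpening the spectrum (default 2).
#' @return List with \code{values} (length k, decreasing eigenvalues of X X')
#'   and \code{vectors} (n x k orthonormal).
#' @export
rsvd_topk <- function(X, k, seed = NULL, oversample = 10L, power_iter = 2L) {
  if (inherits(X, "feature_matrix")) X <- X$values
  n <- nrow(X); p <- ncol(X)
  if (k < 1L || k > min(n, p)) stop("k must be between 1 and min(n, p)")
  if (!is.null(seed)) set.seed(seed)
  if (k == min(n, p)) {
    sv <- svd(X, nu = k, nv = 0)
    return(check_rank_k(list(values = sv$d[seq_len(k)]^2,
                             vectors = sv$u), k))
  }
  l <- min(k + oversample, min(n, p))
  Om <- matrix(stats::rnorm(p * l), p, l)
  Yk <- X %*% Om
  for (i in seq_len(power_iter)) {
    Yk <- qr.Q(qr(Yk))
    Yk <- X %*% crossprod(X, Yk)
  }
  Qm <- qr.Q(qr(Yk))
  B <- crossprod(Qm, X)           # l x p
  sv <- svd(B, nu = l, nv = 0)
  vals <- sv$d^2
  vecs <- Qm %*% sv$u
  check_rank_k(list(values = vals[seq_len(k)],
                    vectors = vecs[, seq_len(k), drop = FALSE]), k)
}

check_rank_k <- function(ev, k) {
  tol <- max(ev$values) * 1e-12
  r <- sum(ev$values > tol)
  if (r < k) {
    warning("requested ", k, " eigenpairs but numerical rank is ", r,
            "; truncating")
    ev$values <- ev$values[seq_len(r)]
    ev$vectors <- ev$vectors[, seq_len(r), drop = FALSE]
  }
  ev
}

#' Empirical-Bayes prior variances for every feature
#'
#' Estimates the shrinkage prior variance \code{sigma_j^2} of each feature's
#' reflection regression by maximizing the profile marginal likelihood
#' ([profile_loglik()]). The eigenvectors of X X' are shared across features;
#' only the eigenvalues are corrected per feature by the rank-one downdate
#' ([eigen_downdate()]), which is exact for the eigenvalues whenever
#' \code{xj} lies in the retained eigenspace. Modes:
#' \describe{
#'   \item{exact}{dense eigendecomposition of each leave-one-out Gram matrix
#'     (slow; the reference oracle).}
#'   \item{rank-one-update}{full SVD of X once, secular-equation downdates per
#'     feature (default).}
#'   \item{rsvd}{randomized top-k eigenpairs of X X' (see [rsvd_topk()]) plus
#'     downdates; for large problems.}
#' }
#'
#' @param X \code{"feature_matrix"} or standardized matrix.
#' @param mode One of \code{"rank-one-update"}, \code{"exact"}, \code{"rsvd"}.
#' @param k Number of leading eigenpairs kept in \code{"rsvd"} mode
#'   (default \code{min(200, n, p)}).
#' @param seed Seed for the randomized sketch (rsvd mode only).
#' @return Object of class \code{"prior_estimate"}: list with \code{sigma2}
#'   (length p, each in (0, 1]), \code{method}, \code{k_eigenpairs},
#'   \code{loglik_at_opt} and \code{flag} (per-feature solution type;
#'   flat-likelihood features are filled with the default 1/p).
#' @export
estimate_priors <- function(X, mode = c("rank-one-update", "exact", "rsvd"),
                            k = NULL, seed = NULL) {
  mode <- match.arg(mode)
  X <- as_feature_matrix(X)
  Xv <- X$values
  n <- X$n; p <- X$p
  sigma2 <- numeric(p)
  flags <- character(p)
  ll <- numeric(p)

  # Embed the m retained eigen-coordinates in the full n-dimensional rotated
  # model: the remaining directions have zero Gram eigenvalue, and the part of
  # xj outside the retained eigenspace lands there as a residual coordinate.
  pad_fit <- function(d, u2, xnorm2) {
    d <- pmax(d, 0)
    m <- length(d)
    resid <- max(0, xnorm2 - sum(u2))
    dd <- numeric(n); dd[seq_len(m)] <- d
    uu <- numeric(n); uu[seq_len(m)] <- u2
    if (m < n) uu[m + 1L] <- resid else uu[m] <- uu[m] + resid
    estimate_sigma_j(dd, uu)
  }

  if (mode == "exact") {
    for (j in seq_len(p)) {
      xj <- Xv[, j]
      sv <- svd(Xv[, -j, drop = FALSE], nu = min(n, p - 1L), nv = 0)
      u2 <- drop(crossprod(sv$u, xj))^2
      est <- pad_fit(sv$d^2, u2, sum(xj^2))
      sigma2[j] <- est; flags[j] <- attr(est, "flag"); ll[j] <- attr(est, "loglik")
    }
    kused <- min(n, p - 1L)
  } else {
    if (mode == "rsvd") {
      if (is.null(k)) k <- min(200L, n, p)
      ev <- rsvd_topk(Xv, k, seed = seed)
      lam <- ev$values; V <- ev$vectors
    } else {
      sv <- svd(Xv, nu = min(n, p), nv = 0)
      lam <- sv$d^2; V <- sv$u
    }
    kused <- length(lam)
    for (j in seq_len(p)) {
      xj <- Xv[, j]
      z <- drop(crossprod(V, xj))
      dd <- downdate_spectrum(lam, z)
      est <- pad_fit(dd$values, dd$u2, sum(xj^2))
      sigma2[j] <- est; flags[j] <- attr(est, "flag"); ll[j] <- attr(est, "loglik")
    }
  }
  flat <- flags == "flat"
  sigma2[flat] <- 1 / p
  structure(list(sigma2 = sigma2, method = mode, k_eigenpairs = kused,
                 loglik_at_opt = ll, flag = flags,
                 feature_names = X$feature_names),
            class = "prior_estimate")
}

#' @export
print.prior_estimate <- function(x, ...) {
  cat(sprintf("Empirical-Bayes prior variances (%s, %d eigenpairs)\n",
              x$method, x$k_eigenpairs))
  print(summary(x$sigma2))
  invisible(x)
}
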