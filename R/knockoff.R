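#' Decorrelation budget and factorization for reflection knockoffs
#'
#' From a reflection result, forms \code{C = cov(Z T^{-1/2})} (unit diagonal
#' without augmentation), eigendecomposes it, and sets the scalar
#' \code{alpha_hat = min(1, 2 / Lambda_1)} where \code{Lambda_1} is the
#' leading eigenvalue. The diagonal decorrelation matrix of the knockoffs is
#' then \code{S = alpha_hat * T}, the largest multiple of T for which the
#' conditional knockoff covariance \code{2S - S Sigma^{-1} S} stays positive
#' semidefinite. The noise loadings are
#' \code{B_j = sqrt(max(0, 2 alpha - alpha^2 Lambda_j))}.
#'
#' When C is numerically diagonal (all off-diagonals below 1e-10, e.g. for
#' orthogonal features) the coordinate basis is used as the eigenbasis
#' rather than the dense eigensolver, whose basis is arbitrary under
#' degenerate eigenvalues; this makes the uncorrelated special case
#' (knockoffs equal to pure noise) hold to machine precision.
#'
#' @param R A \code{"reflection"} from [reflect()].
#' @return Object of class \code{"knockoff_factorization"}: list with
#'   \code{alpha_hat}, \code{alpha_unclipped} (\code{2/Lambda_1} before the
#'   cap at 1), \code{lambda} (eigenvalues, decreasing), \code{Q}
#'   (eigenvectors), \code{S}, \code{B}, \code{T}, and \code{gershgorin}
#'   (per-feature off-diagonal row sums of C, bounding \code{|Lambda_j - 1|}).
#' @export
compute_alpha <- function(R) {
  if (!inherits(R, "reflection")) stop("R must be a reflection result")
  if (any(R$T <= 0)) stop("nonpositive T_j; reflection is degenerate")
  p <- length(R$T)
  Zs <- sweep(R$Z, 2L, sqrt(R$T), "/")
  C <- sample_cov(Zs)
  C <- (C + t(C)) / 2
  offmax <- max(abs(C - diag(diag(C))))
  if (offmax < 1e-10) {
    lambda <- unname(diag(C))
    Q <- diag(1, p)
    ord <- order(lambda, decreasing = TRUE)
    lambda <- lambda[ord]; Q <- Q[, ord, drop = FALSE]
  } else {
    ed <- eigen(C, symmetric = TRUE)
    lambda <- ed$values
    Q <- ed$vectors
  }
  alpha_raw <- 2 / lambda[1L]
  alpha <- min(1, alpha_raw)
  B <- sqrt(pmax(0, 2 * alpha - alpha^2 * lambda))
  gersh <- rowSums(abs(C)) - abs(diag(C))
  structure(list(alpha_hat = alpha, alpha_unclipped = alpha_raw,
                 lambda = lambda, Q = Q,
                 S = alpha * R$T, B = B, T = R$T,
                 gershgorin = gersh),
            class = "knockoff_factorization")
}

#' @export
print.knockoff_factorization <- function(x, ...) {
  cat(sprintf("Knockoff factorization: alpha-hat = %.4f (2/Lambda_1 = %.4f)\n",
              x$alpha_hat, x$alpha_unclipped))
  cat(sprintf("  Lambda_1 = %.4f; S in [%.4g, %.4g]\n",
              x$lambda[1L], min(x$S), max(x$S)))
  invisible(x)
}

# p orthonormal directions orthogonal to col(X) and to the intercept, scaled
# to unit sample variance. Requires n >= 2p + 1.
nullspace_noise <- function(Xv) {
  n <- nrow(Xv); p <- ncol(Xv)
  if (n < 2 * p + 1) {
    stop("null-space noise needs n to exceed 2p (n >= 2p + 1): ",
         "n = ", n, ", p = ", p)
  }
  qrX <- qr(cbind(1, Xv))
  Qfull <- qr.Q(qrX, complete = TRUE)
  basis <- Qfull[, (p + 2L):n, drop = FALSE]
  idx <- sample.int(ncol(basis), p)
  basis[, idx, drop = FALSE] * sqrt(n - 1)
}

#' Sample reflection knockoffs
#'
#' Draws a knockoff copy \code{Xt = X - alpha Z + U diag(B) Q' diag(sqrt(T))}
#' where U supplies the fresh randomness:
#' \describe{
#'   \item{gaussian}{columns of U are i.i.d. standard normal (the default;
#'     second moments hold in expectation, akin to a second-order Model-X
#'     construction).}
#'   \item{nullspace}{columns of U are orthonormal null-space directions of
#'     \code{[1, X]}, rescaled to unit sample variance; the joint sample
#'     covariance of \code{[X, Xt]} then matches the knockoff block structure
#'     exactly (requires n > 2p).}
#' }
#'
#' @param X \code{"feature_matrix"} or standardized matrix.
#' @param R The \code{"reflection"} of X.
#' @param Fz The \code{"knockoff_factorization"} from [compute_alpha()].
#' @param noise_mode \code{"gaussian"} or \code{"nullspace"}.
#' @param seed Optional integer seed.
#' @return An n x p matrix of knockoff features.
#' @export
construct_knockoffs <- function(X, R, Fz, noise_mode = c("gaussian", "nullspace"),
                                seed = NULL) {
  noise_mode <- match.arg(noise_mode)
  X <- as_feature_matrix(X)
  if (!is.null(seed)) set.seed(seed)
  n <- X$n; p <- X$p
  U <- switch(noise_mode,
              gaussian = matrix(stats::rnorm(n * p), n, p),
              nullspace = nullspace_noise(X$values))
  Xt <- X$values - Fz$alpha_hat * R$Z +
    U %*% (Fz$B * t(Fz$Q)) %*% diag(sqrt(Fz$T), p)
  dimnames(Xt) <- list(NULL, X$feature_names)
  Xt
}

#' Equicorrelated second-order Model-X knockoffs (baseline)
#'
#' Gaussian knockoffs built from the sample correlation matrix with the
#' equicorrelated choice \code{S = min(1, 2 lambda_min(Sigma)) I}: each row of
#' the knockoff matrix is drawn from the conditional Gaussian with mean
#' \code{X (I - Sigma^{-1} S)} and covariance \code{2S - S Sigma^{-1} S}.
#' Serves as the comparison baseline for the reflection construction.
#'
#' @param X \code{"feature_matrix"} or standardized matrix.
#' @param seed Optional integer seed.
#' @param shrink Convex shrinkage weight toward the identity applied to the
#'   sample correlation matrix (0 = none). Required to be positive when the
#'   sample covariance is singular (p close to or above n).
#' @return An n x p matrix of knockoff features, with attribute \code{"s"}
#'   (the equicorrelated S scalar).
#' @export
modelx_knockoffs <- function(X, seed = NULL, shrink = 0) {
  X <- as_feature_matrix(X)
  n <- X$n; p <- X$p
  if (p < 2L) stop("need p >= 2")
  Sigma <- sample_cov(X$values)
  if (shrink > 0) Sigma <- (1 - shrink) * Sigma + shrink * diag(p)
  ev <- eigen(Sigma, symmetric = TRUE)
  lmin <- min(ev$values)
  if (lmin <= 1e-10) {
    stop("sample covariance is singular (min eigenvalue ", format(lmin),
         "); set shrink > 0")
  }
  s <- min(1, 2 * lmin)
  Sinv <- ev$vectors %*% (t(ev$vectors) / ev$values)
  Cc <- 2 * s * diag(p) - s^2 * Sinv
  ec <- eigen((Cc + t(Cc)) / 2, symmetric = TRUE)
  Chalf <- ec$vectors %*% (sqrt(pmax(ec$values, 0)) * t(ec$vectors))
  if (!is.null(seed)) set.seed(seed)
  E <- matrix(stats::rnorm(n * p), n, p) %*% Chalf
  Xt <- X$values %*% (diag(p) - s * Sinv) + E
  dimnames(Xt) <- list(NULL, X$feature_names)
  attr(Xt, "s") <- s
  Xt
}

#' Second-moment diagnostic for a knockoff copy
#'
#' Measures how far the joint sample covariance of \code{[X, Xt]} is from the
#' knockoff block structure: \code{cov(Xt) = cov(X)},
#' \code{cov(X_j, Xt_k) = cov(X_j, X_k)} off the diagonal, and
#' \code{cov(X_j, Xt_j) = var(X_j) - S_j}.
#'
#' @param X \code{"feature_matrix"} or standardized matrix.
#' @param Xt Knockoff matrix of the same shape.
#' @param S Length-p vector, the diagonal decorrelation matrix.
#' @return List with the three maximum absolute deviations
#'   (\code{dev_knockoff_cov}, \code{dev_cross_offdiag}, \code{dev_cross_diag})
#'   and their overall maximum \code{dev_max}.
#' @export
second_moment_check <- function(X, Xt, S) {
  X <- as_feature_matrix(X)
  if (!all(dim(Xt) == dim(X$values))) stop("Xt must match the shape of X")
  if (length(S) == 1L) S <- rep(S, X$p)
  SigX <- sample_cov(X$values)
  SigT <- sample_cov(Xt)
  Cr <- sample_cov(X$values, Xt)
  d1 <- max(abs(SigT - SigX))
  off <- Cr - SigX
  d3 <- max(abs(diag(Cr) - (diag(SigX) - S)))
  diag(off) <- 0
  d2 <- max(abs(off))
  list(dev_knockoff_cov = d1, dev_cross_offdiag = d2, dev_cross_diag = d3,
       dev_max = max(d1, d2, d3))
}
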