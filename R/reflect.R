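#' Append ghost samples implementing ridge shrinkage
#'
#' Appends p pseudo-rows \code{diag(1/sigma_1, ..., 1/sigma_p)} to a
#' standardized feature matrix. Each per-column reflection regression run on
#' the augmented matrix then acquires a ridge penalty \code{1/sigma_k^2} on
#' covariate k, which equals the posterior-mean solution under independent
#' Gaussian priors with variance \code{sigma_k^2} on the regression
#' coefficients. Augmentation keeps the reflection residual variance bounded
#' away from zero under high correlation and makes the reflection well defined
#' even when p > n.
#'
#' @param X A \code{"feature_matrix"} (see [standardize()]) or a standardized
#'   numeric matrix.
#' @param priors Length-p vector of positive prior variances \code{sigma_j^2},
#'   or a single value recycled to all columns. The default \code{1/p} keeps
#'   the implied posterior proper for large p; empirical-Bayes estimates
#'   (see [estimate_priors()]) usually perform better.
#' @return An object of class \code{"augmented_matrix"}: list with
#'   \code{values} ((n+p) x p), \code{ghost_weights} (the appended diagonal
#'   \code{1/sigma_j}), and \code{source} (the input feature matrix).
#' @export
augment <- function(X, priors = NULL) {
  X <- as_feature_matrix(X)
  if (is.null(priors)) priors <- 1 / X$p
  if (length(priors) == 1L) priors <- rep(priors, X$p)
  if (length(priors) != X$p) stop("priors must have length p = ", X$p)
  if (any(!is.finite(priors)) || any(priors <= 0)) {
    stop("prior variances sigma_j^2 must be positive and finite")
  }
  d <- 1 / sqrt(priors)
  vals <- rbind(X$values, diag(d, X$p))
  structure(list(values = vals, ghost_weights = d, source = X),
            class = "augmented_matrix")
}

#' @export
print.augmented_matrix <- function(x, ...) {
  cat(sprintf("Augmented feature matrix: %d + %d ghost rows x %d features\n",
              x$source$n, x$source$p, x$source$p))
  invisible(x)
}

# Triangularize R with column j removed by Givens rotations and backsolve
# for the least-squares coefficients of column j on the rest.
# R: p x p upper triangular from qr(Xa). Returns beta (length p-1).
solve_reflection_column <- function(R, j) {
  p <- ncol(R)
  U <- R[, -j, drop = FALSE]      # p x (p-1), upper Hessenberg below column j
  v <- R[, j]
  if (j < p) {
    for (k in j:(p - 1L)) {
      # zero U[k+1, k] against U[k, k]
      a <- U[k, k]; b <- U[k + 1L, k]
      if (b != 0) {
        r <- sqrt(a * a + b * b)
        c <- a / r; s <- b / r
        rows <- c(k, k + 1L)
        G <- rbind(c(c, s), c(-s, c))
        U[rows, k:(p - 1L)] <- G %*% U[rows, k:(p - 1L), drop = FALSE]
        v[rows] <- G %*% v[rows]
      }
    }
  }
  backsolve(U[seq_len(p - 1L), , drop = FALSE], v[seq_len(p - 1L)])
}

#' Householder reflection of every feature across the span of the others
#'
#' For each column j, fits the least-squares regression of X_j on the
#' remaining columns and reflects X_j through its fitted value:
#' \code{Y_j = 2 * fit_j - X_j}. The computation follows the QR route: one QR
#' decomposition of the (possibly ghost-augmented) matrix, then per column a
#' short sequence of Givens rotations restores triangularity of R with that
#' column deleted and back-substitution yields the coefficients. The residual
#' half-difference \code{Z = (X - Y)/2} is orthogonal to every other feature,
#' so \code{T = cov(X, Z)} is diagonal (exactly so without augmentation; with
#' ghost rows the off-diagonals computed on the first n rows are reported as a
#' diagnostic and T is defined as the diagonal).
#'
#' @param Xa An \code{"augmented_matrix"} from [augment()], a
#'   \code{"feature_matrix"}, or a standardized numeric matrix (the latter two
#'   are reflected without shrinkage and must have full column rank).
#' @return An object of class \code{"reflection"}: list with \code{Y} and
#'   \code{Z} (n x p, truncated to the original samples), \code{T} (length-p
#'   diagonal of cov(X, Z)), \code{augmented}, \code{max_offdiag}
#'   (largest |off-diagonal| of cov(X, Z), a diagnostic), and
#'   \code{cov_convention} (the covariance divisor, \code{"n-1"}).
#' @references The identities cov(Y_j, X_k) = cov(X_j, X_k) for j != k and
#'   T_jj = var(Z_j) > 0 hold exactly for the unaugmented reflection.
#' @export
reflect <- function(Xa) {
  if (inherits(Xa, "augmented_matrix")) {
    src <- Xa$source
    A <- Xa$values
    augmented <- TRUE
  } else {
    src <- as_feature_matrix(Xa)
    A <- src$values
    augmented <- FALSE
  }
  n <- src$n; p <- src$p
  if (nrow(A) <= p) stop("need more (augmented) rows than features; enable augmentation")

  qrA <- qr(A)
  if (qrA$rank < p) {
    stop("feature matrix is rank deficient (rank ", qrA$rank, " < p = ", p,
         "); enable ghost-sample augmentation to regularize the reflection")
  }
  Q <- qr.Q(qrA)
  R <- qr.R(qrA)
  # qr() may pivot; undo by permuting columns back
  piv <- qrA$pivot
  R <- R[, order(piv), drop = FALSE]
  # R must be upper triangular in original column order for the Givens sweep;
  # without pivoting it already is. With pivoting, re-triangularize.
  if (any(piv != seq_len(p))) {
    qr2 <- qr(R)
    Q <- Q %*% qr.Q(qr2)
    R <- qr.R(qr2)
  }

  Rt <- matrix(0, p, p)
  for (j in seq_len(p)) {
    beta <- solve_reflection_column(R, j)
    Rt[, j] <- 2 * (R[, -j, drop = FALSE] %*% beta) - R[, j]
  }
  Yfull <- Q %*% Rt
  Y <- Yfull[seq_len(n), , drop = FALSE]
  Z <- (src$values - Y) / 2
  XtZ <- sample_cov(src$values, Z)
  Tdiag <- diag(XtZ)
  if (any(Tdiag <= 0)) {
    stop("nonpositive reflection variance T_j for column(s) ",
         paste(which(Tdiag <= 0), collapse = ", "),
         "; the matrix is (numerically) collinear - enable augmentation")
  }
  off <- XtZ; diag(off) <- 0
  dimnames(Y) <- dimnames(Z) <- list(NULL, src$feature_names)
  structure(list(Y = Y, Z = Z, T = Tdiag,
                 augmented = augmented,
                 max_offdiag = max(abs(off)),
                 cov_convention = "n-1",
                 source = src),
            class = "reflection")
}

#' @export
print.reflection <- function(x, ...) {
  cat(sprintf("Householder reflection of %d x %d features (%s)\n",
              x$source$n, x$source$p,
              if (x$augmented) "ghost-augmented" else "unaugmented"))
  cat(sprintf("  T (diag cov(X,Z)): min %.4g, median %.4g, max %.4g\n",
              min(x$T), stats::median(x$T), max(x$T)))
  cat(sprintf("  max |off-diagonal cov(X,Z)|: %.3g\n", x$max_offdiag))
  invisible(x)
}
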