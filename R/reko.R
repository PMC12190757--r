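#' Fit a reflection-knockoff model to a feature matrix
#'
#' The main entry point of the package. Standardizes the features, estimates
#' (or accepts) per-feature shrinkage prior variances, appends the matching
#' ghost samples, computes the Householder reflection of every feature across
#' the span of the others ([reflect()]), and derives the knockoff
#' factorization \code{S = alpha_hat T} ([compute_alpha()]). The returned
#' object holds everything needed to draw any number of knockoff copies with
#' [simulate.reko()].
#'
#' @param X Numeric matrix (samples x features) or \code{"feature_matrix"}.
#'   Standardized internally if needed.
#' @param priors Shrinkage prior specification: \code{"eb"} (empirical Bayes,
#'   the default), \code{"fixed"} (all \code{sigma_j^2 = 1/p}, or the value(s)
#'   in \code{sigma2}), or \code{"none"} (no ghost augmentation; requires
#'   full column rank and n > p).
#' @param sigma2 Prior variance(s) used when \code{priors = "fixed"}.
#' @param prior_mode Estimation mode passed to [estimate_priors()] when
#'   \code{priors = "eb"}.
#' @param k Leading eigenpairs for \code{prior_mode = "rsvd"}.
#' @param seed Optional integer seed (used by the randomized eigensolver).
#' @return Object of class \code{"reko"}: list with \code{X} (the
#'   \code{"feature_matrix"}), \code{priors} (a \code{"prior_estimate"} or
#'   \code{NULL}), \code{reflection}, \code{factorization}, and \code{call}.
#' @seealso [simulate.reko()] to draw knockoff copies, [knockoff_filter()]
#'   for the full selection pipeline.
#' @examples
#' X <- gen_features(120, 12, structure = list(kind = "ar1", rho = 0.6), seed = 1)
#' fit <- reko(X)
#' fit
#' Xt <- simulate(fit, nsim = 1, seed = 2)[[1]]
#' second_moment_check(X, Xt, fit$factorization$S)$dev_max
#' @export
reko <- function(X, priors = c("eb", "fixed", "none"), sigma2 = NULL,
                 prior_mode = c("rank-one-update", "exact", "rsvd"),
                 k = NULL, seed = NULL) {
  priors <- match.arg(priors)
  prior_mode <- match.arg(prior_mode)
  X <- as_feature_matrix(X)
  pe <- NULL
  if (priors == "eb") {
    pe <- estimate_priors(X, mode = prior_mode, k = k, seed = seed)
    Xa <- augment(X, pe$sigma2)
  } else if (priors == "fixed") {
    if (is.null(sigma2)) sigma2 <- 1 / X$p
    Xa <- augment(X, sigma2)
  } else {
    if (X$n <= X$p) stop("priors = \"none\" requires n > p; use ghost augmentation")
    Xa <- X
  }
  R <- reflect(Xa)
  Fz <- compute_alpha(R)
  structure(list(X = X, priors = pe, prior_kind = priors,
                 reflection = R, factorization = Fz,
                 call = match.call()),
            class = "reko")
}

#' @export
print.reko <- function(x, ...) {
  cat("Reflection-knockoff model\n")
  cat(sprintf("  features: %d samples x %d features (%s priors)\n",
              x$X$n, x$X$p, x$prior_kind))
  cat(sprintf("  alpha-hat = %.4f (unclipped 2/Lambda_1 = %.4f), Lambda_1 = %.4f\n",
              x$factorization$alpha_hat, x$factorization$alpha_unclipped,
              x$factorization$lambda[1L]))
  cat(sprintf("  S = alpha-hat * T: min %.4g, median %.4g, max %.4g\n",
              min(x$factorization$S), stats::median(x$factorization$S),
              max(x$factorization$S)))
  invisible(x)
}

#' @export
summary.reko <- function(object, ...) {
  Fz <- object$factorization
  out <- list(n = object$X$n, p = object$X$p,
              prior_kind = object$prior_kind,
              sigma2 = if (!is.null(object$priors)) object$priors$sigma2,
              alpha_hat = Fz$alpha_hat,
              alpha_unclipped = Fz$alpha_unclipped,
              lambda1 = Fz$lambda[1L],
              S_summary = summary(Fz$S),
              T_summary = summary(Fz$T),
              max_offdiag_covXZ = object$reflection$max_offdiag,
              gershgorin_max = max(Fz$gershgorin))
  class(out) <- "summary.reko"
  out
}

#' @export
print.summary.reko <- function(x, ...) {
  cat(sprintf("Reflection-knockoff model: %d x %d, %s priors\n",
              x$n, x$p, x$prior_kind))
  cat(sprintf("  alpha-hat %.4f (2/Lambda_1 = %.4f); Lambda_1 %.4f\n",
              x$alpha_hat, x$alpha_unclipped, x$lambda1))
  cat("  S (decorrelation budget):\n"); print(x$S_summary)
  cat("  T (reflection variances):\n"); print(x$T_summary)
  cat(sprintf("  max |off-diag cov(X,Z)| = %.3g (diagnostic)\n", x$max_offdiag_covXZ))
  cat(sprintf("  max Gershgorin radius of C = %.3g\n", x$gershgorin_max))
  invisible(x)
}

#' Draw knockoff copies from a fitted reflection-knockoff model
#'
#' @param object A \code{"reko"} fit.
#' @param nsim Number of knockoff copies.
#' @param seed Optional integer seed; copy m uses substream \code{seed + m}.
#' @param noise_mode Passed to [construct_knockoffs()].
#' @param ... Unused.
#' @return A list of \code{nsim} knockoff matrices (n x p each).
#' @export
simulate.reko <- function(object, nsim = 1, seed = NULL,
                          noise_mode = c("gaussian", "nullspace"), ...) {
  noise_mode <- match.arg(noise_mode)
  lapply(seq_len(nsim), function(m) {
    construct_knockoffs(object$X, object$reflection, object$factorization,
                        noise_mode = noise_mode,
                        seed = if (is.null(seed)) NULL else seed + m)
  })
}

#' Residual half-differences of the reflection
#'
#' Returns \code{Z = (X - Y)/2}, the per-feature regression residuals that
#' drive the knockoff decorrelation.
#' @param object A \code{"reko"} fit.
#' @param ... Unused.
#' @export
residuals.reko <- function(object, ...) object$reflection$Z
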