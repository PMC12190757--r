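#' Bundle M sets of knockoff statistics
#'
#' @param W Numeric matrix, M rows (knockoff copies) by p columns (features),
#'   or a single length-p vector.
#' @param importance_kind \code{"beta"} or \code{"pip"}.
#' @return Object of class \code{"knockoff_stats_set"}: list with \code{W},
#'   \code{M}, \code{importance_kind}, \code{W_bar} (column means) and
#'   \code{W_cat} (row-wise concatenation).
#' @export
knockoff_stats_set <- function(W, importance_kind = c("beta", "pip")) {
  importance_kind <- match.arg(importance_kind)
  if (is.null(dim(W))) W <- matrix(W, nrow = 1L)
  structure(list(W = W, M = nrow(W), importance_kind = importance_kind,
                 W_bar = colMeans(W), W_cat = as.numeric(t(W))),
            class = "knockoff_stats_set")
}

#' Knockoff selection threshold
#'
#' The data-dependent threshold
#' \deqn{T = \min\{t : \#\{j: W_j \le -t\} / (\#\{j: W_j \ge t\} \vee 1) \le q\}}
#' over candidate values t in the nonzero |W_j|. The \code{knockoff_plus}
#' variant adds 1 to the numerator and carries the exact finite-sample FDR
#' guarantee. Returns \code{Inf} (select nothing) when no candidate
#' qualifies.
#'
#' @param W Numeric vector of knockoff statistics.
#' @param q Nominal FDR level in (0, 1).
#' @param variant \code{"knockoff"} or \code{"knockoff_plus"}.
#' @return Scalar threshold (possibly \code{Inf}).
#' @export
knockoff_threshold <- function(W, q, variant = c("knockoff", "knockoff_plus")) {
  variant <- match.arg(variant)
  if (q <= 0 || q >= 1) stop("q must be in (0, 1)")
  cand <- sort(unique(abs(W[W != 0])))
  if (length(cand) == 0L) {
    warning("no nonzero knockoff statistics; threshold is Inf")
    return(Inf)
  }
  offset <- if (variant == "knockoff_plus") 1 else 0
  for (t in cand) {
    num <- sum(W <= -t) + offset
    den <- max(sum(W >= t), 1)
    if (num / den <= q) return(t)
  }
  Inf
}

#' Aggregate multiple knockoff-statistic sets and select features
#'
#' Concatenates the M statistic vectors to estimate one threshold
#' ([knockoff_threshold()] on \code{W_cat}), then selects every feature whose
#' average statistic reaches it. With M = 1 this reduces exactly to the
#' single-copy filter. Concatenation stabilizes the threshold (more points in
#' the tail counts) while averaging preserves the null sign-symmetry that the
#' FDR guarantee rests on.
#'
#' @param stats A \code{"knockoff_stats_set"} (or an M x p matrix / length-p
#'   vector, coerced with importance kind \code{"beta"}).
#' @inheritParams knockoff_threshold
#' @return Object of class \code{"knockoff_selection"}: list with
#'   \code{threshold}, \code{selected} (integer indices), \code{q},
#'   \code{variant}, \code{aggregated} (\code{M > 1}), \code{M},
#'   \code{W_bar} and \code{p}.
#' @export
aggregate_select <- function(stats, q, variant = c("knockoff", "knockoff_plus")) {
  variant <- match.arg(variant)
  if (!inherits(stats, "knockoff_stats_set")) stats <- knockoff_stats_set(stats)
  Tcat <- knockoff_threshold(stats$W_cat, q, variant)
  sel <- which(stats$W_bar >= Tcat)
  structure(list(threshold = Tcat, selected = sel, q = q, variant = variant,
                 aggregated = stats$M > 1L, M = stats$M,
                 W_bar = stats$W_bar, p = ncol(stats$W),
                 importance_kind = stats$importance_kind),
            class = "knockoff_selection")
}

#' @export
print.knockoff_selection <- function(x, ...) {
  cat(sprintf("Knockoff selection (%s, q = %.2f%s): %d of %d features\n",
              x$variant, x$q,
              if (x$aggregated) sprintf(", %d copies aggregated", x$M) else "",
              length(x$selected), x$p))
  cat(sprintf("  threshold = %s\n",
              if (is.finite(x$threshold)) format(x$threshold, digits = 4) else "Inf (none selected)"))
  if (length(x$selected)) cat("  selected:", paste(x$selected, collapse = " "), "\n")
  invisible(x)
}

#' Combine two knockoff selections by intersection
#'
#' A feature is selected by the combined filter if and only if both input
#' filters selected it (typically one penalized-regression and one Bayesian
#' importance measure), trading power for a better-calibrated realized FDR.
#'
#' @param selA,selB \code{"knockoff_selection"} objects over the same
#'   feature universe and at the same nominal level.
#' @return A \code{"knockoff_selection"} whose \code{selected} is the
#'   intersection; \code{parents} records the inputs' importance kinds.
#' @export
combined_filter <- function(selA, selB) {
  if (!inherits(selA, "knockoff_selection") || !inherits(selB, "knockoff_selection"))
    stop("inputs must be knockoff_selection objects")
  if (selA$p != selB$p) stop("selections are over different feature universes")
  if (selA$q != selB$q) stop("selections use different nominal FDR levels")
  out <- selA
  out$selected <- sort(intersect(selA$selected, selB$selected))
  out$importance_kind <- "combined"
  out$parents <- c(selA$importance_kind, selB$importance_kind)
  out$threshold <- c(A = selA$threshold, B = selB$threshold)
  out
}

#' Run the full knockoff filter
#'
#' End-to-end selection: fit the reflection-knockoff model (or use the
#' Model-X baseline), draw M knockoff copies, compute the requested
#' importance measure(s) for each copy, form knockoff statistics, aggregate,
#' and select at the nominal FDR level. With \code{importance = "both"} the
#' lasso and PIP filters are run on the same knockoff copies and combined by
#' intersection ([combined_filter()]).
#'
#' @param X Feature matrix (n x p) or \code{"feature_matrix"}.
#' @param y Numeric phenotype of length n.
#' @param M Number of knockoff copies to aggregate (default 10).
#' @param importance \code{"beta"} (lasso coefficients), \code{"pip"}
#'   (spike-and-slab posterior inclusion), or \code{"both"}.
#' @param q Nominal FDR level.
#' @param variant Threshold variant, see [knockoff_threshold()].
#' @param knockoffs \code{"reko"} (reflection, default) or \code{"modelx"}
#'   (equicorrelated second-order baseline).
#' @param priors,prior_mode,noise_mode Passed to [reko()] /
#'   [construct_knockoffs()] when \code{knockoffs = "reko"}.
#' @param shrink Correlation shrinkage for \code{knockoffs = "modelx"}.
#' @param mcmc Sampler settings for [pip_importance()].
#' @param nfolds CV folds for [lasso_importance()].
#' @param seed Integer seed; copy m derives substreams \code{seed + m} for the
#'   knockoff noise and the model fits.
#' @return Object of class \code{"knockoff_filter"}: list with the fitted
#'   \code{model} (for reko), per-kind \code{stats}
#'   (\code{"knockoff_stats_set"}) and \code{selection}, and the
#'   \code{combined} selection when both measures were run.
#' @examples
#' \donttest{
#' X <- gen_features(300, 30, structure = list(kind = "ar1", rho = 0.5), seed = 1)
#' ph <- gen_phenotype(X, n_causal = 5, pve = 0.5, seed = 2)
#' kf <- knockoff_filter(X, ph$y, M = 3, q = 0.2, seed = 3)
#' kf
#' }
#' @export
knockoff_filter <- function(X, y, M = 10L,
                            importance = c("beta", "pip", "both"),
                            q = 0.1,
                            variant = c("knockoff", "knockoff_plus"),
                            knockoffs = c("reko", "modelx"),
                            priors = "eb", prior_mode = "rank-one-update",
                            noise_mode = "gaussian", shrink = 0,
                            mcmc = list(), nfolds = 5L, seed = NULL) {
  importance <- match.arg(importance)
  variant <- match.arg(variant)
  knockoffs <- match.arg(knockoffs)
  X <- as_feature_matrix(X)
  if (M < 1L) stop("M must be at least 1")
  kinds <- if (importance == "both") c("beta", "pip") else importance

  model <- NULL
  if (knockoffs == "reko") {
    model <- reko(X, priors = priors, prior_mode = prior_mode, seed = seed)
  }
  Wmat <- stats::setNames(
    lapply(kinds, function(k) matrix(NA_real_, M, X$p)), kinds)
  for (m in seq_len(M)) {
    sm <- if (is.null(seed)) NULL else seed + m
    Xt <- if (knockoffs == "reko") {
      construct_knockoffs(X, model$reflection, model$factorization,
                          noise_mode = noise_mode, seed = sm)
    } else {
      modelx_knockoffs(X, seed = sm, shrink = shrink)
    }
    for (k in kinds) {
      imp <- if (k == "beta") {
        lasso_importance(X, Xt, y, seed = if (is.null(sm)) NULL else sm + 10000L,
                         nfolds = nfolds)
      } else {
        pip_importance(X, Xt, y, mcmc = mcmc,
                       seed = if (is.null(sm)) NULL else sm + 20000L)
      }
      Wmat[[k]][m, ] <- knockoff_stats(imp)
    }
  }
  stats_sets <- lapply(kinds, function(k) knockoff_stats_set(Wmat[[k]], k))
  names(stats_sets) <- kinds
  selections <- lapply(stats_sets, aggregate_select, q = q, variant = variant)
  combined <- if (length(kinds) == 2L) {
    combined_filter(selections[[1L]], selections[[2L]])
  }
  structure(list(model = model, knockoffs = knockoffs, M = M, q = q,
                 variant = variant, stats = stats_sets,
                 selection = selections, combined = combined,
                 feature_names = X$feature_names, call = match.call()),
            class = "knockoff_filter")
}

#' @export
print.knockoff_filter <- function(x, ...) {
  cat(sprintf("Knockoff filter (%s knockoffs, M = %d, q = %.2f, %s)\n",
              x$knockoffs, x$M, x$q, x$variant))
  for (k in names(x$selection)) {
    s <- x$selection[[k]]
    cat(sprintf("  %s: %d selected (threshold %s)\n", k, length(s$selected),
                if (is.finite(s$threshold)) format(s$threshold, digits = 4) else "Inf"))
  }
  if (!is.null(x$combined)) {
    cat(sprintf("  combined: %d selected\n", length(x$combined$selected)))
  }
  invisible(x)
}

#' @export
summary.knockoff_filter <- function(object, ...) {
  sel <- final_selection(object)
  cat(sprintf("Knockoff filter: %d of %d features selected at q = %.2f\n",
              length(sel$selected), sel$p, object$q))
  if (length(sel$selected)) {
    nm <- object$feature_names[sel$selected]
    df <- data.frame(feature = nm, index = sel$selected,
                     W_bar = sel$W_bar[sel$selected])
    print(df, row.names = FALSE)
  }
  invisible(object)
}

#' Average knockoff statistics of a fitted filter
#' @param object A \code{"knockoff_filter"}.
#' @param kind Importance kind (defaults to the first one fitted).
#' @param ... Unused.
#' @export
coef.knockoff_filter <- function(object, kind = NULL, ...) {
  kind <- kind %||% names(object$stats)[1L]
  stats::setNames(object$stats[[kind]]$W_bar, object$feature_names)
}

#' Plot average knockoff statistics against the selection threshold
#' @param x A \code{"knockoff_filter"}.
#' @param kind Importance kind (defaults to the first one fitted).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.knockoff_filter <- function(x, kind = NULL, ...) {
  kind <- kind %||% names(x$stats)[1L]
  s <- x$selection[[kind]]
  w <- s$W_bar
  col <- ifelse(seq_along(w) %in% s$selected, "firebrick", "grey40")
  graphics::plot(seq_along(w), w, col = col, pch = 19,
                 xlab = "feature index", ylab = "average knockoff statistic",
                 main = sprintf("%s importance, q = %.2f", kind, x$q), ...)
  if (is.finite(s$threshold)) {
    graphics::abline(h = c(s$threshold, -s$threshold), lty = 2, col = "steelblue")
  }
  invisible(x)
}

final_selection <- function(object) {
  if (!is.null(object$combined)) object$combined else object$selection[[1L]]
}
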