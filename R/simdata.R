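#' Generate Gaussian feature matrices with known correlation structure
#'
#' Draws standardized Gaussian features under one of the designs used
#' throughout the simulation studies:
#' \describe{
#'   \item{independent}{i.i.d. standard normal columns.}
#'   \item{ar1}{first-order autoregressive correlation,
#'     \code{cor(X_j, X_k) = rho^|j-k|}.}
#'   \item{block}{equicorrelated blocks of \code{size} features with
#'     within-block correlation \code{rho} (one-factor construction).}
#'   \item{from_matrix}{loads a delimited matrix from \code{path} (see
#'     [read_feature_matrix()]).}
#' }
#'
#' @param n,p Samples and features.
#' @param structure List with \code{kind} and its parameters (\code{rho},
#'   \code{size}, \code{path}); a bare string is accepted for parameter-free
#'   kinds.
#' @param seed Optional integer seed.
#' @return A \code{"feature_matrix"}.
#' @export
gen_features <- function(n, p, structure = list(kind = "independent"),
                         seed = NULL) {
  if (is.character(structure)) structure <- list(kind = structure)
  kind <- match.arg(structure$kind,
                    c("independent", "ar1", "block", "from_matrix"))
  if (!is.null(seed)) set.seed(seed)
  if (kind == "from_matrix") return(read_feature_matrix(structure$path))
  raw <- switch(kind,
    independent = matrix(stats::rnorm(n * p), n, p),
    ar1 = {
      rho <- structure$rho
      if (is.null(rho) || abs(rho) >= 1) stop("ar1 needs rho in (-1, 1)")
      X <- matrix(0, n, p)
      X[, 1L] <- stats::rnorm(n)
      if (p > 1L) for (j in 2:p) {
        X[, j] <- rho * X[, j - 1L] + sqrt(1 - rho^2) * stats::rnorm(n)
      }
      X
    },
    block = {
      rho <- structure$rho; size <- structure$size %||% 5L
      if (is.null(rho) || rho < 0 || rho >= 1) stop("block needs rho in [0, 1)")
      blocks <- rep(seq_len(ceiling(p / size)), each = size)[seq_len(p)]
      Zb <- matrix(stats::rnorm(n * max(blocks)), n, max(blocks))
      sqrt(rho) * Zb[, blocks, drop = FALSE] +
        sqrt(1 - rho) * matrix(stats::rnorm(n * p), n, p)
    })
  standardize(raw)
}

#' Simulate a phenotype with a stated proportion of variance explained
#'
#' Picks \code{n_causal} features uniformly at random, draws their effect
#' sizes from the standard normal, and adds Gaussian noise with variance
#' \code{var(X beta) (1 - pve) / pve}, so the proportion of phenotypic
#' variance explained by the causal predictor is \code{pve} in expectation.
#'
#' @param X \code{"feature_matrix"} or standardized matrix.
#' @param n_causal Number of causal features (1..p).
#' @param pve Target proportion of variance explained, in (0, 1).
#' @param seed Optional integer seed.
#' @return List with \code{y} (length n), \code{causal} (sorted indices),
#'   and \code{beta} (length p, zero off the causal set).
#' @export
gen_phenotype <- function(X, n_causal, pve, seed = NULL) {
  X <- as_feature_matrix(X)
  if (n_causal < 1L || n_causal > X$p) stop("n_causal must be in 1..p")
  if (pve <= 0 || pve >= 1) stop("pve must be strictly inside (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  causal <- sort(sample.int(X$p, n_causal))
  beta <- numeric(X$p)
  beta[causal] <- stats::rnorm(n_causal)
  g <- drop(X$values %*% beta)
  vg <- stats::var(g)
  if (vg <= 0) stop("degenerate causal predictor (zero variance)")
  y <- g + stats::rnorm(X$n, sd = sqrt(vg * (1 - pve) / pve))
  list(y = y, causal = causal, beta = beta)
}

#' Trim features until no pair exceeds a correlation cap
#'
#' Greedy pass over feature pairs in order of decreasing absolute sample
#' correlation: while any pair exceeds \code{r_max}, one member is removed —
#' the one with the weaker marginal association (\code{mode = "weaker"}) or a
#' random one (\code{mode = "random"}). The surviving set has maximum
#' off-diagonal absolute correlation at most \code{r_max}.
#'
#' @param X \code{"feature_matrix"} or numeric matrix.
#' @param marginal_assoc Length-p nonnegative association strengths (e.g.
#'   |marginal t| or -log p); required for \code{mode = "weaker"}.
#' @param r_max Correlation cap in (0, 1).
#' @param mode \code{"weaker"} or \code{"random"}.
#' @param seed Seed for \code{mode = "random"}.
#' @return Sorted integer vector of kept feature indices.
#' @export
trim_features <- function(X, marginal_assoc = NULL, r_max,
                          mode = c("weaker", "random"), seed = NULL) {
  mode <- match.arg(mode)
  if (inherits(X, "feature_matrix")) X <- X$values
  if (r_max <= 0 || r_max >= 1) stop("r_max must be in (0, 1)")
  p <- ncol(X)
  if (mode == "weaker") {
    if (is.null(marginal_assoc) || length(marginal_assoc) != p)
      stop("mode \"weaker\" needs length-p marginal_assoc")
  }
  if (!is.null(seed)) set.seed(seed)
  R <- abs(stats::cor(X))
  diag(R) <- 0
  keep <- rep(TRUE, p)
  repeat {
    Rk <- R
    Rk[!keep, ] <- 0; Rk[, !keep] <- 0
    mx <- max(Rk)
    if (mx <= r_max) break
    ij <- which(Rk == mx, arr.ind = TRUE)[1L, ]
    i <- ij[1L]; j <- ij[2L]
    drop_idx <- if (mode == "weaker") {
      if (marginal_assoc[i] < marginal_assoc[j]) i else j
    } else {
      c(i, j)[sample.int(2L, 1L)]
    }
    keep[drop_idx] <- FALSE
  }
  which(keep)
}

#' Pooled power and realized FDR over simulation replicates
#'
#' Pools true and false positives over replicates: power is pooled TP over
#' the pooled causal count, realized FDR is pooled FP over the pooled number
#' of selections (with a floor of one). Monte-Carlo standard errors use the
#' binomial approximation on the pooled denominators.
#'
#' @param selections List of integer vectors (selected indices per
#'   replicate; a \code{"knockoff_selection"} is accepted).
#' @param causal_sets List of integer vectors (causal indices per replicate).
#' @return List with \code{power}, \code{fdr}, \code{tp}, \code{fp},
#'   \code{n_selected}, \code{n_causal}, \code{se_power}, \code{se_fdr}.
#' @export
evaluate_selections <- function(selections, causal_sets) {
  if (length(selections) != length(causal_sets))
    stop("selections and causal_sets must align per replicate")
  tp <- fp <- nsel <- ncau <- 0L
  for (r in seq_along(selections)) {
    sel <- selections[[r]]
    if (inherits(sel, "knockoff_selection")) sel <- sel$selected
    cau <- causal_sets[[r]]
    tp <- tp + length(intersect(sel, cau))
    fp <- fp + length(setdiff(sel, cau))
    nsel <- nsel + length(sel)
    ncau <- ncau + length(cau)
  }
  power <- if (ncau > 0) tp / ncau else NA_real_
  fdr <- fp / max(nsel, 1L)
  list(power = power, fdr = fdr, tp = tp, fp = fp,
       n_selected = nsel, n_causal = ncau,
       se_power = if (ncau > 0) sqrt(power * (1 - power) / ncau) else NA_real_,
       se_fdr = sqrt(fdr * (1 - fdr) / max(nsel, 1L)))
}

#' Benchmark knockoff methods on synthetic data
#'
#' The full simulation loop: per replicate, generate features and a
#' phenotype, build M knockoff copies per method, compute lasso knockoff
#' statistics, aggregate-select at every nominal level in \code{q_grid}, and
#' pool true/false positives across replicates ([evaluate_selections()]).
#'
#' @param config List (or \code{"reko_config"} from [read_config()]) with
#'   fields \code{n}, \code{p}, \code{structure}, \code{n_causal},
#'   \code{pve}, \code{q_grid}, \code{replicates}, \code{copies} (M),
#'   \code{methods} (subset of \code{"reko"}, \code{"modelx"}),
#'   \code{variant}, \code{seed}, and optionally \code{priors},
#'   \code{noise_mode}, \code{shrink}, \code{nfolds}.
#' @param verbose Print one line per replicate.
#' @return A data.frame with one row per (method, q): power, realized FDR,
#'   pooled counts and Monte-Carlo standard errors. The per-replicate
#'   selections are attached as attribute \code{"selections"}.
#' @export
run_benchmark <- function(config, verbose = FALSE) {
  cf <- config
  stopifnot(!is.null(cf$n), !is.null(cf$p), !is.null(cf$n_causal),
            !is.null(cf$pve), !is.null(cf$replicates))
  methods <- cf$methods %||% c("reko", "modelx")
  q_grid <- cf$q_grid %||% 0.1
  M <- cf$copies %||% 10L
  variant <- cf$variant %||% "knockoff_plus"
  seed <- cf$seed %||% 1L
  structure_ <- cf$structure %||% list(kind = "independent")

  sel <- list()
  causal_sets <- vector("list", cf$replicates)
  for (r in seq_len(cf$replicates)) {
    rs <- seed + 1000L * r
    X <- gen_features(cf$n, cf$p, structure_, seed = rs)
    ph <- gen_phenotype(X, cf$n_causal, cf$pve, seed = rs + 1L)
    causal_sets[[r]] <- ph$causal
    for (met in methods) {
      kf <- knockoff_filter(X, ph$y, M = M, importance = "beta",
                            q = q_grid[1L], variant = variant,
                            knockoffs = met,
                            priors = cf$priors %||% "eb",
                            noise_mode = cf$noise_mode %||% "gaussian",
                            shrink = cf$shrink %||% 0,
                            nfolds = cf$nfolds %||% 5L,
                            seed = rs + 2L)
      ss <- kf$stats[["beta"]]
      for (q in q_grid) {
        key <- paste(met, q, sep = "|")
        sel[[key]] <- c(sel[[key]],
                        list(aggregate_select(ss, q, variant)$selected))
      }
    }
    if (verbose) message(sprintf("replicate %d/%d done", r, cf$replicates))
  }

  rows <- list()
  for (met in methods) for (q in q_grid) {
    ev <- evaluate_selections(sel[[paste(met, q, sep = "|")]], causal_sets)
    rows[[length(rows) + 1L]] <- data.frame(
      method = met, q = q, power = ev$power, fdr = ev$fdr,
      tp = ev$tp, fp = ev$fp, n_selected = ev$n_selected,
      n_causal = ev$n_causal, se_power = ev$se_power, se_fdr = ev$se_fdr)
  }
  out <- do.call(rbind, rows)
  attr(out, "selections") <- sel
  attr(out, "causal_sets") <- causal_sets
  out
}
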