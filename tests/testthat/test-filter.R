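test_that("knockoff statistics are importance differences with antisymmetry", {
  expect_equal(knockoff_stats(c(0.5, 0.2)), 0.3)
  expect_equal(knockoff_stats(rep(0.4, 8)), rep(0, 4))
  imp <- c(0.9, 0.1, 0.3, 0.6, 0.2, 0.8)
  p <- 3
  swapped <- c(imp[(p + 1):(2 * p)], imp[1:p])
  expect_equal(knockoff_stats(swapped), -knockoff_stats(imp))
  expect_error(knockoff_stats(c(1, 2, 3)), "even")
})

test_that("the selection threshold matches the worked example", {
  W <- c(5, 4, 3, -1, -2)
  expect_equal(knockoff_threshold(W, 0.2, "knockoff"), 3)
  sel <- aggregate_select(W, 0.2, "knockoff")
  expect_equal(sel$selected, 1:3)
  # knockoff_plus: the +1 offset makes every candidate fail at q = 0.2
  expect_equal(knockoff_threshold(W, 0.2, "knockoff_plus"), Inf)
  expect_length(aggregate_select(W, 0.2, "knockoff_plus")$selected, 0)
  # all-positive W: numerator 0, the smallest magnitude qualifies
  Wp <- c(0.2, 1.5, 0.7)
  expect_equal(knockoff_threshold(Wp, 0.1, "knockoff"), 0.2)
  expect_equal(aggregate_select(Wp, 0.1, "knockoff")$selected, 1:3)
  # negating all-positive W selects nothing
  expect_length(aggregate_select(-Wp, 0.9, "knockoff")$selected, 0)
})

test_that("the threshold equals a brute-force scan on random statistics", {
  set.seed(80)
  for (i in 1:200) {
    W <- round(rnorm(sample(5:40, 1)) * 3, 2)
    q <- runif(1, 0.05, 0.4)
    for (v in c("knockoff", "knockoff_plus")) {
      expect_identical(knockoff_threshold(W, q, v), threshold_oracle(W, q, v))
    }
  }
  expect_warning(knockoff_threshold(rep(0, 5), 0.1), "Inf")
})

test_that("aggregation reduces to the single-copy filter and ignores duplication", {
  set.seed(81)
  W <- rnorm(30)
  s1 <- aggregate_select(W, 0.2, "knockoff")
  sm <- aggregate_select(knockoff_stats_set(matrix(W, 1)), 0.2, "knockoff")
  expect_identical(s1$selected, sm$selected)
  expect_identical(s1$threshold, sm$threshold)
  # M identical copies: all counting ratios unchanged
  s5 <- aggregate_select(matrix(W, 5, 30, byrow = TRUE), 0.2, "knockoff")
  expect_identical(s5$selected, s1$selected)
  expect_identical(s5$threshold, s1$threshold)
})

test_that("statistic sets record averages and concatenation coherently", {
  Wm <- matrix(1:12, 3, 4)
  ss <- knockoff_stats_set(Wm, "beta")
  expect_equal(ss$W_bar, colMeans(Wm))
  expect_equal(sort(ss$W_cat), sort(as.numeric(Wm)))
  expect_equal(ss$M, 3)
})

test_that("combined filter intersects selections", {
  mk <- function(sel) structure(list(threshold = 1, selected = sel, q = 0.1,
                                     variant = "knockoff", aggregated = FALSE,
                                     M = 1, W_bar = rep(0, 10), p = 10,
                                     importance_kind = "beta"),
                                class = "knockoff_selection")
  expect_equal(combined_filter(mk(c(1, 2, 3)), mk(c(2, 3, 4)))$selected, c(2, 3))
  expect_length(combined_filter(mk(c(1, 2)), mk(integer(0)))$selected, 0)
  expect_equal(combined_filter(mk(1:3), mk(1:3))$selected, 1:3)
  bad <- mk(1:2); bad$p <- 5
  expect_error(combined_filter(mk(1:2), bad), "universe")
})

test_that("lasso importance is sign-symmetric under the null", {
  # no signal: originals and knockoffs exchangeable, so positive W about half
  fracs <- vapply(1:8, function(seed) {
    X <- gen_features(300, 40, "independent", seed = seed)
    set.seed(seed + 100)
    y <- rnorm(300)
    fit <- reko(X, priors = "fixed")
    Xt <- simulate(fit, seed = seed + 200)[[1]]
    W <- knockoff_stats(lasso_importance(X, Xt, y, seed = seed + 300))
    nz <- W[W != 0]
    if (length(nz) < 5) return(NA_real_)
    mean(nz > 0)
  }, numeric(1))
  fracs <- fracs[!is.na(fracs)]
  expect_gt(mean(fracs), 0.3)
  expect_lt(mean(fracs), 0.7)
})

test_that("a single strong causal feature dominates the lasso statistics", {
  wins <- 0L
  for (seed in 1:20) {
    X <- gen_features(200, 25, "independent", seed = seed)
    set.seed(seed + 400)
    y <- 5 * X$values[, 7] + rnorm(200)
    fit <- reko(X, priors = "fixed")
    Xt <- simulate(fit, seed = seed + 500)[[1]]
    W <- knockoff_stats(lasso_importance(X, Xt, y, seed = seed + 600))
    if (which.max(W) == 7 && W[7] > 0) wins <- wins + 1L
  }
  expect_gte(wins, 19L)
})

test_that("using X as its own knockoff leaves no systematic preference", {
  # With identical original/knockoff columns the lasso hands the shared
  # credit to one member of each pair; the randomized interleaving makes the
  # winner a coin flip, so W has no preferred sign and nulls stay near zero.
  X <- gen_features(150, 10, "independent", seed = 90)
  set.seed(91)
  y <- 2 * X$values[, 1] + rnorm(150)
  signs <- integer(0)
  for (seed in 1:14) {
    W <- knockoff_stats(lasso_importance(X, X$values, y, seed = seed))
    expect_lt(max(abs(W[-1])), 0.3)           # null features: near-zero credit
    if (W[1] != 0) signs <- c(signs, sign(W[1]))
  }
  expect_gte(sum(signs > 0), 2)
  expect_gte(sum(signs < 0), 2)
})

test_that("spike-and-slab PIPs calibrate on null data and find strong signals", {
  X <- gen_features(150, 10, "independent", seed = 95)
  set.seed(96)
  y0 <- rnorm(150)
  fit <- reko(X, priors = "fixed")
  Xt <- simulate(fit, seed = 97)[[1]]
  mc <- list(iters = 600, burnin = 150)
  pips0 <- pip_importance(X, Xt, y0, mcmc = mc, seed = 98)
  expect_true(all(pips0 >= 0 & pips0 <= 1))
  expect_lt(mean(pips0), 0.25)    # near the 1/p prior, far from certainty
  # strong single signal
  set.seed(99)
  y1 <- 3 * X$values[, 4] + rnorm(150)
  pips1 <- pip_importance(X, Xt, y1, mcmc = mc, seed = 100)
  expect_gt(pips1[4], 0.9)
  expect_identical(pip_importance(X, Xt, y1, mcmc = mc, seed = 100), pips1)
  expect_error(pip_importance(X, Xt, y1, mcmc = list(iters = 100, burnin = 200)),
               "burnin")
})

test_that("near-duplicate causal features share posterior inclusion", {
  set.seed(101)
  n <- 300
  z <- rnorm(n)
  dup <- sapply(1:4, function(i) z + rnorm(n, sd = 0.02))
  X <- standardize(cbind(dup, matrix(rnorm(n * 6), n, 6)))
  y <- 4 * z + rnorm(n)
  fit <- reko(X, priors = "eb")
  Xt <- simulate(fit, seed = 102)[[1]]
  pips <- pip_importance(X, Xt, y, mcmc = list(iters = 1500, burnin = 300),
                         seed = 104)
  # model averaging spreads inclusion over the four clones (~0.25 each on
  # average); no single clone captures the whole signal
  expect_true(all(pips[1:4] > 0.02 & pips[1:4] < 0.75))
  expect_gt(sum(pips[1:4]), 0.6)
  expect_lt(sum(pips[1:4]), 1.4)
})

test_that("the full filter pipeline runs end to end and respects seeds", {
  X <- gen_features(250, 30, list(kind = "ar1", rho = 0.5), seed = 110)
  ph <- gen_phenotype(X, 5, 0.6, seed = 111)
  kf <- knockoff_filter(X, ph$y, M = 2, q = 0.2, seed = 112)
  kf2 <- knockoff_filter(X, ph$y, M = 2, q = 0.2, seed = 112)
  expect_identical(kf$stats$beta$W, kf2$stats$beta$W)
  expect_s3_class(kf$selection$beta, "knockoff_selection")
  expect_equal(coef(kf), setNames(kf$stats$beta$W_bar, kf$feature_names))
  expect_output(print(kf), "Knockoff filter")
})
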