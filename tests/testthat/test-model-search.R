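# Correlation filter, g-prior marginal likelihoods (against a quadrature
# oracle), the MC3 sampler (against exhaustive enumeration), PIPs, and the
# convergence diagnostic.

test_that("correlation filter drops later near-duplicates deterministically", {
  set.seed(1)
  tab <- data.frame(a = rnorm(20))
  tab$b <- tab$a                      # exact duplicate
  tab$c <- rnorm(20)
  tab$d <- tab$c + rnorm(20, sd = 1e-3)  # near duplicate
  tab$e <- -tab$a                     # anti-correlated
  red <- correlation_filter(tab, threshold = 0.99)
  expect_equal(colnames(red), c("a", "c", "e"))
  rep <- attr(red, "reduction_report")
  expect_equal(rep$dropped$dropped, c("b", "d"))
  expect_equal(rep$dropped$kept, c("a", "c"))
  expect_true(all(diff(rep$stages$n_covariates) <= 0))
  # signed default keeps anti-correlated columns; absolute flag drops them
  red_abs <- correlation_filter(tab, threshold = 0.99, absolute = TRUE)
  expect_false("e" %in% colnames(red_abs))
  # threshold 1 with no exact duplicates: unchanged
  red1 <- correlation_filter(tab[, c("a", "c", "d", "e")], threshold = 1)
  expect_equal(ncol(red1), 4)
  # constant columns survive with a warning
  tab$k <- 1
  expect_warning(redk <- correlation_filter(tab), "constant")
  expect_true("k" %in% colnames(redk))
})

test_that("g-prior log marginal has the complexity/fit monotonicities", {
  prob <- make_bma_problem()
  y <- prob$y
  # null beats any R^2 = 0 alternative (pure complexity penalty):
  # a covariate decorrelated from y exactly
  X0 <- matrix(stats::residuals(stats::lm(rnorm(length(y)) ~ y)), ncol = 1)
  expect_lt(log_marginal(y, X0), log_marginal(y, NULL))
  expect_equal(log_marginal(y, NULL), 0)
  # better fit at equal size wins
  lm_good <- log_marginal(y, prob$X[, 1, drop = FALSE])
  lm_bad <- log_marginal(y, prob$X[, 5, drop = FALSE])
  expect_gt(lm_good, lm_bad)
  # rank-deficient design is excluded
  Xdup <- cbind(prob$X[, 1], prob$X[, 1])
  expect_warning(v <- log_marginal(y, Xdup), "rank")
  expect_equal(v, -Inf)
})

test_that("closed-form marginal matches 3-D quadrature of the integrand", {
  skip_if_not_installed("pracma")
  set.seed(99)
  n <- 12
  x <- rnorm(n)
  y <- 1 + 0.9 * x + rnorm(n, sd = 0.8)
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  g <- n
  # marginal density of y under: p(a, s2) ~ 1/s2, b | s2 ~ N(0, g s2 / sxx)
  # integrated by nested quadrature over (a, b, log s2)
  lik <- function(a, b, s2) {
    exp(-n / 2 * log(2 * pi * s2) - sum((y - a - xc * b)^2) / (2 * s2))
  }
  m_model <- stats::integrate(Vectorize(function(v) {
    s2 <- exp(v)
    stats::integrate(Vectorize(function(b) {
      stats::integrate(Vectorize(function(a) lik(a, b, s2)),
                       mean(y) - 8, mean(y) + 8,
                       rel.tol = 1e-10)$value *
        stats::dnorm(b, 0, sqrt(g * s2 / sxx))
    }), -8, 8, rel.tol = 1e-9)$value
  }), -6, 4, rel.tol = 1e-9)$value
  m_null <- stats::integrate(Vectorize(function(v) {
    s2 <- exp(v)
    stats::integrate(Vectorize(function(a) {
      exp(-n / 2 * log(2 * pi * s2) - sum((y - a)^2) / (2 * s2))
    }), mean(y) - 8, mean(y) + 8, rel.tol = 1e-10)$value
  }), -6, 4, rel.tol = 1e-9)$value
  closed <- log_marginal(y, matrix(x, ncol = 1),
                         prior_spec(g = "fixed", g_value = g))
  expect_equal(log(m_model / m_null), closed, tolerance = 1e-6)
})

test_that("EBL shrinks to the null score when F <= 1 and is finite otherwise", {
  set.seed(7)
  n <- 25
  y <- rnorm(n)
  # a covariate exactly decorrelated from y: R^2 = 0, so F = 0 <= 1 and
  # the EBL estimate shrinks to g = 0, i.e. the null score
  x_noise <- stats::residuals(stats::lm(rnorm(n) ~ y))
  expect_equal(log_marginal(y, matrix(x_noise), prior_spec(g = "ebl")), 0)
  # strong covariate: positive evidence over the null
  x_good <- y + rnorm(n, sd = 0.1)
  expect_gt(log_marginal(y, matrix(x_good), prior_spec(g = "ebl")), 0)
})

test_that("MC3 ledger matches exhaustive enumeration on p = 8", {
  prob <- make_bma_problem()
  oracle <- oracle_enumerate(prob$y, prob$X)
  led <- mc3_sample(prob$y, prob$X, iterations = 40000, K = 256, seed = 20)
  keys <- ledger_keys(led, prob$X)
  # the sampler saw every model that matters: the oracle's top 20
  top20 <- oracle$key[order(-oracle$pmp)][1:20]
  expect_true(all(top20 %in% keys))
  # analytic PMPs agree model-by-model after renormalizing the oracle to
  # the ledger's membership
  om <- oracle[match(keys, oracle$key), ]
  expect_equal(led$pmp, om$pmp / sum(om$pmp), tolerance = 1e-8,
               ignore_attr = TRUE)
  # analytic PIPs match the enumerated sums (ledger covers ~all the mass)
  pip_oracle <- vapply(seq_len(8), function(j) {
    in_m <- vapply(strsplit(oracle$key, ".", fixed = TRUE),
                   function(s) as.character(j) %in% s, logical(1))
    sum(oracle$pmp[in_m])
  }, numeric(1))
  expect_equal(unname(led$pip), pip_oracle, tolerance = 1e-4)
  # frequency PIPs converge to the enumerated PIPs within MC error
  expect_equal(unname(led$pip_freq), pip_oracle, tolerance = 0.03)
  # package's own enumeration agrees with the independent oracle
  led_en <- enumerate_models(prob$y, prob$X, k_max = 8)
  keys_en <- ledger_keys(led_en, prob$X)
  expect_equal(led_en$pmp, oracle$pmp[match(keys_en, oracle$key)],
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("the sampler is reproducible and respects k_max", {
  prob <- make_bma_problem()
  l1 <- mc3_sample(prob$y, prob$X, iterations = 5000, seed = 4)
  l2 <- mc3_sample(prob$y, prob$X, iterations = 5000, seed = 4)
  expect_identical(l1, l2)
  l3 <- mc3_sample(prob$y, prob$X, iterations = 5000, seed = 5)
  expect_false(identical(l1$visits, l3$visits))
  lk <- mc3_sample(prob$y, prob$X, iterations = 5000, seed = 4, k_max = 2)
  expect_true(all(lk$size <= 2))
})

test_that("chain visit frequencies track analytic PMPs on a long run", {
  prob <- make_bma_problem()
  led <- mc3_sample(prob$y, prob$X, iterations = 60000, K = 50, seed = 8)
  expect_gte(convergence_corr(led), 0.95)
  # degenerate ledger flags missing
  single <- led
  single$models <- led$models[1]
  single$visits <- led$visits[1]
  class(single) <- "top_model_ledger"
  expect_warning(v <- convergence_corr(single), "degenerate")
  expect_true(is.na(v))
})

test_that("PIP bookkeeping: always-included covariate has PIP 1", {
  prob <- make_bma_problem(beta = c(5, rep(0, 7)))  # x1 overwhelming
  led <- mc3_sample(prob$y, prob$X, iterations = 20000, seed = 12)
  pt <- compute_pip(led)
  expect_equal(pt$pip[pt$covariate == "x1"], 1, tolerance = 1e-6)
  expect_true(all(pt$pip >= 0 & pt$pip <= 1))
  expect_equal(sum(led$pmp), 1, tolerance = 1e-12)
  # covariate present in every ledger model -> exactly the PMP total
  in_all <- Reduce(intersect, led$models)
  for (cv in in_all) expect_equal(pt$pip[pt$covariate == cv], 1,
                                  tolerance = 1e-12)
})

test_that("model priors change posterior mass as documented", {
  prob <- make_bma_problem()
  led_u <- enumerate_models(prob$y, prob$X)
  led_b <- enumerate_models(prob$y, prob$X,
                            prior = prior_spec(model_prior = "binomial",
                                               theta = 0.1))
  # sparsity prior shifts mass toward smaller models
  expect_lt(sum(led_b$pmp * led_b$size), sum(led_u$pmp * led_u$size))
  led_bb <- enumerate_models(prob$y, prob$X,
                             prior = prior_spec(model_prior = "binomial-beta",
                                                msize = 2))
  expect_lt(sum(led_bb$pmp * led_bb$size), sum(led_u$pmp * led_u$size))
})
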