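# Bayesian model averaging over linear models of the transformed density.
#
# Candidate models are inclusion vectors over the reduced covariate set.
# Under a Zellner g-prior on the slopes (intercept unpenalized, y centered),
# the marginal likelihood of model M with k_M covariates and fit R^2_M is
# known in closed form up to a constant common to all models:
#
#   log ML(M) = (n - 1 - k_M)/2 * log(1 + g) -
#               (n - 1)/2 * log(1 + g (1 - R^2_M))
#
# The empirical-Bayes-local (EBL) variant replaces g per model by
# g_M = max(0, F_M - 1) with F_M = (R^2/k) / ((1 - R^2)/(n - 1 - k)).
# The MC3 Metropolis-Hastings sampler random-walks over inclusion vectors
# (toggle one covariate; optional swap move), and a ledger of the K
# best-scoring distinct models is kept with analytic posterior model
# probabilities, chain visit counts and posterior inclusion probabilities.

#' Prior specification for the model search
#'
#' @param g `"uip"` (unit-information, g = n), `"ebl"`
#'   (empirical-Bayes-local, g estimated per model from its F statistic),
#'   or `"fixed"` with `g_value`.
#' @param g_value Positive g for `g = "fixed"`.
#' @param model_prior `"uniform"` over all models, `"binomial"` with
#'   per-covariate inclusion probability `theta`, or `"binomial-beta"` with
#'   prior expected model size `msize`.
#' @param theta Inclusion probability for the binomial prior (0 < theta < 1).
#' @param msize Prior expected model size for the binomial-beta prior.
#' @return A `prior_spec` object.
#' @export
prior_spec <- function(g = c("uip", "ebl", "fixed"), g_value = NULL,
                       model_prior = c("uniform", "binomial", "binomial-beta"),
                       theta = 0.5, msize = NULL) {
  g <- match.arg(g)
  model_prior <- match.arg(model_prior)
  if (g == "fixed") {
    if (is.null(g_value) || g_value <= 0) stop("fixed g needs g_value > 0")
  }
  if (model_prior == "binomial" && (theta <= 0 || theta >= 1)) {
    stop("binomial model prior needs 0 < theta < 1")
  }
  if (model_prior == "binomial-beta" && (is.null(msize) || msize < 1)) {
    stop("binomial-beta model prior needs msize >= 1")
  }
  structure(list(g = g, g_value = g_value, model_prior = model_prior,
                 theta = theta, msize = msize),
            class = "prior_spec")
}

# g for a given model under the prior spec; n observations, k covariates.
model_g <- function(prior, n, k, r2) {
  switch(prior$g,
         uip = n,
         fixed = prior$g_value,
         ebl = {
           if (k == 0L) 0
           else {
             Fm <- (r2 / k) / ((1 - r2) / (n - 1 - k))
             max(0, Fm - 1)
           }
         })
}

# log model-prior mass (up to a constant); p candidates, k included.
log_model_prior <- function(prior, p, k) {
  switch(prior$model_prior,
         uniform = 0,
         binomial = k * log(prior$theta) + (p - k) * log(1 - prior$theta),
         `binomial-beta` = {
           a <- 1
           b <- (p - prior$msize) / prior$msize
           lbeta(a + k, b + p - k) - lbeta(a, b)
         })
}

# R^2 of y on X[, idx] with intercept; -Inf marker if rank deficient.
model_r2 <- function(y, X, idx) {
  n <- length(y)
  tss <- sum((y - mean(y))^2)
  if (length(idx) == 0L) return(0)
  Xm <- cbind(1, X[, idx, drop = FALSE])
  fit <- stats::.lm.fit(Xm, y)
  if (fit$rank < ncol(Xm)) return(NA_real_)
  1 - sum(fit$residuals^2) / tss
}

#' Log marginal likelihood of one candidate model
#'
#' Closed-form Zellner g-prior marginal likelihood (up to a constant shared
#' by all models on the same data), with the intercept unpenalized and the
#' response centered. The null model scores 0 by convention. For the EBL
#' prior, g is estimated per model from its F statistic and models with
#' F <= 1 shrink to the null score.
#'
#' @param y Transformed response (e.g. sqrt of density).
#' @param X_M Design matrix / data frame of the model's covariates (no
#'   intercept column), or `NULL` for the null model.
#' @param prior A [prior_spec()].
#' @return Log marginal likelihood; `-Inf` (with a warning) for a
#'   rank-deficient design.
#' @export
log_marginal <- function(y, X_M, prior = prior_spec()) {
  n <- length(y)
  if (is.null(X_M)) k <- 0L
  else {
    X_M <- as.matrix(X_M)
    k <- ncol(X_M)
  }
  if (n - 1 - k <= 0) stop("model too large: need k <= n - 2")
  r2 <- if (k == 0L) 0 else model_r2(y, X_M, seq_len(k))
  if (is.na(r2)) {
    warning("rank-deficient design; model excluded (-Inf)")
    return(-Inf)
  }
  g <- model_g(prior, n, k, r2)
  (n - 1 - k) / 2 * log1p(g) - (n - 1) / 2 * log1p(g * (1 - r2))
}

# Internal scorer used by the samplers: log ML + log model prior from a
# precomputed design; idx is an integer index vector into colnames(X).
score_model <- function(y, X, idx, prior, p) {
  n <- length(y)
  k <- length(idx)
  r2 <- model_r2(y, X, idx)
  if (is.na(r2)) return(-Inf)
  g <- model_g(prior, n, k, r2)
  lml <- (n - 1 - k) / 2 * log1p(g) - (n - 1) / 2 * log1p(g * (1 - r2))
  lml + log_model_prior(prior, p, k)
}

new_ledger <- function(entries, names, n, p, prior, iterations = NA_integer_,
                       burnin = NA_integer_, seed = NA_integer_,
                       pip_freq = NULL, n_distinct = NA_integer_) {
  lp <- vapply(entries, function(e) e$lp, numeric(1))
  keys <- vapply(entries, function(e) {
    paste(as.integer(seq_len(p) %in% e$idx), collapse = "")
  }, character(1))
  ord <- order(-lp, keys)
  entries <- entries[ord]
  lp <- lp[ord]
  w <- exp(lp - max(lp))
  pmp <- w / sum(w)
  incl <- matrix(vapply(entries, function(e) seq_len(p) %in% e$idx,
                        logical(p)), nrow = p)  # p x K
  pip <- drop(incl %*% pmp)
  structure(list(
    models = lapply(entries, function(e) names[e$idx]),
    size = vapply(entries, function(e) length(e$idx), integer(1)),
    log_post = lp,
    pmp = pmp,
    visits = vapply(entries, function(e) e$visits, numeric(1)),
    pip = stats::setNames(pip, names),
    pip_freq = pip_freq,
    candidates = names,
    n = n, p = p, prior = prior,
    iterations = iterations, burnin = burnin, seed = seed,
    n_distinct_visited = n_distinct),
    class = "top_model_ledger")
}

#' @export
print.top_model_ledger <- function(x, n_show = 5L, ...) {
  cat("<top_model_ledger> ", length(x$models), " models over ", x$p,
      " candidates (n = ", x$n, ", prior: ", x$prior$g, "/",
      x$prior$model_prior, ")\n", sep = "")
  for (i in seq_len(min(n_show, length(x$models)))) {
    cat(sprintf("  %2d. PMP %.4f  visits %6.0f  {%s}\n", i, x$pmp[i],
                x$visits[i], paste(x$models[[i]], collapse = ", ")))
  }
  top_pip <- sort(x$pip[x$pip > 0.01], decreasing = TRUE)
  cat("  PIP > 0.5: ",
      paste(sprintf("%s=%.3f", names(top_pip[top_pip > 0.5]),
                    top_pip[top_pip > 0.5]), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' MC3 Metropolis-Hastings sampler over candidate models
#'
#' Random-walks over inclusion vectors: each step toggles one uniformly
#' chosen covariate (or, with probability `swap_prob`, swaps an included
#' for an excluded one), and accepts with probability
#' min(1, posterior ratio). Proposals that would exceed `k_max` covariates
#' are rejected. All distinct admissible models seen are scored
#' analytically; the returned ledger keeps the `K` best.
#'
#' @param y Transformed response.
#' @param table Candidate covariate table (data frame or matrix, named
#'   columns; e.g. the reduced output of [correlation_filter()]).
#' @param prior A [prior_spec()].
#' @param iterations Number of MH iterations.
#' @param burnin Iterations to discard for the visit counts (default 10%).
#' @param K Ledger size: number of best models to keep (default 1000).
#' @param seed RNG seed; a fixed seed reproduces the ledger exactly.
#' @param k_max Maximum model size (default n - 3).
#' @param swap_prob Probability of a swap move instead of a toggle.
#' @return A `top_model_ledger` with models, analytic posterior model
#'   probabilities (normalized over the ledger), chain visit counts,
#'   analytic PIPs and chain-frequency PIPs.
#' @export
mc3_sample <- function(y, table, prior = prior_spec(), iterations = 10000L,
                       burnin = max(1L, iterations %/% 10L), K = 1000L,
                       seed = 1L, k_max = length(y) - 3L, swap_prob = 0) {
  X <- as.matrix(table)
  storage.mode(X) <- "double"
  p <- ncol(X)
  n <- length(y)
  if (nrow(X) != n) stop("response and table have different lengths")
  if (iterations <= burnin || burnin < 0) stop("need iterations > burnin >= 0")
  if (K < 1L) stop("K must be >= 1")
  if (k_max > n - 3L) {
    k_max <- n - 3L
    warning("k_max capped at n - 3 = ", k_max)
  }
  set.seed(seed)
  nm <- colnames(X)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  key_of <- function(idx) paste0("m", paste(idx, collapse = "."))
  lookup <- function(idx) {
    k <- key_of(idx)
    e <- seen[[k]]
    if (is.null(e)) {
      e <- list(idx = idx, lp = score_model(y, X, idx, prior, p), visits = 0)
      seen[[k]] <- e
    }
    e
  }
  cur <- integer(0)                  # start at the null model
  cur_e <- lookup(cur)
  freq_incl <- numeric(p)
  n_counted <- 0L
  for (it in seq_len(iterations)) {
    kc <- length(cur)
    do_swap <- swap_prob > 0 && kc > 0L && kc < p &&
      stats::runif(1) < swap_prob
    if (do_swap) {
      drop_j <- cur[sample.int(kc, 1L)]
      add_j <- setdiff(seq_len(p), cur)[sample.int(p - kc, 1L)]
      prop <- sort(c(setdiff(cur, drop_j), add_j))
    } else {
      j <- sample.int(p, 1L)
      prop <- if (j %in% cur) setdiff(cur, j) else sort(c(cur, j))
    }
    if (length(prop) <= k_max) {       # beyond k_max: auto-reject
      prop_e <- lookup(prop)
      if (is.finite(prop_e$lp) &&
          log(stats::runif(1)) < prop_e$lp - cur_e$lp) {
        cur <- prop
        cur_e <- prop_e
      }
    }
    if (it > burnin) {
      k <- key_of(cur)
      e <- seen[[k]]
      e$visits <- e$visits + 1
      seen[[k]] <- e
      cur_e <- e
      if (length(cur)) freq_incl[cur] <- freq_incl[cur] + 1
      n_counted <- n_counted + 1L
    }
  }
  entries <- as.list(seen)
  entries <- entries[order(names(entries))]   # stable before ranking
  entries <- unname(entries)
  entries <- Filter(function(e) is.finite(e$lp), entries)
  lp <- vapply(entries, function(e) e$lp, numeric(1))
  keep <- order(-lp)[seq_len(min(K, length(entries)))]
  new_ledger(entries[keep], nm, n, p, prior,
             iterations = iterations, burnin = burnin, seed = seed,
             pip_freq = stats::setNames(freq_incl / n_counted, nm),
             n_distinct = length(entries))
}

#' Exhaustive Bayesian model averaging over all candidate subsets
#'
#' Enumerates every admissible model (size <= `k_max`) over at most ~20
#' candidates and scores each analytically; posterior masses are normalized
#' over the full enumeration. Useful as the exact reference on small
#' problems.
#'
#' @inheritParams mc3_sample
#' @return A `top_model_ledger` over all enumerated models (visit counts 0).
#' @export
enumerate_models <- function(y, table, prior = prior_spec(),
                             k_max = length(y) - 3L) {
  X <- as.matrix(table)
  p <- ncol(X)
  if (p > 20L) stop("exhaustive enumeration limited to p <= 20")
  entries <- list()
  for (k in 0:min(p, k_max)) {
    sets <- if (k == 0L) list(integer(0))
            else asplit(utils::combn(p, k), 2L)
    for (idx in sets) {
      idx <- as.integer(idx)
      lp <- score_model(y, X, idx, prior, p)
      if (is.finite(lp)) {
        entries[[length(entries) + 1L]] <- list(idx = idx, lp = lp, visits = 0)
      }
    }
  }
  new_ledger(entries, colnames(X), length(y), p, prior,
             n_distinct = length(entries))
}

#' Posterior inclusion probabilities from a ledger
#'
#' Analytic PIPs sum the ledger-normalized posterior model probabilities of
#' the models containing each covariate; the frequency variant (when the
#' ledger came from a chain) is the fraction of post-burnin iterations the
#' covariate was included.
#'
#' @param ledger A `top_model_ledger`.
#' @return Data frame `covariate, pip, pip_freq` sorted by `pip`.
#' @export
compute_pip <- function(ledger) {
  stopifnot(inherits(ledger, "top_model_ledger"))
  if (length(ledger$models) == 0L) stop("empty ledger")
  pip <- stats::setNames(numeric(ledger$p), ledger$candidates)
  for (i in seq_along(ledger$models)) {
    pip[ledger$models[[i]]] <- pip[ledger$models[[i]]] + ledger$pmp[i]
  }
  out <- data.frame(covariate = ledger$candidates,
                    pip = as.numeric(pip),
                    pip_freq = if (is.null(ledger$pip_freq)) NA_real_
                               else as.numeric(ledger$pip_freq),
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(-out$pip), ]
}

#' Sampler convergence: correlation of visit frequencies with analytic PMPs
#'
#' Pearson correlation, over the ledger's models, between the normalized
#' chain visit frequencies (the empirical posterior) and the analytic
#' posterior model probabilities. Values near 1 indicate the chain has
#' equilibrated over the retained models.
#'
#' @param ledger A `top_model_ledger` produced by [mc3_sample()].
#' @return Correlation in \[-1, 1\], or `NA` (with a warning) if degenerate.
#' @export
convergence_corr <- function(ledger) {
  stopifnot(inherits(ledger, "top_model_ledger"))
  if (length(ledger$models) < 2L || sum(ledger$visits) == 0) {
    warning("degenerate ledger: convergence correlation undefined")
    return(NA_real_)
  }
  stats::cor(ledger$visits / sum(ledger$visits), ledger$pmp)
}
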