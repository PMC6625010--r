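# Deterministic fixtures and independent brute-force oracles. The oracles
# deliberately avoid the package's own statistics code paths: plain loops
# over pixels and textbook formulas only.

# A small fully-deterministic section raster: values are smooth functions of
# the pixel coordinates, so every statistic has a reproducible value and no
# degenerate denominators occur.
make_test_raster <- function(n = 12, name = "fixture") {
  idx <- expand.grid(r = seq_len(n), c = seq_len(n))
  mask <- matrix(TRUE, n, n)
  mask[1, 1] <- FALSE  # irregular corner
  bands <- list()
  for (b in c(1, 2, 3, 4, 5, 7)) {
    m <- matrix(0.05 + 0.08 * ((idx$r * b + idx$c) %% 7) / 7 +
                  0.01 * b, n, n)
    m[!mask] <- NA_real_
    bands[[as.character(b)]] <- m
  }
  section_raster(name, bands, mask)
}

# A tiny synthetic scene shared across tests (built once per test run).
small_scene <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sp <- scene_spec(n_sections = 8, section_size_range = c(120, 300),
                       seed = 42)
      cache <<- list(spec = sp, scene = generate_scene(sp))
    }
    cache
  }
})

# A small regression problem for the model-search tests.
make_bma_problem <- function(n = 30, p = 8, seed = 314, beta = NULL) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("x", seq_len(p))))
  if (is.null(beta)) beta <- c(1.2, -0.8, rep(0, p - 2))
  y <- drop(2 + X %*% beta + rnorm(n, sd = 0.7))
  list(y = y, X = as.data.frame(X))
}

# --- brute-force oracles -------------------------------------------------

oracle_mean <- function(x) sum(x) / length(x)

oracle_var <- function(x) {
  m <- oracle_mean(x)
  acc <- 0
  for (v in x) acc <- acc + (v - m)^2
  acc / (length(x) - 1)
}

oracle_stat4 <- function(x) {
  m <- oracle_mean(x)
  v <- oracle_var(x)
  c(mean = m, sd = sqrt(v), var = v, cv = sqrt(v) / m)
}

# loop over the mask grid, collecting one band's pixels
oracle_band_pixels <- function(raster, band) {
  m <- raster$bands[[as.character(band)]]
  out <- numeric(0)
  for (r in seq_len(nrow(m))) {
    for (c in seq_len(ncol(m))) {
      if (raster$mask[r, c]) out <- c(out, m[r, c])
    }
  }
  out
}

oracle_minmax <- function(x) (x - min(x)) / (max(x) - min(x))

# independent log marginal likelihood via lm(): used by the enumeration
# oracle in the model-search tests
oracle_logml_uip <- function(y, X, idx) {
  n <- length(y)
  k <- length(idx)
  g <- n
  r2 <- if (k == 0) 0 else {
    summary(stats::lm(y ~ ., data = data.frame(y = y, X[, idx, drop = FALSE])))$r.squared
  }
  (n - 1 - k) / 2 * log(1 + g) - (n - 1) / 2 * log(1 + g * (1 - r2))
}

# full enumeration of all subsets of p columns (p small): returns data frame
# with model key, log marginal and normalized posterior mass
oracle_enumerate <- function(y, X) {
  p <- ncol(X)
  stopifnot(p <= 12)
  keys <- character(0)
  lml <- numeric(0)
  sets <- list()
  for (code in 0:(2^p - 1)) {
    idx <- which(bitwAnd(code, 2^(seq_len(p) - 1)) > 0)
    keys <- c(keys, paste(idx, collapse = "."))
    sets[[length(sets) + 1]] <- idx
    lml <- c(lml, oracle_logml_uip(y, X, idx))
  }
  w <- exp(lml - max(lml))
  data.frame(key = keys, logml = lml, pmp = w / sum(w),
             stringsAsFactors = FALSE)
}

ledger_keys <- function(ledger, X) {
  vapply(ledger$models, function(m) {
    paste(match(m, colnames(X)), collapse = ".")
  }, character(1))
}
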