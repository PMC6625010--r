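#' Drop near-duplicate covariates by pairwise Pearson correlation
#'
#' Greedy scan in stable column order: walking left to right, a column is
#' dropped if its Pearson correlation with any already-kept column reaches
#' the threshold (the earlier member of each such pair is kept). By default
#' the signed correlation `r >= threshold` is used; `absolute = TRUE`
#' filters on `|r| >= threshold` instead. Constant columns have undefined
#' correlations; they are kept and a warning is issued.
#'
#' @param table Covariate table (data frame or matrix with named columns).
#' @param threshold Correlation threshold in (0, 1\]; default 0.99.
#' @param absolute Filter on the absolute correlation?
#' @return The reduced table, with a `reduction_report` attribute: a list
#'   with `stages` (data frame of stage names and covariate counts) and
#'   `dropped` (data frame `kept, dropped, correlation`).
#' @export
correlation_filter <- function(table, threshold = 0.99, absolute = FALSE) {
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  X <- as.matrix(table)
  if (nrow(X) < 2L) stop("need at least 2 rows to compute correlations")
  p <- ncol(X)
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) {
    warning("constant column(s) kept (correlation undefined): ",
            paste(colnames(X)[sds == 0], collapse = ", "))
  }
  C <- suppressWarnings(stats::cor(X))
  if (absolute) C <- abs(C)
  keep <- logical(p)
  dropped <- list()
  for (j in seq_len(p)) {
    if (sds[j] == 0) {
      keep[j] <- TRUE
      next
    }
    prior_kept <- which(keep & sds > 0)
    hit <- prior_kept[!is.na(C[prior_kept, j]) & C[prior_kept, j] >= threshold]
    if (length(hit)) {
      dropped[[length(dropped) + 1L]] <- data.frame(
        kept = colnames(X)[hit[1L]], dropped = colnames(X)[j],
        correlation = C[hit[1L], j], stringsAsFactors = FALSE)
    } else {
      keep[j] <- TRUE
    }
  }
  out <- table[, keep, drop = FALSE]
  report <- list(
    stages = data.frame(
      stage = c("input", "after correlation filter"),
      n_covariates = c(p, sum(keep)), stringsAsFactors = FALSE),
    dropped = if (length(dropped)) do.call(rbind, dropped)
              else data.frame(kept = character(0), dropped = character(0),
                              correlation = numeric(0)),
    threshold = threshold, absolute = absolute)
  attr(out, "reduction_report") <- report
  out
}
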