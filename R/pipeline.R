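# End-to-end orchestration: covariates -> reduction -> model search ->
# OLS refit -> back-transform/populations -> evaluation (+ optional LOOCV,
# NDVI masking), from one seeded configuration. Every stage artifact is a
# flat CSV/JSON file so any stage can be re-run or inspected in isolation.

#' Pipeline configuration
#'
#' Validates and freezes every knob of a pipeline run. Input is either a
#' synthetic [scene_spec()] (`scene =`) or a directory of section rasters
#' written by [write_scene()] plus a section table CSV (`rasters_dir =`,
#' `sections_csv =`).
#'
#' @param scene A [scene_spec()] for synthetic input, or `NULL`.
#' @param rasters_dir,sections_csv Paths for on-disk input (ignored when
#'   `scene` is given).
#' @param subset Covariate subset: `"spectral"` (default), `"all"`,
#'   `"nonspectral"`.
#' @param norm_scope Min-max normalization scope (`"section"`/`"global"`).
#' @param cor_threshold,cor_absolute Correlation-filter settings.
#' @param transform Response transform (default `"sqrt"`).
#' @param prior A [prior_spec()].
#' @param iterations,burnin,top_k,seed Sampler settings; `burnin = NULL`
#'   means 10 percent of `iterations`.
#' @param ndvi,ndvi_threshold Optional vegetation masking before covariate
#'   computation (off by default).
#' @param run_loocv Run leave-one-out cross-validation?
#' @param outdir Output directory for stage artifacts.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(scene = NULL, rasters_dir = NULL,
                            sections_csv = NULL,
                            subset = c("spectral", "all", "nonspectral"),
                            norm_scope = c("section", "global"),
                            cor_threshold = 0.99, cor_absolute = FALSE,
                            transform = c("sqrt", "ln", "identity"),
                            prior = prior_spec(),
                            iterations = 10000L, burnin = NULL,
                            top_k = 1000L, seed = 1L,
                            ndvi = FALSE, ndvi_threshold = 0.5,
                            run_loocv = TRUE, outdir = NULL) {
  subset <- match.arg(subset)
  norm_scope <- match.arg(norm_scope)
  transform <- match.arg(transform)
  if (is.null(scene)) {
    if (is.null(rasters_dir) || is.null(sections_csv)) {
      stop("give either `scene` or both `rasters_dir` and `sections_csv`")
    }
    if (!dir.exists(rasters_dir)) stop("rasters_dir does not exist")
    if (!file.exists(sections_csv)) stop("sections_csv does not exist")
  } else {
    stopifnot(inherits(scene, "scene_spec"))
  }
  if (cor_threshold <= 0 || cor_threshold > 1) {
    stop("cor_threshold must be in (0, 1]")
  }
  if (ndvi_threshold < -1 || ndvi_threshold > 1) {
    stop("ndvi_threshold must be in [-1, 1]")
  }
  if (is.null(burnin)) burnin <- max(1L, as.integer(iterations) %/% 10L)
  if (iterations <= burnin) stop("iterations must exceed burnin")
  structure(list(
    scene = scene, rasters_dir = rasters_dir, sections_csv = sections_csv,
    subset = subset, norm_scope = norm_scope,
    cor_threshold = cor_threshold, cor_absolute = cor_absolute,
    transform = transform, prior = prior,
    iterations = as.integer(iterations), burnin = as.integer(burnin),
    top_k = as.integer(top_k), seed = as.integer(seed),
    ndvi = isTRUE(ndvi), ndvi_threshold = ndvi_threshold,
    run_loocv = isTRUE(run_loocv), outdir = outdir),
    class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; `scene:` is
#' a mapping of [scene_spec()] arguments, and `prior:` of [prior_spec()]
#' arguments.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$scene)) {
    sc <- cfg$scene
    if (!is.null(sc$truth_model) && !is.null(sc$truth_model$coefficients)) {
      sc$truth_model$coefficients <- unlist(sc$truth_model$coefficients)
    }
    cfg$scene <- do.call(scene_spec, sc)
  }
  if (!is.null(cfg$prior)) cfg$prior <- do.call(prior_spec, cfg$prior)
  do.call(pipeline_config, cfg)
}

ledger_to_json <- function(ledger, path) {
  pip_tab <- compute_pip(ledger)
  jsonlite::write_json(list(
    models = ledger$models,
    log_post = ledger$log_post,
    pmp = ledger$pmp,
    visits = ledger$visits,
    pip = pip_tab,
    convergence_corr = suppressWarnings(convergence_corr(ledger)),
    prior = unclass(ledger$prior),
    n = ledger$n, p = ledger$p,
    iterations = ledger$iterations, burnin = ledger$burnin,
    seed = ledger$seed,
    n_distinct_visited = ledger$n_distinct_visited
  ), path, auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
}

#' Run the full estimation pipeline
#'
#' Executes covariates -> reduction -> MC3 model search -> OLS refit ->
#' back-transform and population estimates -> evaluation, plus optional
#' LOOCV, and writes every stage artifact (CSV/JSON) and a manifest with
#' the seed, package version and file checksums to `config$outdir` (when
#' set). A run is fully reproducible from the configuration and seed.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the report bundle: a list with `sections`,
#'   `covariates`, `reduction`, `ledger`, `fit`, `estimates`, `evaluation`,
#'   `loocv` (or `NULL`) and `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  # -- input
  bundle <- list(config = config)
  if (!is.null(config$scene)) {
    scn <- stage("simulate", {
      scene <- generate_scene(config$scene)
      tm <- config$scene$truth_model
      scene$sections <- generate_truth(scene$rasters, tm, tm$residual_sd,
                                       seed = config$scene$seed + 1L)
      scene
    })
    rasters <- scn$rasters
    sections <- scn$sections
  } else {
    rasters <- stage("load", {
      files <- sort(list.files(config$rasters_dir, pattern = "\\.tif$",
                               full.names = TRUE))
      lapply(files, read_section_raster)
    })
    sections <- utils::read.csv(config$sections_csv,
                                stringsAsFactors = FALSE)
    if (is.null(sections$density)) {
      sections$density <- sections$persons / sections$area_km2
    }
  }
  bundle$sections <- sections
  if (config$ndvi) {
    rasters <- stage("ndvi_mask", {
      lapply(rasters, ndvi_mask, threshold = config$ndvi_threshold)
    })
  }
  # -- covariates & reduction
  bundle$covariates <- stage("covariates", {
    build_covariate_table(rasters, subset = config$subset,
                          norm_scope = config$norm_scope)
  })
  reduced <- stage("reduce", {
    correlation_filter(bundle$covariates, threshold = config$cor_threshold,
                       absolute = config$cor_absolute)
  })
  bundle$reduction <- attr(reduced, "reduction_report")
  # -- model search and refit
  y <- transform_density(sections$density, config$transform)
  bundle$ledger <- stage("bma", {
    mc3_sample(y, reduced, prior = config$prior,
               iterations = config$iterations, burnin = config$burnin,
               K = config$top_k, seed = config$seed)
  })
  top <- bundle$ledger$models[[1L]]
  bundle$fit <- stage("fit", {
    ols_fit(y, reduced[, top, drop = FALSE])
  })
  # -- predict & evaluate
  bundle$estimates <- stage("predict", {
    pr <- predict_density(bundle$fit, transform = config$transform)
    pops <- estimate_populations(pr$density, sections$area_km2)
    data.frame(section = sections$section,
               persons = sections$persons,
               area_km2 = sections$area_km2,
               density = sections$density,
               density_hat = pr$density,
               density_lwr = pr$density_lwr,
               density_upr = pr$density_upr,
               pop_hat = pops$population,
               re_pct = relative_error(pr$density, sections$density),
               stringsAsFactors = FALSE)
  })
  bundle$evaluation <- stage("evaluate", {
    evaluate_estimates(bundle$estimates$density_hat, sections$density,
                       area = sections$area_km2, section = sections$section)
  })
  if (config$run_loocv) {
    bundle$loocv <- stage("loocv", {
      loocv(sections$density, reduced[, top, drop = FALSE],
            section = sections$section, transform = config$transform)
    })
  }
  if (!is.null(config$outdir)) write_bundle(bundle, config$outdir)
  invisible(bundle)
}

# Serialize stage artifacts + manifest. Flat files only; the manifest holds
# seed, versions and md5 checksums (no timestamps, so reruns are
# byte-identical).
write_bundle <- function(bundle, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(df, f) {
    utils::write.csv(df, file.path(outdir, f), row.names = FALSE)
    f
  }
  files <- character(0)
  files <- c(files, wcsv(bundle$sections, "sections.csv"))
  cov <- cbind(section = rownames(bundle$covariates), bundle$covariates)
  files <- c(files, wcsv(cov, "covariates.csv"))
  jsonlite::write_json(bundle$reduction,
                       file.path(outdir, "reduction.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, "reduction.json")
  ledger_to_json(bundle$ledger, file.path(outdir, "ledger.json"))
  files <- c(files, "ledger.json")
  fit <- bundle$fit
  jsonlite::write_json(list(
    covariates = fit$covariates,
    coefficients = as.data.frame(fit$coefficients),
    vif = as.list(fit$vif),
    r_squared = fit$r_squared, adj_r_squared = fit$adj_r_squared,
    df_residual = fit$df_residual),
    file.path(outdir, "fit.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, "fit.json")
  files <- c(files, wcsv(bundle$estimates, "estimates.csv"))
  ev <- bundle$evaluation
  jsonlite::write_json(ev[setdiff(names(ev), "table")],
                       file.path(outdir, "evaluation.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, "evaluation.json")
  if (!is.null(bundle$loocv)) {
    files <- c(files, wcsv(bundle$loocv$folds, "loocv.csv"))
    files <- c(files, wcsv(bundle$loocv$summary, "loocv_summary.csv"))
  }
  manifest <- list(
    package = "popdensat",
    version = as.character(utils::packageVersion("popdensat")),
    seed = bundle$config$seed,
    files = as.list(tools::md5sum(file.path(outdir, files))))
  names(manifest$files) <- files
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(files)
}
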