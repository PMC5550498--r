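#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> explore -> fit -> report and writes
#' all result tables, a DIC JSON and a run manifest to `out`. The run is a
#' pure function of (config, seed): re-running with the same configuration
#' and seed reproduces every output file byte for byte.
#'
#' The configuration is a named list (or a YAML/JSON file path, read via
#' [read_config()]) with elements:
#'
#' * `panel`, `weights`: CSV / GAL input paths plus `schema` for the panel,
#'   **or** `simulate: true` to generate a synthetic panel from `scenario`
#'   (arguments to [sim_scenario()]; omit for the defaults).
#' * `model`: arguments to [model_spec()] (`family`, `covariates`,
#'   `nonlinear`, `bins`, `transforms`).
#' * `priors`: optional `a`, `b` for [hyperpriors()].
#' * `mcmc`: arguments to [mcmc_config()] (the pipeline seed overrides).
#' * `explore`: optional list with `n_permutations` (default 9999).
#' * `stages`: subset of `c("explore", "fit")`; default both.
#'
#' @param config named list or path to a YAML/JSON config file.
#' @param out output directory.
#' @param seed integer master seed; stage sub-seeds are derived from it.
#' @param verbose print progress lines.
#' @return the run manifest (named list), invisibly; also written as
#'   `run_manifest.json` in `out` (the result tables get their own
#'   `manifest.json` via [write_summaries()]).
#' @export
run_pipeline <- function(config, out, seed = 1L, verbose = FALSE) {
  t0 <- Sys.time()
  cfg_path <- NULL
  if (is.character(config) && length(config) == 1) {
    cfg_path <- config
    config <- read_config(config)
  }
  stages <- config$stages %||% c("explore", "fit")
  say <- function(...) if (verbose) message(...)

  # validate the model spec up front so a bad config fails before compute
  spec <- do.call(model_spec, c(
    list(family = config$model$family %||% "model1a"),
    config$model[intersect(names(config$model),
                           c("covariates", "nonlinear", "bins", "transforms",
                             "time_centering"))]))

  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  outputs <- character(0)

  if (isTRUE(config$simulate) || is.null(config$panel)) {
    say("simulating synthetic panel")
    scen <- do.call(sim_scenario, config$scenario %||% list())
    gen_spec <- if (spec$family %in% c("null_parametric", "null_dynamic")) {
      model_spec(spec$family)
    } else {
      model_spec("model1a", covariates = names(scen$covariates),
                 transforms = c(density = "log"))
    }
    panel <- simulate_counts(scen, gen_spec, seed = seed)
    w <- attr(panel, "weights")
    write_panel(panel, file.path(out, "panel.csv"))
    write_gal(w, file.path(out, "weights.gal"))
    write_geojson_polygons(attr(panel, "polygons"),
                           file.path(out, "polygons.geojson"))
    tr <- attr(panel, "truth")
    tr <- tr[!vapply(tr, is.null, logical(1))]
    jsonlite::write_json(tr, file.path(out, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
    outputs <- c(outputs, file.path(out, c("panel.csv", "weights.gal",
                                           "polygons.geojson", "truth.json")))
  } else {
    say("reading panel and weights")
    panel <- read_panel(config$panel$path, config$panel$schema)
    w <- read_gal(config$weights$path)
  }

  tables <- list()
  meta <- list(seed = seed, package_version = as.character(
    utils::packageVersion("stpois")))

  if ("explore" %in% stages) {
    say("exploratory spatial statistics")
    nperm <- config$explore$n_permutations %||% 9999
    ex <- explore_panel(panel, w, n_perm = nperm, seed = seed + 1000L)
    tables$moran_univariate <- ex$univariate
    if (!is.null(ex$bivariate)) tables$moran_bivariate <- ex$bivariate
  }

  if ("fit" %in% stages) {
    say("fitting ", spec$family)
    pr <- if (is.null(config$priors)) hyperpriors()
          else hyperpriors(config$priors$a %||% 1, config$priors$b %||% 5e-5)
    mc_args <- config$mcmc %||% list()
    mc_args$seed <- seed + 2000L
    mc <- do.call(mcmc_config, mc_args)
    fit <- stpois(panel, w, spec, priors = pr, mcmc = mc)
    sm <- summary(fit)
    tables$effects <- sm$fixed
    tables$area_effects <- sm$areas      # residual RR + differential trend
    for (nm in names(sm$curves)) {
      tables[[paste0("curve_", nm)]] <- sm$curves[[nm]]
    }
    if (!is.null(sm$trend)) tables$trend <- sm$trend
    meta$model <- spec$family
    meta$dic <- fit$dic$DIC
    meta$pD <- fit$dic$pD
    meta$max_rhat <- max(fit$rhat, na.rm = TRUE)
  }

  meta$config_hash <- unname(config_hash(config))
  files <- write_summaries(tables, out, meta = meta)
  outputs <- c(outputs, files)

  manifest <- c(list(command = "run_pipeline",
                     config = cfg_path %||% "inline",
                     inputs = if (is.null(config$panel)) "simulated"
                              else config$panel$path,
                     outputs = as.list(outputs),
                     wall_clock_sec = as.numeric(difftime(Sys.time(), t0,
                                                          units = "secs"))),
                meta)
  jsonlite::write_json(manifest, file.path(out, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  missing_out <- outputs[!file.exists(outputs)]
  if (length(missing_out)) {
    stop("pipeline finished but outputs missing: ",
         paste(missing_out, collapse = ", "))
  }
  say("done")
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stable content hash of the configuration (md5 of its canonical JSON)
config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  jsonlite::write_json(config, f, auto_unbox = TRUE, digits = NA)
  tools::md5sum(f)
}
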