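#' Construct an areal space-time panel
#'
#' The central data container: event counts, populations and covariates for a
#' fixed set of areas observed over a contiguous run of periods (e.g. calendar
#' years). Everything downstream -- exploratory statistics, model fitting,
#' simulation -- consumes this object.
#'
#' @param area_ids character vector of unique area identifiers (districts).
#' @param periods strictly increasing, contiguous integer vector of time
#'   labels (e.g. `2007:2011`).
#' @param counts integer matrix (areas x periods) of non-negative event
#'   counts.
#' @param population numeric matrix (areas x periods) of strictly positive
#'   person counts.
#' @param covariates named list of covariate values: either an
#'   (areas x periods) matrix for a time-varying covariate, or a length-n
#'   vector for a static covariate, which is broadcast across periods (one
#'   identical column per period).
#' @param units optional named character vector documenting covariate units
#'   (e.g. `c(income = "EUR 1,000", unemployment = "%")`).
#'
#' @return An object of class `areal_panel`: a list with elements
#'   `area_ids`, `periods`, `counts`, `population`, `covariates` (all
#'   matrices after broadcasting), `static` (logical flags per covariate)
#'   and `units`.
#' @export
areal_panel <- function(area_ids, periods, counts, population,
                        covariates = list(), units = NULL) {
  area_ids <- as.character(area_ids)
  if (anyDuplicated(area_ids)) {
    stop("duplicate area ids: ", paste(unique(area_ids[duplicated(area_ids)]),
                                       collapse = ", "))
  }
  periods <- as.integer(periods)
  if (length(periods) < 1L || is.unsorted(periods, strictly = TRUE)) {
    stop("periods must be strictly increasing")
  }
  if (length(periods) > 1L && !all(diff(periods) == 1L)) {
    stop("periods must be contiguous (consecutive integers)")
  }
  n <- length(area_ids)
  np <- length(periods)

  as_mat <- function(x, what) {
    x <- as.matrix(x)
    if (!all(dim(x) == c(n, np))) {
      stop(what, " must be an ", n, " x ", np, " matrix")
    }
    dimnames(x) <- list(area_ids, periods)
    x
  }
  counts <- as_mat(counts, "counts")
  population <- as_mat(population, "population")
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts))) {
    stop("counts must be finite non-negative integers")
  }
  if (any(!is.finite(population)) || any(population <= 0)) {
    stop("population must be finite and strictly positive")
  }

  static <- logical(0)
  if (length(covariates)) {
    if (is.null(names(covariates)) || any(names(covariates) == "")) {
      stop("covariates must be a named list")
    }
    static <- vapply(covariates, function(x) !is.matrix(x), logical(1))
    covariates <- lapply(covariates, function(x) {
      if (is.matrix(x)) {
        as_mat(x, "covariate")
      } else {
        if (length(x) != n) stop("static covariate must have one value per area")
        as_mat(matrix(rep(as.numeric(x), np), nrow = n), "covariate")
      }
    })
    names(static) <- names(covariates)
    bad <- vapply(covariates, function(x) any(!is.finite(x)), logical(1))
    if (any(bad)) stop("non-finite covariate values in: ",
                       paste(names(covariates)[bad], collapse = ", "))
  }

  structure(list(area_ids = area_ids, periods = periods, counts = counts,
                 population = population, covariates = covariates,
                 static = static, units = units),
            class = "areal_panel")
}

#' @export
print.areal_panel <- function(x, ...) {
  cat("Areal panel:", length(x$area_ids), "areas x", length(x$periods),
      "periods (", x$periods[1], "-", x$periods[length(x$periods)], ")\n")
  cat("  total events:", sum(x$counts),
      " total person-periods:", format(sum(x$population), big.mark = ","), "\n")
  if (length(x$covariates)) {
    cat("  covariates:",
        paste0(names(x$covariates),
               ifelse(x$static[names(x$covariates)], " (static)", ""),
               collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read an areal panel from a long-format CSV
#'
#' One row per (area, period) combination. Column roles are given by `schema`,
#' a named list with entries `area`, `period`, `count`, `population` and
#' `covariates` (a character vector of covariate column names, or a named
#' character vector mapping covariate name to column name). A covariate whose
#' value is constant within every area (a single value per area) is detected
#' as static and broadcast.
#'
#' Any missing (area, period) cell, negative count, or non-positive population
#' is a hard error: the study panel is complete by construction and holes are
#' treated as data corruption, not as missingness to impute.
#'
#' @param path CSV file path (UTF-8, header row).
#' @param schema column-role mapping, see Details.
#' @param units optional named character vector of covariate units.
#' @return An [areal_panel()].
#' @export
read_panel <- function(path, schema, units = NULL) {
  need <- c("area", "period", "count", "population")
  if (!all(need %in% names(schema))) {
    stop("schema must name columns: ", paste(need, collapse = ", "))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  covmap <- schema$covariates
  if (is.null(names(covmap)) && length(covmap)) names(covmap) <- covmap
  cols <- c(unlist(schema[need]), unname(covmap))
  miss <- setdiff(cols, names(df))
  if (length(miss)) stop("columns not in file: ", paste(miss, collapse = ", "))

  area <- as.character(df[[schema$area]])
  period <- as.integer(df[[schema$period]])
  area_ids <- unique(area)
  periods <- sort(unique(period))

  key <- paste(area, period, sep = "\r")
  if (anyDuplicated(key)) {
    d <- strsplit(key[duplicated(key)][1], "\r")[[1]]
    stop("duplicate cell (", d[1], ",", d[2], ")")
  }
  full <- expand.grid(a = area_ids, p = periods, stringsAsFactors = FALSE)
  fkey <- paste(full$a, full$p, sep = "\r")
  hole <- setdiff(fkey, key)
  if (length(hole)) {
    h <- strsplit(hole[1], "\r")[[1]]
    stop("missing cell (", h[1], ",", h[2], ")")
  }

  idx <- match(fkey, key)  # row-major over (area, period) grid
  cell_mat <- function(col) {
    matrix(as.numeric(df[[col]][idx]), nrow = length(area_ids),
           dimnames = list(area_ids, periods))
  }
  covs <- list()
  for (nm in names(covmap)) {
    m <- cell_mat(covmap[[nm]])
    # static when every area carries a single value across periods
    if (ncol(m) > 1L && all(m == m[, 1L])) m <- m[, 1L]
    covs[[nm]] <- m
  }
  areal_panel(area_ids, periods, cell_mat(schema$count),
              cell_mat(schema$population), covs, units = units)
}

#' Write an areal panel to long-format CSV
#'
#' Inverse of [read_panel()]: one row per (area, period), covariates as
#' plain columns. `read_panel(write_panel(p))` reproduces `p` up to float
#' representation.
#'
#' @param panel an [areal_panel()].
#' @param path output CSV path.
#' @param schema column-role mapping as in [read_panel()]; defaults to
#'   canonical names.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path,
                        schema = list(area = "area", period = "period",
                                      count = "count", population = "population",
                                      covariates = names(panel$covariates))) {
  covmap <- schema$covariates
  if (is.null(names(covmap)) && length(covmap)) names(covmap) <- covmap
  n <- length(panel$area_ids); np <- length(panel$periods)
  df <- data.frame(
    a = rep(panel$area_ids, times = np),
    p = rep(panel$periods, each = n),
    y = as.vector(panel$counts),
    P = as.vector(panel$population),
    check.names = FALSE)
  names(df) <- c(schema$area, schema$period, schema$count, schema$population)
  for (nm in names(covmap)) df[[covmap[[nm]]]] <- as.vector(panel$covariates[[nm]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write result tables plus a JSON run manifest
#'
#' Each table becomes `<name>.csv` under `dir`; a single `manifest.json`
#' records the table names together with any metadata passed in `meta`
#' (model family, seed, DIC, ...). Values survive a write/read round trip to
#' at least 12 significant digits.
#'
#' @param tables named list of data frames (may be empty: manifest only).
#' @param dir output directory, created if absent.
#' @param meta named list of run metadata stored in the manifest.
#' @return character vector of files written, invisibly.
#' @export
write_summaries <- function(tables, dir, meta = list()) {
  if (length(tables)) {
    if (is.null(names(tables)) || any(names(tables) == "")) {
      stop("tables must be named")
    }
    if (anyDuplicated(names(tables))) {
      stop("duplicate table name: ",
           names(tables)[duplicated(names(tables))][1])
    }
  }
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    stop("cannot create output directory: ", dir)
  }
  files <- character(0)
  for (nm in names(tables)) {
    f <- file.path(dir, paste0(nm, ".csv"))
    df <- as.data.frame(tables[[nm]])
    num <- vapply(df, is.double, logical(1))
    df[num] <- lapply(df[num], function(x) formatC(x, digits = 15, format = "g"))
    utils::write.csv(df, f, row.names = FALSE, quote = FALSE)
    files <- c(files, f)
  }
  mf <- file.path(dir, "manifest.json")
  manifest <- c(list(tables = as.list(names(tables))), meta)
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(files, mf))
}

#' Read a model/MCMC run configuration file
#'
#' YAML or JSON file holding the model specification, hyperpriors, MCMC
#' settings and seed (see [run_pipeline()] for the recognised fields).
#'
#' @param path configuration file (`.yaml`/`.yml` or `.json`).
#' @return a named list.
#' @export
read_config <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}
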