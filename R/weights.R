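#' Spatial weights objects
#'
#' A neighbour graph over areas with optional row-standardised weights.
#' Constructed by [queen_adjacency()], [read_gal()] or [make_lattice()].
#'
#' @param ids character vector of area labels.
#' @param neighbors list (per area) of integer neighbour indices.
#' @param style `"binary"` or `"row_standardized"`.
#' @return An object of class `spatial_weights`: list with `n`, `ids`,
#'   `neighbors`, `weights`, `style`, `islands` (integer indices of areas
#'   with no neighbours) and `components` (integer component label per area).
#' @export
spatial_weights <- function(ids, neighbors, style = "binary") {
  ids <- as.character(ids)
  n <- length(ids)
  if (anyDuplicated(ids)) stop("duplicate area labels")
  if (length(neighbors) != n) stop("neighbors must have one entry per area")
  neighbors <- lapply(neighbors, function(x) sort(as.integer(x)))
  for (i in seq_len(n)) {
    nb <- neighbors[[i]]
    if (any(nb < 1L | nb > n)) stop("neighbor index out of range for area ", ids[i])
    if (any(nb == i)) stop("self-neighbor at area ", ids[i])
    for (j in nb) {
      if (!(i %in% neighbors[[j]])) {
        stop("asymmetric adjacency: ", ids[i], " lists ", ids[j],
             " but not vice versa")
      }
    }
  }
  style <- match.arg(style, c("binary", "row_standardized"))
  deg <- lengths(neighbors)
  weights <- lapply(seq_len(n), function(i) {
    if (deg[i] == 0L) numeric(0)
    else if (style == "binary") rep(1, deg[i]) else rep(1 / deg[i], deg[i])
  })
  structure(list(n = n, ids = ids, neighbors = neighbors, weights = weights,
                 style = style, islands = which(deg == 0L),
                 components = graph_components(neighbors)),
            class = "spatial_weights")
}

# connected-component labels by breadth-first search
graph_components <- function(neighbors) {
  n <- length(neighbors)
  comp <- integer(n)
  k <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    k <- k + 1L
    queue <- s
    comp[s] <- k
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      for (u in neighbors[[v]]) {
        if (comp[u] == 0L) { comp[u] <- k; queue <- c(queue, u) }
      }
    }
  }
  comp
}

#' @export
print.spatial_weights <- function(x, ...) {
  cat("Spatial weights:", x$n, "areas,",
      sum(lengths(x$neighbors)) / 2, "links,", x$style, "style\n")
  if (length(x$islands)) {
    cat("  islands:", paste(x$ids[x$islands], collapse = ", "), "\n")
  }
  cat("  connected components:", max(x$components), "\n")
  invisible(x)
}

#' Queen-contiguity adjacency from labelled polygons
#'
#' Two areas are first-order queen neighbours when their boundaries share at
#' least one point -- an edge or a single vertex both count. Detection snaps
#' all polygon vertices to a grid of `snap_tolerance` and intersects the
#' snapped point sets, which is robust to floating-point jitter in the
#' coordinates without requiring a geometry library.
#'
#' @param polygons named list, one entry per area; each entry is either a
#'   two-column coordinate matrix or a list of such matrices (rings /
#'   multipolygon parts). See [read_geojson_polygons()].
#' @param snap_tolerance snapping grid spacing in coordinate units.
#' @return A binary-style [spatial_weights()] object; areas touching no other
#'   area are flagged as islands.
#' @export
queen_adjacency <- function(polygons, snap_tolerance = 1e-8) {
  if (is.null(names(polygons)) || any(names(polygons) == "")) {
    stop("polygons must be a named list")
  }
  if (anyDuplicated(names(polygons))) stop("duplicate polygon labels")
  n <- length(polygons)
  vertex_keys <- lapply(polygons, function(p) {
    parts <- if (is.matrix(p)) list(p) else p
    xy <- do.call(rbind, lapply(parts, function(m) {
      m <- as.matrix(m)
      if (!is.numeric(m) || ncol(m) < 2L || nrow(m) == 0L) {
        stop("empty or malformed polygon geometry")
      }
      m[, 1:2, drop = FALSE]
    }))
    unique(paste(round(xy[, 1] / snap_tolerance),
                 round(xy[, 2] / snap_tolerance)))
  })
  # invert: vertex key -> polygons touching it
  owner <- rep(seq_len(n), lengths(vertex_keys))
  key <- unlist(vertex_keys, use.names = FALSE)
  touch <- split(owner, key)
  nb <- vector("list", n)
  for (i in seq_len(n)) nb[[i]] <- integer(0)
  for (g in touch) {
    if (length(g) > 1L) {
      for (i in g) nb[[i]] <- c(nb[[i]], g)
    }
  }
  nb <- lapply(seq_len(n), function(i) sort(setdiff(unique(nb[[i]]), i)))
  spatial_weights(names(polygons), nb, style = "binary")
}

#' Row-standardise a binary weights object
#'
#' Each neighbour weight becomes 1/deg(i); island rows stay empty and remain
#' flagged. Idempotent; the input object is not modified.
#'
#' @param w a [spatial_weights()] object.
#' @return A `spatial_weights` object with `style = "row_standardized"`.
#' @export
row_standardize <- function(w) {
  stopifnot(inherits(w, "spatial_weights"))
  spatial_weights(w$ids, w$neighbors, style = "row_standardized")
}

#' Read / write GAL neighbour files
#'
#' Plain-text contiguity lists: a header line with the number of areas, then
#' for each area a line `id k` followed by a line with its `k` neighbour ids.
#' Asymmetric files are rejected with the offending pair named.
#'
#' @param path GAL file path.
#' @return [read_gal()]: a binary [spatial_weights()] object.
#' @export
read_gal <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  n <- as.integer(toks[length(toks)])  # tolerate "0 n ..." style headers
  if (is.na(n) || n < 1L) stop("malformed GAL header")
  ids <- character(n); nbs <- vector("list", n)
  pos <- 2L
  for (k in seq_len(n)) {
    hd <- strsplit(trimws(lines[pos]), "\\s+")[[1]]
    ids[k] <- hd[1]
    deg <- as.integer(hd[2])
    if (is.na(deg)) stop("malformed GAL record for area ", hd[1])
    if (deg > 0L) {
      nbs[[k]] <- strsplit(trimws(lines[pos + 1L]), "\\s+")[[1]]
      if (length(nbs[[k]]) != deg) {
        stop("GAL record for ", ids[k], " promises ", deg, " neighbors, got ",
             length(nbs[[k]]))
      }
      pos <- pos + 2L
    } else {
      nbs[[k]] <- character(0)
      pos <- pos + 1L
    }
  }
  neighbors <- lapply(nbs, function(x) {
    idx <- match(x, ids)
    if (anyNA(idx)) stop("unknown neighbor id: ", x[is.na(idx)][1])
    idx
  })
  # symmetry check with a named error before construction
  for (i in seq_len(n)) {
    for (j in neighbors[[i]]) {
      if (!(i %in% neighbors[[j]])) {
        stop("asymmetric GAL file: ", ids[i], " lists ", ids[j],
             " but ", ids[j], " omits ", ids[i])
      }
    }
  }
  spatial_weights(ids, neighbors, style = "binary")
}

#' @rdname read_gal
#' @param w a [spatial_weights()] object.
#' @export
write_gal <- function(w, path) {
  stopifnot(inherits(w, "spatial_weights"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(w$n), con)
  for (i in seq_len(w$n)) {
    writeLines(paste(w$ids[i], length(w$neighbors[[i]])), con)
    if (length(w$neighbors[[i]])) {
      writeLines(paste(w$ids[w$neighbors[[i]]], collapse = " "), con)
    }
  }
  invisible(path)
}

#' Read labelled polygons from a GeoJSON FeatureCollection
#'
#' Accepts Polygon and MultiPolygon features; all ring coordinates are kept
#' (queen contiguity only needs the boundary point set).
#'
#' @param path GeoJSON file.
#' @param label property name holding the area label.
#' @return named list of coordinate matrices, suitable for
#'   [queen_adjacency()].
#' @export
read_geojson_polygons <- function(path, label = "id") {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection")
  out <- list()
  for (ft in gj$features) {
    lab <- ft$properties[[label]]
    if (is.null(lab)) stop("feature missing label property '", label, "'")
    geom <- ft$geometry
    rings <- switch(geom$type,
      Polygon = geom$coordinates,
      MultiPolygon = do.call(c, geom$coordinates),
      stop("unsupported geometry type: ", geom$type))
    mats <- lapply(rings, function(r) {
      do.call(rbind, lapply(r, function(pt) c(pt[[1]], pt[[2]])))
    })
    out[[as.character(lab)]] <- mats
  }
  out
}

#' Write lattice/test polygons to GeoJSON
#'
#' @param polygons named list as produced by [make_lattice()].
#' @param path output file.
#' @param label property name for the area label.
#' @return `path`, invisibly.
#' @export
write_geojson_polygons <- function(polygons, path, label = "id") {
  feats <- lapply(names(polygons), function(nm) {
    p <- polygons[[nm]]
    rings <- if (is.matrix(p)) list(p) else p
    coords <- lapply(rings, function(m) {
      lapply(seq_len(nrow(m)), function(i) as.numeric(m[i, 1:2]))
    })
    props <- stats::setNames(list(nm), label)
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon", coordinates = coords))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
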