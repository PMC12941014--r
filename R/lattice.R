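# Lattice construction: edge lists, grids, and queen/rook contiguity from
# GeoJSON polygons. Tract ids are sorted lexicographically at construction
# and that order is fixed for all downstream arrays.

#' Construct a TractLattice from tract ids and an undirected edge list
#'
#' @param tractIds character vector of unique tract identifiers.
#' @param edges two-column matrix or data.frame of tract-id pairs. Pairs are
#'   undirected; with \code{symmetrize = FALSE} every pair must be listed in
#'   both orders or an error is raised.
#' @param symmetrize treat single-direction pairs as undirected
#'   (default \code{TRUE}).
#' @return a \linkS4class{TractLattice}; a warning names any isolated
#'   tracts.
#' @export
TractLattice <- function(tractIds, edges = NULL, symmetrize = TRUE) {
  tractIds <- as.character(tractIds)
  if (anyDuplicated(tractIds))
    stop("duplicate tract ids: ",
         paste(unique(tractIds[duplicated(tractIds)]), collapse = ", "))
  tractIds <- sort(tractIds)
  n <- length(tractIds)
  if (is.null(edges) || NROW(edges) == 0) {
    A <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                              dims = c(n, n),
                              dimnames = list(tractIds, tractIds))
  } else {
    edges <- as.matrix(edges)
    if (ncol(edges) != 2) stop("edges must have two columns")
    src <- as.character(edges[, 1]); dst <- as.character(edges[, 2])
    unknown <- setdiff(c(src, dst), tractIds)
    if (length(unknown))
      stop("edge list references undeclared tract ids: ",
           paste(unique(unknown), collapse = ", "))
    if (any(src == dst))
      stop("self-neighbours are not allowed (edge ",
           src[match(TRUE, src == dst)], " -- itself)")
    i <- match(src, tractIds); j <- match(dst, tractIds)
    if (!symmetrize) {
      key <- paste(i, j); rkey <- paste(j, i)
      if (!all(rkey %in% key))
        stop("edge list is asymmetric; pass symmetrize = TRUE to treat ",
             "pairs as undirected")
    }
    ii <- c(i, j); jj <- c(j, i)
    A <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(n, n),
                              dimnames = list(tractIds, tractIds),
                              use.last.ij = TRUE)
    A@x[] <- 1
  }
  lat <- new("TractLattice", tractIds = tractIds,
             adjacency = methods::as(A, "generalMatrix"))
  iso <- isolatedTracts(lat)
  if (length(iso))
    warning("isolated tracts (no neighbours): ",
            paste(iso, collapse = ", "))
  lat
}

#' @rdname TractLattice-class
#' @return \code{isolatedTracts}: ids of tracts with no neighbours.
#' @export
isolatedTracts <- function(x) {
  m <- neighborCounts(x)
  names(m)[m == 0]
}

#' Mean of each tract's neighbours
#'
#' Computes the neighbourhood means that drive the intrinsic CAR
#' conditional distribution: each tract's value is replaced by the average
#' over its adjacent tracts. Isolated tracts get \code{NA}.
#'
#' @param x a \linkS4class{TractLattice}.
#' @param values numeric vector, one value per tract in lattice order.
#' @return numeric vector of neighbour means.
#' @export
neighborMeans <- function(x, values) {
  stopifnot(length(values) == nTracts(x))
  m <- as.numeric(Matrix::rowSums(x@adjacency))
  out <- as.numeric(x@adjacency %*% values) / m
  out[m == 0] <- NA_real_
  out
}

#' Regular grid lattice with rook or queen contiguity
#'
#' Stand-in for a real tract map in simulations: a rows-by-cols grid where
#' interior cells have 4 (rook) or 8 (queen) neighbours.
#'
#' @param rows,cols grid dimensions (>= 1).
#' @param contiguity \code{"rook"} (shared edge) or \code{"queen"} (shared
#'   edge or corner).
#' @return a \linkS4class{TractLattice} with ids \code{t001, t002, ...} in
#'   row-major order.
#' @export
makeGridLattice <- function(rows, cols, contiguity = c("rook", "queen")) {
  contiguity <- match.arg(contiguity)
  stopifnot(rows >= 1, cols >= 1)
  n <- rows * cols
  wid <- max(3L, nchar(as.character(n)))
  ids <- sprintf("t%0*d", wid, seq_len(n))
  idx <- function(r, c) (r - 1L) * cols + c
  src <- integer(); dst <- integer()
  for (r in seq_len(rows)) for (c in seq_len(cols)) {
    if (c < cols) { src <- c(src, idx(r, c)); dst <- c(dst, idx(r, c + 1L)) }
    if (r < rows) { src <- c(src, idx(r, c)); dst <- c(dst, idx(r + 1L, c)) }
    if (contiguity == "queen" && r < rows) {
      if (c < cols) { src <- c(src, idx(r, c)); dst <- c(dst, idx(r + 1L, c + 1L)) }
      if (c > 1L)   { src <- c(src, idx(r, c)); dst <- c(dst, idx(r + 1L, c - 1L)) }
    }
  }
  if (n == 1L)
    return(suppressWarnings(TractLattice(ids)))
  TractLattice(ids, cbind(ids[src], ids[dst]))
}

#' Read an areal adjacency structure
#'
#' Two sources are supported: an edge-list CSV with header \code{src,dst}
#' (undirected pairs), or a GeoJSON FeatureCollection of polygons from which
#' contiguity is derived by shared-vertex matching (queen: at least one
#' shared vertex; rook: at least two, i.e. a shared edge segment).
#'
#' @param source path to the CSV or GeoJSON file.
#' @param mode \code{"edges"}, \code{"queen"} or \code{"rook"}; \code{"auto"}
#'   picks by file content.
#' @param tractIds for edge-list input, the full id universe (so isolated
#'   tracts can be represented); defaults to the ids seen in the edges.
#' @param idProperty GeoJSON feature property holding the tract id.
#' @param symmetrize see \code{\link{TractLattice}}.
#' @return a \linkS4class{TractLattice}; isolated tracts raise a warning.
#' @export
readAdjacency <- function(source, mode = c("auto", "edges", "queen", "rook"),
                          tractIds = NULL, idProperty = "tract_id",
                          symmetrize = TRUE) {
  mode <- match.arg(mode)
  firstChar <- substr(trimws(readChar(source, 1024L)), 1, 1)
  isGeo <- firstChar == "{"
  if (mode == "auto") mode <- if (isGeo) "queen" else "edges"
  if (mode == "edges") {
    df <- utils::read.csv(source, colClasses = "character")
    if (!all(c("src", "dst") %in% names(df)))
      stop("edge-list CSV needs columns 'src' and 'dst'")
    ids <- if (is.null(tractIds)) sort(unique(c(df$src, df$dst)))
           else as.character(tractIds)
    return(TractLattice(ids, df[, c("src", "dst")], symmetrize = symmetrize))
  }
  gj <- jsonlite::fromJSON(source, simplifyVector = FALSE)
  if (is.null(gj$features)) stop("GeoJSON FeatureCollection expected")
  polys <- lapply(gj$features, function(f) {
    id <- f$properties[[idProperty]]
    if (is.null(id)) stop("feature lacks id property '", idProperty, "'")
    coords <- f$geometry$coordinates
    if (identical(f$geometry$type, "MultiPolygon"))
      rings <- unlist(coords, recursive = FALSE)
    else rings <- coords
    pts <- unique(do.call(rbind, lapply(unlist(rings, recursive = FALSE),
                                        function(p) c(p[[1]], p[[2]]))))
    list(id = as.character(id),
         keys = unique(paste(signif(pts[, 1], 12), signif(pts[, 2], 12))))
  })
  ids <- vapply(polys, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicate tract ids in GeoJSON")
  minShared <- if (mode == "queen") 1L else 2L
  src <- character(); dst <- character()
  for (a in seq_along(polys)) for (b in seq_len(a - 1L)) {
    if (sum(polys[[a]]$keys %in% polys[[b]]$keys) >= minShared) {
      src <- c(src, ids[a]); dst <- c(dst, ids[b])
    }
  }
  TractLattice(ids, if (length(src)) cbind(src, dst) else NULL)
}

#' Write an edge-list CSV for a lattice
#'
#' @param x a \linkS4class{TractLattice}.
#' @param file output path; each undirected edge is written once.
#' @export
writeAdjacency <- function(x, file) {
  A <- as.matrix(adjacencyMatrix(x))
  tri <- which(A != 0, arr.ind = TRUE)
  tri <- tri[tri[, 1] < tri[, 2], , drop = FALSE]
  utils::write.csv(data.frame(src = tractIds(x)[tri[, 1]],
                              dst = tractIds(x)[tri[, 2]]),
                   file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
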