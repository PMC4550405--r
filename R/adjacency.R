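## Tract adjacency construction and GeoBUGS interoperability.

#' Build a per-city tract adjacency structure
#'
#' Edges are given on tract labels; they are mapped to within-city indices
#' using the tract order of \code{data}, symmetrised and deduplicated.
#' Isolated tracts are allowed (their intrinsic-CAR contribution is zero)
#' but are reported with a warning, since census tracts within a city are
#' normally contiguous.
#'
#' @param edges data.frame with columns \code{city}, \code{tract_a},
#'   \code{tract_b} (tract labels).
#' @param data the \code{\link{TractData-class}} the graph refers to.
#' @return a \code{\link{TractAdjacency-class}} object.
#' @export
buildAdjacency <- function(edges, data) {
  stopifnot(is(data, "TractData"))
  need <- c("city", "tract_a", "tract_b")
  miss <- setdiff(need, names(edges))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  ids <- data@cityIds
  tr <- data@tracts
  labels <- lapply(ids, function(cid) tr$tract[tr$city == cid])
  names(labels) <- ids
  nT <- setNames(vapply(labels, length, 0L), ids)

  e <- data.frame(city = as.character(edges$city),
                  a = as.character(edges$tract_a),
                  b = as.character(edges$tract_b), stringsAsFactors = FALSE)
  unknownCity <- !e$city %in% ids
  if (any(unknownCity)) stop("edge references unknown city: ", e$city[which(unknownCity)[1L]])
  from <- to <- integer(nrow(e))
  for (i in seq_len(nrow(e))) {
    lab <- labels[[e$city[i]]]
    fi <- match(e$a[i], lab); ti <- match(e$b[i], lab)
    if (is.na(fi) || is.na(ti))
      stop("edge references tract not in city '", e$city[i], "': ",
           if (is.na(fi)) e$a[i] else e$b[i],
           " (cross-city edges are not allowed)")
    from[i] <- fi; to[i] <- ti
  }
  if (any(from == to))
    stop("self-loop edge at row ", which(from == to)[1L])
  lo <- pmin(from, to); hi <- pmax(from, to)
  key <- paste(e$city, lo, hi)
  keep <- !duplicated(key)
  out <- data.frame(city = e$city[keep], from = lo[keep], to = hi[keep],
                    stringsAsFactors = FALSE)
  adj <- new("TractAdjacency", cityIds = ids, nTracts = nT,
             tractLabels = labels, edges = out)
  iso <- isolatedTracts(adj)
  if (nrow(iso))
    warning(nrow(iso), " isolated tract(s) with no neighbours: ",
            paste(utils::head(paste0(iso$city, ":", iso$tract), 5L), collapse = ", "),
            if (nrow(iso) > 5L) ", ...")
  adj
}

#' Read / write an edge-list CSV (city,tract_a,tract_b)
#' @param path CSV file
#' @param data a TractData
#' @export
readAdjacencyEdges <- function(path, data) {
  buildAdjacency(utils::read.csv(path, stringsAsFactors = FALSE), data)
}

#' @param x a TractAdjacency
#' @rdname readAdjacencyEdges
#' @export
writeAdjacencyEdges <- function(x, path) {
  e <- x@edges
  out <- data.frame(city = e$city,
                    tract_a = vapply(seq_len(nrow(e)), function(i)
                      x@tractLabels[[e$city[i]]][e$from[i]], ""),
                    tract_b = vapply(seq_len(nrow(e)), function(i)
                      x@tractLabels[[e$city[i]]][e$to[i]], ""))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
}

#' Read a GeoBUGS-style adjacency list for one city
#'
#' Parses the \code{num}/\code{adj} vector format used by WinBUGS/GeoBUGS
#' map tools: \code{num} gives the neighbour count of each area in order,
#' \code{adj} the concatenated neighbour indices.  The file may write the
#' vectors as \code{num = c(...)} / \code{adj = c(...)} across any number
#' of lines.
#'
#' @param path text file containing num and adj vectors.
#' @param city city label the areas belong to.
#' @param data the TractData; the city's tracts (in order) are matched to
#'   areas 1..n.
#' @return a \code{\link{TractAdjacency-class}} covering all cities of
#'   \code{data}, with edges only for \code{city}.
#' @export
readGeoBUGSAdjacency <- function(path, city, data) {
  txt <- paste(readLines(path, warn = FALSE), collapse = " ")
  grab <- function(name) {
    m <- regmatches(txt, regexec(paste0(name, "\\s*=\\s*c\\(([^)]*)\\)"), txt))[[1L]]
    if (length(m) < 2L) stop("could not find '", name, " = c(...)' in ", path)
    toks <- strsplit(m[2L], "[,[:space:]]+")[[1L]]
    as.integer(toks[nzchar(toks)])
  }
  num <- grab("num"); adj <- grab("adj")
  if (sum(num) != length(adj))
    stop("GeoBUGS file inconsistent: sum(num) != length(adj)")
  n <- length(num)
  lab <- data@tracts$tract[data@tracts$city == city]
  if (length(lab) != n)
    stop("GeoBUGS file has ", n, " areas but city '", city, "' has ",
         length(lab), " tracts")
  ends <- cumsum(num)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  rows <- list()
  for (i in seq_len(n)) {
    if (num[i] == 0L) next
    nb <- adj[starts[i]:ends[i]]
    rows[[length(rows) + 1L]] <- data.frame(city = city,
                                            tract_a = lab[i], tract_b = lab[nb])
  }
  edges <- if (length(rows)) do.call(rbind, rows)
           else data.frame(city = character(), tract_a = character(),
                           tract_b = character())
  buildAdjacency(edges, data)
}

## Connected components of one city's graph (1-based labels per tract).
## Isolated tracts are singleton components.
graphComponents <- function(n, from, to) {
  comp <- integer(n)
  nbr <- vector("list", n)
  for (i in seq_along(from)) {
    nbr[[from[i]]] <- c(nbr[[from[i]]], to[i])
    nbr[[to[i]]] <- c(nbr[[to[i]]], from[i])
  }
  k <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    k <- k + 1L
    queue <- s
    comp[s] <- k
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      for (w in nbr[[v]]) if (comp[w] == 0L) { comp[w] <- k; queue <- c(queue, w) }
    }
  }
  comp
}

## Per-city component labels and counts for a TractAdjacency.
cityComponents <- function(adjacency, city) {
  j <- match(city, adjacency@cityIds)
  n <- adjacency@nTracts[j]
  e <- adjacency@edges[adjacency@edges$city == city, , drop = FALSE]
  graphComponents(n, e$from, e$to)
}
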