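## City coordinates and intercity distance matrices.  All distances are in
## km so that the effective range of the decay parameter is directly
## interpretable.

#' Construct a CityGeo from city coordinates
#'
#' @param df data.frame with columns \code{city_id}, \code{x}, \code{y}.
#'   With \code{crs = "projected_km"} the coordinates are planar km and
#'   distances are Euclidean; with \code{crs = "lonlat"} they are
#'   degrees longitude/latitude and distances are haversine great-circle
#'   distances in km.
#' @param crs coordinate flavour, \code{"projected_km"} or \code{"lonlat"}.
#' @return a \code{\link{CityGeo-class}} with its distance matrix filled in.
#' @export
cityGeo <- function(df, crs = c("projected_km", "lonlat")) {
  crs <- match.arg(crs)
  need <- c("city_id", "x", "y")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  ids <- as.character(df$city_id)
  if (anyDuplicated(ids)) stop("duplicated city_id")
  xy <- cbind(x = as.numeric(df$x), y = as.numeric(df$y))
  rownames(xy) <- ids
  D <- distanceMatrix(xy, metric = if (crs == "lonlat") "haversine" else "euclidean_km")
  new("CityGeo", cityIds = ids, coords = xy, crs = crs, D = D)
}

#' Read city coordinates from CSV
#' @param path CSV with header city_id,x,y
#' @param crs as in \code{\link{cityGeo}}
#' @export
readCityCoords <- function(path, crs = c("projected_km", "lonlat")) {
  cityGeo(utils::read.csv(path, stringsAsFactors = FALSE), crs = match.arg(crs))
}

#' Intercity distance matrix
#'
#' @param coords numeric matrix (J x 2) of city coordinates, or a
#'   \code{\link{CityGeo-class}} (whose stored matrix is returned).
#' @param metric \code{"euclidean_km"} for planar km coordinates or
#'   \code{"haversine"} for lon/lat degrees (great-circle km, via
#'   \pkg{geosphere}).
#' @return symmetric J x J matrix, km, zero diagonal, positive off-diagonal.
#' @export
distanceMatrix <- function(coords, metric = c("euclidean_km", "haversine")) {
  if (is(coords, "CityGeo")) return(coords@D)
  metric <- match.arg(metric)
  if (!is.matrix(coords) || ncol(coords) != 2L)
    stop("coords must be a J x 2 matrix")
  J <- nrow(coords)
  if (J < 2L) stop("need at least 2 cities")
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  if (metric == "euclidean_km") {
    D <- as.matrix(stats::dist(coords))
  } else {
    D <- matrix(0, J, J)
    for (i in seq_len(J - 1L)) {
      d <- geosphere::distHaversine(coords[i, ], coords[(i + 1L):J, , drop = FALSE]) / 1000
      D[i, (i + 1L):J] <- d
      D[(i + 1L):J, i] <- d
    }
  }
  dimnames(D) <- list(rownames(coords), rownames(coords))
  if (any(D[upper.tri(D)] <= 0))
    stop("two cities share identical coordinates (zero distance)")
  D
}
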