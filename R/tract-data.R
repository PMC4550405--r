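## Tract table construction, file ingestion and indirect standardization.

#' Construct a TractData object from a data.frame
#'
#' Rows are validated and reordered by city (order of first appearance,
#' which defines the model's city order j = 1..J) then by tract label order
#' of appearance within city.
#'
#' @param df data.frame with columns city, tract, observed, expected,
#'   covariate (after renaming via \code{columns}).
#' @param columns optional named character vector mapping internal names to
#'   the data.frame's column names, e.g.
#'   \code{c(observed = "O", expected = "E")}.
#' @return a validated \code{\link{TractData-class}} object.
#' @export
tractData <- function(df, columns = NULL) {
  need <- c("city", "tract", "observed", "expected", "covariate")
  if (!is.null(columns)) {
    for (nm in names(columns)) {
      if (!columns[[nm]] %in% names(df))
        stop("mapped column '", columns[[nm]], "' (for ", nm, ") not found")
      names(df)[names(df) == columns[[nm]]] <- nm
    }
  }
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  df <- df[, need]
  df$city <- factor(as.character(df$city), levels = unique(as.character(df$city)))
  df$tract <- as.character(df$tract)
  bad <- which(!is.finite(df$expected) | df$expected <= 0)
  if (length(bad))
    stop("expected count must be > 0: violated at row ", bad[1L])
  # stable sort preserving first-appearance order within city
  ord <- order(as.integer(df$city))
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  new("TractData", tracts = df, cityIds = levels(df$city))
}

#' Read a tract table from a delimited text file
#'
#' @param path CSV file with a header row.
#' @param columns column-name mapping as in \code{\link{tractData}}.
#' @param sep field separator (default comma).
#' @return a \code{\link{TractData-class}} object.
#' @export
readTractTable <- function(path, columns = NULL, sep = ",") {
  df <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE)
  tractData(df, columns = columns)
}

#' Write a tract table as CSV
#' @param x a TractData
#' @param path output file
#' @export
writeTractTable <- function(x, path) {
  utils::write.csv(x@tracts, path, row.names = FALSE, quote = FALSE)
}

#' Indirect standardization of expected counts
#'
#' Computes tract-level expected counts E_ij from age-stratified deaths and
#' population tables, using the pooled study population as the internal
#' reference: the reference rate for age group a is
#' rate_a = sum(deaths_a) / sum(population_a) over all tracts, and
#' E_ij = sum_a rate_a * population_ija.  With this internal reference the
#' expected counts conserve the total, sum(E) = sum(O).
#'
#' @param strata data.frame with columns \code{city}, \code{tract},
#'   \code{age} (age-group label), \code{deaths}, \code{population}.
#' @return data.frame (city, tract, expected), one row per tract, in the
#'   order of first appearance.
#' @export
indirectStandardization <- function(strata) {
  need <- c("city", "tract", "age", "deaths", "population")
  miss <- setdiff(need, names(strata))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (any(strata$deaths < 0)) stop("deaths must be nonnegative")
  if (any(strata$population < 0)) stop("population must be nonnegative")
  ages <- unique(strata$age)
  pooledD <- vapply(ages, function(a) sum(strata$deaths[strata$age == a]), 0)
  pooledP <- vapply(ages, function(a) sum(strata$population[strata$age == a]), 0)
  bad <- pooledP == 0 & pooledD > 0
  if (any(bad))
    stop("age group(s) with deaths but zero pooled population: ",
         paste(ages[bad], collapse = ", "))
  zero <- pooledP == 0
  if (any(zero))
    warning("age group(s) with zero pooled population: rate set to 0 for ",
            paste(ages[zero], collapse = ", "))
  rate <- ifelse(pooledP > 0, pooledD / pooledP, 0)
  names(rate) <- ages
  key <- paste(strata$city, strata$tract, sep = "\r")
  ukey <- unique(key)
  E <- vapply(ukey, function(k) {
    rows <- key == k
    sum(rate[as.character(strata$age[rows])] * strata$population[rows])
  }, 0)
  first <- match(ukey, key)
  data.frame(city = strata$city[first], tract = strata$tract[first],
             expected = unname(E), stringsAsFactors = FALSE)
}

## Compact fingerprint of the data a model was fit to; used to refuse DIC
## comparison across different datasets.
dataFingerprint <- function(data) {
  tr <- data@tracts
  paste(nrow(tr), length(data@cityIds), sum(tr$observed),
        format(sum(tr$expected), digits = 12),
        format(sum(tr$covariate), digits = 12),
        format(sum(tr$expected * tr$covariate), digits = 12), sep = "|")
}
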