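# Weighted spatial tessellation: the discrete set of locations an agent can
# visit, each with a relevance weight (a popularity proxy such as a call count
# or a population density), plus the derived gravity origin-destination matrix.

#' Construct a weighted spatial tessellation
#'
#' A weighted spatial tessellation is the set of discrete locations available
#' to simulated agents. Each location is identified by the coordinates of its
#' centroid and carries a positive `relevance` weight measuring its popularity
#' (e.g. calls served by a phone tower, stops in a census cell, or population
#' density when no activity data are available).
#'
#' @param locations A data frame with columns `location_id`, `lat`, `lon`,
#'   `relevance`. Row order defines the location indexing used by all derived
#'   matrices.
#' @return An object of class `tessellation`: the validated data frame with
#'   `location_id` coerced to character.
#' @examples
#' tess <- tessellation(data.frame(
#'   location_id = c("a", "b"), lat = c(0, 0), lon = c(0, 1),
#'   relevance = c(1, 3)
#' ))
#' @export
tessellation <- function(locations) {
  stopifnot(is.data.frame(locations))
  required <- c("location_id", "lat", "lon", "relevance")
  missing <- setdiff(required, names(locations))
  if (length(missing) > 0L) {
    stop("tessellation is missing column(s): ", paste(missing, collapse = ", "))
  }
  locations <- as.data.frame(locations)[, required]
  locations$location_id <- as.character(locations$location_id)
  if (nrow(locations) < 2L) {
    stop("a tessellation needs at least 2 locations")
  }
  if (anyDuplicated(locations$location_id)) {
    stop("duplicate location ids: ",
         paste(unique(locations$location_id[duplicated(locations$location_id)]),
               collapse = ", "))
  }
  if (!all(is.finite(locations$lat)) || !all(is.finite(locations$lon))) {
    stop("non-finite coordinates")
  }
  if (any(locations$lat < -90 | locations$lat > 90)) stop("latitude out of [-90, 90]")
  if (any(locations$lon < -180 | locations$lon > 180)) stop("longitude out of [-180, 180]")
  if (any(!is.finite(locations$relevance)) || any(locations$relevance <= 0)) {
    stop("relevances must be positive")
  }
  dup <- duplicated(locations[, c("lat", "lon")])
  if (any(dup)) {
    first <- which(!duplicated(locations[, c("lat", "lon")]) &
                     paste(locations$lat, locations$lon) %in%
                     paste(locations$lat[dup], locations$lon[dup]))
    stop("coincident coordinates for locations: ",
         paste(locations$location_id[c(first[1L], which(dup)[1L])], collapse = " and "))
  }
  rownames(locations) <- NULL
  class(locations) <- c("tessellation", "data.frame")
  locations
}

#' @export
print.tessellation <- function(x, ...) {
  cat("Weighted spatial tessellation:", nrow(x), "locations\n")
  cat("  relevance range:", format(min(x$relevance)), "-",
      format(max(x$relevance)), "\n")
  invisible(x)
}

#' Great-circle distance between points, in kilometres
#'
#' Haversine distance on a sphere of radius 6371 km. Arguments are recycled,
#' so a single point against a vector of points is allowed.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees.
#' @return Distance(s) in kilometres.
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  n <- max(length(lat1), length(lat2))
  p1 <- cbind(rep_len(lon1, n), rep_len(lat1, n))
  p2 <- cbind(rep_len(lon2, n), rep_len(lat2, n))
  geosphere::distHaversine(p1, p2, r = 6371)
}

#' Pairwise distance matrix of a tessellation
#'
#' @param tess A [tessellation()].
#' @return Symmetric matrix of great-circle distances in kilometres, with
#'   location ids as dimnames.
#' @export
distance_matrix <- function(tess) {
  stopifnot(inherits(tess, "tessellation"))
  d <- geosphere::distm(cbind(tess$lon, tess$lat),
                        fun = geosphere::distHaversine) / 1000 * (6371 / 6378.137)
  # distm has no radius argument; rescale from the WGS84 default to R = 6371 km
  dimnames(d) <- list(tess$location_id, tess$location_id)
  d
}

#' Gravity origin-destination matrix
#'
#' Trip probabilities between all ordered location pairs, computed with a
#' gravity kernel: `p_ij` is proportional to `r_i * r_j / d_ij^2`, where `r`
#' is location relevance and `d_ij` the great-circle distance. The diagonal is
#' zero and the whole matrix is normalized to sum to one. Probabilities are
#' invariant under uniform rescaling of all relevances.
#'
#' @param tess A [tessellation()].
#' @return An `od_matrix`: an m x m probability matrix with location ids as
#'   dimnames and the distance matrix attached as attribute `"distances"`.
#' @export
build_od_matrix <- function(tess) {
  stopifnot(inherits(tess, "tessellation"))
  d <- distance_matrix(tess)
  off <- d[upper.tri(d)]
  if (any(off == 0)) {
    idx <- which(d == 0 & upper.tri(d), arr.ind = TRUE)[1L, ]
    stop("zero distance between locations ", tess$location_id[idx[1L]],
         " and ", tess$location_id[idx[2L]],
         ": coincident coordinates give an unbounded gravity weight")
  }
  r <- tess$relevance
  w <- outer(r, r) / d^2
  diag(w) <- 0
  p <- w / sum(w)
  dimnames(p) <- list(tess$location_id, tess$location_id)
  attr(p, "distances") <- d
  class(p) <- c("od_matrix", class(p))
  p
}

#' @export
print.od_matrix <- function(x, ...) {
  cat("Gravity OD matrix over", nrow(x), "locations (entries sum to 1)\n")
  invisible(x)
}

#' Sample a location proportionally to relevance
#'
#' Draws one location with probability `r_j / sum(r)`. Used for home
#' assignment: the more relevant a location, the more likely it hosts an
#' agent's home.
#'
#' @param tess A [tessellation()].
#' @return A single `location_id`.
#' @export
sample_by_relevance <- function(tess) {
  stopifnot(inherits(tess, "tessellation"))
  if (nrow(tess) == 1L) return(tess$location_id)
  sample(tess$location_id, 1L, prob = tess$relevance)
}

#' Read / write a tessellation as CSV
#'
#' The CSV dialect has a header `location_id,lat,lon,relevance`. A GeoJSON
#' FeatureCollection of Point features with a `relevance` property is also
#' accepted by `read_tessellation()` (file extension `.geojson`/`.json`, or
#' `format = "geojson"`).
#'
#' @param path File path.
#' @param format `"csv"`, `"geojson"`, or `"auto"` (by extension).
#' @return `read_tessellation()` returns a [tessellation()];
#'   `write_tessellation()` returns `path` invisibly.
#' @export
read_tessellation <- function(path, format = c("auto", "csv", "geojson")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(geo)?json$", path, ignore.case = TRUE)) "geojson" else "csv"
  }
  if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
  } else {
    gj <- jsonlite::read_json(path, simplifyVector = FALSE)
    if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection: ", path)
    rows <- lapply(gj$features, function(f) {
      coords <- f$geometry$coordinates
      data.frame(location_id = as.character(f$properties$location_id),
                 lat = as.numeric(coords[[2L]]), lon = as.numeric(coords[[1L]]),
                 relevance = as.numeric(f$properties$relevance),
                 stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
  }
  tessellation(df)
}

#' @rdname read_tessellation
#' @param tess A [tessellation()] to write.
#' @export
write_tessellation <- function(tess, path, format = c("auto", "csv", "geojson")) {
  stopifnot(inherits(tess, "tessellation"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(geo)?json$", path, ignore.case = TRUE)) "geojson" else "csv"
  }
  if (format == "csv") {
    utils::write.csv(as.data.frame(tess), path, row.names = FALSE, quote = FALSE)
  } else {
    features <- lapply(seq_len(nrow(tess)), function(i) {
      list(type = "Feature",
           geometry = list(type = "Point",
                           coordinates = c(tess$lon[i], tess$lat[i])),
           properties = list(location_id = tess$location_id[i],
                             relevance = tess$relevance[i]))
    })
    jsonlite::write_json(list(type = "FeatureCollection", features = features),
                         path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
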