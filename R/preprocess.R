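# Readers, writers and cleaning procedures for raw location records:
# CDR-like rows (timestamp, user, serving location) and GPS ping streams
# that are segmented into trips and mapped onto tessellation cells.

parse_timestamps <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  suppressWarnings(num <- as.numeric(x))
  if (!anyNA(num)) return(num)
  ts <- as.POSIXct(x, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                                  "%Y/%m/%d %H:%M", "%Y-%m-%d %H:%M",
                                  "%Y-%m-%d"))
  if (anyNA(ts)) stop("unparseable timestamp(s), e.g. ", x[which(is.na(ts))[1L]])
  as.numeric(ts)
}

#' Read / write CDR-like records
#'
#' CSV with header `timestamp,user_id,location_id`; timestamps may be epoch
#' seconds or ISO-8601 strings and are normalized to epoch seconds. Records
#' are returned ordered by user then time.
#'
#' @param path File path.
#' @return `read_cdr()` returns a data frame
#'   `timestamp, user_id, location_id`.
#' @export
read_cdr <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("timestamp", "user_id", "location_id")
  if (!all(required %in% names(df))) {
    stop("CDR file must have columns ", paste(required, collapse = ", "))
  }
  df$timestamp <- parse_timestamps(df$timestamp)
  df$user_id <- as.character(df$user_id)
  df$location_id <- as.character(df$location_id)
  df[order(df$user_id, df$timestamp), required]
}

#' @rdname read_cdr
#' @param records CDR data frame to write.
#' @export
write_cdr <- function(records, path) {
  utils::write.csv(records[, c("timestamp", "user_id", "location_id")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Filter CDR users for reliable statistics
#'
#' Per-user cleaning applied in this order: (1) locations accounting for a
#' fraction `<= location_min_fraction` of the user's records are dropped
#' (noise towers); (2) users left with a single location are dropped
#' (no observable mobility); (3) users whose overall record rate over the
#' dataset observation span is below `min_rate_per_hour` are dropped
#' (too sparse to abstract). The observation span is the interval between
#' the first and last record of the whole dataset. The filter is idempotent.
#'
#' @param records CDR data frame (`timestamp, user_id, location_id`).
#' @param location_min_fraction Visitation-fraction threshold below or at
#'   which a location is discarded (default 0.005).
#' @param min_rate_per_hour Minimum records per hour (default 0.5).
#' @return The retained records, with the retained user ids in attribute
#'   `"users"`.
#' @export
filter_cdr_users <- function(records, location_min_fraction = 0.005,
                             min_rate_per_hour = 0.5) {
  stopifnot(nrow(records) >= 1L)
  span_hours <- (max(records$timestamp) - min(records$timestamp)) / 3600
  span_hours <- max(span_hours, 1e-9)
  keep <- vector("list", 0L)
  for (u in unique(records$user_id)) {
    rec <- records[records$user_id == u, ]
    cnt <- table(rec$location_id)
    frac <- cnt / sum(cnt)
    good_locs <- names(frac)[frac > location_min_fraction]
    rec <- rec[rec$location_id %in% good_locs, ]
    if (length(unique(rec$location_id)) < 2L) next
    if (nrow(rec) / span_hours < min_rate_per_hour) next
    keep[[u]] <- rec
  }
  out <- if (length(keep) > 0L) do.call(rbind, keep) else records[0L, ]
  rownames(out) <- NULL
  attr(out, "users") <- names(keep)
  out
}

#' Read GPS ping streams
#'
#' CSV with header `timestamp,vehicle_id,lat,lon`; pings are returned
#' time-ordered within vehicle.
#'
#' @param path File path.
#' @return Data frame `timestamp, vehicle_id, lat, lon`.
#' @export
read_gps <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("timestamp", "vehicle_id", "lat", "lon")
  if (!all(required %in% names(df))) {
    stop("GPS file must have columns ", paste(required, collapse = ", "))
  }
  df$timestamp <- parse_timestamps(df$timestamp)
  df$vehicle_id <- as.character(df$vehicle_id)
  df[order(df$vehicle_id, df$timestamp), required]
}

#' Nearest-centroid cell lookup
#'
#' Returns a function mapping coordinate vectors to the `location_id` of the
#' nearest tessellation centroid - the default cell assignment for GPS stops
#' when no polygon layer is available.
#'
#' @param tess A [tessellation()].
#' @return `function(lat, lon) -> location_id` (vectorized).
#' @export
nearest_cell_lookup <- function(tess) {
  stopifnot(inherits(tess, "tessellation"))
  function(lat, lon) {
    vapply(seq_along(lat), function(i) {
      d <- haversine_km(lat[i], lon[i], tess$lat, tess$lon)
      tess$location_id[which.min(d)]
    }, "")
  }
}

#' Segment a vehicle's GPS stream into trips and stops
#'
#' The device logs no points while the vehicle is stopped, so a gap between
#' consecutive pings longer than `stop_minutes` splits the stream into two
#' trips: the observation before the gap ends a trip and the one after it
#' starts the next. Each trip contributes its origin and its destination
#' stop, mapped to a cell id by `cell_lookup`. The result has the same shape
#' as CDR records and feeds [abstractify()] directly.
#'
#' @param pings Data frame `timestamp, vehicle_id, lat, lon` for one
#'   vehicle, time-ordered.
#' @param cell_lookup `function(lat, lon) -> location_id`, e.g. from
#'   [nearest_cell_lookup()]; may return `NA` for unmappable points, which
#'   are dropped (count reported in attribute `"dropped"`).
#' @param stop_minutes Stop-duration threshold in minutes (default 20).
#' @return Data frame `timestamp, user_id, location_id` of trip endpoints,
#'   with the trip count in attribute `"n_trips"`.
#' @export
segment_gps_trips <- function(pings, cell_lookup, stop_minutes = 20) {
  stopifnot(nrow(pings) >= 1L, length(unique(pings$vehicle_id)) == 1L)
  ts <- as.numeric(pings$timestamp)
  if (is.unsorted(ts)) stop("pings must be time-ordered")
  gap <- diff(ts) > stop_minutes * 60
  trip_id <- cumsum(c(0L, gap))
  first <- !duplicated(trip_id)
  last <- !duplicated(trip_id, fromLast = TRUE)
  endpoint <- first | last
  ep <- pings[endpoint, ]
  ids <- cell_lookup(ep$lat, ep$lon)
  dropped <- sum(is.na(ids))
  out <- data.frame(timestamp = ep$timestamp,
                    user_id = ep$vehicle_id,
                    location_id = ids,
                    stringsAsFactors = FALSE)
  out <- out[!is.na(out$location_id), ]
  rownames(out) <- NULL
  attr(out, "n_trips") <- max(trip_id) + 1L
  attr(out, "dropped") <- dropped
  out
}
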