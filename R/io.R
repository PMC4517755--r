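# Flat-file interfaces: survey CSV schemas, a planar track/waypoint CSV
# dialect, and GPX 1.1 for tracks and timestamped bait-plot waypoints.

chewcard_cols <- c("card_id", "line_id", "block_id", "session",
                   "possum", "rat", "other", "nights")
trap_cols <- c("trap_id", "line_id", "block_id", "night", "outcome")

#' Read and write monitoring survey CSV files
#'
#' Chewcard files have columns
#' `card_id,line_id,block_id,session,possum,rat,other,nights` with 0/1
#' species interference flags; trap files have
#' `trap_id,line_id,block_id,night,outcome`. Reading validates the schema.
#'
#' @param records a survey data frame (extra columns are dropped on
#'   write).
#' @param path file path.
#' @return The records (invisibly for writers).
#' @export
write_chewcards_csv <- function(records, path) {
  missing_cols <- setdiff(chewcard_cols, names(records))
  if (length(missing_cols) > 0)
    stop("records lack columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  write.csv(records[chewcard_cols], path, row.names = FALSE, quote = FALSE)
  invisible(records)
}

#' @rdname write_chewcards_csv
#' @export
read_chewcards_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(chewcard_cols, names(d))
  if (length(missing_cols) > 0)
    stop(path, " lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  d
}

#' @rdname write_chewcards_csv
#' @export
write_traps_csv <- function(records, path) {
  missing_cols <- setdiff(trap_cols, names(records))
  if (length(missing_cols) > 0)
    stop("records lack columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  write.csv(records[trap_cols], path, row.names = FALSE, quote = FALSE)
  invisible(records)
}

#' @rdname write_chewcards_csv
#' @export
read_traps_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(trap_cols, names(d))
  if (length(missing_cols) > 0)
    stop(path, " lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  d
}

iso8601 <- function(t) format(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

parse_iso8601 <- function(s) {
  if (any(!grepl("(Z|[+-][0-9]{2}:?[0-9]{2})$", s)))
    stop("naive timestamps (no timezone designator) are rejected; ",
         "use UTC ISO-8601, e.g. 2013-08-09T08:30:00Z", call. = FALSE)
  t <- as.POSIXct(sub("Z$", "+0000", gsub("([+-][0-9]{2}):([0-9]{2})$",
                                          "\\1\\2", s)),
                  format = "%Y-%m-%dT%H:%M:%S%z", tz = "UTC")
  if (any(is.na(t)))
    stop("unparseable ISO-8601 timestamps", call. = FALSE)
  t
}

#' Read and write planar track/waypoint CSV files
#'
#' A simple planar dialect for tracks and bait-plot logs:
#' `line_id,x_m,y_m,t_iso` with ISO-8601 UTC timestamps.
#'
#' @param points a data frame with `line_id`, `x_m`, `y_m` and `time`.
#' @param path file path.
#' @return The points (invisibly for the writer); the reader returns
#'   `line_id`, `x_m`, `y_m`, `time` (POSIXct UTC).
#' @export
write_track_csv <- function(points, path) {
  out <- data.frame(line_id = points$line_id,
                    x_m = points$x_m, y_m = points$y_m,
                    t_iso = iso8601(points$time))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(points)
}

#' @rdname write_track_csv
#' @export
read_track_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  data.frame(line_id = d$line_id, x_m = d$x_m, y_m = d$y_m,
             time = parse_iso8601(d$t_iso))
}

#' Write flight tracks and bait-plot waypoints as GPX 1.1
#'
#' Tracks become `<trk>` elements (one `<trkseg>` per line) and bait-plot
#' events become `<wpt>` waypoints, both with ISO-8601 UTC `<time>`
#' children. Planar coordinates are mapped to lon/lat with the local
#' equirectangular projection about `reference`.
#'
#' @param path output file.
#' @param tracks flight tracks (`line_id`, `x_m`, `y_m`, `time`), or
#'   `NULL`.
#' @param waypoints bait-plot events (`plot_id`, `x_m`, `y_m`, `time`), or
#'   `NULL`.
#' @param reference `c(lon0, lat0)` anchor of the planar frame.
#' @return `path`, invisibly.
#' @export
write_gpx <- function(path, tracks = NULL, waypoints = NULL,
                      reference = c(172.0, -42.5)) {
  doc <- xml2::xml_new_root("gpx", version = "1.1", creator = "baitline",
                            xmlns = "http://www.topografix.com/GPX/1/1")
  add_pt <- function(parent, tag, lon, lat, time, name = NULL) {
    pt <- xml2::xml_add_child(parent, tag, lat = sprintf("%.7f", lat),
                              lon = sprintf("%.7f", lon))
    if (!is.null(name)) xml2::xml_add_child(pt, "name", name)
    xml2::xml_add_child(pt, "time", iso8601(time))
  }
  if (!is.null(waypoints) && nrow(waypoints) > 0) {
    ll <- to_geographic(waypoints[c("x_m", "y_m")], reference)
    for (i in seq_len(nrow(waypoints)))
      add_pt(doc, "wpt", ll$lon[i], ll$lat[i], waypoints$time[i],
             name = waypoints$plot_id[i])
  }
  if (!is.null(tracks) && nrow(tracks) > 0) {
    for (lid in unique(tracks$line_id)) {
      tr <- tracks[tracks$line_id == lid, ]
      ll <- to_geographic(tr[c("x_m", "y_m")], reference)
      trk <- xml2::xml_add_child(doc, "trk")
      xml2::xml_add_child(trk, "name", as.character(lid))
      seg <- xml2::xml_add_child(trk, "trkseg")
      for (i in seq_len(nrow(tr)))
        add_pt(seg, "trkpt", ll$lon[i], ll$lat[i], tr$time[i])
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

gpx_ns_strip <- function(doc) { xml2::xml_ns_strip(doc); doc }

#' Read GPX tracks or waypoints into the planar frame
#'
#' Parses GPX 1.1 `<trk>`/`<trkpt>` (or `<wpt>`) elements. Timestamps must
#' carry a timezone designator (UTC ISO-8601); naive timestamps are
#' rejected. Coordinates are projected to planar metres about `reference`.
#'
#' @param path GPX file.
#' @param reference `c(lon0, lat0)` anchor of the planar frame.
#' @return For tracks: `line_id`, `x_m`, `y_m`, `time`; for waypoints:
#'   `plot_id`, `x_m`, `y_m`, `time`.
#' @export
read_gpx_tracks <- function(path, reference = c(172.0, -42.5)) {
  doc <- gpx_ns_strip(xml2::read_xml(path))
  trks <- xml2::xml_find_all(doc, ".//trk")
  out <- lapply(trks, function(trk) {
    nm <- xml2::xml_text(xml2::xml_find_first(trk, "./name"))
    pts <- xml2::xml_find_all(trk, ".//trkpt")
    ll <- cbind(as.numeric(xml2::xml_attr(pts, "lon")),
                as.numeric(xml2::xml_attr(pts, "lat")))
    xy <- to_planar(ll, reference)
    data.frame(line_id = nm, x_m = xy$x_m, y_m = xy$y_m,
               time = parse_iso8601(
                 xml2::xml_text(xml2::xml_find_all(pts, "./time"))))
  })
  do.call(rbind, out)
}

#' @rdname read_gpx_tracks
#' @export
read_gpx_waypoints <- function(path, reference = c(172.0, -42.5)) {
  doc <- gpx_ns_strip(xml2::read_xml(path))
  pts <- xml2::xml_find_all(doc, ".//wpt")
  if (length(pts) == 0)
    return(data.frame(plot_id = character(), x_m = numeric(),
                      y_m = numeric()))
  ll <- cbind(as.numeric(xml2::xml_attr(pts, "lon")),
              as.numeric(xml2::xml_attr(pts, "lat")))
  xy <- to_planar(ll, reference)
  data.frame(plot_id = xml2::xml_text(xml2::xml_find_first(pts, "./name")),
             x_m = xy$x_m, y_m = xy$y_m,
             time = parse_iso8601(
               xml2::xml_text(xml2::xml_find_all(pts, "./time"))))
}
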