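# GPS trackwork: projection, distance of bait plots to prefeed tracks,
# swath compliance, per-line timing, and sowing-layout arithmetic.

#' Local equirectangular projection to planar metres
#'
#' Projects lon/lat degrees to planar metres about a reference point:
#' `x = (lon - lon0) * cos(lat0) * 111320`, `y = (lat - lat0) * 110540`.
#' Adequate for block-scale work (< 10 km extents, sub-metre distortion).
#' `to_geographic()` is the exact inverse.
#'
#' @param lonlat two-column matrix or data frame of longitude, latitude in
#'   degrees.
#' @param reference length-2 `c(lon0, lat0)` anchor, typically the block
#'   centroid.
#' @param xy two-column matrix or data frame of planar `x_m`, `y_m`.
#' @return A data frame `x_m`, `y_m` (or `lon`, `lat` for the inverse).
#' @export
to_planar <- function(lonlat, reference) {
  lonlat <- as.matrix(lonlat)
  dlon <- lonlat[, 1] - reference[1]
  dlat <- lonlat[, 2] - reference[2]
  if (any(abs(dlon) > 1) || any(abs(dlat) > 1))
    warning("points more than 1 degree from the reference; ",
            "projection distortion may be large", call. = FALSE)
  data.frame(x_m = dlon * cos(reference[2] * pi / 180) * 111320,
             y_m = dlat * 110540)
}

#' @rdname to_planar
#' @export
to_geographic <- function(xy, reference) {
  xy <- as.matrix(xy)
  data.frame(
    lon = reference[1] + xy[, 1] / (cos(reference[2] * pi / 180) * 111320),
    lat = reference[2] + xy[, 2] / 110540)
}

# minimum distances from points (px, py) to the polyline (tx, ty)
dist_to_polyline <- function(px, py, tx, ty) {
  n <- length(tx)
  if (n < 2) stop("a track needs at least 2 fixes", call. = FALSE)
  dx <- diff(tx); dy <- diff(ty)
  len2 <- dx^2 + dy^2
  best <- rep(Inf, length(px))
  for (s in seq_len(n - 1)) {
    if (len2[s] == 0) {
      d2 <- (px - tx[s])^2 + (py - ty[s])^2
    } else {
      t <- ((px - tx[s]) * dx[s] + (py - ty[s]) * dy[s]) / len2[s]
      t <- pmin(pmax(t, 0), 1)
      d2 <- (px - (tx[s] + t * dx[s]))^2 + (py - (ty[s] + t * dy[s]))^2
    }
    best <- pmin(best, d2)
  }
  sqrt(best)
}

#' Minimum distance from a point to a GPS track
#'
#' Euclidean distance from a point to the nearest segment of the track
#' polyline (perpendicular foot where it falls on the segment, nearest
#' endpoint otherwise).
#'
#' @param p length-2 planar point `c(x, y)` in metres.
#' @param track data frame with ordered `x_m`, `y_m` fixes of one line.
#' @return Distance in metres.
#' @examples
#' seg <- data.frame(x_m = c(-100, 100), y_m = c(0, 0))
#' point_to_track_distance(c(0, 30), seg)   # 30 (perpendicular)
#' point_to_track_distance(c(150, 40), seg) # 64.03 (endpoint)
#' @export
point_to_track_distance <- function(p, track) {
  dist_to_polyline(p[1], p[2], track$x_m, track$y_m)
}

#' Swath compliance of bait-plot waypoints against prefeed tracks
#'
#' For each bait-plot event, the distance to its own line's prefeed track
#' (or, when the event references a line with no track, the nearest track,
#' flagged as a fallback), and the fraction of events lying within
#' `half_width_m` of the track — i.e. inside the baited swath centred on
#' the flight path.
#'
#' @param events bait-plot events (`line_id`, `x_m`, `y_m`, ...).
#' @param tracks flight tracks (`line_id`, `x_m`, `y_m`).
#' @param half_width_m half the swath width, metres (30 for a 60 m swath).
#' @return A list: `fraction_within`, and `distances`, a per-event data
#'   frame (`plot_id` if present, `line_id`, `distance_m`, `matched_line`,
#'   `fallback`).
#' @export
swath_compliance <- function(events, tracks, half_width_m) {
  if (is.null(events) || nrow(events) == 0)
    stop("no bait-plot events supplied", call. = FALSE)
  if (is.null(tracks) || nrow(tracks) == 0)
    stop("no tracks supplied", call. = FALSE)
  track_ids <- unique(tracks$line_id)
  n <- nrow(events)
  dist <- numeric(n); matched <- character(n); fallback <- logical(n)
  for (lid in unique(events$line_id)) {
    i <- which(events$line_id == lid)
    if (lid %in% track_ids) {
      tr <- tracks[tracks$line_id == lid, ]
      dist[i] <- dist_to_polyline(events$x_m[i], events$y_m[i],
                                  tr$x_m, tr$y_m)
      matched[i] <- lid
    } else {
      # nearest track overall, flagged
      dmat <- sapply(track_ids, function(tid) {
        tr <- tracks[tracks$line_id == tid, ]
        dist_to_polyline(events$x_m[i], events$y_m[i], tr$x_m, tr$y_m)
      })
      dmat <- matrix(dmat, nrow = length(i))
      j <- apply(dmat, 1, which.min)
      dist[i] <- dmat[cbind(seq_along(i), j)]
      matched[i] <- track_ids[j]
      fallback[i] <- TRUE
    }
  }
  distances <- data.frame(line_id = events$line_id, distance_m = dist,
                          matched_line = matched, fallback = fallback)
  if (!is.null(events$plot_id))
    distances <- cbind(plot_id = events$plot_id, distances)
  list(fraction_within = mean(dist <= half_width_m),
       distances = distances)
}

#' Per-line baiting timing and speed
#'
#' For each line's bait-plot events: elapsed time from the first to the
#' last plot, mean time per plot on the inter-plot-interval convention
#' (`elapsed / (n_plots - 1)`: the logged quantity is the time to bait a
#' plot and move to the next), the path length through the plots, and the
#' line speed `length / elapsed`.
#'
#' @param events bait-plot events with `line_id`, `x_m`, `y_m`, `time`
#'   (POSIXct or numeric seconds); at least two events per line.
#' @return A data frame with one row per line: `line_id`, `n_plots`,
#'   `elapsed_min`, `mean_time_per_plot_min`, `line_length_km`,
#'   `speed_kmh`.
#' @export
line_timing <- function(events) {
  out <- lapply(split(events, events$line_id), function(e) {
    if (nrow(e) < 2)
      stop("line ", e$line_id[1], " has fewer than 2 events",
           call. = FALSE)
    e <- e[order(e$time), , drop = FALSE]
    dt <- diff(as.numeric(e$time))
    if (any(dt <= 0))
      stop("non-monotone timestamps on line ", e$line_id[1],
           call. = FALSE)
    elapsed_min <- sum(dt) / 60
    len_km <- sum(sqrt(diff(e$x_m)^2 + diff(e$y_m)^2)) / 1000
    data.frame(line_id = e$line_id[1], n_plots = nrow(e),
               elapsed_min = elapsed_min,
               mean_time_per_plot_min = elapsed_min / (nrow(e) - 1),
               line_length_km = len_km,
               speed_kmh = len_km / (elapsed_min / 60))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Group and combined summaries of per-line timing
#'
#' Per-group means and standard errors (over lines) of the time per plot
#' and line speed, plus a `Combined` row formed as the line-count-weighted
#' mean of the group means — the convention that reproduces a combined row
#' from printed group summaries. Its SE combines the group SEs as
#' `sqrt(sum((w * se)^2)) / sum(w)`.
#'
#' @param rows a [line_timing()] result, optionally with extra grouping
#'   columns (e.g. `trial`, `treatment`).
#' @param by character vector of grouping column names in `rows`; `NULL`
#'   treats all rows as one group.
#' @return A data frame with one row per group plus the combined row:
#'   group labels, `n_lines`, `n_plots`, `time_per_plot_min`,
#'   `time_per_plot_se`, `speed_kmh`, `speed_se`.
#' @export
timing_summary <- function(rows, by = NULL) {
  grp <- if (is.null(by)) list(group = rep("all", nrow(rows)))
         else rows[by]
  key <- interaction(grp, sep = " / ", drop = TRUE)
  stats <- lapply(split(rows, key), function(r) {
    data.frame(n_lines = nrow(r), n_plots = sum(r$n_plots),
               time_per_plot_min = mean(r$mean_time_per_plot_min),
               time_per_plot_se = sd(r$mean_time_per_plot_min) /
                 sqrt(nrow(r)),
               speed_kmh = mean(r$speed_kmh),
               speed_se = sd(r$speed_kmh) / sqrt(nrow(r)))
  })
  out <- cbind(group = names(stats), do.call(rbind, stats))
  rownames(out) <- NULL
  rbind(out, cbind(group = "Combined", combine_timing_groups(out)))
}

#' Combine printed per-group timing summaries into one row
#'
#' Line-count-weighted combination of group-level mean time per plot and
#' speed (and their SEs, if present), as used for the combined row of a
#' timing table.
#'
#' @param groups data frame with `n_lines`, `n_plots` (optional),
#'   `time_per_plot_min`, `speed_kmh`, and optionally `time_per_plot_se`,
#'   `speed_se`.
#' @return A one-row data frame with the same summary columns.
#' @examples
#' tab <- data.frame(n_lines = c(13, 23, 23, 20),
#'                   time_per_plot_min = c(1.85, 1.42, 1.69, 1.79),
#'                   speed_kmh = c(0.85, 1.05, 0.86, 0.72))
#' combine_timing_groups(tab) # ~1.67 min/plot, ~0.88 km/h
#' @export
combine_timing_groups <- function(groups) {
  w <- groups$n_lines
  comb_se <- function(se) if (is.null(se)) NA_real_ else
    sqrt(sum((w * se)^2)) / sum(w)
  data.frame(
    n_lines = sum(w),
    n_plots = if (is.null(groups$n_plots)) NA_integer_ else
      sum(groups$n_plots),
    time_per_plot_min = sum(w * groups$time_per_plot_min) / sum(w),
    time_per_plot_se = comb_se(groups$time_per_plot_se),
    speed_kmh = sum(w * groups$speed_kmh) / sum(w),
    speed_se = comb_se(groups$speed_se))
}

#' Fraction of the operational area that receives bait
#'
#' With bait laid in non-overlapping circular clusters of radius
#' `cluster_radius_m` every `plot_spacing_m` along lines `fps_m` apart,
#' each plot serves a `plot_spacing_m x fps_m` cell, so the baited fraction
#' is `100 * pi * r^2 / (spacing * fps)` percent.
#'
#' @param cluster_radius_m cluster radius, metres (must be less than half
#'   the plot spacing so clusters do not overlap).
#' @param plot_spacing_m spacing of plots along the line, metres.
#' @param fps_m flight-path (line) spacing, metres.
#' @return Percent of the area baited.
#' @examples
#' baited_area_fraction(5, 20, 100) # 3.93% -- under 5% of the area
#' @export
baited_area_fraction <- function(cluster_radius_m, plot_spacing_m, fps_m) {
  if (cluster_radius_m < 0 || plot_spacing_m <= 0 || fps_m <= 0)
    stop("radius must be >= 0 and spacings positive", call. = FALSE)
  if (cluster_radius_m >= plot_spacing_m / 2)
    stop("clusters overlap: radius must be below half the plot spacing",
         call. = FALSE)
  100 * pi * cluster_radius_m^2 / (plot_spacing_m * fps_m)
}

#' Area-wide bait application rate from the plot layout
#'
#' Each plot of `plot_mass_g` grams serves a `plot_spacing_m x fps_m` cell,
#' giving `(mass/1000) * 10000 / (spacing * fps)` kg per hectare.
#'
#' @param plot_mass_g bait mass per plot, grams.
#' @param plot_spacing_m spacing of plots along the line, metres.
#' @param fps_m line spacing, metres.
#' @return Application rate, kg/ha.
#' @examples
#' realized_application_rate(100, 20, 100) # 0.5 kg/ha
#' @export
realized_application_rate <- function(plot_mass_g, plot_spacing_m, fps_m) {
  if (plot_mass_g < 0 || plot_spacing_m <= 0 || fps_m <= 0)
    stop("mass must be >= 0 and spacings positive", call. = FALSE)
  (plot_mass_g / 1000) * 1e4 / (plot_spacing_m * fps_m)
}
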