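# Synthetic field operations: block geometry, flight tracks, latent animal
# populations, chewcard and trap surveys, and contractor baiting logs.
# All geometry is planar, in metres. Layouts are built in a canonical frame
# (flight lines parallel to the y axis) and rotated to the block's bearing.

rotate_xy <- function(xy, deg, centre) {
  th <- deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  sweep(sweep(as.matrix(xy), 2, centre) %*% t(R), 2, centre, "+")
}

#' Build a rectangular treatment block with parallel flight lines
#'
#' The block is a rectangle of the requested area whose width is a whole
#' number of flight-path spacings, so the union of `fps_m`-wide strips tiles
#' it exactly. Flight lines run down the centre of each strip; their total
#' length is therefore `area_ha / (fps_m / 10)` kilometres regardless of the
#' aspect ratio chosen.
#'
#' @param config a [sim_config()].
#' @return An object of class `bait_block`: a list with the block `name`,
#'   `area_ha`, `fps_m`, `swath_m`, rectangle dimensions `width_m` x
#'   `height_m`, `centre`, `rotation_deg`, the `boundary` corner matrix
#'   (closed, 5 x 2) and `flight_lines`, a data frame with one row per line
#'   (`line_id`, endpoints `x0,y0,x1,y1`, `length_m`).
#' @examples
#' blk <- build_block(sim_config(area_ha = 100, fps_m = 100))
#' sum(blk$flight_lines$length_m) # 10 km of line serves 100 ha at 100 m FPS
#' @export
build_block <- function(config) {
  validate_sim_config(config)
  area_m2 <- config$area_ha * 1e4
  fps <- config$fps_m
  n_lines <- max(1L, round(sqrt(area_m2) / fps))
  width <- n_lines * fps
  height <- area_m2 / width
  centre <- c(width, height) / 2
  xs <- (seq_len(n_lines) - 0.5) * fps
  ends <- rbind(cbind(xs, 0), cbind(xs, height))
  ends <- rotate_xy(ends, config$line_orientation_deg, centre)
  corners <- rbind(c(0, 0), c(width, 0), c(width, height), c(0, height),
                   c(0, 0))
  lines <- data.frame(
    line_id = sprintf("L%02d", seq_len(n_lines)),
    x0 = ends[seq_len(n_lines), 1], y0 = ends[seq_len(n_lines), 2],
    x1 = ends[n_lines + seq_len(n_lines), 1],
    y1 = ends[n_lines + seq_len(n_lines), 2],
    length_m = height
  )
  structure(list(name = config$block_name, area_ha = config$area_ha,
                 fps_m = fps, swath_m = config$swath_m,
                 width_m = width, height_m = height, centre = centre,
                 rotation_deg = config$line_orientation_deg,
                 boundary = rotate_xy(corners, config$line_orientation_deg,
                                      centre),
                 flight_lines = lines),
            class = "bait_block")
}

#' @export
print.bait_block <- function(x, ...) {
  cat(sprintf("<bait_block> %s: %g ha (%g x %g m), %d flight lines at %g m FPS, %.2f km of line\n",
              x$name, x$area_ha, round(x$width_m, 1), round(x$height_m, 1),
              nrow(x$flight_lines), x$fps_m,
              sum(x$flight_lines$length_m) / 1000))
  invisible(x)
}

#' Simulate helicopter GPS tracks along a block's flight lines
#'
#' Fixes are logged at a constant cadence along each line at the given
#' flying speed, with isotropic Gaussian positional noise. Lines are flown
#' serpentine-fashion (alternating direction) with a short turn between
#' lines, so timestamps increase monotonically across the whole operation.
#'
#' @param block a [build_block()] result.
#' @param speed_kmh flying speed (110 km/h is typical of a mid-size
#'   helicopter sowing bait).
#' @param fix_interval_s seconds between GPS fixes.
#' @param jitter_sd_m standard deviation of the isotropic positional noise
#'   on each fix, metres.
#' @param seed integer seed.
#' @param start_time POSIXct (UTC) of the first fix.
#' @param turn_s seconds added between the end of one line and the start of
#'   the next.
#' @return A data frame of class `flight_tracks` with columns `line_id`,
#'   `x_m`, `y_m`, `time`, and attributes `swath_m` and `fps_m`.
#' @export
simulate_flight <- function(block, speed_kmh = 110, fix_interval_s = 2,
                            jitter_sd_m = 3, seed = 1L,
                            start_time = as.POSIXct("2013-07-27 09:00:00",
                                                    tz = "UTC"),
                            turn_s = 30) {
  if (speed_kmh <= 0 || fix_interval_s <= 0)
    stop("speed and fix interval must be positive", call. = FALSE)
  set.seed(seed)
  step <- speed_kmh / 3.6 * fix_interval_s
  fl <- block$flight_lines
  out <- vector("list", nrow(fl))
  t0 <- 0
  for (i in seq_len(nrow(fl))) {
    d <- seq(0, fl$length_m[i], by = step)
    frac <- d / fl$length_m[i]
    if (i %% 2 == 0) frac <- rev(frac)  # serpentine
    x <- fl$x0[i] + frac * (fl$x1[i] - fl$x0[i])
    y <- fl$y0[i] + frac * (fl$y1[i] - fl$y0[i])
    n <- length(d)
    out[[i]] <- data.frame(
      line_id = fl$line_id[i],
      x_m = x + rnorm(n, 0, jitter_sd_m),
      y_m = y + rnorm(n, 0, jitter_sd_m),
      time = start_time + t0 + (seq_len(n) - 1) * fix_interval_s
    )
    t0 <- t0 + (n - 1) * fix_interval_s + turn_s
  }
  res <- do.call(rbind, out)
  attr(res, "swath_m") <- block$swath_m
  attr(res, "fps_m") <- block$fps_m
  class(res) <- c("flight_tracks", "data.frame")
  res
}

#' Simulate a latent animal population over a block
#'
#' Species counts are Poisson with mean `density x area`; activity centres
#' are uniform over the block rectangle expanded by the home-range radius,
#' so animals just outside the boundary can still reach cards and traps near
#' the edge. All animals start alive.
#'
#' @param block a [build_block()] result.
#' @param config the [sim_config()] (supplies densities and the home-range
#'   radius).
#' @param seed integer seed.
#' @return A data frame of class `population`: `id`, `species`, `x_m`,
#'   `y_m`, `alive`.
#' @export
simulate_population <- function(block, config, seed = config$seed) {
  set.seed(seed)
  r <- config$detection_params[["home_range_radius_m"]]
  dens <- config$species_densities
  pieces <- lapply(names(dens), function(sp) {
    n <- rpois(1, dens[[sp]] * block$area_ha)
    if (n == 0) {
      return(data.frame(id = character(), species = character(),
                        x_m = numeric(), y_m = numeric(),
                        alive = logical()))
    }
    xy <- cbind(runif(n, -r, block$width_m + r),
                runif(n, -r, block$height_m + r))
    xy <- rotate_xy(xy, block$rotation_deg, block$centre)
    data.frame(id = sprintf("%s-%05d", sp, seq_len(n)), species = sp,
               x_m = xy[, 1], y_m = xy[, 2], alive = TRUE)
  })
  pop <- do.call(rbind, pieces)
  rownames(pop) <- NULL
  class(pop) <- c("population", "data.frame")
  pop
}

#' Apply a control operation to a population
#'
#' Each animal is independently killed with its species' kill probability.
#' The input population is not modified; a new one is returned with `alive`
#' updated.
#'
#' @param pop a [simulate_population()] result.
#' @param kill_prob named per-species kill probabilities covering every
#'   species present in `pop`.
#' @param seed integer seed.
#' @return The population with updated `alive` flags.
#' @export
apply_control <- function(pop, kill_prob, seed = 1L) {
  missing_sp <- setdiff(unique(pop$species), names(kill_prob))
  if (length(missing_sp) > 0)
    stop("no kill probability for species: ",
         paste(missing_sp, collapse = ", "), call. = FALSE)
  if (any(kill_prob < 0 | kill_prob > 1))
    stop("kill probabilities must lie in [0, 1]", call. = FALSE)
  set.seed(seed)
  out <- pop
  p <- unname(kill_prob[out$species])
  killed <- rbinom(nrow(out), 1, p) == 1
  out$alive <- out$alive & !killed
  out
}

# Card and trap line layouts in the canonical frame, then rotated to the
# block bearing. Lines are parallel to the flight lines, spaced exactly
# `sep` apart and centred in the block.
survey_line_positions <- function(width, sep) {
  n <- floor(width / sep) + 1
  offset <- (width - (n - 1) * sep) / 2
  offset + (seq_len(n) - 1) * sep
}

chewcard_layout <- function(block, config) {
  xs <- survey_line_positions(block$width_m, config$min_line_separation_m)
  n_cards <- floor(block$height_m / config$card_spacing_m)
  ys <- (block$height_m - (n_cards - 1) * config$card_spacing_m) / 2 +
    (seq_len(n_cards) - 1) * config$card_spacing_m
  grid <- expand.grid(y = ys, line = seq_along(xs))
  xy <- rotate_xy(cbind(xs[grid$line], grid$y), block$rotation_deg,
                  block$centre)
  data.frame(card_id = sprintf("C%02d-%02d", grid$line,
                               rep(seq_len(n_cards), length(xs))),
             line_id = sprintf("CL%02d", grid$line),
             x_m = xy[, 1], y_m = xy[, 2])
}

trap_layout <- function(block, config) {
  xs <- survey_line_positions(block$width_m, config$min_line_separation_m)
  if (length(xs) < config$trap_lines)
    stop("block too narrow for ", config$trap_lines,
         " trap lines at the required separation", call. = FALSE)
  xs <- xs[seq_len(config$trap_lines)]
  span <- (config$traps_per_line - 1) * config$trap_spacing_m
  ys <- (block$height_m - span) / 2 +
    (seq_len(config$traps_per_line) - 1) * config$trap_spacing_m
  grid <- expand.grid(y = ys, line = seq_along(xs))
  xy <- rotate_xy(cbind(xs[grid$line], grid$y), block$rotation_deg,
                  block$centre)
  data.frame(trap_id = sprintf("T%02d-%02d", grid$line,
                               rep(seq_len(config$traps_per_line),
                                   length(xs))),
             line_id = sprintf("TL%02d", grid$line),
             x_m = xy[, 1], y_m = xy[, 2])
}

# animals per hectare with activity centres within radius r of (x, y)
local_density <- function(x, y, ax, ay, r) {
  eff_ha <- pi * r^2 / 1e4
  cnt <- vapply(seq_along(x), function(i) {
    sum((ax - x[i])^2 + (ay - y[i])^2 <= r^2)
  }, numeric(1))
  cnt / eff_ha
}

#' Simulate a chewcard monitoring session
#'
#' Cards are laid at `card_spacing_m` intervals along lines parallel to the
#' flight lines and at least `min_line_separation_m` apart. For each card
#' and species the local density `D` (animals per hectare with activity
#' centres within the home-range radius) drives the session interference
#' probability:
#'
#' * `hazard` mode: `p = 1 - exp(-theta * D * nights)` — a constant nightly
#'   hazard, which saturates at high density the way real chewcards do;
#' * `transform_linear` mode: `p = sin^2(min(c * D, pi/2))`, so the
#'   arcsine-square-root index `arcsin(sqrt(p))` equals `c * D` below
#'   saturation and tCCI-based reduction estimates are consistent for the
#'   true density reduction.
#'
#' Interference is drawn independently per card and species.
#'
#' @param pop a population (only `alive` animals interfere).
#' @param block a [build_block()] result.
#' @param config the [sim_config()].
#' @param session `"pre"` or `"post"`.
#' @param seed integer seed.
#' @return A data frame of chewcard records: `card_id`, `line_id`,
#'   `block_id`, `session`, one 0/1 column per species plus `other`, and
#'   `nights`.
#' @export
simulate_chewcard_survey <- function(pop, block, config,
                                     session = c("pre", "post"),
                                     seed = config$seed) {
  session <- match.arg(session)
  set.seed(seed + if (session == "post") 1000L else 0L)
  cards <- chewcard_layout(block, config)
  r <- config$detection_params[["home_range_radius_m"]]
  rec <- data.frame(card_id = cards$card_id, line_id = cards$line_id,
                    block_id = block$name, session = session)
  for (sp in names(config$species_densities)) {
    keep <- pop$species == sp & pop$alive
    D <- local_density(cards$x_m, cards$y_m, pop$x_m[keep], pop$y_m[keep], r)
    p <- switch(config$detection_mode,
      hazard = 1 - exp(-config$detection_params[["theta"]] * D *
                         config$nights_chewcard),
      transform_linear = sin(pmin(config$detection_params[["c"]] * D,
                                  pi / 2))^2,
      stop("unknown detection mode: ", config$detection_mode, call. = FALSE)
    )
    rec[[sp]] <- rbinom(nrow(cards), 1, p)
  }
  rec$other <- 0L
  rec$nights <- config$nights_chewcard
  rec
}

#' Simulate a residual trap-catch survey
#'
#' Traps are run for `trap_nights` nights along `trap_lines` lines of
#' `traps_per_line` traps at `trap_spacing_m` intervals. Each trap-night has
#' exactly one outcome. A possum whose activity centre lies within the
#' home-range radius of a trap is captured with `per_animal_capture_prob`;
#' a capture takes precedence over other outcomes and removes the animal
#' for the remaining nights of the survey (traps are removal devices; the
#' input population is not modified, so animals are "restored" afterwards).
#' Otherwise the trap is sprung by a non-target event with
#' `nontarget_event_prob`, which later costs half a trap night in the RTCI
#' denominator; otherwise the trap-night is empty.
#'
#' @inheritParams simulate_chewcard_survey
#' @return A data frame of trap-night records: `trap_id`, `line_id`,
#'   `block_id`, `night`, `outcome` in
#'   `{possum_capture, nontarget_or_sprung, empty}`.
#' @export
simulate_trap_survey <- function(pop, block, config, seed = config$seed) {
  set.seed(seed + 2000L)
  traps <- trap_layout(block, config)
  r <- config$detection_params[["home_range_radius_m"]]
  possum <- pop[pop$species == "possum" & pop$alive, , drop = FALSE]
  taken <- rep(FALSE, nrow(possum))
  recs <- vector("list", config$trap_nights)
  for (night in seq_len(config$trap_nights)) {
    outcome <- character(nrow(traps))
    for (i in seq_len(nrow(traps))) {
      cand <- which(!taken &
                      (possum$x_m - traps$x_m[i])^2 +
                      (possum$y_m - traps$y_m[i])^2 <= r^2)
      hit <- cand[rbinom(length(cand), 1,
                         config$per_animal_capture_prob) == 1]
      if (length(hit) > 0) {
        taken[hit[1]] <- TRUE
        outcome[i] <- "possum_capture"
      } else if (rbinom(1, 1, config$nontarget_event_prob) == 1) {
        outcome[i] <- "nontarget_or_sprung"
      } else {
        outcome[i] <- "empty"
      }
    }
    recs[[night]] <- data.frame(trap_id = traps$trap_id,
                                line_id = traps$line_id,
                                block_id = block$name,
                                night = night, outcome = outcome)
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

# arithmetic-moment parameterisation of the lognormal
rlnorm_mean_sd <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  s2 <- log(1 + (sd / mean)^2)
  rlnorm(n, meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

#' Simulate a contractor's ground-baiting log along prefeed tracks
#'
#' Bait plots are laid every `plot_spacing_m` along each flight track,
#' except over one contiguous skipped segment per line of relative length
#' `skip_fraction` (e.g. waterlogged ground). Logged waypoints are the track
#' position plus isotropic GPS noise; timestamps accumulate lognormal
#' per-plot durations (time to bait a plot and move to the next), so each
#' line's events are strictly increasing in time.
#'
#' @param tracks a [simulate_flight()] result (or any data frame with
#'   `line_id`, `x_m`, `y_m` ordered along each line).
#' @param config the [sim_config()].
#' @param seed integer seed.
#' @param start_time POSIXct (UTC) when baiting starts.
#' @param between_lines_min minutes between finishing one line and starting
#'   the next.
#' @return A data frame of class `bait_events`: `plot_id`, `line_id`,
#'   `x_m`, `y_m`, `time`, `mass_g`, `bait_type`.
#' @export
simulate_ground_baiting <- function(tracks, config, seed = config$seed,
                                    start_time = as.POSIXct(
                                      "2013-08-09 08:30:00", tz = "UTC"),
                                    between_lines_min = 5) {
  set.seed(seed + 3000L)
  out <- list()
  t_cursor <- 0  # minutes since start_time
  for (lid in unique(tracks$line_id)) {
    tr <- tracks[tracks$line_id == lid, , drop = FALSE]
    seg <- sqrt(diff(tr$x_m)^2 + diff(tr$y_m)^2)
    dcum <- c(0, cumsum(seg))
    L <- dcum[length(dcum)]
    d <- seq(config$plot_spacing_m / 2, L, by = config$plot_spacing_m)
    if (config$skip_fraction > 0) {
      ls <- config$skip_fraction * L
      s0 <- runif(1, 0, L - ls)
      d <- d[d < s0 | d > s0 + ls]
    }
    if (length(d) == 0) next
    x <- approx(dcum, tr$x_m, xout = d, ties = "ordered")$y
    y <- approx(dcum, tr$y_m, xout = d, ties = "ordered")$y
    dur <- rlnorm_mean_sd(length(d), config$per_plot_time_min[[1]],
                          config$per_plot_time_min[[2]])
    tmin <- t_cursor + cumsum(dur) - dur[1]  # first plot at line start
    out[[lid]] <- data.frame(
      plot_id = sprintf("%s-p%03d", lid, seq_along(d)),
      line_id = lid,
      x_m = x + rnorm(length(d), 0, config$gps_noise_sd_m),
      y_m = y + rnorm(length(d), 0, config$gps_noise_sd_m),
      time = start_time + tmin * 60,
      mass_g = config$plot_mass_g,
      bait_type = config$bait_type
    )
    t_cursor <- tmin[length(tmin)] + between_lines_min
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("bait_events", "data.frame")
  res
}
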