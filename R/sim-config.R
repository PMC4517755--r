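#' Configuration for a synthetic baiting operation
#'
#' Bundles every parameter the synthetic field-operation generator needs:
#' block geometry, species densities, control efficacy, chewcard and trap
#' survey design, and the contractor baiting process. Defaults reproduce the
#' design of a typical aerially-prefed ground-toxic trial block: a 250 ha
#' block with 100 m flight-path spacing and a 60 m baited swath, chewcards
#' at 50 m spacing on lines at least 200 m apart run for six nights, eight
#' trap lines of ten traps at 20 m spacing run for three nights, and bait
#' plots of 100 g laid every 20 m along the prefeed lines.
#'
#' @param seed integer seed; every `simulate_*()` call derives its random
#'   stream from this unless given its own `seed`.
#' @param block_name label for the treatment block.
#' @param area_ha block area in hectares.
#' @param fps_m flight-path spacing in metres (100 for ground-toxic blocks,
#'   180 for aerial broadcast blocks).
#' @param swath_m baited swath width centred on each flight line, metres.
#' @param line_orientation_deg bearing of the flight lines, degrees
#'   anticlockwise from north (0 = lines run along the y axis).
#' @param species_densities named numeric vector, animals per hectare per
#'   species (names are species labels, e.g. `possum`, `rat`).
#' @param kill_prob named numeric vector, per-species probability that an
#'   individual is killed by the control operation.
#' @param detection_mode `"hazard"` (nightly interference hazard
#'   proportional to local density, saturates like real chewcards) or
#'   `"transform_linear"` (the session interference probability is
#'   `sin^2(min(c * D, pi/2))`, so the arcsine-transformed index is
#'   proportional to local density below saturation and the tCCI reduction
#'   estimator is consistent for the true kill).
#' @param detection_params named numeric vector with elements `theta`
#'   (per-night hazard per animal/ha, hazard mode), `c` (radians per
#'   animal/ha, transform-linear mode) and `home_range_radius_m` (radius of
#'   the circular neighbourhood defining a card's or trap's local density).
#' @param nights_chewcard nights a chewcard is exposed per session.
#' @param card_spacing_m spacing of cards along a line, metres.
#' @param min_line_separation_m minimum separation between chewcard lines.
#' @param trap_lines,traps_per_line,trap_spacing_m,trap_nights leg-hold trap
#'   survey design.
#' @param per_animal_capture_prob nightly capture probability per possum
#'   whose activity centre lies within the home-range radius of a trap.
#' @param nontarget_event_prob per trap-night probability of a non-target
#'   capture or sprung trap (penalised half a trap night in the RTCI).
#' @param plot_spacing_m spacing of bait plots along the prefeed track.
#' @param plot_mass_g bait mass laid per plot, grams.
#' @param per_plot_time_min length-2 numeric `c(mean, sd)` of the lognormal
#'   per-plot time (minutes): time to bait a plot and walk to the next.
#' @param gps_noise_sd_m isotropic Gaussian GPS error applied to logged
#'   waypoints, metres.
#' @param skip_fraction fraction of each line's length not baited (e.g.
#'   waterlogged ground), taken as one contiguous segment per line.
#' @param bait_type label carried on bait-plot events.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(seed = 1, area_ha = 100, fps_m = 100)
#' cfg$area_ha
#' @export
sim_config <- function(seed = 1L,
                       block_name = "block-1",
                       area_ha = 250,
                       fps_m = 100,
                       swath_m = 60,
                       line_orientation_deg = 0,
                       species_densities = c(possum = 8, rat = 4),
                       kill_prob = c(possum = 0.95, rat = 0.95),
                       detection_mode = c("hazard", "transform_linear"),
                       detection_params = c(theta = 0.065,
                                            c = pi / 4 / 8,
                                            home_range_radius_m = 60),
                       nights_chewcard = 6L,
                       card_spacing_m = 50,
                       min_line_separation_m = 200,
                       trap_lines = 8L,
                       traps_per_line = 10L,
                       trap_spacing_m = 20,
                       trap_nights = 3L,
                       per_animal_capture_prob = 0.02,
                       nontarget_event_prob = 0.005,
                       plot_spacing_m = 20,
                       plot_mass_g = 100,
                       per_plot_time_min = c(mean = 1.67, sd = 0.5),
                       gps_noise_sd_m = 3,
                       skip_fraction = 0,
                       bait_type = "RS5_1080") {
  detection_mode <- match.arg(detection_mode)
  cfg <- list(
    seed = as.integer(seed), block_name = as.character(block_name),
    area_ha = area_ha, fps_m = fps_m, swath_m = swath_m,
    line_orientation_deg = line_orientation_deg,
    species_densities = species_densities, kill_prob = kill_prob,
    detection_mode = detection_mode, detection_params = detection_params,
    nights_chewcard = as.integer(nights_chewcard),
    card_spacing_m = card_spacing_m,
    min_line_separation_m = min_line_separation_m,
    trap_lines = as.integer(trap_lines),
    traps_per_line = as.integer(traps_per_line),
    trap_spacing_m = trap_spacing_m, trap_nights = as.integer(trap_nights),
    per_animal_capture_prob = per_animal_capture_prob,
    nontarget_event_prob = nontarget_event_prob,
    plot_spacing_m = plot_spacing_m, plot_mass_g = plot_mass_g,
    per_plot_time_min = per_plot_time_min,
    gps_noise_sd_m = gps_noise_sd_m, skip_fraction = skip_fraction,
    bait_type = as.character(bait_type)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stop_cfg <- function(msg) stop("invalid sim_config: ", msg, call. = FALSE)
  pos <- c("area_ha", "fps_m", "swath_m", "card_spacing_m",
           "min_line_separation_m", "trap_spacing_m", "plot_spacing_m",
           "plot_mass_g")
  for (f in pos) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || !is.finite(cfg[[f]]) ||
        cfg[[f]] <= 0)
      stop_cfg(sprintf("'%s' must be a single positive number", f))
  }
  cnt <- c("nights_chewcard", "trap_lines", "traps_per_line", "trap_nights")
  for (f in cnt) {
    if (cfg[[f]] < 1L) stop_cfg(sprintf("'%s' must be >= 1", f))
  }
  prob <- c(cfg$kill_prob, cfg$per_animal_capture_prob,
            cfg$nontarget_event_prob)
  if (any(!is.finite(prob)) || any(prob < 0) || any(prob > 1))
    stop_cfg("all probabilities must lie in [0, 1]")
  if (any(cfg$species_densities < 0))
    stop_cfg("species densities must be >= 0")
  if (is.null(names(cfg$species_densities)))
    stop_cfg("'species_densities' must be a named vector")
  if (cfg$skip_fraction < 0 || cfg$skip_fraction >= 1)
    stop_cfg("'skip_fraction' must lie in [0, 1)")
  dp <- cfg$detection_params
  need <- if (cfg$detection_mode == "hazard") "theta" else "c"
  if (!all(c(need, "home_range_radius_m") %in% names(dp)))
    stop_cfg(sprintf("detection_params must name '%s' and 'home_range_radius_m'",
                     need))
  if (any(dp[c(need, "home_range_radius_m")] <= 0))
    stop_cfg("detection parameters must be positive")
  tm <- cfg$per_plot_time_min
  if (length(tm) != 2 || tm[[1]] <= 0 || tm[[2]] < 0)
    stop_cfg("'per_plot_time_min' must be c(mean > 0, sd >= 0)")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$block_name, "\n")
  cat(sprintf("  %g ha, FPS %g m, swath %g m, orientation %g deg\n",
              x$area_ha, x$fps_m, x$swath_m, x$line_orientation_deg))
  cat("  densities/ha:",
      paste(names(x$species_densities), x$species_densities,
            sep = "=", collapse = ", "), "\n")
  cat(sprintf("  detection: %s (%s)\n", x$detection_mode,
              paste(names(x$detection_params),
                    signif(x$detection_params, 3),
                    sep = "=", collapse = ", ")))
  cat(sprintf("  chewcards: %d nights, %g m spacing, lines >= %g m apart\n",
              x$nights_chewcard, x$card_spacing_m, x$min_line_separation_m))
  cat(sprintf("  traps: %d lines x %d traps x %d nights\n",
              x$trap_lines, x$traps_per_line, x$trap_nights))
  cat(sprintf("  baiting: %g g plots every %g m, skip %g%%\n",
              x$plot_mass_g, x$plot_spacing_m, 100 * x$skip_fraction))
  invisible(x)
}
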