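# Operational cost, savings, and coverage models for aerial, hybrid
# (aerial-prefeed / ground-toxic) and all-ground baiting strategies.
# Only direct operational costs are modelled: bait, flying, and baiting
# labour. Helicopter positioning and management costs are excluded.

#' Cost and operational parameters
#'
#' Unit prices and operational rates for the cost models. The prices are
#' documented placeholders in NZ$ — realistic orders of magnitude to be
#' replaced with quoted prices for a real operation; the structural
#' quantities (rates, spacings, speeds) are the trial specifications.
#'
#' @param prefeed_bait_price,toxic_bait_price $/kg of bait.
#' @param prefeed_rate_aerial,toxic_rate_aerial kg/ha sown in a broadcast
#'   aerial operation (2 + 2 kg/ha is standard).
#' @param prefeed_rate_ground_op,toxic_rate_ground_op kg/ha in a
#'   ground-toxic operation (1 kg/ha prefeed; 0.5 kg/ha of toxic bait from
#'   100 g plots every 20 m on 100 m line spacing).
#' @param heli_hourly helicopter charter, $/h.
#' @param flying_speed_kmh sowing speed of the helicopter.
#' @param reload_overhead fractional flying-time overhead for reloading
#'   the bucket.
#' @param fps_aerial_m,fps_ground_m flight-path spacing of broadcast aerial
#'   sowing and of strip prefeed for ground operations, metres.
#' @param labor_day_rate contractor cost, $/person-day.
#' @param hours_baiting_per_day default hours of actual baiting per day.
#' @param bait_station_unit_cost purchase cost of one bait station, $.
#' @param stations_per_ha bait stations per hectare (one per plot cell at
#'   the default layout).
#' @param station_uses operations over which a station's cost is
#'   amortised.
#' @param extra_visit_factor the station-removal visit as a fraction of a
#'   full baiting labour pass.
#' @return An object of class `cost_params` (validated named list).
#' @export
cost_params <- function(prefeed_bait_price = 2.5,
                        toxic_bait_price = 4,
                        prefeed_rate_aerial = 2,
                        toxic_rate_aerial = 2,
                        prefeed_rate_ground_op = 1,
                        toxic_rate_ground_op = 0.5,
                        heli_hourly = 1200,
                        flying_speed_kmh = 110,
                        reload_overhead = 0.10,
                        fps_aerial_m = 180,
                        fps_ground_m = 100,
                        labor_day_rate = 400,
                        hours_baiting_per_day = 7,
                        bait_station_unit_cost = 8,
                        stations_per_ha = 5,
                        station_uses = 10,
                        extra_visit_factor = 1) {
  p <- as.list(environment())
  nonneg <- setdiff(names(p), c("hours_baiting_per_day"))
  for (f in nonneg)
    if (!is.numeric(p[[f]]) || p[[f]] < 0)
      stop("'", f, "' must be non-negative", call. = FALSE)
  if (p$flying_speed_kmh <= 0 || p$fps_aerial_m <= 0 || p$fps_ground_m <= 0)
    stop("speeds and spacings must be positive", call. = FALSE)
  if (p$hours_baiting_per_day <= 0 || p$hours_baiting_per_day > 24)
    stop("'hours_baiting_per_day' must lie in (0, 24]", call. = FALSE)
  structure(p, class = "cost_params")
}

#' Helicopter sowing time per hectare
#'
#' One hectare requires `10000 / fps_m` metres of flight line; at the
#' given flying speed, plus a fractional reloading overhead, this is
#' `(10000 / fps_m) / (speed * 1000) * (1 + overhead)` hours per hectare.
#'
#' @param fps_m flight-path spacing, metres.
#' @param flying_speed_kmh sowing speed, km/h.
#' @param reload_overhead fractional time overhead for reloading.
#' @return Hours of flying per hectare.
#' @examples
#' flight_time_per_ha(180, 110, 0.10) # 5.56e-4 h/ha
#' @export
flight_time_per_ha <- function(fps_m, flying_speed_kmh,
                               reload_overhead = 0) {
  if (fps_m <= 0 || flying_speed_kmh <= 0)
    stop("spacing and speed must be positive", call. = FALSE)
  (1e4 / fps_m) / (flying_speed_kmh * 1000) * (1 + reload_overhead)
}

#' Cost per hectare of a broadcast aerial 1080 operation
#'
#' Bait for the prefeed and toxic sowings plus two sorties of helicopter
#' time (prefeed and toxic), each with the reloading overhead.
#'
#' @param params a [cost_params()].
#' @return A named vector of component costs (`prefeed_bait`,
#'   `toxic_bait`, `flying`) with the `total`, $/ha.
#' @export
aerial_cost_per_ha <- function(params) {
  ft <- flight_time_per_ha(params$fps_aerial_m, params$flying_speed_kmh,
                           params$reload_overhead)
  comp <- c(
    prefeed_bait = params$prefeed_rate_aerial * params$prefeed_bait_price,
    toxic_bait = params$toxic_rate_aerial * params$toxic_bait_price,
    flying = 2 * ft * params$heli_hourly)
  c(comp, total = sum(comp))
}

#' Daily area covered by one ground-baiting contractor
#'
#' A contractor baiting at `speed_kmh` for `hours` a day walks
#' `speed * hours` km of line; each km of line treats `fps_ground_m / 10`
#' hectares.
#'
#' @param speed_kmh rate of bait laying along the line, km/h.
#' @param hours hours of actual baiting per day.
#' @param fps_ground_m line spacing, metres.
#' @return Hectares treated per person-day.
#' @examples
#' ground_coverage_ha_per_day(1, 7, 100) # 70 ha/day
#' @export
ground_coverage_ha_per_day <- function(speed_kmh, hours, fps_ground_m) {
  if (speed_kmh < 0) stop("speed must be >= 0", call. = FALSE)
  if (hours <= 0 || fps_ground_m <= 0)
    stop("hours and spacing must be positive", call. = FALSE)
  speed_kmh * hours * fps_ground_m / 10
}

#' Crew-days to complete a block
#'
#' `area / (per-person daily coverage * staff)`, optionally rounded to
#' whole days.
#'
#' @param area_ha block area, hectares.
#' @param speed_kmh baiting speed, km/h.
#' @param hours hours of baiting per day.
#' @param fps_ground_m line spacing, metres.
#' @param staff crew size.
#' @param rounding `"nearest"`, `"up"`, or `"none"`.
#' @return Days to completion.
#' @examples
#' crew_days_to_complete(10000, 0.88, 7, 100, 10) # 16 days
#' crew_days_to_complete(5000, 0.88, 7, 100, 10)  # 8 days
#' @export
crew_days_to_complete <- function(area_ha, speed_kmh, hours, fps_ground_m,
                                  staff,
                                  rounding = c("nearest", "up", "none")) {
  rounding <- match.arg(rounding)
  if (staff < 1) stop("'staff' must be >= 1", call. = FALSE)
  days <- area_ha /
    (ground_coverage_ha_per_day(speed_kmh, hours, fps_ground_m) * staff)
  switch(rounding, nearest = round(days), up = ceiling(days), none = days)
}

labor_pass_per_ha <- function(params, speed_kmh, hours) {
  params$labor_day_rate /
    ground_coverage_ha_per_day(speed_kmh, hours, params$fps_ground_m)
}

#' Cost per hectare of ground-based strategies, by component
#'
#' Component costs per hectare of the ground-based strategies:
#'
#' * `aerial_prefeed_ground_toxic` — prefeed bait sown in one aerial sortie
#'   at the ground-operation line spacing, then toxic bait hand-laid in one
#'   labour pass;
#' * `all_ground` — prefeed and toxic bait each hand-laid in a labour pass
#'   (two passes, same speed and geometry);
#' * the `_bait_stations` variants of either present the toxic bait in
#'   stations: station hardware amortised over `station_uses` operations
#'   plus a removal visit costed as `extra_visit_factor` of a labour pass.
#'
#' @param params a [cost_params()].
#' @param strategy one of `"aerial_prefeed_ground_toxic"`, `"all_ground"`,
#'   `"aerial_prefeed_ground_toxic_bait_stations"`,
#'   `"all_ground_bait_stations"`.
#' @param speed_kmh ground baiting speed, km/h.
#' @param hours hours of baiting per day (defaults to the params value).
#' @return A named vector of component costs with the `total`, $/ha.
#' @export
ground_strategy_cost_per_ha <- function(params,
                                        strategy = c(
                                          "aerial_prefeed_ground_toxic",
                                          "all_ground",
                                          "aerial_prefeed_ground_toxic_bait_stations",
                                          "all_ground_bait_stations"),
                                        speed_kmh,
                                        hours = params$hours_baiting_per_day) {
  strategy <- match.arg(strategy)
  if (speed_kmh <= 0) stop("ground speed must be positive", call. = FALSE)
  pass <- labor_pass_per_ha(params, speed_kmh, hours)
  aerial_prefeed <- startsWith(strategy, "aerial_prefeed")
  stations <- endsWith(strategy, "bait_stations")
  comp <- c(
    prefeed_bait = params$prefeed_rate_ground_op * params$prefeed_bait_price,
    prefeed_delivery = if (aerial_prefeed)
      flight_time_per_ha(params$fps_ground_m, params$flying_speed_kmh,
                         params$reload_overhead) * params$heli_hourly
      else pass,
    toxic_bait = params$toxic_rate_ground_op * params$toxic_bait_price,
    toxic_labor = pass)
  if (stations) {
    comp <- c(comp,
              station_hardware = params$bait_station_unit_cost *
                params$stations_per_ha / params$station_uses,
              station_removal = params$extra_visit_factor * pass)
  }
  c(comp, total = sum(comp))
}

#' Predicted saving from prefeeding aerially rather than by ground
#'
#' Percentage cost saving of the aerial-prefeed/ground-toxic strategy over
#' the matching all-ground baseline (ground-laid prefeed), at the same
#' baiting speed, hours and prices. With `with_bait_stations = TRUE` both
#' strategies present toxic bait in stations and the baseline is the
#' three-visit operation (prefeed pass, toxic pass, removal pass); the
#' avoided prefeed pass is then a smaller share of the total, so the
#' saving is lower.
#'
#' @param params a [cost_params()].
#' @param speed_kmh ground baiting speed, km/h.
#' @param hours hours of baiting per day.
#' @param with_bait_stations compare the bait-station variants?
#' @return Percent saving (positive when aerial prefeeding is cheaper).
#' @export
savings_vs_ground_prefeed <- function(params, speed_kmh,
                                      hours = params$hours_baiting_per_day,
                                      with_bait_stations = FALSE) {
  suffix <- if (with_bait_stations) "_bait_stations" else ""
  new <- ground_strategy_cost_per_ha(
    params, paste0("aerial_prefeed_ground_toxic", suffix), speed_kmh, hours)
  base <- ground_strategy_cost_per_ha(
    params, paste0("all_ground", suffix), speed_kmh, hours)
  if (base[["total"]] <= 0)
    stop("baseline strategy has zero cost", call. = FALSE)
  100 * (base[["total"]] - new[["total"]]) / base[["total"]]
}
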