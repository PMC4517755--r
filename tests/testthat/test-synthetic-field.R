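test_that("block geometry conserves line length per hectare", {
  # 1 km of line at fps f serves f/10 ha, so total length = area/(fps/10) km
  cases <- list(c(100, 100, 10), c(100, 180, 100 / 18), c(10, 100, 1),
                c(250, 100, 25), c(180, 100, 18))
  for (cs in cases) {
    blk <- build_block(sim_config(area_ha = cs[1], fps_m = cs[2]))
    expect_equal(sum(blk$flight_lines$length_m) / 1000, cs[3],
                 tolerance = 1e-10)
    # strips of width fps tile the block
    expect_equal(nrow(blk$flight_lines) * blk$fps_m, blk$width_m)
    expect_equal(blk$width_m * blk$height_m / 1e4, blk$area_ha)
  }
  expect_error(sim_config(area_ha = -5), "positive")
  expect_error(sim_config(fps_m = 0), "positive")
})

test_that("block orientation rotates lines without changing lengths", {
  blk <- build_block(sim_config(area_ha = 100, line_orientation_deg = 35))
  expect_equal(sum(blk$flight_lines$length_m) / 1000, 10, tolerance = 1e-10)
  dx <- blk$flight_lines$x1 - blk$flight_lines$x0
  dy <- blk$flight_lines$y1 - blk$flight_lines$y0
  expect_equal(sqrt(dx^2 + dy^2), blk$flight_lines$length_m,
               tolerance = 1e-9)
  # all lines share one bearing
  expect_equal(diff(range(atan2(dy, dx))), 0, tolerance = 1e-12)
})

test_that("flight simulation fixes follow the cadence and noise model", {
  blk <- build_block(sim_config(area_ha = 10, fps_m = 100))
  tr0 <- simulate_flight(blk, speed_kmh = 110, fix_interval_s = 2,
                         jitter_sd_m = 0, seed = 1)
  # 110 km/h, 2 s => 61.1 m between fixes
  step <- 110 / 3.6 * 2
  for (lid in unique(tr0$line_id)) {
    t <- tr0[tr0$line_id == lid, ]
    expect_equal(nrow(t), floor(blk$height_m / step) + 1)
    # zero jitter: fixes exactly on the (vertical) line
    expect_equal(diff(range(t$x_m)), 0, tolerance = 1e-9)
    expect_true(all(diff(as.numeric(t$time)) == 2))
  }
  # timestamps strictly increase across the whole operation
  expect_true(all(diff(as.numeric(tr0$time)) > 0))

  # RMS perpendicular distance to the line estimates the jitter sd
  big <- build_block(sim_config(area_ha = 5000, fps_m = 100))
  trj <- simulate_flight(big, speed_kmh = 110, fix_interval_s = 1,
                         jitter_sd_m = 5, seed = 7)
  perp <- abs(trj$x_m - rep(big$flight_lines$x0,
                            table(factor(trj$line_id,
                                         unique(trj$line_id)))))
  expect_gt(length(perp), 10000)
  expect_equal(sqrt(mean(perp^2)), 5, tolerance = 0.05)
})

test_that("population counts are Poisson at the intended density and seeded", {
  cfg <- sim_config(area_ha = 100, species_densities = c(possum = 2))
  blk <- build_block(cfg)
  expect_equal(nrow(simulate_population(blk,
    sim_config(area_ha = 100, species_densities = c(possum = 0)))), 0)
  counts <- vapply(1:400, function(s)
    nrow(simulate_population(blk, cfg, seed = s)), numeric(1))
  expect_lt(abs(mean(counts) - 200), 3 * sd(counts) / sqrt(400))
  # determinism: same seed, byte-identical output
  expect_identical(simulate_population(blk, cfg, seed = 11),
                   simulate_population(blk, cfg, seed = 11))
})

test_that("control kills independently at the species rate", {
  cfg <- sim_config(area_ha = 500,
                    species_densities = c(possum = 20, rat = 5))
  blk <- build_block(cfg)
  pop <- simulate_population(blk, cfg, seed = 3)
  expect_identical(apply_control(pop, c(possum = 0, rat = 0), seed = 1)$alive,
                   pop$alive)
  expect_false(any(apply_control(pop, c(possum = 1, rat = 1),
                                 seed = 1)$alive))
  expect_error(apply_control(pop, c(possum = 0.5), seed = 1), "rat")
  # survivor fraction within binomial 99% bounds at p = 0.95
  n <- sum(pop$species == "possum")
  expect_gt(n, 5000)
  surv <- sum(apply_control(pop, c(possum = 0.95, rat = 0),
                            seed = 9)$alive &
                pop$species == "possum") / n
  expect_lt(abs(surv - 0.05), 2.58 * sqrt(0.05 * 0.95 / n))
  # input untouched
  expect_true(all(pop$alive))
})

test_that("chewcard interference follows the detection law", {
  cfg <- sim_config(area_ha = 100, species_densities = c(possum = 0))
  blk <- build_block(cfg)
  pop <- simulate_population(blk, cfg)
  rec <- simulate_chewcard_survey(pop, blk, cfg, "pre")
  expect_true(all(rec$possum == 0))  # no animals, no interference
  expect_true(all(rec$nights == 6))

  # hazard saturation: theta*D*nights >> 1 => all cards hit
  cfg2 <- sim_config(area_ha = 100, species_densities = c(possum = 50),
                     detection_params = c(theta = 10,
                                          home_range_radius_m = 60))
  pop2 <- simulate_population(blk, cfg2, seed = 5)
  rec2 <- simulate_chewcard_survey(pop2, blk, cfg2, "pre", seed = 5)
  expect_equal(mean(rec2$possum), 1)

  # transform-linear law: constant c*D = pi/4, one night => mean line tCCI
  # near 45 degrees (arcsin(sqrt(0.5)))
  dens_grid <- 100  # one animal per 10 m grid cell
  cfgT <- sim_config(area_ha = 250, nights_chewcard = 1,
                     species_densities = c(possum = dens_grid),
                     detection_mode = "transform_linear",
                     detection_params = c(c = (pi / 4) / dens_grid,
                                          home_range_radius_m = 60))
  blkT <- build_block(cfgT)
  g <- expand.grid(x = seq(-55, blkT$width_m + 55, by = 10),
                   y = seq(-55, blkT$height_m + 55, by = 10))
  popT <- data.frame(id = as.character(seq_len(nrow(g))), species = "possum",
                     x_m = g$x, y_m = g$y, alive = TRUE)
  recT <- simulate_chewcard_survey(popT, blkT, cfgT, "pre", seed = 2)
  idx <- line_indices(recT, "possum")
  expect_equal(mean(idx$tcci), 45, tolerance = 4 / 45)

  # detection probability is monotone in local density in both modes
  D <- seq(0, 30, by = 0.5)
  p_haz <- 1 - exp(-0.065 * D * 6)
  p_lin <- sin(pmin((pi / 4 / 8) * D, pi / 2))^2
  expect_true(all(diff(p_haz) >= 0))
  expect_true(all(diff(p_lin) >= 0))
})

test_that("trap survey outcomes respect design and capture precedence", {
  cfg <- sim_config(area_ha = 250, species_densities = c(possum = 0),
                    nontarget_event_prob = 0)
  blk <- build_block(cfg)
  pop <- simulate_population(blk, cfg)
  rec <- simulate_trap_survey(pop, blk, cfg)
  expect_equal(nrow(rec), 8 * 10 * 3)
  expect_true(all(rec$outcome == "empty"))

  cfg0 <- sim_config(area_ha = 250, species_densities = c(possum = 10),
                     per_animal_capture_prob = 0)
  pop0 <- simulate_population(blk, cfg0, seed = 4)
  expect_equal(sum(simulate_trap_survey(pop0, blk, cfg0,
                                        seed = 4)$outcome ==
                     "possum_capture"), 0)

  # constructed layout: capture prob 1, one night => every trap with an
  # animal in range catches one
  cfg1 <- sim_config(area_ha = 250, per_animal_capture_prob = 1,
                     trap_nights = 1, nontarget_event_prob = 0)
  blk1 <- build_block(cfg1)
  traps <- baitline:::trap_layout(blk1, cfg1)
  # first trap of three separate lines: no earlier trap shares their range
  near <- traps[traps$trap_id %in% c("T01-01", "T03-01", "T06-01"), ]
  pop1 <- data.frame(id = sprintf("a%d", 1:5), species = "possum",
                     x_m = c(near$x_m + c(5, -10, 0), near$x_m[1] + 2e4,
                             near$x_m[2] + 2e4),
                     y_m = c(near$y_m + c(0, 5, -8), near$y_m[1], near$y_m[2]),
                     alive = TRUE)
  rec1 <- simulate_trap_survey(pop1, blk1, cfg1, seed = 1)
  expect_equal(sort(rec1$trap_id[rec1$outcome == "possum_capture"]),
               sort(near$trap_id))
})

test_that("ground baiting lays plots at the specified spacing and timing", {
  # a clean 1 km single line
  track <- data.frame(line_id = "L01",
                      x_m = 50, y_m = seq(0, 1000, by = 10),
                      time = as.POSIXct("2013-08-09 08:00:00", tz = "UTC") +
                        seq(0, 1000, by = 10))
  cfg <- sim_config(gps_noise_sd_m = 0, skip_fraction = 0,
                    per_plot_time_min = c(mean = 1.2, sd = 0))
  ev <- simulate_ground_baiting(track, cfg, seed = 1)
  expect_equal(nrow(ev), 50)  # 1000 m / 20 m
  expect_true(all(diff(as.numeric(ev$time)) > 0))
  # constant 1.2 min per plot: first-to-last elapsed = 49 * 1.2 min
  tim <- line_timing(ev)
  expect_equal(tim$elapsed_min, 49 * 1.2, tolerance = 1e-9)
  expect_equal(tim$mean_time_per_plot_min, 1.2, tolerance = 1e-9)
  expect_equal(ev$mass_g, rep(100, 50))

  # a 9% contiguous skip removes plots; expectation ~45.5 over random skips
  cfg9 <- sim_config(gps_noise_sd_m = 0, skip_fraction = 0.09)
  nplots <- vapply(1:300, function(s)
    nrow(simulate_ground_baiting(track, cfg9, seed = s)), numeric(1))
  expect_true(all(nplots %in% c(45, 46)))
  expect_equal(mean(nplots), 45.5, tolerance = 0.1)

  # per-plot times recovered within 2 SEs of the lognormal mean
  cfgT <- sim_config(gps_noise_sd_m = 0,
                     per_plot_time_min = c(mean = 1.67, sd = 0.5))
  evT <- simulate_ground_baiting(track, cfgT, seed = 2)
  dt <- diff(as.numeric(evT$time)) / 60
  expect_lt(abs(mean(dt) - 1.67), 2 * sd(dt) / sqrt(length(dt)))
})

test_that("identical config and seed give byte-identical operations", {
  cfg <- sim_config(seed = 99, area_ha = 50)
  blk <- build_block(cfg)
  pop <- simulate_population(blk, cfg)
  a <- simulate_chewcard_survey(pop, blk, cfg, "pre")
  b <- simulate_chewcard_survey(pop, blk, cfg, "pre")
  expect_identical(a, b)
  tr <- simulate_flight(blk, seed = 99)
  expect_identical(tr, simulate_flight(blk, seed = 99))
  expect_identical(simulate_ground_baiting(tr, cfg),
                   simulate_ground_baiting(tr, cfg))
})
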