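test_that("signal statistics match hand computations", {
  s <- signal_stats(c(-1, 0, 1))
  expect_equal(s$mean, 0)
  expect_equal(s$range, 2)
  expect_equal(s$sd, sqrt(2 / 3))
  expect_equal(s$max, 1)

  s2 <- signal_stats(rep(2, 10))
  expect_equal(unlist(s2), c(mean = 2, range = 0, sd = 0, max = 2))

  t <- seq(0, 2, by = 1 / 500)
  s3 <- signal_stats(3 * sin(2 * pi * t), t = t, interval = c(0, 2))
  expect_equal(s3$mean, 0, tolerance = 1e-3)
  expect_equal(s3$range, 6, tolerance = 1e-3)

  expect_error(signal_stats(numeric(0)), "empty")
  expect_error(signal_stats(1:5, t = 1:5, interval = c(10, 12)), "empty")
})

test_that("integral and momentum separate net from propulsive impulse", {
  # exact trapezoid on a duplicated-knot step signal
  t <- c(0, 1, 1, 2)
  x <- c(1, 1, -1, -1)
  im <- integral_and_momentum(x, t)
  expect_equal(im$int, 0, tolerance = 1e-12)
  expect_equal(im$momentum, 1, tolerance = 1e-12)

  t2 <- seq(0, 2, by = 0.01)
  im2 <- integral_and_momentum(rep(1, length(t2)), t2)
  expect_equal(im2$int, 2, tolerance = 1e-12)
  expect_equal(im2$momentum, 2, tolerance = 1e-12)

  im3 <- integral_and_momentum(rep(0, length(t2)), t2)
  expect_equal(unlist(im3), c(int = 0, momentum = 0))
})

test_that("efficiency ratios match piecewise integrals and flag zero denominators", {
  t <- c(0, 1, 1, 2)
  acc <- cbind(0, c(1, 1, -1, -1), 0)
  er <- efficiency_ratios(acc, t)
  expect_equal(er$eff, 1, tolerance = 1e-12)
  expect_equal(er$eff_dir, 0.5, tolerance = 1e-12)

  # all-positive forward acceleration: Eff undefined, Eff_dir = 1
  acc_pos <- cbind(0, c(1, 1, 1, 1), 0)
  expect_warning(er2 <- efficiency_ratios(acc_pos, t), "undefined")
  expect_true(is.na(er2$eff))
  expect_equal(er2$eff_dir, 1, tolerance = 1e-12)
})

test_that("distance per stroke integrates velocity over the cycle", {
  t <- seq(0, 5, by = 0.01)
  v <- tibble::tibble(t = t, v = 1.5)
  expect_equal(distance_per_stroke(v, c(1, 2.2)), 1.8, tolerance = 1e-9)

  v2 <- tibble::tibble(t = t, v = 1.5 + 0.2 * sin(2 * pi * (t - 1)))
  expect_equal(distance_per_stroke(v2, c(1, 2)), 1.5, tolerance = 1e-6)

  expect_warning(distance_per_stroke(v, c(1, 1.2)), "0.3 s")
})

test_that("the lap catalogue enumerates the full variable set", {
  cat_fc <- micro_variable_catalogue("front_crawl")
  expect_equal(nrow(cat_fc), 126)
  expect_equal(anyDuplicated(cat_fc$name), 0L)
  # per-phase composition: 12 propulsion, 6 posture, 2 efficiency (+DPS in
  # Swim), 9 gyro stats + duration (+2 kick, +3 stroke/cycle extras)
  counts <- table(cat_fc$phase)
  expect_equal(as.vector(counts[c("Push", "Glid", "StPr", "Swim")]),
               c(30L, 30L, 32L, 34L))
  expect_setequal(unique(cat_fc$category),
                  c("propulsion", "posture", "efficiency", "duration_rate"))
  # identical across techniques
  expect_identical(cat_fc, micro_variable_catalogue("backstroke"))
  expect_equal(nrow(cycle_variable_catalogue()), 31)
})

make_feature_inputs <- function() {
  fs <- 500
  t <- seq(0, 20 - 1 / fs, by = 1 / fs)
  swim_on <- 4
  roll <- 0.5 * sin(2 * pi * 0.8 * (t - swim_on)) * (t >= swim_on)
  gyr_y <- 0.5 * 2 * pi * 0.8 * cos(2 * pi * 0.8 * (t - swim_on)) * (t >= swim_on)
  acc_y <- ifelse(t < 1, 3, ifelse(t < 2.5, -0.4, ifelse(t < swim_on, 0.5, 0))) +
    0.3 * sin(2 * pi * 0.8 * (t - swim_on)) * (t >= swim_on)
  kick <- 2 * sin(2 * pi * 3 * (t - 2.5)) * (t >= 2.5 & t < swim_on)
  glob <- global_recording(t, acc_y = acc_y, gyr_x = kick, gyr_y = gyr_y,
                           theta = roll, phi = -pi + 0.1, fs = fs)
  anat <- imu_recording(t, matrix(0, length(t), 3), cbind(kick, gyr_y, 0),
                        fs = fs, frame = "anatomical")
  ann <- phase_annotation(
    c(0, 20), list(Push = c(0, 1), Glid = c(1, 2.5), StPr = c(2.5, swim_on),
                   Swim = c(swim_on, 20)), source = "synthetic")
  cyc <- cycle_set(seq(swim_on, 14, by = 1.25), "front_crawl")
  list(glob = glob, anat = anat, ann = ann, cyc = cyc)
}

test_that("extraction emits exactly the catalogue and sensible rate counts", {
  x <- make_feature_inputs()
  f <- suppressWarnings(
    extract_micro_variables(x$glob, x$anat, x$ann, x$cyc, "front_crawl",
                            on_undefined = "keep"))
  expect_equal(setdiff(names(f$lap), micro_variable_catalogue()$name),
               character(0))
  expect_equal(ncol(f$lap), 126)
  # 8 cycles at 0.8 Hz within a 16 s Swim phase
  expect_equal(f$lap[["Swim.StrokeCount"]], 8)
  expect_equal(f$lap[["Swim.StrokeRate"]], 60 * 8 / 16)
  expect_equal(f$lap[["Swim.CycleDuration"]], 1.25, tolerance = 1e-9)
  expect_equal(f$lap[["StPr.KickCount"]], 5) # 1.5 s at 3 Hz: 5 positive peaks
  expect_equal(f$lap[["Push.Duration"]], 1)
  # quiet glide: no roll spread, no posture spread
  expect_equal(f$lap[["Glid.Range(theta)"]], 0, tolerance = 1e-9)
  expect_equal(f$lap[["Glid.SD(AccY)"]], 0, tolerance = 1e-9)
  expect_equal(nrow(f$cycles), 8)
  expect_setequal(setdiff(names(f$cycles), "cycle"), cycle_variable_catalogue()$name)
})

test_that("undefined efficiency drops the lap observation by default", {
  x <- make_feature_inputs()
  glob2 <- x$glob
  glob2$acc_y <- abs(glob2$acc_y) + 0.1 # glide deceleration removed
  expect_warning(
    f <- extract_micro_variables(glob2, x$anat, x$ann, x$cyc, "front_crawl"),
    "dropping lap")
  expect_equal(nrow(f$lap), 0L)
})

test_that("statistics are invariant to sampling-rate doubling", {
  for (fs in c(250, 500)) {
    t <- seq(0, 10 - 1 / fs, by = 1 / fs)
    x <- 1.2 + sin(2 * pi * 0.7 * t) + 0.4 * cos(2 * pi * 1.3 * t)
    s <- signal_stats(x, t = t, interval = c(0, 10))
    im <- integral_and_momentum(x, t, c(0, 10))
    if (fs == 250) { s0 <- s; im0 <- im } else {
      expect_equal(s$mean, s0$mean, tolerance = 0.01)
      expect_equal(s$sd, s0$sd, tolerance = 0.01)
      expect_equal(im$int, im0$int, tolerance = 0.01)
      expect_equal(im$momentum, im0$momentum, tolerance = 0.01)
    }
  }
})

test_that("IMU-independent DPS path matches the generator to 5%", {
  lap <- simulate_lap(lap_scenario("front_crawl", pace = 0.9, seed = 21))
  ref <- correct_parallax(lap$reference, lap$scenario$parallax_h,
                          lap$scenario$parallax_d0)
  ci <- cycle_intervals(lap$cycles_true)
  v_df <- tibble::tibble(t = ref$t, v = ref$v)
  dps <- vapply(seq_len(nrow(ci)),
                function(k) distance_per_stroke(v_df, c(ci$on[k], ci$off[k])),
                numeric(1))
  dps_true <- lap$scenario$v_swim / lap$scenario$stroke_rate
  expect_lt(max(abs(dps - dps_true) / dps_true), 0.05)
})

test_that("feature tables are written with a category sidecar", {
  x <- make_feature_inputs()
  f <- suppressWarnings(
    extract_micro_variables(x$glob, x$anat, x$ann, x$cyc, "front_crawl",
                            meta = tibble::tibble(lap_id = 1L),
                            on_undefined = "keep"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(f$lap, path)
  expect_true(file.exists(path))
  cats <- jsonlite::read_json(paste0(path, ".categories.json"))
  expect_equal(length(cats), 126)
  expect_identical(cats[["Swim.DPS"]], "efficiency")
})
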