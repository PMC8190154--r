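test_that("met CSV round-trips and normalizes units", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "TIMESTAMP_START,TA,RH,NETRAD,G,H,LE,P",
    "201906010000,18.5,55,-35,5,10,-9999,0",
    "201906010100,19.0,60,500,50,150,220,1.2"), path)
  rec <- read_met_csv(path, tz_offset = -6)
  expect_equal(rec$RH, c(0.55, 0.60))
  expect_true(is.na(rec$LE[1]))
  expect_equal(rec$LE[2], 220)
  expect_equal(attr(rec, "tz_offset"), -6)

  # full-precision round trip of generated records
  ds <- gen_synthetic_dataset(tiny_config())
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_met_csv(ds$records, p2)
  back <- read_met_csv(p2, tz_offset = ds$config$tz_offset)
  for (col in c("Ta", "RH", "Rn", "G", "H", "LE", "P")) {
    expect_equal(back[[col]], ds$records[[col]], tolerance = 1e-12)
  }
  expect_identical(back$timestamp, ds$records$timestamp)

  # a ten-month hourly file parses to 24 rows/day
  days <- seq(as.Date("2019-01-01"), as.Date("2019-10-31"), by = "day")
  expect_equal(nrow(back) %% 24, 0)

  # schema error names the missing column
  p3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("TIMESTAMP_START,TA,RH,NETRAD,G,H,P",
               "201906010000,18,55,100,5,10,0"), p3)
  expect_error(read_met_csv(p3), "LE")

  # non-monotone timestamps rejected
  p4 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("TIMESTAMP_START,TA,RH,NETRAD,G,H,LE,P",
               "201906010100,18,55,100,5,10,50,0",
               "201906010000,18,55,100,5,10,50,0"), p4)
  expect_error(read_met_csv(p4), "increasing")
})

test_that("daytime mask is Rn > 0", {
  rec <- make_records(Rn = c(-35, 0, 500, NA))
  expect_identical(daytime_mask(rec), c(FALSE, FALSE, TRUE, FALSE))

  # synthetic clear-sky day: mask matches the generator's daylight window
  cfg <- tiny_config(cloud_prob = 0)
  met <- gen_met_series(cfg)
  met$LE <- met$G <- met$H <- 0
  h <- as.POSIXlt(met$timestamp)$hour
  expect_identical(daytime_mask(met),
                   h > cfg$sunrise_hour & h < cfg$sunset_hour)
})

test_that("linear gap filling interpolates in time and is idempotent", {
  rec <- make_records(Rn = 100, LE = c(10, NA, 30))
  expect_equal(gap_fill_linear(rec, "LE")$LE, c(10, 20, 30))

  rec2 <- make_records(Rn = 100, LE = c(0, NA, NA, 9))
  expect_equal(gap_fill_linear(rec2, "LE")$LE, c(0, 3, 6, 9))

  # identity on complete series
  rec3 <- make_records(Rn = 100, LE = c(5, 6, 7))
  expect_identical(gap_fill_linear(rec3, "LE")$LE, rec3$LE)

  # leading/trailing gaps extend the nearest value
  rec4 <- make_records(Rn = 100, LE = c(NA, 4, NA))
  expect_equal(gap_fill_linear(rec4, "LE")$LE, c(4, 4, 4))

  # idempotence property on a noisy gappy series
  set.seed(5)
  le <- rnorm(100, 100, 30)
  le[sample(100, 20)] <- NA
  rec5 <- make_records(Rn = 100, LE = le)
  once <- gap_fill_linear(rec5, "LE")
  expect_identical(gap_fill_linear(once, "LE")$LE, once$LE)
  expect_equal(attr(once, "n_filled"), 20)

  expect_error(gap_fill_linear(make_records(Rn = 1, LE = c(NA, NA)), "LE"),
               "missing")
})

test_that("negative daytime LE is screened and refilled, nighttime exempt", {
  rec <- make_records(Rn = c(500, 500, 500), LE = c(100, -20, 140))
  out <- screen_negative_daytime_le(rec)
  expect_equal(out$LE, c(100, 120, 140))
  expect_equal(attr(out, "n_screened"), 1)

  # nighttime negatives untouched
  rec2 <- make_records(Rn = c(-10, 500, -10), LE = c(-10, 50, -5))
  out2 <- screen_negative_daytime_le(rec2)
  expect_identical(out2$LE, rec2$LE)
  expect_equal(attr(out2, "n_screened"), 0)

  # all non-negative daytime: identity
  rec3 <- make_records(Rn = 500, LE = c(10, 20, 30))
  expect_identical(screen_negative_daytime_le(rec3)$LE, rec3$LE)

  # property: screening never leaves a negative daytime LE
  set.seed(6)
  for (i in 1:20) {
    n <- 48
    rec <- make_records(Rn = rep(c(rep(-20, 7), rep(400, 11), rep(-20, 6)),
                                 2),
                        LE = rnorm(n, 30, 60))
    out <- screen_negative_daytime_le(rec)
    expect_gte(min(out$LE[daytime_mask(out)]), 0)
  }
})

test_that("closure correction is the exact residual", {
  rec <- make_records(Rn = c(500, 0), G = c(50, 0), H = c(150, 0))
  expect_equal(closure_correct(rec), c(300, 0))

  # missing inputs propagate
  rec$G[1] <- NA
  expect_true(is.na(closure_correct(rec)[1]))

  # generator identity: corrected LE equals true LE without noise
  ds <- gen_synthetic_dataset(tiny_config(noise_sd = 0,
                                          closure_gap_fraction = 0.4))
  expect_equal(closure_correct(ds$records), ds$truth$le_total,
               tolerance = 1e-12)
  # closure conservation after correction, exact by definition
  lec <- closure_correct(ds$records)
  expect_identical(ds$records$Rn - ds$records$G - ds$records$H - lec,
                   rep(0, length(lec)))
})

test_that("NDVI stacks round-trip bit-exactly through ASCII grids", {
  ds <- gen_synthetic_dataset(tiny_config())
  dir <- withr::local_tempdir()
  write_ndvi_stack(ds$stack, dir)
  back <- read_ndvi_stack(dir)
  expect_identical(back$grids, ds$stack$grids)
  expect_identical(back$dates, ds$stack$dates)
  expect_equal(back$geotransform, ds$stack$geotransform)

  # out-of-order input paths come back date-sorted
  paths <- list.files(dir, full.names = TRUE)
  back2 <- read_ndvi_stack(rev(paths))
  expect_identical(back2$dates, ds$stack$dates)

  # single date
  one <- read_ndvi_stack(paths[1])
  expect_equal(length(one$dates), 1L)

  # alignment error on shape mismatch
  dir2 <- withr::local_tempdir()
  write_ndvi_stack(ds$stack, dir2)
  small <- ndvi_stack(as.Date("2019-06-30"), array(0.5, c(4, 4, 1)),
                      list(x_origin = 0, y_origin = 12, pixel_size = 3))
  write_ascii_grid <- getFromNamespace("write_ascii_grid", "fieldET")
  write_ascii_grid(small$grids[, , 1], file.path(dir2, "ndvi_2019-06-30.asc"),
                   small$geotransform)
  expect_error(read_ndvi_stack(dir2), "mismatch")

  # constructor sorts dates and validates range
  st <- ndvi_stack(as.Date(c("2019-06-02", "2019-06-01")),
                   array(0.5, c(2, 2, 2)),
                   list(x_origin = 0, y_origin = 6, pixel_size = 3))
  expect_identical(st$dates, as.Date(c("2019-06-01", "2019-06-02")))
  expect_error(ndvi_stack(as.Date("2019-06-01"), array(2, c(2, 2, 1))),
               "\\[-1, 1\\]")
})

test_that("boundaries validate and round-trip through GeoJSON", {
  b <- field_boundary(rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10)),
                      site_id = "US-Ne9")
  expect_equal(b$area, 100)

  path <- withr::local_tempfile(fileext = ".geojson")
  write_boundary(b, path)
  back <- read_boundary(path)
  expect_equal(back$coords, b$coords)
  expect_identical(back$site_id, "US-Ne9")

  expect_error(field_boundary(rbind(c(0, 0), c(1, 1), c(2, 2))), "area")
  crossed <- rbind(c(0, 0), c(4, 0), c(4, 3), c(2, -1))
  expect_error(field_boundary(crossed), "self-intersecting")
})

test_that("point_in_polygon agrees with the mgcv oracle", {
  skip_if_not_installed("mgcv")
  set.seed(7)
  poly <- rbind(c(0, 0), c(6, -1), c(9, 4), c(5, 8), c(-1, 5), c(0, 0))
  px <- runif(500, -2, 10)
  py <- runif(500, -2, 9)
  mine <- point_in_polygon(px, py, poly)
  oracle <- mgcv::in.out(poly, cbind(px, py))
  expect_identical(mine, as.logical(oracle))
})
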