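make_field <- function(vals, axis, lat = c(41, 41.5), lon = c(4, 4.5, 5),
                       name = "schl", units = "mg m-3") {
  grid_field(name, units, lat, lon, axis, vals)
}

test_that("the 8-day axis is anchored to Jan 1 with a truncated last window", {
  ax <- time_axis_8day(2001, 2)
  expect_equal(ax$n_steps, 92)
  expect_equal(ax$start[1], as.Date("2001-01-01"))
  expect_equal(ax$start[47], as.Date("2002-01-01"))
  expect_equal(as.numeric(ax$end[46] - ax$start[46]), 5)
  expect_equal(ax$end[46], as.Date("2002-01-01"))
  expect_equal(ax$center[1], as.Date("2001-01-05"))
  expect_true(all(diff(as.numeric(ax$center)) > 0))
})

test_that("grid_field validates coordinates and reshapes values", {
  ax <- time_axis_8day(2001, 1)
  f <- make_field(1, ax)
  expect_equal(dim(f$values), c(46, 2, 3))
  expect_error(make_field(1, ax, lat = c(41, 40)), "increasing")
  expect_error(make_field(1, ax, lat = c(41, 41.5, 42.5)), "regular")
  expect_error(grid_field("x", "", c(41), c(4), ax, 1))
})

test_that("aggregate_time_8day averages daily values into windows", {
  target <- time_axis_8day(2001, 1)
  daily <- time_axis_daily("2001-01-01", 365)
  v <- array(2.5, c(365, 2, 3))
  f <- make_field(v, daily)
  out <- aggregate_time_8day(f, target)
  expect_equal(out$values[10, 1, 1], 2.5)
  v2 <- array(NA_real_, c(365, 2, 3))
  v2[1:8, , ] <- 1:8
  out2 <- aggregate_time_8day(make_field(v2, daily), target)
  expect_equal(out2$values[1, 2, 3], 4.5)
})

test_that("windows with under 4 valid days are masked, 5 of 8 kept", {
  target <- time_axis_8day(2001, 1)
  daily <- time_axis_daily("2001-01-01", 365)
  v <- array(NA_real_, c(365, 1, 1))
  v[1:8] <- c(1, NA, 3, NA, 5, NA, 7, 9)
  v[9:11] <- c(2, NA, NA)  # 3 valid days in window 2... still < 4
  f <- grid_field("x", "u", 41, 4, daily, v)
  out <- aggregate_time_8day(f, target)
  expect_equal(out$values[1, 1, 1], mean(c(1, 3, 5, 7, 9)))
  expect_true(is.na(out$values[2, 1, 1]))
})

test_that("aggregating an 8-day series onto its own axis is the identity", {
  ax <- time_axis_8day(2001, 1)
  v <- array(runif(46 * 2 * 3), c(46, 2, 3))
  f <- make_field(v, ax)
  out <- aggregate_time_8day(f, ax)
  expect_equal(out$values, v)
})

test_that("aggregation rejects non-overlapping series", {
  target <- time_axis_8day(2001, 1)
  daily <- time_axis_daily("2010-01-01", 30)
  f <- grid_field("x", "u", 41, 4, daily, array(1, c(30, 1, 1)))
  expect_error(aggregate_time_8day(f, target), "overlap")
})

test_that("bilinear regridding is the identity on the same grid", {
  ax <- time_axis_8day(2001, 1)
  v <- array(runif(46 * 2 * 3), c(46, 2, 3))
  f <- make_field(v, ax)
  out <- regrid_bilinear(f, f$lat, f$lon)
  expect_equal(out$values, v, tolerance = 1e-12)
})

test_that("bilinear regridding is exact on planar fields", {
  ax <- time_axis_8day(2001, 1)
  lat <- c(40, 41, 42, 43); lon <- c(3, 4, 5)
  grid <- expand.grid(lat = lat, lon = lon)
  plane <- matrix(2 * grid$lat - 3 * grid$lon + 1, 4, 3)
  v <- array(rep(plane, each = 46), c(46, 4, 3))
  f <- grid_field("x", "u", lat, lon, ax, v)
  tl <- c(40.3, 41.7); tn <- c(3.25, 4.5)
  out <- regrid_bilinear(f, tl, tn)
  want <- outer(tl, tn, function(a, b) 2 * a - 3 * b + 1)
  expect_equal(out$values[5, , ], want, tolerance = 1e-10)
})

test_that("cell-center query of corners (0,0,0,4) gives 1.0", {
  ax <- time_axis_8day(2001, 1)
  z <- matrix(c(0, 0, 0, 4), 2, 2)
  v <- array(rep(z, each = 46), c(46, 2, 2))
  f <- grid_field("x", "u", c(0, 1), c(0, 1), ax, v)
  out <- regrid_bilinear(f, 0.5, 0.5)
  expect_equal(out$values[1, 1, 1], 1.0)
})

test_that("a masked stencil cell masks the interpolated point", {
  ax <- time_axis_8day(2001, 1)
  z <- matrix(c(NA, 2, 3, 4, 5, 6), 2, 3)
  v <- array(rep(z, each = 46), c(46, 2, 3))
  f <- grid_field("x", "u", c(0, 1), c(0, 1, 2), ax, v)
  out <- regrid_bilinear(f, 0.5, c(0.5, 1.5))
  expect_true(is.na(out$values[1, 1, 1]))
  expect_equal(out$values[1, 1, 2], mean(c(3, 4, 5, 6)))
  expect_error(regrid_bilinear(grid_field("x", "u", 41, 4, ax,
                                          array(1, c(46, 1, 1))), 41, 4),
               "2 points")
})

test_that("box means average unmasked pixels in the closed box", {
  ax <- time_axis_8day(2001, 1)
  v <- array(0.4, c(46, 2, 3)); v[, 2, 1] <- 0.8
  f <- make_field(v, ax)
  expect_equal(extract_box_mean(f, c(40, 42), c(3.9, 4.1)),
               rep(0.6, 46))
  expect_equal(extract_box_mean(f, c(41.4, 41.6), c(3.9, 4.1)),
               rep(0.8, 46))
  expect_error(extract_box_mean(f, c(10, 11), c(3.9, 4.1)), "no grid")
})

test_that("NetCDF bundle round-trips values, mask, units and axis", {
  cfg <- sim_config(n_years = 3, seed = 5, n_lat = 2, n_lon = 2)
  b <- simulate_dataset(cfg)
  b$nhf$values[3, 1, 1] <- NA
  path <- tempfile(fileext = ".nc")
  write_bundle(b, path)
  b2 <- read_bundle(path)
  expect_equal(b2$schl$values, b$schl$values, tolerance = 1e-12)
  expect_true(is.na(b2$nhf$values[3, 1, 1]))
  expect_equal(b2$ws$units, "N m-2")
  expect_equal(b2$schl$axis$center, b$schl$axis$center)
  expect_equal(b2$schl$axis$start, b$schl$axis$start)
  unlink(path)
})

test_that("a NetCDF file lacking a variable is rejected naming it", {
  cfg <- sim_config(n_years = 3, seed = 5)
  b <- simulate_dataset(cfg)
  path <- tempfile(fileext = ".nc")
  ax <- b$schl$axis
  dim_lon <- ncdf4::ncdim_def("lon", "degrees_east", b$schl$lon)
  dim_lat <- ncdf4::ncdim_def("lat", "degrees_north", b$schl$lat)
  dim_time <- ncdf4::ncdim_def("time", "days since 1970-01-01",
                               as.numeric(ax$center))
  v <- ncdf4::ncvar_def("schl", "mg m-3",
                        list(dim_lon, dim_lat, dim_time), 1e30)
  nc <- ncdf4::nc_create(path, list(v))
  ncdf4::ncvar_put(nc, v, aperm(b$schl$values, c(3, 2, 1)))
  ncdf4::nc_close(nc)
  expect_error(read_bundle(path), "nhf")
  unlink(path)
})

test_that("pixel CSV round-trips with ISO dates and a 3-row axis", {
  cfg <- sim_config(n_years = 3, seed = 5)
  b <- simulate_dataset(cfg)
  path <- tempfile(fileext = ".csv")
  write_pixel_csv(b, path)
  got <- read_pixel_csv(path)
  expect_equal(got$axis$n_steps, b$schl$axis$n_steps)
  expect_equal(got$data$schl, b$schl$values[, 1, 1], tolerance = 1e-6)
  lines <- readLines(path, n = 2)
  expect_match(lines[2], "^\\d{4}-\\d{2}-\\d{2},")
  short <- tempfile(fileext = ".csv")
  writeLines(c("date_start,date,date_end,schl,nhf,ws",
               "2001-01-01,2001-01-05,2001-01-09,0.5,-100,0.1",
               "2001-01-09,2001-01-13,2001-01-17,0.6,-90,0.1",
               "2001-01-17,2001-01-21,2001-01-25,0.7,-80,0.2"), short)
  expect_equal(read_pixel_csv(short)$axis$n_steps, 3)
  bad <- tempfile(fileext = ".csv")
  writeLines(c("date_start,date_end,schl,ws",
               "2001-01-01,2001-01-09,0.5,0.1"), bad)
  expect_error(read_pixel_csv(bad), "nhf")
  unlink(c(path, short, bad))
})
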