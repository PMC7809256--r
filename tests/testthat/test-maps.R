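const_bundle <- function(schl_val, n_years = 2, lat = c(41, 41.5),
                         lon = c(4, 4.5)) {
  ax <- time_axis_8day(2001, n_years)
  mk <- function(name, units, val)
    grid_field(name, units, lat, lon, ax,
               array(val, c(ax$n_steps, length(lat), length(lon))))
  forcing_bundle(mk("schl", "mg m-3", schl_val), mk("nhf", "W m-2", -50),
                 mk("ws", "N m-2", 0.05))
}

test_that("seasonal climatology averages the right months", {
  b <- const_bundle(0.7)
  clim <- seasonal_climatology(b$schl, "winter")
  expect_equal(as.vector(clim$values), rep(0.7, 4))
  ax <- b$schl$axis
  v <- array(ifelse(axis_month(ax) %in% 3:4, 1, -1),
             c(ax$n_steps, 2, 2))
  f <- grid_field("schl", "mg m-3", c(41, 41.5), c(4, 4.5), ax, v)
  expect_equal(as.vector(seasonal_climatology(f, "spring")$values),
               rep(1, 4))
  expect_error(seasonal_climatology(f, "autumn"))
})

test_that("two years of differing spring means average to their mean", {
  ax <- time_axis_8day(2001, 2)
  spring <- season_mask(ax, "spring")
  v <- array(NA_real_, c(ax$n_steps, 1, 1))
  v[spring & ax$year == 2001] <- 0.4
  v[spring & ax$year == 2002] <- 0.8
  v[!spring] <- 0.1
  f <- grid_field("schl", "mg m-3", 41, 4, ax, v)
  expect_equal(as.vector(seasonal_climatology(f, "spring")$values), 0.6)
})

test_that("bloom mask uses a strict 0.65 threshold", {
  ax <- time_axis_8day(2001, 1)
  mkclim <- function(vals)
    grid_field("clim", "mg m-3", c(41, 41.5), c(4, 4.5),
               time_axis_from_dates(ax$start[1], ax$end[1]),
               array(vals, c(1, 2, 2)))
  m <- bloom_mask(mkclim(c(0.64, 0.66, 0.65, NA)))
  expect_equal(as.vector(m), c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(sum(bloom_mask(mkclim(rep(0, 4)))), 0)
  expect_error(bloom_mask(mkclim(rep(1, 4)), threshold = -1),
               "non-negative")
})

test_that("bloom mask matches a brute-force per-pixel comparison", {
  b <- simulate_dataset(sim_config(n_years = 8, seed = 42, n_lat = 2,
                                   n_lon = 5))
  clim <- seasonal_climatology(b$schl, "spring")
  mask <- bloom_mask(clim)
  spring <- season_mask(b$schl$axis, "spring")
  for (i in 1:2) for (j in 1:5) {
    want <- mean(b$schl$values[spring, i, j]) > 0.65
    expect_identical(mask[i, j], want)
  }
  expect_gt(sum(mask), 0)
  expect_lt(sum(mask), length(mask))
})

test_that("sign agreement is 100% for equal and 0% for opposed signs", {
  ax <- time_axis_8day(2001, 2)
  n <- ax$n_steps - 1
  set.seed(6)
  g <- array(rnorm(n * 2), c(n, 1, 2))
  m <- sign_agreement_map(g, g, ax, "winter", "nhf", 41, c(4, 4.5))
  expect_equal(as.vector(m$values), c(100, 100))
  m0 <- sign_agreement_map(g, -g, ax, "winter", "nhf", 41, c(4, 4.5))
  expect_equal(as.vector(m0$values), c(0, 0))
})

test_that("independent random signs agree near 50%", {
  # an axis whose window centers all fall in January, so every one of
  # the 1001 intervals counts as winter
  years <- rep(1500 + seq_len(501), each = 2)
  starts <- as.Date(paste0(years, c("-01-01", "-01-09")))
  ax <- time_axis_from_dates(starts[1:1002])
  set.seed(7)
  g <- array(sample(c(-1, 1), 1001, TRUE), c(1001, 1, 1))
  d <- array(sample(c(-1, 1), 1001, TRUE), c(1001, 1, 1))
  m <- sign_agreement_map(g, d, ax, "winter", "nhf", 41, 4)
  expect_gt(m$values[1, 1, 1], 45)
  expect_lt(m$values[1, 1, 1], 55)
})

test_that("driver negation complements the agreement to 100%", {
  b <- simulate_dataset(sim_config(n_years = 6, seed = 10, n_lat = 1,
                                   n_lon = 2))
  ax <- b$schl$axis
  n <- ax$n_steps - 1
  g <- array(NA_real_, c(n, 1, 2)); d <- g
  for (j in 1:2) {
    g[, 1, j] <- net_growth_rate(b$schl$values[, 1, j])
    d[, 1, j] <- forward_derivative(b$nhf$values[, 1, j])
  }
  m1 <- sign_agreement_map(g, d, ax, "winter", "nhf", 41, c(4, 4.5))
  m2 <- sign_agreement_map(g, -d, ax, "winter", "nhf", 41, c(4, 4.5))
  expect_equal(as.vector(m1$values + m2$values), c(100, 100))
})

test_that("the wind-stress driver counts opposite signs as agreement", {
  ax <- time_axis_8day(2001, 2)
  n <- ax$n_steps - 1
  set.seed(8)
  g <- array(rnorm(n), c(n, 1, 1))
  m <- sign_agreement_map(g, -g, ax, "winter", "ws", 41, 4)
  expect_equal(as.vector(m$values), 100)
})

test_that("the wind-stress driver echoes the heat-flux relationship", {
  # dWS and dNHF are anti-coupled, so the WS-driver winter map carries
  # the same relationship; it is noisier than the NHF map because WS
  # between storms is nearly flat, so only above-chance agreement is a
  # robust property.
  b <- simulate_dataset(sim_config(n_years = 50, seed = 42))
  px <- bundle_pixel(b)
  ax <- b$schl$axis
  n <- ax$n_steps - 1
  g <- array(net_growth_rate(px$schl), c(n, 1, 1))
  dn <- array(forward_derivative(px$nhf), c(n, 1, 1))
  dw <- array(forward_derivative(px$ws), c(n, 1, 1))
  m_nhf <- sign_agreement_map(g, dn, ax, "winter", "nhf", 41, 4)
  m_ws <- sign_agreement_map(g, dw, ax, "winter", "ws", 41, 4)
  expect_gt(m_ws$values[1, 1, 1], 50)
  expect_lt(abs(m_nhf$values[1, 1, 1] - m_ws$values[1, 1, 1]), 25)
  expect_lt(stats::cor(dn, dw), -0.55)
})

test_that("pixels with under 5 countable intervals are masked", {
  ax <- time_axis_8day(2001, 1)
  n <- ax$n_steps - 1
  g <- array(0, c(n, 1, 1))
  g[1:4, 1, 1] <- 1
  m <- sign_agreement_map(g, g, ax, "winter", "nhf", 41, 4)
  expect_true(is.na(m$values[1, 1, 1]))
})

test_that("ASCII mask export round-trips", {
  mask <- matrix(c(TRUE, FALSE, FALSE, TRUE, TRUE, FALSE), 2, 3)
  path <- tempfile(fileext = ".txt")
  write_mask_ascii(mask, c(41, 41.5), c(4, 4.5, 5), path)
  got <- read_mask_ascii(path)
  expect_identical(got$mask, mask)
  expect_equal(got$lat, c(41, 41.5))
  expect_equal(got$lon, c(4, 4.5, 5))
  expect_false(any(grepl("[^0-9a-z. -]", readLines(path))))
  unlink(path)
})
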