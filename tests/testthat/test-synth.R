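test_that("synthetic MRIO tables are productive and balanced", {
  m <- synth_mrio(2, 2, seed = 0)
  expect_equal(dim(m$A), c(4L, 4L))
  expect_lte(spectral_radius(m$A), 0.7)
  expect_true(all(m$A >= 0) && all(m$y >= 0))
  resid <- m$x - as.numeric(m$A %*% m$x) - rowSums(m$y, dims = 1)
  expect_lt(max(abs(resid)) / max(m$x), 1e-10)
  ## household demand present in every consuming region
  expect_true(all(apply(m$y[, 1:2, ], c(2, 3), sum) > 0))
  expect_identical(synth_mrio(3, 4, seed = 9), synth_mrio(3, 4, seed = 9))
})

test_that("synthetic surveys respect the yearbook grouping scheme", {
  sv <- synth_survey(8, sprintf("S%d", 1:6), seed = 2)$survey_complete
  for (st in c("rural", "urban")) {
    g <- sv$groups[sv$groups$setting == st, ]
    fr_sum <- tapply(g$frac, g$province, sum)
    expect_equal(as.numeric(fr_sum), rep(1, 8))
    for (p in unique(g$province)) {
      inc <- g$income[g$province == p][order(g$group[g$province == p])]
      expect_true(all(diff(inc) > 0))       # strictly increasing with group
    }
    expect_true(all(g$pph >= 1 & g$pph <= 6))
    ## expenditure shares shift toward late (service) sectors with income
    v <- sv$expenditure[[st]][, , 1]
    shares <- sweep(v, 2, colSums(v), "/")
    L <- nrow(shares)
    expect_gt(shares[L, ncol(shares)], shares[L, 1])
    expect_lt(shares[1, ncol(shares)], shares[1, 1])
    expect_equal(unname(colSums(shares)), rep(1, ncol(shares)))
  }
})

test_that("masked surveys match the yearbook missing-data situation", {
  out <- synth_survey(10, sprintf("S%d", 1:4), seed = 3,
                      missing_rural = 0.4, missing_urban = 0.1)
  pr <- out$survey$provinces
  expect_equal(sum(pr$missing[pr$setting == "rural"]), 4L)
  expect_equal(sum(pr$missing[pr$setting == "urban"]), 1L)
  miss <- pr$province[pr$setting == "rural" & pr$missing][1]
  expect_true(all(is.na(
    out$survey$groups$income[out$survey$groups$province == miss &
                             out$survey$groups$setting == "rural"])))
  expect_false(anyNA(out$survey_complete$groups$income))
})

test_that("biomass survey generator follows the fitted power law", {
  ## noise-free: unit income returns the coefficient itself
  b <- synth_biomass_survey(1, sigma = 0, seed = 1)
  expect_equal(b$biomass, 0.7072)
  ## noise-free points are exactly collinear in log-log space
  b <- synth_biomass_survey(c(10, 100, 1000, 12345), sigma = 0, seed = 1)
  fit <- lm(log(biomass) ~ log(income), data = b)
  expect_lt(max(abs(residuals(fit))), 1e-12)
  expect_equal(unname(coef(fit)[2]), -0.18, tolerance = 1e-12)
  ## with noise, OLS recovers the generating exponent to 2 decimals
  set.seed(11)
  incomes <- 10^runif(1000, 3, 5)
  b <- synth_biomass_survey(incomes, sigma = 0.05, seed = 11)
  slope <- unname(coef(lm(log(biomass) ~ log(income), data = b))[2])
  expect_equal(round(abs(slope), 2), 0.18)
  expect_error(synth_biomass_survey(c(1, -2)), "positive")
})

test_that("synthetic fields are nonnegative, additive and kernel-consistent", {
  scen <- test_scenario()
  f <- scen$fields
  expect_true(all(scen$emissions$gridded >= 0))
  expect_true(all(f$population >= 0))
  expect_true(all(f$sens >= 0))
  expect_true(all(f$pm25_all >= f$pm25_no_anth))
  ## gridded sector fields conserve regional totals per species/sector
  R <- length(scen$config$provinces)
  gm <- array(scen$emissions$gridded,
              c(prod(dim(f$population)), dim(scen$emissions$gridded)[3:4]))
  for (r in seq_len(R)) {
    got <- apply(gm[which(f$province_map == r), , , drop = FALSE],
                 c(2, 3), sum)
    expect_equal(got, scen$emissions$totals[r, , ], tolerance = 1e-6)
  }
  ## sensitivity peaks at or upwind (west) of the receptor population mass
  g <- scen$config$grid
  lon <- matrix(g$lon, g$nlat, g$nlon, byrow = TRUE)
  lat <- matrix(g$lat, g$nlat, g$nlon)
  for (rc in seq_along(scen$receptors)) {
    popw <- f$population * (f$receptor_map == rc)
    c_lon <- sum(lon * popw) / sum(popw)
    c_lat <- sum(lat * popw) / sum(popw)
    i <- arrayInd(which.max(f$sens[, , 1, rc]), dim(f$population))
    exp_lon <- c_lon - f$kernel$drift_lon       # plume drifts east
    d <- sqrt((lon[i] - exp_lon)^2 + (lat[i] - c_lat)^2)
    expect_lt(d, 2 * f$kernel$sigma_deg)
    expect_lte(lon[i], c_lon + g$dlon / 2 + 1e-9)  # not downwind of center
  }
})

test_that("scenario regeneration with the same seed is bit-identical", {
  a <- synth_scenario(R = 3, L = 3, seed = 5,
                      grid = ch_grid(100, 106, 24, 28), n_receptors = 2)
  b <- synth_scenario(R = 3, L = 3, seed = 5,
                      grid = ch_grid(100, 106, 24, 28), n_receptors = 2)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
})
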