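test_that("IER relative risk has the right boundary, saturation and shape", {
  p <- list(alpha = 1.2, gamma = 0.05, delta = 0.8, C0 = 7)
  expect_equal(ier_relative_risk(7, p), 1)            # RR(C0) = 1
  expect_equal(ier_relative_risk(0, p), 1)
  expect_equal(ier_relative_risk(1e7, p), 1 + p$alpha, tolerance = 1e-8)
  ## continuity at C0 and monotonicity in C for every endpoint
  for (ep in ch_endpoints()) {
    tab <- ier_parameters()
    pp <- as.list(tab[tab$endpoint == ep, ])
    expect_lt(ier_relative_risk(pp$C0 + 1e-12, pp) - 1, 1e-5)
    C <- seq(0, 300, by = 0.5)
    rr <- ier_relative_risk(C, pp)
    expect_true(all(diff(rr) >= 0))
    expect_true(all(rr <= 1 + pp$alpha))
  }
  ## delta = 1 closed form: at C - C0 = 1/gamma, RR = 1 + alpha(1 - e^-1)
  p1 <- list(alpha = 0.9, gamma = 0.04, delta = 1, C0 = 5)
  expect_equal(ier_relative_risk(5 + 1 / 0.04, p1),
               1 + 0.9 * (1 - exp(-1)), tolerance = 1e-12)
  expect_error(ier_relative_risk(10, list(alpha = -1, gamma = 1, delta = 1,
                                          C0 = 0)), "invalid")
})

test_that("mortality arithmetic matches the attributable-fraction formula", {
  expect_equal(mortality(2, 0.01, 1e5), 500)      # AF = 1/2
  expect_equal(mortality(1, 0.01, 1e5), 0)        # no excess risk
  expect_error(mortality(0.99, 0.01, 1e5), "below 1")
  ## attributable fraction strictly below 1 for finite RR
  rr <- 1 + 10^seq(-3, 3, 1)
  expect_true(all((rr - 1) / rr < 1))
  ## monotone in concentration, population and incidence
  p <- as.list(ier_parameters()[1, ])
  C <- c(10, 20, 40); P <- c(1e4, 2e4); B <- c(0.001, 0.002)
  m1 <- mortality(ier_relative_risk(C, p), B[1], P[1])
  expect_true(all(diff(m1) > 0))
  expect_true(all(mortality(ier_relative_risk(C, p), B[1], P[2]) > m1))
  expect_true(all(mortality(ier_relative_risk(C, p), B[2], P[1]) > m1))
})

test_that("anthropogenic scaling is the concentration ratio per cell", {
  expect_equal(anthropogenic_mortality(100, 50, 10), 80)   # factor 0.8
  expect_equal(anthropogenic_mortality(100, 50, 0), 100)
  expect_equal(anthropogenic_mortality(100, 50, 50), 0)
  expect_error(anthropogenic_mortality(100, 50, 60), "exceeds")
})

test_that("summed cell mortality differs from aggregated-exposure mortality", {
  ## the IER is concave in C above C0, so computing on a spatial mean
  ## concentration does not reproduce the summed per-cell burden
  p <- as.list(ier_parameters()[1, ])
  C <- c(15, 150); P <- c(1e5, 1e5); B <- 0.001
  per_cell <- sum(mortality(ier_relative_risk(C, p), B, P))
  aggregated <- mortality(ier_relative_risk(mean(C), p), B, sum(P))
  expect_gt(abs(per_cell - aggregated) / per_cell, 0.01)
})

test_that("Monte-Carlo intervals bracket the central estimate and stabilize", {
  scen <- small_scenario()
  f <- scen$fields
  nrec <- length(scen$receptors)
  ## zero parameter spread collapses to the point estimate with a warning
  expect_warning(
    mc0 <- monte_carlo_ci(f$pm25_all, f$pm25_no_anth, f$population,
                          f$receptor_map, nrec, n_draws = 100, seed = 1,
                          cv = 0),
    "degenerate")
  expect_equal(mc0$lower, mc0$central, tolerance = 1e-12)
  expect_equal(mc0$upper, mc0$central, tolerance = 1e-12)
  mc1 <- monte_carlo_ci(f$pm25_all, f$pm25_no_anth, f$population,
                        f$receptor_map, nrec, n_draws = 150, seed = 2)
  expect_true(all(mc1$lower <= mc1$central & mc1$central <= mc1$upper))
  mc2 <- monte_carlo_ci(f$pm25_all, f$pm25_no_anth, f$population,
                        f$receptor_map, nrec, n_draws = 300, seed = 2)
  expect_lt(max(abs(mc2$lower - mc1$lower) / mc1$central), 0.05)
  expect_lt(max(abs(mc2$upper - mc1$upper) / mc1$central), 0.05)
  expect_error(monte_carlo_ci(f$pm25_all, f$pm25_no_anth, f$population,
                              f$receptor_map, nrec, n_draws = 10), "100")
})
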