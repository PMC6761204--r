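test_that("semi-normalized sensitivity is the elementwise product", {
  scen <- small_scenario()
  run <- run_pipeline(scen)
  E <- run$beta$E_cell
  ss <- semi_normalized_sensitivity(scen$fields$sens, E)
  expect_equal(semi_normalized_sensitivity(scen$fields$sens, 0 * E),
               0 * ss)
  expect_equal(semi_normalized_sensitivity(scen$fields$sens, 2 * E), 2 * ss)
  ## quadrature oracle: the SS total per receptor equals the
  ## kernel-weighted emission total computed directly from the generating
  ## kernel and populations
  kern <- scen$fields$kernel$matrix
  pop <- as.vector(scen$fields$population)
  for (rc in seq_along(scen$receptors)) {
    popw <- pop * (as.vector(scen$fields$receptor_map) == rc)
    direct <- 0
    for (k in seq_along(scen$config$species)) {
      direct <- direct + 1e-6 * scen$fields$w_species[k] *
        sum(crossprod(kern, popw) * as.vector(E[, , k]))
    }
    expect_equal(sum(ss[, , , rc]), direct, tolerance = 1e-10)
  }
})

test_that("percentage contributions normalize to 100 per receptor", {
  g <- c(3, 4, 2)   # nlat, nlon, K
  ss <- array(0, g)
  ss[2, 2, 1] <- 5
  p <- percentage_contribution(ss)
  expect_equal(p[2, 2, 1], 100)               # single nonzero cell
  ss_u <- array(1, g)
  expect_equal(percentage_contribution(ss_u),
               array(100 / prod(g), g))       # uniform field
  set.seed(9)
  ss_r <- array(rexp(prod(g)), g)
  expect_equal(sum(percentage_contribution(ss_r)), 100, tolerance = 1e-9)
  expect_error(percentage_contribution(array(0, g)), "all-zero")
  scen <- test_scenario()
  run <- test_run()
  P <- percentage_contribution(
    semi_normalized_sensitivity(scen$fields$sens, run$beta$E_cell))
  for (rc in seq_along(scen$receptors)) {
    expect_equal(sum(P[, , , rc]), 100, tolerance = 1e-9)
  }
})

test_that("death attribution captures totals for degenerate ratio fields", {
  nlat <- 2; nlon <- 2; K <- 1; S <- 2; nc <- 3; nrec <- 2
  mk_beta <- function(val) {
    structure(list(
      house = array(0, c(nlat, nlon, K, S, nc)),
      house_direct = array(0, c(nlat, nlon, K, S, nc)),
      house_indirect = array(0, c(nlat, nlon, K, S, nc)),
      other = array(0, c(nlat, nlon, K, 3)),
      E_cell = array(1, c(nlat, nlon, K))), class = "beta_fields")
  }
  P <- array(0, c(nlat, nlon, K, nrec))
  P[, , 1, 1] <- 25; P[, , 1, 2] <- 25       # uniform percentages
  M_r <- c(40, 60)
  b1 <- mk_beta()
  b1$house[, , 1, 2, 3] <- 1                 # one class captures everything
  b1$house_indirect <- b1$house
  attr1 <- attribute_deaths(M_r, P, b1)
  expect_equal(attr1$house[2, 3, ], M_r)
  expect_equal(sum(attr1$house), sum(M_r))
  expect_equal(attr1$external, c(0, 0))
  b0 <- mk_beta()
  attr0 <- attribute_deaths(M_r, P, b0)
  expect_equal(sum(attr0$house), 0)          # beta = 0: nothing attributed
  expect_equal(attr0$external, M_r)          # everything is residual
})

test_that("full attribution is additive and conserves receptor deaths", {
  run <- test_run()
  a <- run$attribution
  total_attributed <- sum(a$house) + sum(a$other) + sum(a$external)
  expect_equal(total_attributed, sum(a$M_receptor), tolerance = 1e-6)
  expect_equal(a$house, a$house_direct + a$house_indirect, tolerance = 1e-10)
  expect_true(all(a$house >= 0) && all(a$other >= 0))
  expect_true(all(a$external > -1e-9))
})

test_that("attributed group shares match the scenario's analytic truth", {
  scen <- test_scenario()
  run <- test_run()
  a <- run$attribution
  sh <- array(0, dim(scen$truth$share_house))
  for (rc in seq_along(scen$receptors)) {
    sh[rc, , ] <- a$house[, , rc] / a$M_receptor[rc]
  }
  rel <- abs(sh - scen$truth$share_house) /
    pmax(scen$truth$share_house, 1e-12)
  expect_lt(max(rel), 1e-6)
})

test_that("cross-region summary marginalizes the attribution correctly", {
  run <- test_run()
  cr <- run$cross_region
  a <- run$attribution
  expect_equal(sum(cr$matrix), sum(a$house), tolerance = 1e-9)
  expect_true(all(cr$offdiagonal_share$offdiagonal_share >= 0 &
                  cr$offdiagonal_share$offdiagonal_share <= 1))
  ## one-receptor world: the off-diagonal share is identically zero
  scen1 <- synth_scenario(R = 3, L = 3, seed = 2,
                          grid = ch_grid(100, 106, 24, 28), n_receptors = 1)
  run1 <- run_pipeline(scen1)
  expect_equal(run1$cross_region$offdiagonal_share$offdiagonal_share,
               rep(0, 2))
})

test_that("the eastward drift pushes deaths into downwind receptor regions", {
  scen <- test_scenario()
  prov_pop <- with(scen$survey$provinces, tapply(population, province, sum))
  prov_pop <- prov_pop[scen$config$provinces]
  mk_run <- function(drift) {
    s <- scen
    s$fields <- synth_fields(s$config$grid, s$emissions$totals,
                             unname(prov_pop), s$receptor_of,
                             de_province = apply(s$emissions$direct, c(1, 4),
                                                 sum),
                             seed = s$seed, drift_lon = drift)
    run_pipeline(s)
  }
  run_drift <- mk_run(1.0)
  run_nodrift <- mk_run(0)
  ## occurrence share of the most eastern receptor region grows with drift
  g <- scen$config$grid
  lon <- matrix(g$lon, g$nlat, g$nlon, byrow = TRUE)
  east_rc <- which.max(vapply(seq_along(scen$receptors), function(rc) {
    sum(lon[scen$fields$receptor_map == rc] *
        scen$fields$population[scen$fields$receptor_map == rc]) /
      sum(scen$fields$population[scen$fields$receptor_map == rc])
  }, 0))
  occ_share <- function(run) {
    m <- apply(run$cross_region$matrix, c(1, 2), sum)
    sum(m[, east_rc]) / sum(m)
  }
  expect_gt(occ_share(run_drift), occ_share(run_nodrift))
})

test_that("relabeling receptor regions permutes the attribution outputs", {
  scen <- small_scenario()
  run <- run_pipeline(scen)
  perm <- c(2, 1)
  P <- percentage_contribution(
    semi_normalized_sensitivity(scen$fields$sens, run$beta$E_cell))
  attr_p <- attribute_deaths(run$mortality$M_receptor_total[perm],
                             P[, , , perm], run$beta)
  expect_equal(attr_p$house, run$attribution$house[, , perm])
  expect_equal(attr_p$external, run$attribution$external[perm])
})
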