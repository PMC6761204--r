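test_that("resident numbers follow the household-size arithmetic", {
  expect_equal(resident_numbers(1000, 4, 0.2, 5), 250)
  ## homogeneous household sizes: rn = P * frac
  fr <- ch_group_fractions("urban")
  expect_equal(resident_numbers(5000, 3.2, fr, rep(3.2, 7)), 5000 * fr)
  expect_error(resident_numbers(-1, 4, 0.2, 5), "positive")
  expect_error(resident_numbers(1000, 4, 1.2, 5), "fractions")
  ## survey-level numbers sum to the provincial populations after
  ## renormalization, and the raw inconsistency stays within 2 %
  scen <- test_scenario()
  sv <- impute_missing_groups(scen$survey)
  rn <- survey_resident_numbers(sv)
  raw <- survey_resident_numbers(sv, renormalize = FALSE)
  key <- paste(rn$province, rn$setting)
  tot <- tapply(rn$rn, key, sum)
  tot_raw <- tapply(raw$rn, key, sum)
  pk <- paste(sv$provinces$province, sv$provinces$setting)
  pops <- sv$provinces$population[match(names(tot), pk)]
  expect_equal(as.numeric(tot), pops, tolerance = 1e-12)
  expect_lt(max(abs(as.numeric(tot_raw) - pops) / pops), 0.02)
})

test_that("imputation scales the proxy pattern by province average income", {
  ## hand-built survey: province B misses rural group detail
  sectors <- c("s1", "s2")
  fr <- ch_group_fractions("rural")
  mk_groups <- function(p, inc, miss = FALSE) {
    data.frame(province = p, setting = "rural", group = 1:5,
               income = if (miss) NA_real_ else inc, frac = fr, pph = 3)
  }
  inc_a <- c(2000, 3000, 4000, 5000, 6000)
  provs <- data.frame(province = c("A", "B"), setting = "rural",
                      population = c(1e6, 2e6), pph = 3,
                      avg_income = c(4000, 2000), missing = c(FALSE, TRUE))
  provs_u <- transform(provs, setting = "urban", missing = FALSE)
  gr_u <- do.call(rbind, lapply(c("A", "B"), function(p) {
    data.frame(province = p, setting = "urban", group = 1:7,
               income = seq(8000, 20000, length.out = 7),
               frac = ch_group_fractions("urban"), pph = 3)
  }))
  ex <- list(rural = array(1, c(2, 5, 2)), urban = array(1, c(2, 7, 2)))
  sv <- grouped_survey(rbind(provs, provs_u),
                       rbind(mk_groups("A", inc_a), mk_groups("B", 0, TRUE),
                             gr_u),
                       ex, sectors)
  sv$expenditure$rural[, , 1] <- matrix(runif(10), 2, 5)
  sv$expenditure$rural[, , 2] <- NA
  done <- impute_missing_groups(sv, proxy = "A")
  got <- done$groups$income[done$groups$province == "B" &
                            done$groups$setting == "rural"]
  ## B's average is half of A's: group incomes are A's halved (equal pph
  ## means the resident weights already normalize A's pattern)
  expect_equal(got, inc_a / 2, tolerance = 1e-10)
  ## resident-weighted mean of imputed incomes equals the province average
  expect_equal(sum(fr * 3 * got) / sum(fr * 3), 2000, tolerance = 1e-10)
  ## expenditure inherits A's pattern scaled by relative average income
  expect_equal(done$expenditure$rural[, , 2],
               sv$expenditure$rural[, , 1] / 2, tolerance = 1e-12)
  expect_false(any(done$provinces$missing))
  ## a proxy with identical average income transfers the pattern verbatim
  sv2 <- sv
  sv2$provinces$avg_income[sv2$provinces$setting == "rural"] <- c(4000, 4000)
  same <- impute_missing_groups(sv2, proxy = "A")
  expect_equal(same$groups$income[same$groups$province == "B" &
                                  same$groups$setting == "rural"],
               inc_a, tolerance = 1e-10)
})

test_that("imputation on the synthetic scenario recovers the ground truth", {
  scen <- test_scenario()
  done <- impute_missing_groups(scen$survey, proxy = "national")
  expect_equal(done$groups$income, scen$survey_complete$groups$income,
               tolerance = 1e-10)
  expect_equal(done$expenditure$rural, scen$survey_complete$expenditure$rural,
               tolerance = 1e-10)
})

test_that("national regrouping is a doubly consistent transport plan", {
  scen <- test_scenario()
  sv <- impute_missing_groups(scen$survey)
  rn <- survey_resident_numbers(sv)
  for (st in c("rural", "urban")) {
    grp <- national_regrouping(sv, st, rn)
    fr <- ch_group_fractions(st)
    total <- sum(grp$alloc)
    ## column sums hit the prescribed national fractions
    expect_equal(grp$group_pop / total, fr, tolerance = 1e-10)
    ## row sums return each province-group's resident number
    rn_st <- rn[rn$setting == st, ]
    for (row in seq_len(nrow(rn_st))) {
      s <- match(rn_st$province[row], grp$provinces)
      expect_equal(sum(grp$alloc[s, rn_st$group[row], ]), rn_st$rn[row],
                   tolerance = 1e-8)
    }
    ## national group mean incomes ascend
    expect_true(all(diff(grp$group_income) > 0))
  }
  expect_error(national_regrouping(sv, "suburban"))
})

test_that("single-province regrouping with uniform household size is the identity", {
  ## constant persons-per-household makes resident fractions equal the
  ## prescribed household fractions, so national groups = original groups
  sectors <- c("s1", "s2")
  provs <- data.frame(province = "A", setting = c("rural", "urban"),
                      population = 1e6, pph = 3, avg_income = c(5000, 15000),
                      missing = FALSE)
  gr <- rbind(
    data.frame(province = "A", setting = "rural", group = 1:5,
               income = seq(2000, 9000, length.out = 5),
               frac = ch_group_fractions("rural"), pph = 3),
    data.frame(province = "A", setting = "urban", group = 1:7,
               income = seq(6000, 30000, length.out = 7),
               frac = ch_group_fractions("urban"), pph = 3))
  sv <- grouped_survey(provs, gr,
                       list(rural = array(1, c(2, 5, 1)),
                            urban = array(1, c(2, 7, 1))), sectors)
  for (st in c("rural", "urban")) {
    grp <- national_regrouping(sv, st)
    J <- length(ch_group_fractions(st))
    off_diag <- grp$alloc[1, , ] * (1 - diag(J))
    expect_lt(max(off_diag) / sum(grp$alloc), 1e-10)
  }
})

test_that("poorer provinces fill the lowest national groups first", {
  sectors <- c("s1", "s2")
  fr <- ch_group_fractions("rural")
  mk <- function(p, base) {
    data.frame(province = p, setting = "rural", group = 1:5,
               income = base * seq(0.5, 1.5, length.out = 5), frac = fr,
               pph = 3)
  }
  provs <- data.frame(province = c("poor", "rich"), setting = "rural",
                      population = c(1e6, 1e6), pph = 3,
                      avg_income = c(1000, 100000), missing = FALSE)
  provs_u <- transform(provs, setting = "urban")
  gu <- do.call(rbind, lapply(c("poor", "rich"), function(p) {
    data.frame(province = p, setting = "urban", group = 1:7,
               income = seq(8000, 20000, length.out = 7),
               frac = ch_group_fractions("urban"), pph = 3)
  }))
  sv <- grouped_survey(rbind(provs, provs_u),
                       rbind(mk("poor", 1000), mk("rich", 100000), gu),
                       list(rural = array(1, c(2, 5, 2)),
                            urban = array(1, c(2, 7, 2))), sectors)
  grp <- national_regrouping(sv, "rural")
  ## disjoint income ranges: the poor province occupies national groups 1-2
  ## (and half of 3), the rich province groups 3(half)-5
  expect_equal(sum(grp$alloc[1, , 1:2]), 8e5, tolerance = 1e-6)
  expect_equal(sum(grp$alloc[2, , 1:2]), 0)
  expect_equal(sum(grp$alloc[1, , 4:5]), 0)
})

test_that("household demand splits conserve demand and follow expenditure", {
  ## equal per-capita expenditure: split proportional to group population
  v <- matrix(1, 3, 5)                       # L = 3 sectors, J = 5 groups
  n_alloc <- diag(5) * c(100, 200, 300, 200, 200)
  y <- rexp(6)                               # R = 2 producing regions
  sp <- split_household_demand(y, v, n_alloc)
  expect_equal(rowSums(sp), y, tolerance = 1e-12)
  expect_equal(sp[1, ] / y[1], c(0.1, 0.2, 0.3, 0.2, 0.2))
  ## a group holding all expenditure on a sector captures its demand
  v2 <- matrix(1, 3, 5); v2[2, ] <- c(0, 0, 0, 0, 1)
  sp2 <- split_household_demand(y, v2, n_alloc)
  expect_equal(sp2[2, 5], y[2])
  expect_equal(sp2[5, 5], y[5])              # sector 2 of region 2
  ## random case reconstruction
  set.seed(31)
  v3 <- matrix(rexp(15), 3, 5)
  n3 <- matrix(rexp(25), 5, 5)
  y3 <- rexp(6)
  expect_equal(rowSums(split_household_demand(y3, v3, n3)), y3,
               tolerance = 1e-12)
  ## zero-expenditure sector falls back to population shares with warning
  v4 <- matrix(1, 3, 5); v4[3, ] <- 0
  expect_warning(sp4 <- split_household_demand(y, v4, n_alloc),
                 "population shares")
  expect_equal(sp4[3, ] / y[3], c(0.1, 0.2, 0.3, 0.2, 0.2))
})

test_that("group embodied emissions are additive over groups", {
  scen <- small_scenario()
  Linv <- leontief_inverse(scen$mrio$A)
  f <- scen$emissions$intensity
  sv <- impute_missing_groups(scen$survey)
  grp <- national_regrouping(sv, "rural")
  y <- scen$mrio$y[, 1, 2]
  sp <- split_household_demand(y, sv$expenditure$rural[, , 2],
                               grp$alloc[2, , ])
  eg <- group_embodied_emissions(f, Linv, sp)
  expect_equal(apply(eg, c(1, 2, 3), sum),
               embodied_emissions(f, Linv, y), tolerance = 1e-10)
  ## degenerate single group equals the ungrouped result; zero demand gives 0
  eg1 <- group_embodied_emissions(f, Linv, cbind(y))
  expect_equal(eg1[, , , 1], embodied_emissions(f, Linv, y))
  expect_equal(group_embodied_emissions(f, Linv, cbind(0 * y))[, , , 1],
               array(0, dim(f)))
})

test_that("biomass per capita follows the fitted power law", {
  expect_equal(biomass_per_capita(1), 0.7072)
  a <- runif(20, 500, 50000)
  expect_equal(biomass_per_capita(2 * a), biomass_per_capita(a) * 2^-0.18)
  expect_true(all(diff(biomass_per_capita(sort(a))) < 0))
  expect_error(biomass_per_capita(0), "positive")
})

test_that("biomass allocation weights groups by population and income", {
  ## two-group case with incomes (a, 16a): share ratio pop1 : pop2 * 16^-0.18
  n_alloc <- diag(c(300, 700))
  out <- allocate_biomass_emissions(10, c(1000, 16000), n_alloc)
  w <- c(300, 700 * 16^-0.18)
  expect_equal(out[, 1], 10 * w / sum(w), tolerance = 1e-12)
  expect_equal(sum(out), 10, tolerance = 1e-12)
  ## equal incomes: split proportional to population
  out2 <- allocate_biomass_emissions(c(5, 8), c(2000, 2000), n_alloc)
  expect_equal(out2[, 1], 5 * c(0.3, 0.7))
  expect_equal(out2[, 2], 8 * c(0.3, 0.7))
  expect_error(allocate_biomass_emissions(10, c(1000, 2000), n_alloc,
                                          setting = "urban"), "rural")
})

test_that("fossil and car allocations follow their expenditure proxies", {
  v <- rbind(energy = c(2, 2, 2), other = c(1, 1, 1),
             transport = c(1, 2, 6))
  n_alloc <- diag(c(100, 100, 100))
  de <- rbind(fossil = c(9, 18), car = c(9, 18))   # two species
  out <- allocate_direct_fossil_car(de, v, n_alloc,
                                    c(residential_energy = 1L,
                                      transport = 3L))
  ## uniform energy proxy: population-proportional thirds
  expect_equal(out[, "fossil", 1], rep(3, 3))
  ## car follows the transport gradient, superproportional for the rich
  expect_equal(out[, "car", 1], 9 * c(1, 2, 6) / 9)
  expect_true(all(diff(out[, "car", 2]) > 0))
  expect_equal(apply(out, c(2, 3), sum),
               rbind(fossil = c(9, 18), car = c(9, 18)), tolerance = 1e-12)
  expect_error(allocate_direct_fossil_car(de, v, n_alloc,
                                          c(transport = 3L)),
               "proxy")
})

test_that("proxy-choice CV is small, zero for identical proxies, scale-free", {
  scen <- test_scenario()
  cv <- cv_sensitivity_scenarios(scen)
  expect_true(all(cv$cv_direct >= 0 & cv$cv_indirect >= 0))
  expect_true(all(cv$n_scenarios >= 2))
  ## identical proxies collapse the spread to zero
  cv0 <- cv_sensitivity_scenarios(scen, proxies = c("national", "national"))
  expect_equal(max(cv0$cv_direct), 0)
  expect_equal(max(cv0$cv_indirect), 0)
  ## CV is invariant to a uniform rescaling of all emissions
  scen2 <- scen
  scen2$emissions$totals <- scen$emissions$totals * 3
  scen2$emissions$direct <- scen$emissions$direct * 3
  scen2$mrio <- scen$mrio
  cv2 <- cv_sensitivity_scenarios(scen2)
  expect_equal(cv2$cv_direct, cv$cv_direct, tolerance = 1e-9)
  expect_equal(cv2$cv_indirect, cv$cv_indirect, tolerance = 1e-9)
  expect_error(cv_sensitivity_scenarios(scen, proxies = "national"),
               "two proxy")
})
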