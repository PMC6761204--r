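## The income-group tracing stage: imputation, national regrouping, demand
## splitting, group embodied emissions, and direct-source allocations, for
## every consuming province. Shared by run_pipeline() and the CV scenarios.
trace_income_groups <- function(scen, intensity, Linv, proxy = "national",
                                survey = NULL) {
  cfg <- scen$config
  R <- length(cfg$provinces); L <- length(cfg$sectors)
  K <- length(cfg$species)
  n_rural <- 5L; n_urban <- 7L; nc <- n_rural + n_urban
  survey <- impute_missing_groups(survey %||% scen$survey, proxy)
  rn <- survey_resident_numbers(survey)
  groupings <- list(rural = national_regrouping(survey, "rural", rn),
                    urban = national_regrouping(survey, "urban", rn))
  proxy_idx <- c(
    residential_energy = match(cfg$proxy_sectors$residential_energy,
                               cfg$sectors),
    transport = match(cfg$proxy_sectors$transport, cfg$sectors))
  e_house <- array(0, c(R, L, K, R, nc))
  de_class <- array(0, c(R, nc, K))
  for (st_i in 1:2) {
    st <- ch_settings()[st_i]
    grp <- groupings[[st]]
    I <- length(grp$group_pop)
    off <- if (st_i == 1) 0L else n_rural
    for (s in seq_len(R)) {
      v <- survey$expenditure[[st]][, , s]
      n_alloc <- grp$alloc[s, , ]
      y_split <- split_household_demand(scen$mrio$y[, st_i, s], v, n_alloc)
      eg <- group_embodied_emissions(intensity, Linv, y_split)
      e_house[, , , s, off + seq_len(I)] <-
        e_house[, , , s, off + seq_len(I)] + eg
      de_s <- scen$emissions$direct[s, st_i, , ]   # [source, K]
      gi <- survey$groups[survey$groups$setting == st &
                          survey$groups$province == cfg$provinces[s], ]
      gi <- gi[order(gi$group), ]
      if (any(de_s["biomass", ] > 0)) {
        bio <- allocate_biomass_emissions(de_s["biomass", ], gi$income,
                                          n_alloc)
        de_class[s, off + seq_len(I), ] <- de_class[s, off + seq_len(I), ] +
          bio
      }
      fc <- allocate_direct_fossil_car(de_s[c("fossil", "car"), ], v,
                                       n_alloc, proxy_idx)
      de_class[s, off + seq_len(I), ] <- de_class[s, off + seq_len(I), ] +
        fc[, "fossil", ] + fc[, "car", ]
    }
  }
  ce_class <- de_class
  for (s in seq_len(R)) for (cl in seq_len(nc)) for (k in seq_len(K)) {
    ce_class[s, cl, k] <- ce_class[s, cl, k] + sum(e_house[, , k, s, cl])
  }
  list(survey = survey, groupings = groupings, e_house = e_house,
       de_class = de_class, ce_class = ce_class)
}

#' Run the full consumption-to-deaths pipeline on a scenario
#'
#' Executes every stage in order: Leontief inverse and embodied-emission
#' accounting; imputation, national regrouping and income-group tracing of
#' household direct and indirect emissions; gridded attribution ratios;
#' IER mortality and its anthropogenic share per receptor region;
#' sensitivity-based attribution of receptor deaths to consuming regions,
#' settings and national income groups; cross-region summary; and the
#' Lorenz/Gini inequality report.
#'
#' @param scen A `ch_scenario` from [synth_scenario()] (or an equivalent
#'   input bundle from [read_scenario()]).
#' @param proxy Imputation proxy, `"national"` or a reporting province.
#' @param mc_draws Monte-Carlo draws for the mortality confidence
#'   intervals; 0 (default) skips the Monte Carlo.
#' @param mc_seed Seed for the Monte-Carlo draws.
#' @return Object of class `conshealth_run` with elements `mortality`,
#'   `attribution`, `cross_region`, `inequality`, `beta`, `trace`,
#'   `mc` (when requested) and the scenario configuration.
#' @export
run_pipeline <- function(scen, proxy = "national", mc_draws = 0L,
                         mc_seed = scen$config$mc_seed) {
  cfg <- scen$config
  Linv <- leontief_inverse(scen$mrio$A)
  intensity <- emission_intensity(scen$emissions$totals, scen$mrio$x)
  e_all <- embodied_all(intensity, Linv, scen$mrio$y)
  e_other <- apply(e_all[, , , 3:5, , drop = FALSE], c(1, 2, 3, 4), sum)
  tr <- trace_income_groups(scen, intensity, Linv, proxy)
  beta <- grid_attribution_ratios(scen$emissions$gridded,
                                  scen$fields$province_map,
                                  scen$fields$population,
                                  tr$e_house, e_other, tr$de_class)
  mort <- mortality_fields(scen$fields$pm25_all, scen$fields$pm25_no_anth,
                           scen$fields$population, scen$fields$receptor_map,
                           length(scen$receptors), cfg$ier, cfg$incidence)
  ss <- semi_normalized_sensitivity(scen$fields$sens, beta$E_cell)
  P <- percentage_contribution(ss)
  attr <- attribute_deaths(mort$M_receptor_total, P, beta)
  cross <- cross_region_summary(attr, cfg$province_receptor, scen$receptors)
  ineq <- inequality_report(attr, tr$groupings)
  mc <- if (mc_draws > 0) {
    monte_carlo_ci(scen$fields$pm25_all, scen$fields$pm25_no_anth,
                   scen$fields$population, scen$fields$receptor_map,
                   length(scen$receptors), cfg$ier, cfg$incidence,
                   n_draws = mc_draws, seed = mc_seed)
  }
  structure(list(config = cfg, receptors = scen$receptors,
                 mortality = mort, attribution = attr,
                 cross_region = cross, inequality = ineq,
                 beta = beta, trace = tr, embodied = e_all, mc = mc,
                 scenario_seed = scen$seed),
            class = "conshealth_run")
}

#' @export
print.conshealth_run <- function(x, ...) {
  tot <- sum(x$mortality$M_receptor_total)
  a <- x$attribution
  cat("Consumption-attributed PM2.5 mortality run\n")
  cat(sprintf("  anthropogenic PM2.5 deaths: %.0f across %d receptor regions\n",
              tot, length(x$receptors)))
  cat(sprintf("  household direct: %.0f (%.0f%%)  household indirect: %.0f (%.0f%%)\n",
              sum(a$house_direct), 100 * sum(a$house_direct) / tot,
              sum(a$house_indirect), 100 * sum(a$house_indirect) / tot))
  cat(sprintf("  other final demand: %.0f (%.0f%%)  external/residual: %.0f (%.0f%%)\n",
              sum(a$other), 100 * sum(a$other) / tot,
              sum(a$external), 100 * sum(a$external) / tot))
  cat(sprintf("  Gini: income %.3f, attributed deaths %.3f\n",
              x$inequality$gini[["income"]], x$inequality$gini[["deaths"]]))
  invisible(x)
}

#' @export
summary.conshealth_run <- function(object, ...) {
  x <- object
  print(x)
  cat("\nPer-receptor anthropogenic deaths:\n")
  tab <- data.frame(receptor = x$receptors,
                    deaths = x$mortality$M_receptor_total)
  if (!is.null(x$mc)) {
    tab$ci_lower <- x$mc$lower; tab$ci_upper <- x$mc$upper
  }
  print(tab, row.names = FALSE)
  od <- x$cross_region$offdiagonal_share
  cat(sprintf("\nCross-region share of indirect household deaths: %.0f%%\n",
              100 * sum(od$total[od$type == "indirect"] *
                        od$offdiagonal_share[od$type == "indirect"]) /
                max(sum(od$total[od$type == "indirect"]), 1e-300)))
  invisible(tab)
}

#' @export
plot.conshealth_run <- function(x, which = c("groups", "lorenz"), ...) {
  which <- match.arg(which)
  if (which == "lorenz") {
    op <- par(mfrow = c(2, 2), mar = c(4, 4, 2, 1)); on.exit(par(op))
    nm <- c(deaths = "deaths (total)", income = "income",
            deaths_direct = "deaths (direct)",
            deaths_indirect = "deaths (indirect)")
    for (i in names(nm)) plot(x$inequality$lorenz[[i]], main = nm[[i]])
    return(invisible(x))
  }
  ## per-capita death intensity by national income group, rural then urban
  a <- x$attribution
  pops <- c(x$trace$groupings$rural$group_pop, x$trace$groupings$urban$group_pop)
  dd <- apply(a$house_direct, 2, sum) / pops * 1e4
  di <- apply(a$house_indirect, 2, sum) / pops * 1e4
  m <- rbind(direct = dd, indirect = di)
  barplot(m, beside = FALSE, names.arg = c(paste0("r", 1:5), paste0("u", 1:7)),
          ylab = "deaths per 10,000 residents",
          main = "Per-capita attributed deaths by income group",
          legend.text = TRUE, ...)
  invisible(x)
}

#' Income-group sensitivity of the imputation proxy choice
#'
#' Recomputes each national group's direct and indirect household
#' emissions under alternative imputation proxies (the national average
#' and each reporting province, per setting) and reports the coefficient
#' of variation across scenarios per group.
#'
#' @param scen A `ch_scenario`.
#' @param proxies Optional character vector of proxies; default the
#'   national average plus every reporting province of the setting.
#' @return data.frame with columns setting, group, n_scenarios, cv_direct,
#'   cv_indirect.
#' @export
cv_sensitivity_scenarios <- function(scen, proxies = NULL) {
  cfg <- scen$config
  Linv <- leontief_inverse(scen$mrio$A)
  intensity <- emission_intensity(scen$emissions$totals, scen$mrio$x)
  out <- list()
  for (st in ch_settings()) {
    prov <- scen$survey$provinces
    have <- prov$province[prov$setting == st & !prov$missing]
    px <- proxies %||% c("national", have)
    ch_check(length(px) >= 2,
             "need at least two proxy scenarios, got %d", length(px))
    other <- setdiff(ch_settings(), st)
    vals_d <- NULL; vals_i <- NULL
    for (p in px) {
      sv <- impute_missing_groups(scen$survey, proxy = p, settings = st)
      sv <- impute_missing_groups(sv, proxy = "national", settings = other)
      tr <- trace_income_groups(scen, intensity, Linv, survey = sv)
      off <- if (st == "rural") 0L else 5L
      I <- if (st == "rural") 5L else 7L
      idx <- off + seq_len(I)
      vals_d <- rbind(vals_d, apply(tr$de_class[, idx, , drop = FALSE], 2, sum))
      ind <- tr$ce_class[, idx, , drop = FALSE] -
        tr$de_class[, idx, , drop = FALSE]
      vals_i <- rbind(vals_i, apply(ind, 2, sum))
    }
    cv <- function(v) apply(v, 2, function(col) {
      if (mean(col) == 0) 0 else sd(col) / mean(col)
    })
    out[[st]] <- data.frame(setting = st, group = seq_len(ncol(vals_d)),
                            n_scenarios = length(px),
                            cv_direct = cv(vals_d), cv_indirect = cv(vals_i))
  }
  do.call(rbind, out)
}
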