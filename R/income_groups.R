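#' Construct a grouped household survey
#'
#' Yearbook-style survey data: per province and setting (rural/urban) the
#' total population, average persons-per-household, average per-capita
#' income, and for each original income group the per-capita income,
#' household fraction and persons-per-household, plus per-capita expenditure
#' by MRIO sector. Provinces may be flagged as missing grouped data (incomes
#' and expenditure), to be completed by [impute_missing_groups()].
#'
#' @param provinces data.frame with columns province, setting, population,
#'   pph, avg_income, missing (logical).
#' @param groups data.frame with columns province, setting, group, income,
#'   frac, pph. Income is NA where the province is flagged missing.
#' @param expenditure list with elements `rural` (`[L, 5, R]`) and `urban`
#'   (`[L, 7, R]`): per-capita expenditure by sector, group, province; NA
#'   slices where flagged missing.
#' @param sectors Character vector of sector names (length `L`).
#' @return Object of class `grouped_survey`.
#' @export
grouped_survey <- function(provinces, groups, expenditure, sectors) {
  for (st in ch_settings()) {
    fr <- ch_group_fractions(st)
    g <- groups[groups$setting == st, ]
    agg <- tapply(g$frac, g$province, sum)
    ch_check(all(abs(agg - 1) < 1e-9),
             "household fractions must sum to 1 per province (%s)", st)
    prov <- provinces[provinces$setting == st, ]
    ok <- !prov$missing
    inc <- g[!is.na(g$income), ]
    ch_check(all(inc$income > 0), "nonpositive group income")
    ch_check(dim(expenditure[[st]])[2] == length(fr),
             "expenditure array for %s must have %d groups", st, length(fr))
  }
  ch_check(all(groups$pph >= 1 & groups$pph <= 6),
           "persons-per-household outside [1, 6]")
  structure(list(provinces = provinces, groups = groups,
                 expenditure = expenditure, sectors = sectors),
            class = "grouped_survey")
}

#' @export
print.grouped_survey <- function(x, ...) {
  np <- length(unique(x$provinces$province))
  miss <- tapply(x$provinces$missing, x$provinces$setting, mean)
  cat(sprintf("<grouped_survey> %d provinces, %d sectors; missing grouped data: rural %.0f%%, urban %.0f%%\n",
              np, length(x$sectors), 100 * miss[["rural"]],
              100 * miss[["urban"]]))
  invisible(x)
}

#' Resident numbers of an income group
#'
#' Converts household fractions to resident counts:
#' `rn = (P / pph) * frac * pph_group`, i.e. households in the province
#' times the group's household share times the group's household size.
#'
#' @param P Total (urban or rural) population of the province.
#' @param pph Province-average persons per household.
#' @param frac Household fraction(s) of the group(s), in (0, 1].
#' @param pph_group Persons per household of the group(s).
#' @return Resident numbers, same length as `frac`.
#' @export
resident_numbers <- function(P, pph, frac, pph_group) {
  ch_check(all(P > 0) && all(pph > 0) && all(pph_group > 0),
           "population and household sizes must be positive")
  ch_check(all(frac > 0 & frac <= 1), "fractions must lie in (0, 1]")
  P / pph * frac * pph_group
}

## Resident numbers for every (province, setting, group), renormalized so
## they sum exactly to the provincial population (the raw identity only
## holds when pph equals the frac-weighted mean group household size).
survey_resident_numbers <- function(survey, renormalize = TRUE) {
  g <- survey$groups
  p <- survey$provinces
  key <- paste(g$province, g$setting)
  pk <- paste(p$province, p$setting)
  idx <- match(key, pk)
  rn <- resident_numbers(p$population[idx], p$pph[idx], g$frac, g$pph)
  if (renormalize) {
    tot <- tapply(rn, key, sum)[key]
    adj <- p$population[idx] / tot
    if (any(abs(adj - 1) > 0.02))
      warning("resident numbers renormalized by more than 2% in some provinces",
              call. = FALSE)
    rn <- rn * adj
  }
  cbind(g[c("province", "setting", "group")], rn = rn)
}

## Per-capita resident weights of the original groups within a province:
## frac_j * pph_j / sum_j frac_j * pph_j.
group_resident_weights <- function(frac, pph_group) {
  w <- frac * pph_group
  w / sum(w)
}

#' Impute grouped data for provinces without yearbook group detail
#'
#' Provinces flagged missing inherit the income-ratio pattern of a proxy
#' (the national average over reporting provinces, or a named reporting
#' province), scaled by the province's own average income and renormalized
#' so the resident-weighted mean of the imputed group incomes equals the
#' province average exactly. Expenditure patterns are scaled linearly with
#' average income from the same proxy.
#'
#' @param survey A [grouped_survey()].
#' @param proxy `"national"` (default) or the name of a reporting province.
#' @param settings Settings to impute (default both).
#' @return A completed `grouped_survey` with no missing flags.
#' @export
impute_missing_groups <- function(survey, proxy = "national",
                                  settings = ch_settings()) {
  out <- survey
  for (st in settings) {
    prov <- survey$provinces[survey$provinces$setting == st, ]
    miss <- prov$province[prov$missing]
    if (!length(miss)) next
    have <- prov$province[!prov$missing]
    ch_check(length(have) > 0,
             "no available proxy for provinces: %s",
             paste(miss, collapse = ", "))
    J <- length(ch_group_fractions(st))
    ratio_of <- function(pv) {
      gi <- survey$groups[survey$groups$setting == st &
                          survey$groups$province == pv, ]
      gi <- gi[order(gi$group), ]
      gi$income / prov$avg_income[prov$province == pv]
    }
    expnorm_of <- function(pv) {    # expenditure per unit average income
      survey$expenditure[[st]][, , match(pv, prov$province)] /
        prov$avg_income[prov$province == pv]
    }
    if (identical(proxy, "national")) {
      rho <- rowMeans(vapply(have, ratio_of, numeric(J)))
      vbar <- Reduce(`+`, lapply(have, expnorm_of)) / length(have)
    } else {
      ch_check(proxy %in% have,
               "proxy province '%s' has no grouped %s data", proxy, st)
      rho <- ratio_of(proxy)
      vbar <- expnorm_of(proxy)
    }
    for (pv in miss) {
      sel <- out$groups$setting == st & out$groups$province == pv
      gi <- out$groups[sel, ]
      o <- order(gi$group)
      w <- group_resident_weights(gi$frac[o], gi$pph[o])
      avg <- prov$avg_income[prov$province == pv]
      out$groups$income[sel][o] <- avg * rho / sum(w * rho)
      out$expenditure[[st]][, , match(pv, prov$province)] <- vbar * avg
    }
    out$provinces$missing[out$provinces$setting == st &
                          out$provinces$province %in% miss] <- FALSE
  }
  out
}

#' Pool provincial income groups into national income groups
#'
#' All (province, original group) units of one setting are ranked by
#' per-capita income (ties broken by province then group order) and cut
#' into national groups at the prescribed cumulative resident-count
#' fractions (urban 10/10/20/20/20/10/10 %, rural five 20 % groups). A unit
#' straddling a cutoff is split proportionally by population between the
#' adjacent national groups.
#'
#' @param survey A completed (imputed) [grouped_survey()].
#' @param setting `"rural"` or `"urban"`.
#' @param rn Optional resident-number table from [survey_resident_numbers()];
#'   computed when omitted.
#' @return List of class `national_grouping`: `alloc` (array
#'   `[province, original group, national group]` of resident counts),
#'   `group_pop`, `group_income` (resident-weighted mean income of each
#'   national group), `units` (the ranked unit table), `setting`.
#' @export
national_regrouping <- function(survey, setting, rn = NULL) {
  setting <- match.arg(setting, ch_settings())
  fr <- ch_group_fractions(setting)
  I <- length(fr)
  if (is.null(rn)) rn <- survey_resident_numbers(survey)
  g <- survey$groups[survey$groups$setting == setting, ]
  ch_check(nrow(g) > 0, "empty setting '%s'", setting)
  ch_check(!anyNA(g$income),
           "survey has missing group incomes; impute first")
  rn <- rn[rn$setting == setting, ]
  provs <- unique(survey$provinces$province[
    survey$provinces$setting == setting])
  u <- merge(g, rn, by = c("province", "setting", "group"))
  u <- u[order(u$income, match(u$province, provs), u$group), ]
  total <- sum(u$rn)
  hi <- cumsum(u$rn)
  lo <- c(0, head(hi, -1))
  cuts <- cumsum(fr) * total
  cuts_lo <- c(0, head(cuts, -1))
  J <- max(g$group)
  alloc <- array(0, c(length(provs), J, I), dimnames = list(provs, NULL, NULL))
  for (row in seq_len(nrow(u))) {
    pi <- match(u$province[row], provs)
    for (i in seq_len(I)) {
      ov <- max(0, min(hi[row], cuts[i]) - max(lo[row], cuts_lo[i]))
      if (ov > 0) alloc[pi, u$group[row], i] <- alloc[pi, u$group[row], i] + ov
    }
  }
  group_pop <- apply(alloc, 3, sum)
  inc_mat <- matrix(0, length(provs), J)
  inc_mat[cbind(match(g$province, provs), g$group)] <- g$income
  group_income <- vapply(seq_len(I), function(i) {
    sum(alloc[, , i] * inc_mat) / group_pop[i]
  }, 0)
  structure(list(alloc = alloc, group_pop = group_pop,
                 group_income = group_income, units = u,
                 provinces = provs, setting = setting),
            class = "national_grouping")
}

#' @export
print.national_grouping <- function(x, ...) {
  cat(sprintf("<national_grouping> %s: %d provinces x %d original -> %d national groups\n",
              x$setting, dim(x$alloc)[1], dim(x$alloc)[2], dim(x$alloc)[3]))
  cat("  national group mean incomes:",
      paste(sprintf("%.0f", x$group_income), collapse = ", "), "\n")
  invisible(x)
}

#' Split one region's household demand across national income groups
#'
#' The sector-wise split weight of national group `i` is the expenditure
#' volume its members account for: `w_i[l] = sum_j n[j,i] * v[l,j]`
#' (population assigned from original group `j` times that group's
#' per-capita expenditure on sector `l`), normalized over groups per sector.
#' Sectors with zero total expenditure but nonzero demand fall back to
#' population shares with a warning.
#'
#' @param y Demand vector for the (category, consuming region) slice,
#'   length `R*L` (region-major over producing region-sectors).
#' @param v Per-capita expenditure matrix `[L, J]` of the consuming province.
#' @param n_alloc Allocation matrix `[J, I]` for the consuming province
#'   (resident counts, original group x national group).
#' @return Matrix `[R*L, I]` with rows summing to `y` exactly.
#' @export
split_household_demand <- function(y, v, n_alloc) {
  L <- nrow(v); I <- ncol(n_alloc)
  ch_check(length(y) %% L == 0, "demand length %d not a multiple of L=%d",
           length(y), L)
  W <- v %*% n_alloc                       # [L, I] expenditure volume
  tot <- rowSums(W)
  share <- W / ifelse(tot > 0, tot, 1)
  R <- length(y) / L
  zero <- tot <= 0
  if (any(zero)) {
    pop_share <- colSums(n_alloc) / sum(n_alloc)
    if (any(y[rep(zero, R)] > 0))
      warning("sector(s) with zero expenditure but nonzero demand: falling back to population shares",
              call. = FALSE)
    share[zero, ] <- matrix(pop_share, sum(zero), I, byrow = TRUE)
  }
  big_share <- share[rep(seq_len(L), R), , drop = FALSE]
  out <- big_share * y
  dimnames(out) <- NULL
  out
}

#' Embodied emissions per national income group
#'
#' Applies the Leontief attribution to each group's demand column;
#' additivity over groups recovers the ungrouped result.
#'
#' @param intensity Intensity array `[R, L, K]`.
#' @param Linv Leontief inverse.
#' @param y_split Matrix `[R*L, I]` from [split_household_demand()].
#' @return Array `[R, L, K, I]` of embodied emissions by group.
#' @export
group_embodied_emissions <- function(intensity, Linv, y_split) {
  d <- dim(intensity); I <- ncol(y_split)
  out <- array(0, c(d, I))
  for (i in seq_len(I)) {
    out[, , , i] <- embodied_emissions(intensity, Linv, y_split[, i])
  }
  out
}

#' Per-capita biomass consumption as a function of income
#'
#' The fitted power law `t_bio = 0.7072 * income^-0.18`: biomass use falls
#' slowly as per-capita income rises, so poorer groups burn more solid
#' biomass per person.
#'
#' @param alpha Per-capita income (positive).
#' @return Per-capita biomass consumption, strictly decreasing in income.
#' @export
biomass_per_capita <- function(alpha) {
  ch_check(all(alpha > 0), "per-capita income must be positive")
  0.7072 * alpha^-0.18
}

#' Allocate rural biomass direct emissions to national income groups
#'
#' Group shares are proportional to assigned population times the
#' per-capita biomass consumption of the *original* provincial group
#' (evaluated at original-group incomes), normalized to preserve the total.
#' Biomass burning is a rural source only.
#'
#' @param e_bio Biomass emission total(s) of the province, one per species.
#' @param incomes Original-group per-capita incomes (length `J`).
#' @param n_alloc Allocation matrix `[J, I]` of resident counts.
#' @param setting Must be `"rural"`.
#' @return Matrix `[I, K]` summing to `e_bio` per species.
#' @export
allocate_biomass_emissions <- function(e_bio, incomes, n_alloc,
                                       setting = "rural") {
  ch_check(identical(setting, "rural"),
           "biomass direct emissions exist only for rural households")
  tb <- biomass_per_capita(incomes)
  w <- as.numeric(crossprod(n_alloc, tb))    # sum_j n[j,i] * t_bio_j
  share <- w / sum(w)
  outer(share, e_bio)
}

#' Allocate household fossil-fuel and private-car direct emissions
#'
#' Fossil-fuel combustion is split across national groups in proportion to
#' assigned population times per-capita residential-energy expenditure of
#' the original group; private-car emissions use the transport expenditure
#' column. Totals are preserved exactly.
#'
#' @param de Matrix `[source, K]` with rows `fossil` and `car` for the
#'   province and setting.
#' @param v Per-capita expenditure matrix `[L, J]`.
#' @param n_alloc Allocation matrix `[J, I]`.
#' @param proxy_idx Named integer vector with elements `residential_energy`
#'   and `transport`: row indices of the proxy sectors in `v`.
#' @return Array `[I, source, K]`.
#' @export
allocate_direct_fossil_car <- function(de, v, n_alloc, proxy_idx) {
  ch_check(all(c("residential_energy", "transport") %in% names(proxy_idx)),
           "configuration error: missing proxy sector column")
  I <- ncol(n_alloc); K <- ncol(de)
  out <- array(0, c(I, 2, K), dimnames = list(NULL, c("fossil", "car"), NULL))
  proxy_row <- c(fossil = proxy_idx[["residential_energy"]],
                 car = proxy_idx[["transport"]])
  for (src in c("fossil", "car")) {
    w <- as.numeric(crossprod(n_alloc, v[proxy_row[[src]], ]))
    share <- if (sum(w) > 0) w / sum(w) else colSums(n_alloc) / sum(n_alloc)
    out[, src, ] <- outer(share, de[src, ])
  }
  out
}
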