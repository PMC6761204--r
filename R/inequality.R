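#' Lorenz curve over income-ranked household groups
#'
#' Ranks population units (household groups) by per-capita income, poorest
#' first, and accumulates population and quantity shares. The ranking key
#' is always per-capita income, also when the quantity is attributed
#' deaths, so death- and income-Lorenz curves are directly comparable.
#'
#' @param population Positive population of each unit.
#' @param quantity Nonnegative quantity held by each unit (income volume,
#'   attributed deaths, ...), with a positive total.
#' @param income Per-capita income of each unit (the ranking key).
#' @return Object of class `ranked_distribution`: data.frame `points` with
#'   cumulative shares `H` (population) and `I` (quantity) including the
#'   (0, 0) origin, plus the ranked unit table.
#' @export
lorenz_curve <- function(population, quantity, income) {
  ch_check(all(population > 0), "populations must be positive")
  ch_check(all(quantity >= 0), "quantities must be nonnegative")
  ch_check(sum(quantity) > 0, "total quantity is zero")
  o <- order(income)
  units <- data.frame(population = population[o], quantity = quantity[o],
                      income = income[o])
  H <- c(0, cumsum(units$population) / sum(units$population))
  I <- c(0, cumsum(units$quantity) / sum(units$quantity))
  structure(list(points = data.frame(H = H, I = I), units = units),
            class = "ranked_distribution")
}

#' @export
print.ranked_distribution <- function(x, ...) {
  cat(sprintf("<ranked_distribution> %d units, Gini %.4f\n",
              nrow(x$units), gini(x)))
  invisible(x)
}

#' @export
plot.ranked_distribution <- function(x, ..., main = "Lorenz curve") {
  plot(x$points$H, x$points$I, type = "l", xlab = "cumulative population share",
       ylab = "cumulative quantity share", main = main, ...)
  abline(0, 1, lty = 2, col = "grey50")
  invisible(x)
}

#' Gini coefficient from a ranked distribution
#'
#' Trapezoid form on the Lorenz points:
#' `G = 1 - | sum_h (H_{h+1} - H_h) (I_h + I_{h+1}) |`.
#' Zero for perfect equality; the absolute value is defensive only, as the
#' package enforces ascending income order.
#'
#' @param dist A `ranked_distribution` from [lorenz_curve()].
#' @return The Gini coefficient, in `[0, 1)`.
#' @export
gini <- function(dist) {
  ch_check(inherits(dist, "ranked_distribution"),
           "gini() expects a ranked_distribution")
  u <- dist$units
  ch_check(!is.unsorted(u$income), "units must be sorted by income")
  H <- dist$points$H; I <- dist$points$I
  n <- length(H)
  1 - abs(sum((H[-1] - H[-n]) * (I[-n] + I[-1])))
}

#' Inequality report over a burden attribution
#'
#' Builds the four Lorenz/Gini summaries of the household health burden:
#' total attributed deaths, household income, direct-emission deaths only,
#' and indirect-emission deaths only, each over the same income-ranked
#' (consuming province x setting x national group) units, plus a decile
#' share table of income and deaths.
#'
#' @param attr A `burden_attribution` from [attribute_deaths()].
#' @param groupings Named list with elements `rural` and `urban`, the
#'   [national_regrouping()] objects used in the attribution.
#' @return List of class `inequality_report`: `lorenz` (named list of
#'   `ranked_distribution`), `gini` (named numeric), `deciles` (data.frame
#'   of decile shares, percent), `units`.
#' @export
inequality_report <- function(attr, groupings) {
  S <- dim(attr$house)[1]
  units <- do.call(rbind, lapply(ch_settings(), function(st) {
    grp <- groupings[[st]]
    I <- length(grp$group_pop)
    off <- if (st == "rural") 0L else length(groupings$rural$group_pop)
    do.call(rbind, lapply(seq_len(I), function(i) {
      pop_s <- rowSums(grp$alloc[, , i, drop = FALSE])  # by province
      inc_s <- vapply(seq_len(S), function(s) {
        j <- grp$alloc[s, , i]
        if (sum(j) == 0) return(0)
        gi <- grp$units[grp$units$province == grp$provinces[s], ]
        gi <- gi[order(gi$group), ]
        sum(j * gi$income[seq_along(j)]) / sum(j)
      }, 0)
      data.frame(province = grp$provinces, setting = st, group = i,
                 population = pop_s, income_pc = inc_s,
                 deaths = attr$house[, off + i, ] |>
                   matrix(nrow = S) |> rowSums(),
                 deaths_direct = attr$house_direct[, off + i, ] |>
                   matrix(nrow = S) |> rowSums(),
                 deaths_indirect = attr$house_indirect[, off + i, ] |>
                   matrix(nrow = S) |> rowSums())
    }))
  }))
  units <- units[units$population > 0, ]
  units$income_volume <- units$population * units$income_pc
  lz <- list(
    deaths = lorenz_curve(units$population, units$deaths, units$income_pc),
    income = lorenz_curve(units$population, units$income_volume,
                          units$income_pc),
    deaths_direct = lorenz_curve(units$population, units$deaths_direct,
                                 units$income_pc),
    deaths_indirect = lorenz_curve(units$population, units$deaths_indirect,
                                   units$income_pc)
  )
  gn <- vapply(lz, gini, 0)
  deciles <- decile_shares(units)
  structure(list(lorenz = lz, gini = gn, deciles = deciles, units = units),
            class = "inequality_report")
}

## Decile shares of income and deaths over income-ranked units, with units
## split proportionally across decile boundaries.
decile_shares <- function(units) {
  o <- order(units$income_pc)
  u <- units[o, ]
  pop <- u$population
  cuts <- seq(0, 1, 0.1) * sum(pop)
  hi <- cumsum(pop); lo <- c(0, head(hi, -1))
  share_of <- function(q) {
    vapply(seq_len(10), function(d) {
      ov <- pmax(0, pmin(hi, cuts[d + 1]) - pmax(lo, cuts[d]))
      sum(q * ov / pop) / sum(q)
    }, 0) * 100
  }
  data.frame(decile = seq_len(10),
             income_share = share_of(u$income_volume),
             deaths_share = share_of(u$deaths),
             deaths_direct_share = share_of(u$deaths_direct),
             deaths_indirect_share = share_of(u$deaths_indirect))
}

#' @export
print.inequality_report <- function(x, ...) {
  cat("<inequality_report>\n  Gini:",
      paste(sprintf("%s %.3f", names(x$gini), x$gini), collapse = ", "), "\n")
  cat(sprintf("  richest decile: %.1f%% of income, %.1f%% of attributed deaths\n",
              x$deciles$income_share[10], x$deciles$deaths_share[10]))
  cat(sprintf("  poorest decile: %.1f%% of income, %.1f%% of attributed deaths\n",
              x$deciles$income_share[1], x$deciles$deaths_share[1]))
  invisible(x)
}
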