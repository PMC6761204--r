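#' Semi-normalized sensitivity of receptor deaths to emissions
#'
#' Multiplies the adjoint sensitivity field (deaths per unit emission, per
#' cell and species) elementwise by the emission field, giving each cell's
#' marginal contribution to the receptor's death total.
#'
#' @param sens Sensitivity array `[nlat, nlon, K]` or `[nlat, nlon, K,
#'   n_receptors]`.
#' @param E Emission array `[nlat, nlon, K]`.
#' @return Array of the same shape as `sens`.
#' @export
semi_normalized_sensitivity <- function(sens, E) {
  ds <- dim(sens); de <- dim(E)
  ch_check(all(ds[1:3] == de[1:3]),
           "sensitivity grid [%s] does not match emission grid [%s]",
           paste(ds[1:3], collapse = "x"), paste(de[1:3], collapse = "x"))
  ss <- if (length(ds) == 3) sens * E else sens * as.vector(E)
  if (length(ds) == 4) {
    tot <- apply(ss, 4, sum)
    if (any(tot < 0))
      warning("negative semi-normalized sensitivity total for some receptors (possible nonphysical adjoint values)",
              call. = FALSE)
  }
  ss
}

#' Percentage contribution of each cell and species to receptor deaths
#'
#' Normalizes the semi-normalized sensitivity to percentages:
#' `P = SS / sum(SS) * 100` per receptor.
#'
#' @param ss Array `[nlat, nlon, K]` (one receptor) or
#'   `[nlat, nlon, K, n_receptors]`.
#' @return Array of the same shape, summing to 100 per receptor.
#' @export
percentage_contribution <- function(ss) {
  d <- dim(ss)
  if (length(d) == 3) {
    tot <- sum(ss)
    ch_check(tot != 0, "undefined contribution: all-zero sensitivity field")
    return(ss / tot * 100)
  }
  out <- ss
  for (r in seq_len(d[4])) {
    tot <- sum(ss[, , , r])
    ch_check(tot != 0,
             "undefined contribution: all-zero sensitivity field for receptor %d", r)
    out[, , , r] <- ss[, , , r] / tot * 100
  }
  out
}

#' Attribute receptor deaths to consuming regions and income groups
#'
#' Combines each receptor's death total with its percentage-contribution
#' field and the gridded attribution ratios:
#' `M[s, class] = sum_r M_r * sum_cells,k P_r/100 * beta[s, class]`.
#' Non-household categories and the residual (emissions outside the mapped
#' provinces, the boundary-inflow analogue) are attributed alongside so the
#' decomposition is additive to 100 % of each receptor's deaths.
#'
#' @param M_receptor Numeric vector of receptor death totals.
#' @param P Percentage-contribution array `[nlat, nlon, K, n_receptors]`.
#' @param beta A `beta_fields` object from [grid_attribution_ratios()].
#' @return Object of class `burden_attribution`: arrays `house`,
#'   `house_direct`, `house_indirect` (`[S, n_class, n_receptors]`),
#'   `other` (`[3, n_receptors]`), `external` (length `n_receptors`), and
#'   the input `M_receptor`.
#' @export
attribute_deaths <- function(M_receptor, P, beta) {
  d <- dim(P); nrec <- d[4]
  db <- dim(beta$house); S <- db[4]; nc <- db[5]
  nck <- prod(db[1:3])
  Bh <- array(beta$house, c(nck, S * nc))
  Bhd <- array(beta$house_direct, c(nck, S * nc))
  Bhi <- array(beta$house_indirect, c(nck, S * nc))
  Bo <- array(beta$other, c(nck, 3))
  house <- array(0, c(S, nc, nrec))
  house_d <- house; house_i <- house
  other <- matrix(0, 3, nrec)
  external <- numeric(nrec)
  for (r in seq_len(nrec)) {
    w <- as.vector(P[, , , r]) / 100
    h <- crossprod(Bh, w); hd <- crossprod(Bhd, w); hi <- crossprod(Bhi, w)
    o <- crossprod(Bo, w)
    tot <- sum(h) + sum(o)
    ch_check(tot <= 1 + 1e-6,
             "consistency error: attributed share %.8f exceeds 1 for receptor %d",
             tot, r)
    house[, , r] <- M_receptor[r] * matrix(h, S, nc)
    house_d[, , r] <- M_receptor[r] * matrix(hd, S, nc)
    house_i[, , r] <- M_receptor[r] * matrix(hi, S, nc)
    other[, r] <- M_receptor[r] * o
    external[r] <- M_receptor[r] * (1 - tot)
  }
  structure(list(house = house, house_direct = house_d,
                 house_indirect = house_i, other = other,
                 external = external, M_receptor = M_receptor),
            class = "burden_attribution")
}

#' @export
print.burden_attribution <- function(x, ...) {
  tot <- sum(x$M_receptor)
  cat(sprintf("<burden_attribution> %.1f deaths across %d receptor regions\n",
              tot, length(x$M_receptor)))
  cat(sprintf("  household direct %.1f%% | household indirect %.1f%% | other categories %.1f%% | external %.1f%%\n",
              100 * sum(x$house_direct) / tot,
              100 * sum(x$house_indirect) / tot,
              100 * sum(x$other) / tot, 100 * sum(x$external) / tot))
  invisible(x)
}

#' Cross-region summary of consumption-attributed deaths
#'
#' Collapses the attribution to a (consuming receptor region x occurring
#' receptor region) matrix per setting and emission type, and reports the
#' share of each consuming region's deaths that occur elsewhere.
#'
#' @param attr A `burden_attribution` from [attribute_deaths()].
#' @param province_receptor Named character vector mapping each consuming
#'   province to its receptor region.
#' @param receptors Character vector of receptor-region names (occurrence
#'   order used in `attr`).
#' @param n_rural Number of rural national groups (classes `1..n_rural` are
#'   rural, the rest urban).
#' @return List: `matrix` (array `[consuming receptor, occurring receptor,
#'   setting, type]` with types direct/indirect), `offdiagonal_share`
#'   (data.frame per consuming receptor and type).
#' @export
cross_region_summary <- function(attr, province_receptor, receptors,
                                 n_rural = 5L) {
  S <- dim(attr$house)[1]; nc <- dim(attr$house)[2]
  nrec <- length(receptors)
  cons_rec <- match(province_receptor, receptors)
  ch_check(length(cons_rec) == S && !anyNA(cons_rec),
           "province-to-receptor mapping inconsistent with attribution")
  setting_of <- rep(c("rural", "urban"), c(n_rural, nc - n_rural))
  out <- array(0, c(nrec, nrec, 2, 2),
               dimnames = list(receptors, receptors, ch_settings(),
                               c("direct", "indirect")))
  for (ty in c("direct", "indirect")) {
    a <- if (ty == "direct") attr$house_direct else attr$house_indirect
    for (s in seq_len(S)) for (cl in seq_len(nc)) {
      st <- match(setting_of[cl], ch_settings())
      out[cons_rec[s], , st, ty] <- out[cons_rec[s], , st, ty] + a[s, cl, ]
    }
  }
  offd <- do.call(rbind, lapply(c("direct", "indirect"), function(ty) {
    m <- matrix(out[, , 1, ty] + out[, , 2, ty], nrec, nrec)
    tot <- rowSums(m)
    data.frame(consuming = receptors, type = ty,
               total = tot,
               offdiagonal_share = ifelse(tot > 0,
                                          1 - diag(as.matrix(m)) / tot, 0))
  }))
  list(matrix = out, offdiagonal_share = offd)
}
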