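#' Gridded attribution ratios of emissions to household classes
#'
#' For every grid cell and species, computes the share of the cell's
#' emissions attributable to each (consuming province, household class)
#' pair -- split into indirect (supply-chain) and direct (local fuel
#' burning) components -- and to each non-household final-demand category.
#' Household classes concatenate the rural national income groups followed
#' by the urban ones.
#'
#' Indirect emissions of producing region `r` are laid onto `r`'s cells in
#' proportion to the sector-specific spatial distribution of the gridded
#' inventory; direct household emissions are local to the consuming
#' province and laid out proportionally to population.
#'
#' @param gridded Production emission array `[nlat, nlon, L, K]`.
#' @param province_map Integer field of province indices (NA = outside).
#' @param population Population field.
#' @param e_house Embodied household emissions `[R, L, K, S, n_class]`
#'   (producing region, sector, species, consuming province, class).
#' @param e_other Embodied non-household emissions `[R, L, K, 3]`
#'   (categories: government, capital, exports).
#' @param de_house Direct household emissions `[S, n_class, K]`.
#' @return List of class `beta_fields`: `house`, `house_direct`,
#'   `house_indirect` (arrays `[nlat, nlon, K, S, n_class]`), `other`
#'   (`[nlat, nlon, K, 3]`), `E_cell` (`[nlat, nlon, K]` total cell
#'   emissions including direct).
#' @export
grid_attribution_ratios <- function(gridded, province_map, population,
                                    e_house, e_other, de_house) {
  d <- dim(gridded); nlat <- d[1]; nlon <- d[2]; L <- d[3]; K <- d[4]
  R <- dim(e_house)[1]; S <- dim(e_house)[4]; nc <- dim(e_house)[5]
  ncell <- nlat * nlon
  Ecv <- array(0, c(ncell, K))
  for (k in seq_len(K)) Ecv[, k] <- rowSums(array(gridded[, , , k],
                                                  c(ncell, L)))
  num_dir <- array(0, c(ncell, K, S, nc))
  for (s in seq_len(S)) {
    cells <- which(province_map == s)
    if (!length(cells)) next
    popshare <- population[cells] / sum(population[cells])
    for (k in seq_len(K)) for (cl in seq_len(nc)) {
      v <- de_house[s, cl, k]
      if (v == 0) next
      idx <- cells + ncell * ((k - 1) + K * ((s - 1) + S * (cl - 1)))
      num_dir[idx] <- num_dir[idx] + popshare * v
      Ecv[cells, k] <- Ecv[cells, k] + popshare * v
    }
  }
  num_ind <- array(0, c(ncell, K, S, nc))
  num_oth <- array(0, c(ncell, K, 3))
  gmat <- array(gridded, c(ncell, L, K))
  for (r in seq_len(R)) {
    cells <- which(province_map == r)
    if (!length(cells)) next
    for (k in seq_len(K)) {
      g <- matrix(gmat[cells, , k], length(cells), L)
      Gr <- colSums(g)
      gshare <- sweep(g, 2, ifelse(Gr > 0, Gr, 1), "/")
      gshare[, Gr <= 0] <- 0
      eh <- matrix(e_house[r, , k, , ], L, S * nc)
      num_ind[cells, k, , ] <- num_ind[cells, k, , ] +
        array(gshare %*% eh, c(length(cells), S, nc))
      num_oth[cells, k, ] <- num_oth[cells, k, ] +
        gshare %*% matrix(e_other[r, , k, ], L, 3)
    }
  }
  denom <- ifelse(Ecv > 0, Ecv, 1)
  bi <- num_ind / as.vector(denom)          # recycles over trailing dims
  bd <- num_dir / as.vector(denom)
  bo <- num_oth / as.vector(denom)
  E_cell <- array(Ecv, c(nlat, nlon, K))
  tot <- rowSums(array(bi + bd, c(ncell * K, S * nc))) +
    rowSums(array(bo, c(ncell * K, 3)))
  ch_check(max(tot) <= 1 + 1e-9,
           "internal consistency error: attribution ratio sum %.6f > 1",
           max(tot))
  shape5 <- c(nlat, nlon, K, S, nc)
  structure(list(
    house = array(bi + bd, shape5),
    house_indirect = array(bi, shape5),
    house_direct = array(bd, shape5),
    other = array(bo, c(nlat, nlon, K, 3)),
    E_cell = E_cell
  ), class = "beta_fields")
}
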