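#' Construct a multi-regional input-output (MRIO) table
#'
#' The MRIO table holds the direct-requirement coefficient block matrix `A`
#' (dimension `R*L x R*L` for `R` regions and `L` sectors, producing index
#' in rows), the final-demand array `y` indexed by producing region-sector,
#' final-demand category (rural households, urban households, government,
#' capital, exports) and consuming region, and the total-output vector `x`
#' satisfying the accounting identity `x = A x + sum(y)`.
#'
#' @param A Nonnegative coefficient matrix, `R*L x R*L`, spectral radius < 1.
#' @param y Nonnegative array `[R*L, 5, R]` (producing region-sector,
#'   category, consuming region).
#' @param regions,sectors Character vectors of region and sector names.
#' @param x Optional output vector; computed from the Leontief solution when
#'   omitted.
#' @return Object of class `mrio_table`.
#' @export
mrio_table <- function(A, y, regions, sectors, x = NULL) {
  R <- length(regions); L <- length(sectors); n <- R * L
  ch_check(is.matrix(A) && all(dim(A) == n),
           "A must be %d x %d for %d regions x %d sectors, found %s",
           n, n, R, L, paste(dim(A), collapse = " x "))
  ch_check(all(A >= 0), "negative direct-requirement coefficient in A")
  dy <- dim(y)
  ch_check(length(dy) == 3 && dy[1] == n && dy[2] == 5 && dy[3] == R,
           "y must be [%d, 5, %d], found [%s]", n, R,
           paste(dy, collapse = ", "))
  ch_check(all(y >= 0), "negative final demand")
  rho <- spectral_radius(A)
  ch_check(rho < 1, "non-productive economy: spectral radius %.4f >= 1", rho)
  ytot <- rowSums(y, dims = 1)
  if (is.null(x)) x <- solve(diag(n) - A, ytot)
  resid <- max(abs(x - A %*% x - ytot)) / max(abs(x))
  ch_check(resid <= 1e-8,
           "accounting identity x = Ax + y violated (relative residual %.2e)",
           resid)
  rs <- paste(rep(regions, each = L), rep(sectors, R), sep = ".")
  dimnames(A) <- list(rs, rs)
  dimnames(y) <- list(rs, ch_categories(), regions)
  structure(list(A = A, y = y, x = setNames(as.numeric(x), rs),
                 regions = regions, sectors = sectors),
            class = "mrio_table")
}

#' @export
print.mrio_table <- function(x, ...) {
  cat(sprintf("<mrio_table> %d regions x %d sectors; spectral radius %.3f\n",
              length(x$regions), length(x$sectors), spectral_radius(x$A)))
  cat(sprintf("  total output %.4g, household final demand share %.1f%%\n",
              sum(x$x),
              100 * sum(x$y[, 1:2, ]) / sum(x$y)))
  invisible(x)
}

#' Spectral radius by power iteration
#'
#' For the nonnegative matrices arising as MRIO coefficient blocks the
#' dominant eigenvalue is real and nonnegative (Perron-Frobenius), so power
#' iteration on a positive start vector converges to the spectral radius.
#'
#' @param A Square numeric matrix.
#' @param iter Maximum iterations (default 50).
#' @param tol Convergence tolerance on the Rayleigh estimate (default 1e-9).
#' @return The spectral radius estimate.
#' @export
spectral_radius <- function(A, iter = 50L, tol = 1e-9) {
  n <- nrow(A)
  if (all(A == 0)) return(0)
  v <- rep(1 / sqrt(n), n)
  lam <- 0
  for (k in seq_len(iter)) {
    w <- as.numeric(A %*% v)
    nw <- sqrt(sum(w^2))
    if (nw == 0) return(0)
    v <- w / nw
    lam_new <- as.numeric(crossprod(v, A %*% v))
    if (abs(lam_new - lam) <= tol * max(1, abs(lam_new))) return(abs(lam_new))
    lam <- lam_new
  }
  abs(lam)
}

#' Leontief inverse (I - A)^-1
#'
#' Computed by a dense solve against the identity after a spectral-radius
#' pre-check; for a nonnegative productive coefficient matrix the inverse is
#' elementwise nonnegative (Neumann series).
#'
#' @param A Nonnegative coefficient matrix with spectral radius < 1.
#' @return The matrix `(I - A)^-1`.
#' @export
leontief_inverse <- function(A) {
  ch_check(is.matrix(A) && nrow(A) == ncol(A), "A must be square")
  ch_check(all(A >= 0), "A must be nonnegative")
  rho <- spectral_radius(A)
  ch_check(rho < 1, "non-productive economy: spectral radius %.4f >= 1", rho)
  Linv <- tryCatch(solve(diag(nrow(A)) - A),
                   error = function(e) ch_stop("Leontief solve failed: %s",
                                               conditionMessage(e)))
  Linv
}

#' Species-specific emission intensities per unit output
#'
#' Divides regional-sectoral production emissions by total sectoral output.
#' Sectors with zero output receive zero intensity (0/0 -> 0) with a warning.
#'
#' @param totals Emission array `[R, L, K]` (region, sector, species), Gg/yr.
#' @param x Output vector of length `R*L` (region-major).
#' @param regions,sectors Names used for error messages only.
#' @return Intensity array `[R, L, K]`, Gg per unit output.
#' @export
emission_intensity <- function(totals, x, regions = NULL, sectors = NULL) {
  d <- dim(totals)
  ch_check(length(d) == 3 && d[1] * d[2] == length(x),
           "totals [R,L,K] inconsistent with output vector length %d",
           length(x))
  ch_check(all(totals >= 0), "negative emission total")
  xm <- matrix(x, d[1], d[2], byrow = TRUE)  # x is region-major
  zero <- xm == 0
  if (any(zero & apply(totals, c(1, 2), sum) > 0))
    ch_stop("sector with zero output but nonzero emissions")
  if (any(zero))
    warning("sectors with zero output assigned zero emission intensity",
            call. = FALSE)
  f <- totals
  for (k in seq_len(d[3])) {
    fk <- totals[, , k] / xm
    fk[zero] <- 0
    f[, , k] <- fk
  }
  f
}

#' Emissions embodied in a final-demand slice
#'
#' Applies the intensity-weighted Leontief attribution
#' `e = f_hat (I - A)^-1 y` to one demand vector (one category, one
#' consuming region), giving the emissions occurring in each producing
#' region and sector that are caused by that demand.
#'
#' @param intensity Intensity array `[R, L, K]` from [emission_intensity()].
#' @param Linv Leontief inverse `[R*L, R*L]`.
#' @param y_slice Nonnegative demand vector of length `R*L` (region-major).
#' @return Array `[R, L, K]` of embodied emissions.
#' @export
embodied_emissions <- function(intensity, Linv, y_slice) {
  d <- dim(intensity)
  ch_check(length(y_slice) == d[1] * d[2],
           "demand vector length %d, expected %d", length(y_slice),
           d[1] * d[2])
  ch_check(all(y_slice >= 0), "negative demand")
  q <- as.numeric(Linv %*% y_slice)           # gross output requirement
  qm <- matrix(q, d[1], d[2], byrow = TRUE)
  e <- intensity
  for (k in seq_len(d[3])) e[, , k] <- intensity[, , k] * qm
  e
}

#' Embodied emissions for every category and consuming region
#'
#' @param intensity Intensity array `[R, L, K]`.
#' @param Linv Leontief inverse.
#' @param y Demand array `[R*L, 5, R]`.
#' @return Array `[R, L, K, 5, R]`: producing region, sector, species,
#'   category, consuming region.
#' @export
embodied_all <- function(intensity, Linv, y) {
  d <- dim(intensity); R <- dim(y)[3]
  out <- array(0, c(d, 5L, R))
  for (t in 1:5) for (s in seq_len(R)) {
    out[, , , t, s] <- embodied_emissions(intensity, Linv, y[, t, s])
  }
  out
}

#' Total household-consumption emissions of a region
#'
#' Adds household direct emissions to the supply-chain (embodied) emissions
#' summed over producing regions and sectors:
#' `ce_t^s = sum_r sum_l e_{l,t}^{r,s} + de_t^s`, per species.
#'
#' @param e Embodied array `[R, L, K, 5, R]` from [embodied_all()].
#' @param de Direct-emission vector/matrix per species for the setting and
#'   region (length `K`), or 0.
#' @param setting `"rural"` or `"urban"`.
#' @param s Consuming-region index.
#' @return Named numeric vector of length `K`.
#' @export
household_total_emissions <- function(e, de, setting, s) {
  setting <- match.arg(setting, ch_settings())
  t <- match(setting, ch_settings())       # rural -> category 1, urban -> 2
  K <- dim(e)[3]
  indirect <- apply(e[, , , t, s, drop = FALSE], 3, sum)
  de <- if (length(de) == 1 && de == 0) numeric(K) else de
  ch_check(length(de) == K, "direct emissions must have one entry per species")
  indirect + de
}
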