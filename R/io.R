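## Plain-text I/O for all tabular and gridded data. Tables are CSV with one
## header row; gridded fields are long-format CSV (lat, lon, optional index
## columns, value) with the grid and units recorded in '#'-comment header
## lines. Every reader/writer pair is a value-preserving round trip.

write_csv_meta <- function(df, path, meta = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(meta)) writeLines(paste0("# ", meta), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

read_csv_meta <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  df <- read.csv(text = lines[!grepl("^#", lines)], stringsAsFactors = FALSE)
  meta <- list()
  for (m in sub("^#\\s*", "", meta_lines)) {
    kv <- strsplit(m, ": ", fixed = TRUE)[[1]]
    if (length(kv) == 2) meta[[kv[1]]] <- kv[2]
  }
  attr(df, "meta") <- meta
  df
}

grid_meta <- function(grid) {
  sprintf("grid: %.10g %.10g %.10g %.10g %.10g %.10g",
          grid$lon_min, grid$lon_max, grid$lat_min, grid$lat_max,
          grid$dlon, grid$dlat)
}

grid_from_meta <- function(meta) {
  ch_check(!is.null(meta$grid), "file has no grid metadata")
  v <- as.numeric(strsplit(meta$grid, " ")[[1]])
  ch_grid(v[1], v[2], v[3], v[4], dlon = v[5], dlat = v[6])
}

#' Write an MRIO table to long-format CSV
#'
#' Coefficient entries carry the consuming sector in
#' `consuming_sector_or_category`; final-demand entries carry the category
#' name. Zero entries are omitted.
#'
#' @param mrio A [mrio_table()].
#' @param path Output CSV path.
#' @export
write_mrio <- function(mrio, path) {
  R <- length(mrio$regions); L <- length(mrio$sectors)
  reg <- rep(mrio$regions, each = L); sec <- rep(mrio$sectors, R)
  iA <- which(mrio$A != 0, arr.ind = TRUE)
  dfA <- data.frame(part = "A",
                    producing_region = reg[iA[, 1]],
                    producing_sector = sec[iA[, 1]],
                    consuming_region = reg[iA[, 2]],
                    consuming_sector_or_category = sec[iA[, 2]],
                    value = mrio$A[iA])
  iy <- which(mrio$y != 0, arr.ind = TRUE)
  dfy <- data.frame(part = "y",
                    producing_region = reg[iy[, 1]],
                    producing_sector = sec[iy[, 1]],
                    consuming_region = mrio$regions[iy[, 3]],
                    consuming_sector_or_category = ch_categories()[iy[, 2]],
                    value = mrio$y[iy])
  write_csv_meta(rbind(dfA, dfy), path,
                 c("units: monetary (table-native)",
                   sprintf("regions: %s", paste(mrio$regions, collapse = " ")),
                   sprintf("sectors: %s", paste(mrio$sectors, collapse = " "))))
}

#' Read an MRIO table from long-format CSV
#'
#' @param path CSV written by [write_mrio()].
#' @param config Optional `ch_config`; when given, region and sector lists
#'   must agree with the file.
#' @return A validated [mrio_table()].
#' @export
read_mrio <- function(path, config = NULL) {
  df <- read_csv_meta(path)
  meta <- attr(df, "meta")
  regions <- strsplit(meta$regions, " ")[[1]]
  sectors <- strsplit(meta$sectors, " ")[[1]]
  if (!is.null(config)) {
    ch_check(identical(regions, config$provinces) &&
             identical(sectors, config$sectors),
             "MRIO table dimensions [%d regions x %d sectors] do not match config [%d x %d]",
             length(regions), length(sectors),
             length(config$provinces), length(config$sectors))
  }
  R <- length(regions); L <- length(sectors); n <- R * L
  ch_check(all(df$value >= 0), "negative coefficient or demand in MRIO file")
  row_of <- function(reg, sec) (match(reg, regions) - 1) * L +
    match(sec, sectors)
  A <- matrix(0, n, n)
  dA <- df[df$part == "A", ]
  A[cbind(row_of(dA$producing_region, dA$producing_sector),
          row_of(dA$consuming_region, dA$consuming_sector_or_category))] <-
    dA$value
  y <- array(0, c(n, 5, R))
  dy <- df[df$part == "y", ]
  y[cbind(row_of(dy$producing_region, dy$producing_sector),
          match(dy$consuming_sector_or_category, ch_categories()),
          match(dy$consuming_region, regions))] <- dy$value
  mrio_table(A, y, regions, sectors)
}

#' Write a gridded field to long-format CSV
#'
#' @param x Field: matrix `[nlat, nlon]` or array with trailing index
#'   dimensions named via `index` (e.g. species, sector, receptor).
#' @param grid The [ch_grid()] of the field.
#' @param path Output path.
#' @param index Named list of index labels for trailing array dimensions.
#' @param units Unit string stored in metadata.
#' @export
write_gridded_field <- function(x, grid, path, index = list(),
                                units = "unspecified") {
  d <- dim(x)
  ch_check(d[1] == grid$nlat && d[2] == grid$nlon,
           "field does not lie on the given grid")
  ## expand.grid varies the first variable fastest, matching the array
  ## layout [nlat, nlon, index...]
  df <- do.call(expand.grid, c(list(lat = grid$lat, lon = grid$lon), index,
                               stringsAsFactors = FALSE))
  df$value <- as.vector(x)
  df <- df[df$value != 0, , drop = FALSE]   # zeros are implicit on read
  rownames(df) <- NULL
  write_csv_meta(df, path, c(grid_meta(grid), sprintf("units: %s", units)))
}

#' Read a gridded field written by [write_gridded_field()]
#'
#' @param path CSV path.
#' @param grid Expected grid; the file's grid must match within 1e-6
#'   degrees.
#' @param index Named list of index labels, as passed at write time.
#' @return Matrix or array `[nlat, nlon, ...]`.
#' @export
read_gridded_field <- function(path, grid, index = list()) {
  df <- read_csv_meta(path)
  fgrid <- grid_from_meta(attr(df, "meta"))
  ch_check(grids_equal(fgrid, grid),
           "grid mismatch: file has %dx%d cells at origin (%g, %g), expected %dx%d at (%g, %g)",
           fgrid$nlat, fgrid$nlon, fgrid$lon_min, fgrid$lat_min,
           grid$nlat, grid$nlon, grid$lon_min, grid$lat_min)
  d <- unname(c(grid$nlat, grid$nlon, vapply(index, length, 0L)))
  x <- array(0, if (length(d) > 2) d else d[1:2])
  ilat <- round((df$lat - grid$lat_min) / grid$dlat + 0.5)
  ilon <- round((df$lon - grid$lon_min) / grid$dlon + 0.5)
  pos <- ilat + grid$nlat * (ilon - 1)
  if (length(index)) {
    mult <- grid$nlat * grid$nlon
    for (nm in names(index)) {
      pos <- pos + mult * (match(df[[nm]], index[[nm]]) - 1)
      mult <- mult * length(index[[nm]])
    }
  }
  x[pos] <- df$value
  x
}

#' Write a grouped survey to a directory of CSV files
#'
#' @param survey A [grouped_survey()].
#' @param dir Output directory (created if absent).
#' @export
write_survey <- function(survey, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_csv_meta(survey$provinces, file.path(dir, "provinces.csv"),
                 "units: persons; persons/household; currency/person/yr")
  write_csv_meta(survey$groups, file.path(dir, "groups.csv"),
                 "units: currency/person/yr")
  ex <- do.call(rbind, lapply(ch_settings(), function(st) {
    v <- survey$expenditure[[st]]
    idx <- expand.grid(sector = survey$sectors,
                       group = seq_len(dim(v)[2]),
                       province = unique(survey$provinces$province),
                       stringsAsFactors = FALSE)
    cbind(setting = st, idx, value = as.vector(v))
  }))
  write_csv_meta(ex, file.path(dir, "expenditure.csv"),
                 "units: currency/person/yr")
  invisible(dir)
}

#' Read a grouped survey written by [write_survey()]
#'
#' @param dir Directory containing provinces.csv, groups.csv,
#'   expenditure.csv.
#' @param sectors Sector name vector (defines expenditure row order).
#' @return A [grouped_survey()].
#' @export
read_survey <- function(dir, sectors) {
  provinces <- read_csv_meta(file.path(dir, "provinces.csv"))
  groups <- read_csv_meta(file.path(dir, "groups.csv"))
  ex <- read_csv_meta(file.path(dir, "expenditure.csv"))
  provs <- unique(provinces$province)
  expenditure <- lapply(setNames(ch_settings(), ch_settings()), function(st) {
    e <- ex[ex$setting == st, ]
    J <- max(e$group)
    v <- array(NA_real_, c(length(sectors), J, length(provs)))
    v[cbind(match(e$sector, sectors), e$group,
            match(e$province, provs))] <- e$value
    v
  })
  attr(provinces, "meta") <- NULL; attr(groups, "meta") <- NULL
  grouped_survey(provinces, groups, expenditure, sectors)
}
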