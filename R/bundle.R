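#' Write a scenario input bundle to a directory
#'
#' Serializes every pipeline input to the package's plain-text formats:
#' `config.yaml`, `mrio.csv`, the survey CSVs, long-format gridded CSVs for
#' emissions, concentrations, population, sensitivities and the province
#' map, `direct_emissions.csv`, and `truth.json` with the generating
#' parameters and analytic shares.
#'
#' @param scen A `ch_scenario`.
#' @param dir Output directory.
#' @export
write_scenario <- function(scen, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- scen$config
  grid <- cfg$grid
  write_run_config(cfg, file.path(dir, "config.yaml"))
  write_mrio(scen$mrio, file.path(dir, "mrio.csv"))
  write_survey(scen$survey, file.path(dir, "survey"))
  write_gridded_field(scen$emissions$gridded, grid,
                      file.path(dir, "emissions.csv"),
                      index = list(sector = cfg$sectors,
                                   species = cfg$species),
                      units = "Gg/yr")
  write_gridded_field(scen$fields$pm25_all, grid,
                      file.path(dir, "pm25_all.csv"), units = "ug/m3")
  write_gridded_field(scen$fields$pm25_no_anth, grid,
                      file.path(dir, "pm25_no_anth.csv"), units = "ug/m3")
  write_gridded_field(scen$fields$population, grid,
                      file.path(dir, "population.csv"), units = "persons")
  write_gridded_field(scen$fields$sens, grid,
                      file.path(dir, "sensitivity.csv"),
                      index = list(species = cfg$species,
                                   receptor = scen$receptors),
                      units = "deaths per Gg/yr")
  write_gridded_field(matrix(as.numeric(scen$fields$province_map),
                             grid$nlat, grid$nlon), grid,
                      file.path(dir, "province_map.csv"),
                      units = "province index")
  de <- scen$emissions$direct
  dn <- dimnames(de)
  idx <- expand.grid(province = dn[[1]], setting = dn[[2]], source = dn[[3]],
                     species = dn[[4]], stringsAsFactors = FALSE)
  idx$value <- as.vector(de)
  write_csv_meta(idx, file.path(dir, "direct_emissions.csv"),
                 "units: Gg/yr")
  if (!is.null(scen$truth)) {
    tr <- scen$truth
    jsonlite::write_json(list(
      seed = tr$seed,
      biomass_coefficient = tr$biomass_coefficient,
      biomass_exponent = tr$biomass_exponent,
      kernel = tr$kernel, w_species = tr$w_species,
      share_house = list(dim = dim(tr$share_house),
                         values = as.vector(tr$share_house)),
      ce_class = list(dim = dim(tr$ce_class),
                      values = as.vector(tr$ce_class))
    ), file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read a scenario input bundle written by [write_scenario()]
#'
#' @param dir Bundle directory.
#' @return A `ch_scenario` (production totals are recovered from the
#'   gridded inventory, which conserves regional totals by construction).
#' @export
read_scenario <- function(dir) {
  cfg <- load_run_config(file.path(dir, "config.yaml"))
  grid <- cfg$grid
  mrio <- read_mrio(file.path(dir, "mrio.csv"), cfg)
  survey <- read_survey(file.path(dir, "survey"), cfg$sectors)
  gridded <- read_gridded_field(file.path(dir, "emissions.csv"), grid,
                                index = list(sector = cfg$sectors,
                                             species = cfg$species))
  receptors <- names(cfg$receptor_regions)
  sens <- read_gridded_field(file.path(dir, "sensitivity.csv"), grid,
                             index = list(species = cfg$species,
                                          receptor = receptors))
  province_map <- matrix(as.integer(round(read_gridded_field(
    file.path(dir, "province_map.csv"), grid))), grid$nlat, grid$nlon)
  receptor_of <- match(cfg$province_receptor, receptors)
  R <- length(cfg$provinces); L <- length(cfg$sectors)
  K <- length(cfg$species)
  totals <- array(0, c(R, L, K))
  gm <- array(gridded, c(grid$nlat * grid$nlon, L, K))
  for (r in seq_len(R)) {
    totals[r, , ] <- apply(gm[which(province_map == r), , , drop = FALSE],
                           c(2, 3), sum)
  }
  de_df <- read_csv_meta(file.path(dir, "direct_emissions.csv"))
  de <- array(0, c(R, 2, 3, K),
              dimnames = list(cfg$provinces, ch_settings(),
                              c("biomass", "fossil", "car"), cfg$species))
  de[cbind(match(de_df$province, cfg$provinces),
           match(de_df$setting, ch_settings()),
           match(de_df$source, c("biomass", "fossil", "car")),
           match(de_df$species, cfg$species))] <- de_df$value
  truth <- NULL
  tpath <- file.path(dir, "truth.json")
  if (file.exists(tpath)) {
    tj <- jsonlite::read_json(tpath, simplifyVector = TRUE)
    truth <- list(seed = tj$seed,
                  biomass_coefficient = tj$biomass_coefficient,
                  biomass_exponent = tj$biomass_exponent,
                  kernel = tj$kernel, w_species = tj$w_species,
                  share_house = array(tj$share_house$values,
                                      tj$share_house$dim),
                  ce_class = array(tj$ce_class$values, tj$ce_class$dim))
  }
  structure(list(
    seed = truth$seed %||% NA_integer_, config = cfg, mrio = mrio,
    survey = survey,
    emissions = list(totals = totals,
                     intensity = emission_intensity(totals, mrio$x),
                     direct = de, gridded = gridded),
    fields = list(
      province_map = province_map,
      receptor_map = matrix(receptor_of[province_map], grid$nlat, grid$nlon),
      population = read_gridded_field(file.path(dir, "population.csv"), grid),
      pm25_all = read_gridded_field(file.path(dir, "pm25_all.csv"), grid),
      pm25_no_anth = read_gridded_field(file.path(dir, "pm25_no_anth.csv"),
                                        grid),
      sens = sens),
    receptors = receptors, receptor_of = receptor_of, truth = truth
  ), class = "ch_scenario")
}

#' Write the report tables of a pipeline run
#'
#' Emits regional mortality, the full long-format attribution, the
#' cross-region matrix, Lorenz points and a JSON summary (Gini values and
#' decile shares) to a directory.
#'
#' @param run A `conshealth_run`.
#' @param dir Output directory.
#' @export
write_report <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_csv_meta(data.frame(receptor = run$receptors,
                            deaths_anth = run$mortality$M_receptor_total),
                 file.path(dir, "regional_mortality.csv"),
                 "units: deaths/yr")
  a <- run$attribution
  S <- dim(a$house)[1]; nc <- dim(a$house)[2]; nr <- dim(a$house)[3]
  idx <- expand.grid(consuming_province = run$config$provinces,
                     class = seq_len(nc), receptor = run$receptors,
                     stringsAsFactors = FALSE)
  idx$setting <- ifelse(idx$class <= 5, "rural", "urban")
  idx$group <- ifelse(idx$class <= 5, idx$class, idx$class - 5L)
  idx$deaths <- as.vector(a$house)
  idx$deaths_direct <- as.vector(a$house_direct)
  idx$deaths_indirect <- as.vector(a$house_indirect)
  write_csv_meta(idx[c("consuming_province", "setting", "group", "receptor",
                       "deaths", "deaths_direct", "deaths_indirect")],
                 file.path(dir, "attribution.csv"), "units: deaths/yr")
  cr <- run$cross_region$matrix
  ci <- expand.grid(consuming = dimnames(cr)[[1]], occurring = dimnames(cr)[[2]],
                    setting = dimnames(cr)[[3]], type = dimnames(cr)[[4]],
                    stringsAsFactors = FALSE)
  ci$deaths <- as.vector(cr)
  write_csv_meta(ci, file.path(dir, "cross_region.csv"), "units: deaths/yr")
  lz <- do.call(rbind, lapply(names(run$inequality$lorenz), function(nm) {
    cbind(curve = nm, run$inequality$lorenz[[nm]]$points)
  }))
  write_csv_meta(lz, file.path(dir, "lorenz.csv"), "units: cumulative share")
  jsonlite::write_json(list(
    gini = as.list(run$inequality$gini),
    deciles = run$inequality$deciles,
    deaths_total = sum(run$mortality$M_receptor_total),
    share_direct = sum(a$house_direct) / sum(run$mortality$M_receptor_total),
    share_indirect = sum(a$house_indirect) / sum(run$mortality$M_receptor_total)
  ), file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA,
  dataframe = "columns")
  invisible(dir)
}
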