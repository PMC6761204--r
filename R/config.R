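#' Build a run configuration in code
#'
#' The run configuration names every index set of a run (provinces, receptor
#' regions, sectors, species, endpoints), carries the grid definition, the
#' IER parameter and baseline-incidence tables, Monte-Carlo settings, and
#' the expenditure-proxy concordance used to allocate household direct
#' emissions. [load_run_config()] reads the same structure from YAML.
#'
#' @param provinces Character vector of province names (the MRIO regions).
#' @param receptor_regions Named list mapping receptor-region name to the
#'   character vector of member provinces; must partition `provinces`.
#' @param sectors Character vector of MRIO sector names.
#' @param species Character vector of emitted species (default the six
#'   anthropogenic PM2.5 precursor/primary species).
#' @param endpoints Mortality endpoints (default IHD, stroke, COPD, LC).
#' @param grid A [ch_grid()].
#' @param ier IER parameter data.frame, see [ier_parameters()].
#' @param incidence Named numeric vector of baseline incidence
#'   (deaths/person/yr) per endpoint, see [baseline_incidence()].
#' @param mc_draws,mc_seed Monte-Carlo draw count and seed.
#' @param proxy_sectors Named list with elements `residential_energy` and
#'   `transport`: the MRIO sector names used as expenditure proxies when
#'   allocating household direct fossil-fuel and private-car emissions.
#' @param paths Optional named list of input file paths.
#' @return Object of class `ch_config`.
#' @export
run_config <- function(provinces, receptor_regions, sectors,
                       species = ch_species(),
                       endpoints = ch_endpoints(),
                       grid = NULL,
                       ier = ier_parameters(),
                       incidence = baseline_incidence(),
                       mc_draws = 1000, mc_seed = 1L,
                       proxy_sectors = list(residential_energy = sectors[1],
                                            transport = sectors[length(sectors)]),
                       paths = list()) {
  cfg <- list(provinces = provinces, receptor_regions = receptor_regions,
              sectors = sectors, species = species, endpoints = endpoints,
              categories = ch_categories(), settings = ch_settings(),
              grid = grid, ier = ier, incidence = incidence,
              mc_draws = mc_draws, mc_seed = mc_seed,
              proxy_sectors = proxy_sectors, paths = paths)
  validate_config(cfg)
}

validate_config <- function(cfg) {
  for (key in c("provinces", "receptor_regions", "sectors", "species",
                "endpoints")) {
    ch_check(!is.null(cfg[[key]]) && length(cfg[[key]]) > 0,
             "configuration error: missing required key '%s'", key)
  }
  for (key in c("sectors", "species", "endpoints", "provinces")) {
    ch_check(!anyDuplicated(cfg[[key]]),
             "configuration error: duplicate entries in '%s'", key)
  }
  members <- unlist(cfg$receptor_regions, use.names = FALSE)
  ch_check(!anyDuplicated(members),
           "region/province mapping is not a partition: %s mapped twice",
           paste(members[duplicated(members)], collapse = ", "))
  ch_check(setequal(members, cfg$provinces),
           "region/province mapping is not a partition: provinces [%s] unassigned",
           paste(setdiff(cfg$provinces, members), collapse = ", "))
  ch_check(all(unlist(cfg$proxy_sectors) %in% cfg$sectors),
           "configuration error: proxy sector not in sector list")
  cfg$mc_draws <- as.integer(cfg$mc_draws %||% 1000L)
  cfg$mc_seed <- as.integer(cfg$mc_seed %||% 1L)
  ## province -> receptor lookup
  cfg$province_receptor <- setNames(
    rep(names(cfg$receptor_regions), lengths(cfg$receptor_regions)),
    unlist(cfg$receptor_regions, use.names = FALSE))[cfg$provinces]
  structure(cfg, class = "ch_config")
}

#' Load and validate a run configuration from YAML
#'
#' Optional fields receive defaults (grid steps 2/3 and 0.5 degrees,
#' 1000 Monte-Carlo draws, seed 1, packaged IER and incidence tables).
#'
#' @param path Path to a YAML configuration file.
#' @return A validated `ch_config`.
#' @export
load_run_config <- function(path) {
  ch_check(file.exists(path), "configuration error: file '%s' not found", path)
  raw <- yaml::read_yaml(path)
  g <- raw$grid
  grid <- if (!is.null(g)) {
    ## cell counts take precedence over steps: they survive serialization
    ## exactly, while a step like 2/3 degrees cannot be written in decimal
    dlon <- if (!is.null(g$nlon)) (g$lon_max - g$lon_min) / g$nlon
            else g$dlon %||% 2 / 3
    dlat <- if (!is.null(g$nlat)) (g$lat_max - g$lat_min) / g$nlat
            else g$dlat %||% 0.5
    ch_grid(g$lon_min, g$lon_max, g$lat_min, g$lat_max,
            dlon = dlon, dlat = dlat)
  }
  ier <- if (!is.null(raw$ier)) {
    do.call(rbind, lapply(names(raw$ier), function(ep) {
      p <- raw$ier[[ep]]
      data.frame(endpoint = ep, alpha = p$alpha, gamma = p$gamma,
                 delta = p$delta, C0 = p$C0)
    }))
  } else ier_parameters()
  incidence <- if (!is.null(raw$incidence)) {
    unlist(raw$incidence)
  } else baseline_incidence()
  run_config(
    provinces = raw$provinces,
    receptor_regions = raw$receptor_regions,
    sectors = raw$sectors,
    species = raw$species %||% ch_species(),
    endpoints = raw$endpoints %||% ch_endpoints(),
    grid = grid, ier = ier, incidence = incidence,
    mc_draws = raw$mc_draws %||% 1000L,
    mc_seed = raw$mc_seed %||% 1L,
    proxy_sectors = raw$proxy_sectors %||%
      list(residential_energy = raw$sectors[1],
           transport = raw$sectors[length(raw$sectors)]),
    paths = raw$paths %||% list()
  )
}

#' Write a run configuration to YAML
#' @param cfg A `ch_config`.
#' @param path Output file path.
#' @export
write_run_config <- function(cfg, path) {
  g <- cfg$grid
  out <- list(
    provinces = cfg$provinces,
    receptor_regions = cfg$receptor_regions,
    sectors = cfg$sectors, species = cfg$species, endpoints = cfg$endpoints,
    grid = if (!is.null(g)) list(lon_min = g$lon_min, lon_max = g$lon_max,
                                 lat_min = g$lat_min, lat_max = g$lat_max,
                                 nlon = g$nlon, nlat = g$nlat),
    ier = setNames(lapply(seq_len(nrow(cfg$ier)), function(i) {
      as.list(cfg$ier[i, c("alpha", "gamma", "delta", "C0")])
    }), cfg$ier$endpoint),
    incidence = as.list(cfg$incidence),
    mc_draws = cfg$mc_draws, mc_seed = cfg$mc_seed,
    proxy_sectors = cfg$proxy_sectors,
    paths = cfg$paths
  )
  yaml::write_yaml(out[!vapply(out, is.null, TRUE)], path)
  invisible(path)
}

#' @export
print.ch_config <- function(x, ...) {
  cat(sprintf(
    "<ch_config> %d provinces in %d receptor regions, %d sectors, %d species, %d endpoints\n",
    length(x$provinces), length(x$receptor_regions), length(x$sectors),
    length(x$species), length(x$endpoints)))
  if (!is.null(x$grid)) print(x$grid)
  invisible(x)
}
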