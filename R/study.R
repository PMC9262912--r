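#' Study configuration
#'
#' Validated bundle of every choice defining a full toy-scale study:
#' grid, span, LAI trend scenario, simulator parameters, ensemble size
#' and seed base, seasons to control, and hydrological regime. The
#' configuration hash is recorded in every output manifest, and an
#' identical configuration reproduces byte-identical summary tables.
#'
#' @param nlat,nlon grid size; cell centres span `lat_range` /
#'   `lon_range`.
#' @param lat_range,lon_range domain bounds in degrees (default the
#'   25-90 deg N northern land belt, full longitudes).
#' @param years simulated calendar years.
#' @param members ensemble size per experiment.
#' @param seed_base member `i` uses seed `seed_base + i`.
#' @param seasons seasonal controls to run (subset of MAM/JJA/SON).
#' @param regime hydrological regime of [default_forcing()].
#' @param scenario named list of [lai_scenario()] overrides.
#' @param params named list of [sim_params()] overrides.
#' @param spinup_years discarded spin-up years per member.
#' @param lai_threshold climatological-LAI land-mask threshold.
#' @return object of class `study_config`.
#' @export
study_config <- function(nlat = 16, nlon = 16, lat_range = c(25, 90),
                         lon_range = c(0, 360), years = 1982:2014,
                         members = 30, seed_base = 1000,
                         seasons = c("MAM", "JJA", "SON"),
                         regime = "wet", scenario = list(),
                         params = list(), spinup_years = 1,
                         lai_threshold = 0.1) {
  stopifnot(nlat >= 2, nlon >= 2, length(years) >= 3, members >= 1,
            all(seasons %in% c("MAM", "JJA", "SON")))
  dlat <- diff(lat_range) / nlat
  dlon <- diff(lon_range) / nlon
  cfg <- structure(list(
    lat = lat_range[1] + dlat * (seq_len(nlat) - 0.5),
    lon = lon_range[1] + dlon * (seq_len(nlon) - 0.5),
    years = as.integer(years),
    members = as.integer(members),
    seed_base = as.integer(seed_base),
    seasons = seasons,
    regime = match.arg(regime, c("wet", "moisture_limited")),
    scenario = do.call(lai_scenario, scenario),
    params = do.call(sim_params, params),
    spinup_years = as.integer(spinup_years),
    lai_threshold = lai_threshold
  ), class = "study_config")
  cfg$hash <- config_hash(unclass(cfg))
  cfg
}

#' Read a study configuration from a YAML file
#'
#' The file holds key-value pairs matching the arguments of
#' [study_config()] (with `scenario:` and `params:` as nested blocks).
#'
#' @param path YAML file path.
#' @return a [study_config()].
#' @export
read_study_config <- function(path) {
  doc <- yaml::read_yaml(path)
  known <- setdiff(names(formals(study_config)), "...")
  bad <- setdiff(names(doc), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (!is.null(doc$years) && length(doc$years) == 2L)
    doc$years <- doc$years[1]:doc$years[2]
  if (!is.null(doc$scenario$slopes))
    doc$scenario$slopes <- unlist(doc$scenario$slopes)
  do.call(study_config, doc)
}

#' Run the full paired-experiment study
#'
#' Executes the whole chain at toy scale: generate the LAI scenario,
#' build one season-fixed control per requested season, run seed-matched
#' ensembles, difference them, decompose the in-season response into
#' forcing components, and produce the figure-ready summary tables:
#' intra-/inter-seasonal induced-temperature trends, the monthly trend
#' matrix, forcing-component trends, the seasonal-amplitude (July minus
#' January) series, and the phase-space summaries of the carry-over
#' response. Identical configurations yield byte-identical tables.
#'
#' @param config a [study_config()].
#' @param out_dir optional directory; when given, all tables are
#'   written as tab-separated text with a units header plus a JSON
#'   manifest carrying the configuration hash.
#' @param keep_members variables to retain per member (memory permitting).
#' @return list with `tables` (named list of data.frames), `mask`,
#'   `set` (the [experiment_set()]), `lai`, and `config`.
#' @export
run_study <- function(config, out_dir = NULL, keep_members = character(0)) {
  stopifnot(inherits(config, "study_config"))
  lat <- config$lat; lon <- config$lon
  log_msg("generating LAI scenario (%d years, %dx%d grid)",
          length(config$years), length(lat), length(lon))
  lai <- generate_lai_scenario(config$scenario, lat, lon, config$years)
  mask <- climatological_lai_mask(lai, config$lai_threshold)
  forcing <- default_forcing(lat, config$regime)
  seeds <- config$seed_base + seq_len(config$members)

  log_msg("running SCE ensemble (%d members)", config$members)
  sce <- run_ensemble(lai, forcing, config$params, seeds,
                      keep_members = keep_members,
                      spinup_years = config$spinup_years)
  controls <- list()
  for (s in config$seasons) {
    log_msg("running %s control ensemble", s)
    controls[[s]] <- run_ensemble(make_control_lai(lai, s), forcing,
                                  config$params, seeds,
                                  keep_members = keep_members,
                                  spinup_years = config$spinup_years)
  }
  set <- experiment_set(sce, controls)

  nh_series <- function(field) area_weighted_mean(field, mask = mask)
  as_series_field <- function(values, months) {
    grid_field(array(values, c(length(values), 1L, 1L)), 0, 0,
               months = months, contiguous = FALSE)
  }
  season_trend <- function(values, months, season) {
    sf <- seasonal_series(as_series_field(values, months), season)
    ols_trend(as.vector(sf$values), sf$years)
  }

  deltas <- lapply(config$seasons, function(s) delta_field(set, "t_a", s))
  names(deltas) <- config$seasons

  # intra/inter trends of NH-mean induced T_a
  rows <- list()
  for (s in config$seasons) {
    dv <- nh_series(deltas[[s]])
    for (target in SEASON_KEYS) {
      tr <- season_trend(dv, deltas[[s]]$months, target)
      rows[[length(rows) + 1L]] <- data.frame(
        control_season = s, target_season = target,
        type = if (target == s) "intra" else "inter",
        slope_decade = tr$slope_decade, se_decade = tr$se_decade,
        p_value = tr$p_value, stars = tr$stars)
    }
  }
  intra_inter <- do.call(rbind, rows)

  # monthly trend matrix
  rows <- list()
  for (s in config$seasons) {
    dv <- nh_series(deltas[[s]])
    for (m in 1:12) {
      sel <- deltas[[s]]$months$month == m
      tr <- ols_trend(dv[sel], deltas[[s]]$months$year[sel])
      rows[[length(rows) + 1L]] <- data.frame(
        control_season = s, month = m, slope_decade = tr$slope_decade,
        se_decade = tr$se_decade, p_value = tr$p_value, stars = tr$stars)
    }
  }
  monthly_matrix <- do.call(rbind, rows)

  # forcing-component trends in the controlled season
  rows <- list()
  for (s in config$seasons) {
    dec <- decompose_experiment(set, s, baseline = "climatology")
    comp_list <- c(unclass(dec$components), dec$groups)
    for (nm in names(comp_list)) {
      f <- grid_field(comp_list[[nm]], dec$lat, dec$lon,
                      months = dec$months, units = "W m-2")
      tr <- season_trend(nh_series(f), dec$months, s)
      rows[[length(rows) + 1L]] <- data.frame(
        control_season = s, component = nm,
        slope_decade = tr$slope_decade, se_decade = tr$se_decade,
        p_value = tr$p_value, stars = tr$stars)
    }
  }
  forcing_trends <- do.call(rbind, rows)

  # seasonal temperature amplitude: SCE and LAI-induced (summed controls)
  months <- set$sce$mean$months
  sce_ta <- nh_series(run_field(set$sce$mean, "t_a"))
  induced <- Reduce(`+`, lapply(deltas, nh_series))
  sat_sce <- sat_amplitude(sce_ta, months)
  sat_ind <- sat_amplitude(induced, months)
  sat_table <- data.frame(year = attr(sat_sce, "years"),
                          sat_sce = as.numeric(sat_sce),
                          sat_induced = as.numeric(sat_ind))
  tr_sce <- ols_trend(sat_table$sat_sce, sat_table$year)
  tr_ind <- ols_trend(sat_table$sat_induced, sat_table$year)
  sat_trends <- data.frame(
    series = c("sat_sce", "sat_induced"),
    slope_decade = c(tr_sce$slope_decade, tr_ind$slope_decade),
    se_decade = c(tr_sce$se_decade, tr_ind$se_decade),
    p_value = c(tr_sce$p_value, tr_ind$p_value),
    stars = c(tr_sce$stars, tr_ind$stars))

  # phase-space summaries of the carry-over (inter-seasonal) response
  phase <- list()
  for (s in config$seasons) {
    inter_trend <- function(variable) {
      d <- delta_field(set, variable, s)
      sp <- split_intra_inter(d, s)
      yearly <- yearly_mean_field(sp$inter)
      trend_map(yearly)$slope_decade
    }
    ps <- phase_space_summary(inter_trend("t_a"), inter_trend("sm"),
                              inter_trend("z500"), mask = mask)
    phase[[s]] <- rbind(
      cbind(driver = "sm", ps$marginal_x),
      cbind(driver = "z500", ps$marginal_y))
  }
  phase_table <- do.call(rbind, lapply(names(phase), function(s)
    cbind(control_season = s, phase[[s]])))

  tables <- list(intra_inter_trends = intra_inter,
                 monthly_trend_matrix = monthly_matrix,
                 forcing_component_trends = forcing_trends,
                 sat_series = sat_table,
                 sat_trends = sat_trends,
                 phase_space = phase_table)
  if (!is.null(out_dir)) write_study_tables(tables, config, out_dir)
  list(tables = tables, mask = mask, set = set, lai = lai, config = config)
}

#' Per-year mean of a (possibly non-contiguous) monthly field
#' @param field monthly [grid_field()].
#' @return an [annual_field()] of per-year means over the months present.
#' @export
yearly_mean_field <- function(field) {
  stopifnot(inherits(field, "grid_field"), is_time_field(field))
  years <- sort(unique(field$months$year))
  d <- dim(field$values)
  out <- array(NA_real_, c(length(years), d[2], d[3]))
  for (i in seq_along(years)) {
    rows <- which(field$months$year == years[i])
    out[i, , ] <- apply(field$values[rows, , , drop = FALSE], c(2, 3), mean)
  }
  annual_field(out, field$lat, field$lon, years, units = field$units,
               name = field$name)
}

#' Write study tables and manifest to a directory
#'
#' Tables are tab-separated with a fixed `%.10g` numeric format, so a
#' rerun under the same configuration is byte-identical. The manifest
#' records the configuration hash, seeds and package version.
#'
#' @param tables named list of data.frames.
#' @param config the [study_config()] that produced them.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_study_tables <- function(tables, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(tables)) {
    df <- tables[[nm]]
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(v) sprintf("%.10g", v))
    utils::write.table(df, file.path(out_dir, paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest <- list(config_hash = config$hash,
                   members = config$members,
                   seed_base = config$seed_base,
                   seasons = config$seasons,
                   package = as.character(utils::packageVersion("greenfeedback")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
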