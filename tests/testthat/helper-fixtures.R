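# Shared in-code fixtures: tiny grids and runs kept small so the whole
# suite stays fast.

tiny_lat <- seq(30, 70, by = 10)     # 5 cells
tiny_lon <- seq(0, 120, by = 40)     # 4 cells

tiny_monthly_field <- function(years = 2001:2003, fill = NULL,
                               lat = tiny_lat, lon = tiny_lon) {
  st <- month_stamps(years)
  nt <- nrow(st)
  vals <- if (is.null(fill)) {
    array(seq_len(nt * length(lat) * length(lon)) / 100,
          c(nt, length(lat), length(lon)))
  } else {
    array(fill, c(nt, length(lat), length(lon)))
  }
  grid_field(vals, lat, lon, months = st, units = "K")
}

tiny_lai <- function(years = 2001:2004, noise_sd = 0, seed = 11,
                     slopes = c(MAM = 0.019, JJA = 0.046, SON = 0.027, DJF = 0),
                     lat = tiny_lat, lon = tiny_lon) {
  generate_lai_scenario(
    lai_scenario(slopes = slopes, noise_sd = noise_sd, seed = seed),
    lat, lon, years)
}

# A small seed-matched paired experiment used by several test files.
tiny_experiment <- function(seasons = "JJA", members = 2, years = 2001:2006,
                            regime = "wet", params = sim_params(),
                            noise_sd = 0, seed_base = 300) {
  lai <- tiny_lai(years, noise_sd = noise_sd)
  forcing <- default_forcing(tiny_lat, regime)
  seeds <- seed_base + seq_len(members)
  sce <- run_ensemble(lai, forcing, params, seeds, keep_members = "t_a")
  controls <- lapply(stats::setNames(seasons, seasons), function(s)
    run_ensemble(make_control_lai(lai, s), forcing, params, seeds,
                 keep_members = "t_a"))
  list(set = experiment_set(sce, controls), lai = lai,
       mask = climatological_lai_mask(lai))
}
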