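#' Control LAI with one season fixed to climatology
#'
#' Reproduces the paired-experiment forcing: inside the chosen season,
#' each calendar month's LAI is replaced (every year) by that month's
#' multi-year climatology; all other months keep their dynamic values.
#' Differencing a dynamic-LAI run against a run forced this way
#' isolates the effect of that season's LAI variability, both in-season
#' and through carry-over into later seasons.
#'
#' @param lai monthly [grid_field()] over the full record.
#' @param season season key whose months are fixed.
#' @return monthly [grid_field()] of the control LAI.
#' @export
make_control_lai <- function(lai, season) {
  stopifnot(inherits(lai, "grid_field"), is_time_field(lai))
  season <- match.arg(season, SEASON_KEYS)
  clim <- monthly_climatology(lai)
  out <- lai$values
  for (m in season_months(season)) {
    rows <- which(lai$months$month == m)
    for (t in rows) out[t, , ] <- clim[m, , ]
  }
  grid_field(out, lai$lat, lai$lon, months = lai$months, units = lai$units,
             name = lai$name)
}

#' Run a seed-indexed initial-condition ensemble
#'
#' One [simulate_run()] per seed, sharing LAI, forcing and parameters.
#' The ensemble mean of every simulator field is accumulated on the
#' fly; full per-member fields are retained only for the variables in
#' `keep_members` (needed e.g. for ensemble sign-agreement counts).
#'
#' @param lai monthly [grid_field()] of LAI.
#' @param forcing a [default_forcing()].
#' @param params a [sim_params()].
#' @param seeds integer vector of distinct member seeds.
#' @param keep_members character vector of variables whose per-member
#'   fields are retained.
#' @param spinup_years passed to [simulate_run()].
#' @return object of class `lasim_ensemble`: list with `mean` (a
#'   `lasim_run` of ensemble-mean fields), `members` (per-member kept
#'   fields), `seeds`, `n`.
#' @export
run_ensemble <- function(lai, forcing, params = sim_params(), seeds,
                         keep_members = character(0), spinup_years = 1L) {
  if (length(seeds) < 1L) stop("at least one seed required", call. = FALSE)
  if (anyDuplicated(seeds)) stop("duplicate member seeds", call. = FALSE)
  acc <- NULL
  members <- vector("list", length(seeds))
  proto <- NULL
  for (i in seq_along(seeds)) {
    run <- simulate_run(lai, forcing, params, seed = seeds[i],
                        spinup_years = spinup_years)
    if (is.null(acc)) {
      acc <- run$fields
      proto <- run
    } else {
      for (v in names(acc)) acc[[v]] <- acc[[v]] + run$fields[[v]]
    }
    if (length(keep_members))
      members[[i]] <- run$fields[keep_members]
  }
  for (v in names(acc)) acc[[v]] <- acc[[v]] / length(seeds)
  mean_run <- proto
  mean_run$fields <- acc
  mean_run$seed <- NA_integer_
  structure(list(mean = mean_run, members = members,
                 seeds = as.integer(seeds), n = length(seeds),
                 keep_members = keep_members),
            class = "lasim_ensemble")
}

#' @export
print.lasim_ensemble <- function(x, ...) {
  cat(sprintf("<lasim_ensemble> %d members, seeds %s..%s\n", x$n,
              x$seeds[1], x$seeds[x$n]))
  invisible(x)
}

#' Ensemble mean as a run object
#' @param ens a `lasim_ensemble`.
#' @return a `lasim_run` holding ensemble-mean fields.
#' @export
ensemble_mean <- function(ens) {
  stopifnot(inherits(ens, "lasim_ensemble"))
  ens$mean
}

#' Paired experiment set: dynamic run plus seasonal controls
#'
#' Bundles the dynamic-LAI ensemble (SCE) with season-fixed control
#' ensembles. All ensembles must share seeds member-by-member (the
#' paired design), grids and spans.
#'
#' @param sce `lasim_ensemble` of the dynamic-LAI experiment.
#' @param controls named list of `lasim_ensemble`s, names in
#'   MAM/JJA/SON, each differing from SCE only in the fixed season's
#'   LAI.
#' @return object of class `experiment_set`.
#' @export
experiment_set <- function(sce, controls) {
  stopifnot(inherits(sce, "lasim_ensemble"),
            all(names(controls) %in% SEASON_KEYS))
  for (nm in names(controls)) {
    ctl <- controls[[nm]]
    stopifnot(inherits(ctl, "lasim_ensemble"))
    if (!identical(ctl$seeds, sce$seeds))
      stop("control ", nm, " does not share SCE member seeds", call. = FALSE)
    if (!identical(dim(ctl$mean$fields$t_a), dim(sce$mean$fields$t_a)))
      stop("control ", nm, " grid/span mismatch with SCE", call. = FALSE)
  }
  structure(list(sce = sce, controls = controls), class = "experiment_set")
}

#' Ensemble-mean difference field (SCE minus a seasonal control)
#'
#' @param set an [experiment_set()].
#' @param variable simulator variable name.
#' @param control_season which seasonal control to difference against.
#' @return monthly [grid_field()] of the ensemble-mean difference, with
#'   attribute `control_season`.
#' @export
delta_field <- function(set, variable, control_season) {
  stopifnot(inherits(set, "experiment_set"))
  control_season <- match.arg(control_season, names(set$controls))
  ctl <- set$controls[[control_season]]
  if (ctl$n != set$sce$n) stop("mismatched member counts", call. = FALSE)
  sce_m <- set$sce$mean
  d <- sce_m$fields[[variable]] - ctl$mean$fields[[variable]]
  out <- grid_field(d, sce_m$lat, sce_m$lon, months = sce_m$months,
                    units = run_field(sce_m, variable)$units,
                    name = paste0("d_", variable))
  attr(out, "control_season") <- control_season
  out
}

#' Per-member difference fields
#'
#' Member-paired differences (same seed in SCE and control) of one
#' variable; requires the variable to have been retained via
#' `keep_members` in both ensembles.
#'
#' @inheritParams delta_field
#' @return list of `[ntime x nlat x nlon]` arrays, one per member.
#' @export
delta_members <- function(set, variable, control_season) {
  stopifnot(inherits(set, "experiment_set"))
  control_season <- match.arg(control_season, names(set$controls))
  ctl <- set$controls[[control_season]]
  if (!variable %in% set$sce$keep_members || !variable %in% ctl$keep_members)
    stop("variable ", variable, " was not retained per member", call. = FALSE)
  lapply(seq_len(set$sce$n), function(i)
    set$sce$members[[i]][[variable]] - ctl$members[[i]][[variable]])
}

#' Partition a difference field into intra- and inter-seasonal months
#'
#' Months falling inside the control's fixed season are the
#' intra-seasonal response (same-season feedback); all other months are
#' the inter-seasonal (carry-over) response. The two parts partition
#' the record: no month is lost or duplicated.
#'
#' @param delta a monthly difference [grid_field()] carrying a
#'   `control_season` attribute (from [delta_field()]), or with
#'   `control_season` supplied explicitly.
#' @param control_season season key; defaults to the attribute.
#' @return list with `intra` and `inter` [grid_field()]s (non-contiguous
#'   month subsets).
#' @export
split_intra_inter <- function(delta, control_season = attr(delta, "control_season")) {
  stopifnot(inherits(delta, "grid_field"), is_time_field(delta))
  if (is.null(control_season)) stop("control_season not specified", call. = FALSE)
  control_season <- match.arg(control_season, SEASON_KEYS)
  in_season <- delta$months$month %in% season_months(control_season)
  subset_months <- function(sel) {
    out <- grid_field(delta$values[sel, , , drop = FALSE], delta$lat, delta$lon,
                      months = delta$months[sel, , drop = FALSE],
                      units = delta$units, name = delta$name,
                      contiguous = FALSE)
    attr(out, "control_season") <- control_season
    out
  }
  list(intra = subset_months(which(in_season)),
       inter = subset_months(which(!in_season)))
}

#' Summed lagged (inter-seasonal) response in a target season
#'
#' For a growing-season target, sums the difference fields from the
#' other growing-season controls evaluated in the target season's
#' months; for DJF — when no experiment fixes winter LAI — sums the
#' responses from all three growing-season controls, giving the
#' overall winter effect of growing-season greening.
#'
#' @param deltas named list (by control season, names in MAM/JJA/SON)
#'   of monthly difference [grid_field()]s.
#' @param target_season season key in which the response is evaluated.
#' @return [grid_field()] over the target season's months (cellwise sum
#'   across the contributing controls).
#' @export
lagged_sum <- function(deltas, target_season) {
  target_season <- match.arg(target_season, SEASON_KEYS)
  growing <- c("MAM", "JJA", "SON")
  need <- if (target_season == "DJF") growing else setdiff(growing, target_season)
  missing <- setdiff(need, names(deltas))
  if (length(missing))
    stop("missing control difference field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  mm <- season_months(target_season)
  acc <- NULL
  ref <- NULL
  for (s in need) {
    d <- deltas[[s]]
    sel <- which(d$months$month %in% mm)
    vals <- d$values[sel, , , drop = FALSE]
    if (is.null(acc)) {
      acc <- vals
      ref <- list(months = d$months[sel, , drop = FALSE], lat = d$lat,
                  lon = d$lon, units = d$units, name = d$name)
    } else {
      acc <- acc + vals
    }
  }
  out <- grid_field(acc, ref$lat, ref$lon, months = ref$months,
                    units = ref$units, name = ref$name, contiguous = FALSE)
  attr(out, "target_season") <- target_season
  out
}

#' Ensemble sign agreement of a regional response
#'
#' Counts the members whose regional/seasonal mean difference shares
#' the sign of the ensemble-mean response — the standard robustness
#' check for circulation-mediated patterns.
#'
#' @param member_deltas list of per-member `[ntime x nlat x nlon]`
#'   difference arrays (see [delta_members()]).
#' @param lat latitudes of the arrays' grid.
#' @param mask optional logical `[nlat x nlon]` region selector.
#' @param month_sel optional logical/integer selector on the time axis.
#' @return list with `count`, `n`, and `fraction` of members agreeing
#'   in sign with the ensemble mean.
#' @export
sign_agreement <- function(member_deltas, lat, mask = NULL, month_sel = NULL) {
  stopifnot(length(member_deltas) >= 1L)
  member_stat <- vapply(member_deltas, function(arr) {
    if (!is.null(month_sel)) arr <- arr[month_sel, , , drop = FALSE]
    series <- area_weighted_mean(
      grid_field(arr, lat, seq_len(dim(arr)[3]),
                 months = data.frame(year = seq_len(dim(arr)[1]), month = 1L),
                 contiguous = FALSE),
      mask = mask)
    mean(series)
  }, numeric(1))
  ens <- mean(member_stat)
  count <- sum(sign(member_stat) == sign(ens))
  list(count = as.integer(count), n = length(member_deltas),
       fraction = count / length(member_deltas))
}
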