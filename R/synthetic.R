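# Bundled toy crop-like model with planted variable roles. The fixture is
# not a calibrated crop model: it exists so that every stage of the
# reduction pipeline can be exercised end-to-end, with known ground truth
# about which variables are essential, redundant, or noise.
#
# Data-generating truth: the model with its two spurious mechanisms turned
# off (radiation-use modifier held at 1, canopy-temperature switch at 0).
# Those mechanisms fluctuate with the weather and bias predictions, which
# is precisely what makes their variables "noise": replacing them with a
# constant improves the fit. Redundancy is planted by construction - terms
# that are analytically near-neutral over the generated driver range - and
# is therefore conditional on that range, as any redundancy finding is.

#' Configuration for the toy crop fixture
#'
#' @param n_sites Number of sites (default 4; site 1 is droughted, site 2
#'   generously watered).
#' @param season_length Days simulated from sowing (default 150).
#' @param sampling_days 0-based days on which biomass and LAI are observed
#'   (default every 12 days from day 20).
#' @param grain_obs_from Grain is only observed from this day on (post
#'   anthesis; default 80), mirroring growth-analysis sampling.
#' @param se_fractions Fractional standard errors per stream (defaults:
#'   biomass 10, grain 10, LAI 20 percent).
#' @param drought_window `c(first, last)` 0-based days with rain withheld
#'   at the droughted site (default days 45-125).
#' @param roles Optional named character vector overriding the planted
#'   role (`"essential"`, `"redundant"`, `"noise"`) per replaceable
#'   variable; the default planted assignment is used when `NULL`.
#' @param seed Integer seed for weather and observation noise.
#' @return A `toy_crop_config` list.
#' @export
toy_crop_config <- function(n_sites = 4L, season_length = 150L,
                            sampling_days = seq(20L, 140L, by = 12L),
                            grain_obs_from = 80L,
                            se_fractions = c(biomass = 0.10, grain = 0.10,
                                             lai = 0.20),
                            drought_window = c(45L, 125L),
                            roles = NULL, seed = 1L) {
  stopifnot(n_sites >= 2L, season_length >= 60L,
            all(sampling_days >= 0L), all(sampling_days < season_length),
            grain_obs_from < season_length,
            length(drought_window) == 2L,
            drought_window[1L] < drought_window[2L],
            drought_window[2L] < season_length,
            all(se_fractions > 0))
  structure(list(n_sites = as.integer(n_sites),
                 season_length = as.integer(season_length),
                 sampling_days = as.integer(sampling_days),
                 grain_obs_from = as.integer(grain_obs_from),
                 se_fractions = se_fractions,
                 drought_window = as.integer(drought_window),
                 roles = roles,
                 seed = as.integer(seed)),
            class = "toy_crop_config")
}

# Planted roles and the mechanism that makes each one so.
.toy_roles <- function() {
  data.frame(
    variable = c("tsoil_adj", "s_soiltemp", "tt", "cum_rain", "evap",
                 "sw", "dfac", "rue_mod", "ctemp_adj", "s_ctemp",
                 "lai", "biomass", "trans_pot", "grain",
                 "dtt", "transp"),
    role = c("redundant", "redundant", "essential", "redundant",
             "redundant", "essential", "essential", "noise", "noise",
             "noise", "essential", "essential", "redundant", "essential",
             "essential", "essential"),
    mechanism = c(
      "soil-temperature adjustment engineered near zero over the driver range",
      "switch gating tsoil_adj; off value 0 removes a near-zero term",
      "cumulative thermal time drives phenology; freezing it breaks development",
      "rain accumulator read by no other rule (pure diagnostic)",
      "soil evaporation is small and near-constant relative to the water budget",
      "soil water budget controls the drought response at the droughted site",
      "drought factor scales canopy growth, senescence and assimilation",
      "spurious radiation-use modifier; absent from the data-generating truth",
      "spurious canopy-temperature adjustment on grain fill; absent from truth",
      "switch gating ctemp_adj; either member of the pair neutralises it",
      "leaf area index is an observed stream",
      "above-ground biomass is an observed stream",
      "translocation cap set from anthesis biomass; cap rarely binds",
      "grain mass is an observed stream",
      "daily thermal time (intermediate end-point; excluded from screening)",
      "transpiration (mass-balance term; excluded from screening)"))
}

#' Exclusion list documented for the toy fixture
#'
#' Stands in for the manual mechanistic curation step: `dtt` is an
#' intermediate whose reduction is better expressed through `tt`, and
#' `transp` would break the water balance if severed from the canopy.
#'
#' @return Character vector of variable names.
#' @export
toy_exclusions <- function() c("dtt", "transp")

#' The data-generating ("truth") replacement state of the toy fixture
#'
#' Turns off the fixture's spurious mechanisms: the radiation-use modifier
#' is held at its neutral value 1 and the canopy-temperature switch at its
#' off value 0. Observations are generated from this state, so these
#' mechanisms only degrade fit - the planted noise variables.
#'
#' @return A [replacement_state()].
#' @export
toy_truth_state <- function() {
  replacement_state(c(rue_mod = 1, s_ctemp = 0))
}

#' Build the toy crop model
#'
#' A daily-step crop analogue: thermal-time-driven leaf number with a
#' phyllochron, canopy expansion reduced by a drought factor from a soil
#' water bucket, Beer's-law light interception and radiation-use-efficiency
#' biomass growth, anthesis three phyllochrons after final leaf number,
#' grain filling capped by a translocation potential set from anthesis
#' biomass, a near-zero soil-temperature adjustment behind a switch, and
#' two spurious weather-tracking modifiers (with a switch) absent from the
#' data-generating truth.
#'
#' @param config A [toy_crop_config()].
#' @return List with `spec` (a [model_spec()]), `roles` (data frame
#'   `variable, role, mechanism` covering every replaceable variable),
#'   `exclusions` and `truth_state`.
#' @export
build_toy_crop_model <- function(config = toy_crop_config()) {
  stopifnot(inherits(config, "toy_crop_config"))
  params <- c(tbase = 0, phyllo = 95, flnum = 9, k = 0.6, rue = 1.3,
              swmax = 120, swcrit = 50, evap_c = 0.25, tr_c = 0.28,
              lexp = 0.006, sen_c = 0.003, gfr = 0.7, tp_frac = 0.25)
  vars <- list(
    variable_def("tmean", "(tmin + tmax) / 2",
                 replaceable = FALSE, tags = "diagnostic"),
    variable_def("tsoil_adj",
                 "0.02 * exp(-1.2 * lag(lai)) * (0.5 * (tmax - tmin) - 5)"),
    variable_def("s_soiltemp", "1", is_switch = TRUE, off_value = 0),
    variable_def("dtt",
                 "pmax(0, tmean + s_soiltemp * tsoil_adj - tbase)",
                 tags = "intermediate"),
    variable_def("tt", "tt + dtt", init = 0),
    variable_def("lnum", "pmin(flnum, tt / phyllo)",
                 replaceable = FALSE, tags = "diagnostic"),
    variable_def("anth", "ifelse(tt >= (flnum + 3) * phyllo, 1, 0)",
                 replaceable = FALSE, tags = "diagnostic"),
    variable_def("cum_rain", "cum_rain + rain", init = 0,
                 tags = "accumulator"),
    variable_def("evap",
                 "evap_c * (0.35 + 0.65 * exp(-1.5 * lag(lai)))"),
    variable_def("transp", "tr_c * lag(lai) * pmax(0, radn) / 10",
                 tags = "mass-balance"),
    variable_def("sw",
                 "pmax(0, pmin(swmax, sw + rain - evap - transp))",
                 init = 120),
    variable_def("dfac", "pmin(1, sw / swcrit)"),
    variable_def("rue_mod", "1 + 0.18 * ((tmax - tmin) - 10) / 4"),
    variable_def("ctemp_adj", "0.18 * (radn - 12) / 8"),
    variable_def("s_ctemp", "1", is_switch = TRUE, off_value = 0),
    variable_def("lai",
                 paste("pmax(0, lai + lexp * dtt * dfac *",
                       "ifelse(lnum < flnum, 1, 0) - sen_c * lai * dtt *",
                       "ifelse(anth > 0.5, 1, 0) * (1 + 2.5 * (1 - dfac)))"),
                 init = 0),
    variable_def("fint", "1 - exp(-k * lai)",
                 replaceable = FALSE, tags = "diagnostic"),
    variable_def("biomass",
                 paste("biomass + rue * rue_mod * (0.5 * radn) * fint *",
                       "(0.35 + 0.65 * dfac)"),
                 init = 0),
    variable_def("bio_anth",
                 "ifelse(anth > 0.5, ifelse(bio_anth > 0, bio_anth, biomass), 0)",
                 init = 0, replaceable = FALSE, tags = "diagnostic"),
    variable_def("trans_pot", "tp_frac * bio_anth"),
    variable_def("grain",
                 paste("pmin(pmax(0, grain + ifelse(anth > 0.5,",
                       "gfr * dtt * (1 + s_ctemp * ctemp_adj) * fint, 0)),",
                       "0.6 * biomass + trans_pot)"),
                 init = 0)
  )
  spec <- model_spec(vars, parameters = params,
                     drivers = c("tmin", "tmax", "radn", "rain"),
                     outputs = c("biomass", "grain", "lai"))
  roles <- .toy_roles()
  if (!is.null(config$roles)) {
    idx <- match(roles$variable, names(config$roles))
    roles$role[!is.na(idx)] <- config$roles[idx[!is.na(idx)]]
  }
  repl <- list_replaceable(spec)
  if (!setequal(roles$variable, repl)) {
    stop("role table must cover exactly the replaceable variables",
         call. = FALSE)
  }
  if (!all(c("essential", "redundant", "noise") %in% roles$role)) {
    stop("fixture must plant at least one variable of each role",
         call. = FALSE)
  }
  list(spec = spec, roles = roles, exclusions = toy_exclusions(),
       truth_state = toy_truth_state())
}

#' Generate synthetic weather drivers
#'
#' Daily `tmin`, `tmax`, `radn`, `rain` per site: seasonal trends plus
#' seeded noise. Sites differ systematically in mean diurnal temperature
#' range. Site 1 has rain withheld over the configured drought window;
#' site 2 has generous rainfall, so its soil water never limits growth.
#' Deterministic for a fixed seed.
#'
#' @param config A [toy_crop_config()].
#' @return A [driver_set()] with sites `site1..siteN`.
#' @export
generate_weather <- function(config = toy_crop_config()) {
  stopifnot(inherits(config, "toy_crop_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(config$seed)
  L <- config$season_length
  d <- 0:(L - 1L)
  dr_base <- rep(c(8, 10, 12, 11), length.out = config$n_sites)
  rows <- lapply(seq_len(config$n_sites), function(i) {
    tm <- 10 + 8 * sin(pi * (d + 10) / (L + 20)) + stats::rnorm(L, 0, 1.5)
    dr <- pmax(3, dr_base[i] + stats::rnorm(L, 0, 1))
    radn <- pmax(1, 8 + 10 * sin(pi * (d + 5) / (L + 10)) +
                   stats::rnorm(L, 0, 1.5))
    wet_p <- if (i == 2L) 0.6 else 0.45
    scale <- if (i == 2L) 5 else 4
    rain <- stats::rbinom(L, 1L, wet_p) *
      stats::rgamma(L, shape = 1.2, scale = scale)
    if (i == 1L) {
      w <- config$drought_window
      rain[d >= w[1L] & d <= w[2L]] <- 0
    }
    data.frame(site = paste0("site", i), day = d,
               tmin = tm - dr / 2, tmax = tm + dr / 2,
               radn = radn, rain = rain)
  })
  driver_set(do.call(rbind, rows))
}

#' Generate synthetic observations from the fixture's truth
#'
#' Simulates the data-generating truth (see [toy_truth_state()]) and draws
#' multiplicative Gaussian noise around it: `O = T * (1 + f * eps)` with
#' `eps ~ N(0, 1)` truncated at -3 (avoiding negative-biomass
#' pathologies), floored at 0. Biomass and LAI are recorded on all
#' sampling days, grain only from `grain_obs_from` onward.
#'
#' @param spec The fixture [model_spec()].
#' @param drivers A [driver_set()] from [generate_weather()].
#' @param config A [toy_crop_config()]; `se_fractions` set both the noise
#'   level and the weighting of the resulting observation set.
#' @param truth_state Replacement state defining the data-generating truth.
#' @param noise_fractions Optional per-stream noise fractions if they
#'   should differ from the weighting fractions (e.g. 0 for noise-free
#'   observations).
#' @return An [observation_set()].
#' @export
generate_observations <- function(spec, drivers, config = toy_crop_config(),
                                  truth_state = toy_truth_state(),
                                  noise_fractions = config$se_fractions) {
  stopifnot(inherits(config, "toy_crop_config"))
  truth <- simulate_model(spec, drivers, truth_state)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(config$seed + 1L)
  recs <- list()
  for (st in drivers$sites) {
    for (stream in spec$outputs) {
      days <- config$sampling_days
      if (stream == "grain") days <- days[days >= config$grain_obs_from]
      tvals <- truth$values[[stream]][days + 1L, st]
      eps <- pmax(-3, stats::rnorm(length(days)))
      f <- noise_fractions[[stream]]
      if (is.null(f) || is.na(f)) f <- 0
      recs[[length(recs) + 1L]] <-
        data.frame(stream = stream, site = st, day = days,
                   value = pmax(0, tvals * (1 + f * eps)))
    }
  }
  observation_set(do.call(rbind, recs), se_fractions = config$se_fractions)
}

#' Write the toy fixture to disk
#'
#' Emits the model spec (JSON), drivers CSV, observations CSV and a
#' truth-roles JSON into a directory; the file set matches what the
#' pipeline consumes.
#'
#' @param config A [toy_crop_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named list of file paths.
#' @export
write_toy_fixture <- function(config = toy_crop_config(), dir) {
  fix <- build_toy_crop_model(config)
  drv <- generate_weather(config)
  obs <- generate_observations(fix$spec, drv, config)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(spec = file.path(dir, "model_spec.json"),
                drivers = file.path(dir, "drivers.csv"),
                observations = file.path(dir, "observations.csv"),
                roles = file.path(dir, "truth_roles.json"))
  write_model_spec(fix$spec, paths$spec)
  write_drivers(drv, paths$drivers)
  utils::write.csv(as.data.frame(obs)[, c("stream", "site", "day", "value")],
                   paths$observations, row.names = FALSE)
  jsonlite::write_json(
    list(roles = fix$roles, exclusions = fix$exclusions,
         truth_constants = as.list(fix$truth_state$constants),
         seed = config$seed),
    paths$roles, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
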