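# Shared fixtures, cached per seed so expensive stages (screening) run
# once per session.

.fix_cache <- new.env(parent = emptyenv())

toy_fix <- function(seed = 1L) {
  key <- paste0("fix", seed)
  if (!is.null(.fix_cache[[key]])) return(.fix_cache[[key]])
  cfg <- toy_crop_config(seed = seed)
  built <- build_toy_crop_model(cfg)
  drv <- generate_weather(cfg)
  obs <- generate_observations(built$spec, drv, cfg)
  out <- list(cfg = cfg, spec = built$spec, roles = built$roles,
              exclusions = built$exclusions,
              truth_state = built$truth_state, drv = drv, obs = obs)
  .fix_cache[[key]] <- out
  out
}

toy_screen <- function(seed = 1L) {
  key <- paste0("scr", seed)
  if (!is.null(.fix_cache[[key]])) return(.fix_cache[[key]])
  fx <- toy_fix(seed)
  sc <- screen_all(fx$spec, fx$drv, fx$obs, exclusions = fx$exclusions)
  .fix_cache[[key]] <- sc
  sc
}

role_vars <- function(fx, role) fx$roles$variable[fx$roles$role == role]

# role assignment produced by a full pipeline run: variables never entering
# the candidate set (excluded or screened out) have replacement
# probability 0 by construction
pipeline_probs <- function(fx, sc, search_seed = 100L) {
  cand <- select_candidates(sc)
  res <- mh_search(fx$spec, fx$drv, fx$obs, cand,
                   search_settings(seed = search_seed))
  pt <- replacement_probabilities(res)
  p <- stats::setNames(rep(0, nrow(fx$roles)), fx$roles$variable)
  p[pt$variable] <- pt$p_alpha_0.05
  p
}

# tiny three-variable spec: a reads a driver, b accumulates a, c is a
# replaceable accumulator nothing else reads
mini_spec <- function() {
  model_spec(
    list(variable_def("a", "x * gain", replaceable = TRUE),
         variable_def("b", "b + a", init = 0),
         variable_def("c", "c + x", init = 0)),
    parameters = c(gain = 2),
    drivers = "x",
    outputs = "b")
}

mini_drivers <- function(x = c(0, 5, 2, 1, 3), sites = "s1") {
  driver_set(do.call(rbind, lapply(sites, function(st) {
    data.frame(site = st, day = seq_along(x) - 1L, x = x)
  })))
}
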