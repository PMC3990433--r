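# Pipeline orchestration: configuration, the four-stage reduction run
# (full model -> screening -> candidate selection -> factorial search),
# report files and a command-line entry point.

#' Reduction run configuration
#'
#' Inputs may be given as file paths (`spec`, `drivers`, `observations`)
#' or as in-memory objects. All randomness in a run flows from `seed`
#' via the search settings.
#'
#' @param spec Path to a model-spec JSON, or a [model_spec()].
#' @param drivers Path to a drivers CSV, or a [driver_set()].
#' @param observations Path to an observations CSV, or an
#'   [observation_set()].
#' @param out_dir Directory for report files (`NULL` = no files written).
#' @param se_fractions Stream-keyed fractional standard errors (required
#'   when observations are read from CSV).
#' @param exclusions Variables excluded from screening on mechanistic
#'   grounds.
#' @param screening List: `threshold` (default 1.1), `grid_points`
#'   (default 25).
#' @param search A [search_settings()].
#' @param report List: `bands` (classification bands, default
#'   `c(0.4, 0.6)`), `trace_interval` (default 250).
#' @param verbose Log stage progress via `message()`.
#' @return A `reduction_config` list.
#' @export
reduction_config <- function(spec, drivers, observations, out_dir = NULL,
                             se_fractions = NULL,
                             exclusions = character(),
                             screening = list(),
                             search = search_settings(),
                             report = list(),
                             verbose = TRUE) {
  screening <- utils::modifyList(list(threshold = 1.1, grid_points = 25L),
                                 screening)
  report <- utils::modifyList(list(bands = c(0.4, 0.6),
                                   trace_interval = 250L), report)
  stopifnot(screening$threshold > 0, report$trace_interval >= 1L,
            inherits(search, "search_settings"))
  if (!is.null(se_fractions) &&
      any(se_fractions <= 0 | se_fractions > 1)) {
    stop("se_fractions must lie in (0, 1]", call. = FALSE)
  }
  for (p in c("spec", "drivers", "observations")) {
    v <- get(p)
    if (is.character(v) && !file.exists(v)) {
      stop("config path for '", p, "' does not exist: ", v, call. = FALSE)
    }
  }
  structure(list(spec = spec, drivers = drivers,
                 observations = observations, out_dir = out_dir,
                 se_fractions = se_fractions, exclusions = exclusions,
                 screening = screening, search = search, report = report,
                 verbose = verbose),
            class = "reduction_config")
}

#' Read a reduction configuration from JSON
#'
#' Top-level keys mirror the [reduction_config()] arguments; `paths` holds
#' `spec`, `drivers`, `observations`, `out_dir` (relative paths resolved
#' against the config file's directory).
#'
#' @param path Config JSON file.
#' @param overrides Named list applied over the file's values.
#' @return A `reduction_config`.
#' @export
read_reduction_config <- function(path, overrides = list()) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  doc <- utils::modifyList(doc, overrides)
  base <- dirname(normalizePath(path))
  rel <- function(p) {
    if (is.null(p)) return(NULL)
    if (!grepl("^(/|[A-Za-z]:)", p)) file.path(base, p) else p
  }
  srch <- do.call(search_settings, as.list(doc$search %||% list()))
  reduction_config(
    spec = rel(doc$paths$spec),
    drivers = rel(doc$paths$drivers),
    observations = rel(doc$paths$observations),
    out_dir = rel(doc$paths$out_dir),
    se_fractions = unlist(doc$se_fractions),
    exclusions = as.character(doc$exclusions %||% character()),
    screening = as.list(doc$screening %||% list()),
    search = srch,
    report = as.list(doc$report %||% list()),
    verbose = doc$verbose %||% TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.load_inputs <- function(config) {
  spec <- if (is.character(config$spec)) read_model_spec(config$spec)
          else config$spec
  drivers <- if (is.character(config$drivers)) read_drivers(config$drivers)
             else config$drivers
  obs <- if (is.character(config$observations)) {
    read_observations(config$observations, config$se_fractions)
  } else config$observations
  stopifnot(inherits(spec, "model_spec"), inherits(drivers, "driver_set"),
            inherits(obs, "observation_set"))
  list(spec = spec, drivers = drivers, obs = obs)
}

#' Run the full reduction pipeline
#'
#' Stages: simulate the full model; screen every candidate one at a time;
#' select candidates below the RSS-ratio threshold; search the replacement
#' space; derive replacement-probability, joint-probability and
#' convergence-trace tables. When `out_dir` is set, CSV reports and a JSON
#' run manifest (seed, settings, RSS of the full model, alpha values,
#' stage counts) are written; a rerun with the same seed reproduces them
#' byte for byte.
#'
#' @param config A [reduction_config()].
#' @return Invisibly, a bundle: `skill`, `screening`, `candidates`,
#'   `search`, `probabilities`, `joint`, `trace`, `manifest`, `files`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "reduction_config"))
  say <- function(...) if (isTRUE(config$verbose)) message("modred: ", ...)
  inp <- .load_inputs(config)
  out_dir <- config$out_dir
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  }
  files <- list()
  emit <- function(df, name) {
    if (is.null(out_dir)) return(invisible(NULL))
    p <- file.path(out_dir, name)
    utils::write.csv(as.data.frame(df), p, row.names = FALSE)
    files[[name]] <<- p
    invisible(p)
  }

  say("stage 1: full model simulation")
  traj_full <- simulate_model(inp$spec, inp$drivers)
  rss_full <- weighted_rss(inp$obs, traj_full)
  skill <- skill_summary(inp$obs, traj_full)
  emit(skill, "skill.csv")
  say("  rss_full = ", signif(rss_full, 6), " over ", nrow(inp$obs),
      " observations")

  say("stage 2: screening ", length(list_replaceable(inp$spec,
                                                     config$exclusions)),
      " candidate variables")
  screening <- screen_all(inp$spec, inp$drivers, inp$obs,
                          exclusions = config$exclusions,
                          threshold = config$screening$threshold,
                          grid_points = config$screening$grid_points)
  emit(screening, "screening.csv")

  candidates <- select_candidates(screening, config$screening$threshold)
  say("stage 3: ", length(candidates$names),
      " candidates enter the factorial stage")

  manifest <- list(
    package_version = as.character(utils::packageVersion("modred")),
    seed = config$search$seed,
    settings = unclass(config$search),
    exclusions = config$exclusions,
    screening = config$screening,
    rss_full = rss_full,
    alpha_values = config$search$alpha_fractions * rss_full,
    n_observations = nrow(inp$obs),
    n_screened = nrow(screening),
    n_candidates = length(candidates$names))

  if (!length(candidates$names)) {
    manifest$status <- "stopped: empty candidate set after screening"
    say(manifest$status)
    if (!is.null(out_dir)) {
      p <- file.path(out_dir, "manifest.json")
      jsonlite::write_json(manifest, p, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
      files[["manifest.json"]] <- p
    }
    return(invisible(list(skill = skill, screening = screening,
                          candidates = candidates, search = NULL,
                          probabilities = NULL, joint = NULL, trace = NULL,
                          manifest = manifest, files = files)))
  }

  say("stage 4: Metropolis-Hastings search (budget ",
      config$search$n_unique, " unique models)")
  result <- mh_search(inp$spec, inp$drivers, inp$obs, candidates,
                      settings = config$search)
  say("  cached ", nrow(result$bits), " unique models in ",
      result$n_iter, " iterations (", result$terminated, ")")

  probs <- replacement_probabilities(result, bands = config$report$bands)
  emit(probs, "probability.csv")
  joint <- if (length(candidates$names) >= 2L) {
    joint_probabilities(result)
  } else NULL
  if (!is.null(joint)) emit(joint, "joint.csv")
  trace <- convergence_trace(result,
                             min(config$report$trace_interval,
                                 nrow(result$bits)))
  emit(trace, "trace.csv")

  last <- trace[trace$unique_count >= 0.9 * nrow(result$bits), ]
  stab <- if (nrow(last)) {
    max(vapply(split(last$probability, last$variable),
               function(p) diff(range(p)), numeric(1)))
  } else NA_real_
  manifest$status <- "complete"
  manifest$n_unique_evaluated <- nrow(result$bits)
  manifest$n_iterations <- result$n_iter
  manifest$terminated <- result$terminated
  manifest$stability_max_change_last_10pct <- stab
  if (!is.null(out_dir)) {
    p <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    files[["manifest.json"]] <- p
  }
  say("done; max probability change over last 10% of cache: ",
      signif(stab, 3))
  invisible(list(skill = skill, screening = screening,
                 candidates = candidates, search = result,
                 probabilities = probs, joint = joint, trace = trace,
                 manifest = manifest, files = files))
}

#' Evaluate a chosen replacement set
#'
#' Applies a replacement state (for example, all variables judged
#' redundant) and reports per-stream and pooled skill of the resulting
#' reduced model - the generic "minimum model" comparison.
#'
#' @param spec A [model_spec()].
#' @param state A [replacement_state()]; the empty state scores the full
#'   model.
#' @param drivers A [driver_set()].
#' @param obs An [observation_set()].
#' @return A [skill_summary()] data frame.
#' @export
apply_replacement_set <- function(spec, state, drivers, obs) {
  skill_summary(obs, simulate_model(spec, drivers, state))
}

# ---- command line ---------------------------------------------------------

.cli_opts <- function(argv) {
  opts <- list(); pos <- character()
  i <- 1L
  while (i <= length(argv)) {
    a <- argv[i]
    if (grepl("^--", a)) {
      key <- sub("^--", "", a)
      if (grepl("=", key)) {
        kv <- strsplit(key, "=", fixed = TRUE)[[1L]]
        opts[[kv[1L]]] <- paste(kv[-1L], collapse = "=")
      } else {
        opts[[key]] <- argv[i + 1L]
        i <- i + 1L
      }
    } else pos <- c(pos, a)
    i <- i + 1L
  }
  list(opts = opts, pos = pos)
}

#' Command-line entry point
#'
#' Subcommands: `synth` (write the toy fixture), `run` (full pipeline),
#' `screen`, `search`, `oracle` (exhaustive enumeration), `evaluate`
#' (score a replacement set). All but `synth` take `--config <json>`;
#' `--seed` and `--out-dir` override config values.
#'
#' @param argv Character vector of arguments (default: the command line).
#' @return Integer exit status, invisibly.
#' @export
modred_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (!length(argv)) {
    message("usage: modred <synth|run|screen|search|oracle|evaluate> ",
            "[--config f] [--seed n] [--out-dir d] [--state f]")
    return(invisible(1L))
  }
  cmd <- argv[1L]
  parsed <- .cli_opts(argv[-1L])
  opts <- parsed$opts
  seed <- if (!is.null(opts$seed)) as.integer(opts$seed) else NULL

  if (cmd == "synth") {
    cfg <- toy_crop_config(seed = seed %||% 1L)
    paths <- write_toy_fixture(cfg, opts$`out-dir` %||% ".")
    message("wrote: ", paste(unlist(paths), collapse = ", "))
    return(invisible(0L))
  }
  if (is.null(opts$config)) {
    message("--config is required for '", cmd, "'")
    return(invisible(1L))
  }
  over <- list()
  if (!is.null(opts$`out-dir`)) over$paths$out_dir <- opts$`out-dir`
  config <- read_reduction_config(opts$config, over)
  if (!is.null(seed)) config$search$seed <- seed

  if (cmd == "run") {
    run_pipeline(config)
    return(invisible(0L))
  }
  inp <- .load_inputs(config)
  if (cmd == "screen") {
    rows <- screen_all(inp$spec, inp$drivers, inp$obs,
                       exclusions = config$exclusions,
                       threshold = config$screening$threshold,
                       grid_points = config$screening$grid_points)
    out <- file.path(config$out_dir %||% ".", "screening.csv")
    dir.create(dirname(out), showWarnings = FALSE, recursive = TRUE)
    write_screening(rows, out)
    message("wrote ", out)
    return(invisible(0L))
  }
  if (cmd %in% c("search", "oracle")) {
    rows <- screen_all(inp$spec, inp$drivers, inp$obs,
                       exclusions = config$exclusions,
                       threshold = config$screening$threshold,
                       grid_points = config$screening$grid_points)
    cand <- select_candidates(rows, config$screening$threshold)
    res <- if (cmd == "search") {
      mh_search(inp$spec, inp$drivers, inp$obs, cand, config$search)
    } else {
      exhaustive_enumeration(inp$spec, inp$drivers, inp$obs, cand,
                             config$search)
    }
    probs <- replacement_probabilities(res, bands = config$report$bands)
    out <- file.path(config$out_dir %||% ".", "probability.csv")
    dir.create(dirname(out), showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(as.data.frame(probs), out, row.names = FALSE)
    message("wrote ", out)
    return(invisible(0L))
  }
  if (cmd == "evaluate") {
    state <- if (!is.null(opts$state)) {
      replacement_state(unlist(jsonlite::fromJSON(opts$state)))
    } else replacement_state()
    sk <- apply_replacement_set(inp$spec, state, inp$drivers, inp$obs)
    print(as.data.frame(sk))
    return(invisible(0L))
  }
  message("unknown subcommand '", cmd, "'")
  invisible(1L)
}
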