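# One-at-a-time screening: replace each candidate variable with a constant
# fitted by RSS minimisation, bounded by the range the variable takes in
# the full-model run.

# RSS of the model with a single extra replacement; Inf when the simulation
# leaves its valid regime (non-finite state).
.rss_for_state <- function(spec, drivers, obs, state) {
  traj <- tryCatch(simulate_model(spec, drivers, state),
                   modred_sim_error = function(e) NULL)
  if (is.null(traj)) return(Inf)
  weighted_rss(obs, traj)
}

#' Fit the replacement constant for one variable
#'
#' Minimises the weighted RSS of the model with only `name` replaced,
#' constrained to the range the variable takes in the run of the full
#' (unreduced) model. The objective can be non-smooth (the constant threads
#' through conditionals), so a coarse grid is scanned first and the best
#' grid cell refined with bounded scalar optimisation; ties break toward
#' the smallest constant. Switch variables are not optimised: their
#' constant is the documented off value.
#'
#' @param spec A [model_spec()].
#' @param drivers A [driver_set()].
#' @param obs An [observation_set()].
#' @param name Replaceable variable to fit.
#' @param full Optional list with elements `traj` (full-model trajectory)
#'   and `rss` (full-model RSS), to avoid recomputation.
#' @param grid_points Number of coarse grid points (default 25).
#' @return List with `constant`, `rss_reduced`, `bounds`.
#' @export
fit_replacement_constant <- function(spec, drivers, obs, name, full = NULL,
                                     grid_points = 25L) {
  stopifnot(inherits(spec, "model_spec"))
  if (!(name %in% names(spec$variables)) ||
      !spec$variables[[name]]$replaceable) {
    stop("'", name, "' is not a replaceable variable", call. = FALSE)
  }
  if (is.null(full)) {
    traj_full <- simulate_model(spec, drivers)
    full <- list(traj = traj_full, rss = weighted_rss(obs, traj_full))
  }
  bounds <- variable_range(full$traj, name)
  vdef <- spec$variables[[name]]
  obj <- function(c0) {
    .rss_for_state(spec, drivers, obs,
                   replacement_state(stats::setNames(c0, name)))
  }
  if (vdef$is_switch) {
    c0 <- vdef$off_value
    return(list(constant = c0, rss_reduced = obj(c0), bounds = bounds))
  }
  if (bounds[1L] == bounds[2L]) {
    return(list(constant = bounds[1L], rss_reduced = obj(bounds[1L]),
                bounds = bounds))
  }
  grid <- seq(bounds[1L], bounds[2L], length.out = max(3L, grid_points))
  grss <- vapply(grid, obj, numeric(1))
  best <- which.min(grss)  # which.min takes the first (smallest) on ties
  lo <- grid[max(1L, best - 1L)]
  hi <- grid[min(length(grid), best + 1L)]
  cand_c <- grid[best]
  cand_r <- grss[best]
  if (is.finite(cand_r) && hi > lo) {
    opt <- stats::optimize(obj, interval = c(lo, hi),
                           tol = max(1e-8, (hi - lo) * 1e-6))
    # keep the refined point only if it genuinely improves; ties go to the
    # smaller constant
    if (opt$objective < cand_r - 1e-12 * max(1, cand_r) ||
        (abs(opt$objective - cand_r) <= 1e-12 * max(1, cand_r) &&
         opt$minimum < cand_c)) {
      cand_c <- opt$minimum
      cand_r <- opt$objective
    }
  }
  cand_c <- min(max(cand_c, bounds[1L]), bounds[2L])
  list(constant = cand_c, rss_reduced = cand_r, bounds = bounds)
}

#' Screen all candidate variables one at a time
#'
#' Simulates the full model once (for its RSS and per-variable ranges),
#' then replaces each replaceable, non-excluded variable individually with
#' its fitted constant. A failed simulation during fitting is recorded as
#' an infinite RSS ratio rather than an error.
#'
#' @inheritParams fit_replacement_constant
#' @param exclusions Variables removed from consideration on mechanistic
#'   grounds (user-supplied; see [list_replaceable()]).
#' @param threshold Inclusion threshold on the RSS ratio (default 1.1).
#' @param grid_points Coarse grid size passed to
#'   [fit_replacement_constant()].
#' @return A `screening_table` data frame with columns
#'   `variable, constant, lower, upper, rss_reduced, rss_ratio, included,
#'   note`; attributes `rss_full` and `threshold`.
#' @export
screen_all <- function(spec, drivers, obs, exclusions = character(),
                       threshold = 1.1, grid_points = 25L) {
  stopifnot(threshold > 0)
  candidates <- list_replaceable(spec, exclusions)
  traj_full <- simulate_model(spec, drivers)
  rss_full <- weighted_rss(obs, traj_full)
  full <- list(traj = traj_full, rss = rss_full)
  rows <- lapply(candidates, function(v) {
    fit <- fit_replacement_constant(spec, drivers, obs, v, full = full,
                                    grid_points = grid_points)
    note <- if (spec$variables[[v]]$is_switch) "switch (off value, not fitted)"
            else if (fit$bounds[1L] == fit$bounds[2L]) "degenerate range"
            else if (!is.finite(fit$rss_reduced)) "simulation failed"
            else ""
    data.frame(variable = v, constant = fit$constant,
               lower = fit$bounds[1L], upper = fit$bounds[2L],
               rss_reduced = fit$rss_reduced,
               rss_ratio = fit$rss_reduced / rss_full,
               included = is.finite(fit$rss_reduced) &&
                 fit$rss_reduced / rss_full <= threshold,
               note = note)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(variable = character(), constant = numeric(),
               lower = numeric(), upper = numeric(),
               rss_reduced = numeric(), rss_ratio = numeric(),
               included = logical(), note = character())
  attr(out, "rss_full") <- rss_full
  attr(out, "threshold") <- threshold
  class(out) <- c("screening_table", "data.frame")
  out
}

#' Select candidates for the multi-factorial stage
#'
#' Keeps variables whose one-at-a-time RSS ratio does not exceed the
#' threshold; their fitted constants are carried through the rest of the
#' analysis unchanged.
#'
#' @param rows A `screening_table` from [screen_all()] (or a data frame
#'   with columns `variable, constant, rss_ratio`).
#' @param threshold Positive RSS-ratio cut-off (default 1.1).
#' @return A `candidate_set`: list with `names` (ordered) and `constants`
#'   (named numeric).
#' @export
select_candidates <- function(rows, threshold = 1.1) {
  stopifnot(is.data.frame(rows), threshold > 0)
  if (!nrow(rows)) {
    return(structure(list(names = character(), constants = numeric()),
                     class = "candidate_set"))
  }
  keep <- is.finite(rows$rss_ratio) & rows$rss_ratio <= threshold
  structure(list(names = rows$variable[keep],
                 constants = stats::setNames(rows$constant[keep],
                                             rows$variable[keep])),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat("<candidate_set> N =", length(x$names), "\n")
  if (length(x$names)) print(x$constants)
  invisible(x)
}

#' Write a screening report CSV
#'
#' @param rows A `screening_table`.
#' @param path Output file.
#' @export
write_screening <- function(rows, path) {
  utils::write.csv(as.data.frame(rows), path, row.names = FALSE)
  invisible(path)
}
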