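# Skill metrics: weighted residual sums of squares, Nash-Sutcliffe
# efficiency, and the informal pseudo-likelihood used to weight reduced
# models.

#' Observation set with fractional standard errors
#'
#' Each record's standard error is `se_fractions[stream] * value`, floored
#' at `se_fractions[stream] * floor_frac * mean(value within stream)` so
#' that zero observations (e.g. pre-emergence LAI) keep a positive weight.
#' If `df` carries an explicit `se` column it is used as-is instead.
#'
#' @param df Data frame with columns `stream, site, day, value` (day is a
#'   0-based integer from sowing) and optionally `se`.
#' @param se_fractions Named numeric vector, stream -> fractional SE, e.g.
#'   `c(biomass = 0.10, grain = 0.10, lai = 0.20)`.
#' @param floor_frac Fraction of the stream's mean observed value used to
#'   floor the SE (default 0.01).
#' @return An `observation_set` object (a data frame with an `s` column).
#' @export
observation_set <- function(df, se_fractions = NULL, floor_frac = 0.01) {
  stopifnot(is.data.frame(df),
            all(c("stream", "site", "day", "value") %in% names(df)))
  df <- df[, intersect(c("stream", "site", "day", "value", "se"), names(df))]
  df$stream <- as.character(df$stream)
  df$site <- as.character(df$site)
  df$day <- as.integer(df$day)
  df$value <- as.numeric(df$value)
  if ("se" %in% names(df)) {
    df$s <- as.numeric(df$se)
    df$se <- NULL
  } else {
    if (is.null(se_fractions)) {
      stop("se_fractions required when no explicit 'se' column is given",
           call. = FALSE)
    }
    missing_fr <- setdiff(unique(df$stream), names(se_fractions))
    if (length(missing_fr)) {
      stop("no SE fraction for stream(s): ",
           paste(missing_fr, collapse = ", "), call. = FALSE)
    }
    if (any(se_fractions <= 0)) {
      stop("SE fractions must be positive", call. = FALSE)
    }
    floor_by_stream <- tapply(df$value, df$stream, mean) * floor_frac
    fr <- se_fractions[df$stream]
    df$s <- fr * pmax(df$value, floor_by_stream[df$stream])
  }
  if (any(!is.finite(df$s) | df$s <= 0)) {
    stop("every observation needs a positive standard error", call. = FALSE)
  }
  structure(df, class = c("observation_set", "data.frame"),
            se_fractions = se_fractions)
}

#' Read observations from CSV
#'
#' @param path CSV with columns `stream, site, day, value`.
#' @inheritParams observation_set
#' @return An [observation_set()].
#' @export
read_observations <- function(path, se_fractions, floor_frac = 0.01) {
  observation_set(utils::read.csv(path, stringsAsFactors = FALSE),
                  se_fractions, floor_frac)
}

# Resolve each observation to a model prediction. Accepts either a
# trajectory_set (streams must be simulated variables) or a long data frame
# of predictions with columns stream, site, day, pred.
.match_predictions <- function(obs, traj = NULL, predictions = NULL) {
  if (!is.null(predictions)) {
    key <- paste(obs$stream, obs$site, obs$day, sep = "\r")
    pkey <- paste(predictions$stream, predictions$site, predictions$day,
                  sep = "\r")
    m <- predictions$pred[match(key, pkey)]
  } else {
    stopifnot(inherits(traj, "trajectory_set"))
    m <- rep(NA_real_, nrow(obs))
    for (i in seq_len(nrow(obs))) {
      v <- traj$values[[obs$stream[i]]]
      d <- obs$day[i] + 1L
      if (!is.null(v) && obs$site[i] %in% colnames(v) &&
          d >= 1L && d <= nrow(v)) {
        m[i] <- v[d, obs$site[i]]
      }
    }
  }
  if (anyNA(m)) {
    bad <- which(is.na(m))[1L]
    stop("observation not matched by a prediction: stream=",
         obs$stream[bad], " site=", obs$site[bad], " day=", obs$day[bad],
         call. = FALSE)
  }
  m
}

#' Weighted residual sum of squares
#'
#' `RSS = sum(((O_j - M_j) / s_j)^2)` over all observations, with `s_j` the
#' per-record standard error. Dimensionless; zero iff the fit is perfect.
#'
#' @param obs An [observation_set()].
#' @param traj A `trajectory_set` whose output streams cover the
#'   observations, or `NULL` if `predictions` is given.
#' @param predictions Optional long data frame `stream, site, day, pred`.
#' @return Scalar RSS.
#' @export
weighted_rss <- function(obs, traj = NULL, predictions = NULL) {
  stopifnot(inherits(obs, "observation_set"))
  m <- .match_predictions(obs, traj, predictions)
  sum(((obs$value - m) / obs$s)^2)
}

#' Nash-Sutcliffe model efficiency
#'
#' `NS = 1 - sum(((O - M)/s)^2) / sum(((O - Obar)/s)^2)`, with the same
#' per-record weights in numerator and denominator and `Obar` the unweighted
#' mean of the observations in scope. For the pooled value (`stream = NULL`)
#' each deviation is taken from its own stream's mean, keeping streams
#' commensurate without cross-stream variance pollution. NS is at most 1
#' and, unlike r-squared, can be negative.
#'
#' @inheritParams weighted_rss
#' @param stream Restrict to one observed stream; `NULL` pools all streams.
#' @return Scalar NS.
#' @export
nash_sutcliffe <- function(obs, traj = NULL, predictions = NULL,
                           stream = NULL) {
  stopifnot(inherits(obs, "observation_set"))
  m <- .match_predictions(obs, traj, predictions)
  keep <- if (is.null(stream)) rep(TRUE, nrow(obs)) else obs$stream == stream
  if (sum(keep) < 2L) {
    stop("need at least 2 observations in scope", call. = FALSE)
  }
  o <- obs$value[keep]; s <- obs$s[keep]; mm <- m[keep]
  obar <- stats::ave(o, obs$stream[keep])
  denom <- sum(((o - obar) / s)^2)
  if (denom == 0) {
    stop("degenerate data: all observations identical in scope",
         call. = FALSE)
  }
  1 - sum(((o - mm) / s)^2) / denom
}

#' Per-stream and pooled skill summary
#'
#' @inheritParams weighted_rss
#' @return A data frame (class `skill_summary`) with one row per stream
#'   plus a `pooled` row, columns `stream, n, rss, ns`.
#' @export
skill_summary <- function(obs, traj = NULL, predictions = NULL) {
  stopifnot(inherits(obs, "observation_set"))
  m <- .match_predictions(obs, traj, predictions)
  streams <- unique(obs$stream)
  rows <- lapply(c(streams, "pooled"), function(st) {
    keep <- if (st == "pooled") rep(TRUE, nrow(obs)) else obs$stream == st
    o <- obs$value[keep]; s <- obs$s[keep]; mm <- m[keep]
    obar <- stats::ave(o, obs$stream[keep])
    rss <- sum(((o - mm) / s)^2)
    denom <- sum(((o - obar) / s)^2)
    data.frame(stream = st, n = sum(keep), rss = rss,
               ns = if (denom > 0) 1 - rss / denom else NA_real_)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("skill_summary", "data.frame")
  out
}

#' Informal pseudo-likelihood of a reduced model
#'
#' Unnormalized belief weight
#' `q = exp(-ln(0.5) * (rss_full - rss_i) / alpha)`
#' relating a reduced model's weighted RSS to the full model's: `q = 1` when
#' `rss_i = rss_full`, and drops by half for every `alpha` of RSS above the
#' full model. The normalisation constant is applied separately by
#' [normalize_q()]; it cancels in Metropolis-Hastings acceptance ratios.
#'
#' @param rss_i RSS of the reduced model(s); vectorised.
#' @param rss_full RSS of the full model.
#' @param alpha Absolute tolerance (> 0), typically a stated fraction of
#'   `rss_full` (2.5, 5 or 10 percent).
#' @return Numeric vector of unnormalized pseudo-likelihoods.
#' @export
pseudo_likelihood <- function(rss_i, rss_full, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0) {
    stop("alpha must be a single positive number", call. = FALSE)
  }
  stopifnot(is.numeric(rss_i), is.numeric(rss_full))
  exp(log(2) * (rss_full - rss_i) / alpha)
}

# log pseudo-likelihood; -Inf for failed (infinite-RSS) models.
.log_q <- function(rss_i, rss_full, alpha) {
  log(2) * (rss_full - rss_i) / alpha
}

# normalized weights from log-q values, stable under large spreads
.norm_log_q <- function(lq) {
  m <- max(lq)
  if (!is.finite(m)) stop("all models have zero pseudo-likelihood",
                          call. = FALSE)
  w <- exp(lq - m)
  w / sum(w)
}

#' Normalize pseudo-likelihoods to probabilities
#'
#' @param values Positive unnormalized pseudo-likelihoods.
#' @return Values scaled to sum to 1; order and ratios preserved.
#' @export
normalize_q <- function(values) {
  if (!length(values)) stop("empty pseudo-likelihood set", call. = FALSE)
  if (any(!is.finite(values) | values <= 0)) {
    stop("pseudo-likelihoods must be positive and finite", call. = FALSE)
  }
  values / sum(values)
}
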