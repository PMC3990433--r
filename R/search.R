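# Multi-factorial stage: Metropolis-Hastings walk over the space of
# replacement combinations, an exhaustive-enumeration oracle for small
# candidate sets, and the probability tables derived from the unique-model
# cache.

#' Settings for the replacement-space search
#'
#' @param n_unique Unique-model evaluation budget (default 10000). When the
#'   candidate space has fewer than `n_unique` states the budget is capped
#'   at `2^N`.
#' @param flips Number of candidate states toggled per proposal (default 1;
#'   one flip per iteration gave the most efficient search in the original
#'   study). The proposal is symmetric, so no Hastings correction is
#'   needed.
#' @param alpha_fractions Tolerances as fractions of the full model's RSS
#'   (default 2.5, 5 and 10 percent).
#' @param seed Integer seed; all search randomness flows from it.
#' @param driving_alpha_index Which alpha drives chain acceptance (default
#'   2, the middle value); probabilities for all alphas are recomputed over
#'   the same cache afterwards.
#' @param max_iter Iteration guard: the walk stops after this many
#'   proposals even if the unique budget is not reached (steep
#'   pseudo-likelihood surfaces can make the deepest low-Q corners of a
#'   small space effectively unreachable; their weight is negligible).
#' @return A `search_settings` list.
#' @export
search_settings <- function(n_unique = 10000L, flips = 1L,
                            alpha_fractions = c(0.025, 0.05, 0.10),
                            seed = 1L, driving_alpha_index = 2L,
                            max_iter = 200000L) {
  stopifnot(n_unique >= 1L, flips >= 1L, length(alpha_fractions) >= 1L,
            all(alpha_fractions > 0),
            driving_alpha_index >= 1L,
            driving_alpha_index <= length(alpha_fractions),
            max_iter >= 1L)
  structure(list(n_unique = as.integer(n_unique), flips = as.integer(flips),
                 alpha_fractions = as.numeric(alpha_fractions),
                 seed = as.integer(seed),
                 driving_alpha_index = as.integer(driving_alpha_index),
                 max_iter = as.integer(max_iter)),
            class = "search_settings")
}

.bits_key <- function(bits) paste(bits, collapse = "")

.state_from_bits <- function(bits, candidates) {
  on <- bits == 1L
  replacement_state(candidates$constants[candidates$names[on]])
}

# Metropolis acceptance rule, Eq.-3 style: accept iff q_trial/q_current > r
# with r ~ U(0,1); computed in log space. Exposed internally for the
# isolated Monte-Carlo check of the rule.
.accept_step <- function(lq_trial, lq_current, r) {
  lq_trial - lq_current > log(r)
}

.new_result <- function(bits, rss, candidates, rss_full, settings,
                        chain, n_iter, terminated) {
  keys <- apply(bits, 1L, .bits_key)
  structure(list(
    models = data.frame(key = keys, rss = rss),
    bits = bits,
    candidates = candidates,
    rss_full = rss_full,
    alpha_fractions = settings$alpha_fractions,
    driving_alpha_index = settings$driving_alpha_index,
    seed = settings$seed,
    settings = settings,
    chain = chain,
    n_iter = n_iter,
    terminated = terminated),
    class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  cat("<search_result> ", nrow(x$bits), " unique models over N = ",
      ncol(x$bits), " candidates (", x$terminated, "); rss_full = ",
      signif(x$rss_full, 6), "\n", sep = "")
  invisible(x)
}

#' Metropolis-Hastings walk over the replacement space
#'
#' Each candidate variable is either normal or replaced (at its screening
#' constant). Starting from the all-normal state, every iteration toggles
#' `flips` states uniformly at random and accepts the move iff
#' `q_trial / q_current > r`, `r ~ U(0,1)`, with q the unnormalized
#' pseudo-likelihood under the driving alpha. Every proposed state is
#' evaluated once and cached (a failed simulation is cached with zero
#' pseudo-likelihood and can never be accepted); revisits reuse the cache.
#' The walk stops once the unique-model cache reaches
#' `min(n_unique, 2^N)` states, or at `max_iter` proposals.
#'
#' @param spec A [model_spec()].
#' @param drivers A [driver_set()].
#' @param obs An [observation_set()].
#' @param candidates A `candidate_set` from [select_candidates()].
#' @param settings A [search_settings()].
#' @return A `search_result`: the unique-model cache (bitmask keys and RSS
#'   values), chain of accepted states, and run metadata.
#' @export
mh_search <- function(spec, drivers, obs, candidates,
                      settings = search_settings()) {
  stopifnot(inherits(candidates, "candidate_set"),
            inherits(settings, "search_settings"))
  N <- length(candidates$names)
  if (N < 1L) stop("candidate set is empty", call. = FALSE)
  n_states <- 2^N
  target <- as.integer(min(settings$n_unique, n_states))

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(settings$seed)

  traj_full <- simulate_model(spec, drivers)
  rss_full <- weighted_rss(obs, traj_full)
  alpha <- settings$alpha_fractions[settings$driving_alpha_index] * rss_full

  cap <- max(target, 16L)
  bits_mat <- matrix(NA_integer_, cap, N)
  rss_vec <- rep(NA_real_, cap)
  key_idx <- new.env(hash = TRUE, parent = emptyenv())

  cur <- integer(N)
  bits_mat[1L, ] <- cur
  rss_vec[1L] <- rss_full
  assign(.bits_key(cur), 1L, envir = key_idx)
  n_uni <- 1L
  lq_cur <- 0
  chain <- integer(settings$max_iter + 1L)
  chain[1L] <- 1L
  n_acc <- 1L
  iter <- 0L

  while (n_uni < target && iter < settings$max_iter) {
    iter <- iter + 1L
    flip <- sample.int(N, settings$flips)
    trial <- cur
    trial[flip] <- 1L - trial[flip]
    key <- .bits_key(trial)
    idx <- key_idx[[key]]
    if (is.null(idx)) {
      rss_t <- .rss_for_state(spec, drivers, obs,
                              .state_from_bits(trial, candidates))
      n_uni <- n_uni + 1L
      bits_mat[n_uni, ] <- trial
      rss_vec[n_uni] <- rss_t
      assign(key, n_uni, envir = key_idx)
      idx <- n_uni
    } else {
      rss_t <- rss_vec[idx]
    }
    lq_t <- .log_q(rss_t, rss_full, alpha)
    if (.accept_step(lq_t, lq_cur, stats::runif(1))) {
      cur <- trial
      lq_cur <- lq_t
      n_acc <- n_acc + 1L
      chain[n_acc] <- idx
    }
  }
  terminated <- if (n_uni >= target) {
    if (target == n_states) "exhausted" else "target"
  } else "max_iter"
  if (terminated == "max_iter") {
    message("mh_search: stopped at max_iter with ", n_uni, "/", target,
            " unique models cached")
  }
  .new_result(bits_mat[seq_len(n_uni), , drop = FALSE],
              rss_vec[seq_len(n_uni)], candidates, rss_full, settings,
              chain[seq_len(n_acc)], iter, terminated)
}

#' Exhaustive enumeration of the replacement space
#'
#' Evaluates all `2^N` replacement combinations (including the all-normal
#' state). Exact probability tables from this result serve as the oracle
#' against which the stochastic search is checked on small candidate sets.
#'
#' @inheritParams mh_search
#' @param cap Refuse to enumerate more than `2^cap` states (default 15).
#' @return A `search_result` covering the whole space.
#' @export
exhaustive_enumeration <- function(spec, drivers, obs, candidates,
                                   settings = search_settings(),
                                   cap = 15L) {
  stopifnot(inherits(candidates, "candidate_set"))
  N <- length(candidates$names)
  if (N < 1L) stop("candidate set is empty", call. = FALSE)
  if (N > cap) {
    stop("refusing exhaustive enumeration for N = ", N, " > cap = ", cap,
         " (2^N states)", call. = FALSE)
  }
  traj_full <- simulate_model(spec, drivers)
  rss_full <- weighted_rss(obs, traj_full)
  n_states <- 2L^N
  bits_mat <- matrix(0L, n_states, N)
  for (j in seq_len(N)) {
    bits_mat[, j] <- bitwAnd(seq_len(n_states) - 1L, bitwShiftL(1L, j - 1L)) > 0L
  }
  storage.mode(bits_mat) <- "integer"
  rss_vec <- numeric(n_states)
  rss_vec[1L] <- rss_full
  for (i in 2:n_states) {
    rss_vec[i] <- .rss_for_state(spec, drivers, obs,
                                 .state_from_bits(bits_mat[i, ], candidates))
  }
  .new_result(bits_mat, rss_vec, candidates, rss_full, settings,
              chain = integer(0), n_iter = n_states - 1L,
              terminated = "exhaustive")
}

# normalized weights over (a prefix of) the cache for one alpha fraction
.cache_weights <- function(result, alpha_fraction, n = nrow(result$bits)) {
  alpha <- alpha_fraction * result$rss_full
  lq <- .log_q(result$models$rss[seq_len(n)], result$rss_full, alpha)
  .norm_log_q(lq)
}

#' Classify a replacement probability
#'
#' Verbal anchors: a probability tending to 1 means performance improved
#' when the variable was replaced (noise); 0.5 means performance was
#' unaffected (redundant); tending to 0 means the variable contributes.
#' Band edges are a reporting choice and configurable.
#'
#' @param p Probability vector.
#' @param bands Length-2 numeric `c(contributing_max, noise_min)`
#'   (default `c(0.4, 0.6)`).
#' @return Character vector: `"contributing"`, `"redundant"` or `"noise"`.
#' @export
classify_probability <- function(p, bands = c(0.4, 0.6)) {
  stopifnot(length(bands) == 2L, bands[1L] <= bands[2L])
  ifelse(p >= bands[2L], "noise",
         ifelse(p <= bands[1L], "contributing", "redundant"))
}

#' Replacement probabilities per candidate and alpha
#'
#' For each alpha the pseudo-likelihoods are normalized to one over all
#' unique models in the cache, and a variable's replacement probability is
#' the sum of normalized pseudo-likelihoods over the models in which it is
#' replaced. All alphas re-weight the same cache.
#'
#' @param result A `search_result`.
#' @param alpha_fractions Alphas (fractions of the full-model RSS);
#'   defaults to those recorded in the result.
#' @param bands Classification bands, see [classify_probability()].
#' @return A `probability_table` data frame: `variable, constant`, one
#'   `p_alpha_<fraction>` column per alpha, and `classification` (under the
#'   driving alpha).
#' @export
replacement_probabilities <- function(result,
                                      alpha_fractions = result$alpha_fractions,
                                      bands = c(0.4, 0.6)) {
  stopifnot(inherits(result, "search_result"))
  B <- result$bits
  out <- data.frame(variable = result$candidates$names,
                    constant = as.numeric(
                      result$candidates$constants[result$candidates$names]))
  for (fr in alpha_fractions) {
    w <- .cache_weights(result, fr)
    out[[paste0("p_alpha_", fr)]] <- as.vector(crossprod(B, w))
  }
  driving <- result$alpha_fractions[result$driving_alpha_index]
  pcol <- paste0("p_alpha_", driving)
  if (!pcol %in% names(out)) pcol <- paste0("p_alpha_", alpha_fractions[1L])
  out$classification <- classify_probability(out[[pcol]], bands)
  class(out) <- c("probability_table", "data.frame")
  out
}

#' Pairwise joint replacement probabilities
#'
#' `P(A and B)` by the same pseudo-likelihood-weighted sum over models in
#' which both variables are replaced, together with the independence ratio
#' `P(A and B) / (P(A) P(B))`: above 1 the two tend to be replaced
#' together, below 1 they substitute for one another.
#'
#' @param result A `search_result` with at least 2 candidates.
#' @param alpha_fraction Alpha used for weighting (default: the driving
#'   alpha).
#' @return Data frame `var_a, var_b, p_joint, independence_ratio`
#'   (unordered pairs, `var_a` earlier in candidate order).
#' @export
joint_probabilities <- function(result,
                                alpha_fraction =
                                  result$alpha_fractions[result$driving_alpha_index]) {
  stopifnot(inherits(result, "search_result"))
  N <- ncol(result$bits)
  if (N < 2L) stop("need at least 2 candidates", call. = FALSE)
  w <- .cache_weights(result, alpha_fraction)
  B <- result$bits
  P <- crossprod(B, B * w)          # N x N; diagonal = marginals
  marg <- diag(P)
  pairs <- utils::combn(N, 2L)
  data.frame(
    var_a = result$candidates$names[pairs[1L, ]],
    var_b = result$candidates$names[pairs[2L, ]],
    p_joint = P[t(pairs)],
    independence_ratio = {
      denom <- marg[pairs[1L, ]] * marg[pairs[2L, ]]
      ifelse(denom > 0, P[t(pairs)] / denom, NA_real_)
    })
}

#' Convergence trace of the replacement probabilities
#'
#' Recomputes the probability table over the growing unique-model cache
#' every `interval` evaluations (plus the final cache), under the driving
#' alpha; the final point equals the full-table value. Stabilisation of
#' the trace is the (inspected, not enforced) stopping diagnostic.
#'
#' @param result A `search_result`.
#' @param interval Positive number of unique evaluations between trace
#'   points.
#' @return Data frame `unique_count, variable, probability`.
#' @export
convergence_trace <- function(result, interval) {
  stopifnot(inherits(result, "search_result"), interval >= 1L)
  M <- nrow(result$bits)
  counts <- unique(c(seq(from = min(interval, M), to = M, by = interval), M))
  fr <- result$alpha_fractions[result$driving_alpha_index]
  do.call(rbind, lapply(counts, function(n) {
    w <- .cache_weights(result, fr, n = n)
    p <- as.vector(crossprod(result$bits[seq_len(n), , drop = FALSE], w))
    data.frame(unique_count = n, variable = result$candidates$names,
               probability = p)
  }))
}
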