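test_that("the acceptance rule accepts in proportion to the q ratio", {
  # q_trial/q_current > r with r ~ U(0,1): a ratio above 1 always accepts,
  # a ratio of one half accepts with long-run frequency 0.5
  set.seed(123)
  r <- runif(1e5)
  expect_true(all(modred:::.accept_step(0.1, 0, r)))
  expect_true(all(modred:::.accept_step(0, 0, r)))
  freq <- mean(modred:::.accept_step(log(0.5), 0, r))
  expect_lt(abs(freq - 0.5), 0.01)
  freq25 <- mean(modred:::.accept_step(log(0.25), 0, r))
  expect_lt(abs(freq25 - 0.25), 0.01)
})

flat_spec <- function(n = 3L) {
  # n replaceable accumulators nothing reads: every replacement state has
  # identical RSS, so all pseudo-likelihoods are equal
  vars <- c(list(variable_def("y", "y + x", init = 0,
                              replaceable = FALSE)),
            lapply(paste0("u", seq_len(n)), function(nm) {
              variable_def(nm, paste(nm, "+ x"), init = 0)
            }))
  model_spec(vars, drivers = "x", outputs = "y")
}
flat_setup <- function(n = 3L) {
  spec <- flat_spec(n)
  drv <- mini_drivers(x = c(1, 2, 3, 2, 1))
  obs <- observation_set(
    data.frame(stream = "y", site = "s1", day = c(1, 3),
               value = c(3.2, 7.9)),
    se_fractions = c(y = 0.1))
  cand <- structure(
    list(names = paste0("u", seq_len(n)),
         constants = stats::setNames(rep(1, n), paste0("u", seq_len(n)))),
    class = "candidate_set")
  list(spec = spec, drv = drv, obs = obs, cand = cand)
}

test_that("a one-candidate space is exhausted with exactly two models", {
  s <- flat_setup(1L)
  res <- mh_search(s$spec, s$drv, s$obs, s$cand,
                   search_settings(n_unique = 10000, seed = 5))
  expect_identical(nrow(res$bits), 2L)
  expect_identical(res$terminated, "exhausted")
  expect_identical(res$bits[1, ], 0L)  # chain starts all-normal
  expect_equal(res$models$rss[1], res$rss_full)
})

test_that("exhaustive enumeration covers all 2^N unique states", {
  s <- flat_setup(3L)
  res <- exhaustive_enumeration(s$spec, s$drv, s$obs, s$cand)
  expect_identical(nrow(res$bits), 8L)
  expect_identical(anyDuplicated(res$models$key), 0L)
  expect_identical(res$bits[1, ], c(0L, 0L, 0L))
  big <- structure(list(names = letters[1:20],
                        constants = stats::setNames(rep(1, 20),
                                                    letters[1:20])),
                   class = "candidate_set")
  expect_error(exhaustive_enumeration(s$spec, s$drv, s$obs, big),
               "cap")
})

test_that("uniform pseudo-likelihoods give probability one half and
          independent pairs", {
  s <- flat_setup(3L)
  res <- exhaustive_enumeration(s$spec, s$drv, s$obs, s$cand)
  expect_true(all(abs(res$models$rss - res$rss_full) < 1e-9))
  pt <- replacement_probabilities(res)
  for (col in grep("^p_alpha_", names(pt), value = TRUE)) {
    expect_equal(pt[[col]], rep(0.5, 3), tolerance = 1e-12)
  }
  expect_identical(pt$classification, rep("redundant", 3))
  jp <- joint_probabilities(res)
  expect_equal(jp$p_joint, rep(0.25, 3), tolerance = 1e-12)
  expect_equal(jp$independence_ratio, rep(1, 3), tolerance = 1e-12)
})

test_that("probability bookkeeping on hand-built caches", {
  cand <- structure(list(names = c("a", "b"),
                         constants = c(a = 1, b = 2)),
                    class = "candidate_set")
  st <- search_settings(alpha_fractions = c(0.05), driving_alpha_index = 1)
  # variable a replaced in every cached model -> probability 1;
  # a and b only ever replaced together -> dependence ratio above 1
  res <- modred:::.new_result(
    bits = rbind(c(1L, 0L), c(1L, 1L)), rss = c(100, 100),
    candidates = cand, rss_full = 100, settings = st,
    chain = integer(), n_iter = 0L, terminated = "constructed")
  pt <- replacement_probabilities(res)
  expect_equal(pt$p_alpha_0.05, c(1, 0.5))
  res2 <- modred:::.new_result(
    bits = rbind(c(0L, 0L), c(1L, 1L)), rss = c(100, 100),
    candidates = cand, rss_full = 100, settings = st,
    chain = integer(), n_iter = 0L, terminated = "constructed")
  jp <- joint_probabilities(res2)
  expect_equal(jp$p_joint, 0.5)
  expect_gt(jp$independence_ratio, 1)
  # failed models (infinite RSS) carry zero weight
  res3 <- modred:::.new_result(
    bits = rbind(c(0L, 0L), c(0L, 1L), c(1L, 0L)), rss = c(100, 100, Inf),
    candidates = cand, rss_full = 100, settings = st,
    chain = integer(), n_iter = 0L, terminated = "constructed")
  pt3 <- replacement_probabilities(res3)
  expect_equal(pt3$p_alpha_0.05, c(0, 0.5))
})

test_that("stochastic search agrees with the exhaustive oracle on the
          fixture", {
  fx <- toy_fix(2L)
  cand <- select_candidates(toy_screen(2L))
  ex <- exhaustive_enumeration(fx$spec, fx$drv, fx$obs, cand)
  mh <- mh_search(fx$spec, fx$drv, fx$obs, cand,
                  search_settings(seed = 77))
  pe <- replacement_probabilities(ex)
  pm <- replacement_probabilities(mh)
  expect_identical(pe$variable, pm$variable)
  for (col in grep("^p_alpha_", names(pe), value = TRUE)) {
    expect_lt(max(abs(pe[[col]] - pm[[col]])), 0.02)
  }
  expect_lte(nrow(mh$bits), 2L^length(cand$names))
  expect_identical(anyDuplicated(mh$models$key), 0L)
})

test_that("search is reproducible from its seed and restores the RNG", {
  fx <- toy_fix()
  cand <- select_candidates(toy_screen())
  set.seed(999)
  before <- .Random.seed
  r1 <- mh_search(fx$spec, fx$drv, fx$obs, cand,
                  search_settings(seed = 42))
  expect_identical(.Random.seed, before)
  r2 <- mh_search(fx$spec, fx$drv, fx$obs, cand,
                  search_settings(seed = 42))
  expect_identical(r1$models, r2$models)
  expect_identical(r1$chain, r2$chain)
  expect_identical(r1$bits, r2$bits)
})

test_that("convergence traces shrink to the final table", {
  fx <- toy_fix()
  cand <- select_candidates(toy_screen())
  res <- mh_search(fx$spec, fx$drv, fx$obs, cand,
                   search_settings(seed = 42))
  M <- nrow(res$bits)
  pt <- replacement_probabilities(res)
  driving <- paste0("p_alpha_", res$alpha_fractions[res$driving_alpha_index])

  tr1 <- convergence_trace(res, interval = M)
  expect_identical(unique(tr1$unique_count), M)
  expect_equal(stats::setNames(tr1$probability, tr1$variable)[pt$variable],
               stats::setNames(pt[[driving]], pt$variable))

  tr <- convergence_trace(res, interval = 25)
  expect_identical(unique(tr$unique_count),
                   unique(c(seq(25, M, by = 25), M)))
  final <- tr[tr$unique_count == M, ]
  expect_equal(stats::setNames(final$probability, final$variable)[pt$variable],
               stats::setNames(pt[[driving]], pt$variable))
})

test_that("noise variables outrank redundant ones at every alpha", {
  fx <- toy_fix()
  cand <- select_candidates(toy_screen())
  ex <- exhaustive_enumeration(fx$spec, fx$drv, fx$obs, cand)
  pt <- replacement_probabilities(ex)
  noise <- intersect(role_vars(fx, "noise"), pt$variable)
  red <- intersect(role_vars(fx, "redundant"), pt$variable)
  for (col in grep("^p_alpha_", names(pt), value = TRUE)) {
    p <- stats::setNames(pt[[col]], pt$variable)
    expect_gt(min(p[noise]), max(p[red]))
  }
})
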