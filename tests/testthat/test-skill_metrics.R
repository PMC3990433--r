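obs_from <- function(value, stream = "biomass", fr = c(biomass = 0.10),
                     se = NULL) {
  df <- data.frame(stream = stream, site = "s1",
                   day = seq_along(value) - 1L, value = value)
  if (!is.null(se)) df$se <- se
  observation_set(df, se_fractions = fr)
}
pred_from <- function(obs, pred) {
  data.frame(stream = obs$stream, site = obs$site, day = obs$day,
             pred = pred)
}

test_that("weighted RSS matches hand arithmetic and its scaling law", {
  obs <- obs_from(c(10, 20))                       # s = (1, 2)
  expect_equal(obs$s, c(1, 2))
  expect_equal(weighted_rss(obs, predictions = pred_from(obs, c(11, 18))),
               2)                                  # 1/1 + (2/2)^2
  expect_equal(weighted_rss(obs, predictions = pred_from(obs, c(10, 20))),
               0)
  obs2 <- obs_from(c(10, 20), fr = c(biomass = 0.20))  # double all s_j
  expect_equal(weighted_rss(obs2, predictions = pred_from(obs2, c(11, 18))),
               0.5)                                # quarters the RSS
  expect_error(
    weighted_rss(obs, predictions = pred_from(obs, c(11, 18))[1, ]),
    "not matched")
})

test_that("Nash-Sutcliffe: perfect model, mean predictor, hand example,
          negative values", {
  obs <- obs_from(c(10, 20, 30))
  expect_equal(nash_sutcliffe(obs, predictions = pred_from(obs, c(10, 20, 30))),
               1)
  # equal explicit weights: predicting the mean gives exactly 0
  obs_eq <- obs_from(c(10, 20, 30), se = c(2, 2, 2))
  expect_equal(nash_sutcliffe(obs_eq,
                              predictions = pred_from(obs_eq, rep(20, 3))),
               0)
  # hand arithmetic of the weighted form, s = 10% of O
  m <- c(12, 20, 28)
  s <- c(1, 2, 3)
  expected <- 1 - sum(((c(10, 20, 30) - m) / s)^2) /
    sum(((c(10, 20, 30) - 20) / s)^2)
  expect_equal(nash_sutcliffe(obs, predictions = pred_from(obs, m)),
               expected)
  # a bad enough model goes negative
  expect_lt(nash_sutcliffe(obs, predictions = pred_from(obs, c(30, 10, 50))),
            0)
  expect_error(
    nash_sutcliffe(obs_from(c(5, 5, 5)),
                   predictions = pred_from(obs, c(1, 2, 3))),
    "degenerate")
})

test_that("NS and RSS are consistent on random observation sets", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(5:30, 1)
    o <- runif(n, 1, 100)
    obs <- obs_from(o)
    m <- o * (1 + rnorm(n, 0, 0.2))
    rss <- weighted_rss(obs, predictions = pred_from(obs, m))
    denom <- sum(((o - mean(o)) / obs$s)^2)
    expect_equal(nash_sutcliffe(obs, predictions = pred_from(obs, m)),
                 1 - rss / denom)
  }
})

test_that("zero observations keep a positive floored standard error", {
  obs <- obs_from(c(0, 10, 20), stream = "lai", fr = c(lai = 0.2))
  expect_true(all(obs$s > 0))
  expect_equal(obs$s[1], 0.2 * 0.01 * 10)  # fraction x 1% of stream mean
})

test_that("pseudo-likelihood halves for every alpha of RSS above the full
          model", {
  for (k in 0:3) {
    expect_equal(pseudo_likelihood(100 + 5 * k, 100, 5), 0.5^k)
  }
  expect_equal(pseudo_likelihood(100, 100, 5), 1)
  expect_equal(pseudo_likelihood(110, 100, 5), 0.25)
  # improvement on the full model earns weight above 1
  expect_gt(pseudo_likelihood(95, 100, 5), 1)
  expect_error(pseudo_likelihood(100, 100, 0), "positive")
  expect_error(pseudo_likelihood(100, 100, -1), "positive")
})

test_that("pseudo-likelihood is monotone in rss and in alpha", {
  rss <- seq(100, 200, by = 10)
  q <- pseudo_likelihood(rss, 100, 5)
  expect_true(all(diff(q) < 0))
  # at fixed excess RSS, larger alpha forgives more
  q_by_alpha <- vapply(c(2, 5, 10, 20),
                       function(a) pseudo_likelihood(130, 100, a),
                       numeric(1))
  expect_true(all(diff(q_by_alpha) > 0))
})

test_that("normalization preserves ratios and sums to one", {
  expect_equal(normalize_q(c(1, 1)), c(0.5, 0.5))
  expect_equal(normalize_q(c(2, 1, 1)), c(0.5, 0.25, 0.25))
  set.seed(11)
  for (i in 1:5) {
    v <- rexp(1000)
    w <- normalize_q(v)
    expect_lt(abs(sum(w) - 1), 1e-12)
    expect_equal(order(w), order(v))
    expect_equal(w[1] / w[2], v[1] / v[2])
  }
  expect_error(normalize_q(numeric()), "empty")
  expect_error(normalize_q(c(1, -1)), "positive")
})

test_that("skill_summary reports per-stream and pooled rows", {
  fx <- toy_fix()
  traj <- simulate_model(fx$spec, fx$drv)
  sk <- skill_summary(fx$obs, traj)
  expect_setequal(sk$stream, c("biomass", "grain", "lai", "pooled"))
  expect_equal(sk$n[sk$stream == "pooled"], nrow(fx$obs))
  expect_equal(sk$rss[sk$stream == "pooled"], weighted_rss(fx$obs, traj))
  expect_equal(sk$ns[sk$stream == "lai"],
               nash_sutcliffe(fx$obs, traj, stream = "lai"))
  expect_true(all(sk$ns <= 1))
})
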