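test_that("a minimal spec parses and simulates its closed form", {
  txt <- '{
    "parameters": {"r": 0.5},
    "drivers": ["x"],
    "outputs": ["b"],
    "variables": [{"name": "b", "rule": "b + r", "init": 0}]
  }'
  spec <- parse_model_spec(txt)
  expect_s3_class(spec, "model_spec")
  expect_length(spec$variables, 1L)
  expect_identical(names(spec$parameters), "r")
  traj <- simulate_model(spec, mini_drivers(x = rep(0, 10)))
  expect_equal(as.vector(traj$values$b), 0.5 * (1:10))
})

test_that("unknown identifiers and intra-step cycles are rejected by name", {
  expect_error(
    model_spec(list(variable_def("y", "tmaxx + 1")), drivers = "tmax"),
    "tmaxx")
  expect_error(
    model_spec(list(variable_def("a", "b + 1"),
                    variable_def("b", "a + 1"))),
    "cycle.*a, b")
  # a lagged reference breaks the same-day cycle
  spec <- model_spec(list(variable_def("a", "lag(b) + 1"),
                          variable_def("b", "a + 1")))
  expect_identical(spec$eval_order, c("a", "b"))
})

test_that("rule validation enforces the primitive whitelist", {
  expect_error(
    model_spec(list(variable_def("z", "system('ls')"))),
    "disallowed")
  expect_error(
    model_spec(list(variable_def("z", "sin(x)")), drivers = "x"),
    "disallowed")
  expect_error(variable_def("s", "1", is_switch = TRUE,
                            replaceable = FALSE),
               "replaceable")
})

test_that("model specs survive a serialize / re-parse round trip", {
  fx <- toy_fix()
  path <- withr::local_tempfile(fileext = ".json")
  write_model_spec(fx$spec, path)
  spec2 <- read_model_spec(path)
  expect_identical(names(spec2$variables), names(fx$spec$variables))
  expect_equal(spec2$parameters, fx$spec$parameters)
  expect_identical(spec2$eval_order, fx$spec$eval_order)
  for (v in names(fx$spec$variables)) {
    a <- fx$spec$variables[[v]]; b <- spec2$variables[[v]]
    expect_identical(a[c("rule", "replaceable", "is_switch", "tags")],
                     b[c("rule", "replaceable", "is_switch", "tags")])
    expect_equal(a$init, b$init)
  }
  # diagnostic-tagged variables are exactly the non-replaceable ones here
  repl <- vapply(spec2$variables, `[[`, logical(1), "replaceable")
  diag <- vapply(spec2$variables,
                 function(v) "diagnostic" %in% v$tags, logical(1))
  expect_identical(unname(!repl), unname(diag))
})

test_that("full-model simulation matches the hand-coded oracle", {
  fx <- toy_fix()
  traj <- simulate_model(fx$spec, fx$drv)
  oracle <- hand_toy_sim(fx$drv)
  for (v in names(oracle)) {
    expect_equal(traj$values[[v]], oracle[[v]], tolerance = 1e-12,
                 label = paste("variable", v))
  }
})

test_that("replacement semantics: constants, locality, determinism", {
  fx <- toy_fix()
  full <- simulate_model(fx$spec, fx$drv)

  # replaced variable is constant everywhere; a no-consumer replacement
  # leaves every other series bit-identical
  red <- simulate_model(fx$spec, fx$drv, replacement_state(c(cum_rain = 7)))
  expect_true(all(red$values$cum_rain == 7))
  for (v in setdiff(names(full$values), "cum_rain")) {
    expect_identical(red$values[[v]], full$values[[v]])
  }

  # locality: replacement only perturbs (transitive) dependents
  for (v in c("evap", "trans_pot", "rue_mod")) {
    down <- downstream_variables(fx$spec, v)
    mid <- mean(variable_range(full, v))
    alt <- simulate_model(fx$spec, fx$drv,
                          replacement_state(stats::setNames(mid, v)))
    for (w in setdiff(names(full$values), c(v, down))) {
      expect_identical(alt$values[[w]], full$values[[w]],
                       label = paste(w, "after replacing", v))
    }
  }

  # identity replacement: site2 never water-limited, so dfac = 1 there and
  # replacing dfac by 1.0 reproduces that site exactly
  expect_equal(min(full$values$dfac[, "site2"]), 1)
  alt <- simulate_model(fx$spec, fx$drv, replacement_state(c(dfac = 1)))
  for (v in names(full$values)) {
    expect_identical(alt$values[[v]][, "site2"],
                     full$values[[v]][, "site2"])
  }

  # determinism
  expect_identical(simulate_model(fx$spec, fx$drv)$values, full$values)

  # replacing a non-replaceable variable is refused
  expect_error(simulate_model(fx$spec, fx$drv,
                              replacement_state(c(tmean = 10))),
               "replaceable")
})

test_that("replacement idempotence: refitting a replaced run changes nothing", {
  fx <- toy_fix()
  st <- replacement_state(c(evap = 0.2))
  t1 <- simulate_model(fx$spec, fx$drv, st)
  t2 <- simulate_model(fx$spec, fx$drv, st)
  expect_identical(t1$values, t2$values)
})

test_that("variable_range reports exact attained extremes", {
  spec <- model_spec(
    list(variable_def("const", "3.2"),
         variable_def("y", "x")),
    drivers = "x", outputs = "y")
  traj <- simulate_model(spec, mini_drivers(x = c(0, 5, 2)))
  expect_equal(variable_range(traj, "const"), c(3.2, 3.2))
  expect_equal(variable_range(traj, "y"), c(0, 5))
  expect_error(variable_range(traj, "nope"), "nope")

  # monotone accumulator: range is (first, last) by direct scan
  fx <- toy_fix()
  full <- simulate_model(fx$spec, fx$drv)
  tt <- full$values$tt
  expect_equal(variable_range(full, "tt"),
               c(min(tt[1, ]), max(tt[nrow(tt), ])))
})

test_that("list_replaceable applies exclusions in spec order", {
  fx <- toy_fix()
  all_repl <- list_replaceable(fx$spec)
  expect_true(all(c("tt", "dtt", "transp") %in% all_repl))
  some <- list_replaceable(fx$spec, fx$exclusions)
  expect_identical(some, setdiff(all_repl, fx$exclusions))
  expect_identical(list_replaceable(fx$spec, character()), all_repl)
  expect_error(list_replaceable(fx$spec, "ghost"), "ghost")
})

test_that("non-finite states raise an error naming variable and day", {
  spec <- model_spec(
    list(variable_def("z", "exp(z) + 1", init = 1)),
    drivers = "x")
  err <- tryCatch(simulate_model(spec, mini_drivers(x = rep(0, 20))),
                  modred_sim_error = function(e) e)
  expect_s3_class(err, "modred_sim_error")
  expect_match(conditionMessage(err), "'z' on day")
  expect_identical(err$variable, "z")
})
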