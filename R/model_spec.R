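# Declarative model language: variables with daily update rules over
# parameters, drivers, other variables and lagged values.

# Whitelisted primitives a rule may call. Everything is vectorised over
# sites; min/max must therefore be the parallel forms.
.RULE_FUNS <- c("+", "-", "*", "/", "^", "(",
                "<", "<=", ">", ">=", "==", "!=", "&", "|", "!",
                "pmin", "pmax", "ifelse", "exp", "log", "sqrt", "abs",
                "lag")

#' Define a model variable
#'
#' A variable is an internal quantity recomputed every day from an update
#' rule. Within a rule, another variable's bare name refers to its value on
#' the *current* day (so it must be computable earlier in the same step),
#' while the variable's *own* name, or `lag(x)` for any variable `x`, refers
#' to the previous day's value. Parameters and drivers are referenced by
#' name.
#'
#' @param name Identifier (unique within a spec).
#' @param rule Update rule as a character string, e.g. `"tt + pmax(0, tmean)"`.
#'   Allowed primitives: arithmetic, comparisons, `&`, `|`, `!`, `pmin`,
#'   `pmax`, `ifelse`, `exp`, `log`, `sqrt`, `abs`, and `lag()`.
#' @param init Value taken on the day before the simulation starts (the
#'   lag-1 value seen on day 0). Default 0.
#' @param replaceable Can this variable be replaced by a constant?
#' @param is_switch Is this an artificial switch variable? Switches are
#'   always replaceable and are replaced at `off_value` without fitting.
#' @param off_value The documented "off" constant for a switch (default 0).
#' @param tags Free-form labels, e.g. `"diagnostic"`, `"mass-balance"`.
#' @return A `variable_def` object.
#' @export
variable_def <- function(name, rule, init = 0, replaceable = TRUE,
                         is_switch = FALSE, off_value = 0,
                         tags = character()) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            is.character(rule), length(rule) == 1L,
            is.numeric(init), length(init) == 1L, is.finite(init))
  if (is_switch && !replaceable) {
    stop("switch variable '", name, "' must be replaceable", call. = FALSE)
  }
  expr <- tryCatch(str2lang(rule), error = function(e) {
    stop("rule for '", name, "' does not parse: ", conditionMessage(e),
         call. = FALSE)
  })
  structure(
    list(name = name, rule = rule, expr = expr, init = as.numeric(init),
         replaceable = isTRUE(replaceable), is_switch = isTRUE(is_switch),
         off_value = as.numeric(off_value), tags = as.character(tags)),
    class = "variable_def"
  )
}

# Walk a rule AST: check the function whitelist and collect symbol
# references, separating current-day from lagged ones.
.analyze_rule <- function(expr, self, var_names, par_names, drv_names) {
  cur <- character(); lagged <- character()
  pars <- character(); drvs <- character()
  walk <- function(e) {
    if (is.numeric(e) || is.logical(e)) return(invisible())
    if (is.symbol(e)) {
      s <- as.character(e)
      if (s == self) lagged <<- c(lagged, s)
      else if (s %in% var_names) cur <<- c(cur, s)
      else if (s %in% par_names) pars <<- c(pars, s)
      else if (s %in% drv_names) drvs <<- c(drvs, s)
      else stop("rule for '", self, "' references unknown identifier '",
                s, "'", call. = FALSE)
      return(invisible())
    }
    if (is.call(e)) {
      fn <- e[[1L]]
      if (!is.symbol(fn) || !(as.character(fn) %in% .RULE_FUNS)) {
        stop("rule for '", self, "' uses disallowed function '",
             deparse(fn), "'", call. = FALSE)
      }
      if (as.character(fn) == "lag") {
        if (length(e) != 2L || !is.symbol(e[[2L]])) {
          stop("in rule for '", self,
               "': lag() takes a single variable name", call. = FALSE)
        }
        s <- as.character(e[[2L]])
        if (!(s %in% var_names)) {
          stop("rule for '", self, "' lags unknown variable '", s, "'",
               call. = FALSE)
        }
        lagged <<- c(lagged, s)
        return(invisible())
      }
      for (i in seq_along(e)[-1L]) walk(e[[i]])
      return(invisible())
    }
    stop("rule for '", self, "' contains unsupported syntax: ",
         deparse(e), call. = FALSE)
  }
  walk(expr)
  list(current = unique(cur), lagged = unique(lagged),
       parameters = unique(pars), drivers = unique(drvs))
}

# Kahn's algorithm over current-day edges; stable tie-break by declaration
# order. Lagged references carry no intra-step edge.
.topo_order <- function(names, refs) {
  n <- length(names)
  indeg <- stats::setNames(integer(n), names)
  out <- stats::setNames(vector("list", n), names)
  for (v in names) {
    for (d in refs[[v]]$current) {
      out[[d]] <- c(out[[d]], v)
      indeg[[v]] <- indeg[[v]] + 1L
    }
  }
  order <- character(0)
  ready <- names[indeg[names] == 0L]
  while (length(ready)) {
    v <- ready[1L]; ready <- ready[-1L]
    order <- c(order, v)
    for (w in out[[v]]) {
      indeg[[w]] <- indeg[[w]] - 1L
      if (indeg[[w]] == 0L) {
        ready <- c(ready, w)
        ready <- names[names %in% ready]  # keep declaration order
      }
    }
  }
  if (length(order) < n) {
    cyc <- setdiff(names, order)
    stop("update rules contain an intra-step cycle involving: ",
         paste(cyc, collapse = ", "),
         " (use lag() to break same-day dependence)", call. = FALSE)
  }
  order
}

#' Construct a model specification
#'
#' Validates identifiers and the intra-step dependency graph, and computes
#' the evaluation order used by [simulate_model()].
#'
#' @param variables List of [variable_def()] objects (declaration order is
#'   the reporting order).
#' @param parameters Named numeric vector of fixed parameters.
#' @param drivers Character vector of required driver stream names.
#' @param outputs Character vector of variable names that are observable
#'   streams (e.g. `biomass`, `grain`, `lai`).
#' @return A `model_spec` object.
#' @export
model_spec <- function(variables, parameters = numeric(),
                       drivers = character(), outputs = character()) {
  stopifnot(is.list(variables), length(variables) >= 1L)
  if (!all(vapply(variables, inherits, logical(1), "variable_def"))) {
    stop("'variables' must be a list of variable_def objects", call. = FALSE)
  }
  vnames <- vapply(variables, `[[`, character(1), "name")
  if (anyDuplicated(vnames)) {
    stop("duplicate variable names: ",
         paste(unique(vnames[duplicated(vnames)]), collapse = ", "),
         call. = FALSE)
  }
  parameters <- unlist(parameters)
  if (length(parameters) && (is.null(names(parameters)) ||
                             any(!nzchar(names(parameters))))) {
    stop("parameters must be named", call. = FALSE)
  }
  clash <- intersect(vnames, c(names(parameters), drivers))
  if (length(clash)) {
    stop("names used for both a variable and a parameter/driver: ",
         paste(clash, collapse = ", "), call. = FALSE)
  }
  bad_out <- setdiff(outputs, vnames)
  if (length(bad_out)) {
    stop("outputs not declared as variables: ",
         paste(bad_out, collapse = ", "), call. = FALSE)
  }
  names(variables) <- vnames
  refs <- lapply(variables, function(v) {
    .analyze_rule(v$expr, v$name, vnames, names(parameters), drivers)
  })
  eval_order <- .topo_order(vnames, refs)
  structure(
    list(variables = variables,
         parameters = parameters,
         drivers = as.character(drivers),
         outputs = as.character(outputs),
         refs = refs,
         eval_order = eval_order,
         .cache = new.env(parent = emptyenv())),
    class = "model_spec"
  )
}

#' @export
print.model_spec <- function(x, ...) {
  nrep <- sum(vapply(x$variables, `[[`, logical(1), "replaceable"))
  cat("<model_spec> ", length(x$variables), " variables (", nrep,
      " replaceable), ", length(x$parameters), " parameters, drivers: ",
      paste(x$drivers, collapse = ", "), "\n", sep = "")
  cat("  outputs: ", paste(x$outputs, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Parse a model specification from JSON text
#'
#' The document has top-level keys `parameters` (name/value map), `drivers`
#' (array of stream names), `outputs` (array of variable names) and
#' `variables` (array of objects with `name`, `rule` and optionally `init`,
#' `replaceable`, `is_switch`, `off_value`, `tags`).
#'
#' @param text JSON document as a single string or character vector of lines.
#' @return A validated [model_spec()].
#' @export
parse_model_spec <- function(text) {
  doc <- jsonlite::fromJSON(paste(text, collapse = "\n"),
                            simplifyVector = FALSE)
  if (is.null(doc$variables) || !length(doc$variables)) {
    stop("model spec document has no 'variables'", call. = FALSE)
  }
  vars <- lapply(doc$variables, function(v) {
    variable_def(name = v$name, rule = v$rule,
                 init = if (is.null(v$init)) 0 else v$init,
                 replaceable = if (is.null(v$replaceable)) TRUE else v$replaceable,
                 is_switch = if (is.null(v$is_switch)) FALSE else v$is_switch,
                 off_value = if (is.null(v$off_value)) 0 else v$off_value,
                 tags = if (is.null(v$tags)) character() else unlist(v$tags))
  })
  model_spec(variables = vars,
             parameters = unlist(doc$parameters),
             drivers = as.character(unlist(doc$drivers)),
             outputs = as.character(unlist(doc$outputs)))
}

#' Read / write a model specification
#'
#' @param path File path of a JSON model-spec document.
#' @return `read_model_spec()` returns a [model_spec()];
#'   `write_model_spec()` returns `path` invisibly.
#' @export
read_model_spec <- function(path) {
  parse_model_spec(readLines(path, warn = FALSE))
}

#' @param spec A [model_spec()].
#' @rdname read_model_spec
#' @export
write_model_spec <- function(spec, path) {
  stopifnot(inherits(spec, "model_spec"))
  doc <- list(
    parameters = as.list(spec$parameters),
    drivers = spec$drivers,
    outputs = spec$outputs,
    variables = lapply(unname(spec$variables), function(v) {
      list(name = v$name, rule = v$rule, init = v$init,
           replaceable = v$replaceable, is_switch = v$is_switch,
           off_value = v$off_value, tags = as.list(v$tags))
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Replacement state: which variables are fixed, and at what constants
#'
#' The empty state denotes the full (unreduced) model. Validity against a
#' particular spec (names exist and are replaceable) is checked by
#' [simulate_model()].
#'
#' @param constants Named numeric vector, variable name -> replacement value.
#' @return A `replacement_state` object.
#' @export
replacement_state <- function(constants = numeric()) {
  constants <- unlist(constants)
  if (length(constants)) {
    if (is.null(names(constants)) || any(!nzchar(names(constants)))) {
      stop("replacement constants must be named by variable", call. = FALSE)
    }
    if (anyDuplicated(names(constants))) {
      stop("duplicate variable in replacement state", call. = FALSE)
    }
    if (any(!is.finite(constants))) {
      stop("replacement constants must be finite", call. = FALSE)
    }
  }
  structure(list(replaced = names(constants),
                 constants = constants),
            class = "replacement_state")
}

#' @export
print.replacement_state <- function(x, ...) {
  if (!length(x$replaced)) {
    cat("<replacement_state> empty (full model)\n")
  } else {
    cat("<replacement_state>", length(x$replaced), "replaced:\n")
    print(x$constants)
  }
  invisible(x)
}

.check_state <- function(spec, state) {
  stopifnot(inherits(state, "replacement_state"))
  unknown <- setdiff(state$replaced, names(spec$variables))
  if (length(unknown)) {
    stop("replacement state names unknown variable(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  repl_ok <- vapply(spec$variables[state$replaced], `[[`, logical(1),
                    "replaceable")
  if (length(repl_ok) && !all(repl_ok)) {
    stop("variable(s) not flagged replaceable: ",
         paste(state$replaced[!repl_ok], collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' List candidate variables for screening
#'
#' Replaceable variables in declaration order, minus an explicit exclusion
#' list. Exclusions stand in for the manual, mechanistic curation step
#' (mass-balance breakers, intermediate steps) that must not be automated.
#'
#' @param spec A [model_spec()].
#' @param exclusions Character vector of variable names to drop.
#' @return Character vector of candidate names.
#' @export
list_replaceable <- function(spec, exclusions = character()) {
  stopifnot(inherits(spec, "model_spec"))
  unknown <- setdiff(exclusions, names(spec$variables))
  if (length(unknown)) {
    stop("exclusion names unknown variable(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  repl <- names(spec$variables)[vapply(spec$variables, `[[`, logical(1),
                                       "replaceable")]
  setdiff(repl, exclusions)
}

#' Variables downstream of a given variable
#'
#' Transitive closure over the full dependency graph (current-day and
#' lagged references alike): the set of variables whose trajectories can
#' change when `name` is altered. Used for locality checks.
#'
#' @param spec A [model_spec()].
#' @param name A variable name.
#' @return Character vector of dependent variable names (excluding `name`).
#' @export
downstream_variables <- function(spec, name) {
  stopifnot(inherits(spec, "model_spec"))
  if (!(name %in% names(spec$variables))) {
    stop("unknown variable '", name, "'", call. = FALSE)
  }
  # invert: for each variable, which variables read it (current or lagged)
  readers <- lapply(names(spec$variables), function(v) character(0))
  names(readers) <- names(spec$variables)
  for (v in names(spec$variables)) {
    for (d in unique(c(spec$refs[[v]]$current,
                       setdiff(spec$refs[[v]]$lagged, v)))) {
      readers[[d]] <- c(readers[[d]], v)
    }
    if (v %in% spec$refs[[v]]$lagged) {
      # self-lag: a variable always depends on itself; irrelevant here
    }
  }
  seen <- character(0)
  frontier <- readers[[name]]
  while (length(frontier)) {
    new <- setdiff(frontier, seen)
    seen <- c(seen, new)
    frontier <- unique(unlist(readers[new]))
  }
  setdiff(seen, name)
}
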