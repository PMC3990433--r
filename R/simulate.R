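# Simulation engine. A model_spec is compiled once into stack-machine
# bytecode (one postfix program per update rule); the daily loop over all
# sites runs in C++ (src/engine.cpp). Replacement states are passed as a
# (mask, constant) pair, so one compiled program serves every point of the
# replacement space.

#' Driver set: per-site daily input streams
#'
#' @param df Long data frame with columns `site`, `day` (0-based integer
#'   index from sowing) and one column per driver stream. Every site must
#'   cover the same contiguous day range `0..n-1`.
#' @return A `driver_set` object: one day-by-site matrix per stream.
#' @export
driver_set <- function(df) {
  stopifnot(is.data.frame(df), all(c("site", "day") %in% names(df)))
  streams <- setdiff(names(df), c("site", "day"))
  if (!length(streams)) stop("no driver streams in data frame", call. = FALSE)
  sites <- unique(as.character(df$site))
  days <- sort(unique(df$day))
  n_days <- length(days)
  if (!identical(as.integer(days), 0:(n_days - 1L))) {
    stop("driver days must be contiguous integers starting at 0",
         call. = FALSE)
  }
  mats <- lapply(streams, function(s) {
    m <- matrix(NA_real_, n_days, length(sites),
                dimnames = list(NULL, sites))
    for (st in sites) {
      sub <- df[df$site == st, ]
      if (nrow(sub) != n_days || !identical(sort(sub$day), days)) {
        stop("site '", st, "' does not cover days 0..", n_days - 1L,
             call. = FALSE)
      }
      m[sub$day + 1L, st] <- as.numeric(sub[[s]])
    }
    m
  })
  names(mats) <- streams
  structure(list(streams = mats, sites = sites, n_days = n_days),
            class = "driver_set")
}

#' @export
print.driver_set <- function(x, ...) {
  cat("<driver_set> ", length(x$streams), " streams x ", x$n_days,
      " days x ", length(x$sites), " sites (",
      paste(x$sites, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Read drivers from CSV
#'
#' Expects columns `site, day, <stream...>` with 0-based days.
#'
#' @param path CSV file path.
#' @return A [driver_set()].
#' @export
read_drivers <- function(path) {
  driver_set(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write drivers to CSV
#' @param drv A [driver_set()].
#' @param path Output file.
#' @export
write_drivers <- function(drv, path) {
  stopifnot(inherits(drv, "driver_set"))
  long <- do.call(rbind, lapply(drv$sites, function(st) {
    out <- data.frame(site = st, day = 0:(drv$n_days - 1L))
    for (s in names(drv$streams)) out[[s]] <- drv$streams[[s]][, st]
    out
  }))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

# opcodes; must mirror enum Op in src/engine.cpp
.OPS <- c(PUSH = 1L, CUR = 2L, LAG = 3L, DRV = 4L,
          ADD = 10L, SUB = 11L, MUL = 12L, DIV = 13L, POW = 14L,
          NEG = 15L,
          LT = 20L, LE = 21L, GT = 22L, GE = 23L, EQ = 24L, NE = 25L,
          AND = 26L, OR = 27L, NOT = 28L,
          PMIN = 30L, PMAX = 31L, IFELSE = 32L,
          EXP = 40L, LOG = 41L, SQRT = 42L, ABS = 43L)

.BINOP <- c("+" = "ADD", "-" = "SUB", "*" = "MUL", "/" = "DIV",
            "^" = "POW", "<" = "LT", "<=" = "LE", ">" = "GT", ">=" = "GE",
            "==" = "EQ", "!=" = "NE", "&" = "AND", "|" = "OR")
.UNFUN <- c(exp = "EXP", log = "LOG", sqrt = "SQRT", abs = "ABS")

# Compile one (already validated) rule AST to postfix bytecode.
.compile_rule <- function(expr, self, spec, vidx, didx) {
  op <- integer(); iarg <- integer(); xarg <- numeric()
  depth <- 0L; max_depth <- 0L
  emit <- function(o, i = 0L, x = 0, d) {
    op[[length(op) + 1L]] <<- .OPS[[o]]
    iarg[[length(iarg) + 1L]] <<- i
    xarg[[length(xarg) + 1L]] <<- x
    depth <<- depth + d
    if (depth > max_depth) max_depth <<- depth
  }
  rec <- function(e) {
    if (is.numeric(e) || is.logical(e)) {
      emit("PUSH", x = as.numeric(e), d = 1L); return(invisible())
    }
    if (is.symbol(e)) {
      s <- as.character(e)
      if (s == self) emit("LAG", i = vidx[[s]], d = 1L)
      else if (s %in% names(vidx)) emit("CUR", i = vidx[[s]], d = 1L)
      else if (s %in% names(spec$parameters)) {
        emit("PUSH", x = spec$parameters[[s]], d = 1L)
      } else emit("DRV", i = didx[[s]], d = 1L)
      return(invisible())
    }
    fn <- as.character(e[[1L]])
    if (fn == "(") return(rec(e[[2L]]))
    if (fn == "lag") {
      emit("LAG", i = vidx[[as.character(e[[2L]])]], d = 1L)
      return(invisible())
    }
    if (fn %in% c("+", "-") && length(e) == 2L) {  # unary sign
      rec(e[[2L]])
      if (fn == "-") emit("NEG", d = 0L)
      return(invisible())
    }
    if (fn == "!") {
      rec(e[[2L]]); emit("NOT", d = 0L); return(invisible())
    }
    if (fn %in% names(.UNFUN)) {
      if (length(e) != 2L) {
        stop("in rule for '", self, "': ", fn, "() takes one argument",
             call. = FALSE)
      }
      rec(e[[2L]]); emit(.UNFUN[[fn]], d = 0L); return(invisible())
    }
    if (fn %in% c("pmin", "pmax")) {
      args <- as.list(e)[-1L]
      if (length(args) < 2L) {
        stop("in rule for '", self, "': ", fn, "() needs >= 2 arguments",
             call. = FALSE)
      }
      rec(args[[1L]])
      for (a in args[-1L]) {  # left fold
        rec(a)
        emit(if (fn == "pmin") "PMIN" else "PMAX", d = -1L)
      }
      return(invisible())
    }
    if (fn == "ifelse") {
      rec(e[[2L]]); rec(e[[3L]]); rec(e[[4L]])
      emit("IFELSE", d = -2L)
      return(invisible())
    }
    if (fn %in% names(.BINOP)) {
      rec(e[[2L]]); rec(e[[3L]])
      emit(.BINOP[[fn]], d = -1L)
      return(invisible())
    }
    stop("internal: unhandled call '", fn, "'")  # unreachable: validated
  }
  rec(expr)
  list(op = op, iarg = iarg, xarg = xarg, depth = max_depth)
}

# Compile the whole spec once; cached in spec$.cache.
.get_program <- function(spec) {
  if (!is.null(spec$.cache$prog)) return(spec$.cache$prog)
  vn <- names(spec$variables)
  vidx <- stats::setNames(seq_along(vn), vn)
  didx <- stats::setNames(seq_along(spec$drivers), spec$drivers)
  rules <- lapply(vn, function(v) {
    .compile_rule(spec$variables[[v]]$expr, v, spec, vidx, didx)
  })
  lens <- vapply(rules, function(r) length(r$op), integer(1))
  prog <- list(
    op = unlist(lapply(rules, `[[`, "op")),
    iarg = unlist(lapply(rules, `[[`, "iarg")),
    xarg = unlist(lapply(rules, `[[`, "xarg")),
    rule_start = cumsum(c(1L, lens[-length(lens)])),
    rule_len = lens,
    eval_order = as.integer(vidx[spec$eval_order]),
    init = vapply(spec$variables, `[[`, numeric(1), "init"),
    max_depth = max(vapply(rules, `[[`, integer(1), "depth")))
  spec$.cache$prog <- prog
  prog
}

#' Simulate a model under a replacement state
#'
#' Runs the daily update loop for all sites at once. Replaced variables
#' hold their replacement constant on every day and site; everything
#' downstream reflects that constant. Deterministic: the model language
#' has no randomness.
#'
#' @param spec A [model_spec()].
#' @param drivers A [driver_set()] covering all required streams.
#' @param state A [replacement_state()]; the default (empty) state is the
#'   full, unreduced model.
#' @return A `trajectory_set`: per-variable day-by-site matrices plus the
#'   global (all-site) min/max range of each variable.
#' @export
simulate_model <- function(spec, drivers, state = replacement_state()) {
  stopifnot(inherits(spec, "model_spec"), inherits(drivers, "driver_set"))
  missing_drv <- setdiff(spec$drivers, names(drivers$streams))
  if (length(missing_drv)) {
    stop("drivers missing required stream(s): ",
         paste(missing_drv, collapse = ", "), call. = FALSE)
  }
  .check_state(spec, state)
  vn <- names(spec$variables)
  repl <- vn %in% state$replaced
  cst <- rep(NA_real_, length(vn))
  cst[match(state$replaced, vn)] <- as.numeric(state$constants[state$replaced])
  prog <- .get_program(spec)
  vals <- .sim_engine(drivers$streams[spec$drivers], prog$op, prog$iarg,
                      prog$xarg, prog$rule_start, prog$rule_len,
                      prog$eval_order, prog$init, repl, cst,
                      drivers$n_days, length(drivers$sites),
                      prog$max_depth)
  names(vals) <- vn
  for (v in vn) {
    m <- vals[[v]]
    if (!all(is.finite(m))) {
      bad <- which(!is.finite(m), arr.ind = TRUE)
      first <- bad[which.min(bad[, 1L]), , drop = TRUE]
      stop(structure(
        class = c("modred_sim_error", "error", "condition"),
        list(message = sprintf(
               "non-finite value for variable '%s' on day %d (site %s)",
               v, first[[1L]] - 1L, drivers$sites[first[[2L]]]),
             call = NULL, variable = v, day = first[[1L]] - 1L)))
    }
    colnames(vals[[v]]) <- drivers$sites
  }
  ranges <- lapply(vals, range)
  structure(list(values = vals, sites = drivers$sites,
                 n_days = drivers$n_days, ranges = ranges,
                 state = state),
            class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat("<trajectory_set> ", length(x$values), " variables x ", x$n_days,
      " days x ", length(x$sites), " sites\n", sep = "")
  invisible(x)
}

#' Range of a variable over the full run
#'
#' Global min/max over all days and sites, as used to bound the fitted
#' replacement constant.
#'
#' @param traj A `trajectory_set` from [simulate_model()].
#' @param name Variable name.
#' @return Numeric length-2 vector `c(min, max)`.
#' @export
variable_range <- function(traj, name) {
  stopifnot(inherits(traj, "trajectory_set"))
  if (!(name %in% names(traj$values))) {
    stop("variable '", name, "' not present in trajectories", call. = FALSE)
  }
  traj$ranges[[name]]
}

#' Export trajectories to a long data frame
#'
#' @param traj A `trajectory_set`.
#' @param variables Optional subset of variable names.
#' @return Data frame with columns `site, day, variable, value`.
#' @export
trajectories_to_df <- function(traj, variables = names(traj$values)) {
  stopifnot(inherits(traj, "trajectory_set"))
  do.call(rbind, lapply(variables, function(v) {
    m <- traj$values[[v]]
    data.frame(site = rep(traj$sites, each = traj$n_days),
               day = rep(0:(traj$n_days - 1L), length(traj$sites)),
               variable = v,
               value = as.vector(m))
  }))
}
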