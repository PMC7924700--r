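#' Advance the constraint store by one tick
#'
#' Instantiates every constraint at tick `k` (substituting already-solved
#' past values), evaluates conditional guards on determined values and posts
#' their consequents (at the current or next tick), and solves the remaining
#' unknowns.  Solving proceeds in two phases: equations with a single
#' unknown are propagated to fixpoint (with guards re-evaluated as values
#' become determined), then simultaneous subsystems are solved together.
#' After the step every instantiated constraint has residual at most the
#' store tolerance; solved values are immutable.
#'
#' @param store a [cob_store()].
#' @param k tick to solve; all earlier ticks must already be solved.
#' @return invisibly, a named list of the values solved at this step.
#' @export
step_store <- function(store, k) {
  k <- as.integer(k)
  if (k != store$next_tick)
    tcob_abort("tcob_parameter_error",
               sprintf("step out of order: expected tick %d, got %d",
                       store$next_tick, k))
  if (k > store$grid$t_end)
    tcob_abort("tcob_parameter_error", "tick beyond the end of the grid")
  reg <- new.env(parent = emptyenv())
  eqs <- list()
  conds <- list()
  wrap_tick <- function(expr) {
    withCallingHandlers(expr, tcob_error = function(e) {
      e$message <- sprintf("tick %d: %s", k, conditionMessage(e))
      stop(e)
    })
  }
  for (inst in store$instances) {
    for (cn in inst$constraints) {
      ctx <- list(inst = inst, k = k, store = store, reg = reg,
                  cmap = cn$cmap, params = NULL, guard_env = cn$env)
      if (cn$kind == "simple") {
        eqs[[length(eqs) + 1L]] <-
          wrap_tick(ground_equation(cn$lhs, cn$rhs, ctx, cn$env,
                                    sprintf("%s@%d", cn$label, k)))
      } else {
        conds[[length(conds) + 1L]] <- list(cn = cn, ctx = ctx)
      }
    }
  }
  ground_consequent <- function(cnd, sol) {
    wrap_tick(ground_equation(cnd$cn$lhs, cnd$cn$rhs, cnd$ctx, cnd$cn$env,
                              sprintf("%s@%d", cnd$cn$label, k)))
  }
  sol <- wrap_tick(solve_equation_set(eqs, conds, store$tolerance,
                                      ground_consequent))
  commit_solution(store, sol, reg)
  store$next_tick <- k + 1L
  out <- as.list(sol)
  names(out) <- pretty_uids(names(out))
  invisible(out)
}

#' Run a store over its whole time grid
#'
#' Calls [step_store()] for every tick of the grid and returns a trace
#' table: one row per tick with model time (`tick * dt`, in ms) and one
#' column per series variable of every instance, named `id.attr`.
#' Unconstrained series values are `NA`.
#'
#' @param store a [cob_store()].
#' @return a `data.frame` of class `tcob_trace`.
#' @export
run_cob <- function(store) {
  g <- store$grid
  if (store$next_tick <= g$t_end)
    for (k in seq(store$next_tick, g$t_end)) step_store(store, k)
  trace_table(store)
}

#' @rdname run_cob
#' @export
trace_table <- function(store) {
  g <- store$grid
  ticks <- seq(g$t_start, g$t_end)
  out <- list(time = ticks * g$dt)
  for (inst in store$instances) {
    for (nm in names(inst$attrs)) {
      a <- inst$attrs[[nm]]
      if (a$kind != "series") next
      vals <- series_values(inst, nm, ticks)
      out[[paste(inst$id, nm, sep = ".")]] <- simplify2array(vals)
    }
  }
  structure(as.data.frame(out, stringsAsFactors = FALSE, check.names = FALSE),
            class = c("tcob_trace", "data.frame"))
}

#' Residual sweep over a solved store
#'
#' Re-instantiates every constraint at every solved tick with the stored
#' values and reports the residuals: the machine-checkable statement that
#' the solver maintained `|lhs - rhs| <= tolerance` throughout the run.
#' Conditional constraints contribute their consequent wherever the guard
#' held; consequents pinned beyond the simulated horizon are skipped.
#'
#' @param store a solved [cob_store()].
#' @return a `data.frame` with columns `tick`, `constraint`, `residual`;
#'   the maximum absolute residual is attached as attribute `max`.
#' @export
store_residuals <- function(store) {
  g <- store$grid
  last <- store$next_tick - 1L
  rows <- list()
  empty_sol <- new.env(parent = emptyenv())
  for (k in seq(g$t_start, last)) {
    for (inst in store$instances) {
      for (cn in inst$constraints) {
        reg <- new.env(parent = emptyenv())
        ctx <- list(inst = inst, k = k, store = store, reg = reg,
                    cmap = cn$cmap, params = NULL, guard_env = cn$env)
        if (cn$kind == "conditional") {
          g_ok <- tryCatch(eval_guard(cn$guard, ctx, empty_sol),
                           tcob_error = function(e) NA)
          if (!isTRUE(g_ok)) next
        }
        eq <- tryCatch(ground_equation(cn$lhs, cn$rhs, ctx, cn$env, cn$label),
                       tcob_error = function(e) NULL)
        if (is.null(eq)) next
        if (length(free_unknowns(eq, empty_sol))) next  # beyond the horizon
        rows[[length(rows) + 1L]] <-
          data.frame(tick = k, constraint = cn$label,
                     residual = abs(eq_residual(eq, empty_sol)))
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(tick = integer(), constraint = character(),
                         residual = numeric())
  attr(out, "max") <- if (nrow(out)) max(out$residual) else 0
  out
}
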