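#' Constraint store
#'
#' The shared store holding every instance, its solved series values and the
#' solver tolerance.  After [step_store()] at tick `k`, every instantiated
#' constraint has residual `|lhs - rhs| <= tolerance`, and a solved value is
#' never discarded or changed.
#'
#' @param grid a [time_grid()].
#' @param tolerance solver residual bound (default 1e-9).
#' @return an environment of class `tcob_store`.
#' @export
cob_store <- function(grid, tolerance = 1e-9) {
  if (!inherits(grid, "tcob_grid"))
    tcob_abort("tcob_parameter_error", "grid must be a time_grid()")
  st <- new.env(parent = emptyenv())
  st$grid <- grid
  st$tolerance <- tolerance
  st$instances <- list()
  st$next_tick <- grid$t_start
  st$counter <- 0L
  class(st) <- "tcob_store"
  st
}

#' @export
print.tcob_store <- function(x, ...) {
  cat(sprintf("<tcob_store> %d instance(s), next tick %d, tolerance %g\n",
              length(x$instances), x$next_tick, x$tolerance))
  invisible(x)
}

#' Instantiate a constrained-object class
#'
#' Creates an instance in `store`: scalar constructor arguments are bound,
#' component attributes are filled from `args`, series initializers from
#' `init`, quantified constraints are expanded over their component arrays,
#' and creational constraints are solved immediately (an unsatisfiable one
#' raises an inconsistency error at creation).
#'
#' @param classdef a [define_class()] definition.
#' @param store a [cob_store()].
#' @param args named list: values for scalar attributes and constructor
#'   parameters, and instances (or lists of instances) for component
#'   attributes.
#' @param init named list of series initializers; each element is a vector
#'   whose names are ticks, e.g. `list(V = c("1" = 0))`.
#' @param id optional instance id (defaults to class name + counter).
#' @return the instance, an environment of class `tcob_instance`.
#' @export
instantiate <- function(classdef, store, args = list(), init = list(), id = NULL) {
  if (!inherits(classdef, "tcob_class"))
    tcob_abort("tcob_definition_error", "classdef must be a tcob_class")
  if (!inherits(store, "tcob_store"))
    tcob_abort("tcob_parameter_error", "store must be a cob_store()")
  params <- classdef$constructor$params
  missing_params <- setdiff(params, names(args))
  if (length(missing_params))
    tcob_abort("tcob_definition_error",
               sprintf("constructor arity mismatch: missing '%s'",
                       missing_params[1]))
  extraneous <- setdiff(names(args), c(names(classdef$attributes), params))
  if (length(extraneous))
    tcob_abort("tcob_definition_error",
               sprintf("argument '%s' matches no attribute or constructor parameter",
                       extraneous[1]))

  store$counter <- store$counter + 1L
  inst <- new.env(parent = emptyenv())
  inst$id <- id %||% paste0(tolower(classdef$name), store$counter)
  if (!is.null(store$instances[[inst$id]]))
    tcob_abort("tcob_definition_error",
               sprintf("instance id '%s' already in use", inst$id))
  inst$cls <- classdef
  nall <- store$grid$t_end + 1L  # room for one-tick-ahead (nxt) values
  attrs <- list()
  for (nm in names(classdef$attributes)) {
    kind <- classdef$attributes[[nm]]
    attrs[[nm]] <- switch(kind,
      scalar = list(kind = "scalar", known = FALSE, value = NULL),
      series = list(kind = "series", values = vector("list", nall),
                    known = logical(nall)),
      component = ,
      components = list(kind = kind, value = NULL))
  }
  inst$attrs <- attrs
  class(inst) <- "tcob_instance"

  # bind arguments
  param_vals <- args[intersect(names(args), params)]
  for (nm in intersect(names(args), names(classdef$attributes))) {
    kind <- classdef$attributes[[nm]]
    val <- args[[nm]]
    if (kind == "scalar") {
      inst$attrs[[nm]]$value <- val
      inst$attrs[[nm]]$known <- TRUE
    } else if (kind == "component") {
      if (!inherits(val, "tcob_instance"))
        tcob_abort("tcob_definition_error",
                   sprintf("component '%s' must be a tcob_instance", nm))
      inst$attrs[[nm]]$value <- val
    } else if (kind == "components") {
      if (!is.list(val) || !all(vapply(val, inherits, TRUE, "tcob_instance")))
        tcob_abort("tcob_definition_error",
                   sprintf("component array '%s' must be a list of instances", nm))
      inst$attrs[[nm]]$value <- val
    } else {
      tcob_abort("tcob_definition_error",
                 sprintf("series attribute '%s' cannot be bound as an argument; use init",
                         nm))
    }
  }

  # series initializers
  for (nm in names(init)) {
    a <- inst$attrs[[nm]]
    if (is.null(a) || a$kind != "series")
      tcob_abort("tcob_definition_error",
                 sprintf("'%s' is not a series attribute", nm))
    v <- init[[nm]]
    ticks <- as.integer(names(v) %||% seq_along(v))
    if (anyNA(ticks))
      tcob_abort("tcob_definition_error",
                 sprintf("initializer ticks for '%s' must be named by tick", nm))
    for (i in seq_along(v)) {
      k <- ticks[i]
      if (k < 1L || k > nall)
        tcob_abort("tcob_parameter_error",
                   sprintf("initializer tick %d for '%s' outside the grid", k, nm))
      inst$attrs[[nm]]$values[[k]] <- unname(v[i])
      inst$attrs[[nm]]$known[k] <- TRUE
    }
  }

  # expand quantified constraints; attach class env and component maps
  expanded <- list()
  for (ci in seq_along(classdef$constraints)) {
    cn <- classdef$constraints[[ci]]
    label <- sprintf("%s[%s] #%d", inst$id, classdef$name, ci)
    if (cn$kind %in% c("simple", "conditional")) {
      expanded[[length(expanded) + 1L]] <-
        list(kind = cn$kind, guard = cn$guard, lhs = cn$lhs, rhs = cn$rhs,
             cmap = NULL, env = classdef$env, label = label)
    } else if (cn$kind == "forall") {
      comps <- component_array(inst, cn$over)
      for (i in seq_along(comps)) {
        expanded[[length(expanded) + 1L]] <-
          list(kind = "simple", guard = NULL, lhs = cn$lhs, rhs = cn$rhs,
               cmap = list(it = comps[[i]]), env = classdef$env,
               label = sprintf("%s[%d]", label, i))
      }
    } else if (cn$kind == "sum") {
      comps <- component_array(inst, cn$over)
      cmap <- list()
      terms <- vector("list", length(comps))
      for (i in seq_along(comps)) {
        pref <- sprintf("itI%d", i)
        cmap[[pref]] <- comps[[i]]
        terms[[i]] <- rewrite_it(cn$term, pref)
      }
      sum_expr <- Reduce(function(a, b) call("+", a, b), terms)
      expanded[[length(expanded) + 1L]] <-
        list(kind = "simple", guard = NULL, lhs = cn$equals, rhs = sum_expr,
             cmap = cmap, env = classdef$env, label = label)
    }
  }
  inst$constraints <- expanded
  store$instances[[inst$id]] <- inst

  # creational constraints, solved at the first tick of the grid
  creational <- classdef$constructor$constraints
  if (length(creational)) {
    reg <- new.env(parent = emptyenv())
    eqs <- list()
    for (ci in seq_along(creational)) {
      cn <- creational[[ci]]
      ctx <- list(inst = inst, k = store$grid$t_start, store = store,
                  reg = reg, cmap = NULL, params = param_vals)
      eqs[[length(eqs) + 1L]] <-
        ground_equation(cn$lhs, cn$rhs, ctx, classdef$env,
                        sprintf("%s creational #%d", inst$id, ci))
    }
    sol <- solve_equation_set(eqs, list(), store$tolerance, NULL)
    commit_solution(store, sol, reg)
  }
  inst
}

component_array <- function(inst, over) {
  a <- inst$attrs[[over]]
  if (is.null(a) || a$kind != "components")
    tcob_abort("tcob_definition_error",
               sprintf("'%s' is not a component-array attribute", over))
  a$value %||% list()
}

# rename `it.X` symbols to `<prefix>.X`
rewrite_it <- function(expr, prefix) {
  if (is.symbol(expr)) {
    nm <- as.character(expr)
    if (nm == "it" || startsWith(nm, "it."))
      return(as.name(sub("^it", prefix, nm)))
    return(expr)
  }
  if (is.call(expr)) {
    for (i in seq_along(expr)[-1]) expr[[i]] <- rewrite_it(expr[[i]], prefix)
  }
  expr
}

#' @export
print.tcob_instance <- function(x, ...) {
  cat(sprintf("<tcob_instance> %s : %s\n", x$id, x$cls$name))
  invisible(x)
}

#' Resolve a series-variable reference
#'
#' Looks up the value of series `attr` of `inst` at tick `k + offset`.
#' Negative offsets (past references) must land on an already-solved or
#' initialized tick, otherwise an underdetermined error is raised.  For
#' offset 0 or +1 at an unsolved tick a `tcob_unknown` marker is returned,
#' to be solved at the current (offset 0) or next (offset +1) step.
#' Offsets beyond +1 are rejected: a constraint at tick `k` may bind values
#' at `k` and `k + 1` only.
#'
#' @param inst a `tcob_instance`.
#' @param attr series attribute name.
#' @param offset signed integer tick offset.
#' @param k reference tick.
#' @return the stored value, or a `tcob_unknown` marker.
#' @export
resolve_series <- function(inst, attr, offset, k) {
  a <- inst$attrs[[attr]]
  if (is.null(a) || a$kind != "series")
    tcob_abort("tcob_definition_error",
               sprintf("'%s' is not a series attribute of '%s'", attr, inst$id))
  offset <- as.integer(offset)
  if (offset > 1L)
    tcob_abort("tcob_definition_error",
               "references more than one tick into the future are not supported")
  tick <- k + offset
  known <- tick >= 1L && tick <= length(a$known) && a$known[tick]
  if (offset < 0L && !known)
    tcob_abort("tcob_underdetermined_error",
               sprintf("past reference to %s.%s at tick %d is undetermined",
                       inst$id, attr, tick))
  if (known) return(a$values[[tick]])
  structure(list(inst = inst$id, attr = attr, tick = tick),
            class = "tcob_unknown")
}

#' Pin series values directly
#'
#' Commits explicit values for a series variable at the given ticks, as an
#' external binding (e.g. a measured current).  Re-binding an already solved
#' tick to a different value is an inconsistency error: solved values are
#' immutable.
#'
#' @param store the store owning `inst`.
#' @param inst a `tcob_instance`.
#' @param attr series attribute name.
#' @param ticks integer vector of ticks.
#' @param values vector of values, recycled to `length(ticks)`.
#' @export
bind_series <- function(store, inst, attr, ticks, values) {
  a <- inst$attrs[[attr]]
  if (is.null(a) || a$kind != "series")
    tcob_abort("tcob_definition_error",
               sprintf("'%s' is not a series attribute of '%s'", attr, inst$id))
  values <- rep_len(values, length(ticks))
  for (i in seq_along(ticks)) {
    set_series_value(store, inst, attr, as.integer(ticks[i]), values[i])
  }
  invisible(inst)
}

set_series_value <- function(store, inst, attr, tick, value) {
  a <- inst$attrs[[attr]]
  if (tick < 1L || tick > length(a$known))
    tcob_abort("tcob_parameter_error",
               sprintf("tick %d outside the grid for %s.%s", tick, inst$id, attr))
  if (a$known[tick]) {
    old <- a$values[[tick]]
    same <- if (is.numeric(old) && is.numeric(value))
      abs(old - value) <= store$tolerance else identical(old, value)
    if (!same)
      tcob_abort("tcob_inconsistency_error",
                 sprintf("%s.%s at tick %d is already solved (%s); refusing to change it to %s",
                         inst$id, attr, tick, format(old), format(value)))
    return(invisible(NULL))
  }
  inst$attrs[[attr]]$values[[tick]] <- value
  inst$attrs[[attr]]$known[tick] <- TRUE
  invisible(NULL)
}

series_values <- function(inst, attr, ticks) {
  a <- inst$attrs[[attr]]
  vals <- a$values[ticks]
  vals[!a$known[ticks]] <- list(NA)
  vals
}
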