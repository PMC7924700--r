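#' Constraint constructors
#'
#' Constraints relate attribute expressions of a constrained-object class.
#' Four forms are supported:
#' \describe{
#'   \item{`con(lhs == rhs)`}{a simple (always-active) equation.}
#'   \item{`con_if(guard, lhs == rhs)`}{a conditional constraint: when the
#'     guard evaluates to `TRUE` at a tick the consequent equation is
#'     enforced.  Guards are evaluated on already-determined values; `&&`
#'     and `||` short-circuit so that e.g. `Time > 1 && prev(V) > 0` is safe
#'     at the first tick.}
#'   \item{`con_forall(over, expr)`}{a quantified constraint expanded at
#'     instantiation over a component-array attribute; inside `expr` the
#'     current component is addressed with the `it.` prefix
#'     (e.g. `it.V == V`).}
#'   \item{`con_sum(over, term, equals)`}{an aggregate constraint equating
#'     the sum of `term` (an `it.` expression) over a component array to
#'     `equals`.}
#' }
#'
#' Within constraint expressions the symbols `Time` (current tick) and `dt`
#' (milliseconds per tick) are built in; `prev(x)` (or `prev(x, j)`) refers
#' to the value of series `x` at the previous (j-th previous) tick and
#' `nxt(x)` to its value at the next tick.  References further than one tick
#' into the future are rejected.
#'
#' @param expr,guard,consequent,term,equals unquoted expressions.
#' @param over name of a component-array attribute.
#' @return a `tcob_constraint` object.
#' @examples
#' con(V == I * R)
#' con_if(C == "on", nxt(C) == "off")
#' con_forall("comps", it.V == V)
#' con_sum("comps", it.I, I)
#' @export
con <- function(expr) con_(substitute(expr))

#' @rdname con
#' @export
con_ <- function(expr) {
  check_equation(expr)
  structure(list(kind = "simple", lhs = expr[[2]], rhs = expr[[3]]),
            class = "tcob_constraint")
}

#' @rdname con
#' @export
con_if <- function(guard, consequent) con_if_(substitute(guard), substitute(consequent))

#' @rdname con
#' @export
con_if_ <- function(guard, consequent) {
  check_equation(consequent)
  structure(list(kind = "conditional", guard = guard,
                 lhs = consequent[[2]], rhs = consequent[[3]]),
            class = "tcob_constraint")
}

#' @rdname con
#' @export
con_forall <- function(over, expr) con_forall_(over, substitute(expr))

#' @rdname con
#' @export
con_forall_ <- function(over, expr) {
  check_equation(expr)
  structure(list(kind = "forall", over = over, lhs = expr[[2]], rhs = expr[[3]]),
            class = "tcob_constraint")
}

#' @rdname con
#' @export
con_sum <- function(over, term, equals) con_sum_(over, substitute(term), substitute(equals))

#' @rdname con
#' @export
con_sum_ <- function(over, term, equals) {
  structure(list(kind = "sum", over = over, term = term, equals = equals),
            class = "tcob_constraint")
}

check_equation <- function(expr) {
  if (!is.call(expr) || !identical(expr[[1]], as.name("==")))
    tcob_abort("tcob_definition_error",
               "a constraint equation must be written with ==")
  invisible(expr)
}

#' @export
print.tcob_constraint <- function(x, ...) {
  cat("<tcob_constraint>", x$kind, "\n")
  invisible(x)
}

# --- class definitions -----------------------------------------------------

#' Define a constrained-object class
#'
#' A class bundles typed attribute declarations with the constraints that
#' relate them; instances created with [instantiate()] share a constraint
#' store in which a per-timestep solver maintains every constraint.  A class
#' may extend a parent class, in which case attributes and constraints are
#' the union of parent and child; redeclaring a parent attribute is a
#' definition error.
#'
#' @param name class name.
#' @param parent optional parent `tcob_class` to extend.
#' @param attributes named character vector/list mapping attribute names to
#'   one of `"scalar"` (a time-invariant value), `"series"` (a time-indexed
#'   sequence), `"component"` (an aggregated instance) or `"components"`
#'   (an array of aggregated instances).
#' @param constraints list of constraints built with [con()] and friends.
#' @param constructor optional list with elements `params` (character vector
#'   of constructor parameter names) and `constraints` (creational
#'   constraints, enforced once at instantiation).
#' @param env environment in which functions called inside constraint
#'   expressions are looked up; defaults to the caller.
#' @return a `tcob_class` definition.
#' @examples
#' component <- define_class("component",
#'   attributes = c(V = "series", I = "series"))
#' resistor <- define_class("resistor", parent = component,
#'   attributes = c(R = "scalar"),
#'   constraints = list(con(V == I * R)))
#' @export
define_class <- function(name, parent = NULL, attributes = list(),
                         constraints = list(), constructor = NULL,
                         env = parent.frame()) {
  attributes <- as.list(attributes)
  kinds <- c("scalar", "series", "component", "components")
  if (length(attributes)) {
    if (is.null(names(attributes)) || any(!nzchar(names(attributes))))
      tcob_abort("tcob_definition_error", "attributes must be named")
    bad <- !vapply(attributes, function(k) is.character(k) && k %in% kinds, TRUE)
    if (any(bad))
      tcob_abort("tcob_definition_error",
                 sprintf("unknown attribute kind for '%s'",
                         names(attributes)[bad][1]))
    if (any(grepl(".", names(attributes), fixed = TRUE)))
      tcob_abort("tcob_definition_error", "attribute names must not contain '.'")
  }
  merged <- attributes
  all_constraints <- constraints
  if (!is.null(parent)) {
    if (!inherits(parent, "tcob_class"))
      tcob_abort("tcob_definition_error", "parent must be a tcob_class")
    dup <- intersect(names(parent$attributes), names(attributes))
    if (length(dup))
      tcob_abort("tcob_definition_error",
                 sprintf("attribute '%s' redeclares a parent attribute", dup[1]))
    merged <- c(parent$attributes, attributes)
    all_constraints <- c(parent$constraints, constraints)
  }
  params <- constructor$params %||% character()
  for (cn in all_constraints) {
    if (!inherits(cn, "tcob_constraint"))
      tcob_abort("tcob_definition_error", "constraints must be built with con()/con_if()/con_forall()/con_sum()")
    check_constraint_symbols(cn, names(merged), params, name)
  }
  for (cn in constructor$constraints %||% list()) {
    if (!inherits(cn, "tcob_constraint"))
      tcob_abort("tcob_definition_error", "creational constraints must be built with con()")
    check_constraint_symbols(cn, names(merged), params, name)
  }
  structure(list(name = name, parent = parent, attributes = merged,
                 own_attributes = attributes, constraints = all_constraints,
                 constructor = list(params = params,
                                    constraints = constructor$constraints %||% list()),
                 env = env),
            class = "tcob_class")
}

#' @export
print.tcob_class <- function(x, ...) {
  cat(sprintf("<tcob_class> %s: %d attribute(s), %d constraint(s)\n",
              x$name, length(x$attributes), length(x$constraints)))
  invisible(x)
}

# every non-function symbol in a constraint must be a declared attribute,
# a constructor parameter, a built-in (Time, dt, pi) or an `it.` reference
# inside a quantified constraint
check_constraint_symbols <- function(cn, attr_names, params, class_name) {
  exprs <- switch(cn$kind,
    simple = list(cn$lhs, cn$rhs),
    conditional = list(cn$guard, cn$lhs, cn$rhs),
    forall = list(cn$lhs, cn$rhs),
    sum = list(cn$term, cn$equals))
  allow_it <- cn$kind %in% c("forall", "sum")
  builtins <- c("Time", "dt", "pi", "T", "F", "TRUE", "FALSE", "Inf", "NA")
  for (e in exprs) {
    for (s in collect_symbols(e)) {
      seg1 <- strsplit(s, ".", fixed = TRUE)[[1]][1]
      ok <- seg1 %in% attr_names || s %in% params || s %in% builtins ||
        (allow_it && seg1 == "it")
      if (!ok)
        tcob_abort("tcob_definition_error",
                   sprintf("unknown symbol '%s' in a constraint of class '%s'",
                           s, class_name))
    }
  }
  invisible(cn)
}

# bare (non call-head) symbols of an expression
collect_symbols <- function(expr) {
  out <- character()
  walk <- function(e) {
    if (is.symbol(e)) {
      out[[length(out) + 1L]] <<- as.character(e)
    } else if (is.call(e)) {
      for (a in as.list(e)[-1]) walk(a)
    }
  }
  walk(expr)
  unique(out)
}
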