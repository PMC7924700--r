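# Per-step constraint solving.
#
# A constraint instantiated at tick k is "grounded": solved past values are
# substituted, and each still-unknown value (a series value at tick k or
# k + 1, or an unbound scalar) becomes a symbol registered in `reg`.
# Grounded equations are then solved by local propagation (equations with a
# single unknown first, to fixpoint, re-evaluating conditional guards as
# values become determined), any remaining simultaneous linear subsystem as
# a linear system, and remaining nonlinear subsystems by damped iteration.

uid_of <- function(inst_id, attr, tick) paste(inst_id, attr, tick, sep = "\r")

register_unknown <- function(reg, inst, attr, tick) {
  uid <- uid_of(inst$id, attr, tick)
  if (is.null(reg[[uid]]))
    assign(uid, list(inst = inst, attr = attr, tick = tick), envir = reg)
  as.name(uid)
}

# resolve a (possibly dotted) attribute path relative to an instance,
# honouring the component map of expanded quantified constraints
resolve_path <- function(inst, name, cmap) {
  segs <- strsplit(name, ".", fixed = TRUE)[[1]]
  base <- inst
  if (!is.null(cmap) && segs[1] %in% names(cmap)) {
    base <- cmap[[segs[1]]]
    segs <- segs[-1]
    if (!length(segs)) return(list(kind = "component", inst = base))
  }
  while (length(segs) > 1L) {
    a <- base$attrs[[segs[1]]]
    if (is.null(a) || a$kind != "component") return(NULL)
    base <- a$value
    segs <- segs[-1]
  }
  a <- base$attrs[[segs[1]]]
  if (is.null(a)) return(NULL)
  list(kind = a$kind, inst = base, attr = segs[1], a = a)
}

# ctx: list(inst, k, store, reg, cmap, params)
ground <- function(expr, ctx) {
  if (is.numeric(expr) || is.character(expr) || is.logical(expr)) return(expr)
  if (is.symbol(expr)) return(ground_symbol(as.character(expr), ctx))
  if (is.call(expr)) {
    head <- expr[[1]]
    hname <- if (is.symbol(head)) as.character(head) else ""
    if (hname == "prev") return(ground_prev(expr, ctx))
    if (hname == "nxt") return(ground_nxt(expr, ctx))
    out <- as.list(expr)
    for (i in seq_along(out)[-1]) out[[i]] <- ground(out[[i]], ctx)
    return(as.call(out))
  }
  expr
}

ground_symbol <- function(name, ctx) {
  if (name == "Time") return(ctx$k)
  if (name == "dt") return(ctx$store$grid$dt)
  if (!is.null(ctx$params) && name %in% names(ctx$params))
    return(ctx$params[[name]])
  res <- resolve_path(ctx$inst, name, ctx$cmap)
  if (is.null(res)) return(as.name(name))  # e.g. pi, package functions
  if (res$kind == "scalar") {
    if (res$a$known) return(res$a$value)
    return(register_unknown(ctx$reg, res$inst, res$attr, 0L))
  }
  if (res$kind == "series") {
    k <- ctx$k
    if (res$a$known[k]) return(res$a$values[[k]])
    return(register_unknown(ctx$reg, res$inst, res$attr, k))
  }
  tcob_abort("tcob_definition_error",
             sprintf("component '%s' used as a value", name))
}

series_ref <- function(expr, ctx, what) {
  arg <- expr[[2]]
  if (!is.symbol(arg))
    tcob_abort("tcob_definition_error",
               sprintf("%s() expects a series attribute reference", what))
  res <- resolve_path(ctx$inst, as.character(arg), ctx$cmap)
  if (is.null(res) || res$kind != "series")
    tcob_abort("tcob_definition_error",
               sprintf("%s() applied to '%s', which is not a series attribute",
                       what, as.character(arg)))
  res
}

ground_prev <- function(expr, ctx) {
  res <- series_ref(expr, ctx, "prev")
  j <- if (length(expr) >= 3L) as.integer(expr[[3]]) else 1L
  if (is.na(j) || j < 1L)
    tcob_abort("tcob_definition_error", "prev() offset must be a positive integer")
  tick <- ctx$k - j
  if (tick < 1L || !res$a$known[tick])
    tcob_abort("tcob_underdetermined_error",
               sprintf("past reference to %s.%s at tick %d is undetermined",
                       res$inst$id, res$attr, tick))
  res$a$values[[tick]]
}

ground_nxt <- function(expr, ctx) {
  if (is.call(expr[[2]]))
    tcob_abort("tcob_definition_error",
               "references more than one tick into the future are not supported")
  res <- series_ref(expr, ctx, "nxt")
  tick <- ctx$k + 1L
  if (tick <= length(res$a$known) && res$a$known[tick])
    return(res$a$values[[tick]])
  register_unknown(ctx$reg, res$inst, res$attr, tick)
}

collect_unknowns <- function(expr, reg) {
  out <- character()
  walk <- function(e) {
    if (is.symbol(e)) {
      nm <- as.character(e)
      if (!is.null(reg[[nm]])) out[[length(out) + 1L]] <<- nm
    } else if (is.call(e)) {
      for (a in as.list(e)[-1]) walk(a)
    }
  }
  walk(expr)
  unique(out)
}

ground_equation <- function(lhs, rhs, ctx, env, label) {
  gl <- ground(lhs, ctx)
  gr <- ground(rhs, ctx)
  list(lhs = gl, rhs = gr,
       unk = unique(c(collect_unknowns(gl, ctx$reg), collect_unknowns(gr, ctx$reg))),
       env = env, label = label, done = FALSE)
}

eq_eval_env <- function(eq, sol, extra = NULL) {
  e <- new.env(parent = eq$env)
  for (uid in eq$unk) {
    v <- sol[[uid]]
    if (!is.null(v)) assign(uid, v, envir = e)
  }
  if (!is.null(extra)) for (nm in names(extra)) assign(nm, extra[[nm]], envir = e)
  e
}

eq_sides <- function(eq, sol, extra = NULL) {
  e <- eq_eval_env(eq, sol, extra)
  list(l = eval(eq$lhs, e), r = eval(eq$rhs, e))
}

eq_residual <- function(eq, sol, extra = NULL) {
  s <- eq_sides(eq, sol, extra)
  if (is.character(s$l) || is.character(s$r) || is.logical(s$l) || is.logical(s$r))
    return(if (identical(s$l, s$r)) 0 else Inf)
  s$l - s$r
}

free_unknowns <- function(eq, sol) eq$unk[vapply(eq$unk, function(u) is.null(sol[[u]]), TRUE)]

# guard evaluation with short-circuiting && / || so that past references in
# a branch are only grounded when the branch is reached
eval_guard <- function(guard, ctx, sol) {
  if (is.call(guard)) {
    h <- if (is.symbol(guard[[1]])) as.character(guard[[1]]) else ""
    if (h %in% c("&&", "&")) {
      l <- eval_guard(guard[[2]], ctx, sol)
      if (isFALSE(l)) return(FALSE)
      r <- eval_guard(guard[[3]], ctx, sol)
      if (isFALSE(r)) return(FALSE)
      if (is.na(l) || is.na(r)) return(NA)
      return(TRUE)
    }
    if (h %in% c("||", "|")) {
      l <- eval_guard(guard[[2]], ctx, sol)
      if (isTRUE(l)) return(TRUE)
      r <- eval_guard(guard[[3]], ctx, sol)
      if (isTRUE(r)) return(TRUE)
      if (is.na(l) || is.na(r)) return(NA)
      return(FALSE)
    }
    if (h == "!") {
      v <- eval_guard(guard[[2]], ctx, sol)
      return(if (is.na(v)) NA else !v)
    }
    if (h == "(") return(eval_guard(guard[[2]], ctx, sol))
  }
  g <- ground(guard, ctx)
  unk <- collect_unknowns(g, ctx$reg)
  pending <- unk[vapply(unk, function(u) is.null(sol[[u]]), TRUE)]
  if (length(pending)) return(NA)
  e <- new.env(parent = ctx$guard_env %||% baseenv())
  for (u in unk) assign(u, sol[[u]], envir = e)
  v <- eval(g, e)
  if (!is.logical(v) || length(v) != 1L || is.na(v))
    tcob_abort("tcob_definition_error", "a guard must evaluate to TRUE or FALSE")
  v
}

solve_single <- function(eq, uid, sol, tol) {
  # assignment fast path (works for symbolic/character values too)
  if (is.symbol(eq$lhs) && as.character(eq$lhs) == uid) {
    if (!length(setdiff(collect_unknowns_sym(eq$rhs, eq$unk), ls_solved(sol))))
      return(list(status = "solved", value = eval(eq$rhs, eq_eval_env(eq, sol))))
  }
  if (is.symbol(eq$rhs) && as.character(eq$rhs) == uid) {
    if (!length(setdiff(collect_unknowns_sym(eq$lhs, eq$unk), ls_solved(sol))))
      return(list(status = "solved", value = eval(eq$lhs, eq_eval_env(eq, sol))))
  }
  f <- function(x) {
    v <- eq_residual(eq, sol, extra = setNames(list(x), uid))
    if (!is.numeric(v)) NaN else v
  }
  r0 <- suppressWarnings(f(0)); r1 <- suppressWarnings(f(1)); r2 <- suppressWarnings(f(2))
  if (all(is.finite(c(r0, r1, r2)))) {
    curv <- r2 - 2 * r1 + r0
    scale <- max(1, abs(r0), abs(r1))
    if (abs(curv) <= 1e-8 * scale) {
      slope <- r1 - r0
      if (abs(slope) < 1e-300) {
        if (abs(r0) <= tol) return(list(status = "vacuous"))
        return(list(status = "inconsistent", residual = r0))
      }
      x <- -r0 / slope
      if (is.finite(x) && abs(f(x)) <= max(tol, 1e-12 * max(1, abs(x))))
        return(list(status = "solved", value = x))
    }
  }
  # damped 1-D iteration for a nonlinear single-unknown equation
  x <- if (is.finite(r1)) 1 else if (is.finite(r0)) 0 else -1
  for (iter in seq_len(100L)) {
    fx <- suppressWarnings(f(x))
    if (is.finite(fx) && abs(fx) <= tol)
      return(list(status = "solved", value = x))
    h <- 1e-6 * max(1, abs(x))
    d <- (suppressWarnings(f(x + h)) - fx) / h
    if (!is.finite(d) || d == 0) {
      x <- x + max(1, abs(x))
      next
    }
    x <- x - 0.5 * fx / d
    if (!is.finite(x)) x <- 0
  }
  tcob_abort("tcob_convergence_error",
             sprintf("no convergence after 100 iterations solving '%s'", eq$label),
             list(iterations = 100L))
}

ls_solved <- function(sol) ls(sol, all.names = TRUE)

collect_unknowns_sym <- function(expr, unk) {
  out <- character()
  walk <- function(e) {
    if (is.symbol(e)) {
      nm <- as.character(e)
      if (nm %in% unk) out[[length(out) + 1L]] <<- nm
    } else if (is.call(e)) for (a in as.list(e)[-1]) walk(a)
  }
  walk(expr)
  unique(out)
}

solve_multi <- function(eqs, unks, sol, tol) {
  n <- length(unks)
  res_at <- function(x) {
    extra <- setNames(as.list(x), unks)
    vapply(eqs, function(eq) {
      v <- eq_residual(eq, sol, extra = extra)
      if (!is.numeric(v)) NaN else v
    }, 0)
  }
  x0 <- rep(0, n)
  r0 <- suppressWarnings(res_at(x0))
  if (!all(is.finite(r0))) { x0 <- rep(1, n); r0 <- suppressWarnings(res_at(x0)) }
  if (!all(is.finite(r0)))
    tcob_abort("tcob_underdetermined_error",
               sprintf("cannot evaluate the subsystem containing '%s'", eqs[[1]]$label))
  A <- matrix(0, length(eqs), n)
  for (j in seq_len(n)) {
    xj <- x0; xj[j] <- xj[j] + 1
    A[, j] <- suppressWarnings(res_at(xj)) - r0
  }
  xt <- x0 + 0.5 + 0.1 * seq_len(n)
  lin_err <- max(abs(suppressWarnings(res_at(xt)) - (r0 + A %*% (xt - x0))))
  scale <- max(1, abs(r0), abs(A))
  if (is.finite(lin_err) && lin_err <= 1e-7 * scale) {
    qrA <- qr(A)
    if (qrA$rank < n)
      tcob_abort("tcob_underdetermined_error",
                 sprintf("underdetermined linear subsystem (%d unknowns, rank %d): %s",
                         n, qrA$rank,
                         paste(vapply(eqs, `[[`, "", "label"), collapse = ", ")))
    x <- qr.coef(qrA, -(r0 - A %*% x0))
    rfin <- suppressWarnings(res_at(x))
    if (max(abs(rfin)) > max(tol, 1e-9 * scale))
      tcob_abort("tcob_inconsistency_error",
                 sprintf("inconsistent constraint set: %s",
                         paste(vapply(eqs, `[[`, "", "label"), collapse = ", ")))
    return(setNames(as.list(as.numeric(x)), unks))
  }
  # damped iteration for a simultaneous nonlinear subsystem
  x <- x0
  for (iter in seq_len(100L)) {
    r <- suppressWarnings(res_at(x))
    if (all(is.finite(r)) && max(abs(r)) <= tol)
      return(setNames(as.list(as.numeric(x)), unks))
    J <- matrix(0, length(eqs), n)
    for (j in seq_len(n)) {
      h <- 1e-6 * max(1, abs(x[j]))
      xj <- x; xj[j] <- xj[j] + h
      J[, j] <- (suppressWarnings(res_at(xj)) - r) / h
    }
    step <- tryCatch(qr.coef(qr(J), -r), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step)))
      tcob_abort("tcob_convergence_error",
                 sprintf("singular Jacobian after %d iterations in a nonlinear subsystem", iter),
                 list(iterations = iter))
    x <- x + 0.5 * step
  }
  tcob_abort("tcob_convergence_error",
             "no convergence after 100 iterations in a nonlinear subsystem",
             list(iterations = 100L))
}

# eqs: grounded equations; conds: list of list(cn=constraint, ctx=ctx)
# ground_consequent(cnd, sol) -> equation
solve_equation_set <- function(eqs, conds, tol, ground_consequent,
                               sol = new.env(parent = emptyenv())) {
  repeat {
    progress <- FALSE
    repeat {
      inner <- FALSE
      # conditional guards on determined values
      if (length(conds)) {
        keep <- rep(TRUE, length(conds))
        for (i in seq_along(conds)) {
          g <- eval_guard(conds[[i]]$cn$guard, conds[[i]]$ctx, sol)
          if (is.na(g)) next
          keep[i] <- FALSE
          inner <- TRUE
          if (isTRUE(g)) eqs[[length(eqs) + 1L]] <- ground_consequent(conds[[i]], sol)
        }
        conds <- conds[keep]
      }
      # local propagation: single-unknown equations first
      for (i in seq_along(eqs)) {
        eq <- eqs[[i]]
        if (eq$done) next
        free <- free_unknowns(eq, sol)
        if (length(free) == 0L) {
          r <- eq_residual(eq, sol)
          if (!is.finite(r) || abs(r) > tol)
            tcob_abort("tcob_inconsistency_error",
                       sprintf("constraint '%s' violated (residual %g)", eq$label, r))
          eqs[[i]]$done <- TRUE
          inner <- TRUE
        } else if (length(free) == 1L) {
          ans <- solve_single(eq, free, sol, tol)
          if (ans$status == "solved") {
            assign(free, ans$value, envir = sol)
          } else if (ans$status == "inconsistent") {
            tcob_abort("tcob_inconsistency_error",
                       sprintf("constraint '%s' violated (residual %g)",
                               eq$label, ans$residual))
          }
          eqs[[i]]$done <- TRUE
          inner <- TRUE
        }
      }
      if (inner) progress <- TRUE else break
    }
    # simultaneous subsystems among the remaining equations
    open <- which(!vapply(eqs, `[[`, TRUE, "done"))
    if (!length(open)) break
    groups <- group_equations(eqs[open], sol)
    acted <- FALSE
    for (grp in groups) {
      idx <- open[grp$eqs]
      ans <- solve_multi(eqs[idx], grp$unks, sol, tol)
      for (nm in names(ans)) assign(nm, ans[[nm]], envir = sol)
      for (i in idx) eqs[[i]]$done <- TRUE
      acted <- TRUE
    }
    if (acted) progress <- TRUE
    if (!progress) break
  }
  if (length(conds)) {
    unres <- unique(unlist(lapply(conds, function(cnd) {
      g <- tryCatch(ground(cnd$cn$guard, cnd$ctx), error = function(e) NULL)
      if (is.null(g)) return(character())
      setdiff(collect_unknowns(g, cnd$ctx$reg), ls_solved(sol))
    })))
    tcob_abort("tcob_underdetermined_error",
               sprintf("conditional guard(s) remain undetermined; unknown: %s",
                       paste(pretty_uids(unres), collapse = ", ")))
  }
  open <- which(!vapply(eqs, `[[`, TRUE, "done"))
  if (length(open)) {
    unres <- unique(unlist(lapply(eqs[open], free_unknowns, sol = sol)))
    tcob_abort("tcob_underdetermined_error",
               sprintf("underdetermined unknowns: %s",
                       paste(pretty_uids(unres), collapse = ", ")))
  }
  sol
}

pretty_uids <- function(uids) {
  vapply(uids, function(u) {
    p <- strsplit(u, "\r", fixed = TRUE)[[1]]
    if (length(p) == 3L) sprintf("%s.%s@%s", p[1], p[2], p[3]) else u
  }, "")
}

# connected components of the bipartite equation/unknown graph
group_equations <- function(eqs, sol) {
  frees <- lapply(eqs, free_unknowns, sol = sol)
  n <- length(eqs)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  by_unk <- list()
  for (i in seq_len(n)) for (u in frees[[i]]) {
    j <- by_unk[[u]]
    if (is.null(j)) by_unk[[u]] <- i
    else { ri <- find(i); rj <- find(j); if (ri != rj) parent[ri] <- rj }
  }
  roots <- vapply(seq_len(n), find, 1L)
  lapply(unique(roots), function(r) {
    idx <- which(roots == r)
    list(eqs = idx, unks = unique(unlist(frees[idx])))
  })
}

commit_solution <- function(store, sol, reg) {
  for (uid in ls_solved(sol)) {
    info <- reg[[uid]]
    if (is.null(info)) next
    if (identical(info$tick, 0L)) {  # scalar
      a <- info$inst$attrs[[info$attr]]
      if (a$known) {
        if (!isTRUE(all.equal(a$value, sol[[uid]], tolerance = store$tolerance)))
          tcob_abort("tcob_inconsistency_error",
                     sprintf("scalar %s.%s already bound", info$inst$id, info$attr))
      } else {
        info$inst$attrs[[info$attr]]$value <- sol[[uid]]
        info$inst$attrs[[info$attr]]$known <- TRUE
      }
    } else {
      set_series_value(store, info$inst, info$attr, info$tick, sol[[uid]])
    }
  }
  invisible(NULL)
}

#' Solve a set of algebraic relations
#'
#' Standalone access to the engine's solver: equations are solved by local
#' propagation (single-unknown equations first, to fixpoint), any remaining
#' simultaneous linear subsystem as a linear system, and remaining nonlinear
#' subsystems by damped iteration (tolerance `1e-9`, at most 100
#' iterations).  Relations are non-directional: any variable of a relation
#' can be the solved-for unknown.
#'
#' @param equations list of equations written as `quote(lhs == rhs)` or as
#'   two-sided formulas `lhs ~ rhs`.
#' @param knowns named list of known values.
#' @param tolerance residual bound.
#' @param env environment for functions used in the equations.
#' @return named list with the values of all solved unknowns.
#' @examples
#' solve_system(list(quote(V == I * R)), knowns = list(V = 10, R = 5))  # I = 2
#' solve_system(list(x + y ~ 3, x - y ~ 1))                             # x = 2, y = 1
#' @export
solve_system <- function(equations, knowns = list(), tolerance = 1e-9,
                         env = parent.frame()) {
  eqs <- list()
  reg <- new.env(parent = emptyenv())
  subst <- function(e) {
    if (is.symbol(e)) {
      nm <- as.character(e)
      if (nm %in% names(knowns)) return(knowns[[nm]])
      if (nm %in% c("pi", "TRUE", "FALSE", "T", "F")) return(e)
      if (is.null(reg[[nm]])) assign(nm, list(free = TRUE), envir = reg)
      return(e)
    }
    if (is.call(e)) {
      for (i in seq_along(e)[-1]) e[[i]] <- subst(e[[i]])
    }
    e
  }
  for (i in seq_along(equations)) {
    eq <- equations[[i]]
    if (inherits(eq, "formula")) {
      if (length(eq) != 3L)
        tcob_abort("tcob_definition_error", "equations given as formulas must be two-sided")
      lhs <- eq[[2]]; rhs <- eq[[3]]
    } else if (is.call(eq) && identical(eq[[1]], as.name("=="))) {
      lhs <- eq[[2]]; rhs <- eq[[3]]
    } else {
      tcob_abort("tcob_definition_error",
                 "each equation must be `lhs ~ rhs` or quote(lhs == rhs)")
    }
    gl <- subst(lhs); gr <- subst(rhs)
    eqs[[i]] <- list(lhs = gl, rhs = gr,
                     unk = unique(c(collect_unknowns(gl, reg),
                                    collect_unknowns(gr, reg))),
                     env = env, label = sprintf("equation %d", i), done = FALSE)
  }
  sol <- solve_equation_set(eqs, list(), tolerance, NULL)
  out <- as.list(sol)
  out[order(names(out))]
}
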