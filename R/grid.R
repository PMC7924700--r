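#' Discrete simulation time grid
#'
#' A temporal constrained object program advances a built-in tick counter
#' `Time`, starting at 1 and incremented by one unit per step.  Model time in
#' milliseconds is obtained by scaling the tick with `dt` (e.g. a tick of 100
#' with `dt = 0.01` is 1 ms).
#'
#' @param t_end final tick (positive integer).
#' @param dt milliseconds per tick; must be positive.
#' @param t_start first tick, 1 by default.
#' @return an object of class `tcob_grid`.
#' @examples
#' g <- time_grid(t_end = 100, dt = 0.01)
#' n_ticks(g)
#' @export
time_grid <- function(t_end, dt = 0.01, t_start = 1L) {
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    tcob_abort("tcob_parameter_error", "dt must be a single positive number")
  t_end <- as.integer(t_end)
  t_start <- as.integer(t_start)
  if (is.na(t_end) || is.na(t_start) || t_end < t_start || t_start < 1L)
    tcob_abort("tcob_parameter_error", "need 1 <= t_start <= t_end")
  structure(list(t_start = t_start, t_end = t_end, dt = dt),
            class = "tcob_grid")
}

#' @rdname time_grid
#' @param grid a `tcob_grid`.
#' @export
n_ticks <- function(grid) grid$t_end - grid$t_start + 1L

#' @export
print.tcob_grid <- function(x, ...) {
  cat(sprintf("<tcob_grid> ticks %d..%d, dt = %g ms (%g ms total)\n",
              x$t_start, x$t_end, x$dt, x$t_end * x$dt))
  invisible(x)
}
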