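#' Powell's direction-set minimisation
#'
#' Derivative-free minimiser in the modified-Powell family: cycles of line
#' minimisations along a direction set, replacing after each cycle the
#' direction of largest decrease by the cycle's net displacement when
#' Powell's quadratic criterion allows it. Line minimisations use Brent's
#' method ([stats::optimize()]) on an adaptively expanded bracket.
#'
#' @param par numeric start vector.
#' @param fn objective returning a finite scalar (may return large penalty
#'   values for infeasible points).
#' @param scale initial line-search half-widths, one per parameter.
#' @param tol relative convergence tolerance on the objective.
#' @param maxit maximum number of direction-set cycles.
#' @return list with `par`, `value`, `counts` (function evaluations),
#'   `convergence` (0 = converged, 1 = cycle limit).
#' @export
powell <- function(par, fn, scale = rep(1, length(par)), tol = 1e-8,
                   maxit = 200) {
  n <- length(par)
  dirs <- diag(n)
  evals <- 0L
  f <- function(x) { evals <<- evals + 1L; fn(x) }
  line_min <- function(x, d, width) {
    g <- function(alpha) f(x + alpha * d)
    lo <- -width; hi <- width
    for (k in 1:12) {
      opt <- stats::optimize(g, c(lo, hi), tol = tol^0.5 * width)
      # expand the bracket while the minimum sits at an edge
      if (opt$minimum > lo + 0.05 * (hi - lo) &&
          opt$minimum < hi - 0.05 * (hi - lo)) break
      lo <- 2 * lo; hi <- 2 * hi
    }
    list(x = x + opt$minimum * d, value = opt$objective,
         step = abs(opt$minimum))
  }
  x <- par
  fx <- f(x)
  for (iter in seq_len(maxit)) {
    x0 <- x; f0 <- fx
    biggest <- 0; ibig <- 1L
    for (i in seq_len(n)) {
      w <- sqrt(sum((dirs[, i] * scale)^2))
      res <- line_min(x, dirs[, i], w)
      if (fx - res$value > biggest) { biggest <- fx - res$value; ibig <- i }
      x <- res$x; fx <- res$value
    }
    if (2 * abs(f0 - fx) <= tol * (abs(f0) + abs(fx) + 1e-12)) {
      return(list(par = x, value = fx, counts = evals, convergence = 0L))
    }
    # Powell's criterion for replacing a direction with the net displacement
    xe <- 2 * x - x0
    fe <- f(xe)
    if (fe < f0) {
      t_crit <- 2 * (f0 - 2 * fx + fe) * (f0 - fx - biggest)^2 -
        biggest * (f0 - fe)^2
      if (t_crit < 0) {
        d_new <- x - x0
        nrm <- sqrt(sum(d_new^2))
        if (nrm > 0) {
          res <- line_min(x, d_new / nrm, max(nrm, min(scale)))
          x <- res$x; fx <- res$value
          dirs[, ibig] <- d_new / nrm
        }
      }
    }
  }
  list(par = x, value = fx, counts = evals, convergence = 1L)
}
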