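#' Build a C1 spline table for a tabulated angle or dihedral term
#'
#' Statistics-derived local terms (Boltzmann-inversion angle and dihedral
#' potentials) reach the engine as tables of energies on a uniform grid of
#' angles.  The table is interpolated by a natural cubic spline (periodic
#' closure for dihedral tables), which reproduces the node values exactly and
#' provides continuous first derivatives for the forces.
#'
#' @param x Uniform grid of abscissae, rad, strictly increasing.
#' @param E Energies at the nodes, kcal/mol.
#' @param periodic Logical: close the spline periodically (dihedral tables,
#'   where the grid must span one period so that `E` matches at both ends).
#' @return Object of class `cg_spline_table`.
#' @examples
#' th <- seq(0.1, pi - 0.1, length.out = 90)
#' tab <- spline_table(th, 20 * (th - 1.9)^2)
#' spline_table_eval(tab, 1.9)$E
#' @export
spline_table <- function(x, E, periodic = FALSE) {
  stopifnot(length(x) == length(E), length(x) >= 4, all(diff(x) > 0))
  dx <- diff(x)
  stopifnot(max(abs(dx - dx[1])) < 1e-8 * dx[1])
  if (periodic && abs(E[1] - E[length(E)]) > 1e-8) {
    stop("periodic table must repeat its first value at the last node")
  }
  method <- if (periodic) "periodic" else "natural"
  fun <- stats::splinefun(x, E, method = method)
  structure(list(x = x, E = E, periodic = periodic, fun = fun,
                 xmin = x[1], xmax = x[length(x)]),
            class = "cg_spline_table")
}

#' Evaluate a spline table
#'
#' Periodic tables wrap the query into the grid period.  Non-periodic tables
#' clamp out-of-domain queries to the boundary (constant energy, zero force)
#' and count them, so a running simulation reports rather than aborts.
#'
#' @param tab A [spline_table()].
#' @param x Query angle(s), rad.
#' @return List with `E`, `dE` and `n_clamped`.
#' @export
spline_table_eval <- function(tab, x) {
  stopifnot(inherits(tab, "cg_spline_table"))
  n_clamped <- 0L
  if (tab$periodic) {
    period <- tab$xmax - tab$xmin
    x <- tab$xmin + (x - tab$xmin) %% period
  } else {
    below <- x < tab$xmin; above <- x > tab$xmax
    n_clamped <- sum(below) + sum(above)
    x <- pmin(pmax(x, tab$xmin), tab$xmax)
    if (n_clamped > 0) {
      out <- list(E = tab$fun(x), dE = tab$fun(x, deriv = 1))
      out$dE[below | above] <- 0
      out$n_clamped <- n_clamped
      return(out)
    }
  }
  list(E = tab$fun(x), dE = tab$fun(x, deriv = 1), n_clamped = n_clamped)
}

# Dense resampling of a spline table onto a uniform grid, used to hand
# tabulated terms to the compiled engine (which interpolates the dense grid
# with cubic Hermite segments built from the spline's own derivatives).
.spline_table_pack <- function(tab, n = 721L) {
  xs <- seq(tab$xmin, tab$xmax, length.out = n)
  list(x0 = tab$xmin, dx = xs[2] - xs[1], periodic = as.integer(tab$periodic),
       E = tab$fun(xs), dE = tab$fun(xs, deriv = 1))
}
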