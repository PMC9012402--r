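#' Bond stretch energy and derivative
#'
#' Evaluates the harmonic bond term \eqn{k^{(1)}(b-b_0)^2} or the
#' quadratic-plus-quartic form \eqn{k^{(2)}(b-b_0)^2 + k^{(3)}(b-b_0)^4}
#' used by the three-site DNA model.
#'
#' @param kind `"harmonic"` or `"quartic"`.
#' @param params For `"harmonic"`: list/vector with `k` (kcal/mol/A^2) and
#'   `b0` (A).  For `"quartic"`: `k2`, `k3` and `b0`.
#' @param b Bond length(s), A.  Must be positive.
#' @return List with `E` (kcal/mol) and `dE` (= dE/db, kcal/mol/A),
#'   vectorised over `b`.
#' @examples
#' bond_energy_force("harmonic", list(k = 100, b0 = 3.8), 3.9)
#' @export
bond_energy_force <- function(kind = c("harmonic", "quartic"), params, b) {
  kind <- match.arg(kind)
  stopifnot(all(b > 0))
  db <- b - params$b0
  if (kind == "harmonic") {
    list(E = params$k * db^2, dE = 2 * params$k * db)
  } else {
    list(E = params$k2 * db^2 + params$k3 * db^4,
         dE = 2 * params$k2 * db + 4 * params$k3 * db^3)
  }
}

#' Bond angle energy and derivative
#'
#' Harmonic form \eqn{k_a(\theta-\theta_0)^2}, or a tabulated
#' (statistics-derived) term evaluated through a C1 spline table built with
#' [spline_table()].  Queries outside a non-periodic table domain are clamped
#' to the boundary value; the number of clamps is returned so long runs can
#' report them without aborting.
#'
#' @param kind `"harmonic"` or `"tabulated"`.
#' @param params `"harmonic"`: `k` (kcal/mol/rad^2), `theta0` (rad);
#'   `"tabulated"`: a `cg_spline_table`.
#' @param theta Angle(s) in radians, in (0, pi).
#' @return List with `E`, `dE` (per rad) and `n_clamped`.
#' @export
angle_energy_force <- function(kind = c("harmonic", "tabulated"), params, theta) {
  kind <- match.arg(kind)
  if (kind == "harmonic") {
    dth <- theta - params$theta0
    list(E = params$k * dth^2, dE = 2 * params$k * dth, n_clamped = 0L)
  } else {
    spline_table_eval(params, theta)
  }
}

#' Dihedral torsion energy and derivative
#'
#' Periodic proper form \eqn{\sum_n k_n [1 + \cos(n(\phi-\phi_0))]}, a
#' Gaussian well \eqn{-\epsilon_\phi \exp(-\Delta\phi^2 / 2\sigma_\phi^2)},
#' or a tabulated periodic spline.  The angle difference is always wrapped
#' into (-pi, pi] before evaluation so the well Gaussian behaves periodically.
#'
#' @param kind `"periodic"`, `"gaussian"` or `"tabulated"`.
#' @param params `"periodic"`: vectors `k`, `n`, `phi0` (one entry per
#'   harmonic); `"gaussian"`: `eps`, `sigma`, `phi0`; `"tabulated"`: a
#'   periodic `cg_spline_table`.
#' @param phi Dihedral angle(s), rad.
#' @return List with `E` and `dE` (per rad).
#' @export
dihedral_energy_force <- function(kind = c("periodic", "gaussian", "tabulated"),
                                  params, phi) {
  kind <- match.arg(kind)
  if (kind == "periodic") {
    E <- 0; dE <- 0
    for (i in seq_along(params$k)) {
      d <- wrap_angle(phi - params$phi0[i])
      E <- E + params$k[i] * (1 + cos(params$n[i] * d))
      dE <- dE - params$k[i] * params$n[i] * sin(params$n[i] * d)
    }
    list(E = E, dE = dE)
  } else if (kind == "gaussian") {
    stopifnot(params$sigma > 0)
    d <- wrap_angle(phi - params$phi0)
    g <- exp(-d^2 / (2 * params$sigma^2))
    list(E = -params$eps * g, dE = params$eps * g * d / params$sigma^2)
  } else {
    out <- spline_table_eval(params, wrap_angle(phi))
    list(E = out$E, dE = out$dE)
  }
}

#' Pairwise nonbonded energy and radial derivative
#'
#' All pairwise radial forms used by the residue-level models:
#' \describe{
#'   \item{go1210}{native-contact 12-10: \eqn{\epsilon[5(\sigma/r)^{12} -
#'     6(\sigma/r)^{10}]}; minimum \eqn{-\epsilon} at \eqn{r=\sigma}.}
#'   \item{lj126}{plain 12-6 Lennard-Jones \eqn{4\epsilon[(\sigma/r)^{12} -
#'     (\sigma/r)^6]}.}
#'   \item{exv_lj_trunc}{LJ (with coefficient-2 sixth power) truncated and
#'     shifted at its minimum \eqn{r=\sigma}: purely repulsive, zero beyond.}
#'   \item{exv12}{single 12th-power repulsion \eqn{\epsilon(\sigma/r)^{12} +
#'     \epsilon'} cut at \eqn{2\sigma} with \eqn{\epsilon' = -2^{-12}\epsilon}
#'     so the energy is continuous (and zero) at the cutoff.}
#'   \item{gaussian}{attractive well \eqn{-\epsilon\exp(-(r-r_0)^2/2w^2)}.}
#'   \item{morse_rep / morse_attr}{repulsive/attractive split of the Morse
#'     potential about its minimum \eqn{r_0}; the repulsive part vanishes for
#'     \eqn{r \ge r_0}, the attractive part is the constant \eqn{-\epsilon}
#'     below \eqn{r_0}.}
#'   \item{ashbaugh_hatch}{hydropathy-scaled LJ: below \eqn{2^{1/6}\sigma}
#'     it is \eqn{E_{LJ} + (1-\lambda)\epsilon}, above it \eqn{\lambda
#'     E_{LJ}}; continuous at the switch.}
#' }
#'
#' @param kind One of the forms above.
#' @param params Named list; fields per kind: `eps`, `sigma` (go1210, lj126,
#'   exv_lj_trunc, exv12), `eps`, `r0`, `w` (gaussian), `eps`, `r0`, `alpha`
#'   (morse_*), `eps`, `sigma`, `lambda` (ashbaugh_hatch).
#' @param r Distance(s), A, positive.
#' @return List with `E` (kcal/mol) and `dE` (= dE/dr, kcal/mol/A).
#' @examples
#' pair_energy_force("go1210", list(eps = 1, sigma = 5), 5)    # E = -1, F = 0
#' pair_energy_force("exv12", list(eps = 1, sigma = 4), 8)     # E = 0
#' @export
pair_energy_force <- function(kind = c("go1210", "lj126", "exv_lj_trunc",
                                       "exv12", "gaussian", "morse_rep",
                                       "morse_attr", "ashbaugh_hatch"),
                              params, r) {
  kind <- match.arg(kind)
  stopifnot(all(r > 0))
  switch(kind,
    go1210 = {
      s <- params$sigma / r
      E <- params$eps * (5 * s^12 - 6 * s^10)
      dE <- params$eps * (-60 * s^12 + 60 * s^10) / r
      list(E = E, dE = dE)
    },
    lj126 = .lj126(params$eps, params$sigma, r),
    exv_lj_trunc = {
      s <- params$sigma / r
      inside <- r < params$sigma
      E <- ifelse(inside, params$eps * (s^12 - 2 * s^6) + params$eps, 0)
      dE <- ifelse(inside, params$eps * (-12 * s^12 + 12 * s^6) / r, 0)
      list(E = E, dE = dE)
    },
    exv12 = {
      rc <- 2 * params$sigma
      s <- params$sigma / r
      inside <- r < rc
      E <- ifelse(inside, params$eps * s^12 - 2^-12 * params$eps, 0)
      dE <- ifelse(inside, -12 * params$eps * s^12 / r, 0)
      list(E = E, dE = dE)
    },
    gaussian = {
      stopifnot(params$w > 0)
      d <- r - params$r0
      g <- exp(-d^2 / (2 * params$w^2))
      list(E = -params$eps * g, dE = params$eps * g * d / params$w^2)
    },
    morse_rep = {
      x <- exp(-params$alpha * (r - params$r0))
      inside <- r < params$r0
      E <- ifelse(inside, params$eps * (1 - x)^2, 0)
      dE <- ifelse(inside, 2 * params$eps * params$alpha * (1 - x) * x, 0)
      list(E = E, dE = dE)
    },
    morse_attr = {
      x <- exp(-params$alpha * (r - params$r0))
      inside <- r < params$r0
      E <- ifelse(inside, -params$eps, params$eps * (1 - x)^2 - params$eps)
      dE <- ifelse(inside, 0, 2 * params$eps * params$alpha * (1 - x) * x)
      list(E = E, dE = dE)
    },
    ashbaugh_hatch = {
      lj <- .lj126(params$eps, params$sigma, r)
      sw <- 2^(1 / 6) * params$sigma
      below <- r <= sw
      E <- ifelse(below, lj$E + (1 - params$lambda) * params$eps,
                  params$lambda * lj$E)
      dE <- ifelse(below, lj$dE, params$lambda * lj$dE)
      list(E = E, dE = dE)
    })
}

.lj126 <- function(eps, sigma, r) {
  s6 <- (sigma / r)^6
  list(E = 4 * eps * (s6^2 - s6),
       dE = 4 * eps * (-12 * s6^2 + 6 * s6) / r)
}

#' Angle-difference modulating function
#'
#' The C1 gate used by all orientation-dependent terms (base stacking and
#' pairing, cross stacking, PWM-based recognition, backbone hydrogen bonds):
#' 1 for \eqn{|\Delta\theta| < \gamma}, \eqn{1 - \cos^2(\pi\Delta\theta /
#' 2\gamma)} on \eqn{\gamma \le |\Delta\theta| \le 2\gamma}, and 0 beyond
#' \eqn{2\gamma}.
#'
#' @param dtheta Angle difference(s) from the reference, rad.
#' @param gamma Tuning half-width, rad, positive.
#' @return List with `f` in \[0, 1\] and `df` (= df/d(dtheta)).
#' @export
modulator <- function(dtheta, gamma) {
  stopifnot(gamma > 0)
  a <- abs(dtheta)
  f <- ifelse(a < gamma, 1,
       ifelse(a <= 2 * gamma, 1 - cos(pi * dtheta / (2 * gamma))^2, 0))
  mid <- a >= gamma & a <= 2 * gamma
  df <- ifelse(mid,
               (pi / (2 * gamma)) * sin(pi * dtheta / gamma),
               0)
  list(f = f, df = df)
}

#' Largest reduced distance at which the 12-6 LJ magnitude equals a tolerance
#'
#' Solves \eqn{|4\epsilon[(\sigma/r)^{12} - (\sigma/r)^6]| =
#' \mathrm{tol}\cdot\epsilon} for its largest root in \eqn{r/\sigma} by
#' bracketing and bisection.  Used to derive the distance at which a
#' hydropathy-model pair interaction can be safely truncated.
#'
#' @param tolerance Fraction of the well depth, in (0, 1).
#' @param tol_root Bisection convergence tolerance on r/sigma.
#' @return The reduced distance r/sigma (dimensionless).
#' @examples
#' lj_cutoff_ratio(1e-4)  # ~ 5.849
#' @export
lj_cutoff_ratio <- function(tolerance, tol_root = 1e-9) {
  stopifnot(tolerance > 0, tolerance < 1)
  # beyond the minimum |E| decays monotonically; bracket the largest root
  f <- function(x) abs(4 * ((1 / x)^12 - (1 / x)^6)) - tolerance
  lo <- 2^(1 / 6)           # |E| = 1 at the minimum
  hi <- 2^(1 / 6)
  while (f(hi) > 0) hi <- hi * 2
  while (hi - lo > tol_root) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Wrap an angle into (-pi, pi]
#' @param x Angle(s), rad.
#' @return Wrapped angle(s).
#' @export
wrap_angle <- function(x) {
  y <- (x + pi) %% (2 * pi)
  # %% maps exact multiples to 0; keep pi itself at +pi
  ifelse(y == 0, pi, y - pi)
}
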