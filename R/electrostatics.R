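#' Relative permittivity of salt water
#'
#' Empirical temperature and salt dependence used by the screened
#' electroststic term: \eqn{\epsilon_r = e(T)\,a(C)} with
#' \eqn{e(T) = 249.4 - 0.788T + 7.20\times10^{-4}T^2} and
#' \eqn{a(C) = 1 - 0.2551C + 5.151\times10^{-2}C^2 - 6.889\times10^{-3}C^3}.
#'
#' @param T_K Temperature, K.
#' @param C_M Salt molarity, mol/L.
#' @return Relative permittivity (dimensionless).
#' @examples
#' permittivity(300, 0)     # 77.8
#' permittivity(300, 0.15)
#' @export
permittivity <- function(T_K, C_M = 0) {
  stopifnot(all(T_K > 0), all(C_M >= 0))
  eT <- 249.4 - 0.788 * T_K + 7.20e-4 * T_K^2
  aC <- 1 - 0.2551 * C_M + 5.151e-2 * C_M^2 - 6.889e-3 * C_M^3
  eT * aC
}

#' Electrostatic environment: permittivity and Debye screening length
#'
#' Derives the relative permittivity \eqn{\epsilon_r(T, C)} and the Debye
#' length \eqn{\lambda_D = \sqrt{k_B T \epsilon_0 \epsilon_r / (2 N_A e_c^2
#' I)}} for a 1:1 salt.  Unless given explicitly, the ionic strength is
#' taken equal to the salt molarity.
#'
#' @param T_K Temperature, K.
#' @param C_M Salt molarity, M.
#' @param I_M Ionic strength, M; defaults to `C_M`.
#' @return Object of class `cg_ele_env`: list with `T_K`, `C_M`, `I_M`,
#'   `eps_r` and `lambda_D` (A).
#' @examples
#' env <- ele_environment(300, 0.15)
#' env$lambda_D   # ~ 7.9 A at physiological salt
#' @export
ele_environment <- function(T_K, C_M, I_M = C_M) {
  stopifnot(T_K > 0, C_M >= 0, I_M >= 0)
  eps_r <- permittivity(T_K, C_M)
  # lambda_D^2 = eps0 eps_r kB T / (2 NA ec^2 I).  In engine units, with the
  # Coulomb constant KC = ec^2/(4 pi eps0) in kcal*A/(mol*e^2) and I in
  # particles/A^3 (I[M] * NA / 1e27):
  lambda_D <- if (I_M > 0) {
    I_A3 <- I_M * 6.02214076e23 / 1e27        # ions/A^3
    sqrt(eps_r * .kB * T_K / (8 * pi * .KC * I_A3))
  } else {
    Inf
  }
  structure(list(T_K = T_K, C_M = C_M, I_M = I_M,
                 eps_r = eps_r, lambda_D = lambda_D),
            class = "cg_ele_env")
}

#' @export
print.cg_ele_env <- function(x, ...) {
  cat(sprintf(
    "Electrostatic environment: T = %g K, C = %g M (I = %g M)\n  eps_r = %.4f, lambda_D = %.4f A\n",
    x$T_K, x$C_M, x$I_M, x$eps_r, x$lambda_D))
  invisible(x)
}

#' Screened (Debye-Hueckel) pair electrostatics
#'
#' \eqn{E = K_C q_1 q_2 \exp(-r/\lambda_D) / (\epsilon_r r)} with \eqn{K_C}
#' the Coulomb constant in kcal A mol^-1 e^-2.
#'
#' @param q1,q2 Charges, e.
#' @param r Distance(s), A, positive.
#' @param env A [ele_environment()].
#' @return List with `E` (kcal/mol) and `dE` (= dE/dr).
#' @examples
#' env <- ele_environment(300, 0.15)
#' debye_huckel(1, -1, 10, env)
#' @export
debye_huckel <- function(q1, q2, r, env) {
  stopifnot(all(r > 0), inherits(env, "cg_ele_env"))
  pre <- .KC * q1 * q2 / env$eps_r
  ex <- exp(-r / env$lambda_D)
  E <- pre * ex / r
  dE <- -E * (1 / r + 1 / env$lambda_D)
  list(E = E, dE = dE)
}
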