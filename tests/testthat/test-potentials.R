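test_that("bond terms reproduce closed-form energies and derivatives", {
  h <- bond_energy_force("harmonic", list(k = 100, b0 = 3.8), 3.8)
  expect_equal(h$E, 0); expect_equal(h$dE, 0)
  h <- bond_energy_force("harmonic", list(k = 100, b0 = 3.8), 3.9)
  expect_equal(h$E, 1.0); expect_equal(h$dE, 20)
  q <- bond_energy_force("quartic", list(k2 = 1, k3 = 1, b0 = 3), 4)
  expect_equal(q$E, 2); expect_equal(q$dE, 6)
})

test_that("angle terms: harmonic arithmetic and spline-table fidelity", {
  a <- angle_energy_force("harmonic", list(k = 20, theta0 = 1.8), 1.9)
  expect_equal(a$E, 0.2, tolerance = 1e-12)
  # table sampled from a closed-form harmonic well on a 1-degree grid
  th <- seq(0.6, 3.0, by = pi / 180)
  tab <- spline_table(th, 15 * (th - 1.9)^2)
  qs <- seq(0.65, 2.95, length.out = 200)
  out <- angle_energy_force("tabulated", tab, qs)
  expect_lt(max(abs(out$E - 15 * (qs - 1.9)^2)), 1e-4)
  # node values are exact, derivative vanishes at the symmetric minimum
  expect_equal(spline_table_eval(tab, th[50])$E, 15 * (th[50] - 1.9)^2)
  expect_lt(abs(angle_energy_force("tabulated", tab, 1.9)$dE), 1e-3)
  # out-of-domain queries clamp and are counted, not fatal
  cl <- spline_table_eval(tab, c(0.1, 1.0, 3.1))
  expect_equal(cl$n_clamped, 2L)
  expect_equal(cl$dE[c(1, 3)], c(0, 0))
})

test_that("dihedral terms: periodic, Gaussian, and angle wrapping", {
  d <- dihedral_energy_force("periodic", list(k = 1, n = 1, phi0 = 0.7), 0.7)
  expect_equal(d$E, 2)
  g <- dihedral_energy_force("gaussian",
                             list(eps = 2, sigma = 0.4, phi0 = 0.5), 0.5)
  expect_equal(g$E, -2)
  g1 <- dihedral_energy_force("gaussian",
                              list(eps = 2, sigma = 0.4, phi0 = 0.5), 0.9)
  expect_equal(g1$E, -2 * exp(-0.5), tolerance = 1e-12)
  # wrap: phi - phi0 = pi + 0.1 is the same geometry as -(pi - 0.1)
  ga <- dihedral_energy_force("gaussian",
                              list(eps = 2, sigma = 0.8, phi0 = 0), pi + 0.1)
  gb <- dihedral_energy_force("gaussian",
                              list(eps = 2, sigma = 0.8, phi0 = 0),
                              -(pi - 0.1))
  expect_equal(ga$E, gb$E, tolerance = 1e-12)
})

test_that("pair terms hit their boundary and minimum identities", {
  go <- pair_energy_force("go1210", list(eps = 1.7, sigma = 5), 5)
  expect_equal(go$E, -1.7, tolerance = 1e-12)
  expect_equal(go$dE, 0, tolerance = 1e-12)
  # direct evaluation of the 12-10 form at r = 1.2 sigma
  expect_equal(pair_energy_force("go1210", list(eps = 1, sigma = 1), 1.2)$E,
               5 / 1.2^12 - 6 / 1.2^10, tolerance = 1e-12)
  expect_equal(round(pair_energy_force("go1210", list(eps = 1, sigma = 1),
                                       1.2)$E, 5), -0.40825)
  ev <- pair_energy_force("exv12", list(eps = 1, sigma = 4), 8)
  expect_identical(ev$E, 0)
  ev <- pair_energy_force("exv12", list(eps = 1, sigma = 4), 4)
  expect_equal(ev$E, 1 - 2^-12, tolerance = 1e-12)
  # exv truncated-LJ form: zero at and beyond sigma, continuous there
  tr <- pair_energy_force("exv_lj_trunc", list(eps = 1, sigma = 5),
                          c(5 - 1e-9, 5, 6))
  expect_lt(abs(tr$E[1]), 1e-8)
  expect_identical(tr$E[2:3], c(0, 0))
  # Morse split: rep zero at/above r0, attr constant -eps below
  mr <- pair_energy_force("morse_rep", list(eps = 2, r0 = 4, alpha = 1),
                          c(3, 4, 5))
  ma <- pair_energy_force("morse_attr", list(eps = 2, r0 = 4, alpha = 1),
                          c(3, 4, 5))
  expect_identical(mr$E[2:3], c(0, 0))
  expect_identical(ma$E[1:2], c(-2, -2))
  expect_equal(mr$E[1] + ma$E[1],
               2 * (1 - exp(-1 * (3 - 4)))^2 - 2, tolerance = 1e-12)
  # Ashbaugh-Hatch continuity at the 2^(1/6) sigma switch
  sw <- 2^(1 / 6) * 5
  ah <- pair_energy_force("ashbaugh_hatch",
                          list(eps = 0.8, sigma = 5, lambda = 0.5),
                          c(sw - 1e-8, sw + 1e-8))
  expect_lt(abs(diff(ah$E)), 1e-6)
})

test_that("pair and bonded derivatives match central finite differences", {
  set.seed(7)
  h <- 1e-6
  for (kind in c("go1210", "lj126", "exv12", "gaussian", "morse_rep",
                 "morse_attr", "ashbaugh_hatch")) {
    for (rep_i in 1:5) {
      params <- list(eps = runif(1, 0.1, 3), sigma = runif(1, 3, 7),
                     r0 = runif(1, 3, 7), w = runif(1, 0.5, 2),
                     alpha = runif(1, 0.5, 3), lambda = runif(1, 0, 1))
      r <- runif(1, 2.5, 9)
      # stay off the non-smooth switch points of the piecewise forms
      if (kind == "exv12" && abs(r - 2 * params$sigma) < 0.1) next
      if (kind == "ashbaugh_hatch" &&
          abs(r - 2^(1 / 6) * params$sigma) < 0.1) next
      if (grepl("morse", kind) && abs(r - params$r0) < 0.1) next
      out <- pair_energy_force(kind, params, r)
      fd <- (pair_energy_force(kind, params, r + h)$E -
             pair_energy_force(kind, params, r - h)$E) / (2 * h)
      expect_equal(out$dE, fd, tolerance = 1e-4,
                   label = paste(kind, "derivative"))
    }
  }
  for (rep_i in 1:5) {
    par <- list(k = runif(1, 1, 50), n = sample(1:3, 1),
                phi0 = runif(1, -3, 3))
    phi <- runif(1, -3, 3)
    out <- dihedral_energy_force("periodic", par, phi)
    fd <- (dihedral_energy_force("periodic", par, phi + h)$E -
           dihedral_energy_force("periodic", par, phi - h)$E) / (2 * h)
    expect_equal(out$dE, fd, tolerance = 1e-4)
  }
})

test_that("modulating gate is bounded, gated and C1 at its joins", {
  g <- 0.3
  m0 <- modulator(0, g)
  expect_equal(m0$f, 1); expect_equal(m0$df, 0)
  expect_equal(modulator(2 * g, g)$f, 0)
  expect_equal(modulator(1.5 * g, g)$f, 0.5, tolerance = 1e-12)
  expect_equal(modulator(2.5 * g, g)$f, 0)
  # C1 continuity at both joins
  for (x0 in c(g, 2 * g)) {
    lo <- modulator(x0 - 1e-7, g); hi <- modulator(x0 + 1e-7, g)
    expect_lt(abs(lo$f - hi$f), 1e-6)
    expect_lt(abs(lo$df - hi$df), 1e-5)
  }
  xs <- seq(-1, 1, by = 0.01)
  fs <- modulator(xs, g)$f
  expect_true(all(fs >= 0 & fs <= 1))
})

test_that("term sign bounds hold on dense grids", {
  rs <- seq(0.5, 20, by = 0.05)
  expect_true(all(pair_energy_force("exv12",
                                    list(eps = 1, sigma = 4), rs)$E >= 0))
  expect_true(all(pair_energy_force("exv_lj_trunc",
                                    list(eps = 1, sigma = 4), rs)$E >= 0))
  expect_true(all(pair_energy_force("gaussian",
                                    list(eps = 1, r0 = 5, w = 1),
                                    rs)$E <= 0))
  expect_true(all(pair_energy_force("morse_attr",
                                    list(eps = 1, r0 = 5, alpha = 1),
                                    rs)$E <= 0))
})

test_that("LJ truncation ratio: bisection agrees with a dense grid scan", {
  root <- lj_cutoff_ratio(1e-4)
  # independent oracle: dense scan for the outermost |E| = tol crossing
  grid <- seq(2^(1 / 6), 12, by = 1e-6)
  Eg <- abs(4 * ((1 / grid)^12 - (1 / grid)^6))
  scan <- grid[max(which(Eg >= 1e-4))]
  expect_equal(root, scan, tolerance = 1e-5)
  # at tolerance 1 the largest root of |E| = eps is the minimum position
  expect_equal(lj_cutoff_ratio(1 - 1e-12), 2^(1 / 6), tolerance = 1e-5)
})

test_that("permittivity and Debye length follow their closed forms", {
  expect_equal(permittivity(300, 0) / (249.4 - 0.788 * 300 +
                                       7.2e-4 * 300^2), 1)
  expect_equal(permittivity(300, 0), 77.8, tolerance = 1e-12)
  aC <- 1 - 0.2551 * 0.15 + 5.151e-2 * 0.15^2 - 6.889e-3 * 0.15^3
  expect_equal(permittivity(300, 0.15), 77.8 * aC, tolerance = 1e-12)
  expect_equal(permittivity(300, 0) * 1, permittivity(300, 0))  # a(0) = 1
  # sqrt law: quadrupling the ionic strength halves the screening length
  e1 <- ele_environment(300, 0.1, I_M = 0.1)
  e4 <- ele_environment(300, 0.1, I_M = 0.4)
  expect_equal(e4$lambda_D, e1$lambda_D / 2, tolerance = 1e-12)
  # lambda_D strictly decreasing in I at fixed T
  ls <- vapply(c(0.05, 0.1, 0.2, 0.5, 1),
               function(I) ele_environment(300, 0.15, I_M = I)$lambda_D,
               numeric(1))
  expect_true(all(diff(ls) < 0))
  # eps_r positive across the stated domain
  grid <- expand.grid(T_K = seq(250, 400, by = 25), C = seq(0, 1, by = 0.2))
  expect_true(all(permittivity(grid$T_K, grid$C) > 0))
})

test_that("screened electrostatics: functional form and cutoff bound", {
  env <- ele_environment(300, 0.15)
  expect_identical(debye_huckel(0, 1, 10, env)$E, 0)
  # E(r + lambda_D) / E(r) = exp(-1) * r / (r + lambda_D)
  r <- 12.3
  ratio <- debye_huckel(1, 1, r + env$lambda_D, env)$E /
    debye_huckel(1, 1, r, env)$E
  expect_equal(ratio, exp(-1) * r / (r + env$lambda_D), tolerance = 1e-12)
  # unit charges at the 52 A default cutoff are below 1e-4 kcal/mol
  expect_lt(abs(debye_huckel(1, -1, 52, env)$E), 1e-4)
  # derivative against finite differences
  h <- 1e-6
  fd <- (debye_huckel(1, -1, r + h, env)$E -
         debye_huckel(1, -1, r - h, env)$E) / (2 * h)
  expect_equal(debye_huckel(1, -1, r, env)$dE, fd, tolerance = 1e-6)
})
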