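test_that("exclusion rules cover bonded, 1-4 and dedicated-term pairs", {
  # linear 4-bead chain with one dihedral -> all six pairs excluded
  p <- cgmdr:::.particle_table(4)
  top <- cg_topology(
    p,
    bonds = data.frame(i = 0:2, j = 1:3, func = 1L, b0 = 3.8, c1 = 10,
                       c2 = 0),
    dihedrals = data.frame(i = 0L, j = 1L, k = 2L, l = 3L, func = 1L,
                           phi0 = 0, mult = 1, kd = 1, sigma = 0,
                           table = "", stringsAsFactors = FALSE),
    exclusions = rbind(cbind(0:2, 1:3), c(0L, 2L), c(1L, 3L)))
  ex <- build_exclusions(top)
  expect_setequal(pair_key(ex$common),
                  c("0 1", "1 2", "2 3", "0 2", "1 3", "0 3"))
  # native contacts and DNA partners are excluded from exv only
  hx <- map_protein(make_fixture("helix_ca", 16))
  atop <- generate_model_topology(hx, "aicg2+")
  exa <- build_exclusions(atop)
  ckey <- pair_key(as.matrix(atop$contacts[, c("i", "j")]))
  expect_true(all(ckey %in% pair_key(exa$exv_only)))
  expect_false(any(ckey %in% pair_key(exa$common)))
  dna <- build_dsdna_from_sequence("ACGTA")
  dtop <- generate_model_topology(dna, "3spn2c")
  exd <- build_exclusions(dtop)
  wc <- pair_key(as.matrix(dtop$basepairs[, c("i", "j")]))
  expect_true(all(wc %in% pair_key(exd$exv_only)))
  # and the engine's exv neighbor list honours them
  sys <- cg_system(dtop)
  prs <- neighbor_pairs(sys, cg_frame(dna$positions))$exv
  expect_false(any(wc %in% pair_key(prs)))
})

test_that("structure-based protein energies at and near the native frame", {
  hx <- map_protein(make_fixture("helix_ca", 18))
  top <- generate_model_topology(hx, "aicg2+")
  sys <- cg_system(top)
  r <- cg_energy(sys, cg_frame(hx$positions))
  expect_equal(unname(r$terms["contact_go"]), -sum(top$contacts$eps),
               tolerance = 1e-12)
  expect_lt(abs(r$terms["bond"]), 1e-20)
  # two-residue contact at r = 1.2 sigma reproduces the 12-10 value
  p2 <- cgmdr:::.particle_table(2)
  t2 <- cg_topology(p2, contacts = data.frame(i = 0L, j = 1L, sigma = 5,
                                              eps = 1.3))
  s2 <- cg_system(t2, terms = character(0))
  e <- cg_energy(s2, cg_frame(rbind(c(0, 0, 0), c(6, 0, 0))))
  expect_equal(unname(e$terms["contact_go"]),
               1.3 * (5 / 1.2^12 - 6 / 1.2^10), tolerance = 1e-12)
  # rigid-body motion leaves the report unchanged
  shift <- sweep(hx$positions, 2, c(10, 10, 10), "+")
  r2 <- cg_energy(sys, cg_frame(shift))
  expect_equal(r2$terms, r$terms, tolerance = 1e-10)
  th <- 0.7
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  r3 <- cg_energy(sys, cg_frame(hx$positions %*% rot))
  expect_equal(r3$terms, r$terms, tolerance = 1e-9)
})

test_that("hydropathy pair term reduces correctly in its limit cases", {
  idp <- mixed_idp(n = 12, copies = 2)
  top <- generate_model_topology(idp, "hps")
  # lambda = 1 everywhere: Ashbaugh-Hatch equals the plain LJ sum
  t1 <- top; t1$particles$lambda <- 1; t1$particles$charge <- 0
  s1 <- cg_system(t1, terms = "hps")
  pos <- idp$positions
  e1 <- cg_energy(s1, cg_frame(pos))
  excl <- build_exclusions(top)$common
  exk <- pair_key(excl)
  n <- nrow(pos)
  lj_sum <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (paste(i - 1, j - 1) %in% exk) next
    d <- sqrt(sum((pos[i, ] - pos[j, ])^2))
    if (d < 39) {
      lj_sum <- lj_sum + pair_energy_force("lj126",
        list(eps = (top$particles$eps[i] + top$particles$eps[j]) / 2,
             sigma = (top$particles$sigma[i] +
                      top$particles$sigma[j]) / 2), d)$E
    }
  }
  expect_equal(unname(e1$terms["hps"]), lj_sum, tolerance = 1e-10)
  # lambda = 0 with all pairs beyond the switch: term vanishes
  t0 <- top; t0$particles$lambda <- 0; t0$particles$charge <- 0
  s0 <- cg_system(t0, terms = "hps")
  spread <- pos * 3    # push everything past 2^(1/6) sigma
  e0 <- cg_energy(s0, cg_frame(spread))
  expect_equal(unname(e0$terms["hps"]), 0, tolerance = 1e-12)
})

test_that("neighbor-listed energies equal the brute-force double loop", {
  idp <- mixed_idp(n = 15, seed = 21, copies = 2)
  top <- generate_model_topology(idp, "hps")
  sys <- cg_system(top, 300, 0.15)
  r <- cg_energy(sys, cg_frame(idp$positions))
  oracle <- brute_hps_ele(top, idp$positions)
  expect_equal(unname(r$terms["hps"]), oracle$hps, tolerance = 1e-10)
  expect_equal(unname(r$terms["ele"]), oracle$ele, tolerance = 1e-10)
})

test_that("three-site DNA terms hit their reference-geometry identities", {
  dna <- build_dsdna_from_sequence("ACGTACGTAC")
  top <- generate_model_topology(dna, "3spn2c")
  sys <- cg_system(top)
  r <- cg_energy(sys, cg_frame(dna$positions))
  # at the built (native) geometry every gate is 1 and every Morse at r0
  expect_equal(unname(r$terms["base_stack"]), -sum(top$stacks$eps),
               tolerance = 1e-9)
  expect_equal(unname(r$terms["base_pair"]), -sum(top$basepairs$eps),
               tolerance = 1e-9)
  expect_equal(unname(r$terms["cross_stack"]), -sum(top$crossstacks$eps),
               tolerance = 1e-9)
  # only Watson-Crick combinations carry pairing parameters
  bp_bases <- top$particles$resname[top$basepairs$i + 1]
  bp_partners <- top$particles$resname[top$basepairs$j + 1]
  comp <- c(DA = "DT", DT = "DA", DC = "DG", DG = "DC")
  expect_identical(unname(comp[bp_bases]), bp_partners)
  # gating: pushing theta1 beyond 2 gamma removes the attractive part
  t1 <- top
  t1$basepairs$theta1_0 <- t1$basepairs$theta1_0 + 2 * t1$basepairs$gamma +
    0.05
  s1 <- cg_system(t1)
  r1 <- cg_energy(s1, cg_frame(dna$positions))
  # Morse repulsive part is zero at r = r0, so the whole term gates to zero
  expect_equal(unname(r1$terms["base_pair"]), 0, tolerance = 1e-9)
})

test_that("structure-based RNA model: native minimum and optional ele", {
  # toy single-strand RNA built from the DNA backbone geometry
  atoms <- build_dsdna_from_sequence("ACGTACGT")$atoms
  atoms <- atoms[atoms$chain == "A", ]
  atoms$resname <- c(DA = "A", DC = "C", DG = "G", DT = "U")[atoms$resname]
  rna <- map_nucleic(atoms, "rna")
  top <- generate_model_topology(rna, "rna_struct")
  expect_true(all(top$particles$class == "rna"))
  sys <- cg_system(top, terms = c("exv", "ele"))
  r <- cg_energy(sys, cg_frame(rna$positions))
  expect_lt(abs(r$terms["bond"]), 1e-18)
  expect_lt(abs(r$terms["angle"]), 1e-18)
  if (nrow(top$contacts)) {
    expect_equal(unname(r$terms["contact_go"]), -sum(top$contacts$eps),
                 tolerance = 1e-10)
  }
  # intra-RNA electrostastics off vs on with zero charges: identical totals
  t0 <- top; t0$particles$charge <- 0
  s_off <- cg_system(t0, terms = "exv")
  s_on <- cg_system(t0, terms = c("exv", "ele"))
  e_off <- cg_energy(s_off, cg_frame(rna$positions))$total
  e_on <- cg_energy(s_on, cg_frame(rna$positions))$total
  expect_equal(e_off, e_on, tolerance = 1e-12)
  # direct-sum oracle for the bonded part on a 5-nt fragment
  frag_atoms <- atoms[atoms$resid <= 5, ]
  frag <- map_nucleic(frag_atoms, "rna")
  ftop <- generate_model_topology(frag, "rna_struct")
  fsys <- cg_system(ftop, terms = character(0))
  pos <- frag$positions + matrix(rnorm(length(frag$positions),
                                       sd = 0.15), nrow(frag$positions), 3)
  fe <- cg_energy(fsys, cg_frame(pos))
  bsum <- sum(vapply(seq_len(nrow(ftop$bonds)), function(k) {
    b <- ftop$bonds[k, ]
    d <- sqrt(sum((pos[b$i + 1, ] - pos[b$j + 1, ])^2))
    bond_energy_force("harmonic", list(k = b$c1, b0 = b$b0), d)$E
  }, numeric(1)))
  expect_equal(unname(fe$terms["bond"]), bsum, tolerance = 1e-10)
})

test_that("PWM recognition and backbone-HB sites evaluate as specified", {
  dna <- build_dsdna_from_sequence("ACGTACGTAC")
  dtop <- generate_model_topology(dna, "3spn2c")
  p <- dna$particles
  ib <- which(p$chain == "A" & p$name == "DB")[5]
  bpos <- dna$positions[ib, ]
  prot_pos <- rbind(bpos + c(8, 0, 0), bpos + c(11.2, 1.5, 0.5),
                    bpos + c(14.8, 2.5, 1))
  prot <- data.frame(name = "CA", class = "protein",
                     resname = c("ARG", "GLY", "GLU"), resid = 1:3,
                     chain = "P", mass = 110, charge = 0, radius = 2.5,
                     lambda = 0.5, sigma = 5, eps = 0.2,
                     stringsAsFactors = FALSE)
  ptop <- cg_topology(prot,
                      bonds = data.frame(i = 0:1, j = 1:2, func = 1L,
                                         b0 = 3.8, c1 = 20, c2 = 0),
                      exclusions = rbind(c(0L, 1L), c(1L, 2L), c(0L, 2L)))
  attr(ptop, "nonbonded") <- "exv"
  top <- merge_topologies(ptop, dtop)
  pos <- rbind(prot_pos, dna$positions)
  a3 <- cgmdr:::.angle3
  ibg <- ib + 2; sb <- ibg - 1
  pb <- which(top$particles$chain == "A" &
                top$particles$name == "DB")[4] - 1L
  th1 <- a3(pos, sb + 1, ibg + 1, 1)
  th2 <- a3(pos, ibg + 1, 1, 2)
  th3 <- a3(pos, pb + 1, ibg + 1, 1)
  r0 <- sqrt(sum((pos[ibg + 1, ] - pos[1, ])^2))
  top$pwmcos <- data.frame(j = 0L, jm = 1L, jp = 2L, m = 0L, r0 = r0,
                           theta1_0 = th1, theta2_0 = th2, theta3_0 = th3,
                           gamma = 0.3, gamma_pwm = 2, eps_shift = 0.5,
                           w = 1.0)
  pwm_path <- tempfile()
  writeLines(c("A C G T", "1.5 0", "0 0", "0.2 0", "0 0", "N 2 2"),
             pwm_path)
  pwm <- read_pwm(pwm_path)
  expect_error(cg_system(top), "supply pwm")
  sys <- cg_system(top, pwm = pwm)
  r <- cg_energy(sys, cg_frame(pos))
  # manual site-by-site oracle over every candidate base
  eng <- sys$engine
  gatef <- function(dth, g) {
    ifelse(abs(dth) < g, 1,
           ifelse(abs(dth) <= 2 * g, 1 - cos(pi * dth / (2 * g))^2, 0))
  }
  tot <- 0
  for (b in eng$nonbonded$pwm_bases) {
    rr <- sqrt(sum((pos[b + 1, ] - pos[1, ])^2))
    if (rr >= r0 + 5) next
    sbb <- eng$base_sugar[b + 1]; pbb <- eng$base_prev[b + 1]
    t1 <- a3(pos, sbb + 1, b + 1, 1)
    t2 <- a3(pos, b + 1, 1, 2)
    t3 <- a3(pos, pbb + 1, b + 1, 1)
    eps <- eng$pwmcos$eps_by_base[eng$base[b + 1] + 1]
    tot <- tot - eps * exp(-(rr - r0)^2 / 2) * gatef(t1 - th1, 0.3) *
      gatef(t2 - th2, 0.3) * gatef(t3 - th3, 0.3)
  }
  expect_equal(unname(r$terms["pwmcos"]), as.numeric(tot),
               tolerance = 1e-10)
  # the aligned base at its reference geometry contributes the combined
  # well depth of its own and the complementary-strand column
  eps_self <- pwm_to_epsilon(pwm, 0, "A", 2, 0.5)
  eps_comp <- pwm_to_epsilon(pwm, 0, "T", 2, 0.5)
  expect_lt(r$terms["pwmcos"], -(eps_self + eps_comp) + 1e-9)
  # beyond-cutoff sites contribute nothing
  far <- pos; far[1, ] <- far[1, ] + c(r0 + 6, 0, 0)
  # keep the chain bonded geometry sane by moving all protein beads
  far[2, ] <- far[2, ] + c(r0 + 6, 0, 0); far[3, ] <- far[3, ] + c(r0 + 6, 0, 0)
  rf <- cg_energy(sys, cg_frame(far))
  expect_equal(unname(rf$terms["pwmcos"]), 0, tolerance = 1e-12)

  # backbone HB site: reference geometry gives -eps, gates multiply
  ip0 <- which(top$particles$chain == "A" &
                 top$particles$name == "DP")[4] - 1L
  si <- which(top$particles$chain == "A" &
                top$particles$name == "DS")[5] - 1L
  hth1 <- a3(pos, si + 1, ip0 + 1, 1)
  hth2 <- a3(pos, ip0 + 1, 1, 3)
  hr0 <- sqrt(sum((pos[ip0 + 1, ] - pos[1, ])^2))
  top$hb <- data.frame(i = ip0, j = 0L, si = si, j2 = 2L, r0 = hr0,
                       theta1_0 = hth1, theta2_0 = hth2, gamma = 0.3,
                       eps = 1.2, w = 1.0)
  s2 <- cg_system(top, pwm = pwm)
  r2 <- cg_energy(s2, cg_frame(pos))
  expect_equal(unname(r2$terms["hb"]), -1.2, tolerance = 1e-12)
  # half-gate arithmetic: dtheta1 = 1.5 gamma, dtheta2 = 0 -> -eps/2
  t3 <- top
  t3$hb$theta1_0 <- t3$hb$theta1_0 - 1.5 * 0.3
  s3 <- cg_system(t3, pwm = pwm)
  r3 <- cg_energy(s3, cg_frame(pos))
  expect_equal(unname(r3$terms["hb"]), -0.6, tolerance = 1e-9)
  # the HB term never touches particle charges
  t4 <- top; t4$particles$charge <- 0
  s4 <- cg_system(t4, pwm = pwm, terms = character(0))
  r4 <- cg_energy(s4, cg_frame(pos))
  expect_equal(unname(r4$terms["hb"]), unname(r2$terms["hb"]),
               tolerance = 1e-12)
})

test_that("assembled models are exact gradients of their reported totals", {
  # randomized fixtures across the model families
  hx <- map_protein(make_fixture("helix_ca", 15))
  atop <- generate_model_topology(hx, "aicg2+")
  set.seed(31)
  pos_a <- hx$positions + matrix(rnorm(length(hx$positions), sd = 0.3),
                                 ncol = 3)
  expect_lt(fd_force_error(cg_system(atop), pos_a), 1e-4)
  idp <- mixed_idp(n = 14, seed = 6, copies = 2)
  htop <- generate_model_topology(idp, "hps")
  expect_lt(fd_force_error(cg_system(htop), idp$positions), 1e-4)
  dna <- build_dsdna_from_sequence("ACGTAC")
  dtop <- generate_model_topology(dna, "3spn2c")
  pos_d <- dna$positions + matrix(rnorm(length(dna$positions), sd = 0.2),
                                  ncol = 3)
  expect_lt(fd_force_error(cg_system(dtop), pos_d), 1e-4)
})

test_that("force and torque balance holds for isolated systems", {
  dna <- build_dsdna_from_sequence("ACGTACG")
  top <- generate_model_topology(dna, "3spn2c")
  sys <- cg_system(top)
  set.seed(13)
  pos <- dna$positions + matrix(rnorm(length(dna$positions), sd = 0.25),
                                ncol = 3)
  r <- cg_energy(sys, cg_frame(pos))
  expect_lt(max(abs(colSums(r$forces))), 1e-8)
  torque <- colSums(cbind(
    pos[, 2] * r$forces[, 3] - pos[, 3] * r$forces[, 2],
    pos[, 3] * r$forces[, 1] - pos[, 1] * r$forces[, 3],
    pos[, 1] * r$forces[, 2] - pos[, 2] * r$forces[, 1]))
  expect_lt(max(abs(torque)), 1e-6)
  # per-term total equals the sum of reported terms
  expect_equal(r$total, sum(r$terms), tolerance = 1e-10)
})

test_that("disallowed model/term combinations are refused, not filtered", {
  idp <- make_fixture("idp_chain", 10, seed = 3)
  top <- generate_model_topology(idp, "hps")
  top$pwmcos <- data.frame(j = 0L, jm = 1L, jp = 2L, m = 0L, r0 = 8,
                           theta1_0 = 1, theta2_0 = 1, theta3_0 = 1,
                           gamma = 0.3, gamma_pwm = 1, eps_shift = 0,
                           w = 1)
  expect_error(cg_system(top, pwm = structure(list(
    scores = matrix(0, 4, 1, dimnames = list(c("A", "C", "G", "T"), NULL)),
    n_contacts = 1), class = "cg_pwm")), "require both protein and DNA")
  # ele disabled -> report omits the ele key but keeps exv
  d <- build_dsdna_from_sequence("ACGT")
  dt <- generate_model_topology(d, "3spn2c")
  s_noele <- cg_system(dt, terms = "exv")
  rr <- cg_energy(s_noele, cg_frame(d$positions))
  expect_false("ele" %in% names(rr$terms))
  expect_true("exv" %in% names(rr$terms))
})
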