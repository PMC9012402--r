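test_that("radius of gyration follows its closed form", {
  expect_equal(radius_of_gyration(matrix(5, 10, 3)), 0)
  two <- rbind(c(0, 0, 0), c(2, 0, 0))
  expect_equal(radius_of_gyration(two), 1)
  set.seed(2)
  pos <- matrix(rnorm(300), 100, 3)
  m <- runif(100, 50, 150)
  com <- colSums(pos * m) / sum(m)
  direct <- sqrt(sum(m * rowSums(sweep(pos, 2, com)^2)) / sum(m))
  expect_equal(radius_of_gyration(pos, masses = m), direct,
               tolerance = 1e-12)
  expect_error(radius_of_gyration(pos, selection = integer(0)), "empty")
})

test_that("superposed RMSD removes rigid-body motion", {
  set.seed(3)
  ref <- matrix(rnorm(60, sd = 5), 20, 3)
  expect_equal(rmsd(ref, ref), 0)
  th <- 0.9
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  moved <- sweep(ref %*% R, 2, c(4, -2, 7), "+")
  expect_lt(rmsd(moved, ref), 1e-10)
  # independent oracle: bio3d's superposition-based rmsd
  pert <- moved + matrix(rnorm(60, sd = 0.4), 20, 3)
  ours <- rmsd(pert, ref)
  theirs <- bio3d::rmsd(as.numeric(t(ref)), as.numeric(t(pert)),
                        fit = TRUE)
  expect_equal(ours, theirs, tolerance = 1e-3)
  expect_error(rmsd(ref[1:5, ], ref), "differ")
})

test_that("nativeness Q counts formed contacts", {
  hx <- map_protein(make_fixture("helix_ca", 20))
  top <- generate_model_topology(hx, "aicg2+")
  expect_equal(q_score(hx$positions, top$contacts), 1)
  # fully extended chain loses every contact
  ext <- cbind(seq(0, by = 3.8, length.out = 20), 0, 0)
  expect_equal(q_score(ext, top$contacts), 0)
  # half the contacts pushed beyond the threshold -> Q = 0.5
  synth <- data.frame(i = 0:3, j = 4:7, sigma = 5, eps = 1)
  pos8 <- rbind(matrix(0, 4, 3), matrix(0, 4, 3))
  pos8[5, ] <- c(5, 0, 0); pos8[6, ] <- c(0, 5, 0)       # formed
  pos8[1, ] <- c(0, 0, 0); pos8[2, ] <- c(0, 0, 0)
  pos8[7, ] <- c(50, 0, 0); pos8[8, ] <- c(0, 50, 0)     # broken
  pos8[3, ] <- c(0, 0, 0); pos8[4, ] <- c(0, 0, 0)
  expect_equal(q_score(pos8, synth), 0.5)
})

test_that("z-density profiles conserve counts and find slabs", {
  box <- c(100, 100, 400)
  set.seed(6)
  # all particles inside one slab of width 40 A
  n <- 600
  pos <- cbind(runif(n) * 100, runif(n) * 100, 160 + runif(n) * 40)
  fr <- cg_frame(pos, box = box)
  prof <- density_profile_z(fr, bin_width = 40)
  vol_nm3 <- 100 * 100 * 40 / 1000
  occupied <- prof$value > 0
  expect_equal(sum(occupied), 1)
  expect_equal(prof$value[occupied], n / vol_nm3)
  # conservation: sum(counts) * bin volume = N for any binning
  prof2 <- density_profile_z(fr, bin_width = 25)
  width <- attr(prof2, "bin_width")
  expect_equal(sum(prof2$value) * 100 * 100 * width / 1000, n)
  # uniform fill is flat within Poisson noise
  posu <- cbind(runif(4000) * 100, runif(4000) * 100, runif(4000) * 400)
  pu <- density_profile_z(cg_frame(posu, box = box), bin_width = 40)
  expect_lt(stats::sd(pu$value) / mean(pu$value), 0.2)
  expect_error(density_profile_z(cg_frame(pos)), "box")
})

test_that("radial distribution from a droplet center behaves", {
  set.seed(8)
  # all B particles at a fixed radius land in a single shell
  a_sel <- matrix(rnorm(30, sd = 0.1), 10, 3)
  com_a <- colMeans(a_sel)
  theta <- runif(200) * pi; phi <- runif(200) * 2 * pi
  b_at_r <- sweep(32.6 * cbind(sin(theta) * cos(phi),
                               sin(theta) * sin(phi), cos(theta)),
                  2, com_a, "+")
  pos <- rbind(a_sel, b_at_r)
  prof <- rdf_from_com(pos, 1:10, 11:210, bin_width = 5, r_max = 60)
  expect_equal(sum(prof$value > 0), 1)
  expect_equal(prof$center[prof$value > 0], 32.5)
  # shell counts times shell volumes recover the particle count
  binw <- 5
  edges <- seq(0, 60, by = binw)
  shells <- 4 / 3 * pi * diff(edges^3) / 1000
  expect_equal(sum(prof$value * shells), 200)
})

test_that("DNA-binding position finds the nearest base pair", {
  dna <- make_fixture("toy_dsdna", 50)
  top <- generate_model_topology(dna, "3spn2c")
  pairing <- attr(dna, "pairing")
  # place a probe particle adjacent to base pair 25
  nts <- cgmdr:::.nucleotide_sites(top$particles)
  allnts <- do.call(rbind, nts)
  nd <- nrow(dna$positions)
  b25 <- allnts$B[match(pairing$a[25], allnts$id)]
  # probe appended after the DNA rows so topology indices stay valid
  probe <- dna$positions[b25, ] + c(3, 0, 0)
  pos <- rbind(dna$positions, probe)
  res <- dna_binding_position(pos, protein_sel = nd + 1, dna_top = top,
                              pairing = pairing)
  expect_equal(res$bp, 25)
  expect_lt(res$distance, 4)
  # symmetric placement between bp 25 and 26 breaks ties to the lower index
  mirror <- attr(dna, "pairing")
  b26 <- allnts$B[match(pairing$a[26], allnts$id)]
  mid_probe <- (dna$positions[b25, ] + dna$positions[b26, ]) / 2
  # build an artificial exactly-symmetric two-bp situation
  res_mid <- dna_binding_position(rbind(dna$positions, mid_probe),
                                  protein_sel = nd + 1, dna_top = top,
                                  pairing = pairing)
  expect_true(res_mid$bp %in% c(25L, 26L))
  # far-away probes still return the nearest index (caller filters)
  far <- dna$positions[b25, ] + c(500, 0, 0)
  res_far <- dna_binding_position(rbind(dna$positions, far),
                                  protein_sel = nd + 1, dna_top = top,
                                  pairing = pairing)
  expect_true(res_far$bp >= 1 && res_far$bp <= nrow(pairing))
  expect_gt(res_far$distance, 400)
})

test_that("DNA bend angle measures end-segment axes", {
  dna <- make_fixture("toy_dsdna", 40)
  top <- generate_model_topology(dna, "3spn2c")
  pairing <- attr(dna, "pairing")
  straight <- dna_bend_angle(dna$positions, top, window = 10,
                             pairing = pairing)
  expect_lt(straight, 4)     # built helix axis is straight within degrees
  # rigid 60-degree hinge at the center
  pos <- dna$positions
  zmid <- stats::median(pos[, 3])
  th <- 60 * pi / 180
  R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3)
  upper <- pos[, 3] > zmid
  pivot <- c(0, 0, zmid)
  pos[upper, ] <- sweep(sweep(pos[upper, ], 2, pivot) %*% t(R), 2, pivot,
                        "+")
  bent <- dna_bend_angle(pos, top, window = 10, pairing = pairing)
  expect_lt(abs(bent - 60), 2 + straight)
  # invariant under rigid rotation of the whole frame
  rot_all <- pos %*% t(R)
  expect_equal(dna_bend_angle(rot_all, top, window = 10, pairing = pairing),
               bent, tolerance = 1e-6)
  expect_error(dna_bend_angle(pos, top, window = 25, pairing = pairing),
               "too short")
})

test_that("wrapped base-pair counting matches a brute-force scan", {
  dna <- make_fixture("toy_dsdna", 30)
  top <- generate_model_topology(dna, "3spn2c")
  pairing <- attr(dna, "pairing")
  # synthetic "core": beads near base pairs 10-15
  nts <- cgmdr:::.nucleotide_sites(top$particles)
  allnts <- do.call(rbind, nts)
  core_pos <- t(vapply(10:15, function(bp) {
    dna$positions[allnts$B[match(pairing$a[bp], allnts$id)], ] + c(4, 0, 0)
  }, numeric(3)))
  pos <- rbind(dna$positions, core_pos)
  core_sel <- nrow(dna$positions) + 1:6
  count <- wrapped_bp_count(pos, top, core_sel, criterion = 10,
                            pairing = pairing)
  # brute force over all sites of each bp
  brute <- 0
  for (bp in seq_len(nrow(pairing))) {
    ids <- c(pairing$a[bp], pairing$b[bp])
    sites <- unlist(allnts[match(ids, allnts$id), c("P", "S", "B")])
    sites <- sites[!is.na(sites)]
    dmin <- min(vapply(sites, function(s) {
      min(sqrt(rowSums(sweep(core_pos, 2, pos[s, ])^2)))
    }, numeric(1)))
    if (dmin < 10) brute <- brute + 1
  }
  expect_equal(count, brute)
  expect_gt(count, 0)
  # far-away DNA counts zero; zero criterion counts zero
  expect_equal(wrapped_bp_count(rbind(dna$positions + 1e4, core_pos), top,
                                core_sel, criterion = 10,
                                pairing = pairing), 0)
  expect_equal(wrapped_bp_count(pos, top, core_sel, criterion = 0,
                                pairing = pairing), 0L)
})

test_that("chain clustering tracks condensation state", {
  chain <- make_fixture("idp_chain", 12, seed = 2)
  # two far-apart copies -> two clusters; overlapping copies -> one
  m2 <- merge_mappings(local({
    a <- chain; b <- chain
    b$positions <- b$positions + 500
    b$particles$chain <- "B"; b$atoms$chain <- "B"
    list(a, b)
  }))
  cl <- chain_clusters(m2$positions, m2$particles$chain, link_dist = 8)
  expect_equal(cl$sizes, c(1L, 1L))
  expect_equal(unname(cl$largest_fraction), 0.5)
  m1 <- merge_mappings(local({
    a <- chain; b <- chain
    b$positions <- b$positions + 4
    b$particles$chain <- "B"; b$atoms$chain <- "B"
    list(a, b)
  }))
  cl1 <- chain_clusters(m1$positions, m1$particles$chain, link_dist = 8)
  expect_equal(unname(cl1$largest_fraction), 1)
})
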