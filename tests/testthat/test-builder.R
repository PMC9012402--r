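test_that("protein mapping: one C-alpha particle per residue", {
  hx <- make_fixture("helix_ca", 20)
  m <- map_protein(hx)
  expect_equal(nrow(m$particles), 20)
  expect_true(all(m$particles$name == "CA"))
  # an 85-residue construct maps to 85 particles
  m85 <- map_protein(make_fixture("helix_ca", 85))
  expect_equal(m85$report$total, 85)
  # residues lacking a C-alpha are reported and skipped
  broken <- hx[!(hx$resid == 3 & hx$name == "CA"), ]
  mb <- map_protein(broken)
  expect_equal(nrow(mb$particles), 19)
  expect_match(mb$report$dropped, "no CA")
  # masses are the summed heavy-atom masses of the mapped group
  expect_equal(m$particles$mass[1], sum(hx$mass[hx$resid == 1]))
})

test_that("nucleic mapping: 3n - 1 sites per strand, COM placement", {
  dna <- build_dsdna_from_sequence(paste(rep("ACGT", 5), collapse = ""))
  # 20 nt per strand -> 59 per strand -> 118
  expect_equal(nrow(dna$particles), 2 * (3 * 20 - 1))
  expect_equal(sum(dna$particles$name == "DP"), 2 * 19)
  # a 50-bp duplex gives 2 x 149 = 298 particles
  d50 <- make_fixture("toy_dsdna", 50)
  expect_equal(nrow(d50$particles), 298)
  # single-nucleotide strand: sugar and base only
  atoms <- dna$atoms
  one <- atoms[atoms$chain == "A" & atoms$resid == 1, ]
  m1 <- map_nucleic(one, "dna")
  expect_equal(nrow(m1$particles), 2)
  expect_setequal(m1$particles$name, c("DS", "DB"))
  # unknown base identity errors
  bad <- atoms[atoms$chain == "A", ]
  bad$resname <- "DX"
  expect_error(map_nucleic(bad, "dna"), "no mappable")
})

test_that("contact detection matches the brute-force heavy-atom scan", {
  hx <- make_fixture("helix_ca", 24)
  m <- map_protein(hx)
  ct <- detect_native_contacts(m, cutoff = 6.5)
  # O(N^2) heavy-atom oracle over residue pairs
  oracle <- NULL
  for (i in 1:23) {
    for (j in (i + 1):24) {
      if (j - i < 4) next
      ai <- hx[hx$resid == i, c("x", "y", "z")]
      aj <- hx[hx$resid == j, c("x", "y", "z")]
      dmin <- min(sqrt(outer(rowSums(ai^2), rowSums(aj^2), "+") -
                       2 * as.matrix(ai) %*% t(as.matrix(aj))))
      if (dmin < 6.5) oracle <- rbind(oracle, c(i - 1, j - 1))
    }
  }
  expect_setequal(pair_key(as.matrix(ct[, c("i", "j")])), pair_key(oracle))
  # sigma is the native site-site distance
  d <- sqrt(rowSums((m$positions[ct$i + 1, , drop = FALSE] -
                     m$positions[ct$j + 1, , drop = FALSE])^2))
  expect_equal(ct$sigma, d)
  # boundary cases: 6.4 A in, 6.6 A out (with the 6.5 A default)
  mk2 <- function(gap) {
    atoms <- data.frame(element = "C", name = "CA",
                        resname = "ALA", resid = c(1, 6),
                        chain = "A", x = c(0, gap), y = 0, z = 0,
                        mass = 12, stringsAsFactors = FALSE)
    class(atoms) <- c("cg_atoms", "data.frame")
    detect_native_contacts(map_protein(atoms), 6.5)
  }
  expect_equal(nrow(mk2(6.4)), 1)
  expect_equal(nrow(mk2(6.6)), 0)
})

test_that("contact detection is independent of chain input order", {
  hx <- make_fixture("helix_ca", 12)
  hx2 <- hx
  hx2$chain <- "B"
  hx2$x <- hx2$x + 4.5
  m_ab <- merge_mappings(map_protein(hx), map_protein(hx2))
  perm <- merge_mappings(map_protein(hx2), map_protein(hx))
  ct1 <- detect_native_contacts(m_ab, 6.5)
  ct2 <- detect_native_contacts(perm, 6.5)
  # map indices back to (chain, resid) labels before comparing
  lab <- function(m, ct) {
    p <- m$particles
    apply(ct, 1, function(r) {
      a <- paste(p$chain[r[1] + 1], p$resid[r[1] + 1])
      b <- paste(p$chain[r[2] + 1], p$resid[r[2] + 1])
      paste(sort(c(a, b)), collapse = "|")
    })
  }
  expect_setequal(lab(m_ab, ct1[, 1:2]), lab(perm, ct2[, 1:2]))
})

test_that("sequence-built dsDNA reproduces target sequences and geometry", {
  # the consensus-insertion construction: TAAACAAT centered in 50-bp poly-CG
  flank <- paste(rep(c("C", "G"), length.out = 21), collapse = "")
  seq50 <- paste0(flank, "TAAACAAT", paste(rep(c("C", "G"),
                                               length.out = 21),
                                           collapse = ""))
  expect_equal(nchar(seq50), 50)
  dna <- build_dsdna_from_sequence(seq50)
  expect_equal(nrow(dna$particles), 298)
  expect_equal(attr(dna, "sequence"), seq50)
  expect_equal(substr(attr(dna, "sequence"), 22, 29), "TAAACAAT")
  # strand B carries the reverse complement
  pa <- dna$particles[dna$particles$chain == "B" & dna$particles$name ==
                        "DB", "resname"]
  comp <- c(DA = "DT", DC = "DG", DG = "DC", DT = "DA")
  strand_a <- dna$particles[dna$particles$chain == "A" &
                              dna$particles$name == "DB", "resname"]
  expect_identical(pa, unname(comp[rev(strand_a)]))
  expect_error(build_dsdna_from_sequence("ACGX"), "invalid characters")
  expect_error(build_dsdna_from_sequence("A"), "length >= 2")
})

test_that("homogeneous base steps compose an exact circular helix", {
  tab <- data.frame(step = c(t(outer(c("A", "C", "G", "T"),
                                     c("A", "C", "G", "T"), paste0))),
                    twist = 34.3, roll = 0, tilt = 0, shift = 0, slide = 0,
                    rise = 3.32, stringsAsFactors = FALSE)
  dna <- build_dsdna_from_sequence("ACGTACGTACGT", step_table = tab)
  # closed form: sugar of strand A nucleotide i lies on a helix of fixed
  # radius and phase i * twist, z = z0 + i * rise
  s_idx <- which(dna$particles$chain == "A" & dna$particles$name == "DS")
  sp <- dna$positions[s_idx, ]
  r_xy <- sqrt(sp[, 1]^2 + sp[, 2]^2)
  expect_lt(max(abs(r_xy - r_xy[1])), 1e-6)
  expect_lt(max(abs(diff(sp[, 3]) - 3.32)), 1e-6)
  phase <- atan2(sp[, 2], sp[, 1])
  dphase <- diff(phase) %% (2 * pi)
  expect_lt(max(abs(dphase - 34.3 * pi / 180)), 1e-6)
})

test_that("charge assignment follows the integer rule and file scheme", {
  atoms <- data.frame(element = "C", name = "CA",
                      resname = c("ARG", "GLY", "GLU"), resid = 1:3,
                      chain = "A", x = c(0, 3.8, 7.6), y = 0, z = 0,
                      mass = 12, stringsAsFactors = FALSE)
  class(atoms) <- c("cg_atoms", "data.frame")
  top <- generate_model_topology(map_protein(atoms), "hps",
                                 charges = "integer")
  expect_equal(top$particles$charge, c(1, 0, -1))
  # 50-bp duplex: 2 x 49 phosphates, all -1
  d50 <- make_fixture("toy_dsdna", 50)
  dtop <- generate_model_topology(d50, "3spn2c")
  expect_equal(sum(dtop$particles$charge == -1), 98)
  expect_equal(sum(dtop$particles$charge != 0), 98)
  # file scheme: charges read verbatim; missing particles rejected
  path <- tempfile()
  writeLines(c("1 0.25", "3 -0.5"), path)
  t2 <- assign_charges(top, "file", path)
  expect_equal(t2$particles$charge, c(0.25, 0, -0.5))
  writeLines("7 1.0", path)
  expect_error(assign_charges(top, "file", path), "outside the topology")
})

test_that("model topologies emit exactly the records each model needs", {
  idp <- make_fixture("idp_chain", n = 100, seed = 11)
  hps <- generate_model_topology(idp, "hps")
  expect_equal(nrow(hps$bonds), 99)
  expect_equal(nrow(hps$angles), 0)
  expect_equal(nrow(hps$dihedrals), 0)
  expect_identical(attr(hps, "nonbonded"), c("hps", "ele"))
  # 2-bp duplex: one pair record per strand pairing, one stack per step
  d2 <- build_dsdna_from_sequence("AC")
  t2 <- generate_model_topology(d2, "3spn2c")
  expect_equal(nrow(t2$basepairs), 2)
  expect_equal(nrow(t2$stacks), 2)     # one intra-strand step per strand
  expect_true(all(t2$bonds$func == 21))
  expect_true(all(t2$angles$func == 1))
  # class mismatches are refused
  expect_error(generate_model_topology(idp, "3spn2c"), "DNA only")
  expect_error(generate_model_topology(d2, "aicg2+"), "cannot be applied")
})

test_that("flexible tail ranges receive local terms only", {
  hx <- make_fixture("helix_ca", 30)
  m <- map_protein(hx)
  top <- generate_model_topology(m, "aicg2+",
                                 flexible = list(c(1, 5), c(26, 30)))
  tails <- c(0:4, 25:29)
  # no native contacts or 1-3 Gaussians touch the tails
  expect_false(any(top$contacts$i %in% tails | top$contacts$j %in% tails))
  expect_false(any(top$gauss13$i %in% tails | top$gauss13$k %in% tails))
  # no Gaussian dihedrals in the tails; tabulated flexible ones remain
  gd <- top$dihedrals[top$dihedrals$func == 21, ]
  expect_false(any(gd$i %in% tails))
  fd <- top$dihedrals[top$dihedrals$func == 22, ]
  expect_equal(nrow(fd), 27)     # every quadruple keeps the flexible term
  # bonds still cover the whole chain
  expect_equal(nrow(top$bonds), 29)
})

test_that("builder outputs always satisfy the topology validator", {
  for (make in list(
    function() generate_model_topology(map_protein(
      make_fixture("helix_ca", 15)), "aicg2+"),
    function() generate_model_topology(
      make_fixture("idp_chain", 20, seed = 2), "hps"),
    function() generate_model_topology(
      build_dsdna_from_sequence("ACGTAC"), "3spn2c"))) {
    top <- make()
    expect_true(validate_topology(top))
    dir <- tempfile()
    write_topology(top, dir, "roundtrip")
    expect_true(validate_topology(
      read_topology(file.path(dir, "roundtrip.top"))))
  }
})

test_that("fixtures are deterministic and obey their construction rules", {
  hx <- make_fixture("helix_ca", 20)
  ca <- as.matrix(hx[hx$name == "CA", c("x", "y", "z")])
  expect_equal(unname(sqrt(rowSums(diff(ca)^2))), rep(3.8, 19),
               tolerance = 1e-12)
  a <- make_fixture("idp_chain", 50, seed = 9)
  b <- make_fixture("idp_chain", 50, seed = 9)
  expect_identical(a$positions, b$positions)
  expect_identical(a$particles$resname, b$particles$resname)
  # slab replication: box attribute, chain count, no close contacts
  chain <- make_fixture("idp_chain", 30, seed = 4)
  slab <- make_fixture("multi_chain_slab", n = 6, seed = 8, chain = chain,
                       box = c(180, 180, 400), tol = 3.5)
  expect_equal(attr(slab, "box"), c(180, 180, 400))
  expect_equal(nrow(slab$particles), 180)
  prs <- cgmdr:::cpp_build_pairs(slab$positions, c(180, 180, 400), TRUE,
                                 seq_len(180) - 1L, integer(0), FALSE, 3.5,
                                 matrix(integer(), ncol = 2))$pairs
  ch <- slab$particles$chain
  inter <- ch[prs[, 1] + 1] != ch[prs[, 2] + 1]
  expect_false(any(inter))
  # impossible packing raises
  expect_error(make_fixture("multi_chain_slab", n = 80, seed = 1,
                            chain = chain, box = c(60, 60, 60), tol = 12,
                            max_tries = 5),
               "impossible packing")
})
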