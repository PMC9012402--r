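# Shared helpers: finite-difference force checks, brute-force energy
# oracles and tiny structure fixtures built in code.

# max |FD - analytic| over sampled coordinates, normalised by the force
# scale (relative error on near-zero components is meaningless noise)
fd_force_error <- function(sys, pos, box = NULL, n_coords = 20, h = 1e-5,
                           seed = 2) {
  fr <- cg_frame(pos, box = box)
  rep <- cg_energy(sys, fr)
  f <- rep$forces
  scale <- max(abs(f), 1)
  set.seed(seed)
  ids <- sample(length(pos), min(n_coords, length(pos)))
  errs <- vapply(ids, function(q) {
    pp <- pos; pp[q] <- pp[q] + h
    ep <- cg_energy(sys, cg_frame(pp, box = box))$total
    pp[q] <- pp[q] - 2 * h
    em <- cg_energy(sys, cg_frame(pp, box = box))$total
    abs(-(ep - em) / (2 * h) - f[q])
  }, numeric(1))
  max(errs) / scale
}

# O(N^2) pair oracle (minimum image when box given)
brute_pairs <- function(pos, rP, box = NULL, subset = NULL,
                        exclusions = NULL) {
  n <- nrow(pos)
  if (is.null(subset)) subset <- seq_len(n) - 1L
  out <- NULL
  for (a in seq_along(subset)) {
    for (b in seq_len(a - 1L)) {
      i <- subset[b]; j <- subset[a]
      d <- pos[i + 1L, ] - pos[j + 1L, ]
      if (!is.null(box)) d <- d - box * round(d / box)
      if (sum(d^2) < rP^2) out <- rbind(out, c(min(i, j), max(i, j)))
    }
  }
  if (is.null(out)) return(matrix(integer(), ncol = 2))
  if (!is.null(exclusions) && nrow(exclusions)) {
    key <- paste(out[, 1], out[, 2])
    exk <- paste(pmin(exclusions[, 1], exclusions[, 2]),
                 pmax(exclusions[, 1], exclusions[, 2]))
    out <- out[!(key %in% exk), , drop = FALSE]
  }
  out[order(out[, 1], out[, 2]), , drop = FALSE]
}

pair_key <- function(m) paste(m[, 1], m[, 2])

# direct-sum HPS + screened-electrostatics oracle from the scalar terms
brute_hps_ele <- function(top, pos, temperature = 300, salt = 0.15,
                          rc_hps = 39, rc_ele = 52) {
  p <- top$particles
  env <- ele_environment(temperature, salt)
  excl <- build_exclusions(top)$common
  exk <- paste(excl[, 1], excl[, 2])
  n <- nrow(p)
  Eh <- 0; Ee <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      if (paste(i - 1, j - 1) %in% exk) next
      d <- sqrt(sum((pos[i, ] - pos[j, ])^2))
      if (d < rc_hps) {
        Eh <- Eh + pair_energy_force("ashbaugh_hatch",
          list(eps = (p$eps[i] + p$eps[j]) / 2,
               sigma = (p$sigma[i] + p$sigma[j]) / 2,
               lambda = (p$lambda[i] + p$lambda[j]) / 2), d)$E
      }
      if (d < rc_ele && p$charge[i] * p$charge[j] != 0) {
        Ee <- Ee + debye_huckel(p$charge[i], p$charge[j], d, env)$E
      }
    }
  }
  list(hps = Eh, ele = Ee)
}

# minimal three-residue protein written as PDB and as mmCIF
tiny_pdb_lines <- function() {
  c(sprintf("ATOM  %5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            1:6,
            c(" N", " CA", " CA", " CB", " CA", " O"),
            c("ALA", "ALA", "GLY", "GLY", "SER", "SER"),
            "A", c(1, 1, 2, 2, 3, 3),
            c(1.0, 2.0, 5.8, 6.5, 9.6, 10.2),
            c(2.0, 2.5, 2.5, 4.0, 2.5, 1.0),
            c(3.0, 3.0, 3.0, 3.0, 3.0, 3.0),
            1.0, 0.0,
            c("N", "C", "C", "C", "C", "O")),
    "END")
}

tiny_cif_lines <- function() {
  hdr <- c("data_test", "#", "loop_",
           paste0("_atom_site.",
                  c("group_PDB", "id", "type_symbol", "label_atom_id",
                    "label_alt_id", "label_comp_id", "label_asym_id",
                    "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
                    "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
                    "B_iso_or_equiv", "pdbx_formal_charge", "auth_seq_id",
                    "auth_comp_id", "auth_asym_id", "auth_atom_id",
                    "pdbx_PDB_model_num")))
  nm <- c("N", "CA", "CA", "CB", "CA", "O")
  el <- c("N", "C", "C", "C", "C", "O")
  res <- c("ALA", "ALA", "GLY", "GLY", "SER", "SER")
  rid <- c(1, 1, 2, 2, 3, 3)
  x <- c(1.0, 2.0, 5.8, 6.5, 9.6, 10.2)
  y <- c(2.0, 2.5, 2.5, 4.0, 2.5, 1.0)
  rows <- sprintf("ATOM %d %s %s . %s A 1 %d ? %.3f %.3f 3.000 1.00 0.00 ? %d %s A %s 1",
                  1:6, el, nm, res, rid, x, y, rid, res, nm)
  c(hdr, rows, "#")
}

# small charged/hydrophobic mixed chain for nonbonded tests
mixed_idp <- function(n = 24, seed = 5, copies = 2) {
  seqs <- rep(c("LYS", "GLU", "TYR", "GLY", "SER", "PHE"), length.out = n)
  make_fixture("idp_chain", n = n, seed = seed, sequence = seqs,
               copies = copies)
}
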