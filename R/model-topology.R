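#' Generate a model topology from a CG mapping
#'
#' Emits exactly the interaction records each model's energy function
#' requires, with reference values taken from the mapped (native) structure:
#'
#' \describe{
#'   \item{aicg2+}{structure-based protein model: harmonic bonds, tabulated
#'     (statistics-derived) angles, Gaussian 1-3 distance terms, Gaussian
#'     plus tabulated dihedrals, Go 12-10 native contacts; non-native pairs
#'     interact through the 12th-power excluded volume with the radius
#'     combination rule.  `flexible` ranges (chain-local residue indices)
#'     receive only local flexible terms — bonds, tabulated angles,
#'     tabulated dihedrals — and take part in no contacts.}
#'   \item{hps / kh}{disordered-chain models: harmonic bonds only; all
#'     nonbonded interactions are the hydropathy-scaled pair term plus
#'     screened electrostatics.  (The pair-specific KH energy matrix is
#'     external parameter data; with the packaged tables both variants use
#'     the per-residue hydropathy scale.)}
#'   \item{3spn2c}{three-site DNA: quartic bonds, harmonic angles, Gaussian
#'     plus periodic backbone dihedrals, base-stacking/pairing/cross-
#'     stacking site records, phosphate charges.}
#'   \item{rna_struct}{structure-based three-site RNA: harmonic bonds,
#'     angles and periodic dihedrals, Go contacts, excluded volume,
#'     optional phosphate electrostatics.}
#' }
#'
#' @param mapping A `cg_mapping` from [map_protein()], [map_nucleic()] or
#'   [build_dsdna_from_sequence()].
#' @param model One of `"aicg2+"`, `"hps"`, `"kh"`, `"3spn2c"`,
#'   `"rna_struct"`.
#' @param contact_eps Go contact energy, kcal/mol (default from the
#'   packaged parameter file); a per-contact table can be supplied instead
#'   by editing the returned records.
#' @param contact_cutoff Heavy-atom contact cutoff, A.
#' @param flexible List of chain-local index ranges (2-vectors) treated as
#'   flexible tails/linkers (aicg2+ only).
#' @param charges `"integer"`, `"none"`, or a file path for
#'   [assign_charges()]'s file scheme.
#' @return A [cg_topology()] tagged with the model's nonbonded terms.
#' @export
generate_model_topology <- function(mapping,
                                    model = c("aicg2+", "hps", "kh",
                                              "3spn2c", "rna_struct"),
                                    contact_eps = NULL,
                                    contact_cutoff = NULL,
                                    flexible = list(),
                                    charges = "integer") {
  model <- match.arg(model)
  p <- mapping$particles
  classes <- unique(p$class)
  if (model %in% c("aicg2+", "hps", "kh") && !all(classes %in%
        c("protein", if (model %in% c("hps", "kh")) "rna"))) {
    stop("model ", model, " cannot be applied to classes: ",
         paste(setdiff(classes, "protein"), collapse = ", "))
  }
  if (model == "3spn2c" && !all(classes == "dna")) {
    stop("model 3spn2c applies to DNA only")
  }
  if (model == "rna_struct" && !all(classes == "rna")) {
    stop("model rna_struct applies to RNA only")
  }
  top <- switch(model,
    "aicg2+" = .top_aicg2p(mapping, contact_eps, contact_cutoff, flexible),
    hps = , kh = .top_hps(mapping),
    "3spn2c" = .top_3spn2c(mapping),
    rna_struct = .top_rna(mapping, contact_eps, contact_cutoff))
  if (identical(charges, "integer")) {
    top <- assign_charges(top, "integer")
  } else if (is.character(charges) && file.exists(charges)) {
    top <- assign_charges(top, "file", charges)
  }
  top
}

.dist3 <- function(pos, i, j) {
  sqrt(sum((pos[i, ] - pos[j, ])^2))
}
.angle3 <- function(pos, i, j, k) {
  u <- pos[i, ] - pos[j, ]; v <- pos[k, ] - pos[j, ]
  acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2)))))
}
.dihedral4 <- function(pos, i, j, k, l) {
  b1 <- pos[j, ] - pos[i, ]; b2 <- pos[k, ] - pos[j, ]
  b3 <- pos[l, ] - pos[k, ]
  n1 <- c(b1[2]*b2[3]-b1[3]*b2[2], b1[3]*b2[1]-b1[1]*b2[3],
          b1[1]*b2[2]-b1[2]*b2[1])
  n2 <- c(b2[2]*b3[3]-b2[3]*b3[2], b2[3]*b3[1]-b2[1]*b3[3],
          b2[1]*b3[2]-b2[2]*b3[1])
  m <- c(n1[2]*n2[3]-n1[3]*n2[2], n1[3]*n2[1]-n1[1]*n2[3],
         n1[1]*n2[2]-n1[2]*n2[1])
  atan2(sum(m * b2) / sqrt(sum(b2^2)), sum(n1 * n2))
}

# chain-contiguous runs of particle indices (1-based)
.chain_runs <- function(p) {
  split(seq_len(nrow(p)), factor(p$chain, levels = unique(p$chain)))
}

.top_aicg2p <- function(mapping, contact_eps, contact_cutoff, flexible) {
  par <- aicg2p_parameters()
  if (is.null(contact_eps)) contact_eps <- unname(par["contact_eps"])
  if (is.null(contact_cutoff)) {
    contact_cutoff <- unname(par["contact_cutoff"])
  }
  p <- mapping$particles
  pos <- mapping$positions
  runs <- .chain_runs(p)
  bonds <- angles <- dihedrals <- gauss13 <- NULL
  is_flex <- rep(FALSE, nrow(p))
  for (run in runs) {
    loc <- seq_along(run)
    flex_loc <- rep(FALSE, length(run))
    for (rg in flexible) flex_loc[loc >= rg[1] & loc <= rg[2]] <- TRUE
    is_flex[run[flex_loc]] <- TRUE
    n <- length(run)
    if (n >= 2) {
      i <- run[-n]; j <- run[-1]
      bonds <- rbind(bonds, data.frame(
        i = i - 1L, j = j - 1L, func = 1L,
        b0 = sqrt(rowSums((pos[i, , drop = FALSE] -
                           pos[j, , drop = FALSE])^2)),
        c1 = unname(par["bond_k"]), c2 = 0))
    }
    if (n >= 3) {
      i <- run[1:(n - 2)]; j <- run[2:(n - 1)]; k <- run[3:n]
      angles <- rbind(angles, data.frame(
        i = i - 1L, j = j - 1L, k = k - 1L, func = 21L, theta0 = 0,
        ka = 0, table = "flex_angle", stringsAsFactors = FALSE))
      core <- !(is_flex[i] | is_flex[j] | is_flex[k])
      if (any(core)) {
        gauss13 <- rbind(gauss13, data.frame(
          i = i[core] - 1L, k = k[core] - 1L,
          r0 = vapply(which(core), function(q) .dist3(pos, i[q], k[q]),
                      numeric(1)),
          eps = unname(par["gauss13_eps"]), w = unname(par["gauss13_w"])))
      }
    }
    if (n >= 4) {
      i <- run[1:(n - 3)]; j <- run[2:(n - 2)]
      k <- run[3:(n - 1)]; l <- run[4:n]
      dihedrals <- rbind(dihedrals, data.frame(
        i = i - 1L, j = j - 1L, k = k - 1L, l = l - 1L, func = 22L,
        phi0 = 0, mult = 0, kd = 0, sigma = 0, table = "flex_dihedral",
        stringsAsFactors = FALSE))
      core <- !(is_flex[i] | is_flex[j] | is_flex[k] | is_flex[l])
      if (any(core)) {
        dihedrals <- rbind(dihedrals, data.frame(
          i = i[core] - 1L, j = j[core] - 1L, k = k[core] - 1L,
          l = l[core] - 1L, func = 21L,
          phi0 = vapply(which(core), function(q) {
            .dihedral4(pos, i[q], j[q], k[q], l[q])
          }, numeric(1)),
          mult = 0, kd = unname(par["dihedral_gauss_eps"]),
          sigma = unname(par["dihedral_gauss_sigma"]), table = "",
          stringsAsFactors = FALSE))
      }
    }
  }
  contacts <- detect_native_contacts(mapping, cutoff = contact_cutoff)
  if (nrow(contacts)) {
    keep <- !(is_flex[contacts$i + 1L] | is_flex[contacts$j + 1L])
    contacts <- contacts[keep, , drop = FALSE]
    contacts$eps <- contact_eps
  }
  top <- cg_topology(p, bonds = .or_empty(bonds, "bonds"),
                     angles = .or_empty(angles, "angles"),
                     dihedrals = .or_empty(dihedrals, "dihedrals"),
                     contacts = .or_empty(contacts, "contacts"),
                     gauss13 = .or_empty(gauss13, "gauss13"),
                     exclusions = .min_exclusions(bonds),
                     molecules = .mol_blocks(p))
  attr(top, "nonbonded") <- c("exv", "ele")
  attr(top, "native_positions") <- pos
  top
}

.top_hps <- function(mapping) {
  p <- mapping$particles
  pos <- mapping$positions
  runs <- .chain_runs(p)
  bonds <- NULL
  for (run in runs) {
    n <- length(run)
    if (n >= 2) {
      i <- run[-n]; j <- run[-1]
      bonds <- rbind(bonds, data.frame(
        i = i - 1L, j = j - 1L, func = 1L,
        b0 = ifelse(p$class[i] == "rna", 5.0, 3.8),
        c1 = 2.39, c2 = 0))   # 10 kJ/mol/A^2 in kcal
    }
  }
  top <- cg_topology(p, bonds = .or_empty(bonds, "bonds"),
                     exclusions = .min_exclusions(bonds),
                     molecules = .mol_blocks(p))
  attr(top, "nonbonded") <- c("hps", "ele")
  attr(top, "native_positions") <- pos
  top
}

.top_3spn2c <- function(mapping) {
  sp <- spn2c_parameters()
  p <- mapping$particles
  pos <- mapping$positions
  step_eps <- unname(sp["stack_eps"])
  bonds <- angles <- dihedrals <- stacks <- NULL
  # per-chain site bookkeeping: nucleotides in order with P/S/B indices
  nts <- .nucleotide_sites(p)
  for (ch in nts) {
    nn <- nrow(ch)
    for (q in seq_len(nn)) {
      s <- ch$S[q]; b <- ch$B[q]; ph <- ch$P[q]
      add_bond <- function(i, j) {
        data.frame(i = i - 1L, j = j - 1L, func = 21L,
                   b0 = .dist3(pos, i, j), c1 = unname(sp["bond_k2"]),
                   c2 = unname(sp["bond_k4"]))
      }
      bonds <- rbind(bonds, add_bond(s, b))
      if (!is.na(ph)) bonds <- rbind(bonds, add_bond(ph, s))
      if (q < nn) {
        pn <- ch$P[q + 1]
        bonds <- rbind(bonds, add_bond(s, pn))
        sn <- ch$S[q + 1]; bn <- ch$B[q + 1]
        add_angle <- function(i, j, k) {
          data.frame(i = i - 1L, j = j - 1L, k = k - 1L, func = 1L,
                     theta0 = .angle3(pos, i, j, k),
                     ka = unname(sp["angle_k"]), table = "",
                     stringsAsFactors = FALSE)
        }
        angles <- rbind(angles, add_angle(s, pn, sn), add_angle(b, s, pn))
        if (!is.na(ph)) angles <- rbind(angles, add_angle(ph, s, pn))
        angles <- rbind(angles, add_angle(pn, sn, bn))
        # backbone dihedral S-P(n)-S(n)-P(n+1) where available
        if (q < nn - 0 && q + 1 <= nn) {
          if (q + 1 < nn) {
            pn2 <- ch$P[q + 2]
            dihedrals <- rbind(dihedrals, data.frame(
              i = s - 1L, j = pn - 1L, k = sn - 1L, l = pn2 - 1L,
              func = 21L, phi0 = .dihedral4(pos, s, pn, sn, pn2),
              mult = 0, kd = unname(sp["dihedral_gauss_eps"]),
              sigma = unname(sp["dihedral_gauss_sigma"]), table = "",
              stringsAsFactors = FALSE), data.frame(
              i = s - 1L, j = pn - 1L, k = sn - 1L, l = pn2 - 1L,
              func = 32L, phi0 = .dihedral4(pos, s, pn, sn, pn2) + pi,
              mult = 1, kd = unname(sp["dihedral_periodic_k"]), sigma = 0,
              table = "", stringsAsFactors = FALSE))
          }
        }
        stacks <- rbind(stacks, data.frame(
          i = b - 1L, j = bn - 1L, s = s - 1L, eps = step_eps,
          alpha = unname(sp["stack_alpha"]), r0 = .dist3(pos, b, bn),
          theta0 = .angle3(pos, s, b, bn), gamma = unname(sp["stack_gamma"])))
      }
    }
  }
  # Watson-Crick pairing and cross stacks from the mapping's pairing table
  pairing <- attr(mapping, "pairing")
  basepairs <- crossstacks <- NULL
  if (!is.null(pairing) && nrow(pairing)) {
    allnts <- do.call(rbind, nts)
    site_of <- function(col, nt_id) allnts[[col]][match(nt_id, allnts$id)]
    for (r in seq_len(nrow(pairing))) {
      bi <- site_of("B", pairing$a[r]); bj <- site_of("B", pairing$b[r])
      si <- site_of("S", pairing$a[r]); sj <- site_of("S", pairing$b[r])
      eps_key <- if (p$resname[bi] %in% c("DA", "DT")) "bp_eps_AT" else
        "bp_eps_GC"
      basepairs <- rbind(basepairs, data.frame(
        i = min(bi, bj) - 1L, j = max(bi, bj) - 1L,
        si = (if (bi < bj) si else sj) - 1L,
        sj = (if (bi < bj) sj else si) - 1L,
        eps = unname(sp[eps_key]), alpha = unname(sp["bp_alpha"]),
        r0 = .dist3(pos, bi, bj),
        theta1_0 = .angle3(pos, if (bi < bj) si else sj, min(bi, bj),
                           max(bi, bj)),
        theta2_0 = .angle3(pos, min(bi, bj), max(bi, bj),
                           if (bi < bj) sj else si),
        phi0 = .dihedral4(pos, if (bi < bj) si else sj, min(bi, bj),
                          max(bi, bj), if (bi < bj) sj else si),
        gamma = unname(sp["bp_gamma"])))
      # cross stacks: base i with the neighbors of its partner base
      pb <- pairing$b[r]
      pb_chain <- allnts$chain[match(pb, allnts$id)]
      for (d in c(-1L, 1L)) {
        bj2 <- site_of("B", pb + d)
        same_strand <- identical(allnts$chain[match(pb + d, allnts$id)],
                                 pb_chain)
        if (!is.na(bj2) && !is.na(bi) && same_strand) {
          sx <- site_of("S", pb + d)
          crossstacks <- rbind(crossstacks, data.frame(
            i = min(bi, bj2) - 1L, j = max(bi, bj2) - 1L,
            ai = (if (bi < bj2) si else sx) - 1L,
            aj = (if (bi < bj2) sx else si) - 1L,
            eps = unname(sp["cstk_eps"]), alpha = unname(sp["cstk_alpha"]),
            r0 = .dist3(pos, bi, bj2),
            theta3_0 = .angle3(pos, if (bi < bj2) si else sx,
                               min(bi, bj2), max(bi, bj2)),
            thetaCS_0 = .angle3(pos, min(bi, bj2), max(bi, bj2),
                                if (bi < bj2) sx else si),
            gamma = unname(sp["cstk_gamma"])))
        }
      }
    }
    if (!is.null(crossstacks)) {
      crossstacks <- unique(crossstacks)
    }
  }
  top <- cg_topology(p, bonds = .or_empty(bonds, "bonds"),
                     angles = .or_empty(angles, "angles"),
                     dihedrals = .or_empty(dihedrals, "dihedrals"),
                     stacks = .or_empty(stacks, "stacks"),
                     basepairs = .or_empty(basepairs, "basepairs"),
                     crossstacks = .or_empty(crossstacks, "crossstacks"),
                     exclusions = .min_exclusions(bonds),
                     molecules = .mol_blocks(p))
  attr(top, "nonbonded") <- c("exv", "ele")
  attr(top, "native_positions") <- pos
  top
}

.top_rna <- function(mapping, contact_eps, contact_cutoff) {
  if (is.null(contact_eps)) contact_eps <- 0.3
  if (is.null(contact_cutoff)) contact_cutoff <- 6.5
  p <- mapping$particles
  pos <- mapping$positions
  bonds <- angles <- dihedrals <- NULL
  nts <- .nucleotide_sites(p)
  for (ch in nts) {
    nn <- nrow(ch)
    for (q in seq_len(nn)) {
      s <- ch$S[q]; b <- ch$B[q]; ph <- ch$P[q]
      add_bond <- function(i, j) {
        data.frame(i = i - 1L, j = j - 1L, func = 1L,
                   b0 = .dist3(pos, i, j), c1 = 15, c2 = 0)
      }
      bonds <- rbind(bonds, add_bond(s, b))
      if (!is.na(ph)) bonds <- rbind(bonds, add_bond(ph, s))
      if (q < nn) {
        pn <- ch$P[q + 1]; sn <- ch$S[q + 1]
        bonds <- rbind(bonds, add_bond(s, pn))
        add_angle <- function(i, j, k) {
          data.frame(i = i - 1L, j = j - 1L, k = k - 1L, func = 1L,
                     theta0 = .angle3(pos, i, j, k), ka = 10, table = "",
                     stringsAsFactors = FALSE)
        }
        angles <- rbind(angles, add_angle(s, pn, sn), add_angle(b, s, pn))
        if (!is.na(ph)) angles <- rbind(angles, add_angle(ph, s, pn))
        if (q + 1 < nn) {
          pn2 <- ch$P[q + 2]
          dihedrals <- rbind(dihedrals, data.frame(
            i = s - 1L, j = pn - 1L, k = sn - 1L, l = pn2 - 1L, func = 32L,
            phi0 = .dihedral4(pos, s, pn, sn, pn2) + pi, mult = 1, kd = 0.5,
            sigma = 0, table = "", stringsAsFactors = FALSE))
        }
      }
    }
  }
  contacts <- detect_native_contacts(mapping, cutoff = contact_cutoff)
  if (nrow(contacts)) contacts$eps <- contact_eps
  top <- cg_topology(p, bonds = .or_empty(bonds, "bonds"),
                     angles = .or_empty(angles, "angles"),
                     dihedrals = .or_empty(dihedrals, "dihedrals"),
                     contacts = .or_empty(contacts, "contacts"),
                     exclusions = .min_exclusions(bonds),
                     molecules = .mol_blocks(p))
  attr(top, "nonbonded") <- c("exv", "ele")
  attr(top, "native_positions") <- pos
  top
}

# nucleotide site table per chain: columns id (global nt counter), P, S, B
.nucleotide_sites <- function(p) {
  out <- list()
  ntid <- 0L
  for (ch in unique(p$chain[p$class %in% c("dna", "rna")])) {
    idx <- which(p$chain == ch & p$class %in% c("dna", "rna"))
    resk <- factor(p$resid[idx], levels = unique(p$resid[idx]))
    per_nt <- split(idx, resk)
    rows <- lapply(per_nt, function(g) {
      nm <- p$name[g]
      ntid <<- ntid + 1L
      data.frame(id = ntid, chain = ch,
                 P = if (any(nm %in% c("DP", "RP"))) {
                   g[nm %in% c("DP", "RP")][1]
                 } else NA_integer_,
                 S = g[nm %in% c("DS", "RS")][1],
                 B = g[nm %in% c("DB", "RB")][1],
                 stringsAsFactors = FALSE)
    })
    out[[ch]] <- do.call(rbind, rows)
  }
  out
}

.or_empty <- function(df, kind) {
  if (is.null(df) || nrow(df) == 0) empty_records(kind) else df
}

.min_exclusions <- function(bonds) {
  if (is.null(bonds) || nrow(bonds) == 0) {
    return(matrix(integer(), ncol = 2))
  }
  fake <- list(bonds = bonds)
  bonded_12_13_pairs(fake)
}

# one molecule block per chain
.mol_blocks <- function(p) {
  runs <- .chain_runs(p)
  out <- list()
  for (nm in names(runs)) {
    run <- runs[[nm]]
    out[[length(out) + 1L]] <- list(name = paste0("MOL_", nm),
                                    first = min(run) - 1L,
                                    last = max(run) - 1L)
  }
  out
}

#' Combine several model topologies into one system topology
#'
#' Offsets particle indices, stacks all record tables and merges molecule
#' blocks, exclusions and nonbonded-term tags; optionally adds
#' inter-molecular Go contacts supplied by the caller.
#'
#' @param ... [cg_topology()] objects (or one list of them).
#' @return A combined [cg_topology()].
#' @export
merge_topologies <- function(...) {
  tops <- list(...)
  if (length(tops) == 1 && !inherits(tops[[1]], "cg_topology")) {
    tops <- tops[[1]]
  }
  off <- 0L
  acc <- list()
  for (tb in names(.sec_of_table)) acc[[tb]] <- list()
  particles <- list(); molecules <- list(); excl <- list()
  nonbonded <- character(0); natpos <- list()
  idx_cols <- c("i", "j", "k", "l", "s", "si", "sj", "ai", "aj", "j2",
                "jm", "jp")
  for (top in tops) {
    stopifnot(inherits(top, "cg_topology"))
    particles[[length(particles) + 1L]] <- top$particles
    for (tb in names(.sec_of_table)) {
      df <- top[[tb]]
      if (nrow(df)) {
        for (cl in intersect(idx_cols, names(df))) df[[cl]] <- df[[cl]] + off
        acc[[tb]][[length(acc[[tb]]) + 1L]] <- df
      }
    }
    if (nrow(top$exclusions)) {
      excl[[length(excl) + 1L]] <- top$exclusions + off
    }
    for (m in top$molecules) {
      m$first <- m$first + off; m$last <- m$last + off
      molecules[[length(molecules) + 1L]] <- m
    }
    nonbonded <- union(nonbonded, attr(top, "nonbonded"))
    np <- attr(top, "native_positions")
    natpos[[length(natpos) + 1L]] <-
      if (is.null(np)) matrix(NA_real_, nrow(top$particles), 3) else np
    off <- off + nrow(top$particles)
  }
  args <- list(particles = do.call(rbind, particles),
               exclusions = if (length(excl)) do.call(rbind, excl) else
                 matrix(integer(), ncol = 2),
               molecules = molecules)
  for (tb in names(.sec_of_table)) {
    args[[tb]] <- if (length(acc[[tb]])) do.call(rbind, acc[[tb]]) else
      empty_records(tb)
  }
  out <- do.call(cg_topology, args)
  attr(out, "nonbonded") <- nonbonded
  attr(out, "native_positions") <- do.call(rbind, natpos)
  out
}
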