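#' Map a protein structure to C-alpha particles
#'
#' One CG particle per amino-acid residue, placed on the C-alpha atom.
#' Residues lacking a C-alpha are reported in the mapping report and
#' skipped.
#'
#' @param atoms A [read_structure()] atom table (protein atoms only or
#'   mixed; non-amino-acid residues are ignored).
#' @return Object of class `cg_mapping`: `particles` (particle table),
#'   `positions` (N x 3, A), `groups` (list of atom row indices per
#'   particle, for contact detection), `atoms` (the atom table used),
#'   `report` (a `cg_mapping_report`).
#' @export
map_protein <- function(atoms) {
  aa <- .canon_res(atoms$resname) %in% .AA3
  atoms_p <- atoms[aa, , drop = FALSE]
  if (nrow(atoms_p) == 0) stop("no mappable protein residues")
  resk <- paste(atoms_p$chain, atoms_p$resid)
  resk <- factor(resk, levels = unique(resk))
  groups_all <- split(seq_len(nrow(atoms_p)), resk)
  dropped <- character(0)
  rows <- list(); groups <- list(); pos <- list()
  hps <- hps_parameters()
  for (g in groups_all) {
    ca <- g[atoms_p$name[g] == "CA"]
    if (length(ca) == 0) {
      dropped <- c(dropped, paste0(atoms_p$chain[g[1]], ":",
                                   atoms_p$resid[g[1]], " (no CA)"))
      next
    }
    res <- .canon_res(atoms_p$resname[g[1]])
    hp <- hps[match(res, hps$residue), ]
    k <- length(rows) + 1L
    rows[[k]] <- data.frame(
      name = "CA", class = "protein", resname = res,
      resid = atoms_p$resid[g[1]], chain = atoms_p$chain[g[1]],
      mass = sum(atoms_p$mass[g]), charge = 0,
      radius = if (!is.na(hp$sigma)) hp$sigma / 2 else 2.5,
      lambda = if (!is.na(hp$lambda)) hp$lambda else 0.5,
      sigma = if (!is.na(hp$sigma)) hp$sigma else 5.0,
      eps = if (!is.na(hp$eps)) hp$eps else 0.2,
      stringsAsFactors = FALSE)
    pos[[k]] <- c(atoms_p$x[ca[1]], atoms_p$y[ca[1]], atoms_p$z[ca[1]])
    groups[[k]] <- which(aa)[g]
  }
  if (!length(rows)) stop("no mappable protein residues")
  .mapping(do.call(rbind, rows), do.call(rbind, pos), groups, atoms, dropped)
}

.AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")

.mapping <- function(particles, positions, groups, atoms, dropped) {
  rownames(particles) <- NULL
  by_chain <- table(particles$chain)
  report <- structure(list(
    per_chain = as.data.frame(by_chain, stringsAsFactors = FALSE),
    dropped = dropped, total = nrow(particles)),
    class = "cg_mapping_report")
  structure(list(particles = particles, positions = positions,
                 groups = groups, atoms = atoms, report = report),
            class = "cg_mapping")
}

#' @export
print.cg_mapping_report <- function(x, ...) {
  cat("Mapping report:", x$total, "CG particles\n")
  if (nrow(x$per_chain)) {
    cat("  per chain:", paste(x$per_chain[, 1], x$per_chain[, 2],
                              sep = "=", collapse = ", "), "\n")
  }
  if (length(x$dropped)) {
    cat("  dropped:", paste(x$dropped, collapse = "; "), "\n")
  }
  invisible(x)
}

#' @export
print.cg_mapping <- function(x, ...) print(x$report)

# atom-name classification for nucleotides
.NUC_P <- c("P", "OP1", "OP2", "O1P", "O2P", "O5'", "O5*")
.NUC_S <- c("C5'", "C4'", "C3'", "C2'", "C1'", "O4'", "O3'", "O2'",
            "C5*", "C4*", "C3*", "C2*", "C1*", "O4*", "O3*", "O2*")

#' Map nucleic-acid chains to three-site particles
#'
#' Each nucleotide becomes phosphate (P), sugar (S) and base (B) particles
#' placed at the center of mass of the group's heavy atoms.  The 5'-terminal
#' nucleotide has no phosphate, so a strand of n nucleotides maps to 3n - 1
#' particles.
#'
#' @param atoms A [read_structure()] atom table.
#' @param class `"dna"` or `"rna"`.
#' @return A `cg_mapping` (see [map_protein()]).
#' @export
map_nucleic <- function(atoms, class = c("dna", "rna")) {
  class <- match.arg(class)
  resmap <- if (class == "dna") {
    c(DA = "DA", DC = "DC", DG = "DG", DT = "DT",
      A = "DA", C = "DC", G = "DG", T = "DT")
  } else {
    c(A = "RA", C = "RC", G = "RG", U = "RU",
      RA = "RA", RC = "RC", RG = "RG", RU = "RU")
  }
  keep <- toupper(atoms$resname) %in% names(resmap)
  atoms_n <- atoms[keep, , drop = FALSE]
  if (nrow(atoms_n) == 0) stop("no mappable ", class, " nucleotides")
  unknown <- setdiff(toupper(atoms$resname), c(names(resmap), .AA3,
                                               "HOH", "WAT"))
  sp <- spn2c_parameters()
  prefix <- if (class == "dna") "D" else "R"
  rows <- list(); groups <- list(); pos <- list()
  dropped <- character(0)
  for (ch in unique(atoms_n$chain)) {
    ach <- atoms_n[atoms_n$chain == ch, , drop = FALSE]
    resk <- factor(paste(ach$resid), levels = unique(paste(ach$resid)))
    res_groups <- split(seq_len(nrow(ach)), resk)
    first <- TRUE
    for (g in res_groups) {
      res <- resmap[toupper(ach$resname[g[1]])]
      base_letter <- substr(res, 2, 2)
      nm <- ach$name[g]
      p_names <- c("P", "OP1", "OP2", "O1P", "O2P")
      s_names <- c(.NUC_S, "O5'", "O5*")
      grp <- list(P = g[nm %in% p_names],
                  S = g[nm %in% s_names],
                  B = g[!(nm %in% c(p_names, s_names))])
      for (site in c("P", "S", "B")) {
        if (site == "P" && (first || length(grp$P) == 0)) next
        ga <- grp[[site]]
        if (length(ga) == 0) {
          dropped <- c(dropped, paste0(ch, ":", ach$resid[g[1]], " (no ",
                                       site, " atoms)"))
          next
        }
        m <- ach$mass[ga]
        com <- c(sum(ach$x[ga] * m), sum(ach$y[ga] * m),
                 sum(ach$z[ga] * m)) / sum(m)
        sitename <- paste0(prefix, site)
        radius <- unname(sp[paste0("radius_",
                                   if (site == "B") "B" else site)])
        k <- length(rows) + 1L
        rows[[k]] <- data.frame(
          name = sitename, class = class, resname = res,
          resid = ach$resid[g[1]], chain = ch, mass = sum(m),
          charge = 0, radius = radius, lambda = 0,
          sigma = 2 * radius, eps = 0.2, stringsAsFactors = FALSE)
        pos[[k]] <- com
        groups[[k]] <- which(keep)[which(atoms_n$chain == ch)[ga]]
      }
      first <- FALSE
    }
  }
  if (!length(rows)) stop("no mappable ", class, " nucleotides")
  .mapping(do.call(rbind, rows), do.call(rbind, pos), groups, atoms,
           dropped)
}

#' Detect Go-type native contacts
#'
#' A pair of CG particles is a native contact when their atom groups contain
#' heavy atoms closer than the cutoff in the native structure and the pair
#' is at least `min_sep` positions apart along its chain (inter-chain pairs
#' always qualify).  The contact distance sigma is the native site-site
#' distance.  Results are ordered i < j and independent of chain input
#' order.
#'
#' @param mapping A `cg_mapping` (or a list of them, already merged by
#'   [merge_mappings()]).
#' @param cutoff Heavy-atom cutoff, A (default 6.5, the conventional
#'   Go-model choice).
#' @param min_sep Minimum intra-chain index separation (default 4).
#' @return Contact record data.frame (`i`, `j`, `sigma`, `eps` = NA to be
#'   filled by the model builder).
#' @export
detect_native_contacts <- function(mapping, cutoff = 6.5, min_sep = 4L) {
  atoms <- mapping$atoms
  groups <- mapping$groups
  n <- length(groups)
  atom_xyz <- as.matrix(atoms[, c("x", "y", "z")])
  owner <- integer(nrow(atom_xyz))
  for (k in seq_len(n)) owner[groups[[k]]] <- k
  used <- which(owner > 0)
  ap <- cpp_build_pairs(atom_xyz, c(0, 0, 0), FALSE, used - 1L, integer(0),
                        FALSE, cutoff, matrix(integer(), ncol = 2))$pairs
  if (nrow(ap) == 0) {
    return(empty_records("contacts"))
  }
  gi <- owner[ap[, 1] + 1L]; gj <- owner[ap[, 2] + 1L]
  swap <- gi > gj
  tmp <- gi[swap]; gi[swap] <- gj[swap]; gj[swap] <- tmp
  keep <- gi != gj
  key <- unique(cbind(gi[keep], gj[keep]))
  if (nrow(key) == 0) return(empty_records("contacts"))
  p <- mapping$particles
  same_chain <- p$chain[key[, 1]] == p$chain[key[, 2]]
  # separation counted in residue/nucleotide numbers along the chain
  sep <- abs(p$resid[key[, 1]] - p$resid[key[, 2]])
  key <- key[!same_chain | sep >= min_sep, , drop = FALSE]
  if (nrow(key) == 0) return(empty_records("contacts"))
  d <- sqrt(rowSums((mapping$positions[key[, 1], , drop = FALSE] -
                     mapping$positions[key[, 2], , drop = FALSE])^2))
  out <- data.frame(i = key[, 1] - 1L, j = key[, 2] - 1L, sigma = d,
                    eps = NA_real_)
  out <- out[order(out$i, out$j), ]
  rownames(out) <- NULL
  out
}

#' Merge mappings of several molecules into one
#'
#' Concatenates particle tables, positions and atom groups with a global
#' numbering (atom tables are stacked too, so contact detection across
#' molecules works).
#'
#' @param ... `cg_mapping` objects (or one list of them).
#' @return A merged `cg_mapping` whose report nests the inputs' totals.
#' @export
merge_mappings <- function(...) {
  maps <- list(...)
  if (length(maps) == 1 && !inherits(maps[[1]], "cg_mapping")) {
    maps <- maps[[1]]
  }
  atom_off <- 0L
  rows <- list(); pos <- list(); groups <- list(); atoms <- list()
  for (m in maps) {
    stopifnot(inherits(m, "cg_mapping"))
    rows[[length(rows) + 1L]] <- m$particles
    pos[[length(pos) + 1L]] <- m$positions
    groups <- c(groups, lapply(m$groups, function(g) g + atom_off))
    atoms[[length(atoms) + 1L]] <-
      m$atoms[, c("element", "name", "resname", "resid", "chain", "x", "y",
                  "z", "mass")]
    atom_off <- atom_off + nrow(m$atoms)
  }
  all_atoms <- do.call(rbind, atoms)
  class(all_atoms) <- c("cg_atoms", "data.frame")
  .mapping(do.call(rbind, rows), do.call(rbind, pos), groups, all_atoms,
           character(0))
}

#' Assign particle charges
#'
#' Scheme `"integer"`: Arg/Lys +1 e, Asp/Glu -1 e, all other amino acids 0;
#' DNA/RNA phosphate sites (and one-bead RNA nucleotides) get the phosphate
#' charge (default -1 e, scalable).  Scheme `"file"`: per-particle charges
#' read verbatim from a two-column table (index, charge) such as a surface
#' charge calculation's output.
#'
#' @param top A [cg_topology()].
#' @param scheme `"integer"` or `"file"`.
#' @param path Charge table for the file scheme: whitespace-separated
#'   `index charge`, 1-based indices.
#' @param phosphate_charge Charge for nucleic phosphates, e.
#' @return The topology with charges filled in.
#' @export
assign_charges <- function(top, scheme = c("integer", "file"), path = NULL,
                           phosphate_charge = -1) {
  scheme <- match.arg(scheme)
  p <- top$particles
  if (scheme == "integer") {
    ch <- numeric(nrow(p))
    ch[p$resname %in% c("ARG", "LYS")] <- 1
    ch[p$resname %in% c("ASP", "GLU")] <- -1
    ch[p$name %in% c("DP", "RP")] <- phosphate_charge
    ch[p$name == "NT"] <- phosphate_charge       # one-bead RNA nucleotide
    top$particles$charge <- ch
  } else {
    stopifnot(!is.null(path))
    tb <- utils::read.table(path, col.names = c("index", "charge"))
    if (any(tb$index < 1 | tb$index > nrow(p))) {
      stop("charge file indexes particles outside the topology")
    }
    if (anyDuplicated(tb$index)) stop("duplicate particle in charge file")
    ch <- numeric(nrow(p))
    ch[tb$index] <- tb$charge
    top$particles$charge <- ch
  }
  top
}
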