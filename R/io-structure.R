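# Atomistic structure input.  Parsing of PDB and PDBx/mmCIF is delegated to
# bio3d; this layer normalises both dialects into one atom table, drops
# hydrogens (CG mapping uses heavy atoms only) and resolves alternate
# locations to the highest-occupancy copy.

.ATOMIC_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                  P = 30.974, S = 32.06, SE = 78.971, FE = 55.845,
                  ZN = 65.38, MG = 24.305, NA. = 22.990, K = 39.098,
                  CL = 35.45, BR = 79.904, I = 126.904)

#' Read an atomistic structure (PDB or PDBx/mmCIF)
#'
#' Heavy atoms are retained with their chain/residue hierarchy; hydrogens
#' are dropped; alternate locations are resolved to the highest-occupancy
#' copy.  The two dialects yield identical atom tables for the same content.
#'
#' @param path Structure file; dialect chosen by extension (`.cif` /
#'   `.mmcif` vs anything else = PDB).
#' @return Object of class `cg_atoms`: data.frame with `element`, `name`,
#'   `resname`, `resid`, `chain`, `x`, `y`, `z` (A), `mass` (amu).
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("no such structure file: ", path)
  is_cif <- grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)
  pdb <- if (is_cif) suppressWarnings(bio3d::read.cif(path)) else {
    bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
  }
  a <- pdb$atom
  if (is.null(a) || nrow(a) == 0) stop("empty model in ", path)
  elem <- toupper(trimws(a$elesy))
  guess <- is.na(elem) | elem == ""
  if (any(guess)) {
    elem[guess] <- substr(gsub("[0-9']", "", trimws(a$elety[guess])), 1, 1)
  }
  atoms <- data.frame(element = elem, name = trimws(a$elety),
                      resname = trimws(a$resid), resid = a$resno,
                      chain = ifelse(is.na(a$chain) | a$chain == "",
                                     "A", a$chain),
                      x = a$x, y = a$y, z = a$z,
                      o = if (!is.null(a$o)) ifelse(is.na(a$o), 1, a$o)
                          else 1,
                      alt = if (!is.null(a$alt)) {
                        ifelse(is.na(a$alt), "", a$alt)
                      } else "",
                      stringsAsFactors = FALSE)
  atoms <- atoms[atoms$element != "H" & atoms$element != "D", , drop = FALSE]
  if (nrow(atoms) == 0) stop("no heavy atoms in ", path)
  # resolve altlocs: per (chain, resid, name) keep the highest occupancy
  atoms$.row <- seq_len(nrow(atoms))
  key <- paste(atoms$chain, atoms$resid, atoms$name)
  if (anyDuplicated(key)) {
    ord <- order(key, -atoms$o)
    atoms <- atoms[ord, ][!duplicated(key[ord]), ]
    atoms <- atoms[order(atoms$.row), ]
  }
  atoms$.row <- NULL
  atoms$mass <- unname(.ATOMIC_MASS[atoms$element])
  atoms$mass[is.na(atoms$mass)] <- 12.011
  atoms$o <- NULL
  atoms$alt <- NULL
  rownames(atoms) <- NULL
  class(atoms) <- c("cg_atoms", "data.frame")
  atoms
}

#' Write an atom table as a PDB file
#'
#' @param atoms A `cg_atoms` table (or compatible data.frame).
#' @param path Output file.
#' @return Invisibly `path`.
#' @export
write_structure <- function(atoms, path) {
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(atoms[, c("x", "y", "z")]))),
                   resno = atoms$resid, resid = atoms$resname,
                   eleno = seq_len(nrow(atoms)), elety = atoms$name,
                   chain = atoms$chain, elesy = atoms$element)
  invisible(path)
}

#' @export
print.cg_atoms <- function(x, ...) {
  cat("Atomistic model:", nrow(x), "heavy atoms,",
      length(unique(paste(x$chain, x$resid))), "residues,",
      length(unique(x$chain)), "chain(s)\n")
  invisible(x)
}
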