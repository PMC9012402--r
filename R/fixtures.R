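#' Synthetic test systems
#'
#' Deterministic generators for the systems used throughout the package's
#' tests and examples:
#' \describe{
#'   \item{helix_ca}{ideal alpha-helical C-alpha trace (100 deg twist,
#'     2.3 A radius, rise chosen so consecutive C-alphas are exactly 3.8 A
#'     apart) with one outward pseudo side-chain atom per residue, as a
#'     `cg_atoms` table ready for mapping and contact detection.}
#'   \item{idp_chain}{synthetic disordered chain(s): a low-complexity
#'     G/S/Q/Y-rich composition (emulating the prion-like domains studied in
#'     phase-separation work), self-avoiding random-walk coordinates with
#'     3.8 A bonds.  `copies` chains are laid out on a grid.  Returns a
#'     `cg_mapping`.}
#'   \item{toy_dsdna}{sequence-built B-DNA duplex
#'     ([build_dsdna_from_sequence()]); `n` base pairs of a poly-CG
#'     sequence unless `seq` is given.}
#'   \item{multi_chain_slab}{replicates a chain mapping into an orthorhombic
#'     box without inter-chain contacts closer than `tol`; chains get
#'     deterministic random positions and orientations.  Returns a merged
#'     `cg_mapping` with a `box` attribute.}
#' }
#'
#' @param kind One of `"helix_ca"`, `"idp_chain"`, `"toy_dsdna"`,
#'   `"multi_chain_slab"`.
#' @param n Size: residues (helix, idp), base pairs (dsdna), chains (slab).
#' @param seed Integer seed; all randomness is reproducible.
#' @param ... Kind-specific parameters: `sequence`, `copies` (idp_chain);
#'   `seq` (toy_dsdna); `chain` (a `cg_mapping`), `box` (length-3, A),
#'   `tol` (minimum inter-chain distance, A) for multi_chain_slab.
#' @return See the list above.
#' @export
make_fixture <- function(kind = c("helix_ca", "idp_chain", "toy_dsdna",
                                  "multi_chain_slab"),
                         n = 20, seed = 1, ...) {
  kind <- match.arg(kind)
  switch(kind,
         helix_ca = .fix_helix(n, ...),
         idp_chain = .fix_idp(n, seed, ...),
         toy_dsdna = .fix_dsdna(n, ...),
         multi_chain_slab = .fix_slab(n, seed, ...))
}

.fix_helix <- function(n, residues = NULL) {
  stopifnot(n >= 2)
  radius <- 2.3
  twist <- 100 * pi / 180
  chord <- 2 * radius * sin(twist / 2)
  rise <- sqrt(3.8^2 - chord^2)      # consecutive Ca distance exactly 3.8
  i <- seq_len(n) - 1
  ca <- cbind(radius * cos(i * twist), radius * sin(i * twist), i * rise)
  cb <- cbind(4.3 * cos(i * twist), 4.3 * sin(i * twist), i * rise)
  if (is.null(residues)) residues <- rep("ALA", n)
  atoms <- data.frame(
    element = rep(c("C", "C"), n),
    name = rep(c("CA", "CB"), n),
    resname = rep(residues, each = 2),
    resid = rep(seq_len(n), each = 2),
    chain = "A",
    x = as.numeric(rbind(ca[, 1], cb[, 1])),
    y = as.numeric(rbind(ca[, 2], cb[, 2])),
    z = as.numeric(rbind(ca[, 3], cb[, 3])),
    mass = 12.011, stringsAsFactors = FALSE)
  class(atoms) <- c("cg_atoms", "data.frame")
  atoms
}

# low-complexity composition emulating prion-like IDR domains (approximate
# residue fractions of the FUS low-complexity region: Q/G/S/Y-rich with a
# substantial tyrosine content, nearly uncharged)
.IDP_COMPOSITION <- c(GLY = 0.19, SER = 0.22, GLN = 0.21, TYR = 0.15,
                      THR = 0.06, PRO = 0.08, ALA = 0.04, ASN = 0.03,
                      ASP = 0.02)

#' Synthetic low-complexity IDR sequence
#'
#' @param n Length (residues).
#' @param seed Seed.
#' @return Character vector of three-letter residue names.
#' @export
idp_sequence <- function(n, seed = 1) {
  set.seed(seed)
  sample(names(.IDP_COMPOSITION), n, replace = TRUE,
         prob = .IDP_COMPOSITION)
}

.fix_idp <- function(n, seed, sequence = NULL, copies = 1L,
                     spacing = NULL) {
  if (is.null(sequence)) sequence <- idp_sequence(n, seed)
  stopifnot(length(sequence) == n)
  set.seed(seed + 1L)
  # one self-avoiding random walk; copies are grid-translated replicas
  pos <- matrix(0, n, 3)
  for (i in seq_len(n)[-1]) {
    for (try in 1:200) {
      d <- stats::rnorm(3)
      cand <- pos[i - 1, ] + 3.8 * d / sqrt(sum(d^2))
      prev <- pos[seq_len(i - 1), , drop = FALSE]
      if (i == 2 || min(rowSums((prev - matrix(cand, i - 1, 3,
                                               TRUE))^2)) > 3.5^2) {
        pos[i, ] <- cand
        break
      }
      if (try == 200) stop("random walk failed to extend")
    }
  }
  hps <- hps_parameters()
  hp <- hps[match(sequence, hps$residue), ]
  one <- data.frame(name = "CA", class = "protein", resname = sequence,
                    resid = seq_len(n), chain = "A", mass = hp$mass,
                    charge = hp$charge, radius = hp$sigma / 2,
                    lambda = hp$lambda, sigma = hp$sigma, eps = hp$eps,
                    stringsAsFactors = FALSE)
  copies <- as.integer(copies)
  if (is.null(spacing)) spacing <- 2 * (max(pos) - min(pos) + 10)
  grid_n <- ceiling(copies^(1 / 3))
  k <- seq_len(copies) - 1L
  shift <- cbind(k %% grid_n, (k %/% grid_n) %% grid_n,
                 k %/% (grid_n^2)) * spacing
  particles <- one[rep(seq_len(n), copies), ]
  particles$chain <- rep(sprintf("C%04d", seq_len(copies)), each = n)
  rownames(particles) <- NULL
  positions <- pos[rep(seq_len(n), copies), , drop = FALSE] +
    shift[rep(seq_len(copies), each = n), , drop = FALSE]
  atoms <- data.frame(element = "C", name = "CA",
                      resname = particles$resname,
                      resid = particles$resid, chain = particles$chain,
                      x = positions[, 1], y = positions[, 2],
                      z = positions[, 3], mass = particles$mass,
                      stringsAsFactors = FALSE)
  class(atoms) <- c("cg_atoms", "data.frame")
  .mapping(particles, positions, as.list(seq_len(n * copies)), atoms,
           character(0))
}

.fix_dsdna <- function(n, seq = NULL) {
  if (is.null(seq)) {
    seq <- paste(rep(c("C", "G"), length.out = n), collapse = "")
  }
  build_dsdna_from_sequence(seq)
}

.fix_slab <- function(n, seed, chain, box, tol = 3.0, max_tries = 400L) {
  stopifnot(inherits(chain, "cg_mapping"), length(box) == 3)
  set.seed(seed)
  nres <- nrow(chain$particles)
  com <- colMeans(chain$positions)
  centered <- sweep(chain$positions, 2, com)
  placed <- list()
  all_pos <- NULL
  for (c_i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      u <- stats::rnorm(4)
      u <- u / sqrt(sum(u^2))        # uniform random rotation (quaternion)
      R <- .quat_rot(u)
      cand <- centered %*% t(R)
      shiftv <- stats::runif(3) * box
      cand <- sweep(cand, 2, shiftv, "+")
      if (is.null(all_pos)) { ok <- TRUE }
      else {
        np <- nrow(all_pos)
        test <- rbind(all_pos, cand)
        prs <- cpp_build_pairs(test, box, TRUE,
                               seq_len(np) - 1L,
                               np + seq_len(nres) - 1L, TRUE, tol,
                               matrix(integer(), ncol = 2))$pairs
        ok <- nrow(prs) == 0
      }
      if (ok) break
    }
    if (!ok) stop("impossible packing: could not place chain ", c_i,
                  " without contacts closer than ", tol, " A")
    placed[[c_i]] <- cand
    all_pos <- rbind(all_pos, cand)
  }
  maps <- lapply(seq_len(n), function(c_i) {
    m <- chain
    m$positions <- placed[[c_i]]
    m$particles$chain <- sprintf("C%04d", c_i)
    m$atoms$chain <- sprintf("C%04d", c_i)
    m$atoms$x <- placed[[c_i]][, 1]
    m$atoms$y <- placed[[c_i]][, 2]
    m$atoms$z <- placed[[c_i]][, 3]
    m
  })
  out <- merge_mappings(maps)
  attr(out, "box") <- box
  out
}

.quat_rot <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}
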