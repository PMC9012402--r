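# Sequence-to-structure dsDNA builder.  Base-pair frames are composed from
# a sequence-dependent base-step parameter table (twist/roll/tilt/shift/
# slide/rise per dinucleotide); within each frame, one pseudo-atom per CG
# site (phosphate, sugar, base) is placed from a fixed local template with
# B-DNA-like radii, the second strand generated by the dyad symmetry
# (x, -y, -z).  The pseudo-atoms carry the full heavy-atom group masses, so
# the subsequent CG mapping reproduces correct bead masses and positions;
# this is a synthetic atomistic model aimed at CG work, not an all-atom
# reconstruction.

# local site template, strand 1, bp frame coordinates (A)
.DNA_SITE_LOCAL <- list(P = c(4.61, 7.63, -0.46),
                        S = c(1.67, 6.70, 1.20),
                        B = c(1.84, 2.62, 0.00))

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

.rot_z <- function(a) {
  matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3,
         byrow = TRUE)
}
.rot_y <- function(a) {
  matrix(c(cos(a), 0, sin(a), 0, 1, 0, -sin(a), 0, cos(a)), 3, 3,
         byrow = TRUE)
}
.rot_x <- function(a) {
  matrix(c(1, 0, 0, 0, cos(a), -sin(a), 0, sin(a), cos(a)), 3, 3,
         byrow = TRUE)
}

#' Build double-stranded DNA from sequence alone
#'
#' Composes base-pair frames step by step from the packaged (or supplied)
#' sequence-dependent base-step table, emits both strands with the
#' complementary sequence, and maps the result to CG particles.  With a
#' homogeneous table (pure twist and rise) the construction is an exact
#' circular helix.
#'
#' @param seq DNA sequence over A/C/G/T (a string), length >= 2; this is
#'   the 5'->3' sequence of strand A.
#' @param step_table Base-step parameter table (default
#'   [base_step_table()]).
#' @return A `cg_mapping` whose `atoms` field is the synthetic atomistic
#'   model (one pseudo-atom per CG site) and which carries a `pairing`
#'   attribute (data.frame `a`, `b` of paired nucleotide ids) used by the
#'   DNA model builder; `frames` attribute holds the 4x4 bp frames.
#' @examples
#' dna <- build_dsdna_from_sequence("ACGTACGT")
#' nrow(dna$particles)  # 2 * (3*8 - 1) = 46
#' @export
build_dsdna_from_sequence <- function(seq, step_table = NULL) {
  letters1 <- strsplit(toupper(seq), "")[[1]]
  if (length(letters1) < 2) stop("sequence must have length >= 2")
  if (!all(letters1 %in% c("A", "C", "G", "T"))) {
    stop("invalid characters in DNA sequence: ",
         paste(setdiff(letters1, c("A", "C", "G", "T")), collapse = ""))
  }
  if (is.null(step_table)) step_table <- base_step_table()
  n <- length(letters1)
  deg <- pi / 180
  # compose frames
  R <- diag(3); o <- c(0, 0, 0)
  frames <- vector("list", n)
  frames[[1]] <- list(R = R, o = o)
  for (i in 2:n) {
    st <- step_table[step_table$step == paste0(letters1[i - 1],
                                               letters1[i]), ]
    if (nrow(st) != 1) {
      stop("base-step table lacks step ", letters1[i - 1], letters1[i])
    }
    o <- o + R %*% c(st$shift, st$slide, st$rise)
    R <- R %*% .rot_z(st$twist * deg) %*% .rot_y(st$roll * deg) %*%
      .rot_x(st$tilt * deg)
    frames[[i]] <- list(R = R, o = as.numeric(o))
  }
  sp <- spn2c_parameters()
  site_mass <- c(P = unname(sp["mass_P"]), S = unname(sp["mass_S"]))
  base_mass <- c(A = unname(sp["mass_A"]), C = unname(sp["mass_C"]),
                 G = unname(sp["mass_G"]), T = unname(sp["mass_T"]))
  atom_rows <- list()
  emit <- function(strand, chain, order_bp) {
    first <- TRUE
    resid <- 0L
    for (bp in order_bp) {
      resid <- resid + 1L
      fr <- frames[[bp]]
      letter <- if (strand == 1) letters1[bp] else
        .COMPLEMENT[letters1[bp]]
      mirror <- if (strand == 1) c(1, 1, 1) else c(1, -1, -1)
      for (site in c("P", "S", "B")) {
        if (site == "P" && first) next
        loc <- .DNA_SITE_LOCAL[[site]] * mirror
        xyz <- as.numeric(fr$o + fr$R %*% loc)
        atom_rows[[length(atom_rows) + 1L]] <<- data.frame(
          element = c(P = "P", S = "C", B = "N")[site],
          name = c(P = "P", S = "C4'", B = "N1")[site],
          resname = paste0("D", letter), resid = resid, chain = chain,
          x = xyz[1], y = xyz[2], z = xyz[3],
          mass = if (site == "B") unname(base_mass[letter]) else
            site_mass[site],
          stringsAsFactors = FALSE)
      }
      first <- FALSE
    }
  }
  emit(1, "A", seq_len(n))
  emit(2, "B", rev(seq_len(n)))
  atoms <- do.call(rbind, atom_rows)
  class(atoms) <- c("cg_atoms", "data.frame")
  mapping <- map_nucleic(atoms, "dna")
  # nucleotide ids: strand A 1..n (bp order), strand B n+1..2n (3'->5' of A)
  pairing <- data.frame(a = seq_len(n), b = n + rev(seq_len(n)))
  attr(mapping, "pairing") <- pairing
  attr(mapping, "frames") <- frames
  attr(mapping, "sequence") <- paste(letters1, collapse = "")
  mapping
}
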