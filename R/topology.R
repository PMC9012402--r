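#' Coarse-grained topology container
#'
#' Holds every particle and interaction record of a CG system.  All particle
#' indices are 0-based internally (text formats use 1-based numbering) and
#' global across molecule blocks.  Interaction pairs are stored with i < j.
#'
#' Record tables (all `data.frame`s; empty tables allowed):
#' \describe{
#'   \item{particles}{`name` (CA, DP, DS, DB, RP, RS, RB, NT), `class`
#'     (protein/dna/rna), `resname`, `resid`, `chain`, `mass` (amu), `charge`
#'     (e), `radius` (excluded-volume radius, A), `lambda` (hydropathy),
#'     `sigma` (pair diameter, A), `eps` (pair well depth, kcal/mol).}
#'   \item{bonds}{`i`, `j`, `func` (1 harmonic, 21 quartic), `b0`, `c1`,
#'     `c2` (harmonic: `c1` = k; quartic: `c1` = k2, `c2` = k3).}
#'   \item{angles}{`i`, `j`, `k`, `func` (1 harmonic, 21 tabulated),
#'     `theta0` (rad), `ka`, `table` (table name for func 21).}
#'   \item{dihedrals}{`i`, `j`, `k`, `l`, `func` (1 periodic, 21 Gaussian,
#'     22 tabulated, 32 periodic with safe force fallback), `phi0` (rad),
#'     `mult`, `kd` (k_phi or eps_phi), `sigma` (Gaussian width, rad),
#'     `table`.}
#'   \item{contacts}{native contacts: `i`, `j`, `sigma` (native distance,
#'     A), `eps` (kcal/mol).}
#'   \item{gauss13}{1-3 Gaussian terms: `i`, `k`, `r0`, `eps`, `w`.}
#'   \item{stacks}{intra-strand base stacking: bases `i`, `j`, sugar `s`
#'     (defines the stacking angle s-i-j), `eps`, `alpha` (1/A), `r0`,
#'     `theta0`, `gamma`.}
#'   \item{basepairs}{Watson-Crick pairs: bases `i`, `j`, sugars `si`, `sj`
#'     (angles si-i-j and i-j-sj; dihedral si-i-j-sj), `eps`, `alpha`, `r0`,
#'     `theta1_0`, `theta2_0`, `phi0`, `gamma`.}
#'   \item{crossstacks}{cross-strand stacking: bases `i`, `j`, angle anchors
#'     `ai`, `aj` (angles ai-i-j and i-j-aj), `eps`, `alpha`, `r0`,
#'     `theta3_0`, `thetaCS_0`, `gamma`.}
#'   \item{pwmcos}{DNA-binding C-alpha sites: `j` (C-alpha), `jm`, `jp`
#'     (flanking C-alphas), `m` (PWM column), `r0`, `theta1_0`, `theta2_0`,
#'     `theta3_0`, `gamma`, `gamma_pwm` (scale), `eps_shift`.}
#'   \item{hb}{backbone hydrogen-bond sites: `i` (phosphate), `j`
#'     (C-alpha), `si` (sugar of i), `j2` (C-alpha neighbor), `r0`,
#'     `theta1_0`, `theta2_0`, `gamma`, `eps`.}
#'   \item{exclusions}{2-column integer matrix of nonbonded exclusions.}
#'   \item{molecules}{list of blocks: `name`, `first`, `last` (0-based
#'     particle range), optional `itp` provenance.}
#' }
#'
#' @param particles Particle table (see above).
#' @param bonds,angles,dihedrals,contacts,gauss13 Bonded/contact records.
#' @param stacks,basepairs,crossstacks,pwmcos,hb DNA / protein-DNA site
#'   records.
#' @param exclusions 2-column matrix.
#' @param molecules List of molecule blocks.
#' @param validate Check invariants (default TRUE).
#' @return Object of class `cg_topology`.
#' @export
cg_topology <- function(particles,
                        bonds = empty_records("bonds"),
                        angles = empty_records("angles"),
                        dihedrals = empty_records("dihedrals"),
                        contacts = empty_records("contacts"),
                        gauss13 = empty_records("gauss13"),
                        stacks = empty_records("stacks"),
                        basepairs = empty_records("basepairs"),
                        crossstacks = empty_records("crossstacks"),
                        pwmcos = empty_records("pwmcos"),
                        hb = empty_records("hb"),
                        exclusions = matrix(integer(), ncol = 2),
                        molecules = list(),
                        validate = TRUE) {
  top <- structure(list(particles = particles, bonds = bonds, angles = angles,
                        dihedrals = dihedrals, contacts = contacts,
                        gauss13 = gauss13, stacks = stacks,
                        basepairs = basepairs, crossstacks = crossstacks,
                        pwmcos = pwmcos, hb = hb,
                        exclusions = exclusions, molecules = molecules),
                   class = "cg_topology")
  if (length(molecules) == 0) {
    top$molecules <- list(list(name = "MOL1", first = 0L,
                               last = nrow(particles) - 1L))
  }
  if (validate) validate_topology(top)
  top
}

#' Empty interaction-record table of a given kind
#' @param kind Record table name (see [cg_topology()]).
#' @return Zero-row data.frame with the right columns.
#' @export
empty_records <- function(kind) {
  cols <- switch(kind,
    particles = c("name", "class", "resname", "resid", "chain", "mass",
                  "charge", "radius", "lambda", "sigma", "eps"),
    bonds = c("i", "j", "func", "b0", "c1", "c2"),
    angles = c("i", "j", "k", "func", "theta0", "ka", "table"),
    dihedrals = c("i", "j", "k", "l", "func", "phi0", "mult", "kd", "sigma",
                  "table"),
    contacts = c("i", "j", "sigma", "eps"),
    gauss13 = c("i", "k", "r0", "eps", "w"),
    stacks = c("i", "j", "s", "eps", "alpha", "r0", "theta0", "gamma"),
    basepairs = c("i", "j", "si", "sj", "eps", "alpha", "r0", "theta1_0",
                  "theta2_0", "phi0", "gamma"),
    crossstacks = c("i", "j", "ai", "aj", "eps", "alpha", "r0", "theta3_0",
                    "thetaCS_0", "gamma"),
    pwmcos = c("j", "jm", "jp", "m", "r0", "theta1_0", "theta2_0",
               "theta3_0", "gamma", "gamma_pwm", "eps_shift", "w"),
    hb = c("i", "j", "si", "j2", "r0", "theta1_0", "theta2_0", "gamma",
           "eps", "w"),
    stop("unknown record kind: ", kind))
  chr <- cols %in% c("name", "class", "resname", "chain", "table")
  df <- as.data.frame(stats::setNames(
    lapply(chr, function(is_chr) if (is_chr) character() else numeric()),
    cols))
  df
}

#' Validate a CG topology
#'
#' Checks index ranges, i < j ordering and uniqueness of pair records,
#' positivity of masses, radii and widths, and that the exclusion list
#' contains every 1-2 and 1-3 bonded pair.
#'
#' @param top A [cg_topology()].
#' @return Invisibly TRUE; stops with a message on the first violation.
#' @export
validate_topology <- function(top) {
  n <- nrow(top$particles)
  chk_idx <- function(v, what) {
    v <- as.integer(v)
    if (length(v) && (min(v) < 0 || max(v) >= n)) {
      stop("index out of range in ", what, " records")
    }
  }
  for (tab in c("bonds", "angles", "dihedrals", "contacts", "gauss13",
                "stacks", "basepairs", "crossstacks", "hb")) {
    df <- top[[tab]]
    for (col in intersect(c("i", "j", "k", "l", "s", "si", "sj", "ai", "aj",
                            "j2"), names(df))) {
      chk_idx(df[[col]], tab)
    }
  }
  for (col in c("j", "jm", "jp")) chk_idx(top$pwmcos[[col]], "pwmcos")
  if (nrow(top$contacts)) {
    if (any(top$contacts$i >= top$contacts$j)) {
      stop("contact pairs must be stored with i < j")
    }
    key <- paste(top$contacts$i, top$contacts$j)
    if (anyDuplicated(key)) stop("duplicate contact pairs")
    if (any(top$contacts$sigma <= 0)) stop("contact sigma must be > 0")
  }
  if (nrow(top$bonds)) {
    key <- paste(pmin(top$bonds$i, top$bonds$j),
                 pmax(top$bonds$i, top$bonds$j))
    if (anyDuplicated(key)) stop("duplicate bond records")
    if (any(top$bonds$b0 <= 0)) stop("bond b0 must be > 0")
  }
  p <- top$particles
  if (any(p$mass <= 0)) stop("particle masses must be > 0")
  if (any(p$radius <= 0)) stop("excluded-volume radii must be > 0")
  if (any(p$sigma <= 0)) stop("pair diameters must be > 0")
  if (nrow(top$gauss13) && any(top$gauss13$w <= 0)) {
    stop("Gaussian 1-3 width must be > 0")
  }
  for (tab in c("stacks", "basepairs", "crossstacks")) {
    if (nrow(top[[tab]]) && any(top[[tab]]$alpha <= 0)) {
      stop("Morse alpha must be > 0 in ", tab)
    }
  }
  # the exclusion list must contain every 1-2 and 1-3 bonded pair
  need <- bonded_12_13_pairs(top)
  if (nrow(need)) {
    have <- paste(top$exclusions[, 1], top$exclusions[, 2])
    missing <- !(paste(need[, 1], need[, 2]) %in% have)
    if (any(missing)) {
      stop(sum(missing), " bonded 1-2/1-3 pairs missing from exclusions")
    }
  }
  invisible(TRUE)
}

# All 1-2 and 1-3 pairs implied by the bond list, as a sorted unique matrix.
bonded_12_13_pairs <- function(top) {
  b <- top$bonds
  if (!nrow(b)) return(matrix(integer(), ncol = 2))
  p12 <- cbind(pmin(b$i, b$j), pmax(b$i, b$j))
  adj <- split(c(b$j, b$i), c(b$i, b$j))
  p13 <- list()
  for (mid in names(adj)) {
    nb <- unique(adj[[mid]])
    if (length(nb) >= 2) {
      cmb <- utils::combn(sort(nb), 2)
      p13[[mid]] <- t(cmb)
    }
  }
  out <- rbind(p12, do.call(rbind, p13))
  out <- unique(out)
  out[order(out[, 1], out[, 2]), , drop = FALSE]
}

#' @export
print.cg_topology <- function(x, ...) {
  cat("CG topology:", nrow(x$particles), "particles,",
      length(x$molecules), "molecule block(s)\n")
  counts <- vapply(c("bonds", "angles", "dihedrals", "contacts", "gauss13",
                     "stacks", "basepairs", "crossstacks", "pwmcos", "hb"),
                   function(tb) nrow(x[[tb]]), integer(1))
  counts <- counts[counts > 0]
  if (length(counts)) {
    cat("  records:", paste(names(counts), counts, sep = "=",
                            collapse = ", "), "\n")
  }
  cat("  exclusions:", nrow(x$exclusions), "pairs\n")
  invisible(x)
}

#' Simulation frame
#'
#' Positions (and optionally velocities) of every particle at one time point.
#'
#' @param positions N x 3 matrix, A.
#' @param velocities Optional N x 3 matrix, A/fs.
#' @param box Optional length-3 vector of orthorhombic box lengths, A.
#' @param step Integer step index.
#' @param time Time stamp, fs.
#' @return Object of class `cg_frame`.
#' @export
cg_frame <- function(positions, velocities = NULL, box = NULL,
                     step = 0L, time = 0) {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 3)
  if (!is.null(velocities)) {
    velocities <- as.matrix(velocities)
    stopifnot(identical(dim(velocities), dim(positions)))
  }
  if (!is.null(box)) {
    stopifnot(length(box) == 3, all(box > 0))
  }
  structure(list(positions = positions, velocities = velocities, box = box,
                 step = as.integer(step), time = time),
            class = "cg_frame")
}

#' @export
print.cg_frame <- function(x, ...) {
  cat("CG frame:", nrow(x$positions), "particles, step", x$step,
      sprintf("(t = %g fs)", x$time))
  if (!is.null(x$box)) cat(sprintf(", box %g x %g x %g A",
                                   x$box[1], x$box[2], x$box[3]))
  cat("\n")
  invisible(x)
}

# quick particle-table constructor used by builders and fixtures
.particle_table <- function(n, name = "CA", class = "protein",
                            resname = "ALA", resid = seq_len(n),
                            chain = "A", mass = 110, charge = 0,
                            radius = 2.5, lambda = 0.5, sigma = 5,
                            eps = 0.2) {
  data.frame(name = rep_len(name, n), class = rep_len(class, n),
             resname = rep_len(resname, n), resid = rep_len(resid, n),
             chain = rep_len(chain, n), mass = rep_len(mass, n),
             charge = rep_len(charge, n), radius = rep_len(radius, n),
             lambda = rep_len(lambda, n), sigma = rep_len(sigma, n),
             eps = rep_len(eps, n), stringsAsFactors = FALSE)
}
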