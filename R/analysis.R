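#' Radius of gyration
#'
#' \eqn{R_g = \sqrt{\sum m_i \|r_i - r_{com}\|^2 / \sum m_i}} (or the
#' unweighted variant).
#'
#' @param frame A [cg_frame()] or N x 3 matrix.
#' @param selection Indices (1-based); default all.
#' @param masses Optional masses for mass weighting; default unweighted.
#' @return Rg in A.
#' @export
radius_of_gyration <- function(frame, selection = NULL, masses = NULL) {
  pos <- if (inherits(frame, "cg_frame")) frame$positions else frame
  if (!is.null(selection)) {
    pos <- pos[selection, , drop = FALSE]
    if (!is.null(masses)) masses <- masses[selection]
  }
  if (nrow(pos) == 0) stop("empty selection")
  if (is.null(masses)) masses <- rep(1, nrow(pos))
  com <- colSums(pos * masses) / sum(masses)
  sqrt(sum(masses * rowSums(sweep(pos, 2, com)^2)) / sum(masses))
}

#' RMSD after optimal rigid superposition
#'
#' Least-squares superposition (rotation + translation, Kabsch/SVD) of the
#' selected particles before computing the root-mean-square deviation.
#'
#' @param frame A [cg_frame()] or N x 3 matrix.
#' @param reference Reference positions (same selection size).
#' @param selection Optional indices applied to both.
#' @return RMSD in A.
#' @export
rmsd <- function(frame, reference, selection = NULL) {
  x <- if (inherits(frame, "cg_frame")) frame$positions else frame
  y <- if (inherits(reference, "cg_frame")) reference$positions else
    reference
  if (!is.null(selection)) {
    x <- x[selection, , drop = FALSE]
    y <- y[selection, , drop = FALSE]
  }
  if (nrow(x) != nrow(y)) stop("selection sizes differ")
  xc <- sweep(x, 2, colMeans(x))
  yc <- sweep(y, 2, colMeans(y))
  s <- svd(crossprod(yc, xc))
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  fit <- xc %*% t(R)
  sqrt(mean(rowSums((fit - yc)^2)))
}

#' Fraction of native contacts (Q)
#'
#' A native contact counts as formed when its instantaneous distance is
#' below `factor` times its native distance sigma.  `factor = 1.2` is the
#' conventional choice.
#'
#' @param frame A [cg_frame()] or position matrix.
#' @param contacts Contact records (`i`, `j` 0-based, `sigma`).
#' @param factor Distance multiplier (default 1.2).
#' @return Fraction in \[0, 1\].
#' @export
q_score <- function(frame, contacts, factor = 1.2) {
  pos <- if (inherits(frame, "cg_frame")) frame$positions else frame
  if (nrow(contacts) == 0) stop("contact list is empty")
  d <- sqrt(rowSums((pos[contacts$i + 1L, , drop = FALSE] -
                     pos[contacts$j + 1L, , drop = FALSE])^2))
  mean(d < factor * contacts$sigma)
}

#' Number density profile along z
#'
#' Counts selected particles in uniform z-bins (wrapped into the periodic
#' box) and normalises by the bin volume, giving particles per nm^3.
#'
#' @param frames List of [cg_frame()]s (or matrices; then `box` required).
#' @param bin_width Bin width, A.
#' @param selection Optional indices.
#' @param box Box lengths if frames are bare matrices.
#' @return Object of class `cg_profile`: data.frame `center` (A), `value`
#'   (particles/nm^3) with the frame count as attribute.
#' @export
density_profile_z <- function(frames, bin_width = 10, selection = NULL,
                              box = NULL) {
  if (inherits(frames, "cg_frame") || is.matrix(frames)) {
    frames <- list(frames)
  }
  f1 <- frames[[1]]
  if (is.null(box)) {
    if (!inherits(f1, "cg_frame") || is.null(f1$box)) {
      stop("a periodic box is required for the z-density profile")
    }
    box <- f1$box
  }
  nbin <- max(1L, round(box[3] / bin_width))
  width <- box[3] / nbin
  counts <- numeric(nbin)
  for (f in frames) {
    pos <- if (inherits(f, "cg_frame")) f$positions else f
    if (!is.null(selection)) pos <- pos[selection, , drop = FALSE]
    z <- pos[, 3] %% box[3]
    idx <- pmin(nbin - 1L, floor(z / width)) + 1L
    tab <- tabulate(idx, nbin)
    counts <- counts + tab
  }
  vol_nm3 <- box[1] * box[2] * width / 1000   # A^3 -> nm^3
  out <- data.frame(center = (seq_len(nbin) - 0.5) * width,
                    value = counts / (length(frames) * vol_nm3))
  attr(out, "n_frames") <- length(frames)
  attr(out, "bin_width") <- width
  class(out) <- c("cg_profile", "data.frame")
  out
}

#' Radial distribution from a droplet's center of mass
#'
#' Shell-volume-normalised density of selection B versus distance from the
#' center of mass of selection A (e.g. protein droplet center vs RNA
#' particles).
#'
#' @param frames List of frames or matrices.
#' @param selection_a Indices defining the center of mass.
#' @param selection_b Indices profiled.
#' @param bin_width Shell width, A.
#' @param r_max Maximum radius, A.
#' @param masses Optional masses for the COM.
#' @return `cg_profile` data.frame: `center` (A), `value` (particles/nm^3).
#' @export
rdf_from_com <- function(frames, selection_a, selection_b, bin_width = 5,
                         r_max = 150, masses = NULL) {
  if (inherits(frames, "cg_frame") || is.matrix(frames)) {
    frames <- list(frames)
  }
  stopifnot(length(selection_a) > 0)
  nbin <- ceiling(r_max / bin_width)
  counts <- numeric(nbin)
  for (f in frames) {
    pos <- if (inherits(f, "cg_frame")) f$positions else f
    pa <- pos[selection_a, , drop = FALSE]
    w <- if (is.null(masses)) rep(1, nrow(pa)) else masses[selection_a]
    com <- colSums(pa * w) / sum(w)
    r <- sqrt(rowSums(sweep(pos[selection_b, , drop = FALSE], 2, com)^2))
    idx <- floor(r / bin_width) + 1L
    idx <- idx[idx <= nbin]
    counts <- counts + tabulate(idx, nbin)
  }
  edges <- (0:nbin) * bin_width
  shell_vol_nm3 <- 4 / 3 * pi * diff(edges^3) / 1000
  out <- data.frame(center = edges[-1] - bin_width / 2,
                    value = counts / (length(frames) * shell_vol_nm3))
  attr(out, "n_frames") <- length(frames)
  class(out) <- c("cg_profile", "data.frame")
  out
}

#' DNA-binding position of a protein
#'
#' Index of the base pair whose CG sites lie nearest to the protein's
#' center of mass (minimum site distance; ties break to the lower index).
#' The caller decides whether the protein is actually bound, e.g. by
#' thresholding the returned distance.
#'
#' @param frame A [cg_frame()] or matrix.
#' @param protein_sel Protein particle indices (1-based).
#' @param dna_top The dsDNA [cg_topology()] (or merged topology); base-pair
#'   ordering is taken from the pairing of strand A's nucleotides.
#' @param pairing Pairing table (attribute of the dsDNA mapping) mapping
#'   base-pair rank to the two nucleotide ids; default
#'   `attr(dna_top, "pairing")`.
#' @param masses Optional protein masses.
#' @return List with `bp` (1-based base-pair index) and `distance` (A).
#' @export
dna_binding_position <- function(frame, protein_sel, dna_top,
                                 pairing = NULL, masses = NULL) {
  pos <- if (inherits(frame, "cg_frame")) frame$positions else frame
  pp <- pos[protein_sel, , drop = FALSE]
  w <- if (is.null(masses)) rep(1, nrow(pp)) else masses[protein_sel]
  com <- colSums(pp * w) / sum(w)
  p <- dna_top$particles
  if (is.null(pairing)) pairing <- attr(dna_top, "pairing")
  # group DNA sites by base-pair rank
  nts <- .nucleotide_sites(p)
  allnts <- do.call(rbind, nts)
  nbp <- if (!is.null(pairing)) nrow(pairing) else nrow(allnts)
  best_bp <- 1L; best_d <- Inf
  for (bp in seq_len(nbp)) {
    ids <- if (!is.null(pairing)) c(pairing$a[bp], pairing$b[bp]) else bp
    sites <- unlist(allnts[match(ids, allnts$id), c("P", "S", "B")])
    sites <- sites[!is.na(sites)]
    d <- min(sqrt(rowSums(sweep(pos[sites, , drop = FALSE], 2, com)^2)))
    if (d < best_d - 1e-12) { best_d <- d; best_bp <- bp }
  }
  list(bp = best_bp, distance = best_d)
}

#' DNA bend angle
#'
#' Angle between the helical-axis directions of the two duplex ends, each
#' fit by total least squares over a window of base-pair centers.
#'
#' @param frame A [cg_frame()] or matrix.
#' @param dna_top dsDNA topology.
#' @param window End-segment window, base pairs (default 10).
#' @param pairing Pairing table; default `attr(dna_top, "pairing")`.
#' @return Bend angle in degrees (0 = straight).
#' @export
dna_bend_angle <- function(frame, dna_top, window = 10L, pairing = NULL) {
  pos <- if (inherits(frame, "cg_frame")) frame$positions else frame
  p <- dna_top$particles
  if (is.null(pairing)) pairing <- attr(dna_top, "pairing")
  stopifnot(!is.null(pairing))
  nbp <- nrow(pairing)
  if (nbp <= 2 * window) stop("duplex too short for the chosen window")
  nts <- .nucleotide_sites(p)
  allnts <- do.call(rbind, nts)
  centers <- t(vapply(seq_len(nbp), function(bp) {
    ids <- c(pairing$a[bp], pairing$b[bp])
    sites <- unlist(allnts[match(ids, allnts$id), c("S", "B")])
    sites <- sites[!is.na(sites)]
    colMeans(pos[sites, , drop = FALSE])
  }, numeric(3)))
  axis_of <- function(rows) {
    seg <- centers[rows, , drop = FALSE]
    sc <- sweep(seg, 2, colMeans(seg))
    v <- svd(sc)$v[, 1]
    # orient along increasing bp index
    if (sum(v * (seg[nrow(seg), ] - seg[1, ])) < 0) v <- -v
    v
  }
  v1 <- axis_of(seq_len(window))
  v2 <- axis_of((nbp - window + 1):nbp)
  acos(max(-1, min(1, sum(v1 * v2)))) * 180 / pi
}

#' Number of DNA base pairs wrapped on a protein core
#'
#' Counts base pairs having at least one CG site within the distance
#' criterion of any core particle.
#'
#' @param frame A [cg_frame()] or matrix.
#' @param dna_top dsDNA topology (merged system topology accepted).
#' @param core_sel Histone-core particle indices (1-based).
#' @param criterion Distance criterion, A (default 10).
#' @param pairing Pairing table; default `attr(dna_top, "pairing")`.
#' @return Integer count.
#' @export
wrapped_bp_count <- function(frame, dna_top, core_sel, criterion = 10,
                             pairing = NULL) {
  if (criterion <= 0) return(0L)
  pos <- if (inherits(frame, "cg_frame")) frame$positions else frame
  p <- dna_top$particles
  if (is.null(pairing)) pairing <- attr(dna_top, "pairing")
  stopifnot(!is.null(pairing))
  nts <- .nucleotide_sites(p)
  allnts <- do.call(rbind, nts)
  core <- pos[core_sel, , drop = FALSE]
  count <- 0L
  for (bp in seq_len(nrow(pairing))) {
    ids <- c(pairing$a[bp], pairing$b[bp])
    sites <- unlist(allnts[match(ids, allnts$id), c("P", "S", "B")])
    sites <- sites[!is.na(sites)]
    sp <- pos[sites, , drop = FALSE]
    dmin <- min(vapply(seq_len(nrow(sp)), function(k) {
      min(rowSums(sweep(core, 2, sp[k, ])^2))
    }, numeric(1)))
    if (dmin < criterion^2) count <- count + 1L
  }
  count
}

#' Largest cluster of chains
#'
#' Single-linkage clustering of chains: two chains join when any inter-chain
#' particle pair is closer than the linking distance (minimum image if a box
#' is given).  Used to monitor condensation in slab simulations.
#'
#' @param frame A [cg_frame()] or matrix.
#' @param chain_ids Chain label per particle.
#' @param link_dist Linking distance, A (default 8).
#' @param box Optional periodic box.
#' @return List with `sizes` (chains per cluster, sorted decreasing) and
#'   `largest_fraction` (fraction of chains in the biggest cluster).
#' @export
chain_clusters <- function(frame, chain_ids, link_dist = 8, box = NULL) {
  pos <- if (inherits(frame, "cg_frame")) frame$positions else frame
  if (is.null(box) && inherits(frame, "cg_frame")) box <- frame$box
  chains <- unique(chain_ids)
  nc <- length(chains)
  cid <- match(chain_ids, chains)
  prs <- cpp_build_pairs(pos, if (is.null(box)) c(0, 0, 0) else box,
                         !is.null(box), seq_len(nrow(pos)) - 1L,
                         integer(0), FALSE, link_dist,
                         matrix(integer(), ncol = 2))$pairs
  parent <- seq_len(nc)
  find <- function(a) { while (parent[a] != a) a <- parent[a]; a }
  if (nrow(prs)) {
    ca <- cid[prs[, 1] + 1L]; cb <- cid[prs[, 2] + 1L]
    diff_ch <- ca != cb
    for (k in which(diff_ch)) {
      ra <- find(ca[k]); rb <- find(cb[k])
      if (ra != rb) parent[ra] <- rb
    }
  }
  roots <- vapply(seq_len(nc), find, integer(1))
  sizes <- sort(table(roots), decreasing = TRUE)
  list(sizes = as.integer(sizes), largest_fraction = sizes[1] / nc)
}
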