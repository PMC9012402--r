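#' Build a cell grid for neighbor-list construction
#'
#' Divides space into cells and, for every interaction term, records (i) the
#' per-cell particle lists restricted to the particles involved in that term
#' and (ii) the set of neighboring-cell offsets whose minimum inter-cell
#' distance is below the term's pair-list distance.  Short-range terms get
#' strictly fewer neighboring cells than long-range ones.
#'
#' The cell edge along each axis is the largest length not exceeding the
#' shortest per-term pair-list distance that divides the box evenly
#' (non-periodic systems use the instantaneous bounding box plus a margin
#' cell).  A periodic box must measure at least three times the largest
#' pair-list distance along every axis.
#'
#' @param frame A [cg_frame()].
#' @param pairlist_distances Named numeric vector of per-term pair-list
#'   distances, A (e.g. `c(exv = 15, ele = 57)`).
#' @param subsets Named list (same names) of 0-based particle index vectors
#'   participating in each term; defaults to all particles for every term.
#' @param boundary `"none"` or `"periodic"` (requires `frame$box`).
#' @return Object of class `cg_cell_grid`.
#' @export
build_grid <- function(frame, pairlist_distances, subsets = NULL,
                       boundary = c("none", "periodic")) {
  boundary <- match.arg(boundary)
  n <- nrow(frame$positions)
  terms <- names(pairlist_distances)
  stopifnot(!is.null(terms), all(pairlist_distances > 0))
  if (is.null(subsets)) {
    subsets <- stats::setNames(rep(list(seq_len(n) - 1L), length(terms)),
                               terms)
  }
  if (boundary == "periodic") {
    stopifnot(!is.null(frame$box))
    if (any(frame$box < 3 * max(pairlist_distances))) {
      stop("periodic box must be equal to or larger than three times the ",
           "largest pair-list distance")
    }
    origin <- c(0, 0, 0)
    L <- frame$box
  } else {
    if (n > 0) {
      lo <- apply(frame$positions, 2, min) - 0.5
      hi <- apply(frame$positions, 2, max) + 0.5
    } else {
      lo <- c(0, 0, 0); hi <- c(1, 1, 1)
    }
    origin <- lo
    L <- pmax(hi - lo, 1)
  }
  edge_target <- min(pairlist_distances)
  nc <- pmax(1L, as.integer(floor(L / edge_target)))
  edge <- L / nc
  cell_of <- function(xyz) {
    rel <- sweep(xyz, 2, origin)
    if (boundary == "periodic") rel <- rel %% matrix(L, nrow(rel), 3, TRUE)
    idx <- pmin(floor(sweep(rel, 2, edge, "/")), matrix(nc - 1L,
                                                        nrow(rel), 3, TRUE))
    idx <- pmax(idx, 0L)
    as.integer(idx[, 1] * nc[2] * nc[3] + idx[, 2] * nc[3] + idx[, 3] + 1L)
  }
  cells <- if (n > 0) cell_of(frame$positions) else integer()
  member_lists <- lapply(subsets, function(sub) {
    split(sub, factor(cells[sub + 1L], levels = seq_len(prod(nc))))
  })
  neighbor_offsets <- lapply(pairlist_distances, function(rp) {
    kr <- as.integer(floor(rp / edge)) + 1L
    if (boundary == "periodic") kr <- pmin(kr, (nc - 1L) %/% 2L)
    else kr <- pmin(kr, nc - 1L)
    offs <- expand.grid(dx = -kr[1]:kr[1], dy = -kr[2]:kr[2],
                        dz = -kr[3]:kr[3])
    rmin2 <- rowSums(matrix(vapply(1:3, function(d) {
      pmax(abs(offs[[d]]) - 1, 0)^2 * edge[d]^2
    }, numeric(nrow(offs))), nrow = nrow(offs)))
    as.matrix(offs[rmin2 < rp^2, , drop = FALSE])
  })
  structure(list(ncell = nc, edge = edge, origin = origin, boundary = boundary,
                 box = if (boundary == "periodic") L else NULL,
                 pairlist_distances = pairlist_distances,
                 cells = cells, members = member_lists,
                 neighbor_offsets = neighbor_offsets),
            class = "cg_cell_grid")
}

#' @export
print.cg_cell_grid <- function(x, ...) {
  cat(sprintf("Cell grid: %d x %d x %d cells (edge %.2f x %.2f x %.2f A), %s\n",
              x$ncell[1], x$ncell[2], x$ncell[3],
              x$edge[1], x$edge[2], x$edge[3], x$boundary))
  for (t in names(x$pairlist_distances)) {
    cat(sprintf("  %-8s rP = %g A, %d neighboring-cell offsets\n",
                t, x$pairlist_distances[t], nrow(x$neighbor_offsets[[t]])))
  }
  invisible(x)
}

#' Candidate pairs of one term from a cell grid
#'
#' Scans the term's per-cell particle lists over its neighboring-cell set and
#' returns every unordered pair within the pair-list distance that is not
#' excluded.  This is the reference (R) path; the compiled engine builds the
#' same lists internally.
#'
#' @param grid A [build_grid()] result.
#' @param frame The frame the grid was built from.
#' @param term Term name (must be present in the grid).
#' @param exclusions Optional 2-column 0-based matrix.
#' @return 2-column 0-based integer matrix with i < j, each row a candidate
#'   pair within the pair-list distance.
#' @export
build_pairs <- function(grid, frame, term, exclusions = NULL) {
  stopifnot(inherits(grid, "cg_cell_grid"), term %in% names(grid$members))
  rp <- grid$pairlist_distances[term]
  members <- grid$members[[term]]
  offs <- grid$neighbor_offsets[[term]]
  nc <- grid$ncell
  pos <- frame$positions
  periodic <- grid$boundary == "periodic"
  L <- grid$box
  dist2 <- function(a, b) {
    d <- pos[a + 1L, , drop = FALSE] - pos[rep(b + 1L, length(a)), ,
                                           drop = FALSE]
    if (periodic) d <- d - sweep(round(sweep(d, 2, L, "/")), 2, L, "*")
    rowSums(d^2)
  }
  out_i <- integer(0); out_j <- integer(0)
  occupied <- which(lengths(members) > 0)
  cell_xyz <- function(ci) {
    ci <- ci - 1L
    c(ci %/% (nc[2] * nc[3]), (ci %/% nc[3]) %% nc[2], ci %% nc[3])
  }
  idx_of <- function(xyz) xyz[1] * nc[2] * nc[3] + xyz[2] * nc[3] + xyz[3] + 1L
  for (ci in occupied) {
    A <- members[[ci]]
    home <- cell_xyz(ci)
    for (r in seq_len(nrow(offs))) {
      o <- offs[r, ]
      tgt <- home + o
      if (periodic) {
        tgt <- tgt %% nc
      } else if (any(tgt < 0) || any(tgt >= nc)) next
      cj <- idx_of(tgt)
      same <- cj == ci
      if (!same && cj < ci) next   # visit each unordered cell pair once
      B <- members[[cj]]
      if (!length(B)) next
      for (a in A) {
        b <- if (same) B[B > a] else B
        if (!length(b)) next
        keep <- dist2(b, a) < rp^2
        if (any(keep)) {
          bb <- b[keep]
          out_i <- c(out_i, pmin(rep(a, length(bb)), bb))
          out_j <- c(out_j, pmax(rep(a, length(bb)), bb))
        }
      }
    }
  }
  pairs <- unique(cbind(out_i, out_j, deparse.level = 0))
  if (!is.null(exclusions) && nrow(pairs) && nrow(exclusions)) {
    key <- paste(pairs[, 1], pairs[, 2])
    exk <- paste(pmin(exclusions[, 1], exclusions[, 2]),
                 pmax(exclusions[, 1], exclusions[, 2]))
    pairs <- pairs[!(key %in% exk), , drop = FALSE]
  }
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  storage.mode(pairs) <- "integer"
  pairs
}

#' Neighbor-list state with cadence-based rebuilds
#'
#' Holds the per-term pair lists together with the step at which they were
#' built.  [maybe_rebuild()] rebuilds them only when the configured interval
#' (default 20 steps) has elapsed.
#'
#' @param system A [cg_system()].
#' @param frame Current frame.
#' @param step Current step index.
#' @return Object of class `cg_neighbor_state`.
#' @export
neighbor_state <- function(system, frame, step = 0L) {
  structure(list(pairs = neighbor_pairs(system, frame),
                 built_step = as.integer(step),
                 snapshot = frame$positions),
            class = "cg_neighbor_state")
}

#' Per-term neighbor lists through the compiled cell-linked-list path
#'
#' @param system A [cg_system()].
#' @param frame Current frame.
#' @return Named list of 2-column 0-based pair matrices for the active
#'   dynamically-listed terms.
#' @export
neighbor_pairs <- function(system, frame) {
  nb <- system$engine$nonbonded
  periodic <- !is.null(frame$box)
  boxv <- if (periodic) frame$box else c(0, 0, 0)
  out <- list()
  run <- function(set, rp, excl) {
    cpp_build_pairs(frame$positions, boxv, periodic, set, integer(0),
                    FALSE, rp, excl)$pairs
  }
  if (nb$use_exv) {
    out$exv <- run(nb$exv_set, nb$rp_exv, system$engine$excl_exv)
  }
  if (nb$use_hps) {
    out$hps <- run(nb$hps_set, nb$rp_hps, system$engine$excl_common)
  }
  if (nb$use_ele) {
    out$ele <- run(nb$ele_set, nb$rp_ele, system$engine$excl_common)
  }
  out
}

#' Rebuild neighbor lists when the update interval has elapsed
#'
#' @param state A [neighbor_state()].
#' @param system A [cg_system()].
#' @param frame Current frame.
#' @param step Current step index.
#' @param interval Update cadence in steps (default 20).
#' @return Updated `cg_neighbor_state` (rebuilt or unchanged).
#' @export
maybe_rebuild <- function(state, system, frame, step, interval = 20L) {
  stopifnot(inherits(state, "cg_neighbor_state"))
  if (step - state$built_step >= interval) {
    neighbor_state(system, frame, step)
  } else {
    state
  }
}
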