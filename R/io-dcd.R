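#' Write a trajectory in DCD format
#'
#' Standard CHARMM-style binary DCD: single-precision coordinates in
#' Angstrom, one coordinate set per frame, frame count in the header, and a
#' unit-cell record only for periodic frames.  Readable by common trajectory
#' readers.
#'
#' @param frames List of [cg_frame()]s (or position matrices) with a
#'   constant particle count.
#' @param path Output file.
#' @param dt Time step between stored frames, fs (header metadata).
#' @return Invisibly `path`.
#' @export
write_dcd <- function(frames, path, dt = 10) {
  get_pos <- function(f) if (inherits(f, "cg_frame")) f$positions else f
  get_box <- function(f) if (inherits(f, "cg_frame")) f$box else NULL
  nf <- length(frames)
  natom <- if (nf > 0) nrow(get_pos(frames[[1]])) else 0L
  for (f in frames) {
    if (nrow(get_pos(f)) != natom) {
      stop("inconsistent particle counts across frames")
    }
  }
  has_cell <- nf > 0 && !is.null(get_box(frames[[1]]))
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4)
  # header block
  wi(84)
  writeChar("CORD", con, 4, eos = NULL)
  icntrl <- integer(20)
  icntrl[1] <- nf          # number of frames
  icntrl[2] <- 1           # first step
  icntrl[3] <- 1           # save interval
  icntrl[4] <- nf          # total steps
  icntrl[11] <- if (has_cell) 1L else 0L
  icntrl[20] <- 24         # version
  wi(icntrl[1:9])
  writeBin(as.numeric(dt / 48.88821), con, size = 4)  # AKMA time units
  wi(icntrl[11:20])
  wi(84)
  # title block
  title <- sprintf("%-80s", "CG trajectory")
  wi(4 + 80); wi(1)
  writeChar(title, con, 80, eos = NULL)
  wi(4 + 80)
  # atom count
  wi(4); wi(natom); wi(4)
  for (f in frames) {
    pos <- get_pos(f)
    box <- get_box(f)
    if (has_cell) {
      b <- if (is.null(box)) c(0, 0, 0) else box
      wi(48)
      writeBin(as.numeric(c(b[1], 0, b[2], 0, 0, b[3])), con, size = 8)
      wi(48)
    }
    for (d in 1:3) {
      wi(4 * natom)
      writeBin(as.numeric(pos[, d]), con, size = 4)
      wi(4 * natom)
    }
  }
  invisible(path)
}

#' Read a DCD trajectory
#'
#' Thin wrapper over the trajectory reader from bio3d, reshaped into a list
#' of position matrices (A).
#'
#' @param path DCD file.
#' @return List of N x 3 matrices, one per frame.
#' @export
read_dcd <- function(path) {
  m <- bio3d::read.dcd(path, verbose = FALSE)
  lapply(seq_len(nrow(m)), function(i) matrix(m[i, ], ncol = 3, byrow = TRUE))
}
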