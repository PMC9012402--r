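#' Write CG coordinates in .gro format
#'
#' Follows the standard nanometer convention of the format (positions nm,
#' velocities nm/ps); the internal unit is Angstrom and fs.  An Angstrom
#' dialect is available for interoperability with tools that expect CG
#' coordinates in A.
#'
#' @param frame A [cg_frame()].
#' @param top Matching [cg_topology()] (names/residues for the records).
#' @param path Output file.
#' @param unit `"nm"` (standard) or `"angstrom"`.
#' @param title Title line.
#' @return Invisibly `path`.
#' @export
write_coordinates <- function(frame, top, path, unit = c("nm", "angstrom"),
                              title = "CG model") {
  unit <- match.arg(unit)
  p <- top$particles
  n <- nrow(frame$positions)
  if (n != nrow(p)) {
    stop("frame has ", n, " particles but topology has ", nrow(p))
  }
  scale <- if (unit == "nm") 0.1 else 1
  vscale <- if (unit == "nm") 1000 * 0.1 else 1  # A/fs -> nm/ps
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%s (%s)", title, unit), con)
  writeLines(sprintf("%d", n), con)
  hasv <- !is.null(frame$velocities)
  for (i in seq_len(n)) {
    line <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                    p$resid[i] %% 100000, substr(p$resname[i], 1, 5),
                    substr(p$name[i], 1, 5), i %% 100000,
                    frame$positions[i, 1] * scale,
                    frame$positions[i, 2] * scale,
                    frame$positions[i, 3] * scale)
    if (hasv) {
      line <- paste0(line, sprintf("%8.4f%8.4f%8.4f",
                                   frame$velocities[i, 1] * vscale,
                                   frame$velocities[i, 2] * vscale,
                                   frame$velocities[i, 3] * vscale))
    }
    writeLines(line, con)
  }
  box <- if (is.null(frame$box)) c(0, 0, 0) else frame$box * scale
  writeLines(sprintf("%10.5f%10.5f%10.5f", box[1], box[2], box[3]), con)
  invisible(path)
}

#' Read CG coordinates from a .gro file
#'
#' @param path Input file.
#' @param top Optional [cg_topology()]; when given, the particle count is
#'   checked against it.
#' @param unit `"nm"` (standard) or `"angstrom"`.
#' @return A [cg_frame()] (positions in A; velocities in A/fs when present).
#' @export
read_coordinates <- function(path, top = NULL, unit = c("nm", "angstrom")) {
  unit <- match.arg(unit)
  lines <- readLines(path)
  n <- as.integer(trimws(lines[2]))
  if (!is.null(top) && n != nrow(top$particles)) {
    stop("coordinate file has ", n, " particles but topology has ",
         nrow(top$particles))
  }
  scale <- if (unit == "nm") 10 else 1
  vscale <- if (unit == "nm") 10 / 1000 else 1  # nm/ps -> A/fs
  body <- lines[3:(2 + n)]
  num <- function(a, b, l) as.numeric(substr(l, a, b))
  pos <- cbind(num(21, 28, body), num(29, 36, body), num(37, 44, body)) * scale
  vel <- NULL
  if (all(nchar(body) >= 68)) {
    vel <- cbind(num(45, 52, body), num(53, 60, body),
                 num(61, 68, body)) * vscale
    if (all(is.na(vel))) vel <- NULL
  }
  boxline <- as.numeric(strsplit(trimws(lines[3 + n]), "\\s+")[[1]])[1:3]
  box <- if (all(!is.na(boxline)) && all(boxline > 0)) boxline * scale else NULL
  cg_frame(pos, velocities = vel, box = box)
}
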