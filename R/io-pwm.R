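#' Read a position weight matrix
#'
#' Plain-text PWM: a header row of base letters giving the row order,
#' followed by four rows of L column scores (one row per base), and an
#' optional final row starting with `N` giving the per-column protein
#' contact counts N_m (default 1).  Scores are log-odds-like energies; the
#' recognition model maps them linearly to well depths via
#' [pwm_to_epsilon()].
#'
#' @param path PWM file.
#' @return Object of class `cg_pwm`: `scores` (4 x L matrix, rows A, C, G,
#'   T) and `n_contacts` (length L).
#' @export
read_pwm <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  hdr <- toupper(strsplit(lines[1], "\\s+")[[1]])
  if (!setequal(hdr, c("A", "C", "G", "T"))) {
    stop("PWM header must list the four base letters")
  }
  rows <- lapply(lines[2:5], function(ln) {
    as.numeric(strsplit(ln, "\\s+")[[1]])
  })
  L <- length(rows[[1]])
  stopifnot(L >= 1, all(lengths(rows) == L))
  m <- do.call(rbind, rows)
  rownames(m) <- hdr
  m <- m[c("A", "C", "G", "T"), , drop = FALSE]
  n_contacts <- rep(1, L)
  if (length(lines) >= 6 && grepl("^[Nn]", lines[6])) {
    n_contacts <- as.numeric(strsplit(lines[6], "\\s+")[[1]][-1])
    stopifnot(length(n_contacts) == L, all(n_contacts >= 1))
  }
  structure(list(scores = m, n_contacts = n_contacts), class = "cg_pwm")
}

#' Write a position weight matrix
#' @param pwm A `cg_pwm`.
#' @param path Output file.
#' @return Invisibly `path`.
#' @export
write_pwm <- function(pwm, path) {
  stopifnot(inherits(pwm, "cg_pwm"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("A C G T", con)
  for (b in c("A", "C", "G", "T")) {
    writeLines(paste(sprintf("%.17g", pwm$scores[b, ]), collapse = " "), con)
  }
  writeLines(paste("N", paste(sprintf("%.17g", pwm$n_contacts),
                              collapse = " ")), con)
  invisible(path)
}

#' @export
print.cg_pwm <- function(x, ...) {
  cat("PWM with", ncol(x$scores), "columns\n")
  print(round(x$scores, 3))
  invisible(x)
}
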