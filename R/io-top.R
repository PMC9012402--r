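# GROMACS-dialect topology reader/writer.
#
# One major .top file plus one .itp per molecule block, linked with
# #include.  An integer "function type" distinguishes potential forms of the
# same interaction class: bonds 1 = harmonic, 21 = quartic; angles 1 =
# harmonic, 21 = tabulated; dihedrals 1 = periodic, 21 = Gaussian, 22 =
# tabulated, 32 = periodic with the safe near-collinear force fallback;
# pairs 1 = Go 12-10.  Indices are 1-based in the files and 0-based in
# memory; records crossing molecule blocks live in the .top with global
# indices.  Unknown function types and unknown sections are errors, never
# silently skipped.

.FT_BONDS <- c(1L, 21L)
.FT_ANGLES <- c(1L, 21L)
.FT_DIHEDRALS <- c(1L, 21L, 22L, 32L)

.num17 <- function(x) sprintf("%.17g", x)

.sec_writers <- list(
  bonds = function(df, off) {
    sprintf("%6d %6d %4d %s %s %s", df$i + 1 - off, df$j + 1 - off, df$func,
            .num17(df$b0), .num17(df$c1), .num17(df$c2))
  },
  angles = function(df, off) {
    sprintf("%6d %6d %6d %4d %s %s %s", df$i + 1 - off, df$j + 1 - off,
            df$k + 1 - off, df$func, .num17(df$theta0), .num17(df$ka),
            ifelse(is.na(df$table) | df$table == "", "-", df$table))
  },
  dihedrals = function(df, off) {
    sprintf("%6d %6d %6d %6d %4d %s %s %s %s %s", df$i + 1 - off,
            df$j + 1 - off, df$k + 1 - off, df$l + 1 - off, df$func,
            .num17(df$phi0), .num17(df$mult), .num17(df$kd),
            .num17(df$sigma),
            ifelse(is.na(df$table) | df$table == "", "-", df$table))
  },
  pairs = function(df, off) {
    sprintf("%6d %6d %4d %s %s", df$i + 1 - off, df$j + 1 - off, 1L,
            .num17(df$sigma), .num17(df$eps))
  },
  cg_gaussian_13 = function(df, off) {
    sprintf("%6d %6d %s %s %s", df$i + 1 - off, df$k + 1 - off,
            .num17(df$r0), .num17(df$eps), .num17(df$w))
  },
  cg_base_stacks = function(df, off) {
    sprintf("%6d %6d %6d %s %s %s %s %s", df$i + 1 - off, df$j + 1 - off,
            df$s + 1 - off, .num17(df$eps), .num17(df$alpha), .num17(df$r0),
            .num17(df$theta0), .num17(df$gamma))
  },
  cg_base_pairs = function(df, off) {
    sprintf("%6d %6d %6d %6d %s %s %s %s %s %s %s", df$i + 1 - off,
            df$j + 1 - off, df$si + 1 - off, df$sj + 1 - off,
            .num17(df$eps), .num17(df$alpha), .num17(df$r0),
            .num17(df$theta1_0), .num17(df$theta2_0), .num17(df$phi0),
            .num17(df$gamma))
  },
  cg_cross_stacks = function(df, off) {
    sprintf("%6d %6d %6d %6d %s %s %s %s %s %s", df$i + 1 - off,
            df$j + 1 - off, df$ai + 1 - off, df$aj + 1 - off,
            .num17(df$eps), .num17(df$alpha), .num17(df$r0),
            .num17(df$theta3_0), .num17(df$thetaCS_0), .num17(df$gamma))
  },
  cg_pwmcos = function(df, off) {
    sprintf("%6d %6d %6d %6d %s %s %s %s %s %s %s %s", df$j + 1 - off,
            df$jm + 1 - off, df$jp + 1 - off, df$m + 1,
            .num17(df$r0), .num17(df$theta1_0), .num17(df$theta2_0),
            .num17(df$theta3_0), .num17(df$gamma), .num17(df$gamma_pwm),
            .num17(df$eps_shift), .num17(df$w))
  },
  cg_hb = function(df, off) {
    sprintf("%6d %6d %6d %6d %s %s %s %s %s %s", df$i + 1 - off,
            df$j + 1 - off, df$si + 1 - off, df$j2 + 1 - off,
            .num17(df$r0), .num17(df$theta1_0), .num17(df$theta2_0),
            .num17(df$gamma), .num17(df$eps), .num17(df$w))
  })

.sec_of_table <- c(bonds = "bonds", angles = "angles",
                   dihedrals = "dihedrals", contacts = "pairs",
                   gauss13 = "cg_gaussian_13", stacks = "cg_base_stacks",
                   basepairs = "cg_base_pairs",
                   crossstacks = "cg_cross_stacks", pwmcos = "cg_pwmcos",
                   hb = "cg_hb")

#' Write a CG topology as .top + .itp files
#'
#' One `.itp` per molecule block plus a major `.top` that `#include`s them.
#' Interaction records whose particles span more than one block are written
#' into the `.top` with global indices.  Numeric fields use full double
#' precision so that [read_topology()] round-trips field-for-field.
#'
#' @param top A [cg_topology()].
#' @param dir Output directory (created if missing).
#' @param name System name; files are `<name>.top` and `<name>_NN.itp`.
#' @return Invisibly the path of the .top file.
#' @export
write_topology <- function(top, dir, name = "system") {
  validate_topology(top)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  blocks <- top$molecules
  nb <- length(blocks)
  block_of <- function(idx) {
    findInterval(idx, vapply(blocks, function(b) b$first, numeric(1)))
  }
  idx_cols <- c("i", "j", "k", "l", "s", "si", "sj", "ai", "aj", "j2", "jm",
                "jp")
  split_records <- function(df) {
    if (!nrow(df)) {
      return(list(per_block = rep(list(df), nb), cross = df))
    }
    cols <- intersect(idx_cols, names(df))
    bmat <- vapply(cols, function(cl) block_of(df[[cl]]),
                   numeric(nrow(df)))
    bmat <- matrix(bmat, nrow = nrow(df))
    same <- apply(bmat, 1, function(r) all(r == r[1]))
    home <- bmat[, 1]
    per_block <- lapply(seq_len(nb), function(bi) {
      df[same & home == bi, , drop = FALSE]
    })
    list(per_block = per_block, cross = df[!same, , drop = FALSE])
  }
  splits <- lapply(names(.sec_of_table), function(tb) split_records(top[[tb]]))
  names(splits) <- names(.sec_of_table)

  itp_files <- character(nb)
  p <- top$particles
  for (bi in seq_len(nb)) {
    b <- blocks[[bi]]
    itp_files[bi] <- sprintf("%s_%02d.itp", name, bi)
    con <- file(file.path(dir, itp_files[bi]), "w")
    rng <- (b$first:b$last) + 1L
    lines <- c("[ moleculetype ]", sprintf("%s 1", b$name), "", "[ atoms ]")
    lines <- c(lines, sprintf(
      "%6d %-4s %6d %-5s %-2s %-8s %s %s %s %s %s %s",
      seq_along(rng), p$name[rng], p$resid[rng], p$resname[rng],
      p$chain[rng], p$class[rng], .num17(p$mass[rng]),
      .num17(p$charge[rng]), .num17(p$radius[rng]), .num17(p$lambda[rng]),
      .num17(p$sigma[rng]), .num17(p$eps[rng])))
    for (tb in names(.sec_of_table)) {
      df <- splits[[tb]]$per_block[[bi]]
      if (nrow(df)) {
        lines <- c(lines, "", sprintf("[ %s ]", .sec_of_table[tb]),
                   .sec_writers[[.sec_of_table[tb]]](df, b$first))
      }
    }
    excl <- top$exclusions
    if (nrow(excl)) {
      inb <- excl[, 1] >= b$first & excl[, 1] <= b$last &
        excl[, 2] >= b$first & excl[, 2] <= b$last
      if (any(inb)) {
        lines <- c(lines, "", "[ exclusions ]",
                   sprintf("%6d %6d", excl[inb, 1] + 1 - b$first,
                           excl[inb, 2] + 1 - b$first))
      }
    }
    writeLines(lines, con)
    close(con)
  }
  top_path <- file.path(dir, paste0(name, ".top"))
  con <- file(top_path, "w")
  lines <- c("; CG topology", sprintf("#include \"%s\"", itp_files), "")
  for (tb in names(.sec_of_table)) {
    df <- splits[[tb]]$cross
    if (nrow(df)) {
      lines <- c(lines, sprintf("[ intermolecular_%s ]", .sec_of_table[tb]),
                 .sec_writers[[.sec_of_table[tb]]](df, 0L), "")
    }
  }
  lines <- c(lines, "[ system ]", name, "", "[ molecules ]",
             vapply(blocks, function(b) sprintf("%s 1", b$name),
                    character(1)))
  writeLines(lines, con)
  close(con)
  invisible(top_path)
}

# tokenizer: strip ';' comments, keep non-empty
.top_tokens <- function(lines) {
  lines <- sub(";.*$", "", lines)
  lines <- trimws(lines)
  lines[nzchar(lines)]
}

.parse_section <- function(sec, body, off, file) {
  f <- function(tok, k) as.numeric(tok[k])
  g <- function(tok, k) as.integer(tok[k]) - 1L + off
  rows <- lapply(seq_along(body), function(li) {
    tok <- strsplit(body[li], "\\s+")[[1]]
    line_err <- function(msg) {
      stop("malformed ", sec, " record (", file, "): ", msg, " [", body[li],
           "]")
    }
    out <- switch(sec,
      bonds = {
        if (length(tok) != 6) line_err("expected 6 fields")
        func <- as.integer(tok[3])
        if (!func %in% .FT_BONDS) line_err(paste("unknown function type",
                                                 func))
        data.frame(i = g(tok, 1), j = g(tok, 2), func = func,
                   b0 = f(tok, 4), c1 = f(tok, 5), c2 = f(tok, 6))
      },
      angles = {
        if (length(tok) != 7) line_err("expected 7 fields")
        func <- as.integer(tok[4])
        if (!func %in% .FT_ANGLES) line_err(paste("unknown function type",
                                                  func))
        data.frame(i = g(tok, 1), j = g(tok, 2), k = g(tok, 3), func = func,
                   theta0 = f(tok, 5), ka = f(tok, 6),
                   table = ifelse(tok[7] == "-", "", tok[7]),
                   stringsAsFactors = FALSE)
      },
      dihedrals = {
        if (length(tok) != 10) line_err("expected 10 fields")
        func <- as.integer(tok[5])
        if (!func %in% .FT_DIHEDRALS) {
          line_err(paste("unknown function type", func))
        }
        data.frame(i = g(tok, 1), j = g(tok, 2), k = g(tok, 3),
                   l = g(tok, 4), func = func, phi0 = f(tok, 6),
                   mult = f(tok, 7), kd = f(tok, 8), sigma = f(tok, 9),
                   table = ifelse(tok[10] == "-", "", tok[10]),
                   stringsAsFactors = FALSE)
      },
      pairs = {
        if (length(tok) != 5) line_err("expected 5 fields")
        if (as.integer(tok[3]) != 1L) {
          line_err(paste("unknown function type", tok[3]))
        }
        data.frame(i = g(tok, 1), j = g(tok, 2), sigma = f(tok, 4),
                   eps = f(tok, 5))
      },
      cg_gaussian_13 = {
        if (length(tok) != 5) line_err("expected 5 fields")
        data.frame(i = g(tok, 1), k = g(tok, 2), r0 = f(tok, 3),
                   eps = f(tok, 4), w = f(tok, 5))
      },
      cg_base_stacks = {
        if (length(tok) != 8) line_err("expected 8 fields")
        data.frame(i = g(tok, 1), j = g(tok, 2), s = g(tok, 3),
                   eps = f(tok, 4), alpha = f(tok, 5), r0 = f(tok, 6),
                   theta0 = f(tok, 7), gamma = f(tok, 8))
      },
      cg_base_pairs = {
        if (length(tok) != 11) line_err("expected 11 fields")
        data.frame(i = g(tok, 1), j = g(tok, 2), si = g(tok, 3),
                   sj = g(tok, 4), eps = f(tok, 5), alpha = f(tok, 6),
                   r0 = f(tok, 7), theta1_0 = f(tok, 8),
                   theta2_0 = f(tok, 9), phi0 = f(tok, 10),
                   gamma = f(tok, 11))
      },
      cg_cross_stacks = {
        if (length(tok) != 10) line_err("expected 10 fields")
        data.frame(i = g(tok, 1), j = g(tok, 2), ai = g(tok, 3),
                   aj = g(tok, 4), eps = f(tok, 5), alpha = f(tok, 6),
                   r0 = f(tok, 7), theta3_0 = f(tok, 8),
                   thetaCS_0 = f(tok, 9), gamma = f(tok, 10))
      },
      cg_pwmcos = {
        if (length(tok) != 12) line_err("expected 12 fields")
        data.frame(j = g(tok, 1), jm = g(tok, 2), jp = g(tok, 3),
                   m = as.integer(tok[4]) - 1L, r0 = f(tok, 5),
                   theta1_0 = f(tok, 6), theta2_0 = f(tok, 7),
                   theta3_0 = f(tok, 8), gamma = f(tok, 9),
                   gamma_pwm = f(tok, 10), eps_shift = f(tok, 11),
                   w = f(tok, 12))
      },
      cg_hb = {
        if (length(tok) != 10) line_err("expected 10 fields")
        data.frame(i = g(tok, 1), j = g(tok, 2), si = g(tok, 3),
                   j2 = g(tok, 4), r0 = f(tok, 5), theta1_0 = f(tok, 6),
                   theta2_0 = f(tok, 7), gamma = f(tok, 8), eps = f(tok, 9),
                   w = f(tok, 10))
      },
      stop("unknown section [ ", sec, " ] in ", file))
    out
  })
  do.call(rbind, rows)
}

#' Read a CG topology from .top + #include'd .itp files
#'
#' @param path Path to the major .top file.
#' @return A validated [cg_topology()] with a single global 0-based
#'   numbering.
#' @export
read_topology <- function(path) {
  dir <- dirname(path)
  lines <- readLines(path)
  inc <- regmatches(lines, regexec('^#include\\s+"([^"]+)"', lines))
  itp_files <- vapply(inc[lengths(inc) == 2], `[`, character(1), 2)
  tabs <- list(particles = NULL)
  for (tb in names(.sec_of_table)) tabs[[tb]] <- empty_records(tb)
  excl_all <- list()
  molecules <- list()
  offset <- 0L

  parse_itp <- function(file) {
    fpath <- file.path(dir, file)
    if (!file.exists(fpath)) stop("missing include file: ", file)
    toks <- .top_tokens(readLines(fpath))
    secs <- .split_sections(toks)
    if (!"moleculetype" %in% names(secs) || !"atoms" %in% names(secs)) {
      stop("itp file ", file, " lacks [ moleculetype ] or [ atoms ]")
    }
    mname <- strsplit(secs$moleculetype[1], "\\s+")[[1]][1]
    atoms <- do.call(rbind, lapply(secs$atoms, function(ln) {
      tok <- strsplit(ln, "\\s+")[[1]]
      if (length(tok) != 12) {
        stop("malformed atom record (", file, "): ", ln)
      }
      data.frame(name = tok[2], class = tok[6], resname = tok[4],
                 resid = as.integer(tok[3]), chain = tok[5],
                 mass = as.numeric(tok[7]), charge = as.numeric(tok[8]),
                 radius = as.numeric(tok[9]), lambda = as.numeric(tok[10]),
                 sigma = as.numeric(tok[11]), eps = as.numeric(tok[12]),
                 stringsAsFactors = FALSE)
    }))
    natom <- nrow(atoms)
    for (sec in setdiff(names(secs), c("moleculetype", "atoms",
                                       "exclusions"))) {
      tb <- names(.sec_of_table)[match(sec, .sec_of_table)]
      if (is.na(tb)) stop("unknown section [ ", sec, " ] in ", file)
      df <- .parse_section(sec, secs[[sec]], offset, file)
      idx_cols <- intersect(c("i", "j", "k", "l", "s", "si", "sj", "ai",
                              "aj", "j2", "jm", "jp"), names(df))
      for (cl in idx_cols) {
        if (any(df[[cl]] < offset | df[[cl]] >= offset + natom)) {
          stop("index out of molecule range in [ ", sec, " ] of ", file)
        }
      }
      tabs[[tb]] <<- rbind(tabs[[tb]], df)
    }
    if ("exclusions" %in% names(secs)) {
      ex <- do.call(rbind, lapply(secs$exclusions, function(ln) {
        tok <- as.integer(strsplit(ln, "\\s+")[[1]])
        c(tok[1] - 1L + offset, tok[2] - 1L + offset)
      }))
      excl_all[[length(excl_all) + 1L]] <<- ex
    }
    tabs$particles <<- rbind(tabs$particles, atoms)
    molecules[[length(molecules) + 1L]] <<-
      list(name = mname, first = offset, last = offset + natom - 1L,
           itp = file)
    offset <<- offset + natom
  }
  for (f in itp_files) parse_itp(f)

  # intermolecular records in the .top itself (global indices)
  toks <- .top_tokens(lines[!grepl("^#include", lines)])
  secs <- .split_sections(toks)
  for (sec in setdiff(names(secs), c("system", "molecules"))) {
    base <- sub("^intermolecular_", "", sec)
    tb <- names(.sec_of_table)[match(base, .sec_of_table)]
    if (is.na(tb)) stop("unknown section [ ", sec, " ] in ", path)
    df <- .parse_section(base, secs[[sec]], 0L, path)
    tabs[[tb]] <- rbind(tabs[[tb]], df)
  }
  excl <- if (length(excl_all)) do.call(rbind, excl_all) else
    matrix(integer(), ncol = 2)
  storage.mode(excl) <- "integer"
  cg_topology(tabs$particles, bonds = tabs$bonds, angles = tabs$angles,
              dihedrals = tabs$dihedrals, contacts = tabs$contacts,
              gauss13 = tabs$gauss13, stacks = tabs$stacks,
              basepairs = tabs$basepairs, crossstacks = tabs$crossstacks,
              pwmcos = tabs$pwmcos, hb = tabs$hb, exclusions = excl,
              molecules = molecules)
}

.split_sections <- function(toks) {
  hdr <- grepl("^\\[", toks)
  sec_names <- tolower(gsub("[][ ]", "", toks[hdr]))
  idx <- cumsum(hdr)
  body <- split(toks[!hdr], factor(idx[!hdr], levels = seq_along(sec_names)))
  stats::setNames(body, sec_names)
}
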