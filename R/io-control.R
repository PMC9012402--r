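# INI-style MD control file: sections [input], [output], [energy],
# [dynamics], [boundary].  Unknown keys are errors, not warnings — a typo in
# a cutoff silently falling back to a default would be dangerous.

.control_keys <- list(
  input = c("topology", "coordinates", "pwm"),
  output = c("trajectory", "log", "traj_stride", "log_stride"),
  energy = c("cutoff_ele", "pairlist_ele", "cutoff_hps", "pairlist_hps",
             "cutoff_bp", "pairlist_bp", "pairlist_exv", "pairlist_pwmcos",
             "eps_exv", "salt", "ionic_strength", "terms"),
  dynamics = c("nsteps", "dt", "temperature", "friction", "seed",
               "neighbor_interval"),
  boundary = c("type", "box_x", "box_y", "box_z"))

#' Read an MD control file
#'
#' INI-sectioned control file; unset keys take the package defaults (per-term
#' cutoff/pair-list distances of [default_cutoffs()], a 10 fs time step, a
#' 20-step neighbor-list update interval).  Validation happens here: every
#' pair-list distance must exceed its cutoff, and a periodic box must be
#' equal to or larger than three times the largest pair-list distance.
#'
#' @param path Control file.
#' @return Object of class `cg_control`: named list of sections with parsed
#'   values and derived cutoff tables.
#' @export
read_control <- function(path) {
  lines <- readLines(path)
  lines <- sub("[;#].*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  sec <- NA_character_
  cfg <- lapply(.control_keys, function(x) list())
  for (ln in lines) {
    if (grepl("^\\[", ln)) {
      sec <- tolower(gsub("[][ ]", "", ln))
      if (!sec %in% names(.control_keys)) {
        stop("unknown control-file section: [", sec, "]")
      }
    } else {
      if (is.na(sec)) stop("key outside any section: ", ln)
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      if (length(kv) != 2) stop("malformed line: ", ln)
      key <- trimws(kv[1]); val <- trimws(kv[2])
      if (!key %in% .control_keys[[sec]]) {
        stop("unknown key '", key, "' in section [", sec, "]")
      }
      cfg[[sec]][[key]] <- val
    }
  }
  num <- function(section, key, default) {
    v <- cfg[[section]][[key]]
    if (is.null(v)) unname(default) else as.numeric(v)
  }
  chr <- function(section, key, default = NULL) {
    v <- cfg[[section]][[key]]
    if (is.null(v)) default else v
  }
  co <- default_cutoffs()
  cutoffs <- list(
    rc = c(ele = num("energy", "cutoff_ele", co$rc["ele"]),
           hps = num("energy", "cutoff_hps", co$rc["hps"]),
           bp = num("energy", "cutoff_bp", co$rc["bp"])),
    rp = c(ele = num("energy", "pairlist_ele",
                     num("energy", "cutoff_ele", co$rc["ele"]) + 5),
           hps = num("energy", "pairlist_hps",
                     num("energy", "cutoff_hps", co$rc["hps"]) + 5),
           bp = num("energy", "pairlist_bp",
                    num("energy", "cutoff_bp", co$rc["bp"]) + 5),
           pwmcos = num("energy", "pairlist_pwmcos", co$rp["pwmcos"]),
           exv = num("energy", "pairlist_exv", co$rp["exv"])))
  bad <- names(cutoffs$rc)[cutoffs$rp[names(cutoffs$rc)] <= cutoffs$rc]
  if (length(bad)) {
    stop("pair-list distance must exceed the cutoff for: ",
         paste(bad, collapse = ", "))
  }
  boundary <- chr("boundary", "type", "none")
  if (!boundary %in% c("none", "periodic")) {
    stop("boundary type must be 'none' or 'periodic'")
  }
  box <- NULL
  if (boundary == "periodic") {
    box <- c(num("boundary", "box_x", NA), num("boundary", "box_y", NA),
             num("boundary", "box_z", NA))
    if (any(is.na(box))) stop("periodic boundary needs box_x/box_y/box_z")
    if (any(box < 3 * max(cutoffs$rp))) {
      stop("periodic box must be equal to or larger than three times the ",
           "largest pair-list distance (", 3 * max(cutoffs$rp), " A)")
    }
  }
  terms <- chr("energy", "terms")
  structure(list(
    input = list(topology = chr("input", "topology"),
                 coordinates = chr("input", "coordinates"),
                 pwm = chr("input", "pwm")),
    output = list(trajectory = chr("output", "trajectory"),
                  log = chr("output", "log"),
                  traj_stride = as.integer(num("output", "traj_stride", 0)),
                  log_stride = as.integer(num("output", "log_stride", 0))),
    cutoffs = cutoffs,
    eps_exv = num("energy", "eps_exv", 0.6),
    salt = num("energy", "salt", 0.15),
    ionic_strength = num("energy", "ionic_strength",
                         num("energy", "salt", 0.15)),
    terms = if (is.null(terms)) NULL else
      strsplit(terms, "[,[:space:]]+")[[1]],
    nsteps = as.integer(num("dynamics", "nsteps", 0)),
    dt = num("dynamics", "dt", 10),
    temperature = num("dynamics", "temperature", 300),
    friction = num("dynamics", "friction", 0.001),
    seed = as.integer(num("dynamics", "seed", 1)),
    neighbor_interval = as.integer(num("dynamics", "neighbor_interval", 20)),
    boundary = boundary, box = box), class = "cg_control")
}

#' @export
print.cg_control <- function(x, ...) {
  cat("CG control: nsteps", x$nsteps, "dt", x$dt, "fs, T", x$temperature,
      "K, friction", x$friction, "1/fs\n")
  cat("  boundary:", x$boundary, "\n")
  cat("  cutoffs (A): ", paste(names(x$cutoffs$rc), x$cutoffs$rc,
                               sep = "=", collapse = " "), "\n")
  cat("  pair lists (A):", paste(names(x$cutoffs$rp), x$cutoffs$rp,
                                 sep = "=", collapse = " "), "\n")
  invisible(x)
}
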