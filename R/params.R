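# Packaged parameter data.  Each loader reads a documented plain-text
# schema from inst/extdata so users can substitute their own calibrations;
# results are cached per session.

.param_env <- new.env(parent = emptyenv())

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "cgmdr")
  if (path == "") path <- file.path("inst", "extdata", file)  # pre-install
  if (!file.exists(path)) stop("missing parameter file: ", file)
  path
}

.cached <- function(key, loader) {
  if (!exists(key, .param_env)) assign(key, loader(), .param_env)
  get(key, .param_env)
}

#' Hydropathy-scale residue parameters
#'
#' Per-residue mass, charge, pair diameter sigma, hydropathy lambda and pair
#' depth epsilon for the HPS model (one bead per amino acid; `R*` rows are
#' one-bead RNA nucleotides).  See `extdata/hps_params.tsv` for the schema.
#'
#' @param path Optional substitute parameter file (same schema).
#' @return data.frame keyed by `residue`.
#' @export
hps_parameters <- function(path = NULL) {
  if (!is.null(path)) return(.read_hps(path))
  .cached("hps", function() .read_hps(.extdata("hps_params.tsv")))
}
.read_hps <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

# key-value parameter files
.read_kv <- function(path) {
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  stats::setNames(as.numeric(df$value), df$key)
}

#' Structure-based protein model defaults
#' @return Named numeric vector (bond_k, gauss13_eps, ...); see
#'   `extdata/aicg2p_params.tsv`.
#' @export
aicg2p_parameters <- function() {
  .cached("aicg2p", function() .read_kv(.extdata("aicg2p_params.tsv")))
}

#' Three-site DNA model constants
#' @return Named numeric vector; see `extdata/spn2c_params.tsv`.
#' @export
spn2c_parameters <- function() {
  .cached("spn2c", function() .read_kv(.extdata("spn2c_params.tsv")))
}

#' Sequence-dependent base-step geometry table
#' @param path Optional substitute table (same schema).
#' @return data.frame with one row per dinucleotide step: twist, roll, tilt
#'   (deg), shift, slide, rise (A).
#' @export
base_step_table <- function(path = NULL) {
  if (!is.null(path)) {
    return(utils::read.delim(path, comment.char = "#",
                             stringsAsFactors = FALSE))
  }
  .cached("base_step", function() {
    utils::read.delim(.extdata("base_step.tsv"), comment.char = "#",
                      stringsAsFactors = FALSE)
  })
}

#' Default tabulated flexible-term spline tables
#'
#' Loads the packaged synthetic statistics-derived angle and dihedral tables
#' (generic shapes standing in for residue-specific calibrations, which are
#' external parameter data).
#'
#' @return Named list of [spline_table()]s: `flex_angle`, `flex_dihedral`.
#' @export
default_flex_tables <- function() {
  .cached("flex_tables", function() {
    a <- utils::read.delim(.extdata("flex_angle_synthetic.tsv"),
                           comment.char = "#")
    d <- utils::read.delim(.extdata("flex_dihedral_synthetic.tsv"),
                           comment.char = "#")
    list(flex_angle = spline_table(a$theta, a$E),
         flex_dihedral = spline_table(d$phi, d$E, periodic = TRUE))
  })
}

# three-letter residue alias table (modified-residue names -> standard)
.RES_ALIAS <- c(MSE = "MET", HSD = "HIS", HSE = "HIS", HSP = "HIS",
                HID = "HIS", HIE = "HIS", HIP = "HIS", CYX = "CYS",
                SEC = "CYS")

.canon_res <- function(resname) {
  out <- toupper(resname)
  hit <- out %in% names(.RES_ALIAS)
  out[hit] <- .RES_ALIAS[out[hit]]
  out
}
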