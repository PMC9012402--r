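#' Rule-based nonbonded exclusions
#'
#' Generic nonbonded terms (excluded volume, electrostatics, hydropathy
#' pairs) skip: every 1-2 and 1-3 bonded pair, every 1-4 dihedral end pair,
#' and — for the excluded-volume term only — native-contact pairs and DNA
#' stacking/pairing/cross-stacking partners (those pairs already interact
#' through their own dedicated terms).
#'
#' @param top A [cg_topology()].
#' @return List with `common` (applies to all generic nonbonded terms) and
#'   `exv_only` (additional exclusions for the excluded-volume term), both
#'   2-column 0-based matrices with i < j.
#' @export
build_exclusions <- function(top) {
  common <- bonded_12_13_pairs(top)
  if (nrow(top$dihedrals)) {
    p14 <- cbind(pmin(top$dihedrals$i, top$dihedrals$l),
                 pmax(top$dihedrals$i, top$dihedrals$l))
    common <- rbind(common, p14)
  }
  common <- unique(common)
  extra <- rbind(
    if (nrow(top$contacts)) cbind(top$contacts$i, top$contacts$j),
    if (nrow(top$stacks)) cbind(pmin(top$stacks$i, top$stacks$j),
                                pmax(top$stacks$i, top$stacks$j)),
    if (nrow(top$basepairs)) cbind(pmin(top$basepairs$i, top$basepairs$j),
                                   pmax(top$basepairs$i, top$basepairs$j)),
    if (nrow(top$crossstacks)) cbind(pmin(top$crossstacks$i,
                                          top$crossstacks$j),
                                     pmax(top$crossstacks$i,
                                          top$crossstacks$j)))
  if (is.null(extra)) extra <- matrix(integer(), ncol = 2)
  extra <- unique(extra)
  storage.mode(common) <- "integer"
  storage.mode(extra) <- "integer"
  list(common = common, exv_only = extra)
}

#' Default nonbonded cutoff and pair-list distances (A)
#'
#' Per-term defaults: electrostatics 52/57, hydropathy (HPS/KH) pairs 39/44,
#' base pairing 18/23, PWM recognition and backbone hydrogen bonds use a
#' per-site cutoff of r0 + 5 with a 23 A pair list, excluded volume has its
#' cutoff built into the functional form with a 15 A pair list.
#'
#' @return Named list of `rc` (cutoffs) and `rp` (pair-list distances).
#' @export
default_cutoffs <- function() {
  list(rc = c(ele = 52, hps = 39, bp = 18),
       rp = c(ele = 57, hps = 44, bp = 23, pwmcos = 23, exv = 15))
}

#' Assemble a simulation system from a topology
#'
#' Precomputes everything the compiled engine needs: flattened interaction
#' records, per-term particle subsets, exclusion sets, the electrostatic
#' environment, spline tables, and cutoff/pair-list distances.  Which
#' generic nonbonded terms are active is taken from the topology (builders
#' tag their model's terms) and can be overridden.
#'
#' @param top A [cg_topology()].
#' @param temperature Temperature, K (used for the electrostatic environment
#'   and thermostat default).
#' @param salt Salt molarity, M.
#' @param ionic_strength Ionic strength, M; defaults to `salt`.
#' @param terms Character vector of generic nonbonded terms to activate,
#'   subset of `c("exv", "hps", "ele")`; default: the topology's
#'   `nonbonded` attribute, else exv plus ele-when-charged.
#' @param eps_exv Excluded-volume energy scale, kcal/mol.
#' @param cutoffs Optional overrides, same shape as [default_cutoffs()].
#' @param pwm Optional [read_pwm()] object, required when the topology has
#'   PWM recognition sites.
#' @param tables Named list of `cg_spline_table`s for tabulated angle and
#'   dihedral records.
#' @return Object of class `cg_system`.
#' @export
cg_system <- function(top, temperature = 300, salt = 0.15,
                      ionic_strength = salt, terms = NULL,
                      eps_exv = 0.6, cutoffs = NULL, pwm = NULL,
                      tables = NULL) {
  validate_topology(top)
  p <- top$particles
  n <- nrow(p)
  co <- default_cutoffs()
  if (!is.null(cutoffs)) {
    for (k in names(cutoffs$rc)) co$rc[k] <- cutoffs$rc[k]
    for (k in names(cutoffs$rp)) co$rp[k] <- cutoffs$rp[k]
  }
  bad <- names(co$rc)[co$rp[names(co$rc)] <= co$rc]
  if (length(bad)) {
    stop("pair-list distance must exceed the cutoff for: ",
         paste(bad, collapse = ", "))
  }
  if (is.null(terms)) {
    terms <- attr(top, "nonbonded")
    if (is.null(terms)) {
      terms <- c("exv", if (any(p$charge != 0)) "ele")
    }
  }
  stopifnot(all(terms %in% c("exv", "hps", "ele")))
  if (nrow(top$pwmcos) && is.null(pwm)) {
    stop("topology has PWM recognition sites; supply pwm =")
  }
  check_model_combination(top, terms)

  env <- ele_environment(temperature, salt, ionic_strength)
  excl <- build_exclusions(top)

  base_code <- match(p$resname, c("DA", "DC", "DG", "DT")) - 1L
  is_base <- p$name %in% c("DB", "RB")
  base_code[is.na(base_code) | !is_base] <- -1L

  # sugar bonded to each base, and the 5' preceding base on the same strand
  base_sugar <- rep(-1L, n); base_prev <- rep(-1L, n)
  if (any(is_base) && nrow(top$bonds)) {
    b <- top$bonds
    sugar_of <- function(idx) {
      nb <- c(b$j[b$i == idx], b$i[b$j == idx])
      nb[p$name[nb + 1] %in% c("DS", "RS")][1]
    }
    for (ib in which(is_base) - 1L) {
      sg <- sugar_of(ib)
      if (is.na(sg)) next
      base_sugar[ib + 1] <- sg
      nbs <- c(b$j[b$i == sg], b$i[b$j == sg])
      ph <- nbs[p$name[nbs + 1] %in% c("DP", "RP") & nbs < sg]
      if (length(ph)) {
        nbp <- c(b$j[b$i == ph[1]], b$i[b$j == ph[1]])
        sprev <- nbp[p$name[nbp + 1] %in% c("DS", "RS") & nbp != sg]
        if (length(sprev)) {
          nbs2 <- c(b$j[b$i == sprev[1]], b$i[b$j == sprev[1]])
          bprev <- nbs2[p$name[nbs2 + 1] %in% c("DB", "RB")]
          if (length(bprev)) base_prev[ib + 1] <- bprev[1]
        }
      }
    }
  }

  # spline tables referenced by angle/dihedral records
  table_names <- unique(c(top$angles$table[top$angles$func == 21],
                          top$dihedrals$table[top$dihedrals$func == 22]))
  table_names <- table_names[!is.na(table_names) & table_names != ""]
  if (length(table_names)) {
    if (is.null(tables)) tables <- default_flex_tables()
    missing <- setdiff(table_names, names(tables))
    if (length(missing)) {
      stop("missing spline tables: ", paste(missing, collapse = ", "))
    }
  }
  packed_tables <- lapply(table_names,
                          function(nm) .spline_table_pack(tables[[nm]]))
  tab_idx <- function(nms) {
    out <- match(nms, table_names) - 1L
    out[is.na(out)] <- -1L
    out
  }

  pw <- top$pwmcos
  eps_by_base <- numeric(0)
  if (nrow(pw)) {
    comp <- c(4, 3, 2, 1)   # A<->T, C<->G (1-based positions in ACGT)
    for (r in seq_len(nrow(pw))) {
      col <- pwm$scores[, pw$m[r] + 1]
      nm <- pwm$n_contacts[pw$m[r] + 1]
      e_self <- pw$gamma_pwm[r] * (col / nm + pw$eps_shift[r])
      # base read on either strand: own column plus complementary base score
      e_eff <- e_self + e_self[comp]
      eps_by_base <- c(eps_by_base, e_eff)
    }
  }

  sys <- list(
    n = n, mass = p$mass, charge = p$charge, radius = p$radius,
    lambda = p$lambda, sigma = p$sigma, eps = p$eps,
    base = base_code,
    bonds = .rec(top$bonds, c("i", "j", "func"), c("b0", "c1", "c2")),
    angles = c(.rec(top$angles, c("i", "j", "k", "func"),
                    c("theta0", "ka")),
               list(table = tab_idx(top$angles$table))),
    dihedrals = c(.rec(top$dihedrals, c("i", "j", "k", "l", "func"),
                       c("phi0", "mult", "kd", "sigma")),
                  list(table = tab_idx(top$dihedrals$table))),
    contacts = .rec(top$contacts, c("i", "j"), c("sigma", "eps")),
    gauss13 = .rec(top$gauss13, c("i", "k"), c("r0", "eps", "w")),
    stacks = .rec(top$stacks, c("i", "j", "s"),
                  c("eps", "alpha", "r0", "theta0", "gamma")),
    basepairs = .rec(top$basepairs, c("i", "j", "si", "sj"),
                     c("eps", "alpha", "r0", "theta1_0", "theta2_0",
                       "phi0", "gamma")),
    crossstacks = .rec(top$crossstacks, c("i", "j", "ai", "aj"),
                       c("eps", "alpha", "r0", "theta3_0", "thetaCS_0",
                         "gamma")),
    pwmcos = c(.rec(pw, c("j", "jm", "jp"),
                    c("r0", "theta1_0", "theta2_0", "theta3_0", "gamma",
                      "w")),
               list(eps_by_base = eps_by_base)),
    hb = .rec(top$hb, c("i", "j", "si", "j2"),
              c("r0", "theta1_0", "theta2_0", "gamma", "eps", "w")),
    base_sugar = base_sugar, base_prev = base_prev,
    tables = packed_tables,
    nonbonded = list(
      use_exv = "exv" %in% terms, use_hps = "hps" %in% terms,
      use_ele = "ele" %in% terms && any(p$charge != 0),
      use_pwm = nrow(pw) > 0,
      eps_exv = eps_exv, eps_r = env$eps_r,
      lambda_D = if (is.finite(env$lambda_D)) env$lambda_D else 1e30,
      rc_ele = unname(co$rc["ele"]), rp_ele = unname(co$rp["ele"]),
      rc_hps = unname(co$rc["hps"]), rp_hps = unname(co$rp["hps"]),
      rc_bp = unname(co$rc["bp"]), rp_bp = unname(co$rp["bp"]),
      rp_exv = unname(co$rp["exv"]), rp_pwm = unname(co$rp["pwmcos"]),
      exv_set = seq_len(n) - 1L,
      hps_set = seq_len(n) - 1L,
      ele_set = which(p$charge != 0) - 1L,
      pwm_bases = which(base_code >= 0 & base_sugar >= 0 &
                          base_prev >= 0) - 1L),
    excl_common = excl$common,
    excl_exv = rbind(excl$common, excl$exv_only))
  structure(list(topology = top, engine = sys, env = env, cutoffs = co,
                 terms = terms, temperature = temperature),
            class = "cg_system")
}

.rec <- function(df, int_cols, num_cols) {
  out <- list()
  for (cl in int_cols) {
    v <- if (cl %in% names(df)) df[[cl]] else integer(nrow(df))
    out[[cl]] <- as.integer(v)
  }
  for (cl in num_cols) {
    v <- if (cl %in% names(df)) df[[cl]] else numeric(nrow(df))
    v[is.na(v)] <- 0
    out[[cl]] <- as.numeric(v)
  }
  out
}

# Terms are only meaningful for the molecule classes that define them.
check_model_combination <- function(top, terms) {
  p <- top$particles
  has_prot <- any(p$class == "protein")
  has_dna <- any(p$class == "dna")
  if (nrow(top$stacks) && !has_dna) {
    stop("base-stacking records require DNA particles")
  }
  if (nrow(top$pwmcos) && !(has_prot && has_dna)) {
    stop("PWM recognition sites require both protein and DNA")
  }
  if (nrow(top$hb) && !(has_prot && has_dna)) {
    stop("backbone hydrogen-bond sites require both protein and DNA")
  }
  invisible(TRUE)
}

#' @export
print.cg_system <- function(x, ...) {
  cat("CG system:", x$engine$n, "particles; nonbonded terms:",
      paste(x$terms, collapse = ", "), "\n")
  print(x$env)
  invisible(x)
}

#' Total energy and forces for one frame
#'
#' Evaluates every interaction term of the assembled system with per-term
#' cell-linked-list neighbor lists, returning the per-term energy
#' decomposition and the analytic forces (the exact gradient of the reported
#' total).
#'
#' @param system A [cg_system()].
#' @param frame A [cg_frame()]; a periodic box on the frame activates
#'   minimum-image conventions.
#' @return Object of class `cg_energy_report`: list with `terms` (named
#'   kcal/mol; only active terms are reported), `total`, `forces` (N x 3,
#'   kcal/mol/A) and `n_pairs` (neighbor-list sizes).
#' @export
cg_energy <- function(system, frame) {
  stopifnot(inherits(system, "cg_system"), inherits(frame, "cg_frame"))
  if (nrow(frame$positions) != system$engine$n) {
    stop("frame has ", nrow(frame$positions), " particles; topology has ",
         system$engine$n)
  }
  periodic <- !is.null(frame$box)
  if (periodic) .check_box_rule(system, frame$box)
  out <- cpp_energy_forces(system$engine, frame$positions,
                           if (periodic) frame$box else c(0, 0, 0),
                           periodic)
  terms <- out$terms
  keep <- .active_terms(system)
  terms <- terms[names(terms) %in% keep]
  structure(list(terms = terms, total = sum(out$terms),
                 forces = out$forces, n_pairs = out$n_pairs),
            class = "cg_energy_report")
}

.active_terms <- function(system) {
  top <- system$topology
  nb <- system$engine$nonbonded
  c(if (nrow(top$bonds)) "bond", if (nrow(top$angles)) "angle",
    if (nrow(top$dihedrals)) "dihedral", if (nrow(top$gauss13)) "gauss13",
    if (nrow(top$contacts)) "contact_go",
    if (nb$use_exv) "exv", if (nb$use_ele) "ele", if (nb$use_hps) "hps",
    if (nrow(top$stacks)) "base_stack", if (nrow(top$basepairs)) "base_pair",
    if (nrow(top$crossstacks)) "cross_stack",
    if (nb$use_pwm) "pwmcos", if (nrow(top$hb)) "hb")
}

.check_box_rule <- function(system, box) {
  nb <- system$engine$nonbonded
  rps <- c(if (nb$use_ele) nb$rp_ele, if (nb$use_hps) nb$rp_hps,
           if (nb$use_exv) nb$rp_exv,
           if (nrow(system$topology$basepairs)) nb$rp_bp,
           if (nb$use_pwm || nrow(system$topology$hb)) nb$rp_pwm)
  if (!length(rps)) return(invisible(TRUE))
  need <- 3 * max(rps)
  if (any(box < need)) {
    stop("periodic box must be equal to or larger than ",
         "three times the largest pair-list distance (", need, " A)")
  }
  invisible(TRUE)
}

#' @export
print.cg_energy_report <- function(x, ...) {
  cat("Energy (kcal/mol):\n")
  for (nm in names(x$terms)) cat(sprintf("  %-12s %12.6f\n", nm, x$terms[nm]))
  cat(sprintf("  %-12s %12.6f\n", "total", x$total))
  invisible(x)
}

#' PWM score to recognition-well depth
#'
#' Linear map from a position-weight-matrix element to the depth of the
#' Gaussian recognition well for one site: \eqn{\epsilon =
#' \gamma(e_{PWM,m}(b)/N_m + \epsilon')}.
#'
#' @param pwm A [read_pwm()] object.
#' @param m Column index (0-based).
#' @param b Base letter ("A", "C", "G", "T").
#' @param gamma_pwm Overall scale, kcal/mol.
#' @param eps_shift Additive shift applied to the per-contact score.
#' @return Well depth, kcal/mol (negative values mean repulsive sites).
#' @export
pwm_to_epsilon <- function(pwm, m, b, gamma_pwm, eps_shift) {
  stopifnot(inherits(pwm, "cg_pwm"))
  bi <- match(toupper(b), c("A", "C", "G", "T"))
  if (is.na(bi)) stop("unknown base: ", b)
  nm <- pwm$n_contacts[m + 1]
  stopifnot(nm >= 1)
  unname(gamma_pwm * (pwm$scores[bi, m + 1] / nm + eps_shift))
}
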