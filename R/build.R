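#' Specification for a synthetic ideal-geometry peptide
#'
#' Describes a single-chain polypeptide by sequence and prescribed
#' torsions.  Scalars are recycled across residues.  Defaults build an
#' alpha-helix (phi -57, psi -47, trans peptides) with common sidechain
#' rotamer values.
#'
#' @param sequence One-letter amino-acid string (length >= 2).
#' @param phi,psi,omega Backbone torsions, degrees (scalar or
#'   per-residue vector).
#' @param chi1,chi2 Sidechain torsions, degrees (scalar or per-residue;
#'   ignored for residues without the torsion).  `NULL` = defaults.
#' @param chain Chain identifier (default `"A"`).
#' @return A list of class `peptide_spec`.
#' @export
peptide_spec <- function(sequence, phi = -57, psi = -47, omega = 180,
                         chi1 = NULL, chi2 = NULL, chain = "A") {
  letters1 <- strsplit(toupper(sequence), "")[[1]]
  if (length(letters1) < 2) stop("sequence must have at least 2 residues")
  res_types <- names(.aa3to1)[match(letters1, .aa3to1)]
  if (any(is.na(res_types)))
    stop("unsupported residue letter(s): ",
         paste(unique(letters1[is.na(res_types)]), collapse = ", "))
  n <- length(res_types)
  d_chi1 <- ifelse(res_types == "PRO", -25, -65)
  d_chi2 <- ifelse(res_types == "PRO", 35, 180)
  spec <- list(res_types = res_types,
               phi = .wrap180(rep_len(phi, n)),
               psi = .wrap180(rep_len(psi, n)),
               omega = .wrap180(rep_len(omega, n)),
               chi1 = .wrap180(rep_len(if (is.null(chi1)) d_chi1 else chi1, n)),
               chi2 = .wrap180(rep_len(if (is.null(chi2)) d_chi2 else chi2, n)),
               chain = chain)
  class(spec) <- "peptide_spec"
  spec
}

#' Build an all-atom peptide with exactly the prescribed torsions
#'
#' Constructs heavy-atom coordinates from ideal internal coordinates
#' (standard bond lengths/angles; sidechain geometry from chemical
#' component reference values) by sequential atom placement, so that
#' measuring any defined torsion of the result recovers the prescribed
#' value to numerical precision.  Deterministic: the same spec always
#' yields bit-identical coordinates.  No steric checking is done -- the
#' product is a stated conformation, not a physically relaxed one.
#'
#' Unmeasurable prescribed torsions (phi/omega of the first residue) do
#' not influence the build; psi of the last residue only orients its
#' carbonyl oxygen.
#'
#' @param spec A [peptide_spec()].
#' @return A `StructureRecord` carrying the spec in element
#'   `peptide_spec`.
#' @export
build_peptide <- function(spec) {
  stopifnot(inherits(spec, "peptide_spec"))
  g <- .bb_geom
  n <- length(spec$res_types)
  rows <- list()
  add <- function(i, name, xyz) {
    rows[[length(rows) + 1]] <<- data.frame(
      chain = spec$chain, res_seq = i, icode = "",
      res_type = spec$res_types[i], atom = name,
      element = substr(name, 1, 1), altloc = "",
      x = xyz[1], y = xyz[2], z = xyz[3], occ = 1, b = 0,
      stringsAsFactors = FALSE)
  }
  prevN <- prevCA <- prevC <- NULL
  for (i in seq_len(n)) {
    if (i == 1) {
      N <- c(0, 0, 0)
      CA <- c(g$n_ca, 0, 0)
      th <- (180 - g$ang_n_ca_c) * pi / 180
      C <- CA + g$ca_c * c(cos(th), sin(th), 0)
    } else {
      N <- .place_atom(prevN, prevCA, prevC, g$c_n, g$ang_ca_c_n,
                       spec$psi[i - 1])
      CA <- .place_atom(prevCA, prevC, N, g$n_ca, g$ang_c_n_ca,
                        spec$omega[i])
      C <- .place_atom(prevC, N, CA, g$ca_c, g$ang_n_ca_c, spec$phi[i])
    }
    add(i, "N", N); add(i, "CA", CA); add(i, "C", C)
    O <- .place_atom(N, CA, C, g$c_o, g$ang_ca_c_o,
                     .wrap180(spec$psi[i] + 180))
    add(i, "O", O)
    ty <- spec$res_types[i]
    pos <- list(N = N, CA = CA, C = C)
    if (ty != "GLY") {
      CB <- .place_atom(N, C, CA, g$cb_bond, g$ang_c_ca_cb,
                        g$improper_n_c_ca_cb)
      add(i, "CB", CB)
      pos$CB <- CB
      zm <- .sidechain_zmat[.sidechain_zmat$res_type == ty, , drop = FALSE]
      for (k in seq_len(nrow(zm))) {
        tor <- switch(zm$tor_ref[k],
                      chi1 = spec$chi1[i] + zm$tor_offset[k],
                      chi2 = spec$chi2[i] + zm$tor_offset[k],
                      zm$tor_offset[k])
        xyz <- .place_atom(pos[[zm$ref3[k]]], pos[[zm$ref2[k]]],
                           pos[[zm$ref1[k]]], zm$bond[k], zm$angle[k],
                           .wrap180(tor))
        add(i, zm$atom[k], xyz)
        pos[[zm$atom[k]]] <- xyz
      }
    }
    prevN <- N; prevCA <- CA; prevC <- C
  }
  x <- structure_record(do.call(rbind, rows), identifier = "synthetic",
                        source_format = "synthetic")
  x$peptide_spec <- spec
  x
}

#' Specification of a torsion-space perturbation
#'
#' Each of `phi`, `psi`, `omega`, `chi1`, `chi2` may be `NULL`
#' (untouched), a single number (fixed delta in degrees, added to every
#' selected residue's torsion) or `list(sd = x)` (independent Gaussian
#' deltas with that standard deviation).  Only measurable torsions are
#' perturbed (phi/omega from residue 2 on, psi up to the penultimate
#' residue, chis where the residue has them).
#'
#' @param phi,psi,omega,chi1,chi2 Per-torsion delta specification.
#' @param residues Residue indices to perturb (default: all).
#' @param flip_omega_at Residue indices whose omega is rotated by 180
#'   (trans -> cis or vice versa).
#' @param truncate_sidechains_at Residue indices whose sidechain atoms
#'   beyond CB are removed from the built structure (emulating
#'   unmodeled sidechains; their chi deltas score as 180 downstream).
#' @param seed Integer seed; all randomness in [perturb()] flows from
#'   it.
#' @return A list of class `perturbation_spec`.
#' @export
perturbation_spec <- function(phi = NULL, psi = NULL, omega = NULL,
                              chi1 = NULL, chi2 = NULL, residues = NULL,
                              flip_omega_at = integer(),
                              truncate_sidechains_at = integer(),
                              seed = 1L) {
  structure(list(phi = phi, psi = psi, omega = omega, chi1 = chi1,
                 chi2 = chi2, residues = residues,
                 flip_omega_at = as.integer(flip_omega_at),
                 truncate_sidechains_at = as.integer(truncate_sidechains_at),
                 seed = as.integer(seed)),
            class = "perturbation_spec")
}

#' Apply a torsion-space perturbation to a built peptide
#'
#' Torsions are changed by exactly the drawn deltas and the structure is
#' rebuilt, so downstream atoms rotate rigidly and every other torsion
#' is untouched; the returned ledger is therefore exact ground truth for
#' the deltas a torsion comparison should recover.
#'
#' @param base A `StructureRecord` produced by [build_peptide()].
#' @param pspec A [perturbation_spec()].
#' @return List: `structure` (the perturbed `StructureRecord`),
#'   `ledger` (data frame `residue`, `torsion`, `applied` in degrees)
#'   and `truncated` (residue indices whose sidechains were removed).
#' @export
perturb <- function(base, pspec) {
  stopifnot(inherits(base, "StructureRecord"),
            inherits(pspec, "perturbation_spec"))
  spec <- base$peptide_spec
  if (is.null(spec)) stop("base was not produced by build_peptide()")
  n <- length(spec$res_types)
  bad <- setdiff(c(pspec$residues, pspec$flip_omega_at,
                   pspec$truncate_sidechains_at), seq_len(n))
  if (length(bad)) stop("residue indices out of range: ",
                        paste(bad, collapse = ", "))
  sel <- if (is.null(pspec$residues)) seq_len(n) else pspec$residues
  has_chi1 <- !is.na(.chi1_atom[spec$res_types])
  has_chi2 <- !is.na(.chi2_atom[spec$res_types])
  eligible <- list(phi = setdiff(sel, 1L),
                   psi = setdiff(sel, n),
                   omega = setdiff(sel, 1L),
                   chi1 = sel[has_chi1[sel]],
                   chi2 = sel[has_chi2[sel]])
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(pspec$seed)
  ledger <- list()
  new_spec <- spec
  for (tor in c("phi", "psi", "omega", "chi1", "chi2")) {
    how <- pspec[[tor]]
    if (is.null(how)) next
    idx <- sort(eligible[[tor]])
    if (!length(idx)) next
    deltas <- if (is.list(how)) stats::rnorm(length(idx), 0, how$sd)
    else rep_len(how, length(idx))
    new_spec[[tor]][idx] <- .wrap180(new_spec[[tor]][idx] + deltas)
    ledger[[length(ledger) + 1]] <-
      data.frame(residue = idx, torsion = tor, applied = deltas)
  }
  flips <- sort(setdiff(pspec$flip_omega_at, 1L))
  if (length(flips)) {
    new_spec$omega[flips] <- .wrap180(new_spec$omega[flips] + 180)
    ledger[[length(ledger) + 1]] <-
      data.frame(residue = flips, torsion = "omega", applied = 180)
  }
  out <- build_peptide(new_spec)
  trunc <- sort(pspec$truncate_sidechains_at)
  if (length(trunc)) {
    a <- out$atoms
    rt <- residue_table(out)
    uids <- rt$res_uid[match(trunc, rt$res_seq)]
    drop <- a$res_uid %in% uids & !(a$atom %in% c("N", "CA", "C", "O", "CB"))
    out$atoms <- a[!drop, , drop = FALSE]
  }
  ledger <- if (length(ledger)) do.call(rbind, ledger) else
    data.frame(residue = integer(), torsion = character(),
               applied = numeric())
  list(structure = out, ledger = ledger, truncated = trunc)
}

#' Simulate a per-model metric table with planted group quality
#'
#' Draws a metric table of the shape consumed by [rank_groups()]:
#' `n_groups` predictor groups each submitting `n_models` models for
#' `n_targets` targets.  Group g carries a latent quality
#' `effect * (n_groups - g) / (n_groups - 1)` (group 1 best, last group
#' 0; `effect` is the planted separation in model-population SD units,
#' 0 = no group differences), each model adds unit-SD noise, and every
#' metric is an oriented linear readout of the model latent plus
#' metric-specific noise.
#'
#' @param n_groups,n_targets Table dimensions (>= 2 each).
#' @param n_models Models per group/target (default 5).
#' @param effect Planted group separation in SD units (default 3).
#' @param seed Integer seed.
#' @return Data frame for [rank_groups()], with attributes
#'   `ground_truth` (data frame `group`, `latent_quality`, best first)
#'   and `seed`.
#' @export
synth_metric_table <- function(n_groups, n_targets, n_models = 5,
                               effect = 3, seed = 1L) {
  stopifnot(n_groups >= 2, n_targets >= 2, n_models >= 1)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  groups <- sprintf("G%02d", seq_len(n_groups))
  targets <- sprintf("T%03d", seq_len(n_targets))
  q <- if (n_groups > 1) effect * (n_groups - seq_len(n_groups)) /
    (n_groups - 1) else 0
  df <- expand.grid(model_index = seq_len(n_models), group = groups,
                    target = targets, stringsAsFactors = FALSE,
                    KEEP.OUT.ATTRS = FALSE)
  latent <- q[match(df$group, groups)] + stats::rnorm(nrow(df))
  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  nz <- function(s) stats::rnorm(nrow(df), 0, s)
  df$GDT_HA <- clamp(50 + 8 * latent + nz(3), 0, 100)
  df$GDT_TS <- clamp(60 + 7 * latent + nz(3), 0, 100)
  df$lDDT <- clamp(60 + 6 * latent + nz(3), 0, 100)
  df$CADaa <- clamp(55 + 6 * latent + nz(3), 0, 100)
  df$SG <- clamp(60 + 6 * latent + nz(3), 0, 100)
  df$ASE <- clamp(70 + 5 * latent + nz(3), 0, 100)
  df$clashscore <- pmax(20 - 4 * latent + nz(2), 0)
  df$mean_backbone <- clamp(0.25 - 0.04 * latent + nz(0.02), 0.005, 0.95)
  df$mean_sidechain <- clamp(0.35 - 0.04 * latent + nz(0.02), 0.005, 0.95)
  df <- df[, c("group", "target", "model_index",
               setdiff(names(df), c("group", "target", "model_index")))]
  attr(df, "ground_truth") <- data.frame(group = groups,
                                         latent_quality = q,
                                         stringsAsFactors = FALSE)
  attr(df, "seed") <- seed
  df
}
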