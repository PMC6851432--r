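#' Backbone torsions of every polymer residue
#'
#' phi(i) = C(i-1)-N(i)-CA(i)-C(i); psi(i) = N(i)-CA(i)-C(i)-N(i+1);
#' omega(i) = CA(i-1)-C(i-1)-N(i)-CA(i), i.e. a residue's omega
#' describes the peptide bond preceding it.  A torsion is `NA` at chain
#' termini, across chain breaks (peptide C-N distance > 2.5 Angstrom),
#' or when a defining atom is missing.
#'
#' @param x A `StructureRecord`.
#' @return Data frame, one row per polymer residue: residue identity
#'   columns plus `phi`, `psi`, `omega` in degrees.
#' @export
backbone_torsions <- function(x) {
  stopifnot(inherits(x, "StructureRecord"))
  rt <- residue_table(x)
  rt <- rt[rt$is_polymer, , drop = FALSE]
  a <- x$atoms
  n <- nrow(rt)
  get <- function(i, name) if (i < 1 || i > n) NULL else .atom_xyz(a, rt$res_uid[i], name)
  linked <- function(i, j) {
    # peptide bond between residues i and j (i precedes j)?
    if (i < 1 || j > n) return(FALSE)
    if (rt$chain[i] != rt$chain[j]) return(FALSE)
    ci <- get(i, "C"); nj <- get(j, "N")
    !is.null(ci) && !is.null(nj) && sqrt(sum((ci - nj)^2)) <= 2.5
  }
  dih_or_na <- function(p1, p2, p3, p4) {
    if (is.null(p1) || is.null(p2) || is.null(p3) || is.null(p4)) return(NA_real_)
    tryCatch(dihedral(p1, p2, p3, p4), error = function(e) NA_real_)
  }
  phi <- psi <- omega <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    Ni <- get(i, "N"); CAi <- get(i, "CA"); Ci <- get(i, "C")
    if (linked(i - 1, i)) {
      phi[i] <- dih_or_na(get(i - 1, "C"), Ni, CAi, Ci)
      omega[i] <- dih_or_na(get(i - 1, "CA"), get(i - 1, "C"), Ni, CAi)
    }
    if (linked(i, i + 1))
      psi[i] <- dih_or_na(Ni, CAi, Ci, get(i + 1, "N"))
  }
  cbind(rt, data.frame(phi = phi, psi = psi, omega = omega))
}

#' Sidechain chi1/chi2 torsions of every polymer residue
#'
#' Uses the standard chi atom quadruples for each residue type (after
#' mapping modified residues to their parent).  `n_chi` is the expected
#' torsion count for the type (0 for Gly/Ala); a chi is `NA` whenever a
#' defining atom is missing.
#'
#' @param x A `StructureRecord`.
#' @return Data frame, one row per polymer residue: residue identity
#'   columns plus `chi1`, `chi2` (degrees) and `n_chi`.
#' @export
chi_torsions <- function(x) {
  stopifnot(inherits(x, "StructureRecord"))
  rt <- residue_table(x)
  rt <- rt[rt$is_polymer, , drop = FALSE]
  a <- x$atoms
  n <- nrow(rt)
  chi1 <- chi2 <- rep(NA_real_, n)
  type <- .parent_or_self(rt$res_type)
  for (i in seq_len(n)) {
    ty <- type[i]
    g_name <- .chi1_atom[ty]
    if (is.na(g_name)) next
    uid <- rt$res_uid[i]
    N <- .atom_xyz(a, uid, "N"); CA <- .atom_xyz(a, uid, "CA")
    CB <- .atom_xyz(a, uid, "CB"); G <- .atom_xyz(a, uid, g_name)
    if (!is.null(N) && !is.null(CA) && !is.null(CB) && !is.null(G)) {
      chi1[i] <- tryCatch(dihedral(N, CA, CB, G), error = function(e) NA_real_)
      d_name <- .chi2_atom[ty]
      if (!is.na(d_name)) {
        D <- .atom_xyz(a, uid, d_name)
        if (!is.null(D))
          chi2[i] <- tryCatch(dihedral(CA, CB, G, D), error = function(e) NA_real_)
      }
    }
  }
  n_chi <- unname(.n_chi_tab[type])
  n_chi[is.na(n_chi)] <- 0L
  cbind(rt, data.frame(chi1 = chi1, chi2 = chi2, n_chi = n_chi))
}

#' Full per-residue torsion table
#'
#' Convenience binding of [backbone_torsions()] and [chi_torsions()].
#'
#' @param x A `StructureRecord`.
#' @return Data frame with `phi`, `psi`, `omega`, `chi1`, `chi2`, `n_chi`.
#' @export
torsion_table <- function(x) {
  bb <- backbone_torsions(x)
  sc <- chi_torsions(x)
  cbind(bb, sc[, c("chi1", "chi2", "n_chi"), drop = FALSE])
}

#' Dump per-residue torsions to CSV (debug aid)
#'
#' @param x A `StructureRecord`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_torsion_csv <- function(x, path) {
  tt <- torsion_table(x)
  utils::write.csv(tt[, c("chain", "res_seq", "icode", "res_type",
                          "phi", "psi", "omega", "chi1", "chi2")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Per-residue torsion differences between target and model
#'
#' For each pair from [pair_residues()], computes minimal angular
#' differences for phi, psi, omega, chi1 and chi2, plus peptide-bond
#' anomaly flags.  Rules:
#' \itemize{
#'   \item a torsion undefined in the target is ignored (`NA`);
#'   \item a chi defined in the target but not constructible in the
#'     model residue (sidechain not modeled, or mutated) is assigned the
#'     maximum difference of 180 degrees;
#'   \item backbone torsions missing in the model are `NA` (the
#'     backbone score renormalizes over the defined subset);
#'   \item `omega_flip` is set when target and model omega fall in
#'     opposite planar classes (cis vs trans); `omega_twist` when the
#'     model omega is twisted more than `twist_cutoff` from planar.
#' }
#' With `chi_symmetry = TRUE` (default), chi2 of Asp/Phe/Tyr is compared
#' under its chemical 2-fold symmetry.
#'
#' @param target,model `StructureRecord` objects.
#' @param pairs Optional pairing from [pair_residues()]; computed with
#'   `pairing_mode` if omitted.
#' @param pairing_mode Passed to [pair_residues()] when `pairs` is `NULL`.
#' @param chi_symmetry Apply 2-fold chi2 symmetry correction.
#' @param twist_cutoff Omega planarity tolerance, degrees.
#' @return Data frame, one row per target polymer residue: identity
#'   columns, `d_phi`, `d_psi`, `d_omega`, `d_chi1`, `d_chi2`,
#'   `n_chi` (number of chi torsions defined in the target residue,
#'   capped at 2), `model_present`, `mutated`, `omega_flip`,
#'   `omega_twist`.
#' @export
torsion_delta <- function(target, model, pairs = NULL,
                          pairing_mode = c("numbering", "alignment"),
                          chi_symmetry = TRUE, twist_cutoff = 30) {
  pairing_mode <- match.arg(pairing_mode)
  if (is.null(pairs)) pairs <- pair_residues(target, model, pairing_mode)
  tt <- torsion_table(target)
  mt <- torsion_table(model)
  ti <- match(pairs$target_uid, tt$res_uid)
  mi <- match(pairs$other_uid, mt$res_uid)
  t_tor <- tt[ti, , drop = FALSE]
  m_tor <- mt[mi, , drop = FALSE]
  model_present <- !is.na(pairs$other_uid)

  d_bb <- function(col) {
    d <- angular_delta(t_tor[[col]], m_tor[[col]])
    d[!model_present] <- NA_real_
    d
  }
  d_phi <- d_bb("phi"); d_psi <- d_bb("psi"); d_omega <- d_bb("omega")

  # chi torsions defined in the target residue (only these are scored)
  t_chi1 <- t_tor$chi1
  t_chi2 <- t_tor$chi2
  n_chi_target <- (!is.na(t_chi1)) + (!is.na(t_chi2))
  sym <- ifelse(chi_symmetry &
                  .parent_or_self(pairs$target_type) %in% .chi2_symmetric, 2L, 1L)
  d_chi1 <- ifelse(is.na(t_chi1), NA_real_,
                   ifelse(is.na(m_tor$chi1), 180,
                          angular_delta(t_chi1, m_tor$chi1)))
  d_chi2 <- rep(NA_real_, nrow(pairs))
  for (k in which(!is.na(t_chi2))) {
    d_chi2[k] <- if (is.na(m_tor$chi2[k])) 180 else
      angular_delta(t_chi2[k], m_tor$chi2[k], symmetry_order = sym[k])
  }
  d_chi1[!model_present] <- NA_real_
  d_chi2[!model_present] <- NA_real_

  t_cls <- classify_omega(t_tor$omega, twist_cutoff)
  m_cls <- classify_omega(m_tor$omega, twist_cutoff)
  omega_flip <- model_present & !is.na(t_cls) & !is.na(m_cls) &
    ((t_cls == "cis" & m_cls == "trans") | (t_cls == "trans" & m_cls == "cis"))
  omega_twist <- model_present & !is.na(m_cls) & m_cls == "twisted"

  data.frame(target_uid = pairs$target_uid, chain = pairs$chain,
             res_seq = pairs$res_seq, icode = pairs$icode,
             res_type = pairs$target_type,
             d_phi = d_phi, d_psi = d_psi, d_omega = d_omega,
             d_chi1 = d_chi1, d_chi2 = d_chi2,
             n_chi = pmin(n_chi_target, 2L),
             model_present = model_present, mutated = pairs$mutated,
             omega_flip = omega_flip, omega_twist = omega_twist,
             stringsAsFactors = FALSE)
}
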