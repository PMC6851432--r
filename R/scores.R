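#' Scoring parameters
#'
#' @param tau Width (degrees) of the Gaussian that gates the chi2
#'   contribution by the chi1 error; default 30, which makes the chi2
#'   term negligible once the chi1 error exceeds about 50 degrees.
#' @param burial_contact_cutoff Heavy-atom contact distance (Angstrom)
#'   for the burial score; default 4.
#' @param twist_cutoff Omega planarity tolerance (degrees); default 30.
#' @param chi_symmetry Compare chi2 of Asp/Phe/Tyr under its chemical
#'   2-fold symmetry (default `TRUE`).
#' @param burial_include_het Include non-water heteroatoms (ligands) in
#'   the burial neighbor count (default `TRUE`); waters are always
#'   excluded.
#' @return A list of class `score_params`.
#' @export
score_params <- function(tau = 30, burial_contact_cutoff = 4,
                         twist_cutoff = 30, chi_symmetry = TRUE,
                         burial_include_het = TRUE) {
  stopifnot(tau > 0, burial_contact_cutoff > 0, twist_cutoff > 0)
  structure(list(tau = tau, burial_contact_cutoff = burial_contact_cutoff,
                 twist_cutoff = twist_cutoff, chi_symmetry = chi_symmetry,
                 burial_include_het = burial_include_het),
            class = "score_params")
}

#' Chord-length torsion deviation score
#'
#' `gamma_torsion(delta) = (1 - cos(delta)) / 2`: the squared length of
#' the chord subtended on the unit circle by an angular deviation,
#' normalized to `[0, 1]` (0 at perfect agreement, 1 at 180 degrees).
#'
#' @param delta Angular deviation(s) in degrees, in `[0, 180]`.
#' @return Score(s) in `[0, 1]`; `NA` propagates.
#' @export
gamma_torsion <- function(delta) {
  bad <- !is.na(delta) & (delta < 0 | delta > 180)
  if (any(bad)) stop("delta outside [0, 180]")
  (1 - cospi(delta / 180)) / 2
}

#' Backbone conformation score
#'
#' Mean of [gamma_torsion()] over the defined subset of the phi, psi and
#' omega deviations (renormalized at chain termini where phi or omega do
#' not exist).  0 = perfect agreement, 1 = maximal disagreement.
#'
#' @param d_phi,d_psi,d_omega Angular deviations in degrees (vectors;
#'   `NA` = undefined).
#' @return Scores in `[0, 1]`; `NA` when no backbone torsion is defined.
#' @export
backbone_score <- function(d_phi, d_psi, d_omega) {
  g <- cbind(gamma_torsion(d_phi), gamma_torsion(d_psi),
             gamma_torsion(d_omega))
  out <- rowMeans(g, na.rm = TRUE)
  out[!rowSums(!is.na(g))] <- NA_real_
  out
}

#' Burial score of each target residue
#'
#' `beta = min(n_close / (3 * n_sc), 1)`, where `n_close` is the number
#' of heavy atoms from other residues (waters excluded) within
#' `burial_contact_cutoff` of any heavy atom of the residue -- always
#' evaluated on the target structure -- and `n_sc` is the canonical
#' sidechain heavy-atom count for the residue type.  Fully exposed
#' residues therefore get `beta = 0` and contribute nothing to the
#' sidechain score; `beta` saturates at 1 for well-buried residues.
#'
#' @param x Target `StructureRecord`.
#' @param params A [score_params()] list.
#' @return Data frame, one row per polymer residue: `res_uid`,
#'   `n_close`, `n_sc`, `beta` (`NA` when `n_sc` is 0, i.e. glycine).
#' @export
burial <- function(x, params = score_params()) {
  stopifnot(inherits(x, "StructureRecord"))
  a <- x$atoms
  heavy <- !(a$element %in% c("H", "D"))
  not_water <- !(a$res_type %in% .water_names)
  neighbor_ok <- heavy & not_water &
    (params$burial_include_het | a$is_polymer)
  rt <- residue_table(x)
  rt <- rt[rt$is_polymer, , drop = FALSE]
  xyz <- cbind(a$x, a$y, a$z)
  cutoff2 <- params$burial_contact_cutoff^2
  n_close <- integer(nrow(rt))
  for (k in seq_len(nrow(rt))) {
    uid <- rt$res_uid[k]
    own <- which(a$res_uid == uid & heavy)
    if (!length(own)) { n_close[k] <- 0L; next }
    others <- which(neighbor_ok & a$res_uid != uid)
    if (!length(others)) { n_close[k] <- 0L; next }
    # bounding-box prefilter keeps the all-pairs distance check small
    box <- apply(xyz[own, , drop = FALSE], 2, range)
    cand <- others[xyz[others, 1] >= box[1, 1] - params$burial_contact_cutoff &
                     xyz[others, 1] <= box[2, 1] + params$burial_contact_cutoff &
                     xyz[others, 2] >= box[1, 2] - params$burial_contact_cutoff &
                     xyz[others, 2] <= box[2, 2] + params$burial_contact_cutoff &
                     xyz[others, 3] >= box[1, 3] - params$burial_contact_cutoff &
                     xyz[others, 3] <= box[2, 3] + params$burial_contact_cutoff]
    if (!length(cand)) { n_close[k] <- 0L; next }
    d2 <- outer(rowSums(xyz[own, , drop = FALSE]^2),
                rowSums(xyz[cand, , drop = FALSE]^2), "+") -
      2 * xyz[own, , drop = FALSE] %*% t(xyz[cand, , drop = FALSE])
    n_close[k] <- sum(apply(d2, 2, min) <= cutoff2)
  }
  n_sc <- unname(.n_sc_tab[.parent_or_self(rt$res_type)])
  beta <- ifelse(!is.na(n_sc) & n_sc > 0,
                 pmin(n_close / (3 * n_sc), 1), NA_real_)
  data.frame(res_uid = rt$res_uid, n_close = n_close, n_sc = n_sc,
             beta = beta)
}

#' Burial-weighted sidechain conformation score
#'
#' For residues with a single chi torsion the score is
#' `beta * gamma(d_chi1)`; otherwise
#' `beta * (1 - (2/3) * (1 - gamma(d_chi1))
#'            - (1/3) * exp(-(d_chi1/tau)^2) * (1 - gamma(d_chi2)))`,
#' so that the chi2 term only matters while chi1 is approximately
#' correct.  Ranges from 0 (both chis perfect) to `beta` (chi1 off by
#' 180).  A residue with chi1 perfect and chi2 maximally wrong scores
#' `beta / 3`.
#'
#' @param d_chi1,d_chi2 Angular deviations in degrees (chis missing from
#'   the model must already be encoded as 180, see [torsion_delta()]).
#' @param n_chi Number of chi torsions defined in the target residue.
#' @param beta Burial weight(s) from [burial()].
#' @param tau Gating width in degrees (default 30).
#' @return Scores in `[0, 1]`; `NA` when `n_chi` is 0 or `beta`
#'   undefined.
#' @export
sidechain_score <- function(d_chi1, d_chi2, n_chi, beta, tau = 30) {
  g1 <- gamma_torsion(d_chi1)
  g2 <- gamma_torsion(d_chi2)
  out <- ifelse(n_chi >= 2,
                beta * (1 - (2 / 3) * (1 - g1) -
                          (1 / 3) * exp(-(d_chi1 / tau)^2) * (1 - g2)),
                ifelse(n_chi == 1, beta * g1, NA_real_))
  out[is.na(beta) | n_chi < 1] <- NA_real_
  out
}

#' Score a model against a target, residue by residue
#'
#' End-to-end torsion-space comparison: pairs residues, computes torsion
#' deltas, burial weights (from the target), the per-residue backbone
#' and sidechain scores, and model-level aggregates.
#'
#' @param target,model `StructureRecord` objects.
#' @param params A [score_params()] list.
#' @param pairing_mode `"numbering"` (models) or `"alignment"`
#'   (templates).
#' @return List with `residues` (per-residue data frame including
#'   `s_backbone`, `s_sidechain`, `beta`, `n_close`, flags) and
#'   `summary` (one-row data frame: `mean_backbone`, `mean_sidechain`,
#'   `n_flips`, `n_twists`, `n_residues_scored`, `n_target_residues`).
#'   Means are taken over residues with a defined score only, so models
#'   of different coverage remain comparable; coverage is reported
#'   separately.
#' @export
score_model <- function(target, model, params = score_params(),
                        pairing_mode = c("numbering", "alignment")) {
  pairing_mode <- match.arg(pairing_mode)
  td <- torsion_delta(target, model, pairing_mode = pairing_mode,
                      chi_symmetry = params$chi_symmetry,
                      twist_cutoff = params$twist_cutoff)
  bu <- burial(target, params)
  bi <- match(td$target_uid, bu$res_uid)
  td$n_close <- bu$n_close[bi]
  td$n_sc <- bu$n_sc[bi]
  td$beta <- bu$beta[bi]
  td$s_backbone <- backbone_score(td$d_phi, td$d_psi, td$d_omega)
  td$s_sidechain <- sidechain_score(td$d_chi1, td$d_chi2, td$n_chi,
                                    td$beta, params$tau)
  summary <- data.frame(
    mean_backbone = mean(td$s_backbone, na.rm = TRUE),
    mean_sidechain = if (all(is.na(td$s_sidechain))) NA_real_ else
      mean(td$s_sidechain, na.rm = TRUE),
    n_flips = sum(td$omega_flip),
    n_twists = sum(td$omega_twist),
    n_residues_scored = sum(td$model_present),
    n_target_residues = nrow(td))
  list(residues = td, summary = summary)
}

#' Compare a model and a template against the same target
#'
#' Scores both structures against the target (the model by shared
#' numbering, the template by sequence alignment) and tabulates
#' per-residue differences `model - template`: negative values mean the
#' modeling improved on the template.  Also reports per-residue Calpha
#' residual distances after least-squares rigid-body superposition on
#' the shared Calpha set, for use as background shading in plots.
#'
#' @param target,model,template `StructureRecord` objects.
#' @param params A [score_params()] list.
#' @return Data frame, one row per target polymer residue, with
#'   per-structure scores, `backbone_delta`, `sidechain_delta`,
#'   `ca_dist_model`, `ca_dist_template` and omega flags.
#' @export
compare_template_model <- function(target, model, template,
                                   params = score_params()) {
  sm <- score_model(target, model, params, pairing_mode = "numbering")$residues
  st <- score_model(target, template, params, pairing_mode = "alignment")$residues
  if (!any(st$model_present))
    stop("template shares no residues with the target")
  stopifnot(identical(sm$target_uid, st$target_uid))
  out <- data.frame(target_uid = sm$target_uid, chain = sm$chain,
                    res_seq = sm$res_seq, icode = sm$icode,
                    res_type = sm$res_type,
                    s_backbone_model = sm$s_backbone,
                    s_backbone_template = st$s_backbone,
                    s_sidechain_model = sm$s_sidechain,
                    s_sidechain_template = st$s_sidechain,
                    stringsAsFactors = FALSE)
  out$backbone_delta <- out$s_backbone_model - out$s_backbone_template
  out$sidechain_delta <- out$s_sidechain_model - out$s_sidechain_template
  out$ca_dist_model <- .ca_residuals(target, model, "numbering")[
    as.character(sm$target_uid)]
  out$ca_dist_template <- .ca_residuals(target, template, "alignment")[
    as.character(st$target_uid)]
  out$flip_model <- sm$omega_flip
  out$twist_model <- sm$omega_twist
  out$flip_template <- st$omega_flip
  out$twist_template <- st$omega_twist
  rownames(out) <- NULL
  out
}

# Per-target-residue Calpha distances after Kabsch superposition of the
# other structure onto the target over shared Calpha atoms.  Returns a
# named vector keyed by target res_uid.
.ca_residuals <- function(target, other, mode) {
  pairs <- pair_residues(target, other, mode)
  ta <- target$atoms
  oa <- other$atoms
  tp <- op <- list()
  uid_keep <- integer()
  for (k in which(!is.na(pairs$other_uid))) {
    p <- .atom_xyz(ta, pairs$target_uid[k], "CA")
    q <- .atom_xyz(oa, pairs$other_uid[k], "CA")
    if (is.null(p) || is.null(q)) next
    tp[[length(tp) + 1]] <- p
    op[[length(op) + 1]] <- q
    uid_keep <- c(uid_keep, pairs$target_uid[k])
  }
  if (length(tp) < 3) stop("fewer than 3 shared Calpha atoms; cannot superpose")
  P <- do.call(rbind, tp)
  Q <- do.call(rbind, op)
  fit <- .kabsch(Q, P)   # superpose other (Q) onto target (P)
  Qr <- sweep(Q, 2, fit$center_q) %*% fit$rot
  Qr <- sweep(Qr, 2, fit$center_p, "+")
  d <- sqrt(rowSums((Qr - P)^2))
  out <- rep(NA_real_, nrow(pairs))
  names(out) <- as.character(pairs$target_uid)
  out[as.character(uid_keep)] <- d
  out
}

# Least-squares rigid-body superposition (Kabsch, via SVD) of point set
# Q onto P (n x 3 each).
.kabsch <- function(Q, P) {
  cq <- colMeans(Q)
  cp <- colMeans(P)
  H <- t(sweep(Q, 2, cq)) %*% sweep(P, 2, cp)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  list(rot = rot, center_q = cq, center_p = cp)
}

#' Write the per-residue score report as CSV
#'
#' @param scores Result of [score_model()] (or its `residues` element).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_residue_scores <- function(scores, path) {
  df <- if (is.data.frame(scores)) scores else scores$residues
  cols <- c("chain", "res_seq", "icode", "res_type", "d_phi", "d_psi",
            "d_omega", "d_chi1", "d_chi2", "beta", "s_backbone",
            "s_sidechain", "omega_flip", "omega_twist")
  utils::write.csv(df[, intersect(cols, names(df))], path, row.names = FALSE)
  invisible(path)
}

#' Multi-panel comparison chart for a template/model/target trio
#'
#' Plots per-residue backbone score traces for model and template, their
#' difference (negative = model improved), sidechain traces and
#' difference, with Calpha residual shading and markers at cis/trans
#' flips (crosses) and twisted peptide bonds (triangles).
#'
#' @param cmp Result of [compare_template_model()].
#' @param main Title.
#' @return `cmp`, invisibly.
#' @export
plot_comparison <- function(cmp, main = "model vs template, torsion space") {
  x <- seq_len(nrow(cmp))
  op <- graphics::par(mfrow = c(4, 1), mar = c(2, 4, 1.5, 1))
  on.exit(graphics::par(op))
  shade <- function(vals, col) {
    v <- vals / max(1e-9, max(vals, na.rm = TRUE))
    v[is.na(v)] <- 0
    base <- grDevices::col2rgb(col)[, 1] / 255
    graphics::rect(x - 0.5, graphics::par("usr")[3], x + 0.5,
                   graphics::par("usr")[4],
                   col = grDevices::rgb(base[1], base[2], base[3],
                                        alpha = 0.25 * sqrt(v)),
                   border = NA)
  }
  graphics::plot(x, cmp$s_backbone_model, type = "l", col = "purple",
                 ylim = c(0, 1), ylab = "S_backbone", main = main)
  shade(cmp$ca_dist_model, "purple")
  graphics::lines(x, cmp$s_backbone_template, col = "darkgreen")
  graphics::points(x[cmp$flip_model], rep(0.95, sum(cmp$flip_model)),
                   pch = 4, col = "purple")
  graphics::points(x[cmp$twist_model], rep(0.9, sum(cmp$twist_model)),
                   pch = 2, col = "purple")
  graphics::plot(x, cmp$backbone_delta, type = "h", col = "grey30",
                 ylab = "bb model - template")
  graphics::abline(h = 0, lty = 3)
  graphics::plot(x, cmp$s_sidechain_model, type = "l", col = "purple",
                 ylim = c(0, 1), ylab = "S_sidechain")
  graphics::lines(x, cmp$s_sidechain_template, col = "darkgreen")
  graphics::plot(x, cmp$sidechain_delta, type = "h", col = "grey30",
                 ylab = "sc model - template")
  graphics::abline(h = 0, lty = 3)
  invisible(cmp)
}
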