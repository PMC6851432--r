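#' MolProbity score from validation percentages
#'
#' Log-scale composite of the all-atom clashscore, rotamer-outlier
#' percentage and Ramachandran percentage:
#' `0.426 * ln(1 + clashscore) + 0.33 * ln(1 + max(0, rotamer% - 1)) +
#'  0.25 * ln(1 + max(0, rama% - 2)) + 0.5`.
#' The floor at perfect inputs is 0.5; fully pathological inputs
#' (clashscore 1000, every residue a rotamer and Ramachandran outlier)
#' give approximately 6.1, the theoretical worst.
#'
#' The third term is defined on the Ramachandran *not-favored*
#' percentage.  Validation tables often print the *outlier* percentage
#' instead, which is smaller; `rama_convention` records which one you
#' are supplying.  With `"outlier"` the same arithmetic is applied and
#' the result is a lower bound on the true score (the difference is at
#' most the marginal-Ramachandran contribution of the third term).
#'
#' @param clashscore Clashes per 1000 atoms (>= 0).
#' @param rotamer_outlier_pct Rotamer outlier percentage, 0-100.
#' @param rama_pct Ramachandran percentage (see `rama_convention`),
#'   0-100.
#' @param rama_convention `"not_favored"` (the formula's native input)
#'   or `"outlier"`.
#' @return MolProbity score(s) (>= 0.5; lower is better).
#' @export
molprobity_score <- function(clashscore, rotamer_outlier_pct, rama_pct,
                             rama_convention = c("not_favored", "outlier")) {
  match.arg(rama_convention)
  if (any(clashscore < 0, na.rm = TRUE) ||
      any(rotamer_outlier_pct < 0 | rotamer_outlier_pct > 100, na.rm = TRUE) ||
      any(rama_pct < 0 | rama_pct > 100, na.rm = TRUE))
    stop("validation statistics out of range")
  0.426 * log(1 + clashscore) +
    0.33 * log(1 + pmax(0, rotamer_outlier_pct - 1)) +
    0.25 * log(1 + pmax(0, rama_pct - 2)) + 0.5
}

.triage_tiers <- c("trusted", "transition", "caution", "reject")

#' Triage an experimental template by resolution and MolProbity score
#'
#' Resolution bands (half-open, boundaries as conventionally quoted):
#' worse than 5 Angstrom -> `reject` (use only with extreme caution;
#' sidechains are effectively invisible); 3.5-5 -> `caution` (register
#' errors common); 2.5-3.5 -> `transition` (mostly correct, loops
#' unreliable); better than 2.5 -> `trusted`.  A MolProbity score above
#' 3 escalates the advice one tier toward distrust (capped at
#' `caution`: `reject` is reserved for very low resolution); below 2 a
#' reassuring note is added.  With no resolution available the advice
#' rests on the MolProbity score alone and says so.
#'
#' @param resolution Resolution in Angstrom, or `NA`.
#' @param molprobity MolProbity score.
#' @return List with `advice` (one of `trusted`, `transition`,
#'   `caution`, `reject`) and `notes` (character vector).
#' @export
triage <- function(resolution, molprobity) {
  notes <- character()
  if (is.na(resolution)) {
    advice <- if (molprobity > 3) "caution"
    else if (molprobity < 2) "trusted" else "transition"
    notes <- c(notes, "no resolution available; advice from MolProbity score alone")
  } else {
    advice <- if (resolution >= 5) "reject"
    else if (resolution >= 3.5) "caution"
    else if (resolution >= 2.5) "transition"
    else "trusted"
    if (advice == "reject")
      notes <- c(notes, "resolution poorer than 5 A: use only with extreme caution; prefer any higher-resolution alternative")
    if (molprobity > 3 && advice %in% c("trusted", "transition")) {
      advice <- .triage_tiers[match(advice, .triage_tiers) + 1L]
      notes <- c(notes, "MolProbity score above 3: escalated one tier")
    } else if (molprobity > 3) {
      notes <- c(notes, "MolProbity score above 3: substantial caution")
    }
  }
  if (molprobity < 2)
    notes <- c(notes, "MolProbity score below 2: stereochemically sound")
  list(advice = advice, notes = notes)
}

#' Triage a table of template-quality records
#'
#' @param records Data frame with columns `resolution` and either
#'   `molprobity_score` or the three inputs of [molprobity_score()]
#'   (`clashscore`, `rotamer_outlier_pct`, `rama_pct`).
#' @param rama_convention Passed to [molprobity_score()] when the score
#'   must be computed.
#' @return The input with `molprobity_score`, `advice` and `notes`
#'   columns added.
#' @export
triage_table <- function(records, rama_convention = "not_favored") {
  if (!"molprobity_score" %in% names(records))
    records$molprobity_score <- molprobity_score(
      records$clashscore, records$rotamer_outlier_pct, records$rama_pct,
      rama_convention)
  res <- if ("resolution" %in% names(records)) records$resolution else
    rep(NA_real_, nrow(records))
  tri <- Map(triage, res, records$molprobity_score)
  records$advice <- vapply(tri, `[[`, "", "advice")
  records$notes <- vapply(tri, function(t) paste(t$notes, collapse = "; "), "")
  records
}

#' Recommend the best template among candidates
#'
#' Candidates below the sequence-identity floor are excluded; the rest
#' are ordered lexicographically by best (numerically lowest)
#' resolution, then lowest MolProbity score, then latest release year,
#' then identifier -- so the result does not depend on input order.
#'
#' @param candidates Data frame with columns `id`, `resolution`,
#'   `molprobity_score`, and optionally `sequence_identity_pct` and
#'   `release_year`.
#' @param identity_floor_pct Minimum sequence identity to the target
#'   (default 0 = no filter).  Candidates with unknown identity are
#'   excluded whenever a positive floor is requested.
#' @return The single recommended row, or `NULL` when no candidate
#'   qualifies.
#' @export
pick_better_template <- function(candidates, identity_floor_pct = 0) {
  stopifnot(all(c("id", "resolution", "molprobity_score") %in% names(candidates)))
  if (identity_floor_pct > 0) {
    ident <- if ("sequence_identity_pct" %in% names(candidates))
      candidates$sequence_identity_pct else rep(NA_real_, nrow(candidates))
    candidates <- candidates[!is.na(ident) & ident >= identity_floor_pct, ,
                             drop = FALSE]
  }
  if (!nrow(candidates)) return(NULL)
  yr <- if ("release_year" %in% names(candidates)) candidates$release_year
  else rep(0, nrow(candidates))
  yr[is.na(yr)] <- 0
  ord <- order(candidates$resolution, candidates$molprobity_score, -yr,
               candidates$id)
  candidates[ord[1], , drop = FALSE]
}
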