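#' Establish residue correspondence between two structures
#'
#' Every polymer residue of `target` appears exactly once in the result,
#' paired with at most one polymer residue of `other`.
#'
#' `mode = "numbering"` pairs residues sharing (chain, seq number,
#' insertion code) -- appropriate for predicted models, which share the
#' target's numbering.  `mode = "alignment"` pairs residues through a
#' global sequence alignment per chain (Needleman-Wunsch via
#' \pkg{Biostrings}) -- appropriate for templates from unrelated
#' depositions whose numbering is arbitrary.
#'
#' @param target,other `StructureRecord` objects.
#' @param mode `"numbering"` or `"alignment"`.
#' @return Data frame with one row per target polymer residue:
#'   `target_uid`, `chain`, `res_seq`, `icode`, `target_type`,
#'   `other_uid` (`NA` when unmatched), `other_type`, `mutated`.
#' @export
pair_residues <- function(target, other, mode = c("numbering", "alignment")) {
  mode <- match.arg(mode)
  stopifnot(inherits(target, "StructureRecord"),
            inherits(other, "StructureRecord"))
  tt <- residue_table(target)
  tt <- tt[tt$is_polymer, , drop = FALSE]
  ot <- residue_table(other)
  ot <- ot[ot$is_polymer, , drop = FALSE]
  if (!nrow(tt) || !nrow(ot))
    stop("cannot pair: a structure has no polymer residues")
  if (mode == "numbering") {
    key_t <- paste(tt$chain, tt$res_seq, tt$icode, sep = "\r")
    key_o <- paste(ot$chain, ot$res_seq, ot$icode, sep = "\r")
    j <- match(key_t, key_o)
  } else {
    j <- rep(NA_integer_, nrow(tt))
    t_chains <- unique(tt$chain)
    o_chains <- unique(ot$chain)
    shared <- intersect(t_chains, o_chains)
    t_rest <- setdiff(t_chains, shared)
    o_rest <- setdiff(o_chains, shared)
    chain_map <- c(stats::setNames(shared, shared),
                   stats::setNames(o_rest[seq_len(min(length(t_rest), length(o_rest)))],
                                   t_rest[seq_len(min(length(t_rest), length(o_rest)))]))
    for (ch in names(chain_map)) {
      ti <- which(tt$chain == ch)
      oi <- which(ot$chain == chain_map[[ch]])
      if (!length(ti) || !length(oi)) next
      al <- .align_indices(.res_letters(tt$res_type[ti]),
                           .res_letters(ot$res_type[oi]))
      j[ti[al$i]] <- oi[al$j]
    }
  }
  if (all(is.na(j))) stop("no residues could be paired")
  out <- data.frame(target_uid = tt$res_uid, chain = tt$chain,
                    res_seq = tt$res_seq, icode = tt$icode,
                    target_type = tt$res_type,
                    other_uid = ot$res_uid[j],
                    other_type = ot$res_type[j],
                    stringsAsFactors = FALSE)
  out$mutated <- !is.na(out$other_type) &
    .parent_or_self(out$target_type) != .parent_or_self(out$other_type)
  out
}

.parent_or_self <- function(res_type) {
  p <- .parent_type(res_type)
  ifelse(is.na(p), res_type, p)
}

.res_letters <- function(res_type) {
  l <- unname(.aa3to1[.parent_or_self(res_type)])
  l[is.na(l)] <- "X"
  l
}

# Global alignment of two letter vectors; returns matched index pairs.
.align_indices <- function(lt, lo) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(paste(lt, collapse = "")),
    Biostrings::AAString(paste(lo, collapse = "")),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ii <- cumsum(pa != "-")
  jj <- cumsum(sa != "-")
  keep <- pa != "-" & sa != "-"
  list(i = ii[keep], j = jj[keep])
}
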