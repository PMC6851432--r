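#' StructureRecord: in-memory representation of a parsed structure
#'
#' A `StructureRecord` is a list with elements `identifier`,
#' `source_format` (`"pdb"`, `"mmcif"` or `"synthetic"`), `resolution`
#' (Angstrom, or `NA`) and `atoms`, a data frame with one row per atom:
#' `chain`, `res_seq`, `icode`, `res_type`, `atom`, `element`, `altloc`,
#' `x`, `y`, `z`, `occ`, `b`, `is_polymer`, `nonstandard`, `res_uid`.
#' `res_uid` is a dense integer index over residues in file order;
#' residues within a chain are ordered by (`res_seq`, `icode`).
#'
#' @param atoms Atom data frame as described above (`res_uid` is
#'   recomputed).
#' @param identifier Structure identifier string.
#' @param source_format Origin format tag.
#' @param resolution Resolution in Angstrom or `NA`.
#' @return A `StructureRecord` object.
#' @export
structure_record <- function(atoms, identifier = "structure",
                             source_format = "synthetic",
                             resolution = NA_real_) {
  needed <- c("chain", "res_seq", "icode", "res_type", "atom", "element",
              "altloc", "x", "y", "z", "occ", "b")
  missing <- setdiff(needed, names(atoms))
  if (length(missing))
    stop("atoms table lacks columns: ", paste(missing, collapse = ", "))
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite atom coordinates")
  occ <- atoms$occ
  if (any(!is.na(occ) & (occ < 0 | occ > 1)))
    stop("occupancy outside [0, 1]")
  parent <- .parent_type(atoms$res_type)
  atoms$nonstandard <- !is.na(parent) & parent != atoms$res_type
  if (!"is_polymer" %in% names(atoms))
    atoms$is_polymer <- !is.na(parent)
  # stable sort: chains in order of first appearance, residues by number
  chain_rank <- match(atoms$chain, unique(atoms$chain))
  ord <- order(chain_rank, atoms$res_seq, atoms$icode)
  atoms <- atoms[ord, , drop = FALSE]
  key <- paste(atoms$chain, atoms$res_seq, atoms$icode, sep = "\r")
  atoms$res_uid <- match(key, unique(key))
  rownames(atoms) <- NULL
  out <- list(identifier = identifier, source_format = source_format,
              resolution = resolution, atoms = atoms)
  class(out) <- "StructureRecord"
  out
}

# Map residue type to its standard parent ("MET" for "MSE", identity for
# the 20 standard types, NA for anything else).
.parent_type <- function(res_type) {
  out <- ifelse(res_type %in% .std_aa3, res_type,
                unname(.nonstandard_parent[res_type]))
  out
}

#' @export
print.StructureRecord <- function(x, ...) {
  rt <- residue_table(x)
  cat(sprintf("StructureRecord '%s' (%s): %d chains, %d residues (%d polymer), %d atoms\n",
              x$identifier, x$source_format,
              length(unique(x$atoms$chain)), nrow(rt), sum(rt$is_polymer),
              nrow(x$atoms)))
  invisible(x)
}

#' Residue-level summary of a structure
#'
#' @param x A `StructureRecord`.
#' @return Data frame with one row per residue: `res_uid`, `chain`,
#'   `res_seq`, `icode`, `res_type`, `is_polymer`, `nonstandard`.
#' @export
residue_table <- function(x) {
  stopifnot(inherits(x, "StructureRecord"))
  a <- x$atoms
  first <- !duplicated(a$res_uid)
  data.frame(res_uid = a$res_uid[first], chain = a$chain[first],
             res_seq = a$res_seq[first], icode = a$icode[first],
             res_type = a$res_type[first], is_polymer = a$is_polymer[first],
             nonstandard = a$nonstandard[first],
             stringsAsFactors = FALSE)
}

# Coordinates of one named atom in one residue (first match), or NULL.
.atom_xyz <- function(atoms, uid, name) {
  i <- which(atoms$res_uid == uid & atoms$atom == name)
  if (!length(i)) return(NULL)
  c(atoms$x[i[1]], atoms$y[i[1]], atoms$z[i[1]])
}

#' Read a structure file
#'
#' Reads PDB (fixed-column) or mmCIF files into a [structure_record()].
#' Only the first model of multi-model files is kept.  For alternate
#' conformations, only the highest-occupancy altloc of each atom is
#' retained (ties broken by lexicographically first altloc id).  Waters
#' and non-amino-acid heteroatoms are kept but flagged non-polymer;
#' common modified residues (e.g. MSE) are flagged polymer and scored as
#' their parent type.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"pdb"` or `"mmcif"`.
#' @return A `StructureRecord`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  if (format == "pdb") .read_pdb(path) else .read_cif(path)
}

.finish_read <- function(df, identifier, source_format, resolution) {
  if (!nrow(df)) stop("no atoms parsed from file (format error?)")
  # altloc resolution: per (chain, res, icode, atom name) keep highest
  # occupancy, ties to first altloc id
  key <- paste(df$chain, df$res_seq, df$icode, df$atom, sep = "\r")
  ord <- order(key, -df$occ, df$altloc)
  keep <- ord[!duplicated(key[ord])]
  df <- df[sort(keep), , drop = FALSE]   # restore file order
  out <- structure_record(df, identifier = identifier,
                          source_format = source_format,
                          resolution = resolution)
  if (!any(out$atoms$is_polymer))
    stop("file contains no amino-acid polymer residues")
  out
}

.read_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  endmdl <- grep("^ENDMDL", lines)
  if (length(endmdl)) lines <- lines[seq_len(endmdl[1] - 1)]
  resolution <- NA_real_
  rem2 <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
  if (length(rem2)) {
    m <- regmatches(rem2[1], regexpr("[0-9]+\\.[0-9]+", rem2[1]))
    if (length(m)) resolution <- as.numeric(m)
  }
  rec <- substr(lines, 1, 6)
  keep <- rec %in% c("ATOM  ", "HETATM")
  lines <- lines[keep]
  if (!length(lines)) stop("no ATOM/HETATM records in ", path)
  num <- function(s) suppressWarnings(as.numeric(s))
  fld <- function(from, to) trimws(substr(lines, from, to))
  occ <- num(fld(55, 60))
  occ[is.na(occ)] <- 1
  elem <- fld(77, 78)
  name <- fld(13, 16)
  guess <- toupper(sub("^[0-9']*", "", name))
  elem <- ifelse(elem == "", substr(guess, 1, 1), elem)
  df <- data.frame(
    chain = substr(lines, 22, 22),
    res_seq = as.integer(num(fld(23, 26))),
    icode = trimws(substr(lines, 27, 27)),
    res_type = fld(18, 20),
    atom = name,
    element = toupper(elem),
    altloc = trimws(substr(lines, 17, 17)),
    x = num(fld(31, 38)), y = num(fld(39, 46)), z = num(fld(47, 54)),
    occ = pmin(pmax(occ, 0), 1),
    b = num(fld(61, 66)),
    stringsAsFactors = FALSE)
  if (any(is.na(df$x)))
    stop("unparsable coordinate field in ", path)
  df$b[is.na(df$b)] <- 0
  .finish_read(df, identifier = sub("\\.[^.]*$", "", basename(path)),
               source_format = "pdb", resolution = resolution)
}

# Minimal mmCIF reader: extracts the _atom_site loop (and, if present,
# _reflns.d_resolution_high).  Handles quoted tokens; multi-line
# semicolon text blocks are not expected inside atom_site loops.
.read_cif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  resolution <- NA_real_
  res_line <- grep("^_reflns\\.d_resolution_high", lines, value = TRUE)
  if (length(res_line)) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(res_line[1]), "\\s+")[[1]][2]))
    if (!is.na(v)) resolution <- v
  }
  loop_starts <- grep("^\\s*loop_\\s*$", lines)
  target_loop <- NULL
  for (ls in loop_starts) {
    i <- ls + 1
    if (i <= length(lines) && grepl("^_atom_site\\.", trimws(lines[i]))) {
      target_loop <- ls
      break
    }
  }
  if (is.null(target_loop)) stop("no _atom_site loop found in ", path)
  i <- target_loop + 1
  fields <- character()
  while (i <= length(lines) && grepl("^_atom_site\\.", trimws(lines[i]))) {
    fields <- c(fields, sub("^_atom_site\\.", "", trimws(lines[i])))
    i <- i + 1
  }
  rows <- list()
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || grepl("^(#|loop_|_[A-Za-z])", ln)) break
    rows[[length(rows) + 1]] <- .cif_tokens(ln)
    i <- i + 1
  }
  if (!length(rows)) stop("empty _atom_site loop in ", path)
  bad <- vapply(rows, length, 1L) != length(fields)
  if (any(bad)) stop("malformed _atom_site row(s) in ", path)
  m <- do.call(rbind, rows)
  colnames(m) <- fields
  col <- function(nm, alt = NULL) {
    if (nm %in% fields) m[, nm]
    else if (!is.null(alt) && alt %in% fields) m[, alt]
    else rep(NA_character_, nrow(m))
  }
  num <- function(s) suppressWarnings(as.numeric(s))
  model_num <- col("pdbx_PDB_model_num")
  keep <- if (all(is.na(model_num))) rep(TRUE, nrow(m)) else
    model_num == model_num[!is.na(model_num)][1]
  blank <- function(v) ifelse(is.na(v) | v %in% c(".", "?"), "", v)
  occ <- num(col("occupancy"))
  occ[is.na(occ)] <- 1
  df <- data.frame(
    chain = blank(col("auth_asym_id", "label_asym_id")),
    res_seq = as.integer(num(col("auth_seq_id", "label_seq_id"))),
    icode = blank(col("pdbx_PDB_ins_code")),
    res_type = blank(col("auth_comp_id", "label_comp_id")),
    atom = blank(col("auth_atom_id", "label_atom_id")),
    element = toupper(blank(col("type_symbol"))),
    altloc = blank(col("label_alt_id")),
    x = num(col("Cartn_x")), y = num(col("Cartn_y")), z = num(col("Cartn_z")),
    occ = pmin(pmax(occ, 0), 1),
    b = num(col("B_iso_or_equiv")),
    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  if (any(is.na(df$x))) stop("unparsable Cartn_x/y/z in ", path)
  df$b[is.na(df$b)] <- 0
  ident <- grep("^data_", lines, value = TRUE)
  ident <- if (length(ident)) sub("^data_", "", ident[1]) else
    sub("\\.[^.]*$", "", basename(path))
  .finish_read(df, identifier = ident, source_format = "mmcif",
               resolution = resolution)
}

# Whitespace tokenizer honoring single/double quotes.
.cif_tokens <- function(line) {
  out <- character()
  i <- 1
  n <- nchar(line)
  while (i <= n) {
    ch <- substr(line, i, i)
    if (grepl("\\s", ch)) { i <- i + 1; next }
    if (ch %in% c("'", '"')) {
      j <- i + 1
      while (j <= n && substr(line, j, j) != ch) j <- j + 1
      out <- c(out, substr(line, i + 1, j - 1))
      i <- j + 1
    } else {
      j <- i
      while (j <= n && !grepl("\\s", substr(line, j, j))) j <- j + 1
      out <- c(out, substr(line, i, j - 1))
      i <- j
    }
  }
  out
}

#' Write a structure as a PDB file
#'
#' Occupancy and B-factor are written with the standard `%6.2f` PDB
#' precision; B values are clamped to the column maximum 999.99 (with a
#' warning), which matters when error estimates are grossly inflated.
#'
#' @param x A `StructureRecord`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path) {
  stopifnot(inherits(x, "StructureRecord"))
  a <- x$atoms
  b <- a$b
  if (any(b > 999.99)) {
    warning(sum(b > 999.99), " B value(s) exceed PDB column maximum; clamped to 999.99")
    b <- pmin(b, 999.99)
  }
  name4 <- ifelse(nchar(a$atom) >= 4 | nchar(a$element) == 2,
                  sprintf("%-4s", a$atom), sprintf(" %-3s", a$atom))
  rec <- ifelse(a$is_polymer & a$res_type %in% .std_aa3, "ATOM  ", "HETATM")
  lines <- sprintf("%s%5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   rec, seq_len(nrow(a)), name4,
                   ifelse(a$altloc == "", " ", a$altloc),
                   a$res_type, a$chain, a$res_seq,
                   ifelse(a$icode == "", " ", a$icode),
                   a$x, a$y, a$z, a$occ, b, a$element)
  # TER after the last polymer residue of each chain
  out <- character()
  for (ch in unique(a$chain)) {
    idx <- which(a$chain == ch)
    out <- c(out, lines[idx], "TER")
  }
  writeLines(c(out, "END"), path)
  invisible(path)
}

#' Write a structure as a minimal mmCIF file
#'
#' @param x A `StructureRecord`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cif <- function(x, path) {
  stopifnot(inherits(x, "StructureRecord"))
  a <- x$atoms
  q <- function(v) ifelse(v == "", ".", ifelse(grepl("\\s|'", v),
                                               paste0('"', v, '"'), v))
  hdr <- c(paste0("data_", gsub("\\s", "_", x$identifier)), "#",
           if (!is.na(x$resolution))
             c(sprintf("_reflns.d_resolution_high %.2f", x$resolution), "#"),
           "loop_",
           paste0("_atom_site.",
                  c("group_PDB", "id", "type_symbol", "label_atom_id",
                    "label_alt_id", "label_comp_id", "auth_asym_id",
                    "auth_seq_id", "pdbx_PDB_ins_code", "Cartn_x",
                    "Cartn_y", "Cartn_z", "occupancy", "B_iso_or_equiv")))
  rec <- ifelse(a$is_polymer & a$res_type %in% .std_aa3, "ATOM", "HETATM")
  rows <- sprintf("%s %d %s %s %s %s %s %d %s %.3f %.3f %.3f %.2f %.2f",
                  rec, seq_len(nrow(a)), q(a$element), q(a$atom),
                  q(a$altloc), q(a$res_type), q(a$chain), a$res_seq,
                  q(a$icode), a$x, a$y, a$z, a$occ, pmin(a$b, 999.99))
  writeLines(c(hdr, rows, "#"), path)
  invisible(path)
}
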