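# Shared fixtures and independent oracles, built in code at test time.

# A small mixed-sequence helix used by many tests.
helix_structure <- function(sequence = "ALKSDEFWYRH", ...) {
  build_peptide(peptide_spec(sequence, ...))
}

# Hand-written minimal 3-residue PDB text (fixed columns verified by eye).
minimal_pdb_lines <- function() {
  c("REMARK   2 RESOLUTION.    1.80 ANGSTROMS.",
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00 10.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00 10.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00 10.00           C",
    "ATOM      4  O   ALA A   1       1.251   2.390   0.000  1.00 10.00           O",
    "ATOM      5  CB  ALA A   1       1.988  -0.773  -1.199  1.00 10.00           C",
    "ATOM      6  N   GLY A   2       3.332   1.536   0.000  1.00 12.00           N",
    "ATOM      7  CA  GLY A   2       3.988   2.833   0.000  1.00 12.00           C",
    "ATOM      8  C   GLY A   2       5.504   2.693   0.000  1.00 12.00           C",
    "ATOM      9  N   SER A   3       6.191   3.839   0.000  1.00 14.00           N",
    "ATOM     10  CA  SER A   3       7.646   3.849   0.000  1.00 14.00           C",
    "ATOM     11  C   SER A   3       8.197   5.269   0.000  1.00 14.00           C",
    "ATOM     12  CB  SER A   3       8.177   3.097   1.223  1.00 14.00           C",
    "ATOM     13  OG  SER A   3       7.743   1.749   1.223  1.00 14.00           O",
    "TER",
    "END")
}

# PDB with an altloc pair on the SER OG (A occ 0.60, B occ 0.40).
altloc_pdb_lines <- function() {
  base <- minimal_pdb_lines()
  og_a <- "ATOM     13  OG ASER A   3       7.743   1.749   1.223  0.60 14.00           O"
  og_b <- "ATOM     14  OG BSER A   3       7.000   1.000   1.000  0.40 15.00           O"
  c(base[1:13], og_a, og_b, base[15:16])
}

write_tmp_lines <- function(lines, ext = ".pdb") {
  path <- withr::local_tempfile(fileext = ext,
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# Wrap to (-180, 180] (test-local copy, independent of package internals).
.wrap180_test <- function(x) x - 360 * round(x / 360)

# --- Independent oracles ------------------------------------------------

# Dihedral via explicit plane normals and acos with a signed volume for
# the sign (a formulation independent of the atan2 path in dihedral()).
brute_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])
  n1 <- cross(b1, b2); n2 <- cross(b2, b3)
  cosang <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
  ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  if (sum(cross(n1, n2) * b2) < 0) ang <- -ang
  if (ang <= -180) ang <- ang + 360
  ang
}

# Literal two-pass adjusted-z implementation (kept deliberately naive).
brute_adjusted_z <- function(values, higher_is_better = TRUE) {
  v <- if (higher_is_better) values else -values
  m1 <- mean(v); s1 <- sd(v)
  z1 <- if (s1 == 0) rep(0, length(v)) else (v - m1) / s1
  kept <- v[z1 >= -2]
  m2 <- mean(kept); s2 <- sd(kept)
  if (length(kept) < 2 || is.na(s2) || s2 == 0) {
    z2 <- rep(0, length(v))
  } else {
    z2 <- (v - m2) / s2
  }
  pmax(z2, 0)
}
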