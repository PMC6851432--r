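# Amino-acid reference data used across the package.
#
# Chi torsion definitions follow the standard convention:
#   chi1 = N-CA-CB-G   (G = CG, or OG/OG1/SG/CG1 as appropriate)
#   chi2 = CA-CB-G-D   (D per residue type)
# Only chi1 and chi2 are ever scored.

.std_aa3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
              "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
              "THR", "TRP", "TYR", "VAL")

.aa3to1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
             GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
             LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
             SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

# Nonstandard residues mapped to a standard parent for scoring purposes.
.nonstandard_parent <- c(MSE = "MET", SEC = "CYS", HYP = "PRO",
                         MLY = "LYS", PTR = "TYR", SEP = "SER",
                         TPO = "THR", CSO = "CYS")

.water_names <- c("HOH", "WAT", "DOD", "H2O")

# Number of sidechain torsions counted for scoring (chi1..chi_n by the
# standard definitions; the scores only ever use chi1/chi2).
.n_chi_tab <- c(ALA = 0, ARG = 4, ASN = 2, ASP = 2, CYS = 1, GLN = 3,
                GLU = 3, GLY = 0, HIS = 2, ILE = 2, LEU = 2, LYS = 4,
                MET = 3, PHE = 2, PRO = 2, SER = 1, THR = 1, TRP = 2,
                TYR = 2, VAL = 1)

# Canonical sidechain heavy-atom counts (CB and beyond).
.n_sc_tab <- c(ALA = 1, ARG = 7, ASN = 4, ASP = 4, CYS = 2, GLN = 5,
               GLU = 5, GLY = 0, HIS = 6, ILE = 4, LEU = 4, LYS = 5,
               MET = 4, PHE = 7, PRO = 3, SER = 2, THR = 3, TRP = 10,
               TYR = 8, VAL = 3)

# Fourth atom of the chi1 quadruple N-CA-CB-<atom>.
.chi1_atom <- c(ARG = "CG", ASN = "CG", ASP = "CG", CYS = "SG",
                GLN = "CG", GLU = "CG", HIS = "CG", ILE = "CG1",
                LEU = "CG", LYS = "CG", MET = "CG", PHE = "CG",
                PRO = "CG", SER = "OG", THR = "OG1", TRP = "CG",
                TYR = "CG", VAL = "CG1")

# Fourth atom of the chi2 quadruple CA-CB-<chi1 atom>-<atom>.
.chi2_atom <- c(ARG = "CD", ASN = "OD1", ASP = "OD1", GLN = "CD",
                GLU = "CD", HIS = "ND1", ILE = "CD1", LEU = "CD1",
                LYS = "CD", MET = "SD", PHE = "CD1", PRO = "CD",
                TRP = "CD1", TYR = "CD1")

# Residue types whose chi2 is chemically 2-fold symmetric (the naming of
# the two equivalent terminal atoms is arbitrary in experimental models).
.chi2_symmetric <- c("ASP", "PHE", "TYR")

# Ideal backbone internal coordinates (Engh & Huber style).
.bb_geom <- list(
  n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
  ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
  ang_ca_c_o = 120.8,
  cb_bond = 1.530, ang_c_ca_cb = 110.1, improper_n_c_ca_cb = 122.6)

# Sidechain Z-matrix derived from CCD ideal residue geometry (heavy atoms).
# torsion = chi1/chi2 placeholder + offset (deg), or absolute value for 'fixed'.
.sidechain_zmat <- data.frame(
  res_type = c("ARG", "ARG", "ARG", "ARG", "ARG", "ARG", "ASN", "ASN", "ASN", "ASP", "ASP", "ASP", "CYS", "GLN", "GLN", "GLN", "GLN", "GLU", "GLU", "GLU", "GLU", "HIS", "HIS", "HIS", "HIS", "HIS", "ILE", "ILE", "ILE", "LEU", "LEU", "LEU", "LYS", "LYS", "LYS", "LYS", "MET", "MET", "MET", "PHE", "PHE", "PHE", "PHE", "PHE", "PHE", "PRO", "PRO", "SER", "THR", "THR", "TRP", "TRP", "TRP", "TRP", "TRP", "TRP", "TRP", "TRP", "TRP", "TYR", "TYR", "TYR", "TYR", "TYR", "TYR", "TYR", "VAL", "VAL"),
  atom = c("CG", "CD", "NE", "CZ", "NH1", "NH2", "CG", "OD1", "ND2", "CG", "OD1", "OD2", "SG", "CG", "CD", "NE2", "OE1", "CG", "CD", "OE1", "OE2", "CG", "ND1", "CD2", "CE1", "NE2", "CG1", "CG2", "CD1", "CG", "CD1", "CD2", "CG", "CD", "CE", "NZ", "CG", "SD", "CE", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "CG", "CD", "OG", "OG1", "CG2", "CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH", "CG1", "CG2"),
  ref1 = c("CB", "CG", "CD", "NE", "CZ", "CZ", "CB", "CG", "CG", "CB", "CG", "CG", "CB", "CB", "CG", "CD", "CD", "CB", "CG", "CD", "CD", "CB", "CG", "CG", "ND1", "CD2", "CB", "CB", "CG1", "CB", "CG", "CG", "CB", "CG", "CD", "CE", "CB", "CG", "SD", "CB", "CG", "CG", "CD1", "CD2", "CE1", "CB", "CG", "CB", "CB", "CB", "CB", "CG", "CG", "CD1", "CD2", "CD2", "CE2", "CE3", "CZ2", "CB", "CG", "CG", "CD1", "CD2", "CE1", "CZ", "CB", "CB"),
  ref2 = c("CA", "CB", "CG", "CD", "NE", "NE", "CA", "CB", "CB", "CA", "CB", "CB", "CA", "CA", "CB", "CG", "CG", "CA", "CB", "CG", "CG", "CA", "CB", "CB", "CG", "CG", "CA", "CA", "CB", "CA", "CB", "CB", "CA", "CB", "CG", "CD", "CA", "CB", "CG", "CA", "CB", "CB", "CG", "CG", "CD1", "CA", "CB", "CA", "CA", "CA", "CA", "CB", "CB", "CG", "CG", "CG", "CD2", "CD2", "CE2", "CA", "CB", "CB", "CG", "CG", "CD1", "CE1", "CA", "CA"),
  ref3 = c("N", "CA", "CB", "CG", "CD", "CD", "N", "CA", "CA", "N", "CA", "CA", "N", "N", "CA", "CB", "CB", "N", "CA", "CB", "CB", "N", "CA", "CA", "CB", "CB", "N", "N", "CA", "N", "CA", "CA", "N", "CA", "CB", "CG", "N", "CA", "CB", "N", "CA", "CA", "CB", "CB", "CG", "N", "CA", "N", "N", "N", "N", "CA", "CA", "CB", "CB", "CB", "CG", "CG", "CD2", "N", "CA", "CA", "CB", "CB", "CG", "CD1", "N", "N"),
  bond = c(1.5371, 1.5273, 1.4435, 1.4058, 1.3906, 1.3912, 1.5066, 1.2133, 1.3476, 1.5075, 1.2080, 1.3415, 1.8141, 1.5284, 1.5066, 1.3471, 1.2122, 1.5306, 1.5076, 1.2084, 1.3425, 1.5100, 1.3513, 1.3376, 1.3369, 1.3739, 1.5294, 1.5303, 1.5288, 1.5303, 1.5300, 1.5285, 1.5307, 1.5308, 1.5291, 1.4694, 1.5284, 1.8137, 1.8135, 1.5052, 1.3817, 1.3832, 1.3820, 1.3819, 1.3806, 1.5426, 1.5437, 1.4283, 1.4280, 1.5301, 1.5067, 1.3426, 1.4639, 1.3686, 1.4068, 1.3961, 1.3906, 1.3659, 1.3773, 1.5062, 1.3823, 1.3830, 1.3810, 1.3809, 1.3867, 1.3582, 1.5299, 1.5292),
  angle = c(114.536, 112.417, 111.016, 123.005, 120.996, 119.815, 109.484, 119.974, 120.012, 109.463, 119.959, 119.999, 109.498, 109.534, 109.543, 120.093, 119.937, 109.402, 109.430, 120.003, 119.998, 112.979, 120.329, 129.928, 107.862, 105.332, 109.547, 109.458, 109.547, 109.495, 109.500, 109.501, 109.418, 109.441, 109.465, 109.500, 109.545, 109.506, 100.034, 109.517, 120.058, 120.005, 120.029, 119.977, 120.047, 105.059, 105.063, 109.512, 109.505, 109.525, 109.442, 126.496, 126.512, 109.932, 106.076, 134.047, 119.346, 119.795, 119.806, 109.497, 119.947, 119.943, 120.073, 120.020, 119.978, 120.130, 109.509, 109.490),
  tor_ref = c("chi1", "chi2", "fixed", "fixed", "fixed", "fixed", "chi1", "chi2", "chi2", "chi1", "chi2", "chi2", "chi1", "chi1", "chi2", "fixed", "fixed", "chi1", "chi2", "fixed", "fixed", "chi1", "chi2", "chi2", "fixed", "fixed", "chi1", "chi1", "chi2", "chi1", "chi2", "chi2", "chi1", "chi2", "fixed", "fixed", "chi1", "chi2", "fixed", "chi1", "chi2", "chi2", "fixed", "fixed", "fixed", "chi1", "chi2", "chi1", "chi1", "chi1", "chi1", "chi2", "chi2", "fixed", "fixed", "fixed", "fixed", "fixed", "fixed", "chi1", "chi2", "chi2", "fixed", "fixed", "fixed", "fixed", "chi1", "chi1"),
  tor_offset = c(0.000, 0.000, 60.183, 179.976, 179.986, -0.012, 0.000, 0.000, -179.926, 0.000, 0.000, -179.936, 0.000, 0.000, 0.000, 179.988, -0.055, 0.000, 0.000, -0.033, -179.970, 0.000, 0.000, 179.846, 179.905, -179.864, 0.000, -119.972, 0.000, 0.000, 0.000, 120.092, 0.000, 0.000, 179.997, -179.951, 0.000, 0.000, -179.995, 0.000, 0.000, 179.757, 179.994, 179.839, -0.048, 0.000, 0.000, 0.000, 0.000, -120.031, 0.000, 0.000, 179.622, 179.944, 179.958, 0.784, -179.825, 179.639, 0.221, 0.000, 0.000, 179.692, -179.976, 179.775, -0.102, -179.966, 0.000, 120.026),
  stringsAsFactors = FALSE)
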