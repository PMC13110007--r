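# Element and residue reference tables used by the featurizers.

# Element symbols for atomic numbers 1..100 (the one-hot vocabulary).
ELEMENT_SYMBOLS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
  "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca",
  "Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
  "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr", "Y", "Zr",
  "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd",
  "Pm", "Sm", "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb",
  "Lu", "Hf", "Ta", "W", "Re", "Os", "Ir", "Pt", "Au", "Hg",
  "Tl", "Pb", "Bi", "Po", "At", "Rn", "Fr", "Ra", "Ac", "Th",
  "Pa", "U", "Np", "Pu", "Am", "Cm", "Bk", "Cf", "Es", "Fm"
)

# Van der Waals radii in Angstrom, Z = 1..100. Main-group values follow
# Bondi (1964); metals, lanthanides and actinides follow later literature
# compilations (Alvarez-type). Fixed table: corpus min/max normalization
# depends on the molecules, never on table revisions.
VDW_RADII <- c(
  1.20, 1.40, 1.81, 1.53, 1.92, 1.70, 1.55, 1.52, 1.47, 1.54,
  2.27, 1.73, 1.84, 2.10, 1.80, 1.80, 1.75, 1.88, 2.75, 2.31,
  2.15, 2.11, 2.07, 2.06, 2.05, 2.04, 2.00, 1.97, 1.96, 2.01,
  1.87, 2.11, 1.85, 1.90, 1.85, 2.02, 3.03, 2.49, 2.32, 2.23,
  2.18, 2.17, 2.16, 2.13, 2.10, 2.10, 2.11, 2.18, 1.93, 2.17,
  2.06, 2.06, 1.98, 2.16, 3.43, 2.68, 2.43, 2.42, 2.40, 2.39,
  2.38, 2.36, 2.35, 2.34, 2.33, 2.31, 2.30, 2.29, 2.27, 2.26,
  2.24, 2.23, 2.22, 2.18, 2.16, 2.16, 2.13, 2.13, 2.14, 2.23,
  1.96, 2.02, 2.07, 1.97, 2.02, 2.20, 3.48, 2.83, 2.47, 2.45,
  2.43, 2.41, 2.39, 2.43, 2.44, 2.45, 2.44, 2.45, 2.45, 2.45
)
names(VDW_RADII) <- ELEMENT_SYMBOLS

# Canonical amino acids, alphabetical by three-letter code. This ordering
# fixes the residue one-hot layout.
AA_THREE <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"
)
AA_ONE <- c(
  "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"
)
names(AA_ONE) <- AA_THREE

# Theoretical maximum accessible surface area per residue type (A^2),
# Tien et al. 2013; used to convert DSSP absolute ASA to relative ASA.
MAX_ASA <- c(
  ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167,
  GLN = 225, GLU = 223, GLY = 104, HIS = 224, ILE = 197,
  LEU = 201, LYS = 236, MET = 224, PHE = 240, PRO = 159,
  SER = 155, THR = 172, TRP = 285, TYR = 263, VAL = 174
)

# Elements admitted by the organic-subset filter.
ORGANIC_ELEMENTS <- c("H", "B", "C", "N", "O", "F", "P", "S", "Cl", "Br", "I")

# Rotatable-bond SMARTS: single, acyclic bonds between two non-terminal
# atoms, excluding bonds adjacent to triple bonds.
ROTOR_SMARTS <- "[!$(*#*)&!D1]-!@[!$(*#*)&!D1]"

atomicNumber <- function(symbol) {
  z <- match(symbol, ELEMENT_SYMBOLS)
  z
}
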