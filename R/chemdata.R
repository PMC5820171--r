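# Chemistry lookup tables shared by the property manifest, the functional-center
# mapping and the synthetic generator. All keys are (resname, atom name) in
# PDB v3 naming; hydrogens are never tabulated (ignored in featurization).

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
         "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL")

# Kyte-Doolittle hydropathy index, per residue
KD_INDEX <- c(ALA = 1.8, ARG = -4.5, ASN = -3.5, ASP = -3.5, CYS = 2.5,
              GLN = -3.5, GLU = -3.5, GLY = -0.4, HIS = -3.2, ILE = 4.5,
              LEU = 3.8, LYS = -3.9, MET = 1.9, PHE = 2.8, PRO = -1.6,
              SER = -0.8, THR = -0.7, TRP = -0.9, TYR = -1.3, VAL = 4.2)

RESIDUE_CLASSES <- list(
  hydrophobic = c("ALA", "VAL", "LEU", "ILE", "PRO", "PHE", "MET", "TRP"),
  polar       = c("SER", "THR", "TYR", "CYS", "ASN", "GLN"),
  acidic      = c("ASP", "GLU"),
  basic       = c("LYS", "ARG", "HIS"),
  amide       = c("ASN", "GLN"),
  sulfur      = c("CYS", "MET"),
  small       = c("GLY", "ALA", "SER", "THR", "CYS"),
  aromatic    = c("PHE", "TYR", "TRP", "HIS")
)

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

# side-chain ring atoms counted by the aromatic-ring property
AROMATIC_RING_ATOMS <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2")
)

# hydrogen-bond capable heavy atoms (side chain); backbone handled separately
HB_DONOR_ATOMS <- list(
  SER = "OG", THR = "OG1", TYR = "OH", ASN = "ND2", GLN = "NE2",
  LYS = "NZ", ARG = c("NE", "NH1", "NH2"), HIS = c("ND1", "NE2"),
  TRP = "NE1", CYS = "SG"
)
HB_ACCEPTOR_ATOMS <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
  SER = "OG", THR = "OG1", TYR = "OH", HIS = c("ND1", "NE2"), MET = "SD"
)

FUNCTIONAL_GROUPS <- list(
  hydroxyl        = list(SER = "OG", THR = "OG1", TYR = "OH"),
  carboxylate     = list(ASP = c("CG", "OD1", "OD2"), GLU = c("CD", "OE1", "OE2")),
  amide           = list(ASN = c("CG", "OD1", "ND2"), GLN = c("CD", "OE1", "NE2")),
  guanidinium     = list(ARG = c("NE", "CZ", "NH1", "NH2")),
  imidazole       = list(HIS = c("CG", "ND1", "CD2", "CE1", "NE2")),
  thiol_thioether = list(CYS = "SG", MET = "SD")
)

# fractional formal charges at physiological pH, spread over the charged group
FORMAL_CHARGES <- list(
  LYS = c(NZ = 1),
  ARG = c(NE = 1 / 3, NH1 = 1 / 3, NH2 = 1 / 3),
  ASP = c(OD1 = -0.5, OD2 = -0.5),
  GLU = c(OE1 = -0.5, OE2 = -0.5)
)

# atom names filling the tail of the 80-property manifest (plain counts)
MANIFEST_ATOM_NAMES <- c(
  "CA", "CB", "CG", "CG1", "CG2", "CD", "CD1", "CD2", "CE", "CE1", "CE2",
  "CE3", "CZ", "CZ2", "CZ3", "CH2", "N", "O", "OD1", "OD2", "OE1", "OE2",
  "OG", "OG1", "OH", "ND1", "NE2"
)

#' Chemistry classes recognised for functional centers
#' @return character vector of the ten class labels.
#' @export
chem_classes <- function() {
  c("hydroxyl", "carboxylate", "amide", "amine", "guanidinium",
    "imidazole", "thiol_thioether", "aromatic", "aliphatic", "backbone")
}

# residue -> (atoms used for the center point, chemistry class). Multi-atom
# entries use the mean of the named atoms; rings use their full-ring centroid.
CENTER_MAP <- list(
  GLY = list(atoms = "CA",                 class = "backbone"),
  ALA = list(atoms = "CB",                 class = "aliphatic"),
  VAL = list(atoms = c("CG1", "CG2"),      class = "aliphatic"),
  LEU = list(atoms = c("CD1", "CD2"),      class = "aliphatic"),
  ILE = list(atoms = "CD1",                class = "aliphatic"),
  PRO = list(atoms = "CG",                 class = "aliphatic"),
  MET = list(atoms = "CE",                 class = "aliphatic"),
  SER = list(atoms = "OG",                 class = "hydroxyl"),
  THR = list(atoms = "OG1",                class = "hydroxyl"),
  CYS = list(atoms = "SG",                 class = "thiol_thioether"),
  ASP = list(atoms = c("OD1", "OD2"),      class = "carboxylate"),
  GLU = list(atoms = c("OE1", "OE2"),      class = "carboxylate"),
  ASN = list(atoms = c("OD1", "ND2"),      class = "amide"),
  GLN = list(atoms = c("OE1", "NE2"),      class = "amide"),
  LYS = list(atoms = "NZ",                 class = "amine"),
  ARG = list(atoms = "CZ",                 class = "guanidinium"),
  HIS = list(atoms = c("ND1", "NE2"),      class = "imidazole"),
  PHE = list(atoms = AROMATIC_RING_ATOMS$PHE, class = "aromatic"),
  TYR = list(atoms = AROMATIC_RING_ATOMS$TYR, class = "aromatic"),
  TRP = list(atoms = AROMATIC_RING_ATOMS$TRP, class = "aromatic")
)
CENTER_FALLBACK <- list(atoms = "CA", class = "backbone")

center_rule <- function(resname) {
  rule <- CENTER_MAP[[toupper(resname)]]
  if (is.null(rule)) CENTER_FALLBACK else rule
}
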