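# Physical constants and bundled parameter tables.
#
# Unit conventions used throughout the package: coordinates and radii in
# Angstrom, charges in elementary charge units, energies in kcal/mol,
# potentials in kT/e, frequencies in GHz.

# Coulomb constant e^2/(4 pi eps0), in kcal*A/(mol*e^2)
COULOMB_KCAL <- 332.0637

# Vacuum "Bjerrum length" e^2/(4 pi eps0 kT) at 298.15 K, in Angstrom.
# Temperature dependence handled by bjerrum_vacuum().
BJERRUM_VAC_298 <- 560.456

bjerrum_vacuum <- function(temperature = 298.15) {
  BJERRUM_VAC_298 * 298.15 / temperature
}

# Inverse Debye length squared (A^-2) for a 1:1 electrolyte:
# kappa^2 = 8 pi (l_B_vac / eps_s) * n, with n the ion number density in A^-3.
debye_kappa2 <- function(ionic_strength, eps_solvent = 80, temperature = 298.15) {
  n <- 6.02214076e-4 * ionic_strength # number density per species, A^-3
  8 * pi * (bjerrum_vacuum(temperature) / eps_solvent) * n
}

# Angstrom -> bohr (CUBE headers are in atomic units)
ANGSTROM_TO_BOHR <- 1.8897259886

# kcal/(mol*A^2) -> N/m, and dalton -> kg (ANM frequency conversion)
KCALMOLA2_TO_NM <- 4184 / (6.02214076e23 * 1e-20) # 0.6947695
DALTON_TO_KG <- 1.66053907e-27

# one- and three-letter amino acid codes
AA_THREE <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
  E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
  M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
  Y = "TYR", V = "VAL"
)
AA_ONE <- setNames(names(AA_THREE), AA_THREE)

aa_one <- function(three) {
  out <- unname(AA_ONE[toupper(three)])
  out[is.na(out)] <- "X"
  out
}

aa_three <- function(one) {
  out <- unname(AA_THREE[toupper(one)])
  if (anyNA(out)) abort(paste0("unknown amino acid code: ", one[is.na(out)][1]))
  out
}

# van der Waals radii by element (A), Bondi-style values
VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
               F = 1.47, CL = 1.75, BR = 1.85, I = 1.98)

# covalent radii (A), used for bond detection in the simplified force field
COV_RADII <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, S = 1.05, P = 1.07)

#' Reference maximum solvent accessibility per residue
#'
#' Theoretical Gly-X-Gly maxima (A^2) used as denominators for relative SASA.
#' @return Named numeric vector, names are three-letter residue codes.
#' @export
max_sasa_table <- function() {
  c(ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167, GLU = 223,
    GLN = 225, GLY = 104, HIS = 224, ILE = 197, LEU = 201, LYS = 236,
    MET = 224, PHE = 240, PRO = 159, SER = 155, THR = 172, TRP = 285,
    TYR = 263, VAL = 174)
}

# Compact per-residue partial charge scheme (heavy atoms only).  Backbone
# atoms sum to zero; side chains carry the residue's formal charge split over
# the chemically relevant atoms.  Atoms not listed carry zero charge.
BACKBONE_CHARGES <- c(N = -0.40, CA = 0.25, C = 0.55, O = -0.40, OXT = -0.40)

SIDECHAIN_CHARGES <- list(
  ASP = c(CG = 0.36, OD1 = -0.68, OD2 = -0.68),
  GLU = c(CD = 0.36, OE1 = -0.68, OE2 = -0.68),
  LYS = c(CE = 0.30, NZ = 0.70),
  ARG = c(CZ = 0.34, NH1 = 0.33, NH2 = 0.33),
  HIS = c(ND1 = -0.30, NE2 = -0.30, CE1 = 0.30, CD2 = 0.30),
  SER = c(CB = 0.25, OG = -0.25),
  THR = c(CB = 0.25, OG1 = -0.25),
  TYR = c(CZ = 0.25, OH = -0.25),
  CYS = c(CB = 0.20, SG = -0.20),
  ASN = c(CG = 0.55, OD1 = -0.55, ND2 = -0.30, CB = 0.30),
  GLN = c(CD = 0.55, OE1 = -0.55, NE2 = -0.30, CG = 0.30),
  TRP = c(CD1 = 0.30, NE1 = -0.30)
)

element_from_name <- function(elety) {
  # strip digits and primes, handle two-letter elements crudely; PDB protein
  # atom names start with the element letter
  nm <- toupper(gsub("[0-9']", "", elety))
  first <- substr(nm, 1, 1)
  ifelse(first %in% names(VDW_RADII), first, first)
}

vdw_radius_of <- function(element, elety = element) {
  r <- VDW_RADII[toupper(element)]
  if (anyNA(r)) {
    bad <- elety[is.na(r)][1]
    abort(paste0("no van der Waals radius for atom '", bad, "'"))
  }
  unname(r)
}
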