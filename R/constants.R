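# Chemical and residue-level constants used across detection and calibration.

.ELEMENTS <- c(
  "H", "HE", "LI", "BE", "B", "C", "N", "O", "F", "NE", "NA", "MG", "AL",
  "SI", "P", "S", "CL", "AR", "K", "CA", "SC", "TI", "V", "CR", "MN", "FE",
  "CO", "NI", "CU", "ZN", "GA", "GE", "AS", "SE", "BR", "KR", "RB", "SR",
  "Y", "ZR", "NB", "MO", "TC", "RU", "RH", "PD", "AG", "CD", "IN", "SN",
  "SB", "TE", "I", "XE", "CS", "BA", "LA", "CE", "PR", "ND", "PM", "SM",
  "EU", "GD", "TB", "DY", "HO", "ER", "TM", "YB", "LU", "HF", "TA", "W",
  "RE", "OS", "IR", "PT", "AU", "HG", "TL", "PB", "BI", "PO", "AT", "RN",
  "FR", "RA", "AC", "TH", "PA", "U", "NP", "PU", "AM", "CM", "BK", "CF",
  "ES", "FM", "MD", "NO", "LR", "RF", "DB", "SG", "BH", "HS", "MT", "DS",
  "RG", "CN", "NH", "FL", "MC", "LV", "TS", "OG", "D"
)

.HALOGENS <- c("F", "CL", "BR", "I")

.WATER_NAMES <- c("HOH", "WAT", "DOD", "H2O")

.CANONICAL_AA <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"
)

# Scorable atomic acceptors in canonical amino acids: O or S atoms whose
# covalent heavy-atom neighbours are all carbon (acceptor classes O-C / S-C).
# The backbone carbonyl oxygen (and C-terminal OXT) applies to every residue.
.BACKBONE_ACCEPTORS <- tibble::tribble(
  ~atom_name, ~element, ~neighbors,
  "O",   "O", list("C"),
  "OXT", "O", list("C")
)

.SIDECHAIN_ACCEPTORS <- tibble::tribble(
  ~residue_name, ~atom_name, ~element, ~neighbors,
  "SER", "OG",  "O", list("CB"),
  "THR", "OG1", "O", list("CB"),
  "TYR", "OH",  "O", list("CZ"),
  "ASP", "OD1", "O", list("CG"),
  "ASP", "OD2", "O", list("CG"),
  "GLU", "OE1", "O", list("CD"),
  "GLU", "OE2", "O", list("CD"),
  "ASN", "OD1", "O", list("CG"),
  "GLN", "OE1", "O", list("CD"),
  "CYS", "SG",  "S", list("CB"),
  "MET", "SD",  "S", list("CG", "CE")
)

# Aromatic ring atom sets of the pi-acceptor residues.  Tryptophan's indole
# is represented by default as two rings (5- and 6-membered); downstream
# best-bond selection keeps the better-scoring one.
.PI_RINGS <- list(
  HIS = list(ring = c("CG", "ND1", "CD2", "CE1", "NE2")),
  PHE = list(ring = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TYR = list(ring = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TRP = list(
    ring5 = c("CG", "CD1", "NE1", "CE2", "CD2"),
    ring6 = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
    indole = c("CG", "CD1", "NE1", "CE2", "CD2", "CE3", "CZ2", "CZ3", "CH2")
  )
)

.PI_CLASS <- c(HIS = "His", PHE = "Phe", TYR = "Tyr", TRP = "Trp")

.ACCEPTOR_CLASSES <- c("O-C", "S-C", "His", "Phe", "Tyr", "Trp")

#' Compound identifiers excluded from halogen-bond analysis
#'
#' Chemical Component Dictionary identifiers of halogen-containing compounds
#' that are excluded from halogen-bond detection: the single-ion halogens
#' (F-, Cl-, Br-, I-) and compounds in which the halogen is not bonded to a
#' carbon atom, such as halogen-metal complexes and halogen acids.
#'
#' @return A character vector of CCD compound identifiers.
#' @examples
#' "IOD" %in% excluded_compound_ids()
#' "TCL" %in% excluded_compound_ids()
#' @export
excluded_compound_ids <- function() {
  c(
    "F", "CL", "BR", "IOD", "08T", "0JC", "0OD", "0TE", "202", "2T8",
    "4IR", "4KV", "5LN", "61C", "61D", "6BP", "6O0", "73M", "7GE", "8TH",
    "8TR", "8WV", "9QB", "9RU", "9TH", "A9J", "AF3", "ALF", "BE7", "BEF",
    "BF2", "BF4", "BFD", "BPT", "C2C", "C7P", "CFO", "CPT", "CUL", "D0X",
    "D7Z", "DAA", "DAE", "DAQ", "E3D", "E5O", "ELJ", "F6Q", "F7T", "FPO",
    "HG2", "HGI", "I2I", "I3M", "I83", "J0K", "J0N", "JR3", "KQB", "KYS",
    "KYT", "LCO", "LCP", "LN8", "MF4", "MGF", "MNQ", "N2N", "N2R", "N2S",
    "N2W", "NG8", "NMQ", "NXC", "O1N", "ONP", "ORS", "OS1", "OT1", "P3C",
    "PC4", "PCL", "PEJ", "PNQ", "PT7", "QLT", "R1N", "RAX", "RBN", "RHE",
    "RSW", "RU0", "RU7", "RUD", "RUH", "SFL", "SRX", "SVP", "SXC", "TBR",
    "TPT", "U0J", "VKZ", "VL2", "YPT", "YXX", "YXZ", "ZN0", "ZN5", "ZN6",
    "ZN7", "ZN8", "ZN9", "ZPT"
  )
}
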