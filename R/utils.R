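# Internal geometry and bookkeeping helpers shared across modules.

# Squared Euclidean distance matrix between two n x 3 coordinate matrices.
# Clamps tiny negative values arising from floating-point cancellation.
dist2_mat <- function(a, b) {
  a <- matrix(a, ncol = 3L)
  b <- matrix(b, ncol = 3L)
  d2 <- outer(rowSums(a * a), rowSums(b * b), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

min_dist <- function(a, b) sqrt(min(dist2_mat(a, b)))

# Extract the n_atoms x 3 coordinate matrix of frame k from an xyz matrix
# stored in the bio3d row-per-frame convention (x1, y1, z1, x2, ...).
frame_coords <- function(xyz, k) {
  matrix(xyz[k, ], ncol = 3L, byrow = TRUE)
}

# Residue identity key: chain, residue number and insertion code together.
res_key <- function(chain, resno, insert = "") {
  insert[is.na(insert)] <- ""
  paste(chain, resno, insert, sep = "|")
}

is_heavy <- function(elesy) !(toupper(elesy) %in% c("H", "D"))

# Three-letter residue names treated as protein.
AMINO_ACIDS <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
  "HSD", "HSE", "HSP", "MSE", "SEC", "PYL", "CYX", "HID", "HIE", "HIP"
)

# Residue names silently excluded as solvent / ions.
SOLVENT_IONS <- c(
  "HOH", "WAT", "TIP", "TIP3", "TP3M", "SPC", "SOL",
  "SOD", "CLA", "POT", "NA", "CL", "K", "MG", "CA2", "CAL", "ZN", "ZN2",
  "CES", "LIT", "RUB", "BAR"
)

# Element symbol from a PDB atom name when the element column is absent.
guess_element <- function(atom_name) {
  nm <- gsub("[0-9' ]", "", toupper(atom_name))
  ifelse(substr(nm, 1L, 1L) %in% c("H", "D") |
           grepl("^[0-9]", trimws(toupper(atom_name))),
         "H", substr(nm, 1L, 1L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_stage <- function(stage, fmt, ...) {
  stop(sprintf("[%s] %s", stage, sprintf(fmt, ...)), call. = FALSE)
}
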