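# Low-level structure file helpers. Reading of PDB/DCD goes through bio3d;
# writing is done here with fixed sprintf formats so outputs are
# deterministic byte-for-byte and multi-model files / pseudo-atom B-factor
# conventions are under our control.

# Format one ATOM record. PDB fixed columns; coordinates to 1e-3 A.
format_atom_record <- function(serial, name, resname, chain, resno, insert,
                               x, y, z, occ = 1, b = 0, element = "") {
  name <- trimws(name)
  # short names start in column 14 unless 4 characters long
  name_fmt <- if (nchar(name) >= 4L) sprintf("%-4s", name)
              else sprintf(" %-3s", name)
  # 4-character residue names (CHARMM probe residues) span columns 18-21,
  # as CHARMM itself writes them.
  sprintf("ATOM  %5d %s %-4s%1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          as.integer(serial) %% 100000L, name_fmt, resname,
          substr(paste0(chain, " "), 1L, 1L), as.integer(resno) %% 10000L,
          substr(paste0(if (is.null(insert) || is.na(insert)) "" else insert,
                        " "), 1L, 1L),
          x, y, z, occ, b, element)
}

# Write a (possibly multi-model) PDB. `atoms` is the atom table; `xyz` is
# either NULL (use atoms$x/y/z) or an n_frames x 3n matrix -> MODEL blocks.
write_pdb_file <- function(atoms, file, xyz = NULL, occ = NULL, b = NULL) {
  n <- nrow(atoms)
  occ <- if (is.null(occ)) rep(1, n) else rep_len(occ, n)
  b   <- if (is.null(b))   rep(0, n) else rep_len(b, n)
  one_model <- function(cm) {
    vapply(seq_len(n), function(i)
      format_atom_record(i, atoms$elety[i], atoms$resid[i], atoms$chain[i],
                         atoms$resno[i], atoms$insert[i],
                         cm[i, 1L], cm[i, 2L], cm[i, 3L],
                         occ[i], b[i], atoms$elesy[i]), "")
  }
  con <- file(file, "wb")  # binary mode: fixed "\n" endings on all platforms
  on.exit(close(con))
  out <- character(0)
  if (is.null(xyz)) {
    out <- c(one_model(cbind(atoms$x, atoms$y, atoms$z)), "END")
  } else {
    xyz <- matrix(xyz, ncol = 3L * n)
    for (k in seq_len(nrow(xyz))) {
      out <- c(out, sprintf("MODEL %8d", k), one_model(frame_coords(xyz, k)),
               "ENDMDL")
    }
    out <- c(out, "END")
  }
  writeLines(out, con, sep = "\n")
  invisible(file)
}

# Minimal X-PLOR/CHARMM PSF atom-section reader. Only the !NATOM block is
# used: enough to name atoms, residues, chains (segments) for a DCD.
read_psf_atoms <- function(file) {
  lines <- readLines(file)
  hit <- grep("!NATOM", lines, fixed = TRUE)
  if (!length(hit)) stop("no !NATOM section in PSF file: ", file)
  natom <- as.integer(sub("^\\s*(\\d+).*", "\\1", lines[hit[1L]]))
  body <- lines[(hit[1L] + 1L):(hit[1L] + natom)]
  fields <- strsplit(trimws(body), "\\s+")
  get <- function(j) vapply(fields, `[[`, "", j)
  atoms <- data.frame(
    eleno = as.integer(get(1L)),
    chain = substr(get(2L), 1L, 1L),   # segment name -> chain letter
    resno = as.integer(get(3L)),
    insert = "",
    resid = toupper(get(4L)),
    elety = get(5L),
    stringsAsFactors = FALSE
  )
  atoms$elesy <- guess_element(atoms$elety)
  atoms$x <- atoms$y <- atoms$z <- NA_real_
  atoms
}

#' Write a CHARMM-format DCD trajectory
#'
#' Emits a plain CHARMM/NAMD binary DCD (no unit-cell blocks, native
#' endianness) readable by [bio3d::read.dcd()] and by common MD tools.
#' Used by the fixture generator to mirror its multi-model PDB trajectories
#' onto the binary reader path.
#'
#' @param xyz Numeric matrix, one row per frame in `(x1, y1, z1, x2, ...)`
#'   order.
#' @param file Output path.
#' @param delta Integration time step field stored in the header (ps).
#' @return `file`, invisibly.
#' @export
write_dcd <- function(xyz, file, delta = 0.004) {
  xyz <- as.matrix(xyz)
  n_frames <- nrow(xyz)
  natom <- ncol(xyz) %/% 3L
  con <- file(file, "wb")
  on.exit(close(con))
  wint <- function(v) writeBin(as.integer(v), con, size = 4L)
  # header record: CORD + 20 control integers (icntrl[20]=24 -> CHARMM 24)
  icntrl <- integer(20L)
  icntrl[1L] <- n_frames; icntrl[2L] <- 1L; icntrl[3L] <- 1L
  icntrl[4L] <- n_frames
  icntrl[20L] <- 24L
  wint(84L); writeChar("CORD", con, nchars = 4L, eos = NULL)
  wint(icntrl[1L:9L])
  writeBin(as.numeric(delta), con, size = 4L)
  wint(icntrl[11L:20L]); wint(84L)
  # title record: one 80-character line
  title <- sprintf("%-80s", "REMARKS synthetic trajectory written by probemap")
  wint(84L); wint(1L); writeChar(title, con, nchars = 80L, eos = NULL); wint(84L)
  # atom-count record
  wint(4L); wint(natom); wint(4L)
  nb <- 4L * natom
  for (k in seq_len(n_frames)) {
    cm <- frame_coords(xyz, k)
    for (j in 1L:3L) {
      wint(nb); writeBin(as.numeric(cm[, j]), con, size = 4L); wint(nb)
    }
  }
  invisible(file)
}
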