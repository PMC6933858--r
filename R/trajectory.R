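#' Load a reference protein structure from a PDB file
#'
#' Reads the structure the whole analysis is framed in: every trajectory
#' frame is later superposed onto this structure's C-alpha atoms, and all
#' grid, hot-spot and site coordinates live in its frame. Chain identifiers
#' and residue numbers are preserved verbatim from the file — no
#' renumbering — because downstream residue reports must match the source
#' PDB's numbering. Only the first alternate location is kept; insertion
#' codes are part of residue identity.
#'
#' @param path Path to a PDB file with at least one ATOM record.
#' @return An object of class `probe_ref`: list with `atoms` (data frame of
#'   atom name, element, residue name/number, insertion code, chain and
#'   coordinates) and `calpha` (indices of C-alpha atoms).
#' @export
load_reference <- function(path) {
  if (!file.exists(path)) stop("reference PDB not found: ", path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  atoms <- normalize_bio3d_atoms(pdb$atom)
  if (nrow(atoms) == 0L) stop("no ATOM records in: ", path)
  key <- paste(res_key(atoms$chain, atoms$resno, atoms$insert), atoms$elety)
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1L]
    stop("duplicate (chain, residue, atom name) record in ", path, ": ", d)
  }
  calpha <- which(atoms$elety == "CA" & atoms$resid %in% AMINO_ACIDS)
  if (!length(calpha)) stop("no C-alpha atoms found in: ", path)
  structure(list(atoms = atoms, calpha = calpha, path = path),
            class = "probe_ref")
}

#' @export
print.probe_ref <- function(x, ...) {
  cat(sprintf("Reference structure: %d atoms, %d C-alpha, chains %s\n",
              nrow(x$atoms), length(x$calpha),
              paste(sort(unique(x$atoms$chain)), collapse = " ")))
  invisible(x)
}

# Standardize a bio3d atom table to the internal column set, keeping the
# first altloc only and treating insertion codes as residue identity.
normalize_bio3d_atoms <- function(at) {
  at <- at[at$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  alt <- at$alt %||% rep("", nrow(at))
  alt[is.na(alt)] <- ""
  keep <- alt %in% c("", " ", "A", "1")
  at <- at[keep, , drop = FALSE]
  ins <- at$insert %||% rep("", nrow(at))
  ins[is.na(ins)] <- ""
  elesy <- at$elesy %||% rep(NA_character_, nrow(at))
  elesy[is.na(elesy) | elesy == ""] <- guess_element(at$elety[is.na(elesy) | elesy == ""])
  chain <- at$chain
  chain[is.na(chain)] <- " "
  data.frame(eleno = seq_len(nrow(at)), elety = at$elety, elesy = elesy,
             resid = toupper(at$resid), resno = at$resno, insert = ins,
             chain = chain, x = at$x, y = at$y, z = at$z,
             stringsAsFactors = FALSE)
}

#' Construct a trajectory ensemble from in-memory components
#'
#' Low-level constructor used by the file readers and the fixture
#' generator. Partitions atoms into protein and probe instances, excludes
#' water and ions, and errors on residue names that are neither protein,
#' solvent, nor a known probe.
#'
#' @param atoms Atom table (as in a `probe_ref`) for one frame's topology.
#' @param xyz Numeric matrix, one row per frame, columns `(x1, y1, z1, ...)`.
#' @param specs Named list of [probe_spec()] objects.
#' @param frame_interval Time between stored frames (ps), metadata only.
#' @return An object of class `probe_traj` with fields `atoms`, `xyz`,
#'   `n_frames`, `protein` (atom indices), `instances` (list of probe
#'   copies, each with `instance_id`, `probe_name`, atom and heavy-atom
#'   indices), `specs` and `superposed`.
#' @export
trajectory_ensemble <- function(atoms, xyz, specs = default_probe_specs(),
                                frame_interval = 4) {
  xyz <- matrix(xyz, ncol = 3L * nrow(atoms))
  stopifnot(all(is.finite(xyz)))
  by_res <- spec_by_resname(specs)
  is_protein <- atoms$resid %in% AMINO_ACIDS
  is_solvent <- atoms$resid %in% SOLVENT_IONS
  is_probe <- atoms$resid %in% names(by_res)
  unknown <- setdiff(unique(atoms$resid[!(is_protein | is_solvent | is_probe)]),
                     character(0))
  if (length(unknown))
    stop("unknown probe residue name(s): ", paste(unknown, collapse = ", "),
         " (no matching probe spec; waters/ions are excluded automatically)")
  instances <- list()
  if (any(is_probe)) {
    pk <- res_key(atoms$chain, atoms$resno, atoms$insert)
    for (k in unique(pk[is_probe])) {
      idx <- which(is_probe & pk == k)
      spec <- by_res[[atoms$resid[idx[1L]]]]
      heavy <- idx[atoms$elety[idx] %in% spec$heavy_atoms]
      instances[[length(instances) + 1L]] <- list(
        instance_id = length(instances) + 1L,
        probe_name = spec$probe_name, resid = atoms$resid[idx[1L]],
        chain = atoms$chain[idx[1L]], resno = atoms$resno[idx[1L]],
        atoms = idx, heavy = heavy)
    }
  }
  structure(list(atoms = atoms, xyz = xyz, n_frames = nrow(xyz),
                 protein = which(is_protein), instances = instances,
                 specs = specs, frame_interval = frame_interval,
                 superposed = FALSE),
            class = "probe_traj")
}

#' @export
print.probe_traj <- function(x, ...) {
  comp <- table(vapply(x$instances, `[[`, "", "probe_name"))
  cat(sprintf("Trajectory ensemble: %d frames, %d atoms (%d protein), %s\n",
              x$n_frames, nrow(x$atoms), length(x$protein),
              if (x$superposed) "superposed" else "not superposed"))
  if (length(comp))
    cat("  probes:", paste(sprintf("%s x%d", names(comp), comp),
                           collapse = ", "), "\n")
  invisible(x)
}

#' Load a probe-simulation trajectory
#'
#' Accepts either a multi-model PDB (topology and coordinates in one file)
#' or a binary DCD paired with a PSF or single-model PDB topology. Probe
#' copies are identified by topology residue name against the supplied
#' probe specs; water and ions are excluded from both the protein and the
#' probe sets.
#'
#' @param topology Path to a PSF or PDB topology. For a multi-model PDB
#'   trajectory, pass that file here and leave `coords` `NULL`.
#' @param coords Optional path to a DCD (or multi-model PDB) holding the
#'   coordinates when `topology` has none.
#' @param specs Named list of [probe_spec()] objects.
#' @param stride Keep every `stride`-th frame (default 1: every frame).
#' @param frame_interval Time between stored frames (ps), metadata only.
#' @return A `probe_traj` object (not yet superposed).
#' @export
load_trajectory <- function(topology, coords = NULL,
                            specs = default_probe_specs(), stride = 1L,
                            frame_interval = 4) {
  if (!file.exists(topology)) stop("topology file not found: ", topology)
  is_psf <- grepl("\\.psf$", topology, ignore.case = TRUE)
  if (is_psf) {
    atoms <- read_psf_atoms(topology)
    xyz <- NULL
  } else {
    pdb <- bio3d::read.pdb(topology, multi = TRUE, verbose = FALSE)
    atoms <- normalize_bio3d_atoms(pdb$atom)
    xyz <- matrix(pdb$xyz, ncol = 3L * nrow(pdb$atom))
  }
  if (!is.null(coords)) {
    if (!file.exists(coords)) stop("trajectory file not found: ", coords)
    if (grepl("\\.dcd$", coords, ignore.case = TRUE)) {
      xyz <- unclass(bio3d::read.dcd(coords, verbose = FALSE))
    } else {
      pdb2 <- bio3d::read.pdb(coords, multi = TRUE, verbose = FALSE)
      xyz <- matrix(pdb2$xyz, ncol = 3L * nrow(pdb2$atom))
    }
  }
  if (is.null(xyz)) stop("no coordinates: PSF topology requires `coords`")
  if (ncol(xyz) != 3L * nrow(atoms))
    stop(sprintf("atom-count mismatch: topology has %d atoms, trajectory frames have %d",
                 nrow(atoms), ncol(xyz) %/% 3L))
  stride <- max(1L, as.integer(stride))
  if (stride > 1L) xyz <- xyz[seq(1L, nrow(xyz), by = stride), , drop = FALSE]
  trajectory_ensemble(atoms, xyz, specs, frame_interval * stride)
}

# Optimal least-squares rotation (Kabsch, SVD-based) mapping `mob` onto
# `fix` (both n x 3). Returns list(R, t) with y = x %*% R + t.
kabsch_fit <- function(mob, fix) {
  cm <- colMeans(mob); cf <- colMeans(fix)
  H <- crossprod(sweep(mob, 2L, cm), sweep(fix, 2L, cf))
  sv <- svd(H)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  R <- t(R)  # row-vector convention: y = x %*% R + t
  list(R = R, t = cf - cm %*% R)
}

#' Superpose every trajectory frame onto the reference structure
#'
#' Each frame is rigidly transformed by the optimal least-squares (Kabsch)
#' rotation and translation fitted on C-alpha atoms, matched between
#' reference and ensemble by (chain, residue number, insertion code). Probe
#' coordinates ride along with their frame's transform, so probe positions
#' end up in the reference frame. Superposition is idempotent and all
#' downstream scores are invariant to rigid motion of the input frames.
#'
#' @param ensemble A `probe_traj` object.
#' @param reference A `probe_ref` object.
#' @return The ensemble with transformed coordinates and
#'   `superposed = TRUE`.
#' @export
superpose <- function(ensemble, reference) {
  stopifnot(inherits(ensemble, "probe_traj"), inherits(reference, "probe_ref"))
  ref_at <- reference$atoms
  ref_ca <- reference$calpha
  ref_keys <- res_key(ref_at$chain[ref_ca], ref_at$resno[ref_ca],
                      ref_at$insert[ref_ca])
  ens_at <- ensemble$atoms
  ens_ca <- ensemble$protein[ens_at$elety[ensemble$protein] == "CA"]
  ens_keys <- res_key(ens_at$chain[ens_ca], ens_at$resno[ens_ca],
                      ens_at$insert[ens_ca])
  pos <- match(ref_keys, ens_keys)
  if (anyNA(pos))
    stop("C-alpha mapping incomplete; missing residue(s): ",
         paste(ref_keys[is.na(pos)], collapse = ", "))
  ens_ca <- ens_ca[pos]
  fix <- cbind(ref_at$x[ref_ca], ref_at$y[ref_ca], ref_at$z[ref_ca])
  xyz <- ensemble$xyz
  for (k in seq_len(ensemble$n_frames)) {
    cm <- frame_coords(xyz, k)
    fit <- kabsch_fit(cm[ens_ca, , drop = FALSE], fix)
    moved <- cm %*% fit$R + matrix(fit$t, nrow(cm), 3L, byrow = TRUE)
    xyz[k, ] <- as.numeric(t(moved))
  }
  ensemble$xyz <- xyz
  ensemble$superposed <- TRUE
  ensemble
}
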