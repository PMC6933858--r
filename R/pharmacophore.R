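# Step 5: co-occurrence snapshots, conformer similarity, snapshot
# extraction, pharmacophore construction and Pharmit session export.

#' Frames where all top-ranked interactions co-occur
#'
#' Intersects the qualifying-frame sets of every record in the top set.
#' These are the snapshots whose probe poses and protein conformations
#' are used to build pharmacophore models.
#'
#' @param top_set Non-empty list of `interaction_record` objects.
#' @return Ascending vector of frame indices; empty (with a warning
#'   suggesting a lower cutoff) if no frame satisfies all records.
#' @export
find_cooccurrence_frames <- function(top_set) {
  if (!length(top_set)) stop("no interactions above cutoff")
  frames <- Reduce(intersect, lapply(top_set, `[[`, "qualifying_frames"))
  if (!length(frames)) {
    warning("no frame satisfies all top-ranked interactions; ",
            "consider lowering the frequency cutoff")
    return(integer(0))
  }
  sort(frames)
}

#' Mean pairwise C-alpha RMSD of selected conformers
#'
#' Average over all unordered frame pairs of the C-alpha RMSD. Frames are
#' already superposed onto the common reference, so no per-pair refitting
#' is performed.
#'
#' @param ensemble A superposed `probe_traj`.
#' @param frame_ids At least two frame indices.
#' @return Mean pairwise RMSD (A).
#' @export
conformer_rmsd <- function(ensemble, frame_ids) {
  stopifnot(inherits(ensemble, "probe_traj"))
  if (length(frame_ids) < 2L)
    stop("at least two frames required for pairwise RMSD")
  at <- ensemble$atoms
  ca <- ensemble$protein[at$elety[ensemble$protein] == "CA"]
  coords <- lapply(frame_ids, function(k)
    frame_coords(ensemble$xyz, k)[ca, , drop = FALSE])
  pairs <- utils::combn(length(frame_ids), 2L)
  rmsds <- apply(pairs, 2L, function(p) {
    d <- coords[[p[1L]]] - coords[[p[2L]]]
    sqrt(mean(rowSums(d * d)))
  })
  mean(rmsds)
}

#' Extract one co-occurrence snapshot to PDB files
#'
#' Writes the frame's protein conformation and, separately, the probe
#' copies that satisfy a top-set interaction in this frame (criteria as
#' in [interaction_frequency()]), both in the superposed frame.
#'
#' @param ensemble A superposed `probe_traj`.
#' @param frame_id Frame index.
#' @param top_set List of `interaction_record` objects.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @param contact_cutoff,hotspot_assign_cutoff Cutoffs, as in
#'   [interaction_frequency()].
#' @return Object of class `pm_snapshot`: `frame_id`, written paths, the
#'   atom table and coordinates of the qualifying probe copies, and their
#'   instance descriptors.
#' @export
extract_snapshot <- function(ensemble, frame_id, top_set, dir = ".",
                             prefix = "snapshot", contact_cutoff = 4.0,
                             hotspot_assign_cutoff = 1.5) {
  stopifnot(inherits(ensemble, "probe_traj"))
  if (!(frame_id %in% seq_len(ensemble$n_frames)))
    stop("invalid frame id: ", frame_id)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  at <- ensemble$atoms
  cm <- frame_coords(ensemble$xyz, frame_id)
  ccut2 <- contact_cutoff^2
  hcut2 <- hotspot_assign_cutoff^2
  qual_ids <- integer(0)
  for (rec in top_set) {
    prot <- ensemble$protein
    ra <- prot[at$chain[prot] == rec$chain & at$resno[prot] == rec$resno &
                 at$insert[prot] == rec$insert &
                 is_heavy(at$elesy[prot])]
    centers <- cbind(rec$hotspots$x, rec$hotspots$y, rec$hotspots$z)
    for (ins in ensemble$instances) {
      if (ins$probe_name != rec$probe_name) next
      if (min(dist2_mat(cm[ins$heavy, , drop = FALSE],
                        cm[ra, , drop = FALSE])) > ccut2) next
      if (min(dist2_mat(cm[ins$atoms, , drop = FALSE], centers)) > hcut2) next
      qual_ids <- union(qual_ids, ins$instance_id)
    }
  }
  inst <- Filter(function(i) i$instance_id %in% qual_ids, ensemble$instances)
  prot_path <- file.path(dir, sprintf("%s_%d_protein.pdb", prefix, frame_id))
  probe_path <- file.path(dir, sprintf("%s_%d_probes.pdb", prefix, frame_id))
  pidx <- ensemble$protein
  pat <- at[pidx, , drop = FALSE]
  pat$x <- cm[pidx, 1L]; pat$y <- cm[pidx, 2L]; pat$z <- cm[pidx, 3L]
  write_pdb_file(pat, prot_path)
  qidx <- unlist(lapply(inst, `[[`, "atoms"))
  qat <- at[qidx, , drop = FALSE]
  if (length(qidx)) {
    qat$x <- cm[qidx, 1L]; qat$y <- cm[qidx, 2L]; qat$z <- cm[qidx, 3L]
  }
  write_pdb_file(qat, probe_path)
  structure(list(frame_id = frame_id, protein_path = prot_path,
                 probe_path = probe_path, probe_atoms = qat,
                 instances = inst),
            class = "pm_snapshot")
}

#' Build a pharmacophore model from a snapshot
#'
#' For each qualifying probe copy in the snapshot, emits one feature per
#' selected template of its probe spec: the feature sphere sits at the
#' template's anchor — a named heavy atom's position, or the centroid of
#' a named heavy-atom subset — with radius 1 A and enabled by default.
#'
#' @param snapshot A [extract_snapshot()] result with at least one probe.
#' @param specs Named list of [probe_spec()] objects.
#' @param features Optional character vector of feature kinds to keep
#'   (e.g. `c("hbond_donor", "hbond_acceptor", "hydrophobic")`); default
#'   all templates.
#' @param radius Feature sphere radius (A).
#' @return Object of class `pharmacophore_model`: `frame_id` and a
#'   feature table (`kind`, `x`, `y`, `z`, `radius`, `enabled`,
#'   `probe_name`, `instance_id`, `anchor`).
#' @export
build_pharmacophore <- function(snapshot, specs = default_probe_specs(),
                                features = NULL, radius = 1.0) {
  stopifnot(inherits(snapshot, "pm_snapshot"))
  if (!length(snapshot$instances))
    stop("snapshot contains no qualifying probe instances")
  rows <- list()
  for (ins in snapshot$instances) {
    spec <- specs[[ins$probe_name]]
    if (is.null(spec)) stop("no probe spec for: ", ins$probe_name)
    qa <- snapshot$probe_atoms
    aidx <- which(qa$chain == ins$chain & qa$resno == ins$resno &
                    qa$resid == ins$resid)
    for (ft in spec$features) {
      if (!is.null(features) && !(ft$kind %in% features)) next
      sel <- aidx[match(ft$atoms, qa$elety[aidx])]
      if (anyNA(sel))
        stop("anchor atom(s) missing from snapshot for ", ins$probe_name)
      cen <- colMeans(cbind(qa$x[sel], qa$y[sel], qa$z[sel]))
      rows[[length(rows) + 1L]] <- data.frame(
        kind = ft$kind, x = cen[1L], y = cen[2L], z = cen[3L],
        radius = radius, enabled = TRUE, probe_name = ins$probe_name,
        instance_id = ins$instance_id,
        anchor = paste(ft$atoms, collapse = "+"),
        stringsAsFactors = FALSE)
    }
  }
  structure(list(frame_id = snapshot$frame_id,
                 features = do.call(rbind, rows)),
            class = "pharmacophore_model")
}

#' @export
print.pharmacophore_model <- function(x, ...) {
  cat(sprintf("Pharmacophore model (frame %s): %d features\n",
              as.character(x$frame_id %||% NA), nrow(x$features)))
  tb <- table(x$features$kind)
  cat(" ", paste(sprintf("%s x%d", names(tb), tb), collapse = ", "), "\n")
  invisible(x)
}

# Closed feature vocabulary -> Pharmit point names.
PHARMIT_NAMES <- c(hbond_donor = "HydrogenDonor",
                   hbond_acceptor = "HydrogenAcceptor",
                   hydrophobic = "Hydrophobic",
                   aromatic = "Aromatic",
                   negative_ion = "NegativeIon",
                   positive_ion = "PositiveIon")

#' Write a pharmacophore model as Pharmit session JSON
#'
#' Emits the session format the Pharmit virtual-screening server
#' consumes: a top-level `points` array whose entries carry the Pharmit
#' feature name (`HydrogenDonor`, `HydrogenAcceptor`, `Hydrophobic`,
#' `Aromatic`, `NegativeIon`, `PositiveIon`), Cartesian coordinates in A,
#' the sphere radius and the enabled flag. Coordinates are written at
#' full precision so [read_pharmit_json()] reproduces the model exactly.
#'
#' @param model A `pharmacophore_model` with at least one feature.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_pharmit_json <- function(model, path) {
  stopifnot(inherits(model, "pharmacophore_model"))
  ft <- model$features
  if (is.null(ft) || nrow(ft) == 0L) stop("empty pharmacophore model")
  bad <- setdiff(unique(ft$kind), names(PHARMIT_NAMES))
  if (length(bad))
    stop("unmappable feature kind(s): ", paste(bad, collapse = ", "))
  points <- lapply(seq_len(nrow(ft)), function(i)
    list(name = unname(PHARMIT_NAMES[[ft$kind[i]]]),
         x = ft$x[i], y = ft$y[i], z = ft$z[i],
         radius = ft$radius[i], enabled = ft$enabled[i]))
  doc <- list(points = points, frame_id = model$frame_id)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a Pharmit session JSON back into a pharmacophore model
#'
#' Inverse of [write_pharmit_json()] for the fields this package writes;
#' feature provenance (probe instance, anchors) is not stored in the
#' session format and comes back as `NA`.
#'
#' @param path Pharmit session JSON file.
#' @return A `pharmacophore_model`.
#' @export
read_pharmit_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  inv <- names(PHARMIT_NAMES)
  names(inv) <- unname(PHARMIT_NAMES)
  rows <- lapply(doc$points, function(p) {
    kind <- inv[[p$name]]
    if (is.null(kind)) stop("unknown Pharmit feature name: ", p$name)
    data.frame(kind = kind, x = as.numeric(p$x), y = as.numeric(p$y),
               z = as.numeric(p$z), radius = as.numeric(p$radius),
               enabled = isTRUE(p$enabled), probe_name = NA_character_,
               instance_id = NA_integer_, anchor = NA_character_,
               stringsAsFactors = FALSE)
  })
  structure(list(frame_id = doc$frame_id %||% NA,
                 features = do.call(rbind, rows)),
            class = "pharmacophore_model")
}

#' pEC50 from a molar EC50
#'
#' `-log10(EC50)`, the standard potency scale used to annotate screening
#' hit tables; a 2.0 nM EC50 gives 8.700 to three decimals.
#'
#' @param ec50 Half-maximal effective concentration in mol/L (> 0).
#' @return pEC50 (dimensionless).
#' @export
pec50_from_ec50 <- function(ec50) {
  if (any(!is.finite(ec50)) || any(ec50 <= 0))
    stop("ec50 must be a positive molar concentration")
  -log10(ec50)
}
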