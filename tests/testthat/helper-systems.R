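# Tiny hand-built systems with fully controlled coordinates, used by the
# unit tests. All built in code; no stored fixtures.

# A minimal protein atom table: `n_res` ALA residues on chain `chain`,
# C-alpha positions given per residue (list of length-3 vectors), plus a
# CB offset so residues have more than one heavy atom.
toy_protein <- function(ca_positions, chain = "A", resno_start = 1L) {
  rows <- list()
  for (i in seq_along(ca_positions)) {
    ca <- ca_positions[[i]]
    rows[[i]] <- data.frame(
      eleno = 0L, elety = c("N", "CA", "CB"), elesy = c("N", "C", "C"),
      resid = "ALA", resno = resno_start + i - 1L, insert = "",
      chain = chain,
      x = ca[1L] + c(-1.2, 0, 0.8), y = ca[2L] + c(0.4, 0, 1.1),
      z = ca[3L] + c(0, 0, 0.6), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$eleno <- seq_len(nrow(out))
  out
}

toy_reference <- function(atoms) {
  structure(list(atoms = atoms, calpha = which(atoms$elety == "CA"),
                 path = NA_character_), class = "probe_ref")
}

# One isopropanol copy whose four heavy atoms sit at the given centroid
# with a compact fixed geometry; optionally an exact position for O2.
ipro_atoms <- function(resno = 1L, chain = "X") {
  data.frame(eleno = 0L, elety = c("C1", "C2", "C3", "O2", "HO2"),
             elesy = c("C", "C", "C", "O", "H"), resid = "IPRO",
             resno = resno, insert = "", chain = chain,
             x = 0, y = 0, z = 0, stringsAsFactors = FALSE)
}

ipro_coords <- function(centroid = c(0, 0, 0)) {
  base <- rbind(c(-1.26, -0.77, 0), c(0, 0, 0), c(1.26, -0.77, 0),
                c(0, 0.70, 1.20), c(0, 1.62, 1.05))
  heavy_cen <- colMeans(base[1:4, ])
  sweep(base, 2L, centroid - heavy_cen, "+")
}

# Assemble an ensemble from a protein atom table and a list of frames,
# each frame a list of probe coordinate matrices (one per instance).
toy_ensemble <- function(prot_atoms, probe_atoms_list, frames,
                         protein_coords = NULL, superposed = TRUE) {
  atoms <- do.call(rbind, c(list(prot_atoms), probe_atoms_list))
  atoms$eleno <- seq_len(nrow(atoms))
  rownames(atoms) <- NULL
  pc <- protein_coords %||% cbind(prot_atoms$x, prot_atoms$y, prot_atoms$z)
  xyz <- t(vapply(frames, function(fr) {
    cm <- rbind(pc, do.call(rbind, fr))
    as.numeric(t(cm))
  }, numeric(3L * nrow(atoms))))
  ens <- trajectory_ensemble(atoms, xyz)
  ens$superposed <- superposed
  ens
}

# Hot-spot table stub for tests that need hand-placed hot spots.
hotspot_table <- function(centers, probe_name = "isopropanol",
                          counts = 100, delta_g = -2) {
  centers <- matrix(centers, ncol = 3L)
  data.frame(hotspot_id = sprintf("%s_%d", probe_name, seq_len(nrow(centers))),
             probe_name = probe_name, x = centers[, 1L], y = centers[, 2L],
             z = centers[, 3L], occupancy_count = rep_len(counts, nrow(centers)),
             delta_g = rep_len(delta_g, nrow(centers)),
             stringsAsFactors = FALSE)
}

# Wrap a hot-spot table as a single clustered site.
as_sites <- function(hs, site_id = 1L) {
  hs$site_id <- site_id
  structure(list(sites = data.frame(site_id = site_id, rank = 1L,
                                    n_hotspots = nrow(hs),
                                    probe_composition = "",
                                    site_score = sum(hs$delta_g)),
                 hotspots = hs, params = grid_params()),
            class = "druggable_sites")
}
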