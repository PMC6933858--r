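# Tabular and volumetric output writers. All writers use fixed formats
# and "\n" line endings so repeated runs are byte-identical.

write_tsv <- function(df, file) {
  con <- file(file, "wb")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  invisible(file)
}

#' Write hot spots as a pseudo-atom PDB
#'
#' One pseudo-atom per hot spot, occupancy count in the B-factor column —
#' the conventional display format for druggability grids (color by
#' B-factor in a molecular viewer). Pseudo-atoms are named after the
#' probe type's residue name.
#'
#' @param hotspots Hot-spot table from [detect_hotspots()] (one probe
#'   type or several).
#' @param file Output path.
#' @param specs Probe specs, used to label pseudo-atoms by residue name.
#' @return `file`, invisibly.
#' @export
write_hotspot_pdb <- function(hotspots, file, specs = default_probe_specs()) {
  n <- nrow(hotspots)
  resname <- vapply(hotspots$probe_name, function(p)
    if (!is.null(specs[[p]])) specs[[p]]$resname else toupper(substr(p, 1, 4)),
    "")
  atoms <- data.frame(eleno = seq_len(n), elety = "DUM", elesy = "C",
                      resid = resname, resno = seq_len(n), insert = "",
                      chain = "H", x = hotspots$x, y = hotspots$y,
                      z = hotspots$z, stringsAsFactors = FALSE)
  write_pdb_file(atoms, file, b = pmin(hotspots$occupancy_count, 9999.99))
}

#' Write the druggable-site summary table
#'
#' TSV with one row per site: id, rank, number of hot spots, probe
#' composition and site score.
#'
#' @param sites A `druggable_sites` object.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_site_table <- function(sites, file) {
  write_tsv(sites$sites, file)
}

#' Write a binding-score profile as TSV
#'
#' Columns `chain`, `resno`, `resid`, `score` — the per-residue curve of
#' the probe's binding profile, ready for plotting.
#'
#' @param profile A [binding_score_profile()] result.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_profile_tsv <- function(profile, file) {
  df <- as.data.frame(profile)[, c("chain", "resno", "resid", "score")]
  df$score <- sprintf("%.6f", df$score)
  write_tsv(df, file)
}

#' Write the interaction-ranking table as TSV
#'
#' Mirrors the ranked residue-probe table: chain, residue, probe, count,
#' frequency, rank and top-set flag.
#'
#' @param ranking An `interaction_ranking` object.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_rank_table <- function(ranking, file) {
  df <- ranking$table
  df$frequency <- sprintf("%.6f", df$frequency)
  write_tsv(df, file)
}

#' Export one probe type's occupancy grid as an OpenDX scalar field
#'
#' Dense regular-grid export of the voxel counts over the grid bounding
#' box, loadable by VMD/PyMOL for isosurface display.
#'
#' @param grid An `occupancy_grid`.
#' @param probe_name Probe type to export.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_grid_dx <- function(grid, probe_name, file) {
  d <- grid$counts[[probe_name]]
  if (is.null(d)) stop("no occupancy data for probe: ", probe_name)
  lo <- grid$bbox_lo; hi <- grid$bbox_hi
  dims <- hi - lo + 1L
  edge <- grid$edge_length
  arr <- array(0, dims)
  if (nrow(d))
    arr[cbind(d$ix - lo[1L] + 1L, d$iy - lo[2L] + 1L, d$iz - lo[3L] + 1L)] <-
      d$count
  con <- file(file, "wb")
  on.exit(close(con))
  origin <- (lo + 0.5) * edge
  hdr <- c(sprintf("object 1 class gridpositions counts %d %d %d",
                   dims[1L], dims[2L], dims[3L]),
           sprintf("origin %.4f %.4f %.4f", origin[1L], origin[2L], origin[3L]),
           sprintf("delta %.4f 0 0", edge),
           sprintf("delta 0 %.4f 0", edge),
           sprintf("delta 0 0 %.4f", edge),
           sprintf("object 2 class gridconnections counts %d %d %d",
                   dims[1L], dims[2L], dims[3L]),
           sprintf("object 3 class array type double rank 0 items %d data follows",
                   prod(dims)))
  # DX stores z fastest-varying: flatten accordingly
  vals <- as.numeric(aperm(arr, c(3L, 2L, 1L)))
  pad <- (3L - length(vals) %% 3L) %% 3L
  chunks <- matrix(c(sprintf("%.1f", vals), rep("", pad)), nrow = 3L)
  body <- apply(chunks, 2L, function(v) trimws(paste(v, collapse = " ")))
  writeLines(c(hdr, body), con, sep = "\n")
  invisible(file)
}
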