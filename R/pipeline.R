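# End-to-end orchestration of the six-stage workflow:
# hotspots -> profile -> siteselect -> rank -> snapshots -> pharmacophore.

#' Pipeline run configuration
#'
#' Collects every tunable of the workflow with the standard defaults:
#' grid parameters per [grid_params()], 4 A residue contact cutoff,
#' 500 1/A^2 high-affinity threshold, 8 A site-residue selection cutoff,
#' 1.5 A hot-spot assignment cutoff and 0.10 frequency cutoff.
#'
#' @param reference Path to the reference PDB.
#' @param trajectory Path to a multi-model PDB or DCD trajectory.
#' @param topology Optional PSF/PDB topology (needed for DCD input).
#' @param out_dir Output directory.
#' @param grid A [grid_params()] object.
#' @param contact_cutoff Residue-probe heavy-atom contact cutoff (A).
#' @param score_threshold High-affinity binding-score threshold (1/A^2).
#' @param site_cutoff Residue-to-hot-spot selection cutoff (A).
#' @param hotspot_assign_cutoff Probe-to-hot-spot assignment cutoff (A).
#' @param frequency_cutoff Top-set frequency cutoff (inclusive).
#' @param features Optional feature-kind subset for the pharmacophore.
#' @param site_id Site analyzed in Steps 3-5 (default: the top-ranked
#'   site).
#' @param stride Frame stride for trajectory loading.
#' @param max_snapshots Cap on extracted co-occurrence snapshots
#'   (`Inf` = all).
#' @param stop_after Run only through the named stage: one of
#'   `"hotspots"`, `"profile"`, `"siteselect"`, `"rank"`, `"snapshots"`,
#'   `"pharmacophore"` (default: the full workflow).
#' @param specs Probe specs.
#' @param verbose Log stage progress and every cutoff to the console.
#' @return List of class `run_config`.
#' @export
run_config <- function(reference, trajectory, topology = NULL,
                       out_dir = "probemap_out", grid = grid_params(),
                       contact_cutoff = 4.0, score_threshold = 500,
                       site_cutoff = 8.0, hotspot_assign_cutoff = 1.5,
                       frequency_cutoff = 0.10, features = NULL,
                       site_id = NULL, stride = 1L, max_snapshots = Inf,
                       stop_after = "pharmacophore",
                       specs = default_probe_specs(), verbose = TRUE) {
  stop_after <- match.arg(stop_after,
                          c("pharmacophore", "hotspots", "profile",
                            "siteselect", "rank", "snapshots"))
  structure(list(reference = reference, trajectory = trajectory,
                 topology = topology, out_dir = out_dir, grid = grid,
                 contact_cutoff = contact_cutoff,
                 score_threshold = score_threshold,
                 site_cutoff = site_cutoff,
                 hotspot_assign_cutoff = hotspot_assign_cutoff,
                 frequency_cutoff = frequency_cutoff, features = features,
                 site_id = site_id, stride = stride,
                 max_snapshots = max_snapshots, stop_after = stop_after,
                 specs = specs,
                 verbose = verbose),
            class = "run_config")
}

#' Run the full hot-spot-to-pharmacophore workflow
#'
#' Executes, in order: trajectory loading and superposition; grid
#' occupancy, hot-spot detection and site clustering; per-residue
#' binding-score profiles and high-affinity calls; site-residue
#' selection; interaction-frequency ranking; co-occurrence snapshot
#' extraction; pharmacophore construction and Pharmit JSON export. Every
#' intermediate artifact is written under `out_dir` and a
#' machine-readable provenance record (package version, parameters,
#' input digests) is saved. A run with no druggable sites returns
#' `status = "no-sites"` after writing the hot-spot outputs; any stage
#' failure aborts with the stage name, leaving earlier outputs in place.
#'
#' @param config A [run_config()].
#' @return List with `status` (`"ok"` or `"no-sites"`), the site table,
#'   ranking, co-occurrence frames, mean conformer RMSD and output
#'   paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_msg <- function(...) if (isTRUE(config$verbose)) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_stage(name, conditionMessage(e)))
  }
  log_msg("parameters: grid edge %.2f A, contact %.2f A, merge %.2f A, site link %.2f A, min hotspots %d, energy cutoff %.2f kcal/mol, score threshold %.0f 1/A^2, site cutoff %.1f A, assign cutoff %.1f A, frequency cutoff %.2f",
          config$grid$edge_length, config$grid$protein_contact_cutoff,
          config$grid$merge_distance, config$grid$site_link_distance,
          config$grid$min_hotspots_per_site,
          config$grid$hotspot_energy_cutoff, config$score_threshold,
          config$site_cutoff, config$hotspot_assign_cutoff,
          config$frequency_cutoff)

  reference <- stage("load-reference", load_reference(config$reference))
  ensemble <- stage("load-trajectory",
                    load_trajectory(config$topology %||% config$trajectory,
                                    coords = if (!is.null(config$topology))
                                      config$trajectory else NULL,
                                    specs = config$specs,
                                    stride = config$stride))
  ensemble <- stage("superpose", superpose(ensemble, reference))
  log_msg("loaded %d frames, %d protein atoms, %d probe instances",
          ensemble$n_frames, length(ensemble$protein),
          length(ensemble$instances))

  grid <- stage("hotspots", accumulate_occupancy(ensemble, config$grid))
  hotspots <- stage("hotspots", detect_hotspots(grid, config$grid))
  sites <- stage("hotspots", cluster_sites(hotspots, config$grid))
  for (p in names(grid$counts)) {
    hp <- hotspots[hotspots$probe_name == p, , drop = FALSE]
    if (nrow(hp))
      write_hotspot_pdb(hp, file.path(out, sprintf("hotspots_%s.pdb", p)),
                        config$specs)
  }
  write_site_table(sites, file.path(out, "sites.tsv"))
  write_provenance(config, reference, ensemble, file.path(out, "provenance.json"))
  log_msg("detected %d hot spots, %d druggable sites", nrow(hotspots),
          nrow(sites$sites))
  if (nrow(sites$sites) == 0L) {
    status_path <- file.path(out, "status.json")
    jsonlite::write_json(list(status = "no-sites"), status_path,
                         auto_unbox = TRUE)
    return(invisible(list(status = "no-sites", sites = sites,
                          out_dir = out)))
  }
  if (config$stop_after == "hotspots")
    return(invisible(list(status = "ok", sites = sites, out_dir = out)))
  site_id <- config$site_id %||% sites$sites$site_id[sites$sites$rank == 1L]

  # Steps 2-3: profiles, high-affinity calls, site selection
  chains <- sort(unique(ensemble$atoms$chain[ensemble$protein]))
  present <- unique(vapply(ensemble$instances, `[[`, "", "probe_name"))
  calls <- list()
  profiles <- list()
  stage("profile", for (p in present) for (ch in chains) {
    pr <- binding_score_profile(ensemble, p, ch, config$contact_cutoff)
    profiles[[paste(p, ch, sep = "_")]] <- pr
    write_profile_tsv(pr, file.path(out, sprintf("profile_%s_%s.tsv", p, ch)))
    calls[[paste(p, ch, sep = "_")]] <-
      high_affinity_residues(pr, config$score_threshold)
  })
  calls_df <- do.call(rbind, calls)
  rownames(calls_df) <- NULL
  write_tsv(calls_df[, setdiff(names(calls_df), "threshold")],
            file.path(out, "high_affinity.tsv"))
  if (config$stop_after == "profile")
    return(invisible(list(status = "ok", sites = sites, site_id = site_id,
                          profiles = profiles, calls = calls_df,
                          out_dir = out)))
  selected <- stage("siteselect",
                    select_site_residues(calls_df, sites, reference,
                                         site_id, config$site_cutoff))
  write_tsv(selected, file.path(out, "site_residues.tsv"))
  log_msg("site %d: %d high-affinity calls, %d selected at site",
          site_id, nrow(calls_df), nrow(selected))
  if (nrow(selected) == 0L) {
    jsonlite::write_json(list(status = "no-sites",
                              detail = "no high-affinity residues at site"),
                         file.path(out, "status.json"), auto_unbox = TRUE)
    return(invisible(list(status = "no-sites", sites = sites,
                          out_dir = out)))
  }

  if (config$stop_after == "siteselect")
    return(invisible(list(status = "ok", sites = sites, site_id = site_id,
                          profiles = profiles, calls = calls_df,
                          selected = selected, out_dir = out)))

  # Step 4: interaction frequencies and ranking
  records <- stage("rank", lapply(seq_len(nrow(selected)), function(i)
    interaction_frequency(ensemble, selected$chain[i], selected$resno[i],
                          selected$probe_name[i], sites, site_id,
                          insert = selected$insert[i] %||% "",
                          contact_cutoff = config$contact_cutoff,
                          hotspot_assign_cutoff = config$hotspot_assign_cutoff,
                          score = selected$score[i])))
  ranking <- stage("rank", rank_interactions(records, config$frequency_cutoff))
  write_rank_table(ranking, file.path(out, "rank.tsv"))
  log_msg("%d interactions ranked, %d in top set", nrow(ranking$table),
          length(ranking$top))
  if (config$stop_after == "rank")
    return(invisible(list(status = "ok", sites = sites, site_id = site_id,
                          profiles = profiles, calls = calls_df,
                          selected = selected, ranking = ranking,
                          out_dir = out)))

  # Step 5: co-occurrence snapshots and pharmacophore models
  frames <- stage("snapshots",
                  if (length(ranking$top)) find_cooccurrence_frames(ranking$top)
                  else integer(0))
  mean_rmsd <- if (length(frames) >= 2L)
    conformer_rmsd(ensemble, frames) else NA_real_
  n_take <- min(length(frames), config$max_snapshots)
  snap_dir <- file.path(out, "snapshots")
  pm_dir <- file.path(out, "pharmacophores")
  models <- list()
  index <- list()
  stage("pharmacophore", for (fid in frames[seq_len(n_take)]) {
    snap <- extract_snapshot(ensemble, fid, ranking$top, snap_dir,
                             contact_cutoff = config$contact_cutoff,
                             hotspot_assign_cutoff = config$hotspot_assign_cutoff)
    n_feat <- NA_integer_
    if (config$stop_after == "pharmacophore") {
      model <- build_pharmacophore(snap, config$specs, config$features)
      dir.create(pm_dir, recursive = TRUE, showWarnings = FALSE)
      write_pharmit_json(model, file.path(pm_dir, sprintf("frame_%d.json", fid)))
      models[[as.character(fid)]] <- model
      n_feat <- nrow(model$features)
    }
    index[[length(index) + 1L]] <- data.frame(
      frame_id = fid, n_features = n_feat,
      mean_rmsd_to_selected = if (is.na(mean_rmsd)) NA_real_ else mean_rmsd)
  })
  if (length(index))
    write_tsv(do.call(rbind, index), file.path(out, "pm_index.tsv"))
  log_msg("%d co-occurrence frames (mean conformer RMSD %.2f A), %d PMs written",
          length(frames), mean_rmsd, length(models))
  jsonlite::write_json(list(status = "ok", n_sites = nrow(sites$sites),
                            site_id = site_id,
                            n_cooccurrence_frames = length(frames)),
                       file.path(out, "status.json"), auto_unbox = TRUE)
  invisible(list(status = "ok", sites = sites, site_id = site_id,
                 profiles = profiles, calls = calls_df, selected = selected,
                 ranking = ranking, frames = frames,
                 mean_conformer_rmsd = mean_rmsd, models = models,
                 out_dir = out))
}

# Machine-readable provenance: versions, parameters, input digests.
# Deliberately timestamp-free so reruns are byte-identical.
write_provenance <- function(config, reference, ensemble, path) {
  digest <- function(f) if (!is.null(f) && is.character(f) && file.exists(f))
    unname(tools::md5sum(f)) else NA_character_
  doc <- list(
    package = "probemap",
    version = as.character(utils::packageVersion("probemap")),
    inputs = list(reference = config$reference,
                  reference_md5 = digest(config$reference),
                  trajectory = config$trajectory,
                  trajectory_md5 = digest(config$trajectory),
                  topology = config$topology,
                  topology_md5 = digest(config$topology)),
    n_frames = ensemble$n_frames,
    parameters = list(
      edge_length = config$grid$edge_length,
      protein_contact_cutoff = config$grid$protein_contact_cutoff,
      merge_distance = config$grid$merge_distance,
      site_link_distance = config$grid$site_link_distance,
      min_hotspots_per_site = config$grid$min_hotspots_per_site,
      hotspot_energy_cutoff = config$grid$hotspot_energy_cutoff,
      max_combination_size = config$grid$max_combination_size,
      temperature = config$grid$temperature,
      contact_cutoff = config$contact_cutoff,
      score_threshold = config$score_threshold,
      site_cutoff = config$site_cutoff,
      hotspot_assign_cutoff = config$hotspot_assign_cutoff,
      frequency_cutoff = config$frequency_cutoff,
      stride = config$stride))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
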