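# Step 1: grid occupancy analysis of the superposed trajectory, hot-spot
# detection and clustering into ranked druggable sites.

GAS_CONSTANT <- 0.0019872  # kcal/mol/K

#' Grid-analysis parameters
#'
#' Bundles every Step-1 cutoff. Defaults are the standard druggability-
#' analysis settings: 0.5 A voxels, probes counted only when a heavy atom
#' is within 2.5 A of a protein heavy atom, high-occupancy voxels merged
#' into hot spots below 5.5 A, sites formed from clusters of at least six
#' hot spots, and a -1.0 kcal/mol inverse-Boltzmann cutoff for calling a
#' voxel high-occupancy. The 5.5 A figure is applied both to voxel
#' merging and to hot-spot/site linkage; the two knobs are independent so
#' either reading of that convention is reachable.
#'
#' @param edge_length Voxel edge (A).
#' @param protein_contact_cutoff Probe-protein heavy-atom contact cutoff
#'   (A) for a probe copy to be counted at all.
#' @param merge_distance Voxel-to-hot-spot merge distance (A), strict `<`.
#' @param site_link_distance Single-linkage distance for clustering hot
#'   spots into sites (A), strict `<`; defaults to `merge_distance`.
#' @param min_hotspots_per_site Minimum cluster size to call a site.
#' @param hotspot_energy_cutoff Voxel free-energy cutoff (kcal/mol); only
#'   voxels at or below it become hot-spot candidates.
#' @param max_combination_size Hot-spot budget for the site score (about a
#'   drug fragment's heavy-atom count).
#' @param temperature Simulation temperature (K); 300 K gives
#'   RT = 0.596 kcal/mol.
#' @return A list of class `grid_params`.
#' @export
grid_params <- function(edge_length = 0.5, protein_contact_cutoff = 2.5,
                        merge_distance = 5.5,
                        site_link_distance = merge_distance,
                        min_hotspots_per_site = 6L,
                        hotspot_energy_cutoff = -1.0,
                        max_combination_size = 7L,
                        temperature = 300) {
  stopifnot(edge_length > 0, protein_contact_cutoff > 0, merge_distance > 0,
            site_link_distance > 0, min_hotspots_per_site >= 1L,
            max_combination_size >= 1L, temperature > 0)
  structure(list(edge_length = edge_length,
                 protein_contact_cutoff = protein_contact_cutoff,
                 merge_distance = merge_distance,
                 site_link_distance = site_link_distance,
                 min_hotspots_per_site = as.integer(min_hotspots_per_site),
                 hotspot_energy_cutoff = hotspot_energy_cutoff,
                 max_combination_size = as.integer(max_combination_size),
                 temperature = temperature),
            class = "grid_params")
}

#' Accumulate per-probe-type voxel occupancy over a trajectory
#'
#' For every frame and probe copy, the copy is counted if and only if at
#' least one of its heavy atoms lies within `protein_contact_cutoff` of a
#' protein heavy atom; the count goes to the single voxel containing the
#' copy's heavy-atom centroid. Voxels are addressed on an absolute lattice
#' (`floor(coordinate / edge_length)` in the reference frame, origin
#' snapped to lattice multiples), so voxel identities are reproducible
#' across runs and the grid extends automatically to wherever probes go —
#' no centroid is ever dropped. Voxels containing a protein heavy atom in
#' any frame are recorded too; they define the accessible volume used as
#' the uniform background for the inverse-Boltzmann energies.
#'
#' @param ensemble A superposed `probe_traj`.
#' @param params A [grid_params()] object.
#' @return An object of class `occupancy_grid`: per-probe voxel count
#'   tables, per-probe totals, the protein-occupied voxel set, the lattice
#'   bounding box and the accessible voxel count.
#' @export
accumulate_occupancy <- function(ensemble, params = grid_params()) {
  stopifnot(inherits(ensemble, "probe_traj"))
  if (!isTRUE(ensemble$superposed))
    stop("ensemble must be superposed before grid analysis")
  edge <- params$edge_length
  cut2 <- params$protein_contact_cutoff^2
  at <- ensemble$atoms
  prot_heavy <- ensemble$protein[is_heavy(at$elesy[ensemble$protein])]
  inst <- ensemble$instances
  probe_names <- unique(vapply(inst, `[[`, "", "probe_name"))
  vox <- lapply(probe_names, function(p) vector("list", ensemble$n_frames))
  names(vox) <- probe_names
  prot_vox <- vector("list", ensemble$n_frames)
  for (k in seq_len(ensemble$n_frames)) {
    cm <- frame_coords(ensemble$xyz, k)
    pm <- cm[prot_heavy, , drop = FALSE]
    prot_vox[[k]] <- unique(floor(pm / edge))
    for (ins in inst) {
      hm <- cm[ins$heavy, , drop = FALSE]
      if (min(dist2_mat(hm, pm)) <= cut2) {
        cen <- colMeans(hm)
        vox[[ins$probe_name]][[k]] <-
          rbind(vox[[ins$probe_name]][[k]], floor(cen / edge))
      }
    }
  }
  counts <- lapply(vox, function(vl) {
    m <- do.call(rbind, vl)
    if (is.null(m) || nrow(m) == 0L)
      return(data.frame(ix = integer(0), iy = integer(0), iz = integer(0),
                        count = integer(0)))
    key <- paste(m[, 1L], m[, 2L], m[, 3L])
    tab <- table(key)
    first <- m[!duplicated(key), , drop = FALSE]
    rownames(first) <- key[!duplicated(key)]
    ord <- order(first[, 1L], first[, 2L], first[, 3L])
    first <- first[ord, , drop = FALSE]
    data.frame(ix = as.integer(first[, 1L]), iy = as.integer(first[, 2L]),
               iz = as.integer(first[, 3L]),
               count = as.integer(tab[rownames(first)]),
               row.names = NULL)
  })
  pv <- unique(do.call(rbind, prot_vox))
  all_vox <- rbind(pv, as.matrix(do.call(rbind, lapply(counts, function(d)
    cbind(d$ix, d$iy, d$iz)))))
  lo <- apply(all_vox, 2L, min)
  hi <- apply(all_vox, 2L, max)
  n_bbox <- prod(hi - lo + 1)
  in_bbox <- pv[, 1L] >= lo[1L] & pv[, 1L] <= hi[1L] &
             pv[, 2L] >= lo[2L] & pv[, 2L] <= hi[2L] &
             pv[, 3L] >= lo[3L] & pv[, 3L] <= hi[3L]
  n_prot <- sum(in_bbox)
  structure(list(edge_length = edge, n_frames = ensemble$n_frames,
                 counts = counts,
                 totals = vapply(counts, function(d) sum(d$count), 0),
                 protein_voxels = pv, bbox_lo = lo, bbox_hi = hi,
                 n_voxels_bbox = n_bbox,
                 n_accessible = max(n_bbox - n_prot, 1),
                 params = params),
            class = "occupancy_grid")
}

#' @export
print.occupancy_grid <- function(x, ...) {
  cat(sprintf("Occupancy grid: %.2f A voxels, %d frames, %g accessible voxels\n",
              x$edge_length, x$n_frames, x$n_accessible))
  for (p in names(x$counts))
    cat(sprintf("  %-16s %6d occupied voxels, %8d probe-frames\n",
                p, nrow(x$counts[[p]]), as.integer(x$totals[[p]])))
  invisible(x)
}

#' Inverse-Boltzmann voxel free energy
#'
#' Converts an observed voxel count into a binding free energy relative to
#' a uniform background, `dG = -RT log(count / expected_count)`. A count
#' equal to the expected (bulk) count gives 0; enrichment gives negative
#' energies. A zero count returns `Inf` so empty voxels can never become
#' hot spots.
#'
#' @param count Observed voxel count (non-negative).
#' @param expected_count Expected count under a uniform distribution over
#'   the accessible volume (> 0).
#' @param temperature Temperature in K.
#' @return Free energy in kcal/mol.
#' @export
voxel_free_energy <- function(count, expected_count, temperature = 300) {
  stopifnot(all(expected_count > 0), temperature > 0)
  dg <- -GAS_CONSTANT * temperature * log(count / expected_count)
  dg[count == 0] <- Inf
  dg
}

# Expected per-voxel count for one probe type: its qualifying probe-frames
# spread uniformly over the accessible voxels of the grid bounding box.
expected_voxel_count <- function(grid, probe_name) {
  grid$totals[[probe_name]] / grid$n_accessible
}

#' Detect per-probe hot spots from an occupancy grid
#'
#' Voxels whose inverse-Boltzmann energy is at or below
#' `hotspot_energy_cutoff` are hot-spot candidates. Candidates are visited
#' in descending occupancy (ties broken by lexicographic voxel index) and
#' greedily merged: each joins the existing hot spot with the nearest
#' current center closer than `merge_distance`, otherwise it seeds a new
#' hot spot. A hot spot's center is the occupancy-weighted centroid of its
#' member voxel centers; its energy is recomputed from the summed count.
#'
#' @param grid An `occupancy_grid`.
#' @param params A [grid_params()] object (defaults to the grid's own).
#' @return Data frame with one row per hot spot: `hotspot_id`,
#'   `probe_name`, `x`, `y`, `z`, `occupancy_count`, `delta_g`.
#' @export
detect_hotspots <- function(grid, params = grid$params) {
  stopifnot(inherits(grid, "occupancy_grid"))
  edge <- grid$edge_length
  out <- list()
  for (p in names(grid$counts)) {
    d <- grid$counts[[p]]
    if (nrow(d) == 0L) next
    exp_count <- expected_voxel_count(grid, p)
    dg <- voxel_free_energy(d$count, exp_count, params$temperature)
    cand <- d[dg <= params$hotspot_energy_cutoff, , drop = FALSE]
    if (nrow(cand) == 0L) next
    cand <- cand[order(-cand$count, cand$ix, cand$iy, cand$iz), , drop = FALSE]
    centers <- matrix(numeric(0), 0L, 3L)
    sums <- numeric(0)      # occupancy-weighted coordinate sums
    counts <- numeric(0)
    members <- list()
    wsum <- matrix(numeric(0), 0L, 3L)
    for (i in seq_len(nrow(cand))) {
      vc <- (c(cand$ix[i], cand$iy[i], cand$iz[i]) + 0.5) * edge
      w <- cand$count[i]
      j <- NA_integer_
      if (nrow(centers) > 0L) {
        dd <- sqrt(rowSums(sweep(centers, 2L, vc)^2))
        jj <- which.min(dd)
        if (dd[jj] < params$merge_distance) j <- jj
      }
      if (is.na(j)) {
        centers <- rbind(centers, vc)
        wsum <- rbind(wsum, vc * w)
        counts <- c(counts, w)
      } else {
        wsum[j, ] <- wsum[j, ] + vc * w
        counts[j] <- counts[j] + w
        centers[j, ] <- wsum[j, ] / counts[j]
      }
    }
    out[[p]] <- data.frame(
      hotspot_id = sprintf("%s_%d", p, seq_along(counts)),
      probe_name = p,
      x = centers[, 1L], y = centers[, 2L], z = centers[, 3L],
      occupancy_count = counts,
      delta_g = voxel_free_energy(counts, exp_count, params$temperature),
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(hotspot_id = character(0), probe_name = character(0),
                      x = numeric(0), y = numeric(0), z = numeric(0),
                      occupancy_count = numeric(0), delta_g = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Connected components (single linkage, strict `<`) over point rows.
linkage_components <- function(xyz, cutoff) {
  n <- nrow(xyz)
  if (n == 0L) return(integer(0))
  d2 <- dist2_mat(xyz, xyz)
  adj <- d2 < cutoff^2
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] > 0L) next
    cur <- cur + 1L
    queue <- i
    comp[i] <- cur
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Cluster hot spots into ranked druggable sites
#'
#' Pools hot spots of all probe types and single-links their centers at
#' `site_link_distance`. Clusters with at least `min_hotspots_per_site`
#' members become druggable sites; smaller clusters are discarded. Each
#' site is scored with [score_site()] and sites are ranked by ascending
#' score (rank 1 = most favorable).
#'
#' @param hotspots Hot-spot table from [detect_hotspots()].
#' @param params A [grid_params()] object.
#' @return An object of class `druggable_sites`: `sites` (one row per
#'   site: `site_id`, `rank`, `n_hotspots`, `probe_composition`,
#'   `site_score`) and `hotspots` (the input table with a `site_id`
#'   column, `NA` for unclustered hot spots).
#' @export
cluster_sites <- function(hotspots, params = grid_params()) {
  hs <- hotspots
  hs$site_id <- rep(NA_integer_, nrow(hs))
  empty <- data.frame(site_id = integer(0), rank = integer(0),
                      n_hotspots = integer(0),
                      probe_composition = character(0),
                      site_score = numeric(0))
  if (nrow(hs) == 0L)
    return(structure(list(sites = empty, hotspots = hs, params = params),
                     class = "druggable_sites"))
  comp <- linkage_components(cbind(hs$x, hs$y, hs$z),
                             params$site_link_distance)
  keep <- as.integer(names(which(table(comp) >= params$min_hotspots_per_site)))
  if (!length(keep))
    return(structure(list(sites = empty, hotspots = hs, params = params),
                     class = "druggable_sites"))
  scores <- vapply(keep, function(cl)
    score_site(hs[comp == cl, , drop = FALSE], params), 0)
  ord <- order(scores, keep)   # ascending score; stable on ties
  sites <- data.frame(site_id = seq_along(keep), rank = seq_along(keep),
                      n_hotspots = vapply(keep[ord], function(cl)
                        sum(comp == cl), 0L),
                      probe_composition = vapply(keep[ord], function(cl) {
                        tb <- table(hs$probe_name[comp == cl])
                        paste(sprintf("%s:%d", names(tb), tb), collapse = ",")
                      }, ""),
                      site_score = scores[ord],
                      stringsAsFactors = FALSE)
  for (i in seq_along(keep))
    hs$site_id[comp == keep[ord[i]]] <- i
  structure(list(sites = sites, hotspots = hs, params = params),
            class = "druggable_sites")
}

#' @export
print.druggable_sites <- function(x, ...) {
  cat(sprintf("Druggable sites: %d (from %d hot spots)\n",
              nrow(x$sites), nrow(x$hotspots)))
  if (nrow(x$sites)) print(x$sites, row.names = FALSE)
  invisible(x)
}

#' Score a druggable site
#'
#' An energy-like site score: the sum of hot-spot free energies over the
#' best (most negative) connected subset of at most
#' `max_combination_size` hot spots, where two hot spots are connected
#' when their centers are within `merge_distance`. The size cap of 7
#' approximates a drug fragment's heavy-atom budget. This scoring is this
#' package's own convention for combining hot spots into a drug-like
#' footprint; it is deterministic given the site.
#'
#' @param site_hotspots Hot-spot table rows belonging to one site.
#' @param params A [grid_params()] object.
#' @return Site score in kcal/mol (sum of member `delta_g`, so negative).
#' @export
score_site <- function(site_hotspots, params = grid_params()) {
  w <- site_hotspots$delta_g
  n <- length(w)
  if (n == 0L) return(0)
  xyz <- cbind(site_hotspots$x, site_hotspots$y, site_hotspots$z)
  adj <- dist2_mat(xyz, xyz) < params$merge_distance^2
  diag(adj) <- FALSE
  neigh <- lapply(seq_len(n), function(i) which(adj[i, ]))
  best <- Inf
  max_size <- params$max_combination_size
  extend <- function(sub, ext, v, nsub) {
    s <- sum(w[sub])
    if (s < best) best <<- s
    if (length(sub) == max_size) return()
    while (length(ext)) {
      wn <- ext[[1L]]
      ext <- ext[-1L]
      add <- neigh[[wn]]
      add <- add[add > v & !(add %in% nsub)]
      extend(c(sub, wn), union(ext, add), v, union(nsub, c(wn, neigh[[wn]])))
    }
  }
  for (v in seq_len(n)) {
    e0 <- neigh[[v]][neigh[[v]] > v]
    extend(v, e0, v, union(v, neigh[[v]]))
  }
  best
}
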