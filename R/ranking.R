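# Step 4: frequency of occurrence of residue-probe interactions at a
# druggable site, and their ranking.

#' Frequency of a residue-probe interaction at a site
#'
#' Counts the snapshots in which a probe copy of the given type
#' simultaneously (a) has at least one *heavy* atom within
#' `contact_cutoff` (4 A) of a heavy atom of the residue and (b) occupies
#' a site hot spot of its own type, i.e. *any* of its atoms — hydrogens
#' included — lies within `hotspot_assign_cutoff` (1.5 A) of a hot-spot
#' center. The heavy-atom/any-atom asymmetry between the two criteria is
#' deliberate: contacts are a heavy-atom notion while hot-spot assignment
#' uses the whole probe. A frame counts at most once however many copies
#' qualify; the frequency is `count / n_frames` exactly.
#'
#' @param ensemble A superposed `probe_traj`.
#' @param chain,resno,insert Residue identity (source-PDB numbering).
#' @param probe_name Probe type.
#' @param sites A `druggable_sites` object.
#' @param site_id Site whose hot spots are used.
#' @param contact_cutoff Heavy-atom residue contact cutoff (A), inclusive.
#' @param hotspot_assign_cutoff Probe-atom to hot-spot-center cutoff (A),
#'   inclusive.
#' @param score Optional binding score `s(p, i)` carried along for
#'   tie-breaking in [rank_interactions()].
#' @return Object of class `interaction_record`: residue and probe
#'   identity, the set of qualifying frame indices, `count`, `frequency`,
#'   the contributing hot-spot ids, and the best (closest-contact) probe
#'   instance per qualifying frame.
#' @export
interaction_frequency <- function(ensemble, chain, resno, probe_name,
                                  sites, site_id = 1L, insert = "",
                                  contact_cutoff = 4.0,
                                  hotspot_assign_cutoff = 1.5,
                                  score = NA_real_) {
  stopifnot(inherits(ensemble, "probe_traj"))
  if (!isTRUE(ensemble$superposed)) stop("ensemble must be superposed")
  hs <- sites$hotspots
  hs <- hs[!is.na(hs$site_id) & hs$site_id == site_id &
             hs$probe_name == probe_name, , drop = FALSE]
  if (!nrow(hs))
    stop("site ", site_id, " has no hot spots of probe type ", probe_name)
  centers <- cbind(hs$x, hs$y, hs$z)
  at <- ensemble$atoms
  prot <- ensemble$protein
  ra <- prot[at$chain[prot] == chain & at$resno[prot] == resno &
               (at$insert[prot] == insert) & is_heavy(at$elesy[prot])]
  if (!length(ra)) stop("residue not found: ", chain, resno, insert)
  resname <- at$resid[ra[1L]]
  inst <- Filter(function(i) i$probe_name == probe_name, ensemble$instances)
  if (!length(inst)) stop("no probe instances of type: ", probe_name)
  ccut2 <- contact_cutoff^2
  hcut2 <- hotspot_assign_cutoff^2
  qualifying <- integer(0)
  best_inst <- integer(0)
  hot_used <- logical(nrow(hs))
  for (k in seq_len(ensemble$n_frames)) {
    cm <- frame_coords(ensemble$xyz, k)
    rc <- cm[ra, , drop = FALSE]
    best_d2 <- Inf
    best_id <- NA_integer_
    for (ins in inst) {
      d2c <- dist2_mat(cm[ins$heavy, , drop = FALSE], rc)
      if (min(d2c) > ccut2) next
      d2h <- dist2_mat(cm[ins$atoms, , drop = FALSE], centers)
      if (min(d2h) > hcut2) next
      hot_used <- hot_used | (apply(d2h <= hcut2, 2L, any))
      if (min(d2c) < best_d2) {
        best_d2 <- min(d2c)
        best_id <- ins$instance_id
      }
    }
    if (!is.na(best_id)) {
      qualifying <- c(qualifying, k)
      best_inst <- c(best_inst, best_id)
    }
  }
  names(best_inst) <- qualifying
  structure(list(chain = chain, resno = resno, insert = insert,
                 resid = resname, probe_name = probe_name,
                 qualifying_frames = qualifying,
                 count = length(qualifying),
                 frequency = length(qualifying) / ensemble$n_frames,
                 n_frames = ensemble$n_frames,
                 hotspot_ids = hs$hotspot_id[hot_used],
                 hotspots = hs,
                 best_instance = best_inst,
                 site_id = site_id, score = score),
            class = "interaction_record")
}

#' @export
print.interaction_record <- function(x, ...) {
  cat(sprintf("%s%d(%s)-%s: %d/%d frames, frequency %.4f\n",
              x$chain, x$resno, x$resid, x$probe_name, x$count,
              x$n_frames, x$frequency))
  invisible(x)
}

#' Rank residue-probe interactions by frequency of occurrence
#'
#' Sorts records by frequency (descending), breaking ties by binding
#' score (descending) and then by (chain, residue number, probe name) so
#' the ordering is reproducible across platforms. The top set contains
#' every record whose frequency is greater than *or equal to* the cutoff
#' (default 0.10).
#'
#' @param records List of [interaction_frequency()] records.
#' @param frequency_cutoff Inclusive top-set cutoff.
#' @return Object of class `interaction_ranking`: `table` (one row per
#'   record with `rank` and `top` flag) and `top` (the top-set records,
#'   in rank order).
#' @export
rank_interactions <- function(records, frequency_cutoff = 0.10) {
  if (!length(records)) {
    tab <- data.frame(chain = character(0), resno = integer(0),
                      resid = character(0), probe_name = character(0),
                      count = integer(0), frequency = numeric(0),
                      score = numeric(0), rank = integer(0), top = logical(0))
    return(structure(list(table = tab, top = list(),
                          frequency_cutoff = frequency_cutoff),
                     class = "interaction_ranking"))
  }
  tab <- do.call(rbind, lapply(records, function(r)
    data.frame(chain = r$chain, resno = r$resno, resid = r$resid,
               probe_name = r$probe_name, count = r$count,
               frequency = r$frequency, score = r$score,
               stringsAsFactors = FALSE)))
  score_key <- ifelse(is.na(tab$score), -Inf, tab$score)
  ord <- order(-tab$frequency, -score_key, tab$chain, tab$resno,
               tab$probe_name)
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  tab$top <- tab$frequency >= frequency_cutoff
  rownames(tab) <- NULL
  structure(list(table = tab, top = records[ord][tab$top],
                 frequency_cutoff = frequency_cutoff),
            class = "interaction_ranking")
}

#' @export
print.interaction_ranking <- function(x, ...) {
  cat(sprintf("Interaction ranking: %d records, %d in top set (cutoff %.2f)\n",
              nrow(x$table), sum(x$table$top), x$frequency_cutoff))
  if (nrow(x$table)) print(x$table, row.names = FALSE)
  invisible(x)
}
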