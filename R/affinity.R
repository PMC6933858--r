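# Steps 2-3: per-residue probe binding-score profiles, high-affinity
# residue calls, and selection of called residues at a druggable site.

#' Per-residue probe binding-score profile
#'
#' For one probe type and one chain, computes for every residue i the
#' binding score `s(p, i) = sum over frames and contacts of 1/d^2`, where
#' d is the distance between a residue heavy atom and a probe heavy atom
#' and a pair contributes whenever `d <= contact_cutoff` (4 A). All
#' qualifying atom pairs in a frame are summed — a residue-probe pair with
#' several simultaneous atom-atom contacts counts them all, reflecting the
#' tightness of the interaction. Units are 1/A^2. Residues never in
#' contact score exactly 0. Chains are profiled separately and never
#' pooled.
#'
#' @param ensemble A superposed `probe_traj`.
#' @param probe_name Probe type to profile.
#' @param chain_id Chain identifier.
#' @param contact_cutoff Heavy-atom contact cutoff (A).
#' @return Object of class `binding_profile`: data frame with `chain`,
#'   `resno`, `insert`, `resid`, `score`, plus attributes `probe_name`,
#'   `n_frames`, `contact_cutoff`.
#' @export
binding_score_profile <- function(ensemble, probe_name, chain_id,
                                  contact_cutoff = 4.0) {
  stopifnot(inherits(ensemble, "probe_traj"))
  if (!isTRUE(ensemble$superposed))
    stop("ensemble must be superposed before profiling")
  at <- ensemble$atoms
  prot <- ensemble$protein
  sel <- prot[at$chain[prot] == chain_id & is_heavy(at$elesy[prot])]
  if (!length(sel)) stop("unknown or empty chain: ", chain_id)
  inst <- Filter(function(i) i$probe_name == probe_name, ensemble$instances)
  if (!length(inst)) stop("no probe instances of type: ", probe_name)
  rkey <- res_key(at$chain[sel], at$resno[sel], at$insert[sel])
  residues <- !duplicated(rkey)
  res_tab <- data.frame(chain = at$chain[sel][residues],
                        resno = at$resno[sel][residues],
                        insert = at$insert[sel][residues],
                        resid = at$resid[sel][residues],
                        stringsAsFactors = FALSE)
  res_index <- match(rkey, rkey[residues])
  score <- numeric(nrow(res_tab))
  cut2 <- contact_cutoff^2
  probe_heavy <- unlist(lapply(inst, `[[`, "heavy"))
  for (k in seq_len(ensemble$n_frames)) {
    cm <- frame_coords(ensemble$xyz, k)
    d2 <- dist2_mat(cm[sel, , drop = FALSE],
                    cm[probe_heavy, , drop = FALSE])
    hit <- d2 <= cut2
    if (!any(hit)) next
    v <- 1 / d2
    v[!hit] <- 0
    contrib <- rowSums(v)
    nz <- contrib > 0
    if (any(nz)) {
      add <- tapply(contrib[nz], res_index[nz], sum)
      idx <- as.integer(names(add))
      score[idx] <- score[idx] + as.numeric(add)
    }
  }
  res_tab$score <- score
  structure(res_tab, class = c("binding_profile", "data.frame"),
            probe_name = probe_name, chain_id = chain_id,
            n_frames = ensemble$n_frames, contact_cutoff = contact_cutoff)
}

#' @export
print.binding_profile <- function(x, ...) {
  cat(sprintf("Binding-score profile: probe %s, chain %s, %d residues, %d frames\n",
              attr(x, "probe_name"), attr(x, "chain_id"), nrow(x),
              attr(x, "n_frames")))
  cat(sprintf("  max s(p,i) = %.1f 1/A^2 at residue %s%d\n",
              max(x$score), x$chain[which.max(x$score)],
              x$resno[which.max(x$score)]))
  invisible(x)
}

#' Plot a binding-score profile
#'
#' Score versus residue number, with the high-affinity threshold drawn as
#' a dashed line.
#'
#' @param x A `binding_profile`.
#' @param threshold High-affinity threshold to mark (1/A^2).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.binding_profile <- function(x, threshold = 500, ...) {
  graphics::plot(x$resno, x$score, type = "l",
                 xlab = "residue number", ylab = "binding score (1/A^2)",
                 main = sprintf("%s, chain %s", attr(x, "probe_name"),
                                attr(x, "chain_id")), ...)
  graphics::abline(h = threshold, lty = 2)
  invisible(x)
}

#' Call high-affinity residues from a binding profile
#'
#' Residues whose score strictly exceeds the threshold (500 1/A^2 by
#' default, calibrated for 40 ns runs with 10,000 stored frames; scores
#' scale linearly with simulation length, so other lengths warrant a
#' proportionally different threshold — no automatic rescaling is done).
#' The inequality is strict: a residue scoring exactly the threshold is
#' not called.
#'
#' @param profile A [binding_score_profile()] result.
#' @param threshold Score threshold (1/A^2).
#' @return Data frame of calls sorted by descending score: `chain`,
#'   `resno`, `insert`, `resid`, `probe_name`, `score`, `threshold`.
#' @export
high_affinity_residues <- function(profile, threshold = 500) {
  calls <- profile[profile$score > threshold, , drop = FALSE]
  calls <- as.data.frame(calls)[order(-calls$score), , drop = FALSE]
  calls$probe_name <- rep(attr(profile, "probe_name"), nrow(calls))
  calls$threshold <- rep(threshold, nrow(calls))
  rownames(calls) <- NULL
  calls
}

#' Select high-affinity residues at a druggable site
#'
#' Keeps a (residue, probe) call when at least one heavy atom of the
#' residue — reference-structure coordinates — lies within `site_cutoff`
#' (8 A) of at least one hot-spot center *of the same probe type*
#' belonging to the chosen site. A probe type with no hot spots at the
#' site contributes nothing (its calls are dropped, not an error). The
#' result is grouped by probe type.
#'
#' @param calls Data frame of high-affinity calls (rows from
#'   [high_affinity_residues()], possibly concatenated across probes and
#'   chains).
#' @param sites A `druggable_sites` object.
#' @param reference The `probe_ref` the ensemble was superposed onto.
#' @param site_id Site to analyze (default 1, the top-ranked site).
#' @param site_cutoff Residue-to-hot-spot distance cutoff (A), inclusive.
#' @return The selected rows of `calls`, ordered by probe then score.
#' @export
select_site_residues <- function(calls, sites, reference, site_id = 1L,
                                 site_cutoff = 8.0) {
  stopifnot(inherits(sites, "druggable_sites"), inherits(reference, "probe_ref"))
  hs <- sites$hotspots
  hs <- hs[!is.na(hs$site_id) & hs$site_id == site_id, , drop = FALSE]
  if (!nrow(hs)) stop("site not found or empty: ", site_id)
  at <- reference$atoms
  heavy <- is_heavy(at$elesy)
  keep <- logical(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    ph <- hs[hs$probe_name == calls$probe_name[i], , drop = FALSE]
    if (!nrow(ph)) next
    ra <- which(heavy & at$chain == calls$chain[i] &
                  at$resno == calls$resno[i] &
                  (at$insert %||% "") == (calls$insert[i] %||% ""))
    if (!length(ra)) next
    dmin <- min_dist(cbind(at$x[ra], at$y[ra], at$z[ra]),
                     cbind(ph$x, ph$y, ph$z))
    keep[i] <- dmin <= site_cutoff
  }
  out <- calls[keep, , drop = FALSE]
  out <- out[order(out$probe_name, -out$score), , drop = FALSE]
  out$site_id <- if (nrow(out)) site_id else integer(0)
  rownames(out) <- NULL
  out
}
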