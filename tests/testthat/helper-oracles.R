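# Independent brute-force oracles. Each reimplements one pipeline
# quantity with a deliberately different, naive algorithm so that
# pipeline-vs-oracle comparisons are meaningful cross-checks.

# Horn's quaternion (eigendecomposition) absolute-orientation method:
# closed-form optimal rigid superposition, independent of the SVD Kabsch
# used by the package. Returns the transformed mobile coordinates.
oracle_superpose_horn <- function(mob, fix) {
  cm <- colMeans(mob); cf <- colMeans(fix)
  a <- sweep(mob, 2L, cm); b <- sweep(fix, 2L, cf)
  M <- crossprod(a, b)  # sum over points of outer(a_i, b_i)
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  N <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,       -Sxx - Syy + Szz),
    4L, 4L, byrow = TRUE)
  q <- eigen(N, symmetric = TRUE)$vectors[, 1L]
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  R <- matrix(c(
    w*w + x*x - y*y - z*z, 2*(x*y - w*z),         2*(x*z + w*y),
    2*(x*y + w*z),         w*w - x*x + y*y - z*z, 2*(y*z - w*x),
    2*(x*z - w*y),         2*(y*z + w*x),         w*w - x*x - y*y + z*z),
    3L, 3L, byrow = TRUE)
  sweep(a %*% t(R), 2L, cf, "+")
}

ca_rmsd <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

# Naive occupancy: explicit loops over frames and probe copies with
# floor-division binning; per-copy contact test against every protein
# heavy atom.
oracle_occupancy <- function(ens, params) {
  at <- ens$atoms
  prot_heavy <- ens$protein[!(toupper(at$elesy[ens$protein]) %in% c("H", "D"))]
  edge <- params$edge_length
  counts <- list()
  for (k in seq_len(ens$n_frames)) {
    cm <- matrix(ens$xyz[k, ], ncol = 3L, byrow = TRUE)
    for (ins in ens$instances) {
      hm <- cm[ins$heavy, , drop = FALSE]
      touching <- FALSE
      for (j in seq_len(nrow(hm))) {
        d <- sqrt(rowSums(sweep(cm[prot_heavy, , drop = FALSE], 2L,
                                hm[j, ])^2))
        if (any(d <= params$protein_contact_cutoff)) { touching <- TRUE; break }
      }
      if (!touching) next
      cen <- colMeans(hm)
      key <- paste(ins$probe_name,
                   floor(cen[1L] / edge), floor(cen[2L] / edge),
                   floor(cen[3L] / edge))
      counts[[key]] <- (counts[[key]] %||% 0L) + 1L
    }
  }
  counts
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Convert an occupancy_grid's count tables into the oracle's key -> count
# map for direct comparison.
grid_as_map <- function(grid) {
  out <- list()
  for (p in names(grid$counts)) {
    d <- grid$counts[[p]]
    for (i in seq_len(nrow(d)))
      out[[paste(p, d$ix[i], d$iy[i], d$iz[i])]] <- d$count[i]
  }
  out
}

# Quadruple-loop binding score: frames x copies x residue atoms x probe
# atoms, scalar distances.
oracle_profile <- function(ens, probe_name, chain_id, cutoff = 4.0) {
  at <- ens$atoms
  prot <- ens$protein
  sel <- prot[at$chain[prot] == chain_id &
                !(toupper(at$elesy[prot]) %in% c("H", "D"))]
  inst <- Filter(function(i) i$probe_name == probe_name, ens$instances)
  keys <- unique(paste(at$resno[sel], at$insert[sel]))
  score <- stats::setNames(numeric(length(keys)), keys)
  for (k in seq_len(ens$n_frames)) {
    cm <- matrix(ens$xyz[k, ], ncol = 3L, byrow = TRUE)
    for (ins in inst) {
      for (ia in sel) {
        for (ib in ins$heavy) {
          d2 <- sum((cm[ia, ] - cm[ib, ])^2)
          if (d2 <= cutoff^2) {
            key <- paste(at$resno[ia], at$insert[ia])
            score[key] <- score[key] + 1 / d2
          }
        }
      }
    }
  }
  score
}

# All-pairs residue-to-hot-spot selection.
oracle_select <- function(calls, hotspots, ref_atoms, cutoff = 8.0) {
  keep <- logical(nrow(calls))
  heavy <- !(toupper(ref_atoms$elesy) %in% c("H", "D"))
  for (i in seq_len(nrow(calls))) {
    hs <- hotspots[hotspots$probe_name == calls$probe_name[i], , drop = FALSE]
    if (!nrow(hs)) next
    ra <- which(heavy & ref_atoms$chain == calls$chain[i] &
                  ref_atoms$resno == calls$resno[i])
    found <- FALSE
    for (a in ra) for (h in seq_len(nrow(hs))) {
      d <- sqrt((ref_atoms$x[a] - hs$x[h])^2 + (ref_atoms$y[a] - hs$y[h])^2 +
                  (ref_atoms$z[a] - hs$z[h])^2)
      if (d <= cutoff) { found <- TRUE; break }
    }
    keep[i] <- found
  }
  keep
}

# Frame-by-frame interaction test with scalar loops.
oracle_frequency <- function(ens, chain, resno, probe_name, centers,
                             ccut = 4.0, hcut = 1.5) {
  at <- ens$atoms
  prot <- ens$protein
  ra <- prot[at$chain[prot] == chain & at$resno[prot] == resno &
               !(toupper(at$elesy[prot]) %in% c("H", "D"))]
  inst <- Filter(function(i) i$probe_name == probe_name, ens$instances)
  qual <- integer(0)
  for (k in seq_len(ens$n_frames)) {
    cm <- matrix(ens$xyz[k, ], ncol = 3L, byrow = TRUE)
    ok <- FALSE
    for (ins in inst) {
      contact <- FALSE
      for (ia in ins$heavy) for (ib in ra)
        if (sum((cm[ia, ] - cm[ib, ])^2) <= ccut^2) { contact <- TRUE; break }
      if (!contact) next
      assigned <- FALSE
      for (ia in ins$atoms) for (h in seq_len(nrow(centers)))
        if (sum((cm[ia, ] - centers[h, ])^2) <= hcut^2) {
          assigned <- TRUE; break
        }
      if (contact && assigned) { ok <- TRUE; break }
    }
    if (ok) qual <- c(qual, k)
  }
  qual
}

# Reference ordering by selection sort with an explicit 3-level
# comparator: frequency desc, score desc, then chain/resno/probe.
oracle_rank_order <- function(tab) {
  cmp <- function(i, j) {
    if (tab$frequency[i] != tab$frequency[j])
      return(tab$frequency[i] > tab$frequency[j])
    si <- ifelse(is.na(tab$score[i]), -Inf, tab$score[i])
    sj <- ifelse(is.na(tab$score[j]), -Inf, tab$score[j])
    if (si != sj) return(si > sj)
    ki <- paste(tab$chain[i], sprintf("%08d", tab$resno[i]), tab$probe_name[i])
    kj <- paste(tab$chain[j], sprintf("%08d", tab$resno[j]), tab$probe_name[j])
    ki <= kj
  }
  idx <- seq_len(nrow(tab))
  for (i in seq_along(idx)) {
    best <- i
    for (j in seq_along(idx)[-seq_len(i)])
      if (!cmp(idx[best], idx[j])) best <- j
    if (best != i) idx[c(i, best)] <- idx[c(best, i)]
  }
  idx
}

# Double-loop mean pairwise C-alpha RMSD.
oracle_conformer_rmsd <- function(ens, frame_ids) {
  at <- ens$atoms
  ca <- ens$protein[at$elety[ens$protein] == "CA"]
  tot <- 0; np <- 0L
  for (i in seq_along(frame_ids)) for (j in seq_along(frame_ids)) {
    if (j <= i) next
    a <- matrix(ens$xyz[frame_ids[i], ], ncol = 3L, byrow = TRUE)[ca, ]
    b <- matrix(ens$xyz[frame_ids[j], ], ncol = 3L, byrow = TRUE)[ca, ]
    tot <- tot + sqrt(mean(rowSums((a - b)^2)))
    np <- np + 1L
  }
  tot / np
}

# Union-find single-linkage components over all point pairs.
oracle_components <- function(xyz, cutoff) {
  n <- nrow(xyz)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    if (sqrt(sum((xyz[i, ] - xyz[j, ])^2)) < cutoff) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  vapply(seq_len(n), find, 0L)
}

# Exhaustive connected-subset site score: all subsets up to max_size,
# connectivity by BFS on the subgraph.
oracle_site_score <- function(hs, params) {
  n <- nrow(hs)
  xyz <- cbind(hs$x, hs$y, hs$z)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    adj[i, j] <- i != j &&
      sqrt(sum((xyz[i, ] - xyz[j, ])^2)) < params$merge_distance
  connected <- function(sub) {
    if (length(sub) == 1L) return(TRUE)
    seen <- sub[1L]; queue <- sub[1L]
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      nb <- sub[adj[v, sub] & !(sub %in% seen)]
      seen <- c(seen, nb); queue <- c(queue, nb)
    }
    length(unique(seen)) == length(sub)
  }
  best <- Inf
  for (sz in seq_len(min(n, params$max_combination_size))) {
    combs <- utils::combn(n, sz)
    for (c_i in seq_len(ncol(combs))) {
      sub <- combs[, c_i]
      if (connected(sub)) best <- min(best, sum(hs$delta_g[sub]))
    }
  }
  best
}
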