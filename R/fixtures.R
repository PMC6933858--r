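# Synthetic druggability-trajectory generator. Builds a rigid toy fold
# (two alpha-helical poly-ALA chains) plus probe molecules with planted,
# manifest-recorded binding events, so every pipeline stage can be tested
# against known ground truth without running MD.
#
# Design notes: a planted locus clusters one copy of each configured probe
# type in a cone around a surface residue's C-beta, every copy anchored at
# firm protein contact (~2.1 A, well inside the 2.5 A counting cutoff and
# the 4 A contact cutoff). Six distinct probe types give six per-type hot
# spots within linkage distance of each other -> exactly one druggable
# site per locus at the default parameters. Planted copies may
# interpenetrate each other: only occupancy statistics matter to the
# analysis, not probe-probe sterics. Bulk copies are resampled uniformly
# per frame in an 8-25 A shell where they can never register a protein
# contact, providing a non-binding population with zero occupancy signal.

# Idealized probe geometries (A). Coordinates are approximate small-
# molecule shapes; `contact` names the heavy atom anchored at the protein.
probe_geometries <- function() {
  list(
    isopropanol = list(
      resname = "IPRO", contact = "O2",
      atoms = c("C1", "C2", "C3", "O2", "HO2"),
      elesy = c("C", "C", "C", "O", "H"),
      xyz = rbind(c(-1.26, -0.77, 0), c(0, 0, 0), c(1.26, -0.77, 0),
                  c(0, 0.70, 1.20), c(0, 1.62, 1.05))),
    acetamide = list(
      resname = "ACAM", contact = "N",
      atoms = c("CC", "CT", "O", "N", "HN1", "HN2"),
      elesy = c("C", "C", "O", "N", "H", "H"),
      xyz = rbind(c(0, 0, 0), c(-1.50, 0, 0), c(0.62, 1.05, 0),
                  c(0.62, -1.05, 0), c(1.62, -1.10, 0), c(0.10, -1.90, 0))),
    imidazole = list(
      resname = "IMID", contact = "NE2",
      atoms = c("CG", "ND1", "CE1", "NE2", "CD2", "HD1"),
      elesy = c("C", "N", "C", "N", "C", "H"),
      xyz = {
        ang <- (90 + c(0, 72, 144, 216, 288)) * pi / 180
        ring <- cbind(1.16 * cos(ang), 1.16 * sin(ang), 0)
        rbind(ring, c(2.16 * cos(ang[2L]), 2.16 * sin(ang[2L]), 0))
      }),
    acetate = list(
      resname = "ACET", contact = "O1",
      atoms = c("C1", "C2", "O1", "O2"),
      elesy = c("C", "C", "O", "O"),
      xyz = rbind(c(-1.52, 0, 0), c(0, 0, 0), c(0.62, 1.06, 0),
                  c(0.62, -1.06, 0))),
    isopropylamine = list(
      resname = "IPAM", contact = "N",
      atoms = c("C1", "C2", "C3", "N", "HN1"),
      elesy = c("C", "C", "C", "N", "H"),
      xyz = rbind(c(-1.26, -0.77, 0), c(0, 0, 0), c(1.26, -0.77, 0),
                  c(0, 0.77, 1.16), c(0, 1.70, 1.50))),
    isobutane = list(
      resname = "IBUT", contact = "C2",
      atoms = c("C1", "C2", "C3", "C4"),
      elesy = c("C", "C", "C", "C"),
      xyz = rbind(c(0, 0, 0), c(1.45, 0, -0.51), c(-0.72, 1.25, -0.51),
                  c(-0.72, -1.25, -0.51)))
  )
}

# Rotation taking unit vector a onto unit vector b (Rodrigues).
rotation_from_to <- function(a, b) {
  a <- a / sqrt(sum(a * a)); b <- b / sqrt(sum(b * b))
  v <- c(a[2L] * b[3L] - a[3L] * b[2L],
         a[3L] * b[1L] - a[1L] * b[3L],
         a[1L] * b[2L] - a[2L] * b[1L])
  cth <- sum(a * b)
  if (abs(cth + 1) < 1e-12) {  # antiparallel: rotate pi about any orthogonal
    p <- if (abs(a[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- p - sum(p * a) * a
    v <- v / sqrt(sum(v * v))
    return(2 * outer(v, v) - diag(3))
  }
  vx <- matrix(c(0, v[3L], -v[2L], -v[3L], 0, v[1L], v[2L], -v[1L], 0), 3L)
  diag(3) + vx + vx %*% vx / (1 + cth)
}

random_rotation <- function() {
  m <- matrix(stats::rnorm(9L), 3L)
  q <- qr(m)
  R <- qr.Q(q) %*% diag(sign(diag(qr.R(q))))
  if (det(R) < 0) R[, 1L] <- -R[, 1L]
  R
}

# Ideal alpha-helical poly-ALA chain along z: 100 deg twist, 1.5 A rise.
helix_chain <- function(chain_id, n_res, x0 = 0, resno_start = 1L) {
  rows <- list()
  for (i in seq_len(n_res)) {
    th <- (i - 1L) * 100 * pi / 180
    z <- (i - 1L) * 1.5
    pt <- function(r, dth, dz) c(x0 + r * cos(th + dth), r * sin(th + dth),
                                 z + dz)
    coords <- rbind(N = pt(1.7, -0.45, -0.8), CA = pt(2.3, 0, 0),
                    C = pt(1.9, 0.45, 0.7), O = pt(3.1, 0.52, 0.85),
                    CB = pt(3.83, 0, 0))
    rows[[i]] <- data.frame(
      elety = rownames(coords), elesy = c("N", "C", "C", "O", "C"),
      resid = "ALA", resno = resno_start + i - 1L, insert = "",
      chain = chain_id, x = coords[, 1L], y = coords[, 2L], z = coords[, 3L],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Configuration for the synthetic-fixture generator
#'
#' Defaults describe the standard validation scenario: a 2,000-frame
#' trajectory of a two-chain helical toy protein (50 residues per chain,
#' about 500 atoms), one planted binding locus clustering all six default
#' probe types with per-frame occupancy probability 0.48 (the order of
#' the strongest interactions seen in real druggability runs), two bulk
#' copies of each probe type, and 0.05 A Gaussian backbone jitter.
#'
#' @param n_frames Number of stored frames.
#' @param n_res Residues per chain.
#' @param chains Chain identifiers (helix axes 16 A apart along x).
#' @param resno_start First residue number (preserved verbatim
#'   downstream).
#' @param loci List of planted loci; each a list with optional `chain`,
#'   `resno` (auto-picked for clearance when `NULL`), `f` (per-frame
#'   occupancy probability), `types` (probe types clustered at the
#'   locus) and `jitter` (positional sd, A).
#' @param n_loci Convenience: replicate the first locus spec this many
#'   times at auto-picked, well-separated residues.
#' @param bulk_per_type Bulk (never-binding) copies per probe type.
#' @param protein_jitter Backbone Gaussian jitter sd (A).
#' @param contact_distance Planted anchor-atom distance to the target
#'   C-beta (A).
#' @param rigid_motion Apply a random rigid transform to every frame
#'   (undone by superposition), emulating unaligned MD output.
#' @param manifest_profiles Also compute full independent per-residue
#'   binding-score profiles for the manifest (the costliest part of the
#'   ground truth; disable when only planted events and centers are
#'   needed).
#' @param frame_interval Frame spacing metadata (ps).
#' @param specs Probe spec list.
#' @return List of class `fixture_config`.
#' @export
fixture_config <- function(n_frames = 2000L, n_res = 50L,
                           chains = c("A", "B"), resno_start = 1L,
                           loci = list(list(f = 0.48)), n_loci = NULL,
                           bulk_per_type = 2L, protein_jitter = 0.05,
                           contact_distance = 2.1, rigid_motion = TRUE,
                           manifest_profiles = TRUE,
                           frame_interval = 4, specs = default_probe_specs()) {
  if (!is.null(n_loci))
    loci <- rep(loci[1L], n_loci)
  loci <- lapply(loci, function(l) {
    list(chain = l$chain %||% NULL, resno = l$resno %||% NULL,
         f = l$f %||% 0.48, types = l$types %||% names(specs),
         jitter = l$jitter %||% 0.05)
  })
  stopifnot(all(vapply(loci, function(l) l$f >= 0 && l$f <= 1, TRUE)))
  structure(list(n_frames = as.integer(n_frames), n_res = as.integer(n_res),
                 chains = chains, resno_start = as.integer(resno_start),
                 loci = loci, bulk_per_type = as.integer(bulk_per_type),
                 protein_jitter = protein_jitter,
                 contact_distance = contact_distance,
                 rigid_motion = isTRUE(rigid_motion),
                 manifest_profiles = isTRUE(manifest_profiles),
                 frame_interval = frame_interval, specs = specs),
            class = "fixture_config")
}

#' Generate a synthetic druggability-trajectory fixture
#'
#' Builds the toy protein, plants probe-binding events as described in
#' [fixture_config()], and records a ground-truth manifest whose expected
#' outcomes (bound-frame sets, binding centers, per-residue binding
#' scores, qualifying frames per interaction) are computed by independent
#' straightforward code, never by the analysis pipeline itself. The same
#' `(config, seed)` pair reproduces the fixture byte for byte.
#'
#' @param config A [fixture_config()].
#' @param seed Integer RNG seed.
#' @param dir Optional output directory; when given, writes
#'   `reference.pdb`, `trajectory.pdb` (multi-model) and `manifest.json`,
#'   plus `trajectory.dcd` when `dcd = TRUE`.
#' @param dcd Also write a DCD mirror of the trajectory.
#' @return List with `reference` (a `probe_ref`), `ensemble` (a
#'   `probe_traj`, not superposed), `manifest`, and `paths` (when files
#'   were written).
#' @export
generate_fixture <- function(config = fixture_config(), seed = 1L,
                             dir = NULL, dcd = FALSE) {
  stopifnot(inherits(config, "fixture_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  geo <- probe_geometries()
  axis_x <- (seq_along(config$chains) - 1L) * 16
  prot <- do.call(rbind, lapply(seq_along(config$chains), function(j)
    helix_chain(config$chains[j], config$n_res, axis_x[j],
                config$resno_start)))
  prot$eleno <- seq_len(nrow(prot))
  prot <- prot[, c("eleno", "elety", "elesy", "resid", "resno", "insert",
                   "chain", "x", "y", "z")]
  prot_xyz <- cbind(prot$x, prot$y, prot$z)
  reference <- structure(list(atoms = prot,
                              calpha = which(prot$elety == "CA"),
                              path = NA_character_),
                         class = "probe_ref")

  loci <- place_loci(config, prot, axis_x)
  planted <- plant_instances(config, loci, geo, prot_xyz)

  # bulk shell: positions 8-25 A from the nearest protein atom
  bulk <- list()
  for (p in names(config$specs)) {
    for (b in seq_len(config$bulk_per_type)) {
      bulk[[length(bulk) + 1L]] <- list(probe_name = p, geom = geo[[p]])
    }
  }
  sample_bulk <- function(avoid) {
    lo <- apply(prot_xyz, 2L, min) - 25
    hi <- apply(prot_xyz, 2L, max) + 25
    repeat {
      pt <- stats::runif(3L, lo, hi)
      d <- sqrt(min(dist2_mat(matrix(pt, 1L), prot_xyz)))
      if (d < 8 || d > 25) next
      if (length(avoid) &&
          min(vapply(avoid, function(a)
            sqrt(sum((pt - a)^2)), 0)) < 12) next
      return(pt)
    }
  }
  locus_centers <- lapply(loci, `[[`, "center")

  # assemble topology: protein atoms then probe instances on chain "X"
  inst_defs <- c(planted, bulk)
  atom_rows <- list(prot)
  next_resno <- 1L
  for (i in seq_along(inst_defs)) {
    g <- inst_defs[[i]]$geom
    atom_rows[[length(atom_rows) + 1L]] <- data.frame(
      eleno = 0L, elety = g$atoms, elesy = g$elesy, resid = g$resname,
      resno = next_resno, insert = "", chain = "X",
      x = 0, y = 0, z = 0, stringsAsFactors = FALSE)
    inst_defs[[i]]$resno <- next_resno
    next_resno <- next_resno + 1L
  }
  atoms <- do.call(rbind, atom_rows)
  atoms$eleno <- seq_len(nrow(atoms))
  rownames(atoms) <- NULL
  n_at <- nrow(atoms)
  probe_offsets <- cumsum(c(nrow(prot),
                            vapply(inst_defs, function(d) nrow(d$geom$xyz), 0L)))

  # per-frame coordinates (reference frame first; rigid motion applied last)
  xyz <- matrix(NA_real_, config$n_frames, 3L * n_at)
  bound_sets <- lapply(inst_defs, function(d)
    if (is.null(d$f)) integer(0)
    else which(stats::runif(config$n_frames) < d$f))
  for (k in seq_len(config$n_frames)) {
    cm <- matrix(NA_real_, n_at, 3L)
    cm[seq_len(nrow(prot)), ] <- prot_xyz +
      matrix(stats::rnorm(3L * nrow(prot), sd = config$protein_jitter),
             ncol = 3L)
    for (i in seq_along(inst_defs)) {
      d <- inst_defs[[i]]
      rows <- (probe_offsets[i] + 1L):probe_offsets[i + 1L]
      if (!is.null(d$f) && k %in% bound_sets[[i]]) {
        jit <- stats::rnorm(3L, sd = d$jitter)
        ang <- stats::rnorm(1L, sd = 0.08)
        ax <- stats::rnorm(3L); ax <- ax / sqrt(sum(ax * ax))
        K <- matrix(c(0, ax[3L], -ax[2L], -ax[3L], 0, ax[1L],
                      ax[2L], -ax[1L], 0), 3L)
        wob <- diag(3) + sin(ang) * K + (1 - cos(ang)) * K %*% K
        # wobble about the heavy-atom centroid so that, at zero jitter,
        # the occupancy centroid is exactly frame-independent
        cen <- colMeans(d$pose[d$geom$elesy != "H", , drop = FALSE])
        cm[rows, ] <- sweep(sweep(d$pose, 2L, cen) %*% wob, 2L,
                            cen + jit, "+")
      } else {
        pt <- sample_bulk(locus_centers)
        R <- random_rotation()
        g <- d$geom
        cm[rows, ] <- sweep(g$xyz %*% R, 2L,
                            pt - colMeans(g$xyz %*% R), "+")
      }
    }
    xyz[k, ] <- as.numeric(t(cm))
  }

  manifest <- build_manifest(config, seed, inst_defs, bound_sets, planted,
                             loci, atoms, xyz, prot, probe_offsets)

  if (config$rigid_motion) {
    for (k in seq_len(config$n_frames)) {
      R <- random_rotation()
      tr <- stats::runif(3L, -20, 20)
      cm <- frame_coords(xyz, k)
      xyz[k, ] <- as.numeric(t(cm %*% R + matrix(tr, n_at, 3L, TRUE)))
    }
  }

  ensemble <- trajectory_ensemble(atoms, xyz, config$specs,
                                  config$frame_interval)
  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    ref_path <- file.path(dir, "reference.pdb")
    trj_path <- file.path(dir, "trajectory.pdb")
    man_path <- file.path(dir, "manifest.json")
    write_pdb_file(prot, ref_path)
    write_pdb_file(atoms, trj_path, xyz = xyz)
    jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    paths <- list(reference = ref_path, trajectory = trj_path,
                  manifest = man_path)
    if (dcd) {
      paths$dcd <- file.path(dir, "trajectory.dcd")
      paths$topology <- file.path(dir, "topology.pdb")
      write_dcd(xyz, paths$dcd, delta = config$frame_interval / 1000)
      at1 <- atoms
      at1$x <- xyz[1L, seq(1L, 3L * n_at, 3L)]
      at1$y <- xyz[1L, seq(2L, 3L * n_at, 3L)]
      at1$z <- xyz[1L, seq(3L, 3L * n_at, 3L)]
      write_pdb_file(at1, paths$topology)
    }
  }
  list(reference = reference, ensemble = ensemble, manifest = manifest,
       paths = paths)
}

# Choose locus target residues with outward clearance and >3x5.5 A mutual
# separation; anchor geometry for each locus.
place_loci <- function(config, prot, axis_x) {
  loci <- config$loci
  out <- list()
  used_centers <- list()
  mid <- length(axis_x) > 1L
  for (li in seq_along(loci)) {
    l <- loci[[li]]
    if (is.null(l$resno)) {
      # spread auto-picked loci along chain A (then B), outward-facing
      cand <- expand.grid(chain = config$chains,
                          resno = seq(config$resno_start + 9L,
                                      config$resno_start + config$n_res - 10L),
                          stringsAsFactors = FALSE)
      pick <- NULL
      for (ci in seq_len(nrow(cand))) {
        cb <- prot[prot$chain == cand$chain[ci] &
                     prot$resno == cand$resno[ci] & prot$elety == "CB", ]
        j <- match(cand$chain[ci], config$chains)
        u <- c(cb$x - axis_x[j], cb$y, 0)
        u <- u / sqrt(sum(u * u))
        # face away from the other chain
        if (mid && length(axis_x) == 2L) {
          other <- axis_x[3L - j]
          if (sign(u[1L]) == sign(other - axis_x[j])) next
        }
        center <- c(cb$x, cb$y, cb$z) + 3 * u
        if (length(used_centers) &&
            min(vapply(used_centers, function(a)
              sqrt(sum((center - a)^2)), 0)) < 3 * 5.5 + 2) next
        pick <- list(chain = cand$chain[ci], resno = cand$resno[ci],
                     u = u, cb = c(cb$x, cb$y, cb$z), center = center)
        break
      }
      if (is.null(pick))
        stop("could not place locus ", li,
             ": no feasible, well-separated surface residue")
      l <- utils::modifyList(l, pick)
    } else {
      cb <- prot[prot$chain == l$chain & prot$resno == l$resno &
                   prot$elety == "CB", ]
      if (!nrow(cb)) stop("locus target residue not found: ",
                          l$chain, l$resno)
      j <- match(l$chain, config$chains)
      u <- c(cb$x - axis_x[j], cb$y, 0)
      u <- u / sqrt(sum(u * u))
      l$u <- u
      l$cb <- c(cb$x, cb$y, cb$z)
      l$center <- l$cb + 3 * u
    }
    used_centers[[length(used_centers) + 1L]] <- l$center
    out[[li]] <- l
  }
  out
}

# Nominal poses for each planted probe copy: contact atom on a cone of
# directions around the outward normal at `contact_distance` from the
# target C-beta, molecule pointing outward.
plant_instances <- function(config, loci, geo, prot_xyz) {
  planted <- list()
  for (li in seq_along(loci)) {
    l <- loci[[li]]
    u <- l$u
    t1 <- c(-u[2L], u[1L], 0)
    t1 <- t1 / sqrt(sum(t1 * t1))
    t2 <- c(u[2L] * t1[3L] - u[3L] * t1[2L],
            u[3L] * t1[1L] - u[1L] * t1[3L],
            u[1L] * t1[2L] - u[2L] * t1[1L])
    types <- l$types
    for (ti in seq_along(types)) {
      g <- geo[[types[ti]]]
      phi <- 2 * pi * (ti - 1L) / max(length(types), 1L)
      half <- 50 * pi / 180
      v <- cos(half) * u + sin(half) * (cos(phi) * t1 + sin(phi) * t2)
      anchor <- l$cb + config$contact_distance * v
      ci <- match(g$contact, g$atoms)
      tpl <- g$xyz
      cen0 <- colMeans(tpl[g$elesy != "H", , drop = FALSE])
      dir0 <- cen0 - tpl[ci, ]
      R <- rotation_from_to(dir0, v)
      pose <- sweep(tpl %*% t(R), 2L,
                    anchor - (tpl %*% t(R))[ci, ], "+")
      dmin <- sqrt(min(dist2_mat(pose[g$elesy != "H", , drop = FALSE],
                                 prot_xyz)))
      if (dmin < 1.6)
        stop("infeasible geometry: planted ", types[ti], " at locus ", li,
             " clashes with the protein (min distance ",
             sprintf("%.2f", dmin), " A)")
      if (dmin > 2.5)
        stop("infeasible geometry: planted ", types[ti], " at locus ", li,
             " fails protein contact (min distance ",
             sprintf("%.2f", dmin), " A)")
      planted[[length(planted) + 1L]] <- list(
        probe_name = types[ti], geom = g, pose = pose, f = l$f,
        jitter = l$jitter, locus = li, target_chain = l$chain,
        target_resno = l$resno)
    }
  }
  planted
}

# Ground-truth manifest. All expected outcomes below are computed with
# plain local loops over the generated coordinates (reference frame),
# independent of the pipeline modules.
build_manifest <- function(config, seed, inst_defs, bound_sets, planted,
                           loci, atoms, xyz, prot, probe_offsets) {
  n_frames <- config$n_frames
  prot_heavy <- which(atoms$chain != "X" & atoms$elesy != "H")
  events <- list()
  for (i in seq_along(inst_defs)) {
    d <- inst_defs[[i]]
    if (is.null(d$f)) next
    rows <- (probe_offsets[i] + 1L):probe_offsets[i + 1L]
    heavy_rows <- rows[d$geom$elesy != "H"]
    bf <- bound_sets[[i]]
    # mean bound-frame heavy centroid = expected hot-spot location
    cen <- if (length(bf)) {
      cs <- vapply(bf, function(k) {
        cm <- frame_coords(xyz, k)
        colMeans(cm[heavy_rows, , drop = FALSE])
      }, numeric(3L))
      rowMeans(cs)
    } else rep(NA_real_, 3L)
    # qualifying frames for the (target residue, probe) interaction:
    # heavy-heavy contact <= 4 A and any probe atom <= 1.5 A from the
    # expected center
    ra <- which(atoms$chain == d$target_chain &
                  atoms$resno == d$target_resno & atoms$chain != "X" &
                  atoms$elesy != "H")
    qual <- integer(0)
    if (length(bf)) {
      for (k in seq_len(n_frames)) {
        cm <- frame_coords(xyz, k)
        dc <- sqrt(min(dist2_mat(cm[heavy_rows, , drop = FALSE],
                                 cm[ra, , drop = FALSE])))
        if (dc > 4) next
        dh <- sqrt(min(dist2_mat(cm[rows, , drop = FALSE],
                                 matrix(cen, 1L))))
        if (dh <= 1.5) qual <- c(qual, k)
      }
    }
    events[[length(events) + 1L]] <- list(
      probe_name = d$probe_name, probe_resno = d$resno, locus = d$locus,
      target_chain = d$target_chain, target_resno = d$target_resno,
      f = d$f, jitter = d$jitter,
      nominal_center = colMeans(d$pose[d$geom$elesy != "H", , drop = FALSE]),
      expected_center = cen,
      bound_frames = bf, n_bound = length(bf),
      qualifying_frames = qual)
  }
  # independent per-residue binding scores, per probe type and chain
  profiles <- list()
  if (config$manifest_profiles)
  for (p in unique(vapply(inst_defs, function(d) d$probe_name, ""))) {
    pidx <- which(vapply(inst_defs, function(d) d$probe_name, "") == p)
    ph_rows <- lapply(pidx, function(i) {
      rows <- (probe_offsets[i] + 1L):probe_offsets[i + 1L]
      rows[inst_defs[[i]]$geom$elesy != "H"]
    })
    for (ch in config$chains) {
      sel <- which(atoms$chain == ch & atoms$elesy != "H")
      rix <- atoms$resno[sel]
      resnos <- sort(unique(rix))
      sc <- stats::setNames(numeric(length(resnos)), resnos)
      for (k in seq_len(n_frames)) {
        cm <- frame_coords(xyz, k)
        rc <- cm[sel, , drop = FALSE]
        for (pr in ph_rows) {
          d2 <- dist2_mat(rc, cm[pr, , drop = FALSE])
          hit <- d2 <= 16
          if (!any(hit)) next
          v <- 1 / d2
          v[!hit] <- 0
          add <- tapply(rowSums(v), rix, sum)
          sc[names(add)] <- sc[names(add)] + as.numeric(add)
        }
      }
      profiles[[paste(p, ch, sep = "_")]] <-
        list(probe_name = p, chain = ch,
             resno = resnos, score = as.numeric(sc))
    }
  }
  list(seed = as.integer(seed), n_frames = n_frames,
       n_res = config$n_res, chains = config$chains,
       protein_atoms = nrow(prot),
       n_loci = length(loci),
       locus_centers = lapply(loci, `[[`, "center"),
       locus_targets = lapply(loci, function(l)
         list(chain = l$chain, resno = l$resno)),
       planted = events,
       n_bulk = sum(vapply(inst_defs, function(d) is.null(d$f), TRUE)),
       expected_profiles = profiles,
       rigid_motion = config$rigid_motion)
}
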