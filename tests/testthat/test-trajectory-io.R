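# Reading references and trajectories, and C-alpha superposition.

write_mini_pdb <- function(path, resno_start = 1L, n_res = 3L) {
  atoms <- toy_protein(lapply(seq_len(n_res), function(i)
    c(3.8 * i, 1.5 * (i %% 2), 0.3 * i)), resno_start = resno_start)
  probemap:::write_pdb_file(atoms, path)
  atoms
}

test_that("reference loading preserves identifiers verbatim", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_mini_pdb(path, resno_start = 4L)
  ref <- load_reference(path)
  expect_s3_class(ref, "probe_ref")
  expect_equal(nrow(ref$atoms), 9L)        # 3 residues x (N, CA, CB)
  expect_length(ref$calpha, 3L)
  expect_equal(sort(unique(ref$atoms$resno)), c(4L, 5L, 6L))
})

test_that("reference loading rejects bad input", {
  expect_error(load_reference(tempfile()), "not found")
  empty <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("REMARK nothing here", "END"), empty)
  expect_error(load_reference(empty))
  # duplicate (chain, resnum, atom name)
  dup <- withr::local_tempfile(fileext = ".pdb")
  atoms <- write_mini_pdb(tempfile(fileext = ".pdb"))
  atoms2 <- rbind(atoms, atoms[2L, ])
  probemap:::write_pdb_file(atoms2, dup)
  expect_error(load_reference(dup), "duplicate")
})

test_that("multi-model PDB loading enumerates frames and probe instances", {
  prot <- toy_protein(list(c(0, 0, 0), c(3.8, 0, 0), c(3.8, 3.8, 0)))
  probes <- list(ipro_atoms(1L), ipro_atoms(2L),
                 data.frame(eleno = 0L, elety = c("C1", "C2", "C3", "C4"),
                            elesy = "C", resid = "IBUT", resno = 3L,
                            insert = "", chain = "X", x = 0, y = 0, z = 0,
                            stringsAsFactors = FALSE))
  frames <- lapply(1:5, function(k)
    list(ipro_coords(c(10, 0, k)), ipro_coords(c(-10, 5, k)),
         matrix(rnorm(12, sd = 0.1), 4L) + 20))
  ens0 <- toy_ensemble(prot, probes, frames)
  path <- withr::local_tempfile(fileext = ".pdb")
  probemap:::write_pdb_file(ens0$atoms, path, xyz = ens0$xyz)
  ens <- load_trajectory(path)
  expect_equal(ens$n_frames, 5L)
  expect_length(ens$instances, 3L)
  expect_setequal(vapply(ens$instances, `[[`, "", "probe_name"),
                  c("isopropanol", "isopropanol", "isobutane"))
  # waters are excluded, unknown residues are an error
  atoms_w <- rbind(ens0$atoms,
                   data.frame(eleno = 0L, elety = "O", elesy = "O",
                              resid = "HOH", resno = 99L, insert = "",
                              chain = "W", x = 50, y = 0, z = 0,
                              stringsAsFactors = FALSE))
  ens_w <- trajectory_ensemble(atoms_w, cbind(ens0$xyz, 50, 0, 0))
  expect_length(ens_w$instances, 3L)
  expect_false(any(ens_w$protein %in% nrow(atoms_w)))
  atoms_u <- atoms_w
  atoms_u$resid[nrow(atoms_u)] <- "XYZ"
  expect_error(trajectory_ensemble(atoms_u, cbind(ens0$xyz, 50, 0, 0)),
               "XYZ")
})

test_that("topology/trajectory atom-count mismatch is an error", {
  prot <- toy_protein(list(c(0, 0, 0), c(3.8, 0, 0), c(3.8, 3.8, 0)))
  top <- withr::local_tempfile(fileext = ".pdb")
  probemap:::write_pdb_file(prot, top)
  dcd <- withr::local_tempfile(fileext = ".dcd")
  write_dcd(matrix(rnorm(3 * (nrow(prot) + 2L)), 1L), dcd)
  expect_error(load_trajectory(top, dcd), "mismatch")
})

test_that("PSF topology with DCD coordinates loads", {
  prot <- toy_protein(list(c(0, 0, 0), c(3.8, 0, 0), c(3.8, 3.8, 0)))
  atoms <- rbind(prot, ipro_atoms(1L))
  atoms$eleno <- seq_len(nrow(atoms))
  psf <- withr::local_tempfile(fileext = ".psf")
  lines <- c("PSF", "", sprintf("%8d !NATOM", nrow(atoms)),
             vapply(seq_len(nrow(atoms)), function(i)
               sprintf("%8d %-4s %-4d %-4s %-4s %-4s %10.6f %13.4f %11d",
                       i, atoms$chain[i], atoms$resno[i], atoms$resid[i],
                       atoms$elety[i], "CT3", 0, 12.011, 0), ""))
  writeLines(lines, psf)
  xyz <- t(vapply(1:3, function(k) {
    cm <- rbind(cbind(prot$x, prot$y, prot$z), ipro_coords(c(8, 0, k)))
    as.numeric(t(cm))
  }, numeric(3L * nrow(atoms))))
  dcd <- withr::local_tempfile(fileext = ".dcd")
  write_dcd(xyz, dcd)
  ens <- load_trajectory(psf, dcd)
  expect_equal(ens$n_frames, 3L)
  expect_length(ens$instances, 1L)
  expect_equal(ens$instances[[1L]]$probe_name, "isopropanol")
  # DCD stores single-precision floats
  expect_lt(max(abs(ens$xyz - xyz)), 1e-4)
})

test_that("superposition recovers exact rigid motions", {
  prot <- toy_protein(list(c(0, 0, 0), c(3.8, 0, 0), c(3.8, 3.8, 0),
                           c(0, 3.8, 2)))
  ref <- toy_reference(prot)
  probe <- ipro_atoms(1L)
  pc0 <- ipro_coords(c(8, 0, 0))
  # frame 1 identical; frame 2 rotated 90 deg about z and translated
  Rz <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3L)
  pcoords <- cbind(prot$x, prot$y, prot$z)
  fr2_prot <- pcoords %*% Rz + matrix(c(5, 0, 0), nrow(prot), 3L, TRUE)
  fr2_probe <- pc0 %*% Rz + matrix(c(5, 0, 0), nrow(pc0), 3L, TRUE)
  ens <- toy_ensemble(prot, list(probe),
                      list(list(pc0), list(fr2_probe)),
                      superposed = FALSE)
  ens$xyz[2L, ] <- as.numeric(t(rbind(fr2_prot, fr2_probe)))
  sup <- superpose(ens, ref)
  expect_true(sup$superposed)
  ca <- sup$protein[sup$atoms$elety[sup$protein] == "CA"]
  fix <- cbind(prot$x, prot$y, prot$z)[prot$elety == "CA", ]
  for (k in 1:2) {
    got <- matrix(sup$xyz[k, ], ncol = 3L, byrow = TRUE)[ca, ]
    expect_lt(ca_rmsd(got, fix), 1e-6)
  }
  # the probe rides along: frame-2 probe back on frame-1 probe
  p1 <- matrix(sup$xyz[1L, ], ncol = 3L, byrow = TRUE)[ens$instances[[1L]]$atoms, ]
  p2 <- matrix(sup$xyz[2L, ], ncol = 3L, byrow = TRUE)[ens$instances[[1L]]$atoms, ]
  expect_lt(max(abs(p1 - p2)), 1e-6)
})

test_that("noisy-frame superposition matches the Horn oracle and is idempotent", {
  set.seed(421)
  prot <- toy_protein(lapply(1:6, function(i)
    c(3.8 * i, 2 * sin(i), 1.5 * cos(i))))
  ref <- toy_reference(prot)
  pcoords <- cbind(prot$x, prot$y, prot$z)
  noisy <- pcoords + matrix(rnorm(length(pcoords), sd = 0.5), ncol = 3L)
  ens <- toy_ensemble(prot, list(), list(list()), protein_coords = noisy,
                      superposed = FALSE)
  pre <- ca_rmsd(noisy[prot$elety == "CA", ], pcoords[prot$elety == "CA", ])
  sup <- superpose(ens, ref)
  got <- matrix(sup$xyz[1L, ], ncol = 3L, byrow = TRUE)
  post <- ca_rmsd(got[prot$elety == "CA", ], pcoords[prot$elety == "CA", ])
  expect_lte(post, pre)
  ca <- which(prot$elety == "CA")
  horn <- oracle_superpose_horn(noisy[ca, ], pcoords[ca, ])
  expect_lt(max(abs(got[ca, ] - horn)), 1e-9)
  sup2 <- superpose(sup, ref)
  expect_lt(max(abs(sup2$xyz - sup$xyz)), 1e-9)
})

test_that("incomplete C-alpha mapping reports the missing residues", {
  prot <- toy_protein(list(c(0, 0, 0), c(3.8, 0, 0), c(3.8, 3.8, 0)))
  ref <- toy_reference(prot)
  prot2 <- prot[prot$resno != 2L, ]
  ens <- toy_ensemble(prot2, list(), list(list()))
  expect_error(superpose(ens, ref), "A\\|2")
})
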