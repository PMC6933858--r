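# Co-occurrence frames, conformer RMSD, snapshot extraction,
# pharmacophore construction and Pharmit JSON round trips.

mkrec <- function(frames, probe = "isopropanol", chain = "A", resno = 1L,
                  hotspots = NULL) {
  structure(list(chain = chain, resno = resno, insert = "", resid = "ALA",
                 probe_name = probe, qualifying_frames = frames,
                 count = length(frames), frequency = length(frames) / 10,
                 n_frames = 10L, hotspot_ids = character(0),
                 hotspots = hotspots, best_instance = integer(0),
                 site_id = 1L, score = NA_real_),
            class = "interaction_record")
}

test_that("co-occurrence frames are the intersection of qualifying sets", {
  expect_equal(find_cooccurrence_frames(list(mkrec(c(7L, 1L, 3L)))),
               c(1L, 3L, 7L))
  expect_equal(find_cooccurrence_frames(list(mkrec(c(1L, 3L, 7L)),
                                             mkrec(c(3L, 7L, 9L)))),
               c(3L, 7L))
  expect_error(find_cooccurrence_frames(list()), "no interactions")
  expect_warning(
    out <- find_cooccurrence_frames(list(mkrec(1L), mkrec(2L))),
    "lowering")
  expect_length(out, 0L)
})

test_that("a planted co-occurrence pattern is recovered through the pipeline", {
  # 12 records over 40 frames, planted so exactly 13 frames satisfy all
  set.seed(66)
  common <- sort(sample(40L, 13L))
  records <- lapply(1:12, function(i) {
    extra <- sample(setdiff(1:40, common), sample(0:5, 1L))
    mkrec(sort(c(common, extra)), resno = i)
  })
  got <- find_cooccurrence_frames(records)
  expect_equal(got, common)
  # subset property: result within every record's qualifying set
  for (r in records)
    expect_true(all(got %in% r$qualifying_frames))
})

test_that("conformer RMSD matches hand-computable cases and the oracle", {
  prot <- toy_protein(lapply(1:4, function(i) c(3.8 * i, 0, 0)))
  pc <- cbind(prot$x, prot$y, prot$z)
  shift <- pc
  shift[, 1L] <- shift[, 1L] + 1
  ens <- toy_ensemble(prot, list(), list(list(), list(), list()),
                      superposed = TRUE)
  ens$xyz[2L, ] <- as.numeric(t(shift))
  expect_equal(conformer_rmsd(ens, c(1L, 3L)), 0)        # identical frames
  expect_equal(conformer_rmsd(ens, c(1L, 2L)), 1.0)      # uniform (1,0,0)
  expect_error(conformer_rmsd(ens, 1L), "two frames")
  set.seed(10)
  ens$xyz <- matrix(rnorm(5 * ncol(ens$xyz), sd = 3), 5L)
  ens$n_frames <- 5L
  expect_equal(conformer_rmsd(ens, 1:5), oracle_conformer_rmsd(ens, 1:5),
               tolerance = 1e-9)
})

test_that("snapshot extraction writes the superposed frame and round-trips", {
  fx <- generate_fixture(fixture_config(n_frames = 30), seed = 41)
  ens <- superpose(fx$ensemble, fx$reference)
  st <- cluster_sites(detect_hotspots(accumulate_occupancy(ens)),
                      grid_params())
  target <- fx$manifest$locus_targets[[1L]]
  recs <- lapply(c("isopropanol", "acetamide", "isobutane"), function(p)
    interaction_frequency(ens, target$chain, target$resno, p, st, 1L))
  frames <- find_cooccurrence_frames(recs)
  dir <- withr::local_tempdir()
  snap <- extract_snapshot(ens, frames[1L], recs, dir)
  expect_equal(length(snap$instances), 3L)
  # protein PDB has the full protein and reloads to PDB precision
  re <- load_reference(snap$protein_path)
  expect_equal(nrow(re$atoms), length(ens$protein))
  cm <- matrix(ens$xyz[frames[1L], ], ncol = 3L, byrow = TRUE)
  expect_lt(max(abs(cbind(re$atoms$x, re$atoms$y, re$atoms$z) -
                      cm[ens$protein, ])), 1e-3 + 1e-9)
  # probe PDB contains exactly the qualifying copies
  probe_lines <- readLines(snap$probe_path)
  expect_equal(length(unique(substr(grep("^ATOM", probe_lines, value = TRUE),
                                    18L, 27L))), 3L)
  expect_error(extract_snapshot(ens, 10000L, recs, dir), "invalid frame")
})

test_that("feature construction follows the probe templates", {
  fx <- generate_fixture(fixture_config(n_frames = 20), seed = 43)
  ens <- superpose(fx$ensemble, fx$reference)
  st <- cluster_sites(detect_hotspots(accumulate_occupancy(ens)),
                      grid_params())
  target <- fx$manifest$locus_targets[[1L]]
  recs <- lapply(c("isobutane", "acetamide", "isopropanol"), function(p)
    interaction_frequency(ens, target$chain, target$resno, p, st, 1L))
  frames <- find_cooccurrence_frames(recs)
  dir <- withr::local_tempdir()
  snap <- extract_snapshot(ens, frames[1L], recs, dir)
  model <- build_pharmacophore(snap)
  # 1 isobutane + 1 acetamide + 1 isopropanol -> 2 hydrophobic, 2 donors,
  # 1 acceptor, all radius 1.0
  tb <- table(model$features$kind)
  expect_equal(as.integer(tb[c("hydrophobic", "hbond_donor",
                               "hbond_acceptor")]),
               c(2L, 2L, 1L))
  expect_equal(nrow(model$features), 5L)
  expect_true(all(model$features$radius == 1.0))
  # donors/acceptors coincide with an atom of their probe copy
  qa <- snap$probe_atoms
  for (i in which(model$features$kind %in% c("hbond_donor",
                                             "hbond_acceptor"))) {
    d <- sqrt((qa$x - model$features$x[i])^2 +
                (qa$y - model$features$y[i])^2 +
                (qa$z - model$features$z[i])^2)
    expect_lt(min(d), 1e-6)
  }
  # hydrophobic centers lie inside their probe copy's bounding box
  for (i in which(model$features$kind == "hydrophobic")) {
    ins <- Filter(function(z) z$instance_id == model$features$instance_id[i],
                  snap$instances)[[1L]]
    sel <- qa[qa$resno == ins$resno & qa$chain == ins$chain, , drop = FALSE]
    ctr <- c(model$features$x[i], model$features$y[i], model$features$z[i])
    expect_true(all(ctr >= c(min(sel$x), min(sel$y), min(sel$z)) - 1e-9))
    expect_true(all(ctr <= c(max(sel$x), max(sel$y), max(sel$z)) + 1e-9))
  }
  # feature selection subsets
  m2 <- build_pharmacophore(snap, features = c("hydrophobic"))
  expect_true(all(m2$features$kind == "hydrophobic"))
  expect_equal(nrow(m2$features), 2L)
})

test_that("Pharmit JSON round-trips losslessly and validates input", {
  fx <- generate_fixture(fixture_config(n_frames = 20), seed = 43)
  ens <- superpose(fx$ensemble, fx$reference)
  st <- cluster_sites(detect_hotspots(accumulate_occupancy(ens)),
                      grid_params())
  target <- fx$manifest$locus_targets[[1L]]
  recs <- lapply(c("isobutane", "acetamide", "isopropanol"), function(p)
    interaction_frequency(ens, target$chain, target$resno, p, st, 1L))
  dir <- withr::local_tempdir()
  snap <- extract_snapshot(ens, find_cooccurrence_frames(recs)[1L], recs, dir)
  model <- build_pharmacophore(snap)
  path <- file.path(dir, "pm.json")
  write_pharmit_json(model, path)
  doc <- jsonlite::read_json(path)
  expect_length(doc$points, 5L)
  expect_setequal(unique(vapply(doc$points, `[[`, "", "name")),
                  c("Hydrophobic", "HydrogenDonor", "HydrogenAcceptor"))
  back <- read_pharmit_json(path)
  cols <- c("kind", "radius", "enabled")
  expect_identical(model$features[, cols], back$features[, cols])
  # coordinates survive the decimal round trip to full double precision
  expect_equal(as.matrix(back$features[, c("x", "y", "z")]),
               as.matrix(model$features[, c("x", "y", "z")]),
               tolerance = 1e-12)
  # empty model is an error
  empty <- structure(list(frame_id = 1L,
                          features = model$features[0, , drop = FALSE]),
                     class = "pharmacophore_model")
  expect_error(write_pharmit_json(empty, path), "empty")
  bad <- model
  bad$features$kind[1L] <- "exotic"
  expect_error(write_pharmit_json(bad, path), "unmappable")
})

test_that("pEC50 conversion matches the worked example", {
  expect_equal(pec50_from_ec50(2.0e-9), 8.700, tolerance = 2e-4)
  expect_equal(pec50_from_ec50(1.0), 0)
  expect_equal(pec50_from_ec50(1e-6), 6)
  expect_error(pec50_from_ec50(0), "positive")
  expect_error(pec50_from_ec50(-1), "positive")
})
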