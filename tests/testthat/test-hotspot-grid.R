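# Grid occupancy, voxel energetics, hot-spot detection, site clustering
# and scoring.

test_that("probes out of protein contact contribute no occupancy", {
  prot <- toy_protein(list(c(0, 0, 0), c(3.8, 0, 0), c(3.8, 3.8, 0)))
  probe <- ipro_atoms(1L)
  # heavy atoms all > 2.5 A from every protein heavy atom, all frames
  frames <- lapply(1:20, function(k) list(ipro_coords(c(20, 20, 20 + k))))
  ens <- toy_ensemble(prot, list(probe), frames)
  grid <- accumulate_occupancy(ens, grid_params())
  expect_equal(sum(grid$counts$isopropanol$count), 0L)
  expect_equal(unname(grid$totals[["isopropanol"]]), 0)
})

test_that("a probe fixed in contact puts every frame in one voxel", {
  prot <- toy_protein(list(c(0, 0, 0), c(3.8, 0, 0), c(3.8, 3.8, 0)))
  probe <- ipro_atoms(1L)
  pc <- ipro_coords(c(2.8, 1.3, 0.4))  # in contact with residue atoms
  frames <- lapply(1:100, function(k) list(pc))
  ens <- toy_ensemble(prot, list(probe), frames)
  grid <- accumulate_occupancy(ens, grid_params())
  d <- grid$counts$isopropanol
  expect_equal(nrow(d), 1L)
  expect_equal(d$count, 100L)
  expect_equal(c(d$ix, d$iy, d$iz), floor(c(2.8, 1.3, 0.4) / 0.5))
})

test_that("occupancy counts match the brute-force oracle on a random system", {
  set.seed(77)
  prot <- toy_protein(lapply(1:8, function(i) c(3.8 * i, 2 * (i %% 3), 0)))
  probes <- list(ipro_atoms(1L), ipro_atoms(2L), ipro_atoms(3L))
  frames <- lapply(1:50, function(k)
    lapply(1:3, function(j)
      ipro_coords(c(runif(1, 0, 32), runif(1, -3, 6), runif(1, -3, 3)))))
  ens <- toy_ensemble(prot, probes, frames)
  params <- grid_params()
  grid <- accumulate_occupancy(ens, params)
  oracle <- oracle_occupancy(ens, params)
  got <- grid_as_map(grid)
  expect_equal(sort(names(got)), sort(names(oracle)))
  for (k in names(oracle))
    expect_equal(got[[k]], as.integer(oracle[[k]]))
  # count conservation against an independent qualifying-pair count
  expect_equal(sum(grid$counts$isopropanol$count),
               sum(vapply(oracle, identity, 0L)))
})

test_that("occupancy requires a superposed ensemble", {
  prot <- toy_protein(list(c(0, 0, 0), c(3.8, 0, 0), c(3.8, 3.8, 0)))
  ens <- toy_ensemble(prot, list(ipro_atoms(1L)),
                      list(list(ipro_coords(c(3, 1, 0)))),
                      superposed = FALSE)
  expect_error(accumulate_occupancy(ens), "superposed")
})

test_that("voxel free energy is inverse-Boltzmann with an Inf sentinel", {
  expect_equal(voxel_free_energy(10, 10, 300), 0)
  expect_equal(voxel_free_energy(exp(1) * 7, 7, 300), -0.0019872 * 300,
               tolerance = 1e-3)
  expect_identical(voxel_free_energy(0, 5, 300), Inf)
  # monotone decreasing in count
  dg <- voxel_free_energy(1:10, 3, 300)
  expect_true(all(diff(dg) < 0))
})

test_that("hot-spot detection merges nearby candidates and recomputes energy", {
  # hand-built grid: two occupied voxels 0.5 A apart, plus uniform floor
  grid <- structure(list(
    edge_length = 0.5, n_frames = 100,
    counts = list(isopropanol = data.frame(
      ix = c(0L, 1L), iy = 0L, iz = 0L, count = c(60L, 40L))),
    totals = c(isopropanol = 100),
    n_accessible = 1000, params = grid_params()),
    class = "occupancy_grid")
  hs <- detect_hotspots(grid, grid_params())
  expect_equal(nrow(hs), 1L)
  expect_equal(hs$occupancy_count, 100)
  # count-weighted midpoint of voxel centers at x = 0.25 and 0.75
  expect_equal(hs$x, 0.6 * 0.25 + 0.4 * 0.75)
  expect_equal(hs$delta_g,
               voxel_free_energy(100, 100 / 1000, 300))
  # uniform occupancy at the expected count -> no candidates
  grid$counts$isopropanol$count <- c(1L, 1L)
  grid$totals <- c(isopropanol = 2)
  grid$n_accessible <- 2
  expect_equal(nrow(detect_hotspots(grid, grid_params())), 0L)
})

test_that("raising the energy cutoff never adds candidate voxels", {
  set.seed(5)
  counts <- data.frame(ix = 1:30, iy = 0L, iz = 0L,
                       count = rpois(30, 5) + 1L)
  grid <- structure(list(edge_length = 0.5, n_frames = 100,
                         counts = list(isopropanol = counts),
                         totals = c(isopropanol = sum(counts$count)),
                         n_accessible = 5000, params = grid_params()),
                    class = "occupancy_grid")
  n_cand <- function(cutoff) {
    hs <- detect_hotspots(grid, grid_params(hotspot_energy_cutoff = cutoff,
                                            merge_distance = 0.4))
    nrow(hs)  # no merging at 0.4 A: one voxel per hot spot
  }
  sizes <- vapply(c(-3, -2, -1, -0.5, 0), n_cand, 0)
  expect_true(all(diff(sizes) >= 0))
})

test_that("site clustering honors the minimum-size rule and single linkage", {
  # 5 mutually linked hot spots: no site
  hs5 <- hotspot_table(cbind(seq(0, 4) * 2, 0, 0))
  expect_equal(nrow(cluster_sites(hs5, grid_params())$sites), 0L)
  # chain of 6 at 5.0 A spacing links into one site
  hs6 <- hotspot_table(cbind(seq(0, 5) * 5.0, 0, 0),
                       probe_name = "isobutane")
  st <- cluster_sites(hs6, grid_params())
  expect_equal(nrow(st$sites), 1L)
  expect_equal(st$sites$n_hotspots, 6L)
  expect_equal(sum(is.na(st$hotspots$site_id)), 0L)
  # chain of 6 at 5.6 A spacing does not link (strict < 5.5)
  hs_far <- hotspot_table(cbind(seq(0, 5) * 5.6, 0, 0))
  expect_equal(nrow(cluster_sites(hs_far, grid_params())$sites), 0L)
})

test_that("cluster membership matches a union-find oracle on random hot spots", {
  set.seed(31)
  xyz <- matrix(runif(90, 0, 30), ncol = 3L)
  comp_pkg <- probemap:::linkage_components(xyz, 5.5)
  comp_orc <- oracle_components(xyz, 5.5)
  # same partition up to label permutation
  expect_equal(length(unique(comp_pkg)), length(unique(comp_orc)))
  for (cl in unique(comp_pkg)) {
    members <- which(comp_pkg == cl)
    expect_length(unique(comp_orc[members]), 1L)
  }
})

test_that("site scores: capped connected-subset sums, vs exhaustive oracle", {
  params <- grid_params()
  # 6 identical hot spots, mutually close
  hs6 <- hotspot_table(cbind(runif(6, 0, 2), runif(6, 0, 2), 0),
                       delta_g = -1)
  expect_equal(score_site(hs6, params), -6)
  # 8 identical mutually linked: cap at 7
  hs8 <- hotspot_table(cbind(runif(8, 0, 2), runif(8, 0, 2), 0),
                       delta_g = -1)
  expect_equal(score_site(hs8, params), -7)
  # random geometry and energies vs brute force
  set.seed(99)
  for (rep in 1:5) {
    hs <- hotspot_table(matrix(runif(30, 0, 12), ncol = 3L),
                        delta_g = -runif(10, 0.5, 3))
    expect_equal(score_site(hs, params), oracle_site_score(hs, params))
  }
})

test_that("planted binding loci are recovered as sites with accurate centers", {
  fx <- generate_fixture(fixture_config(n_frames = 120, n_loci = 2),
                         seed = 202)
  ens <- superpose(fx$ensemble, fx$reference)
  hs <- detect_hotspots(accumulate_occupancy(ens))
  st <- cluster_sites(hs, grid_params())
  expect_equal(nrow(st$sites), 2L)
  for (ev in fx$manifest$planted) {
    h <- st$hotspots[st$hotspots$probe_name == ev$probe_name, , drop = FALSE]
    dmin <- min(sqrt((h$x - ev$expected_center[1])^2 +
                       (h$y - ev$expected_center[2])^2 +
                       (h$z - ev$expected_center[3])^2))
    expect_lt(dmin, 1.0)
  }
})

test_that("identical inputs give byte-identical site tables", {
  fx <- generate_fixture(fixture_config(n_frames = 60), seed = 8)
  run <- function() {
    ens <- superpose(fx$ensemble, fx$reference)
    st <- cluster_sites(detect_hotspots(accumulate_occupancy(ens)),
                        grid_params())
    f <- withr::local_tempfile(fileext = ".tsv")
    write_site_table(st, f)
    readBin(f, "raw", file.size(f))
  }
  expect_identical(run(), run())
})
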