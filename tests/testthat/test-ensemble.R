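test_that("contact-map distance is a metric on binary contact sets", {
  a <- contact_map(rbind(c(1, 4), c(2, 5), c(3, 6)))
  b <- contact_map(rbind(c(1, 6), c(2, 7), c(3, 8), c(4, 9)))
  expect_equal(contact_map_distance(a, a), 0)
  expect_equal(contact_map_distance(a, b), 7)   # disjoint: 3 + 4
  expect_equal(contact_map_distance(a, b), contact_map_distance(b, a))
  expect_equal(contact_map_distance(a, b, method = "jaccard"), 1)
  set.seed(77)
  rand_map <- function() {
    i <- sample(1:20, 6)
    contact_map(cbind(i, i + sample(c(3, 5, 7), 6, TRUE)))
  }
  for (k in 1:1000) {
    x <- rand_map(); y <- rand_map(); z <- rand_map()
    dxy <- contact_map_distance(x, y)
    dyz <- contact_map_distance(y, z)
    dxz <- contact_map_distance(x, z)
    expect_lte(dxz, dxy + dyz)
  }
})

test_that("harvesting picks exactly-Q, decorrelated, re-verified conformations", {
  K <- protein_k()
  run <- run_folding(K, 1.1, 3e5, record_interval = 1e4,
                     snapshot_interval = 2e3, seed = 41, stop_at_fold = FALSE)
  ens <- suppressWarnings(
    harvest_ensemble(list(run), q = 0.1, native = K$native_map, n = 30))
  expect_s3_class(ens, "conformation_ensemble")
  expect_gt(length(ens$conformations), 0)
  for (conf in ens$conformations)
    expect_equal(fraction_native(conf, K$native_map), 0.1)
  if (length(ens$time) > 1) expect_true(all(diff(ens$time) >= ens$gap))
  # a gap wider than the trajectory yields at most one member per run
  wide <- suppressWarnings(
    harvest_ensemble(list(run), q = 0.1, native = K$native_map, n = 10,
                     gap = 1e9))
  expect_lte(length(wide$conformations), 1L)
  expect_warning(
    harvest_ensemble(list(run), q = 0.1, native = K$native_map, n = 1e4),
    "shortfall")
  expect_error(harvest_ensemble(list(run), q = 0.013, native = K$native_map),
               "multiple")
})

test_that("clustering recovers a planted two-group partition exactly", {
  # two groups of conformations with identical within-group contact maps
  g1 <- lattice_conformation(rbind(c(0,0,0), c(1,0,0), c(1,1,0), c(0,1,0),
                                   c(0,1,1), c(0,0,1)))
  g2 <- straight_rod(6)
  ens <- structure(list(q = 0, conformations = c(rep(list(g1), 7), rep(list(g2), 5)),
                        source_run = rep(1, 12), time = 1:12, gap = 1),
                   class = "conformation_ensemble")
  cs <- cluster_ensemble(ens, max_clusters = 8)
  expect_identical(length(cs$sizes), 2L)
  expect_identical(cs$sizes, c(7L, 5L))            # relabelled by size
  expect_identical(cs$assignment[1:7], rep(1L, 7))
  expect_identical(cs$assignment[8:12], rep(2L, 5))
  # probability maps of pure clusters are 0/1
  for (pm in cs$probability_maps) expect_true(all(pm$p %in% c(0, 1)))
  # representative is a member of its own cluster
  expect_identical(unclass(cs$representatives[[1]]), unclass(g1))
  expect_identical(unclass(cs$representatives[[2]]), unclass(g2))
})

test_that("all-identical ensembles collapse to one cluster", {
  g <- straight_rod(6)
  ens <- structure(list(q = 0, conformations = rep(list(g), 6),
                        source_run = rep(1, 6), time = 1:6, gap = 1),
                   class = "conformation_ensemble")
  cs <- cluster_ensemble(ens)
  expect_identical(length(cs$sizes), 1L)
  expect_equal(cs$occupancy, 1)
  expect_error(cluster_ensemble(structure(list(conformations = list(g)),
                                          class = "conformation_ensemble")),
               "at least two")
})

test_that("probability maps marginalize to the total contact count", {
  K <- protein_k()
  run <- run_folding(K, 1.1, 2e5, record_interval = 1e4,
                     snapshot_interval = 2e3, seed = 43, stop_at_fold = FALSE)
  ens <- suppressWarnings(
    harvest_ensemble(list(run), q = 0.1, native = K$native_map, n = 20, gap = 2e3))
  skip_if(length(ens$conformations) < 4, "too few low-Q snapshots harvested")
  cs <- cluster_ensemble(ens, max_clusters = 3, native = K$native_map,
                         min_occupancy = 0)
  total_from_maps <- sum(vapply(seq_along(cs$probability_maps), function(ci)
    sum(cs$probability_maps[[ci]]$p) * cs$sizes[ci], numeric(1)))
  total_direct <- sum(vapply(ens$conformations, function(conf)
    nrow(compute_contacts(conf)), numeric(1)))
  expect_equal(total_from_maps, total_direct, tolerance = 1e-9)
})

test_that("non-native profiles vanish on native and rod ensembles", {
  K <- protein_k()
  native_run <- list(snapshots = rep(list(K$conformation), 5))
  rod_run <- list(snapshots = rep(list(straight_rod(41)), 4))
  prof <- nonnative_profile(list(native_run, rod_run), K$native_map)
  expect_equal(prof$mean_nonnative[abs(prof$q - 1) < 1e-9], 0)
  expect_equal(prof$mean_nonnative[abs(prof$q) < 1e-9], 0)
  expect_identical(prof$n, c(4, 5))
})
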