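test_that("conformation invariants are enforced with offending indices named", {
  expect_error(lattice_conformation(rbind(c(0,0,0), c(2,0,0), c(3,0,0), c(4,0,0))),
               "broken bond between beads 1 and 2")
  expect_error(lattice_conformation(rbind(c(0,0,0), c(1,0,0), c(0,0,0), c(0,1,0))),
               "beads 1 and 3 share")
  expect_error(lattice_conformation(rbind(c(0,0,0), c(1,0,0), c(1,1,0))),
               "at least 4 beads")
  expect_silent(validate_conformation(straight_rod(5)))
})

test_that("contact enumeration matches the exhaustive pairwise oracle on all 8-bead walks", {
  expect_equal(nrow(compute_contacts(straight_rod(10))), 0L)
  walks <- oracle_saws(8L)
  expect_gt(length(walks), 1000L)
  for (w in walks) {
    got <- unclass(compute_contacts(lattice_conformation(w)))
    want <- oracle_contacts(w)
    expect_identical(unname(got), unname(matrix(as.integer(want), ncol = 2L)))
  }
})

test_that("contact maps reject geometrically impossible pairs", {
  expect_error(contact_map(rbind(c(1, 3))), ">= 3")
  expect_error(contact_map(rbind(c(1, 5))), "odd")
  cm <- contact_map(rbind(c(4, 1), c(1, 4)))
  expect_identical(nrow(cm), 1L)
  expect_identical(cm[1, ], c(i = 1L, j = 4L))
})

test_that("contacts are invariant under lattice rotation and translation", {
  set.seed(5)
  conf <- random_unfolded(20, seed = 5)
  base <- unclass(compute_contacts(conf))
  m <- unclass(conf)
  for (rot in knotfold:::proper_rotations()[c(2, 9, 17)]) {
    m2 <- m %*% t(rot)
    m2 <- sweep(m2, 2, c(7, -3, 11), "+")
    rotated <- compute_contacts(lattice_conformation(m2))
    expect_identical(unclass(rotated), base)
  }
})

test_that("gyration radius agrees with closed forms and the direct oracle", {
  # 2-bead closed form (computed on a bare matrix; too short for a chain)
  two <- rbind(c(0L, 0L, 0L), c(1L, 0L, 0L))
  expect_equal(radius_of_gyration(two, angstrom = FALSE), 0.5)
  expect_equal(radius_of_gyration(two), 1.9)
  n <- 11
  expect_equal(radius_of_gyration(straight_rod(n), angstrom = FALSE),
               sqrt((n^2 - 1) / 12))
  expect_equal(radius_of_gyration(straight_rod(n)),
               3.8 * sqrt((n^2 - 1) / 12))
  conf <- random_unfolded(20, seed = 9)
  expect_equal(radius_of_gyration(conf, angstrom = FALSE),
               oracle_rg(unclass(conf)), tolerance = 1e-12)
})

test_that("non-native contact counts match brute-force set difference", {
  u4 <- lattice_conformation(rbind(c(0,0,0), c(1,0,0), c(1,1,0), c(0,1,0)))
  native <- compute_contacts(u4)
  expect_identical(count_nonnative(u4, native), 0L)
  expect_identical(count_nonnative(straight_rod(8), native), 0L)
  set.seed(2)
  for (k in 1:20) {
    conf <- random_unfolded(12, seed = k)
    fake_native <- contact_map(rbind(c(1, 4)))
    all_pairs <- oracle_contacts(unclass(conf))
    is_nat <- nrow(all_pairs) > 0 &&
      any(all_pairs[, 1] == 1 & all_pairs[, 2] == 4)
    expect_identical(count_nonnative(conf, fake_native),
                     as.integer(nrow(all_pairs) - is_nat))
  }
})

test_that("conformation files round-trip bit-exactly", {
  conf <- random_unfolded(15, seed = 3)
  path <- tempfile(fileext = ".conf")
  write_conformation(conf, path)
  back <- read_conformation(path)
  expect_identical(unclass(back), unclass(conf))
  path2 <- tempfile(fileext = ".conf")
  write_conformation(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("sampled proposals cover exactly the enumerable legal move set", {
  conf <- lattice_conformation(rbind(
    c(0,0,0), c(1,0,0), c(1,1,0), c(1,1,1), c(0,1,1), c(0,1,0)))
  legal <- enumerate_moves(conf)
  expect_gt(length(legal), 3)
  cand <- propose_move(conf, n_attempts = 1e5, seed = 42)
  reached <- unique(lapply(Filter(Negate(is.null), cand), unclass))
  key <- function(m) paste(as.vector(m), collapse = ",")
  expect_setequal(vapply(reached, key, character(1)),
                  vapply(lapply(legal, unclass), key, character(1)))
})

test_that("every sampled move is reversible with a legal reverse proposal", {
  confs <- list(
    lattice_conformation(rbind(c(0,0,0), c(1,0,0), c(1,1,0), c(2,1,0), c(2,0,0))),
    random_unfolded(8, seed = 4))
  key <- function(m) paste(as.vector(unclass(m)), collapse = ",")
  for (conf in confs) {
    for (cand in enumerate_moves(conf)) {
      back <- vapply(enumerate_moves(cand), key, character(1))
      expect_true(key(conf) %in% back)
    }
  }
})

test_that("tethering removes the anchored bead from the move set", {
  setup <- folding_setup("plane_tether", anchored_bead = 1L)
  conf <- lattice_conformation(rbind(
    c(0,0,1), c(1,0,1), c(1,1,1), c(0,1,1), c(0,1,2)))
  cand <- propose_move(conf, setup, n_attempts = 2e4, seed = 7)
  for (m in Filter(Negate(is.null), cand)) {
    expect_identical(unclass(m)[1, ], unclass(conf)[1, ])   # anchor fixed
    expect_true(all(unclass(m)[, 3] >= 1L))                 # steric wall
  }
  # corner flip with collinear bonds is a no-move: rod interior beads never move
  rodc <- propose_move(straight_rod(6), n_attempts = 5e3, p_crank = 0, seed = 1)
  moved_interior <- vapply(Filter(Negate(is.null), rodc), function(m)
    any(unclass(m)[2:5, ] != unclass(straight_rod(6))[2:5, ]), logical(1))
  expect_false(any(moved_interior))
})

test_that("plane tethering constrains setup-validated conformations", {
  setup <- folding_setup("plane_tether", anchored_bead = 1L)
  bad <- lattice_conformation(rbind(c(0,0,1), c(0,0,0), c(1,0,0), c(1,0,1)))
  expect_error(knotfold:::check_setup_conf(bad, setup), "steric wall")
  off <- lattice_conformation(rbind(c(1,0,1), c(1,1,1), c(0,1,1), c(0,0,1)))
  expect_error(knotfold:::check_setup_conf(off, setup), "anchor site")
  expect_error(folding_setup("plane_tether", anchored_bead = 1,
                             anchor_site = c(0, 0, 3)), "one lattice spacing")
})
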