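test_that("the minimal unknotted spec designs the unique contact-bearing 4-mer", {
  spec <- native_spec(chain_length = 4, n_contacts = 1, knot_type = "unknot")
  s <- design_knotted_native(spec, seed = 2, restarts = 5,
                             phase_steps = c(2e4, 1e4))
  expect_identical(nrow(s$conformation), 4L)
  expect_identical(unname(unclass(s$native_map)), rbind(c(1L, 4L)))
  expect_identical(s$knot$type_label, "unknot")
  expect_length(verify_native(s), 0)
  # deterministic given (spec, seed)
  s2 <- design_knotted_native(spec, seed = 2, restarts = 5,
                              phase_steps = c(2e4, 1e4))
  expect_identical(unclass(s2$conformation), unclass(s$conformation))
})

test_that("the bundled protein K satisfies every printed constraint", {
  K <- protein_k()
  expect_length(verify_native(K), 0)
  m <- unclass(K$conformation)
  cm <- oracle_contacts(m)                  # independent enumeration
  expect_identical(nrow(cm), 40L)
  expect_equal(mean(cm[, 2] - cm[, 1]), 17.2, tolerance = 1e-12)
  expect_identical(sum(cm[, 2] - cm[, 1]), 688L)   # CO x contacts is an integer
  core_contacts <- sum(cm[, 1] >= 3 & cm[, 2] <= 22)
  expect_identical(core_contacts, 8L)
  expect_identical(knot_report(K$conformation)$alexander_det, 3L)
})

test_that("the bundled protein U is the unknotted 90%-overlap counterpart", {
  U <- protein_u()
  K <- protein_k()
  expect_length(verify_native(U), 0)
  cm <- oracle_contacts(unclass(U$conformation))
  expect_identical(nrow(cm), 40L)
  expect_identical(nrow(unclass(U$conformation)), 40L)   # one bead shorter than K
  expect_equal(mean(cm[, 2] - cm[, 1]), 16, tolerance = 1e-12)
  expect_identical(sum(cm[, 2] - cm[, 1]), 640L)
  expect_identical(knot_report(U$conformation)$alexander_det, 1L)
  expect_equal(superposition_overlap(K, U), 90)
})

test_that("verification reports name the violated constraint", {
  K <- protein_k()
  m <- unclass(K$conformation)
  # relocate the last bead to another vacant neighbour of its bonded neighbour:
  # still a legal chain, but contacts are lost
  pivot <- m[40, ]
  steps <- rbind(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))
  occupied <- apply(m, 1, paste, collapse = ",")
  moved <- NULL
  for (d in 1:6) {
    cand <- pivot + steps[d, ]
    if (paste(cand, collapse = ",") %in% occupied) next
    m2 <- m
    m2[41, ] <- cand
    if (nrow(oracle_contacts(m2)) != 40) { moved <- m2; break }
  }
  expect_false(is.null(moved))
  broken <- native_structure(lattice_conformation(moved), spec_protein_k())
  report <- verify_native(broken)
  expect_true(any(grepl("contact count|contact order|core", report)))
})

test_that("superposition overlap maximizes over proper rotations and translations", {
  rod <- straight_rod(6)
  expect_equal(superposition_overlap(rod, rod), 100)
  rot90 <- lattice_conformation(cbind(0L, seq_len(6) - 1L, 0L))
  expect_equal(superposition_overlap(rod, rot90), 100)
  shifted <- lattice_conformation(sweep(unclass(rod), 2, c(10L, -4L, 2L), "+"))
  expect_equal(superposition_overlap(rod, shifted), 100)
  # two hand-built 6-mers differing in one bead: 5/6, equal to brute force
  a <- lattice_conformation(rbind(c(0,0,0), c(1,0,0), c(1,1,0), c(1,1,1),
                                  c(0,1,1), c(0,1,0)))
  b <- lattice_conformation(rbind(c(0,0,0), c(1,0,0), c(1,1,0), c(1,1,1),
                                  c(0,1,1), c(0,0,1)))
  ov <- superposition_overlap(a, b)
  expect_equal(ov, 100 * 5 / 6, tolerance = 1e-9)
  # brute-force oracle over all 24 rotations and a translation window
  brute <- 0
  perms <- list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
  ma <- unclass(a)
  mb <- unclass(b)
  akeys <- apply(ma, 1, paste, collapse = ",")
  for (p in perms) for (s1 in c(1,-1)) for (s2 in c(1,-1)) for (s3 in c(1,-1)) {
    R <- matrix(0, 3, 3)
    R[1, p[1]] <- s1; R[2, p[2]] <- s2; R[3, p[3]] <- s3
    if (abs(det(R) - 1) > 1e-9) next
    rb <- mb %*% t(R)
    for (tx in -4:4) for (ty in -4:4) for (tz in -4:4) {
      rb2 <- sweep(rb, 2, c(tx, ty, tz), "+")
      hits <- sum(apply(rb2, 1, paste, collapse = ",") %in% akeys)
      brute <- max(brute, hits)
    }
  }
  expect_equal(ov, 100 * brute / 6)
  # reflections are excluded: a chiral structure never overlaps 100% with its
  # mirror unless a proper rotation also maps it
  K <- protein_k()
  expect_equal(superposition_overlap(K, K), 100)
})

test_that("the topology-first designer stages produce verifiable intermediates", {
  closed <- knotfold:::lattice_trefoil_raw()
  expect_identical(knotfold:::polygon_det(closed), 3L)
  # reduction is stochastic; like the designer itself, retry a few seeds until
  # a minimally knotted 20-bead opening exists
  segs <- list()
  for (s in 1:8) {
    set.seed(s)
    poly <- knotfold:::reduce_polygon(closed, max_rounds = 2000, stale_limit = 400)
    expect_lte(nrow(poly), 32L)      # knot-safe reduction approaches the 24-edge minimum
    expect_identical(knotfold:::polygon_det(poly), 3L)
    segs <- knotfold:::open_segments(poly, 20L)
    if (length(segs) > 0L) break
  }
  expect_gt(length(segs), 0L)
  seg <- segs[[1L]]
  expect_identical(knotfold:::.chain_alexander_cpp(seg), 3L)
  expect_identical(as.integer(knotfold:::.knot_core_cpp(seg)), c(1L, 20L))
  tuned <- knotfold:::shuffle_segment(seg, 8L, box_limit = c(2L, 2L, 4L))
  expect_false(is.null(tuned))
  expect_identical(nrow(compute_contacts(lattice_conformation(tuned))), 8L)
  expect_true(knotfold:::segment_ok(tuned))
})

test_that("native specs enforce their own consistency", {
  expect_error(native_spec(10, 5, abs_contact_order = 3.11), "integer sum")
  expect_error(native_spec(10, 5, abs_contact_order = 2.8), "below 3")
  expect_error(native_spec(10, 5, core_range = c(2, 8), n_core_contacts = 9),
               "exceed")
  expect_identical(spec_protein_k()$n_contacts * spec_protein_k()$abs_contact_order,
                   688)
  expect_identical(spec_protein_u()$n_contacts * spec_protein_u()$abs_contact_order,
                   640)
})
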