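# reference closed polygons sampled from parametric knots (helper-oracles.R):
# their knot types, hence Alexander determinants, are textbook facts.

test_that("Alexander determinant classifies the reference knots", {
  expect_identical(alexander_det(ref_circle()), 1L)
  expect_identical(alexander_det(kmt_reduce(ref_trefoil())), 3L)
  expect_identical(alexander_det(kmt_reduce(ref_figure_eight())), 5L)
  # unknotted rectangle
  rect <- rbind(c(0,0,0), c(3,0,0), c(3,2,0), c(0,2,0))
  expect_identical(alexander_det(rect), 1L)
})

test_that("bundled lattice polygons carry their nominal knot types", {
  tref <- lattice_trefoil_polygon()
  fig8 <- lattice_figure_eight_polygon()
  expect_identical(nrow(tref), 24L)
  expect_identical(alexander_det(kmt_reduce(tref)), 3L)
  expect_identical(alexander_det(kmt_reduce(fig8)), 5L)
  # independent oracle: Fox p-colorability by brute force. p divides the
  # determinant iff a nontrivial p-coloring exists.
  red3 <- kmt_reduce(tref)
  red8 <- kmt_reduce(fig8)
  expect_true(oracle_p_colorable(red3, 3))
  expect_false(oracle_p_colorable(red3, 5))
  expect_false(oracle_p_colorable(red8, 3))
  expect_true(oracle_p_colorable(red8, 5))
  expect_false(oracle_p_colorable(kmt_reduce(ref_circle()), 3))
  expect_false(oracle_p_colorable(kmt_reduce(ref_circle()), 5))
})

test_that("chain closure produces a simple polygon and rejects closed input", {
  rod <- straight_rod(8)
  poly <- close_chain(rod)
  expect_s3_class(poly, "closed_polygon")
  expect_gt(nrow(poly), nrow(rod))
  expect_error(close_chain(poly), "already a closed polygon")
  # planar U-shaped chain is unknottable
  u <- lattice_conformation(rbind(c(0,0,0), c(1,0,0), c(2,0,0), c(2,1,0),
                                  c(2,2,0), c(1,2,0), c(0,2,0)))
  expect_identical(alexander_det(close_chain(u)), 1L)
})

test_that("KMT reduction shrinks polygons without changing the determinant", {
  sq <- rbind(c(0,0,0), c(4,0,0), c(4,3,0), c(0,3,0))
  red <- kmt_reduce(sq)
  expect_lte(nrow(red), 4L)
  expect_identical(alexander_det(red), 1L)
  tref <- lattice_trefoil_polygon()
  expect_identical(alexander_det(kmt_reduce(tref)), alexander_det(tref))
  # randomized invariance: shuffled closed polygons of length 30
  set.seed(31)
  poly <- ref_rectangle_polygon(30)
  for (k in 1:60) {
    poly <- shuffle_closed_polygon(poly, sweeps = 6)
    before <- alexander_det(poly)
    after <- alexander_det(kmt_reduce(poly))
    expect_identical(after, before)
  }
})

test_that("knot classification is invariant under rotation, translation and mirroring", {
  K <- protein_k()
  m <- unclass(K$conformation)
  expect_identical(knot_report(K$conformation)$alexander_det, 3L)
  for (rot in knotfold:::proper_rotations()[c(3, 14)]) {
    m2 <- sweep(m %*% t(rot), 2, c(-5, 2, 9), "+")
    expect_identical(knot_report(lattice_conformation(m2))$alexander_det, 3L)
  }
  mirror <- m
  mirror[, 1] <- -mirror[, 1]
  expect_identical(knot_report(lattice_conformation(mirror))$alexander_det, 3L)
})

test_that("knot report fields are mutually consistent", {
  r <- knot_report(protein_k()$conformation, locate_core = TRUE)
  expect_true(r$knotted)
  expect_identical(r$type_label, "trefoil")
  expect_identical(unname(r$core_range), c(3L, 22L))
  rod <- knot_report(straight_rod(10))
  expect_false(rod$knotted)
  expect_identical(rod$type_label, "unknot")
  expect_error(find_knot_core(straight_rod(10)), "not knotted")
})

test_that("greedy core localization agrees with the exhaustive sub-range oracle", {
  # brute force: smallest contiguous range whose closed sub-chain is knotted
  oracle_core <- function(m) {
    n <- nrow(m)
    for (len in 5:n) {
      hits <- NULL
      for (s in 1:(n - len + 1)) {
        sub <- m[s:(s + len - 1), , drop = FALSE]
        d <- tryCatch(knotfold:::.chain_alexander_cpp(sub),
                      error = function(e) 1L)
        if (d != 1L) hits <- rbind(hits, c(s, s + len - 1))
      }
      if (!is.null(hits)) return(hits[1, ])   # nearest bead 1 on ties
    }
    NULL
  }
  K <- unclass(protein_k()$conformation)
  expect_identical(unname(knotfold:::.knot_core_cpp(K)), c(3L, 22L))
  expect_equal(oracle_core(K), c(3, 22))
  # shorter knotted chains: sub-chains of K spanning the core
  for (e in c(25L, 30L)) {
    sub <- K[1:e, , drop = FALSE]
    if (knotfold:::.chain_alexander_cpp(sub) == 1L) next
    got <- knotfold:::.knot_core_cpp(sub)
    expect_equal(as.numeric(unname(got)), unname(oracle_core(sub)))
  }
})

test_that("p_knot curves report per-group fractions with binomial errors", {
  K <- protein_k()
  rod_like <- lapply(1:5, function(k) straight_rod(41))
  natives <- lapply(1:6, function(k) K$conformation)
  curve <- p_knot_curve(list(`0` = rod_like, `1` = natives))
  expect_identical(curve$q, c(0, 1))
  expect_identical(curve$p_knot, c(0, 1))
  expect_identical(curve$n, c(5L, 6L))
  expect_equal(curve$stderr, c(0, 0))
  expect_warning(p_knot_curve(list(`0.5` = list(), `1` = natives)), "empty")
})
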