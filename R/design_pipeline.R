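# Internal machinery of the native-structure designer.
#
# Designing a lattice protein with a *localized* knot is not reachable by
# plain annealing from random states: local moves almost never carry a
# compact unknotted chain into the knotted sector, and when they do the knot
# delocalizes over the whole chain. The pipeline used here instead constructs
# the topology first and optimizes geometry around it:
#
#   1. a lattice trefoil is obtained by walking the cubic lattice along the
#      smooth parametric trefoil and bridging the ends;
#   2. the closed polygon is shortened by knot-safe moves - corner flips and
#      doubled-corner removals. (No lattice bond can pierce the interior of a
#      unit lattice square, so the isotopy swept by either move is always
#      unobstructed and the knot type is provably preserved);
#   3. the minimal polygon is opened at every offset to find short open
#      segments that remain knotted under radial closure and are minimally
#      so (the knotted core is the whole segment);
#   4. corner-flip shuffling (re-verified after every accepted flip) tunes
#      the segment to the required internal contact count;
#   5. the segment is frozen as the future knotted core, terminal beads and
#      the tail are grown around it inside the target box, and constrained
#      simulated annealing (never moving the core) optimizes contact count,
#      contact order, compactness and terminus extension;
#   6. reheat cycles polish the last constraint violations, and the result
#      is accepted only when verify_native() reports no violation.

key3 <- function(p) paste(p[1L], p[2L], p[3L])

unit_steps <- rbind(c(1L,0L,0L), c(-1L,0L,0L), c(0L,1L,0L),
                    c(0L,-1L,0L), c(0L,0L,1L), c(0L,0L,-1L))

# walk the lattice greedily along a densely sampled space curve
latticize_curve <- function(points) {
  L <- round(points[1L, ])
  path <- matrix(as.integer(L), 1L, 3L)
  occ <- new.env(hash = TRUE)
  occ[[key3(L)]] <- TRUE
  for (k in 2:nrow(points)) {
    tgt <- points[k, ]
    while (sqrt(sum((L - tgt)^2)) > 1.0) {
      cand <- sweep(unit_steps, 2L, L, "+")
      moved <- FALSE
      for (o in order(rowSums(sweep(cand, 2L, tgt)^2))) {
        kk <- key3(cand[o, ])
        if (is.null(occ[[kk]])) {
          L <- cand[o, ]
          occ[[kk]] <- TRUE
          path <- rbind(path, as.integer(L))
          moved <- TRUE
          break
        }
      }
      if (!moved) return(NULL)
    }
  }
  path
}

# closed lattice trefoil from the parametric (2,3) torus knot; the walk ends
# adjacent to its start because the curve is closed
lattice_trefoil_raw <- function(scale = 2.8, npts = 400) {
  t <- seq(0, 2 * pi, length.out = npts)
  P <- cbind(sin(t) + 2 * sin(2 * t), cos(t) - 2 * cos(2 * t), -sin(3 * t)) * scale
  for (s in c(scale, scale * 1.07, scale * 1.15, scale * 0.93)) {
    ch <- latticize_curve(P / scale * s)
    if (is.null(ch)) next
    if (sum(abs(ch[1L, ] - ch[nrow(ch), ])) != 1L) next
    if (.alexander_det_cpp(.kmt_reduce_cpp(matrix(as.double(ch), ncol = 3L)), 3L) == 3L)
      return(ch)
  }
  stop("could not latticize the parametric trefoil")
}

polygon_det <- function(V) {
  .alexander_det_cpp(.kmt_reduce_cpp(matrix(as.double(V), ncol = 3L)), 3L)
}

# knot-safe shortening of a closed lattice polygon: random corner flips mix
# the geometry, antiparallel bond pairs (doubled corners) are excised
reduce_polygon <- function(V, max_rounds = 4000, floor_n = 4L, stale_limit = 600L) {
  occ <- new.env(hash = TRUE)
  for (i in seq_len(nrow(V))) occ[[key3(V[i, ])]] <- TRUE
  stale <- 0L
  for (round in seq_len(max_rounds)) {
    n <- nrow(V)
    for (rep in seq_len(n)) {
      i <- sample.int(n, 1L)
      ip <- if (i == 1L) n else i - 1L
      inx <- if (i == n) 1L else i + 1L
      b2 <- V[ip, ] + V[inx, ] - V[i, ]
      if (all(b2 == V[i, ])) next
      if (sum(abs(V[ip, ] - V[inx, ])) != 2L) next
      if (!is.null(occ[[key3(b2)]])) next
      rm(list = key3(V[i, ]), envir = occ)
      V[i, ] <- b2
      occ[[key3(b2)]] <- TRUE
    }
    removed <- FALSE
    i <- 1L
    while (i <= nrow(V) && nrow(V) > floor_n) {
      n <- nrow(V)
      ip <- if (i == 1L) n else i - 1L
      i1 <- if (i == n) 1L else i + 1L
      i2 <- if (i1 == n) 1L else i1 + 1L
      if (all((V[i2, ] - V[i1, ]) == -(V[i, ] - V[ip, ]))) {
        rm(list = c(key3(V[i, ]), key3(V[i1, ])), envir = occ)
        V <- V[-c(i, i1), , drop = FALSE]
        removed <- TRUE
      } else i <- i + 1L
    }
    stale <- if (removed) 0L else stale + 1L
    if (stale > stale_limit) break
  }
  V
}

# open sub-chains of a closed polygon whose knotted core is the whole segment
open_segments <- function(poly, m) {
  n <- nrow(poly)
  out <- list()
  for (off in 0:(n - 1L)) {
    idx <- ((off + seq_len(m) - 1L) %% n) + 1L
    ch <- poly[idx, , drop = FALSE]
    d <- tryCatch(.chain_alexander_cpp(ch), error = function(e) NA_integer_)
    if (is.na(d) || d != 3L) next
    core <- .knot_core_cpp(ch)
    if (core[1L] == 1L && core[2L] == m) out[[length(out) + 1L]] <- ch
  }
  out
}

segment_ok <- function(V) {
  d <- tryCatch(.chain_alexander_cpp(V), error = function(e) NA_integer_)
  if (is.na(d) || d != 3L) return(FALSE)
  core <- .knot_core_cpp(V)
  core[1L] == 1L && core[2L] == nrow(V)
}

# corner-flip shuffling of an open knotted segment towards a target internal
# contact count; topology (trefoil, whole-segment core) is re-verified after
# every accepted flip and offending flips are reverted
shuffle_segment <- function(V, target_contacts, box_limit, iters = 4000, temp = 0.8) {
  ncon <- function(W) nrow(.compute_contacts_cpp(W))
  occ <- new.env(hash = TRUE)
  for (i in seq_len(nrow(V))) occ[[key3(V[i, ])]] <- TRUE
  cur <- ncon(V)
  n <- nrow(V)
  for (it in seq_len(iters)) {
    i <- sample(2:(n - 1L), 1L)
    b2 <- V[i - 1L, ] + V[i + 1L, ] - V[i, ]
    if (all(b2 == V[i, ])) next
    if (sum(abs(V[i - 1L, ] - V[i + 1L, ])) != 2L) next
    if (!is.null(occ[[key3(b2)]])) next
    old <- V[i, ]
    rm(list = key3(old), envir = occ)
    V[i, ] <- b2
    occ[[key3(b2)]] <- TRUE
    cn <- ncon(V)
    dE <- abs(cn - target_contacts) - abs(cur - target_contacts)
    if ((dE <= 0 || stats::runif(1L) < exp(-dE / temp)) && segment_ok(V)) {
      cur <- cn
      if (cn == target_contacts) {
        ext <- sort(apply(V, 2L, function(x) diff(range(x))))
        if (all(ext <= box_limit)) return(V)
      }
    } else {
      rm(list = key3(b2), envir = occ)
      V[i, ] <- old
      occ[[key3(old)]] <- TRUE
    }
  }
  NULL
}

# randomized depth-first growth of `len` beads from `from` within a box
grow_dfs <- function(from, len, occ, lo, hi) {
  path <- matrix(NA_integer_, len, 3L)
  rec <- function(cur, k) {
    if (k > len) return(TRUE)
    for (d in sample.int(6L)) {
      nxt <- cur + unit_steps[d, ]
      if (any(nxt < lo) || any(nxt > hi)) next
      if (!is.null(occ[[key3(nxt)]])) next
      occ[[key3(nxt)]] <- TRUE
      path[k, ] <<- nxt
      if (rec(nxt, k + 1L)) return(TRUE)
      rm(list = key3(nxt), envir = occ)
    }
    FALSE
  }
  if (rec(from, 1L)) path else NULL
}

lattice_rotations <- function() {
  perms <- list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
  out <- list()
  for (p in perms) for (s1 in c(1,-1)) for (s2 in c(1,-1)) for (s3 in c(1,-1))
    out[[length(out) + 1L]] <- list(p = p, s = c(s1, s2, s3))
  out
}

# place the core inside the target box (trying orientations, reversals and
# offsets) and grow the terminal beads and the tail around it
assemble_around_core <- function(core, chain_length, core_range, box_ext, slack = 0L) {
  rots <- lattice_rotations()
  n_head <- core_range[1L] - 1L
  n_tail <- chain_length - core_range[2L]
  for (ri in sample(length(rots))) {
    for (rev_core in c(FALSE, TRUE)) {
      W <- if (rev_core) core[nrow(core):1L, , drop = FALSE] else core
      W <- W[, rots[[ri]]$p, drop = FALSE]
      W <- sweep(W, 2L, rots[[ri]]$s, "*")
      W <- sweep(W, 2L, apply(W, 2L, min))
      ext <- apply(W, 2L, max)
      if (any(ext > box_ext)) next
      for (zoff in 0:(box_ext[3L] - ext[3L])) {
        V <- sweep(W, 2L, c(0L, 0L, zoff), "+")
        occ <- new.env(hash = TRUE)
        for (i in seq_len(nrow(V))) occ[[key3(V[i, ])]] <- TRUE
        tail_part <- grow_dfs(V[nrow(V), ], n_tail, occ,
                              c(0L, 0L, 0L) - slack, box_ext + slack)
        if (is.null(tail_part)) next
        head_part <- grow_dfs(V[1L, ], n_head, occ, c(0L, 0L, 0L) - slack,
                              box_ext + c(0L, 0L, 1L) + slack)
        if (is.null(head_part)) next
        return(rbind(head_part[n_head:1L, , drop = FALSE], V, tail_part))
      }
    }
  }
  NULL
}

# annealing target list for the C++ kernel
anneal_target <- function(spec, n_coincide = -1L, max_runs = -1L) {
  list(n_contacts = spec$n_contacts,
       sum_sep = if (is.null(spec$abs_contact_order)) -1L
                 else as.integer(round(spec$abs_contact_order * spec$n_contacts)),
       det = if (spec$knot_type == "trefoil") 3L else 1L,
       win_s = if (!is.null(spec$core_range)) spec$core_range[1L] else 0L,
       win_e = if (!is.null(spec$core_range)) spec$core_range[2L] else 0L,
       n_win = if (!is.null(spec$n_core_contacts)) spec$n_core_contacts else -1L,
       body_from = spec$body_from,
       box = if (!is.null(spec$body_box)) spec$body_box else integer(0),
       bead1_extend = spec$bead1_extend,
       n_coincide = as.integer(n_coincide), max_runs = as.integer(max_runs))
}

design_weights <- c(ncon = 1, sum = 0.1, box = 2, ext = 2, win = 1,
                    knot = 30, core = 1, ov = 1, runs = 2)

# run with a local, seed-derived RNG state; restores the caller's stream
with_design_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
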