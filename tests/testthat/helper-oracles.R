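# Independent oracles used across the test suite. Everything here is written
# in plain R, separately from the package's compiled implementations, so the
# two routes can disagree when one is wrong.

# exhaustive pairwise contact oracle: non-bonded nearest neighbours, |i-j| >= 3
oracle_contacts <- function(m) {
  n <- nrow(m)
  out <- NULL
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j - i < 3) next
    if (sum(abs(m[i, ] - m[j, ])) == 1) out <- rbind(out, c(i, j))
  }
  if (is.null(out)) matrix(integer(), 0, 2) else out
}

# direct double-loop gyration radius (lattice units)
oracle_rg <- function(m) {
  n <- nrow(m)
  ctr <- colMeans(m)
  s <- 0
  for (i in seq_len(n)) s <- s + sum((m[i, ] - ctr)^2)
  sqrt(s / n)
}

# enumerate all self-avoiding walks with `n` beads and the first step fixed
# to +x (one representative per symmetry class of the first bond)
oracle_saws <- function(n) {
  steps <- rbind(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))
  out <- list()
  walk <- matrix(0L, n, 3)
  walk[2, ] <- c(1L, 0L, 0L)
  occ <- new.env(hash = TRUE)
  key <- function(p) paste(p[1], p[2], p[3])
  occ[[key(walk[1, ])]] <- TRUE
  occ[[key(walk[2, ])]] <- TRUE
  recurse <- function(k) {
    if (k > n) {
      out[[length(out) + 1L]] <<- walk[seq_len(n), , drop = FALSE]
      return(invisible(NULL))
    }
    for (d in 1:6) {
      nxt <- walk[k - 1L, ] + steps[d, ]
      kk <- key(nxt)
      if (!is.null(occ[[kk]])) next
      walk[k, ] <<- nxt
      occ[[kk]] <- TRUE
      recurse(k + 1L)
      rm(list = kk, envir = occ)
    }
  }
  recurse(3L)
  out
}

# enumerate every SAW shape (conformation modulo translation): all walks from
# the origin with a free first step
oracle_shapes <- function(n) {
  steps <- rbind(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))
  out <- list()
  walk <- matrix(0L, n, 3)
  occ <- new.env(hash = TRUE)
  key <- function(p) paste(p[1], p[2], p[3])
  occ[[key(walk[1, ])]] <- TRUE
  recurse <- function(k) {
    if (k > n) {
      out[[length(out) + 1L]] <<- walk[seq_len(n), , drop = FALSE]
      return(invisible(NULL))
    }
    for (d in 1:6) {
      nxt <- walk[k - 1L, ] + steps[d, ]
      kk <- key(nxt)
      if (!is.null(occ[[kk]])) next
      walk[k, ] <<- nxt
      occ[[kk]] <- TRUE
      recurse(k + 1L)
      rm(list = kk, envir = occ)
    }
  }
  recurse(2L)
  out
}

# translation-invariant shape key: the bond-vector sequence
shape_key <- function(m) paste(as.vector(t(diff(m))), collapse = ",")

# ---------------------------------------------------------------------------
# Independent knot oracle: Fox p-colorability by brute-force enumeration.
# A knot diagram is p-colorable (nontrivially) iff p divides the knot
# determinant; the unknot admits only trivial colorings for every p, the
# trefoil is 3-colorable but not 5-colorable, the figure-eight 5- but not
# 3-colorable. The diagram is built here from scratch (own projection and
# crossing detection), independent of the package's C++ machinery.

oracle_diagram <- function(poly, dir = c(0.2471, 0.5341, 0.8097)) {
  dir <- dir / sqrt(sum(dir^2))
  a <- if (abs(dir[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- c(dir[2]*a[3] - dir[3]*a[2], dir[3]*a[1] - dir[1]*a[3], dir[1]*a[2] - dir[2]*a[1])
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(dir[2]*e1[3] - dir[3]*e1[2], dir[3]*e1[1] - dir[1]*e1[3], dir[1]*e1[2] - dir[2]*e1[1])
  px <- poly %*% e1
  py <- poly %*% e2
  ph <- poly %*% dir
  m <- nrow(poly)
  events <- NULL
  ncross <- 0L
  for (i in seq_len(m)) {
    i2 <- i %% m + 1L
    for (j in seq_len(m)) {
      if (j <= i + 1L) next
      if (i == 1L && j == m) next
      j2 <- j %% m + 1L
      r <- c(px[i2] - px[i], py[i2] - py[i])
      s <- c(px[j2] - px[j], py[j2] - py[j])
      den <- r[1] * s[2] - r[2] * s[1]
      if (abs(den) < 1e-12) next
      qp <- c(px[j] - px[i], py[j] - py[i])
      t <- (qp[1] * s[2] - qp[2] * s[1]) / den
      u <- (qp[1] * r[2] - qp[2] * r[1]) / den
      if (t <= 1e-9 || t >= 1 - 1e-9 || u <= 1e-9 || u >= 1 - 1e-9) next
      hi <- ph[i] + t * (ph[i2] - ph[i])
      hj <- ph[j] + u * (ph[j2] - ph[j])
      ncross <- ncross + 1L
      events <- rbind(events,
                      c(edge = i, t = t, crossing = ncross, over = as.integer(hi > hj)),
                      c(edge = j, t = u, crossing = ncross, over = as.integer(hj > hi)))
    }
  }
  if (is.null(events)) return(list(n = 0L))
  events <- events[order(events[, "edge"], events[, "t"]), , drop = FALSE]
  arc <- 0L
  over_arc <- integer(ncross)
  under_in <- integer(ncross)
  under_out <- integer(ncross)
  for (k in seq_len(nrow(events))) {
    cr <- events[k, "crossing"]
    if (events[k, "over"] == 1L) over_arc[cr] <- arc %% ncross
    else {
      under_in[cr] <- arc %% ncross
      arc <- arc + 1L
      under_out[cr] <- arc %% ncross
    }
  }
  list(n = ncross, over = over_arc + 1L, uin = under_in + 1L, uout = under_out + 1L)
}

# number of Fox p-colorings by brute force over all arc colorings
oracle_fox_colorings <- function(diagram, p) {
  n <- diagram$n
  if (n == 0L) return(p)          # one arc, p trivial colorings
  grid <- as.matrix(expand.grid(rep(list(0:(p - 1L)), n)))
  ok <- rep(TRUE, nrow(grid))
  for (cr in seq_len(n)) {
    lhs <- (2L * grid[, diagram$over[cr]] - grid[, diagram$uin[cr]] -
              grid[, diagram$uout[cr]]) %% p
    ok <- ok & lhs == 0L
  }
  sum(ok)
}

# TRUE iff the diagram admits a nontrivial p-coloring (p divides the determinant)
oracle_p_colorable <- function(poly, p) {
  d <- oracle_diagram(poly)
  oracle_fox_colorings(d, p) > p
}

# parametric reference knots, sampled as closed polygons
ref_trefoil <- function(n = 80, scale = 1) {
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(sin(t) + 2 * sin(2 * t), cos(t) - 2 * cos(2 * t), -sin(3 * t)) * scale
}
ref_figure_eight <- function(n = 80) {
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind((2 + cos(2 * t)) * cos(3 * t), (2 + cos(2 * t)) * sin(3 * t), sin(4 * t))
}
ref_circle <- function(n = 24) {
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(cos(t), sin(t), 0 * t)
}
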