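# closed lattice polygons for randomized knot-machinery tests

ref_rectangle_polygon <- function(perimeter = 30) {
  w <- perimeter / 2 - 5
  stopifnot(w >= 1)
  V <- rbind(
    cbind(0:(w - 1), 0, 0),
    cbind(w, 0:4, 0),
    cbind(w:1, 5, 0),
    cbind(0, 5:1, 0))
  storage.mode(V) <- "integer"
  V
}

# pad a closed polygon to `target_n` vertices by inserting U-shaped bumps
# (the inverse of a doubled-corner excision, which never changes knot type)
pad_polygon <- function(V, target_n) {
  key <- function(p) paste(p[1], p[2], p[3])
  occ <- new.env(hash = TRUE)
  for (i in seq_len(nrow(V))) occ[[key(V[i, ])]] <- TRUE
  dirs <- rbind(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))
  while (nrow(V) < target_n) {
    done <- FALSE
    for (i in seq_len(nrow(V))) {
      j <- i %% nrow(V) + 1
      bond <- V[j, ] - V[i, ]
      for (d in seq_len(6)) {
        if (sum(dirs[d, ] * bond) != 0) next
        a <- V[i, ] + dirs[d, ]
        b <- V[j, ] + dirs[d, ]
        if (!is.null(occ[[key(a)]]) || !is.null(occ[[key(b)]])) next
        V <- rbind(V[seq_len(i), , drop = FALSE], a, b,
                   V[seq(j, nrow(V)), , drop = FALSE])
        occ[[key(a)]] <- TRUE
        occ[[key(b)]] <- TRUE
        done <- TRUE
        break
      }
      if (done) break
    }
    if (!done) stop("could not pad polygon")
  }
  storage.mode(V) <- "integer"
  V
}

# random corner flips and cyclic crankshafts on a closed polygon; the
# crankshaft can pass strands through each other, so repeated shuffling
# visits several knot types (which is the point for invariance tests)
shuffle_closed_polygon <- function(V, sweeps = 5) {
  n <- nrow(V)
  occ <- new.env(hash = TRUE)
  key <- function(p) paste(p[1], p[2], p[3])
  for (i in seq_len(n)) occ[[key(V[i, ])]] <- TRUE
  idx <- function(i) (i - 1L) %% n + 1L
  for (s in seq_len(sweeps * n)) {
    if (runif(1) < 0.7) {
      i <- sample.int(n, 1)
      b2 <- V[idx(i - 1), ] + V[idx(i + 1), ] - V[i, ]
      if (all(b2 == V[i, ])) next
      if (sum(abs(V[idx(i - 1), ] - V[idx(i + 1), ])) != 2) next
      if (!is.null(occ[[key(b2)]])) next
      rm(list = key(V[i, ]), envir = occ)
      V[i, ] <- b2
      occ[[key(b2)]] <- TRUE
    } else {
      i <- sample.int(n, 1)
      ax <- V[idx(i + 3), ] - V[i, ]
      if (sum(abs(ax)) != 1) next
      a <- which(ax != 0)
      u <- (a %% 3) + 1
      w <- (u %% 3) + 1
      sgn <- sign(ax[a])
      rot <- sample(0:2, 1)
      np <- matrix(0L, 2, 3)
      ok <- TRUE
      for (m in 1:2) {
        v <- V[idx(i + m), ] - V[i, ]
        r <- v
        if (rot == 1) { r[u] <- -v[u]; r[w] <- -v[w] }
        else if (rot == 0) { r[u] <- -sgn * v[w]; r[w] <- sgn * v[u] }
        else { r[u] <- sgn * v[w]; r[w] <- -sgn * v[u] }
        np[m, ] <- V[i, ] + r
        o <- occ[[key(np[m, ])]]
        if (!is.null(o) && !all(np[m, ] == V[idx(i + 1), ]) &&
            !all(np[m, ] == V[idx(i + 2), ])) ok <- FALSE
      }
      if (!ok || (all(np[1, ] == V[idx(i + 1), ]) && all(np[2, ] == V[idx(i + 2), ])))
        next
      rm(list = c(key(V[idx(i + 1), ]), key(V[idx(i + 2), ])), envir = occ)
      V[idx(i + 1), ] <- np[1, ]
      V[idx(i + 2), ] <- np[2, ]
      occ[[key(np[1, ])]] <- TRUE
      occ[[key(np[2, ])]] <- TRUE
    }
  }
  V
}
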