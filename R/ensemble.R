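#' Harvest Q-binned conformational ensembles from trajectories
#'
#' Collects, from the coordinate snapshots of a set of folding runs, up to
#' `n` conformations holding exactly the requested number of native contacts
#' (`Q * n_native`), subsampled so that members taken from the same
#' trajectory are separated by at least `gap` MCS (the decorrelation gap).
#' Membership is re-verified by contact enumeration.
#'
#' @param runs list of `folding_run` objects with recorded snapshots.
#' @param q requested fraction of native contacts (a multiple of
#'   `1 / n_native`).
#' @param native the native [contact_map()].
#' @param n maximum ensemble size.
#' @param gap minimal intra-trajectory time separation in MCS (default
#'   `10 * N` for an `N`-bead chain).
#' @return A list of class `conformation_ensemble`: `q`, `conformations`,
#'   `source_run`, `time`, `gap`. A shortfall (< `n` members found) is
#'   reported as a warning.
#' @export
harvest_ensemble <- function(runs, q, native, n = 200L, gap = NULL) {
  n_native <- nrow(native)
  want <- as.integer(round(q * n_native))
  if (abs(q * n_native - want) > 1e-9)
    stop("`q` must be a multiple of 1/", n_native)
  confs <- list()
  src <- integer(0)
  tim <- numeric(0)
  for (ri in seq_along(runs)) {
    run <- runs[[ri]]
    if (length(run$snapshots) == 0L) next
    if (is.null(gap)) gap <- 10L * nrow(run$snapshots[[1L]])
    formed <- as.integer(round(run$snapshot_q * n_native))
    hit <- which(formed == want)
    last_t <- -Inf
    for (h in hit) {
      t <- run$snapshot_time[h]
      if (t - last_t < gap) next
      conf <- run$snapshots[[h]]
      # re-verify membership through the exhaustive contact oracle
      if (sum(contact_key(compute_contacts(conf)) %in% contact_key(native)) != want)
        next
      confs[[length(confs) + 1L]] <- conf
      src <- c(src, ri)
      tim <- c(tim, t)
      last_t <- t
      if (length(confs) >= n) break
    }
    if (length(confs) >= n) break
  }
  if (length(confs) < n)
    warning(sprintf("ensemble shortfall at Q = %.3g: %d of %d requested",
                    q, length(confs), n))
  structure(list(q = q, conformations = confs, source_run = src, time = tim,
                 gap = if (is.null(gap)) NA_real_ else gap),
            class = "conformation_ensemble")
}

#' @export
print.conformation_ensemble <- function(x, ...) {
  cat(sprintf("<conformation_ensemble> Q = %.3g, %d conformations from %d runs\n",
              x$q, length(x$conformations), length(unique(x$source_run))))
  invisible(x)
}

#' Contact-map distance
#'
#' Symmetric-difference (Hamming) distance between two contact maps: the
#' number of contacts present in exactly one of the two. `method = "jaccard"`
#' gives `1 - |intersection| / |union|` instead.
#'
#' @param a,b [contact_map()]s.
#' @param method `"hamming"` (default) or `"jaccard"`.
#' @return Non-negative distance.
#' @export
contact_map_distance <- function(a, b, method = c("hamming", "jaccard")) {
  method <- match.arg(method)
  ka <- contact_key(a)
  kb <- contact_key(b)
  inter <- sum(ka %in% kb)
  if (method == "hamming") (length(ka) - inter) + (length(kb) - inter)
  else {
    un <- length(ka) + length(kb) - inter
    if (un == 0L) 0 else 1 - inter / un
  }
}

#' Hierarchical clustering of a conformational ensemble
#'
#' Agglomerative average-linkage clustering on the pairwise contact-map
#' distance, with the tree cut at `max_clusters`. Clusters holding less than
#' `min_occupancy` of the ensemble are merged into their nearest cluster, so
#' the reported classes are the relevant ones. Each cluster reports a
#' contact probability map over all pairs (native and non-native) and a
#' representative: the member minimizing the summed distance to all cluster
#' members' maps (the conformation closest to the cluster centroid; the
#' lowest index wins ties).
#'
#' @param ensemble a `conformation_ensemble` of size >= 2.
#' @param max_clusters cut height of the tree (default 8).
#' @param native optional native [contact_map()]; adds a `native` flag to
#'   probability maps.
#' @param method distance flavour, see [contact_map_distance()].
#' @param min_occupancy occupancy fraction under which clusters are merged.
#' @return A list of class `cluster_set`: `assignment`, `sizes`,
#'   `occupancy`, `probability_maps` (one data frame `i, j, p, native` per
#'   cluster), `representatives` (one conformation per cluster),
#'   `representative_index`.
#' @export
cluster_ensemble <- function(ensemble, max_clusters = 8L, native = NULL,
                             method = "hamming", min_occupancy = 0.05) {
  confs <- ensemble$conformations
  m <- length(confs)
  if (m < 2L) stop("ensemble must hold at least two conformations")
  maps <- lapply(confs, compute_contacts)
  keys <- lapply(maps, contact_key)
  all_keys <- sort(unique(unlist(keys)))
  # binary membership matrix: conformations x contacts
  bm <- matrix(0L, m, length(all_keys))
  for (i in seq_len(m)) bm[i, match(keys[[i]], all_keys)] <- 1L
  sizes_v <- rowSums(bm)
  inter <- tcrossprod(bm)
  d <- outer(sizes_v, sizes_v, "+") - 2 * inter
  if (method == "jaccard") {
    un <- outer(sizes_v, sizes_v, "+") - inter
    d <- ifelse(un == 0, 0, 1 - inter / un)
  }
  hc <- hclust(as.dist(d), method = "average")
  # cut at the height that yields at most `max_clusters` groups; cutting by
  # height (not k) keeps zero-distance ties in one cluster instead of
  # splitting them arbitrarily
  h_cut <- if (m > max_clusters) hc$height[m - max_clusters] else 0
  assign <- cutree(hc, h = h_cut)
  # merge sparse clusters into the nearest (average-distance) big cluster
  repeat {
    occ <- table(assign) / m
    small <- names(occ)[occ < min_occupancy]
    if (length(small) == 0L || length(occ) <= 1L) break
    s <- small[1L]
    others <- setdiff(names(occ), s)
    mean_d <- vapply(others, function(o)
      mean(d[assign == s, assign == o, drop = FALSE]), double(1))
    assign[assign == s] <- as.integer(others[which.min(mean_d)])
  }
  # relabel clusters by decreasing size (ties: lowest original label)
  tab <- sort(table(assign), decreasing = TRUE)
  relabel <- setNames(seq_along(tab), names(tab))
  assign <- unname(relabel[as.character(assign)])
  k <- max(assign)
  prob_maps <- vector("list", k)
  reps <- vector("list", k)
  rep_idx <- integer(k)
  for (cl in seq_len(k)) {
    members <- which(assign == cl)
    p <- colMeans(bm[members, , drop = FALSE])
    sel <- p > 0
    ij <- cbind(all_keys[sel] %/% 1000L, all_keys[sel] %% 1000L)
    pm <- data.frame(i = ij[, 1], j = ij[, 2], p = p[sel])
    pm$native <- if (!is.null(native)) all_keys[sel] %in% contact_key(native)
                 else rep(NA, nrow(pm))
    prob_maps[[cl]] <- pm
    # representative: minimal summed Hamming distance to members
    sums <- rowSums(d[members, members, drop = FALSE])
    rep_idx[cl] <- members[which.min(sums)]
    reps[[cl]] <- confs[[rep_idx[cl]]]
  }
  structure(list(
    assignment = assign,
    sizes = as.integer(table(factor(assign, levels = seq_len(k)))),
    occupancy = as.numeric(table(factor(assign, levels = seq_len(k)))) / m,
    probability_maps = prob_maps,
    representatives = reps,
    representative_index = rep_idx
  ), class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> %d clusters, occupancies %s\n",
              length(x$sizes),
              paste(sprintf("%.0f%%", 100 * x$occupancy), collapse = ", ")))
  invisible(x)
}

#' Mean non-native contacts along the folding coordinate
#'
#' For every visited Q value across the snapshots of a set of runs, the mean
#' and standard error of the number of non-native contacts.
#'
#' @param runs list of `folding_run` objects with snapshots.
#' @param native the native [contact_map()].
#' @return Data frame with columns `q`, `n`, `mean_nonnative`, `stderr`.
#' @export
nonnative_profile <- function(runs, native) {
  n_native <- nrow(native)
  qs <- numeric(0)
  nn <- numeric(0)
  for (run in runs) {
    for (s in seq_along(run$snapshots)) {
      conf <- run$snapshots[[s]]
      map <- compute_contacts(conf)
      formed <- sum(contact_key(map) %in% contact_key(native))
      qs <- c(qs, formed / n_native)
      nn <- c(nn, nrow(map) - formed)
    }
  }
  if (length(qs) == 0L) stop("no snapshots recorded in these runs")
  agg <- aggregate(nn, by = list(q = qs),
                   FUN = function(x) c(n = length(x), mean = mean(x),
                                       se = sd(x) / sqrt(length(x))))
  out <- data.frame(q = agg$q, n = agg$x[, "n"],
                    mean_nonnative = agg$x[, "mean"], stderr = agg$x[, "se"])
  out[order(out$q), , drop = FALSE]
}
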