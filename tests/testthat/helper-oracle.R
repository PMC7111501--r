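# Independent brute-force oracles. These deliberately re-derive results from
# first principles (naive loops over the definitions) and share no code with
# the package internals they check.

# per-pair distance with pairwise-complete rescaling, straight from the formula
oracle_pair_distance <- function(x, y, metric) {
  ok <- !is.na(x) & !is.na(y)
  m <- length(x); k <- sum(ok)
  if (k == 0) return(NA_real_)
  if (metric == "euclidean") {
    sqrt(sum((x[ok] - y[ok])^2) * m / k)
  } else if (metric == "manhattan") {
    sum(abs(x[ok] - y[ok])) * m / k
  } else {
    xs <- x[ok]; ys <- y[ok]
    r <- sum((xs - mean(xs)) * (ys - mean(ys))) /
      sqrt(sum((xs - mean(xs))^2) * sum((ys - mean(ys))^2))
    1 - r
  }
}

oracle_distance_matrix <- function(vectors, metric) {
  n <- nrow(vectors)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- oracle_pair_distance(vectors[i, ], vectors[j, ], metric)
    }
  }
  d
}

# naive O(n^3) agglomeration by repeated minimum search over the active
# distance matrix, with Lance-Williams updates written out longhand
oracle_agglomerate <- function(D, linkage) {
  n <- nrow(D)
  active <- seq_len(n)            # positions still alive
  ids <- -seq_len(n)              # node id at each position (hclust convention)
  sizes <- rep(1L, n)
  heights <- numeric(n - 1)
  merges <- matrix(0L, n - 1, 2)
  members <- lapply(seq_len(n), identity)   # leaf sets per position
  partitions <- vector("list", n - 1)
  for (step in seq_len(n - 1)) {
    best <- Inf; bi <- bj <- NA
    for (a in seq_along(active)) {
      if (a == length(active)) break
      for (b in (a + 1):length(active)) {
        dij <- D[active[a], active[b]]
        if (dij < best) { best <- dij; bi <- a; bj <- b }
      }
    }
    i <- active[bi]; j <- active[bj]
    heights[step] <- best
    merges[step, ] <- sort(c(ids[i], ids[j]))
    ni <- sizes[i]; nj <- sizes[j]
    for (b in seq_along(active)) {
      k <- active[b]
      if (k == i || k == j) next
      nk <- sizes[k]
      dik <- D[i, k]; djk <- D[j, k]; dij <- D[i, j]
      D[i, k] <- D[k, i] <- switch(linkage,
        single   = min(dik, djk),
        complete = max(dik, djk),
        average  = (ni * dik + nj * djk) / (ni + nj),
        ward     = sqrt(((ni + nk) * dik^2 + (nj + nk) * djk^2 - nk * dij^2) /
                          (ni + nj + nk)))
    }
    sizes[i] <- ni + nj
    ids[i] <- step
    members[[i]] <- c(members[[i]], members[[j]])
    active <- active[-bj]
    partitions[[step]] <- lapply(active, function(pos) sort(members[[pos]]))
  }
  list(heights = heights, merges = merges, partitions = partitions)
}

# canonical form of a partition (list of leaf index sets) for comparison
canonical_partition <- function(sets) {
  sets <- lapply(sets, sort)
  sets[order(vapply(sets, `[`, 0, 1))]
}

# partition of leaves implied by a merge table cut into k groups
partition_from_merges <- function(merges, n, k) {
  grp <- as.list(seq_len(n))
  names(grp) <- as.character(-seq_len(n))
  alive <- as.character(-seq_len(n))
  if (n - k >= 1) {
    for (i in seq_len(n - k)) {
      a <- as.character(merges[i, 1]); b <- as.character(merges[i, 2])
      grp[[as.character(i)]] <- c(grp[[a]], grp[[b]])
      alive <- c(setdiff(alive, c(a, b)), as.character(i))
    }
  }
  canonical_partition(grp[alive])
}
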