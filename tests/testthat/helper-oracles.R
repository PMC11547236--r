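# Independent brute-force re-implementations used as oracles.
# Deliberately naive, pure R, structured differently from the package
# engine: flood fill over explicit coordinate loops, and growth as
# repeated single-voxel expansion rounds over the whole grid.

oracle_offsets <- function(connectivity) {
  g <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  m <- abs(g$dz) + abs(g$dy) + abs(g$dx)
  keep <- m > 0 & m <= switch(as.character(connectivity),
                              "6" = 1, "18" = 2, "26" = 3)
  as.matrix(g[keep, , drop = FALSE])
}

.lin <- function(z, y, x, d) z + d[1L] * ((y - 1L) + d[2L] * (x - 1L))

# flood-fill components; labels 1..K in decreasing size, ties by scan
# order of discovery (z fastest, then y, then x == R linear order)
oracle_components <- function(mask, connectivity = 26) {
  d <- dim(mask)
  off <- oracle_offsets(connectivity)
  lab <- array(0L, d)
  sizes <- integer(0)
  nxt <- 0L
  for (i in which(as.vector(mask))) {
    if (lab[i] > 0L) next
    nxt <- nxt + 1L
    lab[i] <- nxt
    stack <- i
    sz <- 0L
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      sz <- sz + 1L
      co <- arrayInd(v, d)
      for (k in seq_len(nrow(off))) {
        z <- co[1L] + off[k, 1L]; y <- co[2L] + off[k, 2L]
        x <- co[3L] + off[k, 3L]
        if (z < 1L || z > d[1L] || y < 1L || y > d[2L] ||
            x < 1L || x > d[3L]) next
        w <- .lin(z, y, x, d)
        if (mask[w] && lab[w] == 0L) {
          lab[w] <- nxt
          stack <- c(stack, w)
        }
      }
    }
    sizes <- c(sizes, sz)
  }
  ord <- order(-sizes, seq_along(sizes))
  rank <- integer(length(sizes))
  rank[ord] <- seq_along(sizes)
  lab2 <- array(0L, d)
  lab2[lab > 0L] <- rank[lab[lab > 0L]]
  list(labels = lab2, sizes = sizes[ord])
}

# one growth pass as repeated single-voxel expansion: each round, every
# unlabeled voxel at/above cit that touches a labeled voxel takes the
# smallest label among its labeled neighbours; rounds repeat to a fixed
# point (rounds == breadth-first levels)
oracle_grow <- function(lab, vol, cit, connectivity = 26) {
  d <- dim(lab)
  off <- oracle_offsets(connectivity)
  repeat {
    cand <- which(lab == 0L & vol >= cit)
    if (!length(cand)) break
    newlab <- integer(length(cand))
    for (j in seq_along(cand)) {
      co <- arrayInd(cand[j], d)
      best <- 0L
      for (k in seq_len(nrow(off))) {
        z <- co[1L] + off[k, 1L]; y <- co[2L] + off[k, 2L]
        x <- co[3L] + off[k, 3L]
        if (z < 1L || z > d[1L] || y < 1L || y > d[2L] ||
            x < 1L || x > d[3L]) next
        L <- lab[.lin(z, y, x, d)]
        if (L > 0L && (best == 0L || L < best)) best <- L
      }
      newlab[j] <- best
    }
    hit <- newlab > 0L
    if (!any(hit)) break
    lab[cand[hit]] <- newlab[hit]
  }
  lab
}

# full naive run: seed from IT, largest-ns selection, growth over an
# independently computed schedule
oracle_bounti <- function(vol, it, tt, ni, ns, connectivity = 26) {
  comp <- oracle_components(vol >= it, connectivity)
  stopifnot(length(comp$sizes) > 0L)
  keep <- min(ns, length(comp$sizes))
  lab <- comp$labels
  lab[lab > keep] <- 0L
  ts <- (it - tt) / ni
  th <- floor(it - ts * (0:ni) + 0.5)
  th[ni + 1L] <- tt
  for (ci in seq_len(ni))
    lab <- oracle_grow(lab, vol, th[ci + 1L], connectivity)
  lab
}

# union of target-threshold components that contain a seed voxel
oracle_reachable_union <- function(vol, tt, seed_lab, connectivity = 26) {
  comp <- oracle_components(vol >= tt, connectivity)
  touched <- unique(comp$labels[seed_lab > 0L])
  touched <- touched[touched > 0L]
  comp$labels %in% touched & comp$labels > 0L
}

rand_volume <- function(d, seed) {
  set.seed(seed)
  array(sample(0:65535, prod(d), replace = TRUE), d)
}

# two-body noise-free phantom under the canonical skull parameters
two_body_phantom <- function(noise = 0, blur = 0) {
  makePhantom(phantomSpec(noiseSigma = noise, blurSigma = blur))
}
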