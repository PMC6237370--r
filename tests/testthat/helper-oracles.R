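# Independent brute-force oracles: naive nested-loop implementations used
# only to verify the vectorized builders. They share no code with the package.

oracle_offsets_all <- function() {
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
}

# GLCM: symmetric pair counts for one offset, normalized.
oracle_glcm <- function(lv, off) {
  ng <- max(lv, na.rm = TRUE)
  dims <- dim(lv)
  M <- matrix(0, ng, ng)
  for (x in seq_len(dims[1])) for (y in seq_len(dims[2])) for (z in seq_len(dims[3])) {
    a <- lv[x, y, z]
    if (is.na(a)) next
    xx <- x + off[1]; yy <- y + off[2]; zz <- z + off[3]
    if (xx < 1 || yy < 1 || zz < 1 || xx > dims[1] || yy > dims[2] || zz > dims[3]) next
    b <- lv[xx, yy, zz]
    if (is.na(b)) next
    M[a, b] <- M[a, b] + 1
    M[b, a] <- M[b, a] + 1
  }
  M
}

# GLRLM: maximal same-level runs along one direction, by walking each line
# from its start voxel.
oracle_glrlm <- function(lv, off) {
  dims <- dim(lv)
  ng <- max(lv, na.rm = TRUE)
  runs <- list()
  inside <- function(p) all(p >= 1) && all(p <= dims)
  for (x in seq_len(dims[1])) for (y in seq_len(dims[2])) for (z in seq_len(dims[3])) {
    p <- c(x, y, z)
    prev <- p - off
    if (inside(prev)) next  # not a line start
    # walk the full line
    lvls <- c()
    while (inside(p)) {
      lvls <- c(lvls, lv[p[1], p[2], p[3]])
      p <- p + off
    }
    r <- rle(lvls)
    for (i in seq_along(r$lengths)) {
      if (!is.na(r$values[i])) {
        runs[[length(runs) + 1]] <- c(r$values[i], r$lengths[i])
      }
    }
  }
  runs <- do.call(rbind, runs)
  maxlen <- max(runs[, 2])
  M <- matrix(0, ng, maxlen)
  for (i in seq_len(nrow(runs))) {
    M[runs[i, 1], runs[i, 2]] <- M[runs[i, 1], runs[i, 2]] + 1
  }
  M
}

# Connected zones of equal level under 26-connectivity, by BFS.
oracle_zones <- function(lv) {
  dims <- dim(lv)
  offs <- oracle_offsets_all()
  seen <- array(FALSE, dims)
  zones <- list()
  idx_all <- which(!is.na(lv))
  for (start in idx_all) {
    if (seen[start]) next
    lev <- lv[start]
    queue <- list(arrayInd(start, dims)[1, ])
    seen[start] <- TRUE
    members <- c(start)
    while (length(queue) > 0) {
      p <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(offs))) {
        q <- p + offs[k, ]
        if (any(q < 1) || any(q > dims)) next
        qi <- q[1] + (q[2] - 1) * dims[1] + (q[3] - 1) * dims[1] * dims[2]
        if (seen[qi] || is.na(lv[qi]) || lv[qi] != lev) next
        seen[qi] <- TRUE
        members <- c(members, qi)
        queue[[length(queue) + 1]] <- q
      }
    }
    zones[[length(zones) + 1]] <- list(level = lev, voxels = members)
  }
  zones
}

oracle_glszm <- function(lv) {
  ng <- max(lv, na.rm = TRUE)
  zones <- oracle_zones(lv)
  sizes <- vapply(zones, function(z) length(z$voxels), numeric(1))
  M <- matrix(0, ng, max(sizes))
  for (z in zones) M[z$level, length(z$voxels)] <- M[z$level, length(z$voxels)] + 1
  M
}

# Chebyshev distance of each mask voxel to nearest outside-mask position
# (grid edge counts as outside), by direct minimization.
oracle_distance_map <- function(mask) {
  dims <- dim(mask)
  d <- array(0, dims)
  for (x in seq_len(dims[1])) for (y in seq_len(dims[2])) for (z in seq_len(dims[3])) {
    if (!mask[x, y, z]) next
    # distance to grid edge (just outside the grid)
    best <- min(x, y, z, dims[1] - x + 1, dims[2] - y + 1, dims[3] - z + 1)
    out <- which(!mask)
    if (length(out) > 0) {
      o <- arrayInd(out, dims)
      cheb <- pmax(abs(o[, 1] - x), pmax(abs(o[, 2] - y), abs(o[, 3] - z)))
      best <- min(best, min(cheb))
    }
    d[x, y, z] <- best
  }
  d
}

oracle_gldzm <- function(lv) {
  ng <- max(lv, na.rm = TRUE)
  dmap <- oracle_distance_map(!is.na(lv))
  zones <- oracle_zones(lv)
  dists <- vapply(zones, function(z) min(dmap[z$voxels]), numeric(1))
  M <- matrix(0, ng, max(dists))
  for (i in seq_along(zones)) {
    M[zones[[i]]$level, dists[i]] <- M[zones[[i]]$level, dists[i]] + 1
  }
  M
}

oracle_ngldm <- function(lv, alpha = 0) {
  dims <- dim(lv)
  ng <- max(lv, na.rm = TRUE)
  offs <- oracle_offsets_all()
  recs <- list()
  for (x in seq_len(dims[1])) for (y in seq_len(dims[2])) for (z in seq_len(dims[3])) {
    a <- lv[x, y, z]
    if (is.na(a)) next
    k <- 0
    for (i in seq_len(nrow(offs))) {
      q <- c(x, y, z) + offs[i, ]
      if (any(q < 1) || any(q > dims)) next
      b <- lv[q[1], q[2], q[3]]
      if (!is.na(b) && abs(a - b) <= alpha) k <- k + 1
    }
    recs[[length(recs) + 1]] <- c(a, k + 1)
  }
  recs <- do.call(rbind, recs)
  M <- matrix(0, ng, max(recs[, 2]))
  for (i in seq_len(nrow(recs))) {
    M[recs[i, 1], recs[i, 2]] <- M[recs[i, 1], recs[i, 2]] + 1
  }
  M
}

# NGTDM per-level sums s(i) and counts n(i).
oracle_ngtdm <- function(lv) {
  dims <- dim(lv)
  ng <- max(lv, na.rm = TRUE)
  offs <- oracle_offsets_all()
  s <- numeric(ng); n <- integer(ng)
  for (x in seq_len(dims[1])) for (y in seq_len(dims[2])) for (z in seq_len(dims[3])) {
    a <- lv[x, y, z]
    if (is.na(a)) next
    nb <- c()
    for (i in seq_len(nrow(offs))) {
      q <- c(x, y, z) + offs[i, ]
      if (any(q < 1) || any(q > dims)) next
      b <- lv[q[1], q[2], q[3]]
      if (!is.na(b)) nb <- c(nb, b)
    }
    if (length(nb) == 0) next
    s[a] <- s[a] + abs(a - mean(nb))
    n[a] <- n[a] + 1L
  }
  list(s = s, n = n)
}

# AUC by explicit positive/negative pair counting (ties count one half).
oracle_auc_paircount <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# Direct (non-separable) 3D convolution of an impulse-centred array with the
# tensor product of per-axis filters, with half-sample symmetric extension.
oracle_separable_response <- function(a, hx, hy, hz) {
  dims <- dim(a)
  refl <- function(p, n) {
    if (n == 1) return(rep(1L, length(p)))
    q <- (p - 1) %% (2 * n)
    as.integer(ifelse(q < n, q + 1, 2 * n - q))
  }
  conv1 <- function(v, h) {
    n <- length(v); L <- length(h); lpad <- L %/% 2
    ext <- v[refl(seq.int(1 - lpad, n + (L - 1 - lpad)), n)]
    out <- numeric(n)
    for (i in seq_len(n)) {
      acc <- 0
      for (k in seq_len(L)) acc <- acc + h[k] * ext[(L - k) + i]
      out[i] <- acc
    }
    out
  }
  out <- a
  for (y in seq_len(dims[2])) for (z in seq_len(dims[3]))
    out[, y, z] <- conv1(out[, y, z], hx)
  for (x in seq_len(dims[1])) for (z in seq_len(dims[3]))
    out[x, , z] <- conv1(out[x, , z], hy)
  for (x in seq_len(dims[1])) for (y in seq_len(dims[2]))
    out[x, y, ] <- conv1(out[x, y, ], hz)
  out
}
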