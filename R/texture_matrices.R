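#' Texture-matrix construction
#'
#' Builders for the six 3D grey-level texture-matrix families computed from a
#' discretized ROI ([discretize()]): co-occurrence (GLCM), run-length
#' (GLRLM), size-zone (GLSZM), distance-zone (GLDZM), neighbouring grey-level
#' dependence (NGLDM) and neighbourhood grey-tone difference (NGTDM).
#' Directional families (GLCM, GLRLM) use the 13 unique 3D direction offsets
#' at a configurable voxel distance and are aggregated by averaging features
#' over directions; zone and neighbourhood families use 26-connectivity.
#' Offsets are defined in voxel units, not mm.
#'
#' @param d A `discretized_roi` from [discretize()].
#' @param distance GLCM pair distance in voxels (default 1).
#' @param offsets Integer matrix of direction offsets (rows), default the 13
#'   unique 3D directions.
#' @return A `texture_matrix` object; the exact contents depend on the
#'   family (per-direction count matrices for GLCM/GLRLM, a single count
#'   matrix for the zone/dependence families, per-level vectors for NGTDM).
#' @name texture_matrices
NULL

#' The 13 unique 3D direction offsets
#'
#' All 26 neighbour offsets in \{-1,0,1\}^3 come in +/- pairs; this returns
#' one representative per pair, the standard direction set for 3D GLCM/GLRLM.
#'
#' @return Integer matrix 13 x 3.
#' @export
offsets_13 <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[!(g[, 1] == 0 & g[, 2] == 0 & g[, 3] == 0), ]
  # keep one representative of each +/- pair: first nonzero component positive
  keep <- apply(g, 1, function(v) {
    nz <- v[v != 0]
    nz[1] > 0
  })
  m <- g[keep, , drop = FALSE]
  dimnames(m) <- NULL
  storage.mode(m) <- "integer"
  m
}

offsets_26 <- function() {
  o <- offsets_13()
  rbind(o, -o)
}

# Shift array contents by offset d (value at x appears at x + d); vacated
# cells take `fill`.
shift_array <- function(a, d, fill = NA) {
  dims <- dim(a)
  out <- array(fill, dims)
  src <- vector("list", 3); dst <- vector("list", 3)
  for (ax in 1:3) {
    n <- dims[ax]; dd <- d[ax]
    if (abs(dd) >= n) return(out)
    if (dd >= 0) { dst[[ax]] <- (1 + dd):n; src[[ax]] <- 1:(n - dd) }
    else { dst[[ax]] <- 1:(n + dd); src[[ax]] <- (1 - dd):n }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# Level pairs (from, to) across offset d, both in mask.
level_pairs <- function(lv, d) {
  nb <- shift_array(lv, -d)  # nb[x] = lv[x + d]
  ok <- !is.na(lv) & !is.na(nb)
  list(from = lv[ok], to = nb[ok])
}

#' @rdname texture_matrices
#' @export
compute_glcm <- function(d, distance = 1L, offsets = offsets_13()) {
  lv <- d$levels; ng <- d$n_levels
  mats <- list()
  for (k in seq_len(nrow(offsets))) {
    off <- offsets[k, ] * as.integer(distance)
    pr <- level_pairs(lv, off)
    if (length(pr$from) == 0) next
    # symmetric: count both (i,j) and (j,i)
    idx <- c((pr$from - 1L) * ng + pr$to, (pr$to - 1L) * ng + pr$from)
    cnt <- tabulate(idx, nbins = ng * ng)
    m <- matrix(cnt, nrow = ng, ncol = ng, byrow = TRUE)
    mats[[length(mats) + 1]] <- m / sum(m)
  }
  if (length(mats) == 0) mats <- list(matrix(1, 1, 1))  # degenerate ROI
  structure(list(family = "GLCM", matrices = mats, n_levels = ng,
                 params = list(distance = distance)),
            class = "texture_matrix")
}

#' @rdname texture_matrices
#' @export
compute_glrlm <- function(d, offsets = offsets_13()) {
  lv <- d$levels; dims <- dim(lv); ng <- d$n_levels
  n_vox <- sum(!is.na(lv))
  v_all <- as.vector(lv)
  ijk <- arrayInd(seq_along(v_all), dims)
  mats <- list()
  for (k in seq_len(nrow(offsets))) {
    off <- offsets[k, ]
    nrm <- sum(off^2)
    t_proj <- ijk[, 1] * off[1] + ijk[, 2] * off[2] + ijk[, 3] * off[3]
    # line keys: constant along a line of direction `off`, integer-valued
    k1 <- ijk[, 1] * nrm - t_proj * off[1]
    k2 <- ijk[, 2] * nrm - t_proj * off[2]
    k3 <- ijk[, 3] * nrm - t_proj * off[3]
    ord <- order(k1, k2, k3, t_proj)
    v <- v_all[ord]
    n <- length(v)
    same_line <- c(FALSE, k1[ord][-1] == k1[ord][-n] &
                     k2[ord][-1] == k2[ord][-n] &
                     k3[ord][-1] == k3[ord][-n])
    valid <- !is.na(v)
    prev_v <- c(NA, v[-n])
    cont <- valid & same_line & !is.na(prev_v) & (v == prev_v)
    cont[is.na(cont)] <- FALSE
    run_id <- cumsum(!cont)
    idv <- run_id[valid]
    vv <- v[valid]
    r <- rle(idv)
    run_len <- r$lengths
    run_lvl <- vv[cumsum(r$lengths)]
    maxlen <- max(run_len)
    cnt <- tabulate((run_lvl - 1L) * maxlen + run_len, nbins = ng * maxlen)
    mats[[k]] <- matrix(cnt, nrow = ng, ncol = maxlen, byrow = TRUE)
  }
  structure(list(family = "GLRLM", matrices = mats, n_levels = ng,
                 n_voxels = n_vox),
            class = "texture_matrix")
}

# 26-connected components of equal grey level within the mask.
# Returns tibble(level, size, zone_id) plus the membership vector over
# in-mask voxels (in `which(!is.na(lv))` order).
grey_level_zones <- function(lv) {
  dims <- dim(lv)
  w <- which(!is.na(lv))
  n <- length(w)
  vert <- integer(length(lv))
  vert[w] <- seq_len(n)
  lin <- array(seq_along(lv), dims)
  edges <- vector("list", 13)
  offs <- offsets_13()
  for (k in seq_len(nrow(offs))) {
    off <- offs[k, ]
    nb_lv <- shift_array(lv, -off)
    nb_lin <- shift_array(lin, -off, fill = 0L)
    ok <- !is.na(lv) & !is.na(nb_lv) & lv == nb_lv
    if (!any(ok)) next
    edges[[k]] <- cbind(vert[lin[ok]], vert[nb_lin[ok]])
  }
  el <- do.call(rbind, edges)
  if (is.null(el) || nrow(el) == 0) {
    membership <- seq_len(n)
  } else {
    g <- igraph::graph_from_edgelist(el, directed = FALSE)
    g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
    membership <- igraph::components(g)$membership[seq_len(n)]
  }
  lvls <- lv[w]
  size <- tabulate(membership)
  zone_level <- as.integer(tapply(lvls, membership, function(z) z[1]))
  list(membership = membership, zone_size = size, zone_level = zone_level,
       voxel_index = w)
}

#' @rdname texture_matrices
#' @export
compute_glszm <- function(d) {
  lv <- d$levels; ng <- d$n_levels
  z <- grey_level_zones(lv)
  maxs <- max(z$zone_size)
  cnt <- tabulate((z$zone_level - 1L) * maxs + z$zone_size, nbins = ng * maxs)
  m <- matrix(cnt, nrow = ng, ncol = maxs, byrow = TRUE)
  structure(list(family = "GLSZM", matrix = m, n_levels = ng,
                 n_voxels = sum(!is.na(lv))),
            class = "texture_matrix")
}

# Chebyshev (chessboard) distance of each mask voxel to the nearest voxel
# outside the mask; the grid edge counts as outside. Minimum value 1.
chebyshev_distance_map <- function(mask_arr) {
  dims <- dim(mask_arr)
  d <- array(0, dims)
  big <- sum(dims) + 1
  d[mask_arr] <- big
  offs <- offsets_26()
  repeat {
    nb_min <- array(0, dims)  # out-of-grid neighbours have distance 0
    nb_min[] <- Inf
    for (k in seq_len(nrow(offs))) {
      nb <- shift_array(d, -offs[k, ], fill = 0)
      nb_min <- pmin(nb_min, nb)
    }
    d_new <- pmin(d, nb_min + 1)
    d_new[!mask_arr] <- 0
    if (identical(d_new, d)) break
    d <- d_new
  }
  d
}

#' @rdname texture_matrices
#' @export
compute_gldzm <- function(d) {
  lv <- d$levels; ng <- d$n_levels
  mask_arr <- !is.na(lv)
  dmap <- chebyshev_distance_map(mask_arr)
  z <- grey_level_zones(lv)
  zone_dist <- as.integer(tapply(dmap[z$voxel_index], z$membership, min))
  maxd <- max(zone_dist)
  cnt <- tabulate((z$zone_level - 1L) * maxd + zone_dist, nbins = ng * maxd)
  m <- matrix(cnt, nrow = ng, ncol = maxd, byrow = TRUE)
  structure(list(family = "GLDZM", matrix = m, n_levels = ng,
                 n_voxels = sum(mask_arr)),
            class = "texture_matrix")
}

#' @rdname texture_matrices
#' @param alpha NGLDM coarseness parameter: a neighbour is "dependent" when
#'   its grey level differs by at most `alpha` (default 0).
#' @export
compute_ngldm <- function(d, alpha = 0L) {
  lv <- d$levels; ng <- d$n_levels
  offs <- offsets_26()
  dep <- array(0L, dim(lv))
  for (k in seq_len(nrow(offs))) {
    nb <- shift_array(lv, -offs[k, ])
    hit <- !is.na(lv) & !is.na(nb) & abs(lv - nb) <= alpha
    dep <- dep + hit
  }
  ok <- !is.na(lv)
  ki <- dep[ok] + 1L  # dependence count k -> column k+1
  gi <- lv[ok]
  maxk <- max(ki)
  cnt <- tabulate((gi - 1L) * maxk + ki, nbins = ng * maxk)
  m <- matrix(cnt, nrow = ng, ncol = maxk, byrow = TRUE)
  structure(list(family = "NGLDM", matrix = m, n_levels = ng,
                 n_voxels = sum(ok), params = list(alpha = alpha)),
            class = "texture_matrix")
}

#' @rdname texture_matrices
#' @export
compute_ngtdm <- function(d) {
  lv <- d$levels; ng <- d$n_levels
  offs <- offsets_26()
  nb_sum <- array(0, dim(lv))
  nb_cnt <- array(0L, dim(lv))
  for (k in seq_len(nrow(offs))) {
    nb <- shift_array(lv, -offs[k, ])
    has <- !is.na(nb)
    nb_sum <- nb_sum + ifelse(has, nb, 0)
    nb_cnt <- nb_cnt + has
  }
  ok <- !is.na(lv) & nb_cnt > 0
  gi <- lv[ok]
  diff <- abs(gi - nb_sum[ok] / nb_cnt[ok])
  s_i <- numeric(ng); n_i <- integer(ng)
  agg <- tapply(diff, gi, sum)
  s_i[as.integer(names(agg))] <- agg
  tab <- tabulate(gi, nbins = ng)
  n_i <- tab
  structure(list(family = "NGTDM", s = s_i, n = n_i,
                 n_levels = ng, n_voxels = sum(ok)),
            class = "texture_matrix")
}

#' @export
print.texture_matrix <- function(x, ...) {
  cat(sprintf("<texture_matrix> %s, %d grey levels\n", x$family, x$n_levels))
  invisible(x)
}
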