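#' Texture features from texture matrices
#'
#' Feature calculators for the six texture-matrix families. Directional
#' families (GLCM, GLRLM) compute features per direction and average over the
#' 13 directions. Degenerate ROIs (single grey level, so no texture) use
#' fixed finite fallbacks so no NaN/Inf ever reaches the model:
#' correlation-type features fall back to 1, entropy-type features to 0, and
#' NGTDM coarseness is computed as `1 / (sum(p * s) + 1e-6)`, which caps it at
#' 1e6 for a perfectly uniform ROI.
#'
#' @param m A `texture_matrix` from the matching `compute_*` builder.
#' @return Named numeric vector (names prefixed with the family).
#' @name texture_features
NULL

#' @rdname texture_features
#' @export
glcm_features <- function(m) {
  stopifnot(m$family == "GLCM")
  per_dir <- lapply(m$matrices, glcm_features_one)
  rowMeans(do.call(cbind, per_dir))
}

glcm_features_one <- function(P) {
  ng <- nrow(P)
  i <- row(P); j <- col(P)
  lev <- seq_len(ng)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum(lev * px); muy <- sum(lev * py)
  sx <- sqrt(sum((lev - mux)^2 * px)); sy <- sqrt(sum((lev - muy)^2 * py))
  autocorr <- sum(i * j * P)
  contrast <- sum((i - j)^2 * P)
  dissim <- sum(abs(i - j) * P)
  energy <- sum(P^2)
  pos <- P > 0
  entropy <- -sum(P[pos] * log2(P[pos]))
  homog <- sum(P / (1 + abs(i - j)))
  idm <- sum(P / (1 + (i - j)^2))
  offd <- i != j
  invvar <- if (any(offd)) sum(P[offd] / (i[offd] - j[offd])^2) else 0
  maxprob <- max(P)
  clus <- function(pw) sum((i + j - mux - muy)^pw * P)
  correl <- if (sx > 0 && sy > 0) (autocorr - mux * muy) / (sx * sy) else 1

  # sum / difference marginals
  psum <- numeric(2 * ng)
  pdiff <- numeric(ng)
  ps <- rowsum(as.vector(P), as.vector(i + j))
  psum[as.integer(rownames(ps))] <- ps
  pd <- rowsum(as.vector(P), as.vector(abs(i - j) + 1))
  pdiff[as.integer(rownames(pd))] <- pd
  sum_avg <- sum(seq_along(psum) * psum)
  spos <- psum > 0
  sum_entropy <- -sum(psum[spos] * log2(psum[spos]))
  dpos <- pdiff > 0
  diff_entropy <- -sum(pdiff[dpos] * log2(pdiff[dpos]))

  # information measures of correlation
  hx <- -sum(px[px > 0] * log2(px[px > 0]))
  hy <- -sum(py[py > 0] * log2(py[py > 0]))
  pxy <- outer(px, py)
  ok <- P > 0 & pxy > 0
  hxy1 <- -sum(P[ok] * log2(pxy[ok]))
  okk <- pxy > 0
  hxy2 <- -sum(pxy[okk] * log2(pxy[okk]))
  denom <- max(hx, hy)
  ic1 <- if (denom > 0) (entropy - hxy1) / denom else 1
  ic2 <- sqrt(pmax(1 - exp(-2 * (hxy2 - entropy)), 0))
  if (denom == 0) ic2 <- 1

  c(GLCM_energy = energy, GLCM_contrast = contrast, GLCM_correl1 = correl,
    GLCM_clusShade = clus(3), GLCM_clusProm = clus(4), GLCM_clusTend = clus(2),
    GLCM_homogeneity = homog, GLCM_idm = idm, GLCM_entropy = entropy,
    GLCM_dissimilarity = dissim, GLCM_autocorr = autocorr,
    GLCM_sumAvg = sum_avg, GLCM_sumEntropy = sum_entropy,
    GLCM_diffEntropy = diff_entropy, GLCM_maxProb = maxprob,
    GLCM_invVariance = invvar, GLCM_infoCorr1 = ic1, GLCM_infoCorr2 = ic2)
}

# Shared machinery for count matrices indexed (grey level i, magnitude j):
# run length, zone size, zone distance or dependence count.
weighted_sums <- function(M) {
  Ns <- sum(M)
  i <- row(M); j <- col(M)
  ri <- rowSums(M); cj <- colSums(M)
  jj <- seq_len(ncol(M)); ii <- seq_len(nrow(M))
  list(N = Ns, i = i, j = j, ri = ri, cj = cj, ii = ii, jj = jj,
       low_j = sum(M / col(M)^2) / Ns,
       high_j = sum(M * col(M)^2) / Ns,
       low_i = sum(M / row(M)^2) / Ns,
       high_i = sum(M * row(M)^2) / Ns,
       gln = sum(ri^2) / Ns, glnn = sum(ri^2) / Ns^2,
       jn = sum(cj^2) / Ns, jnn = sum(cj^2) / Ns^2)
}

#' @rdname texture_features
#' @export
glrlm_features <- function(m) {
  stopifnot(m$family == "GLRLM")
  per_dir <- lapply(m$matrices, function(M) glrlm_features_one(M, m$n_voxels))
  rowMeans(do.call(cbind, per_dir))
}

glrlm_features_one <- function(M, n_vox) {
  w <- weighted_sums(M)
  c(GLRLM_SRE = w$low_j, GLRLM_LRE = w$high_j,
    GLRLM_GLN = w$gln, GLRLM_RLN = w$jn,
    GLRLM_RP = w$N / n_vox,
    GLRLM_LGRE = w$low_i, GLRLM_HGRE = w$high_i,
    GLRLM_SRLGE = sum(M / (row(M)^2 * col(M)^2)) / w$N,
    GLRLM_SRHGE = sum(M * row(M)^2 / col(M)^2) / w$N,
    GLRLM_LRLGE = sum(M * col(M)^2 / row(M)^2) / w$N,
    GLRLM_LRHGE = sum(M * row(M)^2 * col(M)^2) / w$N)
}

#' @rdname texture_features
#' @export
glszm_features <- function(m) {
  stopifnot(m$family == "GLSZM")
  M <- m$matrix
  w <- weighted_sums(M)
  P <- M / w$N
  mu_z <- sum(col(M) * P)
  pos <- P > 0
  c(GLSZM_SZE = w$low_j, GLSZM_LZE = w$high_j,
    GLSZM_GLN = w$gln, GLSZM_GLNN = w$glnn,
    GLSZM_ZSN = w$jn, GLSZM_ZSNN = w$jnn,
    GLSZM_ZP = w$N / m$n_voxels,
    GLSZM_LGZE = w$low_i, GLSZM_HGZE = w$high_i,
    GLSZM_ZSV = sum(P * (col(M) - mu_z)^2),
    GLSZM_ZSE = -sum(P[pos] * log2(P[pos])))
}

#' @rdname texture_features
#' @export
gldzm_features <- function(m) {
  stopifnot(m$family == "GLDZM")
  M <- m$matrix
  w <- weighted_sums(M)
  P <- M / w$N
  mu_d <- sum(col(M) * P)
  pos <- P > 0
  c(GLDZM_SDE = w$low_j, GLDZM_LDE = w$high_j,
    GLDZM_GLN = w$gln, GLDZM_GLNN = w$glnn,
    GLDZM_DZN = w$jn, GLDZM_DZNN = w$jnn,
    GLDZM_ZP = w$N / m$n_voxels,
    GLDZM_LGZE = w$low_i, GLDZM_HGZE = w$high_i,
    GLDZM_DZV = sum(P * (col(M) - mu_d)^2),
    GLDZM_DZE = -sum(P[pos] * log2(P[pos])))
}

#' @rdname texture_features
#' @export
ngldm_features <- function(m) {
  stopifnot(m$family == "NGLDM")
  M <- m$matrix
  w <- weighted_sums(M)
  P <- M / w$N
  mu_j <- sum(col(M) * P)
  pos <- P > 0
  c(NGLDM_LDE = w$low_j, NGLDM_HDE = w$high_j,
    NGLDM_GLN = w$gln, NGLDM_DN = w$jn, NGLDM_DNN = w$jnn,
    NGLDM_LGCE = w$low_i, NGLDM_HGCE = w$high_i,
    NGLDM_DV = sum(P * (col(M) - mu_j)^2),
    NGLDM_DE = -sum(P[pos] * log2(P[pos])))
}

#' @rdname texture_features
#' @param eps Stabilizer in the coarseness denominator (default 1e-6).
#' @export
ngtdm_features <- function(m, eps = 1e-6) {
  stopifnot(m$family == "NGTDM")
  s <- m$s; n <- m$n
  N <- sum(n)
  if (N == 0) {
    return(c(NGTDM_coarseness = 1 / eps, NGTDM_contrast = 0,
             NGTDM_busyness = 0, NGTDM_complexity = 0, NGTDM_strength = 0))
  }
  p <- n / N
  act <- which(p > 0)
  ngp <- length(act)
  coarse <- 1 / (sum(p * s) + eps)
  if (ngp > 1) {
    ii <- act
    pij2 <- outer(p[ii], p[ii])
    d2 <- outer(ii, ii, function(a, b) (a - b)^2)
    contrast <- (sum(pij2 * d2) / (ngp * (ngp - 1))) * (sum(s) / N)
    ip <- ii * p[ii]
    denom_busy <- sum(abs(outer(ip, ip, `-`)))
    busy <- if (denom_busy > 0) sum(p * s) / denom_busy else 0
    psps <- outer(p[ii] * s[ii], p[ii] * s[ii], `+`)
    pp <- outer(p[ii], p[ii], `+`)
    dd <- abs(outer(ii, ii, `-`))
    complexity <- sum(dd * psps / pp) / N
    strength <- sum(outer(p[ii], p[ii], `+`) * d2) / (sum(s) + eps)
  } else {
    contrast <- 0; busy <- 0; complexity <- 0; strength <- 0
  }
  c(NGTDM_coarseness = coarse, NGTDM_contrast = contrast,
    NGTDM_busyness = busy, NGTDM_complexity = complexity,
    NGTDM_strength = strength)
}
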