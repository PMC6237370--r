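test_that("GLCM on the 2x2 worked example gives the known symmetric counts", {
  lv <- array(NA_integer_, c(2, 2, 1))
  lv[, , 1] <- matrix(c(1L, 2L, 1L, 2L), 2, 2)  # levels alternate along x
  d <- structure(list(levels = lv, n_levels = 2L), class = "discretized_roi")
  m <- compute_glcm(d, offsets = matrix(c(1L, 0L, 0L), 1))
  P <- m$matrices[[1]]
  # two (1,2) pairs counted symmetrically -> all mass off-diagonal
  expect_equal(P, matrix(c(0, 0.5, 0.5, 0), 2, 2))
})

test_that("GLCM of a constant ROI is the single-entry matrix; contrast 0", {
  d <- discretize(array(3, c(3, 3, 3)), array(TRUE, c(3, 3, 3)))
  m <- compute_glcm(d)
  expect_true(all(vapply(m$matrices, function(P) identical(dim(P), c(1L, 1L)),
                         logical(1))))
  f <- glcm_features(m)
  expect_equal(f[["GLCM_contrast"]], 0)
  expect_equal(f[["GLCM_energy"]], 1)
  expect_equal(f[["GLCM_correl1"]], 1)  # documented degenerate fallback
})

test_that("each GLCM direction matrix is symmetric and normalized", {
  d <- random_droi(c(5, 5, 4), n_levels = 4, seed = 14)
  m <- compute_glcm(d)
  for (P in m$matrices) {
    expect_equal(P, t(P))
    expect_equal(sum(P), 1, tolerance = 1e-12)
  }
})

test_that("GLRLM matches run examples: 1D runs and full-ROI constant run", {
  lv <- array(NA_integer_, c(4, 1, 1))
  lv[, 1, 1] <- c(1L, 1L, 1L, 2L)
  d <- structure(list(levels = lv, n_levels = 2L), class = "discretized_roi")
  m <- compute_glrlm(d, offsets = matrix(c(1L, 0L, 0L), 1))
  M <- m$matrices[[1]]
  expect_equal(M[1, 3], 1)  # run (level 1, length 3)
  expect_equal(M[2, 1], 1)  # run (level 2, length 1)
  expect_equal(sum(M), 2)

  # constant line of N voxels: single run of length N along the axis
  lvc <- array(1L, c(6, 1, 1))
  dc <- structure(list(levels = lvc, n_levels = 1L), class = "discretized_roi")
  mc <- compute_glrlm(dc, offsets = matrix(c(1L, 0L, 0L), 1))
  expect_equal(mc$matrices[[1]][1, 6], 1)
  expect_equal(sum(mc$matrices[[1]]), 1)
})

test_that("run percentage lies in (0, 1] for random ROIs", {
  for (s in 1:5) {
    d <- random_droi(c(5, 4, 3), n_levels = 3, seed = s)
    f <- glrlm_features(compute_glrlm(d))
    expect_gt(f[["GLRLM_RP"]], 0)
    expect_lte(f[["GLRLM_RP"]], 1)
  }
})

test_that("GLSZM: constant connected ROI is one zone; ZP bounded", {
  d <- discretize(array(2, c(4, 4, 2)), array(TRUE, c(4, 4, 2)))
  m <- compute_glszm(d)
  expect_equal(dim(m$matrix), c(1L, 32L))
  expect_equal(m$matrix[1, 32], 1)  # one zone of size 32
  f <- glszm_features(m)
  expect_equal(f[["GLSZM_ZP"]], 1 / 32)

  for (s in 1:5) {
    dr <- random_droi(c(4, 4, 4), n_levels = 4, seed = s + 30)
    fr <- glszm_features(compute_glszm(dr))
    expect_gt(fr[["GLSZM_ZP"]], 0)
    expect_lte(fr[["GLSZM_ZP"]], 1)
  }
})

test_that("3x3 checkerboard zones follow 26-connectivity (diagonals connect)", {
  lv <- array(NA_integer_, c(3, 3, 1))
  lv[, , 1] <- matrix(c(1L, 2L, 1L, 2L, 1L, 2L, 1L, 2L, 1L), 3, 3)
  d <- structure(list(levels = lv, n_levels = 2L), class = "discretized_roi")
  M <- compute_glszm(d)$matrix
  # diagonal same-level cells connect: one 5-voxel zone of level 1,
  # one 4-voxel zone of level 2 (in-plane diagonal adjacency)
  expect_equal(M, oracle_glszm(lv))
  expect_equal(M[1, 5], 1)
  expect_equal(M[2, 4], 1)
})

test_that("GLDZM: single voxel and centred cube have border distance 1", {
  lv1 <- array(NA_integer_, c(3, 3, 3)); lv1[2, 2, 2] <- 1L
  d1 <- structure(list(levels = lv1, n_levels = 1L), class = "discretized_roi")
  M1 <- compute_gldzm(d1)$matrix
  expect_equal(M1[1, 1], 1)
  f1 <- gldzm_features(compute_gldzm(d1))
  expect_equal(f1[["GLDZM_SDE"]], 1)
  expect_equal(f1[["GLDZM_LDE"]], 1)

  # 5^3 constant cube filling the grid: one zone, min border distance 1
  lv2 <- array(1L, c(5, 5, 5))
  d2 <- structure(list(levels = lv2, n_levels = 1L), class = "discretized_roi")
  M2 <- compute_gldzm(d2)$matrix
  expect_equal(M2, oracle_gldzm(lv2))
  expect_equal(M2[1, 1], 1)
  expect_equal(sum(M2), 1)
})

test_that("SDE <= 1 <= LDE with equality when all zones sit at distance 1", {
  for (s in 1:5) {
    d <- random_droi(c(4, 4, 4), n_levels = 3, seed = s + 60)
    f <- gldzm_features(compute_gldzm(d))
    expect_lte(f[["GLDZM_SDE"]], 1 + 1e-12)
    expect_gte(f[["GLDZM_LDE"]], 1 - 1e-12)
  }
  # thin slab: every voxel touches the border, all zone distances are 1
  lv <- array(1L, c(4, 4, 1))
  d <- structure(list(levels = lv, n_levels = 1L), class = "discretized_roi")
  f <- gldzm_features(compute_gldzm(d))
  expect_equal(f[["GLDZM_SDE"]], 1)
  expect_equal(f[["GLDZM_LDE"]], 1)
})

test_that("NGLDM dependence counts match hand examples", {
  # constant 3x3x3: centre voxel has all 26 neighbours dependent
  lv <- array(1L, c(3, 3, 3))
  d <- structure(list(levels = lv, n_levels = 1L), class = "discretized_roi")
  M <- compute_ngldm(d)$matrix
  expect_equal(M[1, 27], 1)  # k = 26 -> column 27
  expect_equal(sum(M), 27)

  # two isolated same-level voxels: each depends on the other
  lv2 <- array(NA_integer_, c(3, 1, 1)); lv2[c(1, 2), 1, 1] <- 1L
  d2 <- structure(list(levels = lv2, n_levels = 1L), class = "discretized_roi")
  M2 <- compute_ngldm(d2)$matrix
  expect_equal(M2[1, 2], 2)  # both voxels have dependence 1
})

test_that("NGTDM: constant ROI has zero differences and capped coarseness", {
  d <- discretize(array(4, c(3, 3, 3)), array(TRUE, c(3, 3, 3)))
  m <- compute_ngtdm(d)
  expect_equal(sum(m$s), 0)
  f <- ngtdm_features(m)
  expect_equal(f[["NGTDM_coarseness"]], 1e6)  # 1/eps cap
})

test_that("NGTDM s-values for a two-level 1D alternation match hand computation", {
  lv <- array(NA_integer_, c(5, 1, 1))
  lv[, 1, 1] <- c(1L, 2L, 1L, 2L, 1L)
  d <- structure(list(levels = lv, n_levels = 2L), class = "discretized_roi")
  m <- compute_ngtdm(d)
  o <- oracle_ngtdm(lv)
  expect_equal(m$s, o$s)
  expect_equal(m$n, o$n)
  # by hand: ends see one neighbour (2), |1-2| = 1 each; middle 1 sees (2,2)
  # -> s(1) = 1 + 1 + 1 = 3; each 2 sees two 1s -> s(2) = 1 + 1 = 2
  expect_equal(m$s, c(3, 2))
})

test_that("coarseness decreases monotonically with relative noise amplitude", {
  # structured phantom (smooth ramp) plus increasing voxel noise: the finer
  # the voxel-scale variation relative to the structure, the lower the
  # coarseness after ROI-relative discretization
  set.seed(77)
  dims <- c(8, 8, 4)
  ramp <- outer(outer(seq(0, 40, length.out = dims[1]), rep(1, dims[2])),
                rep(1, dims[3]))
  mask <- array(TRUE, dims)
  noise <- array(rnorm(prod(dims)), dims)
  coarse_at <- vapply(c(0.5, 4, 16), function(amp) {
    d <- discretize(ramp + amp * noise, mask, n_bins = 8)
    ngtdm_features(compute_ngtdm(d))[["NGTDM_coarseness"]]
  }, numeric(1))
  expect_true(all(diff(coarse_at) < 0))
})

test_that("all six builders agree exactly with brute-force oracles on random ROIs", {
  offs <- offsets_13()
  for (s in 1:20) {
    d <- random_droi(c(4, 4, 4), n_levels = sample(2:4, 1), seed = s)
    lv <- d$levels
    ng <- d$n_levels

    k <- (s %% 13) + 1
    pr <- compute_glcm(d, offsets = offs[k, , drop = FALSE])$matrices[[1]]
    o <- oracle_glcm(lv, offs[k, ])
    o_pad <- matrix(0, ng, ng); o_pad[seq_len(nrow(o)), seq_len(ncol(o))] <- o
    expect_equal(pr * sum(o_pad), o_pad, tolerance = 1e-12)

    Mr <- compute_glrlm(d, offsets = offs[k, , drop = FALSE])$matrices[[1]]
    Mo <- oracle_glrlm(lv, offs[k, ])
    expect_equal(Mr[seq_len(nrow(Mo)), seq_len(ncol(Mo)), drop = FALSE], Mo)
    expect_equal(sum(Mr), sum(Mo))

    expect_equal(compute_glszm(d)$matrix[seq_len(ng), , drop = FALSE],
                 rbind(oracle_glszm(lv),
                       matrix(0, ng - nrow(oracle_glszm(lv)),
                              ncol(oracle_glszm(lv)))))

    expect_equal(compute_gldzm(d)$matrix, {
      o <- oracle_gldzm(lv)
      rbind(o, matrix(0, ng - nrow(o), ncol(o)))
    })

    expect_equal(compute_ngldm(d)$matrix, {
      o <- oracle_ngldm(lv)
      rbind(o, matrix(0, ng - nrow(o), ncol(o)))
    })

    m <- compute_ngtdm(d); o <- oracle_ngtdm(lv)
    expect_equal(m$s[seq_along(o$s)], o$s)
    expect_equal(m$n[seq_along(o$n)], o$n)
  }
})

test_that("counts are non-negative and integral before normalization", {
  for (s in 1:5) {
    d <- random_droi(c(4, 4, 4), n_levels = 4, seed = 100 + s)
    for (M in list(compute_glszm(d)$matrix, compute_gldzm(d)$matrix,
                   compute_ngldm(d)$matrix,
                   compute_glrlm(d)$matrices[[1]])) {
      expect_true(all(M >= 0))
      expect_equal(M, round(M))
    }
  }
})

test_that("direction-averaged texture features are invariant to mask translation", {
  set.seed(55)
  vals <- rnorm(4 * 4 * 3, 50, 10)
  a1 <- array(NA_real_, c(10, 10, 8)); a2 <- a1
  m1 <- array(FALSE, c(10, 10, 8)); m2 <- m1
  a1[2:5, 2:5, 2:4] <- vals; m1[2:5, 2:5, 2:4] <- TRUE
  a2[5:8, 4:7, 4:6] <- vals; m2[5:8, 4:7, 4:6] <- TRUE
  a1[!m1] <- 0; a2[!m2] <- 0
  d1 <- discretize(a1, m1, n_bins = 8); d2 <- discretize(a2, m2, n_bins = 8)
  expect_equal(glcm_features(compute_glcm(d1)), glcm_features(compute_glcm(d2)))
  expect_equal(glrlm_features(compute_glrlm(d1)), glrlm_features(compute_glrlm(d2)))
  expect_equal(glszm_features(compute_glszm(d1)), glszm_features(compute_glszm(d2)))
})
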