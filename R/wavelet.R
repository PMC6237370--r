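#' 3D stationary wavelet sub-bands
#'
#' Single-level undecimated (stationary) separable 3D wavelet transform.
#' Low- and high-pass analysis filters are applied along x, y and z in all
#' eight combinations, producing sub-band volumes LLL, LLH, LHL, LHH, HLL,
#' HLH, HHL and HHH on the same grid as the input, so the original lesion
#' mask applies unchanged to every band. Band labels give the filter per
#' axis in (x, y, z) order, `L` = low-pass, `H` = high-pass. Boundaries use
#' symmetric (mirror) extension, so ROIs thinner than the filter support
#' are handled without failure.
#'
#' @param vol An [image_volume()] or 3D numeric array.
#' @param wavelet Filter name: `"coif1"` (default), `"haar"` or `"db2"`.
#' @return Named list of eight 3D arrays (`LLL` ... `HHH`).
#' @export
wavelet_bands <- function(vol, wavelet = "coif1") {
  data <- if (inherits(vol, "image_volume")) vol$data else as.array(vol)
  f <- wavelet_filters(wavelet)
  bands <- list()
  labels <- c("L", "H")
  fx <- list(L = conv_axis(data, f$lo, 1), H = conv_axis(data, f$hi, 1))
  for (bx in labels) {
    fy <- list(L = conv_axis(fx[[bx]], f$lo, 2), H = conv_axis(fx[[bx]], f$hi, 2))
    for (by in labels) {
      for (bz in labels) {
        h <- if (bz == "L") f$lo else f$hi
        bands[[paste0(bx, by, bz)]] <- conv_axis(fy[[by]], h, 3)
      }
    }
  }
  bands[c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")]
}

#' Wavelet analysis filter pairs
#'
#' @param name One of `"coif1"`, `"haar"`, `"db2"`.
#' @return List with low-pass `lo` and high-pass `hi` analysis filters.
#' @export
wavelet_filters <- function(name = c("coif1", "haar", "db2")) {
  name <- match.arg(name)
  lo <- switch(name,
    coif1 = c(-0.015655728135791993, -0.07273261951252645, 0.3848648468648578,
              0.8525720202116004, 0.3378976624574818, -0.07273261951252645),
    haar = c(1, 1) / sqrt(2),
    db2 = c(0.48296291314469025, 0.836516303737469, 0.22414386804185735,
            -0.12940952255092145)
  )
  n <- length(lo)
  hi <- rev(lo) * (-1)^(seq_len(n) - 1)
  list(lo = lo, hi = hi, length = n)
}

# Map any integer position onto 1..n by half-sample symmetric reflection.
reflect_index <- function(p, n) {
  if (n == 1) return(rep(1L, length(p)))
  q <- (p - 1) %% (2 * n)
  as.integer(ifelse(q < n, q + 1, 2 * n - q))
}

# Same-size 1D convolution along axis `ax` with symmetric boundary
# extension; the output is centred so a symmetric filter is zero-phase up to
# the half-sample offset inherent to even-length filters.
conv_axis <- function(a, h, ax) {
  dims <- dim(a)
  n <- dims[ax]
  L <- length(h)
  lpad <- L %/% 2
  rpad <- L - 1 - lpad
  # half-sample symmetric extension indices (periodic reflection, so axes
  # thinner than the filter support still work)
  idx <- reflect_index(seq.int(1 - lpad, n + rpad), n)
  # bring target axis first
  perm <- c(ax, setdiff(1:3, ax))
  ap <- aperm(a, perm)
  dp <- dim(ap)
  mat <- matrix(ap, nrow = dp[1])
  padded <- mat[idx, , drop = FALSE]
  out <- matrix(0, nrow = n, ncol = ncol(mat))
  for (k in seq_len(L)) {
    out <- out + h[k] * padded[(L - k) + seq_len(n), , drop = FALSE]
  }
  dim(out) <- dp
  aperm(out, order(perm))
}
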