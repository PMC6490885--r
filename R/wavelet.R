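# Periodized 2-D orthogonal discrete wavelet transform.
#
# The cyclic image-scrambling stimulus needs a transform in which every
# detail coefficient can be rotated and the frame recovered exactly, so the
# filter bank must be orthogonal to machine precision.  The least-asymmetric
# Daubechies filter with 8 vanishing moments (sym8) is used: it is smooth,
# near-symmetric and exactly orthogonal, unlike truncated FIR approximations
# of band-limited wavelets.

# sym8 scaling (low-pass analysis) filter, standard published coefficients.
.sym8_dec_lo <- c(
  -0.0033824159510061256, -0.00054213233179114812, 0.031695087811492981,
  0.0076074873249176054, -0.14329423835080971, -0.061273359067658524,
  0.48135965125837221, 0.77718575170052351, 0.3644418948353314,
  -0.051945838107709037, -0.027219029917056003, 0.049137179673607506,
  0.0038087520138906151, -0.014952258337048231, -0.0003029205147213668,
  0.0018899503327594609)

#' One-level periodized analysis matrix
#'
#' Builds the orthogonal `n x n` matrix whose first `n/2` rows compute the
#' circularly-periodized low-pass (approximation) branch and whose last `n/2`
#' rows compute the high-pass (detail) branch.  Filter taps that wrap past
#' the signal length fold back additively, which preserves orthogonality.
#'
#' @param n signal length (even).
#' @return an `n x n` orthogonal matrix.
#' @keywords internal
dwt_matrix <- function(n) {
  stopifnot(n >= 2, n %% 2 == 0)
  h <- .sym8_dec_lo
  L <- length(h)
  g <- rev(h) * (-1)^(seq_len(L) - 1)  # quadrature mirror high-pass
  W <- matrix(0, n, n)
  half <- n / 2
  for (k in seq_len(half)) {
    idx <- ((2 * (k - 1) + seq_len(L) - 1) %% n) + 1
    for (j in seq_len(L)) {
      W[k, idx[j]] <- W[k, idx[j]] + h[j]
      W[half + k, idx[j]] <- W[half + k, idx[j]] + g[j]
    }
  }
  W
}

.dwt_matrix_cache <- new.env(parent = emptyenv())

dwt_matrix_cached <- function(n) {
  key <- as.character(n)
  if (is.null(.dwt_matrix_cache[[key]]))
    .dwt_matrix_cache[[key]] <- dwt_matrix(n)
  .dwt_matrix_cache[[key]]
}

#' Multi-level 2-D periodized wavelet decomposition
#'
#' @param x numeric matrix; both dimensions must be divisible by `2^levels`.
#' @param levels decomposition depth (default 6).
#' @return a list with `approx` (deepest approximation matrix) and `detail`,
#'   a list (finest level first) of lists with `lh`, `hl`, `hh` matrices.
#' @export
wavedec2 <- function(x, levels = 6L) {
  stopifnot(is.matrix(x), is.numeric(x))
  if (levels < 1L) stop("`levels` must be >= 1")
  if (any(dim(x) %% 2^levels != 0))
    stop(sprintf("image dimensions %dx%d are not divisible by 2^%d; pad first",
                 nrow(x), ncol(x), levels))
  detail <- vector("list", levels)
  a <- x
  for (l in seq_len(levels)) {
    Wr <- dwt_matrix_cached(nrow(a))
    Wc <- dwt_matrix_cached(ncol(a))
    y <- Wr %*% a %*% t(Wc)
    hr <- nrow(a) / 2
    hc <- ncol(a) / 2
    detail[[l]] <- list(
      lh = y[seq_len(hr), hc + seq_len(hc), drop = FALSE],
      hl = y[hr + seq_len(hr), seq_len(hc), drop = FALSE],
      hh = y[hr + seq_len(hr), hc + seq_len(hc), drop = FALSE])
    a <- y[seq_len(hr), seq_len(hc), drop = FALSE]
  }
  structure(list(approx = a, detail = detail, levels = levels),
            class = "wavedec2")
}

#' Inverse of [wavedec2()]
#'
#' @param w a `wavedec2` object.
#' @return the reconstructed numeric matrix.
#' @export
waverec2 <- function(w) {
  stopifnot(inherits(w, "wavedec2"))
  a <- w$approx
  for (l in rev(seq_len(w$levels))) {
    d <- w$detail[[l]]
    hr <- nrow(a); hc <- ncol(a)
    y <- rbind(cbind(a, d$lh), cbind(d$hl, d$hh))
    Wr <- dwt_matrix_cached(2 * hr)
    Wc <- dwt_matrix_cached(2 * hc)
    a <- t(Wr) %*% y %*% Wc
  }
  a
}

#' Pad an image to dimensions compatible with a wavelet depth
#'
#' Pads symmetrically (edge reflection) so that both dimensions become the
#' next multiple of `2^levels`.
#'
#' @param x numeric matrix.
#' @param levels wavelet depth the result must support.
#' @return list with `pixels` (padded matrix) and `rows`, `cols` (the index
#'   ranges of the original image inside the padded one).
#' @export
pad_to_dyadic <- function(x, levels = 6L) {
  m <- 2^levels
  nr <- ceiling(nrow(x) / m) * m
  nc <- ceiling(ncol(x) / m) * m
  top <- floor((nr - nrow(x)) / 2)
  left <- floor((nc - ncol(x)) / 2)
  ridx <- pmin(pmax(seq_len(nr) - top, 1), nrow(x))
  cidx <- pmin(pmax(seq_len(nc) - left, 1), ncol(x))
  list(pixels = x[ridx, cidx, drop = FALSE],
       rows = top + seq_len(nrow(x)), cols = left + seq_len(ncol(x)))
}
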