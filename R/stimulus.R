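# SWIFT stimulus synthesis: cyclic wavelet-domain scrambling.
#
# A SWIFT sequence is a loop of frames obtained by rotating each local
# wavelet-detail coefficient vector along a circle on the sphere of its own
# norm.  Contour information (the joint orientation of the three detail
# subband coefficients at each location/scale) is destroyed smoothly while
# local luminance, contrast and spatial-frequency content are conserved,
# because every coefficient vector keeps its norm and the deep approximation
# coefficients are untouched.  The original image reappears exactly once per
# cycle, at the peak frame (rotation angle zero).

#' Create a cyclic SWIFT scramble of an image
#'
#' Decomposes `image` with a `levels`-deep orthogonal 2-D wavelet transform,
#' then, at every detail location and scale, rotates the 3-vector of
#' (horizontal, vertical, diagonal) coefficients along the circle passing
#' through the original vector and two random vectors of identical norm.
#' Frame `k` uses rotation angle `2*pi*(k - peak_index)/n_frames`, so the
#' sequence is cyclic and frame `peak_index` reconstructs the source image.
#'
#' @param image numeric matrix with values in `[0, 1]`; both dimensions must
#'   be divisible by `2^levels` (use [pad_to_dyadic()] otherwise).
#' @param n_frames number of frames in one cycle (>= 3).
#' @param levels wavelet decomposition depth; default 6.
#' @param rng_seed integer seed for the random path vectors.
#' @param peak_index frame at which the original image appears; default is
#'   the middle frame `floor(n_frames/2) + 1`.
#' @param variant_id integer tag in `{0, 1, 2}` identifying which of the
#'   alternating scramble variants this sequence realises (metadata only).
#' @return a `swift_sequence`: list with `frames` (list of matrices),
#'   `peak_index`, `anchor_index` (frame at path angle pi from the peak, the
#'   most-scrambled frame used to seed noise sequences), `variant_id`,
#'   `n_frames`, `levels` and `source_mean`.
#' @export
swift_scramble <- function(image, n_frames, levels = 6L, rng_seed = 1L,
                           peak_index = NULL, variant_id = 0L) {
  stopifnot(is.matrix(image), is.numeric(image))
  if (anyNA(image)) stop("`image` contains missing values")
  if (levels < 1L) stop("`levels` must be >= 1")
  if (n_frames < 3L) stop("`n_frames` must be >= 3")
  if (any(dim(image) %% 2^levels != 0))
    stop(sprintf(
      "image dimensions %dx%d incompatible with %d decomposition levels",
      nrow(image), ncol(image), levels))
  if (is.null(peak_index)) peak_index <- floor(n_frames / 2) + 1L
  stopifnot(peak_index >= 1L, peak_index <= n_frames)

  w <- wavedec2(image, levels)
  # stack every detail 3-vector as one row of M
  M <- do.call(rbind, lapply(w$detail, function(d)
    cbind(as.vector(d$lh), as.vector(d$hl), as.vector(d$hh))))
  path <- local({
    set.seed(rng_seed)
    circular_paths(M)
  })

  theta <- 2 * pi * (seq_len(n_frames) - peak_index) / n_frames
  frames <- lapply(theta, function(th) {
    P <- path$centre +
      path$rho * (cos(th) * path$e1 + sin(th) * path$e2)
    waverec2(rebuild_details(w, P))
  })
  anchor_index <- ((peak_index - 1L + round(n_frames / 2)) %% n_frames) + 1L
  structure(list(frames = frames, peak_index = peak_index,
                 anchor_index = anchor_index, variant_id = variant_id,
                 n_frames = n_frames, levels = levels,
                 source_mean = mean(image)),
            class = "swift_sequence")
}

# Circle through each row of M and two random vectors of the same norm.
# Returns centre, radius rho and an in-plane orthonormal basis (e1, e2) per
# row, with e1 pointing at the original vector (angle 0).  Rows with
# (near-)zero norm get a degenerate constant path.
circular_paths <- function(M, tol = 1e-12) {
  n <- nrow(M)
  r <- sqrt(rowSums(M^2))
  live <- r > tol
  centre <- matrix(0, n, 3)
  e1 <- matrix(0, n, 3)
  e2 <- matrix(0, n, 3)
  rho <- numeric(n)
  if (any(live)) {
    V0 <- M[live, , drop = FALSE]
    rl <- r[live]
    m <- nrow(V0)
    draw <- function() {
      B <- matrix(stats::rnorm(3 * m), m, 3)
      B / sqrt(rowSums(B^2)) * rl
    }
    V1 <- draw(); V2 <- draw()
    cross <- function(a, b) cbind(
      a[, 2] * b[, 3] - a[, 3] * b[, 2],
      a[, 3] * b[, 1] - a[, 1] * b[, 3],
      a[, 1] * b[, 2] - a[, 2] * b[, 1])
    repeat {
      nv <- cross(V1 - V0, V2 - V0)
      bad <- sqrt(rowSums(nv^2)) < 1e-9 * rl^2
      if (!any(bad)) break
      B <- matrix(stats::rnorm(3 * sum(bad)), sum(bad), 3)
      V1[bad, ] <- B / sqrt(rowSums(B^2)) * rl[bad]
      B <- matrix(stats::rnorm(3 * sum(bad)), sum(bad), 3)
      V2[bad, ] <- B / sqrt(rowSums(B^2)) * rl[bad]
    }
    # circumcentre of (V0, V1, V2); all three lie on the sphere of radius
    # rl, so the circle lies on that sphere and norms are conserved
    u1 <- V1 - V0; u2 <- V2 - V0
    nv <- cross(u1, u2)
    n2 <- rowSums(nv^2)
    cc <- V0 + cross(rowSums(u1^2) * u2 - rowSums(u2^2) * u1, nv) / (2 * n2)
    rad <- V0 - cc
    rh <- sqrt(rowSums(rad^2))
    b1 <- rad / rh
    nh <- nv / sqrt(n2)
    b2 <- cross(nh, b1)
    centre[live, ] <- cc
    e1[live, ] <- b1
    e2[live, ] <- b2
    rho[live] <- rh
  }
  list(centre = centre, e1 = e1, e2 = e2, rho = rho)
}

# Scatter rotated coefficient rows P back into the wavedec2 structure.
rebuild_details <- function(w, P) {
  off <- 0L
  for (l in seq_along(w$detail)) {
    d <- w$detail[[l]]
    nloc <- length(d$lh)
    rows <- off + seq_len(nloc)
    w$detail[[l]]$lh[] <- P[rows, 1]
    w$detail[[l]]$hl[] <- P[rows, 2]
    w$detail[[l]]$hh[] <- P[rows, 3]
    off <- off + nloc
  }
  w
}

#' Noise sequence matched to a SWIFT sequence
#'
#' Applies the SWIFT scramble to the most-scrambled (anchor) frame of an
#' existing sequence, producing a cyclic sequence that shares its low-level
#' statistics but never resolves into the original image.  Used to replace
#' image cycles while keeping the low-level visual drive constant.
#'
#' @param seq a `swift_sequence`.
#' @param n_frames frames per cycle for the noise sequence; defaults to the
#'   source sequence's frame count.
#' @param rng_seed integer seed.
#' @return a `swift_sequence` whose peak frame is the anchor frame of `seq`.
#' @export
make_noise_sequence <- function(seq, n_frames = seq$n_frames, rng_seed = 1L) {
  stopifnot(inherits(seq, "swift_sequence"))
  swift_scramble(seq$frames[[seq$anchor_index]], n_frames,
                 levels = seq$levels, rng_seed = rng_seed,
                 variant_id = seq$variant_id)
}

#' Build the three alternating scramble variants of one image
#'
#' Sequence variants share the same peak image but follow different random
#' scrambling paths; alternating between them across cycles prevents the
#' scrambled in-between frames themselves from frequency-tagging low-level
#' features.  Variant swaps happen at the peak frame when the same image
#' recurs, and at the anchor frame when the category changes.
#'
#' @inheritParams swift_scramble
#' @return list of three `swift_sequence`s with `variant_id` 0, 1, 2.
#' @export
swift_variant_set <- function(image, n_frames, levels = 6L, rng_seed = 1L) {
  lapply(0:2, function(v)
    swift_scramble(image, n_frames, levels = levels,
                   rng_seed = rng_seed + v, variant_id = v))
}

#' Alpha-blend two frame sequences with equal weights
#'
#' @param a,b lists of equally sized numeric matrices.
#' @return list of matrices `0.5*a + 0.5*b`.
#' @export
alpha_blend <- function(a, b) {
  if (length(a) != length(b)) stop("frame counts differ")
  Map(function(x, y) {
    if (!identical(dim(x), dim(y))) stop("frame dimensions differ")
    0.5 * x + 0.5 * y
  }, a, b)
}

#' Sinusoidal contrast modulation of a frame sequence
#'
#' Scales each frame's contrast about its own mean by
#' `c(t) = lo + (hi - lo) * (1 + cos(2*pi*f*t)) / 2`, i.e. full contrast at
#' `t = 0` (the phase convention every stimulus-referenced analysis assumes)
#' and minimum contrast `lo` at `t = 1/(2*f)`.
#'
#' @param frames list of numeric matrices presented at `frame_rate`.
#' @param ssvep_freq contrast-modulation frequency in Hz.
#' @param frame_rate presentation rate in Hz (default 120).
#' @param bounds numeric `(lo, hi)` contrast fractions, default
#'   `c(0.30, 1.00)`.
#' @param t0 time of the first frame in seconds (default 0).
#' @return list of contrast-scaled matrices.
#' @export
contrast_modulate <- function(frames, ssvep_freq, frame_rate = 120,
                              bounds = c(0.30, 1.00), t0 = 0) {
  lo <- bounds[1]; hi <- bounds[2]
  if (lo > hi || lo < 0 || hi > 1)
    stop("`bounds` must satisfy 0 <= lo <= hi <= 1")
  if (frame_rate <= 2 * ssvep_freq)
    stop(sprintf(
      "frame_rate %g Hz cannot render a %g Hz contrast modulation (aliasing)",
      frame_rate, ssvep_freq))
  t <- t0 + (seq_along(frames) - 1) / frame_rate
  ct <- lo + (hi - lo) * (1 + cos(2 * pi * ssvep_freq * t)) / 2
  Map(function(fr, s) mean(fr) + s * (fr - mean(fr)), frames, ct)
}
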