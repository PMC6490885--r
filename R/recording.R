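# Multichannel EEG container and an idealised 10-10 montage.

#' Construct an EEG recording
#'
#' @param data numeric channels x samples matrix, in microvolts.
#' @param fs sampling rate in Hz.
#' @param channel_labels character vector, one 10-10 name per row of `data`.
#' @param channel_positions optional channels x 3 matrix of unit-sphere
#'   coordinates; computed from `channel_labels` via [montage_1010()] when
#'   labels are recognised and this is `NULL`.
#' @param events data frame with columns `sample`, `label` (may be empty).
#' @return an `eeg_recording` object.
#' @export
eeg_recording <- function(data, fs, channel_labels,
                          channel_positions = NULL,
                          events = data.frame(sample = integer(0),
                                              label = character(0))) {
  stopifnot(is.matrix(data), is.numeric(data), fs > 0)
  if (length(channel_labels) != nrow(data))
    stop("one channel label per data row is required")
  if (is.null(channel_positions)) {
    pos <- try(montage_1010(channel_labels), silent = TRUE)
    if (!inherits(pos, "try-error")) channel_positions <- pos
  }
  if (!is.null(channel_positions) &&
      nrow(channel_positions) != nrow(data))
    stop("one channel position per data row is required")
  structure(list(data = data, fs = fs, channel_labels = channel_labels,
                 channel_positions = channel_positions, events = events),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  invisible(x)
}

#' Idealised 10-10 electrode positions on the unit sphere
#'
#' Positions are generated geometrically from the label: the row letter
#' fixes the fraction of the nasion-inion arc and the electrode number fixes
#' the lateral rotation towards the ears in 18-degree steps (odd = left,
#' even = right).  This is an idealised spherical layout, adequate for
#' distance-based channel interpolation, not a digitised head model.
#'
#' @param labels character vector of 10-10 names (e.g. `"POz"`, `"P3"`).
#' @return a `length(labels) x 3` matrix of unit vectors
#'   (x = right, y = front, z = up).
#' @export
montage_1010 <- function(labels) {
  rows <- c(Fp = 0.1, AF = 0.2, F = 0.3, FC = 0.4, C = 0.5, CP = 0.6,
            P = 0.7, PO = 0.8, O = 0.9, T = 0.5, FT = 0.4, TP = 0.6,
            I = 1.0, N = 0.0)
  out <- matrix(NA_real_, length(labels), 3,
                dimnames = list(labels, c("x", "y", "z")))
  for (i in seq_along(labels)) {
    lab <- labels[i]
    m <- regmatches(lab, regexec("^([A-Za-z]+?)(z|[0-9]+)$", lab))[[1]]
    if (length(m) != 3 || !(m[2] %in% names(rows)))
      stop(sprintf("unrecognised 10-10 label: '%s'", lab))
    f <- rows[[m[2]]]
    if (m[3] == "z") {
      step <- 0L; side <- 1
    } else {
      num <- as.integer(m[3])
      # T7/T8 and FT/TP pairs sit at the outermost (ear-level) step
      step <- if (m[2] %in% c("T", "FT", "TP")) 4L else ceiling(num / 2)
      side <- if (num %% 2 == 1) -1 else 1   # odd = left
    }
    a <- (0.5 - f) * pi              # sagittal angle, positive = front
    p <- c(0, sin(a), cos(a))        # point on the midline
    g <- side * step * (18 * pi / 180)
    # rotate about the front-back (y) axis towards the ears
    out[i, ] <- c(p[1] * cos(g) + p[3] * sin(g), p[2],
                  -p[1] * sin(g) + p[3] * cos(g))
  }
  out
}
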