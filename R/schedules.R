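# Trial schedules: the stimulus timeline of one hierarchical
# frequency-tagging trial, and the stimulus phase references consumed by the
# stimulus-referenced coherence variant.

#' Construct a trial schedule
#'
#' Low-level constructor; use [build_exp1_schedule()] or
#' [build_exp2_schedule()] for the two experimental designs.
#'
#' @param cycles data frame with columns `category`, `swift_freq`, `onset`
#'   (seconds) and logical `is_noise`; one row per SWIFT cycle.  For
#'   dual-stream designs pass a list of two such data frames.
#' @param ssvep_freq contrast-modulation frequency in Hz.
#' @param duration trial duration in seconds.
#' @param target_index 1-based index of the target cycle, or `NA`.
#' @param task one of `"IR"`, `"PV"`, `"count_face"`, `"count_house"`,
#'   `"count_cross"`.
#' @param frame_rate presentation rate in Hz.
#' @param contrast_bounds contrast-modulation range, default `c(0.30, 1)`.
#' @param peak_frac position of the peak frame within a cycle as a fraction
#'   of the cycle length (default 0.5: mid-cycle).
#' @return a `trial_schedule` object.
#' @export
trial_schedule <- function(cycles, ssvep_freq, duration, target_index = NA,
                           task, frame_rate = 120,
                           contrast_bounds = c(0.30, 1.00),
                           peak_frac = 0.5) {
  streams <- if (is.data.frame(cycles)) list(cycles) else cycles
  for (s in streams) {
    stopifnot(all(c("category", "swift_freq", "onset", "is_noise") %in%
                    names(s)))
    if (nrow(s) > 1 && any(diff(s$onset) <= 0))
      stop("cycle onsets must be strictly increasing")
  }
  structure(list(streams = streams, ssvep_freq = ssvep_freq,
                 duration = duration, target_index = target_index,
                 task = task, frame_rate = frame_rate,
                 contrast_bounds = contrast_bounds, peak_frac = peak_frac),
            class = "trial_schedule")
}

#' SWIFT frequencies of a schedule
#' @param schedule a `trial_schedule`.
#' @return numeric vector, one frequency per image stream.
#' @export
swift_freqs <- function(schedule) {
  vapply(schedule$streams, function(s) s$swift_freq[1], numeric(1))
}

# first index at which `len` identical categories in a row are completed
first_run_index <- function(categories, len) {
  r <- rle(categories)
  ends <- cumsum(r$lengths)
  hit <- which(r$lengths >= len)
  if (!length(hit)) return(NA_integer_)
  # run may be longer than `len`; the target is reached `len` items in
  ends[hit[1]] - r$lengths[hit[1]] + len
}

#' Build an expectation-manipulation (Experiment-1 style) schedule
#'
#' One face and one house image alternate at a single SWIFT frequency
#' following a repeating pattern; at `violation_index` the category is
#' flipped.  In the pattern-violation (PV) task the observer knows the
#' pattern, so the flip is the target; in the image-repetition (IR) task the
#' same category series is watched for the first run of `ir_run_length`
#' identical images, which the flip creates.  A PV schedule and its paired
#' IR schedule therefore carry identical category series.
#'
#' @param pattern character vector (or single string) of `"F"`/`"H"`
#'   categories; length 5-6 for the PV task.
#' @param task `"PV"` or `"IR"`.
#' @param n_cycles total number of SWIFT cycles in the trial.
#' @param violation_index 1-based cycle at which the pattern is violated;
#'   must lie beyond two full pattern repetitions.
#' @param swift_freq SWIFT frequency in Hz (default 1.2).
#' @param ssvep_freq contrast-modulation frequency in Hz (default 15).
#' @param ir_run_length run length (3 or 4) defining the IR target.
#' @param frame_rate presentation rate in Hz.
#' @return a `trial_schedule`.
#' @export
build_exp1_schedule <- function(pattern, task = c("PV", "IR"), n_cycles,
                                violation_index, swift_freq = 1.2,
                                ssvep_freq = 15, ir_run_length = 3L,
                                frame_rate = 120) {
  task <- match.arg(task)
  if (length(pattern) == 1L && is.character(pattern))
    pattern <- strsplit(pattern, "")[[1]]
  pattern <- toupper(pattern)
  if (!all(pattern %in% c("F", "H"))) stop("pattern must use only F and H")
  if (length(pattern) < 2L) stop("pattern must contain at least 2 images")
  if (task == "PV" && !(length(pattern) %in% 5:6))
    stop("PV patterns must be 5-6 images long")
  if (violation_index <= length(pattern))
    stop("`violation_index` must exceed the pattern length")
  if (violation_index <= 2L * length(pattern))
    stop("`violation_index` must lie beyond two full pattern repetitions")
  if (violation_index > n_cycles)
    stop("`violation_index` exceeds `n_cycles`")
  if (!ir_run_length %in% c(3L, 4L))
    stop("`ir_run_length` must be 3 or 4")

  categories <- rep(pattern, length.out = n_cycles)
  categories[violation_index] <-
    if (categories[violation_index] == "F") "H" else "F"
  target_index <- as.integer(if (task == "PV") violation_index else
    first_run_index(categories, ir_run_length))
  cycles <- data.frame(
    category = ifelse(categories == "F", "face", "house"),
    swift_freq = swift_freq,
    onset = (seq_len(n_cycles) - 1) / swift_freq,
    is_noise = FALSE)
  trial_schedule(cycles, ssvep_freq, duration = n_cycles / swift_freq,
                 target_index = target_index, task = task,
                 frame_rate = frame_rate)
}

#' Build an attention-manipulation (Experiment-2 style) schedule
#'
#' Two image streams (one face, one house) cycle at independent SWIFT
#' frequencies and are alpha-blended on screen; each stream shows its image
#' in only a `presence` fraction of its cycles and the matched noise
#' sequence otherwise, keeping the counting task demanding.
#'
#' @param f_face,f_house SWIFT frequencies of the two streams in Hz
#'   (defaults 0.8 and 1.0).
#' @param duration trial duration in seconds (default 31.5).
#' @param presence fraction of cycles showing the image, in `[0, 1]`;
#'   the experimental range is `[0.70, 0.85]` (default 0.80).
#' @param ssvep_freq contrast-modulation frequency in Hz (default 12).
#' @param task which stream is counted: `"count_face"`, `"count_house"` or
#'   `"count_cross"`.
#' @param rng_seed integer seed choosing which cycles are noise cycles.
#' @param frame_rate presentation rate in Hz.
#' @return a `trial_schedule` with two streams; `$n_images` holds the
#'   per-stream count of image (non-noise) cycles.
#' @export
build_exp2_schedule <- function(f_face = 0.8, f_house = 1.0, duration = 31.5,
                                presence = 0.80, ssvep_freq = 12,
                                task = c("count_face", "count_house",
                                         "count_cross"),
                                rng_seed = 1L, frame_rate = 120) {
  task <- match.arg(task)
  if (presence < 0 || presence > 1) stop("`presence` must lie in [0, 1]")
  set.seed(rng_seed)
  make_stream <- function(freq, category) {
    n_cycles <- floor(duration * freq)
    n_image <- floor(n_cycles * presence)
    noise_at <- sample(n_cycles, n_cycles - n_image)
    is_noise <- seq_len(n_cycles) %in% noise_at
    data.frame(
      category = ifelse(is_noise, paste0("noise_", category), category),
      swift_freq = freq,
      onset = (seq_len(n_cycles) - 1) / freq,
      is_noise = is_noise)
  }
  streams <- list(face = make_stream(f_face, "face"),
                  house = make_stream(f_house, "house"))
  sched <- trial_schedule(streams, ssvep_freq, duration = duration,
                          task = task, frame_rate = frame_rate)
  sched$n_images <- vapply(streams, function(s) sum(!s$is_noise), numeric(1))
  sched
}

#' Build the central-cross event schedule
#'
#' The fixation cross changes height and colour at pseudorandom intervals
#' drawn uniformly from `jitter_bounds`, deliberately avoiding a fixed rate
#' so the cross itself is only weakly frequency-tagged.  Conjunction targets
#' are an up-red or down-green cross.
#'
#' @param duration trial duration in seconds.
#' @param jitter_bounds inter-event interval range in seconds, default
#'   `c(0.850, 1.000)`.
#' @param rng_seed integer seed.
#' @return data frame with columns `time`, `height`, `colour`, `is_target`.
#' @export
build_cross_schedule <- function(duration, jitter_bounds = c(0.850, 1.000),
                                 rng_seed = 1L) {
  if (duration < 0) stop("`duration` must be non-negative")
  set.seed(rng_seed)
  times <- numeric(0)
  t <- stats::runif(1, jitter_bounds[1], jitter_bounds[2])
  while (t <= duration) {
    times <- c(times, t)
    t <- t + stats::runif(1, jitter_bounds[1], jitter_bounds[2])
  }
  n <- length(times)
  height <- sample(c("up", "down"), n, replace = TRUE)
  colour <- sample(c("red", "green", "blue"), n, replace = TRUE)
  data.frame(time = times, height = height, colour = colour,
             is_target = (height == "up" & colour == "red") |
               (height == "down" & colour == "green"))
}

#' Stimulus phase reference
#'
#' Returns the phase (radians) of a tagged stimulus modulation at arbitrary
#' times.  For the SSVEP frequency this is the phase of the contrast cosine
#' (maximum contrast at `t = 0`, so `phase = 2*pi*f*t`).  For a SWIFT
#' frequency it is the phase of a cosine whose maxima coincide with the
#' peak-frame times of that stream, so the phase is `0 (mod 2*pi)` exactly
#' when the original image is on screen.
#'
#' @param schedule a `trial_schedule`.
#' @param freq the requested frequency in Hz; must be the schedule's SSVEP
#'   frequency or one of its SWIFT frequencies.
#' @param times numeric vector of times in seconds.
#' @return numeric vector of phases in radians (unwrapped).
#' @export
stimulus_phase <- function(schedule, freq, times) {
  stopifnot(inherits(schedule, "trial_schedule"))
  tol <- 1e-9
  if (abs(freq - schedule$ssvep_freq) < tol)
    return(2 * pi * freq * times)
  sf <- swift_freqs(schedule)
  j <- which(abs(sf - freq) < tol)
  if (!length(j))
    stop(sprintf("frequency %g Hz is not tagged in this schedule", freq))
  s <- schedule$streams[[j[1]]]
  t_peak0 <- s$onset[1] + schedule$peak_frac / freq
  2 * pi * freq * (times - t_peak0)
}
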