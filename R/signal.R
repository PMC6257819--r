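#' Morlet wavelet bank
#'
#' Frequencies are logarithmically spaced from `f_min` to `f_max` inclusive
#' (default 4-35 Hz in 32 steps). The number of wavelet cycles `n` increases
#' linearly over the bank index from `n_min` to `n_max` (default 3-10),
#' trading temporal for spectral precision with frequency, and each
#' wavelet's temporal width is `sigma = n / (2 * pi * f)` seconds.
#'
#' @param f_min,f_max band edges in Hz.
#' @param n_freqs number of frequencies (>= 2).
#' @param n_min,n_max cycle counts at the first and last frequency.
#' @param srate sampling rate in Hz; `f_max` must stay below Nyquist.
#' @return a `wavelet_bank` list with `freqs`, `cycles`, `sigma` (s),
#'   `sigma_f` (Hz), `srate`.
#' @examples
#' b <- wavelet_bank()
#' b$sigma[1]  # 3 / (2 * pi * 4) ~ 0.1194 s
#' @export
wavelet_bank <- function(f_min = 4, f_max = 35, n_freqs = 32, n_min = 3,
                         n_max = 10, srate = 250) {
  stopifnot(f_min < f_max, n_freqs >= 2)
  if (f_max >= srate / 2) {
    stop(sprintf("f_max (%g Hz) must be below Nyquist (%g Hz)", f_max, srate / 2),
         call. = FALSE)
  }
  freqs <- exp(seq(log(f_min), log(f_max), length.out = n_freqs))
  cycles <- seq(n_min, n_max, length.out = n_freqs)
  sigma <- cycles / (2 * pi * freqs)
  structure(list(freqs = freqs, cycles = cycles, sigma = sigma,
                 sigma_f = 1 / (2 * pi * sigma), srate = srate),
            class = "wavelet_bank")
}

#' Morlet wavelet instantaneous power
#'
#' Convolves every trial and electrode with the bank's complex Morlet
#' wavelets in the frequency domain (FFT, multiply by a one-sided Gaussian
#' kernel centered on the wavelet frequency, inverse FFT) and returns the
#' squared magnitude of the complex signal as instantaneous power. The
#' kernel gain is 1 at the wavelet's center frequency and the analytic
#' (positive-frequency) part is doubled, so a pure sinusoid of amplitude `a`
#' at a bank frequency yields power `a^2` at that frequency. Samples inside
#' the epoch padding are dropped: only the dataset's analysis window is
#' returned, and the epoch must extend at least `3 * sigma` of the lowest
#' frequency beyond it.
#'
#' @param eeg an `eeg_dataset`.
#' @param bank a [wavelet_bank()].
#' @return a `tf_power` list: `power` (trials x electrodes x freqs x times,
#'   microvolt^2), `freqs`, `times` (ms), `srate`, `montage`, `schedule`.
#' @export
tf_power <- function(eeg, bank) {
  stopifnot(inherits(eeg, "eeg_dataset"))
  if (!isTRUE(all.equal(bank$srate, eeg$srate))) {
    stop("wavelet bank and dataset sampling rates differ", call. = FALSE)
  }
  pad_lo <- (eeg$analysis_window[1] - min(eeg$times)) / 1000
  pad_hi <- (max(eeg$times) - eeg$analysis_window[2]) / 1000
  need <- 3 * max(bank$sigma)
  if (pad_lo < need || pad_hi < need) {
    stop(sprintf(
      "epoch padding (%.0f/%.0f ms) shorter than 3 sigma of the lowest frequency (%.0f ms)",
      pad_lo * 1000, pad_hi * 1000, need * 1000), call. = FALSE)
  }
  d <- dim(eeg$data)
  n_t <- d[1]; n_e <- d[2]; n_s <- d[3]
  keep <- which(eeg$times >= eeg$analysis_window[1] &
                  eeg$times <= eeg$analysis_window[2])
  # samples x (trial, electrode) layout for a single batched FFT
  x <- matrix(aperm(eeg$data, c(3, 1, 2)), nrow = n_s)
  spec <- stats::mvfft(x)
  fft_freqs <- (seq_len(n_s) - 1) * eeg$srate / n_s
  pos <- fft_freqs <= eeg$srate / 2
  nf <- length(bank$freqs)
  out <- array(NA_real_, dim = c(n_t, n_e, nf, length(keep)))
  for (k in seq_len(nf)) {
    kern <- numeric(n_s)
    kern[pos] <- 2 * exp(-0.5 * ((fft_freqs[pos] - bank$freqs[k]) / bank$sigma_f[k])^2)
    kern[1] <- 0
    z <- stats::mvfft(spec * kern, inverse = TRUE) / n_s
    pw <- Re(z)^2 + Im(z)^2
    out[, , k, ] <- aperm(array(pw[keep, ], dim = c(length(keep), n_t, n_e)),
                          c(2, 3, 1))
  }
  structure(list(power = out, freqs = bank$freqs, times = eeg$times[keep],
                 srate = eeg$srate, montage = eeg$montage,
                 schedule = eeg$schedule),
            class = "tf_power")
}

#' @export
print.tf_power <- function(x, ...) {
  d <- dim(x$power)
  cat(sprintf("<tf_power: %d trials x %d electrodes x %d freqs x %d times (%g..%g ms)>\n",
              d[1], d[2], d[3], d[4], min(x$times), max(x$times)))
  invisible(x)
}

#' Average re-reference
#'
#' Subtracts the instantaneous mean over all scalp electrodes from every
#' channel (per trial and sample).
#'
#' @param eeg an `eeg_dataset`.
#' @return the re-referenced dataset.
#' @export
avg_reref <- function(eeg) {
  m <- apply(eeg$data, c(1, 3), mean)
  eeg$data <- eeg$data - aperm(array(m, c(dim(eeg$data)[1], dim(eeg$data)[3],
                                          dim(eeg$data)[2])), c(1, 3, 2))
  eeg
}

# windowed reduction helper: applies fun to each sliding window of columns
slide_windows <- function(n_samples, win, step) {
  starts <- seq(1L, n_samples - win + 1L, by = step)
  lapply(starts, function(s) s:(s + win - 1L))
}

#' Screen trials for blink, eye-movement, and blocking artifacts
#'
#' Rules, applied within the analysis window: (1) blink: sliding-window
#' peak-to-peak amplitude above `blink_uv` (default 80 microvolts, 200 ms
#' window, 50 ms step) on any designated blink channel; (2) eye movement:
#' a step detector on the horizontal derivation (difference of the two
#' `heog_channels`) comparing the means of the two window halves, flagged
#' above `eye_uv` (default 40 microvolts, 200 ms window, 10 ms step) -- a
#' voltage stand-in for the gaze-based criterion that needs calibration
#' data; (3) blocking: total within-window range at most `block_range_uv`
#' (default 0.1 microvolts over 200 ms) on any channel. A trial is rejected
#' if any rule fires.
#'
#' @param eeg an `eeg_dataset`.
#' @param thresholds list overriding `blink_uv`, `blink_win_ms`,
#'   `blink_step_ms`, `eye_uv`, `eye_win_ms`, `eye_step_ms`,
#'   `block_range_uv`, `block_win_ms`, `block_step_ms`.
#' @param blink_channels channels screened for blinks (frontal channels
#'   stand in for a VEOG lead in synthetic data).
#' @param heog_channels two channels whose difference stands in for HEOG.
#' @return a `rejection_report` data.frame: per trial logical `blink`,
#'   `eye_movement`, `blocking`, `rejected`; summary counts in
#'   `attr(, "summary")`.
#' @export
reject_artifacts <- function(eeg, thresholds = list(),
                             blink_channels = c("F3", "Fz", "F4"),
                             heog_channels = c("T3", "T4")) {
  th <- utils::modifyList(list(
    blink_uv = 80, blink_win_ms = 200, blink_step_ms = 50,
    eye_uv = 40, eye_win_ms = 200, eye_step_ms = 10,
    block_range_uv = 0.1, block_win_ms = 200, block_step_ms = 10
  ), thresholds)
  miss <- setdiff(c(blink_channels, heog_channels), eeg$montage)
  if (length(miss)) {
    stop("screening channels missing from montage: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  keep <- which(eeg$times >= eeg$analysis_window[1] &
                  eeg$times <= eeg$analysis_window[2])
  n_t <- dim(eeg$data)[1]
  ms2samp <- function(ms) max(2L, round(ms / 1000 * eeg$srate))

  win_p2p_exceeds <- function(mat, win_ms, step_ms, limit) {
    win <- ms2samp(win_ms); step <- ms2samp(step_ms)
    hit <- rep(FALSE, nrow(mat))
    for (idx in slide_windows(ncol(mat), win, step)) {
      sub <- mat[, idx, drop = FALSE]
      rng <- do.call(pmax, as.data.frame(sub)) - do.call(pmin, as.data.frame(sub))
      hit <- hit | (rng > limit)
    }
    hit
  }

  blink <- rep(FALSE, n_t)
  for (ch in match(blink_channels, eeg$montage)) {
    blink <- blink | win_p2p_exceeds(eeg$data[, ch, keep, drop = TRUE],
                                     th$blink_win_ms, th$blink_step_ms,
                                     th$blink_uv)
  }

  h <- eeg$data[, match(heog_channels[1], eeg$montage), keep, drop = TRUE] -
    eeg$data[, match(heog_channels[2], eeg$montage), keep, drop = TRUE]
  win <- ms2samp(th$eye_win_ms); step <- ms2samp(th$eye_step_ms)
  eye <- rep(FALSE, n_t)
  half <- win %/% 2
  for (idx in slide_windows(ncol(h), win, step)) {
    first <- rowMeans(h[, idx[seq_len(half)], drop = FALSE])
    second <- rowMeans(h[, idx[(half + 1):length(idx)], drop = FALSE])
    eye <- eye | (abs(first - second) > th$eye_uv)
  }

  blocking <- rep(FALSE, n_t)
  win <- ms2samp(th$block_win_ms); step <- ms2samp(th$block_step_ms)
  for (ch in seq_len(dim(eeg$data)[2])) {
    mat <- eeg$data[, ch, keep, drop = TRUE]
    for (idx in slide_windows(ncol(mat), win, step)) {
      sub <- mat[, idx, drop = FALSE]
      rng <- do.call(pmax, as.data.frame(sub)) - do.call(pmin, as.data.frame(sub))
      blocking <- blocking | (rng <= th$block_range_uv)
    }
  }

  rep_df <- data.frame(trial = seq_len(n_t), blink = blink,
                       eye_movement = eye, blocking = blocking,
                       rejected = blink | eye | blocking)
  attr(rep_df, "summary") <- c(n_trials = n_t, n_rejected = sum(rep_df$rejected),
                               blink = sum(blink), eye_movement = sum(eye),
                               blocking = sum(blocking))
  class(rep_df) <- c("rejection_report", "data.frame")
  rep_df
}

#' Average power in a frequency band and time window
#'
#' @param tf a `tf_power`.
#' @param band numeric \[f_lo, f_hi\] Hz, or `"theta"` (4-7) / `"alpha"`
#'   (8-12).
#' @param period numeric \[t0, t1\] ms, or `"prep"` (-600-0) / `"probe"`
#'   (0-300).
#' @param electrodes electrode names (default all).
#' @return trials x electrodes matrix of band/period mean power.
#' @export
band_period_power <- function(tf, band, period, electrodes = NULL) {
  band <- resolve_band(band)
  period <- resolve_period(period)
  fsel <- which(tf$freqs >= band[1] & tf$freqs <= band[2])
  tsel <- which(tf$times >= period[1] & tf$times <= period[2])
  if (!length(fsel) || !length(tsel)) {
    stop("empty band/period selection", call. = FALSE)
  }
  esel <- if (is.null(electrodes)) seq_along(tf$montage) else {
    m <- match(electrodes, tf$montage)
    if (anyNA(m)) stop("unknown electrode(s): ",
                       paste(electrodes[is.na(m)], collapse = ", "), call. = FALSE)
    m
  }
  sub <- tf$power[, esel, fsel, tsel, drop = FALSE]
  out <- apply(sub, c(1, 2), mean)
  colnames(out) <- tf$montage[esel]
  out
}

resolve_band <- function(band) {
  if (is.character(band)) {
    switch(band, theta = c(4, 7), alpha = c(8, 12),
           stop("unknown band: ", band, call. = FALSE))
  } else band
}

resolve_period <- function(period) {
  if (is.character(period)) {
    switch(period, prep = c(-600, 0), probe = c(0, 300),
           stop("unknown period: ", period, call. = FALSE))
  } else period
}

#' Group-level band-power condition contrast
#'
#' Computes, per subject, mean power at the named electrodes within a band
#' and window for each condition, forms the within-subject contrast
#' (default: within-chunk position 1 minus the mean of positions 2 and 3,
#' the mid-frontal theta control-demand check), and tests it against zero
#' across subjects (one-sample t; `b` is the group mean contrast).
#'
#' @param tf_list list of per-subject `tf_power` objects whose schedules
#'   carry the condition column.
#' @param code schedule column defining conditions
#'   (default `"within_position"`).
#' @param electrodes electrode names (default mid-frontal Fz, Cz).
#' @param band,period as in [band_period_power()].
#' @param contrast `"pos1_vs_23"` (only built-in).
#' @return list with `b`, `se`, `t`, `p`, `df`, `per_subject`.
#' @export
band_power_contrast <- function(tf_list, code = "within_position",
                                electrodes = c("Fz", "Cz"),
                                band = "theta", period = "prep",
                                contrast = "pos1_vs_23") {
  stopifnot(contrast == "pos1_vs_23")
  per_subj <- vapply(tf_list, function(tf) {
    pw <- rowMeans(band_period_power(tf, band, period, electrodes))
    labs <- tf$schedule[[code]]
    if (!any(labs == 1) || !any(labs %in% c(2, 3))) {
      stop("empty condition cell for contrast", call. = FALSE)
    }
    mean(pw[labs == 1]) - mean(pw[labs %in% c(2, 3)])
  }, numeric(1))
  n <- length(per_subj)
  b <- mean(per_subj)
  se <- if (n > 1) stats::sd(per_subj) / sqrt(n) else NA_real_
  tval <- if (is.na(se)) NA_real_ else if (se == 0) 0 else b / se
  list(b = b, se = se, t = tval,
       p = if (is.na(tval)) NA_real_ else 2 * stats::pt(-abs(tval), df = n - 1),
       df = n - 1, per_subject = per_subj)
}

#' Read epoched EEG from a long-format delimited text file
#'
#' Ingestion interface for real epoched recordings exported as text: a
#' tab-separated file with columns `trial`, `channel`, `time_ms`, `uv`.
#' An optional channel-name mapping renames incoming channels onto the
#' package montage.
#'
#' @param path file path.
#' @param srate sampling rate in Hz.
#' @param analysis_window ms window analyzed downstream; data must extend
#'   beyond it for wavelet padding.
#' @param channel_map optional named character vector: names are incoming
#'   channel labels, values the montage names to use.
#' @param schedule optional `trial_schedule` to attach.
#' @return an `eeg_dataset`.
#' @export
read_epoched_tsv <- function(path, srate = 250,
                             analysis_window = c(-1250, 700),
                             channel_map = NULL, schedule = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("trial", "channel", "time_ms", "uv") %in% names(df)))
  if (!is.null(channel_map)) {
    hit <- df$channel %in% names(channel_map)
    df$channel[hit] <- channel_map[df$channel[hit]]
  }
  trials <- sort(unique(df$trial))
  channels <- unique(df$channel)
  times <- sort(unique(df$time_ms))
  arr <- array(NA_real_, dim = c(length(trials), length(channels), length(times)))
  arr[cbind(match(df$trial, trials), match(df$channel, channels),
            match(df$time_ms, times))] <- df$uv
  if (anyNA(arr)) stop("incomplete trial x channel x time grid", call. = FALSE)
  structure(list(data = arr, srate = srate, times = times,
                 analysis_window = analysis_window, montage = channels,
                 schedule = schedule),
            class = "eeg_dataset")
}
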