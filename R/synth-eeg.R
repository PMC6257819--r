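#' Default 20-channel montage
#'
#' Ordered electrode names of the 10/20-style cap used throughout: the 15
#' standard sites plus OL, OR, PO3, PO4 and POz.
#'
#' @return character vector of 20 unique electrode names.
#' @export
default_montage <- function() {
  c("F3", "Fz", "F4", "T3", "C3", "Cz", "C4", "T4", "P3", "Pz", "P4",
    "T5", "T6", "O1", "O2", "OL", "OR", "PO3", "PO4", "POz")
}

#' Spatial-pattern specification for one control code
#'
#' Describes how a control code (element identity, within-chunk position,
#' chunk identity or chunk position) is embedded in the synthetic EEG: a
#' band-limited oscillation inside a trial window whose spatial weighting
#' over electrodes differs between code instances. Topographies are drawn
#' from a seeded standard normal, unit-normalized, and redrawn until every
#' pair is separated by at least `min_angle` degrees, so that instance
#' separability is governed by `amplitude` rather than chance geometry.
#'
#' @param code schedule column carrying the label: one of `"element"`,
#'   `"within_position"`, `"chunk_identity"`, `"chunk_position"`.
#' @param band numeric length-2, carrier band \[f_lo, f_hi\] in Hz (within
#'   4-35); the carrier is a sinusoid at band center with per-trial uniform
#'   frequency jitter across the band and random phase.
#' @param window numeric length-2, \[t0, t1\] ms relative to probe onset.
#' @param instances character vector of the code's label values.
#' @param amplitude oscillation amplitude in microvolts (>= 0).
#' @param n_electrodes montage size.
#' @param seed seed for topography generation.
#' @param min_angle minimum pairwise angle between instance topographies
#'   (degrees).
#' @return a `code_pattern` list with a `topographies` matrix
#'   (instances x electrodes, unit rows).
#' @export
code_pattern <- function(code, band, window, instances, amplitude,
                         n_electrodes = 20L, seed = 1L, min_angle = 30) {
  stopifnot(length(band) == 2L, band[1] < band[2], band[1] >= 4, band[2] <= 35)
  stopifnot(length(window) == 2L, window[1] < window[2], amplitude >= 0)
  topo <- draw_topographies(length(instances), n_electrodes, seed, min_angle)
  rownames(topo) <- instances
  structure(list(
    code = code, band = band, window = window, instances = instances,
    amplitude = amplitude, topographies = topo
  ), class = "code_pattern")
}

draw_topographies <- function(n, n_electrodes, seed, min_angle) {
  local_rng(seed)
  cos_max <- cos(min_angle * pi / 180)
  for (attempt in 1:200) {
    topo <- matrix(stats::rnorm(n * n_electrodes), nrow = n)
    topo <- topo / sqrt(rowSums(topo^2))
    g <- topo %*% t(topo)
    if (n == 1L || max(abs(g[upper.tri(g)])) <= cos_max) return(topo)
  }
  stop("could not draw topographies satisfying the minimum-angle constraint",
       call. = FALSE)
}

#' Default code-pattern set
#'
#' One pattern per control code, placed in the band and trial period where
#' each code was most clearly expressed in human data: element identity and
#' chunk identity in the alpha band (8-12 Hz), within-chunk and chunk
#' position in the theta band (4-7 Hz); elements and chunk positions in the
#' probe period (0-300 ms), chunk identity and within-chunk positions in the
#' late preparation period (-600-0 ms). The four band-by-window regions are
#' disjoint so each code's recoverability can be assessed independently.
#'
#' @param amplitude amplitude in microvolts applied to every code (scalar or
#'   named vector by code).
#' @param seed base seed; each code derives its own topography seed.
#' @param chunk_pool chunk labels used as chunk-identity instances.
#' @param n_chunk_positions number of chunk positions in the design.
#' @return list of [code_pattern()] objects.
#' @export
default_patterns <- function(amplitude = 4, seed = 1L,
                             chunk_pool = c("ABC", "BCA", "CAB"),
                             n_chunk_positions = 3L) {
  amp <- function(code) {
    if (length(amplitude) == 1L && is.null(names(amplitude))) return(amplitude)
    if (code %in% names(amplitude)) unname(amplitude[code]) else 0
  }
  list(
    code_pattern("element", band = c(8, 12), window = c(0, 300),
                 instances = c("A", "B", "C"), amplitude = amp("element"),
                 seed = seed + 11L),
    code_pattern("within_position", band = c(4, 7), window = c(-600, 0),
                 instances = c("1", "2", "3"),
                 amplitude = amp("within_position"), seed = seed + 23L),
    code_pattern("chunk_identity", band = c(8, 12), window = c(-600, 0),
                 instances = chunk_pool, amplitude = amp("chunk_identity"),
                 seed = seed + 37L),
    code_pattern("chunk_position", band = c(4, 7), window = c(0, 300),
                 instances = as.character(seq_len(n_chunk_positions)),
                 amplitude = amp("chunk_position"), seed = seed + 51L)
  )
}

#' Background-noise specification
#'
#' @param one_over_f_exponent spectral exponent beta of the 1/f^beta
#'   background (>= 0).
#' @param noise_sd per-channel noise RMS in microvolts (> 0).
#' @param channel_correlation shared-noise fraction in \[0, 1).
#' @return a `noise_spec` list.
#' @export
noise_spec <- function(one_over_f_exponent = 1, noise_sd = 10,
                       channel_correlation = 0.2) {
  stopifnot(one_over_f_exponent >= 0, noise_sd > 0,
            channel_correlation >= 0, channel_correlation < 1)
  structure(list(one_over_f_exponent = one_over_f_exponent,
                 noise_sd = noise_sd,
                 channel_correlation = channel_correlation),
            class = "noise_spec")
}

# 1/f^beta noise, one column per series, unit RMS
colored_noise <- function(n_samples, n_series, beta) {
  white <- matrix(stats::rnorm(n_samples * n_series), nrow = n_samples)
  if (beta == 0) return(white)
  spec <- stats::mvfft(white)
  idx <- seq_len(n_samples) - 1
  f <- pmin(idx, n_samples - idx)            # two-sided frequency magnitude
  f[1] <- 1                                  # keep DC finite (then ~zero power)
  gain <- f^(-beta / 2)
  gain[1] <- 0
  x <- Re(stats::mvfft(spec * gain, inverse = TRUE)) / n_samples
  sweep(x, 2, sqrt(colMeans(x^2)), "/")
}

#' Simulate a multichannel EEG dataset from a trial schedule
#'
#' Every trial is 1/f-shaped background noise plus, for each code pattern,
#' a band-limited oscillation (random phase per trial, per-trial frequency
#' jitter across the band) scaled by the topography of that trial's code
#' instance and confined to the pattern's window with raised-cosine on/off
#' ramps. Epochs extend `pad_ms` beyond the analysis window on both sides so
#' that wavelet convolution edge effects stay outside the analyzed samples.
#'
#' @param schedule a `trial_schedule` (one subject).
#' @param patterns list of [code_pattern()]s; every label value occurring in
#'   the schedule for a pattern's code must have a topography.
#' @param noise a [noise_spec()].
#' @param seed integer seed.
#' @param srate sampling rate, Hz (default 250).
#' @param window analysis epoch in ms relative to probe onset
#'   (default c(-1250, 700)).
#' @param pad_ms padding added on each side for wavelet edge handling
#'   (default 500 ms, beyond 3 sigma of the 4 Hz wavelet).
#' @return an `eeg_dataset`: list with `data` (trials x electrodes x
#'   samples, microvolts), `srate`, `times` (ms, 0 = probe onset),
#'   `analysis_window`, `montage`, `schedule`.
#' @export
simulate_eeg <- function(schedule, patterns = default_patterns(),
                         noise = noise_spec(), seed, srate = 250,
                         window = c(-1250, 700), pad_ms = 500) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  stopifnot(nrow(schedule) > 0)
  local_rng(seed)
  montage <- default_montage()
  n_e <- length(montage)
  dt <- 1000 / srate
  times <- seq(window[1] - pad_ms, window[2] + pad_ms, by = dt)
  n_s <- length(times)
  n_t <- nrow(schedule)

  # background: correlated 1/f noise, channel RMS = noise_sd
  shared <- colored_noise(n_s, n_t, noise$one_over_f_exponent)
  dat <- array(0, dim = c(n_t, n_e, n_s))
  rho <- noise$channel_correlation
  own <- colored_noise(n_s, n_t * n_e, noise$one_over_f_exponent)
  dim(own) <- c(n_s, n_t, n_e)
  for (e in seq_len(n_e)) {
    mix <- sqrt(rho) * shared + sqrt(1 - rho) * own[, , e]
    dat[, e, ] <- t(mix) * noise$noise_sd
  }

  tsec <- times / 1000
  for (p in patterns) {
    if (p$amplitude <= 0) next
    labs <- as.character(schedule[[p$code]])
    missing_labs <- setdiff(unique(labs), rownames(p$topographies))
    if (length(missing_labs)) {
      stop(sprintf("pattern for code '%s' lacks topographies for: %s",
                   p$code, paste(missing_labs, collapse = ", ")), call. = FALSE)
    }
    env <- ramp_envelope(times, p$window)
    sel <- env > 0
    f0 <- mean(p$band)
    half <- diff(p$band) / 2
    freqs <- f0 + stats::runif(n_t, -half, half)
    phases <- stats::runif(n_t, 0, 2 * pi)
    topo <- p$topographies[labs, , drop = FALSE]     # n_t x n_e
    carrier <- sin(outer(2 * pi * freqs, tsec[sel]) + phases) * p$amplitude
    carrier <- carrier * rep(env[sel], each = n_t)   # n_t x sum(sel)
    for (e in seq_len(n_e)) {
      dat[, e, sel] <- dat[, e, sel] + carrier * topo[, e]
    }
  }

  structure(list(
    data = dat, srate = srate, times = times, analysis_window = window,
    montage = montage, schedule = schedule
  ), class = "eeg_dataset")
}

# raised-cosine on/off ramps (default 50 ms) inside [t0, t1], zero outside
ramp_envelope <- function(times, window, ramp_ms = 50) {
  env <- numeric(length(times))
  inside <- times >= window[1] & times <= window[2]
  env[inside] <- 1
  up <- inside & times < window[1] + ramp_ms
  env[up] <- 0.5 * (1 - cos(pi * (times[up] - window[1]) / ramp_ms))
  dn <- inside & times > window[2] - ramp_ms
  env[dn] <- 0.5 * (1 - cos(pi * (window[2] - times[dn]) / ramp_ms))
  env
}

#' @export
print.eeg_dataset <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<eeg_dataset: %d trials x %d electrodes x %d samples @ %g Hz, %g..%g ms (analysis %g..%g ms)>\n",
    d[1], d[2], d[3], x$srate, min(x$times), max(x$times),
    x$analysis_window[1], x$analysis_window[2]
  ))
  invisible(x)
}

#' Simulate single-trial behavior for a schedule
#'
#' Reaction times are log-normal with mean `rt_base` plus an additive
#' `boundary_cost` at within-chunk position 1; errors are Bernoulli with
#' rate `error_base` plus `boundary_error_cost` at position 1. For subjects
#' flagged low-WM, both boundary effects are multiplied by
#' `wm_group_scaling`. An optional per-trial `evidence` covariate enters the
#' log-RT mean with slope `evidence_coupling`. The `exp2` variant adds a
#' self-paced retrieval time with its own (much larger) boundary cost.
#'
#' @param schedule a `trial_schedule`.
#' @param params list overriding any of: `rt_base` (450 ms), `boundary_cost`
#'   (14 ms), `error_base` (0.05), `boundary_error_cost` (0.038),
#'   `wm_group_scaling` (2), `evidence_coupling` (0), `rt_sd` (150 ms),
#'   `retrieval_base` (900 ms), `retrieval_boundary_cost` (372 ms),
#'   `retrieval_sd` (500 ms).
#' @param seed integer seed.
#' @param variant `"exp1"`, `"exp2"` (adds retrieval times), or `"exp3"`.
#' @param wm_group `"high"` or `"low"` for this subject.
#' @param evidence optional numeric vector (one value per trial), centered
#'   internally before coupling.
#' @return a `behavior_table` data.frame: schedule columns plus `rt` (ms),
#'   `correct`, and for exp2 `retrieval_time` (ms).
#' @export
simulate_behavior <- function(schedule, params = list(), seed,
                              variant = c("exp1", "exp2", "exp3"),
                              wm_group = "high", evidence = NULL) {
  variant <- match.arg(variant)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  p <- utils::modifyList(list(
    rt_base = 450, boundary_cost = 14, error_base = 0.05,
    boundary_error_cost = 0.038, wm_group_scaling = 2,
    evidence_coupling = 0, rt_sd = 150,
    retrieval_base = 900, retrieval_boundary_cost = 372, retrieval_sd = 500
  ), params)
  stopifnot(p$error_base >= 0, p$error_base + abs(p$boundary_error_cost) <= 1)
  local_rng(seed)
  n <- nrow(schedule)
  at_boundary <- schedule$within_position == 1
  scale_b <- if (isTRUE(unname(as.character(wm_group)) == "low")) p$wm_group_scaling else 1

  mu <- p$rt_base + p$boundary_cost * scale_b * at_boundary
  sdlog <- sqrt(log(1 + (p$rt_sd / mu)^2))
  meanlog <- log(mu) - sdlog^2 / 2
  if (!is.null(evidence)) {
    stopifnot(length(evidence) == n)
    meanlog <- meanlog + p$evidence_coupling * (evidence - mean(evidence))
  }
  rt <- stats::rlnorm(n, meanlog, sdlog)

  p_err <- pmin(pmax(p$error_base + p$boundary_error_cost * scale_b * at_boundary, 0), 1)
  correct <- stats::runif(n) >= p_err

  out <- cbind(as.data.frame(schedule), rt = rt, correct = correct)
  if (variant == "exp2") {
    rmu <- p$retrieval_base + p$retrieval_boundary_cost * scale_b * at_boundary
    rsd <- sqrt(log(1 + (p$retrieval_sd / rmu)^2))
    out$retrieval_time <- stats::rlnorm(n, log(rmu) - rsd^2 / 2, rsd)
  }
  out$wm_group <- wm_group
  class(out) <- c("behavior_table", "data.frame")
  out
}

#' Inject blink and flat-signal artifacts with a ground-truth mask
#'
#' Blinks are frontally weighted, ~300 ms raised-cosine deflections of
#' `blink_amp` microvolts; flat ("blocking") segments replace `flat_ms` of
#' one random channel with a constant. With both rates zero the input is
#' returned unchanged.
#'
#' @param eeg an `eeg_dataset`.
#' @param spec list overriding: `blink_rate` (0), `blink_amp` (100),
#'   `flat_rate` (0), `flat_ms` (200).
#' @param seed integer seed.
#' @return the dataset with an added `artifact_mask` data.frame
#'   (`trial`, `type`).
#' @export
inject_artifacts <- function(eeg, spec = list(), seed) {
  s <- utils::modifyList(list(blink_rate = 0, blink_amp = 100,
                              flat_rate = 0, flat_ms = 200), spec)
  stopifnot(s$blink_rate >= 0, s$blink_rate <= 1, s$flat_rate >= 0, s$flat_rate <= 1)
  if (s$blink_rate == 0 && s$flat_rate == 0) {
    eeg$artifact_mask <- data.frame(trial = integer(), type = character())
    return(eeg)
  }
  if (missing(seed)) stop("seed is required", call. = FALSE)
  local_rng(seed)
  n_t <- dim(eeg$data)[1]
  n_s <- dim(eeg$data)[3]
  # frontal-weighted blink projection
  w <- stats::setNames(rep(0.1, length(eeg$montage)), eeg$montage)
  w[c("F3", "Fz", "F4")] <- 1
  w[c("C3", "Cz", "C4")] <- 0.4
  blink_len <- round(300 / 1000 * eeg$srate)
  bump <- 0.5 * (1 - cos(2 * pi * seq_len(blink_len) / blink_len))

  mask <- list()
  inside <- which(eeg$times >= eeg$analysis_window[1] &
                    eeg$times <= eeg$analysis_window[2])
  blink_trials <- which(stats::runif(n_t) < s$blink_rate)
  for (tr in blink_trials) {
    start <- sample(inside[inside + blink_len <= max(inside)], 1L)
    idx <- start:(start + blink_len - 1L)
    eeg$data[tr, , idx] <- eeg$data[tr, , idx] +
      outer(unname(w), bump) * s$blink_amp
    mask[[length(mask) + 1L]] <- data.frame(trial = tr, type = "blink")
  }
  flat_len <- round(s$flat_ms / 1000 * eeg$srate)
  flat_trials <- which(stats::runif(n_t) < s$flat_rate)
  flat_trials <- setdiff(flat_trials, blink_trials)
  for (tr in flat_trials) {
    start <- sample(inside[inside + flat_len <= max(inside)], 1L)
    ch <- sample(seq_along(eeg$montage), 1L)
    idx <- start:(start + flat_len - 1L)
    eeg$data[tr, ch, idx] <- mean(eeg$data[tr, ch, idx])
    mask[[length(mask) + 1L]] <- data.frame(trial = tr, type = "blocking")
  }
  eeg$artifact_mask <- if (length(mask)) do.call(rbind, mask) else
    data.frame(trial = integer(), type = character())
  eeg
}
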