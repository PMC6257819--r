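# Shared fixtures, memoized so expensive simulate/wavelet steps run once
# per test session.
.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, .fixture_cache)) assign(name, build(), .fixture_cache)
  get(name, .fixture_cache)
}

# small exp1 subject: 4 blocks, all four codes injected at the given
# amplitude, 6-frequency bank
small_subject <- function(amplitude = 0, seed = 101, n_blocks = 4,
                          noise_sd = 10) {
  sub <- simulate_subject("exp1", seed = seed, n_blocks = n_blocks,
                          amplitude = amplitude,
                          noise = noise_spec(noise_sd = noise_sd))
  sub
}

small_bank <- function(n_freqs = 6) wavelet_bank(n_freqs = n_freqs)

small_tf <- function(amplitude = 0, seed = 101, n_blocks = 4, n_freqs = 6) {
  key <- sprintf("tf_a%s_s%d_b%d_f%d", amplitude, seed, n_blocks, n_freqs)
  fixture(key, function() {
    sub <- small_subject(amplitude, seed, n_blocks)
    list(tf = tf_power(sub$eeg, small_bank(n_freqs)),
         schedule = sub$schedule, patterns = sub$patterns)
  })
}

# quick decode config for unit tests
quick_config <- function(seed = 7, n_iterations = 2, window_step = 20) {
  decode_config(n_iterations = n_iterations, window_step = window_step,
                seed = seed)
}

# trials x electrodes pattern matrix with class topographies plus noise;
# used by generalization / chaining / RSA tests that do not need the EEG
# simulation layer
pattern_matrix <- function(labels, topographies, amplitude = 3,
                           noise_sd = 1, seed = 1) {
  set.seed(seed)
  n <- length(labels)
  p <- ncol(topographies)
  topographies[as.character(labels), , drop = FALSE] * amplitude +
    matrix(rnorm(n * p, sd = noise_sd), n, p)
}

unit_topos <- function(labels, p = 20, seed = 5) {
  set.seed(seed)
  t <- matrix(rnorm(length(labels) * p), length(labels))
  t <- t / sqrt(rowSums(t^2))
  rownames(t) <- labels
  t
}

# subject confusion matrices generated from a model matrix plus logit noise
simulate_confusions <- function(model, n_subjects = 10, noise = 0.4,
                                seed = 1) {
  set.seed(seed)
  k <- nrow(model)
  lapply(seq_len(n_subjects), function(s) {
    logit <- qlogis(pmin(pmax(model, 1e-4), 1 - 1e-4))
    plogis(logit + matrix(rnorm(k * k, sd = noise), k, k))
  })
}

# per-subject element-pattern data with optional anticipatory drift of each
# element's late-half pattern toward its within-chunk successor
make_chaining_subject <- function(seed, drift = 0, n_blocks = 8,
                                  trials_per_block = 27) {
  topos <- unit_topos(c("A", "B", "C"), seed = 40)
  set.seed(seed)
  succ <- c(A = "B", B = "C", C = "A")
  n <- n_blocks * trials_per_block
  elements <- sample(c("A", "B", "C"), n, replace = TRUE)
  block <- rep(seq_len(n_blocks), each = trials_per_block)
  late <- block > n_blocks / 2
  base <- topos[elements, , drop = FALSE]
  base[late, ] <- (1 - drift) * base[late, ] +
    drift * topos[succ[elements[late]], , drop = FALSE]
  x <- base * 3 + matrix(rnorm(n * ncol(topos)), n)
  list(x = x, elements = elements, block = block)
}

# multi-subject behavioral cohort at configurable scale
simulate_cohort <- function(n_subjects, params = list(), seed = 1,
                            n_blocks = 24, wm = NULL) {
  d <- experiment_design("exp1")
  do.call(rbind, lapply(seq_len(n_subjects), function(s) {
    sch <- assign_probes(
      build_schedule(d, seed = seed + s, subject = s, n_blocks = n_blocks,
                     allow_unbalanced = TRUE),
      seed = seed + s + 500)
    simulate_behavior(sch, params, seed = seed + s + 1000,
                      wm_group = if (is.null(wm)) "high" else wm[s])
  }))
}
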