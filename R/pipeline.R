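#' Simulate one subject of the cycling-sequence experiment
#'
#' Convenience wrapper chaining [build_schedule()], [assign_probes()],
#' [simulate_eeg()] and [simulate_behavior()] with a single subject seed.
#'
#' @param variant experiment variant.
#' @param seed subject seed (derives schedule/probe/EEG/behavior streams).
#' @param subject subject id.
#' @param n_blocks optional block-count override (e.g. fewer blocks for a
#'   quick run).
#' @param amplitude pattern amplitude(s) passed to [default_patterns()].
#' @param noise a [noise_spec()].
#' @param behavior_params list passed to [simulate_behavior()].
#' @param wm_group `"high"` or `"low"`.
#' @param window,pad_ms epoch geometry passed to [simulate_eeg()].
#' @return list with `schedule`, `eeg`, `behavior`, `patterns`.
#' @export
simulate_subject <- function(variant = "exp1", seed = 1L, subject = 1L,
                             n_blocks = NULL, amplitude = 4,
                             noise = noise_spec(), behavior_params = list(),
                             wm_group = "high", window = c(-1250, 700),
                             pad_ms = 500) {
  design <- experiment_design(variant)
  sched <- build_schedule(design, seed = seed, subject = subject,
                          n_blocks = n_blocks,
                          allow_unbalanced = !is.null(n_blocks))
  sched <- assign_probes(sched, p_match = 0.5, seed = seed + 1000L)
  patterns <- default_patterns(amplitude = amplitude, seed = seed,
                               chunk_pool = design$chunk_pool,
                               n_chunk_positions = design$chunks_per_sequence)
  eeg <- simulate_eeg(sched, patterns, noise, seed = seed + 2000L,
                      window = window, pad_ms = pad_ms)
  behav <- simulate_behavior(sched, behavior_params, seed = seed + 3000L,
                             variant = variant, wm_group = wm_group)
  list(schedule = sched, eeg = eeg, behavior = behav, patterns = patterns)
}

#' Pipeline run configuration
#'
#' @param experiment experiment variant.
#' @param n_subjects number of simulated subjects.
#' @param n_blocks blocks per subject (NULL = the design default).
#' @param seed master seed; every stage derives its stream from it.
#' @param out_dir output directory.
#' @param codes control codes to decode.
#' @param amplitude pattern amplitude(s).
#' @param n_freqs wavelet-bank size.
#' @param decode named list overriding [decode_config()] fields.
#' @param cluster named list: `n_permutations`, `t_threshold`.
#' @return validated `run_config` list.
#' @export
pipeline_config <- function(experiment = "exp1", n_subjects = 4L,
                            n_blocks = NULL, seed = NULL, out_dir = NULL,
                            codes = c("element", "within_position"),
                            amplitude = 4, n_freqs = 8L,
                            decode = list(n_iterations = 3L, window_step = 10L),
                            cluster = list(n_permutations = 200L,
                                           t_threshold = 2.0)) {
  if (is.null(seed)) stop("config validation: seed is required", call. = FALSE)
  if (is.null(out_dir)) stop("config validation: out_dir is required", call. = FALSE)
  stopifnot(n_subjects >= 1, n_freqs >= 2)
  bad <- setdiff(codes, c("element", "within_position", "chunk_identity",
                          "chunk_position"))
  if (length(bad)) stop("config validation: unknown code(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  decode <- utils::modifyList(list(n_iterations = 3L, window_step = 10L),
                              decode)
  cluster <- utils::modifyList(list(n_permutations = 200L, t_threshold = 2.0),
                               cluster)
  structure(list(experiment = experiment, n_subjects = as.integer(n_subjects),
                 n_blocks = n_blocks, seed = as.integer(seed),
                 out_dir = out_dir, codes = codes, amplitude = amplitude,
                 n_freqs = as.integer(n_freqs), decode = decode,
                 cluster = cluster),
            class = "run_config")
}

#' Run the full simulation-to-statistics pipeline
#'
#' Executes simulate, artifact screening, time-frequency decomposition,
#' per-subject frequency-by-time decoding of each configured code,
#' group-level cluster permutation tests, band/period summaries, and
#' behavioral structure contrasts, writing all outputs under the
#' configured directory: `schedule.tsv`, `behavior.tsv` (delimited text),
#' `maps_<code>.rds` (per-subject accuracy arrays), `clusters.json`,
#' `summaries.tsv`, `behavior_stats.tsv`, and a `manifest.json` recording
#' seeds, sizes, counts and runtimes per stage.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) list of in-memory results mirroring the files.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) {
    stop("config validation: use pipeline_config()", call. = FALSE)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  log_lines <- character()
  say <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, sprintf("[%.1fs] %s", proc.time()[["elapsed"]] - t0, msg))
  }
  dcfg <- do.call(decode_config, utils::modifyList(
    list(seed = config$seed), config$decode))
  bank <- wavelet_bank(n_freqs = config$n_freqs)

  subjects <- vector("list", config$n_subjects)
  maps <- stats::setNames(
    replicate(length(config$codes), list(), simplify = FALSE), config$codes)
  say("simulate + decode: %d subjects, codes %s", config$n_subjects,
      paste(config$codes, collapse = "/"))
  for (s in seq_len(config$n_subjects)) {
    sub <- simulate_subject(config$experiment, seed = config$seed + 17L * s,
                            subject = s, n_blocks = config$n_blocks,
                            amplitude = config$amplitude)
    rej <- reject_artifacts(sub$eeg)
    behav <- apply_exclusions(sub$behavior, config$experiment)
    tf <- tf_power(sub$eeg, bank)
    exclude <- rej$rejected | behav$excluded
    say("subject %d: %d trials, %d rejected (artifact), %d excluded (behavior)",
        s, nrow(sub$schedule), sum(rej$rejected), sum(behav$excluded))
    for (code in config$codes) {
      dm <- decode_map(tf, sub$schedule[[code]],
                       utils::modifyList(dcfg, list(seed = dcfg$seed + s)),
                       exclude = exclude)
      maps[[code]][[s]] <- dm
    }
    subjects[[s]] <- list(schedule = sub$schedule, behavior = behav,
                          rejection = rej)
  }

  sched_all <- do.call(rbind, lapply(subjects, `[[`, "schedule"))
  behav_all <- do.call(rbind, lapply(subjects, `[[`, "behavior"))
  utils::write.table(sched_all, file.path(config$out_dir, "schedule.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(behav_all, file.path(config$out_dir, "behavior.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  clusters <- list(); summaries <- list()
  for (code in config$codes) {
    acc <- lapply(maps[[code]], `[[`, "accuracy")
    saveRDS(list(accuracy = acc, freqs = maps[[code]][[1]]$freqs,
                 times = maps[[code]][[1]]$times),
            file.path(config$out_dir, paste0("maps_", code, ".rds")))
    if (config$n_subjects >= 2) {
      cl <- cluster_permutation(acc, chance = maps[[code]][[1]]$chance,
                                t_threshold = config$cluster$t_threshold,
                                n_permutations = config$cluster$n_permutations,
                                seed = config$seed + 7L)
      clusters[[code]] <- lapply(cl$clusters, function(x) {
        list(mass = x$mass, p = x$p, n_cells = sum(x$mask))
      })
      say("cluster test [%s]: %d cluster(s)", code, length(cl$clusters))
    }
    for (band in c("theta", "alpha")) {
      for (period in c("prep", "probe")) {
        vals <- vapply(maps[[code]], summarize_period, numeric(1),
                       band = band, period = period)
        summaries[[length(summaries) + 1L]] <- data.frame(
          code = code, band = band, period = period,
          accuracy = mean(vals), se = stats::sd(vals) / sqrt(length(vals)))
      }
    }
  }
  summaries <- do.call(rbind, summaries)
  utils::write.table(summaries, file.path(config$out_dir, "summaries.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(clusters, file.path(config$out_dir, "clusters.json"),
                       auto_unbox = TRUE, digits = NA)

  bstats <- if (config$n_subjects >= 2) structure_contrasts(behav_all) else NULL
  if (!is.null(bstats)) {
    utils::write.table(bstats$contrasts,
                       file.path(config$out_dir, "behavior_stats.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("oscdecode")),
    r_version = R.version.string,
    seed = config$seed,
    experiment = config$experiment,
    n_subjects = config$n_subjects,
    codes = config$codes,
    n_freqs = config$n_freqs,
    decode = config$decode,
    runtime_s = round(proc.time()[["elapsed"]] - t0, 2),
    log = log_lines
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  writeLines(log_lines, file.path(config$out_dir, "run.log"))
  invisible(list(maps = maps, clusters = clusters, summaries = summaries,
                 behavior = bstats, manifest = manifest))
}

#' Summarize a pipeline results directory
#'
#' Reads a [run_pipeline()] output bundle and produces frequency-by-time
#' group-mean accuracy heatmaps (PNG, one per code, with significant
#' cluster outlines when present), and returns the summary tables after
#' cross-checking that stored band/period summaries match a recomputation
#' from the stored maps. Missing stage outputs yield a partial report with
#' a notice.
#'
#' @param results_dir directory written by [run_pipeline()].
#' @param plot write PNG heatmaps (default TRUE).
#' @return list with `summaries`, `behavior`, `clusters`, `notices`.
#' @export
report <- function(results_dir, plot = TRUE) {
  notices <- character()
  path <- function(f) file.path(results_dir, f)
  summaries <- if (file.exists(path("summaries.tsv"))) {
    utils::read.delim(path("summaries.tsv"))
  } else {
    notices <- c(notices, "summaries.tsv missing")
    NULL
  }
  behavior <- if (file.exists(path("behavior_stats.tsv"))) {
    utils::read.delim(path("behavior_stats.tsv"))
  } else {
    notices <- c(notices, "behavior_stats.tsv missing")
    NULL
  }
  clusters <- if (file.exists(path("clusters.json"))) {
    jsonlite::read_json(path("clusters.json"))
  } else {
    notices <- c(notices, "clusters.json missing")
    NULL
  }
  map_files <- list.files(results_dir, pattern = "^maps_.*\\.rds$",
                          full.names = TRUE)
  for (mf in map_files) {
    code <- sub("^maps_(.*)\\.rds$", "\\1", basename(mf))
    m <- readRDS(mf)
    group <- Reduce(`+`, m$accuracy) / length(m$accuracy)
    if (!is.null(summaries)) {
      stored <- summaries[summaries$code == code & summaries$band == "theta" &
                            summaries$period == "prep", "accuracy"]
      re <- mean(vapply(m$accuracy, function(a) {
        summarize_period(list(accuracy = a, freqs = m$freqs, times = m$times),
                         "theta", "prep")
      }, numeric(1)))
      if (length(stored) && abs(stored - re) > 1e-8) {
        notices <- c(notices, sprintf("summary mismatch for %s", code))
      }
    }
    if (plot) {
      grDevices::png(path(sprintf("map_%s.png", code)), width = 900,
                     height = 600)
      graphics::image(m$times, seq_along(m$freqs), t(group),
                      col = grDevices::hcl.colors(64, "viridis"),
                      xlab = "time (ms)", ylab = "frequency (Hz)", yaxt = "n",
                      main = sprintf("%s decoding accuracy", code))
      graphics::axis(2, at = seq_along(m$freqs), labels = round(m$freqs, 1))
      graphics::abline(v = 0, col = "white", lty = 2)
      grDevices::dev.off()
    }
  }
  list(summaries = summaries, behavior = behavior, clusters = clusters,
       notices = notices)
}
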