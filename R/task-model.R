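#' Cycling-sequence task designs
#'
#' Constructors and utilities for the cycling-sequence paradigm: sequences of
#' 3-element chunks built from three line orientations (45, 90, 135 degrees,
#' coded A/B/C), presented repeatedly ("cycled") within blocks. Two design
#' families are supported: 9-element sequences of three chunks drawn from a
#' 3-chunk pool (variants `exp1`, `exp2`) and 6-element sequences of two
#' chunks drawn from a 6-chunk pool with a no-element-repeat rule at chunk
#' boundaries, applied cyclically (`exp3`).
#'
#' @param variant one of `"exp1"`, `"exp2"`, `"exp3"`.
#' @return an object of class `experiment_design`: a list with fields
#'   `variant`, `chunk_pool` (character vector of 3-letter chunk labels),
#'   `chunks_per_sequence`, `cycles_per_block`, `n_blocks`, and
#'   `boundary_rule` (`"none"` or `"cyclic_no_repeat"`).
#' @examples
#' d <- experiment_design("exp1")
#' length(enumerate_sequences(d))  # 6
#' @export
experiment_design <- function(variant = c("exp1", "exp2", "exp3")) {
  variant <- match.arg(variant)
  if (variant %in% c("exp1", "exp2")) {
    des <- list(
      variant = variant,
      chunk_pool = c("ABC", "BCA", "CAB"),
      chunks_per_sequence = 3L,
      cycles_per_block = 6L,
      n_blocks = 24L,
      boundary_rule = "none"
    )
  } else {
    des <- list(
      variant = variant,
      chunk_pool = c("ABC", "ACB", "BAC", "BCA", "CAB", "CBA"),
      chunks_per_sequence = 2L,
      cycles_per_block = 7L,
      n_blocks = 36L,
      boundary_rule = "cyclic_no_repeat"
    )
  }
  class(des) <- "experiment_design"
  des
}

#' @export
print.experiment_design <- function(x, ...) {
  cat(sprintf(
    "<experiment_design %s: %d chunks/sequence from pool {%s}, %d blocks x %d cycles>\n",
    x$variant, x$chunks_per_sequence, paste(x$chunk_pool, collapse = ","),
    x$n_blocks, x$cycles_per_block
  ))
  invisible(x)
}

validate_design <- function(design) {
  stopifnot(inherits(design, "experiment_design") || is.list(design))
  if (length(design$chunk_pool) == 0L) {
    stop("invalid design: empty chunk pool", call. = FALSE)
  }
  if (design$chunks_per_sequence < 1L) {
    stop("invalid design: chunks_per_sequence must be >= 1", call. = FALSE)
  }
  bad <- nchar(design$chunk_pool) != 3L |
    vapply(strsplit(design$chunk_pool, ""), function(s) anyDuplicated(s) > 0L, logical(1))
  if (any(bad)) {
    stop("invalid design: chunks must be 3 distinct elements", call. = FALSE)
  }
  invisible(design)
}

chunk_elements <- function(label) strsplit(label, "")[[1]]

#' Expand a chunk sequence into per-step control-code labels
#'
#' @param chunks character vector of chunk labels in order.
#' @return a data.frame with one row per element: `element`,
#'   `within_position` (1-3), `chunk_identity`, `chunk_position`.
#' @export
sequence_steps <- function(chunks) {
  steps <- do.call(rbind, lapply(seq_along(chunks), function(i) {
    data.frame(
      element = chunk_elements(chunks[i]),
      within_position = 1:3,
      chunk_identity = chunks[i],
      chunk_position = i,
      stringsAsFactors = FALSE
    )
  }))
  rownames(steps) <- NULL
  steps
}

#' Enumerate all admissible sequences for a design
#'
#' Enumerates every ordered arrangement of `chunks_per_sequence` distinct
#' chunks from the design pool, filtered by the boundary rule. Under
#' `cyclic_no_repeat`, no element may repeat at any chunk junction, including
#' the wrap-around junction from the last back to the first chunk, because
#' sequences cycle within a block. Output order is deterministic
#' (lexicographic on the concatenated chunk labels).
#'
#' @param design an [experiment_design()].
#' @return list of character vectors, each a sequence of chunk labels.
#' @examples
#' length(enumerate_sequences(experiment_design("exp3")))  # 12
#' @export
enumerate_sequences <- function(design) {
  validate_design(design)
  pool <- design$chunk_pool
  k <- design$chunks_per_sequence
  perms <- ordered_tuples(length(pool), k)
  seqs <- lapply(seq_len(nrow(perms)), function(i) pool[perms[i, ]])
  if (identical(design$boundary_rule, "cyclic_no_repeat")) {
    keep <- vapply(seqs, function(s) {
      nxt <- c(s[-1], s[1])  # cyclic successor of each chunk
      all(substring(s, 3, 3) != substring(nxt, 1, 1))
    }, logical(1))
    seqs <- seqs[keep]
  }
  labels <- vapply(seqs, paste, character(1), collapse = "")
  seqs[order(labels)]
}

# all ordered k-tuples of distinct indices from 1..n, as a matrix
ordered_tuples <- function(n, k) {
  if (k == 1L) return(matrix(seq_len(n), ncol = 1))
  sub <- ordered_tuples(n, k - 1L)
  out <- do.call(rbind, lapply(seq_len(n), function(i) {
    keep <- rowSums(sub == i) == 0L
    cbind(i, sub[keep, , drop = FALSE])
  }))
  unname(out)
}

#' Build a counterbalanced trial schedule
#'
#' Assigns sequences to blocks so that each admissible sequence is used
#' equally often across the design's blocks (the order of assignment is
#' seeded-random), then unrolls each block into `cycles_per_block` cycles of
#' its sequence. Because every Exp 1/2 sequence contains each element at each
#' within-chunk position and each chunk at each chunk position exactly once,
#' the resulting schedule is exactly counterbalanced over the four control
#' codes.
#'
#' @param design an [experiment_design()].
#' @param seed integer seed for the block-order randomization.
#' @param subject subject identifier stored in the schedule.
#' @param n_blocks optional override of the design's block count; must be a
#'   multiple of the number of admissible sequences unless
#'   `allow_unbalanced = TRUE`.
#' @param allow_unbalanced allow a block count that is not a multiple of the
#'   sequence count (near-balanced assignment).
#' @return a `trial_schedule` data.frame with columns `subject`, `block`,
#'   `cycle`, `serial_index` (1-based within block), `trial` (within block),
#'   `element`, `within_position`, `chunk_identity`, `chunk_position`,
#'   `sequence`; probe columns are added by [assign_probes()].
#' @export
build_schedule <- function(design, seed, subject = 1L, n_blocks = NULL,
                           allow_unbalanced = FALSE) {
  validate_design(design)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  seqs <- enumerate_sequences(design)
  nb <- if (is.null(n_blocks)) design$n_blocks else as.integer(n_blocks)
  if (nb %% length(seqs) != 0L && !allow_unbalanced) {
    stop(sprintf(
      "n_blocks (%d) is not a multiple of the number of sequences (%d); set allow_unbalanced = TRUE to override",
      nb, length(seqs)
    ), call. = FALSE)
  }
  rng <- local_rng(seed)
  reps <- ceiling(nb / length(seqs))
  assignment <- rep(seq_along(seqs), reps)[seq_len(nb)]
  assignment <- assignment[sample.int(nb)]
  rows <- lapply(seq_len(nb), function(b) {
    s <- seqs[[assignment[b]]]
    steps <- sequence_steps(s)
    len <- nrow(steps)
    cyc <- design$cycles_per_block
    idx <- rep(seq_len(len), cyc)
    out <- steps[idx, , drop = FALSE]
    out$subject <- subject
    out$block <- b
    out$cycle <- rep(seq_len(cyc), each = len)
    out$serial_index <- seq_len(len * cyc)
    out$sequence <- paste(s, collapse = "-")
    out
  })
  sched <- do.call(rbind, rows)
  rownames(sched) <- NULL
  sched$trial <- sched$serial_index
  sched <- sched[, c(
    "subject", "block", "cycle", "serial_index", "trial", "element",
    "within_position", "chunk_identity", "chunk_position", "sequence"
  )]
  class(sched) <- c("trial_schedule", "data.frame")
  sched
}

#' Assign match/mismatch probes to a schedule
#'
#' Each trial's probe orientation equals the current element on match trials
#' (drawn Bernoulli(`p_match`)) and is drawn uniformly from the two non-target
#' orientations on mismatch trials.
#'
#' @param schedule a `trial_schedule`.
#' @param p_match probability of a match probe (default 0.5).
#' @param seed integer seed.
#' @return the schedule with `is_match` (logical) and `probe_orientation`.
#' @export
assign_probes <- function(schedule, p_match = 0.5, seed) {
  stopifnot(p_match >= 0, p_match <= 1)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  rng <- local_rng(seed)
  n <- nrow(schedule)
  elements <- c("A", "B", "C")
  schedule$is_match <- stats::runif(n) < p_match
  probe <- schedule$element
  mism <- which(!schedule$is_match)
  if (length(mism)) {
    probe[mism] <- vapply(schedule$element[mism], function(e) {
      sample(setdiff(elements, e), 1L)
    }, character(1))
  }
  schedule$probe_orientation <- probe
  schedule
}

#' Cowan's K working-memory capacity estimate
#'
#' Change-detection capacity `K = S * (H - F)` where `S` is the memory array
#' set size, `H` the hit rate and `F` the false-alarm rate.
#'
#' @param S set size (> 0).
#' @param H hit rate in \[0, 1\].
#' @param F false-alarm rate in \[0, 1\].
#' @return data.frame with columns `S`, `H`, `F`, `K` (vectorized).
#' @examples
#' cowans_k(8, 0.75, 0.25)$K  # 4
#' @export
cowans_k <- function(S, H, F) {
  if (any(S <= 0)) stop("set size S must be positive", call. = FALSE)
  stopifnot(all(H >= 0 & H <= 1), all(F >= 0 & F <= 1))
  data.frame(S = S, H = H, F = F, K = S * (H - F))
}

#' Median split of subjects by working-memory capacity
#'
#' Subjects with K above the median form the high-capacity group and those
#' below the median the low-capacity group; subjects exactly at the median are
#' assigned per `ties` (default `"low"`).
#'
#' @param k numeric vector of per-subject K scores (>= 2 subjects).
#' @param ties `"low"` or `"high"`: group receiving at-median subjects.
#' @return factor of `"low"`/`"high"` labels, one per subject.
#' @export
median_split_wm <- function(k, ties = c("low", "high")) {
  ties <- match.arg(ties)
  if (length(k) < 2L) stop("median split needs at least 2 subjects", call. = FALSE)
  if (length(unique(k)) == 1L) {
    warning("all K scores equal: degenerate median split", call. = FALSE)
  }
  med <- stats::median(k)
  grp <- ifelse(k > med, "high", ifelse(k < med, "low", ties))
  factor(grp, levels = c("low", "high"))
}

#' Write / read a trial schedule as tab-delimited text
#'
#' @param schedule a `trial_schedule`.
#' @param path file path.
#' @return `read_schedule` returns the schedule data.frame.
#' @export
write_schedule <- function(schedule, path) {
  utils::write.table(schedule, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  sched <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(sched) <- c("trial_schedule", "data.frame")
  sched
}

# Scoped RNG: seeds the session RNG for the calling frame and restores the
# previous state when that frame exits, so seeded operations never disturb
# the caller's RNG stream.
local_rng <- function(seed, envir = parent.frame()) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  set.seed(as.integer(seed) %% .Machine$integer.max)
  restore <- function() {
    if (!is.null(old)) {
      assign(".Random.seed", old, globalenv())
    } else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }
  do.call(on.exit, list(bquote((.(restore))()), add = TRUE), envir = envir)
  invisible(NULL)
}
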