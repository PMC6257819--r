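#' Cross-classification generalization with matched reference scores
#'
#' Tests whether a code (e.g. within-chunk position) generalizes across
#' instances of another control code (e.g. elements). For each instance `g`
#' of the generalization variable and each cross-validation rotation, a
#' classifier is trained on fold-averaged class rows built from trials of
#' all other instances; it is then tested on (a) the held-out fold's trials
#' of instance `g` (generalized score) and (b) an equally sized random
#' subsample of the held-out fold's trials from the training instances
#' (reference score), so both scores rest on identically sized test sets.
#'
#' @param x trials x features matrix (typically [band_period_power()]).
#' @param code_labels per-trial labels of the decoded code.
#' @param gen_labels per-trial labels of the generalization variable
#'   (>= 2 instances).
#' @param config a [decode_config()].
#' @return list: `generalized`, `reference` (overall means), and
#'   `by_instance` data.frame.
#' @export
cross_classify <- function(x, code_labels, gen_labels,
                           config = decode_config()) {
  y <- factor(code_labels)
  g <- factor(gen_labels)
  if (nlevels(g) < 2L) {
    stop("generalization variable needs at least 2 instances", call. = FALSE)
  }
  if (any(table(y, g) == 0)) {
    stop("empty code x generalization cell", call. = FALSE)
  }
  k <- nlevels(y)
  res <- expand.grid(instance = levels(g), stringsAsFactors = FALSE)
  res$generalized <- res$reference <- 0
  counts <- res; counts$generalized <- counts$reference <- 0

  for (iter in seq_len(config$n_iterations)) {
    local_rng(config$seed + iter)
    folds <- make_folds(y, config$n_folds)
    for (gi in seq_len(nlevels(g))) {
      hold <- levels(g)[gi]
      for (r in seq_len(config$n_folds)) {
        tr_sel <- !is.na(folds) & folds != r & g != hold
        train <- avg_class_rows(x, y, folds, which(tr_sel))
        if (is.null(train)) next
        fit <- lda_shrink(train$x, train$y, config$shrinkage)

        te_gen <- which(!is.na(folds) & folds == r & g == hold)
        te_ref_pool <- which(!is.na(folds) & folds == r & g != hold)
        if (!length(te_gen) || !length(te_ref_pool)) next
        # match reference test-set size per class to the generalized set
        ref_idx <- integer()
        ok <- TRUE
        for (cl in seq_len(k)) {
          ng <- sum(as.integer(y[te_gen]) == cl)
          pool <- te_ref_pool[as.integer(y[te_ref_pool]) == cl]
          if (ng == 0 || length(pool) < ng) { ok <- FALSE; break }
          ref_idx <- c(ref_idx, sample(pool, ng))
        }
        if (!ok) next
        gen_rows <- class_rows(x, y, te_gen)
        ref_rows <- class_rows(x, y, ref_idx)
        res$generalized[gi] <- res$generalized[gi] +
          sum(predict(fit, gen_rows$x)$class == gen_rows$y)
        counts$generalized[gi] <- counts$generalized[gi] + length(gen_rows$y)
        res$reference[gi] <- res$reference[gi] +
          sum(predict(fit, ref_rows$x)$class == ref_rows$y)
        counts$reference[gi] <- counts$reference[gi] + length(ref_rows$y)
      }
    }
  }
  res$generalized <- res$generalized / counts$generalized
  res$reference <- res$reference / counts$reference
  list(generalized = mean(res$generalized), reference = mean(res$reference),
       by_instance = res)
}

# class-averaged z-scored rows over the given trial indices (one per class)
class_rows <- function(x, y, idx) {
  lev <- levels(y)
  rows <- lapply(seq_along(lev), function(cl) {
    sel <- idx[as.integer(y[idx]) == cl]
    if (!length(sel)) return(NULL)
    colMeans(x[sel, , drop = FALSE])
  })
  keep <- !vapply(rows, is.null, logical(1))
  list(x = zscore_rows(do.call(rbind, rows[keep])),
       y = factor(lev[keep], levels = lev))
}

# fold-by-class averaged z-scored training rows over the given indices
avg_class_rows <- function(x, y, folds, idx) {
  f <- folds[idx]
  rows <- list(); ys <- character()
  for (fl in unique(f)) {
    sub <- idx[f == fl]
    cr <- class_rows(x, y, sub)
    rows[[length(rows) + 1L]] <- cr$x
    ys <- c(ys, as.character(cr$y))
  }
  if (!length(rows)) return(NULL)
  list(x = do.call(rbind, rows), y = factor(ys, levels = levels(y)))
}

#' Theoretical confusion-model matrices for RSA
#'
#' Column-stochastic matrices (columns index the true class, rows the
#' predicted class) encoding competing hypotheses about the confusion
#' structure of decoding results:
#' \describe{
#'   \item{discrete}{all classes mutually distinct: identity.}
#'   \item{unique_position_1}{position 1 distinct, positions 2 and 3
#'     mutually confusable at 0.5.}
#'   \item{element9 / position9}{over the 9 element-by-position classes,
#'     1/3 among classes sharing the element (resp. position).}
#'   \item{conjunction9}{9 x 9 identity.}
#'   \item{elem_n_minus_1 / elem_n}{over the 6 non-repeating (previous,
#'     current) element pairs, 0.5 among pairs sharing the previous (resp.
#'     current) element.}
#'   \item{conjunction_lag}{6 x 6 identity.}
#' }
#' Nine-class labels are element-major (`A1, A2, A3, B1, ...`); lag-pair
#' labels are `previous+current` (`AB, AC, BA, BC, CA, CB`).
#'
#' @param kind model name (above).
#' @return square matrix with class labels as dimnames and the kind as
#'   `attr(, "kind")`; columns sum to 1.
#' @export
build_model_matrix <- function(kind) {
  elements <- c("A", "B", "C")
  m <- switch(
    kind,
    discrete = diag(3),
    unique_position_1 = matrix(c(1, 0, 0,
                                 0, .5, .5,
                                 0, .5, .5), 3, 3),
    element9 = ,
    position9 = ,
    conjunction9 = {
      cls <- as.vector(t(outer(elements, 1:3, paste0)))   # A1 A2 A3 B1 ...
      el <- substr(cls, 1, 1); po <- substr(cls, 2, 2)
      mm <- switch(kind,
                   element9 = outer(el, el, "==") / 3,
                   position9 = outer(po, po, "==") / 3,
                   conjunction9 = diag(9))
      dimnames(mm) <- list(cls, cls)
      mm
    },
    elem_n_minus_1 = ,
    elem_n = ,
    conjunction_lag = {
      pairs <- c("AB", "AC", "BA", "BC", "CA", "CB")
      prev <- substr(pairs, 1, 1); cur <- substr(pairs, 2, 2)
      mm <- switch(kind,
                   elem_n_minus_1 = outer(prev, prev, "==") / 2,
                   elem_n = outer(cur, cur, "==") / 2,
                   conjunction_lag = diag(6))
      dimnames(mm) <- list(pairs, pairs)
      mm
    },
    stop("unknown model matrix kind: ", kind, call. = FALSE)
  )
  if (kind %in% c("discrete", "unique_position_1")) {
    dimnames(m) <- list(as.character(1:3), as.character(1:3))
  }
  stopifnot(all(abs(colSums(m) - 1) < 1e-12))
  attr(m, "kind") <- kind
  m
}

#' Fit RSA model matrices to subject confusion matrices
#'
#' All confusion cells (including the diagonal) are logit-transformed after
#' clipping and regressed simultaneously on the model-matrix predictors in
#' a hierarchical model: fixed slopes per model plus per-subject random
#' intercepts and slopes (lme4). If the mixed fit fails or does not
#' converge, a two-stage fallback runs per-subject least squares and tests
#' each coefficient across subjects with a one-sample t; the fitting path
#' is recorded. Model predictors are used as given (0/0.5/1 cells), not
#' standardized, unless `standardize = TRUE`.
#'
#' @param confusions list (one per subject) of square confusion matrices,
#'   columns = true class, columns sum to 1.
#' @param models named list of model matrices from [build_model_matrix()].
#' @param clip logit clipping bound (default 1e-4).
#' @param standardize z-score predictors before fitting.
#' @return an `rsa_fit`: data.frame `coefficients` (`model`, `b`, `se`,
#'   `t`), plus `path` (`"mixed"` or `"two_stage"`).
#' @export
fit_rsa <- function(confusions, models, clip = 1e-4, standardize = FALSE) {
  stopifnot(length(confusions) >= 2L)
  if (is.null(names(models))) {
    names(models) <- vapply(models, function(m) attr(m, "kind"), character(1))
  }
  k <- nrow(confusions[[1]])
  stopifnot(all(vapply(models, nrow, integer(1)) == k))
  pred <- vapply(models, as.vector, numeric(k * k))
  if (standardize) pred <- scale(pred)
  if (qr(cbind(1, pred))$rank < ncol(pred) + 1L) {
    stop("collinear model set: ", paste(names(models), collapse = ", "),
         call. = FALSE)
  }
  df <- do.call(rbind, lapply(seq_along(confusions), function(s) {
    cells <- pmin(pmax(as.vector(confusions[[s]]), clip), 1 - clip)
    cbind(data.frame(y = stats::qlogis(cells), subject = s),
          as.data.frame(pred))
  }))
  pnames <- colnames(pred)
  fml <- stats::as.formula(paste(
    "y ~", paste(pnames, collapse = " + "),
    "+ (1 +", paste(pnames, collapse = " + "), "| subject)"))

  fit <- NULL
  path <- "mixed"
  fit <- tryCatch({
    m <- suppressWarnings(suppressMessages(
      lme4::lmer(fml, data = df,
                 control = lme4::lmerControl(check.conv.singular = "ignore",
                                             check.conv.grad = "ignore"))
    ))
    b <- lme4::fixef(m)[pnames]
    se <- sqrt(diag(as.matrix(stats::vcov(m))))[-1]
    data.frame(model = pnames, b = unname(b), se = unname(se),
               t = unname(b / se))
  }, error = function(e) NULL)
  if (is.null(fit)) {
    path <- "two_stage"
    co <- t(vapply(seq_along(confusions), function(s) {
      sub <- df[df$subject == s, ]
      stats::coef(stats::lm(stats::as.formula(
        paste("y ~", paste(pnames, collapse = "+"))), data = sub))[pnames]
    }, numeric(length(pnames))))
    b <- colMeans(co)
    se <- apply(co, 2, stats::sd) / sqrt(nrow(co))
    fit <- data.frame(model = pnames, b = unname(b), se = unname(se),
                      t = unname(b / se))
  }
  structure(list(coefficients = fit, path = path, n_subjects = length(confusions)),
            class = "rsa_fit")
}

#' @export
print.rsa_fit <- function(x, ...) {
  cat(sprintf("<rsa_fit (%s), %d subjects>\n", x$path, x$n_subjects))
  print(x$coefficients, row.names = FALSE)
  invisible(x)
}

#' Within-chunk element-to-element transitions of a chunk pool
#'
#' @param chunk_pool character vector of 3-letter chunk labels.
#' @return data.frame `from`, `to` of unique within-chunk transitions.
#' @export
within_chunk_transitions <- function(chunk_pool) {
  tr <- do.call(rbind, lapply(chunk_pool, function(ch) {
    e <- chunk_elements(ch)
    data.frame(from = e[1:2], to = e[2:3], stringsAsFactors = FALSE)
  }))
  unique(tr)
}

#' Associative-chaining asymmetry test
#'
#' For each within-chunk transition A to B, compares the correlation
#' between A's electrode pattern late in training and B's pattern early in
#' training against the correlation between A early and B late. Under
#' chaining, the representation of A drifts toward B in anticipation, so
#' cor(A_late, B_early) exceeds cor(A_early, B_late). Patterns are mean
#' electrode vectors of band/period-averaged power per element, computed
#' separately for the first and second half of each subject's blocks;
#' correlation differences are Fisher z-transformed, averaged over
#' transitions within subject, and tested against zero across subjects.
#'
#' @param subjects list, one entry per subject: a list with `x` (trials x
#'   electrodes band/period power), `elements` (per-trial element label),
#'   `block` (per-trial block number).
#' @param transitions data.frame `from`, `to` (default: Exp 1/2 chunk-pool
#'   transitions).
#' @param split fraction of blocks in the "early" half (default 0.5).
#' @return a `chaining_result`: `mean_diff`, `t`, `p`, `df`,
#'   `per_subject`.
#' @export
chaining_test <- function(subjects,
                          transitions = within_chunk_transitions(c("ABC", "BCA", "CAB")),
                          split = 0.5) {
  per_subject <- vapply(subjects, function(su) {
    blocks <- sort(unique(su$block))
    cut <- blocks[max(1L, floor(length(blocks) * split))]
    half <- ifelse(su$block <= cut, "early", "late")
    pat <- function(el, h) {
      sel <- su$elements == el & half == h
      if (!any(sel)) return(NULL)
      colMeans(su$x[sel, , drop = FALSE])
    }
    diffs <- numeric()
    for (i in seq_len(nrow(transitions))) {
      a <- transitions$from[i]; b <- transitions$to[i]
      ae <- pat(a, "early"); al <- pat(a, "late")
      be <- pat(b, "early"); bl <- pat(b, "late")
      if (is.null(ae) || is.null(al) || is.null(be) || is.null(bl)) {
        warning(sprintf("transition %s->%s missing in one half; excluded", a, b),
                call. = FALSE)
        next
      }
      diffs <- c(diffs, atanh(stats::cor(al, be)) - atanh(stats::cor(ae, bl)))
    }
    mean(diffs)
  }, numeric(1))
  n <- length(per_subject)
  m <- mean(per_subject)
  se <- if (n > 1) stats::sd(per_subject) / sqrt(n) else NA_real_
  tval <- if (is.na(se)) NA_real_ else if (se == 0) 0 else m / se
  structure(list(mean_diff = m, t = tval,
                 p = 2 * stats::pt(-abs(tval), df = n - 1), df = n - 1,
                 per_subject = per_subject),
            class = "chaining_result")
}
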