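#' Decoding configuration
#'
#' @param n_folds number of cross-validation folds (default 4).
#' @param n_iterations repetitions of the whole cross-validation with fresh
#'   random partitions (default 30).
#' @param window_samples sliding trial-averaging window length in samples
#'   (default 25, i.e. 100 ms at 250 Hz).
#' @param window_step step between evaluated window centers in samples
#'   (default 1; larger values decimate the time axis for speed).
#' @param shrinkage covariance shrinkage intensity for the linear
#'   discriminant: `"auto"` (Ledoit-Wolf toward a scaled identity) or a
#'   number in \[0, 1\].
#' @param seed master seed; iteration i uses stream `seed + i`.
#' @return a `decode_config` list.
#' @export
decode_config <- function(n_folds = 4L, n_iterations = 30L,
                          window_samples = 25L, window_step = 1L,
                          shrinkage = "auto", seed = 1L) {
  stopifnot(n_folds >= 2, n_iterations >= 1, window_samples >= 1,
            window_step >= 1)
  structure(list(n_folds = as.integer(n_folds),
                 n_iterations = as.integer(n_iterations),
                 window_samples = as.integer(window_samples),
                 window_step = as.integer(window_step),
                 shrinkage = shrinkage, seed = as.integer(seed)),
            class = "decode_config")
}

#' Random fold assignment with count equating
#'
#' Partitions trials into `n_folds` folds and equates the number of
#' observations per class within and across folds by randomly dropping
#' trials from larger classes: every fold ends up holding exactly
#' `floor(min(class count) / n_folds)` trials of every class.
#'
#' @param labels class labels (coerced to factor).
#' @param n_folds number of folds.
#' @param seed optional seed; if `NULL` the current RNG stream is used
#'   (as inside the decoder's iteration loop).
#' @return integer vector of fold ids (1..n_folds), `NA` for dropped trials.
#' @export
make_folds <- function(labels, n_folds = 4L, seed = NULL) {
  if (!is.null(seed)) local_rng(seed)
  y <- factor(labels)
  counts <- table(y)
  short <- names(counts)[counts < n_folds]
  if (length(short)) {
    stop("class(es) with fewer trials than folds: ",
         paste(short, collapse = ", "), call. = FALSE)
  }
  per_fold <- floor(min(counts) / n_folds)
  folds <- rep(NA_integer_, length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    keep <- idx[seq_len(per_fold * n_folds)]
    folds[keep] <- rep(seq_len(n_folds), each = per_fold)
  }
  folds
}

# z-score each row across its columns with the population SD; constant
# rows (sd 0) map to all zeros.
zscore_rows <- function(m) {
  mu <- rowMeans(m)
  sdp <- sqrt(rowMeans(m^2) - mu^2)
  sdp[sdp < .Machine$double.eps^0.5] <- Inf
  (m - mu) / sdp
}

#' Shrinkage-regularized linear discriminant classifier
#'
#' Gaussian linear discriminant with a common within-class covariance,
#' shrunk toward a scaled identity: `S* = (1 - lambda) S + lambda *
#' mean(diag(S)) I`. With `shrinkage = "auto"` the intensity follows the
#' Ledoit-Wolf estimate computed from the pooled within-class centered
#' observations, which keeps the classifier well-posed when observations
#' are scarcer than features. Priors are uniform (class counts are equated
#' upstream).
#'
#' @param x numeric matrix (observations x features).
#' @param y class labels.
#' @param shrinkage `"auto"` or fixed intensity in \[0, 1\].
#' @return an `lda_shrink` model (class means, inverse covariance, levels,
#'   lambda used).
#' @export
lda_shrink <- function(x, y, shrinkage = "auto") {
  y <- factor(y)
  k <- nlevels(y)
  stopifnot(k >= 2)
  p <- ncol(x)
  means <- do.call(rbind, lapply(levels(y), function(cl) {
    colMeans(x[y == cl, , drop = FALSE])
  }))
  centered <- x - means[as.integer(y), , drop = FALSE]
  n <- nrow(x)
  s <- crossprod(centered) / n
  mu <- mean(diag(s))
  if (identical(shrinkage, "auto")) {
    d2 <- sum((s - diag(mu, p))^2)
    if (d2 < .Machine$double.eps) {
      lambda <- 0
    } else {
      # Ledoit-Wolf: b2 = average squared deviation of per-observation
      # outer products from S, capped at d2
      ssq <- rowSums(centered^2)
      b2 <- (sum(ssq^2) / n - sum(s^2)) / n
      lambda <- min(1, max(0, b2 / d2))
    }
  } else {
    lambda <- shrinkage
  }
  s_shrunk <- (1 - lambda) * s + diag(lambda * mu + 1e-10, p)
  inv <- solve(s_shrunk)
  structure(list(means = means, inv_cov = inv, levels = levels(y),
                 lambda = lambda), class = "lda_shrink")
}

#' @param object an `lda_shrink` model.
#' @param newdata matrix of observations to classify.
#' @param ... unused.
#' @return `predict` returns a list with `class` (factor) and `posterior`
#'   (matrix, rows sum to 1).
#' @rdname lda_shrink
#' @export
predict.lda_shrink <- function(object, newdata, ...) {
  am <- object$inv_cov %*% t(object$means)          # p x k
  disc <- newdata %*% am - matrix(0.5 * colSums(t(object$means) * am),
                                  nrow(newdata), length(object$levels),
                                  byrow = TRUE)
  disc <- disc - apply(disc, 1, max)
  post <- exp(disc)
  post <- post / rowSums(post)
  colnames(post) <- object$levels
  cls <- factor(object$levels[max.col(post, ties.method = "first")],
                levels = object$levels)
  list(class = cls, posterior = post)
}

# per-group (rows of `groups` factor) mean of the trials x (e*f*t) matrix,
# then centered moving average over time and restriction to valid centers
group_average_smooth <- function(power_mat, groups, n_e, n_f, n_time, win, step) {
  gm <- rowsum(power_mat, groups, reorder = TRUE)
  gm <- gm / as.vector(rowsum(rep(1, length(groups)), groups, reorder = TRUE))
  n_g <- nrow(gm)
  half <- (win - 1L) %/% 2L
  centers <- seq(1L + half, n_time - (win - 1L - half), by = step)
  if (win == 1L) {
    sm <- array(gm, dim = c(n_g, n_e, n_f, n_time))[, , , centers, drop = FALSE]
  } else {
    m3 <- array(gm, dim = c(n_g * n_e * n_f, n_time))
    cs <- cbind(0, t(apply(m3, 1, cumsum)))
    lo <- centers - half
    hi <- centers + (win - 1L - half)
    sm <- (cs[, hi + 1L, drop = FALSE] - cs[, lo, drop = FALSE]) / win
    sm <- array(sm, dim = c(n_g, n_e, n_f, length(centers)))
  }
  list(values = sm, centers = centers)
}

# z-score across electrodes (dim 2) for every (group, freq, time) cell
zscore_electrode_dim <- function(a) {
  mu <- apply(a, c(1, 3, 4), mean)
  sdp <- sqrt(pmax(apply(a^2, c(1, 3, 4), mean) - mu^2, 0))
  sdp[sdp < .Machine$double.eps^0.5] <- Inf
  n_e <- dim(a)[2]
  mu_full <- aperm(array(mu, dim = c(dim(a)[1], dim(a)[3], dim(a)[4], n_e)),
                   c(1, 4, 2, 3))
  sd_full <- aperm(array(sdp, dim = c(dim(a)[1], dim(a)[3], dim(a)[4], n_e)),
                   c(1, 4, 2, 3))
  (a - mu_full) / sd_full
}

#' Frequency-by-time decoding map
#'
#' For every (frequency, time) cell, trains an independent linear
#' discriminant on class-by-fold observations built by (1) randomly
#' partitioning trials into folds with per-class count equating, (2)
#' averaging power over trials within each fold and class with a centered
#' sliding window over time, and (3) z-scoring the averaged values across
#' electrodes separately for every class, frequency and time point. Each
#' fold serves once as the test set while the remaining folds train the
#' classifier, the whole procedure is repeated `n_iterations` times with
#' fresh partitions, and test-set results are averaged. Test observations
#' are constructed within the test fold by the identical
#' averaging/z-scoring transform (no train-to-test parameter transfer).
#'
#' @param tf a `tf_power`.
#' @param labels per-trial class labels (length = trials).
#' @param config a [decode_config()].
#' @param condition optional per-trial stratum labels: test observations
#'   are then additionally built per (class, stratum) within the held-out
#'   fold while training still uses all strata ("train on all, test within
#'   stratum").
#' @param exclude optional logical vector of trials to drop before
#'   decoding (e.g. artifact or behavioral exclusions).
#' @return a `decoding_map`: `accuracy` (freqs x times, or per-stratum list
#'   when `condition` is given), `confusion` (freqs x times x predicted x
#'   true, columns over predicted sum to 1), `freqs`, `times` (window-center
#'   ms), `chance`, `n_classes`.
#' @export
decode_map <- function(tf, labels, config = decode_config(),
                       condition = NULL, exclude = NULL) {
  y_all <- factor(labels)
  stopifnot(length(y_all) == dim(tf$power)[1], nlevels(y_all) >= 2)
  keep0 <- if (is.null(exclude)) rep(TRUE, length(y_all)) else !exclude
  pw <- tf$power[keep0, , , , drop = FALSE]
  y <- droplevels(y_all[keep0])
  cond <- if (is.null(condition)) NULL else factor(condition[keep0])
  d <- dim(pw)
  n_t <- d[1]; n_e <- d[2]; n_f <- d[3]; n_s <- d[4]
  k <- nlevels(y)
  pmat <- matrix(pw, nrow = n_t)

  half <- (config$window_samples - 1L) %/% 2L
  centers <- seq(1L + half, n_s - (config$window_samples - 1L - half),
                 by = config$window_step)
  n_c <- length(centers)
  acc_num <- matrix(0, n_f, n_c)
  acc_den <- 0
  conf <- array(0, dim = c(n_f, n_c, k, k))
  strata <- if (is.null(cond)) NULL else levels(cond)
  if (!is.null(strata)) {
    acc_s <- array(0, dim = c(n_f, n_c, length(strata)))
    den_s <- numeric(length(strata))
  }

  g_fold <- rep(seq_len(config$n_folds), k)       # fold fastest within class
  g_class <- rep(seq_len(k), each = config$n_folds)

  for (iter in seq_len(config$n_iterations)) {
    local_rng(config$seed + iter)
    folds <- make_folds(y, config$n_folds)
    kept <- !is.na(folds)
    # explicit integer group ids keep row order deterministic under rowsum
    gid <- (as.integer(y[kept]) - 1L) * config$n_folds + folds[kept]
    gs <- group_average_smooth(pmat[kept, , drop = FALSE], gid, n_e, n_f, n_s,
                               config$window_samples, config$window_step)
    z <- zscore_electrode_dim(gs$values)

    if (!is.null(strata)) {
      gid2 <- ((as.integer(cond[kept]) - 1L) * k +
                 (as.integer(y[kept]) - 1L)) * config$n_folds + folds[kept]
      gss <- group_average_smooth(pmat[kept, , drop = FALSE], gid2, n_e, n_f,
                                  n_s, config$window_samples,
                                  config$window_step)
      zs <- zscore_electrode_dim(gss$values)
      ids <- sort(unique(gid2))
      info <- data.frame(
        fold = (ids - 1L) %% config$n_folds + 1L,
        class = ((ids - 1L) %/% config$n_folds) %% k + 1L,
        stratum = (ids - 1L) %/% (config$n_folds * k) + 1L
      )
    }

    for (f in seq_len(n_f)) {
      for (ci in seq_len(n_c)) {
        xc <- z[, , f, ci]
        for (r in seq_len(config$n_folds)) {
          tr <- g_fold != r
          fit <- lda_shrink(xc[tr, , drop = FALSE], g_class[tr],
                            config$shrinkage)
          pred <- predict(fit, xc[!tr, , drop = FALSE])
          truth <- g_class[!tr]
          pc <- as.integer(as.character(pred$class))
          acc_num[f, ci] <- acc_num[f, ci] + sum(pc == truth)
          for (j in seq_along(truth)) {
            conf[f, ci, pc[j], truth[j]] <- conf[f, ci, pc[j], truth[j]] + 1
          }
          if (!is.null(strata)) {
            te_s <- which(info$fold == r)
            if (length(te_s)) {
              xt <- matrix(zs[te_s, , f, ci], ncol = n_e)
              preds <- predict(fit, xt)
              hits <- as.integer(as.character(preds$class)) == info$class[te_s]
              for (s in seq_along(strata)) {
                m <- info$stratum[te_s] == s
                if (any(m)) acc_s[f, ci, s] <- acc_s[f, ci, s] + sum(hits[m])
              }
            }
          }
        }
      }
    }
    acc_den <- acc_den + k * config$n_folds
    if (!is.null(strata)) {
      for (s in seq_along(strata)) {
        den_s[s] <- den_s[s] + sum(info$stratum == s)
      }
    }
  }

  conf_norm <- conf
  for (tc in seq_len(k)) {
    colsum <- apply(conf[, , , tc, drop = FALSE], c(1, 2), sum)
    for (pc in seq_len(k)) conf_norm[, , pc, tc] <- conf[, , pc, tc] / colsum
  }

  out <- list(accuracy = acc_num / acc_den, confusion = conf_norm,
              freqs = tf$freqs, times = tf$times[centers], chance = 1 / k,
              n_classes = k, levels = levels(y),
              config = config)
  if (!is.null(strata)) {
    out$accuracy_by_stratum <- lapply(seq_along(strata), function(s) {
      acc_s[, , s] / den_s[s]
    })
    names(out$accuracy_by_stratum) <- strata
    out$strata <- strata
  }
  class(out) <- "decoding_map"
  out
}

#' @export
print.decoding_map <- function(x, ...) {
  cat(sprintf(
    "<decoding_map: %d freqs x %d times, %d classes (chance %.3f), mean accuracy %.3f>\n",
    length(x$freqs), length(x$times), x$n_classes, x$chance,
    mean(x$accuracy)))
  invisible(x)
}

#' Average a decoding map over a band and period
#'
#' @param map a `decoding_map` (or any list with `accuracy`, `freqs`,
#'   `times`).
#' @param band `"theta"` (4-7 Hz), `"alpha"` (8-12 Hz) or numeric
#'   \[f_lo, f_hi\].
#' @param period `"prep"` (-600-0 ms), `"probe"` (0-300 ms) or numeric
#'   \[t0, t1\].
#' @return scalar mean accuracy over the rectangle.
#' @export
summarize_period <- function(map, band = "theta", period = "prep") {
  band <- resolve_band(band)
  period <- resolve_period(period)
  fsel <- map$freqs >= band[1] & map$freqs <= band[2]
  tsel <- map$times >= period[1] & map$times <= period[2]
  if (!any(fsel) || !any(tsel)) stop("empty band/period selection", call. = FALSE)
  mean(map$accuracy[fsel, tsel])
}

#' Decode a single pattern matrix (band/period-reduced data)
#'
#' Same repeated, count-equated, fold-averaged cross-validation as
#' [decode_map()], applied to one trials x features matrix (typically the
#' output of [band_period_power()]): fold-by-class rows are trial averages
#' z-scored across features, and accuracy/confusions come from classifying
#' the held-out fold's class rows. In addition, every held-out single trial
#' (z-scored across features) is classified, and its clipped, logit
#' posterior probability of the correct label is averaged over iterations
#' as per-trial evidence.
#'
#' @param x trials x features matrix.
#' @param labels per-trial class labels.
#' @param config a [decode_config()] (`window_samples` is ignored here).
#' @param evidence compute per-trial evidence (default TRUE).
#' @param posterior_clip clipping bounds applied before the logit.
#' @return list: `accuracy`, `confusion` (predicted x true, columns sum to
#'   1), `evidence` (per input trial, NA if never held out), `chance`,
#'   `levels`.
#' @export
decode_patterns <- function(x, labels, config = decode_config(),
                            evidence = TRUE, posterior_clip = 1e-6) {
  y <- factor(labels)
  stopifnot(nrow(x) == length(y), nlevels(y) >= 2)
  k <- nlevels(y)
  acc_num <- 0; acc_den <- 0
  conf <- matrix(0, k, k)
  ev_sum <- numeric(nrow(x)); ev_n <- numeric(nrow(x))

  for (iter in seq_len(config$n_iterations)) {
    local_rng(config$seed + iter)
    folds <- make_folds(y, config$n_folds)
    for (r in seq_len(config$n_folds)) {
      tr <- which(!is.na(folds) & folds != r)
      te <- which(!is.na(folds) & folds == r)
      train_rows <- class_fold_rows(x, y, folds, setdiff(seq_len(config$n_folds), r))
      fit <- lda_shrink(train_rows$x, train_rows$y, config$shrinkage)
      test_rows <- class_fold_rows(x, y, folds, r)
      pred <- predict(fit, test_rows$x)
      hit <- as.integer(pred$class) == test_rows$y
      acc_num <- acc_num + sum(hit); acc_den <- acc_den + length(hit)
      for (j in seq_along(test_rows$y)) {
        conf[as.integer(pred$class[j]), test_rows$y[j]] <-
          conf[as.integer(pred$class[j]), test_rows$y[j]] + 1
      }
      if (evidence && length(te)) {
        zt <- zscore_rows(x[te, , drop = FALSE])
        pt <- predict(fit, zt)$posterior
        pcorr <- pt[cbind(seq_along(te), as.integer(y[te]))]
        pcorr <- pmin(pmax(pcorr, posterior_clip), 1 - posterior_clip)
        ev_sum[te] <- ev_sum[te] + stats::qlogis(pcorr)
        ev_n[te] <- ev_n[te] + 1
      }
    }
  }
  ev <- ifelse(ev_n > 0, ev_sum / ev_n, NA_real_)
  conf_norm <- sweep(conf, 2, colSums(conf), "/")
  list(accuracy = acc_num / acc_den, confusion = conf_norm,
       evidence = if (evidence) ev else NULL, chance = 1 / k,
       levels = levels(y))
}

# fold-by-class averaged, z-scored rows for the given folds
class_fold_rows <- function(x, y, folds, use_folds) {
  rows <- list(); ys <- integer()
  for (r in use_folds) {
    for (cl in seq_len(nlevels(y))) {
      idx <- which(!is.na(folds) & folds == r & as.integer(y) == cl)
      rows[[length(rows) + 1L]] <- colMeans(x[idx, , drop = FALSE])
      ys <- c(ys, cl)
    }
  }
  list(x = zscore_rows(do.call(rbind, rows)), y = ys)
}

#' Condition-wise decoding
#'
#' Two modes of decoding a code separately per stratum of a condition
#' variable: `"train_all"` trains on data from all strata and tests within
#' each stratum (via [decode_map()]'s `condition` argument); `"within"`
#' trains and tests inside each stratum separately.
#'
#' @param tf a `tf_power`.
#' @param labels per-trial class labels.
#' @param condition per-trial stratum labels.
#' @param config a [decode_config()].
#' @param mode `"train_all"` or `"within"`.
#' @return named list of per-stratum accuracy matrices (plus the full map
#'   for `"train_all"`); `mode` recorded in `attr(, "mode")`. Empty strata
#'   are skipped with a warning.
#' @export
decode_conditional <- function(tf, labels, condition, config = decode_config(),
                               mode = c("train_all", "within")) {
  mode <- match.arg(mode)
  cond <- factor(condition)
  empty <- levels(cond)[!levels(cond) %in% unique(as.character(cond))]
  if (length(empty)) {
    warning("skipping empty strata: ", paste(empty, collapse = ", "),
            call. = FALSE)
    cond <- droplevels(cond)
  }
  if (mode == "train_all") {
    map <- decode_map(tf, labels, config, condition = cond)
    out <- map$accuracy_by_stratum
    attr(out, "map") <- map
  } else {
    out <- lapply(levels(cond), function(s) {
      sel <- cond == s
      sub <- tf
      sub$power <- tf$power[sel, , , , drop = FALSE]
      sub$schedule <- tf$schedule[sel, , drop = FALSE]
      decode_map(sub, labels[sel], config)$accuracy
    })
    names(out) <- levels(cond)
  }
  attr(out, "mode") <- mode
  out
}
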