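#' Flag trials excluded from RT analyses
#'
#' Flags (never deletes) error trials, the trial immediately following an
#' error within the same block, trials with RT below 100 ms, and -- for the
#' self-paced `exp2` variant -- trials with a retrieval time above 8000 ms.
#' Downstream EEG and RT analyses honor the flags. Flagging is idempotent.
#'
#' @param behavior a `behavior_table`.
#' @param variant experiment variant; retrieval-time exclusion only applies
#'   to `"exp2"`.
#' @param rt_min RT floor in ms (default 100).
#' @param retrieval_max retrieval-time ceiling in ms (default 8000).
#' @return the table with logical `excluded` and character
#'   `exclusion_reason` (`""` when kept; reasons joined by `+`).
#' @export
apply_exclusions <- function(behavior, variant = c("exp1", "exp2", "exp3"),
                             rt_min = 100, retrieval_max = 8000) {
  variant <- match.arg(variant)
  n <- nrow(behavior)
  err <- !behavior$correct
  post_err <- rep(FALSE, n)
  blk <- interaction(behavior$subject, behavior$block, drop = TRUE)
  prev_same <- c(FALSE, blk[-n] == blk[-1])
  post_err[which(prev_same)] <- err[which(prev_same) - 1L]
  reasons <- list(
    error = err,
    post_error = post_err,
    fast_rt = behavior$rt < rt_min
  )
  if (variant == "exp2" && "retrieval_time" %in% names(behavior)) {
    reasons$slow_retrieval <- behavior$retrieval_time > retrieval_max
  }
  mat <- do.call(cbind, reasons)
  behavior$excluded <- rowSums(mat) > 0
  behavior$exclusion_reason <- apply(mat, 1, function(r) {
    paste(names(reasons)[r], collapse = "+")
  })
  behavior
}

#' Sequence-structure contrasts on RT and accuracy
#'
#' Computes subject-level condition means by within-chunk position and
#' tests two orthogonal within-subject contrasts: position 1 against the
#' mean of positions 2 and 3 (the chunk-boundary effect), and position 2
#' against position 3. Contrast tests are paired t-tests on the
#' within-subject contrast values (equivalent to the 1-df repeated-measures
#' ANOVA F, with F = t^2). With `wm_groups`, a boundary-by-WM-group
#' interaction (two-sample t on the boundary contrast between groups) is
#' added. RT contrasts use non-excluded trials; accuracy contrasts use all
#' non-post-error trials. Within-subject 95% CIs (subject-mean centered,
#' Cousineau-Morey) accompany the condition means for plotting.
#'
#' @param behavior a `behavior_table` with exclusions applied; multiple
#'   subjects distinguished by the `subject` column.
#' @param wm_groups optional named vector/factor of `"low"`/`"high"` per
#'   subject (names = subject ids).
#' @return list with `contrasts` (data.frame: `measure`, `contrast`,
#'   `estimate`, `se`, `t`, `F`, `p`, `df`) and `cell_means` (per
#'   position means with within-subject CI half-widths).
#' @export
structure_contrasts <- function(behavior, wm_groups = NULL) {
  subjects <- unique(behavior$subject)
  if (length(subjects) < 2L) stop("need at least 2 subjects", call. = FALSE)
  per_subj <- do.call(rbind, lapply(subjects, function(s) {
    d <- behavior[behavior$subject == s, ]
    rt_ok <- d[!d$excluded, ]
    acc_ok <- if ("exclusion_reason" %in% names(d)) {
      d[!grepl("post_error", d$exclusion_reason), ]
    } else d
    pos_rt <- tapply(rt_ok$rt, rt_ok$within_position, mean)
    pos_acc <- tapply(acc_ok$correct, acc_ok$within_position, mean)
    if (anyNA(pos_rt) || length(pos_rt) < 3L) return(NULL)
    data.frame(subject = s,
               rt1 = pos_rt["1"], rt2 = pos_rt["2"], rt3 = pos_rt["3"],
               acc1 = pos_acc["1"], acc2 = pos_acc["2"], acc3 = pos_acc["3"])
  }))
  dropped <- setdiff(subjects, per_subj$subject)
  if (length(dropped)) {
    warning("subject(s) dropped for missing condition cells: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }

  one <- function(vals, measure, contrast) {
    n <- length(vals)
    est <- mean(vals); se <- stats::sd(vals) / sqrt(n)
    tval <- if (se == 0) 0 else est / se
    data.frame(measure = measure, contrast = contrast, estimate = est,
               se = se, t = tval, F = tval^2,
               p = 2 * stats::pt(-abs(tval), n - 1), df = n - 1)
  }
  ctr <- rbind(
    one(per_subj$rt1 - (per_subj$rt2 + per_subj$rt3) / 2, "rt", "pos1_vs_23"),
    one(per_subj$rt2 - per_subj$rt3, "rt", "pos2_vs_3"),
    one((per_subj$acc2 + per_subj$acc3) / 2 - per_subj$acc1, "error", "pos1_vs_23"),
    one(per_subj$acc2 - per_subj$acc3, "error", "pos2_vs_3")
  )
  if (!is.null(wm_groups)) {
    grp <- wm_groups[as.character(per_subj$subject)]
    b_rt <- per_subj$rt1 - (per_subj$rt2 + per_subj$rt3) / 2
    b_ac <- (per_subj$acc2 + per_subj$acc3) / 2 - per_subj$acc1
    for (m in c("rt", "error")) {
      v <- if (m == "rt") b_rt else b_ac
      tt <- stats::t.test(v[grp == "low"], v[grp == "high"], var.equal = TRUE)
      ctr <- rbind(ctr, data.frame(
        measure = m, contrast = "boundary_x_wm",
        estimate = mean(v[grp == "low"]) - mean(v[grp == "high"]),
        se = tt$stderr, t = unname(tt$statistic),
        F = unname(tt$statistic)^2, p = tt$p.value,
        df = unname(tt$parameter)))
    }
  }

  # Cousineau-Morey within-subject CIs on RT cell means
  cm <- as.matrix(per_subj[, c("rt1", "rt2", "rt3")])
  centered <- cm - rowMeans(cm) + mean(cm)
  morey <- sqrt(3 / 2)   # k/(k-1) correction for 3 conditions
  ci <- apply(centered, 2, stats::sd) / sqrt(nrow(cm)) * morey *
    stats::qt(0.975, nrow(cm) - 1)
  cell_means <- data.frame(position = 1:3, rt = colMeans(cm), rt_ci = ci)

  list(contrasts = ctr, cell_means = cell_means, per_subject = per_subj)
}

#' Residualize log RT against design nuisance variables
#'
#' Per subject, regresses log RT of non-excluded trials on linear and
#' quadratic trends of trial and block, the two within-chunk position
#' contrasts (1 vs 2&3, 2 vs 3), and probe match/mismatch, and returns the
#' residuals (NA for excluded trials). Residuals are orthogonal to every
#' nuisance column by construction.
#'
#' @param behavior a `behavior_table` with exclusions applied.
#' @return numeric vector of residual log RT, aligned with the input rows.
#' @export
residualize_rt <- function(behavior) {
  stopifnot("excluded" %in% names(behavior))
  out <- rep(NA_real_, nrow(behavior))
  for (s in unique(behavior$subject)) {
    idx <- which(behavior$subject == s & !behavior$excluded)
    d <- behavior[idx, ]
    x <- data.frame(
      trial = as.numeric(scale(d$serial_index + (d$block - 1) * max(d$serial_index))),
      block = as.numeric(scale(d$block)),
      pos1 = ifelse(d$within_position == 1, 2 / 3, -1 / 3),
      pos23 = ifelse(d$within_position == 2, 0.5,
                     ifelse(d$within_position == 3, -0.5, 0)),
      match = as.numeric(d$is_match)
    )
    x$trial2 <- x$trial^2
    x$block2 <- x$block^2
    fml <- stats::lm(log(d$rt) ~ trial + trial2 + block + block2 + pos1 +
                       pos23 + match, data = x)
    if (any(is.na(stats::coef(fml)))) {
      stop("rank-deficient nuisance design for subject ", s, call. = FALSE)
    }
    out[idx] <- stats::residuals(fml)
  }
  out
}

#' Mixed model relating single-trial decoding evidence to RT
#'
#' Fits residualized log RT on alpha-band element evidence and theta-band
#' position evidence (logit posterior of the correct label) as simultaneous
#' fixed effects with per-subject random intercepts and slopes. If the
#' mixed model fails, a two-stage fallback (per-subject least squares, then
#' one-sample t-tests on the coefficients) is used and recorded. t-values
#' use the normal approximation.
#'
#' @param data data.frame with columns `subject`, `resid_rt`,
#'   `ev_element`, `ev_position` (rows with NA dropped).
#' @return a `multilevel_fit`: `coefficients` data.frame (`term`, `b`,
#'   `se`, `t`), `path`.
#' @export
evidence_rt_model <- function(data) {
  d <- stats::na.omit(data[, c("subject", "resid_rt", "ev_element", "ev_position")])
  if (length(unique(d$subject)) < 2L) stop("need at least 2 subjects", call. = FALSE)
  terms <- c("ev_element", "ev_position")
  fit <- tryCatch({
    m <- suppressWarnings(suppressMessages(
      lme4::lmer(resid_rt ~ ev_element + ev_position +
                   (1 + ev_element + ev_position | subject), data = d,
                 control = lme4::lmerControl(check.conv.singular = "ignore",
                                             check.conv.grad = "ignore"))))
    b <- lme4::fixef(m)[terms]
    se <- sqrt(diag(as.matrix(stats::vcov(m))))[terms]
    list(co = data.frame(term = terms, b = unname(b), se = unname(se),
                         t = unname(b / se)), path = "mixed")
  }, error = function(e) NULL)
  if (is.null(fit)) {
    co <- t(vapply(unique(d$subject), function(s) {
      stats::coef(stats::lm(resid_rt ~ ev_element + ev_position,
                            data = d[d$subject == s, ]))[terms]
    }, numeric(2)))
    b <- colMeans(co); se <- apply(co, 2, stats::sd) / sqrt(nrow(co))
    fit <- list(co = data.frame(term = terms, b = unname(b), se = unname(se),
                                t = unname(b / se)), path = "two_stage")
  }
  structure(list(coefficients = fit$co, path = fit$path,
                 n_subjects = length(unique(d$subject)), n_trials = nrow(d)),
            class = "multilevel_fit")
}

#' @export
print.multilevel_fit <- function(x, ...) {
  cat(sprintf("<multilevel_fit (%s): %d subjects, %d trials>\n",
              x$path, x$n_subjects, x$n_trials))
  print(x$coefficients, row.names = FALSE)
  invisible(x)
}

#' WM-group comparison of decoding summaries
#'
#' Independent-groups t-test of band/period decoding accuracy between
#' high- and low-WM subjects for each code, plus the code-level
#' (chunk identity vs element) by WM-group interaction: the per-subject
#' chunk-minus-element accuracy difference compared between groups
#' (two-sample t; F = t^2).
#'
#' @param summaries data.frame with columns `subject`, `code`, `accuracy`
#'   (one row per subject x code).
#' @param wm_groups named vector/factor `"low"`/`"high"` per subject.
#' @param level_codes length-2 character: the element-level and chunk-level
#'   codes entering the interaction (default `c("element",
#'   "chunk_identity")`).
#' @return list with `group_tests` data.frame and `interaction` row.
#' @export
wm_decoding_comparison <- function(summaries, wm_groups,
                                   level_codes = c("element", "chunk_identity")) {
  grp <- wm_groups[as.character(summaries$subject)]
  if (min(table(grp[!duplicated(summaries$subject)])) < 2L) {
    stop("each WM group needs at least 2 subjects", call. = FALSE)
  }
  tests <- do.call(rbind, lapply(unique(summaries$code), function(cd) {
    sel <- summaries$code == cd
    tt <- stats::t.test(summaries$accuracy[sel & grp == "high"],
                        summaries$accuracy[sel & grp == "low"],
                        var.equal = TRUE)
    data.frame(code = cd,
               high = mean(summaries$accuracy[sel & grp == "high"]),
               low = mean(summaries$accuracy[sel & grp == "low"]),
               t = unname(tt$statistic), p = tt$p.value,
               df = unname(tt$parameter))
  }))
  wide <- stats::reshape(
    summaries[summaries$code %in% level_codes, c("subject", "code", "accuracy")],
    idvar = "subject", timevar = "code", direction = "wide")
  dlev <- wide[[paste0("accuracy.", level_codes[2])]] -
    wide[[paste0("accuracy.", level_codes[1])]]
  g <- wm_groups[as.character(wide$subject)]
  it <- stats::t.test(dlev[g == "high"], dlev[g == "low"], var.equal = TRUE)
  interaction <- data.frame(
    effect = "level_x_wm", t = unname(it$statistic),
    F = unname(it$statistic)^2, p = it$p.value, df = unname(it$parameter))
  list(group_tests = tests, interaction = interaction)
}
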