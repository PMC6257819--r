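# compact behavior table builder for rule tests
toy_behavior <- function(correct, rt = rep(500, length(correct)),
                         retrieval = NULL) {
  df <- data.frame(subject = 1, block = 1, serial_index = seq_along(correct),
                   within_position = rep_len(1:3, length(correct)),
                   is_match = TRUE, rt = rt, correct = correct)
  if (!is.null(retrieval)) df$retrieval_time <- retrieval
  class(df) <- c("behavior_table", "data.frame")
  df
}

test_that("exclusion rules flag errors, post-errors, fast RTs, slow retrievals", {
  b <- apply_exclusions(toy_behavior(c(TRUE, FALSE, TRUE, TRUE)))
  expect_equal(b$excluded, c(FALSE, TRUE, TRUE, FALSE))
  expect_match(b$exclusion_reason[2], "error")
  expect_match(b$exclusion_reason[3], "post_error")

  fast <- apply_exclusions(toy_behavior(rep(TRUE, 3), rt = c(90, 100, 500)))
  expect_equal(fast$excluded, c(TRUE, FALSE, FALSE))

  slow <- toy_behavior(rep(TRUE, 2), retrieval = c(9000, 500))
  expect_true(apply_exclusions(slow, "exp2")$excluded[1])
  expect_false(apply_exclusions(slow, "exp1")$excluded[1])

  # idempotent
  twice <- apply_exclusions(apply_exclusions(toy_behavior(c(TRUE, FALSE, TRUE))))
  once <- apply_exclusions(toy_behavior(c(TRUE, FALSE, TRUE)))
  expect_identical(twice$excluded, once$excluded)

  # post-error does not leak across block boundaries
  two_blocks <- toy_behavior(c(TRUE, FALSE, TRUE, TRUE))
  two_blocks$block <- c(1, 1, 2, 2)
  expect_false(apply_exclusions(two_blocks)$excluded[3])
})


test_that("structure contrasts recover the generator boundary parameters", {
  beh <- apply_exclusions(simulate_cohort(30, list(boundary_cost = 14,
                                                   boundary_error_cost = 0.038),
                                          seed = 60))
  res <- structure_contrasts(beh)
  rt <- res$contrasts[res$contrasts$measure == "rt" &
                        res$contrasts$contrast == "pos1_vs_23", ]
  expect_lt(abs(rt$estimate - 14), qt(0.975, rt$df) * rt$se)
  expect_gt(rt$F, 10)
  err <- res$contrasts[res$contrasts$measure == "error" &
                         res$contrasts$contrast == "pos1_vs_23", ]
  expect_lt(abs(err$estimate - 0.038), qt(0.975, err$df) * err$se)
  expect_equal(rt$F, rt$t^2)
  expect_true(all(c("rt", "rt_ci") %in% names(res$cell_means)))
})

test_that("null boundary cost gives a near-zero contrast", {
  beh <- apply_exclusions(simulate_cohort(12, list(boundary_cost = 0,
                                                   boundary_error_cost = 0),
                                          seed = 61, n_blocks = 12))
  res <- structure_contrasts(beh)
  rt <- res$contrasts[res$contrasts$measure == "rt" &
                        res$contrasts$contrast == "pos1_vs_23", ]
  expect_lt(abs(rt$estimate), 3 * rt$se + 1)
})

test_that("the boundary-cost estimator is unbiased across replicates", {
  # replicate-level mean of the estimate stays within 1 ms of truth
  ests <- vapply(1:60, function(r) {
    beh <- apply_exclusions(simulate_cohort(10, list(boundary_cost = 14),
                                            seed = 6000 + 31 * r,
                                            n_blocks = 8))
    res <- structure_contrasts(beh)
    res$contrasts$estimate[res$contrasts$measure == "rt" &
                             res$contrasts$contrast == "pos1_vs_23"]
  }, numeric(1))
  expect_lt(abs(mean(ests) - 14), 1)
})

test_that("a WM-scaled boundary effect is detected as an interaction", {
  wm <- rep(c("low", "high"), each = 15)
  beh <- apply_exclusions(simulate_cohort(
    30, list(boundary_cost = 14, wm_group_scaling = 3), seed = 62, wm = wm))
  groups <- setNames(wm, 1:30)
  res <- structure_contrasts(beh, wm_groups = groups)
  it <- res$contrasts[res$contrasts$contrast == "boundary_x_wm" &
                        res$contrasts$measure == "rt", ]
  expect_gt(it$estimate, 0)  # low group has the larger boundary cost
  expect_lt(it$p, 0.05)
})

test_that("RT residualization is orthogonal to the nuisance set", {
  beh <- apply_exclusions(simulate_cohort(2, seed = 63, n_blocks = 8))
  r <- residualize_rt(beh)
  ok <- !beh$excluded
  expect_false(anyNA(r[ok]))
  for (s in 1:2) {
    sel <- ok & beh$subject == s
    nuis <- cbind(trial = beh$serial_index[sel] + 54 * (beh$block[sel] - 1),
                  block = beh$block[sel],
                  pos1 = beh$within_position[sel] == 1,
                  match = beh$is_match[sel])
    for (j in seq_len(ncol(nuis))) {
      expect_lt(abs(cor(r[sel], nuis[, j])), 1e-8)
    }
  }
})

test_that("residualization removes a pure quadratic block trend", {
  beh <- apply_exclusions(simulate_cohort(2, seed = 64, n_blocks = 10))
  beh$rt <- exp(6 + 0.02 * (beh$block - 5)^2)   # deterministic trend only
  r <- residualize_rt(beh)
  expect_lt(max(abs(r[!beh$excluded])), 1e-10)
})

test_that("a coupling between evidence and RT survives residualization", {
  d <- experiment_design("exp1")
  set.seed(65)
  rows <- lapply(1:8, function(s) {
    sch <- assign_probes(build_schedule(d, seed = 70 + s, subject = s),
                         seed = 170 + s)
    ev_el <- rnorm(nrow(sch))
    ev_po <- rnorm(nrow(sch))
    beh <- simulate_behavior(sch, list(evidence_coupling = -0.05),
                             seed = 270 + s, evidence = ev_el)
    beh$ev_element <- ev_el
    beh$ev_position <- ev_po
    beh
  })
  beh <- apply_exclusions(do.call(rbind, rows))
  beh$resid_rt <- residualize_rt(beh)
  fit <- evidence_rt_model(beh)
  co <- fit$coefficients
  b_el <- co$b[co$term == "ev_element"]
  se_el <- co$se[co$term == "ev_element"]
  expect_lt(abs(b_el - (-0.05)), 2.5 * se_el)
  expect_lt(b_el, 0)
  b_po <- co$b[co$term == "ev_position"]
  expect_lt(abs(b_po), 3 * co$se[co$term == "ev_position"] + 1e-3)
})

test_that("no coupling yields null slopes for both evidence terms", {
  d <- experiment_design("exp1")
  set.seed(66)
  rows <- lapply(1:6, function(s) {
    sch <- assign_probes(build_schedule(d, seed = 80 + s, subject = s,
                                        n_blocks = 12,
                                        allow_unbalanced = TRUE),
                         seed = 180 + s)
    beh <- simulate_behavior(sch, seed = 280 + s)
    beh$ev_element <- rnorm(nrow(sch))
    beh$ev_position <- rnorm(nrow(sch))
    beh
  })
  beh <- apply_exclusions(do.call(rbind, rows))
  beh$resid_rt <- residualize_rt(beh)
  co <- evidence_rt_model(beh)$coefficients
  expect_true(all(abs(co$t) < 3))
})

test_that("WM group comparison isolates an injected chunk-identity deficit", {
  set.seed(67)
  subjects <- 1:16
  wm <- setNames(rep(c("high", "low"), each = 8), subjects)
  summaries <- do.call(rbind, lapply(subjects, function(s) {
    chunk <- if (wm[s] == "high") rnorm(1, 0.38, 0.02) else rnorm(1, 1 / 3, 0.02)
    data.frame(subject = s,
               code = c("element", "chunk_identity"),
               accuracy = c(rnorm(1, 0.42, 0.02), chunk))
  }))
  res <- wm_decoding_comparison(summaries, wm)
  chunk_row <- res$group_tests[res$group_tests$code == "chunk_identity", ]
  el_row <- res$group_tests[res$group_tests$code == "element", ]
  expect_lt(chunk_row$p, 0.05)
  expect_gt(chunk_row$high, chunk_row$low)
  expect_gt(el_row$p, 0.05)
  expect_lt(res$interaction$p, 0.05)
  expect_error(
    wm_decoding_comparison(summaries[summaries$subject %in% c(1, 9), ],
                           wm[c(1, 9)]),
    "at least 2")
})
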