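mk_series <- function(starts, rate, valid = TRUE, reason = NULL) {
  if (is.null(reason)) reason <- ifelse(rep_len(valid, length(starts)),
                                        "ok", "out_of_band")
  rate_series(starts, rate = rate, quality = NA_real_, valid = valid,
              reason = reason)
}

test_that("exclusion mask drops invalid and out-of-range windows", {
  starts <- 0:9
  est <- mk_series(starts, 70)
  gold <- mk_series(starts, c(rep(70, 5), 150, rep(70, 4)))
  m <- exclusion_mask(est, gold, "hr")
  expect_equal(which(!m$included), 6L)
  expect_equal(m$reason[6], "gold_out_of_range")

  grr <- mk_series(starts, c(0.5, rep(14, 9)))
  mrr <- exclusion_mask(mk_series(starts, 14), grr, "rr")
  expect_equal(which(!mrr$included), 1L)

  clean <- exclusion_mask(est, mk_series(starts, 70), "hr")
  expect_true(all(clean$included))

  est_mv <- mk_series(starts, 70, valid = c(FALSE, rep(TRUE, 9)),
                      reason = c("moving", rep("ok", 9)))
  mm <- exclusion_mask(est_mv, mk_series(starts, 70), "hr")
  expect_equal(mm$reason[1], "est_moving")

  expect_error(exclusion_mask(mk_series(0:5, 70), mk_series(1:6, 70), "hr"),
               "grid")
})

test_that("agreement metrics match hand arithmetic", {
  starts <- 0:3
  gold <- mk_series(starts, 15)
  perfect <- agreement_metrics(mk_series(starts, 15), gold,
                               rep(TRUE, 4), c(1, 0.5))
  expect_equal(unname(perfect$pct_within), c(100, 100))
  expect_equal(perfect$rmse, 0)
  expect_equal(perfect$mae, 0)

  off1 <- agreement_metrics(mk_series(starts, 16), gold, rep(TRUE, 4), c(1, 0.5))
  expect_equal(unname(off1$pct_within), c(100, 0))
  expect_equal(off1$rmse, 1)
  expect_equal(off1$mae, 1)

  est <- mk_series(starts, 15 + c(0, 0, 3, 4))
  m <- agreement_metrics(est, gold, rep(TRUE, 4), c(1, 0.5))
  expect_equal(m$mae, 1.75)
  expect_equal(m$rmse, 2.5)
  expect_equal(m$n_windows_used, 4L)

  expect_error(agreement_metrics(est, gold, rep(FALSE, 4)), "undefined")
})

test_that("metric identities hold across random series", {
  set.seed(23)
  for (i in 1:200) {
    n <- sample(5:60, 1)
    starts <- seq_len(n) - 1
    gold <- mk_series(starts, runif(n, 10, 20))
    est <- mk_series(starts, gold$rate + rnorm(n, sd = runif(1, 0, 3)))
    thresholds <- sort(runif(3, 0.1, 5))
    m <- agreement_metrics(est, gold, rep(TRUE, n), thresholds)
    expect_gte(m$rmse, m$mae)
    expect_true(all(diff(unname(m$pct_within)) >= 0))  # monotone in threshold
    same <- agreement_metrics(gold, gold, rep(TRUE, n), thresholds)
    expect_equal(same$rmse, 0)
    expect_equal(unname(same$pct_within), rep(100, 3))
  }
})

test_that("mean-hold baseline holds the first-10-minute average", {
  starts <- 0:800
  gold <- mk_series(starts, 60)
  base <- mean_hold_baseline(gold)
  expect_equal(base$window_start_s, 600:800)
  expect_true(all(base$rate == 60))

  step <- mk_series(starts, c(rep(60, 600), rep(80, 201)))
  b2 <- mean_hold_baseline(step)
  m <- agreement_metrics(b2, step[step$window_start_s >= 600, ],
                         rep(TRUE, 201), c(5))
  expect_equal(m$mae, 20)

  expect_error(mean_hold_baseline(mk_series(0:100, 60)), "beyond")
})

test_that("pipeline beats the mean-hold baseline when the rate drifts", {
  drift <- round(seq(10, 22, length.out = 700))
  gen <- gen_trajectories(small_scene(duration_s = 700, resp_rate = drift,
                                      heart_rate = 0, noise_sigma_px = 0.05), 30)
  rr <- run_rr(tracked_from_traj(gen))
  truth <- vapply(rr$window_start_s, function(k)
    mean(drift[(k + 1):(k + 30)]), numeric(1))
  gold <- mk_series(rr$window_start_s, truth)
  post <- rr$window_start_s >= 600
  base <- mean_hold_baseline(gold)
  err_base <- sqrt(mean((base$rate - truth[post])^2))
  err_pipe <- sqrt(mean((rr$rate[post & rr$valid] - truth[post & rr$valid])^2))
  expect_gt(err_base, err_pipe)
})

test_that("stratified metrics equal per-subset recomputation", {
  set.seed(4)
  starts <- 0:59
  gold <- mk_series(starts, 15)
  est <- mk_series(starts, 15 + c(rnorm(30, sd = 0.1), rnorm(30, sd = 2)))
  mask <- exclusion_mask(est, gold, "rr")
  ann <- data.frame(start_s = c(0, 30), end_s = c(30, 60),
                    stratum_type = "stage", stratum_value = c("NREM", "REM"))
  strat <- stratified_metrics(est, gold, mask, ann, c(1, 0.5))
  expect_named(strat, "stage")
  expect_setequal(names(strat$stage), c("NREM", "REM"))
  for (v in c("NREM", "REM")) {
    sel <- if (v == "NREM") 1:30 else 31:60
    direct <- agreement_metrics(est[sel, ], gold[sel, ], rep(TRUE, 30), c(1, 0.5))
    expect_equal(strat$stage[[v]]$rmse, direct$rmse)
    expect_equal(strat$stage[[v]]$pct_within, direct$pct_within)
  }

  # pooling consistency: window-weighted squared errors reproduce pooled rmse
  pooled <- agreement_metrics(est, gold, mask, c(1))
  n1 <- strat$stage$NREM$n_windows_used; n2 <- strat$stage$REM$n_windows_used
  recomb <- sqrt((n1 * strat$stage$NREM$rmse^2 + n2 * strat$stage$REM$rmse^2) /
                   (n1 + n2))
  expect_equal(recomb, pooled$rmse)

  # single stratum covering everything equals the pooled report
  all_ann <- data.frame(start_s = 0, end_s = 60, stratum_type = "stage",
                        stratum_value = "all")
  expect_equal(stratified_metrics(est, gold, mask, all_ann, c(1))$stage$all$rmse,
               pooled$rmse)

  # contradictory overlapping annotations are an error
  bad <- rbind(ann, data.frame(start_s = 10, end_s = 20,
                               stratum_type = "stage", stratum_value = "REM"))
  expect_error(stratified_metrics(est, gold, mask, bad), "contradictory")

  # strata not covering any window are omitted
  extra <- rbind(ann, data.frame(start_s = 100, end_s = 120,
                                 stratum_type = "stage", stratum_value = "wake"))
  expect_false("wake" %in% names(stratified_metrics(est, gold, mask, extra)$stage))
})
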