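# Independent scoring oracle: plain-loop evaluation of the candidate score
# S = 2*s1 + (1 - s2) + (1 - s3), used to cross-check score_candidates.
oracle_scores <- function(f, hp, prev, prior, band) {
  width <- band[2] - band[1]
  hp_sum <- sum(hp)
  s <- numeric(length(f))
  for (i in seq_along(f)) {
    s1 <- if (hp_sum > 0) hp[i] / hp_sum else 1 / length(f)
    s3 <- min(abs(prior - f[i]) / width, 1)
    s2 <- if (is.null(prev)) s3 else min(abs(prev - f[i]) / width, 1)
    s[i] <- 2 * s1 + (1 - s2) + (1 - s3)
  }
  s
}

test_that("candidate scoring matches its closed form on pinned cases", {
  cfg <- hr_config()
  one <- score_candidates(data.frame(f = 80, hp = 0.7), prev_bpm = 80, cfg)
  expect_equal(one$s1, 1)
  expect_equal(one$s2, 0)
  expect_equal(one$s3, 0)
  expect_equal(one$S, 4)

  tri <- score_candidates(data.frame(f = c(60, 120, 40), hp = c(0.6, 0.3, 0.1)),
                          prev_bpm = 62, cfg)
  expect_equal(tri$S, oracle_scores(c(60, 120, 40), c(0.6, 0.3, 0.1),
                                    62, 80, c(20, 140)))
  expect_equal(attr(tri, "winner"), 1L)  # 60 bpm: high hp, near prev

  edge <- score_candidates(data.frame(f = 140, hp = 0.5), prev_bpm = 140, cfg)
  expect_equal(edge$s3, 0.5)   # |80 - 140| / 120, clamped band-width scaling
  expect_equal(edge$S, 2 * edge$s1 + 1 + 0.5)
})

test_that("scoring handles degenerate candidate sets", {
  cfg <- hr_config()
  z <- score_candidates(data.frame(f = c(50, 90), hp = c(0, 0)), NULL, cfg)
  expect_equal(z$s1, c(0.5, 0.5))        # zero periodicity -> uniform s1
  expect_error(score_candidates(data.frame(f = numeric(0), hp = numeric(0)),
                                NULL, cfg), "no candidates")
  expect_error(score_candidates(data.frame(f = 150, hp = 1), NULL, cfg),
               "outside")
  # no previous estimate: s2 equals s3
  np <- score_candidates(data.frame(f = c(70, 100), hp = c(0.4, 0.4)), NULL, cfg)
  expect_equal(np$s2, np$s3)
})

test_that("argmax-S selection matches exhaustive enumeration on random sets", {
  cfg <- hr_config()
  set.seed(99)
  for (i in 1:200) {
    n <- sample(1:12, 1)
    f <- runif(n, 20, 140)
    hp <- runif(n)
    prev <- if (runif(1) < 0.3) NULL else runif(1, 20, 140)
    sc <- score_candidates(data.frame(f = f, hp = hp), prev, cfg)
    s_oracle <- oracle_scores(f, hp, prev, 80, c(20, 140))
    expect_equal(sc$S, s_oracle)
    expect_equal(sc$S[attr(sc, "winner")], max(s_oracle))
    # score decomposition identity
    expect_equal(sc$S - 2 * sc$s1 - (1 - sc$s2) - (1 - sc$s3), rep(0, n))
  }
})

test_that("with equal periodicity and no history the prior-nearest candidate wins", {
  cfg <- hr_config()
  set.seed(7)
  for (i in 1:25) {
    f <- runif(sample(2:12, 1), 20, 140)
    sc <- score_candidates(data.frame(f = f, hp = rep(0.5, length(f))), NULL, cfg)
    expect_equal(f[attr(sc, "winner")], f[which.min(abs(f - 80))])
  }
})

test_that("seeded FastICA is deterministic and unmixes synthetic sources", {
  set.seed(12)
  n <- 600
  s1 <- sin(2 * pi * 1.2 * (1:n) / 30)
  s2 <- sign(sin(2 * pi * 0.25 * (1:n) / 30))
  A <- matrix(runif(12, -1, 1), 6, 2)
  X <- cbind(s1, s2) %*% t(A) + matrix(rnorm(n * 6, sd = 0.01), n, 6)
  Y <- camvitals:::fast_ica(X, 2, seed = 5)
  expect_identical(Y, camvitals:::fast_ica(X, 2, seed = 5))
  cors <- abs(cor(cbind(s1, s2), Y))
  expect_gt(max(cors[1, ]), 0.95)
  expect_gt(max(cors[2, ]), 0.95)
})

test_that("ICA window estimation finds the cardiac fundamental", {
  gen <- gen_trajectories(small_scene(duration_s = 30, resp_rate = 15,
                                      heart_rate = 72,
                                      noise_sigma_px = 0.05), 40)
  est <- estimate_hr_window(gen$traj, NULL, hr_config())
  expect_true(est$valid)
  expect_equal(est$rate, 72, tolerance = 2 / 72)

  silent <- gen_trajectories(small_scene(duration_s = 30, heart_rate = 72,
                                         cardiac_amp_px = 0,
                                         noise_sigma_px = 0.05), 40)
  est0 <- estimate_hr_window(silent$traj, NULL, hr_config())
  expect_true(!est0$valid || est0$quality < 0.3)
})

test_that("temporal continuity breaks near-ties toward the previous estimate", {
  cfg <- hr_config()
  sc <- score_candidates(data.frame(f = c(69, 131), hp = c(0.5, 0.5)),
                         prev_bpm = 70, cfg)
  expect_equal(sc$f[attr(sc, "winner")], 69)
})

test_that("run_hr chains the previous estimate and resets after movement", {
  gen <- gen_trajectories(small_scene(duration_s = 60, resp_rate = 15,
                                      heart_rate = 72, noise_sigma_px = 0.05), 40)
  tr <- tracked_from_traj(gen)
  hr <- run_hr(tr)
  expect_equal(nrow(hr), 31L)
  err <- abs(hr$rate[hr$valid] - 72)
  expect_gte(mean(err <= 5), 0.8)

  # all-moving recording: every window invalid
  ev <- gen_trajectories(small_scene(duration_s = 40, heart_rate = 72,
                                     noise_sigma_px = 0.05,
                                     movement_events = list(c(15, 0.2, 25))), 30)
  hr_ev <- run_hr(tracked_from_traj(ev))
  expect_true(all(!hr_ev$valid))
  expect_true(all(hr_ev$reason == "moving"))
})

test_that("heart-rate estimates track a slow ramp", {
  p <- small_scene(duration_s = 180, heart_rate = round(seq(60, 90, length.out = 180)),
                   resp_rate = 15, noise_sigma_px = 0.05)
  gen <- gen_trajectories(p, 40)
  hr <- run_hr(tracked_from_traj(gen))
  truth <- vapply(hr$window_start_s, function(k)
    mean(p$heart_rate[(k + 1):(k + 30)]), numeric(1))
  err <- abs(hr$rate[hr$valid] - truth[hr$valid])
  expect_lte(median(err), 5)
})
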