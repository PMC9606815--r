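p0 <- model_params()

test_that("salience integrates waking cortical activation and decays in sleep", {
  # constant a = 0.5 held for 1 s from s = 0: s ~ lambda * 0.5 (tau_s >> 1 s)
  st <- network_state("A", p0)
  st$ctx$a <- 0.5
  for (i in 1:1000) st <- update_salience(st, p0)
  expect_equal(unname(st$salience), p0$lambda_wake * 0.5 * 1, tolerance = 0.01)

  # waking decay with silent cortex
  st2 <- network_state("A", p0)
  st2$salience[] <- 100
  for (i in 1:1000) st2 <- update_salience(st2, p0)
  expect_equal(unname(st2$salience), 100 * exp(-1 / p0$tau_s), tolerance = 1e-6)

  # sleep: lambda = 0, activity contributes nothing
  st3 <- network_state("A", p0)
  st3$mode <- "sleep"
  st3$salience[] <- 100
  st3$ctx$a <- 1
  for (i in 1:1000) st3 <- update_salience(st3, p0)
  expect_equal(unname(st3$salience), 100 * exp(-1 / p0$tau_s), tolerance = 1e-6)
})

test_that("closed-form salience decay matches the Euler oracle", {
  st <- network_state(c("A", "B"), p0)
  st$salience[] <- c(40, 7)
  expect_equal(decay_salience_closed_form(st, 0, p0)$salience, st$salience)
  expect_equal(unname(decay_salience_closed_form(st, 86400, p0)$salience),
               c(40, 7) * exp(-1))
  expect_error(decay_salience_closed_form(st, -5, p0), "non-negative")

  st_euler <- st
  for (i in 1:10000) st_euler <- update_salience(st_euler, p0)
  st_cf <- decay_salience_closed_form(st, 10, p0)
  expect_equal(st_euler$salience, st_cf$salience, tolerance = 1e-6)
})

test_that("replay cues are drawn in proportion to salience with a null item", {
  # all item saliences zero: the null item is certain
  set.seed(1)
  expect_true(all(is.na(replicate(50, sample_replay_cue(c(A = 0), 0.5)))))
  expect_error(sample_replay_cue(c(A = 0), 0), "invalid configuration")
  expect_error(sample_replay_cue(c(A = -1), 0.5), ">= 0")

  # P(A) = 1.5 / (1.5 + 0.5) = 0.75, Monte Carlo within 3 binomial sigma
  set.seed(2)
  n <- 1e5
  hits <- sum(!is.na(replicate(n, sample_replay_cue(c(A = 1.5), 0.5))))
  expect_lt(abs(hits / n - 0.75), 3 * sqrt(0.75 * 0.25 / n))

  # exactly one uniform draw is consumed per call
  set.seed(3); invisible(sample_replay_cue(c(A = 2, B = 1), 0.5)); nxt <- runif(1)
  set.seed(3); invisible(runif(1))
  expect_identical(runif(1), nxt)
})

test_that("empirical cue frequencies obey the salience sampling law (chi-square)", {
  s <- c(A = 4, B = 4, C = 1, D = 0.5)
  null_s <- 0.5
  set.seed(11)
  draws <- replicate(1e5, sample_replay_cue(s, null_s))
  draws[is.na(draws)] <- "null"
  counts <- table(factor(draws, levels = c(names(s), "null")))
  probs <- c(s, null = null_s) / (sum(s) + null_s)
  gof <- chisq.test(counts, p = probs)
  expect_gt(gof$p.value, 0.01)
  # symmetry: equally salient items are selected equally often
  expect_gt(chisq.test(counts[c("A", "B")], p = c(0.5, 0.5))$p.value, 0.01)
})

test_that("a night with zero salience is 50 null records and pure weight decay", {
  p <- model_params()
  st <- network_state(abcde, p)
  st$ctx$exists[1, 2] <- st$hc$exists[1, 2] <- TRUE
  st$ctx$W[1, 2] <- 0.5; st$hc$W[1, 2] <- 0.5
  set.seed(4)
  out <- run_sleep_block(st, p, night_index = 1)
  expect_equal(nrow(out$records), 50)
  expect_true(all(is.na(out$records$cue)))
  expect_equal(out$records$n_crossings, rep(0, 50))
  block <- 50 / p$swo_frequency
  expect_equal(out$state$ctx$W[1, 2], 0.5 * exp(-block / p$tau_w_c_eff),
               tolerance = 1e-9)
  expect_equal(out$state$hc$W[1, 2], 0.5 * exp(-block / p$tau_w_h_eff),
               tolerance = 1e-9)
  expect_equal(out$state$clock - st$clock, block)
})

test_that("sleep blocks reset transients and never feed salience", {
  fx <- day1_trained()
  st <- fast_forward(fx$state, 3600, p0)
  s0 <- st$salience
  set.seed(5)
  out <- run_sleep_block(st, p0, night_index = 1,
                         sequences = list(ABCDE = abcde))
  expect_equal(out$state$ctx$a, rep(0, 5))
  expect_equal(out$state$hc$g, rep(0, 5))
  # exact closed-form decay of salience over the whole block
  expect_identical(out$state$salience, s0 * exp(-50 / p0$tau_s))
  # trained network: cued UP states produce replay activity
  cued <- out$records[!is.na(out$records$cue), ]
  expect_gt(nrow(cued), 30)
  expect_gt(mean(cued$n_crossings), 1)
})

test_that("an untrained network replays nothing beyond the cued item", {
  st <- network_state(abcde, p0)
  pr <- replay_probe(st, "A", p0, sequences = list(ABCDE = abcde))
  expect_equal(pr$crossings$item, "A")
  expect_false(pr$record$full_replay)
  expect_true(is.na(pr$record$duration))
})

test_that("crossing times in replay records lie inside the UP state", {
  fx <- day1_trained()
  st <- fast_forward(fx$state, 3600, p0)
  set.seed(6)
  out <- run_sleep_block(st, p0, 1, sequences = list(ABCDE = abcde))
  expect_true(all(out$crossings$time >= 0 &
                    out$crossings$time <= p0$up_state_duration))
  expect_true(all(xor(out$records$full_replay, is.na(out$records$duration))))
})
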