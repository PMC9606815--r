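p0 <- model_params()

test_that("a first training trial allocates items and learns causal forward links", {
  st <- network_state(params = p0)   # empty catalog
  out <- run_training_trial(st, "ABCDE", p0)
  st <- out$state
  expect_equal(st$catalog, abcde)
  # adjacent links instantiated in both directions, in both regions
  expect_true(all(st$ctx$exists[fwd_idx]) && all(st$ctx$exists[rev_idx]))
  expect_true(all(st$hc$exists[fwd_idx]))
  # causality: forward weights exceed reverse weights after one trial
  expect_true(all(st$ctx$W[fwd_idx] > st$ctx$W[rev_idx]))
  expect_true(all(st$hc$W[fwd_idx] > st$hc$W[rev_idx]))

  # a repeat trial creates no new links and strengthens forward weights
  n_links <- sum(st$ctx$exists)
  w_before <- st$hc$W[fwd_idx]
  st2 <- fast_forward(st, p0$inter_trial_gap, p0)
  st2 <- run_training_trial(st2, "ABCDE", p0)$state
  expect_equal(sum(st2$ctx$exists), n_links)
  expect_true(all(st2$hc$W[fwd_idx] > w_before))

  # a single-item "sequence" never links anything
  st3 <- run_training_trial(network_state(params = p0), "A", p0)$state
  expect_false(any(st3$ctx$exists))
  expect_error(run_training_trial(st, character(), p0), "non-empty")
})

test_that("cued recall on an untrained network recalls only the cue", {
  st <- network_state(abcde, p0)
  out <- run_recall_test(st, "A", abcde, p0)
  expect_equal(out$result$crossings$item, "A")
  expect_equal(out$result$accuracy, 20)
  expect_equal(out$result$recall_time, 30)
  expect_error(run_recall_test(st, "Z", abcde, p0), "unknown item")
})

test_that("a trained network shows a full ordered recall cascade", {
  fx <- day1_trained()
  st <- fast_forward(fx$state, p0$inter_trial_gap, p0)
  out <- run_recall_test(st, "A", abcde, p0)
  expect_equal(out$result$crossings$item, abcde)
  expect_equal(out$result$accuracy, 100)
  expect_lt(out$result$recall_time, 30)
  expect_gt(out$result$recall_time, p0$recall_cue_duration)
})

test_that("fast-forward matches brute-force Euler integration of an idle gap", {
  fx <- day1_trained()
  st <- reset_transients(fast_forward(fx$state, 1, p0))
  # 60 s gap: closed form vs the engine stepping zero input
  ff <- fast_forward(st, 60, p0)
  euler <- seqconsol:::integrate_segment(st, p0, 60000)$state
  expect_equal(ff$ctx$W, euler$ctx$W, tolerance = 1e-5)
  expect_equal(ff$hc$W, euler$hc$W, tolerance = 1e-5)
  expect_equal(ff$salience, euler$salience, tolerance = 1e-5)

  # 1-hour gap against the engine, 12-hour gap against the discrete recurrence
  ff1h <- fast_forward(st, 3600, p0)
  euler1h <- seqconsol:::integrate_segment(st, p0, 3600000)$state
  expect_equal(ff1h$hc$W, euler1h$hc$W, tolerance = 1e-5)
  expect_equal(ff1h$salience, euler1h$salience, tolerance = 1e-5)
  n12 <- 12 * 3600 * 1000
  expect_equal(fast_forward(st, 43200, p0)$hc$W[1, 2],
               st$hc$W[1, 2] * (1 - p0$dt / p0$tau_w_h_eff)^n12,
               tolerance = 1e-5)
  expect_equal(unname(fast_forward(st, 43200, p0)$salience[1]),
               unname(st$salience[1]) * exp(-43200 / p0$tau_s),
               tolerance = 1e-9)

  # zero gap only resets transients
  st$ctx$a[1] <- 0.3
  z <- fast_forward(st, 0, p0)
  expect_equal(z$ctx$a[1], 0)
  expect_equal(z$ctx$W, st$ctx$W)
  expect_error(fast_forward(st, -1, p0), "non-negative")
})

test_that("experiment specifications are validated", {
  days <- list(list(train = list(list(seq = "ABCDE", trials = 10)),
                    evening_tests = "A"))
  expect_s3_class(experiment_spec("x", 1, days, nights = 1), "experiment_spec")
  expect_error(experiment_spec("x", NULL, days), "seed")
  expect_error(experiment_spec("x", 1, list(list(train = list(
    list(seq = "ABCDE", trials = -1))))), "positive")
  expect_error(experiment_spec("x", 1, list(list(
    train = list(list(seq = "ABCDE", trials = 1)), evening_tests = "Q"))),
    "does not appear")
  # a cue that is not the head of any sequence has no recall target
  expect_error(experiment_spec("x", 1, list(list(
    train = list(list(seq = "ABCDE", trials = 1)), evening_tests = "B"))),
    "starts with")
  expect_error(experiment_spec("x", 1, days, nights = 1, sleep_hour = 5),
    "morning_test_hour < train_hour < sleep_hour")
})

test_that("experiments are bit-reproducible from their seed", {
  a <- run_preset_cached("baseline", 11)
  b <- run_experiment(load_preset("baseline", seed = 11))
  expect_identical(a$replays, b$replays)
  expect_identical(a$recalls, b$recalls)
  expect_identical(a$final_state$ctx$W, b$final_state$ctx$W)
})

test_that("the baseline protocol consolidates the sequence into cortex", {
  res <- run_preset_cached("baseline", 11)
  expect_true(all(res$recalls$accuracy == 100))
  expect_true(all(res$recalls$recall_time < 30))
  # recall accelerates as the cortical trace strengthens
  expect_lt(res$recalls$recall_time[5], res$recalls$recall_time[1])
  w <- snapshot_means(res, "W_ctx")
  expect_gt(unname(w["night4_sleep"]), 2 * unname(w["day1_training"]))
})
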