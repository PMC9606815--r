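# Shared fixtures built in code. Experiment runs are deterministic given a
# seed, so they are cached for reuse across test files.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

run_preset_cached <- function(name, seed = 1) {
  cached(paste0("preset_", name, "_", seed),
         run_experiment(load_preset(name, seed = seed)))
}

abcde <- c("A", "B", "C", "D", "E")
fwd_idx <- cbind(1:4, 2:5)
rev_idx <- cbind(2:5, 1:4)

# One day of training on ABCDE (10 trials, standard timings), tracking the
# peak mean forward weight in each region at 10 Hz.
day1_trained <- function() {
  cached("day1_trained", {
    p <- model_params()
    st <- network_state(abcde, p)
    peak_hc <- 0; peak_ctx <- 0
    for (tr in 1:10) {
      out <- run_training_trial(st, abcde, p,
                                sample_every = 100L, track_pairs = fwd_idx)
      st <- out$state
      for (s in out$samples) {
        peak_hc <- max(peak_hc, max(rowMeans(s$wh)))
        peak_ctx <- max(peak_ctx, max(rowMeans(s$wc)))
      }
      if (tr < 10) st <- fast_forward(st, p$inter_trial_gap, p)
    }
    list(state = st, peak_hc = peak_hc, peak_ctx = peak_ctx, params = p)
  })
}

# Mean forward-link weight trajectory over snapshots of a result.
snapshot_means <- function(res, region = "W_ctx") {
  v <- vapply(res$snapshots, function(sn) mean(sn[[region]][fwd_idx]), numeric(1))
  names(v) <- vapply(res$snapshots, `[[`, "", "label")
  v
}
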