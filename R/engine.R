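# Wrapper around the compiled integrator. Drives both regions for
# `n_steps` Euler steps under a constant input-register drive, with
# plasticity (per gates and mode), optional salience tracking, link
# instantiation, cortical threshold-crossing capture, early stopping and
# weight sampling. Advances the state clock.
integrate_segment <- function(state, params, n_steps,
                              input_items = NULL, input_level = 0,
                              hc_input_items = NULL, hc_input_level = 0,
                              instantiate = FALSE,
                              track_salience = NULL,
                              stop_items = NULL, crossed = NULL,
                              sample_every = 0L, track_pairs = NULL) {
  n <- length(state$catalog)
  n_steps <- as.integer(n_steps)
  if (n_steps < 0) stop("n_steps must be >= 0")
  if (n_steps == 0L) {
    return(list(state = state, crossings = empty_crossings(),
                samples = NULL, steps_run = 0L,
                crossed = if (is.null(crossed)) rep(FALSE, n) else crossed))
  }
  input_c <- numeric(n)
  if (!is.null(input_items) && length(input_items))
    input_c[item_index(state, input_items)] <- input_level
  input_h <- numeric(n)
  if (!is.null(hc_input_items) && length(hc_input_items))
    input_h[item_index(state, hc_input_items)] <- hc_input_level

  sleep <- identical(state$mode, "sleep")
  if (is.null(track_salience)) track_salience <- !sleep
  gates <- state$gates
  learn_c <- state$ctx$learning_enabled &&
    (if (sleep) gates$ctx_learning_sleep else gates$ctx_learning_wake)
  learn_h <- state$hc$learning_enabled &&
    (if (sleep) gates$hc_learning_sleep else gates$hc_learning_wake)

  if (is.null(crossed)) crossed <- rep(FALSE, n)
  stop_idx <- if (is.null(stop_items)) integer() else item_index(state, stop_items)
  if (is.null(track_pairs)) {
    pairs_c <- pairs_h <- matrix(integer(), 0, 2)
  } else {
    pairs_c <- pairs_h <- track_pairs  # same catalog indices in both regions
  }

  out <- cpp_integrate(state$ctx$a, state$ctx$g, state$hc$a, state$hc$g,
                       state$ctx$W, state$hc$W,
                       state$ctx$exists, state$hc$exists,
                       unname(state$salience),
                       input_c, input_h,
                       n_steps, unclass(params),
                       sleep, state$hc_to_ctx_enabled,
                       learn_c, learn_h,
                       isTRUE(instantiate), isTRUE(track_salience),
                       crossed, as.integer(stop_idx),
                       as.integer(sample_every),
                       pairs_c, pairs_h)

  t0 <- state$clock
  state$ctx$a <- out$a_c; state$ctx$g <- out$g_c
  state$hc$a <- out$a_h;  state$hc$g <- out$g_h
  state$ctx$W <- out$W_c; state$hc$W <- out$W_h
  state$ctx$exists <- out$ex_c; state$hc$exists <- out$ex_h
  state$salience <- setNames(out$s, state$catalog)
  state$clock <- t0 + out$steps_run * params$dt

  crossings <- data.frame(
    time = out$cross_step * params$dt,
    item = state$catalog[out$cross_item],
    act = out$cross_act,
    stringsAsFactors = FALSE)

  samples <- NULL
  if (sample_every > 0 && !is.null(track_pairs) && length(out$samp_step)) {
    samples <- list(time = t0 + out$samp_step * params$dt,
                    wc = out$samp_wc, wh = out$samp_wh)
  }

  list(state = state, crossings = crossings, samples = samples,
       steps_run = out$steps_run, crossed = out$crossed)
}

empty_crossings <- function() {
  data.frame(time = numeric(), item = character(), act = numeric(),
             stringsAsFactors = FALSE)
}
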