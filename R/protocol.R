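#' One waking training trial
#'
#' Presents the items of a sequence in order through the cortical input
#' register (default 0.1 for 2 s each, 5 ms inter-stimulus interval),
#' with dynamics, link instantiation, plasticity and salience all active
#' at every step. Novel labels are allocated in the catalog before
#' presentation.
#'
#' @param state A [network_state()] in wake mode.
#' @param sequence Character vector of item labels, or a single string of
#'   single-character labels (`"ABCDE"`).
#' @param params A [model_params()].
#' @param sample_every Integer; if > 0 with `track_pairs`, weight samples
#'   are collected every that many steps.
#' @param track_pairs Integer matrix of (pre, post) catalog indices to
#'   sample.
#' @return A list with `state` and `samples` (or `NULL`).
#' @export
run_training_trial <- function(state, sequence, params,
                               sample_every = 0L, track_pairs = NULL) {
  sequence <- as_item_vector(sequence)
  if (!length(sequence)) stop("training sequence must be non-empty")
  if (!identical(state$mode, "wake")) stop("training requires wake mode")
  state <- add_items(state, sequence)
  item_steps <- as.integer(round(params$train_item_duration / params$dt))
  isi_steps <- as.integer(round(params$inter_stimulus_interval / params$dt))
  samples <- list()
  for (i in seq_along(sequence)) {
    seg <- integrate_segment(state, params, item_steps,
                             input_items = sequence[i],
                             input_level = params$train_input_level,
                             instantiate = TRUE,
                             sample_every = sample_every,
                             track_pairs = track_pairs)
    state <- seg$state
    if (!is.null(seg$samples)) samples[[length(samples) + 1L]] <- seg$samples
    if (i < length(sequence) && isi_steps > 0L) {
      seg <- integrate_segment(state, params, isi_steps, instantiate = TRUE,
                               sample_every = sample_every,
                               track_pairs = track_pairs)
      state <- seg$state
      if (!is.null(seg$samples)) samples[[length(samples) + 1L]] <- seg$samples
    }
  }
  list(state = state, samples = if (length(samples)) samples else NULL)
}

#' Cued waking recall test
#'
#' Presents the cue item in the input register (0.1 for 1.5 s) and lets
#' the network run on — learning and salience still active — until every
#' target item has crossed the cortical recall threshold or the 30 s
#' ceiling elapses. Returns the recall metrics computed from the ordered
#' threshold crossings.
#'
#' @param state A [network_state()] in wake mode.
#' @param cue Item label; must be in the catalog.
#' @param target Character vector (or string) of the target sequence.
#' @param params A [model_params()].
#' @return A list with `state` and `result` (a `recall_result`).
#' @export
run_recall_test <- function(state, cue, target, params) {
  target <- as_item_vector(target)
  if (!identical(state$mode, "wake")) stop("recall tests run in wake mode")
  item_index(state, cue)  # errors on unknown cue
  cue_steps <- as.integer(round(params$recall_cue_duration / params$dt))
  rest_steps <- as.integer(round((params$recall_ceiling -
                                    params$recall_cue_duration) / params$dt))
  seg1 <- integrate_segment(state, params, cue_steps, input_items = cue,
                            input_level = params$recall_cue_level,
                            stop_items = target)
  seg2 <- integrate_segment(seg1$state, params, rest_steps,
                            stop_items = target, crossed = seg1$crossed)
  state <- seg2$state
  seg2$crossings$time <- seg2$crossings$time + cue_steps * params$dt
  crossings <- rbind(seg1$crossings, seg2$crossings)
  list(state = state,
       result = make_recall_result(crossings, cue, target, params))
}

#' Fast-forward an idle gap
#'
#' Event-driven skip of an interval with no scheduled events: transients
#' are reset (activity is treated as zero throughout the gap) and weights
#' and salience decay in closed form; the clock advances by `elapsed`.
#'
#' @param state A [network_state()].
#' @param elapsed Gap duration in seconds (>= 0).
#' @param params A [model_params()].
#' @return The updated state.
#' @export
fast_forward <- function(state, elapsed, params) {
  if (!is.numeric(elapsed) || length(elapsed) != 1L || is.na(elapsed) || elapsed < 0)
    stop("elapsed must be a non-negative duration")
  state <- reset_transients(state)
  state$ctx <- decay_weights_closed_form(state$ctx, elapsed, params)
  state$hc <- decay_weights_closed_form(state$hc, elapsed, params)
  state <- decay_salience_closed_form(state, elapsed, params)
  state$clock <- state$clock + elapsed
  state
}

as_item_vector <- function(x) {
  if (length(x) == 1L && is.character(x) && nchar(x) > 1L)
    strsplit(x, "", fixed = TRUE)[[1]]
  else as.character(x)
}

#' Declarative experiment specification
#'
#' Day-level timeline of an experiment: per-day training blocks
#' (sequence x trial count), morning and evening recall tests, which
#' nights contain a slow-wave-sleep block, parameter overrides, learning
#' gates and the lesion flag. Within each simulated day (86,400 s),
#' morning tests run at `morning_test_hour`, training at `train_hour`
#' (trials separated by the inter-trial gap), evening tests one
#' inter-trial gap after the last trial, and sleep at `sleep_hour`; the
#' intervals between are fast-forwarded, which is where the day-scale
#' salience and hippocampal weight decay happen.
#'
#' @param name Experiment name.
#' @param seed Integer RNG seed (required; the replay cue draws are the
#'   only stochastic element).
#' @param days List of day specifications, each a list with optional
#'   elements `train` (list of `list(seq=, trials=)`), `morning_tests`
#'   and `evening_tests` (character vectors of cue items).
#' @param nights Integer vector: indices of days at whose end a sleep
#'   block runs.
#' @param sequences Optional named list of item vectors; defaults to the
#'   distinct trained sequences (named by their collapsed labels).
#' @param params A [model_params()].
#' @param gates A [plasticity_gates()].
#' @param hc_to_ctx Logical lesion flag (`FALSE` = feedback lesioned).
#' @param morning_test_hour,train_hour,sleep_hour Wall-clock hours within
#'   each day.
#' @return An object of class `experiment_spec`.
#' @export
experiment_spec <- function(name, seed, days, nights = integer(),
                            sequences = NULL,
                            params = model_params(),
                            gates = plasticity_gates(),
                            hc_to_ctx = TRUE,
                            morning_test_hour = 8, train_hour = 9,
                            sleep_hour = 23) {
  if (missing(seed) || is.null(seed) || is.na(suppressWarnings(as.integer(seed))))
    stop("an integer seed is required")
  seed <- as.integer(seed)
  if (!is.list(days) || !length(days)) stop("days must be a non-empty list")
  days <- lapply(days, function(d) {
    d <- as.list(d)
    extra <- setdiff(names(d), c("train", "morning_tests", "evening_tests"))
    if (length(extra)) stop("unknown day field(s): ", paste(extra, collapse = ", "))
    d$train <- lapply(d$train, function(b) {
      b <- as.list(b)
      if (is.null(b$seq)) stop("each training block needs a 'seq'")
      b$seq <- as_item_vector(b$seq)
      b$trials <- if (is.null(b$trials)) 1L else as.integer(b$trials)
      if (is.na(b$trials) || b$trials < 1L)
        stop("trial counts must be positive integers")
      b
    })
    list(train = d$train,
         morning_tests = as.character(d$morning_tests %||% character()),
         evening_tests = as.character(d$evening_tests %||% character()))
  })
  trained <- list()
  for (d in days) for (b in d$train) {
    nm <- paste(b$seq, collapse = "")
    trained[[nm]] <- b$seq
  }
  if (is.null(sequences)) sequences <- trained
  else sequences <- lapply(sequences, as_item_vector)
  if (!length(sequences)) stop("no sequences are trained or declared")

  nights <- as.integer(nights)
  if (any(is.na(nights)) || any(nights < 1L))
    stop("nights must be positive day indices")

  all_items <- unique(unlist(sequences, use.names = FALSE))
  for (d in days) for (cue in c(d$morning_tests, d$evening_tests)) {
    if (!cue %in% all_items)
      stop("test cue '", cue, "' does not appear in any sequence")
    if (is.null(target_for_cue(cue, sequences)))
      stop("no declared sequence starts with test cue '", cue, "'")
  }
  if (!(morning_test_hour < train_hour && train_hour < sleep_hour))
    stop("require morning_test_hour < train_hour < sleep_hour")

  structure(list(name = name, seed = seed, days = days, nights = nights,
                 sequences = sequences, params = params, gates = gates,
                 hc_to_ctx = isTRUE(hc_to_ctx),
                 morning_test_hour = morning_test_hour,
                 train_hour = train_hour, sleep_hour = sleep_hour),
            class = "experiment_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

target_for_cue <- function(cue, sequences) {
  for (nm in names(sequences))
    if (identical(sequences[[nm]][1], cue)) return(sequences[[nm]])
  NULL
}

#' @export
print.experiment_spec <- function(x, ...) {
  cat(sprintf("<experiment_spec> '%s' (seed %d)\n", x$name, x$seed))
  cat(sprintf("  %d day(s); sleep after day(s): %s\n", length(x$days),
              if (length(x$nights)) paste(x$nights, collapse = ", ") else "none"))
  cat("  sequences:", paste(names(x$sequences), collapse = ", "), "\n")
  if (!x$hc_to_ctx) cat("  HC->CTX feedback lesioned\n")
  invisible(x)
}

#' Run a full experiment
#'
#' Executes the day-level timeline of an [experiment_spec()]: morning
#' recall tests, training trials, evening tests and nightly slow-wave
#' sleep, with idle intervals fast-forwarded analytically. Fully
#' reproducible given the spec's seed. Forward-link weights of every
#' declared sequence are sampled at 10 Hz during waking events and
#' snapshotted at epoch boundaries.
#'
#' @param spec An [experiment_spec()].
#' @param sample_every Sampling stride (in integration steps) for weight
#'   trajectories during waking events; default 100 (10 Hz).
#' @return An object of class `consolidation_result`: a list with
#'   `spec`, `recalls` (one row per test), `recall_details`, `replays`
#'   (one row per UP state), `replay_crossings`, `weights` (long sampled
#'   trajectory: time, region, pre, post, w), `snapshots` (per-epoch full
#'   weight matrices and salience), and `final_state`.
#' @export
run_experiment <- function(spec, sample_every = 100L) {
  stopifnot(inherits(spec, "experiment_spec"))
  params <- spec$params
  set.seed(spec$seed)

  all_items <- unique(unlist(spec$sequences, use.names = FALSE))
  state <- network_state(all_items, params, spec$gates,
                         hc_to_ctx_enabled = spec$hc_to_ctx)

  fwd <- forward_pairs(spec$sequences, state)
  recalls <- list(); recall_details <- list()
  replays <- list(); replay_cross <- list()
  weight_samples <- list(); snapshots <- list()

  snap <- function(label) {
    snapshots[[length(snapshots) + 1L]] <<- list(
      time = state$clock, label = label,
      W_ctx = state$ctx$W, W_hc = state$hc$W,
      salience = state$salience)
  }
  ff_to <- function(t_target) {
    if (t_target < state$clock)
      stop("invalid specification: overlapping epochs at t = ", t_target)
    if (t_target > state$clock)
      state <<- fast_forward(state, t_target - state$clock, params)
  }
  add_samples <- function(samps) {
    if (is.null(samps)) return()
    for (s in samps)
      weight_samples[[length(weight_samples) + 1L]] <<- s
  }
  run_tests <- function(cues, day, phase) {
    for (i in seq_along(cues)) {
      if (i > 1L) state <<- fast_forward(state, params$inter_trial_gap, params)
      target <- target_for_cue(cues[i], spec$sequences)
      t0 <- state$clock
      out <- run_recall_test(state, cues[i], target, params)
      state <<- out$state
      res <- out$result
      recalls[[length(recalls) + 1L]] <<- data.frame(
        day = day, phase = phase, time = t0, cue = cues[i],
        target = paste(target, collapse = ""),
        crossing_order = paste(res$crossings$item, collapse = ""),
        accuracy = res$accuracy, recall_time = res$recall_time,
        stringsAsFactors = FALSE)
      recall_details[[length(recall_details) + 1L]] <<- res
    }
  }

  snap("start")
  for (d in seq_along(spec$days)) {
    day <- spec$days[[d]]
    base <- (d - 1) * 86400
    if (length(day$morning_tests)) {
      ff_to(base + spec$morning_test_hour * 3600)
      run_tests(day$morning_tests, d, "morning")
      snap(sprintf("day%d_morning_tests", d))
    }
    if (length(day$train)) {
      ff_to(base + spec$train_hour * 3600)
      first <- TRUE
      for (b in day$train) {
        for (tr in seq_len(b$trials)) {
          if (!first) state <- fast_forward(state, params$inter_trial_gap, params)
          first <- FALSE
          out <- run_training_trial(state, b$seq, params,
                                    sample_every = sample_every,
                                    track_pairs = fwd$pairs)
          state <- out$state
          add_samples(out$samples)
        }
      }
      snap(sprintf("day%d_training", d))
    }
    if (length(day$evening_tests)) {
      state <- fast_forward(state, params$inter_trial_gap, params)
      run_tests(day$evening_tests, d, "evening")
      snap(sprintf("day%d_evening_tests", d))
    }
    if (d %in% spec$nights) {
      ff_to(base + spec$sleep_hour * 3600)
      out <- run_sleep_block(state, params, night_index = d,
                             sequences = spec$sequences)
      state <- out$state
      state$mode <- "wake"
      replays[[length(replays) + 1L]] <- out$records
      if (nrow(out$crossings))
        replay_cross[[length(replay_cross) + 1L]] <- out$crossings
      snap(sprintf("night%d_sleep", d))
    }
  }

  structure(list(
    spec = spec,
    recalls = if (length(recalls)) do.call(rbind, recalls) else NULL,
    recall_details = recall_details,
    replays = if (length(replays)) do.call(rbind, replays) else NULL,
    replay_crossings = if (length(replay_cross)) do.call(rbind, replay_cross) else NULL,
    weights = melt_weight_samples(weight_samples, fwd, state),
    snapshots = snapshots,
    final_state = state), class = "consolidation_result")
}

forward_pairs <- function(sequences, state) {
  pre <- character(); post <- character(); seq_of <- character()
  for (nm in names(sequences)) {
    s <- sequences[[nm]]
    if (length(s) < 2) next
    pre <- c(pre, s[-length(s)]); post <- c(post, s[-1])
    seq_of <- c(seq_of, rep(nm, length(s) - 1))
  }
  keep <- !duplicated(paste(pre, post))
  pre <- pre[keep]; post <- post[keep]; seq_of <- seq_of[keep]
  list(pre = pre, post = post, sequence = seq_of,
       pairs = cbind(item_index(state, pre), item_index(state, post)))
}

melt_weight_samples <- function(samples, fwd, state) {
  if (!length(samples)) return(NULL)
  k <- length(fwd$pre)
  out <- lapply(samples, function(s) {
    ns <- length(s$time)
    data.frame(time = rep(s$time, times = 2 * k),
               region = rep(c("CTX", "HC"), each = ns * k),
               pre = rep(rep(fwd$pre, each = ns), times = 2),
               post = rep(rep(fwd$post, each = ns), times = 2),
               sequence = rep(rep(fwd$sequence, each = ns), times = 2),
               w = c(as.vector(s$wc), as.vector(s$wh)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' @export
print.consolidation_result <- function(x, ...) {
  cat(sprintf("<consolidation_result> '%s' (seed %d)\n",
              x$spec$name, x$spec$seed))
  if (!is.null(x$recalls)) {
    cat("  recall tests:\n")
    print(x$recalls[, c("day", "phase", "cue", "crossing_order",
                        "accuracy", "recall_time")], row.names = FALSE)
  }
  if (!is.null(x$replays)) {
    st <- replay_statistics(x$replays, x$spec$sequences)
    if (nrow(st$shares)) {
      cat("  replay shares (% of non-null cues):\n")
      print(st$shares, row.names = FALSE)
    }
  }
  invisible(x)
}
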