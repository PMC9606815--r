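#' Euler update of the salience trace
#'
#' Salience is a leaky moving average of each item's cortical activation
#' during wake: it decays with time constant `tau_s` (one day) and
#' accumulates `lambda * a` from the cortical activations. The input gain
#' lambda is zero in sleep, so replays never feed back into salience.
#'
#' @param state A [network_state()].
#' @param params A [model_params()].
#' @param dt Integration step.
#' @return The updated state.
#' @export
update_salience <- function(state, params, dt = params$dt) {
  lam <- lambda_for(params, state$mode)
  s <- state$salience + dt * (-state$salience / params$tau_s + lam * state$ctx$a)
  state$salience <- pmax(s, 0)
  state
}

#' Closed-form salience decay
#'
#' Exact decay of the salience trace over an idle interval with no
#' activity: `s <- s * exp(-elapsed / tau_s)`.
#'
#' @param state A [network_state()].
#' @param elapsed Idle duration in seconds (>= 0).
#' @param params A [model_params()].
#' @return The updated state.
#' @export
decay_salience_closed_form <- function(state, elapsed, params) {
  if (!is.numeric(elapsed) || length(elapsed) != 1L || is.na(elapsed) || elapsed < 0)
    stop("elapsed must be a non-negative duration")
  state$salience <- state$salience * exp(-elapsed / params$tau_s)
  state
}

#' Sample the replay cue for one UP state
#'
#' Draws one item (or the null item) with probability proportional to
#' salience: item x is returned with probability
#' `s_x / (sum(s) + null_salience)` and the null item — no replay this UP
#' state — with probability `null_salience / (sum(s) + null_salience)`.
#' Consumes exactly one uniform draw from the R random stream.
#'
#' @param salience Named numeric vector of item saliences (>= 0).
#' @param null_salience Fixed salience of the null item.
#' @return An item label, or `NA_character_` for the null item.
#' @export
#' @examples
#' set.seed(1)
#' sample_replay_cue(c(A = 1.5), null_salience = 0.5)
sample_replay_cue <- function(salience, null_salience) {
  if (any(salience < 0)) stop("saliences must be >= 0")
  total <- sum(salience) + null_salience
  if (total <= 0)
    stop("invalid configuration: all saliences and the null salience are zero")
  u <- runif(1) * total
  if (length(salience)) {
    cum <- cumsum(salience)
    k <- which(u <= cum)
    if (length(k)) return(names(salience)[k[1]])
  }
  NA_character_
}

# Attribute a cue item to the sequence that owns it; NA when the item is
# in no sequence or in more than one (overlapping sequences).
attribute_cue <- function(cue, sequences) {
  if (is.na(cue) || !length(sequences)) return(NA_character_)
  owners <- names(sequences)[vapply(sequences, function(s) cue %in% s, logical(1))]
  if (length(owners) == 1L) owners else NA_character_
}

replay_record <- function(night, up, cue, crossings, sequences, params) {
  attributed <- attribute_cue(cue, sequences)
  full <- FALSE
  duration <- NA_real_
  if (!is.na(attributed)) {
    seq_items <- sequences[[attributed]]
    fc <- first_crossings(crossings)
    hit <- fc[fc$item %in% seq_items, , drop = FALSE]
    if (nrow(hit) == length(seq_items)) {
      full <- TRUE
      duration <- max(hit$time) - min(hit$time)
    }
  }
  data.frame(night = night, up = up, cue = cue, attributed = attributed,
             n_crossings = nrow(crossings), full_replay = full,
             duration = duration, stringsAsFactors = FALSE)
}

#' Run one night's slow-wave-sleep block
#'
#' Simulates SWS as a continuous block of slow-wave oscillations: one UP
#' state per cycle (default 50 cycles at 1 Hz, UP duration 0.5 s). For
#' each UP state a cue is drawn from the salience distribution (including
#' the null item); a non-null cue is pulsed briefly into the cortical
#' input register at UP-state onset and the network then runs freely —
#' with the fast sleep dynamics — for the rest of the UP state, during
#' which activation can sweep through a stored sequence as a
#' time-compressed replay. Learning follows the sleep gates. Activations
#' and inactivation currents are reset at every UP-state end; DOWN states
#' contribute only closed-form weight decay. Salience is not driven by
#' sleep activity and is decayed in closed form over the whole block.
#'
#' @param state A [network_state()] (switched to sleep mode internally;
#'   returned in sleep mode).
#' @param params A [model_params()].
#' @param night_index Integer label for the night.
#' @param sequences Named list of item vectors used to attribute replays
#'   to sequences.
#' @return A list with elements `state`, `records` (one row per UP state:
#'   night, up, cue, attributed sequence, crossing count, full-replay
#'   flag, replay duration) and `crossings` (long data frame of cortical
#'   threshold crossings: night, up, item, time within the UP state).
#' @export
run_sleep_block <- function(state, params, night_index = 1L,
                            sequences = list()) {
  state$mode <- "sleep"
  s_start <- state$salience
  n_up <- as.integer(params$up_states_per_night)
  cycle <- 1 / params$swo_frequency
  up_steps <- as.integer(round(params$up_state_duration / params$dt))
  cue_steps <- as.integer(round(params$sleep_cue_duration / params$dt))
  down_dur <- cycle - params$up_state_duration

  records <- vector("list", n_up)
  cross_all <- vector("list", n_up)

  for (up in seq_len(n_up)) {
    cue <- sample_replay_cue(state$salience, params$null_salience)
    crossings <- empty_crossings()
    if (!is.na(cue)) {
      hc_items <- if (params$hc_cueing) cue else NULL
      seg1 <- integrate_segment(state, params, cue_steps,
                                input_items = cue,
                                input_level = params$sleep_cue_amplitude,
                                hc_input_items = hc_items,
                                hc_input_level = params$sleep_cue_amplitude,
                                track_salience = FALSE)
      seg2 <- integrate_segment(seg1$state, params, up_steps - cue_steps,
                                track_salience = FALSE)
      state <- seg2$state
      seg2$crossings$time <- seg2$crossings$time + cue_steps * params$dt
      crossings <- rbind(seg1$crossings, seg2$crossings)
      state$clock <- state$clock +
        (up_steps - cue_steps - seg2$steps_run) * params$dt
    } else {
      # silent UP state: nothing can cross threshold, weights only decay
      state$ctx <- decay_weights_closed_form(state$ctx, params$up_state_duration, params)
      state$hc <- decay_weights_closed_form(state$hc, params$up_state_duration, params)
      state$clock <- state$clock + params$up_state_duration
    }
    state <- reset_transients(state)
    # DOWN state: activity is zero by construction; weights decay in closed form
    state$ctx <- decay_weights_closed_form(state$ctx, down_dur, params)
    state$hc <- decay_weights_closed_form(state$hc, down_dur, params)
    state$clock <- state$clock + down_dur

    records[[up]] <- replay_record(night_index, up, cue, crossings,
                                   sequences, params)
    if (nrow(crossings)) {
      cross_all[[up]] <- data.frame(night = night_index, up = up,
                                    item = crossings$item,
                                    time = crossings$time,
                                    act = crossings$act,
                                    stringsAsFactors = FALSE)
    }
  }

  # salience was untouched during the block; one exact decay over it
  state$salience <- s_start * exp(-n_up * cycle / params$tau_s)

  list(state = state,
       records = do.call(rbind, records),
       crossings = if (length(cc <- Filter(Negate(is.null), cross_all)))
         do.call(rbind, cc) else
           data.frame(night = integer(), up = integer(), item = character(),
                      time = numeric(), act = numeric(), stringsAsFactors = FALSE))
}

#' Probe a single cued replay
#'
#' Runs one UP-state-style cued integration in sleep mode (without
#' salience sampling): the given item is pulsed into the cortical input
#' register and the network runs for one UP-state duration. Useful for
#' measuring replay duration and compression after training.
#'
#' @param state A [network_state()].
#' @param cue Item label to cue.
#' @param params A [model_params()].
#' @param sequences Named list of item vectors for attribution.
#' @return A list with `state` (transients reset afterwards) and `record`.
#' @export
replay_probe <- function(state, cue, params, sequences = list()) {
  mode0 <- state$mode
  state <- reset_transients(state)  # UP states always start from silence
  state$mode <- "sleep"
  up_steps <- as.integer(round(params$up_state_duration / params$dt))
  cue_steps <- as.integer(round(params$sleep_cue_duration / params$dt))
  seg1 <- integrate_segment(state, params, cue_steps, input_items = cue,
                            input_level = params$sleep_cue_amplitude,
                            track_salience = FALSE)
  seg2 <- integrate_segment(seg1$state, params, up_steps - cue_steps,
                            track_salience = FALSE)
  state <- reset_transients(seg2$state)
  state$mode <- mode0
  seg2$crossings$time <- seg2$crossings$time + cue_steps * params$dt
  crossings <- rbind(seg1$crossings, seg2$crossings)
  list(state = state,
       record = replay_record(NA_integer_, NA_integer_, cue, crossings,
                              sequences, params),
       crossings = crossings)
}
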