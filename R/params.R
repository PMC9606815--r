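#' Model parameters
#'
#' Constructs the full parameter set of the cortico-hippocampal sequence
#' memory model: the shunting activation dynamics, the inactivation current,
#' the causal rate-based learning rule, the salience trace, and the
#' wake/sleep protocol constants (stimulus levels and durations, slow-wave
#' oscillation schedule, recall thresholds). All times are in seconds.
#'
#' Dynamics are integrated with forward Euler at a fixed step `dt`. The
#' effective time constant of an item's activation is `sigma_a * tau_a`
#' (1.6 s awake, 0.032 s asleep), which is what makes sleep replays
#' time-compressed relative to waking recall.
#'
#' The passive weight-decay constants `tau_w_h` and `tau_w_c` are
#' interpreted in the unit given by `decay_time_unit` (default
#' milliseconds) and converted to seconds, giving effective decay time
#' constants of about 18 days (hippocampus) and 432 days (cortex): the
#' hippocampal engram fades over days while the cortical one persists for
#' over a year. With `decay_scaled_by_eta = TRUE` the decay term is
#' additionally multiplied by the regional learning rate.
#'
#' @param sigma_a_wake,sigma_a_sleep Speed-of-dynamics factors for item
#'   activations in wake and sleep (dimensionless divisors of the
#'   right-hand side; smaller is faster).
#' @param tau_a Passive decay parameter of item activation.
#' @param mu_h,mu_c Feedforward gains into hippocampus (from cortex) and
#'   cortex (from the input register).
#' @param gamma Gain of the learned spreading excitation between items.
#' @param alpha,m,t_a Gain, sigmoid order and threshold of self-excitation.
#' @param zeta Gain of hippocampus-to-cortex feedback.
#' @param beta Gain of lateral inhibition between items.
#' @param theta,n,t_h Gain, sigmoid order and threshold of the
#'   inactivation-current self-inhibition.
#' @param sigma_g,tau_g,kappa Speed factor, passive decay parameter and
#'   activation drive of the inactivation current.
#' @param tau_w_h,tau_w_c Passive weight-decay constants (units set by
#'   `decay_time_unit`).
#' @param Q Fraction of the Hebbian gain applied as depression when the
#'   postsynaptic activation is falling; `Q = 0.5` eliminates reverse
#'   links while sparing simultaneous associations.
#' @param eta_h,eta_c Learning rates (hippocampus learns an order of
#'   magnitude faster).
#' @param tau_s Salience passive decay constant (one day).
#' @param lambda_wake,lambda_sleep Salience input gains by mode; zero in
#'   sleep so replays do not feed back into salience.
#' @param dt Euler integration step.
#' @param recall_threshold Cortical activation level above which an item
#'   counts as recalled.
#' @param recall_ceiling Recall-time ceiling assigned to incomplete recalls.
#' @param null_salience Fixed salience of the null item in replay cue
#'   sampling (probability mass of "no replay this UP state").
#' @param train_input_level,train_item_duration,inter_stimulus_interval
#'   Input-register drive, per-item duration and gap used for training
#'   presentations.
#' @param inter_trial_gap Gap separating training trials.
#' @param recall_cue_level,recall_cue_duration Input-register drive and
#'   duration of a recall cue.
#' @param sleep_cue_amplitude,sleep_cue_duration Pulsed replay cue applied
#'   at UP-state onset.
#' @param swo_frequency Slow-wave oscillation frequency (Hz); one UP state
#'   per cycle.
#' @param up_state_duration Duration of each UP state.
#' @param up_states_per_night Number of UP states in a night's SWS block.
#' @param coactivation_threshold Activation level both items must exceed
#'   for a link to be instantiated between them during training.
#' @param decay_time_unit `"ms"` or `"s"`: unit in which `tau_w_h` and
#'   `tau_w_c` are expressed.
#' @param decay_scaled_by_eta Logical; if `TRUE` the passive weight decay
#'   is multiplied by the regional learning rate.
#' @param hc_cueing Logical; if `TRUE` sleep replay cues are also pulsed
#'   directly into the hippocampus (off by default: cues arrive through
#'   the cortical input register).
#'
#' @return An object of class `model_params`: a named list of the above
#'   plus the derived effective decay constants `tau_w_h_eff` and
#'   `tau_w_c_eff` (seconds).
#' @export
#' @examples
#' p <- model_params()
#' p$sigma_a_wake * p$tau_a   # waking activation time constant, seconds
model_params <- function(sigma_a_wake = 2, sigma_a_sleep = 0.04,
                         tau_a = 0.8,
                         mu_h = 2, mu_c = 1,
                         gamma = 0.9,
                         alpha = 1, m = 2, t_a = 0.09,
                         zeta = 0.5,
                         beta = 15,
                         theta = 10, n = 2, t_h = 0.02,
                         sigma_g = 10, tau_g = 1.2, kappa = 1,
                         tau_w_h = 1.5552e9, tau_w_c = 3.73248e10,
                         Q = 0.5,
                         eta_h = 15, eta_c = 1.5,
                         tau_s = 86400,
                         lambda_wake = 1000, lambda_sleep = 0,
                         dt = 0.001,
                         recall_threshold = 0.01,
                         recall_ceiling = 30,
                         null_salience = 0.5,
                         train_input_level = 0.1,
                         train_item_duration = 2,
                         inter_stimulus_interval = 0.005,
                         inter_trial_gap = 60,
                         recall_cue_level = 0.1,
                         recall_cue_duration = 1.5,
                         sleep_cue_amplitude = 0.2,
                         sleep_cue_duration = 0.0125,
                         swo_frequency = 1,
                         up_state_duration = 0.5,
                         up_states_per_night = 50,
                         coactivation_threshold = 0.05,
                         decay_time_unit = c("ms", "s"),
                         decay_scaled_by_eta = TRUE,
                         hc_cueing = FALSE) {
  decay_time_unit <- match.arg(decay_time_unit)
  p <- list(sigma_a_wake = sigma_a_wake, sigma_a_sleep = sigma_a_sleep,
            tau_a = tau_a, mu_h = mu_h, mu_c = mu_c, gamma = gamma,
            alpha = alpha, m = m, t_a = t_a, zeta = zeta, beta = beta,
            theta = theta, n = n, t_h = t_h, sigma_g = sigma_g,
            tau_g = tau_g, kappa = kappa, tau_w_h = tau_w_h,
            tau_w_c = tau_w_c, Q = Q, eta_h = eta_h, eta_c = eta_c,
            tau_s = tau_s, lambda_wake = lambda_wake,
            lambda_sleep = lambda_sleep, dt = dt,
            recall_threshold = recall_threshold,
            recall_ceiling = recall_ceiling,
            null_salience = null_salience,
            train_input_level = train_input_level,
            train_item_duration = train_item_duration,
            inter_stimulus_interval = inter_stimulus_interval,
            inter_trial_gap = inter_trial_gap,
            recall_cue_level = recall_cue_level,
            recall_cue_duration = recall_cue_duration,
            sleep_cue_amplitude = sleep_cue_amplitude,
            sleep_cue_duration = sleep_cue_duration,
            swo_frequency = swo_frequency,
            up_state_duration = up_state_duration,
            up_states_per_night = up_states_per_night,
            coactivation_threshold = coactivation_threshold,
            decay_time_unit = decay_time_unit,
            decay_scaled_by_eta = isTRUE(decay_scaled_by_eta),
            hc_cueing = isTRUE(hc_cueing))

  unit <- if (decay_time_unit == "ms") 1e-3 else 1
  p$tau_w_h_eff <- tau_w_h * unit / (if (p$decay_scaled_by_eta) eta_h else 1)
  p$tau_w_c_eff <- tau_w_c * unit / (if (p$decay_scaled_by_eta) eta_c else 1)

  class(p) <- "model_params"
  validate_model_params(p)
  p
}

validate_model_params <- function(p) {
  num1 <- function(nm) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a finite numeric scalar", call. = FALSE)
    v
  }
  strictly_pos <- c("sigma_a_wake", "sigma_a_sleep", "tau_a", "mu_h", "mu_c",
                    "m", "t_a", "n", "t_h", "sigma_g", "tau_g",
                    "tau_w_h", "tau_w_c", "eta_h", "eta_c", "tau_s", "dt",
                    "recall_ceiling", "train_item_duration",
                    "recall_cue_duration", "sleep_cue_duration",
                    "swo_frequency", "up_state_duration")
  for (nm in strictly_pos)
    if (num1(nm) <= 0) stop("parameter '", nm, "' must be > 0", call. = FALSE)
  nonneg <- c("gamma", "alpha", "zeta", "beta", "theta", "kappa",
              "lambda_wake", "lambda_sleep", "null_salience",
              "train_input_level", "recall_cue_level", "sleep_cue_amplitude",
              "inter_stimulus_interval", "inter_trial_gap",
              "coactivation_threshold")
  for (nm in nonneg)
    if (num1(nm) < 0) stop("parameter '", nm, "' must be >= 0", call. = FALSE)
  if (p$Q < 0 || p$Q > 1) stop("Q must lie in [0, 1]", call. = FALSE)
  if (p$recall_threshold <= 0 || p$recall_threshold >= 1)
    stop("recall_threshold must lie in (0, 1)", call. = FALSE)
  if (p$dt >= p$up_state_duration)
    stop("dt must be smaller than up_state_duration", call. = FALSE)
  if (p$up_states_per_night < 1 || p$up_states_per_night != round(p$up_states_per_night))
    stop("up_states_per_night must be a positive integer", call. = FALSE)
  if (p$up_state_duration > 1 / p$swo_frequency)
    stop("up_state_duration cannot exceed one SWO cycle", call. = FALSE)
  if (p$eta_h <= p$eta_c)
    stop("the hippocampus must learn faster than the cortex (eta_h > eta_c)",
         call. = FALSE)
  if (p$tau_w_h_eff >= p$tau_w_c_eff)
    stop("the hippocampus must forget faster than the cortex ",
         "(effective tau_w_h < tau_w_c)", call. = FALSE)
  invisible(p)
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params>\n")
  cat(sprintf("  activation time constant: %.3g s (wake), %.3g s (sleep)\n",
              x$sigma_a_wake * x$tau_a, x$sigma_a_sleep * x$tau_a))
  cat(sprintf("  learning rates eta (HC/CTX): %g / %g\n", x$eta_h, x$eta_c))
  cat(sprintf("  weight decay (HC/CTX): %.3g / %.3g days\n",
              x$tau_w_h_eff / 86400, x$tau_w_c_eff / 86400))
  cat(sprintf("  salience decay: %g s; null salience: %g\n",
              x$tau_s, x$null_salience))
  cat(sprintf("  SWS: %d UP states of %g s at %g Hz per night\n",
              as.integer(x$up_states_per_night), x$up_state_duration,
              x$swo_frequency))
  invisible(x)
}

# internal helpers
sigma_a_for <- function(params, mode) {
  if (identical(mode, "sleep")) params$sigma_a_sleep else params$sigma_a_wake
}
lambda_for <- function(params, mode) {
  if (identical(mode, "sleep")) params$lambda_sleep else params$lambda_wake
}
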