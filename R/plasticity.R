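#' Instantiate associative links between co-active items
#'
#' During waking training, a directional link pair is created (in both
#' directions, at weight zero) between every two items whose activations
#' both exceed the coactivation threshold and that are not yet linked.
#' Each region's own activations decide that region's links. Links are
#' only ever created while external training input is being presented;
#' existing links are strengthened at other times but new ones do not
#' appear during recall or sleep.
#'
#' @param state A [network_state()].
#' @param params A [model_params()].
#' @param external_training_active Logical; no-op when `FALSE`.
#' @return The updated state.
#' @export
instantiate_links <- function(state, params, external_training_active = TRUE) {
  if (!isTRUE(external_training_active)) return(state)
  thr <- params$coactivation_threshold
  link_region <- function(r) {
    act <- r$a > thr
    if (sum(act) < 2) return(r)
    co <- outer(act, act, `&`)
    diag(co) <- FALSE
    r$exists <- r$exists | co
    r
  }
  state$ctx <- link_region(state$ctx)
  state$hc <- link_region(state$hc)
  state
}

eta_for <- function(region, params) {
  if (identical(region$tag, "HC")) params$eta_h else params$eta_c
}
tau_w_eff_for <- function(region, params) {
  if (identical(region$tag, "HC")) params$tau_w_h_eff else params$tau_w_c_eff
}

#' Causal rate-based weight update
#'
#' One Euler step of the learning rule on every existing link x -> y:
#' the Hebbian term is the presynaptic activation times `(1 - w)` times a
#' rectified function of the postsynaptic rate of change — potentiation
#' when the postsynaptic activation is rising, depression (scaled by `Q`)
#' when it is falling. This makes the learned links causal: forward
#' associations in a sequence grow while reverse ones are suppressed.
#' Passive decay toward zero at the region's effective decay constant is
#' applied whether or not learning is enabled. Weights are clamped to
#' \[0, 1\] and stay identically zero outside the link mask.
#'
#' @param region A [region_state()].
#' @param a Presynaptic activation vector (pre-update state).
#' @param dadt Analytic activation derivatives from [step_network()].
#' @param params A [model_params()].
#' @param dt Integration step.
#' @param learning_on Logical; gates the Hebbian/depression term only.
#' @return The updated region.
#' @export
update_weights <- function(region, a, dadt, params, dt = params$dt,
                           learning_on = TRUE) {
  n <- length(region$a)
  if (length(a) != n || length(dadt) != n)
    stop("a/dadt length must match the region size")
  W <- region$W
  dW <- -W / tau_w_eff_for(region, params)
  if (isTRUE(learning_on)) {
    phi <- pmax(dadt, 0) - params$Q * pmax(-dadt, 0)
    dW <- dW + eta_for(region, params) * outer(a, phi) * (1 - W)
  }
  W_new <- W + dt * dW
  if (any(!is.finite(W_new[region$exists])))
    stop("numerical instability in ", region$tag, " weight update")
  W_new <- pmin(pmax(W_new, 0), 1)
  W_new[!region$exists] <- 0
  region$W <- W_new
  region
}

#' Closed-form passive weight decay
#'
#' Exact solution of the decay-only limit of the learning rule, used to
#' fast-forward idle periods during which no items are active: every
#' weight is scaled by `exp(-elapsed / tau_eff)` with the region's
#' effective decay constant. The link mask is unchanged (links persist
#' even as their weights fade).
#'
#' @param region A [region_state()].
#' @param elapsed Idle duration in seconds (>= 0).
#' @param params A [model_params()].
#' @return The updated region.
#' @export
decay_weights_closed_form <- function(region, elapsed, params) {
  if (!is.numeric(elapsed) || length(elapsed) != 1L || is.na(elapsed) || elapsed < 0)
    stop("elapsed must be a non-negative duration")
  region$W <- region$W * exp(-elapsed / tau_w_eff_for(region, params))
  region$W[!region$exists] <- 0
  region
}
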