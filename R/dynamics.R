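#' Net excitatory input to each item
#'
#' Sum of the feedforward drive (input register for cortex, cortical
#' activation for hippocampus, scaled by the regional gain mu), the
#' learned spreading excitation through directional weights, sigmoidal
#' self-excitation, and — for the cortex — rectified hippocampal feedback
#' supplied through `feedback`.
#'
#' @param region A [region_state()].
#' @param feedforward Numeric vector of feedforward drive, one entry per
#'   item (unscaled; the regional gain is applied here).
#' @param feedback Numeric vector added to the excitation (zero for the
#'   hippocampus; `zeta * pmax(h, 0)` for the cortex, zero when lesioned).
#' @param params A [model_params()].
#' @return Numeric vector `E` of net excitation, elementwise >= 0 for
#'   admissible states.
#' @export
#' @examples
#' r <- region_state(2, "CTX")
#' excitatory_input(r, feedforward = c(0.1, 0), feedback = c(0, 0), model_params())
excitatory_input <- function(region, feedforward, feedback, params) {
  n <- length(region$a)
  if (length(feedforward) != n || length(feedback) != n)
    stop("feedforward/feedback length must match the region size")
  mu <- if (identical(region$tag, "HC")) params$mu_h else params$mu_c
  a <- region$a
  am <- a^params$m
  self_exc <- params$alpha * am / (am + params$t_a^params$m)
  spread <- as.vector(crossprod(region$W, a))
  mu * feedforward + params$gamma * spread + self_exc + feedback
}

#' Net inhibitory input to each item
#'
#' Fixed lateral inhibition from all other items plus the sigmoidal
#' self-inhibition driven by the item's inactivation current, which
#' terminates prolonged activations.
#'
#' @inheritParams excitatory_input
#' @return Numeric vector `I`, elementwise >= 0.
#' @export
inhibitory_input <- function(region, params) {
  a <- region$a
  gn <- region$g^params$n
  params$beta * (sum(a) - a) + params$theta * gn / (gn + params$t_h^params$n)
}

#' One synchronous Euler step of the coupled network
#'
#' Advances activations and inactivation currents of both regions by one
#' forward-Euler step. All derivatives are evaluated at the previous-step
#' state: the hippocampus sees the previous-step cortical activation as
#' feedforward drive, and the cortex sees the previous-step hippocampal
#' activation as feedback (unless lesioned). States are clamped to
#' \[0, 1\] after the update. The analytic derivatives `da/dt` (the
#' shunting right-hand side divided by the mode's sigma_a, at the
#' pre-update state) are returned for use by the learning rule.
#'
#' This is the definitional reference step; long simulations run the same
#' update in compiled code.
#'
#' @param state A [network_state()].
#' @param input_register Numeric vector of input-register drive to the
#'   cortex (training level, recall cue, sleep pulse, or zero).
#' @param params A [model_params()].
#' @param dt Integration step; must equal `params$dt`.
#' @return A list with elements `state`, `dadt_ctx`, `dadt_hc`.
#' @export
step_network <- function(state, input_register, params, dt = params$dt) {
  n <- length(state$catalog)
  if (length(input_register) != n)
    stop("input_register length must match the item catalog")
  if (!isTRUE(all.equal(dt, params$dt)))
    stop("dt must equal params$dt")
  sig_a <- sigma_a_for(params, state$mode)

  fb <- if (state$hc_to_ctx_enabled) params$zeta * pmax(state$hc$a, 0) else numeric(n)
  E_c <- excitatory_input(state$ctx, input_register, fb, params)
  I_c <- inhibitory_input(state$ctx, params)
  E_h <- excitatory_input(state$hc, state$ctx$a, numeric(n), params)
  I_h <- inhibitory_input(state$hc, params)

  a_c <- state$ctx$a; a_h <- state$hc$a
  dadt_c <- (-a_c / params$tau_a + (1 - a_c) * E_c - a_c * I_c) / sig_a
  dadt_h <- (-a_h / params$tau_a + (1 - a_h) * E_h - a_h * I_h) / sig_a
  dgdt_c <- (-state$ctx$g / params$tau_g +
               (1 - state$ctx$g) * params$kappa * a_c) / params$sigma_g
  dgdt_h <- (-state$hc$g / params$tau_g +
               (1 - state$hc$g) * params$kappa * a_h) / params$sigma_g

  a_c_new <- a_c + dt * dadt_c
  a_h_new <- a_h + dt * dadt_h
  bad <- which(!is.finite(a_c_new) | !is.finite(a_h_new))
  if (length(bad))
    stop("numerical instability at item '", state$catalog[bad[1]], "'")

  clamp01 <- function(x) pmin(pmax(x, 0), 1)
  state$ctx$a <- clamp01(a_c_new)
  state$hc$a <- clamp01(a_h_new)
  state$ctx$g <- clamp01(state$ctx$g + dt * dgdt_c)
  state$hc$g <- clamp01(state$hc$g + dt * dgdt_h)

  list(state = state, dadt_ctx = dadt_c, dadt_hc = dadt_h)
}
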