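#' Signed leaky integrate-and-fire neuron with linear leakage
#'
#' The event-driven neuron model used throughout the network. Between input
#' events the membrane decays *linearly* toward the resting level
#' `memb_reset` at rate `(th_plus - memb_reset) / tl_plus` per microsecond
#' when above rest and `(memb_reset - th_minus) / tl_minus` when below,
#' clamped at rest (it never overshoots). On an input event the leak is
#' applied first and the membrane is then updated instantaneously by
#' `sign * weight` (delta-dirac synapse). Reaching `th_plus` (inclusive)
#' emits a `+1` spike and resets to `memb_reset`; reaching `th_minus` resets
#' and emits a `-1` spike only when `emit_negative` is `TRUE` (the degenerate
#' positive-only variant used by the classifier layer resets silently).
#'
#' When `th_minus` is the sentinel `-2^31` (used to disable negative
#' spiking), the below-rest leak slope uses the symmetric magnitude
#' `(th_plus - memb_reset) / tl_minus` rather than the astronomically large
#' literal value: the sentinel's purpose is to disable negative spikes, not
#' to set a leak slope.
#'
#' Membrane values are integers held in doubles (exact up to 2^53, far above
#' the 1e7-8e8 thresholds in use).
#'
#' @param memb_reset resting level (default 0).
#' @param th_plus positive threshold (> `memb_reset`).
#' @param th_minus negative threshold (< `memb_reset`); `-2^31` disables the
#'   negative side entirely.
#' @param tl_plus,tl_minus leakage time constants in microseconds: the time a
#'   membrane at threshold takes to decay back to rest. `Inf` disables leak.
#' @param refractory_us refractory period in microseconds (default 0):
#'   inputs arriving within it are discarded.
#' @param emit_negative emit `-1` spikes at `th_minus` (default `FALSE`).
#' @return a `neuron_params` list.
#' @export
neuron_params <- function(th_plus, th_minus = -th_plus, memb_reset = 0,
                          tl_plus = Inf, tl_minus = tl_plus,
                          refractory_us = 0, emit_negative = FALSE) {
  tl_minus <- abs(tl_minus)  # a negative time constant is read as magnitude
  th_minus_eff <- if (th_minus <= -2^31) -(th_plus - memb_reset) + memb_reset else th_minus
  stopifnot(th_plus > memb_reset, th_minus < memb_reset,
            tl_plus > 0, tl_minus > 0, refractory_us >= 0)
  structure(list(memb_reset = memb_reset, th_plus = th_plus,
                 th_minus = th_minus,
                 slope_plus = (th_plus - memb_reset) / tl_plus,
                 slope_minus = (memb_reset - th_minus_eff) / tl_minus,
                 tl_plus = tl_plus, tl_minus = tl_minus,
                 refractory_us = refractory_us,
                 emit_negative = isTRUE(emit_negative)),
            class = "neuron_params")
}

#' @rdname neuron_params
#' @param t0 time of state creation (microseconds).
#' @return `lif_state()` returns a fresh `NeuronState`: membrane at rest,
#'   `t_last = t0`, not refractory.
#' @export
lif_state <- function(params, t0 = 0) {
  list(vm = params$memb_reset, t_last = t0, t_refrac_end = -Inf)
}

#' @rdname neuron_params
#' @param state a state from [lif_state()].
#' @param params a `neuron_params`.
#' @param t_now current time in microseconds (`>= state$t_last`).
#' @return `lif_leak()` returns the state with the linear leak applied over
#'   `[t_last, t_now]` and `t_last` advanced.
#' @export
lif_leak <- function(state, params, t_now) {
  stopifnot(t_now >= state$t_last)
  dt <- t_now - state$t_last
  state$t_last <- t_now
  rest <- params$memb_reset
  if (dt > 0 && state$vm != rest) {
    if (state$vm > rest) {
      state$vm <- max(rest, state$vm - params$slope_plus * dt)
    } else {
      state$vm <- min(rest, state$vm + params$slope_minus * dt)
    }
  }
  state
}

#' @rdname neuron_params
#' @param weight synaptic weight of the activated connection.
#' @param sign sign of the presynaptic spike (`+1` or `-1`); the update is
#'   `sign * weight`.
#' @return `lif_receive()` returns `list(state, spike)` where `spike` is
#'   `+1`, `-1`, or `0` (no output).
#' @export
lif_receive <- function(state, params, weight, sign, t_now) {
  state <- lif_leak(state, params, t_now)
  if (t_now < state$t_refrac_end) {
    return(list(state = state, spike = 0))
  }
  state$vm <- state$vm + sign * weight
  spike <- 0
  if (state$vm >= params$th_plus) {
    spike <- 1
    state$vm <- params$memb_reset
    state$t_refrac_end <- t_now + params$refractory_us
  } else if (state$vm <= params$th_minus) {
    if (params$emit_negative) spike <- -1
    state$vm <- params$memb_reset
    state$t_refrac_end <- t_now + params$refractory_us
  }
  list(state = state, spike = spike)
}

#' Run one neuron over a weighted event train
#'
#' Reference (pure R) event-driven simulation of a single neuron: each row of
#' `train` is an input event with columns `t` (non-decreasing), `weight`, and
#' `sign`. Used as the unit under test against the clock-driven oracle and by
#' the generic scheduler modules.
#'
#' @param train data frame with columns `t`, `weight`, `sign`.
#' @inheritParams neuron_params
#' @param params a [neuron_params()].
#' @return tibble with one row per input event: `t`, `vm` (membrane after the
#'   update), `spike` (emitted sign or 0).
#' @export
lif_run <- function(train, params) {
  n <- nrow(train)
  vm <- numeric(n); sp <- numeric(n)
  st <- lif_state(params)
  for (i in seq_len(n)) {
    r <- lif_receive(st, params, train$weight[i], train$sign[i], train$t[i])
    st <- r$state
    vm[i] <- st$vm
    sp[i] <- r$spike
  }
  tibble(t = train$t, vm = vm, spike = sp)
}
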